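# Community assembly statistics: the taxonomic normalized stochasticity ratio
# (tNST, in its observed-vs-null exceedance form), Mantel and partial Mantel
# tests, and multiple regression on distance matrices (MRM) with an
# abiotic/biotic/unexplained variance partition.

#' Taxonomic normalized stochasticity ratio (exceedance form)
#'
#' For every within-group pair of samples, builds `null_reps` randomized
#' communities and computes the proportion of (pair, replicate) comparisons
#' in which the observed Bray-Curtis dissimilarity exceeds the null
#' dissimilarity. The null model conserves each sample's richness, draws taxa
#' from the group's pool with probability proportional to their occurrence
#' frequency, and reassigns the sample's own rank-abundance profile to the
#' drawn taxa. Values above 0.5 indicate predominantly stochastic assembly,
#' below 0.5 predominantly deterministic assembly.
#'
#' Note this implements the exceedance-proportion definition directly; the
#' wider NST literature offers several related null models and
#' normalizations, so output is tagged `method = "exceedance-tNST"`.
#'
#' @param table a [community_table()] or samples x taxa count matrix.
#' @param group optional group label: if given, only samples of that group
#'   (per `table$samples$group`) are used; otherwise all samples form one
#'   group.
#' @param null_reps null replicates per pair (default 200, >= 100 enforced).
#' @param seed integer seed.
#' @param pool_freq optional known taxon occurrence-frequency weights for the
#'   null model (named by taxon id, or one value per table column). By
#'   default frequencies are estimated from the group itself; supplying the
#'   generating weights makes the null exactly self-consistent, which is how
#'   the calibration tests exercise it.
#' @return list of class `nst_result`: `group`, `tnst`, `n_pairs`, `n_null`,
#'   `interpretation` (`"stochastic"` if > 0.5 else `"deterministic"`),
#'   `method`.
#' @export
tnst <- function(table, group = NULL, null_reps = 200, seed = 1,
                 pool_freq = NULL) {
  if (null_reps < 100) abort_fmt("null_reps must be >= 100")
  if (inherits(table, "community_table")) {
    m <- table$counts
    if (!is.null(group)) {
      keep <- table$samples$group == group
      if (sum(keep) < 2) abort_fmt("group '%s' has fewer than 2 samples", group)
      m <- m[keep, , drop = FALSE]
    }
  } else {
    m <- as.matrix(table)
  }
  if (nrow(m) < 2) abort_fmt("need at least 2 samples")
  if (!is.null(pool_freq) && !is.null(names(pool_freq)))
    pool_freq <- pool_freq[colnames(m)]
  pool <- which(colSums(m > 0) > 0 | (pool_freq %||% 0) > 0)
  m <- m[, pool, drop = FALSE]
  n <- nrow(m)
  freq <- if (is.null(pool_freq)) colSums(m > 0) / n else pool_freq[pool]
  if (anyNA(freq) || any(freq < 0)) abort_fmt("invalid pool_freq")
  rel <- m / rowSums(m)
  obs <- as.matrix(vegan::vegdist(rel, method = "bray"))
  pair_idx <- which(lower.tri(obs))
  obs_v <- obs[pair_idx]
  n_taxa <- ncol(m)
  profiles <- lapply(seq_len(n), function(i) sort(m[i, m[i, ] > 0],
                                                  decreasing = TRUE))
  rich <- vapply(profiles, length, 1L)
  exceed <- 0
  with_seed(derive_seed(seed, 809), {
    for (b in seq_len(null_reps)) {
      null <- matrix(0, n, n_taxa)
      for (i in seq_len(n)) {
        k <- min(rich[i], n_taxa)
        tx <- sample.int(n_taxa, k, prob = freq)
        null[i, tx] <- profiles[[i]][seq_len(k)]
      }
      nrel <- null / rowSums(null)
      nd <- as.matrix(vegan::vegdist(nrel, method = "bray"))[pair_idx]
      exceed <- exceed + sum(obs_v > nd)
    }
  })
  tnst_v <- exceed / (length(pair_idx) * null_reps)
  structure(list(group = group %||% "all", tnst = tnst_v,
                 n_pairs = length(pair_idx), n_null = null_reps,
                 interpretation = if (tnst_v > 0.5) "stochastic"
                                  else "deterministic",
                 method = "exceedance-tNST"),
            class = "nst_result")
}

.mantel_r <- function(v1, v2, method) {
  # degenerate residuals (e.g. partialling a matrix out of itself) carry no
  # association: report r = 0 rather than 0/0
  if (stats::sd(v1) < 1e-12 * max(abs(v1), 1) ||
      stats::sd(v2) < 1e-12 * max(abs(v2), 1)) return(0)
  stats::cor(v1, v2, method = method)
}

#' Mantel and partial Mantel tests
#'
#' r is the correlation of the off-diagonal (lower-triangle) vectors of two
#' distance matrices. For the partial test, both vectors are replaced by
#' their residuals after linear regression on the third matrix's vector. The
#' one-sided p-value permutes rows/columns of `d1` jointly:
#' p = (1 + #\{permuted r >= observed r\}) / (1 + permutations).
#'
#' @param d1,d2 `dist` objects or distance matrices over the same samples.
#' @param permutations number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @param partial_on optional third distance matrix to partial out.
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `p`, `permutations`, `partial` (logical).
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = 1,
                        partial_on = NULL, method = "pearson") {
  if (permutations < 99) abort_fmt("permutations must be >= 99")
  m1 <- as.matrix(stats::as.dist(d1))
  m2 <- as.matrix(stats::as.dist(d2))
  if (!all(dim(m1) == dim(m2))) abort_fmt("distance matrices must match")
  lt <- lower.tri(m1)
  v2 <- m2[lt]
  resid_on <- NULL
  if (!is.null(partial_on)) {
    m3 <- as.matrix(stats::as.dist(partial_on))
    if (!all(dim(m3) == dim(m1))) abort_fmt("partial matrix must match")
    v3 <- m3[lt]
    v2 <- stats::lm.fit(cbind(1, v3), v2)$residuals
    resid_on <- v3
  }
  stat <- function(mm) {
    v1 <- mm[lt]
    if (!is.null(resid_on))
      v1 <- stats::lm.fit(cbind(1, resid_on), v1)$residuals
    .mantel_r(v1, v2, method)
  }
  r_obs <- stat(m1)
  n <- nrow(m1)
  with_seed(derive_seed(seed, 910), {
    exceed <- 0L
    for (b in seq_len(permutations)) {
      i <- sample.int(n)
      if (stat(m1[i, i]) >= r_obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + permutations)
  })
  list(r = r_obs, p = p, permutations = permutations,
       partial = !is.null(partial_on))
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the response matrix's lower-triangle vector on
#' the predictors' vectors. Coefficient significance comes from permuting the
#' response matrix's rows/columns jointly and comparing |t| statistics;
#' the model p-value compares R^2.
#'
#' @param response `dist` or distance matrix.
#' @param predictors named list of `dist`/distance matrices.
#' @param permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `coefficients` (data.frame: term, estimate, t, p),
#'   `r_squared`, `p_model`, `permutations`.
#' @export
mrm <- function(response, predictors, permutations = 999, seed = 1) {
  if (!length(predictors)) abort_fmt("need at least one predictor")
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("X", seq_along(predictors))
  my <- as.matrix(stats::as.dist(response))
  lt <- lower.tri(my)
  X <- cbind(`(Intercept)` = 1,
             vapply(predictors,
                    function(p) as.matrix(stats::as.dist(p))[lt],
                    numeric(sum(lt))))
  n <- nrow(my)
  fit_stats <- function(y) {
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    tss <- sum((y - mean(y))^2)
    sigma2 <- rss / (length(y) - ncol(X))
    XtXinv <- chol2inv(chol(crossprod(X)))
    tval <- f$coefficients / sqrt(diag(XtXinv) * sigma2)
    list(coef = f$coefficients, t = tval,
         r2 = if (tss > 0) 1 - rss / tss else NA_real_)
  }
  obs <- fit_stats(my[lt])
  with_seed(derive_seed(seed, 1011), {
    exceed_t <- numeric(ncol(X))
    exceed_r2 <- 0L
    for (b in seq_len(permutations)) {
      i <- sample.int(n)
      s <- fit_stats(my[i, i][lt])
      exceed_t <- exceed_t + (abs(s$t) >= abs(obs$t))
      if (s$r2 >= obs$r2) exceed_r2 <- exceed_r2 + 1L
    }
    p_t <- (1 + exceed_t) / (1 + permutations)
    p_model <- (1 + exceed_r2) / (1 + permutations)
  })
  list(coefficients = data.frame(term = colnames(X),
                                 estimate = unname(obs$coef),
                                 t = unname(obs$t),
                                 p = unname(p_t),
                                 stringsAsFactors = FALSE),
       r_squared = obs$r2, p_model = p_model, permutations = permutations)
}

#' Abiotic/biotic/unexplained variance partition from MRM
#'
#' Fits three MRMs (abiotic predictors only, biotic only, both) and splits
#' the full model's R^2 by averaging the two sequential decompositions, so
#' abiotic + biotic + unexplained = 1 exactly:
#' abiotic = (R2_a + R2_full - R2_b) / 2, biotic analogously,
#' unexplained = 1 - R2_full.
#'
#' @param response `dist` or distance matrix.
#' @param abiotic,biotic named lists of predictor distance matrices.
#' @param permutations,seed passed to [mrm()].
#' @return list with `partition` (named numeric: abiotic, biotic,
#'   unexplained), `p_abiotic`, `p_biotic` (marginal model permutation
#'   p-values), and the three fitted models.
#' @export
mrm_partition <- function(response, abiotic, biotic, permutations = 999,
                          seed = 1) {
  fit_a <- mrm(response, abiotic, permutations, derive_seed(seed, 1))
  fit_b <- mrm(response, biotic, permutations, derive_seed(seed, 2))
  fit_f <- mrm(response, c(abiotic, biotic), permutations,
               derive_seed(seed, 3))
  r2a <- fit_a$r_squared; r2b <- fit_b$r_squared; r2f <- fit_f$r_squared
  part <- c(abiotic = (r2a + r2f - r2b) / 2,
            biotic = (r2b + r2f - r2a) / 2,
            unexplained = 1 - r2f)
  list(partition = part, p_abiotic = fit_a$p_model, p_biotic = fit_b$p_model,
       models = list(abiotic = fit_a, biotic = fit_b, full = fit_f))
}
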