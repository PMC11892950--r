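# Dissimilarity, ordination and dispersion statistics for community
# comparison. Bray-Curtis and Sorensen dissimilarities are delegated to
# vegan::vegdist; classical-scaling PCoA to stats::cmdscale. Group dispersion
# (mean distance to group centroid in PCoA space, with the negative-eigenvalue
# correction) is implemented here so the permutation scheme and seed are
# explicit; vegan::betadisper serves as an independent cross-check in the
# test suite.

.as_counts <- function(table) {
  m <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  if (any(m < 0)) abort_fmt("negative abundances")
  if (any(rowSums(m) == 0))
    abort_fmt("all-zero sample: '%s'",
              rownames(m)[which(rowSums(m) == 0)[1L]] %||% "?")
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y).
#'
#' @param table a [community_table()] or samples x taxa matrix.
#' @param relative normalize rows to relative abundances first
#'   (default FALSE).
#' @return a `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(table, relative = FALSE) {
  m <- .as_counts(table)
  if (relative) m <- m / rowSums(m)
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Sorensen dissimilarity matrix (presence/absence)
#'
#' d = 1 - 2a / (2a + b + c) where a is the number of shared taxa and b, c
#' the numbers unique to each sample.
#'
#' @param table a [community_table()] or samples x taxa matrix.
#' @return a `dist` object with attribute `metric = "sorensen"`.
#' @export
sorensen <- function(table) {
  m <- .as_counts(table)
  d <- vegan::vegdist(m, method = "bray", binary = TRUE)
  attr(d, "metric") <- "sorensen"
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared-distance matrix and eigendecomposes it; axes
#' are ordered by eigenvalue and negative eigenvalues (from non-Euclidean
#' dissimilarities) are reported.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param k number of axes to return (default 2, capped at n - 1).
#' @return list with `points` (n x k coordinates), `eigenvalues` (all n),
#'   `negative` (the negative eigenvalues) and `variance_explained`
#'   (positive-eigenvalue fractions).
#' @export
pcoa <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  k <- min(k, n - 1L)
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pos <- fit$eig[fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))]
  pts <- fit$points
  if (ncol(pts) < k) { # pad if fewer positive axes than requested
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  neg_tol <- sqrt(.Machine$double.eps) * max(abs(fit$eig), 1)
  list(points = pts, eigenvalues = fit$eig,
       negative = fit$eig[fit$eig < -neg_tol],
       variance_explained = pos / sum(pos))
}

# Full PCoA embedding retaining real and imaginary axes; squared distances in
# the embedding are sum(real^2) - sum(imag^2) (Gower/McArdle-Anderson
# correction for negative eigenvalues).
.pcoa_embed <- function(d) {
  d <- as.matrix(stats::as.dist(d))
  n <- nrow(d)
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- sqrt(.Machine$double.eps) * max(abs(e$values))
  real <- e$values > tol
  imag <- e$values < -tol
  list(real = e$vectors[, real, drop = FALSE] %*%
         diag(sqrt(e$values[real]), sum(real)),
       imag = e$vectors[, imag, drop = FALSE] %*%
         diag(sqrt(-e$values[imag]), sum(imag)))
}

.dispersion_stats <- function(emb, groups) {
  groups <- as.factor(groups)
  zz <- numeric(length(groups))
  for (g in levels(groups)) {
    i <- which(groups == g)
    cr <- colMeans(emb$real[i, , drop = FALSE])
    ci <- if (ncol(emb$imag)) colMeans(emb$imag[i, , drop = FALSE]) else numeric(0)
    d2 <- rowSums(sweep(emb$real[i, , drop = FALSE], 2, cr)^2)
    if (length(ci))
      d2 <- d2 - rowSums(sweep(emb$imag[i, , drop = FALSE], 2, ci)^2)
    zz[i] <- sqrt(pmax(0, d2))
  }
  means <- tapply(zz, groups, mean)
  k <- nlevels(groups)
  n <- length(zz)
  gm <- mean(zz)
  ssb <- sum(tapply(zz, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum((zz - means[groups])^2)
  f <- if (ssw > 0) (ssb / (k - 1)) / (ssw / (n - k)) else Inf
  list(distances = zz, means = means, F = f)
}

#' Within-group dispersion: mean distance to group centroid
#'
#' Embeds the samples by PCoA (retaining imaginary axes; squared distances
#' use the real^2 - imag^2 correction), computes each sample's distance to
#' its group centroid, and compares groups with a one-way F statistic whose
#' p-value comes from permuting group labels (centroids and distances are
#' recomputed for every permutation).
#'
#' @param d a `dist` object or distance matrix.
#' @param groups group label per sample (>= 2 samples per group).
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `group_means` (named mean distance to centroid),
#'   `distances` (per sample), `F`, `p` (add-one permutation p-value),
#'   `permutations`.
#' @export
group_dispersion <- function(d, groups, permutations = 999, seed = 1) {
  dm <- as.matrix(stats::as.dist(d))
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm))
    abort_fmt("groups length != number of samples")
  if (any(table(groups) < 2)) abort_fmt("every group needs >= 2 samples")
  emb <- .pcoa_embed(dm)
  obs <- .dispersion_stats(emb, groups)
  p <- NA_real_
  if (nlevels(groups) > 1L && permutations > 0) {
    with_seed(derive_seed(seed, 708), {
      exceed <- 0L
      for (b in seq_len(permutations)) {
        gp <- sample(groups)
        if (.dispersion_stats(emb, gp)$F >= obs$F) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (1 + permutations)
    })
  }
  list(group_means = obs$means, distances = obs$distances, F = obs$F,
       p = p, permutations = permutations)
}
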