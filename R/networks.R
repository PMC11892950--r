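# Co-occurrence molecular ecological networks: prevalence-filtered Spearman
# correlations on log-transformed relative abundances, thresholded either at a
# fixed |r| or by a random-matrix-theory (RMT) scan of the eigenvalue
# nearest-neighbour spacing distribution; per-sample sub-networks and
# topological properties via igraph.

#' Build a co-occurrence network from an abundance table
#'
#' Taxa detected in fewer than `min_prevalence` samples are removed; Spearman
#' correlations are computed on log(relative abundance + pseudocount) where
#' the pseudocount is half the smallest nonzero relative abundance; taxon
#' pairs with |r| >= threshold become edges (weight |r|, sign retained).
#'
#' @param table a [community_table()] or samples x taxa matrix.
#' @param min_prevalence minimum number of samples a taxon must be detected
#'   in (default 6, the "at least 6 out of 12 samples" rule).
#' @param threshold numeric |r| cutoff in (0, 1), or `"rmt"` to choose it
#'   with [rmt_threshold()].
#' @param rmt_scan scan grid passed to [rmt_threshold()] when
#'   `threshold = "rmt"`.
#' @return an igraph graph with vertex attribute `name` (taxon id), edge
#'   attributes `weight` (|r|), `r` and `sign`; graph attributes `threshold`,
#'   `min_prevalence`, `pseudocount`.
#' @export
build_network <- function(table, min_prevalence = 6, threshold = "rmt",
                          rmt_scan = seq(0.5, 0.95, by = 0.025)) {
  m <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  if (nrow(m) < 4) abort_fmt("need >= 4 samples")
  if (min_prevalence > nrow(m))
    abort_fmt("min_prevalence exceeds the number of samples")
  keep <- colSums(m > 0) >= min_prevalence
  if (sum(keep) < 2) abort_fmt("fewer than 2 taxa survive the prevalence filter")
  m <- m[, keep, drop = FALSE]
  rel <- m / rowSums(m)
  nz <- rel[rel > 0]
  pseudo <- min(nz) / 2
  lg <- log(rel + pseudo)
  r <- suppressWarnings(stats::cor(lg, method = "spearman"))
  r[is.na(r)] <- 0
  thr <- threshold
  if (identical(threshold, "rmt"))
    thr <- rmt_threshold(abs(r), scan = rmt_scan)
  if (!is.numeric(thr) || thr <= 0 || thr >= 1)
    abort_fmt("threshold must lie in (0, 1) or be \"rmt\"")
  a <- abs(r)
  diag(a) <- 0
  adj <- a >= thr
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    rv <- r[cbind(el[, 1], el[, 2])]
    igraph::E(g)$r <- rv
    igraph::E(g)$weight <- abs(rv)
    igraph::E(g)$sign <- ifelse(rv >= 0, "positive", "negative")
  }
  g <- igraph::set_graph_attr(g, "threshold", thr)
  g <- igraph::set_graph_attr(g, "min_prevalence", min_prevalence)
  g <- igraph::set_graph_attr(g, "pseudocount", pseudo)
  g
}

# Smooth the eigenvalue staircase and return nearest-neighbour spacings with
# unit mean (spectral unfolding via a smoothing spline on the empirical CDF).
.unfold_spacings <- function(ev) {
  ev <- sort(ev)
  # collapse numerically identical eigenvalues (degenerate multiplets carry
  # no spacing information)
  ev <- ev[c(TRUE, diff(ev) > 1e-10)]
  n <- length(ev)
  if (n < 10) return(NULL)
  cdf <- (seq_len(n) - 0.5) / n
  df <- min(10, max(4, floor(n / 10)))
  sm <- stats::smooth.spline(ev, cdf, df = df)
  unfolded <- n * stats::predict(sm, ev)$y
  sp <- diff(unfolded)
  sp <- sp[sp > 0]
  if (!length(sp)) return(NULL)
  sp / mean(sp)
}

# Chi-square goodness-of-fit p-value of spacings against the Poisson
# (exponential, mean 1) nearest-neighbour spacing distribution.
.poisson_nnsd_p <- function(sp, n_bins = 10) {
  if (is.null(sp) || length(sp) < 20) return(NA_real_)
  qs <- stats::qexp(seq(0, 1, length.out = n_bins + 1))
  qs[n_bins + 1] <- Inf
  obs <- table(cut(sp, qs, include.lowest = TRUE))
  expected <- length(sp) / n_bins
  chi2 <- sum((as.numeric(obs) - expected)^2 / expected)
  stats::pchisq(chi2, df = n_bins - 1, lower.tail = FALSE)
}

#' Random-matrix-theory threshold for a similarity matrix
#'
#' Scans candidate thresholds; for each, entries of the |r| matrix below the
#' threshold are zeroed (rows/columns left with no super-threshold neighbour
#' are dropped), the eigenvalues are unfolded, and the nearest-neighbour
#' spacing distribution is tested against the Poisson form by a chi-square
#' test. The smallest threshold whose spacing distribution is consistent with
#' Poisson (p > `alpha`) is returned: below the transition the spectrum shows
#' Wigner (GOE) level repulsion from correlated noise, above it the modular
#' signal yields independent (Poisson) spacings.
#'
#' If fewer than 10 distinct eigenvalues remain at some threshold, the matrix
#' is treated as trivially consistent with Poisson (independent eigenvalues).
#'
#' @param similarity symmetric |r| matrix with unit diagonal.
#' @param scan numeric vector of candidate thresholds in (0, 1).
#' @param alpha chi-square acceptance level (default 0.05).
#' @return the selected threshold (scalar).
#' @export
rmt_threshold <- function(similarity, scan = seq(0.5, 0.95, by = 0.025),
                          alpha = 0.05) {
  s <- as.matrix(similarity)
  if (any(scan <= 0 | scan >= 1)) abort_fmt("scan must lie within (0, 1)")
  for (thr in sort(scan)) {
    a <- s
    a[a < thr] <- 0
    off <- a
    diag(off) <- 0
    keep <- rowSums(off > 0) > 0
    if (sum(keep) < 2) return(thr)  # degenerate: no correlated pairs left
    a <- a[keep, keep, drop = FALSE]
    sp <- .unfold_spacings(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
    p <- .poisson_nnsd_p(sp)
    if (is.na(p) || p > alpha) return(thr)
  }
  abort_fmt(paste("no threshold in the scan yields Poisson spacings;",
                  "supply a fixed threshold"))
}

#' Per-sample sub-network
#'
#' Induced subgraph of the global network on the taxa with positive abundance
#' in one sample.
#'
#' @param net igraph graph from [build_network()].
#' @param abundances named numeric vector (taxon id -> abundance) for one
#'   sample.
#' @return igraph subgraph.
#' @export
sample_subnetwork <- function(net, abundances) {
  if (is.null(names(abundances)))
    abort_fmt("sample abundances must be named by taxon id")
  present <- names(abundances)[abundances > 0]
  nodes <- intersect(igraph::V(net)$name, present)
  igraph::induced_subgraph(net, nodes)
}

#' Topological properties of a network
#'
#' avgK = 2E/N; density = 2E/(N(N-1)); avgCC = mean local clustering
#' coefficient (nodes with degree < 2 contribute 0); GD = mean geodesic
#' distance over the largest connected component; modules and modularity by
#' greedy modularity maximization (Newman).
#'
#' @param net igraph graph.
#' @return data.frame with n_nodes, n_edges, avgK, avgCC, GD, n_modules,
#'   modularity, density.
#' @export
topology_properties <- function(net) {
  n <- igraph::vcount(net)
  if (n < 1) abort_fmt("network has no nodes")
  e <- igraph::ecount(net)
  avgK <- 2 * e / n
  density <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  avgCC <- if (n > 0) mean(cc) else NA_real_
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  gd <- if (igraph::vcount(sub) > 1)  # unweighted skeleton: hop counts
    igraph::mean_distance(sub, directed = FALSE, weights = NA) else NA_real_
  if (e > 0) {
    fc <- igraph::cluster_fast_greedy(net, weights = NA)
    n_mod <- length(unique(igraph::membership(fc)))
    mod <- igraph::modularity(fc)
  } else {
    n_mod <- n
    mod <- NA_real_
  }
  data.frame(n_nodes = n, n_edges = e, avgK = avgK, avgCC = avgCC, GD = gd,
             n_modules = n_mod, modularity = mod, density = density)
}

#' Topological properties of every sample's sub-network
#'
#' @param net global igraph network.
#' @param table the [community_table()] the network was built from (or any
#'   table over the same taxa).
#' @return data.frame keyed by sample_id.
#' @export
subnetwork_properties <- function(net, table) {
  stopifnot(inherits(table, "community_table"))
  res <- lapply(rownames(table$counts), function(sid) {
    sub <- sample_subnetwork(net, table$counts[sid, ])
    if (igraph::vcount(sub) == 0)
      return(NULL)
    cbind(sample_id = sid, topology_properties(sub))
  })
  do.call(rbind, res)
}

#' Write a network as an edge-list TSV (node1, node2, r, sign)
#'
#' @param net igraph graph.
#' @param path file path.
#' @export
write_network_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(node1 = el[, 1], node2 = el[, 2],
                   r = if (igraph::ecount(net)) igraph::E(net)$r else numeric(0),
                   sign = if (igraph::ecount(net)) igraph::E(net)$sign
                          else character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
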