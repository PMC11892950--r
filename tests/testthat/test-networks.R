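test_that("network construction applies prevalence filter and thresholds", {
  set.seed(10)
  n <- 12
  base <- rlnorm(n, 5, 1)
  m <- cbind(t1 = base, t2 = base * 2,            # perfectly rank-correlated
             t3 = rlnorm(n), t4 = rlnorm(n), t5 = rlnorm(n))
  rownames(m) <- paste0("s", 1:n)
  g <- build_network(m, min_prevalence = 6, threshold = 0.9)
  expect_true(igraph::are_adjacent(g, "t1", "t2"))
  e <- igraph::E(g)[igraph::V(g)["t1"] %--% igraph::V(g)["t2"]]
  expect_equal(e$weight, 1)
  expect_identical(e$sign, "positive")

  # a taxon present in only 5 of 12 samples is removed
  m2 <- m
  m2[6:12, "t3"] <- 0
  g2 <- build_network(m2, min_prevalence = 6, threshold = 0.9)
  expect_false("t3" %in% igraph::V(g2)$name)

  expect_error(build_network(m[1:3, ], min_prevalence = 2), ">= 4 samples")
  expect_error(build_network(m, min_prevalence = 13), "exceeds")
})

test_that("edge count under an iid-noise null matches a brute-force oracle", {
  # With 20 iid taxa over 10 samples, |spearman| >= threshold happens with a
  # small per-pair probability; compare the network's edge count to the same
  # count computed directly from the correlation matrix.
  set.seed(20)
  m <- matrix(rlnorm(10 * 20, 4, 0.5), 10, 20,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:20)))
  g <- build_network(m, min_prevalence = 6, threshold = 0.7)
  rel <- m / rowSums(m)
  lg <- log(rel + min(rel[rel > 0]) / 2)
  r <- cor(lg, method = "spearman")
  diag(r) <- 0
  expect_equal(igraph::ecount(g), sum(abs(r) >= 0.7) / 2)
})

test_that("topology matches hand-computed values", {
  k4 <- igraph::make_full_graph(4)
  p <- topology_properties(k4)
  expect_equal(p$avgK, 3)
  expect_equal(p$density, 1)
  expect_equal(p$avgCC, 1)

  tri2 <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                             directed = FALSE)
  p2 <- topology_properties(tri2)
  expect_equal(p2$n_modules, 2)
  expect_equal(p2$density, 0.4)

  p3 <- topology_properties(igraph::make_graph(c(1, 2, 2, 3),
                                               directed = FALSE))
  expect_equal(p3$avgCC, 0)
  expect_equal(p3$GD, 4 / 3)
})

test_that("avgK = density * (N - 1) on random graphs", {
  for (s in 1:20) {
    set.seed(s)
    g <- igraph::sample_gnp(sample(5:30, 1), runif(1, 0.1, 0.9))
    p <- topology_properties(g)
    expect_equal(p$avgK, p$density * (p$n_nodes - 1), tolerance = 1e-12)
  }
})

test_that("sub-networks are induced subgraphs", {
  set.seed(2)
  m <- matrix(rlnorm(12 * 8, 4, 1), 12, 8,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:8)))
  g <- build_network(m, min_prevalence = 6, threshold = 0.3)
  all_taxa <- stats::setNames(rep(1, 8), paste0("t", 1:8))
  full <- sample_subnetwork(g, all_taxa)
  expect_identical(sort(igraph::V(full)$name), sort(igraph::V(g)$name))
  expect_equal(igraph::ecount(full), igraph::ecount(g))

  one <- sample_subnetwork(g, stats::setNames(c(1, rep(0, 7)),
                                              paste0("t", 1:8)))
  expect_equal(igraph::vcount(one), 1)
  expect_equal(igraph::ecount(one), 0)

  # removing a cut vertex disconnects (verified against component count)
  path5 <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 5), directed = FALSE)
  igraph::V(path5)$name <- paste0("t", 1:5)
  drop3 <- stats::setNames(c(1, 1, 0, 1, 1), paste0("t", 1:5))
  split <- sample_subnetwork(path5, drop3)
  expect_equal(igraph::components(split)$no, 2)
})

test_that("module structure beats degree-preserving rewiring", {
  set.seed(6)
  planted <- igraph::sample_sbm(40, pref.matrix = rbind(c(0.6, 0.02),
                                                        c(0.02, 0.6)),
                                block.sizes = c(20, 20))
  mod_planted <- topology_properties(planted)$modularity
  hits <- vapply(1:15, function(s) {
    set.seed(s)
    rw <- igraph::rewire(planted, igraph::keeping_degseq(niter = 500))
    topology_properties(rw)$modularity < mod_planted
  }, logical(1))
  expect_gte(sum(hits), 14)
})

test_that("RMT threshold scan finds the noise/module transition", {
  set.seed(1)
  n <- 60
  blocks <- kronecker(diag(3), matrix(0.9, 20, 20))
  noise <- matrix(rnorm(n * n, 0, 0.08), n, n)
  noise <- (noise + t(noise)) / 2
  sim <- pmin(abs(blocks + noise), 1)
  diag(sim) <- 1
  thr <- rmt_threshold(sim, scan = seq(0.25, 0.95, 0.05))
  expect_gt(thr, 0.2)   # above the noise level
  expect_lt(thr, 0.9)   # below the block correlation

  # dense GOE-like matrix: low thresholds show Wigner repulsion, so the
  # accepted threshold is pushed upward
  set.seed(2)
  w <- matrix(rnorm(n * n, 0, 0.3), n, n)
  w <- abs((w + t(w)) / 2)
  diag(w) <- 1
  thr_goe <- rmt_threshold(pmin(w, 1), scan = seq(0.05, 0.95, 0.05))
  expect_gt(thr_goe, 0.05)

  # threshold high enough to empty the matrix: trivially Poisson-consistent
  expect_equal(rmt_threshold(diag(10), scan = 0.99), 0.99)
})
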