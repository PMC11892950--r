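test_that("Bray-Curtis matches hand computations and bounds", {
  expect_equal(as.numeric(bray_curtis(rbind(a = c(1, 2), b = c(1, 2)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(a = c(1, 0), b = c(0, 3)))), 1)
  expect_equal(as.numeric(bray_curtis(rbind(a = c(2, 0, 4), b = c(2, 4, 0)))),
               1 - 4 / 12)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")

  set.seed(12)
  for (i in 1:10) {
    m <- random_counts(8, 30, seed = i)
    d <- as.matrix(bray_curtis(m))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("Sorensen matches hand computations", {
  expect_equal(as.numeric(sorensen(rbind(a = c(1, 0, 2), b = c(3, 0, 1)))), 0)
  # supports {1,3} vs {1,2}: 1 - 2/4
  expect_equal(as.numeric(sorensen(rbind(a = c(1, 0, 1), b = c(1, 1, 0)))),
               0.5)
  expect_equal(as.numeric(sorensen(rbind(a = c(1, 0), b = c(0, 1)))), 1)
})

test_that("PCoA reproduces Euclidean geometry", {
  set.seed(3)
  pts <- cbind(runif(7), runif(7))
  d <- dist(pts)
  fit <- pcoa(d, k = 2)
  expect_equal(as.numeric(dist(fit$points)), as.numeric(d), tolerance = 1e-9)
  expect_length(fit$negative, 0)

  # all distances equal: the positive eigenvalues of a regular simplex are equal
  n <- 6
  deq <- stats::as.dist(matrix(1, n, n) - diag(n))
  ev <- pcoa(deq, k = 2)$eigenvalues
  pos <- ev[ev > 1e-8]
  expect_length(pos, n - 1)
  expect_lt(diff(range(pos)), 1e-10)

  # duplicated samples coincide
  m <- rbind(a = c(5, 1, 0), b = c(5, 1, 0), c = c(0, 2, 7))
  f2 <- pcoa(bray_curtis(m), k = 2)
  expect_lt(sqrt(sum((f2$points[1, ] - f2$points[2, ])^2)), 1e-7)
})

test_that("group dispersion agrees with vegan::betadisper", {
  d <- synthetic_design(n_taxa = 80, n_samples_per_group = 6, depth = 3000,
                        seed = 21)
  comm <- gen_paired_communities(d)
  bc <- bray_curtis(comm, relative = TRUE)
  gd <- group_dispersion(bc, comm$samples$habitat, permutations = 0)
  bd <- vegan::betadisper(bc, comm$samples$habitat, type = "centroid")
  expect_equal(unname(gd$distances), unname(bd$distances), tolerance = 1e-8)
  expect_equal(as.numeric(gd$group_means),
               as.numeric(tapply(bd$distances, comm$samples$habitat, mean)),
               tolerance = 1e-8)
})

test_that("dispersion is zero for identical samples and detects noise ratio", {
  m <- rbind(a = c(3, 1, 4), b = c(3, 1, 4), c = c(1, 5, 9), d = c(1, 5, 9))
  gd <- group_dispersion(dist(m), groups = c("g1", "g1", "g2", "g2"),
                         permutations = 0)
  expect_equal(as.numeric(gd$group_means), c(0, 0))

  hits <- vapply(1:20, function(s) {
    set.seed(s)
    base <- rep(10, 12)
    g1 <- t(replicate(8, base + rnorm(12, 0, 1)))
    g2 <- t(replicate(8, base + rnorm(12, 0, 2)))
    m <- rbind(g1, g2)
    rownames(m) <- paste0("s", 1:16)
    gd <- group_dispersion(dist(m), rep(c("a", "b"), each = 8),
                           permutations = 0)
    gd$group_means[["b"]] > gd$group_means[["a"]]
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("mantel test matches vegan and honours its contracts", {
  m1 <- random_counts(10, 40, seed = 44)
  m2 <- m1 + random_counts(10, 40, seed = 45)
  d1 <- bray_curtis(m1); d2 <- bray_curtis(m2)
  mt <- mantel_test(d1, d2, permutations = 199, seed = 3)
  mv <- vegan::mantel(d1, d2, permutations = 199)
  expect_equal(mt$r, unname(mv$statistic), tolerance = 1e-12)

  self <- mantel_test(d1, d1, permutations = 199, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)

  # association with d2 entirely via d3 = d2: partial r collapses
  pm <- mantel_test(d1, d2, permutations = 199, seed = 2, partial_on = d2)
  expect_lt(abs(pm$r), 0.05)
})

test_that("MRM recovers exact linear structure and partitions variance", {
  set.seed(9)
  n <- 12
  x1 <- as.matrix(dist(runif(n))); x2 <- as.matrix(dist(runif(n)))
  resp <- 2 + 0.5 * x1 + 1.5 * x2
  fit <- mrm(resp, list(a = x1, b = x2), permutations = 99, seed = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate, c(2, 0.5, 1.5), tolerance = 1e-9)

  part <- mrm_partition(resp, list(a = x1), list(b = x2), permutations = 99,
                        seed = 2)
  expect_equal(sum(part$partition), 1, tolerance = 1e-12)
  expect_equal(unname(part$partition["unexplained"]), 0, tolerance = 1e-9)
})

test_that("tNST is 0 for identical samples, bounded, and reproducible", {
  m <- matrix(rep(c(5, 3, 2, 0, 1, 0, 4, 2), 4), 4, 8, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:8)))
  r <- tnst(m, null_reps = 100, seed = 1)
  expect_equal(r$tnst, 0)
  expect_identical(r$interpretation, "deterministic")

  m2 <- random_counts(6, 50, seed = 77)
  r1 <- tnst(m2, null_reps = 100, seed = 5)
  r2 <- tnst(m2, null_reps = 100, seed = 5)
  expect_identical(r1$tnst, r2$tnst)
  expect_true(r1$tnst >= 0 && r1$tnst <= 1)
  expect_error(tnst(m2[1, , drop = FALSE], null_reps = 100), "2 samples")
  expect_error(tnst(m2, null_reps = 50), "null_reps")
})

test_that("sharpening a deterministic niche filter lowers tNST", {
  # communities assembled at random vs dominated by a fixed deterministic core
  res <- vapply(1:15, function(s) {
    set.seed(s)
    n_taxa <- 60; n <- 8
    profile <- sort(rlnorm(25, 3, 1), decreasing = TRUE)
    draw <- function(strength) {
      # strength = probability mass forced onto a fixed core taxon set
      core <- 1:25
      t(vapply(seq_len(n), function(i) {
        x <- numeric(n_taxa)
        k <- stats::rbinom(1, 25, strength)
        sel <- c(sample(core, k), sample(setdiff(seq_len(n_taxa), core),
                                         25 - k))
        x[sel] <- profile
        x
      }, numeric(n_taxa)))
    }
    loose <- tnst(draw(0.3), null_reps = 100, seed = s)$tnst
    tight <- tnst(draw(0.95), null_reps = 100, seed = s)$tnst
    tight <= loose
  }, logical(1))
  expect_gte(sum(res), 14)
})
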