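# A tiny hand-built probe table: 2 groups of 12 samples.
make_pt <- function(intensity, genes = NULL, groups = NULL) {
  n_probe <- nrow(intensity)
  genes <- genes %||% paste0("g", seq_len(n_probe))
  groups <- groups %||% rep(c("T", "C"), each = ncol(intensity) / 2)
  probe_table(intensity,
              data.frame(probe_id = paste0("p", seq_len(n_probe)),
                         gene = genes, category = "c"),
              groups)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("prevalence filter zeroes sparse probes per group and drops empties", {
  set.seed(5)
  m <- matrix(runif(3 * 24, 10, 100), 3, 24)
  # probe 1: detected in only 2/12 of group T -> zeroed there, kept in C
  m[1, 3:12] <- 0
  # probe 2: detected in exactly 3/12 of T -> retained unchanged
  m[2, 4:12] <- 0
  # probe 3: < 3 detections in both groups -> dropped entirely
  m[3, c(3:12, 15:24)] <- 0
  pt <- make_pt(m)
  f <- filter_probes(pt, min_detect = 3)
  expect_identical(nrow(f$intensity), 2L)
  expect_true(all(f$intensity["p1", 1:12] == 0))
  expect_true(all(f$intensity["p1", 13:24] > 0))
  expect_equal(f$intensity["p2", ], pt$intensity[2, ])
  # idempotence
  expect_identical(filter_probes(f, min_detect = 3)$intensity, f$intensity)
  expect_error(filter_probes(pt, min_detect = 13), "exceeds group size")
})

test_that("normalization equalizes post-log sample sums to the maximum", {
  # two samples engineered so post-log sums are 10 and 20
  x1 <- rep(expm1(1), 10)         # log1p sum = 10
  x2 <- rep(expm1(2), 10)         # log1p sum = 20
  pt <- make_pt(cbind(x1, x2), groups = c("T", "C"))
  nn <- normalize_probes(pt)
  expect_equal(unname(colSums(nn$intensity)), c(20, 20))
  expect_equal(unname(nn$intensity[, 1]), rep(2, 10))  # scale factor 2

  one <- make_pt(matrix(c(5, 7), 2, 1), groups = "T")
  expect_equal(normalize_probes(one)$intensity[, 1], log1p(c(5, 7)),
               ignore_attr = TRUE)

  withz <- make_pt(rbind(c(3, 0), c(5, 8)), groups = c("T", "C"))
  expect_equal(unname(normalize_probes(withz)$intensity[1, 2]), 0)

  bad <- make_pt(rbind(c(3, 0), c(5, 0)), groups = c("T", "C"))
  expect_error(normalize_probes(bad), "all-zero")
})

test_that("response ratio matches closed forms and statuses", {
  # identical groups: RR = 0, ns
  m <- matrix(rep(c(2, 4, 8, 4, 2, 6), 2), 1, 12)
  pt <- make_pt(m, groups = rep(c("T", "C"), each = 6))
  rr <- gene_response_ratio(pt, "g1", 1:6, 7:12)
  expect_equal(rr$RR, 0)
  expect_identical(rr$status, "ns")

  # means 4 vs 2, zero within-group variance: RR = ln 2, zero-width CI
  m2 <- matrix(c(rep(4, 6), rep(2, 6)), 1, 12)
  pt2 <- make_pt(m2, groups = rep(c("T", "C"), each = 6))
  rr2 <- gene_response_ratio(pt2, "g1", 1:6, 7:12)
  expect_equal(rr2$RR, log(2))
  expect_equal(rr2$ci_low, rr2$ci_high)
  expect_identical(rr2$status, "enriched")

  # antisymmetry: swapping groups negates RR and mirrors the CI
  set.seed(7)
  m3 <- matrix(rlnorm(12, 3, 0.4), 1, 12)
  pt3 <- make_pt(m3, groups = rep(c("T", "C"), each = 6))
  a <- gene_response_ratio(pt3, "g1", 1:6, 7:12)
  b <- gene_response_ratio(pt3, "g1", 7:12, 1:6)
  expect_equal(a$RR, -b$RR)
  expect_equal(a$ci_low, -b$ci_high)
  expect_equal(a$ci_high, -b$ci_low)

  # treatment-only detection
  m4 <- matrix(c(rep(5, 6), rep(0, 6)), 1, 12)
  pt4 <- make_pt(m4, groups = rep(c("T", "C"), each = 6))
  rr4 <- gene_response_ratio(pt4, "g1", 1:6, 7:12)
  expect_identical(rr4$status, "treatment_only")
  expect_true(is.na(rr4$RR))
  m5 <- matrix(0, 1, 12)
  pt5 <- make_pt(m5, groups = rep(c("T", "C"), each = 6))
  expect_error(gene_response_ratio(pt5, "g1", 1:6, 7:12), "undetected")
})

test_that("planted 1.5-fold effect is detected with high power at n = 12", {
  hits <- vapply(1:25, function(s) {
    pt <- gen_probe_table(120, groups = rep(c("WL", "CL"), each = 12),
                          detection_rate = 1,
                          effect_map = list(endoglucanase = 1.5),
                          seed = s, noise_sdlog = 0.2)
    pt <- normalize_probes(filter_probes(pt))
    rr <- response_ratio_table(pt, "WL", "CL")
    identical(rr$status[rr$gene == "endoglucanase"], "enriched")
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
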