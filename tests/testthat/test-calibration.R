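test_that("objective is zero at the data-generating parameters", {
  f <- quick_forcing(180, seed = 1, noise = TRUE)
  p <- mend_params()
  obs <- gen_observations(p, mend_state(), f,
                          noise_sd_map = list(rh = 0, mbc = 0, gene = 0),
                          seed = 4)
  o <- objective_total(p, obs, f, objective_spec("gMEND"))
  expect_equal(o$J, 0, tolerance = 1e-12)
  expect_equal(c(o$J1, o$J2, o$J3), c(1, 1, 1), tolerance = 1e-12)

  # tMEND mode is exactly the two-term objective
  ot <- objective_total(p, obs, f, objective_spec("tMEND"))
  expect_equal(ot$J, (1 - ot$J1) + (1 - ot$J2), tolerance = 1e-12)
  expect_true(is.na(ot$J3))
})

test_that("shuffled gene series carries no signal and inflates gMEND J", {
  f <- quick_forcing(200, seed = 2, noise = TRUE)
  p <- mend_params()
  obs <- gen_observations(p, mend_state(), f,
                          noise_sd_map = list(rh = 0, mbc = 0, gene = 0),
                          seed = 4)
  spec <- objective_spec("gMEND")
  j_self <- objective_total(p, obs, f, spec)$J
  set.seed(99)
  j3s <- vapply(1:100, function(i) {
    shuffled <- obs
    shuffled$series$gene$value <- sample(obs$series$gene$value)
    objective_total(p, shuffled, f, spec)$J3
  }, numeric(1))
  expect_lt(abs(mean(j3s)), 0.1)
  shuffled <- obs
  set.seed(100)
  shuffled$series$gene$value <- sample(obs$series$gene$value)
  expect_gt(objective_total(p, shuffled, f, spec)$J, j_self)
})

test_that("SCE finds the optimum of a convex quadratic", {
  truth <- c(a = 0.3, b = -0.2, c = 0.5, d = 0.1, e = -0.4)
  obj <- function(x) sum((x - truth)^2)
  b <- cbind(lower = rep(-1, 5), upper = rep(1, 5))
  rownames(b) <- names(truth)
  r <- sce_optimize(obj, b, max_evals = 3000, seed = 4)
  expect_lt(max(abs(r$par - truth)), 1e-4)

  # determinism and bound respect
  r2 <- sce_optimize(obj, b, max_evals = 3000, seed = 4)
  expect_identical(r$history, r2$history)
  h <- as.matrix(r$history[names(truth)])
  expect_true(all(h >= -1 & h <= 1))

  # best J is non-increasing across shuffling rounds
  best_by_round <- tapply(r$history$J, r$history$round, min)
  expect_true(all(diff(cummin(best_by_round)) <= 0))
})

test_that("COFI arithmetic matches the F-quantile closed form", {
  h <- data.frame(a = seq(0, 1, length.out = 50),
                  J = seq(1, 3, length.out = 50))
  cf <- cofi_uncertainty(h, p = 2, n = 12, alpha = 0.05)
  expect_equal(cf$J_critical, 1 * (1 + 0.2 * qf(0.95, 2, 10)),
               tolerance = 1e-12)
  expect_equal(cf$J_critical, 1.8206, tolerance = 1e-4)
  expect_true(min(cf$feasible$J) == cf$J_min)
  expect_true(all(cf$cv >= 0, na.rm = TRUE))

  # alpha -> 1 collapses the feasible set onto the optimum
  cf2 <- cofi_uncertainty(h, p = 2, n = 12, alpha = 1 - 1e-12)
  expect_lt(cf2$J_critical, cf$J_critical)
  expect_lte(nrow(cf2$feasible), nrow(cf$feasible))
  expect_error(cofi_uncertainty(h, p = 12, n = 12), "n > p")
})

test_that("warming-effect table honours its identities", {
  f <- quick_forcing(240, seed = 5, noise = TRUE)
  p <- mend_params()
  tr <- mend_simulate(p, mend_state(), f)
  tab0 <- warming_effect_table(tr, tr)
  expect_true(all(tab0$delta_pct == 0))
  expect_true(all(tab0$p_value == 1))

  # temperature-only warming with Q10 > 1 raises respiration
  fw <- mend_forcing(f$day, f$temperature_C + 1.8, f$moisture_vv,
                     f$litter_input)
  trw <- mend_simulate(p, mend_state(), fw)
  tab <- warming_effect_table(tr, trw)
  expect_gt(tab$delta_pct[tab$output == "mean_rh"], 0)

  # antisymmetry: swapping arguments maps d to -100 d / (100 + d)
  rev <- warming_effect_table(trw, tr)
  d <- tab$delta_pct
  expect_equal(rev$delta_pct, -100 * d / (100 + d), tolerance = 1e-9)
})

test_that("calibration wrapper returns a coherent result object", {
  f <- quick_forcing(150, seed = 6, noise = TRUE)
  truth <- mend_params(Vd = 0.12, Ec = 0.45)
  obs <- gen_observations(truth, mend_state(), f, seed = 3)
  cal <- calibrate_mend(obs, f, calibrate = c("Vd", "Ec"),
                        spec = objective_spec("tMEND"), max_evals = 120,
                        seed = 2)
  expect_s3_class(cal$best_params, "mend_params")
  expect_true(all(c("Vd", "Ec", "J", "round") %in% names(cal$sce$history)))
  expect_gte(cal$cofi$J_critical, cal$cofi$J_min)
  expect_true(nrow(cal$cofi$feasible) >= 1)
  b <- default_param_bounds(c("Vd", "Ec"))
  expect_true(all(cal$sce$par >= b[, "lower"] & cal$sce$par <= b[, "upper"]))
})
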