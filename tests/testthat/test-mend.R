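test_that("Q10 scaling follows the closed form", {
  expect_equal(q10_scale(0.5, 2, 16.3, 16.3), 0.5)
  expect_equal(q10_scale(0.5, 2, 26.3, 16.3), 1.0)
  expect_equal(q10_scale(1, 2, 11.3, 16.3), 1 / sqrt(2))
  expect_error(q10_scale(1, 0, 20, 16.3), "Q10")
})

test_that("fluxes follow Michaelis-Menten limits", {
  p <- mend_params()
  s0 <- mend_state(D = 0)
  fx <- mend_fluxes(s0, p, p$Tref, p$W_opt)
  expect_equal(fx$uptake$value, 0)
  expect_equal(fx$resp_growth$value, 0)
  expect_gt(fx$resp_maint$value, 0)

  # P1 = Kp1: half saturation exactly (T = Tref, W >= W_opt so fT = fW = 1)
  s1 <- mend_state(P1 = p$Kp1)
  fx1 <- mend_fluxes(s1, p, p$Tref, p$W_opt)
  expect_equal(fx1$dec_P1$value, p$Vp1 * s1[["EP1"]] / 2)

  # saturation: P1 >> Kp1 approaches Vp1 * EP1
  s2 <- mend_state(P1 = p$Kp1 * 1e6)
  fx2 <- mend_fluxes(s2, p, p$Tref, p$W_opt)
  expect_equal(fx2$dec_P1$value, p$Vp1 * s2[["EP1"]], tolerance = 1e-5)
})

test_that("zero pools and zero input stay identically zero", {
  f <- mend_forcing(1:30, rep(16.3, 30), rep(0.3, 30), rep(0, 30))
  z <- mend_state(P1 = 0, P2 = 0, M = 0, D = 0, Q = 0, BA = 0, BD = 0,
                  EP1 = 0, EP2 = 0, EM = 0)
  tr <- mend_simulate(mend_params(), z, f)
  expect_true(all(tr$states == 0))
  expect_true(all(tr$rh == 0))
})

test_that("carbon is conserved on random parameter draws", {
  f <- quick_forcing(365, seed = 3, noise = TRUE)
  for (s in 1:10) {
    tr <- mend_simulate(random_params(s), mend_state(), f)
    expect_lt(mass_balance_residual(tr), 1e-8)
    expect_true(all(tr$states >= 0))
  }
})

test_that("integration is converged: halving the step barely changes Rh", {
  f <- quick_forcing(365, seed = 5, noise = TRUE)
  p <- mend_params()
  r1 <- sum(mend_simulate(p, mend_state(), f, nsub = 2L)$rh)
  r2 <- sum(mend_simulate(p, mend_state(), f, nsub = 4L)$rh)
  expect_lt(abs(r1 - r2) / r1, 1e-6)
})

test_that("T = Tref is bit-identical to Q10 = 1", {
  n <- 120
  f_ref <- mend_forcing(1:n, rep(16.3, n), rep(0.32, n), rep(0.002, n))
  f_hot <- mend_forcing(1:n, rep(24.0, n), rep(0.32, n), rep(0.002, n))
  tr_ref <- mend_simulate(mend_params(Q10 = 2, Tref = 16.3), mend_state(),
                          f_ref)
  tr_q1 <- mend_simulate(mend_params(Q10 = 1, Tref = 16.3), mend_state(),
                         f_hot)
  expect_identical(tr_ref$states, tr_q1$states)
})

test_that("constant forcing approaches a steady state", {
  n <- 36500   # a century: the mineral-associated pool equilibrates slowly
  f <- mend_forcing(1:n, rep(16.3, n), rep(0.30, n), rep(0.002, n))
  tr <- mend_simulate(mend_params(), mend_state(), f)
  last <- tr$rh[(n - 99):n]
  expect_lt((max(last) - min(last)) / mean(last), 1e-6)
})

test_that("derived outputs respect their algebraic bounds", {
  f <- quick_forcing(400, seed = 7, noise = TRUE)
  p <- mend_params()
  out <- derive_outputs(mend_simulate(p, mend_state(), f))
  expect_true(out$active_fraction >= 0 && out$active_fraction <= 1)
  expect_lt(out$cue, p$Ec)     # maintenance always deducts

  nod <- derive_outputs(mend_simulate(mend_params(dormancy = FALSE),
                                      mend_state(BD = 0), f))
  expect_equal(nod$active_fraction, 1)

  for (s in 1:5) {
    ps <- random_params(s + 50)
    o <- derive_outputs(mend_simulate(ps, mend_state(), f))
    expect_lte(o$cue, ps$Ec + 1e-12)
  }

  # doubling Vd increases mean respiration (transient response from a
  # common initial state, before pool depletion re-equilibrates the system)
  w <- 1:100
  lo_rh <- derive_outputs(mend_simulate(p, mend_state(), f), w)$mean_rh
  hi_rh <- derive_outputs(mend_simulate(mend_params(Vd = 0.2), mend_state(),
                                        f), w)$mean_rh
  expect_gt(hi_rh, lo_rh)
})

test_that("parameter and forcing validation catches misuse", {
  expect_error(mend_params(Ec = 1.2), "Ec")
  expect_error(mend_params(fI_P1 = 0.9), "sum to 1")
  expect_error(mend_params(nosuch = 1), "unknown parameter")
  expect_error(mend_state(BA = -1), ">= 0")
  expect_error(mend_forcing(c(1, 3), c(16, 16), c(0.3, 0.3), c(0, 0)),
               "consecutive")
  expect_error(mend_forcing(1:2, c(16, 16), c(0, 0.3), c(0, 0)), "moisture")
})
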