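# Microbial-ENzyme Decomposition (MEND-family) soil carbon model.
#
# Pools (all mg C g^-1 soil):
#   P1  particulate organic matter decomposed by oxidative enzymes
#   P2  particulate organic matter decomposed by hydrolytic enzymes
#   M   mineral-associated organic matter (MOM)
#   D   dissolved organic carbon (DOC)
#   Q   DOC adsorbed to mineral surfaces
#   BA  active microbial biomass carbon
#   BD  dormant microbial biomass carbon
#   EP1 oxidative enzyme pool, EP2 hydrolytic enzyme pool, EM generic MOM enzyme
#   CO2 cumulative heterotrophic respiration (sink)
# plus a bookkeeping accumulator U_cum (cumulative DOC uptake) used for
# realized carbon-use-efficiency summaries; it is not a carbon pool.
#
# Flux topology (every flux leaves exactly one pool and enters exactly one
# pool or the CO2 sink; superscript T marks temperature/moisture-scaled rates):
#   P1 -> D (fraction fD) and M (1-fD):    F_P1 = Vp1^T * EP1 * P1/(Kp1+P1)
#   P2 -> D (fD) and M (1-fD):             F_P2 = Vp2^T * EP2 * P2/(Kp2+P2)
#   M  -> D:                               F_M  = Vm^T  * EM  * M/(Km+M)
#   D  -> BA (uptake):                     U = (1/Ec) * (Vd^T + mR^T) * BA * D/(Kd+D)
#   BA -> CO2 (growth respiration):        (1-Ec) * U
#   BA -> CO2 (maintenance):               mR^T * BA
#   BA -> EP1, EP2, EM (production):       pEP * mR^T * BA each
#   EP1, EP2, EM -> D (turnover):          rE * pool
#   BA -> D and P2 (mortality):            gamma*BA, split f_mort_D / (1-f_mort_D)
#   D <-> Q (adsorption/desorption):       Kads*D*(1-Q/Qmax), Kdes*Q/Qmax
#   BA <-> BD (dormancy, optional):        d_max*(1-s)*BA, r_max*s*BD with
#                                          s = D/(Kd+D)
#   litter input I(t) enters P1, P2, D with fractions fI_P1, fI_P2, fI_D.
# Rh(t) = (1-Ec)*U + mR^T*BA.

.POOLS <- c("P1", "P2", "M", "D", "Q", "BA", "BD", "EP1", "EP2", "EM",
            "CO2_cum", "U_cum")

#' MEND model parameters
#'
#' Constructs a validated parameter set for [mend_simulate()]. Values are
#' daily rates (d^-1), half-saturation constants in mg C g^-1 soil, and
#' dimensionless fractions. The defaults are a documented reference set with a
#' realistic quasi-steady state under temperate-grassland forcing; calibration
#' normally adjusts a subset of them within [default_param_bounds()].
#'
#' @param ... name = value overrides of the defaults.
#' @return named list of class `mend_params`.
#' @export
mend_params <- function(...) {
  p <- list(
    Vp1 = 4.0,  Kp1 = 50,   # oxidative POM decomposition
    Vp2 = 5.0,  Kp2 = 25,   # hydrolytic POM decomposition
    Vm  = 2.0,  Km  = 100,  # MOM decomposition
    Vd  = 0.10, Kd  = 0.25, # DOC uptake
    Ec  = 0.47,             # intrinsic carbon use efficiency
    mR  = 0.006,            # specific maintenance rate
    pEP = 0.04,             # enzyme production fraction (per enzyme pool)
    rE  = 0.005,            # enzyme turnover rate
    gamma = 0.003,          # biomass mortality rate
    fD  = 0.5,              # decomposed POM fraction routed to DOC
    f_mort_D = 0.5,         # mortality fraction routed to DOC (rest to P2)
    Kads = 0.2, Kdes = 0.003, Qmax = 1.7,
    fI_P1 = 0.35, fI_P2 = 0.45, fI_D = 0.20,
    Q10 = 2.0, Tref = 16.3,
    W_opt = 0.45, b_moist = 0.75,
    dormancy = TRUE, d_max = 0.02, r_max = 0.05
  )
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1L]]) && is.null(names(ov)[1L]))
    ov <- ov[[1L]]
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) abort_fmt("unknown parameter(s): %s",
                                 paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  rates <- c("Vp1", "Vp2", "Vm", "Vd", "mR", "rE", "gamma", "Kads", "Kdes",
             "d_max", "r_max")
  if (any(unlist(p[rates]) < 0)) abort_fmt("rates must be >= 0")
  if (any(unlist(p[c("Kp1", "Kp2", "Km", "Kd", "Qmax")]) <= 0))
    abort_fmt("half-saturation constants and Qmax must be > 0")
  fr <- c("pEP", "fD", "f_mort_D", "fI_P1", "fI_P2", "fI_D")
  if (any(unlist(p[fr]) < 0 | unlist(p[fr]) > 1))
    abort_fmt("fractions must lie in [0, 1]")
  if (abs(p$fI_P1 + p$fI_P2 + p$fI_D - 1) > 1e-10)
    abort_fmt("litter input partition fI_P1 + fI_P2 + fI_D must sum to 1")
  if (p$Ec <= 0 || p$Ec >= 1) abort_fmt("Ec must lie in (0, 1)")
  if (p$Q10 <= 0) abort_fmt("Q10 must be > 0")
  structure(p, class = "mend_params")
}

#' Initial MEND state
#'
#' @param ... name = value overrides of the default initial pools
#'   (mg C g^-1 soil).
#' @return named numeric vector of class `mend_state` over pools
#'   P1, P2, M, D, Q, BA, BD, EP1, EP2, EM, CO2_cum, U_cum.
#' @export
mend_state <- function(...) {
  # Near the reference parameter set's attractor under mean temperate-grassland
  # forcing (16.3 degC, moisture 0.30, litter input 0.002 mg C g^-1 d^-1), so
  # default runs need little spin-up.
  s <- c(P1 = 2.1, P2 = 1.4, M = 12, D = 0.035, Q = 1.2, BA = 0.12, BD = 0.34,
         EP1 = 0.006, EP2 = 0.006, EM = 0.006, CO2_cum = 0, U_cum = 0)
  ov <- c(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(s))
    if (length(unknown)) abort_fmt("unknown pool(s): %s",
                                   paste(unknown, collapse = ", "))
    s[names(ov)] <- ov
  }
  if (any(s < 0)) abort_fmt("pools must be >= 0")
  structure(s, class = "mend_state")
}

#' Q10 temperature scaling of a reference rate
#'
#' rate = rate_ref * Q10^((T - Tref)/10).
#'
#' @param rate_ref rate at the reference temperature.
#' @param Q10 multiplicative change per 10 degree C increase (> 0).
#' @param temperature_C temperature at which the rate is wanted.
#' @param Tref reference temperature, degree C.
#' @return scaled rate (vectorised over any argument).
#' @export
q10_scale <- function(rate_ref, Q10, temperature_C, Tref) {
  if (any(Q10 <= 0)) abort_fmt("Q10 must be > 0")
  rate_ref * Q10^((temperature_C - Tref) / 10)
}

#' Moisture scalar applied to decomposition and uptake rates
#'
#' f_W = min(1, (W / W_opt)^b): a power-law reduction below the optimum,
#' capped at 1 above it.
#'
#' @param moisture_vv volumetric moisture.
#' @param W_opt optimal moisture.
#' @param b shape exponent.
#' @return scalar in (0, 1].
#' @export
moisture_scale <- function(moisture_vv, W_opt = 0.45, b = 0.75) {
  pmin(1, (moisture_vv / W_opt)^b)
}

#' Instantaneous MEND fluxes
#'
#' Evaluates every flux of the model at a given state and environment. Mostly
#' a transparency/debugging surface: [mend_simulate()] inlines the same
#' arithmetic.
#'
#' @param state `mend_state` (or named vector over the same pools).
#' @param params `mend_params`.
#' @param temperature_C,moisture_vv scalar environment.
#' @return named list of fluxes, each entry carrying `from`/`to` pool names
#'   and the rate `value` (mg C g^-1 d^-1).
#' @export
mend_fluxes <- function(state, params, temperature_C, moisture_vv) {
  if (any(state[setdiff(.POOLS, c("CO2_cum", "U_cum"))] < 0))
    abort_fmt("negative pool in state: integrator misconfiguration?")
  p <- params
  fT <- q10_scale(1, p$Q10, temperature_C, p$Tref)
  fW <- moisture_scale(moisture_vv, p$W_opt, p$b_moist)
  s <- unclass(state)
  sat <- s[["D"]] / (p$Kd + s[["D"]])
  U <- (1 / p$Ec) * (p$Vd * fT * fW + p$mR * fT) * s[["BA"]] * sat
  fx <- list(
    dec_P1   = list(from = "P1", to = "D/M",
                    value = p$Vp1 * fT * fW * s[["EP1"]] * s[["P1"]] / (p$Kp1 + s[["P1"]])),
    dec_P2   = list(from = "P2", to = "D/M",
                    value = p$Vp2 * fT * fW * s[["EP2"]] * s[["P2"]] / (p$Kp2 + s[["P2"]])),
    dec_M    = list(from = "M", to = "D",
                    value = p$Vm * fT * fW * s[["EM"]] * s[["M"]] / (p$Km + s[["M"]])),
    uptake   = list(from = "D", to = "BA", value = U),
    resp_growth = list(from = "BA", to = "CO2", value = (1 - p$Ec) * U),
    resp_maint  = list(from = "BA", to = "CO2", value = p$mR * fT * s[["BA"]]),
    enz_prod = list(from = "BA", to = "EP1/EP2/EM",
                    value = p$pEP * p$mR * fT * s[["BA"]]),
    enz_turn = list(from = "EP1/EP2/EM", to = "D",
                    value = p$rE * (s[["EP1"]] + s[["EP2"]] + s[["EM"]])),
    mortality = list(from = "BA", to = "D/P2", value = p$gamma * s[["BA"]]),
    adsorption = list(from = "D", to = "Q",
                      value = p$Kads * s[["D"]] * (1 - s[["Q"]] / p$Qmax)),
    desorption = list(from = "Q", to = "D",
                      value = p$Kdes * s[["Q"]] / p$Qmax),
    dormancy_in  = list(from = "BA", to = "BD",
                        value = if (p$dormancy) p$d_max * (1 - sat) * s[["BA"]] else 0),
    dormancy_out = list(from = "BD", to = "BA",
                        value = if (p$dormancy) p$r_max * sat * s[["BD"]] else 0)
  )
  fx
}

# Tight derivative for the integrator: x is the numeric state vector,
# env = c(T, W, I). Returns dx/dt. Kept free of S3 dispatch for speed.
.mend_deriv <- function(x, pv, fT, fW, input) {
  P1 <- x[1L]; P2 <- x[2L]; M <- x[3L]; D <- x[4L]; Q <- x[5L]
  BA <- x[6L]; BD <- x[7L]; EP1 <- x[8L]; EP2 <- x[9L]; EM <- x[10L]

  F1 <- pv[1L] * fT * fW * EP1 * P1 / (pv[2L] + P1)
  F2 <- pv[3L] * fT * fW * EP2 * P2 / (pv[4L] + P2)
  FM <- pv[5L] * fT * fW * EM * M / (pv[6L] + M)
  sat <- D / (pv[8L] + D)
  mRT <- pv[10L] * fT
  U <- (pv[7L] * fT * fW + mRT) * BA * sat / pv[9L]
  enzP <- pv[11L] * mRT * BA
  mort <- pv[13L] * BA
  ads <- pv[16L] * D * (1 - Q / pv[18L])
  des <- pv[17L] * Q / pv[18L]
  if (pv[22L] > 0) {
    dorm_in <- pv[23L] * (1 - sat) * BA
    dorm_out <- pv[24L] * sat * BD
  } else {
    dorm_in <- 0; dorm_out <- 0
  }
  fD <- pv[14L]; fmD <- pv[15L]; rE <- pv[12L]
  rh <- (1 - pv[9L]) * U + mRT * BA

  c(pv[19L] * input - F1,                                      # P1
    pv[20L] * input - F2 + (1 - fmD) * mort,                   # P2
    (1 - fD) * (F1 + F2) - FM,                                 # M
    pv[21L] * input + fD * (F1 + F2) + FM +
      rE * (EP1 + EP2 + EM) + fmD * mort - U - ads + des,      # D
    ads - des,                                                 # Q
    pv[9L] * U - mRT * BA - 3 * enzP - mort - dorm_in + dorm_out, # BA
    dorm_in - dorm_out,                                        # BD
    enzP - rE * EP1,                                           # EP1
    enzP - rE * EP2,                                           # EP2
    enzP - rE * EM,                                            # EM
    rh,                                                        # CO2_cum
    U)                                                         # U_cum
}

.param_vec <- function(p) {
  c(p$Vp1, p$Kp1, p$Vp2, p$Kp2, p$Vm, p$Km, p$Vd, p$Kd, p$Ec, p$mR,
    p$pEP, p$rE, p$gamma, p$fD, p$f_mort_D, p$Kads, p$Kdes, p$Qmax,
    p$fI_P1, p$fI_P2, p$fI_D, as.numeric(p$dormancy), p$d_max, p$r_max)
}

#' Simulate the MEND model over a daily forcing series
#'
#' Integrates the pool ODEs with classical fourth-order Runge-Kutta,
#' holding forcing constant within each day. Runge-Kutta steps preserve the
#' linear carbon-balance invariant exactly, so total carbon
#' (pools + cumulative CO2) tracks cumulative litter input to rounding error.
#' If a day step would drive any pool negative the day is recomputed with
#' doubled sub-stepping (up to `2^max_halvings` sub-steps) before tiny
#' negatives (> -1e-10) are clamped.
#'
#' @param params [mend_params()].
#' @param init [mend_state()].
#' @param forcing [mend_forcing()] data.frame.
#' @param nsub sub-steps per day (default 2).
#' @param max_halvings maximum doublings of `nsub` on negativity (default 8).
#' @return object of class `mend_trajectory`: list with
#'   * `states`: days x pools matrix of end-of-day states,
#'   * `rh`: daily respiration (CO2 increment over each day),
#'   * `uptake`: daily DOC uptake increment,
#'   * `fluxes`: days x 3 matrix of end-of-day instantaneous decomposition
#'     fluxes (F_P1, F_P2, F_M),
#'   * `forcing`, `params`, `init`.
#' @export
mend_simulate <- function(params, init, forcing, nsub = 2L, max_halvings = 8L) {
  stopifnot(inherits(params, "mend_params"))
  if (!inherits(forcing, "mend_forcing")) abort_fmt("forcing must be a mend_forcing")
  x <- as.numeric(init[.POOLS])
  if (anyNA(x)) abort_fmt("init must cover all pools")
  pv <- .param_vec(params)
  n <- nrow(forcing)
  Tday <- forcing$temperature_C
  Wday <- forcing$moisture_vv
  Iday <- forcing$litter_input
  Q10 <- params$Q10; Tref <- params$Tref
  Wopt <- params$W_opt; bm <- params$b_moist

  states <- matrix(NA_real_, n, length(.POOLS),
                   dimnames = list(NULL, .POOLS))
  rh <- numeric(n)
  upt <- numeric(n)
  flx <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("F_P1", "F_P2", "F_M")))

  for (d in seq_len(n)) {
    fT <- Q10^((Tday[d] - Tref) / 10)
    fW <- min(1, (Wday[d] / Wopt)^bm)
    input <- Iday[d]
    co2_0 <- x[11L]; u_0 <- x[12L]
    k <- nsub
    repeat {
      y <- x
      h <- 1 / k
      ok <- TRUE
      for (s in seq_len(k)) {
        k1 <- .mend_deriv(y, pv, fT, fW, input)
        k2 <- .mend_deriv(y + h / 2 * k1, pv, fT, fW, input)
        k3 <- .mend_deriv(y + h / 2 * k2, pv, fT, fW, input)
        k4 <- .mend_deriv(y + h * k3, pv, fT, fW, input)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (any(y[1:10] < 0)) { ok <- FALSE; break }
      }
      if (ok || k >= nsub * 2^max_halvings) break
      k <- k * 2L
    }
    if (any(y[1:10] < -1e-10) || anyNA(y) || any(!is.finite(y)))
      abort_fmt("integration failed at day %d (state: %s); reduce step or check parameters",
                d, paste(signif(y, 4), collapse = ", "))
    y[1:10][y[1:10] < 0] <- 0
    x <- y
    states[d, ] <- x
    rh[d] <- x[11L] - co2_0
    upt[d] <- x[12L] - u_0
    flx[d, 1L] <- pv[1L] * fT * fW * x[8L] * x[1L] / (pv[2L] + x[1L])
    flx[d, 2L] <- pv[3L] * fT * fW * x[9L] * x[2L] / (pv[4L] + x[2L])
    flx[d, 3L] <- pv[5L] * fT * fW * x[10L] * x[3L] / (pv[6L] + x[3L])
  }
  structure(list(states = states, rh = rh, uptake = upt, fluxes = flx,
                 forcing = forcing, params = params,
                 init = as.numeric(init[.POOLS])),
            class = "mend_trajectory")
}

#' Carbon mass-balance residual of a trajectory
#'
#' |sum(pools)(end) + CO2_cum(end) - sum(pools)(0) - cumulative input|,
#' relative to cumulative input (absolute if input is zero).
#'
#' @param traj a `mend_trajectory`.
#' @return relative residual (scalar).
#' @export
mass_balance_residual <- function(traj) {
  pool_cols <- setdiff(.POOLS, "U_cum")
  end <- sum(traj$states[nrow(traj$states), pool_cols])
  start <- sum(traj$init[seq_len(11L)])
  cum_in <- sum(traj$forcing$litter_input)
  resid <- abs(end - start - cum_in)
  if (cum_in > 0) resid / cum_in else resid
}

#' Summaries of a MEND trajectory
#'
#' Time-averaged derived outputs over a stated window: mean heterotrophic
#' respiration, microbial biomass (MB = BA + BD), active biomass (MBA = BA),
#' active fraction BA/(BA+BD), realized carbon use efficiency
#' 1 - sum(Rh)/sum(uptake), and pool-specific decomposition rates
#' F_P1/P1, F_P2/P2, F_M/M.
#'
#' @param traj a `mend_trajectory`.
#' @param window integer vector of day indices to average over (default: the
#'   second half of the run, so summaries describe quasi-equilibrated
#'   behaviour rather than spin-up).
#' @return named list of class `mend_outputs`.
#' @export
derive_outputs <- function(traj, window = NULL) {
  n <- nrow(traj$states)
  if (n < 1L) abort_fmt("empty trajectory")
  if (is.null(window)) window <- seq.int(max(1L, floor(n / 2) + 1L), n)
  st <- traj$states[window, , drop = FALSE]
  ba <- st[, "BA"]; bd <- st[, "BD"]
  tot_up <- sum(traj$uptake[window])
  tot_rh <- sum(traj$rh[window])
  mb <- ba + bd
  af <- ifelse(mb > 0, ba / mb, NA_real_)
  k1 <- ifelse(st[, "P1"] > 0, traj$fluxes[window, "F_P1"] / st[, "P1"], NA_real_)
  k2 <- ifelse(st[, "P2"] > 0, traj$fluxes[window, "F_P2"] / st[, "P2"], NA_real_)
  km <- ifelse(st[, "M"] > 0, traj$fluxes[window, "F_M"] / st[, "M"], NA_real_)
  out <- list(
    mean_rh = mean(traj$rh[window]),
    mb = mean(mb),
    mba = mean(ba),
    active_fraction = mean(af, na.rm = TRUE),
    cue = if (tot_up > 0) 1 - tot_rh / tot_up else NA_real_,
    k_P1 = mean(k1, na.rm = TRUE),
    k_P2 = mean(k2, na.rm = TRUE),
    k_M = mean(km, na.rm = TRUE),
    window = range(window)
  )
  if (!all(is.na(af)) && (out$active_fraction < 0 || out$active_fraction > 1))
    abort_fmt("active fraction outside [0, 1]: integrator problem")
  structure(out, class = "mend_outputs")
}

#' Bounds for commonly calibrated MEND parameters
#'
#' @param names optional character vector selecting a subset (default: the
#'   eleven carbon-flux and enzyme parameters exposed for optimization).
#' @return matrix with columns `lower`, `upper` and parameter rownames.
#' @export
default_param_bounds <- function(names = NULL) {
  b <- rbind(
    Vp1 = c(0.2, 10), Kp1 = c(10, 200),
    Vp2 = c(0.5, 20), Kp2 = c(5, 100),
    Vm  = c(0.05, 3), Km  = c(50, 1000),
    Vd  = c(0.005, 0.5), Kd = c(0.05, 1),
    Ec  = c(0.15, 0.75), mR = c(0.001, 0.05),
    pEP = c(0.001, 0.05)
  )
  colnames(b) <- c("lower", "upper")
  if (!is.null(names)) {
    missing <- setdiff(names, rownames(b))
    if (length(missing)) abort_fmt("no default bounds for: %s",
                                   paste(missing, collapse = ", "))
    b <- b[names, , drop = FALSE]
  }
  b
}
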