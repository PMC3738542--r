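#' Strain kinetic parameter set for batch simulation
#'
#' Bundles the Monod growth and acetate overflow/re-uptake parameters that
#' characterise one *E. coli* strain in aerobic high-glucose batch culture.
#'
#' The growth model is Monod kinetics with a hard lag switch:
#' \eqn{\mu(S) = \mu_{max} S/(K_s + S)} for \eqn{t \ge} `lag_duration`,
#' and \eqn{\mu = 0} before. Specific glucose uptake is
#' \eqn{q_s = \mu / Y_{X/S}}. Acetate is excreted by overflow whenever
#' glucose uptake exceeds the oxidative capacity threshold `q_s_crit`:
#' \eqn{q_{ac} = k_{overflow} \cdot \max(0, q_s - q_{s,crit})}.
#' Acetate re-uptake at up to `q_ac_uptake_max` is switched on either when
#' glucose is depleted or -- for strains with a B-type acetate control
#' mechanism -- whenever the acetate concentration exceeds
#' `acetate_ctrl_threshold` (around 1 g/L for B strains).
#'
#' @param mu_max maximum specific growth rate, 1/h.
#' @param lag_duration lag-phase duration, h (growth rate is 0 before).
#' @param Ks Monod half-saturation constant for glucose, g/L.
#' @param Yxs_true biomass yield on glucose, g CDM per g glucose, in (0,1).
#' @param q_s_crit critical specific glucose uptake above which overflow
#'   acetate is formed, g glucose/(g CDM h). `Inf` disables overflow.
#' @param k_overflow g acetate formed per g of excess glucose flux.
#' @param acetate_ctrl_threshold acetate concentration (g/L) above which
#'   re-uptake is triggered while glucose is still present (B-type control);
#'   `Inf` restricts re-uptake to the glucose-depleted regime.
#' @param q_ac_uptake_max maximum specific acetate uptake rate,
#'   g acetate/(g CDM h).
#' @param side_fractions named numeric vector with elements `formate`,
#'   `pyruvate`, `lactate`: mass of by-product formed per g of glucose flux
#'   (minor late-phase by-products; all default to 0).
#' @return an object of class `strain_kinetics`.
#' @seealso [strain_preset()], [batch_scenario()], [simulate_batch()]
#' @export
strain_kinetics <- function(mu_max, lag_duration = 0, Ks = 0.05, Yxs_true,
                            q_s_crit = Inf, k_overflow = 0,
                            acetate_ctrl_threshold = Inf,
                            q_ac_uptake_max = 0,
                            side_fractions = c(formate = 0, pyruvate = 0,
                                               lactate = 0)) {
  stopifnot(is.numeric(mu_max), length(mu_max) == 1L, mu_max >= 0,
            is.numeric(lag_duration), lag_duration >= 0,
            is.numeric(Ks), Ks > 0,
            is.numeric(Yxs_true), Yxs_true > 0, Yxs_true < 1,
            q_s_crit >= 0, k_overflow >= 0,
            acetate_ctrl_threshold >= 0, q_ac_uptake_max >= 0)
  sf <- c(formate = 0, pyruvate = 0, lactate = 0)
  if (length(side_fractions)) {
    if (is.null(names(side_fractions)) ||
        !all(names(side_fractions) %in% names(sf)))
      stop("side_fractions must be named among formate/pyruvate/lactate")
    sf[names(side_fractions)] <- side_fractions
  }
  if (any(sf < 0)) stop("side_fractions must be >= 0")
  structure(list(mu_max = mu_max, lag_duration = lag_duration, Ks = Ks,
                 Yxs_true = Yxs_true, q_s_crit = q_s_crit,
                 k_overflow = k_overflow,
                 acetate_ctrl_threshold = acetate_ctrl_threshold,
                 q_ac_uptake_max = q_ac_uptake_max,
                 side_fractions = sf),
            class = "strain_kinetics")
}

#' Built-in strain kinetic presets
#'
#' Three parameter sets emulating the phenotypes of typical K-12 and B
#' production strains in glucose batch culture: a K-12 strain with strong
#' acetate overflow (`K12_HMS_like`), a K-12 strain with a pronounced lag
#' phase (`K12_RV_like`), and a B strain with weak overflow plus an acetate
#' control mechanism that re-consumes acetate above about 1 g/L (`B_like`).
#' The presets are illustrative fixtures for the simulator, not measured
#' parameter estimates.
#'
#' @param name one of `"K12_HMS_like"`, `"K12_RV_like"`, `"B_like"`.
#' @return a `strain_kinetics` object.
#' @export
strain_preset <- function(name = c("K12_HMS_like", "K12_RV_like", "B_like")) {
  name <- match.arg(name)
  switch(name,
    K12_HMS_like = strain_kinetics(
      mu_max = 0.43, lag_duration = 0.5, Ks = 0.05, Yxs_true = 0.34,
      q_s_crit = 0.80, k_overflow = 0.42),
    K12_RV_like = strain_kinetics(
      mu_max = 0.50, lag_duration = 2.0, Ks = 0.05, Yxs_true = 0.40,
      q_s_crit = 0.80, k_overflow = 0.40),
    B_like = strain_kinetics(
      mu_max = 0.73, lag_duration = 0, Ks = 0.05, Yxs_true = 0.45,
      q_s_crit = 1.32, k_overflow = 0.25,
      acetate_ctrl_threshold = 1.0, q_ac_uptake_max = 0.12))
}

#' Batch cultivation scenario
#'
#' Initial conditions, integration settings and the measurement-noise model
#' for one simulated batch cultivation.
#'
#' @param kinetics a [strain_kinetics()] object.
#' @param X0 initial cell dry mass concentration, g/L.
#' @param S0 initial glucose concentration, g/L.
#' @param duration maximum simulated time, h.
#' @param dt integration step, h (fixed-step RK4; keep at or below 0.01).
#' @param sample_dt sampling interval of the "measured" series, h.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise applied to the measured series (0 = noiseless).
#' @param volume batch working volume, L.
#' @param seed integer seed for the measurement noise.
#' @return an object of class `batch_scenario`.
#' @export
batch_scenario <- function(kinetics, X0 = 0.4, S0 = 40, duration = 14,
                           dt = 0.01, sample_dt = 0.25, noise_cv = 0,
                           volume = 4, seed = 1L) {
  if (!inherits(kinetics, "strain_kinetics"))
    stop("kinetics must be a strain_kinetics object")
  if (!is.numeric(X0) || X0 <= 0) stop("invalid scenario: X0 must be > 0")
  if (!is.numeric(S0) || S0 <= 0) stop("invalid scenario: S0 must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("invalid scenario: dt must be > 0")
  if (dt > 0.01) stop("invalid scenario: dt must be <= 0.01 h")
  stopifnot(duration > 0, sample_dt >= dt, noise_cv >= 0, volume > 0)
  structure(list(kinetics = kinetics, X0 = X0, S0 = S0, duration = duration,
                 dt = dt, sample_dt = sample_dt, noise_cv = noise_cv,
                 volume = volume, seed = as.integer(seed)),
            class = "batch_scenario")
}

# Carbon mass fractions used in the closure bookkeeping.
.batch_cfrac <- function() {
  c(glucose = carbon_fraction(composition_glucose()),
    biomass = carbon_fraction(composition_biomass()),
    acetate = carbon_fraction(composition_acetate()),
    formate = carbon_fraction(composition_formate()),
    pyruvate = carbon_fraction(composition_pyruvate()),
    lactate = carbon_fraction(composition_lactate()))
}

# State derivative. y = (X, S, Ac, For, Pyr, Lac, CO2C). CO2 carbon is the
# residual of the carbon balance, so total carbon is conserved by
# construction (RK4 preserves linear invariants exactly).
.batch_deriv <- function(t, y, k, cf) {
  X <- y[1L]; S <- max(y[2L], 0); Ac <- max(y[3L], 0)
  mu <- if (t < k$lag_duration) 0 else k$mu_max * S / (k$Ks + S)
  qs <- mu / k$Yxs_true
  qac_prod <- k$k_overflow * max(0, qs - k$q_s_crit)
  # re-uptake activation: full when glucose is gone, otherwise a smooth
  # ramp over 0.1 g/L above the control threshold (keeps the vector field
  # continuous); the saturation term keeps acetate from undershooting zero
  act <- if (S <= 1e-9) 1 else
    min(max((Ac - k$acetate_ctrl_threshold) / 0.1, 0), 1)
  qac_up <- k$q_ac_uptake_max * act * Ac / (Ac + 0.01)
  dX <- mu * X
  dS <- -qs * X
  dAc <- (qac_prod - qac_up) * X
  sf <- k$side_fractions
  dFor <- sf[["formate"]] * qs * X
  dPyr <- sf[["pyruvate"]] * qs * X
  dLac <- sf[["lactate"]] * qs * X
  dCO2C <- cf[["glucose"]] * qs * X - cf[["biomass"]] * dX -
    cf[["acetate"]] * dAc - cf[["formate"]] * dFor -
    cf[["pyruvate"]] * dPyr - cf[["lactate"]] * dLac
  c(dX, dS, dAc, dFor, dPyr, dLac, dCO2C)
}

.rk4_step <- function(t, y, h, k, cf) {
  k1 <- .batch_deriv(t, y, k, cf)
  k2 <- .batch_deriv(t + h / 2, y + h / 2 * k1, k, cf)
  k3 <- .batch_deriv(t + h / 2, y + h / 2 * k2, k, cf)
  k4 <- .batch_deriv(t + h, y + h * k3, k, cf)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate a glucose batch cultivation
#'
#' Integrates the Monod/overflow model of [strain_kinetics()] with a
#' fixed-step 4th-order Runge-Kutta scheme. The CO2 carbon evolution rate is
#' defined as the residual of the elemental carbon balance at every step
#' (input glucose carbon minus carbon fixed in biomass, acetate and side
#' products), so the noiseless trajectory closes its carbon balance by
#' construction. Integration stops at glucose exhaustion or at
#' `scenario$duration`, whichever comes first; the final step is shortened
#' so glucose never becomes negative.
#'
#' @param scenario a [batch_scenario()].
#' @return an object of class `batch_sim`: a list with
#'   \describe{
#'     \item{state}{noiseless trajectory at every integration step
#'       (`time_h`, `cdm_g_per_L`, `glucose_g_per_L`, `acetate_g_per_L`,
#'       `formate_g_per_L`, `pyruvate_g_per_L`, `lactate_g_per_L`,
#'       `co2_rate_gC_per_L_h`, `co2_cum_gC_per_L`).}
#'     \item{measured}{the same columns minus the cumulative CO2, sampled at
#'       `sample_dt` with multiplicative lognormal noise of CV
#'       `noise_cv` (a `process_series`, see [process_series()]).}
#'     \item{scenario}{the input scenario.}
#'   }
#' @examples
#' k <- strain_preset("B_like")
#' sim <- simulate_batch(batch_scenario(k, noise_cv = 0))
#' tail(sim$state, 1)
#' @export
simulate_batch <- function(scenario) {
  if (!inherits(scenario, "batch_scenario"))
    stop("invalid scenario: expected a batch_scenario object")
  k <- scenario$kinetics
  cf <- .batch_cfrac()
  dt <- scenario$dt
  n_max <- ceiling(scenario$duration / dt) + 1L
  times <- numeric(n_max)
  Y <- matrix(NA_real_, n_max, 7L)
  y <- c(scenario$X0, scenario$S0, 0, 0, 0, 0, 0)
  times[1L] <- 0; Y[1L, ] <- y
  i <- 1L
  t <- 0
  while (t < scenario$duration - 1e-12 && y[2L] > 1e-8) {
    h <- min(dt, scenario$duration - t)
    y_new <- .rk4_step(t, y, h, k, cf)
    if (y_new[2L] < 0) {
      # shrink the step so that glucose lands on (almost) zero
      for (it in 1:6) {
        frac <- y[2L] / (y[2L] - y_new[2L])
        h <- h * max(min(frac, 1), 1e-6)
        y_new <- .rk4_step(t, y, h, k, cf)
        if (y_new[2L] >= 0) break
      }
      y_new[2L] <- max(y_new[2L], 0)
    }
    if (any(!is.finite(y_new)))
      stop("integration failure: non-finite state encountered")
    t <- t + h
    y <- y_new
    i <- i + 1L
    times[i] <- t
    Y[i, ] <- y
  }
  times <- times[seq_len(i)]
  Y <- Y[seq_len(i), , drop = FALSE]
  rate <- vapply(seq_len(i),
                 function(j) .batch_deriv(times[j], Y[j, ], k, cf)[7L],
                 numeric(1))
  state <- data.frame(
    time_h = times,
    cdm_g_per_L = Y[, 1L],
    glucose_g_per_L = Y[, 2L],
    acetate_g_per_L = pmax(Y[, 3L], 0),
    formate_g_per_L = Y[, 4L],
    pyruvate_g_per_L = Y[, 5L],
    lactate_g_per_L = Y[, 6L],
    co2_rate_gC_per_L_h = rate,
    co2_cum_gC_per_L = Y[, 7L])

  # measured series: subsample + multiplicative lognormal noise
  keep <- c(which(times %in% times[1L] |
                    abs(times / scenario$sample_dt -
                          round(times / scenario$sample_dt)) < 1e-9), i)
  keep <- sort(unique(keep))
  meas <- state[keep, setdiff(names(state), "co2_cum_gC_per_L")]
  if (scenario$noise_cv > 0) {
    sdlog <- sqrt(log(1 + scenario$noise_cv^2))
    set.seed(scenario$seed)
    for (col in setdiff(names(meas), "time_h")) {
      noise <- exp(stats::rnorm(nrow(meas), -sdlog^2 / 2, sdlog))
      meas[[col]] <- meas[[col]] * noise
    }
  }
  rownames(meas) <- NULL
  meas <- process_series(meas, volume = scenario$volume)
  structure(list(state = state, measured = meas, scenario = scenario),
            class = "batch_sim")
}

#' @export
print.batch_sim <- function(x, ...) {
  st <- x$state
  n <- nrow(st)
  cat("Batch simulation:", n, "steps,",
      sprintf("%.2f h", st$time_h[n]), "\n")
  cat(sprintf("  final CDM %.2f g/L, residual glucose %.3f g/L, acetate %.2f g/L\n",
              st$cdm_g_per_L[n], st$glucose_g_per_L[n], st$acetate_g_per_L[n]))
  invisible(x)
}
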