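#' Elemental composition of a carbon pool
#'
#' Stoichiometric element subscripts (per carbon formula or per molecule) of
#' a metabolite or of biomass, used for carbon-fraction computations.
#' Electron mass of charged species is neglected.
#'
#' @param C,H,O,N stoichiometric subscripts (non-negative; `C` > 0).
#' @param charge formal charge (metadata only).
#' @param label optional label.
#' @return an object of class `elemental_composition`.
#' @examples
#' carbon_fraction(elemental_composition(C = 1, H = 1.77, O = 0.49, N = 0.24))
#' @export
elemental_composition <- function(C, H = 0, O = 0, N = 0, charge = 0,
                                  label = NULL) {
  stopifnot(is.numeric(C), C > 0, H >= 0, O >= 0, N >= 0)
  structure(list(C = C, H = H, O = O, N = N, charge = charge, label = label),
            class = "elemental_composition")
}

#' Built-in elemental compositions
#'
#' Standard formulas for the pools of a glucose batch carbon balance:
#' average *E. coli* biomass (CH\eqn{_{1.77}}O\eqn{_{0.49}}N\eqn{_{0.24}}),
#' the acetate and formate anions, CO2, pyruvate, lactate and glucose.
#'
#' @return an `elemental_composition`.
#' @name compositions
NULL

#' @rdname compositions
#' @export
composition_biomass <- function()
  elemental_composition(1, 1.77, 0.49, 0.24, label = "biomass")
#' @rdname compositions
#' @export
composition_acetate <- function()
  elemental_composition(2, 3, 2, charge = -1, label = "acetate")
#' @rdname compositions
#' @export
composition_formate <- function()
  elemental_composition(1, 1, 2, charge = -1, label = "formate")
#' @rdname compositions
#' @export
composition_co2 <- function()
  elemental_composition(1, 0, 2, label = "co2")
#' @rdname compositions
#' @export
composition_pyruvate <- function()
  elemental_composition(3, 3, 3, charge = -1, label = "pyruvate")
#' @rdname compositions
#' @export
composition_lactate <- function()
  elemental_composition(3, 5, 3, charge = -1, label = "lactate")
#' @rdname compositions
#' @export
composition_glucose <- function()
  elemental_composition(6, 12, 6, label = "glucose")

.atomic_masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

#' Carbon mass fraction of a composition
#'
#' @param comp an [elemental_composition()].
#' @return the dimensionless carbon mass fraction
#'   \eqn{12.011 n_C / M}, with \eqn{M} the molar mass from standard atomic
#'   masses (C 12.011, H 1.008, O 15.999, N 14.007).
#' @export
carbon_fraction <- function(comp) {
  if (!inherits(comp, "elemental_composition"))
    stop("comp must be an elemental_composition")
  if (comp$C <= 0) stop("carbon subscript must be > 0")
  m <- comp$C * .atomic_masses[["C"]] + comp$H * .atomic_masses[["H"]] +
    comp$O * .atomic_masses[["O"]] + comp$N * .atomic_masses[["N"]]
  comp$C * .atomic_masses[["C"]] / m
}

#' Molar mass of a composition
#' @param comp an [elemental_composition()].
#' @return molar mass in g/mol.
#' @export
molar_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  comp$C * .atomic_masses[["C"]] + comp$H * .atomic_masses[["H"]] +
    comp$O * .atomic_masses[["O"]] + comp$N * .atomic_masses[["N"]]
}

#' Process time series container
#'
#' Validates and tags a cultivation time series: time in hours (strictly
#' increasing), concentrations of cell dry mass (CDM), glucose, acetate,
#' formate, pyruvate and lactate in g/L and the CO2 carbon evolution rate in
#' g C/(L h).
#'
#' @param data a data.frame with columns `time_h`, `cdm_g_per_L`,
#'   `glucose_g_per_L`, `acetate_g_per_L`, and optionally
#'   `formate_g_per_L`, `pyruvate_g_per_L`, `lactate_g_per_L`,
#'   `co2_rate_gC_per_L_h` (missing optional columns are filled with 0).
#' @param volume batch volume in litres (default 4).
#' @param co2_cumulative logical; `TRUE` if the CO2 column holds cumulative
#'   g C/L instead of a rate.
#' @return a `process_series` (a data.frame with attributes `volume` and
#'   `co2_cumulative`).
#' @export
process_series <- function(data, volume = 4, co2_cumulative = FALSE) {
  req <- c("time_h", "cdm_g_per_L", "glucose_g_per_L", "acetate_g_per_L")
  opt <- c("formate_g_per_L", "pyruvate_g_per_L", "lactate_g_per_L",
           "co2_rate_gC_per_L_h")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(opt, names(data))) data[[col]] <- 0
  if (nrow(data) < 3L) stop("insufficient data: need at least 3 time points")
  if (any(diff(data$time_h) <= 0)) stop("time must be strictly increasing")
  conc <- setdiff(c(req, opt), "time_h")
  if (any(vapply(conc, function(cl) any(data[[cl]] < -1e-9, na.rm = TRUE),
                 logical(1))))
    stop("concentrations must be non-negative")
  stopifnot(volume > 0)
  structure(as.data.frame(data)[c(req, opt)],
            volume = volume, co2_cumulative = co2_cumulative,
            class = c("process_series", "data.frame"))
}

#' Fit the specific growth rate from a CDM time series
#'
#' Primary estimator: ordinary least-squares slope of \eqn{\ln(CDM)} on time
#' within a window (the exponential-phase growth rate mu). Also returns the
#' endpoint "average rate"
#' \eqn{\ln(CDM_{end}/CDM_{start}) / (t_{end} - t_{start})} over the same
#' window, which is what a whole-batch average growth rate corresponds to.
#'
#' @param series a [process_series()].
#' @param window numeric length-2 time interval in h (default: whole series).
#' @return a list of class `growth_rate_fit` with elements `rate` (1/h, OLS
#'   slope), `se` (standard error of the slope), `average_rate` (endpoint
#'   formula), `n`, and `window`.
#' @export
fit_growth_rate <- function(series, window = NULL) {
  stopifnot(inherits(series, "process_series"))
  t <- series$time_h; x <- series$cdm_g_per_L
  if (is.null(window)) window <- range(t)
  stopifnot(length(window) == 2L)
  sel <- t >= window[1L] - 1e-12 & t <= window[2L] + 1e-12
  t <- t[sel]; x <- x[sel]
  if (length(t) < 3L) stop("insufficient data: need >= 3 points in window")
  if (any(x <= 0)) stop("domain error: cdm must be > 0 in window")
  fit <- stats::lm.fit(cbind(1, t), log(x))
  slope <- fit$coefficients[[2L]]
  rss <- sum(fit$residuals^2)
  df <- length(t) - 2L
  se <- if (df > 0) sqrt(rss / df / sum((t - mean(t))^2)) else NA_real_
  avg <- (log(x[length(x)]) - log(x[1L])) / (t[length(t)] - t[1L])
  structure(list(rate = slope, se = se, average_rate = avg,
                 n = length(t), window = window),
            class = "growth_rate_fit")
}

#' @export
print.growth_rate_fit <- function(x, ...) {
  cat(sprintf("growth rate (OLS on ln CDM): %.4f 1/h (se %.4g, n = %d)\n",
              x$rate, x$se, x$n))
  cat(sprintf("endpoint average rate:       %.4f 1/h\n", x$average_rate))
  invisible(x)
}

#' Summarize replicate cultivations
#'
#' Mean and standard error of the mean (sample standard deviation with
#' denominator n-1, divided by sqrt(n)) over replicate measurements.
#' Values are kept at full precision; round only at the reporting layer
#' (see [round_report()]).
#'
#' @param values numeric vector of replicate measurements (length >= 1).
#' @return list of class `replicate_summary`: `mean`, `sem` (NA for n < 2),
#'   `n`.
#' @examples
#' s <- summarize_replicates(c(13.33, 14.41, 13.43))
#' round_report(s$mean)  # 13.72
#' round_report(s$sem)   # 0.34
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("insufficient data: empty replicate list")
  n <- length(values)
  structure(list(mean = mean(values),
                 sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
                 n = n),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%.2f +/- %.2f (n = %d)\n", x$mean,
              if (is.na(x$sem)) NA else x$sem, x$n))
  invisible(x)
}

#' Round for reporting
#'
#' All computations in this package return full precision; process reports
#' quote 2 decimals. This helper is the single rounding point.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @export
round_report <- function(x, digits = 2) round(x, digits)

#' Glucose mass equivalent of an acetate mass
#'
#' Converts an acetate mass to the glucose mass consumed to form it under
#' homoacetate stoichiometry (1 glucose -> 2 acetate), i.e. multiplies by
#' \eqn{M_{glucose} / (2 M_{acetate}) \approx 1.5}. This is the correction
#' that turns overflow acetate back into "wasted" substrate: 6 g of acetate
#' corresponds to 9 g of glucose.
#'
#' @param acetate_mass acetate mass (g, or g/L), non-negative.
#' @return glucose equivalent in the same units.
#' @export
glucose_equivalent <- function(acetate_mass) {
  if (any(acetate_mass < 0)) stop("domain error: negative acetate mass")
  factor <- molar_mass(composition_glucose()) /
    (2 * molar_mass(composition_acetate()) + 2 * .atomic_masses[["H"]])
  acetate_mass * factor
}

#' Substrate yield coefficients with acetate correction
#'
#' Raw yield `yxs_raw` = final CDM / initial substrate. The corrected yield
#' divides by the substrate actually available for biomass after subtracting
#' the glucose equivalent of the accumulated acetate by-product
#' ([glucose_equivalent()]).
#'
#' @param final_cdm final cell dry mass, g/L.
#' @param substrate0 initial glucose, g/L.
#' @param byproduct_acetate accumulated acetate, g/L.
#' @return list of class `yield_result`: `yxs_raw`, `yxs_corrected` (both
#'   g CDM per g glucose), `glucose_equivalent_of_byproduct` and
#'   `available_substrate` (g/L).
#' @examples
#' y <- yield_coefficients(15.84, 40, 6)
#' round_report(y$yxs_corrected)  # 0.51
#' @export
yield_coefficients <- function(final_cdm, substrate0, byproduct_acetate) {
  stopifnot(final_cdm > 0, substrate0 > 0, byproduct_acetate >= 0)
  geq <- glucose_equivalent(byproduct_acetate)
  avail <- substrate0 - geq
  if (avail <= 0)
    stop("domain error: by-product glucose equivalent exceeds substrate")
  structure(list(yxs_raw = final_cdm / substrate0,
                 yxs_corrected = final_cdm / avail,
                 glucose_equivalent_of_byproduct = geq,
                 available_substrate = avail),
            class = "yield_result")
}

#' Integrate the off-gas CO2 carbon
#'
#' Trapezoidal integration of the CO2 carbon evolution rate over time,
#' scaled by the batch volume. If the series carries a cumulative CO2
#' column (`co2_cumulative = TRUE`), the last value is scaled instead.
#'
#' @param series a [process_series()].
#' @return cumulative CO2 carbon in g.
#' @export
integrate_offgas <- function(series) {
  stopifnot(inherits(series, "process_series"))
  r <- series$co2_rate_gC_per_L_h
  if (is.null(r) || all(is.na(r)))
    stop("missing data: no CO2 channel in series")
  v <- attr(series, "volume")
  if (isTRUE(attr(series, "co2_cumulative")))
    return(r[length(r)] * v)
  t <- series$time_h
  n <- length(t)
  sum(diff(t) * (r[-1L] + r[-n]) / 2) * v
}

#' End-of-batch elemental carbon balance
#'
#' Converts end-of-run concentrations to per-pool carbon masses
#' (concentration x volume x carbon mass fraction), integrates the CO2
#' off-gas, and expresses each pool as a percentage of the total input
#' carbon. The total input carbon (consumed glucose carbon plus any complex
#' media and inoculum carbon) is supplied by the caller; it is not inferred.
#'
#' @param series a [process_series()].
#' @param total_input_carbon total carbon fed to the culture, g (> 0).
#' @param compositions named list of [elemental_composition()] objects for
#'   pools `biomass`, `acetate`, `formate`, `pyruvate`, `lactate` (defaults:
#'   the built-in [compositions]).
#' @return an object of class `carbon_balance`: per-pool grams (`pools_g`),
#'   per-pool percentage of input carbon (`pools_pct`), `total_input_carbon`
#'   and `recovery` (the sum of the pool percentages).
#' @export
carbon_balance <- function(series, total_input_carbon,
                           compositions = list(
                             biomass = composition_biomass(),
                             acetate = composition_acetate(),
                             formate = composition_formate(),
                             pyruvate = composition_pyruvate(),
                             lactate = composition_lactate())) {
  stopifnot(inherits(series, "process_series"))
  if (!is.numeric(total_input_carbon) || total_input_carbon <= 0)
    stop("domain error: total_input_carbon must be > 0")
  v <- attr(series, "volume")
  last <- nrow(series)
  conc <- c(biomass = series$cdm_g_per_L[last],
            acetate = series$acetate_g_per_L[last],
            formate = series$formate_g_per_L[last],
            pyruvate = series$pyruvate_g_per_L[last],
            lactate = series$lactate_g_per_L[last])
  pools <- vapply(names(conc), function(p)
    conc[[p]] * v * carbon_fraction(compositions[[p]]), numeric(1))
  pools <- c(pools, co2 = integrate_offgas(series))
  pct <- 100 * pools / total_input_carbon
  structure(list(pools_g = pools, pools_pct = pct,
                 total_input_carbon = total_input_carbon,
                 recovery = sum(pct)),
            class = "carbon_balance")
}

#' @export
print.carbon_balance <- function(x, ...) {
  df <- data.frame(pool = names(x$pools_g),
                   carbon_g = round_report(unname(x$pools_g)),
                   pct_of_input = round_report(unname(x$pools_pct)))
  print(df, row.names = FALSE)
  cat(sprintf("total input carbon: %.2f g, recovery: %.2f%%\n",
              x$total_input_carbon, x$recovery))
  invisible(x)
}
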