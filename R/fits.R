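# Electrophysiology and Ca2+ response analysis: Boltzmann pressure-response,
# Hill dose-response and exponential inactivation fits (damped least
# squares), background subtraction, and the surface-tension conversion.

fit_result <- function(class, coef, se, converged, rss, data, message = NULL) {
  structure(list(coefficients = coef, se = se, converged = converged,
                 rss = rss, data = data, message = message),
            class = c(class, "piezotraj_fit"))
}

#' @export
print.piezotraj_fit <- function(x, ...) {
  cat(sprintf("%s (converged: %s)\n", class(x)[1], x$converged))
  tab <- rbind(estimate = x$coefficients, se = x$se)
  print(tab, digits = 5)
  if (!is.null(x$message)) cat("note:", x$message, "\n")
  invisible(x)
}

extract_nls <- function(fit, class, data) {
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(co)))
  fit_result(class, co, se[names(co)],
             converged = isTRUE(fit$convInfo$isConv),
             rss = sum(stats::residuals(fit)^2), data = data)
}

failed_fit <- function(class, par_names, data, message) {
  fit_result(class,
             stats::setNames(rep(NA_real_, length(par_names)), par_names),
             stats::setNames(rep(NA_real_, length(par_names)), par_names),
             converged = FALSE, rss = NA_real_, data = data,
             message = message)
}

#' Fit the Boltzmann pressure-response function
#'
#' `I(p) = Imin + (Imax - Imin) / (1 + exp((p - p50)/dp))` by damped
#' (Levenberg-Marquardt) least squares. `dp` may come out negative for
#' responses that grow in magnitude with pressure; report `abs(dp)`
#' alongside the signed value. Initialisation: `Imin`/`Imax` from the
#' responses at the pressure extremes, `p50` at the pressure whose response
#' is nearest the half-range, `dp = -range(p)/6`.
#'
#' @param pressures pressures (mmHg), at least 5 distinct values.
#' @param currents responses, same length.
#' @return A `boltzmann_fit` with coefficients `Imin`, `Imax`, `p50`, `dp`,
#'   standard errors, `converged`, and `rss`. Non-convergence is flagged,
#'   never silent.
#' @export
fit_boltzmann <- function(pressures, currents) {
  if (length(pressures) != length(currents)) abort("length mismatch")
  ok <- is.finite(pressures) & is.finite(currents)
  pressures <- pressures[ok]; currents <- currents[ok]
  if (length(unique(pressures)) < 5) {
    abort("fit_boltzmann needs at least 5 distinct pressures")
  }
  dat <- data.frame(p = pressures, I = currents)
  i_lo <- mean(currents[pressures == min(pressures)])
  i_hi <- mean(currents[pressures == max(pressures)])
  half <- (i_lo + i_hi) / 2
  start <- list(Imin = i_lo, Imax = i_hi,
                p50 = pressures[which.min(abs(currents - half))],
                dp = -diff(range(pressures)) / 6)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ Imin + (Imax - Imin) / (1 + exp((p - p50) / dp)),
                      data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(failed_fit("boltzmann_fit", c("Imin", "Imax", "p50", "dp"),
                      dat, conditionMessage(fit)))
  }
  extract_nls(fit, "boltzmann_fit", dat)
}

#' Fit the Hill dose-response function
#'
#' `R(d) = Rmin + (Rmax - Rmin) d^HC / (EC50^HC + d^HC)` (the standard
#' bounded sigmoid form of the Hill equation) by damped least squares on
#' the log-spaced dose panel. Initialisation: `EC50` at the geometric
#' median dose, `HC = 1`.
#'
#' @param doses doses (> 0), at least 4 points.
#' @param responses responses, same length.
#' @return A `hill_fit` with coefficients `Rmin`, `Rmax`, `EC50`, `HC`.
#' @export
fit_hill <- function(doses, responses) {
  if (length(doses) != length(responses)) abort("length mismatch")
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (length(doses) < 4) abort("fit_hill needs at least 4 points")
  if (any(doses <= 0)) abort("doses must be positive")
  dat <- data.frame(d = doses, R = responses)
  start <- list(Rmin = min(responses), Rmax = max(responses),
                EC50 = exp(stats::median(log(doses))), HC = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(R ~ Rmin + (Rmax - Rmin) * d^HC / (EC50^HC + d^HC),
                      data = dat, start = start,
                      lower = c(-Inf, -Inf, 1e-9, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(failed_fit("hill_fit", c("Rmin", "Rmax", "EC50", "HC"),
                      dat, conditionMessage(fit)))
  }
  extract_nls(fit, "hill_fit", dat)
}

#' Fit the exponential inactivation function
#'
#' `y(t) = A1 exp(-t/tau) + y0`, where `A1` is the current at time zero
#' relative to the residual (non-inactivating) current `y0`.
#' Initialisation: `y0` from the series tail, `A1 = y(0) - y0`, `tau` from
#' the time at which the decay reaches 1/e.
#'
#' @param time time points (ms), at least 4.
#' @param current current values.
#' @return An `exponential_fit` with coefficients `A1`, `tau`, `y0`;
#'   non-decaying input is returned with `converged = FALSE`.
#' @export
fit_exponential <- function(time, current) {
  if (length(time) != length(current)) abort("length mismatch")
  if (length(time) < 4) abort("fit_exponential needs at least 4 points")
  ord <- order(time)
  time <- time[ord]; current <- current[ord]
  dat <- data.frame(t = time, y = current)
  y0_0 <- mean(utils::tail(current, max(2L, length(current) %/% 10L)))
  a1_0 <- current[1] - y0_0
  target <- y0_0 + a1_0 / exp(1)
  cross <- if (a1_0 >= 0) which(current <= target) else which(current >= target)
  tau_0 <- if (length(cross)) max(time[cross[1]] - time[1], diff(range(time)) / 100)
           else diff(range(time)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A1 * exp(-t / tau) + y0, data = dat,
                      start = list(A1 = a1_0, tau = tau_0, y0 = y0_0),
                      lower = c(-Inf, 1e-9, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(failed_fit("exponential_fit", c("A1", "tau", "y0"),
                      dat, conditionMessage(fit)))
  }
  out <- extract_nls(fit, "exponential_fit", dat)
  if (abs(out$coefficients[["A1"]]) < 1e-12) {
    out$converged <- FALSE
    out$message <- "no decaying component detected"
  }
  out
}

#' Subtract matched background responses
#'
#' Subtracts, per panel value (dose or pressure), the mean untreated
#' control response from every treated response: the controls for each
#' matched experiment are treated as background.
#'
#' @param treated data.frame with a panel column (`dose_uM` or
#'   `pressure_mmHg`, autodetected or named via `panel_col`) and `response`.
#' @param control data.frame with the same panel column and `response`
#'   (replicates allowed; they are averaged per panel value).
#' @param panel_col panel column name (default: autodetect).
#' @return `treated` with `response` replaced by the corrected values.
#' @export
subtract_background <- function(treated, control, panel_col = NULL) {
  if (is.null(panel_col)) {
    panel_col <- intersect(c("dose_uM", "pressure_mmHg", "x"),
                           intersect(names(treated), names(control)))[1]
    if (is.na(panel_col)) abort("no shared panel column found")
  }
  if (!panel_col %in% names(treated) || !panel_col %in% names(control)) {
    abort(sprintf("panel column '%s' missing", panel_col))
  }
  bg <- tapply(control$response, control[[panel_col]], mean)
  tp <- as.character(treated[[panel_col]])
  if (!all(tp %in% names(bg))) {
    abort("treated panel values have no matched control")
  }
  treated$response <- treated$response - as.numeric(bg[tp])
  treated
}

#' Bilayer surface tension from the pressure tensor
#'
#' `gamma = Lz (pN - pL)` with `pN = p_zz` and `pL = (p_xx + p_yy)/2`;
#' with `Lz` in nm and pressures in bar, `1 nm bar = 0.1 mN/m`.
#'
#' @param Lz_nm box height in nm (> 0).
#' @param pN_bar normal pressure (bar). Alternatively supply `pxx_bar`,
#'   `pyy_bar`, `pzz_bar`.
#' @param pL_bar lateral pressure (bar).
#' @param pxx_bar,pyy_bar,pzz_bar pressure tensor diagonal (bar).
#' @return Surface tension in mN/m.
#' @export
surface_tension <- function(Lz_nm, pN_bar = NULL, pL_bar = NULL,
                            pxx_bar = NULL, pyy_bar = NULL, pzz_bar = NULL) {
  if (any(Lz_nm <= 0)) abort_config("Lz must be > 0")
  if (is.null(pN_bar)) {
    if (is.null(pzz_bar)) abort_config("supply pN_bar or pzz_bar")
    pN_bar <- pzz_bar
  }
  if (is.null(pL_bar)) {
    if (is.null(pxx_bar) || is.null(pyy_bar)) {
      abort_config("supply pL_bar or pxx_bar and pyy_bar")
    }
    pL_bar <- (pxx_bar + pyy_bar) / 2
  }
  0.1 * Lz_nm * (pN_bar - pL_bar)
}
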