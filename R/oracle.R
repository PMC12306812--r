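# Time-domain oracle: brute-force integration of the coupled linearized
# equations (motor population + membrane circuit) under sinusoidal
# forcing, with steady-state amplitude and phase extracted by
# least-squares fit. Entirely independent of the frequency-domain
# algebra: it never forms the complex transfer function.

#' Closed-loop system matrix
#'
#' The reduced time-domain model is the 3-state linear system
#' `y = (p, dp/dtau, w)` with `w = (beta q / 4) v`:
#' \preformatted{
#'   p'  =  u
#'   u'  = -(1 - gamma ua Kbar_e) p - u / omega_bar_eta + gamma w + drive
#'   w'  = -a1 p - chi u - omega_bar_m w
#' }
#' (time in units of `1/omega_r`). Its eigenvalues give the transient
#' decay rates used to size the integration, and their real parts decide
#' closed-loop stability.
#'
#' @param x An `ohc_parameters` or `ohc_groups` object.
#' @param gamma Electromotile activity in `[0, 1]`.
#' @return A 3x3 numeric matrix.
#' @export
closed_loop_matrix <- function(x, gamma) {
  gr <- as_groups(x)
  stopifnot(gamma >= 0, gamma <= 1)
  matrix(c(
    0, 1, 0,
    -(1 - gamma * gr$ua * gr$Kbar_e), -1 / gr$omega_bar_eta, gamma,
    -gr$a1, -gr$chi, -gr$omega_bar_m),
    nrow = 3, byrow = TRUE)
}

#' Is the closed loop stable?
#'
#' `TRUE` when every eigenvalue of [closed_loop_matrix()] has a strictly
#' negative real part, i.e. the anti-damping produced by the bundle
#' feedback does not exceed the viscous drag and a forced steady state
#' exists.
#'
#' @inheritParams closed_loop_matrix
#' @export
closed_loop_stable <- function(x, gamma) {
  ev <- eigen(closed_loop_matrix(x, gamma), only.values = TRUE)$values
  all(Re(ev) < 0)
}

#' Integrate the forced time-domain system
#'
#' Fixed-step classical RK4 integration of the 3-state linear system from
#' rest, driven by `(1 + alpha_c gamma ua) fbar cos(omega_bar tau)`. The
#' step count is deterministic, so results are bit-reproducible. The
#' number of discarded transient cycles is sized from the eigenvalues of
#' the system matrix (14 e-foldings of the slowest mode, at least 15
#' cycles), which covers both the mechanical envelope (rate
#' `~ 1/(2 omega_bar_eta)`) and the slow electrical pole (rate
#' `~ omega_bar_m`); only the final `keep_cycles` cycles are retained.
#'
#' @param x An `ohc_parameters` or `ohc_groups` object.
#' @param gamma Electromotile activity in `[0, 1]`.
#' @param omega_bar Reduced drive frequency, > 0.
#' @param n_cycles Total number of forcing cycles; default is sized
#'   automatically (transient + `keep_cycles`). Must be >= 20 when given.
#' @param steps_per_cycle Integration steps per forcing cycle (>= 64;
#'   default 256, for which the RK4 discretization error is well below
#'   the 1e-6 fit tolerance).
#' @param keep_cycles Number of trailing cycles retained for the
#'   steady-state fit.
#' @param fbar Reduced drive amplitude.
#' @param y0 Initial state `(p, dp/dtau, w)`; default rest. Extracted
#'   steady-state metrics are independent of it once the transient has
#'   decayed.
#' @return An object of class `ohc_series`: vectors `tau`, `p`, `dp`, `w`
#'   (reduced voltage) and, in physical mode, `v` (volts), plus the drive
#'   metadata.
#' @export
integrate_forced <- function(x, gamma, omega_bar, n_cycles = NULL,
                             steps_per_cycle = 256L, keep_cycles = 5L,
                             fbar = 1, y0 = c(0, 0, 0)) {
  gr <- as_groups(x)
  stopifnot(gamma >= 0, gamma <= 1, omega_bar > 0,
            steps_per_cycle >= 64L, keep_cycles >= 1L)
  ev <- eigen(closed_loop_matrix(gr, gamma), only.values = TRUE)$values
  rate <- min(-Re(ev))
  if (rate <= 0)
    stop("closed loop is not stable at this gamma; no steady state exists",
         call. = FALSE)
  n_transient <- max(15, ceiling((14 / rate) * omega_bar / (2 * pi)))
  if (is.null(n_cycles)) {
    n_cycles <- n_transient + keep_cycles
  } else {
    stopifnot(n_cycles >= 20L)
    if (n_cycles < n_transient + keep_cycles)
      warning("n_cycles may not cover the transient (",
              n_transient + keep_cycles, " cycles advised)", call. = FALSE)
  }
  n_steps <- as.numeric(n_cycles) * steps_per_cycle
  if (n_steps > 2e8)
    stop("integration would need ", format(n_steps), " steps; the system ",
         "is too slowly damped for this frequency. Increase omega_bar or ",
         "relax the transient by moving away from the stability boundary.",
         call. = FALSE)
  famp <- (1 + gr$alpha_c * gamma * gr$ua) * fbar
  h <- 2 * pi / (omega_bar * steps_per_cycle)
  keep_from <- as.integer(n_steps - keep_cycles * steps_per_cycle)
  m <- rk4_forced_cpp(
    k = 1 - gamma * gr$ua * gr$Kbar_e, inv_webar = 1 / gr$omega_bar_eta,
    gamma = gamma, a1 = gr$a1, chi = gr$chi, wm = gr$omega_bar_m,
    famp = famp, wb = omega_bar, h = h, n_steps = as.integer(n_steps),
    keep_from = keep_from, y0 = as.numeric(y0))
  v <- if (inherits(x, "ohc_parameters"))
    m[, "w"] * 4 / ((1 / x$constants$kBT) * x$motor$q) else NULL
  structure(list(
    tau = m[, "tau"], p = m[, "p"], dp = m[, "dp"], w = m[, "w"], v = v,
    omega_bar = omega_bar, gamma = gamma, fbar = fbar, famp = famp,
    n_cycles = n_cycles, steps_per_cycle = steps_per_cycle,
    keep_cycles = keep_cycles, groups = gr),
    class = "ohc_series")
}

#' Steady-state amplitude and phase from a trajectory
#'
#' Least-squares fit of `A cos(omega_bar tau + phi)` (via its cosine and
#' sine quadratures) over the final `n_fit_cycles` cycles of the retained
#' trajectory. The relative RMS residual of the fit flags residual
#' transients or discretization trouble.
#'
#' @param series An [integrate_forced()] result.
#' @param omega_bar Drive frequency; defaults to the one stored in the
#'   series.
#' @param n_fit_cycles Number of trailing cycles to fit (default 5).
#' @param tol Residual tolerance below which the fit is flagged converged.
#' @return An object of class `ohc_steady_state` with fields `amplitude`,
#'   `phase` (radians in `(-pi, pi]`, relative to the drive cosine),
#'   `residual`, `n_cycles_used` and `converged`.
#' @export
steady_state_amp_phase <- function(series, omega_bar = series$omega_bar,
                                   n_fit_cycles = 5L, tol = 1e-6) {
  stopifnot(inherits(series, "ohc_series"))
  n_fit <- min(n_fit_cycles, series$keep_cycles)
  n_pts <- n_fit * series$steps_per_cycle + 1L
  idx <- seq.int(length(series$tau) - n_pts + 1L, length(series$tau))
  tau <- series$tau[idx]
  y <- series$p[idx]
  cw <- cos(omega_bar * tau)
  sw <- sin(omega_bar * tau)
  fit <- stats::lm.fit(cbind(cw, sw), y)
  a <- fit$coefficients[[1]]
  b <- fit$coefficients[[2]]
  amplitude <- sqrt(a^2 + b^2)
  residual <- if (amplitude > 0)
    sqrt(mean(fit$residuals^2)) / amplitude else sqrt(mean(y^2))
  structure(list(
    omega_bar = omega_bar,
    amplitude = amplitude,
    phase = atan2(-b, a),
    residual = residual,
    n_cycles_used = n_fit,
    converged = residual < tol),
    class = "ohc_steady_state")
}

#' @export
print.ohc_steady_state <- function(x, ...) {
  cat(sprintf(
    "<ohc_steady_state> omega_bar=%.4g  A=%.6g  phase=%.6g rad  residual=%.2g%s\n",
    x$omega_bar, x$amplitude, x$phase, x$residual,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Compare time-domain and frequency-domain solutions
#'
#' For each requested frequency, integrates the time-domain system,
#' extracts steady-state amplitude and phase, and compares them with the
#' frequency-domain [exact_response()] at that frequency.
#'
#' @param x An `ohc_parameters` or `ohc_groups` object.
#' @param gamma Electromotile activity in `[0, 1]`.
#' @param omega_bars Reduced frequencies (at most 16, to bound runtime).
#' @param steps_per_cycle Integration steps per cycle.
#' @param fbar Reduced drive amplitude.
#' @return A data frame with columns `omega_bar, amp_fd, amp_td,
#'   rel_err_amp, phase_fd, phase_td, abs_err_phase_rad, converged`, with
#'   the maximum errors in attributes `max_rel_err_amp` and
#'   `max_abs_err_phase`.
#' @export
compare_to_frequency_domain <- function(x, gamma, omega_bars,
                                        steps_per_cycle = 256L, fbar = 1) {
  stopifnot(length(omega_bars) <= 16L, all(omega_bars > 0))
  ev <- response_evaluator(x, gamma, fbar)
  rows <- lapply(omega_bars, function(wb) {
    ser <- integrate_forced(x, gamma, wb, steps_per_cycle = steps_per_cycle,
                            fbar = fbar)
    ss <- steady_state_amp_phase(ser)
    pfd <- ev(wb)
    data.frame(
      omega_bar = wb,
      amp_fd = Mod(pfd), amp_td = ss$amplitude,
      rel_err_amp = abs(ss$amplitude - Mod(pfd)) / Mod(pfd),
      phase_fd = Arg(pfd), phase_td = ss$phase,
      abs_err_phase_rad = abs(wrap_phase(ss$phase - Arg(pfd))),
      converged = ss$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "max_rel_err_amp") <- max(out$rel_err_amp)
  attr(out, "max_abs_err_phase") <- max(out$abs_err_phase_rad)
  out
}
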