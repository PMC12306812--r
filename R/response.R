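# Exact closed-loop frequency response.
#
# Everything is solved per frequency as a single complex linear equation
# in the reduced motor amplitude p:
#
#   [ -wb^2 + i wb / wbeta + 1 - gamma ua Kbar_e + E(wb) ] p
#       = (1 + alpha_c gamma ua) fbar
#
# where wb = omega/omega_r and E is the electrical coupling term obtained
# by eliminating the voltage through the membrane circuit with the bundle
# feedback r = g p closed:
#
#   E(wb) = gamma (i wb chi + a1) / (omega_bar_m + i wb)          (groups)
#         = (beta gamma q / 4) (i w N q + i0 g) / (sigma + i w C0) (SI)
#
# The two forms are algebraically identical; the SI form also covers the
# degenerate C0 = 0 membrane used by the low-frequency limit.

#' Reduced frequency grid
#'
#' @param from,to Reduced frequency bounds (`omega / omega_r`), > 0.
#' @param n Number of points (>= 2).
#' @param spacing `"log"` (default) or `"linear"`.
#' @return An object of class `ohc_grid` holding the strictly increasing
#'   vector `omega_bar`.
#' @export
frequency_grid <- function(from = 0.3, to = 3, n = 400,
                           spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(from > 0, to > from, n >= 2)
  omega_bar <- if (spacing == "log")
    exp(seq(log(from), log(to), length.out = n))
  else seq(from, to, length.out = n)
  structure(list(omega_bar = omega_bar, spacing = spacing),
            class = "ohc_grid")
}

as_grid <- function(grid) {
  if (inherits(grid, "ohc_grid")) return(grid)
  stopifnot(is.numeric(grid), all(grid > 0), !is.unsorted(grid, strictly = TRUE))
  structure(list(omega_bar = as.numeric(grid), spacing = "custom"),
            class = "ohc_grid")
}

# Electrical coupling term E(wb) (per unit gamma) and voltage recovery.
electrical_term <- function(x, omega_bar) {
  if (inherits(x, "ohc_parameters")) {
    g <- x$motor$a * x$motor$N *
      (1 - x$mech$Ke / (x$mech$ko + x$mech$Ke)) * x$bundle$gx
    w <- omega_bar * x$mech$omega_r
    q <- x$motor$q
    beta <- 1 / x$constants$kBT
    den <- x$circuit$sigma + 1i * w * x$circuit$C0
    if (any(Mod(den) == 0))
      stop("sigma and omega*C0 cannot both vanish", call. = FALSE)
    (beta * q / 4) * (1i * w * x$motor$N * q + x$circuit$i0 * g) / den
  } else {
    den <- x$omega_bar_m + 1i * omega_bar
    if (any(Mod(den) == 0))
      stop("omega_bar_m and omega_bar cannot both vanish", call. = FALSE)
    (1i * omega_bar * x$chi + x$a1) / den
  }
}

response_evaluator <- function(x, gamma, fbar = 1) {
  gr <- as_groups(x, allow_degenerate = TRUE)
  if (gr$omega_bar_eta <= 0) stop("omega_bar_eta must be positive", call. = FALSE)
  force(gamma); force(fbar)
  function(omega_bar) {
    D <- -omega_bar^2 + 1i * omega_bar / gr$omega_bar_eta +
      1 - gamma * gr$ua * gr$Kbar_e + gamma * electrical_term(x, omega_bar)
    (1 + gr$alpha_c * gamma * gr$ua) * fbar / D
  }
}

make_response <- function(x, gamma, grid, p, model, fbar, evaluator) {
  gr <- as_groups(x, allow_degenerate = TRUE)
  physical <- inherits(x, "ohc_parameters")
  v <- if (physical) voltage_from_p(x, grid$omega_bar, p) else
    rep(NA_complex_, length(p))
  xamp <- if (physical)
    x$motor$a * x$motor$N * (1 - gr$Kbar_e) * p else
    rep(NA_complex_, length(p))
  structure(list(
    omega_bar = grid$omega_bar, spacing = grid$spacing,
    p = p, x = xamp, v = v,
    gamma = gamma, fbar = fbar, model = model,
    groups = gr, params = if (physical) x else NULL,
    evaluator = evaluator),
    class = "ohc_response")
}

#' Exact closed-loop frequency response
#'
#' Solves, at every grid frequency, the reduced equation of motion with the
#' membrane circuit substituted and the hair-bundle feedback closed
#' (`r = g p`), giving the complex motor-fraction amplitude `p` per unit
#' reduced drive `fbar`, the displacement `x = a N (1 - Kbar_e) p` and the
#' receptor-potential amplitude `v` (the latter two only in physical
#' mode).
#'
#' @param x An [ohc_parameters()] or [dimensionless_groups()] object.
#' @param gamma Electromotile activity in `[0, 1]`.
#' @param grid An [frequency_grid()], or a strictly increasing positive
#'   numeric vector of reduced frequencies.
#' @param fbar Reduced drive amplitude (default 1: unit drive; the response
#'   is exactly linear in `fbar`).
#' @return An object of class `ohc_response` with complex vectors `p`,
#'   `x`, `v` on the grid. `amplitude` and unwrapped `phase` views are
#'   available through [as.data.frame()] and [response_phase()].
#' @export
#' @examples
#' r <- exact_response(figure_mode_groups(), gamma = 1, frequency_grid())
#' max(Mod(r$p))
exact_response <- function(x, gamma, grid = frequency_grid(), fbar = 1) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1)
  grid <- as_grid(grid)
  ev <- response_evaluator(x, gamma, fbar)
  make_response(x, gamma, grid, ev(grid$omega_bar), "exact", fbar, ev)
}

#' Pure piezoelectric response (mechanotransducer removed)
#'
#' [exact_response()] with the bundle feedback deleted (`g = 0`, hence
#' also `a1 = 0`): the cell keeps its piezoelectric body but the hair
#' bundle no longer modulates the transducer current. The only remaining
#' drive enhancement is the `alpha_c gamma ua` term, and the resonance
#' this produces does not amplify.
#'
#' @inheritParams exact_response
#' @return An `ohc_response` with `model = "piezo"`.
#' @export
pure_piezo_response <- function(x, gamma, grid = frequency_grid(), fbar = 1) {
  if (inherits(x, "ohc_parameters")) {
    x$bundle$gx <- 0
  } else {
    x <- as_groups(x)
    x$g <- 0
    x$a1 <- 0
  }
  r <- exact_response(x, gamma, grid, fbar)
  r$model <- "piezo"
  r
}

voltage_from_p <- function(params, omega_bar, p) {
  g <- params$motor$a * params$motor$N *
    (1 - params$mech$Ke / (params$mech$ko + params$mech$Ke)) * params$bundle$gx
  w <- omega_bar * params$mech$omega_r
  den <- params$circuit$sigma + 1i * w * params$circuit$C0
  -(params$circuit$i0 * g * p + 1i * w * params$motor$N * params$motor$q * p) / den
}

#' Receptor-potential amplitude from a computed response
#'
#' Recovers the voltage amplitude `v(omega)` from the membrane-circuit
#' balance, `v = -(i0 g + i w N q) p / (sigma + i w C0)`, for a response
#' computed in physical mode.
#'
#' @param response An `ohc_response` computed from an `ohc_parameters`
#'   object.
#' @param params Optional parameter set; defaults to the one stored in the
#'   response.
#' @return Complex voltage amplitudes (V per unit `fbar`) on the grid.
#' @export
voltage_response <- function(response, params = response$params) {
  stopifnot(inherits(response, "ohc_response"))
  if (is.null(params))
    stop("voltage recovery needs physical parameters", call. = FALSE)
  voltage_from_p(params, response$omega_bar, response$p)
}

#' Unwrapped phase of a response
#'
#' `arg(p)` unwrapped along the grid, starting in `(-pi, pi]`.
#'
#' @param response An `ohc_response`.
#' @param component `"p"`, `"x"` or `"v"`.
#' @return Numeric vector of phases in radians.
#' @export
response_phase <- function(response, component = c("p", "x", "v")) {
  component <- match.arg(component)
  unwrap_phase(Arg(response[[component]]))
}

unwrap_phase <- function(phi) as.numeric(signal::unwrap(phi))

#' Closed-form passive amplitude
#'
#' The `gamma = 0` limit of the model is a plain forced damped oscillator;
#' its amplitude is `fbar / sqrt((1 - wb^2)^2 + (wb / omega_bar_eta)^2)`.
#' Used as an independent closed-form check of the solvers.
#'
#' @param omega_bar Reduced frequencies.
#' @param omega_bar_eta Reduced viscous roll-off frequency.
#' @param fbar Drive amplitude.
#' @return Amplitudes `|p|`.
#' @export
passive_amplitude <- function(omega_bar, omega_bar_eta, fbar = 1) {
  fbar / sqrt((1 - omega_bar^2)^2 + (omega_bar / omega_bar_eta)^2)
}

#' @export
as.data.frame.ohc_response <- function(x, ...) {
  data.frame(
    omega_bar = x$omega_bar,
    gamma = x$gamma,
    model = x$model,
    amp_p = Mod(x$p),
    phase_p_rad = response_phase(x, "p"),
    amp_x_m = Mod(x$x),
    phase_x_rad = if (all(is.na(x$x))) NA_real_ else response_phase(x, "x"),
    amp_v_V = Mod(x$v),
    phase_v_rad = if (all(is.na(x$v))) NA_real_ else response_phase(x, "v"),
    stringsAsFactors = FALSE)
}

#' @export
print.ohc_response <- function(x, ...) {
  cat(sprintf("<ohc_response> model=%s gamma=%g  %d frequencies in [%.4g, %.4g]\n",
              x$model, x$gamma, length(x$omega_bar),
              min(x$omega_bar), max(x$omega_bar)))
  cat(sprintf("  peak |p| = %.4g at omega_bar = %.4g\n",
              max(Mod(x$p)), x$omega_bar[which.max(Mod(x$p))]))
  invisible(x)
}

#' Write responses to CSV
#'
#' One row per grid point with the columns
#' `omega_bar, gamma, model, amp_p, phase_p_rad, amp_x_m, phase_x_rad,
#' amp_v_V, phase_v_rad`; UTF-8, '.' decimal separator, header included.
#'
#' @param responses One `ohc_response` or a list of them (rows are
#'   concatenated in order).
#' @param path Output file.
#' @return The written data frame, invisibly.
#' @export
write_response_csv <- function(responses, path) {
  if (inherits(responses, "ohc_response")) responses <- list(responses)
  df <- do.call(rbind, lapply(responses, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}
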