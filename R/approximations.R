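# Closed-form high- and low-frequency approximations.
#
# High frequency (capacitive membrane, sigma/(w C0) << 1): expanding
# 1/(sigma + i w C0) to first order turns the electrical term into an
# anti-damping factor Ah and a stiffness factor Bh,
#
#   Ah       = a1 - chi * omega_bar_m
#   Bh(wb)   = -ua Kbar_e + chi + a1 omega_bar_m / wb^2
#
# with chi = beta N q^2/(4 C0) (strain-induced polarization stiffness) and
# a1 = beta q i0 g/(4 omega_r C0) (bundle-current anti-damping). The
# wb-dependent third term of Bh carries the small factor sigma/(w C0) and
# is negligible; it is kept in coefficient reports and optionally in the
# response.
#
# Low frequency (resistive membrane): nullifying C0 gives a damping
# factor Al = chi / omega_bar_m = beta omega_r N q^2/(4 sigma) and a
# stiffness factor Bl = -ua Kbar_e + a1 / omega_bar_m.

#' High-frequency coefficients
#'
#' Anti-damping factor `Ah` and stiffness factor `Bh` of the
#' high-frequency form, with each summand exposed:
#' `Ah = Ah_term1 - Ah_term2` where `Ah_term1 = beta q i0 g/(4 omega_r C0)`
#' (positive for the amplifying signs) and
#' `Ah_term2 = beta sigma N q^2/(4 omega_r C0^2) = chi * omega_bar_m`;
#' `Bh(wb) = Bh_term1 + Bh_term2 + Bh_term3(wb)` with
#' `Bh_term1 = -ua Kbar_e`, `Bh_term2 = beta N q^2/(4 C0)` and the small
#' conductance correction `Bh_term3(wb) = Ah_term1 * omega_bar_m / wb^2`.
#'
#' @param x An `ohc_parameters` or `ohc_groups` object.
#' @param include_sigma_correction Logical. When `FALSE` the membrane
#'   conductance is nullified in the expansion: `Ah_term2` and `Bh_term3`
#'   are dropped (the "without membrane conductance" variant of the
#'   high-frequency sweeps).
#' @return An object of class `ohc_hf_coefficients` with fields `Ah`,
#'   `Ah_term1`, `Ah_term2`, `Bh_term1`, `Bh_term2`, the functions
#'   `Bh_at(omega_bar)` and `Bh_term3_at(omega_bar)`, and the scalar `Bh`
#'   (terms 1 + 2, the value the effectiveness condition uses).
#' @export
#' @examples
#' co <- hf_coefficients(guinea_pig_4khz())
#' signif(co$Bh_term2, 3) # 0.989
#' signif(co$Ah_term2, 2) # 0.013
hf_coefficients <- function(x, include_sigma_correction = TRUE) {
  gr <- as_groups(x)
  t1 <- gr$a1
  t2 <- if (include_sigma_correction) gr$chi * gr$omega_bar_m else 0
  Bh1 <- -gr$ua * gr$Kbar_e
  Bh2 <- gr$chi
  t3_at <- if (include_sigma_correction) {
    function(omega_bar) {
      if (any(omega_bar == 0)) stop("omega_bar must be nonzero", call. = FALSE)
      t1 * gr$omega_bar_m / omega_bar^2
    }
  } else function(omega_bar) rep(0, length(omega_bar))
  structure(list(
    Ah = t1 - t2, Ah_term1 = t1, Ah_term2 = t2,
    Bh = Bh1 + Bh2, Bh_term1 = Bh1, Bh_term2 = Bh2,
    Bh_term3_at = t3_at,
    Bh_at = function(omega_bar) Bh1 + Bh2 + t3_at(omega_bar),
    include_sigma_correction = include_sigma_correction,
    groups = gr),
    class = "ohc_hf_coefficients")
}

#' @export
print.ohc_hf_coefficients <- function(x, ...) {
  cat(sprintf("<ohc_hf_coefficients> Ah = %.4g (= %.4g - %.4g)\n",
              x$Ah, x$Ah_term1, x$Ah_term2))
  cat(sprintf("  Bh(1) = %.4g (= %.4g + %.4g + %.4g)\n",
              x$Bh_at(1), x$Bh_term1, x$Bh_term2, x$Bh_term3_at(1)))
  invisible(x)
}

#' High-frequency approximate response
#'
#' Solves `[-wb^2 + i(wb/omega_bar_eta - gamma Ah / wb) + 1 +
#' gamma Bh(wb)] p = (1 + alpha_c gamma ua) fbar` per frequency. Valid for
#' `wb >> omega_bar_m`; a warning is issued (but the response still
#' computed) when the grid reaches below `0.3`.
#'
#' @param coeffs An [hf_coefficients()] object (possibly passed through
#'   [strain_stiffness_toggle()]).
#' @param gamma Electromotile activity in `[0, 1]`.
#' @param grid Frequency grid (see [frequency_grid()]).
#' @param fbar Reduced drive amplitude.
#' @param groups Group set for `omega_bar_eta`, `ua`, `alpha_c`; defaults
#'   to the one the coefficients were built from.
#' @return An `ohc_response` with `model = "hf"`.
#' @export
hf_response <- function(coeffs, gamma, grid = frequency_grid(), fbar = 1,
                        groups = coeffs$groups) {
  stopifnot(inherits(coeffs, "ohc_hf_coefficients"),
            gamma >= 0, gamma <= 1)
  grid <- as_grid(grid)
  if (min(grid$omega_bar) < 0.3)
    warning("high-frequency form evaluated below omega_bar = 0.3, ",
            "outside its validity region", call. = FALSE)
  ev <- function(omega_bar) {
    D <- -omega_bar^2 +
      1i * (omega_bar / groups$omega_bar_eta - gamma * coeffs$Ah / omega_bar) +
      1 + gamma * coeffs$Bh_at(omega_bar)
    (1 + groups$alpha_c * gamma * groups$ua) * fbar / D
  }
  r <- make_response(groups, gamma, grid, ev(grid$omega_bar), "hf", fbar, ev)
  r
}

#' Low-frequency coefficients
#'
#' Damping factor `Al = beta omega_r N q^2 / (4 sigma)` and stiffness
#' factor `Bl = Bl_term1 + Bl_term2` with `Bl_term1 = -ua Kbar_e` and
#' `Bl_term2 = beta g i0 q / (4 sigma)` (positive for the amplifying
#' signs: bundle conductance stiffens the cell at low frequency, while
#' strain-induced polarization turns into drag).
#'
#' @param x An `ohc_parameters` or `ohc_groups` object with positive
#'   membrane conductance.
#' @return An object of class `ohc_lf_coefficients`.
#' @export
lf_coefficients <- function(x) {
  gr <- as_groups(x)
  if (gr$omega_bar_m <= 0)
    stop("low-frequency coefficients need sigma > 0", call. = FALSE)
  Bl1 <- -gr$ua * gr$Kbar_e
  Bl2 <- gr$a1 / gr$omega_bar_m
  structure(list(
    Al = gr$chi / gr$omega_bar_m,
    Bl = Bl1 + Bl2, Bl_term1 = Bl1, Bl_term2 = Bl2,
    groups = gr),
    class = "ohc_lf_coefficients")
}

#' @export
print.ohc_lf_coefficients <- function(x, ...) {
  cat(sprintf("<ohc_lf_coefficients> Al = %.4g, Bl = %.4g (= %.4g + %.4g)\n",
              x$Al, x$Bl, x$Bl_term1, x$Bl_term2))
  invisible(x)
}

#' Low-frequency approximate response
#'
#' The `C0 = 0` (purely resistive membrane) form:
#' `[-wb^2 + i wb (1/omega_bar_eta + gamma Al) + 1 + gamma Bl] p =
#' (1 + alpha_c gamma ua) fbar`. This is exactly [exact_response()]
#' evaluated with the structural capacitance nullified. A warning is
#' issued above `omega_bar_m / 3`, where the resistive approximation
#' degrades.
#'
#' @param coeffs An [lf_coefficients()] object.
#' @inheritParams hf_response
#' @return An `ohc_response` with `model = "lf"`.
#' @export
lf_response <- function(coeffs, gamma, grid, fbar = 1,
                        groups = coeffs$groups) {
  stopifnot(inherits(coeffs, "ohc_lf_coefficients"),
            gamma >= 0, gamma <= 1)
  grid <- as_grid(grid)
  if (groups$omega_bar_m > 0 && max(grid$omega_bar) > groups$omega_bar_m / 3)
    warning("low-frequency form evaluated above omega_bar_m / 3, ",
            "outside its validity region", call. = FALSE)
  ev <- function(omega_bar) {
    D <- -omega_bar^2 +
      1i * omega_bar * (1 / groups$omega_bar_eta + gamma * coeffs$Al) +
      1 + gamma * coeffs$Bl
    (1 + groups$alpha_c * gamma * groups$ua) * fbar / D
  }
  make_response(groups, gamma, grid, ev(grid$omega_bar), "lf", fbar, ev)
}

#' Gating compliance
#'
#' Zero-frequency compliance of the unloaded cell under constant voltage:
#' `x / Fext = (1 + gamma ua) / ko`. The motor population softens the cell
#' by the factor `1 + gamma ua`, the somatic analogue of hair-bundle
#' gating compliance; the effect is small because `ua` is small.
#'
#' @param params An `ohc_parameters` object (the external load is ignored:
#'   the defining condition is `Kbar_e = 0`, `alpha_c = 1`).
#' @param gamma Electromotile activity in `[0, 1]`.
#' @return Compliance in m/N.
#' @export
#' @examples
#' gating_compliance(guinea_pig_4khz(), gamma = 0) # 1/ko = 58.8 m/N
gating_compliance <- function(params, gamma) {
  stopifnot(inherits(params, "ohc_parameters"), gamma >= 0, gamma <= 1)
  if (params$mech$ko <= 0) stop("ko must be positive", call. = FALSE)
  unloaded <- params
  unloaded$mech$Ke <- 0
  ua <- derive_groups(unloaded)$ua
  (1 + gamma * ua) / params$mech$ko
}

#' Amplifier effectiveness gap
#'
#' At full activity the amplifier nulls the net damping near the (stiffened)
#' resonance `wb^2 = 1 + Bh` when `Ah` reaches `(1 + Bh)/omega_bar_eta`.
#' The signed gap `Ah - (1 + Bh)/omega_bar_eta` (positive: the OHC can
#' cancel the viscous drag at resonance) is returned rather than a
#' boolean so parameter sweeps can locate the failure point. `Bh` here is
#' the scalar `Bh_term1 + Bh_term2` (the conductance correction is
#' negligible at the peak).
#'
#' @param coeffs An [hf_coefficients()] object.
#' @param groups Group set providing `omega_bar_eta`; defaults to the one
#'   stored in `coeffs`.
#' @return A list with `gap`, `required_Ah`, `Ah`, `Bh` and the evaluation
#'   frequency `omega_bar_star = sqrt(1 + Bh)`.
#' @export
effectiveness_gap <- function(coeffs, groups = coeffs$groups) {
  stopifnot(inherits(coeffs, "ohc_hf_coefficients"))
  Bh <- coeffs$Bh
  required <- (1 + Bh) / groups$omega_bar_eta
  list(gap = coeffs$Ah - required, required_Ah = required,
       Ah = coeffs$Ah, Bh = Bh, omega_bar_star = sqrt(1 + Bh))
}

#' Toggle the strain-induced polarization stiffness
#'
#' Returns high-frequency coefficients with `Bh_term2` (the
#' strain-polarization stiffness `beta N q^2/(4 C0)`) zeroed when
#' `enabled = FALSE`; the anti-damping factor is left untouched. Used to
#' isolate the upward resonance shift that this stiffness causes in the
#' pure piezoelectric sweeps.
#'
#' @param coeffs An [hf_coefficients()] object.
#' @param enabled `TRUE` returns the coefficients unchanged.
#' @return An `ohc_hf_coefficients` object.
#' @export
strain_stiffness_toggle <- function(coeffs, enabled = TRUE) {
  stopifnot(inherits(coeffs, "ohc_hf_coefficients"))
  if (enabled) return(coeffs)
  coeffs$Bh_term2 <- 0
  Bh1 <- coeffs$Bh_term1
  t3 <- coeffs$Bh_term3_at
  coeffs$Bh <- Bh1
  coeffs$Bh_at <- function(omega_bar) Bh1 + t3(omega_bar)
  coeffs
}
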