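# Dimensionless groups: every solver in the package consumes these rather
# than raw SI values. Frequencies are reduced by the mechanical resonance
# (omega_bar = omega / omega_r).

#' Derive the dimensionless groups of the model
#'
#' Collapses a physical parameter set to the groups the reduced equations
#' use:
#' * `ua = beta a^2 N ko / 4` — gating-compliance strength (effect of
#'   external force on the motor population);
#' * `Kbar_e = Ke / (ko + Ke)` — external-load impedance-mismatch factor;
#' * `alpha_c` — drive factor, 1 for series connectivity and `1 - Kbar_e`
#'   for parallel;
#' * `omega_bar_eta = ((ko + Ke) / eta) / omega_r` — reduced viscous
#'   roll-off frequency;
#' * `omega_bar_m = sigma / (omega_r C0)` — reduced middle frequency, the
#'   crossover between resistive and capacitive membrane impedance;
#' * `g = a N (1 - Kbar_e) gx` — closed-loop bundle feedback gain
#'   (negative for the amplifying sign convention);
#' * `chi = beta N q^2 / (4 C0)` — strain-induced polarization stiffness
#'   (the dominant term of the high-frequency stiffness factor);
#' * `a1 = beta q i0 g / (4 omega_r C0)` — bundle-current anti-damping
#'   gain (the leading term of the high-frequency anti-damping factor).
#'
#' @param params An [ohc_parameters()] object.
#' @param omega_bar_eta_override Optional direct value for `omega_bar_eta`,
#'   replacing the canonical `(ko + Ke)/eta/omega_r`. The published
#'   guinea-pig figures use 10, which is not the canonical value (~18.4)
#'   but matches `Ke/eta/omega_r`; see the methods vignette.
#' @param allow_degenerate Permit `C0 = 0` (the purely resistive membrane
#'   used by the low-frequency limit); the capacitance-scaled groups
#'   `chi`, `a1` and `omega_bar_m` are then infinite and only solvers
#'   that work from SI parameters accept the result. Default `FALSE`:
#'   a non-positive `C0` is an error.
#' @return An object of class `ohc_groups`.
#' @export
#' @examples
#' g <- derive_groups(guinea_pig_4khz())
#' signif(g$ua, 2)          # 0.14
#' signif(g$omega_bar_m, 2) # 0.013
derive_groups <- function(params, omega_bar_eta_override = NULL,
                          allow_degenerate = FALSE) {
  stopifnot(inherits(params, "ohc_parameters"))
  ko <- params$mech$ko
  Ke <- params$mech$Ke
  if (!is.finite(ko + Ke) || ko + Ke <= 0)
    stop("ko + Ke must be positive", call. = FALSE)
  if (params$circuit$C0 < 0 ||
      (params$circuit$C0 == 0 &&
       (!allow_degenerate || params$circuit$sigma <= 0)))
    stop("C0 must be positive to form dimensionless groups", call. = FALSE)
  omega_r <- params$mech$omega_r
  if (omega_r <= 0) stop("resonance frequency must be positive", call. = FALSE)
  beta <- 1 / params$constants$kBT
  a <- params$motor$a
  N <- params$motor$N
  q <- params$motor$q
  Kbar_e <- Ke / (ko + Ke)
  g <- a * N * (1 - Kbar_e) * params$bundle$gx
  omega_bar_eta <- if (is.null(omega_bar_eta_override)) {
    ((ko + Ke) / params$mech$eta) / omega_r
  } else {
    stopifnot(omega_bar_eta_override > 0)
    omega_bar_eta_override
  }
  dimensionless_groups(
    ua = beta * a^2 * N * ko / 4,
    Kbar_e = Kbar_e,
    omega_bar_eta = omega_bar_eta,
    omega_bar_m = params$circuit$sigma / (omega_r * params$circuit$C0),
    g = g,
    chi = beta * N * q^2 / (4 * params$circuit$C0),
    a1 = beta * q * params$circuit$i0 * g / (4 * omega_r * params$circuit$C0),
    connectivity = params$mech$connectivity,
    beta = beta,
    label = params$label)
}

#' Dimensionless parameter mode
#'
#' Constructs the group object directly, bypassing SI parameters — the
#' second input mode of the model. `chi` and `a1` are required because the
#' exact electrical coupling term, `gamma (i w chi + a1) / (omega_bar_m +
#' i w)`, is not expressible through `ua`, `Kbar_e`, `omega_bar_eta`,
#' `omega_bar_m` and `g` alone.
#'
#' @param ua Gating-compliance strength, >= 0.
#' @param Kbar_e External-load factor in `[0, 1)`.
#' @param omega_bar_eta Reduced viscous roll-off frequency, > 0.
#' @param omega_bar_m Reduced middle frequency, >= 0 (0 means a purely
#'   capacitive membrane, sigma = 0).
#' @param g Closed-loop bundle feedback gain (signed; < 0 amplifies).
#' @param chi Strain-induced polarization stiffness, >= 0.
#' @param a1 Bundle-current anti-damping gain (signed; > 0 amplifies;
#'   it carries the product of the signs of `q` and `g`).
#' @param connectivity `"series"` or `"parallel"`.
#' @param beta Optional `1/kBT` (1/J), carried for SI bookkeeping.
#' @param label Optional scenario name.
#' @return An object of class `ohc_groups`.
#' @export
dimensionless_groups <- function(ua, Kbar_e, omega_bar_eta, omega_bar_m,
                                 g = 0, chi = 0, a1 = 0,
                                 connectivity = c("series", "parallel"),
                                 beta = NULL, label = NULL) {
  connectivity <- match.arg(connectivity)
  stopifnot(ua >= 0, Kbar_e >= 0, Kbar_e < 1, omega_bar_eta > 0,
            omega_bar_m >= 0, chi >= 0, is.finite(g), !is.na(a1))
  structure(list(
    ua = ua, Kbar_e = Kbar_e,
    alpha_c = if (connectivity == "series") 1 else 1 - Kbar_e,
    omega_bar_eta = omega_bar_eta, omega_bar_m = omega_bar_m,
    g = g, chi = chi, a1 = a1,
    connectivity = connectivity, beta = beta, label = label),
    class = "ohc_groups")
}

#' @export
print.ohc_groups <- function(x, ...) {
  cat("<ohc_groups>", if (!is.null(x$label)) paste0(" ", x$label), "\n", sep = "")
  cat(sprintf("  ua = %.4g  Kbar_e = %.4g  alpha_c = %.4g (%s)\n",
              x$ua, x$Kbar_e, x$alpha_c, x$connectivity))
  cat(sprintf("  omega_bar_eta = %.4g  omega_bar_m = %.4g\n",
              x$omega_bar_eta, x$omega_bar_m))
  cat(sprintf("  g = %.4g  chi = %.4g  a1 = %.4g\n", x$g, x$chi, x$a1))
  invisible(x)
}

# Coerce either parameters or groups to groups.
as_groups <- function(x, ...) {
  if (inherits(x, "ohc_groups")) x
  else if (inherits(x, "ohc_parameters")) derive_groups(x, ...)
  else stop("expected `ohc_parameters` or `ohc_groups`", call. = FALSE)
}
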