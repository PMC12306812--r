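# Physical parameter containers for one OHC plus its mechanical load.
#
# All quantities are SI. Sign conventions follow the two-state motor:
# a > 0 and q < 0 because depolarization shrinks the cell, and the
# hair-bundle sensitivity carries the sign that makes shortening increase
# the transducer current (amplifying feedback, g < 0).

#' Physical constants
#'
#' Thermal energy and elementary charge used throughout the model.
#'
#' @param kBT Thermal energy in joules. The default, 4.142e-21 J,
#'   corresponds to T = 300 K and is the value under which the reference
#'   guinea-pig coefficients reproduce.
#' @param e_charge Elementary charge in coulombs.
#' @return An object of class `ohc_constants`.
#' @export
physical_constants <- function(kBT = 4.142e-21, e_charge = 1.6e-19) {
  stopifnot(is.numeric(kBT), length(kBT) == 1L, kBT > 0,
            is.numeric(e_charge), length(e_charge) == 1L, e_charge > 0)
  structure(list(kBT = kBT, e_charge = e_charge), class = "ohc_constants")
}

#' Motor element (piezoelectric unit) description
#'
#' A population of `N` two-state motors, each moving charge `q` across the
#' membrane and contributing length `a` when switching from the short to
#' the long state. The operating-point parameter `gamma = 4 P0 (1 - P0)`
#' measures the sensitivity of the population; it is maximal (1) at
#' `P0 = 0.5`.
#'
#' @param q Motile charge per motor (C). Must be negative.
#' @param a Length contribution per motor (m). Must be positive.
#' @param N Number of motors (>= 1).
#' @param P0 Resting open fraction in `[0, 1]`. Optional; when given,
#'   `gamma` is derived as `4 * P0 * (1 - P0)` and must not also be supplied.
#' @param gamma Electromotile activity in `[0, 1]`. Defaults to 1 (operating
#'   point at `P0 = 0.5`) when neither `P0` nor `gamma` is given.
#' @return An object of class `ohc_motor`.
#' @export
motor_element <- function(q, a, N, P0 = NULL, gamma = NULL) {
  stopifnot(is.numeric(q), length(q) == 1L, q < 0)
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  if (!is.null(P0) && !is.null(gamma))
    stop("supply either `P0` or `gamma`, not both", call. = FALSE)
  if (!is.null(P0)) {
    stopifnot(is.numeric(P0), length(P0) == 1L, P0 >= 0, P0 <= 1)
    gamma <- 4 * P0 * (1 - P0)
  } else if (is.null(gamma)) {
    P0 <- 0.5
    gamma <- 1
  }
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1)
  structure(list(q = q, a = a, N = N, P0 = P0, gamma = gamma),
            class = "ohc_motor")
}

#' Membrane circuit description
#'
#' RC circuit of the OHC basolateral membrane driven through the
#' hair-bundle (apical) resistance. Either the steady current `i0` and
#' conductance `sigma` are given directly, or they are derived from the
#' resistances and potentials:
#' `sigma = 1/R0 + 1/Rm` and `i0` via [steady_state_current()].
#'
#' @param C0 Structural (linear) membrane capacitance (F), > 0.
#' @param sigma Steady-state conductance (S), >= 0. Derived from `R0`, `Rm`
#'   when those are given. `sigma = 0` is allowed (used in limiting
#'   analyses) but then `R0`/`Rm` must be absent.
#' @param i0 Steady-state (baseline) transducer current (A), >= 0.
#' @param Rm Basolateral membrane resistance (Ohm).
#' @param R0 Resting hair-bundle resistance (Ohm).
#' @param eep Endocochlear potential (V).
#' @param eK Basolateral reversal potential (V), close to the K+ Nernst
#'   potential.
#' @param V0 Resting membrane potential (V).
#' @return An object of class `ohc_circuit`.
#' @export
membrane_circuit <- function(C0, sigma = NULL, i0 = NULL, Rm = NULL,
                             R0 = NULL, eep = NULL, eK = NULL, V0 = NULL) {
  stopifnot(is.numeric(C0), length(C0) == 1L, C0 >= 0)
  if (is.null(sigma)) {
    if (is.null(R0) || is.null(Rm))
      stop("supply `sigma` or both `R0` and `Rm`", call. = FALSE)
    sigma <- 1 / R0 + 1 / Rm
  }
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (is.null(i0)) {
    i0 <- steady_state_current(
      list(Rm = Rm, R0 = R0, eep = eep, eK = eK, V0 = V0))
  }
  stopifnot(is.numeric(i0), length(i0) == 1L, i0 >= 0)
  structure(list(C0 = C0, sigma = sigma, i0 = i0, Rm = Rm, R0 = R0,
                 eep = eep, eK = eK, V0 = V0),
            class = "ohc_circuit")
}

#' Steady-state transducer current
#'
#' Two documented modes:
#' * resting-potential mode (the default when `V0` is available):
#'   `i0 = (V0 - eK) / Rm` — the current that holds the resting potential
#'   `V0` against the basolateral leak;
#' * divider mode: `i0 = (eep - eK) / (R0 + Rm)` — the endocochlear
#'   potential driving the series combination of bundle and basolateral
#'   resistances.
#'
#' The guinea-pig reference numbers (0.3 nA at -50 mV, 0.4 nA at -40 mV)
#' come from resting-potential mode.
#'
#' @param circuit An `ohc_circuit`, or a bare list with the needed fields.
#' @param mode `"resting"`, `"divider"`, or `"auto"` (resting-potential mode
#'   when `V0` is present, divider mode otherwise).
#' @return Steady current in amperes.
#' @export
#' @examples
#' steady_state_current(list(V0 = -50e-3, eK = -80e-3, Rm = 100e6)) # 3e-10
steady_state_current <- function(circuit, mode = c("auto", "resting", "divider")) {
  mode <- match.arg(mode)
  cc <- unclass(circuit)
  if (mode == "auto")
    mode <- if (!is.null(cc$V0)) "resting" else "divider"
  if (mode == "resting") {
    if (is.null(cc$V0) || is.null(cc$eK) || is.null(cc$Rm))
      stop("resting-potential mode needs V0, eK and Rm", call. = FALSE)
    (cc$V0 - cc$eK) / cc$Rm
  } else {
    if (is.null(cc$eep) || is.null(cc$eK) || is.null(cc$R0) || is.null(cc$Rm))
      stop("divider mode needs eep, eK, R0 and Rm", call. = FALSE)
    (cc$eep - cc$eK) / (cc$R0 + cc$Rm)
  }
}

#' Mechanical system description
#'
#' The OHC (axial stiffness `ko`) loaded by an external elastic element
#' `Ke` (basilar membrane), a viscous drag `eta`, and a mass. The mass is
#' never specified directly: the system is parameterized by its mechanical
#' resonance frequency `fr`, with `m = (ko + Ke) / (2 pi fr)^2`.
#'
#' @param ko OHC axial stiffness (N/m), > 0.
#' @param Ke External (basilar-membrane) stiffness (N/m), >= 0.
#' @param eta Drag coefficient (N s/m), > 0.
#' @param fr Mechanical resonance frequency (Hz), > 0.
#' @param connectivity `"series"` or `"parallel"` attachment of the OHC to
#'   the load; the distinction only matters through the drive factor
#'   `alpha_c` and is insignificant when `ua << 1`.
#' @return An object of class `ohc_mech` with derived fields `omega_r`
#'   (rad/s) and `m` (kg).
#' @export
mechanical_system <- function(ko, Ke, eta, fr,
                              connectivity = c("series", "parallel")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.numeric(ko), length(ko) == 1L, ko > 0)
  stopifnot(is.numeric(Ke), length(Ke) == 1L, Ke >= 0)
  stopifnot(is.numeric(eta), length(eta) == 1L, eta > 0)
  stopifnot(is.numeric(fr), length(fr) == 1L, fr > 0)
  omega_r <- 2 * pi * fr
  structure(list(ko = ko, Ke = Ke, eta = eta, fr = fr,
                 connectivity = connectivity,
                 omega_r = omega_r, m = (ko + Ke) / omega_r^2),
            class = "ohc_mech")
}

#' Hair-bundle coupling
#'
#' The relative hair-bundle resistance change is `r = gx * x` for a bundle
#' deflection equal to the load displacement `x`. In reduced variables the
#' feedback closes as `r = g * p` with `g = a N (1 - Kbar_e) gx`.
#' Amplification requires `g < 0` (since `q < 0`), i.e. cell shortening
#' must increase the transducer current; `gx` therefore carries a negative
#' sign by convention here, while its magnitude is quoted as a sensitivity.
#'
#' @param gx Bundle resistance sensitivity to displacement (1/m), signed.
#'   Negative for the amplifying configuration.
#' @return An object of class `ohc_bundle`.
#' @export
hair_bundle_coupling <- function(gx) {
  stopifnot(is.numeric(gx), length(gx) == 1L, is.finite(gx))
  structure(list(gx = gx), class = "ohc_bundle")
}

#' Full OHC parameter set
#'
#' Bundles the motor, circuit, mechanical and bundle descriptions into one
#' validated object, the physical input to every solver in the package.
#'
#' @param motor An [motor_element()].
#' @param circuit A [membrane_circuit()].
#' @param mech A [mechanical_system()].
#' @param bundle A [hair_bundle_coupling()].
#' @param constants [physical_constants()].
#' @param label Optional scenario name carried through reports.
#' @return An object of class `ohc_parameters`.
#' @seealso [guinea_pig_4khz()], [derive_groups()], [exact_response()]
#' @export
ohc_parameters <- function(motor, circuit, mech, bundle,
                           constants = physical_constants(),
                           label = NULL) {
  stopifnot(inherits(motor, "ohc_motor"), inherits(circuit, "ohc_circuit"),
            inherits(mech, "ohc_mech"), inherits(bundle, "ohc_bundle"),
            inherits(constants, "ohc_constants"))
  structure(list(constants = constants, motor = motor, circuit = circuit,
                 mech = mech, bundle = bundle, label = label),
            class = "ohc_parameters")
}

#' @export
print.ohc_parameters <- function(x, ...) {
  cat("<ohc_parameters>", if (!is.null(x$label)) paste0(" ", x$label), "\n",
      sep = "")
  cat(sprintf("  motor:   q = %.3g C, a = %.3g m, N = %.3g, gamma = %.3g\n",
              x$motor$q, x$motor$a, x$motor$N, x$motor$gamma))
  cat(sprintf("  circuit: C0 = %.3g F, sigma = %.3g S, i0 = %.3g A\n",
              x$circuit$C0, x$circuit$sigma, x$circuit$i0))
  cat(sprintf("  mech:    ko = %.3g N/m, Ke = %.3g N/m, eta = %.3g N s/m, fr = %.3g Hz (%s)\n",
              x$mech$ko, x$mech$Ke, x$mech$eta, x$mech$fr,
              x$mech$connectivity))
  cat(sprintf("  bundle:  gx = %.3g 1/m\n", x$bundle$gx))
  invisible(x)
}

# ---- derivations from measured quantities ---------------------------------

#' Axial stiffness from elastic modulus and exposed length
#'
#' The OHC elastic modulus is quoted as force per unit strain; dividing by
#' the exposed (unclamped) length gives the axial stiffness. For the
#' guinea-pig reference cell, 510 nN over the 30 um not held by the
#' Deiters' cup gives 17 mN/m.
#'
#' @param modulus Force per unit strain (N), >= 0.
#' @param exposed_length Exposed cell length (m), > 0.
#' @return Stiffness in N/m.
#' @export
stiffness_from_modulus <- function(modulus, exposed_length) {
  stopifnot(is.numeric(modulus), modulus >= 0,
            is.numeric(exposed_length))
  if (any(exposed_length <= 0))
    stop("`exposed_length` must be positive", call. = FALSE)
  modulus / exposed_length
}

#' Motor count from peak excess capacitance
#'
#' The motile charge contributes a bell-shaped excess capacitance whose
#' peak is `beta q^2 N / 4`; equating that to a measured peak gives
#' `N = 4 Cpeak kBT / q^2`.
#'
#' @param peak_excess_capacitance Measured peak excess capacitance (F).
#' @param q Motile charge per motor (C); the sign is irrelevant.
#' @param kBT Thermal energy (J).
#' @param signif_digits Optional rounding of the result in significant
#'   figures (the literature quotes 1 s.f.); `NULL` returns full precision.
#' @return Motor count (dimensionless).
#' @export
#' @examples
#' motor_count_from_capacitance(30e-12, 0.8 * 1.6e-19, signif_digits = 1) # 3e7
motor_count_from_capacitance <- function(peak_excess_capacitance, q,
                                         kBT = physical_constants()$kBT,
                                         signif_digits = NULL) {
  if (any(q == 0)) stop("`q` must be nonzero", call. = FALSE)
  stopifnot(peak_excess_capacitance >= 0, kBT > 0)
  N <- 4 * peak_excess_capacitance * kBT / q^2
  if (!is.null(signif_digits)) N <- signif(N, signif_digits)
  N
}

#' Unit displacement from maximal electromotile amplitude
#'
#' The load-free electromotile amplitude is `a N`; given that total (e.g.
#' 5% of the cell length) and the motor count, the per-motor contribution
#' follows.
#'
#' @param total_amplitude Maximal load-free length change `a N` (m).
#' @param N Motor count.
#' @return Unit displacement `a` in meters.
#' @export
unit_displacement_from_amplitude <- function(total_amplitude, N) {
  stopifnot(total_amplitude >= 0, N > 0)
  total_amplitude / N
}

#' Drag coefficient from subtectorial-gap geometry
#'
#' Models the dominant drag as shear flow in the subtectorial space:
#' `eta = viscosity * S / d` with gap area `S` per OHC and gap height `d`
#' (the tallest stereocilia row).
#'
#' @param gap_area Gap area per OHC (m^2), >= 0.
#' @param gap_height Gap height (m), > 0.
#' @param viscosity Dynamic viscosity (Pa s); default water at body
#'   temperature-ish, 0.8 mPa s.
#' @return Drag coefficient in N s/m.
#' @export
drag_from_subtectorial_geometry <- function(gap_area, gap_height,
                                            viscosity = 0.8e-3) {
  stopifnot(gap_area >= 0, viscosity >= 0)
  if (any(gap_height <= 0)) stop("`gap_height` must be positive", call. = FALSE)
  viscosity * gap_area / gap_height
}
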