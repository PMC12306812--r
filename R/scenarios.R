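# Scenario fixtures and scenario-file I/O.

#' Guinea-pig 4 kHz reference scenario
#'
#' The mid-frequency reference cell: a 40 um OHC at the 4 kHz place of the
#' guinea-pig cochlea. Values are the standard compilation for this cell:
#' q = -0.8 e, a = 0.67e-4 nm, N = 3e7, C0 = 30 pF, sigma = 10 nS,
#' i0 = 0.3 nA, ko = 17 mN/m, Ke = 20 mN/m, |gx| = 1/(25 nm),
#' eta = 0.8e-7 N s/m, fr = 4 kHz. `gx` is stored negative (amplifying
#' feedback sign).
#'
#' @param connectivity `"series"` (default) or `"parallel"`.
#' @param amplifying Logical; `FALSE` flips the sign of `gx` to explore the
#'   non-amplifying configuration.
#' @return An [ohc_parameters()] object.
#' @export
#' @examples
#' p <- guinea_pig_4khz()
#' signif(derive_groups(p)$ua, 2) # 0.14
guinea_pig_4khz <- function(connectivity = c("series", "parallel"),
                            amplifying = TRUE) {
  connectivity <- match.arg(connectivity)
  e <- physical_constants()$e_charge
  ohc_parameters(
    motor = motor_element(q = -0.8 * e, a = 0.67e-13, N = 3e7),
    circuit = membrane_circuit(C0 = 30e-12, sigma = 10e-9, i0 = 0.3e-9),
    mech = mechanical_system(ko = 17e-3, Ke = 20e-3, eta = 0.8e-7,
                             fr = 4000, connectivity = connectivity),
    bundle = hair_bundle_coupling(gx = (if (amplifying) -1 else 1) / 25e-9),
    label = "guinea-pig-4khz")
}

#' Figure-mode dimensionless groups
#'
#' The group set under which the published amplitude/phase sweeps of the
#' reference cell are drawn: all electrical and elastic groups derived
#' from [guinea_pig_4khz()], with the reduced viscous roll-off frequency
#' pinned to the quoted `omega_bar_eta = 10` (the canonical
#' `(ko+Ke)/eta/omega_r` gives ~18.4; `Ke/eta/omega_r` gives ~10, which is
#' what the quoted value appears to be). See the methods vignette for the
#' discussion of this choice and of the middle frequency.
#'
#' @param omega_bar_eta Reduced viscous roll-off frequency; default 10.
#' @param omega_bar_m Optional override of the reduced middle frequency;
#'   default is the value derived from the reference electrical parameters
#'   (~0.0133).
#' @return An `ohc_groups` object.
#' @export
figure_mode_groups <- function(omega_bar_eta = 10, omega_bar_m = NULL) {
  g <- derive_groups(guinea_pig_4khz(), omega_bar_eta_override = omega_bar_eta)
  if (!is.null(omega_bar_m)) {
    stopifnot(omega_bar_m >= 0)
    g$omega_bar_m <- omega_bar_m
  }
  g$label <- "guinea-pig-4khz (figure mode)"
  g
}

#' Seeded randomized scenario
#'
#' Draws a physically valid parameter set around the guinea-pig reference
#' for property tests: log-uniform within one decade of the reference for
#' N, C0, sigma, i0, ko, Ke, eta, fr and |gx| (half a decade for q), with
#' the unit displacement `a` set from a one-decade log-uniform draw of the
#' gating-compliance group `ua` (so the small-signal linearization stays
#' defensible). Draws are resampled, deterministically from the seed
#' stream, until the closed loop at `gamma = 1` is stable — the regime in
#' which a forced steady state exists and frequency- and time-domain
#' solutions can be compared.
#'
#' @param seed Integer seed; the same seed always returns the same scenario.
#' @return An [ohc_parameters()] object.
#' @export
random_scenario <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ref <- guinea_pig_4khz()
  kBT <- ref$constants$kBT
  dec <- function(half = FALSE) 10^(runif(1, -1, 1) * (if (half) 0.5 else 1))
  for (attempt in seq_len(1000L)) {
    N  <- ref$motor$N * dec()
    q  <- ref$motor$q * dec(half = TRUE)
    ko <- ref$mech$ko * dec()
    Ke <- ref$mech$Ke * dec()
    ua <- 0.138 * 10^runif(1, -1, 1)
    a  <- sqrt(4 * kBT * ua / (N * ko))
    params <- ohc_parameters(
      motor = motor_element(q = q, a = a, N = N),
      circuit = membrane_circuit(C0 = ref$circuit$C0 * dec(),
                                 sigma = ref$circuit$sigma * dec(),
                                 i0 = ref$circuit$i0 * dec()),
      mech = mechanical_system(ko = ko, Ke = Ke,
                               eta = ref$mech$eta * dec(),
                               fr = ref$mech$fr * dec(),
                               connectivity = sample(c("series", "parallel"), 1)),
      bundle = hair_bundle_coupling(gx = ref$bundle$gx * dec()),
      label = sprintf("random-%d", as.integer(seed)))
    # accept only scenarios comfortably inside the stable regime at full
    # activity (slowest transient decays within ~1e3 reduced time units),
    # so forced steady states exist and are reachable
    ev <- eigen(closed_loop_matrix(derive_groups(params), gamma = 1),
                only.values = TRUE)$values
    if (all(Re(ev) < 0) && min(-Re(ev)) > 1e-3) return(params)
  }
  stop("no stable scenario found for this seed", call. = FALSE)
}

# ---- scenario files -------------------------------------------------------

# "value unit" strings in scenario files; multipliers to SI.
.unit_table <- c(
  "C" = 1, "e" = 1.6e-19,
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "nm" = 1e-9, "pm" = 1e-12,
  "F" = 1, "pF" = 1e-12, "nF" = 1e-9, "uF" = 1e-6,
  "S" = 1, "nS" = 1e-9, "uS" = 1e-6, "pS" = 1e-12,
  "A" = 1, "nA" = 1e-9, "pA" = 1e-12, "uA" = 1e-6,
  "N/m" = 1, "mN/m" = 1e-3, "uN/m" = 1e-6,
  "N s/m" = 1, "N*s/m" = 1, "uN s/m" = 1e-6,
  "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6,
  "V" = 1, "mV" = 1e-3,
  "ohm" = 1, "Mohm" = 1e6, "Gohm" = 1e9,
  "1/m" = 1, "1/um" = 1e6, "1/nm" = 1e9,
  "J" = 1, "N" = 1, "nN" = 1e-9, "Pa s" = 1, "mPa s" = 1e-3)

parse_quantity <- function(x, field = "") {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop("cannot parse quantity for field `", field, "`", call. = FALSE)
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*(.*?)\\s*$", x))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2]))))
    stop("cannot parse quantity `", x, "` for field `", field, "`",
         call. = FALSE)
  val <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(val)
  if (!unit %in% names(.unit_table))
    stop("unknown unit `", unit, "` in field `", field, "`", call. = FALSE)
  val * .unit_table[[unit]]
}

#' Read a scenario file
#'
#' YAML scenario files carry two optional top-level blocks, `physical:`
#' (SI quantities, either bare numbers or `"value unit"` strings) and
#' `dimensionless:` (group values). When both are present the
#' dimensionless block wins and a warning is issued. Physical fields:
#' `q, a, N, C0, sigma, i0, ko, Ke, gx, eta, fr, connectivity`
#' (plus optional `kBT`, `gamma`, `Rm, R0, eep, eK, V0` in place of
#' `sigma`/`i0`). Dimensionless fields: those of [dimensionless_groups()].
#'
#' @param path Path to a YAML file.
#' @return An `ohc_parameters` or `ohc_groups` object.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  label <- sc$label
  if (!is.null(sc$dimensionless)) {
    if (!is.null(sc$physical))
      warning("scenario has both `physical` and `dimensionless` blocks; ",
              "dimensionless values win", call. = FALSE)
    d <- sc$dimensionless
    return(dimensionless_groups(
      ua = d$ua, Kbar_e = d$Kbar_e, omega_bar_eta = d$omega_bar_eta,
      omega_bar_m = d$omega_bar_m,
      g = d$g %||% 0, chi = d$chi %||% 0, a1 = d$a1 %||% 0,
      connectivity = d$connectivity %||% "series",
      beta = d$beta, label = label))
  }
  ph <- sc$physical
  if (is.null(ph)) stop("scenario file has neither `physical` nor ",
                        "`dimensionless` block", call. = FALSE)
  # YAML 1.1 reads a bare `N` key as boolean; map it back
  names(ph)[names(ph) %in% c("FALSE", "TRUE")] <- "N"
  # parse every quantity up front so unit errors surface before any
  # structural validation
  for (field in setdiff(names(ph), "connectivity"))
    ph[[field]] <- parse_quantity(ph[[field]], field)
  qty <- function(field) ph[[field]]
  constants <- physical_constants(kBT = qty("kBT") %||% 4.142e-21)
  circuit <- membrane_circuit(
    C0 = qty("C0"), sigma = qty("sigma"), i0 = qty("i0"),
    Rm = qty("Rm"), R0 = qty("R0"), eep = qty("eep"), eK = qty("eK"),
    V0 = qty("V0"))
  ohc_parameters(
    motor = motor_element(q = qty("q"), a = qty("a"), N = qty("N"),
                          gamma = qty("gamma")),
    circuit = circuit,
    mech = mechanical_system(ko = qty("ko"), Ke = qty("Ke"),
                             eta = qty("eta"), fr = qty("fr"),
                             connectivity = ph$connectivity %||% "series"),
    bundle = hair_bundle_coupling(gx = qty("gx")),
    constants = constants, label = label)
}

#' Export a parameter set and its groups as JSON
#'
#' Flat key/value JSON with a `units` sub-object documenting the SI unit
#' of each physical field; dimensionless groups are appended under
#' `groups`.
#'
#' @param params An `ohc_parameters` object.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
export_parameters_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "ohc_parameters"))
  gr <- derive_groups(params)
  out <- list(
    label = params$label,
    q = params$motor$q, a = params$motor$a, N = params$motor$N,
    gamma = params$motor$gamma,
    C0 = params$circuit$C0, sigma = params$circuit$sigma,
    i0 = params$circuit$i0,
    ko = params$mech$ko, Ke = params$mech$Ke, eta = params$mech$eta,
    fr = params$mech$fr, m = params$mech$m,
    connectivity = params$mech$connectivity,
    gx = params$bundle$gx, kBT = params$constants$kBT,
    units = list(q = "C", a = "m", N = "1", gamma = "1", C0 = "F",
                 sigma = "S", i0 = "A", ko = "N/m", Ke = "N/m",
                 eta = "N s/m", fr = "Hz", m = "kg", gx = "1/m",
                 kBT = "J"),
    groups = unclass(gr)[c("ua", "Kbar_e", "alpha_c", "omega_bar_eta",
                           "omega_bar_m", "g", "chi", "a1")])
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
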