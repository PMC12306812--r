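# Sweep orchestration, peak metrics, approximation-error reports,
# coefficient reports and figure regeneration.

#' Resolve a scenario argument
#'
#' Accepts an `ohc_parameters` or `ohc_groups` object, the name of a
#' built-in fixture (`"guinea-pig-4khz"`, `"figure-mode"`), or the path of
#' a YAML scenario file.
#'
#' @param scenario Scenario object, fixture name or file path.
#' @return An `ohc_parameters` or `ohc_groups` object.
#' @export
resolve_scenario <- function(scenario) {
  if (inherits(scenario, "ohc_parameters") || inherits(scenario, "ohc_groups"))
    return(scenario)
  if (!is.character(scenario) || length(scenario) != 1L)
    stop("scenario must be a parameter object, a fixture name or a file path",
         call. = FALSE)
  if (scenario == "guinea-pig-4khz") return(guinea_pig_4khz())
  if (scenario == "figure-mode") return(figure_mode_groups())
  if (file.exists(scenario)) return(read_scenario(scenario))
  stop("unknown scenario `", scenario, "`; available fixtures: ",
       "guinea-pig-4khz, figure-mode (or give a YAML file path)",
       call. = FALSE)
}

#' Run a frequency sweep over several activity levels
#'
#' Computes one response per `gamma` for the requested model and
#' optionally writes the combined CSV (see [write_response_csv()] for the
#' column layout).
#'
#' @param scenario Scenario object, fixture name or YAML path (see
#'   [resolve_scenario()]).
#' @param gammas Activity levels, each in `[0, 1]`; must be non-empty.
#' @param grid A [frequency_grid()] or numeric vector of reduced
#'   frequencies.
#' @param model `"exact"`, `"hf"`, `"lf"` or `"piezo"`.
#' @param sigma_correction For `model = "hf"`: keep the conductance terms
#'   of the expansion (default `TRUE`).
#' @param strain_stiffness For `model = "hf"`: keep the strain-induced
#'   polarization stiffness term (default `TRUE`).
#' @param fbar Reduced drive amplitude.
#' @param out Optional CSV output path.
#' @return A named list of `ohc_response` objects (names = gamma values).
#' @export
run_sweep <- function(scenario, gammas, grid = frequency_grid(),
                      model = c("exact", "hf", "lf", "piezo"),
                      sigma_correction = TRUE, strain_stiffness = TRUE,
                      fbar = 1, out = NULL) {
  model <- match.arg(model)
  if (length(gammas) == 0)
    stop("`gammas` must contain at least one value", call. = FALSE)
  stopifnot(all(gammas >= 0), all(gammas <= 1))
  x <- resolve_scenario(scenario)
  responses <- lapply(gammas, function(g) {
    switch(model,
      exact = exact_response(x, g, grid, fbar),
      piezo = pure_piezo_response(x, g, grid, fbar),
      hf = {
        co <- hf_coefficients(x, include_sigma_correction = sigma_correction)
        co <- strain_stiffness_toggle(co, enabled = strain_stiffness)
        hf_response(co, g, grid, fbar)
      },
      lf = lf_response(lf_coefficients(x), g, grid, fbar))
  })
  names(responses) <- as.character(gammas)
  if (!is.null(out)) write_response_csv(responses, out)
  responses
}

#' Peak metrics of a response
#'
#' Locates the amplitude peak on the grid, refines it by Brent
#' minimization of `-|p|` on the bracketing grid interval (the response
#' object carries its own frequency-domain evaluator, so refinement
#' re-evaluates the model, not an interpolant), and measures the
#' unwrapped phase drop between 0.5x and 1.5x the peak frequency.
#'
#' @param response An `ohc_response` (from a grid dense enough to bracket
#'   the peak; 100+ points per decade advised).
#' @param refine_tol Relative tolerance of the peak refinement.
#' @return An object of class `ohc_peak`: `gamma`, `peak_omega_bar`,
#'   `peak_amplitude`, `phase_drop` (radians, positive for the usual
#'   downward phase step), and `at_boundary` (flagged `TRUE` when the grid
#'   argmax is an endpoint, in which case no refinement is attempted).
#' @export
peak_metrics <- function(response, refine_tol = 1e-6) {
  stopifnot(inherits(response, "ohc_response"))
  wb <- response$omega_bar
  amp <- Mod(response$p)
  i <- which.max(amp)
  ev <- response$evaluator
  at_boundary <- i == 1L || i == length(wb)
  if (at_boundary) {
    peak_wb <- wb[i]
    peak_amp <- amp[i]
  } else {
    opt <- stats::optimize(function(w) -Mod(ev(w)),
                           lower = wb[i - 1L], upper = wb[i + 1L],
                           tol = refine_tol * wb[i])
    peak_wb <- opt$minimum
    peak_amp <- -opt$objective
  }
  span <- seq(0.5 * peak_wb, 1.5 * peak_wb, length.out = 257L)
  phase <- unwrap_phase(Arg(ev(span)))
  structure(list(
    gamma = response$gamma,
    peak_omega_bar = peak_wb,
    peak_amplitude = peak_amp,
    phase_drop = phase[1L] - phase[length(phase)],
    at_boundary = at_boundary),
    class = "ohc_peak")
}

#' @export
print.ohc_peak <- function(x, ...) {
  cat(sprintf(
    "<ohc_peak> gamma=%g  peak |p|=%.4g at omega_bar=%.6g  phase drop=%.3g rad%s\n",
    x$gamma, x$peak_amplitude, x$peak_omega_bar, x$phase_drop,
    if (x$at_boundary) "  [AT GRID BOUNDARY]" else ""))
  invisible(x)
}

#' Exact vs high-frequency approximation error report
#'
#' For each activity level, the maximum relative amplitude error and the
#' maximum absolute unwrapped-phase difference between [exact_response()]
#' and [hf_response()] (with the conductance correction retained) over a
#' frequency region. At `gamma = 0` the two solvers evaluate the same
#' expression and the errors are identically zero.
#'
#' @param scenario Scenario object, fixture name or YAML path.
#' @param gammas Activity levels.
#' @param region Length-2 reduced-frequency interval.
#' @param n Number of log-spaced evaluation points.
#' @return A data frame with columns `gamma, max_rel_err_amp,
#'   max_abs_err_phase_rad`.
#' @export
approximation_error_report <- function(scenario, gammas = c(0, 0.5, 1),
                                       region = c(0.3, 3), n = 400L) {
  x <- resolve_scenario(scenario)
  grid <- frequency_grid(region[1L], region[2L], n)
  co <- hf_coefficients(x, include_sigma_correction = TRUE)
  rows <- lapply(gammas, function(g) {
    ex <- exact_response(x, g, grid)
    hf <- suppressWarnings(hf_response(co, g, grid))
    data.frame(
      gamma = g,
      max_rel_err_amp = max(abs(Mod(hf$p) - Mod(ex$p)) / Mod(ex$p)),
      max_abs_err_phase_rad = max(abs(
        response_phase(hf) - response_phase(ex))))
  })
  do.call(rbind, rows)
}

# Published coefficient values for the guinea-pig 4 kHz cell, reported
# side by side with the recomputed ones. Ah_term1, Al and Bl_term2 are
# known not to follow from the tabulated cell parameters (they imply an
# effective feedback gain |g| of about 54 instead of a N (1-Kbar_e) gx
# = 37); see the methods vignette.
.published_reference <- list(
  ua = 0.14, omega_bar_m = 0.013,
  Ah = 0.152, Ah_terms = c(0.165, 0.013),
  Bh_at_1 = 0.922, Bh_terms = c(-0.069, 0.989, 0.002),
  Al = 862, Bl = 12.360, Bl_terms = c(-0.069, 12.429))

#' Coefficient report
#'
#' The full dimensionless characterization of a scenario: derived groups,
#' high- and low-frequency coefficients with their summands, the
#' amplifier-effectiveness gap, and — for the guinea-pig reference cell —
#' the published values side by side with the recomputed ones.
#'
#' @param scenario Scenario object, fixture name or YAML path.
#' @param path Optional JSON output file.
#' @return A list (also written as JSON when `path` is given) with keys
#'   `Ah`, `Ah_terms`, `Bh`, `Bh_terms`, `Al`, `Bl`, `Bl_terms`, `ua`,
#'   `Kbar_e`, `omega_bar_eta`, `omega_bar_m`, `required_Ah`, `gap`,
#'   `physical`, `groups` and (for the reference cell) `published`.
#' @export
coefficient_report <- function(scenario, path = NULL) {
  x <- resolve_scenario(scenario)
  gr <- as_groups(x)
  co <- hf_coefficients(x)
  lc <- if (gr$omega_bar_m > 0) lf_coefficients(x) else NULL
  eff <- effectiveness_gap(co)
  physical <- if (inherits(x, "ohc_parameters")) {
    list(q = x$motor$q, a = x$motor$a, N = x$motor$N,
         C0 = x$circuit$C0, sigma = x$circuit$sigma, i0 = x$circuit$i0,
         ko = x$mech$ko, Ke = x$mech$Ke, eta = x$mech$eta, fr = x$mech$fr,
         gx = x$bundle$gx)
  } else NULL
  out <- list(
    scenario = gr$label,
    Ah = co$Ah, Ah_terms = c(co$Ah_term1, co$Ah_term2),
    Bh = co$Bh_at(1), Bh_terms = c(co$Bh_term1, co$Bh_term2,
                                   co$Bh_term3_at(1)),
    Al = if (is.null(lc)) NULL else lc$Al,
    Bl = if (is.null(lc)) NULL else lc$Bl,
    Bl_terms = if (is.null(lc)) NULL else c(lc$Bl_term1, lc$Bl_term2),
    ua = gr$ua, Kbar_e = gr$Kbar_e,
    omega_bar_eta = gr$omega_bar_eta, omega_bar_m = gr$omega_bar_m,
    required_Ah = eff$required_Ah, gap = eff$gap,
    physical = physical,
    groups = unclass(gr)[c("ua", "Kbar_e", "alpha_c", "omega_bar_eta",
                           "omega_bar_m", "g", "chi", "a1")])
  if (!is.null(gr$label) && startsWith(gr$label, "guinea-pig-4khz"))
    out$published <- .published_reference
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  out
}

# ---- figure regeneration --------------------------------------------------

sweep_df <- function(responses, model_label = NULL) {
  df <- do.call(rbind, lapply(responses, function(r) {
    d <- as.data.frame(r)
    if (!is.null(model_label)) d$model <- model_label
    d
  }))
  df$gamma <- factor(df$gamma, levels = sort(unique(df$gamma)))
  df
}

save_panel <- function(plot, path, width = 5, height = 3.5) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
  path
}

#' Regenerate the reference figures
#'
#' Recomputes, from the model (never from stored data), the standard
#' diagnostic figures of the guinea-pig reference scenario:
#' * 3 — anti-damping factor and OHC stiffness versus activity `gamma`;
#' * 4 — high-frequency amplitude/phase (exact and high-frequency forms)
#'   and their difference;
#' * 5 — low-frequency amplitude/phase (exact and resistive-membrane
#'   forms);
#' * 6 — pure piezoelectric resonance, with and without the bundle
#'   mechanotransducer and with and without the strain-polarization
#'   stiffness.
#'
#' Each figure's underlying data are written as CSV next to the PNG
#' panels.
#'
#' @param which Subset of `c(3, 4, 5, 6)`.
#' @param outdir Output directory (created if needed).
#' @param scenario Scenario for the sweeps; default the figure-mode
#'   reference groups.
#' @return Invisibly, the vector of files written.
#' @export
make_figures <- function(which = c(3, 4, 5, 6), outdir = ".",
                         scenario = figure_mode_groups()) {
  stopifnot(all(which %in% c(3, 4, 5, 6)))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir))
      stop("cannot create output directory `", outdir, "`", call. = FALSE)
  }
  x <- resolve_scenario(scenario)
  gammas <- c(0, 0.5, 1)
  files <- character(0)
  if (3 %in% which) files <- c(files, .figure3(x, outdir))
  if (4 %in% which) files <- c(files, .figure4(x, gammas, outdir))
  if (5 %in% which) files <- c(files, .figure5(x, gammas, outdir))
  if (6 %in% which) files <- c(files, .figure6(x, gammas, outdir))
  invisible(files)
}

.gamma_colors <- c("0" = "#3366cc", "0.5" = "#9955bb", "1" = "#cc3333")

.figure3 <- function(x, outdir) {
  gr <- as_groups(x)
  gam <- seq(0, 1, length.out = 101)
  loaded <- hf_coefficients(gr)
  # unloaded variant: Kbar_e = 0 scales the feedback gain g (and a1) by
  # 1/(1 - Kbar_e) and removes the gating term of Bh
  unloaded <- gr
  unloaded$g <- gr$g / (1 - gr$Kbar_e)
  unloaded$a1 <- gr$a1 / (1 - gr$Kbar_e)
  unloaded$Kbar_e <- 0
  unloaded$alpha_c <- 1
  co0 <- hf_coefficients(unloaded)
  df <- rbind(
    data.frame(gamma = gam, quantity = "anti_damping", variant = "with load",
               value = gam * loaded$Ah),
    data.frame(gamma = gam, quantity = "anti_damping", variant = "no load",
               value = gam * co0$Ah),
    data.frame(gamma = gam, quantity = "stiffness", variant = "with load",
               value = 1 + gam * loaded$Bh),
    data.frame(gamma = gam, quantity = "stiffness", variant = "no load",
               value = 1 + gam * co0$Bh),
    data.frame(gamma = gam, quantity = "stiffness",
               variant = "voltage clamped",
               value = 1 / (1 + gam * gr$ua)))
  csv <- file.path(outdir, "fig3.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  pA <- ggplot2::ggplot(df[df$quantity == "anti_damping", ],
                        ggplot2::aes(gamma, value, linetype = variant)) +
    ggplot2::geom_line(color = "#cc3333") +
    ggplot2::labs(x = expression(gamma), y = expression(gamma * A[h]),
                  title = "Anti-damping factor") +
    ggplot2::theme_minimal()
  pB <- ggplot2::ggplot(df[df$quantity == "stiffness", ],
                        ggplot2::aes(gamma, value, linetype = variant)) +
    ggplot2::geom_line(color = "#333333") +
    ggplot2::labs(x = expression(gamma), y = "relative stiffness",
                  title = "OHC stiffness") +
    ggplot2::theme_minimal()
  c(csv,
    save_panel(pA, file.path(outdir, "fig3A.png")),
    save_panel(pB, file.path(outdir, "fig3B.png")))
}

.figure4 <- function(x, gammas, outdir) {
  grid <- frequency_grid(0.3, 3, 400)
  exact <- run_sweep(x, gammas, grid, model = "exact")
  hf1 <- suppressWarnings(run_sweep(x, gammas, grid, model = "hf"))
  hf0 <- suppressWarnings(run_sweep(x, gammas, grid, model = "hf",
                                    sigma_correction = FALSE))
  dfA <- sweep_df(exact)
  dfB <- rbind(sweep_df(hf1, "hf"), sweep_df(hf0, "hf_nosigma"))
  err <- do.call(rbind, lapply(seq_along(gammas), function(i) {
    data.frame(
      omega_bar = grid$omega_bar, gamma = gammas[i],
      rel_err_amp = (Mod(hf1[[i]]$p) - Mod(exact[[i]]$p)) / Mod(exact[[i]]$p),
      err_phase_rad = response_phase(hf1[[i]]) - response_phase(exact[[i]]))
  }))
  fa <- file.path(outdir, "fig4A.csv")
  fb <- file.path(outdir, "fig4B.csv")
  fc <- file.path(outdir, "fig4C.csv")
  utils::write.csv(dfA, fa, row.names = FALSE)
  utils::write.csv(dfB, fb, row.names = FALSE)
  utils::write.csv(err, fc, row.names = FALSE)
  err$gamma <- factor(err$gamma)
  amp_plot <- function(df, lt = NULL) {
    p <- ggplot2::ggplot(df, ggplot2::aes(omega_bar, amp_p, color = gamma)) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::scale_color_manual(values = .gamma_colors) +
      ggplot2::labs(x = expression(omega / omega[r]), y = "|p| / f") +
      ggplot2::theme_minimal()
    if (is.null(lt)) p + ggplot2::geom_line()
    else p + ggplot2::geom_line(ggplot2::aes(linetype = model))
  }
  phase_plot <- function(df, lt = NULL) {
    p <- ggplot2::ggplot(df, ggplot2::aes(omega_bar, phase_p_rad,
                                          color = gamma)) +
      ggplot2::scale_x_log10() +
      ggplot2::scale_color_manual(values = .gamma_colors) +
      ggplot2::labs(x = expression(omega / omega[r]), y = "phase (rad)") +
      ggplot2::theme_minimal()
    if (is.null(lt)) p + ggplot2::geom_line()
    else p + ggplot2::geom_line(ggplot2::aes(linetype = model))
  }
  c(fa, fb, fc,
    save_panel(amp_plot(dfA), file.path(outdir, "fig4A1.png")),
    save_panel(phase_plot(dfA), file.path(outdir, "fig4A2.png")),
    save_panel(amp_plot(dfB, lt = TRUE), file.path(outdir, "fig4B1.png")),
    save_panel(phase_plot(dfB, lt = TRUE), file.path(outdir, "fig4B2.png")),
    save_panel(
      ggplot2::ggplot(err, ggplot2::aes(omega_bar, rel_err_amp,
                                        color = gamma)) +
        ggplot2::geom_line() + ggplot2::scale_x_log10() +
        ggplot2::scale_color_manual(values = .gamma_colors) +
        ggplot2::labs(x = expression(omega / omega[r]),
                      y = "relative amplitude difference") +
        ggplot2::theme_minimal(),
      file.path(outdir, "fig4C1.png")),
    save_panel(
      ggplot2::ggplot(err, ggplot2::aes(omega_bar, err_phase_rad,
                                        color = gamma)) +
        ggplot2::geom_line() + ggplot2::scale_x_log10() +
        ggplot2::scale_color_manual(values = .gamma_colors) +
        ggplot2::labs(x = expression(omega / omega[r]),
                      y = "phase difference (rad)") +
        ggplot2::theme_minimal(),
      file.path(outdir, "fig4C2.png")))
}

.figure5 <- function(x, gammas, outdir) {
  grid <- frequency_grid(1e-3, 1e-1, 400)
  exact <- run_sweep(x, gammas, grid, model = "exact")
  lf <- suppressWarnings(run_sweep(x, gammas, grid, model = "lf"))
  df <- rbind(sweep_df(exact), sweep_df(lf))
  csv <- file.path(outdir, "fig5.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  pA <- ggplot2::ggplot(df, ggplot2::aes(omega_bar, amp_p, color = gamma,
                                         linetype = model)) +
    ggplot2::geom_line() + ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_color_manual(values = .gamma_colors) +
    ggplot2::labs(x = expression(omega / omega[r]), y = "|p| / f") +
    ggplot2::theme_minimal()
  pB <- ggplot2::ggplot(df, ggplot2::aes(omega_bar, phase_p_rad,
                                         color = gamma, linetype = model)) +
    ggplot2::geom_line() + ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = .gamma_colors) +
    ggplot2::labs(x = expression(omega / omega[r]), y = "phase (rad)") +
    ggplot2::theme_minimal()
  c(csv,
    save_panel(pA, file.path(outdir, "fig5A.png")),
    save_panel(pB, file.path(outdir, "fig5B.png")))
}

.figure6 <- function(x, gammas, outdir) {
  grid <- frequency_grid(0.3, 3, 400)
  piezo <- run_sweep(x, gammas, grid, model = "piezo")
  exact <- run_sweep(x, gammas, grid, model = "exact")
  dfA <- rbind(sweep_df(piezo), sweep_df(exact))
  # strain-stiffness toggle, pure piezo, in the high-frequency form
  gr0 <- as_groups(x)
  gr0$g <- 0; gr0$a1 <- 0
  with_ss <- suppressWarnings(run_sweep(gr0, gammas, grid, model = "hf"))
  no_ss <- suppressWarnings(run_sweep(gr0, gammas, grid, model = "hf",
                                      strain_stiffness = FALSE))
  dfB <- rbind(sweep_df(with_ss, "piezo_hf"),
               sweep_df(no_ss, "piezo_hf_no_strain_stiffness"))
  fa <- file.path(outdir, "fig6A.csv")
  fb <- file.path(outdir, "fig6B.csv")
  utils::write.csv(dfA, fa, row.names = FALSE)
  utils::write.csv(dfB, fb, row.names = FALSE)
  plot_amp <- function(df) {
    ggplot2::ggplot(df, ggplot2::aes(omega_bar, amp_p, color = gamma,
                                     linetype = model)) +
      ggplot2::geom_line() + ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::scale_color_manual(values = .gamma_colors) +
      ggplot2::labs(x = expression(omega / omega[r]), y = "|p| / f") +
      ggplot2::theme_minimal()
  }
  c(fa, fb,
    save_panel(plot_amp(dfA), file.path(outdir, "fig6A.png")),
    save_panel(plot_amp(dfB), file.path(outdir, "fig6B.png")))
}
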