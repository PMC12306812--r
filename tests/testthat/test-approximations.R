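test_that("high-frequency coefficients decompose as documented", {
  co <- hf_coefficients(ref_params())
  expect_equal(signif(co$Bh_term2, 3), 0.989)
  expect_equal(signif(co$Ah_term2, 2), 0.013)
  expect_equal(co$Ah, co$Ah_term1 - co$Ah_term2)
  expect_equal(co$Bh_at(1), co$Bh_term1 + co$Bh_term2 + co$Bh_term3_at(1))
  expect_lt(co$Bh_term1, 0)
  expect_gt(co$Bh_term2, 0)
  # amplifying signs on the reference cell
  expect_gt(co$Ah, 0)
  expect_gt(co$Bh, 0)
  # no bundle feedback: only the conductance drag term remains
  p0 <- ref_params()
  p0$bundle$gx <- 0
  co0 <- hf_coefficients(p0)
  expect_equal(co0$Ah_term1, 0)
  expect_lt(co0$Ah, 0)
  # nullifying the conductance drops both sigma terms
  cons <- hf_coefficients(ref_params(), include_sigma_correction = FALSE)
  expect_equal(cons$Ah_term2, 0)
  expect_equal(cons$Bh_term3_at(c(0.5, 1)), c(0, 0))
  expect_error(co$Bh_term3_at(0), "nonzero")
})

test_that("strain-stiffness toggle zeroes only the polarization term", {
  co <- hf_coefficients(ref_params())
  expect_identical(strain_stiffness_toggle(co, enabled = TRUE), co)
  off <- strain_stiffness_toggle(co, enabled = FALSE)
  expect_equal(off$Bh, co$Bh_term1)
  expect_lt(off$Bh, 0)
  expect_equal(off$Ah, co$Ah)
  expect_equal(off$Bh_at(1), co$Bh_term1 + co$Bh_term3_at(1))
})

test_that("high-frequency response matches its squared-amplitude identity", {
  fm <- fig_groups()
  co <- hf_coefficients(fm)
  grid <- hf_grid()
  wb <- grid$omega_bar
  for (g in c(0.5, 1)) {
    r <- hf_response(co, g, grid)
    rhs <- (1 + fm$alpha_c * g * fm$ua)^2 /
      ((1 + g * co$Bh_at(wb) - wb^2)^2 +
         (wb / fm$omega_bar_eta - g * co$Ah / wb)^2)
    expect_equal(Mod(r$p)^2, rhs, tolerance = 1e-12)
  }
  # gamma = 0: the expansion is inert and the solvers agree exactly
  expect_identical(hf_response(co, 0, grid)$p, exact_response(fm, 0, grid)$p)
  expect_warning(hf_response(co, 1, frequency_grid(0.1, 3, 20)),
                 "validity region")
})

test_that("expansion error shrinks with the expansion parameter sigma/(w C0)", {
  grid <- frequency_grid(1, 3, 100)
  err_for <- function(sigma_scale) {
    p <- ref_params()
    p$circuit$sigma <- p$circuit$sigma * sigma_scale
    ex <- exact_response(p, 1, grid)
    hf <- hf_response(hf_coefficients(p), 1, grid)
    max(rel_err(Mod(hf$p), Mod(ex$p)))
  }
  errs <- sapply(c(1, 0.3, 0.1, 0.03), err_for)
  expect_true(all(diff(errs) < 0))
})

test_that("low-frequency coefficients carry the documented signs and limits", {
  lc <- lf_coefficients(ref_params())
  expect_gt(lc$Al, 0)
  expect_gt(lc$Bl_term2, 0)
  expect_equal(lc$Bl_term1, -derive_groups(ref_params())$ua * 20 / 37)
  expect_equal(lc$Bl_term1, -0.0747, tolerance = 1e-2)
  # sigma -> infinity: electrical terms vanish, Bl -> -ua Kbar_e
  pbig <- ref_params()
  pbig$circuit$sigma <- 1e6
  lcb <- lf_coefficients(pbig)
  expect_lt(lcb$Al, 1e-10)
  expect_equal(lcb$Bl, lcb$Bl_term1, tolerance = 1e-8)
  p0 <- ref_params()
  p0$circuit$sigma <- 0
  expect_error(lf_coefficients(p0), "sigma > 0")
})

test_that("low-frequency form equals the exact response with C0 nullified", {
  p0 <- ref_params()
  p0$circuit$C0 <- 0
  grid <- frequency_grid(1e-3, 1e-1, 200)
  lc <- lf_coefficients(ref_params())
  for (g in c(0, 0.5, 1)) {
    ex <- exact_response(p0, g, grid)
    lf <- suppressWarnings(lf_response(lc, g, grid))
    expect_equal(lf$p, ex$p, tolerance = 1e-13)
  }
})

test_that("low-frequency amplitude decreases with activity and has the right DC limit", {
  lc <- lf_coefficients(ref_params())
  fm <- fig_groups()
  grid <- frequency_grid(1e-3, 1e-2, 50)
  amps <- sapply(c(0, 0.5, 1), function(g)
    Mod(suppressWarnings(lf_response(lc, g, grid, groups = fm))$p))
  expect_true(all(amps[, 2] < amps[, 1]))
  expect_true(all(amps[, 3] < amps[, 2]))
  # DC limit |p| -> (1 + alpha_c ua) / (1 + Bl)
  r <- suppressWarnings(lf_response(lc, 1, c(1e-6, 2e-6), groups = fm))
  expect_equal(Mod(r$p[1]), (1 + fm$alpha_c * fm$ua) / (1 + lc$Bl),
               tolerance = 1e-5)
})

test_that("gating compliance softens the unloaded cell with activity", {
  p <- ref_params()
  expect_equal(gating_compliance(p, 0), 1 / 17e-3)
  ua0 <- derive_groups(p)$ua # Ke does not enter ua
  expect_equal(gating_compliance(p, 1), (1 + ua0) / 17e-3)
  cs <- sapply(seq(0, 1, 0.25), function(g) gating_compliance(p, g))
  expect_true(all(diff(cs) > 0))
})

test_that("effectiveness gap tracks drag, stiffness and external load", {
  fm <- fig_groups()
  eff <- effectiveness_gap(hf_coefficients(fm))
  expect_equal(eff$required_Ah, (1 + eff$Bh) / fm$omega_bar_eta)
  expect_equal(eff$gap, eff$Ah - eff$required_Ah)
  expect_equal(eff$omega_bar_star, sqrt(1 + eff$Bh))
  # the reference cell cannot fully null its drag at resonance
  expect_lt(eff$gap, 0)
  # no drag to cancel when the roll-off frequency is huge
  big <- fm; big$omega_bar_eta <- 1e12
  expect_lt(effectiveness_gap(hf_coefficients(big))$required_Ah, 1e-10)
  # stiffer external load reduces the feedback term and the gap
  gaps <- sapply(c(20e-3, 60e-3, 200e-3), function(Ke) {
    p <- ref_params(); p$mech$Ke <- Ke
    co <- hf_coefficients(derive_groups(p, omega_bar_eta_override = 10))
    c(co$Ah_term1, effectiveness_gap(co)$gap)
  })
  expect_true(all(diff(gaps[1, ]) < 0))
  expect_true(all(diff(gaps[2, ]) < 0))
})
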