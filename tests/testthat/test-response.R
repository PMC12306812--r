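test_that("passive limit reduces to the damped-oscillator closed form", {
  fm <- fig_groups()
  grid <- hf_grid()
  r <- exact_response(fm, 0, grid)
  expect_equal(Mod(r$p),
               passive_amplitude(grid$omega_bar, fm$omega_bar_eta),
               tolerance = 1e-13)
  # at resonance with omega_bar_eta = 10: p = -10i
  r1 <- exact_response(fm, 0, c(0.5, 1, 2))
  expect_equal(r1$p[2], -10i, tolerance = 1e-12)
  # DC limit: static compliance of the combined springs, p -> fbar
  rdc <- exact_response(fm, 0, c(1e-5, 2e-5))
  expect_equal(Mod(rdc$p[1]), 1, tolerance = 1e-6)
})

test_that("response is exactly linear in the drive", {
  fm <- fig_groups()
  grid <- hf_grid(50)
  r1 <- exact_response(fm, 1, grid, fbar = 1)
  r3 <- exact_response(fm, 1, grid, fbar = 3.5)
  expect_equal(r3$p, 3.5 * r1$p)
})

test_that("displacement and voltage channels are consistent in physical mode", {
  p <- ref_params()
  gr <- derive_groups(p)
  r <- exact_response(p, 1, hf_grid(50))
  expect_equal(r$x, p$motor$a * p$motor$N * (1 - gr$Kbar_e) * r$p)
  expect_equal(voltage_response(r), r$v)
  # voltage is finite with a sane phase offset at resonance
  rr <- exact_response(p, 1, c(0.99, 1, 1.01))
  expect_true(all(is.finite(Mod(rr$v))))
  dphi <- Arg(rr$v[2]) - Arg(rr$p[2])
  expect_true(dphi > -pi && dphi <= pi)
  # no sources: g = 0 and vanishing motile charge give v ~ 0
  p0 <- ref_params()
  p0$bundle$gx <- 0
  p0$motor$q <- -1e-30
  p0$motor$N <- 1
  r0 <- exact_response(p0, 0, hf_grid(20))
  expect_lt(max(Mod(r0$v)), 1e-15)
  # groups mode carries no physical channels
  rg <- exact_response(fig_groups(), 1, hf_grid(20))
  expect_true(all(is.na(rg$x)))
})

test_that("passive voltage rolls off as a single pole above the middle frequency", {
  p <- ref_params()
  gr <- derive_groups(p)
  grid <- frequency_grid(0.3, 3, 60)
  r <- exact_response(p, 0, grid)
  w <- grid$omega_bar * p$mech$omega_r
  pred <- Mod(-(p$circuit$i0 * gr$g + 1i * w * p$motor$N * p$motor$q) /
                (p$circuit$sigma + 1i * w * p$circuit$C0)) * Mod(r$p)
  expect_equal(Mod(r$v), pred, tolerance = 1e-12)
})

test_that("amplification grows with activity in figure mode", {
  fm <- fig_groups()
  grid <- hf_grid()
  peaks <- lapply(c(0, 0.5, 1),
                  function(g) peak_metrics(exact_response(fm, g, grid)))
  amps <- sapply(peaks, `[[`, "peak_amplitude")
  freqs <- sapply(peaks, `[[`, "peak_omega_bar")
  expect_true(all(diff(amps) > 0))
  expect_true(all(diff(freqs) > 0))
  # phase drops by about pi across the gamma = 1 peak
  expect_equal(peaks[[3]]$phase_drop, 3.0, tolerance = 0.1)
  expect_false(any(sapply(peaks, `[[`, "at_boundary")))
})

test_that("pure piezoelectric resonance does not amplify", {
  fm <- fig_groups()
  grid <- hf_grid()
  # gamma = 0: feedback is inert, responses identical
  expect_equal(pure_piezo_response(fm, 0, grid)$p,
               exact_response(fm, 0, grid)$p)
  # peak height strictly decreases with gamma without the transducer
  pk <- sapply(c(0, 0.5, 1),
               function(g) max(Mod(pure_piezo_response(fm, g, grid)$p)))
  expect_true(all(diff(pk) < 0))
  # physical-mode piezo removes the bundle too
  pp <- pure_piezo_response(ref_params(), 1, hf_grid(20))
  expect_true(all(Mod(pp$v) > 0)) # piezoelectric charge still polarizes
})

test_that("connectivity distinction vanishes linearly with ua", {
  grid <- hf_grid(100)
  sup_diff <- function(ua) {
    gs <- dimensionless_groups(ua = ua, Kbar_e = 20 / 37, omega_bar_eta = 10,
                               omega_bar_m = 0.0133, g = -36.9, chi = 0.989,
                               a1 = 0.1136, connectivity = "series")
    gp <- gs; gp$connectivity <- "parallel"; gp$alpha_c <- 1 - gp$Kbar_e
    max(Mod(exact_response(gs, 1, grid)$p - exact_response(gp, 1, grid)$p))
  }
  d <- sapply(c(1e-1, 1e-2, 1e-3), sup_diff)
  expect_true(all(diff(d) < 0))
  # ratio between decades approaches 10 as the drive factor linearizes
  expect_gt(d[1] / d[2], 8)
  expect_lt(d[1] / d[2], 13)
  expect_equal(d[2] / d[3], 10, tolerance = 0.05)
})

test_that("frequency grids validate and responses serialize to CSV", {
  expect_error(frequency_grid(0, 3), "from > 0")
  expect_error(exact_response(fig_groups(), 0, c(2, 1)))
  r <- exact_response(ref_params(), 0.5, hf_grid(10))
  f <- tempfile(fileext = ".csv")
  df <- write_response_csv(r, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 10)
  expect_named(back, c("omega_bar", "gamma", "model", "amp_p", "phase_p_rad",
                       "amp_x_m", "phase_x_rad", "amp_v_V", "phase_v_rad"))
  expect_equal(back$amp_p, Mod(r$p), tolerance = 1e-12)
})
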