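test_that("quadrature fit recovers a pure sinusoid exactly", {
  s <- fake_series(amplitude = 2.5, phase = 0.7, omega_bar = 1.3)
  ss <- steady_state_amp_phase(s)
  expect_equal(ss$amplitude, 2.5, tolerance = 1e-12)
  expect_equal(ss$phase, 0.7, tolerance = 1e-12)
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-12)
})

test_that("passive integration matches the damped-oscillator closed form", {
  fm <- fig_groups()
  for (wb in c(0.5, 1, 1.7)) {
    ss <- steady_state_amp_phase(integrate_forced(fm, 0, wb))
    expect_equal(ss$amplitude, passive_amplitude(wb, fm$omega_bar_eta),
                 tolerance = 1e-6)
    expect_equal(ss$phase, Arg(1 / (1 - wb^2 + 1i * wb / fm$omega_bar_eta)),
                 tolerance = 1e-6)
  }
  # resonance: amplitude omega_bar_eta, quarter-cycle lag
  ss <- steady_state_amp_phase(integrate_forced(fm, 0, 1))
  expect_equal(ss$amplitude, 10, tolerance = 1e-6)
  expect_equal(ss$phase, -pi / 2, tolerance = 1e-6)
})

test_that("zero drive gives identically zero trajectories and the response scales linearly", {
  fm <- fig_groups()
  s0 <- integrate_forced(fm, 1, 1.2, fbar = 0)
  expect_true(all(s0$p == 0) && all(s0$w == 0))
  a1 <- steady_state_amp_phase(integrate_forced(fm, 1, 1.2, fbar = 1))
  a2 <- steady_state_amp_phase(integrate_forced(fm, 1, 1.2, fbar = 2.5))
  expect_equal(a2$amplitude / a1$amplitude, 2.5, tolerance = 1e-9)
  expect_equal(a2$phase, a1$phase, tolerance = 1e-9)
})

test_that("integration is converged in step size and start-condition independent", {
  fm <- fig_groups()
  a1 <- steady_state_amp_phase(integrate_forced(fm, 1, 1.2,
                                                steps_per_cycle = 512))
  a2 <- steady_state_amp_phase(integrate_forced(fm, 1, 1.2,
                                                steps_per_cycle = 1024))
  expect_lt(rel_err(a2$amplitude, a1$amplitude), 1e-8)
  # start from the analytic steady state instead of rest
  ev <- exact_response(fm, 1, c(1.2))
  p <- ev$p[1]
  wss <- -(fm$a1 + 1i * 1.2 * fm$chi) * p / (fm$omega_bar_m + 1i * 1.2)
  s2 <- steady_state_amp_phase(integrate_forced(
    fm, 1, 1.2, y0 = c(Re(p), Re(1i * 1.2 * p), Re(wss))))
  s1 <- steady_state_amp_phase(integrate_forced(fm, 1, 1.2))
  expect_lt(rel_err(s2$amplitude, s1$amplitude), 1e-6)
  expect_lt(abs(s2$phase - s1$phase), 1e-6)
})

test_that("input power balances viscous dissipation in the passive steady state", {
  fm <- fig_groups()
  ser <- integrate_forced(fm, 0, 0.9, keep_cycles = 10)
  n <- length(ser$tau)
  idx <- (n - 10 * ser$steps_per_cycle):n
  power_in <- mean(ser$famp * cos(0.9 * ser$tau[idx]) * ser$dp[idx])
  dissipated <- mean(ser$dp[idx]^2) / fm$omega_bar_eta
  expect_lt(rel_err(power_in, dissipated), 1e-3)
})

test_that("the integrator agrees with an established ODE solver on a short run", {
  fm <- fig_groups()
  wb <- 1.1
  spc <- 128L
  # a deliberately short run (transient not decayed): the comparison is
  # trajectory-by-trajectory, not of steady states
  ser <- suppressWarnings(
    integrate_forced(fm, 1, wb, n_cycles = 30L, steps_per_cycle = spc,
                     keep_cycles = 1L))
  M <- closed_loop_matrix(fm, 1)
  famp <- (1 + fm$alpha_c * fm$ua)
  rhs <- function(t, y, parms) {
    dy <- as.numeric(M %*% y)
    dy[2] <- dy[2] + famp * cos(wb * t)
    list(dy)
  }
  times <- seq(0, 30 * 2 * pi / wb, by = 2 * pi / (wb * spc))
  sol <- deSolve::ode(c(0, 0, 0), times, rhs, NULL, method = "rk4")
  tail_idx <- (nrow(sol) - spc):nrow(sol)
  expect_equal(ser$p, unname(sol[tail_idx, 2]), tolerance = 1e-10)
  expect_equal(ser$w, unname(sol[tail_idx, 4]), tolerance = 1e-10)
})

test_that("unstable closed loops are refused with a clear error", {
  hot <- fig_groups()
  hot$a1 <- 10 # anti-damping far beyond the drag
  expect_false(closed_loop_stable(hot, 1))
  expect_error(integrate_forced(hot, 1, 1), "not stable")
})

test_that("frequency- and time-domain solutions agree across regimes", {
  fm <- fig_groups()
  cmp0 <- compare_to_frequency_domain(fm, 0, c(0.7, 1, 1.6))
  expect_lt(attr(cmp0, "max_rel_err_amp"), 1e-6)
  expect_lt(attr(cmp0, "max_abs_err_phase"), 1e-6)
  cmp1 <- compare_to_frequency_domain(fm, 1, c(0.7, 1.2, 2.2))
  expect_true(all(cmp1$converged))
  expect_lt(attr(cmp1, "max_rel_err_amp"), 1e-4)
  expect_lt(attr(cmp1, "max_abs_err_phase"), 1e-4)
  expect_named(cmp1, c("omega_bar", "amp_fd", "amp_td", "rel_err_amp",
                       "phase_fd", "phase_td", "abs_err_phase_rad",
                       "converged"))
  # deep resistive regime: the lf form also matches the oracle
  p2 <- ref_params()
  p2$circuit$sigma <- p2$circuit$sigma * 100
  g2 <- derive_groups(p2)
  wb <- g2$omega_bar_m / 10
  ss <- steady_state_amp_phase(integrate_forced(p2, 1, wb))
  lr <- suppressWarnings(lf_response(lf_coefficients(p2), 1, c(wb)))
  expect_lt(rel_err(ss$amplitude, Mod(lr$p[1])), 0.01)
})
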