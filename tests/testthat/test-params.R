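test_that("stiffness follows from elastic modulus and exposed length", {
  expect_equal(stiffness_from_modulus(510e-9, 30e-6), 17e-3)
  expect_equal(stiffness_from_modulus(510e-9, 40e-6), 12.75e-3)
  expect_equal(stiffness_from_modulus(0, 30e-6), 0)
  expect_error(stiffness_from_modulus(510e-9, 0), "positive")
})

test_that("steady-state current modes reproduce the reference currents", {
  circ <- list(V0 = -50e-3, eK = -80e-3, Rm = 100e6)
  expect_equal(steady_state_current(circ), 0.3e-9)
  circ$V0 <- -40e-3
  expect_equal(steady_state_current(circ), 0.4e-9)
  circ$V0 <- circ$eK
  expect_equal(steady_state_current(circ), 0)
  # divider mode uses the endocochlear potential across both resistances
  div <- list(eep = 90e-3, eK = -80e-3, R0 = 100e6, Rm = 70e6)
  expect_equal(steady_state_current(div, mode = "divider"), 1e-9)
  expect_error(steady_state_current(list(eK = -80e-3), mode = "resting"),
               "needs V0")
})

test_that("motor count from peak excess capacitance round-trips", {
  e <- physical_constants()$e_charge
  kBT <- physical_constants()$kBT
  N <- motor_count_from_capacitance(30e-12, 0.8 * e, kBT, signif_digits = 1)
  expect_equal(N, 3e7)
  # doubling the capacitance doubles the count
  expect_equal(motor_count_from_capacitance(60e-12, 0.8 * e, kBT),
               2 * motor_count_from_capacitance(30e-12, 0.8 * e, kBT))
  # round trip: recomputing beta q^2 N / 4 recovers the input capacitance
  Nfull <- motor_count_from_capacitance(30e-12, 0.8 * e, kBT)
  expect_equal((1 / kBT) * (0.8 * e)^2 * Nfull / 4, 30e-12)
  expect_error(motor_count_from_capacitance(30e-12, 0), "nonzero")
  # unit displacement from the 5% load-free amplitude of a 40 um cell
  expect_equal(signif(unit_displacement_from_amplitude(2e-6, 3e7), 2),
               0.67e-13)
})

test_that("subtectorial-gap drag matches the shear estimate", {
  expect_equal(drag_from_subtectorial_geometry(10e-6 * 20e-6, 2e-6, 0.8e-3),
               0.8e-7)
  expect_equal(drag_from_subtectorial_geometry(10e-6 * 20e-6, 2e-6, 0.4e-3),
               0.4e-7)
  expect_equal(drag_from_subtectorial_geometry(0, 2e-6), 0)
  expect_error(drag_from_subtectorial_geometry(1e-10, 0), "positive")
})

test_that("constructors enforce sign conventions and operating point", {
  expect_error(motor_element(q = 1e-19, a = 1e-13, N = 1e7), "q < 0")
  expect_error(motor_element(q = -1e-19, a = -1e-13, N = 1e7), "a > 0")
  expect_error(motor_element(q = -1e-19, a = 1e-13, N = 1e7,
                             P0 = 0.5, gamma = 1), "not both")
  m <- motor_element(q = -1e-19, a = 1e-13, N = 1e7, P0 = 0.25)
  expect_equal(m$gamma, 4 * 0.25 * 0.75)
  expect_equal(motor_element(q = -1e-19, a = 1e-13, N = 1e7)$gamma, 1)
  circ <- membrane_circuit(C0 = 30e-12, Rm = 100e6, R0 = 100e6,
                           V0 = -50e-3, eK = -80e-3)
  expect_equal(circ$sigma, 2e-8)
  expect_equal(circ$i0, 0.3e-9)
})

test_that("derived groups match the reference cell and behave monotonically", {
  gr <- derive_groups(ref_params())
  expect_equal(signif(gr$ua, 2), 0.14)
  expect_equal(signif(gr$omega_bar_m, 2), 0.013)
  expect_equal(gr$Kbar_e, 20 / 37)
  expect_lt(gr$a1, abs(gr$g)) # sanity on magnitudes

  # no external spring: Kbar_e = 0 and alpha_c = 1 for both connectivities
  for (conn in c("series", "parallel")) {
    p0 <- ref_params(connectivity = conn)
    p0$mech$Ke <- 0
    g0 <- derive_groups(p0)
    expect_equal(g0$Kbar_e, 0)
    expect_equal(g0$alpha_c, 1)
  }

  # scaling both stiffnesses by c scales ua by c, keeps Kbar_e
  p2 <- ref_params()
  p2$mech$ko <- p2$mech$ko * 3
  p2$mech$Ke <- p2$mech$Ke * 3
  g2 <- derive_groups(p2)
  expect_equal(g2$ua, 3 * gr$ua)
  expect_equal(g2$Kbar_e, gr$Kbar_e)

  # ua -> 0 as a -> 0; Kbar_e -> 1 monotonically as Ke grows
  uas <- sapply(c(1, 1e-2, 1e-4), function(s) {
    p <- ref_params(); p$motor$a <- p$motor$a * s; derive_groups(p)$ua
  })
  expect_true(all(diff(uas) < 0))
  expect_lt(uas[3], 1e-8 * uas[1])
  kes <- sapply(c(1, 10, 1000), function(s) {
    p <- ref_params(); p$mech$Ke <- p$mech$Ke * s; derive_groups(p)$Kbar_e
  })
  expect_true(all(diff(kes) > 0))
  expect_gt(kes[3], 0.99)

  p3 <- ref_params(); p3$circuit$C0 <- 0
  expect_error(derive_groups(p3), "C0")
})

test_that("reference fixture is deterministic and carries the quoted values", {
  p1 <- ref_params()
  p2 <- ref_params()
  expect_identical(p1, p2)
  expect_equal(p1$circuit$i0, 0.3e-9)
  expect_equal(p1$mech$ko, 17e-3)
  expect_equal(p1$motor$q, -0.8 * 1.6e-19)
  expect_equal(p1$mech$m, (17e-3 + 20e-3) / (2 * pi * 4000)^2)
  expect_false(guinea_pig_4khz(amplifying = FALSE)$bundle$gx < 0)
})
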