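test_that("the calibrated reference configuration sits at the euthyroid setpoint", {
  p <- feedback_parameters()
  eq <- solve_equilibrium(p)
  expect_true(eq$converged)
  expect_equal(eq$tsh, 1.5, tolerance = 1e-6)
  expect_equal(eq$ft4, 15, tolerance = 1e-6)
  expect_lt(eq$residual, 1e-6)
  # the reference thyroid capacity is the GT estimate at the setpoint
  expect_equal(p$g_t, spina_gt(1.5, 15), tolerance = 1e-12)
  # central T3 anchored to peripheral FT3 at reference
  expect_equal(eq$ft3_central, eq$ft3, tolerance = 1e-6)
})

test_that("thyroid transfer is half-maximal at the TSH EC50 and inverts GT", {
  p <- feedback_parameters()
  expect_identical(thyroid_response(0, p), 0)
  half <- thyroid_response(p$constants$D_T, p)
  asym <- thyroid_response(1e9, p)
  expect_equal(half / asym, 0.5, tolerance = 1e-8)
  # agreement with the independent arithmetic oracle
  expect_equal(thyroid_response(2.2, p), oracle_thyroid_ft4(2.2, p$g_t))
  expect_equal(spina_gt(2.2, thyroid_response(2.2, p)), p$g_t,
               tolerance = 1e-12)
})

test_that("peripheral transfer is near-linear in FT4 and inverts GD", {
  p <- feedback_parameters()
  expect_identical(peripheral_ft3(0, p), 0)
  expect_equal(peripheral_ft3(15, p), oracle_peripheral_ft3(15, p$g_d))
  expect_equal(spina_gd(22, peripheral_ft3(22, p)), p$g_d, tolerance = 1e-12)
  # K_M1 is five orders of magnitude above serum FT4, so the transfer is
  # nearly linear: the exact secant-slope ratio between the [5,6] and
  # [39,40] pmol/L windows is ((K_M1 + 5.5e-12)/(K_M1 + 39.5e-12))^2 - 1
  # = -1.36e-4, i.e. a 0.014% slope change across the physiological range
  s_lo <- (peripheral_ft3(6, p) - peripheral_ft3(5, p)) / 1
  s_hi <- (peripheral_ft3(40, p) - peripheral_ft3(39, p)) / 1
  expect_lt(abs(s_hi / s_lo - 1), 2e-4)
})

test_that("pituitary transfer shows divisive inhibition by central T3", {
  p <- feedback_parameters()
  # maximal TSH at zero FT4
  expect_equal(pituitary_response(0, p),
               p$g_h * p$trh_drive / (p$d_h + p$trh_drive))
  # strictly decreasing in FT4
  ft4s <- seq(1, 50, by = 1)
  expect_true(all(diff(pituitary_response(ft4s, p)) < 0))
  # central hyperdeiodination (doubling g_d2) suppresses TSH at fixed FT4
  p2 <- feedback_parameters(g_d2 = 2)
  expect_lt(pituitary_response(15, p2), pituitary_response(15, p))
})

test_that("equilibrium comparative statics follow primary and central dysfunction", {
  ref <- solve_equilibrium(feedback_parameters())
  # falling thyroid capacity: FT4 sinks, TSH rises (primary hypothyroidism)
  gts <- feedback_parameters()$g_t * c(1, 0.7, 0.45, 0.25)
  eqs <- lapply(gts, function(g) solve_equilibrium(feedback_parameters(g_t = g)))
  ft4s <- vapply(eqs, `[[`, 1, "ft4")
  tshs <- vapply(eqs, `[[`, 1, "tsh")
  expect_true(all(diff(ft4s) < 0))
  expect_true(all(diff(tshs) > 0))
  # falling pituitary capacity: FT4 decreased while TSH remains within or
  # below its reference band (partial thyrotropic insufficiency)
  eq_q <- solve_equilibrium(feedback_parameters(g_h = 39 * 0.25))
  expect_lt(eq_q$ft4, 10)
  expect_lt(eq_q$tsh, 4)
  expect_gt(eq_q$tsh, 0.4)
  # rising pituitary capacity raises both coordinates
  eq_h <- solve_equilibrium(feedback_parameters(g_h = 39 * 4))
  expect_gt(eq_h$tsh, ref$tsh)
  expect_gt(eq_h$ft4, ref$ft4)
})

test_that("Michaelis-Menten saturation caps FT4 regardless of TSH drive", {
  p <- feedback_parameters()
  k <- p$constants
  cap <- k$alpha_T * p$g_t /
    (k$beta_T * (1 + k$K41 * p$tbg + k$K42 * p$tbpa))
  ref <- solve_equilibrium(p)
  for (mult in c(1, 10, 100, 1000)) {
    eq <- solve_equilibrium(feedback_parameters(g_h = p$g_h * mult))
    expect_lte(eq$ft4, cap)
  }
  # grossly excessive central drive: TSH rises ~40-fold, FT4 stays under
  # its 2.83-fold saturation ceiling (the "excessively high TSH, mildly
  # elevated hormones" pattern of central hyperthyroidism)
  eq100 <- solve_equilibrium(feedback_parameters(g_h = p$g_h * 100))
  expect_gt(eq100$tsh / ref$tsh, 10)
  expect_lt(eq100$ft4 / ref$ft4, cap / 15 + 1e-9)
  expect_gt(eq100$tsh / ref$tsh, 10 * eq100$ft4 / ref$ft4)
})

test_that("constant schedules hold the equilibrium; dynamics converge from afar", {
  p <- feedback_parameters()
  sim <- simulate_dynamics(p, duration_days = 2, dt = 300)
  expect_lt(max(abs(sim$tsh - sim$tsh[1])), 1e-8)
  expect_lt(max(abs(sim$ft4 - sim$ft4[1])), 1e-8)
  # from a displaced positive state the trajectory relaxes to the unique
  # fixed point
  eq <- solve_equilibrium(p)
  sim2 <- simulate_dynamics(p, duration_days = 120, dt = 600,
                            init = c(tsh = 8, ft4 = 35, ft3 = 9))
  n <- nrow(sim2)
  expect_equal(sim2$tsh[n], eq$tsh, tolerance = 1e-5)
  expect_equal(sim2$ft4[n], eq$ft4, tolerance = 1e-5)
  expect_true(all(sim2$tsh >= 0 & sim2$ft4 >= 0 & sim2$ft3 >= 0))
})

test_that("time constants shape the transient but not the steady state", {
  p_fast <- feedback_parameters(tau_t4 = 7 * 86400 / log(2) / 2,
                                tau_t3 = 86400 / log(2) / 2,
                                tau_tsh = 50 * 60 / log(2) / 2)
  init <- c(tsh = 4, ft4 = 10, ft3 = 3)
  slow <- simulate_dynamics(feedback_parameters(), duration_days = 150,
                            dt = 600, init = init)
  fast <- simulate_dynamics(p_fast, duration_days = 150, dt = 600,
                            init = init)
  expect_equal(tail(slow$tsh, 1), tail(fast$tsh, 1), tolerance = 1e-5)
  expect_equal(tail(slow$ft4, 1), tail(fast$ft4, 1), tolerance = 1e-5)
  # but the fast system closes most of its initial gap sooner
  gap <- function(s) abs(s$tsh - tail(s$tsh, 1))
  i10 <- which.min(abs(slow$time_days - 10))
  expect_lt(gap(fast)[i10], gap(slow)[i10])
})

test_that("central hyperdeiodination reproduces thyrotropic adaptation and rebound", {
  sim <- simulate_dynamics(feedback_parameters(),
                           scenario_thyrotropic_adaptation(),
                           duration_days = 30, dt = 120)
  base <- sim$tsh[1]
  ramp <- sim$time_days >= 5 & sim$time_days <= 14
  rec <- sim$time_days >= 17 & sim$time_days <= 25
  expect_lt(min(sim$tsh[ramp]), 0.8 * base)       # suppressed TSH
  expect_lt(min(sim$ft4[ramp]), 0.9 * sim$ft4[1]) # drifting-down FT4
  expect_gt(max(sim$tsh[rec]), 1.05 * base)       # post-recovery overshoot
  # and the overshoot decays again
  expect_lt(tail(sim$tsh, 1), max(sim$tsh[rec]))
})

test_that("scenarios validate, interpolate and round-trip through CSV", {
  expect_error(scenario("d_h", 0, 1), "not schedulable")
  expect_error(scenario("g_d2", 0, -1), "value > 0")
  scn <- scenario_thyrotropic_adaptation()
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(scn), f, row.names = FALSE)
  scn2 <- read_scenario(f)
  expect_equal(scn2$value, scn$value)
  unlink(f)
  # schedule span must fit in the simulated window
  expect_error(simulate_dynamics(feedback_parameters(), scn,
                                 duration_days = 10),
               "cover the schedule")
})
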