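test_that("equilibrium is a fixed point of free relaxation", {
  tis <- larg_tissue()
  st <- equilibrium_state(tis)
  for (dur in c(0.01, 0.5, 3)) {
    out <- propagate_interval(st, tis, 0, 3, dur)
    expect_lt(max(abs(state_to_vec(out) - state_to_vec(st))), 1e-10)
  }
})

test_that("free relaxation from a perturbed state follows closed forms", {
  # decouple the pools so the water pool relaxes as a single spin
  tis <- larg_tissue(fs = 0, ksw = 0)
  st <- magnetization_state(c(0.3, 0.2, 0.5), c(0, 0, 0))
  t1 <- tis$water$t1; t2 <- tis$water$t2
  for (dur in c(0.05, 0.4, 2)) {
    out <- propagate_interval(st, tis, 0, 2, dur)
    expect_equal(out$water_xyz[3], 1 - 0.5 * exp(-dur / t1),
                 tolerance = 1e-9)
    # transverse magnitude decays as exp(-t/T2) while precessing
    expect_equal(sqrt(sum(out$water_xyz[1:2]^2)),
                 sqrt(0.3^2 + 0.2^2) * exp(-dur / t2), tolerance = 1e-9)
  }
})

test_that("matrix-exponential propagation matches the RK4 oracle", {
  tis <- larg_tissue()
  st <- equilibrium_state(tis)
  a <- propagate_interval(st, tis, 2, 3, 0.1)
  b <- propagate_interval_rk4(st, tis, 2, 3, 0.1, dt = 1e-5)
  expect_lt(abs(a$water_xyz[3] - b$water_xyz[3]) / abs(b$water_xyz[3]),
            1e-6)
  # random physical draws, one saturation interval each
  set.seed(42)
  for (i in 1:20) {
    tis <- larg_tissue(fs = runif(1, 1e-4, 5e-3), ksw = runif(1, 20, 1200),
                       t1w = runif(1, 1, 4), t2w = runif(1, 0.3, 2),
                       b0_shift = runif(1, -0.3, 0.3))
    b1 <- runif(1, 0, 4)
    a <- propagate_interval(st, tis, b1, 3, 0.1)
    b <- propagate_interval_rk4(st, tis, b1, 3, 0.1, dt = 1e-5)
    expect_lt(max(abs(state_to_vec(a) - state_to_vec(b))) /
                max(abs(state_to_vec(b))), 1e-6)
  }
})

test_that("propagation rejects invalid inputs", {
  tis <- larg_tissue()
  st <- equilibrium_state(tis)
  expect_error(propagate_interval(st, tis, 2, 3, -0.1), "duration")
  expect_error(propagate_interval(st, tis, -1, 3, 0.1), "b1_amplitude")
  expect_error(pool_parameters(t1 = 2.5, t2 = NaN), "non-finite")
  expect_error(pool_parameters(t1 = -1, t2 = 1), "positive")
  expect_error(pool_parameters(2.5, 1, volume_fraction = 1.2),
               "volume_fraction")
})

test_that("semisolid lineshape rates match their closed/quadrature forms", {
  mt <- pool_parameters(1.0, 1e-5, exchange_rate = 40,
                        volume_fraction = 0.15, lineshape = "lorentzian")
  expect_identical(apply_semisolid_lineshape(mt, 0, 10), 0)
  # Lorentzian peak: R = gamma^2 B1^2 T2s with gamma in rad/s/uT
  b1 <- 2
  gam <- 2 * pi * 42.5764
  expect_equal(apply_semisolid_lineshape(mt, b1, 0),
               gam^2 * b1^2 * 1e-5, tolerance = 1e-12)
  # super-Lorentzian vs independent quadrature (trapezoid, fine grid)
  sl <- pool_parameters(1.0, 1e-5, exchange_rate = 40,
                        volume_fraction = 0.15,
                        lineshape = "superlorentzian")
  dw <- 2 * pi * hz_per_ppm(3) * 10
  th <- seq(1e-7, pi / 2, length.out = 200001)
  u <- 3 * cos(th)^2 - 1
  f <- sqrt(2 / pi) * sin(th) * (1e-5 / abs(u)) * exp(-2 * (dw * 1e-5 / u)^2)
  g_ref <- sum((f[-1] + f[-length(f)]) / 2 * diff(th))
  rate <- apply_semisolid_lineshape(sl, b1, 10)
  expect_equal(rate, pi * (gam * b1)^2 * g_ref, tolerance = 1e-4)
  bad <- mt
  bad$lineshape <- "boxcar"
  expect_error(apply_semisolid_lineshape(bad, 1, 10))
})

test_that("full-schedule simulation matches the end-to-end RK4 oracle", {
  sch <- short_schedule(m = 4)
  tis <- larg_tissue()
  a <- simulate_schedule(tis, sch)
  b <- simulate_schedule_rk4(tis, sch, dt = 1e-5)
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-5)
  # semisolid pool path
  tism <- mt_tissue()
  schm <- short_schedule(m = 3)
  schm$sat_offset <- c(6, 10, 14)
  schm <- mrf_schedule(schm)
  am <- simulate_schedule(tism, schm)
  bm <- simulate_schedule_rk4(tism, schm, dt = 1e-5)
  expect_lt(max(abs(am - bm)) / max(abs(bm)), 1e-5)
})

test_that("one schedule entry at zero power reads sin(flip) at equilibrium", {
  sch <- mrf_schedule(data.frame(
    sat_power = 0, sat_offset = 3, n_pulses = 13, pulse_duration = 0.1,
    interpulse_delay = 0.1, recovery_delay = 2.5, flip_angle = 15,
    echo_time = 0.011))
  sig <- simulate_schedule(larg_tissue(), sch)
  expect_equal(sig, sin(15 * pi / 180), tolerance = 1e-10)
})

test_that("decoupled solute (fs = 0) reduces to the single-pool solution", {
  sch <- short_schedule(m = 5)
  tis <- larg_tissue(fs = 0, ksw = 300)
  two_pool <- simulate_schedule(tis, sch)
  one_pool <- single_pool_reference(tis$water$t1, tis$water$t2, sch)
  expect_lt(max(abs(two_pool - one_pool)), 1e-10)
})

test_that("post-saturation Z is in [-1, 1] and non-increasing in fs", {
  one_entry <- function(b1) mrf_schedule(data.frame(
    sat_power = b1, sat_offset = 3, n_pulses = 13, pulse_duration = 0.1,
    interpulse_delay = 0.1, recovery_delay = 0, flip_angle = 90,
    echo_time = 0.011))
  fs_grid <- c(1e-4, 5e-4, 1e-3, 3e-3, 1e-2)
  for (b1 in c(1, 2, 3)) {
    z <- vapply(fs_grid, function(fs)
      simulate_schedule(larg_tissue(fs = fs), one_entry(b1)), 1.0)
    expect_true(all(z >= -1 & z <= 1))
    expect_true(all(diff(z) <= 1e-12))
  }
})

test_that("trajectory normalization is exact and idempotent", {
  expect_equal(normalize_trajectory(c(3, 4)), c(0.6, 0.8))
  u <- normalize_trajectory(c(3, 4))
  expect_equal(normalize_trajectory(u), u, tolerance = 1e-15)
  set.seed(11)
  for (i in 1:100) {
    v <- rnorm(30)
    expect_equal(sum(normalize_trajectory(v)^2), 1, tolerance = 1e-12)
  }
  expect_error(normalize_trajectory(rep(0, 5)), "all-zero")
})
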