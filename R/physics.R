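#' Exchanging-pool parameters
#'
#' Describes one proton pool of the two-pool Bloch-McConnell model: the free
#' water pool or an exchanging solute/semisolid pool.
#'
#' @param t1 longitudinal relaxation time, seconds (> 0)
#' @param t2 transverse relaxation time, seconds (> 0; microseconds-scale for
#'   a semisolid pool, where `t2 > t1` is deliberately not enforced)
#' @param chemical_shift resonance offset from water, ppm
#' @param exchange_rate pool-to-water proton exchange rate k_sw, Hz (>= 0)
#' @param volume_fraction relative exchangeable-proton fraction f_s,
#'   water-referenced and dimensionless, in [0, 1)
#' @param lineshape `NULL` for a free (Lorentzian-line liquid) pool handled by
#'   full transverse Bloch dynamics, or one of `"lorentzian"`,
#'   `"superlorentzian"` for a semisolid pool handled through a
#'   lineshape-weighted saturation rate
#' @return an object of class `pool_parameters`
#' @export
pool_parameters <- function(t1, t2, chemical_shift = 0, exchange_rate = 0,
                            volume_fraction = 0, lineshape = NULL) {
  vals <- c(t1, t2, chemical_shift, exchange_rate, volume_fraction)
  if (any(!is.finite(vals))) stopf("non-finite pool parameter")
  if (t1 <= 0 || t2 <= 0) stopf("t1 and t2 must be positive")
  if (exchange_rate < 0) stopf("exchange_rate must be >= 0")
  if (volume_fraction < 0 || volume_fraction >= 1)
    stopf("volume_fraction must be in [0, 1)")
  if (!is.null(lineshape))
    lineshape <- match.arg(lineshape, c("lorentzian", "superlorentzian"))
  if (is.null(lineshape) && t2 < t1 * 1e-3 && t2 < 1e-3)
    warning("microseconds-scale t2 without a lineshape: did you mean a semisolid pool?")
  structure(list(t1 = t1, t2 = t2, chemical_shift = chemical_shift,
                 exchange_rate = exchange_rate,
                 volume_fraction = volume_fraction, lineshape = lineshape),
            class = "pool_parameters")
}

#' Two-pool tissue parameters
#'
#' One free water pool plus exactly one exchanging (solute or semisolid)
#' pool, with static-field offset and transmit-field scale.
#'
#' @param water `pool_parameters` of the water pool; its `volume_fraction` is
#'   forced to 1 and `exchange_rate` to 0
#' @param solute `pool_parameters` of the exchanging pool
#' @param b0_shift static field offset, ppm
#' @param b1_scale transmit-field multiplier (> 0)
#' @return an object of class `tissue_parameters`
#' @export
tissue_parameters <- function(water, solute, b0_shift = 0, b1_scale = 1) {
  stopifnot(inherits(water, "pool_parameters"),
            inherits(solute, "pool_parameters"))
  if (!is.finite(b0_shift) || !is.finite(b1_scale) || b1_scale <= 0)
    stopf("b0_shift must be finite and b1_scale > 0")
  water$volume_fraction <- 1
  water$exchange_rate <- 0
  structure(list(water = water, solute = solute, b0_shift = b0_shift,
                 b1_scale = b1_scale), class = "tissue_parameters")
}

#' @export
print.tissue_parameters <- function(x, ...) {
  cat("Two-pool tissue parameters\n")
  cat(sprintf("  water:  T1 = %.3g s, T2 = %.3g s\n", x$water$t1, x$water$t2))
  cat(sprintf("  solute: T1 = %.3g s, T2 = %.3g s, shift = %.3g ppm, fs = %.3g, ksw = %.3g Hz%s\n",
              x$solute$t1, x$solute$t2, x$solute$chemical_shift,
              x$solute$volume_fraction, x$solute$exchange_rate,
              if (is.null(x$solute$lineshape)) ""
              else paste0(", lineshape = ", x$solute$lineshape)))
  cat(sprintf("  B0 shift = %.3g ppm, B1 scale = %.3g\n", x$b0_shift, x$b1_scale))
  invisible(x)
}

#' Thermal-equilibrium magnetization state
#'
#' @param tissue `tissue_parameters`
#' @return a `magnetization_state`: water and solute (x, y, z) components in
#'   units of the equilibrium water magnetization
#' @export
equilibrium_state <- function(tissue) {
  magnetization_state(c(0, 0, 1), c(0, 0, tissue$solute$volume_fraction))
}

#' Construct a magnetization state
#' @param water_xyz,solute_xyz numeric 3-vectors
#' @return object of class `magnetization_state`
#' @export
magnetization_state <- function(water_xyz, solute_xyz) {
  stopifnot(length(water_xyz) == 3, length(solute_xyz) == 3)
  if (any(!is.finite(c(water_xyz, solute_xyz))))
    stopf("non-finite magnetization state")
  structure(list(water_xyz = as.numeric(water_xyz),
                 solute_xyz = as.numeric(solute_xyz)),
            class = "magnetization_state")
}

state_to_vec <- function(state) c(state$water_xyz, state$solute_xyz)
vec_to_state <- function(v) magnetization_state(v[1:3], v[4:6])

# pool vector consumed by the C++ kernels: (r1w, r2w, r1s, r2s, fs, ksw)
tissue_pool_vec <- function(tissue) {
  c(1 / tissue$water$t1, 1 / tissue$water$t2,
    1 / tissue$solute$t1, 1 / tissue$solute$t2,
    tissue$solute$volume_fraction, tissue$solute$exchange_rate)
}

is_semisolid <- function(tissue) !is.null(tissue$solute$lineshape)

# per-interval RF quantities in the frame rotating at the saturation offset
rf_terms <- function(tissue, b1_amplitude, offset_ppm, b0_field) {
  hpp <- hz_per_ppm(b0_field)
  w1 <- 2 * pi * GAMMA_HZ_PER_UT * b1_amplitude * tissue$b1_scale
  dww <- 2 * pi * hpp * (tissue$b0_shift - offset_ppm)
  dws <- 2 * pi * hpp *
    (tissue$solute$chemical_shift + tissue$b0_shift - offset_ppm)
  rrfb <- 0
  if (is_semisolid(tissue)) {
    rrfb <- apply_semisolid_lineshape(
      tissue$solute, b1_amplitude * tissue$b1_scale,
      offset_ppm - tissue$solute$chemical_shift - tissue$b0_shift,
      b0_field = b0_field)
  }
  list(w1 = w1, dww = dww, dws = dws, rrfb = rrfb)
}

#' Lineshape-weighted saturation rate of a semisolid pool
#'
#' Computes the effective RF saturation rate R_rfb = pi * omega1^2 * g(dw)
#' applied to the longitudinal magnetization of a semisolid pool, where g is
#' the absorption lineshape (Lorentzian or super-Lorentzian) evaluated at the
#' offset from the pool center.
#'
#' @param pool semisolid `pool_parameters` with `lineshape` set
#' @param b1_amplitude saturation amplitude, microtesla (>= 0)
#' @param offset_ppm offset relative to the semisolid pool center, ppm
#' @param b0_field static field, Tesla
#' @param sl_cutoff_hz below this absolute offset (Hz) the super-Lorentzian
#'   on-resonance singularity is handled by clamping g to its cutoff value
#' @return non-negative saturation rate in Hz (1/s)
#' @export
apply_semisolid_lineshape <- function(pool, b1_amplitude, offset_ppm,
                                      b0_field = 3, sl_cutoff_hz = 250) {
  if (is.null(pool$lineshape))
    stopf("pool has no lineshape: not a semisolid pool")
  if (b1_amplitude < 0) stopf("b1_amplitude must be >= 0")
  if (b1_amplitude == 0) return(0)
  w1 <- 2 * pi * GAMMA_HZ_PER_UT * b1_amplitude
  dw <- 2 * pi * hz_per_ppm(b0_field) * offset_ppm
  g <- switch(pool$lineshape,
    lorentzian = (pool$t2 / pi) / (1 + (dw * pool$t2)^2),
    superlorentzian = superlorentzian_g(dw, pool$t2,
                                        cutoff = 2 * pi * sl_cutoff_hz),
    stopf("unknown lineshape '%s'", pool$lineshape))
  pi * w1^2 * g
}

# super-Lorentzian absorption lineshape g(dw) [s], numerically integrated
# over the fiber angle; the integrable on-resonance divergence is clamped
# below `cutoff` (rad/s).
superlorentzian_g <- function(dw, t2, cutoff = 2 * pi * 250) {
  dw <- abs(dw)
  if (dw < cutoff) dw <- cutoff
  integrand <- function(theta) {
    u <- 3 * cos(theta)^2 - 1
    sqrt(2 / pi) * sin(theta) * (t2 / abs(u)) * exp(-2 * (dw * t2 / u)^2)
  }
  brk <- acos(1 / sqrt(3))
  i1 <- integrate(integrand, 0, brk, rel.tol = 1e-9, stop.on.error = FALSE)
  i2 <- integrate(integrand, brk, pi / 2, rel.tol = 1e-9,
                  stop.on.error = FALSE)
  i1$value + i2$value
}

#' Propagate magnetization through one constant-RF interval
#'
#' Evolves the six-dimensional two-pool Bloch-McConnell system
#' dM/dt = A M + b exactly over an interval with constant saturation
#' amplitude and offset, via the augmented 7x7 matrix exponential. Exchange
#' couples the pools with rates k_sw (solute to water) and
#' k_ws = f_s * k_sw (detailed balance).
#'
#' @param state `magnetization_state` at the start of the interval
#' @param tissue `tissue_parameters`
#' @param b1_amplitude saturation amplitude, microtesla (0 = free relaxation)
#' @param offset_ppm saturation offset from water, ppm
#' @param duration interval length, seconds (>= 0)
#' @param b0_field static field, Tesla (fixes the ppm-to-Hz conversion)
#' @return the `magnetization_state` after the interval
#' @export
propagate_interval <- function(state, tissue, b1_amplitude, offset_ppm,
                               duration, b0_field = 3) {
  stopifnot(inherits(state, "magnetization_state"),
            inherits(tissue, "tissue_parameters"))
  if (duration < 0) stopf("duration must be >= 0")
  if (b1_amplitude < 0) stopf("b1_amplitude must be >= 0")
  if (duration == 0) return(state)
  rf <- rf_terms(tissue, b1_amplitude, offset_ppm, b0_field)
  v <- .bm_propagate_cpp(state_to_vec(state), tissue_pool_vec(tissue),
                         rf$w1, rf$dww, rf$dws, rf$rrfb,
                         is_semisolid(tissue), duration)
  vec_to_state(as.numeric(v))
}

#' RK4 reference propagation over one interval
#'
#' Classical fourth-order Runge-Kutta time stepping of the same two-pool
#' system, used as an independent numerical check of the matrix-exponential
#' propagator.
#'
#' @inheritParams propagate_interval
#' @param dt integration step, seconds (default 10 microseconds)
#' @return the `magnetization_state` after the interval
#' @export
propagate_interval_rk4 <- function(state, tissue, b1_amplitude, offset_ppm,
                                   duration, b0_field = 3, dt = 1e-5) {
  stopifnot(inherits(state, "magnetization_state"),
            inherits(tissue, "tissue_parameters"))
  if (duration < 0) stopf("duration must be >= 0")
  if (duration == 0) return(state)
  rf <- rf_terms(tissue, b1_amplitude, offset_ppm, b0_field)
  v <- .bm_rk4_propagate_cpp(state_to_vec(state), tissue_pool_vec(tissue),
                             rf$w1, rf$dww, rf$dws, rf$rrfb,
                             is_semisolid(tissue), duration, dt)
  vec_to_state(as.numeric(v))
}

# Assemble the per-entry numeric schedule matrix consumed by the C++ kernels.
schedule_matrix <- function(tissue, schedule, b0_field = 3,
                            spoil_factor = NULL) {
  entries <- as.data.frame(schedule)
  m <- nrow(entries)
  hpp <- hz_per_ppm(b0_field)
  w1 <- 2 * pi * GAMMA_HZ_PER_UT * entries$sat_power * tissue$b1_scale
  dww <- 2 * pi * hpp * (tissue$b0_shift - entries$sat_offset)
  dws <- 2 * pi * hpp * (tissue$solute$chemical_shift + tissue$b0_shift -
                           entries$sat_offset)
  rrfb <- numeric(m)
  if (is_semisolid(tissue)) {
    for (i in seq_len(m)) {
      rrfb[i] <- apply_semisolid_lineshape(
        tissue$solute, entries$sat_power[i] * tissue$b1_scale,
        entries$sat_offset[i] - tissue$solute$chemical_shift -
          tissue$b0_shift, b0_field = b0_field)
    }
  }
  flip <- entries$flip_angle * pi / 180
  spoil <- if (is.null(spoil_factor)) cos(flip) else rep(spoil_factor, m)
  cbind(w1, dww, dws, rrfb, entries$n_pulses, entries$pulse_duration,
        entries$interpulse_delay, entries$recovery_delay, flip, spoil)
}

#' Simulate a full MRF acquisition schedule
#'
#' Propagates the tissue through every schedule entry in acquisition order,
#' carrying the spin history across entries (no re-equilibration). Each entry
#' consists of a pulsed saturation train (`n_pulses` block pulses of
#' `pulse_duration` at the entry's power and offset, separated by
#' `interpulse_delay` of free relaxation, with no trailing gap), an
#' instantaneous readout (signal = water Mz x sin(flip); afterwards water Mz
#' is scaled by the longitudinal-spoiling factor and transverse components
#' are crushed), and the entry's recovery delay.
#'
#' @param tissue `tissue_parameters`
#' @param schedule an `mrf_schedule` (see [generate_pseudorandom_schedule()])
#' @param b0_field static field, Tesla
#' @param spoil_factor longitudinal scaling of water Mz applied by the
#'   readout; `NULL` (default) uses cos(flip) per entry
#' @return numeric vector of length M: the raw signal trajectory
#' @examples
#' sched <- generate_pseudorandom_schedule(5, "cest_3ppm", seed = 1)
#' larg <- tissue_parameters(
#'   water = pool_parameters(2.5, 1.0),
#'   solute = pool_parameters(1.0, 0.02, chemical_shift = 3,
#'                            exchange_rate = 400,
#'                            volume_fraction = 1.35e-3))
#' simulate_schedule(larg, sched)
#' @export
simulate_schedule <- function(tissue, schedule, b0_field = 3,
                              spoil_factor = NULL) {
  stopifnot(inherits(tissue, "tissue_parameters"))
  schedule <- as_mrf_schedule(schedule)
  sm <- schedule_matrix(tissue, schedule, b0_field, spoil_factor)
  if (any(sm[, 5] < 0) || any(sm[, c(6, 7, 8)] < 0) || any(sm[, 1] < 0))
    stopf("schedule entries must have non-negative powers and durations")
  as.numeric(.bm_simulate_schedule_cpp(tissue_pool_vec(tissue), sm,
                                       is_semisolid(tissue)))
}

#' RK4 reference simulation of a full schedule
#'
#' End-to-end fourth-order Runge-Kutta integration of the same schedule and
#' readout model as [simulate_schedule()]; the independent oracle for the
#' matrix-exponential path.
#'
#' @inheritParams simulate_schedule
#' @param dt integration step, seconds
#' @return numeric signal trajectory of length M
#' @export
simulate_schedule_rk4 <- function(tissue, schedule, b0_field = 3,
                                  spoil_factor = NULL, dt = 1e-5) {
  stopifnot(inherits(tissue, "tissue_parameters"))
  schedule <- as_mrf_schedule(schedule)
  sm <- schedule_matrix(tissue, schedule, b0_field, spoil_factor)
  as.numeric(.bm_rk4_schedule_cpp(tissue_pool_vec(tissue), sm,
                                  is_semisolid(tissue), dt))
}

#' Normalize a signal trajectory to unit l2 norm
#'
#' @param raw numeric trajectory with at least one nonzero element
#' @return trajectory scaled to unit Euclidean norm, direction preserved
#' @export
normalize_trajectory <- function(raw) {
  if (!is.numeric(raw) || length(raw) == 0) stopf("raw must be numeric")
  n <- sqrt(sum(raw^2))
  if (n == 0) stopf("cannot normalize an all-zero trajectory")
  raw / n
}
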