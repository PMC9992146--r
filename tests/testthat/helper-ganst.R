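# Shared fixtures and independent oracles. Everything here is built in code
# at test time; the oracles deliberately avoid the package's own numerical
# paths (Matrix::expm instead of the internal propagator, explicit loops
# instead of vectorized metric code).

larg_tissue <- function(fs = 1.35e-3, ksw = 400, t1w = 2.5, t2w = 1.0,
                        b0_shift = 0) {
  tissue_parameters(pool_parameters(t1w, t2w),
                    pool_parameters(1.0, 0.02, chemical_shift = 3,
                                    exchange_rate = ksw,
                                    volume_fraction = fs),
                    b0_shift = b0_shift)
}

mt_tissue <- function(fss = 0.15, kssw = 40, lineshape = "lorentzian") {
  tissue_parameters(pool_parameters(1.1, 0.08),
                    pool_parameters(1.0, 1e-5, chemical_shift = 0,
                                    exchange_rate = kssw,
                                    volume_fraction = fss,
                                    lineshape = lineshape))
}

# full-strength saturation schedule (13 x 100 ms train) with a shorter
# recovery; used where parameter contrast matters (dictionary/FCN tests)
strong_schedule <- function(m = 8, seed = 13) {
  generate_pseudorandom_schedule(m, "cest_3ppm", seed = seed,
                                 recovery_delay = 1.5)
}

# short schedule for fast unit tests (reduced saturation train)
short_schedule <- function(m = 5, seed = 3, n_pulses = 3) {
  s <- generate_pseudorandom_schedule(m, "cest_3ppm", seed = seed,
                                      recovery_delay = 0.3)
  s$n_pulses <- n_pulses
  s$pulse_duration <- 0.05
  s$interpulse_delay <- 0.05
  mrf_schedule(s, label = "unit_test")
}

# Independent single-pool Bloch simulation of a schedule via Matrix::expm
# on the augmented 4x4 system (x, y, z, 1). Mirrors the readout model:
# signal = Mz sin(flip), Mz *= spoil, transverse crushed, recovery delay.
single_pool_reference <- function(t1, t2, schedule, b0_field = 3,
                                  b0_shift = 0) {
  hpp <- ganst::hz_per_ppm(b0_field)
  gam <- 42.5764
  m <- nrow(schedule)
  sig <- numeric(m)
  y <- c(0, 0, 1)
  for (e in seq_len(m)) {
    w1 <- 2 * pi * gam * schedule$sat_power[e]
    dw <- 2 * pi * hpp * (b0_shift - schedule$sat_offset[e])
    A <- matrix(c(-1 / t2, dw, 0,
                  -dw, -1 / t2, w1,
                  0, -w1, -1 / t1), 3, 3, byrow = TRUE)
    b <- c(0, 0, 1 / t1)
    prop <- function(Amat, bvec, dt) {
      G <- rbind(cbind(Amat, bvec), 0)
      as.matrix(Matrix::expm(G * dt))
    }
    Pp <- prop(A, b, schedule$pulse_duration[e])
    Af <- A; Af[1, 2] <- dw; Af[2, 1] <- -dw; Af[2, 3] <- 0; Af[3, 2] <- 0
    Pg <- prop(Af, b, schedule$interpulse_delay[e])
    aug <- c(y, 1)
    np <- schedule$n_pulses[e]
    aug <- Pp %*% aug
    if (np > 1) for (k in 2:np) aug <- Pp %*% (Pg %*% aug)
    y <- aug[1:3]
    flip <- schedule$flip_angle[e] * pi / 180
    sig[e] <- y[3] * sin(flip)
    y <- c(0, 0, y[3] * cos(flip))
    if (schedule$recovery_delay[e] > 0) {
      aug <- prop(Af, b, schedule$recovery_delay[e]) %*% c(y, 1)
      y <- aug[1:3]
    }
  }
  sig
}

# brute-force SSIM oracle: explicit loop over fully contained windows
ssim_bruteforce <- function(pred, ref, win = 3, sigma = 1.5, L = NULL) {
  if (is.null(L)) L <- diff(range(ref))
  if (L <= 0) L <- 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  half <- (win - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  vals <- c()
  for (i in (half + 1):(nrow(ref) - half)) {
    for (j in (half + 1):(ncol(ref) - half)) {
      px <- pred[(i - half):(i + half), (j - half):(j + half)]
      rx <- ref[(i - half):(i + half), (j - half):(j + half)]
      mx <- sum(w * px); my <- sum(w * rx)
      vx <- sum(w * px^2) - mx^2; vy <- sum(w * rx^2) - my^2
      vxy <- sum(w * px * rx) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * vxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# tiny standardized gan_pairs fixture on n x n images
toy_gan_pairs <- function(n_pairs = 4, size = 16, n_input = 3, seed = 7) {
  withr_seed <- function(code) { set.seed(seed); code }
  set.seed(seed)
  pairs <- lapply(seq_len(n_pairs), function(i) {
    base <- matrix(runif(size * size), size, size)
    inp <- array(0, c(size, size, n_input))
    for (c in seq_len(n_input)) inp[, , c] <- base * c / n_input
    tgt <- array(0, c(size, size, 2))
    tgt[, , 1] <- pmin(pmax(base, 0), 1)
    tgt[, , 2] <- pmin(pmax(1 - base, 0), 1)
    list(input = inp, target = tgt, mask = matrix(TRUE, size, size))
  })
  structure(pairs, target_names = c("volume_fraction", "exchange_rate"),
            output_scaling = list(volume_fraction = c(0, 1),
                                  exchange_rate = c(0, 1)),
            class = "gan_pairs")
}
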