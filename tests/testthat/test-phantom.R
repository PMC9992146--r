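test_that("L-arg exchange rate follows base catalysis", {
  expect_equal(larg_exchange_rate(6, k_base = 300, k_0 = 0), 300)
  # +1 pH unit multiplies the base-catalyzed component by 10
  k0 <- 25
  k5 <- larg_exchange_rate(5, k_base = 400, k_0 = k0)
  k6 <- larg_exchange_rate(6, k_base = 400, k_0 = k0)
  expect_equal(k6 - k0, 10 * (k5 - k0))
  ph <- seq(4, 6, by = 0.25)
  expect_true(all(diff(larg_exchange_rate(ph)) > 0))
  expect_error(larg_exchange_rate(15), "pH")
  expect_error(larg_exchange_rate(5, k_base = -1), "k_base")
})

test_that("volume fraction from concentration is linear in both arguments", {
  expect_equal(fs_from_concentration(50, 3), 150 / 111000)
  expect_equal(fs_from_concentration(0), 0)
  expect_equal(fs_from_concentration(100), 4 * fs_from_concentration(25))
  expect_error(fs_from_concentration(-1), "concentration")
})

test_that("L-arg scenes have the requested geometry and maps", {
  lay <- vial_layout_ring(6, radius = 7)
  conc <- c(25, 50, 100, 25, 50, 100)
  phs <- c(4, 4.4, 4.8, 5.2, 5.6, 6)
  sc <- make_larg_scene(lay, conc, phs)
  expect_equal(sort(unique(as.vector(sc$region_labels))), 0:6)
  for (v in 1:6) {
    sel <- sc$region_labels == v
    # area within one-voxel-ring discretization tolerance of pi r^2
    expect_lt(abs(sum(sel) - pi * 7^2), 2 * pi * 7 + 4)
    expect_true(all(sc$aux$ph[sel] == phs[v]))
    expect_true(all(sc$truth$volume_fraction[sel] ==
                      fs_from_concentration(conc[v])))
    expect_equal(unique(sc$truth$exchange_rate[sel]),
                 larg_exchange_rate(phs[v]))
  }
  # saline background carries no exchanging pool
  expect_true(all(sc$truth$volume_fraction[sc$region_labels == 0] == 0))
  # f_s and concentration maps are proportional voxelwise
  expect_equal(sc$truth$volume_fraction,
               sc$aux$concentration * 3 / 111000)
  empty <- make_larg_scene(vial_layout_ring(0)[0, ], numeric(0), numeric(0))
  expect_true(all(empty$region_labels == 0))
  lay2 <- data.frame(cx = c(20, 25), cy = c(20, 20), r = c(6, 6))
  expect_error(make_larg_scene(lay2, c(25, 50), c(5, 5)), "overlap")
})

test_that("brain scenes draw tissue statistics from the stated Gaussians", {
  sc <- make_brain_scene(shape = c(128, 128), seed = 11)
  wm <- sc$region_labels == 1
  gm <- sc$region_labels == 2
  expect_gt(sum(wm), 2000)
  expect_gt(sum(gm), 2000)
  expect_lt(abs(mean(sc$truth$volume_fraction[wm]) - 0.187), 0.005)
  expect_lt(abs(mean(sc$truth$volume_fraction[gm]) - 0.124), 0.005)
  expect_lt(abs(mean(sc$truth$exchange_rate[wm]) - 33.9), 1.0)
  expect_lt(abs(mean(sc$truth$exchange_rate[gm]) - 49.1), 1.5)
  expect_true(all(sc$truth$volume_fraction >= 0 &
                    sc$truth$volume_fraction < 1))
  sc2 <- make_brain_scene(shape = c(128, 128), seed = 11)
  expect_identical(sc$truth, sc2$truth)
  sct <- make_brain_scene(shape = c(64, 64), tumor = TRUE, seed = 3)
  expect_true(3 %in% sct$region_labels)
})

test_that("B0 artifact injection is local, bounded and seeded", {
  sc <- make_larg_scene(vial_layout_ring(4, radius = 6),
                        c(25, 50, 100, 50), c(4.5, 5, 5.5, 6))
  expect_identical(inject_b0_artifact(sc, 2, 0, seed = 1), sc)
  pert <- inject_b0_artifact(sc, 1, max_shift_ppm = 0.3, seed = 5)
  expect_equal(max(abs(pert$truth$b0_shift)), 0.3, tolerance = 0.01 * 0.3)
  expect_identical(pert$truth$volume_fraction, sc$truth$volume_fraction)
  expect_true(any(attr(pert, "b0_blob_mask")))
  expect_identical(inject_b0_artifact(sc, 1, 0.3, seed = 5)$truth$b0_shift,
                   pert$truth$b0_shift)
})

test_that("rendering matches the simulator and counts its images", {
  sch <- short_schedule(m = 7)
  sc <- make_larg_scene(vial_layout_ring(1, radius = 6)[1, , drop = FALSE],
                        50, 5.2)
  st <- render_raw_stack(sc, sch, noise_sigma = 0)
  expect_equal(dim(st$images), c(64, 64, 7))
  v <- which(sc$region_labels == 1, arr.ind = TRUE)[1, ]
  tis <- larg_tissue(fs = fs_from_concentration(50),
                     ksw = larg_exchange_rate(5.2))
  expect_equal(st$images[v[1], v[2], ],
               abs(simulate_schedule(tis, sch)), tolerance = 1e-12)
  # deterministic at zero noise, seeded otherwise
  st2 <- render_raw_stack(sc, sch, noise_sigma = 0)
  expect_identical(st$images, st2$images)
  n1 <- render_raw_stack(sc, sch, noise_sigma = 1e-3, seed = 3)
  n2 <- render_raw_stack(sc, sch, noise_sigma = 1e-3, seed = 3)
  expect_identical(n1$images, n2$images)
})

test_that("Rician background has the Rayleigh mean", {
  sch <- short_schedule(m = 20)
  sc <- make_larg_scene(vial_layout_ring(0)[0, ], numeric(0), numeric(0))
  sc$truth$t1_water[] <- 2.5
  # zero-signal voxels: remove water signal by zeroing the flip
  sch$flip_angle <- 0
  sch <- mrf_schedule(sch)
  sigma <- 0.01
  st <- render_raw_stack(sc, sch, noise_sigma = sigma, noise_model =
                           "rician", seed = 2)
  m <- mean(st$images)
  expect_lt(abs(m - sigma * sqrt(pi / 2)), 3 * sigma / sqrt(64 * 64 * 20))
})

test_that("sevenfold augmentation preserves pairing and involutions", {
  set.seed(3)
  mk_pair <- function() {
    inp <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
    tgt <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
    list(input = inp, target = tgt)
  }
  pairs <- list(mk_pair(), mk_pair(), mk_pair())
  aug <- augment_pairs(pairs, seed = 10)
  expect_length(aug, 21)
  expect_identical(aug[[1]], pairs[[1]])     # first variant is the original
  # horizontal flip applied twice is the identity
  flip_h <- aug[[2]]$input
  expect_identical(flip_h[rev(seq_len(16)), , ], pairs[[1]]$input)
  # marker voxel: input and target move by the same offset
  marker <- mk_pair()
  marker$input[] <- 0; marker$target[] <- 0
  marker$input[5, 9, 1] <- 1; marker$target[5, 9, 1] <- 1
  aug_m <- augment_pairs(list(marker), seed = 4)
  for (k in 5:7) {  # the translated variants
    pos_i <- which(aug_m[[k]]$input[, , 1] != 0, arr.ind = TRUE)
    pos_t <- which(aug_m[[k]]$target[, , 1] != 0, arr.ind = TRUE)
    if (nrow(pos_i) > 0 || nrow(pos_t) > 0) {
      expect_identical(pos_i, pos_t)
    }
  }
})
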