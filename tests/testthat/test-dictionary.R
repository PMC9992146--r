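make_small_dict <- function(nfs = 9, nk = 9, m = 6, seed = 4) {
  sch <- strong_schedule(m = m, seed = seed)
  grid <- parameter_grid(list(
    volume_fraction = seq(2e-4, 3e-3, length.out = nfs),
    exchange_rate = seq(50, 1200, length.out = nk)))
  generate_dictionary(grid, sch, larg_tissue())
}

test_that("grid construction validates its axes", {
  expect_error(parameter_grid(list()), "at least one axis")
  expect_error(parameter_grid(list(foo = 1:3)), "unknown grid axis")
  expect_error(parameter_grid(list(exchange_rate = c(2, 1))),
               "strictly increasing")
  g <- parameter_grid(list(volume_fraction = c(1e-4, 1e-3),
                           exchange_rate = c(10, 100, 1000)))
  expect_equal(nrow(grid_points(g)), 6)
})

test_that("a one-point dictionary equals a single normalized trajectory", {
  sch <- strong_schedule(m = 6, seed = 4)
  grid <- parameter_grid(list(volume_fraction = 1.35e-3,
                              exchange_rate = 400))
  dict <- generate_dictionary(grid, sch, larg_tissue())
  expect_equal(dim(dict$trajectories), c(1, 6))
  direct <- normalize_trajectory(abs(simulate_schedule(larg_tissue(), sch)))
  expect_equal(as.numeric(dict$trajectories[1, ]), direct,
               tolerance = 1e-12)
})

test_that("dictionary rows are unit norm and regenerate exactly", {
  dict <- make_small_dict()
  expect_equal(nrow(dict$trajectories), 81)
  expect_equal(sqrt(rowSums(dict$trajectories^2)), rep(1, 81),
               tolerance = 1e-12)
  sch <- strong_schedule(m = 6, seed = 4)
  set.seed(8)
  for (i in sample(81, 5)) {
    tis <- larg_tissue(fs = dict$points$volume_fraction[i],
                       ksw = dict$points$exchange_rate[i])
    row <- normalize_trajectory(abs(simulate_schedule(tis, sch)))
    expect_lt(max(abs(row - dict$trajectories[i, ])), 1e-12)
  }
  expect_error(generate_dictionary(
    parameter_grid(list(exchange_rate = c(-5, 10))), sch, larg_tissue()),
    "unphysical")
})

test_that("self-matching is exact and total", {
  dict <- make_small_dict()
  res <- dot_product_match(dict$trajectories, dict)
  expect_true(all(res$matched))
  expect_identical(res$match_index, seq_len(81))
  expect_equal(res$volume_fraction, dict$points$volume_fraction)
})

test_that("matching is scale invariant and flags degenerate voxels", {
  dict <- make_small_dict()
  sig <- dict$trajectories[17, ]
  a <- dot_product_match(sig, dict)
  b <- dot_product_match(sig * 1234, dict)
  expect_identical(a$match_index, b$match_index)
  z <- dot_product_match(rbind(sig, 0), dict)
  expect_false(z$matched[2])
  expect_true(is.na(z$match_index[2]))
  expect_error(dot_product_match(sig[-1], dict), "length")
})

test_that("an off-grid trajectory matches a bracketing grid point", {
  dict <- make_small_dict()
  sch <- strong_schedule(m = 6, seed = 4)
  fs_axis <- dict$grid$axes$volume_fraction
  k_axis <- dict$grid$axes$exchange_rate
  fs_mid <- (fs_axis[4] + fs_axis[5]) / 2
  tis <- larg_tissue(fs = fs_mid, ksw = k_axis[6])
  res <- dot_product_match(abs(simulate_schedule(tis, sch)), dict)
  expect_true(res$volume_fraction %in% fs_axis[4:5])
  expect_equal(res$exchange_rate, k_axis[6])
})

test_that("noisy matching stays near the generating grid point", {
  # Monte-Carlo pilot-calibrated check: unit-norm trajectories perturbed by
  # white noise; matches stay within one grid step along both axes for the
  # overwhelming majority of draws at this noise level
  sch <- strong_schedule(m = 10, seed = 21)
  grid <- parameter_grid(list(
    volume_fraction = seq(2e-4, 3e-3, length.out = 15),
    exchange_rate = seq(50, 1200, length.out = 15)))
  dict <- generate_dictionary(grid, sch, larg_tissue())
  set.seed(99)
  n_draw <- 300
  hits <- 0
  idx <- sample(nrow(dict$points), n_draw, replace = TRUE)
  for (d in seq_len(n_draw)) {
    i <- idx[d]
    noisy <- dict$trajectories[i, ] + rnorm(10, 0, 5e-4)
    r <- dot_product_match(noisy, dict)
    ok_f <- abs(r$volume_fraction - dict$points$volume_fraction[i]) <=
      diff(grid$axes$volume_fraction[1:2]) + 1e-12
    ok_k <- abs(r$exchange_rate - dict$points$exchange_rate[i]) <=
      diff(grid$axes$exchange_rate[1:2]) + 1e-12
    hits <- hits + (ok_f && ok_k)
  }
  expect_gte(hits / n_draw, 0.95)
})

test_that("dictionary container round-trips through its JSON file", {
  dict <- make_small_dict(nfs = 4, nk = 3)
  path <- withr::local_tempfile(fileext = ".dict.json")
  write_dictionary(dict, path)
  back <- read_dictionary(path)
  expect_equal(back$trajectories, dict$trajectories)
  expect_equal(back$points, dict$points)
  expect_identical(back$schedule_label, dict$schedule_label)
  expect_equal(back$base_tissue$solute$exchange_rate,
               dict$base_tissue$solute$exchange_rate)
})
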