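# reference quantifier: dictionary-trained fully connected network

small_fcn_setup <- function(nfs = 11, nk = 11, m = 10, epochs = 150,
                            seed = 2) {
  sch <- strong_schedule(m = m, seed = 13)
  grid <- parameter_grid(list(
    volume_fraction = seq(2e-4, 3e-3, length.out = nfs),
    exchange_rate = seq(50, 1200, length.out = nk)))
  dict <- generate_dictionary(grid, sch, larg_tissue())
  cfg <- fcn_config(m, hidden = c(100, 100),
                    output_scaling = list(volume_fraction = c(2e-4, 3e-3),
                                          exchange_rate = c(50, 1200)),
                    epochs = epochs, noise_sigma = 2e-4, seed = seed)
  list(dict = dict, cfg = cfg, sch = sch)
}

test_that("config validation catches mismatches", {
  s <- small_fcn_setup(nfs = 3, nk = 3, epochs = 2)
  expect_error(fcn_config(10, output_scaling = list(volume_fraction =
                                                      c(2, 1))),
               "output_scaling")
  bad <- s$cfg
  bad$input_length <- 99
  expect_error(train_reference_fcn(s$dict, bad), "input_length")
})

test_that("training is deterministic and predictions are scale invariant", {
  s <- small_fcn_setup(nfs = 5, nk = 5, epochs = 30)
  m1 <- train_reference_fcn(s$dict, s$cfg)
  m2 <- train_reference_fcn(s$dict, s$cfg)
  probe <- s$dict$trajectories[c(1, 7, 20), ]
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_equal(predict(m1, probe * 42), predict(m1, probe),
               tolerance = 1e-9)
})

test_that("a one-point dictionary yields a constant predictor at that point", {
  sch <- strong_schedule(m = 8, seed = 1)
  grid <- parameter_grid(list(volume_fraction = 1.5e-3,
                              exchange_rate = 300))
  dict <- generate_dictionary(grid, sch, larg_tissue())
  cfg <- fcn_config(8, hidden = c(20, 20),
                    output_scaling = list(volume_fraction = c(2e-4, 3e-3),
                                          exchange_rate = c(50, 1200)),
                    epochs = 400, noise_sigma = 1e-3, seed = 5)
  model <- train_reference_fcn(dict, cfg)
  set.seed(2)
  row <- dict$trajectories[1, ]
  probes <- rbind(row, row * 3.1, row * 0.4,
                  row + rnorm(8, 0, 2e-3), row * 2 + rnorm(8, 0, 2e-3))
  pred <- predict(model, probes)
  expect_lt(max(abs(pred[, 1] - 1.5e-3)), 0.05 * (3e-3 - 2e-4))
  expect_lt(max(abs(pred[, 2] - 300)), 0.05 * (1200 - 50))
})

test_that("the FCN agrees with dot-product matching on noiseless rows", {
  # grid restricted to the physically informative region (away from the
  # slow-exchange/low-fraction corner where trajectories are degenerate)
  sch <- strong_schedule(m = 10, seed = 13)
  grid <- parameter_grid(list(
    volume_fraction = seq(8e-4, 3e-3, length.out = 11),
    exchange_rate = seq(100, 1200, length.out = 11)))
  dict <- generate_dictionary(grid, sch, larg_tissue())
  cfg <- fcn_config(10, hidden = c(100, 100),
                    output_scaling = list(volume_fraction = c(8e-4, 3e-3),
                                          exchange_rate = c(100, 1200)),
                    epochs = 800, noise_sigma = 1e-4, seed = 2)
  model <- train_reference_fcn(dict, cfg)
  s <- list(dict = dict)
  pred <- predict(model, s$dict$trajectories)
  match <- dot_product_match(s$dict$trajectories, s$dict)
  step_f <- diff(s$dict$grid$axes$volume_fraction[1:2])
  step_k <- diff(s$dict$grid$axes$exchange_rate[1:2])
  ok <- abs(pred[, 1] - match$volume_fraction) <= step_f + 1e-12 &
    abs(pred[, 2] - match$exchange_rate) <= step_k + 1e-12
  expect_gte(mean(ok), 0.99)
})

test_that("stack quantification masks unmatchable voxels and clips outputs", {
  s <- small_fcn_setup(nfs = 5, nk = 5, epochs = 30)
  model <- train_reference_fcn(s$dict, s$cfg)
  zero_stack <- structure(list(images = array(0, c(4, 4, 10)),
                               schedule_label = "z", noise_sigma = 0,
                               m = 10), class = "raw_stack")
  q <- quantify_stack(model, zero_stack)
  expect_true(all(!q$valid))
  expect_true(all(q$volume_fraction == 0))
  set.seed(3)
  stack <- structure(list(images = array(abs(rnorm(4 * 4 * 10, 0.3, 0.3)),
                                         c(4, 4, 10)),
                          schedule_label = "r", noise_sigma = 0, m = 10),
                     class = "raw_stack")
  q2 <- quantify_stack(model, stack)
  rg <- s$cfg$output_scaling
  expect_true(all(q2$volume_fraction >= rg$volume_fraction[1] &
                    q2$volume_fraction <= rg$volume_fraction[2]))
  expect_true(all(q2$exchange_rate >= rg$exchange_rate[1] &
                    q2$exchange_rate <= rg$exchange_rate[2]))
  bad <- zero_stack
  bad$images <- array(0, c(4, 4, 7)); bad$m <- 7
  expect_error(quantify_stack(model, bad), "M = 10")
})

test_that("brain mode consumes auxiliary (T1, T2, B0) inputs", {
  sch <- short_schedule(m = 6, seed = 9)
  grid <- parameter_grid(list(
    volume_fraction = seq(0.08, 0.22, length.out = 5),
    exchange_rate = seq(20, 60, length.out = 4),
    t1_water = c(1.0, 1.3),
    b0_shift = c(-0.2, 0, 0.2)))
  sch$sat_offset <- seq(6, 14, length.out = 6)
  sch <- mrf_schedule(sch)
  dict <- generate_dictionary(grid, sch, mt_tissue())
  cfg <- fcn_config(6, hidden = c(40, 40), aux_inputs = TRUE,
                    output_scaling = list(volume_fraction = c(0.08, 0.22),
                                          exchange_rate = c(20, 60)),
                    epochs = 40, seed = 8)
  model <- train_reference_fcn(dict, cfg)
  expect_error(predict(model, dict$trajectories[1, ]), "aux")
  aux <- cbind(dict$points$t1_water[1], 0.08, dict$points$b0_shift[1])
  p <- predict(model, dict$trajectories[1, ], aux = aux)
  expect_equal(dim(p), c(1L, 2L))
})
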