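test_that("total variation loss matches brute force and is homogeneous", {
  expect_equal(total_variation_loss(matrix(3.2, 7, 5)), 0)
  # 2x2 single channel: diffs along each axis averaged then summed
  m <- matrix(c(0, 0, 1, 1), 2, 2)  # rows (0,1),(0,1)
  brute <- mean(abs(m[2, ] - m[1, ])) + mean(abs(m[, 2] - m[, 1]))
  expect_equal(total_variation_loss(m), brute)
  set.seed(4)
  x <- array(rnorm(12 * 10 * 2), c(12, 10, 2))
  brute <- 0
  for (c in 1:2) {
    for (i in 1:11) brute <- brute + sum(abs(x[i + 1, , c] - x[i, , c]))
    for (j in 1:9) brute <- brute + sum(abs(x[, j + 1, c] - x[, j, c]))
  }
  got <- total_variation_loss(x)
  expect_equal(got, total_variation_loss(x[, , 1]) +
                 total_variation_loss(x[, , 2]), tolerance = 1e-12)
  for (a in c(0.5, 2, 7)) {
    expect_equal(total_variation_loss(a * x), a * got, tolerance = 1e-10)
  }
  expect_error(total_variation_loss(matrix(1, 1, 1)), "spatial dims")
})

test_that("tv gradient matches numerical differentiation", {
  set.seed(8)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  g <- ganst:::tv_grad(x)
  idx <- sample(length(x), 10)
  for (k in idx) {
    e <- 1e-7
    xp <- x; xp[k] <- xp[k] + e
    xm <- x; xm[k] <- xm[k] - e
    num <- (total_variation_loss(xp) - total_variation_loss(xm)) / (2 * e)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("perceptual loss is a frozen-feature l2 distance", {
  ext <- build_feature_extractor(2, seed = 42)
  set.seed(9)
  a <- array(runif(16 * 16 * 2), c(16, 16, 2))
  expect_equal(perceptual_loss(a, a, ext), 0)
  b <- a
  b[6:9, 6:9, 1] <- b[6:9, 6:9, 1] + 0.5  # localized blob
  expect_gt(perceptual_loss(a, b, ext), 0)
  expect_equal(perceptual_loss(a, b, ext), perceptual_loss(b, a, ext),
               tolerance = 1e-12)
  expect_error(perceptual_loss(a, b, NULL), "extractor")
  # same seed rebuilds identical frozen weights
  ext2 <- build_feature_extractor(2, seed = 42)
  expect_identical(ext[[1]]$W, ext2[[1]]$W)
})

test_that("the composite loss decomposes as the weighted term sum", {
  set.seed(10)
  pred <- array(runif(16 * 16 * 2), c(16, 16, 2))
  target <- array(runif(16 * 16 * 2), c(16, 16, 2))
  ext <- build_feature_extractor(2, seed = 1)
  w0 <- loss_weights(1, 0, 0, 0)
  expect_equal(composite_loss(pred, pred, NULL, w0, NULL)$total, 0)
  expect_equal(composite_loss(target + 0.5, target, NULL, w0, NULL)$total,
               0.5, tolerance = 1e-12)
  logits <- array(rnorm(16), c(4, 4, 1))
  w <- loss_weights(100, 1, 0.1, 1)
  cl <- composite_loss(pred, target, logits, w, ext)
  recombined <- 100 * cl$l1 + 1 * cl$adv + 0.1 * cl$tv + 1 * cl$perceptual
  expect_lt(abs(cl$total - recombined), 1e-9)
  expect_error(loss_weights(0, 0, 0, 0), "at least one")
  expect_error(loss_weights(-1, 0, 0, 1), ">= 0")
})

test_that("generator and discriminator honor their shape contracts", {
  cfg <- gan_config(n_input = 9, base_width = 8, depth = 2, seed = 3)
  G <- build_generator(cfg)
  x <- array(rnorm(64 * 64 * 9), c(64, 64, 9))
  out <- ganst:::gen_forward(G, x)$out$a
  expect_equal(dim(out), c(64, 64, 2))
  expect_true(all(out > 0 & out < 1))  # sigmoid-bounded
  D <- build_discriminator(cfg)
  logits <- ganst:::disc_forward(D, array(rnorm(64 * 64 * 11),
                                          c(64, 64, 11)))$logits
  # three stride-2 stages: 64 / 2^3 = 8 patch grid
  expect_equal(dim(logits), c(8, 8, 1))
  expect_error(gan_config(n_input = 0), "n_input")
  expect_error(gan_config(lr_generator = 0), "learning rates")
})

test_that("training rejects invalid inputs", {
  pairs <- toy_gan_pairs(n_pairs = 2, size = 10)
  cfg <- gan_config(n_input = 3, base_width = 4, depth = 2, epochs = 1,
                    seed = 1)
  expect_error(train_gan(pairs, cfg), "divisible")
  expect_error(train_gan(toy_gan_pairs(0), cfg), "empty|replacement")
  cfg9 <- gan_config(n_input = 9, base_width = 4, epochs = 1)
  expect_error(train_gan(toy_gan_pairs(2, size = 16, n_input = 3), cfg9),
               "channels")
})

test_that("training is seed-reproducible and learns a toy mapping", {
  pairs <- toy_gan_pairs(n_pairs = 6, size = 16, n_input = 3)
  cfg <- gan_config(n_input = 3, base_width = 6, depth = 2, epochs = 6,
                    patience = 6, seed = 11, batch_size = 2,
                    lr_generator = 2e-3, lr_discriminator = 5e-4)
  g1 <- train_gan(pairs, cfg, loss_weights(100, 1, 0.1, 1))
  g2 <- train_gan(pairs, cfg, loss_weights(100, 1, 0.1, 1))
  expect_identical(g1$log, g2$log)
  expect_true(all(diff(g1$log$l1[c(1, nrow(g1$log))]) < 0))
})

test_that("zero adversarial weight degenerates to supervised regression", {
  pairs <- toy_gan_pairs(n_pairs = 4, size = 16, n_input = 3)
  cfg <- gan_config(n_input = 3, base_width = 6, depth = 2, epochs = 3,
                    patience = 3, seed = 2, batch_size = 2)
  gan <- train_gan(pairs, cfg, loss_weights(1, 0, 0, 0))
  # the discriminator is never updated
  D0 <- build_discriminator(cfg, 2)
  expect_identical(gan$discriminator[[1]]$W, D0[[1]]$W)
  expect_true(all(gan$log$adv == 0) && all(gan$log$d_loss == 0))
})

test_that("pure-L1 training approaches the least-absolute-error fit", {
  # constant-image toy problem: targets are an affine function of the
  # constant input plus asymmetric noise, so the optimal constant-slope
  # predictor is the least-absolute-deviation fit, found by direct search
  set.seed(21)
  n <- 12
  a <- runif(n, 0.2, 0.8)
  tvals <- pmin(pmax(0.15 + 0.6 * a + sample(c(-0.05, 0, 0.05), n, TRUE),
                     0), 1)
  pairs <- lapply(seq_len(n), function(i) {
    list(input = array(a[i], c(16, 16, 1)),
         target = array(tvals[i], c(16, 16, 2)))
  })
  pairs <- structure(pairs, target_names = c("volume_fraction",
                                             "exchange_rate"),
                     output_scaling = list(volume_fraction = c(0, 1),
                                           exchange_rate = c(0, 1)),
                     class = "gan_pairs")
  lad <- function(par) sum(abs(tvals - (par[1] + par[2] * a)))
  opt <- optim(c(0, 0.5), lad)
  cfg <- gan_config(n_input = 1, base_width = 4, depth = 2, epochs = 200,
                    patience = 200, seed = 3, batch_size = 4,
                    lr_generator = 5e-3)
  gan <- train_gan(pairs, cfg, loss_weights(1, 0, 0, 0))
  final_l1 <- tail(gan$log$l1, 1)
  # approaches the direct LAD optimum (per-pixel mean absolute residual)
  expect_lt(final_l1, max(1.5 * opt$value / n, 0.02))
})

test_that("stack normalization divides by the first image and clips", {
  set.seed(12)
  img <- array(runif(8 * 8 * 4, 0.5, 1), c(8, 8, 4))
  img[, , 3] <- img[, , 1] * 3   # will clip at 2
  norm <- normalize_stack(img)
  expect_equal(norm[, , 1], matrix(1, 8, 8))
  expect_equal(norm[, , 2], img[, , 2] / img[, , 1], tolerance = 1e-12)
  expect_true(all(norm[, , 3] == 2))
  img[3, 3, 1] <- 0   # dead normalization voxel
  norm2 <- normalize_stack(img)
  expect_equal(norm2[3, 3, ], rep(0, 4))
})

test_that("retargeting swaps targets to scaled aux maps", {
  sc <- make_larg_scene(vial_layout_ring(3, radius = 6),
                        c(25, 50, 100), c(4.2, 5.1, 5.9))
  d <- c(64, 64)
  pairs <- structure(list(list(
    input = array(0, c(d, 3)),
    target = array(0, c(d, 2)), mask = sc$region_labels > 0)),
    target_names = c("volume_fraction", "exchange_rate"),
    output_scaling = list(volume_fraction = c(0, 1),
                          exchange_rate = c(0, 1)), class = "gan_pairs")
  rt <- retarget_to_direct_quantities(pairs, list(sc),
                                      scaling = list(concentration =
                                                       c(0, 120),
                                                     ph = c(3, 7)))
  expect_identical(attr(rt, "target_names"), c("concentration", "ph"))
  tgt <- rt[[1]]$target
  v2 <- sc$region_labels == 2
  expect_true(all(tgt[, , 1][v2] == 50 / 120))
  expect_true(all(tgt[, , 2][v2] == (5.1 - 3) / 4))
  # piecewise constant inside each vial
  for (v in 1:3) expect_equal(sd(tgt[, , 2][sc$region_labels == v]), 0)
  sc2 <- sc; sc2$aux <- NULL
  expect_error(retarget_to_direct_quantities(pairs, list(sc2)), "aux")
})
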