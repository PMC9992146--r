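#' Loss weights of the composite GAN objective
#'
#' The generator is trained on the weighted sum
#' L_total = lambda1 L1 + lambda2 L_adv + lambda3 L_tv + lambda4 L_p:
#' pixelwise l1 content loss, adversarial loss, total-variation loss, and
#' perceptual (feature-space l2) loss. Defaults follow the pix2pix
#' tradition of a dominant content term, tuned once on a synthetic
#' validation split.
#'
#' @param lambda1,lambda2,lambda3,lambda4 non-negative weights; at least one
#'   must be positive
#' @return a `loss_weights` object
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 1, lambda3 = 0.1,
                         lambda4 = 1) {
  l <- c(lambda1, lambda2, lambda3, lambda4)
  if (any(l < 0) || all(l == 0))
    stopf("loss weights must be >= 0 with at least one > 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4), class = "loss_weights")
}

#' Conditional-GAN configuration
#'
#' @param n_input number of raw input images N (channels of the generator
#'   input)
#' @param base_width channels of the first U-Net encoder level; deeper
#'   levels double it
#' @param depth number of stride-2 encoder levels (>= 2), so image dims
#'   must be divisible by `2^depth`
#' @param disc_width channels of the first discriminator level
#' @param lr_generator,lr_discriminator Adam learning rates
#' @param batch_size minibatch size
#' @param epochs maximum training epochs (early stopping may end sooner)
#' @param patience early-stopping patience, epochs
#' @param val_fraction fraction of pairs held out for validation
#' @param seed integer seed (weights, shuffling)
#' @param feature_extractor `"fixed_random_conv"` (default: a frozen
#'   random-weight convolutional stack, no external weights needed) or
#'   `"none"`; externally supplied VGG-style weights can be plugged in by
#'   passing a prebuilt extractor to [train_gan()]
#' @param extractor_seed seed of the frozen random extractor
#' @param output_scaling named list of `c(min, max)` per target channel;
#'   generator outputs live in [0, 1] via a sigmoid and are mapped to these
#'   ranges at inference
#' @return a `gan_config`
#' @export
gan_config <- function(n_input = 9, base_width = 16, depth = 2,
                       disc_width = 16, lr_generator = 1e-4,
                       lr_discriminator = 5e-4, batch_size = 4,
                       epochs = 400, patience = 10, val_fraction = 0.15,
                       seed = 1, feature_extractor = "fixed_random_conv",
                       extractor_seed = 42,
                       output_scaling = list(volume_fraction = c(0, 0.01),
                                             exchange_rate = c(0, 1500))) {
  if (n_input < 1) stopf("n_input must be >= 1")
  if (lr_generator <= 0 || lr_discriminator <= 0)
    stopf("learning rates must be > 0")
  if (depth < 2) stopf("depth must be >= 2")
  feature_extractor <- match.arg(feature_extractor,
                                 c("fixed_random_conv", "none"))
  structure(list(n_input = n_input, base_width = base_width, depth = depth,
                 disc_width = disc_width, lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 batch_size = batch_size, epochs = epochs,
                 patience = patience, val_fraction = val_fraction,
                 seed = seed, feature_extractor = feature_extractor,
                 extractor_seed = extractor_seed,
                 output_scaling = output_scaling),
            class = "gan_config")
}

#' Total-variation loss
#'
#' Anisotropic total variation: for each channel the mean absolute first
#' difference along both spatial axes, summed over channels.
#'
#' @param maps numeric matrix (H x W) or array (H x W x C)
#' @return non-negative scalar
#' @export
total_variation_loss <- function(maps) {
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1))
  d <- dim(maps)
  if (d[1] < 2 || d[2] < 2) stopf("spatial dims must be >= 2")
  tv <- 0
  for (c in seq_len(d[3])) {
    m <- maps[, , c]
    tv <- tv + mean(abs(m[-1, ] - m[-d[1], ])) +
      mean(abs(m[, -1] - m[, -d[2]]))
  }
  tv
}

tv_grad <- function(maps) {
  d <- dim(maps)
  g <- array(0, d)
  for (c in seq_len(d[3])) {
    m <- maps[, , c]
    sh <- sign(m[-1, ] - m[-d[1], ])
    nh <- length(sh)
    g[-1, , c] <- g[-1, , c] + sh / nh
    g[-d[1], , c] <- g[-d[1], , c] - sh / nh
    sv <- sign(m[, -1] - m[, -d[2]])
    nv <- length(sv)
    g[, -1, c] <- g[, -1, c] + sv / nv
    g[, -d[2], c] <- g[, -d[2], c] - sv / nv
  }
  g
}

#' Frozen feature extractor for the perceptual loss
#'
#' A fixed-seed, frozen random-weight convolutional stack (the default
#' pluggable stand-in for a pretrained deep feature network; externally
#' supplied pretrained kernels can be passed in the same structure).
#'
#' @param in_ch input channels (2 for the map pairs)
#' @param width feature channels
#' @param seed seed of the frozen weights
#' @return extractor object (list of conv layers) of class `feature_extractor`
#' @export
build_feature_extractor <- function(in_ch = 2, width = 8, seed = 42) {
  with_seed(seed, {
    structure(list(conv_layer(in_ch, width, act = "relu"),
                   conv_layer(width, width, stride = 2, act = "relu")),
              class = "feature_extractor")
  })
}

extractor_fw <- function(ext, x) {
  caches <- vector("list", length(ext))
  a <- x
  for (i in seq_along(ext)) {
    caches[[i]] <- conv_fw(a, ext[[i]])
    a <- caches[[i]]$a
  }
  list(features = a, caches = caches)
}

extractor_input_grad <- function(ext, caches, dfeat) {
  d <- dfeat
  for (i in rev(seq_along(ext))) {
    g <- conv_bw(caches[[i]], ext[[i]], d, need_dx = TRUE)
    d <- g$dx
  }
  d
}

#' Perceptual loss
#'
#' Mean squared difference between the frozen extractor's feature maps of
#' prediction and target; zero iff the features agree.
#'
#' @param pred,target numeric arrays (H x W x C) matching the extractor's
#'   input channels
#' @param extractor a `feature_extractor` (see [build_feature_extractor()])
#' @return non-negative scalar
#' @export
perceptual_loss <- function(pred, target, extractor) {
  if (is.null(extractor)) stopf("no feature extractor configured")
  fp <- extractor_fw(extractor, pred)$features
  ft <- extractor_fw(extractor, target)$features
  mean((fp - ft)^2)
}

bce_logits <- function(z, label) {
  # numerically stable softplus
  mean(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - label * z)
}

bce_logits_grad <- function(z, label) {
  (1 / (1 + exp(-z)) - label) / length(z)
}

#' Composite GAN training loss with per-term breakdown
#'
#' L_total = lambda1 L1 + lambda2 L_adv + lambda3 L_tv + lambda4 L_p, where
#' L1 is the mean absolute error, L_adv the binary cross-entropy of the
#' discriminator's logits on the generated pair against the "real" label,
#' L_tv the anisotropic total variation of the prediction, and L_p the
#' perceptual loss.
#'
#' @param pred,target maps (H x W x C)
#' @param disc_output discriminator logit map on the generated pair, or
#'   `NULL` (adversarial term 0)
#' @param weights a `loss_weights`
#' @param extractor a `feature_extractor` or `NULL` (perceptual term 0)
#' @return list with `total` and the unweighted terms `l1`, `adv`, `tv`,
#'   `perceptual`
#' @export
composite_loss <- function(pred, target, disc_output = NULL,
                           weights = loss_weights(), extractor = NULL) {
  l1 <- mean(abs(pred - target))
  adv <- if (is.null(disc_output) || weights$lambda2 == 0) 0
  else bce_logits(disc_output, 1)
  tv <- if (weights$lambda3 == 0) 0 else total_variation_loss(pred)
  lp <- if (is.null(extractor) || weights$lambda4 == 0) 0
  else perceptual_loss(pred, target, extractor)
  list(total = weights$lambda1 * l1 + weights$lambda2 * adv +
         weights$lambda3 * tv + weights$lambda4 * lp,
       l1 = l1, adv = adv, tv = tv, perceptual = lp)
}

#' Build the U-Net generator / patch discriminator
#'
#' The generator is a U-Net in the pix2pix tradition: `depth` stride-2
#' encoder convolutions, a bottleneck convolution, and nearest-upsampling
#' decoder stages with skip concatenation from the matching encoder level
#' (the final stage returns to full resolution without a skip), ending in a
#' sigmoid so the output channels live in [0, 1] (mapped to parameter
#' ranges at inference). The discriminator is a conditional patch
#' discriminator on the concatenated (input stack, candidate maps) and
#' returns a logit map over patches.
#'
#' @param config a `gan_config`
#' @param n_targets output channels (2: volume fraction and exchange rate)
#' @return generator / discriminator objects
#' @export
build_generator <- function(config, n_targets = 2) {
  w <- config$base_width
  depth <- config$depth
  with_seed(config$seed, {
    enc <- vector("list", depth)
    for (d in seq_len(depth)) {
      in_ch <- if (d == 1) config$n_input else w * 2^(d - 2)
      enc[[d]] <- conv_layer(in_ch, w * 2^(d - 1), stride = 2, act = "relu")
    }
    mid <- conv_layer(w * 2^(depth - 1), w * 2^(depth - 1), act = "relu")
    dec <- vector("list", depth)
    for (j in seq_len(depth)) {
      ch_up <- if (j == 1) w * 2^(depth - 1) else w * 2^(depth - j)
      # skip: matching encoder level, or the raw input at full resolution
      ch_skip <- if (j < depth) w * 2^(depth - j - 1) else config$n_input
      ch_out <- if (j < depth) ch_skip else w
      dec[[j]] <- conv_layer(ch_up + ch_skip, ch_out, act = "relu")
    }
    out <- conv_layer(w, n_targets, act = "sigmoid")
    structure(list(enc = enc, mid = mid, dec = dec, out = out,
                   depth = depth, n_input = config$n_input,
                   n_targets = n_targets), class = "ganst_generator")
  })
}

#' @rdname build_generator
#' @export
build_discriminator <- function(config, n_targets = 2) {
  w <- config$disc_width
  with_seed(config$seed + 1L, {
    layers <- list(
      conv_layer(config$n_input + n_targets, w, stride = 2, act = "lrelu"),
      conv_layer(w, 2 * w, stride = 2, act = "lrelu"),
      conv_layer(2 * w, 4 * w, stride = 2, act = "lrelu"),
      conv_layer(4 * w, 1, act = "linear"))
    structure(layers, class = "ganst_discriminator")
  })
}

gen_forward <- function(G, x) {
  depth <- G$depth
  caches <- list(enc = vector("list", depth),
                 dec = vector("list", depth))
  a <- x
  for (d in seq_len(depth)) {
    caches$enc[[d]] <- conv_fw(a, G$enc[[d]])
    a <- caches$enc[[d]]$a
  }
  caches$mid <- conv_fw(a, G$mid)
  cur <- caches$mid$a
  for (j in seq_len(depth)) {
    up <- upsample2(cur)
    caches$dec_up_ch[[j]] <- dim(cur)[3]
    inp <- if (j < depth) concat_ch(up, caches$enc[[depth - j]]$a)
    else concat_ch(up, x)  # full-resolution skip from the raw input
    caches$dec[[j]] <- conv_fw(inp, G$dec[[j]])
    cur <- caches$dec[[j]]$a
  }
  caches$out <- conv_fw(cur, G$out)
  caches
}

gen_backward <- function(G, caches, dout) {
  depth <- G$depth
  grads <- list(enc = vector("list", depth),
                dec = vector("list", depth))
  denc_a <- vector("list", depth)  # grads w.r.t. encoder activations

  g <- conv_bw(caches$out, G$out, dout)
  grads$out <- g
  dcur <- g$dx
  for (j in rev(seq_len(depth))) {
    g <- conv_bw(caches$dec[[j]], G$dec[[j]], dcur)
    grads$dec[[j]] <- g
    sp <- split_ch(g$dx, caches$dec_up_ch[[j]])
    if (j < depth) {
      e <- depth - j
      denc_a[[e]] <- if (is.null(denc_a[[e]])) sp$second
      else denc_a[[e]] + sp$second
    }
    dcur <- upsample2_bw(sp$first)
  }
  g <- conv_bw(caches$mid, G$mid, dcur)
  grads$mid <- g
  dd <- g$dx
  for (d in rev(seq_len(depth))) {
    if (!is.null(denc_a[[d]])) dd <- dd + denc_a[[d]]
    g <- conv_bw(caches$enc[[d]], G$enc[[d]], dd, need_dx = d > 1)
    grads$enc[[d]] <- g
    if (d > 1) dd <- g$dx
  }
  grads
}

disc_forward <- function(D, x) {
  caches <- vector("list", length(D))
  a <- x
  for (i in seq_along(D)) {
    caches[[i]] <- conv_fw(a, D[[i]])
    a <- caches[[i]]$a
  }
  list(logits = a, caches = caches)
}

disc_backward <- function(D, caches, dlogits, need_dx = FALSE) {
  grads <- vector("list", length(D))
  d <- dlogits
  for (i in rev(seq_along(D))) {
    g <- conv_bw(caches[[i]], D[[i]], d, need_dx = need_dx || i > 1)
    grads[[i]] <- g
    d <- g$dx
  }
  list(grads = grads, dx = d)
}

# flatten generator grads/layers into parallel lists for the Adam update
gen_layer_list <- function(G) c(G$enc, list(G$mid), G$dec, list(G$out))
gen_grad_list <- function(gr) c(gr$enc, list(gr$mid), gr$dec, list(gr$out))
gen_from_list <- function(G, ll) {
  depth <- G$depth
  G$enc <- ll[seq_len(depth)]
  G$mid <- ll[[depth + 1]]
  G$dec <- ll[depth + 1 + seq_len(depth)]
  G$out <- ll[[2 * depth + 2]]
  G
}

#' Normalize a raw image stack for network input
#'
#' Divides every image by the first schedule entry's image (the
#' normalization image) and clips to [0, 2]; voxels where the normalization
#' image is (near) zero are set to 0.
#'
#' @param images H x W x M array
#' @return normalized array of the same shape
#' @export
normalize_stack <- function(images) {
  ref <- images[, , 1]
  thr <- 1e-6 * max(abs(ref))
  safe <- abs(ref) > thr
  out <- array(0, dim(images))
  for (i in seq_len(dim(images)[3])) {
    sl <- images[, , i]
    v <- sl[safe] / ref[safe]
    o <- array(0, dim(sl))
    o[safe] <- pmin(pmax(v, 0), 2)
    out[, , i] <- o
  }
  out
}

#' Assemble GAN training pairs from scenes
#'
#' For each scene/stack pair: the input is the entry-normalized raw stack
#' truncated to the first `n_input` images; the target is the reference
#' quantifier's (volume fraction, exchange rate) maps min-max-scaled to
#' [0, 1]; the mask marks in-object voxels.
#'
#' @param scenes list of `phantom_scene`
#' @param stacks parallel list of full-length `raw_stack`
#' @param fcn trained `ganst_fcn` reference quantifier
#' @param n_input number of input images N to keep
#' @param output_scaling named list of `c(min, max)` per target channel
#' @return list of training pairs (class `gan_pairs`), each
#'   `list(input, target, mask)`, with the scaling attached as attributes
#' @export
make_training_pairs <- function(scenes, stacks, fcn, n_input,
                                output_scaling =
                                  list(volume_fraction = c(0, 0.01),
                                       exchange_rate = c(0, 1500))) {
  stopifnot(length(scenes) == length(stacks))
  targets <- names(output_scaling)
  pairs <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    st <- stacks[[i]]
    q <- quantify_stack(fcn, st)
    d <- dim(st$images)
    tgt <- array(0, c(d[1], d[2], length(targets)))
    for (j in seq_along(targets)) {
      tgt[, , j] <- pmin(pmax(scale01(q[[targets[j]]],
                                      output_scaling[[targets[j]]]), 0), 1)
    }
    inp <- normalize_stack(st$images)[, , seq_len(n_input), drop = FALSE]
    pairs[[i]] <- list(input = inp, target = tgt,
                       mask = scenes[[i]]$region_labels > 0)
  }
  # per-channel standardization over the whole set: the informative
  # modulation of the normalized signals is small against their mean, so
  # centering/scaling conditions the generator's optimization
  ctr <- numeric(n_input); scl <- numeric(n_input)
  for (ch in seq_len(n_input)) {
    v <- unlist(lapply(pairs, function(p) as.vector(p$input[, , ch])))
    ctr[ch] <- mean(v)
    scl[ch] <- max(sd(v), 1e-8)
  }
  for (i in seq_along(pairs)) {
    for (ch in seq_len(n_input)) {
      pairs[[i]]$input[, , ch] <-
        (pairs[[i]]$input[, , ch] - ctr[ch]) / scl[ch]
    }
  }
  structure(pairs, target_names = targets, output_scaling = output_scaling,
            input_center = ctr, input_scale = scl, class = "gan_pairs")
}

#' Retarget training pairs to direct physical quantities
#'
#' Swaps the target channels from quantifier-derived (volume fraction,
#' exchange rate) to the scenes' gold-standard (concentration, pH) maps -
#' piecewise constant inside each vial - with their own scaling ranges. The
#' training path is unchanged.
#'
#' @param pairs a `gan_pairs` list
#' @param scenes parallel list of `phantom_scene` carrying aux maps
#' @param scaling named list of `c(min, max)` for `concentration` (mM) and
#'   `ph`
#' @return retargeted `gan_pairs`
#' @export
retarget_to_direct_quantities <- function(pairs, scenes,
                                          scaling =
                                            list(concentration = c(0, 120),
                                                 ph = c(3, 7))) {
  stopifnot(length(pairs) == length(scenes))
  targets <- names(scaling)
  for (i in seq_along(pairs)) {
    aux <- scenes[[i]]$aux
    if (is.null(aux) || !all(targets %in% names(aux)))
      stopf("scene %d lacks aux map(s): %s", i,
            paste(setdiff(targets, names(aux)), collapse = ", "))
    d <- dim(pairs[[i]]$input)
    tgt <- array(0, c(d[1], d[2], length(targets)))
    for (j in seq_along(targets)) {
      tgt[, , j] <- pmin(pmax(scale01(aux[[targets[j]]],
                                      scaling[[targets[j]]]), 0), 1)
    }
    pairs[[i]]$target <- tgt
  }
  structure(pairs, target_names = targets, output_scaling = scaling,
            class = "gan_pairs")
}

val_content_loss <- function(G, pairs, idx, weights, extractor) {
  if (!length(idx)) return(NA_real_)
  tot <- 0
  for (i in idx) {
    pred <- gen_forward(G, pairs[[i]]$input)$out$a
    cl <- composite_loss(pred, pairs[[i]]$target, NULL, weights, extractor)
    tot <- tot + cl$total
  }
  tot / length(idx)
}

#' Train the conditional GAN
#'
#' Alternating discriminator/generator Adam updates with the configured
#' learning rates and batch size. The generator minimizes the composite
#' loss (see [composite_loss()]); the discriminator minimizes binary
#' cross-entropy on real/fake conditional pairs. Early stopping monitors
#' the non-adversarial content loss (l1 + TV + perceptual at their
#' weights) on the validation split and restores the best generator.
#' Fully seeded and single-threaded: identical seeds reproduce the logged
#' loss sequence.
#'
#' @param pairs a `gan_pairs` list (>= 2 pairs so a validation split
#'   exists)
#' @param config a `gan_config`
#' @param weights a `loss_weights`
#' @param extractor optionally a prebuilt `feature_extractor` (e.g. with
#'   externally supplied pretrained kernels); by default one is built
#'   according to `config`
#' @return a `ganst_gan` model: generator, discriminator, config, training
#'   log (per-epoch loss terms), and the best-validation epoch
#' @export
train_gan <- function(pairs, config, weights = loss_weights(),
                      extractor = NULL) {
  stopifnot(inherits(config, "gan_config"), inherits(weights, "loss_weights"))
  n <- length(pairs)
  if (n < 1) stopf("empty training set")
  d <- dim(pairs[[1]]$input)
  if (d[3] != config$n_input)
    stopf("pairs carry %d input channels, config expects N = %d", d[3],
          config$n_input)
  div <- 2^config$depth
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stopf("image dims must be divisible by %d for depth %d", div,
          config$depth)
  n_targets <- dim(pairs[[1]]$target)[3]
  G <- build_generator(config, n_targets)
  D <- build_discriminator(config, n_targets)
  if (is.null(extractor) && config$feature_extractor == "fixed_random_conv")
    extractor <- build_feature_extractor(n_targets,
                                         seed = config$extractor_seed)
  gst <- conv_adam_state(gen_layer_list(G))
  dst <- conv_adam_state(D)

  with_seed(config$seed + 2L, {
    n_val <- if (n >= 4) max(1L, round(config$val_fraction * n)) else 0L
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    if (!length(tr_idx)) { tr_idx <- val_idx; val_idx <- integer(0) }

    log <- data.frame()
    best_val <- Inf; best_G <- G; best_epoch <- 0L; bad <- 0L
    use_adv <- weights$lambda2 > 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_terms <- c(d_loss = 0, adv = 0, l1 = 0, tv = 0, perceptual = 0,
                    total = 0)
      n_batches <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        nb <- length(bidx)
        # one generator forward per pair, shared by both updates (the
        # discriminator sees the fake detached; the generator step reuses
        # the cached activations after the discriminator update)
        gcaches <- lapply(bidx, function(i)
          gen_forward(G, pairs[[i]]$input))
        # --- discriminator step
        if (use_adv) {
          dacc <- zero_like_grads(D)
          dl <- 0
          for (k in seq_len(nb)) {
            i <- bidx[k]
            x <- pairs[[i]]$input; y <- pairs[[i]]$target
            fake <- gcaches[[k]]$out$a
            fr <- disc_forward(D, concat_ch(x, y))
            dl <- dl + bce_logits(fr$logits, 1)
            bw <- disc_backward(D, fr$caches,
                                bce_logits_grad(fr$logits, 1))
            dacc <- add_grads(dacc, bw$grads, 0.5 / nb)
            ff <- disc_forward(D, concat_ch(x, fake))
            dl <- dl + bce_logits(ff$logits, 0)
            bw <- disc_backward(D, ff$caches,
                                bce_logits_grad(ff$logits, 0))
            dacc <- add_grads(dacc, bw$grads, 0.5 / nb)
          }
          up <- conv_adam_update(D, dacc, dst, config$lr_discriminator)
          D <- up$net; dst <- up$st
          ep_terms["d_loss"] <- ep_terms["d_loss"] + dl / (2 * nb)
        }
        # --- generator step
        gacc <- zero_like_grads(gen_layer_list(G))
        for (k in seq_len(nb)) {
          i <- bidx[k]
          x <- pairs[[i]]$input; y <- pairs[[i]]$target
          caches <- gcaches[[k]]
          pred <- caches$out$a
          npx <- length(pred)
          dout <- weights$lambda1 * sign(pred - y) / npx
          l1 <- mean(abs(pred - y))
          tvv <- 0; lpv <- 0; advv <- 0
          if (weights$lambda3 > 0) {
            tvv <- total_variation_loss(pred)
            dout <- dout + weights$lambda3 * tv_grad(pred)
          }
          if (weights$lambda4 > 0 && !is.null(extractor)) {
            fp <- extractor_fw(extractor, pred)
            ft <- extractor_fw(extractor, y)
            diff <- fp$features - ft$features
            lpv <- mean(diff^2)
            dfeat <- 2 * diff / length(diff)
            dout <- dout + weights$lambda4 *
              extractor_input_grad(extractor, fp$caches, dfeat)
          }
          if (use_adv) {
            ff <- disc_forward(D, concat_ch(x, pred))
            advv <- bce_logits(ff$logits, 1)
            bw <- disc_backward(D, ff$caches,
                                bce_logits_grad(ff$logits, 1),
                                need_dx = TRUE)
            dout <- dout + weights$lambda2 *
              split_ch(bw$dx, config$n_input)$second
          }
          gr <- gen_backward(G, caches, dout)
          gacc <- add_grads(gacc, gen_grad_list(gr), 1 / nb)
          ep_terms["l1"] <- ep_terms["l1"] + l1 / nb
          ep_terms["tv"] <- ep_terms["tv"] + tvv / nb
          ep_terms["perceptual"] <- ep_terms["perceptual"] + lpv / nb
          ep_terms["adv"] <- ep_terms["adv"] + advv / nb
          ep_terms["total"] <- ep_terms["total"] +
            (weights$lambda1 * l1 + weights$lambda2 * advv +
               weights$lambda3 * tvv + weights$lambda4 * lpv) / nb
        }
        up <- conv_adam_update(gen_layer_list(G), gacc, gst,
                               config$lr_generator)
        G <- gen_from_list(G, up$net)
        gst <- up$st
        n_batches <- n_batches + 1
      }
      ep_terms <- ep_terms / n_batches
      vl <- val_content_loss(G, pairs, val_idx, weights, extractor)
      log <- rbind(log, data.frame(epoch = ep, t(ep_terms), val_loss = vl))
      monitor <- if (is.na(vl)) ep_terms["total"] else vl
      if (monitor < best_val - 1e-12) {
        best_val <- monitor; best_G <- G; best_epoch <- ep; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
    structure(list(generator = best_G, discriminator = D,
                   extractor = extractor, config = config,
                   weights = weights, log = log, best_epoch = best_epoch,
                   target_names = attr(pairs, "target_names"),
                   output_scaling = attr(pairs, "output_scaling"),
                   input_center = attr(pairs, "input_center"),
                   input_scale = attr(pairs, "input_scale")),
              class = "ganst_gan")
  })
}

#' @export
print.ganst_gan <- function(x, ...) {
  cat(sprintf("Conditional GAN reconstructor: N = %d inputs -> %d maps\n",
              x$config$n_input, x$generator$n_targets))
  cat(sprintf("  trained %d epochs (best validation at epoch %d)\n",
              nrow(x$log), x$best_epoch))
  if (!is.null(x$target_names))
    cat("  targets:", paste(x$target_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ganst_gan <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$total, type = "l", xlab = "epoch",
                 ylab = "generator loss", ...)
  if (!all(is.na(x$log$val_loss)))
    graphics::lines(x$log$epoch, x$log$val_loss, lty = 2)
  invisible(x)
}

#' Reconstruct parameter maps from a raw stack
#'
#' Slice-wise generator inference: each slice's raw stack is
#' entry-normalized, truncated to the first N images, pushed through the
#' generator, and the [0, 1] outputs are mapped back to parameter units.
#'
#' @param gan a trained `ganst_gan`
#' @param stacks one `raw_stack` or a list of them (slices of a volume)
#' @return named list of parameter maps (H x W or H x W x slices arrays) in
#'   native units
#' @export
reconstruct_volume <- function(gan, stacks) {
  stopifnot(inherits(gan, "ganst_gan"))
  single <- inherits(stacks, "raw_stack")
  if (single) stacks <- list(stacks)
  n <- gan$config$n_input
  out_maps <- NULL
  for (s in seq_along(stacks)) {
    img <- stacks[[s]]$images
    if (dim(img)[3] < n)
      stopf("stack has %d images, generator needs N = %d", dim(img)[3], n)
    x <- normalize_stack(img)[, , seq_len(n), drop = FALSE]
    if (!is.null(gan$input_center)) {
      for (ch in seq_len(n)) {
        x[, , ch] <- (x[, , ch] - gan$input_center[ch]) /
          gan$input_scale[ch]
      }
    }
    pred <- gen_forward(gan$generator, x)$out$a
    if (is.null(out_maps))
      out_maps <- array(0, c(dim(pred)[1], dim(pred)[2], length(stacks),
                             dim(pred)[3]))
    out_maps[, , s, ] <- pred
  }
  res <- lapply(seq_along(gan$target_names), function(j) {
    m <- out_maps[, , , j]
    if (single) m <- array(m, dim(out_maps)[1:2])
    unscale01(m, gan$output_scaling[[gan$target_names[j]]])
  })
  names(res) <- gan$target_names
  res
}

#' Predict maps for one normalized input slice
#'
#' @param object a `ganst_gan`
#' @param input H x W x N normalized input array
#' @param ... unused
#' @return named list of parameter maps in native units
#' @export
predict.ganst_gan <- function(object, input, ...) {
  pred <- gen_forward(object$generator, input)$out$a
  res <- lapply(seq_along(object$target_names), function(j)
    unscale01(pred[, , j], object$output_scaling[[object$target_names[j]]]))
  names(res) <- object$target_names
  res
}
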