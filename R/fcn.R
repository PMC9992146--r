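#' Configuration of the reference fully connected quantifier
#'
#' The reference quantifier is a pixelwise fully connected network trained
#' on a simulated dictionary: it consumes the full M-length unit-normalized
#' trajectory (plus, in brain mode, the voxel's T1, T2 and B0 as three
#' additional scalars) and emits min-max-scaled volume fraction and exchange
#' rate.
#'
#' @param input_length M (trajectory length, before auxiliary scalars)
#' @param hidden integer vector of hidden-layer widths
#' @param output_scaling named list of `c(min, max)` per output parameter,
#'   defining the [0, 1] training scale; strictly positive width
#' @param aux_inputs use auxiliary (T1, T2, B0) inputs (brain mode)?
#' @param aux_scaling named list of `c(min, max)` for `t1`, `t2`, `b0` when
#'   `aux_inputs` is TRUE
#' @param epochs,batch_size,lr Adam training hyperparameters
#' @param noise_sigma white-noise augmentation sigma added to the network
#'   inputs each epoch
#' @param seed integer seed (weights, shuffling, noise)
#' @return an `fcn_config`
#' @export
fcn_config <- function(input_length,
                       hidden = c(300, 300),
                       output_scaling = list(volume_fraction = c(0, 0.01),
                                             exchange_rate = c(0, 1500)),
                       aux_inputs = FALSE,
                       aux_scaling = list(t1 = c(0.2, 4), t2 = c(0.01, 3),
                                          b0 = c(-1, 1)),
                       epochs = 400, batch_size = 256, lr = 1e-3,
                       noise_sigma = 1e-4, seed = 1) {
  for (nm in names(output_scaling)) {
    rg <- output_scaling[[nm]]
    if (length(rg) != 2 || diff(rg) <= 0)
      stopf("output_scaling$%s must be c(min, max) with max > min", nm)
  }
  structure(list(input_length = input_length, hidden = hidden,
                 output_scaling = output_scaling, aux_inputs = aux_inputs,
                 aux_scaling = aux_scaling, epochs = epochs,
                 batch_size = batch_size, lr = lr,
                 noise_sigma = noise_sigma, seed = seed),
            class = "fcn_config")
}

scale01 <- function(x, rg) (x - rg[1]) / (rg[2] - rg[1])
unscale01 <- function(x, rg) rg[1] + x * (rg[2] - rg[1])

fcn_training_inputs <- function(dict, config) {
  X <- dict$trajectories
  if (config$aux_inputs) {
    pts <- dict$points
    t1 <- if (!is.null(pts$t1_water)) pts$t1_water else
      rep(dict$base_tissue$water$t1, nrow(X))
    t2 <- if (!is.null(pts$t2_water)) pts$t2_water else
      rep(dict$base_tissue$water$t2, nrow(X))
    b0 <- if (!is.null(pts$b0_shift)) pts$b0_shift else
      rep(dict$base_tissue$b0_shift, nrow(X))
    X <- cbind(X, scale01(t1, config$aux_scaling$t1),
               scale01(t2, config$aux_scaling$t2),
               scale01(b0, config$aux_scaling$b0))
  }
  X
}

#' Train the reference fully connected quantifier
#'
#' Trains a dense rectifier network on the dictionary rows (unit-normalized
#' trajectories to min-max-scaled parameters) with mean-squared-error loss,
#' Adam updates, and fresh white-noise input augmentation every epoch.
#' Fully seeded: identical seeds give identical models.
#'
#' @param dict an `mrf_dictionary`
#' @param config an `fcn_config`; its `input_length` must equal the
#'   dictionary's M
#' @return a `ganst_fcn` model (weights, config, provenance) with
#'   [predict.ganst_fcn()] and [quantify_stack()] methods
#' @export
train_reference_fcn <- function(dict, config) {
  stopifnot(inherits(dict, "mrf_dictionary"), inherits(config, "fcn_config"))
  if (config$input_length != dict$m)
    stopf("config input_length %d != dictionary M = %d", config$input_length,
          dict$m)
  targets <- names(config$output_scaling)
  missing <- setdiff(targets, names(dict$points))
  if (length(missing))
    stopf("dictionary grid lacks target parameter(s): %s",
          paste(missing, collapse = ", "))
  Xraw <- fcn_training_inputs(dict, config)
  Y <- sapply(targets, function(nm)
    scale01(dict$points[[nm]], config$output_scaling[[nm]]))
  Y <- matrix(Y, ncol = length(targets))

  # standardize features: trajectories vary by ~1e-3 around an O(0.2) mean,
  # so per-feature centering/scaling conditions the optimization
  ctr <- colMeans(Xraw)
  scl <- apply(Xraw, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  standardize <- function(X) sweep(sweep(X, 2, ctr), 2, scl, "/")

  sizes <- c(ncol(Xraw), config$hidden, ncol(Y))
  layers <- mlp_init(sizes, config$seed)
  st <- mlp_adam_state(layers)
  n <- nrow(Xraw)
  losses <- numeric(config$epochs)
  t_step <- 0
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      # noise augmentation acts on the raw (physical) trajectory scale
      Xep <- standardize(Xraw +
        matrix(rnorm(length(Xraw), 0, config$noise_sigma),
               nrow(Xraw), ncol(Xraw)))
      lr_ep <- config$lr *
        if (ep > 0.85 * config$epochs) 0.1
        else if (ep > 0.6 * config$epochs) 0.3 else 1
      ep_loss <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        acts <- mlp_forward(layers, Xep[idx, , drop = FALSE])
        out <- acts[[length(acts)]]
        err <- out - Y[idx, , drop = FALSE]
        ep_loss <- ep_loss + sum(err^2)
        acts$delta_out <- 2 * err
        grads <- mlp_backward(layers, acts)
        t_step <- t_step + 1
        up <- adam_update(layers, grads, st, lr_ep, t_step)
        layers <- up$params
        st <- up$state
      }
      losses[ep] <- ep_loss / (n * ncol(Y))
    }
  })
  structure(list(layers = layers, config = config, targets = targets,
                 input_center = ctr, input_scale = scl,
                 schedule_label = dict$schedule_label, m = dict$m,
                 training_loss = losses),
            class = "ganst_fcn")
}

#' @export
print.ganst_fcn <- function(x, ...) {
  cat(sprintf("Reference FCN quantifier: %d -> %s -> %d [%s]\n",
              x$config$input_length + if (x$config$aux_inputs) 3 else 0,
              paste(x$config$hidden, collapse = " -> "), length(x$targets),
              x$schedule_label))
  cat(sprintf("  final training MSE: %.3g\n", tail(x$training_loss, 1)))
  invisible(x)
}

#' Predict parameters from trajectories
#'
#' Trajectories are unit-normalized before inference, so predictions are
#' invariant to positive scaling of the raw signal. Outputs are clipped to
#' the configured scaling ranges.
#'
#' @param object a `ganst_fcn`
#' @param trajectories numeric matrix (voxels x M) or vector; raw or
#'   normalized
#' @param aux optional matrix (voxels x 3) of (t1 s, t2 s, b0 ppm) for brain
#'   mode
#' @param ... unused
#' @return matrix (voxels x targets) of parameter estimates in native units
#' @export
predict.ganst_fcn <- function(object, trajectories, aux = NULL, ...) {
  if (is.vector(trajectories)) trajectories <- matrix(trajectories, nrow = 1)
  if (ncol(trajectories) != object$m)
    stopf("trajectory length %d != model M = %d", ncol(trajectories),
          object$m)
  norms <- sqrt(rowSums(trajectories^2))
  norms[norms == 0] <- 1
  X <- trajectories / norms
  cfg <- object$config
  if (cfg$aux_inputs) {
    if (is.null(aux) || ncol(aux) != 3)
      stopf("brain mode requires aux = (t1, t2, b0) per voxel")
    X <- cbind(X, scale01(aux[, 1], cfg$aux_scaling$t1),
               scale01(aux[, 2], cfg$aux_scaling$t2),
               scale01(aux[, 3], cfg$aux_scaling$b0))
  }
  X <- sweep(sweep(X, 2, object$input_center), 2, object$input_scale, "/")
  out <- mlp_predict(object$layers, X)
  for (j in seq_along(object$targets)) {
    rg <- cfg$output_scaling[[object$targets[j]]]
    out[, j] <- unscale01(pmin(pmax(out[, j], 0), 1), rg)
  }
  colnames(out) <- object$targets
  out
}

#' Quantify a raw image stack voxelwise
#'
#' Runs the reference quantifier independently on every voxel trajectory of
#' a raw stack. Voxels with an (effectively) all-zero trajectory are
#' unmatchable: they are set to 0 and flagged invalid.
#'
#' @param model a `ganst_fcn`
#' @param stack a `raw_stack` whose M matches the model
#' @param aux_maps optional named list of matrices `t1`, `t2`, `b0` (brain
#'   mode)
#' @return list of parameter matrices (one per target, native units) plus a
#'   logical `valid` matrix
#' @export
quantify_stack <- function(model, stack, aux_maps = NULL) {
  stopifnot(inherits(model, "ganst_fcn"), inherits(stack, "raw_stack"))
  d <- dim(stack$images)
  if (d[3] != model$m)
    stopf("stack has %d images, model expects M = %d", d[3], model$m)
  flat <- matrix(stack$images, d[1] * d[2], d[3])
  norms <- sqrt(rowSums(flat^2))
  valid <- norms > 1e-12 * max(norms, 1e-300)
  aux <- NULL
  if (model$config$aux_inputs) {
    if (is.null(aux_maps)) stopf("brain mode requires aux_maps (t1, t2, b0)")
    aux <- cbind(as.vector(aux_maps$t1), as.vector(aux_maps$t2),
                 as.vector(aux_maps$b0))
  }
  est <- matrix(0, nrow(flat), length(model$targets))
  if (any(valid)) {
    est[valid, ] <- predict(model, flat[valid, , drop = FALSE],
                            aux = if (is.null(aux)) NULL
                            else aux[valid, , drop = FALSE])
  }
  out <- lapply(seq_along(model$targets), function(j)
    matrix(est[, j], d[1], d[2]))
  names(out) <- model$targets
  out$valid <- matrix(valid, d[1], d[2])
  out
}
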