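#' Base-catalyzed L-arginine exchange rate
#'
#' Proton exchange from the L-arginine guanidinium pool is dominated by
#' base-catalyzed exchange: the rate grows tenfold per pH unit. The
#' parameterization is anchored at pH 6, k_sw = k_0 + k_base * 10^(pH - 6).
#' The default constants are calibration constants of the synthetic phantom
#' world, chosen so that rates span roughly 30-1500 Hz over pH 4-6.
#'
#' @param ph pH value(s) in [0, 14]
#' @param k_base base-catalyzed rate at pH 6, Hz (> 0)
#' @param k_0 pH-independent floor rate, Hz (>= 0)
#' @return exchange rate(s) k_sw in Hz, monotone increasing in pH
#' @examples
#' larg_exchange_rate(c(4, 5, 6))   # tenfold per pH unit on the base term
#' @export
larg_exchange_rate <- function(ph, k_base = 400, k_0 = 25) {
  if (any(ph < 0 | ph > 14)) stopf("pH must be in [0, 14]")
  if (k_base <= 0 || k_0 < 0) stopf("k_base must be > 0 and k_0 >= 0")
  k_0 + k_base * 10^(ph - 6)
}

#' Proton volume fraction from solute concentration
#'
#' The exchangeable-proton volume fraction is referenced to the water proton
#' pool (2 x 55,500 mM): f_s = n_protons * concentration / 111000.
#'
#' @param concentration solute concentration, mM (>= 0)
#' @param n_protons exchangeable protons per molecule (default 3, the
#'   L-arginine guanidinium pool at 3 ppm)
#' @return dimensionless volume fraction f_s
#' @examples
#' fs_from_concentration(50)   # 50 mM L-arg: 150 / 111000
#' @export
fs_from_concentration <- function(concentration, n_protons = 3) {
  if (any(concentration < 0)) stopf("concentration must be >= 0")
  if (n_protons < 1) stopf("n_protons must be >= 1")
  n_protons * concentration / 111000
}

#' Default circular vial layout
#'
#' Places `n` equal-radius vials on a ring centered in the image.
#'
#' @param n number of vials
#' @param shape 2D grid dimensions
#' @param radius vial radius in voxels (default scaled to the grid)
#' @return data.frame with `cx`, `cy`, `r` (voxel units)
#' @export
vial_layout_ring <- function(n, shape = c(64, 64), radius = NULL) {
  if (is.null(radius)) radius <- round(min(shape) * 0.1)
  ang <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  ring <- min(shape) * 0.3
  data.frame(cx = shape[1] / 2 + ring * cos(ang),
             cy = shape[2] / 2 + ring * sin(ang),
             r = rep_len(radius, n))
}

default_larg_solute <- function() {
  pool_parameters(t1 = 1.0, t2 = 0.02, chemical_shift = 3,
                  exchange_rate = 0, volume_fraction = 0)
}

default_mt_solute <- function(lineshape = "lorentzian") {
  pool_parameters(t1 = 1.0, t2 = 1e-5, chemical_shift = 0,
                  exchange_rate = 0, volume_fraction = 0,
                  lineshape = lineshape)
}

new_phantom_scene <- function(shape, voxel_size, labels, truth, aux, solute,
                              mode, label) {
  structure(list(shape = shape, voxel_size = voxel_size,
                 region_labels = labels, truth = truth, aux = aux,
                 solute_template = solute, mode = mode, label = label),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("Phantom scene [%s]: %d x %d voxels (%.2g mm), %d region(s)%s\n",
              x$mode, x$shape[1], x$shape[2], x$voxel_size,
              max(x$region_labels), if (nzchar(x$label))
                paste0(" - ", x$label) else ""))
  invisible(x)
}

#' @export
plot.phantom_scene <- function(x, what = "volume_fraction", ...) {
  img <- if (what %in% names(x$truth)) x$truth[[what]] else x$aux[[what]]
  graphics::image(img, main = what, useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Synthetic L-arginine vial scene
#'
#' Builds a 2D digital phantom of circular L-arginine vials on a saline-like
#' background (f_s = 0): the synthetic stand-in for vial phantoms at 25, 50
#' or 100 mM titrated to pH 4-6. Truth maps carry the per-voxel physics
#' (volume fraction, exchange rate, water T1/T2, B0 shift) and aux maps the
#' gold-standard concentration and pH.
#'
#' @param layout data.frame with vial `cx`, `cy`, `r` in voxel units (e.g.
#'   [vial_layout_ring()])
#' @param concentrations per-vial L-arg concentration, mM
#' @param phs per-vial pH in [4, 6] typically
#' @param shape 2D grid dims
#' @param voxel_size voxel size, mm
#' @param water_t1,water_t2 vial water relaxation times, s
#' @param bg_t1,bg_t2 background water relaxation times, s
#' @param k_base,k_0 exchange-rate calibration constants, Hz
#' @param n_protons exchangeable protons per molecule
#' @param label free text
#' @return a `phantom_scene`
#' @export
make_larg_scene <- function(layout, concentrations, phs, shape = c(64, 64),
                            voxel_size = 1.8, water_t1 = 2.5, water_t2 = 1.0,
                            bg_t1 = 2.5, bg_t2 = 1.0, k_base = 400, k_0 = 25,
                            n_protons = 3, label = "") {
  nv <- nrow(layout)
  if (nv > 0 && (length(concentrations) != nv || length(phs) != nv))
    stopf("concentrations and phs must match the number of vials")
  if (nv > 1) {
    d <- as.matrix(stats::dist(layout[, c("cx", "cy")]))
    rr <- outer(layout$r, layout$r, "+")
    diag(d) <- Inf
    if (any(d < rr)) stopf("overlapping vials in layout")
  }
  zeros <- matrix(0, shape[1], shape[2])
  labels <- zeros
  fs <- zeros; ksw <- zeros; conc <- zeros; phm <- zeros
  t1 <- matrix(bg_t1, shape[1], shape[2])
  t2 <- matrix(bg_t2, shape[1], shape[2])
  xg <- matrix(seq_len(shape[1]), shape[1], shape[2])
  yg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (v in seq_len(nv)) {
    disk <- (xg - layout$cx[v])^2 + (yg - layout$cy[v])^2 <= layout$r[v]^2
    labels[disk] <- v
    fs[disk] <- fs_from_concentration(concentrations[v], n_protons)
    ksw[disk] <- larg_exchange_rate(phs[v], k_base, k_0)
    conc[disk] <- concentrations[v]
    phm[disk] <- phs[v]
    t1[disk] <- water_t1
    t2[disk] <- water_t2
  }
  new_phantom_scene(shape, voxel_size, labels,
                    truth = list(volume_fraction = fs, exchange_rate = ksw,
                                 t1_water = t1, t2_water = t2,
                                 b0_shift = zeros),
                    aux = list(concentration = conc, ph = phm),
                    solute = default_larg_solute(), mode = "larg_cest",
                    label = label)
}

# smooth random field used for procedural tissue geometry
smooth_field <- function(shape, sigma) {
  f <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  gauss_blur(f, sigma)
}

gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv1 <- function(m) {
    # replicate-padded separable convolution along rows
    idx <- pmin(pmax(seq_len(nrow(m) + 2 * r) - r, 1), nrow(m))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[seq_len(nrow(m)) + i - 1, , drop = FALSE]
    }
    out
  }
  t(pad_conv1(t(pad_conv1(img))))
}

#' Synthetic brain-like semisolid-MT scene
#'
#' Procedural white-matter/gray-matter scene (no anatomical atlas): a
#' smoothed random field thresholded inside an elliptical head mask defines
#' the WM/GM geometry, and per-voxel semisolid volume fractions and exchange
#' rates are drawn from Gaussians with the MRF-reference tissue statistics
#' (WM: f_ss 18.7 +/- 2.0 %, k_ssw 33.9 +/- 5.2 Hz; GM: f_ss 12.4 +/- 2.7 %,
#' k_ssw 49.1 +/- 8.5 Hz), truncated at physical bounds. An optional
#' tumor-like ellipse draws from a shifted distribution.
#'
#' @param shape 2D grid dims
#' @param tumor add a tumor-like region?
#' @param seed integer seed (scene is reproducible given the seed)
#' @param voxel_size voxel size, mm
#' @param lineshape semisolid lineshape, `"lorentzian"` (default) or
#'   `"superlorentzian"`
#' @param wm,gm,tumor_stats lists with `fs_mean`, `fs_sd`, `ksw_mean`,
#'   `ksw_sd` (volume fractions dimensionless, rates Hz)
#' @param label free text
#' @return a `phantom_scene` (regions: 1 = WM, 2 = GM, 3 = tumor)
#' @export
make_brain_scene <- function(shape = c(64, 64), tumor = FALSE, seed = 1,
                             voxel_size = 1.8, lineshape = "lorentzian",
                             wm = list(fs_mean = 0.187, fs_sd = 0.020,
                                       ksw_mean = 33.9, ksw_sd = 5.2),
                             gm = list(fs_mean = 0.124, fs_sd = 0.027,
                                       ksw_mean = 49.1, ksw_sd = 8.5),
                             tumor_stats = list(fs_mean = 0.09, fs_sd = 0.02,
                                                ksw_mean = 60, ksw_sd = 10),
                             label = "") {
  with_seed(seed, {
    zeros <- matrix(0, shape[1], shape[2])
    xg <- matrix(seq_len(shape[1]), shape[1], shape[2])
    yg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    cx <- shape[1] / 2 + 0.5
    cy <- shape[2] / 2 + 0.5
    head_mask <- ((xg - cx) / (0.42 * shape[1]))^2 +
      ((yg - cy) / (0.45 * shape[2]))^2 <= 1
    field <- smooth_field(shape, sigma = min(shape) / 16)
    labels <- zeros
    labels[head_mask & field > 0] <- 1   # WM
    labels[head_mask & field <= 0] <- 2  # GM
    if (tumor) {
      ang <- runif(1, 0, 2 * pi)
      tcx <- cx + 0.2 * shape[1] * cos(ang)
      tcy <- cy + 0.2 * shape[2] * sin(ang)
      tmask <- ((xg - tcx) / (0.12 * shape[1]))^2 +
        ((yg - tcy) / (0.09 * shape[2]))^2 <= 1
      labels[head_mask & tmask] <- 3
    }
    rtrunc <- function(n, mean, sd, lo, hi) {
      x <- rnorm(n, mean, sd)
      pmin(pmax(x, lo), hi)
    }
    fs <- zeros; ksw <- zeros
    stats_for <- list(wm, gm, tumor_stats)
    for (lab in 1:3) {
      idx <- labels == lab
      n <- sum(idx)
      if (n == 0) next
      st <- stats_for[[lab]]
      fs[idx] <- rtrunc(n, st$fs_mean, st$fs_sd, 1e-4, 0.999)
      ksw[idx] <- rtrunc(n, st$ksw_mean, st$ksw_sd, 1, Inf)
    }
    t1 <- zeros + 1.3; t2 <- zeros + 0.08
    t1[labels == 1] <- 1.05; t2[labels == 1] <- 0.07
    t1[labels == 2] <- 1.45; t2[labels == 2] <- 0.09
    t1[labels == 3] <- 1.6;  t2[labels == 3] <- 0.11
    new_phantom_scene(shape, voxel_size, labels,
                      truth = list(volume_fraction = fs, exchange_rate = ksw,
                                   t1_water = t1, t2_water = t2,
                                   b0_shift = zeros),
                      aux = NULL, solute = default_mt_solute(lineshape),
                      mode = "brain_mt", label = label)
  })
}

#' Inject localized B0 / susceptibility artifacts
#'
#' Adds smooth Gaussian-profile static-field perturbations at random
#' locations, emulating susceptibility artifacts (air-tissue interfaces).
#' All other truth maps are unchanged. The first blob has exactly the
#' requested peak amplitude; further blobs are scaled down randomly. The
#' union of blob supports is recorded in attribute `b0_blob_mask`.
#'
#' @param scene a `phantom_scene`
#' @param n_blobs number of perturbations
#' @param max_shift_ppm peak |B0 shift| of the strongest blob, ppm (>= 0)
#' @param seed integer seed
#' @param width blob Gaussian sigma in voxels
#' @return the perturbed `phantom_scene`
#' @export
inject_b0_artifact <- function(scene, n_blobs = 1, max_shift_ppm = 0.3,
                               seed = 1, width = NULL) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (max_shift_ppm < 0) stopf("max_shift_ppm must be >= 0")
  if (max_shift_ppm == 0 || n_blobs < 1) return(scene)
  shape <- scene$shape
  if (is.null(width)) width <- min(shape) / 10
  with_seed(seed, {
    xg <- matrix(seq_len(shape[1]), shape[1], shape[2])
    yg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    bump <- matrix(0, shape[1], shape[2])
    mask <- matrix(FALSE, shape[1], shape[2])
    inside <- which(scene$region_labels > 0, arr.ind = TRUE)
    if (nrow(inside) == 0) inside <- which(scene$region_labels >= 0,
                                           arr.ind = TRUE)
    for (b in seq_len(n_blobs)) {
      ctr <- inside[sample.int(nrow(inside), 1), ]
      amp <- if (b == 1) max_shift_ppm else
        runif(1, 0.3, 0.9) * max_shift_ppm
      amp <- amp * sample(c(-1, 1), 1)
      prof <- exp(-((xg - ctr[1])^2 + (yg - ctr[2])^2) / (2 * width^2))
      bump <- bump + amp * prof
      mask <- mask | (prof > exp(-2))   # ~2 sigma support
    }
    scene$truth$b0_shift <- scene$truth$b0_shift + bump
    attr(scene, "b0_blob_mask") <- mask
    scene
  })
}

#' Render a raw MRF image stack from a scene
#'
#' Simulates [simulate_schedule()] for every distinct parameter tuple in the
#' scene's truth maps (cached, so piecewise-constant scenes cost a handful
#' of simulations), assembles the M per-voxel signals into an image stack,
#' and adds per-image noise. Rician noise (magnitude MRI) is the default;
#' Gaussian is available for analytic checks.
#'
#' @param scene a `phantom_scene` with complete truth maps
#' @param schedule an `mrf_schedule`
#' @param noise_sigma noise standard deviation (signal units; 0 = noiseless)
#' @param noise_model `"rician"` or `"gaussian"`
#' @param seed integer seed for the noise draws
#' @param b0_field static field, Tesla
#' @param magnitude render magnitude images (default), the representation
#'   produced by magnitude MRI reconstruction and assumed by the
#'   magnitude dictionaries; `FALSE` keeps signed signals (only meaningful
#'   with Gaussian or no noise, for analytic checks)
#' @return a `raw_stack`: list with `images` (H x W x M array),
#'   `schedule_label`, `noise_sigma`, `m`
#' @export
render_raw_stack <- function(scene, schedule, noise_sigma = 0,
                             noise_model = c("rician", "gaussian"),
                             seed = 1, b0_field = 3, magnitude = TRUE) {
  stopifnot(inherits(scene, "phantom_scene"))
  noise_model <- match.arg(noise_model)
  schedule <- as_mrf_schedule(schedule)
  need <- c("volume_fraction", "exchange_rate", "t1_water", "t2_water",
            "b0_shift")
  missing <- setdiff(need, names(scene$truth))
  if (length(missing)) stopf("scene truth map(s) missing: %s",
                             paste(missing, collapse = ", "))
  m <- nrow(schedule)
  shape <- scene$shape
  key <- do.call(paste, c(lapply(scene$truth[need], as.vector), sep = "|"))
  uk <- !duplicated(key)
  uidx <- which(uk)
  sigs <- matrix(0, length(uidx), m)
  for (i in seq_along(uidx)) {
    v <- uidx[i]
    tis <- scene_tissue_at(scene, v)
    sigs[i, ] <- simulate_schedule(tis, schedule, b0_field = b0_field)
  }
  rows <- match(key, key[uk])
  flat <- sigs[rows, , drop = FALSE]           # voxels x M
  if (magnitude) flat <- abs(flat)
  if (noise_sigma > 0) {
    flat <- with_seed(seed, {
      nvox <- nrow(flat)
      if (noise_model == "gaussian") {
        flat + matrix(rnorm(nvox * m, 0, noise_sigma), nvox, m)
      } else {
        re <- flat + matrix(rnorm(nvox * m, 0, noise_sigma), nvox, m)
        im <- matrix(rnorm(nvox * m, 0, noise_sigma), nvox, m)
        sqrt(re^2 + im^2)
      }
    })
  }
  structure(list(images = array(flat, c(shape[1], shape[2], m)),
                 schedule_label = attr(schedule, "label"),
                 noise_sigma = noise_sigma, m = m),
            class = "raw_stack")
}

# tissue_parameters for one flat voxel index of a scene
scene_tissue_at <- function(scene, v) {
  sol <- scene$solute_template
  sol$volume_fraction <- scene$truth$volume_fraction[v]
  sol$exchange_rate <- scene$truth$exchange_rate[v]
  tissue_parameters(
    pool_parameters(scene$truth$t1_water[v], scene$truth$t2_water[v]),
    sol, b0_shift = scene$truth$b0_shift[v])
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Raw MRF stack: %d x %d x M = %d [%s], noise sigma = %.3g\n",
              d[1], d[2], d[3], x$schedule_label, x$noise_sigma))
  invisible(x)
}

#' Sevenfold augmentation of paired stacks and maps
#'
#' Expands each (input stack, target maps) pair into 7 variants: the
#' original, horizontal/vertical/both flips, and three seeded integer
#' translations with zero fill. The identical transform is applied to every
#' array of a pair, preserving the voxelwise pairing.
#'
#' @param pairs list of pairs; each pair is a named list of numeric arrays
#'   whose first two dimensions are spatial (H x W or H x W x C)
#' @param seed integer seed for the translation draws
#' @param max_shift maximum |translation| per axis, voxels
#' @return list of length `7 * length(pairs)`
#' @export
augment_pairs <- function(pairs, seed = 1, max_shift = 5) {
  if (!length(pairs)) return(pairs)
  apply_tf <- function(arr, tf) {
    sp <- dim(arr)
    if (is.null(sp)) stopf("augmentation expects arrays, not vectors")
    flip_idx <- function(n, flip) if (flip) rev(seq_len(n)) else seq_len(n)
    out <- if (length(sp) == 2)
      arr[flip_idx(sp[1], tf$fh), flip_idx(sp[2], tf$fv), drop = FALSE]
    else arr[flip_idx(sp[1], tf$fh), flip_idx(sp[2], tf$fv), , drop = FALSE]
    if (tf$dx != 0 || tf$dy != 0) {
      shifted <- array(0, dim(out))
      src_x <- seq_len(sp[1]) - tf$dx
      src_y <- seq_len(sp[2]) - tf$dy
      okx <- src_x >= 1 & src_x <= sp[1]
      oky <- src_y >= 1 & src_y <= sp[2]
      if (length(sp) == 2) {
        shifted[okx, oky] <- out[src_x[okx], src_y[oky]]
      } else {
        shifted[okx, oky, ] <- out[src_x[okx], src_y[oky], , drop = FALSE]
      }
      out <- shifted
    }
    out
  }
  with_seed(seed, {
    tfs_for_pair <- function() {
      list(list(fh = FALSE, fv = FALSE, dx = 0, dy = 0),
           list(fh = TRUE, fv = FALSE, dx = 0, dy = 0),
           list(fh = FALSE, fv = TRUE, dx = 0, dy = 0),
           list(fh = TRUE, fv = TRUE, dx = 0, dy = 0),
           list(fh = FALSE, fv = FALSE,
                dx = sample(-max_shift:max_shift, 1),
                dy = sample(-max_shift:max_shift, 1)),
           list(fh = TRUE, fv = FALSE,
                dx = sample(-max_shift:max_shift, 1),
                dy = sample(-max_shift:max_shift, 1)),
           list(fh = FALSE, fv = TRUE,
                dx = sample(-max_shift:max_shift, 1),
                dy = sample(-max_shift:max_shift, 1)))
    }
    out <- vector("list", 7L * length(pairs))
    k <- 0L
    for (p in pairs) {
      for (tf in tfs_for_pair()) {
        k <- k + 1L
        out[[k]] <- lapply(p, function(el) {
          if (is.array(el) || is.matrix(el)) apply_tf(el, tf) else el
        })
      }
    }
    out
  })
}
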