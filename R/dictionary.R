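#' Parameter grid for dictionary generation
#'
#' Cartesian grid over tissue-parameter axes. Supported axis names:
#' `volume_fraction`, `exchange_rate`, `t1_water`, `t2_water`, `b0_shift`.
#' Parameters not placed on an axis are taken from the base tissue at
#' generation time (optionally overridden through `fixed`).
#'
#' @param axes named list of strictly increasing numeric grid vectors
#' @param fixed named list of parameters held constant (same names)
#' @return an object of class `parameter_grid`
#' @export
parameter_grid <- function(axes, fixed = list()) {
  allowed <- c("volume_fraction", "exchange_rate", "t1_water", "t2_water",
               "b0_shift")
  if (length(axes) == 0) stopf("grid needs at least one axis")
  bad <- setdiff(names(axes), allowed)
  if (length(bad)) stopf("unknown grid axis: %s", paste(bad, collapse = ", "))
  for (nm in names(axes)) {
    v <- axes[[nm]]
    if (!is.numeric(v) || length(v) < 1 || any(!is.finite(v)))
      stopf("axis '%s' must be finite numeric", nm)
    if (length(v) > 1 && any(diff(v) <= 0))
      stopf("axis '%s' must be strictly increasing", nm)
  }
  bad <- setdiff(names(fixed), allowed)
  if (length(bad)) stopf("unknown fixed parameter: %s",
                         paste(bad, collapse = ", "))
  structure(list(axes = axes, fixed = fixed), class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  sizes <- vapply(x$axes, length, 1L)
  cat(sprintf("Parameter grid: %s (%d points)\n",
              paste(sprintf("%s[%d]", names(sizes), sizes), collapse = " x "),
              prod(sizes)))
  invisible(x)
}

grid_points <- function(grid) {
  pts <- do.call(expand.grid,
                 c(grid$axes, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE))
  pts
}

# tissue_parameters for one grid point, starting from the base tissue
tissue_at_point <- function(base, point) {
  tis <- base
  ov <- as.list(point)
  if (!is.null(ov$volume_fraction)) tis$solute$volume_fraction <- ov$volume_fraction
  if (!is.null(ov$exchange_rate)) tis$solute$exchange_rate <- ov$exchange_rate
  if (!is.null(ov$t1_water)) tis$water$t1 <- ov$t1_water
  if (!is.null(ov$t2_water)) tis$water$t2 <- ov$t2_water
  if (!is.null(ov$b0_shift)) tis$b0_shift <- ov$b0_shift
  tis
}

#' Generate a simulated-signal MRF dictionary
#'
#' Runs [simulate_schedule()] at every grid point and stores the
#' unit-normalized trajectories (rows) together with the grid. Deterministic:
#' regenerating any row reproduces it exactly.
#'
#' @param grid a `parameter_grid`
#' @param schedule an `mrf_schedule`
#' @param base_tissue `tissue_parameters` supplying everything not on an axis
#' @param b0_field static field, Tesla
#' @param magnitude store magnitude trajectories (default), matching
#'   magnitude MRI reconstruction; set `FALSE` for signed signals
#' @return an `mrf_dictionary`: list with `grid`, `points` (data.frame of
#'   grid-point parameters), `trajectories` (points x M matrix, unit rows),
#'   `schedule_label`, `m`
#' @export
generate_dictionary <- function(grid, schedule, base_tissue, b0_field = 3,
                                magnitude = TRUE) {
  stopifnot(inherits(grid, "parameter_grid"),
            inherits(base_tissue, "tissue_parameters"))
  schedule <- as_mrf_schedule(schedule)
  base <- tissue_at_point(base_tissue, grid$fixed)
  pts <- grid_points(grid)
  if (nrow(pts) == 0) stopf("empty grid")
  check <- function(cond, what) {
    if (any(cond)) stopf("unphysical grid value for %s at point %d", what,
                         which(cond)[1])
  }
  if (!is.null(pts$volume_fraction))
    check(pts$volume_fraction < 0 | pts$volume_fraction >= 1, "volume_fraction")
  if (!is.null(pts$exchange_rate)) check(pts$exchange_rate < 0, "exchange_rate")
  if (!is.null(pts$t1_water)) check(pts$t1_water <= 0, "t1_water")
  if (!is.null(pts$t2_water)) check(pts$t2_water <= 0, "t2_water")

  # pool vectors per point; schedule matrix is shared within a b0 group
  pools <- matrix(rep(tissue_pool_vec(base), each = nrow(pts)),
                  nrow = nrow(pts))
  if (!is.null(pts$t1_water)) pools[, 1] <- 1 / pts$t1_water
  if (!is.null(pts$t2_water)) pools[, 2] <- 1 / pts$t2_water
  if (!is.null(pts$volume_fraction)) pools[, 5] <- pts$volume_fraction
  if (!is.null(pts$exchange_rate)) pools[, 6] <- pts$exchange_rate

  b0s <- if (is.null(pts$b0_shift)) rep(base$b0_shift, nrow(pts)) else pts$b0_shift
  traj <- matrix(NA_real_, nrow(pts), nrow(schedule))
  for (b0 in unique(b0s)) {
    idx <- which(b0s == b0)
    tis <- base
    tis$b0_shift <- b0
    sm <- schedule_matrix(tis, schedule, b0_field)
    traj[idx, ] <- .bm_simulate_batch_cpp(pools[idx, , drop = FALSE], sm,
                                          is_semisolid(base))
  }
  if (magnitude) traj <- abs(traj)
  norms <- sqrt(rowSums(traj^2))
  if (any(norms == 0)) stopf("all-zero trajectory at grid point %d",
                             which(norms == 0)[1])
  structure(list(grid = grid, points = pts, trajectories = traj / norms,
                 schedule_label = attr(schedule, "label"),
                 m = nrow(schedule), base_tissue = base, b0_field = b0_field),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("MRF dictionary: %d entries x M = %d [%s]\n",
              nrow(x$trajectories), x$m, x$schedule_label))
  invisible(x)
}

#' Dot-product dictionary matching
#'
#' Classical MRF quantification: each voxel trajectory is unit-normalized
#' and matched to the dictionary row maximizing the inner product (cosine
#' similarity). Ties are broken by the lowest flat grid index. All-zero
#' voxels are unmatchable and flagged with `NA` parameters.
#'
#' @param signals numeric vector (one voxel) or matrix (voxels x M)
#' @param dict an `mrf_dictionary`
#' @return data.frame with the matched grid parameters per voxel plus
#'   `match_index`, `score`, and logical `matched`
#' @export
dot_product_match <- function(signals, dict) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != dict$m)
    stopf("signal length %d does not match dictionary M = %d", ncol(signals),
          dict$m)
  norms <- sqrt(rowSums(signals^2))
  ok <- norms > 0 & is.finite(norms)
  out <- as.data.frame(dict$points[rep(1L, nrow(signals)), , drop = FALSE])
  rownames(out) <- NULL
  out[] <- NA_real_
  out$match_index <- NA_integer_
  out$score <- NA_real_
  out$matched <- ok
  if (any(ok)) {
    u <- signals[ok, , drop = FALSE] / norms[ok]
    scores <- u %*% t(dict$trajectories)     # voxels x grid
    idx <- max.col(scores, ties.method = "first")
    out[ok, names(dict$points)] <- dict$points[idx, , drop = FALSE]
    out$match_index[ok] <- idx
    out$score[ok] <- scores[cbind(seq_len(nrow(scores)), idx)]
  }
  out
}

#' Read / write dictionary container files
#'
#' Single-file JSON container carrying the grid axes, fixed parameters,
#' schedule label, base tissue and the trajectory matrix at full double
#' precision.
#'
#' @param dict an `mrf_dictionary`
#' @param path file path (conventionally `.dict.json`)
#' @return `read_dictionary` returns the `mrf_dictionary`; `write_dictionary`
#'   returns `path` invisibly
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  payload <- list(
    axes = dict$grid$axes, fixed = dict$grid$fixed,
    schedule_label = dict$schedule_label, m = dict$m,
    b0_field = dict$b0_field,
    base_tissue = unclass_tissue(dict$base_tissue),
    trajectories = dict$trajectories)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) stopf("no such dictionary file: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- parameter_grid(p$axes, if (length(p$fixed)) p$fixed else list())
  base <- reclass_tissue(p$base_tissue)
  structure(list(grid = grid, points = grid_points(grid),
                 trajectories = p$trajectories,
                 schedule_label = p$schedule_label, m = p$m,
                 base_tissue = base, b0_field = p$b0_field),
            class = "mrf_dictionary")
}

unclass_tissue <- function(tis) {
  list(water = unclass(tis$water), solute = unclass(tis$solute),
       b0_shift = tis$b0_shift, b1_scale = tis$b1_scale)
}

reclass_tissue <- function(x) {
  mk <- function(p, vf = p$volume_fraction)
    pool_parameters(p$t1, p$t2, p$chemical_shift, p$exchange_rate, vf,
                    if (is.null(p$lineshape) || length(p$lineshape) == 0)
                      NULL else p$lineshape)
  tissue_parameters(mk(x$water, vf = 0), mk(x$solute), x$b0_shift,
                    x$b1_scale)
}
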