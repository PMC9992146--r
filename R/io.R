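# NIfTI and sidecar input/output. Volumes go through RNifti; every writer
# adds a JSON sidecar recording units, seeds and provenance so a run can be
# reconstructed from its output directory alone.
#
# Conventions: voxel indexing is 0-based in sidecar coordinates, axis order
# (x, y, slice); volume fractions are stored dimensionless (displayed as %),
# exchange rates in Hz, concentrations in mM, B0 shifts in ppm.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read parameter maps as NIfTI
#'
#' Each map in the named list becomes one channel of a NIfTI volume
#' (H x W x 1 x channels); units and channel names live in the JSON
#' sidecar. The voxel size is recorded in the NIfTI header.
#'
#' @param maps named list of numeric matrices (or H x W x S arrays)
#' @param path output `.nii.gz` path
#' @param voxel_size voxel edge length, mm
#' @param meta extra metadata stored in the sidecar (units, seeds, ...)
#' @return `path` (write) or the named list of maps plus attribute
#'   `sidecar` (read)
#' @export
write_parameter_maps <- function(maps, path, voxel_size = 1.8,
                                 meta = list()) {
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  d <- dim(maps[[1]])
  slices <- if (length(d) == 3) d[3] else 1L
  arr <- array(0, c(d[1], d[2], slices, length(maps)))
  for (j in seq_along(maps)) arr[, , , j] <- maps[[j]]
  img <- RNifti::asNifti(arr, pixdim = c(voxel_size, voxel_size, voxel_size,
                                         1))
  RNifti::writeNifti(img, path)
  write_sidecar(path, c(list(channels = names(maps),
                             voxel_size_mm = voxel_size,
                             axis_order = "x,y,slice,channel",
                             indexing = "0-based"), meta))
  invisible(path)
}

#' @rdname write_parameter_maps
#' @export
read_parameter_maps <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  sc <- read_sidecar(path)
  if (is.null(sc$channels)) stopf("%s: sidecar with channel names required",
                                  path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1, 1))
  if (length(dim(arr)) == 3) arr <- array(arr, c(dim(arr), 1))
  maps <- lapply(seq_along(sc$channels), function(j) {
    m <- arr[, , , j]
    if (length(dim(m)) == 3 && dim(m)[3] == 1) m <- m[, , 1]
    m
  })
  names(maps) <- sc$channels
  attr(maps, "sidecar") <- sc
  maps
}

#' Write / read a raw MRF image stack as NIfTI
#'
#' The M raw images form the 4th NIfTI dimension; the sidecar records M,
#' the schedule label and the noise model, and is validated on read.
#'
#' @param stack a `raw_stack`
#' @param path output `.nii.gz` path
#' @param voxel_size voxel edge length, mm
#' @param meta extra sidecar metadata
#' @return `path` (write) or the `raw_stack` (read)
#' @export
write_stack <- function(stack, path, voxel_size = 1.8, meta = list()) {
  stopifnot(inherits(stack, "raw_stack"))
  d <- dim(stack$images)
  arr <- array(stack$images, c(d[1], d[2], 1, d[3]))
  img <- RNifti::asNifti(arr, pixdim = c(voxel_size, voxel_size, voxel_size,
                                         1))
  RNifti::writeNifti(img, path)
  write_sidecar(path, c(list(m = d[3], schedule_label = stack$schedule_label,
                             noise_sigma = stack$noise_sigma,
                             voxel_size_mm = voxel_size,
                             axis_order = "x,y,slice,measurement",
                             indexing = "0-based"), meta))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- as.array(RNifti::readNifti(path))
  sc <- read_sidecar(path)
  if (is.null(sc)) stopf("%s: missing sidecar", path)
  if (length(dim(img)) == 3) img <- array(img, c(dim(img)[1], dim(img)[2],
                                                 1, dim(img)[3]))
  m <- dim(img)[4]
  if (!is.null(sc$m) && sc$m != m)
    stopf("%s: stack has %d images but sidecar says M = %d", path, m, sc$m)
  structure(list(images = array(img[, , 1, ], c(dim(img)[1], dim(img)[2],
                                                m)),
                 schedule_label = sc$schedule_label,
                 noise_sigma = sc$noise_sigma, m = m),
            class = "raw_stack")
}

#' Run configuration
#'
#' One structured configuration object for a full pipeline run. A single
#' master seed is fanned out deterministically to every stochastic stage
#' (see [fan_seed()]), so the configuration fully determines the run.
#'
#' @param mode `"larg_cest"` or `"brain_mt"`
#' @param master_seed integer master seed
#' @param m,n_input full and truncated schedule lengths
#' @param n_scenes training scenes to synthesize
#' @param noise_sigma rendering noise level
#' @param grid_fs,grid_ksw dictionary axis specs `c(min, max, length)`
#' @param fcn,gan named lists of overrides for [fcn_config()] /
#'   [gan_config()]
#' @param output_dir where pipeline stages write their artifacts
#' @return a `run_config`
#' @export
run_config <- function(mode = c("larg_cest", "brain_mt"), master_seed = 1,
                       m = 30, n_input = 9, n_scenes = 200,
                       noise_sigma = 2e-4,
                       grid_fs = c(1e-4, 3.5e-3, 41),
                       grid_ksw = c(10, 1400, 41),
                       fcn = list(), gan = list(), output_dir = ".") {
  mode <- match.arg(mode)
  structure(list(mode = mode, master_seed = as.integer(master_seed), m = m,
                 n_input = n_input, n_scenes = n_scenes,
                 noise_sigma = noise_sigma, grid_fs = grid_fs,
                 grid_ksw = grid_ksw, fcn = fcn, gan = gan,
                 output_dir = output_dir), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Lossless round trip: `read_run_config(write_run_config(cfg, p))` equals
#' `cfg`.
#'
#' @param config a `run_config`
#' @param path YAML file path
#' @return `path` (write) or the `run_config` (read)
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}
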