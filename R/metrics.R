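#' Normalized root mean-squared error (percent)
#'
#' RMSE between prediction and reference within a mask, normalized by the
#' reference's in-mask dynamic range (max - min) by default, expressed in
#' percent. A mean-normalized variant is available by flag.
#'
#' @param pred,ref numeric arrays of equal shape
#' @param mask logical array (default: everywhere)
#' @param normalizer `"range"` (default) or `"mean"`
#' @return NRMSE in percent (>= 0)
#' @export
nrmse <- function(pred, ref, mask = NULL, normalizer = c("range", "mean")) {
  normalizer <- match.arg(normalizer)
  if (!all(dim(pred) == dim(ref) | is.null(dim(pred))))
    stopf("pred and ref must share shape")
  if (is.null(mask)) mask <- rep(TRUE, length(ref))
  p <- pred[mask]; r <- ref[mask]
  if (length(r) == 0) stopf("empty mask")
  scale <- if (normalizer == "range") diff(range(r)) else abs(mean(r))
  if (scale == 0) stopf("degenerate normalization: constant reference in mask")
  100 * sqrt(mean((p - r)^2)) / scale
}

gaussian_window <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'valid' 2D correlation with a small window, via the conv kernel
filter_valid <- function(img, w) {
  k <- nrow(w)
  x <- array(img, c(dim(img), 1L))
  out <- .conv2d_fw_cpp(x, matrix(as.vector(w), ncol = 1), 0, k, k, 1L, 0L)
  out[, , 1]
}

#' Structural similarity index (SSIM)
#'
#' Standard windowed SSIM with a Gaussian window and the canonical
#' stabilizing constants k1 = 0.01, k2 = 0.03 over a declared dynamic
#' range, averaged over the valid (fully-windowed) region, optionally
#' restricted to a mask.
#'
#' @param pred,ref numeric matrices of equal shape
#' @param mask optional logical matrix; the SSIM map is averaged where the
#'   mask is TRUE (after cropping to the valid region)
#' @param dynamic_range scalar L; defaults to the range of the reference
#' @param win_size window size (odd), default 11
#' @param sigma Gaussian window sigma, default 1.5
#' @return mean SSIM, in [-1, 1]
#' @export
ssim <- function(pred, ref, mask = NULL, dynamic_range = NULL, win_size = 11,
                 sigma = 1.5) {
  if (!identical(dim(pred), dim(ref))) stopf("pred and ref must share shape")
  if (min(dim(ref)) < win_size)
    stopf("image smaller than the %dx%d window", win_size, win_size)
  if (is.null(dynamic_range)) dynamic_range <- diff(range(ref))
  if (dynamic_range <= 0) dynamic_range <- 1
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  w <- gaussian_window(win_size, sigma)
  mu_x <- filter_valid(pred, w)
  mu_y <- filter_valid(ref, w)
  sxx <- filter_valid(pred^2, w) - mu_x^2
  syy <- filter_valid(ref^2, w) - mu_y^2
  sxy <- filter_valid(pred * ref, w) - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  if (is.null(mask)) return(mean(smap))
  half <- (win_size - 1) / 2
  mcrop <- mask[(half + 1):(nrow(mask) - half),
                (half + 1):(ncol(mask) - half)]
  if (!any(mcrop)) stopf("mask empty after cropping to the valid region")
  mean(smap[mcrop])
}

#' Pearson correlation and intraclass correlation
#'
#' Pearson's r with its two-sided p-value, plus the intraclass correlation
#' coefficient from the two-way ANOVA decomposition of the paired table
#' (subjects x 2 raters). The default ICC is the single-rater
#' absolute-agreement form ICC(A,1) = (MSR - MSE) /
#' (MSR + (k-1) MSE + k/n (MSC - MSE)); the consistency form ICC(C,1) =
#' (MSR - MSE) / (MSR + (k-1) MSE) is available by flag.
#'
#' @param pred,ref paired numeric vectors (>= 3 finite pairs)
#' @param icc_type `"agreement"` (default) or `"consistency"`
#' @return list with `r`, `p_value`, `icc`
#' @export
pearson_and_icc <- function(pred, ref, icc_type = c("agreement",
                                                    "consistency")) {
  icc_type <- match.arg(icc_type)
  ok <- is.finite(pred) & is.finite(ref)
  x <- pred[ok]; y <- ref[ok]
  if (length(x) < 3) stopf("need at least 3 paired finite values")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("undefined correlation: zero variance")
  ct <- cor.test(x, y)
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (icc_type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  list(r = unname(ct$estimate), p_value = ct$p.value, icc = icc)
}

#' Per-map evaluation report
#'
#' Bundles the evaluation statistics used for quantitative map comparison:
#' per-map NRMSE and SSIM, volume-wise Pearson r / ICC / p, and per-region
#' median and IQR tables.
#'
#' @param pred,ref named lists of numeric matrices (same names and shapes),
#'   e.g. `list(volume_fraction = ..., exchange_rate = ...)`
#' @param mask logical matrix of evaluated voxels (default: all)
#' @param region_labels optional integer matrix (0 = background) for the
#'   per-region tables
#' @return an `evaluation_report`: per-map statistics plus region tables
#' @export
evaluation_report <- function(pred, ref, mask = NULL, region_labels = NULL) {
  stopifnot(is.list(pred), is.list(ref),
            identical(names(pred), names(ref)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ref[[1]]), ncol(ref[[1]]))
  maps <- lapply(names(pred), function(nm) {
    p <- pred[[nm]]; r <- ref[[nm]]
    stat <- pearson_and_icc(p[mask], r[mask])
    regions <- NULL
    if (!is.null(region_labels)) {
      labs <- sort(setdiff(unique(as.vector(region_labels)), 0))
      regions <- do.call(rbind, lapply(labs, function(l) {
        sel <- region_labels == l & mask
        q <- quantile(p[sel], c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(region = l, median = q[2], iqr = q[3] - q[1],
                   ref_median = median(r[sel]))
      }))
    }
    list(nrmse = nrmse(p, r, mask), ssim = ssim(p, r, mask),
         pearson_r = stat$r, icc = stat$icc, p_value = stat$p_value,
         regions = regions)
  })
  names(maps) <- names(pred)
  structure(list(maps = maps, n_voxels = sum(mask)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%d voxels)\n", x$n_voxels))
  for (nm in names(x$maps)) {
    m <- x$maps[[nm]]
    cat(sprintf("  %-16s NRMSE %.2f%%  SSIM %.3f  r %.3f  ICC %.3f  p %.2g\n",
                nm, m$nrmse, m$ssim, m$pearson_r, m$icc, m$p_value))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the scalar statistics as JSON and the per-region tables as CSV
#' next to it (`<stem>_regions_<map>.csv`).
#'
#' @param report an `evaluation_report`
#' @param path JSON output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  scalars <- lapply(report$maps, function(m)
    m[c("nrmse", "ssim", "pearson_r", "icc", "p_value")])
  jsonlite::write_json(list(n_voxels = report$n_voxels, maps = scalars),
                       path, auto_unbox = TRUE, digits = NA)
  stem <- sub("\\.json$", "", path)
  for (nm in names(report$maps)) {
    reg <- report$maps[[nm]]$regions
    if (!is.null(reg))
      utils::write.csv(reg, sprintf("%s_regions_%s.csv", stem, nm),
                       row.names = FALSE)
  }
  invisible(path)
}
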