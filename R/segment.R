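# Vial segmentation: Canny edge detection followed by a gradient-directed
# circle Hough transform. Implemented directly on matrices; images at the
# scales used here (tens of voxels per vial) keep the accumulator cheap.

sobel_gradients <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  ky <- t(kx)
  pad <- function(m) {
    m <- rbind(m[1, ], m, m[nrow(m), ])
    cbind(m[, 1], m, m[, ncol(m)])
  }
  p <- pad(img)
  H <- nrow(img); W <- ncol(img)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (di in -1:1) for (dj in -1:1) {
    wgt_x <- kx[di + 2, dj + 2]
    wgt_y <- ky[di + 2, dj + 2]
    sub <- p[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
    if (wgt_x != 0) gx <- gx + wgt_x * sub
    if (wgt_y != 0) gy <- gy + wgt_y * sub
  }
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' gradient direction, and double-threshold hysteresis.
#'
#' @param img numeric matrix
#' @param sigma Gaussian smoothing sigma, voxels
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   suppressed gradient magnitude
#' @return logical edge matrix
#' @export
canny_edges <- function(img, sigma = 1, low = 0.1, high = 0.3) {
  sm <- gauss_blur(img, sigma)
  g <- sobel_gradients(sm)
  H <- nrow(img); W <- ncol(img)
  ang <- atan2(g$gy, g$gx)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  off <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  nms <- matrix(0, H, W)
  for (s in 0:3) {
    d <- off[[s + 1]]
    shift <- function(m, di, dj) {
      out <- matrix(0, H, W)
      si <- seq_len(H) + di; sj <- seq_len(W) + dj
      ok_i <- si >= 1 & si <= H; ok_j <- sj >= 1 & sj <= W
      out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
      out
    }
    n1 <- shift(g$mag, d[1], d[2])
    n2 <- shift(g$mag, -d[1], -d[2])
    sel <- sector == s & g$mag >= n1 & g$mag >= n2
    nms[sel] <- g$mag[sel]
  }
  mx <- max(nms)
  if (mx == 0) return(matrix(FALSE, H, W))
  strong <- nms >= high * mx
  weak <- nms >= low * mx
  # hysteresis: grow strong edges into weak ones
  edges <- strong
  repeat {
    grown <- edges
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      si <- seq_len(H) - di; sj <- seq_len(W) - dj
      ok_i <- si >= 1 & si <= H; ok_j <- sj >= 1 & sj <= W
      tmp <- matrix(FALSE, H, W)
      tmp[ok_i, ok_j] <- edges[si[ok_i], sj[ok_j]]
      grown <- grown | (tmp & weak)
    }
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' Segment circular vials in a 2D image
#'
#' Detects approximately circular high-contrast vials with Canny edge
#' detection and a gradient-directed circle Hough transform, and returns
#' per-vial masks. When no circles are found the result is empty (with a
#' warning), not an error.
#'
#' @param image numeric matrix (one slice, e.g. the first raw image)
#' @param radii candidate radii in voxels (default 3 to a quarter of the
#'   short image axis)
#' @param min_votes accumulator acceptance threshold, fraction of the ideal
#'   circumference vote count
#' @param sigma Canny smoothing sigma
#' @return list with `n` (circle count), `centers` (n x 2), `radius`
#'   (length n), and `masks` (H x W integer label matrix, 0 background)
#' @export
segment_vials <- function(image, radii = NULL, min_votes = 0.45, sigma = 1) {
  H <- nrow(image); W <- ncol(image)
  if (is.null(radii)) radii <- 3:floor(min(H, W) / 4)
  edges <- canny_edges(image, sigma = sigma)
  empty <- list(n = 0L, centers = matrix(0, 0, 2), radius = numeric(0),
                masks = matrix(0L, H, W))
  if (!any(edges)) {
    warning("no edges detected; returning empty segmentation")
    return(empty)
  }
  g <- sobel_gradients(gauss_blur(image, sigma))
  ei <- which(edges, arr.ind = TRUE)
  ux <- g$gx[edges] / pmax(g$mag[edges], 1e-12)
  uy <- g$gy[edges] / pmax(g$mag[edges], 1e-12)
  found <- list()
  acc_best <- NULL
  for (r in radii) {
    acc <- matrix(0L, H, W)
    for (sgn in c(-1, 1)) {
      # gx differentiates along rows (first axis), gy along columns
      cx <- round(ei[, 1] + sgn * r * ux)
      cy <- round(ei[, 2] + sgn * r * uy)
      ok <- cx >= 1 & cx <= H & cy >= 1 & cy <= W
      if (!any(ok)) next
      tab <- table(cx[ok] + H * (cy[ok] - 1))
      idx <- as.integer(names(tab))
      acc[idx] <- acc[idx] + as.integer(tab)
    }
    # smooth votes over 3x3 neighborhoods to absorb discretization
    accs <- gauss_blur(acc, 0.8)
    thr <- min_votes * 2 * pi * r / 3  # votes spread over ~3 bins after blur
    repeat {
      pk <- which.max(accs)
      if (accs[pk] < thr) break
      ci <- ((pk - 1) %% H) + 1
      cj <- ((pk - 1) %/% H) + 1
      found[[length(found) + 1]] <- c(ci, cj, r, accs[pk] / (2 * pi * r / 3))
      # suppress neighborhood
      ii <- pmax(1, ci - r):pmin(H, ci + r)
      jj <- pmax(1, cj - r):pmin(W, cj + r)
      accs[ii, jj] <- 0
    }
  }
  if (!length(found)) {
    warning("no circles detected")
    return(empty)
  }
  cand <- do.call(rbind, found)
  cand <- cand[order(-cand[, 4]), , drop = FALSE]
  keep <- matrix(numeric(0), 0, 4)
  for (i in seq_len(nrow(cand))) {
    c_i <- cand[i, ]
    if (nrow(keep) == 0 ||
        all(sqrt((keep[, 1] - c_i[1])^2 + (keep[, 2] - c_i[2])^2) >
            0.8 * pmax(keep[, 3], c_i[3]))) {
      keep <- rbind(keep, c_i)
    }
  }
  masks <- matrix(0L, H, W)
  xg <- matrix(seq_len(H), H, W)
  yg <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(nrow(keep))) {
    disk <- (xg - keep[i, 1])^2 + (yg - keep[i, 2])^2 <= keep[i, 3]^2
    masks[disk & masks == 0L] <- i
  }
  list(n = nrow(keep), centers = keep[, 1:2, drop = FALSE],
       radius = keep[, 3], masks = masks)
}
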