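## Valid-region construction and shift-searched MS-SSIM scoring.

#' Valid region of a mosaic
#'
#' Convex hull of the population's receptive-field extents (16 support
#' points per cell on the circle center +- rf_radius), rasterized to a binary
#' pixel mask. Only pixels inside this region are scored by the image-quality
#' metric.
#'
#' @param mosaic a Mosaic
#' @return object of class \code{ValidRegionMask}: list with \code{mask}
#'   (logical H x W matrix), \code{polygon} (hull vertices, pixels)
#' @export
validRegion <- function(mosaic) {
  cl <- mosaicCells(mosaic)
  px <- mosaic@pixelSize
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  ptsX <- as.numeric(outer(cl$rf_radius, cos(ang)) + cl$x) / px
  ptsY <- as.numeric(outer(cl$rf_radius, sin(ang)) + cl$y) / px
  hull <- grDevices::chull(ptsX, ptsY)
  if (length(hull) < 3) stop("degenerate receptive-field geometry: convex hull is not 2-D")
  hx <- ptsX[hull]; hy <- ptsY[hull]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (area < 1) { # less than one pixel^2: nothing scoreable
    stop("degenerate receptive-field geometry: collinear extents")
  }
  h <- mosaic@fieldShape[1]; w <- mosaic@fieldShape[2]
  grid <- expand.grid(col = seq_len(w), row = seq_len(h))
  inside <- pracma::inpolygon(grid$col, grid$row, hx, hy, boundary = TRUE)
  mask <- matrix(FALSE, h, w)
  mask[cbind(grid$row, grid$col)] <- inside
  structure(list(mask = mask, polygon = cbind(x = hx, y = hy)),
            class = "ValidRegionMask")
}

#' @export
print.ValidRegionMask <- function(x, ...) {
  cat("ValidRegionMask:", sum(x$mask), "of", length(x$mask), "pixels valid\n")
  invisible(x)
}

## 2-D convolution with reflective padding (valid output, same size)
conv2Reflect <- function(img, kernel) {
  kr <- (nrow(kernel) - 1) %/% 2
  kc <- (ncol(kernel) - 1) %/% 2
  h <- nrow(img); w <- ncol(img)
  ri <- c(rev(seq_len(kr)), seq_len(h), h + 1 - seq_len(kr))
  ci <- c(rev(seq_len(kc)), seq_len(w), w + 1 - seq_len(kc))
  pad <- img[ri, ci]
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      out <- out + kernel[i, j] * pad[(i - 1) + seq_len(h), (j - 1) + seq_len(w)]
    }
  }
  out
}

gaussianKernel2d <- function(size = 11, sigma = 1.5) {
  r <- (size - 1) / 2
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

## single-scale SSIM: returns mean luminance term and mean contrast-structure
ssimComponents <- function(a, b, dataRange = 1, K1 = 0.01, K2 = 0.03,
                           winSize = 11, sigma = 1.5) {
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  k <- gaussianKernel2d(winSize, sigma)
  mu1 <- conv2Reflect(a, k)
  mu2 <- conv2Reflect(b, k)
  s11 <- conv2Reflect(a * a, k) - mu1^2
  s22 <- conv2Reflect(b * b, k) - mu2^2
  s12 <- conv2Reflect(a * b, k) - mu1 * mu2
  l <- (2 * mu1 * mu2 + C1) / (mu1^2 + mu2^2 + C1)
  cs <- (2 * s12 + C2) / (s11 + s22 + C2)
  list(l = mean(l), cs = mean(cs), lcs = mean(l * cs))
}

downsample2 <- function(img) {
  h <- nrow(img) %/% 2 * 2
  w <- ncol(img) %/% 2 * 2
  x <- img[seq_len(h), seq_len(w)]
  (x[seq(1, h, 2), seq(1, w, 2)] + x[seq(2, h, 2), seq(1, w, 2)] +
     x[seq(1, h, 2), seq(2, w, 2)] + x[seq(2, h, 2), seq(2, w, 2)]) / 4
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Standard MS-SSIM with the canonical five scale weights; the number of
#' scales is reduced automatically so that the coarsest scale still exceeds
#' the 11-pixel analysis window, and the weights are renormalized. Values lie
#' in [-1, 1]; identical images score 1.
#'
#' @param a,b image matrices of equal shape, values on a unit data range
#' @param maxScales cap on the scale count (default 5)
#' @return scalar MS-SSIM
#' @export
msSSIM <- function(a, b, maxScales = 5) {
  stopifnot(identical(dim(a), dim(b)))
  wts <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  nScales <- min(maxScales, max(1, floor(log2(min(dim(a)) / 11)) + 1))
  if (min(dim(a)) < 11) {
    stop("image (", paste(dim(a), collapse = "x"),
         ") is smaller than the 11-px SSIM window; use fewer scales / larger mask")
  }
  wts <- wts[seq_len(nScales)]
  wts <- wts / sum(wts)
  val <- 1
  for (sc in seq_len(nScales)) {
    comp <- ssimComponents(a, b)
    if (sc < nScales) {
      val <- val * max(comp$cs, 0)^wts[sc]
      a <- downsample2(a)
      b <- downsample2(b)
    } else {
      val <- val * max(comp$lcs, 0)^wts[sc]
    }
  }
  val
}

#' Score a reconstruction against the true image over the valid region
#'
#' Both images are cropped to the valid-region bounding box and out-of-mask
#' pixels are replaced by the truth's in-mask mean; MS-SSIM is then computed
#' for every integer shift of the reconstruction within
#' \code{shiftRadius} pixels and the best value is returned (the absolute
#' position of a jointly-estimated drift reconstruction is arbitrary).
#'
#' @param recon reconstructed image
#' @param truth true image (same shape)
#' @param mask a \code{ValidRegionMask} (or logical matrix); NULL scores the
#'   full frame
#' @param shiftRadius shift search radius in pixels (0 for flashed
#'   reconstructions, positive for drift reconstructions)
#' @return object of class \code{QualityScore}: list with \code{value},
#'   \code{shift} (the argmax (dy, dx)), \code{metric}
#' @export
scoreReconstruction <- function(recon, truth, mask = NULL, shiftRadius = 0) {
  stopifnot(identical(dim(recon), dim(truth)))
  m <- if (is.null(mask)) matrix(TRUE, nrow(truth), ncol(truth)) else
    if (is.list(mask)) mask$mask else mask
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  sub <- function(img) img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  mSub <- sub(m)
  fill <- mean(truth[m])
  tSub <- sub(truth)
  tSub[!mSub] <- fill
  best <- -Inf
  bestShift <- c(0L, 0L)
  for (dy in -shiftRadius:shiftRadius) {
    for (dx in -shiftRadius:shiftRadius) {
      rSh <- shiftImage(recon, dy, dx, fill = fill)
      rSub <- sub(rSh)
      rSub[!mSub] <- fill
      v <- msSSIM(rSub, tSub)
      if (v > best) {
        best <- v
        bestShift <- c(dy, dx)
      }
    }
  }
  structure(list(value = best, shift = bestShift, metric = "ms-ssim",
                 shiftRadius = shiftRadius),
            class = "QualityScore")
}

#' @export
print.QualityScore <- function(x, ...) {
  cat("QualityScore:", x$metric, "=", round(x$value, 4), "at shift (",
      x$shift[1], ",", x$shift[2], ")\n")
  invisible(x)
}
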