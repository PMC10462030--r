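## Temporal raised-cosine and spatial B-spline bases.

#' Log-time raised-cosine temporal basis
#'
#' The canonical basis for feedback/coupling/temporal filters in coupled GLM
#' spike-train models: cosine bumps equally spaced in warped time
#' \code{nl(t) = log(t + stretch)}, each of width twice the center spacing, so
#' the bumps tile [1, timeSpanMs] with fine resolution at short lags and
#' coarse resolution at long lags. Tap tau of the matrix applies to lag tau
#' milliseconds (lags start at 1: the basis is strictly causal).
#'
#' @param nBasis number of bumps
#' @param timeSpanMs support of the last bump, in ms
#' @param stretch log-warping offset (larger = more linear spacing)
#' @return an object of class \code{RaisedCosineBasis}: list with
#'   \code{matrix} [nBasis x timeSpanMs], \code{nBasis}, \code{timeSpanMs},
#'   \code{stretch}
#' @export
raisedCosineBasis <- function(nBasis, timeSpanMs, stretch = 10) {
  if (nBasis < 1) stop("nBasis must be >= 1")
  if (timeSpanMs < nBasis) stop("cannot pack ", nBasis, " bumps into ",
                                timeSpanMs, " ms")
  nl <- function(t) log(t + stretch)
  t <- seq_len(timeSpanMs)
  lo <- nl(1)
  hi <- nl(timeSpanMs)
  ## first bump peaks at lag 1; the last bump's support ends exactly at the
  ## time span (peaks pi/2-spaced in warped time)
  spacing <- (hi - lo) / (nBasis + 1)
  centers <- lo + (seq_len(nBasis) - 1) * spacing
  B <- matrix(0, nBasis, timeSpanMs)
  for (j in seq_len(nBasis)) {
    arg <- (nl(t) - centers[j]) * pi / (2 * spacing)
    arg <- pmin(pmax(arg, -pi), pi)
    B[j, ] <- (cos(arg) + 1) / 2
  }
  B <- B / apply(B, 1, max)
  structure(list(matrix = B, nBasis = nBasis, timeSpanMs = timeSpanMs,
                 stretch = stretch),
            class = "RaisedCosineBasis")
}

#' @export
print.RaisedCosineBasis <- function(x, ...) {
  cat("RaisedCosineBasis:", x$nBasis, "bumps over", x$timeSpanMs, "ms\n")
  invisible(x)
}

## kernel (1 ms taps, lag 1..span) from basis coefficients
basisKernel <- function(basis, coef) {
  as.numeric(crossprod(basis$matrix, coef))
}

#' Uniform cubic B-spline spatial basis over a rectangular crop
#'
#' Tensor-product uniform cubic B-splines on an extended knot grid, which sum
#' to one (partition of unity) everywhere inside the crop; filter smoothness
#' over the receptive field is imposed by the basis rather than by extra
#' penalties.
#'
#' @param cropRows integer vector of image rows in the crop
#' @param cropCols integer vector of image columns in the crop
#' @param knotSpacing knot spacing in pixels (default 3)
#' @return object of class \code{SplineSpatialBasis}: list with \code{matrix}
#'   [nPixelsInCrop x nCoef] (pixels in column-major crop order),
#'   \code{cropRows}, \code{cropCols}, \code{nCoef}
#' @export
splineSpatialBasis <- function(cropRows, cropCols, knotSpacing = 3) {
  d1 <- splineDesign1d(length(cropRows), knotSpacing)
  d2 <- splineDesign1d(length(cropCols), knotSpacing)
  ## column-major crop order: row index varies fastest
  M <- matrix(0, length(cropRows) * length(cropCols), ncol(d1) * ncol(d2))
  k <- 1L
  for (jc in seq_len(ncol(d2))) {
    for (jr in seq_len(ncol(d1))) {
      M[, k] <- as.numeric(outer(d1[, jr], d2[, jc]))
      k <- k + 1L
    }
  }
  structure(list(matrix = M, cropRows = cropRows, cropCols = cropCols,
                 nCoef = ncol(M), knotSpacing = knotSpacing),
            class = "SplineSpatialBasis")
}

splineDesign1d <- function(n, h) {
  x <- seq_len(n)
  top <- 1 + h * ceiling((n - 1) / h) # first knot-grid point >= n
  knots <- seq(1 - 3 * h, top + 3 * h, by = h)
  splines::splineDesign(knots, x, ord = 4)
}

#' @export
print.SplineSpatialBasis <- function(x, ...) {
  cat("SplineSpatialBasis:", length(x$cropRows), "x", length(x$cropCols),
      "px crop,", x$nCoef, "coefficients\n")
  invisible(x)
}
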