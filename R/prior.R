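## 1/F spectral Gaussian image prior and the Gaussian-denoiser contract.

#' Construct a 1/F spectral Gaussian prior
#'
#' Penalizes Fourier amplitudes by inverse squared radial frequency:
#' \code{E(y) = lambda * sum_k |a_k(y)|^2 / f_k^2}, with \code{f_k} the
#' Euclidean magnitude of the 2-D DFT frequency in cycles/image and
#' \code{a_k} the unitary-DFT amplitude. The DC term (f = 0) receives zero
#' weight: the prior is improper (flat) in mean luminance, which the
#' likelihood constrains.
#'
#' @param shape image shape (height, width)
#' @param lambda prior weight (default 1)
#' @return object of class \code{SpectralPrior}: list with \code{weights}
#'   (H x W matrix of 1/f^2, zero at DC), \code{lambda}, \code{shape}
#' @export
spectralPrior <- function(shape, lambda = 1) {
  h <- shape[1]; w <- shape[2]
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1) / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1) / w
  f2 <- outer(fy^2, fx^2, "+")
  wts <- 1 / f2
  wts[1, 1] <- 0
  structure(list(weights = wts, lambda = lambda, shape = as.integer(shape)),
            class = "SpectralPrior")
}

#' Spectral prior energy and gradient
#'
#' Quadratic form in the image (scaling the image by c scales the energy by
#' c^2); the gradient is returned in the pixel domain.
#'
#' @param image real-valued image matrix
#' @param prior a \code{\link{spectralPrior}}
#' @param gradient also return the gradient (default FALSE)
#' @return scalar energy, or list(energy, grad)
#' @export
spectralEnergy <- function(image, prior, gradient = FALSE) {
  n <- length(image)
  Y <- stats::fft(image)
  e <- prior$lambda * sum(prior$weights * Mod(Y)^2) / n
  if (!gradient) return(e)
  g <- 2 * prior$lambda * Re(stats::fft(prior$weights * Y, inverse = TRUE)) / n
  list(energy = e, grad = g)
}

#' Exact Gaussian denoiser under the 1/F prior
#'
#' Closed-form minimizer of
#' \code{lambda sum |a_k(x)|^2/f_k^2 + ||x - z||^2 / (2 sigma^2)}: per-
#' frequency Wiener shrinkage \code{X_k = Z_k / (1 + 2 lambda sigma^2 w_k)}.
#' The DC coefficient passes through unchanged. This is the reference
#' denoiser for the Plug-and-Play machinery (a linear, self-adjoint
#' operator).
#'
#' @param noisy image matrix
#' @param noiseVariance sigma^2 >= 0
#' @param prior a \code{\link{spectralPrior}} matching the image shape
#' @return denoised image
#' @export
denoiseExact1F <- function(noisy, noiseVariance, prior) {
  if (noiseVariance < 0) stop("noiseVariance must be >= 0")
  if (noiseVariance == 0) return(noisy)
  Z <- stats::fft(noisy)
  X <- Z / (1 + 2 * prior$lambda * noiseVariance * prior$weights)
  Re(stats::fft(X, inverse = TRUE)) / length(noisy)
}

#' Denoiser factory for the Plug-and-Play contract
#'
#' A denoiser is a function \code{(image, noiseVariance, validMask)} that
#' returns an image of identical shape; it must be deterministic and finite
#' for finite inputs. These constructors wrap the built-in denoisers in that
#' contract. Learned denoisers can be plugged in as any closure satisfying
#' the same contract.
#'
#' @param prior a \code{\link{spectralPrior}}
#' @return a denoiser function
#' @export
exact1FDenoiser <- function(prior) {
  function(image, noiseVariance, validMask = NULL) {
    denoiseExact1F(image, noiseVariance, prior)
  }
}

#' @rdname exact1FDenoiser
#' @export
identityDenoiser <- function() {
  function(image, noiseVariance, validMask = NULL) image
}

#' Validate a denoiser against the contract
#'
#' Checks shape preservation, finiteness and determinism on a grid of test
#' images and noise variances, and reports whether the mean absolute
#' residual |output - input| is non-decreasing in the noise variance.
#'
#' @param denoiser a denoiser function
#' @param testImages list of image matrices
#' @param varianceGrid increasing numeric vector of noise variances
#' @return list: \code{ok}, \code{residuals} (images x variances matrix),
#'   \code{residualMonotone}
#' @export
validateDenoiser <- function(denoiser, testImages, varianceGrid) {
  if (!length(testImages) || !length(varianceGrid)) {
    stop("test images and variance grid must be nonempty")
  }
  res <- matrix(NA_real_, length(testImages), length(varianceGrid))
  for (i in seq_along(testImages)) {
    img <- testImages[[i]]
    for (j in seq_along(varianceGrid)) {
      out <- denoiser(img, varianceGrid[j], NULL)
      if (!identical(dim(out), dim(img))) {
        stop("denoiser contract violation: output shape differs from input ",
             "(image ", i, ", variance ", varianceGrid[j], ")")
      }
      if (any(!is.finite(out))) {
        stop("denoiser contract violation: non-finite output (image ", i,
             ", variance ", varianceGrid[j], ")")
      }
      out2 <- denoiser(img, varianceGrid[j], NULL)
      if (!isTRUE(all.equal(out, out2))) {
        stop("denoiser contract violation: non-deterministic output (image ",
             i, ")")
      }
      res[i, j] <- mean(abs(out - img))
    }
  }
  mono <- all(apply(res, 1, function(r) all(diff(r) >= -1e-12)))
  list(ok = TRUE, residuals = res, residualMonotone = mono)
}
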