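## MAP image reconstruction: half-quadratic splitting (Plug-and-Play),
## exact 1/F MAP, noiseless constrained reconstruction, linear benchmark.

#' Half-quadratic splitting schedule
#'
#' K quadratic-penalty weights rho(1)..rho(K), log-spaced and strictly
#' increasing, plus the prior weight lambda. The prior step at iteration k is
#' a Gaussian denoise at variance lambda / rho(k).
#'
#' @param lambda prior weight
#' @param rhoFirst rho(1)
#' @param rhoLast rho(K)
#' @param K number of iterations (default 10)
#' @return list of class \code{HQSSchedule}
#' @export
hqsSchedule <- function(lambda = 0.1, rhoFirst = 0.2, rhoLast = 200, K = 10) {
  if (K < 1) stop("K must be >= 1")
  rho <- if (K == 1) rhoLast else exp(seq(log(rhoFirst), log(rhoLast),
                                          length.out = K))
  if (any(diff(rho) <= 0)) stop("rho schedule must be strictly increasing")
  structure(list(lambda = lambda, rho = rho, K = K), class = "HQSSchedule")
}

## Backtracking gradient descent for the x-step:
## minimize lik$fn(y) + rho/2 ||y - z||^2, warm-started at `init`.
xStep <- function(lik, z, rho, init = z, tol = 1e-6, maxIter = 60) {
  y <- init
  obj <- function(y) lik$fn(y) + rho / 2 * sum((y - z)^2)
  f <- obj(y)
  step <- 1 / max(rho, 1)
  for (it in seq_len(maxIter)) {
    g <- lik$grad(y) + rho * (y - z)
    gn2 <- sum(g^2)
    if (gn2 < 1e-20) break
    repeat {
      yn <- y - step * g
      fn <- obj(yn)
      if (fn <= f - 0.5 * step * gn2 * 1e-4) break
      step <- step / 2
      if (step < 1e-14) break
    }
    if (fn > f + 1e-8 * abs(f) + 1e-12) {
      stop("x-step diverged: objective increased beyond tolerance at ",
           "iteration ", it, " (", f, " -> ", fn, ")")
    }
    rel <- abs(f - fn) / max(1, abs(f))
    y <- yn
    f <- fn
    step <- step * 2
    if (rel < tol) break
  }
  y
}

#' MAP reconstruction by half-quadratic splitting (Plug-and-Play)
#'
#' Alternates an encoding step (convex minimization of the encoding NLL plus
#' \code{rho/2 ||x - z||^2}, solved by backtracking gradient descent) with a
#' prior step (one pass of the Gaussian denoiser at variance
#' \code{lambda / rho(k)}), over the log-spaced rho schedule. Generic over
#' any image-likelihood object and any denoiser satisfying the contract.
#'
#' @param likelihood an image-likelihood object (e.g.
#'   \code{\link{flashedLikelihood}})
#' @param denoiser denoiser function (image, noiseVariance, validMask)
#' @param schedule an \code{\link{hqsSchedule}}
#' @param init initial z (default: uniform 0.5 gray)
#' @param validMask optional mask forwarded to the denoiser
#' @param xTol x-step relative objective tolerance
#' @param xMaxIter x-step iteration cap
#' @return a \linkS4class{ReconstructionResult}
#' @export
hqsReconstruct <- function(likelihood, denoiser, schedule = hqsSchedule(),
                           init = NULL, validMask = NULL, xTol = 1e-6,
                           xMaxIter = 60) {
  shape <- likelihood$shape
  z <- init %||% matrix(GRAY, shape[1], shape[2])
  xs <- zs <- vector("list", schedule$K)
  nll <- pe <- numeric(schedule$K)
  x <- z
  for (k in seq_len(schedule$K)) {
    rho <- schedule$rho[k]
    x <- xStep(likelihood, z, rho, init = x, tol = xTol, maxIter = xMaxIter)
    z <- denoiser(x, schedule$lambda / rho, validMask)
    xs[[k]] <- x
    zs[[k]] <- z
    nll[k] <- likelihood$fn(x)
    pe[k] <- NA_real_
  }
  new("ReconstructionResult", image = z, xTrace = xs, zTrace = zs,
      nll = nll, priorEnergy = pe,
      schedule = list(lambda = schedule$lambda, rho = schedule$rho))
}

#' Reconstruct a flashed image from population spikes
#'
#' Spikes in the decoding window (flash onset to onset + 150 ms by default)
#' are combined with the fitted encoding model and a denoiser prior by
#' half-quadratic splitting.
#'
#' @param spikes BinnedSpikes of the recording
#' @param model fitted PopulationModel
#' @param movie the flashed StimulusMovie
#' @param trial trial index to reconstruct
#' @param denoiser denoiser function
#' @param schedule an \code{\link{hqsSchedule}}
#' @param windowMs decoding window (default 150)
#' @param ... passed to \code{\link{hqsReconstruct}}
#' @return a \linkS4class{ReconstructionResult}
#' @export
reconstructFlashed <- function(spikes, model, movie, trial, denoiser,
                               schedule = hqsSchedule(), windowMs = 150, ...) {
  lik <- flashedLikelihood(model, spikes, movie, trial, windowMs)
  hqsReconstruct(lik, denoiser, schedule, ...)
}

#' Reconstruct a drift trial with a known eye trajectory
#'
#' The encoding likelihood is evaluated on the movie induced by shifting the
#' candidate image along the (known) trajectory; with a zero trajectory this
#' reduces exactly to flashed-style decoding of the whole trial.
#'
#' @param spikes BinnedSpikes covering the trial
#' @param model fitted PopulationModel
#' @param trajectory a DriftTrajectory (or integer position matrix)
#' @param denoiser denoiser function
#' @param schedule an \code{\link{hqsSchedule}}
#' @param frameEdges frame/bin boundaries (default: 120 Hz edges for the
#'   trajectory's frame count)
#' @param ... passed to \code{\link{hqsReconstruct}}
#' @return a \linkS4class{ReconstructionResult}
#' @export
reconstructKnownTrajectory <- function(spikes, model, trajectory, denoiser,
                                       schedule = hqsSchedule(),
                                       frameEdges = NULL, ...) {
  pos <- if (is(trajectory, "DriftTrajectory")) positions(trajectory) else trajectory
  if (is.null(frameEdges)) frameEdges <- frameBinEdges(nrow(pos))
  lik <- trajectoryLikelihood(model, spikes, pos, frameEdges)
  hqsReconstruct(lik, denoiser, schedule, ...)
}

#' Exact MAP reconstruction under the 1/F spectral prior
#'
#' Minimizes encoding NLL + spectral prior energy directly by backtracking
#' gradient descent (both terms are smooth and convex in the image), stopping
#' when the gradient infinity-norm falls below \code{gradTol} times its
#' initial value.
#'
#' @param likelihood an image-likelihood object
#' @param prior a \code{\link{spectralPrior}} (its lambda is the prior weight)
#' @param init initial image (default gray)
#' @param gradTol relative gradient infinity-norm tolerance (default 1e-4)
#' @param maxIter iteration budget (default 2000)
#' @return list: \code{image}, \code{objective}, \code{converged}
#' @export
reconstructExact1F <- function(likelihood, prior, init = NULL, gradTol = 1e-4,
                               maxIter = 2000) {
  shape <- likelihood$shape
  y <- init %||% matrix(GRAY, shape[1], shape[2])
  obj <- function(y) likelihood$fn(y) + spectralEnergy(y, prior)
  gradf <- function(y) {
    likelihood$grad(y) + spectralEnergy(y, prior, gradient = TRUE)$grad
  }
  f <- obj(y)
  g0 <- max(abs(gradf(y)))
  step <- 1
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    g <- gradf(y)
    if (max(abs(g)) < gradTol * max(g0, 1e-12)) {
      converged <- TRUE
      break
    }
    gn2 <- sum(g^2)
    repeat {
      yn <- y - step * g
      fn <- obj(yn)
      if (fn <= f - 0.5 * step * gn2 * 1e-4 || step < 1e-14) break
      step <- step / 2
    }
    y <- yn
    f <- fn
    step <- step * 2
  }
  if (!converged) warning("gradient tolerance not reached; best iterate returned")
  list(image = y, objective = f, converged = converged)
}

#' Noiseless constrained reconstruction from linear RGC projections
#'
#' Reconstructs an image from noiseless linear responses \code{s = M' y}
#' (columns of M are the unit-L2-normalized spatial stimulus filters) by
#' alternating the closed-form equality-constrained x-step
#' \code{x = z - M (M'M)^{-1} (M'z - s)} with the denoiser prior step; every
#' x iterate satisfies \code{M'x = s} to numerical precision.
#'
#' @param s noiseless response vector (one per cell)
#' @param M projection matrix [nPixels x nCells], full column rank
#' @param denoiser denoiser function
#' @param schedule an \code{\link{hqsSchedule}}
#' @param shape image shape (height, width)
#' @param init initial z (default gray)
#' @return a \linkS4class{ReconstructionResult}
#' @export
reconstructNoiseless <- function(s, M, denoiser, schedule = hqsSchedule(),
                                 shape, init = NULL) {
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- setdiff(seq_len(ncol(M)), qrM$pivot[seq_len(qrM$rank)])
    stop("projection matrix is rank deficient (columns ",
         paste(bad, collapse = ", "), ")")
  }
  MtM <- crossprod(M)
  ch <- chol(MtM)
  project <- function(z) {
    resid <- as.numeric(crossprod(M, as.numeric(z))) - s
    corr <- M %*% backsolve(ch, forwardsolve(t(ch), resid))
    z - matrix(corr, shape[1], shape[2])
  }
  z <- init %||% matrix(GRAY, shape[1], shape[2])
  xs <- zs <- vector("list", schedule$K)
  for (k in seq_len(schedule$K)) {
    x <- project(z)
    z <- denoiser(x, schedule$lambda / schedule$rho[k], NULL)
    xs[[k]] <- x
    zs[[k]] <- z
  }
  new("ReconstructionResult", image = z, xTrace = xs, zTrace = zs,
      nll = rep(NA_real_, schedule$K), priorEnergy = rep(NA_real_, schedule$K),
      schedule = list(lambda = schedule$lambda, rho = schedule$rho))
}

#' Spatial projection matrix of a model's stimulus filters
#'
#' @param model a PopulationModel
#' @return matrix [nPixels x nCells] of unit-L2 spatial filters
#' @export
projectionMatrix <- function(model) {
  fs <- model@mosaic@fieldShape
  M <- vapply(names(model@cells), function(id) {
    v <- as.numeric(spatialField(model@cells[[id]], fs))
    v / max(sqrt(sum(v^2)), 1e-12)
  }, numeric(prod(fs)))
  M
}

#' Fit / apply the ridge linear-reconstruction benchmark
#'
#' Affine map from windowed per-cell spike-count features to image pixels,
#' estimated by ridge-regularized least squares on training pairs; the
#' intercept is the mean training image, so zero features decode to it.
#'
#' @param features matrix [nTrain x nFeatures] of spike-count features
#' @param images list (or [nTrain x nPixels] matrix) of training images
#' @param ridge ridge weight (default 1)
#' @return object of class \code{linearDecoder}
#' @export
linearDecoderFit <- function(features, images, ridge = 1) {
  Y <- if (is.list(images)) t(vapply(images, as.numeric,
                                     numeric(length(images[[1]])))) else images
  shape <- if (is.list(images)) dim(images[[1]]) else NULL
  X <- as.matrix(features)
  if (nrow(X) != nrow(Y)) stop("features and images must pair up")
  if (nrow(X) < 1 || !all(is.finite(X))) stop("degenerate features")
  xm <- colMeans(X)
  ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm)
  if (all(abs(Xc) < 1e-12) ) stop("degenerate features: no variance")
  Yc <- sweep(Y, 2, ym)
  W <- solve(crossprod(Xc) + ridge * diag(ncol(Xc)), crossprod(Xc, Yc))
  structure(list(W = W, xMean = xm, yMean = ym, shape = shape,
                 ridge = ridge), class = "linearDecoder")
}

#' @rdname linearDecoderFit
#' @param decoder a fitted \code{linearDecoder}
#' @param newFeatures feature vector or matrix for decoding
#' @return decoded image (matrix if the training images were matrices)
#' @export
linearDecoderApply <- function(decoder, newFeatures) {
  x <- if (is.matrix(newFeatures)) newFeatures else matrix(newFeatures, 1)
  y <- sweep(x, 2, decoder$xMean) %*% decoder$W
  y <- sweep(y, 2, decoder$yMean, "+")
  if (!is.null(decoder$shape) && nrow(y) == 1) {
    matrix(y, decoder$shape[1], decoder$shape[2])
  } else y
}

#' Windowed spike-count features for the linear decoder
#'
#' @param spikes BinnedSpikes
#' @param movie flashed StimulusMovie (trial table)
#' @param windowMs counting window after flash onset (default 150)
#' @return matrix [nTrials x nCells]
#' @export
spikeCountFeatures <- function(spikes, movie, windowMs = 150) {
  tri <- movie@trials
  Tn <- ncol(spikes@spikes)
  t(vapply(seq_len(nrow(tri)), function(i) {
    bins <- tri$onset_bin[i]:min(Tn, tri$onset_bin[i] + windowMs - 1)
    rowSums(spikes@spikes[, bins, drop = FALSE])
  }, numeric(nrow(spikes@spikes))))
}
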