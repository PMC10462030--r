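## Joint image + eye-trajectory estimation: resampling particle filter and
## MAP-EM.

#' Initialize a particle ensemble at the origin
#'
#' @param n number of particles (10 in the reference configuration)
#' @param pixelSize micrometers per pixel
#' @return a \linkS4class{ParticleEnsemble} of length-1 paths at (0, 0)
#' @export
newParticleEnsemble <- function(n, pixelSize = 8) {
  new("ParticleEnsemble",
      paths = rep(list(matrix(0L, 1, 2, dimnames = list(NULL, c("dy", "dx")))), n),
      weights = rep(1 / n, n), pixelSize = pixelSize)
}

#' Precomputed spike context for the particle filter
#'
#' Caches everything about (model, spikes) that the per-frame particle
#' likelihood needs: history drives, temporal kernels, spatial filter index
#' tables and the frame/bin map.
#'
#' @param model a PopulationModel
#' @param spikes BinnedSpikes covering the drift trial
#' @param frameEdges frame/bin boundaries (length nFrames + 1)
#' @return list of class \code{pfContext}
#' @export
pfContext <- function(model, spikes, frameEdges) {
  ids <- as.integer(names(model@cells))
  n <- length(ids)
  Tn <- min(ncol(spikes@spikes), frameEdges[length(frameEdges)] - 1)
  D <- matrix(0, n, Tn)
  S <- matrix(0, n, Tn)
  kerns <- vector("list", n)
  for (k in seq_len(n)) {
    p <- model@cells[[k]]
    D[k, ] <- historyDrive(model, p, spikes)[seq_len(Tn)]
    S[k, ] <- spikes@spikes[match(ids[k], spikes@cellIds), seq_len(Tn)]
    kerns[[k]] <- temporalKernel(model, p)
  }
  L <- max(vapply(kerns, length, 1L))
  Kpad <- t(vapply(kerns, function(k) c(k, numeric(L - length(k))),
                   numeric(L)))
  maxLagFrames <- L %/% min(diff(frameEdges)) + 2L
  iv <- modelSpatialIV(model)
  gather <- list(
    r = unlist(lapply(iv, `[[`, "r")),
    c = unlist(lapply(iv, `[[`, "c")),
    idx = unlist(lapply(iv, `[[`, "idx")),
    val = unlist(lapply(iv, `[[`, "val")),
    cell = rep(seq_len(n), vapply(iv, function(x) length(x$val), 1L))
  )
  structure(list(model = model, spikes = spikes, D = D, S = S, kerns = kerns,
                 Kpad = Kpad, L = L,
                 iv = iv, gather = gather, frameEdges = frameEdges,
                 fieldShape = model@mosaic@fieldShape, n = n,
                 maxLagFrames = maxLagFrames),
            class = "pfContext")
}

## all-cell spatial drive of the image shifted to a single eye position
driveAt <- function(ctx, contr, dy, dx) {
  h <- ctx$fieldShape[1]; w <- ctx$fieldShape[2]
  g <- ctx$gather
  rr <- g$r - dy
  cc <- g$c - dx
  ok <- rr >= 1 & rr <= h & cc <= w & cc >= 1
  v <- g$val[ok] * contr[g$idx[ok] - dy - dx * h]
  out <- numeric(ctx$n)
  tmp <- rowsum(v, g$cell[ok])
  out[as.integer(rownames(tmp))] <- tmp
  out
}

## per-frame spatial drives a[cell, frame] for frames `frames` of a path
pathDrives <- function(ctx, image, path, frames) {
  contr <- image - GRAY
  A <- matrix(0, ctx$n, length(frames))
  for (fi in seq_along(frames)) {
    A[, fi] <- driveAt(ctx, contr, path[frames[fi], 1], path[frames[fi], 2])
  }
  A
}

## Bernoulli log-likelihood of the spikes in frame f, given the path so far
frameLogLik <- function(ctx, image, path, f, A = NULL) {
  edges <- ctx$frameEdges
  bins <- edges[f]:(edges[f + 1] - 1)
  bins <- bins[bins <= ncol(ctx$D)]
  if (!length(bins)) return(0)
  f0 <- max(1L, f - ctx$maxLagFrames)
  frames <- f0:f
  if (is.null(A)) A <- pathDrives(ctx, image, path, frames)
  ## g over the frame's bins: strictly causal kernel over the recent drive;
  ## bins before the trial carry zero (gray-screen) drive
  tStart <- edges[f0]
  L <- ctx$L
  aMs <- cbind(matrix(0, ctx$n, L),
               A[, rep(seq_along(frames), diff(edges[f0 + 0:length(frames)])),
                 drop = FALSE])
  G <- ctx$D[, bins, drop = FALSE]
  for (bi in seq_along(bins)) {
    off <- bins[bi] - tStart # columns offset into padded drive
    G[, bi] <- G[, bi] +
      rowSums(ctx$Kpad * aMs[, off + L + 1 - seq_len(L), drop = FALSE])
  }
  s <- ctx$S[, bins, drop = FALSE]
  sum(s * G - softplus(G))
}

## sample one discretized Gaussian step (pixels)
sampleStep <- function(transition) {
  if (transition$D == 0) return(c(0L, 0L))
  um <- rnorm(2, 0, sqrt(transition$D))
  as.integer(roundHalfAway(um / transition$pixelSize))
}

systematicResample <- function(weights) {
  n <- length(weights)
  u <- (runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(weights), left.open = TRUE) + 1L
}

#' Advance the particle filter by one frame transition
#'
#' Propagates every particle by a discretized 2-D Gaussian step (the
#' Brownian transition prior: bootstrap proposal), reweights by the
#' likelihood of the new frame's spikes given the extended trajectory and the
#' current image estimate, normalizes, and performs systematic resampling
#' when the effective sample size drops below half the particle count.
#' Deterministic given \code{seed}.
#'
#' @param ensemble a ParticleEnsemble whose paths have length f - 1 frames
#' @param context a \code{\link{pfContext}}
#' @param frameIndex index f of the frame being entered (>= 2)
#' @param image current image estimate
#' @param transition list with D (um^2/frame), pixelSize, optional bounds
#'   (c(lo, hi), clipping cumulative positions per axis)
#' @param seed integer seed
#' @param resampleThreshold ESS fraction triggering resampling (default 0.5)
#' @return the advanced \linkS4class{ParticleEnsemble}
#' @export
pfAdvance <- function(ensemble, context, frameIndex, image, transition, seed,
                      resampleThreshold = 0.5) {
  n <- length(ensemble@paths)
  f <- frameIndex
  f0 <- max(1L, f - context$maxLagFrames)
  ## drives depend only on (image, position): memoize per position, valid
  ## for the current image estimate
  cache <- attr(ensemble, "driveCache")
  if (is.null(cache) || !identical(cache$image, image)) {
    cache <- list(image = image, contr = image - GRAY,
                  env = new.env(parent = emptyenv()))
  }
  driveMemo <- function(dy, dx) {
    key <- paste0(dy, ",", dx)
    v <- cache$env[[key]]
    if (is.null(v)) {
      v <- driveAt(context, cache$contr, dy, dx)
      assign(key, v, envir = cache$env)
    }
    v
  }
  withSeed(seed, {
    paths <- vector("list", n)
    logw <- log(pmax(ensemble@weights, 1e-300))
    for (p in seq_len(n)) {
      step <- sampleStep(transition)
      pos <- ensemble@paths[[p]][frameIndex - 1, ] + step
      if (!is.null(transition$bounds)) {
        pos <- pmin(pmax(pos, transition$bounds[1]), transition$bounds[2])
      }
      paths[[p]] <- rbind(ensemble@paths[[p]], as.integer(pos))
      A <- vapply(f0:f, function(ff) {
        driveMemo(paths[[p]][ff, 1], paths[[p]][ff, 2])
      }, numeric(context$n))
      if (context$n == 1) A <- matrix(A, 1)
      logw[p] <- logw[p] + frameLogLik(context, image, paths[[p]], frameIndex,
                                       A = A)
    }
    if (all(!is.finite(logw))) {
      stop("particle filter degenerate: all weights underflowed at frame ",
           frameIndex)
    }
    logw <- logw - max(logw, na.rm = TRUE)
    wts <- exp(logw)
    wts[!is.finite(wts)] <- 0
    wts <- wts / sum(wts)
    ess <- 1 / sum(wts^2)
    ## the importance-weighted (pre-resampling) ensemble is the filter's
    ## posterior estimate at this frame; resampling only rejuvenates the
    ## particle set for the next transition
    posterior <- list(paths = paths, weights = wts)
    if (ess < resampleThreshold * n) {
      idx <- systematicResample(wts)
      paths <- paths[idx]
      wts <- rep(1 / n, n)
    }
    out <- new("ParticleEnsemble", paths = paths, weights = wts,
               pixelSize = ensemble@pixelSize)
    attr(out, "driveCache") <- cache
    attr(out, "posterior") <- posterior
    out
  })
}

## expectation over q of the encoding NLL: weight-averaged per-particle
## trajectory likelihoods (importance weights, not resampled copies)
ensembleLikelihood <- function(model, spikes, ensemble, frameEdges, maxBin) {
  keep <- which(ensemble@weights > 1e-10)
  ## resampling leaves duplicated trajectories: collapse them first
  keys <- vapply(ensemble@paths[keep],
                 function(p) paste(p, collapse = ","), "")
  first <- !duplicated(keys)
  wts <- vapply(keys[first], function(k) {
    sum(ensemble@weights[keep][keys == k])
  }, 0, USE.NAMES = FALSE)
  liks <- lapply(keep[first], function(p) {
    trajectoryLikelihood(model, spikes, ensemble@paths[[p]], frameEdges,
                         maxBin = maxBin)
  })
  shape <- liks[[1]]$shape
  newImageLikelihood(
    fn = function(y) sum(wts * vapply(liks, function(l) l$fn(y), 0)),
    grad = function(y) {
      g <- matrix(0, shape[1], shape[2])
      for (i in seq_along(liks)) g <- g + wts[i] * liks[[i]]$grad(y)
      g
    },
    shape = shape)
}

#' One EM image update
#'
#' Minimizes the q-expected encoding NLL (importance-weighted over the
#' particle trajectories) plus \code{rho/2 ||x - y|| ^2} by gradient descent,
#' then applies the Gaussian denoiser at variance \code{lambda / rho}.
#'
#' @param yPrev previous image estimate
#' @param ensemble current ParticleEnsemble
#' @param model PopulationModel
#' @param spikes trial BinnedSpikes
#' @param denoiser denoiser function
#' @param rho quadratic tie weight for this update
#' @param lambda prior weight
#' @param frameEdges frame/bin boundaries
#' @param maxBin score spikes up to this bin (default: end of current paths)
#' @param validMask optional mask forwarded to the denoiser
#' @param xMaxIter gradient iterations of the single encoding step
#' @return updated image estimate
#' @export
emImageUpdate <- function(yPrev, ensemble, model, spikes, denoiser, rho,
                          lambda, frameEdges, maxBin = NULL,
                          validMask = NULL, xMaxIter = 25) {
  f <- nrow(ensemble@paths[[1]])
  if (is.null(maxBin)) maxBin <- frameEdges[f + 1] - 1
  lik <- ensembleLikelihood(model, spikes, ensemble, frameEdges, maxBin)
  x <- xStep(lik, yPrev, rho, init = yPrev, maxIter = xMaxIter)
  denoiser(x, lambda / rho, validMask)
}

#' Jointly reconstruct the image and the unknown drift trajectory
#'
#' MAP-EM: the image estimate is initialized by ten half-quadratic-splitting
#' iterations assuming a fixed eye position at the origin; the particle
#' filter is then advanced one frame transition at a time, and the image is
#' updated once every \code{updateEvery} frame transitions (plus once at the
#' final frame) using the importance-weighted expected likelihood. The
#' trajectory estimate is the weighted mean particle path.
#'
#' @param spikes BinnedSpikes covering one drift trial
#' @param model fitted PopulationModel
#' @param denoiser denoiser function
#' @param nFramesTrial frames in the trial (default 60)
#' @param transition list(D, pixelSize) of the Brownian transition prior
#' @param schedule \code{\link{hqsSchedule}} for the initialization phase
#' @param nParticles particles in the ensemble (default 10)
#' @param updateEvery image update period in frame transitions (default 5)
#' @param seed integer seed
#' @param emRho rho values for the EM image updates (default: the final
#'   schedule value rho(K), i.e. the initialization schedule continued at its
#'   cap)
#' @param initWindowMs zero-movement initialization decodes only this many
#'   leading milliseconds of the trial, over which the (unknown) drift
#'   displacement is still small, so the initial image is sharp and nearly
#'   registered (default 150)
#' @param emXMaxIter gradient iterations per EM encoding step (default 8;
#'   a deliberately partial step -- the strong quadratic tie makes full
#'   convergence per update unnecessary and mildly destabilizing)
#' @param validMask optional mask forwarded to the denoiser
#' @return list: \code{image}, \code{trajectory} (weighted-mean path matrix,
#'   pixels), \code{ensemble}, \code{init} (the zero-movement
#'   ReconstructionResult), \code{essTrace}
#' @export
jointReconstruct <- function(spikes, model, denoiser, nFramesTrial = 60,
                             transition, schedule = hqsSchedule(),
                             nParticles = 10, updateEvery = 5, seed = 1,
                             emRho = NULL, initWindowMs = 150,
                             emXMaxIter = 8, validMask = NULL) {
  frameEdges <- frameBinEdges(nFramesTrial)
  zeroPos <- matrix(0L, nFramesTrial, 2)
  init <- hqsReconstruct(
    trajectoryLikelihood(model, spikes, zeroPos, frameEdges,
                         maxBin = initWindowMs),
    denoiser, schedule, validMask = validMask, xMaxIter = 25)
  y <- reconImage(init)
  ctx <- pfContext(model, spikes, frameEdges)
  ensemble <- newParticleEnsemble(nParticles, transition$pixelSize)
  nUpdates <- length(seq(2, nFramesTrial, by = 1)) %/% updateEvery + 1
  if (is.null(emRho)) {
    emRho <- rep(tail(schedule$rho, 1), max(nUpdates, 1))
  }
  ui <- 0
  ess <- numeric(0)
  for (f in 2:nFramesTrial) {
    ensemble <- pfAdvance(ensemble, ctx, f, y, transition,
                          seed = childSeed(seed, f))
    ess <- c(ess, effectiveSampleSize(ensemble))
    if ((f - 1) %% updateEvery == 0 || f == nFramesTrial) {
      ui <- min(ui + 1, length(emRho))
      y <- emImageUpdate(y, ensemble, model, spikes, denoiser,
                         rho = emRho[ui], lambda = schedule$lambda,
                         frameEdges = frameEdges, validMask = validMask,
                         xMaxIter = emXMaxIter)
    }
  }
  W <- ensemble@weights
  traj <- Reduce(`+`, Map(function(p, w) p * w, ensemble@paths, as.list(W)))
  list(image = y, trajectory = traj, ensemble = ensemble, init = init,
       essTrace = ess)
}

#' Eye-position estimation error
#'
#' Per-frame Euclidean distance between an estimated and the true cumulative
#' trajectory, in micrometers, and its time-averaged RMS.
#'
#' @param estimate matrix [nFrames x 2] of estimated positions (pixels), or a
#'   DriftTrajectory
#' @param truth matrix or DriftTrajectory of the same length
#' @param pixelSize micrometers per pixel (taken from `truth` if it is a
#'   DriftTrajectory)
#' @return list: \code{perFrame} (um), \code{rms} (um)
#' @export
trajectoryError <- function(estimate, truth, pixelSize = NULL) {
  if (is(truth, "DriftTrajectory")) {
    pixelSize <- pixelSize %||% truth@pixelSize
    truth <- positions(truth)
  }
  if (is(estimate, "DriftTrajectory")) estimate <- positions(estimate)
  if (is.null(pixelSize)) stop("pixelSize required")
  if (nrow(estimate) != nrow(truth)) {
    stop("estimate and truth trajectories differ in length (",
         nrow(estimate), " vs ", nrow(truth), ")")
  }
  d <- (estimate - truth) * pixelSize
  perFrame <- sqrt(d[, 1]^2 + d[, 2]^2)
  list(perFrame = perFrame, rms = sqrt(mean(perFrame^2)))
}
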