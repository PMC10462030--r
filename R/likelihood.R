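## Image-likelihood objects: encoding NLL as a function of the candidate
## image, with pixel-domain gradients, for the MAP reconstruction machinery.
## A likelihood object is a list with fields `fn(y)` and `grad(y)` (class
## "imageLikelihood"); `shape` gives the image dimensions.

newImageLikelihood <- function(fn, grad, shape, extra = list()) {
  structure(c(list(fn = fn, grad = grad, shape = shape), extra),
            class = "imageLikelihood")
}

## spatial filter index/value tables for all cells of a model; tiny spline
## tails (< 0.5% of each filter's peak) are dropped: negligible drive, much
## smaller gather tables for the reconstruction likelihoods
modelSpatialIV <- function(model) {
  fs <- model@mosaic@fieldShape
  lapply(model@cells, spatialIdxVal, fieldShape = fs, threshold = 5e-3)
}

#' Encoding likelihood of a flashed image
#'
#' Builds the Bernoulli encoding NLL of one flash trial as a function of the
#' displayed image: the stimulus drive of cell i is
#' \code{a_i(y) * h_i[t]} with \code{a_i = m_i' (y - 0.5)} and \code{h_i} the
#' cell's temporal kernel convolved with the flash indicator; feedback,
#' coupling and bias contributions come from the observed spikes. Only spikes
#' in \code{windowMs} after flash onset are scored.
#'
#' @param model a PopulationModel
#' @param spikes BinnedSpikes for the full recording
#' @param movie the flashed StimulusMovie (provides trial bookkeeping)
#' @param trial trial index
#' @param windowMs decoding window after flash onset (default 150)
#' @return an image-likelihood object
#' @export
flashedLikelihood <- function(model, spikes, movie, trial, windowMs = 150) {
  tri <- movie@trials
  if (!nrow(tri)) stop("movie has no trial table")
  onset <- tri$onset_bin[trial]
  Tn <- ncol(spikes@spikes)
  bins <- onset:min(Tn, onset + windowMs - 1)
  edges <- movie@frameEdges
  ## indicator of image-on bins (the 12 image frames of this trial)
  imgFrames <- tri$frame_start[trial]:(tri$frame_start[trial] + 11L)
  ind <- numeric(Tn)
  for (f in imgFrames) ind[edges[f]:(edges[f + 1] - 1)] <- 1
  ids <- as.integer(names(model@cells))
  n <- length(ids)
  fs <- model@mosaic@fieldShape
  iv <- modelSpatialIV(model)
  H <- matrix(0, n, length(bins))
  D <- matrix(0, n, length(bins))
  S <- matrix(0, n, length(bins))
  Smat <- matrix(0, n, prod(fs))
  for (k in seq_len(n)) {
    p <- model@cells[[k]]
    hFull <- causalFilter(ind, temporalKernel(model, p))
    H[k, ] <- hFull[bins]
    D[k, ] <- historyDrive(model, p, spikes)[bins]
    S[k, ] <- spikes@spikes[match(ids[k], spikes@cellIds), bins]
    Smat[k, iv[[k]]$idx] <- iv[[k]]$val
  }
  fn <- function(y) {
    a <- as.numeric(Smat %*% (as.numeric(y) - GRAY))
    G <- a * H + D
    sum(softplus(G) - S * G)
  }
  grad <- function(y) {
    a <- as.numeric(Smat %*% (as.numeric(y) - GRAY))
    G <- a * H + D
    r <- rowSums((plogis(G) - S) * H)
    matrix(as.numeric(crossprod(Smat, r)), fs[1], fs[2])
  }
  newImageLikelihood(fn, grad, fs, list(bins = bins))
}

#' Encoding likelihood of a drift trial with a given eye trajectory
#'
#' Builds the Bernoulli encoding NLL of one drift-jittered trial as a
#' function of the underlying (un-jittered) image, for a fixed candidate
#' trajectory of cumulative integer-pixel eye positions: frame f of the
#' candidate movie is the image shifted by \code{posPx[f, ]}. Feedback,
#' coupling and bias come from the observed spikes.
#'
#' @param model a PopulationModel
#' @param spikes BinnedSpikes covering the trial (cells x ms)
#' @param posPx integer matrix [nFrames x 2] of cumulative (dy, dx) positions
#' @param frameEdges 1-based frame/bin boundaries, length nFrames + 1
#' @param maxBin score only bins 1..maxBin (default: the whole trial)
#' @return an image-likelihood object
#' @export
trajectoryLikelihood <- function(model, spikes, posPx, frameEdges,
                                 maxBin = NULL) {
  fs <- model@mosaic@fieldShape
  h <- fs[1]; w <- fs[2]
  nF <- nrow(posPx)
  frameEdges <- frameEdges[seq_len(nF + 1)] # trajectory prefixes score a prefix
  Tn <- min(ncol(spikes@spikes), frameEdges[nF + 1] - 1)
  if (!is.null(maxBin)) Tn <- min(Tn, maxBin)
  ids <- as.integer(names(model@cells))
  n <- length(ids)
  iv <- modelSpatialIV(model)
  ## concatenated gather table: image index, weight, (cell, frame) group
  IDX <- vector("list", n * nF)
  VAL <- vector("list", n * nF)
  GRP <- vector("list", n * nF)
  q <- 1L
  for (k in seq_len(n)) {
    rk <- iv[[k]]$r; ck <- iv[[k]]$c; vk <- iv[[k]]$val
    rRange <- range(rk); cRange <- range(ck)
    idx0 <- iv[[k]]$idx
    for (f in seq_len(nF)) {
      dy <- posPx[f, 1]; dx <- posPx[f, 2]
      if (rRange[1] - dy >= 1 && rRange[2] - dy <= h &&
            cRange[1] - dx >= 1 && cRange[2] - dx <= w) {
        ## interior shift: pure index offset, no bounds filtering
        IDX[[q]] <- idx0 - dy - dx * h
        VAL[[q]] <- vk
        GRP[[q]] <- rep.int((k - 1L) * nF + f, length(vk))
      } else {
        rr <- rk - dy
        cc <- ck - dx
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        IDX[[q]] <- rr[ok] + (cc[ok] - 1L) * h
        VAL[[q]] <- vk[ok]
        GRP[[q]] <- rep.int((k - 1L) * nF + f, sum(ok))
      }
      q <- q + 1L
    }
  }
  IDX <- unlist(IDX); VAL <- unlist(VAL); GRP <- unlist(GRP)
  ## precomputed segment sums (dense scatter-add over a fixed index vector)
  makeAccumulator <- function(groups, nGroups) {
    perm <- order(groups)
    r <- rle(groups[perm])
    ends <- cumsum(r$lengths)
    ids <- r$values
    function(vals) {
      cs <- cumsum(vals[perm])
      out <- numeric(nGroups)
      out[ids] <- diff(c(0, cs[ends]))
      out
    }
  }
  accGRP <- makeAccumulator(GRP, n * nF)
  accIDX <- makeAccumulator(IDX, h * w)
  D <- matrix(0, n, Tn)
  S <- matrix(0, n, Tn)
  kerns <- vector("list", n)
  for (k in seq_len(n)) {
    p <- model@cells[[k]]
    D[k, ] <- historyDrive(model, p, spikes)[seq_len(Tn)]
    S[k, ] <- spikes@spikes[match(ids[k], spikes@cellIds), seq_len(Tn)]
    kerns[[k]] <- temporalKernel(model, p)
  }
  msOfFrame <- rep(seq_len(nF), diff(frameEdges))
  computeG <- function(y) {
    contr <- as.numeric(y) - GRAY
    a <- accGRP(VAL * contr[IDX])
    A <- matrix(a, n, nF, byrow = TRUE)
    D + batchCausalFilter(A[, msOfFrame, drop = FALSE], kerns)[, seq_len(Tn),
                                                               drop = FALSE]
  }
  fn <- function(y) {
    G <- computeG(y)
    sum(softplus(G) - S * G)
  }
  grad <- function(y) {
    G <- computeG(y)
    R <- plogis(G) - S
    ## u[i, t'] = sum_tau k_i[tau] R[i, t' + tau]  (adjoint of the causal filter)
    u <- batchCausalFilter(R[, rev(seq_len(Tn)), drop = FALSE],
                           kerns)[, rev(seq_len(Tn)), drop = FALSE]
    rho <- t(rowsum(t(cbind(u, matrix(0, n, length(msOfFrame) - Tn))), msOfFrame))
    gv <- accIDX(VAL * as.numeric(t(rho))[GRP])
    matrix(gv, h, w)
  }
  newImageLikelihood(fn, grad, fs, list(nFrames = nF, Tn = Tn))
}

#' Gaussian pseudo-likelihood (testing hook)
#'
#' \code{NLL(y) = ||A vec(y) - b||^2 / (2 sigma^2)}: a quadratic stand-in for
#' the encoding likelihood with a known closed-form MAP under the spectral
#' prior, used to verify the Plug-and-Play machinery against analytic
#' solutions.
#'
#' @param A observation matrix [m x nPixels]
#' @param b observation vector
#' @param noiseVariance sigma^2
#' @param shape image shape (height, width)
#' @return an image-likelihood object
#' @export
gaussianPseudoLikelihood <- function(A, b, noiseVariance, shape) {
  fn <- function(y) {
    r <- as.numeric(A %*% as.numeric(y)) - b
    sum(r^2) / (2 * noiseVariance)
  }
  grad <- function(y) {
    r <- as.numeric(A %*% as.numeric(y)) - b
    matrix(as.numeric(crossprod(A, r)) / noiseVariance, shape[1], shape[2])
  }
  newImageLikelihood(fn, grad, as.integer(shape))
}
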