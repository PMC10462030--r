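## Spike-train and trajectory analyses: PSTH, variance explained,
## cross-correlograms with shift-predictor correction, spike-time
## perturbation, repeat shuffling, drift magnitude.

## repeat raster: 3-D array [nRepeats x nCells x T] (binary)
checkRepeatRaster <- function(raster) {
  if (length(dim(raster)) != 3) stop("repeat raster must be [repeats x cells x T]")
  if (!all(raster %in% c(0, 1))) stop("repeat raster must be binary")
  invisible(raster)
}

## Gaussian smoothing along time with reflective padding
gaussSmooth <- function(x, sdMs) {
  n <- length(x)
  L <- min(max(1L, ceiling(4 * sdMs)), n - 1L)
  k <- exp(-((-L):L)^2 / (2 * sdMs^2))
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(L)]), x, rev(x[(n - L + 1):n]))
  stats::convolve(xp, rev(k), type = "filter")
}

#' Peri-stimulus time histogram
#'
#' Counts spikes in 1 ms bins, smooths with a Gaussian kernel (SD 2 ms by
#' default) using reflective edge padding, and averages over repeated
#' presentations. Smoothing preserves total spike mass up to edge truncation.
#'
#' @param raster binary array [nRepeats x nCells x T] (a single cell may be
#'   supplied as [nRepeats x T])
#' @param kernelSdMs Gaussian kernel SD in ms (default 2)
#' @return matrix [nCells x T] of rates (spikes per 1 ms bin), or a vector
#'   when a single cell was supplied
#' @export
psth <- function(raster, kernelSdMs = 2) {
  single <- length(dim(raster)) == 2
  if (single) raster <- array(raster, c(nrow(raster), 1, ncol(raster)))
  checkRepeatRaster(raster)
  nR <- dim(raster)[1]; nC <- dim(raster)[2]; Tn <- dim(raster)[3]
  out <- matrix(0, nC, Tn)
  for (c in seq_len(nC)) {
    m <- apply(raster[, c, , drop = FALSE], 3, mean) # mean over repeats
    out[c, ] <- gaussSmooth(m, kernelSdMs)
  }
  if (single) out[1, ] else out
}

#' Fraction of PSTH variance explained
#'
#' \code{1 - mean((model - data)^2) / var(data)} with the population
#' (n-denominator) variance; 1 for a perfect match, 0 for predicting the
#' mean, negative for worse than the mean.
#'
#' @param modelPsth model-predicted PSTH (vector)
#' @param dataPsth observed PSTH (vector, same length)
#' @return scalar in (-Inf, 1]
#' @export
fractionVarianceExplained <- function(modelPsth, dataPsth) {
  if (length(modelPsth) != length(dataPsth)) stop("length mismatch")
  v <- mean((dataPsth - mean(dataPsth))^2)
  if (v <= 0) stop("data PSTH has zero variance")
  1 - mean((modelPsth - dataPsth)^2) / v
}

#' Cross-correlogram with shift-predictor correction
#'
#' Raw correlogram: spike-time difference histogram in 1 ms bins, averaged
#' over repeats (\code{CCG[l] = mean_r sum_t a_r[t] b_r[t + l]}). The shift
#' predictor pairs cell b's response from the trial \code{shift} positions
#' later (cyclically), estimating the component predicted by trial structure
#' alone; the corrected correlogram subtracts it.
#'
#' @param rasterA binary matrix [nRepeats x T] for cell a
#' @param rasterB binary matrix [nRepeats x T] for cell b
#' @param maxLagMs largest lag (symmetric axis, ms)
#' @param shift trial offset for the predictor (default 1); set
#'   \code{corrected = FALSE} to skip correction
#' @param corrected apply the shift-predictor correction (default TRUE)
#' @return object of class \code{Correlogram}: list with \code{lags},
#'   \code{raw}, \code{predictor}, \code{corrected}, \code{values}
#' @export
crossCorrelogram <- function(rasterA, rasterB, maxLagMs = 25, shift = 1,
                             corrected = TRUE) {
  stopifnot(identical(dim(rasterA), dim(rasterB)))
  nR <- nrow(rasterA)
  if (corrected && nR < 2) stop("shift-predictor correction needs >= 2 repeats")
  lags <- -maxLagMs:maxLagMs
  ccgOf <- function(A, B) {
    acc <- numeric(length(lags))
    for (r in seq_len(nrow(A))) {
      cc <- crossCorrBinary(A[r, ], B[r, ], maxLagMs)
      acc <- acc + cc
    }
    acc / nrow(A)
  }
  raw <- ccgOf(rasterA, rasterB)
  pred <- rep(NA_real_, length(lags))
  corr <- rep(NA_real_, length(lags))
  if (corrected) {
    idx <- ((seq_len(nR) - 1 + shift) %% nR) + 1
    pred <- ccgOf(rasterA, rasterB[idx, , drop = FALSE])
    corr <- raw - pred
  }
  structure(list(lags = lags, raw = raw, predictor = pred, corrected = corr,
                 values = if (corrected) corr else raw,
                 correctedFlag = corrected),
            class = "Correlogram")
}

## sum_t a[t] b[t + l] for l in -L..L via FFT cross-correlation
crossCorrBinary <- function(a, b, L) {
  n <- length(a)
  m <- stats::nextn(n + L + 1, 2)
  fa <- stats::fft(c(a, numeric(m - n)))
  fb <- stats::fft(c(b, numeric(m - n)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / m
  ## cc[1] = lag 0, cc[1+l] = lag l, cc[m+1-l] = lag -l
  c(cc[(m - L + 1):m], cc[1:(L + 1)])
}

#' @export
print.Correlogram <- function(x, ...) {
  cat("Correlogram: lags", min(x$lags), "..", max(x$lags), "ms;",
      if (x$correctedFlag) "shift-predictor corrected" else "raw", "\n")
  invisible(x)
}

#' Randomly perturb spike times
#'
#' Each spike is shifted by an independent zero-mean Gaussian interval
#' (SD \code{sigmaMs}), reflected at the record boundaries and re-binned at
#' 1 ms. Collisions (two spikes of one cell landing in one bin) are resolved
#' by re-drawing that spike's jitter, so per-cell spike counts and the
#' at-most-one-spike-per-bin invariant are both preserved.
#'
#' @param spikes a BinnedSpikes
#' @param sigmaMs perturbation SD in ms (0 returns the input unchanged)
#' @param seed integer seed
#' @return perturbed BinnedSpikes
#' @export
perturbSpikeTimes <- function(spikes, sigmaMs, seed) {
  if (sigmaMs < 0) stop("sigmaMs must be >= 0")
  if (sigmaMs == 0) return(spikes)
  S <- spikes@spikes
  Tn <- ncol(S)
  reflect <- function(t) {
    ## reflect continuous times into [0.5, Tn + 0.5)
    period <- 2 * Tn
    t <- (t - 0.5) %% period
    t <- ifelse(t >= Tn, period - t - 1e-9, t)
    t + 0.5
  }
  withSeed(seed, {
    out <- matrix(0L, nrow(S), Tn)
    for (i in seq_len(nrow(S))) {
      ts <- which(S[i, ] == 1L)
      if (!length(ts)) next
      for (t0 in ts) {
        placed <- FALSE
        for (attempt in 1:200) {
          tn <- round(reflect(t0 + rnorm(1, 0, sigmaMs)))
          tn <- min(max(tn, 1L), Tn)
          if (out[i, tn] == 0L) {
            out[i, tn] <- 1L
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          free <- which(out[i, ] == 0L)
          tn <- free[which.min(abs(free - t0))]
          out[i, tn] <- 1L
        }
      }
    }
    new("BinnedSpikes", spikes = out, cellIds = spikes@cellIds)
  })
}

#' Shuffle repeats independently per cell
#'
#' Randomly permutes the repeat axis separately for each cell, eliminating
#' noise correlations while exactly preserving every cell's single-trial
#' spike trains (and therefore its PSTH).
#'
#' @param raster binary array [nRepeats x nCells x T]
#' @param seed integer seed
#' @return shuffled raster of the same shape
#' @export
shuffleRepeats <- function(raster, seed) {
  checkRepeatRaster(raster)
  nR <- dim(raster)[1]
  if (nR < 2) {
    warning("single repeat: shuffling is the identity")
    return(raster)
  }
  withSeed(seed, {
    out <- raster
    for (c in seq_len(dim(raster)[2])) {
      out[, c, ] <- raster[sample.int(nR), c, ]
    }
    out
  })
}

#' Realized drift magnitude of a trajectory
#'
#' The standard deviation (n-denominator) of the per-frame 2-D cumulative
#' displacement magnitudes about their mean, in micrometers, computed on the
#' realized (integer-pixel) trajectory.
#'
#' @param trajectory a DriftTrajectory
#' @return scalar, micrometers
#' @export
driftMagnitude <- function(trajectory) {
  p <- positions(trajectory) * trajectory@pixelSize
  mag <- sqrt(p[, 1]^2 + p[, 2]^2)
  sqrt(mean((mag - mean(mag))^2))
}
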