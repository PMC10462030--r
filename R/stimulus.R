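## Stimulus protocols: flashed images and drift-jittered movies.

GRAY <- 0.5

newMovie <- function(frames, frameRate = 120, trials = NULL) {
  nf <- dim(frames)[3]
  edges <- as.integer(frameBinEdges(nf, frameRate))
  if (is.null(trials)) trials <- data.frame()
  new("StimulusMovie", frames = frames, frameRate = frameRate,
      frameEdges = edges, trials = trials)
}

#' Build a flashed-image stimulus movie
#'
#' Each trial presents an image for 100 ms (12 frames at 120 Hz) followed by
#' 400 ms (48 frames) of uniform 0.5 gray, the flashed natural-image protocol.
#'
#' @param images list of H x W matrices with values in [0, 1]
#' @param pixelSize micrometers per pixel (metadata only)
#' @param imageFrames frames per image presentation (default 12)
#' @param grayFrames frames of gray separation (default 48)
#' @return a \linkS4class{StimulusMovie}; its \code{trials} table records, per
#'   trial, the image index, frame range, bin range and flash-onset bin
#' @export
makeFlashedStimulus <- function(images, pixelSize = 8, imageFrames = 12L,
                                grayFrames = 48L) {
  if (!length(images)) stop("at least one image is required")
  d <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), d)) stop("all images must share one shape")
    if (min(im) < -1e-9 || max(im) > 1 + 1e-9) stop("image values must lie in [0, 1]")
  }
  perTrial <- imageFrames + grayFrames
  nf <- perTrial * length(images)
  frames <- array(GRAY, c(d[1], d[2], nf))
  edges <- frameBinEdges(nf)
  trials <- data.frame(trial = seq_along(images), image = seq_along(images),
                       frame_start = NA_integer_, frame_end = NA_integer_,
                       bin_start = NA_integer_, bin_end = NA_integer_,
                       onset_bin = NA_integer_)
  for (i in seq_along(images)) {
    f0 <- (i - 1L) * perTrial + 1L
    frames[, , f0:(f0 + imageFrames - 1L)] <- rep(images[[i]], imageFrames)
    trials$frame_start[i] <- f0
    trials$frame_end[i] <- f0 + perTrial - 1L
    trials$bin_start[i] <- edges[f0]
    trials$bin_end[i] <- edges[f0 + perTrial] - 1L
    trials$onset_bin[i] <- edges[f0]
  }
  newMovie(frames, trials = trials)
}

#' Render a drift-jittered movie from one image and a trajectory
#'
#' Frame k shows the image translated by the trajectory's cumulative pixel
#' displacement at frame k; pixels exposed by the shift are filled with the
#' 0.5 gray border level.
#'
#' @param image H x W matrix in [0, 1]
#' @param trajectory a \linkS4class{DriftTrajectory}
#' @param padAllowance largest tolerated |cumulative displacement| in pixels;
#'   displacement beyond this raises an error (default: a quarter of the
#'   smaller image dimension)
#' @return a \linkS4class{StimulusMovie} with one trial
#' @export
makeDriftMovie <- function(image, trajectory,
                           padAllowance = floor(min(dim(image)) / 4)) {
  pos <- positions(trajectory)
  if (max(abs(pos)) > padAllowance) {
    stop("cumulative drift displacement (", max(abs(pos)),
         " px) exceeds the padding allowance (", padAllowance, " px)")
  }
  nf <- trajectory@nFrames
  frames <- array(GRAY, c(nrow(image), ncol(image), nf))
  for (k in seq_len(nf)) {
    frames[, , k] <- shiftImage(image, pos[k, 1], pos[k, 2], fill = GRAY)
  }
  edges <- frameBinEdges(nf)
  trials <- data.frame(trial = 1L, image = 1L, frame_start = 1L,
                       frame_end = nf, bin_start = edges[1],
                       bin_end = edges[nf + 1] - 1L, onset_bin = edges[1])
  newMovie(frames, trials = trials)
}

#' Generate synthetic naturalistic test images
#'
#' Gaussian textures with a 1/f amplitude spectrum, superimposed hard-edged
#' shapes (rectangles and discs), range-clipped to [0, 1]. These carry both
#' the spectral statistics the 1/F prior models and sharp edges that
#' challenge it.
#'
#' @param n number of images
#' @param shape (height, width) in pixels
#' @param nShapes number of superimposed shapes per image
#' @param contrast RMS contrast of the 1/f texture before clipping
#' @param seed integer seed
#' @return list of H x W matrices in [0, 1]
#' @export
syntheticImages <- function(n, shape = c(32L, 32L), nShapes = 2L,
                            contrast = 0.18, seed = 1) {
  h <- shape[1]; w <- shape[2]
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1) / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1) / w
  f <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- 1 / pmax(f, 1e-12)
  amp[1, 1] <- 0
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      z <- matrix(rnorm(h * w), h, w)
      tex <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (h * w)
      tex <- tex / max(sd(tex), 1e-12) * contrast
      img <- GRAY + tex
      for (s in seq_len(nShapes)) {
        lev <- runif(1, 0.1, 0.9)
        if (runif(1) < 0.5) {
          r0 <- sample.int(h - 3, 1); c0 <- sample.int(w - 3, 1)
          r1 <- min(h, r0 + sample.int(max(2, h %/% 3), 1))
          c1 <- min(w, c0 + sample.int(max(2, w %/% 3), 1))
          img[r0:r1, c0:c1] <- 0.6 * lev + 0.4 * img[r0:r1, c0:c1]
        } else {
          cy <- runif(1, 1, h); cx <- runif(1, 1, w)
          rad <- runif(1, 2, min(h, w) / 4)
          d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
          msk <- d2 <= rad^2
          img[msk] <- 0.6 * lev + 0.4 * img[msk]
        }
      }
      pmin(pmax(img, 0), 1)
    })
  })
}
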