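## Central S4 containers.

CELL_TYPES <- c("ON_parasol", "OFF_parasol", "ON_midget", "OFF_midget")

typePolarity <- function(cellType) ifelse(grepl("^ON", cellType), 1L, -1L)
typeClass <- function(cellType) ifelse(grepl("parasol", cellType), "parasol", "midget")

#' Receptive-field mosaic of a synthetic RGC population
#'
#' Holds one \code{data.frame} row per cell (\code{cell_id}, \code{cell_type},
#' \code{x}, \code{y} receptive-field center in micrometers, \code{rf_radius}
#' in micrometers, \code{polarity} +1/-1), together with the stimulus pixel
#' size (micrometers per pixel) and the field shape (rows, cols) in pixels.
#'
#' @slot cells data.frame of cell specifications
#' @slot pixelSize micrometers per stimulus pixel
#' @slot fieldShape integer (height, width) of the stimulus field in pixels
#' @export
setClass("Mosaic", representation(
  cells = "data.frame",
  pixelSize = "numeric",
  fieldShape = "integer"
))

setValidity("Mosaic", function(object) {
  cl <- object@cells
  msg <- character()
  need <- c("cell_id", "cell_type", "x", "y", "rf_radius", "polarity")
  if (!all(need %in% names(cl))) {
    return(paste("cells must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cl$cell_id)) msg <- c(msg, "duplicate cell ids")
  if (!all(cl$cell_type %in% CELL_TYPES)) msg <- c(msg, "unknown cell type")
  if (any(cl$rf_radius <= 0)) msg <- c(msg, "rf_radius must be > 0")
  if (any(cl$polarity != typePolarity(cl$cell_type))) {
    msg <- c(msg, "polarity inconsistent with cell_type")
  }
  hUm <- object@fieldShape[1] * object@pixelSize
  wUm <- object@fieldShape[2] * object@pixelSize
  if (any(cl$x < 0 | cl$x > wUm | cl$y < 0 | cl$y > hUm)) {
    msg <- c(msg, "receptive-field centers must lie inside the field")
  }
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "Mosaic", function(object) {
  tab <- table(object@cells$cell_type)
  cat("Mosaic:", nrow(object@cells), "cells on a",
      paste(object@fieldShape, collapse = " x "), "px field (",
      object@pixelSize, "um/px )\n")
  for (ty in names(tab)) cat("  ", ty, ":", tab[[ty]], "\n")
})

#' @describeIn Mosaic number of cells
#' @param x a Mosaic
#' @export
nCells <- function(x) nrow(x@cells)

#' Accessor for the cell table of a mosaic
#' @param x a Mosaic
#' @return data.frame of cell specifications
#' @export
mosaicCells <- function(x) x@cells

#' Fixational drift trajectory
#'
#' The latent eye-position variable: per-frame-transition displacement steps.
#' Both the continuous Gaussian steps (micrometers) and their integer pixel
#' discretization are stored; cumulative positions start at (0,0) at frame 1.
#'
#' @slot steps integer matrix [nFrames-1 x 2] of pixel steps (dy, dx)
#' @slot stepsUm numeric matrix [nFrames-1 x 2] of the continuous steps (um)
#' @slot nFrames number of stimulus frames
#' @slot diffusionConstant um^2/frame
#' @slot pixelSize micrometers per pixel
#' @export
setClass("DriftTrajectory", representation(
  steps = "matrix",
  stepsUm = "matrix",
  nFrames = "integer",
  diffusionConstant = "numeric",
  pixelSize = "numeric"
))

setValidity("DriftTrajectory", function(object) {
  if (nrow(object@steps) != object@nFrames - 1L) {
    return("length(steps) must equal nFrames - 1")
  }
  if (ncol(object@steps) != 2L) return("steps must have 2 columns (dy, dx)")
  if (any(object@steps != round(object@steps))) return("pixel steps must be integers")
  if (object@diffusionConstant < 0) return("diffusionConstant must be >= 0")
  TRUE
})

setMethod("show", "DriftTrajectory", function(object) {
  p <- positions(object)
  cat("DriftTrajectory:", object@nFrames, "frames, D =",
      object@diffusionConstant, "um^2/frame; final offset (",
      p[nrow(p), 1], ",", p[nrow(p), 2], ") px\n")
})

#' Cumulative pixel positions of a drift trajectory
#'
#' @param trajectory a DriftTrajectory
#' @return integer matrix [nFrames x 2]; row 1 is (0, 0)
#' @export
positions <- function(trajectory) {
  st <- trajectory@steps
  rbind(c(0L, 0L),
        cbind(cumsum(st[, 1]), cumsum(st[, 2])))
}

## continuous cumulative positions in micrometers
positionsUm <- function(trajectory) {
  st <- trajectory@stepsUm
  rbind(c(0, 0), cbind(cumsum(st[, 1]), cumsum(st[, 2])))
}

#' Stimulus movie on the 120 Hz frame grid
#'
#' Frames are stored as an array [H x W x nFrames] of grayscale values in
#' [0, 1]. \code{frameEdges} maps frames onto the 1 ms spike grid: frame f
#' covers spike bins \code{frameEdges[f] .. frameEdges[f+1]-1}, producing the
#' 8-9 ms pattern of a 120 Hz display on a 1 ms grid.
#'
#' @slot frames numeric array [H x W x nFrames]
#' @slot frameRate frames per second (120)
#' @slot frameEdges integer vector of 1-based bin boundaries, length nFrames+1
#' @slot trials data.frame of trial bookkeeping (may be empty)
#' @export
setClass("StimulusMovie", representation(
  frames = "array",
  frameRate = "numeric",
  frameEdges = "integer",
  trials = "data.frame"
))

setValidity("StimulusMovie", function(object) {
  nf <- dim(object@frames)[3]
  if (length(object@frameEdges) != nf + 1L) {
    return("frameEdges must have length nFrames + 1")
  }
  if (is.unsorted(object@frameEdges, strictly = TRUE)) {
    return("frameEdges must be strictly increasing")
  }
  rng <- range(object@frames)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) return("frames must lie in [0, 1]")
  TRUE
})

setMethod("show", "StimulusMovie", function(object) {
  d <- dim(object@frames)
  cat("StimulusMovie:", d[3], "frames of", d[1], "x", d[2], "px at",
      object@frameRate, "Hz (", movieDurationMs(object), "ms );",
      nrow(object@trials), "trials\n")
})

#' @describeIn StimulusMovie total duration on the 1 ms spike grid
#' @param movie a StimulusMovie
#' @export
movieDurationMs <- function(movie) {
  as.integer(movie@frameEdges[length(movie@frameEdges)] - movie@frameEdges[1])
}

#' Number of frames of a stimulus movie
#' @param movie a StimulusMovie
#' @export
nFrames <- function(movie) dim(movie@frames)[3]

#' Binary population spike raster on the 1 ms grid
#'
#' @slot spikes integer matrix [nCells x T] with entries in {0, 1}
#' @slot cellIds integer cell ids aligned to the mosaic
#' @export
setClass("BinnedSpikes", representation(
  spikes = "matrix",
  cellIds = "integer"
))

setValidity("BinnedSpikes", function(object) {
  if (!all(object@spikes %in% c(0L, 1L))) return("spike raster must be binary")
  if (length(object@cellIds) != nrow(object@spikes)) {
    return("cellIds must match raster rows")
  }
  TRUE
})

setMethod("show", "BinnedSpikes", function(object) {
  cat("BinnedSpikes:", nrow(object@spikes), "cells x", ncol(object@spikes),
      "ms;", sum(object@spikes), "spikes (",
      round(mean(rowSums(object@spikes)) / ncol(object@spikes) * 1000, 1),
      "Hz mean rate )\n")
})

#' Spike raster matrix accessor
#' @param x a BinnedSpikes
#' @export
spikeMatrix <- function(x) x@spikes

#' Population encoding model (LNBRC / LNBR / LNP family)
#'
#' One fitted or synthetic generalized linear encoding model per cell:
#' rank-1 space-time separable stimulus filter (spline spatial coefficients x
#' raised-cosine temporal coefficients), raised-cosine feedback filter,
#' per-neighbor raised-cosine coupling filters, and a scalar bias, plus the
#' shared bases and the neighbor graph.
#'
#' @slot cells named list of per-cell parameter lists
#' @slot bases list with elements temporal, feedback, coupling (RaisedCosineBasis)
#' @slot graph named list: per-cell integer neighbor ids
#' @slot mosaic the generating Mosaic
#' @slot family "lnbrc", "lnbr" or "lnp"
#' @export
setClass("PopulationModel", representation(
  cells = "list",
  bases = "list",
  graph = "list",
  mosaic = "Mosaic",
  family = "character"
))

setValidity("PopulationModel", function(object) {
  if (!object@family %in% c("lnbrc", "lnbr", "lnp")) return("unknown model family")
  ids <- mosaicCells(object@mosaic)$cell_id
  if (!all(names(object@cells) %in% as.character(ids))) {
    return("model cells must exist in the mosaic")
  }
  for (id in names(object@graph)) {
    nb <- object@graph[[id]]
    if (as.integer(id) %in% nb) return("a cell may not neighbor itself")
    if (!all(nb %in% ids)) return("neighbor ids must exist in the mosaic")
  }
  TRUE
})

setMethod("show", "PopulationModel", function(object) {
  nnb <- if (length(object@graph)) mean(lengths(object@graph)) else 0
  cat(toupper(object@family), "PopulationModel:", length(object@cells),
      "cells, mean", round(nnb, 1), "neighbors/cell\n")
})

#' Per-cell parameters of a population model
#' @param model a PopulationModel
#' @param cellId integer cell id
#' @export
cellParams <- function(model, cellId) model@cells[[as.character(cellId)]]

#' Weighted particle ensemble over drift trajectories
#'
#' Represents the variational distribution q over eye-position trajectories:
#' each particle is a cumulative integer-pixel trajectory prefix with a
#' normalized importance weight.
#'
#' @slot paths list of integer matrices [framesSoFar x 2] (cumulative positions)
#' @slot weights numeric, nonnegative, summing to 1
#' @slot pixelSize micrometers per pixel
#' @export
setClass("ParticleEnsemble", representation(
  paths = "list",
  weights = "numeric",
  pixelSize = "numeric"
))

setValidity("ParticleEnsemble", function(object) {
  if (length(object@paths) != length(object@weights)) {
    return("one weight per particle required")
  }
  if (any(object@weights < 0)) return("weights must be nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-12) return("weights must sum to 1")
  ln <- unique(vapply(object@paths, nrow, 1L))
  if (length(ln) > 1) return("all particle paths must share the current length")
  TRUE
})

setMethod("show", "ParticleEnsemble", function(object) {
  cat("ParticleEnsemble:", length(object@paths), "particles at frame",
      nrow(object@paths[[1]]), "; ESS =",
      round(1 / sum(object@weights^2), 2), "\n")
})

#' Effective sample size of a particle ensemble
#' @param ensemble a ParticleEnsemble
#' @export
effectiveSampleSize <- function(ensemble) 1 / sum(ensemble@weights^2)

#' Result of an iterative MAP reconstruction
#'
#' @slot image final image estimate (equals the last z iterate)
#' @slot xTrace list of x (likelihood-step) iterates
#' @slot zTrace list of z (prior-step) iterates
#' @slot nll per-iteration encoding negative log-likelihood of x
#' @slot priorEnergy per-iteration prior energy of z (NA if not applicable)
#' @slot schedule the HQS schedule used (list with lambda, rho)
#' @export
setClass("ReconstructionResult", representation(
  image = "matrix",
  xTrace = "list",
  zTrace = "list",
  nll = "numeric",
  priorEnergy = "numeric",
  schedule = "list"
))

setValidity("ReconstructionResult", function(object) {
  k <- length(object@zTrace)
  if (k > 0 && !identical(object@image, object@zTrace[[k]])) {
    return("image must equal the final z iterate")
  }
  if (length(object@xTrace) != k) return("x and z traces must have equal length")
  TRUE
})

setMethod("show", "ReconstructionResult", function(object) {
  cat("ReconstructionResult:", nrow(object@image), "x", ncol(object@image),
      "px;", length(object@zTrace), "HQS iterations; final NLL",
      signif(tail(object@nll, 1), 6), "\n")
})

#' Final image of a reconstruction result
#' @param x a ReconstructionResult
#' @export
reconImage <- function(x) x@image
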