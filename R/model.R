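## Population model construction: neighbor graphs, synthetic ground truth,
## spatial-filter utilities, cell-type subsetting.

#' Build the coupling neighbor graph of a mosaic
#'
#' Cell j is a neighbor of receiving cell i when their receptive-field
#' centers lie within a class-dependent multiple of the median nearest
#' neighbor distance: 2.0x for parasol receivers and 2.5x for midget
#' receivers, with the median computed within the receiving cell's own type
#' mosaic.
#'
#' @param mosaic a Mosaic
#' @param parasolMult multiplier for parasol receivers (default 2.0)
#' @param midgetMult multiplier for midget receivers (default 2.5)
#' @param homotypicOnly restrict coupling to same-type pairs (default FALSE)
#' @return named list mapping cell id -> integer vector of neighbor ids
#' @export
buildNeighborGraph <- function(mosaic, parasolMult = 2.0, midgetMult = 2.5,
                               homotypicOnly = FALSE) {
  cl <- mosaicCells(mosaic)
  nn <- medianNNDistance(mosaic)
  d <- as.matrix(dist(cl[, c("x", "y")]))
  graph <- list()
  for (i in seq_len(nrow(cl))) {
    ty <- cl$cell_type[i]
    mult <- if (typeClass(ty) == "parasol") parasolMult else midgetMult
    thr <- mult * nn[[ty]]
    if (is.na(thr)) {
      nb <- integer(0)
    } else {
      cand <- which(d[i, ] <= thr & seq_len(nrow(cl)) != i)
      if (homotypicOnly) cand <- cand[cl$cell_type[cand] == ty]
      nb <- cl$cell_id[cand]
    }
    graph[[as.character(cl$cell_id[i])]] <- as.integer(nb)
  }
  graph
}

defaultBases <- function() {
  list(temporal = raisedCosineBasis(5, 50),
       feedback = raisedCosineBasis(5, 50),
       coupling = raisedCosineBasis(4, 30))
}

## crop window around a cell's RF, clipped to the field
cellCrop <- function(cell, mosaic, factor = 2) {
  px <- mosaic@pixelSize
  h <- mosaic@fieldShape[1]; w <- mosaic@fieldShape[2]
  r0 <- round(cell$y / px); c0 <- round(cell$x / px)
  rad <- ceiling(factor * cell$rf_radius / px)
  rows <- max(1, r0 - rad):min(h, r0 + rad)
  cols <- max(1, c0 - rad):min(w, c0 + rad)
  list(rows = rows, cols = cols)
}

## full-field spatial filter (H x W) from spline coefficients
spatialField <- function(params, fieldShape) {
  sb <- params$spatial$basis
  out <- matrix(0, fieldShape[1], fieldShape[2])
  vals <- sb$matrix %*% params$spatial$coef
  out[as.matrix(expand.grid(sb$cropRows, sb$cropCols))] <- vals
  out
}

## linear indices + values of the spatial filter on the full field;
## `threshold` (relative to the peak) optionally drops negligible spline
## tails to shrink gather tables (used by the reconstruction likelihoods)
spatialIdxVal <- function(params, fieldShape, threshold = 0) {
  sb <- params$spatial$basis
  vals <- as.numeric(sb$matrix %*% params$spatial$coef)
  thr <- threshold * max(abs(vals), 1e-300)
  grid <- expand.grid(r = sb$cropRows, c = sb$cropCols)
  keep <- abs(vals) > thr
  list(r = grid$r[keep], c = grid$c[keep],
       idx = grid$r[keep] + (grid$c[keep] - 1L) * fieldShape[1],
       val = vals[keep])
}

## 1 ms temporal kernel of the cell's stimulus filter
temporalKernel <- function(model, params) {
  basisKernel(model@bases$temporal, params$temporal)
}

## least-squares projection of a continuous kernel shape onto a basis
projectKernel <- function(basis, shape) {
  t <- seq_len(basis$timeSpanMs)
  coef <- qr.coef(qr(t(basis$matrix)), shape(t))
  coef[is.na(coef)] <- 0
  coef
}

#' Construct a synthetic ground-truth LNBRC population model
#'
#' Builds, for every cell of the mosaic, a Gaussian center receptive field
#' (SD = rf_radius / 2, signed by ON/OFF polarity) projected onto the spline
#' spatial basis, a biphasic unit-norm temporal kernel (faster and more
#' transient for parasol cells), a strong short-lag negative (refractory)
#' feedback filter, excitatory short-latency coupling for a seeded random
#' subset of close same-type neighbor pairs (all other coupling filters are
#' exactly zero), and a bias set from the target baseline firing rate.
#'
#' @param mosaic a Mosaic
#' @param bases temporal/feedback/coupling bases (default \code{defaultBases()})
#' @param gain peak drive of the stimulus filter (generator-signal units per
#'   unit contrast; default 8, giving naturalistic 20-60 Hz drift-stimulus rates)
#' @param baselineRateHz baseline firing rate set by the bias (default 15)
#' @param couplingProb probability that a close same-type neighbor pair is
#'   functionally coupled (default 0.5)
#' @param couplingStrength peak coupling kernel weight (default 0.8)
#' @param cropFactor crop half-width in units of rf_radius (default 2)
#' @param knotSpacing spline knot spacing in pixels (default 3)
#' @param seed integer seed (coupling-pair selection)
#' @return a \linkS4class{PopulationModel} with family "lnbrc"
#' @export
makeSyntheticModel <- function(mosaic, bases = defaultBases(), gain = 8,
                               baselineRateHz = 15, couplingProb = 0.5,
                               couplingStrength = 0.8, cropFactor = 2,
                               knotSpacing = 3, seed = 1) {
  cl <- mosaicCells(mosaic)
  graph <- buildNeighborGraph(mosaic)
  px <- mosaic@pixelSize
  nn <- medianNNDistance(mosaic)
  d <- as.matrix(dist(cl[, c("x", "y")]))
  withSeed(seed, {
    ## decide functional coupling per unordered close same-type pair
    coupled <- matrix(FALSE, nrow(cl), nrow(cl))
    for (i in seq_len(nrow(cl))) {
      for (j in seq_len(nrow(cl))) {
        if (j <= i) next
        ty <- cl$cell_type[i]
        if (cl$cell_type[j] != ty) next
        if (is.na(nn[[ty]]) || d[i, j] > 1.3 * nn[[ty]]) next
        coupled[i, j] <- coupled[j, i] <- runif(1) < couplingProb
      }
    }
    cells <- list()
    for (i in seq_len(nrow(cl))) {
      cell <- cl[i, ]
      crop <- cellCrop(cell, mosaic, cropFactor)
      sb <- splineSpatialBasis(crop$rows, crop$cols, knotSpacing)
      sig <- cell$rf_radius / 2 / px
      g <- outer(crop$rows - cell$y / px, crop$cols - cell$x / px,
                 function(dr, dc) exp(-(dr^2 + dc^2) / (2 * sig^2)))
      g <- g / sqrt(sum(g^2)) * gain * cell$polarity
      coefs <- qr.coef(qr(sb$matrix), as.numeric(g))
      coefs[is.na(coefs)] <- 0
      ## canonical kernels projected onto whatever bases are in use:
      ## biphasic stimulus time course (faster, more transient for parasols),
      ## decaying refractory feedback, brief excitatory coupling
      tcoef <- projectKernel(bases$temporal, function(t) {
        if (typeClass(cell$cell_type) == "parasol") {
          dgamma(t, 3, rate = 0.45) - 0.8 * dgamma(t, 5, rate = 0.3)
        } else {
          dgamma(t, 4, rate = 0.35) - 0.5 * dgamma(t, 6, rate = 0.22)
        }
      })
      k <- basisKernel(bases$temporal, tcoef)
      sgn <- sign(k[which.max(abs(k))])
      tcoef <- tcoef / sqrt(sum(k^2)) * sgn
      fcoef <- projectKernel(bases$feedback, function(t) -8 * exp(-t / 8))
      cplShape <- projectKernel(bases$coupling, function(t) exp(-(t - 2)^2 / 12))
      kc <- basisKernel(bases$coupling, cplShape)
      cplShape <- cplShape / max(kc)
      cpl <- list()
      for (j in graph[[as.character(cell$cell_id)]]) {
        jj <- which(cl$cell_id == j)
        cpl[[as.character(j)]] <- if (coupled[i, jj]) {
          couplingStrength * cplShape
        } else {
          numeric(bases$coupling$nBasis)
        }
      }
      cells[[as.character(cell$cell_id)]] <- list(
        cell_id = cell$cell_id,
        cell_type = cell$cell_type,
        spatial = list(basis = sb, coef = coefs),
        temporal = tcoef,
        feedback = fcoef,
        coupling = cpl,
        bias = qlogis(baselineRateHz / 1000)
      )
    }
    new("PopulationModel", cells = cells, bases = bases, graph = graph,
        mosaic = mosaic, family = "lnbrc")
  })
}

#' Restrict a model (and optionally spikes) to selected cell types
#'
#' Drops all cells of other types, restricts the neighbor graph and coupling
#' filters to edges within the subset, and subsets the spike raster rows
#' consistently.
#'
#' @param model a PopulationModel
#' @param cellTypes character vector of types to keep
#' @param spikes optional BinnedSpikes aligned to the model
#' @return list with elements \code{model} and (if given) \code{spikes}
#' @export
subsetPopulation <- function(model, cellTypes, spikes = NULL) {
  cl <- mosaicCells(model@mosaic)
  if (!all(cellTypes %in% cl$cell_type)) {
    stop("requested cell types not present: ",
         paste(setdiff(cellTypes, cl$cell_type), collapse = ", "))
  }
  keep <- cl$cell_type %in% cellTypes
  if (!any(keep)) stop("empty cell-type subset")
  keepIds <- cl$cell_id[keep]
  mos <- new("Mosaic", cells = {
    x <- cl[keep, ]
    rownames(x) <- NULL
    x
  }, pixelSize = model@mosaic@pixelSize, fieldShape = model@mosaic@fieldShape)
  cells <- model@cells[as.character(keepIds)]
  graph <- list()
  for (id in as.character(keepIds)) {
    nb <- intersect(model@graph[[id]], keepIds)
    graph[[id]] <- as.integer(nb)
    cells[[id]]$coupling <- cells[[id]]$coupling[as.character(nb)]
  }
  out <- list(model = new("PopulationModel", cells = cells,
                          bases = model@bases, graph = graph, mosaic = mos,
                          family = model@family))
  if (!is.null(spikes)) {
    rows <- match(keepIds, spikes@cellIds)
    out$spikes <- new("BinnedSpikes",
                      spikes = spikes@spikes[rows, , drop = FALSE],
                      cellIds = as.integer(keepIds))
  }
  out
}
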