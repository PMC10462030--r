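## Regularized maximum-likelihood fitting of LNBRC / LNBR / LNP models.

#' Fit configuration for the encoding models
#'
#' @param l1Weight L1 penalty on the spatial spline coefficients
#' @param groupL21Weight L2,1 group penalty on each neighbor's coupling
#'   coefficients
#' @param maxOuter outer space/time alternations (default 2, plus the
#'   final polish pass; the warm-started stages settle quickly)
#' @param outerTol relative objective tolerance across outer alternations
#' @param fistaMaxIter inner FISTA iteration cap per stage
#' @param fistaTol inner relative-objective tolerance
#' @param cropFactor spatial crop half-width in rf_radius units
#' @param knotSpacing spline knot spacing in pixels; NA (default) scales the
#'   spacing to each cell's receptive-field size
#' @param polishIter iteration budget of the final spatial-stage polish pass
#'   (drives converged group-lasso zeros)
#' @param seed integer seed (probe-cell sampling in the grid search)
#' @return list of class \code{fitConfig}
#' @export
fitConfig <- function(l1Weight = 3, groupL21Weight = 200, maxOuter = 2,
                      outerTol = 1e-5, fistaMaxIter = 120, fistaTol = 5e-6,
                      cropFactor = 1.5, knotSpacing = NA, polishIter = 300,
                      seed = 1) {
  stopifnot(l1Weight >= 0, groupL21Weight >= 0, outerTol > 0, fistaTol > 0)
  structure(list(l1Weight = l1Weight, groupL21Weight = groupL21Weight,
                 maxOuter = maxOuter, outerTol = outerTol,
                 fistaMaxIter = fistaMaxIter, fistaTol = fistaTol,
                 cropFactor = cropFactor, knotSpacing = knotSpacing,
                 polishIter = polishIter, seed = seed),
            class = "fitConfig")
}

## power iteration estimate of the logistic-loss Lipschitz constant
lipschitzEstimate <- function(X) {
  v <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (i in 1:6) {
    v <- crossprod(X, X %*% v)
    v <- v / max(sqrt(sum(v^2)), 1e-12)
  }
  lam <- sum((X %*% v)^2)
  max(lam / 4, 1e-8)
}

## one FISTA stage of the Bernoulli model: eta = X beta, L1 on l1Idx,
## group L2,1 on each element of groups
bernoulliStage <- function(X, s, beta0, l1Idx, l1w, groups, l21w, config) {
  ## standardize columns (unit RMS) for first-order conditioning; penalties
  ## are defined in the standardized space (as in glmnet), and coefficients
  ## are mapped back afterwards
  sc <- sqrt(colMeans(X^2))
  sc[sc < 1e-12] <- 1
  X <- sweep(X, 2, sc, "/")
  beta0 <- beta0 * sc
  f <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(softplus(eta) - s * eta)
  }
  grad <- function(b) {
    eta <- as.numeric(X %*% b)
    as.numeric(crossprod(X, plogis(eta) - s))
  }
  pen <- function(b) {
    p <- 0
    if (length(l1Idx) && l1w > 0) p <- p + l1w * sum(abs(b[l1Idx]))
    if (length(groups) && l21w > 0) {
      p <- p + l21w * sum(vapply(groups, function(g) sqrt(sum(b[g]^2)), 0))
    }
    p
  }
  prox <- function(v, step) {
    if (length(l1Idx) && l1w > 0) v[l1Idx] <- proxL1(v[l1Idx], step * l1w)
    if (length(groups) && l21w > 0) v <- proxGroupL21(v, groups, step * l21w)
    v
  }
  ## local curvature of the Bernoulli loss is p(1-p) << 1/4 at realistic
  ## rates; start the line search near it and let backtracking correct
  p0 <- min(max(mean(s), 1e-3), 0.5)
  L0 <- lipschitzEstimate(X) * 4 * p0 * (1 - p0)
  res <- fistaSolve(beta0, f, grad, prox, pen, L0 = L0,
                    maxIter = config$fistaMaxIter, tol = config$fistaTol)
  res$x <- res$x / sc
  res
}

## per-cell precomputation shared by both stages
cellFitContext <- function(spikes, movie, mosaic, graph, bases, config,
                           cellRow, coupling = TRUE) {
  crop <- cellCrop(cellRow, mosaic, config$cropFactor)
  ks <- config$knotSpacing
  if (is.na(ks)) {
    ks <- max(2, round(0.75 * cellRow$rf_radius / mosaic@pixelSize))
  }
  sb <- splineSpatialBasis(crop$rows, crop$cols, ks)
  fs <- mosaic@fieldShape
  nf <- nFrames(movie)
  fr <- matrix(movie@frames, prod(fs), nf)
  lin <- as.matrix(expand.grid(sb$cropRows, sb$cropCols))
  lin <- lin[, 1] + (lin[, 2] - 1L) * fs[1]
  FsF <- crossprod(fr[lin, , drop = FALSE] - GRAY, sb$matrix)
  FsMs <- expandFramesToMs(t(FsF), movie@frameEdges)
  i <- match(cellRow$cell_id, spikes@cellIds)
  s <- spikes@spikes[i, ]
  Bf <- bases$feedback$matrix
  Xfb <- vapply(seq_len(nrow(Bf)),
                function(rr) causalFilter(s, Bf[rr, ]), numeric(length(s)))
  nbrs <- if (coupling) graph[[as.character(cellRow$cell_id)]] else integer(0)
  Bc <- bases$coupling$matrix
  Xcpl <- lapply(nbrs, function(j) {
    r <- match(j, spikes@cellIds)
    vapply(seq_len(nrow(Bc)),
           function(rr) causalFilter(spikes@spikes[r, ], Bc[rr, ]),
           numeric(length(s)))
  })
  names(Xcpl) <- as.character(nbrs)
  list(sb = sb, FsMs = FsMs, s = s, Xfb = Xfb, Xcpl = Xcpl, nbrs = nbrs)
}

fitOneCellBernoulli <- function(ctx, bases, config) {
  nS <- ctx$sb$nCoef
  nT <- bases$temporal$nBasis
  nF <- ncol(ctx$Xfb)
  nC <- bases$coupling$nBasis
  nNbr <- length(ctx$Xcpl)
  Tn <- length(ctx$s)
  ## initialization: zero filters, smooth unit-norm temporal kernel, bias at
  ## the logit of the observed mean rate
  wS <- numeric(nS)
  wT <- rep(1, nT)
  wT <- wT / sqrt(sum(basisKernel(bases$temporal, wT)^2))
  wF <- numeric(nF)
  wC <- lapply(seq_len(nNbr), function(i) numeric(nC))
  b <- qlogis(min(max(mean(ctx$s), 1 / Tn), 1 - 1 / Tn))
  groupsOf <- function(lead) if (nNbr) lapply(seq_len(nNbr), function(i) {
    lead + (i - 1) * nC + seq_len(nC)
  }) else list()
  Xhist <- cbind(ctx$Xfb, do.call(cbind, c(ctx$Xcpl, list(matrix(0, Tn, 0)))), 1)
  stageA <- function(wS, wT, wF, wC, b, maxIter) {
    kT <- basisKernel(bases$temporal, wT)
    Xspat <- apply(ctx$FsMs, 1, function(row) causalFilter(row, kT))
    cfg <- config
    cfg$fistaMaxIter <- maxIter
    res <- bernoulliStage(cbind(Xspat, Xhist), ctx$s, c(wS, wF, unlist(wC), b),
                          seq_len(nS), config$l1Weight, groupsOf(nS + nF),
                          config$groupL21Weight, cfg)
    beta <- res$x
    list(wS = beta[seq_len(nS)], wF = beta[nS + seq_len(nF)],
         wC = lapply(seq_len(nNbr), function(i) {
           beta[nS + nF + (i - 1) * nC + seq_len(nC)]
         }),
         b = beta[length(beta)], obj = res$obj, converged = res$converged)
  }
  ## full regularized objective at the current parameters
  objective <- function(wS, wT, wF, wC, b) {
    kT <- basisKernel(bases$temporal, wT)
    svMs <- as.numeric(crossprod(ctx$FsMs, wS))
    eta <- causalFilter(svMs, kT) + as.numeric(Xhist %*% c(wF, unlist(wC), b))
    sum(softplus(eta) - ctx$s * eta) + config$l1Weight * sum(abs(wS)) +
      config$groupL21Weight * sum(vapply(wC, function(g) sqrt(sum(g^2)), 0))
  }
  best <- NULL
  trace <- numeric(0)
  conv <- TRUE
  for (outer in seq_len(config$maxOuter)) {
    resA <- stageA(wS, wT, wF, wC, b, config$fistaMaxIter)
    wS <- resA$wS; wF <- resA$wF; b <- resA$b
    if (nNbr) wC <- resA$wC
    ## stage B: temporal block (spatial fixed)
    svMs <- as.numeric(crossprod(ctx$FsMs, wS))
    Bt <- bases$temporal$matrix
    Xtemp <- vapply(seq_len(nT), function(rr) causalFilter(svMs, Bt[rr, ]),
                    numeric(Tn))
    XB <- cbind(Xtemp, Xhist)
    resB <- bernoulliStage(XB, ctx$s, c(wT, wF, unlist(wC), b), integer(0), 0,
                           groupsOf(nT + nF), config$groupL21Weight, config)
    betaB <- resB$x
    wT <- betaB[seq_len(nT)]
    wF <- betaB[nT + seq_len(nF)]
    if (nNbr) wC <- lapply(seq_len(nNbr), function(i) {
      betaB[nT + nF + (i - 1) * nC + seq_len(nC)]
    })
    b <- betaB[length(betaB)]
    ## fix the rank-1 scale split: unit-L2 temporal kernel, positive peak
    kT <- basisKernel(bases$temporal, wT)
    sc <- sqrt(sum(kT^2))
    if (sc > 0) {
      sgn <- sign(kT[which.max(abs(kT))])
      wT <- wT / sc * sgn
      wS <- wS * sc * sgn
    }
    objNew <- objective(wS, wT, wF, wC, b)
    trace <- c(trace, objNew)
    conv <- resA$converged && resB$converged
    if (is.null(best) || objNew < best$obj) {
      best <- list(wS = wS, wT = wT, wF = wF, wC = wC, b = b, obj = objNew)
    }
    if (outer > 1 && abs(trace[outer - 1] - objNew) /
          max(1, abs(trace[outer - 1])) < config$outerTol) break
  }
  ## polish: converge the penalized spatial/coupling stage at the best
  ## iterate (this is what drives unnecessary coupling groups to exact zero)
  wS <- best$wS; wT <- best$wT; wF <- best$wF; wC <- best$wC; b <- best$b
  resP <- stageA(wS, wT, wF, wC, b, config$polishIter)
  objP <- objective(resP$wS, wT, resP$wF, resP$wC, resP$b)
  if (objP <= best$obj) {
    best <- list(wS = resP$wS, wT = wT, wF = resP$wF, wC = resP$wC,
                 b = resP$b, obj = objP)
    conv <- resP$converged
  }
  trace <- c(trace, best$obj)
  wC <- best$wC
  names(wC) <- names(ctx$Xcpl)
  list(spatial = list(basis = ctx$sb, coef = best$wS), temporal = best$wT,
       feedback = best$wF, coupling = wC, bias = best$b,
       fit = list(objective = best$obj, trace = trace, converged = conv))
}

#' Fit coupled LNBRC encoding models to a population raster
#'
#' One model per cell, fitted independently by alternating FISTA between the
#' spatial block (stimulus spatial filter + feedback + coupling + bias, with
#' an L1 penalty on the spatial spline coefficients and a group L2,1 penalty
#' per neighbor's coupling coefficients) and the temporal block (stimulus
#' time course + feedback + coupling + bias). The rank-1 scale ambiguity is
#' resolved by a unit-norm, positive-peak temporal kernel.
#'
#' @param spikes a BinnedSpikes raster
#' @param movie the StimulusMovie the spikes were recorded to
#' @param mosaic the Mosaic (receptive-field geometry)
#' @param graph neighbor graph (default \code{buildNeighborGraph(mosaic)})
#' @param bases temporal/feedback/coupling bases
#' @param config a \code{\link{fitConfig}}
#' @param cellIds cells to fit (default: all cells in the raster)
#' @param verbose print per-cell progress
#' @return a \linkS4class{PopulationModel} (family "lnbrc"); per-cell
#'   \code{$fit} carries objective traces and a convergence flag (models are
#'   returned at the best iterate with \code{converged = FALSE} when the
#'   iteration budget was exhausted)
#' @export
fitLNBRC <- function(spikes, movie, mosaic, graph = buildNeighborGraph(mosaic),
                     bases = defaultBases(), config = fitConfig(),
                     cellIds = spikes@cellIds, verbose = FALSE) {
  fitBernoulliFamily(spikes, movie, mosaic, graph, bases, config, cellIds,
                     coupling = TRUE, family = "lnbrc", verbose = verbose)
}

#' Fit uncoupled LNBR encoding models
#'
#' Identical to \code{\link{fitLNBRC}} with the neighbor coupling filters
#' removed; captures stimulus drive and spike-history structure only.
#'
#' @inheritParams fitLNBRC
#' @return a \linkS4class{PopulationModel} (family "lnbr")
#' @export
fitLNBR <- function(spikes, movie, mosaic, bases = defaultBases(),
                    config = fitConfig(), cellIds = spikes@cellIds,
                    verbose = FALSE) {
  fitBernoulliFamily(spikes, movie, mosaic, graph = list(), bases, config,
                     cellIds, coupling = FALSE, family = "lnbr",
                     verbose = verbose)
}

fitBernoulliFamily <- function(spikes, movie, mosaic, graph, bases, config,
                               cellIds, coupling, family, verbose) {
  if (ncol(spikes@spikes) != movieDurationMs(movie)) {
    stop("movie duration does not match the spike raster")
  }
  cl <- mosaicCells(mosaic)
  cells <- list()
  for (id in cellIds) {
    row <- cl[cl$cell_id == id, ]
    ctx <- cellFitContext(spikes, movie, mosaic, graph, bases, config, row,
                          coupling = coupling)
    fit <- fitOneCellBernoulli(ctx, bases, config)
    fit$cell_id <- row$cell_id
    fit$cell_type <- row$cell_type
    if (!fit$fit$converged) {
      warning("cell ", id, ": iteration budget reached; returning best iterate")
    }
    cells[[as.character(id)]] <- fit
    if (verbose) message("fitted cell ", id, " (", row$cell_type, ")")
  }
  useGraph <- if (coupling) {
    lapply(graph[as.character(cellIds)], function(nb) {
      as.integer(intersect(nb, cellIds))
    })
  } else {
    setNames(rep(list(integer(0)), length(cellIds)), as.character(cellIds))
  }
  new("PopulationModel", cells = cells, bases = bases, graph = useGraph,
      mosaic = mosaic, family = family)
}

#' Held-out encoding NLL of a fitted model
#'
#' @param model a PopulationModel
#' @param spikes held-out BinnedSpikes
#' @param movie held-out StimulusMovie
#' @param cellIds cells to evaluate (default all modeled cells)
#' @return mean per-cell NLL (penalty-free) on the held-out data
#' @export
heldOutNLL <- function(model, spikes, movie, cellIds = NULL) {
  ids <- cellIds %||% as.integer(names(model@cells))
  mean(vapply(ids, function(id) lnbrcNLL(model, spikes, movie, id), 0))
}

#' Split a recording into contiguous train and test segments
#'
#' The trailing \code{testFraction} of trials (or frames, when the movie has
#' no trial table) becomes the held-out test partition.
#'
#' @param spikes BinnedSpikes
#' @param movie StimulusMovie
#' @param testFraction fraction held out (default 0.2)
#' @return list with \code{train} and \code{test}, each (spikes, movie)
#' @export
trainTestSplit <- function(spikes, movie, testFraction = 0.2) {
  nf <- nFrames(movie)
  if (nrow(movie@trials)) {
    nTr <- nrow(movie@trials)
    cutTr <- max(1, min(nTr - 1, floor(nTr * (1 - testFraction))))
    cutFrame <- movie@trials$frame_end[cutTr]
  } else {
    cutFrame <- max(1, min(nf - 1, floor(nf * (1 - testFraction))))
  }
  list(train = sliceRecording(spikes, movie, 1L, cutFrame),
       test = sliceRecording(spikes, movie, cutFrame + 1L, nf))
}

sliceRecording <- function(spikes, movie, fromFrame, toFrame) {
  edges <- movie@frameEdges
  bins <- edges[fromFrame]:(edges[toFrame + 1] - 1)
  frames <- movie@frames[, , fromFrame:toFrame, drop = FALSE]
  tri <- movie@trials
  if (nrow(tri)) {
    tri <- tri[tri$frame_start >= fromFrame & tri$frame_end <= toFrame, , drop = FALSE]
    if (nrow(tri)) {
      off <- fromFrame - 1L
      offB <- edges[fromFrame] - 1L
      tri$frame_start <- tri$frame_start - off
      tri$frame_end <- tri$frame_end - off
      tri$bin_start <- tri$bin_start - offB
      tri$bin_end <- tri$bin_end - offB
      tri$onset_bin <- tri$onset_bin - offB
    }
  }
  mv <- new("StimulusMovie", frames = frames, frameRate = movie@frameRate,
            frameEdges = as.integer(edges[fromFrame:(toFrame + 1)] - edges[fromFrame] + 1L),
            trials = tri)
  sp <- new("BinnedSpikes", spikes = spikes@spikes[, bins, drop = FALSE],
            cellIds = spikes@cellIds)
  list(spikes = sp, movie = mv)
}

#' Grid search for the regularization weights
#'
#' Mirrors the per-type hyperparameter selection procedure: for each
#' candidate (l1, l21) pair, probe models are fitted on the training segment
#' for up to \code{nProbePerType} randomly chosen cells of each type, and the
#' pair minimizing the mean held-out NLL is returned (ties broken toward the
#' smallest (l1, l21) lexicographically).
#'
#' @param spikes BinnedSpikes
#' @param movie StimulusMovie
#' @param mosaic Mosaic
#' @param grid data.frame with columns l1, l21
#' @param config base \code{\link{fitConfig}}
#' @param nProbePerType probe cells per type (default 4)
#' @param testFraction held-out fraction (default 0.2)
#' @param seed probe sampling seed
#' @return list: \code{l1}, \code{l21}, \code{table} (grid with mean NLL)
#' @export
gridSearchHyperparams <- function(spikes, movie, mosaic, grid,
                                  config = fitConfig(), nProbePerType = 4,
                                  testFraction = 0.2, seed = 1) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  parts <- trainTestSplit(spikes, movie, testFraction)
  cl <- mosaicCells(mosaic)
  probes <- withSeed(seed, {
    unlist(lapply(split(cl$cell_id, cl$cell_type), function(ids) {
      if (length(ids) <= nProbePerType) ids else sample(ids, nProbePerType)
    }), use.names = FALSE)
  })
  grid <- grid[order(grid$l1, grid$l21), , drop = FALSE]
  grid$meanNLL <- NA_real_
  for (k in seq_len(nrow(grid))) {
    cfg <- config
    cfg$l1Weight <- grid$l1[k]
    cfg$groupL21Weight <- grid$l21[k]
    m <- fitLNBRC(parts$train$spikes, parts$train$movie, mosaic,
                  config = cfg, cellIds = probes)
    grid$meanNLL[k] <- heldOutNLL(m, parts$test$spikes, parts$test$movie)
  }
  best <- which.min(grid$meanNLL) # first minimum = lexicographically smallest
  list(l1 = grid$l1[best], l21 = grid$l21[best], table = grid)
}

## ---------------------------------------------------------------------------
## LNP benchmark (Poisson, frame-resolution bins, exponential nonlinearity)

#' Count spikes in stimulus-frame (8.33 ms) bins
#'
#' @param spikes BinnedSpikes on the 1 ms grid
#' @param movie StimulusMovie providing the frame-to-bin map
#' @return integer matrix [nCells x nFrames]
#' @export
countsPerFrame <- function(spikes, movie) {
  edges <- movie@frameEdges
  nf <- nFrames(movie)
  grp <- rep(seq_len(nf), diff(edges))
  out <- t(rowsum(t(spikes@spikes), grp))
  rownames(out) <- spikes@cellIds
  out
}

## frame-domain filtering including lag 0: y[f] = sum_{tau>=0} k[tau+1] x[f-tau]
frameFilter0 <- function(x, kernel) {
  Tn <- length(x)
  L <- length(kernel)
  y <- numeric(Tn)
  for (tau in 0:(L - 1)) {
    if (tau == 0) y <- y + kernel[1] * x
    else y[(tau + 1):Tn] <- y[(tau + 1):Tn] + kernel[tau + 1] * x[seq_len(Tn - tau)]
  }
  y
}

lnpBases <- function() list(temporal = raisedCosineBasis(4, 8, stretch = 2),
                            feedback = raisedCosineBasis(1, 1),
                            coupling = raisedCosineBasis(1, 1))

#' Poisson (LNP) negative log-likelihood of one cell
#'
#' \code{NLL = sum_f [exp(g[f]) - g[f] s[f]]} with
#' \code{g[f] = m' v[f] + b} on the frame grid (lag-0 inclusive) and an
#' exponential nonlinearity.
#'
#' @param model an LNP PopulationModel
#' @param counts matrix of per-frame spike counts [nCells x nFrames]
#' @param movie StimulusMovie
#' @param cellId cell id
#' @param gradient also return the parameter gradient
#' @return scalar NLL or list(nll, grad)
#' @export
lnpNLL <- function(model, counts, movie, cellId, gradient = FALSE) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  params <- cellParams(model, cellId)
  des <- lnpDesigns(model, params, movie)
  i <- match(as.character(cellId), rownames(counts))
  if (is.na(i)) stop("cell ", cellId, " not present in the count matrix")
  s <- counts[i, ]
  kT <- basisKernel(model@bases$temporal, params$temporal)
  eta <- frameFilter0(as.numeric(des$FsF %*% params$spatial$coef), kT) + params$bias
  mu <- exp(pmin(eta, 50))
  nll <- sum(mu - s * eta)
  if (!gradient) return(nll)
  r <- mu - s
  Xspat <- apply(des$FsF, 2, function(col) frameFilter0(col, kT))
  svF <- as.numeric(des$FsF %*% params$spatial$coef)
  Bt <- model@bases$temporal$matrix
  Xtemp <- vapply(seq_len(nrow(Bt)), function(rr) frameFilter0(svF, Bt[rr, ]),
                  numeric(length(svF)))
  list(nll = nll,
       grad = list(spatial = as.numeric(crossprod(Xspat, r)),
                   temporal = as.numeric(crossprod(Xtemp, r)),
                   bias = sum(r)))
}

lnpDesigns <- function(model, params, movie) {
  fs <- model@mosaic@fieldShape
  sb <- params$spatial$basis
  fr <- matrix(movie@frames, prod(fs), nFrames(movie))
  lin <- as.matrix(expand.grid(sb$cropRows, sb$cropCols))
  lin <- lin[, 1] + (lin[, 2] - 1L) * fs[1]
  list(FsF = crossprod(fr[lin, , drop = FALSE] - GRAY, sb$matrix))
}

#' Fit benchmark LNP models
#'
#' Rank-1 space-time separable stimulus filter, exponential nonlinearity,
#' Poisson spiking on frame-resolution (8.33 ms) bins; L1 on the spatial
#' spline coefficients; fitted by alternating FISTA like the LNBRC.
#'
#' @param spikes BinnedSpikes on the 1 ms grid (counted into frame bins);
#'   may be NULL when \code{counts} is given directly
#' @param movie StimulusMovie
#' @param mosaic Mosaic
#' @param config \code{\link{fitConfig}} (l1Weight applies; coupling ignored)
#' @param cellIds cells to fit
#' @param counts optional per-frame count matrix (rownames = cell ids)
#' @return a \linkS4class{PopulationModel} (family "lnp") on frame-resolution
#'   temporal bases
#' @export
fitLNP <- function(spikes, movie, mosaic, config = fitConfig(l1Weight = 1),
                   cellIds = NULL, counts = NULL) {
  if (is.null(counts)) counts <- countsPerFrame(spikes, movie)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  cellIds <- cellIds %||% as.integer(rownames(counts))
  bases <- lnpBases()
  cl <- mosaicCells(mosaic)
  fs <- mosaic@fieldShape
  fr <- matrix(movie@frames, prod(fs), nFrames(movie))
  cells <- list()
  for (id in cellIds) {
    row <- cl[cl$cell_id == id, ]
    crop <- cellCrop(row, mosaic, config$cropFactor)
    ks <- config$knotSpacing
    if (is.na(ks)) ks <- max(2, round(0.75 * row$rf_radius / mosaic@pixelSize))
    sb <- splineSpatialBasis(crop$rows, crop$cols, ks)
    lin <- as.matrix(expand.grid(sb$cropRows, sb$cropCols))
    lin <- lin[, 1] + (lin[, 2] - 1L) * fs[1]
    FsF <- crossprod(fr[lin, , drop = FALSE] - GRAY, sb$matrix)
    s <- counts[as.character(id), ]
    nS <- sb$nCoef
    nT <- bases$temporal$nBasis
    wS <- numeric(nS)
    wT <- rep(1, nT)
    wT <- wT / sqrt(sum(basisKernel(bases$temporal, wT)^2))
    b <- log(max(mean(s), 1e-3))
    poisStage <- function(X, beta0, l1Idx) {
      f <- function(bb) {
        eta <- as.numeric(X %*% bb)
        sum(exp(pmin(eta, 50)) - s * eta)
      }
      grad <- function(bb) {
        eta <- as.numeric(X %*% bb)
        as.numeric(crossprod(X, exp(pmin(eta, 50)) - s))
      }
      pen <- function(bb) config$l1Weight * sum(abs(bb[l1Idx]))
      prox <- function(v, step) {
        if (length(l1Idx)) v[l1Idx] <- proxL1(v[l1Idx], step * config$l1Weight)
        v
      }
      fistaSolve(beta0, f, grad, prox, pen,
                 L0 = lipschitzEstimate(X) * 4 * max(1, max(s)),
                 maxIter = config$fistaMaxIter, tol = config$fistaTol)
    }
    for (outer in seq_len(config$maxOuter)) {
      kT <- basisKernel(bases$temporal, wT)
      Xspat <- apply(FsF, 2, function(col) frameFilter0(col, kT))
      resA <- poisStage(cbind(Xspat, 1), c(wS, b), seq_len(nS))
      wS <- resA$x[seq_len(nS)]
      b <- resA$x[nS + 1]
      svF <- as.numeric(FsF %*% wS)
      Bt <- bases$temporal$matrix
      Xtemp <- vapply(seq_len(nT), function(rr) frameFilter0(svF, Bt[rr, ]),
                      numeric(length(svF)))
      resB <- poisStage(cbind(Xtemp, 1), c(wT, b), integer(0))
      wT <- resB$x[seq_len(nT)]
      b <- resB$x[nT + 1]
      kT <- basisKernel(bases$temporal, wT)
      sc <- sqrt(sum(kT^2))
      if (sc > 0) {
        sgn <- sign(kT[which.max(abs(kT))])
        wT <- wT / sc * sgn
        wS <- wS * sc * sgn
      }
    }
    cells[[as.character(id)]] <- list(
      cell_id = row$cell_id, cell_type = row$cell_type,
      spatial = list(basis = sb, coef = wS), temporal = wT,
      feedback = NULL, coupling = list(), bias = b,
      fit = list(objective = resB$obj))
  }
  graph <- setNames(rep(list(integer(0)), length(cellIds)), as.character(cellIds))
  new("PopulationModel", cells = cells, bases = bases, graph = graph,
      mosaic = mosaic, family = "lnp")
}
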