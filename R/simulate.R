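## Generator signals, Bernoulli likelihood, and population spike simulation.

## per-cell stimulus drive on the 1 ms grid (strictly causal)
stimulusDrive <- function(model, params, movie) {
  fs <- model@mosaic@fieldShape
  iv <- spatialIdxVal(params, fs)
  nf <- nFrames(movie)
  fr <- matrix(movie@frames, prod(fs), nf)
  svF <- as.numeric(iv$val %*% (fr[iv$idx, , drop = FALSE] - GRAY))
  svMs <- expandFramesToMs(svF, movie@frameEdges)
  causalFilter(svMs, temporalKernel(model, params))
}

## feedback + coupling + bias drive from observed spikes
historyDrive <- function(model, params, spikes) {
  s <- spikes@spikes
  Tn <- ncol(s)
  g <- rep(params$bias, Tn)
  if (!is.null(params$feedback)) {
    i <- match(params$cell_id, spikes@cellIds)
    g <- g + causalFilter(s[i, ], basisKernel(model@bases$feedback, params$feedback))
  }
  for (j in names(params$coupling)) {
    cj <- params$coupling[[j]]
    if (all(cj == 0)) next
    r <- match(as.integer(j), spikes@cellIds)
    g <- g + causalFilter(s[r, ], basisKernel(model@bases$coupling, cj))
  }
  g
}

#' Generator signal of one cell
#'
#' The pre-nonlinearity drive
#' \code{g[t] = m' v[t-1] + (s_i * f_i)[t-1] + sum_j (s_j * c_ij)[t-1] + b},
#' where the stimulus term filters the movie's contrast (frame minus the 0.5
#' gray level) with the rank-1 space-time stimulus filter. All filters are
#' strictly causal: \code{g[t]} depends only on data before bin t.
#'
#' @param model a PopulationModel
#' @param spikes a BinnedSpikes raster aligned to the movie's 1 ms grid
#' @param movie a StimulusMovie
#' @param cellId cell id
#' @return numeric vector of length T
#' @export
generatorSignal <- function(model, spikes, movie, cellId) {
  if (ncol(spikes@spikes) != movieDurationMs(movie)) {
    stop("movie duration (", movieDurationMs(movie),
         " ms) does not match the spike raster (", ncol(spikes@spikes), " ms)")
  }
  params <- cellParams(model, cellId)
  stimulusDrive(model, params, movie) + historyDrive(model, params, spikes)
}

#' Bernoulli encoding negative log-likelihood of one cell
#'
#' \code{NLL = sum_t [log(1 + exp(g[t])) - s[t] g[t]]}, numerically
#' stabilized for large |g|; jointly convex in all filter parameters.
#' Optionally returns the gradient with respect to every parameter block.
#'
#' @param model a PopulationModel
#' @param spikes a BinnedSpikes raster (binary)
#' @param movie a StimulusMovie
#' @param cellId cell id
#' @param gradient also return the parameter-block gradient (default FALSE)
#' @return the scalar NLL, or (with gradient) a list \code{nll}, \code{grad}
#'   where grad has elements spatial, temporal, feedback, coupling (named
#'   list), bias
#' @export
lnbrcNLL <- function(model, spikes, movie, cellId, gradient = FALSE) {
  if (!all(spikes@spikes %in% c(0L, 1L))) stop("spike raster must be binary")
  params <- cellParams(model, cellId)
  g <- generatorSignal(model, spikes, movie, cellId)
  i <- match(cellId, spikes@cellIds)
  s <- spikes@spikes[i, ]
  nll <- sum(softplus(g) - s * g)
  if (!gradient) return(nll)
  r <- plogis(g) - s
  des <- cellDesigns(model, params, spikes, movie)
  grad <- list(
    spatial = as.numeric(crossprod(des$Xspat, r)),
    temporal = as.numeric(crossprod(des$Xtemp, r)),
    feedback = if (is.null(des$Xfb)) NULL else as.numeric(crossprod(des$Xfb, r)),
    coupling = lapply(des$Xcpl, function(X) as.numeric(crossprod(X, r))),
    bias = sum(r)
  )
  list(nll = nll, grad = grad)
}

## design matrices for one cell (used by the NLL gradient and the fitters)
cellDesigns <- function(model, params, spikes, movie, needSpat = TRUE,
                        needTemp = TRUE) {
  fs <- model@mosaic@fieldShape
  sb <- params$spatial$basis
  nf <- nFrames(movie)
  fr <- matrix(movie@frames, prod(fs), nf)
  cropIdx <- as.matrix(expand.grid(sb$cropRows, sb$cropCols))
  lin <- cropIdx[, 1] + (cropIdx[, 2] - 1L) * fs[1]
  contr <- fr[lin, , drop = FALSE] - GRAY
  FsF <- crossprod(contr, sb$matrix)              # nFrames x nCoef
  FsMs <- expandFramesToMs(t(FsF), movie@frameEdges) # nCoef x T
  out <- list()
  if (needSpat) {
    k <- temporalKernel(model, params)
    out$Xspat <- apply(FsMs, 1, function(col) causalFilter(col, k))
  }
  if (needTemp) {
    svMs <- as.numeric(crossprod(FsMs, params$spatial$coef))
    Bt <- model@bases$temporal$matrix
    out$Xtemp <- vapply(seq_len(nrow(Bt)),
                        function(rr) causalFilter(svMs, Bt[rr, ]),
                        numeric(length(svMs)))
  }
  if (!is.null(params$feedback)) {
    i <- match(params$cell_id, spikes@cellIds)
    Bf <- model@bases$feedback$matrix
    out$Xfb <- vapply(seq_len(nrow(Bf)),
                      function(rr) causalFilter(spikes@spikes[i, ], Bf[rr, ]),
                      numeric(ncol(spikes@spikes)))
  }
  out$Xcpl <- list()
  Bc <- model@bases$coupling$matrix
  for (j in names(params$coupling)) {
    r <- match(as.integer(j), spikes@cellIds)
    out$Xcpl[[j]] <- vapply(seq_len(nrow(Bc)),
                            function(rr) causalFilter(spikes@spikes[r, ], Bc[rr, ]),
                            numeric(ncol(spikes@spikes)))
  }
  out
}

#' Simulate Bernoulli population spiking from an LNBRC model
#'
#' Sequential 1 ms sampling of the full population. In the default
#' closed-loop mode each cell's feedback uses its own generated past and the
#' coupling terms use the generated past of the other cells. In
#' \code{mode = "conditioned"} the coupling contribution is computed from a
#' supplied reference raster (e.g. recorded data) while feedback still uses
#' the generated past.
#'
#' @param model a PopulationModel (family lnbrc or lnbr)
#' @param movie a StimulusMovie
#' @param seed integer seed (mandatory; reproducibility contract)
#' @param mode "closed" (default) or "conditioned"
#' @param referenceSpikes BinnedSpikes driving the coupling filters when
#'   \code{mode = "conditioned"}
#' @return a \linkS4class{BinnedSpikes} raster covering the movie duration
#' @export
simulatePopulationResponse <- function(model, movie, seed,
                                       mode = c("closed", "conditioned"),
                                       referenceSpikes = NULL) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  mode <- match.arg(mode)
  ids <- as.integer(names(model@cells))
  n <- length(ids)
  Tn <- movieDurationMs(movie)
  ## static drive: stimulus + bias
  G <- matrix(0, n, Tn)
  for (k in seq_len(n)) {
    p <- model@cells[[k]]
    G[k, ] <- stimulusDrive(model, p, movie) + p$bias
  }
  fbK <- lapply(model@cells, function(p) {
    if (is.null(p$feedback)) numeric(0) else
      basisKernel(model@bases$feedback, p$feedback)
  })
  if (mode == "conditioned") {
    if (is.null(referenceSpikes)) stop("conditioned mode requires referenceSpikes")
    for (k in seq_len(n)) {
      p <- model@cells[[k]]
      for (j in names(p$coupling)) {
        cj <- p$coupling[[j]]
        if (all(cj == 0)) next
        r <- match(as.integer(j), referenceSpikes@cellIds)
        G[k, ] <- G[k, ] + causalFilter(referenceSpikes@spikes[r, ],
                                        basisKernel(model@bases$coupling, cj))
      }
    }
  }
  ## per source cell: which rows receive its spikes through coupling
  cplTarget <- vector("list", n)
  if (mode == "closed") {
    for (k in seq_len(n)) {
      p <- model@cells[[k]]
      for (j in names(p$coupling)) {
        cj <- p$coupling[[j]]
        if (all(cj == 0)) next
        src <- match(as.integer(j), ids)
        kern <- basisKernel(model@bases$coupling, cj)
        cplTarget[[src]] <- c(cplTarget[[src]], list(list(row = k, kernel = kern)))
      }
    }
  }
  Lf <- max(1L, vapply(fbK, length, 1L))
  Lc <- model@bases$coupling$timeSpanMs
  pad <- max(Lf, Lc)
  Gb <- cbind(G, matrix(0, n, pad))
  S <- matrix(0L, n, Tn)
  withSeed(seed, {
    for (t in seq_len(Tn)) {
      p <- plogis(Gb[, t])
      sp <- runif(n) < p
      if (any(sp)) {
        S[sp, t] <- 1L
        for (k in which(sp)) {
          fk <- fbK[[k]]
          if (length(fk)) {
            Gb[k, (t + 1):(t + length(fk))] <- Gb[k, (t + 1):(t + length(fk))] + fk
          }
          for (tg in cplTarget[[k]]) {
            kk <- tg$kernel
            Gb[tg$row, (t + 1):(t + length(kk))] <-
              Gb[tg$row, (t + 1):(t + length(kk))] + kk
          }
        }
      }
    }
  })
  new("BinnedSpikes", spikes = S, cellIds = ids)
}
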