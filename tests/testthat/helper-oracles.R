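# Independent oracles used by the unit and acceptance suites.

# Model whose stimulus kernel spans at most one 8 ms frame, so that the
# emission for the spikes of frame f depends only on the eye positions at
# frames f-1 and f: the filtering distribution then has an exact two-frame
# HMM forward recursion.
shortKernelModel <- function(mosaic, seed = 4, gain = 8) {
  bases <- list(temporal = raisedCosineBasis(2, 8, stretch = 3),
                feedback = raisedCosineBasis(4, 40),
                coupling = raisedCosineBasis(3, 25))
  makeSyntheticModel(mosaic, bases = bases, gain = gain, seed = seed)
}

# small, soft-emission model for the exact-filtering oracle: 3 cells and a
# moderate stimulus gain keep per-frame evidence mild, so the N = 2000
# particle approximation stays well inside the total-variation band
pfOracleModel <- function() {
  mos <- tinyMosaic()
  cl <- mosaicCells(mos)[1:3, ]
  rownames(cl) <- NULL
  mos3 <- new("Mosaic", cells = cl, pixelSize = 8, fieldShape = c(16L, 16L))
  shortKernelModel(mos3, gain = 4)
}

# per-axis discretized-Gaussian step kernel with clipping at +-bound
clippedStepKernel <- function(D, pixelSize, bound) {
  m <- 2 * bound + 1
  if (D == 0) return(diag(m))
  sigma <- sqrt(D)
  P <- matrix(0, m, m) # P[from, to] on positions -bound..bound
  for (fromI in seq_len(m)) {
    from <- fromI - bound - 1
    for (step in (-6 * bound - 6):(6 * bound + 6)) {
      p <- pnorm((step + 0.5) * pixelSize, 0, sigma) -
        pnorm((step - 0.5) * pixelSize, 0, sigma)
      to <- min(max(from + step, -bound), bound)
      P[fromI, to + bound + 1] <- P[fromI, to + bound + 1] + p
    }
  }
  P / rowSums(P)
}

# Exact filtered position marginals p(w_f | spikes up to frame f) on the
# bounded grid, by forward enumeration over (previous, current) position
# pairs. Returns a list over frames of m x m marginal matrices (rows = dy).
hmmForwardOracle <- function(ctx, image, D, pixelSize, bound, nFrames) {
  m <- 2 * bound + 1
  Pax <- clippedStepKernel(D, pixelSize, bound)
  grid <- expand.grid(dy = -bound:bound, dx = -bound:bound)
  nS <- nrow(grid)
  trans <- matrix(0, nS, nS)
  for (i in seq_len(nS)) for (j in seq_len(nS)) {
    trans[i, j] <- Pax[grid$dy[i] + bound + 1, grid$dy[j] + bound + 1] *
      Pax[grid$dx[i] + bound + 1, grid$dx[j] + bound + 1]
  }
  origin <- which(grid$dy == 0 & grid$dx == 0)
  alpha <- numeric(nS)
  alpha[origin] <- 1
  out <- vector("list", nFrames)
  out[[1]] <- matrix(alpha, m, m)
  pathFor <- function(prev, cur, f) {
    path <- matrix(0L, f, 2)
    path[seq_len(f - 1), ] <- matrix(c(grid$dy[prev], grid$dx[prev]),
                                     f - 1, 2, byrow = TRUE)
    path[f, ] <- c(grid$dy[cur], grid$dx[cur])
    path
  }
  for (f in 2:nFrames) {
    logE <- matrix(-Inf, nS, nS)
    for (prev in which(alpha > 1e-300)) {
      for (cur in seq_len(nS)) {
        if (trans[prev, cur] <= 0) next
        logE[prev, cur] <- retinodecode:::frameLogLik(ctx, image,
                                                     pathFor(prev, cur, f), f)
      }
    }
    lmax <- max(logE[is.finite(logE)])
    anew <- numeric(nS)
    for (cur in seq_len(nS)) {
      contrib <- alpha * trans[, cur] * exp(pmax(logE[, cur] - lmax, -700))
      anew[cur] <- sum(contrib)
    }
    alpha <- anew / sum(anew)
    out[[f]] <- matrix(alpha, m, m)
  }
  out
}

# weighted marginal of the filter's posterior estimate (the pre-resampling
# importance-weighted ensemble) on the bounded grid
ensembleMarginal <- function(ensemble, bound) {
  post <- attr(ensemble, "posterior")
  paths <- if (is.null(post)) ensemble@paths else post$paths
  weights <- if (is.null(post)) ensemble@weights else post$weights
  m <- 2 * bound + 1
  out <- matrix(0, m, m)
  f <- nrow(paths[[1]])
  for (p in seq_along(paths)) {
    pos <- pmin(pmax(paths[[p]][f, ], -bound), bound)
    out[pos[1] + bound + 1, pos[2] + bound + 1] <-
      out[pos[1] + bound + 1, pos[2] + bound + 1] + weights[p]
  }
  out
}

# closed-form MAP of a Gaussian pseudo-likelihood under the 1/F prior
quadraticOracle <- function(A, b, sig2, prior, shape) {
  # closed-form MAP of the Gaussian pseudo-likelihood under the 1/F prior
  n <- prod(shape)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n)
    e[i] <- 1
    Q[, i] <- spectralEnergy(matrix(e, shape[1], shape[2]), prior,
                             gradient = TRUE)$grad / 2
  }
  solve(crossprod(A) / sig2 + 2 * Q, crossprod(A, b) / sig2)
}

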