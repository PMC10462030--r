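# Particle filter, EM image updates, joint reconstruction, trajectory error.

test_that("particle filter: single particle, frozen transition, determinism", {
  dat <- tinyDriftData()
  mod <- tinyModel()
  trial <- retinodecode:::sliceRecording(dat$spikes, dat$movie, 1L, 60L)
  edges <- trial$movie@frameEdges
  ctx <- pfContext(mod, trial$spikes, edges)
  img <- dat$images[[1]]

  # N = 1: weight is 1 after every update regardless of the data
  e1 <- newParticleEnsemble(1, 8)
  for (f in 2:8) {
    e1 <- pfAdvance(e1, ctx, f, img, list(D = 10, pixelSize = 8), seed = f)
    expect_equal(e1@weights, 1)
  }

  # zero-variance transition: every particle stays at the origin
  e0 <- newParticleEnsemble(5, 8)
  for (f in 2:8) {
    e0 <- pfAdvance(e0, ctx, f, img, list(D = 0, pixelSize = 8), seed = f)
  }
  for (p in e0@paths) expect_true(all(p == 0L))

  # identical seeds give identical ensembles
  adv <- function(seedBase) {
    e <- newParticleEnsemble(4, 8)
    for (f in 2:6) e <- pfAdvance(e, ctx, f, img, list(D = 10, pixelSize = 8),
                                  seed = seedBase + f)
    e
  }
  a <- adv(100)
  b <- adv(100)
  expect_identical(a@paths, b@paths)
  expect_identical(a@weights, b@weights)
})

test_that("filtered posterior matches exact HMM enumeration on a bounded grid", {
  # small version of the oracle (3x3 grid); the acceptance suite runs the
  # full 5x5 / N = 2000 / 5-seed configuration
  mod <- pfOracleModel()
  img <- syntheticImages(1, c(16L, 16L), seed = 61)[[1]]
  bound <- 1L # positions in {-1, 0, 1}^2
  tr <- generateDriftTrajectory(6, 12, 8, seed = 62)
  tr@steps <- pmin(pmax(tr@steps, -1L), 1L)
  mv <- makeDriftMovie(img, tr, padAllowance = 7)
  spk <- simulatePopulationResponse(mod, mv, seed = 63)
  edges <- mv@frameEdges
  ctx <- pfContext(mod, spk, edges)
  hmm <- hmmForwardOracle(ctx, img, D = 6, pixelSize = 8,
                                         bound = bound, nFrames = 12)
  ens <- newParticleEnsemble(1500, 8)
  for (f in 2:12) {
    ens <- pfAdvance(ens, ctx, f, img,
                     list(D = 6, pixelSize = 8, bounds = c(-bound, bound)),
                     seed = 70 + f)
    pf <- ensembleMarginal(ens, bound)
    tv <- 0.5 * sum(abs(pf - hmm[[f]]))
    expect_lt(tv, 0.12)
  }
})

test_that("EM image update collapses correctly onto the known-trajectory step", {
  dat <- tinyDriftData()
  mod <- tinyModel()
  trial <- retinodecode:::sliceRecording(dat$spikes, dat$movie, 1L, 60L)
  edges <- trial$movie@frameEdges
  tr <- dat$trajectories[[1]]
  pos <- positions(tr)
  prior <- spectralPrior(c(16L, 16L), 0.3)
  den <- exact1FDenoiser(prior)
  y0 <- matrix(0.5, 16, 16)

  # single particle on the true trajectory == one known-trajectory iteration
  ensTrue <- new("ParticleEnsemble", paths = list(pos), weights = 1,
                 pixelSize = 8)
  up1 <- emImageUpdate(y0, ensTrue, mod, trial$spikes, den, rho = 5,
                       lambda = 0.3, frameEdges = edges)
  lik <- trajectoryLikelihood(mod, trial$spikes, pos, edges)
  xref <- retinodecode:::xStep(lik, y0, 5, init = y0, maxIter = 25)
  ref <- den(xref, 0.3 / 5, NULL)
  expect_lt(max(abs(up1 - ref)), 1e-10)

  # duplicated identical particles with uniform weights give the same result
  ensDup <- new("ParticleEnsemble", paths = list(pos, pos, pos),
                weights = rep(1 / 3, 3), pixelSize = 8)
  up3 <- emImageUpdate(y0, ensDup, mod, trial$spikes, den, rho = 5,
                       lambda = 0.3, frameEdges = edges)
  expect_lt(max(abs(up3 - up1)), 1e-8)

  # expected-NLL gradient is the weighted sum of per-particle gradients
  pos2 <- pos
  pos2[, 1] <- pos2[, 1] + 1L
  lik1 <- trajectoryLikelihood(mod, trial$spikes, pos, edges)
  lik2 <- trajectoryLikelihood(mod, trial$spikes, pos2, edges)
  ensMix <- new("ParticleEnsemble", paths = list(pos, pos2),
                weights = c(0.3, 0.7), pixelSize = 8)
  likMix <- retinodecode:::ensembleLikelihood(mod, trial$spikes, ensMix,
                                              edges, maxBin = 500)
  y <- dat$images[[1]]
  gMix <- likMix$grad(y)
  gSum <- 0.3 * lik1$grad(y) + 0.7 * lik2$grad(y)
  expect_lt(max(abs(gMix - gSum)), 1e-10)
  # and matches finite differences of the weighted objective
  e <- matrix(0, 16, 16)
  e[40] <- 1e-5
  fd <- (likMix$fn(y + e) - likMix$fn(y - e)) / (2e-5)
  expect_lt(abs(fd - gMix[40]) / max(abs(fd), 1e-9), 1e-5)
})

test_that("trajectory error metric", {
  tr <- generateDriftTrajectory(10, 30, 8, seed = 71)
  expect_equal(trajectoryError(tr, tr)$rms, 0)

  # constant offset (a, 0) against an origin-bound truth: RMS = a (in um)
  est <- matrix(rep(c(2, 0), each = 30), 30, 2)
  zero <- matrix(0, 30, 2)
  expect_equal(trajectoryError(est, zero, pixelSize = 8)$rms, 16)
  expect_error(trajectoryError(est[1:10, ], zero, pixelSize = 8), "length")

  # ignoring Brownian movement: expected squared error grows ~ 2 D t
  nTr <- 400
  msd <- numeric(29)
  for (i in seq_len(nTr)) {
    t <- generateDriftTrajectory(10, 30, 1, seed = 500 + i) # 1 um/px: no rounding loss
    err <- trajectoryError(matrix(0, 30, 2), t)$perFrame
    msd <- msd + err[-1]^2
  }
  msd <- msd / nTr
  n <- seq_len(29)
  slope <- sum(n * msd) / sum(n^2)
  expect_lt(abs(slope - 20) / 20, 0.15) # 2 D with D = 10
})

test_that("joint reconstruction on a D = 0 trial matches zero-assumed decoding", {
  mod <- tinyModel()
  img <- syntheticImages(1, c(16L, 16L), seed = 81)[[1]]
  mv <- makeDriftMovie(img, zeroTrajectory(60, 8))
  spk <- simulatePopulationResponse(mod, mv, seed = 82)
  prior <- spectralPrior(c(16L, 16L), 0.3)
  den <- exact1FDenoiser(prior)
  sch <- hqsSchedule()
  jr <- jointReconstruct(spk, mod, den, 60,
                         transition = list(D = 0, pixelSize = 8),
                         schedule = sch, nParticles = 5, seed = 83,
                         initWindowMs = 500, emXMaxIter = 25)
  # with zero transition variance the joint algorithm is zero-assumed
  # decoding whose schedule continues at its cap for the 12 EM updates;
  # compare against exactly that
  sch22 <- structure(list(lambda = sch$lambda,
                          rho = c(sch$rho, rep(sch$rho[10], 12)), K = 22),
                     class = "HQSSchedule")
  z <- reconImage(reconstructKnownTrajectory(spk, mod, zeroTrajectory(60, 8),
                                             den, sch22, xMaxIter = 25))
  expect_true(all(jr$trajectory == 0))
  s <- scoreReconstruction(jr$image, z, NULL, 0)
  expect_gt(s$value, 0.98)
})
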