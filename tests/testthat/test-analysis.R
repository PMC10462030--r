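# PSTH, variance explained, correlograms, perturbation, shuffling,
# drift magnitude, cell-type subsetting.

test_that("PSTH: mass conservation, identical repeats, brute-force equality", {
  # one repeat, one spike: Gaussian bump integrating to one spike
  r1 <- array(0L, c(1, 1, 200))
  r1[1, 1, 100] <- 1L
  p1 <- psth(r1)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_equal(which.max(p1[1, ]), 100)

  # identical repeats equal any single smoothed trial
  set.seed(3)
  trial <- array(rbinom(300, 1, 0.1), c(1, 1, 300))
  rep5 <- array(rep(trial, each = 5), c(5, 1, 300))
  expect_equal(psth(rep5), psth(trial), tolerance = 1e-12)

  # random raster equals the per-bin average of smoothed single trials
  ras <- array(rbinom(4 * 2 * 150, 1, 0.08), c(4, 2, 150))
  direct <- psth(ras)
  manual <- matrix(0, 2, 150)
  for (r in 1:4) manual <- manual + psth(array(ras[r, , ], c(1, 2, 150))) / 4
  expect_equal(direct, manual, tolerance = 1e-10)
})

test_that("fraction of PSTH variance explained", {
  set.seed(4)
  d <- runif(100)
  expect_equal(fractionVarianceExplained(d, d), 1)
  expect_equal(fractionVarianceExplained(rep(mean(d), 100), d), 0)
  m <- runif(100)
  expect_equal(fractionVarianceExplained(m, d),
               1 - mean((m - d)^2) / mean((d - mean(d))^2))
  expect_error(fractionVarianceExplained(d, rep(1, 100)), "zero variance")
})

test_that("cross-correlograms: coincidences, symmetry, shift-predictor removal", {
  # perfectly synchronized duplicate trains: raw peak at lag 0 equals the
  # per-trial spike count
  set.seed(5)
  a <- matrix(rbinom(10 * 400, 1, 0.05), 10, 400)
  ccSelf <- crossCorrelogram(a, a, maxLagMs = 10, corrected = FALSE)
  expect_equal(ccSelf$raw[ccSelf$lags == 0], mean(rowSums(a)))

  # CCG symmetry: CCG(a,b) at lag l equals CCG(b,a) at -l
  b <- matrix(rbinom(10 * 400, 1, 0.05), 10, 400)
  ab <- crossCorrelogram(a, b, maxLagMs = 10, corrected = FALSE)
  ba <- crossCorrelogram(b, a, maxLagMs = 10, corrected = FALSE)
  expect_equal(ab$raw, rev(ba$raw), tolerance = 1e-10)

  # two independent cells driven by the same strong stimulus-locked rate:
  # raw CCG has a trial-structure peak, corrected CCG is within 4 SE of 0
  nRep <- 200; Tn <- 300
  rate <- 0.02 + 0.3 * exp(-((1:Tn) - 60)^2 / 50) # shared stimulus transient
  set.seed(6)
  ra <- matrix(rbinom(nRep * Tn, 1, rate), nRep, Tn, byrow = TRUE)
  rb <- matrix(rbinom(nRep * Tn, 1, rate), nRep, Tn, byrow = TRUE)
  cc <- crossCorrelogram(ra, rb, maxLagMs = 15)
  expect_gt(max(cc$raw), 2 * mean(cc$raw[abs(cc$lags) > 10])) # locked peak
  # sampling SE of the corrected CCG from binomial coincidence counts
  se <- sqrt(2 * sum(rate^2) * (1 / nRep))
  expect_true(all(abs(cc$corrected) < 4 * pmax(se, 1e-3)))

  expect_error(crossCorrelogram(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "repeats")
})

test_that("spike-time perturbation: identity, conservation, moment check", {
  dat <- tinyDriftData()
  expect_identical(perturbSpikeTimes(dat$spikes, 0, seed = 1), dat$spikes)

  pert <- perturbSpikeTimes(dat$spikes, 5, seed = 2)
  expect_equal(rowSums(spikeMatrix(pert)), rowSums(spikeMatrix(dat$spikes)))
  expect_true(all(spikeMatrix(pert) %in% c(0L, 1L)))

  # empirical shift SD ~ sigma on a sparse long train
  Tn <- 200000L
  set.seed(7)
  tr <- sort(sample.int(Tn - 200, 4000) + 100)
  sp <- matrix(0L, 1, Tn)
  sp[1, tr] <- 1L
  spikes <- new("BinnedSpikes", spikes = sp, cellIds = 1L)
  out <- perturbSpikeTimes(spikes, 10, seed = 3)
  newT <- which(spikeMatrix(out)[1, ] == 1L)
  # nearest-assignment of perturbed to original spike times is inexact, so
  # compare moment of the pooled displacement distribution instead
  sdEmp <- sqrt(mean((sort(newT) - sort(tr))^2))
  expect_lt(abs(sdEmp - 10) / 10, 0.25)
})

test_that("repeat shuffling preserves per-cell statistics, removes noise correlations", {
  set.seed(8)
  nRep <- 100; Tn <- 250
  rate <- 0.02 + 0.25 * exp(-((1:Tn) - 80)^2 / 80)
  a <- matrix(0L, nRep, Tn)
  b <- matrix(0L, nRep, Tn)
  for (r in 1:nRep) {
    base <- rbinom(Tn, 1, rate)
    shared <- rbinom(Tn, 1, 0.02) # injected shared (noise) spikes
    a[r, ] <- pmin(1L, base + shared)
    b[r, ] <- pmin(1L, rbinom(Tn, 1, rate) + shared)
  }
  ras <- array(0L, c(nRep, 2, Tn))
  ras[, 1, ] <- a
  ras[, 2, ] <- b
  sh <- shuffleRepeats(ras, seed = 9)

  # PSTH exactly invariant, multiset of single-trial trains preserved
  expect_equal(psth(ras), psth(sh), tolerance = 1e-12)
  key <- function(m) sort(apply(m, 1, paste, collapse = ""))
  expect_identical(key(sh[, 1, ]), key(a))
  expect_identical(key(sh[, 2, ]), key(b))
  expect_warning(shuffleRepeats(ras[1, , , drop = FALSE], seed = 1), "single")

  # injected zero-lag correlation: shuffled corrected peak < 25% of original
  ccBefore <- crossCorrelogram(a, b, maxLagMs = 10)
  ccAfter <- crossCorrelogram(sh[, 1, ], sh[, 2, ], maxLagMs = 10)
  peakB <- ccBefore$corrected[ccBefore$lags == 0]
  peakA <- ccAfter$corrected[ccAfter$lags == 0]
  expect_gt(peakB, 0)
  expect_lt(abs(peakA), 0.25 * peakB)
})

test_that("drift magnitude convention", {
  expect_equal(driftMagnitude(zeroTrajectory(60, 8)), 0)

  # positions alternating between (0,0) and (d,0): two-point SD d/2
  steps <- matrix(rep(c(3L, -3L), length.out = 19), ncol = 1)
  steps <- cbind(steps, 0L)
  tr <- new("DriftTrajectory", steps = steps, stepsUm = steps * 8,
            nFrames = 20L, diffusionConstant = 0, pixelSize = 8)
  expect_equal(driftMagnitude(tr), 3 * 8 / 2, tolerance = 1e-6)

  tr2 <- generateDriftTrajectory(10, 60, 8, seed = 11)
  p <- positions(tr2) * 8
  mag <- sqrt(p[, 1]^2 + p[, 2]^2)
  expect_equal(driftMagnitude(tr2), sqrt(mean((mag - mean(mag))^2)))
})

test_that("cell-type subsetting is a consistent restriction", {
  mod <- smallModel()
  dat <- smallDriftData()
  all4 <- subsetPopulation(mod, unique(mosaicCells(mod@mosaic)$cell_type),
                          spikes = dat$spikes)
  expect_equal(length(all4$model@cells), length(mod@cells))
  expect_identical(spikeMatrix(all4$spikes), spikeMatrix(dat$spikes))

  mid <- subsetPopulation(mod, c("ON_midget", "OFF_midget"), spikes = dat$spikes)
  keptTypes <- mosaicCells(mid$model@mosaic)$cell_type
  expect_true(all(grepl("midget", keptTypes)))
  parasolIds <- mosaicCells(mod@mosaic)$cell_id[
    grepl("parasol", mosaicCells(mod@mosaic)$cell_type)]
  for (id in names(mid$model@graph)) {
    expect_length(intersect(mid$model@graph[[id]], parasolIds), 0)
    expect_true(all(!as.character(parasolIds) %in%
                      names(mid$model@cells[[id]]$coupling)))
  }
  expect_false(any(mid$spikes@cellIds %in% parasolIds))
  expect_error(subsetPopulation(mod, "amacrine"), "not present")
})
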