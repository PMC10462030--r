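# Generator signal, Bernoulli likelihood, neighbor graph, model fitting.

test_that("neighbor graph follows the class-dependent median-NN rule", {
  # two parasols at 1.9x the median NN distance of a multi-cell parasol
  # mosaic: edge present in both directions
  cells <- data.frame(
    cell_id = 1:4,
    cell_type = "ON_parasol",
    x = c(0, 100, 200, 390) + 100,
    y = rep(100, 4),
    rf_radius = 50,
    polarity = 1L
  )
  mos <- new("Mosaic", cells = cells, pixelSize = 8, fieldShape = c(60L, 80L))
  # median NN distance = 100; cell 4 sits 190 from cell 3 (1.9 x median)
  g <- buildNeighborGraph(mos)
  expect_true(4L %in% g[["3"]])
  expect_true(3L %in% g[["4"]])
  expect_false(1L %in% g[["4"]]) # 390 > 200

  # single cell: empty neighbor sets, not an error
  one <- generateMosaic(c(10L, 10L), 8,
                        data.frame(cell_type = "ON_midget", spacing = 100,
                                   rf_radius = 30), seed = 1)
  expect_equal(buildNeighborGraph(one)[["1"]], integer(0))

  # random mosaic: graph equals the brute-force distance filter
  mos2 <- smallMosaic()
  g2 <- buildNeighborGraph(mos2)
  cl <- mosaicCells(mos2)
  nn <- medianNNDistance(mos2)
  for (i in seq_len(nrow(cl))) {
    mult <- if (grepl("parasol", cl$cell_type[i])) 2.0 else 2.5
    thr <- mult * nn[[cl$cell_type[i]]]
    d <- sqrt((cl$x - cl$x[i])^2 + (cl$y - cl$y[i])^2)
    brute <- sort(cl$cell_id[d <= thr & cl$cell_id != cl$cell_id[i]])
    expect_equal(sort(g2[[as.character(cl$cell_id[i])]]), brute)
  }
})

test_that("generator signal: hand-evaluated cases and strict causality", {
  mod <- tinyModel()
  mv <- grayMovie(c(16L, 16L), 24)
  Tn <- movieDurationMs(mv)
  ids <- as.integer(names(mod@cells))
  spk <- new("BinnedSpikes", spikes = matrix(0L, length(ids), Tn), cellIds = ids)

  # all weights and bias zero -> g identically 0; bias only -> g = bias
  zero <- mod
  for (id in names(zero@cells)) {
    zero@cells[[id]]$spatial$coef[] <- 0
    zero@cells[[id]]$feedback[] <- 0
    zero@cells[[id]]$coupling <- lapply(zero@cells[[id]]$coupling, function(x) 0 * x)
    zero@cells[[id]]$bias <- 0
  }
  expect_equal(generatorSignal(zero, spk, mv, ids[1]), rep(0, Tn))
  biased <- zero
  biased@cells[[as.character(ids[1])]]$bias <- 0.5
  expect_equal(generatorSignal(biased, spk, mv, ids[1]), rep(0.5, Tn))

  # spike at t-1 through a feedback kernel with weight w at lag 1 adds w
  fb <- zero
  fb@cells[[as.character(ids[1])]]$bias <- 0.5
  fbBasis <- fb@bases$feedback$matrix
  # feedback coefficients chosen so the kernel is exactly 1 at lag 1
  coefs <- qr.coef(qr(t(fbBasis)), c(1, numeric(ncol(fbBasis) - 1)))
  fb@cells[[as.character(ids[1])]]$feedback <- coefs
  k1 <- sum(fbBasis[, 1] * coefs)
  s2 <- spk
  s2@spikes[1, 100] <- 1L
  g <- generatorSignal(fb, s2, mv, ids[1])
  expect_equal(g[101], 0.5 + k1, tolerance = 1e-12)
  expect_equal(g[100], 0.5) # strictly causal: no effect at the spike bin

  # causality: changing stimulus and spikes at times >= t never changes g[t]
  dat <- tinyDriftData()
  t0 <- 300
  g1 <- generatorSignal(mod, dat$spikes, dat$movie, ids[1])
  mv2 <- dat$movie
  futureFrames <- which(mv2@frameEdges[-length(mv2@frameEdges)] >= t0)
  mv2@frames[, , futureFrames] <- 0.9
  sp2 <- dat$spikes
  sp2@spikes[, t0:ncol(sp2@spikes)] <- 0L
  g2 <- generatorSignal(mod, sp2, mv2, ids[1])
  expect_equal(g1[seq_len(t0 - 1)], g2[seq_len(t0 - 1)], tolerance = 1e-10)
})

test_that("Bernoulli NLL: closed forms, finite-difference gradient, convexity", {
  dat <- tinyDriftData()
  mod <- tinyModel()
  ids <- as.integer(names(mod@cells))
  Tn <- ncol(spikeMatrix(dat$spikes))

  # g == 0 -> NLL = T log 2 regardless of the spike pattern
  zero <- mod
  for (id in names(zero@cells)) {
    zero@cells[[id]]$spatial$coef[] <- 0
    zero@cells[[id]]$feedback[] <- 0
    zero@cells[[id]]$coupling <- lapply(zero@cells[[id]]$coupling, function(x) 0 * x)
    zero@cells[[id]]$bias <- 0
  }
  expect_equal(lnbrcNLL(zero, dat$spikes, dat$movie, ids[1]), Tn * log(2))

  # s == 0 and bias -> -Inf gives NLL -> 0
  silent <- zero
  silent@cells[[as.character(ids[1])]]$bias <- -40
  noSpk <- dat$spikes
  noSpk@spikes[] <- 0L
  expect_lt(lnbrcNLL(silent, noSpk, dat$movie, ids[1]), 1e-10)

  # gradient matches central finite differences
  res <- lnbrcNLL(mod, dat$spikes, dat$movie, ids[1], gradient = TRUE)
  p <- cellParams(mod, ids[1])
  checkFD <- function(setter, analytic) {
    eps <- 1e-5
    m1 <- mod; m2 <- mod
    m1@cells[[as.character(ids[1])]] <- setter(p, eps)
    m2@cells[[as.character(ids[1])]] <- setter(p, -eps)
    fd <- (lnbrcNLL(m1, dat$spikes, dat$movie, ids[1]) -
             lnbrcNLL(m2, dat$spikes, dat$movie, ids[1])) / (2 * eps)
    expect_lt(abs(fd - analytic) / max(abs(fd), 1e-6), 1e-5)
  }
  checkFD(function(p, e) { p$spatial$coef[3] <- p$spatial$coef[3] + e; p },
          res$grad$spatial[3])
  checkFD(function(p, e) { p$temporal[2] <- p$temporal[2] + e; p },
          res$grad$temporal[2])
  checkFD(function(p, e) { p$feedback[1] <- p$feedback[1] + e; p },
          res$grad$feedback[1])
  if (length(p$coupling)) {
    checkFD(function(p, e) { p$coupling[[1]][2] <- p$coupling[[1]][2] + e; p },
            res$grad$coupling[[1]][2])
  }
  checkFD(function(p, e) { p$bias <- p$bias + e; p }, res$grad$bias)

  # midpoint convexity over random parameter pairs
  set.seed(11)
  id <- as.character(ids[2])
  nllAt <- function(v) {
    m <- mod
    m@cells[[id]]$spatial$coef <- v[seq_along(p$spatial$coef)]
    m@cells[[id]]$bias <- v[length(v)]
    lnbrcNLL(m, dat$spikes, dat$movie, ids[2])
  }
  nPar <- length(p$spatial$coef) + 1
  for (k in 1:25) {
    a <- rnorm(nPar, 0, 2)
    b <- rnorm(nPar, 0, 2)
    expect_lte(nllAt((a + b) / 2), (nllAt(a) + nllAt(b)) / 2 + 1e-8)
  }

  expect_error(lnbrcNLL(mod, {
    s <- dat$spikes; s@spikes[1, 1] <- 3L; s
  }, dat$movie, ids[1]), "binary")
})

test_that("fitted stimulus filters are rank-1 separable by construction", {
  mod <- tinyModel()
  p <- cellParams(mod, as.integer(names(mod@cells))[1])
  fs <- mod@mosaic@fieldShape
  kern <- retinodecode:::temporalKernel(mod, p)
  spat <- retinodecode:::spatialField(p, fs)
  st <- outer(as.numeric(spat), kern) # (space x time) filter
  sv <- svd(st)
  expect_lt(sv$d[2] / sv$d[1], 1e-10)
})

test_that("degenerate penalties: huge L1 zeroes space, huge L2,1 zeroes coupling", {
  dat <- tinyDriftData()
  mos <- tinyMosaic()
  id <- mosaicCells(mos)$cell_id[1]
  cfgBig <- fitConfig(l1Weight = 1e5, groupL21Weight = 1e6, maxOuter = 1,
                      fistaMaxIter = 40, polishIter = 40)
  fit <- suppressWarnings(fitLNBRC(dat$spikes, dat$movie, mos,
                                   config = cfgBig, cellIds = id))
  p <- cellParams(fit, id)
  expect_true(all(p$spatial$coef == 0))
  expect_true(all(vapply(p$coupling, function(x) all(x == 0), TRUE)))
})

test_that("LNP model: closed form, gradient, Poisson recovery", {
  mos <- tinyMosaic()
  dat <- tinyDriftData()
  counts <- countsPerFrame(dat$spikes, dat$movie)
  expect_error(lnpNLL(fitLNP(dat$spikes, dat$movie, mos,
                             cellIds = mosaicCells(mos)$cell_id[1]),
                      counts - 5, dat$movie, mosaicCells(mos)$cell_id[1]),
               "nonnegative")

  # build an LNP model directly and verify NLL closed form at g == 0
  id <- mosaicCells(mos)$cell_id[1]
  lnp <- suppressWarnings(fitLNP(dat$spikes, dat$movie, mos, cellIds = id,
                                 config = fitConfig(l1Weight = 1, maxOuter = 1,
                                                    fistaMaxIter = 30,
                                                    polishIter = 20)))
  z <- lnp
  z@cells[[as.character(id)]]$spatial$coef[] <- 0
  z@cells[[as.character(id)]]$bias <- 0
  s <- counts[as.character(id), ]
  expect_equal(lnpNLL(z, counts, dat$movie, id), nFrames(dat$movie) - sum(0 * s))

  # gradient vs central finite differences
  res <- lnpNLL(lnp, counts, dat$movie, id, gradient = TRUE)
  p <- cellParams(lnp, id)
  eps <- 1e-6
  m1 <- lnp; m2 <- lnp
  m1@cells[[as.character(id)]]$spatial$coef[4] <- p$spatial$coef[4] + eps
  m2@cells[[as.character(id)]]$spatial$coef[4] <- p$spatial$coef[4] - eps
  fd <- (lnpNLL(m1, counts, dat$movie, id) - lnpNLL(m2, counts, dat$movie, id)) / (2 * eps)
  expect_lt(abs(fd - res$grad$spatial[4]) / max(abs(fd), 1e-8), 1e-4)

  # Poisson simulation from a known rank-1 filter: recovery cosine > 0.9
  mod <- tinyModel()
  idr <- as.integer(names(mod@cells))[1]
  movie <- {
    imgs <- syntheticImages(20, c(16L, 16L), seed = 41)
    trajs <- lapply(seq_along(imgs), function(i) zeroTrajectory(30, 8))
    frames <- array(0.5, c(16, 16, 30 * 20))
    for (i in seq_along(imgs)) {
      frames[, , (i - 1) * 30 + 1:30] <- makeDriftMovie(imgs[[i]], trajs[[i]])@frames
    }
    retinodecode:::newMovie(frames)
  }
  pTrue <- cellParams(mod, idr)
  kern <- retinodecode:::basisKernel(retinodecode:::lnpBases()$temporal,
                                     c(0.4, 1, 0.3, 0))
  fs <- mos@fieldShape
  spat <- retinodecode:::spatialField(pTrue, fs)
  fr <- matrix(movie@frames, prod(fs), nFrames(movie)) - 0.5
  sv <- as.numeric(as.numeric(spat) %*% fr) / 4
  eta <- retinodecode:::frameFilter0(sv, kern) - 1.2
  set.seed(21)
  cnt <- matrix(rpois(length(eta), exp(pmin(eta, 5))), 1)
  rownames(cnt) <- idr
  fitP <- suppressWarnings(fitLNP(NULL, movie, mos, counts = cnt,
                                  cellIds = idr))
  spatHat <- retinodecode:::spatialField(cellParams(fitP, idr), fs)
  cs <- abs(sum(spat * spatHat) / sqrt(sum(spat^2) * sum(spatHat^2)))
  expect_gt(cs, 0.9)
})

test_that("LNBR on coupled data: no better held-out fit than LNBRC", {
  # strongly coupled ground truth so the coupling filters carry real
  # predictive weight on held-out data
  mos <- fitMosaic()
  truth <- makeSyntheticModel(mos, couplingStrength = 1.5, couplingProb = 0.8,
                              seed = 7)
  coupledIds <- as.integer(names(truth@cells))[vapply(truth@cells, function(p) {
    any(vapply(p$coupling, function(cc) any(cc != 0), TRUE))
  }, TRUE)]
  imgs <- syntheticImages(16, c(24L, 24L), seed = 15)
  dat <- simulateDriftRecording(truth, imgs, 10, seed = 16)
  parts <- trainTestSplit(dat$spikes, dat$movie, 0.25)
  cfg <- fitConfig(groupL21Weight = 60, maxOuter = 2, fistaMaxIter = 80,
                   polishIter = 80)
  ids <- head(coupledIds, 3)
  graphH <- buildNeighborGraph(mos, homotypicOnly = TRUE)
  mC <- suppressWarnings(fitLNBRC(parts$train$spikes, parts$train$movie, mos,
                                  graph = graphH, config = cfg, cellIds = ids))
  mU <- suppressWarnings(fitLNBR(parts$train$spikes, parts$train$movie, mos,
                                 config = cfg, cellIds = ids))
  nllC <- heldOutNLL(mC, parts$test$spikes, parts$test$movie)
  nllU <- heldOutNLL(mU, parts$test$spikes, parts$test$movie)
  expect_gte(nllU, nllC - 1e-6)
})

test_that("hyperparameter grid search returns the held-out argmin", {
  dat <- tinyDriftData()
  mos <- tinyMosaic()
  cfg <- fitConfig(maxOuter = 1, fistaMaxIter = 40, polishIter = 30)
  # single-point grid returns that point
  g1 <- suppressWarnings(gridSearchHyperparams(dat$spikes, dat$movie, mos,
                                               data.frame(l1 = 2, l21 = 50),
                                               config = cfg, nProbePerType = 1,
                                               seed = 1))
  expect_equal(c(g1$l1, g1$l21), c(2, 50))

  # 2x2 grid: selection matches exhaustive recomputation
  grid <- expand.grid(l1 = c(1, 20), l21 = c(50, 400))
  gs <- suppressWarnings(gridSearchHyperparams(dat$spikes, dat$movie, mos, grid,
                                               config = cfg, nProbePerType = 1,
                                               seed = 2))
  best <- gs$table[which.min(gs$table$meanNLL), ]
  expect_equal(c(gs$l1, gs$l21), c(best$l1, best$l21))
  expect_equal(nrow(gs$table), 4)
})
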