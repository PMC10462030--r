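## End-to-end experiment runner: simulate -> (fit) -> reconstruct -> evaluate.

#' Default experiment configuration
#'
#' @param protocol "flashed" or "drift"
#' @param seed top-level seed (fanned out to stages via \code{childSeed})
#' @return nested configuration list
#' @export
defaultExperimentConfig <- function(protocol = c("flashed", "drift"), seed = 1) {
  protocol <- match.arg(protocol)
  list(
    experiment = list(protocol = protocol, seed = seed),
    simulator = list(fieldShape = c(32L, 32L), pixelSize = 8,
                     types = mosaicDefaults()[3:4, ], nTrials = 5,
                     diffusionConstant = 10, gain = 8, baselineRateHz = 15),
    model = list(use = "true"),
    prior = list(lambda = 0.1),
    schedule = list(rhoFirst = 0.2, rhoLast = 200, K = 10),
    reconstruction = list(windowMs = 150, shiftRadius = if (protocol == "drift") 3 else 0),
    em = list(particles = 10, updateEvery = 5,
              methods = c("zero", "known", "joint"))
  )
}

#' Simulate a multi-trial drift recording
#'
#' Renders one 500 ms (60-frame) drift-jittered movie per image, concatenates
#' them into a single recording (no gray separation, as in the drift
#' protocol), and simulates closed-loop population spiking. The returned
#' bundle carries the ground truth needed for recovery tests: the model, the
#' per-trial trajectories and the source images.
#'
#' @param model a ground-truth PopulationModel
#' @param images list of images (one per 500 ms trial)
#' @param diffusionConstant D in um^2/frame (default 10)
#' @param seed integer seed (trajectories and spiking)
#' @param framesPerTrial frames per image (default 60)
#' @return list: \code{movie}, \code{spikes}, \code{trajectories},
#'   \code{images}, \code{seed}
#' @export
simulateDriftRecording <- function(model, images, diffusionConstant = 10,
                                   seed = 1, framesPerTrial = 60L) {
  px <- model@mosaic@pixelSize
  fs <- model@mosaic@fieldShape
  nT <- length(images)
  frames <- array(GRAY, c(fs[1], fs[2], framesPerTrial * nT))
  trajs <- vector("list", nT)
  pad <- floor(min(fs) / 2) - 1
  for (i in seq_len(nT)) {
    ## redraw the rare trajectory whose excursion exceeds the gray padding
    ## (the display protocol cannot show content beyond the padded border)
    for (try in 0:19) {
      trajs[[i]] <- generateDriftTrajectory(diffusionConstant, framesPerTrial,
                                            px, seed = childSeed(seed, i + try * 1000003L))
      if (max(abs(positions(trajs[[i]]))) <= pad) break
    }
    mv <- makeDriftMovie(images[[i]], trajs[[i]], padAllowance = pad)
    frames[, , (i - 1) * framesPerTrial + seq_len(framesPerTrial)] <- mv@frames
  }
  edges <- frameBinEdges(framesPerTrial * nT)
  trials <- data.frame(
    trial = seq_len(nT), image = seq_len(nT),
    frame_start = (seq_len(nT) - 1L) * framesPerTrial + 1L,
    frame_end = seq_len(nT) * framesPerTrial)
  trials$bin_start <- edges[trials$frame_start]
  trials$bin_end <- edges[trials$frame_end + 1L] - 1L
  trials$onset_bin <- trials$bin_start
  movie <- newMovie(frames, trials = trials)
  spikes <- simulatePopulationResponse(model, movie,
                                       seed = childSeed(seed, 10000))
  list(movie = movie, spikes = spikes, trajectories = trajs, images = images,
       seed = seed)
}

#' Run a full synthetic experiment
#'
#' Generates a mosaic and ground-truth model, renders the stimulus protocol,
#' simulates population spiking, optionally fits encoding models, decodes
#' every trial, scores reconstructions over the valid region, and writes all
#' artifacts (arrays, PNG images, CSV score table, resolved config, manifest
#' with checksums) to the output directory. Identical (config, seed) pairs
#' reproduce identical result files.
#'
#' @param config configuration list (see
#'   \code{\link{defaultExperimentConfig}}) or path to a YAML file
#' @param outputDir output directory
#' @return the run manifest (invisibly: scores table as attribute)
#' @export
runExperiment <- function(config, outputDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(defaultExperimentConfig(config$experiment$protocol %||% "flashed"),
                    config)
  seed <- cfg$experiment$seed
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulator
  types <- as.data.frame(sim$types)
  mosaic <- generateMosaic(sim$fieldShape, sim$pixelSize, types,
                           seed = childSeed(seed, 1))
  model <- makeSyntheticModel(mosaic, gain = sim$gain,
                              baselineRateHz = sim$baselineRateHz,
                              seed = childSeed(seed, 2))
  images <- syntheticImages(sim$nTrials, sim$fieldShape,
                            seed = childSeed(seed, 3))
  prior <- spectralPrior(sim$fieldShape, cfg$prior$lambda)
  denoiser <- exact1FDenoiser(prior)
  schedule <- hqsSchedule(cfg$prior$lambda, cfg$schedule$rhoFirst,
                          cfg$schedule$rhoLast, cfg$schedule$K)
  mask <- validRegion(mosaic)
  scores <- list()
  artifacts <- list(mosaic = mosaic)
  if (cfg$experiment$protocol == "flashed") {
    movie <- makeFlashedStimulus(images, sim$pixelSize)
    spikes <- simulatePopulationResponse(model, movie, seed = childSeed(seed, 4))
    fitModel <- if (identical(cfg$model$use, "fit")) {
      fitLNBRC(spikes, movie, mosaic)
    } else model
    for (tr in seq_along(images)) {
      rec <- reconstructFlashed(spikes, fitModel, movie, tr, denoiser,
                                schedule, windowMs = cfg$reconstruction$windowMs)
      sc <- scoreReconstruction(reconImage(rec), images[[tr]], mask,
                                cfg$reconstruction$shiftRadius)
      scores[[length(scores) + 1]] <- data.frame(
        trial = tr, method = "map", msSSIM = sc$value)
      writeImagePng(reconImage(rec),
                    file.path(outputDir, sprintf("recon_trial%02d.png", tr)))
    }
    artifacts$movie <- movie
    artifacts$spikes <- spikes
  } else {
    D <- sim$diffusionConstant
    for (tr in seq_along(images)) {
      traj <- generateDriftTrajectory(D, 60, sim$pixelSize,
                                      seed = childSeed(seed, 100 + tr))
      movie <- makeDriftMovie(images[[tr]], traj,
                              padAllowance = floor(min(sim$fieldShape) / 2) - 1)
      spikes <- simulatePopulationResponse(model, movie,
                                           seed = childSeed(seed, 200 + tr))
      for (method in cfg$em$methods) {
        img <- switch(method,
          zero = reconImage(reconstructKnownTrajectory(
            spikes, model, zeroTrajectory(60, sim$pixelSize), denoiser, schedule)),
          known = reconImage(reconstructKnownTrajectory(
            spikes, model, traj, denoiser, schedule)),
          joint = jointReconstruct(
            spikes, model, denoiser, 60,
            transition = list(D = D, pixelSize = sim$pixelSize),
            schedule = schedule, nParticles = cfg$em$particles,
            updateEvery = cfg$em$updateEvery,
            seed = childSeed(seed, 300 + tr))$image,
          stop("unknown method: ", method))
        sc <- scoreReconstruction(img, images[[tr]], mask,
                                  cfg$reconstruction$shiftRadius)
        scores[[length(scores) + 1]] <- data.frame(
          trial = tr, method = method, D = D, msSSIM = sc$value)
        writeImagePng(img, file.path(outputDir,
                                     sprintf("recon_trial%02d_%s.png", tr, method)))
      }
      if (tr == 1) {
        artifacts$trajectory <- traj
        artifacts$spikes <- spikes
      }
    }
  }
  scoreTab <- do.call(rbind, scores)
  write.csv(scoreTab, file.path(outputDir, "scores.csv"), row.names = FALSE)
  writeLines(yaml::as.yaml(cfg), file.path(outputDir, "config.yaml"))
  saveContainer(artifacts, file.path(outputDir, "container"),
                seed = seed, config = cfg)
  files <- list.files(outputDir, recursive = TRUE)
  manifest <- list(
    seed = seed, configHash = hashConfig(cfg),
    files = as.list(tools::md5sum(file.path(outputDir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(outputDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "scores") <- scoreTab
  invisible(manifest)
}
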