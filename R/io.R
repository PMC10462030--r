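## Plain-text container I/O: arrays as full-precision CSV plus a JSON
## manifest (schema version, seed, config hash, checksums), PNG image export.

CONTAINER_SCHEMA <- "1.0"

writeArrayTxt <- function(x, path) {
  dm <- dim(x) %||% length(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(dm, collapse = ","), con)
  writeLines(paste(storage.mode(x)), con)
  writeLines(formatC(as.vector(x), format = if (is.integer(x)) "d" else "g",
                     digits = 17), con)
}

readArrayTxt <- function(path) {
  lines <- readLines(path)
  dm <- as.integer(strsplit(lines[1], ",")[[1]])
  mode <- lines[2]
  vals <- if (mode == "integer") as.integer(lines[-(1:2)]) else
    as.numeric(lines[-(1:2)])
  if (length(dm) > 1) array(vals, dm) else vals
}

objectToParts <- function(obj) {
  if (is(obj, "BinnedSpikes")) {
    list(class = "BinnedSpikes",
         arrays = list(spikes = obj@spikes, cellIds = obj@cellIds))
  } else if (is(obj, "DriftTrajectory")) {
    list(class = "DriftTrajectory",
         arrays = list(steps = obj@steps, stepsUm = obj@stepsUm),
         meta = list(nFrames = obj@nFrames,
                     diffusionConstant = obj@diffusionConstant,
                     pixelSize = obj@pixelSize))
  } else if (is(obj, "StimulusMovie")) {
    list(class = "StimulusMovie",
         arrays = list(frames = obj@frames, frameEdges = obj@frameEdges),
         meta = list(frameRate = obj@frameRate),
         tables = list(trials = obj@trials))
  } else if (is(obj, "Mosaic")) {
    list(class = "Mosaic",
         meta = list(pixelSize = obj@pixelSize,
                     fieldShape = as.integer(obj@fieldShape)),
         tables = list(cells = obj@cells))
  } else if (is.array(obj) || is.numeric(obj) || is.integer(obj)) {
    list(class = "array", arrays = list(data = obj))
  } else {
    stop("unsupported object class: ", paste(class(obj), collapse = "/"))
  }
}

partsToObject <- function(parts, dir, name) {
  arr <- function(a) readArrayTxt(file.path(dir, paste0(name, ".", a, ".txt")))
  tab <- function(a) read.csv(file.path(dir, paste0(name, ".", a, ".csv")),
                              stringsAsFactors = FALSE)
  switch(parts$class,
    BinnedSpikes = {
      sp <- arr("spikes")
      storage.mode(sp) <- "integer"
      new("BinnedSpikes", spikes = sp, cellIds = as.integer(arr("cellIds")))
    },
    DriftTrajectory = {
      st <- arr("steps")
      storage.mode(st) <- "integer"
      um <- arr("stepsUm")
      colnames(st) <- colnames(um) <- c("dy", "dx")
      new("DriftTrajectory", steps = st, stepsUm = um,
          nFrames = as.integer(parts$meta$nFrames),
          diffusionConstant = parts$meta$diffusionConstant,
          pixelSize = parts$meta$pixelSize)
    },
    StimulusMovie = new("StimulusMovie", frames = arr("frames"),
                        frameEdges = as.integer(arr("frameEdges")),
                        frameRate = parts$meta$frameRate,
                        trials = tab("trials")),
    Mosaic = new("Mosaic", cells = tab("cells"),
                 pixelSize = parts$meta$pixelSize,
                 fieldShape = as.integer(parts$meta$fieldShape)),
    array = arr("data"),
    stop("unknown stored class: ", parts$class)
  )
}

#' Save / load a container of analysis objects
#'
#' A container is a directory of full-precision text arrays and CSV tables
#' plus a JSON manifest recording the schema version, the seed, a config
#' hash, and an md5 checksum for every file. Save followed by load is
#' bit-identical for all arrays and metadata.
#'
#' @param objects named list of objects (BinnedSpikes, StimulusMovie,
#'   DriftTrajectory, Mosaic, or plain arrays)
#' @param path container directory (created if missing)
#' @param seed seed to stamp into the manifest
#' @param config configuration list to hash into the manifest
#' @return (invisibly) the manifest list
#' @export
saveContainer <- function(objects, path, seed = NA, config = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schemaVersion = CONTAINER_SCHEMA, seed = seed,
                   configHash = hashConfig(config), objects = list())
  for (name in names(objects)) {
    parts <- objectToParts(objects[[name]])
    entry <- list(class = parts$class, meta = parts$meta)
    for (a in names(parts$arrays)) {
      writeArrayTxt(parts$arrays[[a]], file.path(path, paste0(name, ".", a, ".txt")))
    }
    for (a in names(parts$tables)) {
      writeTableCsv(parts$tables[[a]],
                    file.path(path, paste0(name, ".", a, ".csv")))
    }
    manifest$objects[[name]] <- entry
  }
  files <- setdiff(list.files(path), "manifest.json")
  manifest$checksums <- as.list(tools::md5sum(file.path(path, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname saveContainer
#' @export
loadContainer <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("container not found: ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ver <- manifest$schemaVersion
  if (identical(ver, "0.9")) {
    warning("migrating container from schema 0.9 to ", CONTAINER_SCHEMA)
    manifest$schemaVersion <- CONTAINER_SCHEMA
  } else if (!identical(ver, CONTAINER_SCHEMA)) {
    stop("unsupported container schema version: ", ver)
  }
  out <- list()
  objNames <- names(manifest$objects)
  for (name in objNames) {
    e <- manifest$objects[[name]]
    out[[name]] <- partsToObject(list(class = e$class, meta = as.list(e$meta)),
                                 path, name)
  }
  attr(out, "manifest") <- manifest
  out
}

## CSV writer that round-trips doubles exactly (17 significant digits)
writeTableCsv <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- formatC(out[[cn]], digits = 17,
                                                  format = "g")
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
}

hashConfig <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a grayscale image to PNG
#'
#' @param image matrix with values in [0, 1] (clipped)
#' @param path output file
#' @export
writeImagePng <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
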