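# Movie / ROI / table I/O, data-set scanning and the analysis batch.

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file path.
#' @return numeric array H x W x nFrames (raw counts).
#' @export
readMovieTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(0, c(H, W, length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' Write a movie as multi-page 16-bit TIFF
#'
#' @param stack array H x W x nFrames of non-negative counts (or a
#'   [SyntheticMovie-class]); values are clipped to the 16-bit range.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMovieTiff <- function(stack, path) {
  if (is(stack, "SyntheticMovie")) stack <- stack@stack
  nF <- dim(stack)[3]
  pages <- lapply(seq_len(nF), function(f)
    pmin(pmax(stack[, , f], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a ROI mask image
#'
#' Any non-zero pixel belongs to the region of interest.
#'
#' @param path image path (TIFF).
#' @return logical matrix.
#' @export
readRoiMask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0
}

#' Write / read localization tables
#'
#' CSV schema: `frame`, `x_px`, `y_px`, `x_um`, `y_um`, `amplitude`,
#' `background`.
#'
#' @param locs localization data.frame (as from [detectSpots()]).
#' @param path CSV path.
#' @param pixelSizeUm pixel size used to fill missing unit columns.
#' @return `path` invisibly / the localization data.frame.
#' @export
writeLocalizations <- function(locs, path, pixelSizeUm = 0.16) {
  xPx <- if ("x_px" %in% names(locs)) locs$x_px else locs$x / pixelSizeUm
  yPx <- if ("y_px" %in% names(locs)) locs$y_px else locs$y / pixelSizeUm
  out <- data.frame(frame = locs$frame, x_px = xPx, y_px = yPx,
                    x_um = if ("x" %in% names(locs)) locs$x else xPx * pixelSizeUm,
                    y_um = if ("y" %in% names(locs)) locs$y else yPx * pixelSizeUm,
                    amplitude = if ("amplitude" %in% names(locs)) locs$amplitude else NA,
                    background = if ("background" %in% names(locs)) locs$background else NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path) {
  df <- utils::read.csv(path)
  data.frame(frame = df$frame, x = df$x_um, y = df$y_um,
             x_px = df$x_px, y_px = df$y_px,
             amplitude = df$amplitude, background = df$background)
}

#' Write / read track tables
#'
#' CSV schema: `track_id`, `frame`, `time_s`, `x_um`, `y_um`, `gap_flag`,
#' `intensity` (NA when unknown). `readTracks` reconstructs a
#' [TrackSet-class]; the tracking parameters stored in the header comment
#' are restored when present.
#'
#' @param ts a [TrackSet-class].
#' @param path CSV path.
#' @return `path` invisibly / a [TrackSet-class].
#' @export
writeTracks <- function(ts, path) {
  tr <- ts@tracks
  out <- data.frame(track_id = tr$track_id, frame = tr$frame,
                    time_s = (tr$frame - 1) * ts@frameCycleTime,
                    x_um = tr$x, y_um = tr$y, gap_flag = as.integer(tr$gap),
                    intensity = if ("intensity" %in% names(tr)) tr$intensity else NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sptkit tracks: radius_um=%g gap=%d min_before_gap=%d tau_s=%g",
                     ts@params$trackingRadius, ts@params$maxGapFrames,
                     ts@params$minFramesBeforeGap, ts@frameCycleTime), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#")
  getNum <- function(key, default) {
    m <- regmatches(hdr, regexec(paste0(key, "=([0-9.eE+-]+)"), hdr))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else default
  }
  tau <- getNum("tau_s", 1)
  params <- trackingParams(getNum("radius_um", 1),
                           maxGapFrames = as.integer(getNum("gap", 1)),
                           minFramesBeforeGap = as.integer(getNum("min_before_gap", 2)))
  tr <- data.frame(track_id = df$track_id, frame = df$frame, x = df$x_um,
                   y = df$y_um, gap = df$gap_flag > 0,
                   loc_id = seq_len(nrow(df)))
  new("TrackSet", tracks = tr, params = unclass(params),
      frameCycleTime = tau, source = path)
}

#' Parse frame-cycle times from file names
#'
#' Applies a regular expression with one capture group to each file name;
#' the captured text must be a number followed by an optional unit (`ms` or
#' `s`, default seconds).
#'
#' @param files character vector of file names.
#' @param pattern regex with one capture group, e.g. `"tl-([0-9]+ms)"`.
#' @return numeric vector of frame-cycle times in seconds (NA when the
#'   pattern does not match).
#' @export
parseFrameCycleTime <- function(files, pattern) {
  vapply(files, function(f) {
    m <- regmatches(f, regexec(pattern, f))[[1]]
    if (length(m) < 2) return(NA_real_)
    tok <- m[2]
    num <- as.numeric(sub("(ms|s)$", "", tok))
    if (grepl("ms$", tok)) num / 1000 else num
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan a folder structure for movies
#'
#' Recursively discovers TIFF movies below `root`, parses the frame-cycle
#' time from each file name with `pattern`, and reports unmatched files.
#'
#' @param root folder to scan.
#' @param pattern regex with one capture group for the frame-cycle time
#'   (see [parseFrameCycleTime()]).
#' @param roiSuffix optional suffix marking ROI mask images, matched by file
#'   name next to each movie (default "_roi").
#' @return list of class `"DataSet"`: `movies` (data.frame `path`, `tau`,
#'   `roi`), `unmatched` (paths without a parsable frame-cycle time).
#' @export
scanFolders <- function(root, pattern, roiSuffix = "_roi") {
  all <- list.files(root, pattern = "\\.tiff?$", recursive = TRUE,
                    full.names = TRUE, ignore.case = TRUE)
  isRoi <- grepl(paste0(roiSuffix, "\\.tiff?$"), all, ignore.case = TRUE)
  movies <- all[!isRoi]
  if (!length(movies)) {
    warning("no TIFF movies found under ", root)
    return(structure(list(movies = data.frame(path = character(0),
                                              tau = numeric(0),
                                              roi = character(0)),
                          unmatched = character(0)), class = "DataSet"))
  }
  tau <- parseFrameCycleTime(basename(movies), pattern)
  roi <- vapply(movies, function(p) {
    cand <- sub("\\.tiff?$", paste0(roiSuffix, ".tif"), p, ignore.case = TRUE)
    if (file.exists(cand)) cand else NA_character_
  }, character(1), USE.NAMES = FALSE)
  structure(list(movies = data.frame(path = movies[!is.na(tau)],
                                     tau = tau[!is.na(tau)],
                                     roi = roi[!is.na(tau)],
                                     stringsAsFactors = FALSE),
                 unmatched = movies[is.na(tau)]),
            class = "DataSet")
}

#' @export
print.DataSet <- function(x, ...) {
  cat("DataSet:", nrow(x$movies), "movie(s),",
      length(unique(x$movies$tau)), "condition(s)\n")
  for (tau in sort(unique(x$movies$tau)))
    cat(sprintf("  tau = %g s: %d movie(s)\n", tau, sum(x$movies$tau == tau)))
  if (length(x$unmatched))
    cat("  unmatched:", length(x$unmatched), "file(s)\n")
  invisible(x)
}

#' Run the detection/tracking pipeline over a data set
#'
#' Applies spot detection and nearest-neighbour linking to every movie of a
#' data set with per-condition tracking parameters, isolating failures per
#' movie. Results and the exact parameters that produced them are collected
#' in an analysis batch.
#'
#' @param dataset a `"DataSet"` from [scanFolders()].
#' @param threshold detection threshold in filter-response units.
#' @param paramsByTau named list mapping frame-cycle time (as character) to
#'   [trackingParams()]; a single `TrackingParams` is recycled for all
#'   conditions.
#' @param pixelSizeUm pixel size in um.
#' @param stages character subset of c("detect", "track").
#' @return list of class `"AnalysisBatch"`: `movies` (per movie: `path`,
#'   `tau`, `locs`, `trackset` or `error`), `params`, `provenance`.
#' @export
runBatch <- function(dataset, threshold, paramsByTau, pixelSizeUm = 0.16,
                     stages = c("detect", "track")) {
  if (inherits(paramsByTau, "TrackingParams")) {
    taus <- unique(dataset$movies$tau)
    paramsByTau <- stats::setNames(rep(list(paramsByTau), length(taus)),
                                   as.character(taus))
  }
  movies <- vector("list", nrow(dataset$movies))
  for (i in seq_len(nrow(dataset$movies))) {
    row <- dataset$movies[i, ]
    rec <- list(path = row$path, tau = row$tau)
    res <- tryCatch({
      if ("detect" %in% stages) {
        stack <- readMovieTiff(row$path)
        roi <- if (!is.na(row$roi)) readRoiMask(row$roi) else NULL
        rec$locs <- detectSpots(stack, threshold, roiMask = roi,
                                pixelSizeUm = pixelSizeUm)
      }
      if ("track" %in% stages && !is.null(rec$locs)) {
        p <- paramsByTau[[as.character(row$tau)]]
        rec$trackset <- nearestNeighbourLink(rec$locs, p,
                                             frameCycleTime = row$tau,
                                             source = row$path)
      }
      rec
    }, error = function(e) { rec$error <- conditionMessage(e); rec })
    movies[[i]] <- res
  }
  structure(list(movies = movies,
                 params = list(threshold = threshold,
                               tracking = paramsByTau,
                               pixelSizeUm = pixelSizeUm),
                 provenance = list(created = format(Sys.time()),
                                   package = as.character(utils::packageVersion("sptkit")))),
            class = "AnalysisBatch")
}

#' Export tracks of a batch to CSV files
#'
#' Writes one tracks CSV per successfully tracked movie (schema of
#' [writeTracks()]).
#'
#' @param batch an `"AnalysisBatch"`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths.
#' @export
exportTracks <- function(batch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (rec in batch$movies) {
    if (is.null(rec$trackset)) next
    p <- file.path(dir, paste0(sub("\\.tiff?$", "", basename(rec$path),
                                   ignore.case = TRUE), "_tracks.csv"))
    writeTracks(rec$trackset, p)
    out <- c(out, p)
  }
  out
}

#' Save / load an analysis batch as a directory
#'
#' The batch is serialized as a directory: a YAML manifest (parameters,
#' provenance, movie list) plus one localization CSV and one tracks CSV per
#' movie — diff-able and language-neutral. Saving an unchanged batch twice
#' produces identical files.
#'
#' @param batch an `"AnalysisBatch"`.
#' @param dir target directory.
#' @return `dir` invisibly / the reloaded `"AnalysisBatch"`.
#' @export
saveBatch <- function(batch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    params = list(threshold = batch$params$threshold,
                  pixelSizeUm = batch$params$pixelSizeUm,
                  tracking = lapply(batch$params$tracking, unclass)),
    provenance = batch$provenance,
    movies = lapply(batch$movies, function(rec)
      list(path = rec$path, tau = rec$tau,
           error = if (!is.null(rec$error)) rec$error)))
  yaml::write_yaml(manifest, file.path(dir, "batch.yaml"))
  for (i in seq_along(batch$movies)) {
    rec <- batch$movies[[i]]
    stem <- sprintf("movie%03d", i)
    if (!is.null(rec$locs))
      writeLocalizations(rec$locs, file.path(dir, paste0(stem, "_locs.csv")),
                         batch$params$pixelSizeUm)
    if (!is.null(rec$trackset))
      writeTracks(rec$trackset, file.path(dir, paste0(stem, "_tracks.csv")))
  }
  invisible(dir)
}

#' @rdname saveBatch
#' @export
loadBatch <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "batch.yaml"))
  movies <- vector("list", length(manifest$movies))
  for (i in seq_along(manifest$movies)) {
    rec <- manifest$movies[[i]]
    stem <- sprintf("movie%03d", i)
    lp <- file.path(dir, paste0(stem, "_locs.csv"))
    tp <- file.path(dir, paste0(stem, "_tracks.csv"))
    if (file.exists(lp)) rec$locs <- readLocalizations(lp)
    if (file.exists(tp)) rec$trackset <- readTracks(tp)
    movies[[i]] <- rec
  }
  tracking <- lapply(manifest$params$tracking, function(p)
    trackingParams(p$trackingRadius, p$maxGapFrames, p$minFramesBeforeGap,
                   p$minTrackLengthBound))
  structure(list(movies = movies,
                 params = list(threshold = manifest$params$threshold,
                               tracking = tracking,
                               pixelSizeUm = manifest$params$pixelSizeUm),
                 provenance = manifest$provenance),
            class = "AnalysisBatch")
}

#' Write ground truth and scenario metadata of a synthetic movie
#'
#' `writeGroundTruth` writes the per-frame true positions as CSV (columns
#' `trajectory_id`, `frame`, `x_um`, `y_um`, `state_id`, `alive`);
#' `writeScenarioYaml` stores the full scenario parameterization as YAML.
#'
#' @param traj output of [simulateTrajectories()] (or the `groundTruth` of a
#'   [SyntheticMovie-class]).
#' @param path output path.
#' @return `path` invisibly.
#' @export
writeGroundTruth <- function(traj, path) {
  out <- data.frame(trajectory_id = traj$id, frame = traj$frame,
                    x_um = traj$x, y_um = traj$y, state_id = traj$state,
                    alive = 1L)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @param scenario a [SimScenario-class].
#' @export
writeScenarioYaml <- function(scenario, path) {
  yaml::write_yaml(list(
    moleculesPerFrame = scenario@moleculesPerFrame,
    states = lapply(scenario@states, unclass),
    bleachProbPerFrame = scenario@bleachProbPerFrame,
    timelapseConditions = scenario@timelapseConditions,
    exposureTime = scenario@exposureTime, nFrames = scenario@nFrames,
    frameSize = scenario@frameSize, psfWidth = scenario@psfWidth,
    pixelSizeUm = scenario@pixelSizeUm, snr = scenario@snr,
    dBound = scenario@dBound, dFree = scenario@dFree,
    lognormalShape = scenario@lognormalShape,
    backgroundLevel = scenario@backgroundLevel,
    backgroundNoise = scenario@backgroundNoise,
    structureAmplitude = scenario@structureAmplitude), path)
  invisible(path)
}

#' Read a scenario from YAML
#' @param path YAML path written by [writeScenarioYaml()].
#' @return a [SimScenario-class].
#' @export
readScenarioYaml <- function(path) {
  y <- yaml::read_yaml(path)
  states <- lapply(y$states, function(s)
    bindingState(s$dissociationRate, s$relativeFrequency, s$diffusionCoeff))
  simScenario(y$moleculesPerFrame, states, y$bleachProbPerFrame,
              unlist(y$timelapseConditions), y$exposureTime, y$nFrames,
              y$frameSize, y$psfWidth, y$pixelSizeUm, y$snr, y$dBound,
              y$dFree, y$lognormalShape, y$backgroundLevel,
              y$backgroundNoise, y$structureAmplitude)
}
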