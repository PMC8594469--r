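# --- File formats, configuration, and the end-to-end pipeline ---

#' Write a track table as CSV
#'
#' Rows are ordered by `(track_id, frame)`; positions keep full double
#' precision so metrics round-trip.
#'
#' @param tracks Long-format track data frame (`track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, plus optional columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  req <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing_cols <- setdiff(req, names(tracks))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a track table CSV
#'
#' @param path CSV written by [write_tracks_csv()] (or matching its schema).
#' @return Track data frame ordered by `(track_id, frame)`. An empty file
#'   with a valid header yields zero rows.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(df)
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  key <- paste(df$track_id, df$frame)
  if (anyDuplicated(key)) {
    stop("duplicated (track_id, frame) row(s): ", key[duplicated(key)][1])
  }
  bad <- vapply(split(df$frame, df$track_id),
                function(f) any(diff(f) <= 0), logical(1))
  if (any(bad)) {
    stop("non-monotone frames within track(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask_png()]
#'
#' @param path PNG file.
#' @return Logical matrix (pixels > 0.5 are `TRUE`).
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write an image stack as multi-page TIFF with a calibration sidecar
#'
#' Frames are rescaled to `[0, 1]` and written as 32-bit float TIFF pages;
#' the intensity scale and calibration go to `<path>.json` as
#' `{pixel_size_um, frame_interval_s, intensity_scale}`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(stack$frames, 1)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(f) stack$frames[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size,
         frame_interval_s = stack$frame_interval,
         intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF file with its `.json` sidecar.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  cal <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scale <- cal$intensity_scale %||% 1
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    frames[, , f] <- pg * scale
  }
  image_stack(frames, cal$pixel_size_um, cal$frame_interval_s)
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' @param path Configuration file; format chosen by extension
#'   (`.yml`/`.yaml` vs `.json`).
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Run the track-level analysis pipeline
#'
#' Simulates a particle population, writes the track table, computes per-track
#' metrics, applies the duration filter and the displacement/linearity
#' classification, and writes per-stage CSV outputs plus a JSON manifest
#' with parameters, the seed, and md5 hashes of every output. The same
#' configuration and seed give byte-identical outputs.
#'
#' @param config Named list (or file read by [read_pipeline_config()]) with
#'   optional entries `motion` (arguments to [motion_params()]),
#'   `thresholds` (arguments to [classifier_thresholds()]), `n_tracks`,
#'   `perturbation`, `seed`, `outdir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- config$outdir %||% stop("config$outdir is required")
  seed <- config$seed %||% 1L
  n_tracks <- config$n_tracks %||% 500L
  pert <- config$perturbation %||% "none"
  params <- do.call(motion_params, as.list(config$motion %||% list()))
  thr <- do.call(classifier_thresholds, as.list(config$thresholds %||% list()))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  pop <- tryCatch(
    simulate_population(params, n_tracks, pert, seed = seed),
    error = function(e) stop("stage simulate failed: ", conditionMessage(e))
  )
  tracks_path <- file.path(outdir, "tracks.csv")
  write_tracks_csv(pop$tracks, tracks_path)

  metrics <- tryCatch(
    track_metrics(
      filter_by_duration(pop$tracks, thr$min_duration, params$frame_interval),
      params$frame_interval
    ),
    error = function(e) stop("stage metrics failed: ", conditionMessage(e))
  )
  metrics_path <- file.path(outdir, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE, quote = FALSE)

  classified <- classify_tracks(metrics, thr)
  classified_path <- file.path(outdir, "classified.csv")
  utils::write.csv(classified, classified_path, row.names = FALSE, quote = FALSE)

  summary_df <- data.frame(
    n_tracks = nrow(classified),
    n_directed = sum(classified$motion_class == "long_directed"),
    pct_directed = directed_fraction(classified)
  )
  summary_path <- file.path(outdir, "summary.csv")
  utils::write.csv(summary_df, summary_path, row.names = FALSE, quote = FALSE)

  outputs <- c(tracks = tracks_path, metrics = metrics_path,
               classified = classified_path, summary = summary_path)
  manifest <- list(
    seed = seed,
    n_tracks = n_tracks,
    perturbation = pert,
    motion = unclass(params),
    thresholds = unclass(thr),
    outputs = as.list(outputs),
    md5 = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
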