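#' Write an optical movie as a multi-frame 32-bit float TIFF
#'
#' One TIFF page per frame plus a JSON sidecar (`<file>.json`) carrying
#' `dx_mm`, `frame_interval_ms` and `t0_ms`.
#'
#' @param movie `vf_movie`
#' @param path output TIFF path
#' @return the path, invisibly
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "vf_movie"))
  d <- dim(movie$frames)
  # TIFF float samples are stored in [0, 1]; the affine scale lives in
  # the sidecar so the round trip is exact to float precision
  lo <- min(movie$frames); hi <- max(movie$frames)
  sc <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(k) (movie$frames[, , k] - lo) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(dx_mm = movie$dx_mm, frame_interval_ms = movie$frame_ms,
         t0_ms = movie$t0_ms, value_offset = lo, value_scale = sc),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an optical movie written by [write_movie_tiff()]
#' @param path TIFF path (expects the JSON sidecar alongside)
#' @return `vf_movie`
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  off <- meta$value_offset %||% 0
  sc <- meta$value_scale %||% 1
  vf_movie(arr * sc + off, dx_mm = meta$dx_mm,
           frame_ms = meta$frame_interval_ms, t0_ms = meta$t0_ms)
}

#' Write a scalar map as TIFF plus CSV
#'
#' 32-bit float TIFF (invalid pixels as NaN) and a long-format CSV with
#' `row`, `col`, `value`, `valid`.
#'
#' @param map `vf_map`
#' @param stem output path stem (writes `<stem>.tif` and `<stem>.csv`)
#' @return the stem, invisibly
#' @export
write_map <- function(map, stem) {
  stopifnot(inherits(map, "vf_map"))
  v <- map$values
  ok <- map$valid & is.finite(v)
  lo <- if (any(ok)) min(v[ok]) else 0
  hi <- if (any(ok)) max(v[ok]) else 1
  sc <- if (hi > lo) hi - lo else 1
  vs <- (v - lo) / sc
  vs[!ok] <- 0          # TIFF floats cannot carry NaN here; CSV has the mask
  tiff::writeTIFF(vs, paste0(stem, ".tif"), bits.per.sample = 32)
  jsonlite::write_json(list(kind = map$kind, dx_mm = map$dx_mm,
                            value_offset = lo, value_scale = sc),
                       paste0(stem, ".tif.json"), auto_unbox = TRUE,
                       digits = NA)
  df <- data.frame(row = as.vector(row(v)), col = as.vector(col(v)),
                   value = as.vector(map$values),
                   valid = as.vector(map$valid))
  write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' Write an ECG record as CSV plus pacing sidecar
#' @param ecg `vf_ecg`
#' @param path CSV path (`time_ms`, `amplitude`); pacing events go to
#'   `<path>.json`
#' @return the path, invisibly
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "vf_ecg"))
  write.csv(data.frame(time_ms = ecg$time_ms, amplitude = ecg$amp),
            path, row.names = FALSE)
  jsonlite::write_json(ecg$pacing, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Read an ECG record written by [write_ecg_csv()]
#' @param path CSV path
#' @return `vf_ecg`
#' @export
read_ecg_csv <- function(path) {
  df <- read.csv(path)
  pacing <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(pacing) == 0)
    pacing <- data.frame(time_ms = numeric(0), kind = character(0),
                         cycle_ms = numeric(0))
  ecg <- structure(list(time_ms = df$time_ms, amp = df$amplitude,
                        dt_ms = median(diff(df$time_ms)),
                        pacing = pacing), class = "vf_ecg")
  ecg
}

#' Write the ground truth of an episode as JSON (+ truth maps as TIFF)
#' @param truth the `truth` element of a [simulate_tissue()] result
#' @param stem output stem (writes `<stem>.json`; truth AT/APD maps for a
#'   window can be written separately with [write_map()])
#' @return the stem, invisibly
#' @export
write_truth_json <- function(truth, stem) {
  out <- list(
    stim = truth$stim, ectopic = truth$ectopic, vf = truth$vf,
    truth_contour = truth$truth_contour,
    lesion_fraction = truth$lesion_fraction,
    pacing_log = truth$pacing_log,
    n_rows = truth$n_rows, n_cols = truth$n_cols)
  jsonlite::write_json(out, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(stem)
}

#' Generate and write a set of episode bundles
#'
#' Generates `n` seeded episodes and writes, per episode, the fluorescence
#' movie (TIFF + sidecar), the pseudo-ECG (CSV + pacing sidecar) and the
#' ground truth (JSON), plus a manifest listing every file with its MD5
#' checksum and generator parameters. Reproducible: identical seeds give
#' identical manifests and movies.
#'
#' @param config [study_config()]
#' @param n number of episodes
#' @param out_dir output directory (created)
#' @param seed master seed
#' @return manifest data.frame, invisibly (also written as
#'   `manifest.json`)
#' @export
generate_episode_set <- function(config = study_config(), n = 1, out_dir,
                                 seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  ep_seeds <- if (n > 0) sample.int(.Machine$integer.max %/% 2, n) else integer(0)
  files <- character(0)
  for (k in seq_len(n)) {
    ep <- synth_preparation(config, seed = ep_seeds[k])
    stem <- file.path(out_dir, sprintf("episode_%03d", k))
    write_movie_tiff(ep$optical, paste0(stem, "_movie.tif"))
    write_ecg_csv(ep$ecg, paste0(stem, "_ecg.csv"))
    write_truth_json(ep$sim$truth, paste0(stem, "_truth"))
    files <- c(files, paste0(stem, "_movie.tif"),
               paste0(stem, "_movie.tif.json"),
               paste0(stem, "_ecg.csv"), paste0(stem, "_ecg.csv.json"),
               paste0(stem, "_truth.json"))
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = if (length(files)) unname(tools::md5sum(files)) else character(0),
    stringsAsFactors = FALSE)
  meta <- list(n = n, seed = seed, episode_seeds = ep_seeds,
               files = manifest)
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}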