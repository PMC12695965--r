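#' Write and read observation tables
#'
#' Observation tables travel as plain CSV with the columns `obs_id`,
#' `species_true` (if ground-truthed), `range_m`, `t0_s`, `transit_ms`.
#'
#' @param observations observation data frame.
#' @param path CSV file path.
#' @name observation_io
NULL

#' @rdname observation_io
#' @export
write_observations <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname observation_io
#' @export
read_observations <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read ragged waveform stores
#'
#' Waveforms are stored in long CSV form (`obs_id`, `sample`,
#' `intensity`), one row per sample, keyed by observation id.
#'
#' @param waveforms named list of intensity vectors.
#' @param path CSV file path.
#' @name waveform_io
NULL

#' @rdname waveform_io
#' @export
write_waveforms <- function(waveforms, path) {
  df <- data.frame(
    obs_id = rep(names(waveforms), lengths(waveforms)),
    sample = unlist(lapply(waveforms, seq_along), use.names = FALSE),
    intensity = unlist(waveforms, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname waveform_io
#' @export
read_waveforms <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  split(df$intensity, factor(df$obs_id, levels = unique(df$obs_id)))
}

#' Write and read raw frame blocks
#'
#' Frame blocks are written as flat little-endian unsigned 16-bit binary
#' in the native acquisition layout (column-major: all range bins of
#' exposure 1, then exposure 2, ...), with a JSON sidecar (`<path>.json`)
#' carrying the geometry and axes. The default full-geometry block
#' (2048 range bins x 35,000 exposures) occupies
#' `2048 * 35000 * 2` bytes.
#'
#' @param block integer matrix, range bins x exposures, values in
#'   `[0, 65535]`.
#' @param path output path for the binary payload.
#' @param range_axis,fs axes stored in the sidecar.
#' @name frame_io
NULL

#' @rdname frame_io
#' @export
write_frame_block <- function(block, path, range_axis = NULL, fs = NULL) {
  stopifnot(is.matrix(block))
  v <- as.integer(block)
  if (any(v < 0 | v > 65535)) stop("intensities must fit in uint16")
  con <- file(path, "wb")
  on.exit(close(con))
  # uint16 little-endian: write as raw pairs
  writeBin(as.raw(rbind(v %% 256L, v %/% 256L)), con)
  sidecar <- list(n_range_bins = nrow(block), n_exposures = ncol(block),
                  dtype = "uint16le",
                  range_axis = range_axis, fs = fs)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname frame_io
#' @export
read_frame_block <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_range_bins * meta$n_exposures
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = 2 * n)
  lo <- as.integer(raw[seq(1, 2 * n, by = 2)])
  hi <- as.integer(raw[seq(2, 2 * n, by = 2)])
  m <- matrix(lo + 256L * hi, nrow = meta$n_range_bins)
  attr(m, "range_axis") <- meta$range_axis
  attr(m, "fs") <- meta$fs
  m
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields are passed to [run_config()]. A `seed`
#'   entry is mandatory.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed", call. = FALSE)
  do.call(run_config, y)
}
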