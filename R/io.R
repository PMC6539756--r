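# Readers/writers: geometry tables, waveform export, key-value configs
# and run manifests. Delimited text is comma-separated with '.' decimal
# and '#'-prefixed header comments.

unit_factor <- function(units = c("m", "mm", "cm")) {
  switch(match.arg(units), m = 1, mm = MM_TO_M, cm = CM_TO_M)
}

#' Read a sensor geometry from delimited text
#'
#' The file must have a header with columns `x`, `y`, `z` and at least
#' four rows; `#` lines are comments. Coordinates are converted to
#' meters according to `units`.
#'
#' @param path File path.
#' @param units Units of the coordinates in the file: `"m"`, `"mm"` or
#'   `"cm"`.
#' @param ref_index Reference sensor (default 1).
#' @return A [sensor_array()] in meters.
#' @export
load_geometry <- function(path, units = c("m", "mm", "cm"), ref_index = 1L) {
  if (!file.exists(path)) stop(sprintf("geometry file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  missing_cols <- setdiff(c("x", "y", "z"), names(df))
  if (length(missing_cols))
    stop(sprintf("geometry file %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  for (cn in c("x", "y", "z")) {
    v <- df[[cn]]
    if (!is.numeric(v))
      stop(sprintf("non-numeric cell in column '%s' of %s", cn, path))
  }
  if (nrow(df) < 4L)
    stop(sprintf("geometry file %s has %d rows; at least 4 sensors required",
                 path, nrow(df)))
  sensor_array(as.matrix(df[, c("x", "y", "z")]) * unit_factor(units),
               ref_index = ref_index)
}

#' Write a sensor geometry to delimited text
#'
#' @param array A [sensor_array()].
#' @param path Output path.
#' @param units Units to write the coordinates in.
#' @return `path`, invisibly.
#' @export
save_geometry <- function(array, path, units = c("m", "mm", "cm")) {
  stopifnot(inherits(array, "sensor_array"))
  fac <- unit_factor(units)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sensor geometry, units = %s, ref_index = %d",
                     match.arg(units), array$ref_index), con)
  utils::write.csv(data.frame(x = array$positions[, 1] / fac,
                              y = array$positions[, 2] / fac,
                              z = array$positions[, 3] / fac),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save waveforms to disk
#'
#' `delimited_text` writes a full-precision CSV (`t_s`, one column per
#' channel) with a `#` metadata header; `array_container` uses R
#' serialization (RDS) for a lossless, bit-identical roundtrip with all
#' metadata embedded.
#'
#' @param signals A [pressure_signal()] or list of them sharing one
#'   sample rate.
#' @param path Output path.
#' @param format `"delimited_text"` or `"array_container"`.
#' @return `path`, invisibly.
#' @export
save_waveforms <- function(signals, path,
                           format = c("delimited_text", "array_container")) {
  format <- match.arg(format)
  if (inherits(signals, "pressure_signal")) signals <- list(signals)
  if (!length(signals)) stop("empty signal list")
  stopifnot(all(vapply(signals, inherits, TRUE, "pressure_signal")))
  fs <- signals[[1]]$fs
  if (any(abs(vapply(signals, `[[`, 0, "fs") - fs) > 1e-9 * fs))
    stop("all signals must share one sample rate")
  if (format == "array_container") {
    saveRDS(signals, path)
    return(invisible(path))
  }
  t0 <- signals[[1]]$t0
  n <- max(vapply(signals, function(s) length(s$samples), 0L))
  cols <- lapply(signals, function(s) c(s$samples, rep(NA, n - length(s$samples))))
  df <- data.frame((t0 + (seq_len(n) - 1) / fs), cols)
  names(df) <- c("t_s", paste0("p_pa_ch", seq_along(signals)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# waveforms: fs_hz = %.10g, t0_s = %.10g, units = Pa, channels = %d",
                     fs, t0, length(signals)), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load waveforms saved by [save_waveforms()]
#'
#' @param path File path (CSV or RDS container).
#' @param format Storage format used when saving.
#' @return List of [pressure_signal()].
#' @export
load_waveforms <- function(path,
                           format = c("delimited_text", "array_container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("waveform file not found: %s", path))
  if (format == "array_container") return(readRDS(path))
  hdr <- readLines(path, n = 1L)
  fs <- as.numeric(sub(".*fs_hz = ([0-9.eE+-]+).*", "\\1", hdr))
  t0 <- as.numeric(sub(".*t0_s = ([0-9.eE+-]+).*", "\\1", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  lapply(df[, -1, drop = FALSE], function(col)
    pressure_signal(col[!is.na(col)], fs = fs, t0 = t0))
}

#' Read a key-value configuration file
#'
#' Debian-control-style `key: value` text; numeric-looking values are
#' converted to numbers.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  m <- read.dcf(path)
  out <- as.list(m[1, ])
  lapply(out, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
}

#' Write a run manifest
#'
#' Records the package version, full parameter set, RNG seed, input
#' file digests and a timestamp as JSON; sufficient to reproduce the
#' run exactly.
#'
#' @param dir Output directory.
#' @param params Named list of parameters.
#' @param seed Integer seed (or NULL).
#' @param inputs Character vector of input file paths to digest.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, params, seed = NULL, inputs = character()) {
  manifest <- list(
    tool = "braggloc",
    version = as.character(utils::packageVersion("braggloc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    input_digests = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list()
  )
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
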