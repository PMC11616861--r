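#' Write signals to a European Data Format (EDF) file
#'
#' Minimal continuous-EDF writer: 16-bit samples, one fixed-length data
#' record per `record_s` seconds, physical range set per channel from the
#' signal extrema (so quantisation error is at most range/2^16). All
#' channels must share the sampling rate. A JSON sidecar with sampling
#' rate and units can be written alongside.
#'
#' @param signals named list of numeric vectors (uV), equal lengths.
#' @param fs_hz sampling rate.
#' @param path output file path.
#' @param record_s data-record duration in seconds (default 4).
#' @param sidecar logical; write `<path>.json` with metadata (default
#'   TRUE).
#' @param extra named list merged into the sidecar (e.g. ground truth).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs_hz, path, record_s = EPOCH_LEN_S,
                      sidecar = TRUE, extra = NULL) {
  ns <- length(signals)
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1) stop("all channels must have equal length", call. = FALSE)
  spr <- fs_hz * record_s
  if (spr != round(spr)) stop("fs_hz * record_s must be integer", call. = FALSE)
  n_rec <- floor(n / spr)
  if (n_rec < 1) stop("signal shorter than one data record", call. = FALSE)

  pad <- function(x, width) {
    formatC(substr(as.character(x), 1, width), width = width, flag = "-")
  }
  phys_min <- vapply(signals, function(s) min(-1, floor(min(s))), numeric(1))
  phys_max <- vapply(signals, function(s) max(1, ceiling(max(s))), numeric(1))
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("tinsleep", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8),
                pad(format(record_s), 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, pad, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  }
  field(names(signals), 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(format(phys_min, trim = TRUE), 8)
  field(format(phys_max, trim = TRUE), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      dig <- round((signals[[i]][idx] - phys_min[i]) / scale[i] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  if (sidecar) {
    meta <- c(list(fs_hz = fs_hz, units = "uV", channels = names(signals),
                   n_samples = n_rec * spr, record_s = record_s), extra)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a continuous EDF file written by [write_edf()] (or any
#' fixed-rate 16-bit EDF), returning physical-unit signals. If
#' `expect_channels` is given, missing channel labels raise an error
#' naming the expected label.
#'
#' @param path EDF file path.
#' @param expect_channels optional character vector of required channel
#'   labels.
#' @return list with `signals` (named list, physical units), `fs_hz`,
#'   `record_s`, `labels`, `units`.
#' @export
read_edf <- function(path, expect_channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))

  if (!is.null(expect_channels)) {
    missing <- setdiff(expect_channels, labels)
    if (length(missing)) {
      stop("EDF file is missing expected channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dig_min[i]) * scale[i] + phys_min[i]
    }
  }
  names(sig) <- labels
  list(signals = sig, fs_hz = spr[1] / record_s, record_s = record_s,
       labels = labels, units = units)
}
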