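# Fixed-width ASCII field helpers for the EDF header
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write / read a recording as EDF plus a JSON event sidecar
#'
#' `write_recording()` stores the signal as a standard EDF file
#' (16-bit samples, physical units uV, 1 s data records, per-channel
#' symmetric physical range) and everything EDF cannot carry — the
#' stimulus event table, channel roles and positions, the reference
#' state and the exact sample count — in a JSON sidecar at
#' `<path>.events.json`. `read_recording()` reverses this losslessly up
#' to the 16-bit amplitude quantisation (at most half a quantisation
#' step per sample); the event table round-trips exactly.
#'
#' @param recording an [new_recording()] object.
#' @param path EDF file path.
#' @return `write_recording` returns `path` invisibly;
#'   `read_recording` returns the reconstructed recording.
#' @export
write_recording <- function(recording, path) {
  data <- recording$data
  nch <- nrow(data)
  srate <- recording$srate
  if (srate != round(srate)) stop("EDF writer requires integer Hz")
  n <- ncol(data)
  n_rec <- ceiling(n / srate)
  pad <- n_rec * srate - n
  if (pad > 0) data <- cbind(data, matrix(0, nch, pad))

  phys_max <- pmax(apply(abs(data), 1, max), 1)
  phys_max <- ceiling(phys_max * 100) / 100
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("simulated participant", 80),
    edf_field("p300aptitude synthetic recording", 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + nch), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(nch, 4))
  sig <- paste0(
    paste(vapply(recording$montage$label, edf_field, "", width = 16),
          collapse = ""),
    paste(rep(edf_field("simulated", 80), nch), collapse = ""),
    paste(rep(edf_field("uV", 8), nch), collapse = ""),
    paste(vapply(-phys_max, edf_field, "", width = 8), collapse = ""),
    paste(vapply(phys_max, edf_field, "", width = 8), collapse = ""),
    paste(rep(edf_field(dig_min, 8), nch), collapse = ""),
    paste(rep(edf_field(dig_max, 8), nch), collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field(srate, 8), nch), collapse = ""),
    paste(rep(edf_field("", 32), nch), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  scale <- (dig_max - dig_min) / (2 * phys_max)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * srate + 1L):(r * srate)
    block <- round((data[, cols, drop = FALSE] + phys_max) * scale) + dig_min
    block <- pmin(pmax(block, dig_min), dig_max)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }

  sidecar <- list(
    srate = srate, n_samples = n, reference = recording$reference,
    montage = recording$montage, events = recording$events,
    events_classes = as.list(vapply(recording$events, function(col)
      class(col)[1], character(1))))
  jsonlite::write_json(sidecar, paste0(path, ".events.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".events.json")
  if (!file.exists(sidecar_path))
    stop("missing event sidecar: ", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)

  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readChar(con, 256, useBytes = TRUE)
  if (nchar(head_raw, type = "bytes") < 256 ||
      trimws(substr(head_raw, 1, 8)) != "0")
    stop("corrupt EDF header in ", path)
  n_rec <- as.integer(trimws(substr(head_raw, 237, 244)))
  nch <- as.integer(trimws(substr(head_raw, 253, 256)))
  if (is.na(n_rec) || is.na(nch) || nch < 1L)
    stop("corrupt EDF header in ", path)
  sig_raw <- readChar(con, 256 * nch, useBytes = TRUE)
  field <- function(start, width) {
    vapply(seq_len(nch), function(i)
      trimws(substr(sig_raw, start + (i - 1) * width + 1,
                    start + i * width)), "")
  }
  labels <- field(0, 16)
  phys_min <- as.numeric(field(16 * nch + 80 * nch + 8 * nch, 8))
  phys_max <- as.numeric(field(16 * nch + 80 * nch + 8 * nch + 8 * nch, 8))
  dig_min <- as.numeric(field(16 * nch + 80 * nch + 8 * nch * 3, 8))
  dig_max <- as.numeric(field(16 * nch + 80 * nch + 8 * nch * 4, 8))
  spr <- as.integer(field(16 * nch + 80 * nch * 2 + 8 * nch * 5, 8))

  if (!identical(labels, as.character(side$montage$label)))
    stop("channel labels in EDF and sidecar disagree")
  samples <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = nch * spr[1], size = 2L,
                     endian = "little")
    if (length(block) < nch * spr[1]) stop("truncated EDF data in ", path)
    samples[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
      matrix(block, nrow = nch, byrow = TRUE)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- (samples - dig_min) * gain + phys_min
  data <- data[, seq_len(side$n_samples), drop = FALSE]

  events <- as.data.frame(side$events)
  # JSON drops column types (all-NA columns come back logical); the
  # sidecar records each column's class for a lossless round-trip
  if (!is.null(side$events_classes)) {
    for (nm in names(side$events_classes)) {
      cast <- switch(side$events_classes[[nm]],
                     integer = as.integer, numeric = as.numeric,
                     character = as.character, logical = as.logical,
                     identity)
      events[[nm]] <- cast(events[[nm]])
    }
  }
  new_recording(data, side$srate, as.data.frame(side$montage), events,
                side$reference)
}
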