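#' Quantize a voltage trace to a fixed ADC resolution
#'
#' Uniform mid-tread quantizer scaled so the trace's full range maps onto the
#' signed integer range of the given bit depth (mimicking the 8-bit clinical
#' acquisition chain). The maximum absolute error is half a quantization step.
#'
#' @param samples Numeric trace.
#' @param bits ADC resolution in bits (e.g. 8 or 16).
#' @param full_scale Amplitude mapped to the largest code; defaults to
#'   `max(abs(samples))`.
#' @return List with `samples` (quantized trace), `codes` (integer codes),
#'   `step` (quantization step) and `full_scale`.
#' @export
quantize_trace <- function(samples, bits = 8, full_scale = NULL) {
  if (is.null(full_scale)) full_scale <- max(abs(samples))
  if (full_scale == 0) full_scale <- 1
  levels <- 2^(bits - 1) - 1
  codes <- as.integer(round(samples / full_scale * levels))
  codes <- pmin(pmax(codes, -levels), levels)
  list(
    samples = codes / levels * full_scale,
    codes = codes,
    step = full_scale / levels,
    full_scale = full_scale
  )
}

# Minimal mono PCM WAV writer/reader (8-bit unsigned / 16-bit signed LE).
# No WAV codec ships with the package's dependency set, and the format's
# canonical PCM layout is a 44-byte header plus raw little-endian samples.
write_wav <- function(codes, fs, path, bits = 16) {
  stopifnot(bits %in% c(8L, 16L))
  n <- length(codes)
  bytes_per_sample <- bits / 8
  data_size <- n * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per_sample), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 8L) {
    writeBin(as.raw(codes + 128L), con)
  } else {
    writeBin(as.integer(codes), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_wav <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size <= 44) abort(paste0("empty or truncated WAV file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") abort(paste0("not a RIFF/WAVE file: ", path))
  fs <- NULL; bits <- NULL; codes <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      if (bits == 8L) {
        codes <- as.integer(readBin(con, "raw", size)) - 128L
      } else {
        codes <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                         endian = "little")
      }
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(codes) || length(codes) == 0) abort(paste0("no PCM data in ", path))
  list(codes = codes, fs = fs, bits = bits)
}

#' Save epochs to disk as per-epoch signal files plus a JSON sidecar
#'
#' Writes one signal file per epoch (WAV PCM by default, or headerless
#' single-column CSV) and a `sidecar.json` carrying the metadata WAV cannot
#' hold: depth, label, sampling rate, trajectory id, amplitude scale and any
#' ground-truth borders. [read_trajectory()] inverts the operation.
#'
#' @param epochs An epoch tibble (one or more trajectories).
#' @param out_dir Output directory (created if needed).
#' @param format `"wav"` or `"csv"`.
#' @param bits WAV bit depth, 16 (default) or 8 to mimic the clinical ADC.
#' @return Paths of the written signal files, invisibly; the sidecar is
#'   written alongside them.
#' @export
save_trajectory <- function(epochs, out_dir, format = c("wav", "csv"),
                            bits = 16) {
  format <- match.arg(format)
  if (nrow(epochs) == 0) abort("no epochs to save.")
  validate_epochs(epochs, bandpass_high_hz = NULL)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  epochs <- arrange_epochs(epochs)
  files <- character(nrow(epochs))
  scales <- rep(NA_real_, nrow(epochs))
  for (i in seq_len(nrow(epochs))) {
    base <- sprintf("%s_epoch%03d.%s", epochs$trajectory_id[i], i, format)
    path <- file.path(out_dir, base)
    x <- epochs$samples[[i]]
    if (format == "wav") {
      q <- quantize_trace(x, bits = bits)
      write_wav(q$codes, epochs$fs[i], path, bits = bits)
      scales[i] <- q$full_scale
    } else {
      readr::write_csv(data.frame(x = x), path, col_names = FALSE)
    }
    files[i] <- base
  }
  sidecar <- data.frame(
    file = files,
    trajectory_id = epochs$trajectory_id,
    depth_mm = epochs$depth_mm,
    label = epochs$label,
    fs = epochs$fs,
    duration_s = epochs$duration_s,
    true_dorsal_mm = epochs$true_dorsal_mm,
    true_ventral_mm = epochs$true_ventral_mm,
    format = format,
    bits = if (format == "wav") bits else NA_integer_,
    scale = scales
  )
  jsonlite::write_json(sidecar, file.path(out_dir, "sidecar.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(file.path(out_dir, files))
}

#' Load epochs from signal files and a JSON sidecar
#'
#' @param metadata_file Path to the `sidecar.json` written by
#'   [save_trajectory()] (or hand-authored to the same schema).
#' @param signal_files Optional explicit list of signal files; every one must
#'   have a sidecar entry, otherwise the offending file is named in the error.
#' @return A depth-ordered epoch tibble.
#' @export
read_trajectory <- function(metadata_file, signal_files = NULL) {
  if (!file.exists(metadata_file)) {
    abort(paste0("metadata file not found: ", metadata_file))
  }
  side <- jsonlite::fromJSON(metadata_file)
  dir <- dirname(metadata_file)
  if (!is.null(signal_files)) {
    missing <- setdiff(basename(signal_files), side$file)
    if (length(missing) > 0) {
      abort(paste0("no sidecar metadata for file(s): ",
                   paste(missing, collapse = ", ")))
    }
    side <- side[side$file %in% basename(signal_files), , drop = FALSE]
  }
  if (is.null(side$depth_mm) || any(is.na(side$depth_mm))) {
    bad <- side$file[is.na(side$depth_mm)]
    abort(paste0("sidecar lacks depth_mm for file(s): ",
                 paste(bad, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(side)), function(i) {
    path <- file.path(dir, side$file[i])
    if (!file.exists(path)) abort(paste0("signal file not found: ", path))
    if (identical(side$format[i], "csv") || grepl("\\.csv$", side$file[i])) {
      x <- readr::read_csv(path, col_names = "x", col_types = "d",
                           progress = FALSE)$x
      if (length(x) == 0) abort(paste0("empty signal file: ", path))
    } else {
      w <- read_wav(path)
      levels <- 2^(w$bits - 1) - 1
      scale <- side$scale[i]
      if (is.null(scale) || is.na(scale)) scale <- 1
      x <- w$codes / levels * scale
    }
    lab <- side$label[i]
    mer_epoch(
      x, fs = side$fs[i], depth_mm = side$depth_mm[i],
      trajectory_id = side$trajectory_id[i],
      label = if (is.null(lab) || is.na(lab)) NA_integer_ else as.integer(lab),
      duration_s = if (!is.null(side$duration_s)) side$duration_s[i] else length(x) / side$fs[i],
      true_dorsal_mm = if (!is.null(side$true_dorsal_mm)) side$true_dorsal_mm[i] else NA_real_,
      true_ventral_mm = if (!is.null(side$true_ventral_mm)) side$true_ventral_mm[i] else NA_real_
    )
  })
  out <- arrange_epochs(dplyr::bind_rows(rows))
  validate_epochs(out, bandpass_high_hz = NULL)
  out
}
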