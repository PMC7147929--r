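#' Conventional feature vector of one epoch
#'
#' The ten spike-train and signal statistics used by the classical
#' (post-operative) MER feature space, in fixed order: spike count, ISI SD,
#' pause index, pause ratio, RMS amplitude, spiking rate, Teager energy,
#' zero crossings, curve length, and the detection threshold itself.
#'
#' @param samples Numeric trace.
#' @param fs Sampling rate, Hz.
#' @param duration_s Epoch duration, seconds.
#' @param refractory_ms Spike-detector refractory period.
#' @param pause_cut_ms Pause cut for the ISI statistics.
#' @return Named numeric vector of length 10.
#' @export
conventional_features <- function(samples, fs, duration_s = length(samples) / fs,
                                  refractory_ms = 2, pause_cut_ms = 50) {
  gamma <- threshold_gamma(samples)
  spikes <- detect_spikes(samples, fs, gamma, refractory_ms = refractory_ms)
  isi <- isi_features(spikes$time_s, duration_s, pause_cut_ms = pause_cut_ms)
  c(
    n_spikes = as.numeric(isi$n_spikes),
    isi_sd = isi$isi_sd,
    pause_index = isi$pause_index,
    pause_ratio = isi$pause_ratio,
    rms = rms_amplitude(samples),
    spiking_rate = isi$spiking_rate,
    teager_energy = teager_energy(samples),
    zero_crossings = as.numeric(zero_crossings(samples)),
    curve_length = curve_length(samples),
    threshold_gamma = gamma
  )
}

#' Extract a feature table from an epoch table
#'
#' Maps one of the three feature spaces over every epoch and returns a wide
#' tibble: the epoch metadata columns followed by one numeric column per
#' feature. For the FFT family two spectral summaries, `power_mua_hz`
#' (500--1000 Hz) and `power_sua_hz` (1000--3000 Hz), are appended for
#' plotting; they are not part of the feature vector used by classifiers
#' (see [feature_matrix()]).
#'
#' Feature extraction is per-epoch: with normalization off, an epoch's
#' feature vector depends only on that epoch's trace, which is what makes
#' the FFT and wavelet spaces usable intraoperatively.
#'
#' @param epochs An epoch tibble.
#' @param family `"conventional"`, `"fft"` or `"wavelet"`.
#' @param n_bins FFT bin count (FFT family).
#' @param band FFT frequency band; default 0--Nyquist.
#' @param levels,selection Wavelet decomposition depth and coefficient
#'   selection (wavelet family).
#' @param refractory_ms,pause_cut_ms Conventional-family spike parameters.
#' @return An `stn_features` tibble; attributes `family`, `normalized` and
#'   `feature_names` describe the feature block.
#' @export
extract_features <- function(epochs,
                             family = c("conventional", "fft", "wavelet"),
                             n_bins = 10000, band = NULL,
                             levels = 4, selection = "d1_only",
                             refractory_ms = 2, pause_cut_ms = 50) {
  family <- match.arg(family)
  meta <- epochs[intersect(.meta_cols, names(epochs))]
  meta$samples <- NULL
  rows <- switch(family,
    conventional = lapply(seq_len(nrow(epochs)), function(i) {
      conventional_features(epochs$samples[[i]], epochs$fs[i],
                            epochs$duration_s[i],
                            refractory_ms = refractory_ms,
                            pause_cut_ms = pause_cut_ms)
    }),
    fft = lapply(seq_len(nrow(epochs)), function(i) {
      b <- if (is.null(band)) c(0, epochs$fs[i] / 2) else band
      fft_features(epochs$samples[[i]], epochs$fs[i], n_bins = n_bins, band = b)
    }),
    wavelet = lapply(seq_len(nrow(epochs)), function(i) {
      wavelet_features(epochs$samples[[i]], levels = levels,
                       selection = selection)
    })
  )
  mat <- do.call(rbind, rows)
  out <- dplyr::bind_cols(meta, as_tibble(mat))
  if (family == "fft") {
    out$power_mua_hz <- vapply(rows, function(r) attr(r, "power_mua"), 0)
    out$power_sua_hz <- vapply(rows, function(r) attr(r, "power_sua"), 0)
  }
  new_stn_features(out, family = family, normalized = FALSE,
                   feature_names = colnames(mat))
}

new_stn_features <- function(x, family, normalized, feature_names) {
  attr(x, "family") <- family
  attr(x, "normalized") <- normalized
  attr(x, "feature_names") <- feature_names
  class(x) <- unique(c("stn_features", class(x)))
  x
}

#' Feature block of a feature table as a numeric matrix
#'
#' @param features An `stn_features` tibble (or any tibble whose feature
#'   columns are recorded in its `feature_names` attribute; otherwise every
#'   non-metadata, non-summary numeric column is taken).
#' @return Numeric matrix, one row per epoch.
#' @export
feature_matrix <- function(features) {
  nms <- attr(features, "feature_names")
  if (is.null(nms)) {
    nms <- setdiff(names(features),
                   c(.meta_cols, "power_mua_hz", "power_sua_hz"))
  }
  as.matrix(features[nms])
}

#' Z-score features within each trajectory
#'
#' The conventional feature space is unstable across tracks, so each feature
#' is centred and scaled within its own trajectory (a post-operative step:
#' it needs the whole track). Constant features within a trajectory map to
#' zeros.
#'
#' @param features An `stn_features` tibble.
#' @return The table with the feature block replaced by per-trajectory
#'   z-scores and `normalized = TRUE`.
#' @export
normalize_by_trajectory <- function(features) {
  nms <- attr(features, "feature_names")
  if (is.null(nms)) abort("not a feature table: missing feature_names attribute.")
  mat <- as.matrix(features[nms])
  groups <- split(seq_len(nrow(mat)), features$trajectory_id)
  if (any(lengths(groups) < 2)) {
    abort("per-trajectory normalization is undefined for single-epoch trajectories.")
  }
  for (idx in groups) {
    m <- colMeans(mat[idx, , drop = FALSE])
    s <- apply(mat[idx, , drop = FALSE], 2, sd)
    z <- sweep(mat[idx, , drop = FALSE], 2, m, "-")
    z <- sweep(z, 2, ifelse(s > 0, s, 1), "/")
    z[, s == 0] <- 0
    mat[idx, ] <- z
  }
  features[nms] <- as_tibble(mat)
  new_stn_features(features, family = attr(features, "family"),
                   normalized = TRUE, feature_names = nms)
}

#' Write / read a feature table as TSV plus JSON metadata
#'
#' The TSV holds one row per epoch (metadata columns first, then features);
#' the JSON sidecar records the family, normalization state and feature
#' names so the table round-trips.
#'
#' @param features An `stn_features` tibble.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(as_tibble(as.data.frame(features)), path, progress = FALSE)
  jsonlite::write_json(
    list(family = attr(features, "family"),
         normalized = attr(features, "normalized"),
         feature_names = attr(features, "feature_names")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  new_stn_features(tab, family = meta$family, normalized = meta$normalized,
                   feature_names = meta$feature_names)
}
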