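#' Orthonormal Haar discrete wavelet transform
#'
#' Pyramid DWT with the Haar mother wavelet. At each level the signal is
#' split into pairwise sums and differences scaled by `1/sqrt(2)`, so the
#' transform is orthonormal: total coefficient energy equals signal energy
#' and the inverse transform reconstructs the input exactly. Odd-length
#' inputs at any level are padded by repeating the final sample; the pad
#' positions are recorded so [haar_idwt()] can undo them.
#'
#' Haar suits traces dominated by sudden transitions — extracellular spikes —
#' because its square-shaped basis concentrates a transient's energy into few
#' coefficients.
#'
#' @param samples Numeric vector with `length(samples) >= 2^levels`.
#' @param levels Decomposition depth (default 4).
#' @return A `haar_dwt` list: `details` (list `d1` ... `dL`, finest first),
#'   `approx` (level-L approximation), `levels`, `n` (original length) and
#'   `padded` (per-level logical).
#' @export
#' @examples
#' w <- haar_dwt(c(1, 1, 2, 2), levels = 1)
#' w$approx   # sqrt(2), 2*sqrt(2)
#' w$details$d1 # 0, 0
haar_dwt <- function(samples, levels = 4) {
  x <- as.numeric(samples)
  if (levels < 1) abort("levels must be >= 1.")
  if (length(x) < 2^levels) {
    abort("need length(samples) >= 2^levels for the requested decomposition.")
  }
  details <- vector("list", levels)
  padded <- logical(levels)
  a <- x
  for (j in seq_len(levels)) {
    if (length(a) %% 2 == 1) {
      a <- c(a, a[length(a)])
      padded[j] <- TRUE
    }
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  names(details) <- paste0("d", seq_len(levels))
  structure(
    list(details = details, approx = a, levels = levels,
         n = length(x), padded = padded),
    class = "haar_dwt"
  )
}

#' Inverse orthonormal Haar transform
#'
#' @param w A `haar_dwt` object.
#' @return The reconstructed signal, trimmed back to the original length.
#' @export
haar_idwt <- function(w) {
  a <- w$approx
  for (j in rev(seq_len(w$levels))) {
    d <- w$details[[j]]
    odd <- (a + d) / sqrt(2)
    even <- (a - d) / sqrt(2)
    a <- as.vector(rbind(odd, even))
    if (w$padded[j]) a <- a[-length(a)]
  }
  a[seq_len(w$n)]
}

#' Haar wavelet feature vector of a trace
#'
#' Runs a `levels`-deep Haar decomposition and returns the selected
#' coefficients as a named vector. The default `"d1_only"` keeps the finest
#' detail band — half the sample count, i.e. 120,000 features for a 10-s
#' epoch at 24 kHz — which carries the sharp-transient (spike) energy;
#' `"all_details"` and `"all"` append the coarser bands (and approximation).
#'
#' @param samples Numeric trace.
#' @param levels Decomposition depth (default 4).
#' @param selection `"d1_only"`, `"all_details"` or `"all"`.
#' @return Named numeric vector of wavelet coefficients.
#' @export
wavelet_features <- function(samples, levels = 4,
                             selection = c("d1_only", "all_details", "all")) {
  selection <- match.arg(selection)
  w <- haar_dwt(samples, levels = levels)
  keep <- switch(selection,
    d1_only = w$details["d1"],
    all_details = w$details,
    all = c(w$details, list(a = w$approx))
  )
  out <- unlist(keep, use.names = FALSE)
  names(out) <- unlist(lapply(names(keep), function(nm) {
    sprintf("%s_%06d", nm, seq_along(keep[[nm]]))
  }))
  out
}

#' Binned FFT power-spectrum features of a trace
#'
#' One-sided power spectrum (scaled so the summed bin powers equal the
#' signal's summed squares, i.e. Parseval holds) aggregated into `n_bins`
#' uniform frequency bins over `band`. The default 10,000 bins over
#' 0--Nyquist reproduce the dimensionality of the clinical feature space.
#' Two summary band powers — 500--1000 Hz (multi-unit activity) and
#' 1000--3000 Hz (single-unit activity) — are attached as attributes.
#'
#' @param samples Numeric trace.
#' @param fs Sampling rate, Hz.
#' @param n_bins Number of uniform frequency bins.
#' @param band Two-element frequency range, Hz; must stay within Nyquist.
#' @return Named numeric vector `fft_000001 ...` of bin powers with
#'   attributes `power_mua` (500--1000 Hz) and `power_sua` (1000--3000 Hz).
#' @export
fft_features <- function(samples, fs, n_bins = 10000, band = c(0, fs / 2)) {
  if (band[1] < 0 || band[2] > fs / 2 || band[1] >= band[2]) {
    abort("band must lie within [0, fs/2].")
  }
  x <- as.numeric(samples)
  n <- length(x)
  sp <- fft(x)
  half <- floor(n / 2)
  k <- 0:half
  freqs <- k * fs / n
  pow <- Mod(sp[k + 1])^2 / n
  # fold the negative frequencies onto the positive axis
  dbl <- rep(2, length(k))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(k)] <- 1
  pow <- pow * dbl
  in_band <- freqs >= band[1] & freqs <= band[2]
  width <- (band[2] - band[1]) / n_bins
  idx <- pmin(floor((freqs[in_band] - band[1]) / width), n_bins - 1) + 1
  bins <- numeric(n_bins)
  agg <- tapply(pow[in_band], idx, sum)
  bins[as.integer(names(agg))] <- agg
  names(bins) <- sprintf("fft_%06d", seq_len(n_bins))
  attr(bins, "power_mua") <- sum(pow[freqs >= 500 & freqs <= 1000])
  attr(bins, "power_sua") <- sum(pow[freqs >= 1000 & freqs <= 3000])
  bins
}
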