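#' Acquisition-chain filter specification
#'
#' The clinical recording chain band-passes the microelectrode signal at
#' 500--5000 Hz and notches mains interference at 60 Hz. The same chain is
#' applied to simulated epochs so that synthetic and recorded traces share a
#' spectral envelope.
#'
#' @param band_low_hz,band_high_hz Bandpass corner frequencies in Hz.
#' @param notch_hz Mains notch centre frequency in Hz (`NULL` disables).
#' @param notch_q Notch quality factor; the stop band is
#'   `notch_hz / notch_q` wide.
#' @param filter_order Butterworth order of the bandpass.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(band_low_hz = 500, band_high_hz = 5000,
                        notch_hz = 60, notch_q = 30, filter_order = 4) {
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz)) {
    abort("need 0 < band_low_hz < band_high_hz.")
  }
  structure(
    list(
      band_low_hz = band_low_hz, band_high_hz = band_high_hz,
      notch_hz = notch_hz, notch_q = notch_q, filter_order = filter_order
    ),
    class = "filter_spec"
  )
}

#' Apply the acquisition filter to a voltage trace
#'
#' Zero-phase (forward-backward) Butterworth bandpass followed by a
#' zero-phase band-stop notch. Zero-phase filtering preserves spike timing
#' and waveform symmetry, which matter for threshold-based spike detection.
#'
#' @param samples Numeric voltage trace.
#' @param fs Sampling rate in Hz; must exceed `2 * band_high_hz`.
#' @param spec A [filter_spec()].
#' @return Filtered trace of the same length.
#' @export
apply_acquisition_filter <- function(samples, fs, spec = filter_spec()) {
  if (fs <= 2 * spec$band_high_hz) {
    abort("band edges violate Nyquist: need fs > 2 * band_high_hz.")
  }
  bp <- signal::butter(spec$filter_order,
                       c(spec$band_low_hz, spec$band_high_hz) / (fs / 2),
                       type = "pass")
  y <- signal::filtfilt(bp, samples)
  if (!is.null(spec$notch_hz) && spec$notch_hz > 0) {
    half_bw <- spec$notch_hz / spec$notch_q / 2
    ns <- signal::butter(2,
                         c(spec$notch_hz - half_bw, spec$notch_hz + half_bw) / (fs / 2),
                         type = "stop")
    y <- signal::filtfilt(ns, y)
  }
  as.numeric(y)
}

#' Filter every epoch of a table
#'
#' @param epochs An epoch tibble.
#' @param spec A [filter_spec()].
#' @return The tibble with each `samples` trace filtered in place.
#' @export
filter_epochs <- function(epochs, spec = filter_spec()) {
  epochs$samples <- purrr::map2(
    epochs$samples, epochs$fs,
    function(x, fs) apply_acquisition_filter(x, fs, spec)
  )
  epochs
}

# Squared magnitude response of the full zero-phase chain on a frequency
# grid (Hz). Forward-backward filtering squares each single-pass magnitude,
# so the amplitude response is |H_bp|^2 * |H_notch|^2. Used as an
# independent oracle for noise-power calculations.
filter_power_response <- function(fs, spec = filter_spec(), n = 4096) {
  f <- seq(0, fs / 2, length.out = n)
  w <- 2 * pi * f / fs
  bp <- signal::butter(spec$filter_order,
                       c(spec$band_low_hz, spec$band_high_hz) / (fs / 2),
                       type = "pass")
  h <- abs(signal::freqz(bp$b, bp$a, w)$h)^2
  if (!is.null(spec$notch_hz) && spec$notch_hz > 0) {
    half_bw <- spec$notch_hz / spec$notch_q / 2
    ns <- signal::butter(2,
                         c(spec$notch_hz - half_bw, spec$notch_hz + half_bw) / (fs / 2),
                         type = "stop")
    h <- h * abs(signal::freqz(ns$b, ns$a, w)$h)^2
  }
  list(freq_hz = f, amplitude = h, power = h^2)
}
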