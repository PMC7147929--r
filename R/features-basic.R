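#' Teager energy of a trace
#'
#' Nonlinear energy operator summed over the interior samples,
#' `sum(x_i^2 - x_{i-1} x_{i+1})`, sensitive to both amplitude and frequency
#' content and hence to spiking activity.
#'
#' @param samples Numeric vector, length >= 3.
#' @return Scalar energy.
#' @export
#' @examples
#' teager_energy(c(1, 2, 3)) # 2^2 - 1*3 = 1
teager_energy <- function(samples) {
  n <- length(samples)
  if (n < 3) abort("teager_energy needs at least 3 samples.")
  x <- as.numeric(samples)
  i <- 2:(n - 1)
  sum(x[i]^2 - x[i - 1] * x[i + 1])
}

#' Curve length of a trace
#'
#' Sum of absolute consecutive differences, `sum(|x_{i+1} - x_i|)` — a cheap
#' proxy for waveform complexity.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Scalar length.
#' @export
#' @examples
#' curve_length(c(1, 3, 2)) # 2 + 1 = 3
curve_length <- function(samples) {
  if (length(samples) < 2) abort("curve_length needs at least 2 samples.")
  sum(abs(diff(as.numeric(samples))))
}

#' Zero-crossing count
#'
#' Number of consecutive sample pairs with strictly negative product; exact
#' zeros do not count as crossings.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Integer count.
#' @export
zero_crossings <- function(samples) {
  if (length(samples) < 2) abort("zero_crossings needs at least 2 samples.")
  x <- as.numeric(samples)
  sum(x[-length(x)] * x[-1] < 0)
}

#' Root-mean-square amplitude
#'
#' @param samples Non-empty numeric vector.
#' @return `sqrt(mean(samples^2))`.
#' @export
rms_amplitude <- function(samples) {
  if (length(samples) < 1) abort("rms_amplitude needs at least 1 sample.")
  sqrt(mean(as.numeric(samples)^2))
}

#' Inter-spike-interval statistics of a spike train
#'
#' Computes the five spike-train members of the conventional feature set:
#' spike count, ISI standard deviation, pause index, pause ratio and spiking
#' rate. A "pause" is an inter-spike interval longer than `pause_cut_ms`
#' (50 ms by default); the pause index is the count ratio of long to short
#' ISIs and the pause ratio the summed-duration ratio.
#'
#' Degenerate-input policy (the ratios are otherwise undefined): with 0 or 1
#' spikes all five features are 0 (a single threshold crossing carries no
#' interval information, so the whole block is zeroed rather than mixing real
#' and placeholder values); with no short ISI the pause index falls back to
#' the long-ISI count and the pause ratio to long-ISI time divided by the
#' epoch duration.
#'
#' @param spike_times_s Increasing spike times, seconds.
#' @param duration_s Epoch duration, seconds.
#' @param pause_cut_ms ISI cut separating pauses from ordinary intervals.
#' @return Named list: `n_spikes`, `isi_sd`, `pause_index`, `pause_ratio`,
#'   `spiking_rate`.
#' @export
#' @examples
#' isi_features(cumsum(c(0.01, 0.03, 0.06, 0.07)), duration_s = 1)
isi_features <- function(spike_times_s, duration_s, pause_cut_ms = 50) {
  n <- length(spike_times_s)
  if (n <= 1) {
    return(list(n_spikes = 0, isi_sd = 0, pause_index = 0,
                pause_ratio = 0, spiking_rate = 0))
  }
  isi <- diff(spike_times_s)
  cut <- pause_cut_ms / 1000
  long <- isi > cut
  short <- isi < cut
  pause_index <- if (sum(short) > 0) sum(long) / sum(short) else sum(long)
  pause_ratio <- if (sum(short) > 0 && sum(isi[short]) > 0) {
    sum(isi[long]) / sum(isi[short])
  } else {
    sum(isi[long]) / duration_s
  }
  list(
    n_spikes = n,
    isi_sd = if (length(isi) > 1) sd(isi) else 0,
    pause_index = pause_index,
    pause_ratio = pause_ratio,
    spiking_rate = n / duration_s
  )
}
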