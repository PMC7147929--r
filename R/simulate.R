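#' Synthetic-MER simulator configuration
#'
#' Defines the study conditions for simulated microelectrode trajectories.
#' The electrode descends from 10 mm above the planned target in 1 mm steps,
#' switching to 0.5 mm steps from 5 mm above the target onward, and records
#' one epoch per depth. Inside the STN the simulator raises both the
#' multi-unit firing rate and the background noise amplitude, the two
#' electrophysiological signatures the classifiers rely on.
#'
#' Defaults: a 60 Hz pooled multi-unit rate inside versus 15 Hz outside, and
#' background noise SD 2.5 inside versus 1.0 outside, give class separation
#' that is clear but not degenerate at 1--10 s epochs; the true dorsal border
#' is drawn uniformly in \[-2, 0\] mm and the ventral border in \[+2, +4\] mm,
#' yielding a 2--6 mm nucleus span consistent with STN anatomy.
#'
#' @param fs Sampling rate, Hz.
#' @param epoch_s Epoch duration, seconds.
#' @param depth_start_mm,depth_switch_mm,depth_end_mm Depth schedule limits in
#'   signed mm relative to target (negative above).
#' @param coarse_step_mm,fine_step_mm Step sizes before/after the switch depth.
#' @param rate_outside_hz,rate_inside_hz Pooled Poisson firing rates.
#' @param bg_sigma_outside,bg_sigma_inside Background (pre-filter) noise SD.
#' @param spike_amplitude_mean Mean spike peak amplitude (same units as noise).
#' @param spike_amplitude_cv Coefficient of variation of lognormal spike
#'   amplitudes.
#' @param spike_width_ms Approximate biphasic spike width.
#' @param refractory_ms Absolute refractory period per unit.
#' @param dorsal_mm_range,ventral_mm_range Uniform sampling ranges for the
#'   true borders.
#' @param n_units_inside Number of independent units pooled inside the STN.
#' @param quantize_bits Optional ADC resolution (e.g. 8); `NULL` keeps traces
#'   unquantized.
#' @param filter A [filter_spec()] applied to every rendered epoch.
#' @param seed Integer seed driving all simulator randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 24000, epoch_s = 10,
                       depth_start_mm = -10, depth_switch_mm = -5,
                       depth_end_mm = 5,
                       coarse_step_mm = 1, fine_step_mm = 0.5,
                       rate_outside_hz = 15, rate_inside_hz = 60,
                       bg_sigma_outside = 1.0, bg_sigma_inside = 2.5,
                       spike_amplitude_mean = 6, spike_amplitude_cv = 0.25,
                       spike_width_ms = 1, refractory_ms = 2,
                       dorsal_mm_range = c(-2, 0),
                       ventral_mm_range = c(2, 4),
                       n_units_inside = 3,
                       quantize_bits = NULL,
                       filter = filter_spec(),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$rate_inside_hz <= cfg$rate_outside_hz) {
    abort("rate_inside_hz must exceed rate_outside_hz.")
  }
  if (cfg$bg_sigma_inside <= cfg$bg_sigma_outside) {
    abort("bg_sigma_inside must exceed bg_sigma_outside.")
  }
  if (cfg$refractory_ms <= 0) abort("refractory_ms must be positive.")
  if (max(cfg$dorsal_mm_range) >= min(cfg$ventral_mm_range)) {
    abort("border sampling ranges must be disjoint and ordered.")
  }
  structure(cfg, class = "sim_config")
}

#' Depth schedule of a simulated trajectory
#'
#' @param config A [sim_config()].
#' @return Numeric vector of recording depths (mm), strictly increasing.
#' @export
depth_schedule <- function(config = sim_config()) {
  coarse <- seq(config$depth_start_mm, config$depth_switch_mm,
                by = config$coarse_step_mm)
  fine <- seq(config$depth_switch_mm + config$fine_step_mm,
              config$depth_end_mm, by = config$fine_step_mm)
  c(coarse, fine)
}

#' Simulate a refractory-thinned Poisson spike train
#'
#' Homogeneous Poisson arrivals thinned by an absolute refractory period:
#' an arrival closer than `refractory_ms` to the last retained spike is
#' discarded. The retained rate is `1 / (1/rate_hz + refractory)`.
#'
#' @param rate_hz Mean arrival rate before thinning (>= 0).
#' @param duration_s Train duration, seconds.
#' @param refractory_ms Absolute refractory period, ms.
#' @return Strictly increasing spike times in `[0, duration_s)`, seconds.
#' @export
simulate_spike_train <- function(rate_hz, duration_s, refractory_ms = 2) {
  if (rate_hz < 0) abort("rate_hz must be non-negative.")
  if (rate_hz == 0) return(numeric(0))
  # draw exponential gaps in blocks until the epoch is covered
  t <- numeric(0)
  now <- 0
  repeat {
    gaps <- rexp(max(16, ceiling(rate_hz * (duration_s - now) * 1.5)),
                 rate = rate_hz)
    t <- c(t, now + cumsum(gaps))
    now <- t[length(t)]
    if (now >= duration_s) break
  }
  t <- t[t < duration_s]
  if (length(t) == 0) return(numeric(0))
  tau <- refractory_ms / 1000
  keep <- logical(length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (t[i] - last >= tau) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  t[keep]
}

# Biphasic spike template: difference of two offset Gaussians, peak-normalized
# to +1. width_ms sets the overall positive-negative excursion span.
spike_template <- function(fs, width_ms = 1) {
  w <- width_ms / 1000
  t <- seq(-1.5 * w, 1.5 * w, by = 1 / fs)
  s1 <- 0.18 * w
  s2 <- 0.28 * w
  # equal lobe areas make the template zero-mean (AC-coupled recording),
  # which keeps bandpass ringing small
  shape <- exp(-0.5 * ((t + 0.2 * w) / s1)^2) -
    (s1 / s2) * exp(-0.5 * ((t - 0.25 * w) / s2)^2)
  shape <- shape - mean(shape)
  shape / max(abs(shape))
}

#' Render one synthetic epoch from spike times
#'
#' Places lognormal-amplitude biphasic waveforms at the given spike times on
#' Gaussian background noise (SD chosen by inside/outside status), then
#' applies the acquisition filter and, if configured, ADC quantization.
#'
#' @param spike_times Spike times in seconds, all within `[0, epoch_s)`.
#' @param config A [sim_config()].
#' @param inside Logical: is this epoch inside the STN?
#' @param depth_mm,trajectory_id Epoch metadata.
#' @param true_dorsal_mm,true_ventral_mm Optional ground-truth borders.
#' @return A one-row epoch tibble (see [mer_epoch()]), labelled
#'   `as.integer(inside)`.
#' @export
render_epoch <- function(spike_times, config, inside,
                         depth_mm = NA_real_, trajectory_id = "T001",
                         true_dorsal_mm = NA_real_, true_ventral_mm = NA_real_) {
  n <- round(config$fs * config$epoch_s)
  if (length(spike_times) && (min(spike_times) < 0 ||
                              max(spike_times) >= config$epoch_s)) {
    abort("spike times must lie within [0, epoch_s).")
  }
  sigma <- if (inside) config$bg_sigma_inside else config$bg_sigma_outside
  x <- rnorm(n, 0, sigma)
  if (length(spike_times)) {
    tmpl <- spike_template(config$fs, config$spike_width_ms)
    half <- (length(tmpl) - 1) %/% 2
    cv <- config$spike_amplitude_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(config$spike_amplitude_mean) - sdlog^2 / 2
    amps <- rlnorm(length(spike_times), meanlog, sdlog)
    centers <- round(spike_times * config$fs) + 1L
    for (k in seq_along(centers)) {
      lo <- centers[k] - half
      hi <- centers[k] + half
      src <- seq_along(tmpl)
      if (lo < 1) { src <- src[(2 - lo):length(src)]; lo <- 1 }
      if (hi > n) { src <- src[seq_len(length(src) - (hi - n))]; hi <- n }
      x[lo:hi] <- x[lo:hi] + amps[k] * tmpl[src]
    }
  }
  x <- apply_acquisition_filter(x, config$fs, config$filter)
  if (!is.null(config$quantize_bits)) {
    x <- quantize_trace(x, config$quantize_bits)$samples
  }
  mer_epoch(x, fs = config$fs, depth_mm = depth_mm,
            trajectory_id = trajectory_id, label = as.integer(inside),
            duration_s = config$epoch_s,
            true_dorsal_mm = true_dorsal_mm, true_ventral_mm = true_ventral_mm)
}

# Pooled multi-unit spike times for one epoch given inside/outside status.
pooled_spike_times <- function(config, inside) {
  if (inside) {
    n_units <- max(1L, config$n_units_inside)
    per_unit <- config$rate_inside_hz / n_units
    t <- sort(unlist(lapply(seq_len(n_units), function(u) {
      simulate_spike_train(per_unit, config$epoch_s, config$refractory_ms)
    })))
  } else {
    t <- simulate_spike_train(config$rate_outside_hz, config$epoch_s,
                              config$refractory_ms)
  }
  t
}

#' Simulate one labelled microelectrode trajectory
#'
#' Draws true dorsal/ventral borders from the configured ranges (unless
#' forced), then renders one epoch per scheduled depth. An epoch is labelled
#' inside (1) iff `dorsal <= depth <= ventral`.
#'
#' @param config A [sim_config()]; `config$seed` (unless `NULL`) seeds the
#'   trajectory so repeated calls reproduce it exactly.
#' @param trajectory_id Identifier for the simulated track.
#' @param dorsal_mm,ventral_mm Optional forced border depths.
#' @return An epoch tibble with one row per scheduled depth and the true
#'   borders recorded on every row.
#' @export
simulate_trajectory <- function(config = sim_config(), trajectory_id = "T001",
                                dorsal_mm = NULL, ventral_mm = NULL) {
  run <- function() {
    dd <- if (is.null(dorsal_mm)) {
      runif(1, config$dorsal_mm_range[1], config$dorsal_mm_range[2])
    } else dorsal_mm
    vv <- if (is.null(ventral_mm)) {
      runif(1, config$ventral_mm_range[1], config$ventral_mm_range[2])
    } else ventral_mm
    depths <- depth_schedule(config)
    rows <- lapply(depths, function(d) {
      inside <- d >= dd && d <= vv
      render_epoch(pooled_spike_times(config, inside), config, inside,
                   depth_mm = d, trajectory_id = trajectory_id,
                   true_dorsal_mm = dd, true_ventral_mm = vv)
    })
    new_mer_epochs(dplyr::bind_rows(rows))
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# Deterministic sub-seed stream: one 31-bit seed per trajectory.
derive_subseeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a dataset of independent trajectories
#'
#' Each trajectory gets its own sub-seed derived deterministically from
#' `seed`, so the dataset is reproducible from `(seed, n)` and trajectory
#' `i` does not change when `n` grows.
#'
#' @param n_trajectories Number of trajectories (>= 1).
#' @param config A [sim_config()].
#' @param seed Master seed; defaults to `config$seed`.
#' @return One epoch tibble stacking all trajectories.
#' @export
simulate_dataset <- function(n_trajectories, config = sim_config(),
                             seed = config$seed) {
  if (n_trajectories < 1) abort("n_trajectories must be >= 1.")
  subseeds <- derive_subseeds(seed, n_trajectories)
  rows <- lapply(seq_len(n_trajectories), function(i) {
    cfg_i <- config
    cfg_i$seed <- subseeds[i]
    simulate_trajectory(cfg_i, trajectory_id = sprintf("T%03d", i))
  })
  new_mer_epochs(dplyr::bind_rows(rows))
}
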