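# Independent naive-loop oracles, deliberately written without vectorized
# shortcuts so they cannot share a bug with the implementation.
oracle_teager <- function(x) {
  s <- 0
  for (i in 2:(length(x) - 1)) s <- s + x[i]^2 - x[i - 1] * x[i + 1]
  s
}
oracle_curve <- function(x) {
  s <- 0
  for (i in 1:(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}
oracle_zc <- function(x) {
  s <- 0L
  for (i in 1:(length(x) - 1)) if (x[i] * x[i + 1] < 0) s <- s + 1L
  s
}
oracle_rms <- function(x) {
  s <- 0
  for (i in seq_along(x)) s <- s + x[i]^2
  sqrt(s / length(x))
}

test_that("scalar features match hand cases and naive-loop oracles", {
  expect_equal(teager_energy(c(1, 2, 3)), 1)
  expect_equal(teager_energy(rep(4, 10)), 0)
  expect_equal(curve_length(c(1, 3, 2)), 3)
  expect_equal(curve_length(rep(2, 5)), 0)
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  expect_equal(zero_crossings(1:10), 0)
  expect_equal(rms_amplitude(c(3, 4)), sqrt(12.5))
  expect_equal(rms_amplitude(rep(-2, 9)), 2)

  withr::with_seed(51, {
    for (r in 1:5) {
      x <- rnorm(1000)
      expect_equal(teager_energy(x), oracle_teager(x), tolerance = 1e-9)
      expect_equal(curve_length(x), oracle_curve(x), tolerance = 1e-9)
      expect_identical(zero_crossings(x), oracle_zc(x))
      expect_equal(rms_amplitude(x), oracle_rms(x), tolerance = 1e-9)
    }
  })

  # sine over whole periods (half-sample offset keeps samples off the axis):
  # analytic RMS and two crossings per cycle
  # 8 cycles have 16 axis crossings; the one at t = 0 precedes the first
  # sample, leaving 2k - 1 inside the window
  t <- (0:47999 + 0.5) / 48000
  s <- 2.5 * sin(2 * pi * 8 * t)
  expect_equal(rms_amplitude(s), 2.5 / sqrt(2), tolerance = 1e-3)
  expect_equal(zero_crossings(s), 2 * 8 - 1)

  expect_error(teager_energy(c(1, 2)), "at least 3")
  expect_error(curve_length(1), "at least 2")
})

test_that("ISI statistics match direct arithmetic and the degenerate policy", {
  spikes <- cumsum(c(0.1, 0.030, 0.060, 0.070))
  f <- isi_features(spikes, duration_s = 1)
  expect_equal(f$pause_index, 2)
  expect_equal(f$pause_ratio, 130 / 30)
  expect_equal(f$n_spikes, 4)
  expect_equal(f$spiking_rate, 4)
  expect_equal(f$isi_sd, sd(c(0.030, 0.060, 0.070)))

  for (degenerate in list(numeric(0), 0.3)) {
    g <- isi_features(degenerate, duration_s = 1)
    expect_equal(unname(unlist(g)), rep(0, 5))
  }

  # no short ISI: fall back to counts / epoch-relative time
  h <- isi_features(c(0.1, 0.2, 0.35), duration_s = 1)
  expect_equal(h$pause_index, 2)
  expect_equal(h$pause_ratio, 0.25)
})

test_that("thinned-Poisson spiking rate matches the analytic value", {
  withr::with_seed(52, {
    lambda <- 30; tau <- 2e-3; dur <- 60
    rates <- replicate(40, {
      isi_features(simulate_spike_train(lambda, dur, 2), dur)$spiking_rate
    })
    expected <- 1 / (1 / lambda + tau)
    se <- sd(rates) / sqrt(length(rates))
    expect_lt(abs(mean(rates) - expected), 3 * se + 1e-9)
  })
})

test_that("the conventional vector composes its ten members in order", {
  zero <- conventional_features(numeric(1000), fs = 24000)
  expect_equal(unname(zero), rep(0, 10))
  expect_identical(names(zero),
                   c("n_spikes", "isi_sd", "pause_index", "pause_ratio",
                     "rms", "spiking_rate", "teager_energy", "zero_crossings",
                     "curve_length", "threshold_gamma"))

  withr::with_seed(53, {
    cfg <- quick_config(epoch_s = 0.25)
    e <- render_epoch(simulate_spike_train(40, 0.25), cfg, inside = TRUE)
    x <- e$samples[[1]]
    v <- conventional_features(x, cfg$fs, cfg$epoch_s)
    expect_equal(unname(v["rms"]), rms_amplitude(x))
    expect_equal(unname(v["teager_energy"]), teager_energy(x))
    expect_equal(unname(v["curve_length"]), curve_length(x))
    expect_equal(unname(v["zero_crossings"]), as.numeric(zero_crossings(x)))
    expect_equal(unname(v["threshold_gamma"]), threshold_gamma(x))
    st <- detect_spikes(x, cfg$fs, threshold_gamma(x))
    expect_equal(unname(v["spiking_rate"]),
                 isi_features(st$time_s, cfg$epoch_s)$spiking_rate)
  })
})

test_that("per-trajectory normalization yields zero-mean unit-SD columns", {
  withr::with_seed(54, {
    cfg <- quick_config(epoch_s = 0.1)
    d <- simulate_dataset(2, cfg, seed = 54)
    f <- extract_features(d, "conventional")
    z <- normalize_by_trajectory(f)
    for (tid in unique(z$trajectory_id)) {
      m <- feature_matrix(z[z$trajectory_id == tid, ])
      nontrivial <- apply(m, 2, function(col) any(col != 0))
      expect_lt(max(abs(colMeans(m))), 1e-9)
      expect_lt(max(abs(apply(m[, nontrivial, drop = FALSE], 2, sd) - 1)), 1e-9)
    }
    expect_true(attr(z, "normalized"))
  })

  # hand-built 3 x 2 case against hand-computed z-scores
  tab <- tibble::tibble(
    trajectory_id = "A", depth_mm = 1:3, label = c(0L, 0L, 1L),
    a = c(1, 2, 3), b = c(5, 5, 5)
  )
  tab <- merstn:::new_stn_features(tab, "conventional", FALSE, c("a", "b"))
  z <- normalize_by_trajectory(tab)
  expect_equal(z$a, (c(1, 2, 3) - 2) / 1)
  expect_equal(z$b, c(0, 0, 0)) # constant column policy

  single <- tab[1, ]
  expect_error(normalize_by_trajectory(single), "single-epoch")
})

test_that("Haar transform is orthonormal and invertible", {
  w <- haar_dwt(c(1, 1, 2, 2), levels = 1)
  expect_equal(w$approx, c(sqrt(2), 2 * sqrt(2)))
  expect_equal(w$details$d1, c(0, 0))

  withr::with_seed(55, {
    for (r in 1:10) {
      n <- sample(c(64, 100, 241, 1000), 1)
      x <- rnorm(n)
      lev <- sample(1:4, 1)
      w <- haar_dwt(x, levels = lev)
      energy <- sum(unlist(w$details)^2) + sum(w$approx^2)
      # padding adds energy only through the duplicated edge sample
      if (!any(w$padded)) {
        expect_equal(energy, sum(x^2), tolerance = 1e-6)
      }
      expect_equal(haar_idwt(w), x, tolerance = 1e-9)
    }
  })
  expect_error(haar_dwt(rnorm(8), levels = 4), "2\\^levels")
})

test_that("wavelet feature vector selects the requested coefficients", {
  x <- rnorm(256)
  d1 <- wavelet_features(x, selection = "d1_only")
  expect_length(d1, 128)
  expect_equal(unname(d1), haar_dwt(x, 4)$details$d1)
  all_c <- wavelet_features(x, selection = "all")
  expect_length(all_c, 256)
  expect_equal(sum(all_c^2), sum(x^2), tolerance = 1e-6)
})

test_that("FFT features satisfy Parseval and localize pure tones", {
  withr::with_seed(56, {
    for (n in c(1000, 2401)) {
      x <- rnorm(n)
      bins <- fft_features(x, fs = 24000, n_bins = 50)
      expect_equal(sum(bins), sum(x^2), tolerance = 1e-6)
    }
  })

  fs <- 24000
  tone <- sin(2 * pi * 800 * (0:(fs - 1)) / fs)
  f <- fft_features(tone, fs)
  expect_gte(attr(f, "power_mua") / sum(f), 0.95)
  expect_length(f, 10000)

  expect_equal(as.numeric(fft_features(numeric(1024), fs)), rep(0, 10000))
  expect_error(fft_features(tone, fs, band = c(0, 20000)), "fs/2")
})

test_that("feature extraction is causal: one epoch in, one vector out", {
  withr::with_seed(57, {
    cfg <- quick_config(epoch_s = 0.1)
    traj <- simulate_trajectory(cfg)
    whole <- extract_features(traj, "conventional")
    for (i in c(1, 10, 26)) {
      alone <- extract_features(traj[i, ], "conventional")
      expect_equal(feature_matrix(alone), feature_matrix(whole[i, , drop = FALSE]))
    }
  })
})

test_that("feature tables round-trip through TSV", {
  withr::with_seed(58, {
    cfg <- quick_config(epoch_s = 0.05)
    f <- extract_features(simulate_trajectory(cfg), "conventional")
    path <- withr::local_tempfile(fileext = ".tsv")
    write_features(f, path)
    back <- read_features(path)
    expect_equal(feature_matrix(back), feature_matrix(f), tolerance = 1e-9)
    expect_identical(attr(back, "family"), "conventional")
    expect_identical(nrow(back), nrow(f))
  })
})
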