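# Shared fixtures: desk-scale simulator configs (short epochs keep the unit
# suite fast; fs stays at the clinical 24 kHz so the 500-5000 Hz band is valid).

quick_config <- function(epoch_s = 0.5, seed = 11L, ...) {
  sim_config(epoch_s = epoch_s, seed = seed, ...)
}

# A small labelled feature table that is cheap to build and clearly separable:
# two Gaussian clusters in 2-D, returned as an stn_features tibble.
toy_features <- function(n_per_class = 30, shift = 3, seed = 5) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(2 * n_per_class), ncol = 2),
      matrix(rnorm(2 * n_per_class, mean = shift), ncol = 2)
    )
    tab <- tibble::tibble(
      trajectory_id = rep(c("A", "B"), length.out = 2 * n_per_class),
      depth_mm = seq_len(2 * n_per_class),
      label = rep(0:1, each = n_per_class),
      f1 = x[, 1],
      f2 = x[, 2]
    )
    merstn:::new_stn_features(tab, family = "conventional",
                              normalized = FALSE,
                              feature_names = c("f1", "f2"))
  })
}

# Epoch-shaped tibble from a raw sample vector.
wrap_epoch <- function(samples, fs = 24000, depth_mm = 0, label = NA_integer_,
                       id = "T001") {
  mer_epoch(samples, fs = fs, depth_mm = depth_mm, label = label,
            trajectory_id = id)
}
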