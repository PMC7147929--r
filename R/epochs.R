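#' Build a single microelectrode-recording epoch
#'
#' An epoch is one fixed-duration voltage trace recorded at one depth along a
#' microelectrode trajectory. Epochs are stored as rows of a tibble with the
#' raw trace in a list-column, so a trajectory (or a whole dataset of
#' trajectories) is simply a depth-ordered tibble of epochs that pipes through
#' the usual dplyr verbs.
#'
#' Depth convention: signed millimetres relative to the surgically planned
#' target, negative above the target; insertion increases depth.
#'
#' @param samples Numeric vector, the voltage trace (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param depth_mm Recording depth in mm relative to the planned target.
#' @param trajectory_id Identifier of the microelectrode track.
#' @param label `1L` inside the STN, `0L` outside, `NA` unknown.
#' @param duration_s Nominal epoch duration in seconds; defaults to
#'   `length(samples) / fs`.
#' @param true_dorsal_mm,true_ventral_mm Optional ground-truth border depths
#'   (simulated data only).
#' @return A one-row `mer_epochs` tibble.
#' @export
#' @examples
#' e <- mer_epoch(sin(seq(0, 1, length.out = 240)), fs = 240, depth_mm = -3)
#' e$depth_mm
mer_epoch <- function(samples, fs, depth_mm, trajectory_id = "T001",
                      label = NA_integer_, duration_s = length(samples) / fs,
                      true_dorsal_mm = NA_real_, true_ventral_mm = NA_real_) {
  if (!is.numeric(samples) || length(samples) < 1) {
    abort("`samples` must be a non-empty numeric vector.")
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    abort("`label` must be 0 (outside STN), 1 (inside STN) or NA (unknown).")
  }
  out <- tibble(
    trajectory_id = as.character(trajectory_id),
    depth_mm = as.numeric(depth_mm),
    fs = as.numeric(fs),
    duration_s = as.numeric(duration_s),
    label = as.integer(label),
    true_dorsal_mm = as.numeric(true_dorsal_mm),
    true_ventral_mm = as.numeric(true_ventral_mm),
    samples = list(as.numeric(samples))
  )
  new_mer_epochs(out)
}

new_mer_epochs <- function(x) {
  class(x) <- unique(c("mer_epochs", class(x)))
  x
}

#' Validate a table of epochs
#'
#' Checks the structural invariants of an epoch table: required columns,
#' sample counts consistent with `fs * duration_s`, one sampling rate per
#' trajectory, strictly increasing depths within each trajectory, labels in
#' \{0, 1, NA\}, and ordered ground-truth borders where present.
#'
#' @param epochs An epoch tibble (see [mer_epoch()]).
#' @param bandpass_high_hz Upper analysis band edge used for the Nyquist
#'   check `fs > 2 * bandpass_high_hz`; set `NULL` to skip.
#' @return `epochs`, invisibly, after sorting within trajectory by depth.
#' @export
validate_epochs <- function(epochs, bandpass_high_hz = 5000) {
  need <- setdiff(.meta_cols, c("true_dorsal_mm", "true_ventral_mm"))
  missing <- setdiff(need, names(epochs))
  if (length(missing) > 0) {
    abort(paste0("epoch table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  n_expect <- round(epochs$fs * epochs$duration_s)
  n_got <- lengths(epochs$samples)
  if (any(n_got != n_expect)) {
    abort("sample count does not match round(fs * duration_s) for some epochs.")
  }
  if (!all(is.na(epochs$label) | epochs$label %in% c(0L, 1L))) {
    abort("labels must be 0, 1 or NA.")
  }
  if (!is.null(bandpass_high_hz) && any(epochs$fs <= 2 * bandpass_high_hz)) {
    abort("fs must exceed twice the upper bandpass edge (Nyquist).")
  }
  by_traj <- split(seq_len(nrow(epochs)), epochs$trajectory_id)
  for (idx in by_traj) {
    d <- epochs$depth_mm[idx]
    if (anyDuplicated(d)) abort("duplicate depths within a trajectory.")
    if (length(unique(epochs$fs[idx])) != 1) {
      abort("all epochs of a trajectory must share one sampling rate.")
    }
    dd <- epochs$true_dorsal_mm[idx][1]
    vv <- epochs$true_ventral_mm[idx][1]
    if (!is.na(dd) && !is.na(vv) && dd >= vv) {
      abort("true_dorsal_mm must lie above (less than) true_ventral_mm.")
    }
  }
  invisible(epochs)
}

#' Sort epochs by trajectory and depth
#'
#' @param epochs An epoch tibble.
#' @return The tibble ordered by `trajectory_id` then increasing `depth_mm`.
#' @export
arrange_epochs <- function(epochs) {
  new_mer_epochs(dplyr::arrange(epochs, .data$trajectory_id, .data$depth_mm))
}
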