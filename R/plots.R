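#' Plot a trajectory's per-depth signal envelope
#'
#' RMS amplitude of each epoch against depth, with the ground-truth borders
#' (when present) marked — the visual a neurophysiologist uses to spot the
#' elevated background inside the STN.
#'
#' @param object An epoch tibble (`mer_epochs`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mer_epochs <- function(object, ...) {
  df <- tibble(
    trajectory_id = object$trajectory_id,
    depth_mm = object$depth_mm,
    rms = vapply(object$samples, rms_amplitude, 0),
    label = object$label
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_mm, y = .data$rms)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$label))) +
    ggplot2::scale_colour_manual(values = c(`0` = "#4477AA", `1` = "#CC3311"),
                                 na.value = "grey60", name = "inside STN") +
    ggplot2::facet_wrap(~trajectory_id) +
    ggplot2::labs(x = "depth relative to target (mm)", y = "epoch RMS")
  borders <- unique(object[c("trajectory_id", "true_dorsal_mm", "true_ventral_mm")])
  if (any(!is.na(borders$true_dorsal_mm))) {
    p <- p +
      ggplot2::geom_vline(data = borders,
                          ggplot2::aes(xintercept = .data$true_dorsal_mm),
                          colour = "darkgreen", linetype = 2, na.rm = TRUE) +
      ggplot2::geom_vline(data = borders,
                          ggplot2::aes(xintercept = .data$true_ventral_mm),
                          colour = "darkred", linetype = 2, na.rm = TRUE)
  }
  p
}

#' Plot spectral band power along depth
#'
#' For FFT feature tables: the 500--1000 Hz (multi-unit) and 1000--3000 Hz
#' (single-unit) band powers against depth, per trajectory.
#'
#' @param object An `stn_features` tibble of the FFT family.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stn_features <- function(object, ...) {
  if (!all(c("power_mua_hz", "power_sua_hz") %in% names(object))) {
    abort("band-power plot requires an FFT feature table.")
  }
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("trajectory_id", "depth_mm",
                        "power_mua_hz", "power_sua_hz")],
    c("power_mua_hz", "power_sua_hz"),
    names_to = "band", values_to = "power"
  )
  df$band <- ifelse(df$band == "power_mua_hz",
                    "500-1000 Hz (multi-unit)", "1000-3000 Hz (single-unit)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_mm, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(band ~ trajectory_id, scales = "free_y") +
    ggplot2::labs(x = "depth relative to target (mm)", y = "band power")
}

#' Plot an evaluation confusion matrix
#'
#' @param object An `stn_eval` from [score_predictions()].
#' @param ... Unused.
#' @return A ggplot heatmap of the confusion counts.
#' @export
autoplot.stn_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$truth),
                                   y = factor(.data$predicted),
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_gradient(low = "#4477AA", high = "#CC3311") +
    ggplot2::labs(x = "truth (1 = inside STN)", y = "predicted",
                  title = sprintf("accuracy %.1f%%", 100 * object$accuracy))
}

#' Plot per-fold cross-validation accuracy
#'
#' @param object An `stn_cv` tibble from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stn_cv <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::geom_hline(yintercept = mean(object$accuracy), linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fold", y = "accuracy")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
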