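#' Plot the ventricular volume curves of a sequence
#'
#' LV, myocardial (wall) and RV volumes across the cardiac cycle; requires
#' ggplot2.
#'
#' @param seq a [mesh_sequence()].
#' @return a ggplot object.
#' @export
plot_volume_curve <- function(seq) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  vols <- sequence_volumes(seq)
  df <- data.frame(
    frame = rep(seq_len(nrow(vols)) - 1L, times = ncol(vols)),
    volume = as.vector(vols),
    part = rep(colnames(vols), each = nrow(vols))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = frame, y = volume, colour = part)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "volume (ml)", colour = NULL)
}

#' Plot training loss curves
#'
#' Per-epoch means of the loss components from a training report.
#'
#' @param report the `report` data.frame returned by [train()].
#' @return a ggplot object.
#' @export
plot_training <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  agg <- stats::aggregate(report[, c("L_R", "L_KL", "L_S", "L_total")],
                          by = list(epoch = report$epoch), FUN = mean)
  df <- stats::reshape(agg, direction = "long",
                       varying = c("L_R", "L_KL", "L_S", "L_total"),
                       v.names = "value", timevar = "component",
                       times = c("L_R", "L_KL", "L_S", "L_total"))
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = value,
                                   colour = component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL)
}
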