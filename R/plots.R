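#' Volcano-plot data from a vibration result
#'
#' One point per converged estimate: hazard ratio on the x-axis and
#' `-log10(p)` on the y-axis, plus the reference fit (the favourite model on
#' the unperturbed full cohort) when the run carries one, and the position
#' of the significance threshold line.
#'
#' @param result A `voe_result`.
#' @param alpha Significance level for the threshold line.
#' @return A `voe_volcano` list with `points` (data.frame `hr`,
#'   `neglog10_p`), `reference` (one-row data.frame or `NULL`) and
#'   `alpha_line`.
#' @export
volcano_data <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "voe_result"))
  conv <- result$estimates[result$estimates$converged, , drop = FALSE]
  if (nrow(conv) == 0L) {
    stop("no converged estimates to plot", call. = FALSE)
  }
  ref <- result$reference
  if (!is.null(ref) && isTRUE(ref$converged)) {
    ref <- data.frame(hr = ref$hr, neglog10_p = -log10(ref$p_value))
  } else {
    ref <- NULL
  }
  structure(
    list(points = data.frame(hr = conv$hr,
                             neglog10_p = -log10(conv$p_value)),
         reference = ref,
         alpha_line = -log10(alpha),
         vibration_type = result$vibration_type,
         scenario = result$scenario),
    class = "voe_volcano"
  )
}

#' Build a volcano ggplot
#'
#' Hazard ratios on a log-scaled x-axis (so reciprocal effects are
#' symmetric about HR = 1), `-log10(p)` on the y-axis, a horizontal dashed
#' line at the significance threshold, a vertical line at HR = 1, and a
#' black cross marking the reference fit when present.
#'
#' @param data A `voe_volcano` from [volcano_data()].
#' @param point_color,point_alpha Marker styling.
#' @return A ggplot object.
#' @export
plot_volcano <- function(data, point_color = "#2c7fb8", point_alpha = 0.5) {
  stopifnot(inherits(data, "voe_volcano"))
  ttl <- paste0(data$vibration_type, " vibration",
                if (!is.null(data$scenario)) paste0(" (", data$scenario, ")"))
  p <- ggplot2::ggplot(data$points,
                       ggplot2::aes(x = .data$hr, y = .data$neglog10_p)) +
    ggplot2::geom_point(color = point_color, alpha = point_alpha, size = 1) +
    ggplot2::geom_hline(yintercept = data$alpha_line, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio", y = expression(-log[10](italic(P))),
                  title = ttl) +
    ggplot2::theme_minimal()
  if (!is.null(data$reference)) {
    p <- p + ggplot2::geom_point(data = data$reference, shape = 4,
                                 size = 3, stroke = 1.2, color = "black")
  }
  p
}

#' Render a volcano plot to file
#'
#' @param data A `voe_volcano`.
#' @param out_path Output path; the extension selects the device
#'   (`.png` or `.svg`).
#' @param width,height,dpi Device settings.
#' @return Invisibly, `out_path`.
#' @export
render_volcano <- function(data, out_path, width = 5, height = 4,
                           dpi = 150) {
  p <- plot_volcano(data)
  ggplot2::ggsave(out_path, plot = p, width = width, height = height,
                  dpi = dpi)
  invisible(out_path)
}

#' Build the sample-size sweep figure
#'
#' Two panels from a [vibration_over_sample_sizes()] table: relative hazard
#' ratios against sample size per vibration type (log-scaled x-axis), and
#' stacked bars with the fraction of negative-significant, non-significant
#' and positive-significant estimates per size and type.
#'
#' @param sweep_table Data.frame from [vibration_over_sample_sizes()].
#' @return A list of two ggplot objects, `rhr` and `significance`.
#' @export
plot_sweep <- function(sweep_table) {
  if (nrow(sweep_table) == 0L) stop("sweep table is empty", call. = FALSE)
  p_rhr <- ggplot2::ggplot(
    sweep_table,
    ggplot2::aes(x = .data$n, y = .data$rhr,
                 color = .data$vibration_type,
                 group = .data$vibration_type)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Sample size", y = "Relative hazard ratio",
                  color = "Vibration") +
    ggplot2::theme_minimal()

  long <- do.call(rbind, lapply(
    c("n_neg_sig", "n_nonsig", "n_pos_sig"), function(cl) {
      data.frame(n = sweep_table$n,
                 vibration_type = sweep_table$vibration_type,
                 class = sub("^n_", "", cl),
                 count = sweep_table[[cl]])
    }))
  long$class <- factor(long$class,
                       levels = c("neg_sig", "nonsig", "pos_sig"),
                       labels = c("negative significant", "non-significant",
                                  "positive significant"))
  p_sig <- ggplot2::ggplot(
    long, ggplot2::aes(x = factor(.data$n), y = .data$count,
                       fill = .data$class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::facet_wrap(~vibration_type) +
    ggplot2::labs(x = "Sample size", y = "Fraction of estimates",
                  fill = NULL) +
    ggplot2::theme_minimal()

  list(rhr = p_rhr, significance = p_sig)
}

#' Render the sweep figure to file
#'
#' Writes the RHR panel to `out_path` and the significance panel next to it
#' with a `_significance` suffix.
#'
#' @param sweep_table Data.frame from [vibration_over_sample_sizes()].
#' @param out_path Output path for the RHR panel.
#' @inheritParams render_volcano
#' @return Invisibly, the two written paths.
#' @export
render_sweep <- function(sweep_table, out_path, width = 6, height = 4,
                         dpi = 150) {
  ps <- plot_sweep(sweep_table)
  sig_path <- sub("(\\.[a-zA-Z]+)$", "_significance\\1", out_path)
  ggplot2::ggsave(out_path, plot = ps$rhr, width = width, height = height,
                  dpi = dpi)
  ggplot2::ggsave(sig_path, plot = ps$significance, width = width,
                  height = height, dpi = dpi)
  invisible(c(out_path, sig_path))
}
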