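#' Manhattan plot of an association scan
#'
#' @param object an `assoc_scan` tibble from [glm_scan()] or [mlm_scan()].
#' @param thresholds optional [assoc_thresholds()] tibble drawn as dashed
#'   lines.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot assoc_scan
#' @export
autoplot.assoc_scan <- function(object, thresholds = NULL, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$chrom, .data$pos_bp)
  offs <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos_bp)) |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  df <- dplyr::left_join(df, offs, by = "chrom") |>
    dplyr::mutate(x = .data$pos_bp + .data$offset)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$neg_log10_p,
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position (bp, concatenated)",
                  y = expression(-log[10](p)),
                  title = unique(df$model)[1]) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(
      data = tibble::as_tibble(thresholds),
      ggplot2::aes(yintercept = .data$neg_log10_p),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' LOD profile plot
#'
#' @param object an [hk_scan()] result.
#' @param threshold LOD threshold line.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot lod_profile
#' @export
autoplot.lod_profile <- function(object, threshold = 2.5, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$pos_cM, .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "map position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
}

#' Prediction-accuracy curves
#'
#' Mean accuracy against marker-set size per strategy and phenotype, with a
#' one-standard-deviation ribbon over repeats.
#'
#' @param object a [run_experiment()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pred_curves
#' @export
autoplot.pred_curves <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$size, .data$mean_r,
                               colour = .data$strategy)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                   ymax = .data$mean_r + .data$sd_r,
                   fill = .data$strategy),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~phenotype) +
    ggplot2::labs(x = "marker-set size (tagSNPs)",
                  y = "prediction accuracy (r)") +
    ggplot2::theme_minimal()
}
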