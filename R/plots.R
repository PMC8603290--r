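#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_step geom_line
#'   geom_abline geom_hline geom_vline labs facet_grid theme_bw
#' @export
ggplot2::autoplot

#' Plot PCA sample scores
#'
#' @param object An `expr_pca` object.
#' @param x_component,y_component Components to plot (default PC1 vs PC2).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot expr_pca
#' @export
autoplot.expr_pca <- function(object, x_component = 1L, y_component = 2L,
                              ...) {
  sc <- object$scores
  xc <- paste0("PC", x_component)
  yc <- paste0("PC", y_component)
  stopifnot(all(c(xc, yc) %in% names(sc)))
  pct <- function(i) sprintf("%s (%.1f%%)", paste0("PC", i),
                             100 * object$explained_variance_fraction[i])
  ggplot(sc, aes(x = .data[[xc]], y = .data[[yc]], label = .data$sample)) +
    geom_point(size = 2) +
    labs(x = pct(x_component), y = pct(y_component)) +
    theme_bw()
}

#' Plot a ROC curve with the selected cut-off
#'
#' @param object A `roc_cutoff` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_cutoff
#' @export
autoplot.roc_cutoff <- function(object, ...) {
  cv <- object$curve
  best <- cv[cv$threshold == object$cutoff, ]
  ggplot(cv, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    geom_point(data = best, colour = "red", size = 3) +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("cutoff = %g (J = %.2f, AUC = %.2f)",
                         object$cutoff, object$youden_j, object$auc)) +
    theme_bw()
}

#' Plot an LRR track along the genome
#'
#' Raw per-site LRR in grey with the representative (window-median) LRR on
#' top, faceted by chromosome; optional truth segments drawn as horizontal
#' marks at their expected LRR.
#'
#' @param track Smoothed track from [smooth_lrr()].
#' @param segments Optional truth segment tibble with `expected_lrr`.
#' @return A ggplot.
#' @export
plot_lrr_track <- function(track, segments = NULL) {
  stopifnot(all(c("chrom", "pos", "lrr_raw", "lrr_rep") %in% names(track)))
  p <- ggplot(track, aes(x = .data$pos / 1e6)) +
    geom_point(aes(y = .data$lrr_raw), colour = "grey70", size = 0.3) +
    geom_line(aes(y = .data$lrr_rep), colour = "firebrick") +
    geom_hline(yintercept = 0, linetype = "dotted") +
    facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    labs(x = "position (Mb)", y = "LRR") +
    theme_bw()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      aes(x = .data$start / 1e6, xend = .data$end / 1e6,
          y = .data$expected_lrr, yend = .data$expected_lrr),
      colour = "blue", linetype = "longdash", inherit.aes = FALSE
    )
  }
  p
}

#' Plot Kaplan-Meier curves
#'
#' @param data Cohort tibble.
#' @param time,event Columns (tidy-eval).
#' @param group Optional grouping column.
#' @return A ggplot of step survival curves.
#' @export
plot_km <- function(data, time, event, group = NULL) {
  km <- km_estimate(data, {{ time }}, {{ event }}, {{ group }})
  if ("group" %in% names(km)) {
    start <- km |>
      dplyr::distinct(.data$group) |>
      dplyr::mutate(time = 0, survival = 1)
    ggplot(dplyr::bind_rows(start, km),
           aes(x = .data$time, y = .data$survival,
               colour = .data$group)) +
      geom_step() +
      labs(x = "time (months)", y = "survival", colour = NULL) +
      ggplot2::ylim(0, 1) +
      theme_bw()
  } else {
    ggplot(dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                            km[, c("time", "survival")]),
           aes(x = .data$time, y = .data$survival)) +
      geom_step() +
      labs(x = "time (months)", y = "survival") +
      ggplot2::ylim(0, 1) +
      theme_bw()
  }
}
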