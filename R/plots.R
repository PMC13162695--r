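#' Plot a window track along the genome
#'
#' @param object A window-track tibble (from [windowed_pi()],
#'   [windowed_fst()], [fd_windows()], [xpehh()], ...).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_track <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = unique(object$stat)[1]) +
    ggplot2::theme_minimal()
}

#' Plot a one-dimensional site frequency spectrum
#'
#' @param object An `sfs_tensor` with a single population axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfs_tensor <- function(object, ...) {
  stop_if_not(length(dim(object$counts)) == 1 ||
                sum(dim(object$counts) > 1) == 1,
              "autoplot supports one-dimensional spectra")
  v <- as.vector(object$counts)
  tab <- tibble(count = seq_along(v) - 1L, sites = v,
                masked = as.vector(object$mask))
  ggplot2::ggplot(dplyr::filter(tab, !.data$masked),
                  ggplot2::aes(x = .data$count, y = .data$sites)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = if (object$folded) "minor-allele count"
                  else "derived-allele count", y = "sites") +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison ranking
#'
#' @param ranking Output of [compare_models()].
#' @return A ggplot of delta-likelihood per scenario (lower = better
#'   fit).
#' @export
plot_model_comparison <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$model_id,
                                                  .data$delta),
                               y = .data$delta)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "delta likelihood (log10)") +
    ggplot2::theme_minimal()
}
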