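#' Plot methods
#'
#' `autoplot()` methods return ggplot objects: a metaprofile line with
#' its SEM ribbon, a permutation null histogram with the observed
#' statistic, and a region heatmap for metaprofiles.
#'
#' @param object Result object.
#' @param ... Unused.
#' @name epicoloc-plots
NULL

#' @rdname epicoloc-plots
#' @method autoplot meta_profile
#' @export
autoplot.meta_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      fill = "grey70"
    ) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "position (bp)", y = "mean signal (RPKM)") +
    ggplot2::theme_minimal()
}

#' @rdname epicoloc-plots
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#b2182b") +
    ggplot2::labs(
      x = object$statistic_name, y = "shuffles",
      title = sprintf("observed = %d, p = %.4g", object$observed, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-region metaprofile rows
#'
#' Rows are the individual regions of a [summit_profile()] or
#' [gene_metagene()]; by default they are ordered by descending mean
#' signal.
#'
#' @param profile A `meta_profile`.
#' @param sort_rows Order rows by descending mean (default TRUE).
#' @export
plot_profile_heatmap <- function(profile, sort_rows = TRUE) {
  mat <- attr(profile, "profile_matrix")
  if (is.null(mat)) abort("profile has no per-region matrix")
  ord <- if (sort_rows) order(rowMeans(mat), decreasing = TRUE) else seq_len(nrow(mat))
  df <- tidyr::expand_grid(
    region = seq_len(nrow(mat)), bin = seq_len(ncol(mat))
  )
  df$value <- as.vector(t(mat[ord, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$region,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "RPKM") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "profile bin", y = "region") +
    ggplot2::theme_minimal()
}
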