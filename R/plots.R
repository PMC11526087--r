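#' Volcano plot of a differential table
#'
#' Plots log2 fold change against -log10 p with the DEP thresholds drawn
#' as dotted lines and points colored by direction.
#'
#' @param object A `dep_table` from [welch_dep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dep_table <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$log2fc, y = -log10(.data$p), color = .data$direction)
  ) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::geom_vline(xintercept = c(-th$log2fc, th$log2fc), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(th$p), linetype = "dotted") +
    ggplot2::scale_color_manual(values = c(
      "A-enriched" = "#c0392b", "B-enriched" = "#2980b9", "none" = "grey70"
    )) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves
#'
#' @param object A `km_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- tidy(object)
  if (!"group" %in% names(d)) d$group <- "all"
  # prepend S(0) = 1 per group
  d0 <- d |>
    group_by(.data$group) |>
    dplyr::slice(1) |>
    mutate(time = 0, estimate = 1) |>
    ungroup()
  ggplot2::ggplot(
    bind_rows(d0, d),
    ggplot2::aes(x = .data$time, y = .data$estimate, color = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' PCA embedding scatter plot
#'
#' @param object A `pca_embed` object.
#' @param color Optional vector (aligned with samples) used for color.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_embed <- function(object, color = NULL, ...) {
  d <- object$coords
  ev <- object$explained_variance
  if (!is.null(color)) d$color <- color
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(color)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$color)) +
      ggplot2::labs(color = NULL)
  }
}

#' Bar plot of per-group matrisome category composition
#'
#' @param composition Output of [category_composition()].
#' @param drop_none Drop the non-matrisome remainder (default TRUE).
#' @return A ggplot object.
#' @export
plot_category_composition <- function(composition, drop_none = TRUE) {
  d <- composition$group_means
  if (drop_none) d <- filter(d, .data$category != "none")
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$group, y = .data$mean_rpc, fill = .data$category)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "mean RPC (%)", fill = "category") +
    ggplot2::theme_minimal()
}
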