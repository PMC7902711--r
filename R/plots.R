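#' Plot a masked relative-to-control heatmap
#'
#' Class x element tiles colored by the clipped ratio on a log scale
#' (blue below 1, orange above); blank tiles are non-significant cells.
#' Facets by species/tissue when several strata are present.
#'
#' @param object An `ion_heatmap` from [heatmap_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ion_heatmap <- function(object, ...) {
  clip <- attr(object, "clip") %||% c(0.2, 5)
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$element, y = .data$class, fill = .data$display)
  ) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#e08214",
      midpoint = 0, trans = "log10",
      limits = clip, na.value = "white",
      name = "ratio to control"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  strata <- intersect(c("species", "tissue"), names(object))
  strata <- strata[vapply(
    strata, function(s) length(unique(object[[s]])) > 1, logical(1)
  )]
  if (length(strata) > 0) {
    p <- p + ggplot2::facet_wrap(strata)
  }
  p
}

#' Plot an ionomic signature (VIP grade) heatmap
#'
#' Grayscale class x element tiles at the conventional VIP grades: white
#' below 1, then light/mid/dark gray at 1, 1.5 and 2.
#'
#' @param object An `ion_vip` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ion_vip <- function(object, ...) {
  grades <- vip_threshold_grades(object)
  df <- tibble::tibble(
    class = rep(rownames(object), times = ncol(object)),
    element = rep(colnames(object), each = nrow(object)),
    grade = factor(as.vector(grades), levels = c(0, 1, 1.5, 2))
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$element, y = .data$class, fill = .data$grade)
  ) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(
      values = c(`0` = "white", `1` = "grey75", `1.5` = "grey50", `2` = "grey25"),
      drop = FALSE, name = "VIP grade"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-repetition accuracies of the prediction methods
#'
#' @param object An `ion_protocol`.
#' @param ... Unused.
#' @return A ggplot (boxplot of accuracy by method).
#' @export
autoplot.ion_protocol <- function(object, ...) {
  ggplot2::ggplot(
    object$accuracy,
    ggplot2::aes(x = .data$method, y = .data$accuracy)
  ) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "prediction method", y = "accuracy over repetitions"
    ) +
    ggplot2::theme_minimal()
}

#' Plot PCA scores
#'
#' @param object An `ion_pca`.
#' @param components Two components to display.
#' @param color Optional vector (e.g. class labels) to color points by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ion_pca <- function(object, components = c(1, 2), color = NULL, ...) {
  df <- tibble::tibble(
    x = object$scores[, components[1]],
    y = object$scores[, components[2]]
  )
  lab <- function(a) {
    paste0("PC", a, " (", round(100 * object$explained[a], 1), "%)")
  }
  if (!is.null(color)) {
    df$color <- color
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, color = .data$color))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = lab(components[1]), y = lab(components[2]), color = NULL
    ) +
    ggplot2::theme_minimal()
}
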