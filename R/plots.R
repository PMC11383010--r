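#' PCA biplot of region scores
#'
#' PC1/PC2 scatter colored by a grouping (annotation class, SVM label or
#' refined class), with optional kernel-density contour overlays per
#' group, mirroring the standard biplot-with-contours presentation.
#'
#' @param object A `region_pca`.
#' @param groups Optional tibble `region_id`, `group`.
#' @param contours Overlay per-group KDE contours (default TRUE when
#'   groups are given).
#' @param h,n KDE bandwidth and grid size (defaults 3 and 125).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_pca <- function(object, groups = NULL,
                                contours = !is.null(groups),
                                h = 3, n = 125, ...) {
  df <- object$scores
  ve <- object$var_explained
  labs_xy <- ggplot2::labs(
    x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
    y = sprintf("PC2 (%.0f%%)", 100 * ve[2])
  )
  if (is.null(groups)) {
    return(ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
             ggplot2::geom_point(alpha = 0.4, size = 0.6) +
             labs_xy + ggplot2::theme_minimal())
  }
  df <- left_join(df, as_tibble(groups), by = "region_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                        color = .data$group)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    labs_xy + ggplot2::theme_minimal()
  if (contours) {
    lims <- c(range(df$PC1), range(df$PC2))
    cont <- df %>%
      filter(!is.na(.data$group)) %>%
      group_by(.data$group) %>%
      dplyr::group_modify(function(d, key) {
        if (nrow(d) < 2) return(tibble())
        k <- kde_contours(d$PC1, d$PC2, h = h, n = n, lims = lims)
        tidyr::expand_grid(x = k$x, y = k$y) %>%
          mutate(z = as.vector(t(k$z)))
      }) %>% ungroup()
    if (nrow(cont)) {
      p <- p + ggplot2::geom_contour(
        data = cont,
        ggplot2::aes(.data$x, .data$y, z = .data$z, color = .data$group),
        inherit.aes = FALSE, bins = 6, linewidth = 0.3)
    }
  }
  p
}

#' Heatmap of a reference-point coverage matrix
#'
#' Rows are regions (in matrix order), columns are bins around the
#' region midpoint; the fill scale is clamped to the adaptive
#' `(zmin, zmax)` unless overridden.
#'
#' @param mat A `coverage_matrix`.
#' @param scale Optional `c(zmin, zmax)`; default [adaptive_scale()].
#' @return A ggplot object.
#' @export
plot_coverage_heatmap <- function(mat, scale = NULL) {
  if (is.null(scale)) scale <- adaptive_scale(mat)
  bin <- attr(mat, "bin")
  span <- attr(mat, "span")
  df <- as_tibble(as.table(unclass(mat)), .name_repair = "minimal")
  names(df) <- c("region", "bin_idx", "value")
  df <- df %>%
    mutate(pos = (as.integer(.data$bin_idx) - 0.5) * bin - span,
           row = as.integer(factor(.data$region, levels = rev(rownames(mat)))),
           value = pmin(pmax(.data$value, scale[1]), scale[2]))
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = scale) +
    ggplot2::labs(x = "distance from region center (bp)", y = NULL,
                  fill = "coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Expression-trajectory plot with confidence ribbon
#'
#' @param object An `enhancer_trajectory` (optionally row-bound from
#'   several groups with a `group` column added).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enhancer_trajectory <- function(object, ...) {
  has_group <- "group" %in% names(object)
  aes_line <- if (has_group) {
    ggplot2::aes(.data$time, .data$mean_lfc, color = .data$group,
                 fill = .data$group)
  } else {
    ggplot2::aes(.data$time, .data$mean_lfc)
  }
  ggplot2::ggplot(object, aes_line) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hours post fertilization",
                  y = "mean log2 fold change vs time 0") +
    ggplot2::theme_minimal()
}

#' Per-embryo normalized qRT-PCR values
#'
#' @param object A `qpcr_effect`.
#' @param ... Unused.
#' @return A ggplot object: normalized expression per embryo by group,
#'   control average at 1.
#' @export
autoplot.qpcr_effect <- function(object, ...) {
  ggplot2::ggplot(object$embryos,
                  ggplot2::aes(.data$group, .data$v_norm)) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "expression relative to control mean") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
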