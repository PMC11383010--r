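#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a region PCA
#'
#' @param x A `region_pca`.
#' @param matrix `"scores"` (default), `"loadings"` or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in long broom style.
#' @export
tidy.region_pca <- function(x, matrix = c("scores", "loadings",
                                          "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    x$scores %>%
      tidyr::pivot_longer(-"region_id", names_to = "component",
                          values_to = "score")
  } else if (matrix == "loadings") {
    as_tibble(x$loadings, rownames = "feature") %>%
      tidyr::pivot_longer(-"feature", names_to = "component",
                          values_to = "loading")
  } else {
    tibble(component = paste0("PC", seq_along(x$var_explained)),
           std_dev = x$sdev,
           var_explained = x$var_explained,
           cum_var_explained = cumsum(x$var_explained))
  }
}

#' @rdname tidy.region_pca
#' @export
glance.region_pca <- function(x, ...) {
  tibble(n_regions = nrow(x$scores),
         n_features = nrow(x$loadings),
         pc1_var = x$var_explained[1],
         pc2_var = x$var_explained[2],
         pc12_var = sum(x$var_explained[1:2]))
}

#' Tidy / glance a fitted region classifier
#'
#' @param x A `region_classifier`.
#' @param ... Unused.
#' @return `glance` gives a one-row model summary.
#' @export
glance.region_classifier <- function(x, ...) {
  tibble(n_train = x$n_train,
         n_support_vectors = x$fit$tot.nSV,
         gamma = x$gamma, cost = x$cost, n_pcs = x$n_pcs)
}

#' Tidy a qPCR effect fit
#'
#' @param x A `qpcr_effect`.
#' @param ... Unused.
#' @return Per-embryo normalized expression values.
#' @export
tidy.qpcr_effect <- function(x, ...) {
  select(x$embryos, "embryo_id", "group", "delta_ct", "v", "v_norm")
}

#' @rdname tidy.qpcr_effect
#' @export
glance.qpcr_effect <- function(x, ...) {
  tibble(fold_change = x$fold_change, p_value = x$p_value,
         n_control = x$n_control, n_crispant = x$n_crispant)
}
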