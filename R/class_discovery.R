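#' Assemble the region-by-feature matrix
#'
#' Pivots oriented long features into one row per region with three
#' columns per mark (`<mark>_u`, `<mark>_c`, `<mark>_d`) in declared mark
#' order; 10 marks give the 30-feature matrix used for PCA.
#'
#' @param feats Long oriented feature tibble from [region_features()].
#' @param marks Mark order (default: order of first appearance).
#' @return A `feature_matrix`: tibble with `region_id` plus 3 numeric
#'   columns per mark.
#' @export
assemble_feature_matrix <- function(feats, marks = NULL) {
  feats <- as_tibble(feats)
  if (is.null(marks)) marks <- unique(feats$mark)
  missing_marks <- feats %>%
    distinct(.data$region_id, .data$mark) %>%
    dplyr::count(.data$region_id) %>%
    filter(.data$n < length(.env$marks))
  if (nrow(missing_marks)) {
    abort(paste0("region(s) missing one or more marks: ",
                 paste(head(missing_marks$region_id, 5), collapse = ", ")))
  }
  wide <- feats %>%
    select("region_id", "mark", "u", "c", "d") %>%
    tidyr::pivot_wider(names_from = "mark",
                       values_from = c("u", "c", "d"),
                       names_glue = "{mark}_{.value}")
  cols <- as.vector(t(outer(marks, c("u", "c", "d"), paste, sep = "_")))
  out <- wide %>% select("region_id", all_of(cols))
  if (anyNA(out)) abort("feature matrix contains missing values")
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Principal component analysis of the feature matrix
#'
#' Column-mean-centered, unscaled PCA via singular value decomposition
#' (`stats::prcomp`). Variance explained per component is
#' `sigma_k^2 / sum(sigma^2)`. Component signs are fixed so the loading of
#' largest magnitude in each component is positive, making scores
#' reproducible across platforms.
#'
#' @param fm A `feature_matrix` from [assemble_feature_matrix()].
#' @param scale. Scale columns to unit variance before PCA (default FALSE,
#'   matching centered-only PCA).
#' @return A `region_pca` object: `scores` (tibble with `region_id` and
#'   `PC*` columns), `loadings` (feature x component matrix),
#'   `var_explained`, `center`.
#' @export
run_pca <- function(fm, scale. = FALSE) {
  ids <- fm$region_id
  m <- as.matrix(fm[setdiff(names(fm), "region_id")])
  if (nrow(m) < 2 || ncol(m) < 2) abort("need >= 2 rows and >= 2 columns")
  if (all(apply(m, 2, stats::var) < .Machine$double.eps)) {
    abort("constant feature matrix: zero variance")
  }
  pc <- prcomp(m, center = TRUE, scale. = scale.)
  # fix signs: largest-magnitude loading positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x) %>% mutate(region_id = ids) %>%
    select("region_id", dplyr::everything())
  structure(
    list(scores = scores, loadings = pc$rotation, var_explained = ve,
         center = pc$center, scale = pc$scale, sdev = pc$sdev),
    class = "region_pca"
  )
}

#' @export
print.region_pca <- function(x, ...) {
  cat(sprintf("<region_pca> %d regions x %d features; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings),
              100 * sum(x$var_explained[1:2])))
  invisible(x)
}

#' Fit the promoter-vs-enhancer SVM on principal-component scores
#'
#' A soft-margin radial-basis-kernel support vector machine
#' (`e1071::svm`, gamma = 1, cost = 1) trained on the first `n_pcs`
#' PC scores of regions annotated promoter (label `"promoter"`) or distal
#' (label `"enhancer"`); TSS-proximal regions are excluded from training.
#'
#' @param pca A `region_pca` (or a tibble of scores with `region_id`).
#' @param labels Tibble with `region_id` and `label` in
#'   `c("promoter", "enhancer")` for the training regions.
#' @param n_pcs Number of leading PCs to use (default 3).
#' @param gamma,cost RBF kernel parameters (defaults 1 and 1).
#' @return A `region_classifier` object wrapping the fitted SVM.
#' @export
fit_region_classifier <- function(pca, labels, n_pcs = 3, gamma = 1, cost = 1) {
  scores <- if (inherits(pca, "region_pca")) pca$scores else as_tibble(pca)
  pcs <- paste0("PC", seq_len(n_pcs))
  if (!all(pcs %in% names(scores))) abort("scores lack the requested PCs")
  labels <- as_tibble(labels)
  if (!all(labels$label %in% c("promoter", "enhancer"))) {
    abort("labels must be 'promoter' or 'enhancer'")
  }
  if (length(unique(labels$label)) < 2) abort("need both classes to train")
  train <- inner_join(labels, scores, by = "region_id")
  fit <- e1071::svm(
    x = as.matrix(train[pcs]),
    y = factor(train$label, levels = c("enhancer", "promoter")),
    kernel = "radial", gamma = gamma, cost = cost, scale = FALSE
  )
  structure(list(fit = fit, n_pcs = n_pcs, gamma = gamma, cost = cost,
                 n_train = nrow(train)),
            class = "region_classifier")
}

#' @export
print.region_classifier <- function(x, ...) {
  cat(sprintf("<region_classifier> RBF SVM on PC1-%d (gamma=%g, cost=%g), %d training regions\n",
              x$n_pcs, x$gamma, x$cost, x$n_train))
  invisible(x)
}

#' Classify all regions and flag annotation mismatches
#'
#' Predicts promoter/enhancer for every region from its PC scores, then
#' crosses predictions with the positional annotation: distal regions
#' predicted promoter are `promoter_like_enhancer` (the H3K4me2-enhancer
#' candidates), distal predicted enhancer are `typical_enhancer`,
#' promoters predicted promoter are `typical_promoter`, promoters
#' predicted enhancer are `enhancer_like_promoter`. TSS-proximal regions
#' get mismatch `"n/a"`.
#'
#' @param model A `region_classifier`.
#' @param pca A `region_pca` (or scores tibble) covering all regions.
#' @param anno Tibble with `region_id` and `anno_class`.
#' @return Tibble `region_id`, `anno_class`, `svm_label`, `mismatch`.
#' @export
classify_and_flag <- function(model, pca, anno) {
  scores <- if (inherits(pca, "region_pca")) pca$scores else as_tibble(pca)
  pcs <- paste0("PC", seq_len(model$n_pcs))
  pred <- as.character(predict(model$fit, as.matrix(scores[pcs])))
  out <- tibble(region_id = scores$region_id, svm_label = pred) %>%
    left_join(select(as_tibble(anno), "region_id", "anno_class"),
              by = "region_id") %>%
    mutate(mismatch = case_when(
      anno_class == "distal" & svm_label == "promoter" ~ "promoter_like_enhancer",
      anno_class == "distal" & svm_label == "enhancer" ~ "typical_enhancer",
      anno_class == "promoter" & svm_label == "promoter" ~ "typical_promoter",
      anno_class == "promoter" & svm_label == "enhancer" ~ "enhancer_like_promoter",
      TRUE ~ "n/a"
    )) %>%
    select("region_id", "anno_class", "svm_label", "mismatch")
  out
}

#' Refined fold-enrichment enhancer classes
#'
#' Deterministic class calls from IgG fold enrichments. For distal
#' regions: active enhancers require H3K4me1 fold >= 2 and H3K27ac fold
#' at least 1.5; among them H3K4me2 fold >= 2 gives `k4me2_enhancer`, H3K4me2
#' fold < 1.25 gives `k4me1_enhancer`, and the 1.25--2 gray zone is
#' `unclassified`. Distal regions with H3K4me1 >= 2 but H3K27ac <= 1.5
#' are `poised_enhancer`. TSS-proximal regions with H3K4me3 fold < 1.25
#' are `proximal_potential_enhancer` (with `k4me2_flag` when H3K4me2
#' fold >= 2). A separate strict H3K4me2 flag requires fold > 3.
#'
#' @param enrich Tibble from [region_enrichment()] (long) or a wide tibble
#'   with `region_id` and one fold column per mark named by mark.
#' @param anno Tibble with `region_id`, `anno_class`.
#' @param params [pipeline_params()] carrying the thresholds.
#' @return Tibble `region_id`, `anno_class`, `refined`, `k4me2_flag`,
#'   `k4me2_strict` plus the fold columns used.
#' @export
refine_enhancer_classes <- function(enrich, anno, params = pipeline_params()) {
  enrich <- as_tibble(enrich)
  if ("mark" %in% names(enrich)) {
    enrich <- enrich %>%
      select("region_id", "mark", "fold_igg") %>%
      tidyr::pivot_wider(names_from = "mark", values_from = "fold_igg")
  }
  need <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K27ac")
  miss <- setdiff(need, names(enrich))
  if (length(miss)) abort(paste0("missing fold enrichment for mark(s): ",
                                 paste(miss, collapse = ", ")))
  p <- params
  enrich %>%
    left_join(select(as_tibble(anno), "region_id", "anno_class"),
              by = "region_id") %>%
    mutate(
      refined = case_when(
        anno_class == "distal" & H3K4me1 >= p$min_k4me1_fold &
          H3K27ac >= p$min_k27ac_fold & H3K4me2 >= p$min_k4me2_fold ~
          "k4me2_enhancer",
        anno_class == "distal" & H3K4me1 >= p$min_k4me1_fold &
          H3K27ac >= p$min_k27ac_fold & H3K4me2 < p$max_k4me2_fold_me1 ~
          "k4me1_enhancer",
        anno_class == "distal" & H3K4me1 >= p$min_k4me1_fold &
          H3K27ac <= p$max_k27ac_fold_poised ~ "poised_enhancer",
        anno_class == "proximal" & H3K4me3 < p$max_k4me3_fold_proximal ~
          "proximal_potential_enhancer",
        TRUE ~ "unclassified"
      ),
      k4me2_flag = .data$refined %in%
        c("k4me2_enhancer", "proximal_potential_enhancer") &
        .data$H3K4me2 >= p$min_k4me2_fold,
      k4me2_strict = .data$H3K4me2 > p$strict_k4me2_fold
    )
}

#' Heatmap pre-filter for the four mismatch groups
#'
#' Selects regions with H3K4me1 fold enrichment over IgG >= `min_fold`
#' and mean center+downstream coverage >= `min_rpkm` RPKM, the filter
#' applied before plotting the typical/promoter-like groups.
#'
#' @param enrich Long tibble from [region_enrichment()].
#' @param min_fold Minimum H3K4me1 fold over IgG (default 2).
#' @param min_rpkm Minimum center+downstream coverage (default 10).
#' @return Character vector of passing region ids.
#' @export
heatmap_prefilter <- function(enrich, min_fold = 2, min_rpkm = 10) {
  enrich %>%
    filter(.data$mark == "H3K4me1",
           .data$fold_igg >= .env$min_fold,
           .data$rpkm_cd >= .env$min_rpkm) %>%
    pull("region_id")
}

#' Bivariate kernel density on a grid
#'
#' Axis-aligned Gaussian kernel density of PC1/PC2 scores on an
#' `n` x `n` grid spanning the data range (optionally fixed `lims`),
#' using the convention that the bandwidth argument `h` is 4 Gaussian
#' standard deviations (sd = h/4), so contours match the classical
#' two-dimensional KDE routine used for the biplot overlays.
#'
#' @param x,y Point coordinates (e.g. PC1 and PC2 scores).
#' @param h Bandwidth per axis (default 3); scalar or length-2.
#' @param n Grid points per axis (default 125).
#' @param lims Optional `c(xmin, xmax, ymin, ymax)`; default data range.
#' @return A list with `x`, `y` (grid coordinates) and `z` (`n` x `n`
#'   density matrix integrating to ~1).
#' @export
kde_contours <- function(x, y, h = 3, n = 125, lims = NULL) {
  if (length(x) < 2 || length(x) != length(y)) {
    abort("need >= 2 points with equal-length x and y")
  }
  h <- rep(h, length.out = 2)
  if (is.null(lims)) lims <- c(range(x), range(y))
  gx <- seq(lims[1], lims[2], length.out = n)
  gy <- seq(lims[3], lims[4], length.out = n)
  sdx <- h[1] / 4
  sdy <- h[2] / 4
  # outer product of per-axis kernel matrices: z[i,j] = mean_k K(gx_i - x_k) K(gy_j - y_k)
  ax <- outer(gx, x, function(g, p) dnorm(g - p, sd = sdx))
  ay <- outer(gy, y, function(g, p) dnorm(g - p, sd = sdy))
  z <- (ax %*% t(ay)) / length(x)
  list(x = gx, y = gy, z = z)
}
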