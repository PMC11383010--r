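#' End-to-end enhancer-class discovery
#'
#' Runs the full discovery chain on fragment libraries over an annotated
#' region catalog: size-select/trim/deduplicate fragments, compute
#' oriented log2 RPKM/2 features (3 per mark), assemble the feature
#' matrix, run centered PCA, train the promoter-vs-enhancer SVM on
#' promoter and distal regions, classify all regions and flag mismatches,
#' compute IgG fold enrichments over center+downstream coverage, and call
#' the refined enhancer classes.
#'
#' @param libs Named list of mark `fragment_library` objects (raw; they
#'   are filtered here).
#' @param igg The IgG control `fragment_library`.
#' @param regions Annotated region tibble from [annotate_regions()]
#'   (rows with `retained == FALSE` are dropped).
#' @param params [pipeline_params()].
#' @return An `enhancer_discovery` list: `features`, `matrix`, `pca`,
#'   `classifier`, `calls` (per-region tibble joining annotation, SVM
#'   label, mismatch flag and refined class), `enrichment`.
#' @export
discover_enhancers <- function(libs, igg, regions,
                               params = pipeline_params()) {
  regions <- as_tibble(regions)
  if ("retained" %in% names(regions)) {
    regions <- filter(regions, .data$retained)
  }
  flibs <- purrr::map(libs, filter_fragments,
                      min_len = params$min_frag_len,
                      max_len = params$max_frag_len,
                      trim_to = params$trim_to)
  figg <- filter_fragments(igg, min_len = params$min_frag_len,
                           max_len = params$max_frag_len,
                           trim_to = params$trim_to)

  feats <- region_features(flibs, regions, flank = params$flank,
                           params = params)
  fm <- assemble_feature_matrix(feats)
  pca <- run_pca(fm, scale. = params$pca_scale)

  labels <- regions %>%
    filter(.data$anno_class %in% c("promoter", "distal")) %>%
    mutate(label = if_else(.data$anno_class == "promoter",
                           "promoter", "enhancer")) %>%
    select("region_id", "label")
  clf <- fit_region_classifier(pca, labels, n_pcs = params$n_pcs,
                               gamma = params$svm_gamma,
                               cost = params$svm_cost)
  flags <- classify_and_flag(clf, pca, regions)

  enrich <- region_enrichment(flibs, figg, regions, flank = params$flank,
                              pseudocount = params$fold_pseudocount,
                              params = params)
  refined <- refine_enhancer_classes(enrich, regions, params = params)

  calls <- flags %>%
    left_join(select(refined, "region_id", "refined", "k4me2_flag",
                     "k4me2_strict"),
              by = "region_id")

  structure(
    list(features = feats, matrix = fm, pca = pca, classifier = clf,
         calls = calls, enrichment = enrich, params = params),
    class = "enhancer_discovery"
  )
}

#' @export
print.enhancer_discovery <- function(x, ...) {
  cat(sprintf("<enhancer_discovery> %d regions, %d marks\n",
              nrow(x$matrix), (ncol(x$matrix) - 1) / 3))
  print(table(x$calls$refined))
  invisible(x)
}
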