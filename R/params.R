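#' Pipeline parameters
#'
#' Collects every numeric threshold used across the pipeline into one
#' validated object, so an analysis is reproducible from a single config.
#' Defaults are the values used throughout the package: mononucleosome
#' fragment bounds (140--250 bp, inclusive), the 73-bp tag-centered trim,
#' 500-bp region flanks, the 2-kb TSS-proximal cut, the >20 CAGE-tag TSS
#' support threshold, log2 RPKM/2 normalization with pseudocount 1,
#' fold-enrichment pseudocount 0.1 (0.01 in log2 mode), refined class
#' thresholds (H3K4me1 >= 2, H3K27ac >= 1.5, H3K4me2 >= 2 vs < 1.25,
#' poised H3K27ac <= 1.5, proximal H3K4me3 < 1.25, strict H3K4me2 > 3),
#' directional-transcription rule (>= 1 RPKM, >= 2-fold, >= 2 samples,
#' 100-bp windows), methylation depth >= 10 with 20%/80% strata bounds,
#' and the reference-point matrix geometry (span 2500 bp, 25-bp bins).
#'
#' @param ... Named overrides for any default listed above.
#'
#' @return A `pipeline_params` object (a validated named list).
#' @examples
#' p <- pipeline_params()
#' p$min_frag_len
#' pipeline_params(proximal_cut = 1000)$proximal_cut
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    # fragment processing
    min_frag_len    = 140,
    max_frag_len    = 250,
    trim_to         = 73,
    # region geometry
    flank           = 500,
    proximal_cut    = 2000,
    min_cage_tags   = 20,
    # normalization
    norm_unit       = 500,   # RPKM/2: per 500 bp rather than per 1 kb
    norm_pseudocount = 1,
    # fold enrichment
    fold_pseudocount      = 0.1,
    fold_pseudocount_log2 = 0.01,
    # refined class thresholds
    min_k4me1_fold  = 2,
    min_k27ac_fold  = 1.5,
    min_k4me2_fold  = 2,
    max_k4me2_fold_me1 = 1.25,
    max_k27ac_fold_poised = 1.5,
    max_k4me3_fold_proximal = 1.25,
    strict_k4me2_fold = 3,
    # heatmap pre-filter
    prefilter_min_fold = 2,
    prefilter_min_rpkm = 10,
    # directional transcription
    rna_window      = 100,
    rna_min_rpkm    = 1,
    rna_min_fold    = 2,
    rna_min_samples = 2,
    # methylation
    meth_window     = 200,
    meth_min_depth  = 10,
    meth_low_cut    = 0.20,
    meth_high_cut   = 0.80,
    # motif / sequence
    motif_half_window = 100,
    cpg_window      = 500,
    pwm_threshold_frac = 0.6,
    # coverage matrices
    matrix_span     = 2500,
    matrix_bin      = 25,
    scale_zmin_bins = 20,
    scale_zmax_bins = 8,
    scale_zmax_quantile = 0.9,
    # classifier
    svm_gamma       = 1,
    svm_cost        = 1,
    n_pcs           = 3,
    pca_scale       = FALSE,
    # KDE
    kde_h           = 3,
    kde_n           = 125,
    # downstream
    mz_rpkm_cut     = 0.5,
    trajectory_pseudocount = 0.1,
    ci_level        = 0.95
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0("unknown pipeline parameter(s): ",
                   paste(bad, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  p <- defaults
  stopifnot(
    p$trim_to <= p$min_frag_len,
    p$min_frag_len <= p$max_frag_len,
    p$flank > 0, p$proximal_cut > 0,
    p$meth_low_cut < p$meth_high_cut,
    p$matrix_span %% p$matrix_bin == 0
  )
  structure(p, class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params> with", length(x), "settings\n")
  nm <- names(x)
  for (i in seq_along(x)) cat(sprintf("  %-24s %s\n", nm[i], format(x[[i]])))
  invisible(x)
}
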