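#' Distance from each enhancer to the nearest TSS of a gene group
#'
#' Edge-to-point distance (0 when the TSS lies inside the region) from
#' each enhancer to the nearest selected TSS of genes in the requested
#' group. Enhancers on unassembled scaffolds should be excluded by the
#' caller (pass `assembled_chroms` to do it here); enhancers on
#' chromosomes carrying no group genes get `NA`.
#'
#' @param enhancers Region tibble (`region_id`, `chrom`, `start`, `end`).
#' @param genes Tibble with `gene_id`, `chrom`, `tss` (0-based position)
#'   and `nps_class` (e.g. `"down"` / `"unaffected"`).
#' @param group Which `nps_class` to measure against (NULL = all genes).
#' @param assembled_chroms Optional character vector; enhancers on other
#'   chromosomes are dropped.
#' @return Tibble `region_id`, `distance` (bp).
#' @export
nearest_gene_distance <- function(enhancers, genes, group = NULL,
                                  assembled_chroms = NULL) {
  enhancers <- as_tibble(enhancers)
  genes <- as_tibble(genes)
  if (!is.null(assembled_chroms)) {
    enhancers <- filter(enhancers, .data$chrom %in% .env$assembled_chroms)
  }
  if (!is.null(group)) genes <- filter(genes, .data$nps_class == .env$group)
  d <- min_distance_to_points(enhancers,
                              tibble(chrom = genes$chrom, pos = genes$tss))
  tibble(region_id = enhancers$region_id, distance = d)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test: exact enumeration when the pooled sample is
#' small (`n + m <= exact_max`, default 12) and tie-free, otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Largest pooled size for the exact test (default 12).
#' @return One-row tibble: `statistic` (Mann-Whitney U of `x`),
#'   `p_value`, `method`.
#' @examples
#' two_sample_rank_test(c(1, 2), c(3, 4))$p_value  # 1/3 exactly
#' @export
two_sample_rank_test <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    # degenerate all-tied input: no evidence against the null
    return(tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                  method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = use_exact, correct = !use_exact)
  )
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (use_exact) "exact" else "normal_approx")
}

#' Kruskal-Wallis rank test across groups
#'
#' Multi-group rank comparison (chi-squared approximation), used for the
#' per-mark coverage comparisons across the four mismatch groups.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor/vector of the same length.
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
rank_test_groups <- function(values, groups) {
  kt <- stats::kruskal.test(values, factor(groups))
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Chi-squared test of motif-count bins across enhancer classes
#'
#' Pearson chi-squared test (no continuity correction) on a 2 x 3
#' contingency table of region counts: two enhancer classes by binned
#' motif hits `{0, 1, >= 2}` (2 degrees of freedom).
#'
#' @param counts Either a 2 x 3 matrix of counts, or a tibble with
#'   `class` (two levels) and `hits` per region, which is binned here.
#' @return One-row tibble `statistic`, `df`, `p_value` plus the table as
#'   an attribute `"table"`.
#' @export
motif_class_chisq <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- as_tibble(counts)
    bins <- cut(counts$hits, breaks = c(-Inf, 0, 1, Inf),
                labels = c("0", "1", ">=2"))
    counts <- as.matrix(table(counts$class, bins))
  }
  if (!all(dim(counts) == c(2, 3))) abort("need a 2 x 3 contingency table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("contingency table has a zero marginal")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  out <- tibble(statistic = unname(ct$statistic),
                df = unname(ct$parameter), p_value = ct$p.value)
  attr(out, "table") <- counts
  out
}

#' Expression trajectories with t-based confidence intervals
#'
#' Per gene, the log2 fold change at each time point relative to time 0
#' with a pseudocount: `lfc_t = log2(e_t + pc) - log2(e_0 + pc)`. Per
#' time point, the mean across genes and the
#' `mean +/- qt(0.975, n - 1) * sd / sqrt(n)` confidence interval.
#'
#' @param tc Tidy time-course tibble: `gene_id`, `time`, `expression`
#'   (>= 0; time 0 must be present for every gene).
#' @param genes Optional subset of gene ids.
#' @param pseudocount Added before log2 (default 0.1).
#' @param level Confidence level (default 0.95).
#' @return A tibble `time`, `mean_lfc`, `lo`, `hi`, `n` of class
#'   `enhancer_trajectory`.
#' @export
trajectory_with_ci <- function(tc, genes = NULL, pseudocount = 0.1,
                               level = 0.95) {
  tc <- as_tibble(tc)
  if (!is.null(genes)) tc <- filter(tc, .data$gene_id %in% .env$genes)
  if (any(tc$expression < 0)) abort("expression must be >= 0")
  base <- tc %>% filter(.data$time == 0) %>%
    select("gene_id", e0 = "expression")
  if (length(unique(tc$gene_id)) < 2) abort("need >= 2 genes")
  if (nrow(base) < length(unique(tc$gene_id))) {
    abort("every gene needs a time-0 value")
  }
  out <- tc %>%
    inner_join(base, by = "gene_id") %>%
    mutate(lfc = log2(.data$expression + .env$pseudocount) -
             log2(.data$e0 + .env$pseudocount)) %>%
    group_by(.data$time) %>%
    summarise(
      mean_lfc = mean(.data$lfc),
      n = dplyr::n(),
      se = sd(.data$lfc) / sqrt(dplyr::n())
    ) %>%
    mutate(
      tq = qt(1 - (1 - .env$level) / 2, .data$n - 1),
      lo = .data$mean_lfc - .data$tq * .data$se,
      hi = .data$mean_lfc + .data$tq * .data$se
    ) %>%
    select("time", "mean_lfc", "lo", "hi", "n")
  class(out) <- c("enhancer_trajectory", class(out))
  out
}

#' Maternal-zygotic versus strictly zygotic genes
#'
#' Genes with pooled 2-cell expression strictly above `cut` RPKM are
#' maternal-zygotic; the rest are strictly zygotic.
#'
#' @param two_cell_rpkm Named (or plain) numeric vector of 2-cell RPKM.
#' @param cut Threshold (default 0.5; strict `>`).
#' @return Character vector `"maternal_zygotic"` / `"strictly_zygotic"`.
#' @examples
#' classify_maternal_zygotic(c(0, 0.5, 0.51))
#' @export
classify_maternal_zygotic <- function(two_cell_rpkm, cut = 0.5) {
  if (any(two_cell_rpkm < 0)) abort("expression must be >= 0")
  out <- if_else(two_cell_rpkm > cut, "maternal_zygotic", "strictly_zygotic")
  names(out) <- names(two_cell_rpkm)
  out
}

#' Crispant qRT-PCR effect from delta-Ct values
#'
#' Technical replicate Ct values are averaged per (embryo, gene); per
#' embryo `dCt = mean Ct_target - mean Ct_reference`, converted to
#' `v = 2^-dCt`, then normalized by the control-embryo average so the
#' control group mean is exactly 1. The fold decrease is the ratio of
#' control to crispant group means of the normalized values
#' (`1 / mean(v' crispant)`), and the p-value is a two-sided rank-sum
#' test on the normalized values.
#'
#' @param plate Tidy Ct table: `embryo_id`, `group`
#'   (`"control"`/`"crispant"`), `gene` (`"target"`/`"reference"`), `ct`
#'   (one row per technical replicate; 3 per (embryo, gene) expected).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` group mean
#'   for the fold change.
#' @return A `qpcr_effect` object: `embryos` (per-embryo tibble with
#'   `delta_ct`, `v`, `v_norm`), `fold_change` (control/crispant),
#'   `p_value`.
#' @export
qpcr_effect <- function(plate, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  plate <- as_tibble(plate)
  if (any(plate$ct <= 0 | plate$ct > 40)) abort("Ct values must be in (0, 40]")
  reps <- plate %>% dplyr::count(.data$embryo_id, .data$gene)
  if (length(unique(reps$n)) > 1) {
    short <- reps$embryo_id[reps$n < max(reps$n)]
    abort(paste0("uneven technical replicates; embryo(s): ",
                 paste(unique(short), collapse = ", ")))
  }
  per_gene <- plate %>%
    group_by(.data$embryo_id, .data$group, .data$gene) %>%
    summarise(ct = mean(.data$ct), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  if (!all(c("target", "reference") %in% names(per_gene)) ||
      anyNA(per_gene$target) || anyNA(per_gene$reference)) {
    bad <- per_gene$embryo_id[is.na(per_gene$target) | is.na(per_gene$reference)]
    abort(paste0("embryo(s) missing target or reference Ct: ",
                 paste(bad, collapse = ", ")))
  }
  embryos <- per_gene %>%
    mutate(delta_ct = .data$target - .data$reference,
           v = 2^(-.data$delta_ct))
  ctrl <- embryos$v[embryos$group == "control"]
  if (!length(ctrl)) abort("no control embryos")
  embryos <- mutate(embryos, v_norm = .data$v / mean(ctrl))
  gm <- function(z) if (mean_type == "geometric") exp(mean(log(z))) else mean(z)
  vc <- embryos$v_norm[embryos$group == "control"]
  vx <- embryos$v_norm[embryos$group == "crispant"]
  fold <- if (length(vx)) gm(vc) / gm(vx) else NA_real_
  p <- if (length(vx)) two_sample_rank_test(vc, vx)$p_value else NA_real_
  structure(list(embryos = embryos, fold_change = fold, p_value = p,
                 n_control = length(vc), n_crispant = length(vx)),
            class = "qpcr_effect")
}

#' @export
print.qpcr_effect <- function(x, ...) {
  cat(sprintf(
    "<qpcr_effect> %d control vs %d crispant embryos: fold decrease %.3g (rank-sum p = %.3g)\n",
    x$n_control, x$n_crispant, x$fold_change, x$p_value))
  invisible(x)
}
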