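#' Merge accessible regions from two ATAC-seq peak sources
#'
#' Builds the accessible-region catalog: every peak from the primary source
#' is kept and numbered `atac_L#####` in genomic sort order; peaks from the
#' secondary source that do not overlap any primary peak (by even a single
#' bp) are appended as `atac_P#####`. A secondary peak overlapping a primary
#' peak by >= 1 bp is dropped.
#'
#' @param primary_peaks,secondary_peaks Data frames with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return A tibble with `region_id`, `chrom`, `start`, `end`, `source`
#'   (`"primary"`/`"secondary"`).
#' @examples
#' p <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' s <- tibble::tibble(chrom = "chr1", start = c(150, 300), end = c(250, 400))
#' union_atac_regions(p, s)  # secondary 150-250 dropped, 300-400 kept
#' @export
union_atac_regions <- function(primary_peaks, secondary_peaks) {
  primary_peaks <- check_intervals(as_tibble(primary_peaks), "primary_peaks")
  secondary_peaks <- check_intervals(as_tibble(secondary_peaks), "secondary_peaks")

  prim <- primary_peaks %>%
    arrange(.data$chrom, .data$start, .data$end) %>%
    mutate(region_id = sprintf("atac_L%05d", row_number()),
           source = "primary")

  sec <- secondary_peaks %>%
    arrange(.data$chrom, .data$start, .data$end)
  if (nrow(sec) > 0 && nrow(prim) > 0) {
    sec <- sec[!overlaps_any0(sec, prim), , drop = FALSE]
  }
  sec <- sec %>%
    mutate(region_id = sprintf("atac_P%05d", row_number()),
           source = "secondary")

  bind_rows(prim, sec) %>%
    select("region_id", "chrom", "start", "end", "source")
}

#' Select one TSS per gene by CAGE support
#'
#' For each gene, selects the isoform TSS with the maximal CAGE tag count,
#' provided that count strictly exceeds `min_tags`; ties are broken by the
#' smallest coordinate. Genes with no qualifying TSS fall back to a
#' supplemental annotation if one is provided, otherwise they are omitted
#' from the selected set (their isoform TSSs still count for proximity
#' annotation).
#'
#' @param cage_counts Data frame with columns `gene_id`, `chrom`, `pos`
#'   (0-based TSS position), `strand`, `tags` (CAGE tag count).
#' @param min_tags Strict lower bound on tag support (default 20).
#' @param supplemental Optional data frame (`gene_id`, `chrom`, `pos`,
#'   `strand`) of fallback TSS positions for genes without CAGE support.
#' @return A tibble of all isoform TSS rows with a logical `selected`
#'   column marking the chosen TSS per gene (at most one per gene).
#' @export
select_gene_tss <- function(cage_counts, min_tags = 20, supplemental = NULL) {
  cage_counts <- as_tibble(cage_counts)
  need <- c("gene_id", "chrom", "pos", "strand", "tags")
  miss <- setdiff(need, names(cage_counts))
  if (length(miss)) abort(paste0("cage_counts missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(cage_counts$tags < 0)) abort("tag counts must be >= 0")
  strands <- cage_counts %>%
    distinct(.data$gene_id, .data$strand) %>%
    dplyr::count(.data$gene_id)
  if (any(strands$n > 1)) {
    abort(paste0("gene(s) with conflicting strands: ",
                 paste(head(strands$gene_id[strands$n > 1], 5), collapse = ", ")))
  }

  tss <- cage_counts %>%
    group_by(.data$gene_id) %>%
    arrange(desc(.data$tags), .data$pos, .by_group = TRUE) %>%
    mutate(selected = row_number() == 1L & .data$tags > .env$min_tags) %>%
    ungroup() %>%
    mutate(tss_source = "cage")

  if (!is.null(supplemental)) {
    supplemental <- as_tibble(supplemental)
    no_sel <- tss %>% group_by(.data$gene_id) %>%
      summarise(has = any(.data$selected)) %>% filter(!.data$has)
    fallback <- supplemental %>%
      filter(.data$gene_id %in% no_sel$gene_id |
               !(.data$gene_id %in% tss$gene_id)) %>%
      group_by(.data$gene_id) %>% slice(1) %>% ungroup() %>%
      mutate(tags = NA_real_, selected = TRUE, tss_source = "supplemental")
    tss <- bind_rows(tss, fallback)
  }
  arrange(tss, .data$gene_id, .data$pos)
}

#' Annotate accessible regions as promoter, TSS-proximal, or distal
#'
#' A region containing a selected TSS is a promoter; otherwise a region
#' whose edge lies < `proximal_cut` bp from any isoform TSS is
#' TSS-proximal; regions >= `proximal_cut` bp from every isoform TSS are
#' distal elements (putative enhancers). Regions lacking a complete
#' `flank` on either side (chromosome edge) are flagged `edge_discarded`;
#' regions on chromosomes bearing no genes are flagged `no_gene_scaffold`;
#' both are excluded (`anno_class` NA, `retained` FALSE).
#'
#' @param regions Tibble from [union_atac_regions()] (needs `region_id`,
#'   `chrom`, `start`, `end`).
#' @param tss Tibble from [select_gene_tss()]: all isoform TSS rows with a
#'   `selected` flag.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param flank Required complete flank on both sides in bp (default 500).
#' @param proximal_cut Distal threshold in bp (default 2000; distance
#'   at or above the cut means distal).
#' @return The input with `anno_class` (`promoter`/`proximal`/`distal` or
#'   NA), `edge_discarded`, `no_gene_scaffold`, `retained` columns.
#' @export
annotate_regions <- function(regions, tss, chrom_sizes,
                             flank = 500, proximal_cut = 2000) {
  regions <- check_intervals(as_tibble(regions), "regions")
  tss <- as_tibble(tss)
  unknown <- setdiff(unique(regions$chrom), names(chrom_sizes))
  if (length(unknown)) {
    abort(paste0("region(s) on unknown chromosome(s): ",
                 paste(unknown, collapse = ", ")))
  }

  gene_chroms <- unique(tss$chrom)
  sel <- tss %>% filter(.data$selected)

  # promoter: region strictly contains a selected TSS coordinate
  contains_sel <- logical(nrow(regions))
  if (nrow(sel) > 0) {
    sel_by_chrom <- split(sel$pos, sel$chrom)
    contains_sel <- purrr::pmap_lgl(
      list(regions$chrom, regions$start, regions$end),
      function(chrom, start, end) {
        pts <- sel_by_chrom[[chrom]]
        !is.null(pts) && any(pts >= start & pts < end)
      }
    )
  }

  dmin <- min_distance_to_points(regions,
                                 tibble(chrom = tss$chrom, pos = tss$pos))

  out <- regions %>%
    mutate(
      edge_discarded = .data$start < .env$flank |
        .data$end + .env$flank > unname(.env$chrom_sizes[.data$chrom]),
      no_gene_scaffold = !(.data$chrom %in% .env$gene_chroms),
      anno_class = case_when(
        edge_discarded | no_gene_scaffold ~ NA_character_,
        contains_sel ~ "promoter",
        !is.na(dmin) & dmin < .env$proximal_cut ~ "proximal",
        TRUE ~ "distal"
      ),
      retained = !.data$edge_discarded & !.data$no_gene_scaffold
    )
  out
}
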