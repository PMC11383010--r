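#' Construct a CUT&RUN fragment library
#'
#' @param fragments Data frame of fragment intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param mark Histone-mark (or control) name, e.g. `"H3K4me1"`, `"IgG"`.
#' @param total_mapped Total mapped fragment count for RPKM normalization;
#'   defaults to `nrow(fragments)`.
#' @param yeast_pairs Unique yeast spike-in read-pair count (NA if the
#'   library has no spike-in).
#' @return A `fragment_library` object.
#' @export
fragment_library <- function(fragments, mark,
                             total_mapped = nrow(fragments),
                             yeast_pairs = NA_real_) {
  fragments <- check_intervals(as_tibble(fragments), "fragments")
  if (total_mapped < nrow(fragments)) {
    abort("total_mapped must be >= the number of fragments")
  }
  if (!is.na(yeast_pairs) && yeast_pairs < 0) abort("yeast_pairs must be >= 0")
  structure(
    list(mark = mark, fragments = fragments,
         total_mapped = total_mapped, yeast_pairs = yeast_pairs),
    class = "fragment_library"
  )
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library> %s: %d fragments (total_mapped %s, yeast_pairs %s)\n",
              x$mark, nrow(x$fragments), format(x$total_mapped),
              format(x$yeast_pairs)))
  invisible(x)
}

#' Pool replicate libraries for one mark
#'
#' Replicates are pooled by fragment concatenation before any counting;
#' total mapped counts and spike-in pairs are summed.
#'
#' @param libs List of `fragment_library` objects sharing one mark.
#' @return A single pooled `fragment_library`.
#' @export
pool_libraries <- function(libs) {
  marks <- unique(purrr::map_chr(libs, "mark"))
  if (length(marks) != 1) abort("all libraries must share one mark")
  yp <- purrr::map_dbl(libs, "yeast_pairs")
  fragment_library(
    bind_rows(purrr::map(libs, "fragments")),
    mark = marks,
    total_mapped = sum(purrr::map_dbl(libs, "total_mapped")),
    yeast_pairs = if (all(is.na(yp))) NA_real_ else sum(yp, na.rm = TRUE)
  )
}

#' Size-select, trim and deduplicate CUT&RUN fragments
#'
#' Keeps mononucleosome-sized fragments (length in `[min_len, max_len]`,
#' inclusive at both ends), replaces each with a `trim_to`-bp interval
#' centered on the fragment midpoint base
#' (`center = floor((start + end - 1) / 2)`, trimmed interval
#' `[center - 36, center + 37)` for the 73-bp default), then removes exact
#' duplicate (chrom, start, end) intervals keeping one.
#'
#' @param lib A `fragment_library`.
#' @param min_len,max_len Inclusive fragment-length bounds in bp
#'   (defaults 140 and 250).
#' @param trim_to Trimmed tag width in bp (default 73; must be <= min_len).
#' @return A `fragment_library` with filtered, trimmed, deduplicated
#'   fragments; `total_mapped` and `yeast_pairs` carried over.
#' @examples
#' lib <- fragment_library(
#'   tibble::tibble(chrom = "chr1", start = 1000, end = 1146), "H3K4me1")
#' filter_fragments(lib)$fragments  # chr1:1036-1109
#' @export
filter_fragments <- function(lib, min_len = 140, max_len = 250, trim_to = 73) {
  if (trim_to > min_len) abort("trim_to must be <= min_len")
  fr <- lib$fragments
  len <- fr$end - fr$start
  fr <- fr[len >= min_len & len <= max_len, , drop = FALSE]
  center <- floor((fr$start + fr$end - 1) / 2)
  half <- trim_to %/% 2
  fr <- tibble(chrom = fr$chrom,
               start = center - half,
               end = center - half + trim_to) %>%
    distinct(.data$chrom, .data$start, .data$end)
  fragment_library(fr, lib$mark, total_mapped = max(lib$total_mapped, nrow(fr)),
                   yeast_pairs = lib$yeast_pairs)
}

#' Yeast spike-in scale factor
#'
#' Coverage tracks are scaled by `1e6 / yeast_pairs` when spike-in
#' normalization is enabled.
#'
#' @param lib A `fragment_library` with a positive `yeast_pairs` count.
#' @return The multiplicative scale factor.
#' @examples
#' lib <- fragment_library(tibble::tibble(chrom = "chr1", start = 0, end = 100),
#'                         "H3K4me1", yeast_pairs = 5e5)
#' spike_scale_factor(lib)  # 2
#' @export
spike_scale_factor <- function(lib) {
  yp <- lib$yeast_pairs
  if (is.na(yp) || yp == 0) {
    abort("library has no yeast spike-in pairs; run without spike normalization")
  }
  1e6 / yp
}

#' Count fragments in region flanks and centers
#'
#' For each region, counts fragments overlapping (by >= 1 bp) the
#' upstream flank `[start - flank, start)`, the open interval
#' `[start, end)`, and the downstream flank `[end, end + flank)`. A
#' fragment straddling a boundary counts in every interval it touches.
#'
#' @param lib A `fragment_library` (typically after [filter_fragments()]).
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`.
#' @param flank Flank width in bp (default 500).
#' @return A tibble `region_id`, `count_u`, `count_c`, `count_d`.
#' @export
region_counts <- function(lib, regions, flank = 500) {
  regions <- check_intervals(as_tibble(regions), "regions")
  fr <- lib$fragments
  count_in <- function(start, end) {
    iv <- tibble(chrom = regions$chrom, start = start, end = end)
    if (nrow(fr) == 0) return(rep(0L, nrow(regions)))
    count_overlaps0(iv, fr)
  }
  tibble(
    region_id = regions$region_id,
    count_u = count_in(regions$start - flank, regions$start),
    count_c = count_in(regions$start, regions$end),
    count_d = count_in(regions$end, regions$end + flank)
  )
}

#' Length- and depth-normalized log2 coverage
#'
#' `log2(counts / (interval_len / unit) / (total_mapped / 1e6) + pseudocount)`.
#' With the defaults (`unit = 500`, pseudocount 1) this is the log2
#' "RPKM/2" used for the feature matrix: reads per 500 bp per million
#' mapped, so zero counts map to exactly 0 and values are never negative.
#'
#' @param counts Fragment counts (vectorized).
#' @param interval_len Interval length(s) in bp.
#' @param total_mapped Total mapped fragments in the library.
#' @param unit Length unit in bp (500 for RPKM/2; 1000 for standard RPKM).
#' @param pseudocount Added inside the log (default 1).
#' @return log2-normalized coverage values.
#' @examples
#' normalize_features(1, 500, 1e6)  # exactly 1
#' normalize_features(0, 500, 1e6)  # exactly 0
#' @export
normalize_features <- function(counts, interval_len, total_mapped,
                               unit = 500, pseudocount = 1) {
  if (any(interval_len <= 0)) abort("interval_len must be > 0")
  if (any(total_mapped <= 0)) abort("total_mapped must be > 0")
  log2(counts / (interval_len / unit) / (total_mapped / 1e6) + pseudocount)
}

# Linear-scale RPKM/2 (no log, no pseudocount); used for orientation sums
# and region-level enrichment ratios.
rpkm_linear <- function(counts, interval_len, total_mapped, unit = 500) {
  counts / (interval_len / unit) / (total_mapped / 1e6)
}

#' Per-region oriented coverage features across marks
#'
#' Computes upstream/center/downstream counts per mark, normalizes them to
#' log2 RPKM/2 (pseudocount 1), and orients each region so that
#' "downstream" is the flank with the higher total coverage summed over
#' all marks. The flank sum is taken on linear RPKM (pre-log); a tie
#' leaves the region as-is.
#'
#' @param libs Named list of `fragment_library` objects, one per mark
#'   (pool replicates first with [pool_libraries()]).
#' @param regions Annotated region tibble (retained regions only is
#'   typical).
#' @param flank Flank width in bp (default 500).
#' @param orient Apply flank orientation (default TRUE).
#' @param params A [pipeline_params()] object for normalization settings.
#' @return A long tibble: `region_id`, `mark`, `u`, `c`, `d`
#'   (log2-normalized, oriented), `u_rpkm`, `d_rpkm` (linear, oriented)
#'   and `orientation` (`asis`/`flipped`).
#' @export
region_features <- function(libs, regions, flank = 500, orient = TRUE,
                            params = pipeline_params()) {
  regions <- as_tibble(regions)
  marks <- purrr::map_chr(libs, "mark")
  names(libs) <- marks
  len_u <- rep(flank, nrow(regions))
  len_c <- regions$end - regions$start
  len_d <- rep(flank, nrow(regions))

  feats <- purrr::map2_dfr(libs, marks, function(lib, mark) {
    cts <- region_counts(lib, regions, flank = flank)
    tibble(
      region_id = cts$region_id,
      mark = mark,
      u = normalize_features(cts$count_u, len_u, lib$total_mapped,
                             unit = params$norm_unit,
                             pseudocount = params$norm_pseudocount),
      c = normalize_features(cts$count_c, len_c, lib$total_mapped,
                             unit = params$norm_unit,
                             pseudocount = params$norm_pseudocount),
      d = normalize_features(cts$count_d, len_d, lib$total_mapped,
                             unit = params$norm_unit,
                             pseudocount = params$norm_pseudocount),
      u_rpkm = rpkm_linear(cts$count_u, len_u, lib$total_mapped,
                           unit = params$norm_unit),
      d_rpkm = rpkm_linear(cts$count_d, len_d, lib$total_mapped,
                           unit = params$norm_unit)
    )
  })
  if (orient) orient_features(feats) else mutate(feats, orientation = "asis")
}

#' Orient features so "downstream" is the higher-coverage flank
#'
#' For each region, sums linear-RPKM flank coverage over all marks; if the
#' upstream sum exceeds the downstream sum, upstream and downstream values
#' are swapped for every mark and the region is marked `flipped`. Ties
#' (including all-zero regions) stay `asis`. Applying the operation twice
#' leaves labels unchanged.
#'
#' @param feats Long feature tibble from [region_features()] (columns
#'   `region_id`, `mark`, `u`, `c`, `d`, `u_rpkm`, `d_rpkm`).
#' @return The tibble with flanks swapped where needed and an
#'   `orientation` column.
#' @export
orient_features <- function(feats) {
  flip_tbl <- feats %>%
    group_by(.data$region_id) %>%
    summarise(flip = sum(.data$u_rpkm) > sum(.data$d_rpkm))
  feats %>%
    left_join(flip_tbl, by = "region_id") %>%
    mutate(
      u_new = if_else(.data$flip, .data$d, .data$u),
      d_new = if_else(.data$flip, .data$u, .data$d),
      u_rpkm_new = if_else(.data$flip, .data$d_rpkm, .data$u_rpkm),
      d_rpkm_new = if_else(.data$flip, .data$u_rpkm, .data$d_rpkm),
      orientation = if_else(.data$flip, "flipped", "asis")
    ) %>%
    mutate(u = .data$u_new, d = .data$d_new,
           u_rpkm = .data$u_rpkm_new, d_rpkm = .data$d_rpkm_new) %>%
    select(-"flip", -"u_new", -"d_new", -"u_rpkm_new", -"d_rpkm_new")
}

#' Fold enrichment over the IgG control
#'
#' `(mark + pseudocount) / (igg + pseudocount)`, with the convention that
#' an exactly zero/zero pair yields 1 (no evidence either way). In log2
#' mode returns `log2` of the ratio with the smaller pseudocount 0.01.
#'
#' @param mark_val,igg_val Non-negative normalized coverage values
#'   (vectorized).
#' @param pseudocount Ratio pseudocount (default 0.1).
#' @param log2 Return log2 ratio with pseudocount `log2_pseudocount`.
#' @param log2_pseudocount Pseudocount for log2 mode (default 0.01).
#' @return Fold-enrichment ratios (or log2 ratios).
#' @examples
#' fold_enrichment(1.9, 0.9)   # 2
#' fold_enrichment(0, 0)       # 1
#' @export
fold_enrichment <- function(mark_val, igg_val, pseudocount = 0.1,
                            log2 = FALSE, log2_pseudocount = 0.01) {
  if (any(mark_val < 0) || any(igg_val < 0)) abort("coverage must be >= 0")
  pc <- if (log2) log2_pseudocount else pseudocount
  r <- (mark_val + pc) / (igg_val + pc)
  r[mark_val == 0 & igg_val == 0] <- 1
  if (log2) base::log2(r) else r
}

#' Region-level enrichment profile over IgG
#'
#' For each region and mark, the mean linear RPKM/2 coverage over the
#' combined center + downstream-flank interval, and its pseudocount ratio
#' against the IgG control, as used for the refined enhancer class calls
#' and the heatmap pre-filter.
#'
#' @param libs Named list of mark `fragment_library` objects.
#' @param igg The IgG control `fragment_library`.
#' @param regions Region tibble.
#' @param flank Flank width in bp (default 500).
#' @param pseudocount Ratio pseudocount (default 0.1).
#' @param params [pipeline_params()] for the normalization unit.
#' @return Tibble `region_id`, `mark`, `rpkm_cd` (mark coverage),
#'   `fold_igg`.
#' @export
region_enrichment <- function(libs, igg, regions, flank = 500,
                              pseudocount = 0.1,
                              params = pipeline_params()) {
  regions <- as_tibble(regions)
  len_cd <- regions$end - regions$start + flank
  cd <- tibble(region_id = regions$region_id, chrom = regions$chrom,
               start = regions$start, end = regions$end + flank)
  igg_counts <- region_counts(igg, cd, flank = flank)
  igg_rpkm <- rpkm_linear(igg_counts$count_c, len_cd, igg$total_mapped,
                          unit = params$norm_unit)
  purrr::map_dfr(libs, function(lib) {
    cts <- region_counts(lib, cd, flank = flank)
    rp <- rpkm_linear(cts$count_c, len_cd, lib$total_mapped,
                      unit = params$norm_unit)
    tibble(region_id = cd$region_id, mark = lib$mark, rpkm_cd = rp,
           fold_igg = fold_enrichment(rp, igg_rpkm, pseudocount = pseudocount))
  })
}

#' Reference-point coverage matrix
#'
#' Bins normalized per-bp coverage around region midpoints: rows are
#' regions, columns are `2 * span / bin` bins of mean coverage, with
#' missing data (off-chromosome or uncovered) as 0. Rows can be sorted by
#' descending signal of a chosen mark via `sort_order`.
#'
#' @param lib A `fragment_library`; per-bp coverage is its fragment pileup
#'   multiplied by `scale_factor`.
#' @param regions Region tibble (`region_id`, `chrom`, `start`, `end`).
#' @param span Half-window around the midpoint in bp (default 2500).
#' @param bin Bin width in bp (default 25; must divide `span`).
#' @param scale_factor Multiplicative track scaling (e.g. the spike-in
#'   factor from [spike_scale_factor()]); default 1.
#' @param sort_order Optional numeric vector (one per region); rows are
#'   ordered by decreasing value.
#' @return A `coverage_matrix`: a numeric matrix with region-id rownames
#'   plus `span`/`bin` attributes.
#' @export
coverage_matrix <- function(lib, regions, span = 2500, bin = 25,
                            scale_factor = 1, sort_order = NULL) {
  if (span %% bin != 0) abort("bin must divide span")
  regions <- as_tibble(regions)
  nbins <- as.integer(2 * span / bin)
  cov <- GenomicRanges::coverage(as_granges0(lib$fragments))
  mids <- floor((regions$start + regions$end) / 2)
  m <- matrix(0, nrow = nrow(regions), ncol = nbins,
              dimnames = list(regions$region_id, NULL))
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    lo <- mids[i] - span       # 0-based
    hi <- mids[i] + span
    vals <- numeric(2 * span)
    if (chrom %in% names(cov)) {
      rl <- cov[[chrom]]
      clen <- length(rl)
      from <- max(lo, 0)
      to <- min(hi, clen)
      if (to > from) {
        vals[(from - lo + 1):(to - lo)] <-
          as.numeric(S4Vectors::window(rl, start = from + 1, end = to))
      }
    }
    m[i, ] <- colMeans(matrix(vals, nrow = bin)) * scale_factor
  }
  if (!is.null(sort_order)) m <- m[order(sort_order, decreasing = TRUE), , drop = FALSE]
  structure(m, span = span, bin = bin, class = c("coverage_matrix", "matrix", "array"))
}

#' Adaptive heatmap color scale
#'
#' `zmin` is the mean signal over all rows in the leftmost
#' `n_upstream_bins` bins; `zmax` is the `q` quantile (linear-interpolation
#' definition) of the signal in the `n_center_bins` central bins. If the
#' data are so flat that `zmax < zmin`, `zmax` is clamped to `zmin`.
#'
#' @param mat A `coverage_matrix` (or any numeric matrix with >= 28 bins).
#' @param n_upstream_bins Leftmost bins for `zmin` (default 20).
#' @param n_center_bins Central bins for `zmax` (default 8).
#' @param q Quantile for `zmax` (default 0.9).
#' @return Named numeric vector `c(zmin, zmax)`.
#' @export
adaptive_scale <- function(mat, n_upstream_bins = 20, n_center_bins = 8,
                           q = 0.9) {
  if (!length(mat) || nrow(mat) == 0) abort("empty matrix")
  nb <- ncol(mat)
  if (nb < 28) abort("need at least 28 bins")
  zmin <- mean(mat[, seq_len(n_upstream_bins), drop = FALSE])
  ctr <- (nb / 2 - n_center_bins / 2 + 1):(nb / 2 + n_center_bins / 2)
  zmax <- unname(quantile(as.numeric(mat[, ctr, drop = FALSE]), q, type = 7))
  if (zmax < zmin) zmax <- zmin
  c(zmin = zmin, zmax = zmax)
}
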