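# Mean per-bp coverage of bedGraph-style intervals over query windows.
# cov: tibble (chrom, start, end, value); windows: tibble (chrom, start, end).
# Uncovered bp contribute 0; windows are averaged over their full width.
window_mean_cov <- function(cov, windows) {
  out <- numeric(nrow(windows))
  if (nrow(cov) == 0 || nrow(windows) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges0(windows), as_granges0(cov))
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(windows$end[qi], cov$end[si]) - pmax(windows$start[qi], cov$start[si])
    contrib <- tapply(ov * cov$value[si], qi, sum)
    out[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  out / (windows$end - windows$start)
}

#' Detect directional transcription flanking accessible regions
#'
#' Flags putative gene TSSs among accessible regions using strand-specific
#' RNA-seq coverage in 100-bp windows immediately upstream and downstream
#' (in genomic coordinates) of the open interval. A region is `plus_tss`
#' when, in at least `min_samples` samples, (+)-strand coverage downstream
#' is >= `min_rpkm` and >= `min_fold` times the (+)-strand coverage
#' upstream; `minus_tss` analogously with (-)-strand coverage upstream
#' at least `min_fold` times downstream. Regions whose flank windows intersect
#' an annotated exon are never called (the signal is attributed to the
#' surrounding gene). Regions called either way are removed from the
#' enhancer set downstream.
#'
#' @param regions Region tibble (`region_id`, `chrom`, `start`, `end`).
#' @param coverage Stranded coverage tibble: `sample`, `strand`
#'   (`"+"`/`"-"`), `chrom`, `start`, `end`, `value` with values on the
#'   RPKM scale (per-bp, length-normalized per kb, depth-normalized per
#'   million).
#' @param exons Tibble of exon intervals (`chrom`, `start`, `end`); may be
#'   empty.
#' @param window Flank window width in bp (default 100).
#' @param min_rpkm Minimum window coverage (default 1 RPKM).
#' @param min_fold Minimum downstream/upstream (or upstream/downstream)
#'   ratio (default 2).
#' @param min_samples Minimum number of supporting samples (default 2).
#' @return Tibble `region_id`, `call` in `c("none", "plus_tss",
#'   "minus_tss")`, `n_plus`, `n_minus`, `exon_flank`.
#' @export
directional_transcription <- function(regions, coverage, exons = NULL,
                                      window = 100, min_rpkm = 1,
                                      min_fold = 2, min_samples = 2) {
  regions <- check_intervals(as_tibble(regions), "regions")
  coverage <- as_tibble(coverage)
  samples <- unique(coverage$sample)
  if (length(samples) < 2) abort("need stranded coverage for >= 2 samples")

  up <- tibble(chrom = regions$chrom,
               start = regions$start - window, end = regions$start)
  dn <- tibble(chrom = regions$chrom,
               start = regions$end, end = regions$end + window)

  exon_flank <- rep(FALSE, nrow(regions))
  if (!is.null(exons) && nrow(exons) > 0) {
    exons <- as_tibble(exons)
    exon_flank <- overlaps_any0(up, exons) | overlaps_any0(dn, exons)
  }

  n_plus <- n_minus <- integer(nrow(regions))
  for (s in samples) {
    plus <- filter(coverage, .data$sample == s, .data$strand == "+")
    minus <- filter(coverage, .data$sample == s, .data$strand == "-")
    pu <- window_mean_cov(plus, up);  pd <- window_mean_cov(plus, dn)
    mu <- window_mean_cov(minus, up); md <- window_mean_cov(minus, dn)
    n_plus <- n_plus + (pd >= min_rpkm & pd >= min_fold * pu)
    n_minus <- n_minus + (mu >= min_rpkm & mu >= min_fold * md)
  }

  tibble(
    region_id = regions$region_id,
    n_plus = as.integer(n_plus), n_minus = as.integer(n_minus),
    exon_flank = exon_flank
  ) %>%
    mutate(call = case_when(
      exon_flank ~ "none",
      n_plus >= .env$min_samples & n_plus >= n_minus ~ "plus_tss",
      n_minus >= .env$min_samples ~ "minus_tss",
      TRUE ~ "none"
    )) %>%
    select("region_id", "call", "n_plus", "n_minus", "exon_flank")
}

#' Region DNA-methylation level and stratum
#'
#' Mean per-CpG methylation fraction over CpGs with sequencing depth
#' at least `min_depth` inside a window centered on the region midpoint.
#' Strata follow strict bounds: `low` below `low_cut` (default 20%),
#' `high` above `high_cut` (default 80%), `medium` in between (exactly
#' 20% or 80% is medium). Regions with no qualifying CpG get `NA` and are
#' excluded from strata.
#'
#' @param regions Region tibble.
#' @param meth Methylation table: `chrom`, `pos` (0-based CpG position),
#'   `meth` (methylated count), `total` (total count).
#' @param center_window Window width in bp (default 200).
#' @param min_depth Minimum per-CpG depth (default 10).
#' @param low_cut,high_cut Stratum bounds (defaults 0.20, 0.80).
#' @return Tibble `region_id`, `meth_level`, `n_cpg`, `stratum`.
#' @export
methylation_level <- function(regions, meth, center_window = 200,
                              min_depth = 10, low_cut = 0.20,
                              high_cut = 0.80) {
  regions <- as_tibble(regions)
  meth <- as_tibble(meth)
  if (any(meth$meth > meth$total)) abort("methylated count exceeds total")
  keep <- meth[meth$total >= min_depth, , drop = FALSE]
  mids <- floor((regions$start + regions$end) / 2)
  win <- tibble(chrom = regions$chrom,
                start = mids - center_window %/% 2,
                end = mids + center_window %/% 2)
  lvl <- rep(NA_real_, nrow(regions))
  ncpg <- integer(nrow(regions))
  if (nrow(keep) > 0) {
    pts <- tibble(chrom = keep$chrom, start = keep$pos, end = keep$pos + 1)
    hits <- GenomicRanges::findOverlaps(as_granges0(win), as_granges0(pts))
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      frac <- keep$meth[si] / keep$total[si]
      agg <- tapply(frac, qi, mean)
      cnt <- tapply(frac, qi, length)
      idx <- as.integer(names(agg))
      lvl[idx] <- as.numeric(agg)
      ncpg[idx] <- as.integer(cnt)
    }
  }
  tibble(region_id = regions$region_id, meth_level = lvl, n_cpg = ncpg) %>%
    mutate(stratum = case_when(
      is.na(meth_level) ~ NA_character_,
      meth_level < .env$low_cut ~ "low",
      meth_level > .env$high_cut ~ "high",
      TRUE ~ "medium"
    ))
}

#' Gamete overlap of hypomethylated enhancers
#'
#' Among regions hypomethylated in the embryo (level < `hypo_cut`), flags
#' those equivalently hypomethylated (< `hypo_cut`) in both egg and sperm,
#' and reports the shared fraction.
#'
#' @param levels Tibble with `region_id` and per-sample methylation
#'   levels in columns `embryo`, `egg`, `sperm` (fractions in \[0, 1\]).
#' @param hypo_cut Hypomethylation threshold (default 0.20).
#' @return A list with `flags` (tibble `region_id`, `embryo_hypo`,
#'   `shared`) and `shared_fraction` (NA when no region is embryo-hypo).
#' @export
gamete_overlap <- function(levels, hypo_cut = 0.20) {
  levels <- as_tibble(levels)
  flags <- levels %>%
    mutate(
      embryo_hypo = !is.na(.data$embryo) & .data$embryo < .env$hypo_cut,
      shared = .data$embryo_hypo &
        !is.na(.data$egg) & .data$egg < .env$hypo_cut &
        !is.na(.data$sperm) & .data$sperm < .env$hypo_cut
    ) %>%
    select("region_id", "embryo_hypo", "shared")
  n_hypo <- sum(flags$embryo_hypo)
  list(
    flags = flags,
    shared_fraction = if (n_hypo == 0) NA_real_ else sum(flags$shared) / n_hypo
  )
}

#' Construct a position weight matrix with a log-odds threshold
#'
#' @param name Motif name.
#' @param matrix A 4 x L probability matrix with rownames A, C, G, T;
#'   columns must each sum to 1 (within 1e-6).
#' @param background Background base probabilities (default uniform 0.25).
#' @param threshold Log-odds score threshold for a hit; default
#'   `threshold_frac` of the maximal achievable score.
#' @param threshold_frac Fraction of the maximum log-odds score used when
#'   `threshold` is NULL (default 0.6).
#' @param pseudoprob Small probability added before taking log-odds so
#'   zero cells stay finite (default 1e-3).
#' @return A `pwm` object with the probability matrix, log-odds matrix
#'   and threshold.
#' @export
pwm <- function(name, matrix, background = rep(0.25, 4), threshold = NULL,
                threshold_frac = 0.6, pseudoprob = 1e-3) {
  if (nrow(matrix) != 4) abort("PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  sums <- colSums(matrix)
  if (any(abs(sums - 1) > 1e-6)) abort("PWM columns must sum to 1")
  prob <- (matrix + pseudoprob) / (1 + 4 * pseudoprob)
  lo <- log2(prob / background)
  max_score <- sum(apply(lo, 2, max))
  if (is.null(threshold)) threshold <- threshold_frac * max_score
  structure(list(name = name, prob = matrix, log_odds = lo,
                 threshold = threshold, max_score = max_score),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d bp, threshold %.2f (max %.2f)\n",
              x$name, ncol(x$prob), x$threshold, x$max_score))
  invisible(x)
}

# Score every position of a sequence (character scalar) against a pwm;
# returns numeric scores, NA where the window has a non-ACGT base.
scan_scores <- function(seq, pw) {
  L <- ncol(pw$log_odds)
  codes <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  n <- length(codes) - L + 1
  if (n < 1) return(numeric(0))
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- codes[i:(i + L - 1)]
    if (anyNA(win)) next
    scores[i] <- sum(pw$log_odds[cbind(win, seq_len(L))])
  }
  scores
}

# Extract a [start, end) window from a named genome sequence set
# (character vector or DNAStringSet), truncating at chromosome ends with
# a warning.
get_window_seq <- function(genome, chrom, start, end) {
  if (methods::is(genome, "DNAStringSet")) {
    genome_chr <- as.character(genome[[chrom]])
  } else {
    genome_chr <- genome[[chrom]]
  }
  clen <- nchar(genome_chr)
  if (start < 0 || end > clen) {
    warn(sprintf("window %s:%d-%d truncated to chromosome bounds", chrom,
                 start, end))
  }
  s <- max(start, 0)
  e <- min(end, clen)
  if (e <= s) return("")
  substr(genome_chr, s + 1, e)
}

#' Motif density around region midpoints
#'
#' Scans both strands of a window centered on each region midpoint with
#' log-odds-scored position weight matrices, counting positions with
#' score >= the PWM threshold (overlapping hits each counted). The scan
#' window spans `2 * half_window + L - 1` bp so every hit whose footprint
#' touches the +/- `half_window` core is seen.
#'
#' @param regions Region tibble.
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param half_window Half-width of the scan window in bp (default 100).
#' @return Tibble `region_id`, `pwm`, `hits`; total density per region is
#'   `sum(hits)` over PWMs.
#' @export
motif_density <- function(regions, genome, pwms, half_window = 100) {
  regions <- as_tibble(regions)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  mids <- floor((regions$start + regions$end) / 2)
  purrr::map_dfr(pwms, function(pw) {
    L <- ncol(pw$log_odds)
    hits <- purrr::map_int(seq_len(nrow(regions)), function(i) {
      seq <- get_window_seq(genome, regions$chrom[i],
                            mids[i] - half_window - (L - 1) %/% 2,
                            mids[i] + half_window + L %/% 2)
      if (nchar(seq) < L) return(0L)
      fwd <- scan_scores(seq, pw)
      rev <- scan_scores(revcomp(seq), pw)
      sum(fwd >= pw$threshold, na.rm = TRUE) +
        sum(rev >= pw$threshold, na.rm = TRUE)
    })
    tibble(region_id = regions$region_id, pwm = pw$name, hits = hits)
  })
}

# Reverse complement of a character sequence (keeps non-ACGT as N).
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    gsub("[^ACGTacgt]", "N", seq))))
}

#' CpG and G+C content of region centers
#'
#' Counts forward-strand CG dinucleotides and the G+C fraction in a
#' window centered on each region midpoint. Ambiguity codes are excluded
#' from both the numerator and the denominator of the G+C fraction;
#' counting is case-insensitive.
#'
#' @param regions Region tibble.
#' @param genome Named character vector or `DNAStringSet`.
#' @param window Window width in bp (default 500).
#' @return Tibble `region_id`, `cpg_count`, `gc_fraction` (NA when the
#'   window has no unambiguous base).
#' @export
cpg_content <- function(regions, genome, window = 500) {
  regions <- as_tibble(regions)
  mids <- floor((regions$start + regions$end) / 2)
  res <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    seq <- toupper(get_window_seq(genome, regions$chrom[i],
                                  mids[i] - window %/% 2,
                                  mids[i] + window %/% 2))
    bases <- strsplit(seq, "")[[1]]
    ok <- bases %in% c("A", "C", "G", "T")
    cg <- sum(bases == "C" | bases == "G")
    n_ok <- sum(ok)
    cpg <- if (nchar(seq) >= 2) {
      length(gregexpr("CG", seq, fixed = TRUE)[[1]][
        gregexpr("CG", seq, fixed = TRUE)[[1]] > 0])
    } else 0L
    tibble(cpg_count = as.integer(cpg),
           gc_fraction = if (n_ok == 0) NA_real_ else cg / n_ok)
  })
  bind_cols(tibble(region_id = regions$region_id), res)
}
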