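# Independent brute-force oracles used across tests. These deliberately
# avoid the package's interval machinery: plain loops and closed forms.

# O(n*m) overlap counter: fragments overlapping [start, end) by >= 1 bp.
brute_count_overlaps <- function(regions, fragments) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(fragments$chrom == regions$chrom[i] &
          fragments$start < regions$end[i] &
          fragments$end > regions$start[i])
  }, integer(1))
}

# Quadratic union filter: secondary peaks kept iff zero-bp overlap with
# every primary peak.
brute_union_count <- function(primary, secondary) {
  kept <- 0L
  for (j in seq_len(nrow(secondary))) {
    ov <- FALSE
    for (i in seq_len(nrow(primary))) {
      if (secondary$chrom[j] == primary$chrom[i] &&
          secondary$start[j] < primary$end[i] &&
          secondary$end[j] > primary$start[i]) {
        ov <- TRUE
        break
      }
    }
    if (!ov) kept <- kept + 1L
  }
  nrow(primary) + kept
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  stats_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats_all - mu) >= abs(r_obs - mu) - 1e-9)
}

# Direct per-cell kernel sum for the 2D KDE (sd = h/4 per axis).
brute_kde_grid <- function(x, y, h, n, lims) {
  gx <- seq(lims[1], lims[2], length.out = n)
  gy <- seq(lims[3], lims[4], length.out = n)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    z[i, j] <- mean(dnorm(gx[i] - x, sd = h / 4) * dnorm(gy[j] - y, sd = h / 4))
  }
  list(x = gx, y = gy, z = z)
}

# Pearson chi-squared from the textbook formula.
brute_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# All-pairs minimum interval-to-point distance (same convention as the
# package: 0 inside, else gap from the edge).
brute_min_distance <- function(regions, points) {
  vapply(seq_len(nrow(regions)), function(i) {
    pts <- points$pos[points$chrom == regions$chrom[i]]
    if (!length(pts)) return(NA_real_)
    min(pmax(regions$start[i] - pts, pts - regions$end[i], 0))
  }, numeric(1))
}

# Shared tiny catalog for tests that only need layout, reused to keep the
# suite fast. Built once per test run.
tiny_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_truth_catalog(
        c(promoter = 15, k4me1_enhancer = 20, k4me2_enhancer = 20,
          poised_enhancer = 8, inactive = 15),
        seed = 42,
        chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
        n_genes = 24
      )
    }
    cache
  }
})

# Random interval tibble on a small genome.
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             width_range = c(50, 500)) {
  start <- floor(runif(n, 0, max_pos))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + floor(runif(n, width_range[1], width_range[2]))
  )
}
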