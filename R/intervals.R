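#' Genomic interval conventions
#'
#' All coordinates in this package are 0-based, half-open `[start, end)`
#' (BED convention). A "point" such as a TSS is a 0-based base position.
#' The distance from an interval to a point is 0 when the point falls
#' inside the interval and otherwise `max(start - p, p - end)`, i.e. the
#' gap in bp measured from the region edge.
#'
#' @name interval-conventions
NULL

# Validate a tibble of intervals (chrom/start/end), returning it invisibly.
check_intervals <- function(x, what = "intervals") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0(what, " must have columns chrom/start/end; missing: ",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end) | is.na(x$chrom) | x$chrom == "")
  if (length(bad)) {
    abort(paste0("malformed interval(s) in ", what, " at row(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 " (need 0 <= start < end, non-empty chrom)"))
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed)
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Count, for each row of `query`, the rows of `subject` overlapping by >= 1 bp.
count_overlaps0 <- function(query, subject) {
  GenomicRanges::countOverlaps(as_granges0(query), as_granges0(subject))
}

# Logical: does each query interval overlap any subject interval by >= 1 bp?
overlaps_any0 <- function(query, subject) {
  IRanges::overlapsAny(as_granges0(query), as_granges0(subject))
}

#' Distance from intervals to points
#'
#' Vectorized interval-to-point distance under the package convention:
#' 0 if the point lies inside the half-open interval, otherwise
#' `max(start - p, p - end)` bp measured from the interval edge.
#'
#' @param start,end Interval bounds (0-based half-open), recycled.
#' @param p Point positions (0-based).
#' @return Integer-valued distances in bp.
#' @examples
#' interval_point_distance(5000, 5100, 8000)  # 2900
#' interval_point_distance(100, 200, 150)     # 0
#' @export
interval_point_distance <- function(start, end, p) {
  pmax(start - p, p - end, 0)
}

# For each point set per chromosome, the minimum distance from each interval
# in `regions` to any point on the same chromosome; NA when the chromosome
# has no points.
min_distance_to_points <- function(regions, points) {
  split_pts <- split(points$pos, points$chrom)
  purrr::pmap_dbl(
    list(regions$chrom, regions$start, regions$end),
    function(chrom, start, end) {
      pts <- split_pts[[chrom]]
      if (is.null(pts) || !length(pts)) return(NA_real_)
      min(interval_point_distance(start, end, pts))
    }
  )
}
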