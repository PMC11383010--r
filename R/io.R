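#' Read and write BED-style interval files
#'
#' Three-column BED (chrom, start, end) with optional extra columns; all
#' coordinates 0-based half-open. `read_bed` reports the offending line
#' number on malformed input.
#'
#' @param path File path.
#' @param extra_cols Names for columns beyond the first three (optional).
#' @return A tibble with `chrom`, `start`, `end` (+ extras).
#' @export
read_bed <- function(path, extra_cols = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 3) abort("BED file needs at least 3 columns")
  names(x)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_cols)) {
    names(x)[3 + seq_along(extra_cols)] <- extra_cols
  }
  bad <- which(!is.numeric(x$start) | !is.numeric(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    abort(paste0("malformed BED interval at line ", bad[1], " of ", path))
  }
  as_tibble(x)
}

#' @param x Interval tibble (`chrom`, `start`, `end`, extra columns kept
#'   in order).
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  check_intervals(x, "bed intervals")
  readr::write_tsv(x, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write bedGraph coverage tracks
#'
#' Four columns: chrom, start, end, value (0-based half-open).
#'
#' @param path File path.
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       show_col_types = FALSE, progress = FALSE)
  check_intervals(x, paste0("bedGraph ", path))
  x
}

#' @param x Coverage tibble with `chrom`, `start`, `end`, `value`.
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write per-CpG methylation tables
#'
#' Tab-separated `chrom`, `pos` (0-based), `meth`, `total`.
#'
#' @param path File path.
#' @return Tibble `chrom`, `pos`, `meth`, `total`.
#' @export
read_methylation <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "pos", "meth", "total"),
                       show_col_types = FALSE, progress = FALSE)
  if (any(x$meth > x$total)) abort("methylated count exceeds total")
  x
}

#' @param x Methylation tibble.
#' @rdname read_methylation
#' @export
write_methylation <- function(x, path) {
  readr::write_tsv(x[c("chrom", "pos", "meth", "total")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write and read the truth-label sidecar for a synthetic catalog
#'
#' @param catalog A `truth_catalog`.
#' @param path File path.
#' @return `read_truth_regions` returns the planted-region tibble.
#' @export
write_truth_regions <- function(catalog, path) {
  readr::write_tsv(catalog$regions, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth_regions
#' @export
read_truth_regions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a genome to FASTA / read it back
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path File path.
#' @return `read_genome_fasta` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), names(dna))
}

#' Read position weight matrices in JASPAR-style plain text
#'
#' Parses records of the form `>name` followed by four rows
#' `A [ 10 20 ... ]` (counts or probabilities; counts are normalized
#' per column).
#'
#' @param path File path.
#' @param ... Passed to [pwm()] (e.g. `threshold_frac`).
#' @return A named list of `pwm` objects.
#' @export
read_pwms_jaspar <- function(path, ...) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) abort("no PWM records found")
  out <- purrr::map(seq_along(starts), function(i) {
    name <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lines[(starts[i] + 1):(starts[i] + 4)]
    m <- t(vapply(rows, function(r) {
      x <- sub("^[ACGTacgt]", "", r)
      as.numeric(regmatches(x, gregexpr("[-+0-9.eE]+", x))[[1]])
    }, numeric(length(gregextract_first(rows[1])))))
    dimnames(m) <- NULL
    rownames(m) <- toupper(substr(trimws(rows), 1, 1))
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    m <- sweep(m, 2, colSums(m), "/")
    pwm(name, m, ...)
  })
  setNames(out, purrr::map_chr(out, "name"))
}

# number of numeric fields in the first matrix row (helper for parsing)
gregextract_first <- function(row) {
  x <- sub("^[ACGTacgt]", "", row)
  regmatches(x, gregexpr("[-+0-9.eE]+", x))[[1]]
}

#' Write the class-call table
#'
#' @param calls Tibble of per-region calls (e.g. joined output of
#'   [classify_and_flag()] and [refine_enhancer_classes()]).
#' @param path File path.
#' @export
write_class_calls <- function(calls, path) {
  readr::write_tsv(calls, path, progress = FALSE)
  invisible(path)
}
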