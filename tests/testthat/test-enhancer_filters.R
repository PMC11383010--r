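cov_row <- function(sample, strand, start, end, value, chrom = "chr1") {
  tibble::tibble(sample = sample, strand = strand, chrom = chrom,
                 start = start, end = end, value = value)
}

test_that("directional transcription applies the RPKM, fold, and sample rules", {
  reg <- tibble::tibble(region_id = "r1", chrom = "chr1",
                        start = 1000, end = 1500)
  # zero coverage everywhere -> none
  empty <- dplyr::bind_rows(cov_row("s1", "+", 0, 1, 0), cov_row("s2", "+", 0, 1, 0))
  expect_equal(directional_transcription(reg, empty)$call, "none")

  # downstream(+) 5 RPKM vs upstream(+) 1 RPKM in 2 of 4 samples -> plus_tss
  cov <- dplyr::bind_rows(
    cov_row("s1", "+", 1500, 1600, 5), cov_row("s1", "+", 900, 1000, 1),
    cov_row("s2", "+", 1500, 1600, 5), cov_row("s2", "+", 900, 1000, 1),
    cov_row("s3", "+", 1500, 1600, 0.2), cov_row("s4", "+", 1500, 1600, 0.2)
  )
  out <- directional_transcription(reg, cov)
  expect_equal(out$call, "plus_tss")
  expect_equal(out$n_plus, 2L)

  # (-)-strand rule: upstream coverage 2-fold over downstream
  covm <- dplyr::bind_rows(
    cov_row("s1", "-", 900, 1000, 4), cov_row("s1", "-", 1500, 1600, 1),
    cov_row("s2", "-", 900, 1000, 4), cov_row("s2", "-", 1500, 1600, 1)
  )
  expect_equal(directional_transcription(reg, covm)$call, "minus_tss")

  # a flank inside an annotated exon suppresses the call
  exons <- tibble::tibble(chrom = "chr1", start = 1550, end = 1700)
  expect_equal(directional_transcription(reg, cov, exons)$call, "none")

  # sub-threshold signal (0.9 RPKM) or insufficient fold never calls
  weak <- dplyr::bind_rows(cov_row("s1", "+", 1500, 1600, 0.9),
                           cov_row("s2", "+", 1500, 1600, 0.9))
  expect_equal(directional_transcription(reg, weak)$call, "none")
  lowfold <- dplyr::bind_rows(
    cov_row("s1", "+", 1500, 1600, 4), cov_row("s1", "+", 900, 1000, 3),
    cov_row("s2", "+", 1500, 1600, 4), cov_row("s2", "+", 900, 1000, 3))
  expect_equal(directional_transcription(reg, lowfold)$call, "none")

  expect_error(directional_transcription(reg, cov_row("s1", "+", 0, 1, 0)),
               "2 samples")
})

test_that("directional transcription is invariant to sample order", {
  set.seed(11)
  reg <- tibble::tibble(region_id = sprintf("r%d", 1:20), chrom = "chr1",
                        start = seq(5000, 100000, by = 5000),
                        end = seq(5000, 100000, by = 5000) + 400)
  cov <- purrr::map_dfr(sprintf("s%d", 1:4), function(s) {
    k <- 40
    st <- sample(seq(4000, 101000, by = 100), k)
    cov_row(s, sample(c("+", "-"), k, replace = TRUE), st, st + 150,
            runif(k, 0, 6))
  })
  a <- directional_transcription(reg, cov)
  b <- directional_transcription(reg, dplyr::arrange(cov, dplyr::desc(sample)))
  expect_equal(a, b)
})

test_that("methylation level averages depth-filtered CpGs and stratifies strictly", {
  reg <- tibble::tibble(region_id = "r1", chrom = "chr1",
                        start = 1000, end = 1200)  # midpoint 1100, window 1000-1200
  # all CpGs 0/20 -> level 0, low
  m0 <- tibble::tibble(chrom = "chr1", pos = c(1050, 1150), meth = 0, total = 20)
  out0 <- methylation_level(reg, m0)
  expect_equal(out0$meth_level, 0)
  expect_equal(out0$stratum, "low")
  # {8/10, 9/10} -> 0.85, high
  m1 <- tibble::tibble(chrom = "chr1", pos = c(1050, 1150),
                       meth = c(8, 9), total = 10)
  out1 <- methylation_level(reg, m1)
  expect_equal(out1$meth_level, 0.85)
  expect_equal(out1$stratum, "high")
  # only depth-9 CpGs -> missing
  m2 <- tibble::tibble(chrom = "chr1", pos = 1100, meth = 5, total = 9)
  expect_true(is.na(methylation_level(reg, m2)$meth_level))
  # boundary strata: exactly 0.20 and 0.80 are medium
  m20 <- tibble::tibble(chrom = "chr1", pos = 1100, meth = 2, total = 10)
  expect_equal(methylation_level(reg, m20)$stratum, "medium")
  m80 <- tibble::tibble(chrom = "chr1", pos = 1100, meth = 8, total = 10)
  expect_equal(methylation_level(reg, m80)$stratum, "medium")
  # level always in [0, 1] on random tables
  set.seed(12)
  tot <- sample(5:40, 60, replace = TRUE)
  mr <- tibble::tibble(chrom = "chr1", pos = sample(1000:1200, 60),
                       meth = rbinom(60, tot, 0.5), total = tot)
  lv <- methylation_level(reg, mr)$meth_level
  expect_true(lv >= 0 && lv <= 1)
})

test_that("gamete overlap counts triple-hypomethylated regions", {
  lv <- tibble::tibble(region_id = c("a", "b", "c"),
                       embryo = c(0, 0.1, 0.9),
                       egg = c(0, 0.1, 0),
                       sperm = c(0, 0.9, 0))
  go <- gamete_overlap(lv)
  expect_equal(go$shared_fraction, 0.5)  # a shared, b not, c not embryo-hypo
  expect_equal(go$flags$shared, c(TRUE, FALSE, FALSE))
  # all-zero levels: fraction 1
  z <- tibble::tibble(region_id = "a", embryo = 0, egg = 0, sperm = 0)
  expect_equal(gamete_overlap(z)$shared_fraction, 1)
  # random levels match a brute-force triple-threshold count
  set.seed(13)
  r <- tibble::tibble(region_id = sprintf("r%03d", 1:200),
                      embryo = runif(200), egg = runif(200), sperm = runif(200))
  go2 <- gamete_overlap(r)
  hypo <- r$embryo < 0.2
  expect_equal(go2$shared_fraction,
               sum(hypo & r$egg < 0.2 & r$sperm < 0.2) / sum(hypo))
})

test_that("PWM scanning finds planted consensus sites and is strand-symmetric", {
  mat <- matrix(0.02, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- c("T", "G", "A", "C", "C", "A")
  for (i in 1:6) mat[consensus[i], i] <- 0.94
  pw <- pwm("toy", mat)
  reg <- tibble::tibble(region_id = "r1", chrom = "chr1", start = 450, end = 550)
  # background of A's cannot hit a high threshold
  bgA <- stats::setNames(paste(rep("A", 1000), collapse = ""), "chr1")
  expect_equal(motif_density(reg, bgA, pw)$hits, 0L)
  # plant the consensus at the region midpoint
  seq <- bgA
  substr(seq, 498, 503) <- "TGACCA"
  expect_equal(motif_density(reg, seq, pw)$hits, 1L)
  # reverse-complementing the chromosome leaves the both-strand total unchanged
  rc <- stats::setNames(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))), "chr1")
  reg_rc <- tibble::tibble(region_id = "r1", chrom = "chr1",
                           start = 1000 - 550, end = 1000 - 450)
  expect_equal(motif_density(reg_rc, rc, pw)$hits, 1L)
})

test_that("motif scanning warns and truncates at chromosome ends", {
  mat <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pw <- pwm("flat", mat, threshold = 100)
  genome <- stats::setNames(paste(rep("A", 150), collapse = ""), "chr1")
  reg <- tibble::tibble(region_id = "r1", chrom = "chr1", start = 10, end = 30)
  expect_warning(out <- motif_density(reg, genome, pw), "truncated")
  expect_equal(out$hits, 0L)
})

test_that("planted consensus sites in the simulated genome are recovered", {
  cat_ <- tiny_catalog()
  mat <- matrix(0.01, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- c("T", "T", "G", "C", "A", "T", "A", "A")
  for (i in 1:8) mat[consensus[i], i] <- 0.97
  pw <- pwm("nps_like", mat)
  enh <- cat_$regions[cat_$regions$true_class == "k4me2_enhancer", ][1:5, ]
  genome <- simulate_genome_sequence(
    cat_, seed = 4, gc = 0.4,
    plant = tibble::tibble(region_id = enh$region_id, pwm_name = "nps_like"),
    pwms = list(pw))
  hits <- motif_density(enh, genome, pw)
  expect_true(all(hits$hits >= 1))
})

test_that("CpG and GC content follow the string oracles", {
  reg <- tibble::tibble(region_id = "r1", chrom = "chr1", start = 0, end = 500)
  g_cg <- stats::setNames(paste(rep("CG", 250), collapse = ""), "chr1")
  out <- cpg_content(reg, g_cg, window = 500)
  expect_equal(out$cpg_count, 250L)
  expect_equal(out$gc_fraction, 1)
  g_a <- stats::setNames(paste(rep("A", 500), collapse = ""), "chr1")
  out_a <- cpg_content(reg, g_a, window = 500)
  expect_equal(out_a$cpg_count, 0L)
  expect_equal(out_a$gc_fraction, 0)
  g_acgt <- stats::setNames(paste(rep("ACGT", 125), collapse = ""), "chr1")
  expect_equal(cpg_content(reg, g_acgt, window = 500)$gc_fraction, 0.5)
  # ambiguity codes drop out of numerator and denominator
  g_n <- stats::setNames(paste(c(rep("N", 250), rep("G", 125), rep("A", 125)),
                               collapse = ""), "chr1")
  expect_equal(cpg_content(reg, g_n, window = 500)$gc_fraction, 0.5)
})
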