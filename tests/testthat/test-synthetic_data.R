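test_that("truth catalogs are deterministic and respect placement rules", {
  cc <- c(promoter = 10, k4me1_enhancer = 15, k4me2_enhancer = 15,
          poised_enhancer = 5, inactive = 10)
  a <- make_truth_catalog(cc, seed = 5, chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                          n_genes = 20)
  b <- make_truth_catalog(cc, seed = 5, chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                          n_genes = 20)
  expect_identical(a, b)
  expect_equal(unname(table(a$regions$true_class)[names(cc)]),
               unname(cc), ignore_attr = TRUE)
  # all-zero counts: genes only, empty region list
  empty <- make_truth_catalog(c(), seed = 1,
                              chrom_sizes = c(chr1 = 2e6), n_genes = 5)
  expect_equal(nrow(empty$regions), 0)
  expect_equal(nrow(empty$genes), 5)
  # regions stay >= 500 bp from chromosome ends
  expect_true(all(a$regions$start >= 500))
  expect_true(all(a$regions$end + 500 <=
                    unname(a$chrom_sizes[a$regions$chrom])))
  # capacity error when the genome cannot host the request
  expect_error(
    make_truth_catalog(c(inactive = 10000), seed = 1,
                       chrom_sizes = c(chr1 = 5e4), n_genes = 2),
    "fit")
})

test_that("planted enhancers are >= 2 kb from every isoform TSS (brute force)", {
  cat_ <- make_truth_catalog(
    c(k4me2_enhancer = 50), seed = 8,
    chrom_sizes = c(chr1 = 3e6, chr2 = 3e6), n_genes = 30)
  enh <- cat_$regions[cat_$regions$true_class == "k4me2_enhancer", ]
  expect_equal(nrow(enh), 50)
  dmin <- brute_min_distance(enh, tibble::tibble(chrom = cat_$tss$chrom,
                                                 pos = cat_$tss$pos))
  expect_true(all(dmin >= 2000))
  # planted regions never overlap each other
  r <- dplyr::arrange(cat_$regions, chrom, start)
  same <- r$chrom[-1] == r$chrom[-nrow(r)]
  expect_true(all(r$start[-1][same] >= r$end[-nrow(r)][same]))
})

test_that("a flat archetype yields background-level coverage in planted regions", {
  cat_ <- tiny_catalog()
  lib <- simulate_cutrun_library(cat_, default_archetype(strength = 0),
                                 "H3K4me1", depth = 2e5, seed = 3)
  expect_equal(nrow(lib$fragments), 2e5, tolerance = 0.01)
  # mean per-bp fragment-start rate inside regions within 3 sd of background
  reg <- cat_$regions
  n_in <- sum(brute_count_overlaps(reg, lib$fragments))
  w <- sum(reg$end - reg$start)
  frag_len <- mean(lib$fragments$end - lib$fragments$start)
  expected <- 2e5 * (w + nrow(reg) * frag_len) / sum(cat_$chrom_sizes)
  expect_lt(abs(n_in - expected), 3 * sqrt(expected))
})

test_that("fragment lengths exercise the size filter and depth is validated", {
  cat_ <- tiny_catalog()
  lib <- simulate_cutrun_library(cat_, default_archetype(), "H3K4me2",
                                 depth = 5e4, seed = 9)
  len <- lib$fragments$end - lib$fragments$start
  expect_gt(mean(len < 140), 0.05)   # sub-nucleosomal tail present
  expect_gt(mean(len > 250), 0.05)   # long tail present
  expect_gt(mean(len >= 140 & len <= 250), 0.5)
  expect_error(simulate_cutrun_library(cat_, default_archetype(), "H3K4me2",
                                       depth = 0), "depth")
  expect_error(simulate_cutrun_library(cat_, default_archetype(), "H3K99",
                                       depth = 10), "mark")
})

test_that("an 8x H3K4me2 multiplier gives > 2-fold empirical enrichment over IgG", {
  cat_ <- tiny_catalog()
  k4me2 <- cat_$regions[cat_$regions$true_class == "k4me2_enhancer", ]
  hits <- purrr::map_dbl(1:10, function(s) {
    lib <- filter_fragments(simulate_cutrun_library(
      cat_, default_archetype(), "H3K4me2", depth = 4e5, seed = s))
    igg <- filter_fragments(simulate_cutrun_library(
      cat_, default_archetype(), "IgG", depth = 4e5, seed = s))
    enr <- region_enrichment(list(lib), igg, k4me2)
    mean(enr$fold_igg > 2)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("per-library RNG streams are independent of the library set", {
  cat_ <- tiny_catalog()
  a <- simulate_cutrun_library(cat_, default_archetype(), "H3K4me1",
                               depth = 1e4, seed = 2)
  # simulating another mark in between must not change this library
  invisible(simulate_cutrun_library(cat_, default_archetype(), "H3K27ac",
                                    depth = 1e4, seed = 2))
  b <- simulate_cutrun_library(cat_, default_archetype(), "H3K4me1",
                               depth = 1e4, seed = 2)
  expect_identical(a$fragments, b$fragments)
  expect_false(identical(
    a$fragments,
    simulate_cutrun_library(cat_, default_archetype(), "H3K4me1",
                            depth = 1e4, seed = 3)$fragments))
})

test_that("simulated directional transcription drives the detector as planted", {
  cat_ <- tiny_catalog()
  enh <- cat_$regions[grepl("enhancer", cat_$regions$true_class), ]
  exons <- tidyr::unnest(dplyr::select(cat_$genes, chrom, exons), exons)
  # fraction 0: no planted enhancer flagged
  r0 <- simulate_rnaseq(cat_, transcribed_fraction = 0, n_samples = 3, seed = 6)
  d0 <- directional_transcription(enh, r0$coverage, exons)
  expect_lt(mean(d0$call != "none"), 0.01)
  # fraction 1, strong signal: >= 95% detected, matching the planted strand
  r1 <- simulate_rnaseq(cat_, transcribed_fraction = 1, n_samples = 3, seed = 6)
  d1 <- directional_transcription(enh, r1$coverage, exons)
  expect_gte(mean(d1$call != "none"), 0.95)
  flagged <- d1[d1$call != "none", ]
  ori <- enh$true_orientation[match(flagged$region_id, enh$region_id)]
  expect_true(all(flagged$call == ifelse(ori == "right", "plus_tss", "minus_tss")))
  expect_error(simulate_rnaseq(cat_, 0.5, n_samples = 1), "n_samples")
  expect_error(simulate_rnaseq(cat_, 1.2, n_samples = 2), "fraction")
})

test_that("simulated methylomes encode class levels, shared set, and low-depth sites", {
  cat_ <- tiny_catalog()
  ms <- simulate_methylomes(cat_, seed = 14, shared_fraction = 1,
                            noise_sd = 0, mean_depth = 200,
                            low_depth_fraction = 0.05)
  enh <- cat_$regions[grepl("enhancer", cat_$regions$true_class), ]
  lv <- purrr::map(ms$tables, ~ methylation_level(enh, .x))
  levels <- tibble::tibble(
    region_id = enh$region_id,
    true_class = enh$true_class,
    embryo = lv$embryo$meth_level, egg = lv$egg$meth_level,
    sperm = lv$sperm$meth_level)
  # noiseless shared fraction 1: every embryo-hypo enhancer shared
  go <- gamete_overlap(levels)
  expect_equal(go$shared_fraction, 1)
  # k4me1 enhancers hypermethylated at high depth (law of large numbers)
  k4me1 <- levels[levels$true_class == "k4me1_enhancer", ]
  expect_true(all(k4me1$embryo > 0.8))
  # low-depth sites exist to exercise the depth filter
  expect_gt(sum(ms$tables$embryo$total < 10), 0)
})

test_that("null and alternative qPCR simulations recover the planted effect", {
  cat_ <- tiny_catalog()
  # effect 1: fold ~ 1, rank-sum p roughly uniform across seeds
  null_res <- purrr::map_dfr(1:40, function(s) {
    q <- qpcr_effect(simulate_expression_and_qpcr(
      cat_, effect_fold = 1, n_embryos = 5, seed = s)$qpcr)
    tibble::tibble(fold = q$fold_change, p = q$p_value)
  })
  expect_lt(abs(mean(log2(null_res$fold))), 0.1)
  expect_gt(mean(null_res$p > 0.05), 0.8)
  # exact rank-sum p-values are discrete, so the KS test warns about ties;
  # the uniformity check itself is still informative at this sample size
  ks <- suppressWarnings(stats::ks.test(null_res$p, "punif"))
  expect_gt(ks$p.value, 0.01)

  # effect 1.7, low noise: recovered fold lands in [1.5, 1.9] nearly always
  rec <- purrr::map_dbl(1:100, function(s) {
    qpcr_effect(simulate_expression_and_qpcr(
      cat_, effect_fold = 1.7, n_embryos = 10, seed = s,
      ct_sd = 0.08, embryo_sd = 0.05)$qpcr)$fold_change
  })
  expect_gte(mean(rec >= 1.5 & rec <= 1.9), 0.9)

  # three technical replicates per embryo per gene
  sim <- simulate_expression_and_qpcr(cat_, effect_fold = 1.7,
                                      n_embryos = 4, seed = 2)
  reps <- dplyr::count(sim$qpcr, embryo_id, gene)
  expect_true(all(reps$n == 3))
  expect_error(simulate_expression_and_qpcr(cat_, effect_fold = 0), "effect_fold")
  expect_error(simulate_expression_and_qpcr(cat_, n_embryos = 2), "3 embryos")
})

test_that("time-course trajectories separate the planted gene groups", {
  cat_ <- tiny_catalog()
  sim <- simulate_expression_and_qpcr(cat_, seed = 31)
  tc <- sim$time_course
  down <- trajectory_with_ci(tc[tc$nps_class == "down", ])
  unaff <- trajectory_with_ci(tc[tc$nps_class == "unaffected", ])
  # unaffected genes switch on earlier: larger lfc at the 2.5 hpf point
  expect_gt(unaff$mean_lfc[unaff$time == 2.5], down$mean_lfc[down$time == 2.5])
  # both groups end activated
  expect_gt(min(down$mean_lfc[down$time == 6], unaff$mean_lfc[unaff$time == 6]), 1)
})
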