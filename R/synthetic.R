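#' Deterministic per-library seed derivation
#'
#' Hashes a master seed and a stream name into a 32-bit seed so that each
#' simulated library draws from its own stream: adding a library never
#' perturbs the others.
#'
#' @param seed Master integer seed.
#' @param name Stream name (e.g. the mark).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(as.character(name))) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate code under a temporary RNG state; restores the caller's stream.
with_seed_local <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Default histone-mark panel
#'
#' The ten modifications profiled for the feature matrix (three features
#' each gives the 30-column input), in declared order.
#' @return Character vector of mark names.
#' @export
default_marks <- function() {
  c("H3K4me1", "H3K4me2", "H3K4me3", "H3K27ac", "H2BNTac",
    "H3K9ac", "H3K14ac", "H3K18ac", "H3K27me3", "H2AZ")
}

#' Default signal archetype for the planted classes
#'
#' Per (true class, mark) enrichment multipliers over a uniform
#' background. The defaults encode the qualitative pattern the pipeline
#' must recover: promoters high in H3K4me2/3 and acetylation;
#' H3K4me2 enhancers high in H3K4me1, H3K4me2, H3K27ac and H2A.Z but not
#' H3K4me3; H3K4me1 enhancers high in H3K4me1/H3K27ac with H3K4me2 at
#' background (below the 1.25-fold call threshold); poised enhancers
#' H3K4me1-only; inactive regions flat. Multipliers for the called marks
#' sit at >= 4x their detection thresholds so planted classes are
#' recoverable. The IgG control is all-background.
#'
#' @param strength Scales the (multiplier - 1) excess of every entry
#'   (default 1); 0 gives a flat archetype.
#' @return A `signal_archetype`: tibble `true_class`, `mark`,
#'   `multiplier`.
#' @export
default_archetype <- function(strength = 1) {
  marks <- default_marks()
  base <- list(
    promoter       = c(2.5, 10, 12, 6, 6, 6, 5, 5, 1, 4),
    k4me2_enhancer = c(8,   8,  1,  6, 4, 3, 3, 3, 1, 5),
    k4me1_enhancer = c(8,   1,  1,  6, 2, 2, 2, 2, 1, 1.5),
    poised_enhancer = c(8,  1,  1,  1, 1, 1, 1, 1, 2, 1),
    inactive       = rep(1, 10)
  )
  tbl <- purrr::imap_dfr(base, function(mult, cls) {
    tibble(true_class = cls, mark = marks, multiplier = mult)
  })
  tbl <- bind_rows(tbl, tibble(true_class = names(base), mark = "IgG",
                               multiplier = 1))
  tbl$multiplier <- 1 + (tbl$multiplier - 1) * strength
  if (any(tbl$multiplier < 0)) abort("multipliers must be >= 0")
  structure(tbl, class = c("signal_archetype", class(tbl)))
}

#' Build a truth catalog of genes and planted region classes
#'
#' Lays out a small synthetic genome: genes at regular spacing with 1--3
#' isoform TSSs, exons, CAGE tag support (the primary TSS has > 20 tags),
#' an NPS-dependence label and a 2-cell RPKM; accessible regions planted
#' as promoters (overlapping the primary TSS) and enhancer-class regions
#' (every isoform TSS >= 2 kb away), all non-overlapping, >= 500 bp from
#' chromosome edges, with a true orientation for directional
#' transcription; and a CpG position list over region centers plus
#' intergenic background.
#'
#' @param class_counts Named counts of planted regions per class, among
#'   `promoter`, `k4me1_enhancer`, `k4me2_enhancer`, `poised_enhancer`,
#'   `inactive`. Promoter count must not exceed the number of genes.
#' @param seed Integer seed; identical seeds give identical catalogs.
#' @param chrom_sizes Named chromosome lengths in bp (default two 4-Mb
#'   chromosomes); lengths must be >= 10 kb.
#' @param n_genes Number of genes (default 40).
#' @param region_width_range Planted region widths in bp (default
#'   600--1000).
#' @param params [pipeline_params()]; the flank and proximal cut control
#'   placement margins.
#' @return A `truth_catalog`.
#' @export
make_truth_catalog <- function(class_counts, seed,
                               chrom_sizes = c(chr1 = 4e6, chr2 = 4e6),
                               n_genes = 40,
                               region_width_range = c(600, 1000),
                               params = pipeline_params()) {
  classes <- c("promoter", "k4me1_enhancer", "k4me2_enhancer",
               "poised_enhancer", "inactive")
  cc <- setNames(rep(0, length(classes)), classes)
  if (length(class_counts)) {
    bad <- setdiff(names(class_counts), classes)
    if (length(bad)) abort(paste0("unknown class(es): ", paste(bad, collapse = ", ")))
    if (any(class_counts < 0)) abort("class counts must be >= 0")
    cc[names(class_counts)] <- class_counts
  }
  if (any(chrom_sizes < 1e4)) abort("chromosome lengths must be >= 10 kb")
  if (cc["promoter"] > n_genes) abort("more promoters requested than genes")

  with_seed_local(derive_seed(seed, "catalog"), {
    flank <- params$flank
    prox <- params$proximal_cut

    # genes on a regular grid, round-robin across chromosomes
    chroms <- names(chrom_sizes)
    gene_chrom <- rep(chroms, length.out = n_genes)
    n_per <- table(factor(gene_chrom, levels = chroms))
    gene_pos <- unlist(purrr::map(chroms, function(ch) {
      k <- n_per[[ch]]
      if (k == 0) return(numeric(0))
      spacing <- floor((chrom_sizes[[ch]] - 2e4) / max(k, 1))
      1e4 + spacing * (seq_len(k) - 1)
    }), use.names = FALSE)
    gene_chrom <- unlist(purrr::map(chroms, function(ch) {
      rep(ch, n_per[[ch]])
    }), use.names = FALSE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)

    genes <- purrr::map_dfr(seq_len(n_genes), function(i) {
      n_iso <- sample(1:3, 1)
      extra <- if (n_iso > 1) gene_pos[i] + sort(sample(100:800, n_iso - 1)) else numeric(0)
      tss <- c(gene_pos[i], extra)
      dir <- if (strand[i] == "+") 1 else -1
      ex_start <- gene_pos[i] + dir * cumsum(sample(300:1200, 3))
      exons <- tibble(start = pmin(ex_start, ex_start + dir * 200),
                      end = pmax(ex_start, ex_start + dir * 200))
      tibble(
        gene_id = sprintf("gene%03d", i),
        chrom = gene_chrom[i], strand = strand[i],
        tss = list(tss), exons = list(exons),
        nps_class = sample(c("down", "unaffected"), 1),
        two_cell_rpkm = round(ifelse(runif(1) < 0.5, runif(1, 0.6, 20),
                                     runif(1, 0, 0.4)), 3)
      )
    })

    # flat isoform TSS table with CAGE tags (primary > 20 tags)
    tss_tbl <- genes %>%
      select("gene_id", "chrom", "strand", "tss") %>%
      tidyr::unnest_longer("tss", values_to = "pos") %>%
      group_by(.data$gene_id) %>%
      mutate(is_primary = row_number() == 1L) %>%
      ungroup() %>%
      mutate(tags = if_else(.data$is_primary,
                            sample(30:1000, dplyr::n(), replace = TRUE),
                            sample(0:15, dplyr::n(), replace = TRUE)))

    widths <- function(k) if (k) sample(region_width_range[1]:region_width_range[2],
                                        k, replace = TRUE) else integer(0)

    # promoters over primary TSSs of a seeded gene subset
    prom_genes <- sample(seq_len(n_genes), cc[["promoter"]])
    prom <- purrr::map_dfr(prom_genes, function(i) {
      w <- widths(1)
      center_off <- sample(-100:100, 1)
      tss0 <- gene_pos[i]
      tibble(chrom = gene_chrom[i],
             start = tss0 + center_off - w %/% 2,
             end = tss0 + center_off - w %/% 2 + w,
             true_class = "promoter")
    })

    # candidate slots for non-promoter regions: a grid, filtered against
    # TSS proximity and chromosome edges
    all_tss <- tibble(chrom = tss_tbl$chrom, pos = tss_tbl$pos)
    slot_step <- 3000
    max_w <- region_width_range[2]
    cand <- purrr::map_dfr(chroms, function(ch) {
      tibble(chrom = ch,
             center = seq(flank + max_w, chrom_sizes[[ch]] - flank - max_w,
                          by = slot_step))
    })
    cand_iv <- tibble(chrom = cand$chrom,
                      start = cand$center - max_w %/% 2,
                      end = cand$center + max_w %/% 2)
    dmin <- min_distance_to_points(cand_iv, all_tss)
    # keep slots clear of TSSs (distal annotation) and of exons (so flank
    # windows of planted enhancers never fall inside an annotated exon)
    exons_flat <- genes %>%
      select("chrom", "exons") %>%
      tidyr::unnest("exons")
    pad <- 300
    near_exon <- overlaps_any0(
      tibble(chrom = cand_iv$chrom, start = cand_iv$start - pad,
             end = cand_iv$end + pad),
      exons_flat)
    cand <- cand[(is.na(dmin) | dmin >= prox + 100) & !near_exon, , drop = FALSE]

    n_needed <- sum(cc[classes != "promoter"])
    if (nrow(cand) < n_needed) {
      abort(sprintf("requested %d non-promoter regions but only %d slots fit",
                    n_needed, nrow(cand)))
    }
    pick <- cand[sample(nrow(cand), n_needed), , drop = FALSE]
    other_classes <- rep(classes[classes != "promoter"],
                         times = cc[classes != "promoter"])
    w <- widths(n_needed)
    other <- tibble(chrom = pick$chrom,
                    start = pick$center - w %/% 2,
                    end = pick$center - w %/% 2 + w,
                    true_class = other_classes)

    regions <- bind_rows(prom, other)
    if (nrow(regions) == 0) {
      regions <- tibble(region_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        true_class = character(),
                        true_orientation = character())
    } else {
      regions <- regions %>%
        arrange(.data$chrom, .data$start) %>%
        mutate(region_id = sprintf("truth_%04d", row_number()),
               true_orientation = sample(c("left", "right"), dplyr::n(),
                                         replace = TRUE)) %>%
        select("region_id", "chrom", "start", "end", "true_class",
               "true_orientation")
    }

    # CpG sites: a ladder across each region center plus intergenic background
    mids <- floor((regions$start + regions$end) / 2)
    cpgs_reg <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      tibble(chrom = regions$chrom[i],
             pos = seq(mids[i] - 90, mids[i] + 90, by = 10))
    })
    cpgs_bg <- purrr::map_dfr(chroms, function(ch) {
      grid <- seq(1000, chrom_sizes[[ch]] - 1000, by = 50)
      tibble(chrom = ch,
             pos = sort(sample(grid, min(400, length(grid)))))
    })
    cpgs <- bind_rows(cpgs_reg, cpgs_bg) %>%
      distinct(.data$chrom, .data$pos) %>%
      arrange(.data$chrom, .data$pos)

    structure(
      list(chrom_sizes = chrom_sizes, genes = genes, tss = tss_tbl,
           regions = regions, cpgs = cpgs, class_counts = cc, seed = seed),
      class = "truth_catalog"
    )
  })
}

#' @export
print.truth_catalog <- function(x, ...) {
  cat(sprintf("<truth_catalog> %d chromosomes, %d genes, %d planted regions (seed %d)\n",
              length(x$chrom_sizes), nrow(x$genes), nrow(x$regions), x$seed))
  cc <- table(x$regions$true_class)
  for (cl in names(cc)) cat(sprintf("  %-20s %d\n", cl, cc[[cl]]))
  invisible(x)
}

#' Simulate one CUT&RUN fragment library
#'
#' Draws `depth` fragments from a uniform genomic background plus
#' Gaussian-around-center enrichment (sd 150 bp) at planted regions,
#' with per-(class, mark) multipliers from the archetype: the expected
#' per-bp fragment rate inside a region is `multiplier` times background.
#' Fragment lengths come from a three-component mixture (short,
#' mononucleosomal, long) so the 140--250 bp size filter is exercised.
#' The RNG stream is derived from (seed, mark), so libraries are
#' independent of one another.
#'
#' @param catalog A `truth_catalog`.
#' @param archetype A `signal_archetype` tibble (see
#'   [default_archetype()]).
#' @param mark Mark name present in the archetype (`"IgG"` for the
#'   all-background control).
#' @param depth Number of fragments to draw (> 0).
#' @param yeast_pairs Spike-in pair count carried on the library.
#' @param seed Master seed.
#' @return A `fragment_library`.
#' @export
simulate_cutrun_library <- function(catalog, archetype, mark, depth,
                                    yeast_pairs = 1e6, seed = 1) {
  if (depth <= 0) abort("depth must be > 0")
  arch <- as_tibble(archetype) %>% filter(.data$mark == .env$mark)
  if (nrow(arch) == 0) abort(paste0("mark not in archetype: ", mark))

  with_seed_local(derive_seed(seed, paste0("cutrun_", mark)), {
    regions <- catalog$regions %>%
      left_join(select(arch, "true_class", "multiplier"), by = "true_class")
    if (anyNA(regions$multiplier)) {
      abort("archetype lacks a multiplier for some planted class")
    }
    glen <- sum(catalog$chrom_sizes)
    wid <- regions$end - regions$start
    extra_w <- pmax(regions$multiplier - 1, 0) * wid
    probs <- c(glen, extra_w)
    alloc <- as.integer(rmultinom(1, depth, probs))

    # background: chromosome by length, position uniform
    n_bg <- alloc[1]
    bg_chrom <- sample(names(catalog$chrom_sizes), n_bg, replace = TRUE,
                       prob = catalog$chrom_sizes)
    bg_pos <- floor(runif(n_bg) * unname(catalog$chrom_sizes[bg_chrom]))

    # enrichment: Gaussian around region centers
    n_reg <- alloc[-1]
    idx <- rep(seq_len(nrow(regions)), n_reg)
    ctr <- floor((regions$start + regions$end) / 2)[idx]
    reg_pos <- round(rnorm(length(idx), mean = ctr, sd = 150))
    reg_chrom <- regions$chrom[idx]

    chrom <- c(bg_chrom, reg_chrom)
    pos <- c(bg_pos, reg_pos)

    # fragment length mixture: sub-140, mononucleosomal, over-250
    n <- length(pos)
    comp <- sample(1:3, n, replace = TRUE, prob = c(0.12, 0.73, 0.15))
    len <- round(ifelse(comp == 1, rnorm(n, 105, 15),
                        ifelse(comp == 2, rnorm(n, 190, 22),
                               rnorm(n, 320, 40))))
    len <- pmax(len, 30)
    start <- pos - len %/% 2
    end <- start + len
    clen <- unname(catalog$chrom_sizes[chrom])
    start <- pmax(start, 0)
    end <- pmin(end, clen)
    keep <- end > start
    frags <- tibble(chrom = chrom[keep], start = start[keep],
                    end = end[keep]) %>%
      arrange(.data$chrom, .data$start, .data$end)
    fragment_library(frags, mark = mark, total_mapped = depth,
                     yeast_pairs = yeast_pairs)
  })
}

#' Simulate a full CUT&RUN mark panel plus IgG control
#'
#' @param catalog A `truth_catalog`.
#' @param archetype Archetype tibble (default [default_archetype()]).
#' @param marks Marks to simulate (default [default_marks()]).
#' @param depth Fragments per library.
#' @param seed Master seed; each library derives its own stream.
#' @param yeast_pairs Spike-in pairs per library (recycled).
#' @return Named list of `fragment_library` objects including `IgG`.
#' @export
simulate_cutrun_panel <- function(catalog, archetype = default_archetype(),
                                  marks = default_marks(), depth = 2e5,
                                  seed = 1, yeast_pairs = 1e6) {
  all_marks <- c(marks, "IgG")
  yp <- rep(yeast_pairs, length.out = length(all_marks))
  libs <- purrr::map2(all_marks, yp, function(mk, y) {
    simulate_cutrun_library(catalog, archetype, mk, depth = depth,
                            yeast_pairs = y, seed = seed)
  })
  setNames(libs, all_marks)
}

#' Simulate strand-specific RNA-seq coverage
#'
#' Generates per-sample, per-strand coverage tracks on the RPKM scale:
#' exonic signal on gene bodies, directional transcription at a seeded
#' fraction of planted enhancer-class regions (signal placed downstream
#' of the region on the (+) strand for `right`-oriented regions, upstream
#' on the (-) strand for `left`), and sub-threshold background noise.
#'
#' @param catalog A `truth_catalog`.
#' @param transcribed_fraction Fraction of enhancer-class regions given
#'   directional signal (in \[0, 1\]).
#' @param n_samples Number of samples (>= 2).
#' @param seed Master seed.
#' @param signal_rpkm Mean directional signal (default 5 RPKM).
#' @param noise_rpkm Maximum background noise level (default 0.4 RPKM,
#'   below the 1-RPKM detection floor).
#' @return A list: `coverage` (tibble `sample`, `strand`, `chrom`,
#'   `start`, `end`, `value`), `transcribed` (region ids with planted
#'   signal).
#' @export
simulate_rnaseq <- function(catalog, transcribed_fraction, n_samples,
                            seed = 1, signal_rpkm = 5, noise_rpkm = 0.4) {
  if (transcribed_fraction < 0 || transcribed_fraction > 1) {
    abort("transcribed_fraction must be in [0, 1]")
  }
  if (n_samples < 2) abort("n_samples must be >= 2")

  enh <- catalog$regions %>%
    filter(.data$true_class %in% c("k4me1_enhancer", "k4me2_enhancer",
                                   "poised_enhancer"))
  transcribed <- with_seed_local(derive_seed(seed, "rnaseq_pick"), {
    n_t <- round(transcribed_fraction * nrow(enh))
    if (n_t > 0) sort(sample(enh$region_id, n_t)) else character(0)
  })
  tr <- filter(enh, .data$region_id %in% transcribed)

  cov <- purrr::map_dfr(seq_len(n_samples), function(s) {
    with_seed_local(derive_seed(seed, paste0("rnaseq_s", s)), {
      # directional enhancer signal
      dir_cov <- if (nrow(tr) > 0) {
        right <- tr$true_orientation == "right"
        tibble(
          strand = if_else(right, "+", "-"),
          chrom = tr$chrom,
          start = if_else(right, tr$end, tr$start - 800),
          end = if_else(right, tr$end + 800, tr$start),
          value = pmax(rnorm(nrow(tr), signal_rpkm, signal_rpkm / 10), 1.5)
        )
      } else tibble(strand = character(), chrom = character(),
                    start = numeric(), end = numeric(), value = numeric())
      # exonic gene-body signal on the gene strand
      ex <- catalog$genes %>%
        select("gene_id", "chrom", "strand", "exons") %>%
        tidyr::unnest("exons")
      exon_cov <- tibble(strand = ex$strand, chrom = ex$chrom,
                         start = ex$start, end = ex$end,
                         value = runif(nrow(ex), 1, 10))
      # background noise below the detection floor
      n_noise <- floor(sum(catalog$chrom_sizes) / 2e4)
      noise_chrom <- sample(names(catalog$chrom_sizes), n_noise,
                            replace = TRUE, prob = catalog$chrom_sizes)
      noise_start <- floor(runif(n_noise) *
                             (unname(catalog$chrom_sizes[noise_chrom]) - 200))
      noise_cov <- tibble(strand = sample(c("+", "-"), n_noise, replace = TRUE),
                          chrom = noise_chrom, start = noise_start,
                          end = noise_start + 200,
                          value = runif(n_noise, 0, noise_rpkm))
      bind_rows(dir_cov, exon_cov, noise_cov) %>%
        mutate(sample = sprintf("sample%02d", s)) %>%
        select("sample", "strand", "chrom", "start", "end", "value")
    })
  })
  list(coverage = cov, transcribed = transcribed)
}

#' Simulate bisulfite methylation tables for embryo, egg and sperm
#'
#' Draws per-CpG methylated/total counts at the catalog's CpG positions.
#' H3K4me2 enhancers and promoters are hypomethylated in the embryo;
#' a seeded `shared_fraction` of the H3K4me2 enhancers is also
#' hypomethylated in egg and sperm (the gamete-shared set); H3K4me1 and
#' poised enhancers and background CpGs are hypermethylated. A fraction
#' of sites is drawn at low depth so the depth-10 filter is exercised.
#'
#' @param catalog A `truth_catalog`.
#' @param seed Master seed.
#' @param shared_fraction Fraction of H3K4me2 enhancers hypomethylated in
#'   both gametes (default 0.69).
#' @param mean_depth Mean per-CpG depth (default 30).
#' @param low_depth_fraction Fraction of sites drawn at mean depth 5
#'   (default 0.1).
#' @param noise_sd Beta-noise spread around class methylation means; 0
#'   gives noiseless class levels (default 0.02).
#' @return A list: `tables` (named list of tibbles `chrom`, `pos`,
#'   `meth`, `total` for `embryo`, `egg`, `sperm`), `shared_regions`
#'   (ids of the planted gamete-shared set).
#' @export
simulate_methylomes <- function(catalog, seed = 1, shared_fraction = 0.69,
                                mean_depth = 30, low_depth_fraction = 0.1,
                                noise_sd = 0.02) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("shared_fraction must be in [0, 1]")
  }
  k4me2 <- catalog$regions$region_id[catalog$regions$true_class == "k4me2_enhancer"]
  shared <- with_seed_local(derive_seed(seed, "meth_shared"), {
    n_s <- round(shared_fraction * length(k4me2))
    if (n_s > 0) sort(sample(k4me2, n_s)) else character(0)
  })

  # class-level means per sample
  level_for <- function(true_class, region_id, sample) {
    embryo <- c(promoter = 0.05, k4me2_enhancer = 0.05,
                k4me1_enhancer = 0.92, poised_enhancer = 0.9,
                inactive = 0.85)
    gamete_base <- c(promoter = 0.1, k4me2_enhancer = 0.9,
                     k4me1_enhancer = 0.92, poised_enhancer = 0.9,
                     inactive = 0.85)
    if (sample == "embryo") return(unname(embryo[true_class]))
    lv <- unname(gamete_base[true_class])
    lv[region_id %in% shared] <- 0.05
    lv
  }

  # map each CpG to its covering region (if any)
  reg <- catalog$regions
  cpg <- catalog$cpgs
  pts <- tibble(chrom = cpg$chrom, start = cpg$pos, end = cpg$pos + 1)
  hits <- GenomicRanges::findOverlaps(as_granges0(pts), as_granges0(reg))
  cpg_class <- rep("background", nrow(cpg))
  cpg_region <- rep(NA_character_, nrow(cpg))
  cpg_class[S4Vectors::queryHits(hits)] <- reg$true_class[S4Vectors::subjectHits(hits)]
  cpg_region[S4Vectors::queryHits(hits)] <- reg$region_id[S4Vectors::subjectHits(hits)]

  tables <- purrr::map(c(embryo = "embryo", egg = "egg", sperm = "sperm"),
                       function(smp) {
    with_seed_local(derive_seed(seed, paste0("meth_", smp)), {
      mu <- rep(0.85, nrow(cpg))
      in_reg <- cpg_class != "background"
      mu[in_reg] <- level_for(cpg_class[in_reg], cpg_region[in_reg], smp)
      if (noise_sd > 0) {
        mu <- pmin(pmax(mu + rnorm(nrow(cpg), 0, noise_sd), 0), 1)
      }
      low <- runif(nrow(cpg)) < low_depth_fraction
      total <- rpois(nrow(cpg), if_else(low, 5, mean_depth))
      meth <- rbinom(nrow(cpg), total, mu)
      tibble(chrom = cpg$chrom, pos = cpg$pos, meth = meth, total = total)
    })
  })
  list(tables = tables, shared_regions = shared)
}

#' Simulate an expression time course and a crispant qRT-PCR plate
#'
#' The time course gives each gene a logistic activation on top of its
#' maternal baseline, with NPS-dependent (`down`) genes switching on
#' later than unaffected genes. The qRT-PCR plate draws three technical
#' replicate Ct values per embryo per gene (target and reference), with
#' the crispant group's target expression reduced `effect_fold`-fold
#' (target Ct shifted up by `log2(effect_fold)`).
#'
#' @param catalog A `truth_catalog`.
#' @param effect_fold True fold reduction of target expression in
#'   crispants (> 0; 1 = no effect).
#' @param n_embryos Embryos per group (>= 3).
#' @param seed Master seed.
#' @param ct_sd Technical-replicate Ct standard deviation (default 0.15).
#' @param embryo_sd Between-embryo delta-Ct standard deviation (default
#'   0.1).
#' @param timepoints Time points in hours post fertilization (first must
#'   be 0).
#' @return A list: `time_course` (tibble `gene_id`, `nps_class`, `time`,
#'   `expression`), `qpcr` (tibble `embryo_id`, `group`, `gene`,
#'   `replicate`, `ct`).
#' @export
simulate_expression_and_qpcr <- function(catalog, effect_fold = 1.7,
                                         n_embryos = 10, seed = 1,
                                         ct_sd = 0.15, embryo_sd = 0.1,
                                         timepoints = c(0, 2.5, 3.3, 4, 4.7, 6)) {
  if (effect_fold <= 0) abort("effect_fold must be > 0")
  if (n_embryos < 3) abort("need >= 3 embryos per group")
  if (timepoints[1] != 0) abort("first timepoint must be 0")

  tc <- with_seed_local(derive_seed(seed, "timecourse"), {
    purrr::map_dfr(seq_len(nrow(catalog$genes)), function(i) {
      g <- catalog$genes[i, ]
      onset <- if (g$nps_class == "down") 3.3 else 2.5
      amp <- runif(1, 4, 12)
      act <- amp / (1 + exp(-(timepoints - onset) / 0.4))
      expr <- pmax(g$two_cell_rpkm + act + rnorm(length(timepoints), 0, 0.1), 0)
      tibble(gene_id = g$gene_id, nps_class = g$nps_class,
             time = timepoints, expression = expr)
    })
  })

  qpcr <- with_seed_local(derive_seed(seed, "qpcr"), {
    purrr::map_dfr(c("control", "crispant"), function(grp) {
      purrr::map_dfr(seq_len(n_embryos), function(e) {
        ref_mu <- rnorm(1, 18, 0.3)
        dct <- 2 + rnorm(1, 0, embryo_sd) +
          if (grp == "crispant") log2(effect_fold) else 0
        tibble(
          embryo_id = sprintf("%s_%02d", grp, e), group = grp,
          gene = rep(c("reference", "target"), each = 3),
          replicate = rep(1:3, 2),
          ct = c(rnorm(3, ref_mu, ct_sd), rnorm(3, ref_mu + dct, ct_sd))
        )
      })
    })
  })
  list(time_course = tc, qpcr = qpcr)
}

#' Simulate genome sequence with planted motif sites
#'
#' I.i.d. bases at a configurable GC fraction per chromosome, with the
#' consensus sequence of chosen PWMs planted at region midpoints so motif
#' scanning can be verified against known ground truth.
#'
#' @param catalog A `truth_catalog`.
#' @param seed Master seed.
#' @param gc GC fraction of the background sequence (default 0.4).
#' @param plant Optional tibble `region_id`, `pwm_name`; each row plants
#'   one forward-strand consensus site at that region's midpoint.
#' @param pwms List of `pwm` objects (required when `plant` is given).
#' @return Named character vector of chromosome sequences.
#' @export
simulate_genome_sequence <- function(catalog, seed = 1, gc = 0.4,
                                     plant = NULL, pwms = NULL) {
  seqs <- with_seed_local(derive_seed(seed, "genome"), {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    purrr::map(catalog$chrom_sizes, function(len) {
      paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
    })
  })
  if (!is.null(plant)) {
    if (is.null(pwms)) abort("pwms must be supplied to plant sites")
    names(pwms) <- purrr::map_chr(pwms, "name")
    plant <- as_tibble(plant)
    for (i in seq_len(nrow(plant))) {
      pw <- pwms[[plant$pwm_name[i]]]
      if (is.null(pw)) abort(paste0("unknown pwm: ", plant$pwm_name[i]))
      consensus <- paste(c("A", "C", "G", "T")[apply(pw$prob, 2, which.max)],
                         collapse = "")
      r <- catalog$regions[catalog$regions$region_id == plant$region_id[i], ]
      if (nrow(r) != 1) abort(paste0("unknown region: ", plant$region_id[i]))
      mid <- floor((r$start + r$end) / 2)
      at <- mid - nchar(consensus) %/% 2
      substr(seqs[[r$chrom]], at + 1, at + nchar(consensus)) <- consensus
    }
  }
  unlist(seqs)
}
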