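fake_features <- function(n_regions, marks) {
  tidyr::expand_grid(region_id = sprintf("r%03d", seq_len(n_regions)),
                     mark = marks) |>
    dplyr::mutate(u = runif(dplyr::n()), c = runif(dplyr::n()),
                  d = runif(dplyr::n()),
                  u_rpkm = u, d_rpkm = d)
}

test_that("feature matrix has three columns per mark in declared order", {
  set.seed(1)
  marks10 <- sprintf("mark%02d", 1:10)
  fm <- assemble_feature_matrix(fake_features(12, marks10))
  expect_equal(ncol(fm) - 1, 30)
  expect_equal(names(fm)[2:4], c("mark01_u", "mark01_c", "mark01_d"))
  fm1 <- assemble_feature_matrix(fake_features(5, "m1"))
  expect_equal(dim(fm1), c(5, 4))
  # a region missing one mark is an error naming the region
  broken <- fake_features(3, c("m1", "m2"))[-1, ]
  expect_error(assemble_feature_matrix(broken), "r001")
})

test_that("feature matrix column order survives a write/read round trip", {
  set.seed(2)
  fm <- assemble_feature_matrix(fake_features(6, c("a", "b")))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(fm, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), names(fm))
  expect_equal(as.data.frame(back), as.data.frame(fm), tolerance = 1e-12)
})

test_that("PCA is centered, sign-fixed, and reconstructs the data", {
  # exact line in 2D: PC1 explains everything
  line <- tibble::tibble(region_id = sprintf("r%d", 1:20),
                         x = 1:20, y = 2 * (1:20) + 3)
  class(line) <- c("feature_matrix", class(line))
  pca <- run_pca(line)
  expect_equal(pca$var_explained[1], 1)
  expect_equal(sum(pca$var_explained), 1)

  # random matrix: full-rank reconstruction from scores and loadings
  set.seed(3)
  m <- tibble::as_tibble(matrix(rnorm(300), 50, 6),
                         .name_repair = ~ sprintf("f%d", 1:6))
  m$region_id <- sprintf("r%02d", 1:50)
  pca2 <- run_pca(m)
  scores <- as.matrix(pca2$scores[paste0("PC", 1:6)])
  recon <- scores %*% t(pca2$loadings) +
    matrix(pca2$center, 50, 6, byrow = TRUE)
  expect_lt(max(abs(recon - as.matrix(m[sprintf("f%d", 1:6)]))), 1e-8)
  # sign convention: largest-magnitude loading per component is positive
  for (k in 1:6) {
    expect_gt(pca2$loadings[which.max(abs(pca2$loadings[, k])), k], 0)
  }
  const <- tibble::tibble(region_id = c("a", "b"), f1 = 1, f2 = 1)
  expect_error(run_pca(const), "variance")
})

test_that("SVM separates toy clusters and refuses single-class training", {
  set.seed(4)
  scores <- tibble::tibble(
    region_id = sprintf("r%03d", 1:80),
    PC1 = c(rnorm(40, -4, 0.3), rnorm(40, 4, 0.3)),
    PC2 = rnorm(80, 0, 0.3), PC3 = rnorm(80, 0, 0.3)
  )
  labels <- tibble::tibble(region_id = scores$region_id,
                           label = rep(c("enhancer", "promoter"), each = 40))
  clf <- fit_region_classifier(scores, labels)
  pred <- classify_and_flag(
    clf, scores,
    tibble::tibble(region_id = scores$region_id,
                   anno_class = rep(c("distal", "promoter"), each = 40)))
  expect_equal(mean(pred$svm_label == labels$label), 1)
  expect_error(fit_region_classifier(scores, labels[1:40, ]), "both classes")
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  set.seed(5)
  n <- 200
  scores <- tibble::tibble(
    region_id = sprintf("r%03d", 1:n),
    PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n)
  )
  labels <- tibble::tibble(region_id = scores$region_id,
                           label = sample(rep(c("enhancer", "promoter"), n / 2)))
  # 2-fold: train on half, evaluate on the other half
  accs <- vapply(1:4, function(rep) {
    idx <- sample(n, n / 2)
    clf <- fit_region_classifier(scores[idx, ], labels[idx, ])
    pred <- classify_and_flag(
      clf, scores[-idx, ],
      tibble::tibble(region_id = scores$region_id[-idx], anno_class = "distal"))
    mean(pred$svm_label == labels$label[-idx])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("mismatch flags cross SVM labels with annotation and partition regions", {
  scores <- tibble::tibble(region_id = sprintf("r%d", 1:6),
                           PC1 = c(-3, -3, 3, 3, -3, 3),
                           PC2 = 0, PC3 = 0)
  labels <- tibble::tibble(region_id = c("r1", "r3"),
                           label = c("enhancer", "promoter"))
  clf <- fit_region_classifier(scores, labels)
  anno <- tibble::tibble(
    region_id = sprintf("r%d", 1:6),
    anno_class = c("distal", "distal", "promoter", "promoter",
                   "proximal", "distal"))
  out <- classify_and_flag(clf, scores, anno)
  expect_equal(out$mismatch[out$region_id == "r1"], "typical_enhancer")
  expect_equal(out$mismatch[out$region_id == "r3"], "typical_promoter")
  expect_equal(out$mismatch[out$region_id == "r5"], "n/a")
  expect_equal(out$mismatch[out$region_id == "r6"], "promoter_like_enhancer")
  pd <- out[out$anno_class %in% c("promoter", "distal"), ]
  expect_false(any(pd$mismatch == "n/a"))
})

test_that("distal regions with promoter-like signal are flagged promoter-like", {
  # plant k4me2 enhancers with the promoter archetype so their histone
  # profile is indistinguishable from promoters; the positional annotation
  # still says distal, so the SVM should flag them as promoter-like
  arch <- default_archetype()
  prom <- arch[arch$true_class == "promoter", ]
  arch$multiplier[arch$true_class == "k4me2_enhancer"] <-
    prom$multiplier[match(arch$mark[arch$true_class == "k4me2_enhancer"],
                          prom$mark)]
  cat_ <- make_truth_catalog(
    c(promoter = 90, k4me1_enhancer = 60, k4me2_enhancer = 30, inactive = 40),
    seed = 19, chrom_sizes = c(chr1 = 3e6, chr2 = 3e6), n_genes = 90)
  libs <- simulate_cutrun_panel(cat_, archetype = arch, depth = 3e5, seed = 19)
  igg <- libs$IgG; libs$IgG <- NULL
  anno <- annotate_regions(cat_$regions, select_gene_tss(cat_$tss),
                           cat_$chrom_sizes)
  disc <- discover_enhancers(libs, igg, anno)
  calls <- dplyr::left_join(disc$calls,
                            cat_$regions[, c("region_id", "true_class")],
                            by = "region_id")
  k4me2 <- calls[calls$true_class == "k4me2_enhancer", ]
  expect_gte(mean(k4me2$mismatch == "promoter_like_enhancer"), 0.9)
})

test_that("refined classes follow the fold-threshold table", {
  anno <- tibble::tibble(region_id = sprintf("r%d", 1:6),
                         anno_class = c(rep("distal", 4), "proximal", "proximal"))
  folds <- tibble::tibble(
    region_id = anno$region_id,
    H3K4me1 = c(3, 3, 3, 1, 1, 1),
    H3K27ac = c(2, 2, 1.2, 2, 1, 1),
    H3K4me2 = c(2.5, 1.0, 1.0, 3, 2.5, 1),
    H3K4me3 = c(1, 1, 1, 1, 1.0, 2)
  )
  out <- refine_enhancer_classes(folds, anno)
  expect_equal(out$refined,
               c("k4me2_enhancer", "k4me1_enhancer", "poised_enhancer",
                 "unclassified", "proximal_potential_enhancer",
                 "unclassified"))
  expect_true(out$k4me2_flag[5])   # proximal with H3K4me2 >= 2
  expect_false(out$k4me2_strict[1])  # 2.5 is not > 3
  expect_true(refine_enhancer_classes(
    dplyr::mutate(folds[1, ], H3K4me2 = 3.5), anno[1, ])$k4me2_strict)
  expect_error(refine_enhancer_classes(folds[, 1:3], anno), "missing fold")
})

test_that("refined classes match a table-driven oracle on random folds", {
  set.seed(6)
  n <- 500
  folds <- tibble::tibble(
    region_id = sprintf("r%03d", 1:n),
    H3K4me1 = runif(n, 0, 4), H3K27ac = runif(n, 0, 3),
    H3K4me2 = runif(n, 0, 4), H3K4me3 = runif(n, 0, 3)
  )
  anno <- tibble::tibble(region_id = folds$region_id,
                         anno_class = sample(c("distal", "proximal", "promoter"),
                                             n, replace = TRUE))
  out <- refine_enhancer_classes(folds, anno)
  oracle <- function(a, k1, k27, k2, k3) {
    if (a == "distal") {
      if (k1 >= 2 && k27 >= 1.5) {
        if (k2 >= 2) return("k4me2_enhancer")
        if (k2 < 1.25) return("k4me1_enhancer")
        return("unclassified")
      }
      if (k1 >= 2 && k27 <= 1.5) return("poised_enhancer")
      return("unclassified")
    }
    if (a == "proximal" && k3 < 1.25) return("proximal_potential_enhancer")
    "unclassified"
  }
  want <- mapply(oracle, anno$anno_class, folds$H3K4me1, folds$H3K27ac,
                 folds$H3K4me2, folds$H3K4me3)
  expect_equal(out$refined, unname(want))
  # classes are mutually exclusive by construction (single label per region)
  expect_equal(nrow(out), n)
})

test_that("KDE grid matches direct kernel sums, integrates to ~1, peaks at the cluster", {
  set.seed(7)
  x <- rnorm(30, 2, 0.5); y <- rnorm(30, -1, 0.5)
  lims <- c(range(x), range(y))
  k <- kde_contours(x, y, h = 3, n = 40, lims = lims)
  expect_equal(dim(k$z), c(40, 40))
  b <- brute_kde_grid(x, y, h = 3, n = 40, lims = lims)
  expect_lt(max(abs(k$z - b$z)), 1e-10)
  # default grid is 125 x 125
  expect_equal(dim(kde_contours(x, y)$z), c(125, 125))
  # tight cluster: maximum near the data mean on a wide grid
  kt <- kde_contours(rnorm(50, 0, 0.05), rnorm(50, 0, 0.05), h = 1, n = 61,
                     lims = c(-3, 3, -3, 3))
  peak <- which(kt$z == max(kt$z), arr.ind = TRUE)
  expect_lt(abs(kt$x[peak[1]]), 0.2)
  expect_lt(abs(kt$y[peak[2]]), 0.2)
  # trapezoid integral close to 1 on a generous grid
  kk <- kde_contours(rnorm(100), rnorm(100), h = 3, n = 80,
                     lims = c(-5, 5, -5, 5))
  dx <- diff(kk$x[1:2]); dy <- diff(kk$y[1:2])
  expect_lt(abs(sum(kk$z) * dx * dy - 1), 0.01)
  expect_error(kde_contours(1, numeric(0)), "points")
})
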