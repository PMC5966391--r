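counts_tbl <- function(values, samples, features = NULL) {
  m <- if (is.matrix(values)) values else {
    matrix(values, ncol = length(samples), byrow = TRUE)
  }
  colnames(m) <- samples
  features <- features %||% sprintf("f%02d", seq_len(nrow(m)))
  tibble::add_column(tibble::as_tibble(m), feature = features, .before = 1)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

design_33 <- tibble::tibble(
  sample = c(paste0("G1_", 1:3), paste0("G2_", 1:3), paste0("G3_", 1:3)),
  population = rep(c("G1", "G2", "G3"), each = 3),
  replicate = rep(1:3, 3))

test_that("expression filter applies the two population rules", {
  x <- counts_tbl(rbind(
    c(6, 7, 9, 0, 1, 2, 0, 0, 0),     # G1 qualifies under both rules
    c(4, 50, 1, 0, 0, 0, 0, 0, 0),    # mean 18.3 but a replicate < 5
    c(0, 0, 0, 0, 0, 0, 0, 0, 0)),    # all zero
    design_33$sample)
  strict <- filter_expressed(x, design_33, rule = "strict")
  meano <- filter_expressed(x, design_33, rule = "mean_only")
  expect_equal(strict$feature, "f01")
  expect_setequal(meano$feature, c("f01", "f02"))
  expect_error(filter_expressed(x, design_33, min_reads = -1), ">= 0")
})

test_that("strict-filtered features are a subset of mean-only features", {
  for (seed in 1:10) {
    x <- withr::with_seed(seed, counts_tbl(
      stats::rnbinom(20 * 9, mu = 6, size = 2), design_33$sample))
    s <- filter_expressed(x, design_33, rule = "strict")$feature
    m <- filter_expressed(x, design_33, rule = "mean_only")$feature
    expect_true(all(s %in% m))
  }
})

test_that("CPM normalization scales columns to one million", {
  x <- counts_tbl(rbind(c(200, 0), c(1999800, 100)), c("s1", "s2"))
  cpm <- cpm_normalize(x)
  expect_equal(cpm$s1[1], 100)          # 200 / 2e6 * 1e6
  expect_equal(cpm$s2[1], 0)
  expect_equal(colSums(as.matrix(cpm[c("s1", "s2")])), c(s1 = 1e6, s2 = 1e6))
  expect_warning(cpm_normalize(counts_tbl(rbind(c(1, 0)), c("a", "b"))),
                 "all-zero")
})

test_that("median-of-ratios size factors recover scalar multiples", {
  a <- c(10, 100, 1000, 50)
  x <- counts_tbl(cbind(a, 2 * a), c("s1", "s2"), sprintf("f%d", 1:4))
  sf <- estimate_size_factors(x)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- estimate_size_factors(
    counts_tbl(cbind(a, a, a), c("s1", "s2", "s3"), sprintf("f%d", 1:4)))
  expect_equal(same$size_factor, rep(1, 3))

  single <- estimate_size_factors(counts_tbl(cbind(a), "s1",
                                             sprintf("f%d", 1:4)))
  expect_equal(single$size_factor, 1)

  disjoint <- counts_tbl(rbind(c(5, 0), c(0, 5)), c("s1", "s2"))
  expect_error(estimate_size_factors(disjoint), "pseudocount")
})

test_that("identical groups give log2FC 0 and p 1", {
  x <- counts_tbl(rbind(c(10, 10, 10, 10, 10, 10),
                        c(7, 9, 8, 7, 9, 8)),
                  design_33$sample[1:6])
  de <- differential_expression(x, design_33, "G1", "G2")
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$pvalue, c(1, 1))
})

test_that("differential expression is antisymmetric in the group order", {
  x <- withr::with_seed(11, counts_tbl(
    stats::rnbinom(50 * 6, mu = 100, size = 5), design_33$sample[1:6]))
  ab <- differential_expression(x, design_33, "G1", "G2")
  ba <- differential_expression(x, design_33, "G2", "G1")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$pvalue, ba$pvalue)
  expect_equal(ab$base_mean_a, ba$base_mean_b)
})

test_that("planted log2FC 4 at mean >= 50 has the right sign >= 99%", {
  cfg <- simulation_config(seed = 21, n_features = 500, de_n = 100,
                           de_log2fc = 4, de_mean_range = c(50, 2000),
                           traj_per_shape = 0L,
                           populations = c("PSC", "CM"),
                           de_population = "CM")
  cs <- simulate_counts(cfg)
  de <- differential_expression(cs$counts, cs$design, "PSC", "CM")
  planted <- de$log2fc[cs$truth$de]
  expect_gte(mean(planted > 0), 0.99)
})

test_that("DE errors without two replicates per group", {
  x <- counts_tbl(rbind(c(10, 10, 10, 10)),
                  c("G1_1", "G1_2", "G1_3", "G2_1"))
  expect_error(differential_expression(x, design_33, "G1", "G2"),
               "replicates")
})

test_that("volcano labels follow the fold and p cuts", {
  de <- tibble::tibble(feature = c("a", "b", "c", "d"),
                       log2fc = c(4.2, -3.5, 2.9, 3.5),
                       pvalue = c(0.001, 0.005, 1e-6, 0.05),
                       padj = c(0.01, 0.02, 1e-4, 0.2))
  lab <- volcano_classify(de)
  expect_equal(lab$label, c("up", "down", "ns", "ns"))
  lab2 <- volcano_classify(de, use = "padj", p_cut = 0.05)
  expect_equal(lab2$label, c("up", "down", "ns", "ns"))
})

test_that("BH adjustment is monotone in p", {
  x <- withr::with_seed(5, counts_tbl(
    stats::rnbinom(100 * 6, mu = 50, size = 2), design_33$sample[1:6]))
  de <- differential_expression(x, design_33, "G1", "G2")
  ord <- order(de$pvalue)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
  expect_true(all(de$padj >= de$pvalue - 1e-12))
})

test_that("sample distances are Euclidean, symmetric, zero on the diagonal", {
  k <- 9
  m <- counts_tbl(cbind(rep(0, k), rep(1, k), rep(0, k)),
                  c("a", "b", "c"), sprintf("f%d", 1:k))
  d <- sample_distances(m)
  dd <- function(x, y) d$distance[d$sample_a == x & d$sample_b == y]
  expect_equal(dd("a", "a"), 0)
  expect_equal(dd("a", "c"), 0)            # identical samples
  expect_equal(dd("a", "b"), sqrt(k))      # +1 on each of k features
  expect_equal(dd("b", "a"), dd("a", "b")) # symmetry
})

test_that("PCA orders components and reconstructs distances at full rank", {
  # samples on a 1-D line in feature space
  line <- counts_tbl(outer(c(1, 2, 5), c(1, 2, 3, 4)),
                     sprintf("s%d", 1:4) , sprintf("f%d", 1:3))
  p1 <- pca_project(line, n_components = 2)
  expect_gt(p1$explained$variance_fraction[1], 0.999)

  x <- withr::with_seed(2, counts_tbl(matrix(stats::rnorm(8 * 6), 8),
                                      sprintf("s%d", 1:6)))
  full <- pca_project(x, n_components = 5)
  expect_true(all(diff(full$explained$variance_fraction) <= 1e-12))
  # full-rank scores reproduce pairwise sample distances
  sc <- as.matrix(full$scores[-1])
  got <- as.matrix(stats::dist(sc))
  want <- as.matrix(stats::dist(t(as.matrix(x[-1]))))
  dimnames(got) <- dimnames(want)
  expect_equal(got, want, tolerance = 1e-8)

  expect_error(pca_project(x, n_components = 6), "n_components")
})
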