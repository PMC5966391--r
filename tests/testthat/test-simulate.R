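test_that("simulated references parse and plant clusters and families", {
  cfg <- simulation_config(seed = 5)
  sim <- simulate_reference(cfg, withr::local_tempdir())
  ref <- sim$reference
  expect_s3_class(ref, "mirna_reference")

  cl <- detect_genomic_clusters(ref)
  fam <- group_families(ref)
  # every planted cluster is found with exactly its members
  for (i in seq_len(nrow(sim$truth$clusters))) {
    want <- sim$truth$clusters$members[[i]]
    hit <- purrr::detect(cl$members, ~ setequal(.x, want))
    expect_false(is.null(hit))
  }
  # shared-seed plans produce one family == cluster
  shared <- sim$truth$matures |>
    dplyr::filter(!is.na(cluster_id)) |>
    dplyr::group_by(cluster_id) |>
    dplyr::summarise(n_seeds = dplyr::n_distinct(seed),
                     n = dplyr::n())
  planted_shared <- shared$cluster_id[shared$n_seeds == 1 & shared$n > 1]
  expect_gt(length(planted_shared), 0)
  for (cid in planted_shared) {
    members <- sim$truth$matures$mature_name[
      which(sim$truth$matures$cluster_id == cid)]
    expect_true(any(purrr::map_lgl(fam$members, ~ setequal(.x, members))))
  }
})

test_that("hairpins two cluster-gaps beyond the threshold do not cluster", {
  cfg <- simulation_config(
    seed = 6,
    cluster_plan = list(list(chrom = "chr1", n = 2L, gap = 20001L,
                             shared_seed = FALSE)),
    singleton_plan = c(chr2 = 1L))
  sim <- simulate_reference(cfg, withr::local_tempdir())
  cl <- detect_genomic_clusters(sim$reference)
  # the two far-apart hairpins may cluster internally (5p/3p of one
  # hairpin are close) but never across the 20 kb gap
  hp_of <- stats::setNames(sim$reference$matures$hairpin_id,
                           sim$reference$matures$mature_name)
  for (m in cl$members) {
    expect_length(unique(hp_of[m]), 1L)
  }
})

test_that("an infeasible cluster plan errors", {
  cfg <- simulation_config(
    seed = 1, chrom_length = 5000,
    cluster_plan = list(list(chrom = "chr1", n = 3L, gap = 9000L,
                             shared_seed = FALSE)),
    singleton_plan = c(chr2 = 1L))
  expect_error(simulate_reference(cfg, withr::local_tempdir()),
               "infeasible")
})

test_that("simulated reads stay within tolerance and carry truth", {
  cfg <- simulation_config(seed = 8, reads_per_mature = 8L)
  ref <- simulate_reference(cfg, withr::local_tempdir())$reference
  sim <- simulate_reads(cfg, ref)
  expect_equal(nrow(sim$reads), nrow(sim$truth))
  expect_true(all(abs(sim$truth$shift5) <= 3))
  expect_true(all(abs(sim$truth$shift3) <= 3))
  # every read has at least one positive count
  cnt <- as.matrix(sim$reads[setdiff(names(sim$reads),
                                     c("read_id", "sequence"))])
  expect_true(all(rowSums(cnt) > 0))
  # truth covers every emitted record exactly once
  expect_equal(anyDuplicated(sim$truth$sequence), 0L)
})

test_that("exact-only configuration classifies everything as exact", {
  cfg <- simulation_config(
    seed = 9, reads_per_mature = 4L, sub_rate = 0, adar_n_sites = 0L,
    class_probs = c(exact = 1, iso5 = 0, iso3 = 0, iso5_iso3 = 0))
  ref <- simulate_reference(cfg, withr::local_tempdir())$reference
  sim <- simulate_reads(cfg, ref)
  tab <- call_isomirs(sim$reads, ref)
  expect_equal(nrow(tab$unassigned), 0L)
  expect_true(all(tab$calls$iso_class == "exact"))
  # zero ADAR plan leads to zero detected sites
  ad <- detect_adar(tab, ref)
  expect_equal(nrow(ad$sites), 0L)
})

test_that("collapsed FASTA round-trips through read_collapsed_fasta", {
  cfg <- simulation_config(seed = 10, reads_per_mature = 6L)
  ref <- simulate_reference(cfg, withr::local_tempdir())$reference
  dir <- withr::local_tempdir()
  sim <- simulate_reads(cfg, ref, dir = dir)
  manifest <- tibble::tibble(sample = names(sim$paths),
                             file = unname(sim$paths))
  back <- read_collapsed_fasta(manifest)
  samples <- manifest$sample
  a <- dplyr::arrange(sim$reads, sequence)[c("sequence", samples)]
  b <- dplyr::arrange(back, sequence)[c("sequence", samples)]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("simulated counts match their NB means in the Poisson limit", {
  cfg <- simulation_config(seed = 12, n_features = 1000, de_n = 0L,
                           traj_per_shape = 0L,
                           mean_range = c(100, 100),
                           dispersion_range = c(1e-8, 1e-8),
                           populations = c("A", "B"))
  cs <- simulate_counts(cfg)
  m <- as.matrix(cs$counts[-1])
  # Poisson mode: grand mean within 3 standard errors of 100
  se <- sqrt(100 / length(m))
  expect_lt(abs(mean(m) - 100), 3 * se)
})

test_that("score tables plant the configured overlap structure", {
  cfg <- simulation_config(seed = 13)
  sim <- simulate_score_table(cfg)
  expect_true(all(sim$table$score >= 0 & sim$table$score <= 1))
  targets <- filter_targets(sim$table, 0.8)
  sets <- split(targets$gene, targets$predictor)
  expect_equal(sort(sets$A), sim$truth$A)
  expect_equal(length(intersect(sets$A, sets$B)), 30L)
  expect_equal(length(intersect(sets$A, sets$C)), 10L)
  ov <- overlap_counts(sets[c("A", "B")])
  expect_equal(ov$count[ov$region == "A_B"], 30L)
  expect_equal(ov$count[ov$region == "A_only"], 70L)
  expect_equal(ov$count[ov$region == "B_only"], 70L)

  bad <- simulation_config(seed = 1, score_sizes = c(A = 10L, B = 10L),
                           score_overlaps = c(A_B = 30L))
  expect_error(simulate_score_table(bad), "inconsistent")

  ident <- simulation_config(seed = 2, score_sizes = c(A = 20L, B = 20L),
                             score_overlaps = c(A_B = 20L))
  tab2 <- simulate_score_table(ident)
  sc <- score_correlation(
    dplyr::filter(tab2$table, .data$score > 0.8) |>
      dplyr::distinct(.data$gene, .data$predictor, .keep_all = TRUE))
  expect_gt(sc$n_common[1], 2)
})

test_that("all generators are deterministic given the seed", {
  cfg <- simulation_config(seed = 99, reads_per_mature = 5L,
                           n_features = 50L, de_n = 5L,
                           traj_per_shape = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_reference(cfg, d1); r2 <- simulate_reference(cfg, d2)
  for (f in names(r1$paths)) {
    expect_identical(readLines(r1$paths[[f]]), readLines(r2$paths[[f]]))
  }
  s1 <- simulate_reads(cfg, r1$reference, file.path(d1, "reads"))
  s2 <- simulate_reads(cfg, r2$reference, file.path(d2, "reads"))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  for (sm in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[sm]]), readLines(s2$paths[[sm]]))
  }
  c1 <- simulate_counts(cfg); c2 <- simulate_counts(cfg)
  expect_identical(c1$counts, c2$counts)
  t1 <- simulate_score_table(cfg); t2 <- simulate_score_table(cfg)
  expect_identical(t1$table, t2$table)
  p1 <- simulate_trajectory_profiles(cfg)
  p2 <- simulate_trajectory_profiles(cfg)
  expect_identical(p1$profiles, p2$profiles)
})
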