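test_that("classification handles canonical, trimmed, tailed and substituted reads", {
  ref <- tiny_ref()
  canon <- "UGAGGUAGUAGGUUGUAUAGUU"

  exact <- classify_read(canon, ref)
  expect_equal(exact$mature_name, "tst-let7a")
  expect_equal(exact$iso_class, "exact")
  expect_equal(c(exact$shift5, exact$shift3), c(0L, 0L))
  expect_equal(exact$n_sub, 0L)

  trim <- classify_read(substr(canon, 1, 20), ref)
  expect_equal(trim$iso_class, "iso3")
  expect_equal(trim$shift3, -2L)

  # hairpin continues "CC" after the mature: +CC is a templated addition
  templ <- classify_read(paste0(canon, "CC"), ref)
  expect_equal(templ$shift3, 2L)
  expect_true(templ$added3_templated)
  expect_equal(templ$n_sub, 0L)

  nontempl <- classify_read(paste0(canon, "AA"), ref)
  expect_equal(nontempl$shift3, 2L)
  expect_false(nontempl$added3_templated)
  expect_equal(nontempl$n_sub, 0L)   # tail mismatches are not substitutions

  sub <- classify_read("UGAGGUAGUGGGUUGUAUAGUU", ref)  # A->G at pos 10
  expect_equal(sub$iso_class, "exact")
  expect_equal(sub$n_sub, 1L)
  expect_equal(sub$sub_pos, 10L)
  expect_equal(c(sub$sub_ref, sub$sub_alt), c("A", "G"))

  over <- classify_read(paste0(canon, "UUUU"), ref)   # 4 nt beyond bounds
  expect_true("reason" %in% names(over))
  expect_match(over$reason, "shift exceeds")
})

test_that("classify_read agrees with the brute-force oracle on enumerated reads", {
  ref <- tiny_ref()
  reads <- oracle_enumerate_reads(ref)
  expect_gt(length(reads), 400)
  tab <- call_isomirs(tibble::tibble(
    read_id = paste0("e", seq_along(reads)), sequence = reads, n = 1), ref)
  got <- dplyr::bind_rows(
    tab$calls[c("read_id", "mature_name", "shift5", "shift3", "n_sub",
                "sub_pos", "added5_templated", "added3_templated")],
    tab$unassigned["read_id"])
  got <- got[match(paste0("e", seq_along(reads)), got$read_id), ]
  for (i in seq_along(reads)) {
    want <- oracle_classify(reads[i], ref)
    if (is.null(want)) {
      expect_true(is.na(got$mature_name[i]), label = reads[i])
    } else {
      expect_equal(got$mature_name[i], want$mature_name, label = reads[i])
      expect_equal(got$shift5[i], want$shift5, label = reads[i])
      expect_equal(got$shift3[i], want$shift3, label = reads[i])
      expect_equal(got$n_sub[i], want$n_sub, label = reads[i])
      expect_equal(got$sub_pos[i], want$sub_pos, label = reads[i])
      expect_equal(got$added5_templated[i], want$added5_templated,
                   label = reads[i])
      expect_equal(got$added3_templated[i], want$added3_templated,
                   label = reads[i])
    }
  }
})

test_that("every canonical mature classifies as exact to itself", {
  cfg <- simulation_config(seed = 3)
  ref <- simulate_reference(cfg, withr::local_tempdir())$reference
  tab <- call_isomirs(tibble::tibble(
    read_id = ref$matures$mature_name, sequence = ref$matures$sequence,
    n = 1), ref)
  expect_equal(nrow(tab$unassigned), 0L)
  expect_true(all(tab$calls$iso_class == "exact"))
  expect_equal(tab$calls$mature_name, tab$calls$read_id)
})

test_that("call_isomirs merges duplicates and conserves counts", {
  ref <- tiny_ref()
  canon <- "UGAGGUAGUAGGUUGUAUAGUU"
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    sequence = c(canon, substr(canon, 1, 21), canon,
                 paste0(rep("ACGU", 6), collapse = "")),
    s1 = c(2, 7, 3, 5), s2 = c(1, 0, 0, 2))
  expect_warning(tab <- call_isomirs(reads, ref), "merged")
  expect_equal(nrow(tab$calls) + nrow(tab$unassigned), 3L)
  merged <- tab$calls[tab$calls$iso_class == "exact", ]
  expect_equal(merged$s1, 5)
  expect_equal(merged$s2, 1)
  # count conservation per sample
  expect_equal(sum(tab$calls$s1) + sum(tab$unassigned$s1), sum(reads$s1))
  expect_equal(sum(tab$calls$s2) + sum(tab$unassigned$s2), sum(reads$s2))

  empty <- call_isomirs(reads[0, ], ref)
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(nrow(empty$unassigned), 0L)
})

test_that("isoform class counts tally sequences and expression", {
  ref <- tiny_ref()
  canon <- "UGAGGUAGUAGGUUGUAUAGUU"
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = c(canon, substr(canon, 1, 21), substr(canon, 1, 20)),
    s1 = c(10, 5, 2))
  tab <- call_isomirs(reads, ref)
  cc <- isoform_class_counts(tab)
  expect_equal(cc$n_sequences[cc$iso_class == "exact"], 1L)
  expect_equal(cc$n_sequences[cc$iso_class == "iso3"], 2L)
  expect_equal(cc$n_sequences[cc$iso_class == "iso5"], 0L)
  expect_equal(sum(cc$expression), sum(reads$s1))  # conservation
})

test_that("end position histogram is additive and excludes shift 0", {
  ref <- tiny_ref()
  canon <- "UGAGGUAGUAGGUUGUAUAGUU"
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = c(substr(canon, 1, 21),          # shift3 -1
                 substr(canon, 4, 22),          # shift5 -3
                 substr(canon, 4, 22)),         # duplicate; merged
    s1 = c(7, 5, 2))
  expect_warning(tab <- call_isomirs(reads, ref), "merged")
  h <- end_position_summary(tab)
  expect_equal(h$expression[h$end == "3p" & h$shift == -1L], 7)
  expect_equal(h$expression[h$end == "5p" & h$shift == -3L], 7)
  expect_false(any(h$shift == 0L))
})

test_that("substitution spectrum reports DNA-space categories", {
  ref <- tiny_ref()
  canon <- "UGAGGUAGUAGGUUGUAUAGUU"
  r1 <- canon; substr(r1, 10, 10) <- "G"   # A>G at 10
  r2 <- canon; substr(r2, 10, 10) <- "C"   # A>C at 10
  reads <- tibble::tibble(read_id = c("a", "b", "c"),
                          sequence = c(r1, r2, canon),
                          s1 = c(2, 1, 50))
  tab <- call_isomirs(reads, ref)
  sp <- substitution_spectrum(tab)
  expect_equal(nrow(sp$spectrum), 12L)
  expect_equal(sp$spectrum$expression[sp$spectrum$substitution == "A>G"], 2)
  expect_equal(sp$spectrum$expression[sp$spectrum$substitution == "A>C"], 1)
  expect_equal(sum(sp$spectrum$expression), 3)
  expect_equal(sp$by_position$position, 10L)

  none <- substitution_spectrum(call_isomirs(
    tibble::tibble(read_id = "x", sequence = canon, s1 = 1), ref))
  expect_true(all(none$spectrum$expression == 0))
})

test_that("ADAR sites sit on internal reference-A positions only", {
  ref <- tiny_ref()
  canon <- "UGAGGUAGUAGGUUGUAUAGUU"
  edited <- canon; substr(edited, 10, 10) <- "G"   # A at 10 -> candidate
  uc <- canon; substr(uc, 9, 9) <- "C"             # U>C at 9 -> not ADAR
  reads <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                          sequence = c(canon, edited, uc),
                          s1 = c(90, 10, 4))
  tab <- call_isomirs(reads, ref)
  ad <- detect_adar(tab, ref)
  expect_equal(nrow(ad$sites), 1L)
  expect_equal(ad$sites$position, 10L)
  expect_equal(ad$sites$fraction, 10 / 104)
  # reference base at every called position is A
  m <- ref$matures[match(ad$sites$mature_name, ref$matures$mature_name), ]
  expect_true(all(substr(m$sequence, ad$sites$position,
                         ad$sites$position) == "A"))
  expect_equal(ad$sample_summary$n_matures_edited, 1L)
})

test_that("edited fraction is edited over total mature counts", {
  ref <- tiny_ref()
  canon <- "UGAGGUAGUAGGUUGUAUAGUU"
  edited <- canon; substr(edited, 10, 10) <- "G"
  tab <- call_isomirs(tibble::tibble(
    read_id = c("a", "b"), sequence = c(canon, edited),
    s1 = c(90, 10)), ref)
  ad <- detect_adar(tab, ref)
  expect_equal(ad$sites$fraction, 0.10)
  expect_equal(ad$mature_summary$adar_pct, 10)
})

test_that("ADAR group comparison is a two-sided t test with guards", {
  mk_adar <- function(counts) {
    structure(list(sample_summary = tibble::tibble(
      sample = names(counts), n_matures_edited = unname(counts))),
      class = "adar_result")
  }
  design <- tibble::tibble(sample = c(paste0("P", 1:3), paste0("C", 1:3)),
                           population = rep(c("PSC", "CM"), each = 3))
  same <- mk_adar(stats::setNames(rep(10L, 6), design$sample))
  res <- compare_adar_groups(same, design, "PSC", "CM")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  diff <- mk_adar(stats::setNames(c(10L, 11L, 9L, 2L, 2L, 2L),
                                  design$sample))
  res2 <- compare_adar_groups(diff, design, "PSC", "CM")
  expect_lt(res2$p_value, 0.01)
  # cross-check against stats::t.test on the same numbers
  tt <- stats::t.test(c(10, 11, 9), c(2, 2, 2))
  expect_equal(res2$p_value, tt$p.value)
  expect_equal(res2$statistic, unname(tt$statistic))

  one_rep <- mk_adar(stats::setNames(c(10L, 2L, 2L, 2L),
                                     c("P1", "C1", "C2", "C3")))
  expect_error(compare_adar_groups(one_rep, design, "PSC", "CM"),
               ">= 2 replicates")
})
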