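# IsomiR classification of collapsed small-RNA reads against
# mature-in-hairpin references: exact/5'/3'/both end classes, templated vs
# non-templated additions, <=1 internal substitution, ADAR candidates.

# Precompute per-mature comparison context. Sequences are held as integer
# (UTF-8) vectors; left/right context are the hairpin bases flanking the
# mature (NA where the hairpin ends), used to decide templated additions.
prep_classify_index <- function(ref, max_shift = 3L) {
  hp <- stats::setNames(ref$hairpins$sequence, ref$hairpins$hairpin_id)
  mat <- ref$matures
  ord_rank <- stats::setNames(
    rank(stringr::str_rank(mat$mature_name, locale = "C")), mat$mature_name)
  lapply(seq_len(nrow(mat)), function(i) {
    s <- mat$sequence[i]
    h <- hp[[mat$hairpin_id[i]]]
    off <- mat$offset[i]
    L <- nchar(s)
    ctx_at <- function(pos) {
      ifelse(pos >= 1L & pos <= nchar(h),
             utf8ToInt(h)[pmax(pmin(pos, nchar(h)), 1L)], NA_integer_)
    }
    list(
      name = mat$mature_name[i],
      rank = unname(ord_rank[mat$mature_name[i]]),
      L = L,
      body = utf8ToInt(s),
      body_chr = strsplit(s, "", fixed = TRUE)[[1]],
      left_ctx = ctx_at(off - seq_len(max_shift)),      # [k] = base at off-k
      right_ctx = ctx_at(off + L - 1L + seq_len(max_shift))
    )
  })
}

#' Classify collapsed reads into isomiR calls
#'
#' For every read sequence, candidate alignments against every mature are
#' enumerated over all end-shift pairs `(shift5, shift3)` in
#' `[-max_shift, max_shift]^2` whose implied length matches the read.
#' Negative shifts trim bases relative to the canonical end, positive shifts
#' add bases. Mismatches inside the canonical body are substitutions (at most
#' `max_sub`); mismatches within added 5'/3' bases mark that addition
#' non-templated and do not consume the substitution budget; additions
#' extending beyond the hairpin are allowed and always non-templated. The
#' best candidate minimizes `|shift5| + |shift3| + substitutions`, with ties
#' broken by fewer substitutions, then smaller `|shift5|`, then mature name
#' (C-locale), then signed `(shift5, shift3)`. Reads with no valid candidate
#' are reported unassigned with a reason.
#'
#' @param reads tibble with columns `read_id`, `sequence` and one numeric
#'   count column per sample; duplicate sequences are merged with summed
#'   counts (with a warning).
#' @param ref a `mirna_reference` from [load_reference()].
#' @param max_shift maximum end shift in nt (default 3, both ends).
#' @param max_sub maximum internal substitutions (default 1).
#' @return an object of class `isomir_table`: list with tibbles `calls`
#'   (read_id, mature_name, shift5, shift3, iso_class, n_sub, sub_pos,
#'   sub_ref, sub_alt, added5_templated, added3_templated, plus the count
#'   columns) and `unassigned` (read_id, reason, count columns).
#'   `iso_class` is `exact`, `iso5`, `iso3` or `iso5_iso3` from the shifts;
#'   substitution positions are 1-based canonical-mature coordinates.
#' @export
call_isomirs <- function(reads, ref, max_shift = 3L, max_sub = 1L) {
  stopifnot(inherits(ref, "mirna_reference"),
            all(c("read_id", "sequence") %in% names(reads)))
  max_shift <- as.integer(max_shift)
  reads <- tibble::as_tibble(reads)
  reads$sequence <- norm_rna(reads$sequence)
  cnt_cols <- setdiff(names(reads), c("read_id", "sequence"))

  if (anyDuplicated(reads$sequence)) {
    warning("duplicate read sequences merged with summed counts")
    reads <- reads |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(read_id = dplyr::first(.data$read_id),
                       dplyr::across(dplyr::all_of(cnt_cols), sum),
                       .groups = "drop") |>
      dplyr::select("read_id", "sequence", dplyr::all_of(cnt_cols))
  }

  n_reads <- nrow(reads)
  empty_calls <- tibble::tibble(
    read_id = character(), mature_name = character(),
    shift5 = integer(), shift3 = integer(), iso_class = character(),
    n_sub = integer(), sub_pos = integer(),
    sub_ref = character(), sub_alt = character(),
    added5_templated = logical(), added3_templated = logical())
  if (n_reads == 0) {
    return(new_isomir_table(
      dplyr::bind_cols(empty_calls, reads[0, cnt_cols, drop = FALSE]),
      tibble::tibble(read_id = character(), reason = character())))
  }

  b <- classify_batch(reads$sequence, ref, max_shift, max_sub)
  lens <- nchar(reads$sequence)

  assigned <- !is.na(b$score)
  iso_class <- dplyr::case_when(
    b$s5 == 0L & b$s3 == 0L ~ "exact",
    b$s5 != 0L & b$s3 == 0L ~ "iso5",
    b$s5 == 0L & b$s3 != 0L ~ "iso3",
    TRUE ~ "iso5_iso3")
  calls <- tibble::tibble(
    read_id = reads$read_id[assigned],
    mature_name = b$name[assigned],
    shift5 = b$s5[assigned], shift3 = b$s3[assigned],
    iso_class = iso_class[assigned],
    n_sub = b$nsub[assigned], sub_pos = b$subpos[assigned],
    sub_ref = b$subref[assigned], sub_alt = b$subalt[assigned],
    added5_templated = b$add5[assigned],
    added3_templated = b$add3[assigned])
  calls <- dplyr::bind_cols(calls, reads[assigned, cnt_cols, drop = FALSE])

  # reasons: a read that becomes assignable under a doubled shift window
  # failed on the end-shift tolerance, not on mismatches
  reason <- rep(NA_character_, n_reads)
  un <- which(!assigned)
  if (length(un)) {
    short <- lens[un] < 16L
    reason[un[short]] <- "read shorter than 16 nt"
    chk <- un[!short]
    if (length(chk)) {
      wide <- classify_batch(reads$sequence[chk], ref, 2L * max_shift,
                             max_sub)
      reason[chk] <- ifelse(!is.na(wide$score),
                            paste0("shift exceeds ±", max_shift),
                            paste0("no alignment within ±", max_shift,
                                   " nt and ", max_sub, " substitution(s)"))
    }
  }
  unassigned <- tibble::tibble(read_id = reads$read_id[!assigned],
                               reason = reason[!assigned])
  unassigned <- dplyr::bind_cols(unassigned,
                                 reads[!assigned, cnt_cols, drop = FALSE])
  new_isomir_table(calls, unassigned)
}

# Vectorized candidate enumeration over all (mature, shift5, shift3) pairs;
# returns the per-sequence best candidate under the declared tie-break.
classify_batch <- function(sequences, ref, max_shift, max_sub) {
  idx <- prep_classify_index(ref, max_shift)
  n_reads <- length(sequences)
  lens <- nchar(sequences)

  # best-candidate state per read
  b <- list(score = rep(NA_integer_, n_reads), nsub = integer(n_reads),
            abs5 = integer(n_reads), rank = integer(n_reads),
            s5 = integer(n_reads), s3 = integer(n_reads),
            name = character(n_reads), subpos = rep(NA_integer_, n_reads),
            subref = rep(NA_character_, n_reads),
            subalt = rep(NA_character_, n_reads),
            add5 = rep(NA, n_reads), add3 = rep(NA, n_reads))

  for (n in sort(unique(lens))) {
    rows <- which(lens == n)
    if (n < 16L) next
    M <- do.call(rbind, lapply(sequences[rows], utf8ToInt))
    for (mi in seq_along(idx)) {
      m <- idx[[mi]]
      diff <- n - m$L
      if (abs(diff) > 2L * max_shift) next
      s5_range <- seq.int(max(-max_shift, diff - max_shift),
                          min(max_shift, diff + max_shift))
      for (s5 in s5_range) {
        s3 <- diff - s5
        # template over read positions 1..n in mature coordinates i - s5
        tmpl <- rep(NA_integer_, n)
        body_cols <- seq.int(max(1L, s5 + 1L), min(n, s5 + m$L))
        tmpl[body_cols] <- m$body[body_cols - s5]
        a5_cols <- if (s5 > 0L) seq_len(s5) else integer()
        if (length(a5_cols)) tmpl[a5_cols] <- rev(m$left_ctx[seq_len(s5)])
        a3_cols <- if (s3 > 0L) seq.int(s5 + m$L + 1L, n) else integer()
        if (length(a3_cols)) tmpl[a3_cols] <- m$right_ctx[seq_len(s3)]

        mm <- M != matrix(tmpl, nrow(M), n, byrow = TRUE)
        mm_body <- mm[, body_cols, drop = FALSE]
        nsub <- as.integer(rowSums(mm_body))
        valid <- nsub <= max_sub
        if (!any(valid)) next
        score <- abs(s5) + abs(s3) + nsub

        add_ok <- function(cols) {
          if (!length(cols)) return(rep(NA, nrow(M)))
          v <- mm[, cols, drop = FALSE]
          v[is.na(v)] <- TRUE   # beyond hairpin => non-templated
          rowSums(v) == 0
        }
        add5 <- add_ok(a5_cols)
        add3 <- add_ok(a3_cols)

        subpos <- rep(NA_integer_, nrow(M))
        one <- which(nsub == 1L & valid)
        if (length(one)) {
          col1 <- body_cols[max.col(mm_body[one, , drop = FALSE],
                                    ties.method = "first")]
          subpos[one] <- col1 - s5
        }

        g <- rows  # global indices
        better <- valid & (
          is.na(b$score[g]) | score < b$score[g] |
          (score == b$score[g] & (nsub < b$nsub[g] |
            (nsub == b$nsub[g] & (abs(s5) < b$abs5[g] |
              (abs(s5) == b$abs5[g] & (m$rank < b$rank[g] |
                (m$rank == b$rank[g] & (s5 < b$s5[g] |
                  (s5 == b$s5[g] & s3 < b$s3[g]))))))))))
        better[is.na(better)] <- FALSE
        if (!any(better)) next
        gi <- g[better]; li <- which(better)
        b$score[gi] <- score[li]; b$nsub[gi] <- nsub[li]
        b$abs5[gi] <- abs(s5); b$rank[gi] <- m$rank
        b$s5[gi] <- s5; b$s3[gi] <- s3; b$name[gi] <- m$name
        b$subpos[gi] <- subpos[li]
        has_sub <- !is.na(subpos[li])
        b$subref[gi] <- ifelse(has_sub, m$body_chr[subpos[li]],
                               NA_character_)
        b$subalt[gi] <- ifelse(has_sub,
                               substr(sequences[gi], subpos[li] + s5,
                                      subpos[li] + s5), NA_character_)
        b$add5[gi] <- add5[li]; b$add3[gi] <- add3[li]
      }
    }
  }
  b
}

new_isomir_table <- function(calls, unassigned) {
  structure(list(calls = calls, unassigned = unassigned),
            class = "isomir_table")
}

#' @export
print.isomir_table <- function(x, ...) {
  cat("<isomir_table> ", nrow(x$calls), " calls, ",
      nrow(x$unassigned), " unassigned\n", sep = "")
  invisible(x)
}

#' Classify a single read sequence
#'
#' Single-sequence convenience wrapper around [call_isomirs()].
#'
#' @inheritParams call_isomirs
#' @param sequence one read sequence (>= 16 nt for a call).
#' @return one-row tibble of the call, or a one-row tibble with `read_id`
#'   and `reason` if unassigned.
#' @export
classify_read <- function(sequence, ref, max_shift = 3L, max_sub = 1L) {
  stopifnot(length(sequence) == 1L)
  tab <- call_isomirs(
    tibble::tibble(read_id = "read", sequence = sequence, count = 1),
    ref, max_shift = max_shift, max_sub = max_sub)
  if (nrow(tab$calls)) tab$calls else tab$unassigned
}

isomir_count_cols <- function(tab) {
  setdiff(names(tab$calls),
          c("read_id", "mature_name", "shift5", "shift3", "iso_class",
            "n_sub", "sub_pos", "sub_ref", "sub_alt",
            "added5_templated", "added3_templated"))
}

#' Per-class sequence counts and expression totals
#'
#' Tallies, for each isomiR class (`exact`, `iso5`, `iso3`, `iso5_iso3`),
#' the number of distinct read sequences and the summed read counts per
#' sample. Optionally the expression filter of [filter_expressed()] is
#' applied to the call count table first.
#'
#' @param tab an `isomir_table`.
#' @param design optional sample design (columns `sample`, `population`);
#'   when given together with `min_reads`, calls failing the expression
#'   filter are dropped before tallying.
#' @param min_reads,rule filter parameters, see [filter_expressed()].
#' @return long tibble with columns `iso_class`, `sample`, `n_sequences`,
#'   `expression`; all four classes are always present.
#' @export
isoform_class_counts <- function(tab, design = NULL, min_reads = 5,
                                 rule = c("mean_only", "strict")) {
  stopifnot(inherits(tab, "isomir_table"))
  rule <- match.arg(rule)
  calls <- tab$calls
  cnt_cols <- isomir_count_cols(tab)
  if (!is.null(design)) {
    ctab <- dplyr::select(calls, feature = "read_id",
                          dplyr::all_of(cnt_cols))
    kept <- filter_expressed(ctab, design, min_reads = min_reads,
                             rule = rule)$feature
    calls <- dplyr::filter(calls, .data$read_id %in% kept)
  }
  classes <- c("exact", "iso5", "iso3", "iso5_iso3")
  calls |>
    tidyr::pivot_longer(dplyr::all_of(cnt_cols), names_to = "sample",
                        values_to = "count") |>
    dplyr::group_by(iso_class = factor(.data$iso_class, classes),
                    .data$sample) |>
    dplyr::summarise(n_sequences = dplyr::n_distinct(.data$read_id),
                     expression = sum(.data$count), .groups = "drop") |>
    tidyr::complete(.data$iso_class,
                    sample = unique(c(calls_samples(cnt_cols, calls))),
                    fill = list(n_sequences = 0L, expression = 0)) |>
    dplyr::mutate(iso_class = as.character(.data$iso_class)) |>
    dplyr::arrange(match(.data$iso_class, classes), .data$sample)
}

calls_samples <- function(cnt_cols, calls) cnt_cols

#' Expression histogram over end-shift positions
#'
#' For each end (5' and 3') and shift value in `-max..-1, +1..+max`
#' (shift 0, the canonical end, is excluded) sums the expression of the
#' calls carrying that shift. Reported per sample, or per population when a
#' design is given.
#'
#' @param tab an `isomir_table`.
#' @param design optional sample design; when given, counts are summed
#'   within populations.
#' @return long tibble `end` (`"5p"`/`"3p"`), `shift`, `sample` (or
#'   `population`), `expression`.
#' @export
end_position_summary <- function(tab, design = NULL) {
  stopifnot(inherits(tab, "isomir_table"))
  cnt_cols <- isomir_count_cols(tab)
  long <- tab$calls |>
    tidyr::pivot_longer(dplyr::all_of(cnt_cols), names_to = "sample",
                        values_to = "count") |>
    tidyr::pivot_longer(c("shift5", "shift3"), names_to = "end",
                        values_to = "shift") |>
    dplyr::mutate(end = dplyr::if_else(.data$end == "shift5", "5p", "3p")) |>
    dplyr::filter(.data$shift != 0L)
  if (!is.null(design)) {
    check_design(design, unique(long$sample))
    long <- long |>
      dplyr::left_join(design[c("sample", "population")], by = "sample") |>
      dplyr::group_by(.data$end, .data$shift,
                      sample = .data$population)
  } else {
    long <- dplyr::group_by(long, .data$end, .data$shift, .data$sample)
  }
  long |>
    dplyr::summarise(expression = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$end), .data$shift)
}

#' Substitution spectrum of isomiR calls
#'
#' Counts the 12 ordered base-substitution categories (reported in the DNA
#' alphabet, U mapped to T, for comparability with DNA-space tools) and the
#' per-position totals along the canonical mature (1-based). Each call is
#' weighted by its total read count across samples; `n_sequences` counts
#' distinct read sequences.
#'
#' @param tab an `isomir_table`.
#' @return list with tibbles `spectrum` (`substitution`, e.g. `"A>G"`,
#'   `n_sequences`, `expression`; all 12 categories present) and
#'   `by_position` (`position`, `n_sequences`, `expression`).
#' @export
substitution_spectrum <- function(tab) {
  stopifnot(inherits(tab, "isomir_table"))
  cnt_cols <- isomir_count_cols(tab)
  subs <- tab$calls |>
    dplyr::filter(.data$n_sub == 1L) |>
    dplyr::mutate(total = rowSums(dplyr::pick(dplyr::all_of(cnt_cols))),
                  substitution = paste0(chartr("U", "T", .data$sub_ref), ">",
                                        chartr("U", "T", .data$sub_alt)))
  bases <- c("A", "C", "G", "T")
  all_cats <- as.vector(outer(bases, bases, function(a, b)
    paste0(a, ">", b)))
  all_cats <- sort(all_cats[substr(all_cats, 1, 1) !=
                              substr(all_cats, 3, 3)])
  spectrum <- subs |>
    dplyr::group_by(substitution = factor(.data$substitution, all_cats)) |>
    dplyr::summarise(n_sequences = dplyr::n(),
                     expression = sum(.data$total), .groups = "drop") |>
    tidyr::complete(.data$substitution,
                    fill = list(n_sequences = 0L, expression = 0)) |>
    dplyr::mutate(substitution = as.character(.data$substitution))
  by_position <- subs |>
    dplyr::group_by(position = .data$sub_pos) |>
    dplyr::summarise(n_sequences = dplyr::n(),
                     expression = sum(.data$total), .groups = "drop") |>
    dplyr::arrange(.data$position)
  list(spectrum = spectrum, by_position = by_position)
}

#' Detect candidate A-to-I (ADAR) editing sites
#'
#' A-to-I editing is read as A->G in sequencing data: every call carrying a
#' single A->G substitution at an internal position of the canonical mature
#' (positions 2 to length-1; the extremes are excluded as end artifacts)
#' contributes to an editing site. Per site and sample the edited fraction is
#' edited counts over the mature's total assigned counts. The per-sample
#' summary gives the number of distinct matures with at least one edited
#' read, and per mature the edited expression as CPM (relative to the
#' sample's total assigned counts) and as percentage of that mature's total.
#'
#' @param tab an `isomir_table`.
#' @param ref the `mirna_reference` the calls were made against.
#' @return object of class `adar_result`: list with tibbles `sites`
#'   (`mature_name`, `position`, `sample`, `edited`, `total`, `fraction`),
#'   `mature_summary` (`mature_name`, `sample`, `edited`, `total`,
#'   `adar_cpm`, `adar_pct`) and `sample_summary` (`sample`,
#'   `n_matures_edited`).
#' @export
detect_adar <- function(tab, ref) {
  stopifnot(inherits(tab, "isomir_table"), inherits(ref, "mirna_reference"))
  cnt_cols <- isomir_count_cols(tab)
  len_by <- stats::setNames(ref$matures$length, ref$matures$mature_name)
  long <- tab$calls |>
    tidyr::pivot_longer(dplyr::all_of(cnt_cols), names_to = "sample",
                        values_to = "count")
  totals <- long |>
    dplyr::group_by(.data$mature_name, .data$sample) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  lib <- long |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(lib_size = sum(.data$count), .groups = "drop")

  edited <- long |>
    dplyr::filter(.data$n_sub == 1L, .data$sub_ref == "A",
                  .data$sub_alt == "G",
                  .data$sub_pos > 1L,
                  .data$sub_pos < len_by[.data$mature_name]) |>
    dplyr::group_by(.data$mature_name, position = .data$sub_pos,
                    .data$sample) |>
    dplyr::summarise(edited = sum(.data$count), .groups = "drop")

  sites <- edited |>
    dplyr::left_join(totals, by = c("mature_name", "sample")) |>
    dplyr::mutate(fraction = ifelse(.data$total > 0,
                                    .data$edited / .data$total, 0)) |>
    dplyr::arrange(.data$mature_name, .data$position, .data$sample)

  mature_summary <- sites |>
    dplyr::group_by(.data$mature_name, .data$sample) |>
    dplyr::summarise(edited = sum(.data$edited),
                     total = dplyr::first(.data$total), .groups = "drop") |>
    dplyr::left_join(lib, by = "sample") |>
    dplyr::mutate(adar_cpm = .data$edited / .data$lib_size * 1e6,
                  adar_pct = 100 * .data$edited / .data$total) |>
    dplyr::select(-"lib_size")

  sample_summary <- mature_summary |>
    dplyr::filter(.data$edited > 0) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_matures_edited = dplyr::n_distinct(.data$mature_name),
                     .groups = "drop") |>
    tidyr::complete(sample = cnt_cols, fill = list(n_matures_edited = 0L))

  structure(list(sites = sites, mature_summary = mature_summary,
                 sample_summary = sample_summary),
            class = "adar_result")
}

#' @export
print.adar_result <- function(x, ...) {
  cat("<adar_result> ", nrow(x$sites), " site-sample records over ",
      dplyr::n_distinct(x$sites$mature_name), " matures\n", sep = "")
  invisible(x)
}

#' Compare ADAR burden between two populations
#'
#' Unpaired two-sided Welch t-test on the per-replicate numbers of
#' ADAR-modified matures in two populations. Degenerate zero-variance input
#' with equal means yields statistic 0 and p = 1.
#'
#' @param adar an `adar_result` from [detect_adar()].
#' @param design sample design (columns `sample`, `population`).
#' @param pop_a,pop_b population labels to compare.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
compare_adar_groups <- function(adar, design, pop_a, pop_b) {
  stopifnot(inherits(adar, "adar_result"))
  check_design(design)
  d <- adar$sample_summary |>
    dplyr::inner_join(design[c("sample", "population")], by = "sample")
  xa <- d$n_matures_edited[d$population == pop_a]
  xb <- d$n_matures_edited[d$population == pop_b]
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("need >= 2 replicates per compared population", call. = FALSE)
  }
  va <- stats::var(xa); vb <- stats::var(xb)
  delta <- mean(xa) - mean(xb)
  se2 <- va / length(xa) + vb / length(xb)
  if (se2 == 0) {
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    df <- length(xa) + length(xb) - 2
    p <- if (delta == 0) 1 else 0
  } else {
    stat <- delta / sqrt(se2)
    df <- se2^2 / ((va / length(xa))^2 / (length(xa) - 1) +
                     (vb / length(xb))^2 / (length(xb) - 1))
    p <- 2 * stats::pt(-abs(stat), df)
  }
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 mean_a = mean(xa), mean_b = mean(xb),
                 n_a = length(xa), n_b = length(xb))
}
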