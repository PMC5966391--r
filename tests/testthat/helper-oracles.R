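# Shared fixtures and independent oracles used across the suite.

# -- tiny hand-written reference -----------------------------------------
# Three hairpins, five matures:
#   hp-let7 (chr9):  let-7a-like mature at offset 5, hairpin continues "CC"
#   hp-a    (chr4):  a 5p and a 3p mature
#   hp-b    (chr4):  one mature sharing hp-a-3p's seed (same family),
#                    1 kb downstream of hp-a (same genomic cluster)
tiny_ref_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  let7_mat <- "UGAGGUAGUAGGUUGUAUAGUU"
  let7_hp <- paste0("AAGC", let7_mat, "CCGAGGUAGUAAUUUACAUCAAGGGAGAUAACUGUACAGCC")
  a5 <- "ACGUACGUACGAUCGAUCGAUU"
  a3 <- "GGCAUGCAUGGCUAGCUAGCAA"
  hp_a <- paste0("GUAC", a5, "GGGAAACCC", a3, "AGGU")
  b3 <- "AGCAUGCAUGCAAUCGAAUCGG"   # seed GCAUGCA == seed of a3
  hp_b <- paste0("UUAG", b3, "CAGGCAUUACGGAUACGGAUGGAU")
  stopifnot(substr(a3, 2, 8) == substr(b3, 2, 8))

  fa_lines <- function(named) {
    unlist(purrr::imap(named, function(s, n) c(paste0(">", n), s)))
  }
  hp_fa <- file.path(dir, "hairpin.fa")
  mat_fa <- file.path(dir, "mature.fa")
  gff <- file.path(dir, "ref.gff3")
  writeLines(fa_lines(list(`hp-let7` = let7_hp, `hp-a` = hp_a,
                           `hp-b` = hp_b)), hp_fa)
  writeLines(fa_lines(list(`tst-let7a` = let7_mat, `tst-miR-a-5p` = a5,
                           `tst-miR-a-3p` = a3, `tst-miR-b-3p` = b3)),
             mat_fa)
  g <- function(chrom, start, end, type, id, name, derives = NULL) {
    attrs <- paste0("ID=", id, ";Name=", name)
    if (!is.null(derives)) attrs <- paste0(attrs, ";Derives_from=", derives)
    paste(chrom, "test", type, start, end, ".", "+", ".", attrs,
          sep = "\t")
  }
  off <- function(hp_start, offset, len) {
    c(hp_start + offset - 1L, hp_start + offset + len - 2L)
  }
  let7_o <- off(5000L, 5L, 22L)
  a5_o <- off(1000L, 5L, 22L)
  a3_o <- off(1000L, 36L, 22L)
  b3_o <- off(2100L, 5L, 22L)
  writeLines(c(
    "##gff-version 3",
    g("chr9", 5000, 5000 + nchar(let7_hp) - 1, "miRNA_primary_transcript",
      "MI001", "hp-let7"),
    g("chr9", let7_o[1], let7_o[2], "miRNA", "MIMAT001", "tst-let7a",
      "MI001"),
    g("chr4", 1000, 1000 + nchar(hp_a) - 1, "miRNA_primary_transcript",
      "MI002", "hp-a"),
    g("chr4", a5_o[1], a5_o[2], "miRNA", "MIMAT002", "tst-miR-a-5p",
      "MI002"),
    g("chr4", a3_o[1], a3_o[2], "miRNA", "MIMAT003", "tst-miR-a-3p",
      "MI002"),
    g("chr4", 2100, 2100 + nchar(hp_b) - 1, "miRNA_primary_transcript",
      "MI003", "hp-b"),
    g("chr4", b3_o[1], b3_o[2], "miRNA", "MIMAT004", "tst-miR-b-3p",
      "MI003")), gff)
  list(hairpin = hp_fa, mature = mat_fa, gff = gff,
       let7_mat = let7_mat, let7_hp = let7_hp)
}

tiny_ref <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f <- tiny_ref_files(dir)
  load_reference(f$hairpin, f$mature, f$gff)
}

# -- independent brute-force isomiR classifier ---------------------------
# Per-position character loops; enumerates every (mature, shift5, shift3)
# candidate and applies the declared tie-break by explicit sort.
oracle_classify <- function(sequence, ref, max_shift = 3, max_sub = 1) {
  seq_ch <- strsplit(sequence, "")[[1]]
  n <- length(seq_ch)
  hp_seqs <- stats::setNames(ref$hairpins$sequence, ref$hairpins$hairpin_id)
  cands <- list()
  for (i in seq_len(nrow(ref$matures))) {
    mt <- ref$matures[i, ]
    mat_ch <- strsplit(mt$sequence, "")[[1]]
    hp_ch <- strsplit(hp_seqs[[mt$hairpin_id]], "")[[1]]
    L <- length(mat_ch)
    for (s5 in -max_shift:max_shift) {
      for (s3 in -max_shift:max_shift) {
        if (L + s5 + s3 != n) next
        nsub <- 0L; sub_pos <- NA_integer_
        sub_ref <- NA_character_; sub_alt <- NA_character_
        add5 <- if (s5 > 0) TRUE else NA
        add3 <- if (s3 > 0) TRUE else NA
        for (ri in seq_len(n)) {
          mp <- ri - s5
          if (mp >= 1 && mp <= L) {
            if (seq_ch[ri] != mat_ch[mp]) {
              nsub <- nsub + 1L
              sub_pos <- mp; sub_ref <- mat_ch[mp]; sub_alt <- seq_ch[ri]
            }
          } else {
            hpos <- mt$offset + mp - 1L
            templ <- hpos >= 1 && hpos <= length(hp_ch) &&
              seq_ch[ri] == hp_ch[hpos]
            if (!templ) {
              if (mp < 1) add5 <- FALSE else add3 <- FALSE
            }
          }
        }
        if (nsub <= max_sub) {
          cands[[length(cands) + 1L]] <- data.frame(
            mature_name = mt$mature_name, shift5 = s5, shift3 = s3,
            n_sub = nsub,
            sub_pos = if (nsub == 1L) sub_pos else NA_integer_,
            sub_ref = if (nsub == 1L) sub_ref else NA_character_,
            sub_alt = if (nsub == 1L) sub_alt else NA_character_,
            added5_templated = add5, added3_templated = add3,
            score = abs(s5) + abs(s3) + nsub)
        }
      }
    }
  }
  if (!length(cands)) return(NULL)
  cd <- do.call(rbind, cands)
  nm_rank <- rank(stringr::str_rank(cd$mature_name, locale = "C"),
                  ties.method = "min")
  ord <- order(cd$score, cd$n_sub, abs(cd$shift5), nm_rank,
               cd$shift5, cd$shift3)
  cd[ord[1], ]
}

# reads generated from every candidate shape the oracle understands
oracle_enumerate_reads <- function(ref, max_shift = 3, with_subs = TRUE) {
  hp_seqs <- stats::setNames(ref$hairpins$sequence, ref$hairpins$hairpin_id)
  other <- c(A = "G", C = "A", G = "U", U = "C")
  out <- character()
  for (i in seq_len(nrow(ref$matures))) {
    mt <- ref$matures[i, ]
    hp_ch <- strsplit(hp_seqs[[mt$hairpin_id]], "")[[1]]
    mat_ch <- strsplit(mt$sequence, "")[[1]]
    L <- length(mat_ch)
    for (s5 in -max_shift:max_shift) {
      for (s3 in -max_shift:max_shift) {
        n <- L + s5 + s3
        if (n < 16) next
        base <- character(n)
        for (ri in seq_len(n)) {
          mp <- ri - s5
          if (mp >= 1 && mp <= L) {
            base[ri] <- mat_ch[mp]
          } else {
            hpos <- mt$offset + mp - 1L
            base[ri] <- if (hpos >= 1 && hpos <= length(hp_ch)) {
              hp_ch[hpos]
            } else {
              "A"   # beyond the hairpin: arbitrary non-templated base
            }
          }
        }
        out <- c(out, paste(base, collapse = ""))
        if (with_subs) {
          for (mp in c(5L, L - 5L)) {     # two internal substitution spots
            ri <- mp + s5
            if (ri >= 1 && ri <= n) {
              v <- base
              v[ri] <- other[[v[ri]]]
              out <- c(out, paste(v, collapse = ""))
            }
          }
          if (s3 > 0) {                   # non-templated 3' tail variant
            v <- base
            v[n] <- other[[v[n]]]
            out <- c(out, paste(v, collapse = ""))
          }
        }
      }
    }
  }
  unique(out)
}

# -- brute-force genomic clustering --------------------------------------
# transitive closure of the pairwise "same chromosome, gap <= max_gap"
# relation, by boolean matrix powers
brute_clusters <- function(matures, max_gap) {
  n <- nrow(matures)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (matures$chrom[i] == matures$chrom[j]) {
        gap <- max(matures$start[i], matures$start[j]) -
          min(matures$end[i], matures$end[j]) - 1L
        if (gap <= max_gap) adj[i, j] <- TRUE
      }
    }
  }
  repeat {
    nxt <- adj | ((adj %*% adj) > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[which(adj[i, ])] <- k
    }
  }
  groups <- split(matures$mature_name, comp)
  lapply(unname(groups[lengths(groups) >= 2]), sort)
}

# -- exact hypergeometric by enumeration (universe <= 12) ----------------
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d <= K) >= k)
  mean(hits)
}

# random coordinate reference (clusters module property tests)
random_coord_ref <- function(n, seed, n_chrom = 3, span = 60000) {
  withr::with_seed(seed, {
    start <- sample.int(span, n, replace = TRUE)
    tibble::tibble(
      mature_name = sprintf("m%03d", seq_len(n)),
      chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
      start = start, end = start + 21L)
  })
}

# wrap a coordinate tibble as a minimal mirna_reference for cluster calls
as_coord_ref <- function(coords) {
  structure(list(
    hairpins = tibble::tibble(),
    matures = dplyr::mutate(coords, hairpin_id = NA_character_,
                            offset = 1L, length = 22L,
                            sequence = NA_character_,
                            seed = NA_character_, strand = "+")),
    class = "mirna_reference")
}
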