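# Synthetic references, reads, count matrices and score tables with planted
# ground truth, emulating the structure of a three-stage (PSC/MPC/CM,
# 3 replicates each) cardiac-differentiation small-RNA-seq study.

#' Simulation configuration
#'
#' Bundles the planted study conditions used by the `simulate_*` generators.
#' Defaults emulate the study design: three cell populations (PSC, MPC, CM)
#' with three replicates; negative-binomial counts; five trajectory shapes;
#' isomiR end-shift distributions with 5' mode at -3 and 3' mode at -1;
#' a substitution spectrum enriched for C>G, G>A and T>C (U>C in RNA
#' space); and low-rate A-to-G editing at a handful of internal sites.
#'
#' @param seed master seed; all generators derive their randomness from it.
#' @param populations population labels, in stage order.
#' @param replicates replicates per population.
#' @param cluster_plan list of genomic-cluster plans, each a list with
#'   `chrom`, `n` (hairpins), `gap` (intervening bases between hairpins) and
#'   `shared_seed` (single-mature hairpins sharing one seed, a
#'   family == cluster situation).
#' @param singleton_plan named integer vector: isolated hairpins per
#'   chromosome (separated by `singleton_gap` bases).
#' @param singleton_gap separation between singleton hairpins (default
#'   20001, beyond the clustering threshold).
#' @param chrom_length chromosome length bound used for feasibility checks.
#' @param hairpin_length,mature_length hairpin and mature lengths in nt.
#' @param n_minus_strand number of hairpins placed on the minus strand.
#' @param reads_per_mature distinct read sequences drawn per mature.
#' @param class_probs probabilities of the four end classes
#'   (exact, iso5, iso3, iso5_iso3).
#' @param shift5_probs,shift3_probs named probability vectors over shifts
#'   `-3..-1, 1..3` (defaults put the 5' mode at -3 and the 3' mode at -1).
#' @param sub_rate fraction of reads carrying one internal substitution.
#' @param sub_weights named weights for the 12 DNA-space substitution
#'   categories (defaults upweight C>G, G>A, T>C).
#' @param adar_n_sites number of matures given one planted A-to-G editing
#'   site (at an internal reference-A position).
#' @param adar_rate per-read editing probability at a planted site.
#' @param read_mean_range,read_dispersion_range NB mean and dispersion
#'   ranges for per-sequence read counts.
#' @param n_features features in simulated count matrices.
#' @param mean_range,dispersion_range NB mean and dispersion ranges for
#'   count matrices.
#' @param de_n,de_log2fc,de_population planted differential expression:
#'   number of features, log2 fold change, and the population carrying it.
#' @param de_mean_range,de_dispersion_range NB mean and dispersion ranges
#'   for the planted DE features (defaults place them among well-expressed,
#'   well-measured features, as in a filtered analysis).
#' @param traj_per_shape trajectory features planted per shape (five
#'   shapes: monotone up, late up, late down, early down, transient up).
#' @param traj_amplitude amplitude (log2 units) of the stage effect.
#' @param traj_noise_sd Gaussian noise s.d. added to the standardized shape.
#' @param score_sizes,score_overlaps,score_pool,score_nontargets score-table
#'   plan: per-predictor target-set sizes, pairwise overlaps (named
#'   `"A_B"`), gene-pool size and non-target rows per predictor.
#' @return a list of class `mirnaome_sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    populations = c("PSC", "MPC", "CM"),
    replicates = 3L,
    cluster_plan = list(
      list(chrom = "chr1", n = 3L, gap = 5000L, shared_seed = FALSE),
      list(chrom = "chr2", n = 2L, gap = 8000L, shared_seed = FALSE),
      list(chrom = "chr4", n = 4L, gap = 2000L, shared_seed = TRUE),
      list(chrom = "chr5", n = 4L, gap = 9000L, shared_seed = TRUE)
    ),
    singleton_plan = c(chr1 = 2L, chr2 = 1L, chr3 = 5L, chr6 = 6L,
                       chr7 = 3L),
    singleton_gap = 20001L,
    chrom_length = 5e6,
    hairpin_length = 70L,
    mature_length = 22L,
    n_minus_strand = 2L,
    reads_per_mature = 25L,
    class_probs = c(exact = 0.35, iso5 = 0.10, iso3 = 0.35,
                    iso5_iso3 = 0.20),
    shift5_probs = c(`-3` = 0.35, `-2` = 0.15, `-1` = 0.15,
                     `1` = 0.15, `2` = 0.10, `3` = 0.10),
    shift3_probs = c(`-3` = 0.10, `-2` = 0.15, `-1` = 0.35,
                     `1` = 0.20, `2` = 0.10, `3` = 0.10),
    sub_rate = 0.10,
    sub_weights = NULL,
    adar_n_sites = 5L,
    adar_rate = 0.2,
    read_mean_range = c(20, 500),
    read_dispersion_range = c(0.05, 0.2),
    n_features = 600L,
    mean_range = c(20, 2000),
    dispersion_range = c(0.01, 0.2),
    de_n = 50L,
    de_log2fc = 6,
    de_population = "CM",
    de_mean_range = c(200, 2000),
    de_dispersion_range = c(0.01, 0.1),
    traj_per_shape = 20L,
    traj_amplitude = 2,
    traj_noise_sd = 0.2,
    score_sizes = c(A = 100L, B = 100L, C = 80L),
    score_overlaps = c(A_B = 30L, A_C = 10L, B_C = 10L),
    score_pool = 1000L,
    score_nontargets = 150L) {
  if (is.null(sub_weights)) {
    bases <- c("A", "C", "G", "T")
    cats <- as.vector(outer(bases, bases, paste, sep = ">"))
    cats <- cats[substr(cats, 1, 1) != substr(cats, 3, 3)]
    sub_weights <- stats::setNames(rep(1, length(cats)), cats)
    sub_weights[c("C>G", "G>A", "T>C")] <- 6
  }
  stopifnot(abs(sum(class_probs) - 1) < 1e-8,
            abs(sum(shift5_probs) - 1) < 1e-8,
            abs(sum(shift3_probs) - 1) < 1e-8,
            sub_rate >= 0, sub_rate <= 1, adar_rate >= 0, adar_rate <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "mirnaome_sim_config")
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Simulate a miRBase-style reference
#'
#' Generates hairpin/mature FASTA files and a GFF3 according to the
#' configuration's cluster and family plan, together with the planted
#' ground truth. Clustered hairpins are separated by the planned gap;
#' singletons by `singleton_gap`. Plans whose cumulative span exceeds
#' `chrom_length` are rejected.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (hairpin_fasta, mature_fasta, gff3), the
#'   loaded `reference`, and `truth`: tibbles `matures` (mature, hairpin,
#'   chrom, start, strand, seed, planted cluster id or NA) and the planted
#'   `clusters` (cluster id, chrom, members).
#' @export
simulate_reference <- function(config = simulation_config(), dir) {
  stopifnot(inherits(config, "mirnaome_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, {
    hp_rows <- list(); mat_rows <- list()
    hp_i <- 0L
    add_hairpin <- function(chrom, start, strand, matures_per_hairpin,
                            seed7 = NULL, cluster_id = NA_character_) {
      hp_i <<- hp_i + 1L
      hl <- config$hairpin_length; ml <- config$mature_length
      hp_id <- sprintf("sim-mir-%03d", hp_i)
      seq <- rand_seq(1, hl)
      offs <- if (matures_per_hairpin == 2L) {
        c(4L, hl - ml - 3L)
      } else {
        4L
      }
      arms <- if (matures_per_hairpin == 2L) c("-5p", "-3p") else "-3p"
      for (j in seq_along(offs)) {
        ms <- rand_seq(1, ml)
        if (!is.null(seed7)) {
          substr(ms, 2L, 8L) <- seed7
        }
        substr(seq, offs[j], offs[j] + ml - 1L) <- ms
        m_start <- if (strand == "+") {
          start + offs[j] - 1L
        } else {
          start + hl - (offs[j] + ml - 1L)
        }
        mat_rows[[length(mat_rows) + 1L]] <<- tibble::tibble(
          mature_name = paste0(sprintf("sim-miR-%03d", hp_i), arms[j]),
          hairpin_id = hp_id, chrom = chrom, start = m_start,
          end = m_start + ml - 1L, strand = strand,
          offset = offs[j], cluster_id = cluster_id)
      }
      hp_rows[[length(hp_rows) + 1L]] <<- tibble::tibble(
        hairpin_id = hp_id, sequence = seq, chrom = chrom, start = start,
        end = start + hl - 1L, strand = strand)
    }

    cursor <- list()  # next free coordinate per chromosome
    advance <- function(chrom, span) {
      at <- (cursor[[chrom]] %||% 1000L)
      if (at + span > config$chrom_length) {
        stop("cluster plan infeasible: span exceeds chromosome length on ",
             chrom, call. = FALSE)
      }
      at
    }
    planted_clusters <- list()
    for (ci in seq_along(config$cluster_plan)) {
      pl <- config$cluster_plan[[ci]]
      cl_id <- paste0("planted_", ci)
      seed7 <- if (isTRUE(pl$shared_seed)) rand_seq(1, 7) else NULL
      mph <- if (isTRUE(pl$shared_seed)) 1L else 2L
      span <- pl$n * config$hairpin_length + (pl$n - 1L) * pl$gap
      at <- advance(pl$chrom, span)
      for (k in seq_len(pl$n)) {
        add_hairpin(pl$chrom, at, "+", mph, seed7, cl_id)
        at <- at + config$hairpin_length + pl$gap
      }
      cursor[[pl$chrom]] <- at - pl$gap + config$singleton_gap
      planted_clusters[[cl_id]] <- pl$chrom
    }
    minus_left <- config$n_minus_strand
    for (chrom in names(config$singleton_plan)) {
      for (k in seq_len(config$singleton_plan[[chrom]])) {
        at <- advance(chrom, config$hairpin_length)
        strand <- if (minus_left > 0L) {
          minus_left <- minus_left - 1L; "-"
        } else "+"
        add_hairpin(chrom, at, strand, 2L)
        cursor[[chrom]] <- at + config$hairpin_length +
          config$singleton_gap
      }
    }

    hairpins <- dplyr::bind_rows(hp_rows)
    matures <- dplyr::bind_rows(mat_rows)
    if (anyDuplicated(matures$mature_name)) {
      stop("internal: duplicate simulated mature names")
    }

    paths <- c(hairpin_fasta = file.path(dir, "hairpin.fa"),
               mature_fasta = file.path(dir, "mature.fa"),
               gff3 = file.path(dir, "reference.gff3"))
    write_fasta(stats::setNames(hairpins$sequence, hairpins$hairpin_id),
                paths[["hairpin_fasta"]])
    mature_seq <- vapply(seq_len(nrow(matures)), function(i) {
      hp <- hairpins$sequence[hairpins$hairpin_id == matures$hairpin_id[i]]
      substr(hp, matures$offset[i],
             matures$offset[i] + config$mature_length - 1L)
    }, character(1))
    matures$sequence <- mature_seq
    matures$seed <- seed_of(mature_seq)
    write_fasta(stats::setNames(matures$sequence, matures$mature_name),
                paths[["mature_fasta"]])

    gr_hp <- GenomicRanges::GRanges(
      hairpins$chrom,
      IRanges::IRanges(hairpins$start, hairpins$end),
      strand = hairpins$strand, type = "miRNA_primary_transcript",
      ID = hairpins$hairpin_id, Name = hairpins$hairpin_id)
    gr_mat <- GenomicRanges::GRanges(
      matures$chrom, IRanges::IRanges(matures$start, matures$end),
      strand = matures$strand, type = "miRNA",
      ID = matures$mature_name, Name = matures$mature_name,
      Derives_from = matures$hairpin_id)
    gr <- c(gr_hp, gr_mat)
    gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr))]
    rtracklayer::export(gr, paths[["gff3"]], format = "gff3")

    truth_clusters <- matures |>
      dplyr::filter(!is.na(.data$cluster_id)) |>
      dplyr::group_by(cluster_id = .data$cluster_id,
                      chrom = .data$chrom) |>
      dplyr::summarise(members = list(sort(.data$mature_name)),
                       .groups = "drop")
    list(paths = paths,
         reference = load_reference(paths[["hairpin_fasta"]],
                                    paths[["mature_fasta"]],
                                    paths[["gff3"]]),
         truth = list(matures = matures, clusters = truth_clusters))
  })
}

# enumerate all valid candidates for one read; used for ambiguity flags
enumerate_candidates <- function(sequence, idx, max_shift = 3L,
                                 max_sub = 1L) {
  r <- utf8ToInt(sequence)
  n <- length(r)
  out <- list()
  for (m in idx) {
    diff <- n - m$L
    if (abs(diff) > 2L * max_shift) next
    for (s5 in seq.int(max(-max_shift, diff - max_shift),
                       min(max_shift, diff + max_shift))) {
      s3 <- diff - s5
      body_cols <- seq.int(max(1L, s5 + 1L), min(n, s5 + m$L))
      nsub <- sum(r[body_cols] != m$body[body_cols - s5])
      if (nsub <= max_sub) {
        out[[length(out) + 1L]] <- c(score = abs(s5) + abs(s3) + nsub,
                                     s5 = s5, s3 = s3, nsub = nsub)
        names(out)[length(out)] <- m$name
      }
    }
  }
  out
}

#' Simulate collapsed small-RNA reads
#'
#' Draws, per mature, a set of distinct read sequences constructed by
#' applying sampled end shifts (within the classifier's tolerance),
#' at most one internal substitution with a spectrum-weighted category, and
#' A-to-G editing at the planted sites; every read then receives NB counts
#' per sample. Reads are written as per-sample collapsed FASTA
#' (`>{id}_x{count}` headers). Each emitted sequence is recorded with its
#' generating call and an `ambiguous` flag (TRUE when some other candidate
#' ties or beats the generating one under brute-force enumeration).
#'
#' @param config a [simulation_config()].
#' @param ref a `mirna_reference` (e.g. from [simulate_reference()]).
#' @param dir optional output directory for per-sample collapsed FASTA.
#' @return list with `reads` (tibble `read_id`, `sequence` + one count
#'   column per sample), `truth` (generating mature, shifts, substitution,
#'   ADAR flag, `ambiguous`), `adar_sites` (planted sites) and `paths`
#'   (named FASTA paths, if `dir` was given).
#' @export
simulate_reads <- function(config = simulation_config(), ref, dir = NULL) {
  stopifnot(inherits(config, "mirnaome_sim_config"),
            inherits(ref, "mirna_reference"))
  samples <- paste0(rep(config$populations, each = config$replicates),
                    seq_len(config$replicates))
  withr::with_seed(config$seed + 1L, {
    mat <- ref$matures
    hp_seq <- stats::setNames(ref$hairpins$sequence,
                              ref$hairpins$hairpin_id)
    # planted ADAR sites: internal A positions well inside the body
    adar <- mat |>
      dplyr::mutate(apos = purrr::map2(.data$sequence, .data$length,
        function(s, L) {
          p <- which(strsplit(s, "")[[1]] == "A")
          p[p >= 5 & p <= L - 4]
        })) |>
      dplyr::filter(lengths(.data$apos) > 0)
    adar <- adar[sample(nrow(adar), min(config$adar_n_sites, nrow(adar))), ]
    adar_sites <- tibble::tibble(
      mature_name = adar$mature_name,
      position = purrr::map_int(adar$apos, ~ .x[sample(length(.x), 1)]),
      rate = config$adar_rate)

    # preallocated record store (appending tibbles row-wise is too slow
    # at the fixture sizes used for recovery checks)
    cap <- 2L * nrow(mat) * config$reads_per_mature + 16L
    rec <- list(sequence = character(cap), mature_name = character(cap),
                shift5 = integer(cap), shift3 = integer(cap),
                sub_pos = rep(NA_integer_, cap),
                sub_ref = rep(NA_character_, cap),
                sub_alt = rep(NA_character_, cap), adar = logical(cap))
    cnt_store <- matrix(0, cap, length(samples))
    n_rec <- 0L
    push <- function(seqc, nm, s5, s3, sp, sr, sa, ad, counts) {
      n_rec <<- n_rec + 1L
      rec$sequence[n_rec] <<- seqc; rec$mature_name[n_rec] <<- nm
      rec$shift5[n_rec] <<- s5; rec$shift3[n_rec] <<- s3
      rec$sub_pos[n_rec] <<- sp; rec$sub_ref[n_rec] <<- sr
      rec$sub_alt[n_rec] <<- sa; rec$adar[n_rec] <<- ad
      cnt_store[n_rec, ] <<- counts
    }
    for (i in seq_len(nrow(mat))) {
      nm <- mat$mature_name[i]
      s <- mat$sequence[i]
      L <- mat$length[i]
      hp <- hp_seq[[mat$hairpin_id[i]]]
      off <- mat$offset[i]
      is_adar <- nm %in% adar_sites$mature_name
      base_mean <- exp(stats::runif(1, log(config$read_mean_range[1]),
                                    log(config$read_mean_range[2])))
      n_seq <- config$reads_per_mature
      cls <- sample(names(config$class_probs), n_seq, replace = TRUE,
                    prob = config$class_probs)
      cls[1] <- "exact"   # the canonical sequence is always present
      for (k in seq_len(n_seq)) {
        s5 <- if (cls[k] %in% c("iso5", "iso5_iso3")) {
          as.integer(sample(names(config$shift5_probs), 1,
                            prob = config$shift5_probs))
        } else 0L
        s3 <- if (cls[k] %in% c("iso3", "iso5_iso3")) {
          as.integer(sample(names(config$shift3_probs), 1,
                            prob = config$shift3_probs))
        } else 0L
        # build sequence in hairpin space where possible
        start_h <- off - s5; end_h <- off + L - 1L + s3
        core <- substr(hp, max(1L, start_h), min(nchar(hp), end_h))
        pre <- if (start_h < 1L) rand_seq(1, 1L - start_h) else ""
        post <- if (end_h > nchar(hp)) {
          rand_seq(1, end_h - nchar(hp))
        } else ""
        rs <- paste0(pre, core, post)
        sub_pos <- NA_integer_; sub_ref <- NA_character_
        sub_alt <- NA_character_
        if (!is_adar && k > 1 && stats::runif(1) < config$sub_rate) {
          # internal substitution in canonical-body coordinates
          p <- sample(seq(2L, L - 1L), 1L)
          rp <- p + s5   # read coordinate of canonical-body position p
          if (rp >= 1L && rp <= nchar(rs)) {
            ref_b <- substr(s, p, p)
            w <- config$sub_weights
            alts <- setdiff(c("A", "C", "G", "U"), ref_b)
            wk <- vapply(alts, function(a) {
              unname(w[paste0(chartr("U", "T", ref_b), ">",
                              chartr("U", "T", a))])
            }, numeric(1))
            alt <- sample(alts, 1, prob = wk)
            substr(rs, rp, rp) <- alt
            sub_pos <- p; sub_ref <- ref_b; sub_alt <- alt
          }
        }
        counts <- stats::rnbinom(
          length(samples),
          mu = base_mean * stats::runif(1, 0.2, 1),
          size = 1 / stats::runif(1, config$read_dispersion_range[1],
                                  config$read_dispersion_range[2]))
        if (all(counts == 0)) counts[1] <- 1
        counts <- as.numeric(counts)
        if (is_adar) {
          site <- adar_sites[adar_sites$mature_name == nm, ]
          rp <- site$position + s5
          edited <- stats::rbinom(length(counts), counts, site$rate)
          if (rp >= 1L && rp <= nchar(rs) &&
              substr(rs, rp, rp) == "A" && any(edited > 0)) {
            es <- rs
            substr(es, rp, rp) <- "G"
            push(es, nm, s5, s3, site$position, "A", "G", TRUE,
                 as.numeric(edited))
            counts <- counts - edited
          }
        }
        push(rs, nm, s5, s3, sub_pos, sub_ref, sub_alt, FALSE, counts)
      }
    }
    truth <- tibble::as_tibble(lapply(rec, `[`, seq_len(n_rec)))
    colnames(cnt_store) <- samples
    truth <- dplyr::bind_cols(
      truth, tibble::as_tibble(cnt_store[seq_len(n_rec), , drop = FALSE]))
    # merge duplicate sequences: keep the first generating record, sum counts
    truth <- truth |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(dplyr::across(c("mature_name", "shift5", "shift3",
                                       "sub_pos", "sub_ref", "sub_alt",
                                       "adar"), dplyr::first),
                       dplyr::across(dplyr::all_of(samples), sum),
                       .groups = "drop")
    truth <- truth[rowSums(as.matrix(truth[samples])) > 0, ]
    ord <- order(truth$mature_name, truth$sequence)
    truth <- truth[ord, ]
    truth$read_id <- sprintf("r%05d", seq_len(nrow(truth)))

    # ambiguity flag by candidate enumeration
    idx <- prep_classify_index(ref)
    truth$ambiguous <- vapply(seq_len(nrow(truth)), function(i) {
      cand <- enumerate_candidates(truth$sequence[i], idx)
      if (!length(cand)) return(TRUE)
      scores <- vapply(cand, `[[`, numeric(1), "score")
      best <- which(scores == min(scores))
      if (length(best) > 1L) return(TRUE)
      bc <- cand[[best]]
      !(names(cand)[best] == truth$mature_name[i] &&
          bc[["s5"]] == truth$shift5[i] && bc[["s3"]] == truth$shift3[i])
    }, logical(1))

    reads <- truth[c("read_id", "sequence", samples)]
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- stats::setNames(
        file.path(dir, paste0(samples, ".fa")), samples)
      for (sm in samples) {
        nonzero <- reads[reads[[sm]] > 0, ]
        write_fasta(stats::setNames(
          nonzero$sequence,
          paste0(nonzero$read_id, "_x",
                 format(nonzero[[sm]], scientific = FALSE,
                        trim = TRUE))),
          paths[[sm]])
      }
    }
    list(reads = reads,
         truth = truth[c("read_id", "sequence", "mature_name", "shift5",
                         "shift3", "sub_pos", "sub_ref", "sub_alt",
                         "adar", "ambiguous")],
         adar_sites = adar_sites, paths = paths)
  })
}

#' Read collapsed FASTA files into a read table
#'
#' Parses per-sample collapsed FASTA files whose headers carry the read
#' multiplicity as `{id}_x{count}`. Sequences occurring in several samples
#' are merged into one row (the first id wins); absent sequences get
#' count 0.
#'
#' @param manifest tibble with columns `sample` and `file`.
#' @return tibble `read_id`, `sequence`, plus one count column per sample.
#' @export
read_collapsed_fasta <- function(manifest) {
  stopifnot(all(c("sample", "file") %in% names(manifest)))
  per_sample <- purrr::map2(manifest$file, manifest$sample,
    function(f, sm) {
      ss <- Biostrings::readBStringSet(f)
      nm <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
      count <- as.numeric(sub(".*_x([0-9]+)$", "\\1", nm))
      if (anyNA(count)) {
        stop("header(s) without _xCOUNT suffix in ", f, call. = FALSE)
      }
      tibble::tibble(read_id = sub("_x[0-9]+$", "", nm),
                     sequence = norm_rna(as.character(ss)),
                     sample = sm, count = count)
    })
  dplyr::bind_rows(per_sample) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::mutate(read_id = dplyr::first(.data$read_id)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0, values_fn = sum)
}

#' Simulate a count matrix with planted structure
#'
#' Draws NB counts for `n_features` features across the configured
#' populations and replicates. A planted subset carries a `de_log2fc`
#' mean shift in `de_population`; five further subsets follow the planted
#' trajectory shapes (monotone up, late up, late down, early down,
#' transient up) as standardized stage effects of amplitude
#' `traj_amplitude` (log2 units) plus Gaussian noise.
#'
#' @param config a [simulation_config()].
#' @param populations optional override of the config populations (e.g. six
#'   cell types for the cell-type-selection fixture).
#' @param n_unique number of features made exclusive to `de_population`
#'   (zero counts everywhere else); default 0.
#' @return list with `counts` (tibble `feature` + sample columns),
#'   `design`, and `truth` (tibble `feature`, `base_mean`, `dispersion`,
#'   `de`, `unique`, `shape`).
#' @export
simulate_counts <- function(config = simulation_config(),
                            populations = NULL, n_unique = 0L) {
  stopifnot(inherits(config, "mirnaome_sim_config"))
  pops <- populations %||% config$populations
  reps <- config$replicates
  samples <- paste0(rep(pops, each = reps), seq_len(reps))
  design <- tibble::tibble(
    sample = samples, population = rep(pops, each = reps),
    replicate = rep(seq_len(reps), times = length(pops)))
  G <- config$n_features
  shapes <- list(
    monotone_up = c(-1, 0, 1),
    late_up = c(0, 0, 1), late_down = c(0, 0, -1),
    early_down = c(1, 0, 0), transient_up = c(0, 1, 0))
  withr::with_seed(config$seed + 2L, {
    base <- exp(stats::runif(G, log(config$mean_range[1]),
                             log(config$mean_range[2])))
    disp <- stats::runif(G, config$dispersion_range[1],
                         config$dispersion_range[2])
    feature <- sprintf("feat%04d", seq_len(G))
    shape <- rep(NA_character_, G)
    de <- rep(FALSE, G)
    uniq <- rep(FALSE, G)
    slots <- seq_len(G)
    if (n_unique > 0L) {
      uniq[slots[seq_len(n_unique)]] <- TRUE
      slots <- slots[-seq_len(n_unique)]
    }
    if (config$de_n > 0L) {
      de_idx <- slots[seq_len(config$de_n)]
      de[de_idx] <- TRUE
      base[de_idx] <- exp(stats::runif(config$de_n,
                                       log(config$de_mean_range[1]),
                                       log(config$de_mean_range[2])))
      disp[de_idx] <- stats::runif(config$de_n,
                                   config$de_dispersion_range[1],
                                   config$de_dispersion_range[2])
      slots <- slots[-seq_len(config$de_n)]
    }
    if (config$traj_per_shape > 0L && length(pops) >= 3L) {
      for (sh in names(shapes)) {
        shape[slots[seq_len(config$traj_per_shape)]] <- sh
        slots <- slots[-seq_len(config$traj_per_shape)]
      }
    }
    # per-feature per-population log2 mean
    log2mu <- matrix(log2(base), G, length(pops))
    colnames(log2mu) <- pops
    if (any(de) || any(uniq)) {
      tgt <- match(config$de_population, pops)
      if (is.na(tgt)) stop("de_population not among populations",
                           call. = FALSE)
      log2mu[de, tgt] <- log2mu[de, tgt] + config$de_log2fc
    }
    traj_idx <- which(!is.na(shape))
    if (length(traj_idx)) {
      # trajectory patterns are planted on well-measured features: high
      # expression, low dispersion, as after expression filtering
      base[traj_idx] <- exp(stats::runif(
        length(traj_idx), log(max(500, config$mean_range[1])),
        log(max(2000, config$mean_range[2]))))
      disp[traj_idx] <- stats::runif(length(traj_idx), 0.01, 0.05)
      log2mu[traj_idx, ] <- log2(base[traj_idx])
    }
    for (i in traj_idx) {
      z <- shapes[[shape[i]]][seq_len(min(3L, length(pops)))]
      z <- (z - mean(z)) / stats::sd(z)
      z <- z + stats::rnorm(length(z), 0, config$traj_noise_sd)
      log2mu[i, seq_along(z)] <- log2(base[i]) + config$traj_amplitude * z
    }
    counts <- matrix(0, G, length(samples),
                     dimnames = list(feature, samples))
    for (p in seq_along(pops)) {
      mu <- 2^log2mu[, p]
      if (any(uniq)) {
        if (pops[p] == config$de_population) {
          mu[uniq] <- pmax(mu[uniq], 200)
        } else {
          mu[uniq] <- 0
        }
      }
      for (r in seq_len(reps)) {
        sm <- paste0(pops[p], r)
        counts[, sm] <- ifelse(mu == 0, 0L,
                               stats::rnbinom(G, mu = mu, size = 1 / disp))
      }
    }
    list(counts = matrix_to_count_tbl(counts), design = design,
         truth = tibble::tibble(feature = feature, base_mean = base,
                                dispersion = disp, de = de,
                                unique = uniq, shape = shape))
  })
}

#' Simulate standardized trajectory profiles
#'
#' Draws per-feature three-stage profiles directly in standardized shape
#' space: each feature follows one of the five planted dynamic patterns
#' (monotone up, late up, late down, early down, transient up; the
#' z-scored shape) plus Gaussian noise of s.d. `traj_noise_sd` per stage.
#' This isolates the clustering problem from count noise; use
#' [simulate_counts()] for the full count-level route.
#'
#' @param config a [simulation_config()]; uses `traj_per_shape`,
#'   `traj_noise_sd` and the first three `populations` as stage names.
#' @param n_per_shape optional override of features per shape.
#' @return list with `profiles` (tibble `feature` + one column per stage,
#'   not yet standardized) and `truth` (tibble `feature`, `shape`).
#' @export
simulate_trajectory_profiles <- function(config = simulation_config(),
                                         n_per_shape = NULL) {
  stopifnot(inherits(config, "mirnaome_sim_config"))
  n_per <- n_per_shape %||% config$traj_per_shape
  stages <- config$populations[1:3]
  shapes <- list(monotone_up = c(-1, 0, 1), late_up = c(0, 0, 1),
                 late_down = c(0, 0, -1), early_down = c(1, 0, 0),
                 transient_up = c(0, 1, 0))
  withr::with_seed(config$seed + 4L, {
    rows <- purrr::imap(shapes, function(s, nm) {
      z <- (s - mean(s)) / stats::sd(s)
      m <- t(replicate(n_per, z + stats::rnorm(3, 0, config$traj_noise_sd)))
      rownames(m) <- paste0(nm, "_", seq_len(n_per))
      m
    })
    m <- do.call(rbind, rows)
    colnames(m) <- stages
    list(profiles = matrix_to_count_tbl(m),
         truth = tibble::tibble(
           feature = rownames(m),
           shape = rep(names(shapes), each = n_per)))
  })
}

#' Simulate a target-prediction score table
#'
#' Builds per-predictor target gene sets with configured pairwise overlaps
#' (overlap genes are disjoint across pairs), scores targets
#' Uniform(0.8, 1) and adds non-target rows scored Uniform(0, 0.8).
#'
#' @param config a [simulation_config()]; uses `score_sizes`,
#'   `score_overlaps`, `score_pool`, `score_nontargets`.
#' @return list with `table` (tibble `gene`, `predictor`, `score`) and
#'   `truth` (named list of the planted target sets).
#' @export
simulate_score_table <- function(config = simulation_config()) {
  stopifnot(inherits(config, "mirnaome_sim_config"))
  sizes <- config$score_sizes
  overlaps <- config$score_overlaps
  preds <- names(sizes)
  shared_per_pred <- stats::setNames(integer(length(preds)), preds)
  for (nm in names(overlaps)) {
    pr <- strsplit(nm, "_", fixed = TRUE)[[1]]
    shared_per_pred[pr] <- shared_per_pred[pr] + overlaps[[nm]]
  }
  if (any(shared_per_pred > sizes)) {
    stop("overlap plan inconsistent: pairwise overlaps exceed a set size",
         call. = FALSE)
  }
  withr::with_seed(config$seed + 3L, {
    pool <- sprintf("g%05d", seq_len(config$score_pool))
    remaining <- pool
    take <- function(n) {
      if (n > length(remaining)) stop("gene pool exhausted", call. = FALSE)
      g <- remaining[seq_len(n)]
      remaining <<- remaining[-seq_len(n)]
      g
    }
    sets <- stats::setNames(vector("list", length(preds)), preds)
    for (nm in names(overlaps)) {
      pr <- strsplit(nm, "_", fixed = TRUE)[[1]]
      g <- take(overlaps[[nm]])
      sets[[pr[1]]] <- c(sets[[pr[1]]], g)
      sets[[pr[2]]] <- c(sets[[pr[2]]], g)
    }
    for (p in preds) {
      sets[[p]] <- c(sets[[p]], take(sizes[[p]] - length(sets[[p]])))
    }
    rows <- purrr::imap_dfr(sets, function(g, p) {
      tibble::tibble(gene = g, predictor = p,
                     score = stats::runif(length(g), 0.8, 1))
    })
    nont <- purrr::map_dfr(preds, function(p) {
      g <- sample(setdiff(pool, sets[[p]]), config$score_nontargets)
      tibble::tibble(gene = g, predictor = p,
                     score = stats::runif(length(g), 0, 0.8))
    })
    table <- dplyr::arrange(dplyr::bind_rows(rows, nont),
                            .data$predictor, .data$gene)
    list(table = table, truth = lapply(sets, sort))
  })
}
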