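# miRBase-style reference handling: hairpin/mature FASTA + GFF3 parsing,
# seed extraction, genomic clusters and seed families.

#' Extract the seed of a mature miRNA sequence
#'
#' The seed is the 7-mer at positions 2--8 (1-based, inclusive) of the mature
#' sequence, the principal determinant of target recognition. miRNAs sharing
#' an identical seed form a seed family.
#'
#' @param sequence character vector of mature sequences (A/C/G/U or T,
#'   normalized internally); every element must be at least 8 nt.
#' @return character vector of 7-nt seeds.
#' @examples
#' seed_of("UGAGGUAGUAGGUUGUAUAGUU")
#' @export
seed_of <- function(sequence) {
  sequence <- norm_rna(sequence)
  if (any(nchar(sequence) < 8)) {
    stop("seed_of() needs sequences of length >= 8", call. = FALSE)
  }
  substr(sequence, 2L, 8L)
}

#' Load a miRBase-style reference
#'
#' Reads hairpin and mature FASTA files plus a GFF3 with
#' `miRNA_primary_transcript` and `miRNA` records (attributes `ID`, `Name`,
#' `Derives_from`) and builds a joint index. Every mature is located inside
#' its hairpin by exact substring match; for minus-strand hairpins whose FASTA
#' carries the genomic-plus sequence, the reverse complement is tried before
#' failing. T/U spelling is normalized to U.
#'
#' @param hairpin_fasta,mature_fasta paths to FASTA files; the first
#'   whitespace-separated token of each header is the record name.
#' @param gff3 path to the GFF3 annotation.
#' @return an object of class `mirna_reference`: a list with tibbles
#'   `hairpins` (hairpin_id, sequence, chrom, start, end, strand) and
#'   `matures` (mature_name, hairpin_id, offset, length, sequence, seed,
#'   chrom, start, end, strand). `offset` is the 1-based start of the mature
#'   within the (transcribed) hairpin sequence.
#' @details A mature sequence absent from its `Derives_from` hairpin is a
#'   hard error naming the record; duplicate mature `Name`s are a hard error;
#'   `miRNA` records without `Derives_from` are skipped with a warning.
#' @export
load_reference <- function(hairpin_fasta, mature_fasta, gff3) {
  hp_seqs <- read_fasta_named(hairpin_fasta)
  mat_seqs <- read_fasta_named(mature_fasta)

  gr <- rtracklayer::import(gff3)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  get_attr <- function(i, what) {
    v <- meta[[what]]
    if (is.null(v)) return(rep(NA_character_, length(i)))
    out <- as.character(v[i])
    out[!nzchar(out %|na|% "")] <- NA_character_
    out
  }

  is_hp <- which(type == "miRNA_primary_transcript")
  is_mat <- which(type == "miRNA")

  hp_name <- dplyr::coalesce(get_attr(is_hp, "Name"), get_attr(is_hp, "ID"))
  hairpins <- tibble::tibble(
    hairpin_id = hp_name,
    gff_id = get_attr(is_hp, "ID"),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_hp]),
    start = GenomicRanges::start(gr)[is_hp],
    end = GenomicRanges::end(gr)[is_hp],
    strand = as.character(GenomicRanges::strand(gr)[is_hp])
  )
  if (anyDuplicated(hairpins$hairpin_id)) {
    stop("duplicate hairpin Name in GFF3", call. = FALSE)
  }
  missing_hp <- setdiff(hairpins$hairpin_id, names(hp_seqs))
  if (length(missing_hp)) {
    stop("hairpin(s) in GFF3 absent from FASTA: ",
         paste(utils::head(missing_hp, 3), collapse = ", "), call. = FALSE)
  }
  hairpins$sequence <- unname(hp_seqs[hairpins$hairpin_id])

  mat_name <- get_attr(is_mat, "Name")
  derives <- get_attr(is_mat, "Derives_from")
  keep <- !is.na(derives)
  if (any(!keep)) {
    warning(sum(!keep), " miRNA record(s) without Derives_from skipped")
  }
  matures <- tibble::tibble(
    mature_name = mat_name[keep],
    derives_from = derives[keep],
    chrom = as.character(GenomicRanges::seqnames(gr)[is_mat])[keep],
    start = GenomicRanges::start(gr)[is_mat][keep],
    end = GenomicRanges::end(gr)[is_mat][keep],
    strand = as.character(GenomicRanges::strand(gr)[is_mat])[keep]
  )
  if (anyDuplicated(matures$mature_name)) {
    dup <- matures$mature_name[duplicated(matures$mature_name)]
    stop("duplicate mature Name: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  # Derives_from may reference the hairpin's GFF ID rather than its Name
  id2name <- stats::setNames(hairpins$hairpin_id, hairpins$gff_id)
  hid <- ifelse(matures$derives_from %in% hairpins$hairpin_id,
                matures$derives_from,
                unname(id2name[matures$derives_from]))
  if (anyNA(hid)) {
    stop("Derives_from does not match any hairpin: ",
         paste(utils::head(matures$derives_from[is.na(hid)], 3),
               collapse = ", "), call. = FALSE)
  }
  matures$hairpin_id <- hid

  missing_seq <- setdiff(matures$mature_name, names(mat_seqs))
  if (length(missing_seq)) {
    stop("mature(s) in GFF3 absent from FASTA: ",
         paste(utils::head(missing_seq, 3), collapse = ", "), call. = FALSE)
  }
  matures$sequence <- unname(mat_seqs[matures$mature_name])

  hp_by_id <- stats::setNames(hairpins$sequence, hairpins$hairpin_id)
  hp_strand <- stats::setNames(hairpins$strand, hairpins$hairpin_id)
  offs <- integer(nrow(matures))
  for (i in seq_len(nrow(matures))) {
    hp <- hp_by_id[[matures$hairpin_id[i]]]
    o <- as.integer(regexpr(matures$sequence[i], hp, fixed = TRUE))
    if (o < 1L && identical(hp_strand[[matures$hairpin_id[i]]], "-")) {
      # hairpin FASTA stored as genomic-plus sequence
      o <- as.integer(regexpr(matures$sequence[i], revcomp_rna(hp),
                              fixed = TRUE))
      if (o >= 1L) {
        hp_by_id[[matures$hairpin_id[i]]] <- revcomp_rna(hp)
      }
    }
    if (o < 1L) {
      stop("mature '", matures$mature_name[i],
           "' not found in its hairpin '", matures$hairpin_id[i], "'",
           call. = FALSE)
    }
    offs[i] <- o
  }
  hairpins$sequence <- unname(hp_by_id[hairpins$hairpin_id])
  matures$offset <- offs
  matures$length <- nchar(matures$sequence)
  bad_len <- matures$length < 16L | matures$length > 28L
  if (any(bad_len)) {
    warning("mature length outside 16..28 nt: ",
            paste(matures$mature_name[bad_len], collapse = ", "))
  }
  matures$seed <- seed_of(matures$sequence)

  new_mirna_reference(
    hairpins = hairpins[c("hairpin_id", "sequence", "chrom", "start",
                          "end", "strand")],
    matures = matures[c("mature_name", "hairpin_id", "offset", "length",
                        "sequence", "seed", "chrom", "start", "end",
                        "strand")]
  )
}

# tolerate NA in nzchar guard above
`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)

read_fasta_named <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- norm_rna(as.character(ss))
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  stats::setNames(seqs, nm)
}

new_mirna_reference <- function(hairpins, matures) {
  structure(list(hairpins = hairpins, matures = matures),
            class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat("<mirna_reference> ", nrow(x$hairpins), " hairpins, ",
      nrow(x$matures), " matures on ",
      length(unique(x$matures$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Write a reference back to FASTA + GFF3
#'
#' Inverse of [load_reference()]: emits the hairpin FASTA, mature FASTA
#' (wrapped at 60 columns) and a miRBase-dialect GFF3, such that re-loading
#' reproduces the index.
#'
#' @param ref a `mirna_reference`.
#' @param hairpin_fasta,mature_fasta,gff3 output paths.
#' @return invisibly, the three paths.
#' @export
write_reference <- function(ref, hairpin_fasta, mature_fasta, gff3) {
  stopifnot(inherits(ref, "mirna_reference"))
  write_fasta(stats::setNames(ref$hairpins$sequence, ref$hairpins$hairpin_id),
              hairpin_fasta)
  write_fasta(stats::setNames(ref$matures$sequence, ref$matures$mature_name),
              mature_fasta)

  hp <- ref$hairpins
  mat <- ref$matures
  gr_hp <- GenomicRanges::GRanges(
    seqnames = hp$chrom,
    ranges = IRanges::IRanges(start = hp$start, end = hp$end),
    strand = hp$strand,
    type = "miRNA_primary_transcript",
    ID = hp$hairpin_id, Name = hp$hairpin_id
  )
  gr_mat <- GenomicRanges::GRanges(
    seqnames = mat$chrom,
    ranges = IRanges::IRanges(start = mat$start, end = mat$end),
    strand = mat$strand,
    type = "miRNA",
    ID = mat$mature_name, Name = mat$mature_name,
    Derives_from = mat$hairpin_id
  )
  gr <- c(gr_hp, gr_mat)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(c(hairpin_fasta, mature_fasta, gff3))
}

write_fasta <- function(named_seqs, path, wrap = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(named_seqs)) {
    s <- named_seqs[[nm]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(c(paste0(">", nm),
                 substring(s, starts, pmin(starts + wrap - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Detect genomic miRNA clusters
#'
#' Genomic clusters follow the miRBase convention: miRNAs located within
#' `max_gap` bases of one another on the same chromosome. Coordinate-sorted
#' matures are chained by single linkage while the gap (intervening bases,
#' `next start - previous end - 1`) is at most `max_gap`; overlap counts as
#' gap zero. Singletons are not clusters but are reported in the
#' `"singletons"` attribute. Clusters are strand-agnostic and named
#' `Chr{chrom}.{k}` with `k` the 1-based ordinal by start on the chromosome.
#'
#' @param ref a `mirna_reference`.
#' @param max_gap maximum separation in bases (default 10000).
#' @return tibble with columns `cluster`, `chrom`, `start`, `end`,
#'   `n_members` and a list-column `members` of mature names; attribute
#'   `singletons` holds unclustered mature names.
#' @export
detect_genomic_clusters <- function(ref, max_gap = 10000) {
  stopifnot(inherits(ref, "mirna_reference"), max_gap >= 0)
  mat <- ref$matures
  empty <- tibble::tibble(cluster = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_members = integer(), members = list())
  if (nrow(mat) == 0) {
    attr(empty, "singletons") <- character()
    return(empty)
  }
  res <- mat |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$mature_name) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      gap = .data$start - dplyr::lag(cummax(.data$end)) - 1L,
      new_block = dplyr::if_else(is.na(.data$gap) | .data$gap > max_gap, 1L, 0L),
      block = cumsum(.data$new_block)
    ) |>
    dplyr::group_by(.data$chrom, .data$block) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_members = dplyr::n(),
      members = list(.data$mature_name), .groups = "drop_last"
    )
  singles <- res |>
    dplyr::filter(.data$n_members < 2L) |>
    dplyr::pull(.data$members) |>
    unlist() %||% character()
  out <- res |>
    dplyr::filter(.data$n_members >= 2L) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(cluster = paste0("Chr", sub("^chr", "", .data$chrom),
                                   ".", .data$k)) |>
    dplyr::select("cluster", "chrom", "start", "end", "n_members", "members")
  attr(out, "singletons") <- as.character(singles)
  out
}

#' Group mature miRNAs into families
#'
#' In `seed` mode, matures are partitioned by exact identity of the seed
#' (positions 2--8); `family_id` is `"seed:<seed>"`. In `annotated` mode an
#' external table assigns curated family labels; matures absent from the
#' table fall back to seed grouping and are flagged.
#'
#' @param ref a `mirna_reference`.
#' @param mode `"seed"` (default) or `"annotated"`.
#' @param annotation for `annotated` mode, a data frame with columns
#'   `mature_name` and `family_id`; mapping one mature to two families is an
#'   error.
#' @return tibble with columns `family_id`, `seed` (NA for annotated
#'   families), `n_members`, list-column `members`, and `fallback` (TRUE for
#'   seed-derived families created for unannotated matures).
#' @export
group_families <- function(ref, mode = c("seed", "annotated"),
                           annotation = NULL) {
  stopifnot(inherits(ref, "mirna_reference"))
  mode <- match.arg(mode)
  mat <- ref$matures
  seed_families <- function(m, fallback) {
    m |>
      dplyr::group_by(seed = .data$seed) |>
      dplyr::summarise(n_members = dplyr::n(),
                       members = list(sort(.data$mature_name)),
                       .groups = "drop") |>
      dplyr::mutate(family_id = paste0("seed:", .data$seed),
                    fallback = fallback) |>
      dplyr::select("family_id", "seed", "n_members", "members", "fallback")
  }
  if (mode == "seed") {
    return(dplyr::arrange(seed_families(mat, FALSE), .data$family_id))
  }
  if (is.null(annotation)) {
    stop("annotated mode requires an `annotation` table", call. = FALSE)
  }
  ann <- tibble::as_tibble(annotation)
  stopifnot(all(c("mature_name", "family_id") %in% names(ann)))
  multi <- ann |>
    dplyr::distinct(.data$mature_name, .data$family_id) |>
    dplyr::count(.data$mature_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    stop("mature(s) mapped to more than one family: ",
         paste(multi$mature_name, collapse = ", "), call. = FALSE)
  }
  annotated <- mat |>
    dplyr::inner_join(dplyr::distinct(ann), by = "mature_name") |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(seed = NA_character_, n_members = dplyr::n(),
                     members = list(sort(.data$mature_name)),
                     fallback = FALSE, .groups = "drop")
  rest <- dplyr::anti_join(mat, ann, by = "mature_name")
  out <- dplyr::bind_rows(annotated,
                          if (nrow(rest)) seed_families(rest, TRUE))
  dplyr::arrange(out, .data$family_id)
}

#' Turn cluster or family tables into a mature-to-group map
#'
#' Convenience for [aggregate_by_group()]: unnests the `members` list-column
#' into a two-column tibble.
#'
#' @param groups output of [detect_genomic_clusters()] or [group_families()].
#' @return tibble with columns `mature_name`, `group_id`.
#' @export
group_membership <- function(groups) {
  id_col <- if ("cluster" %in% names(groups)) "cluster" else "family_id"
  tibble::tibble(
    group_id = rep(groups[[id_col]], lengths(groups$members)),
    mature_name = unlist(groups$members) %||% character()
  )[c("mature_name", "group_id")]
}
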