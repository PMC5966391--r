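# Set-level statistics over externally produced target-prediction score
# tables: score filtering, Venn overlaps, multiplicity histograms, score
# correlations and hypergeometric over-representation.

check_score_table <- function(table) {
  stopifnot(all(c("gene", "predictor", "score") %in% names(table)))
  if (any(table$score < 0 | table$score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(table[c("gene", "predictor")])) {
    stop("duplicate (gene, predictor) pairs", call. = FALSE)
  }
  invisible(table)
}

#' Filter predicted targets by score
#'
#' Keeps (predictor, gene) pairs whose score is above `min_score`
#' (strict `>` by default; `strict = FALSE` uses `>=`). Raising `min_score`
#' never adds a gene.
#'
#' @param table score tibble with columns `gene`, `predictor`,
#'   `score` in \[0, 1\].
#' @param min_score threshold (default 0.8).
#' @param strict use strict inequality (default TRUE).
#' @return tibble `predictor`, `gene` of retained pairs.
#' @export
filter_targets <- function(table, min_score = 0.8, strict = TRUE) {
  check_score_table(table)
  keep <- if (strict) table$score > min_score else table$score >= min_score
  tibble::as_tibble(table[keep, c("predictor", "gene")])
}

# targets tibble -> named list of gene sets
target_sets <- function(targets) {
  split(targets$gene, targets$predictor)
}

#' Venn region counts for two or three gene sets
#'
#' Counts every disjoint region of the 2- or 3-set Venn diagram; region
#' counts sum to the union size and reconstruct each set's cardinality.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return tibble with columns `region` (e.g. `"A_only"`, `"A_B"`,
#'   `"A_B_C"`, using the set names) and `count`.
#' @export
overlap_counts <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  k <- length(sets)
  if (k < 2 || k > 3) {
    stop("2 or 3 sets supported; for more, compare pairwise", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) member <- matrix(logical(), 0, k)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))[, k:1, drop = FALSE]
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  names(combos) <- names(sets)
  region <- apply(combos, 1, function(r) {
    inc <- names(sets)[as.logical(r)]
    if (length(inc) == 1) paste0(inc, "_only") else paste(inc, collapse = "_")
  })
  count <- apply(combos, 1, function(r) {
    sum(apply(member, 1, function(x) all(x == as.logical(r))))
  })
  tibble::tibble(region = region, count = as.integer(count))
}

#' Histogram of target multiplicity
#'
#' For a group of predictors (e.g. the members of one miRNA cluster),
#' counts how many genes are targeted by exactly 1, 2, ... predictors.
#' Every gene in the union is counted once; the histogram sums to the union
#' size.
#'
#' @param targets tibble `predictor`, `gene` (e.g. from
#'   [filter_targets()]).
#' @return tibble `n_predictors`, `n_genes`.
#' @export
multiplicity_histogram <- function(targets) {
  stopifnot(all(c("predictor", "gene") %in% names(targets)))
  targets |>
    dplyr::distinct(.data$predictor, .data$gene) |>
    dplyr::count(.data$gene, name = "n_predictors") |>
    dplyr::count(.data$n_predictors, name = "n_genes") |>
    dplyr::arrange(.data$n_predictors)
}

#' Pairwise correlation of target scores
#'
#' Correlates the scores of predictor pairs over the genes scored by both
#' (no zero-filling of missing pairs: absent predictions are not evidence
#' of score 0). Pairs with fewer than 3 common genes are undefined and
#' flagged with `NA`.
#'
#' @param table score tibble (`gene`, `predictor`, `score`).
#' @param predictors optional character vector restricting (and validating)
#'   the predictors compared; default all.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return tibble `predictor_a`, `predictor_b`, `n_common`, `r` for all
#'   unordered pairs.
#' @export
score_correlation <- function(table, predictors = NULL,
                              method = c("pearson", "spearman")) {
  check_score_table(table)
  method <- match.arg(method)
  preds <- predictors %||% sort(unique(table$predictor))
  unknown <- setdiff(preds, table$predictor)
  if (length(unknown)) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  wide <- table |>
    dplyr::filter(.data$predictor %in% preds) |>
    tidyr::pivot_wider(names_from = "predictor", values_from = "score")
  pairs <- utils::combn(preds, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    r <- if (n >= 3) stats::cor(a[ok], b[ok], method = method) else NA_real_
    tibble::tibble(predictor_a = pr[1], predictor_b = pr[2],
                   n_common = n, r = r)
  })
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric test `P(X >= k)` of the overlap between a
#' query gene list and each gene set, against a fixed universe, with BH
#' adjustment across sets. The enrichment machinery is generic: gene sets
#' are user-supplied (e.g. GO-style categories).
#'
#' @param query character vector of query genes; must be contained in
#'   `universe`.
#' @param gene_sets named list of character vectors (each a subset of
#'   `universe`).
#' @param universe character vector of all considered genes.
#' @param alpha significance threshold on the adjusted p (default 0.01).
#' @return tibble with columns `set`, `k` (overlap), `K` (set size),
#'   `n` (query size), `N` (universe size), `p_value`, `padj`,
#'   `significant`.
#' @export
enrich_hypergeometric <- function(query, gene_sets, universe,
                                  alpha = 0.01) {
  query <- unique(query); universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(names(gene_sets))) {
    stop("`gene_sets` must be a named list", call. = FALSE)
  }
  N <- length(universe); n <- length(query)
  out <- purrr::imap_dfr(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, k = k, K = K, n = n, N = N, p_value = p)
  })
  out$padj <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$padj <= alpha
  out
}
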