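# Group-level expression: aggregation by family/cluster, cluster-family
# links, word-cloud rankings and the three-tier cell-type miRNAome report.

#' Aggregate expression by group
#'
#' Sums per-sample expression (typically CPM) over the members of each
#' group (seed family or genomic cluster). Matures outside every group are
#' returned separately, so that group sums plus the ungrouped remainder
#' conserve column totals exactly. Members absent from the matrix are
#' treated as zero with a warning.
#'
#' @param x tibble with a `feature` column (mature names) and numeric
#'   sample columns.
#' @param grouping two-column tibble `mature_name`, `group_id` (see
#'   [group_membership()]); a mature may belong to at most one group.
#' @return object of class `mirnaome_group_expr`: list with tibbles
#'   `expression` (`group_id` + sample columns) and `ungrouped` (the
#'   unaggregated rows outside every group).
#' @export
aggregate_by_group <- function(x, grouping) {
  stopifnot(all(c("mature_name", "group_id") %in% names(grouping)))
  if (anyDuplicated(grouping$mature_name)) {
    stop("a mature may contribute to at most one group", call. = FALSE)
  }
  cols <- sample_cols(x)
  missing <- setdiff(grouping$mature_name, x$feature)
  if (length(missing)) {
    warning("group member(s) absent from the matrix (treated as 0): ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  empty_groups <- grouping |>
    dplyr::filter(.data$mature_name %in% missing) |>
    dplyr::anti_join(dplyr::filter(grouping,
                                   .data$mature_name %in% x$feature),
                     by = "group_id") |>
    dplyr::distinct(.data$group_id)
  if (nrow(empty_groups)) {
    warning("group(s) with no member in the matrix (reported as 0): ",
            paste(empty_groups$group_id, collapse = ", "))
  }
  joined <- x |>
    dplyr::inner_join(grouping, by = c(feature = "mature_name"))
  expr <- joined |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), sum),
                     .groups = "drop")
  if (nrow(empty_groups)) {
    zeros <- tibble::as_tibble(
      c(list(group_id = empty_groups$group_id),
        stats::setNames(rep(list(0), length(cols)), cols)))
    expr <- dplyr::arrange(dplyr::bind_rows(expr, zeros), .data$group_id)
  }
  ungrouped <- dplyr::anti_join(x, grouping,
                                by = c(feature = "mature_name"))
  structure(list(expression = expr, ungrouped = ungrouped),
            class = "mirnaome_group_expr")
}

#' @export
print.mirnaome_group_expr <- function(x, ...) {
  cat("<mirnaome_group_expr> ", nrow(x$expression), " groups, ",
      nrow(x$ungrouped), " ungrouped matures\n", sep = "")
  invisible(x)
}

#' Link genomic clusters to seed families
#'
#' For each genomic cluster, lists the seed families its members belong to
#' and classifies the cluster as `single_family` (all members from one
#' family) or `multi_family`.
#'
#' @param clusters output of [detect_genomic_clusters()].
#' @param families output of [group_families()].
#' @return tibble with columns `cluster`, `families` (list-column),
#'   `n_families`, `link_type`.
#' @export
cluster_family_links <- function(clusters, families) {
  fam_of <- group_membership(families)
  purrr::map2_dfr(clusters$cluster, clusters$members, function(cl, mem) {
    fams <- sort(unique(fam_of$group_id[match(mem, fam_of$mature_name)]))
    tibble::tibble(cluster = cl, families = list(fams),
                   n_families = length(fams),
                   link_type = if (length(fams) == 1L) "single_family"
                   else "multi_family")
  })
}

#' Rank groups for a word cloud
#'
#' Weights each group by its mean expression (typically CPM) over the
#' replicates of one population, normalized so the top group has weight 1.
#' Order is deterministic: weight descending, then group name.
#'
#' @param group_expr a `mirnaome_group_expr` from [aggregate_by_group()].
#' @param population population label to rank within.
#' @param design sample design (columns `sample`, `population`).
#' @return tibble with columns `group_id`, `mean_expression`, `weight`.
#' @export
rank_for_wordcloud <- function(group_expr, population, design) {
  stopifnot(inherits(group_expr, "mirnaome_group_expr"))
  check_design(design)
  samples <- design$sample[design$population == population]
  if (!length(samples)) {
    stop("unknown population: ", population, call. = FALSE)
  }
  expr <- group_expr$expression
  samples <- intersect(samples, names(expr))
  means <- rowMeans(as.matrix(expr[samples]))
  top <- max(means)
  tibble::tibble(group_id = expr$group_id, mean_expression = means,
                 weight = if (top > 0) means / top else rep(0, length(means))) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$group_id)
}

#' Select the three-tier cell-type miRNAome
#'
#' Builds the three ranked lists characterizing one target population:
#' * `top_expressed` - the `top_n` expressed features by target-population
#'   mean CPM among features passing the expression filter;
#' * `de_vs_all` - features labelled `up` (volcano rule, `lfc_cut`/`p_cut`
#'   on the raw p-value) in the target against *every* other population
#'   separately, ranked by target mean CPM;
#' * `unique` - features with zero raw counts in every sample of every
#'   other population and target mean CPM of at least `min_mean`.
#'
#' @param counts raw count tibble (`feature` + sample columns).
#' @param design sample design covering at least two populations.
#' @param target target population label.
#' @param top_n length of the top-expressed list (default 10).
#' @param lfc_cut,p_cut volcano thresholds (defaults 3 and 0.01).
#' @param min_mean CPM floor for the unique list (default 5).
#' @param min_reads,rule expression filter settings
#'   (see [filter_expressed()]).
#' @return object of class `mirnaome_report`: list of tibbles
#'   `top_expressed` (`feature`, `mean_cpm`), `de_vs_all` (`feature`,
#'   `mean_cpm`, `n_comparisons`, list-column `evidence` of per-comparison
#'   DE rows) and `unique` (`feature`, `mean_cpm`), each sorted by target
#'   mean CPM descending.
#' @export
select_mirnaome <- function(counts, design, target, top_n = 10,
                            lfc_cut = 3, p_cut = 0.01, min_mean = 5,
                            min_reads = 5, rule = "strict") {
  m <- count_tbl_to_matrix(counts)
  check_design(design, colnames(m))
  pops <- unique(design$population)
  if (!target %in% pops) stop("unknown target population", call. = FALSE)
  if (length(pops) < 2L) stop("need >= 2 populations", call. = FALSE)
  others <- setdiff(pops, target)

  cpm <- count_tbl_to_matrix(cpm_normalize(counts))
  tgt_samples <- design$sample[design$population == target]
  tgt_mean <- rowMeans(cpm[, tgt_samples, drop = FALSE])

  expressed <- filter_expressed(counts, design, min_reads = min_reads,
                                rule = rule)$feature
  top_expressed <- tibble::tibble(feature = names(tgt_mean),
                                  mean_cpm = unname(tgt_mean)) |>
    dplyr::filter(.data$feature %in% expressed) |>
    dplyr::arrange(dplyr::desc(.data$mean_cpm), .data$feature) |>
    utils::head(top_n)

  de_list <- purrr::map(others, function(p) {
    de <- differential_expression(counts, design, pop_a = p,
                                  pop_b = target)
    de <- volcano_classify(de, lfc_cut = lfc_cut, p_cut = p_cut)
    dplyr::mutate(de, versus = p)
  })
  up_sets <- purrr::map(de_list, ~ .x$feature[.x$label == "up"])
  up_all <- Reduce(intersect, up_sets)
  evidence <- dplyr::bind_rows(de_list) |>
    dplyr::filter(.data$feature %in% up_all)
  de_vs_all <- tibble::tibble(feature = up_all,
                              mean_cpm = unname(tgt_mean[up_all]),
                              n_comparisons = length(others)) |>
    dplyr::left_join(tidyr::nest(evidence, evidence = -"feature"),
                     by = "feature") |>
    dplyr::arrange(dplyr::desc(.data$mean_cpm), .data$feature)

  other_samples <- design$sample[design$population %in% others]
  zero_outside <- rowSums(m[, other_samples, drop = FALSE] > 0) == 0
  uniq <- names(tgt_mean)[zero_outside & tgt_mean >= min_mean]
  unique_tbl <- tibble::tibble(feature = uniq,
                               mean_cpm = unname(tgt_mean[uniq])) |>
    dplyr::arrange(dplyr::desc(.data$mean_cpm), .data$feature)

  structure(list(top_expressed = top_expressed, de_vs_all = de_vs_all,
                 unique = unique_tbl, target = target),
            class = "mirnaome_report")
}

#' @export
print.mirnaome_report <- function(x, ...) {
  cat("<mirnaome_report> target ", x$target, ": ",
      nrow(x$top_expressed), " top-expressed, ",
      nrow(x$de_vs_all), " up vs all, ",
      nrow(x$unique), " unique\n", sep = "")
  invisible(x)
}
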