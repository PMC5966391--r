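# Count-matrix handling: expression filtering, CPM normalization,
# median-of-ratios size factors, NB Wald differential expression, volcano
# labels, sample distances and PCA.

#' Filter features by expression
#'
#' Keeps a feature when at least one population supports it: under the
#' `"strict"` rule every replicate of some population must have at least
#' `min_reads` reads; under `"mean_only"` some population's replicate mean
#' must be at least `min_reads`. The strict rule implies the mean rule, so
#' `strict` feature sets are always a subset of `mean_only` sets.
#'
#' @param counts tibble with a `feature` column and one numeric count column
#'   per sample.
#' @param design sample design (columns `sample`, `population`) covering all
#'   count columns.
#' @param min_reads non-negative threshold (default 5).
#' @param rule `"strict"` (default) or `"mean_only"`.
#' @return the filtered count tibble.
#' @export
filter_expressed <- function(counts, design, min_reads = 5,
                             rule = c("strict", "mean_only")) {
  rule <- match.arg(rule)
  if (min_reads < 0) stop("`min_reads` must be >= 0", call. = FALSE)
  m <- count_tbl_to_matrix(counts)
  check_design(design, colnames(m))
  pops <- split(design$sample[design$sample %in% colnames(m)],
                design$population[design$sample %in% colnames(m)])
  keep <- Reduce(`|`, lapply(pops, function(s) {
    sub <- m[, s, drop = FALSE]
    if (rule == "strict") {
      apply(sub, 1, function(x) all(x >= min_reads))
    } else {
      rowMeans(sub) >= min_reads
    }
  }))
  counts[keep, , drop = FALSE]
}

#' Counts-per-million normalization
#'
#' Scales each sample (column) to a library size of one million:
#' `cpm = count / column_total * 1e6`. All-zero columns are returned as
#' zeros with a warning.
#'
#' @param counts tibble with a `feature` column and numeric sample columns.
#' @return tibble of the same shape with CPM values.
#' @export
cpm_normalize <- function(counts) {
  m <- count_tbl_to_matrix(counts)
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("all-zero sample column(s): ",
            paste(colnames(m)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  matrix_to_count_tbl(sweep(m, 2, tot, "/") * 1e6)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with nonzero counts in every sample) of the ratio of the
#' count to the feature's geometric mean across samples; factors are then
#' rescaled to geometric mean 1.
#'
#' @param counts tibble with a `feature` column and numeric sample columns.
#' @return tibble with columns `sample`, `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- count_tbl_to_matrix(counts)
  if (ncol(m) == 1L) {
    return(tibble::tibble(sample = colnames(m), size_factor = 1))
  }
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) {
    stop("no feature has nonzero counts in every sample; ",
         "consider adding a pseudocount to the matrix", call. = FALSE)
  }
  logm <- log(m[ok, , drop = FALSE])
  gm <- rowMeans(logm)
  sf <- exp(apply(logm - gm, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Negative-binomial Wald differential expression
#'
#' A transparent NB Wald pipeline: counts are normalized by median-of-ratios
#' size factors; per-feature dispersion is estimated by method of moments on
#' the normalized counts pooled within the two compared groups,
#' `alpha = max((s2 - mu)/mu^2, min_dispersion)` with `s2` the df-weighted
#' pooled within-group variance and `mu` the overall normalized mean; the
#' fold change is `log2((meanB + pseudocount)/(meanA + pseudocount))`; the
#' Wald statistic divides it by a delta-method standard error under the NB
#' variance `mu + alpha mu^2`; two-sided p-values use a t reference with
#' `nA + nB - 2` degrees of freedom (a small-sample calibration; pass
#' `df = Inf` for the normal reference) and are BH-adjusted across features.
#' Dispersion is pooled within the two compared groups only, with no
#' shrinkage toward a mean-dispersion trend.
#'
#' @param counts tibble with a `feature` column and numeric sample columns.
#' @param design sample design (columns `sample`, `population`).
#' @param pop_a,pop_b the two population labels to compare (fold changes are
#'   B versus A).
#' @param pseudocount added to group means before the log ratio
#'   (default 0.5).
#' @param min_dispersion dispersion floor (default 1e-8, effectively
#'   Poisson).
#' @param df degrees of freedom of the p-value reference; default
#'   `nA + nB - 2`, `Inf` gives the normal reference.
#' @return tibble of class `mirnaome_de` with columns `feature`,
#'   `base_mean_a`, `base_mean_b`, `log2fc`, `se`, `stat`, `pvalue`, `padj`.
#' @export
differential_expression <- function(counts, design, pop_a, pop_b,
                                    pseudocount = 0.5,
                                    min_dispersion = 1e-8, df = NULL) {
  m <- count_tbl_to_matrix(counts)
  check_design(design, colnames(m))
  sa <- design$sample[design$population == pop_a]
  sb <- design$sample[design$population == pop_b]
  sa <- intersect(sa, colnames(m)); sb <- intersect(sb, colnames(m))
  if (length(sa) < 2L || length(sb) < 2L) {
    stop("need >= 2 replicates in each compared population", call. = FALSE)
  }
  sub <- m[, c(sa, sb), drop = FALSE]
  sf <- estimate_size_factors(matrix_to_count_tbl(sub))
  norm <- sweep(sub, 2, sf$size_factor[match(colnames(sub), sf$sample)], "/")
  A <- norm[, sa, drop = FALSE]; B <- norm[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  mu_a <- rowMeans(A); mu_b <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  s2 <- (va * (na - 1) + vb * (nb - 1)) / (na + nb - 2)
  mu <- (mu_a * na + mu_b * nb) / (na + nb)
  disp <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, min_dispersion),
                 min_dispersion)
  log2fc <- log2((mu_b + pseudocount) / (mu_a + pseudocount))
  var_a <- (mu_a + disp * mu_a^2) / na
  var_b <- (mu_b + disp * mu_b^2) / nb
  se <- sqrt(var_a / (mu_a + pseudocount)^2 +
               var_b / (mu_b + pseudocount)^2) / log(2)
  se[se == 0] <- NA_real_
  stat <- log2fc / se
  stat[is.na(stat) & log2fc == 0] <- 0
  df_use <- df %||% (na + nb - 2)
  pvalue <- 2 * stats::pt(-abs(stat), df = df_use)
  pvalue[is.na(pvalue)] <- 1
  out <- tibble::tibble(feature = rownames(m),
                        base_mean_a = unname(mu_a),
                        base_mean_b = unname(mu_b),
                        log2fc = unname(log2fc), se = unname(se),
                        stat = unname(stat), pvalue = unname(pvalue),
                        padj = unname(stats::p.adjust(pvalue, "BH")))
  class(out) <- c("mirnaome_de", class(out))
  attr(out, "comparison") <- c(a = pop_a, b = pop_b)
  attr(out, "df") <- df_use
  out
}

#' Volcano classification of DE results
#'
#' Labels each feature `up` if `log2fc >= lfc_cut` and its p-value is at
#' most `p_cut`, `down` for the mirrored condition, otherwise `ns`.
#'
#' @param de a `mirnaome_de` tibble from [differential_expression()].
#' @param lfc_cut absolute log2 fold-change threshold (default 3).
#' @param p_cut p-value threshold (default 0.01).
#' @param use `"pvalue"` (default, the raw p-value) or `"padj"`.
#' @return the input with an added `label` column.
#' @export
volcano_classify <- function(de, lfc_cut = 3, p_cut = 0.01,
                             use = c("pvalue", "padj")) {
  use <- match.arg(use)
  p <- de[[use]]
  de$label <- dplyr::case_when(
    de$log2fc >= lfc_cut & p <= p_cut ~ "up",
    de$log2fc <= -lfc_cut & p <= p_cut ~ "down",
    TRUE ~ "ns")
  de
}

#' Euclidean sample-to-sample distances
#'
#' Computes the Euclidean distance between all sample pairs over features,
#' typically on a `log2(CPM + 1)` matrix.
#'
#' @param x tibble with a `feature` column and numeric sample columns.
#' @return long tibble `sample_a`, `sample_b`, `distance` covering all
#'   ordered pairs (symmetric with a zero diagonal).
#' @export
sample_distances <- function(x) {
  m <- count_tbl_to_matrix(x)
  d <- as.matrix(stats::dist(t(m)))
  tibble::tibble(sample_a = rep(rownames(d), ncol(d)),
                 sample_b = rep(colnames(d), each = nrow(d)),
                 distance = as.vector(d))
}

#' Principal component analysis of samples
#'
#' PCA of samples over features (samples are observations). Components are
#' ordered by decreasing explained variance and loadings are orthonormal.
#'
#' @param x tibble with a `feature` column and numeric sample columns,
#'   typically `log2(CPM + 1)` values.
#' @param n_components number of components to return (default 2); must not
#'   exceed `min(n_samples - 1, n_features)`.
#' @param scale scale features to unit variance first (default FALSE;
#'   constant features are dropped when scaling).
#' @return object of class `mirnaome_pca`: list with tibbles `scores`
#'   (`sample`, `PC1`, ...), `loadings` (`feature`, `PC1`, ...) and
#'   `explained` (`component`, `variance_fraction`).
#' @export
pca_project <- function(x, n_components = 2, scale = FALSE) {
  m <- count_tbl_to_matrix(x)
  if (scale) {
    sds <- apply(m, 1, stats::sd)
    m <- m[sds > 0, , drop = FALSE]
  }
  max_comp <- min(ncol(m) - 1L, nrow(m))
  if (n_components > max_comp) {
    stop("n_components exceeds min(samples - 1, features) = ", max_comp,
         call. = FALSE)
  }
  pc <- stats::prcomp(t(m), center = TRUE, scale. = scale)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(n_components)
  scores <- tibble::as_tibble(pc$x[, keep, drop = FALSE])
  scores <- tibble::add_column(scores, sample = colnames(m), .before = 1)
  loadings <- tibble::as_tibble(pc$rotation[, keep, drop = FALSE])
  loadings <- tibble::add_column(loadings, feature = rownames(m),
                                 .before = 1)
  structure(list(scores = scores, loadings = loadings,
                 explained = tibble::tibble(
                   component = paste0("PC", seq_along(ev)),
                   variance_fraction = ev)),
            class = "mirnaome_pca")
}

#' @export
print.mirnaome_pca <- function(x, ...) {
  cat("<mirnaome_pca> ", nrow(x$scores), " samples; explained: ",
      paste0(round(100 * utils::head(x$explained$variance_fraction, 3), 1),
             "%", collapse = ", "), "\n", sep = "")
  invisible(x)
}
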