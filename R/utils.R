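# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U; errors on any character outside A/C/G/U.
#' @param x character vector of sequences.
#' @return character vector in the A/C/G/U alphabet.
#' @keywords internal
#' @noRd
norm_rna <- function(x) {
  x <- chartr("acgtuT", "ACGUUU", x)
  bad <- grepl("[^ACGU]", x) | !nzchar(x)
  if (any(bad)) {
    stop("sequence(s) outside the A/C/G/U alphabet (after T->U): ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  x
}

# reverse complement in the RNA alphabet
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- count-table helpers -----------------------------------------------
# User-facing count matrices are tibbles with a `feature` id column and one
# numeric column per sample; these converters move to/from a plain matrix.

count_tbl_to_matrix <- function(x, feature_col = "feature") {
  stopifnot(is.data.frame(x), feature_col %in% names(x))
  feats <- as.character(x[[feature_col]])
  if (anyDuplicated(feats)) stop("duplicate feature names", call. = FALSE)
  m <- as.matrix(x[setdiff(names(x), feature_col)])
  if (!is.numeric(m)) stop("sample columns must be numeric", call. = FALSE)
  rownames(m) <- feats
  m
}

matrix_to_count_tbl <- function(m, feature_col = "feature") {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, !!feature_col := rownames(m), .before = 1)
  out
}

check_design <- function(design, samples = NULL) {
  stopifnot(is.data.frame(design))
  if (!all(c("sample", "population") %in% names(design))) {
    stop("`design` needs columns `sample` and `population`", call. = FALSE)
  }
  if (anyDuplicated(design$sample)) {
    stop("duplicate sample names in `design`", call. = FALSE)
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, design$sample)
    if (length(missing)) {
      stop("samples absent from `design`: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(design)
}

# sample columns of a count tibble (everything but the feature id column)
sample_cols <- function(x, feature_col = "feature") {
  setdiff(names(x), feature_col)
}
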