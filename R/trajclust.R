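# Fuzzy c-means clustering of standardized per-stage expression profiles.

#' Per-stage mean profiles
#'
#' Collapses a sample-level expression matrix to per-population replicate
#' means, in the stage order given by `stages` (or the order of appearance
#' in the design). Typically applied to `log2(CPM + 1)` values.
#'
#' @param x tibble with a `feature` column and numeric sample columns.
#' @param design sample design (columns `sample`, `population`).
#' @param stages optional character vector fixing the stage order.
#' @param log2 take `log2(x + 1)` of the values first (default TRUE, for
#'   CPM input).
#' @return tibble with a `feature` column and one column per stage.
#' @export
stage_profiles <- function(x, design, stages = NULL, log2 = TRUE) {
  m <- count_tbl_to_matrix(x)
  check_design(design, colnames(m))
  if (log2) m <- log2(m + 1)
  stages <- stages %||% unique(design$population[
    design$sample %in% colnames(m)])
  prof <- vapply(stages, function(p) {
    rowMeans(m[, design$sample[design$population == p], drop = FALSE])
  }, numeric(nrow(m)))
  matrix_to_count_tbl(prof)
}

#' Standardize expression profiles
#'
#' Row-wise z-scoring (sample standard deviation, ddof 1) of per-stage
#' profiles, so that clustering sees shapes rather than expression levels.
#' Constant rows cannot be standardized; they are dropped with a warning and
#' recorded in the `"dropped"` attribute.
#'
#' @param profiles tibble with a `feature` column and at least two numeric
#'   stage columns.
#' @return tibble of the same shape; every row has mean 0 and sd 1.
#' @export
standardize_profiles <- function(profiles) {
  m <- count_tbl_to_matrix(profiles)
  if (ncol(m) < 2L) stop("need at least 2 stages", call. = FALSE)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  constant <- sdv == 0 | !is.finite(sdv)
  if (any(constant)) {
    warning(sum(constant), " constant profile(s) dropped")
  }
  z <- (m[!constant, , drop = FALSE] - mu[!constant]) / sdv[!constant]
  out <- matrix_to_count_tbl(z)
  attr(out, "dropped") <- rownames(m)[constant]
  out
}

# canonical row order by profile values, so initialization is independent of
# input row order
canonical_row_order <- function(m) {
  do.call(order, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                   list(rownames(m))))
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with Euclidean distances: memberships
#' `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))`, centroids the
#' `u^m`-weighted means of the rows, iterated until the largest membership
#' change falls below `tol` or `max_iter` is reached. A point coincident
#' with a centroid gets membership 1 there. Initial centroids are `c`
#' distinct rows chosen by a seeded draw over the canonical (value-sorted)
#' row order, so results do not depend on input row order.
#'
#' @param profiles tibble with a `feature` column and numeric stage
#'   columns, usually from [standardize_profiles()].
#' @param c number of clusters (`1 <= c <=` number of rows).
#' @param m fuzzifier, > 1 (default 2); values near 1 approach hard
#'   clustering.
#' @param tol convergence tolerance on memberships (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param seed integer seed for the initialization draw.
#' @param restarts number of seeded random restarts (default 10); the fit
#'   with the lowest final objective is returned. Ignored when `init` is
#'   given.
#' @param init optional numeric matrix of initial centroids (c x stages),
#'   overriding the seeded draw (single fit).
#' @return object of class `mirnaome_fcm`: list with `membership`
#'   (features x c matrix), `centroids` (c x stages matrix), `objective`
#'   (per-iteration trace of the weighted within-cluster sum of squared
#'   distances), `m`, `c`, and `features`/`stages` names.
#' @export
fuzzy_cmeans <- function(profiles, c, m = 2, tol = 1e-6, max_iter = 500,
                         seed = 1L, restarts = 10L, init = NULL) {
  if (is.null(init) && restarts > 1L) {
    fits <- lapply(seq_len(restarts), function(r) {
      fuzzy_cmeans(profiles, c = c, m = m, tol = tol,
                   max_iter = max_iter, seed = seed * 131L + r,
                   restarts = 1L)
    })
    obj <- vapply(fits, function(f) utils::tail(f$objective, 1),
                  numeric(1))
    return(fits[[which.min(obj)]])
  }
  x <- count_tbl_to_matrix(profiles)
  n <- nrow(x)
  if (c > n) stop("`c` exceeds the number of profiles", call. = FALSE)
  stopifnot(c >= 1, m > 1)

  if (is.null(init)) {
    ord <- canonical_row_order(x)
    xs <- x[ord, , drop = FALSE]
    uniq <- !duplicated(xs)
    pool <- which(uniq)
    if (length(pool) < c) {
      stop("fewer than `c` distinct profiles", call. = FALSE)
    }
    pick <- withr::with_seed(seed, sample(pool, c))
    init <- xs[pick, , drop = FALSE]
  }
  centroids <- as.matrix(init)

  u_from_centroids <- function(cent) {
    d2 <- outer(rowSums(x^2), rep(1, nrow(cent))) -
      2 * x %*% t(cent) + outer(rep(1, n), rowSums(cent^2))
    d2[d2 < 0] <- 0
    zero <- d2 < 1e-300
    u <- matrix(0, n, nrow(cent))
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    if (any(!hit)) {
      w <- d2[!hit, , drop = FALSE]^(-1 / (m - 1))
      u[!hit, ] <- w / rowSums(w)
    }
    list(u = u, d2 = d2)
  }

  res <- u_from_centroids(centroids)
  u <- res$u
  objective <- sum(u^m * res$d2)
  for (it in seq_len(max_iter)) {
    um <- u^m
    centroids <- (t(um) %*% x) / colSums(um)
    res <- u_from_centroids(centroids)
    objective <- c(objective, sum(res$u^m * res$d2))
    delta <- max(abs(res$u - u))
    u <- res$u
    if (delta < tol) break
  }
  dimnames(u) <- list(rownames(x), paste0("cluster", seq_len(c)))
  dimnames(centroids) <- list(paste0("cluster", seq_len(c)), colnames(x))
  structure(list(membership = u, centroids = centroids,
                 objective = objective, m = m, c = c,
                 features = rownames(x), stages = colnames(x)),
            class = "mirnaome_fcm")
}

#' @export
print.mirnaome_fcm <- function(x, ...) {
  cat("<mirnaome_fcm> c = ", x$c, ", m = ", x$m, ", ",
      length(x$features), " profiles, ", length(x$objective) - 1,
      " iterations, objective ",
      signif(utils::tail(x$objective, 1), 6), "\n", sep = "")
  invisible(x)
}

#' Choose the number of fuzzy clusters
#'
#' Fits best-of-`restarts` fuzzy c-means models for each candidate `c` and
#' reports the minimum pairwise centroid distance as the separation
#' diagnostic. The chosen `c` is the largest candidate whose minimum
#' centroid distance exceeds `min_separation` (in standardized units);
#' splitting a real pattern in two produces nearly coincident centroids and
#' a collapsing diagnostic.
#'
#' @param profiles standardized profile tibble.
#' @param c_range integer candidates (default 2:10).
#' @param m fuzzifier (default 2).
#' @param seed integer seed; restart seeds are derived from it.
#' @param restarts random restarts per candidate (default 10); the model
#'   with the lowest final objective is kept.
#' @param min_separation separation threshold (default 0.5).
#' @return list with `chosen_c` and `diagnostics`, a tibble of `c`,
#'   `objective` and `min_centroid_distance`.
#' @export
select_cluster_number <- function(profiles, c_range = 2:10, m = 2,
                                  seed = 1L, restarts = 10,
                                  min_separation = 0.5) {
  if (!length(c_range)) stop("empty `c_range`", call. = FALSE)
  fits <- purrr::map(c_range, function(cc) {
    fuzzy_cmeans(profiles, c = cc, m = m,
                 seed = seed * 1000L + cc, restarts = restarts)
  })
  diag <- purrr::map2_dfr(fits, c_range, function(fit, cc) {
    cent <- fit$centroids
    min_d <- if (nrow(cent) < 2) Inf else min(stats::dist(cent))
    tibble::tibble(c = cc, objective = utils::tail(fit$objective, 1),
                   min_centroid_distance = min_d)
  })
  ok <- diag$c[diag$min_centroid_distance > min_separation]
  chosen <- if (length(ok)) max(ok) else min(c_range)
  list(chosen_c = chosen, diagnostics = diag)
}

#' Hard cluster assignment from a fuzzy model
#'
#' Assigns each feature to its maximum-membership cluster when that
#' membership reaches `min_membership`, otherwise leaves it unassigned
#' (`NA`). Ties go to the lowest cluster index.
#'
#' @param model a `mirnaome_fcm`.
#' @param min_membership assignment threshold (default 0.5).
#' @return tibble with columns `feature`, `cluster` (integer or NA) and
#'   `membership` (the maximum membership).
#' @export
assign_clusters <- function(model, min_membership = 0.5) {
  stopifnot(inherits(model, "mirnaome_fcm"))
  u <- model$membership
  best <- max.col(u, ties.method = "first")
  mx <- u[cbind(seq_len(nrow(u)), best)]
  tibble::tibble(feature = model$features,
                 cluster = ifelse(mx >= min_membership, best, NA_integer_),
                 membership = mx)
}
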