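# Retrieval evaluation: average precision, MAP, precision at X, the
# fraction of queries with any top-X hit, query-level k-fold splits, and
# the dual (paired t-test AND Wilcoxon signed-rank) significance rule.

#' Average precision of one ranked run
#'
#' AP = (1/k) * sum over the k targets of j / rank(j-th target), with
#' targets indexed in rank order — equivalently the mean of the
#' precision at each target's rank. A query with no targets scores 0:
#' ranking systems are evaluated on uncorrelated pairs too, so such
#' queries stay in the denominator of MAP.
#'
#' @param ranked_ids Character vector of candidate ids in rank order
#'   (no duplicates).
#' @param targets Character vector of target (relevant) ids.
#' @return AP in [0, 1].
#' @export
average_precision <- function(ranked_ids, targets) {
  if (length(ranked_ids) == 0L) {
    stop("empty candidate ranking", call. = FALSE)
  }
  if (anyDuplicated(ranked_ids)) {
    stop("ranked candidate list contains duplicates", call. = FALSE)
  }
  hits <- ranked_ids %in% targets
  k <- sum(hits)
  if (k == 0L) return(0)
  ranks <- which(hits)
  mean(seq_len(k) / ranks)
}

#' Mean average precision over queries
#'
#' Arithmetic mean of per-query AP over all queries, including
#' zero-target queries (which contribute 0).
#'
#' @param runs List of runs, each a list with `ranked_ids` and
#'   `targets`.
#' @return MAP in [0, 1].
#' @export
mean_average_precision <- function(runs) {
  if (length(runs) == 0L) stop("no runs to average", call. = FALSE)
  mean(vapply(runs, function(r) {
    average_precision(r$ranked_ids, r$targets)
  }, 1.0))
}

#' Precision at X
#'
#' Fraction of the top X ranked candidates that are targets. The
#' denominator stays X even when fewer than X candidates exist.
#'
#' @inheritParams average_precision
#' @param x Cut-off X >= 1.
#' @return P@X in [0, 1].
#' @export
precision_at_x <- function(ranked_ids, targets, x) {
  stopifnot(x >= 1)
  top <- ranked_ids[seq_len(min(x, length(ranked_ids)))]
  sum(top %in% targets) / x
}

#' Fraction of queries with any top-X hit
#'
#' @inheritParams mean_average_precision
#' @param x Cut-off X >= 1.
#' @return Fraction of runs with P@X > 0, in [0, 1].
#' @export
fraction_pairs_positive <- function(runs, x) {
  if (length(runs) == 0L) stop("no runs", call. = FALSE)
  mean(vapply(runs, function(r) {
    precision_at_x(r$ranked_ids, r$targets, x) > 0
  }, TRUE))
}

#' Split queries into cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so folds
#' partition the queries with sizes differing by at most one and the
#' plan is reproducible from the seed.
#'
#' @param pair_ids Character vector of query identifiers.
#' @param k Number of folds (>= 2). Default 4.
#' @param seed Integer seed.
#' @return A `crf_fold_plan`: list of k character vectors.
#' @export
make_folds <- function(pair_ids, k = 4, seed = 1) {
  if (k < 2) stop("at least 2 folds required", call. = FALSE)
  if (length(pair_ids) < k) {
    stop("need at least as many queries as folds", call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(pair_ids)
  assignment <- rep_len(seq_len(k), length(shuffled))
  folds <- lapply(seq_len(k), function(i) shuffled[assignment == i])
  structure(folds, seed = seed, class = "crf_fold_plan")
}

#' @export
print.crf_fold_plan <- function(x, ...) {
  cat("<crf_fold_plan: ", length(x), " folds of sizes ",
      paste(lengths(x), collapse = "/"), ", seed ", attr(x, "seed"),
      ">\n", sep = "")
  invisible(x)
}

#' Dual significance test on paired per-query metrics
#'
#' Runs both the paired t-test and the Wilcoxon signed-rank test on the
#' per-query differences and declares the difference significant only
#' if BOTH p-values are at or below `alpha`. Zero differences are
#' dropped for the signed-rank test (its standard convention); when all
#' differences are zero the verdict is not-significant with
#' `degenerate = TRUE`.
#'
#' @param metric_a,metric_b Equal-length numeric vectors, paired by
#'   query.
#' @param alpha Significance level. Default 0.05.
#' @return List with `p_t`, `p_wilcoxon`, `significant`, `degenerate`,
#'   `mean_diff` (mean of b - a).
#' @export
compare_significance <- function(metric_a, metric_b, alpha = 0.05) {
  if (length(metric_a) != length(metric_b)) {
    stop("paired metric vectors must have equal length", call. = FALSE)
  }
  if (length(metric_a) < 5L) {
    stop("at least 5 paired observations required", call. = FALSE)
  }
  d <- metric_b - metric_a
  if (all(d == 0)) {
    return(list(p_t = NA_real_, p_wilcoxon = NA_real_,
                significant = FALSE, degenerate = TRUE, mean_diff = 0))
  }
  p_t <- stats::t.test(metric_b, metric_a, paired = TRUE)$p.value
  nz <- d[d != 0]
  p_w <- suppressWarnings(
    stats::wilcox.test(nz, exact = FALSE, correct = TRUE)$p.value
  )
  list(p_t = p_t, p_wilcoxon = p_w,
       significant = isTRUE(p_t <= alpha) && isTRUE(p_w <= alpha),
       degenerate = FALSE, mean_diff = mean(d))
}
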