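#' Fit a pairwise linear ranking SVM
#'
#' Reduces learning-to-rank with binary relevance to large-margin
#' classification of preference pairs: within each query group, every
#' (relevant, non-relevant) row difference becomes a training vector,
#' mirrored as both (p - n, +1) and (n - p, -1) for symmetry. A linear
#' scorer is fitted on the standardized differences by minimizing the
#' L2-regularized squared-hinge primal
#' \deqn{\tfrac12\|w\|^2 + C \sum_i \max(0, 1 - y_i w^\top x_i)^2}
#' with a deterministic quasi-Newton solve, so refitting with the same
#' inputs reproduces identical weights. Features are standardized with
#' the mean and standard deviation of the training rows (queries' raw
#' candidate rows, not differences); constant features get weight 0.
#'
#' @param x Numeric feature matrix, one row per candidate.
#' @param y Binary relevance labels (0/1 or logical), length `nrow(x)`.
#' @param group Query identifier per row; differences are only formed
#'   within a group.
#' @param c_reg Regularization strength C (> 0). Default 1.
#' @param tol Convergence tolerance of the solver. Default 1e-6.
#' @param seed Optional integer recorded in the model (the solve itself
#'   is deterministic; the seed only matters when
#'   `max_diffs_per_group` subsamples difference pairs).
#' @param max_diffs_per_group Cap on (positive, negative) combinations
#'   per group; pairs beyond the cap are subsampled with `seed`.
#'   Default `Inf` (all pairs).
#' @return An object of class `ranksvm` with components `weights`
#'   (standardized space), `center`, `scale`, `feature_names`, `c_reg`,
#'   `tol`, `seed`, `n_groups`, `n_diffs`, `objective`, `convergence`.
#' @seealso [rank_candidates()], [coef.ranksvm()], [predict.ranksvm()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 2)
#' y <- as.integer(x[, 1] > 0)
#' fit <- ranksvm(x, y, group = rep(1:10, each = 10))
#' coef(fit)
#' @export
ranksvm <- function(x, y, group, c_reg = 1, tol = 1e-6, seed = NULL,
                    max_diffs_per_group = Inf) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(as.logical(y))
  group <- as.character(group)
  if (nrow(x) != length(y) || nrow(x) != length(group)) {
    stop("`x`, `y` and `group` must have matching lengths", call. = FALSE)
  }
  stopifnot(c_reg > 0, tol > 0)
  feature_names <- colnames(x)
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(x)))
    colnames(x) <- feature_names
  }

  center <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  constant <- !is.finite(sdv) | sdv < 1e-12
  scale_ <- ifelse(constant, 1, sdv)
  xs <- sweep(sweep(x, 2L, center, "-"), 2L, scale_, "/")

  # all (positive, negative) index pairs within each group
  pos_idx <- integer(0)
  neg_idx <- integer(0)
  groups <- split(seq_along(group), group)
  if (is.finite(max_diffs_per_group) && !is.null(seed)) set.seed(seed)
  for (g in groups) {
    p <- g[y[g] == 1L]
    n <- g[y[g] == 0L]
    if (length(p) == 0L || length(n) == 0L) next
    pi <- rep(p, each = length(n))
    ni <- rep(n, times = length(p))
    if (is.finite(max_diffs_per_group) && length(pi) > max_diffs_per_group) {
      keep <- sample.int(length(pi), max_diffs_per_group)
      pi <- pi[keep]
      ni <- ni[keep]
    }
    pos_idx <- c(pos_idx, pi)
    neg_idx <- c(neg_idx, ni)
  }
  if (length(pos_idx) == 0L) {
    stop("vacuous training set: no query group has both a relevant and ",
         "a non-relevant candidate", call. = FALSE)
  }
  d <- xs[pos_idx, , drop = FALSE] - xs[neg_idx, , drop = FALSE]
  X <- rbind(d, -d)[, !constant, drop = FALSE]
  yv <- c(rep(1, nrow(d)), rep(-1, nrow(d)))

  obj <- function(w) {
    m <- pmax(0, 1 - yv * drop(X %*% w))
    0.5 * sum(w^2) + c_reg * sum(m^2)
  }
  grad <- function(w) {
    m <- pmax(0, 1 - yv * drop(X %*% w))
    w - 2 * c_reg * drop(crossprod(X, yv * m))
  }
  fit <- stats::optim(rep(0, ncol(X)), obj, grad, method = "BFGS",
                      control = list(reltol = tol, maxit = 2000L))

  weights <- stats::setNames(numeric(ncol(x)), feature_names)
  weights[!constant] <- fit$par
  structure(
    list(weights = weights, center = center, scale = scale_,
         constant = constant, feature_names = feature_names,
         c_reg = c_reg, tol = tol, seed = seed,
         n_groups = sum(vapply(groups, function(g) {
           any(y[g] == 1L) && any(y[g] == 0L)
         }, TRUE)),
         n_diffs = nrow(d), objective = fit$value,
         convergence = fit$convergence, call = match.call()),
    class = "ranksvm"
  )
}

#' @export
print.ranksvm <- function(x, digits = max(3L, getOption("digits") - 3L),
                          ...) {
  cat("Pairwise linear ranking SVM\n")
  cat("  features:", length(x$weights), " queries with preferences:",
      x$n_groups, " difference pairs:", x$n_diffs, "\n")
  cat("  C =", format(x$c_reg), " objective =",
      format(x$objective, digits = digits), "\n")
  cat("Weights (standardized feature space):\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' Extract ranking weights
#'
#' @param object A `ranksvm` fit.
#' @param scale `"standardized"` (the space the model was fitted in) or
#'   `"raw"` (weights divided by the per-feature training standard
#'   deviation, so they apply to unscaled features).
#' @param ... Unused.
#' @return Named numeric weight vector.
#' @export
coef.ranksvm <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") object$weights
  else object$weights / object$scale
}

#' Score new candidates with a fitted ranking SVM
#'
#' @param object A `ranksvm` fit.
#' @param newdata Numeric matrix (or data frame) with the same feature
#'   columns as at fit time.
#' @param ... Unused.
#' @return Numeric score vector (larger = ranked higher).
#' @export
predict.ranksvm <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$weights)) {
    stop("newdata has ", ncol(x), " columns but the model was fitted on ",
         length(object$weights), call. = FALSE)
  }
  xs <- sweep(sweep(x, 2L, object$center, "-"), 2L, object$scale, "/")
  drop(xs %*% object$weights)
}

#' @export
summary.ranksvm <- function(object, ...) {
  w <- object$weights
  out <- list(model = object,
              table = data.frame(feature = object$feature_names,
                                 weight_std = unname(w),
                                 weight_raw = unname(w / object$scale),
                                 constant = unname(object$constant)))
  class(out) <- "summary.ranksvm"
  out
}

#' @export
print.summary.ranksvm <- function(x, ...) {
  print(x$model)
  cat("\nPer-feature weights:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ranksvm <- function(x, ...) {
  graphics::barplot(x$weights, las = 2,
                    main = "Ranking SVM weights (standardized)",
                    ylab = "weight", ...)
  invisible(x)
}

#' Rank candidates for one query
#'
#' Scores the candidates with a fitted model (or uses supplied scores)
#' and orders them by descending score, ties broken by ascending
#' `ref_id` in the C locale, so rankings are fully deterministic.
#'
#' @param model A `ranksvm` fit, or `NULL` when `scores` is given.
#' @param features Feature matrix for the candidates (ignored when
#'   `scores` is given).
#' @param ref_ids Candidate identifiers, one per row/score.
#' @param scores Optional precomputed scores (for the score-based
#'   baselines).
#' @return Data frame with `rank`, `ref_id`, `score` in rank order.
#' @export
rank_candidates <- function(model, features, ref_ids, scores = NULL) {
  if (is.null(scores)) {
    scores <- predict(model, features)
  }
  ref_ids <- as.character(ref_ids)
  if (length(scores) != length(ref_ids)) {
    stop("one score per candidate required", call. = FALSE)
  }
  ord <- order(-scores, ref_ids, method = "radix")
  data.frame(rank = seq_along(ord), ref_id = ref_ids[ord],
             score = scores[ord], stringsAsFactors = FALSE)
}

#' Serialize a ranking SVM model to a plain-text file
#'
#' Key-value format: one line per scalar field plus tab-separated
#' per-feature lines (name, center, scale, weight).
#'
#' @param model A `ranksvm` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranksvm <- function(model, path) {
  num <- function(x) format(x, digits = 17)
  lines <- c(
    "format: ranksvm/1",
    paste0("c_reg: ", num(model$c_reg)),
    paste0("tol: ", num(model$tol)),
    paste0("seed: ", if (is.null(model$seed)) "NA" else model$seed),
    paste0("n_groups: ", model$n_groups),
    paste0("n_diffs: ", model$n_diffs),
    paste0("objective: ", num(model$objective)),
    "features:",
    vapply(seq_along(model$weights), function(i) {
      paste(model$feature_names[i], num(model$center[i]),
            num(model$scale[i]), num(model$weights[i]), sep = "\t")
    }, "")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a serialized ranking SVM model
#'
#' @param path Path written by [write_ranksvm()].
#' @return A `ranksvm` object (without the original call).
#' @export
read_ranksvm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[1L], "format: ranksvm/1")) {
    stop("not a ranksvm model file: ", path, call. = FALSE)
  }
  header <- lines[2:7]
  get_val <- function(key) {
    ln <- header[startsWith(header, paste0(key, ": "))]
    sub(paste0("^", key, ": "), "", ln)
  }
  feat_lines <- lines[(which(lines == "features:") + 1L):length(lines)]
  parts <- strsplit(feat_lines, "\t", fixed = TRUE)
  feature_names <- vapply(parts, `[[`, "", 1L)
  center <- stats::setNames(as.numeric(vapply(parts, `[[`, "", 2L)),
                            feature_names)
  scale_ <- stats::setNames(as.numeric(vapply(parts, `[[`, "", 3L)),
                            feature_names)
  weights <- stats::setNames(as.numeric(vapply(parts, `[[`, "", 4L)),
                             feature_names)
  seed_raw <- get_val("seed")
  structure(
    list(weights = weights, center = center, scale = scale_,
         constant = weights == 0 & scale_ == 1,
         feature_names = feature_names,
         c_reg = as.numeric(get_val("c_reg")),
         tol = as.numeric(get_val("tol")),
         seed = if (seed_raw == "NA") NULL else as.integer(seed_raw),
         n_groups = as.integer(get_val("n_groups")),
         n_diffs = as.integer(get_val("n_diffs")),
         objective = as.numeric(get_val("objective")),
         convergence = 0L, call = NULL),
    class = "ranksvm"
  )
}

#' Concatenate feature providers into one integrative vector
#'
#' Builds the feature vector of an integrative ranker by concatenating
#' named component blocks (scalar baseline scores and/or sub-vectors
#' such as the CRFref factors or PosFreq flags) in the declared order.
#'
#' @param pieces Named list mapping component name to a numeric scalar
#'   or vector.
#' @param components Character vector of component names, in order.
#' @return Named numeric vector, names prefixed by component.
#' @export
build_integrative_features <- function(pieces, components) {
  if (length(components) == 0L) {
    stop("at least one component is required", call. = FALSE)
  }
  missing <- setdiff(components, names(pieces))
  if (length(missing) > 0L) {
    stop("unknown component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- numeric(0)
  for (comp in components) {
    v <- pieces[[comp]]
    nm <- if (length(v) == 1L && is.null(names(v))) comp
          else paste(comp, if (is.null(names(v))) seq_along(v) else names(v),
                     sep = ".")
    out <- c(out, stats::setNames(as.numeric(v), nm))
  }
  out
}
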