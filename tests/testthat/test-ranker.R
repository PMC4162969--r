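separable_1d <- function() {
  # every positive exceeds every negative within each query
  x <- matrix(c(2, 1, 0, 3, 2.5, 0.5), ncol = 1,
              dimnames = list(NULL, "f1"))
  list(x = x, y = c(1, 0, 0, 1, 1, 0),
       group = c("q1", "q1", "q1", "q2", "q2", "q2"))
}

test_that("a separable 1-D problem yields a positive weight and perfect ranking", {
  d <- separable_1d()
  fit <- ranksvm(d$x, d$y, d$group)
  expect_gt(coef(fit)[["f1"]], 0)
  held <- matrix(c(5, 1, 3), ncol = 1, dimnames = list(NULL, "f1"))
  rk <- rank_candidates(fit, held, c("a", "b", "c"))
  expect_equal(rk$ref_id, c("a", "c", "b"))
})

test_that("vacuous training sets and dimension mismatches error", {
  x <- matrix(1:4, ncol = 1)
  expect_error(ranksvm(x, c(1, 1, 0, 0), c("q1", "q1", "q2", "q2")),
               "vacuous")
  d <- separable_1d()
  fit <- ranksvm(d$x, d$y, d$group)
  expect_error(predict(fit, matrix(1:4, ncol = 2)), "columns")
})

test_that("ties are broken by ascending ref_id and sorting matches a brute-force sort", {
  d <- separable_1d()
  fit <- ranksvm(d$x, d$y, d$group)
  same <- matrix(c(1, 1), ncol = 1, dimnames = list(NULL, "f1"))
  rk <- rank_candidates(fit, same, c("r2", "r1"))
  expect_equal(rk$ref_id, c("r1", "r2"))
  expect_equal(rank_candidates(fit, same[1, , drop = FALSE], "solo")$rank,
               1L)

  set.seed(3)
  x <- matrix(rnorm(60), ncol = 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  ids <- sprintf("r%02d", sample(20))
  scores <- predict(fit_multi <- ranksvm(
    rbind(x, x + 1), rep(c(0, 1), each = 20),
    rep(sprintf("q%d", 1:20), 2)), x)
  rk <- rank_candidates(fit_multi, x, ids)
  ord <- order(-scores, ids, method = "radix")
  expect_equal(rk$ref_id, ids[ord])
  expect_equal(rk$score, scores[ord])
})

test_that("refitting reproduces identical weights and scores are scale-invariant", {
  set.seed(9)
  x <- matrix(rnorm(300), ncol = 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  w_true <- c(1, -0.5, 0.25)
  group <- rep(sprintf("q%d", 1:10), each = 10)
  y <- as.integer(drop(x %*% w_true) >
                    stats::ave(drop(x %*% w_true), group,
                               FUN = stats::median))
  f1 <- ranksvm(x, y, group, seed = 1)
  f2 <- ranksvm(x, y, group, seed = 1)
  expect_identical(f1$weights, f2$weights)

  # affine rescaling of a raw feature is absorbed by the scaler
  x_scaled <- x
  x_scaled[, 2] <- 100 * x[, 2] + 7
  f3 <- ranksvm(x_scaled, y, group, seed = 1)
  expect_equal(predict(f3, x_scaled), predict(f1, x), tolerance = 1e-6)
})

test_that("constant features get zero weight", {
  set.seed(2)
  x <- cbind(f1 = rnorm(40), f2 = rep(3, 40))
  group <- rep(sprintf("q%d", 1:8), each = 5)
  y <- as.integer(x[, 1] > stats::ave(x[, 1], group, FUN = stats::median))
  fit <- ranksvm(x, y, group)
  expect_equal(unname(coef(fit)["f2"]), 0)
})

test_that("planted weights are recovered on noise-free separable data", {
  set.seed(21)
  n_pairs <- 40
  n_cand <- 15
  p <- 5
  w_star <- c(2, -1, 0.5, 1.5, -0.75)
  x <- matrix(runif(n_pairs * n_cand * p), ncol = p,
              dimnames = list(NULL, paste0("f", 1:p)))
  group <- rep(sprintf("q%02d", 1:n_pairs), each = n_cand)
  s <- drop(x %*% w_star)
  y <- as.integer(s > stats::ave(s, group, FUN = stats::median))
  fit <- ranksvm(x, y, group, c_reg = 100)
  w_hat <- coef(fit, scale = "raw")
  cosine <- sum(w_hat * w_star) /
    sqrt(sum(w_hat^2) * sum(w_star^2))
  expect_gte(cosine, 0.95)
  # training rankings are perfect on separable data
  runs <- lapply(unique(group), function(q) {
    sel <- group == q
    rk <- rank_candidates(fit, x[sel, , drop = FALSE],
                          sprintf("r%02d", seq_len(sum(sel))))
    list(ranked_ids = rk$ref_id,
         targets = sprintf("r%02d", which(y[sel] == 1)))
  })
  expect_equal(mean_average_precision(runs), 1.0)
})

test_that("weight direction agrees with an independent linear SVM", {
  # cross-check the pairwise reduction against libsvm on the same
  # difference vectors
  set.seed(31)
  p <- 3
  x <- matrix(rnorm(40 * p), ncol = p,
              dimnames = list(NULL, paste0("f", 1:p)))
  w_star <- c(1, 2, -1)
  group <- rep(sprintf("q%d", 1:8), each = 5)
  s <- drop(x %*% w_star)
  y <- as.integer(s > stats::ave(s, group, FUN = stats::median))
  fit <- ranksvm(x, y, group, c_reg = 10)

  xs <- scale(x, center = fit$center, scale = fit$scale)
  diffs <- NULL
  for (q in unique(group)) {
    pos <- which(group == q & y == 1)
    neg <- which(group == q & y == 0)
    for (i in pos) for (j in neg) {
      diffs <- rbind(diffs, xs[i, ] - xs[j, ])
    }
  }
  svm_fit <- e1071::svm(rbind(diffs, -diffs),
                        factor(rep(c(1, -1), each = nrow(diffs))),
                        kernel = "linear", cost = 10, scale = FALSE)
  w_svm <- drop(t(svm_fit$coefs) %*% svm_fit$SV)
  if (svm_fit$labels[1] == -1) w_svm <- -w_svm
  cosine <- sum(w_svm * fit$weights) /
    sqrt(sum(w_svm^2) * sum(fit$weights^2))
  expect_gte(cosine, 0.99)
})

test_that("uninformative features give chance-level held-out ranking", {
  # labels independent of features: held-out MAP should sit near the
  # random-ranking expectation, far below a informative fit
  set.seed(17)
  n_pairs <- 50
  n_cand <- 10
  x <- matrix(rnorm(n_pairs * n_cand * 3), ncol = 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  group <- rep(sprintf("q%02d", 1:n_pairs), each = n_cand)
  y <- rbinom(n_pairs * n_cand, 1, 0.3)
  train <- group %in% sprintf("q%02d", 1:25)
  has_both <- stats::ave(y[train], group[train], FUN = function(v) {
    any(v == 1) && any(v == 0)
  }) == 1
  fit <- ranksvm(x[train, ][has_both, ], y[train][has_both],
                 group[train][has_both])
  test_groups <- sprintf("q%02d", 26:50)
  map_fit <- mean_average_precision(lapply(test_groups, function(q) {
    sel <- group == q
    rk <- rank_candidates(fit, x[sel, ], sprintf("r%02d", 1:n_cand))
    list(ranked_ids = rk$ref_id,
         targets = sprintf("r%02d", which(y[sel] == 1)))
  }))
  # permutation null: random rankings of the same label sets
  null_maps <- replicate(200, {
    mean(vapply(test_groups, function(q) {
      sel <- group == q
      perm <- sample(sprintf("r%02d", 1:n_cand))
      average_precision(perm, sprintf("r%02d", which(y[sel] == 1)))
    }, 1.0))
  })
  expect_gte(map_fit, quantile(null_maps, 0.005))
  expect_lte(map_fit, quantile(null_maps, 0.995))
})

test_that("models serialize to text and back without changing predictions", {
  d <- separable_1d()
  fit <- ranksvm(d$x, d$y, d$group, c_reg = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_ranksvm(fit, path)
  back <- read_ranksvm(path)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$center, fit$center)
  expect_equal(back$scale, fit$scale)
  expect_equal(back$c_reg, fit$c_reg)
  newx <- matrix(c(0.3, 1.7), ncol = 1, dimnames = list(NULL, "f1"))
  expect_equal(predict(back, newx), predict(fit, newx))
})

test_that("integrative feature vectors concatenate blocks in declared order", {
  pieces <- list(crfref_full = stats::setNames(runif(13),
                                               paste0("f", 1:13)),
                 posfreq = stats::setNames(rbinom(8, 1, 0.5),
                                           paste0("pf", 1:8)),
                 bm25 = 1.23)
  v <- build_integrative_features(pieces, c("crfref_full", "posfreq"))
  expect_length(v, 21)
  v2 <- build_integrative_features(pieces, c("bm25", "posfreq"))
  expect_length(v2, 9)
  expect_equal(unname(v2[1]), 1.23)
  expect_identical(v, build_integrative_features(
    pieces, c("crfref_full", "posfreq")))
  expect_error(build_integrative_features(pieces, character(0)), "one")
  expect_error(build_integrative_features(pieces, "nope"), "unknown")
})
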