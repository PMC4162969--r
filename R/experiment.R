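# Experiment orchestration: cross-validated train/rank/evaluate over a
# roster of rankers, with per-fold corpus statistics and scalers so no
# test-fold information leaks into training.

ranker_atoms <- c("crfref_full", "crfref_conclusiveness",
                  "crfref_conclusiveness_richness", "posfreq",
                  "bm25", "vsm", "bm25_proximity")

#' Valid ranker names
#'
#' Atomic rankers are the three CRFref variants, `posfreq`, and the
#' score baselines `bm25`, `vsm`, `bm25_proximity`. Integrative rankers
#' are formed by joining atoms with `+` (e.g. `"bm25+posfreq"`,
#' `"crfref_full+bm25+posfreq"`); their feature blocks are concatenated
#' in the declared order and integrated by the ranking SVM. A ranker is
#' trained whenever it has more than one feature column; a single
#' scalar baseline ranks directly by its score.
#'
#' @return Character vector of atomic ranker names.
#' @export
ranker_names <- function() ranker_atoms

parse_ranker <- function(name) {
  atoms <- strsplit(name, "+", fixed = TRUE)[[1]]
  bad <- setdiff(atoms, ranker_atoms)
  if (length(atoms) == 0L || length(bad) > 0L) {
    stop("unknown ranker `", name, "`; valid components: ",
         paste(ranker_atoms, collapse = ", "), call. = FALSE)
  }
  atoms
}

piece_cols <- list(
  crfref_full = 13L, crfref_conclusiveness = 7L,
  crfref_conclusiveness_richness = 9L, posfreq = 8L,
  bm25 = 1L, vsm = 1L, bm25_proximity = 1L
)

#' Compute per-candidate feature pieces
#'
#' Computes, for every (pair, candidate) row, all atomic feature blocks
#' the rankers draw from: the 13 CRFref factors, the 8 PosFreq flags,
#' and the BM25, VSM and proximity-BM25 scores, using the supplied
#' training-fold corpus statistics.
#'
#' @param corpus A `crf_corpus`.
#' @param index Corpus mention index from [index_corpus()].
#' @param stats Training-fold [corpus_stats()].
#' @param sigma Proximity kernel bandwidth in tokens.
#' @return List with `meta` (data frame `pair_id`, `ref_id`, `label`)
#'   and `blocks` (named list of numeric matrices, rows aligned with
#'   `meta`).
#' @export
compute_feature_pieces <- function(corpus, index, stats, sigma = 25) {
  pair_ids <- corpus$pairs$pair_id
  n_rows <- sum(lengths(corpus$candidates[pair_ids]))
  meta <- data.frame(pair_id = character(n_rows),
                     ref_id = character(n_rows),
                     label = integer(n_rows), stringsAsFactors = FALSE)
  crf <- matrix(0, n_rows, 13L,
                dimnames = list(NULL, crfref_factor_names))
  pf <- matrix(0, n_rows, 8L, dimnames = list(NULL, posfreq_names))
  sc <- matrix(0, n_rows, 3L,
               dimnames = list(NULL, c("bm25", "vsm", "bm25_proximity")))
  row <- 0L
  for (p in seq_len(nrow(corpus$pairs))) {
    pid <- corpus$pairs$pair_id[p]
    pair <- list(gene_id = corpus$pairs$gene_id[p],
                 disease_id = corpus$pairs$disease_id[p])
    targets <- corpus$qrels[[pid]]
    for (rid in corpus$candidates[[pid]]) {
      row <- row + 1L
      ref <- corpus$references[[rid]]
      gm <- index[[rid]]$gene
      dm <- index[[rid]]$disease
      meta$pair_id[row] <- pid
      meta$ref_id[row] <- rid
      meta$label[row] <- as.integer(rid %in% targets)
      crf[row, ] <- crfref_features(ref, pair, gm, dm, stats, "full")
      pf[row, ] <- posfreq_features(ref, pair, gm, dm)
      sc[row, "bm25"] <- bm25_score(ref, pair, gm, dm, stats)
      sc[row, "vsm"] <- vsm_score(ref, pair, gm, dm, stats)
      tf_adj <- proximity_adjust_tf(ref, pair, gm, dm, sigma)
      sc[row, "bm25_proximity"] <- bm25_score(ref, pair, gm, dm, stats,
                                              tf = tf_adj)
    }
  }
  blocks <- list(
    crfref_full = crf,
    crfref_conclusiveness = crf[, 1:7, drop = FALSE],
    crfref_conclusiveness_richness = crf[, 1:9, drop = FALSE],
    posfreq = pf,
    bm25 = sc[, "bm25", drop = FALSE],
    vsm = sc[, "vsm", drop = FALSE],
    bm25_proximity = sc[, "bm25_proximity", drop = FALSE]
  )
  list(meta = meta, blocks = blocks)
}

ranker_matrix <- function(pieces, atoms) {
  mats <- lapply(atoms, function(a) {
    m <- pieces$blocks[[a]]
    colnames(m) <- paste(a, colnames(m), sep = ".")
    m
  })
  do.call(cbind, mats)
}

#' Run the full cross-validated ranking experiment
#'
#' For each fold, corpus statistics and feature scalers are computed
#' from the training pairs only; trained rankers are fitted on the
#' training pairs' candidates and every ranker then orders the held-out
#' pairs' candidates. Per-pair AP and P@X are pooled over folds, and
#' each ranker is compared against a designated reference ranker with
#' the dual significance rule (paired t-test AND Wilcoxon signed-rank,
#' both at `alpha`).
#'
#' @param corpus A `crf_corpus` (from [generate_corpus()] or
#'   [load_corpus()]).
#' @param rankers Character vector of ranker names (see
#'   [ranker_names()]; join atoms with `+` for integrative rankers).
#' @param k Number of cross-validation folds. Default 4.
#' @param seed Integer seed driving the fold split (and any difference
#'   subsampling).
#' @param alpha Significance level for the dual rule. Default 0.05.
#' @param px Precision cut-offs. Default `c(1, 2, 3)`.
#' @param reference_ranker Ranker the others are compared against.
#'   Default the first element of `rankers`.
#' @param c_reg Ranking SVM regularization strength.
#' @param sigma Proximity kernel bandwidth in tokens.
#' @param out_dir Optional directory for TSV reports and the run log.
#' @return A `crf_experiment` object: list with `summary` (one row per
#'   ranker: MAP, mean P@X, fraction of pairs with P@X > 0), `per_pair`
#'   (long data frame of per-pair metrics), `significance`, `runs`,
#'   `folds`, and the call settings.
#' @export
run_experiment <- function(corpus, rankers = c("crfref_full", "bm25",
                                               "posfreq"),
                           k = 4, seed = 1, alpha = 0.05, px = c(1, 2, 3),
                           reference_ranker = rankers[1L],
                           c_reg = 1, sigma = 25, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  atoms_by_ranker <- lapply(rankers, parse_ranker)
  names(atoms_by_ranker) <- rankers
  if (!reference_ranker %in% rankers) {
    stop("reference_ranker must be among `rankers`", call. = FALSE)
  }
  if (is.null(seed)) {
    stop("an explicit seed is required (no silent nondeterminism)",
         call. = FALSE)
  }

  pair_ids <- corpus$pairs$pair_id
  index <- index_corpus(corpus$references, corpus$gene_thesaurus,
                        corpus$disease_thesaurus)
  folds <- make_folds(pair_ids, k = k, seed = seed)
  t_index <- proc.time()[["elapsed"]]

  runs <- lapply(rankers, function(r) {
    stats::setNames(vector("list", length(pair_ids)), pair_ids)
  })
  names(runs) <- rankers
  fold_of_pair <- stats::setNames(rep(NA_integer_, length(pair_ids)),
                                  pair_ids)

  for (f in seq_len(k)) {
    test_pairs <- folds[[f]]
    fold_of_pair[test_pairs] <- f
    train_pairs <- setdiff(pair_ids, test_pairs)
    train_refs <- unique(unlist(corpus$candidates[train_pairs]))
    stats_f <- corpus_stats(index[train_refs])
    pieces <- compute_feature_pieces(corpus, index, stats_f, sigma)
    in_train <- pieces$meta$pair_id %in% train_pairs
    in_test <- !in_train
    for (r in rankers) {
      x <- ranker_matrix(pieces, atoms_by_ranker[[r]])
      if (ncol(x) > 1L) {
        fit <- ranksvm(x[in_train, , drop = FALSE],
                       pieces$meta$label[in_train],
                       pieces$meta$pair_id[in_train],
                       c_reg = c_reg, seed = seed + f)
        scores <- predict(fit, x[in_test, , drop = FALSE])
      } else {
        scores <- x[in_test, 1L]
      }
      test_meta <- pieces$meta[in_test, , drop = FALSE]
      for (pid in test_pairs) {
        sel <- test_meta$pair_id == pid
        runs[[r]][[pid]] <- list(
          ranking = rank_candidates(NULL, NULL, test_meta$ref_id[sel],
                                    scores = scores[sel]),
          targets = corpus$qrels[[pid]])
      }
    }
  }
  t_cv <- proc.time()[["elapsed"]]

  per_pair <- do.call(rbind, lapply(rankers, function(r) {
    do.call(rbind, lapply(pair_ids, function(pid) {
      run <- runs[[r]][[pid]]
      ranked <- run$ranking$ref_id
      row <- data.frame(ranker = r, pair_id = pid,
                        fold = fold_of_pair[[pid]],
                        ap = average_precision(ranked, run$targets),
                        stringsAsFactors = FALSE)
      for (x in px) {
        row[[paste0("p_at_", x)]] <-
          precision_at_x(ranked, run$targets, x)
      }
      row
    }))
  }))
  rownames(per_pair) <- NULL

  summary_df <- do.call(rbind, lapply(rankers, function(r) {
    d <- per_pair[per_pair$ranker == r, , drop = FALSE]
    row <- data.frame(ranker = r, map = mean(d$ap),
                      stringsAsFactors = FALSE)
    for (x in px) {
      col <- paste0("p_at_", x)
      row[[paste0("mean_", col)]] <- mean(d[[col]])
      row[[paste0("frac_", col, "_pos")]] <- mean(d[[col]] > 0)
    }
    row
  }))

  sig_rows <- list()
  ref_d <- per_pair[per_pair$ranker == reference_ranker, , drop = FALSE]
  ref_d <- ref_d[order(ref_d$pair_id, method = "radix"), ]
  for (r in setdiff(rankers, reference_ranker)) {
    d <- per_pair[per_pair$ranker == r, , drop = FALSE]
    d <- d[order(d$pair_id, method = "radix"), ]
    for (metric in c("ap", paste0("p_at_", px))) {
      cmp <- compare_significance(d[[metric]], ref_d[[metric]],
                                  alpha = alpha)
      sig_rows[[length(sig_rows) + 1L]] <- data.frame(
        reference = reference_ranker, ranker = r, metric = metric,
        mean_diff = cmp$mean_diff, p_t = cmp$p_t,
        p_wilcoxon = cmp$p_wilcoxon, significant = cmp$significant,
        degenerate = cmp$degenerate, stringsAsFactors = FALSE)
    }
  }
  significance <- if (length(sig_rows) > 0L) {
    do.call(rbind, sig_rows)
  } else {
    data.frame()
  }
  t_end <- proc.time()[["elapsed"]]

  result <- structure(
    list(summary = summary_df, per_pair = per_pair,
         significance = significance, runs = runs, folds = folds,
         rankers = rankers, reference_ranker = reference_ranker,
         k = k, seed = seed, alpha = alpha, px = px, c_reg = c_reg,
         sigma = sigma,
         timings = c(index = t_index - t0, cv = t_cv - t_index,
                     evaluate = t_end - t_cv)),
    class = "crf_experiment")
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' @export
print.crf_experiment <- function(x, digits = 4, ...) {
  cat("Cross-validated ranking experiment (", x$k, " folds, seed ",
      x$seed, ")\n", sep = "")
  s <- x$summary
  s[-1L] <- lapply(s[-1L], round, digits)
  print(s, row.names = FALSE)
  if (nrow(x$significance) > 0L) {
    cat("\nDual significance vs `", x$reference_ranker, "` (alpha = ",
        x$alpha, "):\n", sep = "")
    sg <- x$significance
    sg$mean_diff <- round(sg$mean_diff, digits)
    sg$p_t <- signif(sg$p_t, 3)
    sg$p_wilcoxon <- signif(sg$p_wilcoxon, 3)
    print(sg[, c("ranker", "metric", "mean_diff", "p_t", "p_wilcoxon",
                 "significant")], row.names = FALSE)
  }
  invisible(x)
}

#' Write experiment reports to a directory
#'
#' Emits `ranked_runs.tsv` (ranker, pair, rank, ref, score),
#' `per_pair_metrics.tsv`, `summary.tsv`, `significance.tsv` and a
#' `run_log.txt` recording seed, fold sizes and timings.
#'
#' @param experiment A `crf_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  run_rows <- do.call(rbind, lapply(experiment$rankers, function(r) {
    do.call(rbind, lapply(names(experiment$runs[[r]]), function(pid) {
      rk <- experiment$runs[[r]][[pid]]$ranking
      data.frame(ranker = r, pair_id = pid, rank = rk$rank,
                 ref_id = rk$ref_id,
                 score = format(rk$score, digits = 12),
                 stringsAsFactors = FALSE)
    }))
  }))
  wt(run_rows, "ranked_runs.tsv")
  pp <- experiment$per_pair
  pp$ap <- format(pp$ap, digits = 12)
  wt(pp, "per_pair_metrics.tsv")
  wt(experiment$summary, "summary.tsv")
  wt(experiment$significance, "significance.tsv")
  writeLines(c(
    paste0("seed: ", experiment$seed),
    paste0("folds: ", experiment$k, " sizes: ",
           paste(lengths(experiment$folds), collapse = "/")),
    paste0("rankers: ", paste(experiment$rankers, collapse = ", ")),
    paste0("reference: ", experiment$reference_ranker),
    paste0("alpha: ", experiment$alpha),
    paste0("timing_index_s: ",
           format(experiment$timings[["index"]], digits = 4)),
    paste0("timing_cv_s: ",
           format(experiment$timings[["cv"]], digits = 4)),
    paste0("timing_evaluate_s: ",
           format(experiment$timings[["evaluate"]], digits = 4))
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Run an experiment from a configuration file
#'
#' The YAML configuration carries flat keys `rankers` (list),
#' `reference_ranker`, `folds`, `alpha`, `px`, `c_reg`, `sigma`,
#' `seed`, and either `corpus_dir` (a directory written by
#' [write_corpus()]) or a `simulate` block of [sim_config()] fields.
#'
#' @param config_path Path to the YAML configuration.
#' @param seed Optional seed overriding the configured one.
#' @param out_dir Optional report directory overriding the configured
#'   `out_dir`.
#' @return A `crf_experiment`.
#' @export
run_experiment_file <- function(config_path, seed = NULL, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(seed)) {
    stop("config must carry a `seed` (or pass one explicitly)",
         call. = FALSE)
  }
  corpus <- if (!is.null(cfg$corpus_dir)) {
    load_corpus(cfg$corpus_dir)
  } else if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (is.null(sim$seed)) sim$seed <- seed
    if (!is.null(sim$beta)) sim$beta <- unlist(sim$beta)
    if (!is.null(sim$candidates_range)) {
      sim$candidates_range <- unlist(sim$candidates_range)
    }
    generate_corpus(do.call(sim_config, sim))
  } else {
    stop("config needs either `corpus_dir` or a `simulate` block",
         call. = FALSE)
  }
  args <- list(corpus = corpus, seed = as.integer(seed))
  if (!is.null(cfg$rankers)) args$rankers <- unlist(cfg$rankers)
  if (!is.null(cfg$reference_ranker)) {
    args$reference_ranker <- cfg$reference_ranker
  }
  if (!is.null(cfg$folds)) args$k <- cfg$folds
  if (!is.null(cfg$alpha)) args$alpha <- cfg$alpha
  if (!is.null(cfg$px)) args$px <- unlist(cfg$px)
  if (!is.null(cfg$c_reg)) args$c_reg <- cfg$c_reg
  if (!is.null(cfg$sigma)) args$sigma <- cfg$sigma
  args$out_dir <- if (!is.null(out_dir)) out_dir else cfg$out_dir
  do.call(run_experiment, args)
}
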