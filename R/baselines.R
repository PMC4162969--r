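# Comparison rankers: Okapi BM25, a tf-idf vector-space scorer, a
# Gaussian proximity boost feeding BM25, and the PosFreq positional
# flags. The "terms" of the query are the gene and the disease, with
# aliases folded into their entity, so TF counts entity mentions.

#' BM25 parameters
#'
#' @param k1 Term-frequency saturation (> 0). Default 2.
#' @param b Length-normalization slope in [0, 1]. Default 0.75.
#' @return A `bm25_params` list.
#' @export
bm25_params <- function(k1 = 2, b = 0.75) {
  stopifnot(k1 > 0, b >= 0, b <= 1)
  structure(list(k1 = k1, b = b), class = "bm25_params")
}

bm25_idf <- function(N, n) max(0, log((N - n + 0.5) / (n + 0.5)))

#' Okapi BM25 score of a reference for a gene-disease pair
#'
#' Sums, over the two query terms t in {gene, disease}, the Okapi
#' contribution idf(t) * TF * (k1 + 1) / (TF + k1 * (1 - b + b * |r| /
#' avg_len)), where TF counts entity mentions (aliases folded),
#' idf(t) = ln((N - n + 0.5) / (n + 0.5)) floored at 0, and N, n,
#' avg_len come from the training corpus statistics.
#'
#' @param ref A `crf_reference`.
#' @param pair List with `gene_id`, `disease_id`.
#' @param gene_mentions,disease_mentions `crf_mentions` for the
#'   reference.
#' @param stats A `crf_corpus_stats`.
#' @param params A [bm25_params()] object.
#' @param tf Optional named numeric `c(gene =, disease =)` overriding
#'   the raw term frequencies (used by the proximity baseline).
#' @return A single non-negative score.
#' @export
bm25_score <- function(ref, pair, gene_mentions, disease_mentions, stats,
                       params = bm25_params(), tf = NULL) {
  n_r <- ref_length(ref)
  if (n_r == 0L) stop("degenerate reference of length 0", call. = FALSE)
  if (is.null(tf)) {
    tf <- c(gene = mention_tf(gene_mentions, pair$gene_id),
            disease = mention_tf(disease_mentions, pair$disease_id))
  }
  df <- c(gene = entity_df(stats, pair$gene_id),
          disease = entity_df(stats, pair$disease_id))
  norm <- params$k1 * (1 - params$b + params$b * n_r / stats$avg_len)
  score <- 0
  for (t in c("gene", "disease")) {
    if (tf[[t]] <= 0) next
    idf <- bm25_idf(stats$N, df[[t]])
    score <- score + idf * tf[[t]] * (params$k1 + 1) / (tf[[t]] + norm)
  }
  score
}

#' Vector-space tf-idf score of a reference for a gene-disease pair
#'
#' The classic practical tf-idf cosine approximation: sum over the two
#' query terms of sqrt(TF) * idf(t)^2 / sqrt(|r|), with
#' idf(t) = 1 + ln(N / (n + 1)).
#'
#' @inheritParams bm25_score
#' @return A single non-negative score.
#' @export
vsm_score <- function(ref, pair, gene_mentions, disease_mentions, stats) {
  n_r <- ref_length(ref)
  if (n_r == 0L) stop("degenerate reference of length 0", call. = FALSE)
  tf <- c(mention_tf(gene_mentions, pair$gene_id),
          mention_tf(disease_mentions, pair$disease_id))
  df <- c(entity_df(stats, pair$gene_id),
          entity_df(stats, pair$disease_id))
  idf <- 1 + log(stats$N / (df + 1))
  sum(sqrt(tf) * idf^2) / sqrt(n_r)
}

#' Proximity-adjusted term frequencies
#'
#' Boosts the term frequency of each query term when the other query
#' term occurs nearby: TF'(g) = TF(g) + sum over all (gene occurrence,
#' disease occurrence) pairs of exp(-dist^2 / (2 sigma^2)), where dist
#' is the token distance between match starts; symmetrically for the
#' disease. Feeding the adjusted TF into [bm25_score()] yields the
#' proximity baseline (a generic kernel stand-in for the
#' proximity-enhanced rankers it represents).
#'
#' @inheritParams bm25_score
#' @param sigma Kernel bandwidth in tokens (> 0). Default 25.
#' @return Named numeric `c(gene =, disease =)` adjusted frequencies.
#' @export
proximity_adjust_tf <- function(ref, pair, gene_mentions, disease_mentions,
                                sigma = 25) {
  stopifnot(sigma > 0)
  tf_g <- mention_tf(gene_mentions, pair$gene_id)
  tf_d <- mention_tf(disease_mentions, pair$disease_id)
  inc <- 0
  gm <- gene_mentions$matches[[pair$gene_id]]
  dm <- disease_mentions$matches[[pair$disease_id]]
  if (!is.null(gm) && !is.null(dm)) {
    dist <- outer(gm$start, dm$start, function(a, b) abs(a - b))
    inc <- sum(exp(-dist^2 / (2 * sigma^2)))
  }
  c(gene = tf_g + inc, disease = tf_d + inc)
}

posfreq_names <- c("g_in_title", "d_in_title", "g_first_sentence",
                   "d_last_sentence", "g_last_sentence", "d_first_sentence",
                   "g_tf_ge3", "d_tf_ge3")

# Does the entity have a match wholly inside the given abstract sentence?
mention_in_sentence <- function(mentions, entity_id, span) {
  m <- mentions$matches[[entity_id]]
  if (is.null(m)) return(FALSE)
  astart <- m$start - mentions$title_len
  any(!m$in_title & astart >= span[1L] & astart + m$length <= span[2L])
}

# Number of matches lying in the abstract (not the title).
mention_abstract_tf <- function(mentions, entity_id) {
  m <- mentions$matches[[entity_id]]
  if (is.null(m)) 0L else sum(!m$in_title)
}

#' Position-and-frequency (PosFreq) flags
#'
#' The eight binary factors of the position-and-frequency baseline:
#' whether the gene / disease appears in the title, in the first or last
#' sentence of the abstract, and at least three times in the abstract.
#' The flags are integrated by the pairwise ranking SVM.
#'
#' @inheritParams bm25_score
#' @return Named numeric vector of eight 0/1 flags in the canonical
#'   order `g_in_title`, `d_in_title`, `g_first_sentence`,
#'   `d_last_sentence`, `g_last_sentence`, `d_first_sentence`,
#'   `g_tf_ge3`, `d_tf_ge3`.
#' @export
posfreq_features <- function(ref, pair, gene_mentions, disease_mentions) {
  nb <- nrow(ref$sentence_bounds)
  first <- if (nb > 0L) ref$sentence_bounds[1L, ] else NULL
  last <- if (nb > 0L) ref$sentence_bounds[nb, ] else NULL
  in_sent <- function(m, e, span) {
    if (is.null(span)) return(0)
    as.numeric(mention_in_sentence(m, e, span))
  }
  g <- pair$gene_id
  d <- pair$disease_id
  c(g_in_title = as.numeric(mention_in_title(gene_mentions, g)),
    d_in_title = as.numeric(mention_in_title(disease_mentions, d)),
    g_first_sentence = in_sent(gene_mentions, g, first),
    d_last_sentence = in_sent(disease_mentions, d, last),
    g_last_sentence = in_sent(gene_mentions, g, last),
    d_first_sentence = in_sent(disease_mentions, d, first),
    g_tf_ge3 = as.numeric(mention_abstract_tf(gene_mentions, g) >= 3L),
    d_tf_ge3 = as.numeric(mention_abstract_tf(disease_mentions, d) >= 3L))
}
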