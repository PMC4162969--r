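# The thirteen CRFref factors.
#
# Conclusiveness (1-7): normalized length, gene/disease term frequency,
# gene/disease in title, gene/disease ending score (how close the last
# mention is to the end of the reference). Richness (8-9): number of
# distinct OTHER genes/diseases mentioned. Focus (10-13): whether and
# how conclusively those other genes/diseases appear in the concluding
# parts (title, ending). Every factor lies in [0, 1].

crfref_factor_names <- c(
  "length", "gene_tf", "disease_tf", "gene_at_title", "disease_at_title",
  "gene_at_ending", "disease_at_ending", "not_gene_num", "not_disease_num",
  "not_gene_at_title", "not_disease_at_title", "not_gene_at_ending",
  "not_disease_at_ending"
)

#' Corpus statistics from training references
#'
#' Summaries of the training references that length normalization and
#' the BM25/VSM baselines need: the number of references `N`, the
#' average body length (`AvgLen` / `avgrl`), and the per-entity document
#' frequency (number of training references containing the entity).
#'
#' @param mentions A corpus index from [index_corpus()] restricted to
#'   the training references.
#' @return A `crf_corpus_stats` list with `N`, `avg_len`, `df` (named
#'   integer vector over entity ids).
#' @export
corpus_stats <- function(mentions) {
  if (length(mentions) == 0L) {
    stop("corpus statistics need at least one training reference",
         call. = FALSE)
  }
  lens <- vapply(mentions, function(m) m$gene$body_len, 1L)
  present <- unlist(lapply(mentions, function(m) {
    c(names(m$gene$matches), names(m$disease$matches))
  }))
  df <- if (length(present) > 0L) {
    tab <- table(present)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(N = length(mentions), avg_len = mean(lens), df = df),
            class = "crf_corpus_stats")
}

#' @export
print.crf_corpus_stats <- function(x, ...) {
  cat("<crf_corpus_stats: N=", x$N, ", avg_len=", round(x$avg_len, 2),
      ", ", length(x$df), " entities with df>0>\n", sep = "")
  invisible(x)
}

entity_df <- function(stats, entity_id) {
  n <- stats$df[entity_id]
  if (is.na(n)) 0L else as.integer(n)
}

#' Conclusiveness factors (1-7)
#'
#' `length` = min(|r| / AvgLen, 1); `gene_tf`/`disease_tf` =
#' min(TF/3, 1) with aliases folded; `*_at_title` = 1 iff any mention
#' lies wholly in the title; `*_at_ending` = (1-based index of the final
#' token of the last mention) / |r|, 0 if the entity is absent.
#'
#' @param ref A `crf_reference`.
#' @param pair List with `gene_id` and `disease_id`.
#' @param gene_mentions,disease_mentions `crf_mentions` for the
#'   reference against the gene and disease thesauri.
#' @param stats A `crf_corpus_stats` (supplies `avg_len`).
#' @return Named numeric vector of the seven factors, each in [0, 1].
#' @export
conclusiveness_factors <- function(ref, pair, gene_mentions,
                                   disease_mentions, stats) {
  n <- ref_length(ref)
  if (n == 0L) stop("degenerate reference of length 0", call. = FALSE)
  ending <- function(m, e) mention_last_end(m, e) / n
  c(length = min(n / stats$avg_len, 1),
    gene_tf = min(mention_tf(gene_mentions, pair$gene_id) / 3, 1),
    disease_tf = min(mention_tf(disease_mentions, pair$disease_id) / 3, 1),
    gene_at_title = as.numeric(mention_in_title(gene_mentions, pair$gene_id)),
    disease_at_title =
      as.numeric(mention_in_title(disease_mentions, pair$disease_id)),
    gene_at_ending = ending(gene_mentions, pair$gene_id),
    disease_at_ending = ending(disease_mentions, pair$disease_id))
}

distractor_ids <- function(mentions, own_id) {
  setdiff(names(mentions$matches), own_id)
}

#' Richness factors (8-9)
#'
#' Counts the distinct genes other than the query gene (and diseases
#' other than the query disease) mentioned in the reference, squashed
#' into [0, 1) as c / (c + 1).
#'
#' @inheritParams conclusiveness_factors
#' @return Named numeric vector `not_gene_num`, `not_disease_num`.
#' @export
richness_factors <- function(ref, pair, gene_mentions, disease_mentions) {
  squash <- function(c_) c_ / (c_ + 1)
  c(not_gene_num =
      squash(length(distractor_ids(gene_mentions, pair$gene_id))),
    not_disease_num =
      squash(length(distractor_ids(disease_mentions, pair$disease_id))))
}

#' Focus factors (10-13)
#'
#' The counterparts of the title/ending conclusiveness factors for
#' genes and diseases that are neither the query gene nor the query
#' disease: whether any such entity appears in the title, and the
#' maximum ending score over such entities (0 if none). A high value
#' signals that the reference's conclusion is diluted by other
#' entities.
#'
#' @inheritParams conclusiveness_factors
#' @return Named numeric vector of the four focus factors.
#' @export
focus_factors <- function(ref, pair, gene_mentions, disease_mentions) {
  n <- ref_length(ref)
  if (n == 0L) stop("degenerate reference of length 0", call. = FALSE)
  title_any <- function(m, own) {
    any(vapply(distractor_ids(m, own), function(e) mention_in_title(m, e),
               TRUE))
  }
  ending_max <- function(m, own) {
    ids <- distractor_ids(m, own)
    if (length(ids) == 0L) return(0)
    max(vapply(ids, function(e) mention_last_end(m, e), 1L)) / n
  }
  c(not_gene_at_title =
      as.numeric(title_any(gene_mentions, pair$gene_id)),
    not_disease_at_title =
      as.numeric(title_any(disease_mentions, pair$disease_id)),
    not_gene_at_ending = ending_max(gene_mentions, pair$gene_id),
    not_disease_at_ending = ending_max(disease_mentions, pair$disease_id))
}

#' Assemble a CRFref feature vector
#'
#' Concatenates the factor groups in their canonical order for one of
#' the three ablation variants: factors 1-7 (`"conclusiveness"`), 1-9
#' (`"conclusiveness_richness"`), or all 13 (`"full"`).
#'
#' @inheritParams conclusiveness_factors
#' @param variant One of `"conclusiveness"`, `"conclusiveness_richness"`,
#'   `"full"`.
#' @return Named numeric vector of length 7, 9, or 13.
#' @export
crfref_features <- function(ref, pair, gene_mentions, disease_mentions,
                            stats,
                            variant = c("full", "conclusiveness",
                                        "conclusiveness_richness")) {
  variant <- match.arg(variant)
  f <- conclusiveness_factors(ref, pair, gene_mentions, disease_mentions,
                              stats)
  if (variant == "conclusiveness") return(f)
  f <- c(f, richness_factors(ref, pair, gene_mentions, disease_mentions))
  if (variant == "conclusiveness_richness") return(f)
  c(f, focus_factors(ref, pair, gene_mentions, disease_mentions))
}

#' Export a feature matrix as TSV
#'
#' Writes `pair_id`, `ref_id`, `label`, then one column per feature, for
#' audit and cross-language testing.
#'
#' @param features Data frame with columns `pair_id`, `ref_id`, `label`
#'   and numeric feature columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix TSV
#'
#' @param path Path written by [write_feature_tsv()].
#' @return Data frame with `pair_id`, `ref_id`, `label` and feature
#'   columns.
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, quote = "",
                          stringsAsFactors = FALSE)
  df$pair_id <- as.character(df$pair_id)
  df$ref_id <- as.character(df$ref_id)
  df
}
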