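# Dictionary matching of entity aliases in reference bodies.
#
# Matching is strict (exact on normalized tokens, no stemming) with a
# left-to-right greedy longest-match scan: at each body position the
# longest matching alias across all requested entities wins and the scan
# resumes after it. Overlapping matches for different entities at the
# same winning span are all recorded (an ambiguous alias credits every
# owning entity). Matches never straddle the title/abstract boundary.

compile_dictionary <- function(thesaurus, entity_ids = NULL) {
  ids <- names(thesaurus)
  if (!is.null(entity_ids)) {
    missing <- setdiff(entity_ids, ids)
    if (length(missing) > 0L) {
      stop("unknown entity id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    ids <- entity_ids
  }
  entity <- character(0)
  tokens <- list()
  for (id in ids) {
    for (a in thesaurus[[id]]) {
      entity <- c(entity, id)
      tokens <- c(tokens, list(a))
    }
  }
  lens <- vapply(tokens, length, 1L)
  first <- new.env(parent = emptyenv(), size = length(tokens))
  for (k in seq_along(tokens)) {
    key <- tokens[[k]][1L]
    assign(key, c(get0(key, envir = first, ifnotfound = integer(0)), k),
           envir = first)
  }
  list(entity = entity, tokens = tokens, len = lens, first = first)
}

#' Find entity mentions in a reference
#'
#' Scans the reference body (title then abstract tokens) for thesaurus
#' aliases using greedy longest-match dictionary matching; aliases of an
#' entity count as the entity. See the package vignette for the exact
#' resolution rules.
#'
#' @param ref A `crf_reference`.
#' @param thesaurus A `crf_thesaurus`.
#' @param entity_ids Optional subset of entity ids to match; default all.
#' @return A `crf_mentions` object: list with `matches` (named list
#'   `entity_id -> data.frame(start, length, in_title)`, starts 0-based
#'   over the body, sorted by start), `title_len`, and `body_len`.
#'   Entities without matches are absent from `matches`.
#' @export
find_mentions <- function(ref, thesaurus, entity_ids = NULL) {
  dict <- compile_dictionary(thesaurus, entity_ids)
  scan_mentions(ref, dict)
}

scan_mentions <- function(ref, dict) {
  body <- ref_body(ref)
  tlen <- length(ref$title_tokens)
  n <- length(body)
  ent <- character(0)
  start <- integer(0)
  len <- integer(0)
  i <- 1L
  while (i <= n) {
    cand <- get0(body[i], envir = dict$first, ifnotfound = NULL)
    best <- 0L
    hits <- integer(0)
    if (!is.null(cand)) {
      for (k in cand) {
        L <- dict$len[k]
        j <- i + L - 1L
        if (j > n) next
        if (i <= tlen && j > tlen) next   # straddles title/abstract boundary
        if (L > 1L && !identical(body[i:j], dict$tokens[[k]])) next
        if (L > best) {
          best <- L
          hits <- k
        } else if (L == best) {
          hits <- c(hits, k)
        }
      }
    }
    if (best > 0L) {
      for (k in unique(hits)) {
        ent <- c(ent, dict$entity[k])
        start <- c(start, i - 1L)
        len <- c(len, best)
      }
      i <- i + best
    } else {
      i <- i + 1L
    }
  }
  matches <- list()
  if (length(ent) > 0L) {
    for (e in unique(ent)) {
      sel <- ent == e
      df <- data.frame(start = start[sel], length = len[sel],
                       in_title = start[sel] + len[sel] <= tlen)
      # the scan is left-to-right so starts are already sorted
      matches[[e]] <- df
    }
  }
  structure(list(matches = matches, title_len = tlen, body_len = n),
            class = "crf_mentions")
}

#' @export
print.crf_mentions <- function(x, ...) {
  cat("<crf_mentions: ", length(x$matches), " entity(ies) matched in ",
      x$body_len, " tokens>\n", sep = "")
  invisible(x)
}

# Number of matches for one entity (term frequency with alias folding).
mention_tf <- function(mentions, entity_id) {
  m <- mentions$matches[[entity_id]]
  if (is.null(m)) 0L else nrow(m)
}

# 1-based index of the final token of the entity's last match, 0 if absent.
mention_last_end <- function(mentions, entity_id) {
  m <- mentions$matches[[entity_id]]
  if (is.null(m)) 0L else max(m$start + m$length)
}

mention_in_title <- function(mentions, entity_id) {
  m <- mentions$matches[[entity_id]]
  !is.null(m) && any(m$in_title)
}

#' Filter candidate references for a gene-disease pair
#'
#' Keeps exactly the references that mention both the pair's gene and
#' its disease (aliases folded into their entity), preserving order.
#'
#' @param refs List of `crf_reference` objects.
#' @param pair A list or one-row data frame with `gene_id`, `disease_id`.
#' @param gene_thes,disease_thes `crf_thesaurus` objects.
#' @return The subset of `refs` mentioning both entities.
#' @export
filter_candidates <- function(refs, pair, gene_thes, disease_thes) {
  gdict <- compile_dictionary(gene_thes, pair$gene_id)
  ddict <- compile_dictionary(disease_thes, pair$disease_id)
  keep <- vapply(refs, function(ref) {
    gm <- scan_mentions(ref, gdict)
    if (mention_tf(gm, pair$gene_id) == 0L) return(FALSE)
    dm <- scan_mentions(ref, ddict)
    mention_tf(dm, pair$disease_id) > 0L
  }, TRUE)
  refs[keep]
}

#' Index a corpus of references against both thesauri
#'
#' Runs the full-thesaurus mention scan once per reference, for reuse by
#' the factor, baseline, and experiment code.
#'
#' @param refs Named list of `crf_reference` objects.
#' @param gene_thes,disease_thes `crf_thesaurus` objects.
#' @return Named list (by `ref_id`) of `list(gene =, disease =)`
#'   `crf_mentions` pairs.
#' @export
index_corpus <- function(refs, gene_thes, disease_thes) {
  gdict <- compile_dictionary(gene_thes)
  ddict <- compile_dictionary(disease_thes)
  out <- lapply(refs, function(ref) {
    list(gene = scan_mentions(ref, gdict),
         disease = scan_mentions(ref, ddict))
  })
  names(out) <- vapply(refs, function(r) r$ref_id, "")
  out
}
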