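#' Construct a normalized reference record
#'
#' A reference is the unit of ranking: the title and abstract of one
#' candidate article after text normalization. The *body* of a reference
#' is the title tokens followed by the abstract tokens; token positions
#' are 0-based over this concatenation and the reference length `|r|`
#' is the total token count.
#'
#' @param ref_id Opaque identifier (e.g. a PMID). Must be non-empty.
#' @param title_tokens Character vector of normalized title tokens.
#' @param abstract_tokens Character vector of normalized abstract tokens.
#' @param sentence_bounds Integer matrix with columns `start`, `end`:
#'   half-open 0-based token spans over `abstract_tokens`, partitioning
#'   them in order. One row per abstract sentence.
#' @return An object of class `crf_reference`.
#' @export
new_reference <- function(ref_id, title_tokens, abstract_tokens,
                          sentence_bounds = NULL) {
  if (length(ref_id) != 1L || !nzchar(ref_id) || is.na(ref_id)) {
    stop("`ref_id` must be a single non-empty string", call. = FALSE)
  }
  title_tokens <- as.character(title_tokens)
  abstract_tokens <- as.character(abstract_tokens)
  bad <- c(title_tokens, abstract_tokens)
  if (any(!grepl("^[A-Za-z0-9]+$", bad))) {
    stop("tokens must be non-empty and alphanumeric; run normalize_text() first",
         call. = FALSE)
  }
  if (length(title_tokens) == 0L && length(abstract_tokens) == 0L) {
    stop("reference ", ref_id, " has neither title nor abstract tokens",
         call. = FALSE)
  }
  if (is.null(sentence_bounds)) {
    sentence_bounds <- if (length(abstract_tokens) > 0L) {
      matrix(c(0L, length(abstract_tokens)), ncol = 2L)
    } else {
      matrix(integer(0), ncol = 2L)
    }
  }
  sentence_bounds <- matrix(as.integer(sentence_bounds), ncol = 2L,
                            dimnames = list(NULL, c("start", "end")))
  n_ab <- length(abstract_tokens)
  if (nrow(sentence_bounds) > 0L) {
    starts <- sentence_bounds[, 1L]
    ends <- sentence_bounds[, 2L]
    ok <- starts[1L] == 0L && ends[nrow(sentence_bounds)] == n_ab &&
      all(ends > starts) &&
      all(starts[-1L] == ends[-nrow(sentence_bounds)])
    if (!ok) {
      stop("sentence_bounds must partition the abstract tokens in order",
           call. = FALSE)
    }
  } else if (n_ab > 0L) {
    stop("non-empty abstract requires sentence_bounds", call. = FALSE)
  }
  structure(
    list(ref_id = as.character(ref_id),
         title_tokens = title_tokens,
         abstract_tokens = abstract_tokens,
         sentence_bounds = sentence_bounds),
    class = "crf_reference"
  )
}

#' Build a reference from raw title/abstract strings
#'
#' Applies [normalize_text()] to the title and to each abstract sentence.
#' Sentences are taken from `sentences` when supplied (exact fixtures);
#' otherwise the raw abstract is split on a period followed by
#' whitespace. Sentences that normalize to zero tokens are dropped.
#'
#' @param ref_id Identifier string.
#' @param title Raw title string.
#' @param abstract Raw abstract string (ignored when `sentences` given).
#' @param sentences Optional character vector of raw sentence strings.
#' @return A `crf_reference`.
#' @export
make_reference <- function(ref_id, title, abstract = "", sentences = NULL) {
  title_tokens <- normalize_text(title)
  if (is.null(sentences)) {
    sentences <- split_sentences(abstract)
  }
  sent_tokens <- lapply(sentences, normalize_text)
  sent_tokens <- sent_tokens[vapply(sent_tokens, length, 1L) > 0L]
  abstract_tokens <- as.character(unlist(sent_tokens))
  if (length(sent_tokens) > 0L) {
    ends <- cumsum(vapply(sent_tokens, length, 1L))
    bounds <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
  } else {
    bounds <- matrix(integer(0), ncol = 2L)
  }
  new_reference(ref_id, title_tokens, abstract_tokens, bounds)
}

#' @export
print.crf_reference <- function(x, ...) {
  cat("<crf_reference ", x$ref_id, ">\n", sep = "")
  cat("  title   : ", paste(x$title_tokens, collapse = " "), "\n", sep = "")
  cat("  abstract: ", length(x$abstract_tokens), " tokens in ",
      nrow(x$sentence_bounds), " sentence(s)\n", sep = "")
  invisible(x)
}

# Body = title tokens then abstract tokens; |r| over the concatenation.
ref_body <- function(ref) c(ref$title_tokens, ref$abstract_tokens)

#' Reference length
#'
#' Total token count of a reference body (title plus abstract).
#' @param ref A `crf_reference`.
#' @return Integer length `|r|`.
#' @export
ref_length <- function(ref) {
  length(ref$title_tokens) + length(ref$abstract_tokens)
}
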