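#' Read candidate references from disk
#'
#' Two dialects are supported. `"jsonl"` holds one JSON object per line
#' with keys `id`, `title`, `abstract`, and optionally `sentences` (a
#' list of raw sentence strings that bypasses the period splitter, for
#' exact fixtures). `"medline"` is the MEDLINE flat-file format with
#' `PMID`, `TI` and `AB` tags and continuation-line unwrapping.
#' Titles and abstracts are normalized with [normalize_text()].
#'
#' @param path File path.
#' @param format `"jsonl"` or `"medline"`.
#' @return A named list of [new_reference()] objects, in file order,
#'   named by `ref_id`.
#' @export
read_references <- function(path, format = c("jsonl", "medline")) {
  format <- match.arg(format)
  switch(format,
         jsonl = read_references_jsonl(path),
         medline = read_references_medline(path))
}

read_references_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  refs <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed JSON on line ", i, " of ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(rec$id) || !nzchar(as.character(rec$id)[1L])) {
      stop("record on line ", i, " of ", path, " is missing `id`",
           call. = FALSE)
    }
    if (is.null(rec$title) || is.null(rec$abstract)) {
      stop("record on line ", i, " of ", path,
           " must carry `title` and `abstract`", call. = FALSE)
    }
    sentences <- if (!is.null(rec$sentences)) as.character(rec$sentences)
    refs[[i]] <- tryCatch(
      make_reference(as.character(rec$id), as.character(rec$title),
                     as.character(rec$abstract), sentences = sentences),
      error = function(e) {
        stop("invalid record on line ", i, " of ", path, ": ",
             conditionMessage(e), call. = FALSE)
      })
    ids[i] <- refs[[i]]$ref_id
  }
  if (anyDuplicated(ids)) {
    stop("duplicate reference ids in ", path, call. = FALSE)
  }
  names(refs) <- ids
  refs
}

read_references_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # unwrap continuation lines (leading blanks continue the previous tag)
  recs <- list()
  cur <- NULL
  flush_field <- function(cur, tag, val) {
    if (!is.null(tag)) cur[[tag]] <- c(cur[[tag]], val)
    cur
  }
  tag <- NULL
  val <- NULL
  finish <- function() {
    if (!is.null(cur) && length(cur) > 0L) recs[[length(recs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      if (!is.null(tag)) cur <- flush_field(cur, tag, val)
      tag <- NULL
      finish()
      next
    }
    if (grepl("^[A-Z0-9]{1,4} *- ", ln)) {
      if (!is.null(tag)) cur <- flush_field(cur, tag, val)
      tag <- trimws(sub("^([A-Z0-9]{1,4}) *- .*$", "\\1", ln))
      val <- sub("^[A-Z0-9]{1,4} *- ", "", ln)
      if (is.null(cur)) cur <- list()
    } else if (grepl("^ +", ln) && !is.null(tag)) {
      val <- paste(val, trimws(ln))
    } else {
      stop("malformed MEDLINE line in ", path, ": ", ln, call. = FALSE)
    }
  }
  refs <- list()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    if (is.null(rec$PMID)) {
      stop("MEDLINE record ", i, " in ", path, " has no PMID", call. = FALSE)
    }
    refs[[i]] <- make_reference(trimws(rec$PMID[1L]),
                                paste(rec$TI, collapse = " "),
                                paste(rec$AB, collapse = " "))
  }
  ids <- vapply(refs, function(r) r$ref_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate PMIDs in ", path, call. = FALSE)
  }
  names(refs) <- ids
  refs
}

#' Write references as JSON lines
#'
#' Serializes normalized references in the jsonl dialect read by
#' [read_references()]. Sentences are emitted explicitly so the file
#' round-trips exactly (the period splitter is bypassed on re-read).
#'
#' @param refs List of `crf_reference` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_references_jsonl <- function(refs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (ref in refs) {
    nb <- nrow(ref$sentence_bounds)
    sentences <- vapply(seq_len(nb), function(i) {
      span <- ref$sentence_bounds[i, ]
      paste(ref$abstract_tokens[(span[1L] + 1L):span[2L]], collapse = " ")
    }, "")
    writeLines(jsonlite::toJSON(list(
      id = ref$ref_id,
      title = paste(ref$title_tokens, collapse = " "),
      abstract = paste(sentences, collapse = ". "),
      sentences = as.list(sentences)
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a gene or disease thesaurus
#'
#' TSV rows of the form `entity_id TAB alias1|alias2|...`. Aliases are
#' normalized with [normalize_text()] and deduplicated within an entity;
#' an alias may map to several entity ids (it is recorded for each).
#'
#' @param path File path.
#' @param kind `"gene"` or `"disease"`.
#' @return A `crf_thesaurus`: a named list `entity_id -> list of alias
#'   token vectors`, with attribute `kind`.
#' @export
read_thesaurus <- function(path, kind = c("gene", "disease")) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty thesaurus file: ", path, call. = FALSE)
  }
  entries <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(trimws(parts[2L]))) {
      stop("thesaurus row ", i, " in ", path, " has no alias", call. = FALSE)
    }
    id <- trimws(parts[1L])
    raw_aliases <- strsplit(parts[2L], "|", fixed = TRUE)[[1]]
    aliases <- lapply(raw_aliases, normalize_text)
    if (any(vapply(aliases, length, 1L) == 0L)) {
      stop("thesaurus row ", i, " in ", path,
           " has an alias that normalizes to nothing", call. = FALSE)
    }
    aliases <- unique(aliases)
    entries[[id]] <- unique(c(entries[[id]], aliases))
  }
  new_thesaurus(entries, kind)
}

#' Construct a thesaurus from alias lists
#'
#' @param entries Named list: `entity_id -> list of alias token vectors`
#'   (already normalized).
#' @param kind `"gene"` or `"disease"`.
#' @return A `crf_thesaurus`.
#' @export
new_thesaurus <- function(entries, kind = c("gene", "disease")) {
  kind <- match.arg(kind)
  if (length(entries) == 0L || is.null(names(entries))) {
    stop("thesaurus needs at least one named entry", call. = FALSE)
  }
  for (id in names(entries)) {
    al <- entries[[id]]
    if (length(al) == 0L) stop("entity ", id, " has no alias", call. = FALSE)
    for (a in al) {
      if (length(a) == 0L || any(!grepl("^[A-Za-z0-9]+$", a))) {
        stop("entity ", id, " has a non-normalized alias", call. = FALSE)
      }
      if (!identical(unname(a), normalize_text(paste(a, collapse = " ")))) {
        stop("entity ", id, " alias is not normalization-stable",
             call. = FALSE)
      }
    }
  }
  structure(entries, kind = kind, class = "crf_thesaurus")
}

#' @export
print.crf_thesaurus <- function(x, ...) {
  n_alias <- sum(vapply(x, length, 1L))
  cat("<crf_thesaurus kind=", attr(x, "kind"), ": ", length(x),
      " entities, ", n_alias, " aliases>\n", sep = "")
  invisible(x)
}

#' Write a thesaurus as TSV
#'
#' Inverse of [read_thesaurus()]: multi-token aliases are joined with
#' spaces, aliases with `|`.
#'
#' @param thesaurus A `crf_thesaurus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(thesaurus, path) {
  rows <- vapply(names(thesaurus), function(id) {
    aliases <- vapply(thesaurus[[id]], paste, "", collapse = " ")
    paste0(id, "\t", paste(aliases, collapse = "|"))
  }, "")
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Read relevance judgments (qrels)
#'
#' TSV rows `pair_id TAB ref_id TAB label` with label in `{0,1}`.
#' A pair whose rows are all label 0 gets an empty target set; pairs
#' with no rows at all are absent from the result.
#'
#' @param path File path.
#' @return Named list `pair_id -> character vector of target ref_ids`.
#' @export
read_qrels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("pair_id", "ref_id", "label"))
  if (!all(df$label %in% c("0", "1"))) {
    stop("qrels labels must be 0 or 1", call. = FALSE)
  }
  qrels <- lapply(split(df, df$pair_id), function(d) {
    sort(unique(d$ref_id[d$label == "1"]))
  })
  qrels[order(names(qrels), method = "radix")]
}

#' Write relevance judgments as TSV
#'
#' @param qrels Named list `pair_id -> target ref_ids`.
#' @param candidates Named list `pair_id -> candidate ref_ids`; every
#'   candidate gets a row with label 1 if it is a target, else 0.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(qrels, candidates, path) {
  rows <- character(0)
  for (pid in names(candidates)) {
    tgt <- qrels[[pid]]
    lab <- as.integer(candidates[[pid]] %in% tgt)
    rows <- c(rows, paste(pid, candidates[[pid]], lab, sep = "\t"))
  }
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
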