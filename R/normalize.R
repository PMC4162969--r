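#' Normalize biomedical text into tokens
#'
#' Replaces every non-alphanumeric character with a space, splits on
#' whitespace, and lowercases each token unless the token's alphabetic
#' characters are all uppercase. The exemption keeps gene symbols such as
#' `"BRCA1"` or `"DNA"` intact while folding ordinary words and mixed-case
#' tokens (`"HbS"` becomes `"hbs"`). Digits never block the exemption:
#' the test is applied to the alphabetic characters only, so an all-digit
#' token is returned unchanged.
#'
#' The function is idempotent: normalizing the space-joined output again
#' yields the same tokens.
#'
#' @param raw A single character string (may be empty or `NA`).
#' @return A character vector of tokens, possibly empty. Every token is
#'   non-empty and contains only characters in `[A-Za-z0-9]`.
#' @examples
#' normalize_text("Beta-globin gene.")   # "beta" "globin" "gene"
#' normalize_text("DNA repair")          # "DNA" "repair"
#' normalize_text("HbS allele (Hb C)")   # "hbs" "allele" "hb" "c"
#' @export
normalize_text <- function(raw) {
  if (length(raw) != 1L || !is.character(raw)) {
    stop("`raw` must be a single character string", call. = FALSE)
  }
  if (is.na(raw) || raw == "") {
    return(character(0))
  }
  spaced <- gsub("[^A-Za-z0-9]", " ", raw)
  toks <- strsplit(trimws(spaced), "[ ]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) {
    return(character(0))
  }
  alpha <- gsub("[0-9]", "", toks)
  all_upper <- alpha == toupper(alpha)
  toks[!all_upper] <- tolower(toks[!all_upper])
  toks
}

# Split a raw abstract into sentence strings on period-plus-whitespace.
# Used only when a record does not supply explicit sentences.
split_sentences <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) {
    return(character(0))
  }
  sents <- strsplit(raw, "\\.\\s+")[[1]]
  sents[nzchar(trimws(sents))]
}
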