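#' Valence lexicons
#'
#' A valence lexicon is one row per word: orthographic form, language code,
#' phonological transcription in the neutral symbol dialect (with tone
#' tokens for Chinese), a valence rating on the 1--9 scale, and optionally
#' a log frequency. [validate_lexicon()] enforces the contract; the TSV
#' readers/writers round-trip the table exactly.
#'
#' @name valence_lexicon
NULL

#' @rdname valence_lexicon
#' @param lexicon a tibble/data frame with columns `word`, `language`,
#'   `transcription`, `valence` and optionally `log_frequency`.
#' @return the validated lexicon (invisibly for the writer).
#' @export
validate_lexicon <- function(lexicon) {
  need <- c("word", "language", "transcription", "valence")
  miss <- setdiff(need, names(lexicon))
  if (length(miss)) stop("lexicon lacks columns: ", paste(miss, collapse = ", "))
  if (!all(lexicon$language %in% PHONO_LANGUAGES)) {
    stop("unknown language codes: ",
         paste(setdiff(unique(lexicon$language), PHONO_LANGUAGES), collapse = ", "))
  }
  if (any(!is.finite(lexicon$valence) | lexicon$valence < 1 |
            lexicon$valence > 9)) {
    stop("valence ratings must lie in [1, 9]")
  }
  dup <- duplicated(lexicon[c("language", "word")])
  if (any(dup)) {
    stop("duplicate words within a language: ",
         paste(utils::head(lexicon$word[dup], 5), collapse = ", "))
  }
  invisible(lexicon)
}

#' @rdname valence_lexicon
#' @param path TSV file path.
#' @export
read_lexicon <- function(path) {
  lex <- readr::read_tsv(path, col_types = readr::cols(
    word = "c", language = "c", transcription = "c", valence = "d",
    .default = "d"))
  validate_lexicon(lex)
  lex
}

#' @rdname valence_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  validate_lexicon(lexicon)
  readr::write_tsv(lexicon, path)
  invisible(lexicon)
}
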