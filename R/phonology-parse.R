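#' Phonological transcriptions
#'
#' A transcription is an ordered phoneme sequence, optionally carrying
#' syllable boundaries and (for Chinese) one tone per syllable. Two input
#' dialects are supported:
#'
#' * the neutral whitespace-separated symbol dialect ([parse_transcription()]):
#'   tokens are inventory symbols; for Chinese, a bare digit token `1`--`5`
#'   closes the current syllable and records its tone, so a Chinese
#'   transcription is fully syllabified and toned by construction;
#' * strict numeric-tone Pinyin ([parse_pinyin()]): each syllable is a
#'   standard Mandarin initial+final spelling with a mandatory trailing tone
#'   digit `1`--`5` (`5` = neutral tone).
#'
#' @name transcription
NULL

new_transcription <- function(language, symbols, rows,
                              syllable_ends = NULL, tones = NULL) {
  structure(list(language = language, symbols = symbols, rows = rows,
                 syllable_ends = syllable_ends, tones = tones),
            class = "transcription")
}

#' @export
print.transcription <- function(x, ...) {
  cat("<transcription> [", x$language, "] /",
      paste(x$symbols, collapse = " "), "/", sep = "")
  if (!is.null(x$tones)) cat("  tones:", paste(x$tones, collapse = ""))
  cat("\n")
  invisible(x)
}

n_phonemes <- function(t) length(t$symbols)

#' Parse the neutral symbol dialect
#'
#' Splits `text` on whitespace and looks every token up in the inventory's
#' symbol map. An unmapped token is an error naming the token and its
#' position; a silent skip would corrupt every downstream feature count.
#' For the Chinese inventory, digit tokens `1`--`5` act as syllable
#' terminators carrying tone (see [transcription]); every Chinese syllable
#' must be closed by a tone token.
#'
#' @param text non-empty string of whitespace-separated symbols.
#' @param inventory a [phoneme_inventory()].
#' @return a `transcription`.
#' @examples
#' parse_transcription("m a n", phoneme_inventory("nl"))
#' parse_transcription("m a 3 m a 1", phoneme_inventory("zh"))
#' @export
parse_transcription <- function(text, inventory) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty transcription")
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  language <- inventory_language(inventory)
  if (language == "zh") {
    is_tone <- tokens %in% as.character(1:5)
    if (!any(is_tone)) {
      stop("Chinese transcription lacks tone tokens: '", text, "'")
    }
    pos <- which(is_tone)
    lens <- diff(c(0L, pos)) - 1L
    if (any(lens == 0L)) stop("tone token without preceding syllable in '", text, "'")
    if (max(pos) != length(tokens)) {
      stop("trailing phonemes without a closing tone token in '", text, "'")
    }
    symbols <- tokens[!is_tone]
    rows <- symbol_rows(symbols, inventory)
    new_transcription(language, symbols, rows,
                      syllable_ends = cumsum(lens),
                      tones = as.integer(tokens[is_tone]))
  } else {
    rows <- symbol_rows(tokens, inventory)
    new_transcription(language, tokens, rows)
  }
}

#' Render a transcription back to the neutral symbol dialect
#'
#' Inverse of [parse_transcription()]: for Chinese, tone digits are emitted
#' after each syllable, so render/reparse round-trips exactly.
#'
#' @param t a `transcription`.
#' @return single string in the neutral dialect.
#' @export
render_transcription <- function(t) {
  if (is.null(t$tones)) return(paste(t$symbols, collapse = " "))
  starts <- c(1L, utils::head(t$syllable_ends, -1L) + 1L)
  parts <- mapply(function(s, e, tone)
    paste(c(t$symbols[s:e], tone), collapse = " "),
    starts, t$syllable_ends, t$tones)
  paste(parts, collapse = " ")
}

.pinyin_cache <- new.env(parent = emptyenv())

pinyin_tables <- function() {
  if (is.null(.pinyin_cache$tables)) {
    ini <- readr::read_tsv(pkg_extdata("pinyin_initials.tsv"),
                           col_types = readr::cols(initial = "c", symbols = "c"))
    fin <- readr::read_tsv(pkg_extdata("pinyin_finals.tsv"),
                           col_types = readr::cols(final = "c", symbols = "c"))
    .pinyin_cache$tables <- list(
      initials = stats::setNames(ini$symbols, ini$initial),
      finals = stats::setNames(fin$symbols, fin$final))
  }
  .pinyin_cache$tables
}

# Orthographic normalization of one toneless Pinyin syllable body into
# (initial, final-table key). Zero-initial y-/w- spellings are rewritten to
# their medial form (ya -> ia, wo -> uo, yu -> v ...), and u after j/q/x
# denotes the front rounded vowel.
pinyin_split <- function(body) {
  tabs <- pinyin_tables()
  if (startsWith(body, "yu")) {
    return(c("", paste0("v", substring(body, 3L))))
  }
  if (startsWith(body, "yi")) {
    return(c("", substring(body, 2L)))
  }
  if (startsWith(body, "y")) {
    return(c("", paste0("i", substring(body, 2L))))
  }
  if (body == "wu") return(c("", "u"))
  if (startsWith(body, "w")) {
    return(c("", paste0("u", substring(body, 2L))))
  }
  two <- substring(body, 1L, 2L)
  one <- substring(body, 1L, 1L)
  if (two %in% names(tabs$initials)) {
    ini <- two
  } else if (one %in% names(tabs$initials)) {
    ini <- one
  } else {
    ini <- ""
  }
  fin <- substring(body, nchar(ini) + 1L)
  if (ini %in% c("j", "q", "x") && startsWith(fin, "u")) {
    fin <- paste0("v", substring(fin, 2L))
  }
  c(ini, fin)
}

#' Parse strict numeric-tone Pinyin
#'
#' Each whitespace-separated syllable must be a standard Mandarin spelling
#' with a trailing tone digit `1`--`5` (`5` = neutral tone); tone diacritics
#' are rejected. Syllables are decomposed through the bundled initial and
#' final tables into inventory phonemes; medial glides surface as the
#' approximants `y`/`w` in the onset.
#'
#' @param text e.g. `"ma3"` or `"bei1 shang1"`.
#' @return a `transcription` over the `zh` inventory, with one tone and one
#'   syllable boundary per input syllable.
#' @examples
#' parse_pinyin("ma3")
#' parse_pinyin("bei1 shang1")
#' @export
parse_pinyin <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty Pinyin string")
  inv <- phoneme_inventory("zh")
  tabs <- pinyin_tables()
  sylls <- strsplit(trimws(tolower(text)), "\\s+")[[1]]
  all_symbols <- character(0)
  ends <- integer(length(sylls))
  tones <- integer(length(sylls))
  for (i in seq_along(sylls)) {
    s <- sylls[i]
    last <- substring(s, nchar(s))
    if (!grepl("^[1-5]$", last)) {
      stop("Pinyin syllable '", s, "' lacks a tone digit 1-5")
    }
    body <- substring(s, 1L, nchar(s) - 1L)
    if (!nzchar(body) || grepl("[^a-z]", body)) {
      stop("unparseable Pinyin syllable: '", s, "'")
    }
    parts <- pinyin_split(body)
    fin <- parts[2]
    if (!nzchar(fin) || !(fin %in% names(tabs$finals))) {
      stop("unparseable Pinyin syllable: '", s, "' (no final '", fin, "')")
    }
    syms <- character(0)
    if (nzchar(parts[1])) {
      syms <- strsplit(tabs$initials[[parts[1]]], " ")[[1]]
    }
    syms <- c(syms, strsplit(tabs$finals[[fin]], " ")[[1]])
    all_symbols <- c(all_symbols, syms)
    ends[i] <- length(all_symbols)
    tones[i] <- as.integer(last)
  }
  new_transcription("zh", all_symbols, symbol_rows(all_symbols, inv),
                    syllable_ends = ends, tones = tones)
}
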