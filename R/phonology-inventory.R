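#' Supported language codes
#'
#' The four languages covered by the bundled research inventories:
#' English (`en`), Dutch (`nl`), German (`de`) and Mandarin Chinese (`zh`).
#'
#' @export
PHONO_LANGUAGES <- c("en", "nl", "de", "zh")

.inventory_cache <- new.env(parent = emptyenv())

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "phonovalence")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ may be mounted directly
    path <- system.file(file, package = "phonovalence")
  }
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}

#' Load a phoneme inventory
#'
#' Reads the bundled research inventory for one language: a compact set of
#' roughly 25--45 segments, each annotated with sound class (consonant or
#' vowel), manner and place of articulation, voicing, and for vowels height,
#' backness, rounding, length and diphthong status. The inventories are
#' deliberately small: they carry exactly the class memberships the feature
#' schema reads, not exhaustive phonologies. English includes the dental
#' fricatives, Dutch and German each include a trill and a uvular segment,
#' and the Chinese inventory is read by the Pinyin parser (tone lives on the
#' transcription, not on segments).
#'
#' @param language one of `"en"`, `"nl"`, `"de"`, `"zh"`.
#' @return a `phoneme_inventory`: a tibble of phonemes (one row per symbol)
#'   with attributes `language` and `symbol_index` (a fast symbol-to-row map).
#' @export
phoneme_inventory <- function(language) {
  language <- match.arg(language, PHONO_LANGUAGES)
  key <- paste0("inv_", language)
  if (!is.null(.inventory_cache[[key]])) return(.inventory_cache[[key]])
  tab <- readr::read_tsv(pkg_extdata(paste0("inventory_", language, ".tsv")),
                         col_types = readr::cols(
                           symbol = "c", sound_class = "c", manner = "c",
                           place = "c", voiced = "l", height = "c",
                           backness = "c", rounded = "l", long = "l",
                           diphthong = "l"))
  validate_inventory(tab, language)
  idx <- seq_len(nrow(tab))
  names(idx) <- tab$symbol
  attr(tab, "language") <- language
  attr(tab, "symbol_index") <- idx
  class(tab) <- c("phoneme_inventory", class(tab))
  .inventory_cache[[key]] <- tab
  tab
}

validate_inventory <- function(tab, language) {
  if (anyDuplicated(tab$symbol)) {
    stop("duplicate symbols in ", language, " inventory: ",
         paste(unique(tab$symbol[duplicated(tab$symbol)]), collapse = ", "))
  }
  cons <- tab$sound_class == "consonant"
  bad <- cons & (tab$manner == "none" | tab$height != "none")
  bad <- bad | (!cons & (tab$height == "none" | tab$manner != "none"))
  if (any(bad)) {
    stop("ill-formed phoneme rows in ", language, " inventory: ",
         paste(tab$symbol[bad], collapse = ", "))
  }
  invisible(tab)
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat("<phoneme_inventory> language:", attr(x, "language"),
      "|", sum(x$sound_class == "consonant"), "consonants,",
      sum(x$sound_class == "vowel"), "vowels\n")
  NextMethod()
}

inventory_language <- function(inventory) attr(inventory, "language")

# Row indices in the inventory for a vector of symbols; errors name the
# first unmapped symbol and its 1-based token position.
symbol_rows <- function(symbols, inventory) {
  idx <- attr(inventory, "symbol_index")[symbols]
  if (anyNA(idx)) {
    at <- which(is.na(idx))[1L]
    stop("unknown symbol '", symbols[at], "' at token ", at,
         " (language ", inventory_language(inventory), ")")
  }
  unname(idx)
}

#' Legal onset clusters for a language
#'
#' Multi-consonant clusters that may begin a syllable, used by the
#' maximal-onset syllabifier and by the lexicon generator. Any single
#' consonant is always a legal onset and is not listed.
#'
#' @param language one of `"en"`, `"nl"`, `"de"`, `"zh"`.
#' @return character vector of space-separated symbol clusters (possibly
#'   empty for languages without onset clusters).
#' @export
legal_onsets <- function(language) {
  language <- match.arg(language, PHONO_LANGUAGES)
  key <- "onsets"
  if (is.null(.inventory_cache[[key]])) {
    .inventory_cache[[key]] <- readr::read_tsv(
      pkg_extdata("legal_onsets.tsv"),
      col_types = readr::cols(language = "c", onset = "c"))
  }
  tab <- .inventory_cache[[key]]
  tab$onset[tab$language == language]
}
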