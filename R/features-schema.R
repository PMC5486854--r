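#' The master phonological feature list
#'
#' Returns the bundled 105-entry master list of phonological feature
#' specifications, spanning five families:
#'
#' 1. `word_count` — number of phonemes in the word matching a class
#'    (e.g. `n_nasal`), plus total phoneme count;
#' 2. `word_proportion` — the same counts divided by word length;
#' 3. `onset` — counts restricted to the first syllable of the word;
#' 4. `first_consonant` — indicators describing the word-initial phoneme
#'    when it is a consonant (all zero for vowel-initial words), including
#'    `nasal_first`;
#' 5. `vowel` — indicator banks for the first vowel's height, backness,
#'    rounding, length and diphthong status, plus the Chinese tone bank
#'    (first-syllable tone indicators and mean word tone).
#'
#' The classes are the cross-product of manner and place of articulation
#' with voicing and broad vowel classes. Each entry lists the languages it
#' applies to: dental classes are English-only, trills and uvulars belong
#' to Dutch and German, tone to Chinese, and the close-mid/open-mid and
#' near-front/near-back vowel distinctions are absent from Chinese.
#'
#' @return tibble with columns `name`, `family`, `predicate`, `statistic`,
#'   `languages` (comma-separated codes); exactly 105 rows.
#' @export
feature_specs <- function() {
  if (is.null(.inventory_cache$specs)) {
    tab <- readr::read_tsv(pkg_extdata("feature_specs.tsv"),
                           col_types = readr::cols(.default = "c"))
    stopifnot(nrow(tab) == 105L, !anyDuplicated(tab$name))
    .inventory_cache$specs <- tab
  }
  .inventory_cache$specs
}

#' Build the feature schema for one language
#'
#' Filters the master list ([feature_specs()]) down to the specs whose
#' language set includes `language`. The order of the master list is
#' preserved, so vector positions are stable across calls.
#'
#' @param language one of `"en"`, `"nl"`, `"de"`, `"zh"`.
#' @return a `feature_schema`: the filtered spec tibble with attribute
#'   `language`.
#' @examples
#' nrow(build_schema("zh"))   # 89 of the 105 master specs apply to Chinese
#' @export
build_schema <- function(language) {
  language <- match.arg(language, PHONO_LANGUAGES)
  specs <- feature_specs()
  keep <- vapply(strsplit(specs$languages, ","),
                 function(x) language %in% x, logical(1))
  schema <- specs[keep, ]
  attr(schema, "language") <- language
  class(schema) <- c("feature_schema", class(schema))
  schema
}

schema_language <- function(schema) attr(schema, "language")

# Evaluate a phoneme-class predicate over all inventory rows.
class_predicate <- function(predicate, inventory) {
  cons <- inventory$sound_class == "consonant"
  vow <- !cons
  if (predicate == "any") return(rep(TRUE, nrow(inventory)))
  if (predicate == "voiced_consonant") return(cons & inventory$voiced)
  if (predicate == "long_vowel") return(vow & inventory$long)
  if (predicate == "diphthong") return(inventory$diphthong)
  if (predicate == "rounded_vowel") return(vow & inventory$rounded)
  kv <- strsplit(predicate, "=", fixed = TRUE)[[1]]
  if (length(kv) != 2L) stop("unknown class predicate: ", predicate)
  field <- kv[1]; value <- kv[2]
  switch(field,
         sound_class = inventory$sound_class == value,
         manner = cons & inventory$manner == value,
         place = cons & inventory$place == value,
         stop("unknown class predicate: ", predicate))
}
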