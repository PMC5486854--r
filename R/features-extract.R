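#' Is the word nasal-first?
#'
#' Indicator for the strongest shared sound-symbolic cue in the valence
#' analyses: 1 if and only if the word-initial phoneme is a nasal
#' consonant. A word whose nasal appears later, or which starts with a
#' vowel, scores 0.
#'
#' @param t a `transcription` with at least one phoneme.
#' @return 0 or 1.
#' @examples
#' inv <- phoneme_inventory("nl")
#' nasal_first(parse_transcription("m a:", inv))    # 1
#' nasal_first(parse_transcription("p a: n", inv))  # 0
#' @export
nasal_first <- function(t) {
  if (n_phonemes(t) == 0L) stop("empty transcription")
  inv <- phoneme_inventory(t$language)
  r <- t$rows[1L]
  as.integer(inv$sound_class[r] == "consonant" & inv$manner[r] == "nasal")
}

# Precompute everything extract needs for one (schema, inventory) pair:
# a numeric membership matrix over inventory rows (one column per class
# predicate used by families 1-4) and the schema-row dispatch tables.
prep_extractor <- function(schema, inventory) {
  fam <- schema$family
  cls_rows <- fam %in% c("word_count", "word_proportion", "onset", "first_consonant")
  preds <- unique(schema$predicate[cls_rows])
  M <- vapply(preds, function(p) as.numeric(class_predicate(p, inventory)),
              numeric(nrow(inventory)))
  colnames(M) <- preds
  vowel_rows <- which(fam == "vowel")
  vinfo <- lapply(schema$predicate[vowel_rows], function(p) {
    if (grepl("^tone=", p)) list(kind = "tone", level = as.integer(sub("tone=", "", p)))
    else if (p == "tone_mean") list(kind = "tone_mean")
    else if (p == "v1_rounded") list(kind = "vfield", field = "rounded")
    else if (p == "v1_long") list(kind = "vfield", field = "long")
    else if (p == "v1_diphthong") list(kind = "vfield", field = "diphthong")
    else {
      kv <- strsplit(p, "=", fixed = TRUE)[[1]]
      list(kind = "vlevel", field = kv[1], value = kv[2])
    }
  })
  list(inventory = inventory, M = M,
       names = schema$name, family = fam,
       pred_col = match(schema$predicate, preds),
       vowel_rows = vowel_rows, vinfo = vinfo,
       is_vowel = inventory$sound_class == "vowel",
       is_cons = inventory$sound_class == "consonant")
}

extract_core <- function(t, prep) {
  rows <- t$rows
  np <- length(rows)
  memb <- prep$M[rows, , drop = FALSE]
  counts <- .colSums(memb, np, ncol(memb))
  vflags <- prep$is_vowel[rows]
  e1 <- first_syllable_end(t, vflags)
  counts1 <- .colSums(memb[seq_len(e1), , drop = FALSE], e1, ncol(memb))
  first_cons <- prep$is_cons[rows[1L]]
  vals <- numeric(length(prep$names))
  fam <- prep$family
  pc <- prep$pred_col
  wc <- fam == "word_count"
  vals[wc] <- counts[pc[wc]]
  wp <- fam == "word_proportion"
  vals[wp] <- counts[pc[wp]] / np
  on <- fam == "onset"
  vals[on] <- counts1[pc[on]]
  fc <- fam == "first_consonant"
  vals[fc] <- if (first_cons) memb[1L, pc[fc]] else 0
  if (length(prep$vowel_rows)) {
    fv <- which(vflags)[1L]                 # first vowel (guaranteed by contract)
    fvrow <- if (is.na(fv)) NA_integer_ else rows[fv]
    inv <- prep$inventory
    for (k in seq_along(prep$vowel_rows)) {
      vi <- prep$vinfo[[k]]
      vals[prep$vowel_rows[k]] <- switch(vi$kind,
        tone = as.numeric(!is.null(t$tones) && t$tones[1L] == vi$level),
        tone_mean = if (is.null(t$tones)) 0 else mean(t$tones),
        vfield = if (is.na(fvrow)) 0 else as.numeric(inv[[vi$field]][fvrow]),
        vlevel = if (is.na(fvrow)) 0 else
          as.numeric(inv[[vi$field]][fvrow] == vi$value))
    }
  }
  names(vals) <- prep$names
  vals
}

#' Extract one word's phonological feature vector
#'
#' Computes the word's value for every spec in the schema: class counts
#' over the whole word, their proportions, class counts within the first
#' syllable, first-consonant indicators (all zero for vowel-initial
#' words), and the first-vowel/tone banks. Values are aligned to schema
#' order and named by feature.
#'
#' @param t a `transcription`.
#' @param schema a [build_schema()] result for the same language.
#' @return named numeric vector, one value per schema spec.
#' @examples
#' inv <- phoneme_inventory("nl")
#' v <- extract_features(parse_transcription("m a: n", inv), build_schema("nl"))
#' v[c("n_nasal", "p_nasal", "nasal_first")]
#' @export
extract_features <- function(t, schema) {
  if (t$language != schema_language(schema)) {
    stop("transcription language '", t$language,
         "' does not match schema language '", schema_language(schema), "'")
  }
  inv <- phoneme_inventory(t$language)
  extract_core(t, prep_extractor(schema, inv))
}

#' Feature matrix for a whole lexicon
#'
#' Parses every transcription in the lexicon and extracts its feature
#' vector under the language's schema. The first columns identify the word
#' and carry its valence; the remaining columns are the schema features in
#' schema order.
#'
#' @param lexicon a valence lexicon tibble (see [generate_lexicon()] /
#'   [read_lexicon()]): columns `word`, `language`, `transcription`,
#'   `valence`.
#' @param schema optional [build_schema()]; defaults to the lexicon's
#'   language.
#' @return tibble: `word`, `language`, `valence`, then one column per
#'   feature.
#' @export
feature_matrix <- function(lexicon, schema = NULL) {
  stopifnot(all(c("word", "language", "transcription", "valence") %in%
                  names(lexicon)))
  language <- unique(lexicon$language)
  if (length(language) != 1L) {
    stop("feature_matrix expects a single-language lexicon; got: ",
         paste(language, collapse = ", "))
  }
  if (is.null(schema)) schema <- build_schema(language)
  if (schema_language(schema) != language) {
    stop("schema language '", schema_language(schema),
         "' does not match lexicon language '", language, "'")
  }
  inv <- phoneme_inventory(language)
  prep <- prep_extractor(schema, inv)
  vals <- matrix(0, nrow(lexicon), length(prep$names),
                 dimnames = list(NULL, prep$names))
  for (i in seq_len(nrow(lexicon))) {
    vals[i, ] <- extract_core(parse_transcription(lexicon$transcription[i], inv),
                              prep)
  }
  dplyr::bind_cols(
    tibble::tibble(word = lexicon$word, language = lexicon$language,
                   valence = lexicon$valence),
    tibble::as_tibble(vals))
}
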