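#' Syllabification by maximal onset
#'
#' Segments a transcription into syllables. Transcriptions that already
#' carry syllable boundaries (the Pinyin path and the tone-token dialect)
#' are split on those boundaries verbatim. For unboundaried input every
#' vowel is a nucleus and each intervocalic consonant cluster is split so
#' that the following syllable receives the longest cluster suffix that is
#' a legal onset: any single consonant, or a cluster listed in
#' [legal_onsets()] for the language. Word-initial consonants all join the
#' first onset and word-final consonants the last coda, so the
#' concatenation of syllables always reproduces the phoneme sequence.
#'
#' @param t a `transcription`.
#' @param inventory the matching [phoneme_inventory()].
#' @return list of syllables, each a list with character vectors `onset`,
#'   `nucleus` (never empty) and `coda`.
#' @examples
#' inv <- phoneme_inventory("nl")
#' syllabify(parse_transcription("m a n d a:", inv), inv)
#' @export
syllabify <- function(t, inventory) {
  if (t$language != inventory_language(inventory)) {
    stop("transcription language '", t$language, "' does not match inventory '",
         inventory_language(inventory), "'")
  }
  is_vowel <- inventory$sound_class[t$rows] == "vowel"
  if (!any(is_vowel)) {
    stop("cannot syllabify a vowel-free transcription: /",
         paste(t$symbols, collapse = " "), "/")
  }
  ends <- syllable_ends(t, is_vowel)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(i) {
    span <- starts[i]:ends[i]
    v <- is_vowel[span]
    if (!any(v)) {
      stop("syllable without a vowel at positions ", starts[i], "-", ends[i])
    }
    first_v <- which(v)[1L]
    # nucleus = the contiguous vowel run beginning at the first vowel
    run_end <- first_v
    while (run_end < length(span) && v[run_end + 1L]) run_end <- run_end + 1L
    if (any(v[-seq_len(run_end)])) {
      stop("ill-formed syllable: vowel after coda at positions ",
           starts[i], "-", ends[i])
    }
    list(onset = t$symbols[span[seq_len(first_v - 1L)]],
         nucleus = t$symbols[span[first_v:run_end]],
         coda = if (run_end < length(span))
           t$symbols[span[(run_end + 1L):length(span)]] else character(0))
  })
}

# End index (into the phoneme sequence) of every syllable. Uses stored
# boundaries when present, else maximal onset against the legal-onset list.
syllable_ends <- function(t, is_vowel) {
  if (!is.null(t$syllable_ends)) return(t$syllable_ends)
  onset_set <- legal_onsets(t$language)
  vpos <- which(is_vowel)
  k <- length(vpos)
  if (k == 1L) return(length(t$symbols))
  ends <- integer(k)
  ends[k] <- length(t$symbols)
  for (j in 2:k) {
    lo <- vpos[j - 1L] + 1L   # first consonant after previous nucleus
    hi <- vpos[j] - 1L        # last consonant before this nucleus
    len <- hi - lo + 1L
    o <- 0L
    if (len >= 1L) {
      o <- 1L                 # a single consonant is always a legal onset
      if (len >= 2L) {
        for (cand in len:2L) {
          cluster <- paste(t$symbols[(vpos[j] - cand):(vpos[j] - 1L)],
                           collapse = " ")
          if (cluster %in% onset_set) { o <- cand; break }
        }
      }
    }
    ends[j - 1L] <- vpos[j] - o - 1L
  }
  ends
}

# Length of the first syllable only; same segmentation rule as syllabify()
# but without building syllable structures (hot path of the extractor).
first_syllable_end <- function(t, is_vowel) {
  if (!is.null(t$syllable_ends)) return(t$syllable_ends[1L])
  vpos <- which(is_vowel)
  if (length(vpos) < 2L) return(length(t$symbols))
  syllable_ends(t, is_vowel)[1L]
}
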