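#' Synthetic lexicon model
#'
#' Parameters of the synthetic valence lexicon generator. Defaults emulate
#' the shape of the real norm databases the corpus study draws on: words of
#' 1--4 syllables averaging just over two, a quarter of words beginning
#' with a nasal, valence centred at the scale midpoint 5 with rating noise
#' of a bit over one scale point, and a signed nasal-first valence shift
#' `beta` (positive means nasal-first words are rated more positive).
#'
#' @param language one of `"en"`, `"nl"`, `"de"`, `"zh"`.
#' @param n_words number of words to generate.
#' @param syllable_dist probabilities for 1--4 syllables (sums to 1).
#' @param nasal_first_rate probability that a word is generated
#'   nasal-initial; strictly inside (0, 1).
#' @param mu baseline mean valence on the 1--9 scale.
#' @param beta signed valence shift for nasal-first words (scale points).
#' @param sigma SD of Gaussian valence noise (scale points).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `lexicon_model` list.
#' @export
lexicon_model <- function(language, n_words,
                          syllable_dist = c(0.2, 0.6, 0.15, 0.05),
                          nasal_first_rate = 0.25,
                          mu = 5, beta = 0.3, sigma = 1.3, seed) {
  language <- match.arg(language, PHONO_LANGUAGES)
  stopifnot(n_words >= 1, length(syllable_dist) == 4,
            abs(sum(syllable_dist) - 1) < 1e-8,
            nasal_first_rate > 0, nasal_first_rate < 1,
            sigma >= 0, is.numeric(seed))
  structure(list(language = language, n_words = as.integer(n_words),
                 syllable_dist = syllable_dist,
                 nasal_first_rate = nasal_first_rate,
                 mu = mu, beta = beta, sigma = sigma,
                 seed = as.integer(seed)),
            class = "lexicon_model")
}

# Syllable building blocks for a language: onset pool (includes the empty
# onset and legal clusters), vowel nuclei, coda pool.
syllable_pools <- function(language) {
  inv <- phoneme_inventory(language)
  cons <- inv$symbol[inv$sound_class == "consonant"]
  vowels <- inv$symbol[inv$sound_class == "vowel"]
  singles <- setdiff(cons, "N")          # the velar nasal never starts a word
  clusters <- legal_onsets(language)
  if (language == "zh") {
    codas <- intersect(c("n", "N"), cons)
  } else {
    eligible <- inv$manner %in% c("nasal", "plosive", "fricative", "lateral",
                                  "trill") & inv$place != "glottal"
    codas <- inv$symbol[inv$sound_class == "consonant" & eligible]
  }
  onsets <- c("", singles, clusters)
  onset_prob <- c(0.15, rep(0.65 / length(singles), length(singles)),
                  if (length(clusters)) rep(0.20 / length(clusters),
                                            length(clusters)))
  onset_prob <- onset_prob / sum(onset_prob)
  first_sym <- vapply(strsplit(onsets, " "), function(x)
    if (length(x)) x[1] else "", character(1))
  nasal_start <- first_sym %in% inv$symbol[inv$manner == "nasal"]
  list(inv = inv, vowels = vowels, codas = codas, onsets = onsets,
       onset_prob = onset_prob, nasal_start = nasal_start)
}

#' Generate a synthetic valence lexicon
#'
#' Samples `n_words` phonotactically legal words (onset + nucleus + coda
#' syllables; Chinese syllables additionally carry a tone token) from the
#' language's inventory, forces a nasal-initial first phoneme at rate
#' `nasal_first_rate`, and draws valence as
#' `mu + beta * nasal_first + Normal(0, sigma)` clipped to the 1--9 scale.
#' The returned table is a valid lexicon (see [validate_lexicon()]) with
#' the generator's ground-truth `nasal_first` flag as an extra column.
#'
#' @param m a [lexicon_model()].
#' @return tibble: `word`, `language`, `transcription`, `valence`,
#'   `log_frequency`, `nasal_first`.
#' @examples
#' lex <- generate_lexicon(lexicon_model("nl", 50, seed = 1))
#' head(lex)
#' @export
generate_lexicon <- function(m) {
  stopifnot(inherits(m, "lexicon_model"))
  pools <- syllable_pools(m$language)
  nasal_onsets <- pools$onsets[pools$nasal_start]
  if (!length(nasal_onsets)) {
    stop("inventory for ", m$language,
         " has no nasal onsets; cannot force nasal-first words")
  }
  plain_onsets <- pools$onsets[!pools$nasal_start]
  plain_prob <- pools$onset_prob[!pools$nasal_start]
  plain_prob <- plain_prob / sum(plain_prob)

  set.seed(m$seed)
  n <- m$n_words
  n_syll <- sample.int(4L, n, replace = TRUE, prob = m$syllable_dist)
  total <- sum(n_syll)
  word_id <- rep.int(seq_len(n), n_syll)
  first_idx <- cumsum(c(1L, n_syll[-n]))

  onset <- sample(pools$onsets, total, replace = TRUE, prob = pools$onset_prob)
  nucleus <- sample(pools$vowels, total, replace = TRUE)
  coda <- ifelse(stats::runif(total) < 0.4,
                 sample(pools$codas, total, replace = TRUE), "")
  nasal <- stats::rbinom(n, 1L, m$nasal_first_rate)
  n_nasal <- sum(nasal == 1L)
  if (n_nasal) {
    onset[first_idx[nasal == 1L]] <-
      sample(nasal_onsets, n_nasal, replace = TRUE)
  }
  resample <- which(nasal == 0L)[
    onset[first_idx[nasal == 0L]] %in% nasal_onsets]
  if (length(resample)) {
    onset[first_idx[resample]] <-
      sample(plain_onsets, length(resample), replace = TRUE, prob = plain_prob)
  }
  tone <- if (m$language == "zh") {
    as.character(sample.int(5L, total, replace = TRUE,
                            prob = c(0.24, 0.24, 0.24, 0.24, 0.04)))
  } else ""
  syll <- trimws(gsub(" +", " ", paste(onset, nucleus, coda, tone)))
  transcription <- vapply(split(syll, word_id), paste, character(1),
                          collapse = " ")
  valence <- m$mu + m$beta * nasal + stats::rnorm(n, 0, m$sigma)
  valence <- pmin(9, pmax(1, valence))
  lex <- tibble::tibble(
    word = sprintf("w%06d", seq_len(n)),
    language = m$language,
    transcription = unname(transcription),
    valence = valence,
    log_frequency = stats::rnorm(n, 14, 2),
    nasal_first = as.integer(nasal))
  validate_lexicon(lex)
  lex
}
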