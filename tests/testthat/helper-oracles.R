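# Independent brute-force oracles used by the property tests. These
# deliberately re-derive every quantity from first principles (explicit
# per-phoneme scans, exhaustive enumeration) and share no code with the
# implementation paths they check.

# Does one phoneme row of `inv` satisfy a class predicate string?
oracle_match <- function(inv, row, predicate) {
  ph <- inv[row, ]
  if (predicate == "any") return(TRUE)
  if (predicate == "voiced_consonant")
    return(ph$sound_class == "consonant" && ph$voiced)
  if (predicate == "long_vowel") return(ph$sound_class == "vowel" && ph$long)
  if (predicate == "diphthong") return(isTRUE(ph$diphthong))
  if (predicate == "rounded_vowel")
    return(ph$sound_class == "vowel" && ph$rounded)
  kv <- strsplit(predicate, "=", fixed = TRUE)[[1]]
  if (kv[1] == "sound_class") return(ph$sound_class == kv[2])
  if (kv[1] == "manner")
    return(ph$sound_class == "consonant" && ph$manner == kv[2])
  if (kv[1] == "place")
    return(ph$sound_class == "consonant" && ph$place == kv[2])
  stop("oracle: unknown predicate ", predicate)
}

# Naive re-computation of one word's value for one feature spec: a fresh
# scan over the phoneme sequence per call.
oracle_feature <- function(t, spec, inv, first_syl_len = NULL) {
  rows <- match(t$symbols, inv$symbol)
  stopifnot(!anyNA(rows))
  hits <- if (spec$family != "vowel") {
    vapply(rows, function(r) oracle_match(inv, r, spec$predicate),
           logical(1))
  }
  if (spec$family == "word_count") return(sum(hits))
  if (spec$family == "word_proportion") return(sum(hits) / length(rows))
  if (spec$family == "onset") {
    if (is.null(first_syl_len)) {
      syl <- syllabify(t, inv)
      first_syl_len <- length(syl[[1]]$onset) + length(syl[[1]]$nucleus) +
        length(syl[[1]]$coda)
    }
    return(sum(hits[seq_len(first_syl_len)]))
  }
  if (spec$family == "first_consonant") {
    if (inv$sound_class[rows[1]] != "consonant") return(0)
    return(as.numeric(hits[1]))
  }
  # vowel family: first-vowel banks and tone specs
  p <- spec$predicate
  if (grepl("^tone=", p)) {
    lev <- as.integer(sub("tone=", "", p))
    return(as.numeric(!is.null(t$tones) && t$tones[1] == lev))
  }
  if (p == "tone_mean") return(if (is.null(t$tones)) 0 else mean(t$tones))
  vpos <- which(inv$sound_class[rows] == "vowel")
  if (!length(vpos)) return(0)
  fv <- rows[vpos[1]]
  if (p == "v1_rounded") return(as.numeric(inv$rounded[fv]))
  if (p == "v1_long") return(as.numeric(inv$long[fv]))
  if (p == "v1_diphthong") return(as.numeric(inv$diphthong[fv]))
  kv <- strsplit(p, "=", fixed = TRUE)[[1]]
  as.numeric(inv[[kv[1]]][fv] == kv[2])
}

oracle_feature_vector <- function(t, schema, inv) {
  syl <- syllabify(t, inv)
  k1 <- length(syl[[1]]$onset) + length(syl[[1]]$nucleus) +
    length(syl[[1]]$coda)
  vals <- vapply(seq_len(nrow(schema)), function(i)
    oracle_feature(t, schema[i, ], inv, first_syl_len = k1), numeric(1))
  names(vals) <- schema$name
  vals
}

# All ways to cut a phoneme sequence into legal syllables (each a C*VC*
# span whose onset is empty, a single consonant, or a listed cluster);
# used to check the maximal-onset segmentation exhaustively.
oracle_segmentations <- function(symbols, inv, onsets) {
  n <- length(symbols)
  is_v <- inv$sound_class[match(symbols, inv$symbol)] == "vowel"
  legal_syllable <- function(span) {
    v <- is_v[span]
    if (sum(v) != 1) return(FALSE)
    on <- span[seq_len(which(v) - 1)]
    length(on) <= 1 ||
      paste(symbols[on], collapse = " ") %in% onsets
  }
  res <- list()
  recurse <- function(start, acc) {
    if (start > n) { res[[length(res) + 1]] <<- acc; return(invisible()) }
    for (end in start:n) {
      if (legal_syllable(start:end)) recurse(end + 1, c(acc, end))
    }
  }
  recurse(1, integer(0))
  res
}

# A random word drawn symbol-by-symbol (not via the package generator):
# guarantees at least one vowel; Chinese words get a tone per syllable by
# construction of the dialect, so zh words are built as CV(C) syllables.
random_transcription <- function(language, inv, max_len = 7) {
  vows <- inv$symbol[inv$sound_class == "vowel"]
  cons <- inv$symbol[inv$sound_class == "consonant"]
  if (language == "zh") {
    k <- sample(1:3, 1)
    syl <- replicate(k, {
      paste(c(if (runif(1) < 0.8) sample(cons, 1),
              sample(vows, 1),
              if (runif(1) < 0.4) sample(c("n", "N"), 1),
              sample(1:5, 1)), collapse = " ")
    })
    return(paste(syl, collapse = " "))
  }
  len <- sample(2:max_len, 1)
  syms <- sample(c(vows, cons), len, replace = TRUE)
  if (!any(syms %in% vows)) syms[sample(len, 1)] <- sample(vows, 1)
  paste(syms, collapse = " ")
}

# A small feature table with a known structure, for classifier tests that
# do not need real phonology.
toy_feature_table <- function(n, seed, p_noise = 5) {
  set.seed(seed)
  valence <- runif(n, 1, 9)
  tab <- tibble::tibble(word = sprintf("t%05d", seq_len(n)),
                        language = "en", valence = valence)
  for (j in seq_len(p_noise)) tab[[paste0("noise", j)]] <- rnorm(n)
  tab
}
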