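---
title: "Phonological cues to lexical valence: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phonological cues to lexical valence: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonovalence)
```

## The scientific question

Sound symbolism is the hypothesis that a word's sound carries a
non-arbitrary trace of its meaning. One testable version: phonological
features of a word — for instance whether it begins with a nasal
consonant — predict its emotional valence (how positive or negative the
word feels, conventionally rated 1–9) slightly but reliably, and the
direction of the association can differ between languages. `phonovalence`
implements both halves of that research program as a reusable pipeline:

1. a **corpus study** — encode every word of a valence-normed lexicon as a
   vector of phonological features, classify the valence extremes with a
   cross-validated linear SVM, and scan each feature for a valence
   association, intersecting the significant predictors across languages;
2. an **experimental analysis** — by-item 2 (native language) × 2
   (nasal-first) ANOVA of binary valence judgments with partial
   eta-squared, point-biserial correlations, and descriptive summaries.

The lexical resources such studies draw on (valence norms, pronunciation
databases) are licensed and cannot ship with a package, so a third
component generates synthetic lexicons and synthetic rating experiments
with the statistical structure the analyses assume. Everything downstream
is exercised against data whose ground truth is known.

## Phonological substrate

Each language (`en`, `nl`, `de`, `zh`) has a compact research inventory of
25–45 segments annotated with sound class, manner, place, voicing, and for
vowels height, backness, rounding, length and diphthong status. These are
editable TSVs under `inst/extdata/`, deliberately minimal: the feature
schema reads only class memberships, so an exhaustive phonology would add
nothing. Diagnostic asymmetries are respected — dental fricatives only in
English, a trill and a uvular in Dutch and German, tone only in Chinese,
and no close-mid/open-mid or near-front/near-back vowel distinctions in
Chinese.

Transcriptions use two dialects:

* a **neutral whitespace-separated symbol dialect** (`parse_transcription()`),
  replacing licensed database encodings. For Chinese, bare digit tokens
  `1`–`5` close each syllable and record its tone, so Chinese words are
  fully syllabified and toned by construction and render/reparse
  round-trips exactly;
* **strict numeric-tone Pinyin** (`parse_pinyin()`): each syllable is a
  standard initial+final spelling with a mandatory trailing tone digit
  (5 = neutral tone). Diacritic tones are rejected — the numeric form is
  unambiguous to parse. Zero-initial `y-`/`w-` spellings are rewritten to
  their medial forms and `u` after `j/q/x` denotes the front rounded vowel.

Unboundaried words are syllabified by **maximal onset**: every vowel is a
nucleus, and each intervocalic cluster is split so the following syllable
receives the longest suffix that is a legal onset (any single consonant, or
a cluster listed per language in `legal_onsets.tsv`). Pronunciation
databases ship proprietary syllable boundaries we cannot redistribute and
published studies rarely state their syllabifier; maximal onset is the
standard default and is stated here as ours. Ties are impossible by
construction (candidate onsets of different lengths are ordered). A
vowel-free transcription is an error, and the segmentation always
concatenates back to the input — both properties are tested on generated
words.

## The feature schema

The master list (`feature_specs()`) has exactly 105 named entries in five
families: word-level class counts (plus total phoneme count), class
proportions, first-syllable class counts, first-consonant indicators, and
first-vowel banks (height, backness, rounding, length, diphthong) plus the
Chinese tone bank (first-syllable tone indicators and mean word tone). The
classes are the manner/place/voicing/vowel-class cross-product. Published
studies of this design describe the families with one example each and
never enumerate the list; ours is therefore a documented reconstruction,
shipped as an editable TSV and constrained to exactly 105 entries, with
per-language subsets (91 en / 95 nl / 95 de / 89 zh) following the stated
phonological asymmetries.

Conventions worth making explicit:

* `nasal_first` is 1 iff the *word-initial phoneme* is a nasal consonant;
  words whose first consonant appears after a vowel score 0. The
  first-consonant family describes the initial phoneme only when it is
  consonantal.
* Vowel-initial words set every first-consonant indicator to 0 rather than
  missing, keeping feature vectors dense and classifiers well defined.
* Tone features read the first syllable's tone (indicators) and the mean
  tone over syllables (a level feature); for non-tonal schemas they are
  simply absent.

Every extracted value is checked against an independent brute-force
re-scan of the phoneme sequence, per predicate, on 1,000 random words per
language.

## Corpus study

`select_extremes()` implements the extreme-group design: words at or below
the bottom-q valence quantile are negative, at or above the top-q positive
(default q = 0.2), the middle discarded. Boundaries are closed, so ties
are all included and the rule is order-invariant; a near-constant valence
column (coinciding quantiles) is an error, not a silent empty set.

`train_evaluate()` uses a stratified 70/30 split. Ten-fold
cross-validation lives *inside* the training portion as an overfitting
check; the headline number is the holdout accuracy on the untouched 30%.
Features are standardized with training-portion statistics only. The
classifier contract is pluggable; shipped are `svm_linear` and a
`majority` baseline.

**Regularization.** The SVM cost defaults to 0.01, not 1. With ~90–95
standardized, highly collinear features, roughly 1,400 training rows and a
single weak generative signal, a linear SVM at cost 1 fits noise
directions and its holdout accuracy collapses to chance (ordinary logistic
regression behaves the same); the one informative indicator alone
classifies at ~55%. At cost 0.01 the fit stays margin-dominated, holdout
accuracy sits in the low-to-mid 50s under the reference conditions, and
label-permuted accuracy remains at chance. The cost is an explicit
argument for users who want the textbook default.

`feature_scan()` runs on the full lexicon, not the extremes: each feature
is dichotomized at presence (> 0) and mean valence compared between
with/without groups using the pooled-variance Student t with
`df = n_with + n_without − 2` (this df convention matches how such scans
are conventionally reported against full lexicon sizes). Welch's t is
available behind a flag. No multiple-testing correction is applied by
default — intersections are reported at raw alpha, as is conventional for
this design — but Benjamini–Hochberg is available via `adjust = "BH"`.
Constant features are flagged untestable and excluded from intersections
rather than erroring. `shared_predictors()` reports every Venn region of
the per-language significant sets and, for the all-language core, the
per-language direction, since the interesting outcome is precisely a
shared cue with opposite signs (nasal-first: positive in Chinese, negative
in the European languages).

## Experimental analysis

The experiments being emulated present written words to Chinese and Dutch
participants who judge each word positive or negative under a response
deadline. The unit of analysis is the *item*: `item_means()` collapses
trials to one mean rating per (item, rating group) on the 1–2 coding,
dropping missing responses within item and excluding (with a logged count)
items that lose all responses. With 200 items in a 2 × 2 design the
between-items ANOVA has 196 error degrees of freedom, which is the
published signature of this analysis. Response coding stays {1, 2} as in
the source figures; F statistics are invariant to the shift, which is
tested.

`two_way_anova()` fits rating ~ language * nasal and uses **Type-II sums
of squares** (via `car::Anova`) — the standard choice for unbalanced
factorials when no interaction-conditional main-effect test is wanted —
and reports partial eta-squared per term, `F·df1 / (F·df1 + df2)`, an
identity verified on every result. A by-participant analysis can be run by
passing participant means instead; the by-item path is the reference.

`point_biserial()` is the Pearson correlation of item mean ratings with
the binary nasal-first flag within one rating group. `union_probability()`
is the inclusion–exclusion illustration: two independent 55%-accurate cues
jointly reach 0.7975 ≈ 80%.

## Synthetic data: what it emulates and what it does not

`generate_lexicon()` samples phonotactically legal words — onsets from the
legal-onset pool (empty onsets included), vowel nuclei, optional codas;
1–4 syllables with mean just above 2; Chinese syllables carry tones — then
forces a nasal-initial first phoneme at rate 0.25 and draws valence as
`mu + beta·nasal_first + N(0, sigma)` clipped to [1, 9]. Defaults: mu = 5,
sigma = 1.3, |beta| = 0.3. The reference study conditions used throughout
the tests are n = 5,000 words, sigma = 1.5 and beta = +0.3 (zh) / −0.3
(nl, en, de), which places group means ≈ 0.2 SD apart — the regime in
which holdout accuracies land in the low-to-mid 50s.

`generate_responses()` draws binary judgments with
`P(positive) = plogis(alpha_g + s_g·gamma·nasal + u_participant + u_item)`,
`s_zh = +1`, `s_nl = −1`, additive Gaussian random effects on the log-odds
scale, joint response/RT missingness, and lognormal RTs (defaults give
mean ≈ 760 ms, SD ≈ 270 ms, missingness 0.7%). The default crossover
magnitude gamma = 1.39 separates nasal-first from other items by ≈ 0.3 on
the 1–2 mean-rating scale within each group. Group baselines default to
`0.43 ∓ gamma/2`: with equal baselines this parameterization would
manufacture a language main effect whenever gamma ≠ 0, whereas the pattern
being emulated is a pure crossover — both groups ≈ 60% positive, the
interaction carrying essentially all the structure. At gamma = 0 the
groups are identical, which is what the type-I calibration requires.

What the generator does *not* emulate: word frequency effects, morphology,
semantic neighborhoods, translation equivalence across the four lexicons,
participant-level response biases beyond a scalar random effect, and any
dependence of RT on difficulty. Passing tests therefore demonstrate that
the pipeline recovers the structure it assumes, at realistic sizes and
noise levels — not that real lexicons contain that structure, and not the
published real-data accuracy values, which require the licensed resources.

## Calibration results the tests compute

* label-permuted classification: mean holdout accuracy over 100 runs on a
  fixed 2,000-word lexicon stays within [0.48, 0.52];
* signal recovery: at the reference conditions the t-scan recovers the
  generated sign of the nasal-first effect in ≥ 95 of 100 seeded lexicons,
  holdout accuracy exceeds the permutation band, and the four-language
  intersection places `nasal_first` in the all-language Venn cell with the
  (+, −, −, −) direction pattern;
* ANOVA size and power: with gamma = 0 the interaction rejects at the
  nominal 4–6% over 2,000 simulated experiments; at the default crossover
  magnitude power exceeds 80% (in practice ≈ 100%) and every detection has
  the generated direction;
* determinism: identical seeds give byte-identical lexicons, splits and
  response tables.

Problem sizes used by the test suite (1,000 words per language for the
feature oracle, 100 permutation runs, 100 recovery seeds, 2,000 null
ANOVA simulations, 200 power simulations) are the sizes at which the
binomial/normal error of each calibration quantity is comfortably inside
the asserted band.

## Known limitations

* The 105-entry schema is a principled reconstruction, not a recovered
  artifact; feature-level conclusions transfer only to the extent the
  families are faithful.
* Compact inventories collapse some allophony (e.g. a single rhotic per
  language) and ignore stress entirely.
* The Pinyin dialect accepts only numeric tones and the bundled
  initial/final tables (standard Mandarin); erhua and syllabic nasals are
  out of scope.
* The pooled t-scan treats words as exchangeable; no frequency weighting
  or phonological neighborhood control is attempted.
* Mixed-effects models are deliberately absent: the reference analyses
  are by-item, and the generator's random-effect structure exists to
  stress the by-item path, not to be recovered.
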