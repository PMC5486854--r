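#' Per-feature valence scan
#'
#' For every feature in the schema, dichotomizes the lexicon at feature
#' presence (`value > 0`) and tests mean valence with-feature against
#' without-feature. The reference test is the pooled-variance two-sample
#' Student t with `df = n_with + n_without - 2`, run on the full lexicon
#' (not the extremes). Features constant across the lexicon (an empty
#' group) are flagged untestable and excluded from intersections.
#'
#' @param features a [feature_matrix()].
#' @param schema optional schema (defaults to the lexicon language's).
#' @param welch use Welch's t instead of the pooled test.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching raw-alpha reporting; `"BH"` available).
#' @return tibble of feature effects: `feature`, `n_with`, `n_without`,
#'   `mean_with`, `mean_without`, `t`, `df`, `p`, `p_adj`, `direction`
#'   (sign of mean difference), `testable`.
#' @export
feature_scan <- function(features, schema = NULL, welch = FALSE,
                         adjust = "none") {
  language <- unique(features$language)
  stopifnot(length(language) == 1L)
  if (is.null(schema)) schema <- build_schema(language)
  v <- features$valence
  n <- length(v)
  out <- lapply(schema$name, function(f) {
    with_f <- features[[f]] > 0
    n1 <- sum(with_f); n0 <- n - n1
    if (n1 < 2 || n0 < 2) {
      return(tibble::tibble(feature = f, n_with = n1, n_without = n0,
                            mean_with = NA_real_, mean_without = NA_real_,
                            t = NA_real_, df = NA_real_, p = NA_real_,
                            direction = NA_integer_, testable = FALSE))
    }
    x1 <- v[with_f]; x0 <- v[!with_f]
    m1 <- mean(x1); m0 <- mean(x0)
    if (welch) {
      se2 <- stats::var(x1) / n1 + stats::var(x0) / n0
      df <- se2^2 / ((stats::var(x1) / n1)^2 / (n1 - 1) +
                       (stats::var(x0) / n0)^2 / (n0 - 1))
      tstat <- (m1 - m0) / sqrt(se2)
    } else {
      sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) /
        (n1 + n0 - 2)
      df <- n1 + n0 - 2
      tstat <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    }
    p <- 2 * stats::pt(-abs(tstat), df)
    tibble::tibble(feature = f, n_with = n1, n_without = n0,
                   mean_with = m1, mean_without = m0,
                   t = tstat, df = df, p = p,
                   direction = as.integer(sign(m1 - m0)), testable = TRUE)
  })
  out <- dplyr::bind_rows(out)
  out$p_adj <- NA_real_
  out$p_adj[out$testable] <- stats::p.adjust(out$p[out$testable],
                                             method = adjust)
  out
}

#' Cross-language intersection of significant valence predictors
#'
#' Given per-language feature scans, finds for each language the set of
#' testable features with `p_adj < alpha` and reports every region of the
#' resulting Venn diagram. For the all-language core — the features
#' significant in every language — the per-language direction of the
#' effect is reported, since a shared cue may flip sign between languages
#' (nasal-first words trend positive in Chinese but negative in the
#' European languages).
#'
#' @param scans named list (language -> [feature_scan()] tibble), at least
#'   two languages.
#' @param alpha significance threshold on the (adjusted) p value.
#' @return a `shared_predictors` list: `cells` (tibble `languages`,
#'   `feature`, one row per feature in its exact Venn region), `core`
#'   (tibble `feature` plus one `direction_<lang>` column per language)
#'   and `significant` (the per-language sets).
#' @export
shared_predictors <- function(scans, alpha = 0.05) {
  if (length(scans) < 2 || is.null(names(scans)) || any(names(scans) == "")) {
    stop("scans must be a named list of at least two per-language scans")
  }
  stopifnot(alpha >= 0, alpha <= 1)
  if (any(vapply(scans, nrow, integer(1)) == 0)) stop("empty feature scan")
  langs <- names(scans)
  sig <- lapply(scans, function(s)
    s$feature[s$testable & !is.na(s$p_adj) & s$p_adj < alpha])
  all_feats <- unique(unlist(sig))
  if (length(all_feats)) {
    membership <- vapply(sig, function(s) all_feats %in% s,
                         logical(length(all_feats)))
    membership <- matrix(membership, nrow = length(all_feats),
                         dimnames = list(NULL, langs))
    region <- apply(membership, 1, function(m)
      paste(langs[m], collapse = "+"))
    cells <- tibble::tibble(languages = region, feature = all_feats)
    cells <- cells[order(cells$languages, cells$feature), ]
    core_feats <- all_feats[rowSums(membership) == length(langs)]
  } else {
    cells <- tibble::tibble(languages = character(0), feature = character(0))
    core_feats <- character(0)
  }
  core <- tibble::tibble(feature = core_feats)
  for (lg in langs) {
    s <- scans[[lg]]
    core[[paste0("direction_", lg)]] <-
      s$direction[match(core_feats, s$feature)]
  }
  structure(list(cells = cells, core = core, significant = sig,
                 alpha = alpha),
            class = "shared_predictors")
}

#' @export
print.shared_predictors <- function(x, ...) {
  cat("<shared_predictors> alpha =", x$alpha, "\n")
  counts <- table(x$cells$languages)
  for (r in names(counts)) cat("  ", r, ": ", counts[[r]], " feature(s)\n",
                               sep = "")
  if (nrow(x$core)) {
    cat("  shared by all languages:\n")
    print(x$core)
  } else {
    cat("  no feature significant in every language\n")
  }
  invisible(x)
}
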