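#' Summarize responses per item
#'
#' Collapses a trial-level response table to the by-item unit of analysis:
#' one row per (item, rating group) with the mean rating on the 1--2 coding
#' (1 = negative, 2 = positive), the number of answered trials and the
#' missing fraction. Missing responses are dropped within item; items that
#' lose all responses are excluded and their count reported via a message.
#'
#' @param responses tibble with columns `participant_id`,
#'   `native_language`, `item_id`, `nasal_first`, `response` (1/2 or `NA`),
#'   `rt_ms`.
#' @return tibble: `item_id`, `native_language`, `nasal_first`,
#'   `mean_rating`, `n_responses`, `missing_fraction`.
#' @export
item_means <- function(responses) {
  if (nrow(responses) == 0) stop("empty response table")
  out <- responses |>
    dplyr::group_by(.data$item_id, .data$native_language) |>
    dplyr::summarise(
      nasal_first = .data$nasal_first[1],
      mean_rating = mean(.data$response, na.rm = TRUE),
      n_responses = sum(!is.na(.data$response)),
      missing_fraction = mean(is.na(.data$response)),
      .groups = "drop")
  empty <- out$n_responses == 0
  if (any(empty)) {
    message(sum(empty), " item(s) with no responses excluded")
    out <- out[!empty, ]
  }
  out
}

#' By-item two-way ANOVA of mean ratings
#'
#' The reference analysis of the rating experiments: a between-items
#' 2 (rating group's native language) x 2 (nasal-first) ANOVA on item mean
#' ratings, with Type-II sums of squares for unbalanced cell counts and
#' partial eta-squared per term, `eta_p2 = F * df1 / (F * df1 + df2)`.
#'
#' @param items an [item_means()] table; all four design cells must be
#'   non-empty.
#' @return tibble with one row per term (`language`, `nasal_first`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
two_way_anova <- function(items) {
  dat <- data.frame(rating = items$mean_rating,
                    language = factor(items$native_language),
                    nasal = factor(items$nasal_first))
  cells <- table(dat$language, dat$nasal)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: language ", rownames(cells)[bad[1]],
         ", nasal_first ", colnames(cells)[bad[2]])
  }
  fit <- stats::lm(rating ~ language * nasal, data = dat)
  aov2 <- car::Anova(fit, type = 2)
  ss <- aov2[["Sum Sq"]]; df <- aov2[["Df"]]
  rows <- rownames(aov2)
  resid_i <- which(rows == "Residuals")
  term_of <- c("language" = "language", "nasal" = "nasal_first",
               "language:nasal" = "interaction")
  keep <- match(names(term_of), rows)
  f <- aov2[["F value"]][keep]
  tibble::tibble(
    term = unname(term_of),
    F = f,
    df1 = df[keep],
    df2 = df[resid_i],
    p = aov2[["Pr(>F)"]][keep],
    eta_p2 = ss[keep] / (ss[keep] + ss[resid_i]))
}

#' Point-biserial correlation of item ratings with nasal-first
#'
#' Pearson correlation between item mean ratings and the binary
#' nasal-first flag, within one rating group, with a two-sided p value.
#'
#' @param items an [item_means()] table.
#' @param within_language group to correlate within (`"zh"` or `"nl"`, or
#'   any language code present).
#' @return list: `r`, `p`, `n_items`.
#' @export
point_biserial <- function(items, within_language) {
  sub <- items[items$native_language == within_language, ]
  if (nrow(sub) < 3) stop("need at least 3 items in language ", within_language)
  if (length(unique(sub$nasal_first)) < 2) {
    stop("both nasal-first levels must be present in language ",
         within_language)
  }
  ct <- stats::cor.test(sub$mean_rating, sub$nasal_first)
  list(r = unname(ct$estimate), p = ct$p.value, n_items = nrow(sub))
}

#' Probability that at least one of two independent cues predicts correctly
#'
#' Inclusion-exclusion for two independent prediction events:
#' `pA + pB - pA * pB`. With two cues each at 55% accuracy the union
#' reaches 0.7975, i.e. about 80%.
#'
#' @param pA,pB probabilities in \[0, 1\].
#' @return probability in \[0, 1\].
#' @examples
#' union_probability(0.55, 0.55)  # 0.7975
#' @export
union_probability <- function(pA, pB) {
  if (!is.numeric(pA) || !is.numeric(pB) ||
      any(pA < 0 | pA > 1 | pB < 0 | pB > 1)) {
    stop("pA and pB must lie in [0, 1]")
  }
  pA + pB - pA * pB
}

#' Descriptive summary of a rating experiment
#'
#' Per rating group: trial count, missing fraction, the fraction of
#' answered trials judged positive (response = 2; `NA` when a group has no
#' answered trials), and the mean and SD of response time.
#'
#' @param responses a trial-level response table (see [item_means()]).
#' @return tibble: `native_language`, `n_trials`, `missing_fraction`,
#'   `positive_fraction`, `mean_rt_ms`, `sd_rt_ms`.
#' @export
summarize_experiment <- function(responses) {
  responses |>
    dplyr::group_by(.data$native_language) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      missing_fraction = mean(is.na(.data$response)),
      positive_fraction = if (all(is.na(.data$response))) NA_real_
        else mean(.data$response[!is.na(.data$response)] == 2),
      mean_rt_ms = if (all(is.na(.data$rt_ms))) NA_real_
        else mean(.data$rt_ms, na.rm = TRUE),
      sd_rt_ms = if (all(is.na(.data$rt_ms))) NA_real_
        else stats::sd(.data$rt_ms, na.rm = TRUE),
      .groups = "drop")
}
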