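make_responses <- function(item_id, native_language, nasal_first, response,
                           rt = ifelse(is.na(response), NA_real_, 750)) {
  tibble::tibble(
    participant_id = paste0("p", seq_along(response)),
    native_language = native_language,
    item_id = item_id, item_language = native_language,
    nasal_first = nasal_first, response = response, rt_ms = rt)
}

test_that("item means drop missing trials and report the missing fraction", {
  rt <- make_responses("i1", "zh", 1L, c(2L, 2L, 1L, NA))
  im <- item_means(rt)
  expect_equal(im$mean_rating, 5 / 3)
  expect_equal(im$missing_fraction, 0.25)
  expect_equal(im$n_responses, 3)

  rt2 <- dplyr::bind_rows(rt, make_responses("i2", "zh", 0L,
                                             c(NA_integer_, NA_integer_)))
  expect_message(im2 <- item_means(rt2), "1 item")
  expect_equal(im2$item_id, "i1")

  # permutation invariance over rows
  set.seed(601)
  im3 <- item_means(rt[sample(nrow(rt)), ])
  expect_equal(im3, im)
  expect_error(item_means(rt[0, ]), "empty")
})

test_that("the two-way ANOVA reproduces the textbook closed form", {
  # balanced 2x2, two observations per cell, chosen so all sums of squares
  # are integers: cell means 2,4,6,4; SS_lang = 8, SS_nasal = 0,
  # SS_int = 8, SS_resid = 8 on 4 df, hence F = 4, 0, 4 and
  # partial eta^2 = 0.5, 0, 0.5 (hand computation).
  items <- tibble::tibble(
    item_id = paste0("i", 1:8),
    native_language = rep(c("zh", "zh", "nl", "nl"), each = 2),
    nasal_first = rep(c(0L, 1L, 0L, 1L), each = 2),
    mean_rating = c(1, 3, 3, 5, 5, 7, 3, 5),
    n_responses = 10, missing_fraction = 0)
  res <- two_way_anova(items)
  expect_equal(res$F[res$term == "language"], 4)
  expect_equal(res$F[res$term == "nasal_first"], 0)
  expect_equal(res$F[res$term == "interaction"], 4)
  expect_equal(res$df1, c(1, 1, 1))
  expect_equal(res$df2, c(4, 4, 4))
  expect_equal(res$eta_p2, c(0.5, 0, 0.5))
})

test_that("identical cell means with noise give an interaction F of 0", {
  # every cell holds the same multiset {1.2, 1.8} x 5: all four cell means
  # equal 1.5 while within-cell variance is positive
  items <- tibble::tibble(
    item_id = paste0("i", 1:40),
    native_language = rep(c("zh", "nl"), each = 20),
    nasal_first = rep(rep(c(0L, 1L), each = 10), 2),
    mean_rating = rep(c(1.2, 1.8), 20))
  res <- two_way_anova(items)
  expect_lt(res$F[res$term == "interaction"], 1e-10)
})

test_that("a crossover pattern makes the interaction the dominant term", {
  # simulation oracle: item means drawn around the crossover cell pattern
  set.seed(603)
  wins <- 0L
  for (rep_i in 1:200) {
    items <- tibble::tibble(
      item_id = paste0("i", 1:80),
      native_language = rep(c("zh", "nl"), each = 40),
      nasal_first = rep(rep(c(1L, 0L), each = 20), 2),
      mean_rating = rnorm(80, mean = rep(c(1.8, 1.4, 1.4, 1.8), each = 20),
                          sd = 0.1))
    res <- two_way_anova(items)
    fs <- res$F
    if (which.max(fs) == which(res$term == "interaction")) wins <- wins + 1L
  }
  expect_gte(wins, 198)
})

test_that("empty design cells are rejected by name", {
  items <- tibble::tibble(
    item_id = paste0("i", 1:30),
    native_language = c(rep("zh", 20), rep("nl", 10)),
    nasal_first = c(rep(c(0L, 1L), 10), rep(0L, 10)),
    mean_rating = runif(30, 1, 2))
  expect_error(two_way_anova(items), "empty design cell: language nl")
})

test_that("partial eta squared satisfies its defining identity", {
  set.seed(604)
  items <- tibble::tibble(
    item_id = paste0("i", 1:97),   # unbalanced on purpose
    native_language = sample(c("zh", "nl"), 97, TRUE),
    nasal_first = sample(c(0L, 1L), 97, TRUE),
    mean_rating = runif(97, 1, 2))
  res <- two_way_anova(items)
  expect_equal(res$eta_p2, res$F * res$df1 / (res$F * res$df1 + res$df2))
})

test_that("F statistics are invariant to a constant response shift", {
  set.seed(605)
  items <- tibble::tibble(
    item_id = paste0("i", 1:60),
    native_language = rep(c("zh", "nl"), each = 30),
    nasal_first = rep(c(0L, 1L), 30),
    mean_rating = runif(60, 1, 2))
  res1 <- two_way_anova(items)
  items$mean_rating <- items$mean_rating + 7
  res2 <- two_way_anova(items)
  expect_equal(res1$F, res2$F)
  expect_equal(res1$eta_p2, res2$eta_p2)
})

test_that("point-biserial correlation behaves at its limit cases", {
  items <- tibble::tibble(
    item_id = paste0("i", 1:20),
    native_language = "zh",
    nasal_first = rep(c(1L, 0L), each = 10),
    mean_rating = rep(c(2, 1), each = 10))
  expect_equal(point_biserial(items, "zh")$r, 1.0)
  flipped <- items
  flipped$mean_rating <- rep(c(1, 2), each = 10)
  expect_equal(point_biserial(flipped, "zh")$r, -1.0)
  one_level <- items; one_level$nasal_first <- 1L
  expect_error(point_biserial(one_level, "zh"), "both nasal-first levels")
  expect_error(point_biserial(items[1:2, ], "zh"), "at least 3")
})

test_that("permuting nasal labels centres the correlation at zero", {
  set.seed(606)
  items <- tibble::tibble(
    item_id = paste0("i", 1:50), native_language = "zh",
    nasal_first = rep(c(1L, 0L), 25),
    mean_rating = runif(50, 1, 2))
  rs <- replicate(500, {
    perm <- items
    perm$nasal_first <- sample(perm$nasal_first)
    point_biserial(perm, "zh")$r
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("union probability follows inclusion-exclusion exactly", {
  expect_equal(union_probability(0.55, 0.55), 0.7975)
  expect_equal(union_probability(0.3, 0.4), 0.58)
  expect_equal(union_probability(0, 0.37), 0.37)
  expect_equal(union_probability(1, 0.37), 1)
  expect_error(union_probability(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(union_probability(0.5, 1.2), "\\[0, 1\\]")
})

test_that("experiment summaries report missingness, positivity and RT", {
  resp <- make_responses(rep("i1", 1000), "zh", 1L,
                         c(rep(NA_integer_, 7), rep(2L, 601), rep(1L, 392)))
  s <- summarize_experiment(resp)
  expect_equal(s$missing_fraction, 0.007)
  expect_equal(s$positive_fraction, 601 / 993)
  expect_equal(s$mean_rt_ms, 750)
  expect_equal(s$sd_rt_ms, 0)

  allmiss <- make_responses("i1", "nl", 0L, rep(NA_integer_, 5))
  s2 <- summarize_experiment(allmiss)
  expect_true(is.na(s2$positive_fraction))
})
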