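test_that("extreme selection labels the tails and discards the middle", {
  tab <- toy_feature_table(10, seed = 501)
  tab$valence <- 1:10
  ls <- select_extremes(tab, 0.2)
  expect_setequal(ls$valence[ls$label == "negative"], c(1, 2))
  expect_setequal(ls$valence[ls$label == "positive"], c(9, 10))
  expect_equal(attr(ls, "n_discarded"), 6)

  same <- toy_feature_table(20, seed = 502)
  same$valence <- rep(5, 20)
  expect_error(select_extremes(same, 0.2), "coincide")
  expect_error(select_extremes(tab, 0.6), "strictly inside")
  expect_error(select_extremes(tab, 0))
})

test_that("extremes match a sort-based oracle and ignore row order", {
  lex <- generate_lexicon(lexicon_model("en", 5000, seed = 503))
  fm <- feature_matrix(lex)
  ls <- select_extremes(fm, 0.2)
  expect_gte(nrow(ls), 2000)
  expect_gte(min(ls$valence[ls$label == "positive"]),
             max(ls$valence[ls$label == "negative"]))
  # sort-based oracle: the labeled words are exactly those outside the
  # open interval between the two order statistics used as thresholds
  v <- sort(fm$valence)
  lo <- attr(ls, "lo"); hi <- attr(ls, "hi")
  expect_setequal(ls$word, fm$word[fm$valence <= lo | fm$valence >= hi])
  # row-order invariance
  set.seed(504)
  ls2 <- select_extremes(fm[sample(nrow(fm)), ], 0.2)
  expect_setequal(ls2$word, ls$word)
  expect_equal(attr(ls2, "lo"), lo)
})

test_that("a perfectly separating feature yields holdout accuracy 1", {
  tab <- toy_feature_table(200, seed = 505)
  tab$separator <- as.numeric(tab$valence > stats::median(tab$valence))
  ls <- select_extremes(tab, 0.2)
  res <- train_evaluate(ls, folds = 5, seed = 1)
  expect_equal(res$holdout_accuracy, 1.0)
  expect_gte(mean(res$fold_accuracies), 0.9)
})

test_that("permuted labels stay inside the central binomial band", {
  lex <- generate_lexicon(lexicon_model("nl", 2000, beta = 0, seed = 506))
  fm <- feature_matrix(lex)
  ls <- select_extremes(fm, 0.2)
  set.seed(507)
  ls$label <- sample(ls$label)
  res <- train_evaluate(ls, folds = 0, seed = 508)
  n <- res$n_test
  band <- 1.96 * sqrt(0.25 / n)
  expect_gt(res$holdout_accuracy, 0.5 - band)
  expect_lt(res$holdout_accuracy, 0.5 + band)
})

test_that("identical seeds reproduce identical classification results", {
  tab <- toy_feature_table(300, seed = 509)
  tab$weak <- tab$valence / 10 + rnorm(300)
  ls <- select_extremes(tab, 0.2)
  r1 <- train_evaluate(ls, seed = 42)
  r2 <- train_evaluate(ls, seed = 42)
  expect_identical(r1, r2)
  r3 <- train_evaluate(ls, seed = 43)
  expect_false(identical(r1$fold_accuracies, r3$fold_accuracies))
})

test_that("degenerate classifier inputs are rejected", {
  tab <- toy_feature_table(100, seed = 510)
  ls <- select_extremes(tab, 0.2)
  one <- ls[ls$label == "positive", ]
  expect_error(train_evaluate(one, seed = 1), "both valence labels")
  expect_error(train_evaluate(ls[c(1:6, 21:26), ], folds = 20, seed = 1),
               "folds")
})

test_that("the majority baseline predicts the modal training label", {
  tab <- toy_feature_table(200, seed = 511)
  ls <- select_extremes(tab, 0.2)
  res <- train_evaluate(ls, folds = 0, classifier = "majority", seed = 2)
  # balanced extremes: majority baseline cannot beat chance by much
  expect_lt(abs(res$holdout_accuracy - 0.5), 0.15)
})

test_that("the valence scan reproduces the closed-form pooled t", {
  # constructed zero-noise lexicon: nasal-first words valence 8, rest 2
  tab <- toy_feature_table(60, seed = 512)
  tab$nasal_first <- rep(c(1, 0), each = 30)
  tab$valence <- ifelse(tab$nasal_first == 1, 8, 2)
  tab$valence <- tab$valence + rep(c(-0.01, 0.01), 30)  # avoid 0 variance
  tab$language <- "en"
  sch <- tibble::tibble(name = c("nasal_first", "noise1"),
                        family = "first_consonant",
                        predicate = "manner=nasal", statistic = "indicator",
                        languages = "en")
  attr(sch, "language") <- "en"
  class(sch) <- c("feature_schema", class(sch))
  scan <- feature_scan(tab, sch)
  eff <- scan[scan$feature == "nasal_first", ]
  expect_equal(eff$direction, 1L)
  expect_equal(eff$df, 58)
  expect_lt(eff$p, 1e-12)
  # cross-check t against stats::t.test with pooled variance
  ref <- t.test(tab$valence[tab$nasal_first > 0],
                tab$valence[tab$nasal_first == 0], var.equal = TRUE)
  expect_equal(eff$t, unname(ref$statistic))
  expect_equal(eff$p, ref$p.value)
})

test_that("scan t-tests agree with stats::t.test on noisy data, both forms", {
  tab <- toy_feature_table(500, seed = 513)
  tab$flag <- rbinom(500, 1, 0.3)
  for (welch in c(FALSE, TRUE)) {
    sch <- tibble::tibble(name = "flag", family = "first_consonant",
                          predicate = "manner=nasal",
                          statistic = "indicator", languages = "en")
    attr(sch, "language") <- "en"
    scan <- feature_scan(tab, sch, welch = welch)
    ref <- t.test(tab$valence[tab$flag > 0], tab$valence[tab$flag == 0],
                  var.equal = !welch)
    expect_equal(scan$t, unname(ref$statistic))
    expect_equal(scan$df, unname(ref$parameter))
    expect_equal(scan$p, ref$p.value)
  }
})

test_that("constant features are flagged untestable; identical groups give t = 0", {
  tab <- toy_feature_table(50, seed = 514)
  tab$always <- 1
  tab$never <- 0
  sch <- tibble::tibble(name = c("always", "never"),
                        family = "word_count", predicate = "any",
                        statistic = "count", languages = "en")
  attr(sch, "language") <- "en"
  scan <- feature_scan(tab, sch)
  expect_false(any(scan$testable))
  expect_true(all(is.na(scan$p)))

  tab2 <- toy_feature_table(6, seed = 515)
  tab2$valence <- c(5, 6, 7, 5, 6, 7)
  tab2$half <- c(1, 1, 1, 0, 0, 0)
  sch2 <- sch; sch2$name <- c("half", "never")
  scan2 <- feature_scan(tab2, sch2)
  expect_equal(scan2$t[1], 0)
  expect_equal(scan2$direction[1], 0L)
})

test_that("shared predictors land in the correct Venn cells with directions", {
  mk_scan <- function(feats, ps, dirs) tibble::tibble(
    feature = feats, n_with = 50, n_without = 50,
    mean_with = 5, mean_without = 5, t = 0, df = 98,
    p = ps, p_adj = ps, direction = dirs, testable = TRUE)
  scans <- list(
    zh = mk_scan(c("nasal_first", "p_velar"), c(1e-6, 0.001), c(1L, 1L)),
    nl = mk_scan(c("nasal_first", "p_velar"), c(1e-6, 0.8), c(-1L, 1L)),
    en = mk_scan(c("nasal_first", "n_trill"), c(1e-4, 0.01), c(-1L, -1L)),
    de = mk_scan(c("nasal_first", "n_trill"), c(1e-5, 0.2), c(-1L, 1L)))
  rep <- shared_predictors(scans, alpha = 0.05)
  expect_equal(rep$core$feature, "nasal_first")
  expect_equal(rep$core$direction_zh, 1L)
  expect_equal(rep$core$direction_nl, -1L)
  expect_equal(rep$core$direction_en, -1L)
  expect_equal(rep$core$direction_de, -1L)
  expect_true("zh" %in% rep$cells$languages[rep$cells$feature == "p_velar"])
  expect_equal(rep$cells$languages[rep$cells$feature == "n_trill"], "en")

  empty <- shared_predictors(scans, alpha = 0)
  expect_equal(nrow(empty$cells), 0)
  expect_equal(nrow(empty$core), 0)

  disjoint <- shared_predictors(list(
    zh = mk_scan("p_velar", 1e-4, 1L),
    nl = mk_scan("n_trill", 1e-4, 1L)), alpha = 0.05)
  expect_equal(nrow(disjoint$core), 0)
  expect_error(shared_predictors(list(zh = mk_scan("a", 1, 1L))), "at least two")
})
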