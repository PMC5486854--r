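#' Label the valence extremes of a lexicon
#'
#' The extreme-group design of the corpus study: words at or below the
#' bottom `q` valence quantile are labeled `negative`, words at or above
#' the top `q` quantile `positive`, and the neutral middle is discarded.
#' Quantile boundaries are closed, so ties at a boundary are all included
#' and the labeled set can slightly exceed `2 * q * nrow(lexicon)`; the
#' rule is deterministic and invariant to row order.
#'
#' @param features a [feature_matrix()] (or any tibble with `valence` and
#'   feature columns).
#' @param q quantile fraction in (0, 0.5); the study uses 0.2.
#' @return a `labeled_set`: the extreme rows plus a `label` factor
#'   (`negative`/`positive`), with attributes `q`, `lo`, `hi` and
#'   `n_discarded`.
#' @export
select_extremes <- function(features, q = 0.2) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 0.5) {
    stop("q must lie strictly inside (0, 0.5)")
  }
  if (nrow(features) < 10) stop("need at least 10 rows to take extremes")
  v <- features$valence
  lo <- stats::quantile(v, q, names = FALSE)
  hi <- stats::quantile(v, 1 - q, names = FALSE)
  if (lo >= hi) {
    stop("valence quantiles coincide (lo = ", lo, ", hi = ", hi,
         "); extremes are undefined for near-constant valence")
  }
  keep <- v <= lo | v >= hi
  out <- features[keep, ]
  out$label <- factor(ifelse(out$valence >= hi, "positive", "negative"),
                      levels = c("negative", "positive"))
  attr(out, "q") <- q
  attr(out, "lo") <- lo
  attr(out, "hi") <- hi
  attr(out, "n_discarded") <- sum(!keep)
  class(out) <- c("labeled_set", class(out))
  out
}

labeled_feature_columns <- function(ls) {
  setdiff(names(ls), c("word", "language", "valence", "label"))
}

standardize_train <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(train = scale(train, center = mu, scale = sd),
       test = scale(test, center = mu, scale = sd))
}

fit_predict <- function(classifier, xtr, ytr, xte, cost = 0.01) {
  if (classifier == "svm_linear") {
    fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
    predict(fit, xte)
  } else if (classifier == "majority") {
    lev <- names(which.max(table(ytr)))
    factor(rep(lev, nrow(xte)), levels = levels(ytr))
  } else {
    stop("unknown classifier: ", classifier)
  }
}

# Stratified fold assignment: within each label, a seeded permutation is
# dealt round-robin across folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train and evaluate a valence classifier
#'
#' The classification protocol of the corpus study: a stratified 70/30
#' split, ten-fold cross-validation inside the training portion as an
#' overfitting check, and a single holdout accuracy on the untouched 30%
#' as the headline number. Features are standardized using training-portion
#' statistics only. Classifiers: `"svm_linear"` (support vector machine,
#' linear kernel) or the `"majority"` baseline.
#'
#' The SVM cost defaults to 0.01 rather than 1: with on the order of 100
#' standardized, highly collinear phonological features and a weak signal,
#' a lightly regularized linear SVM fits noise directions and its holdout
#' accuracy collapses to chance; a small cost keeps the fit in the
#' margin-dominated regime appropriate for this feature-to-sample ratio.
#'
#' @param ls a [select_extremes()] result (both labels present).
#' @param train_fraction fraction of rows used for training (default 0.7).
#' @param folds number of cross-validation folds within the training
#'   portion (default 10); `0` skips cross-validation and reports only the
#'   holdout accuracy.
#' @param classifier `"svm_linear"` or `"majority"`.
#' @param cost SVM regularization constant (ignored by `"majority"`).
#' @param seed integer; the split, folds and fit are deterministic given it.
#' @return a `classification_result` list: `holdout_accuracy`,
#'   `fold_accuracies`, `n_train`, `n_test`, `classifier`, `seed`.
#' @export
train_evaluate <- function(ls, train_fraction = 0.7, folds = 10,
                           classifier = c("svm_linear", "majority"),
                           cost = 0.01, seed) {
  classifier <- match.arg(classifier)
  stopifnot(train_fraction > 0, train_fraction < 1, is.numeric(seed))
  y <- ls$label
  if (nlevels(droplevels(y)) < 2) {
    stop("both valence labels must be present to train a classifier")
  }
  if (folds > 0 && nrow(ls) < folds) {
    stop("fewer rows (", nrow(ls), ") than folds (", folds, ")")
  }
  X <- as.matrix(ls[labeled_feature_columns(ls)])
  set.seed(as.integer(seed))
  train_idx <- unlist(lapply(levels(y), function(lev) {
    idx <- which(y == lev)
    sample(idx, floor(train_fraction * length(idx)))
  }), use.names = FALSE)
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  Xte <- X[-train_idx, , drop = FALSE]; yte <- y[-train_idx]

  fold_acc <- numeric(0)
  if (folds > 0) {
    fold_id <- stratified_folds(ytr, folds)
    fold_acc <- vapply(seq_len(folds), function(k) {
      ink <- fold_id != k
      z <- standardize_train(Xtr[ink, , drop = FALSE],
                             Xtr[!ink, , drop = FALSE])
      mean(fit_predict(classifier, z$train, ytr[ink], z$test, cost) ==
             ytr[!ink])
    }, numeric(1))
  }
  z <- standardize_train(Xtr, Xte)
  holdout <- mean(fit_predict(classifier, z$train, ytr, z$test, cost) == yte)
  structure(list(holdout_accuracy = holdout, fold_accuracies = fold_acc,
                 n_train = length(train_idx), n_test = nrow(Xte),
                 classifier = classifier, seed = as.integer(seed)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>", x$classifier,
      sprintf("| holdout accuracy %.4f (n_test = %d)",
              x$holdout_accuracy, x$n_test), "\n")
  if (length(x$fold_accuracies)) {
    cat(sprintf("  %d-fold CV accuracy (training portion): mean %.4f\n",
                length(x$fold_accuracies), mean(x$fold_accuracies)))
  }
  invisible(x)
}
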