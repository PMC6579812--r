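#' @title Score fusion with classical classifiers
#' @description Merges the DL score into tabular functional/conservation
#'   feature tables and runs the classical-classifier stage: random
#'   forest, gradient boosted trees and SVM training with a stratified
#'   holdout, tree-ensemble feature importance, recursive feature
#'   elimination and Spearman rank correlation of the selected features.
#' @name fusion
NULL

#' The shipped feature-selection profiles
#'
#' `top8` is the 8-feature reduced set (ensemble scores, DL score and five
#' conservation scores); `top3` keeps only the two ensemble scores and the
#' DL score.
#' @export
FEATURE_PROFILES <- list(
  top8 = c("RadialSVM", "LR", "DL_score", "GerpRS", "LRT", "verPhyloP",
           "SiPhy", "GerpN"),
  top3 = c("RadialSVM", "LR", "DL_score")
)

#' Read a feature table from TSV
#'
#' @param path TSV with a header; one key column, one label column, the
#'   rest numeric features. Missing values may be encoded as `NA` or `.`.
#' @param key column name holding the unique variant key (default
#'   `"key"`).
#' @param label column name holding the class label (default `"label"`);
#'   values are case-normalized to driver/passenger.
#' @return a data.frame with `key`, `label` and numeric feature columns.
#' @export
read_feature_table <- function(path, key = "key", label = "label") {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  if (!key %in% names(df)) stop("key column '", key, "' missing")
  if (!label %in% names(df)) stop("label column '", label, "' missing")
  if (anyDuplicated(df[[key]])) {
    stop("duplicated variant key(s): ",
         paste(utils::head(unique(df[[key]][duplicated(df[[key]])])), collapse = ", "))
  }
  feats <- setdiff(names(df), c(key, label))
  for (f in feats) {
    if (!is.numeric(df[[f]])) {
      bad <- which(!is.na(df[[f]]) & is.na(suppressWarnings(as.numeric(df[[f]]))))
      if (length(bad) > 0L) {
        stop("non-numeric value in feature '", f, "' at data row ", bad[1])
      }
      df[[f]] <- as.numeric(df[[f]])
    }
  }
  df[[label]] <- normalize_label(df[[label]])
  names(df)[names(df) == key] <- "key"
  names(df)[names(df) == label] <- "label"
  df
}

#' Attach DL scores to a feature table
#'
#' @param table a feature table (data.frame with `key` column).
#' @param scores a `dl_score_table` from [compute_dl_scores()] (or any
#'   data.frame with `key` and `dl_score`).
#' @param join `"inner"` (keep matched keys only) or `"left"` (keep all
#'   table rows; unmatched get `NA`).
#' @return the table with a new `DL_score` column.
#' @export
attach_dl_score <- function(table, scores, join = c("inner", "left")) {
  join <- match.arg(join)
  stopifnot("key" %in% names(table), all(c("key", "dl_score") %in% names(scores)))
  idx <- match(table$key, scores$key)
  n_match <- sum(!is.na(idx))
  if (n_match == 0L) stop("no overlap between table keys and score keys")
  out <- table
  out$DL_score <- scores$dl_score[idx]
  if (join == "inner") out <- out[!is.na(idx), , drop = FALSE]
  message(sprintf("attach_dl_score: %d/%d keys matched (%s join)",
                  n_match, nrow(table), join))
  out
}

feature_columns <- function(table, features = NULL) {
  cand <- setdiff(names(table), c("key", "label"))
  if (is.null(features)) return(cand)
  miss <- setdiff(features, cand)
  if (length(miss) > 0L) stop("feature(s) not in table: ", paste(miss, collapse = ", "))
  features
}

# median imputation fitted on the training rows only
impute_median <- function(x_train, x_other = NULL) {
  med <- vapply(x_train, function(col) stats::median(col, na.rm = TRUE), numeric(1))
  med[is.na(med)] <- 0
  fill <- function(df) {
    for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- med[j]
    df
  }
  list(train = fill(x_train), other = if (!is.null(x_other)) fill(x_other))
}

#' Train a classical classifier on a feature table
#'
#' Splits 80/20 stratified (seeded, so holdout membership is identical
#' across algorithms under the same seed), median-imputes missing values
#' using training-split medians, fits the requested model and evaluates
#' on the holdout.
#'
#' @param table feature table with `label` column.
#' @param algorithm `"random_forest"`, `"gradient_boosted_trees"` or
#'   `"svm"` (RBF kernel with probability output; features standardized
#'   for SVM only).
#' @param features optional character vector restricting the feature set
#'   (e.g. `FEATURE_PROFILES$top8`).
#' @param holdout stratified holdout fraction (default 0.2).
#' @param seed RNG seed (default 1).
#' @param ntree forest size / boosting rounds (default 300 / 200).
#' @return an object of class `classifier_fit`: `model`, `algorithm`,
#'   `features`, `report` (a [classification_report()] with AUC on the
#'   holdout), `holdout` (logical vector), `scores` (holdout driver
#'   probabilities).
#' @export
train_classifier <- function(table,
                             algorithm = c("random_forest",
                                           "gradient_boosted_trees", "svm"),
                             features = NULL, holdout = 0.2, seed = 1L,
                             ntree = NULL) {
  algorithm <- match.arg(algorithm)
  y <- as_binary_label(table$label)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  feats <- feature_columns(table, features)
  X <- table[, feats, drop = FALSE]
  hold <- stratified_holdout(y, holdout, seed)
  imp <- impute_median(X[!hold, , drop = FALSE], X[hold, , drop = FALSE])
  x_tr <- imp$train; x_te <- imp$other
  y_tr <- y[!hold]; y_te <- y[hold]
  # zero-variance training columns carry no information and can break the
  # fitters; drop them, and with nothing left fall back to the
  # no-information probability 1/2 (so AUC is 0.5 by the tie convention)
  informative <- vapply(x_tr, function(col) stats::sd(col) > 0, logical(1))
  if (!all(informative)) {
    message("train_classifier: dropping zero-variance feature(s): ",
            paste(feats[!informative], collapse = ", "))
    x_tr <- x_tr[, informative, drop = FALSE]
    x_te <- x_te[, informative, drop = FALSE]
  }
  if (ncol(x_tr) == 0L) {
    p_te <- rep(0.5, sum(hold))
    cc <- confusion(y_te, as.integer(p_te >= 0.5))
    report <- classification_report(cc, labels = y_te, scores = p_te)
    return(structure(
      list(model = NULL, algorithm = algorithm, features = character(0),
           report = report, holdout = hold, scores = p_te, seed = seed),
      class = "classifier_fit"))
  }
  feats <- feats[informative]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (algorithm == "random_forest") {
    model <- randomForest::randomForest(
      x = x_tr, y = factor(y_tr, levels = c(0, 1)),
      ntree = if (is.null(ntree)) 300L else ntree)
    p_te <- stats::predict(model, x_te, type = "prob")[, "1"]
  } else if (algorithm == "gradient_boosted_trees") {
    dtr <- xgboost::xgb.DMatrix(as.matrix(x_tr), label = y_tr)
    model <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 4,
                    eta = 0.1, nthread = 1),
      data = dtr, nrounds = if (is.null(ntree)) 200L else ntree, verbose = 0)
    p_te <- stats::predict(model, as.matrix(x_te))
  } else {
    mu <- vapply(x_tr, mean, numeric(1))
    sg <- vapply(x_tr, stats::sd, numeric(1)); sg[sg == 0 | is.na(sg)] <- 1
    scale_df <- function(df) as.data.frame(scale(df, center = mu, scale = sg))
    model <- e1071::svm(x = scale_df(x_tr), y = factor(y_tr, levels = c(0, 1)),
                        kernel = "radial", probability = TRUE)
    pr <- stats::predict(model, scale_df(x_te), probability = TRUE)
    p_te <- attr(pr, "probabilities")[, "1"]
    attr(model, "scaling") <- list(mu = mu, sg = sg)
  }
  cc <- confusion(y_te, as.integer(p_te >= 0.5))
  report <- classification_report(cc, labels = y_te, scores = p_te)
  structure(
    list(model = model, algorithm = algorithm, features = feats,
         report = report, holdout = hold, scores = p_te, seed = seed),
    class = "classifier_fit"
  )
}

#' @export
print.classifier_fit <- function(x, ...) {
  cat(sprintf("%s on %d features; holdout performance:\n",
              x$algorithm, length(x$features)))
  print(x$report)
  invisible(x)
}

#' Normalized feature importance of a tree-ensemble fit
#'
#' Impurity-decrease importances (mean decrease in Gini for the random
#' forest, total gain for the boosted trees), normalized to sum to 1.
#' SVMs have no per-feature importance here and raise an error; see
#' [woe_iv_report()] for the model-free information-value alternative.
#'
#' @param fit a `classifier_fit`.
#' @return a data.frame with `feature` and `importance`, sorted
#'   decreasing.
#' @export
feature_importance <- function(fit) {
  stopifnot(inherits(fit, "classifier_fit"))
  if (fit$algorithm == "svm") {
    stop("feature importance is defined for tree ensembles only")
  }
  if (fit$algorithm == "random_forest") {
    imp <- randomForest::importance(fit$model)[, 1]
    imp <- stats::setNames(as.numeric(imp), rownames(randomForest::importance(fit$model)))
  } else {
    tab <- xgboost::xgb.importance(model = fit$model)
    imp <- stats::setNames(rep(0, length(fit$features)), fit$features)
    imp[tab$Feature] <- tab$Gain
  }
  imp <- pmax(imp, 0)
  full <- stats::setNames(rep(0, length(fit$features)), fit$features)
  full[names(imp)] <- imp
  if (sum(full) > 0) full <- full / sum(full)
  out <- data.frame(feature = names(full), importance = as.numeric(full),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Recursive feature elimination
#'
#' Repeatedly fits the tree-ensemble classifier and drops the
#' lowest-importance feature until `k` remain. The full elimination order
#' is returned; the procedure is deterministic under the seed.
#'
#' @param table feature table.
#' @param algorithm `"random_forest"` or `"gradient_boosted_trees"`.
#' @param k target number of retained features.
#' @param features starting feature set (default: all).
#' @param seed,holdout forwarded to [train_classifier()].
#' @return a list with `retained` (character vector of k features) and
#'   `eliminated` (features in elimination order, first dropped first).
#' @export
recursive_feature_elimination <- function(table,
                                          algorithm = c("random_forest",
                                                        "gradient_boosted_trees"),
                                          k, features = NULL, seed = 1L,
                                          holdout = 0.2) {
  algorithm <- match.arg(algorithm)
  current <- feature_columns(table, features)
  if (k < 1L || k > length(current)) {
    stop("k must be between 1 and the number of features (", length(current), ")")
  }
  eliminated <- character(0)
  while (length(current) > k) {
    fit <- train_classifier(table, algorithm, features = current,
                            holdout = holdout, seed = seed)
    imp <- feature_importance(fit)
    worst <- imp$feature[nrow(imp)]
    eliminated <- c(eliminated, worst)
    current <- setdiff(current, worst)
  }
  list(retained = current, eliminated = eliminated)
}

#' Spearman rank correlation matrix of selected features
#'
#' Average-rank tie handling, pairwise-complete observations. A
#' zero-variance column yields `NA` coefficients with a warning.
#'
#' @param table feature table.
#' @param features feature names (default: all).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, features = NULL) {
  feats <- feature_columns(table, features)
  X <- table[, feats, drop = FALSE]
  if (nrow(X) < 2L) stop("need at least 2 rows")
  const <- vapply(X, function(col) stats::sd(col, na.rm = TRUE) == 0 ||
                    all(is.na(col)), logical(1))
  if (any(const)) {
    warning("zero-variance column(s), coefficients undefined: ",
            paste(feats[const], collapse = ", "))
  }
  M <- suppressWarnings(
    stats::cor(X, method = "spearman", use = "pairwise.complete.obs"))
  diag(M) <- ifelse(const, NA_real_, 1)
  M
}

#' Information value / weight-of-evidence feature report
#'
#' A model-free importance criterion: each feature is binned at training
#' deciles and the information value
#' IV = sum over bins of (pct_driver - pct_passenger) * WoE, with
#' WoE = log(pct_driver / pct_passenger), is reported. Zero cells are
#' Laplace-smoothed.
#'
#' @param table feature table with `label`.
#' @param features feature names (default: all).
#' @param bins number of quantile bins (default 10).
#' @return data.frame with `feature` and `iv`, sorted decreasing.
#' @export
woe_iv_report <- function(table, features = NULL, bins = 10L) {
  feats <- feature_columns(table, features)
  y <- as_binary_label(table$label)
  iv1 <- function(x) {
    ok <- !is.na(x)
    qs <- unique(stats::quantile(x[ok], probs = seq(0, 1, length.out = bins + 1)))
    if (length(qs) < 2L) return(0)
    b <- cut(x[ok], qs, include.lowest = TRUE)
    tab <- base::table(b, factor(y[ok], levels = c(0, 1)))
    g <- (tab[, "1"] + 0.5) / (sum(tab[, "1"]) + 0.5 * nrow(tab))
    p <- (tab[, "0"] + 0.5) / (sum(tab[, "0"]) + 0.5 * nrow(tab))
    sum((g - p) * log(g / p))
  }
  out <- data.frame(feature = feats,
                    iv = vapply(table[, feats, drop = FALSE], iv1, numeric(1)),
                    stringsAsFactors = FALSE)
  out[order(-out$iv), , drop = FALSE]
}
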