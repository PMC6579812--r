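# class-conditional Gaussian fixture table: k_sig separated features,
# k_noise pure-noise features
gauss_table <- function(n = 2000, k_sig = 2, k_noise = 5, sep = 3, seed = 1,
                        sig_names = NULL) {
  set.seed(seed)
  y <- rbinom(n, 1, 6389 / 19330)
  y[1:2] <- c(0, 1)
  cols <- list()
  if (is.null(sig_names)) sig_names <- paste0("sig", seq_len(k_sig))
  for (i in seq_len(k_sig)) cols[[sig_names[i]]] <- rnorm(n) + sep * y
  for (i in seq_len(k_noise)) cols[[paste0("noise", i)]] <- rnorm(n)
  df <- data.frame(key = paste0("v", seq_len(n)),
                   label = ifelse(y == 1, "driver", "passenger"))
  if (length(cols) > 0) df <- cbind(df, as.data.frame(cols))
  df
}

test_that("read_feature_table types, masks and validates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("key\tlabel\tRadialSVM\tLR",
               "v1\tDriver\t0.5\t1.2",
               "v2\tpassenger\tNA\t0.3",
               "v3\tpassenger\t.\t-0.1",
               "v4\tdriver\t2.2\t0.9",
               "v5\tpassenger\t0.1\t0.2"), path)
  ft <- read_feature_table(path)
  expect_equal(nrow(ft), 5L)
  expect_equal(ft$label[1], "driver")            # case normalized
  expect_true(is.na(ft$RadialSVM[2]) && is.na(ft$RadialSVM[3]))
  writeLines(c("key\tlabel\tX", "v1\tdriver\t1", "v1\tpassenger\t2"), path)
  expect_error(read_feature_table(path), "duplicated")
  writeLines(c("key\tlabel\tX", "v1\tdriver\tabc"), path)
  expect_error(read_feature_table(path), "non-numeric")
})

test_that("attach_dl_score joins on keys with the declared policy", {
  tb <- data.frame(key = c("a", "b", "c"), label = "driver", f = 1:3)
  sc <- data.frame(key = c("a", "b", "c"), dl_score = c(0.1, 0.2, 0.3))
  out <- suppressMessages(attach_dl_score(tb, sc))
  expect_equal(nrow(out), 3L)
  expect_equal(out$DL_score, c(0.1, 0.2, 0.3))
  # partial overlap: inner join shrinks, left join keeps NA
  sc2 <- sc[1:2, ]
  expect_equal(nrow(suppressMessages(attach_dl_score(tb, sc2))), 2L)
  left <- suppressMessages(attach_dl_score(tb, sc2, join = "left"))
  expect_equal(nrow(left), 3L)
  expect_true(is.na(left$DL_score[3]))
  sc3 <- data.frame(key = "zzz", dl_score = 0.5)
  expect_error(suppressMessages(attach_dl_score(tb, sc3)), "overlap")
})

test_that("strongly separated features give high holdout F1 for all algorithms", {
  tb <- gauss_table(n = 2000, sep = 3, seed = 2)
  for (algo in c("random_forest", "gradient_boosted_trees", "svm")) {
    fit <- train_classifier(tb, algo, seed = 7)
    expect_gte(fit$report$f1, 0.9)
    expect_gte(fit$report$auc, 0.95)
  }
})

test_that("holdout membership is identical across algorithms under one seed", {
  tb <- gauss_table(n = 400, seed = 3)
  f1 <- train_classifier(tb, "random_forest", seed = 11)
  f2 <- train_classifier(tb, "svm", seed = 11)
  expect_identical(f1$holdout, f2$holdout)
  f3 <- train_classifier(tb, "random_forest", seed = 12)
  expect_false(identical(f1$holdout, f3$holdout))
})

test_that("permuted labels give chance-level holdout AUC across seeds", {
  aucs <- vapply(1:5, function(s) {
    tb <- gauss_table(n = 600, sep = 3, seed = 20 + s)
    set.seed(s); tb$label <- sample(tb$label)
    train_classifier(tb, "random_forest", seed = s)$report$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("constant features give AUC 0.5 under the tie convention", {
  tb <- gauss_table(n = 200, k_sig = 0, k_noise = 0, seed = 4)
  tb$flat1 <- 1; tb$flat2 <- 2
  fit <- suppressMessages(train_classifier(tb, "random_forest", seed = 5))
  expect_equal(fit$report$auc, 0.5)
})

test_that("feature importance is normalized and finds the planted feature", {
  tb <- gauss_table(n = 2000, k_sig = 1, k_noise = 9, sep = 3, seed = 6)
  for (algo in c("random_forest", "gradient_boosted_trees")) {
    fit <- train_classifier(tb, algo, seed = 8)
    imp <- feature_importance(fit)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
    expect_equal(imp$feature[1], "sig1")
  }
  sfit <- train_classifier(gauss_table(n = 200, seed = 6), "svm", seed = 8)
  expect_error(feature_importance(sfit), "tree ensembles")
})

test_that("duplicated informative columns share the single-column importance", {
  tb1 <- gauss_table(n = 1500, k_sig = 1, k_noise = 6, sep = 2.5, seed = 9)
  imp1 <- feature_importance(train_classifier(tb1, "random_forest", seed = 10))
  single <- imp1$importance[imp1$feature == "sig1"]
  tb2 <- tb1
  tb2$sig1b <- tb1$sig1
  imp2 <- feature_importance(train_classifier(tb2, "random_forest", seed = 10))
  combined <- sum(imp2$importance[imp2$feature %in% c("sig1", "sig1b")])
  expect_lt(abs(combined - single) / single, 0.35)
})

test_that("recursive feature elimination keeps planted informative features", {
  hits <- vapply(1:5, function(s) {
    tb <- gauss_table(n = 800, k_sig = 3, k_noise = 7, sep = 2, seed = 30 + s)
    rfe <- recursive_feature_elimination(tb, "random_forest", k = 3, seed = s)
    all(c("sig1", "sig2", "sig3") %in% rfe$retained)
  }, logical(1))
  expect_gte(sum(hits), 4L)
  # k = feature count is the identity subset; k = 1 keeps the signal
  tb <- gauss_table(n = 500, k_sig = 1, k_noise = 3, sep = 3, seed = 40)
  all_feats <- setdiff(names(tb), c("key", "label"))
  expect_setequal(
    recursive_feature_elimination(tb, "random_forest", k = length(all_feats))$retained,
    all_feats)
  expect_equal(recursive_feature_elimination(tb, "random_forest", k = 1,
                                             seed = 1)$retained, "sig1")
  expect_error(recursive_feature_elimination(tb, "random_forest", k = 99),
               "between")
})

test_that("spearman_matrix matches the hand rank formula and conventions", {
  # rho = 1 - 6*sum(d^2)/(n(n^2-1)) on x=1..5, y=(2,1,4,3,5): d^2 sums to 4
  tb <- data.frame(key = paste0("v", 1:5), label = "driver",
                   x = 1:5, y = c(2, 1, 4, 3, 5))
  M <- spearman_matrix(tb, c("x", "y"))
  expect_equal(M["x", "y"], 1 - 6 * 4 / (5 * 24))
  expect_equal(M["x", "y"], 0.8)
  expect_equal(diag(M), c(x = 1, y = 1))
  expect_equal(M, t(M))
  # self vs reversal
  tb$z <- rev(1:5)
  M2 <- spearman_matrix(tb, c("x", "z"))
  expect_equal(M2["x", "z"], -1)
  # zero-variance column warns and reports NA
  tb$c0 <- 1
  expect_warning(M3 <- spearman_matrix(tb, c("x", "c0")), "zero-variance")
  expect_true(is.na(M3["x", "c0"]))
})

test_that("information-value report ranks separated features above noise", {
  tb <- gauss_table(n = 1500, k_sig = 2, k_noise = 5, sep = 2, seed = 50)
  iv <- woe_iv_report(tb)
  expect_setequal(iv$feature[1:2], c("sig1", "sig2"))
  expect_true(all(iv$iv >= 0))
})

test_that("adding an independent DL score improves fused holdout AUC", {
  # the tabular signal and the 'sequence' signal are independent by
  # construction, so fusing the DL score must add information
  gains <- vapply(1:5, function(s) {
    tb <- gauss_table(n = 800, k_sig = 2, k_noise = 3, sep = 1.2, seed = 60 + s)
    y <- as.integer(tb$label == "driver")
    set.seed(1000 + s)
    # stand-in DL score: informative, independent of the tabular columns
    dl <- data.frame(key = tb$key, dl_score = plogis(rnorm(nrow(tb)) + 1.6 * y))
    tb_dl <- suppressMessages(attach_dl_score(tb, dl))
    a1 <- train_classifier(tb, "random_forest", seed = s)$report$auc
    a2 <- train_classifier(tb_dl, "random_forest", seed = s)$report$auc
    a2 - a1
  }, numeric(1))
  expect_gt(mean(gains), 0)
  expect_gte(sum(gains > 0), 4L)
})
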