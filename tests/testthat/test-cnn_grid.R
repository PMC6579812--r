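# Shared small fixtures: building them once keeps the suite fast.
null_ds <- fixture_encoded(n_total = 240, q = 0, seed = 1)      # no signal
sig_ds  <- fixture_encoded(n_total = 600, q = 1, seed = 2)      # planted motif
fast_cfg <- function(epochs = 6, seed = 1, lr = 3e-3, folds = 3)
  training_config(epochs = epochs, folds = folds, seed = seed, lr = lr)

test_that("architecture specs validate the width constraints", {
  a <- architecture_spec(c(32, 16), c(8))
  expect_s3_class(a, "architecture_spec")
  expect_error(architecture_spec(c(3)), "powers of 2")
  expect_error(architecture_spec(c(512)), "powers of 2")
  expect_error(architecture_spec(c(2, 2, 2, 2)), "between")
  expect_error(architecture_spec(c(2), dropout = 1), "dropout")
})

test_that("the default grid enumerates 72 architectures; cardinality law holds", {
  grid <- enumerate_architectures()
  expect_length(grid, 72L)
  # |conv| x |dense| x |widths|
  expect_length(enumerate_architectures(1, 1, 2), 1L)
  expect_length(enumerate_architectures(1:2, 1:3, c(4, 8)), 12L)
  expect_error(enumerate_architectures(widths = 3), "powers of 2")
  # deterministic ordering: two calls identical
  expect_identical(enumerate_architectures(), grid)
  # tapered preset lists 11 architectures
  expect_length(tapered_architectures(), 11L)
})

test_that("parameter counts grow with width and drive the final tie-break", {
  C <- 10; L <- 21
  small <- n_parameters(architecture_spec(2, 2), C, L)
  big <- n_parameters(architecture_spec(256, 256), C, L)
  expect_lt(small, big)
  # hand-computed: conv(2,k3,C10): (10*3+1)*2 = 62; flatten 2*19 = 38;
  # dense(2): 39*2 = 78; head: 3*1 = 3 -> 143
  expect_equal(small, 62 + 78 + 3)
})

test_that("cross-validation bookkeeping: folds, epochs, stratification, determinism", {
  cfg <- fast_cfg(epochs = 4)
  recs <- train_evaluate_cv(null_ds, architecture_spec(4, 4), cfg)
  expect_length(recs, 3L)
  for (r in recs) {
    expect_equal(nrow(r$history), 4L)
    expect_true(all(c("accuracy", "f1", "auc") %in% names(r$history)))
    expect_true(r$best_epoch >= 1 && r$best_epoch <= 4)
    # best epoch maximizes validation F1, earliest wins ties
    expect_equal(r$best_epoch, which.max(r$history$f1))
  }
  # stratification: each fold's class ratio within one sample of global
  y <- null_ds$y
  fold_sizes <- vapply(recs, function(r) length(r$val_idx), numeric(1))
  for (r in recs) {
    n_d <- sum(y[r$val_idx] == 1)
    expected <- length(r$val_idx) * mean(y)
    expect_lte(abs(n_d - expected), 1 + 1e-9)
  }
  # folds partition the dataset
  expect_setequal(unlist(lapply(recs, `[[`, "val_idx")), seq_along(y))
  # determinism under a fixed seed
  recs2 <- train_evaluate_cv(null_ds, architecture_spec(4, 4), cfg)
  expect_identical(lapply(recs, `[[`, "history"), lapply(recs2, `[[`, "history"))
})

test_that("grid search selects the max mean F1 with deterministic tie-breaking", {
  cfg <- fast_cfg(epochs = 3)
  grid <- list(architecture_spec(4, 4), architecture_spec(8, 4),
               architecture_spec(4, 8), architecture_spec(8, 8))
  gs <- grid_search(sig_ds, grid, cfg)
  expect_equal(nrow(gs$summary), 4L)
  expect_equal(gs$summary$mean_f1[gs$selected_index], max(gs$summary$mean_f1))
  # identical architectures give identical metrics -> tie resolved by
  # parameter count, deterministically
  tie <- grid_search(null_ds, list(architecture_spec(8, 8),
                                   architecture_spec(4, 4)), cfg)
  s <- tie$summary
  expect_equal(tie$selected_index,
               order(-s$mean_f1, -s$mean_auc, s$n_parameters)[1])
  tie2 <- grid_search(null_ds, list(architecture_spec(8, 8),
                                    architecture_spec(4, 4)), cfg)
  expect_identical(tie$selected_index, tie2$selected_index)
  # singleton grid selects its only member
  one <- grid_search(null_ds, list(architecture_spec(2, 2)), cfg)
  expect_equal(one$selected_index, 1L)
})

test_that("DL scores cover every sample once, in [0,1], without leakage", {
  cfg <- fast_cfg(epochs = 4)
  sc <- compute_dl_scores(null_ds, architecture_spec(4, 4), cfg)
  expect_equal(nrow(sc), length(null_ds$y))
  expect_false(anyDuplicated(sc$key) > 0)
  expect_true(all(sc$dl_score >= 0 & sc$dl_score <= 1))
  hold <- attr(sc, "holdout")
  expect_true(all(sc$provenance[hold] == "holdout-model"))
  expect_true(all(sc$provenance[!hold] == "out-of-fold"))
  # stratified holdout: fraction and class balance respected
  expect_equal(sum(hold), round(0.2 * sum(null_ds$y == 1)) +
                 round(0.2 * sum(null_ds$y == 0)))
  # paper mode scores everything with one model
  sp <- compute_dl_scores(null_ds, architecture_spec(4, 4), cfg, mode = "paper")
  expect_true(all(sp$provenance == "full-model"))
})

test_that("null-signal data yields chance-level DL scores across seeds", {
  aucs <- vapply(1:5, function(s) {
    ds <- fixture_encoded(n_total = 240, q = 0, seed = 100 + s)
    sc <- compute_dl_scores(ds, architecture_spec(8, 8),
                            fast_cfg(epochs = 6, seed = s))
    roc_auc(sc$label, sc$dl_score)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("a fully planted motif is recovered with high validation F1 and AUC", {
  ds2k <- fixture_encoded(n_total = 2000, q = 1, seed = 6)
  cfg <- fast_cfg(epochs = 20, seed = 4)
  recs <- train_evaluate_cv(ds2k, architecture_spec(c(16, 16), 16), cfg)
  mean_f1 <- mean(vapply(recs, function(r) r$best[["f1"]], numeric(1)))
  mean_auc <- mean(vapply(recs, function(r) r$best[["auc"]], numeric(1)))
  expect_gte(mean_f1, 0.85)
  expect_gte(mean_auc, 0.9)
})

test_that("holdout AUC does not degrade as planted-motif strength rises", {
  mean_auc_at_q <- function(q) {
    mean(vapply(1:2, function(s) {
      ds <- fixture_encoded(n_total = 400, q = q, seed = 200 + s)
      sc <- compute_dl_scores(ds, architecture_spec(16, 16),
                              fast_cfg(epochs = 12, seed = s))
      hold <- attr(sc, "holdout")
      roc_auc(sc$label[hold], sc$dl_score[hold])$auc
    }, numeric(1)))
  }
  a0 <- mean_auc_at_q(0); a1 <- mean_auc_at_q(0.5); a2 <- mean_auc_at_q(1)
  noise <- 0.1
  expect_gte(a1, a0 - noise)
  expect_gte(a2, a1 - noise)
  expect_gt(a2, a0)   # strong signal clearly beats none
})
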