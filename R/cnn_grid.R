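#' @title Architecture grid search, cross-validation and DL scores
#' @description Enumerates the CNN architecture family, runs the stratified
#'   holdout + k-fold cross-validation protocol with per-epoch validation
#'   tracking, selects the best architecture by mean validation F1 (AUC,
#'   then parameter count, break ties), and produces the per-variant DL
#'   score used downstream as a feature.
#' @name cnn_grid
NULL

#' Enumerate the CNN architecture grid
#'
#' One architecture per (convolutional depth, dense depth, shared width)
#' combination; the defaults (depths 1-3 for both stacks, widths 2, 4, ...,
#' 256) give 72 architectures, from one 2-filter convolution into one
#' 2-node dense layer up to three 256-filter convolutions into three
#' 256-node dense layers.
#'
#' @param conv_depths,dense_depths integer sets of layer counts.
#' @param widths integer set of shared layer widths (powers of 2 in
#'   `[2, 256]`).
#' @param kernel,dropout forwarded to [architecture_spec()].
#' @return a list of `architecture_spec` objects in deterministic
#'   (width-major, then conv depth, then dense depth) order.
#' @export
enumerate_architectures <- function(conv_depths = 1:3, dense_depths = 1:3,
                                    widths = 2L^(1:8), kernel = 3L,
                                    dropout = 0.25) {
  if (length(conv_depths) == 0L || length(dense_depths) == 0L ||
      length(widths) == 0L) stop("depth and width sets must be non-empty")
  widths <- as.integer(widths)
  bad <- widths[widths < 2L | widths > 256L | bitwAnd(widths, widths - 1L) != 0L]
  if (length(bad) > 0L) {
    stop("widths must be powers of 2 in [2, 256]; got ", paste(bad, collapse = ", "))
  }
  grid <- expand.grid(dense = sort(dense_depths), conv = sort(conv_depths),
                      width = sort(widths))
  lapply(seq_len(nrow(grid)), function(i) {
    architecture_spec(rep(grid$width[i], grid$conv[i]),
                      rep(grid$width[i], grid$dense[i]),
                      kernel = kernel, dropout = dropout)
  })
}

#' The tapered architecture preset
#'
#' Eleven architectures with per-layer widths tapering down to a 2-node
#' output head (treated here as the sigmoid output, not a hidden layer):
#' the first listed width is the convolutional layer and the remaining
#' pre-head widths are dense layers.
#'
#' @inheritParams enumerate_architectures
#' @return a list of `architecture_spec` objects.
#' @export
tapered_architectures <- function(kernel = 3L, dropout = 0.25) {
  presets <- list(
    c(32), c(16, 8), c(16, 16), c(32, 16), c(32, 8), c(64, 32), c(64, 16),
    c(64, 64, 16), c(128, 64, 16), c(128, 64, 32), c(128, 64, 32, 16)
  )
  lapply(presets, function(v) {
    n_conv <- if (length(v) >= 4L) 2L else 1L  # keep stacks within depth 3
    architecture_spec(v[seq_len(n_conv)], v[-seq_len(n_conv)],
                      kernel = kernel, dropout = dropout)
  })
}

# deterministic stratified fold assignment: within each class, samples are
# dealt round-robin over folds in a seeded shuffled order
stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# stratified holdout split: returns logical vector, TRUE = holdout
stratified_holdout <- function(y, fraction, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hold <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_h <- round(length(idx) * fraction)
    hold[sample(idx, n_h)] <- TRUE
  }
  hold
}

#' Cross-validated training of one architecture
#'
#' Splits the samples into `cfg$folds` stratified folds; for each fold the
#' network trains on the others and records validation accuracy, F1 and
#' AUC after every epoch. The best epoch per fold maximizes validation F1
#' (earliest epoch wins ties).
#'
#' @param data an `encoded_dataset` from [encode_dataset()] (labeled).
#' @param arch an `architecture_spec`.
#' @param cfg a `training_config`.
#' @return a list of fold records, each with `fold`, `history` (per-epoch
#'   data.frame), `best_epoch`, `best` (named metric vector at the best
#'   epoch) and `val_idx` (indices the fold model never trained on).
#' @export
train_evaluate_cv <- function(data, arch, cfg = training_config()) {
  stopifnot(inherits(data, "encoded_dataset"))
  y <- data$y
  if (anyNA(y)) stop("all samples must be labeled for cross-validation")
  fold <- stratified_folds(y, cfg$folds, cfg$seed)
  for (f in seq_len(cfg$folds)) {
    yv <- y[fold == f]
    if (length(unique(yv)) < 2L || length(unique(y[fold != f])) < 2L) {
      stop("fold ", f, " does not contain both classes")
    }
  }
  lapply(seq_len(cfg$folds), function(f) {
    tr <- fold != f
    fit <- cnn_fit(data$x[tr, , , drop = FALSE], y[tr], arch, cfg,
                   x_val = data$x[!tr, , , drop = FALSE], y_val = y[!tr],
                   seed_offset = f)
    best <- as.numeric(fit$history[fit$best_epoch, c("accuracy", "f1", "auc")])
    names(best) <- c("accuracy", "f1", "auc")
    list(fold = f, history = fit$history, best_epoch = fit$best_epoch,
         best = best, val_idx = which(!tr), model = fit$best_net)
  })
}

#' Grid search over CNN architectures
#'
#' Runs [train_evaluate_cv()] for every architecture and selects the one
#' with the highest mean best-epoch validation F1 across folds; ties are
#' broken by mean AUC, then by the smallest parameter count.
#'
#' @param data an `encoded_dataset`.
#' @param grid list of `architecture_spec`s (e.g. from
#'   [enumerate_architectures()]).
#' @param cfg a `training_config`.
#' @return an object of class `grid_search_result`: `summary` (data.frame
#'   with one row per architecture: mean/sd F1, mean AUC, parameter count),
#'   `selected` (the winning `architecture_spec`), `selected_index`,
#'   `fold_records` for the winner, and the `cfg`.
#' @export
grid_search <- function(data, grid, cfg = training_config()) {
  if (length(grid) == 0L) stop("empty architecture grid")
  C <- dim(data$x)[2]; L <- dim(data$x)[3]
  records <- lapply(grid, function(a) train_evaluate_cv(data, a, cfg))
  summ <- do.call(rbind, lapply(seq_along(grid), function(i) {
    b <- do.call(rbind, lapply(records[[i]], `[[`, "best"))
    data.frame(
      arch = i,
      conv = paste(grid[[i]]$conv_filters, collapse = ","),
      dense = paste(grid[[i]]$dense_widths, collapse = ","),
      mean_f1 = mean(b[, "f1"]), sd_f1 = stats::sd(b[, "f1"]),
      mean_auc = mean(b[, "auc"]), mean_accuracy = mean(b[, "accuracy"]),
      n_parameters = n_parameters(grid[[i]], C, L)
    )
  }))
  ord <- order(-summ$mean_f1, -summ$mean_auc, summ$n_parameters, summ$arch)
  sel <- ord[1]
  structure(
    list(summary = summ, selected = grid[[sel]], selected_index = sel,
         fold_records = records[[sel]], cfg = cfg),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("Grid search over %d architectures (folds = %d, epochs = %d)\n",
              nrow(x$summary), x$cfg$folds, x$cfg$epochs))
  cat(sprintf("Selected #%d: conv(%s) dense(%s)  mean F1 %.4f, mean AUC %.4f\n",
              x$selected_index,
              paste(x$selected$conv_filters, collapse = ","),
              paste(x$selected$dense_widths, collapse = ","),
              x$summary$mean_f1[x$selected_index],
              x$summary$mean_auc[x$selected_index]))
  invisible(x)
}

#' Compute per-variant DL scores
#'
#' The default (`mode = "oof"`) avoids train-on-test leakage: a stratified
#' holdout is set aside, the remaining training portion is scored
#' out-of-fold (each sample predicted by the fold model that never saw
#' it), and the holdout is scored by a model refit on the full training
#' portion. `mode = "paper"` instead scores the entire dataset with the
#' single refit model.
#'
#' @param data a labeled `encoded_dataset`.
#' @param arch the `architecture_spec` to use (e.g. the grid-search
#'   winner).
#' @param cfg a `training_config`.
#' @param mode `"oof"` (default) or `"paper"`.
#' @return an object of class `dl_score_table`: a data.frame with columns
#'   `key`, `label`, `dl_score` (in `[0, 1]`), `provenance`
#'   (`"out-of-fold"` / `"holdout-model"` / `"full-model"`), plus an
#'   attribute `holdout` (logical vector marking holdout membership).
#' @export
compute_dl_scores <- function(data, arch, cfg = training_config(),
                              mode = c("oof", "paper")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "encoded_dataset"))
  y <- data$y
  if (anyNA(y)) stop("all samples must be labeled to compute DL scores")
  n <- length(y)
  hold <- stratified_holdout(y, cfg$holdout, cfg$seed)
  tr_idx <- which(!hold)
  score <- rep(NA_real_, n)
  provenance <- rep(NA_character_, n)

  # model refit on the full training portion, validated on the holdout so
  # the best epoch can be selected
  full_fit <- cnn_fit(data$x[tr_idx, , , drop = FALSE], y[tr_idx], arch, cfg,
                      x_val = data$x[hold, , , drop = FALSE], y_val = y[hold],
                      seed_offset = 1000L)
  if (mode == "paper") {
    score <- cnn_predict(full_fit$best_net, data$x)
    provenance <- rep("full-model", n)
  } else {
    sub <- structure(list(x = data$x[tr_idx, , , drop = FALSE], y = y[tr_idx],
                          keys = data$keys[tr_idx], scheme = data$scheme,
                          w = data$w), class = "encoded_dataset")
    folds <- train_evaluate_cv(sub, arch, cfg)
    for (fr in folds) {
      global_idx <- tr_idx[fr$val_idx]
      score[global_idx] <- cnn_predict(fr$model,
                                       data$x[global_idx, , , drop = FALSE])
      provenance[global_idx] <- "out-of-fold"
    }
    score[hold] <- cnn_predict(full_fit$best_net,
                               data$x[hold, , , drop = FALSE])
    provenance[hold] <- "holdout-model"
  }
  out <- data.frame(key = data$keys, label = ifelse(y == 1L, "driver", "passenger"),
                    dl_score = score, provenance = provenance,
                    stringsAsFactors = FALSE)
  attr(out, "holdout") <- hold
  attr(out, "best_epoch") <- full_fit$best_epoch
  class(out) <- c("dl_score_table", "data.frame")
  out
}
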