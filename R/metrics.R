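#' @title Evaluation metrics for driver/passenger classification
#' @description Confusion counts, the standard classification report
#'   (accuracy, precision, recall, F1, sensitivity/TPR, specificity/TNR,
#'   FPR, FNR) and ROC/AUC. The driver class is always the positive class.
#' @name metrics
NULL

# Normalize a label vector to 0/1 integers with driver = 1.
# Accepts "driver"/"passenger" (any case), logicals, or 0/1 numerics.
as_binary_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    lx <- tolower(trimws(x))
    out <- ifelse(lx == "driver", 1L, ifelse(lx == "passenger", 0L, NA_integer_))
    if (anyNA(out)) {
      stop("labels must be 'driver'/'passenger' or 0/1; got: ",
           paste(unique(x[is.na(out)]), collapse = ", "))
    }
    return(out)
  }
  if (is.logical(x)) return(as.integer(x))
  xi <- as.integer(x)
  if (any(is.na(xi)) || !all(xi %in% c(0L, 1L))) {
    stop("numeric labels must be 0 (passenger) or 1 (driver)")
  }
  xi
}

#' Confusion counts with driver as the positive class
#'
#' @param labels true class labels: `"driver"`/`"passenger"` strings or 0/1
#'   (driver = 1).
#' @param predictions predicted class labels, same conventions.
#' @return an object of class `confusion_counts`: a list with integer
#'   components `TP`, `TN`, `FP`, `FN` and `n = TP + TN + FP + FN`.
#' @examples
#' confusion(c(1, 0), c(1, 0))
#' @export
confusion <- function(labels, predictions) {
  y <- as_binary_label(labels)
  p <- as_binary_label(predictions)
  if (length(y) != length(p)) {
    stop("labels and predictions have different lengths (",
         length(y), " vs ", length(p), ")")
  }
  if (length(y) == 0L) stop("empty input")
  out <- list(
    TP = sum(y == 1L & p == 1L),
    TN = sum(y == 0L & p == 0L),
    FP = sum(y == 0L & p == 1L),
    FN = sum(y == 1L & p == 0L)
  )
  out$n <- out$TP + out$TN + out$FP + out$FN
  class(out) <- "confusion_counts"
  out
}

#' Classification report from confusion counts
#'
#' Computes accuracy = (TP+TN)/n, precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2*precision*recall/(precision+recall),
#' sensitivity (TPR), specificity (TNR), FPR and FNR. When a denominator is
#' zero the affected precision/recall/F1 are reported as 0 (so a constant
#' all-passenger predictor has a well-defined F1 of 0); rates with zero
#' denominators are reported as `NA`.
#'
#' @param counts a `confusion_counts` object.
#' @param labels,scores optional true labels and real-valued driver scores;
#'   when both are supplied an AUC and ROC curve are attached via
#'   [roc_auc()].
#' @return an object of class `classification_report`: a list of numeric
#'   metrics (and `auc`/`roc` when scores were given).
#' @export
classification_report <- function(counts, labels = NULL, scores = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0L) stop("empty confusion counts")
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  safe <- function(num, den, zero = NA_real_) if (den > 0) num / den else zero
  precision <- safe(TP, TP + FP, zero = 0)
  recall    <- safe(TP, TP + FN, zero = 0)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  rep <- list(
    accuracy    = (TP + TN) / counts$n,
    precision   = precision,
    recall      = recall,
    f1          = f1,
    sensitivity = safe(TP, TP + FN),
    specificity = safe(TN, TN + FP),
    tpr         = safe(TP, TP + FN),
    tnr         = safe(TN, TN + FP),
    fpr         = safe(FP, FP + TN),
    fnr         = safe(FN, FN + TP),
    counts      = counts
  )
  if (!is.null(labels) && !is.null(scores)) {
    ra <- roc_auc(labels, scores)
    rep$auc <- ra$auc
    rep$roc <- ra$roc
  }
  class(rep) <- "classification_report"
  rep
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (positive class = driver)\n")
  cat(sprintf("  n = %d  [TP %d  TN %d  FP %d  FN %d]\n",
              x$counts$n, x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("  TPR %.4f  TNR %.4f  FPR %.4f  FNR %.4f\n",
              x$tpr, x$tnr, x$fpr, x$fnr))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.4f\n", x$auc))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank (Mann-Whitney) construction: the probability
#' that a randomly chosen driver receives a higher score than a randomly
#' chosen passenger, with tied scores contributing 1/2. The ROC points are
#' generated by sweeping a threshold through the unique score values
#' (plus infinite endpoints); this trapezoid construction yields the same
#' area.
#'
#' @param labels true labels (driver = positive).
#' @param scores real-valued scores, higher = more driver-like.
#' @return a list with `auc` (scalar) and `roc` (data.frame with columns
#'   `threshold`, `fpr`, `tpr`, ordered from strictest threshold down).
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_label(labels)
  s <- as.numeric(scores)
  if (length(y) != length(s)) stop("labels and scores have different lengths")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute ROC/AUC")
  }
  # rank-sum AUC; average ranks give the ties-count-half convention
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(s >= t & y == 1L) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & y == 0L) / n_neg, numeric(1))
  list(auc = auc, roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}
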