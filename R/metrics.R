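# Evaluation metrics. Zero-denominator precision/recall are defined as 0
# with a warning (keeps macro averages over rare classes finite); AUROC uses
# the rank statistic (ties counted one half), AUPR step-wise
# precision-recall integration. Multi-class AUROC/AUPR are one-vs-rest,
# macro-averaged over classes present in the labels.

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as 0")
    return(0)
  }
  num / den
}

#' Binary classification metrics from hard predictions
#'
#' @param labels 0/1 vector of true labels.
#' @param predictions 0/1 vector (threshold applied upstream, default 0.5).
#' @return list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
binary_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels (", length(labels), ") and predictions (",
         length(predictions), ") differ in length")
  }
  stopifnot(all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall, f1 = f1)
}

#' Threshold-free ranking metrics
#'
#' AUROC is the probability that a random positive outscores a random
#' negative with ties counted one half (equivalently the normalised rank-sum
#' statistic); AUPR integrates the precision-recall curve stepwise in
#' recall.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return list with `auroc` and `aupr`.
#' @export
rank_metrics <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("rank metrics undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # stepwise PR integration over the score-sorted list
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / n_pos
  # sum precision at each new true positive (step height 1/n_pos)
  aupr <- sum(prec[y == 1]) / n_pos
  list(auroc = auroc, aupr = aupr)
}

#' Macro-averaged multi-class metrics
#'
#' Per-class precision/recall/F1 are computed one-vs-rest and averaged
#' without class weights over the classes present in the labels.
#'
#' @param labels true class tokens.
#' @param predictions predicted class tokens (same length).
#' @return list with `macro_p`, `macro_r`, `macro_f1`, `accuracy` and the
#'   `confusion` matrix (rows = truth, columns = prediction).
#' @export
macro_metrics <- function(labels, predictions) {
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(predictions)) stop("length mismatch")
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  classes <- sort(unique(labels))
  lv <- sort(unique(c(labels, predictions)))
  conf <- table(factor(labels, lv), factor(predictions, lv))
  per <- vapply(classes, function(cl) {
    tp <- sum(labels == cl & predictions == cl)
    fp <- sum(labels != cl & predictions == cl)
    fn <- sum(labels == cl & predictions != cl)
    p <- safe_ratio(tp, tp + fp, paste0("precision[", cl, "]"))
    r <- safe_ratio(tp, tp + fn, paste0("recall[", cl, "]"))
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }, numeric(3))
  list(macro_p = mean(per[1L, ]), macro_r = mean(per[2L, ]),
       macro_f1 = mean(per[3L, ]), accuracy = mean(labels == predictions),
       confusion = conf)
}

#' Full evaluation report
#'
#' @param labels binary 0/1 labels, or event-class tokens.
#' @param scores probabilities (binary) or a class-probability matrix with
#'   class tokens as column names (event).
#' @param mode "binary" or "event".
#' @param threshold classification threshold for the binary confusion
#'   metrics.
#' @return named list of metrics (an `EvalReport`).
#' @export
eval_report <- function(labels, scores, mode = c("binary", "event"),
                        threshold = 0.5) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    labels <- as.numeric(labels)
    hard <- as.numeric(scores >= threshold)
    c(binary_metrics(labels, hard), rank_metrics(labels, scores))
  } else {
    stopifnot(is.matrix(scores), !is.null(colnames(scores)))
    labels <- as.character(labels)
    pred <- colnames(scores)[max.col(scores, ties.method = "first")]
    mm <- macro_metrics(labels, pred)
    present <- intersect(colnames(scores), unique(labels))
    rk <- vapply(present, function(cl) {
      bin <- as.numeric(labels == cl)
      if (all(bin == 1) || all(bin == 0)) return(c(NA_real_, NA_real_))
      unlist(rank_metrics(bin, scores[, cl]))
    }, numeric(2))
    mm$auroc <- mean(rk[1L, ], na.rm = TRUE)
    mm$aupr <- mean(rk[2L, ], na.rm = TRUE)
    mm
  }
}
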