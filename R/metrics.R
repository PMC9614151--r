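#' Binary classification metrics
#'
#' Confusion-matrix metrics at a probability threshold plus ROC-AUC in its
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, ties counted one half (computed via midranks).
#'
#' @param y_true Integer labels in \{0, 1\}.
#' @param scores Positive-class probabilities in `[0, 1]`.
#' @param threshold Decision threshold on the positive-class probability.
#' @return A `dpi_eval_report` list: `acc`, `auc`, `precision`, `recall`,
#'   `f1`, `n_samples`, `threshold`, `confusion` (TP/FP/TN/FN). `auc` is
#'   `NA` (with a warning) when only one class is present; `precision` is 0
#'   (with a warning) when nothing is predicted positive.
#' @export
binary_metrics <- function(y_true, scores, threshold = 0.5) {
  y <- as.integer(y_true)
  s <- as.numeric(scores)
  stopifnot(length(y) == length(s), all(y %in% c(0L, 1L)))
  n <- length(y)
  pred <- as.integer(s >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  acc <- (tp + tn) / n
  if (tp + fp == 0L) {
    warning("no positive predictions: precision reported as 0", call. = FALSE)
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auc <- auc_mann_whitney(y, s)
  structure(list(acc = acc, auc = auc, precision = precision, recall = recall,
                 f1 = f1, n_samples = n, threshold = threshold,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "dpi_eval_report")
}

auc_mann_whitney <- function(y, s) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(s)                         # midranks give the half-tie credit
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass classification metrics
#'
#' Accuracy by row-wise argmax (ties to the lowest class index) and a macro
#' one-vs-rest ROC-AUC averaged over the classes present in `y_true`;
#' absent classes are excluded with a warning. Precision/recall/F1 are
#' macro-averaged over present classes. `average = "micro"` pools the
#' one-vs-rest decisions into a single AUC instead.
#'
#' @param y_true Integer labels in `0 .. K-1`.
#' @param scores n x K probability matrix with rows summing to 1.
#' @param average `"macro"` (default) or `"micro"` for the AUC aggregation.
#' @return A `dpi_eval_report` with a `per_class` data frame attached.
#' @export
multiclass_metrics <- function(y_true, scores, average = c("macro", "micro")) {
  average <- match.arg(average)
  y <- as.integer(y_true)
  scores <- as.matrix(scores)
  K <- ncol(scores)
  stopifnot(length(y) == nrow(scores), all(y >= 0L), all(y < K))
  if (max(abs(rowSums(scores) - 1)) > 1e-6) {
    stop("score rows must sum to 1")
  }
  pred <- max.col(scores, ties.method = "first") - 1L
  acc <- mean(pred == y)
  present <- sort(unique(y))
  if (length(present) < K) {
    warning(sprintf("class(es) %s absent from y_true: excluded from macro averages",
                    paste(setdiff(0:(K - 1L), present), collapse = ", ")),
            call. = FALSE)
  }
  per <- lapply(present, function(k) {
    yk <- as.integer(y == k)
    predk <- as.integer(pred == k)
    tp <- sum(predk & yk); fp <- sum(predk & !yk); fn <- sum(!predk & yk)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    data.frame(class = k, n = sum(yk),
               precision = prec, recall = rec,
               f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
               auc = suppressWarnings(auc_mann_whitney(yk, scores[, k + 1L])))
  })
  per <- do.call(rbind, per)
  auc <- if (average == "macro") {
    mean(per$auc, na.rm = TRUE)
  } else {
    yy <- unlist(lapply(present, function(k) as.integer(y == k)))
    ss <- unlist(lapply(present, function(k) scores[, k + 1L]))
    auc_mann_whitney(yy, ss)
  }
  structure(list(acc = acc, auc = auc,
                 precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1), n_samples = length(y),
                 per_class = per, average = average),
            class = "dpi_eval_report")
}

#' @export
print.dpi_eval_report <- function(x, ...) {
  cat(sprintf("<dpi_eval_report: n=%d acc=%.4f auc=%s prec=%.4f rec=%.4f f1=%.4f>\n",
              x$n_samples, x$acc,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc),
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate a fitted model on a record set
#'
#' Scores every record at the posterior mean (deterministic) and computes
#' binary or multiclass metrics according to the model's class count.
#'
#' @param model A `dpi_model` or `dpi_fit`.
#' @param records Data frame with `drug`, `protein`, `label`.
#' @param batch_size Scoring batch size.
#' @return A `dpi_eval_report`.
#' @export
evaluate_model <- function(model, records, batch_size = 256L) {
  if (inherits(model, "dpi_fit")) model <- model$model
  ds <- prepare_dataset(records, model$drug_vocab, model$protein_vocab,
                        model$config)
  probs <- predict_dataset(model, ds, batch_size)
  if (model$config$n_classes == 2L) {
    binary_metrics(ds$y, probs[, 2L])
  } else {
    multiclass_metrics(ds$y, probs)
  }
}
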