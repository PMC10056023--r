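#' Confusion matrix for binary screening
#'
#' The positive class defaults to `"hypertensive"`: a true positive is a
#' hypertensive window predicted hypertensive.
#'
#' @param predicted,truth Character/factor vectors of class labels.
#' @param positive Name of the positive class.
#' @return A `confusion_matrix`: list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(predicted, truth, positive = "hypertensive") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  structure(list(
    TP = sum(predicted == positive & truth == positive),
    TN = sum(predicted != positive & truth != positive),
    FP = sum(predicted == positive & truth != positive),
    FN = sum(predicted != positive & truth == positive),
    positive = positive), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = %s\n", x$positive))
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              truth = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R). Ratios with a zero denominator are
#' returned as `NA` (flagged undefined), never silently zeroed.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list with the four metrics and `undefined`, a character
#'   vector naming any metric whose denominator was zero.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0) stop("compute_metrics: empty confusion matrix")
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  accuracy <- (cm$TP + cm$TN) / total
  precision <- safe(cm$TP, cm$TP + cm$FP, "precision")
  recall <- safe(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undef <- c(undef, "f1"); NA_real_
  } else f1_score(precision, recall)
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, undefined = undef)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * P * R / (P + R)`.
#'
#' @param precision,recall Proportions in `[0, 1]`.
#' @return F1 score.
#' @export
f1_score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Evaluation report for one protocol
#'
#' @param predicted,truth Label vectors.
#' @param positive Positive class.
#' @param protocol `"test"`, `"robustness"` or `"reliability"`.
#' @return An `evaluation_report`: protocol tag, confusion matrix and the
#'   four metrics.
#' @export
evaluation_report <- function(predicted, truth, positive = "hypertensive",
                              protocol = c("test", "robustness",
                                           "reliability")) {
  protocol <- match.arg(protocol)
  cm <- confusion_matrix(predicted, truth, positive)
  m <- compute_metrics(cm)
  structure(list(protocol = protocol, confusion = cm,
                 accuracy = m$accuracy, precision = m$precision,
                 recall = m$recall, f1 = m$f1, undefined = m$undefined),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> protocol %s: acc %.3f  P %.3f  R %.3f  F1 %.3f\n",
              x$protocol, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

report_to_row <- function(r) {
  data.frame(protocol = r$protocol, TP = r$confusion$TP, TN = r$confusion$TN,
             FP = r$confusion$FP, FN = r$confusion$FN,
             accuracy = r$accuracy, precision = r$precision,
             recall = r$recall, f1 = r$f1, stringsAsFactors = FALSE)
}

#' Robustness protocol: evaluate on unprocessed windows
#'
#' The model is trained on preprocessed windows; here its test windows
#' are re-cut from the raw records (drift and noise retained, no
#' filtering or baseline removal) and re-classified, probing resistance
#' to interference.
#'
#' @param model A trained `ppg_model`.
#' @param raw_dataset `window_dataset` built with `preprocess = FALSE`
#'   from the same cohort (window positions align with the processed
#'   dataset).
#' @param split The split assignment used in training; evaluation uses
#'   its `"test"` windows.
#' @param positive Positive class.
#' @return An `evaluation_report` tagged `"robustness"`.
#' @export
robustness_protocol <- function(model, raw_dataset, split,
                                positive = "hypertensive") {
  stopifnot(inherits(raw_dataset, "window_dataset"))
  X <- raw_dataset$X[split == "test", , drop = FALSE]
  y <- raw_dataset$label[split == "test"]
  pp <- predict_proba(model, X)
  pred <- model$classes[max.col(pp)]
  evaluation_report(pred, y, positive, protocol = "robustness")
}

#' Reliability protocol: leave one subject per class out
#'
#' Randomly holds out one healthy and one hypertensive subject, trains on
#' all remaining subjects' windows, and tests on the held-out subjects'
#' windows only. No held-out window enters training (asserted), probing
#' generalisation to unseen individuals.
#'
#' @param dataset Preprocessed `window_dataset` for the whole cohort.
#' @param spec A [model_spec()].
#' @param config A [train_config()]; its `rng_seed` picks the held-out
#'   subjects and seeds training.
#' @param kind Model kind.
#' @param positive Positive class.
#' @return An `evaluation_report` tagged `"reliability"`, with the
#'   held-out subject ids in `$held_out` and the trained model in
#'   `$model`.
#' @export
reliability_protocol <- function(dataset, spec = model_spec(),
                                 config = train_config(),
                                 kind = "lstm_attention",
                                 positive = "hypertensive") {
  stopifnot(inherits(dataset, "window_dataset"))
  subj <- unique(data.frame(subject_id = dataset$subject_id,
                            label = dataset$label))
  per_class <- split(subj$subject_id, subj$label)
  if (length(per_class) < 2L || any(lengths(per_class) < 2L))
    stop("reliability_protocol: need at least 2 subjects per class")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)
  held <- vapply(per_class, function(s) sample(s, 1L), character(1))

  is_held <- dataset$subject_id %in% held
  # train/validation split over the retained subjects' windows
  split <- ifelse(is_held, "test", NA_character_)
  keep_idx <- which(!is_held)
  lab <- dataset$label[keep_idx]
  set.seed(config$rng_seed + 1L)
  for (cl in unique(lab)) {
    idx <- keep_idx[lab == cl]
    nv <- max(1L, round(0.125 * length(idx)))
    val <- sample(idx, nv)
    split[idx] <- "train"
    split[val] <- "validation"
  }
  stopifnot(!any(dataset$subject_id[split == "train"] %in% held))

  tr <- train_model(kind, dataset, split, spec, config)
  X <- dataset$X[is_held, , drop = FALSE]
  y <- dataset$label[is_held]
  pred <- tr$model$classes[max.col(predict_proba(tr$model, X))]
  rep_ <- evaluation_report(pred, y, positive, protocol = "reliability")
  rep_$held_out <- held
  rep_$model <- tr$model
  rep_$n_train_subjects <- length(unique(dataset$subject_id[split == "train"]))
  rep_
}
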