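#' Build a confusion matrix from label vectors
#'
#' Rows are true labels, columns predicted labels, both in the order of
#' `classes`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors; every
#'   label must appear in `classes`.
#' @param classes Ordered class vector (default `c("ST", "SI", "WA")`).
#' @return Integer matrix of class `har_cm` with `dimnames` `true` x
#'   `predicted`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             classes = HAR_CLASSES) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop_bad_arg("label vectors must have equal length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad)) {
    stop_bad_arg("unknown label(s): ", paste(bad, collapse = ", "))
  }
  cm <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("har_cm", class(m)))
}

#' Coerce a plain count matrix to a confusion matrix
#'
#' @param m Square non-negative count matrix (rows true, columns predicted).
#' @param classes Class labels; default taken from `rownames(m)` or
#'   `c("ST","SI","WA")`.
#' @return A `har_cm` matrix.
#' @export
as_confusion_matrix <- function(m, classes = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_bad_arg("confusion matrix must be square")
  if (any(m < 0)) stop_bad_arg("confusion matrix entries must be >= 0")
  classes <- classes %||% rownames(m) %||% HAR_CLASSES[seq_len(nrow(m))]
  dimnames(m) <- list(true = classes, predicted = classes)
  structure(m, class = c("har_cm", class(m)))
}

#' Overall accuracy of a confusion matrix, in percent
#'
#' `100 * trace / total`, reported to 2 decimals.
#'
#' @param cm A confusion matrix (any square count matrix).
#' @param digits Rounding digits (default 2); `NA` for full precision.
#' @return Accuracy percentage.
#' @export
accuracy_from_cm <- function(cm, digits = 2) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop_bad_arg("empty confusion matrix")
  acc <- 100 * sum(diag(cm)) / total
  if (is.na(digits)) acc else round(acc, digits)
}

#' Per-class and macro precision, recall and F1 from a confusion matrix
#'
#' Per class: precision = N_TP / N_PP (true positives over predicted
#' positives), recall = N_TP / N_AP (true positives over actual positives),
#' F1 = harmonic mean of the two. A zero denominator (a class never
#' predicted, or absent from the truth) yields 0 for that metric with the
#' corresponding `undefined_*` flag set. Macro metrics are unweighted class
#' means. All values in percent.
#'
#' @param cm A confusion matrix (rows true, columns predicted).
#' @return A `metrics_report` list: `accuracy`, `per_class` data.frame
#'   (class, n_tp, n_pp, n_ap, precision, recall, f1, undefined_precision,
#'   undefined_recall), and `macro` (precision, recall, f1).
#' @export
precision_recall_f1 <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) <= 0) stop_bad_arg("empty confusion matrix")
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  n_tp <- diag(cm)
  n_pp <- colSums(cm)
  n_ap <- rowSums(cm)
  prec <- ifelse(n_pp > 0, 100 * n_tp / n_pp, 0)
  rec <- ifelse(n_ap > 0, 100 * n_tp / n_ap, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(
    class = classes, n_tp = as.numeric(n_tp), n_pp = as.numeric(n_pp),
    n_ap = as.numeric(n_ap), precision = prec, recall = rec, f1 = f1,
    undefined_precision = n_pp == 0, undefined_recall = n_ap == 0,
    row.names = NULL
  )
  structure(
    list(accuracy = accuracy_from_cm(cm, digits = NA),
         per_class = per_class,
         macro = list(precision = mean(prec), recall = mean(rec),
                      f1 = mean(f1))),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy: %.2f%%  macro P/R/F1: %.2f / %.2f / %.2f\n",
              x$accuracy, x$macro$precision, x$macro$recall, x$macro$f1))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Accuracy difference between two confusion matrices
#'
#' `accuracy(cm_a) - accuracy(cm_b)` in percentage points, computed at full
#' precision and rounded to 2 decimals.
#'
#' @param cm_a,cm_b Confusion matrices.
#' @return Percentage-point difference.
#' @export
accuracy_delta <- function(cm_a, cm_b) {
  round(accuracy_from_cm(cm_a, digits = NA) -
          accuracy_from_cm(cm_b, digits = NA), 2)
}

#' Learning-rate sweep over feature-set variants
#'
#' Trains one model per (variant, learning rate, seed) on the given training
#' sets and evaluates all of them on the same held-out test set —
#' augmentation only ever touches training rows, so the test set is shared
#' and its size constant across variants.
#'
#' @param train_sets Named list of [feature_set()] training variants (e.g.
#'   `list(OR = ..., "OR+LA1" = ...)`).
#' @param test_set A `feature_set` used for evaluation of every model.
#' @param learning_rates Numeric vector of learning rates.
#' @param cfg Base [lstm_config()]; its learning rate and seed are
#'   overridden per run.
#' @param seeds Integer vector of training seeds (default 1).
#' @return List with `report` (data.frame: variant, learning_rate, seed,
#'   accuracy, macro_precision, macro_recall, macro_f1, n_train, n_test)
#'   and `matrices` (list of `har_cm`, named `variant@rate@seed`).
#' @export
sweep_learning_rates <- function(train_sets, test_set, learning_rates,
                                 cfg = lstm_config(), seeds = 1L) {
  stopifnot(length(train_sets) >= 1, length(learning_rates) >= 1,
            inherits(test_set, "feature_set"))
  if (is.null(names(train_sets)) || any(names(train_sets) == "")) {
    stop_bad_arg("train_sets must be a named list")
  }
  rows <- list(); mats <- list()
  for (variant in names(train_sets)) {
    tr <- train_sets[[variant]]
    for (lr in learning_rates) {
      for (sd_ in seeds) {
        run_cfg <- cfg
        run_cfg$learning_rate <- lr
        run_cfg$seed <- as.integer(sd_)
        model <- train_lstm(tr, run_cfg)
        pred <- predict(model, test_set)
        cm <- confusion_matrix(as.character(test_set$labels),
                               as.character(pred),
                               classes = model$classes)
        rep_ <- precision_recall_f1(cm)
        key <- sprintf("%s@%g@%d", variant, lr, sd_)
        mats[[key]] <- cm
        rows[[key]] <- data.frame(
          variant = variant, learning_rate = lr, seed = as.integer(sd_),
          accuracy = round(rep_$accuracy, 2),
          macro_precision = round(rep_$macro$precision, 2),
          macro_recall = round(rep_$macro$recall, 2),
          macro_f1 = round(rep_$macro$f1, 2),
          n_train = nrow(tr$features), n_test = nrow(test_set$features))
      }
    }
  }
  list(report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       matrices = mats)
}
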