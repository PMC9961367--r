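#' Confusion matrix from true and predicted labels
#'
#' Cross-tabulates true against predicted class labels in a fixed class
#' order. Rows index the true class, columns the predicted class, so entry
#' `(i, j)` counts subjects of true class `i` predicted as class `j`.
#'
#' @param y_true,y_pred Vectors of class labels (character or factor), equal
#'   length. Every label must occur in `class_order`.
#' @param class_order Character vector fixing the row/column order, e.g.
#'   `c("CN", "MCI", "AD")`.
#' @param positive_class For binary tasks, the label treated as positive in
#'   [binary_metrics()]. Defaults to the last element of `class_order` (the
#'   more impaired class under the CN < MCI < AD ordering).
#' @return A `confusion_matrix` object: an integer k x k matrix with
#'   `class_order` dimnames and a `positive_class` attribute.
#' @examples
#' cm <- confusion(c("A", "A", "B"), c("A", "B", "B"), class_order = c("A", "B"))
#' cm
#' @export
confusion <- function(y_true, y_pred, class_order,
                      positive_class = class_order[length(class_order)]) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have the same length.")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad) > 0) {
    abort(paste0("Labels not in `class_order`: ", paste(bad, collapse = ", ")))
  }
  if (!positive_class %in% class_order) {
    abort("`positive_class` must be one of `class_order`.")
  }
  k <- length(class_order)
  counts <- matrix(0L, k, k, dimnames = list(true = class_order, pred = class_order))
  if (length(y_true) > 0) {
    tab <- table(factor(y_true, levels = class_order),
                 factor(y_pred, levels = class_order))
    counts[] <- as.integer(tab)
  }
  structure(counts,
            class = c("confusion_matrix", "matrix", "array"),
            positive_class = positive_class)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted); positive class: ",
      attr(x, "positive_class"), "\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall, `2 * pre * rec / (pre + rec)`,
#' on whatever scale the inputs share (percentages in this package's
#' reports). Returns 0 when both inputs are 0.
#'
#' @param pre,rec Precision and recall (vectors recycle).
#' @return Numeric F1 on the same scale as the inputs.
#' @examples
#' f1_score(91.7, 89.2) # 90.4 to one decimal
#' @export
f1_score <- function(pre, rec) {
  out <- ifelse(pre + rec == 0, 0, 2 * pre * rec / (pre + rec))
  as.numeric(out)
}

#' Binary classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient from a 2 x 2 confusion matrix, all expressed as percentages:
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{PRE = TP/(TP+FP), \quad REC = TP/(TP+FN)}
#' \deqn{F1 = 2 \cdot PRE \cdot REC / (PRE + REC)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}
#' A ratio with zero denominator is reported as 0 and the corresponding
#' metric name recorded in the `undefined` list-column.
#'
#' @param cm A 2 x 2 [confusion()] object.
#' @param positive_class Override the positive class stored on `cm`.
#' @return One-row tibble: `acc`, `pre`, `rec`, `f1`, `mcc` (percent) plus
#'   `undefined` (list of metric names whose denominator was zero).
#' @export
binary_metrics <- function(cm, positive_class = attr(cm, "positive_class")) {
  if (!inherits(cm, "confusion_matrix") || nrow(cm) != 2) {
    abort("`cm` must be a 2 x 2 confusion_matrix.")
  }
  classes <- rownames(cm)
  pos <- positive_class
  neg <- setdiff(classes, pos)
  tp <- cm[pos, pos]; tn <- cm[neg, neg]
  fp <- cm[neg, pos]; fn <- cm[pos, neg]
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  acc <- ratio(tp + tn, tp + tn + fp + fn, "acc")
  pre <- ratio(tp, tp + fp, "pre")
  rec <- ratio(tp, tp + fn, "rec")
  f1 <- if (pre + rec == 0) {
    undefined <- c(undefined, "f1"); 0
  } else 2 * pre * rec / (pre + rec)
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- ratio(tp * tn - fp * fn, mcc_den, "mcc")
  tibble(acc = 100 * acc, pre = 100 * pre, rec = 100 * rec,
         f1 = 100 * f1, mcc = 100 * mcc,
         undefined = list(unique(undefined)))
}

#' Multi-class metrics from a confusion matrix
#'
#' Overall accuracy is the trace over the total count; per-class precision
#' and recall (sensitivity) come from the one-vs-rest reduction of each
#' class.
#'
#' @param cm A k x k [confusion()] object, k >= 2.
#' @return A list with `accuracy` (percent) and `per_class`, a tibble with
#'   one row per class (`class`, `precision`, `recall`, both percent).
#' @export
multiclass_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) abort("`cm` must be a confusion_matrix.")
  total <- sum(cm)
  if (total == 0) abort("Empty confusion matrix.")
  classes <- rownames(cm)
  per_class <- purrr::map(classes, function(cl) {
    tp <- cm[cl, cl]
    pre_den <- sum(cm[, cl])
    rec_den <- sum(cm[cl, ])
    tibble(class = cl,
           precision = if (pre_den == 0) 0 else 100 * tp / pre_den,
           recall = if (rec_den == 0) 0 else 100 * tp / rec_den)
  }) %>% list_rbind()
  list(accuracy = 100 * sum(diag(cm)) / total, per_class = per_class)
}

#' SVM vector-feature baseline
#'
#' Fits a linear support-vector machine on the training rows of a feature
#' matrix (or a single score column) and evaluates it on the test rows.
#' This is the vector-feature comparator for the population-graph models:
#' it sees exactly the same per-subject inputs but no subject-to-subject
#' edges.
#'
#' @param x Numeric matrix (subjects x features) or a numeric vector
#'   (a single score). Row order matches `labels`.
#' @param labels Class labels per subject (character or factor).
#' @param split Character vector per subject in `{train, val, test}`;
#'   validation rows are folded into training (the SVM has no early
#'   stopping to drive).
#' @param class_order Label order for the confusion matrix; default sorted
#'   unique labels.
#' @param seed Integer seed (SVM fitting is deterministic for a linear
#'   kernel, but the seed also guards any cost cross-validation added later).
#' @param cost SVM cost parameter.
#' @return A list: `metrics` (binary tasks: [binary_metrics()] tibble;
#'   multi-class: [multiclass_metrics()] list) and `confusion`.
#' @export
vector_baseline <- function(x, labels, split, class_order = NULL, seed = 1,
                            cost = 1) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  labels <- as.character(labels)
  if (is.null(class_order)) class_order <- sort(unique(labels))
  stopifnot(nrow(x) == length(labels), length(split) == length(labels))
  tr <- split %in% c("train", "val")
  te <- split == "test"
  if (length(unique(labels[tr])) < 2) {
    abort("Training data contain a single class; cannot fit the SVM baseline.")
  }
  fit <- with_seed(seed, {
    e1071::svm(x = x[tr, , drop = FALSE],
               y = factor(labels[tr], levels = class_order),
               kernel = "linear", cost = cost, scale = FALSE)
  })
  pred <- as.character(predict(fit, x[te, , drop = FALSE]))
  cm <- confusion(labels[te], pred, class_order)
  metrics <- if (length(class_order) == 2) binary_metrics(cm) else multiclass_metrics(cm)
  list(metrics = metrics, confusion = cm)
}

#' @export
#' @method tidy confusion_matrix
#' @rdname confusion
#' @param x A `confusion_matrix`.
#' @param ... Unused.
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame.table(as.table(unclass(x)), responseName = "n")
  as_tibble(df) %>%
    mutate(true = as.character(.data$true), pred = as.character(.data$pred))
}
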