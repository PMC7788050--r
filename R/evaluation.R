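#' Confusion matrix of true vs predicted cell types
#'
#' Rows are true classes, columns predicted classes, in the fixed order
#' ESC, iPSC, ECC, somatic.
#'
#' @param true_labels,predicted_labels Character vectors of equal
#'   length; any label outside `classes` raises an error.
#' @param classes Class order.
#' @return A `confusion_matrix`: a k x k integer matrix.
#' @export
confusion <- function(true_labels, predicted_labels,
                      classes = cell_type_classes()) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stopf("label vectors differ in length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad) > 0)
    stopf("label(s) outside the class set: %s", paste(bad, collapse = ", "))
  tab <- table(factor(true_labels, levels = classes),
               factor(predicted_labels, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Per-class precision from a confusion matrix
#'
#' Precision of class `i` is the diagonal count over the predicted
#' column total. An empty column yields `NaN` (the undefined flag);
#' [macro_metrics()] substitutes 0 with a warning.
#'
#' @param cm A `confusion_matrix`.
#' @param class_index Column index or class name.
#' @return A fraction in `[0, 1]`, or `NaN` when undefined.
#' @export
class_precision <- function(cm, class_index) {
  i <- resolve_class_index(cm, class_index)
  cm[i, i] / sum(cm[, i])
}

#' Per-class recall from a confusion matrix
#'
#' Recall of class `i` is the diagonal count over the true row total.
#'
#' @inheritParams class_precision
#' @return A fraction in `[0, 1]`, or `NaN` for an empty row.
#' @export
class_recall <- function(cm, class_index) {
  i <- resolve_class_index(cm, class_index)
  cm[i, i] / sum(cm[i, ])
}

resolve_class_index <- function(cm, class_index) {
  if (is.character(class_index)) {
    i <- match(class_index, rownames(cm))
    if (is.na(i)) stopf("unknown class '%s'", class_index)
    i
  } else {
    if (class_index < 1 || class_index > nrow(cm)) stopf("class index out of range")
    as.integer(class_index)
  }
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Macro precision and recall are unweighted means of the per-class
#' values; the macro F-score is the harmonic combination of the two
#' macro averages, `2 P R / (P + R)` (not a mean of per-class
#' F-scores); accuracy is the trace over the total. Undefined per-class
#' values (empty row or column) enter the macro average as 0, with a
#' warning — this keeps the metrics defined for degenerate checkpoints
#' early in training.
#'
#' @param cm A `confusion_matrix`.
#' @return A `macro_metrics` list: `per_class_precision`,
#'   `per_class_recall` (named fractions), `precision_macro`,
#'   `recall_macro`, `f_macro`, `accuracy`, `n` (total samples).
#' @export
macro_metrics <- function(cm) {
  k <- nrow(cm)
  classes <- rownames(cm)
  prec <- vapply(seq_len(k), function(i) class_precision(cm, i), numeric(1))
  rec <- vapply(seq_len(k), function(i) class_recall(cm, i), numeric(1))
  names(prec) <- names(rec) <- classes
  if (any(is.nan(prec)) || any(is.nan(rec))) {
    warning("undefined per-class precision/recall (empty row or column); using 0 in the macro average")
    prec[is.nan(prec)] <- 0
    rec[is.nan(rec)] <- 0
  }
  pm <- mean(prec)
  rm_ <- mean(rec)
  fm <- if (pm + rm_ == 0) 0 else 2 * pm * rm_ / (pm + rm_)
  structure(list(per_class_precision = prec, per_class_recall = rec,
                 precision_macro = pm, recall_macro = rm_,
                 f_macro = fm, accuracy = sum(diag(cm)) / sum(cm),
                 n = sum(cm)),
            class = "macro_metrics")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' @export
print.macro_metrics <- function(x, ...) {
  cat(sprintf("Macro-averaged metrics over %d samples\n", x$n))
  pc <- rbind(`precision %` = as_percent(x$per_class_precision),
              `recall %`    = as_percent(x$per_class_recall))
  print(pc)
  cat(sprintf(
    "accuracy %.2f%%  precision_macro %.2f%%  recall_macro %.2f%%  F_macro %.2f%%\n",
    as_percent(x$accuracy), as_percent(x$precision_macro),
    as_percent(x$recall_macro), as_percent(x$f_macro)))
  invisible(x)
}

#' Machine-readable metrics report keyed by confusion-table cell names
#'
#' Serializes a 4-class confusion matrix and its metrics using the
#' conventional cell naming: counts `a1..d4` (rows = true class,
#' letters = predicted class column), per-class precisions `e1..e4`,
#' recalls `f1..f4`, then the macro averages and accuracy — all rates
#' as percentages rounded half-up to two decimals.
#'
#' @param cm A 4x4 `confusion_matrix`.
#' @return A named list of numbers.
#' @export
metrics_report <- function(cm) {
  if (!all(dim(cm) == c(4, 4))) stopf("metrics_report expects a 4x4 matrix")
  m <- macro_metrics(cm)
  cells <- list()
  letters4 <- c("a", "b", "c", "d")
  for (i in 1:4) for (j in 1:4)
    cells[[paste0(letters4[j], i)]] <- unname(cm[i, j])
  for (i in 1:4) cells[[paste0("e", i)]] <- as_percent(m$per_class_precision[[i]])
  for (i in 1:4) cells[[paste0("f", i)]] <- as_percent(m$per_class_recall[[i]])
  cells$precision_macro <- as_percent(m$precision_macro)
  cells$recall_macro <- as_percent(m$recall_macro)
  cells$f_macro <- as_percent(m$f_macro)
  cells$accuracy <- as_percent(m$accuracy)
  cells
}
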