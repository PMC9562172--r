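#' Confusion matrix for multi-class predictions
#'
#' @param truth integer true labels in `[0, C)`.
#' @param pred integer predicted labels in `[0, C)`.
#' @param n_classes number of classes C (defaults to the max label + 1).
#' @return `C x C` integer matrix, rows = true class, columns =
#'   predicted class.
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  if (is.null(n_classes)) n_classes <- max(truth, pred) + 1L
  lv <- seq_len(n_classes) - 1L
  tab <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  m <- matrix(as.integer(tab), n_classes, n_classes,
              dimnames = list(true = lv, predicted = lv))
  m
}

#' Classification accuracy from a confusion matrix
#'
#' Multi-class accuracy is the proportion of correctly classified
#' samples, `trace(confusion) / N`; for a binary one-vs-rest table this
#' equals `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param confusion square confusion matrix (rows true, columns
#'   predicted).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n < 1) stop("empty confusion matrix")
  sum(diag(confusion)) / n
}

#' Matthews correlation coefficient
#'
#' For two classes this is the classical formula
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; for more
#' classes the generalized (covariance-form) multi-class MCC is used,
#' which reduces exactly to the binary formula at C = 2. A zero
#' denominator (e.g. all samples predicted as one class) returns 0 by
#' convention.
#'
#' @param confusion square confusion matrix (rows true, columns
#'   predicted).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(confusion) {
  Cm <- as.matrix(confusion) * 1.0
  s <- sum(Cm)
  if (s < 1) stop("empty confusion matrix")
  c_ <- sum(diag(Cm))
  t_ <- rowSums(Cm) # true-class totals
  p_ <- colSums(Cm) # predicted-class totals
  num <- c_ * s - sum(t_ * p_)
  den <- sqrt(s^2 - sum(p_^2)) * sqrt(s^2 - sum(t_^2))
  if (den == 0) return(0)
  num / den
}

#' Macro one-vs-rest area under the ROC curve
#'
#' Computes, per class, the one-vs-rest ROC curve (TPR against FPR over
#' all score thresholds) and its trapezoidal area, then macro-averages
#' over the classes that have at least one positive and one negative
#' sample. Classes without both are skipped with a warning; if every
#' class is skipped an error is raised.
#'
#' @param scores `N x C` matrix of class probabilities (rows sum to 1),
#'   or a vector of positive-class scores for a binary problem.
#' @param labels integer labels in `[0, C)`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (is.null(dim(scores))) scores <- cbind(1 - scores, scores)
  if (nrow(scores) != length(labels)) stop("scores and labels differ in length")
  C <- ncol(scores)
  aucs <- rep(NA_real_, C)
  for (k in seq_len(C)) {
    pos <- labels == (k - 1L)
    if (!any(pos) || all(pos)) {
      warning(sprintf("class %d skipped in AUC: needs both positives and negatives", k - 1L))
      next
    }
    r <- pROC::roc(response = pos, predictor = scores[, k],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    aucs[k] <- as.numeric(pROC::auc(r))
  }
  if (all(is.na(aucs))) stop("no class had both positives and negatives; AUC undefined")
  mean(aucs, na.rm = TRUE)
}

#' Write a metrics report
#'
#' Emits a JSON report with overall accuracy, MCC and AUC plus
#' per-class precision/recall, and a TSV confusion matrix alongside.
#'
#' @param metrics list as returned by [tgem_evaluate()].
#' @param path path of the JSON report; the confusion matrix goes to
#'   `paste0(path_without_ext, "_confusion.tsv")`.
#' @param class_names optional class names for the per-class block.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path, class_names = NULL) {
  conf <- metrics$confusion
  C <- nrow(conf)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(C) - 1L)
  per_class <- lapply(seq_len(C), function(k) {
    tp <- conf[k, k]
    list(precision = if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else NA,
         recall = if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else NA,
         support = sum(conf[k, ]))
  })
  names(per_class) <- class_names
  jsonlite::write_json(list(acc = metrics$acc, mcc = metrics$mcc,
                            auc = metrics$auc, per_class = per_class),
                       path, auto_unbox = TRUE, digits = NA)
  conf_path <- paste0(sub("\\.json$", "", path), "_confusion.tsv")
  conf_df <- as.data.frame.matrix(conf)
  colnames(conf_df) <- class_names
  rownames(conf_df) <- class_names
  utils::write.table(conf_df, conf_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
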