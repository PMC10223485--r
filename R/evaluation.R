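#' One-vs-rest confusion counts per event class
#'
#' Derived from the 3x3 confusion matrix: for each class `c`, `TP_c` counts
#' blocks of class `c` predicted as `c`, `FN_c` blocks of class `c` predicted
#' otherwise, `FP_c` blocks of other classes predicted as `c`, and `TN_c` the
#' remainder.
#'
#' @param pred Predicted class label codes.
#' @param truth True class label codes, same length.
#' @param n_classes Number of classes.
#' @return A `confusion_counts` list with vectors `tp`, `fp`, `tn`, `fn`, the
#'   full `matrix` (truth in rows, prediction in columns), and `n`.
#' @export
confusion_counts <- function(pred, truth, n_classes = 3L) {
  pred <- validate_labels(pred, "predictions")
  truth <- validate_labels(truth, "truth")
  if (length(pred) != length(truth)) {
    stop("prediction and truth lengths differ (", length(pred), " vs ",
         length(truth), ")", call. = FALSE)
  }
  if (length(pred) == 0L) stop("empty prediction/truth vectors", call. = FALSE)
  lev <- seq_len(n_classes) - 1L
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(truth = lev, pred = lev))
  N <- length(pred)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- N - tp - fn - fp
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, matrix = cm, n = N),
            class = "confusion_counts")
}

#' Per-class accuracy, sensitivity, specificity
#'
#' Exact one-vs-rest arithmetic:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity (true-negative rate) `TN/(TN+FP)`. A `0/0` cell is reported as
#' `NA` ("missing"), never as 0 or 1, so degenerate test sets cannot inflate
#' results.
#'
#' @param counts A [confusion_counts()] object.
#' @return Data frame with one row per class and columns `class`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
class_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  k <- length(counts$tp)
  data.frame(
    class = names(class_labels())[seq_len(k)],
    accuracy = (counts$tp + counts$tn) / counts$n,
    sensitivity = safe_div(counts$tp, counts$tp + counts$fn),
    specificity = safe_div(counts$tn, counts$tn + counts$fp),
    row.names = NULL
  )
}

#' One-vs-rest ROC points for a class
#'
#' Sweeps the class's sigmoid score over every unique value as a threshold
#' (prediction positive when `score >= threshold`), returning
#' `(FPR, TPR)` points sorted by FPR and including `(0, 0)` and `(1, 1)`.
#'
#' @param scores `N x n_classes` score matrix (or the class's score vector).
#' @param truth True class label codes.
#' @param class Class code the curve is computed for.
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth, class) {
  truth <- validate_labels(truth, "truth")
  s <- if (is.matrix(scores)) scores[, class + 1L] else scores
  stopifnot(length(s) == length(truth))
  pos <- truth == class
  if (all(pos) || !any(pos)) {
    stop("degenerate ROC: truth contains a single class", call. = FALSE)
  }
  nP <- sum(pos); nN <- sum(!pos)
  pts <- t(vapply(sort(unique(s), decreasing = TRUE), function(thr) {
    hit <- s >= thr
    c(fpr = sum(hit & !pos) / nN, tpr = sum(hit & pos) / nP)
  }, c(fpr = 0, tpr = 0)))
  pts <- rbind(c(0, 0), pts, c(1, 1))
  pts <- unique(pts[order(pts[, 1L], pts[, 2L]), , drop = FALSE])
  data.frame(fpr = pts[, 1L], tpr = pts[, 2L])
}

#' Trapezoidal AUC of an ROC point set
#'
#' @param pts Data frame from [roc_points()].
#' @return Scalar area under the curve.
#' @export
auc_trapezoid <- function(pts) {
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1L) + utils::tail(pts$tpr, -1L)) / 2)
}

#' Evaluate trained models on a test set
#'
#' Produces the per-event metrics table (mean and, with several runs,
#' standard deviation across replicates), the 3x3 confusion matrix (averaged
#' element-wise over runs), and per-class ROC points. Only per-event metrics
#' are reported: under heavy class imbalance a pooled accuracy would be
#' misleading, so none is printed.
#'
#' @param models A trained `fall_ensemble`, a [train_fall_detector()] result,
#'   or a list of either (replicates).
#' @param test A non-empty `block_dataset`.
#' @param out_dir Optional directory; when given, writes `metrics.csv`,
#'   `confusion.csv`, and `roc_<class>.csv`.
#' @param priority Tie-break priority for fusion.
#' @return A `fall_report`: list with `metrics` (data frame), `confusion`,
#'   `roc` (list of data frames), `n_runs`, `n_test`.
#' @export
evaluation_report <- function(models, test, out_dir = NULL,
                              priority = default_tie_break()) {
  stopifnot(inherits(test, "block_dataset"))
  if (n_blocks(test) == 0L) stop("empty test set", call. = FALSE)
  if (inherits(models, "fall_ensemble")) models <- list(models)
  if (!is.null(models$model)) models <- list(models)
  models <- lapply(models, function(m) if (inherits(m, "fall_ensemble")) m else m$model)
  runs <- lapply(models, function(m) {
    scores <- predict_scores(m, test)
    pred <- fuse_proposed(scores, priority)
    cc <- confusion_counts(pred, test$label)
    list(scores = scores, metrics = class_metrics(cc), confusion = cc$matrix)
  })
  k <- length(runs)
  per_run <- lapply(runs, `[[`, "metrics")
  metric_cols <- c("accuracy", "sensitivity", "specificity")
  agg <- per_run[[1L]]["class"]
  for (mc in metric_cols) {
    vals <- sapply(per_run, `[[`, mc)
    vals <- matrix(vals, nrow = nrow(agg))
    agg[[paste0(mc, "_mean")]] <- rowMeans(vals)
    if (k > 1L) agg[[paste0(mc, "_sd")]] <- apply(vals, 1L, stats::sd)
  }
  confusion <- Reduce(`+`, lapply(runs, `[[`, "confusion")) / k
  roc <- lapply(class_labels(), function(cl) {
    tryCatch(roc_points(runs[[1L]]$scores, test$label, cl),
             error = function(e) NULL)
  })
  rep_ <- structure(
    list(metrics = agg, confusion = confusion, roc = roc,
         n_runs = k, n_test = n_blocks(test)),
    class = "fall_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(agg, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(confusion),
                     file.path(out_dir, "confusion.csv"))
    for (nm in names(roc)) {
      if (!is.null(roc[[nm]])) {
        utils::write.csv(roc[[nm]], file.path(out_dir, paste0("roc_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  rep_
}

#' @export
print.fall_report <- function(x, ...) {
  cat(sprintf("<fall_report> %d run(s), %d test blocks\n", x$n_runs, x$n_test))
  print(x$metrics, digits = 3)
  cat("confusion matrix (truth rows x prediction columns",
      if (x$n_runs > 1L) ", mean over runs" else "", "):\n", sep = "")
  print(x$confusion)
  invisible(x)
}
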