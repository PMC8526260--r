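#' Confusion matrix with fixed class order
#'
#' Rows are true classes, columns predicted. The class order defaults to the
#' clinical reporting order (A, AS, AL, I, IL, IP, IPL, P, H, O) restricted
#' to the classes present.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class order; default [class_order()] of the union.
#' @return Integer matrix of class `ecg_confusion`.
#' @export
confusion_counts <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- class_order(c(truth, predicted))
  unknown <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unknown) > 0) {
    stop("unknown labels: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cm <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("ecg_confusion", "matrix"))
}

#' Per-class one-vs-rest metrics
#'
#' Collapses the confusion matrix one-vs-rest per class and reports
#' sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, positive
#' predictive value `+p = TP/(TP+FP)` and accuracy
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, in percent at full precision. A
#' zero-denominator metric is reported as `NA` (undefined), never as 0.
#'
#' @param cm An `ecg_confusion` matrix (or any square count matrix with
#'   dimnames).
#' @return Tibble: `class`, `tp`, `tn`, `fp`, `fn`, `se`, `sp`, `ppv`,
#'   `acc`.
#' @export
class_metrics <- function(cm) {
  total <- sum(cm)
  stopifnot(total > 0)
  classes <- rownames(cm)
  purrr::map_dfr(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    tibble::tibble(class = classes[k], tp = tp, tn = tn, fp = fp, fn = fn,
                   se = pct(tp, tp + fn), sp = pct(tn, tn + fp),
                   ppv = pct(tp, tp + fp), acc = pct(tp + tn, total))
  })
}

#' Overall (multiclass) accuracy of a confusion matrix, percent
#' @param cm Square count matrix.
#' @export
overall_accuracy <- function(cm) {
  100 * sum(diag(cm)) / sum(cm)
}

#' Stratified k-fold cross-validation of the full classifier
#'
#' Splits beats into `k` stratified folds; within each fold the QT
#' compressor (for PCA/LPP) and the boosted ensemble are fitted on the
#' training beats only, and the held-out beats are predicted. Reports the
#' pooled confusion matrix over all held-out predictions (primary), the
#' per-class metrics, and the per-fold accuracies with their mean.
#'
#' @param features Tidy per-(beat, lead) feature table from
#'   [extract_features()] (must carry `label`).
#' @param k Number of folds (default 10).
#' @param method QT compression backend: `"dwt"`, `"pca"`, `"lpp"`.
#' @param feature_set `"fused"`, `"rule"`, or `"ventricular"`.
#' @param seed Seed for fold assignment and column subsampling.
#' @param nrounds,max_depth,learning_rate,lambda,gamma,colsample Boosting
#'   hyperparameters, see [boost_fit()].
#' @param early_stop_logloss Early stop, see [boost_fit()].
#' @return An `mi_cv` object: `confusion`, `metrics`, `accuracy` (pooled,
#'   %), `fold_accuracy`, `mean_fold_accuracy`, `predictions` tibble.
#' @export
kfold_cv <- function(features, k = 10L, method = c("dwt", "pca", "lpp"),
                     feature_set = c("fused", "rule", "ventricular"),
                     seed = NULL, nrounds = 60L, max_depth = 6L,
                     learning_rate = 0.1, lambda = 1, gamma = 0,
                     colsample = 0.8, early_stop_logloss = 1e-3) {
  method <- match.arg(method)
  feature_set <- match.arg(feature_set)
  beats <- features |>
    dplyr::distinct(.data$beat, .data$label)
  counts <- table(beats$label)
  short <- names(counts)[counts < k]
  if (length(short) > 0) {
    stop("class(es) with fewer than k = ", k, " beats: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  leads <- intersect(ECG_LEADS, unique(features$lead))
  with_seed(seed, {
    fold_of <- integer(nrow(beats))
    for (cl in names(counts)) {
      idx <- sample(which(beats$label == cl))
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    preds <- vector("list", k)
    for (f in seq_len(k)) {
      train_beats <- beats$beat[fold_of != f]
      test_beats <- beats$beat[fold_of == f]
      ftr <- features[features$beat %in% train_beats, ]
      fte <- features[features$beat %in% test_beats, ]
      compressors <- NULL
      if (feature_set != "rule") {
        compressors <- lapply(stats::setNames(leads, leads), function(ld) {
          xtr <- if (method == "dwt") NULL else qt_matrix(ftr, ld)
          compress_fit(xtr, method = method)
        })
      }
      wtr <- fuse_features(ftr, compressors, feature_set, leads = leads)
      wte <- fuse_features(fte, compressors, feature_set, leads = leads)
      fit <- boost_fit(wtr, nrounds = nrounds, max_depth = max_depth,
                       learning_rate = learning_rate, lambda = lambda,
                       gamma = gamma, colsample = colsample,
                       early_stop_logloss = early_stop_logloss)
      preds[[f]] <- tibble::tibble(
        fold = f, beat = wte$beat, label = wte$label,
        predicted = predict(fit, wte))
    }
    predictions <- dplyr::bind_rows(preds)
    cm <- confusion_counts(predictions$label, predictions$predicted,
                           classes = class_order(beats$label))
    fold_acc <- predictions |>
      dplyr::group_by(.data$fold) |>
      dplyr::summarise(accuracy =
        100 * mean(.data$label == .data$predicted), .groups = "drop")
    structure(list(confusion = cm, metrics = class_metrics(cm),
                   accuracy = overall_accuracy(cm),
                   fold_accuracy = fold_acc,
                   mean_fold_accuracy = mean(fold_acc$accuracy),
                   predictions = predictions, k = k, method = method,
                   feature_set = feature_set),
              class = "mi_cv")
  })
}

#' @export
print.mi_cv <- function(x, ...) {
  cat(sprintf(
    "<mi_cv: %d-fold, %s features, %s compression>\n  pooled accuracy %.2f%% (mean fold %.2f%%), %d beats\n",
    x$k, x$feature_set, x$method, x$accuracy, x$mean_fold_accuracy,
    nrow(x$predictions)))
  invisible(x)
}

#' Per-class metric table of a cross-validation result
#' @param x An `mi_cv` object.
#' @param ... Unused.
#' @export
tidy.mi_cv <- function(x, ...) x$metrics

#' One-row cross-validation summary
#' @param x An `mi_cv` object.
#' @param ... Unused.
#' @export
glance.mi_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 mean_fold_accuracy = x$mean_fold_accuracy,
                 k = x$k, n = nrow(x$predictions),
                 feature_set = x$feature_set, method = x$method)
}

#' Yield a Table-style per-class report (counts + percentages)
#' @param cv An `mi_cv` object.
#' @param digits Rounding for display columns.
#' @return Tibble formatted for reporting.
#' @export
cv_report <- function(cv, digits = 2) {
  dplyr::mutate(cv$metrics,
                dplyr::across(c("se", "sp", "ppv", "acc"),
                              ~ round(.x, digits)))
}
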