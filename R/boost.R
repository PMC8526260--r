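#' Softmax gradient and Hessian
#'
#' First and second derivatives of the multiclass cross-entropy loss with
#' respect to the raw (pre-softmax) scores: `g = p - 1{true class}` and
#' `h = p (1 - p)` per class, where `p = softmax(scores)`. The Hessian is
#' the diagonal approximation used by second-order boosting, and is
#' nonnegative by construction.
#'
#' @param scores Numeric matrix, samples x classes, of raw scores.
#' @param y Integer vector of true class indices (1-based, per row).
#' @return List: `g` and `h` matrices (samples x classes), `p`
#'   probabilities.
#' @export
softmax_grad_hess <- function(scores, y) {
  p <- softmax_probs(scores)
  g <- p
  g[cbind(seq_along(y), y)] <- g[cbind(seq_along(y), y)] - 1
  list(g = g, h = p * (1 - p), p = p)
}

softmax_probs <- function(scores) {
  z <- scores - apply(scores, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Optimal leaf weight
#'
#' For a leaf accumulating gradient sum `G` and Hessian sum `H` under L2
#' penalty `lambda`, the weight minimizing the leaf's quadratic objective
#' `G w + (H + lambda) w^2 / 2` is `w = -G / (H + lambda)`.
#'
#' @param G,H Gradient and Hessian sums.
#' @param lambda L2 regularization on leaf weights.
#' @return Optimal weight.
#' @export
leaf_weight <- function(G, H, lambda = 1) {
  if (any(H + lambda <= 0)) stop("H + lambda must be positive", call. = FALSE)
  -G / (H + lambda)
}

#' Best single split of a node
#'
#' Exact greedy scan over all (feature, threshold) candidates; thresholds are
#' midpoints between consecutive distinct observed values. The gain is
#' `1/2 [G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda)] - gamma`,
#' and a split is only returned when the gain is positive; ties go to the
#' lowest feature index, then the lowest threshold.
#'
#' @param x Feature matrix (samples x features).
#' @param g,h Per-sample gradient and Hessian.
#' @param lambda,gamma Regularization (L2 on weights; per-leaf penalty).
#' @return One-row tibble `feature`, `threshold`, `gain` (1-based feature
#'   index), or `NULL` when no split has positive gain.
#' @export
boost_best_split <- function(x, g, h, lambda = 1, gamma = 0) {
  x <- as.matrix(x)
  sorted_idx <- apply(x, 2, order) - 1L
  if (!is.matrix(sorted_idx)) sorted_idx <- matrix(sorted_idx, ncol = ncol(x))
  tr <- .cpp_build_tree(x, as.numeric(g), as.numeric(h), sorted_idx,
                        seq_len(ncol(x)) - 1L, lambda, gamma, 1L, 0, 1)
  if (tr$feature[1] < 0) return(NULL)
  gl <- tr$G[tr$left[1] + 1L]; hl <- tr$H[tr$left[1] + 1L]
  gr <- tr$G[tr$right[1] + 1L]; hr <- tr$H[tr$right[1] + 1L]
  gain <- 0.5 * (gl^2 / (hl + lambda) + gr^2 / (hr + lambda) -
                   (gl + gr)^2 / (hl + hr + lambda)) - gamma
  tibble::tibble(feature = tr$feature[1] + 1L, threshold = tr$threshold[1],
                 gain = gain)
}

#' Fit a second-order gradient-boosted tree classifier
#'
#' Additive tree ensemble trained round by round on the softmax
#' cross-entropy loss: each round computes per-sample gradients and
#' (diagonal) Hessians at the current scores and fits one regression tree
#' per class by exact greedy split search; scores are updated by the
#' learning rate times each tree's leaf weights `-G_j/(H_j + lambda)`.
#' Splits must clear the per-leaf penalty `gamma` to be kept.
#'
#' @param data Data frame with one label column and numeric feature columns.
#' @param label Name of the label column (default `"label"`).
#' @param nrounds Boosting rounds `K` (default 200).
#' @param max_depth Maximum tree depth (default 6).
#' @param learning_rate Shrinkage per round (default 0.1).
#' @param lambda L2 regularization on leaf weights (default 1).
#' @param gamma Per-leaf complexity penalty (default 0).
#' @param colsample Fraction of features sampled per tree (default 0.8).
#' @param min_child_weight Minimum Hessian sum per child (default 0).
#' @param seed Seed for column subsampling.
#' @param early_stop_logloss Stop when training log-loss drops below this
#'   (`NULL` to disable).
#' @return An `mi_boost` object.
#' @export
boost_fit <- function(data, label = "label", nrounds = 200L, max_depth = 6L,
                      learning_rate = 0.1, lambda = 1, gamma = 0,
                      colsample = 0.8, min_child_weight = 0, seed = NULL,
                      early_stop_logloss = NULL) {
  stopifnot(label %in% names(data))
  y_raw <- data[[label]]
  feat_cols <- setdiff(names(data), c(label, "beat"))
  x <- as.matrix(as.data.frame(data[, feat_cols]))
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features contain NA", call. = FALSE)
  classes <- if (is.factor(y_raw)) levels(y_raw) else class_order(y_raw)
  y <- match(as.character(y_raw), classes)
  C <- length(classes)
  if (C < 2) stop("need at least 2 classes", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  with_seed(seed, {
    sorted_idx <- apply(x, 2, order) - 1L
    scores <- matrix(0, n, C)
    rounds <- vector("list", nrounds)
    logloss <- numeric(0)
    ncols <- max(1L, round(colsample * p))
    for (k in seq_len(nrounds)) {
      gh <- softmax_grad_hess(scores, y)
      ll <- -mean(log(pmax(gh$p[cbind(seq_len(n), y)], 1e-15)))
      logloss <- c(logloss, ll)
      if (!is.null(early_stop_logloss) && ll < early_stop_logloss) break
      class_trees <- vector("list", C)
      for (cc in seq_len(C)) {
        cols <- if (ncols < p) sort(sample.int(p, ncols)) - 1L else
          seq_len(p) - 1L
        tr <- .cpp_build_tree(x, gh$g[, cc], gh$h[, cc], sorted_idx, cols,
                              lambda, gamma, max_depth, min_child_weight,
                              learning_rate)
        scores[, cc] <- scores[, cc] + tr$fitted
        class_trees[[cc]] <- tr[c("feature", "threshold", "left", "right",
                                  "weight", "n_leaves")]
      }
      rounds[[k]] <- class_trees
    }
    rounds <- rounds[!vapply(rounds, is.null, logical(1))]
    structure(list(trees = rounds, classes = classes,
                   feature_names = feat_cols,
                   params = list(nrounds = nrounds, max_depth = max_depth,
                                 learning_rate = learning_rate,
                                 lambda = lambda, gamma = gamma,
                                 colsample = colsample,
                                 min_child_weight = min_child_weight),
                   train_logloss = logloss),
              class = "mi_boost")
  })
}

# Reporting order for class labels: the fixed clinical order when all labels
# belong to it, alphabetical otherwise.
class_order <- function(y) {
  u <- unique(as.character(y))
  if (all(u %in% MI_CLASSES)) MI_CLASSES[MI_CLASSES %in% u] else sort(u)
}

#' Predict from a boosted ensemble
#'
#' @param object An `mi_boost` model.
#' @param newdata Data frame or matrix with the training feature columns.
#' @param type `"class"` (labels), `"prob"` (softmax probabilities), or
#'   `"score"` (raw additive scores).
#' @param ... Unused.
#' @return Character vector of labels, or a matrix with one column per
#'   class.
#' @export
predict.mi_boost <- function(object, newdata,
                             type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$feature_names, names(newdata))
    if (length(missing) > 0) {
      stop("newdata lacks features: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    newdata <- as.matrix(as.data.frame(newdata[, object$feature_names]))
  } else if (ncol(newdata) != length(object$feature_names)) {
    stop("feature count mismatch: model has ",
         length(object$feature_names), ", newdata has ", ncol(newdata),
         call. = FALSE)
  }
  storage.mode(newdata) <- "double"
  C <- length(object$classes)
  scores <- matrix(0, nrow(newdata), C)
  for (round in object$trees) {
    for (cc in seq_len(C)) {
      tr <- round[[cc]]
      scores[, cc] <- scores[, cc] +
        .cpp_predict_tree(newdata, tr$feature, tr$threshold, tr$left,
                          tr$right, tr$weight)
    }
  }
  if (type == "score") {
    colnames(scores) <- object$classes
    return(scores)
  }
  p <- softmax_probs(scores)
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' @export
print.mi_boost <- function(x, ...) {
  cat(sprintf(
    "<mi_boost: %d rounds x %d classes, depth <= %d, lr %.3g, lambda %.3g, gamma %.3g>\n",
    length(x$trees), length(x$classes), x$params$max_depth,
    x$params$learning_rate, x$params$lambda, x$params$gamma))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a boosted ensemble: one row per tree
#' @param x An `mi_boost` model.
#' @param ... Unused.
#' @return Tibble: `round`, `class`, `n_leaves`.
#' @export
tidy.mi_boost <- function(x, ...) {
  purrr::imap_dfr(x$trees, function(rd, k) {
    leaves <- vapply(rd, function(tr) as.numeric(tr$n_leaves), numeric(1))
    tibble::tibble(round = k, class = x$classes, n_leaves = leaves)
  })
}

#' One-row model summary
#' @param x An `mi_boost` model.
#' @param ... Unused.
#' @export
glance.mi_boost <- function(x, ...) {
  ll <- utils::tail(x$train_logloss, 1)
  tibble::tibble(nrounds = length(x$trees),
                 n_classes = length(x$classes),
                 n_features = length(x$feature_names),
                 train_logloss = if (length(ll)) ll else NA_real_)
}

#' Serialize / restore a boosted model as JSON
#' @param model An `mi_boost` object.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$trees <- lapply(m$trees, function(round) {
    lapply(round, function(tr) {
      list(feature = vapply(tr$feature, as.integer, integer(1)),
           threshold = vapply(tr$threshold,
                              function(v) if (is.null(v)) NA_real_
                                          else as.numeric(v), numeric(1)),
           left = vapply(tr$left, as.integer, integer(1)),
           right = vapply(tr$right, as.integer, integer(1)),
           weight = vapply(tr$weight, as.numeric, numeric(1)),
           n_leaves = as.integer(tr$n_leaves))
    })
  })
  m$classes <- unlist(m$classes)
  m$feature_names <- unlist(m$feature_names)
  m$train_logloss <- as.numeric(unlist(m$train_logloss))
  m$params <- lapply(m$params, function(v) if (is.list(v)) unlist(v) else v)
  structure(m, class = "mi_boost")
}
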