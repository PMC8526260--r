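#' Wavelet compression of a QT ventricular-activity vector
#'
#' Linearly resamples the 1000-sample QT vector to 1024 points, runs a
#' 5-level db4 decomposition with periodized boundaries, and returns the 32
#' level-5 approximation coefficients. The approximation band is the
#' smoothest summary of the waveform and stays closest to the original
#' shape, which is why it (and not the detail bands) is kept. Training-free
#' and fully deterministic.
#'
#' @param qt Numeric vector of length 1000 (or a matrix with 1000 columns,
#'   one row per beat-lead).
#' @return Numeric vector of length 32 (or matrix with 32 columns).
#' @export
dwt_compress <- function(qt) {
  if (is.matrix(qt)) {
    return(t(apply(qt, 1, dwt_compress)))
  }
  x1024 <- stats::approx(seq_along(qt), qt, n = 1024L)$y
  dwt(x1024, basis = "db4", levels = 5L)$approx
}

#' Fit a PCA projection for QT compression
#'
#' Centres the training matrix by its column means and takes the top-`k`
#' right singular vectors; compressing a vector is centring followed by
#' projection onto those components. Fitting must only ever see training
#' rows.
#'
#' @param x Training matrix, beats x 1000 samples (`m >= k` rows).
#' @param k Number of components (default 32).
#' @return Object of class `qt_pca`: `rotation` (n x k), `center`, `k`.
#' @export
pca_fit <- function(x, k = 32L) {
  x <- as.matrix(x)
  if (nrow(x) < k) {
    stop("need at least ", k, " training rows for PCA, got ", nrow(x),
         call. = FALSE)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = k)
  structure(list(rotation = sv$v[, seq_len(k), drop = FALSE], center = ctr,
                 sdev = sv$d / sqrt(max(1, nrow(x) - 1)), k = k),
            class = "qt_pca")
}

#' @rdname pca_fit
#' @param fit A `qt_pca` object.
#' @param newdata Vector of length 1000 or matrix with 1000 columns.
#' @return Numeric vector of length `k` (or matrix with `k` columns).
#' @export
pca_transform <- function(fit, newdata) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  out <- sweep(newdata, 2, fit$center) %*% fit$rotation
  if (nrow(out) == 1) as.numeric(out) else out
}

#' Fit a locality preserving projection (LPP) for QT compression
#'
#' Builds a k-nearest-neighbour adjacency graph with heat-kernel weights
#' `exp(-||x_i - x_j||^2 / t)` (`t` defaulting to the mean squared neighbour
#' distance), and solves the generalized eigenproblem
#' `X L X' a = lambda X D X' a` for the `k` smallest eigenvalues, where `L =
#' D - W` is the graph Laplacian. The learned linear map sends neighbouring
#' training points to nearby embeddings, preserving local structure that a
#' global variance criterion can miss. For conditioning the data is first
#' reduced by PCA to its numerical rank, and a small ridge (1e-8) is added
#' to the denominator matrix.
#'
#' @param x Training matrix, beats x 1000 (`m >= k` rows).
#' @param k Embedding dimension (default 32).
#' @param n_neighbors Neighbourhood size for the graph (default 7).
#' @param t Heat-kernel bandwidth; `NULL` for the mean squared neighbour
#'   distance.
#' @return Object of class `qt_lpp`: `projection` (n x k), `center`,
#'   hyperparameters, and the (symmetric, zero-diagonal) weight matrix `W`.
#' @export
lpp_fit <- function(x, k = 32L, n_neighbors = 7L, t = NULL) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < k) {
    stop("need at least ", k, " training rows for LPP, got ", m,
         call. = FALSE)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  d2 <- pairwise_sqdist(xc)
  W <- knn_heat_weights(d2, n_neighbors, t)
  D <- rowSums(W)
  # PCA pre-reduction for conditioning
  sv <- svd(xc, nu = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  rank <- max(rank, k)
  P <- sv$v[, seq_len(rank), drop = FALSE]
  y <- xc %*% P                       # m x rank
  XDX <- crossprod(y * D, y)
  XLX <- XDX - crossprod(y, W %*% y)
  XDX <- XDX + diag(1e-8, rank)
  # generalized symmetric eigenproblem via Cholesky whitening
  R <- chol(XDX)
  Rin <- backsolve(R, diag(rank))
  Mw <- t(Rin) %*% XLX %*% Rin
  Mw <- (Mw + t(Mw)) / 2
  eg <- eigen(Mw, symmetric = TRUE)
  sel <- order(eg$values)[seq_len(k)]
  A <- Rin %*% eg$vectors[, sel, drop = FALSE]
  structure(list(projection = P %*% A, center = ctr, k = k,
                 n_neighbors = n_neighbors, t = attr(W, "t"), W = W,
                 eigenvalues = eg$values[sel]),
            class = "qt_lpp")
}

#' @rdname lpp_fit
#' @param fit A `qt_lpp` object.
#' @param newdata Vector of length 1000 or matrix with 1000 columns.
#' @export
lpp_transform <- function(fit, newdata) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  out <- sweep(newdata, 2, fit$center) %*% fit$projection
  if (nrow(out) == 1) as.numeric(out) else out
}

pairwise_sqdist <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

# Symmetrized kNN heat-kernel weights with zero diagonal.
knn_heat_weights <- function(d2, n_neighbors, t = NULL) {
  m <- nrow(d2)
  nn <- min(n_neighbors, m - 1L)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != i][seq_len(nn)]
    adj[i, ord] <- TRUE
  }
  adj <- adj | t(adj)
  if (is.null(t)) {
    t <- mean(d2[adj])
    if (!is.finite(t) || t <= 0) t <- 1
  }
  W <- matrix(0, m, m)
  W[adj] <- exp(-d2[adj] / t)
  diag(W) <- 0
  attr(W, "t") <- t
  W
}

#' LPP graph-smoothness objective
#'
#' Evaluates `sum_ij ||y_i - y_j||^2 W_ij` for an embedding `Y = X A`; the
#' quantity LPP minimizes (subject to the `X D X'` normalization).
#'
#' @param y Embedded coordinates, m x k.
#' @param W Symmetric weight matrix.
#' @return Scalar objective value.
#' @export
lpp_objective <- function(y, W) {
  D <- rowSums(W)
  L <- diag(D) - W
  sum(diag(crossprod(y, L %*% y)))
}

#' Fit a QT compressor
#'
#' Unified front end over the three 1000-to-32 compression backends: `"dwt"`
#' (training-free wavelet approximation), `"pca"`, `"lpp"`. Fit on training
#' rows only; apply anywhere with [compress_apply()].
#'
#' @param x Training matrix (beats x 1000); ignored for `"dwt"`.
#' @param method One of `"dwt"`, `"pca"`, `"lpp"`.
#' @param k Output dimension (default 32).
#' @param ... Passed to the backend fit.
#' @return A `qt_compressor` object.
#' @export
compress_fit <- function(x = NULL, method = c("dwt", "pca", "lpp"), k = 32L,
                         ...) {
  method <- match.arg(method)
  fit <- switch(method,
    dwt = NULL,
    pca = pca_fit(x, k = k, ...),
    lpp = lpp_fit(x, k = k, ...)
  )
  structure(list(method = method, k = k, fit = fit),
            class = "qt_compressor")
}

#' @rdname compress_fit
#' @param comp A `qt_compressor`.
#' @param newdata Vector of length 1000 or matrix with 1000 columns.
#' @export
compress_apply <- function(comp, newdata) {
  switch(comp$method,
    dwt = dwt_compress(newdata),
    pca = pca_transform(comp$fit, newdata),
    lpp = lpp_transform(comp$fit, newdata)
  )
}

#' Fuse per-lead features into the final vector
#'
#' Builds the wide modelling table from the tidy per-(beat, lead) feature
#' table: per lead, the 7 rule features then the 32 compressed QT values, in
#' fixed lead order, giving 12 x 39 = 468 columns for the fused set
#' (84 rule-only, 384 ventricular-only). Column names are
#' `<lead>_<feature>` (e.g. `V2_j_relative`, `V2_qt_07`).
#'
#' @param features Tidy feature tibble from [extract_features()].
#' @param compressor A `qt_compressor`, a named list of per-lead
#'   `qt_compressor`s (as fitted inside cross-validation folds), or `NULL`
#'   when `feature_set = "rule"`.
#' @param feature_set `"fused"`, `"rule"`, or `"ventricular"`.
#' @param leads Lead order (default [ECG_LEADS] restricted to leads
#'   present).
#' @return Wide tibble: `beat`, `label` (if present), then feature columns.
#'   Beats missing any lead are dropped.
#' @export
fuse_features <- function(features, compressor = NULL,
                          feature_set = c("fused", "rule", "ventricular"),
                          leads = NULL) {
  feature_set <- match.arg(feature_set)
  if (is.null(leads)) leads <- intersect(ECG_LEADS, unique(features$lead))
  keep <- features |>
    dplyr::count(.data$beat) |>
    dplyr::filter(.data$n == length(leads)) |>
    dplyr::pull(.data$beat)
  feats <- features[features$beat %in% keep & features$lead %in% leads, ]
  beats <- sort(unique(feats$beat))
  use_rule <- feature_set %in% c("fused", "rule")
  use_vent <- feature_set %in% c("fused", "ventricular")
  if (use_vent && is.null(compressor)) {
    stop("a compressor is required for ventricular features", call. = FALSE)
  }
  blocks <- list()
  for (ld in leads) {
    fl <- feats[feats$lead == ld, ]
    fl <- fl[order(fl$beat), ]
    if (use_rule) {
      rb <- as.matrix(fl[, RULE_FEATURE_NAMES])
      colnames(rb) <- paste(ld, RULE_FEATURE_NAMES, sep = "_")
      blocks[[length(blocks) + 1L]] <- rb
    }
    if (use_vent) {
      qtm <- do.call(rbind, fl$qt)
      comp_ld <- if (inherits(compressor, "qt_compressor")) compressor
                 else compressor[[ld]]
      cb <- compress_apply(comp_ld, qtm)
      if (!is.matrix(cb)) cb <- matrix(cb, nrow = 1)
      colnames(cb) <- sprintf("%s_qt_%02d", ld, seq_len(ncol(cb)))
      blocks[[length(blocks) + 1L]] <- cb
    }
  }
  wide <- tibble::as_tibble(as.data.frame(do.call(cbind, blocks)))
  out <- tibble::tibble(beat = beats)
  if ("label" %in% names(feats)) {
    lab <- feats |>
      dplyr::distinct(.data$beat, .data$label) |>
      dplyr::arrange(.data$beat)
    out$label <- lab$label
  }
  dplyr::bind_cols(out, wide)
}

#' QT matrix for one lead from a tidy feature table
#'
#' Convenience accessor: the per-beat 1000-sample QT vectors of one lead
#' stacked as rows (beats ordered by beat number).
#'
#' @param features Tidy feature tibble from [extract_features()].
#' @param lead Lead name.
#' @return Matrix, beats x 1000.
#' @export
qt_matrix <- function(features, lead) {
  fl <- features[features$lead == lead, ]
  fl <- fl[order(fl$beat), ]
  do.call(rbind, fl$qt)
}
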