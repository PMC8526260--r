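#' Wavelet denoising of an ECG record
#'
#' Removes baseline drift and high-frequency noise per lead by multilevel
#' discrete wavelet decomposition and selective reconstruction: the coarsest
#' approximation band (which carries the sub-hertz drift) is zeroed, the two
#' finest detail bands are soft-thresholded with the universal threshold
#' `sigma * sqrt(2 log n)` (sigma estimated from the median absolute
#' deviation of the finest detail band), and the signal is reconstructed.
#' Intermediate bands — which carry the QRS energy the downstream features
#' depend on — are left untouched.
#'
#' @param record An `ecg_record`.
#' @param basis Wavelet basis; default `"db6"`.
#' @param levels Decomposition depth, or `NULL` to choose
#'   `ceiling(log2(fs / 0.7))` (capped at 9 and by the record length) so the
#'   retained approximation band falls below roughly 0.7 Hz.
#' @return A denoised `ecg_record` with the same shape and attributes.
#' @export
ecg_denoise <- function(record, basis = "db6", levels = NULL) {
  fs <- ecg_fs(record)
  stopifnot(!is.null(fs))
  m <- ecg_matrix(record)
  n <- nrow(m)
  L <- length(wavelet_filter(basis))
  max_lev <- floor(log2(n / L)) + 1L
  if (is.null(levels)) {
    levels <- min(ceiling(log2(fs / 0.7)), 9L, max_lev)
  }
  if (levels > max_lev) {
    stop("record too short for ", levels, " decomposition levels",
         call. = FALSE)
  }
  out <- m
  for (k in seq_len(ncol(m))) {
    out[, k] <- denoise_lead(m[, k], basis, levels)
  }
  res <- record
  res[, colnames(m)] <- tibble::as_tibble(as.data.frame(out))
  res
}

denoise_lead <- function(x, basis, levels) {
  pyr <- dwt(x, basis = basis, levels = levels)
  # drop the drift band
  pyr$approx[] <- 0
  # universal soft threshold on the two finest detail bands
  d1 <- pyr$detail[[1]]
  sigma <- stats::median(abs(d1)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  for (lev in seq_len(min(2L, levels))) {
    pyr$detail[[lev]] <- soft_threshold(pyr$detail[[lev]], thr)
  }
  idwt(pyr)
}

# Band energy between lo and hi Hz via the periodogram (used in tests and
# sanity checks).
band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(sp[f >= lo & f <= hi])
}
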