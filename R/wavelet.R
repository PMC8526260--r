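#' Daubechies scaling filters
#'
#' Returns the orthonormal scaling (lowpass) filter for a named Daubechies
#' basis. Coefficients are the standard published values, normalised so that
#' `sum(h) = sqrt(2)` and `sum(h^2) = 1`.
#'
#' @param basis Basis name, one of `"db4"` or `"db6"` (number of vanishing
#'   moments; filter lengths 8 and 12).
#' @return Numeric vector of filter taps.
#' @export
wavelet_filter <- function(basis) {
  switch(basis,
    db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
            0.0328830116668852, -0.010597401785069032),
    db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
            0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
            0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
            0.0005538422011614961, 0.004777257510945511,
            -0.0010773010853084796),
    stop("unknown wavelet basis: '", basis, "' (supported: db4, db6)",
         call. = FALSE)
  )
}

# Quadrature mirror highpass from the scaling filter.
qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

# One circular analysis step. Rows of the implied transform matrix are the
# filters shifted by 2, so the transform is exactly orthonormal and the
# synthesis step is its transpose.
dwt_step <- function(x, h) {
  n <- length(x)
  if (n %% 2L != 0L) stop("dwt_step requires even length", call. = FALSE)
  g <- qmf(h)
  half <- n / 2L
  L <- length(h)
  # x[(m + 2k) mod n] for k = 0..half-1, m = 0..L-1
  idx <- outer(seq_len(L) - 1L, 2L * (seq_len(half) - 1L), "+") %% n + 1L
  xm <- matrix(x[idx], nrow = L)
  list(approx = as.numeric(crossprod(xm, h)),
       detail = as.numeric(crossprod(xm, g)))
}

idwt_step <- function(approx, detail, h) {
  half <- length(approx)
  n <- 2L * half
  g <- qmf(h)
  L <- length(h)
  x <- numeric(n)
  ks <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(L)) {
    pos <- (ks + (m - 1L)) %% n + 1L
    contrib <- approx * h[m] + detail * g[m]
    # positions repeat only if n < L; accumulate safely
    x[pos] <- x[pos] + contrib
  }
  x
}

#' Multilevel discrete wavelet transform
#'
#' Decomposes a signal into a coefficient pyramid (one approximation band and
#' one detail band per level) using circular (periodized) boundary handling.
#' With an orthonormal Daubechies filter the transform is exactly orthogonal:
#' energy is preserved and [idwt()] reconstructs the input to machine
#' precision. Odd-length inputs at any level are padded by repeating the last
#' sample; the original lengths are recorded so the inverse restores them.
#'
#' @param x Numeric signal.
#' @param basis Wavelet basis name (see [wavelet_filter()]).
#' @param levels Number of decomposition levels (>= 1).
#' @return Object of class `ecg_dwt`: list with `approx` (coarsest
#'   approximation), `detail` (list, finest level first), `basis`, `lengths`.
#' @export
dwt <- function(x, basis = "db4", levels = 1L) {
  h <- wavelet_filter(basis)
  stopifnot(levels >= 1L)
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- as.numeric(x)
  for (lev in seq_len(levels)) {
    if (length(cur) < length(h)) {
      stop("signal too short for ", levels, " levels with basis ", basis,
           " (need length >= filter length at every level)", call. = FALSE)
    }
    lengths[lev] <- length(cur)
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    st <- dwt_step(cur, h)
    details[[lev]] <- st$detail
    cur <- st$approx
  }
  structure(list(approx = cur, detail = details, basis = basis,
                 lengths = lengths),
            class = "ecg_dwt")
}

#' Inverse multilevel discrete wavelet transform
#'
#' @param pyramid An `ecg_dwt` object from [dwt()].
#' @return Reconstructed numeric signal of the original length.
#' @export
idwt <- function(pyramid) {
  h <- wavelet_filter(pyramid$basis)
  cur <- pyramid$approx
  for (lev in rev(seq_along(pyramid$detail))) {
    cur <- idwt_step(cur, pyramid$detail[[lev]], h)
    cur <- cur[seq_len(pyramid$lengths[lev])]
  }
  cur
}

# Mexican hat (Ricker) mother wavelet, unit energy.
ricker <- function(t) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)
}

#' Continuous wavelet transform with the Mexican-hat kernel
#'
#' Computes CWT coefficients at the requested scales by FFT convolution with
#' the Ricker (Mexican hat) wavelet. The Mexican hat's centre frequency is
#' 0.25 cycles/sample at scale 1, so a pseudo-frequency f (Hz) maps to scale
#' `0.25 * fs / f`.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param freqs Pseudo-frequencies (Hz) at which to analyse.
#' @return Matrix `length(x)` x `length(freqs)` of coefficients.
#' @export
cwt_mexh <- function(x, fs, freqs = c(5, 7.5, 10, 15)) {
  n <- length(x)
  out <- matrix(0, n, length(freqs))
  for (k in seq_along(freqs)) {
    a <- 0.25 * fs / freqs[k]
    half <- ceiling(5 * a)
    t <- (-half):half
    kern <- ricker(t / a) / sqrt(a)
    out[, k] <- conv_same(x, kern)
  }
  out
}

# Zero-padded "same" convolution with a centred odd-length kernel, done by
# FFT at a 2-3-5-smooth length (arbitrary record lengths would otherwise hit
# quadratic mixed-radix FFTs).
conv_same <- function(x, kern) {
  n <- length(x)
  m <- length(kern)
  half <- (m - 1L) / 2L
  N <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  fx <- stats::fft(c(x, numeric(N - n)))
  fk <- stats::fft(c(kern, numeric(N - m)))
  full <- Re(stats::fft(fx * fk, inverse = TRUE)) / N
  full[(half + 1L):(half + n)]
}

# Universal-threshold soft shrinkage used by the denoiser.
soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)
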