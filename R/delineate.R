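#' QRS detection by Mexican-hat multiscale decomposition
#'
#' Computes the continuous wavelet transform of one lead at scales spanning
#' the QRS band (5–15 Hz) with the Mexican-hat kernel, forms the cross-scale
#' product (which reinforces energy present at every scale and suppresses
#' isolated artefacts), and thresholds it at 0.4 times a rolling 2-second RMS.
#' Local maxima of the product above the threshold, separated by a 200 ms
#' refractory window, become R peaks. The threshold is relative, so detection
#' is invariant to overall amplitude scaling.
#'
#' @param x Numeric vector, one denoised lead (mV).
#' @param fs Sampling rate, Hz.
#' @param freqs Pseudo-frequencies (Hz) of the analysis scales.
#' @param threshold_frac Fraction of the rolling RMS used as threshold.
#' @param refractory Minimum distance between peaks, s.
#' @return Sorted integer vector of R-peak sample indices (1-based).
#' @export
detect_r_peaks <- function(x, fs, freqs = c(5, 7.5, 10, 15),
                           threshold_frac = 0.4, refractory = 0.2) {
  if (length(x) < 2 * fs) {
    stop("record shorter than 2 s; cannot detect QRS complexes",
         call. = FALSE)
  }
  W <- cwt_mexh(x, fs, freqs)
  # cross-scale product; keep sign-consistent energy only
  prod_pos <- apply(pmax(W, 0), 1, prod)
  prod_neg <- apply(pmax(-W, 0), 1, prod)
  p <- prod_pos + prod_neg
  thr <- threshold_frac * rolling_rms(p, round(2 * fs))
  cand <- which(p > thr & p > 0)
  if (length(cand) == 0) return(integer(0))
  # local maxima with refractory spacing, strongest first
  ord <- cand[order(p[cand], decreasing = TRUE)]
  min_gap <- round(refractory * fs)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 || all(abs(keep - i) >= min_gap)) {
      keep <- c(keep, i)
    }
  }
  # refine each detection to the nearest extremum of the raw lead
  half <- round(0.05 * fs)
  n <- length(x)
  refined <- vapply(keep, function(i) {
    w <- max(1, i - half):min(n, i + half)
    w[which.max(abs(x[w] - stats::median(x[w])))]
  }, integer(1))
  sort(unique(refined))
}

rolling_rms <- function(p, win) {
  n <- length(p)
  win <- max(2L, min(win, n))
  cs <- cumsum(c(0, p^2))
  lo <- pmax(0L, seq_len(n) - win %/% 2L - 1L) + 1L
  hi <- pmin(n, seq_len(n) + win %/% 2L)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Delineate all fiducial points of one beat
#'
#' Starting from a detected R peak: Q and S are the nearest local extrema of
#' polarity opposite to R within 80 ms before/after R; the QRS onset (I
#' point) is the last sample before Q where the absolute slope falls below
#' 10% of the maximum QRS slope (searched up to 40 ms before Q), and the J
#' point is found symmetrically after S. The T search window is
#' `[J + 80 ms, J + 0.6 RR]`; the T peak is the sample with the largest
#' absolute deviation from the I-point baseline, and T onset/end are where
#' the absolute slope first drops below 10% of the maximal T-wave slope,
#' scanning outwards from the peak. The P peak (optional) is the largest
#' baseline deviation in `[R - 0.30 RR, R - 0.10 RR]`.
#'
#' @param x One lead (numeric, mV).
#' @param r_pos R-peak index (1-based).
#' @param rr Local RR interval, s.
#' @param fs Sampling rate, Hz.
#' @param slope_frac Slope fraction defining onsets/offsets.
#' @param slope Optional precomputed slope vector `c(0, diff(x)) * fs`
#'   (avoids recomputation when delineating many beats of one lead).
#' @return Named list of indices (`i`, `q`, `r`, `s`, `j`, `t_start`,
#'   `t_peak`, `t_end`, `p`), or a zero-length list of class
#'   `"ecg_beat_drop"` whose `"reason"` attribute says why the beat was
#'   dropped.
#' @export
delineate_beat <- function(x, r_pos, rr, fs, slope_frac = 0.10,
                           slope = NULL) {
  n <- length(x)
  ms <- function(k) round(k * fs / 1000)
  drop_beat <- function(reason) {
    structure(list(), class = "ecg_beat_drop", reason = reason)
  }
  w80 <- ms(80)
  if (r_pos - w80 - ms(40) < 1 || r_pos + round(0.6 * rr * fs) > n) {
    return(drop_beat("window exceeds record bounds"))
  }
  r_sign <- sign(x[r_pos] - stats::median(
    x[max(1, r_pos - round(0.4 * rr * fs)):min(n, r_pos + round(0.4 * rr * fs))]))
  if (r_sign == 0) r_sign <- 1
  # Q: nearest opposite-polarity local extremum before R
  q_pos <- nearest_extremum(x, r_pos, -w80, -r_sign)
  s_pos <- nearest_extremum(x, r_pos, w80, -r_sign)
  if (is.na(q_pos) || is.na(s_pos)) return(drop_beat("no Q/S extremum"))
  if (is.null(slope)) slope <- c(0, diff(x)) * fs
  qrs_slope <- max(abs(slope[q_pos:s_pos]))
  thr <- slope_frac * qrs_slope
  i_pos <- onset_scan(slope, q_pos, -ms(40), thr)
  j_pos <- onset_scan(slope, s_pos, ms(40), thr)
  # T wave search
  t_lo <- j_pos + ms(80)
  t_hi <- min(n, j_pos + round(0.6 * rr * fs))
  if (t_lo >= t_hi) return(drop_beat("empty T window"))
  base <- x[i_pos]
  t_peak <- t_lo + which.max(abs(x[t_lo:t_hi] - base)) - 1L
  t_slope_max <- max(abs(slope[t_lo:t_hi]))
  t_thr <- slope_frac * t_slope_max
  t_start <- onset_scan(slope, t_peak, -(t_peak - t_lo), t_thr)
  t_end <- onset_scan(slope, t_peak, t_hi - t_peak, t_thr)
  # optional P peak
  p_lo <- max(1, r_pos - round(0.30 * rr * fs))
  p_hi <- max(1, r_pos - round(0.10 * rr * fs))
  p_pos <- if (p_hi > p_lo) {
    p_lo + which.max(abs(x[p_lo:p_hi] - base)) - 1L
  } else NA_integer_
  fid <- list(i = i_pos, q = q_pos, r = r_pos, s = s_pos, j = j_pos,
              t_start = t_start, t_peak = t_peak, t_end = t_end, p = p_pos)
  ok <- with(fid, i <= q && q <= r && r <= s && s <= j && j < t_start &&
               t_start <= t_peak && t_peak <= t_end)
  if (!ok) return(drop_beat("fiducial ordering violated"))
  fid
}

# Nearest local extremum of the given sign within `span` samples of r_pos
# (negative span searches backwards). Falls back to the windowed extremum.
nearest_extremum <- function(x, r_pos, span, sgn) {
  n <- length(x)
  idx <- if (span < 0) seq(r_pos - 1L, max(1L, r_pos + span)) else
    seq(r_pos + 1L, min(n, r_pos + span))
  if (length(idx) < 3) return(NA_integer_)
  v <- sgn * x[idx]
  # local maxima of v
  loc <- which(diff(sign(diff(v))) < 0) + 1L
  if (length(loc) > 0) return(idx[loc[1L]])
  idx[which.max(v)]
}

# Scan outward from an extremum at `from` by up to `span` samples (sign gives
# direction): first cross the flank's slope maximum, then return the first
# index past it where |slope| < thr (else the window edge). Starting the
# threshold test only after the flank peak keeps the near-zero slope at the
# extremum itself from terminating the scan immediately.
# The effective threshold is capped at 25% of the flank's own slope maximum,
# so that low-amplitude waves (whose flank slope may sit entirely below 10%
# of the QRS maximum) still get their onset at the foot of the flank rather
# than at its crest.
onset_scan <- function(slope, from, span, thr, local_frac = 0.25) {
  if (span == 0) return(from)
  step <- sign(span)
  path <- from + step * seq_len(abs(span))
  path <- path[path >= 1 & path <= length(slope)]
  if (length(path) == 0) return(from)
  s <- abs(slope[path])
  # the wave's own flank is the FIRST substantial local slope maximum along
  # the path; the global maximum may belong to a neighbouring wave (e.g. the
  # next beat's P) and would drag the offset outward
  m <- which.max(s)
  cand <- which(diff(sign(diff(c(-Inf, s, -Inf)))) < 0)
  cand <- cand[s[cand] >= local_frac * s[m]]
  if (length(cand) > 0) m <- cand[1]
  thr <- min(thr, local_frac * s[m])
  for (k in m:length(path)) {
    if (s[k] < thr) return(path[k])
  }
  # no sub-threshold point (overlapping neighbouring wave): take the
  # flattest point past the flank instead of the window edge
  path[m - 1L + which.min(s[m:length(path)])]
}

#' Delineate every beat of every lead of a record
#'
#' Runs [detect_r_peaks()] on a reference lead (II by default), then
#' delineates each beat independently on every lead, matching beats across
#' leads by the nearest R peak within 150 ms.
#'
#' @param record An `ecg_record` (ideally denoised).
#' @param leads Leads to delineate; default all.
#' @param ref_lead Lead used for QRS detection.
#' @return Tibble with columns `beat`, `lead`, and fiducial index columns
#'   `i, q, r, s, j, t_start, t_peak, t_end, p` (1-based samples). Beats that
#'   fail delineation on a lead are absent from that lead's rows; dropped
#'   beats are recorded in the `"drops"` attribute.
#' @export
delineate_record <- function(record, leads = NULL, ref_lead = "II") {
  fs <- ecg_fs(record)
  m <- ecg_matrix(record)
  if (is.null(leads)) leads <- colnames(m)
  r_ref <- detect_r_peaks(m[, ref_lead], fs)
  if (length(r_ref) < 1) {
    return(tibble::tibble(beat = integer(), lead = character()))
  }
  rr_all <- stats::median(diff(r_ref)) / fs
  rows <- list()
  drops <- list()
  for (ld in leads) {
    x <- m[, ld]
    slope_ld <- c(0, diff(x)) * fs
    for (b in seq_along(r_ref)) {
      # refine the reference R to this lead's extremum within 150 ms
      half <- round(0.15 * fs)
      w <- max(1, r_ref[b] - half):min(nrow(m), r_ref[b] + half)
      r_ld <- w[which.max(abs(x[w] - stats::median(x[w])))]
      rr <- if (b < length(r_ref)) (r_ref[b + 1] - r_ref[b]) / fs else rr_all
      fid <- delineate_beat(x, r_ld, rr, fs, slope = slope_ld)
      if (inherits(fid, "ecg_beat_drop")) {
        drops[[length(drops) + 1L]] <-
          tibble::tibble(beat = b, lead = ld,
                         reason = attr(fid, "reason") %||% "unknown")
        next
      }
      rows[[length(rows) + 1L]] <-
        tibble::tibble(beat = b, lead = ld, !!!fid)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "drops") <- dplyr::bind_rows(drops)
  attr(out, "fs") <- fs
  out
}

#' Match detected events against reference events
#'
#' Greedy one-to-one matching of two sorted index lists within a tolerance,
#' reporting the wave-detection convention metrics: sensitivity
#' `Se = TP/(TP+FN)`, positive predictivity `+p = TP/(TP+FP)` and accuracy
#' `Acc = TP/(TP+FP+FN)`, each in percent.
#'
#' @param detected,truth Sorted integer vectors of sample indices.
#' @param tolerance_ms Matching tolerance, ms.
#' @param fs Sampling rate, Hz.
#' @return One-row tibble: `tp`, `fp`, `fn`, `se`, `ppv`, `acc`.
#' @export
match_detections <- function(detected, truth, tolerance_ms = 50, fs = 1000) {
  if (tolerance_ms < 0) stop("tolerance must be nonnegative", call. = FALSE)
  tol <- tolerance_ms * fs / 1000
  used <- logical(length(truth))
  tp <- 0L
  for (d in detected) {
    cand <- which(!used & abs(truth - d) <= tol)
    if (length(cand) > 0) {
      j <- cand[which.min(abs(truth[cand] - d))]
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 se = pct(tp, tp + fn),
                 ppv = pct(tp, tp + fp),
                 acc = pct(tp, tp + fp + fn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
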