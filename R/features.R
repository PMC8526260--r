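#' Rule features for one delineated lead-beat
#'
#' The seven clinically grounded scalars computed from fiducial amplitudes
#' and positions, all relative to the beat's own baseline (the amplitude at
#' the QRS onset, the "I point"):
#' \describe{
#'   \item{j_relative}{`J_amp - I_amp` (mV): J-point deviation, the primary
#'     ST-shift indicator.}
#'   \item{st_relative}{`Tstart_amp - J_amp` (mV): ST-segment course.}
#'   \item{q_ratio}{`(Q_amp - I_amp) / (R_amp - I_amp)`: Q depth as a
#'     fraction of R height (abnormal Q criterion).}
#'   \item{q_interval}{`(Q_pos - I_pos) / SR` (s): Q-wave duration.}
#'   \item{t_ratio}{`(T_amp - I_amp) / (R_amp - I_amp)`: T height relative
#'     to R (hyperacute / flat T criterion).}
#'   \item{tstart_relative}{`T_amp - Tstart_amp` (mV).}
#'   \item{tend_relative}{`T_amp - Tend_amp` (mV): with `tstart_relative`,
#'     T-wave upright vs inverted.}
#' }
#' Every formula is a difference, or a ratio of differences, against the
#' I-point baseline, so the features are exactly invariant to adding a
#' constant to the lead.
#'
#' @param x One lead (numeric, mV).
#' @param fid Fiducial list (as returned by [delineate_beat()]).
#' @param fs Sampling rate `SR`, Hz.
#' @return One-row tibble with the seven features, or `NULL` if
#'   `R_amp == I_amp` (degenerate beat, zero denominator).
#' @export
rule_features <- function(x, fid, fs) {
  i_amp <- x[fid$i]; q_amp <- x[fid$q]; r_amp <- x[fid$r]
  j_amp <- x[fid$j]; t_amp <- x[fid$t_peak]
  ts_amp <- x[fid$t_start]; te_amp <- x[fid$t_end]
  r_rel <- r_amp - i_amp
  if (r_rel == 0) return(NULL)
  tibble::tibble(
    j_relative = j_amp - i_amp,
    st_relative = ts_amp - j_amp,
    q_ratio = (q_amp - i_amp) / r_rel,
    q_interval = (fid$q - fid$i) / fs,
    t_ratio = (t_amp - i_amp) / r_rel,
    tstart_relative = t_amp - ts_amp,
    tend_relative = t_amp - te_amp
  )
}

#' Names of the seven rule features, in order
#' @export
RULE_FEATURE_NAMES <- c("j_relative", "st_relative", "q_ratio", "q_interval",
                        "t_ratio", "tstart_relative", "tend_relative")

#' QT-segment ventricular activity feature
#'
#' Extracts the samples on the closed span from QRS onset (I point) to T-wave
#' end and resamples them to exactly 1000 points by linear interpolation on a
#' uniform grid including both endpoints. The QT segment spans ventricular
#' depolarization and repolarization, so this vector is a complete record of
#' ventricular activity for the beat.
#'
#' @param x One lead (numeric, mV).
#' @param fid Fiducial list with `i` and `t_end`.
#' @param n_out Output length (default 1000).
#' @return Numeric vector of length `n_out`, or `NULL` if the span is
#'   shorter than 8 samples.
#' @export
extract_qt <- function(x, fid, n_out = 1000L) {
  span <- fid$i:fid$t_end
  if (length(span) < 8) return(NULL)
  seg <- x[span]
  if (length(seg) == n_out) return(seg)
  stats::approx(seq_along(seg), seg, n = n_out)$y
}

#' Per-beat feature table for a 12-lead record
#'
#' Delineates (or reuses supplied fiducials for) every lead, computes the
#' seven rule features and the 1000-sample QT vector per lead-beat, and
#' returns a tidy table with one row per (beat, lead). Beats missing any
#' requested lead, failing delineation, hitting a zero R-I denominator, or
#' whose QT span collides with the next beat's onset are dropped whole.
#'
#' @param record An `ecg_record`.
#' @param fiducials Optional fiducial tibble from [delineate_record()];
#'   computed if missing.
#' @param labels Optional per-beat label vector (indexed by beat number); for
#'   simulated records defaults to the ground-truth labels.
#' @param leads Leads to use (default all 12).
#' @return Tibble: `beat`, `label`, `lead`, the seven rule features, and a
#'   `qt` list-column of 1000-vectors.
#' @export
extract_features <- function(record, fiducials = NULL, labels = NULL,
                             leads = NULL) {
  fs <- ecg_fs(record)
  m <- ecg_matrix(record)
  if (is.null(leads)) leads <- colnames(m)
  if (is.null(fiducials)) fiducials <- delineate_record(record, leads = leads)
  if (is.null(labels)) {
    tr <- ecg_truth(record)
    if (!is.null(tr)) labels <- tr$label
  }
  rows <- list()
  for (b in sort(unique(fiducials$beat))) {
    fb <- fiducials[fiducials$beat == b, ]
    if (!all(leads %in% fb$lead)) next
    # QT purity: the span must end before the next beat's onset
    nxt <- fiducials$i[fiducials$beat == b + 1]
    if (length(nxt) > 0 && any(fb$t_end >= min(nxt))) next
    lead_rows <- vector("list", length(leads))
    ok <- TRUE
    for (li in seq_along(leads)) {
      ld <- leads[li]
      fid <- as.list(fb[fb$lead == ld, ])
      x <- m[, ld]
      rf <- rule_features(x, fid, fs)
      qt <- extract_qt(x, fid)
      if (is.null(rf) || is.null(qt)) { ok <- FALSE; break }
      lead_rows[[li]] <- dplyr::bind_cols(
        tibble::tibble(beat = b, lead = ld), rf,
        tibble::tibble(qt = list(qt)))
    }
    if (ok) rows[[length(rows) + 1L]] <- dplyr::bind_rows(lead_rows)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0 && !is.null(labels)) {
    out <- tibble::add_column(out, label = labels[out$beat], .after = "beat")
  }
  out
}
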