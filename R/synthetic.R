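#' Synthetic 12-lead ECG generation
#'
#' Beats are modelled as a sum of five Gaussian bumps (P, Q, R, S, T) plus a
#' raised-cosine-edged ST plateau between the J point and T-wave onset. Every
#' beat carries exact, analytically known fiducial sample indices, so
#' delineation and feature extraction can be tested against ground truth.
#' Class archetypes reproduce the textbook infarction signatures — abnormal
#' (deep, wide) Q waves, ST-segment elevation or depression, hyperacute or
#' inverted T waves — each confined to a clinically motivated subset of the
#' 12 leads. The lead assignments are documented constants, not a claim of
#' clinical fidelity.
#'
#' @name synthetic_ecg
NULL

# Baseline (healthy) wave parameters: centre offset from R (s), amplitude
# (mV), width (Gaussian sigma, s).
normal_waves <- function() {
  tibble::tibble(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(-0.20, -0.040, 0.0, 0.040, 0.30),
    amp    = c(0.12, -0.08, 1.00, -0.18, 0.30),
    width  = c(0.030, 0.010, 0.012, 0.010, 0.055)
  )
}

# Class archetypes: which leads carry the abnormality and how the affected
# waves deviate from the healthy template. q = c(amp, width); t = c(amp,
# center); r = amp; st = plateau offset (mV). NULL means "as healthy".
mi_archetypes <- function() {
  list(
    A   = list(leads = c("V2", "V3", "V4"),
               st = 0.22, t = c(0.55, 0.30)),
    AS  = list(leads = c("V1", "V2", "V3", "V4"),
               st = 0.20, t = c(-0.35, 0.30)),
    AL  = list(leads = c("I", "aVL", "V4", "V5", "V6"),
               st = 0.18, q = c(-0.35, 0.020), t = c(0.35, 0.30)),
    I   = list(leads = c("II", "III", "aVF"),
               st = 0.00, q = c(-0.38, 0.022), t = c(-0.28, 0.30)),
    IL  = list(leads = c("II", "III", "aVF", "V5", "V6"),
               st = 0.12, q = c(-0.32, 0.020), t = c(-0.25, 0.30)),
    IP  = list(leads = c("II", "III", "aVF", "V1", "V2"),
               st = -0.15, q = c(-0.30, 0.020), t = c(0.45, 0.30)),
    IPL = list(leads = c("II", "III", "aVF", "V5", "V6", "V1", "V2"),
               st = 0.12, q = c(-0.30, 0.018), t = c(-0.30, 0.30)),
    P   = list(leads = c("V1", "V2", "V3"),
               st = -0.18, r = 1.40, t = c(0.50, 0.30)),
    H   = list(leads = character(0), st = 0.00),
    O   = list(leads = ECG_LEADS,
               st = 0.00, r = 0.80, t = c(0.12, 0.36))
  )
}

#' Draw a randomized beat morphology for a class
#'
#' Samples wave timing and amplitudes around the class archetype. Timing
#' (centres, widths) is shared between the affected and unaffected leads of a
#' beat so that the true fiducials are a per-beat property; amplitudes and the
#' ST offset differ between the affected-lead and healthy-lead variants.
#' Randomness comes from R's RNG; seed it for reproducibility.
#'
#' @param label Class label, one of [MI_CLASSES].
#' @param jitter_sd Relative SD of the multiplicative jitter applied to
#'   amplitudes, widths and the ST offset; centres get additive jitter of
#'   `3 * jitter_sd` milliseconds SD. Use 0 for the archetype itself.
#' @return A `beat_morphology` list: `waves` (tibble with `wave`, `center`,
#'   `width`, `amp_normal`, `amp_abnormal`), `st_offset` (affected leads, mV),
#'   `leads` (affected lead names), `label`.
#' @export
morphology_for_class <- function(label, jitter_sd = 0.05) {
  arch <- mi_archetypes()[[label]]
  if (is.null(arch)) {
    stop("unknown beat class '", label, "'; expected one of ",
         paste(MI_CLASSES, collapse = ", "), call. = FALSE)
  }
  w <- normal_waves()
  ab <- w$amp
  if (!is.null(arch$q)) {
    ab[w$wave == "Q"] <- arch$q[1]
    w$width[w$wave == "Q"] <- arch$q[2]
  }
  if (!is.null(arch$t)) {
    ab[w$wave == "T"] <- arch$t[1]
    w$center[w$wave == "T"] <- arch$t[2]
  }
  if (!is.null(arch$r)) ab[w$wave == "R"] <- arch$r
  w$amp_abnormal <- ab
  w$amp_normal <- normal_waves()$amp
  names(w)[names(w) == "amp"] <- "amp_template"
  w$amp_template <- NULL
  if (jitter_sd > 0) {
    mult <- function(v) v * exp(stats::rnorm(length(v), 0, jitter_sd))
    w$width <- mult(w$width)
    w$amp_normal <- mult(w$amp_normal)
    w$amp_abnormal <- mult(w$amp_abnormal)
    jit <- stats::rnorm(nrow(w), 0, 3e-3 * jitter_sd / 0.05)
    jit[w$wave == "R"] <- 0
    w$center <- w$center + jit
    st <- arch$st * exp(stats::rnorm(1, 0, jitter_sd))
  } else {
    st <- arch$st
  }
  structure(list(waves = w, st_offset = st, leads = arch$leads,
                 label = label),
            class = "beat_morphology")
}

# True fiducial offsets (seconds, relative to R centre) implied by a
# morphology. QRS onset/end are defined at 2 sigma outside the Q/S bumps; T
# onset/end at 2.5 sigma around the T bump.
true_fiducial_offsets <- function(waves) {
  g <- function(nm, col) waves[[col]][waves$wave == nm]
  list(
    p      = g("P", "center"),
    i      = g("Q", "center") - 2.0 * g("Q", "width"),
    q      = g("Q", "center"),
    r      = g("R", "center"),
    s      = g("S", "center"),
    j      = g("S", "center") + 2.0 * g("S", "width"),
    t_start = g("T", "center") - 2.5 * g("T", "width"),
    t_peak  = g("T", "center"),
    t_end   = g("T", "center") + 2.5 * g("T", "width")
  )
}

# Raised-cosine-edged ST plateau evaluated on times t (s, relative to R).
# Rises from 0.5*w_S after the S centre to the J point, holds, and returns to
# zero at T onset, so the delineated J point sits on the full offset.
st_plateau <- function(t, st_offset, waves) {
  if (st_offset == 0) return(numeric(length(t)))
  s_c <- waves$center[waves$wave == "S"]
  s_w <- waves$width[waves$wave == "S"]
  fid <- true_fiducial_offsets(waves)
  up0 <- s_c + 0.5 * s_w
  up1 <- fid$j
  dn1 <- fid$t_start
  dn0 <- dn1 - min(0.020, 0.25 * (dn1 - up1))
  y <- numeric(length(t))
  ramp <- function(x) (1 - cos(pi * pmin(pmax(x, 0), 1))) / 2
  y[t >= up1 & t <= dn0] <- 1
  rise <- t > up0 & t < up1
  y[rise] <- ramp((t[rise] - up0) / (up1 - up0))
  fall <- t > dn0 & t < dn1
  y[fall] <- ramp((dn1 - t[fall]) / (dn1 - dn0))
  st_offset * y
}

#' Render one single-lead beat from a morphology
#'
#' Evaluates the five-Gaussian bump model plus ST plateau on a uniform grid
#' of `round(rr * fs)` samples, with the R peak placed `r_offset` seconds
#' into the window.
#'
#' @param morph A `beat_morphology` from [morphology_for_class()].
#' @param fs Sampling rate (Hz).
#' @param rr Beat duration (s).
#' @param variant `"abnormal"` (affected-lead amplitudes) or `"normal"`.
#' @param r_offset Position of the R peak within the window (s); default
#'   `0.35 * rr`.
#' @return List: `signal` (numeric vector, mV), `fiducials` (named list of
#'   1-based sample indices within the beat), `n` (samples).
#' @export
make_beat <- function(morph, fs, rr, variant = c("abnormal", "normal"),
                      r_offset = 0.35 * rr) {
  variant <- match.arg(variant)
  w <- morph$waves
  amp <- if (variant == "abnormal") w$amp_abnormal else w$amp_normal
  st <- if (variant == "abnormal") morph$st_offset else 0
  lo <- min(w$center - 2.5 * w$width)
  hi <- max(w$center + 2.5 * w$width)
  if (r_offset + lo < 0 || r_offset + hi > rr) {
    stop("beat morphology does not fit in an RR window of ", rr,
         " s (span ", round(lo, 3), "..", round(hi, 3),
         " s around R)", call. = FALSE)
  }
  n <- as.integer(round(rr * fs))
  t <- (seq_len(n) - 1) / fs - r_offset
  sig <- numeric(n)
  for (k in seq_len(nrow(w))) {
    sig <- sig + amp[k] * exp(-0.5 * ((t - w$center[k]) / w$width[k])^2)
  }
  sig <- sig + st_plateau(t, st, w)
  fid <- true_fiducial_offsets(w)
  idx <- lapply(fid, function(off) as.integer(round((off + r_offset) * fs)) + 1L)
  list(signal = sig, fiducials = idx, n = n)
}

#' Simulate a labelled 12-lead ECG record
#'
#' Concatenates per-beat waveforms (affected-lead morphology on the class's
#' lead subset, healthy morphology elsewhere), scales each lead by
#' `lead_gain`, and adds sinusoidal baseline wander plus white Gaussian
#' noise. The record is a wide tibble (`time` + 12 lead columns, mV) of class
#' `ecg_record`, carrying the sampling rate and a ground-truth fiducial table
#' as attributes.
#'
#' @param classes Character vector of beat labels (one of [MI_CLASSES] each);
#'   its length is the number of beats.
#' @param fs Sampling rate, Hz (>= 250).
#' @param mean_rr Mean RR interval, s.
#' @param rr_jitter_sd SD of per-beat RR jitter, s.
#' @param lead_gain Numeric 12-vector of per-lead scale factors.
#' @param baseline_amp,baseline_freq Baseline-wander sinusoid amplitude (mV)
#'   and frequency (Hz).
#' @param noise_sd SD of additive white noise (mV).
#' @param jitter_sd Morphology jitter passed to [morphology_for_class()].
#' @param seed Optional integer seed; the same seed reproduces the record
#'   bit-for-bit.
#' @return An `ecg_record` tibble with attributes `fs` and `truth` (tibble:
#'   `beat`, `label`, `st_offset`, affected `leads` list-column, and 1-based
#'   sample indices `i`, `q`, `r`, `s`, `j`, `t_start`, `t_peak`, `t_end`,
#'   `p`).
#' @export
simulate_ecg <- function(classes, fs = 1000, mean_rr = 0.8,
                         rr_jitter_sd = 0.02, lead_gain = rep(1, 12),
                         baseline_amp = 0.1, baseline_freq = 0.3,
                         noise_sd = 0.02, jitter_sd = 0.05, seed = NULL) {
  stopifnot(fs >= 250, mean_rr > 0, length(classes) >= 1,
            length(lead_gain) == 12)
  with_seed(seed, {
    n_beats <- length(classes)
    rr <- pmax(mean_rr + stats::rnorm(n_beats, 0, rr_jitter_sd),
               0.75 * mean_rr)
    sig <- vector("list", n_beats)
    truth <- vector("list", n_beats)
    offset <- 0L
    for (b in seq_len(n_beats)) {
      morph <- morphology_for_class(classes[b], jitter_sd = jitter_sd)
      # size the window to the drawn morphology: slow repolarization
      # stretches the beat rather than being rejected
      lo <- min(morph$waves$center - 2.5 * morph$waves$width)
      hi <- max(morph$waves$center + 2.5 * morph$waves$width)
      rr_b <- max(rr[b], hi - lo + 0.03)
      r_off <- max(0.35 * rr_b, -lo + 0.015)
      beat_ab <- make_beat(morph, fs, rr_b, "abnormal", r_offset = r_off)
      beat_no <- make_beat(morph, fs, rr_b, "normal", r_offset = r_off)
      m <- matrix(0, beat_ab$n, 12, dimnames = list(NULL, ECG_LEADS))
      for (ld in ECG_LEADS) {
        m[, ld] <- if (ld %in% morph$leads) beat_ab$signal else beat_no$signal
      }
      sig[[b]] <- m
      truth[[b]] <- tibble::tibble(
        beat = b, label = classes[b], st_offset = morph$st_offset,
        leads = list(morph$leads),
        !!!lapply(beat_ab$fiducials, function(ix) ix + offset)
      )
      offset <- offset + beat_ab$n
    }
    full <- do.call(rbind, sig)
    full <- sweep(full, 2, lead_gain, `*`)
    n <- nrow(full)
    tgrid <- (seq_len(n) - 1) / fs
    if (baseline_amp > 0) {
      phases <- stats::runif(12, 0, 2 * pi)
      for (k in 1:12) {
        full[, k] <- full[, k] +
          baseline_amp * sin(2 * pi * baseline_freq * tgrid + phases[k])
      }
    }
    if (noise_sd > 0) {
      full <- full + matrix(stats::rnorm(n * 12, 0, noise_sd), n, 12)
    }
    rec <- tibble::as_tibble(as.data.frame(full))
    names(rec) <- ECG_LEADS
    rec <- tibble::add_column(rec, time = tgrid, .before = 1)
    structure(rec, fs = fs, truth = dplyr::bind_rows(truth),
              class = c("ecg_record", class(rec)))
  })
}

#' Sampling rate of an ECG record
#' @param record An `ecg_record`.
#' @return Sampling rate in Hz.
#' @export
ecg_fs <- function(record) attr(record, "fs")

#' Ground-truth fiducial table of a simulated record
#' @param record An `ecg_record` from [simulate_ecg()].
#' @return Truth tibble, or `NULL` for records read from files.
#' @export
ecg_truth <- function(record) attr(record, "truth")

#' Construct an `ecg_record` from a samples-by-leads table
#'
#' @param data Data frame or matrix of samples (rows) by leads (columns), mV.
#' @param fs Sampling rate, Hz.
#' @param leads Lead names; defaults to `colnames(data)` or [ECG_LEADS].
#' @return An `ecg_record` tibble.
#' @export
as_ecg_record <- function(data, fs, leads = NULL) {
  m <- as.data.frame(data)
  if (is.null(leads)) {
    leads <- if (!is.null(colnames(data))) colnames(data)
             else ECG_LEADS[seq_len(ncol(m))]
  }
  names(m) <- leads
  rec <- tibble::as_tibble(m)
  rec <- tibble::add_column(rec, time = (seq_len(nrow(m)) - 1) / fs,
                            .before = 1)
  structure(rec, fs = fs, class = c("ecg_record", class(rec)))
}

#' Lead columns of a record as a plain samples-by-leads matrix
#' @param record An `ecg_record`.
#' @return Numeric matrix (mV) with lead names as columns.
#' @export
ecg_matrix <- function(record) {
  as.matrix(record[, setdiff(names(record), "time"), drop = FALSE])
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record: %d samples x %d leads @ %g Hz (%.1f s)>\n",
              nrow(x), ncol(x) - 1L, ecg_fs(x), nrow(x) / ecg_fs(x)))
  NextMethod()
}
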