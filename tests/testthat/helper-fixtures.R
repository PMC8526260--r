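# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, .fixture_env)) assign(key, build(), .fixture_env)
  get(key, .fixture_env)
}

# Small 3-class record with default noise, denoised, with tidy features.
fixture_small <- function() {
  memo("small", function() {
    rec <- simulate_ecg(rep(c("H", "A", "I"), times = 30), seed = 101)
    den <- ecg_denoise(rec)
    feats <- extract_features(den)
    list(record = rec, denoised = den, features = feats,
         truth = ecg_truth(rec))
  })
}

# Noiseless record covering all ten classes, for exact-recovery checks.
fixture_noiseless <- function(n_per_class = 6) {
  memo(paste0("noiseless", n_per_class), function() {
    classes <- rep(MI_CLASSES, times = n_per_class)
    rec <- simulate_ecg(classes, baseline_amp = 0, noise_sd = 0, seed = 202)
    fid <- delineate_record(rec)
    list(record = rec, fiducials = fid, truth = ecg_truth(rec))
  })
}

# A fast synthetic tidy feature table (no signal processing): class-dependent
# rule features and QT templates over two leads, for fold-logic tests.
fixture_fake_features <- function(n_per_class = 12, classes = c("H", "A", "I"),
                                  leads = c("II", "V2"), seed = 7) {
  withr::local_seed(seed)
  n <- n_per_class * length(classes)
  labs <- rep(classes, each = n_per_class)
  grid <- seq(0, 1, length.out = 1000)
  rows <- list()
  for (b in seq_len(n)) {
    shift <- match(labs[b], classes)
    for (ld in leads) {
      qt <- sin(2 * pi * shift * grid) + rnorm(1000, 0, 0.05)
      rf <- as.list(stats::setNames(shift + rnorm(7, 0, 0.1),
                                    RULE_FEATURE_NAMES))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        beat = b, label = labs[b], lead = ld, !!!rf, qt = list(qt))
    }
  }
  dplyr::bind_rows(rows)
}

# Archetype (jitter-free) morphology as plain pieces for closed-form checks.
archetype_morph <- function(label) morphology_for_class(label, jitter_sd = 0)

# Evaluate the Gaussian-bump model analytically at time t (s from R peak).
bump_model_value <- function(morph, t, variant = "abnormal") {
  w <- morph$waves
  amp <- if (variant == "abnormal") w$amp_abnormal else w$amp_normal
  sum(amp * exp(-0.5 * ((t - w$center) / w$width)^2))
}
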