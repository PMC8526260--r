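test_that("class archetypes respect their defining constraints", {
  withr::local_seed(1)
  h <- morphology_for_class("H")
  expect_identical(h$st_offset, 0)
  w <- h$waves
  expect_lt(abs(w$amp_abnormal[w$wave == "Q"]),
            0.25 * w$amp_abnormal[w$wave == "R"])
  expect_gt(w$amp_abnormal[w$wave == "T"], 0)

  a <- morphology_for_class("A")
  expect_gt(a$st_offset, 0)          # ST-elevation archetype
  i <- morphology_for_class("I")
  wi <- i$waves
  expect_lt(wi$amp_abnormal[wi$wave == "T"], 0)   # inverted T
  expect_lt(wi$amp_abnormal[wi$wave == "Q"],
            -0.25 * wi$amp_abnormal[wi$wave == "R"])  # abnormal Q

  expect_error(morphology_for_class("XX"), "unknown beat class")
})

test_that("equal seeds give identical morphologies and records", {
  m1 <- withr::with_seed(42, morphology_for_class("AL"))
  m2 <- withr::with_seed(42, morphology_for_class("AL"))
  expect_identical(m1, m2)
  r1 <- simulate_ecg(c("H", "A"), seed = 9)
  r2 <- simulate_ecg(c("H", "A"), seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(ecg_truth(r1), ecg_truth(r2))
})

test_that("beat rendering is linear in the wave amplitudes", {
  m <- archetype_morph("H")
  m0 <- m
  m0$waves$amp_normal[] <- 0
  m0$waves$amp_abnormal[] <- 0
  b0 <- make_beat(m0, fs = 500, rr = 0.9)
  expect_identical(b0$signal, rep(0, b0$n))

  b1 <- make_beat(m, fs = 500, rr = 0.9)
  m2 <- m
  m2$waves$amp_abnormal <- 2 * m$waves$amp_abnormal
  b2 <- make_beat(m2, fs = 500, rr = 0.9)
  expect_equal(b2$signal, 2 * b1$signal, tolerance = 1e-12)
})

test_that("ST plateau holds the offset between J and T onset", {
  m <- archetype_morph("A")        # ST elevation, jitter-free
  fs <- 1000
  b <- make_beat(m, fs = fs, rr = 0.9)
  mid <- round((b$fiducials$j + b$fiducials$t_start) / 2)
  r_off <- (b$fiducials$r - 1) / fs
  t_mid <- (mid - 1) / fs - r_off
  expected <- bump_model_value(m, t_mid) + m$st_offset
  expect_equal(b$signal[mid], expected, tolerance = 1e-9)
})

test_that("bump centers outside the RR window are rejected", {
  m <- archetype_morph("H")
  expect_error(make_beat(m, fs = 500, rr = 0.4), "does not fit")
})

test_that("record length follows the RR arithmetic", {
  rec <- simulate_ecg(rep("H", 3), fs = 500, mean_rr = 0.8,
                      rr_jitter_sd = 0, baseline_amp = 0, noise_sd = 0,
                      jitter_sd = 0, seed = 1)
  expect_identical(nrow(rec), 3L * 400L)
})

test_that("without noise, wander or gain all healthy leads coincide", {
  rec <- simulate_ecg(rep("H", 2), baseline_amp = 0, noise_sd = 0, seed = 3)
  m <- ecg_matrix(rec)
  expect_true(all(apply(m, 1, function(r) max(r) - min(r)) < 1e-12))
})

test_that("additive noise has the configured standard deviation", {
  classes <- rep("H", 15)
  clean <- simulate_ecg(classes, baseline_amp = 0, noise_sd = 0, seed = 4)
  noisy <- simulate_ecg(classes, baseline_amp = 0, noise_sd = 0.05, seed = 4)
  resid <- ecg_matrix(noisy) - ecg_matrix(clean)
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.05) / 0.05, 0.10)
})

test_that("the true R index is the local amplitude maximum", {
  fx <- fixture_noiseless()
  m <- ecg_matrix(fx$record)
  tr <- fx$truth
  half <- round(0.05 * ecg_fs(fx$record))
  for (b in seq_len(nrow(tr))) {
    w <- (tr$r[b] - half):(tr$r[b] + half)
    # grid discretization of the bump centre allows a 2-sample offset
    expect_lte(abs(which.max(abs(m[w, "II"])) + w[1] - 1 - tr$r[b]), 2)
  }
})

test_that("records round-trip through CSV and carry fs", {
  rec <- simulate_ecg(c("H", "O"), fs = 500, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(rec, path)
  back <- read_ecg_csv(path)
  expect_equal(ecg_fs(back), 500)
  expect_equal(ecg_matrix(back), ecg_matrix(rec), tolerance = 1e-12)
})
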