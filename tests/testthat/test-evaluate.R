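# Published per-class confusion counts used as an arithmetic fixture: a
# 10-class result with 3730 pooled beats, reported alongside its one-vs-rest
# count and percentage table.
published_confusion <- function() {
  cls <- c("A", "AS", "AL", "I", "IL", "IP", "IPL", "P", "H", "O")
  m <- matrix(0L, 10, 10, dimnames = list(truth = cls, predicted = cls))
  diag(m) <- c(500L, 468L, 320L, 537L, 339L, 50L, 173L, 46L, 582L, 710L)
  m["AS", "A"] <- 1L
  m["AL", "P"] <- 1L
  m["I", "IL"] <- 1L
  m["I", "O"] <- 1L
  m["O", "H"] <- 1L
  structure(m, class = c("ecg_confusion", "matrix"))
}

published_counts <- tibble::tribble(
  ~class, ~tp, ~tn, ~fp, ~fn,
  "A", 500L, 3229L, 1L, 0L,
  "AS", 468L, 3261L, 0L, 1L,
  "AL", 320L, 3409L, 0L, 1L,
  "I", 537L, 3191L, 0L, 2L,
  "IL", 339L, 3390L, 1L, 0L,
  "IP", 50L, 3680L, 0L, 0L,
  "IPL", 173L, 3557L, 0L, 0L,
  "P", 46L, 3683L, 1L, 0L,
  "H", 582L, 3147L, 1L, 0L,
  # the O row's published TN (3019) sums to 3731 of 3730 beats; the value
  # consistent with the published matrix is 3018 (percentages unaffected
  # at two decimals)
  "O", 710L, 3018L, 1L, 1L)

test_that("confusion construction is exact", {
  cm <- confusion_counts(c("H", "A", "A"), c("H", "A", "A"))
  expect_true(all(cm[row(cm) != col(cm)] == 0))
  cm2 <- confusion_counts(c("H", "A", "A"), c("H", "A", "H"))
  expect_identical(sum(cm2[row(cm2) != col(cm2)]), 1L)
  expect_identical(cm2["A", "H"], 1L)
  expect_error(confusion_counts("H", "Z", classes = c("H", "A")),
               "unknown labels")
})

test_that("the published matrix round-trips to its count table", {
  cm <- published_confusion()
  got <- class_metrics(cm)
  expect_identical(got[, c("class", "tp", "tn", "fp", "fn")],
                   published_counts)
})

test_that("per-class percentages reproduce the published cells", {
  met <- class_metrics(published_confusion())
  g <- function(cl, col) met[[col]][met$class == cl]
  expect_equal(round(g("P", "ppv"), 2), 97.87)   # 46/47
  expect_equal(round(g("P", "sp"), 2), 99.97)
  expect_equal(round(g("I", "se"), 2), 99.63)    # 537/539
  expect_equal(round(g("A", "acc"), 2), 99.97)   # 3729/3730
  expect_equal(round(g("A", "se"), 2), 100)
  expect_equal(round(g("IP", "ppv"), 2), 100)
})

test_that("overall accuracy is the matrix trace over the total", {
  expect_equal(overall_accuracy(diag(5L)), 100)
  cm <- published_confusion()
  expect_equal(sum(diag(cm)), 3725L - 0L)
  expect_equal(round(overall_accuracy(cm), 2), 99.87)  # 3725/3730
  # invariant to a simultaneous permutation of the class order
  p <- sample(10)
  expect_equal(overall_accuracy(cm[p, p]), overall_accuracy(cm))
})

test_that("random predictions over balanced classes approach 1/C", {
  withr::local_seed(61)
  n <- 1e5
  truth <- sample(MI_CLASSES, n, replace = TRUE)
  pred <- sample(MI_CLASSES, n, replace = TRUE)
  acc <- overall_accuracy(confusion_counts(truth, pred))
  expect_lt(abs(acc - 10), 0.5)
})

test_that("degenerate metrics are undefined, not zero", {
  cm <- confusion_counts(c("H", "H"), c("H", "H"), classes = c("H", "A"))
  met <- class_metrics(cm)
  expect_true(is.na(met$se[met$class == "A"]))    # no A cases
  expect_true(is.na(met$ppv[met$class == "A"]))   # never predicted A
  all2 <- class_metrics(confusion_counts(c("H", "A"), c("H", "A")))
  expect_true(all(unlist(all2[, c("se", "sp", "ppv", "acc")]) == 100))
})

test_that("pooled sensitivity equals brute-force counting", {
  withr::local_seed(62)
  truth <- sample(c("H", "A", "I"), 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.8, truth,
                 sample(c("H", "A", "I"), 500, replace = TRUE))
  cm <- confusion_counts(truth, pred)
  met <- class_metrics(cm)
  for (cl in rownames(cm)) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    expect_equal(met$se[met$class == cl], 100 * tp / (tp + fn))
  }
  expect_identical(sum(met$tp), sum(diag(cm)))
  expect_identical(as.integer(sum(met$tp + met$fn)), length(truth))
})

test_that("folds are stratified, deterministic, and leak-free", {
  feats <- fixture_fake_features(n_per_class = 10, classes = c("H", "A", "I"),
                                 leads = c("II", "V2"))
  cv <- kfold_cv(feats, k = 10, method = "dwt", seed = 5, nrounds = 10)
  # 30 beats, 3 classes, k=10: every fold holds out one beat per class
  sizes <- table(cv$predictions$fold)
  expect_true(all(sizes == 3))
  per_fold_class <- table(cv$predictions$fold, cv$predictions$label)
  expect_true(all(per_fold_class == 1))

  cv2 <- kfold_cv(feats, k = 10, method = "dwt", seed = 5, nrounds = 10)
  expect_identical(unclass(cv$confusion), unclass(cv2$confusion))

  expect_error(kfold_cv(feats[feats$label != "H" | feats$beat <= 5, ],
                        k = 10, seed = 1),
               "fewer than k")
})

test_that("a separable synthetic set cross-validates above 95%", {
  fx <- fixture_small()
  cv <- kfold_cv(fx$features, k = 5, method = "dwt", seed = 9, nrounds = 25)
  expect_gte(cv$accuracy, 95)
  expect_identical(sum(cv$confusion), length(unique(fx$features$beat)))
  # metric table and summaries agree
  expect_identical(tidy(cv), cv$metrics)
  expect_equal(glance(cv)$accuracy, overall_accuracy(cv$confusion))
})
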