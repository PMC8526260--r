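test_that("softmax gradient and Hessian have their closed forms", {
  scores <- matrix(0, 4, 10)
  y <- c(1L, 3L, 5L, 10L)
  gh <- softmax_grad_hess(scores, y)
  expect_equal(gh$p, matrix(0.1, 4, 10))
  expect_equal(gh$g[cbind(1:4, y)], rep(-0.9, 4))
  expect_equal(gh$h, matrix(0.09, 4, 10))
  expect_true(all(gh$h >= 0))

  strong <- matrix(c(50, 0, 0, 50), 2, 2, byrow = TRUE)
  gh2 <- softmax_grad_hess(strong, c(1L, 2L))
  expect_lt(max(abs(gh2$g[cbind(1:2, c(1L, 2L))])), 1e-10)
})

test_that("softmax derivatives match numerical differentiation", {
  withr::local_seed(51)
  n <- 6; C <- 4
  scores <- matrix(rnorm(n * C), n, C)
  y <- sample.int(C, n, replace = TRUE)
  loss <- function(s) {
    p <- exp(s - max(s)); p <- p / sum(p)
    -log(p[1])   # placeholder, replaced per use below
  }
  gh <- softmax_grad_hess(scores, y)
  eps <- 1e-5
  for (i in 1:n) {
    for (k in 1:C) {
      li <- function(sik) {
        s <- scores[i, ]; s[k] <- sik
        p <- exp(s - max(s)); p <- p / sum(p)
        -log(p[y[i]])
      }
      g_num <- (li(scores[i, k] + eps) - li(scores[i, k] - eps)) / (2 * eps)
      h_num <- (li(scores[i, k] + eps) - 2 * li(scores[i, k]) +
                  li(scores[i, k] - eps)) / eps^2
      expect_lt(abs(gh$g[i, k] - g_num), 1e-5)
      expect_lt(abs(gh$h[i, k] - h_num), 1e-4)
    }
  }
})

test_that("leaf weights minimize the per-leaf quadratic", {
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  expect_equal(leaf_weight(0, 5, 1), 0)
  expect_error(leaf_weight(1, -3, 1), "positive")
  withr::local_seed(52)
  for (rep in 1:10) {
    G <- rnorm(1, 0, 3); H <- runif(1, 0.1, 5); lam <- runif(1, 0, 2)
    w_grid <- seq(-5, 5, by = 1e-4)
    obj <- G * w_grid + 0.5 * (H + lam) * w_grid^2
    expect_lt(abs(leaf_weight(G, H, lam) - w_grid[which.min(obj)]), 1e-3)
  }
})

test_that("the hand-worked split example is reproduced", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  g <- c(-1, -1, 1, 1); h <- rep(1, 4)
  sp <- boost_best_split(x, g, h, lambda = 1, gamma = 0)
  expect_identical(sp$feature, 1L)
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$gain, 0.5 * (4 / 3 + 4 / 3 - 0 / 5), tolerance = 1e-12)
})

test_that("uniform gradients admit no split once gamma > 0", {
  x <- matrix(rnorm(20), ncol = 2)
  sp <- boost_best_split(x, rep(1, 10), rep(1, 10), lambda = 1, gamma = 0.1)
  expect_null(sp)
})

# Exhaustive oracle: every (feature, threshold) candidate, best gain wins,
# ties to lowest feature then lowest threshold.
exhaustive_split <- function(x, g, h, lambda, gamma) {
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    for (ti in seq_len(length(vals) - 1)) {
      thr <- (vals[ti] + vals[ti + 1]) / 2
      L <- x[, j] <= thr
      gl <- sum(g[L]); hl <- sum(h[L])
      gr <- sum(g[!L]); hr <- sum(h[!L])
      gain <- 0.5 * (gl^2 / (hl + lambda) + gr^2 / (hr + lambda) -
                       sum(g)^2 / (sum(h) + lambda)) - gamma
      if (gain > 1e-10 && (is.null(best) || gain > best$gain + 1e-12)) {
        best <- list(feature = j, threshold = thr, gain = gain)
      }
    }
  }
  best
}

test_that("split search equals exhaustive enumeration on small tables", {
  withr::local_seed(53)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    p <- sample(1:3, 1)
    # duplicate values on purpose to exercise tie handling
    x <- matrix(sample(1:4, n * p, replace = TRUE) + 0, n, p)
    g <- rnorm(n); h <- runif(n, 0.1, 2)
    lam <- runif(1, 0, 2); gam <- sample(c(0, 0.1), 1)
    got <- boost_best_split(x, g, h, lambda = lam, gamma = gam)
    ref <- exhaustive_split(x, g, h, lam, gam)
    if (is.null(ref)) {
      expect_null(got)
    } else {
      expect_identical(got$feature, as.integer(ref$feature))
      expect_equal(got$threshold, ref$threshold)
      expect_equal(got$gain, ref$gain, tolerance = 1e-9)
    }
  }
})

toy_data <- function(n = 20, seed = 54) {
  withr::local_seed(seed)
  x1 <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  x2 <- rnorm(n)
  tibble::tibble(label = rep(c("neg", "pos"), each = n / 2),
                 f1 = x1, f2 = x2)
}

test_that("separable data is fit to 100% within 20 rounds", {
  d <- toy_data()
  fit <- boost_fit(d, nrounds = 20, max_depth = 3, colsample = 1, seed = 1)
  expect_identical(mean(predict(fit, d) == d$label), 1)
  expect_true(all(diff(fit$train_logloss) <= 1e-8))  # non-increasing
})

test_that("an empty ensemble predicts uniform probabilities", {
  d <- toy_data()
  fit <- boost_fit(d, nrounds = 0, seed = 1)
  p <- predict(fit, d, type = "prob")
  expect_true(all(abs(p - 0.5) < 1e-12))
})

test_that("probabilities sum to one and classes go to their side", {
  d <- toy_data(40)
  fit <- boost_fit(d, nrounds = 30, max_depth = 3, colsample = 1, seed = 2)
  test <- tibble::tibble(label = c("neg", "pos"), f1 = c(-3, 3), f2 = 0)
  p <- predict(fit, test, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_identical(predict(fit, test), c("neg", "pos"))
  expect_error(predict(fit, test[, c("label", "f1")]), "lacks features")
})

test_that("increasing gamma never grows the ensemble's leaf count", {
  withr::local_seed(55)
  n <- 60
  d <- tibble::tibble(label = sample(c("a", "b", "c"), n, replace = TRUE),
                      f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  leaves <- sapply(c(0, 0.1, 0.5, 2), function(gam) {
    fit <- boost_fit(d, nrounds = 3, max_depth = 4, gamma = gam,
                     colsample = 1, seed = 3)
    sum(tidy(fit)$n_leaves)
  })
  expect_true(all(diff(leaves) <= 0))
})

test_that("training is deterministic given the seed", {
  d <- toy_data(30)
  f1 <- boost_fit(d, nrounds = 10, colsample = 0.5, seed = 7)
  f2 <- boost_fit(d, nrounds = 10, colsample = 0.5, seed = 7)
  expect_identical(predict(f1, d, type = "score"),
                   predict(f2, d, type = "score"))
})

test_that("models survive a JSON round trip", {
  d <- toy_data(30)
  fit <- boost_fit(d, nrounds = 8, max_depth = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(predict(back, d, type = "prob"),
               predict(fit, d, type = "prob"), tolerance = 1e-12)
})

test_that("predictions agree with the reference boosted-tree library", {
  skip_if_not_installed("xgboost")
  withr::local_seed(56)
  n <- 150
  d <- tibble::tibble(
    label = rep(c("a", "b", "c"), each = n / 3),
    f1 = c(rnorm(n / 3, -2), rnorm(n / 3, 0), rnorm(n / 3, 2)),
    f2 = c(rnorm(n / 3, 1), rnorm(n / 3, -1), rnorm(n / 3, 0)),
    f3 = rnorm(n))
  fit <- boost_fit(d, nrounds = 30, max_depth = 4, learning_rate = 0.1,
                   lambda = 1, gamma = 0, colsample = 1, seed = 5)
  X <- as.matrix(d[, c("f1", "f2", "f3")])
  dm <- xgboost::xgb.DMatrix(X, label = match(d$label, c("a", "b", "c")) - 1)
  ref <- xgboost::xgb.train(
    params = list(objective = "multi:softmax", num_class = 3,
                  max_depth = 4, eta = 0.1, lambda = 1, gamma = 0,
                  nthread = 1),
    data = dm, nrounds = 30, verbose = 0)
  ref_pred <- c("a", "b", "c")[predict(ref, dm) + 1]
  expect_gte(mean(predict(fit, d) == ref_pred), 0.95)
})
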