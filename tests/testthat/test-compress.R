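test_that("wavelet compression yields 32 smooth-summary coefficients", {
  qt <- rep(0.5, 1000)
  out <- dwt_compress(qt)
  expect_length(out, 32L)
  expect_true(all(out > 0))
  expect_lt(diff(range(out)), 1e-9)    # constant in, constant out (scaled)

  # smooth input is well represented by the approximation band alone
  grid <- seq(0, 1, length.out = 1000)
  smooth <- 0.3 * sin(2 * pi * 2 * grid) + 0.2 * cos(2 * pi * 5 * grid)
  x1024 <- stats::approx(seq_along(smooth), smooth, n = 1024)$y
  pyr <- dwt(x1024, basis = "db4", levels = 5)
  for (k in seq_along(pyr$detail)) pyr$detail[[k]][] <- 0
  recon <- idwt(pyr)
  expect_gt(cor(recon, x1024), 0.95)

  m <- matrix(rnorm(5000), 5, 1000)
  expect_identical(dim(dwt_compress(m)), c(5L, 32L))
  # training-free determinism
  expect_identical(dwt_compress(m), dwt_compress(m))
})

test_that("PCA projection matches the dense eigensolver oracle", {
  withr::local_seed(41)
  x <- matrix(rnorm(50 * 40), 50, 40)
  fit <- pca_fit(x, k = 32)
  expect_true(all(abs(crossprod(fit$rotation) - diag(32)) < 1e-8))
  # component variances are non-increasing
  proj <- pca_transform(fit, x)
  v <- apply(proj, 2, var)
  expect_true(all(diff(v) <= 1e-10))
  # total captured variance equals the top eigenvalues of the covariance
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_lt(abs(sum(v) - sum(ev[1:32])), 1e-8)
})

test_that("rank-deficient data is represented exactly", {
  withr::local_seed(42)
  basis <- matrix(rnorm(5 * 100), 5, 100)
  x <- matrix(rnorm(60 * 5), 60, 5) %*% basis
  fit <- pca_fit(x, k = 32)
  expect_lt(max(fit$sdev[6:32]), 1e-8)
  recon <- pca_transform(fit, x) %*% t(fit$rotation)
  recon <- sweep(recon, 2, fit$center, `+`)
  expect_lt(max(abs(recon - x)), 1e-6)
  expect_error(pca_fit(x[1:10, ], k = 32), "at least 32")
})

test_that("LPP separates well-separated clusters in one dimension", {
  withr::local_seed(43)
  a <- matrix(rnorm(40 * 1000, 0, 0.5), 40, 1000)
  b <- matrix(rnorm(40 * 1000, 0, 0.5), 40, 1000)
  b[, 1:50] <- b[, 1:50] + 6
  x <- rbind(a, b)
  fit <- lpp_fit(x, k = 1)
  y <- lpp_transform(fit, x)
  gap <- abs(mean(y[1:40]) - mean(y[41:80]))
  within <- max(sd(y[1:40]), sd(y[41:80]))
  expect_gt(gap, 4 * within)
})

test_that("the LPP objective beats a random normalized projection", {
  withr::local_seed(44)
  x <- matrix(rnorm(60 * 120), 60, 120)
  x[31:60, 1:10] <- x[31:60, 1:10] + 3
  fit <- lpp_fit(x, k = 4)
  xc <- sweep(x, 2, fit$center)
  W <- fit$W
  D <- rowSums(W)
  obj_fit <- lpp_objective(xc %*% fit$projection, W)
  # random projection, columns normalized to a' X D X' a = 1 like LPP's
  A <- qr.Q(qr(matrix(rnorm(120 * 4), 120, 4)))
  ya <- xc %*% A
  scale <- sqrt(colSums(ya^2 * D))
  obj_rand <- lpp_objective(sweep(ya, 2, scale, `/`), W)
  expect_lte(obj_fit, obj_rand)
  expect_identical(ncol(fit$projection), 4L)
  # weight matrix contract
  expect_true(isSymmetric(unname(W)))
  expect_true(all(W >= 0))
  expect_true(all(diag(W) == 0))
})

test_that("every backend emits length-32 features through the common API", {
  withr::local_seed(45)
  x <- matrix(rnorm(40 * 1000), 40, 1000)
  for (meth in c("dwt", "pca", "lpp")) {
    comp <- compress_fit(x, method = meth)
    out <- compress_apply(comp, x[1, ])
    expect_length(out, 32L)
  }
})

test_that("fused vectors have the documented widths and block layout", {
  feats <- fixture_fake_features(n_per_class = 4, leads = ECG_LEADS[1:12])
  comp <- compress_fit(method = "dwt")
  fused <- fuse_features(feats, comp, "fused")
  expect_identical(ncol(fused) - 2L, 468L)   # beat + label + 12*39
  rule <- fuse_features(feats, NULL, "rule")
  expect_identical(ncol(rule) - 2L, 84L)
  vent <- fuse_features(feats, comp, "ventricular")
  expect_identical(ncol(vent) - 2L, 384L)

  # per-lead blocks are independent: permuting lead order permutes columns
  rev_leads <- rev(ECG_LEADS)
  fused_rev <- fuse_features(feats, comp, "fused", leads = rev_leads)
  expect_identical(fused_rev[, names(fused)], fused)

  # a beat missing one lead is dropped whole
  feats2 <- feats[!(feats$beat == 2 & feats$lead == "V6"), ]
  fused2 <- fuse_features(feats2, comp, "fused")
  expect_false(2 %in% fused2$beat)
})

test_that("projections fitted on training rows ignore test rows", {
  withr::local_seed(46)
  x <- matrix(rnorm(80 * 200), 80, 200)
  train <- x[1:50, ]
  fit1 <- pca_fit(train, k = 10)
  x_perturbed <- x
  x_perturbed[51:80, ] <- x_perturbed[51:80, ] + 100
  fit2 <- pca_fit(x_perturbed[1:50, ], k = 10)
  expect_identical(fit1$rotation, fit2$rotation)
  l1 <- lpp_fit(train, k = 5)
  l2 <- lpp_fit(x_perturbed[1:50, ], k = 5)
  expect_identical(l1$projection, l2$projection)
})
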