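test_that("the canonical HRF has the expected shape", {
  tr <- 0.1
  h <- canonical_hrf(tr)
  t_axis <- seq(0, 32, by = tr)
  expect_lt(abs(t_axis[which.max(h)] - 6), tr / 2 + 1e-9)
  expect_lt(abs(h[1]), 1e-6)
  expect_gt(sum(h) * tr, 0)
  expect_equal(max(h), 1)
  # undershoot present and small relative to the peak
  expect_lt(min(h), 0)
  expect_gt(min(h), -0.5)
})

test_that("block designs are model-matched and reject collinearity", {
  timing <- block_timing(data.frame(condition = "faces", onset_s = 30,
                                    duration_s = 20))
  T_ <- 60; tr <- 2
  D <- build_block_design(timing, T_, tr)
  expect_identical(colnames(D), c("intercept", "faces"))
  # noiseless voxel built from the same kernel: beta recovered exactly
  y <- 3.7 * D[, "faces"] + 1.2
  b <- qr.coef(qr(D), y)
  expect_equal(unname(b["faces"]), 3.7, tolerance = 1e-8)
  expect_equal(unname(b["intercept"]), 1.2, tolerance = 1e-8)

  empty <- block_timing(data.frame(condition = character(0),
                                   onset_s = numeric(0),
                                   duration_s = numeric(0)))
  D0 <- build_block_design(empty, 20, 2)
  expect_identical(colnames(D0), "intercept")

  dup <- block_timing(data.frame(condition = c("a", "b"),
                                 onset_s = c(10, 10), duration_s = 20))
  expect_error(build_block_design(dup, 60, 2), "rank deficient")
  expect_error(build_block_design(timing, 60, 2, conditions = "scenes"),
               "unknown condition")
  late <- block_timing(data.frame(condition = "a", onset_s = 110,
                                  duration_s = 20))
  expect_error(build_block_design(late, 60, 2), "after the run")
})

test_that("contrast t equals the closed-form OLS computation", {
  T_ <- 60
  timing <- block_timing(data.frame(
    condition = rep(c("faces", "objects"), 3),
    onset_s = seq(0, 100, by = 20), duration_s = 16))
  X <- build_block_design(timing, T_, 2)
  withr::with_seed(8, Y <- matrix(rnorm(30 * T_), 30, T_))
  cvec <- c(0, 1, -1)
  fit <- fit_contrast_tmap(Y, X, c(faces = 1, objects = -1))
  # independent brute-force route: explicit normal equations per voxel
  XtXi <- solve(t(X) %*% X)
  for (v in seq_len(30)) {
    b <- XtXi %*% t(X) %*% Y[v, ]
    r <- Y[v, ] - X %*% b
    s2 <- sum(r^2) / (T_ - ncol(X))
    t_hand <- (t(cvec) %*% b) / sqrt(s2 * t(cvec) %*% XtXi %*% cvec)
    expect_equal(fit$t[v], as.numeric(t_hand), tolerance = 1e-10)
  }
  expect_equal(fit$df, T_ - 3)

  # t is invariant to rescaling the data
  fit2 <- fit_contrast_tmap(Y * 7.3, X, c(faces = 1, objects = -1))
  expect_equal(fit2$t, fit$t, tolerance = 1e-10)
})

test_that("a null contrast is centred on zero and degenerate fits are capped", {
  T_ <- 100
  timing <- block_timing(data.frame(
    condition = rep(c("a", "b"), 4),
    onset_s = seq(0, 175, by = 25), duration_s = 20))
  X <- build_block_design(timing, T_, 2)
  withr::with_seed(21, Y <- matrix(rnorm(500 * T_), 500, T_))
  fit <- fit_contrast_tmap(Y, X, c(a = 1, b = -1))
  expect_lt(abs(mean(fit$t)), 0.1)

  # noiseless planted effect: large finite t with a degeneracy flag
  Yd <- matrix(rep(2 * X[, "a"] - X[, "b"], 2), 2, T_, byrow = TRUE)
  fitd <- fit_contrast_tmap(Yd, X, c(a = 1, b = -1))
  expect_true(all(is.finite(fitd$t)))
  expect_true(all(fitd$flagged))
  expect_true(all(abs(fitd$t) <= 1e6))
})

test_that("missing TRs are excluded listwise", {
  T_ <- 60
  timing <- block_timing(data.frame(
    condition = rep(c("a", "b"), 2),
    onset_s = c(0, 30, 60, 90), duration_s = 20))
  X <- build_block_design(timing, T_, 2)
  withr::with_seed(5, Y <- matrix(rnorm(10 * T_), 10, T_))
  Yna <- Y; Yna[, c(3, 40)] <- NA
  fit_na <- fit_contrast_tmap(Yna, X, c(a = 1, b = -1))
  fit_drop <- fit_contrast_tmap(Y[, -c(3, 40)], X[-c(3, 40), ],
                                c(a = 1, b = -1))
  expect_equal(fit_na$t, fit_drop$t, tolerance = 1e-12)
  expect_equal(fit_na$df, T_ - 2 - 3)
})

test_that("the GLM's false-positive rate is calibrated under pure noise", {
  g <- null_calibration_glm(n_seeds = 50, n_vox = 200, t_ = 100, seed = 14)
  expect_gte(g$exceedance_rate, 0.03)
  expect_lte(g$exceedance_rate, 0.07)
})

test_that("contrast strings parse to signed weights", {
  w <- parse_contrast("faces>objects")
  expect_equal(w, c(faces = 1, objects = -1))
  expect_error(parse_contrast("faces"), "A>B")
})
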