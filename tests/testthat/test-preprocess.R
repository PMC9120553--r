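test_that("artifact detection applies both criteria with strict thresholds", {
  T_ <- 20
  motion <- matrix(0, T_, 6)
  motion[10:T_, 1] <- 2.5          # persistent 2.5-mm step at TR 10
  flags <- detect_artifact_timepoints(motion, rnorm(T_, sd = 1e-6))
  expect_identical(which(as.logical(flags)), 10L)

  gs <- rep(0, T_); gs[3] <- 1     # isolated global-signal excursion
  flags2 <- detect_artifact_timepoints(matrix(0, T_, 6), gs)
  expect_identical(which(as.logical(flags2)), 3L)

  # exactly 2.0 mm is NOT an artifact (strict inequality)
  m3 <- matrix(0, T_, 6); m3[5:T_, 2] <- 2.0
  flags3 <- detect_artifact_timepoints(m3, rnorm(T_, sd = 1e-6))
  expect_false(any(as.logical(flags3)))

  # rotations count via arc displacement on the head sphere
  m4 <- matrix(0, T_, 6); m4[7:T_, 4] <- 2.5 / 65
  flags4 <- detect_artifact_timepoints(m4, rnorm(T_, sd = 1e-6))
  expect_identical(which(as.logical(flags4)), 7L)

  # the first TR can only be flagged through the global signal
  m5 <- matrix(0, 4, 6)
  expect_false(as.logical(detect_artifact_timepoints(m5, c(0, 0, 0, 0)))[1])
})

test_that("the one-third QC rule drops at exactly T/3 flagged", {
  expect_false(subject_passes_qc(artifact_mask(rep(c(TRUE, FALSE),
                                                   c(56, 112)))))
  expect_true(subject_passes_qc(artifact_mask(rep(c(TRUE, FALSE),
                                                  c(55, 113)))))
  expect_true(subject_passes_qc(artifact_mask(rep(FALSE, 168))))
})

test_that("nearest-neighbour interpolation breaks ties toward earlier TRs", {
  tc <- c(1, 2, 9, 4)
  out <- interpolate_artifacts(tc, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out, c(1, 2, 2, 4))
  # leading artifact takes the first unflagged value
  expect_equal(interpolate_artifacts(c(9, 9, 3, 4),
                                     c(TRUE, TRUE, FALSE, FALSE)),
               c(3, 3, 3, 4))
  expect_equal(interpolate_artifacts(tc, rep(FALSE, 4)), tc)
  expect_error(interpolate_artifacts(tc, rep(TRUE, 4)), "all TRs")
})

test_that("6-connected erosion shrinks cubes as expected", {
  cube5 <- array(FALSE, dim = c(7, 7, 7))
  cube5[2:6, 2:6, 2:6] <- TRUE
  e1 <- erode_mask(cube5, iterations = 1)
  expect_equal(sum(e1), 27)
  e2 <- erode_mask(cube5, iterations = 2)
  expect_equal(sum(e2), 1)
  expect_true(e2[4, 4, 4])
  cube3 <- array(FALSE, dim = c(5, 5, 5))
  cube3[2:4, 2:4, 2:4] <- TRUE
  expect_error(erode_mask(cube3, iterations = 2), "empty")
})

test_that("CompCor recovers exact low-rank factors and matches brute force", {
  T_ <- 50
  withr::with_seed(1, {
    f1 <- rnorm(T_); f2 <- rnorm(T_)
    f1 <- f1 - mean(f1); f2 <- residuals(lm(f2 ~ f1))
    W <- outer(rnorm(20), f1) + outer(rnorm(20), f2)
  })
  expect_warning(comps <- compute_compcor(W, n_components = 5),
                 "non-degenerate")
  expect_equal(ncol(comps), 2)
  # recovered components span the planted factor space
  proj <- lm(comps ~ cbind(f1, f2))
  expect_lt(max(abs(residuals(proj))), 1e-8)
  expect_lt(abs(sum(comps[, 1] * comps[, 2])), 1e-10)

  # full-rank instance: agreement with eigendecomposition of the T x T
  # covariance (independent route), up to sign
  withr::with_seed(2, X <- matrix(rnorm(20 * T_), 20, T_))
  got <- compute_compcor(X, n_components = 5)
  Xc <- X - rowMeans(X)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  for (j in 1:5) {
    v <- ev$vectors[, j]
    if (sum(v * got[, j]) < 0) v <- -v
    expect_lt(max(abs(v - got[, j])), 1e-8)
  }
})

test_that("DCT high-pass removes slow components and keeps fast ones", {
  T_ <- 168; tr <- 2
  expect_equal(highpass_filter(rep(5, T_), tr), rep(0, T_),
               tolerance = 1e-10)
  t_s <- (seq_len(T_) - 1) * tr
  slow <- sin(2 * pi * t_s / 200)
  fast <- sin(2 * pi * t_s / 20)
  # independent oracle: residual variance after projecting on the basis
  B <- cbind(1, dct_basis(T_, tr, 100))
  orac <- function(x) {
    r <- residuals(lm(x ~ B - 1))
    var(r) / var(x)
  }
  expect_lt(orac(slow), 0.10)
  expect_gt(orac(fast), 0.95)
  expect_equal(var(highpass_filter(slow, tr)) / var(slow), orac(slow),
               tolerance = 1e-10)
  expect_equal(var(highpass_filter(fast, tr)) / var(fast), orac(fast),
               tolerance = 1e-10)
  expect_error(highpass_filter(rnorm(20), tr_s = 2, cutoff_s = 4), "cutoff")
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  T_ <- 60
  withr::with_seed(3, {
    comps <- qr.Q(qr(matrix(rnorm(T_ * 3), T_, 3)))
    mask <- rep(FALSE, T_); mask[c(7, 20)] <- TRUE
    nu <- nuisance_set(mask, comps)
    Y <- matrix(rnorm(5 * T_), 5, T_)
    Y[1, ] <- comps[, 2]          # a voxel equal to a nuisance component
  })
  R <- regress_nuisance(Y, nu)
  expect_lt(max(abs(R[1, ])), 1e-8)
  expect_lt(max(abs(R %*% nu)), 1e-8)
  # spike regressor forces an exact zero at its TR before filtering
  expect_lt(max(abs(R[, c(7, 20)])), 1e-10)

  # no nuisance, no artifacts: cleaning reduces to the high-pass filter
  out <- clean_voxel_timecourses(Y, rep(FALSE, T_), NULL, tr_s = 2)
  expect_equal(out, highpass_filter(Y, 2), tolerance = 1e-12)

  # collinear nuisance columns are pruned with a warning
  expect_warning(regress_nuisance(Y, cbind(nu, nu[, 1])), "collinear")
})

test_that("the cleaning stages are applied in the documented order", {
  T_ <- 80
  withr::with_seed(4, {
    Y <- matrix(rnorm(3 * T_), 3, T_)
    nu <- matrix(rnorm(T_ * 2), T_, 2)
  })
  mask <- rep(FALSE, T_)
  ours <- clean_voxel_timecourses(Y, mask, nu, tr_s = 2)
  swapped <- regress_nuisance(highpass_filter(Y, 2), nu)
  expect_gt(max(abs(ours - swapped)), 1e-6)
})

test_that("ROI averaging NaNs artifact TRs after the mean", {
  Y <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(5, 6, 7, 8))
  mask <- c(FALSE, FALSE, TRUE, FALSE)
  tc <- roi_mean_timecourse(Y, c(0L, 1L), mask)
  expect_equal(tc, c(1, 2, NA, 4))
  # single-voxel ROI is identity plus NaN-ing
  expect_equal(roi_mean_timecourse(Y, 2L, mask), c(5, 6, NA, 8))
  expect_error(roi_mean_timecourse(Y, integer(0), mask), "empty")
})
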