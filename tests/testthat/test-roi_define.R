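test_that("top-k selection saturates, partitions, and breaks ties by index", {
  p <- cube_parcel(c(10, 10, 10), 2, 8, label = "big")   # 343 voxels
  idx <- parcel_indices(p)
  withr::with_seed(2, tv <- rnorm(length(idx)))
  top <- top_k_voxels(tv, p, k = 100, tail = "top")
  bot <- top_k_voxels(tv, p, k = 100, tail = "bottom")
  expect_length(intersect(top$voxels, bot$voxels), 0)
  expect_setequal(top$voxels, idx[order(-tv)][1:100])

  p100 <- cube_parcel(c(8, 8, 8), 2, 6, label = "p125")  # 125 voxels
  expect_warning(all_roi <- top_k_voxels(rnorm(125), p100, k = 200),
                 "returning all")
  expect_setequal(all_roi$voxels, parcel_indices(p100))

  # ties go to the lower linear index
  tied <- rep(1, length(idx)); tied[5] <- 2
  r <- top_k_voxels(tied, p, k = 3)
  expect_identical(r$voxels, c(idx[5], setdiff(idx, idx[5])[1:2]))
  expect_error(top_k_voxels(rep(NA_real_, length(idx)), p), "missing")
})

test_that("noiseless planted t-maps are recovered with Dice 1", {
  p <- cube_parcel(c(6, 6, 6), 1, 6, label = "full")     # 216 voxels
  idx <- parcel_indices(p)
  withr::with_seed(3, planted <- sort(sample(idx, 100)))
  tv <- numeric(length(idx))
  tv[match(planted, idx)] <- 10
  roi <- top_k_voxels(tv, p, k = 100)
  expect_setequal(roi$voxels, planted)
})

test_that("predictor sets honour leave-one-out and per-TR missingness", {
  mk <- function(x) list(roi = list(FFA = x, LOC = x * 2),
                         counter = list(FFA = -x, LOC = -x * 2))
  a <- mk(c(1, 2, 3, 4)); b <- mk(c(5, 6, 7, 8))
  P <- build_predictor_set(list(s1 = a, s2 = b), leave_out = "s1")
  expect_equal(unname(P[, "FFA"]), c(5, 6, 7, 8))
  src <- attr(P, "source")
  expect_false("s1" %in% src$contributors)

  # identical subjects, no leave-out: mean equals any one subject
  P2 <- build_predictor_set(list(s1 = a, s2 = a))
  expect_equal(unname(P2[, "LOC"]), c(2, 4, 6, 8))

  # one subject missing TR 2: mean over the remaining contributor
  a_na <- mk(c(1, NA, 3, 4))
  P3 <- build_predictor_set(list(s1 = a_na, s2 = b))
  expect_equal(unname(P3[, "FFA"]), c(3, 6, 5, 6))
  # a TR missing in all contributors stays missing
  b_na <- mk(c(5, NA, 7, 8))
  P4 <- build_predictor_set(list(s1 = a_na, s2 = b_na))
  expect_true(is.na(P4[2, "FFA"]))

  expect_error(build_predictor_set(list(s1 = a), leave_out = "s1"),
               "no contributors")
})

test_that("movie ssROIs recover planted voxels from noisy data", {
  dice <- recovery_experiment(seed = 4, noise_sd = 0.5)
  expect_true(all(dice >= 0.9))
})

test_that("the movie contrast ranks construction-matched voxels correctly", {
  regs <- region_table()$region
  labels <- c(regs, paste0(regs, "_counter"))
  lat <- make_latent_timecourses(168, labels, seed = 6)
  p <- cube_parcel(c(6, 6, 6), 1, 6, label = "FFA")
  idx <- parcel_indices(p)
  withr::with_seed(7, Y <- matrix(rnorm(216 * 168, sd = 0.5), 216, 168))
  Y[1, ] <- lat[, "LOC"]          # a voxel equal to the LOC predictor
  full <- matrix(0, 216, 168); full[] <- Y   # rows align with idx already
  roi <- define_movie_ssroi(Y, lat, p, "FFA", k = 100)
  tvals <- attr(roi, "t")
  expect_lt(tvals[1], median(tvals))

  # predictor column order never changes the selected ROI
  perm <- sample(ncol(lat))
  roi2 <- define_movie_ssroi(Y, lat[, perm], p, "FFA", k = 100)
  expect_identical(roi$voxels, roi2$voxels)
})

test_that("collinear predictors are pruned but contrast columns survive", {
  regs <- region_table()$region
  labels <- c(regs, paste0(regs, "_counter"))
  lat <- make_latent_timecourses(100, labels, seed = 9)
  lat[, "PPA"] <- lat[, "RSC"]    # exact collinearity away from the contrast
  p <- cube_parcel(c(6, 6, 6), 1, 6)
  withr::with_seed(10, Y <- matrix(rnorm(216 * 100), 216, 100))
  expect_warning(roi <- define_movie_ssroi(Y, lat, p, "FFA", k = 50),
                 "collinear")
  expect_length(roi$voxels, 50)
})

test_that("split-half splicing crosses definition and extraction", {
  res <- splithalf_noiseless_experiment(seed = 2)
  expect_identical(res$length_trs, 165L)
  expect_gt(res$min_latent_r, 0.99)
  expect_true(all(res$dice == 1))

  # the guard TRs 83-85 never contribute to any output
  expect_length(intersect(83:85, res$kept_trs), 0)
  expect_identical(res$kept_trs, c(1:82, 86:168))
})

test_that("split-half guards reject runs that are too short", {
  regs <- region_table()$region
  labels <- c(regs, paste0(regs, "_counter"))
  lat <- make_latent_timecourses(90, labels, seed = 3)
  p <- list(FFA = cube_parcel(c(6, 6, 6), 1, 6, label = "FFA"))
  Y <- matrix(rnorm(216 * 90), 216, 90)
  expect_error(split_half_define_extract(Y, lat, p, split = c(88, 91)),
               "too short")
  expect_error(split_half_define_extract(Y, lat, p, split = c(50, 51)),
               "guard")
})
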