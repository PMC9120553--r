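test_that("latent timecourses honour the requested correlation structure", {
  labs <- c("FFA", "pSTS", "LOC")
  L <- make_latent_timecourses(10000, labs, seed = 3)
  expect_equal(colMeans(L), setNames(rep(0, 3), labs), tolerance = 1e-8)
  expect_equal(apply(L, 2, sd), setNames(rep(1, 3), labs),
               tolerance = 1e-8)
  off <- cor(L)[upper.tri(diag(3))]
  expect_true(all(abs(off) < 0.05))

  C <- diag(3); C[1, 3] <- C[3, 1] <- 0.8
  dimnames(C) <- list(labs, labs)
  L2 <- make_latent_timecourses(10000, labs, corr = C, seed = 3)
  expect_gt(cor(L2)[1, 3], 0.75)
  expect_lt(cor(L2)[1, 3], 0.85)

  expect_identical(make_latent_timecourses(100, labs, seed = 9),
                   make_latent_timecourses(100, labs, seed = 9))
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(make_latent_timecourses(50, labs[1:2], corr = bad),
               "positive semi-definite")
})

test_that("localizer timing is palindromic and 415.8 s long", {
  tm <- make_localizer_timing(seed = 1)
  expect_equal(attr(tm, "run_s"), 415.8)
  ord <- attr(tm, "block_order")
  expect_length(ord, 21)
  expect_equal(sum(ord == "fix"), 5)
  expect_equal(ord[c(1, 6, 11, 16, 21)], rep("fix", 5))
  stim <- ord[ord != "fix"]
  expect_length(stim, 16)
  expect_identical(stim[9:16], rev(stim[1:8]))
  expect_equal(as.integer(table(tm$condition)), rep(4L, 4))

  tm2 <- make_localizer_timing(seed = 2)
  stim2 <- attr(tm2, "block_order")[attr(tm2, "block_order") != "fix"]
  expect_false(identical(stim, stim2))
  expect_identical(stim2[9:16], rev(stim2[1:8]))
})

test_that("noiseless planted voxels reproduce the latent exactly", {
  dir <- tempfile("noiseless")
  cc <- cohort_config(groups = list(adult = list(n = 1, ages = 25)),
                      noise_sd = 0, shared_sd = 0, artifact_rate = 0,
                      localizer_groups = character(0), seed = 5)
  man <- generate_cohort(cc, dir)
  sid <- man$subjects[[1]]$subject_id
  bold <- read_bold(file.path(dir, sid, "func_movie.nii.gz"))
  d <- dim(bold$data)
  X <- matrix(bold$data, prod(d[1:3]), d[4])
  planted <- unlist(man$selective_voxels$FFA)
  mean_tc <- colMeans(X[planted + 1L, ])
  expect_equal(mean_tc, unname(man$latents[, "FFA"]), tolerance = 1e-10)
  # artifact rate 0: all composite motion deltas stay below threshold
  motion <- read_motion(file.path(dir, sid, "motion_movie.tsv"))
  expect_true(all(composite_motion(motion) < 2))
  unlink(dir, recursive = TRUE)
})

test_that("the planted child lag shows up as a -1 TR cross-correlation peak", {
  dir <- tempfile("lagged")
  cc <- cohort_config(groups = list(threeyo = list(n = 1, ages = 3)),
                      noise_sd = 0.1, shared_sd = 0, artifact_rate = 0,
                      child_psts_mix = 0, child_lag_trs = 1,
                      localizer_groups = character(0), seed = 11)
  man <- generate_cohort(cc, dir)
  sid <- man$subjects[[1]]$subject_id
  bold <- read_bold(file.path(dir, sid, "func_movie.nii.gz"))
  d <- dim(bold$data)
  X <- matrix(bold$data, prod(d[1:3]), d[4])
  planted <- unlist(man$selective_voxels$pSTS)
  child <- colMeans(X[planted + 1L, ])
  adult_latent <- man$latents[, "pSTS"]
  cc_lags <- sapply(-3:3, function(l)
    cor(shift_timecourse(child, l), adult_latent,
        use = "pairwise.complete.obs"))
  expect_equal((-3:3)[which.max(cc_lags)], -1)
  unlink(dir, recursive = TRUE)
})

test_that("generated artifacts are exactly recovered at default thresholds", {
  res <- artifact_detection_experiment(n_seeds = 5, seed = 3)
  expect_equal(res$sensitivity, 1.0)
  expect_gte(res$specificity, 0.999)
})

test_that("planted selectivity clears the empirical contrast floor", {
  dir <- small_cohort_dir()
  man <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                             simplifyVector = TRUE)
  sid <- "sub-adult01"
  bold <- read_bold(file.path(dir, sid, "func_movie.nii.gz"))
  d <- dim(bold$data)
  X <- matrix(bold$data, prod(d[1:3]), d[4])
  lat <- as.matrix(as.data.frame(
    read_timecourse_table(file.path(dir, "latents.tsv"))))
  for (region in c("FFA", "LOC", "EVC")) {
    p <- read_parcel(file.path(dir, "parcels", paste0(region, ".nii.gz")),
                     label = region)
    idx <- parcel_indices(p)
    planted <- unlist(man$selective_voxels[[region]])
    rest <- setdiff(idx, planted)
    r_planted <- cor(t(X[planted + 1L, ]), lat[, region])
    r_rest <- cor(t(X[rest + 1L, ]), lat[, region])
    tt <- t.test(r_planted, r_rest)
    expect_gt(unname(tt$statistic), 0)
  }
})
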