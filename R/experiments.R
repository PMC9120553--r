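# Validation experiments on synthetic cohorts with planted ground truth.
# Each function regenerates its inputs from a seed, runs the relevant part
# of the pipeline, and measures recovery -- shared by the test suite and by
# the acceptance script.

#' Movie-ssROI recovery experiment
#'
#' One synthetic subject per region: 100 planted selective voxels inside a
#' 216-voxel parcel carry the region latent at unit weight over voxel noise
#' (SD 0.5); predictors are the noiseless latents (7 regions + 7
#' independent counter series). Measures the Dice overlap between the
#' defined movie ssROI and the planted voxel set.
#'
#' @param seed RNG seed
#' @param noise_sd voxel noise SD (default 0.5)
#' @param t_movie run length in TRs (default 168)
#' @return named numeric vector of Dice coefficients, one per region
#' @export
recovery_experiment <- function(seed = 1, noise_sd = 0.5, t_movie = 168) {
  regs <- region_table()$region
  labels <- c(regs, paste0(regs, "_counter"))
  lat <- make_latent_timecourses(t_movie, labels, seed = seed)
  cfg <- cohort_config()
  grid <- default_grid(cfg$grid_dim, cfg$voxel_mm)
  parcels <- cohort_parcels(cfg)[regs]
  dice <- stats::setNames(numeric(length(regs)), regs)
  with_seed(seed + 7L, {
    nvox <- prod(grid$dim)
    for (region in regs) {
      idx <- parcel_indices(parcels[[region]])
      planted <- sort(sample(idx, 100))
      Y <- matrix(stats::rnorm(nvox * t_movie, sd = noise_sd), nvox, t_movie)
      Y[planted + 1L, ] <- Y[planted + 1L, ] +
        rep(lat[, region], each = length(planted))
      anti <- setdiff(idx, planted)
      Y[anti + 1L, ] <- Y[anti + 1L, ] -
        rep(0.2 * lat[, region], each = length(anti))
      roi <- define_movie_ssroi(Y, lat, parcels[[region]], region, k = 100)
      dice[region] <- 2 * length(intersect(roi$voxels, planted)) /
        (length(roi$voxels) + length(planted))
    }
  })
  dice
}

#' Artifact-detection experiment
#'
#' Generates single-subject movie runs through the cohort generator (3-mm
#' planted motion steps, global-signal excursions, 0.1-mm background motion
#' random walk), runs the artifact detector at its default thresholds, and
#' scores flagged TRs against the planted ones.
#'
#' @param n_seeds number of independent subjects (default 20)
#' @param seed base seed
#' @return list(sensitivity, specificity, n_planted, n_flagged)
#' @export
artifact_detection_experiment <- function(n_seeds = 20, seed = 1) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n_seeds)) {
    dir <- tempfile("artifact_exp")
    cc <- cohort_config(groups = list(adult = list(n = 1, ages = 25)),
                        localizer_groups = character(0),
                        seed = seed + i)
    man <- generate_cohort(cc, dir)
    sid <- man$subjects[[1]]$subject_id
    planted <- man$subjects[[1]]$artifact_trs_movie
    ds <- load_dataset(dir)
    bold <- read_bold(file.path(dir, sid, "func_movie.nii.gz"),
                      subject_id = sid)
    motion <- read_motion(file.path(dir, sid, "motion_movie.tsv"))
    d <- dim(bold$data)
    X <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
    gs <- colMeans(X[ds$brain_idx + 1L, , drop = FALSE])
    mask <- detect_artifact_timepoints(motion, gs)
    flagged <- which(as.logical(mask))
    tp <- tp + length(intersect(flagged, planted))
    fp <- fp + length(setdiff(flagged, planted))
    fn <- fn + length(setdiff(planted, flagged))
    tn <- tn + (d[4] - length(union(flagged, planted)))
    unlink(dir, recursive = TRUE)
  }
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = tn / (tn + fp),
       n_planted = tp + fn, n_flagged = tp + fp)
}

#' Planted-lag detection experiment
#'
#' Child timecourses are the adult latent delayed by one TR plus voxel-level
#' noise; counts the seeds in which shifting the child timecourse one TR
#' earlier increases its correlation with the adult latent.
#'
#' @param n_seeds number of seeds (default 20)
#' @param noise_sd noise SD on the child timecourse (default 0.5)
#' @param seed base seed
#' @return list(n_improved, n_seeds)
#' @export
lag_experiment <- function(n_seeds = 20, noise_sd = 0.5, seed = 1) {
  n_improved <- 0L
  for (i in seq_len(n_seeds)) {
    lat <- make_latent_timecourses(168, "adult", seed = seed + 100 + i)[, 1]
    child <- with_seed(seed + 200 + i,
                       delay_tc(lat, 1) + stats::rnorm(168, sd = noise_sd))
    r_shift <- stats::cor(shift_timecourse(child, -1), lat,
                          use = "complete.obs")
    r_plain <- stats::cor(child, lat)
    if (r_shift > r_plain) n_improved <- n_improved + 1L
  }
  list(n_improved = n_improved, n_seeds = n_seeds)
}

#' Noiseless split-half experiment
#'
#' A noiseless subject whose planted voxels carry the region latents
#' exactly; checks the spliced timecourse length (165 TRs for a 168-TR run)
#' and its correlation with the latent over the kept TRs.
#'
#' @param seed RNG seed (placement of planted voxels)
#' @return list(length_trs, min_latent_r, dice)
#' @export
splithalf_noiseless_experiment <- function(seed = 1) {
  regs <- region_table()$region
  labels <- c(regs, paste0(regs, "_counter"))
  lat <- make_latent_timecourses(168, labels, seed = seed)
  cfg <- cohort_config()
  grid <- default_grid(cfg$grid_dim, cfg$voxel_mm)
  parcels <- cohort_parcels(cfg)[regs]
  nvox <- prod(grid$dim)
  Y <- matrix(0, nvox, 168)
  planted <- list()
  with_seed(seed + 7L, {
    for (region in regs) {
      idx <- parcel_indices(parcels[[region]])
      planted[[region]] <- sort(sample(idx, 100))
      Y[planted[[region]] + 1L, ] <- Y[planted[[region]] + 1L, ] +
        rep(lat[, region], each = 100)
    }
  })
  sp <- split_half_define_extract(Y, lat, parcels, k = 100)
  rs <- vapply(regs, function(region)
    stats::cor(sp$timecourses[[region]], lat[sp$kept_trs, region]),
    numeric(1))
  dice <- vapply(regs, function(region) {
    got <- union(sp$roi_half_A[[region]]$voxels,
                 sp$roi_half_B[[region]]$voxels)
    2 * length(intersect(got, planted[[region]])) /
      (length(got) + length(planted[[region]]))
  }, numeric(1))
  list(length_trs = length(sp$timecourses[[1]]), min_latent_r = min(rs),
       dice = dice, kept_trs = sp$kept_trs)
}

#' Per-TR event-test null calibration
#'
#' iid standard-normal group matrices (no signal): the per-TR one-tailed
#' rejection rate should match alpha, and the mean count of >= 2-TR events
#' should match the closed-form expectation
#' `alpha^2 * (1 + (T-2) * (1-alpha))` for independent TRs.
#'
#' @param n_seeds simulated groups (default 200)
#' @param n_sub subjects per group (default 30)
#' @param t_ TRs (default 168)
#' @param alpha test level (default 0.05)
#' @param seed base seed
#' @return list(sig_rate, event_count_mean, event_count_expected,
#'   event_count_mc_halfwidth)
#' @export
null_calibration_revcorr <- function(n_seeds = 200, n_sub = 30, t_ = 168,
                                     alpha = 0.05, seed = 1) {
  counts <- numeric(n_seeds)
  n_sig <- 0
  with_seed(seed, {
    for (i in seq_len(n_seeds)) {
      Z <- matrix(stats::rnorm(n_sub * t_), n_sub, t_)
      ev <- detect_events(Z, alpha = alpha)
      counts[i] <- nrow(ev$intervals)
      n_sig <- n_sig + sum(ev$significant)
    }
  })
  expected <- alpha^2 * (1 + (t_ - 2) * (1 - alpha))
  list(sig_rate = n_sig / (n_seeds * t_),
       event_count_mean = mean(counts),
       event_count_expected = expected,
       event_count_mc_halfwidth = 1.96 * stats::sd(counts) / sqrt(n_seeds))
}

#' GLM contrast-t null calibration
#'
#' Pure-noise voxel data against a two-condition block design: the rate of
#' |t| exceeding the two-sided 5% critical value should be near 0.05.
#'
#' @param n_seeds simulated datasets (default 50)
#' @param n_vox voxels per dataset (default 200)
#' @param t_ TRs (default 100)
#' @param tr_s TR (default 2)
#' @param seed base seed
#' @return list(exceedance_rate, df)
#' @export
null_calibration_glm <- function(n_seeds = 50, n_vox = 200, t_ = 100,
                                 tr_s = 2, seed = 1) {
  onsets <- seq(0, t_ * tr_s - 40, by = 40)
  timing <- block_timing(data.frame(
    condition = rep(c("A", "B"), length.out = length(onsets)),
    onset_s = onsets, duration_s = 20))
  design <- build_block_design(timing, t_, tr_s)
  n_exc <- 0
  df_used <- NA_integer_
  with_seed(seed, {
    for (i in seq_len(n_seeds)) {
      Y <- matrix(stats::rnorm(n_vox * t_), n_vox, t_)
      fit <- fit_contrast_tmap(Y, design, c(A = 1, B = -1))
      crit <- stats::qt(0.975, df = fit$df)
      n_exc <- n_exc + sum(abs(fit$t) > crit)
      df_used <- fit$df
    }
  })
  list(exceedance_rate = n_exc / (n_seeds * n_vox), df = df_used)
}

#' Selectivity pattern experiment (movie ssROI vs group ROI vs traditional)
#'
#' Full pipeline on an adult-only synthetic cohort: localizer-measured
#' selectivity (contrast t of the preferred versus non-preferred condition,
#' averaged over ROI voxels) compared across whole-parcel group ROIs,
#' traditional ssROIs and movie ssROIs, with a one-sided paired t-test per
#' region for movie > group.
#'
#' @param seed cohort seed
#' @param n_adults adults in the cohort (default 12)
#' @return list(selectivity (per-subject table), movie_vs_group (per-region
#'   one-sided p), traditional_minus_movie (per-region mean difference))
#' @export
selectivity_experiment <- function(seed = 1, n_adults = 12) {
  dir <- tempfile("selectivity_exp")
  cc <- cohort_config(groups = list(adult = list(n = n_adults,
                                                 ages = rep(25, n_adults))),
                      seed = seed)
  generate_cohort(cc, dir)
  out <- tempfile("selectivity_out")
  res <- run_pipeline(run_config(dataset = dir, out = out, seed = seed))
  sel <- res$selectivity
  regions <- unique(sel$region)
  p_mg <- vapply(regions, function(rg) {
    s <- sel[sel$region == rg, ]
    ht <- paired_t(s$movie, s$group_roi)
    if (is.na(ht$t)) return(1)
    if (ht$t > 0) ht$p / 2 else 1 - ht$p / 2
  }, numeric(1))
  tm <- vapply(regions, function(rg) {
    s <- sel[sel$region == rg, ]
    mean(s$traditional - s$movie)
  }, numeric(1))
  unlink(c(dir, out), recursive = TRUE)
  list(selectivity = sel, movie_vs_group = p_mg,
       traditional_minus_movie = tm)
}

#' Developmental pattern experiment (young pSTS, ISC specificity)
#'
#' Full pipeline on a three-group cohort (adults with localizer, 3-year-olds
#' with the pSTS mixing + lag effects, 8-12-year-olds without). Computes,
#' for pSTS, each child's correlation to the leave-one-out 3-year-old group
#' mean versus the adult group mean of spliced movie-ssROI timecourses
#' (paired t per group), the lag contrast for 3-year-olds (shifted vs
#' unshifted correlation to adult traditional targets), and the ISC
#' specificity fraction (own-region target beats the mean non-matching
#' target).
#'
#' @param seed cohort seed
#' @return list(p_3yo, p_old (one-sided paired p values),
#'   mean_diff_3yo, mean_diff_old, lag (paired test for shifted > unshifted
#'   pSTS in 3-year-olds), specificity_fraction, n_subjects)
#' @export
development_experiment <- function(seed = 1) {
  dir <- tempfile("development_exp")
  cc <- cohort_config(
    groups = list(adult = list(n = 12, ages = rep(25, 12)),
                  threeyo = list(n = 17, ages = seq(3, 3.9,
                                                    length.out = 17)),
                  oldchild = list(n = 14, ages = seq(8.5, 12,
                                                     length.out = 14))),
    seed = seed)
  generate_cohort(cc, dir)
  out <- tempfile("development_out")
  res <- run_pipeline(run_config(dataset = dir, out = out, seed = seed))

  groups <- stats::setNames(res$isc$group[!duplicated(res$isc$subject_id)],
                            res$isc$subject_id[!duplicated(res$isc$subject_id)])
  kept <- res$kept
  spl_psts <- t(vapply(kept, function(sid)
    res$spliced[[sid]]$timecourses$pSTS,
    numeric(length(res$spliced[[kept[1]]]$timecourses$pSTS))))
  rownames(spl_psts) <- kept
  ids_3yo <- kept[groups[kept] == "threeyo"]
  ids_old <- kept[groups[kept] == "oldchild"]
  ids_ad <- kept[groups[kept] == "adult"]
  adult_mean <- colMeans(spl_psts[ids_ad, , drop = FALSE], na.rm = TRUE)

  corr_pair <- function(ids) {
    r3 <- vapply(ids, function(sid) {
      m3 <- if (sid %in% ids_3yo)
        loo_group_mean(spl_psts[ids_3yo, , drop = FALSE], sid)
      else colMeans(spl_psts[ids_3yo, , drop = FALSE], na.rm = TRUE)
      stats::cor(spl_psts[sid, ], m3, use = "pairwise.complete.obs")
    }, numeric(1))
    ra <- vapply(ids, function(sid)
      stats::cor(spl_psts[sid, ], adult_mean,
                 use = "pairwise.complete.obs"), numeric(1))
    list(r_3yo_mean = r3, r_adult_mean = ra)
  }
  one_sided <- function(ht, direction) {
    if (is.na(ht$t)) return(1)
    if (direction * ht$t > 0) ht$p / 2 else 1 - ht$p / 2
  }
  c3 <- corr_pair(ids_3yo)
  co <- corr_pair(ids_old)
  p_3yo <- one_sided(paired_t(c3$r_3yo_mean, c3$r_adult_mean), +1)
  p_old <- one_sided(paired_t(co$r_3yo_mean, co$r_adult_mean), -1)

  # lag contrast from the isc table: shifted vs spliced r to the pSTS target
  isc <- res$isc
  own <- isc[isc$region == "pSTS" & isc$target == "pSTS" &
               isc$subject_id %in% ids_3yo, ]
  r_sh <- own$r[own$variant == "shifted"]
  r_pl <- own$r[own$variant == "spliced"]
  lag <- list(p = one_sided(paired_t(r_sh, r_pl), +1),
              mean_diff = mean(r_sh - r_pl),
              n_improved = sum(r_sh > r_pl), n = length(r_sh))

  # ISC specificity over children: own target vs mean non-matching target
  child_spl <- isc[isc$variant == "spliced" &
                     isc$subject_id %in% c(ids_3yo, ids_old), ]
  spec_hits <- 0L; spec_total <- 0L
  for (sid in unique(child_spl$subject_id)) {
    s <- child_spl[child_spl$subject_id == sid, ]
    for (rg in unique(s$region)) {
      own_r <- s$r[s$region == rg & s$target == rg]
      oth_r <- mean(s$r[s$region == rg & s$target != rg], na.rm = TRUE)
      if (is.finite(own_r) && own_r > oth_r) spec_hits <- spec_hits + 1L
      spec_total <- spec_total + 1L
    }
  }
  unlink(c(dir, out), recursive = TRUE)
  list(p_3yo = p_3yo, p_old = p_old,
       mean_diff_3yo = mean(c3$r_3yo_mean - c3$r_adult_mean),
       mean_diff_old = mean(co$r_3yo_mean - co$r_adult_mean),
       lag = lag,
       specificity_fraction = spec_hits / spec_total,
       n_subjects = length(kept))
}
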