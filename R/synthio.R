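# Synthetic multi-subject BOLD cohorts with planted ground truth:
# shared latent region timecourses mixed into parcel voxels, a palindromic
# blocked localizer, motion-artifact timepoints, and developmental effects
# (reduced region differentiation and a delayed pSTS response in young
# children). Everything downstream is testable against the manifest.

#' Smooth, correlated latent region timecourses
#'
#' White Gaussian noise per region, temporally smoothed with a Gaussian
#' kernel (FWHM in TRs) to emulate haemodynamic autocorrelation,
#' standardized, then linearly mixed so the column covariance equals `corr`,
#' and re-standardized to zero mean / unit SD. Sample correlations approach
#' `corr` as T grows.
#'
#' @param T_ number of TRs
#' @param labels region names (columns of the result)
#' @param corr correlation matrix over `labels` (default identity)
#' @param smooth_fwhm_trs Gaussian smoothing FWHM in TRs (default 3)
#' @param seed RNG seed
#' @return T x R matrix, columns named by `labels`, each zero-mean, unit-SD
#' @export
make_latent_timecourses <- function(T_, labels, corr = NULL,
                                    smooth_fwhm_trs = 3, seed = 1) {
  R <- length(labels)
  if (is.null(corr)) corr <- diag(R)
  corr <- as.matrix(corr)
  stopifnot(all(dim(corr) == R))
  if (max(abs(corr - t(corr))) > 1e-10) stop("corr must be symmetric")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("corr is not positive semi-definite")
  mix <- with_seed(seed, {
    X <- matrix(stats::rnorm(T_ * R), T_, R)
    X <- apply(X, 2, gauss_smooth, fwhm = smooth_fwhm_trs)
    X <- scale(X)
    L <- t(chol(corr + diag(1e-12, R)))
    X %*% t(L)
  })
  out <- scale(mix)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  colnames(out) <- labels
  out
}

# Gaussian smoothing along a vector with kernel renormalization at edges.
gauss_smooth <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  sdk <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sdk))
  k <- stats::dnorm(seq(-half, half), sd = sdk)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
  den <- stats::filter(wp, k, sides = 2)[(half + 1):(half + n)]
  as.numeric(num / den)
}

# Evaluate expr with a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Palindromic blocked localizer timing
#'
#' 16 stimulus blocks (4 per condition) of `block_s` seconds arranged in
#' four 4-block segments, with five fixation blocks: one at the start, three
#' between segments, one at the end — 21 blocks, 415.8 s at the defaults.
#' The second half of the stimulus-block order is the reverse of the first
#' half; the first half is a random permutation pair drawn from `seed`.
#'
#' @param n_blocks_per_cond blocks per condition (default 4)
#' @param block_s block duration (default 19.8 s)
#' @param conditions condition labels
#' @param seed RNG seed for the first-half order
#' @return `block_timing` with attribute `block_order` (the 21-slot
#'   sequence, `"fix"` for fixation)
#' @export
make_localizer_timing <- function(n_blocks_per_cond = 4, block_s = 19.8,
                                  conditions = c("faces", "objects",
                                                 "scenes", "scrambled"),
                                  seed = 1) {
  stopifnot(length(conditions) >= 1, n_blocks_per_cond >= 2,
            n_blocks_per_cond %% 2 == 0)
  n_seg <- n_blocks_per_cond  # segments of length n_conditions
  first_half <- with_seed(seed, {
    unlist(lapply(seq_len(n_seg / 2), function(i) sample(conditions)))
  })
  stim <- c(first_half, rev(first_half))
  # interleave fixation: start, between the four segments, end
  seg_len <- length(conditions)
  segs <- split(stim, ceiling(seq_along(stim) / seg_len))
  order <- c("fix", unlist(lapply(segs, function(s) c(s, "fix")),
                           use.names = FALSE))
  onsets <- (seq_along(order) - 1) * block_s
  keep <- order != "fix"
  timing <- block_timing(data.frame(condition = order[keep],
                                    onset_s = onsets[keep],
                                    duration_s = block_s))
  attr(timing, "block_order") <- order
  attr(timing, "run_s") <- length(order) * block_s
  timing
}

#' Default region set and preferences
#'
#' Seven regions: two face (FFA, pSTS), three scene (OPA, PPA, RSC), one
#' object (LOC) and an early-visual control (EVC), with their preferred
#' localizer condition and traditional localizer contrast.
#' @return data.frame(region, preferred, contrast_pos, contrast_neg)
#' @export
region_table <- function() {
  data.frame(
    region = c("FFA", "pSTS", "OPA", "PPA", "RSC", "LOC", "EVC"),
    preferred = c("faces", "faces", "scenes", "scenes", "scenes",
                  "objects", "scrambled"),
    contrast_pos = c("faces", "faces", "scenes", "scenes", "scenes",
                     "objects", "scrambled"),
    contrast_neg = c("objects", "objects", "objects", "objects", "objects",
                     "scrambled", "objects"),
    stringsAsFactors = FALSE)
}

#' Default inter-latent correlation matrix
#'
#' Within-domain pairs (face-face, scene-scene) correlate at `within`,
#' everything else at `between`.
#' @param within,between correlation levels (defaults 0.3 / 0.1)
#' @export
default_latent_corr <- function(within = 0.3, between = 0.1) {
  regs <- region_table()$region
  domain <- c(FFA = "face", pSTS = "face", OPA = "scene", PPA = "scene",
              RSC = "scene", LOC = "object", EVC = "evc")
  R <- length(regs)
  C <- matrix(between, R, R, dimnames = list(regs, regs))
  for (i in seq_len(R)) for (j in seq_len(R))
    if (domain[regs[i]] == domain[regs[j]]) C[i, j] <- within
  diag(C) <- 1
  C
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults encode the emulated study conditions: a 168-TR movie run at
#' TR = 2 s, a 415.8-s palindromic 4-condition localizer, 24x24x18 grid of
#' 2-mm voxels with seven disjoint 6x6x6 parcels plus a white-matter block,
#' 100 planted selective voxels per parcel, and developmental effects for
#' young children (pSTS mixing with the face latent, +1 TR response lag).
#'
#' @param groups named list; each element `list(n =, ages =)` (ages length n)
#' @param t_movie movie volumes (default 168)
#' @param tr_s TR in seconds (default 2)
#' @param grid_dim,voxel_mm grid geometry
#' @param parcel_side side of the cubic parcels (default 6)
#' @param n_selective planted selective voxels per parcel (default 100)
#' @param weight selectivity gain (default 1)
#' @param anti_pref gain of the weak anti-preference in non-selective parcel
#'   voxels (default 0.2)
#' @param noise_sd voxel noise SD (default 0.5)
#' @param shared_sd subject-global shared noise SD (default 0.2)
#' @param latent_corr inter-latent correlation matrix
#' @param smooth_fwhm_trs latent smoothing FWHM (default 3 TRs)
#' @param artifact_rate expected fraction of artifact TRs (default 0.06)
#' @param motion_spike_mm planted spike magnitude (default 3 mm)
#' @param gs_spike global-signal excursion at artifact TRs, signal units
#' @param child_psts_mix fraction of the FFA latent mixed into pSTS at age
#'   3, decaying linearly to 0 at age 8 (default 0.6)
#' @param child_lag_trs response delay (TRs) of pSTS in children younger
#'   than 5 (default 1)
#' @param localizer_groups groups that also get a localizer run
#' @param n_localizer_runs localizer runs per localizer subject
#' @param qc_fail_ids subject ids forced to fail QC (60/168 artifact TRs)
#' @param seed root seed; every derived seed is recorded in the manifest
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(groups = list(
                            adult = list(n = 12, ages = rep(25, 12)),
                            threeyo = list(n = 17,
                                           ages = seq(3, 4, length.out = 17))),
                          t_movie = 168, tr_s = 2,
                          grid_dim = c(24L, 24L, 18L), voxel_mm = 2,
                          parcel_side = 6, n_selective = 100, weight = 1,
                          anti_pref = 0.2, noise_sd = 0.5, shared_sd = 0.2,
                          latent_corr = default_latent_corr(),
                          smooth_fwhm_trs = 3,
                          artifact_rate = 0.06, motion_spike_mm = 3,
                          gs_spike = 3,
                          child_psts_mix = 0.6, child_lag_trs = 1,
                          localizer_groups = "adult", n_localizer_runs = 1,
                          qc_fail_ids = character(0), seed = 1) {
  stopifnot(t_movie >= 2, tr_s > 0, n_selective >= 1, noise_sd >= 0,
            shared_sd >= 0, artifact_rate >= 0, artifact_rate <= 1,
            child_psts_mix >= 0, child_psts_mix <= 1)
  for (g in names(groups)) {
    stopifnot(groups[[g]]$n >= 1,
              length(groups[[g]]$ages) == groups[[g]]$n)
  }
  structure(as.list(environment()), class = "cohort_config")
}

# Parcel placement: eight disjoint cube slots, seven regions + white matter.
cohort_parcels <- function(config) {
  d <- config$grid_dim
  s <- config$parcel_side
  starts <- rbind(c(2, 2, 2), c(14, 2, 2), c(2, 14, 2), c(14, 14, 2),
                  c(2, 2, 10), c(14, 2, 10), c(2, 14, 10), c(14, 14, 10))
  labels <- c(region_table()$region, "wm")
  if (any(starts + s > matrix(d, 8, 3, byrow = TRUE)))
    stop("grid too small for the default parcel layout")
  out <- list()
  occupied <- array(FALSE, dim = d)
  for (i in seq_along(labels)) {
    m <- array(FALSE, dim = d)
    rng <- lapply(1:3, function(a) (starts[i, a] + 1):(starts[i, a] + s))
    m[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
    if (any(occupied & m))
      stop("parcels overlap; a voxel would be selective for two regions")
    occupied <- occupied | m
    out[[labels[i]]] <- parcel(m, label = labels[i])
  }
  out
}

# Age-dependent effect sizes: mixing decays linearly from `mix` at age 3
# to 0 at age 8; the response lag applies below age 5.
child_effects <- function(age, mix, lag) {
  m <- if (age >= 8) 0 else if (age <= 3) mix else mix * (8 - age) / 5
  l <- if (age < 5) lag else 0L
  list(mix = m, lag = as.integer(l))
}

# Delay a timecourse by `lag` TRs (value at t becomes value at t+lag),
# padding the lead with the first value.
delay_tc <- function(x, lag) {
  if (lag == 0) return(x)
  n <- length(x)
  c(rep(x[1], lag), x[seq_len(n - lag)])
}

#' Generate a synthetic cohort on disk
#'
#' Writes the full dataset layout (per-subject movie and localizer NIfTI
#' runs, motion TSVs, parcels, white-matter mask, participants table) plus a
#' ground-truth manifest (`ground_truth.json`) and the latent timecourses
#' (`latents.tsv`). Within each parcel, `n_selective` voxels carry
#' `weight x latent` (plus an HRF-convolved condition response in the
#' localizer); the remaining parcel voxels carry a weak anti-preference.
#' Planted artifact TRs get a 3-mm motion step and a global-signal
#' excursion. Children get the configured pSTS mixing and lag.
#'
#' @param config `cohort_config`
#' @param out_dir output directory (created)
#' @return the ground-truth manifest (invisibly written as JSON), a list
#'   with elements grid, parcels, latents, subjects, config echoes
#' @export
generate_cohort <- function(config = cohort_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- default_grid(config$grid_dim, config$voxel_mm)
  parcels <- cohort_parcels(config)
  wm <- parcels$wm
  parcels <- parcels[region_table()$region]
  regs <- region_table()

  latent_seed <- (config$seed * 1000L) %% .Machine$integer.max
  latents <- make_latent_timecourses(config$t_movie, regs$region,
                                     corr = config$latent_corr,
                                     smooth_fwhm_trs = config$smooth_fwhm_trs,
                                     seed = latent_seed)

  # masks + latents on disk
  dir.create(file.path(out_dir, "parcels"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "wm_masks"), showWarnings = FALSE)
  for (p in parcels)
    write_bold(p$mask, file.path(out_dir, "parcels",
                                 paste0(p$label, ".nii.gz")), grid = grid)
  write_bold(wm$mask, file.path(out_dir, "wm_masks", "wm.nii.gz"),
             grid = grid)
  write_timecourse_table(as.data.frame(latents),
                         file.path(out_dir, "latents.tsv"))

  # planted selective voxels per region (deterministic in the root seed)
  sel <- with_seed((config$seed * 1000L + 777L) %% .Machine$integer.max, {
    lapply(parcels, function(p) {
      idx <- parcel_indices(p)
      if (config$n_selective > length(idx))
        stop("n_selective exceeds parcel size")
      sort(sample(idx, config$n_selective))
    })
  })

  # localizer timing shared across runs/subjects except the order seed
  t_loc <- as.integer(ceiling(21 * 19.8 / config$tr_s))

  subjects <- list()
  rows <- list()
  si <- 0L
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    for (j in seq_len(grp$n)) {
      si <- si + 1L
      sid <- sprintf("sub-%s%02d", g, j)
      sseed <- (config$seed * 100000L + si * 131L) %% .Machine$integer.max
      age <- grp$ages[j]
      eff <- child_effects(age, config$child_psts_mix, config$child_lag_trs)
      has_loc <- g %in% config$localizer_groups
      info <- simulate_subject(sid, g, age, eff, sseed, config, grid,
                               parcels, wm, sel, latents, t_loc,
                               out_dir, with_localizer = has_loc,
                               qc_fail = sid %in% config$qc_fail_ids)
      subjects[[sid]] <- info
      rows[[sid]] <- data.frame(subject_id = sid, group = g,
                                age_years = age, stringsAsFactors = FALSE)
    }
  }
  participants <- do.call(rbind, rows)
  utils::write.table(participants, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    grid_dim = grid$dim, voxel_mm = config$voxel_mm,
    t_movie = config$t_movie, tr_s = config$tr_s,
    regions = regs$region,
    preferred = stats::setNames(regs$preferred, regs$region),
    selective_voxels = sel,
    weight = config$weight, anti_pref = config$anti_pref,
    noise_sd = config$noise_sd, shared_sd = config$shared_sd,
    latent_corr = config$latent_corr,
    child_psts_mix = config$child_psts_mix,
    child_lag_trs = config$child_lag_trs,
    subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, list(latents = latents, dataset_dir = out_dir)))
}

# Simulate and write one subject (movie + optional localizer run).
simulate_subject <- function(sid, group, age, eff, sseed, config, grid,
                             parcels, wm, sel, latents, t_loc, out_dir,
                             with_localizer = TRUE, qc_fail = FALSE) {
  sdir <- file.path(out_dir, sid)
  dir.create(sdir, showWarnings = FALSE)
  T_ <- config$t_movie
  nvox <- prod(grid$dim)
  regs <- region_table()

  with_seed(sseed, {
    # subject-specific latent view: children get mixed + delayed pSTS
    lat <- latents
    if (eff$mix > 0 || eff$lag > 0) {
      mixed <- (1 - eff$mix) * lat[, "pSTS"] + eff$mix * lat[, "FFA"]
      mixed <- (mixed - mean(mixed)) / stats::sd(mixed)
      lat[, "pSTS"] <- delay_tc(mixed, eff$lag)
    }

    movie <- build_run(lat, T_, config, grid, parcels, wm, sel,
                       design = NULL)
    art_movie <- plant_artifacts(T_, config, qc_fail)
    movie$data <- add_gs_excursion(movie$data, art_movie$trs,
                                   config$gs_spike)
    write_bold(bold_run(array(movie$data, dim = c(grid$dim, T_)),
                        tr_s = config$tr_s, affine = grid$affine,
                        subject_id = sid, run_label = "movie"),
               file.path(sdir, "func_movie.nii.gz"))
    write_motion(art_movie$motion, file.path(sdir, "motion_movie.tsv"))

    art_loc_trs <- integer(0)
    if (with_localizer) {
      timing <- make_localizer_timing(seed = (sseed + 17L) %%
                                        .Machine$integer.max)
      design <- build_block_design(timing, t_loc, config$tr_s)
      loc <- build_run(NULL, t_loc, config, grid, parcels, wm, sel,
                       design = design)
      art_loc <- plant_artifacts(t_loc, config, FALSE)
      loc$data <- add_gs_excursion(loc$data, art_loc$trs, config$gs_spike)
      write_bold(bold_run(array(loc$data, dim = c(grid$dim, t_loc)),
                          tr_s = config$tr_s, affine = grid$affine,
                          subject_id = sid, run_label = "localizer"),
                 file.path(sdir, "func_localizer.nii.gz"))
      write_motion(art_loc$motion, file.path(sdir, "motion_localizer.tsv"))
      write_block_timing(timing, file.path(sdir, "localizer_timing.tsv"))
      art_loc_trs <- art_loc$trs
    }

    list(subject_id = sid, group = group, age_years = age, seed = sseed,
         mix = eff$mix, lag = eff$lag,
         artifact_trs_movie = art_movie$trs,
         artifact_trs_localizer = art_loc_trs,
         localizer = if (with_localizer) "func_localizer.nii.gz" else NA)
  })
}

# Core voxel model shared by the movie (latent-driven) and localizer
# (design-driven) runs. Returns nvox x T matrix.
build_run <- function(lat, T_, config, grid, parcels, wm, sel, design) {
  nvox <- prod(grid$dim)
  g <- config$shared_sd * gauss_smooth(stats::rnorm(T_), 3)
  data <- matrix(stats::rnorm(nvox * T_, sd = config$noise_sd), nvox, T_)
  data <- sweep(data, 2, g, "+")
  regs <- region_table()
  for (r in seq_len(nrow(regs))) {
    region <- regs$region[r]
    p <- parcels[[region]]
    idx <- parcel_indices(p)
    sidx <- sel[[region]]
    nidx <- setdiff(idx, sidx)
    if (is.null(design)) {
      sig <- lat[, region]
    } else {
      sig <- design[, regs$preferred[r]]
    }
    data[sidx + 1L, ] <- data[sidx + 1L, ] +
      rep(config$weight * sig, each = length(sidx))
    if (length(nidx) > 0 && config$anti_pref > 0)
      data[nidx + 1L, ] <- data[nidx + 1L, ] -
        rep(config$anti_pref * config$weight * sig, each = length(nidx))
  }
  list(data = data, shared = g)
}

# Sample artifact TRs and build the motion trace: a slow random walk plus
# persistent 3-mm steps at the planted TRs.
plant_artifacts <- function(T_, config, qc_fail) {
  n_art <- if (qc_fail) 60L
           else stats::rbinom(1, T_ - 1, config$artifact_rate)
  trs <- if (n_art > 0) sort(sample(2:T_, min(n_art, T_ - 1))) else integer(0)
  steps <- matrix(stats::rnorm(T_ * 6, sd = c(rep(0.1, 3), rep(0.001, 3))),
                  T_, 6, byrow = TRUE)
  steps[1, ] <- 0
  if (length(trs) > 0) {
    ax <- sample(1:3, length(trs), replace = TRUE)
    steps[cbind(trs, ax)] <- steps[cbind(trs, ax)] +
      config$motion_spike_mm * sample(c(-1, 1), length(trs), replace = TRUE)
  }
  motion <- apply(steps, 2, cumsum)
  list(trs = trs, motion = motion)
}

# Global-signal excursion: constant offset added to every voxel at the
# planted TRs.
add_gs_excursion <- function(data, trs, amplitude) {
  if (length(trs) > 0 && amplitude != 0)
    data[, trs] <- data[, trs] + amplitude
  data
}
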