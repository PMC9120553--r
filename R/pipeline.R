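# End-to-end orchestration: simulate -> preprocess -> localizer GLM ->
# ROI definition -> split-half extraction -> reverse correlation ->
# inter-regional correlation, with a resolved config and an output manifest.

#' Pipeline run configuration
#'
#' All stage parameters at their standard defaults: 2 mm composite-motion
#' and 3 SD global-signal artifact thresholds, 100 s high-pass, 5 CompCor
#' components, k = 100 voxels per ssROI, 82/86 split with a 3-TR guard,
#' alpha = 0.05 for the per-TR event test, and a -1 TR (earlier) shift for
#' the lag analysis.
#'
#' @param dataset dataset directory (layout as written by
#'   [generate_cohort()])
#' @param out output directory
#' @param motion_mm,gs_sd artifact thresholds
#' @param hp_s high-pass cutoff (s)
#' @param ncomp CompCor components
#' @param k ssROI size
#' @param split split-half boundaries (1-based TRs)
#' @param alpha event-test significance level
#' @param shift lag shift in TRs for the shifted variant
#' @param head_radius_mm rotation-to-displacement radius
#' @param tr_s TR override (NULL to trust headers)
#' @param seed root seed (recorded; the pipeline itself is deterministic)
#' @return list of class `run_config`
#' @export
run_config <- function(dataset, out, motion_mm = 2, gs_sd = 3, hp_s = 100,
                       ncomp = 5, k = 100, split = c(82L, 86L),
                       alpha = 0.05, shift = -1L, head_radius_mm = 65,
                       tr_s = NULL, seed = 1) {
  if (missing(dataset) || is.null(dataset))
    stop("config must name a dataset directory")
  structure(as.list(environment()), class = "run_config")
}

#' Load a dataset's cohort-level pieces
#' @param dir dataset directory
#' @return list(participants, parcels, wm, brain_idx)
#' @export
load_dataset <- function(dir) {
  pfile <- file.path(dir, "participants.tsv")
  if (!file.exists(pfile)) stop("no participants.tsv under ", dir)
  participants <- utils::read.delim(pfile, stringsAsFactors = FALSE)
  pdir <- file.path(dir, "parcels")
  pfiles <- list.files(pdir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(pfiles) == 0) stop("no parcels under ", pdir)
  parcels <- lapply(pfiles, read_parcel)
  names(parcels) <- vapply(parcels, function(p) p$label, character(1))
  ord <- intersect(region_table()$region, names(parcels))
  parcels <- parcels[c(ord, setdiff(names(parcels), ord))]
  wm <- read_parcel(file.path(dir, "wm_masks", "wm.nii.gz"), label = "wm")
  brain <- Reduce(`|`, lapply(parcels, function(p) p$mask))
  list(participants = participants, parcels = parcels, wm = wm,
       brain_idx = which(brain) - 1L)
}

# Preprocess one run of one subject: artifact detection on raw data,
# CompCor from the eroded white-matter mask, nuisance regression, high-pass.
preprocess_run <- function(dir, sid, run, ds, wm_idx, cfg) {
  bfile <- file.path(dir, sid, paste0("func_", run, ".nii.gz"))
  mfile <- file.path(dir, sid, paste0("motion_", run, ".tsv"))
  bold <- read_bold(bfile, tr_s = cfg$tr_s, subject_id = sid,
                    run_label = run)
  motion <- read_motion(mfile)
  d <- dim(bold$data)
  X <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  gs <- colMeans(X[ds$brain_idx + 1L, , drop = FALSE])
  mask <- detect_artifact_timepoints(motion, gs, motion_mm = cfg$motion_mm,
                                     gs_sd = cfg$gs_sd,
                                     head_radius_mm = cfg$head_radius_mm)
  passed <- subject_passes_qc(mask)
  cleaned <- NULL
  if (passed) {
    comps <- compute_compcor(X[wm_idx + 1L, , drop = FALSE], mask,
                             n_components = cfg$ncomp)
    nu <- nuisance_set(mask, comps)
    cleaned <- clean_voxel_timecourses(X, mask, nu, tr_s = bold$tr_s,
                                       cutoff_s = cfg$hp_s)
  }
  list(cleaned = cleaned, mask = mask, n_artifacts = sum(mask),
       passed = passed, tr_s = bold$tr_s)
}

#' Run the full analysis pipeline on a dataset
#'
#' Stages, in dependency order: per-subject preprocessing and QC of the
#' movie run (subjects with one-third or more artifact TRs are dropped
#' everywhere downstream); localizer GLM and traditional + counter ssROIs
#' for subjects with a localizer run; leave-one-out predictor sets; movie
#' ssROIs (full run) and split-half spliced timecourses; localizer
#' selectivity extracted from group ROIs, traditional ssROIs and movie
#' ssROIs; reverse-correlation events per group; inter-regional correlations
#' of spliced timecourses against leave-one-out adult traditional targets,
#' plain and lag-shifted. Writes tidy TSV/JSON outputs plus a manifest, and
#' returns everything invisibly.
#'
#' @param cfg `run_config`
#' @return (invisible) list: qc, selectivity, isc (long data.frame),
#'   events (per group), spliced (per subject), rois, manifest
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  ds <- load_dataset(cfg$dataset)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  regs <- region_table()
  regions <- intersect(regs$region, names(ds$parcels))
  parcels <- ds$parcels[regions]
  wm_er <- erode_mask(ds$wm, iterations = 2)
  wm_idx <- parcel_indices(wm_er)

  subs <- ds$participants$subject_id
  groups <- stats::setNames(ds$participants$group, subs)
  ages <- stats::setNames(ds$participants$age_years, subs)

  qc <- list(); movie <- list()
  for (sid in subs) {
    pr <- preprocess_run(cfg$dataset, sid, "movie", ds, wm_idx, cfg)
    qc[[sid]] <- data.frame(subject_id = sid, run = "movie",
                            n_artifacts = pr$n_artifacts,
                            passed = pr$passed)
    if (pr$passed) movie[[sid]] <- pr
  }
  kept <- names(movie)

  # ---- localizer GLM -> traditional + counter ssROIs -----------------------
  trad <- list()   # per subject: list(roi=, counter=, tmap_fit per region)
  for (sid in kept) {
    lfile <- file.path(cfg$dataset, sid, "func_localizer.nii.gz")
    if (!file.exists(lfile)) next
    pr <- preprocess_run(cfg$dataset, sid, "localizer", ds, wm_idx, cfg)
    if (!pr$passed) next
    timing <- read_block_timing(file.path(cfg$dataset, sid,
                                          "localizer_timing.tsv"))
    design <- build_block_design(timing, ncol(pr$cleaned), pr$tr_s)
    Y <- pr$cleaned
    Y[, as.logical(pr$mask)] <- NA_real_   # artifact TRs excluded listwise
    rois <- list(); counters <- list(); tfits <- list()
    for (r in seq_len(nrow(regs))) {
      region <- regs$region[r]
      if (!region %in% regions) next
      idx <- parcel_indices(parcels[[region]])
      fit <- fit_contrast_tmap(Y[idx + 1L, , drop = FALSE], design,
                               stats::setNames(c(1, -1),
                                               c(regs$contrast_pos[r],
                                                 regs$contrast_neg[r])))
      rois[[region]] <- top_k_voxels(fit$t, parcels[[region]], k = cfg$k,
                                     tail = "top", method = "traditional")
      counters[[region]] <- top_k_voxels(fit$t, parcels[[region]],
                                         k = cfg$k, tail = "bottom")
      tfits[[region]] <- fit
    }
    trad[[sid]] <- list(roi = rois, counter = counters, tmap = tfits,
                        design = design, cleaned_localizer = Y,
                        localizer_mask = pr$mask)
  }
  loc_ids <- names(trad)
  if (length(loc_ids) < 2)
    stop("need at least 2 QC-passing subjects with a localizer run")

  # movie timecourses from traditional + counter ROIs (artifact-NaNed)
  cohort_tcs <- lapply(loc_ids, function(sid) {
    cl <- movie[[sid]]$cleaned; msk <- movie[[sid]]$mask
    list(roi = lapply(trad[[sid]]$roi, function(r)
           roi_mean_timecourse(cl, r, msk)),
         counter = lapply(trad[[sid]]$counter, function(r)
           roi_mean_timecourse(cl, r, msk)))
  })
  names(cohort_tcs) <- loc_ids

  predictors <- lapply(kept, function(sid) {
    if (sid %in% loc_ids) build_predictor_set(cohort_tcs, leave_out = sid)
    else build_predictor_set(cohort_tcs)
  })
  names(predictors) <- kept

  # ---- movie ssROIs (full run) + split-half spliced timecourses ------------
  movie_rois <- list(); spliced <- list()
  for (sid in kept) {
    cl <- movie[[sid]]$cleaned
    msk <- as.logical(movie[[sid]]$mask)
    P <- predictors[[sid]]
    Pna <- P; Pna[msk, ] <- NA_real_  # never fit on artifact TRs
    rois <- lapply(regions, function(region)
      define_movie_ssroi(cl, Pna, parcels[[region]], region, k = cfg$k))
    names(rois) <- regions
    movie_rois[[sid]] <- rois
    sp <- split_half_define_extract(cl, Pna, parcels, k = cfg$k,
                                    split = cfg$split,
                                    artifact_mask = msk)
    spliced[[sid]] <- sp
  }

  # ---- localizer selectivity in group / traditional / movie ROIs -----------
  selectivity <- list()
  for (sid in loc_ids) {
    for (region in regions) {
      tarr <- tmap_from_fit(trad[[sid]]$tmap[[region]],
                            parcel_indices(parcels[[region]]),
                            dim(parcels[[region]]$mask))
      mean_t <- function(voxels) mean(tarr$t[voxels + 1L], na.rm = TRUE)
      selectivity[[length(selectivity) + 1L]] <- data.frame(
        subject_id = sid, region = region,
        group_roi = mean_t(parcel_indices(parcels[[region]])),
        traditional = mean_t(trad[[sid]]$roi[[region]]$voxels),
        movie = mean_t(movie_rois[[sid]][[region]]$voxels))
    }
  }
  selectivity <- do.call(rbind, selectivity)

  # ---- reverse correlation per group ---------------------------------------
  events <- list(); group_z <- list()
  for (g in unique(groups[kept])) {
    gids <- kept[groups[kept] == g]
    if (length(gids) < 3) next
    events[[g]] <- list(); group_z[[g]] <- list()
    for (region in regions) {
      Z <- t(vapply(gids, function(sid)
        znormalize(spliced[[sid]]$timecourses[[region]]),
        numeric(length(spliced[[gids[1]]]$timecourses[[region]]))))
      rownames(Z) <- gids
      group_z[[g]][[region]] <- Z
      events[[g]][[region]] <- detect_events(Z, alpha = cfg$alpha)
    }
  }

  # ---- inter-regional correlations vs adult traditional targets ------------
  kept_trs <- spliced[[kept[1]]]$kept_trs
  target_bank <- function(exclude = NULL) {
    ids <- setdiff(loc_ids, exclude)
    sapply(regions, function(rg) {
      M <- vapply(ids, function(sid) cohort_tcs[[sid]]$roi[[rg]][kept_trs],
                  numeric(length(kept_trs)))
      m <- rowMeans(as.matrix(M), na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      m
    })
  }
  isc <- list()
  for (sid in kept) {
    targets <- target_bank(exclude = if (sid %in% loc_ids) sid else NULL)
    for (region in regions) {
      tc <- spliced[[sid]]$timecourses[[region]]
      for (variant in c("spliced", "shifted")) {
        v <- if (variant == "shifted") shift_timecourse(tc, cfg$shift)
             else tc
        prof <- suppressWarnings(correlate_to_targets(v, targets))
        isc[[length(isc) + 1L]] <- data.frame(
          subject_id = sid, group = groups[[sid]],
          age_years = ages[[sid]],
          n_artifacts = qc[[sid]]$n_artifacts,
          region = region, target = prof$target, r = prof$r, z = prof$z,
          n_pairs = prof$n_pairs, variant = variant)
      }
    }
  }
  isc <- do.call(rbind, isc)
  rownames(isc) <- NULL

  # ---- outputs -------------------------------------------------------------
  qc <- do.call(rbind, qc); rownames(qc) <- NULL
  utils::write.table(qc, file.path(cfg$out, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(isc, file.path(cfg$out, "isc_long.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(selectivity, file.path(cfg$out, "selectivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr_movie <- movie[[kept[1]]]$tr_s
  ev_json <- lapply(events, function(by_region)
    lapply(by_region, function(e)
      list(alpha = e$alpha,
           intervals = e$intervals,
           intervals_s = data.frame(start_s = (e$intervals$start_tr - 1) *
                                      tr_movie,
                                    end_s = e$intervals$end_tr * tr_movie))))
  jsonlite::write_json(ev_json, file.path(cfg$out, "events.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg_out <- cfg; class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, file.path(cfg$out, "config_resolved.yaml"))
  manifest <- list(
    dataset = cfg$dataset, seed = cfg$seed,
    parameters = cfg_out[setdiff(names(cfg_out), c("dataset", "out"))],
    subjects = lapply(subs, function(sid)
      list(subject_id = sid, group = groups[[sid]],
           n_artifacts = qc$n_artifacts[qc$subject_id == sid],
           qc_passed = qc$passed[qc$subject_id == sid],
           has_localizer = sid %in% loc_ids)),
    outputs = c("qc.tsv", "isc_long.tsv", "selectivity.tsv", "events.json",
                "config_resolved.yaml", "manifest.json"))
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(qc = qc, selectivity = selectivity, isc = isc,
                 events = events, group_z = group_z, spliced = spliced,
                 movie_rois = movie_rois, traditional = trad,
                 predictors = predictors, cohort_tcs = cohort_tcs,
                 kept = kept, manifest = manifest))
}
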