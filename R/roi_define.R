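# Group-constrained subject-specific ROI definition: top-k / bottom-k voxel
# selection on contrast t-maps, the 14-predictor movie regression with its
# per-region contrast table, and the split-half define/extract/splice
# procedure that keeps definition and measurement independent within a
# single run.

#' Select the top (or bottom) k voxels of a parcel by t-value
#'
#' Voxels inside the parcel are ranked by the contrast t statistic,
#' descending for `tail = "top"` (the ssROI) or ascending for
#' `tail = "bottom"` (the counter ROI, the least selective voxels). Ties are
#' broken by ascending linear voxel index. If the parcel holds fewer than
#' `k` voxels the whole parcel is returned with a warning.
#'
#' @param tmap `tmap` (3D t array) or numeric vector of per-voxel t values
#'   aligned with `parcel_indices(parcel)`
#' @param parcel `parcel` search space
#' @param k ROI size (default 100)
#' @param tail `"top"` or `"bottom"`
#' @param method method tag stored on the result
#' @return `ssroi`
#' @export
top_k_voxels <- function(tmap, parcel, k = 100, tail = c("top", "bottom"),
                         method = NULL) {
  tail <- match.arg(tail)
  idx <- parcel_indices(parcel)
  tv <- if (inherits(tmap, "tmap")) tmap$t[idx + 1L] else as.numeric(tmap)
  if (length(tv) != length(idx))
    stop("t values do not align with the parcel voxels")
  if (all(is.na(tv))) stop("all t values inside the parcel are missing")
  if (k > length(idx)) {
    warning("parcel ", parcel$label, " has only ", length(idx),
            " voxels (< k = ", k, "); returning all")
    k_eff <- length(idx)
  } else k_eff <- k
  key <- if (tail == "top") -tv else tv
  ord <- order(key, idx, na.last = TRUE)
  if (is.null(method)) method <- if (tail == "top") "traditional" else "counter"
  ssroi(label = parcel$label, method = method,
        voxels = idx[ord[seq_len(k_eff)]], k = k,
        parcel_label = parcel$label)
}

#' Build the 14-predictor set for movie ssROI definition
#'
#' Per-TR mean, across contributing subjects, of each region's traditional
#' ssROI timecourse and counter-ROI timecourse (7 + 7 predictors), with the
#' left-out subject excluded from every mean. Missing entries are ignored
#' per TR; a TR missing in every contributor stays missing.
#'
#' @param cohort_tcs named list: per subject, a list with elements `roi` and
#'   `counter`, each a named list of region timecourses (equal length T)
#' @param leave_out subject id to exclude, or NULL
#' @return T x 14 matrix with columns `<region>` and `<region>_counter`,
#'   attribute `source` recording the contributing subjects
#' @export
build_predictor_set <- function(cohort_tcs, leave_out = NULL) {
  ids <- names(cohort_tcs)
  if (!is.null(leave_out)) {
    if (!leave_out %in% ids)
      warning("leave_out subject '", leave_out, "' not among contributors")
    ids <- setdiff(ids, leave_out)
    if (length(ids) < 1)
      stop("no contributors left after leave-one-out")
  }
  regions <- names(cohort_tcs[[ids[1]]]$roi)
  T_ <- length(cohort_tcs[[ids[1]]]$roi[[1]])
  nacol_mean <- function(kind) {
    out <- vapply(regions, function(rg) {
      M <- vapply(ids, function(id) {
        tc <- cohort_tcs[[id]][[kind]][[rg]]
        if (length(tc) != T_) stop("timecourse length mismatch for ", id)
        tc
      }, numeric(T_))
      rowMeans(as.matrix(M), na.rm = TRUE)
    }, numeric(T_))
    colnames(out) <- regions
    out
  }
  roi_m <- nacol_mean("roi")
  ctr_m <- nacol_mean("counter")
  roi_m[is.nan(roi_m)] <- NA_real_
  ctr_m[is.nan(ctr_m)] <- NA_real_
  colnames(ctr_m) <- paste0(regions, "_counter")
  out <- cbind(roi_m, ctr_m)
  attr(out, "source") <- list(contributors = ids, leave_out = leave_out)
  out
}

#' The per-region movie contrast table
#'
#' Which predictor is contrasted against which when defining each movie
#' ssROI: face and scene regions against the object region's timecourse
#' (mirroring faces>objects / scenes>objects localizer contrasts), LOC
#' against EVC, and EVC against LOC.
#'
#' @return data.frame(region, positive, negative)
#' @export
region_contrast_table <- function() {
  data.frame(
    region = c("FFA", "pSTS", "OPA", "PPA", "RSC", "LOC", "EVC"),
    positive = c("FFA", "pSTS", "OPA", "PPA", "RSC", "LOC", "EVC"),
    negative = c("LOC", "LOC", "LOC", "LOC", "LOC", "EVC", "LOC"),
    stringsAsFactors = FALSE)
}

#' Define a movie ssROI by regression on predictor timecourses
#'
#' Each parcel voxel's movie timecourse is regressed (OLS, with intercept)
#' on all 14 predictors; the per-region contrast t (positive minus negative
#' predictor, per [region_contrast_table()]) ranks voxels and the top `k`
#' are kept. TRs missing in the data or predictors are dropped listwise.
#' Collinear predictors are pruned with a warning, never the two contrast
#' columns.
#'
#' @param cleaned voxel x T cleaned movie matrix (rows = linear index + 1)
#' @param predictors T x 14 matrix from [build_predictor_set()]
#' @param parcel `parcel` search space for the region
#' @param region region label (row of the contrast table)
#' @param table contrast table (default [region_contrast_table()])
#' @param k ROI size (default 100)
#' @param method method tag (default "movie")
#' @return `ssroi` with attribute `t` (the per-parcel-voxel contrast t)
#' @export
define_movie_ssroi <- function(cleaned, predictors, parcel, region,
                               table = region_contrast_table(), k = 100,
                               method = "movie") {
  row <- table[table$region == region, ]
  if (nrow(row) != 1) stop("region '", region, "' not in the contrast table")
  P <- as.matrix(predictors)
  if (!all(c(row$positive, row$negative) %in% colnames(P)))
    stop("contrast predictors missing from the predictor set")
  keep <- prune_collinear(P, protect = c(row$positive, row$negative))
  P <- P[, keep, drop = FALSE]
  design <- cbind(intercept = 1, P)
  idx <- parcel_indices(parcel)
  Y <- cleaned[idx + 1L, , drop = FALSE]
  contrast <- stats::setNames(c(1, -1), c(row$positive, row$negative))
  fit <- fit_contrast_tmap(Y, design, contrast)
  roi <- top_k_voxels(fit$t, parcel, k = k, tail = "top", method = method)
  attr(roi, "t") <- fit$t
  roi
}

# Columns to keep after collinearity pruning (intercept implied); protected
# columns are moved to the front so QR pivoting never drops them.
prune_collinear <- function(P, protect = character(0)) {
  cn <- colnames(P)
  ord <- c(match(protect, cn), setdiff(seq_along(cn), match(protect, cn)))
  D <- cbind(1, P[, ord, drop = FALSE])
  D <- D[stats::complete.cases(D), , drop = FALSE]
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- qrD$pivot[(qrD$rank + 1):ncol(D)] - 1L  # minus intercept col
    dropped <- dropped[dropped > 0]
    warning("pruning collinear predictor(s): ",
            paste(cn[ord][dropped], collapse = ", "))
    keep_ord <- setdiff(seq_along(ord), dropped)
  } else keep_ord <- seq_along(ord)
  sort(ord[keep_ord])
}

#' Split-half definition and crossed extraction of movie timecourses
#'
#' Movie ssROIs are defined separately on the first half of the run
#' (TRs 1..`split[1]`, 1-based inclusive) and on the second half
#' (TRs `split[2]`..T); the guard TRs between the halves are never used.
#' Extraction is crossed: the first-half timecourse is read from the
#' second-half-defined ROI and the second-half timecourse from the
#' first-half-defined ROI, then concatenated (165 TRs for a 168-TR run at
#' the default 82/86 split).
#'
#' @param cleaned voxel x T cleaned movie matrix
#' @param predictors T x 14 predictor matrix (full run)
#' @param parcels named list of `parcel`s, one per region
#' @param table contrast table
#' @param k ROI size
#' @param split length-2 integer: last TR of half A, first TR of half B
#'   (1-based; default c(82, 86))
#' @param artifact_mask optional logical per-TR flags; flagged TRs are
#'   missing in the extracted timecourses
#' @return list with `timecourses` (named list of spliced length-165
#'   vectors), `roi_half_A`, `roi_half_B` (named lists of `ssroi`)
#' @export
split_half_define_extract <- function(cleaned, predictors, parcels,
                                      table = region_contrast_table(),
                                      k = 100, split = c(82L, 86L),
                                      artifact_mask = NULL) {
  T_ <- ncol(cleaned)
  if (split[2] - split[1] < 2)
    stop("split must leave a guard between the halves")
  if (split[2] >= T_) stop("run too short for the requested split")
  iA <- seq_len(split[1])
  iB <- seq(split[2], T_)
  roi_A <- list(); roi_B <- list(); tcs <- list()
  for (region in names(parcels)) {
    roi_A[[region]] <- define_movie_ssroi(cleaned[, iA, drop = FALSE],
                                          predictors[iA, , drop = FALSE],
                                          parcels[[region]], region,
                                          table = table, k = k,
                                          method = "movie_half_A")
    roi_B[[region]] <- define_movie_ssroi(cleaned[, iB, drop = FALSE],
                                          predictors[iB, , drop = FALSE],
                                          parcels[[region]], region,
                                          table = table, k = k,
                                          method = "movie_half_B")
    # crossed extraction: half-A data from half-B ROIs and vice versa
    mA <- if (is.null(artifact_mask)) NULL else artifact_mask[iA]
    mB <- if (is.null(artifact_mask)) NULL else artifact_mask[iB]
    tc_A <- roi_mean_timecourse(cleaned[, iA, drop = FALSE],
                                roi_B[[region]], mA)
    tc_B <- roi_mean_timecourse(cleaned[, iB, drop = FALSE],
                                roi_A[[region]], mB)
    tcs[[region]] <- c(tc_A, tc_B)
  }
  list(timecourses = tcs, roi_half_A = roi_A, roi_half_B = roi_B,
       kept_trs = c(iA, iB))
}
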