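# Timecourse hygiene: artifact detection, QC, interpolation, CompCor
# nuisance regression, DCT high-pass, ROI averaging, NaN-ing.
# Pipeline order is fixed: interpolate -> nuisance regression -> high-pass
# -> ROI average -> NaN artifact TRs.

#' Composite per-TR head displacement
#'
#' Scalar displacement between consecutive TRs combining translations and
#' rotations, following the usual artifact-detection convention: each
#' rotation delta (radians) is converted to the worst-case arc displacement
#' on a sphere of `head_radius_mm`, and the composite is the Euclidean norm
#' of the six converted deltas. The first TR has no predecessor and gets 0.
#'
#' @param motion T x 6 matrix: 3 translations (mm), 3 rotations (rad)
#' @param head_radius_mm nominal head radius (default 65 mm)
#' @return numeric length-T vector of displacements (mm)
#' @export
composite_motion <- function(motion, head_radius_mm = 65) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, all(is.finite(motion)))
  if (nrow(motion) < 2) stop("need at least 2 TRs of motion parameters")
  d <- diff(motion)
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  c(0, sqrt(rowSums(d^2)))
}

#' Detect artifact timepoints
#'
#' A TR is flagged iff (a) composite motion relative to the previous TR
#' exceeds `motion_mm` (strict inequality), or (b) the global signal deviates
#' from its mean by more than `gs_sd` standard deviations. The first TR can
#' only be flagged by the global-signal criterion. Mean and SD of the global
#' signal are computed over the whole run.
#'
#' @param motion T x 6 motion matrix (see [composite_motion()])
#' @param global_signal length-T global signal timecourse
#' @param motion_mm motion threshold in mm (default 2)
#' @param gs_sd global-signal threshold in SD units (default 3)
#' @param head_radius_mm passed to [composite_motion()]
#' @return an `artifact_mask`: logical length-T vector with attribute
#'   `n_flagged`
#' @export
detect_artifact_timepoints <- function(motion, global_signal, motion_mm = 2,
                                       gs_sd = 3, head_radius_mm = 65) {
  gs <- as.numeric(global_signal)
  if (length(gs) < 2) stop("need at least 2 TRs")
  if (nrow(as.matrix(motion)) != length(gs))
    stop("motion and global signal lengths differ")
  disp <- composite_motion(motion, head_radius_mm)
  mflag <- disp > motion_mm
  mflag[1] <- FALSE
  s <- stats::sd(gs)
  gflag <- if (is.finite(s) && s > 0) abs(gs - mean(gs)) > gs_sd * s
           else rep(FALSE, length(gs))
  artifact_mask(mflag | gflag)
}

#' Construct an artifact mask
#' @param flags logical per-TR vector
#' @export
artifact_mask <- function(flags) {
  flags <- as.logical(flags)
  structure(flags, n_flagged = sum(flags), class = "artifact_mask")
}

#' Subject-level quality control
#'
#' A subject fails (is dropped) if one-third or more of the run's timepoints
#' are artifact timepoints.
#'
#' @param mask `artifact_mask` (or logical vector)
#' @return TRUE if the subject is retained
#' @export
subject_passes_qc <- function(mask) {
  flags <- as.logical(mask)
  sum(flags) < length(flags) / 3
}

#' Nearest-neighbour interpolation over artifact timepoints
#'
#' Flagged TRs take the value of the nearest unflagged TR; ties between an
#' earlier and a later neighbour at equal distance go to the earlier one.
#'
#' @param tc numeric timecourse (or matrix voxel x T, interpolated row-wise)
#' @param mask logical per-TR artifact flags
#' @return same shape as `tc`
#' @export
interpolate_artifacts <- function(tc, mask) {
  flags <- as.logical(mask)
  if (all(flags)) stop("all TRs flagged; nothing to interpolate from")
  good <- which(!flags)
  bad <- which(flags)
  if (length(bad) == 0) return(tc)
  # nearest unflagged index per bad TR, earlier wins ties
  src <- vapply(bad, function(b) {
    d <- abs(good - b)
    good[which.min(d)]  # which.min returns the first (earlier) minimum
  }, integer(1))
  if (is.matrix(tc)) {
    tc[, bad] <- tc[, src, drop = FALSE]
  } else {
    tc[bad] <- tc[src]
  }
  tc
}

#' Erode a 3D mask
#'
#' Each iteration removes voxels with any 6-connected neighbour outside the
#' mask (faces of the grid count as outside).
#'
#' @param mask `parcel` or 3D logical array
#' @param iterations number of erosion passes (default 2)
#' @return same type as the input
#' @export
erode_mask <- function(mask, iterations = 2) {
  is_parcel <- inherits(mask, "parcel")
  m <- if (is_parcel) mask$mask else mask
  stopifnot(length(dim(m)) == 3)
  d <- dim(m)
  for (it in seq_len(iterations)) {
    # pad with FALSE then AND the six face-shifted copies
    shift <- function(arr, ax, by) {
      out <- array(FALSE, dim = d)
      idx_src <- lapply(d, seq_len)
      idx_dst <- idx_src
      n <- d[ax]
      if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
      else         { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      out
    }
    m <- m & shift(m, 1, 1) & shift(m, 1, -1) & shift(m, 2, 1) &
      shift(m, 2, -1) & shift(m, 3, 1) & shift(m, 3, -1)
    if (!any(m))
      stop("mask empty after ", it, " erosion iteration(s); use fewer")
  }
  if (is_parcel) parcel(m, label = mask$label) else m
}

#' Component-based noise regressors (CompCor)
#'
#' Principal-component timecourses of white-matter voxel data. Artifact TRs
#' are interpolated ("scrubbed") per voxel before decomposition; each voxel
#' is then mean-centred and the first `n_components` right singular vectors
#' of the voxel x T matrix are returned, variance-ordered and unit-norm.
#' Sign is fixed deterministically: the spatial loading of largest magnitude
#' is made positive. Components whose singular value is numerically zero are
#' dropped with a warning.
#'
#' @param wm_bold voxel x T numeric matrix of white-matter timecourses
#' @param artifact_mask logical per-TR flags (NULL for none)
#' @param n_components number of components (default 5)
#' @return T x k matrix of component timecourses, columns `compcor1..k`
#' @export
compute_compcor <- function(wm_bold, artifact_mask = NULL, n_components = 5) {
  X <- as.matrix(wm_bold)
  if (nrow(X) < 1) stop("empty white-matter matrix")
  if (!is.null(artifact_mask) && any(as.logical(artifact_mask)))
    X <- interpolate_artifacts(X, artifact_mask)
  X <- X - rowMeans(X)
  sv <- svd(X, nu = min(dim(X)), nv = min(dim(X)))
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  keep <- which(sv$d > max(tol, 1e-12))
  k <- min(n_components, length(keep))
  if (k < n_components)
    warning("only ", k, " non-degenerate component(s) available (asked for ",
            n_components, ")")
  if (k == 0) return(matrix(numeric(0), nrow = ncol(X), ncol = 0))
  comps <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- sv$u[, j]
    if (load[which.max(abs(load))] < 0) comps[, j] <- -comps[, j]
  }
  colnames(comps) <- paste0("compcor", seq_len(k))
  comps
}

#' Assemble the nuisance design
#'
#' One indicator ("spike") column per artifact TR plus the CompCor component
#' columns.
#'
#' @param mask logical per-TR artifact flags
#' @param compcor T x k component matrix (may have 0 columns)
#' @return T x (n_spikes + k) named matrix (0 columns if nothing to remove)
#' @export
nuisance_set <- function(mask, compcor = NULL) {
  flags <- as.logical(mask)
  T_ <- length(flags)
  spikes <- which(flags)
  S <- matrix(0, T_, length(spikes))
  if (length(spikes) > 0) {
    S[cbind(spikes, seq_along(spikes))] <- 1
    colnames(S) <- paste0("spike_tr", spikes)
  }
  if (!is.null(compcor) && ncol(compcor) > 0) {
    stopifnot(nrow(compcor) == T_)
    out <- cbind(S, compcor)
  } else out <- S
  out
}

#' Discrete-cosine high-pass filter
#'
#' Removes the projection of the timecourse onto an intercept plus the DCT
#' basis functions with period longer than `cutoff_s`; the standard fMRI
#' realization of "high-pass filtered with a cutoff of 100 s". Exactly
#' linear; output mean is 0.
#'
#' @param tc numeric timecourse (no missing values) or voxel x T matrix
#' @param tr_s sampling interval (s)
#' @param cutoff_s cutoff period in seconds (default 100)
#' @return filtered timecourse(s)
#' @export
highpass_filter <- function(tc, tr_s, cutoff_s = 100) {
  if (cutoff_s <= 2 * tr_s)
    stop("cutoff_s must exceed twice the TR (", 2 * tr_s, " s)")
  T_ <- if (is.matrix(tc)) ncol(tc) else length(tc)
  if (anyNA(tc)) stop("high-pass filter requires complete timecourses")
  B <- dct_basis(T_, tr_s, cutoff_s)
  B <- cbind(1, B)
  if (is.matrix(tc)) {
    beta <- t(qr.coef(qr(B), t(tc)))
    tc - beta %*% t(B)
  } else {
    as.numeric(tc - B %*% qr.coef(qr(B), tc))
  }
}

#' Low-frequency DCT basis for a run
#' @param T_ number of TRs
#' @param tr_s TR (s)
#' @param cutoff_s cutoff period (s)
#' @return T x K matrix (K = floor(2 * T * tr_s / cutoff_s)), no intercept
#' @export
dct_basis <- function(T_, tr_s, cutoff_s) {
  K <- floor(2 * T_ * tr_s / cutoff_s)
  t0 <- seq_len(T_) - 1
  B <- matrix(0, T_, K)
  for (k in seq_len(K))
    B[, k] <- cos(pi * k * (2 * t0 + 1) / (2 * T_))
  B
}

#' Clean voxel timecourses
#'
#' Per voxel: interpolate artifact TRs, regress on an intercept plus the
#' nuisance columns (spike indicators and CompCor components), keep the
#' residuals, then high-pass filter. Collinear nuisance columns are dropped
#' with a warning. Residuals are orthogonal to every retained nuisance
#' column by construction.
#'
#' @param bold voxel x T numeric matrix, or a `bold_run` (flattened to
#'   voxel x T in linear-index order)
#' @param mask logical per-TR artifact flags
#' @param nuisance T x P nuisance matrix from [nuisance_set()] (0 columns OK)
#' @param tr_s TR in seconds (taken from a `bold_run` input if absent)
#' @param cutoff_s high-pass cutoff (default 100 s)
#' @return voxel x T matrix of cleaned timecourses
#' @export
clean_voxel_timecourses <- function(bold, mask, nuisance = NULL, tr_s = NULL,
                                    cutoff_s = 100) {
  if (inherits(bold, "bold_run")) {
    if (is.null(tr_s)) tr_s <- bold$tr_s
    d <- dim(bold$data)
    X <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  } else {
    X <- as.matrix(bold)
    if (is.null(tr_s)) stop("tr_s required for matrix input")
  }
  flags <- as.logical(mask)
  stopifnot(length(flags) == ncol(X))
  X <- interpolate_artifacts(X, flags)
  resid <- regress_nuisance(X, nuisance)
  highpass_filter(resid, tr_s = tr_s, cutoff_s = cutoff_s)
}

#' Regress nuisance covariates out of voxel timecourses
#'
#' OLS residuals of each row of `X` on an intercept plus the nuisance
#' columns; residuals are exactly orthogonal to every retained column.
#' Collinear columns are dropped with a warning.
#'
#' @param X voxel x T matrix (already artifact-interpolated)
#' @param nuisance T x P nuisance matrix, NULL or 0 columns for none
#' @return voxel x T residual matrix
#' @export
regress_nuisance <- function(X, nuisance = NULL) {
  X <- as.matrix(X)
  T_ <- ncol(X)
  N <- if (is.null(nuisance)) matrix(numeric(0), T_, 0) else as.matrix(nuisance)
  D <- cbind(intercept = 1, N)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- qrD$pivot[(qrD$rank + 1):ncol(D)]
    warning("dropping ", length(drop_cols), " collinear nuisance column(s): ",
            paste(colnames(D)[drop_cols], collapse = ", "))
    D <- D[, -drop_cols, drop = FALSE]
    qrD <- qr(D)
  }
  t(qr.resid(qrD, t(X)))
}

#' ROI mean timecourse with artifact NaN-ing
#'
#' Averages cleaned voxel timecourses over the ROI, then sets artifact TRs
#' to missing (the "NaN" step that follows averaging).
#'
#' @param cleaned voxel x T matrix whose row r holds linear voxel index r-1
#' @param roi `ssroi`, or a vector of 0-based linear voxel indices
#' @param mask logical per-TR artifact flags (NULL for none)
#' @return numeric length-T timecourse with NA at artifact TRs
#' @export
roi_mean_timecourse <- function(cleaned, roi, mask = NULL) {
  idx <- if (inherits(roi, "ssroi")) roi$voxels else as.integer(roi)
  if (length(idx) == 0) stop("empty ROI")
  if (any(idx < 0) || any(idx >= nrow(cleaned)))
    stop("ROI voxel indices outside the data matrix")
  tc <- colMeans(cleaned[idx + 1L, , drop = FALSE])
  if (!is.null(mask)) tc[as.logical(mask)] <- NA_real_
  tc
}

#' Global signal of a run
#'
#' Mean over in-brain voxels at each TR. The brain mask defaults to the
#' union of the supplied parcels when no explicit mask is given.
#'
#' @param bold `bold_run` or voxel x T matrix
#' @param brain_mask optional 3D logical array or vector of 0-based indices
#' @return length-T numeric vector
#' @export
global_signal <- function(bold, brain_mask = NULL) {
  if (inherits(bold, "bold_run")) {
    d <- dim(bold$data)
    X <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  } else X <- as.matrix(bold)
  if (is.null(brain_mask)) return(colMeans(X))
  idx <- if (is.array(brain_mask)) which(brain_mask) - 1L
         else as.integer(brain_mask)
  colMeans(X[idx + 1L, , drop = FALSE])
}
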