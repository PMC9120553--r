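# Localizer GLM: canonical HRF, block design construction, per-voxel OLS
# and contrast t-maps. Ordinary least squares, no prewhitening; missing TRs
# are removed listwise from data and design.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with response peak at 6 s and
#' undershoot peak at 16 s, undershoot ratio 1/6, sampled every `tr_s`
#' seconds over `[0, duration_s]` and normalized to peak 1.
#'
#' @param tr_s sampling interval (s)
#' @param duration_s kernel support (default 32 s)
#' @return numeric kernel sampled at `seq(0, duration_s, by = tr_s)`
#' @export
canonical_hrf <- function(tr_s, duration_s = 32) {
  stopifnot(tr_s > 0)
  t <- seq(0, duration_s, by = tr_s)
  # gamma density with unit rate has mode shape-1, so shape = peak + 1
  h <- stats::dgamma(t, shape = 7, rate = 1) -
    stats::dgamma(t, shape = 17, rate = 1) / 6
  h / max(h)
}

#' Build a block design matrix
#'
#' One column per condition: a boxcar of the condition's blocks convolved
#' with the HRF on an oversampled time grid, sampled back at volume
#' acquisition times, plus an intercept. Collinear condition columns (e.g.
#' two conditions with identical timing) are an error.
#'
#' @param timing `block_timing` table
#' @param T_ number of volumes
#' @param tr_s TR (s)
#' @param hrf_duration_s HRF kernel support passed to [canonical_hrf()]
#' @param conditions optional declared condition set; timing rows with other
#'   names are an error
#' @param oversample time-grid refinement within one TR (default 16)
#' @return T x P matrix with an `intercept` column and one named column per
#'   condition, with attribute `conditions`
#' @export
build_block_design <- function(timing, T_, tr_s, hrf_duration_s = 32,
                               conditions = NULL, oversample = 16L) {
  timing <- block_timing(as.data.frame(timing))
  conds <- unique(timing$condition)
  if (!is.null(conditions)) {
    bad <- setdiff(conds, conditions)
    if (length(bad) > 0)
      stop("unknown condition(s) in timing: ", paste(bad, collapse = ", "))
    conds <- intersect(conditions, conds)
  }
  run_s <- T_ * tr_s
  if (nrow(timing) > 0 && any(timing$onset_s + timing$duration_s > run_s))
    stop("a block ends after the run (", run_s, " s)")
  dt <- tr_s / oversample
  n_fine <- as.integer(ceiling(run_s / dt))
  t_fine <- (seq_len(n_fine) - 1) * dt
  hrf_fine <- stats::dgamma(seq(0, hrf_duration_s, by = dt), shape = 7,
                            rate = 1) -
    stats::dgamma(seq(0, hrf_duration_s, by = dt), shape = 17, rate = 1) / 6
  hrf_fine <- hrf_fine / max(hrf_fine)
  X <- matrix(0, T_, length(conds))
  colnames(X) <- conds
  sample_at <- as.integer(round((seq_len(T_) - 1) * tr_s / dt)) + 1L
  for (cond in conds) {
    rows <- timing[timing$condition == cond, , drop = FALSE]
    box <- numeric(n_fine)
    for (r in seq_len(nrow(rows))) {
      on <- rows$onset_s[r]; off <- on + rows$duration_s[r]
      box[t_fine >= on & t_fine < off] <- 1
    }
    conv <- stats::convolve(box, rev(hrf_fine), type = "open")[seq_len(n_fine)]
    X[, cond] <- conv[sample_at] * dt  # dt scaling: discretized integral
  }
  D <- cbind(intercept = 1, X)
  if (qr(D)$rank < ncol(D))
    stop("design is rank deficient (collinear condition columns)")
  attr(D, "conditions") <- conds
  D
}

#' Fit per-voxel OLS and a contrast t-map
#'
#' For each voxel, ordinary least squares of the timecourse on the design;
#' the contrast t is `c'b / sqrt(s2 * c'(X'X)^-1 c)` with residual variance
#' `s2` on `df = n_used - rank(X)` degrees of freedom. TRs missing in the
#' data (artifact-NaNed) are excluded listwise. Voxels with numerically zero
#' residual variance get t capped at +/- 1e6 and are flagged.
#'
#' @param cleaned voxel x T numeric matrix (NA allowed, uniform across
#'   voxels at NaN-ed artifact TRs)
#' @param design T x P design matrix with named columns
#' @param contrast named numeric vector of contrast weights over design
#'   columns; unnamed columns get weight 0
#' @return object of class `tmap_fit`: list(t, df, flagged, beta)
#' @export
fit_contrast_tmap <- function(cleaned, design, contrast) {
  X <- as.matrix(design)
  Y <- as.matrix(cleaned)
  stopifnot(ncol(Y) == nrow(X))
  cvec <- numeric(ncol(X))
  names(cvec) <- colnames(X)
  if (is.null(names(contrast)))
    stop("contrast must be a named vector keyed by design columns")
  unknown <- setdiff(names(contrast), colnames(X))
  if (length(unknown) > 0)
    stop("contrast names not in design: ", paste(unknown, collapse = ", "))
  cvec[names(contrast)] <- contrast
  if (all(cvec == 0)) stop("contrast has no nonzero weight")

  good <- which(stats::complete.cases(t(Y)) & stats::complete.cases(X))
  Xg <- X[good, , drop = FALSE]
  Yg <- Y[, good, drop = FALSE]
  qrX <- qr(Xg)
  rnk <- qrX$rank
  df <- length(good) - rnk
  if (df <= 0) stop("no residual degrees of freedom (df = ", df, ")")
  if (rnk < ncol(Xg))
    stop("design rank deficient after listwise deletion")
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- qr.coef(qrX, t(Yg))               # P x V
  res <- t(Yg) - Xg %*% beta                # n x V
  s2 <- colSums(res^2) / df
  cb <- as.numeric(crossprod(cvec, beta))
  cvar <- as.numeric(crossprod(cvec, XtXinv %*% cvec))
  flagged <- s2 < 1e-12
  se <- sqrt(pmax(s2, 1e-12) * cvar)
  tval <- cb / se
  tval[flagged] <- sign(cb[flagged]) * pmin(abs(cb[flagged] / se[flagged]),
                                            1e6)
  tval[flagged & cb == 0] <- 0
  structure(list(t = tval, df = df, flagged = flagged, beta = beta),
            class = "tmap_fit")
}

#' Place per-voxel t statistics into a 3D map
#'
#' @param fit `tmap_fit` over the voxels listed in `voxel_idx`
#' @param voxel_idx 0-based linear indices matching the rows of the fitted
#'   data
#' @param dim grid dimensions
#' @return object of class `tmap`: list(t = 3D array (NA outside), df)
#' @export
tmap_from_fit <- function(fit, voxel_idx, dim) {
  arr <- array(NA_real_, dim = dim)
  arr[voxel_idx + 1L] <- fit$t
  structure(list(t = arr, df = fit$df), class = "tmap")
}

#' Parse a contrast string "A>B" into weights
#' @param s string like `"faces>objects"`
#' @return named weight vector (+1, -1)
#' @export
parse_contrast <- function(s) {
  parts <- strsplit(s, ">", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("contrast must look like 'A>B': ", s)
  parts <- trimws(parts)
  stats::setNames(c(1, -1), parts)
}
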