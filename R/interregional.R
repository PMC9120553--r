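# Inter-regional correlation statistics: correlations of spliced movie-ssROI
# timecourses against target timecourse banks, Fisher z, partial
# correlations, lag shifts, leave-one-out group means, and the simple group
# tests reported alongside.

#' Fisher z transform with degeneracy clipping
#'
#' `atanh(r)` after clipping |r| at 1 - 1e-15 so that group statistics stay
#' finite; clipped values are flagged via the `clipped` attribute.
#'
#' @param r correlation(s) in [-1, 1]
#' @return z value(s), attribute `clipped` logical
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-15
  clipped <- !is.na(r) & abs(r) >= lim
  z <- atanh(pmin(pmax(r, -lim), lim))
  attr(z, "clipped") <- clipped
  z
}

#' Correlate a timecourse against a bank of targets
#'
#' Pearson r over pairwise-complete TRs per target, plus the Fisher z.
#' Targets with fewer than 3 complete pairs get a missing entry with a
#' warning.
#'
#' @param tc numeric timecourse
#' @param targets named list or T x k matrix of target timecourses
#' @return data.frame(target, r, z, n_pairs)
#' @export
correlate_to_targets <- function(tc, targets) {
  if (is.list(targets)) targets <- do.call(cbind, targets)
  targets <- as.matrix(targets)
  stopifnot(nrow(targets) == length(tc))
  out <- lapply(colnames(targets), function(nm) {
    y <- targets[, nm]
    ok <- !is.na(tc) & !is.na(y)
    if (sum(ok) < 3) {
      warning("fewer than 3 complete pairs for target ", nm)
      return(data.frame(target = nm, r = NA_real_, z = NA_real_,
                        n_pairs = sum(ok)))
    }
    r <- stats::cor(tc[ok], y[ok])
    data.frame(target = nm, r = r, z = as.numeric(fisher_z(r)),
               n_pairs = sum(ok))
  })
  do.call(rbind, out)
}

#' Partial correlation by residualization
#'
#' Pearson correlation between the residuals of `tc` and of `target` after
#' each is OLS-regressed on an intercept plus the `others` timecourses, on
#' the TRs where all series are complete. Collinear `others` columns are
#' pruned with a warning. Equivalent to the precision-matrix formula on
#' complete data.
#'
#' @param tc,target numeric timecourses
#' @param others named list or T x m matrix of controlled timecourses
#' @return partial correlation (scalar)
#' @export
partial_correlation <- function(tc, target, others) {
  if (is.list(others)) others <- do.call(cbind, others)
  O <- if (is.null(others)) matrix(numeric(0), length(tc), 0)
       else as.matrix(others)
  ok <- !is.na(tc) & !is.na(target)
  if (ncol(O) > 0) ok <- ok & stats::complete.cases(O)
  n <- sum(ok)
  if (n < ncol(O) + 3)
    stop("need at least ", ncol(O) + 3, " complete TRs, have ", n)
  if (ncol(O) == 0) return(stats::cor(tc[ok], target[ok]))
  D <- cbind(1, O[ok, , drop = FALSE])
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- qrD$pivot[(qrD$rank + 1):ncol(D)]
    warning("pruning ", length(drop_cols), " collinear control column(s)")
    D <- D[, -drop_cols, drop = FALSE]
    qrD <- qr(D)
  }
  ex <- qr.resid(qrD, tc[ok])
  ey <- qr.resid(qrD, target[ok])
  # a series inside the span of the controls leaves only rounding noise
  if (stats::sd(ex) <= 1e-10 * max(stats::sd(tc[ok]), 1e-300) ||
      stats::sd(ey) <= 1e-10 * max(stats::sd(target[ok]), 1e-300))
    return(0)
  stats::cor(ex, ey)
}

#' Shift a timecourse in time
#'
#' Negative shifts move the series earlier: the value at TR t of the output
#' is the input at TR t + |shift|; vacated TRs at the ends become missing.
#' Length is preserved.
#'
#' @param tc numeric timecourse
#' @param shift_trs integer shift (negative = earlier)
#' @return shifted timecourse
#' @export
shift_timecourse <- function(tc, shift_trs) {
  T_ <- length(tc)
  s <- as.integer(shift_trs)
  if (abs(s) >= T_) stop("|shift| must be smaller than the run length")
  if (s == 0) return(tc)
  out <- rep(NA_real_, T_)
  if (s < 0) {
    out[seq_len(T_ + s)] <- tc[seq(1 - s, T_)]
  } else {
    out[seq(1 + s, T_)] <- tc[seq_len(T_ - s)]
  }
  out
}

#' Leave-one-out group mean timecourse
#'
#' Per-TR mean over the remaining subjects, ignoring missing entries. If
#' the excluded id is not in the group the plain mean is returned with a
#' warning.
#'
#' @param tcs subject x TR matrix with subject ids as row names
#' @param exclude_id subject to exclude
#' @return length-T numeric mean timecourse
#' @export
loo_group_mean <- function(tcs, exclude_id) {
  M <- as.matrix(tcs)
  if (nrow(M) < 2) stop("need at least 2 subjects")
  if (!exclude_id %in% rownames(M)) {
    warning("subject '", exclude_id, "' not in the group; plain mean used")
  } else {
    M <- M[rownames(M) != exclude_id, , drop = FALSE]
  }
  out <- colMeans(M, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' One-sample t-test summary
#'
#' Standard two-sided one-sample t-test with Cohen's d = mean / SD. Zero
#' variance yields a degenerate result (p = 1, flagged) rather than an
#' error, keeping group summaries total.
#'
#' @param values numeric vector (NA dropped)
#' @param mu null mean (default 0)
#' @return list(test, t, df, p, cohen_d, degenerate)
#' @export
one_sample_t <- function(values, mu = 0) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 values")
  if (stats::sd(v) == 0)
    return(list(test = "one_sample_t", t = NA_real_,
                df = length(v) - 1, p = 1, cohen_d = NA_real_,
                degenerate = TRUE))
  ht <- stats::t.test(v, mu = mu)
  list(test = "one_sample_t", t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value,
       cohen_d = (mean(v) - mu) / stats::sd(v), degenerate = FALSE)
}

#' Paired t-test summary
#'
#' Two-sided paired t-test with Cohen's d = mean difference / SD of the
#' differences. Identical pairs yield the degenerate result (p = 1,
#' flagged).
#'
#' @param a,b paired numeric vectors; incomplete pairs dropped
#' @return list(test, t, df, p, cohen_d, degenerate)
#' @export
paired_t <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  d <- a[ok] - b[ok]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0)
    return(list(test = "paired_t", t = NA_real_, df = length(d) - 1,
                p = 1, cohen_d = NA_real_, degenerate = TRUE))
  ht <- stats::t.test(d, mu = 0)
  list(test = "paired_t", t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value,
       cohen_d = mean(d) / stats::sd(d), degenerate = FALSE)
}
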