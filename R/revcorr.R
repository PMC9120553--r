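# Reverse correlation: z-normalization, per-TR one-tailed group t-tests
# against baseline, events as runs of >= 2 consecutive significant TRs,
# event-response magnitudes, and Spearman partial correlations for age
# trends with motion as covariate.

#' z-normalize a timecourse
#'
#' Non-missing entries are transformed to mean 0, SD 1 (n-1 denominator);
#' missing entries are preserved.
#'
#' @param tc numeric timecourse, NA allowed
#' @return z-scored timecourse
#' @export
znormalize <- function(tc) {
  ok <- !is.na(tc)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  s <- stats::sd(tc[ok])
  if (!is.finite(s) || s == 0) stop("zero variance; cannot z-normalize")
  tc[ok] <- (tc[ok] - mean(tc[ok])) / s
  tc
}

#' Detect reliably positive group events
#'
#' At each TR, subjects' z-scored values are tested against baseline 0 with
#' a one-tailed one-sample t-test (H1: mean > 0). A TR with fewer than
#' `min_n` contributing subjects is non-significant by definition. Events
#' are maximal runs of at least `min_run` consecutive significant TRs
#' (>= 4 s at TR = 2 s).
#'
#' @param group subject x TR matrix of z-scored timecourses (NA allowed)
#' @param alpha per-TR significance level (default 0.05, uncorrected)
#' @param min_run minimum event length in TRs (default 2)
#' @param min_n minimum subjects per testable TR (default 3)
#' @return object of class `event_set`: list(intervals = data.frame
#'   (start_tr, end_tr), 1-based inclusive; significant = logical per TR;
#'   p = per-TR p values; alpha)
#' @export
detect_events <- function(group, alpha = 0.05, min_run = 2, min_n = 3) {
  G <- as.matrix(group)
  T_ <- ncol(G)
  n <- colSums(!is.na(G))
  m <- colMeans(G, na.rm = TRUE)
  s <- apply(G, 2, stats::sd, na.rm = TRUE)
  tstat <- m / (s / sqrt(n))
  p <- stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  sig <- !is.na(p) & p < alpha & n >= min_n
  intervals <- runs_to_intervals(sig, min_run)
  structure(list(intervals = intervals, significant = sig, p = p,
                 alpha = alpha, min_run = min_run, min_n = min_n),
            class = "event_set")
}

# Maximal runs of TRUE of length >= min_run, as 1-based inclusive intervals.
runs_to_intervals <- function(sig, min_run) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start_tr = starts[keep], end_tr = ends[keep])
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d event(s) at alpha=%g (one-tailed, >=%d TRs)\n",
              nrow(x$intervals), x$alpha, x$min_run))
  if (nrow(x$intervals) > 0)
    cat(paste0("  TRs ", x$intervals$start_tr, "-", x$intervals$end_tr,
               collapse = "\n"), "\n")
  invisible(x)
}

#' TRs covered by an event set
#' @param events `event_set`
#' @return integer vector of 1-based TRs (union of intervals)
#' @export
event_trs <- function(events) {
  iv <- events$intervals
  if (nrow(iv) == 0) return(integer(0))
  unlist(Map(seq, iv$start_tr, iv$end_tr), use.names = FALSE)
}

#' Average response magnitude over event timepoints
#'
#' Mean of a z-scored timecourse over the union of event TRs, ignoring
#' missing entries. Returns NA (with a warning) when the event set is empty
#' or no event TR has data.
#'
#' @param tc z-scored timecourse
#' @param events `event_set`
#' @return scalar mean response (z units), or NA
#' @export
event_response <- function(tc, events) {
  trs <- event_trs(events)
  if (length(trs) == 0) {
    warning("empty event set; response magnitude undefined")
    return(NA_real_)
  }
  v <- tc[trs]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Spearman partial correlation
#'
#' All three variables are rank-transformed (midranks for ties); the partial
#' correlation of the ranked x and y given the ranked covariate is computed
#' by the residual method, with p from the t approximation on n - 3 degrees
#' of freedom (two-sided).
#'
#' @param x,y,covariate equal-length numeric vectors; rows with any missing
#'   value are dropped pairwise-complete
#' @return list(r_s, p, n)
#' @export
spearman_partial <- function(x, y, covariate) {
  ok <- stats::complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; z <- covariate[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete observations")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant input after ranking")
  if (stats::sd(rz) == 0) {
    r <- stats::cor(rx, ry)
  } else {
    ex <- stats::resid(stats::lm(rx ~ rz))
    ey <- stats::resid(stats::lm(ry ~ rz))
    # ranks fully explained by the covariate leave only rounding noise
    if (stats::sd(ex) <= 1e-10 * stats::sd(rx) ||
        stats::sd(ey) <= 1e-10 * stats::sd(ry)) {
      r <- 0
    } else {
      r <- stats::cor(ex, ey)
    }
  }
  df <- n - 3
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  list(r_s = r, p = p, n = n)
}
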