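# UPS (ASA2/4) trajectory analysis: displacement buckets with box-plot
# statistics and the coupled mean F1 rotation, plus sliding-window frame
# selection along a latent coordinate for 3D-movie reconstruction.

#' Box-plot statistics of F1 rotation over UPS displacement buckets
#'
#' Buckets the signed UPS trajectory displacement into bins of `bucket`
#' Angstrom that tile the observed range without gaps, and computes per
#' bucket: n, median, quartiles, 1.5*IQR whisker bounds, outlier count, and
#' the mean F1-head angle. Spans reported: full displacement span
#' (max - min) and full span of the bucket-mean F1 angle; middle-95%
#' displacement span (empirical 2.5-97.5 percentiles) and the corresponding
#' F1 span interpolated from the bucket means at those percentiles.
#'
#' @param t A data.frame with `ups_disp` and `theta_f1`.
#' @param bucket Bucket width in Angstrom.
#' @return Object of class `trajectory_summary`: list with `buckets` (a
#'   `data.frame`), `full_span` (named: `disp_A`, `f1_deg`) and
#'   `middle95_span` (same names).
#' @export
trajectory_bin_stats <- function(t, bucket = 1) {
  d <- t$ups_disp
  if (is.null(d) || !length(d)) stop("`ups_disp` required and non-empty", call. = FALSE)
  f1 <- t$theta_f1
  lo <- floor(min(d) / bucket) * bucket
  hi <- ceiling(max(d) / bucket) * bucket
  if (hi <= lo) hi <- lo + bucket
  edges <- seq(lo, hi, by = bucket)
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  rows <- lapply(seq_len(nb), function(k) {
    x <- d[idx == k]
    if (!length(x)) {
      return(data.frame(bucket_lo = edges[k], bucket_hi = edges[k + 1],
                        n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        whisker_lo = NA_real_, whisker_hi = NA_real_,
                        n_outliers = NA_integer_, mean_f1 = NA_real_))
    }
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    inside <- x >= qs[1] - 1.5 * iqr & x <= qs[3] + 1.5 * iqr
    data.frame(bucket_lo = edges[k], bucket_hi = edges[k + 1],
               n = length(x), median = qs[2], q1 = qs[1], q3 = qs[3],
               whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
               n_outliers = sum(!inside), mean_f1 = mean(f1[idx == k]))
  })
  buckets <- do.call(rbind, rows)
  nonempty <- buckets$n > 0
  full_f1 <- diff(range(buckets$mean_f1[nonempty]))
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  mid <- (buckets$bucket_lo + buckets$bucket_hi) / 2
  f1_at <- if (sum(nonempty) < 2) {
    rep(buckets$mean_f1[nonempty][1], 2)
  } else {
    stats::approx(mid[nonempty], buckets$mean_f1[nonempty], xout = q,
                  rule = 2)$y
  }
  structure(list(
    buckets = buckets,
    full_span = c(disp_A = max(d) - min(d), f1_deg = full_f1),
    middle95_span = c(disp_A = q[2] - q[1], f1_deg = abs(f1_at[2] - f1_at[1]))
  ), class = "trajectory_summary")
}

#' Sliding particle windows along a latent coordinate
#'
#' Sorts particles by `coord` and returns `n_frames` windows of exactly
#' `window` consecutive particles whose start positions are evenly spaced
#' from the first to the last possible window (as used to reconstruct
#' 1600-particle movie frames along the leading latent eigenvector).
#'
#' @param coord Numeric per-particle coordinate.
#' @param window Particles per frame.
#' @param n_frames Requested number of frames.
#' @return List of integer index vectors into `coord`, each of length
#'   `window`; a single frame when only one window fits.
#' @export
sliding_window_frames <- function(coord, window = 1600, n_frames = 9) {
  n <- length(coord)
  if (n < window) stop("fewer particles than the window size", call. = FALSE)
  if (window < 1 || n_frames < 1) stop("window and n_frames must be >= 1", call. = FALSE)
  ord <- order(coord)
  n_pos <- n - window + 1
  starts <- unique(round(seq(1, n_pos, length.out = min(n_frames, n_pos))))
  lapply(starts, function(s) ord[s:(s + window - 1)])
}
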