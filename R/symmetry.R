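# c-ring symmetry-order inference via two indirect metrics: the per-degree
# rotational self-correlation curve (count of evenly spaced minima) and the
# c1..cN symmetry-imposition similarity scan.

#' Rotational self-correlation curve about z
#'
#' `scores[k] = pearson_similarity(rotate_about_z(v, k*step), v, mask)` for
#' rotations covering a full turn. Score at 0 degrees is 1 by construction.
#'
#' @param v A [density_volume()].
#' @param mask Optional [mask_spec()] or weight array.
#' @param step Angular step in degrees; must divide 360.
#' @return An object of class `rotation_curve`: list with `step`, `angles`
#'   (degrees) and `scores`.
#' @export
self_rotation_curve <- function(v, mask = NULL, step = 1) {
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9) {
    stop("`step` must be positive and divide 360", call. = FALSE)
  }
  w <- resolve_mask(mask, v)
  ref <- as.numeric(v$grid)
  angles <- seq(0, 360 - step, by = step)
  scores <- vapply(angles, function(a) {
    rot <- if (a == 0) ref else as.numeric(rotate_grid_z(v$grid, a))
    weighted_pearson(rot, ref, w)
  }, numeric(1))
  structure(list(step = step, angles = angles, scores = scores),
            class = "rotation_curve")
}

# circular local minima of s with absolute prominence >= prom_abs;
# for maxima pass -s. Ties resolve to the left edge of a plateau.
circ_extrema <- function(s, prom_abs) {
  n <- length(s)
  if (n < 3 || diff(range(s)) == 0) return(integer())
  left <- s[c(n, seq_len(n - 1))]
  right <- s[c(seq_len(n - 1) + 1, 1)]
  cand <- which(s < left & s <= right)
  keep <- vapply(cand, function(i) {
    walk <- function(dir) {
      m <- -Inf
      j <- i
      for (k in seq_len(n - 1)) {
        j <- ((j - 1 + dir) %% n) + 1
        if (s[j] < s[i]) break
        m <- max(m, s[j])
      }
      m
    }
    min(walk(1L), walk(-1L)) - s[i] >= prom_abs
  }, logical(1))
  cand[keep]
}

#' Count evenly spaced minima of a rotation curve
#'
#' Smooths the curve with a circular moving average, finds circular local
#' minima with prominence above a fraction of the curve range, and reports
#' the count together with the coefficient of variation of the circular gaps
#' between consecutive minima (0 = perfectly even spacing).
#'
#' @param curve A [self_rotation_curve()] result.
#' @param smooth_window Moving-average window in degrees.
#' @param prominence Required prominence as a fraction of the curve range.
#' @return List with `count`, `spacing_cv` and `minima_deg`.
#' @export
count_evenly_spaced_minima <- function(curve, smooth_window = 3,
                                       prominence = 0.05) {
  s <- curve$scores
  w <- max(1L, round(smooth_window / curve$step))
  if (w %% 2 == 0) w <- w + 1L
  sm <- if (w > 1) {
    as.numeric(stats::filter(s, rep(1 / w, w), sides = 2, circular = TRUE))
  } else s
  rng <- diff(range(sm))
  if (rng == 0) {
    return(list(count = 0L, spacing_cv = NA_real_, minima_deg = numeric()))
  }
  idx <- circ_extrema(sm, prominence * rng)
  ang <- sort(curve$angles[idx])
  cv <- NA_real_
  if (length(ang) >= 2) {
    gaps <- diff(c(ang, ang[1] + 360))
    cv <- stats::sd(gaps) / mean(gaps)
  }
  list(count = length(idx), spacing_cv = cv, minima_deg = ang)
}

#' Count evenly spaced maxima of a rotation curve (cross-check utility)
#'
#' Same procedure as [count_evenly_spaced_minima()] applied to the negated
#' curve; a cN ring yields N minima and N maxima per turn.
#'
#' @inheritParams count_evenly_spaced_minima
#' @return List with `count`, `spacing_cv` and `maxima_deg`.
#' @export
count_evenly_spaced_maxima <- function(curve, smooth_window = 3,
                                       prominence = 0.05) {
  neg <- curve
  neg$scores <- -curve$scores
  out <- count_evenly_spaced_minima(neg, smooth_window, prominence)
  list(count = out$count, spacing_cv = out$spacing_cv,
       maxima_deg = out$minima_deg)
}

#' Symmetry-imposition similarity scan c1..c(n_max)
#'
#' For each order `n`, scores the n-fold symmetrised volume against the
#' original with masked Pearson similarity. Divisors of the true order are
#' exact symmetries and also score highly, so the scan's "best" order is the
#' largest order within 90% of the best score over orders >= 2 (plain argmax
#' is ill-posed under divisor degeneracy).
#'
#' @param v A [density_volume()].
#' @param mask Optional [mask_spec()] or weight array.
#' @param n_max Highest order scanned (>= 2).
#' @return An object of class `symmetry_scan`: list with `orders`, `scores`,
#'   `best` (largest high-scoring order) and `candidates`.
#' @export
symmetry_order_scan <- function(v, mask = NULL, n_max = 15) {
  if (n_max < 2 || n_max != round(n_max)) {
    stop("`n_max` must be an integer >= 2", call. = FALSE)
  }
  w <- resolve_mask(mask, v)
  ref <- as.numeric(v$grid)
  scores <- vapply(seq_len(n_max), function(n) {
    sym <- if (n == 1) ref else as.numeric(impose_symmetry(v, n)$grid)
    weighted_pearson(sym, ref, w)
  }, numeric(1))
  hi <- 0.9 * max(scores[-1])
  candidates <- which(scores >= hi)
  candidates <- candidates[candidates >= 2]
  structure(list(orders = seq_len(n_max), scores = scores,
                 best = max(candidates), candidates = candidates),
            class = "symmetry_scan")
}

#' Combine the symmetry scan and the self-rotation curve into an order call
#'
#' The inferred order is the largest order scoring within 90% of the best
#' scan score (over orders >= 2) when that order equals the number of evenly
#' spaced self-correlation minima; if the two metrics disagree, both are
#' reported with `agreement = FALSE` and `order = NA`.
#'
#' @param scan A [symmetry_order_scan()] result.
#' @param curve A [self_rotation_curve()] result on the same volume and mask.
#' @param smooth_window,prominence Passed to [count_evenly_spaced_minima()].
#' @return List with `order` (NA on disagreement), `scan_order`,
#'   `minima_count`, `spacing_cv` and logical `agreement`.
#' @export
infer_order <- function(scan, curve, smooth_window = 3, prominence = 0.05) {
  if (!inherits(scan, "symmetry_scan")) stop("`scan` must be a symmetry_scan", call. = FALSE)
  minima <- count_evenly_spaced_minima(curve, smooth_window, prominence)
  agree <- scan$best == minima$count
  list(order = if (agree) scan$best else NA_integer_,
       scan_order = scan$best,
       minima_count = minima$count,
       spacing_cv = minima$spacing_cv,
       agreement = agree)
}
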