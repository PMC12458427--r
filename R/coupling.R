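# Statistical core of the stalk-head coupling analysis: binning F1-head
# angles by central-stalk state, per-bin two-sample KS tests against the F1
# reference distribution, the tri-periodic sinusoid fit with permutation
# inference, the chord-based angular-resolution bound, and detection power.

#' Per-bin occupancies of the in situ reference ensemble
#'
#' Sample sizes of the 20 central-stalk bins (18 degrees each, left to right
#' from -180) of the in situ C. reinhardtii ensemble this pipeline models;
#' they sum to 19262, against an F1 reference distribution of n = 22630.
#' Used as the default ensemble structure for null calibration and power
#' analysis.
#'
#' @return Integer vector of 20 bin sizes.
#' @export
default_bin_sizes <- function() {
  c(654L, 650L, 939L, 1003L, 939L, 939L, 897L, 840L, 983L, 1209L, 1288L,
    971L, 928L, 976L, 971L, 985L, 1094L, 1092L, 1071L, 833L)
}

#' Group F1-head angles by central-stalk bin
#'
#' Half-open bins `[edge, edge + width)` of width `360/n_bins` starting at
#' -180 degrees (the final bin is closed at 180 so the bins cover
#' (-180, 180]). Each particle's F1 angle is assigned to the bin holding its
#' stalk angle.
#'
#' @param t A [particle_table()] (or any data.frame with `theta_stalk` and
#'   `theta_f1`).
#' @param n_bins Number of bins; must divide 360.
#' @return List with `bin_edges` (length `n_bins + 1`), `bin_n`, `groups`
#'   (list of F1-angle vectors) and `bin_index` per row.
#' @export
bin_by_stalk <- function(t, n_bins = 20) {
  if (n_bins < 1 || 360 %% n_bins != 0) {
    stop("`n_bins` must divide 360", call. = FALSE)
  }
  width <- 360 / n_bins
  edges <- seq(-180, 180, by = width)
  idx <- pmin(floor((t$theta_stalk + 180) / width) + 1, n_bins)
  groups <- lapply(seq_len(n_bins), function(k) t$theta_f1[idx == k])
  list(bin_edges = edges, bin_n = lengths(groups), groups = groups,
       bin_index = idx)
}

#' KS tests of binned F1 angles against the reference distribution
#'
#' Two-sample Kolmogorov-Smirnov p-value of each non-empty bin's F1-head
#' angles against the F1 reference distribution (which, as in the headline
#' analysis, may contain the binned particles themselves). Empty bins give
#' `NA`. No multiple-testing correction is applied here.
#'
#' @param groups List of per-bin F1-angle vectors (from [bin_by_stalk()]).
#' @param reference Numeric vector of reference F1 angles (non-empty).
#' @return Numeric vector of p-values, one per bin.
#' @export
ks_bins_vs_reference <- function(groups, reference) {
  if (!length(reference)) stop("reference must be non-empty", call. = FALSE)
  vapply(groups, function(g) {
    if (!length(g)) return(NA_real_)
    suppressWarnings(stats::ks.test(g, reference)$p.value)
  }, numeric(1))
}

#' Fit a tri-periodic sinusoid to F1 angles over stalk angles
#'
#' Least-squares fit of `theta_f1 ~ c0 + a*sin(3*theta_stalk - b)` via the
#' linearisation `a*sin(3x - b) = c1*sin(3x) + c2*cos(3x)` with
#' `a = sqrt(c1^2 + c2^2)`, `b = atan2(-c2, c1)`. Significance of the
#' amplitude comes from a permutation test shuffling the pairing between
#' stalk and F1 angles.
#'
#' @param theta_stalk,theta_f1 Equal-length angle vectors (degrees), n >= 3.
#' @param n_perm Number of permutations (0 skips the test; `permutation_p`
#'   is then `NA`).
#' @param seed Optional integer seed for the permutations.
#' @return List with `a` (degrees), `b` (degrees, wrapped), `permutation_p`,
#'   and the linear coefficients `c0`, `c1`, `c2`.
#' @export
fit_sinusoid <- function(theta_stalk, theta_f1, n_perm = 999, seed = NULL) {
  n <- length(theta_stalk)
  if (length(theta_f1) != n) stop("inputs must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(theta_stalk)) || any(!is.finite(theta_f1))) {
    stop("angles must be finite", call. = FALSE)
  }
  xr <- deg2rad(3 * theta_stalk)
  S <- sin(xr); C <- cos(xr)
  if (diff(range(S)) < 1e-12 && diff(range(C)) < 1e-12) {
    stop("degenerate design: all stalk angles identical (mod 120 degrees)",
         call. = FALSE)
  }
  X <- cbind(1, S, C)
  XtX <- crossprod(X)
  cf <- solve(XtX, crossprod(X, theta_f1))
  a <- sqrt(cf[2]^2 + cf[3]^2)
  b <- wrap_deg(rad2deg(atan2(-cf[3], cf[2])))
  p <- NA_real_
  if (n_perm > 0) {
    set_local_seed(seed)
    cnt <- 0L
    for (k in seq_len(n_perm)) {
      ck <- solve(XtX, crossprod(X, theta_f1[sample.int(n)]))
      if (sqrt(ck[2]^2 + ck[3]^2) >= a - 1e-12) cnt <- cnt + 1L
    }
    p <- (1 + cnt) / (n_perm + 1)
  }
  list(a = a, b = b, permutation_p = p,
       c0 = cf[1], c1 = cf[2], c2 = cf[3])
}

#' Full stalk-head coupling test
#'
#' Combines the binned KS protocol (20 bins of 18 degrees of central-stalk
#' state, each tested against the F1 reference distribution) with the
#' tri-periodic sinusoid permutation test. The decision is `"coupled"` if
#' the minimum bin p-value clears Bonferroni at level `alpha` or the
#' permutation p is at most `alpha`; otherwise `"not_detected"`.
#'
#' @param t A [particle_table()].
#' @param reference F1 reference angles; defaults to `t$theta_f1` (the
#'   binned particles are part of the reference, as in the headline test).
#' @param n_bins Number of stalk bins.
#' @param n_perm Permutations for the sinusoid test.
#' @param alpha Decision level.
#' @param seed Optional integer seed.
#' @return Object of class `coupling_result`: list with `bin_edges`,
#'   `bin_n`, `bin_p`, `sinusoid` (see [fit_sinusoid()]) and `decision`.
#' @export
coupling_test <- function(t, reference = NULL, n_bins = 20, n_perm = 999,
                          alpha = 0.05, seed = NULL) {
  if (is.null(reference)) reference <- t$theta_f1
  bins <- bin_by_stalk(t, n_bins)
  bin_p <- ks_bins_vs_reference(bins$groups, reference)
  fit <- fit_sinusoid(t$theta_stalk, t$theta_f1, n_perm = n_perm, seed = seed)
  min_p <- suppressWarnings(min(bin_p, na.rm = TRUE))
  coupled <- (is.finite(min_p) && min_p < alpha / n_bins) ||
    (is.finite(fit$permutation_p) && fit$permutation_p <= alpha)
  structure(list(bin_edges = bins$bin_edges, bin_n = bins$bin_n,
                 bin_p = bin_p, sinusoid = fit,
                 decision = if (coupled) "coupled" else "not_detected"),
            class = "coupling_result")
}

#' Chord-based angular resolution bound
#'
#' The smallest rotation detectable at radius `radius` given a local map
#' resolution (chord length) `chord`: `theta = 2*asin(chord / (2*radius))`.
#' With the outermost central-stalk features at ~30 Angstrom and a ~10
#' Angstrom local resolution this gives ~19 degrees.
#'
#' @param chord Local resolution (chord length) in Angstrom.
#' @param radius Feature radius in Angstrom.
#' @return Central angle in degrees, in (0, 180].
#' @examples
#' angular_resolution_deg(10, 30)
#' @export
angular_resolution_deg <- function(chord, radius) {
  if (!is.numeric(chord) || !is.numeric(radius) || chord <= 0 || radius <= 0) {
    stop("`chord` and `radius` must be positive", call. = FALSE)
  }
  if (chord > 2 * radius) {
    stop("invalid geometry: chord exceeds the diameter 2*radius", call. = FALSE)
  }
  rad2deg(2 * asin(chord / (2 * radius)))
}

#' Power of the sinusoid permutation test against tri-periodic coupling
#'
#' For each coupling amplitude, simulates ensembles with the default trimodal
#' stalk distribution and `theta_f1 = a*sin(3*theta_stalk - b) + noise`
#' (wrapped normal noise of sd `noise_sd`, the full marginal F1 width by
#' default) at the ensemble size implied by `bin_sizes`, and reports the
#' fraction of ensembles where the permutation test rejects at level `alpha`.
#'
#' @param a_grid Coupling amplitudes in degrees.
#' @param bin_sizes Ensemble bin occupancies; the ensemble size is their sum.
#' @param noise_sd F1 residual sd in degrees.
#' @param reps Simulated ensembles per amplitude (>= 100).
#' @param n_perm Permutations per test.
#' @param b Coupling phase in degrees.
#' @param alpha Rejection level.
#' @param seed Integer seed.
#' @param cfg A [generator_config()] supplying the stalk mixture.
#' @return A `data.frame` with columns `a` and `power`.
#' @export
detection_power <- function(a_grid, bin_sizes = default_bin_sizes(),
                            noise_sd = 19 / 1.96, reps = 200, n_perm = 199,
                            b = 0, alpha = 0.05, seed = 1,
                            cfg = generator_config()) {
  if (reps < 100) stop("`reps` must be at least 100", call. = FALSE)
  n <- sum(bin_sizes)
  set_local_seed(seed)
  power <- vapply(a_grid, function(a) {
    rej <- 0L
    for (r in seq_len(reps)) {
      th <- sample_stalk_angles(n, cfg$stalk_modes, cfg$stalk_sds,
                                cfg$stalk_weights)
      f1 <- wrap_deg(rnorm(n, 0, noise_sd) + couple_f1_to_stalk(th, a, b))
      fit <- fit_sinusoid(th, f1, n_perm = n_perm)
      if (fit$permutation_p <= alpha) rej <- rej + 1L
    }
    rej / reps
  }, numeric(1))
  data.frame(a = a_grid, power = power)
}
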