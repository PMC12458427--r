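# Synthetic particle ensembles with the statistical structure of the in situ
# ATP synthase dataset this pipeline models: a unimodal F1-head angle
# distribution (95% of particles within +/-19 degrees), a trimodal central
# stalk distribution with dwells near 120, 0, -120 degrees (one narrow, two
# wide), an upper-peripheral-stalk displacement coupled to F1 rotation
# (7 A full span over 6.5 degrees; middle 95%: 5 A over 6 degrees), and
# dimers whose monomers are independent by default.

#' Generator configuration for synthetic ATP synthase particle ensembles
#'
#' Collects the calibrated defaults of the synthetic-data model. The F1-head
#' width is a wrapped normal with sd `19/1.96` so the central-95% interval is
#' +/-19 degrees. Stalk dwell widths derive from dwell arcs of 15, 29 and 32
#' degrees (`sd = arc/4`): one narrow mode (assigned to 0 degrees) and two
#' wide ones. The measurement-noise sd treats the ~19 degree angular
#' resolution as a FWHM (`19/2.355`). The UPS displacement is a truncated
#' normal (sd 1.276 A, truncated at +/-3.5 A) coupled to F1 rotation through
#' the odd piecewise-linear map [ups_coupling_g()].
#'
#' @param f1_sd Wrapped-normal sd of the F1-head angle (degrees).
#' @param stalk_modes Central-stalk dwell centers (degrees).
#' @param stalk_sds Per-mode wrapped-normal sds (degrees).
#' @param stalk_weights Mode occupancies; must be non-negative and sum to 1.
#' @param coupling_a,coupling_b Amplitude (degrees) and phase (degrees) of the
#'   tri-periodic stalk-to-F1 coupling `a*sin(3*theta - b)`; `a = 0` (the
#'   default) makes F1 and stalk angles independent.
#' @param noise_sd Angular measurement-noise sd (degrees) for
#'   [add_wrapped_noise()].
#' @param ups_sd Sd of the UPS displacement before truncation (Angstrom).
#' @param ups_trunc Truncation bound of the UPS displacement (Angstrom).
#' @param ups_slope_inner Inner slope of the UPS-to-F1 coupling (degrees/A),
#'   applying for |d| <= `ups_inner_limit`.
#' @param ups_inner_limit Break point of the piecewise coupling (Angstrom).
#' @param ups_outer_deg Coupling value at the truncation bound (degrees).
#' @param ups_residual_sd Sd of the F1 residual on top of the UPS coupling
#'   (degrees), chosen so the marginal F1 width stays at `f1_sd`.
#' @param intradimer_correlation In `[0, 1]`: probability that monomer 1 of a
#'   dimer copies monomer 0's state (0 = independent, 1 = identical).
#' @param seed Integer seed used by generator operations unless overridden;
#'   `NULL` (the default) continues the current RNG stream, so repeated draws
#'   differ while a fixed seed gives byte-identical tables.
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config()
#' cfg$f1_sd
#' @export
generator_config <- function(f1_sd = 19 / 1.96,
                             stalk_modes = c(0, 120, -120),
                             stalk_sds = c(3.75, 7.25, 8.0),
                             stalk_weights = c(1, 1, 1) / 3,
                             coupling_a = 0,
                             coupling_b = 0,
                             noise_sd = 19 / 2.355,
                             ups_sd = 1.276,
                             ups_trunc = 3.5,
                             ups_slope_inner = 1.2,
                             ups_inner_limit = 2.5,
                             ups_outer_deg = 3.25,
                             ups_residual_sd = 9.57,
                             intradimer_correlation = 0,
                             seed = NULL) {
  cfg <- list(
    f1_sd = f1_sd, stalk_modes = stalk_modes, stalk_sds = stalk_sds,
    stalk_weights = stalk_weights, coupling_a = coupling_a,
    coupling_b = coupling_b, noise_sd = noise_sd, ups_sd = ups_sd,
    ups_trunc = ups_trunc, ups_slope_inner = ups_slope_inner,
    ups_inner_limit = ups_inner_limit, ups_outer_deg = ups_outer_deg,
    ups_residual_sd = ups_residual_sd,
    intradimer_correlation = intradimer_correlation, seed = seed
  )
  if (any(c(cfg$f1_sd, cfg$stalk_sds, cfg$noise_sd, cfg$ups_sd,
            cfg$ups_residual_sd) < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  k <- length(cfg$stalk_modes)
  if (length(cfg$stalk_sds) != k || length(cfg$stalk_weights) != k) {
    stop("stalk modes, sds and weights must have equal length", call. = FALSE)
  }
  if (any(cfg$stalk_weights < 0) || abs(sum(cfg$stalk_weights) - 1) > 1e-9) {
    stop("stalk weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (cfg$ups_trunc <= 0 || cfg$ups_inner_limit <= 0 ||
      cfg$ups_inner_limit >= cfg$ups_trunc) {
    stop("require 0 < ups_inner_limit < ups_trunc", call. = FALSE)
  }
  if (cfg$intradimer_correlation < 0 || cfg$intradimer_correlation > 1) {
    stop("intradimer_correlation must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Sample F1-head rotation angles
#'
#' Draws from a wrapped normal centred at 0 degrees. With the default sd
#' (`19/1.96`) the central 95% of a large sample spans +/-19 degrees.
#'
#' @param n Number of angles.
#' @param sd Wrapped-normal sd in degrees.
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return Numeric vector of `n` wrapped angles in degrees.
#' @export
sample_f1_angles <- function(n, sd = 19 / 1.96, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop("`n` must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1 || sd < 0) {
    stop("`sd` must be a non-negative scalar", call. = FALSE)
  }
  set_local_seed(seed)
  wrap_deg(rnorm(n, mean = 0, sd = sd))
}

#' Sample central-stalk rotation angles from a trimodal wrapped mixture
#'
#' Mixture of wrapped normals; components are chosen by `weights`. The
#' defaults place dwells at 0, 120 and -120 degrees with one narrow and two
#' wide modes.
#'
#' @param n Number of angles.
#' @param modes Mode centres in degrees.
#' @param sds Per-mode sds in degrees.
#' @param weights Mode probabilities summing to 1.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` wrapped angles in degrees.
#' @export
sample_stalk_angles <- function(n,
                                modes = c(0, 120, -120),
                                sds = c(3.75, 7.25, 8.0),
                                weights = c(1, 1, 1) / 3,
                                seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop("`n` must be a non-negative integer", call. = FALSE)
  }
  k <- length(modes)
  if (length(sds) != k || length(weights) != k) {
    stop("`modes`, `sds` and `weights` must have equal length", call. = FALSE)
  }
  if (any(sds < 0)) stop("`sds` must be non-negative", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be non-negative and sum to 1", call. = FALSE)
  }
  set_local_seed(seed)
  comp <- sample.int(k, size = n, replace = TRUE, prob = weights)
  wrap_deg(rnorm(n, mean = modes[comp], sd = sds[comp]))
}

#' Tri-periodic coupling offset of the F1 head to the central stalk
#'
#' Computes `a * sin(3*theta - b)` with `theta` and `b` in degrees. The
#' offset is 120-degree periodic in `theta` and is added to F1 angles by the
#' caller before any measurement noise.
#'
#' @param stalk_angles Central-stalk angles in degrees.
#' @param a Amplitude in degrees.
#' @param b Phase in degrees.
#' @return Numeric vector of offsets in degrees.
#' @examples
#' couple_f1_to_stalk(30, a = 10, b = 0) # 10 * sin(90 deg) = 10
#' @export
couple_f1_to_stalk <- function(stalk_angles, a = 0, b = 0) {
  a * sin(deg2rad(3 * stalk_angles - b))
}

#' Add wrapped angular measurement noise
#'
#' Perturbs angles by a wrapped normal of sd `sd` (degrees) and wraps the
#' result back to (-180, 180]. Models the finite (~19 degree) angular
#' resolution of per-particle assignment.
#'
#' @param angles Angles in degrees.
#' @param sd Noise sd in degrees; `0` is the identity.
#' @param seed Optional integer seed.
#' @return Wrapped angles of the same length.
#' @export
add_wrapped_noise <- function(angles, sd = 19 / 2.355, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1 || sd < 0) {
    stop("`sd` must be a non-negative scalar", call. = FALSE)
  }
  set_local_seed(seed)
  if (sd == 0) return(wrap_deg(angles))
  wrap_deg(angles + rnorm(length(angles), 0, sd))
}

#' Odd piecewise-linear UPS-to-F1 coupling map
#'
#' Maps a UPS (ASA2/4) displacement `d` in Angstrom to the coupled F1-head
#' rotation in degrees: slope `ups_slope_inner` (1.2 deg/A) up to
#' `ups_inner_limit` (2.5 A), then linear to (`ups_trunc`, `ups_outer_deg`) =
#' (3.5 A, 3.25 deg). This reproduces both calibration anchors of the
#' ensemble: the middle-95% pair (5 A over 6 degrees) and the full-span pair
#' (7 A over 6.5 degrees), which are not mutually proportional.
#'
#' @param d Displacements in Angstrom (signed along the trajectory).
#' @param cfg A [generator_config()].
#' @return Coupled F1 rotations in degrees; `g(0) = 0` and `g(-d) = -g(d)`.
#' @export
ups_coupling_g <- function(d, cfg = generator_config()) {
  a <- abs(d)
  knee <- cfg$ups_slope_inner * cfg$ups_inner_limit
  outer_slope <- (cfg$ups_outer_deg - knee) / (cfg$ups_trunc - cfg$ups_inner_limit)
  sign(d) * (cfg$ups_slope_inner * pmin(a, cfg$ups_inner_limit) +
               outer_slope * pmax(a - cfg$ups_inner_limit, 0))
}

# truncated normal on [-lim, lim] by inverse-CDF sampling
r_truncnorm <- function(n, sd, lim) {
  lo <- pnorm(-lim, 0, sd)
  qnorm(runif(n, lo, 1 - lo), 0, sd)
}

#' Sample a UPS trajectory ensemble
#'
#' Draws `n` UPS displacements from a normal (sd `cfg$ups_sd`) truncated to
#' `[-ups_trunc, ups_trunc]` and the coupled F1-head angle
#' `g(d) + residual`, with a wrapped-normal residual of sd
#' `cfg$ups_residual_sd` so that the marginal F1 width matches the +/-19
#' degree calibration.
#'
#' @param n Number of particles (>= 1).
#' @param seed Optional integer seed (default: `cfg$seed`).
#' @param cfg A [generator_config()].
#' @return A `data.frame` with columns `particle_id`, `ups_disp`, `theta_f1`,
#'   `true_ups_disp`, `true_theta_f1` (the noise-free coupled angle).
#' @export
sample_ups_ensemble <- function(n, seed = NULL, cfg = generator_config()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  set_local_seed(if (is.null(seed)) cfg$seed else seed)
  d <- r_truncnorm(n, cfg$ups_sd, cfg$ups_trunc)
  g <- ups_coupling_g(d, cfg)
  data.frame(
    particle_id = seq_len(n),
    ups_disp = d,
    theta_f1 = wrap_deg(g + rnorm(n, 0, cfg$ups_residual_sd)),
    true_ups_disp = d,
    true_theta_f1 = g
  )
}

# one monomer's worth of states under cfg
sample_monomer_states <- function(n, cfg) {
  stalk <- sample_stalk_angles(n, cfg$stalk_modes, cfg$stalk_sds,
                               cfg$stalk_weights)
  d <- r_truncnorm(n, cfg$ups_sd, cfg$ups_trunc)
  offset <- ups_coupling_g(d, cfg) +
    couple_f1_to_stalk(stalk, cfg$coupling_a, cfg$coupling_b)
  f1 <- wrap_deg(offset + rnorm(n, 0, cfg$ups_residual_sd))
  list(stalk = stalk, f1 = f1, ups = d, true_f1 = wrap_deg(offset))
}

#' Generate a synthetic dimer particle table
#'
#' Produces `2 * n_dimers` monomer rows. Each monomer's central-stalk angle is
#' drawn from the trimodal mixture; the F1-head angle combines the UPS
#' coupling, the optional tri-periodic stalk coupling (`cfg$coupling_a`), and
#' a wrapped-normal residual, so with default `coupling_a = 0` the F1 and
#' stalk angles are independent and the F1 marginal keeps its +/-19 degree
#' central-95% width. Monomers within a dimer are independent unless
#' `cfg$intradimer_correlation > 0`, in which case monomer 1 copies
#' monomer 0's state with that probability.
#'
#' @param n_dimers Number of dimers (>= 1).
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed (default: `cfg$seed`).
#' @param dimers_per_tomogram Dimers assigned to each synthetic tomogram id.
#' @return A validated [particle_table()] `data.frame`.
#' @export
make_particle_table <- function(n_dimers, cfg = generator_config(),
                                seed = NULL, dimers_per_tomogram = 50L) {
  if (!is.numeric(n_dimers) || length(n_dimers) != 1 || n_dimers < 1 ||
      n_dimers != round(n_dimers)) {
    stop("`n_dimers` must be a positive integer", call. = FALSE)
  }
  n_dimers <- as.integer(n_dimers)
  set_local_seed(if (is.null(seed)) cfg$seed else seed)
  m0 <- sample_monomer_states(n_dimers, cfg)
  m1 <- sample_monomer_states(n_dimers, cfg)
  if (cfg$intradimer_correlation > 0) {
    copy <- runif(n_dimers) < cfg$intradimer_correlation
    m1$stalk[copy] <- m0$stalk[copy]
    m1$f1[copy] <- m0$f1[copy]
    m1$ups[copy] <- m0$ups[copy]
    m1$true_f1[copy] <- m0$true_f1[copy]
  }
  dimer_id <- rep(seq_len(n_dimers), each = 2L)
  monomer_index <- rep(c(0L, 1L), times = n_dimers)
  pick <- function(a, b) ifelse(monomer_index == 0L, a[dimer_id], b[dimer_id])
  tab <- data.frame(
    particle_id = seq_len(2L * n_dimers),
    tomogram_id = (dimer_id - 1L) %/% as.integer(dimers_per_tomogram) + 1L,
    dimer_id = dimer_id,
    monomer_index = monomer_index,
    theta_f1 = pick(m0$f1, m1$f1),
    theta_stalk = pick(m0$stalk, m1$stalk),
    ups_disp = pick(m0$ups, m1$ups),
    true_theta_f1 = pick(m0$true_f1, m1$true_f1),
    true_theta_stalk = pick(m0$stalk, m1$stalk),
    true_ups_disp = pick(m0$ups, m1$ups)
  )
  particle_table(tab)
}

#' Detect prominent modes of an angular histogram
#'
#' Bins wrapped angles at `bin_width` degrees, finds circular local maxima of
#' the counts with prominence at least `prominence` times the count range,
#' and refines each mode centre by a parabolic fit through the peak bin and
#' its two circular neighbours.
#'
#' @param angles Angles in degrees.
#' @param bin_width Histogram bin width in degrees (must divide 360).
#' @param prominence Fraction of the count range required as prominence.
#' @return Numeric vector of mode centres in degrees, sorted ascending.
#' @export
find_angle_modes <- function(angles, bin_width = 5, prominence = 0.2) {
  if (360 %% bin_width != 0) stop("`bin_width` must divide 360", call. = FALSE)
  nb <- as.integer(360 / bin_width)
  idx <- pmin(floor((wrap_deg(angles) + 180) / bin_width) + 1, nb)
  counts <- tabulate(idx, nbins = nb)
  rng <- diff(range(counts))
  if (rng == 0) return(numeric())
  peaks <- circ_extrema(-counts, prominence * rng)
  centers <- -180 + (peaks - 0.5) * bin_width
  refined <- vapply(seq_along(peaks), function(i) {
    k <- peaks[i]
    sl <- counts[if (k == 1) nb else k - 1]
    sr <- counts[if (k == nb) 1 else k + 1]
    denom <- sl - 2 * counts[k] + sr
    delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (sl - sr) / denom
    centers[i] + max(-1, min(1, delta)) * bin_width
  }, numeric(1))
  sort(wrap_deg(refined))
}
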