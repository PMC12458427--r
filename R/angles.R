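# Angle utilities. All public angles are degrees in (-180, 180].

#' Wrap angles into (-180, 180]
#'
#' Shifts each angle by a multiple of 360 degrees so that the result lies in
#' the half-open interval (-180, 180]. Idempotent and 360-periodic.
#'
#' @param x Numeric vector of angles in degrees. Must be finite.
#' @return Numeric vector of the same length, each element in (-180, 180].
#' @examples
#' wrap_deg(c(190, 180, -180, 365))
#' @export
wrap_deg <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (length(x) && any(!is.finite(x))) stop("angles must be finite", call. = FALSE)
  x - 360 * ceiling((x - 180) / 360)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean of angles in degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Circular mean in (-180, 180].
#' @export
circ_mean_deg <- function(x) {
  xr <- deg2rad(x)
  wrap_deg(rad2deg(atan2(mean(sin(xr)), mean(cos(xr)))))
}

#' Circular standard deviation of angles in degrees
#'
#' Mardia's circular standard deviation, `sqrt(-2 log R)` scaled to degrees,
#' where R is the mean resultant length. For a wrapped normal with small sd
#' this equals the underlying normal sd.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Circular sd in degrees (`Inf` for a uniform resultant of zero).
#' @export
circ_sd_deg <- function(x) {
  xr <- deg2rad(x)
  r <- sqrt(mean(sin(xr))^2 + mean(cos(xr))^2)
  if (r <= 0) return(Inf)
  rad2deg(sqrt(-2 * log(r)))
}

# restore-on-exit seeding; a NULL seed leaves the RNG stream untouched
set_local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  set.seed(as.integer(seed))
  invisible(NULL)
}
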