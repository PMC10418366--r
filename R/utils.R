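# Internal helpers: classed error conditions and circular arithmetic.

stop_chisno <- function(msg, class) {
  cond <- structure(
    class = c(class, "chisno_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# shortest angular distance on the circle, degrees in [0, 180]
circ_dist <- function(a, b) abs(((a - b + 180) %% 360) - 180)

#' Circular mean of angles in degrees
#'
#' Direction of the mean resultant vector, reported in `[0, 360)`.
#'
#' @param angles numeric vector of angles, degrees.
#' @return circular mean in degrees.
#' @export
circ_mean <- function(angles) {
  r <- deg2rad(angles)
  rad2deg(atan2(mean(sin(r)), mean(cos(r)))) %% 360
}

#' Circular standard deviation of angles in degrees
#'
#' `sqrt(-2 log Rbar)` where `Rbar` is the mean resultant length; for a
#' tightly concentrated von Mises sample this estimates the angular spread
#' sigma of the well.
#'
#' @param angles numeric vector of angles, degrees.
#' @return circular standard deviation in degrees.
#' @export
circ_sd <- function(angles) {
  r <- deg2rad(angles)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rad2deg(sqrt(-2 * log(rbar)))
}
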