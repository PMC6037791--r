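#' Positive change of touch activation
#'
#' The goal generator only sees increases in sensor activation: a hand
#' arriving at a body location produces a signal, a hand resting on it or
#' leaving it does not.
#'
#' @param current,previous touch activation vectors of equal length.
#' @return elementwise `max(current - previous, 0)`.
#' @export
positive_change <- function(current, previous) {
  if (length(current) != length(previous)) {
    stop("touch vectors must have the same length", call. = FALSE)
  }
  pmax(current - previous, 0)
}

#' Encode a touch change as a two-dimensional neural map
#'
#' Converts the one-dimensional profile of positive touch changes into the
#' `rows` x `cols` input map of the goal generator.  The horizontal axis
#' indexes body position (the sensor profile is linearly resampled onto
#' `cols` columns in sensor-index space) and the vertical axis place-codes
#' the change amplitude: each active column holds a fixed-width Gaussian
#' bump whose centre row is proportional to the column's amplitude
#' (clipped to `[0, 1]`).  A silent column stays all-zero, so an all-zero
#' change yields an all-zero map.
#'
#' @param delta non-negative touch change vector (any number of sensors).
#' @param rows,cols map size (default 20 x 20, i.e. a 400-dimensional input).
#' @param bump_sigma vertical Gaussian width in rows (default 1.5).
#' @return a `rows` x `cols` matrix; flatten with `as.vector()` to feed the
#'   self-organizing map.
#' @export
encode_map <- function(delta, rows = 20, cols = 20, bump_sigma = 1.5) {
  if (any(delta < 0) || any(!is.finite(delta))) {
    stop("`delta` must be finite and non-negative", call. = FALSE)
  }
  n <- length(delta)
  amp <- if (n == cols) delta else {
    stats::approx(seq_len(n), delta, xout = seq(1, n, length.out = cols))$y
  }
  amp <- pmin(amp, 1)
  m <- matrix(0, rows, cols)
  active <- which(amp > 0)
  if (length(active)) {
    centre <- round(amp[active] * (rows - 1)) + 1
    rr <- seq_len(rows)
    m[, active] <- exp(-outer(rr, centre, "-")^2 / (2 * bump_sigma^2))
  }
  m
}
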