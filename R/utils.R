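#' @keywords internal
"_PACKAGE"

#' @importFrom stats median cor density rnorm rpois runif rbinom quantile
#'   ks.test sd filter lm pf optimize coef fitted var mad dist fft
#' @importFrom utils head tail read.csv write.csv
NULL

# wrap angles to [0, 2*pi)
wrap_2pi <- function(theta) theta %% (2 * pi)

# wrap angular differences to (-pi, pi]
wrap_pi <- function(dtheta) {
  out <- (dtheta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Unwrap a circular angle series
#'
#' Reconstructs a continuous accumulated-rotation series from angles on
#' the circle by integrating successive differences wrapped to (-pi, pi].
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of unwrapped (accumulating) angles, starting at
#'   `theta[1]`.
#' @export
unwrap_angle <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) >= 1)
  if (length(theta) == 1) return(theta)
  theta[1] + c(0, cumsum(wrap_pi(diff(theta))))
}

#' Circular median of angles
#'
#' Median for circular data: the observation minimizing the summed
#' absolute circular deviation to all observations; when several
#' observations tie (as for two antipodally symmetric points), the
#' circular mean of the minimizers is returned.
#'
#' @param theta numeric vector of angles in radians.
#' @return a single angle in `[0, 2*pi)`.
#' @export
circ_median <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0) return(NA_real_)
  if (length(theta) == 1) return(wrap_2pi(theta))
  dev <- vapply(theta, function(m) sum(abs(wrap_pi(theta - m))), numeric(1))
  best <- theta[dev <= min(dev) + 1e-12]
  out <- wrap_2pi(atan2(mean(sin(best)), mean(cos(best))))
  if (2 * pi - out < 1e-9) out <- 0
  out
}

# circular mean helper
circ_mean <- function(theta) wrap_2pi(atan2(mean(sin(theta)), mean(cos(theta))))

# contiguous runs of TRUE in a logical vector -> matrix [start, end]
true_runs <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# centered moving average with edge shrinkage
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window == 1L) return(x)
  k <- rep(1 / window, window)
  sm <- stats::filter(x, k, sides = 2)
  # fill edges with partial-window means
  n <- length(x)
  half <- window %/% 2
  idx <- which(is.na(sm))
  for (i in idx) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(x[lo:hi])
  }
  as.numeric(sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
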