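#' Wrap angles onto the ring
#'
#' Maps angles in degrees onto the half-open interval `(-l/2, l/2]`.
#'
#' @param x Numeric vector of angles (degrees).
#' @param l Length of the circular stimulus range (degrees).
#' @return Numeric vector of wrapped angles.
#' @export
wrap_angle <- function(x, l = 360) {
  y <- x %% l
  y[y > l / 2] <- y[y > l / 2] - l
  y[y <= -l / 2] <- y[y <= -l / 2] + l
  y
}

#' Minimal-arc angular difference
#'
#' Wrapped difference `a - b` in degrees, in `(-l/2, l/2]`.
#'
#' @param a,b Numeric vectors of angles (degrees).
#' @param l Stimulus-range length (degrees).
#' @return Wrapped differences.
#' @export
ang_diff <- function(a, b, l = 360) wrap_angle(a - b, l)

# Circular mean of angles (degrees) with optional weights; NA when the
# resultant vector vanishes.
circ_mean <- function(x, w = NULL, l = 360) {
  if (is.null(w)) w <- rep(1, length(x))
  k <- 2 * pi / l
  cs <- sum(w * cos(k * x))
  sn <- sum(w * sin(k * x))
  if (cs == 0 && sn == 0) return(NA_real_)
  wrap_angle(atan2(sn, cs) / k, l)
}

# Circular-aware mean and covariance of a matrix of angle columns:
# means are circular, covariance is taken over minimal-arc deviations
# from the mean (n - 1 denominator).
circ_moments <- function(x, l = 360) {
  x <- as.matrix(x)
  mu <- apply(x, 2, circ_mean, l = l)
  dev <- sweep(x, 2, mu, function(a, b) ang_diff(a, b, l))
  list(mean = mu, cov = stats::cov(dev), n = nrow(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# Wrap-safe population-vector mean: circular resultant locates the bump,
# then the linear mean of minimal-arc deviations matches the activity-
# weighted (likelihood) mean exactly. NA when undefined.
popvec_mean <- function(theta, w, l = 360) {
  ref <- circ_mean(theta, w, l)
  tot <- sum(w)
  if (is.na(ref) || tot == 0) return(NA_real_)
  wrap_angle(ref + sum(w * ang_diff(theta, ref, l)) / tot, l)
}
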