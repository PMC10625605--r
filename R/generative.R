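#' Ring tuning model
#'
#' Defines a population of `n_e` neurons with preferred stimuli evenly
#' spaced on the ring `(-l_deg/2, l_deg/2]` and Gaussian log-tuning of
#' width `a_deg`: `h_j(s) = -d(s, theta_j)^2 / (2 a^2)` with `d` the
#' minimal-arc (wrapped) difference.
#'
#' @param n_e Number of excitatory neurons.
#' @param a_deg Tuning width (degrees).
#' @param l_deg Stimulus-range length (degrees).
#' @return A `tuning_model` object with fields `theta`, `a`, `l`, `n_e`.
#' @examples
#' tun <- tuning_model(180, 40)
#' range(log_tuning(tun, 0))
#' @export
tuning_model <- function(n_e = 180, a_deg = 40, l_deg = 360) {
  stopifnot(n_e > 0, a_deg > 0, l_deg > 0)
  dth <- l_deg / n_e
  theta <- seq(-l_deg / 2 + dth, l_deg / 2, by = dth)
  structure(list(theta = theta, a = a_deg, l = l_deg, n_e = as.integer(n_e)),
            class = "tuning_model")
}

#' @export
print.tuning_model <- function(x, ...) {
  cat(sprintf("<tuning_model> %d neurons on (-%g, %g], width a = %g deg\n",
              x$n_e, x$l / 2, x$l / 2, x$a))
  invisible(x)
}

#' Log tuning profile
#'
#' Log firing-rate profile of the population at stimulus `s`:
#' `h_j(s) = -d(s, theta_j)^2 / (2 a^2)` with wrapped distance, so
#' `max_s h_j(s) = 0`.
#'
#' @param tuning A [tuning_model()].
#' @param s Stimulus value (degrees, scalar).
#' @return Numeric vector of log rates, all `<= 0`.
#' @export
log_tuning <- function(tuning, s) {
  stop_if_not_scalar(s, "s")
  d <- ang_diff(s, tuning$theta, tuning$l)
  -d^2 / (2 * tuning$a^2)
}

#' Hierarchical generative world
#'
#' The stimulus-parameter hierarchy: a stimulus parameter `z` uniform on
#' the ring, a stimulus `s ~ N(z, 1/Lambda_s)` (wrapped), and feedforward
#' Poisson input counts tuned to `s` with peak rate `u_f`.
#'
#' @param lambda_s Prior precision coupling `s` and `z` (deg^-2), `>= 0`.
#' @param u_f Peak feedforward count per draw, `> 0`.
#' @param tuning A [tuning_model()].
#' @return A `hierarchical_world` object.
#' @export
hierarchical_world <- function(lambda_s, u_f, tuning = tuning_model()) {
  stopifnot(lambda_s >= 0, u_f > 0)
  structure(list(lambda_s = lambda_s, u_f = u_f, tuning = tuning),
            class = c("hierarchical_world", "world"))
}

#' Parallel two-stimulus generative world
#'
#' Two stimuli with uniform marginals and an improper pairwise prior
#' `p(s1, s2) propto exp(-Lambda_s (s1 - s2)^2 / 2)`; the prior precision
#' matrix `Lambda_s [[1, -1], [-1, 1]]` is singular by construction. Each
#' stimulus generates its own feedforward input with peak rate `u_f`.
#'
#' @inheritParams hierarchical_world
#' @return A `parallel_world` object.
#' @export
parallel_world <- function(lambda_s, u_f, tuning = tuning_model()) {
  stopifnot(lambda_s >= 0, u_f > 0)
  structure(list(lambda_s = lambda_s, u_f = u_f, tuning = tuning),
            class = c("parallel_world", "world"))
}

new_ff_input <- function(counts, tuning) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == tuning$n_e, all(counts >= 0))
  n_f <- sum(counts)
  if (n_f == 0) {
    mu_f <- NA_real_
    lambda_f <- 0
  } else {
    # exact likelihood mean: wrap-safe two-pass linear weighted mean
    mu_f <- popvec_mean(tuning$theta, counts, tuning$l)
    lambda_f <- n_f / tuning$a^2
  }
  structure(list(counts = counts, theta = tuning$theta, a = tuning$a,
                 l = tuning$l, mu_f = mu_f, lambda_f = lambda_f, n_f = n_f,
                 empty = n_f == 0),
            class = "ff_input")
}

#' @export
print.ff_input <- function(x, ...) {
  cat(sprintf(
    "<ff_input> n_f = %g spikes, mu_f = %.2f deg, Lambda_f = %.4g deg^-2%s\n",
    x$n_f, x$mu_f, x$lambda_f, if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' @export
as_tibble.ff_input <- function(x, ...) {
  tibble::tibble(neuron_index = seq_along(x$counts), theta_deg = x$theta,
                 count = x$counts)
}

#' Draw one feedforward input
#'
#' Samples independent Poisson counts `u^f_j ~ Poisson(U_f exp(h_j(s)))`
#' and decodes the Gaussian likelihood they convey: mean `mu_f` (circular
#' population vector) and precision `Lambda_f = n_f / a^2` with `n_f` the
#' total count.
#'
#' @param world A [hierarchical_world()] or [parallel_world()].
#' @param s Stimulus value (degrees).
#' @return An `ff_input` object (fields `counts`, `mu_f`, `lambda_f`,
#'   `n_f`; `empty` flags a zero-count draw whose likelihood is undefined).
#' @export
sample_feedforward <- function(world, s) {
  tun <- world$tuning
  rate <- world$u_f * exp(log_tuning(tun, s))
  new_ff_input(stats::rpois(tun$n_e, rate), tun)
}

#' Build a feedforward input from a count vector
#'
#' @param counts Non-negative integer vector, one entry per neuron.
#' @param tuning A [tuning_model()].
#' @return An `ff_input` object.
#' @export
ff_input <- function(counts, tuning = tuning_model()) new_ff_input(counts, tuning)

#' Decode the likelihood carried by a feedforward input
#'
#' @param input An `ff_input`.
#' @param tuning Optional [tuning_model()] overriding the one stored in
#'   the input (must share the preferred-stimulus grid).
#' @return A list with `mu_f` (degrees) and `lambda_f` (deg^-2).
#' @export
decode_likelihood <- function(input, tuning = NULL) {
  if (input$n_f == 0) stop("empty input: likelihood undefined (n_f = 0)")
  if (is.null(tuning)) {
    list(mu_f = input$mu_f, lambda_f = input$lambda_f)
  } else {
    tmp <- ff_input(input$counts, tuning)
    list(mu_f = tmp$mu_f, lambda_f = tmp$lambda_f)
  }
}

#' Sample latents and feedforward inputs from a generative world
#'
#' Hierarchical world: `z ~ Uniform` on the ring, `s ~ N(z, 1/Lambda_s)`
#' (wrapped; uniform when `Lambda_s = 0`), one input. Parallel world: a
#' uniform common centre `z0` plus a zero-mean difference with
#' `Var(s1 - s2) = 1/Lambda_s`, matching the stated improper pairwise
#' density; two independent inputs.
#'
#' @param world A generative world.
#' @param n Number of independent draws.
#' @return A tibble with one row per draw: latent values and a
#'   list-column `input` (hierarchical) or `input1`/`input2` (parallel).
#' @export
sample_world <- function(world, n = 1) UseMethod("sample_world")

#' @export
sample_world.hierarchical_world <- function(world, n = 1) {
  l <- world$tuning$l
  z <- stats::runif(n, -l / 2, l / 2)
  s <- if (world$lambda_s == 0) {
    stats::runif(n, -l / 2, l / 2)
  } else {
    wrap_angle(z + stats::rnorm(n, 0, 1 / sqrt(world$lambda_s)), l)
  }
  tibble::tibble(z = z, s = s,
                 input = lapply(s, function(si) sample_feedforward(world, si)))
}

#' @export
sample_world.parallel_world <- function(world, n = 1) {
  l <- world$tuning$l
  z0 <- stats::runif(n, -l / 2, l / 2)
  d <- if (world$lambda_s == 0) {
    stats::runif(n, -l / 2, l / 2)
  } else {
    stats::rnorm(n, 0, 1 / sqrt(world$lambda_s))
  }
  s1 <- wrap_angle(z0 + d / 2, l)
  s2 <- wrap_angle(z0 - d / 2, l)
  tibble::tibble(
    s1 = s1, s2 = s2,
    input1 = lapply(s1, function(si) sample_feedforward(world, si)),
    input2 = lapply(s2, function(si) sample_feedforward(world, si)))
}

new_posterior <- function(mu, K, labels, degenerate = FALSE, l = 360) {
  K <- (K + t(K)) / 2
  structure(list(mu_p = stats::setNames(mu, labels), k_p = K,
                 labels = labels, degenerate = degenerate, l = l),
            class = "gaussian_posterior")
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat("<gaussian_posterior>", paste(x$labels, collapse = ", "),
      if (x$degenerate) "[degenerate]" else "", "\n")
  cat("mean:", paste(sprintf("%.3f", x$mu_p), collapse = ", "), "deg\n")
  cat("precision matrix (deg^-2):\n")
  print(signif(x$k_p, 4))
  invisible(x)
}

#' Analytic posterior of the hierarchical model
#'
#' Joint Gaussian posterior of `(s, z)` given one feedforward input:
#' mean `(mu_f, mu_f)` and precision
#' `K_p = [[Lambda_f + Lambda_s, -Lambda_s], [-Lambda_s, Lambda_s]]`.
#' At `Lambda_s = 0` the joint precision is singular; the returned object
#' is flagged degenerate and only the `s` marginal (variance
#' `1/Lambda_f`) is meaningful.
#'
#' @param input An `ff_input` with `n_f > 0`.
#' @param lambda_s Prior precision (deg^-2).
#' @return A `gaussian_posterior` with labels `c("s", "z")`.
#' @export
posterior_hierarchical <- function(input, lambda_s) {
  if (input$lambda_f <= 0) stop("empty input: posterior undefined")
  lf <- input$lambda_f
  K <- matrix(c(lf + lambda_s, -lambda_s, -lambda_s, lambda_s), 2, 2)
  new_posterior(c(input$mu_f, input$mu_f), K, c("s", "z"),
                degenerate = lambda_s == 0, l = input$l)
}

#' Analytic posterior of the parallel two-stimulus model
#'
#' Precision is the sum of likelihood and prior precisions,
#' `K_p = diag(Lambda_f1, Lambda_f2) + Lambda_s [[1, -1], [-1, 1]]`, and
#' the mean is the precision-weighted combination
#' `mu_p = K_p^-1 diag(Lambda_f) mu_f`, computed on wrapped deviations
#' from the circular mean of the two likelihood centres.
#'
#' @param input1,input2 `ff_input` objects for the two networks.
#' @param lambda_s Pairwise prior precision (deg^-2).
#' @return A `gaussian_posterior` with labels `c("s1", "s2")`.
#' @export
posterior_parallel <- function(input1, input2, lambda_s) {
  lf <- c(input1$lambda_f, input2$lambda_f)
  if (any(lf <= 0)) stop("empty input: posterior undefined")
  K <- diag(lf) + lambda_s * matrix(c(1, -1, -1, 1), 2, 2)
  l <- input1$l
  ref <- circ_mean(c(input1$mu_f, input2$mu_f), l = l)
  dmu <- ang_diff(c(input1$mu_f, input2$mu_f), ref, l)
  mu <- wrap_angle(ref + solve(K, lf * dmu), l)
  new_posterior(mu, K, c("s1", "s2"), l = l)
}

#' Marginal mean and covariance of a Gaussian posterior
#'
#' @param p A `gaussian_posterior`.
#' @return List with `mean` and `cov` (the inverse precision); for a
#'   degenerate hierarchical posterior only the `s` marginal is returned.
#' @export
posterior_moments <- function(p) {
  if (p$degenerate) {
    list(mean = p$mu_p["s"], cov = matrix(1 / p$k_p[1, 1], 1, 1,
                                          dimnames = list("s", "s")))
  } else {
    list(mean = p$mu_p, cov = solve(p$k_p))
  }
}

#' @export
tidy.gaussian_posterior <- function(x, ...) {
  m <- posterior_moments(x)
  tibble::tibble(latent = names(m$mean), mean = as.numeric(m$mean),
                 sd = sqrt(diag(m$cov)))
}
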