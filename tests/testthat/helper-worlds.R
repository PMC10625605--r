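# Shared fixtures: the standard ring (180 neurons, a = 40 deg) and seeded
# worlds. Seed convention: one base seed, per-test offsets.
BASE_SEED <- 20251001

std_tuning <- function() tuning_model(180, 40)

std_world <- function(lambda_s = 0.08, u_f = 5) {
  hierarchical_world(lambda_s, u_f, std_tuning())
}

std_input <- function(world = std_world(), s = 0, seed = BASE_SEED) {
  set.seed(seed)
  sample_feedforward(world, s)
}

# dense-grid Bayes oracle: numerically normalize the product of likelihood
# and prior on a fine stimulus grid, return mean and variance per latent
grid_posterior_hier <- function(input, lambda_s, ds = 0.1, half = 60) {
  s_grid <- seq(input$mu_f - half, input$mu_f + half, by = ds)
  z_grid <- s_grid
  loglik <- vapply(s_grid, function(s)
    sum(input$counts * (-(ang_diff(s, input$theta))^2 / (2 * input$a^2))),
    numeric(1))
  joint <- exp(outer(loglik, rep(0, length(z_grid)), "+") -
                 lambda_s / 2 * outer(s_grid, z_grid, "-")^2)
  joint <- joint / sum(joint)
  ps <- rowSums(joint)
  pz <- colSums(joint)
  list(mean_s = sum(ps * s_grid), var_s = sum(ps * s_grid^2) - sum(ps * s_grid)^2,
       mean_z = sum(pz * z_grid), var_z = sum(pz * z_grid^2) - sum(pz * z_grid)^2)
}

# quadrature oracle for 1-D KL between two Gaussians, in bits
kl_quadrature_1d <- function(mu_p, var_p, mu_q, var_q) {
  f <- function(x) {
    p <- stats::dnorm(x, mu_p, sqrt(var_p))
    q <- stats::dnorm(x, mu_q, sqrt(var_q))
    ifelse(p > 0, p * (log(p) - log(q)), 0)
  }
  stats::integrate(f, mu_p - 12 * sqrt(var_p), mu_p + 12 * sqrt(var_p),
                   rel.tol = 1e-10)$value / log(2)
}

# wrap a bare numeric vector as a one-latent sample chain
new_chain_for_test <- function(s) {
  neurosampler:::new_sample_chain(tibble::tibble(step = seq_along(s), s = s),
                                  burn_in = 0L)
}
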