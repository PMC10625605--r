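#' Network configuration for the spiking simulators
#'
#' Collects the parameters of the excitatory-inhibitory (E-I) ring network
#' and its coupled variant. Defaults mirror the base network: 180 E and 45
#' I neurons, connectivity footprint `a = 40` degrees, synaptic time
#' constant 2 ms, Euler step 0.1 ms, 2 ms refractory period, inhibitory
#' weight ratio `w_I / w_E = 5`, feedforward-to-I scale `w_if = 0.8`, and
#' population-vector decoding in non-overlapping 20 ms windows.
#'
#' `w_e` is the reference excitatory strength: it sets the E-to-I weight
#' and, through `w_ratio`, the I-to-E and I-to-I weights. `w_ee` is the
#' peak E-to-E ring weight and defaults to `w_e`; setting `w_ee = 0` while
#' keeping `w_e > 0` gives the feedforward regime in which only the
#' E-to-E connections are removed. `input_width_deg` is the tuning width
#' of the feedforward drive, defaulting to `sqrt(2) * a_deg` (exponent
#' `4 a^2`); the theory-side generative model uses exponent `2 a^2`.
#'
#' @param n_e,n_i E and I neuron counts.
#' @param a_deg Connectivity footprint on the ring (degrees).
#' @param l_deg Ring length (degrees).
#' @param u_f_hz Peak feedforward rate onto E neurons (spikes/s).
#' @param input_width_deg Feedforward tuning width (degrees).
#' @param w_e Reference excitatory weight (dimensionless).
#' @param w_ee Peak E-to-E weight; defaults to `w_e`.
#' @param w_ratio Ratio `w_I / w_E` of inhibitory to excitatory weights.
#' @param w_if Feedforward-to-I scale.
#' @param w_mn Cross-network E weight (coupled circuits only).
#' @param tau_d_ms Synaptic time constant (ms).
#' @param dt_ms Euler step (ms).
#' @param refractory_ms Refractory period (ms); 0 disables it.
#' @param t_ms Simulated duration (ms).
#' @param window_ms Decoding window (ms).
#' @param rec_noise Multiplicative recurrent noise (variance = mean)?
#' @param rate_ceiling_mult Stability guard: abort when the summed E rate
#'   exceeds this multiple of the feedforward-only rate.
#' @param seed Optional integer seed recorded in the config.
#' @return A `network_config` list.
#' @export
network_config <- function(n_e = 180L, n_i = 45L, a_deg = 40, l_deg = 360,
                           u_f_hz = 50, input_width_deg = sqrt(2) * a_deg,
                           w_e = 0.1, w_ee = w_e, w_ratio = 5, w_if = 0.8,
                           w_mn = 0, tau_d_ms = 2, dt_ms = 0.1,
                           refractory_ms = 2, t_ms = 1000, window_ms = 20,
                           rec_noise = TRUE, rate_ceiling_mult = 10,
                           seed = NULL) {
  stopifnot(n_e > 0, n_i > 0, dt_ms < tau_d_ms, w_e >= 0, w_ee >= 0,
            w_mn >= 0, a_deg > 0)
  structure(list(n_e = as.integer(n_e), n_i = as.integer(n_i), a_deg = a_deg,
                 l_deg = l_deg, u_f_hz = u_f_hz,
                 input_width_deg = input_width_deg, w_e = w_e, w_ee = w_ee,
                 w_ratio = w_ratio, w_if = w_if, w_mn = w_mn,
                 tau_d_ms = tau_d_ms, dt_ms = dt_ms,
                 refractory_ms = refractory_ms, t_ms = t_ms,
                 window_ms = window_ms, rec_noise = rec_noise,
                 rate_ceiling_mult = rate_ceiling_mult, seed = seed),
            class = "network_config")
}

ring_gaussian_matrix <- function(theta, w_peak, a, l) {
  d <- outer(theta, theta, function(x, y) ang_diff(x, y, l))
  j <- w_peak * l / (sqrt(2 * pi) * a) * exp(-d^2 / (2 * a^2))
  if (w_peak > 0) {
    # finite-ring wrap truncation is O(1e-5); rescale so each row sums to
    # exactly n * w_peak as the normalisation prescribes
    j <- j * (length(theta) * w_peak / rowSums(j))
  }
  j
}

#' Build the ring connectivity of the E-I network
#'
#' E-to-E weights decay as a wrapped Gaussian of the preferred-stimulus
#' distance, `J^EE_jk = w_ee L / (sqrt(2 pi) a) exp(-d^2 / (2 a^2))`, so
#' that each row sums to `n_e * w_ee`. The other blocks are unstructured:
#' `J^IE = w_e`, `J^EI = J^II = -w_ratio * w_e` (inhibitory entries carry
#' their sign). All blocks are scaled by `1/sqrt(N)` at use, not here.
#'
#' @param config A [network_config()].
#' @return List of matrices `j_ee`, `j_ei`, `j_ie`, `j_ii`.
#' @export
build_ring_connectivity <- function(config) {
  tun <- tuning_model(config$n_e, config$a_deg, config$l_deg)
  w_i <- config$w_ratio * config$w_e
  list(
    j_ee = ring_gaussian_matrix(tun$theta, config$w_ee, config$a_deg,
                                config$l_deg),
    j_ei = matrix(-w_i, config$n_e, config$n_i),
    j_ie = matrix(config$w_e, config$n_i, config$n_e),
    j_ii = matrix(-w_i, config$n_i, config$n_i))
}

#' Optimal recurrent weight
#'
#' The self-connection strength at which the excitatory-only network's
#' recurrent input encodes the prior precision exactly:
#' `w_E* = Lambda_s / (Lambda_f + Lambda_s)`, in `[0, 1)`.
#'
#' @param lambda_s Prior precision (deg^-2), `>= 0`.
#' @param lambda_f Likelihood precision (deg^-2), `> 0`.
#' @return The optimal weight.
#' @export
optimal_weight <- function(lambda_s, lambda_f) {
  stopifnot(lambda_s >= 0)
  if (lambda_f <= 0) stop("lambda_f must be positive")
  lambda_s / (lambda_f + lambda_s)
}

#' Optimal cross-network weight in coupled circuits
#'
#' Same ratio law as [optimal_weight()], with the partner network's
#' likelihood precision: `w_mn* = Lambda_s / (Lambda_s + Lambda_f_n)`.
#'
#' @param lambda_s Pairwise prior precision (deg^-2).
#' @param lambda_f_n Likelihood precision of the source network (deg^-2).
#' @return The optimal coupling weight.
#' @export
cross_network_weight <- function(lambda_s, lambda_f_n) {
  optimal_weight(lambda_s, lambda_f_n)
}

new_sim_trace <- function(samples, kind, params, extra = list()) {
  structure(c(list(samples = tibble::as_tibble(samples), kind = kind,
                   params = params), extra),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %s, %d decoded samples\n", x$kind,
              nrow(x$samples)))
  invisible(x)
}

#' Simulate the excitatory-only linear sampling network
#'
#' A fixed feedforward count vector is presented at every step; the
#' recurrent input is `w_e` times the previous step's spikes
#' (self-connections only), corrupted by Gaussian noise whose variance
#' equals the rectified mean (mimicking Poisson variability), and spikes
#' are drawn as independent Poissons from the rectified rate. At
#' `w_e = Lambda_s / (Lambda_f + Lambda_s)` the decoded spike positions
#' and recurrent-input positions form a Gibbs chain over `(s, z)`.
#'
#' @param input An `ff_input` presented at every step.
#' @param w_e Recurrent weight, `>= 0`.
#' @param n_steps Number of steps.
#' @param seed Optional integer seed.
#' @param noise `"multiplicative"` (variance = mean, the default) or
#'   `"additive"` (SD `sigma_r`) recurrent noise.
#' @param sigma_r Additive recurrent noise SD (used when
#'   `noise = "additive"`; also added on top if positive).
#' @param keep_arrays Keep full per-step spike, recurrent-input and rate
#'   matrices (memory scales with `n_e * n_steps`).
#' @param rate_ceiling_mult Abort with an "unstable" error when the
#'   summed instantaneous rate exceeds this multiple of `n_f`.
#' @return A `sim_trace` whose `samples` tibble has one row per step:
#'   decoded spike position `s_hat` with mass `n_r`, decoded
#'   recurrent-input position `z_hat` with mass `n_ur`, and the rate
#'   position `s_bar` with total rate `n_lambda`.
#' @export
simulate_e_only <- function(input, w_e, n_steps, seed = NULL,
                            noise = c("multiplicative", "additive"),
                            sigma_r = 0, keep_arrays = FALSE,
                            rate_ceiling_mult = 10) {
  noise <- match.arg(noise)
  stopifnot(w_e >= 0, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  ceiling_abs <- max(rate_ceiling_mult * input$n_f, 10)
  res <- sim_eonly_cpp(input$counts, w_e, as.integer(n_steps), input$theta,
                       noise == "multiplicative", sigma_r, ceiling_abs,
                       keep_arrays)
  if (res$status != 0) {
    stop(sprintf("unstable: summed rate exceeded %.3g at step %d",
                 ceiling_abs, res$bad_step))
  }
  samples <- tibble::as_tibble(as.data.frame(res$summary))
  names(samples) <- c("s_hat", "n_r", "z_hat", "n_ur", "s_bar", "n_lambda")
  samples <- tibble::add_column(samples, step = seq_len(nrow(samples)),
                                .before = 1)
  extra <- if (keep_arrays) list(r = res$r, u_r = res$u_r,
                                 lambda = res$lambda) else list()
  new_sim_trace(samples, "e_only",
                params = list(w_e = w_e, n_steps = n_steps, seed = seed,
                              noise = noise, sigma_r = sigma_r,
                              mu_f = input$mu_f, lambda_f = input$lambda_f,
                              n_f = input$n_f, a = input$a, l = input$l,
                              theta = input$theta),
                extra = extra)
}

ei_rates <- function(config, s) {
  tun <- tuning_model(config$n_e, config$input_width_deg, config$l_deg)
  rate_e <- config$u_f_hz / 1000 * exp(log_tuning(tun, s)) # spikes/ms
  rate_i <- config$w_if / config$n_i * sum(rate_e)
  list(rate_e = rate_e, rate_i = rate_i)
}

#' Simulate the full E-I ring network
#'
#' Hawkes-process network of `n_e` tuned E and `n_i` untuned I Poisson
#' neurons: feedforward Poisson spike streams and recurrent spikes are
#' filtered through an exponential synapse `eta(t) = exp(-t/tau_d)/tau_d`,
#' rates are the sum of feedforward and recurrent input (weights scaled by
#' `1/sqrt(N)`), spiking is Poisson per Euler step with a refractory
#' period, and the recurrent input carries multiplicative noise with
#' variance equal to its rectified mean. E spikes are decoded with a
#' population vector in non-overlapping windows; the feedforward stream
#' and the recurrent input are decoded in the same windows.
#'
#' @param config A [network_config()].
#' @param s Stimulus driving the feedforward input (degrees).
#' @param keep_arrays Keep the full E spike matrix.
#' @return A `sim_trace` with per-window decodes: `s_hat`/`n_spikes`
#'   (E spikes), `mu_ff`/`n_ff` (feedforward stream), `z_hat`/`n_ur`
#'   (recurrent input), plus mean population rates in Hz.
#' @export
simulate_ei <- function(config, s, keep_arrays = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  tun <- tuning_model(config$n_e, config$a_deg, config$l_deg)
  rates <- ei_rates(config, s)
  J <- build_ring_connectivity(config)
  n_tot <- config$n_e + config$n_i
  sc <- 1 / sqrt(n_tot)
  n_steps <- floor(config$t_ms / config$dt_ms)
  window_steps <- max(1L, round(config$window_ms / config$dt_ms))
  ref_steps <- round(config$refractory_ms / config$dt_ms)
  ceiling_abs <- config$rate_ceiling_mult * sum(rates$rate_e)
  res <- sim_ei_cpp(rates$rate_e, rates$rate_i, J$j_ee * sc, J$j_ei * sc,
                    J$j_ie * sc, J$j_ii * sc, n_steps, config$dt_ms,
                    config$tau_d_ms, ref_steps, window_steps, tun$theta,
                    config$rec_noise, ceiling_abs, keep_arrays)
  if (res$status != 0) {
    stop(sprintf("unstable: summed E rate exceeded %.3g at step %d",
                 ceiling_abs, res$bad_step))
  }
  w <- tibble::as_tibble(as.data.frame(res$windows))
  names(w) <- c("window", "s_hat", "n_spikes", "mu_ff", "n_ff", "z_hat",
                "n_ur")
  w$time_ms <- w$window * config$window_ms
  extra <- c(list(mean_rate_e = res$mean_rate_e,
                  mean_rate_i = res$mean_rate_i),
             if (keep_arrays) list(r_e = res$r_e) else list())
  new_sim_trace(w, "ei", params = c(config, list(s = s)), extra = extra)
}

#' Simulate two coupled E-I circuits
#'
#' Two copies of the E-I ring exchange excitatory projections: E neurons
#' of one network target E neurons of the other with the ring-Gaussian
#' profile (peak `w_mn`) and its I neurons uniformly with the same peak
#' weight. Within a network there are no E-to-E connections (uniform
#' marginal priors) and the recurrent interactions carry no noise. Each
#' network's E spikes are decoded locally per window.
#'
#' @param config A [network_config()]; `w_mn` sets the symmetric coupling.
#' @param s1,s2 Stimuli driving the two feedforward streams (degrees).
#' @return A `sim_trace` with per-window columns for both networks
#'   (`s1_hat`, `n1`, `mu_ff1`, `n_ff1`, and the same for network 2).
#' @export
simulate_coupled <- function(config, s1, s2) {
  if (!is.null(config$seed)) set.seed(config$seed)
  tun <- tuning_model(config$n_e, config$a_deg, config$l_deg)
  r1 <- ei_rates(config, s1)
  r2 <- ei_rates(config, s2)
  J <- build_ring_connectivity(config)
  n_tot <- config$n_e + config$n_i
  sc <- 1 / sqrt(n_tot)
  jx <- ring_gaussian_matrix(tun$theta, config$w_mn, config$a_deg,
                             config$l_deg) * sc
  jxi <- matrix(config$w_mn * sc, config$n_i, config$n_e)
  n_steps <- floor(config$t_ms / config$dt_ms)
  window_steps <- max(1L, round(config$window_ms / config$dt_ms))
  ref_steps <- round(config$refractory_ms / config$dt_ms)
  ceiling_abs <- config$rate_ceiling_mult * (sum(r1$rate_e) + sum(r2$rate_e))
  res <- sim_coupled_cpp(cbind(r1$rate_e, r2$rate_e),
                         (r1$rate_i + r2$rate_i) / 2, J$j_ei * sc,
                         J$j_ie * sc, J$j_ii * sc, jx, jxi, n_steps,
                         config$dt_ms, config$tau_d_ms, ref_steps,
                         window_steps, tun$theta, ceiling_abs)
  if (res$status != 0) {
    stop(sprintf("unstable: summed E rate exceeded %.3g at step %d",
                 ceiling_abs, res$bad_step))
  }
  w <- tibble::as_tibble(as.data.frame(res$windows))
  names(w) <- c("window", "s1_hat", "n1", "mu_ff1", "n_ff1", "s2_hat", "n2",
                "mu_ff2", "n_ff2")
  w$time_ms <- w$window * config$window_ms
  new_sim_trace(w, "coupled", params = c(config, list(s1 = s1, s2 = s2)))
}

#' Draw Poisson spike counts from a fixed rate vector
#'
#' The spike-generation stage in isolation: `n_draws` independent Poisson
#' count vectors from one instantaneous rate profile (refractoriness
#' off). Used to study sampling and Fano statistics of spike generation.
#'
#' @param rate Non-negative rate vector (expected counts per draw).
#' @param n_draws Number of repeats.
#' @param seed Optional integer seed.
#' @return Integer matrix, neurons by draws.
#' @export
draw_spike_counts <- function(rate, n_draws, seed = NULL) {
  stopifnot(all(rate >= 0))
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rpois(length(rate) * n_draws, rate), nrow = length(rate))
}
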