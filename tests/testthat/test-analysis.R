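test_that("Gaussian KL matches quadrature and its closed-form pieces", {
  p <- list(mean = c(s = 0), cov = matrix(1, 1, 1, dimnames = list("s", "s")))
  q <- list(mean = c(s = 0), cov = matrix(2, 1, 1, dimnames = list("s", "s")))
  expect_equal(kl_gaussian(p, p), 0)
  expect_equal(kl_gaussian(q, p), kl_quadrature_1d(0, 1, 0, 2),
               tolerance = 1e-8)
  # a mean offset adds delta^2 K_q / 2 (in bits)
  q2 <- list(mean = c(s = 3), cov = q$cov)
  expect_equal(kl_gaussian(q2, p) - kl_gaussian(q, p),
               (3^2 / 2) / 2 / log(2), tolerance = 1e-10)
  expect_error(kl_gaussian(list(mean = c(s = 0),
                                cov = matrix(0, 1, 1,
                                             dimnames = list("s", "s"))), p),
               "singular")
})

test_that("information identity I = I_q + D_KL holds to 1e-9 bits", {
  set.seed(BASE_SEED + 501)
  for (i in 1:100) {
    lf <- runif(1, 0.02, 0.5)
    ls <- runif(1, 0.005, 0.5)
    kp <- matrix(c(lf + ls, -ls, -ls, ls), 2, 2)
    mu_p <- runif(1, -20, 20)
    p <- list(mean = c(s = mu_p, z = mu_p), cov = solve(kp))
    a <- matrix(rnorm(4, sd = 0.3), 2, 2)
    kq <- kp + crossprod(a)
    q <- list(mean = c(s = mu_p + rnorm(1), z = mu_p + rnorm(1)),
              cov = solve(kq))
    rep <- mutual_info_bound(q, p, ls)
    expect_lt(abs(rep$i_bits - rep$i_q_bits - kl_gaussian(q, p)), 1e-9)
    expect_gte(rep$kl_bits, 0)
  }
})

test_that("ideal mutual information grows with input rate", {
  tun <- std_tuning()
  ls <- 0.05
  i_bits <- sapply(c(1, 2, 5, 10, 20), function(uf) {
    lf <- uf * sum(exp(log_tuning(tun, 0))) / tun$a^2
    kp <- matrix(c(lf + ls, -ls, -ls, ls), 2, 2)
    p <- list(mean = c(s = 0, z = 0), cov = solve(kp))
    mutual_info_bound(p, p, ls)$i_bits
  })
  expect_true(all(diff(i_bits) > 0))
})

test_that("LFI estimator recovers the Poisson closed form and is invariant", {
  tun <- std_tuning()
  ds <- 4
  f1 <- 5 * exp(log_tuning(tun, -ds / 2))
  f2 <- 5 * exp(log_tuning(tun, ds / 2))
  set.seed(BASE_SEED + 502)
  r1 <- t(draw_spike_counts(f1, 1e4))
  r2 <- t(draw_spike_counts(f2, 1e4))
  est <- linear_fisher_information(r1, r2, ds)
  f0 <- 5 * exp(log_tuning(tun, 0))
  fp <- (f2 - f1) / ds
  closed <- sum(fp[f0 > 1e-6]^2 / f0[f0 > 1e-6])
  expect_lt(abs(est$lfi - closed) / closed, 0.05)
  # invertible linear mixing leaves LFI unchanged (2%)
  keep <- f0 > 1e-3
  set.seed(BASE_SEED + 503)
  m <- diag(sum(keep)) + matrix(rnorm(sum(keep)^2, sd = 0.05), sum(keep))
  est_raw <- linear_fisher_information(r1[, keep], r2[, keep], ds)
  est_mix <- linear_fisher_information(r1[, keep] %*% m, r2[, keep] %*% m, ds,
                                       bias_correct = FALSE)
  est_unmix <- linear_fisher_information(r1[, keep], r2[, keep], ds,
                                         bias_correct = FALSE)
  expect_lt(abs(est_mix$lfi - est_unmix$lfi) / est_unmix$lfi, 0.02)
  # too few trials for the correction
  expect_error(linear_fisher_information(r1[1:50, ], r2[1:50, ], ds),
               "too few trials")
  # bootstrap SE is available
  est_b <- linear_fisher_information(r1[1:500, ], r2[1:500, ], ds,
                                     n_boot = 20)
  expect_true(is.finite(est_b$se) && est_b$se > 0)
})

test_that("Fano factors behave for Poisson and scaled-Poisson counts", {
  set.seed(BASE_SEED + 504)
  m <- matrix(rpois(100 * 2000, 5), 100)
  ff <- fano_factor(m)
  expect_lt(abs(ff$mean_fano - 1), 3 * sqrt(2 / 2000 / 100))
  ff2 <- fano_factor(2 * m)
  expect_lt(abs(ff2$mean_fano - 2), 0.1)
  expect_error(fano_factor(matrix(0, 3, 10)), "zero")
  expect_error(fano_factor(matrix(1, 3, 1)), "repeats")
})

test_that("differential correlations vanish at w = 0 and split into parts", {
  w <- std_world(lambda_s = 0.08)
  d0 <- differential_correlations(w, 0, mode = "given_input",
                                  n_steps = 5000, seed = BASE_SEED + 505)
  expect_lt(d0$v_internal, 0.05)
  # self-connected recurrence carries position wander in per-neuron
  # variance: the cross-neuron f'f'^T amplitude stays near zero even
  # though the position variance is substantial
  wst <- optimal_weight(w$lambda_s, 0.157)
  d1 <- differential_correlations(w, wst, mode = "given_input",
                                  n_steps = 2e4, fit_amplitude = TRUE,
                                  seed = BASE_SEED + 506)
  expect_gt(d1$v_internal, 1)
  expect_lt(abs(d1$amplitude_fit), 0.2 * d1$v_internal)
})

test_that("the E-I ring generates anti-symmetric differential correlations", {
  cfg <- network_config(w_e = 0.1, t_ms = 20000, u_f_hz = 50, seed = 26)
  tr <- simulate_ei(cfg, 0, keep_arrays = TRUE)
  tun <- std_tuning()
  fit <- diff_corr_fit(tr, tun)
  # a positive collective amplitude along the f' direction
  expect_gt(fit$amplitude_fit, 0)
  # the measured covariance (Poisson diagonal removed) shows the
  # anti-symmetric quadrant pattern around the bump: same-side neuron
  # pairs covary positively, opposite-side pairs negatively
  fp <- fit$f_prime
  pos <- which(fp > quantile(fp, 0.92))
  neg <- which(fp < quantile(fp, 0.08))
  dc <- fit$sigma_dc
  offmean <- function(m) mean(m[row(m) != col(m)])
  expect_gt(offmean(dc[pos, pos]), 0)
  expect_gt(offmean(dc[neg, neg]), 0)
  expect_lt(mean(dc[pos, neg]), 0)
})

test_that("subjective-prior fitting recovers the generative prior", {
  tun <- std_tuning()
  pw <- parallel_world(0.05, 5, tun)
  set.seed(BASE_SEED + 507)
  inputs <- list(sample_feedforward(pw, -10), sample_feedforward(pw, 10))
  ch <- run_chain("parallel", inputs, 0.05, n_steps = 5e4,
                  seed = BASE_SEED + 508)
  cmp <- compare_to_posterior(ch, inputs)
  expect_lt(abs(cmp$fitted_lambda_s - 0.05) / 0.05, 0.10)
  # predicted mean from measured covariance matches the sampling mean
  q <- fit_distribution(ch)
  se <- sqrt(diag(q$cov) / q$n_samples)
  expect_true(all(abs(ang_diff(cmp$predicted_mean, cmp$sampling_mean)) <
                    3 * se + 0.05))
  # flat-prior chains fit a flat prior
  ch0 <- run_chain("parallel", inputs, 0, n_steps = 2e4,
                   seed = BASE_SEED + 509)
  cmp0 <- compare_to_posterior(ch0, inputs)
  expect_lt(cmp0$fitted_lambda_s, 0.005)
})

test_that("predicted means track sampling means across configurations", {
  tun <- std_tuning()
  set.seed(BASE_SEED + 510)
  ok <- 0
  for (k in 1:20) {
    ls <- runif(1, 0.01, 0.2)
    u1 <- runif(1, 3, 8)
    pw <- parallel_world(ls, u1, tun)
    s1 <- runif(1, -60, 60)
    inputs <- list(sample_feedforward(pw, s1),
                   sample_feedforward(pw, s1 + runif(1, -25, 25)))
    ch <- run_chain("parallel", inputs, ls, n_steps = 5000,
                    seed = BASE_SEED + 520 + k)
    cmp <- compare_to_posterior(ch, inputs)
    q <- fit_distribution(ch)
    se <- sqrt(diag(q$cov) / q$n_samples)
    if (all(abs(ang_diff(cmp$predicted_mean, cmp$sampling_mean)) <
              3 * se + 0.1)) ok <- ok + 1
  }
  expect_gte(ok, 18)
})
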