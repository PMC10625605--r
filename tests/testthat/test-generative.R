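test_that("log tuning has unit peak, correct width and circular wrapping", {
  tun <- tuning_model(180, 40)
  k <- 30
  expect_equal(log_tuning(tun, tun$theta[k])[k], 0)
  expect_equal(log_tuning(tun, tun$theta[k] + 40)[k], -0.5)
  # wrapped distance across the boundary: 179 vs -179 is 2 degrees
  tun2 <- tuning_model(360, 40)
  j <- which(tun2$theta == -179)
  expect_equal(log_tuning(tun2, 179)[j], -(2^2) / (2 * 40^2))
  expect_true(all(log_tuning(tun, 123.4) <= 0))
  expect_error(log_tuning(tun, NaN))
})

test_that("feedforward draws decode to the exact likelihood parameters", {
  w <- std_world(u_f = 2)
  set.seed(BASE_SEED + 101)
  # expected count at the preferred neuron is U_f
  rate_peak <- w$u_f * exp(log_tuning(w$tuning, w$tuning$theta[10]))[10]
  expect_equal(rate_peak, w$u_f)
  # Lambda_f = n_f / a^2 exactly on every draw; n_f sums counts
  for (i in 1:20) {
    inp <- sample_feedforward(w, runif(1, -180, 180))
    expect_identical(inp$n_f, sum(inp$counts))
    expect_equal(inp$lambda_f, inp$n_f / 40^2)
  }
  # sum-to-integral oracle: E[n_f] ~ U_f sqrt(2 pi) a / spacing
  n_f <- replicate(300, sample_feedforward(w, 0)$n_f)
  expected <- w$u_f * sqrt(2 * pi) * 40 / 2
  expect_lt(abs(mean(n_f) - expected) / expected, 0.02)
})

test_that("likelihood decoding recovers position: point masses and Monte Carlo", {
  tun <- tuning_model(36, 40)
  counts <- rep(0, 36)
  counts[tun$theta == 30] <- 1
  inp <- ff_input(counts, tun)
  expect_equal(inp$mu_f, 30)
  expect_equal(inp$lambda_f, 1 / 40^2)
  counts2 <- rep(0, 36)
  counts2[tun$theta %in% c(-10, 10)] <- 1
  expect_equal(ff_input(counts2, tun)$mu_f, 0)
  # empty input is flagged and refuses to decode
  empty <- ff_input(rep(0, 36), tun)
  expect_true(empty$empty)
  expect_error(decode_likelihood(empty), "empty")
  # Monte Carlo: decoded mean unbiased within 3 SE over 500 seeded draws
  w <- std_world(u_f = 5)
  set.seed(BASE_SEED + 102)
  mus <- replicate(500, sample_feedforward(w, 40)$mu_f)
  se <- sd(ang_diff(mus, 40)) / sqrt(500)
  expect_lt(abs(ang_diff(mean(mus), 40)), 3 * se)
})

test_that("hierarchical world sampling matches its stated conditionals", {
  w <- std_world(lambda_s = 0.02)
  set.seed(BASE_SEED + 103)
  draws <- sample_world(w, 2000)
  # var(s - z) ~ 1 / Lambda_s
  v <- var(ang_diff(draws$s, draws$z))
  expect_lt(abs(v - 1 / w$lambda_s) / (1 / w$lambda_s), 0.12)
  # marginal of s uniform over the ring
  expect_gt(ks.test((draws$s + 180) / 360, "punif")$p.value, 0.01)
  # strong-prior limit: s collapses onto z
  w2 <- std_world(lambda_s = 1e6)
  d2 <- sample_world(w2, 50)
  expect_lt(max(abs(ang_diff(d2$s, d2$z))), 0.1)
})

test_that("parallel world respects the improper pairwise prior", {
  tun <- std_tuning()
  pw <- parallel_world(0.02, 5, tun)
  set.seed(BASE_SEED + 104)
  d <- sample_world(pw, 2000)
  v <- var(ang_diff(d$s1, d$s2))
  expect_lt(abs(v - 1 / 0.02) / (1 / 0.02), 0.12)
  expect_gt(ks.test((d$s1 + 180) / 360, "punif")$p.value, 0.01)
  pw2 <- parallel_world(1e6, 5, tun)
  d2 <- sample_world(pw2, 50)
  expect_lt(max(abs(ang_diff(d2$s1, d2$s2))), 0.1)
})

test_that("hierarchical posterior matches the closed form and the grid oracle", {
  inp <- std_input(seed = BASE_SEED + 105)
  ls <- 0.05
  post <- posterior_hierarchical(inp, ls)
  expect_equal(post$k_p[1, 2], -ls)
  expect_equal(post$k_p[2, 2], ls)
  expect_equal(post$k_p[1, 1], inp$lambda_f + ls)
  # marginal variance of s is 1/Lambda_f for any Lambda_s > 0
  m <- posterior_moments(post)
  expect_equal(m$cov[1, 1], 1 / inp$lambda_f, tolerance = 1e-10)
  # strong prior: s and z become perfectly correlated
  m2 <- posterior_moments(posterior_hierarchical(inp, 1e7))
  expect_gt(m2$cov[1, 2] / sqrt(m2$cov[1, 1] * m2$cov[2, 2]), 0.999)
  # dense-grid Bayes oracle within 1% on mean and variance
  g <- grid_posterior_hier(inp, ls)
  expect_lt(abs(g$mean_s - m$mean["s"]), 0.01 * sqrt(m$cov[1, 1]))
  expect_lt(abs(g$var_s - m$cov[1, 1]) / m$cov[1, 1], 0.01)
  expect_lt(abs(g$var_z - m$cov[2, 2]) / m$cov[2, 2], 0.01)
  # degenerate prior flagged
  expect_true(posterior_hierarchical(inp, 0)$degenerate)
})

test_that("parallel posterior adds precisions and fuses means", {
  tun <- std_tuning()
  pw <- parallel_world(0.05, 5, tun)
  set.seed(BASE_SEED + 106)
  in1 <- sample_feedforward(pw, -10)
  in2 <- sample_feedforward(pw, 10)
  post <- posterior_parallel(in1, in2, 0.05)
  # precision additivity, elementwise
  expect_equal(post$k_p, diag(c(in1$lambda_f, in2$lambda_f)) +
                 0.05 * matrix(c(1, -1, -1, 1), 2, 2))
  # no prior: means are the likelihood means
  p0 <- posterior_parallel(in1, in2, 0)
  expect_equal(as.numeric(p0$mu_p), c(in1$mu_f, in2$mu_f))
  # infinitely strong coupling with equal precisions: symmetric fusion
  in_eq <- in2
  in_eq$counts <- in1$counts
  in_eq$n_f <- in1$n_f
  in_eq$lambda_f <- in1$lambda_f
  pinf <- posterior_parallel(in1, in_eq, 1e8)
  fused <- (in1$mu_f + in_eq$mu_f) / 2
  expect_equal(as.numeric(pinf$mu_p), rep(fused, 2), tolerance = 1e-4)
})

test_that("posteriors are translation equivariant on the ring", {
  w <- std_world()
  tun <- w$tuning
  a <- std_input(w, s = 10, seed = BASE_SEED + 107)
  pa <- posterior_hierarchical(a, 0.05)
  rot_right <- function(x, k) {
    k <- k %% length(x)
    c(utils::tail(x, k), utils::head(x, length(x) - k))
  }
  for (k_bins in c(15, -60)) {
    delta <- k_bins * tun$l / tun$n_e
    rotated <- ff_input(rot_right(a$counts, k_bins), tun)
    pb <- posterior_hierarchical(rotated, 0.05)
    expect_equal(unname(ang_diff(pb$mu_p, pa$mu_p)), rep(delta, 2),
                 tolerance = 1e-8)
    expect_equal(pa$k_p, pb$k_p, tolerance = 1e-12)
  }
})

test_that("feedforward inputs round-trip through CSV with sidecar", {
  inp <- std_input(seed = BASE_SEED + 108)
  path <- file.path(tempdir(), "ffin.csv")
  write_ff_input(inp, path, seed = 1)
  back <- read_ff_input(path)
  expect_equal(back$counts, inp$counts)
  expect_equal(back$mu_f, inp$mu_f)
  expect_equal(back$lambda_f, inp$lambda_f)
})
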