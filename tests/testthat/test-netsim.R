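test_that("ring connectivity has the stated normalisation and symmetry", {
  cfg <- network_config(w_e = 0.2)
  J <- build_ring_connectivity(cfg)
  # each row of J^EE sums to N_E * w_EE (wrap-sum tolerance)
  expect_equal(rowSums(J$j_ee), rep(180 * 0.2, 180), tolerance = 1e-9)
  # rows are symmetric about the diagonal neuron (even Gaussian)
  j <- 90
  row <- J$j_ee[j, ]
  expect_equal(row[j + 1:40], row[j - 1:40])
  # unstructured blocks with the stated ratios and signs
  expect_true(all(J$j_ie == 0.2))
  expect_true(all(J$j_ei == -1.0))
  expect_true(all(J$j_ii == -1.0))
  J0 <- build_ring_connectivity(network_config(w_e = 0.2, w_ee = 0))
  expect_true(all(J0$j_ee == 0))
})

test_that("optimal weights follow the precision-ratio law", {
  expect_equal(optimal_weight(0, 1), 0)
  expect_equal(optimal_weight(2, 2), 0.5)
  expect_equal(optimal_weight(1e9, 1), 1, tolerance = 1e-8)
  expect_error(optimal_weight(1, 0))
  expect_equal(cross_network_weight(0.3, 0.7), optimal_weight(0.3, 0.7))
  expect_equal(cross_network_weight(0.5, 0.5), 0.5)
})

test_that("the excitatory-only network obeys its degenerate limits", {
  tun <- std_tuning()
  silent <- ff_input(rep(0, 180), tun)
  tr <- simulate_e_only(silent, 0.5, 100, seed = 1)
  expect_true(all(tr$samples$n_r == 0))
  expect_true(all(is.na(tr$samples$s_hat)))
  expect_error(chain_from_trace(tr), "empty")
})

test_that("runaway excitation triggers the stability guard", {
  inp <- std_input(seed = BASE_SEED + 401)
  expect_error(simulate_e_only(inp, 1.6, 5000, seed = 2), "unstable")
})

test_that("identical seeds give bit-identical traces", {
  inp <- std_input(seed = BASE_SEED + 402)
  a <- simulate_e_only(inp, 0.3, 500, seed = 11)
  b <- simulate_e_only(inp, 0.3, 500, seed = 11)
  expect_identical(a$samples, b$samples)
})

test_that("rotating the input rotates the whole sampling distribution", {
  w <- std_world()
  tun <- w$tuning
  inp <- std_input(w, s = 0, seed = BASE_SEED + 403)
  k <- 30  # bins; 60 degrees
  rot <- ff_input(c(utils::tail(inp$counts, k), utils::head(inp$counts, 150)),
                  tun)
  wst <- optimal_weight(w$lambda_s, inp$lambda_f)
  q1 <- fit_distribution(chain_from_trace(
    simulate_e_only(inp, wst, 3e4, seed = BASE_SEED + 404)))
  q2 <- fit_distribution(chain_from_trace(
    simulate_e_only(rot, wst, 3e4, seed = BASE_SEED + 405)))
  expect_equal(unname(ang_diff(q2$mean, q1$mean)), c(60, 60), tolerance = 1)
  expect_equal(q1$cov, q2$cov, tolerance = 0.12)
})

test_that("internally generated position variance follows the weight law", {
  # V grows monotonically and ~linearly over [0, 1.5 w*]
  inp <- std_input(seed = BASE_SEED + 406)
  ls <- 0.5 * inp$lambda_f
  wst <- optimal_weight(ls, inp$lambda_f)
  grid <- wst * c(0, 0.5, 1, 1.5)
  v <- sapply(seq_along(grid), function(i) {
    tr <- simulate_e_only(inp, grid[i], 2e4, seed = BASE_SEED + 410 + i)
    sb <- tr$samples$s_bar[-(1:500)]
    var(ang_diff(sb, mean(sb)))
  })
  expect_true(all(diff(v) > 0))
  fit <- lm(v ~ grid)
  expect_gt(summary(fit)$r.squared, 0.97)
})

test_that("spike generation at fixed rates is Poisson with unit Fano", {
  inp <- std_input(seed = BASE_SEED + 407)
  tr <- simulate_e_only(inp, 0, 5000, seed = BASE_SEED + 408,
                        keep_arrays = TRUE)
  # w = 0, fixed input: every step draws from the same rate vector
  ff <- fano_factor(tr$r)
  live <- ff$per_neuron$fano[ff$per_neuron$mean_count > 1]
  se_mean <- sqrt(2 / 5000 / length(live))
  expect_lt(abs(mean(live) - 1), 3 * se_mean)
})

test_that("E-I network is silent without drive and stable at defaults", {
  cfg <- network_config(t_ms = 500, u_f_hz = 0.001, seed = 21)
  tr <- simulate_ei(cfg, 0)
  expect_lt(tr$mean_rate_e, 0.5)
  cfg2 <- network_config(t_ms = 1000, seed = 22)
  tr2 <- simulate_ei(cfg2, 0)
  expect_gt(tr2$mean_rate_e, 1)
  expect_lt(tr2$mean_rate_e, 100)
})

test_that("E-I sampling precision scales with likelihood precision", {
  # feedforward regime (no E-to-E): decoded precision proportional to the
  # decoded likelihood precision across input rates
  res <- sapply(c(25, 50, 100), function(uf) {
    cfg <- network_config(w_e = 0.1, w_ee = 0, t_ms = 6000, u_f_hz = uf,
                          refractory_ms = 0, seed = 23)
    tr <- simulate_ei(cfg, 0)
    s <- tr$samples
    c(lambda_f = mean(s$n_ff) / cfg$input_width_deg^2,
      prec = 1 / var(ang_diff(s$s_hat, mean(s$s_hat))))
  })
  ratios <- res["prec", ] / res["lambda_f", ]
  expect_true(all(diff(res["prec", ]) > 0))
  expect_lt(max(ratios) / min(ratios), 1.6)
})

test_that("E-I window counts are Poisson-like with filtered-input dispersion", {
  cfg <- network_config(w_e = 0.05, w_ee = 0, t_ms = 4000, u_f_hz = 50,
                        refractory_ms = 0, rec_noise = FALSE, seed = 24)
  tr <- simulate_ei(cfg, 0, keep_arrays = TRUE)
  # 20 ms window counts per neuron across windows
  n_win <- floor(ncol(tr$r_e) / 200)
  grp <- rep(seq_len(n_win), each = 200)
  wins <- t(rowsum(t(tr$r_e[, seq_len(n_win * 200)]), grp))
  ff <- fano_factor(wins)
  live <- ff$per_neuron[ff$per_neuron$mean_count > 1, ]
  # spike generation is Poisson given the rate (unit Fano, tested on the
  # fixed-rate stage); window counts over a filtered Poisson drive are
  # doubly stochastic, adding roughly the feedforward count variance
  expect_gt(mean(live$fano), 0.95)
  expect_lt(mean(live$fano), 2.2)
})

test_that("coupled circuits decouple at zero coupling and converge with it", {
  gap <- sapply(c(0, 0.1), function(wmn) {
    cfg <- network_config(w_e = 0.1, w_ee = 0, w_mn = wmn, t_ms = 4000,
                          u_f_hz = 50, seed = 25)
    tr <- simulate_coupled(cfg, -10, 10)
    s <- tr$samples
    c(gap = mean(ang_diff(s$s2_hat, s$s1_hat), na.rm = TRUE),
      rho = cor(s$s1_hat, s$s2_hat, use = "complete.obs"))
  })
  expect_lt(abs(gap["rho", 1]), 0.15)
  expect_gt(gap["gap", 1] - gap["gap", 2], 1)  # coupling pulls means together
  expect_gt(gap["rho", 2], gap["rho", 1])
})

test_that("network configs round-trip through YAML", {
  cfg <- network_config(w_e = 0.07, u_f_hz = 33, t_ms = 123, seed = 5L)
  path <- file.path(tempdir(), "cfg.yaml")
  write_network_config(cfg, path)
  back <- read_network_config(path)
  expect_equal(back[names(back) != "seed"], cfg[names(cfg) != "seed"])
  expect_equal(back$seed, 5L)
})
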