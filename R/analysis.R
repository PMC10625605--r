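as_gaussian <- function(x) {
  if (inherits(x, "gaussian_posterior")) {
    m <- posterior_moments(x)
    list(mean = m$mean, cov = m$cov)
  } else if (inherits(x, "sampling_dist")) {
    list(mean = x$mean, cov = as.matrix(x$cov))
  } else {
    stopifnot(is.list(x), !is.null(x$mean), !is.null(x$cov))
    list(mean = x$mean, cov = as.matrix(x$cov))
  }
}

align_gaussians <- function(q, p) {
  if (!is.null(names(p$mean)) && !is.null(names(q$mean))) {
    common <- intersect(names(p$mean), names(q$mean))
    if (length(common) == 0) stop("no shared latent dimensions")
    iq <- match(common, names(q$mean))
    ip <- match(common, names(p$mean))
    q <- list(mean = q$mean[iq], cov = q$cov[iq, iq, drop = FALSE])
    p <- list(mean = p$mean[ip], cov = p$cov[ip, ip, drop = FALSE])
  } else if (length(q$mean) != length(p$mean)) {
    stop("dimension mismatch between q and p")
  }
  list(q = q, p = p)
}

#' KL divergence between two Gaussians, in bits
#'
#' Closed-form `D_KL[p || q]` (reference direction: true posterior `p`
#' against approximating distribution `q`), reported in bits. Mean
#' differences are taken as minimal-arc angular differences.
#'
#' A degenerate hierarchical posterior (`lambda_s = 0`) factorises into a
#' Gaussian over `s` and a uniform over `z` on the ring. Against a joint
#' `(s, z)` approximation the divergence is then computed exactly for
#' that product density (uniform entropy `log L`, second moment
#' `L^2/12`, no mean term for the uniform axis); against an `s`-only
#' approximation — a network with no recurrent input, whose readout
#' encodes precisely the uninformative `z` prior — the `z` axis matches
#' exactly and only the `s` marginals are compared.
#'
#' @param q Approximating distribution: a `sampling_dist`,
#'   `gaussian_posterior`, or `list(mean, cov)`.
#' @param p Reference distribution, same forms.
#' @return KL divergence in bits (scalar, `>= 0` up to sampling error).
#' @export
kl_gaussian <- function(q, p) {
  if (inherits(p, "gaussian_posterior") && isTRUE(p$degenerate)) {
    qg <- as_gaussian(q)
    l <- p$l %||% 360
    sps2 <- 1 / p$k_p[1, 1]
    mu_ps <- p$mu_p[["s"]]
    if (length(qg$mean) >= 2 && all(c("s", "z") %in% names(qg$mean))) {
      iq <- match(c("s", "z"), names(qg$mean))
      qc <- qg$cov[iq, iq]
      detq <- det(qc)
      if (detq <= 0) stop("singular covariance along z")
      kq <- solve(qc)
      delta <- c(ang_diff(qg$mean[iq][1], mu_ps), 0)
      sp <- diag(c(sps2, l^2 / 12))
      nats <- -(0.5 * log(2 * pi * exp(1) * sps2) + log(l)) +
        0.5 * log((2 * pi)^2 * detq) +
        0.5 * (sum(diag(kq %*% sp)) + drop(t(delta) %*% kq %*% delta))
      return(nats / log(2))
    }
  }
  qg <- as_gaussian(q)
  pg <- as_gaussian(p)
  if (length(pg$mean) == 2 && identical(names(pg$mean), c("s", "z")) &&
      !"z" %in% names(qg$mean)) {
    # approximation has no z representation: its readout is the
    # uninformative uniform; D_KL[p || q_s x U_z] in closed form
    l <- if (inherits(p, "gaussian_posterior")) p$l %||% 360 else 360
    sqs2 <- qg$cov[match("s", names(qg$mean)), match("s", names(qg$mean))]
    if (sqs2 <= 0) stop("singular covariance along s")
    dlt <- ang_diff(qg$mean[["s"]], pg$mean[["s"]], l)
    sps2 <- pg$cov[1, 1]
    nats <- -0.5 * log((2 * pi * exp(1))^2 * det(pg$cov)) +
      0.5 * log(2 * pi * sqs2) + (sps2 + dlt^2) / (2 * sqs2) + log(l)
    return(nats / log(2))
  }
  al <- align_gaussians(qg, pg)
  q <- al$q
  p <- al$p
  d <- length(p$mean)
  detq <- det(q$cov)
  detp <- det(p$cov)
  if (detq <= 0 || detp <= 0) {
    bad <- names(which(diag(as.matrix(q$cov)) == 0))
    stop(sprintf("singular covariance%s",
                 if (length(bad)) paste0(" along ", paste(bad, collapse = ", "))
                 else ""))
  }
  kq <- solve(q$cov)
  delta <- ang_diff(as.numeric(q$mean), as.numeric(p$mean))
  nats <- 0.5 * (sum(diag(kq %*% p$cov)) + drop(t(delta) %*% kq %*% delta) -
                   d + log(detq / detp))
  nats / log(2)
}

#' Mutual-information accounting for a Gaussian approximation
#'
#' Lower-bound mutual information carried by a bivariate Gaussian
#' approximating distribution `q` about the feedforward input, relative
#' to the ideal observer using the true posterior `p`:
#' `I_q = log2(L) + (1/2)[1 + log(|K_q| / (2 pi Lambda_s)) -
#' tr(K_q K_p^-1) - (mu_p - mu_q)^T K_q (mu_p - mu_q)] / ln 2`, with the
#' ideal `I` the `q = p` case. The identity `I - I_q = D_KL[p || q]`
#' holds exactly.
#'
#' @param q Approximating bivariate Gaussian (`sampling_dist` or
#'   `list(mean, cov)`).
#' @param p True posterior (`gaussian_posterior` or `list(mean, cov)`),
#'   non-degenerate.
#' @param lambda_s Prior precision (deg^-2), `> 0`.
#' @param l Stimulus-range length (degrees).
#' @return A one-row tibble: `i_bits`, `i_q_bits`, `kl_bits`.
#' @export
mutual_info_bound <- function(q, p, lambda_s, l = 360) {
  if (lambda_s <= 0) stop("mutual information undefined at lambda_s = 0")
  al <- align_gaussians(as_gaussian(q), as_gaussian(p))
  q <- al$q
  p <- al$p
  stopifnot(length(p$mean) == 2)
  kq <- solve(q$cov)
  kp <- solve(p$cov)
  delta <- ang_diff(as.numeric(p$mean), as.numeric(q$mean))
  iq <- log2(l) + (1 + log(det(kq) / (2 * pi * lambda_s)) -
                     sum(diag(kq %*% p$cov)) -
                     drop(t(delta) %*% kq %*% delta)) / (2 * log(2))
  i <- log2(l) - (1 + log(2 * pi * lambda_s) - log(det(kp))) / (2 * log(2))
  tibble::tibble(i_bits = i, i_q_bits = iq, kl_bits = i - iq)
}

#' Scan the recurrent weight against the analytic posterior
#'
#' For each weight on the grid the excitatory-only network is simulated
#' with one fixed feedforward input, the sample chain is decoded, summarised
#' by its moment-matched Gaussian, and compared with the analytic
#' posterior by KL divergence. With `lambda_s > 0` the comparison is on
#' the joint `(s, z)` distribution (the `z` chain is decoded from the
#' recurrent input, so the `w = 0` point has no `z` samples and is
#' recorded as missing); at `lambda_s = 0` the posterior is degenerate in
#' `z` and the comparison is on the `s` marginal.
#'
#' @param world A [hierarchical_world()].
#' @param w_grid Weight grid; should include 0.
#' @param input Optional fixed `ff_input`; drawn at `s = 0` otherwise.
#' @param n_steps Steps per grid point.
#' @param seed Integer seed; each grid point derives its own stream.
#' @return A `weight_scan` tibble with columns `w_e`, `kl_bits`,
#'   `i_q_bits`, `v_internal`, `n_eff`; attributes `w_argmin`, `w_star`,
#'   `lambda_f`, `lambda_s`.
#' @export
weight_scan <- function(world, w_grid, input = NULL, n_steps = 5e4,
                        seed = 1) {
  if (is.null(input)) {
    set.seed(seed)
    input <- sample_feedforward(world, 0)
  }
  lambda_s <- world$lambda_s
  post <- posterior_hierarchical(input, lambda_s)
  rows <- purrr::map(seq_along(w_grid), function(i) {
    w <- w_grid[i]
    tr <- tryCatch(
      simulate_e_only(input, w, n_steps, seed = seed + i),
      error = function(e) NULL)
    if (is.null(tr)) {
      return(tibble::tibble(w_e = w, kl_bits = NA_real_, i_q_bits = NA_real_,
                            v_internal = NA_real_, n_eff = 0L))
    }
    ch <- chain_from_trace(tr)
    kl <- tryCatch({
      q <- fit_distribution(ch)
      kl_gaussian(q, post)
    }, error = function(e) NA_real_)
    iq <- if (lambda_s > 0 && is.finite(kl)) {
      tryCatch({
        q <- fit_distribution(ch)
        if (all(c("s", "z") %in% names(q$mean))) {
          mutual_info_bound(q, post, lambda_s)$i_q_bits
        } else NA_real_
      }, error = function(e) NA_real_)
    } else NA_real_
    sb <- tr$samples$s_bar
    sb <- sb[tr$samples$step > attr(ch, "burn_in") %||% 0]
    vint <- stats::var(ang_diff(sb, circ_mean(sb)))
    tibble::tibble(w_e = w, kl_bits = kl, i_q_bits = iq, v_internal = vint,
                   n_eff = nrow(ch))
  })
  out <- dplyr::bind_rows(rows)
  ok <- is.finite(out$kl_bits)
  w_argmin <- if (any(ok)) out$w_e[ok][which.min(out$kl_bits[ok])] else NA_real_
  structure(out, w_argmin = w_argmin,
            w_star = optimal_weight(lambda_s, input$lambda_f),
            lambda_f = input$lambda_f, lambda_s = lambda_s,
            class = c("weight_scan", class(out)))
}

#' @export
glance.weight_scan <- function(x, ...) {
  tibble::tibble(w_argmin = attr(x, "w_argmin"), w_star = attr(x, "w_star"),
                 kl_min = suppressWarnings(min(x$kl_bits, na.rm = TRUE)),
                 lambda_f = attr(x, "lambda_f"),
                 lambda_s = attr(x, "lambda_s"))
}

#' Bias-corrected linear Fisher information
#'
#' Empirical linear Fisher information (LFI) `f'^T Sigma^-1 f'` about a
#' stimulus from paired response sets recorded at `s - ds/2` and
#' `s + ds/2`, with the standard finite-sample bias correction
#' `(2T - N - 3) / (2T - 2)` on the quadratic form and the `2N / (T ds^2)`
#' subtraction. Optionally bootstraps trials for a standard error.
#'
#' @param resp1,resp2 Trial-by-neuron response matrices at the two
#'   stimulus values.
#' @param ds Stimulus separation (degrees).
#' @param bias_correct Apply the finite-sample correction.
#' @param n_boot Bootstrap resamples for the SE (0 to skip).
#' @return List with `lfi`, `lfi_raw`, `se`, `f_prime`, `n_trials`,
#'   `n_neurons`.
#' @export
linear_fisher_information <- function(resp1, resp2, ds, bias_correct = TRUE,
                                      n_boot = 0) {
  resp1 <- as.matrix(resp1)
  resp2 <- as.matrix(resp2)
  stopifnot(ncol(resp1) == ncol(resp2))
  # silent neurons (zero variance at both stimuli) carry no response and
  # would make the covariance singular
  keep <- (apply(resp1, 2, stats::var) + apply(resp2, 2, stats::var)) > 0
  resp1 <- resp1[, keep, drop = FALSE]
  resp2 <- resp2[, keep, drop = FALSE]
  n <- ncol(resp1)
  t_tr <- min(nrow(resp1), nrow(resp2))
  if (bias_correct && t_tr <= (n + 3) / 2) {
    stop("too few trials for the bias correction: need T > (N + 3) / 2")
  }
  lfi_once <- function(r1, r2) {
    kp <- (apply(r1, 2, stats::var) + apply(r2, 2, stats::var)) > 0
    r1 <- r1[, kp, drop = FALSE]
    r2 <- r2[, kp, drop = FALSE]
    fp <- (colMeans(r2) - colMeans(r1)) / ds
    sig <- (stats::cov(r1) + stats::cov(r2)) / 2
    # resamples can duplicate near-silent trials into exact collinearity;
    # a negligible ridge keeps the inverse defined
    diag(sig) <- diag(sig) + 1e-9 * mean(diag(sig))
    raw <- drop(t(fp) %*% solve(sig, fp))
    if (bias_correct) {
      raw * (2 * t_tr - n - 3) / (2 * t_tr - 2) - 2 * n / (t_tr * ds^2)
    } else {
      raw
    }
  }
  fp <- (colMeans(resp2) - colMeans(resp1)) / ds
  sig <- (stats::cov(resp1) + stats::cov(resp2)) / 2
  raw <- drop(t(fp) %*% solve(sig, fp))
  est <- if (bias_correct) {
    raw * (2 * t_tr - n - 3) / (2 * t_tr - 2) - 2 * n / (t_tr * ds^2)
  } else raw
  se <- NA_real_
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      i1 <- sample.int(nrow(resp1), replace = TRUE)
      i2 <- sample.int(nrow(resp2), replace = TRUE)
      lfi_once(resp1[i1, , drop = FALSE], resp2[i2, , drop = FALSE])
    }, numeric(1))
    se <- stats::sd(boots)
  }
  list(lfi = est, lfi_raw = raw, se = se, f_prime = fp, n_trials = t_tr,
       n_neurons = n)
}

# derivative of the mean response profile along the stimulus using ring
# translation equivariance: f(s + d)_j = f(s)_{j shifted}, one grid step.
profile_derivative <- function(f_mean, tuning) {
  n <- length(f_mean)
  dth <- tuning$l / n
  lag1 <- c(f_mean[n], f_mean[-n])   # profile shifted to larger s
  lead1 <- c(f_mean[-1], f_mean[1])  # shifted to smaller s
  (lag1 - lead1) / (2 * dth)
}

#' Differential-correlation decomposition of the sampling network
#'
#' Quantifies fluctuations of the network's rate position along the
#' stimulus subspace. `mode = "given_input"` holds one feedforward input
#' fixed and measures the internally generated position variance
#' `V(s_bar | u^f)` (theory: `a^2 n_f^-1 w_E*` at the optimal weight);
#' `mode = "given_stimulus"` redraws the input every trial so the
#' variance also inherits the sensory term `a^2 n_f^-1`. With
#' `fit_amplitude = TRUE` (given_input only) the response covariance is
#' accumulated and the coefficient of the differential-correlation
#' component `f' f'^T` in `Sigma - diag(f)` is fit by least squares.
#'
#' @param world A [hierarchical_world()].
#' @param w_e Recurrent weight: a number, or a function of the drawn
#'   `ff_input` returning one (e.g. the per-draw optimal weight).
#' @param s Stimulus (degrees).
#' @param mode `"given_input"` or `"given_stimulus"`.
#' @param n_steps Steps (per trial in given_stimulus mode).
#' @param n_trials Trials (given_stimulus mode).
#' @param burn_in Steps discarded at the start of each run.
#' @param fit_amplitude Also fit the `f' f'^T` amplitude from the spike
#'   covariance (needs the spike arrays; given_input mode). In this
#'   self-connected network the instantaneous spike covariance is
#'   diagonal — position wander is carried by amplified per-neuron
#'   variance — so the fitted amplitude is near zero; the collective
#'   covariance signature appears in the laterally connected E-I ring
#'   (see [diff_corr_fit()]).
#' @param seed Integer seed.
#' @return A list: `v_internal` or `v_total` (deg^2), `f_prime`,
#'   `amplitude_fit` (given_input with `fit_amplitude`), `n_f`, `w_e`.
#' @export
differential_correlations <- function(world, w_e, s = 0,
                                      mode = c("given_input",
                                               "given_stimulus"),
                                      n_steps = 1e4, n_trials = 100,
                                      burn_in = 200, fit_amplitude = FALSE,
                                      seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  pick_w <- function(input) if (is.function(w_e)) w_e(input) else w_e
  if (mode == "given_input") {
    input <- sample_feedforward(world, s)
    w_use <- pick_w(input)
    tr <- simulate_e_only(input, w_use, n_steps, keep_arrays = fit_amplitude)
    sb <- tr$samples$s_bar[tr$samples$step > burn_in]
    # drift guard: a stationary chain has matching half means
    h1 <- circ_mean(sb[seq_len(floor(length(sb) / 2))])
    h2 <- circ_mean(sb[-seq_len(floor(length(sb) / 2))])
    v <- stats::var(ang_diff(sb, circ_mean(sb)))
    if (abs(ang_diff(h1, h2)) > 6 * sqrt(2 * v / length(sb)) + 1) {
      stop("nonstationary trace: drifting position")
    }
    out <- list(v_internal = v, n_f = input$n_f, w_e = w_use,
                lambda_f = input$lambda_f)
    if (fit_amplitude) {
      r <- tr$r[, -seq_len(burn_in), drop = FALSE]
      f_mean <- rowMeans(r)
      fp <- profile_derivative(f_mean, world$tuning)
      sig <- stats::cov(t(r))
      resid <- sig - diag(f_mean)
      b <- fp %o% fp
      # diagonal carries private Poisson noise; fit covariances only
      off <- row(b) != col(b)
      out$amplitude_fit <- sum(resid[off] * b[off]) / sum(b[off]^2)
      out$f_prime <- fp
      out$sigma_resid <- resid
    }
    out
  } else {
    sb_all <- numeric(0)
    for (k in seq_len(n_trials)) {
      input <- sample_feedforward(world, s)
      if (input$n_f == 0) next
      tr <- simulate_e_only(input, pick_w(input), n_steps)
      sb_all <- c(sb_all, tr$samples$s_bar[tr$samples$step > burn_in])
    }
    list(v_total = stats::var(ang_diff(sb_all, circ_mean(sb_all))),
         w_e = w_e, n_trials = n_trials)
  }
}


#' Fit the differential-correlation amplitude from windowed spike counts
#'
#' Estimates the coefficient of the differential-correlation component
#' `f' f'^T` in the noise covariance of windowed population spike counts
#' (an E-I ring trace, or any neuron-by-window count matrix). The tuning
#' derivative `f'` is taken from the trial-averaged window profile using
#' ring translation equivariance, the diagonal (private Poisson noise) is
#' removed as `diag(f)`, and the amplitude is the least-squares
#' coefficient of `f' f'^T` over the off-diagonal entries.
#'
#' @param x A `sim_trace` from [simulate_ei()] run with
#'   `keep_arrays = TRUE`, or a neuron-by-window count matrix.
#' @param tuning A [tuning_model()] matching the neuron grid.
#' @param window_steps Steps aggregated per window when `x` is a trace.
#' @param burn_windows Initial windows discarded.
#' @return List: `amplitude_fit` (the `f' f'^T` coefficient),
#'   `amplitude_ff` (the `f f^T` coefficient), `f_prime`, `f_mean`,
#'   `sigma_resid` (covariance minus `diag(f)`), and `sigma_dc`
#'   (`sigma_resid` with the amplitude-fluctuation component removed).
#' @export
diff_corr_fit <- function(x, tuning, window_steps = 200, burn_windows = 5) {
  wins <- if (inherits(x, "sim_trace")) {
    if (is.null(x$r_e)) stop("trace must be run with keep_arrays = TRUE")
    n_win <- floor(ncol(x$r_e) / window_steps)
    grp <- rep(seq_len(n_win), each = window_steps)
    t(rowsum(t(x$r_e[, seq_len(n_win * window_steps), drop = FALSE]), grp))
  } else {
    as.matrix(x)
  }
  if (burn_windows > 0 && ncol(wins) > burn_windows) {
    wins <- wins[, -seq_len(burn_windows), drop = FALSE]
  }
  f_mean <- rowMeans(wins)
  fp <- profile_derivative(f_mean, tuning)
  resid <- stats::cov(t(wins)) - diag(f_mean)
  # joint least squares on the off-diagonal entries for the differential
  # component f'f'^T and the amplitude-fluctuation component f f^T
  b1 <- fp %o% fp
  b2 <- f_mean %o% f_mean
  off <- row(b1) != col(b1)
  g <- matrix(c(sum(b1[off]^2), sum(b1[off] * b2[off]),
                sum(b1[off] * b2[off]), sum(b2[off]^2)), 2, 2)
  rhs <- c(sum(resid[off] * b1[off]), sum(resid[off] * b2[off]))
  beta <- solve(g, rhs)
  list(amplitude_fit = beta[1], amplitude_ff = beta[2], f_prime = fp,
       f_mean = f_mean, sigma_resid = resid,
       sigma_dc = resid - beta[2] * b2)
}

#' Fano factors of repeated spike counts
#'
#' Per-neuron variance/mean over repeats; neurons with zero mean count
#' are excluded from the average.
#'
#' @param count_matrix Neurons-by-repeats count matrix (>= 2 repeats).
#' @return List with `per_neuron` tibble (`neuron`, `mean_count`, `fano`)
#'   and `mean_fano`.
#' @export
fano_factor <- function(count_matrix) {
  count_matrix <- as.matrix(count_matrix)
  if (ncol(count_matrix) < 2) stop("need at least 2 repeats")
  if (all(count_matrix == 0)) stop("all counts are zero")
  m <- rowMeans(count_matrix)
  v <- apply(count_matrix, 1, stats::var)
  fano <- ifelse(m > 0, v / m, NA_real_)
  list(per_neuron = tibble::tibble(neuron = seq_along(m), mean_count = m,
                                   fano = fano),
       mean_fano = mean(fano, na.rm = TRUE))
}

#' Compare a sampling distribution with the predicted posterior
#'
#' For a two-stimulus chain and its feedforward inputs: predicts the
#' sampling mean from the measured covariance and decoded likelihoods,
#' `<s_tilde>_pred = Sigma_s Lambda_f mu_f`, then fits the single
#' subjective prior-precision parameter by minimising the KL divergence
#' `D_KL[p(Lambda_s) || q]` between the implied posterior and the
#' sampling distribution over `lambda_s_grid` (refined continuously
#' around the grid optimum), and reports the implied posterior precision
#' `K_pred = Lambda_s-matrix + Lambda_f` against the empirical precision.
#'
#' @param chain A `sample_chain` with two latents (`s1`, `s2`).
#' @param inputs List of the two `ff_input`s.
#' @param lambda_s_grid Candidate prior precisions (deg^-2).
#' @return List: `predicted_mean`, `fitted_lambda_s`, `k_pred`,
#'   `k_empirical`, `kl_min_bits`, `sampling_mean`.
#' @export
compare_to_posterior <- function(chain, inputs,
                                 lambda_s_grid = NULL) {
  q <- fit_distribution(chain)
  if (det(as.matrix(q$cov)) <= 0) stop("singular sampling covariance")
  lf <- vapply(inputs, function(x) x$lambda_f, numeric(1))
  mu_f <- vapply(inputs, function(x) x$mu_f, numeric(1))
  l <- inputs[[1]]$l
  ref <- circ_mean(mu_f, l = l)
  dmu <- ang_diff(mu_f, ref, l)
  pred_mean <- wrap_angle(ref + drop(as.matrix(q$cov) %*% (lf * dmu)), l)
  names(pred_mean) <- names(q$mean)
  if (is.null(lambda_s_grid)) {
    lambda_s_grid <- c(0, 10^seq(-5, 0, length.out = 41))
  }
  klfun <- function(ls) {
    kl_gaussian(q, posterior_parallel(inputs[[1]], inputs[[2]], ls))
  }
  kls <- vapply(lambda_s_grid, klfun, numeric(1))
  i0 <- which.min(kls)
  lo <- lambda_s_grid[max(1, i0 - 1)]
  hi <- lambda_s_grid[min(length(lambda_s_grid), i0 + 1)]
  fitted <- if (hi > lo) {
    stats::optimize(klfun, c(lo, hi))$minimum
  } else lambda_s_grid[i0]
  if (klfun(fitted) > kls[i0]) fitted <- lambda_s_grid[i0]
  k_pred <- diag(lf) + fitted * matrix(c(1, -1, -1, 1), 2, 2)
  list(predicted_mean = pred_mean, fitted_lambda_s = fitted, k_pred = k_pred,
       k_empirical = solve(as.matrix(q$cov)), kl_min_bits = klfun(fitted),
       sampling_mean = q$mean)
}
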