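#' One Gibbs step for the hierarchical model
#'
#' Given the previous stimulus-parameter sample `z_prev`, draws
#' `s ~ N(s_bar, 1/(Lambda_f + Lambda_s))` with
#' `s_bar = (Lambda_f mu_f + Lambda_s z_prev) / (Lambda_f + Lambda_s)`
#' (the precision-weighted mean, computed on wrapped deviations from
#' `mu_f`), then `z ~ N(s, 1/Lambda_s)`. With `Lambda_s = 0` the `z` step
#' is undefined and `z` is drawn uniform on the ring.
#'
#' @param z_prev Previous `z` sample (degrees).
#' @param input An `ff_input` with `n_f > 0`.
#' @param lambda_s Prior precision (deg^-2).
#' @return Named numeric vector `c(s = , z = )`, wrapped to the ring.
#' @export
gibbs_step_hier <- function(z_prev, input, lambda_s) {
  if (input$lambda_f <= 0) stop("empty input: conditional undefined")
  lf <- input$lambda_f
  l <- input$l
  dz <- ang_diff(z_prev, input$mu_f, l)
  s_bar <- input$mu_f + lambda_s * dz / (lf + lambda_s)
  s_new <- wrap_angle(stats::rnorm(1, s_bar, 1 / sqrt(lf + lambda_s)), l)
  z_new <- if (lambda_s == 0) {
    stats::runif(1, -l / 2, l / 2)
  } else {
    wrap_angle(stats::rnorm(1, s_new, 1 / sqrt(lambda_s)), l)
  }
  c(s = s_new, z = z_new)
}

#' One Gibbs step for the parallel model
#'
#' Draws `s_m ~ N((Lambda_fm mu_fm + Lambda_s s_other) / (Lambda_fm +
#' Lambda_s), 1/(Lambda_fm + Lambda_s))` given the other network's last
#' sample, with wrapped differences relative to `mu_fm`.
#'
#' @param s_other_prev Last sample of the other stimulus (degrees).
#' @param input An `ff_input` for this network.
#' @param lambda_s Pairwise prior precision (deg^-2).
#' @return New sample of this stimulus (degrees).
#' @export
gibbs_step_parallel <- function(s_other_prev, input, lambda_s) {
  if (input$lambda_f <= 0) stop("empty input: conditional undefined")
  lf <- input$lambda_f
  l <- input$l
  d <- ang_diff(s_other_prev, input$mu_f, l)
  m <- input$mu_f + lambda_s * d / (lf + lambda_s)
  wrap_angle(stats::rnorm(1, m, 1 / sqrt(lf + lambda_s)), l)
}

new_sample_chain <- function(df, burn_in, dt_sample = 1, meta = list()) {
  structure(tibble::as_tibble(df),
            burn_in = as.integer(burn_in), dt_sample = dt_sample,
            meta = meta,
            class = c("sample_chain", class(tibble::tibble())))
}

#' Run a reference Gibbs chain
#'
#' Alternating-conditional Gibbs sampler for either generative model; the
#' algorithmic oracle the spiking networks are checked against. The
#' update order is fixed (`s` then `z`; network 1 then network 2) and the
#' chain is deterministic given `seed`. Initialisation: `z = mu_f`
#' (hierarchical) and `s_m = mu_fm` (parallel), i.e. in the high-density
#' region, matching the input-driven network start.
#'
#' @param model `"hierarchical"` or `"parallel"`.
#' @param input An `ff_input` (hierarchical) or list of two (parallel).
#' @param lambda_s Prior precision (deg^-2).
#' @param n_steps Chain length.
#' @param burn_in Samples discarded by [fit_distribution()]; default 10%
#'   of the chain with a floor of 100 (capped below `n_steps`).
#' @param seed Optional integer seed.
#' @return A `sample_chain` tibble with columns `step` and the latents
#'   (`s`, `z` or `s1`, `s2`), plus `burn_in` and metadata attributes.
#' @export
run_chain <- function(model = c("hierarchical", "parallel"), input, lambda_s,
                      n_steps = 1000L, burn_in = NULL, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in)) burn_in <- max(100L, ceiling(n_steps / 10))
  burn_in <- min(burn_in, n_steps - 1L)
  stopifnot(n_steps > burn_in)

  if (model == "hierarchical") {
    z <- input$mu_f
    s_out <- z_out <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      sz <- gibbs_step_hier(z, input, lambda_s)
      s_out[t] <- sz[["s"]]
      z <- sz[["z"]]
      z_out[t] <- z
    }
    df <- tibble::tibble(step = seq_len(n_steps), s = s_out, z = z_out)
  } else {
    stopifnot(is.list(input), length(input) == 2)
    s1 <- input[[1]]$mu_f
    s2 <- input[[2]]$mu_f
    s1_out <- s2_out <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      s1 <- gibbs_step_parallel(s2, input[[1]], lambda_s)
      s2 <- gibbs_step_parallel(s1, input[[2]], lambda_s)
      s1_out[t] <- s1
      s2_out[t] <- s2
    }
    df <- tibble::tibble(step = seq_len(n_steps), s1 = s1_out, s2 = s2_out)
  }
  new_sample_chain(df, burn_in,
                   meta = list(model = model, lambda_s = lambda_s,
                               seed = seed))
}

chain_latents <- function(chain) {
  setdiff(names(chain), c("step", "time_ms", "n_spikes", "skipped"))
}

#' Moment summary of a sample chain
#'
#' Circular-aware first two moments of the post-burn-in samples: circular
#' means, and the covariance of minimal-arc deviations from the mean
#' (`n - 1` denominator).
#'
#' @param chain A `sample_chain`.
#' @param burn_in Override for the stored burn-in.
#' @return A `sampling_dist` object with `mean`, `cov`, `n_samples`;
#'   `degenerate` flags a zero-covariance chain.
#' @export
fit_distribution <- function(chain, burn_in = NULL) {
  burn_in <- burn_in %||% attr(chain, "burn_in") %||% 0L
  lat <- chain_latents(chain)
  x <- as.matrix(chain[chain$step > burn_in, lat, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 post-burn-in samples")
  m <- circ_moments(x)
  structure(list(mean = m$mean, cov = m$cov, n_samples = m$n,
                 degenerate = all(m$cov == 0)),
            class = "sampling_dist")
}

#' @export
print.sampling_dist <- function(x, ...) {
  cat(sprintf("<sampling_dist> %d samples%s\n", x$n_samples,
              if (x$degenerate) " [degenerate]" else ""))
  cat("mean:", paste(sprintf("%.3f", x$mean), collapse = ", "), "deg\n")
  cat("covariance (deg^2):\n")
  print(signif(x$cov, 4))
  invisible(x)
}

#' @export
tidy.sampling_dist <- function(x, ...) {
  tibble::tibble(latent = names(x$mean) %||% paste0("latent_", seq_along(x$mean)),
                 mean = as.numeric(x$mean), sd = sqrt(diag(x$cov)))
}

#' @export
glance.sampling_dist <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples,
                 generalized_var = det(as.matrix(x$cov)),
                 degenerate = x$degenerate)
}

#' Write / read a sample chain as CSV with a JSON sidecar
#'
#' Chains serialise to CSV (step plus one column per latent); seed,
#' burn-in and model parameters go to `<path>.json`.
#'
#' @param chain A `sample_chain`.
#' @param path CSV path.
#' @return `path`, invisibly (`write_chain`); a `sample_chain`
#'   (`read_chain`).
#' @export
write_chain <- function(chain, path) {
  readr::write_csv(tibble::as_tibble(chain), path)
  meta <- c(attr(chain, "meta"),
            list(burn_in = attr(chain, "burn_in"),
                 dt_sample = attr(chain, "dt_sample")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_sample_chain(df, burn_in = meta$burn_in %||% 0L,
                   dt_sample = meta$dt_sample %||% 1,
                   meta = meta[setdiff(names(meta), c("burn_in", "dt_sample"))])
}
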