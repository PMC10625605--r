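#' Define a reproducible experiment
#'
#' An experiment spec bundles a name, a model label, world and network
#' parameters, scan grids and a seed; a run is fully determined by
#' `(spec, seed)` and the spec round-trips losslessly through YAML.
#'
#' @param name Experiment name; one of `"weight_scan"`,
#'   `"feedforward_precision"`, `"lfi_ratio"`, `"coupled_gibbs"`, or a
#'   custom label dispatched by `model`.
#' @param model `"eonly"`, `"ei"`, `"coupled"`, or `"gibbs"`.
#' @param world Named list of generative parameters (`lambda_s`, `u_f`,
#'   `n_e`, `a_deg`, `l_deg`).
#' @param network Named list of [network_config()] overrides.
#' @param grids Named list of scan grids (e.g. `w_grid`, `u_f_grid`).
#' @param n_steps Simulation steps or chain length.
#' @param seed Integer seed.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(name, model = c("eonly", "ei", "coupled",
                                            "gibbs"),
                            world = list(lambda_s = 0.02, u_f = 2,
                                         n_e = 180, a_deg = 40,
                                         l_deg = 360),
                            network = list(), grids = list(),
                            n_steps = 2e4, seed = 1, output_dir = NULL) {
  model <- match.arg(model)
  structure(list(name = name, model = model, world = world,
                 network = network, grids = grids, n_steps = n_steps,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_spec")
}

spec_world <- function(spec) {
  w <- spec$world
  tun <- tuning_model(w$n_e %||% 180, w$a_deg %||% 40, w$l_deg %||% 360)
  hierarchical_world(w$lambda_s %||% 0.02, w$u_f %||% 2, tun)
}

#' Read / write an experiment spec as YAML
#'
#' @param spec An [experiment_spec()].
#' @param path YAML file path.
#' @return The path (write) or an `experiment_spec` (read).
#' @export
write_experiment_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_experiment_spec
#' @export
read_experiment_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(experiment_spec, x)
}

#' Read / write a network config as YAML
#'
#' @param config A [network_config()].
#' @param path YAML file path.
#' @return The path (write) or a `network_config` (read).
#' @export
write_network_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  do.call(network_config, yaml::read_yaml(path))
}

emit <- function(tbl, spec, file) {
  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tbl, file.path(spec$output_dir, file))
  }
  tbl
}

#' Run an experiment
#'
#' Deterministic given the spec's seed. Known experiment names:
#' `"weight_scan"` (KL against the analytic posterior over a recurrent
#' weight grid), `"feedforward_precision"` (sampling precision of the
#' uncoupled network against decoded likelihood precision across input
#' rates), `"lfi_ratio"` (linear Fisher information of the spiking stage
#' relative to its feedforward input), `"coupled_gibbs"` (coupled-model
#' Gibbs chain compared with the analytic bivariate posterior). Tables
#' are returned and, when `output_dir` is set, written as CSV with a JSON
#' provenance sidecar (spec, seed, package version).
#'
#' @param spec An [experiment_spec()].
#' @return A list with `result` (tibble), `spec`, and auxiliary objects
#'   per experiment.
#' @export
run_experiment <- function(spec) {
  set.seed(spec$seed)
  world <- spec_world(spec)
  out <- switch(
    spec$name,
    weight_scan = {
      grid <- spec$grids$w_grid %||% seq(0, 0.6, by = 0.05)
      scan <- weight_scan(world, grid, n_steps = spec$n_steps,
                          seed = spec$seed)
      list(result = emit(tibble::as_tibble(scan), spec, "weight_scan.csv"),
           glance = glance(scan), scan = scan)
    },
    feedforward_precision = {
      rates <- spec$grids$u_f_grid %||% c(0.5, 1, 2, 4, 8)
      rows <- purrr::map(seq_along(rates), function(i) {
        w2 <- hierarchical_world(0, rates[i], world$tuning)
        input <- sample_feedforward(w2, 0)
        tr <- simulate_e_only(input, 0, spec$n_steps,
                              seed = spec$seed + i)
        ch <- chain_from_trace(tr)
        q <- fit_distribution(ch)
        tibble::tibble(u_f = rates[i], lambda_f = input$lambda_f,
                       sampling_precision = 1 / q$cov[1, 1])
      })
      list(result = emit(dplyr::bind_rows(rows), spec,
                         "feedforward_precision.csv"))
    },
    lfi_ratio = {
      ds <- spec$grids$ds %||% 4
      n_trials <- spec$grids$n_trials %||% 2000
      res <- lfi_halving(world, ds = ds, n_trials = n_trials,
                         seed = spec$seed)
      list(result = emit(res, spec, "lfi_ratio.csv"))
    },
    coupled_gibbs = {
      pw <- parallel_world(world$lambda_s, world$u_f, world$tuning)
      inputs <- list(sample_feedforward(pw, -10), sample_feedforward(pw, 10))
      ch <- run_chain("parallel", inputs, pw$lambda_s,
                      n_steps = spec$n_steps, seed = spec$seed)
      cmp <- compare_to_posterior(ch, inputs)
      post <- posterior_parallel(inputs[[1]], inputs[[2]], pw$lambda_s)
      q <- fit_distribution(ch)
      list(result = emit(tibble::tibble(
        latent = c("s1", "s2"), sampling_mean = as.numeric(q$mean),
        predicted_mean = as.numeric(cmp$predicted_mean),
        posterior_mean = as.numeric(post$mu_p)), spec, "coupled_gibbs.csv"),
        compare = cmp, chain = ch, posterior = post)
    },
    stop(sprintf("unknown experiment name '%s'", spec$name)))
  if (!is.null(spec$output_dir)) {
    jsonlite::write_json(
      list(spec = unclass(spec),
           package_version = as.character(utils::packageVersion("neurosampler")),
           r_version = R.version.string),
      file.path(spec$output_dir, paste0(spec$name, "_provenance.json")),
      auto_unbox = TRUE, null = "null")
  }
  c(out, list(spec = spec))
}

#' Linear Fisher information halving at the spike-generation stage
#'
#' Draws feedforward Poisson inputs at `s = -ds/2` and `s = +ds/2`, passes
#' each through one independent Poisson spike-generation stage (the
#' uncoupled network, `w_E = 0`), and reports the bias-corrected LFI of
#' input and response and their ratio. One noisy Poisson stage on top of
#' a Poisson input doubles the effective noise, so the ratio approaches
#' one half.
#'
#' @param world A [hierarchical_world()]; only the tuning and `u_f` are
#'   used.
#' @param ds Stimulus separation (degrees).
#' @param n_trials Trials per stimulus.
#' @param seed Integer seed.
#' @return One-row tibble: `lfi_input`, `lfi_response`, `ratio`,
#'   `n_trials`.
#' @export
lfi_halving <- function(world, ds = 4, n_trials = 2000, seed = 1) {
  set.seed(seed)
  tun <- world$tuning
  rate1 <- world$u_f * exp(log_tuning(tun, -ds / 2))
  rate2 <- world$u_f * exp(log_tuning(tun, ds / 2))
  u1 <- t(draw_spike_counts(rate1, n_trials))
  u2 <- t(draw_spike_counts(rate2, n_trials))
  # spike generation: r ~ Poisson(u^f), one stage past the input
  r1 <- matrix(stats::rpois(length(u1), u1), nrow = n_trials)
  r2 <- matrix(stats::rpois(length(u2), u2), nrow = n_trials)
  lfi_in <- linear_fisher_information(u1, u2, ds)
  lfi_out <- linear_fisher_information(r1, r2, ds)
  tibble::tibble(lfi_input = lfi_in$lfi, lfi_response = lfi_out$lfi,
                 ratio = lfi_out$lfi / lfi_in$lfi, n_trials = n_trials)
}

#' Write small seeded fixtures for tests and demos
#'
#' Writes two feedforward inputs with likelihood means near -10 and +10
#' degrees (the standard two-network test configuration), one input drawn
#' under a flat prior (`lambda_s = 0`), and a short reference Gibbs
#' chain, all as CSV with JSON sidecars, plus a checksum manifest.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Tibble of written files and their MD5 checksums.
#' @export
make_fixtures <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  tun <- tuning_model(36, 40)
  pw <- parallel_world(0.02, 5, tun)
  in1 <- sample_feedforward(pw, -10)
  in2 <- sample_feedforward(pw, 10)
  hw0 <- hierarchical_world(0, 5, tun)
  in0 <- sample_feedforward(hw0, 0)
  write_ff_input(in1, file.path(dir, "input_m10.csv"), seed = seed)
  write_ff_input(in2, file.path(dir, "input_p10.csv"), seed = seed)
  write_ff_input(in0, file.path(dir, "input_flat_prior.csv"), seed = seed)
  ch <- run_chain("parallel", list(in1, in2), pw$lambda_s, n_steps = 500,
                  seed = seed)
  write_chain(ch, file.path(dir, "reference_chain.csv"))
  files <- list.files(dir, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Write / read a feedforward input as CSV + JSON sidecar
#'
#' CSV columns `neuron_index`, `theta_deg`, `count`; the sidecar records
#' `mu_f`, `lambda_f`, `n_f`, the tuning parameters and the seed.
#'
#' @param input An `ff_input`.
#' @param path CSV path.
#' @param seed Seed recorded in the sidecar.
#' @return The path (write) or an `ff_input` (read).
#' @export
write_ff_input <- function(input, path, seed = NULL) {
  readr::write_csv(as_tibble(input), path)
  jsonlite::write_json(list(mu_f = input$mu_f, lambda_f = input$lambda_f,
                            n_f = input$n_f, a_deg = input$a,
                            l_deg = input$l, seed = seed),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_ff_input
#' @export
read_ff_input <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tun <- tuning_model(nrow(df), meta$a_deg, meta$l_deg)
  new_ff_input(df$count, tun)
}
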