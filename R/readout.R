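#' Population-vector decoder
#'
#' Wrap-safe activity-weighted mean of a non-negative mass vector (spike
#' counts or rates) over the preferred stimuli: the circular resultant
#' `sum_j m_j exp(i theta_j 2 pi / L)` locates the activity bump, and the
#' linear mean of minimal-arc deviations about it reproduces the
#' activity-weighted mean `sum_j m_j theta_j / sum_j m_j` exactly away
#' from the wrap point while staying well defined across the boundary
#' (equal masses at 179 and -179 decode to 180, not 0).
#'
#' @param mass Non-negative numeric vector, one entry per neuron.
#' @param tuning A [tuning_model()].
#' @return A one-row tibble with `value` (degrees) and `weight` (total
#'   mass used).
#' @export
population_vector <- function(mass, tuning) {
  stopifnot(length(mass) == tuning$n_e, all(mass >= 0))
  tot <- sum(mass)
  if (tot <= 0) stop("empty window: zero total mass")
  tibble::tibble(value = popvec_mean(tuning$theta, mass, tuning$l),
                 weight = tot)
}

#' Decode the stimulus-parameter sample carried by a recurrent input
#'
#' The recurrent input's position on the ring is the stimulus-parameter
#' sample `z`, and its summed magnitude reads out the prior precision it
#' encodes: `Lambda_s = a^-2 sum_j u^r_j`. Entries may be negative (the
#' recurrent noise is signed); only the total must be positive.
#'
#' @param u_r Recurrent-input vector.
#' @param tuning A [tuning_model()].
#' @return List with `z` (degrees) and `lambda_s_readout` (deg^-2).
#' @export
decode_recurrent <- function(u_r, tuning) {
  stopifnot(length(u_r) == tuning$n_e)
  tot <- sum(u_r)
  if (tot <= 0) stop("nonpositive total recurrent input")
  list(z = popvec_mean(tuning$theta, u_r, tuning$l),
       lambda_s_readout = tot / tuning$a^2)
}

#' Extract a sample chain from a simulation trace
#'
#' Decodes latent samples from a `sim_trace` in non-overlapping windows.
#' For the excitatory-only theory network the native cadence is one
#' sample per step (`window = 1`); larger windows require the trace to
#' have been run with `keep_arrays = TRUE` and re-decode aggregated spike
#' counts. E-I traces are decoded at their native window in the
#' simulator; this function converts them to a `sample_chain`. Windows
#' with no spikes (or nonpositive recurrent input for the `z` chain) are
#' skipped and counted.
#'
#' @param trace A `sim_trace`.
#' @param window Window length in native steps (E-only traces) — the
#'   default 1 emits one sample per step.
#' @param tuning Optional [tuning_model()] for re-decoding.
#' @return A `sample_chain` with columns `step`, `s` and (when the trace
#'   carries a recurrent-input decode) `z`; attribute `skipped` counts
#'   dropped windows.
#' @export
chain_from_trace <- function(trace, window = 1L, tuning = NULL) {
  if (trace$kind %in% c("ei", "coupled")) {
    w <- trace$samples
    if (trace$kind == "coupled") {
      df <- tibble::tibble(step = w$window, s1 = w$s1_hat, s2 = w$s2_hat)
    } else {
      df <- tibble::tibble(step = w$window, s = w$s_hat, z = w$z_hat)
      if (all(is.na(df$z))) df$z <- NULL
    }
    keep <- stats::complete.cases(df[setdiff(names(df), "z")])
    skipped <- sum(!keep)
    if (!any(keep)) stop("all windows empty")
    ch <- new_sample_chain(df[keep, ], burn_in = min(10L, sum(keep) - 1L),
                           dt_sample = trace$params$window_ms,
                           meta = list(kind = trace$kind))
    attr(ch, "skipped") <- skipped
    return(ch)
  }

  # e_only trace
  p <- trace$params
  if (window == 1L) {
    df <- tibble::tibble(step = trace$samples$step, s = trace$samples$s_hat,
                         z = trace$samples$z_hat)
    if (all(is.na(df$z))) df$z <- NULL
  } else {
    if (is.null(trace$r)) {
      stop("window > 1 requires a trace run with keep_arrays = TRUE")
    }
    tuning <- tuning %||% tuning_model(length(p$theta), p$a, p$l)
    n_win <- floor(ncol(trace$r) / window)
    grp <- rep(seq_len(n_win), each = window)
    idx <- seq_len(n_win * window)
    rw <- t(rowsum(t(trace$r[, idx, drop = FALSE]), grp))
    uw <- t(rowsum(t(trace$u_r[, idx, drop = FALSE]), grp))
    s <- vapply(seq_len(n_win), function(i) {
      tot <- sum(rw[, i])
      if (tot <= 0) NA_real_ else popvec_mean(tuning$theta, rw[, i], tuning$l)
    }, numeric(1))
    z <- vapply(seq_len(n_win), function(i) {
      tot <- sum(uw[, i])
      if (tot <= 0) NA_real_ else popvec_mean(tuning$theta, uw[, i], tuning$l)
    }, numeric(1))
    df <- tibble::tibble(step = seq_len(n_win), s = s, z = z)
    if (all(is.na(df$z))) df$z <- NULL
  }
  keep <- !is.na(df$s)
  skipped <- sum(!keep)
  if (!any(keep)) stop("all windows empty")
  ch <- new_sample_chain(df[keep, ],
                         burn_in = max(100L, ceiling(sum(keep) / 10)),
                         meta = list(kind = "e_only", w_e = p$w_e,
                                     seed = p$seed))
  attr(ch, "skipped") <- skipped
  ch
}
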