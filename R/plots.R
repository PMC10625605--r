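#' Plot a sample chain
#'
#' Joint scatter of the two latents (with the alternating Gibbs
#' trajectory for the first `n_path` post-burn-in samples) or, for a
#' one-latent chain, the sample trace over steps.
#'
#' @param object A `sample_chain`.
#' @param n_path Number of consecutive samples to connect.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_chain <- function(object, n_path = 100, ...) {
  lat <- chain_latents(object)
  burn <- attr(object, "burn_in") %||% 0L
  df <- object[object$step > burn, , drop = FALSE]
  if (length(lat) >= 2) {
    path <- utils::head(df, n_path)
    ggplot2::ggplot(df, ggplot2::aes(.data[[lat[1]]], .data[[lat[2]]])) +
      ggplot2::geom_point(alpha = 0.15, size = 0.6) +
      ggplot2::geom_path(data = path, colour = "firebrick",
                         linewidth = 0.3) +
      ggplot2::labs(x = paste(lat[1], "(deg)"), y = paste(lat[2], "(deg)"),
                    title = "Latent samples") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$step, .data[[lat[1]]])) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "step", y = paste(lat[1], "(deg)")) +
      ggplot2::theme_minimal()
  }
}

#' Plot a recurrent weight scan
#'
#' KL divergence to the analytic posterior against the recurrent weight,
#' with the theoretical optimum marked.
#'
#' @param object A `weight_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weight_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$w_e, .data$kl_bits)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "w_star"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(w[E]), y = "KL divergence (bits)",
                  title = "Sampling distribution vs posterior") +
    ggplot2::theme_minimal()
}

#' Plot a feedforward input
#'
#' Spike counts against preferred stimulus, with the decoded likelihood
#' mean marked.
#'
#' @param object An `ff_input`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ff_input <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$theta_deg, .data$count)) +
    ggplot2::geom_col(width = diff(df$theta_deg[1:2]) * 0.8,
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$mu_f, linetype = "dashed") +
    ggplot2::labs(x = "preferred stimulus (deg)", y = "spike count") +
    ggplot2::theme_minimal()
}

#' Plot a simulation trace
#'
#' Decoded sample position over time for a network trace.
#'
#' @param object A `sim_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_trace <- function(object, ...) {
  s <- object$samples
  xcol <- if ("time_ms" %in% names(s)) "time_ms" else "step"
  ycol <- if ("s_hat" %in% names(s)) "s_hat" else "s1_hat"
  ggplot2::ggplot(s, ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::labs(x = if (xcol == "time_ms") "time (ms)" else "step",
                  y = "decoded position (deg)") +
    ggplot2::theme_minimal()
}
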