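#' Broom-style accessors and plots
#'
#' `tidy()` returns per-epoch (or per-iteration) optimization traces as
#' tibbles; `glance()` returns one-row model summaries; `autoplot()` draws the
#' standard diagnostic for each object. The decoded-covariate tibble from
#' [decode_covariate()] is already tidy.
#'
#' @param x a fitted object
#' @param ... unused
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.clusterless_fit <- function(x, ...) x$trace

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.clusterless_fit <- function(x, ...) {
  tibble::tibble(
    d_x = x$model$d_x,
    d_z = x$model$jmi$d_z,
    lambda0 = exp(x$model$jmi$log_lambda0),
    epochs = nrow(x$trace),
    elbo_init = x$elbo_init,
    elbo_best = if (nrow(x$trace)) max(x$trace$val) else x$elbo_init
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.gmm_intensity <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$L_c),
    lambda = x$lambda,
    mu_x = lapply(seq_len(x$L_c), function(l) x$mu_x[l, ]),
    mu_k = lapply(seq_len(x$L_c), function(l) x$mu_k[l, ])
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.gmm_intensity <- function(x, ...) {
  tibble::tibble(components = x$L_c, d_x = x$d_x, d_k = x$d_k,
                 total_rate_scale = sum(x$lambda))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.laplace_result <- function(x, ...) {
  R <- nrow(x$mean); d <- ncol(x$mean)
  tibble::tibble(bin = rep(seq_len(R), d),
                 dim = rep(seq_len(d), each = R),
                 estimate = as.vector(x$mean))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.laplace_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 objective = x$objective_trace[length(x$objective_trace)])
}

#' @rdname tidiers
#' @param object a `clusterless_fit`
#' @exportS3Method ggplot2::autoplot
autoplot.clusterless_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("train", "val"),
                            names_to = "split", values_to = "elbo")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$elbo,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "ELBO", colour = NULL,
                  title = "Training and validation evidence lower bound") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @exportS3Method ggplot2::autoplot
autoplot.marked_events <- function(object, ...) {
  amp <- apply(object$marks, 1L, function(m) max(abs(m)))
  df <- tibble::tibble(time = object$times, amplitude = amp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::labs(x = "time (s)", y = "peak |mark|",
                  title = "Unsorted spikes") +
    ggplot2::theme_minimal()
}

#' Plot decoded against true covariates
#'
#' @param decoded tibble from [decode_clusterless()] (columns bin, dim,
#'   estimate, variance)
#' @param y_true matching R x D_y matrix of true covariate values
#' @param dt_bin bin width in seconds (x axis scaling)
#' @return a ggplot
#' @export
plot_decoding <- function(decoded, y_true, dt_bin = 1) {
  y_true <- as.matrix(y_true)
  truth <- tibble::tibble(bin = rep(sort(unique(decoded$bin)), ncol(y_true)),
                          dim = rep(seq_len(ncol(y_true)), each = nrow(y_true)),
                          truth = as.vector(y_true))
  df <- dplyr::left_join(decoded, truth, by = c("bin", "dim"))
  df$t <- df$bin * dt_bin
  df$lo <- df$estimate - 2 * sqrt(df$variance)
  df$hi <- df$estimate + 2 * sqrt(df$variance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$truth), colour = "black",
                       linetype = "dashed") +
    ggplot2::facet_wrap(~dim, scales = "free_y", ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "covariate",
                  title = "Decoded covariate (solid, 2-sigma band) vs truth (dashed)") +
    ggplot2::theme_minimal()
}
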