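#' Fit the full clusterless state-space model to a dataset
#'
#' High-level pipeline: merges probes into one event stream, bins events and
#' covariates, standardizes the covariate (the scaling is stored and undone at
#' decode time), builds the intensity VAE, state-space model and structured
#' variational family, and trains everything jointly by maximizing the ELBO.
#'
#' @param sequences a [marked_events()] or list of them (probes are merged;
#'   mark dimensions must agree)
#' @param cov a [covariate_series()]
#' @param dt_bin bin width, seconds
#' @param split list with integer ranges `train = c(lo, hi)` and
#'   `validation = c(lo, hi)` in bins (as written by [make_trials()])
#' @param d_x hidden state dimension (default 10)
#' @param d_z intensity-VAE latent dimension
#' @param hidden hidden widths for all networks
#' @param bound_cfg a [bound_config()]
#' @param epochs,lr,segment_len,patience,n_mc training controls (see
#'   [fit_ssm()])
#' @param seed seed
#' @param verbose print progress
#' @return object of class `clusterless_fit`
#' @export
fit_clusterless <- function(sequences, cov, dt_bin, split,
                            d_x = 10L, d_z = 2L, hidden = c(32L, 32L),
                            bound_cfg = bound_config(L = 5L),
                            epochs = 15L, lr = 3e-3, segment_len = 200L,
                            patience = 5L, n_mc = 1L, seed = 1L,
                            verbose = FALSE) {
  seq1 <- merge_probes(sequences)
  y_mean <- colMeans(cov$values)
  y_sd <- apply(cov$values, 2L, stats::sd)
  y_sd[y_sd < 1e-8] <- 1
  cov_std <- covariate_series(cov$dt, scale(cov$values, center = y_mean,
                                            scale = y_sd))
  binned <- bin_events(seq1, cov_std, dt_bin)
  tr <- bin_subset(binned, split$train[1]:split$train[2])
  va <- bin_subset(binned, split$validation[1]:split$validation[2])
  d_y <- ncol(cov$values)
  d_k <- ncol(seq1$marks)
  n_train <- sum(tr$counts)
  lambda0_init <- max(n_train / (tr$R * dt_bin), 1e-3)
  jmi <- jmi_vae(d_x, d_k, d_z, hidden, lambda0_init = lambda0_init,
                 bound_cfg = bound_cfg, seed = seed)
  model <- state_space_model(d_x, d_y, jmi, hidden, seed = seed)
  q <- structured_var_family(d_x, d_y, d_k, hidden, seed = seed + 1L)
  elbo_init <- ssm_elbo(model, q, va, n_mc = max(n_mc, 2L), seed = seed + 2L)
  fit <- fit_ssm(model, q, tr, va, epochs = epochs, lr = lr,
                 patience = patience, segment_len = segment_len, n_mc = n_mc,
                 seed = seed + 3L, verbose = verbose)
  structure(list(model = fit$model, q = fit$q, trace = fit$trace,
                 elbo_init = elbo_init,
                 binned = binned, split = split,
                 y_mean = y_mean, y_sd = y_sd, dt_bin = dt_bin,
                 seed = seed),
            class = "clusterless_fit")
}

merge_probes <- function(sequences) {
  if (inherits(sequences, "marked_events")) return(sequences)
  stopifnot(length(sequences) >= 1L)
  if (length(sequences) == 1L) return(sequences[[1]])
  times <- unlist(lapply(sequences, function(s) s$times))
  marks <- do.call(rbind, lapply(sequences, function(s) s$marks))
  marked_events(times, marks, duration_T = sequences[[1]]$duration_T,
                probe_id = "merged")
}

#' @export
print.clusterless_fit <- function(x, ...) {
  cat(sprintf("<clusterless_fit: d_x = %d, %d training epochs, val ELBO %.2f -> %.2f>\n",
              x$model$d_x, nrow(x$trace), x$elbo_init,
              if (nrow(x$trace)) max(x$trace$val) else x$elbo_init))
  invisible(x)
}

#' Decode the covariate from spikes on a bin range
#'
#' Runs the concavified Newton MAP on the requested bins using spikes only,
#' then pushes Laplace posterior samples through the covariate observation
#' model and undoes the training standardization.
#'
#' @param fit a [fit_clusterless()] result
#' @param bins integer range of bins (e.g. the test split)
#' @param L_dec frozen latent samples per decoding term
#' @param K_max,tol Newton controls
#' @param S posterior samples for the covariate push-through
#' @param seed seed
#' @param init `"spike_experts"` warm-starts the Newton ascent at the mean of
#'   the variational spike-expert posterior (chain + per-spike experts + base
#'   expert; the covariate encoder is *not* used, so decoding still sees
#'   spikes only); `"prior"` starts from the prior mean path
#' @return list: `y_hat` (R x D_y, original units), `decoded` (tibble),
#'   `laplace` ([newton_map()] result)
#' @export
decode_clusterless <- function(fit, bins, L_dec = 16L, K_max = 15L, tol = 1e-4,
                               S = 100L, seed = 1L,
                               init = c("spike_experts", "prior")) {
  init <- match.arg(init)
  data <- bin_subset(fit$binned, bins)
  x0 <- NULL
  if (init == "spike_experts") {
    qk <- fit$q
    qk$enc_y <- NULL
    x0 <- build_structured_posterior(qk, data)$mean
  }
  lap <- newton_map(fit$model, data, init = x0, K_max = K_max, tol = tol,
                    L_dec = L_dec, seed = seed)
  dec <- decode_covariate(fit$model, lap, S = S, seed = seed + 1L)
  Dy <- fit$model$d_y
  R <- data$R
  est <- matrix(dec$estimate, R, Dy)
  y_hat <- sweep(sweep(est, 2L, fit$y_sd, "*"), 2L, fit$y_mean, "+")
  vu <- sweep(matrix(dec$variance, R, Dy), 2L, fit$y_sd^2, "*")
  decoded <- tibble::tibble(bin = rep(bins, Dy),
                            dim = rep(seq_len(Dy), each = R),
                            estimate = as.vector(y_hat),
                            variance = as.vector(vu))
  list(y_hat = y_hat, decoded = decoded, laplace = lap)
}

#' Evaluate a fitted model on a bin range
#'
#' Returns the test NLL bound (negative ELBO) and, if decoding output is
#' given, the decoding MSE in original covariate units.
#'
#' @param fit a [fit_clusterless()] result
#' @param bins integer bin range
#' @param y_hat optional decoded covariate (original units) for the MSE
#' @param n_mc,seed ELBO estimate controls
#' @return tibble with columns `metric`, `value`
#' @export
evaluate_clusterless <- function(fit, bins, y_hat = NULL, n_mc = 4L, seed = 1L) {
  data <- bin_subset(fit$binned, bins)
  nll <- ssm_predict_nll(fit$model, fit$q, data, n_mc = n_mc, seed = seed)
  out <- tibble::tibble(metric = "nll_bound", value = nll)
  if (!is.null(y_hat)) {
    y_true <- sweep(sweep(data$y, 2L, fit$y_sd, "*"), 2L, fit$y_mean, "+")
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "decode_mse", value = decode_mse(as.matrix(y_hat), y_true)))
  }
  out
}

#' True covariate on a bin range, in original units
#' @param fit a [fit_clusterless()] result
#' @param bins integer bin range
#' @export
true_covariate <- function(fit, bins) {
  data <- bin_subset(fit$binned, bins)
  sweep(sweep(data$y, 2L, fit$y_sd, "*"), 2L, fit$y_mean, "+")
}
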