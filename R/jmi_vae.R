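#' Joint mark intensity model based on a variational autoencoder
#'
#' Defines the clusterless intensity `lambda(x, kappa) = lambda0 * p(x, kappa)`
#' where `p(x, kappa) = integral p(x | z) p(kappa | z) p(z) dz` is the density
#' of a latent-variable generative model: a standard normal prior over a
#' low-dimensional latent `z`, and two Gaussian decoder networks making state
#' and mark conditionally independent given `z` (so the ground intensity
#' `lambda(x) = lambda0 * integral p(x | z) p(z) dz` is available from the
#' state decoder alone). Two encoder networks, `q(z | x, kappa)` for the
#' per-spike evidence and `q(z | x)` for the ground-intensity evidence, supply
#' the importance-weight proposals of the training bound; they are deliberately
#' separate networks (the marginalization constraint linking them is not
#' enforced).
#'
#' @param d_x,d_k,d_z state, mark and latent dimensions
#' @param hidden hidden-layer widths for all four networks
#' @param lambda0_init initial base intensity (stored as log lambda0)
#' @param bound_cfg a [bound_config()]
#' @param seed seed for deterministic parameter initialization
#' @return object of class `jmi_vae`
#' @export
jmi_vae <- function(d_x, d_k, d_z = 2L, hidden = c(64L, 64L), lambda0_init = 1,
                    bound_cfg = bound_config(), seed = 1L) {
  stopifnot(d_x >= 1L, d_k >= 1L, d_z >= 1L, lambda0_init > 0)
  structure(list(
    d_x = d_x, d_k = d_k, d_z = d_z,
    log_lambda0 = log(lambda0_init),
    decoder_x = gaussian_net(d_z, d_x, hidden, seed = seed * 4L + 1L),
    decoder_k = gaussian_net(d_z, d_k, hidden, seed = seed * 4L + 2L),
    encoder_xk = gaussian_net(d_x + d_k, d_z, hidden, seed = seed * 4L + 3L),
    encoder_x = gaussian_net(d_x, d_z, hidden, seed = seed * 4L + 4L),
    bound_cfg = bound_cfg
  ), class = "jmi_vae")
}

#' @export
print.jmi_vae <- function(x, ...) {
  cat(sprintf("<jmi_vae: d_x = %d, d_k = %d, d_z = %d, lambda0 = %.4g>\n",
              x$d_x, x$d_k, x$d_z, exp(x$log_lambda0)))
  invisible(x)
}

#' Log importance weights for the evidence terms
#'
#' Draws `L` latent samples per row of `X` from the proposal and returns the
#' n x L matrix of `log w = log p(x|z) [+ log p(k|z)] + log p(z) - log q(z|.)`.
#' With `proposal = "prior"` the prior is the proposal (so the q and p(z)
#' terms cancel); this is the plain Monte Carlo estimator kept as an oracle.
#' The base intensity `lambda0` is *not* included.
#'
#' @param model a [jmi_vae()]
#' @param X n x d_x states
#' @param K n x d_k marks, or NULL for the ground-intensity (state) weights
#' @param L samples per row
#' @param seed integer seed (ignored when `eps` given)
#' @param eps optional (n*L) x d_z standard normal noise, rows ordered with the
#'   L samples of row 1 first
#' @param proposal `"encoder"` or `"prior"`
#' @return n x L matrix of log weights
#' @export
jmi_log_w <- function(model, X, K = NULL, L, seed = 1L, eps = NULL,
                      proposal = c("encoder", "prior")) {
  proposal <- match.arg(proposal)
  X <- as_matrix_rows(X, model$d_x)
  n <- nrow(X)
  if (!is.null(K)) K <- as_matrix_rows(K, model$d_k)
  if (is.null(eps)) {
    rng <- local_rng(seed)
    eps <- matrix(rng$norm(n * L * model$d_z), n * L, model$d_z)
  }
  rep_idx <- rep(seq_len(n), each = L)
  if (proposal == "prior") {
    Z <- eps
    lq_minus_lpz <- 0
  } else {
    enc <- if (is.null(K)) model$encoder_x else model$encoder_xk
    inp <- if (is.null(K)) X else cbind(X, K)
    q <- gmap_eval(enc, inp)
    mu_rep <- q$mean[rep_idx, , drop = FALSE]
    if (identical(enc$prec_type, "full")) {
      Z <- gauss_sample(mu_rep, q$prec, eps)
      lq <- gauss_logpdf(Z, mu_rep, q$prec)
    } else {
      prec_rep <- q$prec[rep_idx, , drop = FALSE]
      Z <- gauss_sample_diag(mu_rep, prec_rep, eps)
      lq <- gauss_logpdf_diag(Z, mu_rep, prec_rep)
    }
    lpz <- -0.5 * rowSums(Z^2) - 0.5 * model$d_z * log(2 * pi)
    lq_minus_lpz <- lq - lpz
  }
  eval_dec <- function(dec, target) {
    out <- gmap_eval(dec, Z)
    if (identical(dec$prec_type, "full")) gauss_logpdf(target, out$mean, out$prec)
    else gauss_logpdf_diag(target, out$mean, out$prec)
  }
  lw <- eval_dec(model$decoder_x, X[rep_idx, , drop = FALSE])
  if (!is.null(K))
    lw <- lw + eval_dec(model$decoder_k, K[rep_idx, , drop = FALSE])
  lw <- lw - lq_minus_lpz
  matrix(lw, n, L, byrow = TRUE)
}

#' Monte Carlo estimates of the joint and ground intensity
#'
#' `intensity_estimate` evaluates `lambda(x, kappa)` and
#' `ground_intensity_estimate` evaluates `lambda(x)` by importance sampling
#' (self-normalization is unnecessary: the weights are unbiased for the
#' evidence). Consistent as `S` grows; exact for decoders that ignore `z`.
#'
#' @inheritParams jmi_log_w
#' @param x state vector
#' @param k mark vector
#' @param S number of Monte Carlo samples
#' @return a positive scalar
#' @export
intensity_estimate <- function(model, x, k, S = 100L, seed = 1L,
                               proposal = c("encoder", "prior")) {
  if (!all(is.finite(x)) || !all(is.finite(k)))
    stop("non-finite inputs", call. = FALSE)
  lw <- jmi_log_w(model, matrix(x, 1L), matrix(k, 1L), L = S, seed = seed,
                  proposal = match.arg(proposal))
  exp(model$log_lambda0 + logmeanexp(drop(lw)))
}

#' @rdname intensity_estimate
#' @export
ground_intensity_estimate <- function(model, x, S = 100L, seed = 1L,
                                      proposal = c("encoder", "prior")) {
  if (!all(is.finite(x))) stop("non-finite inputs", call. = FALSE)
  lw <- jmi_log_w(model, matrix(x, 1L), NULL, L = S, seed = seed,
                  proposal = match.arg(proposal))
  exp(model$log_lambda0 + logmeanexp(drop(lw)))
}

#' Point-process bound for an observed-state dataset (numeric)
#'
#' Evaluates the training surrogate: per-spike Renyi terms minus per-grid-point
#' exponentiated chi terms, at given reparameterization noise.
#'
#' @param model a [jmi_vae()]
#' @param x_spikes n x d_x states at spike times
#' @param marks n x d_k marks
#' @param x_grid m x d_x states at grid times
#' @param dt grid spacing (the integral term is `sum_j lambda(x_j) dt`); pass
#'   `dt = 1` to absorb the bin width into lambda0
#' @param cfg bound configuration (defaults to the model's)
#' @param seed,eps_spk,eps_grid reparameterization noise
#' @return scalar lower bound on the (dt-weighted) log-likelihood
#' @export
jmi_pp_bound <- function(model, x_spikes, marks, x_grid, dt, cfg = NULL,
                         seed = 1L, eps_spk = NULL, eps_grid = NULL) {
  cfg <- cfg %||% model$bound_cfg
  n <- if (is.null(x_spikes)) 0L else nrow(as_matrix_rows(x_spikes, model$d_x))
  rng <- local_rng(seed)
  s <- 0
  if (n > 0L) {
    if (is.null(eps_spk))
      eps_spk <- matrix(rng$norm(n * cfg$L * model$d_z), n * cfg$L, model$d_z)
    lw <- jmi_log_w(model, x_spikes, marks, L = cfg$L, eps = eps_spk)
    lwl <- lw + model$log_lambda0
    s <- sum(apply(lwl, 1L, function(v) renyi_lower_bound(v, cfg$alpha)))
  }
  m <- nrow(as_matrix_rows(x_grid, model$d_x))
  if (is.null(eps_grid))
    eps_grid <- matrix(rng$norm(m * cfg$L * model$d_z), m * cfg$L, model$d_z)
  lwg <- jmi_log_w(model, x_grid, NULL, L = cfg$L, eps = eps_grid)
  chi <- vapply(seq_len(m), function(j)
    chi_state_value(lwg[j, ], cfg, model$log_lambda0 + log(dt)), numeric(1))
  s - sum(chi)
}

#' Negative log-likelihood bound
#'
#' The negative of [jmi_pp_bound()]; since the surrogate lower-bounds the
#' log-likelihood, this value *upper*-bounds the true NLL (the model is at a
#' disadvantage when compared against exact-likelihood baselines).
#'
#' @inheritParams jmi_pp_bound
#' @export
jmi_nll_bound <- function(model, x_spikes, marks, x_grid, dt, cfg = NULL,
                          seed = 1L) {
  -jmi_pp_bound(model, x_spikes, marks, x_grid, dt, cfg = cfg, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- tape objective ----

# Emit the spike-side Renyi sum on the tape. Returns the scalar node, or NULL
# when there are no spikes. `Xnode` is an n x d_x node (a constant for the
# observed-state fit; a sliced sample-path node inside the state-space ELBO, so
# gradients flow into the path). The doubly reparameterized gradient option
# runs a parallel forward with detached parameters.
jmi_spike_term_tp <- function(tp, pn, model, Xnode, marks, eps, cfg, lam_node) {
  n <- nrow(tpv(tp, Xnode))
  if (n == 0L) return(NULL)
  L <- cfg$L
  rep_idx <- rep(seq_len(n), each = L)
  Xr <- tp_slice_rows(tp, Xnode, rep_idx)
  Kr <- tp_const(tp, marks[rep_idx, , drop = FALSE])
  inp <- tp_cbind(tp, Xnode, tp_const(tp, marks))
  q <- gnet_forward_tp(tp, pn$encoder_xk, inp, model$encoder_xk)
  mu_rep <- tp_slice_rows(tp, q$mean, rep_idx)
  prec_rep <- tp_slice_rows(tp, q$prec, rep_idx)
  epsn <- tp_const(tp, eps)
  Z <- tp_add(tp, mu_rep, tp_div(tp, epsn, tp_sqrt(tp, prec_rep)))
  logw_of <- function(Znode, dec_pn, enc_mu, enc_prec) {
    dx <- gnet_forward_tp(tp, dec_pn$decoder_x, Znode, model$decoder_x)
    dk <- gnet_forward_tp(tp, dec_pn$decoder_k, Znode, model$decoder_k)
    lpx <- tp_gauss_diag_logpdf(tp, Xr, dx$mean, dx$prec)
    lpk <- tp_gauss_diag_logpdf(tp, Kr, dk$mean, dk$prec)
    lpz <- tp_addc(tp, tp_scale(tp, tp_rowsums(tp, tp_square(tp, Znode)), -0.5),
                   -0.5 * model$d_z * log(2 * pi))
    lq <- tp_gauss_diag_logpdf(tp, Znode, enc_mu, enc_prec)
    tp_sub(tp, tp_add(tp, tp_add(tp, lpx, lpk), lpz), lq)
  }
  if (cfg$use_dreg && cfg$alpha == 1) {
    # doubly reparameterized spike gradient (alpha = 1 / importance-weighted
    # case): decoder route uses plain weights with z detached; encoder route
    # uses squared normalized weights with the z path live but the encoder
    # density parameters detached.
    pn_detached <- lapply(pn, function(group) lapply(group, function(id) tp_detach(tp, id)))
    mu_d <- tp_detach(tp, mu_rep); prec_d <- tp_detach(tp, prec_rep)
    lw_dec <- logw_of(tp_detach(tp, Z), pn, mu_d, prec_d)
    lw_dec <- tp_adds(tp, lw_dec, lam_node)
    lw_enc <- logw_of(Z, pn_detached, mu_d, prec_d)
    lwmat <- matrix(tpv(tp, lw_dec), n, L, byrow = TRUE)
    wt <- exp(lwmat - apply(lwmat, 1L, max))
    wt <- wt / rowSums(wt)
    wt_flat <- as.vector(t(wt))
    t_dec <- tp_sum(tp, tp_mul(tp, tp_const(tp, wt_flat), lw_dec))
    t_enc <- tp_sum(tp, tp_mul(tp, tp_const(tp, wt_flat^2), lw_enc))
    # value correction so the node's *value* equals the plain bound
    plain <- sum(apply(lwmat, 1L, logmeanexp))
    surr <- tp_add(tp, t_dec, t_enc)
    tp_addc(tp, surr, plain - tpv(tp, surr))
  } else {
    lw <- logw_of(Z, pn, mu_rep, prec_rep)
    lw <- tp_adds(tp, lw, lam_node)
    lwm <- tp_reshape_rows(tp, lw, n, L)
    lse <- tp_logsumexp_rows(tp, tp_scale(tp, lwm, cfg$alpha))
    tp_sum(tp, tp_scale(tp, tp_addc(tp, lse, -log(L)), 1 / cfg$alpha))
  }
}

# Emit the chi (ground-intensity) sum on the tape: returns the scalar node for
# sum_j lambda0 * dt * power-mean_j, optionally jackknife-debiased. `Xnode` as
# in jmi_spike_term_tp.
jmi_state_term_tp <- function(tp, pn, model, Xnode, eps, cfg, lam_node, log_dt) {
  m <- nrow(tpv(tp, Xnode))
  L <- cfg$L
  rep_idx <- rep(seq_len(m), each = L)
  Xr <- tp_slice_rows(tp, Xnode, rep_idx)
  q <- gnet_forward_tp(tp, pn$encoder_x, Xnode, model$encoder_x)
  mu_rep <- tp_slice_rows(tp, q$mean, rep_idx)
  prec_rep <- tp_slice_rows(tp, q$prec, rep_idx)
  Z <- tp_add(tp, mu_rep, tp_div(tp, tp_const(tp, eps), tp_sqrt(tp, prec_rep)))
  dx <- gnet_forward_tp(tp, pn$decoder_x, Z, model$decoder_x)
  lpx <- tp_gauss_diag_logpdf(tp, Xr, dx$mean, dx$prec)
  lpz <- tp_addc(tp, tp_scale(tp, tp_rowsums(tp, tp_square(tp, Z)), -0.5),
                 -0.5 * model$d_z * log(2 * pi))
  lq <- tp_gauss_diag_logpdf(tp, Z, mu_rep, prec_rep)
  lw <- tp_sub(tp, tp_add(tp, lpx, lpz), lq)
  lw <- tp_addc(tp, tp_adds(tp, lw, lam_node), log_dt)
  lw <- tp_clampmax(tp, lw, cfg$chi_log_clamp)
  lwm <- tp_reshape_rows(tp, lw, m, L)
  beta <- cfg$beta
  if (cfg$use_jackknife && L >= 2L) {
    vals <- tpv(tp, lwm)
    cmax <- apply(beta * vals, 1L, max)
    E <- tp_exp(tp, tp_sub(tp, tp_scale(tp, lwm, beta),
                           tp_const(tp, matrix(cmax, m, L))))
    S <- tp_rowsums(tp, E)
    scale_j <- exp(cmax / beta) # exact identity in cmax, so constants are safe
    t_full <- tp_mul(tp, tp_const(tp, scale_j),
                     tp_powc(tp, tp_scale(tp, S, 1 / L), 1 / beta))
    Smat <- tp_matmul(tp, tp_ascol(tp, S), tp_const(tp, matrix(1, 1, L)))
    loo <- tp_powc(tp, tp_scale(tp, tp_sub(tp, Smat, E), 1 / (L - 1)), 1 / beta)
    loo_sum <- tp_mul(tp, tp_const(tp, scale_j), tp_rowsums(tp, loo))
    corr <- tp_sub(tp, tp_scale(tp, t_full, L), tp_scale(tp, loo_sum, (L - 1) / L))
    tp_sum(tp, corr)
  } else {
    lse <- tp_logsumexp_rows(tp, tp_scale(tp, lwm, beta))
    logpm <- tp_scale(tp, tp_addc(tp, lse, -log(L)), 1 / beta)
    tp_sum(tp, tp_exp(tp, tp_clampmax(tp, logpm, cfg$chi_log_clamp)))
  }
}

# column-vector view of a vector node
tp_ascol <- function(tp, a) {
  x <- tpv(tp, a)
  tp_emit(tp, matrix(x, length(x), 1L), a, function(g) list(drop(g)))
}

jmi_param_nodes <- function(tp, model) {
  list(decoder_x = lapply(model$decoder_x$params, function(p) tp_param(tp, p)),
       decoder_k = lapply(model$decoder_k$params, function(p) tp_param(tp, p)),
       encoder_xk = lapply(model$encoder_xk$params, function(p) tp_param(tp, p)),
       encoder_x = lapply(model$encoder_x$params, function(p) tp_param(tp, p)))
}

jmi_collect_params <- function(model) {
  c(params_flatten(list(decoder_x = model$decoder_x$params,
                        decoder_k = model$decoder_k$params,
                        encoder_xk = model$encoder_xk$params,
                        encoder_x = model$encoder_x$params)),
    list(log_lambda0 = model$log_lambda0))
}

jmi_set_params <- function(model, flat) {
  for (key in names(flat)) {
    if (key == "log_lambda0") { model$log_lambda0 <- flat[[key]]; next }
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    model[[path[1]]]$params[[path[2]]] <- flat[[key]]
  }
  model
}

#' Fit the intensity model with observed states
#'
#' Maximizes the Monte Carlo point-process bound over the decoder, encoder and
#' base-intensity parameters with Adam (full batch, fresh reparameterization
#' noise per epoch from one seeded stream). A contiguous tail of the data is
#' held out for validation; the returned model carries the best-validation
#' parameters (early stopping with the given patience). The validation bound
#' uses noise that is fixed across epochs so its trace is comparable.
#'
#' @inheritParams jmi_pp_bound
#' @param epochs maximum epochs (0 returns the model unchanged)
#' @param lr Adam learning rate
#' @param val_frac fraction of spikes/grid points (contiguous tail) held out
#' @param patience epochs without validation improvement before stopping
#' @param seed seed for noise and reproducibility
#' @param verbose print per-epoch objective values
#' @return `list(model, trace)`; `trace` is a tibble (epoch, train, val)
#' @export
fit_jmi_observed <- function(model, x_spikes, marks, x_grid, dt,
                             epochs = 100L, lr = 1e-2, val_frac = 0.1,
                             patience = 10L, seed = 1L, verbose = FALSE) {
  cfg <- model$bound_cfg
  x_spikes <- as_matrix_rows(x_spikes, model$d_x)
  marks <- as_matrix_rows(marks, model$d_k)
  x_grid <- as_matrix_rows(x_grid, model$d_x)
  n <- nrow(x_spikes); m <- nrow(x_grid)
  n_val_s <- max(1L, floor(val_frac * n)); n_val_g <- max(1L, floor(val_frac * m))
  tr_s <- seq_len(n - n_val_s); va_s <- setdiff(seq_len(n), tr_s)
  tr_g <- seq_len(m - n_val_g); va_g <- setdiff(seq_len(m), tr_g)
  if (epochs == 0L)
    return(list(model = model,
                trace = tibble::tibble(epoch = integer(), train = numeric(),
                                       val = numeric())))
  rng <- local_rng(seed)
  eps_val_s <- matrix(rng$norm(length(va_s) * cfg$L * model$d_z),
                      length(va_s) * cfg$L, model$d_z)
  eps_val_g <- matrix(rng$norm(length(va_g) * cfg$L * model$d_z),
                      length(va_g) * cfg$L, model$d_z)
  flat <- jmi_collect_params(model)
  opt <- adam_new(flat, lr = lr)
  best <- list(val = -Inf, flat = flat)
  stall <- 0L
  rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    eps_s <- matrix(rng$norm(length(tr_s) * cfg$L * model$d_z),
                    length(tr_s) * cfg$L, model$d_z)
    eps_g <- matrix(rng$norm(length(tr_g) * cfg$L * model$d_z),
                    length(tr_g) * cfg$L, model$d_z)
    tp <- tape_new()
    pn <- jmi_param_nodes(tp, model)
    lam <- tp_param(tp, model$log_lambda0)
    spike <- jmi_spike_term_tp(tp, pn, model,
                               tp_const(tp, x_spikes[tr_s, , drop = FALSE]),
                               marks[tr_s, , drop = FALSE], eps_s, cfg, lam)
    state <- jmi_state_term_tp(tp, pn, model,
                               tp_const(tp, x_grid[tr_g, , drop = FALSE]),
                               eps_g, cfg, lam, log(dt))
    obj <- if (is.null(spike)) tp_neg(tp, state) else tp_sub(tp, spike, state)
    val_obj <- tpv(tp, obj)
    if (!is.finite(val_obj))
      stop(sprintf("objective diverged at epoch %d (lambda0 = %.3g)",
                   ep, exp(model$log_lambda0)), call. = FALSE)
    grads_by_node <- tp_backward(tp, obj)
    grads <- list(log_lambda0 = grads_by_node[[lam]] %||% 0)
    for (grp in names(pn)) for (nm in names(pn[[grp]])) {
      grads[[paste(grp, nm, sep = ".")]] <-
        grads_by_node[[pn[[grp]][[nm]]]] %||% (flat[[paste(grp, nm, sep = ".")]] * 0)
    }
    stepped <- adam_step(opt, flat, grads, maximize = TRUE)
    flat <- stepped$flat; opt <- stepped$state
    model <- jmi_set_params(model, flat)
    val <- jmi_pp_bound(model, x_spikes[va_s, , drop = FALSE],
                        marks[va_s, , drop = FALSE],
                        x_grid[va_g, , drop = FALSE], dt,
                        eps_spk = eps_val_s, eps_grid = eps_val_g)
    rows[[ep]] <- tibble::tibble(epoch = ep, train = val_obj, val = val)
    if (verbose) message(sprintf("epoch %3d train %.3f val %.3f", ep, val_obj, val))
    if (val > best$val) { best <- list(val = val, flat = flat); stall <- 0L }
    else stall <- stall + 1L
    if (stall >= patience) break
  }
  model <- jmi_set_params(model, best$flat)
  list(model = model, trace = dplyr::bind_rows(rows))
}

#' Frozen per-spike and per-state weight ingredients for decoding
#'
#' At a fixed expansion state `x_bar`, draws L latent samples from the
#' relevant encoder and returns, per sample, the state-decoder Gaussian
#' (`mu`, diagonal `prec`) plus the x-independent log constant (mark decoder,
#' prior, proposal and base-intensity contributions, including the state
#' decoder's normalizer). The log weight as a function of the bin state x is
#' then `logc_l - 0.5 * sum_j prec_lj (x_j - mu_lj)^2`: a fixed quadratic per
#' sample, which is what the Gauss-Newton concavification linearizes.
#'
#' @param model a [jmi_vae()]
#' @param x_bar expansion state (length d_x)
#' @param kappa mark vector, or NULL for the ground-intensity (chi) ingredient
#' @param L sample count
#' @param eps L x d_z standard normal noise
#' @return list(mu = L x d_x, prec = L x d_x, logc = length L)
#' @export
jmi_frozen_weights <- function(model, x_bar, kappa, L, eps) {
  xb <- matrix(x_bar, 1L)
  enc <- if (is.null(kappa)) model$encoder_x else model$encoder_xk
  inp <- if (is.null(kappa)) xb else cbind(xb, matrix(kappa, 1L))
  q <- gmap_eval(enc, inp)
  mu_rep <- q$mean[rep(1L, L), , drop = FALSE]
  if (identical(enc$prec_type, "full")) {
    Z <- gauss_sample(mu_rep, q$prec, eps)
    lq <- gauss_logpdf(Z, mu_rep, q$prec)
  } else {
    prec_rep <- q$prec[rep(1L, L), , drop = FALSE]
    Z <- gauss_sample_diag(mu_rep, prec_rep, eps)
    lq <- gauss_logpdf_diag(Z, mu_rep, prec_rep)
  }
  dx <- gmap_eval(model$decoder_x, Z)
  stopifnot(identical(model$decoder_x$prec_type, "diag"))
  logc <- model$log_lambda0 +
    (-0.5 * rowSums(Z^2) - 0.5 * model$d_z * log(2 * pi)) - # prior
    lq +                                                    # minus proposal
    0.5 * rowSums(log(dx$prec)) - 0.5 * model$d_x * log(2 * pi) # x-normalizer
  if (!is.null(kappa)) {
    dk <- gmap_eval(model$decoder_k, Z)
    Kt <- matrix(kappa, L, model$d_k, byrow = TRUE)
    logc <- logc + if (identical(model$decoder_k$prec_type, "full"))
      gauss_logpdf(Kt, dk$mean, dk$prec)
    else gauss_logpdf_diag(Kt, dk$mean, dk$prec)
  }
  list(mu = dx$mean, prec = dx$prec, logc = logc)
}
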