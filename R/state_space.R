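#' Linear-Gaussian chain dynamics
#'
#' Initial distribution `N(x_1 | a1, V1^{-1})` and transitions
#' `N(x_r | F x_{r-1} + a, V^{-1})` with SPD precision matrices. The same
#' structure serves the generative prior over the latent path and the Markov
#' part of the structured variational family. For gradient-based training the
#' precisions are parameterized through unconstrained lower-triangular Cholesky
#' factors with softplus diagonals.
#'
#' @param d state dimension
#' @param a1,V1 initial mean and precision
#' @param F,a,V transition matrix, offset and precision
#' @export
lg_dynamics <- function(d, a1 = rep(0, d), V1 = diag(d), F = 0.99 * diag(d),
                        a = rep(0, d), V = diag(d)) {
  structure(list(d = d, a1 = a1, V1 = as.matrix(V1), F = as.matrix(F),
                 a = a, V = as.matrix(V)),
            class = "lg_dynamics")
}

# unconstrained raw matrix -> SPD via lower Cholesky with softplus diagonal
spd_raw_init <- function(V) {
  L <- t(chol(V))
  raw <- L
  diag(raw) <- log(expm1(pmax(diag(L), 1e-6)))
  raw
}

spd_from_raw <- function(raw) {
  L <- raw
  L[upper.tri(L)] <- 0
  diag(L) <- softplus(diag(raw))
  tcrossprod(L)
}

spd_from_raw_tp <- function(tp, raw_node) {
  d <- nrow(tpv(tp, raw_node))
  strict <- lower.tri(diag(d)) * 1
  L <- tp_add(tp, tp_maskmul(tp, raw_node, strict),
              tp_diag_make(tp, tp_softplus(tp, tp_diag_extract(tp, raw_node))))
  list(P = tp_matmul(tp, L, tp_t(tp, L)), L = L)
}

dyn_raw_params <- function(dyn, prefix) {
  out <- list()
  out[[paste0(prefix, "_m1")]] <- dyn$a1
  out[[paste0(prefix, "_rawP1")]] <- spd_raw_init(dyn$V1)
  out[[paste0(prefix, "_F")]] <- dyn$F
  out[[paste0(prefix, "_m")]] <- dyn$a
  out[[paste0(prefix, "_rawP")]] <- spd_raw_init(dyn$V)
  out
}

dyn_from_raw <- function(flat, prefix, d) {
  lg_dynamics(d,
              a1 = flat[[paste0(prefix, "_m1")]],
              V1 = spd_from_raw(flat[[paste0(prefix, "_rawP1")]]),
              F = flat[[paste0(prefix, "_F")]],
              a = flat[[paste0(prefix, "_m")]],
              V = spd_from_raw(flat[[paste0(prefix, "_rawP")]]))
}

#' Black-box state-space model for covariates and unsorted spikes
#'
#' Generative model `p(x) p(y | x) p(kappa | x)`: linear-Gaussian latent
#' dynamics over a hidden state of dimension `d_x` (10 by default), a Gaussian
#' neural observation model for the covariate, and the VAE joint mark
#' intensity as the per-bin marked point process observation model for spikes.
#'
#' @param d_x hidden state dimension
#' @param d_y covariate dimension
#' @param jmi a [jmi_vae()] with `d_x` matching
#' @param hidden hidden widths of the covariate observation network
#' @param seed initialization seed
#' @export
state_space_model <- function(d_x, d_y, jmi, hidden = c(64L, 64L), seed = 1L) {
  stopifnot(inherits(jmi, "jmi_vae"), jmi$d_x == d_x)
  structure(list(d_x = d_x, d_y = d_y,
                 dyn = lg_dynamics(d_x),
                 obs_y = gaussian_net(d_x, d_y, hidden, seed = seed * 7L + 5L),
                 jmi = jmi),
            class = "state_space_model")
}

#' Structured variational family over the latent path
#'
#' `q(x | y, kappa)` proportional to a Markov chain of Gaussian factors times
#' per-bin Gaussian experts: one expert per covariate observation (a network
#' on `y_r`), one per spike (a network on the mark), and one constant base
#' expert per bin (playing the role of the no-spike/exponential factor). The
#' product is Gaussian with block-tridiagonal precision.
#'
#' @param d_x,d_y,d_k dimensions
#' @param hidden hidden widths for both encoder networks
#' @param seed initialization seed
#' @export
structured_var_family <- function(d_x, d_y, d_k, hidden = c(64L, 64L), seed = 1L) {
  structure(list(d_x = d_x, d_y = d_y, d_k = d_k,
                 qdyn = lg_dynamics(d_x),
                 enc_y = gaussian_net(d_y, d_x, hidden, seed = seed * 7L + 6L),
                 enc_k = gaussian_net(d_k, d_x, hidden, seed = seed * 7L + 7L),
                 base_mean = rep(0, d_x),
                 base_rawprec = rep(log(expm1(0.1)), d_x)),
            class = "structured_var_family")
}

#' Assemble a chain-plus-experts Gaussian in information form
#'
#' Low-level product-of-Gaussians assembly: a linear-Gaussian chain
#' (`lg_dynamics`, giving the block-tridiagonal skeleton) multiplied by
#' arbitrary per-bin Gaussian experts (`list(mean, prec)`, precision a full
#' matrix or a diagonal vector). Returns mean and block-tridiagonal precision.
#'
#' @param chain a [lg_dynamics()] (use NULL for no chain factors; then every
#'   bin must have at least one expert)
#' @param experts list of R lists of experts; each expert is
#'   `list(mean, prec)`
#' @param R number of bins
#' @return a [posterior_gaussian()]
#' @export
assemble_chain_gaussian <- function(chain, experts, R = length(experts)) {
  d <- if (!is.null(chain)) chain$d else length(experts[[1]][[1]]$mean)
  dg <- replicate(R, matrix(0, d, d), simplify = FALSE)
  h <- replicate(R, numeric(d), simplify = FALSE)
  off <- NULL
  if (!is.null(chain)) {
    GtW <- t(chain$F) %*% chain$V
    GtWG <- GtW %*% chain$F
    dg[[1]] <- dg[[1]] + chain$V1
    h[[1]] <- h[[1]] + chain$V1 %*% chain$a1
    if (R > 1L) {
      for (r in 2:R) {
        dg[[r]] <- dg[[r]] + chain$V
        h[[r]] <- h[[r]] + chain$V %*% chain$a
        dg[[r - 1L]] <- dg[[r - 1L]] + GtWG
        h[[r - 1L]] <- h[[r - 1L]] - GtW %*% chain$a
      }
      off <- replicate(R - 1L, -chain$V %*% chain$F, simplify = FALSE)
    }
  } else if (R > 1L) {
    off <- replicate(R - 1L, matrix(0, d, d), simplify = FALSE)
  }
  for (r in seq_len(R)) {
    for (ex in experts[[r]]) {
      Px <- ex$prec
      if (is.matrix(Px)) {
        dg[[r]] <- dg[[r]] + Px
        h[[r]] <- h[[r]] + Px %*% ex$mean
      } else {
        dg[[r]] <- dg[[r]] + diag(Px, d)
        h[[r]] <- h[[r]] + Px * ex$mean
      }
    }
  }
  P <- block_tridiag(dg, off %||% list())
  mean_vec <- bt_solve(P, unlist(h))
  posterior_gaussian(matrix(mean_vec, R, d, byrow = TRUE), P)
}

#' Build the structured variational posterior for a binned dataset
#'
#' Evaluates the covariate and mark encoder networks on the data and forms the
#' product of the Markov chain, the per-bin covariate expert, one expert per
#' spike, and the base expert. Empty bins receive only the chain, covariate
#' and base factors.
#'
#' @param q a [structured_var_family()]
#' @param data a [bin_events()] result
#' @return a [posterior_gaussian()]
#' @export
build_structured_posterior <- function(q, data) {
  R <- data$R
  ey <- if (!is.null(q$enc_y)) gmap_eval(q$enc_y, data$y) else NULL
  experts <- vector("list", R)
  base <- if (!is.null(q$base_mean))
    list(mean = q$base_mean, prec = softplus(q$base_rawprec) + 1e-4) else NULL
  for (r in seq_len(R)) {
    ex <- list()
    if (!is.null(ey))
      ex <- c(ex, list(list(mean = ey$mean[r, ], prec = ey$prec[r, ])))
    if (!is.null(q$enc_k) && data$counts[r] > 0L) {
      ek <- gmap_eval(q$enc_k, data$mark_sets[[r]])
      for (i in seq_len(nrow(ek$mean)))
        ex <- c(ex, list(list(mean = ek$mean[i, ], prec = ek$prec[i, ])))
    }
    if (!is.null(base)) ex <- c(ex, list(base))
    experts[[r]] <- ex
  }
  assemble_chain_gaussian(q$qdyn, experts, R)
}

## ---- parameter registry for the joint model ----

ssm_collect_params <- function(model, q) {
  c(dyn_raw_params(model$dyn, "p"),
    dyn_raw_params(q$qdyn, "q"),
    params_flatten(list(obs_y = model$obs_y$params,
                        enc_y = q$enc_y$params,
                        enc_k = q$enc_k$params,
                        decoder_x = model$jmi$decoder_x$params,
                        decoder_k = model$jmi$decoder_k$params,
                        encoder_xk = model$jmi$encoder_xk$params,
                        encoder_x = model$jmi$encoder_x$params)),
    list(base_mean = q$base_mean, base_rawprec = q$base_rawprec,
         log_lambda0 = model$jmi$log_lambda0))
}

ssm_set_params <- function(model, q, flat) {
  model$dyn <- dyn_from_raw(flat, "p", model$d_x)
  q$qdyn <- dyn_from_raw(flat, "q", q$d_x)
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L) next
    grp <- parts[1]; nm <- parts[2]
    if (grp == "obs_y") model$obs_y$params[[nm]] <- flat[[key]]
    else if (grp == "enc_y") q$enc_y$params[[nm]] <- flat[[key]]
    else if (grp == "enc_k") q$enc_k$params[[nm]] <- flat[[key]]
    else model$jmi[[grp]]$params[[nm]] <- flat[[key]]
  }
  q$base_mean <- flat$base_mean
  q$base_rawprec <- flat$base_rawprec
  model$jmi$log_lambda0 <- flat$log_lambda0
  list(model = model, q = q)
}

## ---- ELBO on the tape ----

# Builds the full ELBO tape for one contiguous segment and returns
# list(tp, obj, pnodes). `n_mc` reparameterized paths; `eps_path` (R*d x n_mc)
# and per-spike/bin latent noise must be supplied (callers manage the stream).
ssm_elbo_tape <- function(model, q, data, n_mc, eps_path, eps_spk, eps_grid,
                          include_pp = TRUE) {
  R <- data$R; d <- model$d_x
  cfg <- model$jmi$bound_cfg
  tp <- tape_new()
  flat <- ssm_collect_params(model, q)
  pnodes <- lapply(flat, function(p) tp_param(tp, p))
  # q-side chain pieces
  qP1 <- spd_from_raw_tp(tp, pnodes$q_rawP1)
  qP <- spd_from_raw_tp(tp, pnodes$q_rawP)
  G <- pnodes$q_F
  Wn <- qP$P; W1n <- qP1$P
  GtW <- tp_matmul(tp, tp_t(tp, G), Wn)
  GtWG <- tp_matmul(tp, GtW, G)
  WG <- tp_matmul(tp, Wn, G)
  b1col <- tp_ascol(tp, pnodes$q_m1)
  bcol <- tp_ascol(tp, pnodes$q_m)
  Wb <- tp_matmul(tp, Wn, bcol)
  W1b1 <- tp_matmul(tp, W1n, b1col)
  GtWb <- tp_matmul(tp, tp_t(tp, G), Wb)
  # encoders on data
  ey <- gnet_forward_tp(tp, pnodes_group(pnodes, "enc_y"), tp_const(tp, data$y), q$enc_y)
  all_marks <- do.call(rbind, data$mark_sets)
  n_spk <- nrow(all_marks) %||% 0L
  if (n_spk > 0L) {
    ek <- gnet_forward_tp(tp, pnodes_group(pnodes, "enc_k"),
                          tp_const(tp, all_marks), q$enc_k)
  }
  spike_bin <- rep(seq_len(R), data$counts)
  base_prec <- tp_addc(tp, tp_softplus(tp, pnodes$base_rawprec), 1e-4)
  base_h <- tp_mul(tp, base_prec, pnodes$base_mean)
  # vectorized expert accumulation: R x d nodes of summed diagonal precisions
  # and information vectors (one scatter matmul collects the per-spike experts)
  dmat <- tp_addbias(tp, ey$prec, base_prec)
  hmat <- tp_addbias(tp, tp_mul(tp, ey$prec, ey$mean), base_h)
  if (n_spk > 0L) {
    scat <- matrix(0, R, n_spk)
    scat[cbind(spike_bin, seq_len(n_spk))] <- 1
    scat_n <- tp_const(tp, scat)
    dmat <- tp_add(tp, dmat, tp_matmul(tp, scat_n, ek$prec))
    hmat <- tp_add(tp, hmat, tp_matmul(tp, scat_n, tp_mul(tp, ek$prec, ek$mean)))
  }
  diag_nodes <- vector("list", R)
  h_nodes <- vector("list", R)
  for (r in seq_len(R)) {
    D <- tp_diag_make(tp, tp_dropdim(tp, tp_slice_rows(tp, dmat, r)))
    D <- tp_add(tp, D, if (r == 1L) W1n else Wn)
    if (r < R) D <- tp_add(tp, D, GtWG)
    hcol <- tp_t(tp, tp_slice_rows(tp, hmat, r))
    hcol <- tp_add(tp, hcol, if (r == 1L) W1b1 else Wb)
    if (r < R) hcol <- tp_sub(tp, hcol, GtWb)
    diag_nodes[[r]] <- D
    h_nodes[[r]] <- hcol
  }
  off_nodes <- if (R > 1L) replicate(R - 1L, tp_neg(tp, WG), simplify = FALSE) else list()
  fac <- bt_factorize_tp(tp, diag_nodes, off_nodes)
  mean_nodes <- bt_solve_tp(tp, fac, h_nodes)
  logdetP <- bt_logdet_tp(tp, fac)
  paths <- bt_sample_tp(tp, fac, mean_nodes, eps_path) # list R of d x n_mc
  # -log q(x_s) = -0.5 logdet + 0.5 ||eps_s||^2 + (Rd/2) log 2pi, averaged
  neg_logq <- tp_addc(tp, tp_scale(tp, logdetP, -0.5),
                      0.5 * mean(colSums(eps_path^2)) + 0.5 * R * d * log(2 * pi))
  # stacked sample states (R * n_mc) x d, rows: bin-major then sample
  Xstack <- tp_vstack(tp, lapply(paths, function(pnode) tp_t(tp, pnode)))
  # p-side chain pieces; log p(x) vectorized over bins and samples
  pP1 <- spd_from_raw_tp(tp, pnodes$p_rawP1)
  pP <- spd_from_raw_tp(tp, pnodes$p_rawP)
  X1 <- tp_slice_rows(tp, Xstack, seq_len(n_mc)) # n_mc x d
  diff1 <- tp_addbias(tp, X1, tp_neg(tp, pnodes$p_m1))
  u1 <- tp_matmul(tp, diff1, pP1$L) # row quad: ||x' L||^2 = x' P x
  ld1 <- tp_scale(tp, tp_sum(tp, tp_log(tp, tp_diag_extract(tp, pP1$L))), 2)
  logpx <- tp_add(tp,
                  tp_scale(tp, ld1, n_mc),
                  tp_scale(tp, tp_sum(tp, tp_square(tp, u1)), -1))
  if (R > 1L) {
    ldV <- tp_scale(tp, tp_sum(tp, tp_log(tp, tp_diag_extract(tp, pP$L))), 2)
    idx_prev <- seq_len((R - 1L) * n_mc)
    Xprev <- tp_slice_rows(tp, Xstack, idx_prev)
    Xcur <- tp_slice_rows(tp, Xstack, idx_prev + n_mc)
    pred <- tp_addbias(tp, tp_matmul(tp, Xprev, tp_t(tp, pnodes$p_F)),
                       pnodes$p_m)
    ur <- tp_matmul(tp, tp_sub(tp, Xcur, pred), pP$L)
    logpx <- tp_add(tp, logpx,
                    tp_add(tp, tp_scale(tp, ldV, (R - 1L) * n_mc),
                           tp_scale(tp, tp_sum(tp, tp_square(tp, ur)), -1)))
  }
  logpx <- tp_addc(tp, tp_scale(tp, logpx, 0.5 / n_mc),
                   -0.5 * R * d * log(2 * pi))
  # log p(y | x)
  oy <- gnet_forward_tp(tp, pnodes_group(pnodes, "obs_y"), Xstack, model$obs_y)
  yrep <- data$y[rep(seq_len(R), each = n_mc), , drop = FALSE]
  logpy <- tp_scale(tp, tp_sum(tp, tp_gauss_diag_logpdf(tp, tp_const(tp, yrep),
                                                        oy$mean, oy$prec)), 1 / n_mc)
  obj <- tp_add(tp, tp_add(tp, logpx, logpy), neg_logq)
  # point-process term via the per-bin bound
  if (include_pp) {
    jpn <- list(decoder_x = pnodes_group(pnodes, "decoder_x"),
                decoder_k = pnodes_group(pnodes, "decoder_k"),
                encoder_xk = pnodes_group(pnodes, "encoder_xk"),
                encoder_x = pnodes_group(pnodes, "encoder_x"))
    lam <- pnodes$log_lambda0
    state_term <- jmi_state_term_tp(tp, jpn, model$jmi, Xstack, eps_grid, cfg,
                                    lam, log(data$dt_bin))
    obj <- tp_sub(tp, obj, tp_scale(tp, state_term, 1 / n_mc))
    if (n_spk > 0L) {
      # per-spike state rows: the sampled states of the spike's bin, all mc
      spike_rows <- as.integer(as.vector(vapply(spike_bin, function(r)
        (r - 1) * n_mc + seq_len(n_mc), numeric(n_mc))))
      Xspk <- tp_slice_rows(tp, Xstack, spike_rows)
      marks_rep <- all_marks[rep(seq_len(n_spk), each = n_mc), , drop = FALSE]
      spike_term <- jmi_spike_term_tp(tp, jpn, model$jmi, Xspk, marks_rep,
                                      eps_spk, cfg, lam)
      obj <- tp_add(tp, obj, tp_scale(tp, spike_term, 1 / n_mc))
    }
  }
  list(tp = tp, obj = obj, pnodes = pnodes)
}

pnodes_group <- function(pnodes, grp) {
  keys <- grep(paste0("^", grp, "\\."), names(pnodes), value = TRUE)
  out <- pnodes[keys]
  names(out) <- sub(paste0("^", grp, "\\."), "", keys)
  out
}

# Draw the three noise blocks for one segment from a seeded stream.
ssm_draw_eps <- function(rng, R, d, d_z, n_mc, n_spk, L) {
  list(path = matrix(rng$norm(R * d * n_mc), R * d, n_mc),
       spk = if (n_spk > 0L)
         matrix(rng$norm(n_spk * n_mc * L * d_z), n_spk * n_mc * L, d_z)
       else matrix(0, 0L, d_z),
       grid = matrix(rng$norm(R * n_mc * L * d_z), R * n_mc * L, d_z))
}

#' Monte Carlo evidence lower bound of the state-space model
#'
#' Reparameterized ELBO estimate on a binned dataset: expected log prior,
#' covariate likelihood and per-bin point-process bound under sampled paths
#' from the structured posterior, plus the posterior entropy evaluated through
#' the block-tridiagonal log-determinant. Deterministic given `seed`.
#'
#' @param model a [state_space_model()]
#' @param q a [structured_var_family()]
#' @param data a binned dataset
#' @param n_mc number of sampled paths
#' @param seed seed for all reparameterization noise
#' @return scalar ELBO estimate
#' @export
ssm_elbo <- function(model, q, data, n_mc = 4L, seed = 1L) {
  rng <- local_rng(seed)
  n_spk <- sum(data$counts)
  eps <- ssm_draw_eps(rng, data$R, model$d_x, model$jmi$d_z, n_mc, n_spk,
                      model$jmi$bound_cfg$L)
  built <- ssm_elbo_tape(model, q, data, n_mc, eps$path, eps$spk, eps$grid)
  tp_value(built$tp, built$obj)
}

#' Test negative log-likelihood bound of the state-space model
#'
#' `-ssm_elbo(...)` on held-out data: an upper bound on the true NLL of the
#' covariate and spikes.
#' @inheritParams ssm_elbo
#' @export
ssm_predict_nll <- function(model, q, data, n_mc = 8L, seed = 1L) {
  -ssm_elbo(model, q, data, n_mc = n_mc, seed = seed)
}

#' Fit the state-space model and variational family jointly
#'
#' Maximizes the segment-summed ELBO with Adam: each epoch sweeps contiguous
#' segments (default 200 bins, 1-bin overlap; the initial-distribution factors
#' handle segment boundaries) with one parameter update per segment and fresh
#' reparameterization noise from a single seeded stream. Validation ELBO (fixed
#' noise) drives early stopping; best-validation parameters are returned.
#'
#' @param model,q model and variational family
#' @param data training [bin_events()] data
#' @param val_data validation data (same structure)
#' @param epochs,lr,patience optimization controls (`epochs = 0` is a no-op)
#' @param segment_len bins per segment
#' @param n_mc sampled paths per update
#' @param seed seed
#' @param verbose print per-epoch values
#' @return list(model, q, trace)
#' @export
fit_ssm <- function(model, q, data, val_data, epochs = 20L, lr = 3e-3,
                    patience = 5L, segment_len = 200L, n_mc = 1L, seed = 1L,
                    verbose = FALSE) {
  if (epochs == 0L)
    return(list(model = model, q = q,
                trace = tibble::tibble(epoch = integer(), train = numeric(),
                                      val = numeric())))
  R <- data$R
  starts <- if (R <= segment_len) 1L
  else unique(pmin(seq(1L, R, by = segment_len - 1L), R - segment_len + 1L))
  segs <- lapply(starts, function(s) s:min(s + segment_len - 1L, R))
  segs <- segs[!duplicated(vapply(segs, function(ix) ix[1], integer(1)))]
  rng <- local_rng(seed)
  flat <- ssm_collect_params(model, q)
  opt <- adam_new(flat, lr = lr)
  val_seed <- rng$derive()
  best <- list(val = -Inf, flat = flat)
  stall <- 0L
  rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    train_total <- 0
    for (seg in segs) {
      sd <- bin_subset(data, seg)
      n_spk <- sum(sd$counts)
      eps <- ssm_draw_eps(rng, sd$R, model$d_x, model$jmi$d_z, n_mc, n_spk,
                          model$jmi$bound_cfg$L)
      built <- ssm_elbo_tape(model, q, sd, n_mc, eps$path, eps$spk, eps$grid)
      v <- tp_value(built$tp, built$obj)
      if (!is.finite(v))
        stop(sprintf("ELBO diverged at epoch %d (lambda0 = %.3g)",
                     ep, exp(model$jmi$log_lambda0)), call. = FALSE)
      train_total <- train_total + v
      gnodes <- tp_backward(built$tp, built$obj)
      grads <- lapply(names(flat), function(nm)
        gnodes[[built$pnodes[[nm]]]] %||% (flat[[nm]] * 0))
      names(grads) <- names(flat)
      stepped <- adam_step(opt, flat, grads, maximize = TRUE)
      flat <- stepped$flat; opt <- stepped$state
      upd <- ssm_set_params(model, q, flat)
      model <- upd$model; q <- upd$q
    }
    val <- ssm_elbo(model, q, val_data, n_mc = max(n_mc, 2L), seed = val_seed)
    rows[[ep]] <- tibble::tibble(epoch = ep, train = train_total, val = val)
    if (verbose) message(sprintf("epoch %3d train %.2f val %.2f", ep, train_total, val))
    if (val > best$val) { best <- list(val = val, flat = flat); stall <- 0L }
    else stall <- stall + 1L
    if (stall >= patience) break
  }
  upd <- ssm_set_params(model, q, best$flat)
  list(model = upd$model, q = upd$q, trace = dplyr::bind_rows(rows))
}
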