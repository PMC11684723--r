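#' Gaussian-mixture joint mark intensity (baseline)
#'
#' The classical clusterless intensity model: each component is a Gaussian in
#' state space times a Gaussian in mark space, scaled by a positive rate,
#' `lambda(x, kappa) = sum_l lambda_l N(x | mu_l^x, P_l^x) N(kappa | mu_l^k,
#' P_l^k)` with diagonal precisions. Both the intensity and its mark marginal
#' (the ground intensity) are exact closed forms — no Monte Carlo — which makes
#' this the reference likelihood when comparing against bound-based models.
#'
#' @param lambda length-L_c positive scales
#' @param mu_x,prec_x L_c x d_x means and (positive) diagonal precisions
#' @param mu_k,prec_k L_c x d_k means and diagonal precisions
#' @export
gmm_intensity_model <- function(lambda, mu_x, prec_x, mu_k, prec_k) {
  mu_x <- as.matrix(mu_x); mu_k <- as.matrix(mu_k)
  prec_x <- as.matrix(prec_x); prec_k <- as.matrix(prec_k)
  stopifnot(all(lambda > 0), all(prec_x > 0), all(prec_k > 0),
            nrow(mu_x) == length(lambda), nrow(mu_k) == length(lambda))
  structure(list(lambda = lambda, mu_x = mu_x, prec_x = prec_x,
                 mu_k = mu_k, prec_k = prec_k,
                 L_c = length(lambda), d_x = ncol(mu_x), d_k = ncol(mu_k)),
            class = "gmm_intensity")
}

#' @export
print.gmm_intensity <- function(x, ...) {
  cat(sprintf("<gmm_intensity: %d components, d_x = %d, d_k = %d>\n",
              x$L_c, x$d_x, x$d_k))
  invisible(x)
}

# n x L_c matrix of per-component log state densities
gmm_log_nx <- function(g, X) {
  X <- as_matrix_rows(X, g$d_x)
  matrix(vapply(seq_len(g$L_c), function(l)
    gauss_logpdf(X, g$mu_x[l, ], g$prec_x[l, ]), numeric(nrow(X))),
    nrow(X), g$L_c)
}

gmm_log_nk <- function(g, K) {
  K <- as_matrix_rows(K, g$d_k)
  matrix(vapply(seq_len(g$L_c), function(l)
    gauss_logpdf(K, g$mu_k[l, ], g$prec_k[l, ]), numeric(nrow(K))),
    nrow(K), g$L_c)
}

rowlse <- function(M) {
  if (!is.matrix(M)) M <- matrix(M, 1L)
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Evaluate the GMM joint mark intensity and its ground intensity
#'
#' Vectorized over rows of `X` (and `K`). Exact closed forms; the ground
#' intensity is the analytic mark marginal.
#'
#' @param g a [gmm_intensity_model()]
#' @param X states (n x d_x or a single vector)
#' @param K marks (n x d_k or a single vector)
#' @return numeric vector of intensities
#' @export
gmm_intensity <- function(g, X, K) {
  X <- as_matrix_rows(X, g$d_x); K <- as_matrix_rows(K, g$d_k)
  if (nrow(X) != nrow(K)) stop("X and K must have matching rows", call. = FALSE)
  lw <- sweep(gmm_log_nx(g, X) + gmm_log_nk(g, K), 2L, log(g$lambda), "+")
  exp(rowlse(lw))
}

#' @rdname gmm_intensity
#' @export
gmm_ground_intensity <- function(g, X) {
  X <- as_matrix_rows(X, g$d_x)
  lw <- sweep(gmm_log_nx(g, X), 2L, log(g$lambda), "+")
  exp(rowlse(lw))
}

#' Exact point-process log-likelihood under the GMM intensity
#'
#' `sum_i log lambda(x_i, kappa_i) - dt * sum_j lambda(x_j)`; exact (no
#' bounds), hence the baseline reference in model comparisons.
#'
#' @param g a [gmm_intensity_model()]
#' @param x_spikes,marks per-spike states and marks
#' @param x_grid states at grid points
#' @param dt grid spacing
#' @export
gmm_loglik <- function(g, x_spikes, marks, x_grid, dt) {
  s <- 0
  if (!is.null(x_spikes) && nrow(as_matrix_rows(x_spikes, g$d_x)) > 0L)
    s <- sum(log(gmm_intensity(g, x_spikes, marks)))
  s - dt * sum(gmm_ground_intensity(g, x_grid))
}

gmm_collect <- function(g) {
  list(log_lambda = log(g$lambda), mu_x = g$mu_x, raw_px = log(g$prec_x),
       mu_k = g$mu_k, raw_pk = log(g$prec_k))
}

gmm_set <- function(g, flat, prec_cap = 1e3) {
  g$lambda <- exp(flat$log_lambda)
  g$mu_x <- flat$mu_x; g$mu_k <- flat$mu_k
  px <- exp(flat$raw_px); pk <- exp(flat$raw_pk)
  if (any(px > prec_cap) || any(pk > prec_cap))
    warning("component precision capped (possible component collapse)")
  g$prec_x <- pmin(px, prec_cap); g$prec_k <- pmin(pk, prec_cap)
  g
}

# tape version of gmm_loglik; returns list(tp, obj, pnodes)
gmm_loglik_tape <- function(g, x_spikes, marks, x_grid, dt) {
  tp <- tape_new()
  flat <- gmm_collect(g)
  pn <- lapply(flat, function(p) tp_param(tp, p))
  n <- nrow(x_spikes)
  comp_logdens <- function(Xnode, mu_node, raw_node, l, d) {
    mu_l <- tp_dropdim(tp, tp_slice_rows(tp, mu_node, l))
    raw_l <- tp_dropdim(tp, tp_slice_rows(tp, raw_node, l))
    diffn <- tp_addbias(tp, Xnode, tp_neg(tp, mu_l))
    quad <- tp_rowsums(tp, tp_sweep_mul(tp, tp_square(tp, diffn), tp_exp(tp, raw_l)))
    tp_addc(tp, tp_scale(tp, tp_sub(tp, tp_sum_bcast(tp, raw_l, quad), quad), 0.5),
            -0.5 * d * log(2 * pi))
  }
  # sum_bcast: broadcast sum(raw_l) to the length of quad
  spike_cols <- vector("list", g$L_c)
  grid_cols <- vector("list", g$L_c)
  Xg <- tp_const(tp, x_grid)
  if (n > 0L) { Xs <- tp_const(tp, x_spikes); Ks <- tp_const(tp, marks) }
  for (l in seq_len(g$L_c)) {
    ll_l <- tp_slice_rows(tp, tp_ascol(tp, pn$log_lambda), l)
    lgx <- comp_logdens(Xg, pn$mu_x, pn$raw_px, l, g$d_x)
    grid_cols[[l]] <- tp_ascol(tp, tp_adds(tp, lgx, tp_dropdim(tp, ll_l)))
    if (n > 0L) {
      lsx <- comp_logdens(Xs, pn$mu_x, pn$raw_px, l, g$d_x)
      lsk <- comp_logdens(Ks, pn$mu_k, pn$raw_pk, l, g$d_k)
      spike_cols[[l]] <- tp_ascol(tp, tp_adds(tp, tp_add(tp, lsx, lsk),
                                              tp_dropdim(tp, ll_l)))
    }
  }
  hstack <- function(cols) Reduce(function(a, b) tp_cbind(tp, a, b), cols)
  grid_mat <- hstack(grid_cols)
  ground <- tp_sum(tp, tp_exp(tp, tp_logsumexp_rows(tp, grid_mat)))
  obj <- tp_scale(tp, ground, -dt)
  if (n > 0L) {
    spk_mat <- hstack(spike_cols)
    obj <- tp_add(tp, obj, tp_sum(tp, tp_logsumexp_rows(tp, spk_mat)))
  }
  list(tp = tp, obj = obj, pnodes = pn)
}

tp_sum_bcast <- function(tp, v, like) {
  s <- tp_sum(tp, v)
  n <- length(tpv(tp, like))
  tp_mul(tp, tp_const(tp, rep(1, n)), s)
}

#' Fit the GMM intensity by gradient ascent on the exact log-likelihood
#'
#' Means are initialized by k-means on spikes (states and marks jointly,
#' standardized), scales to `n / (L_c * total time)`, precisions to the
#' reciprocal within-cluster variances. Each iteration takes a gradient step
#' with backtracking halving, so the objective trace is non-decreasing.
#' Component precisions are capped at 1e3 per dimension (collapse guard,
#' with a warning).
#'
#' @inheritParams gmm_loglik
#' @param L_c number of components
#' @param iters maximum gradient iterations (0 returns the initialization)
#' @param lr initial step scale
#' @param seed seed (k-means initialization)
#' @return list(model = [gmm_intensity_model()], trace = tibble)
#' @export
gmm_fit <- function(x_spikes, marks, x_grid, dt, L_c = 16L, iters = 200L,
                    lr = 0.05, seed = 1L) {
  x_spikes <- as.matrix(x_spikes); marks <- as.matrix(marks)
  x_grid <- as.matrix(x_grid)
  n <- nrow(x_spikes)
  d_x <- ncol(x_spikes); d_k <- ncol(marks)
  L_c <- min(L_c, max(1L, n %/% 2L))
  feat <- scale(cbind(x_spikes, marks))
  feat[!is.finite(feat)] <- 0
  rng <- local_rng(seed)
  km <- if (n > L_c) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(rng$derive())
    res <- stats::kmeans(feat, centers = L_c, nstart = 3L, iter.max = 30L)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    res$cluster
  } else rep(seq_len(L_c), length.out = n)
  mu_x <- matrix(0, L_c, d_x); mu_k <- matrix(0, L_c, d_k)
  prec_x <- matrix(1, L_c, d_x); prec_k <- matrix(1, L_c, d_k)
  for (l in seq_len(L_c)) {
    rows <- which(km == l)
    if (!length(rows)) rows <- seq_len(n)
    mu_x[l, ] <- colMeans(x_spikes[rows, , drop = FALSE])
    mu_k[l, ] <- colMeans(marks[rows, , drop = FALSE])
    vx <- apply(x_spikes[rows, , drop = FALSE], 2L, stats::var)
    vk <- apply(marks[rows, , drop = FALSE], 2L, stats::var)
    gx <- apply(x_spikes, 2L, stats::var); gk <- apply(marks, 2L, stats::var)
    prec_x[l, ] <- 1 / pmax(ifelse(is.finite(vx) & vx > 0, vx, gx), 1e-4)
    prec_k[l, ] <- 1 / pmax(ifelse(is.finite(vk) & vk > 0, vk, gk), 1e-4)
  }
  total_time <- dt * nrow(x_grid)
  g <- gmm_intensity_model(rep(max(n, 1L) / (L_c * total_time), L_c),
                           mu_x, prec_x, mu_k, prec_k)
  trace <- numeric(0)
  f0 <- gmm_loglik(g, x_spikes, marks, x_grid, dt)
  step <- lr / max(n, 1L) # gradient scales with the data size
  for (it in seq_len(iters)) {
    built <- gmm_loglik_tape(g, x_spikes, marks, x_grid, dt)
    gn <- tp_backward(built$tp, built$obj)
    flat <- gmm_collect(g)
    grads <- lapply(names(flat), function(nm) gn[[built$pnodes[[nm]]]] %||% (flat[[nm]] * 0))
    names(grads) <- names(flat)
    if (sqrt(sum(unlist(grads)^2)) < 1e-8) break
    improved <- FALSE
    for (bk in 0:25) {
      cand <- flat
      for (nm in names(flat)) cand[[nm]] <- flat[[nm]] + step * grads[[nm]]
      g_cand <- suppressWarnings(gmm_set(g, cand))
      f_cand <- gmm_loglik(g_cand, x_spikes, marks, x_grid, dt)
      if (is.finite(f_cand) && f_cand >= f0) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    g <- g_cand; f0 <- f_cand
    if (n > 0L) {
      # exact coordinate update of the common scale: loglik as a function of a
      # global factor c is n log c - c * I, maximized at c = n / I. This is a
      # closed-form ascent step, so the trace stays monotone.
      I <- dt * sum(gmm_ground_intensity(g, x_grid))
      g$lambda <- g$lambda * (n / I)
      f0 <- gmm_loglik(g, x_spikes, marks, x_grid, dt)
    }
    trace <- c(trace, f0)
    step <- step * 2 # expand again after a successful step
  }
  list(model = g, trace = tibble::tibble(iter = seq_along(trace), loglik = trace))
}

#' Concavified per-bin objective under a GMM intensity (for decoding)
#'
#' The GMM per-bin log-likelihood `sum_i log lambda(x, kappa_i) - dt lambda(x)`
#' is a composition of concave outer functions (log-sum and a negated sum)
#' with per-component exponential-of-quadratic inner maps, so the same
#' Gauss-Newton linearization as [concave_bin_bound()] applies: each spike term
#' contributes a rank-one `g g'` curvature block and the ground term is
#' linearized to zero curvature.
#'
#' @param g a [gmm_intensity_model()]
#' @param marks the bin's marks
#' @param x_bar expansion state
#' @param dt bin width
#' @export
gmm_bin_objective <- function(g, marks, x_bar, dt) {
  n_r <- nrow(marks)
  d <- g$d_x
  ctx_of <- function(logc) { # logc: L_c per-component x-independent log consts
    lw <- logc + drop(gmm_log_nx(g, matrix(x_bar, 1L)))
    cmax <- max(lw)
    if (!is.finite(cmax))
      return(list(u0 = rep(0, g$L_c), G = matrix(0, g$L_c, d),
                  cmax = -.Machine$double.xmax, logc = logc))
    list(u0 = exp(lw - cmax), G = g$prec_x * sweep(g$mu_x, 2L, x_bar, "-"),
         cmax = cmax, logc = logc)
  }
  spk_ctx <- lapply(seq_len(n_r), function(i)
    ctx_of(log(g$lambda) + drop(gmm_log_nk(g, matrix(marks[i, ], 1L)))))
  st_ctx <- ctx_of(log(g$lambda) + log(dt))
  lin_u <- function(ctx, x) pmax(ctx$u0 * (1 + drop(ctx$G %*% (x - x_bar))), 0)
  lw_at <- function(ctx, x) ctx$logc + drop(gmm_log_nx(g, matrix(x, 1L)))
  value <- function(x) {
    v <- 0
    for (ctx in spk_ctx) {
      s <- sum(lin_u(ctx, x))
      v <- v + if (s > 0) log(s) + ctx$cmax else -Inf
    }
    v - exp(st_ctx$cmax) * sum(lin_u(st_ctx, x))
  }
  value_frozen <- function(x) {
    v <- 0
    for (ctx in spk_ctx) v <- v + rowlse(matrix(lw_at(ctx, x), 1L))
    v - sum(exp(lw_at(st_ctx, x)))
  }
  grad <- function(x) {
    gt <- numeric(d)
    for (ctx in spk_ctx) {
      u <- lin_u(ctx, x); S <- sum(u)
      if (S > 0) gt <- gt + drop(crossprod(ctx$G, (ctx$u0 / S)))
    }
    gt - exp(st_ctx$cmax) * drop(crossprod(st_ctx$G, st_ctx$u0))
  }
  neg_hess <- function(x) {
    H <- matrix(0, d, d)
    for (ctx in spk_ctx) {
      u <- lin_u(ctx, x); S <- sum(u)
      if (S > 0) {
        gg <- drop(crossprod(ctx$G, ctx$u0)) / S
        H <- H + tcrossprod(gg)
      }
    }
    H
  }
  structure(list(value = value, value_frozen = value_frozen, grad = grad,
                 neg_hess = neg_hess, x_bar = x_bar, n_spikes = n_r),
            class = "concave_bin_bound")
}

#' Estimate linear-Gaussian dynamics from a covariate path
#'
#' Least-squares AR(1) fit `y_r ~ F y_{r-1} + a` with Gaussian residuals,
#' giving the smoothness prior used when decoding with the GMM baseline
#' (state = observed covariate).
#'
#' @param values R x d matrix of consecutive observations
#' @return an [lg_dynamics()]
#' @export
estimate_lg_dynamics <- function(values) {
  values <- as.matrix(values)
  R <- nrow(values); d <- ncol(values)
  Y0 <- cbind(values[-R, , drop = FALSE], 1)
  Y1 <- values[-1, , drop = FALSE]
  B <- solve(crossprod(Y0) + diag(1e-8, d + 1), crossprod(Y0, Y1))
  F <- t(B[seq_len(d), , drop = FALSE])
  a <- B[d + 1, ]
  resid <- Y1 - Y0 %*% B
  Sig <- crossprod(resid) / max(R - 2, 1) + diag(1e-8, d)
  V1 <- solve(stats::cov(values) + diag(1e-8, d))
  lg_dynamics(d, a1 = colMeans(values), V1 = V1, F = F, a = a, V = solve(Sig))
}

#' Decode the covariate with the GMM baseline
#'
#' Classical clusterless decoding: the GMM intensity is defined directly on
#' the covariate space, an AR(1) prior supplies temporal smoothness, and the
#' same concavified Newton machinery computes the Laplace posterior over the
#' covariate path.
#'
#' @param g a [gmm_intensity_model()] fitted with the covariate as state
#' @param dyn an [lg_dynamics()] prior over the covariate path
#' @param data binned test data
#' @param ... passed to [newton_map()]
#' @return list(laplace, y_hat) with `y_hat` an R x d matrix (the posterior
#'   mean path; the state *is* the covariate here)
#' @export
gmm_decode <- function(g, dyn, data, ...) {
  gen <- function(r, x_r) gmm_bin_objective(g, data$mark_sets[[r]], x_r, data$dt_bin)
  lap <- newton_map(list(dyn = dyn), data, bin_objectives = gen, ...)
  list(laplace = lap, y_hat = lap$mean)
}

#' Paired Wilcoxon signed-rank tests with Holm-Sidak correction
#'
#' For every pair of models, a two-sided paired Wilcoxon signed-rank test on
#' the per-trial scores; p values are then adjusted by the Holm-Sidak step-down
#' rule `p_(i) = max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, clipped at 1,
#' which is monotone in rank and componentwise >= the raw p values.
#'
#' @param scores tibble/data.frame with columns `trial`, `model`, `value`
#'   (one metric; filter beforehand if several are stacked)
#' @return tibble with columns `model1`, `model2`, `p_raw`, `p_adj`
#' @export
wilcoxon_holm_sidak <- function(scores) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("trial", "model", "value") %in% names(scores)))
  wide <- tidyr::pivot_wider(scores, id_cols = "trial", names_from = "model",
                             values_from = "value")
  models <- setdiff(names(wide), "trial")
  if (anyNA(wide[models]))
    stop("unpaired or missing scores for some trial/model combinations",
         call. = FALSE)
  if (nrow(wide) < 5L)
    stop("need at least 5 paired observations per model pair", call. = FALSE)
  pairs <- utils::combn(models, 2L)
  p_raw <- apply(pairs, 2L, function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    if (all(d == 0)) return(1) # identical scores carry no evidence
    suppressWarnings(stats::wilcox.test(wide[[pr[1]]], wide[[pr[2]]],
                                        paired = TRUE, exact = FALSE)$p.value)
  })
  out <- tibble::tibble(model1 = pairs[1, ], model2 = pairs[2, ], p_raw = p_raw)
  out$p_adj <- holm_sidak_adjust(out$p_raw)
  out
}

#' Holm-Sidak step-down adjustment of a vector of p values
#' @param p numeric vector of raw p values
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, val)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}
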