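#' Concave per-bin bound for decoding
#'
#' At a fixed expansion state `x_bar`, the per-bin point-process bound is a sum
#' of composite terms: per-spike Renyi terms `pi(F_ri(x))` and the negative chi
#' term `rho(G_r(x))`, where the inner maps collect the L frozen importance
#' weights (latent samples drawn once at `x_bar` and held fixed) and the outer
#' functions are concave. Each weight depends on the bin state only through the
#' state decoder's Gaussian, so the inner maps are exponentials of fixed
#' quadratics. Replacing the inner maps by their first-order Taylor expansion
#' at `x_bar` (the Gauss-Newton step) makes the composite globally concave:
#' the surrogate matches the frozen bound in value and gradient at `x_bar` and
#' its Hessian is negative semidefinite everywhere.
#'
#' @param jmi a [jmi_vae()]
#' @param marks n_r x d_k matrix of the bin's marks (may have zero rows)
#' @param x_bar expansion state (length d_x)
#' @param dt bin width (enters the chi term as `lambda0 * dt`)
#' @param L number of frozen latent samples per term
#' @param eps_spikes list of n_r L x d_z noise matrices (one per spike)
#' @param eps_state L x d_z noise matrix for the chi term
#' @return object of class `concave_bin_bound` with functions `value(x)`
#'   (the concavified surrogate), `value_frozen(x)` (the unlinearized frozen
#'   bound), `grad(x)` and `neg_hess(x)`
#' @export
concave_bin_bound <- function(jmi, marks, x_bar, dt, L = 32L,
                              eps_spikes = NULL, eps_state = NULL, seed = 1L) {
  n_r <- nrow(marks)
  d <- jmi$d_x
  if (is.null(eps_spikes) || is.null(eps_state)) {
    rng <- local_rng(seed)
    if (is.null(eps_state)) eps_state <- matrix(rng$norm(L * jmi$d_z), L, jmi$d_z)
    if (is.null(eps_spikes))
      eps_spikes <- lapply(seq_len(n_r), function(i)
        matrix(rng$norm(L * jmi$d_z), L, jmi$d_z))
  }
  alpha <- jmi$bound_cfg$alpha
  beta <- jmi$bound_cfg$beta
  frozen_spk <- lapply(seq_len(n_r), function(i)
    jmi_frozen_weights(jmi, x_bar, marks[i, ], L, eps_spikes[[i]]))
  frozen_state <- jmi_frozen_weights(jmi, x_bar, NULL, L, eps_state)
  frozen_state$logc <- frozen_state$logc + log(dt)
  logw_at <- function(fr, x) {
    dmat <- sweep(-fr$mu, 2L, x, "+") # L x d rows: x - mu_l
    fr$logc - 0.5 * rowSums(fr$prec * dmat^2)
  }
  grad_rows <- function(fr, x) { # g_l = prec_l * (mu_l - x), L x d
    fr$prec * sweep(fr$mu, 2L, x, "-")
  }
  # spike expansion constants (scaled weights and Jacobian rows at x_bar);
  # a term whose weights all underflow to zero is marked dead and contributes
  # no gradient or curvature (its value is -Inf for a spike, 0 for the state
  # term); the state multiplier is clamped like the training chi term
  clamp <- jmi$bound_cfg$chi_log_clamp
  mk_ctx <- function(fr, mult_clamp = Inf) {
    lw <- logw_at(fr, x_bar)
    cmax <- max(lw)
    if (!is.finite(cmax)) {
      return(list(fr = fr, u0 = rep(0, L), G = matrix(0, L, d),
                  cmax = -.Machine$double.xmax, mult = 0, dead = TRUE))
    }
    list(fr = fr, u0 = exp(lw - cmax), G = grad_rows(fr, x_bar), cmax = cmax,
         mult = exp(min(cmax, mult_clamp)), dead = FALSE)
  }
  spk_ctx <- lapply(frozen_spk, mk_ctx)
  st_ctx <- mk_ctx(frozen_state, mult_clamp = clamp)
  lin_u <- function(ctx, x) pmax(ctx$u0 * (1 + drop(ctx$G %*% (x - x_bar))), 0)
  value <- function(x) {
    v <- 0
    for (ctx in spk_ctx) {
      u <- lin_u(ctx, x)
      s <- mean(u^alpha)
      v <- v + if (s > 0) (log(s) / alpha + ctx$cmax) else -Inf
    }
    if (st_ctx$dead) return(v)
    u <- lin_u(st_ctx, x)
    v - st_ctx$mult * mean(u^beta)^(1 / beta)
  }
  value_frozen <- function(x) {
    v <- 0
    for (ctx in spk_ctx)
      v <- v + renyi_lower_bound(logw_at(ctx$fr, x), alpha)
    u <- logw_at(st_ctx$fr, x)
    v - exp(min(chi_upper_bound(u, beta), clamp))
  }
  grad <- function(x) {
    gtot <- numeric(d)
    for (ctx in spk_ctx) gtot <- gtot + gpi_chain(ctx, lin_u(ctx, x), alpha)
    gtot + grho_chain(st_ctx, lin_u(st_ctx, x), beta)
  }
  gpi_chain <- function(ctx, u, alpha) {
    # grad of pi(lin_u(x)): J' dpi; J_l. = u0_l G_l.; dpi_l = u_l^(a-1)/(L S)
    L <- length(u)
    S <- mean(u^alpha)
    if (S <= 0) return(numeric(ncol(ctx$G)))
    live <- u > 0
    coef <- numeric(L)
    coef[live] <- u[live]^(alpha - 1) / (L * S) * ctx$u0[live]
    drop(crossprod(ctx$G, coef))
  }
  grho_chain <- function(ctx, u, beta) {
    L <- length(u)
    if (ctx$dead) return(numeric(ncol(ctx$G)))
    M <- mean(u^beta)^(1 / beta)
    if (M <= 0) return(numeric(ncol(ctx$G)))
    coef <- -ctx$mult * M^(1 - beta) * u^(beta - 1) / L * ctx$u0
    drop(crossprod(ctx$G, coef))
  }
  neg_hess <- function(x) {
    H <- matrix(0, d, d)
    for (ctx in spk_ctx) {
      if (ctx$dead) next
      u <- lin_u(ctx, x)
      S <- mean(u^alpha)
      if (S <= 0) next
      live <- u > 0
      J <- ctx$G * ctx$u0 # L x d
      L <- length(u)
      dvec <- numeric(L)
      dvec[live] <- (1 - alpha) * u[live]^(alpha - 2) / (L * S)
      a1 <- numeric(L)
      a1[live] <- u[live]^(alpha - 1)
      # -H_pi = (1-a) diag(u^(a-2))/(LS) + a/(LS)^2 (u^(a-1))(u^(a-1))'
      H <- H + crossprod(J * sqrt(dvec)) +
        alpha / (L * S)^2 * tcrossprod(drop(crossprod(J, a1)))
    }
    u <- lin_u(st_ctx, x)
    Mb <- if (st_ctx$dead) 0 else mean(u^beta)
    if (Mb > 0) {
      M <- Mb^(1 / beta)
      L <- length(u)
      J <- st_ctx$G * st_ctx$u0
      live <- u > 0
      dvec <- numeric(L); dvec[live] <- u[live]^(beta - 2)
      b1 <- u^(beta - 1)
      # -H_rho = (b-1) [M^(1-b) diag(u^(b-2))/L - M^(1-2b) (u^(b-1)/L)(.)']
      Hr <- (beta - 1) * (M^(1 - beta) * crossprod(J * sqrt(dvec)) / L -
                            M^(1 - 2 * beta) * tcrossprod(drop(crossprod(J, b1 / L))))
      H <- H + st_ctx$mult * Hr
    }
    (H + t(H)) / 2
  }
  structure(list(value = value, value_frozen = value_frozen, grad = grad,
                 neg_hess = neg_hess, x_bar = x_bar, n_spikes = n_r),
            class = "concave_bin_bound")
}

#' Quadratic (linear-Gaussian) bin objective for testing and baselines
#'
#' Replaces the per-bin point-process bound by an exact Gaussian log-density
#' `log N(obs | x, prec)` (up to constants): `value`, `grad` and `neg_hess`
#' with the same interface as [concave_bin_bound()].
#'
#' @param obs observed pseudo-measurement of the bin state (length d)
#' @param prec d x d SPD precision (or diagonal vector)
#' @export
quadratic_bin_objective <- function(obs, prec) {
  d <- length(obs)
  P <- if (is.matrix(prec)) prec else diag(prec, d)
  v <- function(x) -0.5 * drop(t(x - obs) %*% P %*% (x - obs))
  structure(list(value = v, value_frozen = v,
                 grad = function(x) drop(P %*% (obs - x)),
                 neg_hess = function(x) P,
                 x_bar = obs, n_spikes = 0L),
            class = "concave_bin_bound")
}

prior_chain_info <- function(dyn, R) {
  d <- dyn$d
  dg <- replicate(R, matrix(0, d, d), simplify = FALSE)
  h <- replicate(R, numeric(d), simplify = FALSE)
  dg[[1]] <- dyn$V1
  h[[1]] <- drop(dyn$V1 %*% dyn$a1)
  off <- NULL
  if (R > 1L) {
    GtW <- t(dyn$F) %*% dyn$V
    for (r in 2:R) {
      dg[[r]] <- dg[[r]] + dyn$V
      dg[[r - 1L]] <- dg[[r - 1L]] + GtW %*% dyn$F
      h[[r]] <- h[[r]] + drop(dyn$V %*% dyn$a)
      h[[r - 1L]] <- h[[r - 1L]] - drop(GtW %*% dyn$a)
    }
    off <- replicate(R - 1L, -dyn$V %*% dyn$F, simplify = FALSE)
  }
  list(diag = dg, off = off %||% list(), h = h)
}

#' Laplace approximation of the state posterior given spikes alone
#'
#' Newton ascent on the concavified log joint density
#' `log p(x) + sum_r L_hat_r(x_r)`: at each outer iteration the latent samples
#' are redrawn at the current iterate with common random numbers (one noise
#' draw per spike/bin, fixed across iterations), the per-bin terms are
#' re-expanded, and a full Newton step on the concave surrogate is taken with
#' backtracking halving on the frozen objective. The final negative Hessian
#' (prior precision plus per-bin Gauss-Newton blocks) is the Laplace precision
#' and is positive definite by construction.
#'
#' @param model a [state_space_model()] (its `dyn` and `jmi` are used)
#' @param data binned test data (only `mark_sets` and `dt_bin` are used)
#' @param init R x d matrix of initial states; default: the prior mean path
#' @param K_max maximum Newton iterations
#' @param tol convergence threshold on the infinity norm of the accepted step
#' @param L_dec frozen latent samples per term
#' @param seed seed for the common random numbers
#' @param bin_objectives optional list of R precomputed `concave_bin_bound`-like
#'   objects (e.g. [quadratic_bin_objective()]), bypassing the intensity model
#' @return object of class `laplace_result`: `mean` (R x d), `precision`
#'   ([block_tridiag()]), `iterations`, `converged`, `objective_trace`
#' @export
newton_map <- function(model, data, init = NULL, K_max = 50L, tol = 1e-6,
                       L_dec = 32L, seed = 1L, bin_objectives = NULL) {
  dyn <- model$dyn
  d <- dyn$d
  R <- data$R
  prior <- prior_chain_info(dyn, R)
  if (is.null(init)) {
    init <- matrix(0, R, d)
    init[1, ] <- dyn$a1
    if (R > 1L) for (r in 2:R) init[r, ] <- drop(dyn$F %*% init[r - 1L, ]) + dyn$a
  }
  use_jmi <- is.null(bin_objectives)
  if (use_jmi) {
    rng <- local_rng(seed)
    d_z <- model$jmi$d_z
    eps_state <- lapply(seq_len(R), function(r)
      matrix(rng$norm(L_dec * d_z), L_dec, d_z))
    eps_spikes <- lapply(seq_len(R), function(r)
      lapply(seq_len(data$counts[r]), function(i)
        matrix(rng$norm(L_dec * d_z), L_dec, d_z)))
  }
  prior_quad <- function(xmat) { # log p(x) up to its constant
    v <- as.vector(t(xmat))
    Pv <- bt_matvec(prior$diag, prior$off, v)
    sum(unlist(prior$h) * v) - 0.5 * sum(v * Pv)
  }
  make_bounds <- function(x_bar_mat) {
    if (!use_jmi) {
      if (is.function(bin_objectives))
        return(lapply(seq_len(R), function(r) bin_objectives(r, x_bar_mat[r, ])))
      return(bin_objectives)
    }
    lapply(seq_len(R), function(r)
      concave_bin_bound(model$jmi, data$mark_sets[[r]], x_bar_mat[r, ],
                        dt = data$dt_bin, L = L_dec,
                        eps_spikes = eps_spikes[[r]], eps_state = eps_state[[r]]))
  }
  phi <- function(bounds, xmat) {
    prior_quad(xmat) + sum(vapply(seq_len(R), function(r)
      bounds[[r]]$value_frozen(xmat[r, ]), numeric(1)))
  }
  x <- init
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  H_fac <- NULL
  for (k in seq_len(K_max)) {
    iterations <- k
    bounds <- make_bounds(x)
    f0 <- phi(bounds, x)
    if (k == 1L) trace <- f0
    # assemble Newton system: negative Hessian and gradient
    dgH <- prior$diag
    grad <- -bt_matvec(prior$diag, prior$off, as.vector(t(x))) + unlist(prior$h)
    for (r in seq_len(R)) {
      dgH[[r]] <- dgH[[r]] + bounds[[r]]$neg_hess(x[r, ])
      grad[(r - 1L) * d + seq_len(d)] <- grad[(r - 1L) * d + seq_len(d)] +
        bounds[[r]]$grad(x[r, ])
    }
    H <- block_tridiag(dgH, prior$off)
    H_fac <- tryCatch(bt_factorize(H), error = function(e) NULL)
    jit <- 0L
    while (is.null(H_fac) && jit < 3L) {
      jit <- jit + 1L
      dgH <- lapply(dgH, function(Dk) Dk + diag(1e-6 * 10^jit, d))
      H <- block_tridiag(dgH, prior$off)
      H_fac <- tryCatch(bt_factorize(H), error = function(e) NULL)
    }
    if (is.null(H_fac))
      return(structure(list(mean = x, precision = NULL, iterations = k,
                            converged = FALSE, objective_trace = trace),
                       class = "laplace_result"))
    step <- matrix(bt_solve(H_fac, grad), R, d, byrow = TRUE)
    t_step <- 1
    accepted <- FALSE
    # terms linearized to zero curvature (e.g. the ground term) can yield very
    # long Newton steps; the directional derivative is positive, so enough
    # halvings always recover an ascent step
    for (bk in 0:30) {
      cand <- x + t_step * step
      # re-expand at the candidate so acceptance is measured on the frozen
      # objective at the new point (guards re-linearization noise)
      f_cand <- phi(make_bounds(cand), cand)
      if (is.finite(f_cand) && f_cand >= f0) {
        accepted <- TRUE
        break
      }
      t_step <- t_step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    x <- cand
    trace <- c(trace, f_cand)
    if (max(abs(t_step * step)) < tol) { converged <- TRUE; break }
  }
  # final precision at the solution
  bounds <- make_bounds(x)
  dgH <- prior$diag
  for (r in seq_len(R)) dgH[[r]] <- dgH[[r]] + bounds[[r]]$neg_hess(x[r, ])
  H <- block_tridiag(dgH, prior$off)
  ok <- tryCatch({ bt_factorize(H); TRUE }, error = function(e) FALSE)
  structure(list(mean = x, precision = if (ok) H else NULL,
                 iterations = iterations, converged = converged && ok,
                 objective_trace = trace),
            class = "laplace_result")
}

#' @export
print.laplace_result <- function(x, ...) {
  cat(sprintf("<laplace_result: %d bins, %d iterations, converged = %s>\n",
              nrow(x$mean), x$iterations, x$converged))
  invisible(x)
}

# block-tridiagonal matrix-vector product from block lists; off[[r]] is the
# block at (row r+1, column r), so row r picks up off[[r-1]] %*% v_{r-1} from
# below the diagonal and t(off[[r]]) %*% v_{r+1} from above it
bt_matvec <- function(dg, off, v) {
  R <- length(dg)
  d <- nrow(dg[[1]])
  out <- numeric(R * d)
  for (r in seq_len(R)) {
    i <- (r - 1L) * d + seq_len(d)
    acc <- dg[[r]] %*% v[i]
    if (r > 1L) acc <- acc + off[[r - 1L]] %*% v[i - d]
    if (r < R) acc <- acc + t(off[[r]]) %*% v[i + d]
    out[i] <- acc
  }
  out
}

#' Decode the covariate from the state posterior
#'
#' Samples latent paths from the Laplace posterior `N(mean, precision^{-1})`
#' and pushes them through the covariate observation model:
#' `y_hat_r = mean_s mu_y(x_{s,r})`, with predictive variance from the law of
#' total variance (mean observation variance plus variance of the means).
#'
#' @param model a [state_space_model()]
#' @param laplace a converged [newton_map()] result
#' @param S number of posterior samples
#' @param seed seed
#' @return tibble with columns `bin`, `dim`, `estimate`, `variance`
#' @export
decode_covariate <- function(model, laplace, S = 200L, seed = 1L) {
  if (is.null(laplace$precision))
    stop("Laplace result has no valid precision (not converged)", call. = FALSE)
  post <- posterior_gaussian(laplace$mean, laplace$precision)
  draws <- bt_sample(post, S, seed = seed) # S x R x d
  R <- dim(draws)[2]
  Dy <- model$d_y
  mean_acc <- matrix(0, R, Dy)
  m2_acc <- matrix(0, R, Dy)
  var_acc <- matrix(0, R, Dy)
  for (s in seq_len(S)) {
    oy <- gmap_eval(model$obs_y, matrix(draws[s, , ], R))
    mean_acc <- mean_acc + oy$mean
    m2_acc <- m2_acc + oy$mean^2
    var_acc <- var_acc + 1 / oy$prec
  }
  est <- mean_acc / S
  vtot <- var_acc / S + pmax(m2_acc / S - est^2, 0)
  tibble::tibble(bin = rep(seq_len(R), Dy),
                 dim = rep(seq_len(Dy), each = R),
                 estimate = as.vector(est),
                 variance = as.vector(vtot))
}

#' Mean squared decoding error
#'
#' `(1/R) sum_r || y_hat_r - y_r ||_2^2` over bins.
#'
#' @param y_hat,y_true R x D_y matrices (or a [decode_covariate()] tibble for
#'   `y_hat`)
#' @export
decode_mse <- function(y_hat, y_true) {
  if (tibble::is_tibble(y_hat)) {
    R <- max(y_hat$bin)
    y_hat <- matrix(y_hat$estimate[order(y_hat$dim, y_hat$bin)], R)
  }
  y_hat <- as.matrix(y_hat); y_true <- as.matrix(y_true)
  if (!all(dim(y_hat) == dim(y_true)))
    stop("shape mismatch between decoded and true covariates", call. = FALSE)
  mean(rowSums((y_hat - y_true)^2))
}
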