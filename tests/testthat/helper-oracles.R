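# Shared fixtures: tractable linear-Gaussian intensity models with closed-form
# evidences and exact-posterior encoders, random block-tridiagonal instances,
# and a central finite-difference helper.

fd_grad <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# A jmi_vae whose decoders are affine with constant precision, so p(x, k),
# p(x) and the latent posteriors are exact Gaussians. Returns the model with
# exact-posterior encoders installed plus closed-form evaluators.
linear_gaussian_jmi <- function(d_x = 3L, d_k = 4L, d_z = 2L, lambda0 = 2,
                                seed = 1L) {
  rng <- markvae:::local_rng(seed)
  Ax <- matrix(rng$norm(d_z * d_x), d_z, d_x); ax <- rng$norm(d_x)
  Ak <- matrix(rng$norm(d_z * d_k), d_z, d_k); ak <- rng$norm(d_k)
  Px <- diag(d_x) * 2; Pk <- diag(d_k) * 1.5
  model <- jmi_vae(d_x, d_k, d_z, hidden = c(4L), lambda0_init = lambda0,
                   seed = seed)
  model$decoder_x <- affine_gauss_map(Ax, ax, Px)
  model$decoder_k <- affine_gauss_map(Ak, ak, Pk)
  Ppost <- diag(d_z) + Ax %*% Px %*% t(Ax) + Ak %*% Pk %*% t(Ak)
  Sol <- solve(Ppost, cbind(Ax %*% Px, Ak %*% Pk))
  model$encoder_xk <- affine_gauss_map(t(Sol), -drop(Sol %*% c(ax, ak)), Ppost)
  Ppx <- diag(d_z) + Ax %*% Px %*% t(Ax)
  Solx <- solve(Ppx, Ax %*% Px)
  model$encoder_x <- affine_gauss_map(t(Solx), -drop(Solx %*% ax), Ppx)
  Aj <- cbind(Ax, Ak)
  Sj <- t(Aj) %*% Aj + rbind(cbind(solve(Px), matrix(0, d_x, d_k)),
                             cbind(matrix(0, d_k, d_x), solve(Pk)))
  Sx <- t(Ax) %*% Ax + solve(Px)
  list(
    model = model,
    log_p_joint = function(x, k)
      gauss_logpdf(matrix(c(x, k), 1L), c(ax, ak), solve(Sj)),
    log_p_x = function(x) gauss_logpdf(matrix(x, 1L), ax, solve(Sx)),
    d_x = d_x, d_k = d_k, d_z = d_z
  )
}

rand_bt_spd <- function(R, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  off <- lapply(seq_len(max(R - 1L, 0L)), function(r)
    matrix(rnorm(d * d, sd = 0.3), d, d))
  dg <- lapply(seq_len(R), function(r)
    crossprod(matrix(rnorm(d * d), d, d)) + diag(d) * (d + 2))
  block_tridiag(dg, off)
}

# tiny binned dataset with random marks
toy_binned <- function(R, d_y, d_k, counts, seed = 1L) {
  set.seed(seed)
  marks <- lapply(counts, function(nr) matrix(rnorm(nr * d_k), nr, d_k))
  structure(list(dt_bin = 0.1, R = R, y = matrix(rnorm(R * d_y), R, d_y),
                 mark_sets = marks, counts = as.integer(counts)),
            class = "binned_dataset")
}
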