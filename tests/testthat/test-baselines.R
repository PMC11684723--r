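test_that("GMM closed forms: mode evaluation, marginal identity, linearity", {
  g <- gmm_intensity_model(lambda = c(2, 5), mu_x = rbind(c(0, 0), c(1, 1)),
                           prec_x = rbind(c(1, 2), c(2, 1)),
                           mu_k = rbind(-1, 2), prec_k = rbind(4, 1))
  # single-component peak evaluation
  g1 <- gmm_intensity_model(3, rbind(c(0, 0)), rbind(c(1, 2)),
                            rbind(-1), rbind(4))
  peak <- 3 * exp(gauss_logpdf(matrix(0, 1, 2), c(0, 0), c(1, 2))) *
    exp(gauss_logpdf(matrix(-1, 1, 1), -1, 4))
  expect_equal(gmm_intensity(g1, c(0, 0), -1), drop(peak))
  # kappa-marginal identity against quadrature (1-d mark)
  x0 <- c(0.3, -0.1)
  quad <- stats::integrate(function(k)
    vapply(k, function(kk) gmm_intensity(g, x0, kk), numeric(1)),
    -20, 25, rel.tol = 1e-10)$value
  expect_lt(abs(quad - gmm_ground_intensity(g, x0)) / gmm_ground_intensity(g, x0),
            1e-3)
  # scaling all lambda_l by 2 doubles both intensities
  g2 <- g; g2$lambda <- 2 * g$lambda
  expect_equal(gmm_intensity(g2, x0, 0.5), 2 * gmm_intensity(g, x0, 0.5))
  expect_equal(gmm_ground_intensity(g2, x0), 2 * gmm_ground_intensity(g, x0))
  expect_error(gmm_intensity(g, matrix(0, 2, 2), matrix(0, 3, 1)), "matching")
})

test_that("GMM fitting: zero iterations, monotone trace, parameter recovery", {
  rng <- markvae:::local_rng(21)
  R <- 4000; dt <- 0.01
  xg <- matrix(0, R, 2)
  for (r in 2:R) xg[r, ] <- 0.995 * xg[r - 1, ] + rng$norm(2) * 0.2
  g_true <- gmm_intensity_model(60, rbind(c(0.5, -0.5)), rbind(c(2, 2)),
                                rbind(c(1, -1)), rbind(c(4, 4)))
  lam <- gmm_ground_intensity(g_true, xg)
  ns <- rng$pois(R, lam * dt)
  rows <- rep(seq_len(R), ns)
  n <- length(rows)
  xs <- xg[rows, , drop = FALSE]
  ks <- matrix(rng$norm(n * 2) * 0.5, n, 2) +
    matrix(c(1, -1), n, 2, byrow = TRUE)
  init <- gmm_fit(xs, ks, xg, dt, L_c = 1, iters = 0, seed = 3)
  expect_equal(nrow(init$trace), 0L)
  fit <- gmm_fit(xs, ks, xg, dt, L_c = 1, iters = 200, seed = 3)
  # non-decreasing up to floating-point noise at the converged plateau
  expect_gt(min(diff(fit$trace$loglik)), -1e-10)
  # posterior-scale recovery: means within a few empirical SEs, scale within 15%
  expect_lt(max(abs(fit$model$mu_x - c(0.5, -0.5))), 4 / sqrt(n) * 3 + 0.15)
  expect_lt(max(abs(fit$model$mu_k - c(1, -1))), 3 * 0.5 / sqrt(n) + 0.05)
  # total-rate consistency: fitted intensity integrates to about n
  expect_lt(abs(sum(gmm_ground_intensity(fit$model, xg)) * dt - n) / n, 0.1)
  expect_lt(abs(fit$model$lambda - 60) / 60, 0.3)
})

test_that("homogeneous-rate recovery on flat-tuning generator output", {
  dec <- waveform_decoder(seed = 2)
  flat <- mixture_intensity_model(lambda = 8, c_dirs = matrix(0, 1, 3),
                                  d_dirs = matrix(0, 1, 3),
                                  z_means = matrix(0, 1, 2),
                                  z_precs = list(diag(2)), decoder = dec, T = 30)
  path <- matrix(markvae:::local_rng(3)$norm(3000 * 3), 3000, 3)
  ev <- simulate_spikes(flat, path, 0.01, seed = 7)
  xs <- state_at_spikes(covariate_series(0.01, path), ev$times)
  fit <- gmm_fit(xs, ev$marks, path, 0.01, L_c = 1, iters = 120, seed = 5)
  n <- length(ev$times)
  expect_lt(abs(sum(gmm_ground_intensity(fit$model, path)) * 0.01 - n) / n, 0.1)
})

test_that("GMM per-bin objective matches the exact likelihood and its gradient", {
  set.seed(71)
  g <- gmm_intensity_model(lambda = c(2, 5), mu_x = rbind(c(0, 0), c(1, 1)),
                           prec_x = rbind(c(1, 2), c(2, 1)),
                           mu_k = rbind(-1, 2), prec_k = rbind(4, 1))
  marks <- matrix(rnorm(3), 3, 1)
  xb <- c(0.2, 0.4)
  ob <- gmm_bin_objective(g, marks, xb, dt = 0.03)
  exact <- sum(log(gmm_intensity(g, matrix(xb, 3, 2, byrow = TRUE), marks))) -
    0.03 * gmm_ground_intensity(g, xb)
  expect_equal(ob$value_frozen(xb), exact, tolerance = 1e-12)
  expect_equal(ob$value(xb), exact, tolerance = 1e-12)
  fd <- fd_grad(ob$value_frozen, xb)
  expect_lt(max(abs(ob$grad(xb) - fd)), 1e-6)
  eig <- eigen(-ob$neg_hess(xb + 0.3), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(eig), 1e-10)
})

test_that("AR(1) dynamics estimation recovers a linear-Gaussian chain", {
  set.seed(72)
  R <- 3000; d <- 2
  F_true <- matrix(c(0.9, 0.05, -0.02, 0.85), 2, 2)
  a_true <- c(0.1, -0.05)
  y <- matrix(0, R, d)
  for (r in 2:R) y[r, ] <- drop(F_true %*% y[r - 1, ]) + a_true + rnorm(d) * 0.3
  dyn <- estimate_lg_dynamics(y)
  expect_lt(max(abs(dyn$F - F_true)), 0.05)
  expect_lt(max(abs(dyn$a - a_true)), 0.05)
  expect_lt(max(abs(solve(dyn$V) - diag(0.09, 2))), 0.02)
})

test_that("Holm-Sidak adjustment: formula, dominance, monotonicity", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  set.seed(73)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_false(is.unsorted(adj[order(p)]))
  }
})

test_that("paired Wilcoxon harness: identical columns, separation, errors", {
  idc <- tibble::tibble(trial = rep(1:6, 2), model = rep(c("A", "B"), each = 6),
                        value = rep(seq_len(6), 2))
  res <- wilcoxon_holm_sidak(idc)
  expect_equal(res$p_raw, 1); expect_equal(res$p_adj, 1)
  set.seed(74)
  sc <- tibble::tibble(trial = rep(1:10, 3),
                       model = rep(c("A", "B", "C"), each = 10),
                       value = c(rnorm(10), rnorm(10) + 3, rnorm(10) + 3.2))
  res3 <- wilcoxon_holm_sidak(sc)
  expect_equal(nrow(res3), 3L)
  expect_true(all(res3$p_adj >= res3$p_raw - 1e-12))
  ab <- res3$p_adj[res3$model1 == "A" & res3$model2 == "B"]
  expect_lt(ab, 0.05)
  short <- tibble::tibble(trial = rep(1:3, 2), model = rep(c("A", "B"), each = 3),
                          value = rnorm(6))
  expect_error(wilcoxon_holm_sidak(short), "at least 5")
  unpaired <- sc[-1, ]
  expect_error(wilcoxon_holm_sidak(unpaired), "unpaired|missing")
})

test_that("GMM decoding tracks the covariate on an informative fixture", {
  # marks strongly indicate which of two state clusters generated each spike
  rng <- markvae:::local_rng(31)
  R <- 400; dt <- 0.02
  y <- matrix(0, R, 1)
  for (r in 2:R) y[r, ] <- 0.98 * y[r - 1, ] + rng$norm(1) * 0.25
  g_true <- gmm_intensity_model(lambda = c(40, 40),
                                mu_x = rbind(1.2, -1.2),
                                prec_x = rbind(2, 2),
                                mu_k = rbind(c(2, 0), c(-2, 0)),
                                prec_k = matrix(4, 2, 2))
  lam <- gmm_ground_intensity(g_true, y)
  ns <- rng$pois(R, lam * dt)
  rows <- rep(seq_len(R), ns)
  resp <- t(vapply(rows, function(r) {
    w <- g_true$lambda * exp(markvae:::gmm_log_nx(g_true, y[r, , drop = FALSE]))
    w / sum(w)
  }, numeric(2)))
  comp <- ifelse(rng$unif(length(rows)) < resp[, 1], 1L, 2L)
  ks <- g_true$mu_k[comp, , drop = FALSE] +
    matrix(rng$norm(2 * length(rows)) * 0.5, ncol = 2)
  times <- (rows - 0.5) * dt
  ev <- marked_events(times, ks, duration_T = R * dt)
  data <- bin_events(ev, covariate_series(dt, y), dt)
  dyn <- estimate_lg_dynamics(y)
  dec <- gmm_decode(g_true, dyn, data, K_max = 60, L_dec = 8, seed = 2)
  expect_true(dec$laplace$converged)
  # decoding must beat the constant mean predictor
  mse_dec <- decode_mse(dec$y_hat, y)
  mse_mean <- decode_mse(matrix(mean(y), R, 1), y)
  expect_lt(mse_dec, mse_mean)
})
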