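test_that("chain-plus-experts assembly: single factor and scalar product", {
  # R = 1, only q(x1) = N(0, I): posterior is N(0, I)
  chain <- lg_dynamics(2)
  post <- assemble_chain_gaussian(chain, list(list()), R = 1)
  expect_equal(post$mean, matrix(0, 1, 2))
  expect_equal(post$precision$diag[[1]], diag(2))
  # two scalar factors N(.|0, prec 1) and N(.|2, prec 1) on one bin
  post2 <- assemble_chain_gaussian(NULL,
                                   list(list(list(mean = 0, prec = 1),
                                             list(mean = 2, prec = 1))), R = 1)
  expect_equal(drop(post2$mean), 1)
  expect_equal(post2$precision$diag[[1]], matrix(2, 1, 1))
})

test_that("structured posterior matches a dense Gaussian-product oracle", {
  set.seed(41)
  for (rep in 1:20) {
    R <- sample(2:6, 1); d <- sample(2:4, 1)
    d_y <- sample(1:3, 1); d_k <- sample(2:5, 1)
    q <- structured_var_family(d, d_y, d_k, hidden = c(4), seed = rep)
    q$qdyn <- lg_dynamics(d, a1 = rnorm(d),
                          V1 = crossprod(matrix(rnorm(d * d), d)) + diag(d),
                          F = matrix(rnorm(d * d, sd = 0.3), d),
                          a = rnorm(d),
                          V = crossprod(matrix(rnorm(d * d), d)) + diag(d))
    counts <- sample(0:3, R, replace = TRUE)
    data <- toy_binned(R, d_y, d_k, counts, seed = rep + 100)
    post <- build_structured_posterior(q, data)
    # dense oracle: accumulate all factors in information form
    blk <- function(r) (r - 1) * d + seq_len(d)
    P <- matrix(0, R * d, R * d); h <- numeric(R * d)
    ch <- q$qdyn
    P[blk(1), blk(1)] <- ch$V1; h[blk(1)] <- ch$V1 %*% ch$a1
    for (r in 2:R) {
      P[blk(r), blk(r)] <- P[blk(r), blk(r)] + ch$V
      P[blk(r - 1), blk(r - 1)] <- P[blk(r - 1), blk(r - 1)] +
        t(ch$F) %*% ch$V %*% ch$F
      P[blk(r), blk(r - 1)] <- P[blk(r), blk(r - 1)] - ch$V %*% ch$F
      P[blk(r - 1), blk(r)] <- P[blk(r - 1), blk(r)] - t(ch$F) %*% ch$V
      h[blk(r)] <- h[blk(r)] + ch$V %*% ch$a
      h[blk(r - 1)] <- h[blk(r - 1)] - t(ch$F) %*% ch$V %*% ch$a
    }
    ey <- gmap_eval(q$enc_y, data$y)
    bp <- markvae:::softplus(q$base_rawprec) + 1e-4
    for (r in seq_len(R)) {
      P[blk(r), blk(r)] <- P[blk(r), blk(r)] + diag(ey$prec[r, ]) + diag(bp)
      h[blk(r)] <- h[blk(r)] + ey$prec[r, ] * ey$mean[r, ] + bp * q$base_mean
      if (counts[r] > 0) {
        ek <- gmap_eval(q$enc_k, data$mark_sets[[r]])
        for (i in seq_len(counts[r])) {
          P[blk(r), blk(r)] <- P[blk(r), blk(r)] + diag(ek$prec[i, ])
          h[blk(r)] <- h[blk(r)] + ek$prec[i, ] * ek$mean[i, ]
        }
      }
    }
    expect_lt(max(abs(bt_dense(post$precision) - P)), 1e-8)
    expect_lt(max(abs(as.vector(t(post$mean)) - solve(P, h))), 1e-8)
  }
})

# linear-Gaussian spike-free state-space model with exact-posterior family and
# simulated observations; returns everything the oracle comparisons need
linear_ssm_fixture <- function(R = 6, seed = 8) {
  d <- 2; Dy <- 2
  jmi <- jmi_vae(d, 3, 2, hidden = c(4), lambda0_init = exp(-50), seed = 3)
  model <- state_space_model(d, Dy, jmi, hidden = integer(0), seed = 4)
  model$obs_y$params$Wm <- diag(1.5, d)
  model$obs_y$params$bm <- rep(0.3, Dy)
  model$obs_y$params$Wp <- matrix(0, d, Dy)
  model$obs_y$params$bp <- rep(log(expm1(2 - 1e-4)), Dy)
  model$dyn <- lg_dynamics(d, a1 = c(0.5, -0.5), V1 = diag(d) * 1.2,
                           F = 0.9 * diag(d), a = c(0.1, 0), V = diag(d) * 2)
  rng <- markvae:::local_rng(seed)
  x <- matrix(0, R, d)
  x[1, ] <- model$dyn$a1 + rng$norm(d) / sqrt(1.2)
  for (r in 2:R) x[r, ] <- 0.9 * x[r - 1, ] + model$dyn$a + rng$norm(d) / sqrt(2)
  y <- 1.5 * x + 0.3 + matrix(rng$norm(R * Dy), R, Dy) / sqrt(2)
  data <- structure(list(dt_bin = 0.1, R = R, y = y,
                         mark_sets = replicate(R, matrix(0, 0, 3),
                                               simplify = FALSE),
                         counts = rep(0L, R)), class = "binned_dataset")
  qf <- structured_var_family(d, Dy, 3, hidden = integer(0), seed = 5)
  qf$qdyn <- model$dyn
  qf$enc_y$params$Wm <- diag(1 / 1.5, Dy)
  qf$enc_y$params$bm <- rep(-0.3 / 1.5, d)
  qf$enc_y$params$Wp <- matrix(0, Dy, d)
  qf$enc_y$params$bp <- rep(log(expm1(4.5 - 1e-4)), d)
  qf$base_rawprec <- rep(-60, d)
  # dense log marginal likelihood of y
  blk <- function(r) (r - 1) * d + seq_len(d)
  P <- matrix(0, R * d, R * d); h <- numeric(R * d)
  P[blk(1), blk(1)] <- model$dyn$V1; h[blk(1)] <- model$dyn$V1 %*% model$dyn$a1
  for (r in 2:R) {
    P[blk(r), blk(r)] <- P[blk(r), blk(r)] + model$dyn$V
    P[blk(r - 1), blk(r - 1)] <- P[blk(r - 1), blk(r - 1)] +
      t(model$dyn$F) %*% model$dyn$V %*% model$dyn$F
    P[blk(r), blk(r - 1)] <- P[blk(r), blk(r - 1)] - model$dyn$V %*% model$dyn$F
    P[blk(r - 1), blk(r)] <- P[blk(r - 1), blk(r)] - t(model$dyn$F) %*% model$dyn$V
    h[blk(r)] <- h[blk(r)] + model$dyn$V %*% model$dyn$a
    h[blk(r - 1)] <- h[blk(r - 1)] - t(model$dyn$F) %*% model$dyn$V %*% model$dyn$a
  }
  Sx <- solve(P); mx <- Sx %*% h
  Cb <- kronecker(diag(R), diag(1.5, d))
  Sy <- Cb %*% Sx %*% t(Cb) + diag(1 / 2, R * Dy)
  my <- drop(Cb %*% mx + 0.3)
  true_ll <- gauss_logpdf(matrix(as.vector(t(y)), 1), my, solve(Sy))
  list(model = model, q = qf, data = data, true_ll = drop(true_ll))
}

test_that("ELBO matches the exact log evidence with the exact posterior", {
  fx <- linear_ssm_fixture()
  elbos <- vapply(1:6, function(s)
    ssm_elbo(fx$model, fx$q, fx$data, n_mc = 32, seed = s), numeric(1))
  expect_lt(abs(mean(elbos) - fx$true_ll), 1e-3)
  # and the estimator is a lower bound in expectation for a perturbed family
  qp <- fx$q
  qp$qdyn$a <- qp$qdyn$a + 0.5
  elbos_p <- vapply(1:6, function(s)
    ssm_elbo(fx$model, qp, fx$data, n_mc = 256, seed = s), numeric(1))
  expect_lt(mean(elbos_p), fx$true_ll)
  # bound ordering: exact posterior beats the perturbed one
  expect_gt(mean(elbos), mean(elbos_p))
})

test_that("ELBO is deterministic given a seed and consistent in n_mc", {
  fx <- linear_ssm_fixture()
  qp <- fx$q; qp$qdyn$a <- qp$qdyn$a + 0.3
  e1 <- ssm_elbo(fx$model, qp, fx$data, n_mc = 8, seed = 5)
  expect_identical(e1, ssm_elbo(fx$model, qp, fx$data, n_mc = 8, seed = 5))
  reps1 <- vapply(1:12, function(s) ssm_elbo(fx$model, qp, fx$data, 16, s),
                  numeric(1))
  reps2 <- vapply(13:24, function(s) ssm_elbo(fx$model, qp, fx$data, 32, s),
                  numeric(1))
  se <- sqrt(stats::var(reps1) / 12 + stats::var(reps2) / 12)
  expect_lt(abs(mean(reps1) - mean(reps2)), 4 * se)
  # predict_nll is the negative ELBO
  expect_equal(ssm_predict_nll(fx$model, qp, fx$data, n_mc = 4, seed = 2),
               -ssm_elbo(fx$model, qp, fx$data, n_mc = 4, seed = 2))
})

test_that("predict_nll upper-bounds the exact NLL and degrades under corruption", {
  fx <- linear_ssm_fixture()
  qp <- fx$q; qp$enc_y$params$bm <- qp$enc_y$params$bm + 0.4
  nlls <- vapply(1:10, function(s)
    ssm_predict_nll(fx$model, qp, fx$data, n_mc = 64, seed = s), numeric(1))
  expect_gt(mean(nlls), -fx$true_ll)
  bad <- fx$model
  bad$obs_y$params$bm <- bad$obs_y$params$bm + 3 # always-wrong offset
  nll_bad <- ssm_predict_nll(bad, fx$q, fx$data, n_mc = 32, seed = 3)
  nll_ok <- ssm_predict_nll(fx$model, fx$q, fx$data, n_mc = 32, seed = 3)
  expect_gt(nll_bad, nll_ok)
})

test_that("joint fitting: zero steps is the identity; stable at the truth", {
  fx <- linear_ssm_fixture()
  out0 <- fit_ssm(fx$model, fx$q, fx$data, fx$data, epochs = 0)
  expect_identical(out0$model$obs_y$params, fx$model$obs_y$params)
  expect_identical(out0$q$qdyn, fx$q$qdyn)
  # initialized at the truth, validation ELBO does not collapse over epochs
  base <- ssm_elbo(fx$model, fx$q, fx$data, n_mc = 64, seed = 91)
  out <- fit_ssm(fx$model, fx$q, fx$data, fx$data, epochs = 6, lr = 1e-3,
                 n_mc = 2, segment_len = 10, seed = 92)
  expect_gt(max(out$trace$val), base - 2) # no catastrophic degradation
})

test_that("state-space training improves a spiking fixture's validation ELBO", {
  cfg <- synthetic_config(T = 4, n_probes = 1L, seed = 3)
  tdir <- tempfile(); dir.create(tdir)
  tr <- make_trials(1, cfg, seeds = 17L, dir = tdir)
  ds <- load_dataset(tr$file[1])
  fit <- fit_clusterless(ds$sequences, ds$covariate, cfg$dt,
                         split = list(train = c(1, 320), validation = c(321, 400)),
                         d_x = 4, d_z = 2, hidden = c(8, 8),
                         bound_cfg = bound_config(L = 3),
                         epochs = 4, lr = 5e-3, segment_len = 80, seed = 5)
  expect_gt(max(fit$trace$val), fit$elbo_init)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
})
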