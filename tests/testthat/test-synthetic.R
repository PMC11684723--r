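lorenz_fp <- function(cfg = lorenz_config()) {
  c(sqrt(cfg$gamma * (cfg$rho - 1)), sqrt(cfg$gamma * (cfg$rho - 1)),
    cfg$rho - 1)
}

test_that("Lorenz integrator: fixed point, drift, RK4 order", {
  cfg <- lorenz_config(T = 1)
  fp <- lorenz_fp(cfg)
  expect_lt(max(abs(markvae:::lorenz_deriv(fp, cfg))), 1e-12)
  path <- lorenz_path(lorenz_config(x0 = fp, T = 1), 0.01)
  expect_lt(max(abs(sweep(path, 2, fp))), 1e-3)
  # Richardson-style order check: halving the step shrinks the endpoint error
  # by about 2^4
  ends <- lapply(c(2e-3, 1e-3, 5e-4), function(h)
    lorenz_path(lorenz_config(x0 = c(1, 1, 25), T = 1, dt_int = h), 1)[1, ])
  ratio <- max(abs(ends[[1]] - ends[[3]])) / max(abs(ends[[2]] - ends[[3]]))
  expect_gt(ratio, 8); expect_lt(ratio, 40)
  expect_error(lorenz_path(cfg, 0.0015), "integer multiple")
})

test_that("covariate projections", {
  path <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE)
  expect_equal(make_covariate(path, "3D", 0.1)$values, path)
  p2 <- make_covariate(path, "2D", 0.1)$values
  expect_equal(p2, path[, c(1, 3)])
  expect_equal(p2, make_covariate(path, "3D", 0.1)$values[, c(1, 3)])
})

test_that("mixture intensity: flat tuning, endpoint drift, swap flag", {
  dec <- waveform_decoder(seed = 2)
  flat <- mixture_intensity_model(lambda = 1.5, c_dirs = matrix(0, 1, 3),
                                  d_dirs = matrix(0, 1, 3),
                                  z_means = matrix(0, 1, 2),
                                  z_precs = list(diag(2)), decoder = dec, T = 10)
  for (t in c(0, 3, 10)) expect_equal(mixture_intensity(flat, t, rnorm(3)), 1.5)
  expect_error(mixture_intensity(flat, -1, rep(0, 3)), "outside")
  drift <- mixture_intensity_model(lambda = 2, c_dirs = matrix(c(1, 0, 0), 1),
                                   d_dirs = matrix(c(0, 1, 0), 1),
                                   z_means = matrix(0, 1, 2),
                                   z_precs = list(diag(2)), decoder = dec, T = 10)
  x <- c(0.3, -0.2, 0.1)
  # as printed, the weight t/T multiplies c: direction is d at t = 0, c at t = T
  expect_equal(mixture_intensity(drift, 0, x), 2 * exp(-0.2))
  expect_equal(mixture_intensity(drift, 10, x), 2 * exp(0.3))
  swapped <- mixture_intensity_model(lambda = 2, c_dirs = matrix(c(1, 0, 0), 1),
                                     d_dirs = matrix(c(0, 1, 0), 1),
                                     z_means = matrix(0, 1, 2),
                                     z_precs = list(diag(2)), decoder = dec,
                                     T = 10, swap_cd = TRUE)
  expect_equal(mixture_intensity(swapped, 0, x), 2 * exp(0.3))
})

test_that("closed-form mark factor matches a Monte Carlo estimate", {
  dec <- waveform_decoder(seed = 3)
  mix <- mixture_intensity_model(lambda = 1, c_dirs = matrix(0, 1, 3),
                                 d_dirs = matrix(0, 1, 3),
                                 z_means = matrix(c(0.4, -0.6), 1),
                                 z_precs = list(diag(2) * 2), decoder = dec,
                                 T = 10)
  mm <- mix$mark_marg[[1]]
  set.seed(61)
  k0 <- drop(gauss_sample(matrix(mm$mean, 1), solve(mm$cov),
                          matrix(rnorm(32), 1)))
  S <- 40000L
  z <- matrix(rnorm(S * 2) / sqrt(2), S, 2) +
    matrix(c(0.4, -0.6), S, 2, byrow = TRUE)
  out <- gmap_eval(dec, z)
  dens <- exp(gauss_logpdf(matrix(k0, S, 32, byrow = TRUE), out$mean, dec$prec))
  mc <- mean(dens)
  se <- stats::sd(dens) / sqrt(S)
  cf <- exp(gauss_logpdf(matrix(k0, 1), mm$mean, solve(mm$cov)))
  expect_lt(abs(mc - cf), 3 * se)
  # intensity with the mark factor
  expect_equal(mixture_intensity(mix, 2, rep(0, 3), k0), cf)
})

test_that("thinning simulation: zero-rate, determinism, Poisson counts", {
  dec <- waveform_decoder(seed = 2)
  path <- matrix(rnorm(1000 * 3), 1000, 3)
  tiny <- mixture_intensity_model(lambda = 1e-12, c_dirs = matrix(0, 1, 3),
                                  d_dirs = matrix(0, 1, 3),
                                  z_means = matrix(0, 1, 2),
                                  z_precs = list(diag(2)), decoder = dec, T = 10)
  expect_length(simulate_spikes(tiny, path, 0.01, seed = 1)$times, 0)
  flat <- mixture_intensity_model(lambda = 5, c_dirs = matrix(0, 1, 3),
                                  d_dirs = matrix(0, 1, 3),
                                  z_means = matrix(0, 1, 2),
                                  z_precs = list(diag(2)), decoder = dec, T = 10)
  e1 <- simulate_spikes(flat, path, 0.01, seed = 4)
  e2 <- simulate_spikes(flat, path, 0.01, seed = 4)
  expect_identical(e1$times, e2$times)
  expect_identical(e1$marks, e2$marks)
  e3 <- simulate_spikes(flat, path, 0.01, seed = 5)
  expect_false(identical(length(e1$times), length(e3$times)) &&
                 isTRUE(all.equal(e1$times, e3$times)))
  counts <- vapply(1:80, function(s)
    length(simulate_spikes(flat, path, 0.01, seed = s)$times), numeric(1))
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 80))
  expect_gt(stats::var(counts) / mean(counts), 0.6)
  expect_lt(stats::var(counts) / mean(counts), 1.4)
  # empirical mark mean approaches the closed-form marginal mark mean
  big <- simulate_spikes(mixture_intensity_model(lambda = 120,
                                                 c_dirs = matrix(0, 1, 3),
                                                 d_dirs = matrix(0, 1, 3),
                                                 z_means = matrix(c(0.5, 0), 1),
                                                 z_precs = list(diag(2) * 2),
                                                 decoder = dec, T = 10),
                         path, 0.01, seed = 6)
  mm_mean <- drop(matrix(c(0.5, 0), 1) %*% dec$A)
  n <- length(big$times)
  sds <- apply(big$marks, 2, stats::sd)
  expect_true(all(abs(colMeans(big$marks) - mm_mean) < 4 * sds / sqrt(n) + 1e-8))
})

test_that("time-rescaled inter-event intervals are Exp(1) (KS)", {
  cfg <- synthetic_config(T = 20, n_probes = 1L, seed = 5)
  mix <- synthetic_mixtures(cfg)[[1]]
  path <- lorenz_path(cfg$lorenz, cfg$dt)
  ev <- simulate_spikes(mix, path, cfg$dt, seed = 8)
  expect_gt(length(ev$times), 500)
  Lam <- cumulative_ground_intensity(mix, path, cfg$dt, ev$times)
  gaps <- diff(c(0, Lam))
  expect_gt(stats::ks.test(gaps, stats::pexp, 1)$p.value, 0.01)
  # expected-count conservation: total transformed time ~ N
  expect_lt(abs(max(Lam) - length(ev$times)) / length(ev$times), 0.15)
})

test_that("trial generation: files, splits and determinism", {
  cfg <- synthetic_config(T = 2, n_probes = 2L, seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  tr1 <- make_trials(1, cfg, seeds = 3L, dir = d1)
  tr2 <- make_trials(1, cfg, seeds = 3L, dir = d2)
  got <- load_dataset(tr1$file[1])
  expect_length(got$sequences, 2L)
  expect_equal(ncol(got$covariate$values), 3L)
  binned <- bin_events(got$sequences[[1]], got$covariate, cfg$dt)
  expect_equal(binned$R, 200L)
  split <- jsonlite::read_json(tr1$manifest[1], simplifyVector = TRUE)
  expect_equal(split$train, c(1, 160))
  expect_equal(split$validation, c(161, 180))
  expect_equal(split$test, c(181, 200))
  # same seed gives identical datasets; different seeds differ
  g2 <- load_dataset(tr2$file[1])
  expect_identical(got$sequences[[1]]$times, g2$sequences[[1]]$times)
  tr3 <- make_trials(1, cfg, seeds = 4L, dir = tempfile())
  g3 <- load_dataset(tr3$file[1])
  expect_false(length(g3$sequences[[1]]$times) == length(got$sequences[[1]]$times) &&
                 isTRUE(all.equal(g3$sequences[[1]]$times, got$sequences[[1]]$times)))
})
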