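#' Lorenz-attractor hidden dynamics
#'
#' Configuration and fixed-step RK4 integration of the Lorenz system
#' `dx1 = sigma (x2 - x1); dx2 = x1 (rho - x3) - x2; dx3 = x1 x2 - gamma x3`.
#' The three parameters are the classical sigma/rho/gamma (often written as
#' alpha/beta/gamma in dynamical-systems texts); the chaotic regime
#' `sigma = 10, rho = 28, gamma = 8/3` is the default.
#'
#' @param sigma,rho,gamma Lorenz parameters
#' @param dt_int integrator step, seconds
#' @param x0 initial 3-vector
#' @param T duration, seconds
#' @export
lorenz_config <- function(sigma = 10, rho = 28, gamma = 8 / 3,
                          dt_int = 1e-3, x0 = c(1, 1, 25), T = 100) {
  stopifnot(dt_int > 0, T > 0, length(x0) == 3L)
  structure(list(sigma = sigma, rho = rho, gamma = gamma, dt_int = dt_int,
                 x0 = as.numeric(x0), T = T),
            class = "lorenz_config")
}

lorenz_deriv <- function(x, cfg) {
  c(cfg$sigma * (x[2] - x[1]),
    x[1] * (cfg$rho - x[3]) - x[2],
    x[1] * x[2] - cfg$gamma * x[3])
}

#' Integrate the Lorenz system and subsample the path
#'
#' Classical fourth-order Runge-Kutta with fixed step `cfg$dt_int`, subsampled
#' to `sample_dt` (an integer multiple of the integrator step). The returned
#' matrix has one row per sample time `j * sample_dt`, `j = 1..T/sample_dt`
#' (the initial state at t = 0 is not included, matching the (0, T] grid).
#'
#' @param cfg a [lorenz_config()]
#' @param sample_dt output grid spacing, seconds
#' @return (T/sample_dt) x 3 matrix
#' @export
lorenz_path <- function(cfg, sample_dt = cfg$dt_int) {
  ratio <- sample_dt / cfg$dt_int
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    stop("sample_dt must be a positive integer multiple of dt_int", call. = FALSE)
  ratio <- as.integer(round(ratio))
  n_out <- as.integer(round(cfg$T / sample_dt))
  h <- cfg$dt_int
  x <- cfg$x0
  out <- matrix(0, n_out, 3L)
  for (j in seq_len(n_out)) {
    for (s in seq_len(ratio)) {
      k1 <- lorenz_deriv(x, cfg)
      k2 <- lorenz_deriv(x + h / 2 * k1, cfg)
      k3 <- lorenz_deriv(x + h / 2 * k2, cfg)
      k4 <- lorenz_deriv(x + h * k3, cfg)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (!all(is.finite(x)))
      stop("Lorenz integration diverged (non-finite state)", call. = FALSE)
    out[j, ] <- x
  }
  out
}

#' Observed covariate from the hidden Lorenz path
#'
#' In the 3D setting the covariate equals the hidden state; in the 2D setting
#' it is the projection dropping the second coordinate (so one generating
#' dimension is unobserved).
#'
#' @param path n x 3 matrix from [lorenz_path()]
#' @param mode `"3D"` or `"2D"`
#' @param dt grid spacing of the path, seconds
#' @return a [covariate_series()]
#' @export
make_covariate <- function(path, mode = c("3D", "2D"), dt) {
  mode <- match.arg(mode)
  values <- if (mode == "3D") path else path[, c(1L, 3L), drop = FALSE]
  covariate_series(dt, values)
}

#' Ground-truth mixture joint mark intensity
#'
#' The generator's intensity has `L_c` components; component l contributes
#' `lambda_l * exp(u_l(t)' x)` with a tuning direction that drifts linearly in
#' time, `u_l(t) = (t/T) c_l + (1 - t/T) d_l` (a simple model of tuning
#' plasticity), times a closed-form Gaussian mark density: marks are produced
#' by an affine Gaussian decoder `kappa = A z + m + noise` applied to a
#' component-specific Gaussian latent `z ~ N(mu_l, Lambda_l^{-1})`, so the
#' marginal mark density of component l is
#' `N(kappa | A mu_l + m, A Sigma_l A' + Sigma_noise)`.
#'
#' Note the endpoint convention: as written, the drift weight attaches `c_l`
#' to `t/T`, so the tuning direction is `d_l` at t = 0 and `c_l` at t = T.
#' `swap_cd = TRUE` swaps the roles.
#'
#' @param lambda numeric vector of component scales (> 0)
#' @param c_dirs,d_dirs L_c x 3 matrices of tuning directions
#' @param z_means L_c x d_z latent prior means
#' @param z_precs list of L_c SPD d_z x d_z latent prior precisions
#' @param decoder an [affine_gauss_map()] z -> mark
#' @param T duration, seconds
#' @param swap_cd swap the roles of `c_dirs` and `d_dirs` in the drift
#' @export
mixture_intensity_model <- function(lambda, c_dirs, d_dirs, z_means, z_precs,
                                    decoder, T, swap_cd = FALSE) {
  c_dirs <- as.matrix(c_dirs); d_dirs <- as.matrix(d_dirs)
  z_means <- as.matrix(z_means)
  Lc <- length(lambda)
  stopifnot(all(lambda > 0), nrow(c_dirs) == Lc, nrow(d_dirs) == Lc,
            nrow(z_means) == Lc, length(z_precs) == Lc,
            inherits(decoder, "affine_gauss_map"))
  if (swap_cd) { tmp <- c_dirs; c_dirs <- d_dirs; d_dirs <- tmp }
  d_z <- ncol(z_means)
  # closed-form component mark marginals (affine decoder)
  Sig_noise <- solve(decoder$prec)
  mark_marg <- lapply(seq_len(Lc), function(l) {
    Sig_z <- solve(z_precs[[l]])
    mean <- drop(z_means[l, ] %*% decoder$A) + decoder$offset
    cov <- t(decoder$A) %*% Sig_z %*% decoder$A + Sig_noise
    list(mean = mean, cov = (cov + t(cov)) / 2)
  })
  structure(list(lambda = lambda, c_dirs = c_dirs, d_dirs = d_dirs,
                 z_means = z_means, z_precs = z_precs, decoder = decoder,
                 T = T, d_z = d_z, D_k = decoder$d_out, L_c = Lc,
                 mark_marg = mark_marg),
            class = "mixture_intensity")
}

tuning_dir <- function(mix, t) {
  w <- t / mix$T
  w * mix$c_dirs + (1 - w) * mix$d_dirs
}

#' Per-component ground intensity at (t, x)
#' @keywords internal
mixture_component_rates <- function(mix, t, x) {
  U <- tuning_dir(mix, t) # L_c x 3
  mix$lambda * exp(drop(U %*% x))
}

#' Evaluate the generator's joint mark intensity
#'
#' With `k = NULL` returns the ground intensity (the mark density integrates
#' to one, leaving the exponential-tuning sum); otherwise multiplies each
#' component rate by its closed-form marginal mark density.
#'
#' @param mix a [mixture_intensity_model()]
#' @param t time in \[0, T\]
#' @param x hidden state 3-vector
#' @param k mark vector or NULL
#' @return nonnegative scalar
#' @export
mixture_intensity <- function(mix, t, x, k = NULL) {
  if (t < 0 || t > mix$T) stop("t outside [0, T]", call. = FALSE)
  rates <- mixture_component_rates(mix, t, x)
  if (is.null(k)) return(sum(rates))
  dens <- vapply(seq_len(mix$L_c), function(l) {
    mm <- mix$mark_marg[[l]]
    exp(gauss_logpdf(matrix(k, 1L), mm$mean, solve(mm$cov)))
  }, numeric(1))
  sum(rates * dens)
}

#' Simulate marked spikes along a state path by thinning
#'
#' Exact (Ogata-style) simulation of the inhomogeneous marked process: the
#' ground intensity along the path (nearest-sample state, linear drift in t)
#' is dominated per time segment by 1.2 x its maximum over the path grid;
#' candidate times from the dominating homogeneous rate are accepted with
#' probability intensity/majorant. If the exact intensity ever exceeds the
#' majorant (possible between grid points), the majorant is inflated and the
#' segment re-simulated, with a warning. Each accepted event draws its
#' component with probability proportional to the per-component intensity,
#' then a latent `z` from the component prior, then a mark from the decoder.
#'
#' @param mix a [mixture_intensity_model()]
#' @param path n x 3 hidden state path on the grid `j * sample_dt`
#' @param sample_dt path grid spacing, seconds
#' @param seed integer seed
#' @param segment_len majorant segment length, seconds
#' @param probe_id optional label for the output
#' @return a [marked_events()]
#' @export
simulate_spikes <- function(mix, path, sample_dt, seed = 1L, segment_len = 0.5,
                            probe_id = NULL) {
  rng <- local_rng(seed)
  n_grid <- nrow(path)
  Tdur <- n_grid * sample_dt
  grid_t <- seq_len(n_grid) * sample_dt
  ground_at <- function(t) {
    j <- min(max(1L, floor(t / sample_dt + 0.5 + 1e-9)), n_grid)
    mixture_component_rates(mix, t, path[j, ])
  }
  grid_rate <- vapply(grid_t, function(t) sum(ground_at(t)), numeric(1))
  if (any(!is.finite(grid_rate)))
    stop("ground intensity not finite along the path", call. = FALSE)
  seg_starts <- seq(0, Tdur - 1e-12, by = segment_len)
  times <- numeric(0)
  comps <- integer(0)
  for (s0 in seg_starts) {
    s1 <- min(s0 + segment_len, Tdur)
    in_seg <- grid_t > s0 - sample_dt & grid_t <= s1 + sample_dt
    maj <- 1.2 * max(grid_rate[in_seg], 0)
    repeat {
      if (maj <= 0) break
      n_prop <- rng$pois(1L, maj * (s1 - s0))
      if (n_prop == 0) { accepted <- list(t = numeric(0), c = integer(0)); break }
      t_prop <- sort(s0 + rng$unif(n_prop) * (s1 - s0))
      rates_prop <- lapply(t_prop, ground_at)
      tot <- vapply(rates_prop, sum, numeric(1))
      if (any(tot > maj)) {
        warning("majorant violated; inflating and re-simulating segment")
        maj <- 1.5 * max(tot, maj)
        next
      }
      u <- rng$unif(n_prop)
      keep <- u < tot / maj
      comp <- integer(sum(keep))
      ki <- 0L
      for (i in which(keep)) {
        ki <- ki + 1L
        p <- rates_prop[[i]]
        comp[ki] <- if (mix$L_c == 1L) 1L else rng$sample_int(mix$L_c, 1L, prob = p)
      }
      accepted <- list(t = t_prop[keep], c = comp)
      break
    }
    times <- c(times, accepted$t)
    comps <- c(comps, accepted$c)
  }
  n <- length(times)
  marks <- matrix(0, n, mix$D_k)
  if (n) {
    zeps <- matrix(rng$norm(n * mix$d_z), n, mix$d_z)
    keps <- matrix(rng$norm(n * mix$D_k), n, mix$D_k)
    for (i in seq_len(n)) {
      l <- comps[i]
      z <- gauss_sample(matrix(mix$z_means[l, ], 1L), mix$z_precs[[l]],
                        zeps[i, , drop = FALSE])
      out <- gmap_eval(mix$decoder, z)
      marks[i, ] <- gauss_sample(out$mean, out$prec, keps[i, , drop = FALSE])
    }
  }
  times <- pmin(pmax(times, .Machine$double.eps), Tdur)
  marked_events(times, marks, duration_T = Tdur, probe_id = probe_id)
}

#' A spike-waveform-like affine mark decoder
#'
#' Maps a low-dimensional latent to a concatenated multi-site waveform snippet
#' (32 samples per site) through smooth bump-shaped basis columns — a
#' depolarization trough followed by a repolarization hump — so generated
#' marks qualitatively resemble extracellular spike waveforms. Synthetic by
#' construction; no real recording parameters are used.
#'
#' @param d_z latent dimension
#' @param n_sites recording sites (mark dimension is 32 * n_sites)
#' @param noise_sd mark observation noise standard deviation
#' @param seed seed for small random site-weight variation
#' @export
waveform_decoder <- function(d_z = 2L, n_sites = 1L, noise_sd = 0.08, seed = 1L) {
  rng <- local_rng(seed)
  s <- seq_len(32L)
  trough <- -exp(-(s - 10)^2 / 10)
  hump <- 0.45 * exp(-(s - 19)^2 / 40)
  base <- trough + hump
  A <- matrix(0, d_z, 32L * n_sites)
  for (site in seq_len(n_sites)) {
    cols <- (site - 1L) * 32L + s
    w <- 0.4 + rng$unif(d_z) # per-site latent loading
    for (j in seq_len(d_z)) {
      shift <- (j - 1L) * 2L
      shape <- c(rep(0, shift), base)[seq_len(32L)]
      A[j, cols] <- w[j] * shape
    }
  }
  affine_gauss_map(A, offset = rep(0, 32L * n_sites),
                   prec = diag(1 / noise_sd^2, 32L * n_sites))
}

#' Default synthetic study configuration
#'
#' One call bundles the full generator: Lorenz hidden dynamics, per-probe
#' four-component drifting-tuning intensities, and waveform-like marks. Scales
#' (`T`, probes, components) default to the full study setting; pass smaller
#' values for fixtures.
#'
#' @param T duration, seconds
#' @param dt time grid, seconds
#' @param n_probes number of probes
#' @param n_components mixture components per probe
#' @param rate_scale per-component base rate scale
#' @param mode covariate mode, `"3D"` or `"2D"`
#' @param swap_cd see [mixture_intensity_model()]
#' @param seed integer seed
#' @export
synthetic_config <- function(T = 100, dt = 0.01, n_probes = 4L,
                             n_components = 4L, rate_scale = 4,
                             mode = "3D", swap_cd = FALSE, seed = 1L) {
  structure(list(T = T, dt = dt, n_probes = n_probes,
                 n_components = n_components, rate_scale = rate_scale,
                 mode = mode, swap_cd = swap_cd, seed = seed,
                 lorenz = lorenz_config(T = T)),
            class = "synthetic_config")
}

#' Build the per-probe mixture intensities for a configuration
#' @param cfg a [synthetic_config()]
#' @keywords internal
#' @export
synthetic_mixtures <- function(cfg) {
  rng <- local_rng(cfg$seed + 1000L)
  lapply(seq_len(cfg$n_probes), function(pr) {
    Lc <- cfg$n_components
    # the Lorenz state has magnitude O(10-40); direction entries ~N(0, 0.05)
    # give exponents of order +-1.5, i.e. peak/trough rate ratios around
    # 10-30x, comparable to place-field modulation depths; with scale 4 per
    # component this yields multiunit rates of roughly 40-80 Hz per probe
    c_dirs <- matrix(rng$norm(Lc * 3) * 0.05, Lc, 3L)
    d_dirs <- matrix(rng$norm(Lc * 3) * 0.05, Lc, 3L)
    z_means <- matrix(rng$norm(Lc * 2) * 1.5, Lc, 2L)
    z_precs <- lapply(seq_len(Lc), function(l) diag(2) * (2 + rng$unif(1)))
    dec <- waveform_decoder(d_z = 2L, n_sites = 1L, seed = cfg$seed + pr)
    mixture_intensity_model(lambda = rep(cfg$rate_scale, Lc),
                            c_dirs = c_dirs, d_dirs = d_dirs,
                            z_means = z_means, z_precs = z_precs,
                            decoder = dec, T = cfg$T, swap_cd = cfg$swap_cd)
  })
}

#' Generate trials of synthetic data on disk
#'
#' Each trial integrates a Lorenz path from a perturbed initial condition,
#' simulates marked spikes per probe by thinning, and writes the dataset in
#' the documented layout, plus a JSON manifest of contiguous train/validation/
#' test splits (80/10/10 in whole bins, remainder to training).
#'
#' @param n_trials number of trials
#' @param cfg a [synthetic_config()]
#' @param seeds integer vector of per-trial seeds (length `n_trials`)
#' @param dir output directory
#' @return tibble with one row per trial: file, n_spikes per probe, split bins
#' @export
make_trials <- function(n_trials, cfg, seeds, dir) {
  stopifnot(length(seeds) == n_trials)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mixes <- synthetic_mixtures(cfg)
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    rng <- local_rng(seeds[tr])
    lz <- cfg$lorenz
    lz$x0 <- lz$x0 + rng$norm(3L) * 2
    path <- lorenz_path(lz, sample_dt = cfg$dt)
    cov <- make_covariate(path, mode = cfg$mode, dt = cfg$dt)
    seqs <- lapply(seq_along(mixes), function(pr) {
      simulate_spikes(mixes[[pr]], path, cfg$dt, seed = seeds[tr] * 131L + pr,
                      probe_id = paste0("probe", pr))
    })
    names(seqs) <- paste0("probe", seq_along(mixes))
    file <- file.path(dir, sprintf("trial%02d.rds", tr))
    save_dataset(seqs, cov, file)
    R <- nrow(cov$values)
    n_train <- floor(0.8 * R); n_val <- floor(0.1 * R); n_test <- floor(0.1 * R)
    n_train <- R - n_val - n_test # remainder to training
    split <- list(train = c(1L, n_train),
                  validation = c(n_train + 1L, n_train + n_val),
                  test = c(n_train + n_val + 1L, R))
    manifest <- file.path(dir, sprintf("trial%02d_split.json", tr))
    jsonlite::write_json(split, manifest, auto_unbox = FALSE)
    rows[[tr]] <- tibble::tibble(
      trial = tr, file = file, manifest = manifest,
      n_spikes = sum(vapply(seqs, function(s) length(s$times), numeric(1))),
      R = R, train_end = n_train, val_end = n_train + n_val)
  }
  dplyr::bind_rows(rows)
}

#' Cumulative ground intensity along a path (trapezoid rule)
#'
#' Integrates the generator's ground intensity over (0, t] for each requested
#' time, using the same nearest-sample state convention as the simulator; the
#' time-rescaling theorem maps inter-event intervals through this integral to
#' Exp(1) variables when the simulator is exact.
#'
#' @param mix a [mixture_intensity_model()]
#' @param path,sample_dt as in [simulate_spikes()]
#' @param times evaluation times
#' @export
cumulative_ground_intensity <- function(mix, path, sample_dt, times) {
  n_grid <- nrow(path)
  grid_t <- seq_len(n_grid) * sample_dt
  rate <- vapply(seq_len(n_grid), function(j)
    sum(mixture_component_rates(mix, grid_t[j], path[j, ])), numeric(1))
  # trapezoid cumulative integral on (0, t]; rate at t=0 taken as rate[1]
  rate0 <- rate[1]
  cum <- c(0, cumsum((c(rate0, rate[-n_grid]) + rate) / 2 * sample_dt))
  grid0 <- c(0, grid_t)
  vapply(times, function(t) {
    stats::approx(grid0, cum, xout = t, rule = 2)$y
  }, numeric(1))
}
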