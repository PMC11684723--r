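#' Gaussian conditional maps: neural networks and affine oracles
#'
#' Every conditional distribution in the model family (decoders, encoders, the
#' covariate observation map) is a Gaussian whose mean and precision are
#' functions of the conditioning input. Two implementations share one
#' interface:
#'
#' * `gaussian_net()` — a multilayer perceptron with two heads: a linear mean
#'   head and a diagonal precision head passed through softplus with a floor of
#'   1e-4, so the output precision is positive definite by construction. With
#'   `hidden = integer(0)` both heads act on the input directly, giving an
#'   exactly affine mean (used for linear-Gaussian special cases).
#' * `affine_gauss_map()` — an affine mean with a *constant* (possibly full)
#'   precision matrix. Affine maps have closed-form marginals and posteriors,
#'   so they serve as the tractable oracles in the tests and as the synthetic
#'   generator's waveform decoder.
#'
#' `gmap_eval(map, X)` returns `list(mean, prec)` where `mean` is n-by-d_out
#' and `prec` is either an n-by-d_out matrix of diagonal entries
#' (`prec_type = "diag"`) or a single d_out-by-d_out matrix
#' (`prec_type = "full"`).
#'
#' @param d_in,d_out input and output dimension
#' @param hidden integer vector of hidden-layer widths
#' @param activation hidden activation, `"tanh"` only
#' @param prec_init approximate initial diagonal precision value
#' @param seed integer seed for reproducible initialization
#' @return an object of class `gaussian_net` or `affine_gauss_map`
#' @export
gaussian_net <- function(d_in, d_out, hidden = c(64L, 64L), activation = "tanh",
                         prec_init = 1, seed = 1L) {
  stopifnot(d_in >= 1L, d_out >= 1L, activation == "tanh")
  hidden <- as.integer(hidden) # length 0 gives an exactly affine mean head
  rng <- local_rng(seed)
  dims <- c(d_in, hidden)
  params <- list()
  for (i in seq_along(hidden)) {
    sd <- sqrt(2 / (dims[i] + dims[i + 1]))
    params[[paste0("W", i)]] <- matrix(rng$norm(dims[i] * dims[i + 1]) * sd, dims[i], dims[i + 1])
    params[[paste0("b", i)]] <- rep(0, dims[i + 1])
  }
  h_last <- if (length(hidden)) hidden[length(hidden)] else d_in
  sd <- sqrt(2 / (h_last + d_out))
  params$Wm <- matrix(rng$norm(h_last * d_out) * sd, h_last, d_out)
  params$bm <- rep(0, d_out)
  params$Wp <- matrix(rng$norm(h_last * d_out) * sd * 0.1, h_last, d_out)
  # softplus(x) = prec_init - floor at x = log(expm1(.))
  params$bp <- rep(log(expm1(max(prec_init - 1e-4, 1e-3))), d_out)
  structure(list(params = params, d_in = d_in, d_out = d_out, hidden = hidden,
                 prec_type = "diag", prec_floor = 1e-4),
            class = "gaussian_net")
}

#' @rdname gaussian_net
#' @param A d_in-by-d_out coefficient matrix
#' @param offset length-d_out offset vector
#' @param prec d_out-by-d_out SPD precision matrix
#' @export
affine_gauss_map <- function(A, offset, prec) {
  A <- as.matrix(A)
  prec <- as.matrix(prec)
  stopifnot(ncol(A) == length(offset), nrow(prec) == length(offset),
            isTRUE(all.equal(prec, t(prec), tolerance = 1e-10)))
  structure(list(A = A, offset = offset, prec = prec,
                 d_in = nrow(A), d_out = ncol(A), prec_type = "full"),
            class = "affine_gauss_map")
}

#' Evaluate a Gaussian conditional map
#' @param map a `gaussian_net` or `affine_gauss_map`
#' @param X n-by-d_in input matrix (rows are inputs)
#' @return `list(mean, prec)`; see [gaussian_net()]
#' @export
gmap_eval <- function(map, X) UseMethod("gmap_eval")

#' @export
gmap_eval.gaussian_net <- function(map, X) {
  X <- as_matrix_rows(X, map$d_in)
  H <- X
  nlayer <- length(map$hidden)
  for (i in seq_len(nlayer)) {
    H <- tanh(sweep(H %*% map$params[[paste0("W", i)]], 2L, map$params[[paste0("b", i)]], "+"))
  }
  mean <- sweep(H %*% map$params$Wm, 2L, map$params$bm, "+")
  raw <- sweep(H %*% map$params$Wp, 2L, map$params$bp, "+")
  prec <- softplus(raw) + map$prec_floor
  list(mean = mean, prec = prec)
}

#' @export
gmap_eval.affine_gauss_map <- function(map, X) {
  X <- as_matrix_rows(X, map$d_in)
  list(mean = sweep(X %*% map$A, 2L, map$offset, "+"), prec = map$prec)
}

#' Tape forward pass of a Gaussian network
#'
#' @param tp tape
#' @param pnodes named list of tape node ids for the network parameters (as
#'   produced by registering `net$params` with [tp_param()])
#' @param Xnode tape node id of the n-by-d_in input
#' @param net the `gaussian_net` (for architecture metadata)
#' @return `list(mean = id, prec = id)` of n-by-d_out nodes
#' @export
gnet_forward_tp <- function(tp, pnodes, Xnode, net) {
  H <- Xnode
  for (i in seq_along(net$hidden)) {
    H <- tp_tanh(tp, tp_addbias(tp, tp_matmul(tp, H, pnodes[[paste0("W", i)]]),
                                pnodes[[paste0("b", i)]]))
  }
  mean <- tp_addbias(tp, tp_matmul(tp, H, pnodes$Wm), pnodes$bm)
  raw <- tp_addbias(tp, tp_matmul(tp, H, pnodes$Wp), pnodes$bp)
  prec <- tp_addc(tp, tp_softplus(tp, raw), net$prec_floor)
  list(mean = mean, prec = prec)
}

## ---- numeric Gaussian utilities ----

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

as_matrix_rows <- function(X, d) {
  if (is.matrix(X)) {
    stopifnot(ncol(X) == d)
    X
  } else {
    stopifnot(length(X) == d)
    matrix(X, 1L, d)
  }
}

#' Row-wise Gaussian log-density with diagonal or shared full precision
#'
#' @param X n-by-d observations
#' @param mean n-by-d means (or length-d vector recycled over rows)
#' @param prec n-by-d diagonal precision entries, a length-d vector, or a
#'   single d-by-d SPD matrix
#' @return length-n vector of log densities
#' @export
gauss_logpdf <- function(X, mean, prec) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (!is.matrix(mean)) mean <- matrix(mean, nrow(X), d, byrow = TRUE)
  diffn <- X - mean
  if (is.matrix(prec) && identical(dim(prec), c(1L, 1L)) && d == 1L)
    prec <- as.numeric(prec)
  if (is.matrix(prec) && nrow(prec) == d && ncol(prec) == d && d > 1L) {
    L <- t(chol(prec))
    u <- diffn %*% L # rows: t(L) %*% diff ... (diff' L)(L' diff) = diff' P diff
    quad <- rowSums(u^2)
    0.5 * (2 * sum(log(diag(L))) - quad) - 0.5 * d * log(2 * pi)
  } else {
    if (!is.matrix(prec)) prec <- matrix(prec, nrow(X), d, byrow = TRUE)
    quad <- rowSums(prec * diffn^2)
    0.5 * (rowSums(log(prec)) - quad) - 0.5 * d * log(2 * pi)
  }
}

#' Draw from row-wise Gaussians given mean and precision
#'
#' @inheritParams gauss_logpdf
#' @param eps n-by-d matrix of standard normal noise (the reparameterization
#'   noise; supply it for common-random-number schemes)
#' @return n-by-d samples
#' @export
gauss_sample <- function(mean, prec, eps) {
  mean <- as.matrix(mean)
  d <- ncol(mean)
  if (is.matrix(prec) && identical(dim(prec), c(1L, 1L)) && d == 1L)
    prec <- as.numeric(prec)
  if (is.matrix(prec) && nrow(prec) == d && ncol(prec) == d && d > 1L) {
    L <- t(chol(prec)) # prec = L L', cov = L^-T L^-1, x = mean + L^-T eps
    mean + t(backsolve(t(L), t(eps), upper.tri = TRUE))
  } else {
    if (!is.matrix(prec)) prec <- matrix(prec, nrow(mean), d, byrow = TRUE)
    mean + eps / sqrt(prec)
  }
}

# Diagonal-precision variants used where the caller knows prec is an n x d
# matrix of diagonal entries (avoids the n == d shape ambiguity of the
# polymorphic versions).
gauss_logpdf_diag <- function(X, mean, prec) {
  d <- ncol(X)
  quad <- rowSums(prec * (X - mean)^2)
  0.5 * (rowSums(log(prec)) - quad) - 0.5 * d * log(2 * pi)
}

gauss_sample_diag <- function(mean, prec, eps) mean + eps / sqrt(prec)

## ---- parameter registry ----

#' Flatten a nested parameter list to dotted names
#' @param pl nested named list of numeric arrays
#' @keywords internal
#' @export
params_flatten <- function(pl, prefix = NULL) {
  out <- list()
  for (nm in names(pl)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    x <- pl[[nm]]
    if (is.list(x)) out <- c(out, params_flatten(x, key)) else out[[key]] <- x
  }
  out
}

#' Write dotted-name parameters back into a nested list
#' @keywords internal
#' @export
params_unflatten <- function(pl, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    pl[[path]] <- flat[[key]]
  }
  pl
}

## ---- Adam optimizer ----

#' Adam optimizer over a named list of arrays
#'
#' @param flat named list of numeric arrays (parameters)
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decays and stabilizer
#' @return an optimizer state; advance it with [adam_step()]
#' @export
adam_new <- function(flat, lr = 1e-2, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero <- lapply(flat, function(x) { x[] <- 0; x })
  list(m = zero, v = zero, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' @rdname adam_new
#' @param state optimizer state
#' @param grads named list of gradients (same shapes as the parameters);
#'   gradients of a quantity being *maximized* should be passed with
#'   `maximize = TRUE`
#' @param maximize ascend instead of descend
#' @return `list(flat, state)` with updated parameters and state
#' @export
adam_step <- function(state, flat, grads, maximize = FALSE) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (maximize) g <- -g
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    flat[[nm]] <- flat[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(flat = flat, state = state)
}

## ---- seeded RNG stream ----

#' A local RNG stream that does not disturb the global .Random.seed
#' @keywords internal
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(
    norm = with_state(function(n) stats::rnorm(n)),
    unif = with_state(function(n) stats::runif(n)),
    pois = with_state(function(n, lambda) stats::rpois(n, lambda)),
    sample_int = with_state(function(n, size, prob = NULL, replace = FALSE)
      sample.int(n, size, replace = replace, prob = prob)),
    derive = with_state(function() sample.int(.Machine$integer.max - 1L, 1L))
  )
}
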