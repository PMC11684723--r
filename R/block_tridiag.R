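#' Block-tridiagonal symmetric positive-definite matrices
#'
#' The structured variational posterior over a latent state path, the Laplace
#' precision in decoding, and the prior of the linear-Gaussian chain all have a
#' precision matrix whose only nonzero blocks couple temporally adjacent state
#' vectors. This class stores the R diagonal blocks (d x d) and the R - 1
#' subdiagonal blocks, and supports Cholesky factorization, linear solves,
#' log-determinants and exact Gaussian sampling in O(R d^3) time and O(R d^2)
#' memory — never materializing the dense (R d) x (R d) matrix.
#'
#' @param diag list of R symmetric d x d blocks (diagonal asymmetry above 1e-8
#'   triggers a warning; blocks are symmetrized on input)
#' @param offdiag list of R - 1 blocks; `offdiag[[r]]` couples block r + 1
#'   (row) to block r (column)
#' @return an object of class `block_tridiag`
#' @export
block_tridiag <- function(diag, offdiag = list()) {
  stopifnot(is.list(diag), length(diag) >= 1L, is.list(offdiag),
            length(offdiag) == length(diag) - 1L)
  d <- nrow(as.matrix(diag[[1]]))
  diag <- lapply(diag, function(Dk) {
    Dk <- as.matrix(Dk)
    stopifnot(nrow(Dk) == d, ncol(Dk) == d)
    asym <- max(abs(Dk - t(Dk)))
    if (asym > 1e-8)
      warning(sprintf("diagonal block asymmetry %.2e symmetrized", asym))
    (Dk + t(Dk)) / 2
  })
  offdiag <- lapply(offdiag, function(Ok) {
    Ok <- as.matrix(Ok)
    stopifnot(nrow(Ok) == d, ncol(Ok) == d)
    Ok
  })
  structure(list(R = length(diag), d = d, diag = diag, offdiag = offdiag),
            class = "block_tridiag")
}

#' @export
print.block_tridiag <- function(x, ...) {
  cat(sprintf("<block_tridiag SPD: R = %d blocks of size %d x %d>\n", x$R, x$d, x$d))
  invisible(x)
}

#' Assemble the dense matrix (for oracles and small problems only)
#' @param P a `block_tridiag`
#' @export
bt_dense <- function(P) {
  R <- P$R; d <- P$d
  M <- matrix(0, R * d, R * d)
  for (r in seq_len(R)) {
    i <- (r - 1L) * d + seq_len(d)
    M[i, i] <- P$diag[[r]]
    if (r < R) {
      j <- r * d + seq_len(d)
      M[j, i] <- P$offdiag[[r]]
      M[i, j] <- t(P$offdiag[[r]])
    }
  }
  M
}

#' Block Cholesky factorization
#'
#' Computes the lower block-bidiagonal factor L with `P = L %*% t(L)`: R lower
#' triangular diagonal blocks and R - 1 subdiagonal blocks, by the forward
#' block recursion. Fails with the index of the first non-positive-definite
#' Schur complement.
#'
#' @param P a [block_tridiag()]
#' @return object of class `bt_chol` with fields `Ld` (list of lower-triangular
#'   diagonal blocks) and `Lo` (list of subdiagonal blocks)
#' @export
bt_factorize <- function(P) {
  R <- P$R; d <- P$d
  Ld <- vector("list", R)
  Lo <- vector("list", max(R - 1L, 0L))
  S <- P$diag[[1]]
  for (r in seq_len(R)) {
    U <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(U))
      stop(sprintf("block %d: Schur complement not positive definite", r),
           call. = FALSE)
    Ld[[r]] <- t(U)
    if (r < R) {
      # L[r+1, r] = O_r L_rr^{-T} = t( L_rr^{-1} t(O_r) )
      Lo[[r]] <- t(forwardsolve(Ld[[r]], t(P$offdiag[[r]])))
      S <- P$diag[[r + 1]] - tcrossprod(Lo[[r]])
    }
  }
  structure(list(R = R, d = d, Ld = Ld, Lo = Lo), class = "bt_chol")
}

#' Solve P x = b using a block Cholesky factor
#'
#' @param fac a `bt_chol` from [bt_factorize()] (or a `block_tridiag`, which is
#'   factorized on the fly)
#' @param rhs numeric vector of length R*d or matrix with R*d rows
#' @return solution with the shape of `rhs`
#' @export
bt_solve <- function(fac, rhs) {
  if (inherits(fac, "block_tridiag")) fac <- bt_factorize(fac)
  R <- fac$R; d <- fac$d
  v <- is.null(dim(rhs))
  Y <- if (v) matrix(rhs, ncol = 1L) else as.matrix(rhs)
  stopifnot(nrow(Y) == R * d)
  # forward: L u = rhs
  U <- Y
  for (r in seq_len(R)) {
    i <- (r - 1L) * d + seq_len(d)
    acc <- Y[i, , drop = FALSE]
    if (r > 1L) {
      im <- (r - 2L) * d + seq_len(d)
      acc <- acc - fac$Lo[[r - 1L]] %*% U[im, , drop = FALSE]
    }
    U[i, ] <- forwardsolve(fac$Ld[[r]], acc)
  }
  # backward: t(L) x = u
  X <- U
  for (r in seq(R, 1L)) {
    i <- (r - 1L) * d + seq_len(d)
    acc <- U[i, , drop = FALSE]
    if (r < R) {
      ip <- r * d + seq_len(d)
      acc <- acc - t(fac$Lo[[r]]) %*% X[ip, , drop = FALSE]
    }
    X[i, ] <- backsolve(t(fac$Ld[[r]]), acc, upper.tri = TRUE)
  }
  if (v) drop(X) else X
}

#' Log-determinant from the block Cholesky factor
#' @inheritParams bt_solve
#' @export
bt_logdet <- function(fac) {
  if (inherits(fac, "block_tridiag")) fac <- bt_factorize(fac)
  2 * sum(vapply(fac$Ld, function(L) sum(log(diag(L))), numeric(1)))
}

#' Gaussian over a state path with block-tridiagonal precision
#'
#' @param mean R x d matrix of per-bin means
#' @param precision a [block_tridiag()]
#' @export
posterior_gaussian <- function(mean, precision) {
  mean <- as.matrix(mean)
  stopifnot(inherits(precision, "block_tridiag"),
            nrow(mean) == precision$R, ncol(mean) == precision$d)
  structure(list(mean = mean, precision = precision), class = "posterior_gaussian")
}

#' @export
print.posterior_gaussian <- function(x, ...) {
  cat(sprintf("<posterior_gaussian: %d bins x %d dims>\n",
              x$precision$R, x$precision$d))
  invisible(x)
}

#' Sample state paths from a block-tridiagonal Gaussian
#'
#' Draws `x = mean + L^{-T} eps` with `P = L t(L)` and standard normal `eps`,
#' so draws have covariance `P^{-1}`; cost linear in R. Deterministic given
#' `seed`.
#'
#' @param post a [posterior_gaussian()]
#' @param n_samples number of draws
#' @param seed integer seed (independent of the global RNG state)
#' @param eps optional (R*d) x n_samples matrix of standard normal noise,
#'   overriding `seed` (for common-random-number schemes)
#' @return array of dim c(n_samples, R, d)
#' @export
bt_sample <- function(post, n_samples, seed = 1L, eps = NULL) {
  fac <- bt_factorize(post$precision)
  R <- fac$R; d <- fac$d
  if (is.null(eps)) {
    rng <- local_rng(seed)
    eps <- matrix(rng$norm(R * d * n_samples), R * d, n_samples)
  } else {
    stopifnot(nrow(eps) == R * d, ncol(eps) == n_samples)
  }
  # backward substitution t(L) u = eps
  X <- eps
  for (r in seq(R, 1L)) {
    i <- (r - 1L) * d + seq_len(d)
    acc <- eps[i, , drop = FALSE]
    if (r < R) {
      ip <- r * d + seq_len(d)
      acc <- acc - t(fac$Lo[[r]]) %*% X[ip, , drop = FALSE]
    }
    X[i, ] <- backsolve(t(fac$Ld[[r]]), acc, upper.tri = TRUE)
  }
  mu <- as.vector(t(post$mean)) # stacked by bin: entries (r-1)*d + 1..d are bin r
  out <- array(0, dim = c(n_samples, R, d))
  for (s in seq_len(n_samples)) {
    out[s, , ] <- matrix(X[, s] + mu, R, d, byrow = TRUE)
  }
  out
}

#' Log-density of stacked state paths under a block-tridiagonal Gaussian
#'
#' @param post a [posterior_gaussian()]
#' @param paths array c(n, R, d) or a single R x d matrix
#' @export
bt_logpdf <- function(post, paths) {
  if (is.matrix(paths)) paths <- array(paths, dim = c(1L, dim(paths)))
  fac <- bt_factorize(post$precision)
  R <- fac$R; d <- fac$d
  ld <- bt_logdet(fac)
  mu <- as.vector(t(post$mean))
  n <- dim(paths)[1]
  out <- numeric(n)
  for (s in seq_len(n)) {
    v <- as.vector(t(matrix(paths[s, , ], R, d))) - mu
    # quad = v' P v = || t(L) v ||^2; compute t(L) v blockwise
    q <- 0
    for (r in seq_len(R)) {
      i <- (r - 1L) * d + seq_len(d)
      u <- t(fac$Ld[[r]]) %*% v[i]
      if (r < R) u <- u + t(fac$Lo[[r]]) %*% v[r * d + seq_len(d)]
      q <- q + sum(u^2)
    }
    out[s] <- 0.5 * (ld - q) - 0.5 * R * d * log(2 * pi)
  }
  out
}

## ---- tape (differentiable) versions ----

#' Differentiable block Cholesky on the tape
#'
#' `bt_factorize_tp` takes lists of tape node ids for the diagonal and
#' subdiagonal blocks and returns node-id lists for the factor; `bt_logdet_tp`,
#' `bt_solve_mean_tp` and `bt_sample_tp` consume them. Used by the state-space
#' ELBO so gradients flow through posterior assembly, the mean solve, the
#' entropy log-determinant, and reparameterized path samples.
#'
#' @param tp tape
#' @param diag_nodes,offdiag_nodes lists of node ids (d x d blocks)
#' @keywords internal
#' @export
bt_factorize_tp <- function(tp, diag_nodes, offdiag_nodes) {
  R <- length(diag_nodes)
  Ld <- vector("list", R)
  Lo <- vector("list", max(R - 1L, 0L))
  S <- diag_nodes[[1]]
  for (r in seq_len(R)) {
    Ld[[r]] <- tp_chol(tp, S)
    if (r < R) {
      # Lo_r = O_r L_rr^{-T}  =>  t(Lo_r) = L_rr^{-1} t(O_r)
      Lo[[r]] <- tp_t(tp, tp_trisolve(tp, Ld[[r]], tp_t(tp, offdiag_nodes[[r]])))
      S <- tp_sub(tp, diag_nodes[[r + 1]],
                  tp_matmul(tp, Lo[[r]], tp_t(tp, Lo[[r]])))
    }
  }
  list(R = R, Ld = Ld, Lo = Lo)
}

#' @rdname bt_factorize_tp
#' @param fac factor from `bt_factorize_tp`
#' @export
bt_logdet_tp <- function(tp, fac) {
  total <- NULL
  for (r in seq_len(fac$R)) {
    term <- tp_sum(tp, tp_log(tp, tp_diag_extract(tp, fac$Ld[[r]])))
    total <- if (is.null(total)) term else tp_add(tp, total, term)
  }
  tp_scale(tp, total, 2)
}

#' @rdname bt_factorize_tp
#' @param h_nodes list of R information-vector nodes (d x 1 matrices)
#' @return list of R mean nodes (d x 1)
#' @export
bt_solve_tp <- function(tp, fac, h_nodes) {
  R <- fac$R
  U <- vector("list", R)
  for (r in seq_len(R)) {
    acc <- h_nodes[[r]]
    if (r > 1L) acc <- tp_sub(tp, acc, tp_matmul(tp, fac$Lo[[r - 1L]], U[[r - 1L]]))
    U[[r]] <- tp_trisolve(tp, fac$Ld[[r]], acc)
  }
  X <- vector("list", R)
  for (r in seq(R, 1L)) {
    acc <- U[[r]]
    if (r < R) acc <- tp_sub(tp, acc, tp_matmul(tp, tp_t(tp, fac$Lo[[r]]), X[[r + 1L]]))
    X[[r]] <- tp_trisolve(tp, fac$Ld[[r]], acc, transpose = TRUE)
  }
  X
}

#' @rdname bt_factorize_tp
#' @param mean_nodes list of R mean nodes (d x 1)
#' @param eps (R*d) x n matrix of standard normal noise (plain numeric)
#' @return list of R nodes, each d x n (the sampled paths, stacked by bin)
#' @export
bt_sample_tp <- function(tp, fac, mean_nodes, eps) {
  R <- fac$R
  d <- nrow(tpv(tp, fac$Ld[[1]]))
  X <- vector("list", R)
  for (r in seq(R, 1L)) {
    acc <- tp_const(tp, eps[(r - 1L) * d + seq_len(d), , drop = FALSE])
    if (r < R) acc <- tp_sub(tp, acc, tp_matmul(tp, tp_t(tp, fac$Lo[[r]]), X[[r + 1L]]))
    X[[r]] <- tp_trisolve(tp, fac$Ld[[r]], acc, transpose = TRUE)
  }
  lapply(seq_len(R), function(r) {
    tp_add(tp, X[[r]], tp_matmul(tp, mean_nodes[[r]],
                                 tp_const(tp, matrix(1, 1, ncol(eps)))))
  })
}
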