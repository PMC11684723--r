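#' @title Reverse-mode automatic differentiation tape
#'
#' @description
#' A minimal reverse-mode autodiff engine used by all gradient-based fitting in
#' the package (the joint-mark-intensity VAE, the state-space ELBO, and the
#' Gaussian-mixture baseline). Values are numeric scalars, vectors or matrices;
#' every operation records its parents and a backward closure on a tape, and
#' [tp_backward()] accumulates gradients by a single reverse sweep. The op set
#' is deliberately small: dense linear algebra (including Cholesky factors and
#' triangular solves, so block-tridiagonal Gaussian sampling is differentiable),
#' elementwise transcendentals, reductions, row slicing, and a stop-gradient.
#'
#' These functions are internal; they are exported for power users and for the
#' test suite, which checks every operation against central finite differences.
#'
#' @name tape
#' @keywords internal
NULL

#' Create a new autodiff tape
#' @return an environment holding node values, parents and backward closures
#' @export
tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  # hashed environments keyed by node id: O(1) insertion without the
  # copy-on-write penalty of growing a plain list in place
  tp$val <- new.env(hash = TRUE, parent = emptyenv(), size = 4096L)
  tp$bw <- new.env(hash = TRUE, parent = emptyenv(), size = 4096L)
  tp$parents <- new.env(hash = TRUE, parent = emptyenv(), size = 4096L)
  tp$n <- 0L
  class(tp) <- "markvae_tape"
  tp
}

tp_emit <- function(tp, value, parents = integer(0), backward = NULL) {
  # Force the lazy arguments first: they may themselves emit nodes, and this
  # node must come after all of its parents on the tape.
  force(value)
  force(parents)
  n <- tp$n + 1L
  k <- as.character(n)
  assign(k, value, envir = tp$val)
  if (length(parents)) assign(k, parents, envir = tp$parents)
  if (!is.null(backward)) assign(k, backward, envir = tp$bw)
  tp$n <- n
  n
}

#' Read the value stored at a tape node
#' @param tp tape
#' @param id node id
#' @export
tp_value <- function(tp, id) {
  force(id)
  get(as.character(id), envir = tp$val)
}

# Internal value fetch that forces its argument first. Op arguments are often
# unevaluated nested op calls (R promises); the promise must run (and emit its
# node) before the value is read back off the tape.
tpv <- function(tp, id) {
  force(id)
  get(as.character(id), envir = tp$val)
}

#' Register a constant (gradient sink) on the tape
#' @rdname tape-ops
#' @export
tp_const <- function(tp, x) tp_emit(tp, x)

#' Register a parameter (gradient source) on the tape
#' @rdname tape-ops
#' @export
tp_param <- function(tp, x) tp_emit(tp, x)

#' Run the reverse sweep from a scalar root node
#'
#' @param tp tape
#' @param root id of a scalar node
#' @return list of gradients indexed by node id (NULL where no gradient flows)
#' @export
tp_backward <- function(tp, root) {
  stopifnot(length(tpv(tp, root)) == 1L)
  acc <- new.env(hash = TRUE, parent = emptyenv(), size = 4096L)
  assign(as.character(root), 1, envir = acc)
  for (id in seq(root, 1L)) {
    key <- as.character(id)
    g <- get0(key, envir = acc, ifnotfound = NULL)
    bw <- get0(key, envir = tp$bw, ifnotfound = NULL)
    if (is.null(g) || is.null(bw)) next
    pg <- bw(g)
    ps <- get0(key, envir = tp$parents, ifnotfound = integer(0))
    for (k in seq_along(ps)) {
      contrib <- pg[[k]]
      if (is.null(contrib)) next
      pk <- as.character(ps[k])
      prev <- get0(pk, envir = acc, ifnotfound = NULL)
      assign(pk, if (is.null(prev)) contrib else prev + contrib, envir = acc)
    }
  }
  grads <- vector("list", tp$n)
  for (key in ls(acc, sorted = FALSE))
    grads[[as.integer(key)]] <- get(key, envir = acc)
  grads
}

## ---- arithmetic ----

#' Tape operations
#'
#' Elementwise and linear-algebra operations on tape nodes. All take node ids
#' and return a node id; shapes must agree exactly (no broadcasting except the
#' documented bias/sweep helpers).
#'
#' @param tp tape
#' @param a,b,X,L,B,v node ids
#' @param s,p,cmax,idx,M,margin plain (non-node) constants
#' @param transpose solve against the transposed factor
#' @name tape-ops
NULL

#' @rdname tape-ops
#' @export
tp_add <- function(tp, a, b) {
  tp_emit(tp, tpv(tp, a) + tpv(tp, b), c(a, b), function(g) list(g, g))
}

#' @rdname tape-ops
#' @export
tp_sub <- function(tp, a, b) {
  tp_emit(tp, tpv(tp, a) - tpv(tp, b), c(a, b), function(g) list(g, -g))
}

#' @rdname tape-ops
#' @export
tp_neg <- function(tp, a) tp_emit(tp, -tpv(tp, a), a, function(g) list(-g))

#' @rdname tape-ops
#' @export
tp_mul <- function(tp, a, b) {
  va <- tpv(tp, a); vb <- tpv(tp, b)
  stopifnot(length(va) == length(vb) || length(va) == 1L || length(vb) == 1L)
  tp_emit(tp, va * vb, c(a, b), function(g) {
    ga <- g * vb; gb <- g * va
    if (length(va) == 1L) ga <- sum(ga)
    if (length(vb) == 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

#' @rdname tape-ops
#' @export
tp_div <- function(tp, a, b) {
  va <- tpv(tp, a); vb <- tpv(tp, b)
  y <- va / vb
  tp_emit(tp, y, c(a, b), function(g) {
    ga <- g / vb; gb <- -g * y / vb
    if (length(va) == 1L) ga <- sum(ga)
    if (length(vb) == 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

#' @rdname tape-ops
#' @export
tp_scale <- function(tp, a, s) tp_emit(tp, s * tpv(tp, a), a, function(g) list(s * g))

#' @rdname tape-ops
#' @export
tp_addc <- function(tp, a, s) tp_emit(tp, tpv(tp, a) + s, a, function(g) list(g))

## ---- elementwise transcendentals ----

#' @rdname tape-ops
#' @export
tp_tanh <- function(tp, a) {
  y <- tanh(tpv(tp, a))
  tp_emit(tp, y, a, function(g) list(g * (1 - y^2)))
}

#' @rdname tape-ops
#' @export
tp_softplus <- function(tp, a) {
  x <- tpv(tp, a)
  y <- pmax(x, 0) + log1p(exp(-abs(x)))
  tp_emit(tp, y, a, function(g) list(g * stats::plogis(x)))
}

#' @rdname tape-ops
#' @export
tp_exp <- function(tp, a) {
  y <- exp(tpv(tp, a))
  tp_emit(tp, y, a, function(g) list(g * y))
}

#' @rdname tape-ops
#' @export
tp_log <- function(tp, a) {
  x <- tpv(tp, a)
  tp_emit(tp, log(x), a, function(g) list(g / x))
}

#' @rdname tape-ops
#' @export
tp_sqrt <- function(tp, a) {
  y <- sqrt(tpv(tp, a))
  tp_emit(tp, y, a, function(g) list(g / (2 * y)))
}

#' @rdname tape-ops
#' @export
tp_square <- function(tp, a) {
  x <- tpv(tp, a)
  tp_emit(tp, x^2, a, function(g) list(2 * g * x))
}

#' @rdname tape-ops
#' @export
tp_powc <- function(tp, a, p) {
  x <- tpv(tp, a)
  tp_emit(tp, x^p, a, function(g) list(g * p * x^(p - 1)))
}

#' @rdname tape-ops
#' @export
tp_clampmax <- function(tp, a, cmax) {
  x <- tpv(tp, a)
  tp_emit(tp, pmin(x, cmax), a, function(g) list(g * (x < cmax)))
}

## ---- reductions ----

#' @rdname tape-ops
#' @export
tp_sum <- function(tp, a) {
  x <- tpv(tp, a)
  tp_emit(tp, sum(x), a, function(g) {
    out <- x; out[] <- g; list(out)
  })
}

#' @rdname tape-ops
#' @export
tp_rowsums <- function(tp, a) {
  x <- tpv(tp, a)
  tp_emit(tp, rowSums(x), a, function(g) list(matrix(g, nrow(x), ncol(x))))
}

#' @rdname tape-ops
#' @export
tp_colsums <- function(tp, a) {
  x <- tpv(tp, a)
  tp_emit(tp, colSums(x), a, function(g) list(matrix(g, nrow(x), ncol(x), byrow = TRUE)))
}

#' @rdname tape-ops
#' @export
tp_logsumexp_rows <- function(tp, a) {
  x <- tpv(tp, a)
  mx <- apply(x, 1L, max)
  mx[!is.finite(mx)] <- 0
  y <- mx + log(rowSums(exp(x - mx)))
  sm <- exp(x - y) # softmax rows
  tp_emit(tp, y, a, function(g) list(g * sm))
}

## ---- structural ----

#' @rdname tape-ops
#' @export
tp_slice_rows <- function(tp, a, idx) {
  x <- tpv(tp, a)
  tp_emit(tp, x[idx, , drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(x), ncol(x))
    rs <- rowsum(g, idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

#' Broadcast-add a scalar node to every element of a node
#' @rdname tape-ops
#' @export
tp_adds <- function(tp, a, s) {
  va <- tpv(tp, a); vs <- tpv(tp, s)
  stopifnot(length(vs) == 1L)
  tp_emit(tp, va + vs, c(a, s), function(g) list(g, sum(g)))
}

#' Reshape a length-(n*m) vector node into an n-by-m matrix, row-major
#' @rdname tape-ops
#' @export
tp_reshape_rows <- function(tp, a, n, m) {
  x <- tpv(tp, a)
  stopifnot(length(x) == n * m)
  tp_emit(tp, matrix(x, n, m, byrow = TRUE), a, function(g) {
    out <- as.vector(t(g))
    dim(out) <- dim(x)
    list(out)
  })
}

#' @rdname tape-ops
#' @export
tp_cbind <- function(tp, a, b) {
  va <- tpv(tp, a); vb <- tpv(tp, b)
  na <- ncol(va)
  tp_emit(tp, cbind(va, vb), c(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

#' @rdname tape-ops
#' @export
tp_t <- function(tp, a) tp_emit(tp, t(tpv(tp, a)), a, function(g) list(t(g)))

#' @rdname tape-ops
#' @export
tp_detach <- function(tp, a) tp_emit(tp, tpv(tp, a))

#' @rdname tape-ops
#' @export
tp_maskmul <- function(tp, a, M) {
  tp_emit(tp, tpv(tp, a) * M, a, function(g) list(g * M))
}

#' @rdname tape-ops
#' @export
tp_diag_extract <- function(tp, a) {
  x <- tpv(tp, a)
  d <- nrow(x)
  tp_emit(tp, diag(x), a, function(g) {
    out <- matrix(0, d, d); diag(out) <- g; list(out)
  })
}

#' @rdname tape-ops
#' @export
tp_diag_make <- function(tp, v) {
  x <- tpv(tp, v)
  tp_emit(tp, diag(x, nrow = length(x)), v, function(g) list(diag(g)))
}

#' Column sums of a matrix node, kept as a 1-by-d row matrix
#' @rdname tape-ops
#' @export
tp_colsums_row <- function(tp, a) {
  x <- tpv(tp, a)
  tp_emit(tp, matrix(colSums(x), 1L, ncol(x)), a, function(g) {
    list(matrix(g, nrow(x), ncol(x), byrow = TRUE))
  })
}

#' View a length-d vector node as a 1-by-d row matrix
#' @rdname tape-ops
#' @export
tp_rowview <- function(tp, v) {
  x <- tpv(tp, v)
  tp_emit(tp, matrix(x, 1L, length(x)), v, function(g) list(drop(g)))
}

#' Drop the dimensions of a 1-by-d (or d-by-1) matrix node to a vector
#' @rdname tape-ops
#' @export
tp_dropdim <- function(tp, a) {
  x <- tpv(tp, a)
  tp_emit(tp, drop(x), a, function(g) {
    out <- g; dim(out) <- dim(x); list(out)
  })
}

#' Stack matrix nodes by rows
#' @rdname tape-ops
#' @param nodes list of node ids with equal column counts
#' @export
tp_vstack <- function(tp, nodes) {
  nodes <- lapply(nodes, function(id) { force(id); id })
  vals <- lapply(nodes, function(id) tpv(tp, id))
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr)
  tp_emit(tp, do.call(rbind, vals), unlist(nodes), function(g) {
    lapply(seq_along(nr), function(k) {
      g[(ends[k] - nr[k] + 1L):ends[k], , drop = FALSE]
    })
  })
}

## ---- linear algebra ----

#' @rdname tape-ops
#' @export
tp_matmul <- function(tp, a, b) {
  va <- tpv(tp, a); vb <- tpv(tp, b)
  tp_emit(tp, va %*% vb, c(a, b), function(g) {
    list(g %*% t(vb), t(va) %*% g)
  })
}

#' Add a bias row-vector to every row of a matrix node
#' @rdname tape-ops
#' @export
tp_addbias <- function(tp, X, b) {
  vx <- tpv(tp, X); vb <- tpv(tp, b)
  tp_emit(tp, sweep(vx, 2L, vb, "+"), c(X, b), function(g) {
    list(g, colSums(g))
  })
}

#' Multiply every row of a matrix node elementwise by a vector node
#' @rdname tape-ops
#' @export
tp_sweep_mul <- function(tp, X, v, margin = 2L) {
  vx <- tpv(tp, X); vv <- tpv(tp, v)
  tp_emit(tp, sweep(vx, margin, vv, "*"), c(X, v), function(g) {
    if (margin == 2L) list(sweep(g, 2L, vv, "*"), colSums(g * vx))
    else list(sweep(g, 1L, vv, "*"), rowSums(g * vx))
  })
}

#' Lower Cholesky factor of a symmetric positive-definite node
#'
#' Returns the lower-triangular L with `A = L %*% t(L)`. The backward pass uses
#' the standard Cholesky reverse-mode rule (lower-triangle projection with the
#' diagonal halved, sandwiched between inverse factors), symmetrized on output.
#' @rdname tape-ops
#' @export
tp_chol <- function(tp, a) {
  A <- tpv(tp, a)
  U <- tryCatch(chol(A), error = function(e) {
    stop("tp_chol: matrix not positive definite", call. = FALSE)
  })
  L <- t(U)
  tp_emit(tp, L, a, function(g) {
    # Murray-style reverse mode through the Cholesky
    P <- t(L) %*% g
    P[upper.tri(P)] <- 0
    diag(P) <- diag(P) / 2
    S <- backsolve(t(L), t(backsolve(t(L), t(P), upper.tri = TRUE)), upper.tri = TRUE)
    list((S + t(S)) / 2)
  })
}

#' Triangular solve against a lower factor node
#'
#' Computes `solve(L, B)` (or `solve(t(L), B)` when `transpose = TRUE`) where
#' `L` is lower triangular.
#' @rdname tape-ops
#' @export
tp_trisolve <- function(tp, L, B, transpose = FALSE) {
  vL <- tpv(tp, L); vB <- tpv(tp, B)
  if (!is.matrix(vB)) vB <- matrix(vB, ncol = 1L)
  X <- if (transpose) backsolve(t(vL), vB, upper.tri = TRUE)
  else forwardsolve(vL, vB)
  tp_emit(tp, X, c(L, B), function(g) {
    if (!is.matrix(g)) g <- matrix(g, ncol = 1L)
    if (!transpose) {
      gB <- backsolve(t(vL), g, upper.tri = TRUE)
      gL <- -gB %*% t(X)
    } else {
      gB <- forwardsolve(vL, g)
      gL <- -X %*% t(gB)
    }
    gL[upper.tri(gL)] <- 0
    list(gL, gB)
  })
}

## ---- composite helpers ----

#' Diagonal-precision Gaussian log-density, row-wise on the tape
#'
#' For matrices of observations `X`, means `mu` and positive diagonal precision
#' entries `prec` (all n-by-d nodes), returns the n-vector node of
#' `log N(x_i | mu_i, diag(prec_i))`.
#' @rdname tape-ops
#' @export
tp_gauss_diag_logpdf <- function(tp, X, mu, prec) {
  d <- ncol(tpv(tp, X))
  diffn <- tp_sub(tp, X, mu)
  quad <- tp_rowsums(tp, tp_mul(tp, prec, tp_square(tp, diffn)))
  logdet <- tp_rowsums(tp, tp_log(tp, prec))
  half <- tp_scale(tp, tp_sub(tp, logdet, quad), 0.5)
  tp_addc(tp, half, -0.5 * d * log(2 * pi))
}
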