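# Small single-factor design generator and dense reference pieces shared
# across the suite. All fixtures are built in code at test time.

make_toy <- function(n = 30, l = 6, qk = 1, p = 3, seed = 1, d = 0.8,
                     rho = 0.5, miss = 0) {
  set.seed(seed)
  X <- cbind(1, matrix(runif(n * (p - 1), -0.5, 0.5), n))
  g <- sample(c(rep(seq_len(l), qk), sample.int(l, n - l * qk, replace = TRUE)))
  z <- cbind(rep(1, n))
  if (qk > 1) z <- cbind(z, matrix(runif(n * (qk - 1), -0.5, 0.5), n))
  spec <- model_spec(X, list(factor_spec(g, z)))
  Z <- build_random_design(spec)
  Dk <- matrix(rho * d, qk, qk); diag(Dk) <- d
  Dfull <- assemble_full_D(list(Dk), spec)
  b <- drop(crossprod(chol(Dfull + diag(1e-12, spec$q)), rnorm(spec$q)))
  beta <- rev(seq_len(p))
  y <- drop(X %*% beta + Z %*% b + rnorm(n))
  m <- rep(1, n)
  if (miss > 0) m[sample(n, miss)] <- 0
  list(spec = spec, X = X, Z = Z, y = y * m, m = m, beta = beta,
       Dk = Dk, Dfull = Dfull, g = g, z = z)
}

# Two crossed factors (the most general design family exercised).
make_toy2 <- function(n = 48, l1 = 6, l2 = 4, seed = 1) {
  set.seed(seed)
  X <- cbind(1, runif(n, -0.5, 0.5))
  g1 <- sample(c(rep(seq_len(l1), 2), sample.int(l1, n - 2 * l1, TRUE)))
  g2 <- sample(c(seq_len(l2), sample.int(l2, n - l2, TRUE)))
  z1 <- cbind(1, runif(n, -0.5, 0.5))
  spec <- model_spec(X, list(factor_spec(g1, z1),
                             factor_spec(g2, cbind(rep(1, n)))))
  Z <- build_random_design(spec)
  D1 <- matrix(c(1, .4, .4, 1), 2); D2 <- matrix(0.8)
  Dfull <- assemble_full_D(list(D1, D2), spec)
  b <- drop(crossprod(chol(Dfull + diag(1e-10, spec$q)), rnorm(spec$q)))
  y <- drop(X %*% c(2, 1) + Z %*% b + rnorm(n))
  list(spec = spec, X = X, Z = Z, y = y, D = list(D1, D2), Dfull = Dfull)
}

# Build single-voxel product forms directly (independent of the package's
# batched map-reduce path; doubles as its oracle).
single_forms <- function(X, Z, y, m = rep(1, nrow(X))) {
  Xm <- X * m; Zm <- Z * m; ym <- y * m
  list(P = crossprod(Xm), Q = drop(crossprod(Xm, ym)), R = crossprod(Xm, Zm),
       S = sum(ym^2), Tv = drop(crossprod(Zm, ym)), U = crossprod(Zm),
       n_v = sum(m))
}

dense_V <- function(Z, Dfull) diag(nrow(Z)) + Z %*% Dfull %*% t(Z)

# Dense restricted log-likelihood written from the definition (rows with
# m = 0 deleted), kept independent of the package internals.
dense_crit <- function(X, y, Z, Dfull, beta, sigma2, m = NULL) {
  if (!is.null(m)) {
    keep <- as.logical(m)
    X <- X[keep, , drop = FALSE]; y <- y[keep]; Z <- Z[keep, , drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  V <- dense_V(Z, Dfull)
  Vi <- solve(V)
  e <- y - drop(X %*% beta)
  XtViX <- crossprod(X, Vi %*% X)
  as.numeric(
    -0.5 * ((n - p) * log(sigma2) + drop(crossprod(e, Vi %*% e)) / sigma2 +
              determinant(V, logarithm = TRUE)$modulus +
              determinant(XtViX, logarithm = TRUE)$modulus))
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(max(abs(b)), 1e-12), tol)
}
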