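# Slow, independent REML reference: direct numerical maximisation of the dense
# restricted log-likelihood for a single voxel. Methodologically independent of
# the Fisher-scoring path: dense V = I + Z D Z', log-Cholesky parameterisation
# of each D_k (feasible by construction, no projections), multi-start
# quasi-Newton search with a quadratic polish.

# Dense restricted log-likelihood at (beta, sigma2, D), observed rows only.
dense_reml_criterion <- function(X, y, Z, Dfull, beta, sigma2, m = NULL) {
  if (!is.null(m)) {
    keep <- as.logical(m)
    X <- X[keep, , drop = FALSE]; y <- y[keep]; Z <- Z[keep, , drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  V <- diag(n) + Z %*% Dfull %*% t(Z)
  cv <- chol(V)
  e <- y - X %*% beta
  ei <- backsolve(cv, forwardsolve(t(cv), e))
  Xi <- backsolve(cv, forwardsolve(t(cv), X))
  XtViX <- crossprod(X, Xi)
  -0.5 * ((n - p) * log(sigma2) + sum(e * ei) / sigma2 +
            2 * sum(log(diag(cv))) +
            as.numeric(determinant(XtViX, logarithm = TRUE)$modulus))
}

# Profiled criterion: beta by GLS, sigma2 = e'V^-1 e / (n - p).
dense_profiled <- function(X, y, Z, Dfull) {
  n <- nrow(X); p <- ncol(X)
  V <- diag(n) + Z %*% Dfull %*% t(Z)
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(list(value = -Inf))
  Li <- forwardsolve(t(cv), cbind(X, y))
  XtViX <- crossprod(Li[, 1:p, drop = FALSE])
  XtViy <- crossprod(Li[, 1:p, drop = FALSE], Li[, p + 1])
  cb <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cb)) return(list(value = -Inf))
  beta <- backsolve(cb, forwardsolve(t(cb), XtViy))
  evie <- sum(Li[, p + 1]^2) - sum(XtViy * beta)
  sigma2 <- max(evie, .Machine$double.xmin) / (n - p)
  value <- -0.5 * ((n - p) * log(sigma2) + (n - p) +
                     2 * sum(log(diag(cv))) + 2 * sum(log(diag(cb))))
  list(value = value, beta = drop(beta), sigma2 = sigma2)
}

# log-Cholesky <-> covariance block
theta_to_blocks <- function(theta, qks) {
  ofs <- 0L
  lapply(qks, function(qk) {
    npar <- qk * (qk + 1L) / 2L
    th <- theta[ofs + seq_len(npar)]
    ofs <<- ofs + npar
    L <- matrix(0, qk, qk)
    L[lower.tri(L, diag = TRUE)] <- th
    diag(L) <- exp(diag(L))
    tcrossprod(L)
  })
}

blocks_to_theta <- function(blocks) {
  unlist(lapply(blocks, function(Dk) {
    Dk <- as.matrix(Dk)
    ch <- chol(Dk + diag(1e-8, nrow(Dk)))
    L <- t(ch)
    diag(L) <- log(diag(L))
    L[lower.tri(L, diag = TRUE)]
  }))
}

#' Direct dense REML maximisation (reference oracle)
#'
#' Maximises the dense restricted log-likelihood over the per-factor
#' covariance blocks, with `beta` and `sigma^2` profiled out analytically.
#' Each `D_k` is parameterised by the log-Cholesky factor, guaranteeing
#' feasibility without projections; optimisation is multi-start quasi-Newton
#' (`optim` BFGS) followed by a local quadratic polish. Intended for small
#' single-voxel instances as the correctness reference for the scoring
#' optimiser, never for image-scale use.
#'
#' @param X `n x p` fixed design. @param y length-`n` response.
#' @param spec a [model_spec()] describing the random effects (its `X` is
#'   ignored; `X` above is used).
#' @param m optional 0/1 missingness indicator; unobserved rows are deleted.
#' @param n_starts number of optimisation starts (>= 1; additional starts
#'   perturb the first).
#' @param tol criterion tolerance for the polish stage.
#' @return list with `beta`, `sigma2`, `D` (list of blocks), `loglik`,
#'   `converged`, and optimiser diagnostics `starts` (per-start values).
#' @export
direct_reml <- function(X, y, spec, m = NULL, n_starts = 3L, tol = 1e-10) {
  Z <- build_random_design(spec)
  if (!is.null(m)) {
    keep <- as.logical(m)
    X <- X[keep, , drop = FALSE]; y <- y[keep]; Z <- Z[keep, , drop = FALSE]
  }
  qks <- vapply(spec$factors, function(f) f$n_effects, 0L)
  if (spec$r == 0L) {
    pr <- dense_profiled(X, y, matrix(0, nrow(X), 0), matrix(0, 0, 0))
    return(list(beta = pr$beta, sigma2 = pr$sigma2, D = list(),
                loglik = pr$value, converged = TRUE, starts = pr$value))
  }
  negf <- function(theta) {
    Dfull <- assemble_full_D(theta_to_blocks(theta, qks), spec)
    -dense_profiled(X, y, Z, Dfull)$value
  }
  npar <- sum(qks * (qks + 1) / 2)
  starts <- list(rep(0, npar), rep(-1, npar), rep(0.5, npar))
  if (n_starts > 3) for (i in seq_len(n_starts - 3))
    starts <- c(starts, list(stats::rnorm(npar, 0, 0.7)))
  starts <- starts[seq_len(max(1L, n_starts))]
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, negf, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14)),
             error = function(e) list(value = Inf, par = s, convergence = 99)))
  vals <- vapply(fits, `[[`, 0, "value")
  if (!any(is.finite(vals)))
    return(list(beta = NULL, sigma2 = NA, D = NULL, loglik = NA,
                converged = FALSE, starts = -vals))
  best <- fits[[which.min(vals)]]
  th <- polish_quadratic(negf, best$par, tol = tol)
  Dbl <- theta_to_blocks(th, qks)
  pr <- dense_profiled(X, y, Z, assemble_full_D(Dbl, spec))
  list(beta = pr$beta, sigma2 = pr$sigma2, D = Dbl, loglik = pr$value,
       converged = is.finite(pr$value), starts = -vals)
}

# Newton polish with central finite differences; shrinking step sizes.
polish_quadratic <- function(fn, par, tol = 1e-10, max_steps = 12L) {
  d <- length(par)
  f0 <- fn(par)
  h <- 1e-4
  for (it in seq_len(max_steps)) {
    g <- numeric(d)
    H <- matrix(0, d, d)
    fp <- numeric(d); fm <- numeric(d)
    for (i in seq_len(d)) {
      ei <- replace(numeric(d), i, h)
      fp[i] <- fn(par + ei); fm[i] <- fn(par - ei)
      g[i] <- (fp[i] - fm[i]) / (2 * h)
      H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
    }
    if (d > 1) {
      for (i in seq_len(d - 1)) for (j in seq.int(i + 1, d)) {
        ei <- replace(numeric(d), i, h); ej <- replace(numeric(d), j, h)
        fpp <- fn(par + ei + ej); fmm <- fn(par - ei - ej)
        H[i, j] <- H[j, i] <-
          (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) / (2 * h^2)
      }
    }
    step <- tryCatch(-solve(H, g), error = function(e) -g / max(abs(diag(H)), 1))
    if (!all(is.finite(step))) break
    # backtracking on the polish step
    lam <- 1
    repeat {
      f1 <- fn(par + lam * step)
      if (is.finite(f1) && f1 <= f0) break
      lam <- lam / 2
      if (lam < 1e-6) { f1 <- f0; step <- 0 * step; break }
    }
    moved <- abs(f0 - f1)
    par <- par + lam * step
    f0 <- f1
    h <- max(h / 4, 1e-6)
    if (moved < tol && it > 1) break
  }
  par
}

#' Fast dense REML oracle for single-variance designs
#'
#' For designs whose full covariance is `d * I_q` (one factor, one effect per
#' level) the marginal covariance is `I + d Z Z'`, so one singular-value
#' decomposition of the zero-ed design `Z` per missingness pattern makes each
#' criterion evaluation O(n p). Used to cross-validate the scoring optimiser
#' over whole images at high precision.
#'
#' @param X,Z designs with unobserved rows zeroed; `y` response (0 at
#'   unobserved rows); `n_v` observation count.
#' @param sv optional precomputed `svd(Z)`; pass when many voxels share `Z`.
#' @param d_max upper bracket for the variance ratio search.
#' @param tol bracket tolerance for the final refinement.
#' @return list with `d` (variance ratio), `beta`, `sigma2`, `loglik`.
#' @export
direct_reml_1var <- function(X, y, Z, n_v, sv = NULL, d_max = 100, tol = 1e-12) {
  p <- ncol(X)
  if (is.null(sv)) sv <- svd(Z, nv = 0)
  keep <- sv$d > max(dim(Z)) * .Machine$double.eps * max(sv$d)
  Uo <- sv$u[, keep, drop = FALSE]
  lam <- sv$d[keep]^2                      # eigenvalues of Z Z'
  Xu <- crossprod(Uo, X)                   # k x p
  yu <- drop(crossprod(Uo, y))
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y^2)
  prof <- function(d) {
    w <- d * lam / (1 + d * lam)
    XtViX <- XtX - crossprod(Xu, Xu * w)
    XtViy <- Xty - drop(crossprod(Xu, yu * w))
    cb <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cb)) return(list(value = -Inf))
    beta <- backsolve(cb, forwardsolve(t(cb), XtViy))
    evie <- yty - sum(yu^2 * w) - sum(XtViy * beta)
    sigma2 <- max(evie, .Machine$double.xmin) / (n_v - p)
    list(value = -0.5 * ((n_v - p) * log(sigma2) + (n_v - p) +
                           sum(log1p(d * lam)) + 2 * sum(log(diag(cb)))),
         beta = drop(beta), sigma2 = sigma2)
  }
  f <- function(d) prof(d)$value
  opt <- stats::optimize(f, c(0, d_max), maximum = TRUE, tol = 1e-9)
  d <- opt$maximum
  # refine to near machine precision: root of the Richardson-extrapolated
  # central-difference derivative (O(h^4) truncation, noise ~ eps/h)
  gdash <- function(x) {
    h <- 1e-3 * (1 + abs(x))
    (8 * (f(x + h) - f(x - h)) - (f(x + 2 * h) - f(x - 2 * h))) / (12 * h)
  }
  lo <- max(d - 0.05 * (1 + d), 1e-12); hi <- d + 0.05 * (1 + d)
  glo <- gdash(lo); ghi <- gdash(hi)
  if (is.finite(glo) && is.finite(ghi) && glo > 0 && ghi < 0) {
    d <- stats::uniroot(gdash, c(lo, hi), f.lower = glo, f.upper = ghi,
                        tol = tol)$root
  }
  if (f(0) >= f(d)) d <- 0                 # boundary check
  pr <- prof(d)
  list(d = d, beta = pr$beta, sigma2 = pr$sigma2, loglik = pr$value)
}
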