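#' Control parameters for the Fisher-scoring REML optimiser
#'
#' @param tol convergence tolerance on the absolute change of the restricted
#'   log-likelihood between successive iterations.
#' @param max_iter maximum number of iterations before a voxel is flagged
#'   non-converged.
#' @param sigma_denom denominator of the generalised-least-squares variance
#'   update: `"reml"` uses `n_v - p` (the value that maximises the restricted
#'   log-likelihood, the default), `"ml"` uses `n_v` as in the printed update
#'   rule.
#' @param max_halvings maximum number of step-size halvings within one
#'   iteration before the covariance update is skipped for that iteration.
#' @param method kernel route: `"auto"` picks the single-factor block-diagonal
#'   fast path when `r = 1`, otherwise dense; both give identical results.
#' @return list of class `"fsfs_control"`.
#' @export
#' @param polish single-factor designs only: after convergence of the scoring
#'   loop, refine the interior optimum by Newton root-finding on the profiled
#'   score until stationarity at machine precision (the single-factor
#'   structure makes each score evaluation cheap enough for this).
fsfs_control <- function(tol = 1e-6, max_iter = 1e4,
                         sigma_denom = c("reml", "ml"),
                         max_halvings = 20L,
                         method = c("auto", "general", "blockdiag"),
                         polish = TRUE) {
  stopifnot(tol > 0, max_iter >= 1)
  list(tol = tol, max_iter = as.integer(max_iter),
       sigma_denom = match.arg(sigma_denom),
       max_halvings = as.integer(max_halvings),
       method = match.arg(method), polish = isTRUE(polish))
}

#' Restricted log-likelihood from product forms
#'
#' Evaluates the REML criterion (constants dropped)
#' `-1/2 [ (n_v - p) log sigma^2 + e'V^-1 e / sigma^2 + log|V| + log|X'V^-1 X| ]`
#' using only the voxel's product forms, via the Woodbury identity and the
#' matrix determinant lemma.
#'
#' @param forms single-voxel product forms: list with `P`, `Q`, `R`, `S`,
#'   `Tv`, `U`, `n_v`.
#' @param spec the [model_spec()].
#' @param beta fixed-effects vector, `sigma2` error variance, `Dblocks` list
#'   of per-factor covariance blocks (sigma^2-relative).
#' @param method kernel route, see [fsfs_control()].
#' @return scalar restricted log-likelihood.
#' @export
reml_criterion <- function(forms, spec, beta, sigma2, Dblocks,
                           method = "auto") {
  kern <- pf_kernels(forms, spec, Dblocks, method)
  kern_criterion(kern, beta, sigma2, forms$n_v, spec$p)
}

#' Generalised-least-squares update of beta and sigma^2
#'
#' `beta = (X'V^-1X)^-1 X'V^-1Y` and `sigma^2 = e'V^-1e / d` with `d` the
#' chosen denominator (`n_v - p` by default), all via product forms.
#'
#' @inheritParams reml_criterion
#' @param sigma_denom `"reml"` (`n_v - p`) or `"ml"` (`n_v`).
#' @return list with `beta` and `sigma2`.
#' @export
gls_update <- function(forms, spec, Dblocks, sigma_denom = c("reml", "ml"),
                       method = "auto") {
  sigma_denom <- match.arg(sigma_denom)
  kern <- pf_kernels(forms, spec, Dblocks, method)
  kern_gls(kern, forms$n_v, spec$p, sigma_denom)
}

kern_gls <- function(kern, n_v, p, sigma_denom) {
  beta <- drop(chol_solve(kern$XtViX, kern$XtViY, "X' V^-1 X")$sol)
  evie <- kern_evie(kern, beta)
  denom <- if (sigma_denom == "reml") n_v - p else n_v
  if (denom <= 0) stop(condition_numeric("non-positive variance denominator"))
  list(beta = beta, sigma2 = max(evie / denom, .Machine$double.xmin))
}

# Per-level q_k x q_k blocks of a factor from a dense q x q matrix.
factor_blocks_array <- function(A, spec, k) {
  f <- spec$factors[[k]]
  qk <- f$n_effects; l <- f$n_levels
  cols <- spec$block_cols[[k]]
  array(A[cols, cols], c(qk, l, qk, l))   # [a, i, b, j] = (block_ij)[a, b]
}

#' Simplified Fisher information block for one factor
#'
#' `F^k = sum_{i,j} (Z^(k,i)' V^-1 Z^(k,j)) %x% (Z^(k,i)' V^-1 Z^(k,j))` over
#' all level pairs, assembled from the product forms. For a single-factor
#' design the cross-level blocks vanish and the sum runs over the diagonal.
#'
#' @inheritParams reml_criterion
#' @param k factor index.
#' @return `q_k^2 x q_k^2` symmetric matrix.
#' @export
fisher_info_block <- function(forms, spec, Dblocks, k, method = "auto") {
  kern <- pf_kernels(forms, spec, Dblocks, method)
  kern_fisher_block(kern, spec, k)
}

kern_fisher_block <- function(kern, spec, k) {
  qk <- spec$factors[[k]]$n_effects
  if (kern$type == "block") {
    Fm <- matrix(0, qk * qk, qk * qk)
    B <- kern$Bdiag
    for (a1 in seq_len(qk)) for (a2 in seq_len(qk))
      for (b1 in seq_len(qk)) for (b2 in seq_len(qk))
        Fm[(a1 - 1L) * qk + a2, (b1 - 1L) * qk + b2] <-
          sum(B[a1, b1, ] * B[a2, b2, ])
    return(Fm)
  }
  A <- factor_blocks_array(kern$ZtViZ, spec, k)  # [a, i, b, j]
  Fm <- matrix(0, qk * qk, qk * qk)
  for (a1 in seq_len(qk)) for (a2 in seq_len(qk))
    for (b1 in seq_len(qk)) for (b2 in seq_len(qk))
      Fm[(a1 - 1L) * qk + a2, (b1 - 1L) * qk + b2] <-
        sum(A[a1, , b1, ] * A[a2, , b2, ])
  Fm
}

#' Score vector for one factor's covariance block
#'
#' The gradient-direction statistic of the restricted log-likelihood with
#' respect to `vec(D_k)` (up to the constant factor that cancels against the
#' simplified information in the scoring update):
#' `vec( sum_j (Z_j'V^-1 e)(Z_j'V^-1 e)'/sigma^2 - Z_j'V^-1 Z_j
#'       + Z_j'V^-1 X (X'V^-1X)^-1 X'V^-1 Z_j )`.
#' The residual outer product is scaled by `1/sigma^2` so that the zero of the
#' score is the REML stationary point for the sigma^2-relative covariance.
#'
#' @inheritParams fisher_info_block
#' @param beta,sigma2 current fixed-effect and variance estimates.
#' @return numeric vector of length `q_k^2` (column-major `vec`).
#' @export
score_vector <- function(forms, spec, beta, sigma2, Dblocks, k,
                         method = "auto") {
  kern <- pf_kernels(forms, spec, Dblocks, method)
  kern_score(kern, spec, beta, sigma2, k)
}

kern_score <- function(kern, spec, beta, sigma2, k, xtvix_inv = NULL) {
  kern_score_parts(kern, spec, beta, sigma2, k, xtvix_inv)$score
}

# Score plus the summed diagonal blocks of Z' P_V Z for the same factor (the
# latter is the sigma^2 cross-information direction used to profile the
# scoring step).
kern_score_parts <- function(kern, spec, beta, sigma2, k, xtvix_inv = NULL) {
  f <- spec$factors[[k]]
  qk <- f$n_effects; l <- f$n_levels
  cols <- spec$block_cols[[k]]
  u <- (kern$ZtViY - kern$ZtViX %*% beta)[cols]     # Z_k' V^-1 e
  Um <- matrix(u, qk, l)
  Souter <- tcrossprod(Um) / sigma2
  if (is.null(xtvix_inv))
    xtvix_inv <- chol2inv(chol(kern$XtViX))
  W <- kern$ZtViX[cols, , drop = FALSE]             # (l qk) x p
  H <- W %*% xtvix_inv                              # (l qk) x p
  Wa <- array(0, c(qk, l, spec$p)); Wa[] <- W       # fill column-major: rows level-major
  Ha <- array(0, c(qk, l, spec$p)); Ha[] <- H
  Sproj <- matrix(0, qk, qk)
  for (a in seq_len(qk)) for (b in seq_len(qk))
    Sproj[a, b] <- sum(Ha[a, , ] * Wa[b, , ])
  if (kern$type == "block") {
    Sdiag <- apply(kern$Bdiag, c(1, 2), sum)
  } else {
    A <- factor_blocks_array(kern$ZtViZ, spec, k)
    Sdiag <- matrix(0, qk, qk)
    for (a in seq_len(qk)) for (b in seq_len(qk))
      Sdiag[a, b] <- sum(A[a, , b, ][cbind(seq_len(l), seq_len(l))])
  }
  list(score = as.numeric(Souter - Sdiag + Sproj),
       pv_diag_sum = Sdiag - Sproj)
}

#' Project a symmetric matrix onto the non-negative definite cone
#'
#' Symmetrises, eigendecomposes, clips negative eigenvalues at zero and
#' reconstructs. Idempotent, and the identity on matrices that are already
#' non-negative definite.
#'
#' @param A square numeric matrix.
#' @return nearest (Frobenius) non-negative definite matrix.
#' @export
project_nnd <- function(A) {
  A <- (A + t(A)) / 2
  if (nrow(A) == 1L) return(matrix(max(A[1, 1], 0), 1, 1))
  eg <- eigen(A, symmetric = TRUE)
  if (all(eg$values >= 0)) return(A)
  v <- pmax(eg$values, 0)
  B <- eg$vectors %*% (v * t(eg$vectors))
  (B + t(B)) / 2
}

# Method-of-moments starting covariance: variance of level-wise OLS residual
# means of the first effect, relative to sigma^2, floored at 1e-6.
fsfs_init_D <- function(forms, spec, beta, sigma2) {
  lapply(seq_len(spec$r), function(k) {
    f <- spec$factors[[k]]
    qk <- f$n_effects
    cols1 <- spec$block_cols[[k]][seq(1, f$n_levels * qk, by = qk)]
    ze <- (forms$Tv - t(forms$R) %*% beta)[cols1]
    den <- pmax(diag(forms$U)[cols1], 1)
    v <- stats::var(ze / den) / sigma2
    if (!is.finite(v)) v <- 0
    diag(max(v, 1e-6), qk)
  })
}

#' Fit one voxel by Full Simplified Fisher Scoring
#'
#' Iterates the generalised-least-squares update for `(beta, sigma^2)` and a
#' Fisher-scoring update on `vec(D_k)` for each factor, with the step size
#' reset to 1 each iteration and halved whenever the restricted log-likelihood
#' would decrease, followed by projection of each `D_k` onto the non-negative
#' definite cone. Convergence is declared when the absolute change in
#' restricted log-likelihood between successive iterations falls below `tol`;
#' exceeding `max_iter` flags the voxel non-converged. Numerical failure
#' mid-iteration flags the voxel and returns the last valid parameters.
#'
#' @param forms single-voxel product forms (`P`, `Q`, `R`, `S`, `Tv`, `U`,
#'   `n_v`).
#' @param spec the [model_spec()].
#' @param control an [fsfs_control()] list.
#' @return list with `beta`, `sigma2`, `D` (list of blocks), `loglik`,
#'   `n_iter`, `converged`, `flagged`, and `loglik_path` (restricted
#'   log-likelihood after each accepted iteration).
#' @export
fsfs_fit <- function(forms, spec, control = fsfs_control()) {
  res <- list(beta = rep(NA_real_, spec$p), sigma2 = NA_real_,
              D = NULL, loglik = NA_real_, n_iter = 0L,
              converged = FALSE, flagged = FALSE, loglik_path = numeric(0))
  out <- tryCatch(fsfs_fit_core(forms, spec, control),
                  error = function(e) NULL)
  if (is.null(out)) { res$flagged <- TRUE; return(res) }
  out
}

fsfs_fit_core <- function(forms, spec, control) {
  p <- spec$p; n_v <- forms$n_v
  ols <- chol_solve(forms$P, forms$Q, "X'X")
  beta <- drop(ols$sol)
  rss <- drop(forms$S - 2 * sum(beta * forms$Q) +
                crossprod(beta, forms$P %*% beta))
  sigma2 <- max(rss, .Machine$double.xmin) / max(n_v - p, 1)

  if (spec$r == 0L) {                     # ordinary linear model path
    kern <- pf_kernels(forms, spec, list())
    ll <- kern_criterion(kern, beta, sigma2, n_v, p)
    return(list(beta = beta, sigma2 = sigma2, D = list(), loglik = ll,
                n_iter = 0L, converged = TRUE, flagged = FALSE,
                loglik_path = ll))
  }

  D <- fsfs_init_D(forms, spec, beta, sigma2)
  prep <- if (spec$r == 1L && control$method != "general")
    prep_blockdiag(forms, spec) else NULL
  kern <- pf_kernels(forms, spec, D, control$method, prep)
  g <- kern_gls(kern, n_v, p, control$sigma_denom)
  beta <- g$beta; sigma2 <- g$sigma2
  ll_cur <- kern_criterion(kern, beta, sigma2, n_v, p)
  path <- ll_cur
  n_iter <- 0L
  converged <- FALSE
  repeat {
    xtvix_inv <- chol2inv(chol(kern$XtViX))
    scores <- lapply(seq_len(spec$r), function(k)
      kern_score_parts(kern, spec, beta, sigma2, k, xtvix_inv))
    step_for <- function(profiled) lapply(seq_len(spec$r), function(k) {
      Fk <- kern_fisher_block(kern, spec, k)
      if (profiled) {
        # profile out the sigma^2 coupling: rank-one Schur correction of the
        # information so the step is Newton-like on the profiled criterion
        cv <- as.numeric(scores[[k]]$pv_diag_sum)
        Fp <- Fk - tcrossprod(cv) / (n_v - p)
        sol <- tryCatch(chol_solve(Fp, scores[[k]]$score, "information block")$sol,
                        voxlmm_numeric = function(e)
                          chol_solve(Fk, scores[[k]]$score,
                                     "Fisher information block")$sol)
      } else {
        sol <- chol_solve(Fk, scores[[k]]$score, "Fisher information block")$sol
      }
      drop(sol)
    })
    # step halving on the end-of-iteration (post-GLS) restricted likelihood;
    # if the profiled step fails its whole line search (typically a boundary
    # voxel whose projected step is not an ascent direction), retry with the
    # plain expected-information step before giving up
    cand <- NULL
    for (profiled in c(TRUE, FALSE)) {
      deltas <- step_for(profiled)
      alpha <- 1
      halvings <- 0L
      repeat {
        Dnew <- lapply(seq_len(spec$r), function(k) {
          qk <- spec$factors[[k]]$n_effects
          project_nnd(D[[k]] + alpha * matrix(deltas[[k]], qk, qk))
        })
        cand <- tryCatch({
          kn <- pf_kernels(forms, spec, Dnew, control$method, prep)
          gn <- kern_gls(kn, n_v, p, control$sigma_denom)
          list(kern = kn, gls = gn,
               ll = kern_criterion(kn, gn$beta, gn$sigma2, n_v, p))
        }, voxlmm_numeric = function(e) NULL)
        if (!is.null(cand) && cand$ll >= ll_cur - 1e-12) break
        cand <- NULL
        alpha <- alpha / 2
        halvings <- halvings + 1L
        if (halvings > control$max_halvings) break
      }
      if (!is.null(cand)) break
    }
    if (is.null(cand)) {
      # no ascent step found; if the projected score direction cannot leave
      # the current point, this is a boundary stationary point (converged),
      # otherwise leave the voxel honestly non-converged
      path <- c(path, ll_cur)
      n_iter <- n_iter + 1L
      stuck <- all(vapply(seq_len(spec$r), function(k) {
        qk <- spec$factors[[k]]$n_effects
        sk <- matrix(scores[[k]]$score, qk, qk)
        tt <- 1e-7 / max(1, max(abs(sk)))
        max(abs(project_nnd(D[[k]] + tt * sk) - D[[k]])) < 1e-12
      }, TRUE))
      if (stuck) converged <- TRUE
      break
    }
    D <- Dnew; kern <- cand$kern
    beta <- cand$gls$beta; sigma2 <- cand$gls$sigma2
    ll <- cand$ll
    n_iter <- n_iter + 1L
    path <- c(path, ll)
    if (abs(ll - ll_cur) < control$tol) {
      converged <- TRUE
      ll_cur <- ll
      break
    }
    if (n_iter >= control$max_iter) { ll_cur <- ll; break }
    ll_cur <- ll
  }
  if (converged && control$polish && spec$r == 1L &&
      control$method != "general") {
    pol <- tryCatch(polish_single_factor(forms, spec, D, control, prep),
                    voxlmm_numeric = function(e) NULL)
    if (!is.null(pol)) {
      D <- pol$D; kern <- pol$kern
      g <- kern_gls(kern, n_v, p, control$sigma_denom)
      beta <- g$beta; sigma2 <- g$sigma2
      ll_new <- kern_criterion(kern, beta, sigma2, n_v, p)
      if (ll_new >= ll_cur - 1e-9) {     # keep only non-degrading refinements
        ll_cur <- ll_new
        path <- c(path, ll_cur)
      }
    }
  }
  list(beta = beta, sigma2 = sigma2, D = D, loglik = ll_cur,
       n_iter = n_iter, converged = converged, flagged = FALSE,
       loglik_path = path)
}

# Newton refinement of an interior single-factor optimum: drives the profiled
# score (evaluated from product forms at the GLS-profiled beta, sigma^2) to
# zero over the unique elements of D_1, with a finite-difference Jacobian.
# Skipped when the non-negative-definiteness projection is active at the
# solution (boundary optimum).
polish_single_factor <- function(forms, spec, D, control, prep = NULL) {
  qk <- spec$factors[[1]]$n_effects
  if (min(eigen((D[[1]] + t(D[[1]])) / 2, symmetric = TRUE,
                only.values = TRUE)$values) < 1e-7)
    return(NULL)
  n_v <- forms$n_v; p <- spec$p
  iu <- which(lower.tri(diag(qk), diag = TRUE), arr.ind = TRUE)
  to_D <- function(u) {
    Dk <- matrix(0, qk, qk)
    Dk[iu] <- u; Dk[iu[, c(2, 1), drop = FALSE]] <- u
    list(Dk)
  }
  score_at <- function(u) {
    Db <- to_D(u)
    kern <- pf_kernels(forms, spec, Db, control$method, prep)
    g <- kern_gls(kern, n_v, p, control$sigma_denom)
    s <- matrix(kern_score(kern, spec, g$beta, g$sigma2, 1), qk, qk)
    list(g = s[iu], kern = kern)
  }
  u <- D[[1]][iu]
  sc <- score_at(u)
  d <- length(u)
  J <- NULL
  for (it in 1:10) {
    gnorm <- max(abs(sc$g))
    if (gnorm < 1e-11) break
    if (is.null(J)) {                  # (re)build the finite-difference Jacobian
      J <- matrix(0, d, d)
      for (j in seq_len(d)) {
        h <- 1e-6 * (1 + abs(u[j]))
        up <- u; up[j] <- up[j] + h
        um <- u; um[j] <- um[j] - h
        J[, j] <- (score_at(up)$g - score_at(um)$g) / (2 * h)
      }
    }
    step <- tryCatch(-solve(J, sc$g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    if (max(abs(step)) > 0.1) step <- step * 0.1 / max(abs(step))
    u_new <- u + step
    Dk_new <- to_D(u_new)[[1]]
    if (min(eigen(Dk_new, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
      break                             # heading to the boundary: stop
    sc_new <- tryCatch(score_at(u_new), voxlmm_numeric = function(e) NULL)
    if (is.null(sc_new)) break
    u <- u_new
    # the Jacobian changes slowly near the optimum; rebuild it only when the
    # reused one stops contracting the score
    if (max(abs(sc_new$g)) > 0.3 * gnorm) J <- NULL
    sc <- sc_new
    if (max(abs(step)) < 1e-12) break
  }
  list(D = to_D(u), kern = sc$kern)
}

#' Fit a batch of voxels sharing a design pattern
#'
#' Runs the Fisher-scoring fit for every voxel of a product-form pattern group
#' (all voxels share `P`, `R`, `U` and hence `p`, `q`). Step halving and
#' convergence are tracked independently per voxel, and a numerical failure in
#' one voxel flags that voxel only — the batch never aborts.
#'
#' @param group one pattern group from [build_product_forms()].
#' @param spec the [model_spec()].
#' @param control an [fsfs_control()] list.
#' @return list of per-voxel [fsfs_fit()] results, in `group$voxels` order.
#' @export
fsfs_fit_voxels <- function(group, spec, control = fsfs_control()) {
  lapply(seq_along(group$voxels), function(j)
    fsfs_fit(voxel_forms(group, j), spec, control))
}
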