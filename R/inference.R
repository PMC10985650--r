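# Wald inference with Welch-Satterthwaite degrees of freedom, multiple-testing
# correction, and mixture chi-squared likelihood-ratio tests for random effects.

# Variance-parameter bookkeeping: eta = (sigma^2, vech(D_1), ..., vech(D_r)),
# one coordinate per unique element of each within-level covariance block.
vech_index <- function(qk) {
  idx <- which(lower.tri(diag(qk), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]   # column-major lower triangle
}

n_var_par <- function(spec) {
  as.integer(1 + sum(vapply(spec$factors, function(f)
    f$n_effects * (f$n_effects + 1) / 2, 0)))
}

# Z' P_V Z with P_V = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1, from a kernel object.
kern_ztpvz <- function(kern, spec, xtvix_inv) {
  Zz <- kern_ztviz(kern, spec)
  W <- kern$ZtViX
  Zz - W %*% xtvix_inv %*% t(W)
}

# Expected REML information of the variance parameters, unique-element
# parameterisation: I[u, w] = 1/2 tr(P Sig_u P Sig_w) with P the REML
# projection sigma^-2 P_V and Sig_u the derivative of the marginal covariance
# sigma^2 (I + Z D Z') in coordinate u.
variance_par_information <- function(kern, spec, sigma2, n_v, xtvix_inv) {
  d <- n_var_par(spec)
  info <- matrix(0, d, d)
  info[1, 1] <- (n_v - spec$p) / (2 * sigma2^2)
  if (spec$r == 0L) return(info)
  G <- kern_ztpvz(kern, spec, xtvix_inv)
  ofs <- 1L
  blocks <- list()
  for (k in seq_len(spec$r)) {
    f <- spec$factors[[k]]
    qk <- f$n_effects
    iu <- vech_index(qk)
    blocks[[k]] <- list(qk = qk, l = f$n_levels, iu = iu,
                        ofs = ofs, cols = spec$block_cols[[k]])
    ofs <- ofs + nrow(iu)
  }
  # sigma^2 x D_k cross terms: (1/(2 sigma^2)) * sum_j tr(S_u Z_j'P_V Z_j)
  for (k in seq_len(spec$r)) {
    bk <- blocks[[k]]
    Msum <- matrix(0, bk$qk, bk$qk)
    for (j in seq_len(bk$l)) {
      idx <- bk$cols[(j - 1L) * bk$qk + seq_len(bk$qk)]
      Msum <- Msum + G[idx, idx]
    }
    for (u in seq_len(nrow(bk$iu))) {
      a <- bk$iu[u, 1]; b <- bk$iu[u, 2]
      val <- if (a == b) Msum[a, a] else 2 * Msum[a, b]
      info[1, 1L + bk$ofs + u - 1L] <- info[1L + bk$ofs + u - 1L, 1] <-
        val / (2 * sigma2)
    }
  }
  # D_k x D_k' blocks via the pair tensor H[a,b,c,d] = sum_ij G_ij[a,c] G_ij[b,d]
  for (k in seq_len(spec$r)) for (k2 in k:spec$r) {
    bk <- blocks[[k]]; bk2 <- blocks[[k2]]
    A <- array(G[bk$cols, bk2$cols], c(bk$qk, bk$l, bk2$qk, bk2$l))
    H <- array(0, c(bk$qk, bk$qk, bk2$qk, bk2$qk))
    for (a in seq_len(bk$qk)) for (b in seq_len(bk$qk))
      for (cc in seq_len(bk2$qk)) for (dd in seq_len(bk2$qk))
        H[a, b, cc, dd] <- sum(A[a, , cc, ] * A[b, , dd, ])
    for (u in seq_len(nrow(bk$iu))) for (w in seq_len(nrow(bk2$iu))) {
      a <- bk$iu[u, 1]; b <- bk$iu[u, 2]
      cc <- bk2$iu[w, 1]; dd <- bk2$iu[w, 2]
      # tr(S_u G S_w G') summed over level pairs, S_u = E_ab (+ E_ba if a != b)
      val <- H[b, a, cc, dd]
      if (cc != dd) val <- val + H[b, a, dd, cc]
      if (a != b) {
        val <- val + H[a, b, cc, dd]
        if (cc != dd) val <- val + H[a, b, dd, cc]
      }
      i1 <- 1L + bk$ofs + u - 1L; i2 <- 1L + bk2$ofs + w - 1L
      info[i1, i2] <- info[i2, i1] <- val / 2
    }
  }
  info
}

# Gradient of S^2(eta) = sigma^2 L (X'V^-1X)^-1 L' (scalar, row contrast L)
# in the unique-element parameterisation.
s2_gradient <- function(kern, spec, sigma2, L, xtvix_inv) {
  d <- n_var_par(spec)
  g <- numeric(d)
  a_row <- drop(L %*% xtvix_inv)                   # 1 x p
  g[1] <- sum(a_row * drop(L))                     # L (X'V^-1X)^-1 L'
  if (spec$r == 0L) return(g)
  Av <- drop(a_row %*% t(kern$ZtViX))              # L (X'V^-1X)^-1 X'V^-1 Z, length q
  ofs <- 1L
  for (k in seq_len(spec$r)) {
    f <- spec$factors[[k]]
    qk <- f$n_effects
    Am <- matrix(Av[spec$block_cols[[k]]], qk, f$n_levels)
    iu <- vech_index(qk)
    for (u in seq_len(nrow(iu))) {
      a <- iu[u, 1]; b <- iu[u, 2]
      val <- if (a == b) sum(Am[a, ]^2) else 2 * sum(Am[a, ] * Am[b, ])
      g[1L + ofs + u - 1L] <- sigma2 * val
      }
    ofs <- ofs + nrow(iu)
  }
  g
}

#' Wald T statistic for a single-row contrast
#'
#' `T = L beta / sqrt(sigma^2 L (X'V^-1 X)^-1 L')` with `V = I + Z D Z'`
#' evaluated at the REML estimates, entirely via product forms.
#'
#' @param fit an [fsfs_fit()] result.
#' @param forms the voxel's product forms. @param spec the [model_spec()].
#' @param L numeric contrast vector of length `p`.
#' @param method kernel route.
#' @return scalar statistic (NaN with a warning-free flag when the contrast
#'   variance is not positive).
#' @export
wald_T <- function(fit, forms, spec, L, method = "auto") {
  L <- matrix(L, 1)
  kern <- pf_kernels(forms, spec, fit$D, method)
  xtvix_inv <- chol2inv(chol(kern$XtViX))
  s2c <- fit$sigma2 * drop(L %*% xtvix_inv %*% t(L))
  if (!is.finite(s2c) || s2c <= 0) return(NaN)
  drop(L %*% fit$beta) / sqrt(s2c)
}

#' Wald F statistic for a rank-`r` contrast matrix
#'
#' `F = beta' L' [L (X'V^-1X)^-1 L']^-1 L beta / (sigma^2 rank(L))`.
#'
#' @inheritParams wald_T
#' @param L contrast matrix with full row rank and `p` columns.
#' @return scalar statistic (`F >= 0`), NaN on non-positive-definite contrast
#'   covariance.
#' @export
wald_F <- function(fit, forms, spec, L, method = "auto") {
  L <- as.matrix(L)
  if (ncol(L) != spec$p) L <- t(L)
  kern <- pf_kernels(forms, spec, fit$D, method)
  xtvix_inv <- chol2inv(chol(kern$XtViX))
  Mid <- L %*% xtvix_inv %*% t(L)
  ch <- tryCatch(chol(Mid), error = function(e) NULL)
  if (is.null(ch)) return(NaN)
  Lb <- drop(L %*% fit$beta)
  v <- forwardsolve(t(ch), Lb)
  sum(v^2) / (fit$sigma2 * nrow(L))
}

#' Welch-Satterthwaite degrees of freedom for a Wald contrast
#'
#' Moment matching: `v = 2 (S^2)^2 / Var(S^2)` with
#' `S^2 = sigma^2 L (X'V^-1X)^-1 L'`. `Var(S^2)` uses the delta method
#' `(dS^2/d eta)' Var(eta) (dS^2/d eta)` over the variance parameters
#' `eta = (sigma^2, vech D_1, ..., vech D_r)`; the gradient is exact
#' closed-form matrix calculus in product forms and `Var(eta)` is the inverse
#' of the expected restricted-likelihood information. For a multi-row `L` the
#' denominator degrees of freedom pool the per-direction values
#' (Fai-Cornelius style) over an orthogonal decomposition of the contrast.
#'
#' @inheritParams wald_T
#' @param L contrast vector (T) or matrix (F).
#' @return estimated degrees of freedom (NaN at flagged voxels).
#' @export
satterthwaite_df <- function(fit, forms, spec, L, method = "auto") {
  L <- if (is.null(dim(L))) matrix(L, 1) else as.matrix(L)
  kern <- pf_kernels(forms, spec, fit$D, method)
  xtvix_inv <- chol2inv(chol(kern$XtViX))
  info <- variance_par_information(kern, spec, fit$sigma2, forms$n_v, xtvix_inv)
  Var_eta <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(Var_eta)) return(NaN)
  one_df <- function(Lrow) {
    g <- s2_gradient(kern, spec, fit$sigma2, matrix(Lrow, 1), xtvix_inv)
    S2 <- fit$sigma2 * g[1]
    vS2 <- drop(crossprod(g, Var_eta %*% g))
    if (!is.finite(S2) || S2 <= 0 || vS2 <= 0) return(NaN)
    2 * S2^2 / vS2
  }
  if (nrow(L) == 1L) return(one_df(L[1, ]))
  # orthogonalise the contrast directions in the metric L (X'V^-1X)^-1 L'
  Mid <- L %*% xtvix_inv %*% t(L)
  eg <- eigen((Mid + t(Mid)) / 2, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  dirs <- crossprod(eg$vectors[, keep, drop = FALSE], L)
  nus <- apply(dirs, 1, one_df)
  nus <- nus[is.finite(nus) & nus > 2]
  if (!length(nus)) return(NaN)
  E <- sum(nus / (nus - 2))
  rk <- sum(keep)
  if (E <= rk) return(NaN)
  2 * E / (E - rk)
}

#' p-values for Wald statistic maps
#'
#' T statistics are referred to a Student t distribution on the estimated
#' degrees of freedom (two-sided by default); F statistics to an F
#' distribution on `(rank(L), df)`.
#'
#' @param stat numeric vector of statistics. @param df degrees of freedom
#'   (recycled). @param kind `"T"` or `"F"`.
#' @param df1 numerator degrees of freedom for F.
#' @param two_sided logical, T statistics only.
#' @return vector of p-values (NaN propagates).
#' @export
p_values <- function(stat, df, kind = c("T", "F"), df1 = 1, two_sided = TRUE) {
  kind <- match.arg(kind)
  if (kind == "T") {
    p <- stats::pt(abs(stat), df, lower.tail = FALSE)
    if (two_sided) p <- 2 * p
    pmin(p, 1)
  } else {
    stats::pf(stat, df1, df, lower.tail = FALSE)
  }
}

#' Multiple-testing correction over the analysis mask
#'
#' Bonferroni (family-wise error) or Benjamini-Hochberg (false discovery
#' rate) over the `m` voxels tested.
#'
#' @param p vector of p-values over the final analysis mask.
#' @param method `"bonferroni"` or `"BH"`. @param alpha significance level.
#' @return list with `adjusted` p-values, `significant` logical mask, and the
#'   effective `threshold` on raw p-values.
#' @export
multiple_testing <- function(p, method = c("bonferroni", "BH"), alpha = 0.05) {
  method <- match.arg(method)
  ok <- is.finite(p)
  if (!any(ok)) stop("no finite p-values to correct (empty mask?)")
  m <- sum(ok)
  adj <- rep(NaN, length(p))
  adj[ok] <- stats::p.adjust(p[ok], method = if (method == "BH") "BH" else "bonferroni")
  sig <- adj <= alpha & ok
  thr <- if (method == "bonferroni") alpha / m else {
    ps <- sort(p[ok])
    below <- ps <= alpha * seq_len(m) / m
    if (any(below)) ps[max(which(below))] else 0
  }
  list(adjusted = adj, significant = sig, threshold = thr)
}

#' Mixture chi-squared likelihood-ratio test for random effects
#'
#' Compares two nested single-factor fits differing only by the inclusion of
#' random effects (`q_tilde` effects removed under the null). The statistic
#' `2 (l_full - l_null)` is clipped at zero (the boundary null makes small
#' negative values numerically possible) and referred to an even 50/50
#' mixture of chi-squared distributions on `q - q_tilde` and `q` degrees of
#' freedom, with the zero-df component a point mass at 0.
#'
#' @param loglik_null,loglik_full restricted log-likelihood vectors on the
#'   same voxels, same missingness.
#' @param q total random-effects columns in the full model.
#' @param q_tilde number removed under the null.
#' @param clip_tol most negative statistic tolerated before flagging.
#' @return list with `stat`, `df` (the pair), `p`, `flagged` (non-nested or
#'   non-converged voxels) and `n_clipped`.
#' @export
likelihood_ratio_test <- function(loglik_null, loglik_full, q, q_tilde,
                                  clip_tol = 1e-6) {
  stat <- 2 * (loglik_full - loglik_null)
  flagged <- is.finite(stat) & (stat < -clip_tol)
  flagged[!is.finite(stat)] <- TRUE
  n_clipped <- sum(stat < 0 & !flagged, na.rm = TRUE)
  stat <- pmax(stat, 0)
  a <- q - q_tilde; b <- q
  surv <- function(x, df) {
    if (df == 0) as.numeric(x <= 0) else stats::pchisq(x, df, lower.tail = FALSE)
  }
  p <- 0.5 * vapply(stat, surv, 0, df = a) + 0.5 * vapply(stat, surv, 0, df = b)
  p[stat == 0] <- 1
  p[flagged] <- NaN
  list(stat = stat, df = c(a, b), p = p, flagged = flagged,
       n_clipped = n_clipped)
}
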