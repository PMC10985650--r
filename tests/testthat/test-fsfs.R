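test_that("product-form restricted likelihood matches the dense definition", {
  toy <- make_toy(n = 15, l = 3, qk = 1, p = 2, seed = 71)
  fo <- single_forms(toy$X, toy$Z, toy$y)
  beta <- c(1.7, -0.4); s2 <- 1.3
  for (d in c(0.3, 1, 2.5)) {
    Dk <- matrix(d)
    expect_rel_equal(reml_criterion(fo, toy$spec, beta, s2, list(Dk)),
                     dense_crit(toy$X, toy$y, toy$Z,
                                assemble_full_D(list(Dk), toy$spec), beta, s2),
                     1e-10)
  }
  # shifting Y shifts S, Q, Tv and the criterion consistently with dense
  y2 <- toy$y + 2
  fo2 <- single_forms(toy$X, toy$Z, y2)
  expect_equal(fo2$S, sum(y2^2), tolerance = 1e-12)
  expect_rel_equal(reml_criterion(fo2, toy$spec, beta, s2, list(matrix(1))),
                   dense_crit(toy$X, y2, toy$Z,
                              assemble_full_D(list(matrix(1)), toy$spec),
                              beta, s2), 1e-10)
  # D = 0: identity-V linear-model limit
  D0 <- matrix(0)
  expect_rel_equal(reml_criterion(fo, toy$spec, beta, s2, list(D0)),
                   dense_crit(toy$X, toy$y, toy$Z, matrix(0, 3, 3), beta, s2),
                   1e-10)
  # with missingness the voxel's n_v (not n) enters
  toym <- make_toy(n = 15, l = 3, qk = 1, p = 2, seed = 72, miss = 3)
  fom <- single_forms(toym$X, toym$Z, toym$y, toym$m)
  expect_rel_equal(reml_criterion(fom, toym$spec, beta, s2, list(matrix(1))),
                   dense_crit(toym$X, toym$y, toym$Z,
                              assemble_full_D(list(matrix(1)), toym$spec),
                              beta, s2, m = toym$m), 1e-10)
})

test_that("GLS update matches the dense solution and its invariances", {
  toy <- make_toy(n = 12, l = 3, qk = 1, seed = 81)
  fo <- single_forms(toy$X, toy$Z, toy$y)
  # D = 0 reduces to ordinary least squares
  g0 <- gls_update(fo, toy$spec, list(matrix(0)))
  expect_rel_equal(g0$beta, drop(solve(fo$P, fo$Q)), 1e-12)
  # dense GLS oracle
  Dk <- matrix(0.7)
  g1 <- gls_update(fo, toy$spec, list(Dk))
  V <- dense_V(toy$Z, assemble_full_D(list(Dk), toy$spec))
  Vi <- solve(V)
  bd <- solve(crossprod(toy$X, Vi %*% toy$X), crossprod(toy$X, Vi %*% toy$y))
  expect_rel_equal(g1$beta, drop(bd), 1e-10)
  e <- toy$y - drop(toy$X %*% bd)
  expect_rel_equal(g1$sigma2, drop(crossprod(e, Vi %*% e)) / (12 - 3), 1e-10)
  # the printed update denominator is exposed as the "ml" scale
  gm <- gls_update(fo, toy$spec, list(Dk), sigma_denom = "ml")
  expect_rel_equal(gm$sigma2, drop(crossprod(e, Vi %*% e)) / 12, 1e-10)
  # and the product-form GLS is invariant to how the rows are batched
  fo2 <- single_forms(toy$X[c(7:12, 1:6), ], toy$Z[c(7:12, 1:6), ],
                      toy$y[c(7:12, 1:6)])
  g2 <- gls_update(fo2, toy$spec, list(Dk))
  expect_rel_equal(g2$beta, g1$beta, 1e-10)
})

test_that("Fisher information block matches the explicit Kronecker sum", {
  toy <- make_toy(n = 18, l = 3, qk = 2, seed = 91)
  fo <- single_forms(toy$X, toy$Z, toy$y)
  Dk <- matrix(c(0.9, 0.3, 0.3, 0.6), 2)
  Fm <- fisher_info_block(fo, toy$spec, list(Dk), 1)
  Vi <- solve(dense_V(toy$Z, assemble_full_D(list(Dk), toy$spec)))
  Fref <- matrix(0, 4, 4)
  for (i in 1:3) for (j in 1:3) {
    Zi <- toy$Z[, voxlmm:::level_cols(toy$spec, 1, i), drop = FALSE]
    Zj <- toy$Z[, voxlmm:::level_cols(toy$spec, 1, j), drop = FALSE]
    B <- crossprod(Zi, Vi %*% Zj)
    Fref <- Fref + kronecker(B, B)
  }
  expect_rel_equal(Fm, Fref, 1e-10)
  expect_rel_equal(Fm, t(Fm), 1e-12)
  # general (dense) route agrees with the block route
  expect_rel_equal(fisher_info_block(fo, toy$spec, list(Dk), 1, method = "general"),
                   Fm, 1e-10)
  # two-factor design: cross-level terms present, dense oracle
  toy2 <- make_toy2(seed = 92)
  fo2 <- single_forms(toy2$X, toy2$Z, toy2$y)
  Vi2 <- solve(dense_V(toy2$Z, toy2$Dfull))
  for (k in 1:2) {
    qk <- toy2$spec$factors[[k]]$n_effects
    Fref <- matrix(0, qk^2, qk^2)
    lk <- toy2$spec$factors[[k]]$n_levels
    for (i in seq_len(lk)) for (j in seq_len(lk)) {
      Zi <- toy2$Z[, voxlmm:::level_cols(toy2$spec, k, i), drop = FALSE]
      Zj <- toy2$Z[, voxlmm:::level_cols(toy2$spec, k, j), drop = FALSE]
      B <- crossprod(Zi, Vi2 %*% Zj)
      Fref <- Fref + kronecker(B, B)
    }
    expect_rel_equal(fisher_info_block(fo2, toy2$spec, toy2$D, k), Fref, 1e-9)
  }
  # q_k = 1: scalar sum of squared elements
  toy1 <- make_toy(n = 12, l = 4, qk = 1, seed = 93)
  fo1 <- single_forms(toy1$X, toy1$Z, toy1$y)
  Vi1 <- solve(dense_V(toy1$Z, diag(0.5, 4)))
  expect_rel_equal(fisher_info_block(fo1, toy1$spec, list(matrix(0.5)), 1),
                   sum(crossprod(toy1$Z, Vi1 %*% toy1$Z)^2), 1e-10)
})

test_that("score vector matches symmetric-direction finite differences (x2)", {
  toy <- make_toy(n = 15, l = 3, qk = 2, seed = 101)
  fo <- single_forms(toy$X, toy$Z, toy$y)
  beta <- c(2.8, 1.9, 0.7); s2 <- 1.1
  Dk <- matrix(c(1, .4, .4, .8), 2)
  sc <- matrix(score_vector(fo, toy$spec, beta, s2, list(Dk), 1), 2, 2)
  h <- 1e-6
  crit <- function(D) dense_crit(toy$X, toy$y, toy$Z,
                                 assemble_full_D(list(D), toy$spec), beta, s2)
  for (u in list(c(1, 1), c(2, 2), c(1, 2))) {
    S <- matrix(0, 2, 2); S[u[1], u[2]] <- 1; S[u[2], u[1]] <- 1
    fd <- (crit(Dk + h * S) - crit(Dk - h * S)) / (2 * h)
    along <- sum(sc * S)                  # directional derivative of the score form
    expect_equal(along, 2 * fd, tolerance = 1e-4 * max(1, abs(fd)))
  }
  # q_k = 1, D = 0, beta at OLS: hand-computable scalar value
  toy1 <- make_toy(n = 6, l = 2, qk = 1, p = 2, seed = 102)
  fo1 <- single_forms(toy1$X, toy1$Z, toy1$y)
  bols <- drop(solve(fo1$P, fo1$Q))
  e <- toy1$y - drop(toy1$X %*% bols)
  s2h <- sum(e^2) / 4
  hand <- 0
  Px <- toy1$X %*% solve(crossprod(toy1$X)) %*% t(toy1$X)
  for (j in 1:2) {
    zj <- toy1$Z[, j]
    hand <- hand + sum(zj * e)^2 / s2h - sum(zj * zj) +
      drop(crossprod(zj, Px %*% zj))
  }
  expect_equal(score_vector(fo1, toy1$spec, bols, s2h, list(matrix(0)), 1),
               hand, tolerance = 1e-10)
  # near-zero score at the oracle's interior optimum
  toyb <- make_toy(n = 80, l = 10, qk = 1, seed = 103, d = 1)
  fob <- single_forms(toyb$X, toyb$Z, toyb$y)
  orc <- direct_reml(toyb$X, toyb$y, toyb$spec, tol = 1e-12)
  expect_gt(orc$D[[1]][1, 1], 1e-3)      # interior, stationarity applies
  sc_opt <- score_vector(fob, toyb$spec, orc$beta, orc$sigma2, orc$D, 1)
  expect_lt(max(abs(sc_opt)), 1e-4)
})

test_that("non-negative definite projection clips eigenvalues and is idempotent", {
  A <- matrix(c(1, 2, 2, 1), 2)
  expect_equal(project_nnd(A), matrix(1.5, 2, 2), tolerance = 1e-12)
  set.seed(111)
  for (i in 1:20) {
    q <- sample(1:4, 1)
    B <- matrix(rnorm(q * q), q)
    P1 <- project_nnd(B)
    expect_gte(min(eigen(P1, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
    expect_equal(project_nnd(P1), P1, tolerance = 1e-13)
  }
  S <- crossprod(matrix(rnorm(9), 3))
  expect_equal(project_nnd(S), S, tolerance = 1e-14)
})

test_that("scoring fits agree with the dense REML oracle across design families", {
  ctl <- fsfs_control(tol = 1e-10)
  n_bad <- 0
  cases <- list()
  for (s in 1:6) cases <- c(cases,
    list(make_toy(n = 60, l = 10, qk = 1, seed = 200 + s)),
    list(make_toy(n = 60, l = 8, qk = 2, seed = 300 + s)))
  for (s in 1:4) cases <- c(cases, list(make_toy2(n = 60, seed = 400 + s)))
  for (toy in cases) {
    fo <- single_forms(toy$X, toy$Z, toy$y)
    fit <- fsfs_fit(fo, toy$spec, ctl)
    orc <- direct_reml(toy$X, toy$y, toy$spec, tol = 1e-12)
    expect_false(fit$flagged)
    interior <- all(vapply(fit$D, function(Dk)
      min(eigen(Dk, symmetric = TRUE, only.values = TRUE)$values) > 1e-6, TRUE))
    if (interior && fit$converged) {
      ok <- max(abs(c(fit$beta - orc$beta, fit$sigma2 - orc$sigma2,
                      unlist(fit$D) - unlist(orc$D)))) <= 1e-4 &&
        abs(fit$loglik - orc$loglik) <= 1e-6
      if (!ok) n_bad <- n_bad + 1
    }
    # monotone accepted restricted log-likelihoods, every voxel
    expect_true(all(diff(fit$loglik_path) > -1e-9))
  }
  # boundary/local-optimum voxels aside, interior fits must match the oracle
  expect_lte(n_bad, 1)
})

test_that("estimates are scale-equivariant: beta ~ c, sigma2 ~ c^2, D invariant", {
  toy <- make_toy(n = 40, l = 8, qk = 1, seed = 121)
  fo1 <- single_forms(toy$X, toy$Z, toy$y)
  fo2 <- single_forms(toy$X, toy$Z, 3 * toy$y)
  ctl <- fsfs_control(tol = 1e-10)
  f1 <- fsfs_fit(fo1, toy$spec, ctl)
  f2 <- fsfs_fit(fo2, toy$spec, ctl)
  expect_rel_equal(f2$beta, 3 * f1$beta, 1e-7)
  expect_rel_equal(f2$sigma2, 9 * f1$sigma2, 1e-7)
  expect_rel_equal(f2$D[[1]], f1$D[[1]], 1e-6)
})

test_that("block-diagonal fast route reproduces the general route", {
  for (qk in 1:2) {
    toy <- make_toy(n = 36, l = 6, qk = qk, seed = 130 + qk, miss = 4)
    fo <- single_forms(toy$X, toy$Z, toy$y, toy$m)
    f_blk <- fsfs_fit(fo, toy$spec, fsfs_control(tol = 1e-10, method = "blockdiag",
                                                 polish = FALSE))
    f_gen <- fsfs_fit(fo, toy$spec, fsfs_control(tol = 1e-10, method = "general",
                                                 polish = FALSE))
    expect_lt(max(abs(c(f_blk$beta - f_gen$beta, f_blk$sigma2 - f_gen$sigma2,
                        unlist(f_blk$D) - unlist(f_gen$D)))), 1e-10)
    expect_equal(f_blk$n_iter, f_gen$n_iter)
  }
})

test_that("batched voxel fits equal single fits, isolate failures, and dedupe", {
  toy <- make_toy(n = 30, l = 5, qk = 1, seed = 141)
  V <- 20
  set.seed(142)
  B <- sqrt(0.8) * matrix(rnorm(toy$spec$q * V), toy$spec$q, V)
  Y <- drop(toy$X %*% toy$beta) + toy$Z %*% B + matrix(rnorm(30 * V), 30, V)
  pf <- build_product_forms(toy$X, toy$Z, Y, matrix(TRUE, 30, V))
  ctl <- fsfs_control(tol = 1e-8)
  batch <- fsfs_fit_voxels(pf[[1]], toy$spec, ctl)
  for (j in seq_len(V)) {
    single <- fsfs_fit(voxlmm:::voxel_forms(pf[[1]], j), toy$spec, ctl)
    expect_lt(max(abs(c(batch[[j]]$beta - single$beta,
                        unlist(batch[[j]]$D) - unlist(single$D)))), 1e-10)
  }
  # identical voxels give identical output
  Y2 <- Y[, c(1, 1, 2)]
  pf2 <- build_product_forms(toy$X, toy$Z, Y2, matrix(TRUE, 30, 3))
  b2 <- fsfs_fit_voxels(pf2[[1]], toy$spec, ctl)
  expect_identical(b2[[1]], b2[[2]])
  # one corrupted voxel flags without aborting the batch
  pf3 <- build_product_forms(toy$X, toy$Z, Y[, 1:4], matrix(TRUE, 30, 4))
  pf3[[1]]$Q[, 4] <- NaN
  b3 <- fsfs_fit_voxels(pf3[[1]], toy$spec, ctl)
  expect_false(any(vapply(b3[1:3], `[[`, TRUE, "flagged")))
  expect_true(b3[[4]]$flagged)
})

test_that("iteration counts for well-specified designs are typically 5-30", {
  iters <- integer(0)
  for (s in 1:8) {
    toy <- make_toy(n = 60, l = 12, qk = 1, seed = 500 + s)
    fo <- single_forms(toy$X, toy$Z, toy$y)
    iters <- c(iters, fsfs_fit(fo, toy$spec)$n_iter)
  }
  expect_lte(median(iters), 30)
  expect_gte(median(iters), 2)
})

test_that("the r = 0 degenerate path is ordinary least squares", {
  set.seed(151)
  X <- cbind(1, rnorm(25)); y <- drop(X %*% c(1, 2)) + rnorm(25)
  spec <- model_spec(X)
  fo <- single_forms(X, matrix(0, 25, 0), y)
  fit <- fsfs_fit(fo, spec)
  lmf <- lm(y ~ X - 1)
  expect_rel_equal(fit$beta, unname(coef(lmf)), 1e-10)
  expect_rel_equal(fit$sigma2, summary(lmf)$sigma^2, 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$n_iter, 0L)
})
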