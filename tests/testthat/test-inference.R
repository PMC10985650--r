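test_that("Wald T reduces to the classical t statistic when D = 0", {
  set.seed(161)
  X <- cbind(1, runif(30, -0.5, 0.5), runif(30, -0.5, 0.5))
  y <- drop(X %*% c(1, 2, 0)) + rnorm(30)
  spec <- model_spec(X)
  fo <- single_forms(X, matrix(0, 30, 0), y)
  fit <- fsfs_fit(fo, spec)
  lmf <- summary(lm(y ~ X - 1))$coefficients
  for (j in 1:3) {
    L <- replace(numeric(3), j, 1)
    expect_equal(wald_T(fit, fo, spec, L), unname(lmf[j, "t value"]),
                 tolerance = 1e-10)
    # and the Satterthwaite reference matches classical df exactly
    p_pkg <- p_values(wald_T(fit, fo, spec, L),
                      satterthwaite_df(fit, fo, spec, L))
    expect_equal(p_pkg, unname(lmf[j, "Pr(>|t|)"]), tolerance = 1e-9)
  }
})

test_that("Wald statistics match the dense formula; F collapses to T^2", {
  toy <- make_toy(n = 40, l = 8, qk = 1, seed = 171)
  fo <- single_forms(toy$X, toy$Z, toy$y)
  fit <- fsfs_fit(fo, toy$spec, fsfs_control(tol = 1e-10))
  Vi <- solve(dense_V(toy$Z, assemble_full_D(fit$D, toy$spec)))
  XtViX <- crossprod(toy$X, Vi %*% toy$X)
  L <- c(0, 1, 0)
  t_dense <- sum(L * fit$beta) /
    sqrt(fit$sigma2 * drop(t(L) %*% solve(XtViX) %*% L))
  expect_equal(wald_T(fit, fo, toy$spec, L), t_dense, tolerance = 1e-10)
  expect_equal(wald_F(fit, fo, toy$spec, matrix(L, 1)),
               wald_T(fit, fo, toy$spec, L)^2, tolerance = 1e-10)
  Lm <- rbind(c(0, 1, 0), c(0, 0, 1))
  Fd <- drop(t(Lm %*% fit$beta) %*%
               solve(Lm %*% solve(XtViX) %*% t(Lm)) %*% (Lm %*% fit$beta)) /
    (fit$sigma2 * 2)
  expect_equal(wald_F(fit, fo, toy$spec, Lm), Fd, tolerance = 1e-9)
  # zero contrast effect gives a zero statistic
  fit0 <- fit; fit0$beta <- c(5, 0, 3)
  expect_equal(wald_T(fit0, fo, toy$spec, c(0, 1, 0)), 0)
  # beta in the null space of L gives F = 0
  fitn <- fit; fitn$beta <- c(1, 0, 0)
  expect_lt(wald_F(fitn, fo, toy$spec, Lm), 1e-20)
})

test_that("Satterthwaite df agree with the dense trace-formula oracle", {
  for (s in 1:4) {
    toy <- make_toy(n = 60, l = 8, qk = 1, seed = 180 + s)
    fo <- single_forms(toy$X, toy$Z, toy$y)
    fit <- fsfs_fit(fo, toy$spec, fsfs_control(tol = 1e-10))
    if (fit$D[[1]][1, 1] < 1e-5) next
    L <- c(0, 1, 0)
    v_pkg <- satterthwaite_df(fit, fo, toy$spec, L)
    # oracle: same moment-matching formula, but with a finite-difference
    # gradient of S^2 and dense-matrix expected information
    s2h <- fit$sigma2; dh <- fit$D[[1]][1, 1]
    n <- 60
    S2f <- function(s2, dd) {
      V <- diag(n) + dd * tcrossprod(toy$Z)
      s2 * drop(t(L) %*% solve(crossprod(toy$X, solve(V, toy$X))) %*% L)
    }
    h <- 1e-6
    gfd <- c((S2f(s2h + h, dh) - S2f(s2h - h, dh)) / (2 * h),
             (S2f(s2h, dh + h) - S2f(s2h, dh - h)) / (2 * h))
    V <- diag(n) + dh * tcrossprod(toy$Z)
    Vi <- solve(V)
    Pv <- Vi - Vi %*% toy$X %*% solve(crossprod(toy$X, Vi %*% toy$X)) %*%
      t(toy$X) %*% Vi
    P <- Pv / s2h
    Sd <- list(V, s2h * tcrossprod(toy$Z))
    I2 <- matrix(0, 2, 2)
    for (a in 1:2) for (b in 1:2)
      I2[a, b] <- 0.5 * sum(diag(P %*% Sd[[a]] %*% P %*% Sd[[b]]))
    v_orc <- 2 * S2f(s2h, dh)^2 / drop(t(gfd) %*% solve(I2) %*% gfd)
    expect_lt(abs(v_pkg - v_orc) / v_orc, 1e-3)
    expect_gt(v_pkg, 0)
  }
})

test_that("Satterthwaite df in the D -> 0 limit equal n_v - p", {
  set.seed(191)
  X <- cbind(1, rnorm(40)); y <- drop(X %*% c(1, 1)) + rnorm(40)
  spec <- model_spec(X)
  fo <- single_forms(X, matrix(0, 40, 0), y)
  fit <- fsfs_fit(fo, spec)
  expect_equal(satterthwaite_df(fit, fo, spec, c(1, 0)), 38, tolerance = 1e-9)
  # with missingness, the voxel's own observation count enters
  m <- rep(1, 40); m[1:5] <- 0
  fom <- single_forms(X, matrix(0, 40, 0), y * m, m)
  fitm <- fsfs_fit(fom, spec)
  expect_equal(satterthwaite_df(fitm, fom, spec, c(1, 0)), 33, tolerance = 1e-9)
})

test_that("Satterthwaite df are strictly positive over random converged fits", {
  set.seed(201)
  n_ok <- 0
  for (s in 1:25) {
    toy <- make_toy(n = 40, l = 6, qk = 1, seed = 600 + s,
                    d = runif(1, 0.2, 2))
    fo <- single_forms(toy$X, toy$Z, toy$y)
    fit <- fsfs_fit(fo, toy$spec)
    if (!fit$converged || fit$flagged) next
    v <- satterthwaite_df(fit, fo, toy$spec, c(0, 1, 0))
    expect_gt(v, 0)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 20)
})

test_that("p-values follow the reference distributions", {
  expect_equal(p_values(0, 10), 1)
  expect_equal(p_values(qt(0.975, 7), 7), 0.05, tolerance = 1e-12)
  expect_equal(p_values(2, 1e8), 2 * pnorm(2, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(p_values(1.5, 10, two_sided = FALSE),
               pt(1.5, 10, lower.tail = FALSE))
  expect_equal(p_values(qf(0.95, 2, 11), 11, kind = "F", df1 = 2), 0.05,
               tolerance = 1e-12)
  expect_true(is.nan(p_values(NaN, 10)))
})

test_that("multiple-testing correction: Bonferroni and step-up BH", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  # step-up by hand: 0.04 > 0.05 * 3/4, 0.02 <= 0.05 * 2/4 -> reject two
  bh <- multiple_testing(p, "BH", alpha = 0.05)
  expect_equal(unname(bh$significant), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(bh$adjusted), p.adjust(p, "BH"))
  bh2 <- multiple_testing(c(0.01, 0.02, 0.0374, 0.5), "BH", alpha = 0.05)
  expect_equal(unname(bh2$significant), c(TRUE, TRUE, TRUE, FALSE))
  bf <- multiple_testing(p, "bonferroni", alpha = 0.05)
  expect_equal(unname(bf$significant), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(bf$threshold, 0.05 / 4)
  one <- multiple_testing(0.04, "bonferroni")
  expect_true(one$significant)
  expect_true(multiple_testing(0.04, "BH")$significant)
  none <- multiple_testing(rep(1, 6), "BH")
  expect_false(any(none$significant))
  expect_error(multiple_testing(rep(NaN, 3)), "no finite")
})

test_that("mixture chi-squared LRT follows the printed even-mixture rule", {
  r0 <- likelihood_ratio_test(0, 0, q = 1, q_tilde = 1)
  expect_equal(r0$p, 1)
  expect_equal(r0$df, c(0, 1))
  # zero-df component is a point mass: p = 0.5 * P(chi2_1 > x) for x > 0
  x <- 2.7
  r1 <- likelihood_ratio_test(0, x / 2, q = 1, q_tilde = 1)
  expect_equal(r1$p, 0.5 * pchisq(x, 1, lower.tail = FALSE))
  # hand-computed even mixture at a = 1, b = 2, x = 3.84
  r2 <- likelihood_ratio_test(0, 3.84 / 2, q = 2, q_tilde = 1)
  expect_equal(r2$p, 0.5 * pchisq(3.84, 1, lower.tail = FALSE) +
                 0.5 * pchisq(3.84, 2, lower.tail = FALSE), tolerance = 1e-12)
  # monotone non-increasing in the statistic, bounded in [0, 1]
  xs <- seq(0, 20, by = 0.25)
  ps <- likelihood_ratio_test(numeric(81), xs / 2, q = 2, q_tilde = 1)$p
  expect_true(all(diff(ps) <= 1e-14))
  expect_true(all(ps >= 0 & ps <= 1))
  # small negative statistics clip to zero; large ones flag
  rneg <- likelihood_ratio_test(c(0, 0), c(-1e-9, -1), q = 1, q_tilde = 1)
  expect_equal(rneg$stat, c(0, 0))
  expect_equal(rneg$flagged, c(FALSE, TRUE))
  expect_true(is.nan(rneg$p[2]))
  expect_equal(rneg$n_clipped, 1)
})

test_that("LRT for the null-true random intercept is conservative", {
  # 1000 null replicates: data generated with no random effect, tested for a
  # single random intercept (0/1 mixture reference)
  set.seed(211)
  n <- 40; l <- 8
  X <- cbind(1, runif(n, -0.5, 0.5))
  g <- sample(c(rep(1:l, 2), sample.int(l, n - 2 * l, TRUE)))
  spec1 <- model_spec(X, list(factor_spec(g, matrix(1, n, 1))))
  spec0 <- model_spec(X)
  Z <- build_random_design(spec1)
  B <- 1000
  stats <- numeric(B)
  for (b in seq_len(B)) {
    y <- drop(X %*% c(1, 1)) + rnorm(n)
    f1 <- fsfs_fit(single_forms(X, Z, y), spec1)
    f0 <- fsfs_fit(single_forms(X, matrix(0, n, 0), y), spec0)
    stats[b] <- 2 * (f1$loglik - f0$loglik)
  }
  res <- likelihood_ratio_test(numeric(B), stats / 2, q = 1, q_tilde = 1)
  alpha <- 0.05
  rate <- mean(res$p < alpha, na.rm = TRUE)
  mc_se <- sqrt(alpha * (1 - alpha) / B)
  expect_lte(rate, alpha + 3 * mc_se)
})
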