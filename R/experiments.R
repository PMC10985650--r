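# Whole-image validation experiments: scaled-down reproductions of the
# simulation study. Exported so that reproducibility scripts and the test
# suite run exactly the same code paths.

# Fit every retained voxel of one simulated instance; returns per-voxel
# estimate matrices plus the pattern groups (for oracle reuse).
fit_instance <- function(sim, sim_img, threshold = 50, tol = 1e-6,
                         max_iter = 1e4, keep_y = FALSE) {
  spec <- sim$spec
  mask_v <- as.vector(sim_img$mask)
  Y <- sim_img$Y[, mask_v, drop = FALSE]
  masks <- sim_img$image_masks[, mask_v, drop = FALSE]
  M <- compute_missingness(Y, masks)
  keep <- apply_missingness_threshold(M, threshold)
  Y[!M] <- 0
  Yk <- Y[, keep, drop = FALSE]
  pf <- build_product_forms(spec$X, sim$Z, Yk, M[, keep, drop = FALSE])
  rf <- rank_filter(pf, safe_mode = TRUE,
                    full_rank_P = voxlmm_rank(crossprod(spec$X)),
                    full_rank_U = voxlmm_rank(crossprod(sim$Z)))
  groups <- pf[rf$keep]
  ctl <- fsfs_control(tol = tol, max_iter = max_iter)
  fits <- lapply(groups, fsfs_fit_voxels, spec = spec, control = ctl)
  ygroups <- if (keep_y)
    lapply(groups, function(g) Yk[, g$voxels, drop = FALSE]) else NULL
  list(spec = spec, groups = groups, fits = fits, ygroups = ygroups,
       n_kept = sum(keep), n_dropped = rf$n_dropped)
}

# Pull a named per-voxel summary out of fit_instance output.
collect_fits <- function(inst, fun) {
  unlist(lapply(seq_along(inst$groups), function(gi)
    vapply(inst$fits[[gi]], fun, 0)), use.names = FALSE)
}

#' Scoring-vs-oracle agreement experiment (single-variance design)
#'
#' Simulates instances of the one-factor/one-effect design, fits every
#' retained voxel with the Fisher-scoring optimiser at a tight tolerance and
#' with the independent dense spectral REML oracle, and reports the mean
#' absolute difference of the random-effects variance estimates across all
#' voxels and instances.
#'
#' @param n_instances simulation instances. @param dims volume dimensions.
#' @param n observations per instance. @param n_levels factor levels.
#' @param tol scoring convergence tolerance. @param seed base random seed.
#' @return list with `mad_d` (mean absolute difference), `per_instance`,
#'   `n_voxels`, `iter_median`.
#' @export
run_oracle_agreement <- function(n_instances = 10, dims = c(16, 16, 16),
                                 n = 200, n_levels = 100, tol = 1e-10,
                                 seed = 1) {
  diffs <- numeric(0)
  per_instance <- numeric(n_instances)
  iters <- integer(0)
  for (inst in seq_len(n_instances)) {
    set.seed(seed + 7919L * inst)
    sim <- simulate_design(1, n = n, levels = n_levels)
    sim_img <- simulate_images(sim, dims = dims)
    fit <- fit_instance(sim, sim_img, tol = tol, keep_y = TRUE)
    d_inst <- numeric(0)
    for (gi in seq_along(fit$groups)) {
      g <- fit$groups[[gi]]
      Zm <- zero_out_rows(sim$Z, g$m)
      Xm <- zero_out_rows(sim$spec$X, g$m)
      sv <- svd(Zm, nv = 0)
      for (j in seq_along(g$voxels)) {
        f <- fit$fits[[gi]][[j]]
        if (f$flagged || !f$converged) next
        orc <- direct_reml_1var(Xm, fit$ygroups[[gi]][, j], Zm, g$n_v, sv = sv)
        d_inst <- c(d_inst, abs(f$D[[1]][1, 1] - orc$d))
        iters <- c(iters, f$n_iter)
      }
    }
    diffs <- c(diffs, d_inst)
    per_instance[inst] <- mean(d_inst)
  }
  list(mad_d = mean(diffs), per_instance = per_instance,
       n_voxels = length(diffs), iter_median = stats::median(iters))
}

#' Parameter-recovery experiment
#'
#' Simulates instances of a chosen design at the generative values
#' (`beta = (4,3,2,1,0)`, `sigma^2 = 1`, covariance blocks with unit diagonal
#' and 0.5 off-diagonal), fits every retained voxel, and reports means of the
#' estimates across voxels and instances along with Monte-Carlo standard
#' errors (across instance means).
#'
#' @param design 1, 2 or 3. @param n_instances instances. @param dims volume
#'   dimensions. @param n observations. @param levels optional level-count
#'   override. @param tol scoring tolerance. @param seed base seed.
#' @return list with `beta_mean` (length p), `D_diag_mean`, `D_offdiag_mean`
#'   (first factor), `sigma2_mean`, matching `*_se` Monte-Carlo standard
#'   errors, `iter_median`, `conv_rate`, `n_voxels`.
#' @export
run_recovery <- function(design = 1, n_instances = 25, dims = c(12, 12, 12),
                         n = 200, levels = NULL, tol = 1e-6, seed = 1) {
  p <- 5L
  inst_beta <- matrix(NA_real_, n_instances, p)
  inst_diag <- rep(NA_real_, n_instances)
  inst_off <- rep(NA_real_, n_instances)
  inst_s2 <- rep(NA_real_, n_instances)
  iters <- integer(0); conv <- logical(0); nvox <- 0L
  for (inst in seq_len(n_instances)) {
    set.seed(seed + 7919L * inst)
    sim <- simulate_design(design, n = n, levels = levels)
    sim_img <- simulate_images(sim, dims = dims)
    fit <- fit_instance(sim, sim_img, tol = tol)
    ok_beta <- matrix(NA_real_, 0, p); dg <- numeric(0); off <- numeric(0)
    s2 <- numeric(0)
    for (gi in seq_along(fit$groups)) {
      for (f in fit$fits[[gi]]) {
        conv <- c(conv, f$converged && !f$flagged)
        if (f$flagged || !f$converged) next
        iters <- c(iters, f$n_iter)
        ok_beta <- rbind(ok_beta, f$beta)
        s2 <- c(s2, f$sigma2)
        D1 <- f$D[[1]]
        dg <- c(dg, D1[1, 1])
        if (nrow(D1) > 1) off <- c(off, D1[1, 2])
      }
    }
    nvox <- nvox + nrow(ok_beta)
    inst_beta[inst, ] <- colMeans(ok_beta)
    inst_diag[inst] <- mean(dg)
    if (length(off)) inst_off[inst] <- mean(off)
    inst_s2[inst] <- mean(s2)
  }
  se <- function(x) stats::sd(x) / sqrt(sum(is.finite(x)))
  list(beta_mean = colMeans(inst_beta), beta_se = apply(inst_beta, 2, se),
       D_diag_mean = mean(inst_diag), D_diag_se = se(inst_diag),
       D_offdiag_mean = mean(inst_off), D_offdiag_se = se(inst_off),
       sigma2_mean = mean(inst_s2), sigma2_se = se(inst_s2),
       iter_median = stats::median(iters), conv_rate = mean(conv),
       n_voxels = nvox)
}
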