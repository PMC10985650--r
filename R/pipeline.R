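# End-to-end orchestration: input specification, product-form computation,
# parameter estimation, inference and output.

#' Load and validate an analysis configuration
#'
#' YAML key/value configuration naming the response images, fixed design,
#' random-effects factors, masks, contrasts and estimation settings. Defaults:
#' `tol 1e-6`, `maxnit 1e4`, `safe_mode TRUE`, `missingness_threshold 50`
#' (percent), `n_batches 1`. The analysis mask is mandatory.
#'
#' @param path YAML file path.
#' @return validated configuration list (class `"voxlmm_config"`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("responses", "fixed_design", "analysis_mask"))
    if (is.null(cfg[[key]])) stop("config is missing mandatory key '", key, "'")
  defaults <- list(missingness_threshold = 50, threshold_type = "percent",
                   tol = 1e-6, maxnit = 1e4, safe_mode = TRUE,
                   n_batches = 1L, n_voxel_batches = 1L, header = FALSE,
                   factors = list(), image_masks = NULL, contrasts = list(),
                   output_dir = "voxlmm_out", seed = NULL)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  paths <- c(cfg$responses, cfg$fixed_design, cfg$analysis_mask, cfg$image_masks,
             unlist(lapply(cfg$factors, function(f)
               c(f$factor_vector, f$raw_regressors))))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  if (!is.null(cfg$image_masks) &&
      length(cfg$image_masks) != length(cfg$responses))
    stop("image_masks must parallel the response list (",
         length(cfg$image_masks), " vs ", length(cfg$responses), ")")
  class(cfg) <- "voxlmm_config"
  cfg
}

#' Save a configuration
#' @param cfg configuration list. @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

read_design_matrix <- function(path, header = FALSE) {
  as.matrix(utils::read.table(path, header = header,
                              sep = if (grepl("\\.tsv$", path)) "\t" else ","))
}

# Read one NIfTI and check grid/affine against the analysis mask.
read_checked_nifti <- function(path, ref_dim, ref_xform) {
  img <- RNifti::readNifti(path)
  if (!all(dim(img)[1:3] == ref_dim))
    stop("image grid mismatch with analysis mask: ", path)
  if (max(abs(RNifti::xform(img) - ref_xform)) > 1e-4)
    stop("image affine mismatch with analysis mask: ", path)
  img
}

#' Run the full mass-univariate LMM pipeline
#'
#' Four stages: input specification (read designs, images, masks), product
#' form computation (image-wise batched map-reduce, persisted so a rerun
#' resumes here), parameter estimation (Fisher scoring per voxel, grouped by
#' missingness pattern), and inference and output (Wald statistics with
#' Satterthwaite degrees of freedom, p-value maps, NIfTI output).
#'
#' @param config a [load_config()] result or a YAML path.
#' @param verbose print per-stage progress.
#' @return an output bundle (list) with per-voxel estimates, statistic maps,
#'   the final mask, and the paths of written NIfTI files.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- load_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # --- stage 1: input specification -----------------------------------------
  mask_img <- RNifti::readNifti(config$analysis_mask)
  dims <- dim(mask_img)[1:3]
  ref_xform <- RNifti::xform(mask_img)
  mask_idx <- which(as.vector(mask_img) != 0)
  X <- read_design_matrix(config$fixed_design, config$header)
  n <- length(config$responses)
  if (nrow(X) != n)
    stop("fixed design has ", nrow(X), " rows but ", n, " response images")
  factors <- lapply(config$factors, function(f)
    factor_spec(drop(read_design_matrix(f$factor_vector, config$header)),
                read_design_matrix(f$raw_regressors, config$header)))
  spec <- model_spec(X, factors)
  Z <- build_random_design(spec)
  Y <- matrix(0, n, length(mask_idx))
  image_masks <- matrix(TRUE, n, length(mask_idx))
  for (i in seq_len(n)) {
    img <- read_checked_nifti(config$responses[i], dims, ref_xform)
    Y[i, ] <- as.vector(img)[mask_idx]
    if (!is.null(config$image_masks)) {
      mi <- read_checked_nifti(config$image_masks[i], dims, ref_xform)
      image_masks[i, ] <- as.vector(mi)[mask_idx] != 0
    }
  }
  say("stage 1 (input): n = %d images, %d mask voxels [%.1fs]",
      n, length(mask_idx), as.numeric(Sys.time() - t0, units = "secs"))

  # --- stage 2: missingness + product forms ---------------------------------
  M <- compute_missingness(Y, image_masks)
  keep <- apply_missingness_threshold(M, config$missingness_threshold,
                                      config$threshold_type)
  Y[!M] <- 0
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  pf_cache <- file.path(config$output_dir, "product_forms.rds")
  if (file.exists(pf_cache)) {
    pf <- readRDS(pf_cache)
    say("stage 2 (product forms): resumed from %s", pf_cache)
  } else {
    pf <- build_product_forms(X, Z, Y[, keep, drop = FALSE],
                              M[, keep, drop = FALSE], config$n_batches)
    saveRDS(pf, pf_cache)
    say("stage 2 (product forms): %d pattern group(s) over %d voxels [%.1fs]",
        length(pf), sum(keep), as.numeric(Sys.time() - t0, units = "secs"))
  }
  rf <- rank_filter(pf, config$safe_mode,
                    full_rank_P = voxlmm_rank(crossprod(X)),
                    full_rank_U = voxlmm_rank(crossprod(Z)))
  pf_kept <- pf[rf$keep]

  # --- stage 3: estimation ---------------------------------------------------
  ctl <- fsfs_control(tol = config$tol, max_iter = config$maxnit)
  Vkeep <- sum(keep)
  est <- list(beta = matrix(NaN, spec$p, Vkeep), sigma2 = rep(NaN, Vkeep),
              D = matrix(NaN, sum(vapply(spec$factors, function(f)
                f$n_effects * (f$n_effects + 1) / 2, 0)), Vkeep),
              loglik = rep(NaN, Vkeep), n_iter = rep(NA_integer_, Vkeep),
              converged = rep(FALSE, Vkeep), flagged = rep(FALSE, Vkeep),
              n_v = rep(NA_integer_, Vkeep))
  fits <- vector("list", Vkeep)
  for (g in pf_kept) {
    res <- fsfs_fit_voxels(g, spec, ctl)
    for (j in seq_along(g$voxels)) {
      v <- g$voxels[j]
      fits[[v]] <- res[[j]]
      est$n_v[v] <- g$n_v
      est$flagged[v] <- res[[j]]$flagged
      if (!res[[j]]$flagged) {
        est$beta[, v] <- res[[j]]$beta
        est$sigma2[v] <- res[[j]]$sigma2
        if (spec$r > 0)
          est$D[, v] <- unlist(lapply(res[[j]]$D, function(Dk)
            Dk[lower.tri(Dk, diag = TRUE)]))
        est$loglik[v] <- res[[j]]$loglik
        est$n_iter[v] <- res[[j]]$n_iter
        est$converged[v] <- res[[j]]$converged
      }
    }
  }
  say("stage 3 (estimation): %d voxels fit, %d flagged, %d dropped by rank filter [%.1fs]",
      sum(!is.na(est$n_v)), sum(est$flagged, na.rm = TRUE), rf$n_dropped,
      as.numeric(Sys.time() - t0, units = "secs"))

  # --- stage 4: inference ----------------------------------------------------
  contrasts <- lapply(config$contrasts, function(ct) {
    L <- matrix(unlist(ct$L), ncol = spec$p, byrow = TRUE)
    kind <- toupper(if (is.null(ct$kind)) "T" else ct$kind)
    stat <- rep(NaN, Vkeep); df <- rep(NaN, Vkeep); Lb <- rep(NaN, Vkeep)
    for (g in pf_kept) for (j in seq_along(g$voxels)) {
      v <- g$voxels[j]
      fit <- fits[[v]]
      if (is.null(fit) || fit$flagged || !fit$converged) next
      fo <- voxel_forms(g, j)
      Lb[v] <- drop(L[1, , drop = FALSE] %*% fit$beta)
      stat[v] <- if (kind == "T") wald_T(fit, fo, spec, L[1, ])
                 else wald_F(fit, fo, spec, L)
      df[v] <- satterthwaite_df(fit, fo, spec, if (kind == "T") L[1, ] else L)
    }
    p <- p_values(stat, df, kind = if (kind == "T") "T" else "F",
                  df1 = nrow(L))
    list(name = if (is.null(ct$name)) "contrast" else ct$name,
         kind = kind, L = L, Lbeta = Lb, stat = stat, df = df, p = p,
         neglog10p = -log10(p))
  })
  say("stage 4 (inference): %d contrast(s) [%.1fs]", length(contrasts),
      as.numeric(Sys.time() - t0, units = "secs"))

  bundle <- list(spec = spec, config = config, dims = dims,
                 mask_idx = mask_idx, keep = keep, estimates = est,
                 contrasts = contrasts, rank_report = rf$report,
                 n_dropped = rf$n_dropped)
  bundle$files <- write_output_maps(bundle, mask_img, config$output_dir)
  saveRDS(bundle, file.path(config$output_dir, "bundle.rds"))
  bundle
}

#' Write output maps as NIfTI
#'
#' One map per fixed-effect column, the error variance, the unique elements
#' of each covariance block, the restricted log-likelihood, observation
#' count, iteration and convergence maps, and per contrast the effect
#' (`L beta`), statistic, degrees-of-freedom, raw p and `-log10(p)` maps.
#' Voxels outside the final analysis mask (or flagged) are NaN; the affine is
#' copied from the analysis mask.
#'
#' @param bundle pipeline output bundle. @param mask_img analysis-mask NIfTI
#'   used as geometry template. @param dir output directory.
#' @return named character vector of file paths.
#' @export
write_output_maps <- function(bundle, mask_img, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  final_idx <- bundle$mask_idx[bundle$keep]
  put <- function(vals, name) {
    vol <- array(NaN, bundle$dims)
    vol[final_idx] <- vals
    path <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol, reference = mask_img), path)
    path
  }
  est <- bundle$estimates
  files <- c()
  for (i in seq_len(nrow(est$beta)))
    files[paste0("beta", i)] <- put(est$beta[i, ], sprintf("beta_%02d", i))
  files["sigma2"] <- put(est$sigma2, "sigma2")
  if (nrow(est$D) > 0)
    for (i in seq_len(nrow(est$D)))
      files[paste0("D", i)] <- put(est$D[i, ], sprintf("D_%02d", i))
  files["loglik"] <- put(est$loglik, "loglik")
  files["n_v"] <- put(est$n_v, "n_v")
  files["n_iter"] <- put(est$n_iter, "n_iter")
  files["converged"] <- put(as.numeric(est$converged), "converged")
  for (ct in bundle$contrasts) {
    nm <- ct$name
    files[paste0(nm, "_effect")] <- put(ct$Lbeta, paste0(nm, "_Lbeta"))
    files[paste0(nm, "_stat")] <- put(ct$stat, paste0(nm, "_", ct$kind, "stat"))
    files[paste0(nm, "_df")] <- put(ct$df, paste0(nm, "_df"))
    files[paste0(nm, "_p")] <- put(ct$p, paste0(nm, "_p"))
    files[paste0(nm, "_neglog10p")] <- put(ct$neglog10p, paste0(nm, "_neglog10p"))
  }
  files
}

#' Dense-oracle debugging fit for one voxel of a configured analysis
#'
#' Reads the configured design and images, extracts a single voxel (indexed
#' within the thresholded analysis mask) and fits it with the slow dense REML
#' reference [direct_reml()]. Intended for debugging disagreements at
#' individual voxels.
#'
#' @param config a [load_config()] result or YAML path.
#' @param voxel index within the final (thresholded) analysis mask.
#' @param n_starts optimisation starts for the oracle.
#' @return the [direct_reml()] result plus the voxel's observation count.
#' @export
oracle_voxel <- function(config, voxel = 1L, n_starts = 3L) {
  if (is.character(config)) config <- load_config(config)
  mask_img <- RNifti::readNifti(config$analysis_mask)
  dims <- dim(mask_img)[1:3]
  ref_xform <- RNifti::xform(mask_img)
  mask_idx <- which(as.vector(mask_img) != 0)
  X <- read_design_matrix(config$fixed_design, config$header)
  n <- length(config$responses)
  factors <- lapply(config$factors, function(f)
    factor_spec(drop(read_design_matrix(f$factor_vector, config$header)),
                read_design_matrix(f$raw_regressors, config$header)))
  spec <- model_spec(X, factors)
  Y <- matrix(0, n, length(mask_idx))
  image_masks <- matrix(TRUE, n, length(mask_idx))
  for (i in seq_len(n)) {
    img <- read_checked_nifti(config$responses[i], dims, ref_xform)
    Y[i, ] <- as.vector(img)[mask_idx]
    if (!is.null(config$image_masks))
      image_masks[i, ] <- as.vector(read_checked_nifti(config$image_masks[i],
                                                       dims, ref_xform))[mask_idx] != 0
  }
  M <- compute_missingness(Y, image_masks)
  keep <- apply_missingness_threshold(M, config$missingness_threshold,
                                      config$threshold_type)
  kept <- which(keep)
  if (voxel < 1 || voxel > length(kept))
    stop("voxel index out of range 1..", length(kept))
  v <- kept[voxel]
  m <- M[, v]
  res <- direct_reml(X, ifelse(m, Y[, v], 0), spec, m = m, n_starts = n_starts)
  res$n_v <- sum(m)
  res
}

#' Likelihood-ratio comparison of two completed analyses
#'
#' Both analyses must share the response set, fixed design, analysis mask and
#' missingness (the usual use: a model with and without some random effects
#' of a single factor). Voxels must overlap exactly; non-overlapping or
#' non-converged voxels are flagged.
#'
#' @param bundle_null,bundle_full pipeline bundles of the nested fits.
#' @param q_tilde number of random effects removed under the null.
#' @return a [likelihood_ratio_test()] result over the shared voxels.
#' @export
pipeline_lrt <- function(bundle_null, bundle_full, q_tilde) {
  if (bundle_full$spec$r != 1L)
    stop("likelihood-ratio testing is offered for single-random-factor ",
         "models only")
  if (!identical(bundle_null$mask_idx, bundle_full$mask_idx) ||
      !identical(bundle_null$keep, bundle_full$keep))
    stop("the two analyses do not share an identical final voxel set")
  # df convention: q counts within-level random effects of the single factor
  # (a random intercept + slope model has q = 2), matching the boundary-null
  # mixture for removing q_tilde of them.
  likelihood_ratio_test(bundle_null$estimates$loglik,
                        bundle_full$estimates$loglik,
                        q = bundle_full$spec$factors[[1]]$n_effects,
                        q_tilde = q_tilde)
}
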