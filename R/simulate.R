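# Synthetic image-shaped LMM data: the generator behind every test and
# validation run. Emulates the simulation conditions of the validation study:
# uniform[-0.5, 0.5] regressors, Gaussian random-effect and noise fields,
# isotropic Gaussian smoothing of the response (FWHM 5 voxels), and randomly
# perturbed brain-shaped masks inducing missingness at the mask edge.

#' Separable 3-D Gaussian smoothing
#'
#' Convolves a volume with an isotropic Gaussian kernel
#' (`sigma = fwhm / 2.3548` voxels, truncated at 4 sigma), applied separately
#' along each axis. The kernel is renormalised at the volume boundary (each
#' smoothing weight row sums to 1), so constant fields are preserved exactly.
#'
#' @param vol 3-D numeric array. @param fwhm full width at half maximum in
#'   voxel units; 0 returns the input unchanged.
#' @return smoothed array of the same dimension.
#' @export
gaussian_smooth_3d <- function(vol, fwhm = 5) {
  if (fwhm <= 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  dims <- dim(vol)
  Ks <- lapply(dims, function(d) {
    K <- outer(seq_len(d), seq_len(d), function(i, j)
      exp(-((i - j)^2) / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > ceiling(4 * sigma)] <- 0
    K / rowSums(K)
  })
  # axis 1: K1 %*% unfold; axis 2 and 3 via permutes
  x <- matrix(vol, dims[1])
  x <- Ks[[1]] %*% x
  x <- array(x, dims)
  x <- aperm(x, c(2, 1, 3))
  x <- array(Ks[[2]] %*% matrix(x, dims[2]), dims[c(2, 1, 3)])
  x <- aperm(x, c(2, 1, 3))
  x <- aperm(x, c(3, 1, 2))
  x <- array(Ks[[3]] %*% matrix(x, dims[3]), dims[c(3, 1, 2)])
  aperm(x, c(2, 3, 1))
}

#' Brain-shaped base analysis mask
#'
#' A smooth ellipsoid occupying roughly half the volume, standing in for a
#' standard-space brain mask so that simulations have an interior far from
#' the boundary and an edge band where perturbed masks induce missingness.
#'
#' @param dims integer length-3 volume dimensions (each >= 8).
#' @return logical 3-D array.
#' @export
make_base_mask <- function(dims) {
  stopifnot(length(dims) == 3, all(dims >= 8))
  ax <- lapply(1:3, function(i) (seq_len(dims[i]) - (dims[i] + 1) / 2) / (0.48 * dims[i]))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  array(r2 <= 1, dims)
}

#' Generate a simulation design
#'
#' Three canonical designs: (1) one factor grouping one random effect into
#' 100 levels; (2) one factor grouping two effects into 50 levels; (3) two
#' crossed factors, 2 effects x 20 levels and 1 effect x 10 levels. The fixed
#' design is an intercept plus four uniform[-0.5, 0.5] regressors with
#' `beta = (4, 3, 2, 1, 0)` and `sigma^2 = 1`; the first random effect of
#' each factor is an intercept, additional effects are uniform[-0.5, 0.5];
#' observations are assigned to levels uniformly at random (resampled until
#' every level is non-empty); within-level covariance blocks have unit
#' diagonal and 0.5 off-diagonal.
#'
#' @param design 1, 2 or 3.
#' @param n number of observations (images).
#' @param levels optional override of the per-factor level counts (ratio
#'   structure preserved for scaled-down runs).
#' @param beta,sigma2 generative fixed effects and error variance.
#' @return list with `spec` (a [model_spec()]), `Z`, and `truth` (`beta`,
#'   `sigma2`, `D` blocks).
#' @export
simulate_design <- function(design = 1, n = 200, levels = NULL,
                            beta = c(4, 3, 2, 1, 0), sigma2 = 1) {
  conf <- switch(as.character(design),
                 "1" = list(l = 100, qk = 1),
                 "2" = list(l = 50, qk = 2),
                 "3" = list(l = c(20, 10), qk = c(2, 1)),
                 stop("design must be 1, 2 or 3"))
  if (!is.null(levels)) conf$l <- levels
  if (any(n < conf$l)) stop("n must be at least the number of levels")
  p <- length(beta)
  X <- cbind(1, matrix(stats::runif(n * (p - 1), -0.5, 0.5), n))
  factors <- lapply(seq_along(conf$l), function(k) {
    l <- conf$l[k]; qk <- conf$qk[k]
    if (n < l * qk)
      stop("n must be at least levels x effects (", l * qk, ") for factor ", k)
    # uniform level assignment, conditioned on every level receiving at least
    # q_k observations (pinned, order randomised): an unconstrained uniform
    # draw leaves some level with < q_k observations with high probability,
    # making the within-level block of Z'Z singular and the full design
    # rank-deficient — the rank filter would then discard every voxel
    g <- sample(c(rep(seq_len(l), qk), sample.int(l, n - l * qk, replace = TRUE)))
    z <- cbind(rep(1, n))
    if (qk > 1) z <- cbind(z, matrix(stats::runif(n * (qk - 1), -0.5, 0.5), n))
    factor_spec(g, z)
  })
  spec <- model_spec(X, factors)
  D <- lapply(conf$qk, function(qk) {
    Dk <- matrix(0.5, qk, qk); diag(Dk) <- 1; Dk
  })
  list(spec = spec, Z = build_random_design(spec),
       truth = list(beta = beta, sigma2 = sigma2, D = D))
}

# Calibrated mask perturbation: the smoothed mask indicator is jittered with a
# unit-variance smoothed Gaussian field and re-thresholded at 0.5, flipping
# voxels in the band where the smoothed indicator is near 0.5 (the mask edge).
perturb_mask <- function(base, smooth_ind, fwhm = 5, amplitude = 0.05) {
  dims <- dim(base)
  noise <- gaussian_smooth_3d(array(stats::rnorm(prod(dims)), dims), fwhm)
  noise <- noise / stats::sd(noise)
  base & ((smooth_ind + amplitude * noise) > 0.5)
}

#' Simulate a full image set under a design
#'
#' Per voxel `v`: `Y_v = X beta + Z b_v + eps_v` with
#' `b_v ~ N(0, sigma^2 D)` and `eps_v ~ N(0, sigma^2 I)`, generated as
#' independent Gaussian fields over the volume. Each response image is then
#' smoothed (isotropic Gaussian, FWHM in voxels) to induce spatial
#' correlation, and masked by a randomly perturbed copy of the base mask,
#' simulating missingness near the brain edge; masked-out values are encoded
#' as 0. Smoothing scales the marginal variance of both `b` and `eps` by the
#' same kernel factor, so `beta` and the sigma^2-relative covariance `D` are
#' preserved as estimands while `sigma^2` shrinks to the kernel-dependent
#' value.
#'
#' @param sim output of [simulate_design()].
#' @param dims volume dimensions. @param fwhm smoothing FWHM in voxels.
#' @param mask optional base analysis mask (default [make_base_mask()]).
#' @param perturb logical: apply per-image random mask perturbation.
#' @param amplitude perturbation noise amplitude.
#' @return list with `Y` (`n x V` matrix over the full grid, masked values
#'   0), `image_masks` (`n x V` logical), `mask` (base analysis mask array),
#'   `dims`, and `truth` carried through (including the random-effect field
#'   `b`, `q x V`).
#' @export
simulate_images <- function(sim, dims = c(20, 20, 20), fwhm = 5,
                            mask = NULL, perturb = TRUE, amplitude = 0.05) {
  spec <- sim$spec
  n <- spec$n; q <- spec$q
  Vn <- prod(dims)
  if (is.null(mask)) mask <- make_base_mask(dims)
  truth <- sim$truth
  b <- matrix(stats::rnorm(q * Vn), q, Vn)
  if (q > 0) {
    Dfull <- assemble_full_D(truth$D, spec)
    b <- sqrt(truth$sigma2) * crossprod(chol(Dfull + diag(1e-12, q)), b)
    Yl <- sim$Z %*% b
  } else Yl <- matrix(0, n, Vn)
  eps <- matrix(stats::rnorm(n * Vn, sd = sqrt(truth$sigma2)), n, Vn)
  Y <- as.vector(spec$X %*% truth$beta) + Yl + eps
  if (fwhm > 0)
    for (i in seq_len(n))
      Y[i, ] <- as.vector(gaussian_smooth_3d(array(Y[i, ], dims), fwhm))
  image_masks <- matrix(TRUE, n, Vn)
  if (perturb) {
    smooth_ind <- gaussian_smooth_3d(array(as.numeric(mask), dims), fwhm)
    for (i in seq_len(n))
      image_masks[i, ] <- as.vector(perturb_mask(mask, smooth_ind, fwhm, amplitude))
  } else {
    image_masks <- matrix(rep(as.logical(mask), each = n), n, Vn)
  }
  Y[!image_masks] <- 0
  list(Y = Y, image_masks = image_masks, mask = mask, dims = dims,
       truth = c(truth, list(b = b)))
}

#' Write a simulated instance to disk as NIfTI + delimited text
#'
#' Emits one NIfTI per response image and per-image mask, the analysis mask,
#' the fixed design and per-factor specifications as delimited text, and the
#' generative truth as JSON, plus a ready-to-run analysis configuration.
#'
#' @param sim_img output of [simulate_images()]. @param sim the matching
#'   [simulate_design()] output. @param dir output directory.
#' @return the configuration file path, invisibly.
#' @export
write_simulation <- function(sim_img, sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- sim$spec
  dims <- sim_img$dims
  mask_path <- file.path(dir, "analysis_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(sim_img$mask), dims)),
                     mask_path)
  y_paths <- character(spec$n); m_paths <- character(spec$n)
  for (i in seq_len(spec$n)) {
    y_paths[i] <- file.path(dir, sprintf("Y_%04d.nii.gz", i))
    m_paths[i] <- file.path(dir, sprintf("mask_%04d.nii.gz", i))
    RNifti::writeNifti(RNifti::asNifti(array(sim_img$Y[i, ], dims)), y_paths[i])
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(sim_img$image_masks[i, ]),
                                             dims)), m_paths[i])
  }
  utils::write.table(spec$X, file.path(dir, "X.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  fac <- list()
  for (k in seq_len(spec$r)) {
    gp <- file.path(dir, sprintf("factor%d_g.csv", k))
    zp <- file.path(dir, sprintf("factor%d_z.csv", k))
    utils::write.table(spec$factors[[k]]$g, gp, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(spec$factors[[k]]$z, zp, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    fac[[k]] <- list(factor_vector = gp, raw_regressors = zp)
  }
  jsonlite::write_json(list(beta = sim$truth$beta, sigma2 = sim$truth$sigma2,
                            D = lapply(sim$truth$D, as.vector)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- list(responses = y_paths, fixed_design = file.path(dir, "X.csv"),
              analysis_mask = mask_path, image_masks = m_paths,
              factors = fac, missingness_threshold = 50,
              output_dir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
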