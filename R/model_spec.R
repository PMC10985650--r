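#' Specify one random-effects factor
#'
#' A factor groups `q_k` random-effect regressors into `l_k` levels. The
#' grouping is given by a factor vector (one label per observation) and the
#' regressors by a "raw" regressor matrix `z_k` of dimension `n x q_k` (for a
#' random intercept, a column of ones).
#'
#' Level labels may be arbitrary (integers, strings); they are normalised to
#' dense integers `1..l_k` in order of first appearance and the mapping is
#' retained in the returned object.
#'
#' @param g length-`n` vector of level labels.
#' @param z `n x q_k` numeric matrix of raw regressors (a vector is treated as
#'   a single column).
#' @param name optional factor name used in printing and output file names.
#' @return An object of class `"factor_spec"` with elements `g` (dense integer
#'   labels), `z`, `n_levels`, `n_effects`, `levels` (original labels in
#'   mapped order) and `name`.
#' @export
factor_spec <- function(g, z, name = NULL) {
  if (is.matrix(g)) g <- drop(g)
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (length(g) != nrow(z))
    stop("factor vector and raw regressor matrix disagree on n: ",
         length(g), " vs ", nrow(z))
  if (anyNA(g)) stop("factor vector contains missing labels")
  lev <- unique(g)                      # first-appearance order
  gi <- match(g, lev)
  if (any(colSums(z != 0) == 0))
    stop("raw regressor matrix has an all-zero column")
  structure(list(g = as.integer(gi), z = z,
                 n_levels = length(lev), n_effects = ncol(z),
                 levels = lev, name = name),
            class = "factor_spec")
}

validate_factor_spec <- function(fs, n) {
  if (length(fs$g) != n) stop("factor vector length ", length(fs$g),
                              " does not match design rows ", n)
  tab <- tabulate(fs$g, fs$n_levels)
  if (any(tab == 0))
    stop("factor level(s) ", paste(which(tab == 0), collapse = ", "),
         " never appear in the factor vector")
  bad <- which(fs$g < 1L | fs$g > fs$n_levels)
  if (length(bad))
    stop("factor label out of range at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  invisible(fs)
}

#' Specify a mass-univariate linear mixed model design
#'
#' Bundles the fixed-effects design matrix `X` with an ordered list of
#' [factor_spec()] objects and derives the model dimensions. `r = 0` factors is
#' accepted and yields the ordinary linear-model degenerate path (used, for
#' example, as the null model of a random-effects likelihood-ratio test).
#'
#' @param X `n x p` numeric fixed-effects design matrix.
#' @param factors list of [factor_spec()] objects (possibly empty).
#' @return An object of class `"model_spec"` with elements `X`, `factors`, and
#'   dimensions `n`, `p`, `q` (total random-effects columns, `sum(l_k * q_k)`),
#'   `r`, plus per-factor column index list `block_cols`.
#' @export
model_spec <- function(X, factors = list()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (p < 1) stop("fixed-effects design must have at least one column")
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  for (fs in factors) {
    if (!inherits(fs, "factor_spec")) stop("factors must be factor_spec objects")
    validate_factor_spec(fs, n)
  }
  qk <- vapply(factors, function(f) f$n_levels * f$n_effects, 0)
  q <- as.integer(sum(qk))
  # level-major column ordering within each factor block
  ends <- cumsum(qk)
  block_cols <- lapply(seq_along(factors), function(k)
    seq.int(c(0, ends)[k] + 1L, ends[k]))
  structure(list(X = X, factors = factors, n = n, p = p, q = q,
                 r = length(factors), block_cols = block_cols),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Linear mixed model design: n =", x$n, ", p =", x$p,
      ", q =", x$q, ", r =", x$r, "\n")
  for (k in seq_len(x$r)) {
    f <- x$factors[[k]]
    cat(sprintf("  factor %d%s: %d levels x %d effect(s)\n", k,
                if (is.null(f$name)) "" else paste0(" (", f$name, ")"),
                f$n_levels, f$n_effects))
  }
  invisible(x)
}

#' Build the level-indicator matrix of a factor
#'
#' Row `i` has a single 1 in column `g[i]`; columns therefore partition the
#' observations by level.
#'
#' @param g length-`n` integer vector of dense level labels in `1..l`.
#' @param l number of levels.
#' @return `n x l` 0/1 matrix.
#' @export
build_indicator_matrix <- function(g, l) {
  g <- as.integer(g)
  bad <- which(g < 1L | g > l)
  if (length(bad))
    stop("level label out of range 1..", l, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  J <- matrix(0, length(g), l)
  J[cbind(seq_along(g), g)] <- 1
  J
}

#' Build the random-effects design matrix Z
#'
#' Z is the horizontal concatenation of one block per factor; block `k` is the
#' row-wise (Khatri-Rao) product of the factor's level-indicator matrix with
#' its raw regressor matrix, so row `i` of the block is the Kronecker product
#' of indicator row `i` with regressor row `i`. Columns are ordered
#' level-major: all `q_k` effects of level 1, then level 2, and so on —
#' the same ordering used for `vec(D_k)` throughout.
#'
#' @param spec a [model_spec()], or a list of [factor_spec()] objects.
#' @param n number of rows (only needed when `spec` is a bare factor list).
#' @return `n x q` numeric matrix (`n x 0` when there are no factors).
#' @export
build_random_design <- function(spec, n = NULL) {
  if (inherits(spec, "model_spec")) { factors <- spec$factors; n <- spec$n }
  else factors <- spec
  if (is.null(n)) stop("n required when factors are supplied directly")
  if (!length(factors)) return(matrix(0, n, 0))
  blocks <- lapply(factors, function(f) {
    qk <- f$n_effects
    Zk <- matrix(0, n, f$n_levels * qk)
    cols <- (f$g - 1L) * qk              # level-major offset per row
    for (e in seq_len(qk))
      Zk[cbind(seq_len(n), cols + e)] <- f$z[, e]
    Zk
  })
  do.call(cbind, blocks)
}

#' Assemble the full block-diagonal random-effects covariance D
#'
#' The full `q x q` covariance is the direct sum over factors of `l_k`
#' identical copies of the within-level covariance `D_k`, consistent with the
#' level-major column ordering of [build_random_design()].
#'
#' @param D_blocks list of `q_k x q_k` symmetric matrices, one per factor.
#' @param spec the matching [model_spec()].
#' @return `q x q` numeric matrix.
#' @export
assemble_full_D <- function(D_blocks, spec) {
  if (length(D_blocks) != spec$r)
    stop("expected ", spec$r, " covariance block(s), got ", length(D_blocks))
  D <- matrix(0, spec$q, spec$q)
  for (k in seq_len(spec$r)) {
    f <- spec$factors[[k]]
    Dk <- as.matrix(D_blocks[[k]])
    if (!all(dim(Dk) == f$n_effects))
      stop("covariance block ", k, " is ", nrow(Dk), "x", ncol(Dk),
           " but factor has ", f$n_effects, " effect(s)")
    qk <- f$n_effects
    base <- spec$block_cols[[k]][1] - 1L
    for (j in seq_len(f$n_levels)) {
      idx <- base + (j - 1L) * qk + seq_len(qk)
      D[idx, idx] <- Dk
    }
  }
  D
}

# Column indices of level j of factor k (level-major ordering).
level_cols <- function(spec, k, j) {
  qk <- spec$factors[[k]]$n_effects
  spec$block_cols[[k]][1] - 1L + (j - 1L) * qk + seq_len(qk)
}
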