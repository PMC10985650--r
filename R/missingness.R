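#' Derive per-voxel missingness patterns
#'
#' Works on the response laid out as an `n x V` matrix over the voxels of the
#' analysis mask (one row per input image). A voxel/image pair is missing when
#' the per-image mask excludes it or the stored value is exactly 0 or NaN
#' (implicit masking). Missing responses are encoded as 0 downstream.
#'
#' @param Y `n x V` numeric response matrix.
#' @param image_masks optional `n x V` logical/0-1 matrix of per-image masks.
#' @return `n x V` logical matrix `M`; `M[i, v]` is TRUE when image `i` is
#'   observed at voxel `v`. Column sums are the per-voxel observation counts.
#' @export
compute_missingness <- function(Y, image_masks = NULL) {
  M <- is.finite(Y) & Y != 0
  if (!is.null(image_masks)) {
    if (!all(dim(image_masks) == dim(Y)))
      stop("per-image mask matrix dimensions do not match the response")
    M <- M & (image_masks != 0)
  }
  M
}

#' Apply a missingness threshold to the pattern map
#'
#' A voxel is retained when its observation count `n_v` reaches the threshold:
#' `n_v >= ceiling(threshold/100 * n)` in percentage form (boundary inclusive,
#' "at least this fraction observed"), or `n_v >= threshold` in count form.
#'
#' @param M `n x V` logical missingness pattern matrix.
#' @param threshold percentage in (0, 100] or integer count in 1..n.
#' @param type `"percent"` or `"count"`.
#' @return logical length-`V` vector: voxel retained.
#' @export
apply_missingness_threshold <- function(M, threshold = 50, type = c("percent", "count")) {
  type <- match.arg(type)
  n <- nrow(M)
  nv <- colSums(M)
  if (type == "percent") {
    if (threshold <= 0 || threshold > 100)
      stop("percentage missingness threshold must lie in (0, 100]")
    need <- ceiling(threshold / 100 * n)
  } else {
    if (threshold < 1 || threshold > n || threshold != round(threshold))
      stop("count missingness threshold must be an integer in 1..n")
    need <- threshold
  }
  nv >= need
}

#' Zero out design rows for one missingness pattern
#'
#' Rows where `m` is 0/FALSE are replaced with zeros, leaving the others
#' untouched. Cross-products of the zero-ed design equal those of the design
#' with the rows deleted, which is why the analysis proceeds as if the missing
#' rows were never present.
#'
#' @param A numeric matrix with `length(m)` rows.
#' @param m length-`n` 0/1 or logical indicator (1 = observed).
#' @return matrix of the same shape with unobserved rows zeroed.
#' @export
zero_out_rows <- function(A, m) {
  A * as.numeric(m)
}

#' Group voxels sharing a missingness pattern
#'
#' Far from mask boundaries most voxels have complete data and share one
#' pattern; design-dependent quantities (`P`, `R`, `U`, rank checks) need
#' computing only once per group. Grouping is exact: patterns are keyed by
#' their packed byte representation and verified by comparison, so it never
#' changes numerical results, only cost.
#'
#' @param M `n x V` logical missingness pattern matrix (columns = voxels,
#'   typically already restricted to thresholded voxels).
#' @return list of groups; each has `m` (logical length-n pattern), `n_v`, and
#'   `voxels` (column indices of `M` sharing the pattern).
#' @export
group_by_pattern <- function(M) {
  V <- ncol(M)
  if (V == 0) return(list())
  pad <- logical((-nrow(M)) %% 8)  # packBits needs a multiple of 8 bits
  keys <- vapply(seq_len(V), function(v)
    paste(packBits(c(M[, v], pad), "raw"), collapse = ""), "")
  idx <- split(seq_len(V), factor(keys, levels = unique(keys)))
  lapply(idx, function(vox) {
    m <- M[, vox[1]]
    if (length(vox) > 1L && !all(M[, vox] == m))  # verify on key collision
      stop("internal error: missingness pattern key collision")
    list(m = m, n_v = sum(m), voxels = vox)
  })
}
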