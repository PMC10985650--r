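#' Plan the image-wise batching of the design rows
#'
#' Rows `1..n` are split into `B` contiguous blocks whose sizes differ by at
#' most one, mirroring the partition of the input image list across compute
#' nodes. The plan only affects where work happens, never the reduced result.
#'
#' @param n number of observations (input images).
#' @param n_batches number of batches `B`.
#' @return list of integer row-index vectors, one per batch.
#' @export
batch_plan <- function(n, n_batches = 1L) {
  n_batches <- max(1L, min(as.integer(n_batches), n))
  sizes <- rep(n %/% n_batches, n_batches)
  extra <- n %% n_batches
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  mapply(function(a, b) seq.int(a, b), c(1L, ends[-n_batches] + 1L), ends,
         SIMPLIFY = FALSE)
}

new_pf_group <- function(m, n_v, voxels, p, q) {
  list(m = m, n_v = n_v, voxels = voxels,
       P = matrix(0, p, p), R = matrix(0, p, q), U = matrix(0, q, q),
       Q = matrix(0, p, length(voxels)), Tm = matrix(0, q, length(voxels)),
       S = numeric(length(voxels)))
}

#' Partial product forms for one batch of rows
#'
#' Computes, for every pattern group, the contribution of the given row block
#' to the six cross-products `P = X'X`, `Q = X'Y`, `R = X'Z`, `S = Y'Y`,
#' `T = Y'Z`, `U = Z'Z`, with the batch rows zero-ed per group pattern.
#' Design-level pieces (`P`, `R`, `U`) are shared within a group; `Q`, `T`,
#' `S` are per voxel (stored as columns).
#'
#' @param X,Z design matrices restricted to the batch rows.
#' @param Y `length(rows) x V` response block (missing entries encoded 0).
#' @param groups output of [group_by_pattern()] over the full pattern map.
#' @param rows row indices of this batch within `1..n`.
#' @return list of per-group partial forms, in group order.
#' @export
compute_batch_product_forms <- function(X, Z, Y, groups, rows) {
  p <- ncol(X); q <- ncol(Z)
  lapply(groups, function(g) {
    mb <- as.numeric(g$m[rows])
    Xm <- X * mb
    Zm <- Z * mb
    Yb <- Y[, g$voxels, drop = FALSE]
    out <- new_pf_group(g$m, g$n_v, g$voxels, p, q)
    out$P <- crossprod(Xm)
    out$R <- crossprod(Xm, Zm)
    out$U <- crossprod(Zm)
    out$Q <- crossprod(Xm, Yb)
    out$Tm <- crossprod(Zm, Yb)
    out$S <- colSums(Yb * Yb)
    out
  })
}

#' Reduce batched partial product forms
#'
#' Element-wise sums over batches, taken pairwise in fixed batch order so the
#' result is run-to-run deterministic. By the block identity
#' `A'B = sum_b A^(b)' B^(b)` the reduction equals the single-shot
#' cross-products on the full design.
#'
#' @param partials list over batches of [compute_batch_product_forms()] output.
#' @param batch_ids optional identifiers used in the missing-batch error.
#' @return list of reduced per-group product forms.
#' @export
reduce_product_forms <- function(partials, batch_ids = seq_along(partials)) {
  absent <- vapply(partials, is.null, TRUE)
  if (any(absent))
    stop("missing product-form batch(es): ", paste(batch_ids[absent], collapse = ", "))
  acc <- partials[[1]]
  for (b in seq_along(partials)[-1]) {
    pb <- partials[[b]]
    for (gi in seq_along(acc)) {
      for (fld in c("P", "R", "U", "Q", "Tm", "S"))
        acc[[gi]][[fld]] <- acc[[gi]][[fld]] + pb[[gi]][[fld]]
    }
  }
  acc
}

#' Compute per-voxel product forms via image-wise map-reduce
#'
#' Convenience driver: plans batches, maps [compute_batch_product_forms()] over
#' them and reduces. After this stage only objects of size `O(p^2 + pq + q^2)`
#' per pattern group plus `O((p + q) V)` per-voxel pieces remain; nothing
#' scaling with `n` is retained.
#'
#' @param X `n x p` fixed design, `Z` `n x q` random design.
#' @param Y `n x V` response matrix (missing entries 0).
#' @param M `n x V` logical missingness pattern matrix.
#' @param n_batches number of image-wise batches.
#' @return object of class `"pf_set"`: list of per-group forms plus attributes
#'   `p`, `q`, `n`.
#' @export
build_product_forms <- function(X, Z, Y, M, n_batches = 1L) {
  groups <- group_by_pattern(M)
  plan <- batch_plan(nrow(X), n_batches)
  partials <- lapply(plan, function(rows)
    compute_batch_product_forms(X[rows, , drop = FALSE], Z[rows, , drop = FALSE],
                                Y[rows, , drop = FALSE], groups, rows))
  out <- reduce_product_forms(partials)
  structure(out, p = ncol(X), q = ncol(Z), n = nrow(X), class = "pf_set")
}

# exported-ish alias used by callers computing full-design reference ranks
voxlmm_rank <- function(A) numerical_rank(A)

numerical_rank <- function(A) {
  if (!length(A)) return(0L)
  sv <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A)) * .Machine$double.eps * max(sv, 0)
  sum(sv > tol)
}

#' Drop voxels with rank-deficient designs
#'
#' After reduction, voxels whose observed-row design loses rank relative to
#' the full design (e.g. a factor level with no observed rows at that voxel,
#' or fixed-effect columns collinear on the observed rows) cannot be
#' estimated stably. With `safe_mode` on (default) such voxels are dropped
#' and counted; with it off they are retained with a warning. Rank is
#' numerical: singular values above `max(p, q) * eps * sigma_max`.
#'
#' The reference ranks default to `p` and `q` but can be lowered to the full
#' design's own ranks: crossed random-intercept designs are structurally
#' rank-deficient in `Z'Z` (each factor's intercept columns sum to the ones
#' vector), which is benign — only *additional* deficiency induced by
#' missingness marks a voxel as unestimable.
#'
#' @param pf a `"pf_set"` from [build_product_forms()].
#' @param safe_mode logical.
#' @param full_rank_P,full_rank_U ranks of the complete-data `X'X` and
#'   `Z'Z`.
#' @return list with `keep` (logical per group), `report` (data.frame of per-
#'   group ranks and voxel counts) and `n_dropped` (voxel count).
#' @export
rank_filter <- function(pf, safe_mode = TRUE, full_rank_P = attr(pf, "p"),
                        full_rank_U = attr(pf, "q")) {
  p <- attr(pf, "p"); q <- attr(pf, "q")
  rp <- vapply(pf, function(g) numerical_rank(g$P), 0L)
  ru <- vapply(pf, function(g) if (q > 0) numerical_rank(g$U) else 0L, 0L)
  ok <- rp >= full_rank_P & ru >= full_rank_U
  nvox <- vapply(pf, function(g) length(g$voxels), 0L)
  report <- data.frame(group = seq_along(pf), n_v = vapply(pf, `[[`, 0, "n_v"),
                       rank_P = rp, rank_U = ru, n_voxels = nvox, retained = ok)
  if (!safe_mode && any(!ok)) {
    warning(sum(nvox[!ok]), " voxel(s) have rank-deficient designs; ",
            "retained because safe_mode is off")
    ok[] <- TRUE
  }
  list(keep = ok, report = report, n_dropped = sum(nvox[!report$retained]))
}

#' Persist partial product forms as flat binary arrays
#'
#' One `.bin` file of doubles plus a JSON sidecar carrying the batch id,
#' dimensions, voxel count and a checksum, so an interrupted run can resume at
#' the reduction step.
#'
#' @param partial one batch's output of [compute_batch_product_forms()].
#' @param path file stem; writes `<path>.bin` and `<path>.json`.
#' @param batch_id integer id recorded in the sidecar.
#' @export
write_partial_forms <- function(partial, path, batch_id) {
  vals <- unlist(lapply(partial, function(g)
    c(g$P, g$R, g$U, g$Q, g$Tm, g$S)), use.names = FALSE)
  con <- file(paste0(path, ".bin"), "wb"); on.exit(close(con))
  writeBin(vals, con, size = 8)
  meta <- list(batch_id = batch_id,
               n_groups = length(partial),
               group_voxels = lapply(partial, `[[`, "voxels"),
               group_nv = vapply(partial, `[[`, 0, "n_v"),
               p = nrow(partial[[1]]$P), q = nrow(partial[[1]]$U),
               n = length(partial[[1]]$m),
               patterns = lapply(partial, function(g) which(g$m)),
               checksum = sum(vals))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read partial product forms written by [write_partial_forms()]
#' @param path file stem used at write time.
#' @return the partial-forms list.
#' @export
read_partial_forms <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb"); on.exit(close(con))
  p <- meta$p; q <- meta$q; n <- meta$n
  vox <- meta$group_voxels
  if (is.matrix(vox)) vox <- lapply(seq_len(ncol(vox)), function(i) vox[, i])
  if (!is.list(vox)) vox <- list(vox)
  pats <- meta$patterns
  if (is.matrix(pats)) pats <- lapply(seq_len(ncol(pats)), function(i) pats[, i])
  if (!is.list(pats)) pats <- list(pats)
  total <- 0
  out <- vector("list", meta$n_groups)
  for (gi in seq_len(meta$n_groups)) {
    nv_g <- length(vox[[gi]])
    m <- logical(n); m[pats[[gi]]] <- TRUE
    g <- new_pf_group(m, meta$group_nv[gi], vox[[gi]], p, q)
    sz <- c(p * p, p * q, q * q, p * nv_g, q * nv_g, nv_g)
    vals <- readBin(con, "double", sum(sz), size = 8)
    total <- total + sum(vals)
    ofs <- cumsum(c(0, sz))
    g$P <- matrix(vals[ofs[1] + seq_len(sz[1])], p, p)
    g$R <- matrix(vals[ofs[2] + seq_len(sz[2])], p, q)
    g$U <- matrix(vals[ofs[3] + seq_len(sz[3])], q, q)
    g$Q <- matrix(vals[ofs[4] + seq_len(sz[4])], p, nv_g)
    g$Tm <- matrix(vals[ofs[5] + seq_len(sz[5])], q, nv_g)
    g$S <- vals[ofs[6] + seq_len(sz[6])]
    out[[gi]] <- g
  }
  if (abs(total - meta$checksum) > 1e-6 * max(1, abs(meta$checksum)))
    stop("checksum mismatch reading partial forms at ", path)
  out
}

# Single-voxel product-form bundle from a group (internal).
voxel_forms <- function(group, j) {
  list(P = group$P, R = group$R, U = group$U,
       Q = group$Q[, j], Tv = group$Tm[, j], S = group$S[j],
       n_v = group$n_v)
}
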