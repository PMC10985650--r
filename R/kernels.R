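# Product-form kernels: every quantity the estimation and inference code needs
# (X'V^-1 X, X'V^-1 Y, Y'V^-1 Y, Z'V^-1 Z, Z'V^-1 X, Z'V^-1 Y, log|V|) evaluated
# from the six product forms alone, via the Woodbury identity
#   V^-1 = I - Z D (I_q + U D)^-1 Z'
# and the determinant lemma log|V| = log|I_q + U D|.
#
# Two routes give identical values (tested to 1e-10):
#  - "general": dense q x q algebra, any number of factors;
#  - "blockdiag": single-factor designs, where Z'Z (and hence I + UD and
#    Z'V^-1 Z) is block diagonal by level, reducing the per-iteration cost
#    from O(q^3) to O(l_k q_k^3).

condition_numeric <- function(msg) {
  structure(class = c("voxlmm_numeric", "error", "condition"),
            list(message = msg, call = NULL))
}

# Cholesky solve with a single jitter retry (1e-10 * mean diagonal).
chol_solve <- function(A, B, what = "linear system") {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(A + diag(1e-10 * mean(diag(A)), nrow(A))),
                   error = function(e) NULL)
    if (is.null(ch)) stop(condition_numeric(paste("singular", what)))
  }
  list(sol = backsolve(ch, forwardsolve(t(ch), B)),
       logdet = 2 * sum(log(diag(ch))))
}

# Dense-route kernels.
kernels_general <- function(forms, Dfull) {
  q <- nrow(Dfull)
  IUD <- diag(q) + forms$U %*% Dfull
  ld <- determinant(IUD, logarithm = TRUE)
  if (ld$sign <= 0) stop(condition_numeric("I + U D has non-positive determinant"))
  Wi <- tryCatch(solve(IUD), error = function(e)
    stop(condition_numeric("singular I + U D")))
  G <- Dfull %*% Wi                      # D (I + U D)^-1, symmetric
  G <- (G + t(G)) / 2
  UG <- forms$U %*% G
  RG <- forms$R %*% G
  list(type = "dense",
       XtViX = forms$P - RG %*% t(forms$R),
       XtViY = drop(forms$Q - RG %*% forms$Tv),
       YtViY = drop(forms$S - crossprod(forms$Tv, G %*% forms$Tv)),
       ZtViZ = forms$U - UG %*% forms$U,
       ZtViX = t(forms$R) - UG %*% t(forms$R),
       ZtViY = drop(forms$Tv - UG %*% forms$Tv),
       logdetV = as.numeric(ld$modulus))
}

# D-independent per-level arrays for the single-factor route; computed once
# per voxel fit and reused across every kernel evaluation.
prep_blockdiag <- function(forms, spec) {
  f <- spec$factors[[1]]
  l <- f$n_levels; qk <- f$n_effects; p <- spec$p; q <- spec$q
  Ua <- array(0, c(qk, qk, l))
  for (a in seq_len(qk)) for (b in seq_len(qk))
    Ua[a, b, ] <- forms$U[cbind(seq(a, q, by = qk), seq(b, q, by = qk))]
  Ra <- array(forms$R, c(p, qk, l))
  list(Ua = Ua, Ra = Ra, Rta = aperm(Ra, c(2, 1, 3)),
       Ta = matrix(forms$Tv, qk, l))
}

# Single-factor route: per-level blocks stacked in arrays [qk, ., l].
kernels_blockdiag <- function(forms, spec, Dk, prep = NULL) {
  f <- spec$factors[[1]]
  l <- f$n_levels; qk <- f$n_effects; p <- spec$p; q <- spec$q
  if (is.null(prep)) prep <- prep_blockdiag(forms, spec)
  Ua <- prep$Ua
  # A_j = Dk (I + U_j Dk)^-1 and log det(I + U_j Dk), vectorised over levels
  Aa <- array(0, c(qk, qk, l))
  if (qk == 1L) {
    denom <- 1 + Ua[1, 1, ] * Dk[1, 1]
    if (any(denom <= 0)) stop(condition_numeric("non-positive 1 + u d"))
    Aa[1, 1, ] <- Dk[1, 1] / denom
    logdetV <- sum(log(denom))
  } else if (qk == 2L) {
    M11 <- 1 + Ua[1, 1, ] * Dk[1, 1] + Ua[1, 2, ] * Dk[2, 1]
    M12 <- Ua[1, 1, ] * Dk[1, 2] + Ua[1, 2, ] * Dk[2, 2]
    M21 <- Ua[2, 1, ] * Dk[1, 1] + Ua[2, 2, ] * Dk[2, 1]
    M22 <- 1 + Ua[2, 1, ] * Dk[1, 2] + Ua[2, 2, ] * Dk[2, 2]
    det <- M11 * M22 - M12 * M21
    if (any(det <= 0)) stop(condition_numeric("non-positive det(I + U_j D_k)"))
    logdetV <- sum(log(det))
    I11 <- M22 / det; I12 <- -M12 / det; I21 <- -M21 / det; I22 <- M11 / det
    Aa[1, 1, ] <- Dk[1, 1] * I11 + Dk[1, 2] * I21
    Aa[1, 2, ] <- Dk[1, 1] * I12 + Dk[1, 2] * I22
    Aa[2, 1, ] <- Dk[2, 1] * I11 + Dk[2, 2] * I21
    Aa[2, 2, ] <- Dk[2, 1] * I12 + Dk[2, 2] * I22
  } else {
    logdetV <- 0
    Iq <- diag(qk)
    for (j in seq_len(l)) {
      Mj <- Iq + Ua[, , j] %*% Dk
      dj <- determinant(Mj, logarithm = TRUE)
      if (dj$sign <= 0) stop(condition_numeric("non-positive det(I + U_j D_k)"))
      logdetV <- logdetV + as.numeric(dj$modulus)
      Aa[, , j] <- Dk %*% solve(Mj)
    }
  }
  # RA[, (j,b)] = sum_a R[, (j,a)] A_j[a, b]  (p x q)
  Ra <- prep$Ra
  RAa <- array(0, c(p, qk, l))
  Ta <- prep$Ta
  TAa <- matrix(0, qk, l)                 # A_j' Tv_j
  for (b in seq_len(qk)) for (a in seq_len(qk)) {
    RAa[, b, ] <- RAa[, b, ] + Ra[, a, ] * rep(Aa[a, b, ], each = p)
    TAa[b, ] <- TAa[b, ] + Aa[a, b, ] * Ta[a, ]
  }
  RA <- matrix(RAa, p, q)
  XtViX <- forms$P - RA %*% t(forms$R)
  XtViY <- drop(forms$Q - RA %*% forms$Tv)
  YtViY <- drop(forms$S - sum(TAa * Ta))
  # UA_j = U_j A_j; per-level Z'V^-1 Z block B_j = U_j - UA_j U_j
  UAa <- array(0, c(qk, qk, l))
  for (a in seq_len(qk)) for (b in seq_len(qk)) for (cc in seq_len(qk))
    UAa[a, b, ] <- UAa[a, b, ] + Ua[a, cc, ] * Aa[cc, b, ]
  Ba <- Ua
  ZtViY <- Ta
  for (a in seq_len(qk)) for (b in seq_len(qk)) {
    for (cc in seq_len(qk))
      Ba[a, b, ] <- Ba[a, b, ] - UAa[a, cc, ] * Ua[cc, b, ]
    ZtViY[a, ] <- ZtViY[a, ] - UAa[a, b, ] * Ta[b, ]
  }
  ZtViXa <- array(0, c(qk, p, l))         # Z_j' V^-1 X = R_j' - U_j A_j R_j'
  Rta <- prep$Rta                         # [a, p, l] = R_j'[a, ]
  for (a in seq_len(qk)) {
    acc <- Rta[a, , , drop = FALSE]
    dim(acc) <- c(p, l)
    for (b in seq_len(qk)) {
      rb <- Rta[b, , , drop = FALSE]; dim(rb) <- c(p, l)
      acc <- acc - rb * rep(UAa[a, b, ], each = p)
    }
    ZtViXa[a, , ] <- acc
  }
  ZtViX <- matrix(aperm(ZtViXa, c(1, 3, 2)), q, p)
  list(type = "block", qk = qk, l = l,
       XtViX = XtViX, XtViY = XtViY, YtViY = YtViY,
       Bdiag = Ba,                        # per-level Z'V^-1 Z blocks
       ZtViX = ZtViX, ZtViY = as.numeric(ZtViY),
       logdetV = logdetV)
}

# Unified entry point.
pf_kernels <- function(forms, spec, Dblocks,
                       method = c("auto", "general", "blockdiag"),
                       prep = NULL) {
  method <- match.arg(method)
  if (spec$r == 0L) {
    return(list(type = "dense", XtViX = forms$P, XtViY = drop(forms$Q),
                YtViY = drop(forms$S),
                ZtViZ = matrix(0, 0, 0), ZtViX = matrix(0, 0, spec$p),
                ZtViY = numeric(0), logdetV = 0))
  }
  if (method == "blockdiag" || (method == "auto" && spec$r == 1L))
    kernels_blockdiag(forms, spec, as.matrix(Dblocks[[1]]), prep)
  else
    kernels_general(forms, assemble_full_D(Dblocks, spec))
}

# Dense Z'V^-1 Z from a kernel object (assembles the block route on demand).
kern_ztviz <- function(kern, spec) {
  if (kern$type == "dense") return(kern$ZtViZ)
  q <- spec$q; qk <- kern$qk
  Zz <- matrix(0, q, q)
  for (j in seq_len(kern$l)) {
    idx <- (j - 1L) * qk + seq_len(qk)
    Zz[idx, idx] <- kern$Bdiag[, , j]
  }
  Zz
}

# e' V^-1 e for arbitrary beta.
kern_evie <- function(kern, beta) {
  drop(kern$YtViY - 2 * sum(beta * kern$XtViY) +
         crossprod(beta, kern$XtViX %*% beta))
}

# Restricted log-likelihood (constants dropped), Eq.-2 form with the voxel's
# observation count.
kern_criterion <- function(kern, beta, sigma2, n_v, p) {
  if (sigma2 <= 0) stop(condition_numeric("non-positive sigma^2"))
  ldX <- determinant(kern$XtViX, logarithm = TRUE)
  if (ldX$sign <= 0) stop(condition_numeric("singular X' V^-1 X"))
  -0.5 * ((n_v - p) * log(sigma2) + kern_evie(kern, beta) / sigma2 +
            kern$logdetV + as.numeric(ldX$modulus))
}
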