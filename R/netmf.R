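#' Heterogeneous circRNA-miRNA network adjacency
#'
#' Builds the `(m + n) x (m + n)` block adjacency `[[0, CM], [CM', 0]]`
#' whose first `m` nodes are circRNAs and remaining `n` nodes are miRNAs.
#' Node names are prefixed `circ:` / `mi:` to keep the namespaces distinct.
#'
#' @param CM Binary circRNA x miRNA interaction matrix.
#' @return Symmetric binary adjacency matrix with zero diagonal.
#' @export
hetero_adjacency <- function(CM) {
  CM <- as.matrix(CM)
  if (!all(CM %in% c(0, 1))) stop("CM must be binary")
  m <- nrow(CM)
  n <- ncol(CM)
  A <- matrix(0, m + n, m + n)
  A[seq_len(m), m + seq_len(n)] <- CM
  A[m + seq_len(n), seq_len(m)] <- t(CM)
  ids <- c(paste0("circ:", rownames(CM) %||% seq_len(m)),
           paste0("mi:", colnames(CM) %||% seq_len(n)))
  dimnames(A) <- list(ids, ids)
  A
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact small-window NetMF target matrix:
#   M = vol(G) / (b T) * (sum_{r=1..T} P^r) %*% Dinv,  P = Dinv %*% A,
# with Dinv entries defined as 0 for isolated nodes (no walks start or end
# there). Dense powers are used; the networks here have ~10^2-10^3 nodes.
netmf_target <- function(A, window = 10L, neg = 1) {
  stopifnot(window >= 1L, neg > 0)
  deg <- rowSums(A)
  vol <- sum(A)
  if (vol == 0) stop("network has no edges; cannot embed")
  dinv <- ifelse(deg > 0, 1 / deg, 0)
  P <- A * dinv  # row-scaled: diag(dinv) %*% A
  acc <- matrix(0, nrow(A), ncol(A))
  Pr <- diag(nrow(A))
  for (r in seq_len(window)) {
    Pr <- Pr %*% P
    acc <- acc + Pr
  }
  M <- (vol / (neg * window)) * sweep(acc, 2L, dinv, `*`)
  dimnames(M) <- dimnames(A)
  M
}

# Deterministic SVD sign convention: each left singular vector is flipped
# so that its largest-magnitude entry is positive.
svd_fix_signs <- function(sv) {
  flip <- vapply(seq_len(ncol(sv$u)), function(j) {
    col <- sv$u[, j]
    i <- which.max(abs(col))
    if (col[i] < 0) -1 else 1
  }, 0)
  sv$u <- sweep(sv$u, 2L, flip, `*`)
  sv$v <- sweep(sv$v, 2L, flip, `*`)
  sv
}

#' NetMF node embedding of the heterogeneous network
#'
#' Computes the exact small-window NetMF factorization: the random-walk
#' matrix polynomial `M = vol(G)/(bT) (sum_r P^r) D^-1` is truncated at
#' `M' = log(pmax(M, 1))` and factorized by a rank-`d` SVD; the embedding
#' is `U_d sqrt(Sigma_d)`. The computation is deterministic (LAPACK SVD
#' plus a fixed sign convention), so repeated calls are bit-identical.
#'
#' @param A Symmetric adjacency from [hetero_adjacency()].
#' @param d Embedding dimension (default 16).
#' @param window Random-walk context window `T` (default 10).
#' @param neg Negative-sampling constant `b` (default 1).
#' @return `(m + n) x d` matrix of node vectors, rownames from `A`.
#' @export
netmf_embedding <- function(A, d = 16L, window = 10L, neg = 1) {
  n_nodes <- nrow(A)
  if (d > n_nodes) stop("embedding dimension d exceeds the node count")
  M <- netmf_target(A, window = window, neg = neg)
  Mlog <- log(pmax(M, 1))
  sv <- svd_fix_signs(svd(Mlog, nu = d, nv = d))
  emb <- sv$u %*% diag(sqrt(sv$d[seq_len(d)]), d, d)
  rownames(emb) <- rownames(A)
  colnames(emb) <- paste0("dim", seq_len(d))
  emb
}

#' Split a heterogeneous embedding into circRNA and miRNA blocks
#'
#' @param emb `(m + n) x d` embedding matrix.
#' @param m Number of circRNA nodes (the first `m` rows).
#' @return List with `circ` (`m x d`) and `mi` (`n x d`) blocks.
#' @export
split_embedding <- function(emb, m) {
  if (m <= 0L || m >= nrow(emb)) stop("m must satisfy 0 < m < nrow(emb)")
  list(circ = emb[seq_len(m), , drop = FALSE],
       mi = emb[-seq_len(m), , drop = FALSE])
}

#' Min-max normalize columns to [0, 1]
#'
#' The downstream multiplicative updates require non-negative feature
#' matrices, but raw NetMF vectors are signed; each embedding column is
#' therefore rescaled to `[0, 1]`. Constant columns map to 0.
#'
#' @param X Numeric matrix.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_columns <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  out <- sweep(sweep(X, 2L, lo, `-`), 2L, span, `/`)
  out[, hi == lo] <- 0
  out
}
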