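#' Gaussian interaction profile kernel bandwidth
#'
#' The bandwidth is the reciprocal of the mean squared Euclidean norm of
#' the interaction profiles: `gamma = n / sum_i ||p_i||^2`. When every
#' profile is all-zero the bandwidth is undefined; we fall back to
#' `gamma = 1` with a warning so that cold-start entities remain usable.
#'
#' @param profiles Matrix whose rows are interaction profiles (for circRNAs
#'   the rows of CM, for miRNAs the rows of `t(CM)`).
#' @return A positive scalar bandwidth.
#' @export
gip_bandwidth <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1L) stop("need at least one profile row")
  total <- sum(profiles^2)
  if (total == 0) {
    warning("all interaction profiles are zero; using bandwidth gamma = 1")
    return(1)
  }
  nrow(profiles) / total
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' `S(i, j) = exp(-gamma * ||p_i - p_j||^2)` with the bandwidth from
#' [gip_bandwidth()]. The result is symmetric with unit diagonal and
#' entries in `(0, 1]`.
#'
#' @inheritParams gip_bandwidth
#' @param gamma Optional bandwidth override; default computed from `profiles`.
#' @return Symmetric similarity matrix, dimnames copied from the profile rows.
#' @export
gip_kernel <- function(profiles, gamma = gip_bandwidth(profiles)) {
  profiles <- as.matrix(profiles)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # clip tiny negative round-off
  S <- exp(-gamma * d2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Cosine similarity between interaction profiles
#'
#' `S(i, j) = <p_i, p_j> / (||p_i|| ||p_j||)`; for non-negative profiles the
#' result lies in `[0, 1]`. Rows with zero norm get similarity 0 against
#' everything, including themselves: an all-zero profile carries no
#' functional evidence, and the downstream fusion rule substitutes the GIP
#' similarity there.
#'
#' @param profiles Non-negative matrix whose rows are association profiles
#'   (rows of CC for circRNAs, rows of MC for miRNAs).
#' @return Symmetric similarity matrix with entries in `[0, 1]`.
#' @export
cosine_profile_similarity <- function(profiles) {
  profiles <- as.matrix(profiles)
  nrm <- sqrt(rowSums(profiles^2))
  S <- tcrossprod(profiles)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, S / denom, 0)
  S[S > 1] <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Fuse GIP and functional similarity
#'
#' Elementwise piecewise combination: the functional (cosine) similarity is
#' used wherever it is nonzero, and the GIP similarity fills in the exact
#' zeros. With binary profiles the cosine is exactly zero for disjoint
#' profiles, so a literal `== 0` test is well defined and no tolerance is
#' needed.
#'
#' @param gip GIP similarity matrix.
#' @param func Functional (cosine) similarity matrix of identical shape.
#' @return Fused similarity matrix with entries in `[0, 1]`.
#' @export
fuse_similarity <- function(gip, func) {
  if (!identical(dim(gip), dim(func))) {
    stop("similarity matrices must have identical shapes")
  }
  out <- ifelse(func == 0, gip, func)
  dimnames(out) <- dimnames(gip)
  out
}

#' All similarity matrices for a dataset
#'
#' Convenience wrapper computing the circRNA and miRNA GIP kernels from a
#' (possibly training-masked) interaction matrix, the cosine functional
#' similarities from the cancer association matrices, and their fusion.
#'
#' @param CM Binary circRNA x miRNA interaction matrix (training copy).
#' @param CC Binary circRNA x cancer matrix.
#' @param MC Binary miRNA x cancer matrix.
#' @return List with `circ_gip`, `mi_gip`, `circ_cos`, `mi_cos`,
#'   `circ_fused`, `mi_fused`.
#' @export
similarity_set <- function(CM, CC, MC) {
  circ_gip <- gip_kernel(CM)
  mi_gip <- gip_kernel(t(CM))
  circ_cos <- cosine_profile_similarity(CC)
  mi_cos <- cosine_profile_similarity(MC)
  list(circ_gip = circ_gip, mi_gip = mi_gip,
       circ_cos = circ_cos, mi_cos = mi_cos,
       circ_fused = fuse_similarity(circ_gip, circ_cos),
       mi_fused = fuse_similarity(mi_gip, mi_cos))
}
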