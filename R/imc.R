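#' Configuration for the inductive matrix completion solver
#'
#' @param ranks Low-rank dimensions for the ensemble, one fit per rank
#'   (default `c(128, 64)`). Ranks larger than a feature width are clamped
#'   at fit time with a warning.
#' @param theta1,theta2 Frobenius regularization weights on the two factors
#'   (default 1 each).
#' @param max_iter Maximum multiplicative-update sweeps (default 200).
#' @param tol Relative objective-change convergence threshold (default 1e-4).
#' @param seed Base RNG seed; run `i` of the ensemble uses `seed + i`.
#' @param eps Denominator guard added inside the update divisions.
#' @return A list of class `imc_config`.
#' @export
imc_config <- function(ranks = c(128L, 64L), theta1 = 1, theta2 = 1,
                       max_iter = 200L, tol = 1e-4, seed = 1L, eps = 1e-10) {
  stopifnot(length(ranks) >= 1L, all(ranks >= 1L), theta1 >= 0, theta2 >= 0,
            max_iter >= 1L, tol > 0, eps > 0)
  structure(list(ranks = as.integer(ranks), theta1 = theta1, theta2 = theta2,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), eps = eps),
            class = "imc_config")
}

#' Regularized inductive-matrix-completion objective
#'
#' `1/2 ||CM - X W H' Y'||_F^2 + theta1/2 ||W||_F^2 + theta2/2 ||H||_F^2`
#' where `X` is the circRNA feature matrix (rows = circRNAs) and `Y` the
#' miRNA feature matrix, so the reconstruction is circRNA x miRNA like `CM`.
#'
#' @param CM Interaction matrix (n_circ x n_mi).
#' @param circ_f,mi_f Feature matrices (n_circ x p, n_mi x q).
#' @param W,H Factor matrices (p x d, q x d).
#' @param theta1,theta2 Regularization weights.
#' @return Non-negative scalar.
#' @export
imc_objective <- function(CM, circ_f, mi_f, W, H, theta1 = 1, theta2 = 1) {
  if (ncol(circ_f) != nrow(W) || ncol(mi_f) != nrow(H) || ncol(W) != ncol(H) ||
      nrow(circ_f) != nrow(CM) || nrow(mi_f) != ncol(CM)) {
    stop("non-conformable shapes in IMC objective")
  }
  R <- CM - circ_f %*% W %*% t(H) %*% t(mi_f)
  0.5 * sum(R^2) + theta1 / 2 * sum(W^2) + theta2 / 2 * sum(H^2)
}

#' One multiplicative update sweep
#'
#' Rescales `W` then `H` (with the fresh `W`) by the ratio of the positive
#' and negative gradient parts of the regularized objective. Non-negative
#' inputs stay non-negative; an `eps` in the denominator guards 0/0.
#'
#' @inheritParams imc_objective
#' @param eps Denominator guard.
#' @return List with updated `W` and `H`.
#' @export
imc_update <- function(CM, circ_f, mi_f, W, H, theta1 = 1, theta2 = 1,
                       eps = 1e-10) {
  XtX <- crossprod(circ_f)
  YtY <- crossprod(mi_f)
  XtCMY <- t(circ_f) %*% CM %*% mi_f   # p x q

  numW <- XtCMY %*% H
  denW <- XtX %*% W %*% (crossprod(H, YtY %*% H)) + theta1 * W + eps
  W <- W * numW / denW
  if (any(!is.finite(W))) stop("multiplicative update produced non-finite W")

  numH <- t(XtCMY) %*% W
  denH <- YtY %*% H %*% (crossprod(W, XtX %*% W)) + theta2 * H + eps
  H <- H * numH / denH
  if (any(!is.finite(H))) stop("multiplicative update produced non-finite H")

  list(W = W, H = H)
}

#' Fit a single IMC factorization
#'
#' Initializes `W` and `H` with seeded uniform(0, 1) entries and iterates
#' [imc_update()] until the relative objective change falls below `tol` or
#' `max_iter` sweeps are reached.
#'
#' @inheritParams imc_objective
#' @param rank Low-rank dimension `d`; clamped (with a warning) to the
#'   smaller feature width if it exceeds it.
#' @param cfg An [imc_config()]; its `ranks` field is ignored here.
#' @param seed RNG seed for initialization (default `cfg$seed`).
#' @return List of class `imc_fit`: `W`, `H`, `rank`, `objective_trace`,
#'   `iterations`, `converged`.
#' @export
imc_fit <- function(CM, circ_f, mi_f, rank, cfg = imc_config(), seed = cfg$seed) {
  width <- min(ncol(circ_f), ncol(mi_f))
  if (rank > width) {
    warning(sprintf("rank %d exceeds feature width %d; clamping", rank, width))
    rank <- width
  }
  withr::with_seed(seed, {
    W <- matrix(stats::runif(ncol(circ_f) * rank), ncol(circ_f), rank)
    H <- matrix(stats::runif(ncol(mi_f) * rank), ncol(mi_f), rank)
  })
  obj <- imc_objective(CM, circ_f, mi_f, W, H, cfg$theta1, cfg$theta2)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    upd <- imc_update(CM, circ_f, mi_f, W, H, cfg$theta1, cfg$theta2, cfg$eps)
    W <- upd$W
    H <- upd$H
    obj_new <- imc_objective(CM, circ_f, mi_f, W, H, cfg$theta1, cfg$theta2)
    trace <- c(trace, obj_new)
    if (obj_new > 10 * trace[[1L]]) stop("IMC objective diverged")
    if (abs(obj_new - obj) / max(obj, cfg$eps) < cfg$tol) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  structure(list(W = W, H = H, rank = rank, objective_trace = trace,
                 iterations = length(trace) - 1L, converged = converged),
            class = "imc_fit")
}

#' Multi-rank ensemble prediction scores
#'
#' Runs [imc_fit()] once per rank in `cfg$ranks` (run `i` seeded with
#' `cfg$seed + i`) and returns the elementwise mean of the per-rank score
#' matrices `circ_f W H' mi_f'`.
#'
#' @inheritParams imc_objective
#' @param cfg An [imc_config()].
#' @return n_circ x n_mi score matrix (class `matrix`), with an attribute
#'   `fits` holding the per-rank `imc_fit` objects.
#' @export
imc_ensemble <- function(CM, circ_f, mi_f, cfg = imc_config()) {
  if (length(cfg$ranks) == 0L) stop("ensemble needs at least one rank")
  fits <- vector("list", length(cfg$ranks))
  acc <- matrix(0, nrow(CM), ncol(CM))
  for (i in seq_along(cfg$ranks)) {
    fits[[i]] <- imc_fit(CM, circ_f, mi_f, cfg$ranks[[i]], cfg,
                         seed = cfg$seed + i)
    acc <- acc + circ_f %*% fits[[i]]$W %*% t(fits[[i]]$H) %*% t(mi_f)
  }
  scores <- acc / length(cfg$ranks)
  dimnames(scores) <- dimnames(CM)
  attr(scores, "fits") <- fits
  scores
}
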