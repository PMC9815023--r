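#' Partition known interactions into cross-validation folds
#'
#' The positive entries of `CM` are shuffled with the given seed and dealt
#' round-robin into `n_folds` folds, so fold sizes differ by at most one.
#'
#' @param CM Binary interaction matrix.
#' @param n_folds Number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return List with `positive_pairs` (k x 2 index matrix), `fold_of_pair`
#'   (integer vector of fold ids in `1..n_folds`), `n_folds`, `seed`.
#' @export
make_folds <- function(CM, n_folds = 10L, seed = 1L) {
  pos <- which(CM != 0, arr.ind = TRUE)
  dimnames(pos) <- list(NULL, c("circ", "mi"))
  if (nrow(pos) < n_folds) {
    stop(sprintf("only %d positives but %d folds requested", nrow(pos), n_folds))
  }
  perm <- withr::with_seed(seed, sample.int(nrow(pos)))
  fold <- integer(nrow(pos))
  fold[perm] <- rep_len(seq_len(n_folds), nrow(pos))
  list(positive_pairs = pos, fold_of_pair = fold,
       n_folds = as.integer(n_folds), seed = as.integer(seed))
}

#' ROC and precision-recall curves with tie-aware thresholds
#'
#' Thresholds sweep the unique scores in descending order, processing all
#' tied items at once. AUROC is the trapezoidal area under (FPR, TPR) —
#' with tie grouping this equals the Mann-Whitney concordance statistic
#' with ties credited 0.5. AUPR uses the step-wise sum
#' `sum_i (recall_i - recall_{i-1}) * precision_i`.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (same length; both classes must be present).
#' @return List with `curve` (data.frame of threshold, TP, FP, TN, FN, TPR,
#'   FPR, precision, recall), `auroc`, `aupr`.
#' @export
roc_pr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels != 0)
  P <- sum(labels)
  N <- length(labels) - P
  if (P == 0L || N == 0L) stop("both classes must be present to draw a curve")

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp_per <- as.numeric(tapply(l, grp, sum))
  n_per <- as.numeric(tabulate(grp))
  thr <- s[!duplicated(s)]

  TP <- cumsum(tp_per)
  FP <- cumsum(n_per - tp_per)
  TN <- N - FP
  FN <- P - TP
  TPR <- TP / P
  FPR <- FP / N
  precision <- ifelse(TP + FP > 0, TP / (TP + FP), 1)

  x <- c(0, FPR)
  y <- c(0, TPR)
  auroc <- sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
  aupr <- sum(diff(c(0, TPR)) * precision)

  list(curve = data.frame(threshold = thr, TP = TP, FP = FP, TN = TN, FN = FN,
                          TPR = TPR, FPR = FPR, precision = precision,
                          recall = TPR),
       auroc = auroc, aupr = aupr)
}

#' Degree-product baseline scorer
#'
#' Scores every pair by (row degree) x (column degree) of the training
#' matrix — a topology-blind popularity baseline that any informative
#' model should beat.
#'
#' @param CM Training interaction matrix.
#' @return Score matrix of the same shape.
#' @export
degree_baseline <- function(CM) {
  out <- outer(rowSums(CM), colSums(CM))
  dimnames(out) <- dimnames(CM)
  out
}

# Default per-fold scorer: the full similarity -> embedding -> fusion ->
# IMC-ensemble pipeline, trained on the masked matrix only.
pipeline_scorer <- function(train_CM, ds, cfg, fold_seed) {
  feats <- build_features(train_CM, ds$CC, ds$MC, d = cfg$embed_dim,
                          window = cfg$window, neg = cfg$neg,
                          topology = cfg$mode != "no_topology")
  ranks <- if (cfg$mode == "single_rank") cfg$ranks[[1L]] else cfg$ranks
  icfg <- imc_config(ranks = ranks, theta1 = cfg$theta1, theta2 = cfg$theta2,
                     max_iter = cfg$max_iter, tol = cfg$tol, seed = fold_seed)
  suppressWarnings(imc_ensemble(train_CM, feats$circ, feats$mi, icfg))
}

#' End-to-end pipeline configuration
#'
#' Bundles the hyperparameters of every stage. Defaults follow the model's
#' reference settings: embedding dimension 16, IMC ranks `c(128, 64)` with
#' unit regularization, 10 folds.
#'
#' @param embed_dim NetMF embedding dimension.
#' @param window,neg NetMF context window and negative-sampling constant.
#' @param ranks IMC ensemble ranks (clamped to feature width when needed).
#' @param theta1,theta2 IMC regularization weights.
#' @param tol,max_iter IMC convergence controls.
#' @param folds Number of CV folds.
#' @param seed Base seed for folds and factor initialization.
#' @param mode Ablation mode: `"full"`, `"no_topology"` (similarity-only
#'   features), or `"single_rank"` (first rank only, no ensemble).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(embed_dim = 16L, window = 10L, neg = 1,
                            ranks = c(128L, 64L), theta1 = 1, theta2 = 1,
                            tol = 1e-4, max_iter = 200L, folds = 10L,
                            seed = 1L,
                            mode = c("full", "no_topology", "single_rank")) {
  mode <- match.arg(mode)
  structure(list(embed_dim = as.integer(embed_dim), window = as.integer(window),
                 neg = neg, ranks = as.integer(ranks), theta1 = theta1,
                 theta2 = theta2, tol = tol, max_iter = as.integer(max_iter),
                 folds = as.integer(folds), seed = as.integer(seed),
                 mode = mode),
            class = "pipeline_config")
}

#' 10-fold cross-validation of the interaction predictor
#'
#' For each fold the held-out positives are zeroed in a training copy of
#' `CM`; GIP similarities, the heterogeneous network, embeddings and
#' features are recomputed from that training matrix alone (the cosine
#' similarities depend only on `CC`/`MC` and are fold-independent), the IMC
#' ensemble is fitted, and all pairs are scored. Test-fold positives are
#' evaluated against the negatives — every pair that is 0 in the full `CM`;
#' training positives are never scored as either class. Pooled overall
#' metrics use each positive's score from the model that held it out and
#' each negative's score averaged across folds.
#'
#' @param ds An `interaction_dataset`.
#' @param cfg A [pipeline_config()].
#' @param scorer Per-fold scoring function `(train_CM, ds, cfg, fold_seed)`
#'   returning a full score matrix; default is the IMC pipeline. Supply
#'   e.g. `function(train, ...) degree_baseline(train)` for baselines.
#' @return List with `auroc`, `aupr` (pooled), `per_fold` (data.frame of
#'   fold, auroc, aupr), `pooled_scores`, `pooled_labels`, `folds`.
#' @export
run_cv <- function(ds, cfg = pipeline_config(), scorer = pipeline_scorer) {
  CM <- ds$CM
  folds <- make_folds(CM, cfg$folds, cfg$seed)
  pos <- folds$positive_pairs
  neg_idx <- which(CM == 0)
  if (length(neg_idx) == 0L) stop("no negative pairs: evaluation is degenerate")

  pos_score <- rep(NA_real_, nrow(pos))
  neg_score_sum <- numeric(length(neg_idx))
  per_fold <- data.frame(fold = seq_len(folds$n_folds), auroc = NA_real_,
                         aupr = NA_real_)

  for (f in seq_len(folds$n_folds)) {
    in_fold <- folds$fold_of_pair == f
    if (!any(in_fold)) stop("fold ", f, " holds no positives")
    train <- CM
    train[pos[in_fold, , drop = FALSE]] <- 0
    scores <- scorer(train, ds, cfg, cfg$seed + f)
    p <- scores[pos[in_fold, , drop = FALSE]]
    n <- scores[neg_idx]
    pos_score[in_fold] <- p
    neg_score_sum <- neg_score_sum + n
    fold_eval <- roc_pr(c(p, n), c(rep(1L, length(p)), rep(0L, length(n))))
    per_fold$auroc[[f]] <- fold_eval$auroc
    per_fold$aupr[[f]] <- fold_eval$aupr
  }

  pooled_scores <- c(pos_score, neg_score_sum / folds$n_folds)
  pooled_labels <- c(rep(1L, nrow(pos)), rep(0L, length(neg_idx)))
  pooled <- roc_pr(pooled_scores, pooled_labels)
  list(auroc = pooled$auroc, aupr = pooled$aupr, per_fold = per_fold,
       pooled_scores = pooled_scores, pooled_labels = pooled_labels,
       folds = folds)
}

#' Top-ranked circRNAs for a query miRNA
#'
#' Ranks the query's score column in descending order, breaking ties by
#' row-index order, optionally excluding known (training) interactions.
#'
#' @param scores circRNA x miRNA score matrix with identifier dimnames.
#' @param query miRNA identifier (a column name of `scores`).
#' @param top_n Number of rows to return (default 10).
#' @param exclude_known Drop known pairs before ranking? Requires `CM`.
#' @param CM Binary matrix marking known pairs (same shape as `scores`).
#' @return data.frame with columns `rank`, `circRNA`, `score`.
#' @export
rank_query <- function(scores, query, top_n = 10L, exclude_known = FALSE,
                       CM = NULL) {
  if (!query %in% colnames(scores)) {
    near <- utils::head(agrep(query, colnames(scores), value = TRUE,
                              max.distance = 0.3), 3L)
    stop("unknown miRNA id '", query, "'",
         if (length(near) > 0) paste0("; nearest matches: ",
                                      paste(near, collapse = ", ")))
  }
  col <- scores[, query]
  keep <- rep(TRUE, length(col))
  if (exclude_known) {
    if (is.null(CM)) stop("exclude_known = TRUE requires CM")
    keep <- CM[, query] == 0
  }
  ids <- rownames(scores)[keep]
  vals <- col[keep]
  o <- order(-vals, seq_along(vals))
  n <- min(top_n, length(vals))
  data.frame(rank = seq_len(n), circRNA = ids[o][seq_len(n)],
             score = vals[o][seq_len(n)], row.names = NULL)
}
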