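#' Load a tripartite dataset from three edge-list files
#'
#' @param cm_path,cc_path,mc_path Paths to the circRNA-miRNA,
#'   circRNA-cancer and miRNA-cancer edge lists.
#' @return An `interaction_dataset`.
#' @export
load_dataset <- function(cm_path, cc_path, mc_path) {
  build_dataset(read_edge_list(cm_path, "circ-mi"),
                read_edge_list(cc_path, "circ-cancer"),
                read_edge_list(mc_path, "mi-cancer"))
}

#' Score all circRNA-miRNA pairs on the full data
#'
#' Runs similarity computation, NetMF embedding, feature fusion and the
#' IMC ensemble on the complete interaction matrix (no held-out fold) and
#' returns the prediction score matrix.
#'
#' @param ds An `interaction_dataset`.
#' @param cfg A [pipeline_config()].
#' @return circRNA x miRNA score matrix; attribute `fits` carries the
#'   per-rank factorizations.
#' @export
predict_interactions <- function(ds, cfg = pipeline_config()) {
  pipeline_scorer(ds$CM, ds, cfg, cfg$seed)
}

#' Export a score matrix in long format
#'
#' Writes `(circRNA, miRNA, score, known)` rows sorted by descending score,
#' plus (optionally) the full score matrix as a TSV.
#'
#' @param scores Score matrix with identifier dimnames.
#' @param CM Binary matrix flagging known interactions.
#' @param path Output TSV path for the long table.
#' @param matrix_path Optional path for the full matrix TSV.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, CM, path, matrix_path = NULL) {
  idx <- which(!is.na(scores), arr.ind = TRUE)
  df <- data.frame(circRNA = rownames(scores)[idx[, 1L]],
                   miRNA = colnames(scores)[idx[, 2L]],
                   score = scores[idx],
                   known = as.integer(CM[idx] != 0))
  df <- df[order(-df$score, df$circRNA, df$miRNA), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) write_id_matrix(scores, matrix_path)
  invisible(path)
}

#' Write a cross-validation report
#'
#' Emits a JSON summary (pooled and per-fold AUROC/AUPR plus the effective
#' configuration) and a TSV of the pooled ROC/PR curve points.
#'
#' @param cv Result of [run_cv()].
#' @param cfg The [pipeline_config()] used.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(cv, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(auroc = cv$auroc, aupr = cv$aupr,
                  per_fold = cv$per_fold,
                  config = unclass(cfg))
  jsonlite::write_json(summary, file.path(dir, "cv_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pooled <- roc_pr(cv$pooled_scores, cv$pooled_labels)
  utils::write.table(pooled$curve, file.path(dir, "cv_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
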