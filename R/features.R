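#' Concatenate embedding and similarity features
#'
#' Forms the per-entity feature matrix `[embedding | similarity]`: each row
#' is the entity's normalized topological embedding followed by its fused
#' similarity profile. Both blocks must be non-negative; normalize the
#' embedding with [minmax_columns()] first.
#'
#' @param net_block `n x d` non-negative embedding block for one entity class.
#' @param sim `n x n` fused similarity matrix for the same entities.
#' @return `n x (d + n)` feature matrix.
#' @export
fuse_features <- function(net_block, sim) {
  net_block <- as.matrix(net_block)
  sim <- as.matrix(sim)
  if (nrow(net_block) != nrow(sim)) stop("row counts of embedding and similarity differ")
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  if (any(net_block < 0) || any(sim < 0)) {
    stop("feature blocks must be non-negative (normalize embeddings upstream)")
  }
  out <- cbind(net_block, sim)
  rownames(out) <- rownames(sim)
  out
}

#' Feature matrices under an ablation mode
#'
#' `"fused"` concatenates embedding and similarity blocks; `"sim_only"`
#' uses the fused similarity matrix alone (the topology-free ablation).
#'
#' @param mode `"fused"` or `"sim_only"`.
#' @param sim Fused similarity matrix.
#' @param net_block Non-negative embedding block (required for `"fused"`).
#' @return Feature matrix for one entity class.
#' @export
ablation_features <- function(mode, sim, net_block = NULL) {
  switch(mode,
    sim_only = as.matrix(sim),
    fused = {
      if (is.null(net_block)) stop("fused mode requires an embedding block")
      fuse_features(net_block, sim)
    },
    stop("unknown ablation mode: ", mode)
  )
}

# Build circRNA and miRNA feature matrices from a training CM and the
# dataset's cancer associations. topology = FALSE drops the embedding block.
build_features <- function(CM, CC, MC, d = 16L, window = 10L, neg = 1,
                           topology = TRUE) {
  sims <- similarity_set(CM, CC, MC)
  if (!topology) {
    return(list(circ = sims$circ_fused, mi = sims$mi_fused, sims = sims))
  }
  A <- hetero_adjacency(CM)
  emb <- netmf_embedding(A, d = min(d, nrow(A)), window = window, neg = neg)
  blocks <- split_embedding(emb, nrow(CM))
  list(circ = fuse_features(minmax_columns(blocks$circ), sims$circ_fused),
       mi = fuse_features(minmax_columns(blocks$mi), sims$mi_fused),
       sims = sims)
}
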