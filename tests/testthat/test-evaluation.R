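test_that("fold assignment partitions positives into near-equal deterministic folds", {
  withr::local_seed(51)
  CM <- matrix(0, 40, 30)
  CM[sample(length(CM), 756)] <- 1
  fa <- make_folds(CM, 10L, seed = 3L)
  sizes <- tabulate(fa$fold_of_pair, 10L)
  expect_equal(sum(sizes), 756L)
  expect_true(all(sizes %in% c(75L, 76L)))
  expect_identical(fa$fold_of_pair, make_folds(CM, 10L, seed = 3L)$fold_of_pair)
  expect_false(identical(fa$fold_of_pair, make_folds(CM, 10L, seed = 4L)$fold_of_pair))
  expect_error(make_folds(diag(3), 10L), "folds")
})

test_that("ROC/PR handles separable, inverted and degenerate inputs", {
  expect_equal(roc_pr(c(0.9, 0.8, 0.1), c(1, 1, 0))$auroc, 1)
  expect_equal(roc_pr(c(0.9, 0.1), c(0, 1))$auroc, 0)
  expect_error(roc_pr(c(1, 2), c(1, 1)), "both classes")
  cv <- roc_pr(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0))
  expect_true(all(cv$curve$TP + cv$curve$FN == 2))
  expect_true(all(cv$curve$FP + cv$curve$TN == 2))
  expect_equal(cv$curve$recall, cv$curve$TPR)
  # tied scores are processed at a single threshold
  expect_equal(nrow(cv$curve), 3L)
})

test_that("trapezoidal AUROC equals brute-force concordance with ties at 0.5", {
  withr::local_seed(52)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_lt(abs(roc_pr(scores, labels)$auroc -
                    concordance_oracle(scores, labels)), 1e-12)
  }
})

test_that("AUPR of a random scorer converges to the positive prevalence", {
  withr::local_seed(53)
  prev <- 0.15
  auprs <- replicate(50, {
    labels <- stats::rbinom(400, 1, prev)
    if (sum(labels) == 0) labels[1] <- 1
    roc_pr(stats::runif(400), labels)$aupr
  })
  expect_lt(abs(mean(auprs) - prev), 0.03)
})

test_that("cross-validation recomputes training-side inputs per fold without leakage", {
  ds <- tiny_dataset(seed = 2L)
  seen <- list()
  spy <- function(train, ds_in, cfg, fold_seed) {
    seen[[length(seen) + 1L]] <<- train
    degree_baseline(train)
  }
  cfg <- pipeline_config(folds = 5L, seed = 11L)
  cv <- run_cv(ds, cfg, scorer = spy)
  expect_equal(length(seen), 5L)
  held_out <- vapply(seen, function(tr) sum(ds$CM) - sum(tr), 0)
  # every fold masks its own positives, and the masks partition the positives
  expect_equal(sum(held_out), sum(ds$CM))
  expect_true(all(held_out >= 1))
  for (tr in seen) expect_true(all(tr <= ds$CM))  # mask only removes edges
  expect_equal(nrow(cv$per_fold), 5L)
  expect_true(all(is.finite(c(cv$auroc, cv$aupr))))
  # pooled vectors cover each positive once and each negative once
  expect_equal(sum(cv$pooled_labels), sum(ds$CM))
  expect_equal(length(cv$pooled_labels), sum(ds$CM) + sum(ds$CM == 0))
})

test_that("cross-validation of the full pipeline beats a permuted-score null", {
  ds <- tiny_dataset(seed = 6L, n_circ = 30L, n_mi = 24L)
  cfg <- pipeline_config(embed_dim = 8L, ranks = c(8L, 4L), folds = 5L, seed = 2L)
  cv <- suppressWarnings(run_cv(ds, cfg))
  expect_equal(nrow(cv$per_fold), 5L)
  null_auroc <- withr::with_seed(1L, {
    mean(replicate(20, roc_pr(sample(cv$pooled_scores), cv$pooled_labels)$auroc))
  })
  expect_gt(cv$auroc, 0.5)
  expect_gt(cv$auroc, null_auroc + 0.1)
})

test_that("query ranking orders by score with index-order tie-breaks", {
  scores <- matrix(c(0.9, 0.5, 0.7, 0.2, 0.2, 0.2), 3, 2,
                   dimnames = list(c("c1", "c2", "c3"), c("m1", "m2")))
  out <- rank_query(scores, "m1", top_n = 2L)
  expect_equal(out$circRNA, c("c1", "c3"))
  expect_equal(out$rank, 1:2)

  # all-equal scores fall back to index order; big top_n returns everything
  out2 <- rank_query(scores, "m2", top_n = 10L)
  expect_equal(out2$circRNA, c("c1", "c2", "c3"))

  CM <- matrix(c(1, 0, 0, 0, 0, 0), 3, 2, dimnames = dimnames(scores))
  out3 <- rank_query(scores, "m1", exclude_known = TRUE, CM = CM)
  expect_false("c1" %in% out3$circRNA)
  expect_error(rank_query(scores, "m9"), "unknown miRNA")
})

test_that("rank-1 planted structure surfaces the strongest partners in the top ranks", {
  sd <- synth_generate(synth_config(n_circ = 40L, n_mi = 30L, n_cancer = 10L,
                                    latent_rank = 1L, density_cm = 0.1,
                                    density_cc = 0.15, density_mc = 0.15,
                                    noise_flip_rate = 0, seed = 4L))
  ds <- sd$dataset
  cfg <- pipeline_config(embed_dim = 8L, ranks = c(8L,  4L), seed = 1L)
  scores <- suppressWarnings(predict_interactions(ds, cfg))
  # with rank-1 structure the highest-factor circRNAs dominate every column
  strongest <- order(-rowSums(sd$scores_cm))[1:10]
  top <- rank_query(scores, colnames(scores)[1], top_n = 10L)
  hits <- sum(top$circRNA %in% rownames(ds$CM)[strongest])
  expect_gte(hits, 5L)
})
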