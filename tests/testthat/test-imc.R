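rand_instance <- function(n = 6L, m = 5L, p = 4L, q = 3L, d = 2L) {
  list(CM = rand_binary(n, m),
       X = matrix(stats::runif(n * p), n, p),
       Y = matrix(stats::runif(m * q), m, q),
       W = matrix(stats::runif(p * d), p, d),
       H = matrix(stats::runif(q * d), q, d))
}

test_that("IMC objective matches closed forms and a scalar loop oracle", {
  withr::local_seed(31)
  ins <- rand_instance()
  W0 <- matrix(0, 4, 2)
  H0 <- matrix(0, 3, 2)
  expect_equal(imc_objective(ins$CM, ins$X, ins$Y, W0, H0, 3, 7),
               0.5 * sum(ins$CM))

  # exact factorization with no regularization scores zero
  pred <- ins$X %*% ins$W %*% t(ins$H) %*% t(ins$Y)
  expect_equal(imc_objective(pred, ins$X, ins$Y, ins$W, ins$H, 0, 0), 0)

  for (rep in 1:5) {
    ins <- rand_instance()
    expect_lt(abs(imc_objective(ins$CM, ins$X, ins$Y, ins$W, ins$H, 1, 1) -
                    objective_oracle(ins$CM, ins$X, ins$Y, ins$W, ins$H, 1, 1)),
              1e-10)
  }
  expect_error(imc_objective(ins$CM, ins$X, ins$Y, ins$H, ins$W), "conformable")
})

test_that("multiplicative updates preserve non-negativity and decrease the objective", {
  withr::local_seed(32)
  for (rep in 1:50) {
    ins <- rand_instance()
    upd <- imc_update(ins$CM, ins$X, ins$Y, ins$W, ins$H)
    expect_true(all(upd$W >= 0))
    expect_true(all(upd$H >= 0))
  }
  for (rep in 1:20) {
    ins <- rand_instance()
    W <- ins$W
    H <- ins$H
    obj <- imc_objective(ins$CM, ins$X, ins$Y, W, H)
    for (it in 1:30) {
      upd <- imc_update(ins$CM, ins$X, ins$Y, W, H)
      W <- upd$W
      H <- upd$H
      obj_new <- imc_objective(ins$CM, ins$X, ins$Y, W, H)
      expect_lte(obj_new, obj + 1e-9)
      obj <- obj_new
    }
  }
})

test_that("fitting is deterministic, respects stopping rules, and clamps ranks", {
  withr::local_seed(33)
  ins <- rand_instance(8L, 6L, 5L, 4L)
  cfg <- imc_config(ranks = 2L, seed = 17L)
  f1 <- imc_fit(ins$CM, ins$X, ins$Y, 2L, cfg)
  f2 <- imc_fit(ins$CM, ins$X, ins$Y, 2L, cfg)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_true(all(diff(f1$objective_trace) <= 1e-9))

  # an effectively infinite tolerance stops after a single sweep
  f3 <- imc_fit(ins$CM, ins$X, ins$Y, 2L, imc_config(ranks = 2L, tol = 1e18))
  expect_equal(f3$iterations, 1L)

  expect_warning(f4 <- imc_fit(ins$CM, ins$X, ins$Y, 50L, cfg), "clamping")
  expect_equal(f4$rank, 4L)
})

test_that("a planted exactly-low-rank instance is recovered to < 5% error", {
  withr::local_seed(34)
  n <- 20L; m <- 16L; p <- 8L; q <- 7L; d <- 3L
  X <- matrix(stats::runif(n * p), n, p)
  Y <- matrix(stats::runif(m * q), m, q)
  Wstar <- matrix(stats::runif(p * d), p, d)
  Hstar <- matrix(stats::runif(q * d), q, d)
  CM <- X %*% Wstar %*% t(Hstar) %*% t(Y)
  cfg <- imc_config(ranks = d, theta1 = 0, theta2 = 0, max_iter = 2000L,
                    tol = 1e-12, seed = 2L)
  fit <- imc_fit(CM, X, Y, d, cfg)
  rel_err <- norm(CM - X %*% fit$W %*% t(fit$H) %*% t(Y), "F") / norm(CM, "F")
  expect_lt(rel_err, 0.05)
})

test_that("with identity features the solver matches an independent regularized NMF", {
  withr::local_seed(35)
  n <- 10L; m <- 8L; d <- 3L; iters <- 100L
  CM <- rand_binary(n, m, 0.4)
  X <- diag(n)
  Y <- diag(m)
  cfg <- imc_config(ranks = d, max_iter = iters, tol = 1e-18, seed = 9L)
  fit <- imc_fit(CM, X, Y, d, cfg, seed = 9L)
  init <- withr::with_seed(9L, list(
    W = matrix(stats::runif(n * d), n, d),
    H = matrix(stats::runif(m * d), m, d)))
  ref <- nmf_reference(CM, init$W, init$H, 1, 1, iters)
  obj_fit <- imc_objective(CM, X, Y, fit$W, fit$H)
  expect_lt(abs(obj_fit - ref$objective) / ref$objective, 0.05)
})

test_that("the ensemble degenerates to a single fit for one rank and averages otherwise", {
  withr::local_seed(36)
  ins <- rand_instance(8L, 6L, 5L, 4L)
  cfg <- imc_config(ranks = 2L, seed = 5L)
  sc1 <- imc_ensemble(ins$CM, ins$X, ins$Y, cfg)
  fit <- imc_fit(ins$CM, ins$X, ins$Y, 2L, cfg, seed = cfg$seed + 1L)
  expect_equal(unname(sc1), ins$X %*% fit$W %*% t(fit$H) %*% t(ins$Y),
               ignore_attr = TRUE)
  expect_true(all(sc1 >= 0))

  sc2 <- imc_ensemble(ins$CM, ins$X, ins$Y, imc_config(ranks = c(2L, 3L), seed = 5L))
  expect_true(all(is.finite(sc2)))
  expect_error(imc_ensemble(ins$CM, ins$X, ins$Y,
                            structure(list(ranks = integer(0)), class = "imc_config")),
               "at least one rank")
})

test_that("ensemble scores are equivariant under simultaneous circRNA permutation", {
  withr::local_seed(37)
  ins <- rand_instance(7L, 6L, 5L, 4L)
  cfg <- imc_config(ranks = c(2L, 3L), seed = 8L)
  base <- imc_ensemble(ins$CM, ins$X, ins$Y, cfg)
  perm <- sample(7)
  permuted <- imc_ensemble(ins$CM[perm, ], ins$X[perm, ], ins$Y, cfg)
  expect_equal(unname(permuted), unname(base[perm, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
})
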