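# Independent scalar/loop oracles used to cross-check the vectorized
# implementations. Deliberately naive: no shared code with R/.

rand_binary <- function(nr, nc, p = 0.3) {
  matrix(as.numeric(stats::runif(nr * nc) < p), nr, nc)
}

# GIP kernel by explicit double loop over profile pairs.
gip_oracle <- function(P) {
  n <- nrow(P)
  total <- 0
  for (i in seq_len(n)) total <- total + sum(P[i, ]^2)
  gamma <- if (total == 0) 1 else n / total
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
    }
  }
  S
}

# Cosine similarity by explicit double loop; zero-norm rows score 0.
cosine_oracle <- function(P) {
  n <- nrow(P)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(P[i, ]^2))
      nj <- sqrt(sum(P[j, ]^2))
      S[i, j] <- if (ni == 0 || nj == 0) 0 else sum(P[i, ] * P[j, ]) / (ni * nj)
    }
  }
  S
}

# Naive matrix product with explicit loops (keeps the NetMF oracle
# independent of BLAS-backed %*%).
matmul_loop <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      s <- 0
      for (k in seq_len(ncol(A))) s <- s + A[i, k] * B[k, j]
      out[i, j] <- s
    }
  }
  out
}

# NetMF target matrix M computed entirely with scalar loops.
netmf_oracle <- function(A, window = 10L, neg = 1) {
  n <- nrow(A)
  deg <- numeric(n)
  for (i in seq_len(n)) deg[i] <- sum(A[i, ])
  vol <- sum(deg)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (deg[i] > 0) for (j in seq_len(n)) P[i, j] <- A[i, j] / deg[i]
  }
  acc <- matrix(0, n, n)
  Pr <- diag(n)
  for (r in seq_len(window)) {
    Pr <- matmul_loop(Pr, P)
    acc <- acc + Pr
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dj <- if (deg[j] > 0) 1 / deg[j] else 0
      M[i, j] <- vol / (neg * window) * acc[i, j] * dj
    }
  }
  M
}

# Mann-Whitney concordance with ties credited 0.5, by brute-force pair loop.
concordance_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

# IMC objective via scalar loops (reconstruction built entry by entry).
objective_oracle <- function(CM, X, Y, W, H, theta1, theta2) {
  WH <- matmul_loop(W, t(H))            # p x q
  XWH <- matmul_loop(X, WH)             # n_circ x q
  pred <- matmul_loop(XWH, t(Y))        # n_circ x n_mi
  0.5 * sum((CM - pred)^2) + theta1 / 2 * sum(W^2) + theta2 / 2 * sum(H^2)
}

# Independent regularized NMF (Lee-Seung multiplicative updates with a
# Tikhonov term), used to cross-check the identity-feature reduction.
nmf_reference <- function(V, W, H, theta1, theta2, iters, eps = 1e-10) {
  for (it in seq_len(iters)) {
    W <- W * (V %*% H) / (W %*% crossprod(H) + theta1 * W + eps)
    H <- H * (crossprod(V, W)) / (H %*% crossprod(W) + theta2 * H + eps)
  }
  list(W = W, H = H,
       objective = 0.5 * sum((V - tcrossprod(W, H))^2) +
         theta1 / 2 * sum(W^2) + theta2 / 2 * sum(H^2))
}

# Small deterministic tripartite dataset for plumbing tests.
tiny_dataset <- function(seed = 7L, n_circ = 25L, n_mi = 20L, n_cancer = 6L) {
  synth_generate(synth_config(n_circ = n_circ, n_mi = n_mi,
                              n_cancer = n_cancer, latent_rank = 2L,
                              density_cm = 0.1, density_cc = 0.15,
                              density_mc = 0.15, noise_flip_rate = 0,
                              seed = seed))$dataset
}
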