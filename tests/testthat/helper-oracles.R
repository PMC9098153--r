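# Independent oracles and fixture builders shared across the suite. These
# deliberately take different computational routes from the package code so
# agreement is evidence, not tautology.

# data whose *sample* covariance (n-1 convention) equals S exactly:
# whiten a random matrix, then colour it with chol(S)
exact_cov_data <- function(n, S, seed = 1) {
  p <- ncol(S)
  stopifnot(n > p)
  withr::with_seed(seed, M <- matrix(rnorm(n * p), n, p))
  M <- scale(M, center = TRUE, scale = FALSE)
  W <- M %*% solve(chol(stats::cov(M)))
  W %*% chol(S)
}

# partial correlation of items i and j given all others, via the Schur
# complement of the conditional covariance (not the precision matrix)
partial_cor_oracle <- function(R, i, j) {
  rest <- setdiff(seq_len(ncol(R)), c(i, j))
  if (length(rest) == 0) return(R[i, j])
  S <- R[c(i, j), c(i, j)] -
    R[c(i, j), rest, drop = FALSE] %*%
    solve(R[rest, rest, drop = FALSE]) %*%
    R[rest, c(i, j), drop = FALSE]
  S[1, 2] / sqrt(S[1, 1] * S[2, 2])
}

kmo_oracle <- function(R) {
  p <- ncol(R)
  r2 <- a2 <- 0
  for (i in seq_len(p - 1)) {
    for (j in seq.int(i + 1, p)) {
      r2 <- r2 + R[i, j]^2
      a2 <- a2 + partial_cor_oracle(R, i, j)^2
    }
  }
  r2 / (r2 + a2)
}

# brute-force multinomial naive Bayes posterior in plain probability
# arithmetic (no logs, no matrices)
nb_posterior_oracle <- function(documents, labels, tokens, smoothing = 1) {
  vocab <- sort(unique(unlist(documents)))
  classes <- sort(unique(labels))
  V <- length(vocab)
  post <- numeric(length(classes))
  names(post) <- classes
  for (cl in classes) {
    docs <- documents[labels == cl]
    all_tok <- unlist(docs)
    prob <- length(docs) / length(documents)
    for (tok in tokens) {
      if (!(tok %in% vocab)) next  # OOV ignored, as declared
      prob <- prob * (sum(all_tok == tok) + smoothing) /
        (length(all_tok) + smoothing * V)
    }
    post[cl] <- prob
  }
  post / sum(post)
}

# full-matrix Wagner-Fischer edit distance (different code path from the
# package's two-row version)
edit_distance_oracle <- function(a, b) {
  n <- length(a)
  m <- length(b)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]),
                             D[i, j + 1] + 1L,
                             D[i + 1, j] + 1L)
    }
  }
  D[n + 1, m + 1]
}

# two-class unigram models with disjoint vocabularies (trivially separable)
disjoint_unigrams <- function() {
  list(
    negative = c(bad = 0.5, awful = 0.5, calm = 0, nice = 0),
    positive = c(bad = 0, awful = 0, calm = 0.5, nice = 0.5)
  )
}

# planted-structure response fixture shared by recovery tests
recovery_fixture <- function(seed, n = 500, contaminated = FALSE) {
  L <- simple_structure_loadings(18, 3, 0.7)
  cfg <- sim_config(
    n, 18, 3, loading_pattern = L,
    outlier_fraction = if (contaminated) 0.05 else 0,
    outlier_magnitude = if (contaminated) 4 else 0,
    seed = seed
  )
  list(X = simulate_responses(cfg), L = L)
}

# aligned RMSE against the planted loadings, padding with zero columns when
# fewer than 3 factors were retained
recovery_rmse <- function(fit, L) {
  k <- min(3, fit$retained_k)
  est <- cbind(fit$loadings[, seq_len(k), drop = FALSE],
               matrix(0, nrow(L), 3 - k))
  align_loadings(est, L)$rmse
}
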