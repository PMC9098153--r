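# Fuzzy exploratory factor analysis: classical PCA-extraction EFA made robust
# by iteratively down-weighting outlying respondents through fuzzy
# memberships, plus the sampling-adequacy tests (KMO, Bartlett) that decide
# whether a correlation matrix is worth factoring at all.

#' Fuzzy (membership-weighted) column means
#'
#' `FE = colSums(U * X) / sum(U)`: the fuzzy mean of the response matrix
#' under per-respondent membership weights. With all memberships equal it
#' reduces to the ordinary column mean.
#'
#' @param X numeric matrix (respondents x items).
#' @param U non-negative membership weights, length `nrow(X)`, not all zero.
#' @return numeric vector of length `ncol(X)`.
#' @export
fuzzy_mean <- function(X, U) {
  X <- as.matrix(X)
  U <- as.numeric(U)
  stopifnot(length(U) == nrow(X))
  if (any(U < 0) || any(!is.finite(U))) {
    stop("memberships must be finite and non-negative", call. = FALSE)
  }
  su <- sum(U)
  if (su <= 0) stop("degenerate memberships: all weights are zero",
                    call. = FALSE)
  as.numeric(crossprod(U, X)) / su
}

#' Update fuzzy memberships from distances to the current centre
#'
#' Respondent `k` receives membership `U_k = 1 / (1 + (d_k / s)^2)` where
#' `d_k` is the Euclidean distance of the standardised response row from the
#' current fuzzy mean and `s = scale * median(d)`. The Cauchy-type weight is
#' smooth, bounded in `(0, 1]`, equals 1 at the centre, 0.5 at the median
#' distance (for `scale = 1`), and decays quadratically, so outlying rows are
#' down-weighted without hard rejection. Columns are standardised by their
#' sample SDs so items on different effective scales contribute comparably.
#'
#' If every row coincides with the centre all memberships are 1. If the
#' median distance is zero while some rows differ, the mean distance is used
#' as the scale instead.
#'
#' @param X numeric matrix (respondents x items).
#' @param current_mean centre vector, length `ncol(X)`.
#' @param scale positive multiplier on the median distance.
#' @return membership vector in `(0, 1]`, length `nrow(X)`.
#' @export
update_membership <- function(X, current_mean, scale = 1) {
  X <- as.matrix(X)
  stopifnot(length(current_mean) == ncol(X), scale > 0)
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0] <- 1
  Z <- sweep(sweep(X, 2L, current_mean), 2L, sds, `/`)
  d <- sqrt(rowSums(Z^2))
  if (all(d == 0)) return(rep(1, nrow(X)))
  s <- scale * stats::median(d)
  if (s <= 0) s <- scale * mean(d)
  1 / (1 + (d / s)^2)
}

#' Fuzzy (membership-weighted) covariance matrix
#'
#' `FCov = sum(U_k (x_k - m)(x_k - m)^T) / sum(U_k)`; weights are normalised
#' by their sum, matching the fuzzy-mean convention, so with all memberships
#' equal this is the population-normalised covariance.
#'
#' @param X numeric matrix.
#' @param U membership weights.
#' @param centre centre vector; defaults to `fuzzy_mean(X, U)`.
#' @return symmetric positive semidefinite `p x p` matrix.
#' @export
fuzzy_covariance <- function(X, U, centre = fuzzy_mean(X, U)) {
  X <- as.matrix(X)
  U <- as.numeric(U)
  stopifnot(length(U) == nrow(X), length(centre) == ncol(X))
  su <- sum(U)
  if (su <= 0 || any(U < 0)) {
    stop("degenerate memberships: weights must be non-negative, not all zero",
         call. = FALSE)
  }
  Xc <- sweep(X, 2L, centre)
  V <- crossprod(Xc * U, Xc) / su
  (V + t(V)) / 2
}

#' Fit a fuzzy exploratory factor model
#'
#' Alternates the fuzzy mean and the membership update until the mean
#' stabilises (`max |delta FE| < tol`) or `max_iter` iterations elapse, then
#' eigendecomposes the fuzzy correlation matrix (the fuzzy covariance
#' rescaled by the fuzzy SDs). Factors are retained by the Kaiser criterion
#' (eigenvalues strictly greater than 1) and loadings are
#' `L[, j] = sqrt(lambda_j) * e_j`, the principal-component extraction.
#' Analysing the correlation rather than covariance matrix keeps the Kaiser
#' rule meaningful for items on a common Likert metric.
#'
#' With `fuzzy = FALSE` (or `max_iter = 0`) memberships stay pinned at 1 and
#' the fit reduces to a classical PCA-extraction EFA of the sample
#' correlation matrix.
#'
#' @param X response matrix (respondents x items).
#' @param max_iter maximum alternating iterations.
#' @param tol convergence tolerance on the fuzzy mean.
#' @param scale membership scale multiplier, see [update_membership()].
#' @param fuzzy logical; `FALSE` fixes all memberships at 1.
#' @param rotation `"none"` (default) or `"varimax"` applied to the retained
#'   loadings.
#' @return object of class `"fuzzy_fa"`: fuzzy mean, fuzzy covariance and
#'   correlation, eigenvalues (descending) and eigenvectors, retained
#'   loadings, `retained_k`, per-factor and cumulative variance
#'   contributions, final memberships, iteration count and convergence flag.
#' @examples
#' X <- simulate_responses(sim_config(300, 9, 3, seed = 7))
#' fit <- fit_fuzzy_fa(X)
#' fit$retained_k
#' @export
fit_fuzzy_fa <- function(X, max_iter = 50L, tol = 1e-4, scale = 1,
                         fuzzy = TRUE, rotation = c("none", "varimax")) {
  rotation <- match.arg(rotation)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) warning("fewer respondents than items + 1; ",
                      "factor solution may be unstable")
  if (any(apply(X, 2L, stats::sd) == 0)) {
    stop("constant item(s) present; prune before factoring", call. = FALSE)
  }

  U <- rep(1, n)
  FE <- fuzzy_mean(X, U)
  iters <- 0L
  converged <- TRUE
  if (fuzzy && max_iter > 0) {
    converged <- FALSE
    for (iters in seq_len(max_iter)) {
      U <- update_membership(X, FE, scale = scale)
      FE_new <- fuzzy_mean(X, U)
      delta <- max(abs(FE_new - FE))
      FE <- FE_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) warning("fuzzy iteration did not converge in ",
                            max_iter, " iterations")
  }

  FCov <- fuzzy_covariance(X, U, FE)
  sds <- sqrt(diag(FCov))
  if (any(sds == 0)) stop("zero fuzzy variance for an item", call. = FALSE)
  R <- FCov / tcrossprod(sds)
  diag(R) <- 1

  eig <- eigen(R, symmetric = TRUE)
  lambda <- eig$values
  vectors <- eig$vectors
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(p)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }

  # Kaiser rule, strict ">": ties at exactly 1 are excluded; the epsilon
  # guards against eigensolver round-off promoting an exact 1
  retained_k <- sum(lambda > 1 + 1e-8)
  loadings <- vectors[, seq_len(retained_k), drop = FALSE] %*%
    diag(sqrt(pmax(lambda[seq_len(retained_k)], 0)), retained_k)
  if (rotation == "varimax" && retained_k >= 2) {
    loadings <- stats::varimax(loadings)$loadings[, , drop = TRUE]
    loadings <- matrix(loadings, p, retained_k)
  }
  rownames(loadings) <- colnames(X)

  contribution <- lambda / p
  structure(
    list(fuzzy_mean = FE, fuzzy_cov = FCov, fuzzy_cor = R,
         eigenvalues = lambda, eigenvectors = vectors,
         loadings = loadings, retained_k = retained_k,
         variance_contribution = contribution,
         cumulative_contribution = cumsum(contribution),
         memberships = U, iterations_run = iters, converged = converged,
         rotation = rotation),
    class = "fuzzy_fa"
  )
}

#' @export
print.fuzzy_fa <- function(x, ...) {
  cat("Fuzzy exploratory factor model\n")
  cat(sprintf("  items: %d, retained factors (Kaiser > 1): %d\n",
              length(x$fuzzy_mean), x$retained_k))
  cat(sprintf("  iterations: %d (converged: %s)\n",
              x$iterations_run, x$converged))
  k <- max(1L, x$retained_k)
  cat(sprintf("  cumulative variance contribution at k: %.1f%%\n",
              100 * x$cumulative_contribution[k]))
  invisible(x)
}

#' Least-squares factor scores
#'
#' Scores each respondent by the normal-equations solve
#' `F = (L^T L)^{-1} L^T (x - FE)`. A rank-deficient `L^T L` falls back to
#' the Moore-Penrose pseudo-inverse with a warning.
#'
#' @param model a fitted [fit_fuzzy_fa()] object with `retained_k >= 1`.
#' @param X response matrix on the same items.
#' @return numeric matrix (`nrow(X)` x `retained_k`).
#' @export
factor_scores <- function(model, X) {
  stopifnot(inherits(model, "fuzzy_fa"))
  if (model$retained_k < 1) stop("no retained factors to score",
                                 call. = FALSE)
  X <- as.matrix(X)
  L <- model$loadings
  stopifnot(ncol(X) == nrow(L))
  Xc <- sweep(X, 2L, model$fuzzy_mean)
  G <- crossprod(L)
  Ginv <- tryCatch(solve(G), error = function(e) {
    warning("rank-deficient loading matrix; using pseudo-inverse")
    MASS::ginv(G)
  })
  Xc %*% L %*% t(Ginv)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares raw correlations with anti-image partial correlations:
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum a_ij^2)` over off-diagonal pairs,
#' where `a_ij = -q_ij / sqrt(q_ii q_jj)` are the partial correlations
#' obtained from the precision matrix `Q = R^{-1}`. Values near 1 indicate
#' the correlation structure is dominated by shared variance and is suitable
#' for factoring; values near 0.5 or below indicate it is not.
#'
#' @param R correlation matrix (invertible).
#' @return scalar in `[0, 1]`.
#' @export
kmo_statistic <- function(R) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R))
  Q <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; prune collinear items first",
         call. = FALSE)
  })
  A <- -Q / sqrt(tcrossprod(diag(Q)))
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(A[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity (no shared variance):
#' `chi2 = -(n - 1 - (2p + 5) / 6) * log(det(R))` on `p(p - 1)/2` degrees of
#' freedom, with an upper-tail p-value.
#'
#' @param R correlation matrix.
#' @param n sample size used to estimate `R` (must exceed `ncol(R)`).
#' @return list with `chi2`, `df` and `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(nrow(R) == p, n > p)
  detR <- det(R)
  if (detR <= 0) stop("non-positive determinant: R is not a valid ",
                      "positive-definite correlation matrix", call. = FALSE)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Align an estimated loading matrix with a reference
#'
#' Factor solutions are identified only up to column permutation and sign.
#' Greedily matches each reference column with the estimated column of
#' maximal absolute inner product, flips signs to agree, and returns the
#' aligned estimate, so recovery error can be measured as a plain RMSE.
#'
#' @param estimate,reference loading matrices with equal dimensions.
#' @return list with `aligned` (permuted/sign-flipped estimate) and `rmse`.
#' @export
align_loadings <- function(estimate, reference) {
  estimate <- as.matrix(estimate)
  reference <- as.matrix(reference)
  stopifnot(all(dim(estimate) == dim(reference)))
  k <- ncol(reference)
  aligned <- matrix(0, nrow(reference), k)
  remaining <- seq_len(k)
  for (j in seq_len(k)) {
    ip <- as.numeric(crossprod(estimate[, remaining, drop = FALSE],
                               reference[, j]))
    pick <- which.max(abs(ip))
    aligned[, j] <- estimate[, remaining[pick]] * sign(ip[pick] + (ip[pick] == 0))
    remaining <- remaining[-pick]
  }
  list(aligned = aligned,
       rmse = sqrt(mean((aligned - reference)^2)))
}
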