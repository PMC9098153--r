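# Validation suite: closed-form reliability/validity values on constructed
# covariance fixtures, discrimination verdicts on planted items, normality
# flags, readability arithmetic, and the vote-weighting table rules.

test_that("Cronbach's alpha reproduces closed forms", {
  # identical items are perfectly consistent
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)

  # two items with variance 1, covariance 0.5: alpha = 2 * (1 - 2/3) = 2/3
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  X <- exact_cov_data(60, S, seed = 3)
  expect_equal(cronbach_alpha(X), 2 / 3, tolerance = 1e-12)

  # independent items: alpha near zero at n = 2000
  X0 <- matrix(rnorm(2000 * 6), 2000, 6)
  expect_lt(abs(cronbach_alpha(X0)), 0.05)

  expect_error(cronbach_alpha(matrix(1, 5, 1)), "2 items")
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "variance")
})

test_that("alpha on parallel items follows the Spearman-Brown form", {
  for (r in c(0.3, 0.6)) {
    for (K in c(4, 7)) {
      S <- matrix(r, K, K)
      diag(S) <- 1
      X <- exact_cov_data(80, S, seed = K)
      expect_equal(cronbach_alpha(X), K * r / (1 + (K - 1) * r),
                   tolerance = 1e-8)
    }
  }
})

test_that("retest reliability and criterion validity share the Pearson kernel", {
  X1 <- simulate_responses(sim_config(200, 6, 2, seed = 41))
  X2 <- simulate_responses(sim_config(200, 6, 2, seed = 42))
  expect_equal(retest_reliability(X1, X2),
               criterion_validity(rowSums(X1), rowSums(X2)),
               tolerance = 1e-12)
  expect_equal(retest_reliability(X1, X1), 1)

  # sign symmetry via negated totals
  expect_equal(criterion_validity(X1, -rowSums(X1)), -1)
  expect_equal(criterion_validity(X1, 2 * rowSums(X1) + 3), 1)

  # 3-point toy against the hand value
  expect_equal(criterion_validity(c(1, 2, 3), c(1, 2, 4)),
               3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(criterion_validity(c(1, 2, 3), c(1, 2, 4)), 0.981980506,
               tolerance = 1e-9)

  expect_error(retest_reliability(matrix(3, 5, 2), matrix(3, 5, 2)),
               "constant")
})

test_that("item discrimination keeps planted signal and deletes noise", {
  withr::with_seed(51, {
    n <- 300
    latent <- rnorm(n)
    signal <- sapply(1:8, function(j) {
      findInterval(latent + rnorm(n, sd = 0.6), c(-1.5, -0.5, 0.5, 1.5)) + 1L
    })
    noise <- sapply(1:2, function(j) sample(1:5, n, replace = TRUE))
  })
  X <- cbind(signal, noise)
  colnames(X) <- paste0("item_", 1:10)
  verdicts <- item_discrimination(X)
  expect_true(all(verdicts$verdict[1:8] == "keep"))
  expect_true(all(verdicts$p_value[1:8] < 1e-6))

  # a constant item cannot discriminate
  Xc <- cbind(X, item_11 = 3L)
  vc <- item_discrimination(Xc)
  expect_identical(vc$verdict[11], "delete")
  expect_equal(vc$cr[11], 0)

  # verdicts invariant to respondent order
  perm <- withr::with_seed(52, sample(nrow(X)))
  expect_identical(item_discrimination(X[perm, ])$verdict, verdicts$verdict)
})

test_that("pure-noise items among discriminating ones are deleted reliably", {
  hits <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      n <- 200
      latent <- rnorm(n)
      signal <- sapply(1:8, function(j) {
        findInterval(latent + rnorm(n, sd = 0.6),
                     c(-1.5, -0.5, 0.5, 1.5)) + 1L
      })
      noise <- sapply(1:2, function(j) sample(1:5, n, replace = TRUE))
    })
    v <- item_discrimination(cbind(signal, noise))
    identical(which(v$verdict == "delete"), c(9L, 10L))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("normality screening flags floor effects and constants only", {
  # symmetric uniform 5-point distribution: not flagged
  sym <- rep(1:5, each = 40)
  # 99% floor: heavily skewed, flagged
  floor_item <- c(rep(1L, 198), rep(5L, 2))
  const <- rep(3L, 200)
  X <- cbind(sym = sym, floor = floor_item, const = const)
  out <- normality_screen(X)
  expect_identical(out$flagged, c(FALSE, TRUE, TRUE))

  # oracle check of the flagged skewness by direct moment arithmetic
  m <- mean(floor_item)
  sk_oracle <- mean((floor_item - m)^3) / mean((floor_item - m)^2)^1.5
  expect_equal(out$skewness[2], sk_oracle, tolerance = 1e-12)
})

test_that("reading-ease formula matches scalar arithmetic and is monotone", {
  expect_equal(flesch_reading_ease(3, 1, 3), 206.835 - 3.045 - 84.6,
               tolerance = 1e-9)
  expect_equal(flesch_reading_ease(100, 5, 150),
               206.835 - 1.015 * 20 - 84.6 * 1.5, tolerance = 1e-9)
  expect_equal(flesch_reading_ease(100, 5, 150), 59.635, tolerance = 1e-9)
  # longer sentences read harder at fixed syllable rate
  expect_gt(flesch_reading_ease(100, 10, 120),
            flesch_reading_ease(100, 4, 120))
  expect_error(flesch_reading_ease(0, 1, 1), "positive")

  # vowel-group heuristic with the declared silent-e rule
  expect_identical(count_syllables(c("sea", "tired", "isolation", "wave")),
                   c(1L, 2L, 4L, 1L))
})

test_that("dimension vote weighting ranks, weights and excludes correctly", {
  votes <- data.frame(
    dimension = c("anxiety", "depression", "pirate_threat", "thin_spread"),
    g1 = c(10, 5, 20, 50), g2 = c(10, 10, 20, 50), g3 = c(10, 20, 20, 50),
    g4 = c(10, 40, 20, 50), g5 = c(160, 125, 20, 50)
  )
  # totals: 200, 200, 100, 250; max grade mass: 160, 125, 20, 50
  out <- dimension_vote_weighting(votes)
  expect_identical(out$dimension, c("anxiety", "depression"))
  expect_equal(out$weight[out$dimension == "anxiety"],
               (10 + 20 + 30 + 40 + 800) / 1000)
  expect_identical(attr(out, "excluded"), c("pirate_threat", "thin_spread"))

  # all votes at the top grade: weight 1, rank 1
  top <- data.frame(dimension = "x", g1 = 0, g2 = 0, g3 = 0, g4 = 0,
                    g5 = 150)
  out_top <- dimension_vote_weighting(top)
  expect_equal(out_top$weight, 1)
  expect_identical(out_top$rank, 1L)

  # ties broken by name
  tie <- data.frame(dimension = c("b_dim", "a_dim"),
                    g1 = 0, g2 = 0, g3 = 0, g4 = 0, g5 = c(150, 150))
  expect_identical(dimension_vote_weighting(tie)$dimension,
                   c("a_dim", "b_dim"))

  expect_error(dimension_vote_weighting(votes[0, ]), "non-empty")
})

test_that("scale_report assembles the suite coherently", {
  X <- simulate_responses(sim_config(400, 10, 2, seed = 61))
  retest <- simulate_retest(X, 0.85, seed = 62)
  crit <- simulate_criterion(X, 0.6, seed = 63)
  rep <- scale_report(X, retest = retest, criterion = crit,
                      readability = flesch_reading_ease(100, 10, 140))
  expect_s3_class(rep, "scale_report")
  expect_equal(rep$alpha, cronbach_alpha(X))
  expect_equal(rep$retest_r, retest_reliability(X, retest))
  expect_equal(unname(rep$criterion_r), criterion_validity(X, crit))
  expect_lte(rep$alpha, 1)
  expect_output(print(rep), "Cronbach")
})
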