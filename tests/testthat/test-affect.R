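# Text and speech channels: tokenisation rules, naive Bayes against
# brute-force enumeration, SAMME boosting arithmetic and behaviour on
# separable data, valence scoring, the Gaussian emotion scorer, and WER
# against a full-matrix edit-distance oracle.

test_that("tokenisation lowercases, strips punctuation and splits hyphens", {
  expect_identical(preprocess_text("I feel FINE."), c("i", "feel", "fine"))
  expect_identical(preprocess_text(""), character(0))
  expect_identical(preprocess_text(NA_character_), character(0))
  expect_identical(preprocess_text("so-so, so so"),
                   c("so", "so", "so", "so"))
  expect_identical(preprocess_text("don't worry!"), c("don't", "worry"))
})

test_that("naive Bayes posteriors equal exhaustive enumeration", {
  docs <- list(c("a", "a", "b"), c("b", "b"), c("a", "c"), c("c", "c", "b"))
  labs <- c("negative", "negative", "positive", "positive")
  corp <- labeled_corpus(docs, labs)
  model <- train_naive_bayes(corp)

  # likelihoods normalise over the vocabulary
  expect_equal(rowSums(exp(model$log_likelihoods)), c(1, 1),
               ignore_attr = TRUE)
  expect_equal(sum(exp(model$log_priors)), 1)

  test_docs <- list(character(0), "a", c("a", "b"), c("c", "c", "a", "b"),
                    c("zzz"), c("a", "zzz"))
  for (td in test_docs) {
    expect_equal(nb_posterior(model, td),
                 nb_posterior_oracle(docs, labs, td),
                 tolerance = 1e-12)
  }
  # no evidence or only OOV evidence returns the priors
  expect_equal(unname(nb_posterior(model, character(0))), c(0.5, 0.5))
  expect_equal(nb_posterior(model, "zzz"), nb_posterior(model, character(0)))
})

test_that("single-class and symmetric corpora give degenerate posteriors", {
  one <- train_naive_bayes(labeled_corpus(list(c("x", "y")), "objective"))
  expect_equal(unname(nb_posterior(one, "x")), 1)

  sym <- train_naive_bayes(labeled_corpus(
    list(c("a", "a"), c("b", "b")), c("negative", "positive")
  ))
  expect_equal(unname(nb_posterior(sym, c("a", "b"))), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("SAMME weight arithmetic and halting rules hold", {
  # alpha for K = 3, eps = 0.3
  expect_equal(log(0.7 / 0.3) + log(2), 1.540445041, tolerance = 1e-9)

  # a separable corpus reaches training accuracy 1 within 10 rounds and
  # every stored round has positive vote weight and sub-chance error
  corp <- simulate_corpus(default_class_unigrams(), 40, 25, seed = 71)
  ens <- train_adaboost(corp, n_rounds = 10, seed = 72)
  expect_lte(ens$n_rounds, 10)
  acc <- mean(ensemble_classify(ens, corp$documents) == corp$labels)
  expect_equal(acc, 1)
  eps <- vapply(ens$rounds, `[[`, numeric(1), "epsilon")
  alpha <- vapply(ens$rounds, `[[`, numeric(1), "alpha")
  expect_true(all(alpha > 0))
  expect_true(all(eps < 2 / 3))

  # determinism
  ens2 <- train_adaboost(corp, n_rounds = 10, seed = 72)
  expect_equal(vapply(ens2$rounds, `[[`, numeric(1), "alpha"), alpha)

  expect_error(train_adaboost(labeled_corpus(list("a", "b"), c("x", "x"))),
               "2 classes")
})

test_that("binary boosting drives weighted error below the product bound", {
  u <- list(negative = c(bad = 0.6, sad = 0.2, ok = 0.1, fine = 0.1),
            positive = c(bad = 0.1, sad = 0.1, ok = 0.2, fine = 0.6))
  corp <- simulate_corpus(u, 60, 8, seed = 73)
  ens <- train_adaboost(corp, n_rounds = 15, seed = 74)
  eps <- vapply(ens$rounds, `[[`, numeric(1), "epsilon")
  train_err <- mean(ensemble_classify(ens, corp$documents) != corp$labels)
  expect_lte(train_err, prod(2 * sqrt(eps * (1 - eps))) + 1e-12)
})

test_that("ensemble accuracy is non-decreasing in rounds on separable data", {
  u <- disjoint_unigrams()
  corp <- simulate_corpus(u, 30, 6, seed = 75)
  accs <- vapply(c(1, 3, 6), function(T) {
    ens <- train_adaboost(corp, n_rounds = T, seed = 76)
    mean(ensemble_classify(ens, corp$documents) == corp$labels)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[3], 1)
  # disjoint vocabularies generalise perfectly to fresh draws
  fresh <- simulate_corpus(u, 30, 6, seed = 77)
  ens <- train_adaboost(corp, n_rounds = 6, seed = 76)
  expect_equal(mean(ensemble_classify(ens, fresh$documents) == fresh$labels),
               1)
})

test_that("sse_score is the valence expectation of the vote distribution", {
  # hand-built ensemble: three single-class learners with vote mass
  # 0.6 / 0.2 / 0.2 on negative / objective / positive
  single <- function(cl, tok) {
    train_naive_bayes(labeled_corpus(list(tok), cl))
  }
  ens <- structure(
    list(rounds = list(
      list(model = single("negative", "w"), alpha = 0.6, epsilon = 0.1),
      list(model = single("objective", "w"), alpha = 0.2, epsilon = 0.1),
      list(model = single("positive", "w"), alpha = 0.2, epsilon = 0.1)
    ), classes = c("negative", "objective", "positive"), n_rounds = 3L),
    class = "sentiment_ensemble"
  )
  expect_equal(sse_score(ens, "w"), 0.6 * 0 + 0.2 * 0.5 + 0.2 * 1)

  # splitting one learner's weight across duplicates changes nothing
  ens_split <- ens
  ens_split$rounds <- c(ens$rounds, ens$rounds[1])
  ens_split$rounds[[1]]$alpha <- 0.3
  ens_split$rounds[[4]]$alpha <- 0.3
  expect_equal(sse_score(ens_split, "w"), sse_score(ens, "w"))

  # unanimity and symmetry extremes
  ens_pos <- ens
  for (i in 1:3) ens_pos$rounds[[i]]$model <- single("positive", "w")
  expect_equal(sse_score(ens_pos, "w"), 1)
  ens_unif <- ens
  ens_unif$rounds[[1]]$alpha <- 0.2
  expect_equal(sse_score(ens_unif, "w"), 0.5)
})

test_that("emotion scorer posteriors and valence behave as declared", {
  sc <- emotion_scorer(separation = 6)
  # features at a well-separated class mean identify that class
  s <- see_score(sc$means["sad", , drop = FALSE], sc)
  expect_gt(s$posterior[1, "sad"], 0.99)
  expect_lt(s$score, 0.05)

  # indistinguishable classes: uniform posterior, mean valence
  flat <- emotion_scorer(separation = 0)
  s0 <- see_score(rnorm(6), flat)
  expect_equal(as.numeric(s0$posterior), rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(s0$score, mean(flat$valence))

  # the scorer is the Bayes rule for the generating model: on cohort
  # prosody its accuracy matches a plain-loop Bayes-classifier oracle
  # exactly, and grows with the class separation
  bayes_oracle <- function(x, means) {
    d <- apply(means, 1, function(m) sum((x - m)^2))
    rownames(means)[which.min(d)]  # equal SDs: nearest mean
  }
  acc_at <- function(effect, seed) {
    co <- simulate_cohort(cohort_config(400, prosody_effect = effect),
                          seed = seed)
    post <- see_score(co$prosody, co$scorer)$posterior
    pred <- co$scorer$classes[max.col(post)]
    oracle <- apply(co$prosody, 1, bayes_oracle, means = co$scorer$means)
    expect_identical(pred, unname(oracle))
    mean(pred == co$emotions)
  }
  a2 <- acc_at(2, seed = 78)
  a4 <- acc_at(4, seed = 78)
  expect_gt(a2, 0.7)
  expect_gt(a4, 0.95)
  expect_gt(a4, a2)

  expect_error(see_score(rnorm(4), sc), "dimension")
})

test_that("word error rate equals the edit-distance oracle", {
  expect_equal(word_error_rate(c("a", "b", "c"), c("a", "b", "c")), 0)
  expect_equal(word_error_rate(c("a", "b", "c"), c("a", "x", "c")), 1 / 3)
  expect_equal(word_error_rate(c("a", "b", "c"), character(0)), 1)
  expect_error(word_error_rate(character(0), "a"), "empty reference")

  withr::with_seed(79, {
    for (i in 1:25) {
      ref <- sample(letters[1:4], sample(1:8, 1), replace = TRUE)
      hyp <- sample(letters[1:4], sample(0:8, 1), replace = TRUE)
      expect_equal(word_error_rate(ref, hyp),
                   edit_distance_oracle(ref, hyp) / length(ref))
    }
  })
})
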