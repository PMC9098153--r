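# Subjective-channel scoring. Text: multinomial naive Bayes over unigrams,
# strengthened by SAMME AdaBoost, mapped to a scalar sentiment score
# (semantic summary extraction, SSE). Speech: a pluggable Gaussian scorer
# over prosody features for six emotion classes (speech emotion extraction,
# SEE). Plus the word-error-rate metric for the transcription front end.

CANONICAL_SENTIMENTS <- c("negative", "objective", "positive")

#' Tokenise raw text
#'
#' Lowercases, replaces every character that is not a letter, digit or
#' apostrophe with a space (so hyphens and punctuation split tokens), and
#' splits on whitespace. Empty input yields an empty token vector.
#'
#' @param raw character scalar.
#' @return character vector of tokens.
#' @examples
#' preprocess_text("I feel FINE.")
#' @export
preprocess_text <- function(raw) {
  stopifnot(length(raw) <= 1)
  if (length(raw) == 0 || is.na(raw) || !nzchar(raw)) return(character(0))
  cleaned <- gsub("[^a-z0-9']+", " ", tolower(raw))
  tokens <- strsplit(trimws(cleaned), "\\s+")[[1L]]
  tokens[nzchar(tokens)]
}

#' Train a multinomial naive Bayes sentiment classifier
#'
#' Token log-likelihoods use additive (Laplace) smoothing over the corpus
#' vocabulary: `P(w | c) = (count(w, c) + s) / (tokens(c) + s * V)`. Class
#' priors are document proportions. Classes are ordered canonically
#' (negative, objective, positive first, then any others alphabetically) so
#' results are label-order invariant.
#'
#' @param corpus a [labeled_corpus()].
#' @param smoothing additive smoothing constant `s > 0`.
#' @return object of class `"nb_model"` with `classes`, `log_priors`,
#'   `log_likelihoods` (class x vocabulary) and `vocabulary`.
#' @export
train_naive_bayes <- function(corpus, smoothing = 1) {
  stopifnot(inherits(corpus, "labeled_corpus"), smoothing > 0)
  vocab <- corpus$vocabulary
  if (length(vocab) == 0) stop("empty vocabulary", call. = FALSE)
  present <- unique(corpus$labels)
  classes <- c(intersect(CANONICAL_SENTIMENTS, present),
               sort(setdiff(present, CANONICAL_SENTIMENTS)))
  K <- length(classes)
  counts <- matrix(0, K, length(vocab),
                   dimnames = list(classes, vocab))
  for (i in seq_along(corpus$documents)) {
    tab <- table(factor(corpus$documents[[i]], levels = vocab))
    counts[corpus$labels[i], ] <- counts[corpus$labels[i], ] + as.numeric(tab)
  }
  log_lik <- log(counts + smoothing) -
    log(rowSums(counts) + smoothing * length(vocab))
  priors <- as.numeric(table(factor(corpus$labels, levels = classes))) /
    length(corpus$labels)
  structure(
    list(classes = classes, log_priors = stats::setNames(log(priors), classes),
         log_likelihoods = log_lik, vocabulary = vocab,
         smoothing = smoothing),
    class = "nb_model"
  )
}

# class log-posterior numerators for a list of token vectors (n x K)
nb_log_scores <- function(model, documents) {
  n <- length(documents)
  K <- length(model$classes)
  S <- matrix(rep(model$log_priors, each = n), n, K,
              dimnames = list(NULL, model$classes))
  doc_id <- rep.int(seq_len(n), lengths(documents))
  idx <- match(unlist(documents, use.names = FALSE), model$vocabulary)
  ok <- !is.na(idx)  # out-of-vocabulary tokens carry no evidence
  if (any(ok)) {
    for (k in seq_len(K)) {
      contrib <- rowsum(model$log_likelihoods[k, idx[ok]], doc_id[ok])
      rows <- as.integer(rownames(contrib))
      S[rows, k] <- S[rows, k] + contrib[, 1L]
    }
  }
  S
}

#' Posterior class probabilities under a naive Bayes model
#'
#' Computed in the log domain and normalised. Out-of-vocabulary tokens are
#' ignored (they contribute equal smoothing mass to every class), so a
#' document of only unseen tokens — or an empty document — returns the class
#' priors.
#'
#' @param model an `"nb_model"`.
#' @param tokens character vector of tokens.
#' @return named probability vector over the model's classes.
#' @export
nb_posterior <- function(model, tokens) {
  stopifnot(inherits(model, "nb_model"))
  s <- nb_log_scores(model, list(as.character(tokens)))[1L, ]
  e <- exp(s - max(s))
  e / sum(e)
}

nb_classify_many <- function(model, documents) {
  S <- nb_log_scores(model, documents)
  model$classes[max.col(S, ties.method = "first")]
}

#' Boost naive Bayes sentiment learners with SAMME AdaBoost
#'
#' Multi-class AdaBoost (SAMME). Each round trains a naive Bayes weak
#' learner on a weight-proportional bootstrap resample of the corpus, scores
#' it by the weighted training error `eps_t`, assigns the vote weight
#' `alpha_t = log((1 - eps_t) / eps_t) + log(K - 1)`, multiplies the weights
#' of misclassified documents by `exp(alpha_t)` and renormalises. Boosting
#' halts when a weak learner is no better than class-proportion guessing
#' (`eps_t >= (K - 1) / K`, which gives `alpha_t <= 0`) or perfect
#' (`eps_t = 0`, clamped to `1e-10` so `alpha_t` stays finite). With two
#' classes this reduces to the classical binary AdaBoost.
#'
#' @param corpus a [labeled_corpus()] with at least 2 classes.
#' @param n_rounds maximum boosting rounds `T`.
#' @param smoothing naive Bayes smoothing constant.
#' @param seed integer seed controlling the resamples.
#' @return object of class `"sentiment_ensemble"`: list of rounds (each with
#'   `model`, `alpha`, `epsilon`), the class set, and the training corpus
#'   vocabulary.
#' @export
train_adaboost <- function(corpus, n_rounds = 50L, smoothing = 1, seed = 1L) {
  stopifnot(inherits(corpus, "labeled_corpus"), n_rounds >= 1)
  classes <- unique(corpus$labels)
  if (length(classes) < 2) {
    stop("boosting requires at least 2 classes", call. = FALSE)
  }
  K <- length(classes)
  n <- length(corpus$documents)
  w <- rep(1 / n, n)
  rounds <- list()
  withr::with_seed(seed, {
    for (t in seq_len(n_rounds)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      weak <- train_naive_bayes(
        labeled_corpus(corpus$documents[idx], corpus$labels[idx]),
        smoothing = smoothing
      )
      pred <- nb_classify_many(weak, corpus$documents)
      miss <- pred != corpus$labels
      eps <- sum(w[miss])
      if (eps >= (K - 1) / K) break  # no better than chance: alpha <= 0
      eps_c <- max(eps, 1e-10)
      alpha <- log((1 - eps_c) / eps_c) + log(K - 1)
      rounds[[length(rounds) + 1L]] <-
        list(model = weak, alpha = alpha, epsilon = eps)
      if (eps == 0) break
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
  })
  if (length(rounds) == 0) {
    # degenerate corpus: fall back to a single unboosted learner on the
    # full data so the ensemble still predicts
    weak <- train_naive_bayes(corpus, smoothing = smoothing)
    rounds <- list(list(model = weak, alpha = 1, epsilon = NA_real_))
  }
  structure(
    list(rounds = rounds, classes = rounds[[1L]]$model$classes,
         n_rounds = length(rounds)),
    class = "sentiment_ensemble"
  )
}

#' Weighted-vote class distribution of a boosted ensemble
#'
#' Each weak learner casts its `alpha`-weighted vote for its predicted
#' class; the result is normalised to a distribution over classes.
#'
#' @param ensemble a `"sentiment_ensemble"`.
#' @param documents list of token vectors (or a single token vector).
#' @return matrix (`n` x `K`) of vote shares, columns named by class.
#' @export
ensemble_votes <- function(ensemble, documents) {
  stopifnot(inherits(ensemble, "sentiment_ensemble"))
  if (!is.list(documents)) documents <- list(documents)
  n <- length(documents)
  classes <- ensemble$classes
  V <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (r in ensemble$rounds) {
    pred <- nb_classify_many(r$model, documents)
    V[cbind(seq_len(n), match(pred, classes))] <-
      V[cbind(seq_len(n), match(pred, classes))] + r$alpha
  }
  V / rowSums(V)
}

#' Classify documents with a boosted ensemble
#'
#' @inheritParams ensemble_votes
#' @return character vector of predicted class labels (arg-max of the vote
#'   distribution, first class on ties).
#' @export
ensemble_classify <- function(ensemble, documents) {
  V <- ensemble_votes(ensemble, documents)
  ensemble$classes[max.col(V, ties.method = "first")]
}

#' Scalar sentiment score from the ensemble vote (SSE)
#'
#' Maps the weighted-vote distribution over (negative, objective, positive)
#' to `[0, 1]` by the valence expectation under the map negative = 0,
#' objective = 0.5, positive = 1. A unanimous positive vote scores 1; a
#' uniform vote scores 0.5. Higher = more positive sentiment.
#'
#' @param ensemble a `"sentiment_ensemble"` over the canonical sentiment
#'   classes.
#' @param tokens token vector, or a list of token vectors.
#' @return numeric score(s) in `[0, 1]`.
#' @export
sse_score <- function(ensemble, tokens) {
  V <- ensemble_votes(ensemble, tokens)
  valence <- stats::setNames(c(0, 0.5, 1), CANONICAL_SENTIMENTS)
  missing <- setdiff(colnames(V), names(valence))
  if (length(missing) > 0) {
    stop("ensemble classes outside the sentiment set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.numeric(V %*% valence[colnames(V)])
}

#' Gaussian prosody-feature emotion scorer (SEE surrogate)
#'
#' A pluggable scorer over six emotion classes (neutral, happy, sad, angry,
#' fearful, surprised). Class-conditional features are modelled as
#' independent Gaussians; the default parameterisation places class means at
#' `separation` times a one-hot direction with unit SDs. The valence map —
#' how emotion classes become a scalar in `[0, 1]` — is a declared fixed
#' total order: sad 0 < angry 0.1 < fearful 0.2 < neutral 0.5 <
#' surprised 0.8 < happy 1. Any trained acoustic model producing a
#' distribution over these classes can be plugged in by supplying its
#' posteriors to the same valence expectation.
#'
#' @param means matrix (6 x feature_dim) of class means, rows named by the
#'   emotion classes; built from `separation` if omitted.
#' @param sds matrix of matching shape of per-feature SDs (default 1).
#' @param valence named numeric valence map over the 6 classes.
#' @param feature_dim,separation used to build default one-hot means.
#' @return object of class `"emotion_scorer"`.
#' @export
emotion_scorer <- function(means = NULL, sds = NULL, valence = NULL,
                           feature_dim = 6L, separation = 2) {
  classes <- c("neutral", "happy", "sad", "angry", "fearful", "surprised")
  if (is.null(means)) {
    means <- separation * diag(length(classes))[, seq_len(feature_dim),
                                                drop = FALSE]
    rownames(means) <- classes
  }
  means <- as.matrix(means)
  if (is.null(rownames(means)) ||
      !setequal(rownames(means), classes)) {
    stop("`means` must have one row per emotion class", call. = FALSE)
  }
  means <- means[classes, , drop = FALSE]
  if (is.null(sds)) sds <- matrix(1, nrow(means), ncol(means))
  sds <- as.matrix(sds)
  stopifnot(all(dim(sds) == dim(means)), all(sds > 0))
  if (is.null(valence)) {
    valence <- c(sad = 0, angry = 0.1, fearful = 0.2, neutral = 0.5,
                 surprised = 0.8, happy = 1)
  }
  stopifnot(setequal(names(valence), classes))
  structure(
    list(classes = classes, means = means, sds = sds,
         valence = valence[classes]),
    class = "emotion_scorer"
  )
}

#' Score prosody features against the emotion classes (SEE)
#'
#' Computes the Gaussian posterior over the six emotion classes (uniform
#' priors) and the scalar valence expectation in `[0, 1]`. Higher = more
#' positive expressed emotion.
#'
#' @param features numeric vector (one subject) or matrix (subjects x
#'   features) matching the scorer's feature dimension.
#' @param scorer an [emotion_scorer()].
#' @return list with `posterior` (matrix, subjects x 6) and `score`
#'   (numeric vector).
#' @export
see_score <- function(features, scorer) {
  stopifnot(inherits(scorer, "emotion_scorer"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != ncol(scorer$means)) {
    stop(sprintf("feature dimension %d does not match scorer dimension %d",
                 ncol(features), ncol(scorer$means)), call. = FALSE)
  }
  n <- nrow(features)
  K <- length(scorer$classes)
  loglik <- matrix(0, n, K, dimnames = list(NULL, scorer$classes))
  for (k in seq_len(K)) {
    loglik[, k] <- rowSums(stats::dnorm(
      features,
      mean = matrix(scorer$means[k, ], n, ncol(features), byrow = TRUE),
      sd = matrix(scorer$sds[k, ], n, ncol(features), byrow = TRUE),
      log = TRUE
    ))
  }
  m <- apply(loglik, 1L, max)
  post <- exp(loglik - m)
  post <- post / rowSums(post)
  list(posterior = post,
       score = as.numeric(post %*% scorer$valence))
}

#' Word error rate
#'
#' Minimal edit distance (substitutions + insertions + deletions) between a
#' reference and a hypothesis token sequence, divided by the reference
#' length. The standard transcription-quality metric; can exceed 1 when the
#' hypothesis is much longer than the reference.
#'
#' @param reference non-empty character vector of reference tokens.
#' @param hypothesis character vector of hypothesis tokens.
#' @return non-negative real.
#' @examples
#' word_error_rate(c("a", "b", "c"), c("a", "x", "c"))
#' @export
word_error_rate <- function(reference, hypothesis) {
  reference <- as.character(reference)
  hypothesis <- as.character(hypothesis)
  n <- length(reference)
  m <- length(hypothesis)
  if (n == 0) stop("empty reference: WER undefined", call. = FALSE)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    if (m > 0) {
      for (j in seq_len(m)) {
        cost <- if (reference[i] == hypothesis[j]) 0 else 1
        cur[j + 1L] <- min(prev[j] + cost,  # substitution / match
                           prev[j + 1L] + 1,  # deletion
                           cur[j] + 1)  # insertion
      }
    }
    prev <- cur
  }
  prev[m + 1L] / n
}
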