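# Generators for every input the assessment pipeline consumes, with planted
# statistical structure so downstream stages have a known ground truth.

#' Simulation configuration for Likert questionnaire responses
#'
#' Bundles the latent common-factor model that generates questionnaire
#' responses. Each respondent draws standard-normal factor scores; item
#' latents are `loading_pattern %*% factors` plus unique noise, and a fixed
#' set of global cutpoints discretises the latent continuum into the 1-5
#' Likert scores. A configurable fraction of respondents is contaminated by a
#' mean shift in latent space, emulating careless or atypical responders.
#'
#' @param n_respondents,n_items,n_factors positive integers; dimensions of the
#'   generated response matrix and of the latent factor space.
#' @param loading_pattern numeric matrix (`n_items` x `n_factors`) of factor
#'   loadings in `[-1, 1]`. Row-wise sums of squares must not exceed 1 so that
#'   a non-negative unique variance exists. Defaults to a simple structure
#'   with loading 0.7 (see [simple_structure_loadings()]).
#' @param uniqueness per-item unique variance (length `n_items`, non-negative,
#'   recycled if scalar). Defaults to `1 - rowSums(loading_pattern^2)` so each
#'   item latent has unit variance.
#' @param likert_cutpoints four strictly ascending reals partitioning the
#'   latent continuum into scores 1-5. The default `(-1.5, -0.5, 0.5, 1.5)`
#'   yields a symmetric, roughly bell-shaped item marginal.
#' @param outlier_fraction fraction of respondents in `[0, 0.5)` whose latent
#'   rows are shifted before thresholding.
#' @param outlier_magnitude size of the contaminating shift in units of the
#'   per-item latent standard deviation.
#' @param seed integer seed; the configuration together with the seed fully
#'   determines the generated matrix.
#'
#' @return an object of class `"sim_config"`.
#' @seealso [simulate_responses()]
#' @export
sim_config <- function(n_respondents, n_items, n_factors,
                       loading_pattern = NULL, uniqueness = NULL,
                       likert_cutpoints = c(-1.5, -0.5, 0.5, 1.5),
                       outlier_fraction = 0, outlier_magnitude = 0,
                       seed = 1L) {
  stopifnot(
    length(n_respondents) == 1L, n_respondents >= 1,
    length(n_items) == 1L, n_items >= 1,
    length(n_factors) == 1L, n_factors >= 1
  )
  n <- as.integer(n_respondents)
  p <- as.integer(n_items)
  k <- as.integer(n_factors)
  if (is.null(loading_pattern)) {
    loading_pattern <- simple_structure_loadings(p, k)
  }
  loading_pattern <- as.matrix(loading_pattern)
  if (!all(is.finite(loading_pattern))) {
    stop("`loading_pattern` must be finite", call. = FALSE)
  }
  if (nrow(loading_pattern) != p || ncol(loading_pattern) != k) {
    stop("`loading_pattern` must be n_items x n_factors", call. = FALSE)
  }
  if (any(abs(loading_pattern) > 1)) {
    stop("loadings must lie in [-1, 1]", call. = FALSE)
  }
  communality <- rowSums(loading_pattern^2)
  if (any(communality > 1 + 1e-8)) {
    stop("row-wise sums of squared loadings must not exceed 1", call. = FALSE)
  }
  if (is.null(uniqueness)) uniqueness <- pmax(0, 1 - communality)
  uniqueness <- rep_len(as.numeric(uniqueness), p)
  if (any(!is.finite(uniqueness)) || any(uniqueness < 0)) {
    stop("`uniqueness` must be finite and non-negative", call. = FALSE)
  }
  if (length(likert_cutpoints) != 4L || any(diff(likert_cutpoints) <= 0)) {
    stop("`likert_cutpoints` must be 4 strictly ascending values",
         call. = FALSE)
  }
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stop("`outlier_fraction` must lie in [0, 0.5)", call. = FALSE)
  }
  if (outlier_magnitude < 0) stop("`outlier_magnitude` must be >= 0",
                                  call. = FALSE)
  structure(
    list(
      n_respondents = n, n_items = p, n_factors = k,
      loading_pattern = loading_pattern, uniqueness = uniqueness,
      likert_cutpoints = as.numeric(likert_cutpoints),
      outlier_fraction = outlier_fraction,
      outlier_magnitude = outlier_magnitude,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simple-structure loading pattern
#'
#' Items are split as evenly as possible across factors; each item loads
#' `loading` on exactly one factor and 0 elsewhere.
#'
#' @param n_items,n_factors matrix dimensions.
#' @param loading the single non-zero loading value.
#' @return an `n_items` x `n_factors` matrix.
#' @export
simple_structure_loadings <- function(n_items, n_factors, loading = 0.7) {
  stopifnot(n_items >= n_factors, abs(loading) <= 1)
  L <- matrix(0, n_items, n_factors)
  assign_to <- rep_len(seq_len(n_factors), n_items)
  L[cbind(seq_len(n_items), sort(assign_to))] <- loading
  L
}

#' Simulate a Likert response matrix from a latent factor model
#'
#' Draws standard-normal factor scores and unique noise, forms item latents
#' `F %*% t(Lambda) + sqrt(psi) * e`, shifts the latent rows of the configured
#' outlier fraction upward by `outlier_magnitude` latent standard deviations,
#' and thresholds at the configured cutpoints to integer scores 1-5.
#'
#' Exactly `floor(outlier_fraction * n)` respondents are contaminated; their
#' (sorted) row indices are returned in the `"outliers"` attribute so that
#' downstream robustness checks can verify the bookkeeping. The cutpoints are
#' attached as a `"cutpoints"` attribute for companion generators.
#'
#' @param config a [sim_config()].
#' @return integer matrix (`n_respondents` x `n_items`, entries 1-5) with
#'   column names `item_1..item_p` and attributes `outliers` and `cutpoints`.
#' @examples
#' cfg <- sim_config(100, 6, 2, seed = 42)
#' X <- simulate_responses(cfg)
#' table(X)
#' @export
simulate_responses <- function(config) {
  sim <- simulate_latent(config)
  latent <- sim$latent
  n <- config$n_respondents
  p <- config$n_items
  outliers <- sim$outliers
  resp <- matrix(
    findInterval(latent, config$likert_cutpoints) + 1L,
    n, p, dimnames = list(NULL, paste0("item_", seq_len(p)))
  )
  storage.mode(resp) <- "integer"
  attr(resp, "outliers") <- outliers
  attr(resp, "cutpoints") <- config$likert_cutpoints
  resp
}

# pre-threshold latent responses; shared by simulate_responses and the
# moment-recovery checks
simulate_latent <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_respondents
  p <- config$n_items
  k <- config$n_factors
  L <- config$loading_pattern
  withr::with_seed(config$seed, {
    scores <- matrix(stats::rnorm(n * k), n, k)
    noise <- matrix(stats::rnorm(n * p), n, p)
    latent <- tcrossprod(scores, L) +
      sweep(noise, 2L, sqrt(config$uniqueness), `*`)
    m <- floor(config$outlier_fraction * n)
    outliers <- integer(0)
    if (m > 0) {
      outliers <- sort(sample.int(n, m))
      latent_sd <- sqrt(rowSums(L^2) + config$uniqueness)
      shift <- config$outlier_magnitude * latent_sd
      latent[outliers, ] <- latent[outliers, ] +
        matrix(shift, m, p, byrow = TRUE)
    }
  })
  list(latent = latent, outliers = outliers)
}

# Correlation between a standard-normal latent and its 5-point discretisation
# under the given cutpoints: cov(Z, score) = sum(dnorm(cutpoints)) because the
# score is 1 + sum of threshold indicators. Used to undo discretisation
# attenuation when planting a target correlation.
discretisation_attenuation <- function(cutpoints) {
  probs <- diff(c(0, stats::pnorm(cutpoints), 1))
  s <- seq_along(probs)
  v <- sum(s^2 * probs) - sum(s * probs)^2
  sum(stats::dnorm(cutpoints)) / sqrt(v)
}

#' Simulate a retest administration with a target reliability
#'
#' Generates a second administration of the questionnaire whose total-score
#' Pearson correlation with the base administration converges to
#' `reliability` as the sample grows. Each retest item latent mixes the
#' standardised base item with fresh noise drawn with the base's own
#' inter-item correlation structure (so the retest preserves the factor
#' structure of the instrument). The mixing weight is `reliability`
#' corrected, in closed form, for (a) the attenuation incurred when the
#' continuous retest latent is discretised back to the 1-5 scale and (b) the
#' variance ratio between base and retest totals that the discretisation
#' induces.
#'
#' @param base integer response matrix as returned by [simulate_responses()].
#' @param reliability target test-retest correlation in `[0, 1]`.
#'   `reliability = 1` returns `base` unchanged.
#' @param seed integer seed.
#' @return integer matrix with the same shape and column names as `base`.
#' @export
simulate_retest <- function(base, reliability, seed = 1L) {
  if (length(reliability) != 1L || !is.finite(reliability) ||
      reliability < 0 || reliability > 1) {
    stop("`reliability` must lie in [0, 1]", call. = FALSE)
  }
  base <- as.matrix(base)
  if (reliability == 1) return(base)
  cutpoints <- attr(base, "cutpoints")
  if (is.null(cutpoints)) cutpoints <- c(-1.5, -0.5, 0.5, 1.5)
  n <- nrow(base)
  p <- ncol(base)
  Z <- scale(base)
  Z[!is.finite(Z)] <- 0  # constant items carry no retest signal
  C <- suppressWarnings(stats::cor(base))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  c_att <- discretisation_attenuation(cutpoints)
  S <- sum(C) - p  # off-diagonal correlation mass
  # totals: cov(T1, T2) ~ a * c * (p + S); var(T2) ~ p + c^2 * S
  adj <- c_att * sqrt((p + S) / (p + c_att^2 * S))
  a <- min(1, reliability / adj)
  es <- eigen(C, symmetric = TRUE)
  sqrtC <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(n * p), n, p) %*% sqrtC
    latent <- a * Z + sqrt(1 - a^2) * noise
  })
  resp <- matrix(findInterval(latent, cutpoints) + 1L, n, p,
                 dimnames = dimnames(base))
  storage.mode(resp) <- "integer"
  attr(resp, "cutpoints") <- cutpoints
  resp
}

#' Simulate a criterion score with a target validity correlation
#'
#' Produces a continuous criterion-scale total (an established instrument
#' standing in for, e.g., the SCL-90) whose Pearson correlation with the base
#' matrix's total scores converges to `validity`.
#'
#' @param base integer response matrix.
#' @param validity target correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return numeric vector of length `nrow(base)`.
#' @export
simulate_criterion <- function(base, validity, seed = 1L) {
  if (length(validity) != 1L || !is.finite(validity) || abs(validity) > 1) {
    stop("`validity` must lie in [-1, 1]", call. = FALSE)
  }
  totals <- rowSums(as.matrix(base))
  s <- stats::sd(totals)
  if (s == 0) stop("base totals are constant; validity is undefined",
                   call. = FALSE)
  z <- (totals - mean(totals)) / s
  withr::with_seed(seed, {
    out <- validity * z + sqrt(1 - validity^2) * stats::rnorm(length(z))
  })
  out
}

#' Labelled text corpus container
#'
#' @param documents list of character vectors (token sequences).
#' @param labels character vector of class labels, one per document. The
#'   canonical sentiment label set is `negative`, `objective`, `positive`,
#'   but any label set with at least one class is accepted so the container
#'   also serves binary classification fixtures.
#' @return an object of class `"labeled_corpus"` with fields `documents`,
#'   `labels` and `vocabulary` (the sorted token union).
#' @export
labeled_corpus <- function(documents, labels) {
  stopifnot(is.list(documents))
  labels <- as.character(labels)
  if (length(documents) != length(labels)) {
    stop("`documents` and `labels` must have equal length", call. = FALSE)
  }
  if (length(documents) == 0L) stop("corpus is empty", call. = FALSE)
  structure(
    list(documents = documents, labels = labels,
         vocabulary = sort(unique(unlist(documents, use.names = FALSE)))),
    class = "labeled_corpus"
  )
}

#' Simulate a labelled corpus from class-conditional unigram models
#'
#' Each class contributes `docs_per_class` documents of `doc_length` tokens
#' drawn i.i.d. from that class's unigram distribution over the shared
#' vocabulary (balanced classes).
#'
#' @param class_unigrams named list of probability vectors, one per class,
#'   all over the same named vocabulary and each summing to 1 (tolerance
#'   1e-9).
#' @param docs_per_class,doc_length positive integers.
#' @param seed integer seed.
#' @return a [labeled_corpus()].
#' @export
simulate_corpus <- function(class_unigrams, docs_per_class, doc_length,
                            seed = 1L) {
  stopifnot(is.list(class_unigrams), length(class_unigrams) >= 1,
            docs_per_class >= 1, doc_length >= 1)
  classes <- names(class_unigrams)
  if (is.null(classes) || any(classes == "")) {
    stop("`class_unigrams` must be a named list", call. = FALSE)
  }
  vocab <- names(class_unigrams[[1L]])
  for (cl in classes) {
    d <- class_unigrams[[cl]]
    if (is.null(names(d)) || !identical(sort(names(d)), sort(vocab))) {
      stop("all class distributions must share one named vocabulary",
           call. = FALSE)
    }
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      stop(sprintf("distribution for class '%s' is not normalized", cl),
           call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    documents <- vector("list", docs_per_class * length(classes))
    labels <- character(length(documents))
    i <- 0L
    for (cl in classes) {
      d <- class_unigrams[[cl]]
      for (j in seq_len(docs_per_class)) {
        i <- i + 1L
        documents[[i]] <- sample(names(d), doc_length, replace = TRUE,
                                 prob = as.numeric(d))
        labels[i] <- cl
      }
    }
  })
  labeled_corpus(documents, labels)
}

#' Default sentiment unigram distributions
#'
#' A small shared vocabulary with negative-leaning, neutral and
#' positive-leaning tokens, and three class distributions (`negative`,
#' `objective`, `positive`) that concentrate mass on the matching token group
#' while overlapping on the neutral tokens, so classes are separable but not
#' trivially so.
#'
#' @return named list of three probability vectors.
#' @export
default_class_unigrams <- function() {
  vocab <- c("sad", "hopeless", "tired", "afraid",
             "ship", "work", "day", "sea",
             "calm", "happy", "good", "rested")
  grp <- rep(c("neg", "neu", "pos"), each = 4L)
  mass <- function(neg, neu, pos) {
    w <- c(neg, neu, pos)[match(grp, c("neg", "neu", "pos"))] / 4
    stats::setNames(w / sum(w), vocab)
  }
  list(
    negative = mass(0.60, 0.30, 0.10),
    objective = mass(0.10, 0.80, 0.10),
    positive = mass(0.10, 0.30, 0.60)
  )
}

#' Cohort simulation configuration
#'
#' Describes a cohort with a binary ground-truth mental-health state that
#' drives three observation channels: the objective questionnaire, a
#' free-text channel, and a prosody-feature (speech) channel, plus a noisy
#' interview label.
#'
#' Effect sizes are per-channel: `scale_effect` shifts every item latent of
#' at-risk subjects (in latent SD units); `text_effect` in `[0, 1]` mixes each
#' subject's token distribution from the neutral `objective` unigram model
#' toward the `negative` (at-risk) or `positive` (healthy) model;
#' `prosody_effect` separates the 6 emotion-class feature means (in feature
#' SD units), with at-risk subjects expressing low-valence emotions (sad,
#' angry, fearful) and healthy subjects neutral/surprised/happy ones.
#'
#' @param n_subjects integer >= 2.
#' @param n_items number of questionnaire items.
#' @param prevalence probability of the at-risk state.
#' @param scale_effect,text_effect,prosody_effect channel effect sizes
#'   (`text_effect` must lie in `[0, 1]`).
#' @param interview_noise probability (< 0.5) that the interview label flips
#'   the true state.
#' @param doc_length tokens per subject document.
#' @param likert_cutpoints passed through to the response generator.
#' @return an object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects, n_items = 12L, prevalence = 0.5,
                          scale_effect = 1, text_effect = 0.6,
                          prosody_effect = 2, interview_noise = 0,
                          doc_length = 30L,
                          likert_cutpoints = c(-1.5, -0.5, 0.5, 1.5)) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2", call. = FALSE)
  stopifnot(prevalence > 0, prevalence < 1,
            scale_effect >= 0, prosody_effect >= 0,
            text_effect >= 0, text_effect <= 1,
            interview_noise >= 0, interview_noise < 0.5,
            n_items >= 1, doc_length >= 1)
  structure(
    list(n_subjects = as.integer(n_subjects), n_items = as.integer(n_items),
         prevalence = prevalence, scale_effect = scale_effect,
         text_effect = text_effect, prosody_effect = prosody_effect,
         interview_noise = interview_noise, doc_length = as.integer(doc_length),
         likert_cutpoints = as.numeric(likert_cutpoints)),
    class = "cohort_config"
  )
}

#' Simulate an assessment cohort with planted ground truth
#'
#' Generates all three observation channels plus a noisy interview label from
#' a single binary latent state per subject. One root seed spawns per-channel
#' child seeds by fixed offsets so the channels are mutually independent given
#' the state, yet the whole cohort is reproducible from `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed.
#' @return an object of class `"assessment_cohort"`: a list with fields
#'   `true_state` (0/1 vector), `responses` (integer Likert matrix), `texts`
#'   (list of token vectors), `emotions` (true emotion labels), `prosody`
#'   (numeric feature matrix), `interview_label` (0/1 vector), and the
#'   generating `text_params` (class unigram list) and `scorer`
#'   ([emotion_scorer()]) describing the channel models.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  p <- config$n_items
  seed <- as.integer(seed)

  state <- withr::with_seed(seed, stats::rbinom(n, 1L, config$prevalence))

  # objective channel: every item latent of at-risk subjects shifts upward
  withr::with_seed(seed + 1L, {
    latent <- config$scale_effect * state +
      matrix(stats::rnorm(n * p), n, p)
  })
  responses <- matrix(findInterval(latent, config$likert_cutpoints) + 1L,
                      n, p, dimnames = list(NULL, paste0("item_", seq_len(p))))
  storage.mode(responses) <- "integer"
  attr(responses, "cutpoints") <- config$likert_cutpoints

  # text channel: subject-specific unigram mixtures
  unigrams <- default_class_unigrams()
  mix <- function(target) {
    w <- config$text_effect
    d <- w * unigrams[[target]] + (1 - w) * unigrams$objective
    d / sum(d)
  }
  dist_risk <- mix("negative")
  dist_healthy <- mix("positive")
  withr::with_seed(seed + 2L, {
    texts <- lapply(seq_len(n), function(i) {
      d <- if (state[i] == 1L) dist_risk else dist_healthy
      sample(names(d), config$doc_length, replace = TRUE, prob = as.numeric(d))
    })
  })

  # speech channel: emotion class drawn by state, features Gaussian about the
  # class mean (one-hot direction scaled by the effect size)
  scorer <- emotion_scorer(feature_dim = 6L,
                           separation = config$prosody_effect)
  low <- c("sad", "angry", "fearful")
  high <- c("neutral", "surprised", "happy")
  withr::with_seed(seed + 3L, {
    emotions <- vapply(state, function(s) {
      sample(if (s == 1L) low else high, 1L)
    }, character(1))
    prosody <- scorer$means[emotions, , drop = FALSE] +
      matrix(stats::rnorm(n * 6L), n, 6L)
  })
  rownames(prosody) <- NULL

  withr::with_seed(seed + 4L, {
    flip <- stats::rbinom(n, 1L, config$interview_noise)
  })
  interview <- ifelse(flip == 1L, 1L - state, state)

  structure(
    list(true_state = state, responses = responses, texts = texts,
         emotions = emotions, prosody = prosody,
         interview_label = as.integer(interview),
         text_params = list(risk = dist_risk, healthy = dist_healthy,
                            training = unigrams),
         scorer = scorer, config = config, seed = seed),
    class = "assessment_cohort"
  )
}
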