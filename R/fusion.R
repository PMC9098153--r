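# Weighted late fusion of the objective scale score with the two subjective
# channels, a thresholded risk decision, and calibration metrics of the
# fused system against interview ground truth.

#' Normalise a raw scale total to [0, 1]
#'
#' Min-max normalisation over the attainable range of a Likert total:
#' `(total - n_items * min) / (n_items * (max - min))`. All-minimum
#' responses map to 0, all-maximum to 1.
#'
#' @param total raw total score(s).
#' @param n_items number of items summed.
#' @param likert_range attainable per-item range, default `c(1, 5)`.
#' @return numeric in `[0, 1]`.
#' @export
normalize_objective <- function(total, n_items, likert_range = c(1, 5)) {
  lo <- n_items * likert_range[1L]
  hi <- n_items * likert_range[2L]
  if (any(total < lo) || any(total > hi)) {
    stop(sprintf("total outside attainable range [%g, %g]", lo, hi),
         call. = FALSE)
  }
  (total - lo) / (hi - lo)
}

#' Fuse objective and subjective assessment components
#'
#' Convex combination `fused = sum(w_i c_i) / sum(w_i)` of the three
#' components, each in `[0, 1]`. The default weights 6 : 1.5 : 3.5 give the
#' objective scale 6/11 of the mass and split the remaining subjective mass
#' between text and speech in proportion 1.5 : 3.5 (echoing the 7-38-55
#' communication-channel rule applied to the subjective share); they are
#' normalised internally so any non-negative, not-all-zero triple works.
#'
#' @param objective,sse,see component scores in `[0, 1]` (vectors of equal
#'   length are fused element-wise).
#' @param weights non-negative weight triple (objective, sse, see).
#' @return object of class `"fused_assessment"`: data.frame with columns
#'   `objective`, `sse`, `see`, `fused`, carrying the normalised weights as
#'   an attribute.
#' @examples
#' fuse(0.8, 0.4, 0.6)
#' @export
fuse <- function(objective, sse, see, weights = c(6, 1.5, 3.5)) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  if (sum(weights) == 0) stop("weights must not all be zero", call. = FALSE)
  comp <- cbind(objective = objective, sse = sse, see = see)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 1)) {
    stop("components must lie in [0, 1]", call. = FALSE)
  }
  w <- weights / sum(weights)
  out <- data.frame(comp, fused = as.numeric(comp %*% w))
  attr(out, "weights") <- w
  class(out) <- c("fused_assessment", "data.frame")
  out
}

#' Threshold a fused score into a binary risk decision
#'
#' At-risk (`1`) iff `score >= threshold`; the tie at exactly the threshold
#' is declared at-risk so the rule is deterministic.
#'
#' @param score fused score(s) in `[0, 1]`.
#' @param threshold decision threshold, default 0.5.
#' @return integer vector of 0/1 decisions.
#' @export
classify_risk <- function(score, threshold = 0.5) {
  if (any(score < 0) || any(score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  as.integer(score >= threshold)
}

#' Calibration of the fused system against ground truth
#'
#' Compares the accuracy of the fused (dual subjective-objective) decisions
#' with the scale-only decisions against interview ground truth. The
#' calibration rate is the relative accuracy improvement in percent:
#' `100 * (acc_fused - acc_scale) / acc_scale`. If self-reported scores are
#' supplied, the self-test error is the mean absolute difference between
#' fused scores and self-reports.
#'
#' @param fused_decisions,scale_decisions,truth equal-length 0/1 vectors.
#' @param fused_scores,self_reports optional equal-length numeric vectors
#'   for the self-test error.
#' @return object of class `"calibration_result"` with `acc_fused`,
#'   `acc_scale_only`, `calibration_rate` (percent, `NA` when scale-only
#'   accuracy is zero) and `self_test_error` (or `NULL`).
#' @export
calibration_rate <- function(fused_decisions, scale_decisions, truth,
                             fused_scores = NULL, self_reports = NULL) {
  n <- length(truth)
  stopifnot(n >= 1, length(fused_decisions) == n,
            length(scale_decisions) == n)
  acc_f <- mean(fused_decisions == truth)
  acc_s <- mean(scale_decisions == truth)
  rate <- if (acc_s == 0) NA_real_ else 100 * (acc_f - acc_s) / acc_s
  ste <- NULL
  if (!is.null(fused_scores) && !is.null(self_reports)) {
    stopifnot(length(fused_scores) == length(self_reports))
    ste <- mean(abs(fused_scores - self_reports))
  }
  structure(
    list(acc_fused = acc_f, acc_scale_only = acc_s,
         calibration_rate = rate, self_test_error = ste),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration against interview ground truth\n")
  cat(sprintf("  fused accuracy:      %.3f\n", x$acc_fused))
  cat(sprintf("  scale-only accuracy: %.3f\n", x$acc_scale_only))
  cat(sprintf("  calibration rate:    %s\n",
              if (is.na(x$calibration_rate)) "undefined (zero baseline)"
              else sprintf("%+.2f%%", x$calibration_rate)))
  if (!is.null(x$self_test_error)) {
    cat(sprintf("  self-test error:     %.3f\n", x$self_test_error))
  }
  invisible(x)
}

#' Assess a simulated cohort end to end
#'
#' Runs the full dual assessment on a cohort from [simulate_cohort()]:
#' the objective component is the min-max normalised scale total; the text
#' component is the risk direction of the SSE sentiment (`1 - sse_score`,
#' since negative sentiment indicates risk); the speech component is
#' `1 - see_score` likewise. The sentiment ensemble is trained on a fresh
#' reference corpus drawn from the cohort's class unigram models; the
#' emotion scorer is the cohort's own channel model (a stand-in for a
#' pretrained acoustic model). Components are fused, thresholded, and
#' calibrated against the interview labels.
#'
#' @param cohort an `"assessment_cohort"`.
#' @param weights fusion weight triple.
#' @param threshold decision threshold.
#' @param n_rounds boosting rounds for the sentiment ensemble.
#' @param train_docs_per_class reference-corpus size per sentiment class.
#' @param seed seed for ensemble training (resampling + reference corpus);
#'   defaults to the cohort seed plus a fixed offset.
#' @param ensemble optional pre-trained `"sentiment_ensemble"` to reuse for
#'   the text channel instead of training one here.
#' @return list with `assessment` (a [fuse()] data.frame plus `decision` and
#'   `scale_decision` columns) and `calibration` (a
#'   [calibration_rate()] result).
#' @export
assess_cohort <- function(cohort, weights = c(6, 1.5, 3.5), threshold = 0.5,
                          n_rounds = 5L, train_docs_per_class = 100L,
                          seed = NULL, ensemble = NULL) {
  stopifnot(inherits(cohort, "assessment_cohort"))
  if (is.null(seed)) seed <- cohort$seed + 100L
  p <- ncol(cohort$responses)

  objective <- normalize_objective(rowSums(cohort$responses), p)

  if (is.null(ensemble)) {
    train <- simulate_corpus(cohort$text_params$training,
                             docs_per_class = train_docs_per_class,
                             doc_length = cohort$config$doc_length,
                             seed = seed)
    ensemble <- train_adaboost(train, n_rounds = n_rounds, seed = seed + 1L)
  }
  sse_risk <- 1 - sse_score(ensemble, cohort$texts)

  see_risk <- 1 - see_score(cohort$prosody, cohort$scorer)$score

  fused <- fuse(objective, sse_risk, see_risk, weights = weights)
  fused$decision <- classify_risk(fused$fused, threshold)
  fused$scale_decision <- classify_risk(objective, threshold)

  calib <- calibration_rate(fused$decision, fused$scale_decision,
                            cohort$interview_label,
                            fused_scores = fused$fused,
                            self_reports = objective)
  list(assessment = fused, calibration = calib)
}
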