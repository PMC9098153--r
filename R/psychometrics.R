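# Scale validation suite: internal consistency, stability over time,
# agreement with an established criterion instrument, item discrimination,
# distributional screening, readability, and vote-based dimension weighting.

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = K/(K-1) * (1 - sum(var(items)) / var(total))`, with unbiased
#' (n-1) sample variances throughout. Since the item and total variances
#' share one convention, alpha itself is convention-free.
#'
#' @param X numeric matrix (respondents x items), `K >= 2` items.
#' @return scalar `<= 1` (can be negative for incoherent scales).
#' @examples
#' X <- simulate_responses(sim_config(200, 8, 1, seed = 3))
#' cronbach_alpha(X)
#' @export
cronbach_alpha <- function(X) {
  X <- as.matrix(X)
  K <- ncol(X)
  if (K < 2) stop("alpha requires at least 2 items", call. = FALSE)
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) stop("zero total-score variance", call. = FALSE)
  item_var <- sum(apply(X, 2L, stats::var))
  K / (K - 1) * (1 - item_var / total_var)
}

#' Test-retest reliability
#'
#' Pearson correlation of total scores across two administrations of the
#' same instrument to the same respondents (matched row order).
#'
#' @param X1,X2 response matrices with equal row counts.
#' @return correlation in `[-1, 1]`.
#' @export
retest_reliability <- function(X1, X2) {
  t1 <- rowSums(as.matrix(X1))
  t2 <- rowSums(as.matrix(X2))
  stopifnot(length(t1) == length(t2))
  if (stats::sd(t1) == 0 || stats::sd(t2) == 0) {
    stop("constant total scores: correlation undefined", call. = FALSE)
  }
  stats::cor(t1, t2)
}

#' Criterion validity
#'
#' Pearson correlation between scale scores and an external criterion
#' measure (e.g., totals of an established instrument such as the SCL-90).
#' The moment form `sum((X - mean)(Y - mean)) / (N S_X S_Y)` is honoured by
#' using one N-convention in numerator and denominators, which makes the
#' result identical to [stats::cor()].
#'
#' @param scale_scores numeric vector of totals, or a response matrix whose
#'   rows are summed.
#' @param criterion numeric vector of criterion scores.
#' @return correlation in `[-1, 1]`.
#' @export
criterion_validity <- function(scale_scores, criterion) {
  if (is.matrix(scale_scores) || is.data.frame(scale_scores)) {
    scale_scores <- rowSums(as.matrix(scale_scores))
  }
  stopifnot(length(scale_scores) == length(criterion))
  if (stats::sd(scale_scores) == 0 || stats::sd(criterion) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(scale_scores, criterion)
}

#' Item discrimination by the critical ratio method
#'
#' For each item, ranks respondents by their total over the *remaining*
#' items, takes the top and bottom `high_low_fraction` (Kelley's classic 27%
#' by default; total ties are broken by the full response pattern, so
#' verdicts do not depend on respondent order), and computes a Welch t
#' statistic (the critical ratio) for the item between the two groups.
#' Excluding the item under test from its own ranking total is the standard
#' correction that stops an uninformative item from appearing to
#' discriminate merely because it contributes to the total it is ranked by.
#' Items whose groups do not differ significantly (`p > alpha_level`) fail
#' to discriminate and are marked for deletion. An item constant within both
#' groups gets `cr = 0`, `p = 1` and a `delete` verdict rather than a
#' numerical failure.
#'
#' @param X response matrix.
#' @param high_low_fraction fraction in each extreme group (both groups must
#'   end up with >= 2 members).
#' @param alpha_level significance level for the keep/delete verdict.
#' @return data.frame with columns `item`, `cr`, `p_value`, `verdict`.
#' @export
item_discrimination <- function(X, high_low_fraction = 0.27,
                                alpha_level = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- floor(high_low_fraction * n)
  if (m < 2) stop("groups too small: need floor(fraction * n) >= 2",
                  call. = FALSE)
  items <- colnames(X)
  if (is.null(items)) items <- paste0("item_", seq_len(ncol(X)))
  totals <- rowSums(X)
  res <- lapply(seq_len(ncol(X)), function(j) {
    # rank by the rest-of-scale total; ties resolved by the full response
    # pattern so the split is invariant to respondent order
    ord <- do.call(order, c(list(totals - X[, j]), as.data.frame(X)))
    low <- ord[seq_len(m)]
    high <- ord[seq.int(n - m + 1L, n)]
    hi <- X[high, j]
    lo <- X[low, j]
    if (stats::sd(hi) == 0 && stats::sd(lo) == 0) {
      return(c(cr = 0, p = 1))
    }
    tt <- tryCatch(stats::t.test(hi, lo, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) return(c(cr = 0, p = 1))
    c(cr = unname(tt$statistic), p = tt$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(
    item = items,
    cr = res[, "cr"],
    p_value = res[, "p"],
    verdict = ifelse(res[, "p"] > alpha_level, "delete", "keep"),
    stringsAsFactors = FALSE
  )
}

#' Screen items for departure from normality
#'
#' Flags an item when `|skewness| > skew_threshold` or
#' `|excess kurtosis| > kurtosis_threshold` (moment definitions, e1071
#' type 1). The default thresholds (2 and 7) are the conventional bounds for
#' severe non-normality in questionnaire data; floor/ceiling-affected items
#' exceed them readily. Constant items are flagged.
#'
#' @param X response matrix (`n >= 20` recommended).
#' @return data.frame with `item`, `skewness`, `excess_kurtosis`, `flagged`.
#' @export
normality_screen <- function(X, skew_threshold = 2, kurtosis_threshold = 7) {
  X <- as.matrix(X)
  if (nrow(X) < 20) warning("fewer than 20 respondents; ",
                            "moment estimates are unstable")
  items <- colnames(X)
  if (is.null(items)) items <- paste0("item_", seq_len(ncol(X)))
  sk <- apply(X, 2L, e1071::skewness, type = 1)
  ku <- apply(X, 2L, e1071::kurtosis, type = 1)
  flagged <- !is.finite(sk) | !is.finite(ku) |
    abs(sk) > skew_threshold | abs(ku) > kurtosis_threshold
  data.frame(item = items, skewness = sk, excess_kurtosis = ku,
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Flesch reading-ease score
#'
#' `206.835 - 1.015 * (words / sentences) - 84.6 * (syllables / words)`.
#' Higher is easier; roughly 60-70 corresponds to plain English. Note this
#' is the reading-ease formula, on a 0-100-ish scale, not the grade-level
#' variant; the two are often conflated in applied reports.
#'
#' @param word_count,sentence_count,syllable_count positive counts.
#' @return scalar reading-ease score.
#' @export
flesch_reading_ease <- function(word_count, sentence_count, syllable_count) {
  if (word_count <= 0 || sentence_count <= 0 || syllable_count <= 0) {
    stop("counts must be positive", call. = FALSE)
  }
  206.835 - 1.015 * (word_count / sentence_count) -
    84.6 * (syllable_count / word_count)
}

#' Heuristic syllable count
#'
#' Counts maximal vowel groups per word (English heuristic: a trailing
#' silent "e" after a consonant is dropped; every word has at least one
#' syllable). A convenience only — the readability interface takes counts so
#' the formula stays language-neutral.
#'
#' @param words character vector.
#' @return integer vector of per-word syllable counts.
#' @export
count_syllables <- function(words) {
  vapply(tolower(words), function(w) {
    w <- gsub("[^a-z]", "", w)
    if (nchar(w) == 0) return(0L)
    w <- sub("([^aeiouy])e$", "\\1", w)
    groups <- gregexpr("[aeiouy]+", w)[[1L]]
    max(1L, sum(groups > 0))
  }, integer(1), USE.NAMES = FALSE)
}

#' Vote-weighted ranking of candidate scale dimensions
#'
#' Expert/stakeholder votes on each candidate dimension use a 5-point
#' grading (`g = 1..5`). The dimension weight is the grade-mass fraction
#' `sum(g * count_g) / (5 * total_votes)`. Dimensions with too few total
#' votes (`total < min_total`) or too small a largest single-grade mass
#' (`max(count_g) < min_grade_mass`) fail the statistical criteria and are
#' excluded from the ranking. Remaining dimensions are ranked by descending
#' weight, ties broken alphabetically by name.
#'
#' @param votes data.frame with columns `dimension, g1, g2, g3, g4, g5`.
#' @param min_total minimum total votes per dimension.
#' @param min_grade_mass minimum largest single-grade count.
#' @return data.frame `dimension, total_votes, weight, rank` for retained
#'   dimensions, plus an `excluded` attribute naming the dropped ones.
#' @export
dimension_vote_weighting <- function(votes, min_total = 142,
                                     min_grade_mass = 80) {
  cols <- c("dimension", paste0("g", 1:5))
  if (!is.data.frame(votes) || !all(cols %in% names(votes)) ||
      nrow(votes) == 0) {
    stop("`votes` must be a non-empty data.frame with columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(votes[, paste0("g", 1:5)])
  if (any(counts < 0)) stop("vote counts must be non-negative",
                            call. = FALSE)
  total <- rowSums(counts)
  weight <- as.numeric(counts %*% (1:5)) / (5 * total)
  weight[total == 0] <- 0
  keep <- total >= min_total & apply(counts, 1L, max) >= min_grade_mass
  out <- data.frame(dimension = as.character(votes$dimension),
                    total_votes = total, weight = weight,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-out$weight, out$dimension), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- as.character(votes$dimension)[!keep]
  out
}

#' Full psychometric report for a scale
#'
#' Convenience wrapper assembling the validation suite into one object:
#' Cronbach's alpha, test-retest reliability, criterion validity (per
#' criterion column if several are supplied), item-discrimination verdicts,
#' and normality flags.
#'
#' @param X response matrix.
#' @param retest optional second administration.
#' @param criterion optional criterion vector or matrix (one column per
#'   criterion dimension).
#' @param readability optional precomputed reading-ease score to carry along.
#' @param ... passed to [item_discrimination()].
#' @return object of class `"scale_report"`.
#' @export
scale_report <- function(X, retest = NULL, criterion = NULL,
                         readability = NULL, ...) {
  X <- as.matrix(X)
  crit_r <- NULL
  if (!is.null(criterion)) {
    criterion <- as.matrix(criterion)
    crit_r <- apply(criterion, 2L, function(y) criterion_validity(X, y))
  }
  structure(
    list(
      alpha = cronbach_alpha(X),
      retest_r = if (!is.null(retest)) retest_reliability(X, retest),
      criterion_r = crit_r,
      item_verdicts = item_discrimination(X, ...),
      normality_flags = normality_screen(X),
      readability = readability
    ),
    class = "scale_report"
  )
}

#' @export
print.scale_report <- function(x, ...) {
  cat("Scale validation report\n")
  cat(sprintf("  Cronbach's alpha: %.3f\n", x$alpha))
  if (!is.null(x$retest_r)) {
    cat(sprintf("  test-retest reliability: %.3f\n", x$retest_r))
  }
  if (!is.null(x$criterion_r)) {
    cat(sprintf("  criterion validity: %s\n",
                paste(sprintf("%.3f", x$criterion_r), collapse = ", ")))
  }
  cat(sprintf("  items flagged for deletion: %d of %d\n",
              sum(x$item_verdicts$verdict == "delete"),
              nrow(x$item_verdicts)))
  if (!is.null(x$readability)) {
    cat(sprintf("  readability (Flesch reading ease): %.1f\n",
                x$readability))
  }
  invisible(x)
}
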