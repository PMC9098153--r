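# Orchestration and file I/O: validated CSV ingestion of response matrices,
# a stage-toggled end-to-end pipeline over the simulation, factor-analysis,
# psychometric, affect and fusion modules, and a reproducible report writer.

#' Pipeline configuration
#'
#' Collects stage toggles and per-stage options for [run_pipeline()]. Every
#' source of randomness in the pipeline descends from the single `seed`.
#'
#' @param seed root integer seed.
#' @param out_dir output directory (created if missing).
#' @param stages named logical list toggling `simulate`, `efa`, `validate`,
#'   `affect`, `fusion`; missing entries default to `TRUE`.
#' @param n_respondents,n_items,n_factors,outlier_fraction,outlier_magnitude
#'   response-simulation settings (see [sim_config()]).
#' @param retest_reliability,validity planted targets for the retest and
#'   criterion companions.
#' @param readability_counts optional named list/vector with `words`,
#'   `sentences`, `syllables` for the scale-text readability score.
#' @param n_subjects,cohort_args cohort size and extra [cohort_config()]
#'   arguments for the fusion stage.
#' @param weights,threshold fusion weights and decision threshold.
#' @param efa_args extra arguments for [fit_fuzzy_fa()].
#' @param adaboost_rounds boosting rounds for the affect stage.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("mhdual_"),
                            stages = list(),
                            n_respondents = 283L, n_items = 18L,
                            n_factors = 3L,
                            outlier_fraction = 0.05, outlier_magnitude = 4,
                            retest_reliability = 0.873, validity = 0.65,
                            readability_counts = NULL,
                            n_subjects = 200L, cohort_args = list(),
                            weights = c(6, 1.5, 3.5), threshold = 0.5,
                            efa_args = list(), adaboost_rounds = 5L) {
  all_stages <- c("simulate", "efa", "validate", "affect", "fusion")
  on <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  bad <- setdiff(names(stages), all_stages)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  on[names(stages)] <- vapply(stages, isTRUE, logical(1))
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, stages = as.list(on),
         n_respondents = as.integer(n_respondents),
         n_items = as.integer(n_items), n_factors = as.integer(n_factors),
         outlier_fraction = outlier_fraction,
         outlier_magnitude = outlier_magnitude,
         retest_reliability = retest_reliability, validity = validity,
         readability_counts = readability_counts,
         n_subjects = as.integer(n_subjects), cohort_args = cohort_args,
         weights = weights, threshold = threshold,
         efa_args = efa_args, adaboost_rounds = as.integer(adaboost_rounds)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' @param path path to a JSON file whose keys match [pipeline_config()]
#'   arguments.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(args), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(args$stages)) args$stages <- as.list(args$stages)
  if (!is.null(args$cohort_args)) args$cohort_args <- as.list(args$cohort_args)
  if (!is.null(args$efa_args)) args$efa_args <- as.list(args$efa_args)
  do.call(pipeline_config, args)
}

#' Read and validate a Likert response CSV
#'
#' Expects a comma-separated UTF-8 file with a header row (`item_1..item_p`
#' or any item names), one respondent per row, integer entries 1-5. Any
#' malformed or out-of-range cell is rejected with its (row, column)
#' coordinates.
#'
#' @param path CSV path.
#' @return integer response matrix with column names from the header.
#' @export
read_response_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) {
    stop("no response data in ", path, call. = FALSE)
  }
  X <- suppressWarnings(
    vapply(df, function(col) as.numeric(as.character(col)),
           numeric(nrow(df)))
  )
  X <- matrix(X, nrow = nrow(df),
              dimnames = list(NULL, names(df)))
  bad <- which(!is.finite(X) | X != round(X) | X < 1 | X > 5,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid Likert entry at row %d, column %d ('%s'): values must be integers 1-5",
      bad[1L, 1L], bad[1L, 2L], as.character(df[bad[1L, 1L], bad[1L, 2L]])
    ), call. = FALSE)
  }
  storage.mode(X) <- "integer"
  X
}

#' Write a response matrix as CSV
#'
#' Comma-separated, UTF-8, mandatory header row, one respondent per row.
#'
#' @param X integer response matrix.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(X, path) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("item_", seq_len(ncol(X)))
  }
  utils::write.csv(as.data.frame(X), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # hash the analysis settings, not the destination
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                           null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the dual-assessment pipeline end to end
#'
#' Executes, in order and as toggled: response/retest/criterion simulation,
#' fuzzy exploratory factor analysis with sampling-adequacy tests,
#' psychometric validation, sentiment-ensemble training for the text
#' channel, and cohort-level fusion with calibration. Later stages consume
#' earlier stages' outputs; enabling a stage whose dependency is disabled is
#' a configuration error naming the stage. All artifacts are written under
#' `config$out_dir` and are byte-reproducible from `(config, seed)`.
#'
#' @param config a [pipeline_config()] (or a path to a JSON config).
#' @param quiet suppress progress messages.
#' @return object of class `"report_bundle"`: per-stage results plus a
#'   provenance block (config hash, seed, package version).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  on <- config$stages
  need <- function(stage, dep) {
    if (isTRUE(on[[stage]]) && !isTRUE(on[[dep]])) {
      stop(sprintf("stage '%s' requires stage '%s' to be enabled",
                   stage, dep), call. = FALSE)
    }
  }
  need("efa", "simulate")
  need("validate", "simulate")
  need("fusion", "affect")
  say <- function(...) if (!quiet) message(sprintf(...))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list(provenance = list(
    package = "mhdual",
    version = as.character(utils::packageVersion("mhdual")),
    seed = config$seed,
    config_hash = config_hash(config)
  ))

  responses <- retest <- criterion <- NULL
  if (isTRUE(on$simulate)) {
    say("stage simulate: n=%d respondents, p=%d items",
        config$n_respondents, config$n_items)
    scfg <- sim_config(config$n_respondents, config$n_items,
                       config$n_factors,
                       outlier_fraction = config$outlier_fraction,
                       outlier_magnitude = config$outlier_magnitude,
                       seed = config$seed)
    responses <- simulate_responses(scfg)
    retest <- simulate_retest(responses, config$retest_reliability,
                              seed = config$seed + 10L)
    criterion <- simulate_criterion(responses, config$validity,
                                    seed = config$seed + 11L)
    write_response_csv(responses, file.path(config$out_dir, "responses.csv"))
    write_response_csv(retest, file.path(config$out_dir, "retest.csv"))
    utils::write.csv(data.frame(criterion = criterion),
                     file.path(config$out_dir, "criterion.csv"),
                     row.names = FALSE, quote = FALSE)
    bundle$simulate <- list(n_outliers = length(attr(responses, "outliers")))
  }

  if (isTRUE(on$efa)) {
    fit <- do.call(fit_fuzzy_fa, c(list(X = responses), config$efa_args))
    adequacy <- list(
      kmo = kmo_statistic(fit$fuzzy_cor),
      bartlett = bartlett_sphericity(fit$fuzzy_cor, nrow(responses))
    )
    say("stage efa: retained_k=%d, KMO=%.3f", fit$retained_k, adequacy$kmo)
    bundle$efa <- list(model = fit, adequacy = adequacy)
  }

  if (isTRUE(on$validate)) {
    readability <- NULL
    rc <- config$readability_counts
    if (!is.null(rc)) {
      readability <- flesch_reading_ease(rc$words, rc$sentences,
                                         rc$syllables)
    }
    report <- scale_report(responses, retest = retest,
                           criterion = criterion,
                           readability = readability)
    say("stage validate: alpha=%.3f, retest_r=%.3f",
        report$alpha, report$retest_r)
    bundle$validate <- report
  }

  ensemble <- NULL
  if (isTRUE(on$affect)) {
    corpus <- simulate_corpus(default_class_unigrams(),
                              docs_per_class = 100L, doc_length = 30L,
                              seed = config$seed + 20L)
    ensemble <- train_adaboost(corpus, n_rounds = config$adaboost_rounds,
                               seed = config$seed + 21L)
    train_acc <- mean(ensemble_classify(ensemble, corpus$documents) ==
                        corpus$labels)
    say("stage affect: %d boosting rounds, training accuracy %.3f",
        ensemble$n_rounds, train_acc)
    bundle$affect <- list(
      n_rounds = ensemble$n_rounds,
      epsilon = vapply(ensemble$rounds, `[[`, numeric(1), "epsilon"),
      alpha = vapply(ensemble$rounds, `[[`, numeric(1), "alpha"),
      training_accuracy = train_acc
    )
  }

  if (isTRUE(on$fusion)) {
    ccfg <- do.call(cohort_config,
                    c(list(n_subjects = config$n_subjects),
                      config$cohort_args))
    cohort <- simulate_cohort(ccfg, seed = config$seed + 30L)
    assessed <- assess_cohort(cohort, weights = config$weights,
                              threshold = config$threshold,
                              seed = config$seed + 31L,
                              ensemble = ensemble)
    say("stage fusion: fused acc=%.3f, scale-only acc=%.3f",
        assessed$calibration$acc_fused, assessed$calibration$acc_scale_only)
    utils::write.csv(
      cbind(assessed$assessment, truth = cohort$interview_label),
      file.path(config$out_dir, "assessment.csv"),
      row.names = FALSE, quote = FALSE
    )
    bundle$fusion <- assessed$calibration
  }

  class(bundle) <- "report_bundle"
  manifest <- write_report(bundle, config$out_dir)
  bundle$manifest <- manifest
  bundle
}

# flatten a report bundle into JSON-friendly structures
bundle_for_json <- function(bundle) {
  out <- list(provenance = bundle$provenance)
  if (!is.null(bundle$simulate)) out$simulate <- bundle$simulate
  if (!is.null(bundle$efa)) {
    m <- bundle$efa$model
    out$efa <- list(
      retained_k = m$retained_k,
      eigenvalues = m$eigenvalues,
      loadings = as.data.frame(m$loadings),
      variance_contribution = m$variance_contribution,
      cumulative_contribution = m$cumulative_contribution,
      memberships = m$memberships,
      iterations_run = m$iterations_run,
      converged = m$converged,
      kmo = bundle$efa$adequacy$kmo,
      bartlett = bundle$efa$adequacy$bartlett
    )
  }
  if (!is.null(bundle$validate)) out$validate <- unclass(bundle$validate)
  if (!is.null(bundle$affect)) out$affect <- bundle$affect
  if (!is.null(bundle$fusion)) out$fusion <- unclass(bundle$fusion)
  out
}

#' Write the report bundle to disk
#'
#' Writes `report.json` (all scalar results, eigenvalues, memberships,
#' contributions), `loadings.csv` when a factor model is present, and a
#' `manifest.csv` listing every written file with its MD5 checksum. Outputs
#' contain no timestamps, so two runs from the same `(config, seed)` are
#' byte-identical.
#'
#' @param bundle a `"report_bundle"`.
#' @param dir writable output directory.
#' @return data.frame manifest (`file`, `md5`).
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2L) != 0) stop("directory not writable: ", dir,
                                      call. = FALSE)
  jsonlite::write_json(bundle_for_json(bundle),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE,
                       null = "null")
  if (!is.null(bundle$efa)) {
    L <- bundle$efa$model$loadings
    utils::write.csv(
      data.frame(item = rownames(L), as.data.frame(L)),
      file.path(dir, "loadings.csv"), row.names = FALSE, quote = FALSE
    )
  }
  files <- setdiff(list.files(dir), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}
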