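# End-to-end experiment orchestration: feature-set comparisons evaluated by
# leave-one-out cross-validation, with optional shuffled-label nulls.

#' Standard feature-set runs for cohort classification experiments
#'
#' A convenience catalogue of the feature sets usually compared: CDR3
#' amino-acid 3-mers, V gene usage, V-J-CDR3-length clusters, the full 5-mer
#' SHM model, its WA/TW- and WRC/GYW-restricted variants, the
#' synonymous-only model and the 3-mer collapse.
#'
#' @param runs optional character subset of the catalogue names.
#' @return named list usable as the `runs` element of [experiment_config()].
#' @export
standard_runs <- function(runs = NULL) {
  all <- list(
    cdr3_3mer = list(family = "cdr3_kmers", k = 3L),
    v_usage = list(family = "v_usage"),
    vjl_clusters = list(family = "vjl_clusters"),
    shm_5mer_all = list(family = "shm_5mer"),
    shm_wa_tw = list(family = "shm_5mer", motif_filter = "wa_tw"),
    shm_wrc_gyw = list(family = "shm_5mer", motif_filter = "wrc_gyw"),
    shm_synonymous = list(family = "shm_5mer", synonymous_only = TRUE),
    shm_3mer = list(family = "shm_3mer"))
  if (is.null(runs)) all else all[runs]
}

#' Experiment configuration
#'
#' @param runs named list of feature-family specs (see
#'   [assemble_feature_table()]); e.g. [standard_runs()].
#' @param top_k screening size per run (scalar or named per-run vector; 0 =
#'   no selection).
#' @param selection_scope `"per_fold"` or `"global"`.
#' @param tuning elastic-net tuning grid (see [fit_elasticnet_logistic()]).
#' @param n_permutations shuffled-label permutations per run (0 = skip the
#'   null).
#' @param seed master seed.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(runs = standard_runs(), top_k = 30L,
                              selection_scope = "per_fold", tuning = NULL,
                              n_permutations = 0L, seed = 1L) {
  if (is.null(names(runs)) || anyDuplicated(names(runs)))
    stop("runs must have unique names")
  structure(list(runs = runs, top_k = top_k,
                 selection_scope = selection_scope, tuning = tuning,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

run_top_k <- function(config, run) {
  k <- config$top_k
  if (!is.null(names(k)) && run %in% names(k)) k[[run]] else k[[1]]
}

#' Run a feature-set comparison experiment on a cohort
#'
#' For every configured run: assemble the feature table, evaluate by
#' leave-one-out cross-validation, and (optionally) compute a shuffled-label
#' null. A failing run is recorded as an error and the others proceed.
#'
#' @param x a [cohort()].
#' @param config an [experiment_config()].
#' @param out_dir optional directory: per-run CV results are written as JSON
#'   together with a config snapshot.
#' @return object of class `shm_experiment`: per-run list with `cv`,
#'   `null`, `error`; plus a `comparison` data frame of F1 with confidence
#'   intervals across runs.
#' @export
run_experiment <- function(x, config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(x, "cohort"), inherits(config, "experiment_config"))
  results <- list()
  for (run in names(config$runs)) {
    t0 <- Sys.time()
    res <- tryCatch({
      feats <- assemble_feature_table(x, config$runs[run])
      cv <- loo_cross_validate(feats, x$labels,
                               top_k = run_top_k(config, run),
                               tuning = config$tuning,
                               selection_scope = config$selection_scope,
                               seed = derive_seed(config$seed,
                                                  paste0("cv_", run)))
      nul <- if (config$n_permutations > 0)
        shuffled_label_null(feats, x$labels,
                            n_permutations = config$n_permutations,
                            top_k = run_top_k(config, run),
                            tuning = config$tuning,
                            selection_scope = config$selection_scope,
                            seed = derive_seed(config$seed,
                                               paste0("null_", run)))
      else NULL
      list(cv = cv, null = nul, error = NULL)
    }, error = function(e) list(cv = NULL, null = NULL,
                                error = conditionMessage(e)))
    res$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("run '%s': %s (%.1fs)", run,
                    if (is.null(res$error))
                      sprintf("F1 %.3f", metric_value(res$cv$metrics))
                    else paste("FAILED:", res$error),
                    res$elapsed))
    results[[run]] <- res
  }
  comparison <- do.call(rbind, lapply(names(results), function(run) {
    r <- results[[run]]
    if (!is.null(r$error))
      return(data.frame(run = run, f1 = NA_real_, lower = NA_real_,
                        upper = NA_real_, null_median = NA_real_,
                        error = r$error, stringsAsFactors = FALSE))
    tab <- r$cv$metrics$table
    f1 <- tab[tab$metric == "f1", ]
    data.frame(run = run, f1 = f1$value, lower = f1$lower, upper = f1$upper,
               null_median = if (is.null(r$null)) NA_real_ else r$null$median,
               error = NA_character_, stringsAsFactors = FALSE)
  }))
  out <- structure(list(results = results, comparison = comparison,
                        config = config),
                   class = "shm_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (run in names(results))
      if (is.null(results[[run]]$error))
        write_cv_result(results[[run]]$cv,
                        file.path(out_dir, paste0(run, "_cv.json")))
    snapshot <- config
    snapshot$runs <- lapply(snapshot$runs, function(s) s)
    jsonlite::write_json(list(comparison = comparison,
                              top_k = config$top_k,
                              selection_scope = config$selection_scope,
                              n_permutations = config$n_permutations,
                              seed = config$seed),
                         file.path(out_dir, "experiment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.shm_experiment <- function(x, ...) {
  cat("feature-set comparison (", length(x$results), " runs)\n", sep = "")
  print(x$comparison, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Train on one cohort and classify another
#'
#' Assembles the same feature family on both cohorts, then delegates to
#' [cross_cohort_transfer()].
#'
#' @param train,test [cohort()] objects.
#' @param run a single feature-family spec (named list entry as in
#'   [assemble_feature_table()]).
#' @param top_k screening size.
#' @param tuning elastic-net tuning grid.
#' @param seed master seed.
#' @return the [cross_cohort_transfer()] result.
#' @export
run_transfer <- function(train, test, run = list(family = "shm_5mer"),
                         top_k = 30L, tuning = NULL, seed = 1L) {
  spec <- stats::setNames(list(run), "transfer")
  tr <- assemble_feature_table(train, spec)
  te <- assemble_feature_table(test, spec)
  cross_cohort_transfer(tr, train$labels, te, test$labels,
                        top_k = top_k, tuning = tuning, seed = seed)
}
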