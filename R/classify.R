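# Elastic-net logistic classification with per-fold t-test screening,
# leave-one-out evaluation, shuffled-label nulls and cross-cohort transfer.

#' Rank and select features by two-sample Student's t-test
#'
#' Features are tested on the training rows with a pooled-variance t-test and
#' ranked by ascending p-value (ties broken by descending absolute t, then by
#' name). Constant features, and features with fewer than two non-missing
#' values in either class, are excluded before ranking. `top_k = 0` is a
#' sentinel meaning "no selection": all valid features are returned.
#'
#' @param features subjects x features numeric matrix.
#' @param labels `case`/`control` vector for the rows.
#' @param top_k number of features to keep (0 = all valid).
#' @return character vector of selected feature names.
#' @export
student_t_feature_selection <- function(features, labels, top_k = 30L) {
  stopifnot(is.matrix(features), top_k >= 0)
  is_case <- labels == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    # too few subjects for a t-test: screening is a no-op
    warning("fewer than two training subjects per class; skipping screening")
    keep <- colSums(!is.na(features)) > 0
    return(colnames(features)[keep])
  }
  res <- col_ttest(features, is_case)
  res <- res[!is.na(res$p), , drop = FALSE]
  ord <- order(res$p, -abs(res$t), res$feature)
  ranked <- res$feature[ord]
  if (top_k == 0L || top_k >= length(ranked)) {
    if (top_k > length(ranked))
      warning("only ", length(ranked), " valid features available")
    return(ranked)
  }
  ranked[seq_len(top_k)]
}

default_tuning <- function() {
  list(alpha = c(0, 0.25, 0.5, 0.75, 1), nlambda = 30L,
       lambda_min_ratio = 1e-4, inner_folds = 3L)
}

# Stratified fold ids for the inner CV, shuffled within class from `seed`.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Fit an elastic-net-regularised logistic regression classifier
#'
#' Minimises the penalised mean negative log-likelihood
#' `(1/n) sum nll + lambda * (alpha * |b|_1 + (1 - alpha)/2 * |b|_2^2)`
#' over a grid of mixing values `alpha` and a 30-point log-spaced lambda path
#' (via \pkg{glmnet}), choosing `(alpha, lambda)` by inner stratified
#' cross-validated deviance on the training rows only. Columns are
#' standardized (mean 0, sd 1) and missing values mean-imputed, with both
#' sets of parameters estimated from the training rows only so nothing leaks
#' from held-out data; all-missing or constant columns are dropped.
#'
#' @param features training matrix (subjects x features).
#' @param labels `case`/`control` vector; `case` is the positive class.
#' @param tuning list with `alpha`, `nlambda`, `lambda_min_ratio`,
#'   `inner_folds` (see `default_tuning()` values in the description).
#'   Supplying `lambda_fixed` (with a single `alpha`) bypasses the inner CV
#'   and fits at that penalty, e.g. to inspect the heavily-penalised limit.
#' @param seed integer seed controlling inner fold assignment.
#' @return object of class `shm_fit` with the selected `alpha`, `lambda`,
#'   `coefficients` (named, non-intercept), `intercept`, the imputation and
#'   standardization parameters, and the underlying glmnet fit.
#' @export
fit_elasticnet_logistic <- function(features, labels, tuning = NULL,
                                    seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) stop("training labels are single-class")
  tuning <- utils::modifyList(default_tuning(), tuning %||% list())
  y <- as.integer(labels == "case")

  impute_mean <- colMeans(features, na.rm = TRUE)
  usable <- !is.nan(impute_mean)
  X <- features[, usable, drop = FALSE]
  impute_mean <- impute_mean[usable]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- impute_mean[j]
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    X <- X[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]; impute_mean <- impute_mean[keep]
  }
  if (ncol(X) == 0L) stop("no usable (non-constant) features")
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  p_real <- ncol(X)
  if (p_real == 1L) {
    # glmnet requires >= 2 columns; pad with an all-zero dummy whose
    # coefficient is necessarily zero and is dropped below
    X <- cbind(X, `.dummy` = 0)
  }

  if (!is.null(tuning$lambda_fixed)) {
    # bypass the inner CV: fit at a fixed (alpha, lambda), entering along a
    # decreasing path for glmnet stability
    a <- tuning$alpha[1]
    lam <- tuning$lambda_fixed
    path <- sort(unique(lam * c(1000, 100, 10, 1)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = a,
                          lambda = path, standardize = FALSE,
                          thresh = 1e-10)
    beta <- as.numeric(stats::coef(fit, s = lam, exact = TRUE, x = X, y = y))
    chosen <- list(alpha = a, lambda = lam, fit = fit)
  } else {
    foldid <- stratified_folds(y, min(tuning$inner_folds, nrow(X)), seed)
    best <- NULL
    for (a in tuning$alpha) {
      cv <- tryCatch(suppressWarnings(glmnet::cv.glmnet(
        X, y, family = "binomial", alpha = a, foldid = foldid,
        nlambda = tuning$nlambda, lambda.min.ratio = tuning$lambda_min_ratio,
        standardize = FALSE, type.measure = "deviance")),
        error = function(e) NULL)
      if (is.null(cv)) next
      score <- min(cv$cvm)
      if (is.null(best) || score < best$score)
        best <- list(score = score, alpha = a, cv = cv)
    }
    if (is.null(best)) {
      # cohorts too small for inner CV (single-class folds): fall back to a
      # deterministic mid-path fit at alpha 0.5, or, when even a plain fit is
      # impossible (a class with fewer than two observations), to the
      # intercept-only model at class prevalence
      warning("inner cross-validation infeasible; using fallback fit")
      fit <- tryCatch(suppressWarnings(glmnet::glmnet(
        X, y, family = "binomial", alpha = 0.5, nlambda = tuning$nlambda,
        lambda.min.ratio = tuning$lambda_min_ratio, standardize = FALSE)),
        error = function(e) NULL)
      if (is.null(fit)) {
        prev <- min(max(mean(y), 1 / (length(y) + 1)),
                    length(y) / (length(y) + 1))
        beta <- c(log(prev / (1 - prev)), rep(0, ncol(X)))
        chosen <- list(alpha = 0.5, lambda = Inf, fit = NULL)
      } else {
        lam <- fit$lambda[ceiling(length(fit$lambda) / 2)]
        beta <- as.numeric(stats::coef(fit, s = lam))
        chosen <- list(alpha = 0.5, lambda = lam, fit = fit)
      }
    } else {
      beta <- as.numeric(stats::coef(best$cv, s = "lambda.min"))
      chosen <- list(alpha = best$alpha, lambda = best$cv$lambda.min,
                     fit = best$cv)
    }
  }
  names(beta) <- c("(Intercept)", colnames(X))
  beta <- beta[names(beta) != ".dummy"]
  real_names <- setdiff(colnames(X), ".dummy")
  structure(list(alpha = chosen$alpha,
                 lambda = chosen$lambda,
                 intercept = beta[1],
                 coefficients = beta[-1],
                 feature_names = real_names,
                 impute_mean = impute_mean,
                 center = ctr, scale = scl,
                 glmnet_fit = chosen$fit,
                 n = nrow(X)),
            class = "shm_fit")
}

#' @export
print.shm_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("elastic-net logistic fit: alpha ", x$alpha, ", lambda ",
      signif(x$lambda, 3), ", ", nz, " / ", length(x$coefficients),
      " non-zero coefficients\n", sep = "")
  invisible(x)
}

#' @export
coef.shm_fit <- function(object, ...) {
  c("(Intercept)" = unname(object$intercept), object$coefficients)
}

#' @export
predict.shm_fit <- function(object, newdata, type = c("response", "label"),
                            ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  X <- matrix(NA_real_, nrow = nrow(newdata), ncol = length(object$feature_names),
              dimnames = list(rownames(newdata), object$feature_names))
  shared <- intersect(colnames(newdata), object$feature_names)
  X[, shared] <- newdata[, shared]
  for (j in seq_len(ncol(X)))
    X[is.na(X[, j]), j] <- object$impute_mean[j]
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  eta <- drop(X %*% object$coefficients) + object$intercept
  p <- 1 / (1 + exp(-eta))
  if (type == "response") p else ifelse(p > 0.5, "case", "control")
}

#' Signed coefficient report for a fitted classifier
#'
#' @param fit an `shm_fit`.
#' @return data frame of non-zero coefficients with `direction`
#'   (`"favors case"` / `"favors control"`), ordered by absolute size.
#' @export
coefficient_report <- function(fit) {
  stopifnot(inherits(fit, "shm_fit"))
  b <- fit$coefficients[fit$coefficients != 0]
  out <- data.frame(feature = names(b), coefficient = unname(b),
                    direction = ifelse(b > 0, "favors case", "favors control"),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$coefficient)), , drop = FALSE]
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Classification metrics with binomial confidence intervals
#'
#' Computes F1 (`2TP / (2TP + FP + FN)`), accuracy, sensitivity and
#' specificity with `case` as the positive class, each with a 95%
#' Clopper-Pearson interval treating the metric as a proportion of
#' `n = length(labels)` subjects (an acknowledged approximation for F1 and
#' for the class-conditional rates). Metrics with a zero denominator are
#' reported as `NA` with `undefined = TRUE`, never as 0.
#'
#' @param predicted predicted labels (`case`/`control`).
#' @param labels true labels.
#' @param conf confidence level.
#' @return object of class `shm_metrics`: data frame `$table` with columns
#'   `metric`, `value`, `lower`, `upper`, `undefined`, plus `$confusion`
#'   (TP, FP, FN, TN).
#' @export
binary_metrics_with_ci <- function(predicted, labels, conf = 0.95) {
  if (length(predicted) == 0L) stop("empty prediction vector")
  stopifnot(length(predicted) == length(labels))
  n <- length(labels)
  tp <- sum(predicted == "case" & labels == "case")
  fp <- sum(predicted == "case" & labels == "control")
  fn <- sum(predicted == "control" & labels == "case")
  tn <- sum(predicted == "control" & labels == "control")
  vals <- c(
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn),
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
  tab <- data.frame(metric = names(vals), value = unname(vals),
                    lower = NA_real_, upper = NA_real_,
                    undefined = is.na(vals), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    if (tab$undefined[i]) next
    ci <- clopper_pearson(round(tab$value[i] * n), n, conf)
    tab$lower[i] <- ci["lower"]; tab$upper[i] <- ci["upper"]
  }
  structure(list(table = tab,
                 confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 n = n),
            class = "shm_metrics")
}

#' @export
print.shm_metrics <- function(x, ...) {
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    if (tab$undefined[i]) {
      cat(sprintf("%-12s undefined\n", tab$metric[i]))
    } else {
      cat(sprintf("%-12s %.3f  [%.3f, %.3f]\n", tab$metric[i], tab$value[i],
                  tab$lower[i], tab$upper[i]))
    }
  }
  invisible(x)
}

metric_value <- function(metrics, which = "f1") {
  metrics$table$value[metrics$table$metric == which]
}

#' Leave-one-out cross-validation of the classification pipeline
#'
#' For each held-out subject, feature screening
#' ([student_t_feature_selection()]), imputation, standardization and the
#' elastic-net fit are recomputed on the remaining subjects only
#' (`selection_scope = "per_fold"`, the leakage-free default); with
#' `"global"` scope the screening is done once on all subjects and shared
#' across folds (a variant that deliberately lets the held-out subject
#' influence feature choice). The held-out subject is predicted `case` when
#' its predicted probability exceeds 0.5. Metrics are pooled over all
#' subjects.
#'
#' @param features subjects x features matrix.
#' @param labels named or aligned `case`/`control` vector.
#' @param top_k screening size (0 = no selection).
#' @param tuning see [fit_elasticnet_logistic()].
#' @param selection_scope `"per_fold"` or `"global"`.
#' @param seed master seed; per-fold seeds are derived deterministically.
#' @return object of class `shm_cv`: `$predictions` (per-subject truth,
#'   predicted label and probability), `$metrics` (an `shm_metrics`),
#'   `$selected` (per-fold selected features).
#' @export
loo_cross_validate <- function(features, labels, top_k = 30L, tuning = NULL,
                               selection_scope = c("per_fold", "global"),
                               seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  selection_scope <- match.arg(selection_scope)
  n <- nrow(features)
  if (n < 4L) stop("leave-one-out evaluation needs at least 4 subjects")
  subjects <- rownames(features)
  if (is.null(subjects)) subjects <- paste0("s", seq_len(n))
  global_sel <- if (selection_scope == "global")
    student_t_feature_selection(features, labels, top_k) else NULL
  prob <- numeric(n)
  selected <- vector("list", n)
  fold_coefs <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- if (is.null(global_sel))
      student_t_feature_selection(features[tr, , drop = FALSE], labels[tr],
                                  top_k)
    else global_sel
    fit <- fit_elasticnet_logistic(features[tr, sel, drop = FALSE],
                                   labels[tr], tuning = tuning,
                                   seed = derive_seed(seed, paste0("fold", i)))
    prob[i] <- predict(fit, features[i, sel, drop = FALSE], type = "response")
    selected[[i]] <- sel
    fold_coefs[[i]] <- stats::coef(fit)
  }
  pred <- ifelse(prob > 0.5, "case", "control")
  metrics <- binary_metrics_with_ci(pred, labels)
  structure(list(predictions = data.frame(subject_id = subjects,
                                          label = unname(labels),
                                          predicted = pred,
                                          probability = prob,
                                          stringsAsFactors = FALSE),
                 metrics = metrics,
                 selected = selected,
                 fold_coefs = fold_coefs,
                 selection_scope = selection_scope,
                 top_k = top_k, seed = seed),
            class = "shm_cv")
}

#' @export
print.shm_cv <- function(x, ...) {
  cat("leave-one-out cross-validation (", nrow(x$predictions), " subjects, ",
      x$selection_scope, " selection, top_k = ", x$top_k, ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
summary.shm_cv <- function(object, ...) {
  print(object)
  freq <- sort(table(unlist(object$selected)), decreasing = TRUE)
  cat("most frequently selected features:\n")
  print(utils::head(freq, 10))
  invisible(object)
}

#' Shuffled-label null distribution of the leave-one-out F1 score
#'
#' Re-runs the full leave-one-out pipeline on uniformly permuted labels
#' (class sizes preserved); an informative classifier should beat this null,
#' whose F1 median is expected near 0.5 for balanced cohorts.
#'
#' @inheritParams loo_cross_validate
#' @param n_permutations number of label permutations.
#' @return object of class `shm_null`: `$f1` (per-permutation F1),
#'   `$median`, and the permutation seeds used.
#' @export
shuffled_label_null <- function(features, labels, n_permutations = 25L,
                                top_k = 30L, tuning = NULL,
                                selection_scope = "per_fold", seed = 1L) {
  stopifnot(n_permutations >= 1L)
  f1 <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm_seed <- derive_seed(seed, paste0("perm", b))
    perm <- with_seed(perm_seed, sample(labels))
    cv <- loo_cross_validate(features, perm, top_k = top_k, tuning = tuning,
                             selection_scope = selection_scope,
                             seed = derive_seed(seed, paste0("permfit", b)))
    f1[b] <- metric_value(cv$metrics, "f1")
  }
  structure(list(f1 = f1, median = stats::median(f1, na.rm = TRUE),
                 n_permutations = n_permutations, seed = seed),
            class = "shm_null")
}

#' @export
print.shm_null <- function(x, ...) {
  cat("shuffled-label null: ", x$n_permutations, " permutations, median F1 ",
      sprintf("%.3f", x$median), " (90% range ",
      sprintf("%.3f-%.3f", stats::quantile(x$f1, 0.05, na.rm = TRUE),
              stats::quantile(x$f1, 0.95, na.rm = TRUE)), ")\n", sep = "")
  invisible(x)
}

#' Train on one cohort, evaluate on another
#'
#' Feature screening, imputation and standardization are computed on the
#' training cohort only; the model is then applied to every test subject
#' over the shared feature space (features absent from the test table are
#' imputed from training means).
#'
#' @param train_features,train_labels training cohort table and labels.
#' @param test_features,test_labels test cohort table and labels.
#' @inheritParams loo_cross_validate
#' @return list with `metrics` (an `shm_metrics`), `predictions`,
#'   `coefficients` (a [coefficient_report()]), and the fitted model.
#' @export
cross_cohort_transfer <- function(train_features, train_labels,
                                  test_features, test_labels,
                                  top_k = 30L, tuning = NULL, seed = 1L) {
  shared <- intersect(colnames(train_features), colnames(test_features))
  if (length(shared) == 0L)
    stop("training and test cohorts share no features")
  sel <- student_t_feature_selection(train_features, train_labels, top_k)
  sel <- intersect(sel, shared)
  if (length(sel) == 0L)
    stop("no screened training feature exists in the test cohort")
  fit <- fit_elasticnet_logistic(train_features[, sel, drop = FALSE],
                                 train_labels, tuning = tuning, seed = seed)
  prob <- predict(fit, test_features[, sel, drop = FALSE], type = "response")
  pred <- ifelse(prob > 0.5, "case", "control")
  list(metrics = binary_metrics_with_ci(pred, test_labels),
       predictions = data.frame(subject_id = rownames(test_features),
                                label = unname(test_labels),
                                predicted = pred, probability = prob,
                                stringsAsFactors = FALSE),
       coefficients = coefficient_report(fit),
       fit = fit)
}

#' Export a cross-validation result as JSON
#'
#' @param cv an `shm_cv`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  out <- list(predictions = cv$predictions,
              metrics = cv$metrics$table,
              confusion = as.list(cv$metrics$confusion),
              selection_scope = cv$selection_scope,
              top_k = cv$top_k,
              selected = cv$selected)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
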