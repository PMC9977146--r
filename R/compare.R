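# Cohort-level comparison of per-subject SHM models.

# Vectorised two-sample pooled-variance (Student) t-test over the columns of
# a subjects x features matrix. Returns per-feature t, p, means and the
# per-class counts of non-missing values.
col_ttest <- function(X, is_case) {
  X1 <- X[is_case, , drop = FALSE]
  X0 <- X[!is_case, , drop = FALSE]
  n1 <- colSums(!is.na(X1)); n0 <- colSums(!is.na(X0))
  m1 <- colMeans(X1, na.rm = TRUE); m0 <- colMeans(X0, na.rm = TRUE)
  ss1 <- colSums(sweep(X1, 2, m1)^2, na.rm = TRUE)
  ss0 <- colSums(sweep(X0, 2, m0)^2, na.rm = TRUE)
  df <- n1 + n0 - 2
  sp2 <- ifelse(df > 0, (ss1 + ss0) / df, NA_real_)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(t), df)
  valid <- n1 >= 2 & n0 >= 2 & is.finite(t)
  t[!valid] <- NA_real_; p[!valid] <- NA_real_
  data.frame(feature = colnames(X), t = unname(t), p = unname(p),
             mean_case = unname(m1), mean_control = unname(m0),
             n_case = unname(n1), n_control = unname(n0),
             stringsAsFactors = FALSE)
}

#' Compare per-subject model features between case and control groups
#'
#' Runs a two-sample Student's (pooled-variance) t-test per feature and
#' computes, separately within each hotspot motif class, the Spearman
#' correlation between the control-group and case-group feature means.
#' Features missing in more than half of the subjects, or constant, are
#' dropped and their count reported in attribute `n_dropped`.
#'
#' @param features subjects x features numeric matrix (e.g. rows of
#'   [flatten_model_features()] values aligned across subjects, or an
#'   [assemble_feature_table()] result).
#' @param labels named or positional `case`/`control` vector for the rows.
#' @return list with `table` (per-feature data frame: means, t, p, motif
#'   class) and `spearman` (named correlation per motif class).
#' @export
compare_cohort_models <- function(features, labels) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  is_case <- labels == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("need at least two subjects per class")
  missing_frac <- colMeans(is.na(features))
  keep <- missing_frac <= 0.5
  res <- col_ttest(features[, keep, drop = FALSE], is_case)
  n_dropped <- sum(!keep) + sum(is.na(res$p))
  res <- res[!is.na(res$p), , drop = FALSE]
  # motif class of the 5-mer embedded in the feature name ("mut|AACGT", ...)
  fm <- sub("^[a-z]+\\|([ACGT]{5}).*$", "\\1", res$feature)
  res$motif <- classify_hotspot(fm)
  sp <- vapply(split(res, res$motif), function(d)
    stats::cor(d$mean_control, d$mean_case, method = "spearman"),
    numeric(1))
  structure(list(table = res, spearman = sp), n_dropped = n_dropped,
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("cohort model comparison: ", nrow(x$table), " features\n", sep = "")
  cat("Spearman rho of group means by motif class:\n")
  print(round(x$spearman, 3))
  top <- utils::head(x$table[order(x$table$p), ], 5)
  cat("top differing features:\n")
  print(top[, c("feature", "mean_control", "mean_case", "p", "motif")],
        row.names = FALSE)
  invisible(x)
}

#' Case/control mutability ratios for generalized 3-mer motifs
#'
#' For each generalized motif (`AAN`, `TAN`, `NTT`, `NTA` by default, where
#' `N` is a wildcard), computes the ratio of the case-group mean to the
#' control-group mean 3-mer mutability for every member 3-mer. Ratios above 1
#' indicate higher relative mutability in cases. Members with a zero
#' control mean are excluded and counted in attribute `n_excluded`.
#'
#' @param models named list of [collapse_to_3mer()] results, one per subject.
#' @param labels `case`/`control` vector aligned with `models`.
#' @param motifs character vector of generalized 3-mer motifs over
#'   `A/C/G/T/N`.
#' @return named list of numeric ratio vectors, one per motif.
#' @export
motif_ratio_summary <- function(models, labels,
                                motifs = c("AAN", "TAN", "NTT", "NTA")) {
  stopifnot(length(models) == length(labels))
  mat <- do.call(rbind, lapply(models, function(m) m$mutability))
  is_case <- labels == "case"
  mean_case <- colMeans(mat[is_case, , drop = FALSE], na.rm = TRUE)
  mean_ctrl <- colMeans(mat[!is_case, , drop = FALSE], na.rm = TRUE)
  tm <- colnames(mat)
  n_excluded <- 0L
  out <- list()
  for (mot in motifs) {
    pat <- paste0("^", gsub("N", "[ACGT]", mot), "$")
    members <- tm[grepl(pat, tm)]
    ok <- members[!is.na(mean_ctrl[members]) & mean_ctrl[members] > 0 &
                    !is.na(mean_case[members])]
    n_excluded <- n_excluded + length(members) - length(ok)
    out[[mot]] <- stats::setNames(mean_case[ok] / mean_ctrl[ok], ok)
  }
  structure(out, n_excluded = n_excluded)
}
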