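toy_table <- function(n = 20, p = 51, seed = 7, sep = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  labels <- rep(c("case", "control"), length.out = n)
  X[labels == "case", 1] <- X[labels == "case", 1] + sep
  list(X = X, labels = labels)
}

test_that("t-test screening finds a planted feature and honours the sentinel", {
  d <- toy_table()
  sel <- student_t_feature_selection(d$X, d$labels, top_k = 1)
  expect_equal(sel, "f1")
  # cross-check the ranking against stats::t.test on every column
  p_ref <- apply(d$X, 2, function(col)
    stats::t.test(col[d$labels == "case"], col[d$labels == "control"],
                  var.equal = TRUE)$p.value)
  expect_equal(sel, names(which.min(p_ref)))

  all_sel <- student_t_feature_selection(d$X, d$labels, top_k = 0)
  expect_equal(sort(all_sel), sort(colnames(d$X)))

  Xc <- d$X; Xc[, 2] <- 5
  expect_false("f2" %in% student_t_feature_selection(Xc, d$labels, top_k = 0))
})

test_that("vectorised pooled t-test matches stats::t.test", {
  set.seed(21)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[3, 2] <- NA
  is_case <- rep(c(TRUE, FALSE), 6)
  res <- shmclass:::col_ttest(X, is_case)
  for (j in 1:5) {
    ref <- stats::t.test(X[is_case, j], X[!is_case, j], var.equal = TRUE)
    expect_equal(res$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-12)
  }
})

test_that("separable data are fit to perfect training accuracy", {
  d <- toy_table(sep = 6)
  fit <- fit_elasticnet_logistic(d$X[, 1:2], d$labels, seed = 3)
  pred <- predict(fit, d$X[, 1:2], type = "label")
  expect_equal(unname(pred), d$labels)
})

test_that("an overwhelming penalty collapses to the intercept-only model", {
  d <- toy_table(n = 24)
  prev <- mean(d$labels == "case")
  fit <- fit_elasticnet_logistic(d$X, d$labels,
                                 tuning = list(alpha = 1, lambda_fixed = 1e3),
                                 seed = 1)
  expect_true(all(fit$coefficients == 0))
  expect_equal(unname(fit$intercept), log(prev / (1 - prev)),
               tolerance = 1e-6)
})

test_that("lasso coefficients match an independent proximal-gradient oracle", {
  set.seed(11)
  X <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- c(1, 0, 1, 0, 1, 0)
  lambda <- 0.05
  for (alpha in c(1, 0.5)) {
    g <- suppressWarnings(
      glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                     lambda = sort(lambda * c(100, 10, 1), decreasing = TRUE),
                     standardize = FALSE, thresh = 1e-12))
    got <- as.numeric(stats::coef(g, s = lambda, exact = TRUE, x = X, y = y))
    ref <- prox_enet_logistic(X, y, lambda, alpha)
    expect_equal(got, ref, tolerance = 1e-4)
  }
})

test_that("penalised objective never exceeds the null-model objective", {
  d <- toy_table(n = 16, p = 6, sep = 1.5)
  fit <- fit_elasticnet_logistic(d$X, d$labels, seed = 5)
  y <- as.numeric(d$labels == "case")
  Xs <- scale(d$X, center = fit$center, scale = fit$scale)
  obj <- function(b0, b) {
    eta <- b0 + drop(Xs[, names(b), drop = FALSE] %*% b)
    mean(log(1 + exp(eta)) - y * eta) +
      fit$lambda * (fit$alpha * sum(abs(b)) +
                      (1 - fit$alpha) / 2 * sum(b^2))
  }
  b_null <- stats::setNames(rep(0, ncol(Xs)), colnames(Xs))
  expect_lte(obj(fit$intercept, fit$coefficients),
             obj(log(mean(y) / (1 - mean(y))), b_null) + 1e-8)
})

test_that("confusion metrics and Clopper-Pearson intervals are exact", {
  pred <- c(rep("case", 3), "case", "control", rep("control", 5))
  truth <- c(rep("case", 3), "control", "case", rep("control", 5))
  m <- binary_metrics_with_ci(pred, truth)
  expect_equal(unname(m$confusion), c(3, 1, 1, 5))
  tab <- m$table
  expect_equal(tab$value[tab$metric == "f1"], 0.75)
  expect_equal(tab$value[tab$metric == "accuracy"], 0.8)
  expect_equal(tab$value[tab$metric == "sensitivity"], 0.75)
  expect_equal(tab$value[tab$metric == "specificity"], 5 / 6)

  perfect <- binary_metrics_with_ci(rep(c("case", "control"), 5),
                                    rep(c("case", "control"), 5))
  ptab <- perfect$table
  expect_true(all(ptab$value == 1))
  expect_equal(ptab$lower[ptab$metric == "accuracy"], 0.025^(1 / 10),
               tolerance = 1e-9)
  expect_equal(ptab$lower, rep(0.6915029, 4), tolerance = 1e-6)

  none <- binary_metrics_with_ci(rep("control", 4), rep("control", 4))
  ntab <- none$table
  expect_true(ntab$undefined[ntab$metric == "f1"])
  expect_true(ntab$undefined[ntab$metric == "sensitivity"])
  expect_false(is.na(ntab$value[ntab$metric == "accuracy"]))
  expect_error(binary_metrics_with_ci(character(0), character(0)), "empty")
})

test_that("metrics are recomputable from the stored confusion counts", {
  d <- toy_table(n = 12, p = 8, sep = 2)
  cv <- loo_cross_validate(d$X, d$labels, top_k = 3, seed = 2)
  cc <- cv$metrics$confusion
  tab <- cv$metrics$table
  expect_equal(tab$value[tab$metric == "f1"],
               2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"]),
               ignore_attr = TRUE)
  ref <- binary_metrics_with_ci(cv$predictions$predicted,
                                cv$predictions$label)
  expect_equal(cv$metrics$table, ref$table)
})

test_that("leave-one-out runs on a minimal 2+2 cohort", {
  set.seed(8)
  X <- matrix(rnorm(16), 4, 4, dimnames = list(paste0("s", 1:4),
                                               paste0("f", 1:4)))
  labels <- c("case", "case", "control", "control")
  cv <- suppressWarnings(loo_cross_validate(X, labels, top_k = 2, seed = 4))
  expect_equal(nrow(cv$predictions), 4)
  expect_true(all(cv$predictions$predicted %in% c("case", "control")))
})

test_that("per-fold scope shields the fold model from the held-out subject", {
  d <- toy_table(n = 14, p = 10, sep = 2)
  cv_a <- loo_cross_validate(d$X, d$labels, top_k = 4, seed = 9)
  for (i in c(1, 7)) {
    B <- d$X
    B[i, ] <- B[i, ] + 100   # perturb only the held-out subject
    cv_b <- loo_cross_validate(B, d$labels, top_k = 4, seed = 9)
    expect_identical(cv_a$selected[[i]], cv_b$selected[[i]])
    expect_equal(cv_a$fold_coefs[[i]], cv_b$fold_coefs[[i]],
                 tolerance = 1e-12)
  }
})

test_that("global scope lets the held-out subject influence selection", {
  set.seed(31)
  X <- matrix(rnorm(14 * 30), 14, 30,
              dimnames = list(paste0("s", 1:14), paste0("f", 1:30)))
  labels <- rep(c("case", "control"), 7)
  sel_a <- student_t_feature_selection(X, labels, top_k = 3)
  B <- X; B[1, ] <- B[1, ] + 50
  sel_b <- student_t_feature_selection(B, labels, top_k = 3)
  expect_false(identical(sel_a, sel_b))
})

test_that("shuffled-label permutations preserve class sizes and reproduce", {
  d <- toy_table(n = 10, p = 6, sep = 0)
  nul <- shuffled_label_null(d$X, d$labels, n_permutations = 2, top_k = 2,
                             seed = 12)
  expect_length(nul$f1, 2)
  nul2 <- shuffled_label_null(d$X, d$labels, n_permutations = 2, top_k = 2,
                              seed = 12)
  expect_identical(nul$f1, nul2$f1)
  perm <- shmclass:::with_seed(derive_seed(12, "perm1"), sample(d$labels))
  expect_equal(sort(as.vector(table(perm))), sort(as.vector(table(d$labels))))
  expect_setequal(names(table(perm)), names(table(d$labels)))
  one <- shuffled_label_null(d$X, d$labels, n_permutations = 1, top_k = 2,
                             seed = 3)
  expect_length(one$f1, 1)
})

test_that("cross-cohort transfer requires shared features and recovers signal", {
  d <- toy_table(n = 20, sep = 6)
  res <- cross_cohort_transfer(d$X, d$labels, d$X, d$labels, top_k = 5,
                               seed = 2)
  expect_equal(metric_value <- res$metrics$table$value[
    res$metrics$table$metric == "accuracy"], 1.0)
  expect_true(all(res$coefficients$direction %in%
                    c("favors case", "favors control")))

  other <- d$X; colnames(other) <- paste0("g", seq_len(ncol(other)))
  expect_error(cross_cohort_transfer(d$X, d$labels, other, d$labels),
               "share no features")

  test_small <- d$X[, 1:10]
  res2 <- cross_cohort_transfer(d$X, d$labels, test_small, d$labels,
                                top_k = 5, seed = 2)
  expect_equal(nrow(res2$predictions), 20)
})
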