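test_that("a single informative mutation yields a one-hot targeting model", {
  rec <- make_records(1, germline_alignment = "TTAAT",
                      sequence_alignment = "TTGAT")
  m <- estimate_targeting_model(repertoire(rec, "s"), min_background = 1)
  expect_false(m$degenerate)
  expect_equal(unname(m$mutability["TTAAT"]), 1)
  expect_equal(sum(m$mutability, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(unname(m$substitution["TTAAT", "G"]), 1)
  expect_equal(unname(m$targeting["TTAAT", "G"]), 1)
  expect_equal(unname(m$background_count["TTAAT"]), 1)
  expect_equal(unname(m$mutation_count["TTAAT"]), 1)
})

test_that("a mutation-free repertoire produces a degenerate model", {
  rec <- make_records(3, germline_alignment = "ATGCATGCATGC")
  m <- estimate_targeting_model(repertoire(rec, "s"))
  expect_true(m$degenerate)
  expect_true(all(is.na(m$mutability) | m$mutability == 0))
  expect_error(collapse_to_3mer(m), "degenerate")
})

test_that("counts match the brute-force nested-loop oracle exactly", {
  sim <- small_sim_cohort()
  r <- sim$cohort$repertoires[[1]]
  r <- repertoire(r$records[1:40, ], "sub", validate = FALSE)
  for (opts in list(list(syn = FALSE, mask = NULL),
                    list(syn = TRUE, mask = NULL),
                    list(syn = FALSE, mask = "cdr"))) {
    est <- estimate_targeting_model(r, synonymous_only = opts$syn,
                                    region_mask = opts$mask,
                                    min_background = 1)
    orc <- oracle_counts(r, synonymous_only = opts$syn,
                         region_mask = opts$mask)
    for (w in ls(orc$bg))
      expect_equal(unname(est$background_count[w]), orc$bg[[w]],
                   info = paste("bg", w))
    expect_equal(sum(est$background_count), sum(unlist(as.list(orc$bg))))
    for (w in ls(orc$mut))
      expect_equal(unname(est$mutation_count[w]), orc$mut[[w]],
                   info = paste("mut", w))
    expect_equal(sum(est$mutation_count), sum(unlist(as.list(orc$mut))))
  }
})

test_that("model normalization invariants hold on every estimation path", {
  sim <- small_sim_cohort()
  r <- sim$cohort$repertoires[[2]]
  for (m in list(estimate_targeting_model(r),
                 estimate_targeting_model(r, synonymous_only = TRUE),
                 estimate_targeting_model(r, region_mask = "cdr",
                                          min_background = 3),
                 estimate_targeting_model(r, representatives_only = TRUE))) {
    expect_equal(sum(m$mutability, na.rm = TRUE), 1, tolerance = 1e-9)
    rs <- rowSums(m$substitution, na.rm = TRUE)
    expect_true(all(abs(rs[m$mutation_count > 0] - 1) < 1e-9))
    expect_true(all(m$background_count >= 0 & m$mutation_count >= 0))
    expect_equal(m$targeting, m$substitution * m$mutability)
  }
})

test_that("3-mer collapse is a background-weighted mean of 5-mer values", {
  mut <- c(AACGA = 0.2, CACGC = 0.4, ATTTA = 0.3, GTTTC = 0.1)
  bg <- stats::setNames(rep(0, 1024), shmclass:::all_fivemers())
  bg[names(mut)] <- c(100, 300, 200, 200)
  m <- targeting_model(mut, background_count = bg)
  m3 <- collapse_to_3mer(m)
  # inner 3-mers: ACG from the first two (weighted mean .35 pre-normalisation),
  # TTT from the last two (weighted mean .2); ratio survives renormalisation
  expect_equal(unname(m3$mutability["ACG"] / m3$mutability["TTT"]), 0.35 / 0.2)
  expect_equal(sum(m3$mutability, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(sum(!is.na(m3$mutability)), 2)
})

test_that("collapse of equal-mutability constituents is flat", {
  fm <- shmclass:::all_fivemers()
  inner <- substr(fm, 2, 4)
  mut <- stats::setNames(rep(1, sum(inner == "ACG")), fm[inner == "ACG"])
  m3 <- collapse_to_3mer(targeting_model(mut))
  expect_equal(unname(m3$mutability["ACG"]), 1)
})

test_that("collapse-then-normalize equals normalize-then-collapse", {
  sim <- small_sim_cohort()
  m <- estimate_targeting_model(sim$cohort$repertoires[[3]])
  m_scaled <- m
  m_scaled$mutability <- m$mutability * 7.3   # global rescale
  a <- collapse_to_3mer(m)$mutability
  b <- collapse_to_3mer(m_scaled)$mutability
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("flattened feature vectors have the documented names and sizes", {
  sim <- small_sim_cohort()
  m <- estimate_targeting_model(sim$cohort$repertoires[[1]])
  f_mut <- flatten_model_features(m, parts = "mutability")
  expect_equal(length(f_mut), 1024)
  expect_true(all(grepl("^mut\\|[ACGT]{5}$", names(f_mut))))
  f_all <- flatten_model_features(m)
  expect_equal(length(f_all), 1024 + 3072 + 3072)
  expect_true(any(grepl("^sub\\|[ACGT]{5}>[ACGT]$", names(f_all))))
  f_wa <- flatten_model_features(m, parts = "mutability",
                                 motif_filter = "wa_tw")
  expect_equal(length(f_wa), 256)
  expect_true(all(classify_hotspot(sub("mut\\|", "", names(f_wa))) == "wa_tw"))
  expect_error(flatten_model_features(m, parts = character(0)), "parts")
})

test_that("targeting model TSV export round-trips", {
  sim <- small_sim_cohort()
  m <- estimate_targeting_model(sim$cohort$repertoires[[1]])
  path <- tempfile(fileext = ".tsv")
  write_targeting_model(m, path)
  m2 <- read_targeting_model(path)
  expect_equal(m2$mutability, m$mutability, tolerance = 1e-12)
  expect_equal(m2$background_count, m$background_count)
})

test_that("cohort model comparison flags shifted features and group structure", {
  set.seed(5)
  fm <- shmclass:::all_fivemers()
  feats <- matrix(rnorm(20 * 60), nrow = 20,
                  dimnames = list(paste0("s", 1:20),
                                  paste0("mut|", fm[1:60])))
  labels <- rep(c("case", "control"), each = 10)
  same <- compare_cohort_models(feats, labels)
  expect_true(all(abs(same$spearman) <= 1))

  shifted <- feats
  shifted[labels == "case", 7] <- shifted[labels == "case", 7] + 5
  cmp <- compare_cohort_models(shifted, labels)
  expect_equal(cmp$table$feature[which.min(cmp$table$p)],
               colnames(feats)[7])

  const <- feats; const[, 3] <- 1
  cmp2 <- compare_cohort_models(const, labels)
  expect_false(colnames(feats)[3] %in% cmp2$table$feature)
})

test_that("identical case/control tables give unit ratios and rho 1", {
  feats <- matrix(rep(runif(40), each = 8), nrow = 8,
                  dimnames = list(paste0("s", 1:8),
                                  paste0("mut|", shmclass:::all_fivemers()[1:40])))
  feats <- feats + 1e-3
  labels <- rep(c("case", "control"), 4)
  cmp <- compare_cohort_models(feats, labels)
  expect_equal(nrow(cmp$table), 0)  # constant features all dropped
  feats2 <- feats + matrix(rnorm(320, sd = 1e-6), nrow = 8)
  cmp2 <- compare_cohort_models(feats2, labels)
  expect_true(all(cmp2$spearman > 0.99))
})

test_that("generalized motif ratios behave on identical cohorts", {
  sim <- small_sim_cohort()
  m3 <- collapse_to_3mer(estimate_targeting_model(sim$cohort$repertoires[[1]]))
  models <- list(m3, m3, m3, m3)
  ratios <- motif_ratio_summary(models, c("case", "case", "control", "control"))
  expect_equal(sort(names(ratios)), sort(c("AAN", "TAN", "NTT", "NTA")))
  expect_true(all(abs(unlist(ratios) - 1) < 1e-12))
  expect_equal(length(ratios$AAN), 4)
  expect_equal(sort(names(ratios$AAN)), c("AAA", "AAC", "AAG", "AAT"))
})
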