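usage_fixture <- function() {
  # three clones: IGHV1-2 (sizes 3 and 1) and IGHV3-23 (size 1), junctions
  # chosen so default clone partitioning recovers exactly these clones
  df <- make_records(5, v_call = c(rep("IGHV1-2*02", 4), "IGHV3-23*01"),
                     j_call = c(rep("IGHJ4*01", 4), "IGHJ6*01"))
  df$junction <- c(rep(strrep("A", 12), 3), strrep("C", 12), strrep("G", 12))
  repertoire(df, "s", validate = FALSE)
}

test_that("V gene usage respects weighting and aggregation level", {
  r <- usage_fixture()
  cl <- partition_clones(r)
  by_clone <- v_gene_usage(r, weighting = "clone", clones = cl)
  expect_equal(unname(by_clone[c("IGHV1-2", "IGHV3-23")]), c(2 / 3, 1 / 3))
  by_fam <- v_gene_usage(r, level = "family", weighting = "clone", clones = cl)
  expect_equal(unname(by_fam[c("IGHV1", "IGHV3")]), c(2 / 3, 1 / 3))
  by_seq <- v_gene_usage(r, weighting = "sequence")
  expect_equal(unname(by_seq[c("IGHV1-2", "IGHV3-23")]), c(4 / 5, 1 / 5))
  expect_equal(sum(by_seq), 1, tolerance = 1e-9)
})

test_that("V-J pair usage is keyed by pairs and sums to one", {
  df <- make_records(1, v_call = "IGHV1-2*02", j_call = "IGHJ4*01")
  one <- vj_gene_usage(repertoire(df, "s", validate = FALSE))
  expect_equal(unname(one["IGHV1-2|IGHJ4"]), 1.0)

  df2 <- make_records(2, v_call = "IGHV1-2*02",
                      j_call = c("IGHJ4*01", "IGHJ6*01"))
  df2$junction <- c(strrep("A", 12), strrep("C", 15))
  two <- vj_gene_usage(repertoire(df2, "s", validate = FALSE))
  expect_equal(unname(two), c(0.5, 0.5))

  sim <- small_sim_cohort()
  u <- vj_gene_usage(sim$cohort$repertoires[[1]])
  expect_equal(sum(u), 1, tolerance = 1e-9)
})

test_that("CDR3 k-mers are counted on the flank-trimmed junction", {
  df <- make_records(1)
  df$junction_aa <- "CARDYW"
  km <- cdr3_kmer_frequencies(repertoire(df, "s", validate = FALSE), k = 3)
  expect_equal(sort(names(km)), c("ARD", "RDY"))
  expect_equal(unname(km), c(0.5, 0.5))

  df2 <- df; df2$junction_aa <- "CAW"   # CDR3 length 1 < k
  expect_error(cdr3_kmer_frequencies(repertoire(df2, "s", validate = FALSE)),
               "no CDR3")
  sim <- small_sim_cohort()
  expect_equal(sum(cdr3_kmer_frequencies(sim$cohort$repertoires[[2]])), 1,
               tolerance = 1e-9)
})

test_that("V-J-length cluster features keep the inclusive union of large triples", {
  base <- make_records(1)
  mk <- function(id, n_major, n_minor) {
    rows <- base[rep(1, n_major + n_minor), ]
    rows$sequence_id <- sprintf("%s_%04d", id, seq_len(n_major + n_minor))
    rows$junction_aa <- c(rep("CARDYW", n_major), rep("CTTTTTTTW", n_minor))
    repertoire(rows, id, validate = FALSE)
  }
  co <- cohort(list(mk("a", 999, 1), mk("b", 1000, 0)),
               c(a = "case", b = "control"))
  feats <- vjl_cluster_features(co, min_freq = 0.001)
  # the rare triple sits exactly at 1/1000 in subject a: retained (inclusive)
  rare <- grep("\\|7$", colnames(feats), value = TRUE)
  expect_length(rare, 1)
  expect_equal(unname(feats["a", rare]), 0.001)
  expect_equal(unname(feats["b", rare]), 0)   # union column valued everywhere
  feats2 <- vjl_cluster_features(co, min_freq = 0.0011)
  expect_length(grep("\\|7$", colnames(feats2)), 0)
})

test_that("CDR3 identity clustering joins at the inclusive identity bound", {
  base <- make_records(1)
  mk <- function(id, cdr3s) {
    rows <- base[rep(1, length(cdr3s)), ]
    rows$sequence_id <- paste0(id, seq_along(cdr3s))
    rows$junction_aa <- paste0("C", cdr3s, "W")
    repertoire(rows, id, validate = FALSE)
  }
  s20a <- strrep("A", 20)
  s20b <- paste0(strrep("G", 3), strrep("A", 17))     # identity 17/20 = 0.85
  s10a <- strrep("A", 10)
  s10b <- paste0("GG", strrep("A", 8))                # identity 0.8 < 0.85
  co <- cohort(list(mk("a", c(s20a, s10a)), mk("b", c(s20b, s10b, s20a))),
               c(a = "case", b = "control"))
  feats <- cdr3_identity_cluster_features(co, identity = 0.85, min_freq = 0)
  cl20 <- grep("\\|20\\|", colnames(feats), value = TRUE)
  expect_length(cl20, 1)               # the two length-20 CDR3s merge
  expect_true(feats["a", cl20] > 0 & feats["b", cl20] > 0)
  cl10 <- grep("\\|10\\|", colnames(feats), value = TRUE)
  expect_length(cl10, 2)               # 0.8 identity stays apart
})

test_that("Hill numbers follow the closed form and vegan agrees", {
  expect_equal(hill_diversity(rep(0.25, 4), 2)$D, 4.0)
  expect_equal(hill_diversity(c(0.7, 0.3), 2)$D, 1 / 0.58, tolerance = 1e-9)
  d <- hill_diversity(c(0.5, 0.2, 0.2, 0.1), c(1 - 1e-4, 1, 1 + 1e-4))$D
  expect_true(abs(d[2] - d[1]) < 1e-3 && abs(d[3] - d[2]) < 1e-3)
  expect_error(hill_diversity(c(0.5, 0.5), -1), "negative")

  skip_if_not_installed("vegan")
  set.seed(99)
  for (i in 1:5) {
    p <- stats::runif(sample(3:12, 1)); p <- p / sum(p)
    q <- c(0, 0.5, 1, 2, 4)
    ours <- hill_diversity(p, q)$D
    ref <- as.numeric(vegan::renyi(p, scales = q, hill = TRUE))
    expect_equal(ours, ref, tolerance = 1e-8)
    expect_true(all(diff(ours) <= 1e-12))  # non-increasing in q
  }
})

test_that("repertoire percentiles use linear interpolation", {
  df <- make_records(10)
  # CDR3 lengths 10..19 -> junction_aa lengths 12..21
  df$junction_aa <- vapply(10:19, function(L)
    paste0("C", strrep("A", L), "W"), character(1))
  pct <- repertoire_percentiles(repertoire(df, "s", validate = FALSE))
  expect_equal(unname(pct$cdr3_length["50%"]), 14.5)
  expect_equal(unname(pct$germline_identity), c(1, 1, 1))

  df2 <- make_records(3)
  pct2 <- repertoire_percentiles(repertoire(df2, "s", validate = FALSE))
  expect_equal(length(unique(pct2$cdr3_length)), 1)
})

test_that("feature tables align subjects, tag provenance and honour specs", {
  sim <- small_sim_cohort()
  co <- sim$cohort
  ft <- assemble_feature_table(co, "v_usage")
  expect_equal(nrow(ft), 8)
  expect_true(all(attr(ft, "provenance") == "v_usage"))
  expect_equal(rownames(ft), names(co$repertoires))

  ft2 <- assemble_feature_table(co, list(
    wa = list(family = "shm_5mer", parts = "mutability",
              motif_filter = "wa_tw", min_background = 1),
    usage = list(family = "v_usage")))
  expect_true(ncol(ft2) <= 256 + 12)
  expect_equal(sort(unique(attr(ft2, "provenance"))), c("usage", "wa"))
  expect_true(all(grepl("^(wa|usage):", colnames(ft2))))
  expect_error(assemble_feature_table(co, "no_such_family"), "unknown")
})
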