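# Shared fixtures and independent oracles for the test suite.

# Minimal valid record(s); alignments default to simple ungapped sequences.
make_records <- function(n = 1, v_call = "IGHV1-2*02", j_call = "IGHJ4*01",
                         junction = "TGTGCGAAAGATTACTGG",
                         sequence_alignment = "ATGCATGCATGC",
                         germline_alignment = sequence_alignment,
                         duplicate_count = 1L, ...) {
  df <- data.frame(sequence_id = sprintf("seq%03d", seq_len(n)),
                   v_call = v_call, j_call = j_call,
                   junction = junction,
                   junction_aa = vapply(junction, function(j)
                     paste(shmclass:::codon_table()[
                       substring(j, seq(1, nchar(j) - 2, 3),
                                 seq(3, nchar(j), 3))], collapse = ""),
                     character(1), USE.NAMES = FALSE),
                   sequence_alignment = sequence_alignment,
                   germline_alignment = germline_alignment,
                   duplicate_count = duplicate_count,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

write_airr_text <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# Brute-force single-linkage partition: threshold graph + connected
# components by breadth-first search. Independent of hclust.
brute_single_linkage <- function(junctions, threshold) {
  n <- length(junctions)
  chars <- strsplit(junctions, "")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- chars[[i]]; b <- chars[[j]]
    mm <- sum(a != b & a != "N" & b != "N") / length(a)
    adj[i, j] <- mm <= threshold
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Same-partition check up to relabelling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, function(i) length(unique(b[i])) == 1)) &&
    length(unique(a)) == length(unique(b))
}

# Brute-force nested-loop oracle for 5-mer mutation/background counts.
# Deliberately unvectorised and independent of the package internals.
oracle_counts <- function(rep, synonymous_only = FALSE, region_mask = NULL) {
  region_of <- function(p) {
    if (p <= 78) "fwr" else if (p <= 114) "cdr" else if (p <= 165) "fwr"
    else if (p <= 195) "cdr" else if (p <= 312) "fwr" else "unknown"
  }
  mut <- new.env(); bg <- new.env()
  add <- function(env, key) assign(key, (if (is.null(env[[key]])) 0
                                         else env[[key]]) + 1, envir = env)
  for (r in seq_len(nrow(rep$records))) {
    g <- strsplit(rep$records$germline_alignment[r], "")[[1]]
    o <- strsplit(rep$records$sequence_alignment[r], "")[[1]]
    keep <- g != "."
    gu <- g[keep]; ou <- o[keep]; gapped <- which(keep)
    for (u in seq_along(gu)) {
      if (u < 3 || u > length(gu) - 2) next
      win <- gu[(u - 2):(u + 2)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      if (!is.null(region_mask) && !(region_of(gapped[u]) %in% region_mask))
        next
      w <- paste(win, collapse = "")
      add(bg, w)
      if (ou[u] %in% c("A", "C", "G", "T") && ou[u] != gu[u]) {
        if (synonymous_only) {
          p <- gapped[u]
          st <- ((p - 1) %/% 3) * 3 + 1
          if (st + 2 > length(g)) next
          cod <- g[st:(st + 2)]
          if (any(!cod %in% c("A", "C", "G", "T"))) next
          mutc <- cod; mutc[p - st + 1] <- ou[u]
          aa0 <- seqinr::translate(cod); aa1 <- seqinr::translate(mutc)
          if (aa1 == "*" || aa0 != aa1) next
        }
        add(mut, w)
      }
    }
  }
  list(mut = mut, bg = bg)
}

# Independent proximal-gradient minimiser of the elastic-net logistic
# objective (1/n) sum nll + lambda * (alpha |b|_1 + (1-alpha)/2 |b|_2^2),
# intercept unpenalised.
prox_enet_logistic <- function(X, y, lambda, alpha, iters = 200000) {
  n <- nrow(X); p <- ncol(X)
  b0 <- 0; b <- rep(0, p)
  L <- max(eigen(crossprod(cbind(1, X)) / (4 * n))$values) +
    lambda * (1 - alpha)
  step <- 1 / L
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (it in seq_len(iters)) {
    eta <- b0 + drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    g0 <- mean(mu - y)
    g <- drop(crossprod(X, mu - y)) / n + lambda * (1 - alpha) * b
    b0 <- b0 - step * g0
    b <- soft(b - step * g, step * lambda * alpha)
  }
  unname(c(b0, b))
}

# Heavy shared simulations, built lazily and reused across test files.
.sim_store <- new.env(parent = emptyenv())
cached_fixture <- function(name, builder) {
  if (is.null(.sim_store[[name]])) .sim_store[[name]] <- builder()
  .sim_store[[name]]
}

small_sim_cohort <- function() {
  cached_fixture("small_cohort", function() {
    cfg <- simulation_config(n_subjects = 4, n_sequences = 150, seed = 42)
    simulate_cohort(cfg)
  })
}
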