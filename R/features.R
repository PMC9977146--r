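# Repertoire-level features beyond the SHM model: gene usage, CDR3 k-mers,
# sequence clusters, Hill diversity, summary percentiles.

cdr3_aa <- function(junction_aa) {
  # CDR3 = junction minus the conserved first (Cys) and last (Trp/Phe) residue
  out <- substr(junction_aa, 2L, nchar(junction_aa) - 1L)
  out[is.na(junction_aa) | nchar(junction_aa) < 3L] <- NA_character_
  out
}

usage_weights <- function(x, weighting, clones) {
  if (weighting == "clone") {
    if (is.null(clones)) clones <- partition_clones(x)
    reps <- select_representatives(x, clones)
    list(records = reps$records, w = rep(1, nrow(reps$records)))
  } else {
    list(records = x$records, w = rep(1, nrow(x$records)))
  }
}

#' V gene (or family) usage frequencies
#'
#' @param x a [repertoire()].
#' @param level `"gene"` or `"family"`.
#' @param weighting `"sequence"` (each unique sequence counts once, the
#'   default: DNA libraries sample cells uniformly) or `"clone"` (each clone
#'   counted once via its representative).
#' @param clones optional [partition_clones()] result for clone weighting.
#' @return named frequency vector summing to 1.
#' @export
v_gene_usage <- function(x, level = c("gene", "family"),
                         weighting = c("sequence", "clone"), clones = NULL) {
  level <- match.arg(level); weighting <- match.arg(weighting)
  u <- usage_weights(x, weighting, clones)
  key <- if (level == "gene") gene_of(u$records$v_call)
         else family_of(u$records$v_call)
  tab <- tapply(u$w, key, sum)
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, names(tab))
}

#' V-J gene pair usage frequencies
#'
#' @inheritParams v_gene_usage
#' @return named frequency vector over `"Vgene|Jgene"` pairs, summing to 1.
#' @export
vj_gene_usage <- function(x, weighting = c("sequence", "clone"),
                          clones = NULL) {
  weighting <- match.arg(weighting)
  u <- usage_weights(x, weighting, clones)
  key <- paste(gene_of(u$records$v_call), gene_of(u$records$j_call), sep = "|")
  tab <- tapply(u$w, key, sum)
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, names(tab))
}

#' CDR3 amino-acid k-mer frequencies
#'
#' The CDR3 is the junction amino-acid sequence with its first and last
#' (conserved) residues trimmed. All sliding windows of length `k` across all
#' CDR3s are counted and normalised to sum to 1; CDR3s shorter than `k` are
#' skipped.
#'
#' @param x a [repertoire()].
#' @param k k-mer length (default 3).
#' @return named frequency vector summing to 1.
#' @export
cdr3_kmer_frequencies <- function(x, k = 3L) {
  cdr3 <- cdr3_aa(x$records$junction_aa)
  cdr3 <- cdr3[!is.na(cdr3) & nchar(cdr3) >= k]
  if (length(cdr3) == 0L) stop("no CDR3 of length >= k in repertoire")
  kmers <- unlist(lapply(cdr3, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }), use.names = FALSE)
  tab <- table(kmers)
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, names(tab))
}

subject_triples <- function(rep) {
  cdr3 <- cdr3_aa(rep$records$junction_aa)
  ok <- !is.na(cdr3)
  paste(gene_of(rep$records$v_call[ok]), gene_of(rep$records$j_call[ok]),
        nchar(cdr3[ok]), sep = "|")
}

#' Frequencies of large V-J-CDR3-length sequence clusters
#'
#' Per subject, the frequency of each (V gene, J gene, CDR3 amino-acid
#' length) triple. The feature set is the union, over subjects, of triples
#' whose frequency reaches `min_freq` (inclusive) in at least one subject;
#' all other triples are dropped.
#'
#' @param x a [cohort()].
#' @param min_freq retention threshold (default 0.001).
#' @return subjects x triples matrix of frequencies.
#' @export
vjl_cluster_features <- function(x, min_freq = 0.001) {
  stopifnot(inherits(x, "cohort"))
  freqs <- lapply(x$repertoires, function(rep) {
    tr <- subject_triples(rep)
    tab <- table(tr)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  all_triples <- sort(unique(unlist(lapply(freqs, names), use.names = FALSE)))
  mat <- matrix(0, nrow = length(freqs), ncol = length(all_triples),
                dimnames = list(names(x$repertoires), all_triples))
  for (i in seq_along(freqs)) mat[i, names(freqs[[i]])] <- freqs[[i]]
  keep <- apply(mat, 2, max) >= min_freq
  mat[, keep, drop = FALSE]
}

#' Frequencies of cross-subject CDR3 identity clusters
#'
#' Within each (V gene, J gene, CDR3 length) triple pooled across subjects,
#' CDR3 amino-acid sequences are clustered greedily: unique sequences are
#' visited in canonical order (descending total count, then lexical); each
#' either joins the first established centroid with which its identity
#' (matching positions / length) is at least `identity`, or founds a new
#' cluster. Features are per-subject frequencies of each cluster; clusters
#' never reaching `min_freq` in any subject are dropped.
#'
#' @param x a [cohort()].
#' @param identity minimum fractional amino-acid identity (default 0.85).
#' @param min_freq retention threshold on per-subject frequency.
#' @return subjects x clusters matrix of frequencies; cluster names are
#'   `"V|J|len|centroid"`.
#' @export
cdr3_identity_cluster_features <- function(x, identity = 0.85,
                                           min_freq = 0.001) {
  stopifnot(inherits(x, "cohort"))
  subjects <- names(x$repertoires)
  pooled <- do.call(rbind, lapply(subjects, function(s) {
    rep <- x$repertoires[[s]]
    cdr3 <- cdr3_aa(rep$records$junction_aa)
    ok <- !is.na(cdr3)
    data.frame(subject = s,
               triple = paste(gene_of(rep$records$v_call[ok]),
                              gene_of(rep$records$j_call[ok]),
                              nchar(cdr3[ok]), sep = "|"),
               cdr3 = cdr3[ok], stringsAsFactors = FALSE)
  }))
  totals <- vapply(subjects, function(s) sum(pooled$subject == s), numeric(1))
  cluster_of <- rep(NA_character_, nrow(pooled))
  for (tr in unique(pooled$triple)) {
    idx <- which(pooled$triple == tr)
    seqs <- pooled$cdr3[idx]
    tab <- sort(table(seqs), decreasing = TRUE)
    uniq <- names(tab)[order(-as.numeric(tab), names(tab))]
    centroids <- character(0)
    assign_u <- character(length(uniq))
    L <- nchar(uniq[1])
    um <- matrix(unlist(strsplit(uniq, "", fixed = TRUE), use.names = FALSE),
                 ncol = L, byrow = TRUE)
    cm <- NULL
    for (k in seq_along(uniq)) {
      hit <- NA_integer_
      if (length(centroids) > 0L) {
        idmat <- cm == matrix(um[k, ], nrow = nrow(cm), ncol = L, byrow = TRUE)
        ids <- rowSums(idmat) / L
        w <- which(ids >= identity)
        if (length(w) > 0L) hit <- w[1]
      }
      if (is.na(hit)) {
        centroids <- c(centroids, uniq[k])
        cm <- rbind(cm, um[k, ])
        hit <- length(centroids)
      }
      assign_u[k] <- centroids[hit]
    }
    names(assign_u) <- uniq
    cluster_of[idx] <- paste(tr, assign_u[seqs], sep = "|")
  }
  counts <- table(pooled$subject, cluster_of)
  mat <- matrix(0, nrow = length(subjects), ncol = ncol(counts),
                dimnames = list(subjects, colnames(counts)))
  mat[rownames(counts), ] <- unclass(counts)
  mat <- sweep(mat, 1, totals, "/")
  keep <- apply(mat, 2, max) >= min_freq
  mat[, keep, drop = FALSE]
}

#' Hill diversity profile of a clone abundance distribution
#'
#' Hill numbers generalize richness (`q = 0`), the exponential of Shannon
#' entropy (`q = 1`) and the inverse Simpson index (`q = 2`):
#' `D_q = (sum p_i^q)^(1/(1-q))`.
#'
#' @param p abundance vector (will be normalised; zeros dropped), e.g. from
#'   [clone_abundance()].
#' @param q_values non-negative diversity orders.
#' @return data frame with columns `q` and `D`.
#' @export
hill_diversity <- function(p, q_values = c(0, 1, 2, 4)) {
  if (any(q_values < 0)) stop("negative q not allowed")
  p <- p[!is.na(p) & p > 0]
  if (length(p) == 0L) stop("empty abundance profile")
  p <- p / sum(p)
  D <- vapply(q_values, function(q) {
    if (abs(q - 1) < 1e-12) exp(-sum(p * log(p)))
    else sum(p^q)^(1 / (1 - q))
  }, numeric(1))
  data.frame(q = q_values, D = D)
}

#' Summary percentiles of CDR3 length and germline identity
#'
#' Germline identity per record is the fraction of matching positions among
#' aligned V-region positions (gapped positions 1-312) where both the
#' sequence and germline carry an unambiguous base. Percentiles (10/50/90 by
#' default) use linear interpolation between order statistics.
#'
#' @param x a [repertoire()].
#' @param probs percentile levels.
#' @return list with numeric vectors `cdr3_length` and `germline_identity`.
#' @export
repertoire_percentiles <- function(x, probs = c(0.1, 0.5, 0.9)) {
  cdr3 <- cdr3_aa(x$records$junction_aa)
  len <- nchar(cdr3[!is.na(cdr3)])
  ident <- vapply(seq_len(nrow(x$records)), function(i) {
    g <- strsplit(substr(x$records$germline_alignment[i], 1L, 312L), "",
                  fixed = TRUE)[[1]]
    s <- strsplit(substr(x$records$sequence_alignment[i], 1L, 312L), "",
                  fixed = TRUE)[[1]]
    n <- min(length(g), length(s))
    g <- g[seq_len(n)]; s <- s[seq_len(n)]
    ok <- g %in% NUCS & s %in% NUCS
    if (!any(ok)) return(NA_real_)
    sum(g[ok] == s[ok]) / sum(ok)
  }, numeric(1))
  list(cdr3_length = stats::quantile(len, probs, type = 7, names = TRUE),
       germline_identity = stats::quantile(ident[!is.na(ident)], probs,
                                           type = 7, names = TRUE))
}

# ---- feature table assembly -------------------------------------------------

align_feature_vectors <- function(vecs) {
  cols <- sort(unique(unlist(lapply(vecs, names), use.names = FALSE)))
  mat <- matrix(NA_real_, nrow = length(vecs), ncol = length(cols),
                dimnames = list(names(vecs), cols))
  for (i in seq_along(vecs)) mat[i, names(vecs[[i]])] <- vecs[[i]]
  mat
}

#' Assemble a subjects-by-features table from named feature families
#'
#' Each element of `spec` describes one feature family:
#' \describe{
#'   \item{`v_usage`}{V gene usage, options `level`, `weighting`.}
#'   \item{`vj_usage`}{V-J pair usage.}
#'   \item{`cdr3_kmers`}{CDR3 amino-acid k-mer frequencies, option `k`.}
#'   \item{`vjl_clusters`}{V-J-CDR3-length cluster frequencies, option
#'     `min_freq`.}
#'   \item{`cdr3_identity_clusters`}{cross-subject CDR3 identity clusters,
#'     options `identity`, `min_freq`.}
#'   \item{`shm_5mer`}{flattened 5-mer targeting model, options `parts`,
#'     `motif_filter`, `synonymous_only`, `region_mask`,
#'     `representatives_only`, `min_background`.}
#'   \item{`shm_3mer`}{3-mer mutability collapsed from the 5-mer model.}
#' }
#' Usage-style families fill frequencies absent in a subject with 0 (a gene
#' not observed has frequency zero); SHM model families keep absence as
#' missing (`NA`), to be imputed at training time.
#'
#' @param x a [cohort()].
#' @param spec named list of family specs; each a list with element `family`
#'   plus options. A bare character vector of family names is also accepted.
#' @return subjects x features numeric matrix; attribute `provenance` tags
#'   each column with the name of the spec entry it came from.
#' @export
assemble_feature_table <- function(x, spec) {
  stopifnot(inherits(x, "cohort"))
  if (is.character(spec))
    spec <- stats::setNames(lapply(spec, function(f) list(family = f)), spec)
  if (is.null(names(spec)) || any(names(spec) == ""))
    stop("spec entries must be named")
  subjects <- names(x$repertoires)
  blocks <- list()
  for (run in names(spec)) {
    s <- spec[[run]]
    fam <- s$family
    blk <- switch(fam,
      v_usage = {
        vecs <- lapply(x$repertoires, function(r)
          v_gene_usage(r, level = s$level %||% "gene",
                       weighting = s$weighting %||% "sequence"))
        m <- align_feature_vectors(vecs); m[is.na(m)] <- 0; m
      },
      vj_usage = {
        vecs <- lapply(x$repertoires, function(r)
          vj_gene_usage(r, weighting = s$weighting %||% "sequence"))
        m <- align_feature_vectors(vecs); m[is.na(m)] <- 0; m
      },
      cdr3_kmers = {
        vecs <- lapply(x$repertoires, function(r)
          cdr3_kmer_frequencies(r, k = s$k %||% 3L))
        m <- align_feature_vectors(vecs); m[is.na(m)] <- 0; m
      },
      vjl_clusters = vjl_cluster_features(x, min_freq = s$min_freq %||% 0.001),
      cdr3_identity_clusters =
        cdr3_identity_cluster_features(x, identity = s$identity %||% 0.85,
                                       min_freq = s$min_freq %||% 0.001),
      shm_5mer = {
        vecs <- lapply(x$repertoires, function(r) {
          m <- estimate_targeting_model(
            r, synonymous_only = isTRUE(s$synonymous_only),
            region_mask = s$region_mask,
            representatives_only = isTRUE(s$representatives_only),
            min_background = s$min_background %||% 10)
          flatten_model_features(
            m, parts = s$parts %||% c("mutability", "substitution", "targeting"),
            motif_filter = s$motif_filter)
        })
        align_feature_vectors(vecs)
      },
      shm_3mer = {
        vecs <- lapply(x$repertoires, function(r) {
          m5 <- estimate_targeting_model(
            r, synonymous_only = isTRUE(s$synonymous_only),
            region_mask = s$region_mask,
            representatives_only = isTRUE(s$representatives_only),
            min_background = s$min_background %||% 10)
          m3 <- collapse_to_3mer(m5)
          stats::setNames(m3$mutability,
                          paste0("mut3|", names(m3$mutability)))
        })
        align_feature_vectors(vecs)
      },
      stop("unknown feature family: ", fam)
    )
    drop_all_na <- colSums(!is.na(blk)) > 0
    blk <- blk[, drop_all_na, drop = FALSE]
    if (ncol(blk) == 0L)
      stop("feature family '", run, "' produced no usable features")
    blk <- blk[subjects, , drop = FALSE]
    colnames(blk) <- paste0(run, ":", colnames(blk))
    blocks[[run]] <- blk
  }
  out <- do.call(cbind, blocks)
  attr(out, "provenance") <- rep(names(spec),
                                 vapply(blocks, ncol, integer(1)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature table with provenance tags
#'
#' Two header rows: feature-family tag and feature name; one row per subject.
#'
#' @param features matrix from [assemble_feature_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  prov <- attr(features, "provenance")
  if (is.null(prov)) prov <- rep("feature", ncol(features))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("family", prov), collapse = "\t"), con)
  writeLines(paste(c("subject_id", colnames(features)), collapse = "\t"), con)
  utils::write.table(cbind(rownames(features), features), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
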