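# Clonal inference: single-linkage clustering of junctions within
# V gene / J gene / junction-length partitions.

# Normalized Hamming distance matrix between equal-length junctions.
# Positions where either base is N are not counted as mismatches.
junction_dist <- function(junctions) {
  n <- length(junctions)
  L <- nchar(junctions[1])
  m <- matrix(unlist(strsplit(junctions, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      mm <- sum(m[i, ] != m[j, ] & m[i, ] != "N" & m[j, ] != "N")
      d[i, j] <- d[j, i] <- mm / L
    }
  }
  d
}

#' Partition a repertoire into B-cell clones
#'
#' Sequences are first grouped by V gene, J gene (allele suffixes dropped,
#' first call of multi-assignments used) and junction length; within each
#' group, single-linkage hierarchical clustering on the normalized Hamming
#' distance between junction nucleotide sequences is cut at `threshold`.
#' Records lacking a junction become singleton clones (their count is
#' reported in attribute `n_missing_junction`). Clone identifiers are
#' assigned in order of each clone's first appearance in the input, so the
#' partition is deterministic given the record order and invariant to order
#' up to relabelling.
#'
#' @param x a [repertoire()].
#' @param threshold normalized junction distance in `[0, 1]` below or at
#'   which sequences are linked (default 0.15, the conventional heavy-chain
#'   value).
#' @return an object of class `clone_assignment`: `$assignment` maps
#'   `sequence_id` to `clone_id` (with `duplicate_count` carried along),
#'   `$clones` summarises each clone (V gene, J gene, junction length, size).
#' @export
partition_clones <- function(x, threshold = 0.15) {
  stopifnot(inherits(x, "repertoire"), threshold >= 0, threshold <= 1)
  rec <- x$records
  v_gene <- gene_of(rec$v_call)
  j_gene <- gene_of(rec$j_call)
  junction <- rec$junction
  has_j <- !is.na(junction) & nchar(junction) > 0L
  key <- paste(v_gene, j_gene, nchar(junction), sep = "|")
  cl <- integer(nrow(rec))
  next_id <- 0L
  # temporary labels per group; final ids assigned by first appearance
  grp_labels <- rep(NA_integer_, nrow(rec))
  for (g in unique(key[has_j])) {
    idx <- which(has_j & key == g)
    if (length(idx) == 1L) {
      grp_labels[idx] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    ju <- junction[idx]
    d <- junction_dist(ju)
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    memb <- stats::cutree(hc, h = threshold)
    grp_labels[idx] <- next_id + memb
    next_id <- next_id + max(memb)
  }
  miss <- which(!has_j)
  if (length(miss) > 0L) {
    grp_labels[miss] <- next_id + seq_along(miss)
    next_id <- next_id + length(miss)
  }
  # relabel by first appearance so ids are stable and readable
  first_seen <- !duplicated(grp_labels)
  remap <- stats::setNames(seq_len(sum(first_seen)), grp_labels[first_seen])
  clone_id <- sprintf("clone_%04d", remap[as.character(grp_labels)])
  dup <- if ("duplicate_count" %in% names(rec)) rec$duplicate_count
         else rep(1L, nrow(rec))
  dup[is.na(dup)] <- 1L
  assignment <- data.frame(sequence_id = rec$sequence_id,
                           clone_id = unname(clone_id),
                           duplicate_count = dup,
                           stringsAsFactors = FALSE)
  agg <- split(seq_len(nrow(rec)), clone_id)
  agg <- agg[unique(clone_id)]
  clones <- data.frame(
    clone_id = names(agg),
    v_gene = vapply(agg, function(i) v_gene[i[1]], character(1)),
    j_gene = vapply(agg, function(i) j_gene[i[1]], character(1)),
    junction_length = vapply(agg, function(i) nchar(junction[i[1]]), integer(1)),
    n_sequences = vapply(agg, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(clones) <- NULL
  structure(list(assignment = assignment, clones = clones,
                 threshold = threshold),
            n_missing_junction = length(miss),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat("clone assignment: ", nrow(x$assignment), " sequences in ",
      nrow(x$clones), " clones (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Relative clone abundances
#'
#' @param assignment a [partition_clones()] result.
#' @param weighting `"sequence"` (each unique sequence counts 1) or
#'   `"duplicate"` (sequences weighted by `duplicate_count`).
#' @return named numeric vector of clone abundances summing to 1.
#' @export
clone_abundance <- function(assignment, weighting = c("sequence", "duplicate")) {
  stopifnot(inherits(assignment, "clone_assignment"))
  weighting <- match.arg(weighting)
  w <- if (weighting == "duplicate") assignment$assignment$duplicate_count
       else rep(1, nrow(assignment$assignment))
  tot <- tapply(w, assignment$assignment$clone_id, sum)
  tot <- tot[assignment$clones$clone_id]
  p <- as.numeric(tot) / sum(tot)
  stats::setNames(p, assignment$clones$clone_id)
}

#' Keep one representative record per clone
#'
#' The representative is the member with the highest `duplicate_count`
#' (missing counts treated as 1), ties broken by the lexicographically
#' smallest `sequence_id`, so the choice is deterministic.
#'
#' @param x a [repertoire()].
#' @param assignment a matching [partition_clones()] result.
#' @return a [repertoire()] with exactly one record per clone.
#' @export
select_representatives <- function(x, assignment) {
  stopifnot(inherits(x, "repertoire"), inherits(assignment, "clone_assignment"))
  a <- assignment$assignment
  ord <- order(a$clone_id, -a$duplicate_count, a$sequence_id)
  a <- a[ord, , drop = FALSE]
  reps <- a$sequence_id[!duplicated(a$clone_id)]
  keep <- x$records$sequence_id %in% reps
  repertoire(x$records[keep, , drop = FALSE], x$subject_id, x$metadata,
             validate = FALSE)
}

#' Export a clone assignment as a two-column table
#'
#' @param assignment a [partition_clones()] result.
#' @param path output TSV path (`sequence_id`, `clone_id`).
#' @return `path`, invisibly.
#' @export
write_clone_assignment <- function(assignment, path) {
  utils::write.table(assignment$assignment[c("sequence_id", "clone_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
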