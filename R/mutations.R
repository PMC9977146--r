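# Mutation enumeration against the inferred germline, with 5-mer context,
# FWR/CDR region assignment and synonymy classification.

# IMGT nucleotide boundaries of the V region (gapped coordinates):
# FR1 1-78, CDR1 79-114, FR2 115-165, CDR2 166-195, FR3 196-312.
# Positions beyond 312 (junction / J segment) are not IMGT-numbered here and
# are labelled "unknown".
imgt_region <- function(pos) {
  out <- rep("unknown", length(pos))
  out[pos >= 1 & pos <= 78] <- "fwr"
  out[pos >= 79 & pos <= 114] <- "cdr"
  out[pos >= 115 & pos <= 165] <- "fwr"
  out[pos >= 166 & pos <= 195] <- "cdr"
  out[pos >= 196 & pos <= 312] <- "fwr"
  out
}

# Per-germline profile, cached because clone members share their germline.
# Contexts are computed on the gap-stripped germline; windows that run off
# either end or contain a non-ACGT character are uninformative (NA).
germline_profile <- function(germ, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[germ]])) return(cache[[germ]])
  chars <- strsplit(germ, "", fixed = TRUE)[[1]]
  nongap <- chars != "."
  gapped_pos <- which(nongap)         # ungapped index -> gapped position
  ungapped <- chars[nongap]
  L <- length(ungapped)
  rank <- cumsum(nongap)              # gapped position -> ungapped index
  rank[!nongap] <- NA_integer_
  ctx <- rep(NA_character_, L)
  if (L >= 5L) {
    centers <- 3:(L - 2L)
    us <- paste(ungapped, collapse = "")
    win <- substring(us, centers - 2L, centers + 2L)
    win[grepl("[^ACGT]", win)] <- NA_character_
    ctx[centers] <- win
  }
  region <- imgt_region(seq_along(chars))
  prof <- list(chars = chars, ungapped = ungapped, rank = rank,
               gapped_pos = gapped_pos, context = ctx,
               context_idx = match(ctx, fivemer_universe()),
               informative = which(!is.na(ctx)),
               region = region,
               is_acgt = chars %in% NUCS)
  if (!is.null(cache)) cache[[germ]] <- prof
  prof
}

#' Classify the synonymy of single-nucleotide mutations
#'
#' The reading frame is defined by codons starting at position 1 of the
#' IMGT-gapped alignment; IMGT gaps occur in codon triplets, so codon
#' boundaries are taken on gapped coordinates. The germline codon is compared
#' with the germline codon carrying only this mutation. Codons containing
#' gaps or `N` are `"ambiguous"`; a mutated codon that becomes a stop is
#' `"stop"`.
#'
#' @param record a single-row record list/data.frame with
#'   `germline_alignment`.
#' @param position gapped alignment position(s) of the mutation (1-based).
#' @param to_base replacement base(s).
#' @return character vector in
#'   `{"synonymous", "nonsynonymous", "stop", "ambiguous"}`.
#' @export
classify_synonymy <- function(record, position, to_base) {
  germ <- normalize_nt(record$germline_alignment[1])
  prof <- germline_profile(germ)
  synonymy_from_profile(prof, position, to_base)
}

synonymy_from_profile <- function(prof, position, to_base) {
  n <- length(position)
  out <- rep("ambiguous", n)
  codon_i <- (position - 1L) %/% 3L
  start <- codon_i * 3L + 1L
  for (k in seq_len(n)) {
    if (start[k] + 2L > length(prof$chars)) next
    cod <- prof$chars[start[k]:(start[k] + 2L)]
    if (any(!cod %in% NUCS)) next
    off <- position[k] - start[k] + 1L
    mut <- cod
    mut[off] <- to_base[k]
    aa0 <- codon_table()[paste(cod, collapse = "")]
    aa1 <- codon_table()[paste(mut, collapse = "")]
    out[k] <- if (aa1 == "*") "stop"
      else if (aa0 == aa1) "synonymous" else "nonsynonymous"
  }
  out
}

#' Enumerate point mutations of a record relative to its germline
#'
#' One mutation is reported for every aligned position where germline and
#' observed base are both in A/C/G/T and differ. The 5-mer context is taken
#' from the gap-stripped germline, centred on the mutated position; windows
#' that run off either end of the sequence or contain a non-ACGT character
#' are uninformative (`NA` context). Regions follow the IMGT V-region
#' numbering (see Details of [estimate_targeting_model()]).
#'
#' @param record one-row data frame (or list) with `sequence_id`,
#'   `sequence_alignment`, `germline_alignment`.
#' @param region_mask optional subset of `c("fwr", "cdr")`: only mutations in
#'   those regions are returned.
#' @return data frame with columns `sequence_id`, `position` (gapped,
#'   1-based), `context`, `from`, `to`, `region`, `synonymy`.
#' @export
enumerate_mutations <- function(record, region_mask = NULL) {
  germ <- normalize_nt(record$germline_alignment[1])
  obs <- normalize_nt(record$sequence_alignment[1])
  if (nchar(germ) != nchar(obs))
    stop("sequence and germline alignments differ in length")
  prof <- germline_profile(germ)
  mutations_from_profile(prof, obs, record$sequence_id[1], region_mask)
}

mutations_from_profile <- function(prof, obs, sequence_id, region_mask = NULL) {
  oc <- strsplit(obs, "", fixed = TRUE)[[1]]
  pos <- which(prof$is_acgt & oc %in% NUCS & prof$chars != oc)
  if (!is.null(region_mask) && length(pos) > 0L)
    pos <- pos[prof$region[pos] %in% region_mask]
  if (length(pos) == 0L)
    return(data.frame(sequence_id = character(0), position = integer(0),
                      context = character(0), from = character(0),
                      to = character(0), region = character(0),
                      synonymy = character(0), stringsAsFactors = FALSE))
  u <- prof$rank[pos]
  data.frame(sequence_id = rep(sequence_id, length(pos)),
             position = pos,
             context = prof$context[u],
             from = prof$chars[pos],
             to = oc[pos],
             region = prof$region[pos],
             synonymy = synonymy_from_profile(prof, pos, oc[pos]),
             stringsAsFactors = FALSE)
}

# All mutations of a repertoire, reusing germline profiles across records.
repertoire_mutations <- function(x, region_mask = NULL) {
  cache <- new.env(parent = emptyenv())
  rec <- x$records
  out <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    prof <- germline_profile(rec$germline_alignment[i], cache)
    out[[i]] <- mutations_from_profile(prof, rec$sequence_alignment[i],
                                       rec$sequence_id[i], region_mask)
  }
  do.call(rbind, out)
}
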