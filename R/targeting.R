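# Per-repertoire 5-mer SHM targeting models: mutability, substitution and
# their product, estimated by counting mutations against germline context.

#' Estimate a 5-mer SHM targeting model from a repertoire
#'
#' For every ACGT 5-mer `w` the model holds a background count (number of
#' informative germline positions whose centred 5-mer context is `w`), a
#' mutation count (observed germline-vs-sequence mismatches with context
#' `w`), a mutability value (mutation/background rate, normalised so that
#' values present sum to 1, i.e. the probability that a mutation occurs in
#' that context), a substitution row (empirical distribution of the
#' replacement base given `w`) and targeting (mutability times
#' substitution). 5-mers whose background count falls below `min_background`
#' have absent (`NA`) mutability: low-coverage contexts yield high-variance
#' rates and are treated as missing rather than zero. Contexts are always
#' taken from the (pre-mutation) germline, so several mutations in one
#' sequence each count against the germline context.
#'
#' The model describes the combined effect of SHM targeting and
#' affinity-dependent selection, not enzymology alone. Restricting to
#' synonymous mutations (`synonymous_only = TRUE`) removes most selection
#' pressure; the background then still counts all informative positions,
#' which is a deliberate, simple approximation. `region_mask` restricts both
#' mutation and background counting to IMGT framework (`"fwr"`) and/or CDR
#' (`"cdr"`) positions of the V region (FR1 1-78, CDR1 79-114, FR2 115-165,
#' CDR2 166-195, FR3 196-312 in gapped coordinates; positions beyond 312 are
#' "unknown" and only used when no mask is given).
#'
#' @param x a [repertoire()].
#' @param synonymous_only count only synonymous mutations.
#' @param region_mask optional subset of `c("fwr", "cdr")`.
#' @param representatives_only use one representative per clone (requires
#'   `clones` or computes [partition_clones()] with defaults).
#' @param clones optional [partition_clones()] result, used when
#'   `representatives_only = TRUE`.
#' @param min_background minimum background count for a 5-mer's mutability to
#'   be considered estimable (default 10).
#' @return an object of class `targeting_model` with elements `mutability`
#'   (named length-1024 vector, `NA` = absent), `substitution` (1024 x 4
#'   matrix of replacement-base probabilities, centre base `NA`), `targeting`
#'   (1024 x 4), `mutation_count`, `background_count`, `options`, and logical
#'   `degenerate` (no informative mutations at all).
#' @seealso [collapse_to_3mer()], [flatten_model_features()],
#'   [classify_hotspot()]
#' @examples
#' rec <- data.frame(sequence_id = "s1", v_call = "IGHV1-1*01",
#'   j_call = "IGHJ4*01", junction = "TGTGCGTGG", junction_aa = "CAW",
#'   sequence_alignment = "TTGATAAGGCTG", germline_alignment = "TTAATAAGGCTG")
#' rep1 <- repertoire(rec, "s")
#' m <- estimate_targeting_model(rep1, min_background = 1)
#' coef(m)[!is.na(coef(m))]
#' @export
estimate_targeting_model <- function(x, synonymous_only = FALSE,
                                     region_mask = NULL,
                                     representatives_only = FALSE,
                                     clones = NULL,
                                     min_background = 10) {
  stopifnot(inherits(x, "repertoire"))
  if (representatives_only) {
    if (is.null(clones)) clones <- partition_clones(x)
    x <- select_representatives(x, clones)
  }
  fm <- fivemer_universe()
  rec <- x$records

  # background: informative 5-mer windows per unique germline, weighted by
  # how many records carry that germline
  germs <- rec$germline_alignment
  tab <- table(germs)
  bg <- stats::setNames(numeric(length(fm)), fm)
  cache <- new.env(parent = emptyenv())
  for (g in names(tab)) {
    prof <- germline_profile(g, cache)
    ctx <- prof$context
    if (!is.null(region_mask)) {
      reg <- prof$region[prof$gapped_pos]
      ctx <- ctx[reg %in% region_mask]
    }
    ctx <- ctx[!is.na(ctx)]
    if (length(ctx) == 0L) next
    cnt <- table(ctx)
    bg[names(cnt)] <- bg[names(cnt)] + as.numeric(cnt) * as.numeric(tab[[g]])
  }

  # mutation counting avoids per-record data frames: it accumulates
  # (5-mer index, replacement base index) pairs and tabulates once
  ctx_acc <- vector("list", nrow(rec))
  to_acc <- vector("list", nrow(rec))
  n_mut_total <- 0L
  for (i in seq_len(nrow(rec))) {
    prof <- germline_profile(rec$germline_alignment[i], cache)
    oc <- strsplit(rec$sequence_alignment[i], "", fixed = TRUE)[[1]]
    pos <- which(prof$is_acgt & oc %in% NUCS & prof$chars != oc)
    if (!is.null(region_mask) && length(pos) > 0L)
      pos <- pos[prof$region[pos] %in% region_mask]
    if (length(pos) == 0L) next
    if (synonymous_only) {
      syn <- synonymy_from_profile(prof, pos, oc[pos])
      pos <- pos[syn == "synonymous"]
      if (length(pos) == 0L) next
    }
    ci <- prof$context_idx[prof$rank[pos]]
    ok <- !is.na(ci)
    if (!any(ok)) next
    ctx_acc[[i]] <- ci[ok]
    to_acc[[i]] <- match(oc[pos[ok]], NUCS)
    n_mut_total <- n_mut_total + sum(ok)
  }
  mut_count <- stats::setNames(numeric(length(fm)), fm)
  sub_count <- matrix(0, nrow = length(fm), ncol = 4L,
                      dimnames = list(fm, NUCS))
  degenerate <- n_mut_total == 0L
  if (!degenerate) {
    ci <- unlist(ctx_acc, use.names = FALSE)
    ti <- unlist(to_acc, use.names = FALSE)
    mut_count[] <- tabulate(ci, nbins = length(fm))
    sub_count[] <- tabulate((ti - 1L) * length(fm) + ci,
                            nbins = 4L * length(fm))
  }

  raw <- ifelse(bg >= min_background, mut_count / pmax(bg, 1), NA_real_)
  raw[bg < min_background] <- NA_real_
  tot <- sum(raw, na.rm = TRUE)
  mutability <- if (tot > 0) raw / tot else raw

  substitution <- sub_count / ifelse(rowSums(sub_count) > 0,
                                     rowSums(sub_count), NA_real_)
  center <- substr(fm, 3L, 3L)
  for (b in NUCS) substitution[center == b, b] <- NA_real_
  targeting <- substitution * mutability

  structure(list(mutability = mutability,
                 substitution = substitution,
                 targeting = targeting,
                 mutation_count = mut_count,
                 background_count = bg,
                 options = list(synonymous_only = synonymous_only,
                                region_mask = region_mask,
                                representatives_only = representatives_only,
                                min_background = min_background),
                 degenerate = degenerate,
                 subject_id = x$subject_id,
                 n_mutations = n_mut_total),
            class = "targeting_model")
}

#' Construct a targeting model directly from its components
#'
#' Used by the simulator and by tests; performs normalisation and fills the
#' targeting product.
#'
#' @param mutability named numeric vector over the 1024 5-mers (will be
#'   normalised to sum to 1 over present values).
#' @param substitution 1024 x 4 matrix of replacement-base probabilities; if
#'   `NULL`, a uniform distribution over the three non-centre bases is used.
#' @param background_count optional named background counts (defaults to a
#'   flat pseudo-background of 1000).
#' @return a `targeting_model`.
#' @export
targeting_model <- function(mutability, substitution = NULL,
                            background_count = NULL) {
  fm <- fivemer_universe()
  m <- stats::setNames(rep(NA_real_, length(fm)), fm)
  m[names(mutability)] <- mutability
  m <- m / sum(m, na.rm = TRUE)
  if (is.null(substitution)) {
    substitution <- matrix(1 / 3, nrow = length(fm), ncol = 4L,
                           dimnames = list(fm, NUCS))
  }
  center <- substr(fm, 3L, 3L)
  for (b in NUCS) substitution[center == b, b] <- NA_real_
  substitution <- substitution / rowSums(substitution, na.rm = TRUE)
  if (is.null(background_count))
    background_count <- stats::setNames(rep(1000, length(fm)), fm)
  structure(list(mutability = m, substitution = substitution,
                 targeting = substitution * m,
                 mutation_count = stats::setNames(rep(NA_real_, length(fm)), fm),
                 background_count = background_count,
                 options = list(synonymous_only = FALSE, region_mask = NULL,
                                representatives_only = FALSE,
                                min_background = 0),
                 degenerate = all(is.na(m)),
                 subject_id = NA_character_,
                 n_mutations = NA_integer_),
            class = "targeting_model")
}

#' @export
print.targeting_model <- function(x, ...) {
  n_present <- sum(!is.na(x$mutability))
  cat("5-mer SHM targeting model",
      if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]"), "\n", sep = "")
  cat("  present 5-mers: ", n_present, " / 1024\n", sep = "")
  if (!is.na(x$n_mutations))
    cat("  mutations counted: ", x$n_mutations, "\n", sep = "")
  if (x$degenerate) cat("  (degenerate: no informative mutations)\n")
  op <- x$options
  if (isTRUE(op$synonymous_only)) cat("  synonymous mutations only\n")
  if (!is.null(op$region_mask))
    cat("  region mask: ", paste(op$region_mask, collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.targeting_model <- function(object, ...) {
  cls <- hotspot_classes()
  m <- object$mutability
  by_class <- tapply(m, cls[names(m)], sum, na.rm = TRUE)
  out <- list(present = sum(!is.na(m)),
              mass_by_motif = by_class,
              top = utils::head(sort(m, decreasing = TRUE), 10),
              degenerate = object$degenerate)
  class(out) <- "summary.targeting_model"
  out
}

#' @export
print.summary.targeting_model <- function(x, ...) {
  cat("present 5-mers:", x$present, "\n")
  cat("mutability mass by motif class:\n")
  print(round(x$mass_by_motif, 4))
  cat("top 10 mutable 5-mers:\n")
  print(round(x$top, 5))
  invisible(x)
}

#' @export
coef.targeting_model <- function(object, ...) object$mutability

#' @export
plot.targeting_model <- function(x, n = 30, ...) {
  m <- sort(x$mutability[!is.na(x$mutability)], decreasing = TRUE)
  m <- utils::head(m, n)
  cls <- hotspot_classes()[names(m)]
  col <- c(wa_tw = "purple", wrc_gyw = "steelblue", neutral = "grey60")[cls]
  graphics::barplot(m, las = 2, col = col, cex.names = 0.6,
                    ylab = "normalised mutability",
                    main = "top 5-mer mutabilities", ...)
  graphics::legend("topright", fill = c("purple", "steelblue", "grey60"),
                   legend = c("WA/TW", "WRC/GYW", "neutral"), bty = "n")
  invisible(x)
}

#' Collapse a 5-mer model to a central-3-mer mutability model
#'
#' Each 3-mer's value is the background-weighted mean of the mutabilities of
#' the sixteen 5-mers whose positions 2-4 equal that 3-mer, renormalised to
#' sum to 1. 3-mers with no present constituent 5-mer are absent.
#'
#' @param model a `targeting_model`.
#' @return an object of class `threemer_model`: `$mutability` (named
#'   length-64 vector) and `$background_count`.
#' @export
collapse_to_3mer <- function(model) {
  stopifnot(inherits(model, "targeting_model"))
  if (model$degenerate) stop("cannot collapse a degenerate targeting model")
  fm <- names(model$mutability)
  inner <- substr(fm, 2L, 4L)
  tm <- all_threemers()
  val <- stats::setNames(rep(NA_real_, length(tm)), tm)
  bg3 <- stats::setNames(rep(0, length(tm)), tm)
  present <- !is.na(model$mutability)
  w <- model$background_count
  num <- tapply(ifelse(present, model$mutability * w, 0), inner, sum)
  den <- tapply(ifelse(present, w, 0), inner, sum)
  v <- ifelse(den > 0, num / den, NA_real_)
  val[names(v)] <- v
  bg3[names(den)] <- den
  val <- val / sum(val, na.rm = TRUE)
  structure(list(mutability = val, background_count = bg3,
                 subject_id = model$subject_id),
            class = "threemer_model")
}

#' @export
print.threemer_model <- function(x, ...) {
  cat("3-mer SHM mutability model: ", sum(!is.na(x$mutability)),
      " / 64 present\n", sep = "")
  invisible(x)
}

#' Flatten a targeting model into a named feature vector
#'
#' Features are named `mut|AACGT`, `sub|AACGT>T` and `targ|AACGT>T` (the
#' centre-base substitution is never emitted). Absent model entries become
#' `NA` features. With `motif_filter`, only features whose 5-mer belongs to
#' that hotspot class are kept.
#'
#' @param model a `targeting_model`.
#' @param parts non-empty subset of
#'   `c("mutability", "substitution", "targeting")`.
#' @param motif_filter optional `"wa_tw"`, `"wrc_gyw"` or `"neutral"`.
#' @return named numeric vector (deterministic order).
#' @export
flatten_model_features <- function(model,
                                   parts = c("mutability", "substitution",
                                             "targeting"),
                                   motif_filter = NULL) {
  stopifnot(inherits(model, "targeting_model"))
  if (length(parts) == 0L) stop("'parts' must name at least one component")
  parts <- match.arg(parts, several.ok = TRUE)
  fm <- fivemer_universe()
  keep <- rep(TRUE, length(fm))
  if (!is.null(motif_filter)) {
    motif_filter <- match.arg(motif_filter, c("wa_tw", "wrc_gyw", "neutral"))
    keep <- hotspot_classes()[fm] == motif_filter
  }
  out <- numeric(0)
  if ("mutability" %in% parts) {
    v <- model$mutability[keep]
    names(v) <- paste0("mut|", fm[keep])
    out <- c(out, v)
  }
  center <- substr(fm, 3L, 3L)
  for (part in intersect(c("substitution", "targeting"), parts)) {
    mat <- if (part == "substitution") model$substitution else model$targeting
    tag <- if (part == "substitution") "sub" else "targ"
    for (b in NUCS) {
      sel <- keep & center != b
      v <- mat[sel, b]
      names(v) <- paste0(tag, "|", fm[sel], ">", b)
      out <- c(out, v)
    }
  }
  out
}

#' Write / read a targeting model as TSV
#'
#' Columns: `fivemer`, `mutability`, `sub_A`..`sub_T`, `mutation_count`,
#' `background_count`. The centre-base substitution column is empty.
#'
#' @param model a `targeting_model`.
#' @param path file path.
#' @return `path` (write) or a `targeting_model` (read).
#' @export
write_targeting_model <- function(model, path) {
  df <- data.frame(fivemer = names(model$mutability),
                   mutability = model$mutability,
                   sub_A = model$substitution[, "A"],
                   sub_C = model$substitution[, "C"],
                   sub_G = model$substitution[, "G"],
                   sub_T = model$substitution[, "T"],
                   mutation_count = model$mutation_count,
                   background_count = model$background_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_targeting_model
#' @export
read_targeting_model <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  sub <- as.matrix(df[, c("sub_A", "sub_C", "sub_G", "sub_T")])
  dimnames(sub) <- list(df$fivemer, NUCS)
  m <- targeting_model(stats::setNames(df$mutability, df$fivemer),
                       substitution = sub,
                       background_count = stats::setNames(df$background_count,
                                                          df$fivemer))
  m$mutation_count <- stats::setNames(df$mutation_count, df$fivemer)
  m
}
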