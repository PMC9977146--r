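# AIRR Rearrangement I/O and repertoire/cohort containers.

AIRR_REQUIRED <- c("sequence_id", "v_call", "j_call", "junction",
                   "junction_aa", "sequence_alignment", "germline_alignment")
AIRR_OPTIONAL <- c("d_call", "duplicate_count", "clone_id")

#' Construct a repertoire from a data frame of rearrangement records
#'
#' A repertoire is one subject's set of annotated heavy-chain rearrangements:
#' a data frame with the AIRR-required columns (`sequence_id`, `v_call`,
#' `j_call`, `junction`, `junction_aa`, `sequence_alignment`,
#' `germline_alignment`), optional `d_call`, `duplicate_count` and
#' `clone_id`, plus any extra columns carried through opaquely.
#'
#' @param records data frame of rearrangement records.
#' @param subject_id subject identifier.
#' @param metadata optional named list (age, tissue, material, ...).
#' @param validate drop records whose aligned sequence and germline differ in
#'   length (they violate the alignment contract); the number dropped is kept
#'   in attribute `n_rejected`.
#' @return an object of class `repertoire`.
#' @export
repertoire <- function(records, subject_id, metadata = list(), validate = TRUE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(AIRR_REQUIRED, names(records))
  if (length(missing_cols) > 0L)
    stop("missing required AIRR column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L) stop("a repertoire must contain at least one record")
  for (col in intersect(c("junction", "sequence_alignment", "germline_alignment"),
                        names(records)))
    records[[col]] <- normalize_nt(as.character(records[[col]]))
  records$sequence_id <- as.character(records$sequence_id)
  if (anyDuplicated(records$sequence_id))
    stop("duplicate sequence_id within repertoire '", subject_id, "'")
  if ("duplicate_count" %in% names(records)) {
    records$duplicate_count <- as.integer(records$duplicate_count)
    bad <- !is.na(records$duplicate_count) & records$duplicate_count < 1L
    if (any(bad)) stop("duplicate_count must be >= 1 when present")
  }
  n_rejected <- 0L
  if (validate) {
    ok <- nchar(records$sequence_alignment) == nchar(records$germline_alignment)
    n_rejected <- sum(!ok)
    if (n_rejected > 0L) {
      message("repertoire '", subject_id, "': skipped ", n_rejected,
              " record(s) with sequence/germline alignment length mismatch")
      records <- records[ok, , drop = FALSE]
    }
    if (nrow(records) == 0L)
      stop("all records of repertoire '", subject_id, "' failed validation")
  }
  rownames(records) <- NULL
  structure(list(subject_id = as.character(subject_id),
                 records = records,
                 metadata = metadata),
            n_rejected = n_rejected,
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("AIRR repertoire '", x$subject_id, "': ", nrow(x$records),
      " records\n", sep = "")
  invisible(x)
}

n_records <- function(x) nrow(x$records)

#' Read an AIRR Rearrangement TSV file into a repertoire
#'
#' Expects a tab-separated file with a header row naming at least the
#' required AIRR fields. Nucleotide columns are uppercased and `-` gap
#' characters normalised to the IMGT `.`; unknown extra columns are preserved
#' and survive a round trip through [write_airr()]. Records whose
#' `sequence_alignment` and `germline_alignment` lengths disagree are skipped
#' with a message; the count is available as `attr(x, "n_rejected")`.
#'
#' @param path path to an AIRR TSV file.
#' @param subject_id subject identifier; defaults to the file name.
#' @param metadata optional named list attached to the repertoire.
#' @return a [repertoire()] object, rows in file order.
#' @export
read_airr <- function(path, subject_id = NULL, metadata = list()) {
  if (!file.exists(path)) stop("AIRR file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"), quote = "")
  missing_cols <- setdiff(AIRR_REQUIRED, names(df))
  if (length(missing_cols) > 0L)
    stop("AIRR file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  # fully-empty optional columns are treated as absent, not empty strings
  for (col in intersect(AIRR_OPTIONAL, names(df)))
    if (all(is.na(df[[col]]))) df[[col]] <- NULL
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  repertoire(df, subject_id = subject_id, metadata = metadata)
}

#' Write a repertoire to an AIRR Rearrangement TSV file
#'
#' Round-trip companion of [read_airr()]: all required and present optional
#' columns, plus any extra columns, are written field-exactly.
#'
#' @param x a [repertoire()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(x, path) {
  stopifnot(inherits(x, "repertoire"))
  if (nrow(x$records) == 0L) stop("refusing to write an empty repertoire")
  utils::write.table(x$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Load a cohort of labelled repertoires from a manifest
#'
#' The manifest is a TSV with columns `subject_id`, `file` and `label`. File
#' paths are resolved relative to the manifest's directory. Label tokens are
#' translated to the internal vocabulary `case`/`control` through
#' `label_map`; `case` is the positive (disease) class throughout the
#' package.
#'
#' @param manifest path to the manifest TSV.
#' @param label_map named character vector mapping manifest label tokens to
#'   `"case"`/`"control"`, e.g. `c(CD = "case", CTRL = "control")`.
#' @return an object of class `cohort`: a named list of repertoires plus a
#'   `subject_id -> label` vector.
#' @export
load_cohort <- function(manifest,
                        label_map = c(case = "case", control = "control")) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  mf <- utils::read.delim(manifest, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("subject_id", "file", "label")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(mf$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(mf$subject_id[duplicated(mf$subject_id)]), collapse = ", "))
  unknown <- setdiff(unique(mf$label), names(label_map))
  if (length(unknown) > 0L)
    stop("unknown label token(s) in manifest: ", paste(unknown, collapse = ", "),
         " (extend label_map)")
  labels <- unname(label_map[mf$label])
  if (!all(labels %in% c("case", "control")))
    stop("label_map values must be 'case' or 'control'")
  base_dir <- dirname(manifest)
  reps <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    f <- mf$file[i]
    if (!file.exists(f)) f <- file.path(base_dir, mf$file[i])
    if (!file.exists(f))
      stop("file for subject '", mf$subject_id[i], "' not found: ", mf$file[i])
    reps[[i]] <- read_airr(f, subject_id = mf$subject_id[i])
  }
  names(reps) <- mf$subject_id
  cohort(reps, stats::setNames(labels, mf$subject_id))
}

#' Construct a cohort from repertoires and labels
#'
#' @param repertoires named list of [repertoire()] objects.
#' @param labels named character vector (`case`/`control`), one entry per
#'   repertoire.
#' @return an object of class `cohort`.
#' @export
cohort <- function(repertoires, labels) {
  subjects <- vapply(repertoires, function(r) r$subject_id, character(1))
  names(repertoires) <- subjects
  if (!setequal(names(labels), subjects) || length(labels) != length(subjects))
    stop("labels must name every repertoire exactly once")
  labels <- labels[subjects]
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  structure(list(repertoires = repertoires, labels = labels),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort: ", length(x$repertoires), " subjects (",
      sum(x$labels == "case"), " case / ", sum(x$labels == "control"),
      " control)\n", sep = "")
  invisible(x)
}

#' Filter the records of a repertoire by simple rules
#'
#' Supported rules: `v_family` (keep records whose V call belongs to the
#' given IGHV family, e.g. `"IGHV1"`), `productive` (keep records whose
#' junction length is divisible by three and whose junction amino-acid
#' sequence contains no stop), and `min_length` (minimum number of
#' non-gap positions in the sequence alignment). The counts removed by each
#' rule are reported in attribute `removed`.
#'
#' @param x a [repertoire()].
#' @param rules named list with any of `v_family`, `productive`, `min_length`.
#' @return the filtered repertoire (record order preserved).
#' @export
filter_records <- function(x, rules = list()) {
  stopifnot(inherits(x, "repertoire"))
  known <- c("v_family", "productive", "min_length")
  bad <- setdiff(names(rules), known)
  if (length(bad) > 0L)
    stop("unknown filter rule(s): ", paste(bad, collapse = ", "))
  rec <- x$records
  keep <- rep(TRUE, nrow(rec))
  removed <- integer(0)
  if (!is.null(rules$v_family)) {
    ok <- family_of(rec$v_call) %in% rules$v_family
    removed["v_family"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (isTRUE(rules$productive)) {
    jl <- nchar(rec$junction)
    ok <- !is.na(rec$junction) & jl %% 3L == 0L & jl > 0L &
      !grepl("*", rec$junction_aa, fixed = TRUE)
    removed["productive"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!is.null(rules$min_length)) {
    ok <- nchar(gsub(".", "", rec$sequence_alignment, fixed = TRUE)) >=
      rules$min_length
    removed["min_length"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!any(keep)) stop("all records removed by filter")
  out <- repertoire(rec[keep, , drop = FALSE], x$subject_id, x$metadata,
                    validate = FALSE)
  attr(out, "removed") <- removed
  out
}

#' Read a germline segment reference from FASTA
#'
#' @param path FASTA file of germline V/D/J segments; sequences may be
#'   ungapped or IMGT-gapped (`.` gaps).
#' @param segment optional segment type for all entries (`"V"`, `"D"`,
#'   `"J"`); if `NULL` it is guessed from the name (`IGHV`/`IGHD`/`IGHJ`).
#' @return a data frame with columns `name`, `segment`, `seq`.
#' @export
read_germline_fasta <- function(path, segment = NULL) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  name <- names(fa)
  if (anyDuplicated(name)) stop("duplicate sequence names in ", path)
  seq <- normalize_nt(vapply(fa, as.character, character(1)))
  if (any(grepl("[^ACGTN.]", seq)))
    stop("germline sequences must be over A/C/G/T/N/.")
  if (is.null(segment)) {
    segment <- rep(NA_character_, length(name))
    segment[grepl("V", name)] <- "V"
    segment[grepl("D", name) & is.na(segment)] <- "D"
    segment[grepl("J", name) & is.na(segment)] <- "J"
  }
  data.frame(name = name, segment = segment, seq = unname(seq),
             stringsAsFactors = FALSE)
}
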