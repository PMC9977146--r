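# Core constants and low-level helpers shared across the package.

NUCS <- c("A", "C", "G", "T")

#' Classify a DNA 5-mer into an SHM hotspot motif class
#'
#' Somatic hypermutation concentrates at two well-characterised hotspot
#' motifs: WRC/GYW (W = A/T, R = A/G, Y = C/T), attributed to AID-mediated
#' deamination, and WA/TW, attributed to error-prone synthesis by DNA
#' polymerase eta. Classification is based on the central (third) base of the
#' 5-mer, the mutated position, and its immediate neighbours:
#'
#' * central `A` preceded by W, or central `T` followed by W -> `"wa_tw"`
#' * central `C` with W,R at positions 1,2, or central `G` with Y,W at
#'   positions 4,5 -> `"wrc_gyw"`
#' * anything else -> `"neutral"`
#'
#' The three classes partition the 1024 ACGT 5-mers into 256 WA/TW, 128
#' WRC/GYW and 640 neutral contexts (disjoint because they key on different
#' central bases).
#'
#' @param fivemer character vector of 5-mers over A/C/G/T (case-insensitive).
#' @return character vector with values `"wa_tw"`, `"wrc_gyw"`, `"neutral"`,
#'   or `NA` for strings that are not length-5 ACGT words.
#' @examples
#' classify_hotspot(c("TTACG", "TAGCA", "GGCGG"))
#' @export
classify_hotspot <- function(fivemer) {
  fivemer <- toupper(as.character(fivemer))
  out <- rep(NA_character_, length(fivemer))
  ok <- !is.na(fivemer) & nchar(fivemer) == 5L &
    !grepl("[^ACGT]", fivemer)
  if (!any(ok)) return(out)
  f <- fivemer[ok]
  b <- matrix(unlist(strsplit(f, "", fixed = TRUE), use.names = FALSE),
              ncol = 5L, byrow = TRUE)
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  wa <- (b[, 3] == "A" & b[, 2] %in% W) | (b[, 3] == "T" & b[, 4] %in% W)
  wrc <- (b[, 3] == "C" & b[, 1] %in% W & b[, 2] %in% R) |
         (b[, 3] == "G" & b[, 4] %in% Y & b[, 5] %in% W)
  cls <- rep("neutral", nrow(b))
  cls[wrc] <- "wrc_gyw"
  cls[wa] <- "wa_tw"   # disjoint from wrc by central base; order immaterial
  out[ok] <- cls
  out
}

# Enumeration of all 1024 5-mers in fixed lexicographic order, and their
# hotspot classes; position 3 is the (potentially) mutated base.
all_fivemers <- function() {
  g <- expand.grid(p5 = NUCS, p4 = NUCS, p3 = NUCS, p2 = NUCS, p1 = NUCS,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4, g$p5))
}

all_threemers <- function() {
  g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

.shm_cache <- new.env(parent = emptyenv())

fivemer_universe <- function() {
  if (is.null(.shm_cache$fivemers)) .shm_cache$fivemers <- all_fivemers()
  .shm_cache$fivemers
}

hotspot_classes <- function() {
  if (is.null(.shm_cache$hotspot))
    .shm_cache$hotspot <- stats::setNames(classify_hotspot(fivemer_universe()),
                                          fivemer_universe())
  .shm_cache$hotspot
}

# Codon -> amino acid lookup (standard code, via seqinr); "*" marks stop.
codon_table <- function() {
  if (is.null(.shm_cache$codons)) {
    g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS, stringsAsFactors = FALSE)
    codons <- paste0(g$p1, g$p2, g$p3)
    aa <- vapply(strsplit(codons, "", fixed = TRUE),
                 function(x) seqinr::translate(x), character(1))
    .shm_cache$codons <- stats::setNames(aa, codons)
  }
  .shm_cache$codons
}

translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Derive a reproducible stream seed from a master seed
#'
#' All stochastic stages (simulation, inner cross-validation folds, label
#' permutations) draw their seeds from one master seed through this
#' deterministic hash, so independent streams stay decoupled while the whole
#' analysis is reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param stream character tag naming the stream (e.g. `"perm3"`).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- as.double(master) %% 2147483647
  for (k in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Normalize nucleotide strings: uppercase, "-" -> "." (IMGT gap).
normalize_nt <- function(x) {
  chartr("-acgtn", ".ACGTN", x)
}

gene_of <- function(call) {
  # first assignment, allele suffix dropped: "IGHV1-2*02,IGHV1-3*01" -> "IGHV1-2"
  first <- sub(",.*$", "", as.character(call))
  sub("\\*.*$", "", first)
}

family_of <- function(call) {
  sub("[-/].*$", "", gene_of(call))
}
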