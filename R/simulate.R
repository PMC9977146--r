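# Synthetic AIRR cohorts: VDJ recombination with clonal expansion and
# context-dependent SHM under a configurable targeting model.

random_nt <- function(n) paste(sample(NUCS, n, replace = TRUE), collapse = "")

#' Packaged toy germline reference
#'
#' A deterministic synthetic reference of 12 IGHV-like segments (IMGT-gapped
#' to 312 positions, conserved Cys codon at 310-312, occasional gap triplets
#' in CDR1), 6 IGHD-like and 5 IGHJ-like segments (each J with its conserved
#' Trp codon at a known offset). The set is synthetic -- generated once from
#' a fixed internal seed, with realistic base composition but no relation to
#' real database alleles -- so it can ship without licensed content.
#'
#' @return data frame with columns `name`, `segment`, `seq`, plus attribute
#'   `j_trp_offset` (position of the Trp codon within each J).
#' @export
toy_germline_reference <- function() {
  if (!is.null(.shm_cache$toy_germline)) return(.shm_cache$toy_germline)
  ref <- with_seed(89123001L, {
    vs <- character(12)
    for (i in 1:12) {
      s <- random_nt(312)
      substr(s, 310, 312) <- "TGT"          # conserved Cys
      if (i %% 2 == 0) substr(s, 100, 102) <- "..."  # IMGT gap triplet, CDR1
      if (i %% 4 == 0) substr(s, 103, 105) <- "..."
      vs[i] <- s
    }
    fam <- rep(1:5, length.out = 12)
    v_names <- sprintf("IGHV%d-S%d*01", fam, seq_len(12))
    ds <- vapply(1:6, function(i) random_nt(sample(15:22, 1)), character(1))
    d_names <- sprintf("IGHD%d-S%d*01", rep(1:3, each = 2), 1:6)
    trp_off <- integer(5)
    js <- character(5)
    for (i in 1:5) {
      p <- sample(5:8, 1)                   # 5' part ahead of the Trp codon
      js[i] <- paste0(random_nt(p), "TGG", random_nt(30))
      trp_off[i] <- p + 1L
    }
    j_names <- sprintf("IGHJ%d*01", 1:5)
    out <- data.frame(name = c(v_names, d_names, j_names),
                      segment = rep(c("V", "D", "J"), c(12, 6, 5)),
                      seq = c(vs, ds, js), stringsAsFactors = FALSE)
    attr(out, "j_trp_offset") <- stats::setNames(trp_off, j_names)
    out
  })
  .shm_cache$toy_germline <- ref
  ref
}

#' Baseline 5-mer targeting model for simulations
#'
#' Mutability combines hotspot-class weights (WRC/GYW 5, WA/TW 1.5,
#' neutral 1 -- AID hotspots are the hottest contexts, polymerase-eta
#' hotspots intermediate) with a fixed per-5-mer lognormal jitter (sdlog
#' 0.3) so contexts within a class differ, as they do in empirical targeting
#' models. Substitution is transition-biased (transition 0.5, each
#' transversion 0.25). The model is deterministic: the jitter comes from a
#' fixed internal seed.
#'
#' @return a [targeting_model()].
#' @export
baseline_targeting_model <- function() {
  if (!is.null(.shm_cache$baseline_model)) return(.shm_cache$baseline_model)
  fm <- fivemer_universe()
  cls <- hotspot_classes()
  w <- c(neutral = 1, wa_tw = 1.5, wrc_gyw = 5)[cls[fm]]
  jit <- with_seed(55510007L, stats::rlnorm(length(fm), 0, 0.3))
  mut <- stats::setNames(as.numeric(w) * jit, fm)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  sub <- matrix(0.25, nrow = length(fm), ncol = 4, dimnames = list(fm, NUCS))
  center <- substr(fm, 3, 3)
  for (b in NUCS) {
    sub[center == b, transition[[b]]] <- 0.5
    sub[center == b, b] <- NA_real_
  }
  m <- targeting_model(mut, substitution = sub)
  .shm_cache$baseline_model <- m
  m
}

#' Simulation configuration
#'
#' @param n_subjects subjects per group (default 25, a typical single-centre
#'   clinical cohort).
#' @param n_sequences sequences per subject (default 2000).
#' @param clone_exponent power-law exponent of the clone-size distribution
#'   (`P(s) ~ s^-exponent`, default 2.5; values near 1 give dominant
#'   expanded clones).
#' @param max_clone_size truncation of the clone-size distribution.
#' @param expected_mutations Poisson mean of mutations per sequence (default
#'   15, the order of magnitude seen in mucosal memory B cells).
#' @param effect_motif hotspot class whose mutability is shifted in the case
#'   group (`"wa_tw"`, `"wrc_gyw"` or `"neutral"`).
#' @param effect_factor multiplicative shift applied to `effect_motif`
#'   mutabilities in cases (1 = null cohort).
#' @param subject_sdlog per-subject lognormal variation (sdlog) of the
#'   overall activity of each motif class, modelling inter-individual
#'   differences in the AID / polymerase-eta balance (default 0.2).
#' @param baseline baseline [targeting_model()] shared by all subjects.
#' @param germline germline reference data frame (default
#'   [toy_germline_reference()]).
#' @param track_mutations keep the true per-sequence mutation lists in the
#'   ground truth (memory-heavy for large cohorts).
#' @param seed master seed; every stream below it is derived
#'   deterministically.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 25L, n_sequences = 2000L,
                              clone_exponent = 2.5, max_clone_size = 100L,
                              expected_mutations = 15,
                              effect_motif = "wa_tw", effect_factor = 1,
                              subject_sdlog = 0.2,
                              baseline = baseline_targeting_model(),
                              germline = toy_germline_reference(),
                              track_mutations = FALSE, seed = 1L) {
  stopifnot(n_subjects > 0, n_sequences > 0, expected_mutations >= 0,
            effect_factor > 0, clone_exponent > 0)
  effect_motif <- match.arg(effect_motif, c("wa_tw", "wrc_gyw", "neutral"))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sequences = as.integer(n_sequences),
                 clone_exponent = clone_exponent,
                 max_clone_size = as.integer(max_clone_size),
                 expected_mutations = expected_mutations,
                 effect_motif = effect_motif, effect_factor = effect_factor,
                 subject_sdlog = subject_sdlog,
                 baseline = baseline, germline = germline,
                 track_mutations = isTRUE(track_mutations),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Multiply the mutability of one motif class by `factor` and renormalise.
shift_motif_class <- function(model, motif, factor) {
  cls <- hotspot_classes()
  m <- model$mutability
  sel <- cls[names(m)] == motif
  m[sel] <- m[sel] * factor
  targeting_model(m, substitution = model$substitution,
                  background_count = model$background_count)
}

# Per-subject true model: class-level lognormal activity noise, then the
# case-group effect for case subjects.
subject_true_model <- function(config, group, subject_seed) {
  m <- config$baseline$mutability
  cls <- hotspot_classes()[names(m)]
  fac <- with_seed(subject_seed,
                   stats::rlnorm(3, 0, config$subject_sdlog))
  names(fac) <- c("neutral", "wa_tw", "wrc_gyw")
  m <- m * fac[cls]
  model <- targeting_model(m, substitution = config$baseline$substitution,
                           background_count = config$baseline$background_count)
  if (group == "case" && config$effect_factor != 1)
    model <- shift_motif_class(model, config$effect_motif,
                               config$effect_factor)
  model
}

# One clone founder: V + trimmed D + trimmed J with N-insertions; the
# junction runs from the V Cys codon (gapped 310-312) through the J Trp
# codon and is kept in frame and stop-free by construction.
make_founder <- function(config, clone_tag) {
  ref <- config$germline
  vs <- ref[ref$segment == "V", ]
  ds <- ref[ref$segment == "D", ]
  js <- ref[ref$segment == "J", ]
  trp <- attr(config$germline, "j_trp_offset")
  for (try in 1:25) {
    vi <- sample.int(nrow(vs), 1)
    di <- sample.int(nrow(ds), 1)
    ji <- sample.int(nrow(js), 1)
    dseq <- ds$seq[di]
    t5 <- sample.int(min(6L, nchar(dseq) - 3L), 1) - 1L
    t3 <- sample.int(min(6L, nchar(dseq) - 3L - t5), 1) - 1L
    dcore <- substr(dseq, t5 + 1L, nchar(dseq) - t3)
    p <- trp[[js$name[ji]]] - 1L          # J bases ahead of the Trp codon
    tj <- sample.int(p, 1) - 1L           # 5' J trim, Trp always retained
    jseq <- substr(js$seq[ji], tj + 1L, nchar(js$seq[ji]))
    n1 <- sample.int(7L, 1) - 1L
    n2 <- sample.int(7L, 1) - 1L
    jl <- 3L + n1 + nchar(dcore) + n2 + (p - tj) + 3L
    n1 <- n1 + (3L - jl %% 3L) %% 3L      # pad insertion to keep frame
    ins1 <- if (n1 > 0) random_nt(n1) else ""
    ins2 <- if (n2 > 0) random_nt(n2) else ""
    tail_seq <- paste0(ins1, dcore, ins2, jseq)
    junction <- paste0("TGT", ins1, dcore, ins2,
                       substr(jseq, 1L, p - tj + 3L))
    junction_aa <- translate_nt(junction)
    if (grepl("*", junction_aa, fixed = TRUE)) next
    aln <- paste0(vs$seq[vi], tail_seq)
    return(list(sequence_alignment = aln,
                v_call = vs$name[vi], d_call = ds$name[di],
                j_call = js$name[ji],
                junction = junction, junction_aa = junction_aa,
                clone_tag = clone_tag))
  }
  stop("could not build a stop-free junction after 25 attempts")
}

#' Simulate a naive (unmutated) repertoire with clonal structure
#'
#' Clone founders are built by VDJ recombination over the configured germline
#' reference (random trimming of D and J, random N-insertions, frame- and
#' stop-free junctions); clone sizes follow a truncated power law, and clone
#' members copy the founder sequence exactly (all intra-clone variation is
#' introduced later by SHM). The founder sequence doubles as the
#' `germline_alignment` of every member.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed for this repertoire.
#' @param subject_id subject identifier.
#' @return list with `repertoire` (a [repertoire()]) and `truth` (clone
#'   membership data frame).
#' @export
simulate_naive_repertoire <- function(config, seed, subject_id = "sim") {
  with_seed(seed, {
    sizes <- integer(0)
    total <- 0L
    s_support <- seq_len(config$max_clone_size)
    s_prob <- s_support^(-config$clone_exponent)
    while (total < config$n_sequences) {
      s <- sample(s_support, 1, prob = s_prob)
      s <- min(s, config$n_sequences - total)
      sizes <- c(sizes, s)
      total <- total + s
    }
    founders <- lapply(seq_along(sizes), function(k)
      make_founder(config, sprintf("true_clone_%04d", k)))
    rows <- vector("list", length(sizes))
    seq_no <- 0L
    for (k in seq_along(sizes)) {
      f <- founders[[k]]
      ids <- sprintf("%s_seq%05d", subject_id, seq_no + seq_len(sizes[k]))
      seq_no <- seq_no + sizes[k]
      rows[[k]] <- data.frame(sequence_id = ids,
                              v_call = f$v_call, d_call = f$d_call,
                              j_call = f$j_call,
                              junction = f$junction,
                              junction_aa = f$junction_aa,
                              sequence_alignment = f$sequence_alignment,
                              germline_alignment = f$sequence_alignment,
                              duplicate_count = 1L,
                              stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rows)
    truth <- data.frame(sequence_id = rec$sequence_id,
                        clone = rep(vapply(founders, `[[`, character(1),
                                           "clone_tag"), sizes),
                        stringsAsFactors = FALSE)
    list(repertoire = repertoire(rec, subject_id, validate = FALSE),
         truth = truth)
  })
}

# Mutation machinery shared by apply_shm() and the cohort simulator.
# `prof` is a germline_profile(); weights fall back to the smallest present
# mutability for contexts the model does not cover. The mutability vector and
# substitution matrix are indexed numerically (they are always aligned with
# fivemer_universe()), which keeps the per-record cost low.
draw_mutations <- function(prof, model, expected) {
  informative <- prof$informative
  if (length(informative) == 0L) return(NULL)
  mut_num <- unname(model$mutability)
  w <- mut_num[prof$context_idx[informative]]
  w[is.na(w)] <- 0            # contexts absent from the model never mutate
  if (all(w == 0)) w[] <- 1   # fully uncovered sequence: uniform placement
  n <- stats::rpois(1, expected)
  if (n == 0L) return(NULL)
  n_avail <- sum(w > 0)
  if (n > n_avail) {
    warning("requested more mutations than mutable positions; truncating")
    n <- n_avail
  }
  sel <- sample.int(length(informative), n, prob = w)
  picks <- informative[sel]
  from <- prof$ungapped[picks]
  P <- model$substitution[prof$context_idx[informative][sel], , drop = FALSE]
  P[is.na(P)] <- 0
  zero <- rowSums(P) == 0                  # uncovered context: uniform
  if (any(zero)) {
    U <- matrix(1 / 3, sum(zero), 4, dimnames = list(NULL, NUCS))
    U[cbind(seq_len(sum(zero)), match(from[zero], NUCS))] <- 0
    P[zero, ] <- U
  }
  P <- P / rowSums(P)
  u <- stats::runif(n)
  cum1 <- P[, 1]; cum2 <- cum1 + P[, 2]; cum3 <- cum2 + P[, 3]
  to <- NUCS[1L + (u > cum1) + (u > cum2) + (u > cum3)]
  list(ungapped = picks, gapped = prof$gapped_pos[picks],
       from = from, to = to, context = prof$context[picks])
}

#' Introduce context-dependent somatic hypermutation into a record
#'
#' The number of mutations is Poisson(`expected_mutations`); positions are
#' drawn without replacement with probability proportional to the model
#' mutability of the germline 5-mer context (contexts absent from the model
#' fall back to the smallest present mutability), and the replacement base
#' follows the model's substitution row. Contexts are always evaluated on
#' the founder germline -- they are not updated between mutations -- which
#' matches how the estimator counts mutations against germline context.
#'
#' @param record one-row data frame with `sequence_alignment` and
#'   `germline_alignment` (typically a naive simulated record).
#' @param model a [targeting_model()].
#' @param expected_mutations Poisson mean.
#' @param seed optional seed.
#' @return list with `record` (mutated copy) and `mutations` (data frame of
#'   true mutations: gapped position, context, from, to).
#' @export
apply_shm <- function(record, model, expected_mutations = 15, seed = NULL) {
  with_seed(seed, {
    prof <- germline_profile(normalize_nt(record$germline_alignment[1]))
    mu <- draw_mutations(prof, model, expected_mutations)
    rec <- record
    if (is.null(mu)) {
      muts <- data.frame(position = integer(0), context = character(0),
                         from = character(0), to = character(0))
    } else {
      chars <- strsplit(normalize_nt(record$sequence_alignment[1]), "",
                        fixed = TRUE)[[1]]
      chars[mu$gapped] <- mu$to
      rec$sequence_alignment <- paste(chars, collapse = "")
      muts <- data.frame(position = mu$gapped, context = mu$context,
                         from = mu$from, to = mu$to,
                         stringsAsFactors = FALSE)
    }
    list(record = rec, mutations = muts)
  })
}

#' @export
simulate.targeting_model <- function(object, nsim = 1, seed = NULL,
                                     repertoire, expected_mutations = 15,
                                     ...) {
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("sim", s))
    out[[s]] <- mutate_repertoire(repertoire, object, expected_mutations,
                                  rep_seed %||% sample.int(2^30, 1))$repertoire
  }
  if (nsim == 1) out[[1]] else out
}

# Mutate every record of a (naive) repertoire under one model. Germline
# profiles are cached per founder, so clone members are cheap.
mutate_repertoire <- function(x, model, expected_mutations, seed,
                              track = FALSE) {
  with_seed(seed, {
    cache <- new.env(parent = emptyenv())
    rec <- x$records
    seqs <- rec$sequence_alignment
    tracked <- if (track) vector("list", nrow(rec)) else NULL
    for (i in seq_len(nrow(rec))) {
      prof <- germline_profile(rec$germline_alignment[i], cache)
      mu <- draw_mutations(prof, model, expected_mutations)
      if (!is.null(mu)) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        chars[mu$gapped] <- mu$to
        seqs[i] <- paste(chars, collapse = "")
        if (track)
          tracked[[i]] <- data.frame(sequence_id = rec$sequence_id[i],
                                     position = mu$gapped,
                                     context = mu$context,
                                     from = mu$from, to = mu$to,
                                     stringsAsFactors = FALSE)
      }
    }
    rec$sequence_alignment <- seqs
    list(repertoire = repertoire(rec, x$subject_id, x$metadata,
                                 validate = FALSE),
         mutations = if (track) do.call(rbind, tracked) else NULL)
  })
}

#' Simulate a labelled case/control cohort
#'
#' Control subjects are mutated under per-subject variants of the baseline
#' targeting model (class-level lognormal activity noise); case subjects
#' additionally receive the configured motif-class mutability shift
#' (renormalised). Everything is reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (a [cohort()]) and `truth` (per-subject true
#'   models, clone memberships, and -- when `track_mutations` -- true
#'   mutation lists).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  groups <- c(rep("control", config$n_subjects),
              rep("case", config$n_subjects))
  ids <- c(sprintf("ctrl%02d", seq_len(config$n_subjects)),
           sprintf("case%02d", seq_len(config$n_subjects)))
  reps <- vector("list", length(ids))
  truth <- list(models = list(), clones = list(), mutations = list())
  for (i in seq_along(ids)) {
    model <- subject_true_model(config, groups[i],
                                derive_seed(config$seed,
                                            paste0("model_", ids[i])))
    naive <- simulate_naive_repertoire(config,
                                       derive_seed(config$seed,
                                                   paste0("vdj_", ids[i])),
                                       subject_id = ids[i])
    mut <- mutate_repertoire(naive$repertoire, model,
                             config$expected_mutations,
                             derive_seed(config$seed,
                                         paste0("shm_", ids[i])),
                             track = config$track_mutations)
    reps[[i]] <- mut$repertoire
    truth$models[[ids[i]]] <- model
    truth$clones[[ids[i]]] <- naive$truth
    if (config$track_mutations) truth$mutations[[ids[i]]] <- mut$mutations
  }
  names(reps) <- ids
  list(cohort = cohort(reps, stats::setNames(groups, ids)), truth = truth)
}

#' Write a simulated cohort as AIRR files plus a manifest
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- sim$cohort
  files <- character(length(x$repertoires))
  for (i in seq_along(x$repertoires)) {
    files[i] <- paste0(names(x$repertoires)[i], ".tsv")
    write_airr(x$repertoires[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(subject_id = names(x$repertoires),
                         file = files, label = unname(x$labels))
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
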