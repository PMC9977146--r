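---
title: "Classifying BCR repertoires by somatic hypermutation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying BCR repertoires by somatic hypermutation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmclass)
```

## The problem

B cells diversify their receptors (BCRs) twice: first by V(D)J
recombination, then by somatic hypermutation (SHM) during affinity
maturation. SHM is not uniform along the gene — activation-induced deaminase
(AID) preferentially attacks WRC/GYW motifs (W = A/T, R = A/G, Y = C/T,
mutated base central) and the error-prone polymerase eta leaves its mark at
WA/TW motifs. A sequenced repertoire therefore carries, beyond its clonal
composition, a *mutation-pattern fingerprint*: how often each local DNA
context mutated and what it mutated into.

`shmclass` asks whether that fingerprint, summarised per subject as a 5-mer
targeting model, can separate a disease cohort from controls when no single
conventional repertoire feature (CDR3 length, mutation load, diversity, gene
usage) does. It provides the whole chain: AIRR-format I/O, clonal inference,
targeting-model estimation, hotspot dissection, repertoire featurization,
penalised classification under leave-one-out cross-validation, and a
simulator that generates cohorts with known ground truth so that every stage
can be verified without patient data.

## The 5-mer targeting model

For a repertoire of sequences aligned to their inferred germlines, and for
every DNA 5-mer $w$ (1024 of them), the estimator counts

* $b(w)$ — *background*: informative germline positions whose centred 5-mer
  is $w$ (window entirely A/C/G/T, not running off either end), and
* $m(w)$ — *mutations*: positions with germline context $w$ where the
  observed base differs from the germline base.

The mutability is the normalised rate
$\mu(w) = \frac{m(w)/b(w)}{\sum_v m(v)/b(v)}$, read as the probability that
a mutation happens in context $w$. The substitution profile $s(w, b)$ is the
empirical distribution of replacement bases given $w$, and targeting is the
product $\tau(w, b) = \mu(w)\, s(w, b)$. Because sequences are compared to
their germline (not to ancestors along a lineage tree), the model captures
the *combined* effect of SHM targeting and antigen-driven selection; the
synonymous-only variant (`synonymous_only = TRUE`) suppresses most of the
selection component.

Choices worth knowing:

* **Minimum background** (`min_background = 10`): a context seen fewer than
  10 times yields a rate with useless variance; its mutability is *absent*
  (`NA`), never zero. Absent features are mean-imputed from training folds
  at classification time, so no information leaks from held-out subjects.
* **Contexts come from the germline**, also when mutations are adjacent:
  with ~15 mutations per ~350 nt sequence, context updating would change
  few windows but make the estimator path-dependent.
* **No 5-mer-to-3-mer fallback** for sparse contexts (unlike some published
  targeting-model implementations): absent means absent, which keeps the
  estimator exactly testable against a brute-force oracle.
* **Frame and regions**: codons start at position 1 of the IMGT-gapped
  alignment and IMGT gaps occur in codon triplets, so synonymy is decidable
  per codon on gapped coordinates. FWR/CDR masks use the IMGT V-region
  nucleotide boundaries (FR1 1–78, CDR1 79–114, FR2 115–165, CDR2 166–195,
  FR3 196–312); positions beyond 312 (junction and J) are not IMGT-numbered
  here, are labelled `unknown`, and drop out whenever a region mask is
  active.

The 3-mer collapse averages the sixteen 5-mers sharing a central 3-mer,
weighted by background counts, then renormalises; it is invariant to global
rescaling of the input model.

## From repertoires to a classifier

Feature families (`assemble_feature_table()`): V and V–J gene usage, CDR3
amino-acid k-mers (CDR3 = junction minus its conserved flanking residues),
V–J–CDR3-length cluster frequencies (retained when reaching frequency 0.001
in at least one subject, inclusive), cross-subject CDR3 identity clusters
(greedy centroid joining at ≥ 85% identity, canonical order by descending
count then lexical — deterministic and linear, where a full hierarchical
clustering would buy nothing at these sizes), Hill diversity over clone
abundances, and the flattened SHM model (`mut|AACGT`, `sub|AACGT>T`,
`targ|AACGT>T`), optionally restricted to one hotspot class.

Classification follows the classical screen-then-shrink recipe:

1. **Screening**: per feature, a two-sample pooled-variance Student's
   t-test on the training subjects; the `top_k` smallest p-values are kept
   (30 by default; 200 is conventional for the full SHM matrix; 0 disables
   screening). The t-test is a ranking device, so no multiplicity
   correction applies.
2. **Elastic-net logistic regression** (glmnet): standardisation and
   imputation parameters from training rows only;
   $(\alpha, \lambda)$ chosen by 3-fold stratified inner CV over
   $\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$ and a 30-point log-spaced
   $\lambda$ path spanning four decades.
3. **Leave-one-out**: each subject predicted by a model that never saw it —
   screening included — under the default `per_fold` scope. A `global`
   scope (screen once on everyone) is provided deliberately: descriptions
   of this design in the literature are ambiguous between the two, and the
   difference is exactly a leakage; both variants are exposed so the
   comparison can be made. Predicted case when the probability exceeds 0.5;
   an exact tie predicts control, a measure-zero determinism guarantee.

Metrics (F1 with case positive, accuracy, sensitivity, specificity) carry
95% Clopper–Pearson intervals treating each metric as a proportion of the
number of subjects — an acknowledged approximation for F1 and the
class-conditional rates, chosen because it is the standard "binomial CI"
reading and is monotone in the metric. Undefined metrics (zero denominator)
are reported as undefined, never as 0. Every result should be compared with
its shuffled-label null (`shuffled_label_null()`): labels permuted with
class sizes preserved, the entire leave-one-out pipeline re-run; for a
balanced cohort the null F1 median sits near 0.5.

Clonal inference groups sequences by V gene, J gene and junction length,
then single-links junctions at normalized Hamming distance ≤ 0.15 (the
conventional heavy-chain threshold; configurable). N positions never count
as mismatches. Ties and labels are deterministic given input order, and the
partition is order-invariant up to relabelling.

## What the simulator emulates — and what it does not

`simulate_cohort()` builds AIRR cohorts from a packaged *synthetic*
germline set (IGHV-like, IMGT-gapped, conserved Cys/Trp junction flanks; no
relation to database alleles, so nothing licensed ships with the package):

* VDJ recombination with random D/J trimming and N-insertions; junctions
  kept in frame and stop-free, as IgBlast-annotated productive data would
  be.
* Clonal expansion with truncated power-law clone sizes (exponent 2.5,
  cap 100). Clone members copy the founder before SHM, so clone ground
  truth is exact.
* Context-dependent SHM: Poisson(15) mutations per sequence — the order of
  magnitude of mucosal memory B cells — placed without replacement with
  probability proportional to mutability of the *founder* germline context,
  substitutions from the model's profile. Contexts the model does not cover
  never mutate (or, for a fully absent model, mutate uniformly).
* The baseline model gives hotspot classes weights WRC/GYW 5, WA/TW 1.5,
  neutral 1 (AID hotspots hottest, polymerase-eta intermediate, as in
  empirical targeting models), a fixed per-5-mer lognormal jitter (sdlog
  0.3) so contexts within a class differ, and transition-biased
  substitution (0.5/0.25/0.25).
* **Inter-individual variation**: each subject's true model multiplies each
  hotspot class by a lognormal factor (sdlog 0.2), modelling individual
  AID/polymerase-eta balance. This matters: because mutability is
  normalised per subject, a case-group WA/TW shift mechanically depresses
  the *relative* mutability of every other context by a common factor.
  Without between-subject class-level variability that artefactual common
  factor would itself be learnable from WRC/GYW features; with realistic
  class-level noise (sdlog 0.2, larger than the ~0.1 log-shift a 1.5-fold
  WA/TW effect induces on other classes) only the directly shifted motif
  class carries a reliably learnable signal. These values were fixed by
  this power reasoning at design time.
* The case effect multiplies one motif class's mutability (WA/TW by
  default) and renormalises.

Not modelled: allele-level germline diversity, isotypes and class
switching, selection dynamics beyond the targeting model, sequencing error,
FFPE fragmentation noise, and intra-clone junction variation. Passing
recovery and effect-detection tests therefore demonstrates that the
*estimator and classifier* behave correctly under the stated generative
assumptions — not that real cohorts of this size are separable; real-data
noise sources are systematically larger.

## Reproducibility and problem sizes

All randomness flows from one master seed through `derive_seed()` (a
deterministic string-keyed hash), so simulation, inner CV folds and label
permutations use decoupled reproducible streams. The package's own
validation runs at these sizes, chosen as the smallest scales at which the
properties are meaningful: cohorts of 20 + 20 subjects with 2000 sequences
each for null-distribution and effect-detection checks (25 label
permutations each); single repertoires of 500–5000 sequences for recovery
of a known targeting model (Spearman rho ≥ 0.9 at 5000); repertoires of
≤ 50 sequences for exact agreement with a nested-loop counting oracle; and
small algebraic fixtures for closed forms (Hill numbers, confusion-matrix
metrics, Clopper–Pearson bounds, penalty limits of the elastic net).

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_subjects = 10, n_sequences = 500,
                         effect_factor = 1.5, seed = 7)
sim <- simulate_cohort(cfg)

m <- estimate_targeting_model(sim$cohort$repertoires[[1]])
summary(m)
plot(m)

exp_cfg <- experiment_config(
  runs = standard_runs(c("v_usage", "shm_wa_tw", "shm_wrc_gyw")),
  top_k = 30, n_permutations = 10, seed = 7)
report <- run_experiment(sim$cohort, exp_cfg)
report
```

## Known limitations

* The targeting model conflates SHM targeting with selection; the
  synonymous-only switch mitigates but does not remove this (synonymous
  codon usage is itself under weak selection).
* The Clopper–Pearson interval on F1 is heuristic (F1 is not a binomial
  proportion of n subjects).
* Clone abundance weighting defaults to unique sequences (appropriate for
  DNA libraries that sample cells uniformly); duplicate-count weighting is
  available for RNA/UMI data.
* Non-productive rearrangements are kept by default — they still inform
  background counts — with `filter_records()` available to drop them; this
  default is a documented choice, not a community consensus.
* Sequences beyond IMGT position 312 lack region labels, so region-masked
  models ignore CDR3.
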