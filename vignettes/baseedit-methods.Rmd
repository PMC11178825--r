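---
title: "Methods: models, parameters and design choices in baseedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in baseedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baseedit)
```

# Scope

`baseedit` characterizes cytosine, adenine and dual base editors from two
kinds of input: targeted amplicon reads (FASTQ plus a target-site table) and
per-plant variant tables (VCF plus a reference genome and gRNA list). This
vignette documents the statistical models, the tunable parameters, the
numerical conventions, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# Coordinate and outcome conventions

* Protospacer positions are numbered 1 (PAM-distal 5' end) to 20
  (PAM-proximal); the PAM occupies the three bases immediately 3' of
  position 20 on the protospacer strand. This matches the convention in
  which TadA-derived editors act around positions 4-8.
* Genomic intervals are 0-based half-open internally (BED-style); VCF-facing
  positions are 1-based.
* Read outcomes form seven classes: `WT`, `C_TO_T`, `A_TO_G`,
  `SIMULTANEOUS`, `C_TO_G`, `OTHER_SUB`, `INDEL`, assigned by fixed
  precedence `SIMULTANEOUS` (at least one C→T *and* one A→G) > `C_TO_T` >
  `A_TO_G` > `C_TO_G` > `OTHER_SUB` > `WT`; any alignment gap overlapping
  the protospacer+PAM footprint makes the read `INDEL` regardless of
  substitutions. Simultaneous editing is its own category because dual
  editors are defined by it; keeping per-position numerators marginal while
  class tallies partition the reads lets one table serve both purposes.

# Read simulation model

`simulate_amplicon_reads()` draws, per read:

1. **Conversions.** Each protospacer position carrying the substrate base
   (C for C→T/C→G, A for A→G) converts with its profile probability. At a C
   position, C→T and C→G compete for the same base; their probabilities
   partition a single uniform draw and may not sum above 1. A positive
   probability at a position whose base cannot undergo the conversion is
   rejected with an error — a profile is only meaningful relative to a
   protospacer, and `restrict_profile()` exists to mask a generic editor
   profile onto a concrete site (the modeling counterpart of "no editable A
   in the window means no A→G editing").
2. **Co-occurrence.** Under `independent`, every position uses its own
   uniform draw. Under `linked`, one uniform draw per read is shared by all
   positions: position *i* converts iff *u* < *p&#8205;ᵢ*. This comonotone
   coupling preserves every marginal rate exactly while making all window
   conversions activate together, which reproduces the simultaneous
   C→T + A→G top alleles a dual editor produces without introducing a
   multi-parameter dependence model.
3. **Indels.** With probability `indel_rate` per read, one indel of length
   1-5 bp (uniform; insertion or deletion with equal probability) is
   anchored uniformly inside the protospacer. Aggregate indel frequency is
   the only quantity reported downstream, so any small-indel model with the
   right rate suffices.
4. **Sequencing error.** Uniform substitution at `seq_error_rate` per base,
   applied after editing and indels. There is no quality model; FASTQ
   qualities are written as constant Q37. PCR duplicates, chimeras and
   primer bias are out of scope.

Truth labels record the *editing* outcome (before sequencing error), so rate
recovery can be measured against the generating probabilities.

Default preset magnitudes (`preset_profile()`: peak 0.5, window 4-8 narrow
editors, 3-16 broad APOBEC-style editor) are plausible illustrative values —
per-position rates for real editors are only published graphically, so the
presets are labeled presets, never measurements.

# Alignment and classification

Reads are aligned to the amplicon globally with affine gaps (match +2,
mismatch −1, gap open −6, gap extend −1, via Biostrings). These scores are
not dictated by any published pipeline; they were chosen so that a ~250 bp
amplicon read with a few tenths of a percent substitution error aligns
without spurious gaps while small real indels still open one. Reads whose
alignment identity over the amplicon falls below `min_identity` (default
0.6) are discarded but counted — read accounting
(`WT + edited classes + INDEL + discarded = input`) is exact and tested.

Full-length reads with ≥ 90% identity take a gap-free fast path (direct
positional comparison); a property test asserts the fast path agrees with an
independently written per-read string-comparison oracle on 100% of gap-free
reads.

Efficiency denominators exclude indel and discarded reads: substitution
efficiency and indel frequency are reported as separate quantities, which is
how amplicon characterization figures are conventionally drawn. Both the
read-fraction site-level efficiency (default headline) and the
max-per-position variant are emitted, since published "site efficiency" can
mean either; the read fraction is the default because it is the quantity the
allele table normalizes to.

# Editing-window inference

`aggregate_positions()` averages per-position efficiencies across sites,
using at each (position, conversion) only the sites whose reference base
there admits the conversion; SEM uses the sample standard deviation (n − 1)
and is undefined below two eligible sites. `infer_window()` then takes the
maximal contiguous run of positions with mean ≥ `threshold_fraction` × peak
mean (default 0.5, i.e. half-max; ties between equal-length runs resolve to
the run containing the argmax; positions with no eligible site break runs).
Editing windows are described verbally in the literature rather than
defined; half-max is a standard peak-width convention and the fraction is an
explicit tunable. No curve fitting or smoothing is applied.

# Off-target search and attribution

`enumerate_sites()` scans every 20-mer window on both strands of every
chromosome, counting case-insensitive Hamming mismatches against each gRNA
(non-ACGT bases always mismatch) and requiring the adjacent 3-nt PAM to
match an IUPAC pattern. The scan is a vectorized exhaustive pass (integer
comparison per protospacer position over the whole chromosome), so its
complexity is O(23 × genome length) per gRNA and strand; no seed-filter
heuristic is used. Relaxed NG PAMs are encoded as the fixed-length pattern
`"NGN"`. Bulge-tolerant (gapped) matching is out of scope, and the default
off-target PAM is `NGG` (configurable) since the stricter constraint is the
conventional screen. A test asserts set-identity against an independent
oracle built on `Biostrings::matchPattern` with `max.mismatch`, across
budgets 0-3 and patterns NGG/NGN on genomes with planted sites at 0-4
mismatches, plus budget monotonicity and strand symmetry.

`attribute_snvs()` intersects SNVs with candidate protospacer intervals
(GenomicRanges), reports the protospacer position (1 = PAM-distal) and the
conversion on the protospacer strand (minus-strand candidates complement
ref/alt), and flags a result consistent when the conversion is one a base
editor produces (C>T, A>G, C>G).

# Cohort model and variant profiling

`simulate_plant_cohort()` plants specified edits (site, protospacer
position, protospacer-strand conversion, allele frequency) in every plant,
validating that the genome reference base matches — a planted C→T at a
minus-strand site is recorded as G→A at genome coordinates. Background
somaclonal-style SNVs are Poisson per plant; each drawn from a six-class
pyrimidine-anchored spectrum, placed uniformly on genome positions carrying
the class base or its complement, with allele frequencies from a
subclonal / heterozygous / homozygous mixture drawn strictly inside the
classification bands (0.05-0.29, 0.31-0.69, 0.71-1.0) so planted zygosity
labels are recoverable exactly. Background indels (1-3 bp, VCF-style
anchored ref/alt) are simulated at a separate Poisson rate. An `avoid` list
of intervals lets tests keep background variants out of candidate sites.

Zygosity thresholds are strict: AF > 0.7 homozygous/biallelic,
AF > 0.3 heterozygous, else subclonal — boundary values fall to the lower
class, following the "> 30%" / "> 70%" convention for mutation and
biallelic-mutation calls in regenerated diploid plants. The
germline-transmittable fraction is defined as heterozygous ∪ homozygous.
Allele frequency is read from the `AF` INFO field; when absent it is
computed from AD-style allele depths, and records with neither are rejected
with a count. Multi-allelic records split into one row per ALT.

Motif context extracts the 3-mer around each mutated base on the strand
where that base is C (C→T/G→A) or A (A→G/T→C), so the mutated base sits at
position 2; information content is R = 2 − H bits with H the plug-in
Shannon entropy, no small-sample correction — the quantity a standard
sequence-logo tool draws. Chromosome-edge records lacking a full flank are
skipped and counted.

RNA-mode tables (`molecule = "RNA"`) reuse every operation unchanged:
C-to-U events appear as the C>T class and A-to-I as T>C, which is exactly
how RNA-seq variant callers report them.

# Pipeline, determinism and statistics

All randomness flows from explicit integer seeds through one local RNG
scope per generator call (`with_rng()` saves and restores the caller's RNG
state), so identical (spec, seed) pairs are byte-identical, which
`run_pipeline()` surfaces as md5 checksums in its manifest. Config
validation runs before any computation: thresholds must sit in their
documented ranges (zygosity cutoffs strictly ordered inside (0,1), mismatch
budget 0-6, window fraction and identity floor in (0,1)).

Two statistical conventions used by the tests are worth stating:

* Rate recovery is asserted at positions with stipulated nonzero
  probability, within 4 binomial standard errors
  √(p(1−p)/n) of the generating p. At p = 0 the binomial SE is zero and any
  sequencing-error read would fail vacuously, so null positions are checked
  implicitly through the error model instead.
* Spectrum recovery is asserted in the joint multinomial 99% acceptance
  region via the chi-square goodness-of-fit statistic (df = 5) rather than
  six marginal binomial bands; marginal bands reject a correct sampler in
  roughly 6% of runs purely by multiplicity.

# Problem sizes

The test suite and acceptance script use sizes chosen to make the binomial
and Poisson bands tight enough to be informative while keeping a full run
in the tens of seconds on one CPU: 10,000 reads per site for rate recovery
(SE ≤ 0.005 at p = 0.5), five designed sites × 5,000 reads for window
recovery, 100-kb genomes for off-target scans, cohorts of ~650 background
SNVs for attribution specificity, and n ≈ 1,000 SNVs for spectrum recovery.

# What the generator does and does not emulate

The simulator reproduces the statistical structure that the estimators
consume: per-position conversion rates inside/outside a window, linked dual
editing, low indel rates, uniform sequencing error, Poisson background SNV
loads with a six-type spectrum and an AF mixture, and planted off-target
sites at exact mismatch counts on both strands. It does not model PCR
amplification artifacts, quality-dependent or context-dependent sequencing
error, structural variants, caller-specific biases, or linkage between
background variants. Passing tests therefore demonstrate the correctness of
the estimators under the stated generative model, not the end-to-end
accuracy of upstream alignment and variant calling on real reads — those
stages are deliberately upstream of this package, which consumes their
outputs.

# Known limitations

* Off-target search is mismatch-only (no DNA/RNA bulges) and fixed to
  3-nt PAMs.
* The aligner is exact Needleman-Wunsch per read; throughput relies on the
  gap-free fast path, so data with very high indel rates will be slower.
* Window inference assumes a unimodal activity profile; a genuinely bimodal
  editor would report only the taller mode's run.
* Zygosity is inferred from allele frequency alone; it does not model
  copy-number variation or chimeric tissue composition beyond the
  subclonal class.
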