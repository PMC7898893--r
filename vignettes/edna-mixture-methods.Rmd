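---
title: "Estimating population allele frequencies and contributor counts from eDNA: models and methods"
author: "ednamix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population allele frequencies and contributor counts from eDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednamix)
```

## The problem

A water sample contains DNA shed by an unknown number of individuals of a
target species.  Sequencing a panel of multiallelic microsatellite loci
from that environmental DNA (eDNA) yields, per locus, a set of detected
alleles and their read counts.  `ednamix` addresses two questions:

1. How well do allele frequencies estimated from eDNA read frequencies
   agree with frequencies estimated from genotyped tissue samples?
2. How many distinct diploid individuals contributed DNA to the sample?

The second question is answered with a DNA-mixture estimator of the kind
developed in criminal forensics: it uses only the *presence* of alleles
and their population frequencies, not eDNA concentration, so it targets
absolute abundance rather than a correlative index.

## The masked-allele mixture model

Let a locus show $n$ distinct alleles $A = a_1, \dots, a_n$ with
population frequencies $p_1, \dots, p_n$.  If $x$ diploid individuals
contributed, the mixture contains $2x$ gene copies, of which
$d = 2x - n$ are *masked*: present but hidden behind an already-observed
allele.  Treating the $2x$ copies as independent draws from the
population (no relatedness, no substructure), the probability that
exactly the set $A$ is observed is the sum of multinomial probabilities
over all allocations $g_i \ge 1$, $\sum g_i = 2x$ of copies to observed
alleles:

$$
L(x \mid A, p) \;=\; \sum_{\{g_i \ge 1,\ \sum g_i = 2x\}}
\frac{(2x)!}{\prod_i g_i!} \prod_i p_i^{g_i}.
$$

The estimator multiplies this likelihood across loci and maximises over
a candidate grid:

$$
\hat{x} \;=\; \arg\max_x \prod_j L_j(x \mid A_j, p_j).
$$

Low-frequency alleles carry most of the information: observing a rare
allele is unlikely unless many gene copies were drawn.

### Three numerically equivalent evaluators

* `likelihood_bruteforce()` enumerates the compositions directly.  It is
  exponential in problem size and exists as the reference oracle; a
  configurable cap aborts enumeration with a pointer to the efficient
  form.
* `likelihood_efficient()` uses the inclusion–exclusion identity
  $L = \sum_{B \subseteq A} (-1)^{|A| - |B|} (\sum_{a \in B} p_a)^{2x}$.
  The series alternates, and cancellation grows with $x$, so terms are
  accumulated with compensated (Kahan) summation; results outside
  $[0, 1]$ by more than a tolerance raise an error naming the locus and
  $x$, and residuals within tolerance are clipped.
* `likelihood_grid()` is what the estimator actually uses.  Writing
  $L = (2x)!\,[z^{2x}] \prod_i (e^{p_i z} - 1)$, the factorial-scaled
  coefficients of the product are themselves probabilities (coverage
  probabilities of multinomial draws), and folding alleles in one at a
  time by binomial convolution keeps every intermediate term
  non-negative — there is no cancellation at any $x$.  Frequencies are
  renormalised internally and the factor $(\sum_i p_i)^{2x}$ restored in
  log space, so allele sets carrying little total frequency mass remain
  representable.  One pass yields the whole candidate grid.

The test suite asserts three-way agreement to a relative $10^{-9}$ and
checks the distribution property that subset likelihoods of a full
allele set sum to one.

### Estimation conventions

* The default candidate grid is $x = 1, \dots, 100$, wide enough for the
  designs the package simulates; the bootstrap experiment raises it as
  needed (it must cover at least the largest possible truth).
* Ties in the argmax are resolved toward the smallest $x$: the most
  parsimonious abundance claim.  A maximiser at the upper grid boundary
  is flagged (`boundary`), since the true maximum may lie beyond.
* Observed alleles with no entry in the population frequencies are
  dropped before evaluation and counted (`n_dropped_alleles`) — the
  model can only reason about alleles whose frequency it knows.  Loci
  emptied by that rule are skipped and counted.  A locus that no grid
  value can explain (more alleles than $2\,\max(x)$) aborts with a
  diagnostic rather than silently truncating the likelihood.
* Any $x$ for which some locus shows more than $2x$ alleles has
  log-likelihood $-\infty$; consequently
  $\hat{x} \ge \lceil \max_j n_j / 2 \rceil$ always.

## From reads to allele sets

### Tissue genotyping

Diploid genotypes are called per individual and locus from allele read
counts: the top allele is the first allele; the second-ranked allele
joins iff it holds at least 20% of the locus reads *and* at least 10
reads; otherwise the call is homozygous; a top allele below 10 reads
means a missing call.  The 20% rule is evaluated against total locus
reads (not the top allele's reads), which is the natural reading of a
fraction "of the reads"; exact ties for the top allele are broken by
allele identifier so calls are deterministic.  Population allele
frequencies count gene copies over the non-missing calls.

Locus QC tests Hardy–Weinberg proportions with a chi-square goodness of
fit against expectations from the sample allele frequencies (df = number
of genotype classes minus number of alleles), with an optional
Monte-Carlo permutation p-value for sparse multiallelic tables.  A locus
is flagged for exclusion only when the deviation is significant *and*
heterozygotes are in excess — the signature of co-amplified paralogous
loci.  A heterozygote deficit (the dropout signature) is reported but
not auto-excluded, and no multiplicity correction is applied by default;
both choices are configurable.

### eDNA processing

The chain is fixed, in this order:

1. `min_read_filter()` — alleles with fewer than 10 reads in a sample
   are unreliable detections and are removed.
2. `scale_to_100()` — counts are scaled to 100 reads per sample and
   locus so frequency filters act uniformly across sequencing depths.
   Scaled counts stay real-valued: rounding at a total of 100 would
   erase sub-1% alleles before any frequency filter could see them.
3. `low_freq_filter()` — alleles under 1% within a sample are the
   typical stutter/error signature and are removed, *per sample* (the
   filter precedes pooling; a config switch allows the pooled-level
   order instead).  Counts are not re-scaled afterwards: frequencies
   are recomputed from survivors at estimation time.
4. `pool_replicates()` — replicate water samples of one unit are summed
   (after scaling, so replicates weigh equally regardless of depth).
5. Either `edna_allele_freqs()` (read frequencies per locus, the eDNA
   allele-frequency estimate) or `threshold_filter()` +
   `to_mixture_profile()` (the observed-allele set for the mixture
   model).

Filtering thresholds for the sensitivity analysis are 0.001, 0.01 and
0.1, plus a *variable* scheme driven by per-locus allelic richness: a
2-allele locus is filtered at 0.1 and a 21-allele locus at 0.001.  Only
those endpoints are fixed by the design; this package interpolates
log-linearly in richness between them, which passes through 0.01 at the
richness midpoint and so spans the three fixed thresholds smoothly.
Richness defaults to the tissue-genotyped reference panel's per-locus
allele counts, falling back to observed eDNA richness.

### Read processing

Paired-end amplicon FASTQ (demultiplexed, adapter-free) is reduced to
read counts by: 3′ sliding-window quality trimming (window 4, mean
Phred ≥ 20; "trim low-quality" is read as trimming tails and discarding
only reads left shorter than the forward primer, which preserves
amplicon structure while honouring the Q20 rule); overlap merging
(longest overlap ≥ 20 bp with mismatch rate strictly < 0.05,
disagreements resolved toward the higher-quality base); locus
assignment by exact forward-primer prefix match (a mismatch allowance
exists for noisy data; ambiguous matches are dropped and counted);
exact collapsing of identical contigs; and an ungapped identity filter
of ≥ 90% over the first 40 bases against the locus reference prefix.
Boundary semantics are literal: a mismatch rate of exactly 0.05 fails,
an identity of exactly 90% passes.  Per-sample accounting is exact:
pairs in = quality-discarded + merge-failed + unassigned +
reference-filtered + counted.

## The synthetic-data generator

`simulate_study()` emulates the study design the package is built
around: 28 tetranucleotide microsatellite loci with 2–21 alleles per
locus (mean ≈ 9.4), 73 genotyped individuals from one panmictic
population (Hardy–Weinberg genotypes over symmetric-Dirichlet
frequencies), 58 of them stocked into 12 mesocosms (densities 1/3/5/10
in triplicate, one 11-fish unit) with duplicate eDNA water samples
each, and a field trial with three replicate samples.  Total depths
default to ~45,000 reads per tissue sample, ~37,000 per mesocosm eDNA
sample and ~4,300 per field sample, negative-binomially dispersed
across loci.

Error processes, chosen as typical magnitudes for tetranucleotide
microsatellite amplicon sequencing and exposed in `sim_config()`:

* *Contribution inequality*: per-individual DNA contributions are a
  symmetric Dirichlet draw (concentration 1 by default; lower = more
  unequal), shared across replicate samples of a unit.  The true
  shedding distribution is unknown; the concentration is a parameter,
  not an assertion.
* *Stutter* (default 0.05): each read moves to the one-repeat-shorter
  allele with this probability.  Allele universes are contiguous in
  repeat count, so stutter usually lands on a *real* neighbouring
  allele — the hard case for filtering, and single-repeat loss is the
  dominant artifact mode for tetranucleotides (multi-step stutter is out
  of scope).
* *Substitution errors* (default 0.005): a read becomes one of two
  deterministic sequence variants of its template allele.  These
  variants are absent from the population frequencies, so they exercise
  the dropped-allele accounting.
* *Allelic dropout* (default 0.02 baseline): an allele's reads in a
  replicate are zeroed with probability inflated in proportion to the
  inverse of the allele's expected contribution share, reproducing the
  preferential loss of rare-source alleles.
* *Amplification bias*: heterozygote read splits follow
  Beta(50, 50) around 1:1.

With all error rates zero the pipeline is exact end to end: emitted
FASTQ round-trips through read processing to the generating count
table, and genotype calls match the simulated truth completely.  The
generator does *not* model hydrological transport, degradation,
PCR-cycle-explicit amplification or inhibition; passing tests therefore
validate the statistical machinery under the stated error model, not
field performance of any particular assay.

## What the experiments show

`run_mesocosm_experiment()` reproduces the threshold-sensitivity logic:
permissive thresholds (0.001, 0.01) admit stutter and error alleles and
bias contributor estimates upward; the strict threshold (0.1) removes
true alleles in 5- and 10-fish mixtures and biases estimates downward;
the richness-adaptive scheme sits between the extremes.  Pooled-tissue
profiles with tissue-derived frequencies recover the stocked densities
within ±2.  `run_bootstrap_experiment()` combines 2–12 mesocosms per
draw (without replacement, so the truth is capped by the 58 available
fish; draw size is uniform over the range) and shows the strict
threshold saturating while the variable scheme keeps tracking the
truth.  `run_field_experiment()` runs the low-depth triplicate design
under both population-frequency sources: tissue-derived frequencies
restrict the profile to known alleles (an under-count when rare alleles
were never genotyped), while eDNA-derived frequencies admit more
alleles and give larger estimates — both labelled explicitly in the
output.

Problem sizes in the shipped tests and in `scripts/acceptance.R` are
chosen to keep a full run on one CPU comfortable: 200 bootstrap
replicates instead of 1,000, and a candidate grid of 1–70 for the
bootstrap (its largest truth is 58).  The qualitative conclusions are
insensitive to these sizes.

## Numerical and degenerate-input conventions

* Population frequencies must be positive and sum to 1 per locus
  (tolerance $10^{-6}$); query frequencies may sum to less than 1
  (an observed subset) but never more than $1 + 10^{-9}$.
* Inclusion–exclusion uses Kahan summation; the grid evaluator avoids
  subtraction entirely, and underflow is deferred by renormalising
  frequencies and restoring $(\sum p)^{2x}$ in log space.
* Empty allele sets, loci with zero surviving reads, and samples
  without a pooling unit raise errors rather than propagating silently;
  filters that can legitimately empty a table return empty tables.
* All generators are pure functions of (inputs, seed); the bootstrap is
  bit-reproducible from its seed.

## Known limitations

* The likelihood assumes unrelated contributors from one panmictic
  population; relatedness, substructure, and read-depth-weighted
  (continuous) forensic models are out of scope, as is deconvolution
  into individual genotypes.
* eDNA allele frequencies are read frequencies; no correction for
  amplification bias between alleles is attempted.
* The contributor estimator's accuracy degrades once most loci are
  saturated (every common allele observed); with this panel design that
  begins well below 100 contributors, which is why boundary estimates
  are flagged rather than trusted.
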