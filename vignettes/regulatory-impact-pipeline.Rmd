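---
title: "Methods: regulatory-impact analysis of a two-genotype muscle transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-impact analysis of a two-genotype muscle transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the synthetic
world the generators emulate, and the design choices made where the methods
left room. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The analysis problem

Purebred Iberian pigs (IB) and Iberian × Duroc crossbreds (IBxDU) differ in
growth, fatness and meat quality from birth. Comparing their neonatal
muscle transcriptomes involves five linked analyses: (1) finding
differentially expressed (DE) genes from RNA-Seq counts, (2) asking which
candidate transcription regulators (TRFs, from a curated catalogue) could
drive those differences, (3) validating expression differences by qPCR,
(4) contrasting variant allele-frequency spectra between the genotypes, and
(5) summarizing intramuscular fatty-acid composition. `rifpipe` implements
each stage behind a plain function interface and generates every input
synthetically with planted truth.

## Expression and DE filtering

FPKM is `counts * 1e9 / (length_bp * total_mapped)` with per-sample totals
defaulting to column sums, so per sample `sum(fpkm * length_kb) == 1e6`
exactly — a tested invariant.

A gene enters the analysis when its mean FPKM strictly exceeds 0.5 in at
least one group. The DE filter adds `|FC| >= 1.5` (inclusive) and
`p <= 0.01` (inclusive). The mixed strict/inclusive reading follows the
thresholds' wording literally; the boundary cases are pinned by tests.

The p-value source is an in-repo substitute for the usual count-based DE
engines, and is deliberately labelled non-equivalent to them: an exact
negative-binomial test that conditions on each gene's total
library-size-normalized count and sums the conditional probabilities of
group splits at most as likely as the observed one. Dispersion is estimated
by the method of moments per gene and shrunk toward the common value with
`prior_df = 50`; at 6 + 6 samples the per-gene moment estimate has about 10
residual df, and weaker shrinkage leaves the plug-in test visibly liberal.
A mid-p correction (on by default) compensates the conservatism of the
discrete two-sided rule; the null-calibration acceptance test checks the
resulting size at the nominal 5% within binomial 99% bounds.

Expression summaries feeding the regulator analysis (`e1`, `e2`, `a`, `d`)
are means of `log2(FPKM + 0.25)` per group. The log scale is the
conventional one for co-expression work; the offset (configurable)
stabilizes zeros. Fold changes are computed on the linear FPKM scale with a
0.25 pseudocount; whether the original analyses used FPKM or normalized
counts for FC is not stated anywhere, so both the scale and the pseudocount
are explicit arguments.

## Regulatory Impact Factors

For regulator *i* and the DE set of size *n*:

* `RIF1_i = (1/n) Σ_j a_j d_j (r1_ij − r2_ij)²` — extreme for regulators
  whose co-expression with abundant, strongly DE genes differs most between
  genotypes;
* `RIF2_i = (1/n) Σ_j [(e1_j r1_ij)² − (e2_j r2_ij)²]` — extreme for
  regulators whose ability to predict DE-gene abundance changes most.

Correlations are Pearson on `log2(FPKM + offset)` within each group
(Spearman available); a zero-variance vector yields the sentinel 0 so the
sums stay defined, and the implementation is pinned to a naive double-loop
oracle at 1e-12 relative error. z-standardization uses the sample (n−1) SD
over the candidate set; a degenerate all-equal input returns zeros with a
flag.

The null is a percentile bootstrap: each repetition draws `n` genes without
replacement from the expressed genes and recomputes both metrics and their
z-scores for all regulators; z-scores are pooled across regulators and
repetitions, and the 95%/99% bounds are the corresponding percentiles of
the pooled distribution (10,000 repetitions by default). Three choices
deserve a note:

* the draw pool excludes the candidate regulators themselves — the
  published description draws from "the expressed genes" without saying
  whether regulators are eligible, and excluding them avoids
  self-correlation artifacts;
* sampling is without replacement within a repetition, reading "a set of
  randomly selected genes" as distinct genes;
* per-draw statistics (`a`, `d`, `e1`, `e2` of the drawn genes) are
  re-derived each repetition rather than re-using the observed DE set's
  values, since the metrics are defined in terms of the gene set in use.

A regulator is significant at a level when its z lies strictly outside the
interval. The pooled interval is a single pair of bounds per metric (as the
published footnotes report), not a per-regulator interval.

## qPCR validation

The transform `y = −log2(E^−Cp) = Cp·log2(E)` converts cycles to a log2
expression-equivalent scale using each gene's amplification efficiency
`E ∈ (1, 2]`. The joint mixed model

    y_gikr = TG_gi + B_gk + D_ik + e_gikr

has fixed gene-by-genotype cell means, random pig-within-gene effects, a
random sample effect shared by all genes, and a residual. Estimation uses
REML via `lme4` — the established mixed-model fitter in this toolchain —
rather than a hand-written optimizer; when the fit degenerates (zero
variance components, singular designs) an ordinary-least-squares fallback
returns the same cell means. Replicates enter as repeated measures by
default; `mean_cp = TRUE` reproduces the variant where replicate Cp values
are averaged first.

`diff_TG` is the genotype contrast of the target minus the mean contrast of
the reference genes (arithmetic mean on the y scale, equivalent to
geometric-mean normalization on the quantity scale), with standard error
from the fixed-effect covariance and a t test on containment degrees of
freedom `n_animals − 2` — the most conservative simple choice, since no df
rule is stated. `FC = 2^(−diff_TG)` exactly inverts the contrast. With all
efficiencies 2 and a noiseless balanced design the estimate equals the
classical ΔΔCt, which the tests verify.

Reference-gene stability uses the geNorm-style statistic: `M_g` is the mean
over other candidates of the SD across samples of the pairwise log-ratio.
The two lowest-M genes define per-sample normalization factors as the
geometric mean of their quantities. The full iterative geNorm elimination
is not implemented — with the typical four candidates the one-shot ranking
selects the same pair in the cases the tests cover.

Concordance between RNA-Seq and qPCR fold changes uses Lin's CCC with
population (1/n) moments, `2·cov / (var_x + var_y + (mean_x − mean_y)²)`.

## Variants

Filtering removes calls with coverage strictly under 30 reads (10 in
candidate-gene mode) or allele frequency strictly under 5%, so boundary
values survive. A call is potentially fixed at γ ≥ 90%, else segregating.
Groups are compared on the exact key (chrom, pos, ref, alt) — the
conservative choice, since the published comparison does not state its
matching key — yielding shared/unique categories and the
differential-segregation flag (fixed in IB, segregating in IBxDU).
Variant types follow the anchored-allele taxonomy (SNV, MNV, insertion,
deletion, replacement).

Consequence annotation projects a variant onto the spliced CDS of the
overlapping toy transcript (strand-aware, alleles reverse-complemented on
minus-strand models), rebuilds the alternate CDS, translates both with the
standard genetic code, and classifies synonymous / missense / in-frame
indel (net length change divisible by 3, residue difference reported) /
frameshift; UTR variants report UTR. Variants straddling a CDS boundary
are rejected rather than guessed. Multi-transcript genes are reported
per-transcript.

## The synthetic world

The generators state a world once and the tests measure the pipeline
against it; none of the parameters below were revisited after the
acceptance measurements.

* **Expression**: 2 genotypes × 6 animals (the study design), 2,000 genes
  at desk scale, 149 truly DE with log-uniform fold-change magnitudes on
  [1.9, 12] and the purebred-skewed 95:54 direction split, 100 candidate
  regulators of which 3 are planted, negative-binomial counts (dispersion
  0.1, typical bulk RNA-Seq biological CV) with log-normal baseline means
  scaled to 10⁶ fragments per sample and ±10% depth wobble, gene lengths
  uniform on 300–10,000 bp.
* **Regulator coupling**: the planted regulators form one co-active
  program driving the module of DE genes upregulated in the purebred
  group, via a single latent per-sample factor (natural-log sd 1). The
  factor loads with coefficient 1 on the regulators and 0.4 on the module
  genes; in the crossbred group the module's loading flips sign, so the
  regulator–target correlation inverts between genotypes. The asymmetric
  loadings matter: regulators are exempt from the DE test, so their large
  factor variance is harmless, while the weaker module loading keeps the
  module genes' within-group dispersion low enough for the DE filter to
  retain them. An earlier design with private factors per regulator and
  symmetric loadings was discarded because overlapping modules dilute each
  regulator's correlation signature and the factor variance pushed the
  module genes out of the detected DE set.
* **qPCR**: 9 targets + 2 references, triplicates, baseline cell means
  uniform on 18–26 cycles-equivalent, pig/sample/residual SDs
  0.2/0.15/0.2 — variance components of the order seen in well-behaved
  qPCR experiments.
* **Variants**: allele frequencies uniform on [0.90, 1] for fixed calls
  and [0.05, 0.90) otherwise, a 5% sub-threshold tail to exercise the
  filters, negative-binomial coverage around 60×.
* **Fatty acids**: group means default to the shipped reference profile of
  neonatal pig biceps femoris (IB and IBxDU columns); per-animal Gaussian
  noise, truncation at zero and renormalization to 100 g/100 g.

What a green test does **not** establish: the generator has no read-level
error, no mapping ambiguity, no GC or length bias, no correlated library
composition effects, no linkage between variant loci, and fold-change
magnitudes are independent of expression level. Conclusions about those
phenomena need real data.

One published-table caveat the phenotype module documents rather than
hides: in the reference fatty-acid table, only the ΣSFA group sums are
exactly the sums of the listed component rows; the printed ΣMUFA, ΣPUFA and
Σn-3 values differ slightly from the sums of their listed components
(unlisted minor fatty acids presumably contribute). `summary_indices` sums
supplied components only, so its ΣSFA matches the printed values exactly
while the other class sums track the listed rows.

## Numerical choices and degenerate inputs

* Exact-test p-values are computed in log space and renormalized; ties in
  the conditional probabilities are compared with a 1e-10 log-tolerance.
* `standardize` of an all-equal vector returns zeros with a `degenerate`
  flag instead of dividing by zero.
* Correlation of a constant vector is the sentinel 0, flagged in the
  profile rather than propagated as `NA`.
* `group_compare` with zero residual variance flags the fit and returns
  `p = NA` (no difference) or `p = 0` (exact difference) instead of a
  division-by-zero t statistic; the covariate is dropped when its own p
  exceeds 0.05, per the stated modelling rule.
* Sub-seeds for the generator streams are derived from one root seed by a
  fixed affine map modulo 2³¹ − 1, keeping every derived seed a valid
  32-bit integer.

## Scaled-down test sizes

The suite keeps the default run inside a CI budget by scaling simulation
sizes, never by weakening thresholds: power and parameter-recovery examples
run 20–60 replicates with Monte-Carlo-SE-based tolerances; the
planted-regulator recovery criterion runs the full 50 replicates but with
500 bootstrap repetitions per replicate instead of 10,000 (the interval
bounds stabilize well before that); the null-calibration criterion uses one
10,000-gene transcriptome and 500 independent qPCR replicates as specified.

## Known limitations

* The DE engine is a documented substitute: it shares the conditional
  exact-test idea with the standard count-based tools but not their
  quantile-adjustment or empirical-Bayes machinery, and makes no claim of
  numerical equivalence.
* The bootstrap null treats regulators' z-scores as exchangeable when
  pooling; regulators with extreme mean expression could in principle have
  slightly different null spread.
* Consequence annotation handles single-transcript toy models with intact
  CDS; it is not a general-purpose variant effect predictor.
* The qPCR model assumes a common residual variance across genes.
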