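---
title: "Detecting condition-specific 3'-end depletion with half-gene differential testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-specific 3'-end depletion with half-gene differential testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terminseq)
```

## The problem

When RNA polymerase II terminates prematurely, the cell accumulates 5'
fragments of a transcript instead of full-length mRNA. In plants these
fragments are normally degraded by the nuclear exosome, guided by helicase
co-factors such as HEN2. A mutant that both fails to degrade the fragments
*and* terminates more often shows a characteristic positional signature in
poly(A) RNA-seq: coverage is elevated near the transcription start site and
depleted toward the poly(A) site. Standard whole-gene differential
expression is blind to this signature — the 5' surplus can mask a genuine
3' deficit, so the gene looks unchanged.

`terminseq` implements the positional analysis that resolves this
ambiguity: every gene is split at its midpoint into a 5' and a 3' half,
fragments are counted per half, each half is tested for differential
abundance between genotypes within a condition, and genes whose 3' half is
depleted specifically under one condition (for instance cold stress, where
transcriptional demand is high) are selected and visualised as scaled
metagene profiles. A generative simulator of the underlying elongation /
degradation process provides ground truth for benchmarking every step.

## Gene bisection

Genes are represented on 0-based half-open coordinates (BED arithmetic).
A gene of length $L$ is split so that the 5' half holds
$\lceil L/2 \rceil$ bases counted from the biological TSS; for odd $L$ the
extra base therefore goes to the 5' half, a deterministic choice with no
effect at RNA-seq scale. The split is strand-aware: on the minus strand
the 5' half is the right-hand interval. Bisection acts on the genomic gene
span, not on spliced transcript models; exon-aware halving would change
half lengths for multi-exonic genes and is out of scope (we record it as
the main untested alternative).

```{r}
g <- gene_models("AT1G01010", "chr1", 1000, 3001, "+")
bisect_genes(g)
```

## Fragment counting

A sequenced fragment is reduced to its outer genomic span. Each fragment
is assigned to **the half containing its biological 5'-most base** (its
start on a `+` gene, its `end - 1` on a `-` gene). The rule is
deterministic, strand-aware, and guarantees the conservation identity

$$\mathrm{count}(5') + \mathrm{count}(3') = \mathrm{count}(\text{gene})$$

for every fragment inside a gene, so the half-level analysis never
double-counts or loses a fragment that straddles the midpoint.
`stranded = "reverse"` decodes dUTP-style libraries in which the read
strand is opposite the RNA strand. Fragments overlapping two genes are
counted for both; contamination of metagene profiles by neighbouring
transcription is instead handled explicitly by `adjacency_filter()`.

Normalization uses median-of-ratios size factors (the DESeq approach),
rescaled to geometric mean 1, computed over regions with all-positive
counts. When no such region exists the package falls back to library-size
ratios with a warning.

## The half-level test

Counts are modelled as negative binomial with variance
$\mu + \alpha \mu^2$. Dispersions are estimated per region by the method
of moments on normalized counts (variances pooled within sample groups),
then shrunk toward a mean–dispersion trend
$\alpha_{\mathrm{tr}}(\mu) = a_0 + a_1/\mu$ (fitted by least squares on
the log scale) with weight $w = n/(n+4)$, where $n$ is the pooled residual
degrees of freedom — a design with one replicate per group has $n = 0$
and receives the pure trend value. In the full pipeline, dispersions are
estimated once from **all** samples grouped by genotype × condition,
which roughly doubles the residual degrees of freedom available to any
single two-group contrast and is what keeps the per-contrast Wald test
close to its nominal size at 3 replicates per group.

The test itself is a Wald test on the log2 ratio of group means with a
pseudocount of 0.5 (which keeps fold changes finite for empty groups):
$\log_2 FC = \log_2\frac{\bar\mu_{test} + 0.5}{\bar\mu_{ref} + 0.5}$, with
a delta-method standard error from the NB variance and a standard normal
reference. P-values are Benjamini–Hochberg adjusted across all tested
halves within one contrast (not per chromosome, not pooled across
contrasts). A region is called UP/DOWN when `fdr <= alpha` (default 0.05)
and `|log2FC| >= lfc_min` (default 0); both thresholds are exposed in
`contrast_spec()`. The published analysis this package generalises did
not state its thresholds, so the defaults are the conventional ones.

Condition-specific selection is the literal conjunction: a gene is
selected when its 3' half is DOWN in the cold contrast **and** NS in the
control contrast, with "not DE" operationalized under the same
alpha/lfc_min as the cold contrast (a symmetric choice; nothing in the
procedure requires asymmetric thresholds). The selection is then
cross-referenced against the reference genotype's own cold response at
the whole-gene level, labelling each selected gene UP, DOWN or NS — in
the motivating study most such genes are cold-induced in the wild type,
i.e. genes whose activation the mutant fails to sustain.

## Metagene profiles

Per-base coverage over each gene is rescaled to 100 bins (bin 1 = 5' end
regardless of strand). Binning is base-weighted with proportional edge
handling: a base split across two bins contributes fractionally to each,
so the mean over bins equals the mean per-base coverage exactly — the
profile preserves coverage mass, which matters when ratios between group
profiles are interpreted. Profiles are averaged arithmetically across
genes per genotype × condition group; per-sample weights (reciprocal size
factors) are supported because the upstream normalization of published
metaplots is rarely stated. The bin count is configurable; 100 matches
common scale-regions practice.

## The simulator

`simulate_termination` encodes the working model of the biology as a
generative process. One initiation event elongates 5'→3' and terminates
prematurely at base $x$ with probability $h(1-h)^{x-1}$ (constant per-base
hazard $h$, i.e. geometric termination), reaching full length with
probability $(1-h)^L$. A prematurely terminated RNA survives degradation
with probability $1-\delta_{pt}$; a full-length mRNA with
$1-\delta_{fl}$. Surviving RNAs are sheared into one read-length fragment
(default 100 bases, uniform start within the RNA) so both
5'-base-assignment counting and coverage-proportional measures can be
exercised; shearing can be disabled to study the unsheared process, whose
per-base expected coverage has the closed form

$$\mathrm{cov}(x) = \lambda\left[(1-\delta_{pt})\left((1-h)^x - (1-h)^L\right) + (1-\delta_{fl})(1-h)^L\right]$$

implemented in `expected_half_counts()` and used as the analytic oracle
for the sampler. Replicate noise is gamma-Poisson: per-gene event counts
are NB with mean $\lambda$ (times a cold-induction factor $\kappa$ for
cold-responsive genes in the cold condition) and shared dispersion
$\varphi$. All randomness flows from one seed with deterministic
per-sample substreams.

Genotype presets reproduce the qualitative contrasts of the biology
rather than measured rates, which are not available:

| preset | hazard | $\delta_{pt}$ | $\delta_{fl}$ | behaviour |
|---|---|---|---|---|
| `WT` | baseline | 0.95 | 0 | degrades 5' fragments efficiently |
| `hen2` | elevated at affected genes | 0.2 | 0 | 5' accumulation **and** 3' depletion |
| `exosome_core` | baseline | 0.2 | 0 | 5' accumulation only |
| `zcchc8ab` | baseline | 0.95 | 0.3 | full-length level modifier only |

Baseline hazard is $2\times10^{-4}$ per base (a 2 kb gene yields ~65%
full-length product), initiation $\lambda = 100$ events per gene per
library, cold induction $\kappa = 4$, dispersion $\varphi = 0.05$ —
magnitudes chosen once to give realistic RNA-seq count depths and
clearly visible but not caricatural contrasts. Premature termination is
gene-specific: only a configurable subset of genes ("termination-prone")
carries the baseline hazard at all, mirroring the observation that 5'
fragment accumulation affects a subset of genes, not the whole
transcriptome; the remaining genes produce pure full-length mRNA and act
as clean nulls. The hazard elevation at affected genes is parameterized
by its effect: for a fold-reduction $f$ in full-length yield,
$(1-h')^L = (1-h)^L/f$, so "4-fold 3' depletion" is exact in
expectation regardless of gene length. An optional 5'-proximal
elevated-hazard window (motivated by promoter-proximal short transcripts)
is not enabled by default.

The default benchmark (`make_benchmark()`) draws 600 genes with
log-normal lengths (median ≈ 2.2 kb, floor 600 bases — the affected genes
in this biology tend to be long), flags 60 of them with cold-specific
elevated termination in *hen2* (all cold-induced, so the wild-type
cross-reference step has signal), makes 30% of the remaining genes
cold-induced background and 20% termination-prone background, and
simulates 3 replicates × 2 genotypes × 2 conditions. These sizes keep a
full pipeline run under ~10 s while giving the selection step enough
events to estimate sensitivity and FDR stably.

## What the simulator does not emulate

Splicing (fragments are contiguous outer spans), sequence-level read
errors, positional biases of library chemistry, multimapping,
gene-to-gene dispersion variation (a single $\varphi$ is shared), and
genuine biological co-regulation between neighbouring genes. Passing the
benchmark therefore demonstrates that the statistical machinery recovers
the positional signal it is designed for under its own model assumptions;
it does not certify performance on real libraries, where the DE interface
deliberately accepts any external per-region table (`select_3prime_specific`
only needs `region_id` and `call` columns) so a dedicated engine can be
swapped in.

## Assays

Relative qPCR quantification follows the textbook
$2^{-\Delta\Delta C_t}$ recipe: $\Delta C_t = C_t^{target} - \overline{C_t^{ref}}$
per sample, $\Delta\Delta C_t$ against the reference genotype, fold
change $2^{-\Delta\Delta C_t}$. Multiple reference genes are combined by
the arithmetic mean of their $C_t$ values (equivalent to a geometric mean
of linear quantities); no efficiency correction is applied. Error bars
are SEM over biological replicates computed on the fold-change scale.

Electrolyte-leakage freezing curves are fitted with the four-parameter
logistic $y = b + (t-b)/(1 + 10^{(e - T)s})$ on the temperature axis by
Levenberg–Marquardt least squares from a deterministic multi-start grid
(LogEC50 at the quartiles of the observed temperatures × six slopes of
both signs); the parameterization is symmetric under swapping asymptotes
and negating the slope, and fits are canonicalized to $b \le t$. Flat
data returns a flagged degenerate fit rather than an error. Two curves
are compared with the extra sum-of-squares F-test: the null model shares
all four parameters, the full model frees LogEC50 per curve while sharing
bottom/top/slope (the common Prism recipe; which parameters are shared is
the main dialect choice and the shared-slope variant is the default
because separate slopes make the EC50 comparison confounded with shape).
The full model is additionally refitted from the null solution so
$RSS_{full} \le RSS_{null}$ by construction; a persistent violation
raises an error instead of reporting a negative F.

## Numerical choices and degenerate inputs

* Coordinates: 0-based half-open everywhere internally; GFF3/GTF
  converted on read, BED taken as-is.
* Genes shorter than 2 bases cannot be bisected and raise an error.
* All-zero regions receive the dispersion trend value and p = 1.
* `scale_region` handles `n_bins` larger than the region by proportional
  interpolation (bins map to fractional bases).
* Ties in the adjacency filter: with distance 0 only literal overlap
  removes a gene; touching-but-not-overlapping neighbours are removed
  only for positive distances.
* Seeds: every stochastic entry point takes an explicit seed and derives
  per-sample substreams as `seed + 7919 * sample_index` (kept below
  2^31).

## Known limitations

Half-gene resolution is coarse: a depletion confined to the last decile
dilutes into the whole 3' half. The Wald test with moment dispersions is
slightly anticonservative at 3 replicates (the pooled-dispersion design
above mitigates but does not remove this); analyses where calibration is
critical should treat borderline FDRs accordingly or plug in an external
DE engine. Bisection of genomic spans ignores isoform structure, and the
counting rule treats spliced fragments as their outer span.
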