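---
title: "ctlnc: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctlnc: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cancer-testis (CT) genes are silent in somatic tissues, expressed in
testis, and reactivated in tumors. For long non-coding RNAs the analysis
chain has three difficulties that this package addresses explicitly:
lncRNAs are lowly and sparsely expressed, so reactivation must be detected
as an *outlier* pattern rather than a mean shift; lncRNAs carry no direct
functional annotation, so function must be inferred from co-expressed
coding genes (guilt by association); and the candidate regulatory
machinery (testis-specific promoters, methylation sites, enhancers) acts
at a distance, so evidence is positional.

# Models and procedures

## Testis specificity (SPM)

For gene $g$ with per-tissue mean expression $x_1,\dots,x_k$ and target
tissue $t$:

$$\mathrm{SPM}_g = \frac{x_t^2}{\sum_i x_i^2} \in [0,1]$$

SPM is scale-invariant and equals 1 iff expression is confined to the
target tissue; a uniform profile over $k$ tissues gives $1/k$. Cutoffs are
configuration, not derivable from first principles: defaults are
**0.9** (high confidence) and **0.6** (moderate), exposed in
`classify_testis_specific()`. Only high-confidence TS-lncRNAs enter CT
calling. Gene models are pre-filtered to the six lncRNA biotypes, and any
lncRNA with an exon overlapping (≥ 1 bp, either strand) a coding gene's
span is removed. The overlap is tested exon-vs-gene-span: the looser of
the two defensible readings, chosen because it is the conservative one for
downstream claims (fewer ambiguous models survive); antisense models
survive only when the paired coding annotation is absent from the supplied
coding set.

## CT and EECT calling

With unit dialect RPKM the expression floor is **0.1**; with normalized
read counts it is **5**. A TS-lncRNA is **CT** in a cohort when strictly
above the floor in at least **1%** of samples (`>=` on the exact fraction
count/n, no rounding). For the extreme-expression (EE) rule, zeros are set
to one before the log2 transform — so zeros contribute 0, not $-\infty$ —
and the per-gene threshold is

$$\mathrm{mean}(\log_2 x) + k \cdot \mathrm{SD}(\log_2 x), \quad k = 3$$

computed over **all** samples of the cohort with the $n-1$ sample SD. A CT
gene is **EECT** when strictly above its threshold in ≥ 1% of samples.
Both inequalities at thresholds are strict; ties are non-calls. The
per-sample **activation count** is the number of EECT genes strictly above
their thresholds in that sample. Numerical consequence of the zero rule
worth knowing: for a gene expressed in a fraction $f$ of samples at level
$L$ (log2), the threshold is roughly $fL + 3L\sqrt{f(1-f)}$, which stays
below $L$ for $f \lesssim 4\%$ — the rule is intrinsically tuned to sparse
reactivation.

## Conservation

Promoters are 2 kb upstream / 0.5 kb downstream of the strand-aware gene
start (one promoter per gene, at the 5'-most coordinate — gene-level
summaries are what the comparisons consume). Region scores are
length-weighted means over the interval union; track gaps follow a
`missing_policy` (default `skip`; `zero` counts uncovered bases as 0).
PhyloP is rescaled by $1 - 0.5\cdot 10^{-p}$ for $p>0$ and
$0.5\cdot 10^{p}$ for $p<0$; the printed piecewise formula leaves $p = 0$
undefined and both one-sided limits equal $0.5$, so 0 maps to 0.5. The
rescaling is strictly increasing and antisymmetric,
$f(-p) = 1 - f(p)$.

Group comparisons use a two-sided Wilcoxon rank-sum test with three
regimes: full permutation enumeration (mid-ranks, valid under ties) for
combined $n \le 12$; the closed-form Mann-Whitney null for tie-free
samples with combined $n \le 20$; otherwise a tie-corrected normal
approximation with signed continuity correction. The signed correction
(`sign(u - mn/2) * 0.5`) keeps two identical samples at exactly $p = 1$
and holds the exact-vs-approximate gap at $n = 10+10$ to < 0.01, where the
uncorrected version reaches 0.034.

## Guilt-by-association annotation

Genes pass the expression filter when above the floor in ≥ 1% of samples.
For each lncRNA, Spearman's $\rho$ (Pearson on mid-ranks) against every
tested coding gene; the leading $\lfloor 10\% \rfloor$ by $\rho$
descending and ascending are the positive/negative partner sets, boundary
ties broken lexicographically by gene id so selection is deterministic.
The query set is the **union** of both directions (a configuration switch
tests them separately); each term is tested with the upper-tail
hypergeometric

$$P(X \ge m), \qquad X \sim \mathrm{Hypergeom}(N, M, n)$$

over the universe of *tested* coding genes present in the database — not
all database genes — to avoid bias from unexpressed genes. Terms at
$P_{BH} < 0.01$ annotate the lncRNA. Annotated genes are folded back into
the database (`expand_db()`: members and universe grow, so $N$ and $M$ of
later tests reflect the expansion; idempotent), and the CT-lncRNA set is
tested per term against the expanded counts.

## Regulatory-element windows

Window geometry is strand-aware and half-open: promoter window 100 bp–5 kb
upstream of the gene start, methylation window 100 bp–1 kb upstream,
enhancer flanks 20 kb upstream plus 5 kb beyond the gene end; the gene
body is excluded and coordinates are clipped at zero. "100 bp–5 kb
upstream" is read as excluding the first 100 bp ahead of the start — the
only reading under which the promoter and methylation statements contrast.
Presence is ≥ 1 bp overlap of a strandless element with any window
interval. Enrichment is a two-sided Fisher's exact test (target vs
background × present vs absent), with the sample odds ratio $ad/bc$ and a
Haldane-corrected OR (+0.5 per cell) reported for display; the test always
uses exact probabilities, summing point probabilities ≤ the observed one
(the `fisher.test` convention, implemented directly on `dhyper` for
speed). Background defaults to non-TS lncRNAs.

## Association models

Ordinary least squares with complete-case handling; categorical covariates
are dummy-coded against the first sorted level, factors that collapse to
one level are dropped with a message, and a rank-deficient design is an
error naming the collinear terms. AJCC stage enters numerically (1–4):
the scientific claim is a linear trend. The SMG-ratio model defaults to
activated count regressed on the ratio (the reverse orientation is a
flag); only the sign of the association is interpreted, which is
orientation-invariant. The mutual-exclusivity screen tests every
(lncRNA, driver) pair plus a per-lncRNA "any driver" aggregate with the
exact 2×2 test; direction is `exclusive` for OR < 1; pairs with a
zero-variance margin are skipped with a recorded reason; BH across tested
pairs (the multiplicity correction for this screen is not stated in the
source analysis; raw p-values are also reported).

# The synthetic world

`cohort_spec()` fixes the stated world: 24 tissues × 30 individuals,
two tumor cohorts of 200 samples, 1,500 genes of which 500 lncRNAs, 30% of
lncRNAs TS, 60% of those CT, activation effect 6 log2 units at frequency
5%, five 20-gene modules (5 lncRNAs + 15 coding) at within-module Spearman
0.8, 50 gene-set terms. Expression is log2-normal with a dropout point
mass at zero; activation adds a constant log2 shift to a Bernoulli-chosen
sample subset — the simplest model under which the mean + 3 SD rule has
planted positives. Module correlation uses a Gaussian-copula latent factor
with $r = 2\sin(\pi\rho_s/6)$ so the *rank* correlation targets
`rho_within`. Activation probability scales with stage
(`stage_effect`, default 0.5 relative per stage unit around stage 2.5),
is forced to zero in samples mutated for the paired driver, and activated
samples draw promoter beta values shifted down by
`methylation_effect_size` (default 0.3 from a baseline Beta with mean
0.7). Planted elements are placed inside their strand-aware windows;
background elements uniformly over the intergenic space ≥ 26 kb from any
gene, which no window can reach. One chromosome per 500 genes, 65 kb start
spacing, alternating strands: flanking windows of adjacent genes can never
collide, making window tests unambiguous.

Free parameters the source material does not constrain were set once to
values a cohort analyst would call realistic and are exposed in the spec:
testis shift 3 log2 units over baseline 3 ± 1; TS leakage 2% of non-testis
samples at ~0.25 RPKM (panel) and ~0.04 RPKM (tumors, deliberately below
the 0.1 floor so never-reactivated TS genes are clean negatives); dropout
5%; 5 drivers at 30% mutation rate; conservation Beta means 0.8 (high)
vs 0.2 (CT genes, low); PhyloP normals at +2 vs −1.

What the generator does **not** emulate: library-size and GC biases,
batch effects, cohort-level heteroscedasticity, copy-number-driven
expression, isoform structure, and realistic LD between drivers. A green
recovery test therefore establishes that the *procedure* recovers the
planted structure under the stated noise model — not that the thresholds
are optimal for any real cohort.

# Numerical and design notes

- All genomic coordinates are 0-based half-open internally; GRanges
  conversion happens only at format boundaries.
- The 2×2 exact test is computed directly from `dhyper` with the
  `fisher.test` relative-error guard; `stats::fisher.test` is two orders
  of magnitude slower and is used only as a cross-check in the tests.
- Child seeds: sub-generators derive seeds as
  `(seed * 1000003 + offset) mod (2^31 - 1)` so components are
  independently reproducible under one global seed.
- Determinism: `simulate_cohort()` and `run_pipeline()` are pure functions
  of (spec, seed); the pipeline manifest carries md5 hashes and re-runs
  byte-identically.
- Degenerate inputs: SD = 0 genes can never be EECT (strict inequality);
  all-zero expression profiles have undefined SPM and are reported
  `non_TS`; single-sample cohorts are an error for the EE rule.

## A known limitation of guilt-by-association

Under a null in which only the lncRNA's sample labels are shuffled, the
coding co-expression modules remain intact and can enter the lncRNA's
leading decile as a correlated block; the per-term hypergeometric then
treats $m$ correlated hits as independent evidence and the per-lncRNA
annotation rate is far above nominal (~40% in our planted world). This is
a property of guilt-by-association with correlated gene sets, not of this
implementation. The calibrated reference null — under which the
hypergeometric model is correct and the ≤ 5% bound holds — shuffles every
gene's labels independently, removing all co-expression. Annotations of
real, correlated data should therefore be read as ranked evidence, not as
calibrated per-term error rates.

## Open choices resolved here

- Specificity statistic and cutoffs are deferred to prior work by the
  source analysis; SPM with configurable 0.9/0.6 cutoffs is implemented.
- Per-cancer "1% of samples" is applied per cohort, then unioned across
  cohorts ("in at least one cancer type").
- Exon-union (not per-transcript) conservation averages.
- The per-lncRNA enrichment universe is the tested coding genes; the
  original tooling's universe convention is not recoverable.
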