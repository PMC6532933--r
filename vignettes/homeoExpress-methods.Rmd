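---
title: "Models and methods behind homeoExpress"
author: "homeoExpress authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind homeoExpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoExpress)
```

# Scope and data model

`homeoExpress` analyses expression and mutation load in an
allotetraploid together with its two parental species.  Throughout,
*CG* and *CO* denote the two parents (an outcrossing and a selfing
*Capsella*-like pair in the motivating system), and *Cg* / *Co* the
subgenomes of the tetraploid derived from them.  Inputs are plain
tables: unphased gene x sample counts (`ExpressionCounts`, a
`SummarizedExperiment` with a validated integer `counts` assay),
phased per-accession homeologue counts (`PhasedCounts`, assays `co`
and `cg`; missing pairs are `NA`, never 0), per-SNP DNA allelic counts
for the mapping-bias screen, per-gene mutation counts, and BED gene
positions (0-based half-open on disk, following the BED convention so
distances are unambiguous; `GRanges` in memory).

Everything upstream of counts — read mapping, genotyping, subgenome
phasing, functional annotation of variants — is out of scope and
consumed as prepared tables.

# Normalization and filtering

* **CPM.** `value = (count + pseudo)/library * 1e6`.  The default
  pseudo-count of 1 keeps zeros loggable; with pseudo-count 0, columns
  sum to exactly 1e6.
* **TMM.** The trimmed-mean-of-M-values scaling is implemented at the
  canonical parameters (30% two-sided trim on log-ratios M, 5% on
  abundances A, inverse asymptotic-variance weights, factors
  renormalized to geometric mean 1; the reference sample is the one
  whose upper-quartile CPM is closest to the mean upper quartile).
  The test suite cross-checks it against edgeR's implementation on
  majority-unchanged data, and against a literal brute-force
  recomputation on a 50/50-shifted toy where TMM's majority assumption
  is deliberately violated.
* **Phased normalization.** Both subgenomes of an accession are
  divided by the same denominator, the mean of the two subgenome
  library sizes, preserving within-accession homeologue ratios.
* **Homeologue scaling.** SNP-level phased counts suffer from uneven
  SNP density and coverage along genes, so only their ratio is used:
  `scaled_co = total * co/(co + cg)`, `scaled_cg = total - scaled_co`.
  Totals are conserved exactly; 0/0 ratios with a positive total are
  flagged unphaseable (`NA`).
* **Mapping-bias screen.** Each SNP's DNA counts are tested against
  the fair 0.5 ratio by a two-sided exact binomial test with
  Benjamini-Hochberg correction across SNPs; genes retaining no SNP
  are dropped.  This is a deliberately simple, calibrated frequentist
  screen; externally computed keep lists (e.g. from a hierarchical
  Bayesian allelic model) can be substituted, and the same surrogate
  design is used for homeologue-specific expression (HSE) calls.
  Null simulations in the test suite confirm the false-drop and
  false-positive rates stay at or below the configured FDR.
* **Presence filter.** A gene is kept only if every population or
  species has at least one sample with a non-zero count.
* **Silenced genes.** A gene is silenced on a subgenome when its raw
  count is zero in every accession of that subgenome.

# Differential-expression engine

Classification consumes only three-state calls (up / down / ns at an
FDR threshold), so the engine is pluggable.  The built-in engine is a
Welch t-test on `log2(CPM + pseudo)` with BH correction — a documented
approximation chosen because the package's contribution lies
downstream of DE calling; negative-binomial GLM machinery is not
reproduced.  `importCalls()` accepts externally computed tables (e.g.
edgeR output) and recomputes directions from the configured threshold
rather than trusting the file.  HSE is tested per sample (exact
binomial on the homeologue pair) or pooled across accessions (paired
test on per-accession log-ratios); both modes are exposed because
per-sample testing matches per-sample summaries while pooled testing
matches cross-accession classification.

# Classification decision tables

The phased scheme assigns each gene one of seven categories from the
six pairwise contrasts among {CG, CO, Cg, Co} (a 3^6 = 729-vector
decision table) plus the point estimates of the group means, which
settle interval membership (inside/outside the parental range) and
which parent is closer.  Any such table is somewhat arbitrary for
intransitive call patterns (A = B, B = C, A != C), so the
arbitrariness is made explicit and testable as a precedence order:
after *no difference* (all six ns), compensatory drift, then
transgressive > dominance > legacy > reverse > intermediate, and
`ambiguous` for vectors matching no rule.

One precedence choice deserves its rationale: *compensatory drift*
(parents statistically equal, subgenomes diverging) is checked before
*transgressive*.  With statistically equal parents the parental
interval collapses to a point-estimate artifact, and a diverging
subgenome pair — the defining compensatory-drift configuration — would
otherwise always be captured by the "outside the parental range" rule,
leaving the category unreachable.  When the parents do differ,
transgressive takes precedence as usual.  Exhaustive enumeration tests
verify the table is total over all 729 vectors and symmetric under the
joint relabeling CG&harr;CO, Cg&harr;Co (legacy and reverse map to
themselves, 6a&harr;6b, 7a&harr;7b).

The unphased 4-category scheme (no difference / intermediate /
dominance / transgressive over three contrasts) resolves its residual
patterns by the analogous precedence, with dominance orientation
decided by the closer parent when both parental comparisons are ns.

Category proportions are reported over all genes and renormalized over
differentially expressed genes only (without the *no difference*
class); thresholds of 0.01/0.05/0.1 can be swept by re-running the
classifier, since directions are a pure function of the FDR threshold.

# Cis/trans decomposition

For each gene the parental log-ratio `x = log2(E_CG/E_CO)` and the
subgenome log-ratio `y = log2(E_Cg/E_Co)` are paired.  Pure cis
regulation keeps each homeologue at its parental level (`y = x`);
complete cross trans-regulation equalizes homeologues (`y = 0`).  The
OLS slope of `y` on `x` therefore estimates the aggregate cis fraction,
and a mixture of pure-cis and trans-equalized genes with matched
predictor variance yields a slope equal to the cis fraction (verified
by simulation).  Log2 ratios are used because symmetric ratio axes and
standard practice imply a log scale; natural-scale ratios sit behind
a flag, as does major-axis regression for sensitivity analyses (OLS is
the primary fit because the quantity of interest is a directional
slope against fixed reference lines).

Two numerical caveats are documented rather than hidden.  First,
counting noise on the *predictor* attenuates the slope below 1 even
under pure cis truth (classical errors-in-variables); with the default
generator (dispersion 0.05, four accessions per parent) the
attenuation is on the order of a few percent, which the test suite
accounts for by testing count-level simulations against a band rather
than the exact endpoint.  The acceptance-level endpoint checks
therefore place measurement noise on the response log-ratio, where OLS
is unbiased.  Second, the one-sided Fisher variance test
(`F = var(x)/var(y)`, `(n-1, n-1)` df) assumes approximate normality
of the ratios; its null rejection rate is verified by simulation.

# Similarity, dominance and convergence indices

With the parental midpoint `mu = (E_CO + E_CG)/2`, the similarity
index of a subgenome is `S = (E_sub - mu)/mu`, multiplied by -1 when
`E_CG > E_CO`, so `S < 0` always reads "CG-like" and `S > 0`
"CO-like".  `S` is scale-invariant and undefined (excluded) when
`mu = 0` or the parental means are exactly equal — consistent with the
intended restriction to genes differentially expressed between the
parents.  The dominance score is `Delta_S = |S_Co| - |S_Cg|`.  Note
that under *complete* expression-level dominance both subgenomes sit
at the same parental level, so `|S_Co| = |S_Cg|` and `Delta_S` centers
on 0; a positive median `Delta_S` arises from *asymmetric* convergence
(one subgenome pulled towards the other's parent), which is exactly
what it is meant to measure.

The convergence index compares the parental gap
`Delta_par = |E_CG - E_CO|` with a comparison-specific gap `Delta_x`
(between subgenomes, or between one subgenome and the opposite
parent): `C = (Delta_par - Delta_x)/max(Delta_par, Delta_x)`, bounded
in [-1, 1], positive when subgenomes are closer than parents, 0 when
the gaps are equal.  All indices operate on natural-scale mean CPM, as
the formulas use raw differences.  Because homeologues share the same
RNA pool within an accession, `convergenceSummary()` exposes pairing
modes: averaging each subgenome across accessions first (the default,
which partly breaks the shared-pool association), within-accession
pairing, and cross-accession pairing that removes shared-individual
effects entirely; shared per-accession factors in the generator let
the expected ordering (same-individual at least as convergent as
cross-individual) be tested.

The spatial-clustering test asks whether a category's genes cluster
along a scaffold: distances between randomly sampled within-category
midpoint pairs are compared with between-category pairs by a
Wilcoxon-Mann-Whitney test.  The number of sampled pairs per
(scaffold, category) is capped at the category's gene count: reusing
each gene in many pairs makes the distances strongly dependent and the
rank test anti-conservative, which the cap avoids (verified by null
calibration under shuffled labels).

# Beta-binomial mutation-placement model

For each gene, `n` derived mutations fall on a homeologue pair and `k`
of them on the Cg copy.  The placement is `k ~ BB(n, b, phi)` with
`alpha = (0.5 + b)/phi` and `beta = (0.5 - b)/phi`: `b` in (-0.5, 0.5)
is the accumulation bias towards Cg and `phi >= 0` the overdispersion
of the per-gene placement probability; `phi -> 0` recovers
`Binomial(n, 0.5 + b)`.  The model lattice is M1 (`b = 0, phi = 0`),
M2 (free `b`), M3 (free `phi`), M4 (both), selected by hierarchical
likelihood-ratio tests (chi-square, df = parameter difference, 5%
level), stepping M1 -> {M2, M3} -> M4 with a direct M1 -> M4 test when
neither single-parameter extension is supported.  Joint models share
or free `(b, phi)` between the synonymous (SYN) and deleterious (DEL)
classes; SYN acts as the null that absorbs mapping bias and sampling
noise, and the reported `Delta_b = b_DEL - b_SYN`,
`Delta_phi = phi_DEL - phi_SYN` come from the fully free fit.

Numerical choices: optimization runs on the unconstrained working
scale `(logit(0.5 + b), log phi)` with three starting points (a
moment-based start for `b` plus dispersed alternatives), and the
`phi = 0` boundary is always evaluated explicitly, so boundary optima
are found exactly and flagged.  M2's estimate is the closed-form
`sum(k)/sum(n) - 0.5`.  Genes with `n = 0` carry no information and
are dropped; genes with `n = 1` inform `b` but not `phi`.  Tests
freeing `phi` place the null on the parameter boundary, so the
chi-square(1) reference is conservative; the
`0.5*chi2(0) + 0.5*chi2(1)` mixture is available behind the
`boundaryMixture` flag.  Confidence intervals are percentile
bootstraps resampling genes (the likelihood unit); failing replicates
are redrawn and counted.  Likelihood nesting
(`LL(M4) >= LL(M2), LL(M3) >= LL(M1)`) is asserted on every fit and an
LL decrease raises an internal error, since it can only mean optimizer
failure.

# Load-expression association

Per gene and accession, `d = DEL_Cg - DEL_Co` and
`e = E_Co/(E_Co + E_Cg)` (from normalized phased expression).  Records
with `d = 0`, without significant HSE, or with a (0, 0) expression
pair are excluded; the remainder is collapsed to a 2x2 table (sign of
`d` x side of `e`) and tested by a two-sided Fisher exact test with
the conditional-ML odds ratio.  An odds ratio above 1 means the copy
carrying more deleterious mutations tends to be the lower-expressed
one.  The synonymous control repeats the analysis with `d` computed
from synonymous mutations, restricted to genes with no deleterious
mutation at all: a mapping or annotation artifact would reproduce the
association there, a genuine load effect would not.

# The synthetic-data generator

`simulateExpression()` draws negative-binomial counts around per-group
means set by each gene's true category.  Defaults were chosen once to
emulate the motivating study design and are not tuning knobs: four
accessions per parental species and sixteen tetraploid accessions;
log-normal base expression (meanlog `log(100)` CPM, sdlog 1); parental
divergence `N(0, 1)` log2 units for divergently regulated genes;
gene-level dispersion log-normal around 0.05 (typical for inbred plant
lines); a category mix dominated by *no difference* (~60%) with a few
percent each of legacy, dominance, compensatory drift and reverse and
~13% transgressive, close to what allopolyploid flower tissue shows.
Transgressive genes sit one log2 unit beyond the more extreme parent
(configurable; no magnitude is implied by the motivating data).
Homeologue counts are drawn independently given their means by
default; an optional shared per-accession log-normal factor models the
fact that both homeologues are measured from the same RNA pool.
`simulateMutations()` draws per-gene totals Poisson (mean 5 by
default, matching a handful of derived coding variants per gene) and
places them by the beta-binomial above.  Ground truth is exported
alongside every dataset and never read by inference code.

What the generator does *not* emulate — and hence what passing tests
do and do not show about real data: no read-level artifacts (mapping
bias enters only through the DNA-count screen), no correlated gene
modules or batch structure, no length/GC biases, no tissue effects
within one simulated dataset, and mean-dispersion trends only through
the log-normal dispersion spread.  Calibration and recovery results on
these simulations demonstrate correctness of the implementation under
its stated model, not robustness to every artifact of real RNA-seq.

# Problem sizes and determinism

All randomness flows from explicit integer seeds; identical seeds give
bit-identical datasets, bootstrap intervals and reports
(`writeReport()` serializes floats at fixed precision for
byte-identical reruns).  The shipped tests use simulation sizes chosen
to make each statistical check decisive at its stated tolerance while
keeping the whole suite quick on a single CPU: 2000-gene regressions
for the cis/trans endpoints, 5000-gene fits for parameter recovery
(median absolute bias below 0.02 across a `b x phi` grid), 200
simulation replicates for bootstrap coverage and for the LRT type-I
checks, and 10,000-SNP null screens for FDR calibration.

# Known limitations

* The built-in DE engine is a log-CPM Welch test; users wanting
  count-model power should import edgeR/DESeq2 calls via
  `importCalls()`.
* HSE and mapping-bias screens are per-unit exact binomial surrogates;
  they do not pool information across SNPs or samples the way
  hierarchical Bayesian models do.
* The classifier's precedence resolves genuinely ambiguous call
  patterns by convention; proportions in the rarer categories shift
  with the FDR threshold (sweeping 0.01-0.1 is recommended).
* `phi` inference needs genes with `n >= 2`; datasets dominated by
  singleton mutations identify `b` only.
* The cis/trans slope from count-level data is attenuated by predictor
  noise; with deep data the effect is small, but comparisons across
  datasets with very different depths should use the same design.
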