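---
title: "Models and methods behind duetseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind duetseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duetseq)
```

duetseq dissects the combined and individual activities of two
interacting transcription factors from a 2×2 genetic design. This
vignette records the statistical models, the parameter choices and their
rationale, what the synthetic-data generator does and does not emulate,
and the numerical decisions that a maintainer would otherwise have to
reverse-engineer from the code. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The expression model

Log2 expression is modelled per gene as

$$S_{gytr} = GYT_{gyt} + R_r + \varepsilon_{gytr},$$

one mean per genotype × condition × tissue cell plus a biological
replicate effect. `fit_linear_model()` fits all genes in a single
vectorised least-squares pass. The replicate term is fitted as a *fixed*
sum-to-zero effect rather than a random effect: with three replicates
the shrinkage a random-effect fit would add is negligible, while the
fixed fit is exactly reproducible by a hand-written normal-equations
solver — which is how the unit tests verify it to 10⁻⁸.

`ebayes_moderate()` shrinks the gene-wise residual variances toward a
common prior. Writing $z_g = \log s_g^2$, the moments of $z$ under a
scaled-F model identify the prior degrees of freedom $d_0$ (by trigamma
inversion, Newton iterations) and the prior variance $s_0^2$ (from the
digamma-corrected mean). The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ feeds every
moderated t-statistic on $d_0 + d_g$ degrees of freedom. Degenerate
inputs are handled, not rejected: if the observed variances are
underdispersed relative to chi-square sampling noise (including the
all-equal and all-zero cases), $d_0 = \infty$ and the common value is
used; zero posterior variance yields $t = \pm\infty$, $p = 0$ for a
non-zero contrast. The implementation is cross-checked in the test
suite against limma's `eBayes()` on random data — limma is used only as
an independent oracle, never called by the package itself.

Storey q-values use the fixed-λ estimator
$\hat\pi_0 = \#\{p > 0.5\}/(0.5\,m)$, clamped to $(0, 1]$; the
smoothing-spline variant is unnecessary at the few-thousand-gene scale
this package targets and would add a tuning surface. With $\pi_0 = 1$
the q-values reduce exactly to Benjamini–Hochberg, which the tests
assert. A gene is a DEG when its fold-change exceeds 2
(`|log2FC| > 1`, strict) *and* `q < 0.01`. The fold-change threshold is
applied to the moderated cell-mean difference; with the fixed-effect
replicate fit the moderated and raw mean differences coincide, so the
choice is immaterial here but documented.

## Signal allocation and clustering

The four genotypes form a 2×2 factorial in the presence indicators
$f$ (functional FLC) and $s$ (functional SVP):

$$y = \beta_0 + \beta_F f + \beta_S s + \beta_{FS} f s,$$

with the double mutant as baseline. This encoding makes the published
sign convention exact — a negative presence coefficient is a repressive
contribution — and turns the coefficients into closed-form contrasts:
$\beta_F = \bar y_{svp} - \bar y_{double}$,
$\beta_S = \bar y_{flc} - \bar y_{double}$,
$\beta_{FS} = \bar y_{WT} - \bar y_{flc} - \bar y_{svp} + \bar y_{double}$.
The contrast identity is asserted to 10⁻¹⁰ in the tests.

Before clustering, genes must be up-regulated (DEG, direction up) in at
least one mutant, and genes whose change in a *single* mutant exceeds
the double-mutant change are excluded: such patterns cannot arise from
repression by the two factors and their complex alone. The exclusion
margin is one pooled standard error of the single-minus-double
difference. The underlying rule is qualitative; without a margin,
sampling noise alone would excise a noticeable fraction of genes whose
single and double effects are truly equal (complex-dependent and
single-factor modes), while a much larger margin would admit genuinely
anomalous genes. One SE is the smallest margin that makes the exclusion
a statement about signal rather than noise.

Cluster labels use coefficient significance at BH-adjusted p < 0.01
within each coefficient across genes, with precedence D (complex), B
(compensatory), C (additive), then A (single-factor) — interaction-
significant genes must never fall through to the additive class.
`allocation_recovery()` reports accuracy over the *analysed* (filtered)
genes: the filter is a deliberate abstention, not a misclassification,
and per-mode recall over all planted genes is reported alongside so the
abstention rate stays visible.

## Synthetic data: what it emulates, and what not

The generator's defaults are the study conditions the package is built
around: a 4-genotype × 2-tissue × 3-replicate expression design with 100
genes in each of six regulatory modes (single-factor ×2, additive,
compensatory, complex-dependent, null), planted effect size $e = 2$
log2 units, observation noise 0.2, and a per-replicate offset (sd 0.1)
shared across genes, genotypes and tissues — the exact counterpart of
the fitted $R_r$ term. Planted effects are identical in both tissues;
tissue-specific regulation is not emulated.

The ChIP arm plants, per TF, 40 ubiquitous (UB), 30 mutant-only (1TF)
and 30 WT-only (2TF) binding regions of width 100–200 bp on a 500 kb,
two-chromosome, 36 % GC genome (Arabidopsis-like), between 600 compact
gene models (300–500 bp). Gene models are deliberately compact so a
desk-scale genome carries a realistic gene count for annotation and
target-set arithmetic; UTR and intron structure is schematic (two exons,
50 bp terminal UTRs). Coverage is Poisson background (2 reads/bp before
rescaling) plus a Gaussian kernel at each active summit with
sd = width/4 truncated at ±2 sd — smooth summits make shape analysis
meaningful — at 20-fold enrichment, rescaled so each track totals the
library size (10⁶ reads) in expectation. Half of the UB regions double
their width in the mutant: the planted shape difference the Hotelling
test must find. Every region carries a CArG-box at its summit (spacer
T-biased in 1TF regions, A-biased otherwise); UB and 2TF regions carry
a G-box 150 bp downstream of the CArG-box; SVP UB/2TF regions a CE-box
100 bp upstream. Each output stream draws from its own RNG stream
derived from `(seed, role)`, so any single artefact regenerates
independently and byte-identically.

What passing tests on these data do *not* show: robustness to
fragment-length artefacts, duplicate reads, mappability gaps,
copy-number variation, probe effects, or tissue-specific regulation —
none of which are simulated. The generator validates the statistical
machinery against known truth; it does not certify performance on any
real library preparation.

## Peak calling and reproducibility

The caller tests each 10 bp bin against a local Poisson rate
λ = max(genome mean; 1, 5, 10 kb centred window means) from the control
track or, absent a control, from the sample itself excluding the tested
bin — the classic local-λ logic. Significant bins (P < 10⁻³) merge
across gaps ≤ 150 bp; regions shorter than 100 bp are dropped. The
summit is the leftmost argmax of a 3-bin (30 bp) moving average of
coverage within the peak: a raw single-bin argmax is dominated by
Poisson noise at 10-fold enrichment (neighbouring bins differ by about
one standard deviation), and the light smoothing recovers summit
positions to ±25 bp, which the tests demand at ≥ 95 % recovery.

Replicate consistency replaces a full irreproducible-discovery-rate
analysis with an overlap filter: peaks from different replicates link
when reciprocally overlapping ≥ 50 % of each; a consensus region needs
peaks from ≥ 2 of 3 replicates that mutually overlap, spans their
union, and takes the summit of the highest-scoring supporter. Within a
cluster of any-overlap peaks the best replicate-distinct
mutually-overlapping subset is found exhaustively (clusters are tiny)
with a greedy score-ordered fallback for pathological pile-ups.

## Dependency classes, scores, and shape testing

Comparing one TF's consensus peaks between genotypes uses ≥ 1 bp
interval overlap (the most inclusive reading; a reciprocal-fraction
mode exists), with many-to-one overlaps collapsed to a single UB region
anchored on the WT peak. Region strength is reads-per-million inside
the region; the direction summary reports the count and rounded
percentage of regions scoring higher with the partner present.

Shape testing extracts ±750 bp summit-centred profiles in 30 bp bins,
reads-per-million, windows snapped to the coverage grid and zero-filled
(and flagged) at chromosome ends. Functional PCA is fitted **once on
the stacked rows of all regions and samples**, not per region: with
only six profiles per region, per-region loadings would be selected by
the same noise they are then tested on, inflating the type-I error of
the downstream test; the aggregated fit keeps the F reference honest,
which the null simulation in the tests confirms at 0.05 ± 0.01. The
retained dimension is the smallest k reaching 85 % cumulative variance,
capped at $n_1 + n_2 - 3$ so the Hotelling F transform keeps at least
two denominator degrees of freedom (k ≤ 3 at 3 + 3 replicates; in
practice the cumulative-variance rule selects 1–2). Per region,
$T^2 = \frac{n_1 n_2}{n_1+n_2} d^\top S_{pooled}^{-1} d$ on the
replicate scores, F-transformed, BH-adjusted across regions,
significant at adjusted p ≤ 0.05. A singular pooled covariance falls
back to the Moore–Penrose pseudo-inverse and is flagged rather than
hidden. Heatmap ordering sorts regions by the maximum of
non-overlapping window medians, descending with a stable tie-break, and
masks regions containing any value above 20 on the same normalized
scale as the heatmap values.

Because coverage tracks are library-rescaled, a genotype whose peaks
carry more total signal has slightly depressed background and peak
heights elsewhere; ubiquitous regions can therefore show genuine,
detectable amplitude differences between genotypes even without a
planted shape shift. This mirrors the quantitative binding differences
the dependency analysis is designed to expose and is not suppressed.

## Motif statistics

PWMs are consensus-with-pseudocount constructions (the exact published
probabilities are not available): consensus positions carry
$1 - 3\varepsilon$, bracketed alternatives split their mass uniformly,
CArG spacer positions give $0.5 - \varepsilon$ to each of A and T, with
$\varepsilon = 0.01$. The CE-box consensus
`[CA]CGG[GT][AT]A[TG][AT]GCCGGT` spells 15 positions, and the PWM has
width 15 accordingly.

Scanning discretizes log-odds scores to 0.01 log2-unit ticks; *all*
scoring uses the tick matrix, and the match p-value is the exact upper
tail of the tick-score distribution computed by dynamic programming
(per-position convolution) under the 0-order background — so the
p-values are exact for the scored matrix, and the test suite verifies
them against exhaustive enumeration of all 4^w words up to width 8.
The discretization error on the score itself is at most half a tick per
position, far below anything that matters at the p < 0.001 match
threshold. Both strands are scanned (reverse-complemented tick matrix);
windows containing N are skipped; the background defaults to the base
composition of the scanned sequences (Laplace-smoothed so absent bases
keep log-odds finite) and can be fixed explicitly.

Note a structural property of threshold scanning: p < 10⁻³ admits, by
construction, about one window per kilobase per strand of *any*
background, so "contains ≥ 1 match" saturates in long regions. The
permutation test absorbs this — the null sets see the same saturation —
but Z-scores are most informative for compact regions.

Permutation enrichment places, 1000 times, a random region set with
*exactly* the observed lengths (exact matching removes a free
parameter) uniformly over the genome, counting regions that contain at
least one significant match; Z = (observed − null mean)/null sd, with
Z > 3 significant. A degenerate null (sd = 0) yields Z = 0 when the
observation equals the null mean, otherwise an infinite Z reported
significant only when the observation exceeds the mean. Co-occurrence
uses the same scheme on regions containing both motifs; this
permutation construction is the package's choice of significance
scheme, as the original analysis states significance without naming a
test. Nearest-distance distributions measure start-to-start distances
from each match of one motif to the closest match of the other within
the same region; spacer composition tables are strand-resolved (motif
orientation) so biological A/T asymmetries survive aggregation.

## Annotation and integration

A peak is assigned to *every* gene whose window it overlaps — the
window spans 3 kb upstream of the TSS to 1 kb downstream of the TES in
transcription direction — because the underlying rule speaks of peaks
residing in such windows, and overlap is the inclusive reading (a
summit-containment mode and a nearest-gene flag exist). Summit location
classes use the precedence promoter > 5'UTR > 3'UTR > exon > intron >
immediate-downstream > intergenic; the precedence is a package
convention (promoter first, because MADS-box binding concentrates in
promoters), and no enhancer class is emitted since the synthetic genome
carries no enhancer annotation. Set algebra (`venn_counts()`,
`dependency_sets()`, `shared_fraction()`, `direct_target_report()`)
treats gene identity as plain string matching. `chisq_2x2()` delegates
to the standard Pearson test with Yates correction on by default; the
published comparison of unique-versus-shared targets between genotypes
does not state its table construction, so the package's rows-=-genotype,
columns-=-(unique, shared) construction is documented as a choice, not
asserted as the original's.

## Problem sizes and reproducibility

The default design — 500 kb genome, 600 genes, 100 binding regions per
TF, three replicates per genotype — was chosen so a complete
simulate-fit-call-test cycle runs in well under a minute on a single
core while every recovery statistic (cluster accuracy ≥ 0.9, summit
recovery ≥ 95 % at 10-fold enrichment, shape-shift power ≥ 80 %,
nominal Hotelling type-I error, permutation Z separation) is computed
at the scale its contract states. Null-calibration checks use 2000
regions and 5000 genes. `scripts/acceptance.R` re-runs the whole of
this from a single `--seed` and writes the resulting numbers as JSON;
every random draw in the package flows through a named RNG stream
derived from that seed.

## Known limitations

Fragment-level read simulation, duplicate handling, mappability and
copy-number artefacts are out of scope, as are probe-level microarray
summarization and de novo motif discovery (known-motif scanning covers
the downstream statistics). The reproducibility filter is a documented
simplification of IDR. Backgrounds above order 0 are not supported in
the scanner. The chi-square table construction and the fPCA component
rule are package conventions where the original analysis is silent;
both are parameterized.
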