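---
title: "Methods: geographic clines and cytonuclear co-introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographic clines and cytonuclear co-introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cytocline` analyses hybrid zones between two poplar lineages — *Populus
trichocarpa* (PT) and *P. balsamifera* (PB) — where the chloroplast
genome and individual nuclear genes may cross the zone at different
places and rates. This vignette documents the statistical machinery; see
the README for a quick tour.

## 1. Transect geometry

Samples are placed on a one-dimensional transect per contact zone.
Great-circle distances use the haversine formula with a spherical Earth
radius of 6371.0 km. Within each contact zone, distance from an anchor
sample (by default the westernmost, i.e. minimum longitude; an explicit
anchor id may be supplied) is min–max scaled to [0, 1]. Zones are scaled
independently, so cline parameters are comparable only within a zone.

## 2. The cline model family

The core of the package is a sigmoid cline for the probability (or mean)
of PT ancestry at scaled position $x$:

$$\Psi(x) = \frac{1 + \tanh\!\big(2 (x - c)/w\big)}{2},$$

with center $c$ (where $\Psi = 1/2$) and width $w$ defined as the
inverse of the maximum slope. Optional exponential **tails** replace the
sigmoid beyond offsets $\delta_L$, $\delta_R$ from the center:

$$\Psi(x) = \Psi(c - \delta_L)\, e^{4 \tau_L (x - (c - \delta_L)) / w}
\quad (x < c - \delta_L),$$

and symmetrically on the right, continuous at the junctions. **Scaling**
maps $\Psi$ to observed frequencies $p(x) = p_{\min} + (p_{\max} -
p_{\min})\, \Psi(x)$, where the ends are fixed at 0/1 (`none`), set to
the empirical bottom/top decile means (`fixed`), or estimated (`free`).
Three scalings × five tail configurations (`none`, `left`, `right`,
`mirror`, `both`) give 15 variants with $k = 2$ to $8$ parameters.

Three likelihoods share this mean function: `bernoulli` (a single
haplotype or the chlorotype), `binomial2` (diploid gene ancestry in
{0, ½, 1}), and `gaussian` (continuous summaries such as mean ancestry),
whose variance is profiled out analytically. Probabilities are clamped
to $[10^{-9}, 1 - 10^{-9}]$ before taking logs.

### Fitting and numerical choices

`fit_cline()` maximizes the log-likelihood with L-BFGS-B from a
space-filling (Latin hypercube) set of starts (default 20), seeded
deterministically; the best converged start wins. Free scaling is
reparameterized as $(p_{\min}, \text{gap})$ with $p_{\max} = p_{\min} +
\text{gap}\,(1 - p_{\min})$ so the box constraint $p_{\min} < p_{\max}$
is linear. Bounds: $c \in [10^{-4}, 1 - 10^{-4}]$, $w \in [10^{-3}, 2]$,
$\tau \in [10^{-3}, 1]$, $\delta \in [0, 1]$. Estimates within
$10^{-6}$ of a bound are flagged. `select_cline_model()` fits any subset
of the 15 variants and picks the minimum AIC ($2k - 2\ln L$), breaking
ties toward fewer parameters.

### Support intervals

Uncertainty uses profile-likelihood support intervals: the set of values
whose profile log-likelihood lies within $\Delta = 2$ units of the
maximum (roughly a 95% interval for one parameter). Endpoints are found
by `uniroot` on each side of the estimate; a side that never drops by
$\Delta$ before its box bound is reported at the bound and flagged.

## 3. Co-introgression classification

Reference clines are fitted for the chloroplast (bernoulli, on the
chlorotype) and for the genome-wide mean nuclear ancestry (gaussian).
Each candidate gene's ancestry proportions (mean of the two haplotype
indicators over the SNPs in the gene ± 100 bp flanks) are fitted with
the same variant family, and the gene is classified by a
both-parameter overlap rule: it *overlaps* a reference when **both** its
center and width point estimates fall inside that reference's support
intervals. A gene is

* `co_introgressing` — overlaps the chloroplast reference only,
* `ambiguous` — overlaps both references,
* `independent` — anything else,
* `unevaluable` — its fit did not converge.

A complementary constrained likelihood-ratio test refits the gene with
its center bounded inside a reference's center interval; the statistic
$2(\ln L_{\text{free}} - \ln L_{\text{constrained}})$ is referred to
$\chi^2_1$. Per-gene seeds are derived from the gene id, so verdicts do
not depend on gene order.

## 4. Climate association (Firth logistic regression)

Chlorotype is regressed on one climate variable at a time, per contact
zone, on the variable's native unit scale. Because zones can approach
chlorotype fixation (separation), we use Firth's bias-reduced logistic
regression, maximizing $\ell^*(\beta) = \ell(\beta) + \tfrac12 \ln \det
I(\beta)$ by Newton iterations on the modified score $X^\top\!\big(y -
p + h(\tfrac12 - p)\big)$ (with $h$ the hat diagonals), with
step-halving. Standard errors come from the inverse penalized
information. Degenerate strata are reported as `monomorphic`,
`too_few`, or `rank_deficient` rather than erroring.

## 5. Common-garden quantitative genetics

Broad-sense heritability per garden uses the clonal-replicate REML model
`value ~ (1 | genotype) + (1 | block)` and $H^2 = V_G / (V_G + V_E +
V_{\epsilon})$. The cytonuclear model is
`value ~ N * C + garden + (1 | garden:block)` with $N$ the continuous PT
nuclear ancestry and $C$ the chlorotype indicator (PT = 1); Wald tests
use Satterthwaite degrees of freedom, and marginal/conditional $R^2$
follow the variance-partitioning convention (fixed effects alone vs
fixed plus block). Exact-interpolation data (residual variance
numerically zero) fall back to the least-squares solution.

## 6. Chloroplast fixed differences

A fixed difference is an alignment column where each chlorotype group is
internally monomorphic for a different nucleotide; any gap or ambiguity
code masks the column (reported separately via the `masked_columns`
attribute, since indels are not substitutions). Effects use the plastid
(bacterial/plant-plastid, table 11) genetic code; minus-strand codons
are reverse-complemented before translation, and multiple fixed
differences in one codon are translated jointly and flagged
`multi_site`. Distances are Jukes–Cantor, $d = -\tfrac34 \ln(1 -
\tfrac43 \hat p)$ over pairwise-complete ACGT sites (undefined at $\hat
p \ge 0.75$). Trees are neighbour-joining with taxa processed in
lexicographic order and negative branch lengths clamped to zero, the
deficit moved to the sister branch so path lengths are preserved.
Polarization roots the tree on an outgroup: a chlorotype is called
ancestral only when the other group is monophyletic and strictly farther
from the outgroups on average; anything less is `unresolved`.

## 7. Synthetic data

All generators are deterministic given a seed, with independent
substreams per component. The hybrid-zone generator places $n$ samples
on a constant-latitude line (so haversine + min–max scaling recovers the
planted transect), draws the chlorotype from a Bernoulli cline (default
$c = 0.43$, $w = 0.05$), and draws two independent haplotype ancestries
per gene per individual (Hardy–Weinberg at the local cline frequency —
real data's linkage disequilibrium is out of scope), constant across the
SNPs of a gene. Co-introgressing genes get the chloroplast cline's
parameters; the rest use the nuclear default ($c = 0.68$). The trait
generator follows $y = \mu + \beta_N N + \beta_C C + \beta_{N \times C}
N C + \beta_E \mathbf 1(\text{garden}) + G + \text{block} + \epsilon$ on
a balanced two-garden, three-block design. The chloroplast alignment
generator plants exact numbers of synonymous (four-fold third
positions of GGN codons), nonsynonymous (AAA→GAA first positions) and
noncoding differences — 30/9/23 = 62 by default — honoring CDS frames
and strands, plus private within-group polymorphisms that can never
create spurious fixed differences.

## 8. Pipeline

`run_all()` executes simulate → transect → co-introgression scan →
climate association → quantitative genetics → chloroplast scan, records
per-stage status and wall time, skips only the dependents of a failed
stage, and writes every table plus a `run_report.json` whose
`config_hash` excludes the output directory, so identical analyses in
different directories hash identically.

## Conventions resolved by this package

Where the underlying methods admit choices, `cytocline` fixes them as
follows: transects are normalized per contact zone; overlap requires
both center and width (point estimates vs reference intervals); the
constrained LRT bounds the center inside the reference interval rather
than pinning it to a point; climate slopes are reported per native unit
(per °C, per %, per mm); ancestry matrices use a haplotype-per-row TSV
layout (`id_1`/`id_2` suffixes, `chrom:pos` columns); and haplotypes are
simulated independently within individuals.
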