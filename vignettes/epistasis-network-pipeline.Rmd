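---
title: "From an epistatic QTL pair to candidate interacting gene networks"
author: "qtlspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From an epistatic QTL pair to candidate interacting gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

qtlspan implements an inference chain for quantitative traits governed by a
pair of *interacting* loci: two-dimensional two-QTL genome scans with
permutation thresholds, haplotype-window delimitation of the linked
regions, and cross-locus protein-network prioritization by
degree-preserving randomization.  The motivating use case is native airway
constrictor responsiveness in mouse F2 intercrosses, where animals
homozygous for the high-responder founder allele at two unlinked loci show
roughly doubled responsiveness while neither locus has a detectable
marginal effect.  This vignette records the models, the tunable
parameters, the numerical conventions, and the design choices behind the
package.

## The synthetic study design

No individual-level genotype or phenotype data are available for the study
design the package emulates, so the simulator is a first-class module: it
defines the conditions under which every downstream claim is tested.

**Marker map.** `make_map()` lays out 384 markers over the 19 mouse
autosomes by default, allocated proportionally to physical chromosome
lengths (largest-remainder rule, at least one marker per autosome) and
spaced uniformly.  The default spacing of 6.5 Mb is the total autosomal
length (~2.5 Gb) divided by 384; the published description of such panels
quotes a 3 Mb average density, which is not consistent with 384 markers
genome-wide, so the spacing is an explicit parameter rather than a
resolved constant.  Genetic positions use a constant 0.5 cM/Mb, the mouse
genome-wide average.  The X chromosome is omitted: the emulated study
phenotyped males only, and modelling hemizygous segregation would add
machinery without exercising any additional code path.

**Meiosis.** `simulate_f2()` draws each F2 animal as the sum of two
independent gametes.  Along a gamete the founder allele switches between
adjacent markers with the Haldane recombination fraction
$r = (1 - e^{-2d/100})/2$ for map distance $d$ cM — the standard
no-interference model, chosen because nothing in the emulated design
constrains interference.  Chromosomes segregate independently.

**Phenotype.** `simulate_phenotype()` implements the epistatic model

$$y_i = \mu \, \rho^{\,[g_{ia} = AA \;\wedge\; g_{ib} = AA]} + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

truncated below at $10^{-6}$ to preserve positivity.  Defaults:
baseline $\mu = 1$ (arbitrary responsiveness units; every LOD statistic is
invariant under affine rescaling of the phenotype), effect ratio
$\rho = 2$ reproducing the "about double" responsiveness of
double-homozygous animals, and $\sigma = 0.25$, i.e. a 25% coefficient of
variation — a realistic noise level for forced-oscillation resistance
measurements, and one at which the planted interaction is clearly but not
trivially detectable at $n = 115$.  Under independent segregation a
fraction $1/16$ of F2 animals (~7 of 115) is double-homozygous.

**Parental averages.** `add_parental_averages()` appends one all-AA and
one all-BB row whose phenotypes are the exact model means, emulating the
practice of entering one average animal per parental strain so that the
founders inform the scan without being over-represented.  Scans include
these rows by default (`include_parental = TRUE`), giving the canonical
117-row analysis; permutations shuffle the phenotype across all 117 rows,
parental averages included, since nothing distinguishes them once they are
in the design.

## The two-QTL scan

`scan_one()` and `scan_two()` are marker-regression scans on typed
genotypes with complete-case handling per marker (pair).  The emulated
panel is fully genotyped, so multipoint hidden-Markov genotype
reconstruction and pseudomarker grids are deliberately out of scope; on
fully informative markers the two coincide.

For a model $M$ with residual sum of squares $RSS_M$ on $n$ complete
cases, $LOD = (n/2)\log_{10}(RSS_0/RSS_M)$ with $RSS_0$ from the grand
mean.  The pair scan fits

* the **full** model: one mean per observed cell of the 3×3
  joint-genotype table (empty cells contribute no parameters, so the
  degrees of freedom shrink with the observed table);
* the **additive** model: intercept plus marker-a and marker-b main
  effects, at most 5 free parameters, fitted by least squares through a
  Moore–Penrose pseudo-inverse so that collinear designs (e.g. tightly
  linked pairs) degrade gracefully to the projection onto the attainable
  column space;

and reports `lod_full`, `lod_add`, and the pointwise interaction score
`lod_int = lod_full − lod_add` per marker pair.  A zero full-model
residual is carried as an explicit infinite-LOD flag rather than a large
number, and flagged pairs are excluded from permutation maxima so that a
single perfectly separable pair cannot dominate a threshold.  When the
additive model is itself saturated the interaction score is exactly zero.
Internally the scan is expressed in per-pair sufficient statistics (cell
counts, cell sums, quadratic forms against precomputed pseudo-inverses),
so a phenotype permutation costs ten dense matrix products instead of
73,536 model fits; this is what makes genome-wide permutation thresholds
at full study size routine on one core.

**The interaction summary statistic.** Two conventions coexist for "the"
interaction LOD.  The pointwise score above is the per-pair quantity and
is what `scan_two()` records.  Standard two-QTL mapping software, however,
summarises interaction evidence per *chromosome pair* as

$$M_i(j,k) = \max_{\text{surface}(j,k)} LOD_{\text{full}}
           \;-\; \max_{\text{surface}(j,k)} LOD_{\text{add}},$$

the two maxima taken separately over the pair's two-locus surface
(`chrpair_interaction()`).  Because the additive maximum need not occur at
the full-model peak, $M_i \le \max(\text{pointwise } lod_{int})$, and the
two statistics have visibly different genome-wide null distributions: at
117 animals × 384 markers the 5% permutation threshold is ≈ 7.6 for the
pointwise maximum but ≈ 6.5 for the chromosome-pair statistic.  qtlspan
uses the chromosome-pair convention for `permutation_thresholds(statistic
= "max_int")` and for significance calls, matching the convention under
which published interaction cutoffs in this design (≈ 6.3) were derived;
`peak_pair()` still ranks marker pairs by the pointwise score for
localization and reports both values.

**Permutations.** The phenotype vector is permuted uniformly among all
scanned animals with genotypes fixed; the threshold is the empirical
$1-\alpha$ quantile (type-7 linear interpolation — stated because
permutation thresholds differ across quantile conventions) of the
per-permutation genome-wide maxima.  1,000 permutations is the default;
500 give a threshold standard error near 0.1 LOD at study size.  Same-
chromosome pairs are scanned (an interacting pair on one chromosome is
biologically admissible), and `exclude_adjacent_cM` can suppress
near-collinear neighbours; the default of 0 excludes nothing.
Multiplicity across the pair grid is handled solely by this genome-wide
max-statistic null; there is no per-pair FDR.

## Haplotype windows and gene lists

Given the peak interacting pair, `select_high_responders()` takes the
mice homozygous AA at both peak markers (the parental all-AA average row
qualifies by construction).  `nonrecombinant_span()` delimits, on each
peak's chromosome, the maximal contiguous marker run containing the peak
at which *no crossover is observed* in any selected mouse: an observed AB
or BB genotype terminates the run, while a missing genotype is treated as
compatible — a crossover must be seen to delimit the locus, absence of
data is not evidence of recombination.  `extend_interval()` converts the
span to physical coordinates and extends it by 1 Mb (default) on both
ends, clamped to the chromosome, to admit distal cis-regulatory elements;
a `one_sided` mode extends only the telomeric end, since descriptions of
this procedure vary between "1 Mb on either end" and "1 Mb telomeric" and
the package does not guess which was meant.

Coordinates are 1-based inclusive internally; BED input/output is
converted on read/write (via rtracklayer), since an off-by-one here
silently changes gene lists.  `genes_in_interval()` uses the any-overlap
rule (≥ 1 bp, strand ignored): the regulatory-element motivation for the
flank argues for inclusiveness, and a gene abutting the interval boundary
is kept.

## Cross-locus network prioritization

`filter_string_edges()` reduces a STRING-dialect detailed-links table to
a high-confidence network: combined score strictly greater than 800 *and*
at least one positive score among the fusion, experimental and database
channels — which removes interactions supported only by literature text
mining.  Duplicate A–B/B–A records merge by elementwise maximum; the
filter is idempotent.

The SPAN question is whether specific proteins encoded in window A
interact with proteins encoded in window B more than their overall
connectivity predicts.  The null model conserves every protein's degree
in the *full* filtered network (not the bipartite subgraph), so
cross-locus counts reflect genome-wide degree structure.  It is sampled
by double-edge swaps — `swaps_per_edge = 10` swap trials per edge per
sample, each sample restarted from the observed network with an
independent seeded stream — rejecting swaps that would create self-loops
or multi-edges.  For each candidate protein the observed cross-locus
degree is compared with its null distribution; for each observed
cross-locus edge, its null occurrence frequency.  Empirical p-values use
the pseudocount estimator $p = (r+1)/(N+1)$, which cannot reach zero
under finite sampling, and Benjamini–Hochberg FDR is applied separately
to the node and edge families.  Display tiers follow the convention
strong $q < 10^{-4}$, weak $q < 0.5$, background otherwise; the headline
subnetworks are those whose edge *and* both endpoint nodes are strong.

On graphs small enough to enumerate every degree-preserving simple graph,
the Monte-Carlo p-values agree with exhaustive enumeration within
binomial error (see the test suite); rigid graphs such as a triangle
yield p = 1 everywhere, and proteins absent from the network report an
observed cross-degree of 0 with p = 1 rather than an error.

## The pipeline and its synthetic scenario

`run_pipeline()` chains the stages (simulate/load → scans → permutation
threshold → peak pair → windows → gene lists → network filter → SPAN)
with per-stage seeds derived from one configuration seed, so a
configuration reruns byte-identically; every artifact embeds the seed and
an MD5 hash of the canonical configuration text.  The default simulated
scenario plants the interacting pair at the middle markers of
chromosomes 11 and 18, tiles genes every 2 Mb with guaranteed genes at
the two peaks, maps genes 1:1 to opaque protein identifiers, and builds a
preferential-attachment background network (~1.5 edges per node) in which
the two peak-gene proteins share a planted low-degree cross-locus edge
while decoy cross-locus edges attach to deliberately hub-boosted
endpoints — so recovering the planted edge as the top-ranked interaction
is a discriminating test, not a tautology.

## What the simulations do and do not show

The generator reproduces the statistical skeleton the analysis assumes:
Mendelian F2 segregation, Haldane linkage, a multiplicative two-locus
penetrance with Gaussian noise, and a degree-heterogeneous interaction
network with planted structure.  It does not emulate genotyping-batch
artifacts, segregation distortion, crossover interference, phenotype
skew or dose-titration ceilings, polygenic background beyond the planted
pair, or the ascertainment structure of a real interaction database.
Passing tests therefore demonstrate correctness of the machinery and
calibration under the stated model, not robustness to every pathology of
real cross data.

## Numerical conventions and degenerate inputs

* Residual sums of squares below $10^{-12}\,\max(\sum y^2, 1)$ count as
  zero (perfect fit → infinite-LOD flag; constant phenotype → all LODs 0).
* `lod_int` is clamped to be non-negative; the additive RSS is clamped
  between the full-model and null RSS before logs are taken.
* Markers (pairs) with fewer than two observed genotype classes are
  flagged with LOD 0 and a warning, never an exception; an all-missing
  marker reports `n_used = 0`.
* Ties in `peak_pair()` break lexicographically by chromosome and
  position, so output order is total and reproducible.
* All randomness flows through explicit integer seed arguments
  (`withr::with_seed`); no function touches the global RNG state.

## Problem sizes used in the checks

The shipped checks run the full 117 × 384 design with 500 permutations
for the threshold reproduction, a 60-animal × 48-marker panel with 200
permutations × 100 seeds for type-I calibration, 5,000 randomizations for
the enumeration comparison, and the complete default scenario (100
permutations, 500 randomizations) for end-to-end planted-truth recovery —
sizes chosen so the whole suite completes in minutes on one core while
leaving each statistical comparison adequately powered.
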