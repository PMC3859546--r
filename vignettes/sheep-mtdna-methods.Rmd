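---
title: "Methods: sheep mtDNA haplogroups, diversity and demographic history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sheep mtDNA haplogroups, diversity and demographic history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovismthap)
```

`ovismthap` analyses sheep mitochondrial DNA variation: classification of
control-region (CR) sequences into the five domestic-sheep haplogroups
(HPG A–E), the 75/76 bp tandem-repeat length polymorphism marking the two
maternal clusters, diversity and neutrality statistics, mismatch
distributions under the sudden-expansion model, spatial autocorrelation of
haplogroup composition, and tree/network summaries. This vignette explains
the models, the defaults, and what the synthetic-data generators do and do
not emulate.

## Coordinates and sequence handling

All genomic positions are 1-based, inclusive, on the sheep mitochondrial
reference AF010406: the CR used in practice spans positions 15437–16616
(1180 bp), a short ancient-DNA fragment spans 15391–15534 (144 bp), and
the partial cytochrome B alignment spans 14180–15221. `anchor_to_reference()`
locates a fragment on a reference by an exact 20-mer seed and a semi-global
alignment (end gaps in the reference are free, so a fragment floats inside
the longer reference; match +1, mismatch −1, gap −2, `N` neutral). Input of
exactly the reference length is taken as pre-aligned, so users who aligned
their data elsewhere bypass the built-in aligner entirely. The alignment
mode matters: a fully global alignment can let the first few columns of a
fragment wander into the padding when a substitution sits near the
fragment edge; free reference end-gaps remove that incentive, and the test
suite checks the coordinate map against an independently coded aligner.

`N`, `-` and `?` are treated as missing and deleted *pairwise* from every
difference and distance computation — the convention of the standard
DNA-polymorphism software, and the safe choice for ancient-DNA-grade data.
Haplotype collapsing merges sequences identical at all mutually non-missing
sites; because that relation is not transitive, merging is greedy in input
order with representative back-filling, a deterministic rule for a
fundamentally ambiguous situation.

## Haplogroup classification

The shipped diagnostic table encodes the five-site CR scheme
(positions 15459, 15476, 15484, 15509, 15512): HPG A = 15459 T + 15484 A,
HPG C = 15509 G, HPG E = 15476 C + 15509 G, and HPG B = the reference
state at every site. HPG D and the wild *O. g. anatolica* X haplotype have
no published signature in this scheme; their slots ship empty and such
samples fall to `unassigned` unless the user supplies rules — the package
never invents diagnostic bases.

A sample matches a haplogroup when it carries **all** of that haplogroup's
required derived bases; among several matches the most specific signature
(by set inclusion) wins, so an E sample (15476 C + 15509 G) is not called
C (15509 G alone). Extra variation at sites a signature does not constrain
is tolerated: ancient samples occasionally carry private or damage-derived
states at other diagnostic positions, and requiring the full five-site
profile to be exactly reference-or-signature would discard them. Partial
possession of a signature, by contrast, is never nearest-matched — those
samples are `unassigned` (`max_missing` defaults to 0, so any unreadable
diagnostic site also voids the call).

## Tandem-repeat clusters

The CR carries 3–5 tandem copies of a 75 bp unit; the first unit is always
75 bp, and the length of the second and subsequent units separates the two
maternal clusters: 75 bp for HPGs A, B, D (cluster i) and 76 bp for HPGs
C, E and the wild X haplotype (cluster ii). Because the literature quotes
the array start both as position 15640 and as the 213th CR base (15650),
`parse_repeats()` does not trust a fixed coordinate: it searches a ±30 bp
window around the expected start for the position with the best 75/76 bp
self-similarity, then extends greedily, accepting up to `d_max = 5`
mismatches per unit and deciding 75 vs 76 by the better-scoring
continuation (ties prefer 75). Arrays outside 3–5 units warn; an
undetectable array is an error, never a guess.

## Diversity statistics

* Haplotype diversity: `h = n(1 − Σp²)/(n − 1)` with Nei's (1987, eq. 8.12)
  sampling variance. A two-sequence, two-haplotype group gives
  `h = 1.000 ± 0.500` — a useful analytic checkpoint.
* Nucleotide diversity: `π = Σ_{i<j} d_ij / C(n,2) / L̄` under pairwise
  deletion, variance per Nei (1987, eq. 10.7).
* Between-group divergence: `Dxy = mean pairwise cross-group differences
  per site`, symmetric by construction.

The tandem-repeat array is masked (`mask_repeat_region()`) before
diversity, tree and network computations in the pipeline: repeat-number
variation would otherwise register as large indel blocks. A user can pass
unmasked alignments to the individual functions if inclusion is wanted.

## Neutrality tests

Tajima's D uses the 1989 constants; `S = 0` yields an undefined statistic,
not zero. Fu's Fs is computed from the Ewens sampling formula at
`θ̂ = mean pairwise differences` (Fu's own estimator choice):
`S′ = P(K ≥ k_obs)` evaluated with unsigned Stirling numbers of the first
kind in log space (stable for n up to several hundred; the recurrence is
verified against direct polynomial expansion), and `Fs = ln(S′/(1 − S′))`.
`k_obs` uses the same haplotype-collapsing rules as the diversity module.

p-values come from coalescent simulation, the approach of the standard
population-genetics packages: for D, constant-size replicates at
`θ = S/a₁` with a two-tailed comparison on |D|; for Fs, replicates at
`θ = θ̂` with `P(Fs_sim ≤ Fs_obs)`. All Monte-Carlo p-values in the
package (neutrality, SSD bootstrap, spatial permutation) include the
observed dataset in the reference set — `p = (1 + k)/(B + 1)` — the form
with a finite-sample validity guarantee. The default is 10,000 replicates;
tests and the pipeline scale this down (the vignette's calibration checks
use 300 replicates per dataset, 100 datasets).

## Mismatch distributions and the sudden-expansion model

A population at scaled size `θ0 = 2N0u` expands instantly to `θ1 = 2N1u`
at time `τ = 2ut` (mutational units) before sampling. With
`F̂_j(θ) = θ^j/(1+θ)^{j+1}` the geometric equilibrium distribution of
pairwise differences, the transient distribution is

    F_j(τ) = F̂_j(θ1) + e^{−τ(θ1+1)/θ1} Σ_{i=0}^{j} τ^{j−i}/(j−i)! [F̂_i(θ0) − F̂_i(θ1)]

This was re-derived from the pair coalescent with a piecewise-constant
size rather than copied: at `τ = 0` it reduces to `F̂(θ0)` (immediately
after the expansion the pairwise differences still reflect the
pre-expansion equilibrium) and approaches `F̂(θ1)` as `τ` grows. The
transcription is *validated against the package's own coalescent
simulator*: at (τ = 4, θ0 = 1, θ1 = 100) the total-variation distance
between the formula and 2,000 simulated replicates is required to be
below 0.03 — the simulator, not the algebra, is the source of truth.

Fitting minimises the sum of squared deviations between observed and
expected mismatch frequencies over (τ, θ0, θ1): a deterministic coarse
grid (τ over [0, 2·mean], θ0 over (0, mean], θ1 ∈ mean·{10, 100, 1000})
followed by Nelder–Mead refinement with box penalties. θ1 is capped at
10⁵·mean — beyond that the surface flattens into an unidentifiable ridge.
θ0 ≤ θ1 is enforced. The goodness-of-fit test is a parametric bootstrap:
simulate under the fitted parameters, refit each replicate, and report
`p = (1 + #{SSD_sim ≥ SSD_obs})/(B + 1)` (minimum 100 bootstraps;
default 1000). One calibration caveat is worth knowing: when θ0 is weakly
identified (small samples, strong expansions) the least-squares fit tends
to drive θ0 toward zero, and simulating the bootstrap null at the fitted
rather than the true parameters makes the test mildly anti-conservative —
rejection rates a few points above nominal in the package's own
calibration experiments, against exact calibration when the null is
simulated at the true parameters. This is inherent to the plug-in
parametric bootstrap the method prescribes, not to this implementation.

Analyses that repeat a statistic over nested sample sets and trimming
windows (the E1/E2/E3 pattern: the same haplogroup at n = 11/15/20 and
886 or 665 bp) are expressed as pipeline configuration, not code.

## The coalescent generator

`gen_coalescent()` simulates the standard n-coalescent with infinite-sites
mutations, time measured in mutational units (`s = ut`): `k` lineages
coalesce at rate `k(k−1)/θ`, mutations fall at rate 1 per lineage per unit
`s`. Under sudden expansion the size switches from the θ1 scale to the θ0
scale at `s = τ/2` looking backward, which makes the generator's τ
directly comparable to the fitted mismatch τ. The generator is validated
against closed-form coalescent expectations — E(π) = θ,
E(S) = a₁θ, Var(S) = a₁θ + a₂θ² — rather than against another simulator;
the analytic moments are an equally independent oracle and keep the test
suite self-contained. No recombination, selection, or recurrent mutation;
the infinite-sites assumption applies to simulated data only, never to
real-data operations.

## Spatial autocorrelation

Haplogroup labels give a binary haploid squared distance (0 same, 1
different); double-centring yields a covariance matrix C, and for each
geographic distance class `r(h) = Σ c_ij / Σ (c_ii + c_jj)/2` over the
pairs in the class (Smouse & Peakall 1999). Defaults follow field
practice: 150 km half-open classes (boundary pairs go up), a 95%
permutation belt from 999 label permutations, per-class 95% bootstrap CIs
from 1000 pair resamples, and one-tailed upper permutation p-values with
the +1 correction. Real coordinates use great-circle (haversine) distance;
the synthetic flock generator works on a plane in km (its `x_km`/`y_km`
columns feed `metric = "planar"`), since nothing in the method depends on
the curvature of a 1500 km study area. Individuals within a flock share
the flock's coordinates, so within-flock pairs fall in the first class.

## Trees and networks

TN93 distances are computed from the two transition proportions, the
transversion proportion and base frequencies pooled over the collection
(no rate heterogeneity); saturated pairs flag an infinite distance.
Neighbor-joining uses the standard agglomeration (via ape) with negative
branch lengths clamped to zero; bootstrap support resamples alignment
columns, rebuilds the TN93+NJ tree and counts original bipartitions.

The median-joining network follows Bandelt–Forster–Röhl: an ε-relaxed
minimum spanning network (an edge is kept iff its weight is within ε of
the single-linkage merge level of its endpoints, computed from minimax MST
paths), iteratively augmented with quasi-median vectors — the positionwise
majority state of linked triplets, ties resolved deterministically toward
the central node — whenever one strictly reduces the total spanning cost,
then pruned of median vectors with degree < 3. Defaults: ε = 0 and uniform
position weights of 10, the conventions of the standard network software;
the exact per-position weighting used in published cytB networks is not
fully specified in the literature this package follows, so weights are a
user-configurable table. Positions with any missing state are removed
before network construction (complete deletion) to keep the weighted
Hamming distance a metric. With ε = 0 the network always contains a
minimum spanning tree of its final node set; once median vectors enter,
direct links between observed haplotypes may legitimately be replaced by
shorter paths through a median (the 3-haplotype Steiner star is the
canonical example).

## Synthetic data: what it does and does not show

The generators are pure functions of (parameters, seed):

* `gen_haplogroup_panel()` emits CR sequences (positions 15391–16616 of a
  deterministic *synthetic* reference — same coordinate layout and site
  structure as AF010406, not its real bases) carrying their haplogroup's
  diagnostic bases, a 75 bp first repeat unit, 2–4 further units of 75 or
  76 bp (total 3–5; four dominates at 90%, five only in the 76 bp
  cluster), and Poisson-distributed private substitutions (default mean 2)
  at non-diagnostic, non-repeat sites. Default haplogroup frequencies
  (A 0.30, B 0.40, C 0.20, E 0.10) echo the approximate modern composition
  of Turkish native breeds.
* `gen_spatial_panel()` places flocks uniformly on a square (default
  1500 km, roughly the east–west extent of Anatolia; default 20 flocks of
  15) and draws individual haplogroups from a frequency vector whose
  target-haplogroup component changes linearly west to east.
* `gen_coalescent()` as above.

Passing tests on these panels shows the *algorithms* are correct under
the stated models. It does not show robustness to what real data add:
alignment error, ancient-DNA damage beyond site unreadability, recurrent
mutation at CR hotspots, heterogeneous sampling, or breed structure
beyond a single linear cline.

## Problem sizes and numerical choices

The test suite and calibration checks use deliberately modest problem
sizes chosen to keep the full suite fast while leaving sampling error well
inside the asserted bands: 1,500–2,000 coalescent replicates for moment
and total-variation checks, 100 seeded replicates for τ recovery
(asserting the [1, 8] band at τ = 4, n = 50), 100 datasets × 200
bootstraps for SSD calibration, 100–150 seeds × 199 permutations for
permutation-test validity, 50 random additive trees for NJ recovery.
Ties are broken deterministically throughout (lexicographic or
first-index); every stochastic routine takes an explicit seed, and the
pipeline derives per-stage seeds from one master seed by a fixed counter
scheme, so any stage can be reproduced in isolation.

## Known limitations

* The five-site scheme cannot call HPG D or the wild X haplotype; such
  samples require user-supplied rules or fall to `unassigned`.
* Fu's Fs via exact Stirling rows is comfortable to n ≈ 200; far larger
  samples would need an asymptotic route the package does not implement.
* The mismatch model is purely demographic (no spatial expansion variant,
  no raggedness statistic).
* The MJ implementation adds one best median per iteration (greedy); for
  the small haplotype sets typical of mtDNA surveys this reproduces the
  textbook constructions, but it is not tuned for thousands of haplotypes.
* Accession-based replication of archived sequence sets requires a
  download step outside the package; the test suite substitutes clearly
  labelled synthetic stand-ins with the same structure (e.g. a 22/8
  two-haplotype wild population).
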