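---
title: "Methods: blockwise-SFS demographic inference for two genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blockwise-SFS demographic inference for two genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the data summary

`bsfsdem` infers the divergence history of two closely related taxa from a
single diploid genome of each — the situation of the European green lizards
*Lacerta viridis* and *L. bilineata*, where one individual per species is
sequenced against a shared reference. With two diploids there are four
sampled alleles per site, and the only distinguishable site patterns,
after folding (no ancestral-allele polarization), are:

1. sites heterozygous only in the B sample (`het_b`),
2. sites heterozygous only in the V sample (`het_v`),
3. sites heterozygous in both (`shared_het`),
4. homozygous fixed differences (`fixed_diff`).

The genome's intergenic sequence is chopped into non-overlapping 200-bp
blocks, and each block is summarized by its vector of the four counts —
its *mutational configuration*. The distribution of configurations across
blocks is the blockwise site frequency spectrum (bSFS). Short blocks
justify two modelling assumptions: no recombination within a block (one
genealogy per block) and infinite sites (every mutation hits a new
position). Blocks violating the four-gamete criterion — containing both a
fixed difference and a shared heterozygous site, which no single genealogy
can produce under infinite sites — are removed before fitting.

## Demography models

All models share a two-deme topology: demes V and B merge into a single
ancestral deme at `T_split`. Time is measured backwards in units of
2·Ne_ref generations; a deme of relative size `c` coalesces each lineage
pair at rate `1/c`. The ancestor is the reference size (`c_anc = 1`), and
at most one species carries a free deviating size `c_x` (the `(x)` mark in
model labels). Gene flow is either continuous unidirectional migration
(IM: lineages in the recipient deme jump, backwards in time, to the donor
at rate `m` per lineage per time unit) or a discrete admixture pulse (ADM:
at `T_adm`, each lineage in the recipient deme independently relocates to
the donor deme with probability `f`). The pulse semantics are the
conventional backwards-in-time reading of a one-off admixture event; the
source analysis does not define the pulse formally.

The 13-model grid mirrors the published scenario set: `M1.1–M1.3`
(single size: strict divergence, IM V→B, IM B→V), `M2.*`/`M3.*` (the same
three with a free size for V or B respectively), and `M4.2/M4.3`,
`M5.2/M5.3` (admixture pulses in either direction with a free size for V
or B). The published table repeats one model id and mixes type labels, so
the grid here is reconstructed from the scenario-figure legend; the
best-supported published scenario corresponds to `M3.3` (IM, two sizes
with B reduced, gene flow B→V). Free-parameter counts are 2 (DIV, single
size), 3 (IM single size; DIV two sizes), 4 (IM two sizes) and 5 (ADM two
sizes), always counting `theta_block`.

## The mutation scaler and a units caveat

`theta_block` is defined operationally: the expected number of mutations
per block on a branch of one time unit (2·Ne_ref generations). Mutation
counts per class are Poisson with mean `theta_block × tau_class`, where
`tau_class` is the class-resolved branch length. This convention is what
fixes the package's closed-form anchors, e.g. the panmictic probability of
a mutation-free block, `∏_{k=4,3,2} C(k,2)/(C(k,2) + k·theta)`, which
equals 0.25 at `theta_block = 0.5`.

A consequence worth stating explicitly: a branch of one time unit spans
2·Ne_ref generations, so `theta_block = 2·Ne_ref·mu·L` for block length
`L`, and `scale_estimates()` inverts with `Ne_ref =
theta_block/(2·mu·L)`. Under this pairing the simulator's per-site
heterozygosity is exactly the textbook `4·Ne·mu` and its `dxy` is
`2·mu·(T_generations + 2·Ne_anc)`, both verified by simulation tests. A
`4·Ne·mu·L` reading of `theta_block` is sometimes seen with a
mutation-rate-per-half-unit convention; combining that reading with
Poisson(`theta·tau`) would misstate π and Ne by a factor of two, so the
package consistently uses the operational definition above.

## Analytic configuration probabilities

The probability of a configuration `(k1,k2,k3,k4)` is the expectation over
genealogies of a product of four Poisson masses. Rather than
differentiating a generating function, the package computes it by
augmenting the structured-coalescent state space with the running mutation
counts:

* A *lineage state* is a set partition of the four sampled alleles (each
  part is one ancestral lineage, annotated with the folded class its leaf
  subset maps to) plus a deme label per lineage. The reachable pre-split
  state space is enumerated breadth-first per model structure.
* Each lineage state accrues mutations of class `i` at rate
  `theta_block × n_i` (its number of class-`i` lineages). Counts are
  truncated at `k_max` with one lumped overflow cell per class; mutation
  events in an already-overflowed class are dropped from inflow and
  outflow alike, which is an exact lumping.
* Over the pre-split epoch of length `T_split` the augmented chain is
  propagated by **uniformization** — the exact series
  `exp(Gt) = Σ_k Pois(k; Λt)·(I + G/Λ)^k` — with the series truncated when
  the cumulative Poisson weight exceeds `1 − 1e−14`. The admixture pulse
  is an instantaneous linear map applied between two propagations.
* The ancestral epoch is absorbing and needs no time limit, so it is
  solved exactly by one ordered sweep over the (partition × counts)
  lattice: counts only grow and lineages only merge, so every state is
  visited at most once and the visit probabilities satisfy a triangular
  system.

Probability is conserved at every step, which is why the full table
(including lumped cells) sums to 1 to within the series tail (< 1e−13);
normalization is asserted at 1e−8 in the tests. Negative entries beyond
−1e−10 raise an error (none are expected; uniformization is
non-negative by construction). Probabilities are floored at 1e−300 before
logging, with a warning, so impossible configurations under extreme
parameters yield a finite penalized lnCL instead of `−Inf`.

The per-evaluation cost is dominated by sparse matrix–vector products on
the augmented space (state count × `(k_max+2)^4` cells). The generator's
sparsity pattern and parameter coefficients are cached per model
structure, so a likelihood evaluation only refills numeric values.

`k_max` defaults to 3; the source analysis never states its truncation, so
it is exposed everywhere and lnCL values are only comparable at a fixed
`k_max`. The recovery experiments in the test suite use `k_max = 2`, which
keeps the augmented space at 256 count cells; at the diversity level of
this system (≈ 0.3 expected mutations per block per time unit) counts
above 2 are rare, and the lumped cells absorb them exactly.

## The Monte-Carlo oracle

`mc_config_probability()` / `mc_config_table()` estimate the same
quantities by a genuinely independent route: Gillespie simulation of
genealogies (C++, driven by R's RNG) and Rao-Blackwellized averaging of
Poisson masses given the simulated class-resolved branch lengths. The test
suite verifies analytic/Monte-Carlo agreement cell-by-cell in all 13 model
classes (`k_max = 2`, 1e5 simulations, one a-priori parameter set per
class). Because 3,328 cells are compared, "agreement" is asserted
family-wise: the largest |z| must stay below a Bonferroni-style 4.5 bound
and at most 0.5% of cells may exceed 3 SE (0.27% would exceed it by chance
even for an exact implementation). This is a deliberate re-statement of a
naive per-cell 3-SE rule, which a correct implementation would fail with
high probability at this number of comparisons.

## Composite likelihood, linkage and AIC

Blocks are treated as independent, so `lnCL = Σ n_config · ln P(config)`.
On real data adjacent blocks are physically linked and the composite
likelihood overstates the information; the published correction divides
lnCL by 1,000 (equivalently, treats every 1,000th block as independent).
Both forms are implemented: `linkage_mode = "factor"` (default factor
1,000) and `linkage_mode = "thin"` (fit every 1,000th block, no factor).
Model comparison uses `AIC = 2k − 2·lnCL_corrected` and reports ΔAIC in
the published sign convention (best − model, so the best row is 0 and all
others negative) alongside the textbook non-negative differences.

Two consequences of the correction are worth spelling out:

* On *simulated* data the blocks are independent by construction, so the
  factor-1,000 correction would discard 99.9% of the information and make
  model recovery at 5e4 blocks essentially random (the corrected AIC gap
  between the true IM model and its DIV restriction is ~0.3). The recovery
  experiments therefore fit with factor 1, which is the statistically
  correct treatment of unlinked blocks. The 1/1000 arithmetic itself is
  asserted exactly (`lnCL_corrected = lnCL_raw/1000`).
* The equivalence of the two corrections is tested at the score level:
  the raw lnCL of an every-1,000th-block tally matches the full raw
  lnCL/1000 within Monte-Carlo error. A best-model *ranking* agreement
  test between the two modes would compare two severely underpowered
  selectors (both reduce the effective data to ~50 blocks) and would be
  uninformative noise.

## Optimization

Free parameters are maximized by Nelder–Mead on transformed coordinates:
log for `theta_block`, `T_split`, `c_x`, `m`; logit for `f` and for
`T_adm/T_split` (which enforces `0 < T_adm < T_split` by construction).
Default: 10 starts (the first moment-based — θ from the mean
heterozygous-site counts, T from the fixed-difference mean, the size ratio
from the het-count ratio — the rest log-uniform over documented bounds:
θ ∈ [1e−3, 10], T ∈ [0.01, 20], c_x ∈ [0.05, 20], m ∈ [1e−4, 10],
f ∈ [0.01, 0.99]), at most 2,000 evaluations per start. Points outside the
bounds are penalized, not clamped. ADM fits whose admixture time collapses
onto either end of `(0, T_split)` (fraction outside [0.015, 0.985]) are
flagged `boundary_degenerate`. Refits with the same seed are
bit-reproducible. The scaled-down acceptance experiments use 2 starts and
600 evaluations; at 5e4 blocks the moment start lands close enough that
this recovered all parameters within a few percent in the recorded runs.

## The synthetic world

The generator's default scenario (`default_truth_model()`) is the stated
world used across tests: IM with two sizes, gene flow B→V, `theta_block =
0.3`, `c_B = 0.4`, `T_split = 2`, `m = 0.576`. These values were chosen
once to echo the published summaries of the lizard pair — per-site
heterozygosity near 0.003/0.002 (π_B/π_V ≈ the published ratio through
`c_B` and migration), a fixed-difference level giving dxy near 0.01, an
Ne ratio near 37,890/95,400, and `m/2 ≈ 0.29` migrants per generation into
V, matching the published M = 0.288 under the `Ne·m` convention — and were
not revisited.

What the generator emulates: coalescent correlation of sites within a
block (complete linkage), independence between blocks, folded biallelic
genotypes of one diploid per species, optional missing-genotype injection,
and exact VCF/BED/FASTA round-trippability. What it does not emulate:
physical linkage *between* nearby blocks (the very thing the 1/1000
correction addresses on real data), recombination within blocks,
multi-allelic sites, sequencing/genotyping error, reference bias, and
callable-site heterogeneity. A green recovery test therefore establishes
correctness of the estimator under its own assumptions, not robustness to
the artefacts of real variant calls.

## Summary statistics and scaling

`diversity_stats()` computes π per species (heterozygous sites over
callable sites), dxy (mean fraction of the four between-species allele
pairs differing, over callable sites) and FST. The published FST of 0.688
is not reproducible from the published π and dxy under either common
estimator (Hudson's `1 − πw/dxy` gives ≈ 0.79), so the estimator is an
explicit, labelled choice: Hudson by default, a `(dxy − πw)/(dxy + πw)`
ratio form as an option — never silently matched to the printed value.
Callable sites default to the summed BED width, an approximation that
ignores within-region uncallable bases.

`scale_estimates()` converts dimensionless MLEs using a mutation rate and
generation time. Both published calibrations are defaults (`mu = 1.77e−8`
from mitochondrial divergence; `mu = 1e−9` from four-fold degenerate
sites; `g = 3.5` years), and the same dimensionless fit scales to split
times in the ratio 17.7 between them — the mechanism behind the published
1.15 vs 20.37 Mya pair. Migration is reported under both `Ne·m` and
`4·Ne·m` conventions with labels, since a bare "migrants per generation"
does not identify the scaler. `mutation_rate_from_divergence()` documents
its convention (`mu = d / T_total`, total separation = 2 × split time);
the published mitochondrial rate is not reconstructible from the published
distance and split-window alone, so the function exposes the arithmetic
instead of guessing it.

`generation_length()` is the fecundity-weighted mean age of mothers,
`G = Σ a·n_a·m_a / Σ n_a·m_a`.

## Degenerate inputs and edge behaviour

`T_split = 0` is accepted and handled by skipping the pre-split epoch
(the panmictic limit used by the closed-form tests). `theta_block = 0`
yields a point mass on the zero configuration. `m = 0` reproduces the DIV
model cell-for-cell. Blocks whose excluded-site count (missing genotypes,
more than two alleles among the four sampled) exceeds 10% of the block
length are dropped and reported — the source analysis is silent on
missing data, so the policy is explicit and configurable. Sites absent
from the variant-only VCF are treated as invariant; callable-site masks
are out of scope.

## Known limitations

One diploid per taxon and two demes only; unfolded spectra would need an
outgroup; no recombination within blocks; no confidence intervals or
likelihood-ratio tests (AIC only, as in the source analysis); the
uniformization budget caps `Λ·T` at 2e5, which bounds how extreme
(size, time, rate) combinations may get before an explicit error; fitting
cost grows as `(k_max + 2)^4`, making `k_max` above ~4 expensive.
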