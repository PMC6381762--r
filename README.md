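# bsfsdem

Demographic inference for a pair of closely related taxa from **one diploid
genome of each**, via the blockwise site frequency spectrum (bSFS). The
package was built around the analysis design used for the European green
lizards *Lacerta viridis* and *L. bilineata*: intergenic sequence is chopped
into 200-bp blocks, each block is summarized by its folded mutational
configuration, and a grid of 13 divergence / isolation-with-migration /
admixture scenarios is compared by linkage-corrected composite-likelihood
AIC.

## What it computes

With two diploids (four sampled alleles) the folded joint SFS of a block
reduces to four counts:

```
(het_b, het_v, shared_het, fixed_diff)
```

— sites heterozygous only in sample B, only in sample V, in both, and
homozygous fixed differences. For a demography model Θ (split time
`T_split`, relative deme sizes, continuous migration `m` or an admixture
pulse `(f, T_adm)`; time in units of 2·Ne_ref generations) the probability
of a configuration is

```
P(k | Θ, θ) = E_Θ [ ∏_i Pois(k_i ; θ · τ_i) ]
```

where `τ_i` is the genealogy's branch length in folded class `i` and `θ`
(`theta_block`) is the expected number of mutations per block per unit
branch length. The package computes `P` **analytically** (a
count-augmented Markov chain: uniformization over the pre-split epoch, an
exact absorbing sweep in the ancestral deme) and **by Monte Carlo** (a C++
structured-coalescent simulator with Rao-Blackwellized averaging); the two
routes are cross-checked in the tests. Model fit is by
`lnCL = Σ n_k · ln P(k)` with a 1/1000 linkage correction (or 1-in-1000
block thinning), compared across models with `AIC = 2k − 2·lnCL` and ΔAIC
in the published sign convention (best = 0, others negative).

## Worked example

Simulate a dataset under the scenario class best supported for the lizard
pair (IM, two sizes with B reduced, gene flow B→V), tabulate it, and
compare models:

```r
library(bsfsdem)

truth <- default_truth_model()        # IM B->V, c_B = 0.4, T = 2, m = 0.576
sp    <- simulate_block_spectra(sim_config(truth, theta_block = 0.3,
                                           n_blocks = 5e4, seed = 1))
flt   <- four_gamete_filter(sp)
tally <- bsfs_tally(flt$kept, flt$n_removed)
tally
#> <bsfs_tally: 50000 blocks (0 filtered), 231 distinct configurations, 162 recurrent>
#>   het_b het_v shared_het fixed_diff n_blocks
#> 1     0     0          0          0    12606
#> 2     0     1          0          0     6908
#> ...

fit <- fit_model(tally, model_grid()[["M3.3"]], k_max = 2,
                 optimizer_config(n_starts = 3, max_eval = 800, seed = 1))
round(fit$mle, 4)
#> theta_block     T_split         c_x           m
#>      0.2974      2.0623      0.4057      0.5689
```

The MLEs recover the generating values (0.3, 2, 0.4, 0.576) to within a
few percent. Scaling to demographic units under the four-fold-degenerate
calibration (`mu = 1e-9` per site per generation, `g = 3.5` years):

```r
scale_estimates(fit, calibration(mu = 1e-9, g = 3.5, block_len = 200))
#> <scaled_estimates: mu = 1e-09, g = 3.5 y>
#>   Ne_ref = 743530  Ne_V = 743530  Ne_B = 301638  Ne_anc = 743530
#>   T_split = 3066823 generations = 1.07e+07 years
#>   gene flow B->V: Nm = 0.2844 (4Nm = 1.138) migrants/generation
```

`Nm` is the estimated number of migrants per generation into V (the
generating value is `m/2 = 0.288`); both `Ne·m` and `4·Ne·m` conventions
are reported because a bare "migrants per generation" does not identify
the scaler. The same dimensionless fit under the mitochondrial calibration
`mu = 1.77e-8` gives split-time years smaller by exactly 17.7 — the
mechanism behind a 1.15 vs 20.37 Mya pair of headline dates.

Real data enter through a VCF (two samples, GT) plus a BED of intergenic
regions:

```r
blocks  <- partition_blocks("intergenic.bed", block_len = 200)
spectra <- tabulate_blocks(blocks, "calls.vcf")       # 4-type counts per block
flt     <- four_gamete_filter(spectra)
tally   <- bsfs_tally(flt$kept, flt$n_removed)
cmp     <- compare_models(tally, model_grid(), k_max = 3)
cmp$table     # model_id, type label, lnCL_raw, lnCL/1000, AIC, dAIC
```

There is also a command-line front end
(`inst/exec/bsfsdem <simulate|tabulate|fit|summarize>`) that writes
TSV/JSON reports plus a reproducibility manifest; exit codes are 0
(success), 2 (input/validation), 3 (numerical failure).

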