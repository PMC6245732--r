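# alleleKinetics

Stochastic hidden-state models of mono- and bi-allelic gene activation in
proliferating cell populations, and the estimators needed to confront them
with dual-reporter single-cell data.

## The scientific problem

When a gene's two chromosomal copies carry distinguishable fluorescent
reporters (YFP on one allele, mCherry on the other), every cell falls into
one of four observable classes — non-expressing, mono-allelic for either
reporter, or bi-allelic. How those class fractions evolve, and how allelic
states distribute within clonal lineages, discriminates between competing
activation mechanisms:

- **cis-only**: each allele switches on independently by a stochastic
  first-order *cis*-epigenetic event at rate *k*<sub>C</sub> (per hour);
  class fractions follow the closed form
  *f*<sub>none</sub> = e<sup>−2k<sub>C</sub>t</sup>,
  *f*<sub>mono</sub> = e<sup>−k<sub>C</sub>t</sup>(1 − e<sup>−k<sub>C</sub>t</sup>)
  per allele, *f*<sub>bi</sub> = (1 − e<sup>−k<sub>C</sub>t</sup>)².
- **sequential trans–cis**: a cell-wide *trans* step (rate *k*<sub>T</sub>)
  must precede any *cis* activation.
- **parallel trans–cis**: *trans* and per-allele *cis* steps run
  independently and expression requires both, so alleles can be
  *cis*-activated silently.

Each model is a small continuous-time Markov chain solved exactly by
matrix exponentials. Around the models, the package provides:

- constrained four-component bivariate Gaussian mixture quantification of
  class fractions from two-channel intensity tables, with anchored
  non-expressing shape and propagated uncertainties;
- detection-delay estimation and delay-corrected least-squares model
  fitting scored by reduced χ², with F-test model comparison;
- Monte-Carlo clonal lineage simulation with path-aware clone
  classification (single / mixed mono-allelic, bi-allelic only) and the
  single-category (O−E)²/E clone-level test;
- perturbation phase-space analysis (*F*<sub>m</sub> vs *F*<sub>b</sub>
  endpoints under graded cis or trans perturbations, with exact
  direct-vs-mono-mediated reversion flux decomposition);
- a seeded synthetic timelapse/snapshot generator emulating the
  statistical structure of the imaging data (stochastic activation,
  20 h divisions, reporter maturation lag, class-conditional noise).

It is intended for quantitative biologists analysing dual-reporter
activation kinetics, and as a reference implementation of the
model-selection analysis itself.

## Worked example

```r
library(alleleKinetics)

m <- AllelicModel("parallel", kC = 0.0042, kT = 0.012)
populationFractions(m, c(0, 50, 100))
#>   time_h    f_none   f_monoY   f_monoR       f_bi
#> 1      0 1.0000000 0.0000000 0.0000000 0.00000000
#> 2     50 0.8452635 0.0692743 0.0692743 0.01618788
#> 3    100 0.6028760 0.1574663 0.1574663 0.08219136
```

At these rates roughly 40% of cells express within 100 h, twice as many
mono- as bi-allelic — the slow-switch regime in which allelic
intermediates accumulate.

Clonal predictions depend on the starting population. For progenitors
*sorted* as non-expressing after a 100 h pre-culture (which, under the
parallel model, includes silently cis-activated cells):

```r
init <- sortedNoneInit("parallel", kC = 0.0042, kT = 0.012)
mSorted <- AllelicModel("parallel", kC = 0.0042, kT = 0.012, init = init)
cloneClassDistribution(mSorted, cloneSimConfig(nClones = 10000, seed = 1))
#> CloneClassDistribution: parallel model, 10000 clones (seed 1)
#>   counts: single_mono_allelic=3054 mixed_mono_allelic=6307 bi_allelic_only=638 non_expressing=1
#>   expressing-clone fractions: single_mono_allelic=0.305 mixed_mono_allelic=0.631 bi_allelic_only=0.064
```

The same rates under the sequential model give zero bi-allelic-only
clones (a sequential path to bi-allelic must pass through a mono state)
and a lower single-mono fraction — the clone-level signature separating
the two trans–cis schemes. An observed clone count is tested against a
predicted fraction with the single-category statistic:

```r
cloneClassChi2(7, 9, 0.201)   # 7 of 9 clones vs a predicted 20.1%
#> $statistic 14.9 ; df 1 ; p-value 0.00011
```

The full staged pipeline (quantify → fit & compare → clone analysis →
phase sweep) runs from one config:

```r
mv <- generateMovie(movieSpec(seed = 1))      # synthetic timelapse cohort
write.table(mv$tracks, "tracks.tsv", sep = "\t", row.names = FALSE)
runAll(list(input = list(tracks = "tracks.tsv"), outdir = "out"))
```

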