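# radburst

Did a clade diversify in an early burst? Adaptive-radiation theory predicts
that both speciation and morphological change concentrate near the base of a
radiation and slow as ecological niches fill. Testing that prediction from
extant species alone takes a full stack of comparative machinery, and
`radburst` provides it as one coherent, tested R package for
phylogeneticists working with time-calibrated trees and continuous traits:

- **Tree simulation** (`sim_bd_tree()`, `sim_conditioned_tree()`): forward
  Yule and birth–death simulation, with rejection conditioning on crown age
  and exact extant richness, plus random / diversified / semidiversified
  taxon subsampling (`sample_tips()`) and lineage-through-time tables
  (`ltt()`).
- **Trait simulation** (`sim_trait()`): exact Brownian-motion and
  single-optimum Ornstein–Uhlenbeck transitions, with time windows in which
  the rate of trait evolution is multiplied — the staged-radiation design
  (`stage_windows()`, `run_stage_experiment()`).
- **Disparity through time** (`dtt()`, `dtt_null()`, `mdi()`): average
  relative subclade disparity at every divergence time, simulated null
  envelopes, and the morphological disparity index
  $\mathrm{MDI} = \int_0^{0.9} (\mathrm{DTT}_\mathrm{obs} -
  \mathrm{DTT}_\mathrm{null\ median})\,dt$, whose negative values are the
  early-burst signature.
- **Model comparison** (`fit_trait_model()`, `compare_over_trees()`):
  maximum-likelihood BM and OU fits (dense and pruning likelihood routes)
  with AICc comparison across posterior tree samples.
- **Rate-shift detection** (`fit_rate_shifts()`): stepwise-AICc search for
  diversification-rate shifts on diversity trees whose tips carry extant
  richness counts, with per-regime net diversification $r = \lambda - \mu$
  and turnover $\varepsilon = \mu / \lambda$.
- **Interval rates** (`km_rate()`, `km_rate_envelope()`): per-geological-
  stage Kendall–Moran estimates (branching events / lineage time) against
  quantile envelopes from conditioned simulated phylogenies.
- **Synthetic data** (`make_fixture()`): a deterministic radiation-shaped
  data set (49-tip, 13.4-myr chronogram; 132 species of richness with 122
  in the focal clade; five traits) so the whole pipeline runs and is tested
  without any external downloads.

Trees are `ape::phylo` objects; every result is a tibble or a small S3
object with `tidy()` / `glance()` methods and `autoplot()` /
`plot_*()` displays, so everything chains with the pipe.

## Worked example

```r
library(radburst)

fx <- make_fixture(seed = 1)

# Disparity through time for the constrained body-shape axis
dn <- dtt_null(fx$tree, fx$traits, trait = "cv2", n_sims = 100, seed = 1)
glance(dn)
#>       mdi model n_sims t_max crown_age
#> 1 -0.0105 OU       100   0.9      13.4

# Which trait model fits?
glance(fit_trait_model(fx$tree, fx$traits, model = "OU", trait = "cv2"))
#>   model sigma2 alpha    z0 logLik     k     n  AICc convergence
#> 1 OU      21.4 0.244 0.572  -150.     3    49  307.           0

# Diversification-rate shifts on the diversity tree
fit_rate_shifts(fx$tree, fx$richness)
#> Diversification-rate shift model: 1 shift(s), logLik = -110.562, AICc = 232.374
#>   regime shift_node     r epsilon loglik boundary
#> 1      1         NA 0.122       0  -10.5 FALSE
#> 2      2         53 0.565       0 -100.  FALSE

# Per-stage Kendall-Moran rates
km_rate(fx$tree)
#>   stage       old_bound young_bound n_events lineage_time   rate
#> 1 Tortonian        11.6         7.2        4         23.1 0.173
#> 2 Messinian         7.2         5.3        1         14.6 0.0687
#> 3 Zanclean          5.3         3.6        5         16.0 0.312
#> 4 Piacenzian        3.6         2.6        7         16.6 0.422
#> 5 Pleistocene       2.6         0         29         80.6 0.360
```

Reading the output: the cv2-like trait was generated under a constrained
(OU) process, and its MDI against the *fitted* (OU) null is ~0 — the
observed disparity trajectory is what the constrained model predicts. The
shift scan retains exactly one rate shift, at the crown of the species-rich
focal clade (node 53), with net diversification rising from 0.12 to 0.57
per myr. The elevated Pleistocene Kendall–Moran rate reflects the young
nested subclade the fixture plants. `run_stage_experiment()` reproduces the
classic simulation result that early 10-fold rate elevation drives MDI
negative, while trait-space constraints push it back up and can mask the
early burst entirely.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's full chain on the synthetic fixture —
fixture generation, DTT with fitted null envelopes and MDI for all five
traits, BM/OU model comparison, the stepwise rate-shift search, and
per-stage Kendall–Moran rates — logging each stage's headline numbers and
writing the JSON results file.

## Package layout

- `R/treesim.R`, `R/traitsim.R` — simulators.
- `R/disparity.R` — DTT, null envelopes, MDI.
- `R/modelfit.R` — BM/OU likelihoods and AICc model comparison.
- `R/shiftscan.R` — diversification-rate shift search.
- `R/kmrates.R` — interval rate estimates and envelopes.
- `R/synthdata.R` — the synthetic fixture generator.
- `R/io.R`, `R/pipeline.R`, `R/plots.R` — Newick/NEXUS and TSV I/O, the
  config-driven pipeline, ggplot2 displays.
- `vignettes/radburst-methods.Rmd` — the models, numerical choices and
  design decisions in detail.
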