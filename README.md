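# oppsel

Sex-specific selection analysis for competitive mating assays.

`oppsel` is for experiments of the following shape, common in insect
evolutionary ecology (the motivating system is the red flour beetle
*Tribolium castaneum* under diet manipulation): focal individuals of both
sexes are raised under a stressor (here, yeast-deprived wheat or whole-wheat
flour), then assayed in mating groups of one focal, one genetically marked
competitor of the same sex, and two mating partners. Offspring are assigned
to the focal or the competitor with a dominant visible marker. Two assay
arms are run: one in which only the focal is stressed (measuring selection
*against* stressed individuals under competition) and one in which the whole
group is stressed (measuring the opportunity for selection in a stressed
population).

## What it computes

Writing `W` for an individual's reproductive success (number of offspring
sired by a male, or produced by a female):

- **Selection coefficient against the stressed class**

  `s = 1 − W̄_stressed / W̄_control`,

  with a percentile bootstrap CI (groups resampled independently at their
  original sizes) and a stratified permutation test for the male−female
  difference `Δs = s_m − s_f` (sex labels shuffled within treatment strata,
  two-sided `p = (1 + #{|Δ_perm| ≥ |Δ_obs|}) / (n_perm + 1)`).

- **Opportunity for selection** (Crow's index)

  `I = var(W / W̄)` — the sample variance of mean-relativized fitness, an
  upper bound on the strength of selection — with a bootstrap CI per design
  cell.

- **Multiplicative decomposition of male fitness.** Each male's total sired
  offspring satisfies `T = MS × Fec × PS` exactly, where `MS` is his genetic
  mating success (partners with ≥ 1 focal-sired offspring), `Fec` the pooled
  fecundity of those partners per mate, and `PS` his pooled paternity share.
  After relativizing each factor, `I_total` is split as

  `I_total = I_MS + I_Fec + I_PS + 2(cov_MS,Fec + cov_MS,PS + cov_Fec,PS) + remainder`,

  with the higher-order remainder reported explicitly (the identity holds to
  machine precision by construction).

- **Conventional inference**: Gaussian (body mass) and quasi-Poisson
  (offspring, mating success) treatment GLMs with pairwise link-scale
  contrasts, Pearson-dispersion SEs, omnibus F, Benjamini–Hochberg adjusted
  p-values; Yates-corrected chi-squared tests on female mortality tables.

- **A synthetic-data generator** emulating the full design (negative
  binomial fecundity, Bernoulli mating failure, beta-binomial paternity
  under sperm competition, mortality-truncated laying), so the entire
  pipeline runs and is tested without any external data.

## Worked example

```r
library(oppsel)

## Arm 1: only the focal is stressed -> selection against stressed focals
d <- simulate_experiment(sim_params(n_focal = 50), "focal_only", seed = 42)
estimate_selection(d, "male", "wheat", "none", n_boot = 2000, seed = 7)
#> Selection estimate [focal_only / male / wheat / none]
#>   s = 0.8905  (boot mean 0.8901, 95% CI 0.8253 to 0.9430, 2000 replicates)
#>   n_control = 50, n_stressed = 50

sd <- sex_difference_in_s(d, "wheat", "none", n_boot = 2000, n_perm = 2000, seed = 7)
#> sex difference: -0.055 (95% CI -0.126 to 0.002), permutation p = 0.1524

## Arm 2: the whole group is stressed -> opportunity for selection
d2 <- simulate_experiment(sim_params(n_focal = 50), "whole_group", seed = 43)
estimate_opportunity(d2, "female", "wheat", "none", n_boot = 2000, seed = 8)
#> Opportunity for selection [whole_group / female / wheat / none]
#>   I = 1.0535 (boot mean 1.0719, 95% CI 0.6732 to 1.6148)
#>   n = 50

decompose_opportunity(cell_subset(d2, "male", "wheat", "none"),
                      n_boot = 2000, seed = 9)
#> Male opportunity-for-selection decomposition (n = 50 males)
#>        term estimate boot_mean   ci_low ci_high
#>     I_total   0.8422    0.8385  0.54254  1.2283
#>        I_MS   0.3293    0.3339  0.18714  0.5268
#>       I_Fec   0.4899    0.4931  0.30745  0.7422
#>        I_PS   0.2570    0.2632  0.12094  0.4510
#>  cov_MS_Fec   0.2693    0.2748  0.12645  0.4733
#>   cov_MS_PS   0.1956    0.2019  0.06682  0.3808
#>  cov_Fec_PS   0.1858    0.1918  0.05460  0.3663
#>   remainder  -1.5354   -1.5887 -2.94148 -0.5233
```

Reading the output: stressed males sire ~89% fewer offspring than control
males when competing against an unstressed rival (`s ≈ 0.89`), the sexes do
not differ detectably (`p ≈ 0.15`), and in a fully stressed population
female `I` is strongly inflated relative to the generator's control regime
(`I ≈ 0.2`). In the male decomposition all three components and their
(positive) covariances contribute; because the components are strongly
correlated under stress, the first-order terms overshoot `I_total` and the
higher-order remainder is large and negative — reported, not hidden.

The same pipeline runs from the command line against a CSV
(`focal_id, sex, flour, yeast, assay, genotype, body_mass_mg, survived,
p1_total, p1_sired, p2_total, p2_sired, laying_week`):

```sh
Rscript inst/cli/oppsel simulate --seed 9 --out data.csv
Rscript inst/cli/oppsel validate data.csv
Rscript inst/cli/oppsel analyze --input data.csv --out results/ --seed 1
# or: analyze --simulate  to run on generated data directly
```

`analyze` writes `selection_coefficients.csv`, `opportunity.csv`,
`decomposition.csv`, `glm_contrasts.csv`, `mortality.csv` and a
`run_manifest.json`; runs are byte-identical given the same config and seed.

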