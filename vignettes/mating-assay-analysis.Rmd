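---
title: "Sex-specific selection and the opportunity for selection in competitive mating assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific selection and the opportunity for selection in competitive mating assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oppsel)
```

## The experimental design this package models

A focal individual (male or female) is placed in a mating group with one
same-sex competitor carrying a dominant visible marker and two
opposite-sex mating partners. After a fixed mating period, females lay for a
fixed window and all adult offspring are scored for the marker, assigning
each offspring to the focal or the competitor. Crossed with this are a diet
manipulation (two flour types; yeast at 5% control, 1% only in whole-wheat,
or absent) and two assay arms: *focal-only* (only the focal is stressed;
competitors and partners are raised on control diet) and *whole-group*
(everyone in the group is stressed, mimicking a population under dietary
stress).

Reproductive success `W` is the number of offspring sired by a focal male
(summed over his two partners) or produced by a focal female (her single
clutch). One row per focal, with per-partner counts kept separate for males,
is the tidy unit of the data model.

## Statistics

### Selection coefficient

For a stressed treatment against its control within one (assay, sex, flour)
cell,

$$ s = 1 - \frac{\bar W_{\text{stressed}}}{\bar W_{\text{control}}}, $$

a standardized measure of selection against the stressed class: `s = 1` is
complete selection, `s = 0` none, `s < 0` a stressed advantage. It is
invariant to common rescaling of both groups, which is why the
per-female-scaled male values offered for display (`T/2`) never enter the
estimator. Uncertainty comes from a nonparametric bootstrap that resamples
the control and stressed groups independently at their original sizes — the
resampling analogue of repeating the experiment with its group sizes fixed
by design.

The sex difference `Δs = s_m − s_f` gets its CI from a joint bootstrap over
all four sex-by-treatment groups, and its p-value from a permutation test
that shuffles sex labels among focal individuals *within each treatment
stratum*. Stratification matters: shuffling across strata would confound the
sex difference with the treatment effect itself. Whether the original
analyses of such designs stratify is typically unstated; stratification is
the defensible default and is what the package does.

### Opportunity for selection

$$ I = \operatorname{var}\!\left(\frac{W}{\bar W}\right), $$

the variance of mean-relativized fitness (Crow's index), an upper bound on
the strength of directional selection in the cell. Two conventions are
pinned down because they silently differ between implementations:

- **Variance denominator**: the sample variance (n − 1). Reports of such
  assays rarely state the choice; n − 1 matches the default of the analysis
  stacks this field uses.
- **Relativization** is by the cell mean, so `mean(W/W̄) = 1` exactly and
  `I = var(W)/mean(W)²` algebraically (asserted in tests).

### Male variance decomposition

Male reproductive success is modeled multiplicatively:
`T = MS × Fec × PS` with `MS` the genetic mating success (number of partner
females with at least one focal-sired offspring), `Fec` partner fecundity
and `PS` paternity share. The prose definitions of `Fec` ("average offspring
of partner females") and `PS` ("proportion sired per partner") are ambiguous
between *pooled ratios* and *means of per-partner ratios*. The package's
default is the pooled form —

`Fec = (total offspring of fertilized partners)/MS`,
`PS = (total focal-sired)/(total offspring of fertilized partners)`

— because it makes `T = MS·Fec·PS` an exact identity per male, which in turn
makes the variance decomposition close exactly. The per-partner-mean variant
is available (`pooled = FALSE`) and then carries a per-male identity
residual that is reported, never silently dropped. Males with `MS = 0` get
`Fec = PS = 0`: the identity still holds and zero-fitness males stay in the
variance they plainly contribute to; an `include_ms0 = FALSE` flag removes
them for sensitivity analysis.

After relativizing each component by its cell mean,

$$ I_T = I_{MS} + I_{Fec} + I_{PS}
   + 2(\mathrm{cov}_{MS,Fec} + \mathrm{cov}_{MS,PS} + \mathrm{cov}_{Fec,PS})
   + \text{remainder}, $$

where the remainder collects all higher-order product terms and is defined
by difference, so the identity holds to machine precision on every call
(asserted). First-order treatments in this literature drop the remainder;
with the strong component correlations that stress induces it can be large
(the README example shows −1.5 against `I_T = 0.84`), which is exactly why
it is reported. Covariances are emitted both raw and doubled, since plots of
such decompositions are often ambiguous about which is shown.

### Resampling conventions

- Percentile bootstrap CIs using R's type-7 (linear interpolation)
  empirical quantiles; 10,000 replicates by default.
- Permutation p-values use add-one smoothing,
  `p = (1 + #extreme)/(n + 1)`: never zero, super-uniform at worst under
  the null; 10,000 permutations by default.
- A bootstrap replicate whose resampled control group has zero mean fitness
  would make `s` undefined; such replicates signal a typed degeneracy
  condition, are redrawn and counted, and a warning is attached if more than
  1% of replicates were degenerate. Redrawing (rather than propagating NA)
  keeps the replicate count and the CI definition intact; the count is
  reported so heavy degeneracy is visible.
- A single master seed spawns one deterministic substream per analysis cell
  (`spawn_seed`), so adding or removing a cell never perturbs any other
  cell's draws, and full pipeline runs are byte-identical given config +
  seed.

### Conventional inference

Treatment GLMs use `stats::glm` IRLS: Gaussian for body mass, quasi-Poisson
for counts (offspring, mating success), one fixed effect, all pairwise
link-scale contrasts with SEs scaled by the Pearson dispersion estimate, an
omnibus F, and Benjamini–Hochberg adjustment applied within each
(flour × sex × response) contrast family — the grouping in which such
tables conventionally present their adjusted p-values. Note BH adjustment is
*not* idempotent (re-adjusting adjusted p-values changes them); tests assert
the valid invariants (rank-monotonicity, `p_adj ≥ p_raw`) against
`stats::p.adjust` as oracle. A sex-by-treatment interaction model on
within-sex mean-relativized responses tests whether proportional effects
differ between the sexes. Mortality uses the Pearson chi-squared test with
the Yates correction on 2×2 tables; degrees of freedom are the conventional
(r−1)(c−1), with the sample-size-based n−1 value (which some reports print)
returned alongside for comparability.

## The synthetic-data generator

`simulate_experiment()` generates the full design so that every stage of
the pipeline is exercised and tested offline. Its generative model:

- **Fecundity**: each female's clutch is negative binomial NB(μ, θ). The
  analysis-side quasi-Poisson family has no generative form; NB is its
  standard generative stand-in, with `θ` controlling the overdispersion the
  quasi-Poisson dispersion picks up. On the relativized scale a NB clutch
  has `E[I] = 1/μ + 1/θ` exactly, which the recovery tests use as ground
  truth.
- **Mating**: each male inseminates each partner female independently with
  probability `p_mate` of his treatment; a female with no successful male
  has a zero clutch.
- **Paternity**: when both males inseminate a female, the focal's sired
  count is beta-binomial with mean share `w_f/(w_f + w_c)` and concentration
  `κ`; `κ → ∞` collapses to the deterministic share, `w_c = 0` to full
  paternity. `MS`, `Fec`, `PS` are then *emergent*, not drawn directly.
- **Mortality**: a focal female dies before the end of laying with her
  cell's probability `q`; death truncates her clutch by a uniform fraction
  of the laying window (expected factor `1 − q/2`), since only period-level
  mortality is ever reported for such assays.
- **Assay rule**: in `focal_only`, competitors and partners use the control
  cell's parameters; in `whole_group`, everyone uses the focal's cell.

### Default calibration (the stated world)

Defaults are calibrated once to the published regime of the motivating
experiment and not revisited:

| parameter | default | rationale |
|---|---|---|
| `mu` control | 50 offspring | realistic two-week adult output per female; with θ gives control `I ≈ 0.2` |
| `mu` wheat, no yeast | 3.6 | the reported log-scale count contrast of −2.64 (`50·e^{−2.64}`), implying `s ≈ 0.93` |
| `mu` whole-wheat 1% / none | 43.5 / 40 | log contrasts −0.14 / −0.22 (weak, non-significant effects) |
| `theta` | 5.5 | free overdispersion knob; chosen so control `I = 1/50 + 1/5.5 ≈ 0.2`, matching control-cell estimates |
| `p_mate` | 0.95 control; ×e^(mating-success contrast) under stress (0.67 wheat-none, 0.86, 0.74 whole-wheat) | mirrors the reported mating-success contrasts (−0.35 etc.) |
| `w_competitor` | 0.35 | the marker strain sires ~65% fewer offspring than wildtype |
| `w_mult` wheat-none | 0.028 | solves for the overall 14-fold male fitness deficit after the mating-success share |
| body mass | ♂ 1.85 mg, ♀ 2.10 mg, SD 0.12; wheat-none ×0.957 / ×0.910 | ~2 mg adults; the reported 4.08% / 8.98% reductions |
| `mortality` | 4% / 19% wheat, 0 / 0.5% / 1.1% whole-wheat | reported female laying-period mortality |
| `n_focal` | 50 | the order of the real cell sizes (≈ 40–55) |

This is *calibration, not ground truth*: the generator reproduces the
published regime's first moments and dispersion, not the real data. What a
green recovery test establishes is that the estimators are unbiased and the
intervals calibrated *under this generative model*; it cannot establish
that the model captures real clutch-size dynamics (true beetle
overdispersion is unpublished, `θ` is a free knob), density effects during
rearing, development-time differences, or reproductive senescence beyond
the two-week window — all deliberately unmodeled.

## Degenerate inputs and edge policy

- All-zero fitness cells: relativization and `s` raise typed degeneracy
  errors rather than returning NaN.
- `n_boot = 0` returns plug-in points with empty CI fields.
- Dead females stay in fitness analyses by default (`include_dead = TRUE`):
  mortality is part of realized fitness; a switch excludes them since the
  original handling of such deaths is unstated.
- Missing body mass is allowed and dropped pairwise in mass analyses.
- Totals-only tables (per-partner columns empty for males) disable the
  decomposition stage with a capability error / pipeline warning; everything
  else runs.
- Both plug-in and bootstrap-mean point values are reported: published
  tables of this kind appear to print bootstrap means (their printed sex
  difference does not equal the difference of the printed per-sex values),
  so both are kept side by side.

## Known limitations

- The permutation test assumes exchangeability of individuals within
  treatment strata; block structure (e.g. assay week) is not modeled.
- Percentile intervals undercover slightly at small n (measured ~92% for
  n = 40 overdispersed counts, 94.9% for a normal mean at n = 50); BCa was
  considered and left out to keep the interval definition pinned and simple.
- The decomposition treats the two-partner design as fixed; designs with
  variable partner numbers would need `MS` renormalization.
- Genotype scoring is assumed error-free (the marker is fully penetrant and
  dominant); no misassignment model.
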