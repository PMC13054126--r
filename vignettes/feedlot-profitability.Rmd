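---
title: "Profitability phenotypes and multi-trait animal models for feedlot cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profitability phenotypes and multi-trait animal models for feedlot cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`feedlotgen` implements a complete quantitative-genetics pipeline for
economic feedlot traits in beef cattle (the motivating populations are
Nelore, *Bos indicus*):

1. **Phenotype engineering.** From daily feedlot sensor logs (body weight,
   dry-matter intake) the package derives accumulated feedlot profitability
   (AFP, the animal's total profit over the evaluation window) and profit
   per arroba of carcass gain (PFT), plus the auxiliary traits ADG,
   metabolic weight, residual feed intake (RFI), residual gain (RG), frame
   score and age-adjusted weight at 450 days (W450).
2. **Data editing.** Contemporary-group (CG) formation
   (farm | lot | sex | year | season, plus the feed-efficiency test for
   profit/efficiency traits) and the customary edits: unknown parents, CGs
   with fewer than 4 members, records beyond ±3.5 CG standard deviations.
   Genotype QC: call rate, MAF, monomorphism, map rules, exact
   Hardy-Weinberg test, parent-offspring opposing homozygotes.
3. **Relationship matrices.** Pedigree A (tabular method, with inbreeding),
   VanRaden genomic G, and the single-step inverse
   H⁻¹ = A⁻¹ + [0, 0; 0, G_b⁻¹ − A₂₂⁻¹] on the genotyped block.
4. **Inference.** A multi-trait Bayesian animal model
   y = Xβ + Za + e with Var(a) = G₀ ⊗ A (or H) and Var(e) = R₀ ⊗ I,
   fitted by Gibbs sampling, mixing linear and binary (threshold) traits.
5. **Summaries.** Heritabilities and genetic/residual correlations as
   per-draw transforms, shortest-HPD intervals, the Geweke diagnostic and
   the usual magnitude classifications (Bourdon bands for h², Hill bands
   for correlations).

A synthetic-data generator produces pedigrees, gene-dropped genotypes,
breeding values, phenotypes and feedlot logs with exactly the statistical
structure the model assumes, so the whole chain is testable without
proprietary herd data.

## The profit equations

For an animal with live weight $w_d$ and intake $\mathrm{DMI}_d$ on day
$d$, sex-specific carcass dressing $c$ (% of shrunk body weight) and
shrink factor $s$ (default 0.96):

$$\mathrm{acc}_d = \frac{s\, w_d \cdot c/100}{15}, \qquad
  \mathrm{gain}_d = \mathrm{acc}_d - \mathrm{acc}_{d-1},$$

$$\mathrm{revenue}_d = p_{@}\,\mathrm{gain}_d, \qquad
  \mathrm{cost}_d = p_{\mathrm{diet}}\,\mathrm{DMI}_d + o,$$

$$\mathrm{AFP} = \sum_d (\mathrm{revenue}_d - \mathrm{cost}_d), \qquad
  \mathrm{PFT} = \frac{\mathrm{AFP}}{\mathrm{acc}_T - \mathrm{acc}_1}.$$

Here $p_@$ is the arroba price (one arroba = 15 kg of carcass),
$p_\mathrm{diet}$ the diet price per kg of dry matter and $o$ the daily
non-feed overhead; all three are standardized across animals, as
commercial evaluations do. Design choices worth stating:

* **Daily gain as first differences.** The period equations only define
  the total gain; using first differences of the accumulated-arroba series
  makes the daily and period forms consistent (the daily gains telescope
  exactly to the total). Day 1 has no gain by convention.
* **Per-arroba PFT.** The published summary magnitude of PFT matches the
  per-arroba ratio (total profit ≈ 152 $ over ≈ 3.9 arrobas ≈ 39 $/@),
  not a literal per-kg reading, so PFT is reported in \$/arroba with a
  per-kg conversion (÷15) available.
* **No growth-curve smoothing by default.** Observed weights are used as
  recorded; commercial systems fit proprietary growth curves that are not
  reproducible, and a linear re-fit is available to the user who wants
  smoothing (`fit_adg()` + prediction).
* **Negative daily profit is retained** — losses are real phenotypes
  (published minima are negative).
* The evaluation window defaults to the full log (80 days in the
  emulation defaults); it is exposed as a `window` argument because
  efficiency-test protocols use 70-day valid phases.

## Derived traits

* ADG is the OLS slope of weight on day-on-test; the intercept estimates
  initial weight.
* Metabolic weight is read as **mid-test** weight to the 0.75 power,
  $(\alpha + \beta\,\mathrm{DET}/2)^{0.75}$: the printed formulas of this
  trait family are typographically ambiguous, and mid-test metabolic
  weight is the quantity the classical Koch feed-efficiency construction
  uses. This is an interpretation, recorded here.
* RFI and RG are cohort-level OLS residuals (intake on ADG + MW, and ADG
  on intake + MW). They are fitted within test cohort because the CG for
  efficiency traits includes the test identity; residuals sum to zero
  within each cohort by construction.
* Frame score uses the published sex-specific linear equations; fat
  depths enter in **cm** (field records often store rump fat in mm, so
  the interface accepts `rft_mm` and converts).
* W450 uses the standard linear age adjustment
  $W_{450} = w + \mathrm{ADG}\,(450 - \mathrm{age})$ with ADG taken from
  the 405–495-day window; the source method is named but not written out
  in the motivating work, so the standard adjustment is used and
  documented.

## The animal model and its sampler

Per iteration the Gibbs sampler performs:

1. **Location effects** (CG levels, then per-animal breeding-value
   blocks) from their Gaussian full conditionals, single-site /
   single-animal Gauss–Seidel sweeps in a fixed order. The per-animal
   update uses the sparse A⁻¹ row, so an iteration is O(animals ×
   nonzeros).
2. **Augmentation.** Missing phenotypes are drawn from their conditional
   Gaussian given the observed traits of the same animal (keeping the R₀
   update conjugate — the two published trait groups overlap only
   partially, so this matters); binary liabilities are drawn from
   truncated normals given the observed category, with the threshold
   fixed at 0.
3. **R₀** from its inverted-Wishart full conditional on the residual
   cross-products, then a rescale of each binary trait's row/column (and
   of that trait's liabilities, CG effects and breeding values) so the
   binary residual variance is exactly 1 — the standard identifiability
   device for threshold models.
4. **G₀** from the inverted-Wishart with scale a′A⁻¹a + prior scale.

Priors are proper but weak: inverted-Wishart with df = t + 1 and scale =
half the phenotypic (co)variance guess (diagonal). Fixed effects get flat
priors; all CG levels are kept (no explicit constraint) and posterior
reporting is restricted to variance parameters, which are invariant to
the location confounding. Chain defaults mirror long production runs
(600k/100k/100); the validation studies in this package use 20k/4k/10,
which the recovery experiments show is adequate at the ~2,000-animal
scale.

Numerical choices: covariance draws use the Bartlett decomposition with
R's RNG (so chains are reproducible under `set.seed()`); truncated
normals use inverse-CDF sampling with an exponential-rejection branch in
the far tail (stable beyond 8 SDs); the sparse A⁻¹ comes from Henderson's
rules with exact inbreeding (F from the tabular A diagonal) and is tested
equal to `solve(A)`; `h_inverse()` uses dense numerical inverses, with G
blended as G_b = 0.95 G + 0.05 A₂₂ by default to guarantee invertibility
(weight exposed, 1.0 allowed). Dense A and H limit the practical scale to
a few thousand animals, which is the intended synthetic-validation
regime.

The sampler's correctness is tested three ways: (i) in residual-only mode
its posterior matches the closed-form inverse-chi-square; (ii) a
successive-conditional simulation (alternately drawing parameters given
data and data given parameters) recovers the prior's precision moments —
the classic joint-distribution test for Gibbs implementations; (iii)
parameter-recovery studies on synthetic data recover the generating
heritability and genetic correlation within Monte-Carlo error, with
nominal HPD coverage.

## Posterior summaries

Heritability is summarized as the posterior mean of per-draw ratios (not
the ratio of posterior means), matching the Bayesian convention of
transforming draws; the same applies to correlations. HPD intervals are
the shortest contiguous window containing ⌈prob·n⌉ sorted draws (ties to
the lowest left endpoint); an equal-tailed alternative is a one-liner via
`quantile()` if preferred. The Geweke statistic compares the first 10%
and last 50% of a chain; the spectral density at zero is estimated from
an AR fit with AIC order selection — a Bartlett lag window was evaluated
and calibrated noticeably below nominal on both iid and autocorrelated
chains, while the AR estimator holds close to the nominal 95% acceptance
on iid chains without collapsing on AR(0.7) chains.

## What the generator emulates — and what it does not

The generator reproduces the assumed statistical structure exactly:
founders N(0, G₀), Mendelian-sampling deviations with variance
(0.5 − 0.25(F_s + F_d))G₀ using exact parental inbreeding (so
Var(vec(a)) = A ⊗ G₀ holds, verified empirically against the tabular A),
liability-scale binary traits, MVN residuals, random non-selfing matings
(sires may serve several dams, so inbreeding accumulates by chance), and
unlinked SNPs gene-dropped through the pedigree. Feedlot logs are linear
growth plus weighing noise with intake coupled to growth rate.

Defaults were chosen once by desk calibration against published Nelore
feedlot summaries: ADG 1.3 ± 0.12 kg/day, intake
DMI = 8.06 + 3.5(ADG − 1.3) + N(0, 1.5²) kg/day, diet price 1.30 \$/kg DM,
overhead 2.06 \$/day, arroba price 300 \$ (typical of the fat-cattle
indicator at data-collection time), entire males (dressing 58.55%),
80-day window. Under the profit equations these imply a mean AFP of about
152 \$ and mean DMI of 8.06 kg/day, with AFP SD ≈ 70 \$ — close to the
published descriptive statistics. The herd-structure defaults (400
founders, 4 generations, 2 offspring per dam, 25 CGs) are chosen for test
power, not demographic realism; published totals give no herd-structure
parameters.

Real data differ in ways the generator does not attempt: selection and
assortative mating, non-additive genetic effects, linkage disequilibrium,
heterogeneous CG sizes and variances, growth curves that bend over the
feeding period, and informative missingness. Passing recovery tests
therefore validates the estimation machinery under the model's own
assumptions — they do not certify behaviour under model misspecification.

## Validation problem sizes

The recovery studies use ~1,600–2,000 animals (400 founders, 4
generations), single- and two-trait models, chains of 20,000 iterations
(4,000 burn-in, thin 10), and 10–20 replicate seeds; oracle equivalences
(path-counting A, brute-force H⁻¹ and HPD windows, normal-equation
residuals) run on exhaustive small cases. These sizes were chosen as the
smallest at which the posterior concentrates enough for 3-SE recovery
checks to be informative.

## Known limitations

* Dense A/H inverses: no sparse large-pedigree factorizations; the
  practical ceiling is a few thousand animals.
* No REML alternative, maternal or permanent-environment effects,
  genetic groups, or heterogeneous residual variances across CGs.
* The optimal-slaughter-day optimization and commercial growth-curve
  machinery behind the original phenotypes are out of scope; profits are
  computed from observed daily records.
* Threshold-trait heritabilities on modest data show the usual mild
  shrinkage toward the prior; linear-trait recovery is unbiased within
  Monte-Carlo error in the validation studies.

## A worked example

```{r, eval = FALSE}
library(feedlotgen)

cfg <- sim_config(n_founders = 400, n_generations = 4,
                  traits = list(trait_spec("AFP")),
                  G0 = matrix(6321.23), R0 = matrix(28687.29), seed = 11)
ped <- simulate_pedigree(cfg)
bv  <- simulate_breeding_values(ped, cfg$G0, seed = 12)
phe <- simulate_phenotypes(ped, bv, cfg, seed = 13)

fit <- animal_model("AFP", phe, ped, cg = "cg",
                    chain = chain_config(20000, 4000, 10, seed = 14))
summary(fit)
heritability(fit, "AFP")
```
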