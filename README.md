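# feedlotgen

Genetic analysis of feedlot profitability traits in beef cattle.

Feedlot margins are narrow, and the traits breeders usually select on are
measured long before finishing. `feedlotgen` is for quantitative
geneticists who want to treat feedlot **profit itself** as a heritable
phenotype: it derives per-animal economic phenotypes from daily sensor
records, edits them into contemporary groups, and estimates variance
components, heritabilities and genetic correlations with a multi-trait
Bayesian animal model — together with a synthetic-data generator that
makes the whole pipeline testable without proprietary herd data.

## What it computes

**Economic phenotypes.** From daily weight `w_d` and dry-matter intake
`DMI_d`, with shrink factor `s = 0.96`, sex-specific carcass dressing `c`
(%), arroba price `p@` ($/15 kg carcass), diet price `p` ($/kg DM) and
daily overhead `o`:

    acc_d   = s * w_d * c/100 / 15          (accumulated arrobas)
    AFP     = sum_d [ p@ * (acc_d - acc_{d-1}) - (p * DMI_d + o) ]
    PFT     = AFP / (acc_T - acc_1)         ($ per arroba gained)

**Auxiliary traits.** ADG (OLS slope of weight on day), mid-test
metabolic weight `(alpha + beta*DET/2)^0.75`, cohort-level residual feed
intake and residual gain (Koch regressions), sex-specific frame-score
equations, and the linear age adjustment of weight to 450 days.

**Relationship matrices.** Pedigree `A` (tabular method, with
inbreeding), VanRaden genomic `G = ZZ'/2Σp_k q_k`, and the single-step
inverse `H⁻¹ = A⁻¹ + [0 0; 0 G_b⁻¹ − A₂₂⁻¹]`.

**Inference.** `animal_model()` fits `y = Xβ + Za + e` for any mix of
linear and binary (threshold/liability) traits by Gibbs sampling, with
contemporary-group fixed effects, `Var(a) = G₀ ⊗ A` (or `H`),
`Var(e) = R₀ ⊗ I`, missing-phenotype augmentation, and returns an S3
object with `print`, `summary`, `coef` and `plot` methods. Summaries
include per-draw heritabilities and correlations, shortest-HPD intervals,
Geweke diagnostics and the standard magnitude classes.

## A worked example

```r
library(feedlotgen)

# simulate a 4-generation herd with the published AFP variance components
cfg <- sim_config(n_founders = 400, n_generations = 4,
                  traits = list(trait_spec("AFP")),
                  G0 = matrix(6321.23), R0 = matrix(28687.29), seed = 11)
ped <- simulate_pedigree(cfg)            # 1,926 animals
bv  <- simulate_breeding_values(ped, cfg$G0, seed = 12)
phe <- simulate_phenotypes(ped, bv, cfg, seed = 13)

fit <- animal_model("AFP", phe, ped, cg = "cg",
                    chain = chain_config(20000, 4000, 10, seed = 14))
summary(fit)
```

```
Posterior summaries from 1600 stored draws (HPD 95%)

Heritabilities and variance components:
 trait    var_a    var_e    h2     sd hpd_low hpd_high geweke_z class
   AFP 6107.892 29269.39 0.172 0.0393  0.0918    0.250     2.73   low
```

The simulation truth is h² = 6321.23/(6321.23 + 28687.29) = 0.18; the
posterior mean from this single reduced chain is 0.172 with a 95% HPD of
[0.092, 0.250] — the generating value sits comfortably inside. The profit
engine works the same way from raw logs:

```r
log  <- simulate_feedlot_log(paste0("a", 1:1000), n_days = 80, seed = 45)
meta <- data.frame(animal = unique(log$animal), sex = "male")
prof <- profit_phenotypes(log, meta)       # afp, pft, costs, revenues
mean(prof$afp)   # 150.85 $  (80-day accumulated profit)
mean(log$dmi_kg) # 8.07 kg/day
```

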