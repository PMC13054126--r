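test_that("simulate_pedigree satisfies structural invariants", {
  cfg0 <- sim_config(n_founders = 2, n_generations = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 2L)
  expect_true(all(ped0$sire == "0" & ped0$dam == "0"))

  cfg <- sim_config(n_founders = 100, n_generations = 3,
                    offspring_per_mating = 2, seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_false(anyDuplicated(ped$animal) > 0)
  nf <- ped[ped$generation > 0, ]
  expect_true(all(nf$sire != "0" & nf$dam != "0"))
  expect_true(all(nf$sire != nf$animal & nf$dam != nf$animal))
  # parents come from the previous generation
  gen <- setNames(ped$generation, ped$animal)
  expect_true(all(gen[nf$sire] == nf$generation - 1))
  expect_true(all(gen[nf$dam] == nf$generation - 1))
  # determinism under a fixed seed
  expect_identical(ped, simulate_pedigree(cfg))
  expect_error(sim_config(n_founders = 0), "n_founders")
})

test_that("gene dropping gives HWE founders and zero Mendelian conflicts", {
  cfg <- sim_config(n_founders = 600, n_generations = 1, n_snps = 60,
                    maf_range = c(0.5, 0.5), seed = 3)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  founders <- g[ped$generation == 0, ]
  # binomial(2, 0.5): mean 1, variance 0.5; 3 MC SE over 600 x 60 draws
  se_mean <- sqrt(0.5 / length(founders))
  expect_lt(abs(mean(founders) - 1), 3 * se_mean)
  expect_lt(abs(var(as.vector(founders)) - 0.5), 3 * 0.5 * sqrt(2 / length(founders)))
  # no parent-offspring opposing homozygotes, by construction
  nf <- which(ped$generation > 0)
  si <- match(ped$sire[nf], ped$animal); di <- match(ped$dam[nf], ped$animal)
  opp <- (g[nf, ] == 0 & g[si, ] == 2) | (g[nf, ] == 2 & g[si, ] == 0) |
         (g[nf, ] == 0 & g[di, ] == 2) | (g[nf, ] == 2 & g[di, ] == 0)
  expect_equal(sum(opp), 0L)
  # forced inheritance: both parents homozygous 0 at a locus -> offspring 0
  hom0 <- g[si, ] == 0 & g[di, ] == 0
  expect_true(all(g[nf, ][hom0] == 0))
})

test_that("founder breeding values have the configured variance", {
  ped <- data.frame(animal = paste0("f", 1:10000), sire = "0", dam = "0",
                    stringsAsFactors = FALSE)
  bv <- simulate_breeding_values(ped, matrix(4), seed = 4)
  # chi-square CI: at n = 10000 the sample variance of N(0,4) stays in
  # [3.7, 4.3] with overwhelming probability
  expect_gt(var(bv[, 1]), 3.7)
  expect_lt(var(bv[, 1]), 4.3)
  expect_error(simulate_breeding_values(ped, matrix(0)), "positive-definite")
})

test_that("breeding-value covariance matches A (x) G0 on a small pedigree", {
  ped <- fullsib_pedigree()
  A <- numerator_relationship(ped)
  G0 <- matrix(2)
  reps <- 4000
  set.seed(5)
  draws <- vapply(seq_len(reps),
                  function(r) simulate_breeding_values(ped, G0)[, 1],
                  numeric(nrow(ped)))
  emp <- tcrossprod(draws) / reps     # mean-zero: use raw second moments
  expected <- A * 2
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    prods <- draws[i, ] * draws[j, ]
    se <- sd(prods) / sqrt(reps)
    expect_lt(abs(emp[i, j] - expected[i, j]), 3 * se + 1e-9)
  }
})

test_that("phenotype generator respects its noise, threshold and correlation structure", {
  # noise-free limit: phenotype == breeding value when CG effects are off
  cfg <- sim_config(n_founders = 50, n_generations = 1, G0 = matrix(4),
                    R0 = matrix(1e-12), cg_effect_sd = 0, seed = 6)
  sim <- simulate_pedigree(cfg)
  bv <- simulate_breeding_values(sim, cfg$G0, seed = 7)
  phe <- simulate_phenotypes(sim, bv, cfg, seed = 8)
  expect_equal(phe$y, unname(bv[, 1]), tolerance = 1e-4)

  # binary trait with threshold at the liability median: ~50% success
  cfgb <- sim_config(n_founders = 5000, n_generations = 0,
                     traits = list(trait_spec("b", "binary")),
                     G0 = matrix(1), R0 = matrix(1), cg_effect_sd = 0,
                     seed = 9)
  pedb <- simulate_pedigree(cfgb)
  bvb <- simulate_breeding_values(pedb, cfgb$G0, seed = 10)
  pheb <- simulate_phenotypes(pedb, bvb, cfgb, seed = 11)
  p <- mean(pheb$b == 2)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 5000))

  # residual correlation 0.9 shows up in the sampled residuals
  R0 <- matrix(c(1, 0.9, 0.9, 1), 2)
  cfg2 <- sim_config(n_founders = 5000, n_generations = 0,
                     traits = list(trait_spec("u"), trait_spec("v")),
                     G0 = diag(1e-8, 2), R0 = R0, cg_effect_sd = 0, seed = 12)
  ped2 <- simulate_pedigree(cfg2)
  bv2 <- simulate_breeding_values(ped2, cfg2$G0, seed = 13)
  ph2 <- simulate_phenotypes(ped2, bv2, cfg2, seed = 14)
  r <- cor(ph2$u, ph2$v)
  expect_lt(abs(r - 0.9), 3 * (1 - 0.9^2) / sqrt(5000))

  # sex restriction produces missingness only in the other sex
  cfgs <- sim_config(n_founders = 200, n_generations = 0,
                     traits = list(trait_spec("sc", sex_restriction = "male")),
                     G0 = matrix(1), R0 = matrix(1), seed = 15)
  peds <- simulate_pedigree(cfgs)
  bvs <- simulate_breeding_values(peds, cfgs$G0, seed = 16)
  phs <- simulate_phenotypes(peds, bvs, cfgs, seed = 17)
  expect_true(all(is.na(phs$sc[phs$sex == "female"])))
  expect_true(all(!is.na(phs$sc[phs$sex == "male"])))
})

test_that("feedlot log is linear without noise and reproducible", {
  log0 <- simulate_feedlot_log(c("a1", "a2"), n_days = 10,
                               weight_noise_sd = 0, dmi_noise_sd = 0,
                               init_weight_sd = 0, adg_sd = 0, seed = 18)
  w <- log0$weight_kg[log0$animal == "a1"]
  expect_equal(diff(w), rep(1.3, 9), tolerance = 1e-12)
  expect_identical(log0, simulate_feedlot_log(c("a1", "a2"), n_days = 10,
                                              weight_noise_sd = 0,
                                              dmi_noise_sd = 0,
                                              init_weight_sd = 0, adg_sd = 0,
                                              seed = 18))
  expect_error(simulate_feedlot_log("a", n_days = 1), "n_days")
})
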