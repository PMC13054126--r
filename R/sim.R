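# Synthetic-data generators: pedigree, gene-dropped genotypes, breeding
# values with exact Mendelian-sampling variance, phenotypes (linear and
# liability-scale binary) and daily feedlot sensor logs. These reproduce the
# statistical structure the animal model assumes, so the estimation machinery
# can be validated end-to-end without proprietary herd data.

#' Trait specification
#'
#' @param name trait name (column name in simulated tables).
#' @param kind "linear" or "binary". Binary traits are observed as codes
#'   1 (failure) / 2 (success) from a thresholded latent liability.
#' @param sex_restriction "both", "male" or "female"; restricted traits are
#'   missing for the other sex.
#' @return an object of class "trait_spec".
#' @export
trait_spec <- function(name, kind = c("linear", "binary"),
                       sex_restriction = c("both", "male", "female")) {
  kind <- match.arg(kind)
  sex_restriction <- match.arg(sex_restriction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, kind = kind, sex_restriction = sex_restriction),
            class = "trait_spec")
}

#' Simulation configuration
#'
#' Bundles the herd structure, marker panel and (co)variance truth used by
#' the generators. `G0` and `R0` are the across-trait additive-genetic and
#' residual covariance matrices; both must be symmetric positive-definite.
#'
#' @param n_founders number of unrelated founder animals (>= 2).
#' @param n_generations number of discrete offspring generations (>= 0).
#' @param offspring_per_mating offspring produced per dam.
#' @param n_snps number of independent biallelic SNPs.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param traits list of [trait_spec()] objects.
#' @param G0,R0 t x t genetic and residual covariance matrices (t = number of
#'   traits).
#' @param cg_count number of contemporary-group levels.
#' @param cg_effect_sd per-trait SD of contemporary-group effects; defaults
#'   to 0.3 x residual SD.
#' @param binary_thresholds named liability thresholds for binary traits
#'   (default 0).
#' @param seed integer seed controlling all downstream draws.
#' @return an object of class "sim_config".
#' @export
sim_config <- function(n_founders = 400, n_generations = 4,
                       offspring_per_mating = 2, n_snps = 500,
                       maf_range = c(0.05, 0.5),
                       traits = list(trait_spec("y")),
                       G0 = matrix(1), R0 = matrix(1),
                       cg_count = 25, cg_effect_sd = NULL,
                       binary_thresholds = NULL, seed = NULL) {
  n_founders <- .check_count(n_founders, "n_founders", min = 2L)
  n_generations <- .check_count(n_generations, "n_generations", min = 0L)
  offspring_per_mating <- .check_count(offspring_per_mating,
                                       "offspring_per_mating", min = 1L)
  n_snps <- .check_count(n_snps, "n_snps", min = 1L)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must lie within (0, 0.5]")
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  .check_pd(G0, "G0"); .check_pd(R0, "R0")
  t <- length(traits)
  if (nrow(G0) != t || nrow(R0) != t)
    stop("G0 and R0 must be t x t for t = length(traits)")
  nm <- vapply(traits, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("trait names must be unique")
  dimnames(G0) <- dimnames(R0) <- list(nm, nm)
  if (is.null(cg_effect_sd)) cg_effect_sd <- 0.3 * sqrt(diag(R0))
  cg_effect_sd <- rep_len(cg_effect_sd, t)
  structure(list(n_founders = n_founders, n_generations = n_generations,
                 offspring_per_mating = offspring_per_mating,
                 n_snps = n_snps, maf_range = maf_range, traits = traits,
                 trait_names = nm, G0 = G0, R0 = R0, cg_count = cg_count,
                 cg_effect_sd = cg_effect_sd,
                 binary_thresholds = binary_thresholds, seed = seed),
            class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Founders are unrelated and have unknown ("0") parents. In every later
#' generation each female of the previous generation is mated to a randomly
#' chosen male of that generation (sires may serve several dams, as in
#' natural-service beef herds) and produces `offspring_per_mating` offspring
#' of random sex. Relatives therefore mate by chance from the second
#' offspring generation on, so inbreeding accumulates.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns animal, sire, dam ("0" = unknown),
#'   generation and sex, parents always listed before offspring.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    id <- function(g, k) sprintf("G%02d_%05d", g, k)
    n0 <- cfg$n_founders
    sex <- sample(c("male", "female"), n0, replace = TRUE)
    # mating needs both sexes
    if (all(sex == sex[1])) sex[1] <- setdiff(c("male", "female"), sex[1])
    ped <- data.frame(animal = id(0, seq_len(n0)), sire = "0", dam = "0",
                      generation = 0L, sex = sex, stringsAsFactors = FALSE)
    prev <- ped
    if (cfg$n_generations > 0) {
      for (g in seq_len(cfg$n_generations)) {
        dams <- prev$animal[prev$sex == "female"]
        sires <- prev$animal[prev$sex == "male"]
        if (length(dams) == 0L || length(sires) == 0L)
          stop("a generation ran out of one sex; increase n_founders")
        mate_sire <- sample(sires, length(dams), replace = TRUE)
        n_off <- length(dams) * cfg$offspring_per_mating
        off_sex <- sample(c("male", "female"), n_off, replace = TRUE)
        if (all(off_sex == off_sex[1]) && n_off > 1L)
          off_sex[1] <- setdiff(c("male", "female"), off_sex[1])
        off <- data.frame(
          animal = id(g, seq_len(n_off)),
          sire = rep(mate_sire, each = cfg$offspring_per_mating),
          dam = rep(dams, each = cfg$offspring_per_mating),
          generation = g, sex = off_sex, stringsAsFactors = FALSE)
        ped <- rbind(ped, off)
        prev <- off
      }
    }
    .validate_pedigree(ped)
    ped
  })
}

.validate_pedigree <- function(ped) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) stop("pedigree needs animal/sire/dam columns")
  if (anyDuplicated(ped$animal)) stop("duplicate animal IDs in pedigree")
  idx <- match(ped$sire, ped$animal)
  jdx <- match(ped$dam, ped$animal)
  known_s <- ped$sire != "0"; known_d <- ped$dam != "0"
  if (any(known_s & is.na(idx)) || any(known_d & is.na(jdx)))
    stop("pedigree references parents that are not listed as animals")
  if (any(ped$sire == ped$animal | ped$dam == ped$animal))
    stop("an animal cannot be its own parent")
  invisible(ped)
}

# topological order (parents before offspring); errors on cycles
.topo_order <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal); si[ped$sire == "0"] <- NA
  di <- match(ped$dam, ped$animal); di[ped$dam == "0"] <- NA
  depth <- rep(NA_integer_, n)
  pending <- rep(TRUE, n)
  guard <- 0L
  while (any(pending)) {
    guard <- guard + 1L
    if (guard > n + 1L) stop("pedigree contains a cycle")
    progressed <- FALSE
    for (i in which(pending)) {
      ds <- if (is.na(si[i])) -1L else depth[si[i]]
      dd <- if (is.na(di[i])) -1L else depth[di[i]]
      if (!is.na(ds) && !is.na(dd)) {
        depth[i] <- max(ds, dd) + 1L
        pending[i] <- FALSE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("pedigree contains a cycle")
  }
  order(depth, seq_len(n))
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder allele frequencies are drawn uniformly inside the configured MAF
#' range and founder genotypes in Hardy-Weinberg proportions; each offspring
#' receives one allele from each parent per locus, independently across the
#' (unlinked) loci. Mendelian consistency therefore holds by construction.
#'
#' @param ped pedigree from [simulate_pedigree()] (or any data.frame with
#'   animal/sire/dam, parents listed before offspring resolvable).
#' @param cfg a [sim_config()].
#' @return integer matrix (animals x SNPs, values 0/1/2) with animal row
#'   names; attribute "freq" carries founder allele frequencies.
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .validate_pedigree(ped)
  ord <- .topo_order(ped)
  ped <- ped[ord, , drop = FALSE]
  .with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, {
    n <- nrow(ped); m <- cfg$n_snps
    p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    geno <- matrix(0L, n, m, dimnames = list(ped$animal, NULL))
    si <- match(ped$sire, ped$animal)
    di <- match(ped$dam, ped$animal)
    transmit <- function(g) {
      al <- as.integer(g > 0L)          # 0 -> 0, 2 -> 1
      het <- g == 1L
      if (any(het)) al[het] <- rbinom(sum(het), 1L, 0.5)
      al
    }
    for (i in seq_len(n)) {
      if (is.na(si[i]) && is.na(di[i])) {
        geno[i, ] <- rbinom(m, 2L, p)
      } else if (!is.na(si[i]) && !is.na(di[i])) {
        geno[i, ] <- transmit(geno[si[i], ]) + transmit(geno[di[i], ])
      } else {
        known <- if (is.na(si[i])) di[i] else si[i]
        geno[i, ] <- transmit(geno[known, ]) + rbinom(m, 1L, p)
      }
    }
    attr(geno, "freq") <- p
    geno
  })
}

#' Simulate additive breeding values
#'
#' Founders are iid N(0, G0); each non-founder is the parental mean plus a
#' Mendelian-sampling deviation with covariance
#' (0.5 - 0.25 (F_s + F_d)) G0, using the exact parental inbreeding
#' coefficients from the pedigree, so that Var(vec(a)) = A (x) G0 holds
#' exactly (not only in the non-inbred approximation).
#'
#' @param ped pedigree data.frame (animal/sire/dam).
#' @param G0 t x t positive-definite genetic covariance matrix.
#' @param seed optional seed.
#' @return numeric matrix animals x traits, rows named by animal, in the
#'   input pedigree order.
#' @export
simulate_breeding_values <- function(ped, G0, seed = NULL) {
  .validate_pedigree(ped)
  G0 <- as.matrix(G0)
  .check_pd(G0, "G0")
  t <- nrow(G0)
  ord <- .topo_order(ped)
  pedo <- ped[ord, , drop = FALSE]
  Fi <- inbreeding(pedo)
  .with_seed(seed, {
    n <- nrow(pedo)
    L <- chol(G0)                       # upper: z %*% L has covariance G0
    z <- matrix(rnorm(n * t), n, t) %*% L
    si <- match(pedo$sire, pedo$animal)
    di <- match(pedo$dam, pedo$animal)
    a <- matrix(0, n, t, dimnames = list(pedo$animal, colnames(G0)))
    for (i in seq_len(n)) {
      if (is.na(si[i]) && is.na(di[i])) {
        a[i, ] <- z[i, ]
      } else {
        pm <- 0; vscale <- 0
        fs <- if (is.na(si[i])) NA else Fi[si[i]]
        fd <- if (is.na(di[i])) NA else Fi[di[i]]
        if (!is.na(si[i]) && !is.na(di[i])) {
          pm <- 0.5 * (a[si[i], ] + a[di[i], ])
          vscale <- 0.5 - 0.25 * (fs + fd)
        } else {
          ip <- if (is.na(si[i])) di[i] else si[i]
          fp <- if (is.na(si[i])) fd else fs
          pm <- 0.5 * a[ip, ]
          vscale <- 0.75 - 0.25 * fp
        }
        a[i, ] <- pm + sqrt(vscale) * z[i, ]
      }
    }
    a[match(ped$animal, pedo$animal), , drop = FALSE]
  })
}

#' Simulate phenotypes under the animal model
#'
#' Linear traits are y = CG effect + breeding value + residual with residuals
#' MVN(0, R0) per animal; binary traits are generated on the liability scale
#' (same linear predictor) and observed as 2 (success) when the liability
#' exceeds the trait's threshold, 1 otherwise. Sex-restricted traits are
#' missing for the other sex; additional completely-at-random missingness is
#' available through `missing_rate`.
#'
#' @param ped pedigree data.frame; a `sex` column is used for restrictions
#'   (all "male" assumed when absent).
#' @param bv breeding-value matrix from [simulate_breeding_values()], rows
#'   matching `ped$animal`.
#' @param cfg a [sim_config()] supplying R0, trait specs, CG structure and
#'   thresholds.
#' @param cg optional integer CG assignment per animal (recycled none);
#'   defaults to a uniform random assignment over `cfg$cg_count` levels.
#' @param trait_means optional per-trait means (default 0).
#' @param missing_rate per-trait probability of missing-at-random records.
#' @param seed optional seed.
#' @return data.frame: animal, sex, cg, then one column per trait (binary
#'   traits coded 1/2, missing NA). The true CG effects are attached as
#'   attribute "cg_effects".
#' @export
simulate_phenotypes <- function(ped, bv, cfg, cg = NULL, trait_means = NULL,
                                missing_rate = 0, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  R0 <- cfg$R0
  .check_pd(R0, "R0")
  t <- nrow(R0)
  n <- nrow(ped)
  if (nrow(bv) != n) stop("bv rows must match pedigree animals")
  sex <- if ("sex" %in% names(ped)) ped$sex else rep("male", n)
  if (is.null(trait_means)) trait_means <- rep(0, t)
  trait_means <- rep_len(trait_means, t)
  missing_rate <- rep_len(missing_rate, t)
  .with_seed(seed, {
    if (is.null(cg)) cg <- sample.int(cfg$cg_count, n, replace = TRUE)
    cg_eff <- matrix(rnorm(cfg$cg_count * t), cfg$cg_count, t)
    cg_eff <- sweep(cg_eff, 2L, cfg$cg_effect_sd, `*`)
    e <- matrix(rnorm(n * t), n, t) %*% chol(R0)
    out <- data.frame(animal = ped$animal, sex = sex, cg = cg,
                      stringsAsFactors = FALSE)
    for (j in seq_len(t)) {
      spec <- cfg$traits[[j]]
      y <- trait_means[j] + cg_eff[cg, j] + bv[, j] + e[, j]
      if (spec$kind == "binary") {
        thr <- 0
        if (!is.null(cfg$binary_thresholds) &&
            spec$name %in% names(cfg$binary_thresholds))
          thr <- cfg$binary_thresholds[[spec$name]]
        y <- ifelse(y > thr, 2, 1)
      }
      if (spec$sex_restriction != "both") y[sex != spec$sex_restriction] <- NA
      if (missing_rate[j] > 0)
        y[runif(n) < missing_rate[j]] <- NA
      out[[spec$name]] <- y
    }
    attr(out, "cg_effects") <- cg_eff
    out
  })
}

#' Simulate a daily feedlot sensor log
#'
#' Each animal gets a linear growth trajectory (initial weight + ADG x day)
#' observed with weighing noise, and a daily dry-matter intake that tracks
#' its growth rate: DMI = base + slope x (ADG - mean ADG) + daily noise,
#' floored at a small positive value. The defaults are calibrated so that a
#' default run of the profit engine on entire males reproduces the typical
#' feedlot summary moments of Nelore efficiency-test data (pooled DMI mean
#' about 8.06 kg/day, accumulated 80-day profit mean about 152 $).
#'
#' @param animals character vector of animal IDs.
#' @param n_days number of daily records per animal (>= 2).
#' @param init_weight_mean,init_weight_sd initial body weight distribution (kg).
#' @param adg_mean,adg_sd across-animal average daily gain distribution (kg/day).
#' @param weight_noise_sd weighing error SD (kg).
#' @param dmi_base mean daily dry-matter intake at the mean ADG (kg/day).
#' @param dmi_adg_slope kg DM per kg of ADG deviation (intake-growth coupling).
#' @param dmi_noise_sd day-to-day intake noise SD (kg).
#' @param adg optional per-animal ADG overriding the random draw.
#' @param seed optional seed.
#' @return data.frame with columns animal, day (1..n_days), weight_kg,
#'   dmi_kg.
#' @export
simulate_feedlot_log <- function(animals, n_days = 80,
                                 init_weight_mean = 350, init_weight_sd = 25,
                                 adg_mean = 1.3, adg_sd = 0.12,
                                 weight_noise_sd = 2,
                                 dmi_base = 8.06, dmi_adg_slope = 3.5,
                                 dmi_noise_sd = 1.5,
                                 adg = NULL, seed = NULL) {
  n_days <- .check_count(n_days, "n_days", min = 2L)
  n <- length(animals)
  if (n < 1L) stop("need at least one animal")
  .with_seed(seed, {
    w0 <- rnorm(n, init_weight_mean, init_weight_sd)
    if (is.null(adg)) adg <- rnorm(n, adg_mean, adg_sd)
    adg <- rep_len(adg, n)
    day <- seq_len(n_days)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      w <- w0[i] + adg[i] * (day - 1) + rnorm(n_days, 0, weight_noise_sd)
      dmi <- dmi_base + dmi_adg_slope * (adg[i] - adg_mean) +
        rnorm(n_days, 0, dmi_noise_sd)
      dmi <- pmax(dmi, 0.5)
      out[[i]] <- data.frame(animal = animals[i], day = day,
                             weight_kg = w, dmi_kg = dmi,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
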