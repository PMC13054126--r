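# Multi-trait Bayesian linear-threshold animal model fitted by Gibbs
# sampling. The general model per trait is y = Xb + Za + e with b the
# contemporary-group fixed effects (flat prior), a the additive genetic
# effects with Var(vec(a)) = G0 (x) A (or H in single-step form) and
# residuals Var = R0 (x) I across animals. Binary traits enter through a
# latent liability thresholded at zero with residual variance fixed at 1.

#' Gibbs chain configuration
#'
#' Defaults mirror the long production chain (600,000 iterations, 100,000
#' burn-in, thin 100); validation runs use much shorter chains, e.g.
#' `chain_config(20000, 4000, 10)`.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before storage.
#' @param thin storage interval.
#' @param seed seed applied immediately before sampling (optional).
#' @return an object of class "chain_config".
#' @export
chain_config <- function(n_iter = 600000, burn_in = 100000, thin = 100,
                         seed = NULL) {
  n_iter <- .check_count(n_iter, "n_iter")
  burn_in <- .check_count(burn_in, "burn_in", min = 0L)
  thin <- .check_count(thin, "thin")
  if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed),
            class = "chain_config")
}

#' Build incidence structures for the animal model
#'
#' Maps trait records to contemporary-group levels and to animal effects.
#' Returned per trait: the record rows (animals with a non-missing value),
#' the CG incidence matrix X (records x levels, one 1 per row), the animal
#' incidence Z (records x pedigree animals) and the integer index vectors
#' the sampler consumes.
#'
#' @param data data.frame with an `id` column, trait columns and CG columns.
#' @param traits character vector of trait column names.
#' @param cg NULL (no fixed effects), a single CG column name, or a named
#'   vector mapping trait -> CG column.
#' @param ped_ids character vector of pedigree animal IDs (the index set of
#'   the relationship matrix).
#' @param id name of the animal-ID column.
#' @return list with per-trait design info and the N x t matrices `y_mat`
#'   and `cg_mat` used by the sampler.
#' @export
build_design <- function(data, traits, cg = NULL, ped_ids, id = "animal") {
  if (!id %in% names(data)) stop("no '", id, "' column in data")
  missing_tr <- setdiff(traits, names(data))
  if (length(missing_tr))
    stop("trait columns not in data: ", paste(missing_tr, collapse = ", "))
  row_of <- match(data[[id]], ped_ids)
  if (anyNA(row_of))
    stop("phenotyped animals absent from the pedigree/relationship ids: ",
         paste(head(unique(data[[id]][is.na(row_of)])), collapse = ", "))
  t <- length(traits)
  if (!is.null(cg)) {
    if (length(cg) == 1L && is.null(names(cg))) cg <- rep(cg, t)
    if (!is.null(names(cg))) cg <- cg[traits]
    if (length(cg) != t || anyNA(cg))
      stop("'cg' must name one CG column per trait")
    missing_cg <- setdiff(unique(cg), names(data))
    if (length(missing_cg))
      stop("CG columns not in data: ", paste(missing_cg, collapse = ", "))
  }
  N <- length(ped_ids)
  y_mat <- matrix(NA_real_, N, t, dimnames = list(ped_ids, traits))
  cg_mat <- matrix(0L, N, t)
  per_trait <- vector("list", t); names(per_trait) <- traits
  for (j in seq_len(t)) {
    yj <- data[[traits[j]]]
    obs <- which(!is.na(yj))
    rows <- row_of[obs]
    if (anyDuplicated(rows))
      stop("repeated records for trait '", traits[j],
           "': the model expects at most one record per animal")
    y_mat[rows, j] <- yj[obs]
    levels_j <- character(0)
    if (!is.null(cg)) {
      lab <- as.character(data[[cg[j]]][obs])
      if (anyNA(lab) || any(lab == ""))
        stop("missing CG label for observed records of trait '", traits[j], "'")
      levels_j <- sort(unique(lab))
      cg_mat[rows, j] <- match(lab, levels_j)
    }
    X <- if (length(levels_j))
      Matrix::sparseMatrix(i = seq_along(obs),
                           j = match(as.character(data[[cg[j]]][obs]), levels_j),
                           x = 1, dims = c(length(obs), length(levels_j)),
                           dimnames = list(NULL, levels_j))
    else Matrix::Matrix(0, length(obs), 0)
    Z <- Matrix::sparseMatrix(i = seq_along(obs), j = rows, x = 1,
                              dims = c(length(obs), N),
                              dimnames = list(NULL, ped_ids))
    per_trait[[j]] <- list(records = obs, animal_row = rows, X = X, Z = Z,
                           cg_levels = levels_j)
  }
  list(per_trait = per_trait, y_mat = y_mat, cg_mat = cg_mat,
       traits = traits, ped_ids = ped_ids)
}

.default_prior <- function(y_mat, binary_flag) {
  t <- ncol(y_mat)
  v <- numeric(t)
  for (j in seq_len(t)) {
    yj <- y_mat[, j]
    v[j] <- if (binary_flag[j]) 1 else var(yj, na.rm = TRUE)
    if (!is.finite(v[j]) || v[j] <= 0) v[j] <- 1
  }
  list(Sg = diag(0.5 * v, t), nug = t + 1,
       Sr = diag(0.5 * v, t), nur = t + 1)
}

#' Fit the multi-trait Bayesian animal model
#'
#' Gibbs sampler for t traits (linear and/or binary) with per-trait
#' contemporary-group fixed effects and additive genetic effects structured
#' by a relationship matrix: the sparse pedigree A-inverse by default, or
#' any user-supplied relationship inverse (e.g. the single-step H-inverse
#' from [h_inverse()]). Missing phenotypes are handled by data augmentation;
#' binary traits by liability augmentation with the threshold fixed at 0 and
#' the binary residual variance fixed at 1. Every `thin`-th post-burn-in
#' draw of (G0, R0) is stored.
#'
#' @param traits character vector of trait columns in `data`.
#' @param data data.frame with animal IDs, trait values (binary traits coded
#'   1/2) and CG labels.
#' @param pedigree data.frame animal/sire/dam; defines the animal index set
#'   and the default relationship structure.
#' @param cg NULL, a single CG column name, or a named trait -> column map.
#' @param binary character vector naming the binary traits.
#' @param relationship_inverse optional relationship inverse (dense or
#'   sparse, with animal dimnames) overriding the pedigree A-inverse.
#' @param chain a [chain_config()].
#' @param prior list(Sg, nug, Sr, nur): inverted-Wishart scales and degrees
#'   of freedom for G0 and R0. Default: df = t + 1 and scale = half the
#'   per-trait phenotypic variance (weakly informative, proper).
#' @param genetic set FALSE to drop the genetic effect entirely (residual
#'   model only; mostly useful for sampler validation).
#' @param init optional list(G0, R0, a, b, e) of starting values (used to
#'   resume a chain).
#' @param store_effects accumulate posterior means of breeding values and CG
#'   effects.
#' @param id animal-ID column name.
#' @return object of class "animal_model"; see [summary.animal_model()].
#' @seealso [heritability()], [genetic_correlation()], [hpd_interval()]
#' @examples
#' cfg <- sim_config(n_founders = 60, n_generations = 2, n_snps = 10,
#'                   G0 = matrix(4), R0 = matrix(6), seed = 1)
#' ped <- simulate_pedigree(cfg)
#' bv <- simulate_breeding_values(ped, cfg$G0, seed = 2)
#' phe <- simulate_phenotypes(ped, bv, cfg, seed = 3)
#' fit <- animal_model("y", phe, ped, cg = "cg",
#'                     chain = chain_config(400, 100, 2, seed = 4))
#' summary(fit)
#' @export
animal_model <- function(traits, data, pedigree = NULL, cg = NULL,
                         binary = character(0),
                         relationship_inverse = NULL,
                         chain = chain_config(), prior = NULL,
                         genetic = TRUE, init = list(),
                         store_effects = TRUE, id = "animal") {
  stopifnot(inherits(chain, "chain_config"))
  if (genetic && is.null(pedigree) && is.null(relationship_inverse))
    stop("supply a pedigree or a relationship inverse (or genetic = FALSE)")
  if (!is.null(relationship_inverse)) {
    ped_ids <- rownames(relationship_inverse)
    if (is.null(ped_ids)) stop("relationship inverse needs animal dimnames")
    P <- methods::as(methods::as(Matrix::Matrix(relationship_inverse,
                                                sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  } else if (!is.null(pedigree)) {
    .validate_pedigree(pedigree)
    ped_ids <- pedigree$animal
    P <- if (genetic) ainverse(pedigree) else NULL
  } else {
    ped_ids <- unique(data[[id]])
    P <- NULL
  }
  design <- build_design(data, traits, cg = cg, ped_ids = ped_ids, id = id)
  t <- length(traits)
  binary_flag <- traits %in% binary
  for (j in which(binary_flag)) {
    vals <- design$y_mat[, j]
    if (!all(vals %in% c(1, 2) | is.na(vals)))
      stop("binary trait '", traits[j], "' must be coded 1/2")
  }
  if (is.null(prior)) prior <- .default_prior(design$y_mat, binary_flag)
  .check_pd(as.matrix(prior$Sg), "prior$Sg")
  .check_pd(as.matrix(prior$Sr), "prior$Sr")
  ncg <- vapply(design$per_trait, function(d) length(d$cg_levels), integer(1))

  if (genetic) {
    Pi <- P@i; Pp <- P@p; Px <- P@x
  } else {
    Pi <- integer(0); Pp <- integer(length(ped_ids) + 1L); Px <- numeric(0)
  }
  if (!is.null(chain$seed)) set.seed(chain$seed)
  res <- .gibbs_mt_cpp(design$y_mat, design$cg_mat, as.integer(ncg),
                       binary_flag, Pi, Pp, Px, genetic,
                       as.matrix(prior$Sg), prior$nug,
                       as.matrix(prior$Sr), prior$nur,
                       chain$n_iter, chain$burn_in, chain$thin,
                       init, store_effects)
  n_kept <- res$n_kept
  G0s <- res$G0[, , seq_len(max(n_kept, 1)), drop = FALSE]
  R0s <- res$R0[, , seq_len(max(n_kept, 1)), drop = FALSE]
  dimnames(G0s) <- dimnames(R0s) <- list(traits, traits, NULL)
  bv <- res$a_mean
  dimnames(bv) <- list(ped_ids, traits)
  structure(list(
    traits = traits, binary = traits[binary_flag], n_animals = length(ped_ids),
    n_records = res$n_records, samples = list(G0 = G0s, R0 = R0s),
    n_kept = n_kept, chain = chain, prior = prior, genetic = genetic,
    breeding_values = if (store_effects) bv else NULL,
    cg_effects = if (store_effects)
      setNames(lapply(seq_len(t), function(j)
        setNames(res$b_mean[[j]],
                 design$per_trait[[j]]$cg_levels)), traits) else NULL,
    state = res$state, design = list(cg_levels = lapply(design$per_trait,
                                                        `[[`, "cg_levels")),
    call = match.call()), class = "animal_model")
}
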