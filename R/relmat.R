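# Pedigree (A), genomic (G) and single-step (H) relationship machinery.

#' Numerator relationship matrix (tabular method)
#'
#' Computes Wright's numerator relationship matrix by the tabular method:
#' a(i,i) = 1 + 0.5 a(s,d) and a(i,j) = 0.5 (a(j,s) + a(j,d)) with unknown
#' parents contributing zero, so the diagonal equals 1 + F (F = inbreeding
#' coefficient). Dense representation; intended for pedigrees up to a few
#' thousand animals.
#'
#' @param ped data.frame with columns animal, sire, dam ("0" = unknown).
#' @return symmetric matrix with animal IDs as dimnames, in the input order.
#' @export
numerator_relationship <- function(ped) {
  .validate_pedigree(ped)
  ord <- .topo_order(ped)
  pedo <- ped[ord, , drop = FALSE]
  si <- match(pedo$sire, pedo$animal); si[is.na(si)] <- 0L
  di <- match(pedo$dam, pedo$animal); di[is.na(di)] <- 0L
  A <- .tabular_a_cpp(as.integer(si), as.integer(di))
  dimnames(A) <- list(pedo$animal, pedo$animal)
  back <- match(ped$animal, pedo$animal)
  A[back, back, drop = FALSE]
}

#' Pedigree inbreeding coefficients
#'
#' F(i) = a(i,i) - 1 from the tabular numerator relationship matrix;
#' founders have F = 0.
#'
#' @inheritParams numerator_relationship
#' @return named numeric vector of inbreeding coefficients (input order).
#' @export
inbreeding <- function(ped) {
  A <- numerator_relationship(ped)
  diag(A) - 1
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' d = 1 / (0.5 - 0.25 (F_s + F_d)) (both parents known; the usual
#' adjustments apply with one or no known parent) to the familiar
#' 9-entry pattern. Exact, and equal to solve(A) up to numerical error;
#' used by the sampler because its sparsity makes the per-animal
#' conditional updates cheap.
#'
#' @inheritParams numerator_relationship
#' @return a symmetric sparse matrix (Matrix dgCMatrix) with animal
#'   dimnames (input order).
#' @export
ainverse <- function(ped) {
  .validate_pedigree(ped)
  Fi <- inbreeding(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  fs <- ifelse(is.na(si), NA, Fi[si])
  fd <- ifelse(is.na(di), NA, Fi[di])
  d <- ifelse(!is.na(si) & !is.na(di), 1 / (0.5 - 0.25 * (fs + fd)),
       ifelse(!is.na(si), 1 / (0.75 - 0.25 * fs),
       ifelse(!is.na(di), 1 / (0.75 - 0.25 * fd), 1)))
  # vectorized triplet accumulation
  add(seq_len(n), seq_len(n), d)
  ks <- which(!is.na(si)); kd <- which(!is.na(di))
  add(ks, si[ks], -0.5 * d[ks]); add(si[ks], ks, -0.5 * d[ks])
  add(kd, di[kd], -0.5 * d[kd]); add(di[kd], kd, -0.5 * d[kd])
  add(si[ks], si[ks], 0.25 * d[ks])
  add(di[kd], di[kd], 0.25 * d[kd])
  kb <- which(!is.na(si) & !is.na(di))
  add(si[kb], di[kb], 0.25 * d[kb]); add(di[kb], si[kb], 0.25 * d[kb])
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$animal, ped$animal))
  methods::as(Matrix::drop0(M), "CsparseMatrix")
}

#' Genomic relationship matrix (VanRaden)
#'
#' G = Z Z' / (2 sum p_k q_k), with Z the genotype matrix centered by twice
#' the allele frequency of each SNP. Frequencies default to those observed
#' in the genotyped set; missing genotypes are mean-imputed per SNP before
#' centering.
#'
#' @param geno animals x SNPs matrix of 0/1/2 dosages (NA = missing), with
#'   animal row names.
#' @param freq optional per-SNP allele frequencies to center by.
#' @return symmetric genomic relationship matrix with attribute "freq".
#' @export
vanraden_g <- function(geno, freq = NULL) {
  geno <- as.matrix(geno)
  if (nrow(geno) < 2L) stop("need at least two genotyped animals")
  if (is.null(freq)) freq <- colMeans(geno, na.rm = TRUE) / 2
  if (anyNA(geno)) {
    for (k in which(colSums(is.na(geno)) > 0L)) {
      miss <- is.na(geno[, k])
      geno[miss, k] <- 2 * freq[k]
    }
  }
  denom <- 2 * sum(freq * (1 - freq))
  if (denom < 1e-12)
    stop("all SNPs monomorphic: VanRaden denominator is zero")
  Z <- sweep(geno, 2L, 2 * freq, `-`)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "freq") <- freq
  G
}

#' Single-step relationship inverse (H-inverse)
#'
#' Combines the pedigree relationship matrix A and a genomic matrix G into
#' the single-step inverse
#' H^-1 = A^-1 + \[0 0; 0 Gb^-1 - A22^-1\] on the genotyped block, where
#' Gb = w G + (1 - w) A22 is the blended genomic matrix (blending guarantees
#' invertibility; w = 1 disables it).
#'
#' @param A numerator relationship matrix with animal dimnames.
#' @param G genomic relationship matrix for the genotyped subset.
#' @param genotyped_ids IDs (subset of rownames(A)) in the row order of G.
#' @param blend_weight weight w on G in the blend (default 0.95).
#' @return dense H-inverse matrix in the animal order of A.
#' @export
h_inverse <- function(A, G, genotyped_ids = rownames(G), blend_weight = 0.95) {
  ids <- rownames(A)
  if (is.null(ids)) stop("A must carry animal IDs as dimnames")
  if (blend_weight < 0 || blend_weight > 1)
    stop("'blend_weight' must be in [0, 1]")
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("A is numerically singular: ", conditionMessage(e)))
  if (length(genotyped_ids) == 0L) {
    dimnames(Ainv) <- dimnames(A)
    return(Ainv)
  }
  g <- match(genotyped_ids, ids)
  if (anyNA(g)) stop("genotyped IDs absent from A: ",
                     paste(genotyped_ids[is.na(g)], collapse = ", "))
  A22 <- A[g, g, drop = FALSE]
  Gb <- blend_weight * G + (1 - blend_weight) * A22
  Gbinv <- tryCatch(solve(Gb), error = function(e)
    stop("blended genomic block is singular: ", conditionMessage(e)))
  A22inv <- tryCatch(solve(A22), error = function(e)
    stop("A22 block is singular: ", conditionMessage(e)))
  H <- Ainv
  H[g, g] <- H[g, g] + Gbinv - A22inv
  dimnames(H) <- dimnames(A)
  H
}
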