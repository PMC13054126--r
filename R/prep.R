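# Contemporary-group formation and the phenotype / genotype editing rules
# applied before variance-component estimation.

#' Birth season from calendar month
#'
#' Central-Brazil convention: April-September is the dry season,
#' October-March the rainy season.
#'
#' @param month integer month, 1-12 (vectorized).
#' @return character vector, "dry" or "rainy".
#' @export
birth_season <- function(month) {
  if (any(is.na(month)) || any(month < 1 | month > 12 | month != round(month)))
    stop("month must be an integer in 1..12")
  ifelse(month >= 4 & month <= 9, "dry", "rainy")
}

#' Form contemporary-group labels
#'
#' CG = farm | lot | sex | birth year | birth season, with the
#' feed-efficiency test identifier appended for profitability and feed
#' efficiency traits (they are measured inside a specific test).
#'
#' @param table data.frame with columns farm, lot, sex, birth_year,
#'   birth_month (and test_id when `include_test` is TRUE).
#' @param trait trait name (used to decide the default for `include_test`).
#' @param include_test append test_id to the label; defaults to TRUE for
#'   profitability/feed-efficiency traits (afp, pft, dmi, rfi, rg) and FALSE
#'   otherwise.
#' @return character CG labels; rows with missing metadata get NA and a
#'   warning.
#' @export
form_cg <- function(table, trait,
                    include_test = tolower(trait) %in%
                      c("afp", "pft", "dmi", "rfi", "rg")) {
  need <- c("farm", "lot", "sex", "birth_year", "birth_month")
  if (include_test) need <- c(need, "test_id")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "))
  season <- rep(NA_character_, nrow(table))
  okm <- !is.na(table$birth_month)
  season[okm] <- birth_season(table$birth_month[okm])
  parts <- cbind(table$farm, table$lot, table$sex, table$birth_year, season)
  if (include_test) parts <- cbind(parts, table$test_id)
  bad <- apply(parts, 1L, anyNA)
  lab <- apply(parts, 1L, paste, collapse = "|")
  lab[bad] <- NA_character_
  if (any(bad))
    warning(sum(bad), " record(s) with missing metadata flagged (NA label)")
  lab
}

#' Apply phenotype editing rules
#'
#' In order: (1) drop records of animals with unknown sire or dam;
#' (2) drop contemporary groups with fewer than `min_cg` members;
#' (3) drop records outside mean +/- `sd_limit` SD of their CG (mean and SD
#' computed on the CG including the candidate record); (4) re-check CG size
#' once, since the SD filter may have shrunk groups below the minimum.
#' The order is fixed so results are deterministic.
#'
#' @param table data.frame with an animal column and the trait column.
#' @param trait trait column name to edit.
#' @param cg character/factor CG label per row (NA = excluded).
#' @param pedigree optional data.frame animal/sire/dam used for the
#'   known-parent rule; rule skipped when NULL or `require_parents = FALSE`.
#' @param min_cg minimum CG size (default 4).
#' @param sd_limit outlier bound in CG standard deviations (default 3.5).
#' @param require_parents drop records of animals with unknown parents.
#' @return the edited table, with a "qc_report" attribute: named removal
#'   counts (in application order) that reconcile with the row change.
#' @export
apply_edits <- function(table, trait, cg, pedigree = NULL, min_cg = 4,
                        sd_limit = 3.5, require_parents = TRUE) {
  if (!trait %in% names(table)) stop("trait column not found: ", trait)
  if (length(cg) != nrow(table)) stop("cg must label every row")
  keep <- !is.na(table[[trait]]) & !is.na(cg)
  report <- c(missing_value_or_cg = sum(!keep))
  tab <- table[keep, , drop = FALSE]
  cg <- as.character(cg[keep])

  if (require_parents && !is.null(pedigree)) {
    known <- pedigree$animal[pedigree$sire != "0" & pedigree$dam != "0"]
    ok <- tab$animal %in% known
    report <- c(report, unknown_parents = sum(!ok))
    tab <- tab[ok, , drop = FALSE]; cg <- cg[ok]
  } else report <- c(report, unknown_parents = 0L)

  sizes <- table(cg)
  ok <- sizes[cg] >= min_cg
  report <- c(report, small_cg = sum(!ok))
  tab <- tab[ok, , drop = FALSE]; cg <- cg[ok]

  y <- tab[[trait]]
  mu <- ave(y, cg, FUN = mean)
  sdv <- ave(y, cg, FUN = sd)
  ok <- is.na(sdv) | sdv == 0 | abs(y - mu) <= sd_limit * sdv
  report <- c(report, outlier = sum(!ok))
  tab <- tab[ok, , drop = FALSE]; cg <- cg[ok]

  sizes <- table(cg)
  ok <- if (length(cg)) sizes[cg] >= min_cg else logical(0)
  report <- c(report, small_cg_recheck = sum(!ok))
  tab <- tab[ok, , drop = FALSE]; cg <- cg[ok]

  if (nrow(tab) == 0L) warning("all records removed by the edits")
  tab$cg <- cg
  attr(tab, "qc_report") <- report
  tab
}

# exact Hardy-Weinberg test (two-sided, full enumeration of heterozygote
# counts conditional on allele counts)
.hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_a <- 2L * n_aa + n_ab
  rare <- min(n_a, 2L * n - n_a)
  het_range <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(het_range, function(h) {
    hom_r <- (rare - h) %/% 2L
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  sum(p[p <= p[match(n_ab, het_range)] + 1e-12])
}

#' Genotype quality control
#'
#' Sequentially removes: animals then SNPs below the call-rate threshold;
#' monomorphic SNPs and SNPs below the MAF threshold; non-autosomal and
#' duplicate-position SNPs (when a map is given); SNPs failing the exact
#' Hardy-Weinberg test; and SNPs whose parent-offspring opposing-homozygote
#' conflict rate exceeds `mendel`.
#'
#' @param geno animals x SNPs matrix of 0/1/2 (NA = missing), animal row
#'   names, SNP column names.
#' @param pedigree optional data.frame animal/sire/dam for the Mendelian
#'   rule.
#' @param map optional data.frame (snp, chromosome, position); chromosomes
#'   not coercible to a number are treated as non-autosomal.
#' @param call_rate minimum call rate for animals and SNPs (default 0.90).
#' @param maf minimum minor allele frequency (default 0.05).
#' @param mendel maximum opposing-homozygote rate per SNP (default 0.01).
#' @param hwe_alpha Hardy-Weinberg rejection level (default 1e-5).
#' @param animal_first filter animal call rate before SNP call rate.
#' @return filtered genotype matrix with attribute "qc_report" (named
#'   removal counts).
#' @export
genotype_qc <- function(geno, pedigree = NULL, map = NULL,
                        call_rate = 0.90, maf = 0.05, mendel = 0.01,
                        hwe_alpha = 1e-5, animal_first = TRUE) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  if (!all(geno %in% c(0, 1, 2) | is.na(geno)))
    stop("genotypes must be 0/1/2 or NA")
  report <- c()
  drop_animals <- function(g) {
    cr <- rowMeans(!is.na(g))
    keep <- cr >= call_rate
    report <<- c(report, animals_call_rate = sum(!keep))
    g[keep, , drop = FALSE]
  }
  drop_snps_cr <- function(g) {
    cr <- colMeans(!is.na(g))
    keep <- cr >= call_rate
    report <<- c(report, snps_call_rate = sum(!keep))
    g[, keep, drop = FALSE]
  }
  geno <- if (animal_first) drop_snps_cr(drop_animals(geno)) else
    drop_animals(drop_snps_cr(geno))

  p <- colMeans(geno, na.rm = TRUE) / 2
  mono <- p %in% c(0, 1) | !is.finite(p)
  report <- c(report, monomorphic = sum(mono))
  geno <- geno[, !mono, drop = FALSE]; p <- p[!mono]
  low <- pmin(p, 1 - p) < maf
  report <- c(report, low_maf = sum(low))
  geno <- geno[, !low, drop = FALSE]

  if (!is.null(map)) {
    m <- map[match(colnames(geno), map$snp), , drop = FALSE]
    auto <- suppressWarnings(!is.na(as.numeric(as.character(m$chromosome))))
    report <- c(report, non_autosomal = sum(!auto, na.rm = TRUE) + sum(is.na(auto)))
    geno <- geno[, which(auto), drop = FALSE]
    m <- m[which(auto), , drop = FALSE]
    dup <- duplicated(paste(m$chromosome, m$position))
    report <- c(report, duplicate_position = sum(dup))
    geno <- geno[, !dup, drop = FALSE]
  } else report <- c(report, non_autosomal = 0L, duplicate_position = 0L)

  hwe_fail <- vapply(seq_len(ncol(geno)), function(k) {
    g <- geno[, k]; g <- g[!is.na(g)]
    .hwe_exact_p(sum(g == 2), sum(g == 1), sum(g == 0)) < hwe_alpha
  }, logical(1))
  report <- c(report, hwe = sum(hwe_fail))
  geno <- geno[, !hwe_fail, drop = FALSE]

  if (!is.null(pedigree)) {
    po <- rbind(
      data.frame(off = pedigree$animal, par = pedigree$sire),
      data.frame(off = pedigree$animal, par = pedigree$dam))
    po <- po[po$par != "0" & po$off %in% rownames(geno) &
               po$par %in% rownames(geno), , drop = FALSE]
    if (nrow(po)) {
      go <- geno[po$off, , drop = FALSE]
      gp <- geno[po$par, , drop = FALSE]
      opp <- (go == 0 & gp == 2) | (go == 2 & gp == 0)
      informative <- !is.na(go) & !is.na(gp)
      rate <- colSums(opp, na.rm = TRUE) / pmax(colSums(informative), 1L)
      bad <- rate > mendel
      report <- c(report, mendel_conflict = sum(bad))
      geno <- geno[, !bad, drop = FALSE]
    } else report <- c(report, mendel_conflict = 0L)
  } else report <- c(report, mendel_conflict = 0L)

  if (ncol(geno) == 0L)
    stop("no SNPs survived QC; report: ",
         paste(names(report), report, sep = "=", collapse = ", "))
  attr(geno, "qc_report") <- report
  geno
}
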