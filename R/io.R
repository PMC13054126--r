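# Plain-text readers/writers for the pipeline's file dialects. All files are
# UTF-8 with "." as decimal separator; unknown parents are written "0",
# missing values "NA".

#' Read / write a pedigree file
#'
#' Three-column CSV: animal,sire,dam with "0" for unknown parents.
#'
#' @param path file path.
#' @return `read_pedigree`: data.frame animal/sire/dam (character).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  names(ped)[1:3] <- c("animal", "sire", "dam")
  .validate_pedigree(ped)
  ped
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped[, c("animal", "sire", "dam")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a genotype matrix
#'
#' TSV with the animal ID in the first column and one 0/1/2/NA column per
#' SNP.
#'
#' @param path file path.
#' @return `read_genotypes`: animals x SNPs numeric matrix with animal row
#'   names.
#' @export
read_genotypes <- function(path) {
  d <- read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_genotypes
#' @param geno genotype matrix with animal row names.
#' @export
write_genotypes <- function(geno, path) {
  d <- data.frame(animal = rownames(geno), geno, check.names = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a trait table
#'
#' TSV with header trait names and "NA" for missing values.
#'
#' @param path file path.
#' @export
read_trait_table <- function(path) {
  read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
             stringsAsFactors = FALSE)
}

#' @rdname read_trait_table
#' @param table trait table data.frame.
#' @export
write_trait_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a feedlot log
#'
#' TSV with columns animal, day, weight_kg, dmi_kg.
#'
#' @param path file path.
#' @export
read_feedlot_log <- function(path) {
  log <- read.delim(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  need <- c("animal", "day", "weight_kg", "dmi_kg")
  if (!all(need %in% names(log)))
    stop("feedlot log needs columns: ", paste(need, collapse = ", "))
  log
}

#' @rdname read_feedlot_log
#' @param log feedlot log data.frame.
#' @export
write_feedlot_log <- function(log, path) {
  write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a flat key-value economic configuration file
#'
#' Lines of the form `key = value` (or `key: value`), keys matching the
#' [econ_config()] arguments; missing keys keep their defaults.
#'
#' @param path file path.
#' @return an [econ_config()].
#' @export
read_econ_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) < 2) next
    key <- trimws(p[1]); val <- as.numeric(trimws(paste(p[-1], collapse = "")))
    args[[key]] <- val
  }
  known <- names(formals(econ_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    warning("ignoring unknown economic keys: ", paste(unknown, collapse = ", "))
  do.call(econ_config, args[intersect(names(args), known)])
}
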