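# File formats.
#
# PED/MAP (PLINK text): whitespace-delimited; PED columns are
#   family/line id, sample id, paternal id, maternal id, sex (1=M, 2=F,
#   0=unknown), phenotype, then two allele columns per locus ("0" = missing).
# MAP columns: chromosome, locus id, genetic distance, bp position.
#
# TSV dialect: <prefix>.geno.tsv has a header row (sample_id, line, sex, then
# one column per locus) and calls as two-character strings ("NN" = missing);
# <prefix>.loci.tsv carries locus_id, chromosome, position_bp, assembly,
# alt_chromosome.
#
# Allele labels already in the canonical alphabet {A, B} are kept as-is;
# any other labels (e.g. nucleotides) are normalised to {A, B} in
# first-observed order per locus. A locus with more than two distinct
# alleles is an error.

.normalise_locus <- function(a1, a2, locus_id) {
  miss <- is.na(a1) | is.na(a2) | a1 == "0" | a2 == "0"
  obs <- unique(as.vector(rbind(a1[!miss], a2[!miss])))
  if (length(obs) > 2)
    stop(sprintf("locus %s has %d distinct alleles (%s); loci must be biallelic",
                 locus_id, length(obs), paste(obs, collapse = ",")))
  code <- rep(.CALL_MISSING, length(a1))
  if (length(obs) == 0) return(code)
  if (all(obs %in% c("A", "B"))) {
    lab <- c(A = "A", B = "B")
  } else {
    lab <- stats::setNames(c("A", "B")[seq_along(obs)], obs)
  }
  nA <- (lab[a1] == "A") + (lab[a2] == "A")
  code[!miss] <- (3L - as.integer(nA))[!miss]
  code
}

.drop_y <- function(loci) {
  y <- loci$chromosome %in% c("Y", "y")
  if (any(y))
    warning(sprintf("dropping %d Y-chromosome locus/loci (sex-mismatch loci are excluded from the analysis)",
                    sum(y)))
  y
}

#' Read a genotype matrix from disk
#'
#' Reads either a PLINK-style PED/MAP pair (`<path>.ped` + `<path>.map`) or
#' the package's TSV dialect (`<path>.geno.tsv` + `<path>.loci.tsv`).
#' Per-locus allele labels are normalised to \{A, B\} (see file-format notes
#' in the source); Y-chromosome loci are dropped with a warning.
#'
#' @param path file path prefix (no extension).
#' @param dialect `"ped_map"` or `"tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("ped_map", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") .read_ped_map(path) else .read_geno_tsv(path)
}

.read_ped_map <- function(prefix) {
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  if (!file.exists(ped_file)) stop("no such file: ", ped_file)
  if (!file.exists(map_file)) stop("no such file: ", map_file)
  map <- utils::read.table(map_file, header = FALSE, colClasses = "character",
                           col.names = c("chromosome", "locus_id", "cm", "position_bp"))
  ped <- utils::read.table(ped_file, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop(sprintf("PED/MAP dimension mismatch: %s has %d loci so %s needs %d columns, found %d",
                 basename(map_file), m, basename(ped_file), 6 + 2 * m, ncol(ped)))
  loci <- data.frame(locus_id = map$locus_id,
                     chromosome = map$chromosome,
                     position_bp = as.integer(map$position_bp),
                     assembly = NA_character_,
                     alt_chromosome = NA_character_,
                     stringsAsFactors = FALSE)
  sex <- c("1" = "M", "2" = "F")[ped[[5]]]
  samples <- data.frame(sample_id = ped[[2]], line = ped[[1]],
                        sex = unname(sex), stringsAsFactors = FALSE)
  calls <- matrix(.CALL_MISSING, nrow(ped), m)
  for (j in seq_len(m)) {
    calls[, j] <- .normalise_locus(ped[[5 + 2 * j]], ped[[6 + 2 * j]],
                                   loci$locus_id[j])
  }
  y <- .drop_y(loci)
  genotype_matrix(calls[, !y, drop = FALSE], samples, loci[!y, , drop = FALSE])
}

.read_geno_tsv <- function(prefix) {
  geno_file <- paste0(prefix, ".geno.tsv")
  loci_file <- paste0(prefix, ".loci.tsv")
  if (!file.exists(geno_file)) stop("no such file: ", geno_file)
  if (!file.exists(loci_file)) stop("no such file: ", loci_file)
  loci <- utils::read.table(loci_file, header = TRUE, sep = "\t",
                            colClasses = "character", na.strings = "NA")
  loci$position_bp <- as.integer(loci$position_bp)
  geno <- utils::read.table(geno_file, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
  locus_cols <- setdiff(names(geno), c("sample_id", "line", "sex"))
  if (!identical(locus_cols, loci$locus_id))
    stop(sprintf("genotype columns do not match the locus file (%d vs %d loci)",
                 length(locus_cols), nrow(loci)))
  m <- nrow(loci)
  calls <- matrix(.CALL_MISSING, nrow(geno), m)
  for (j in seq_len(m)) {
    s <- geno[[loci$locus_id[j]]]
    s[s == "NN"] <- NA_character_
    calls[, j] <- .normalise_locus(substr(s, 1, 1), substr(s, 2, 2),
                                   loci$locus_id[j])
  }
  samples <- data.frame(sample_id = geno$sample_id, line = geno$line,
                        sex = if ("sex" %in% names(geno)) geno$sex else NA_character_,
                        stringsAsFactors = FALSE)
  samples$sex[samples$sex %in% c("", "NA")] <- NA_character_
  y <- .drop_y(loci)
  genotype_matrix(calls[, !y, drop = FALSE], samples, loci[!y, , drop = FALSE])
}

#' Write a genotype matrix to disk
#'
#' Counterpart of [read_genotypes()]. Alleles are written as literal
#' `A`/`B` so that a write/read round trip reproduces the matrix exactly.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path prefix (no extension).
#' @param dialect `"ped_map"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, dialect = c("ped_map", "tsv")) {
  dialect <- match.arg(dialect)
  gm <- genotypes
  if (dialect == "ped_map") {
    a1 <- c("0", "A", "A", "B")[gm$calls + 1L]
    a2 <- c("0", "A", "B", "B")[gm$calls + 1L]
    dim(a1) <- dim(a2) <- dim(gm$calls)
    allele_cols <- matrix("", nrow(gm$calls), 2L * ncol(gm$calls))
    allele_cols[, seq(1, by = 2, length.out = ncol(gm$calls))] <- a1
    allele_cols[, seq(2, by = 2, length.out = ncol(gm$calls))] <- a2
    sexcode <- c(M = "1", F = "2")[gm$samples$sex]
    sexcode[is.na(sexcode)] <- "0"
    ped <- cbind(gm$samples$line, gm$samples$sample_id, "0", "0",
                 unname(sexcode), "-9", allele_cols)
    utils::write.table(ped, paste0(path, ".ped"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    map <- cbind(gm$loci$chromosome, gm$loci$locus_id, "0",
                 as.character(gm$loci$position_bp))
    utils::write.table(map, paste0(path, ".map"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    strs <- calls_to_strings(gm$calls)
    geno <- data.frame(sample_id = gm$samples$sample_id,
                       line = gm$samples$line, sex = gm$samples$sex,
                       strs, check.names = FALSE, stringsAsFactors = FALSE)
    names(geno) <- c("sample_id", "line", "sex", gm$loci$locus_id)
    utils::write.table(geno, paste0(path, ".geno.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    utils::write.table(gm$loci[, c("locus_id", "chromosome", "position_bp",
                                   "assembly", "alt_chromosome")],
                       paste0(path, ".loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a transplant-pair table
#'
#' Reads a TSV with header columns `donor_id`, `recipient_id`, `outcome`
#' (`accepted`/`rejected`, case-insensitive) and validates every id against
#' the genotype matrix. An empty table (header only) is a valid empty cohort.
#'
#' @param path TSV file path.
#' @param genotypes a [genotype_matrix()] the ids must resolve into.
#' @return a [transplant_cohort()].
#' @export
read_pairs <- function(path, genotypes) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("donor_id", "recipient_id", "outcome")
  if (!all(need %in% names(tab)))
    stop("pair table must have columns donor_id, recipient_id, outcome")
  transplant_cohort(tab[, need], genotypes)
}

#' Load the packaged significant-SNP table
#'
#' The 61 SNP loci reported genome-wide significant in the porcine corneal
#' graft mismatch scan, shipped as a plain-text fixture: 57 loci where a
#' donor-recipient mismatch associated with rejection and 4 with acceptance,
#' flagged per rejection model (directional model 1, symmetric model 2).
#' `position_bp == 0` marks an unknown position; chromosome `"0"` an unknown
#' chromosome; `alt_chromosome` a different chromosome assignment under the
#' earlier genome assembly.
#'
#' @return data frame of class `significant_snp_table` with columns
#'   `chromosome`, `position_bp`, `position_alt_bp`, `model1`, `model2`,
#'   `direction`, `alt_chromosome`, `unknown_location`.
#' @export
load_significant_snps <- function() {
  path <- system.file("extdata", "significant_snps.tsv",
                      package = "minormatch", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", colClasses = "character",
                           na.strings = "NA")
  tab$position_bp <- as.integer(tab$position_bp)
  tab$position_alt_bp <- as.integer(tab$position_alt_bp)
  tab$model1 <- tab$model1 == "1"
  tab$model2 <- tab$model2 == "1"
  tab$unknown_location <- tab$position_bp == 0L
  stopifnot(all(tab$model1 | tab$model2),
            all(tab$direction %in% c("rejection", "acceptance")))
  class(tab) <- c("significant_snp_table", "data.frame")
  tab
}
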