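# Genotype calls are stored as integer codes throughout the package:
#   0 = missing, 1 = AA, 2 = AB, 3 = BB.
# Alleles are abstracted to the biallelic alphabet {A, B}: the analysis only
# ever needs allele identity/difference, never the nucleotide.

.CALL_MISSING <- 0L
.CALL_AA <- 1L
.CALL_AB <- 2L
.CALL_BB <- 3L

# Canonical chromosome display order: autosomes, X, then "0" (unknown).
.CHROM_ORDER <- c(as.character(1:18), "X", "0")

.chrom_rank <- function(chrom) {
  r <- match(chrom, .CHROM_ORDER)
  # labels outside the canonical set sort after it, alphabetically
  r[is.na(r)] <- length(.CHROM_ORDER) + xtfrm(chrom[is.na(r)])
  r
}

#' Construct a genotype matrix
#'
#' Bundles a samples-by-loci grid of biallelic genotype calls with its sample
#' table (ids, line membership, sex) and locus map (chromosome, base-pair
#' position, assembly). Calls are unordered allele pairs over \{A, B\}:
#' `"AA"`, `"AB"`, `"BB"` or `NA` (missing). Chromosome `"0"` and position 0
#' are the sentinels for unknown location.
#'
#' @param calls samples x loci matrix of calls, either character
#'   (`"AA"`/`"AB"`/`"BB"`/`NA`/`"NN"`) or the internal integer codes 0:3.
#' @param samples data frame with columns `sample_id` (unique), `line`, and
#'   optionally `sex` (`"M"`/`"F"`/`NA`).
#' @param loci data frame with columns `locus_id` (unique), `chromosome`
#'   (character; `"1"`..`"18"`, `"X"`, `"0"` = unknown), `position_bp`
#'   (non-negative integer, 0 = unknown), and optionally `assembly`,
#'   `alt_chromosome`.
#' @return An object of class `genotype_matrix` with elements `calls`
#'   (integer matrix), `samples` and `loci`.
#' @export
genotype_matrix <- function(calls, samples, loci) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(is.matrix(calls), !is.null(samples$sample_id), !is.null(samples$line),
            !is.null(loci$locus_id), !is.null(loci$chromosome),
            !is.null(loci$position_bp))
  if (is.character(calls)) calls <- calls_from_strings(calls)
  storage.mode(calls) <- "integer"
  if (anyNA(calls)) calls[is.na(calls)] <- .CALL_MISSING
  if (!all(calls %in% 0:3))
    stop("genotype calls must be codes 0:3 or strings AA/AB/BB/NN")
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(loci))
    stop(sprintf("call grid is %d x %d but there are %d samples and %d loci",
                 nrow(calls), ncol(calls), nrow(samples), nrow(loci)))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (anyDuplicated(loci$locus_id))
    stop("duplicate locus_id in locus map")
  loci$chromosome <- as.character(loci$chromosome)
  loci$position_bp <- as.integer(loci$position_bp)
  if (any(loci$position_bp < 0)) stop("position_bp must be non-negative")
  if (is.null(samples$sex)) samples$sex <- NA_character_
  if (is.null(loci$assembly)) loci$assembly <- NA_character_
  if (is.null(loci$alt_chromosome)) loci$alt_chromosome <- NA_character_
  dimnames(calls) <- list(samples$sample_id, loci$locus_id)
  structure(list(calls = calls, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  tab <- table(x$samples$line)
  cat("  lines:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                        collapse = ", "), "\n")
  miss <- mean(x$calls == .CALL_MISSING)
  cat(sprintf("  chromosomes: %s\n  missing calls: %.2f%%\n",
              paste(unique(x$loci$chromosome), collapse = " "), 100 * miss))
  invisible(x)
}

#' Convert genotype call strings to integer codes
#'
#' `"AA"` -> 1, `"AB"`/`"BA"` -> 2, `"BB"` -> 3, `"NN"`/`NA` -> 0.
#' Shape and dimnames are preserved.
#'
#' @param x character vector or matrix of two-letter calls over \{A, B\}.
#' @return integer vector or matrix of call codes.
#' @export
calls_from_strings <- function(x) {
  map <- c(AA = .CALL_AA, AB = .CALL_AB, BA = .CALL_AB, BB = .CALL_BB,
           NN = .CALL_MISSING)
  out <- unname(map[as.character(x)])
  out[is.na(out)] <- .CALL_MISSING
  if (is.matrix(x)) {
    dim(out) <- dim(x)
    dimnames(out) <- dimnames(x)
  }
  out
}

#' Convert integer call codes to strings
#'
#' Inverse of [calls_from_strings()]; missing becomes `"NN"`.
#' @param x integer vector or matrix of call codes 0:3.
#' @return character vector or matrix.
#' @export
calls_to_strings <- function(x) {
  out <- c("NN", "AA", "AB", "BB")[as.integer(x) + 1L]
  if (is.matrix(x)) {
    dim(out) <- dim(x)
    dimnames(out) <- dimnames(x)
  }
  out
}

#' Construct a transplant cohort
#'
#' A table of donor-to-recipient grafts with a binary outcome. Each recipient
#' appears at most once (one graft per recipient); donors may repeat (one
#' animal can donate more than one graft). Both ids must resolve in the
#' accompanying genotype matrix when one is supplied.
#'
#' @param pairs data frame with columns `donor_id`, `recipient_id`,
#'   `outcome` (`"accepted"`/`"rejected"`, case-insensitive).
#' @param genotypes optional [genotype_matrix()] used to validate ids.
#' @return data frame of class `transplant_cohort`.
#' @export
transplant_cohort <- function(pairs, genotypes = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("donor_id", "recipient_id", "outcome") %in% names(pairs)))
  pairs$outcome <- tolower(trimws(as.character(pairs$outcome)))
  bad <- setdiff(unique(pairs$outcome), c("accepted", "rejected"))
  if (length(bad))
    stop("unknown outcome token(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(pairs$recipient_id))
    stop("duplicate recipient_id: ",
         paste(unique(pairs$recipient_id[duplicated(pairs$recipient_id)]),
               collapse = ", "))
  if (!is.null(genotypes)) {
    ids <- genotypes$samples$sample_id
    miss <- setdiff(unique(c(pairs$donor_id, pairs$recipient_id)), ids)
    if (length(miss))
      stop("pair table names sample id(s) absent from the genotype matrix: ",
           paste(miss, collapse = ", "))
  }
  class(pairs) <- c("transplant_cohort", "data.frame")
  pairs
}
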