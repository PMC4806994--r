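# Within-line homozygosity profiling.
#
# A SNP is "fixed" (invariant) within a line iff every non-missing call in
# that line is the same homozygote; a line where all animals are AB carries
# both alleles and counts as segregating. Fixation, MAF and heterozygosity
# are judged on non-missing calls only; a SNP with no non-missing call in a
# line is excluded from that line's denominators.

.per_locus_counts <- function(calls) {
  nAA <- colSums(calls == .CALL_AA)
  nAB <- colSums(calls == .CALL_AB)
  nBB <- colSums(calls == .CALL_BB)
  n <- nAA + nAB + nBB
  freqA <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)
  list(nAA = nAA, nAB = nAB, nBB = nBB, n = n,
       used = n > 0,
       fixed = n > 0 & (nAA == n | nBB == n),
       freqA = freqA,
       maf = pmin(freqA, 1 - freqA),
       het = ifelse(n > 0, nAB / n, NA_real_))
}

.stats_row <- function(line, chromosome, cc, idx) {
  used <- cc$used[idx]
  seg <- cc$used[idx] & !cc$fixed[idx]
  n_used <- sum(used)
  data.frame(
    line = line, chromosome = chromosome,
    n_snps = length(idx), n_used = n_used,
    prop_fixed = if (n_used > 0) sum(cc$fixed[idx]) / n_used else NA_real_,
    n_segregating = sum(seg),
    mean_maf = if (sum(seg) > 0) mean(cc$maf[idx][seg]) else NA_real_,
    mean_het = if (sum(seg) > 0) mean(cc$het[idx][seg]) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Per-line homozygosity, MAF and heterozygosity summaries
#'
#' For each line: the proportion of SNPs fixed (monomorphic) within the line,
#' the mean minor allele frequency over SNPs still segregating in the line,
#' and the mean proportion of heterozygous animals over segregating SNPs.
#' With `by = "chromosome"` one row per chromosome per line (unknown-position
#' SNPs as their own pseudo-chromosome `"Unknown"`) plus a genome-total row
#' `"Total"`; with `by = "genome"` only the total row.
#'
#' @param genotypes a [genotype_matrix()].
#' @param by `"chromosome"` or `"genome"`.
#' @param lines lines to summarise (default all).
#' @return data frame of class `homozygosity_stats` with columns `line`,
#'   `chromosome`, `n_snps`, `n_used`, `prop_fixed`, `n_segregating`,
#'   `mean_maf`, `mean_het`. `mean_maf`/`mean_het` are `NA` when a group has
#'   no segregating SNP.
#' @export
line_stats <- function(genotypes, by = c("chromosome", "genome"), lines = NULL) {
  by <- match.arg(by)
  if (is.null(lines)) lines <- unique(genotypes$samples$line)
  chrom <- genotypes$loci$chromosome
  chrom_lab <- ifelse(chrom == "0", "Unknown", chrom)
  out <- list()
  for (ln in lines) {
    in_line <- genotypes$samples$line == ln
    if (!any(in_line)) stop("no samples in line ", ln)
    cc <- .per_locus_counts(genotypes$calls[in_line, , drop = FALSE])
    if (by == "chromosome") {
      labs <- unique(chrom_lab[order(.chrom_rank(chrom))])
      for (ch in labs)
        out[[length(out) + 1L]] <- .stats_row(ln, ch, cc, which(chrom_lab == ch))
    }
    out[[length(out) + 1L]] <- .stats_row(ln, "Total", cc,
                                          seq_along(chrom_lab))
  }
  res <- do.call(rbind, out)
  class(res) <- c("homozygosity_stats", "data.frame")
  res
}

#' Fraction of SNPs jointly fixed across lines
#'
#' The fraction of SNPs fixed for the same homozygote in every named line —
#' always at most the smallest within-line fixation proportion, and lower
#' when lines have drifted to different alleles. The denominator is SNPs
#' with at least one non-missing call in every line.
#'
#' @param genotypes a [genotype_matrix()].
#' @param lines character vector of at least two line labels (default all).
#' @return a single fraction in \[0, 1\].
#' @export
cross_line_fixed <- function(genotypes, lines = NULL) {
  if (is.null(lines)) lines <- unique(genotypes$samples$line)
  if (length(lines) < 2) stop("cross_line_fixed needs at least two lines")
  fixed_all <- rep(TRUE, ncol(genotypes$calls))
  used_all <- rep(TRUE, ncol(genotypes$calls))
  allele <- NULL
  same <- rep(TRUE, ncol(genotypes$calls))
  for (ln in lines) {
    in_line <- genotypes$samples$line == ln
    if (!any(in_line)) stop("no samples in line ", ln)
    cc <- .per_locus_counts(genotypes$calls[in_line, , drop = FALSE])
    used_all <- used_all & cc$used
    fixed_all <- fixed_all & cc$fixed
    this_allele <- ifelse(cc$nAA == cc$n, "A", "B")   # only read where fixed
    if (is.null(allele)) allele <- this_allele
    else same <- same & (allele == this_allele)
  }
  ok <- used_all
  if (!any(ok)) return(NA_real_)
  sum(fixed_all[ok] & same[ok]) / sum(ok)
}

#' Per-animal genotype-category map of one chromosome
#'
#' Classifies every animal at every locus of a chromosome as homozygous for
#' the within-line major allele, heterozygous, homozygous for the minor
#' allele, or unknown (missing call). "Major" is the more frequent allele
#' within the animal's own line (ties broken toward allele A), so the same
#' genotype can be major-homozygous in one line and minor-homozygous in
#' another. Loci are ordered by ascending position.
#'
#' @param genotypes a [genotype_matrix()].
#' @param chromosome chromosome label present in the locus map.
#' @return object of class `homozygosity_map`: list with `samples`, `loci`
#'   (position-ordered) and `categories`, a samples x loci character matrix
#'   over \{`major_hom`, `het`, `minor_hom`, `unknown`\}.
#' @export
homozygosity_map <- function(genotypes, chromosome) {
  sel <- which(genotypes$loci$chromosome == as.character(chromosome))
  if (!length(sel)) stop("no loci on chromosome ", chromosome)
  sel <- sel[order(genotypes$loci$position_bp[sel])]
  loci <- genotypes$loci[sel, , drop = FALSE]
  calls <- genotypes$calls[, sel, drop = FALSE]
  cats <- matrix("unknown", nrow(calls), ncol(calls),
                 dimnames = dimnames(calls))
  for (ln in unique(genotypes$samples$line)) {
    in_line <- genotypes$samples$line == ln
    cc <- .per_locus_counts(calls[in_line, , drop = FALSE])
    major_is_A <- is.na(cc$freqA) | cc$freqA >= 0.5   # tie -> A major
    major_hom <- ifelse(major_is_A, .CALL_AA, .CALL_BB)
    minor_hom <- ifelse(major_is_A, .CALL_BB, .CALL_AA)
    sub <- calls[in_line, , drop = FALSE]
    lab <- matrix("unknown", nrow(sub), ncol(sub))
    lab[sub == .CALL_AB] <- "het"
    lab[sub == rep(major_hom, each = nrow(sub))] <- "major_hom"
    lab[sub == rep(minor_hom, each = nrow(sub))] <- "minor_hom"
    cats[in_line, ] <- lab
  }
  structure(list(samples = genotypes$samples, loci = loci, categories = cats),
            class = "homozygosity_map")
}

#' Write a homozygosity map as TSV
#'
#' One row per animal (`sample_id`, `line`, then one category column per
#' locus in map order).
#'
#' @param map a [homozygosity_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_homozygosity_map <- function(map, path) {
  out <- data.frame(sample_id = map$samples$sample_id,
                    line = map$samples$line,
                    map$categories, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "line", map$loci$locus_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.homozygosity_map <- function(x, ...) {
  lev <- c("major_hom", "het", "minor_hom", "unknown")
  z <- matrix(match(x$categories, lev), nrow(x$categories))
  ord <- order(x$samples$line)
  graphics::image(t(z[ord, , drop = FALSE]),
                  col = c("#d73027", "#fee090", "#4575b4", "white"),
                  axes = FALSE, ...)
  graphics::box()
  invisible(x)
}
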