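# Grouping of genome-wide significant SNPs into genomic blocks.
#
# Within each (model, direction, chromosome) group, positioned SNPs sorted
# by base pair are split wherever consecutive positions are more than
# `gap_bp` apart. Rows carrying an alternative-assembly chromosome
# assignment are moved to that chromosome first, and their printed position
# (a coordinate on a different assembly) is treated as unknown for grouping
# and span purposes. Unknown-position rows on a chromosome are attached to
# that chromosome's block when exactly one block exists there (for that
# model/direction); with several blocks they stay unassigned; with none
# they form a single position-less block. Rows with unknown chromosome
# ("0") each form a singleton unplaced block. Spans use positioned members
# only.

.sig_long <- function(tab) {
  stopifnot(all(c("model1", "model2") %in% names(tab)))
  pieces <- lapply(c("model1", "model2"), function(m) {
    sel <- tab[[m]]
    data.frame(chromosome = tab$chromosome[sel],
               position_bp = tab$position_bp[sel],
               model = m,
               direction = tab$direction[sel],
               alt_chromosome = tab$alt_chromosome[sel],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Group significant SNPs into genomic blocks
#'
#' @param x either a long data frame with columns `chromosome`,
#'   `position_bp`, `model`, `direction` (and optionally `alt_chromosome`),
#'   or a [load_significant_snps()] table (wide `model1`/`model2` flags),
#'   which is expanded so a SNP significant under both models appears once
#'   per model.
#' @param gap_bp maximum base-pair gap between consecutive positioned
#'   members of one block (default 5 Mb).
#' @return object of class `snp_blocks`: list with `blocks` (one row per
#'   block: `block_id`, `model`, `direction`, `chromosome`, `n_snps`,
#'   `n_positioned`, `start_bp`, `end_bp`, `span_bp`, `span_mbp`) and
#'   `members` (one row per input SNP-model record with its assigned
#'   `block_id`, `NA` when unassignable).
#' @export
find_blocks <- function(x, gap_bp = 5e6) {
  stopifnot(gap_bp > 0)
  long <- if (!is.null(x$model1)) .sig_long(x) else as.data.frame(x)
  stopifnot(all(c("chromosome", "position_bp", "model", "direction")
                %in% names(long)))
  if (is.null(long$alt_chromosome)) long$alt_chromosome <- NA_character_
  long$chrom_assigned <- ifelse(is.na(long$alt_chromosome),
                                long$chromosome, long$alt_chromosome)
  long$pos_known <- long$position_bp > 0L & is.na(long$alt_chromosome)
  long$block_id <- NA_character_
  blocks <- list()
  add_block <- function(id, model, dir, chrom, idx) {
    pos <- long$position_bp[idx][long$pos_known[idx]]
    n_pos <- length(pos)
    span <- if (n_pos >= 2) max(pos) - min(pos) else NA_integer_
    blocks[[length(blocks) + 1L]] <<- data.frame(
      block_id = id, model = model, direction = dir, chromosome = chrom,
      n_snps = length(idx), n_positioned = n_pos,
      start_bp = if (n_pos) min(pos) else NA_integer_,
      end_bp = if (n_pos) max(pos) else NA_integer_,
      span_bp = span,
      span_mbp = if (n_pos >= 2) round(span / 1e6, 1) else NA_real_,
      stringsAsFactors = FALSE)
    long$block_id[idx] <<- id
  }
  for (model in unique(long$model)) {
    for (dir in unique(long$direction[long$model == model])) {
      grp <- long$model == model & long$direction == dir
      # unknown chromosome: singleton unplaced blocks
      for (i in which(grp & long$chrom_assigned == "0"))
        add_block(sprintf("%s_%s_unplaced%d", model, dir, i),
                  model, dir, "0", i)
      for (chrom in unique(long$chrom_assigned[grp & long$chrom_assigned != "0"])) {
        idx <- which(grp & long$chrom_assigned == chrom)
        pos_idx <- idx[long$pos_known[idx]]
        unk_idx <- idx[!long$pos_known[idx]]
        pos_idx <- pos_idx[order(long$position_bp[pos_idx])]
        if (length(pos_idx)) {
          gaps <- diff(long$position_bp[pos_idx])
          grp_no <- cumsum(c(1L, as.integer(gaps > gap_bp)))
          n_blocks <- max(grp_no)
          for (b in seq_len(n_blocks)) {
            members <- pos_idx[grp_no == b]
            if (n_blocks == 1L) members <- c(members, unk_idx)
            add_block(sprintf("%s_%s_chr%s_b%d", model, dir, chrom, b),
                      model, dir, chrom, members)
          }
        } else if (length(unk_idx)) {
          # no positioned member on this chromosome: one position-less block
          add_block(sprintf("%s_%s_chr%s_b1", model, dir, chrom),
                    model, dir, chrom, unk_idx)
        }
      }
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(), model = character(),
               direction = character(), chromosome = character(),
               n_snps = integer(), n_positioned = integer(),
               start_bp = integer(), end_bp = integer(),
               span_bp = integer(), span_mbp = numeric())
  structure(list(blocks = blocks, members = long, gap_bp = gap_bp),
            class = "snp_blocks")
}

#' @export
print.snp_blocks <- function(x, ...) {
  cat(sprintf("snp_blocks: %d blocks from %d SNP-model records (gap %g bp)\n",
              nrow(x$blocks), nrow(x$members), x$gap_bp))
  print(x$blocks[, c("block_id", "n_snps", "span_mbp")], row.names = FALSE)
  invisible(x)
}

#' Block spans in megabases
#'
#' Span = (max - min) over positioned members, reported in Mbp rounded to
#' one decimal; `NA` for blocks with fewer than two positioned members.
#'
#' @param blocks a [find_blocks()] result.
#' @return named numeric vector of spans (Mbp) by `block_id`.
#' @export
block_span <- function(blocks) {
  stats::setNames(blocks$blocks$span_mbp, blocks$blocks$block_id)
}

#' Outcome-group distribution at a locus
#'
#' Counts of donor-recipient pairs in the four outcome groups
#' (matched-accepted, matched-rejected, mismatched-accepted,
#' mismatched-rejected) at one or more loci, over pairs with known status,
#' plus the predictive accuracy (matched-accepted + mismatched-rejected) /
#' total — the fraction of grafts whose fate a pre-transplant typing at that
#' locus would have called correctly.
#'
#' @param match a [build_match_matrix()] result.
#' @param cohort optional [transplant_cohort()] (defaults to the match
#'   matrix's pairs).
#' @param locus_id one or more locus ids present in the match matrix.
#' @return data frame with one row per locus: the four counts, `n_known`,
#'   `accuracy`.
#' @export
outcome_groups <- function(match, cohort = NULL, locus_id) {
  pairs <- if (is.null(cohort)) match$pairs else as.data.frame(cohort)
  li <- match(locus_id, match$loci$locus_id)
  if (anyNA(li))
    stop("unknown locus id(s): ",
         paste(locus_id[is.na(li)], collapse = ", "))
  rej <- pairs$outcome == "rejected"
  out <- lapply(seq_along(li), function(k) {
    st <- match$status[li[k], ]
    known <- !is.na(st)
    ma <- sum(known & st == 1L & !rej); mr <- sum(known & st == 1L & rej)
    xa <- sum(known & st == 2L & !rej); xr <- sum(known & st == 2L & rej)
    n <- ma + mr + xa + xr
    data.frame(locus_id = locus_id[k],
               matched_accepted = ma, matched_rejected = mr,
               mismatched_accepted = xa, mismatched_rejected = xr,
               n_known = n,
               accuracy = if (n > 0) (ma + xr) / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
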