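# Donor-recipient mismatch coding.
#
# Model 1 (directional, host-versus-graft): a pair is mismatched iff the
# donor (graft) carries at least one allele absent from the recipient —
# AB into AA/BB is mismatched, AA/BB into AB is matched; graft-versus-host
# direction is irrelevant. Model 2 (symmetric): any difference between the
# unordered genotypes is a mismatch. A missing call on either side makes
# the status unknown.

# status lookup indexed [donor code + 1, recipient code + 1];
# 1 = matched, 2 = mismatched, NA = unknown
.M1 <- matrix(c(NA, NA, NA, NA,
                NA, 1L, 1L, 2L,    # donor AA
                NA, 2L, 1L, 2L,    # donor AB
                NA, 2L, 1L, 1L),   # donor BB
              nrow = 4, byrow = TRUE)
.M2 <- matrix(c(NA, NA, NA, NA,
                NA, 1L, 2L, 2L,
                NA, 2L, 1L, 2L,
                NA, 2L, 2L, 1L),
              nrow = 4, byrow = TRUE)

.STATUS_LEVELS <- c("matched", "mismatched")

.code_pair_int <- function(donor, recipient, model) {
  M <- if (model == "model1") .M1 else .M2
  M[cbind(as.vector(donor) + 1L, as.vector(recipient) + 1L)]
}

#' Classify one donor-recipient genotype pair
#'
#' @param donor,recipient genotype calls (`"AA"`/`"AB"`/`"BB"`/`NA`/`"NN"`),
#'   vectorised.
#' @param model `"model1"` (directional) or `"model2"` (symmetric).
#' @return character vector over \{`matched`, `mismatched`, `unknown`\}.
#' @examples
#' code_pair("AB", "AA", "model1")  # mismatched: graft carries B, host lacks it
#' code_pair("AA", "AB", "model1")  # matched: host already carries A
#' code_pair("AA", "AB", "model2")  # mismatched: genotypes differ
#' @export
code_pair <- function(donor, recipient, model = c("model1", "model2")) {
  model <- match.arg(model)
  st <- .code_pair_int(calls_from_strings(donor), calls_from_strings(recipient),
                       model)
  out <- .STATUS_LEVELS[st]
  out[is.na(out)] <- "unknown"
  out
}

#' Build the pair-by-locus match matrix
#'
#' Applies the mismatch coding of [code_pair()] over every pair and locus and
#' flags each locus as testable. A locus is testable iff both matched and
#' mismatched statuses occur among pairs with known status — otherwise the
#' association test is identically zero.
#'
#' @param genotypes a [genotype_matrix()].
#' @param cohort a [transplant_cohort()]; must be non-empty.
#' @param model `"model1"` or `"model2"`.
#' @return object of class `match_matrix`: list with `model`, `status`
#'   (loci x pairs integer matrix, 1 = matched, 2 = mismatched,
#'   `NA` = unknown), `testable` (per-locus logical), `loci`, `pairs`
#'   (cohort rows, including outcome).
#' @export
build_match_matrix <- function(genotypes, cohort,
                               model = c("model1", "model2")) {
  model <- match.arg(model)
  if (nrow(cohort) == 0) stop("cohort is empty")
  di <- match(cohort$donor_id, genotypes$samples$sample_id)
  ri <- match(cohort$recipient_id, genotypes$samples$sample_id)
  if (anyNA(di) || anyNA(ri))
    stop("cohort ids do not all resolve in the genotype matrix")
  # loci x pairs
  d <- t(genotypes$calls[di, , drop = FALSE])
  r <- t(genotypes$calls[ri, , drop = FALSE])
  status <- .code_pair_int(d, r, model)
  dim(status) <- dim(d)
  dimnames(status) <- list(genotypes$loci$locus_id,
                           cohort$recipient_id)
  known <- !is.na(status)
  testable <- rowSums(known & status == 1L, na.rm = TRUE) > 0 &
    rowSums(known & status == 2L, na.rm = TRUE) > 0
  structure(list(model = model, status = status,
                 testable = unname(testable),
                 loci = genotypes$loci,
                 pairs = as.data.frame(cohort)),
            class = "match_matrix")
}

#' @export
print.match_matrix <- function(x, ...) {
  cat(sprintf("match_matrix (%s): %d loci x %d pairs; %d testable loci\n",
              x$model, nrow(x$status), ncol(x$status), sum(x$testable)))
  invisible(x)
}

#' Export a match matrix as a TSV audit table
#'
#' @param match a [build_match_matrix()] result.
#' @param path output file path; one row per locus, one column per pair
#'   (status codes `M`/`X`/`?` for matched/mismatched/unknown).
#' @return `path`, invisibly.
#' @export
write_match_matrix <- function(match, path) {
  codes <- matrix(c("M", "X")[match$status], nrow(match$status))
  codes[is.na(codes)] <- "?"
  out <- data.frame(locus_id = match$loci$locus_id,
                    testable = match$testable, codes,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("locus_id", "testable",
                  paste(match$pairs$donor_id, match$pairs$recipient_id,
                        sep = ">"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
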