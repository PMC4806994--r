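# Per-locus likelihood-ratio (G) test of match status against graft outcome.
#
# For the 2x2 table O indexed (outcome: accepted/rejected) x (status:
# matched/mismatched), G = 2 * sum O_ij log(O_ij / E_ij) with
# E_ij = row_i * col_j / N. Terms with O_ij = 0 contribute 0; a table with a
# zero row or column marginal has G = 0 by convention (the test is
# undefined there and the locus is untestable). Under the null G ~ chi2(1).
# Genome-wide significance uses a maxT permutation threshold: outcome labels
# are permuted across pairs, the per-permutation maximum G over loci is
# recorded, and the threshold is the empirical (1 - alpha) quantile of those
# maxima (order statistic at ceiling((1 - alpha) * n)).

# vectorised G over count vectors:
# am/amm/rm/rmm = accepted-matched, accepted-mismatched, rejected-matched,
# rejected-mismatched
.lrt_counts <- function(am, amm, rm, rmm) {
  n <- am + amm + rm + rmm
  ra <- am + amm; rr <- rm + rmm
  cm <- am + rm; cmm <- amm + rmm
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * (term(am, ra * cm / n) + term(amm, ra * cmm / n) +
              term(rm, rr * cm / n) + term(rmm, rr * cmm / n))
  g[n == 0 | ra == 0 | rr == 0 | cm == 0 | cmm == 0] <- 0
  g
}

.direction_counts <- function(am, amm, rm, rmm) {
  n <- am + amm + rm + rmm
  e_rmm <- (rm + rmm) * (amm + rmm) / n
  out <- rep("none", length(am))
  degenerate <- n == 0 | (am + amm) == 0 | (rm + rmm) == 0 |
    (am + rm) == 0 | (amm + rmm) == 0
  out[!degenerate & rmm > e_rmm] <- "rejection"
  out[!degenerate & rmm < e_rmm] <- "acceptance"
  out
}

.check_table <- function(O) {
  O <- as.matrix(O)
  stopifnot(identical(dim(O), c(2L, 2L)))
  if (any(O < 0)) stop("contingency table counts must be non-negative")
  O
}

#' Likelihood-ratio (G) statistic for a 2x2 outcome-by-status table
#'
#' @param O 2x2 matrix of observed counts, rows = outcome
#'   (accepted, rejected), columns = status (matched, mismatched).
#' @return the non-negative G statistic; 0 when any marginal total is 0.
#' @examples
#' lrt_statistic(rbind(c(5, 5), c(5, 5)))    # 0: observed equals expected
#' lrt_statistic(rbind(c(10, 0), c(0, 10)))  # 40 * log(2): perfect association
#' @export
lrt_statistic <- function(O) {
  O <- .check_table(O)
  .lrt_counts(O[1, 1], O[1, 2], O[2, 1], O[2, 2])
}

#' Direction of association for a 2x2 outcome-by-status table
#'
#' `"rejection"` when mismatched-rejected pairs exceed their expectation
#' under independence, `"acceptance"` when they fall short, `"none"` when
#' observed equals expected or the table is degenerate.
#'
#' @inheritParams lrt_statistic
#' @return one of `"rejection"`, `"acceptance"`, `"none"`.
#' @export
lrt_direction <- function(O) {
  O <- .check_table(O)
  .direction_counts(O[1, 1], O[1, 2], O[2, 1], O[2, 2])
}

# per-locus counts for an outcome assignment; rej is logical per pair
.scan_counts <- function(match, rej) {
  M <- !is.na(match$status) & match$status == 1L
  MM <- !is.na(match$status) & match$status == 2L
  storage.mode(M) <- "double"; storage.mode(MM) <- "double"
  acc <- as.double(!rej); rejd <- as.double(rej)
  list(am = drop(M %*% acc), amm = drop(MM %*% acc),
       rm = drop(M %*% rejd), rmm = drop(MM %*% rejd))
}

#' Genome-wide association scan of match status against outcome
#'
#' One G test per locus; untestable loci (only one status observed) are
#' carried with `lrt = 0` and `testable = FALSE`. Pairs with unknown status
#' at a locus drop out of that locus's table, so the per-locus total N can
#' vary.
#'
#' @param match a [build_match_matrix()] result.
#' @param cohort optional [transplant_cohort()]; defaults to the pairs the
#'   match matrix was built from, and must contain at least one accepted and
#'   one rejected outcome.
#' @return data frame of class `association_scan` (attribute `model`) with
#'   columns `locus_id`, `chromosome`, `position_bp`, `model`, `lrt`,
#'   `direction`, `pointwise_p` (upper-tail chi2(1)), `testable`.
#' @export
assoc_scan <- function(match, cohort = NULL) {
  pairs <- if (is.null(cohort)) match$pairs else as.data.frame(cohort)
  rej <- pairs$outcome == "rejected"
  if (!any(rej) || all(rej))
    stop("cohort must contain both accepted and rejected outcomes")
  cc <- .scan_counts(match, rej)
  lrt <- .lrt_counts(cc$am, cc$amm, cc$rm, cc$rmm)
  res <- data.frame(
    locus_id = match$loci$locus_id,
    chromosome = match$loci$chromosome,
    position_bp = match$loci$position_bp,
    model = match$model,
    lrt = lrt,
    direction = .direction_counts(cc$am, cc$amm, cc$rm, cc$rmm),
    pointwise_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    testable = match$testable,
    stringsAsFactors = FALSE)
  res$lrt[!res$testable] <- 0
  res$direction[!res$testable] <- "none"
  res$pointwise_p[!res$testable] <- 1
  attr(res, "model") <- match$model
  class(res) <- c("association_scan", "data.frame")
  res
}

# all C(n, r) rejected-label assignments as an n x C(n, r) 0/1 matrix
.exhaustive_assignments <- function(n, r) {
  idx <- utils::combn(n, r)
  P <- matrix(0, n, ncol(idx))
  P[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = r))] <- 1
  P
}

#' maxT permutation threshold for genome-wide significance
#'
#' Shuffles outcome labels across pairs (the match matrix stays fixed),
#' recomputes every locus's G statistic, and records the per-permutation
#' maximum; the threshold is the empirical `(1 - alpha)` quantile of the
#' recorded maxima. When the number of distinct label assignments
#' `choose(N, n_rejected)` does not exceed `n_perm` (and no strata are
#' given), all assignments are enumerated exactly instead of sampled and the
#' result is flagged `exact`.
#'
#' @param match a [build_match_matrix()] result.
#' @param n_perm number of permutations (>= 1).
#' @param alpha genome-wide significance level in (0, 1).
#' @param seed RNG seed for the sampled mode (optional).
#' @param method `"auto"` (exhaustive when feasible), `"sample"`, or
#'   `"exhaustive"`.
#' @param strata optional factor over pairs; labels are then permuted within
#'   strata only (e.g. within line combination). Sampled mode only.
#' @return object of class `permutation_result`: `model`, `n_perm` (draws
#'   actually used), `alpha`, `max_lrt` (per-permutation maxima),
#'   `threshold`, `exact`, `seed`.
#' @export
permutation_threshold <- function(match, n_perm = 1000, alpha = 0.05,
                                  seed = NULL,
                                  method = c("auto", "sample", "exhaustive"),
                                  strata = NULL) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1)
  rej <- match$pairs$outcome == "rejected"
  n <- length(rej); r <- sum(rej)
  n_distinct <- choose(n, r)
  exact <- method == "exhaustive" ||
    (method == "auto" && is.null(strata) && n_distinct <= n_perm)
  if (exact && !is.null(strata))
    stop("exhaustive enumeration does not support strata")
  M <- !is.na(match$status) & match$status == 1L
  MM <- !is.na(match$status) & match$status == 2L
  storage.mode(M) <- "double"; storage.mode(MM) <- "double"
  max_of <- function(P) {   # P: pairs x draws 0/1 rejected indicator
    am <- M %*% (1 - P); amm <- MM %*% (1 - P)
    rm_ <- M %*% P; rmm <- MM %*% P
    g <- .lrt_counts(as.vector(am), as.vector(amm),
                     as.vector(rm_), as.vector(rmm))
    dim(g) <- dim(am)
    apply(g, 2, max)
  }
  if (exact) {
    draws <- max_of(.exhaustive_assignments(n, r))
  } else {
    if (!is.null(seed)) set.seed(seed)
    if (!is.null(strata)) strata <- as.factor(strata)
    draws <- numeric(0)
    left <- n_perm
    while (left > 0) {
      k <- min(left, 2000L)
      P <- matrix(0, n, k)
      for (i in seq_len(k)) {
        perm <- if (is.null(strata)) sample.int(n) else {
          o <- seq_len(n)
          for (s in levels(strata)) {
            w <- which(strata == s)
            o[w] <- w[sample.int(length(w))]
          }
          o
        }
        P[perm[rej], i] <- 1
      }
      draws <- c(draws, max_of(P))
      left <- left - k
    }
  }
  sorted <- sort(draws)
  threshold <- sorted[ceiling((1 - alpha) * length(sorted))]
  structure(list(model = match$model, n_perm = length(draws), alpha = alpha,
                 max_lrt = draws, threshold = threshold, exact = exact,
                 seed = seed, n_distinct = n_distinct),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result (%s): %s, %d draws, alpha = %g, threshold = %.3f\n",
              x$model, if (x$exact) "exhaustive" else "sampled",
              x$n_perm, x$alpha, x$threshold))
  invisible(x)
}

#' Flag genome-wide significant loci
#'
#' Marks loci whose statistic strictly exceeds the permutation threshold
#' (ties at the threshold are not significant).
#'
#' @param results an [assoc_scan()] result.
#' @param perm a [permutation_threshold()] result for the same model.
#' @return `results` with an added logical column `genomewide_significant`.
#' @export
call_significant <- function(results, perm) {
  model <- attr(results, "model")
  if (is.null(model)) model <- unique(results$model)
  if (length(model) && !identical(model, perm$model))
    stop(sprintf("model mismatch: scan is %s, permutation result is %s",
                 paste(model, collapse = "/"), perm$model))
  results$genomewide_significant <- results$testable &
    results$lrt > perm$threshold
  results
}

#' Order scan results for a Manhattan display
#'
#' Chromosome order 1..18, X, then unknown (`"0"`); within a chromosome,
#' positioned loci ascending with unknown-position loci appended after them.
#' Y-chromosome loci are excluded.
#'
#' @param results an [assoc_scan()] result (optionally after
#'   [call_significant()]).
#' @return the re-ordered data frame with an added integer column `plot_index`.
#' @export
manhattan_export <- function(results) {
  res <- results[!(results$chromosome %in% c("Y", "y")), , drop = FALSE]
  unknown_pos <- res$position_bp == 0L
  ord <- order(.chrom_rank(res$chromosome), unknown_pos, res$position_bp)
  res <- res[ord, , drop = FALSE]
  res$plot_index <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Manhattan plot of an association scan
#'
#' Alternating colours per chromosome for rejection-direction loci, blue for
#' acceptance-direction loci, and a horizontal line at the permutation
#' threshold.
#'
#' @param results an [assoc_scan()] result.
#' @param threshold numeric threshold to draw (e.g.
#'   `perm$threshold`), or `NULL` for none.
#' @param ... passed to [graphics::plot()].
#' @return the plotted (ordered) data frame, invisibly.
#' @export
plot_manhattan <- function(results, threshold = NULL, ...) {
  res <- manhattan_export(results)
  chrom <- factor(res$chromosome, levels = unique(res$chromosome))
  col <- c("#d73027", "#1a9850")[(as.integer(chrom) %% 2L) + 1L]
  col[res$direction == "acceptance"] <- "#4575b4"
  graphics::plot(res$plot_index, res$lrt, col = col, pch = 20,
                 xlab = "locus (genome order)", ylab = "LRT", xaxt = "n", ...)
  mid <- tapply(res$plot_index, chrom, stats::median)
  graphics::axis(1, at = mid, labels = levels(chrom), cex.axis = 0.7)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(res)
}
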