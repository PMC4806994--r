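test_that("G statistic reproduces closed-form and oracle values", {
  expect_equal(lrt_statistic(rbind(c(5, 5), c(5, 5))), 0)
  expect_equal(lrt_statistic(rbind(c(10, 0), c(0, 10))), 40 * log(2))
  # frozen from the saturated-vs-independence log-likelihood oracle
  expect_equal(lrt_statistic(rbind(c(9, 1), c(0, 10))), 21.0227, tolerance = 1e-4)
  expect_equal(lrt_statistic(rbind(c(9, 1), c(0, 10))),
               oracle_g(rbind(c(9, 1), c(0, 10))))
  # zero marginals: statistic defined as 0
  expect_equal(lrt_statistic(rbind(c(3, 4), c(0, 0))), 0)
  expect_equal(lrt_statistic(rbind(c(3, 0), c(4, 0))), 0)
  expect_error(lrt_statistic(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("G equals twice the multinomial log-likelihood gap on every table up to N = 12", {
  for (N in c(1, 5, 12)) {
    for (O in all_tables(N)) {
      expect_equal(lrt_statistic(O), oracle_g(O), tolerance = 1e-12)
    }
  }
})

test_that("statistic is invariant to joint relabelling; direction flips with status labels", {
  set.seed(77)
  for (rep in 1:20) {
    O <- matrix(rpois(4, 5), 2, 2)
    # swap both row labels and column labels
    expect_equal(lrt_statistic(O), lrt_statistic(O[2:1, 2:1]))
    # relabelling matched<->mismatched preserves G, flips direction
    expect_equal(lrt_statistic(O), lrt_statistic(O[, 2:1]))
    d <- lrt_direction(O)
    d_flip <- lrt_direction(O[, 2:1])
    if (d == "rejection") expect_equal(d_flip, "acceptance")
    if (d == "acceptance") expect_equal(d_flip, "rejection")
    if (d == "none") expect_equal(d_flip, "none")
  }
})

test_that("direction follows the mismatched-rejected excess", {
  expect_equal(lrt_direction(rbind(c(9, 1), c(0, 10))), "rejection")
  expect_equal(lrt_direction(rbind(c(0, 10), c(9, 1))), "acceptance")
  expect_equal(lrt_direction(rbind(c(5, 5), c(5, 5))), "none")
})

test_that("the scan ties per-locus tables to the genome map", {
  # locus 1: status equals outcome for all pairs; locus 2: all matched
  gm <- make_gm(rbind(cbind(rep("AA", 10), "AA"),
                      cbind(c(rep("BB", 5), rep("AA", 5)), "AA")),
                line = rep(c("don", "rec"), each = 10),
                chromosome = c("2", "2"), position = c(100L, 200L))
  cohort <- make_cohort(gm$samples$sample_id[1:10],
                        gm$samples$sample_id[11:20],
                        rep(c("rejected", "accepted"), each = 5), gm)
  mm <- build_match_matrix(gm, cohort, "model2")
  res <- assoc_scan(mm)
  # 10 pairs, status equals outcome: table [[5,0],[0,5]], G = 20 log 2
  expect_equal(res$lrt[1], 20 * log(2))
  expect_equal(res$direction[1], "rejection")
  expect_true(res$testable[1])
  expect_false(res$testable[2])
  expect_equal(res$lrt[2], 0)
  expect_equal(res$pointwise_p[1],
               pchisq(20 * log(2), 1, lower.tail = FALSE))

  # single-class outcomes are refused
  bad <- make_cohort(gm$samples$sample_id[1:2], gm$samples$sample_id[11:12],
                     c("rejected", "rejected"), gm)
  expect_error(assoc_scan(build_match_matrix(gm, bad, "model2")),
               "accepted and rejected")
})

test_that("scan results are invariant to locus ordering", {
  set.seed(13)
  gm <- random_gm(n = 12, m = 30, missing_rate = 0.1)
  cohort <- make_cohort(gm$samples$sample_id[1:6], gm$samples$sample_id[7:12],
                        rep(c("rejected", "accepted"), 3), gm)
  res <- assoc_scan(build_match_matrix(gm, cohort, "model1"))
  perm <- sample.int(30)
  gm_shuf <- genotype_matrix(calls_to_strings(gm$calls[, perm]),
                             gm$samples, gm$loci[perm, ])
  res_shuf <- assoc_scan(build_match_matrix(gm_shuf, cohort, "model1"))
  expect_equal(res_shuf$lrt[match(res$locus_id, res_shuf$locus_id)], res$lrt)
})

test_that("null statistics are calibrated against chi2(1) up to discreteness", {
  # 2000 loci, each pair mismatched with probability 1/2, independent of a
  # balanced 20-pair outcome
  set.seed(42)
  n_loci <- 2000; n_pairs <- 20
  rej <- rep(c(TRUE, FALSE), each = n_pairs / 2)
  status <- matrix(rbinom(n_loci * n_pairs, 1, 0.5) + 1L, n_loci, n_pairs)
  am <- rowSums((status == 1L)[, !rej]); amm <- rowSums((status == 2L)[, !rej])
  rm_ <- rowSums((status == 1L)[, rej]); rmm <- rowSums((status == 2L)[, rej])
  g <- minormatch:::.lrt_counts(am, amm, rm_, rmm)
  frac <- mean(g > qchisq(0.95, 1))
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.07)
  # Kolmogorov distance to chi2(1): dominated by the point mass near zero,
  # bounded loosely rather than asserted tight
  ks <- max(abs(ecdf(g)(sort(g)) - pchisq(sort(g), 1)))
  expect_lt(ks, 0.5)
})

test_that("significance calls use a strict threshold and matching models", {
  gm <- make_gm(rbind(cbind(rep("AA", 6), "AA"),
                      cbind(c(rep("BB", 3), rep("AA", 3)), "AA")),
                line = rep(c("don", "rec"), each = 6))
  cohort <- make_cohort(gm$samples$sample_id[1:6], gm$samples$sample_id[7:12],
                        rep(c("rejected", "accepted"), each = 3), gm)
  mm <- build_match_matrix(gm, cohort, "model2")
  res <- assoc_scan(mm)
  perm <- permutation_threshold(mm, n_perm = 100, method = "exhaustive")
  called <- call_significant(res, perm)
  expect_type(called$genomewide_significant, "logical")
  # lrt equal to the threshold is not significant
  fake <- perm; fake$threshold <- res$lrt[1]
  expect_false(call_significant(res, fake)$genomewide_significant[1])
  fake$threshold <- res$lrt[1] - 1e-9
  expect_true(call_significant(res, fake)$genomewide_significant[1])
  # model mismatch is refused
  mm1 <- build_match_matrix(gm, cohort, "model1")
  perm1 <- permutation_threshold(mm1, n_perm = 50)
  expect_error(call_significant(res, perm1), "model mismatch")
  expect_equal(nrow(call_significant(res[0, ], perm)), 0L)
})

test_that("manhattan ordering excludes Y and groups unknowns last", {
  res <- data.frame(locus_id = sprintf("L%d", 1:6),
                    chromosome = c("2", "1", "0", "X", "1", "Y"),
                    position_bp = c(500L, 900L, 0L, 10L, 0L, 5L),
                    model = "model1", lrt = 1, direction = "none",
                    pointwise_p = 1, testable = TRUE)
  out <- manhattan_export(res)
  expect_false("Y" %in% out$chromosome)
  expect_equal(out$locus_id, c("L2", "L5", "L1", "L4", "L3"))
  expect_equal(out$plot_index, 1:5)
})
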