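test_that("configuration invariants are enforced before simulation", {
  expect_error(sim_config(background_rejection = 1.5), "background_rejection")
  expect_error(sim_config(causal_loci = data.frame(locus = NA, model = "model1",
                                                   penetrance = 1.5)),
               "penetrance")
  expect_error(sim_config(causal_loci = data.frame(locus = NA, model = "model3",
                                                   penetrance = 0.5)),
               "model")
  expect_error(sim_config(lines = data.frame(label = "a", n = 3,
                                             fixation = 0.1),
                          pairings = data.frame(donor_line = "a",
                                                recipient_line = "a",
                                                n_grafts = 1)),
               "shared_fixation")
  expect_error(sim_config(maf_mean = 0.7), "maf_mean")
  expect_error(sim_config(pairings = data.frame(donor_line = "zz",
                                                recipient_line = "cc",
                                                n_grafts = 2)),
               "zz")
})

test_that("fully shared fixation leaves no mismatches and no rejections", {
  cfg <- sim_config(seed = 3, n_snps = 300, shared_fixation = 1,
                    lines = data.frame(label = c("u", "v"), n = c(4, 8),
                                       fixation = c(1, 1)),
                    pairings = data.frame(donor_line = "u",
                                          recipient_line = "v", n_grafts = 4),
                    causal_loci = data.frame(locus = integer(), model = character(),
                                             penetrance = numeric()),
                    background_rejection = 0)
  sim <- simulate_cohort(cfg)
  mm <- build_match_matrix(sim$genotypes, sim$cohort, "model2")
  expect_true(all(mm$status == 1L))
  expect_equal(sum(mm$testable), 0L)
  expect_true(all(sim$cohort$outcome == "accepted"))
})

test_that("per-line fixation proportions are recovered within tolerance", {
  cfg <- sim_config(seed = 11, n_snps = 6000)
  sim <- simulate_cohort(cfg)
  st <- line_stats(sim$genotypes, by = "genome")
  expect_lt(abs(st$prop_fixed[st$line == "bb"] - 0.86), 0.03)
  expect_lt(abs(st$prop_fixed[st$line == "cc"] - 0.71), 0.03)
  expect_lt(abs(st$prop_fixed[st$line == "dd"] - 0.78), 0.03)
  # across-line joint fixation sits near the configured shared level
  expect_lt(abs(cross_line_fixed(sim$genotypes) - 0.40), 0.05)
  # testable loci are neither none nor all
  mm <- build_match_matrix(sim$genotypes, sim$cohort, "model2")
  expect_gt(sum(mm$testable), 0)
  expect_lt(sum(mm$testable), nrow(sim$genotypes$loci))
})

test_that("raising line fixation lowers the number of testable loci", {
  testable_at <- function(f, seed) {
    cfg <- sim_config(seed = seed, n_snps = 1500, shared_fixation = 0.2,
                      lines = data.frame(label = "w", n = 12, fixation = f),
                      pairings = data.frame(donor_line = "w",
                                            recipient_line = "w",
                                            n_grafts = 6),
                      causal_loci = data.frame(locus = integer(),
                                               model = character(),
                                               penetrance = numeric()),
                      background_rejection = 0.5)
    sim <- simulate_cohort(cfg)
    sum(build_match_matrix(sim$genotypes, sim$cohort, "model2")$testable)
  }
  lo <- vapply(1:4, function(s) testable_at(0.4, s), numeric(1))
  hi <- vapply(1:4, function(s) testable_at(0.9, s), numeric(1))
  expect_gt(mean(lo), mean(hi))
})

test_that("with full penetrance every rejection traces to a causal mismatch", {
  for (seed in c(2, 5, 8)) {
    cfg <- sim_config(seed = seed, n_snps = 600,
                      causal_loci = data.frame(locus = NA, model = "model1",
                                               penetrance = 1),
                      background_rejection = 0)
    sim <- simulate_cohort(cfg)
    rejected <- sim$cohort$outcome == "rejected"
    mism <- sim$truth$pair_causal_mismatch[, 1]
    expect_equal(rejected, mism)
    # and the truth record names exactly the configured causal loci
    expect_equal(nrow(sim$truth$causal), 1L)
    expect_equal(sim$truth$causal$model, "model1")
  }
})

test_that("writing and re-reading a simulated cohort is lossless and deterministic", {
  cfg <- sim_config(seed = 21, n_snps = 200, missing_rate = 0.02)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_genotypes(file.path(dir, "cohort"), "ped_map")
  expect_identical(back$calls, sim$genotypes$calls)
  pairs <- read_pairs(file.path(dir, "pairs.tsv"), back)
  expect_equal(as.data.frame(pairs), as.data.frame(sim$cohort),
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$causal$locus_id, sim$truth$causal$locus_id)

  # identical seed, identical bytes
  dir2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), dir2)
  for (f in c("cohort.ped", "cohort.map", "pairs.tsv", "truth.json"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("a fully penetrant causal locus tops the scan or ties with its LD block", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_snps = 800,
                      pairings = data.frame(donor_line = c("bb", "dd", "cc"),
                                            recipient_line = "cc",
                                            n_grafts = c(6L, 10L, 4L)),
                      causal_loci = data.frame(locus = NA, model = "model2",
                                               penetrance = 1),
                      background_rejection = 0)
    sim <- simulate_cohort(cfg)
    if (length(unique(sim$cohort$outcome)) < 2) next
    res <- assoc_scan(build_match_matrix(sim$genotypes, sim$cohort, "model2"))
    top <- res$locus_id[res$lrt == max(res$lrt)]
    if (any(top %in% sim$truth$block_members[[1]])) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
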