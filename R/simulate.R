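# Simulator of semi-inbred multi-line SNP cohorts with planted causal
# minor-histocompatibility loci.
#
# Per SNP: with probability `shared_fixation` every line fixes the same
# allele (shared ancestral fixation); otherwise each line independently
# fixes a line-chosen allele with its own probability f_l, and is
# segregating otherwise. Segregating sites are organised into LD blocks:
# per line and block a small pool of haplotypes is drawn (each segregating
# site polymorphic within the pool), and every animal draws two pool
# haplotypes per block, so neighbouring SNPs co-segregate and genotypes
# follow within-line Hardy-Weinberg at the realized pool frequencies.
# Graft outcome: a pair mismatched (under the locus's model) at >= 1 causal
# locus is rejected with the locus penetrance (jointly
# 1 - prod(1 - p_i) over mismatched causal loci); otherwise with the
# background rate.

# chip-like default layout: per-chromosome SNP counts of a ~60k porcine
# array (autosomes 1-18, X, unknown), used as proportions at scaled totals
.CHIP_CHROM <- c(as.character(1:18), "X", "0")
.CHIP_SNPS <- c(6792, 3179, 2694, 3645, 2352, 2849, 3427, 2554, 3088, 1571,
                1860, 1475, 3523, 3947, 2774, 1816, 1663, 1284, 1420, 7939)

.default_lines <- function() {
  data.frame(label = c("bb", "cc", "dd"), n = c(5L, 27L, 11L),
             fixation = c(0.86, 0.71, 0.78), stringsAsFactors = FALSE)
}

.default_pairings <- function() {
  data.frame(donor_line = c("bb", "dd", "cc"),
             recipient_line = c("cc", "cc", "cc"),
             n_grafts = c(6L, 10L, 5L), stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults mirror the study design the package targets: three
#' MHC-homozygous pig lines of 5/27/11 animals with within-line fixation
#' proportions 0.86/0.71/0.78, a shared-fixation probability of 0.35 (so
#' about 40% of SNPs are fixed for the same allele across all three lines),
#' segregating-site minor allele frequencies drawn from a scaled Beta with
#' mean 0.24, a ~60k-array chromosome layout scaled to `n_snps`, and grafts
#' in three line combinations (6, 10, 5).
#'
#' @param seed RNG seed (integer).
#' @param lines data frame `label`, `n`, `fixation`.
#' @param shared_fixation probability a SNP is fixed for one shared allele
#'   across all lines.
#' @param n_snps total number of SNPs.
#' @param maf_mean,maf_shape segregating-site MAF ~ 0.5 * Beta(a, b) with
#'   mean `maf_mean` and concentration `maf_shape`.
#' @param ld_block_snps mean SNPs per LD block.
#' @param pool_haplotypes haplotypes in each per-line per-block pool (>= 2).
#' @param pairings data frame `donor_line`, `recipient_line`, `n_grafts`.
#' @param causal_loci data frame `locus` (index into the locus map, or `NA`
#'   to auto-pick a segregating locus at simulation time), `model`
#'   (`"model1"`/`"model2"`), `penetrance` in \[0, 1\]. May have zero rows.
#' @param background_rejection rejection probability for pairs with no
#'   causal mismatch.
#' @param missing_rate per-call missing probability.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lines = .default_lines(),
                       shared_fixation = 0.35,
                       n_snps = 6000L,
                       maf_mean = 0.24,
                       maf_shape = 5,
                       ld_block_snps = 20,
                       pool_haplotypes = 4L,
                       pairings = .default_pairings(),
                       causal_loci = data.frame(locus = NA_integer_,
                                                model = "model1",
                                                penetrance = 0.9),
                       background_rejection = 0.02,
                       missing_rate = 0) {
  cfg <- list(seed = as.integer(seed),
              lines = as.data.frame(lines, stringsAsFactors = FALSE),
              shared_fixation = shared_fixation,
              n_snps = as.integer(n_snps),
              maf_mean = maf_mean, maf_shape = maf_shape,
              ld_block_snps = ld_block_snps,
              pool_haplotypes = as.integer(pool_haplotypes),
              pairings = as.data.frame(pairings, stringsAsFactors = FALSE),
              causal_loci = as.data.frame(causal_loci,
                                          stringsAsFactors = FALSE),
              background_rejection = background_rejection,
              missing_rate = missing_rate)
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  prob_fields <- c("shared_fixation", "background_rejection", "missing_rate")
  for (f in prob_fields)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("config field '%s' must be a probability in [0, 1]", f))
  if (!all(c("label", "n", "fixation") %in% names(cfg$lines)))
    stop("config field 'lines' needs columns label, n, fixation")
  if (any(cfg$lines$fixation < 0 | cfg$lines$fixation > 1))
    stop("config field 'lines$fixation' must be probabilities in [0, 1]")
  if (any(cfg$lines$fixation < cfg$shared_fixation))
    stop("every line's fixation probability must be >= shared_fixation (shared fixation is a subset of line fixation)")
  if (any(cfg$lines$n < 1)) stop("every line needs at least one animal")
  if (cfg$n_snps < 1) stop("config field 'n_snps' must be positive")
  if (cfg$maf_mean <= 0 || cfg$maf_mean >= 0.5)
    stop("config field 'maf_mean' must lie in (0, 0.5)")
  if (cfg$pool_haplotypes < 2)
    stop("config field 'pool_haplotypes' must be >= 2")
  if (nrow(cfg$pairings)) {
    known <- cfg$lines$label
    bad <- setdiff(c(cfg$pairings$donor_line, cfg$pairings$recipient_line),
                   known)
    if (length(bad)) stop("pairings name unknown line(s): ",
                          paste(bad, collapse = ", "))
  }
  if (nrow(cfg$causal_loci)) {
    if (!all(cfg$causal_loci$model %in% c("model1", "model2")))
      stop("config field 'causal_loci$model' must be model1 or model2")
    if (any(cfg$causal_loci$penetrance < 0 | cfg$causal_loci$penetrance > 1))
      stop("config field 'causal_loci$penetrance' must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [sim_config()]; `lines`,
#' `pairings` and `causal_loci` are lists of records.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(x) do.call(rbind, lapply(x, as.data.frame))
  args <- y
  for (f in c("lines", "pairings", "causal_loci"))
    if (!is.null(y[[f]])) args[[f]] <- to_df(y[[f]])
  do.call(sim_config, args)
}

.sim_layout <- function(cfg) {
  counts <- round(cfg$n_snps * .CHIP_SNPS / sum(.CHIP_SNPS))
  counts[1] <- counts[1] + (cfg$n_snps - sum(counts))  # fix rounding drift
  chrom <- rep(.CHIP_CHROM, counts)
  pos <- unlist(lapply(counts, function(k) seq_len(k) * 40000L),
                use.names = FALSE)
  pos[chrom == "0"] <- 0L   # unknown-position SNPs carry the 0 sentinel
  loci <- data.frame(locus_id = sprintf("snp%05d", seq_along(chrom)),
                     chromosome = chrom, position_bp = pos,
                     assembly = "simulated", alt_chromosome = NA_character_,
                     stringsAsFactors = FALSE)
  # LD blocks: consecutive runs within a chromosome
  block <- integer(nrow(loci)); nb <- 0L; i <- 1L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    while (length(idx)) {
      size <- min(length(idx), stats::rpois(1, cfg$ld_block_snps - 1) + 1L)
      nb <- nb + 1L
      block[idx[seq_len(size)]] <- nb
      idx <- idx[-seq_len(size)]
    }
  }
  loci$ld_block <- block
  loci
}

# one line's call matrix (n x m); seg sites drawn block-wise from pools
.sim_line_calls <- function(cfg, loci, n, fixed, fixed_allele) {
  m <- nrow(loci)
  calls <- matrix(rep(ifelse(fixed, fixed_allele, .CALL_MISSING), each = n),
                  nrow = n)
  K <- cfg$pool_haplotypes
  a <- cfg$maf_shape * 2 * cfg$maf_mean
  b <- cfg$maf_shape * (1 - 2 * cfg$maf_mean)
  maf <- 0.5 * stats::rbeta(m, a, b)
  for (blk in unique(loci$ld_block)) {
    s <- which(loci$ld_block == blk & !fixed)
    if (!length(s)) next
    k_minor <- pmin(pmax(stats::rbinom(length(s), K, maf[s]), 1L), K - 1L)
    pool <- matrix(FALSE, K, length(s))   # TRUE = haplotype carries minor
    for (j in seq_along(s))
      pool[sample.int(K, k_minor[j]), j] <- TRUE
    h1 <- sample.int(K, n, replace = TRUE)
    h2 <- sample.int(K, n, replace = TRUE)
    n_minor <- pool[h1, , drop = FALSE] + pool[h2, , drop = FALSE]
    minor_is_A <- stats::runif(length(s)) < 0.5
    nA <- sweep(n_minor, 2, ifelse(minor_is_A, 0L, 2L), function(x, base)
      abs(base - x))   # minor_is_A: nA = n_minor; else nA = 2 - n_minor
    calls[, s] <- 3L - nA
  }
  calls
}

.sim_pairs <- function(cfg, samples) {
  pr <- cfg$pairings
  # recipients first, without replacement within each recipient line
  for (ln in unique(pr$recipient_line)) {
    need <- sum(pr$n_grafts[pr$recipient_line == ln])
    have <- sum(samples$line == ln)
    if (have < need)
      stop(sprintf("line %s has %d animals but %d recipients are required",
                   ln, have, need))
  }
  recipients <- vector("list", nrow(pr))
  used <- character(0)
  for (p in seq_len(nrow(pr))) {
    rpool <- setdiff(samples$sample_id[samples$line == pr$recipient_line[p]],
                     used)
    recipients[[p]] <- sample(rpool, pr$n_grafts[p])
    used <- c(used, recipients[[p]])
  }
  cohort <- NULL
  for (p in seq_len(nrow(pr))) {
    k <- pr$n_grafts[p]
    # donors never double as recipients; an animal can donate twice
    dpool <- setdiff(samples$sample_id[samples$line == pr$donor_line[p]], used)
    donors <- if (length(dpool) >= k) sample(dpool, k)
    else sample(dpool, k, replace = TRUE)
    cohort <- rbind(cohort, data.frame(donor_id = donors,
                                       recipient_id = recipients[[p]],
                                       stringsAsFactors = FALSE))
  }
  cohort
}

.resolve_causal <- function(cfg, gm, seg_by_line) {
  causal <- cfg$causal_loci
  if (!nrow(causal)) return(causal)
  involved <- unique(c(cfg$pairings$donor_line, cfg$pairings$recipient_line))
  seg_inv <- seg_by_line[, involved, drop = FALSE]
  causal$locus <- as.integer(causal$locus)
  for (k in which(is.na(causal$locus))) {
    cand <- which(rowSums(seg_inv) == ncol(seg_inv))  # segregating everywhere
    if (!length(cand)) cand <- which(rowSums(seg_inv) > 0)
    if (!length(cand)) stop("no segregating locus available for a causal pick")
    taken_blocks <- gm$loci$ld_block[causal$locus[!is.na(causal$locus)]]
    cand <- cand[!(gm$loci$ld_block[cand] %in% taken_blocks)]
    if (!length(cand)) stop("not enough distinct LD blocks for causal loci")
    causal$locus[k] <- cand[sample.int(length(cand), 1)]
  }
  bad <- rowSums(seg_by_line[causal$locus, involved, drop = FALSE]) == 0
  if (any(bad))
    stop("causal locus not segregating in any involved line: ",
         paste(gm$loci$locus_id[causal$locus[bad]], collapse = ", "))
  causal
}

#' Simulate a semi-inbred multi-line transplant cohort
#'
#' Generates line-structured genotypes, donor-recipient pairings and graft
#' outcomes driven by mismatches at planted causal loci (see the file-level
#' notes in the source for the generative model). All randomness derives
#' from `config$seed`, so a given configuration is fully reproducible.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `genotypes` ([genotype_matrix()],
#'   with an extra `ld_block` locus column), `cohort`
#'   ([transplant_cohort()]), and `truth` — the planted causal loci
#'   (`locus_id`, model, penetrance, LD-block members) and each pair's
#'   causal mismatch status.
#' @export
simulate_cohort <- function(config) {
  cfg <- .validate_sim_config(config)
  set.seed(cfg$seed)
  loci <- .sim_layout(cfg)
  m <- nrow(loci); L <- nrow(cfg$lines)
  shared <- stats::runif(m) < cfg$shared_fixation
  shared_allele <- sample(c(.CALL_AA, .CALL_BB), m, replace = TRUE)
  calls <- NULL
  samples <- NULL
  for (l in seq_len(L)) {
    n_l <- cfg$lines$n[l]
    # shared fixation is a subset of line fixation, so the total per-line
    # fixation probability equals the configured value f_l:
    # P(fixed) = c + (1 - c) * (f_l - c) / (1 - c) = f_l
    f_extra <- (cfg$lines$fixation[l] - cfg$shared_fixation) /
      (1 - cfg$shared_fixation)
    fixed <- shared | stats::runif(m) < f_extra
    fixed_allele <- ifelse(shared, shared_allele,
                           sample(c(.CALL_AA, .CALL_BB), m, replace = TRUE))
    calls <- rbind(calls, .sim_line_calls(cfg, loci, n_l, fixed, fixed_allele))
    samples <- rbind(samples,
                     data.frame(sample_id = sprintf("%s_%02d",
                                                    cfg$lines$label[l],
                                                    seq_len(n_l)),
                                line = cfg$lines$label[l],
                                sex = NA_character_,
                                stringsAsFactors = FALSE))
  }
  if (cfg$missing_rate > 0)
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- .CALL_MISSING
  gm <- genotype_matrix(calls, samples, loci)
  if (!nrow(cfg$pairings)) {
    return(structure(list(genotypes = gm, cohort = NULL,
                          truth = list(causal = cfg$causal_loci[0, ],
                                       pairs = NULL, seed = cfg$seed)),
                     class = "sim_cohort"))
  }
  pairs <- .sim_pairs(cfg, samples)
  # within-line segregation (both alleles present) per locus per line
  seg_by_line <- vapply(cfg$lines$label, function(ln) {
    cc <- .per_locus_counts(gm$calls[samples$line == ln, , drop = FALSE])
    cc$used & !cc$fixed
  }, logical(m))
  causal <- .resolve_causal(cfg, gm, seg_by_line)
  di <- match(pairs$donor_id, samples$sample_id)
  ri <- match(pairs$recipient_id, samples$sample_id)
  p_rej <- rep(cfg$background_rejection, nrow(pairs))
  mism <- matrix(FALSE, nrow(pairs), nrow(causal))
  if (nrow(causal)) {
    p_no_causal <- rep(1, nrow(pairs))
    for (k in seq_len(nrow(causal))) {
      st <- .code_pair_int(gm$calls[di, causal$locus[k]],
                           gm$calls[ri, causal$locus[k]],
                           causal$model[k])
      mism[, k] <- !is.na(st) & st == 2L
      p_no_causal <- p_no_causal * ifelse(mism[, k],
                                          1 - causal$penetrance[k], 1)
    }
    any_mism <- rowSums(mism) > 0
    p_rej <- ifelse(any_mism, 1 - p_no_causal, cfg$background_rejection)
  }
  outcome <- ifelse(stats::runif(nrow(pairs)) < p_rej, "rejected", "accepted")
  cohort <- transplant_cohort(cbind(pairs, outcome = outcome), gm)
  truth_causal <- if (nrow(causal)) data.frame(
    locus_id = gm$loci$locus_id[causal$locus],
    locus_index = causal$locus,
    model = causal$model,
    penetrance = causal$penetrance,
    chromosome = gm$loci$chromosome[causal$locus],
    position_bp = gm$loci$position_bp[causal$locus],
    ld_block = gm$loci$ld_block[causal$locus],
    stringsAsFactors = FALSE) else causal
  block_members <- lapply(seq_len(nrow(causal)), function(k)
    gm$loci$locus_id[gm$loci$ld_block == gm$loci$ld_block[causal$locus[k]]])
  colnames(mism) <- if (nrow(causal)) truth_causal$locus_id else NULL
  structure(list(genotypes = gm, cohort = cohort,
                 truth = list(causal = truth_causal,
                              block_members = block_members,
                              pair_causal_mismatch = mism,
                              seed = cfg$seed)),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes PED/MAP genotypes (`cohort.ped`/`cohort.map`), the pair table
#' (`pairs.tsv`) and the simulation truth (`truth.json`) into a directory;
#' re-reading with [read_genotypes()] and [read_pairs()] reproduces the
#' matrices exactly.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "cohort"), "ped_map")
  if (!is.null(sim$cohort))
    utils::write.table(as.data.frame(sim$cohort), file.path(dir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$pair_causal_mismatch <- as.data.frame(truth$pair_causal_mismatch)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
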