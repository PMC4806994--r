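# Small in-code fixtures and independent oracles shared across test files.

# genotype matrix from a character grid; samples named s1..sn, default one line
make_gm <- function(calls_chr, line = "L1", chromosome = NULL,
                    position = NULL, sex = NA_character_) {
  calls_chr <- as.matrix(calls_chr)
  n <- nrow(calls_chr); m <- ncol(calls_chr)
  if (length(line) == 1) line <- rep(line, n)
  if (is.null(chromosome)) chromosome <- rep("1", m)
  if (is.null(position)) position <- seq_len(m) * 1000L
  genotype_matrix(
    calls_chr,
    samples = data.frame(sample_id = sprintf("s%d", seq_len(n)),
                         line = line, sex = sex),
    loci = data.frame(locus_id = sprintf("L%03d", seq_len(m)),
                      chromosome = chromosome, position_bp = position))
}

# random genotype matrix (for property-style round trips)
random_gm <- function(n, m, missing_rate = 0.1, n_lines = 2) {
  calls <- matrix(sample(c("AA", "AB", "BB"), n * m, replace = TRUE), n, m)
  calls[runif(n * m) < missing_rate] <- "NN"
  make_gm(calls,
          line = sample(sprintf("line%d", seq_len(n_lines)), n, replace = TRUE),
          chromosome = sample(c("1", "2", "X"), m, replace = TRUE),
          position = sample.int(1e6, m))
}

make_cohort <- function(donors, recipients, outcomes, gm = NULL) {
  transplant_cohort(data.frame(donor_id = donors, recipient_id = recipients,
                               outcome = outcomes), gm)
}

# Independent G-test oracle: twice the gap between the saturated and the
# independence multinomial log-likelihoods, written from the likelihoods
# rather than the O*log(O/E) identity.
oracle_g <- function(O) {
  O <- as.matrix(O); N <- sum(O)
  if (N == 0) return(0)
  p_sat <- O / N
  p_ind <- outer(rowSums(O) / N, colSums(O) / N)
  ll <- function(p) sum(O[O > 0] * log(p[O > 0]))
  if (any(rowSums(O) == 0) || any(colSums(O) == 0)) return(0)
  2 * (ll(p_sat) - ll(p_ind))
}

# all 2x2 tables with total N (enumeration oracle helper)
all_tables <- function(N) {
  out <- list()
  for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
    d <- N - a - b - c
    out[[length(out) + 1L]] <- matrix(c(a, c, b, d), 2, 2)
  }
  out
}

# brute-force per-SNP homozygosity recount used against line_stats
oracle_line_stats <- function(gm, line) {
  calls <- gm$calls[gm$samples$line == line, , drop = FALSE]
  per <- apply(calls, 2, function(x) {
    x <- x[x != 0L]
    if (!length(x)) return(c(used = 0, fixed = NA, maf = NA, het = NA))
    nA <- sum(x == 1L) * 2 + sum(x == 2L)
    nB <- sum(x == 3L) * 2 + sum(x == 2L)
    fixed <- length(unique(x)) == 1 && x[1] != 2L
    c(used = 1, fixed = fixed,
      maf = min(nA, nB) / (nA + nB),
      het = mean(x == 2L))
  })
  used <- per["used", ] == 1
  seg <- used & per["fixed", ] == 0
  list(prop_fixed = sum(per["fixed", used]) / sum(used),
       n_segregating = sum(seg),
       mean_maf = if (any(seg)) mean(per["maf", seg]) else NA_real_,
       mean_het = if (any(seg)) mean(per["het", seg]) else NA_real_)
}
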