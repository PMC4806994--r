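---
title: "Donor-recipient mismatch association: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor-recipient mismatch association: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minormatch)
```

## The scientific problem

When a graft is transplanted between animals matched at the major
histocompatibility complex (MHC), rejection — if it occurs — is driven by
*minor* histocompatibility loci: ordinary polymorphic genes whose allelic
peptide differences between donor and recipient are seen by the recipient's
T cells. In semi-inbred lines (here, MHC-homozygous pig lines used in
corneal transplantation research), most of the genome is fixed within each
line, so the loci still segregating within and between lines form a natural
mapping panel: code each donor–recipient pair at each SNP as *matched* or
*mismatched*, and ask which SNPs' mismatch status predicts graft outcome.

`minormatch` implements that analysis end to end: within-line homozygosity
profiling, mismatch coding under two rejection models, a per-SNP
likelihood-ratio test with a permutation-derived genome-wide threshold,
block-level reporting of significant SNPs, and a cohort simulator used to
validate the machinery.

## Mismatch models

Genotypes are abstracted to unordered pairs over a biallelic alphabet
$\{A,B\}$; the analysis only ever needs allele identity, never the
nucleotide.

* **Model 1 (directional, host-versus-graft).** A pair is mismatched iff
  the donor carries at least one allele the recipient lacks — the T-cell
  epitope logic in which only graft antigens foreign to the host matter.
  $AB \to AA$ is mismatched; $AA \to AB$ is matched.
* **Model 2 (symmetric).** Any difference between the unordered genotypes
  is a mismatch; direction is ignored. Every Model-1 mismatch is a
  Model-2 mismatch.

A missing call on either side makes the status *unknown*, and that pair
simply drops out of that locus's table; with cohorts of ~20 pairs we do not
impute. A locus enters the scan (is *testable*) only when both statuses
occur among known-status pairs — otherwise the test statistic is
identically zero. This pair-level testability rule is our operational
definition; a line-level segregation filter would give slightly different
locus counts, and neither count is treated as a reproducible quantity.

## The test

At each locus the pairs with known status form a 2×2 table $O_{ij}$
(outcome accepted/rejected × status matched/mismatched). The statistic is
the G statistic (likelihood-ratio test of independence),

$$G \;=\; 2\sum_{i,j} O_{ij}\,\ln\!\frac{O_{ij}}{E_{ij}},
\qquad E_{ij} = \frac{O_{i\cdot}\,O_{\cdot j}}{N},$$

asymptotically $\chi^2_1$ under the null. Conventions: $0\ln 0 \equiv 0$;
a table with a zero row or column marginal has $G = 0$; $N$ is per-locus
(missing statuses reduce it). The factor 2 is part of the definition —
without it the statistic could never exceed $N\ln 2 \approx 13.9$ at
$N = 20$ and no genome-wide threshold in the high teens could ever be
crossed, nor would the $\chi^2_1$ reference apply. The association
*direction* is read from the mismatched-rejected cell: above its
expectation → rejection-associated, below → acceptance-associated.

### Genome-wide threshold

Multiplicity is handled by maxT permutation: outcome labels are permuted
across pairs (the match matrix is fixed), all testable-locus statistics are
recomputed, and the per-permutation maximum is recorded; the 5% genome-wide
threshold is the empirical 95% quantile (order statistic at
$\lceil(1-\alpha) n_\mathrm{perm}\rceil$) of those maxima. When
$\binom{N}{r}$ (distinct label assignments for $r$ rejected among $N$) does
not exceed `n_perm`, all assignments are enumerated exactly. Significance
uses a strict inequality (a statistic equal to the threshold is not
called), the conservative choice for a discrete null. Permutations are
unstratified by default; a `strata` argument permutes within groups (e.g.
line combinations) for users who consider the line combination a design
variable, and is documented as an extension rather than the primary
analysis.

### Null calibration

At $N = 20$ the table is highly discrete, so the pointwise $\chi^2_1$
reference is approximate. The test suite calibrates the statistic on a
balanced exchangeable null (each pair mismatched with probability 1/2,
independent of a 10/10 outcome split): across 2,000 null loci the fraction
exceeding the $\chi^2_1$ 5% point (3.841) must land in [0.01, 0.07]. The
population exceedance rate of this design, measured once at 400k loci, is
≈ 0.052: the G test is mildly anti-conservative at this sample size, which
is exactly why genome-wide calls rest on the permutation threshold rather
than on pointwise $\chi^2$ p-values. Skewed mismatch frequencies push the
rate toward ≈ 0.066, still within the band but close to its edge.

## Homozygosity profiling

A SNP is *fixed* within a line iff every non-missing call in the line is
the same homozygote; a locus where all animals are heterozygous carries
both alleles and counts as segregating. MAF and heterozygosity are
reported over segregating SNPs only, and a group with no segregating SNP
reports `NA`, not 0. SNPs with no non-missing call in a line leave that
line's denominators. Ties at MAF 0.5 take allele B as minor (equivalently
A as major in the genotype-category maps), a determinism convention with no
analytical consequence. No Hardy–Weinberg structure is assumed or checked
in real data — semi-inbred lines are exactly where HWE fails — so
heterozygosity is reported as a direct count, never derived from allele
frequencies.

## Blocks and outcome groups

Significant SNPs are grouped per model and direction: positioned SNPs on a
chromosome, sorted by base pair, are split where consecutive positions are
more than `gap_bp` apart. The 5 Mb default was chosen because, applied to
the packaged published significant-SNP table, it reproduces the reported
structure — exactly four rejection blocks of ≥ 4 SNPs (chromosomes 1, 4, 6
and 9) — while keeping the distant chromosome-4 singleton separate; it is a
reporting granularity, not a biological constant, and is configurable.

Three conventions handle incomplete locations:

* a row whose chromosome was assigned under an earlier genome assembly is
  regrouped to that chromosome, but its printed position (a coordinate on
  the other assembly) is treated as unknown for grouping and span purposes;
* unknown-position rows attach to their chromosome's block when exactly one
  block exists there (else they are reported unassigned; if the chromosome
  has no positioned block at all they form one position-less block);
* rows with unknown chromosome form singleton "unplaced" blocks.

Spans use positioned members only, reported in Mbp to one decimal.
Per-locus outcome-group tables (matched-accepted, matched-rejected,
mismatched-accepted, mismatched-rejected) summarise each significant
locus's predictive value; the *accuracy* is the fraction of grafts whose
fate pre-transplant typing at that locus would have called correctly.

## The cohort simulator

No genotype data accompany the study this package re-implements, so the
simulator is a first-class module: it generates cohorts with the
statistical structure the analysis assumes, and every end-to-end claim in
the test suite is exercised against it.

Generative model, per SNP:

* with probability `shared_fixation` (default 0.35) all lines are fixed for
  one shared allele. Shared fixation is a *subset* of line fixation, so a
  line's total fixation probability is exactly its configured `fixation`
  $f_\ell$; with $f = 0.86/0.71/0.78$ the default 0.35 puts the across-line
  same-allele fixed fraction near 0.40
  ($c + (1-c)\prod_\ell\frac{f_\ell - c}{1-c}\cdot\frac{1}{4} \approx 0.40$,
  the factor $\tfrac14$ being the chance three independently fixed lines
  chose one common allele);
* otherwise each line independently fixes a line-chosen allele with the
  residual probability, and is segregating otherwise.

Segregating sites are organised into LD blocks (mean `ld_block_snps` = 20
SNPs): per line and block a pool of `pool_haplotypes` = 4 haplotypes is
drawn, each segregating site carrying both alleles within the pool, and
every animal draws two pool haplotypes per block. Neighbouring SNPs
therefore co-segregate — the mechanism behind the blocks-of-significant-SNPs
phenomenon — and genotypes follow within-line Hardy–Weinberg at the
realized pool frequencies. Target MAFs come from $0.5\,\mathrm{Beta}$
with mean `maf_mean` = 0.24, but the small pool coarsens realized
frequencies to multiples of $1/4$, so realized segregating-site MAF means
run nearer 0.30. Fixation proportions are unaffected (pool conditioning
guarantees segregating sites stay polymorphic, so realized fixation equals
$f_\ell$ up to binomial noise), and no quantitative claim in this package
depends on the realized MAF mean.

Outcomes: a pair mismatched (under the locus's model) at ≥ 1 causal locus
is rejected with the locus penetrance (jointly $1-\prod(1-p_i)$ over
mismatched causal loci), otherwise with `background_rejection`. The default
architecture is a *single* directional causal locus with penetrance 0.9
over a 2% background: the published per-block outcome distributions are
each ≥ 18/20 concordant with outcome under both models, which implies one
dominant causal mismatch pattern with near-complete penetrance, and a
directional mismatch being a subset of the symmetric mismatch at the same
locus lets a single locus produce signal under both models. Several
independent causal loci of partial penetrance — superficially plausible —
cannot produce per-locus concordance that high.

What the simulator does **not** model: the lines' actual breeding history
(founder bottlenecks, drift; within-line HWE at segregating sites is a
simplification), sex-specific X inheritance (X is simulated as autosomal;
Y is excluded from analysis by design), genotyping error, and assembly
ambiguity (simulated maps have one clean coordinate system). Passing tests
on synthetic cohorts therefore validate the statistical machinery, not the
biology of any particular real cohort.

## Problem sizes and numerical choices

The analysis scripts and tests run at desk scale by choice: 6,000-SNP
cohorts (array-proportional chromosome layout), 10,000 permutations in the
worked example, 2,000 loci in the calibration suite, 20 seeds in the
power check, and one full-array run (59,852 SNPs × 27 animals) for
fixation recovery. Thresholds stabilise well below these permutation
counts for ~20-pair cohorts because the null maximum takes few distinct
values. All randomness flows from explicit seeds; the permutation sampler
is bit-reproducible given its seed, and exhaustive and sampled modes agree
on small cohorts where both apply.

Degenerate inputs are given defined answers rather than errors where a
convention is defensible (zero-marginal tables score 0; all-identical
outcomes give threshold 0; empty significant sets give empty block tables)
and errors where silence would corrupt results (non-biallelic loci,
unresolved sample ids, single-class outcomes in the scan, model mismatch
between scan and threshold).

## Known limitations

* With ~20 pairs the scan detects only near-deterministic effects; the
  power check plants penetrance-1 loci for exactly that reason.
* The test is anti-conservative pointwise at this sample size; only
  permutation-thresholded calls should be reported.
* Blocks are a reporting device; the gap rule does not estimate LD.
* Printed spans for blocks containing reassigned or unknown-position
  members depend on the positioned subset and on assembly vintage; spans
  across assemblies are not comparable and are not reconstructed here.
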