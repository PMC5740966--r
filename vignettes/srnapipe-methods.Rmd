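---
title: "Methods: small RNA profiling of paired tumor/normal libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling of paired tumor/normal libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

# Scope and model

`srnapipe` implements the standard analysis of a paired tumor/non-tumor
small RNA sequencing cohort:

1. **Read cleaning** — 3' adapter removal, mean-quality and ambiguity
   filtering, retention of 18–30 nt inserts.
2. **Tag annotation** — collapsing reads to unique tags and assigning each
   tag to exactly one small RNA class through a priority cascade
   (miRNA > rRNA > tRNA > snRNA > snoRNA > scRNA > repeat > exon > intron >
   unannotated), giving a per-library composition table.
3. **miRNA expression profiling** — TPM normalization, per-pair
   tumor/normal fold-change classes, paired t-tests across patients, and a
   clustered log-ratio matrix.
4. **miRNA editing** — single-mismatch variants of mature miRNAs among the
   unannotated tags, with seed-region classification and per-sample
   edited/wild-type summaries; A-to-I editing appears as an A-to-G
   substitution in sequencing because inosine pairs like guanosine.
5. **Pathway enrichment** — hypergeometric tests of predicted miRNA target
   genes against pathway gene sets, Bonferroni-corrected, separately for
   up- and down-regulated miRNA sets.

A synthetic-data module simulates paired cohorts with a complete ground
truth so that every stage can be validated by parameter recovery.

# Statistical procedures

**Paired t-test.** All tumor-versus-normal comparisons of composition or
editing percentages use the paired t statistic
$t = \bar d / (s_d/\sqrt{n})$ on per-patient differences, with $n-1$
degrees of freedom, one-tailed where a direction is asserted. Degenerate
all-zero differences report $t = 0$ with one-tailed $p = 0.5$. The
per-miRNA differential-expression test is the same statistic on
$\log_2(\mathrm{TPM}+1)$, two-tailed. The test statistic itself is not
novel; it delegates to `stats::t.test()` and is checked in the test suite
against the closed-form df = 2 CDF $P(T \le t) = 1/2 + t/(2\sqrt{2+t^2})$.

**Hypergeometric enrichment.** For a pathway of $K$ genes within a
universe of $N$, with $n$ selected genes and overlap $k$, the reported
p-value is the upper tail $P(X \ge k)$ from `stats::phyper`, validated
against exhaustive subset enumeration for all instances with $N \le 12$.
Bonferroni correction multiplies by the number of pathways that intersect
the universe.

**Rounding.** Report-facing percentages use half-up rounding to 2
decimals (`round_half_up()`), matching the convention of the published
tables; base R's half-to-even rounding disagrees at `.xx5` boundaries.

# Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_len`, `max_len` | 18, 30 nt | retained insert length range |
| `min_mean_q` | 20 | minimum mean Phred score; "low quality" is not defined upstream, so a conventional Q20 mean is used |
| adapter seed | first 8 nt, ≤1 mismatch, earliest hit | adapter localisation rule; fixed so trimming is bit-reproducible |
| `min_count` (grey rule) | 5 reads | a pair member below this makes the pair's fold change *missing* |
| ratio classes | >2 up; (1/2, 2] unchanged; ≤1/2 down | per-pair fold-change classes |
| `min_detect_fraction` | 0.5 | detection filter: count ≥ 1 in more than half the samples |
| `min_avg_reads` | 100 | abundance filter defining the DE set |
| `pseudo` | 0.01 TPM | symmetric pseudo-count for pair ratios (zero TPM ratios are otherwise undefined) |
| seed window | positions 2–8 | seed region of the mature miRNA, 1-based from the 5' end |

Design choices that the upstream description leaves open, fixed here:

* **Adapter algorithm.** No trimmer is named upstream; the 8 nt seed with
  at most one mismatch and earliest-match-wins is documented so results
  are exactly reproducible. Because the earliest hit wins, re-cleaning
  already-cleaned reads is a no-op (idempotence is tested). A false seed
  hit inside a genuine insert mis-trims roughly 0.6% of reads; this is a
  property of all seed-based trimmers.
* **Reads with no adapter hit** are kept only when their full length is
  already ≤ `max_len`: a longer read without an adapter cannot have its
  insert sized.
* **N-containing reads are dropped**: exact-match annotation requires
  unambiguous bases.
* **Annotation priority among the structural RNA classes**
  (rRNA > tRNA > snRNA > snoRNA > scRNA > repeat) is not dictated by the
  data model; it is fixed (and configurable) so that the partition of tags
  is deterministic. miRNA matches accept containment in either the mature
  or the precursor sequence.
* **Genome mapping** is an exact-match (0-mismatch) substring index over
  both strands rather than an external aligner: mapping here is
  interchangeable infrastructure, while the cascade logic is the analysis.
  Multi-locus hits do not split counts; a tag's whole count goes to its
  single highest-priority category.
* **TPM denominator** is the count matrix's own column totals — total
  miRNA-assigned reads when the matrix is miRNA-only. Passing a broader
  matrix changes the denominator accordingly.
* **DE statistic.** The upstream description reports fold change and
  p-value without naming the per-miRNA test; a paired t-test on
  log2(TPM+1), two-tailed at α = 0.05, matches the paired design and the
  t-test used elsewhere in the analysis. No multiplicity correction is
  applied to the DE p-values, mirroring the original report.
* **Editing pool.** "Edited" counts include *every* single-mismatch tag
  (12 substitution types reported separately); `a_to_g_only = TRUE`
  restricts to the A-to-I proxy. Tag length must equal the mature length:
  no indels, no 5'/3' isomiR offsets. A tag at distance one from several
  matures goes to the mature with the higher same-sample wild-type count
  (ties: lexicographic id) — an invented but deterministic rule.
* **Enrichment universe** defaults to all genes in the target map, and the
  Bonferroni multiplier is the number of pathways intersecting the
  universe.
* **Cluster distances** are Euclidean over the cells two profiles share
  (not rescaled by missingness as `stats::dist` would); profiles sharing
  no cells sit at the maximum observed distance; rows are pre-sorted by
  miRNA id so leaf order is deterministic.

# The synthetic cohort generator

The generator (`build_reference()`, `sim_profile()`, `simulate_library()`,
`simulate_cohort()`) emulates the sequenced cohort: 10 patients, paired
non-tumor/tumor libraries, with per-library depth jittered ±20% (published
library totals vary roughly that much around their mean).

* **Reference.** A random genome embedding mature miRNAs (20–23 nt) inside
  precursors (70–90 nt), plus non-overlapping loci for the other classes.
  Windows resembling the adapter's 8 nt seed (either orientation, ≤1
  mismatch) are scrubbed from the genome so that no genuine insert can
  trigger a false adapter trim — the synthetic analogue of designing
  adapters against the transcriptome.
* **Category fractions** default to a miRNA-dominated mixture (66% miRNA,
  7% rRNA, ~22% unannotated, small structural classes) patterned on the
  published composition table.
* **Abundances** are log-normal (sdlog 2 by default), reproducing the
  observed many-orders-of-magnitude dynamic range in which a handful of
  miRNAs dominate the pool.
* **Biological variability**: each library re-draws every miRNA's weight
  with log-normal jitter (sdlog 0.75). This value was calibrated against
  the published per-patient editing percentages, whose cross-patient
  standard deviation (~5 percentage points) and paired-difference spread
  (~5.6) the simulation reproduces (~4.3 and ~6.0).
* **Editing rates** per miRNA come from a Beta(1.2, 4) component plus a
  near-saturated Beta(20, 2) component (10% of miRNAs), reflecting
  reported cases where the edited form dominates or reaches 100% of the
  pool. In `seed_biased` mode an edited read carries A→G at an adenosine
  in the seed window when one exists; otherwise (and in `uniform` mode) a
  random substitution at a random position.
* **Lengths** follow a discrete 18–30 nt distribution with its mode at
  21–22 nt, matching the observed 20–23 nt peak.
* **Quality model**: constant Phred 38 for good reads; 2% of reads at
  Phred 10 emulate the low-quality fraction removed during cleaning.

Every library carries a truth manifest (realized category counts,
per-miRNA totals, edited counts with positions) sufficient to compute all
downstream expectations without re-reading the FASTQ. Truth is identical
whether or not read sequences are materialised, so count-level studies can
skip read emission.

**What the generator does not model:** sequencing errors beyond the
low-quality class, PCR duplication, FFPE degradation profiles, isomiR
length heterogeneity, genomic SNPs (which in real data can masquerade as
editing), and cross-mapping artifacts. Passing recovery tests therefore
demonstrates correctness of the pipeline's logic under clean conditions,
not robustness to those artifacts.

# Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
round-trips for every reader/writer pair; enumeration for the
hypergeometric tail; the df = 2 closed form for the paired t; conservation
identities (cleaning tally, tag counts, TPM column sums); and parameter
recovery on simulated libraries (category fractions and per-miRNA editing
rates within 3σ binomial bounds). Monte-Carlo operating characteristics
use deliberately desk-scale sizes: 20,000-read libraries for single-library
checks, 25 cohorts of 10 pairs at 20,000 reads for differential-expression
power (≥80% at |log2FC| = 2) and null rejection (≤10%, which includes the
systematic compositional shift TPM normalization imposes on null miRNAs
when strongly deregulated miRNAs carry much of the pool — a known property
of library-size normalization, not a bug), 200 cohorts at 5,000 reads for
the editing comparison's type-I rate, and 50 cohorts for its power against
a +0.05 tumor editing-rate shift (run without the saturated rate component,
where a +0.05 shift would clip at 1 and the realized effect would be
smaller than nominal).

The packaged transcriptions of the published cohort tables serve as exact
regression fixtures. Two quirks of the printed tables are preserved rather
than corrected: per-category counts fall slightly short of the printed
per-library totals (gaps of 109–1,897 reads per library, origin unknown),
and one per-patient editing percentage (patient Q1, non-tumor) is
inconsistent with the formula that reproduces every other row. One printed
comparison (the scRNA composition p-value, 0.049) is not reproducible by a
paired one-tailed t-test on either printed or recomputed percentage
columns (both give ≈0.09) and is excluded from regression checks; the
printed miRNA comparison p-value appears truncated rather than rounded
(exact 0.0245).

# Known limitations

* Exact-match annotation is stricter than mismatch-tolerant genome
  mapping: real degraded or polymorphic tags that an aligner would place
  are unannotated here.
* Editing detection cannot distinguish A-to-I editing from genomic SNPs or
  sequencing error without external variant data; counts are reported with
  per-substitution breakdowns so users can apply their own filters.
* The per-pair fold-change "missing" rule and detection filters reproduce
  the published thresholds verbatim; they are heuristics, not inference.
* With 10 pairs the paired t-test has limited power for small composition
  shifts, and percentages near 0 or 100 violate normality; the published
  convention is followed regardless.
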