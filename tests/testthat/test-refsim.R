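test_that("reference construction is deterministic and internally consistent", {
  r1 <- build_reference(n_mirnas = 5, n_other_loci = 2, seed = 0)
  r2 <- build_reference(n_mirnas = 5, n_other_loci = 2, seed = 0)
  expect_identical(r1$mature, r2$mature)
  expect_identical(as.character(r1$genome), as.character(r2$genome))

  # every mature sequence is retrievable from the genome at its interval
  ref <- demo_ref()
  genome <- as.character(ref$genome)[[1]]
  gr <- ref$categories[ref$categories$category == "miRNA_mature"]
  for (i in seq_along(gr)) {
    s <- substr(genome, GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
    if (as.character(GenomicRanges::strand(gr))[i] == "-") s <- revcomp(s)
    expect_identical(s, unname(ref$mature[[gr$locus_id[i]]]))
  }
  # and is contained in its precursor
  for (id in names(ref$mature)) {
    expect_true(grepl(ref$mature[[id]], ref$precursor[[paste0("pre-", id)]],
                      fixed = TRUE))
  }
  expect_true(all(GenomicRanges::end(ref$categories) <=
                    Biostrings::width(ref$genome)))
  expect_error(build_reference(10, 2, seed = 1, genome_length = 100),
               "genome_length")
})

test_that("mature miRNA sequences do not collide across 50 seeded references", {
  all_matures <- unlist(lapply(1:50, function(s)
    build_reference(n_mirnas = 5, n_other_loci = 1, seed = s)$mature))
  expect_false(anyDuplicated(all_matures) > 0)
})

test_that("profile validation enforces fraction and rate invariants", {
  prof <- demo_profile()
  expect_equal(sum(prof$category_fractions), 1, tolerance = 1e-12)
  bad <- prof
  bad$category_fractions[["miRNA"]] <- 0.9
  expect_error(validate_profile(bad), "sum to 1")
  bad <- prof
  bad$editing_rate[1] <- 1.5
  expect_error(validate_profile(bad), "editing rates")
  bad <- prof
  bad$adapter <- "ACGT"
  expect_error(validate_profile(bad), "at least 8 nt")
})

test_that("simulated libraries honor the profile's degenerate settings", {
  ref <- demo_ref()
  prof <- demo_profile()
  prof$editing_rate[] <- 0
  prof$tumor_editing_rate[] <- 0
  lib <- simulate_library(ref, prof, seed = 3, emit_reads = FALSE)
  expect_true(all(lib$truth$edited_counts == 0))
  expect_equal(nrow(lib$truth$edit_events), 0L)

  prof2 <- demo_profile()
  prof2$category_fractions <- c(miRNA = 1.0)
  lib2 <- simulate_library(ref, prof2, seed = 4, emit_reads = FALSE)
  expect_equal(unname(lib2$truth$category_counts[["miRNA"]]),
               prof2$n_reads)
  expect_equal(sum(lib2$truth$mirna_counts), prof2$n_reads)
})

test_that("truth manifests account for every read and every edit", {
  lib <- demo_library()
  tr <- lib$truth
  expect_equal(sum(tr$category_counts), tr$n_reads)
  expect_equal(sum(tr$mirna_counts), unname(tr$category_counts[["miRNA"]]))
  expect_equal(sum(tr$edit_events$count), sum(tr$edited_counts))
  expect_true(all(tr$edited_counts <= tr$mirna_counts))
  expect_equal(tr$n_good + tr$n_low_quality, tr$n_reads)
  # identical seed reproduces the library bit for bit
  again <- simulate_library(demo_ref(), demo_profile(), seed = 11,
                            sample_name = "Q1N")
  expect_identical(again$reads, lib$reads)
  expect_identical(again$truth, lib$truth)
  # reads are insert + adapter: every read carries the adapter seed
  expect_true(all(grepl(substr(demo_profile()$adapter, 1, 8),
                        lib$reads$sequence[1:200], fixed = TRUE)))
})

test_that("truth is unchanged when read emission is skipped", {
  a <- simulate_library(demo_ref(), demo_profile(), seed = 21)
  b <- simulate_library(demo_ref(), demo_profile(), seed = 21,
                        emit_reads = FALSE)
  expect_identical(a$truth, b$truth)
  expect_null(b$reads)
})

test_that("realized miRNA fraction lands in the binomial 99% interval", {
  prof <- demo_profile(n_reads = 200000L)
  prof$category_fractions <- c(miRNA = 0.7, rRNA = 0.1, unannotated = 0.2)
  lib <- simulate_library(demo_ref(), prof, seed = 17, emit_reads = FALSE)
  p <- 0.7; n <- 200000
  half <- qnorm(0.995) * sqrt(p * (1 - p) / n)
  frac <- lib$truth$category_counts[["miRNA"]] / n
  expect_true(abs(frac - p) < half)
})

test_that("realized category fractions converge to the profile at depth 1e6", {
  prof <- demo_profile(n_reads = 1000000L)
  lib <- simulate_library(demo_ref(), prof, seed = 19, emit_reads = FALSE)
  n <- prof$n_reads
  for (cat in names(prof$category_fractions)) {
    p <- prof$category_fractions[[cat]]
    sigma <- sqrt(p * (1 - p) / n)
    expect_lt(abs(lib$truth$category_counts[[cat]] / n - p), 3 * sigma + 1e-9)
  }
})

test_that("cohorts are paired, labelled, and depth-jittered within bounds", {
  coh <- simulate_cohort(demo_ref(), demo_profile(n_reads = 5000L),
                         n_pairs = 10, seed = 5, emit_reads = FALSE)
  expect_length(coh$libraries, 20L)
  expect_setequal(coh$meta$patient, c(paste0("Q", 1:5), paste0("S", 1:5)))
  expect_equal(sum(coh$meta$tissue == "T"), 10L)
  depths <- vapply(coh$libraries, function(l) l$truth$n_reads, numeric(1))
  expect_true(all(depths >= 4000 & depths <= 6000))
  tumors <- vapply(coh$libraries, function(l) l$truth$tumor, logical(1))
  expect_identical(unname(tumors), coh$meta$tissue == "T")

  cm <- truth_counts_matrix(coh)
  expect_equal(dim(cm), c(25L, 20L))
  tot <- truth_editing_totals(coh)
  expect_equal(tot$edited + tot$wildtype,
               unname(vapply(coh$libraries,
                             function(l) sum(l$truth$mirna_counts),
                             numeric(1))))
})

test_that("a tumor editing-rate shift is detected in most seeded cohorts", {
  # 10 pairs, +0.05 editing rate in tumors, rates drawn without the
  # saturated component so the realized pooled shift equals the nominal one
  ref <- build_reference(n_mirnas = 50, n_other_loci = 3, seed = 7)
  hits <- vapply(1:50, function(s) {
    prof <- sim_profile(ref, seed = 500 + s, n_reads = 5000,
                        tumor_editing_delta = 0.05, saturated_fraction = 0)
    coh <- simulate_cohort(ref, prof, n_pairs = 10, seed = 7000 + s,
                           emit_reads = FALSE)
    tot <- truth_editing_totals(coh)
    tot$pct <- editing_percentage(tot$edited, tot$wildtype)
    compare_editing(tot)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("references and libraries round-trip through their on-disk formats", {
  dir <- withr::local_tempdir()
  ref <- build_reference(n_mirnas = 5, n_other_loci = 2, seed = 2)
  paths <- write_reference(ref, dir)
  expect_true(all(file.exists(paths)))
  mat <- read_fasta(paths[["mature"]])
  expect_equal(setNames(mat$sequence, mat$id), ref$mature)
  cats <- read_bed_categories(paths[["categories"]])
  expect_equal(length(cats), length(ref$categories))

  lib <- demo_library()
  fq <- file.path(dir, "lib.fq")
  write_fastq(lib$reads[1:1000, ], fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, lib$reads$sequence[1:1000])
})
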