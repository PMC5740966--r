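#' @importFrom stats rbeta
NULL

#' Build a toy reference set with known structure
#'
#' Constructs a random genome in which mature miRNAs are embedded inside
#' hairpin precursors, and loci for the other small RNA classes (rRNA,
#' tRNA, snRNA, snoRNA, scRNA, repeat, exon, intron) are placed without
#' overlapping any miRNA. All placements are deterministic for a fixed
#' seed. The result stands in for a genome + annotation track + mature
#' miRNA catalogue when no real reference is supplied.
#'
#' @param n_mirnas Number of mature miRNA / precursor pairs (>= 1).
#' @param n_other_loci Loci per non-miRNA category (>= 1).
#' @param seed Integer RNG seed.
#' @param genome_length Optional fixed genome length; an error is raised if
#'   the requested loci do not fit.
#' @param adapter_guard 3' adapter whose first 8 nt are kept out of the
#'   genome (to within one mismatch, both orientations), so that no genuine
#'   insert can trigger a false adapter trim; mirrors how sequencing
#'   adapters are designed against the transcriptome. `NULL` disables the
#'   scrub.
#' @return An object of class `reference_set`: list with `genome`
#'   (named [Biostrings::DNAStringSet]), `categories` (GRanges with a
#'   `category` column, 0-based half-open on disk via BED), `mature` and
#'   `precursor` (named character vectors of oriented sequences).
#' @export
build_reference <- function(n_mirnas = 50, n_other_loci = 5, seed = 0,
                            genome_length = NULL,
                            adapter_guard = "TGGAATTCTCGGGTGCCAAGG") {
  if (n_mirnas < 1 || n_other_loci < 1)
    stop("locus counts must be >= 1", call. = FALSE)
  other_cats <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "repeat",
                  "exon", "intron")
  withr::with_seed(seed, {
    pre_len <- sample(70:90, n_mirnas, replace = TRUE)
    mat_len <- sample(20:23, n_mirnas, replace = TRUE)
    mat_off <- vapply(seq_len(n_mirnas),
                      function(i) sample.int(pre_len[i] - mat_len[i] + 1L, 1L),
                      integer(1))
    oth_len <- sample(80:200, length(other_cats) * n_other_loci, replace = TRUE)
    n_loci <- n_mirnas + length(oth_len)
    gaps <- sample(20:50, n_loci + 1L, replace = TRUE)
    widths <- c(pre_len, oth_len)
    starts <- gaps[1] + cumsum(c(0L, widths[-n_loci] + gaps[2:n_loci]))
    needed <- starts[n_loci] + widths[n_loci] + gaps[n_loci + 1L]
    if (is.null(genome_length)) genome_length <- needed
    if (genome_length < needed)
      stop("requested loci need ", needed, " bases but genome_length is ",
           genome_length, call. = FALSE)
    genome_seq <- random_dna(genome_length)
    if (!is.null(adapter_guard))
      genome_seq <- scrub_adapter_sites(genome_seq,
                                        substr(toupper(adapter_guard), 1, 8))
    strand <- sample(c("+", "-"), n_loci, replace = TRUE)

    pre_start <- starts[seq_len(n_mirnas)]
    pre_end <- pre_start + pre_len - 1L
    # mature offset is measured along the oriented precursor
    mat_start <- ifelse(strand[seq_len(n_mirnas)] == "+",
                        pre_start + mat_off - 1L,
                        pre_end - mat_off - mat_len + 2L)
    mat_end <- mat_start + mat_len - 1L

    oriented <- function(s, e, str) {
      x <- substring(genome_seq, s, e)
      ifelse(str == "+", x, revcomp(x))
    }
    mir_ids <- sprintf("mir-%03d", seq_len(n_mirnas))
    mature <- setNames(oriented(mat_start, mat_end,
                                strand[seq_len(n_mirnas)]), mir_ids)
    precursor <- setNames(oriented(pre_start, pre_end,
                                   strand[seq_len(n_mirnas)]),
                          paste0("pre-", mir_ids))
    if (anyDuplicated(mature))
      stop("random mature miRNA sequences collided; use another seed",
           call. = FALSE)

    oth_idx <- n_mirnas + seq_along(oth_len)
    gr <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(
        start = c(mat_start, pre_start, starts[oth_idx]),
        end = c(mat_end, pre_end, starts[oth_idx] + oth_len - 1L)),
      strand = c(strand[seq_len(n_mirnas)], strand[seq_len(n_mirnas)],
                 strand[oth_idx]),
      category = c(rep("miRNA_mature", n_mirnas),
                   rep("miRNA_precursor", n_mirnas),
                   rep(other_cats, each = n_other_loci)),
      locus_id = c(mir_ids, paste0("pre-", mir_ids),
                   paste0(rep(other_cats, each = n_other_loci), "-",
                          seq_len(n_other_loci)))
    )
    genome <- Biostrings::DNAStringSet(setNames(genome_seq, "chr1"))
    ref <- structure(list(genome = genome, categories = gr,
                          mature = mature, precursor = precursor),
                     class = "reference_set")
    # oriented locus sequences cached once; the simulator samples from
    # these every library
    ref$locus_seqs <- setNames(
      lapply(other_cats, function(cat) extract_locus_sequences(ref, cat)),
      other_cats)
    ref
  })
}

# Redraw every genome window matching `seed8` (either orientation, <= 1
# mismatch) until none remains, so adapter detection cannot fire inside a
# genuine insert.
scrub_adapter_sites <- function(genome_seq, seed8) {
  pats <- unique(c(seed8, revcomp(seed8)))
  for (iter in 1:100) {
    subj <- Biostrings::DNAString(genome_seq)
    hits <- do.call(rbind, lapply(pats, function(p) {
      m <- Biostrings::matchPattern(p, subj, max.mismatch = 1)
      cbind(Biostrings::start(m), Biostrings::end(m))
    }))
    if (is.null(hits) || nrow(hits) == 0L) return(genome_seq)
    for (r in seq_len(nrow(hits))) {
      w <- hits[r, 2] - hits[r, 1] + 1L
      substr(genome_seq, hits[r, 1], hits[r, 2]) <- random_dna(w)
    }
  }
  stop("could not scrub adapter-like sites from the genome", call. = FALSE)
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: genome %d bp, %d mature miRNAs, %d loci\n",
              sum(Biostrings::width(x$genome)), length(x$mature),
              length(x$categories)))
  invisible(x)
}

#' Extract the oriented sequence of category loci
#'
#' @param ref A `reference_set`.
#' @param category A category label present in `ref$categories`.
#' @return Named character vector of strand-oriented locus sequences.
#' @export
locus_sequences <- function(ref, category) {
  if (!is.null(ref$locus_seqs) && category %in% names(ref$locus_seqs))
    return(ref$locus_seqs[[category]])
  extract_locus_sequences(ref, category)
}

extract_locus_sequences <- function(ref, category) {
  gr <- ref$categories[ref$categories$category == category]
  if (length(gr) == 0L) return(setNames(character(0), character(0)))
  chrom <- as.character(ref$genome)[as.character(GenomicRanges::seqnames(gr))]
  seqs <- substring(chrom, GenomicRanges::start(gr), GenomicRanges::end(gr))
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  setNames(seqs, gr$locus_id)
}

#' Default simulation profile for a paired tumor/normal library
#'
#' Encodes the cohort conditions the simulator emulates: library category
#' fractions patterned on the published composition table (miRNA-dominated,
#' with an unannotated remainder), log-normal mature-miRNA abundances,
#' per-miRNA editing rates drawn from a mixture with a near-saturated
#' component, insert lengths peaking at 21-22 nt within 18-30 nt, a 3'
#' adapter appended to every insert, and a small low-quality read fraction.
#'
#' @param ref A `reference_set` (provides the miRNA catalogue).
#' @param seed Seed for the profile-level random draws (abundances, fold
#'   changes, editing rates).
#' @param category_fractions Named fractions over the insert classes;
#'   must sum to 1.
#' @param n_reads Reads per library before depth jitter.
#' @param abundance_sdlog Log-normal sdlog for miRNA abundance weights.
#' @param biological_cv Log-scale standard deviation of the per-library
#'   abundance jitter (between-sample biological variability applied to
#'   every miRNA independently in each simulated library).
#' @param n_de Number of miRNAs given a tumor fold change (half up,
#'   half down).
#' @param de_log2fc Absolute tumor log2 fold change for those miRNAs.
#' @param saturated_fraction Fraction of miRNAs whose editing rate is drawn
#'   from the near-saturated Beta(20, 2) component (the remainder uses
#'   Beta(1.2, 4)).
#' @param tumor_editing_delta Added to every miRNA's editing rate in tumor
#'   libraries (clamped to \[0, 1\]).
#' @param edit_position_mode `"seed_biased"` (A-to-G at an adenosine in the
#'   seed window when one exists) or `"uniform"` (any position, any
#'   substitution).
#' @param adapter 3' adapter sequence (>= 8 nt).
#' @param low_quality_fraction Fraction of reads emitted at the low mean
#'   Phred; defaults to 2%.
#' @param good_phred,low_phred Constant Phred scores for good and
#'   low-quality reads.
#' @param read_length Raw read length (bases; inserts are padded with the
#'   adapter and random bases up to this length).
#' @return An object of class `sim_profile`.
#' @export
sim_profile <- function(ref, seed = 0,
                        category_fractions = c(
                          miRNA = 0.66, rRNA = 0.07, tRNA = 0.005,
                          snRNA = 0.003, snoRNA = 0.003, scRNA = 0.002,
                          `repeat` = 0.002, exon = 0.03, intron = 0.005,
                          unannotated = 0.22),
                        n_reads = 200000L,
                        abundance_sdlog = 2,
                        biological_cv = 0.75,
                        n_de = 0L, de_log2fc = 2,
                        saturated_fraction = 0.1,
                        tumor_editing_delta = 0,
                        edit_position_mode = c("seed_biased", "uniform"),
                        adapter = "TGGAATTCTCGGGTGCCAAGG",
                        low_quality_fraction = 0.02,
                        good_phred = 38L, low_phred = 10L,
                        read_length = 50L) {
  edit_position_mode <- match.arg(edit_position_mode)
  mir_ids <- names(ref$mature)
  m <- length(mir_ids)
  withr::with_seed(seed, {
    abund <- setNames(rlnorm(m, meanlog = 0, sdlog = abundance_sdlog), mir_ids)
    lfc <- setNames(rep(0, m), mir_ids)
    if (n_de > 0L) {
      if (n_de > m) stop("n_de exceeds the number of miRNAs", call. = FALSE)
      de <- sample(mir_ids, n_de)
      n_up <- ceiling(n_de / 2)
      lfc[de[seq_len(n_up)]] <- de_log2fc
      lfc[de[-seq_len(n_up)]] <- -de_log2fc
    }
    sat <- runif(m) < saturated_fraction
    erate <- ifelse(sat, rbeta(m, 20, 2), rbeta(m, 1.2, 4))
    erate <- setNames(erate, mir_ids)
  })
  profile <- structure(list(
    category_fractions = category_fractions,
    mirna_abundances = abund,
    biological_cv = biological_cv,
    tumor_log2fc = lfc,
    editing_rate = erate,
    tumor_editing_rate = setNames(pmin(1, pmax(0, erate + tumor_editing_delta)),
                                  mir_ids),
    edit_position_mode = edit_position_mode,
    adapter = toupper(adapter),
    n_reads = as.integer(n_reads),
    # relative weight of each insert length 18..30; mode at 21-22
    length_weights = setNames(
      c(1, 2, 6, 10, 9, 5, 2, 1, 0.5, 0.5, 0.3, 0.2, 0.2), 18:30),
    low_quality_fraction = low_quality_fraction,
    good_phred = as.integer(good_phred),
    low_phred = as.integer(low_phred),
    read_length = as.integer(read_length)), class = "sim_profile")
  validate_profile(profile)
  profile
}

#' Validate a simulation profile
#' @param profile A `sim_profile`.
#' @return The profile, invisibly; errors on violated invariants.
#' @export
validate_profile <- function(profile) {
  f <- profile$category_fractions
  if (any(f < 0 | f > 1) || abs(sum(f) - 1) > 1e-9)
    stop("category fractions must lie in [0, 1] and sum to 1", call. = FALSE)
  if (any(profile$editing_rate < 0 | profile$editing_rate > 1) ||
      any(profile$tumor_editing_rate < 0 | profile$tumor_editing_rate > 1))
    stop("editing rates must lie in [0, 1]", call. = FALSE)
  if (nchar(profile$adapter) < 8L)
    stop("adapter must be at least 8 nt", call. = FALSE)
  if (profile$n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  invisible(profile)
}

# Draw insert lengths from the profile's 18..30 nt model.
draw_lengths <- function(profile, n) {
  if (n == 0L) return(integer(0))
  sample(18:30, n, replace = TRUE, prob = profile$length_weights)
}

#' Simulate one small RNA library with ground truth
#'
#' Inserts are drawn per the profile's category fractions; miRNA inserts
#' follow the abundance weights (scaled by `2^tumor_log2fc` when
#' `tumor = TRUE`), and each miRNA read is independently edited with that
#' miRNA's editing rate: one substitution, A-to-G at an adenosine in the
#' seed window (positions 2-8) in `seed_biased` mode when one exists,
#' otherwise a uniformly placed random substitution. Non-miRNA inserts are
#' substrings of category loci; `unannotated` inserts are random sequences.
#' Every read is the insert plus the 3' adapter, padded with random bases
#' to the read length; a configured fraction is emitted at low quality.
#'
#' @param ref A `reference_set`.
#' @param profile A `sim_profile`.
#' @param seed Integer RNG seed for this library.
#' @param tumor Apply tumor fold changes and tumor editing rates?
#' @param sample_name Label recorded in the truth manifest.
#' @param emit_reads If `FALSE`, skip materialising read sequences and
#'   return the truth manifest only (fast path for count-level studies).
#' @return List with `reads` (data.frame `id`, `sequence`, `quality`, or
#'   `NULL`) and `truth` (class `sim_truth`): realized category counts,
#'   per-miRNA total and edited read counts, the per-event edit table
#'   (miRNA, position, ref, obs, count), low-quality read count and seed.
#' @export
simulate_library <- function(ref, profile, seed = 0, tumor = FALSE,
                             sample_name = "S1", emit_reads = TRUE) {
  validate_profile(profile)
  withr::with_seed(seed, {
    fr <- profile$category_fractions
    n <- profile$n_reads
    cat_counts <- setNames(as.integer(rmultinom(1, n, fr)), names(fr))

    mir_ids <- names(ref$mature)
    w <- profile$mirna_abundances
    if (tumor) w <- w * 2^profile$tumor_log2fc
    if (profile$biological_cv > 0)
      w <- w * rlnorm(length(w), 0, profile$biological_cv)
    n_mir <- if ("miRNA" %in% names(cat_counts)) cat_counts[["miRNA"]] else 0L
    mir_counts <- setNames(as.integer(rmultinom(1, n_mir, w)), mir_ids)
    rates <- if (tumor) profile$tumor_editing_rate else profile$editing_rate
    edited_counts <- setNames(rbinom(length(mir_ids), mir_counts,
                                     rates[mir_ids]), mir_ids)

    # truth-relevant draws first, so emit_reads does not change the truth
    edit_rows <- list()
    mir_inserts <- list()
    for (id in mir_ids[mir_counts > 0L]) {
      mseq <- ref$mature[[id]]
      len <- nchar(mseq)
      ne <- edited_counts[[id]]
      nw <- mir_counts[[id]] - ne
      eseq <- character(0)
      if (ne > 0L) {
        seed_a <- which(strsplit(substr(mseq, 2, min(8L, len)), "")[[1]] == "A") + 1L
        if (profile$edit_position_mode == "seed_biased" && length(seed_a) > 0L) {
          pos <- seed_a[sample.int(length(seed_a), ne, replace = TRUE)]
          obs <- rep("G", ne)
        } else {
          pos <- sample.int(len, ne, replace = TRUE)
          obs <- vapply(pos, function(p) {
            sample(setdiff(c("A", "C", "G", "T"), substr(mseq, p, p)), 1L)
          }, character(1))
        }
        eseq <- rep(mseq, ne)
        substr(eseq, pos, pos) <- obs
        edit_rows[[id]] <- data.frame(
          mirna = id, position = pos,
          ref = substring(mseq, pos, pos), obs = obs,
          stringsAsFactors = FALSE)
      }
      mir_inserts[[id]] <- c(rep(mseq, nw), eseq)
    }

    other_cats <- setdiff(names(fr), c("miRNA", "unannotated"))
    other_draws <- list()
    for (cat in other_cats) {
      nc <- cat_counts[[cat]]
      if (nc == 0L) next
      loci <- locus_sequences(ref, cat)
      if (length(loci) == 0L)
        stop("reference has no loci for category ", cat, call. = FALSE)
      L <- draw_lengths(profile, nc)
      li <- sample.int(length(loci), nc, replace = TRUE)
      lw <- nchar(loci)[li]
      L <- pmin(L, lw)
      st <- 1L + floor(runif(nc) * (lw - L + 1))
      other_draws[[cat]] <- substring(loci[li], st, st + L - 1L)
    }
    n_unann <- if ("unannotated" %in% names(fr)) cat_counts[["unannotated"]] else 0L
    unann_len <- draw_lengths(profile, n_unann)
    n_low <- rbinom(1, n, profile$low_quality_fraction)

    edits <- if (length(edit_rows)) {
      agg <- do.call(rbind, edit_rows)
      out <- aggregate(list(count = rep(1L, nrow(agg))),
                       agg[c("mirna", "position", "ref", "obs")], sum)
      out[order(out$mirna, out$position, out$obs), , drop = FALSE]
    } else {
      data.frame(mirna = character(0), position = integer(0),
                 ref = character(0), obs = character(0), count = integer(0))
    }
    truth <- structure(list(
      sample = sample_name, tumor = tumor, seed = seed, n_reads = n,
      category_counts = cat_counts, mirna_counts = mir_counts,
      edited_counts = edited_counts, edit_events = edits,
      n_low_quality = n_low, n_good = n - n_low), class = "sim_truth")

    reads <- NULL
    if (emit_reads) {
      inserts <- c(unlist(mir_inserts, use.names = FALSE),
                   unlist(other_draws, use.names = FALSE),
                   random_dna(unann_len))
      low <- c(rep(TRUE, n_low), rep(FALSE, n - n_low))
      perm <- sample.int(n)
      inserts <- inserts[perm]
      tail_len <- pmax(0L, profile$read_length - nchar(inserts) -
                         nchar(profile$adapter))
      seqs <- substr(paste0(inserts, profile$adapter, random_dna(tail_len)),
                     1L, profile$read_length)
      qchar <- ifelse(low, intToUtf8(profile$low_phred + 33L),
                      intToUtf8(profile$good_phred + 33L))
      reads <- data.frame(
        id = sprintf("%s_read_%07d", sample_name, seq_len(n)),
        sequence = seqs,
        quality = strrep(qchar, nchar(seqs)),
        stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth %s (%s): %d reads, %d miRNA, %d edited, %d low-quality\n",
              x$sample, if (x$tumor) "tumor" else "normal", x$n_reads,
              sum(x$mirna_counts), sum(x$edited_counts), x$n_low_quality))
  invisible(x)
}

#' Simulate a paired tumor/normal cohort
#'
#' Generates `2 * n_pairs` libraries labelled `(patient, N|T)`. Tumor
#' members apply the profile's tumor fold changes and tumor editing rates;
#' each library's depth is jittered uniformly within +/-20% of the
#' profile's `n_reads`.
#'
#' @param ref A `reference_set`.
#' @param base_profile A `sim_profile` shared by all libraries.
#' @param n_pairs Number of patients (>= 1); 10 patients are labelled
#'   Q1-Q5 and S1-S5, other sizes P1, P2, ...
#' @param seed Integer RNG seed; per-library seeds are derived from it.
#' @param emit_reads Materialise read sequences? (`FALSE` keeps only truth.)
#' @param depth_jitter Half-width of the relative depth jitter.
#' @return An object of class `sim_cohort`: list with `libraries` (named
#'   list of `simulate_library()` results) and `meta` (data.frame
#'   `sample`, `patient`, `tissue`).
#' @export
simulate_cohort <- function(ref, base_profile, n_pairs = 10, seed = 0,
                            emit_reads = TRUE, depth_jitter = 0.2) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  patients <- if (n_pairs == 10) c(paste0("Q", 1:5), paste0("S", 1:5))
              else paste0("P", seq_len(n_pairs))
  meta <- data.frame(
    sample = paste0(rep(patients, each = 2), c("N", "T")),
    patient = rep(patients, each = 2),
    tissue = rep(c("N", "T"), n_pairs),
    stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    lib_seeds <- sample.int(.Machine$integer.max - 1L, nrow(meta))
    jit <- runif(nrow(meta), 1 - depth_jitter, 1 + depth_jitter)
  })
  libraries <- lapply(seq_len(nrow(meta)), function(i) {
    p <- base_profile
    p$n_reads <- max(1L, as.integer(round(base_profile$n_reads * jit[i])))
    simulate_library(ref, p, seed = lib_seeds[i],
                     tumor = meta$tissue[i] == "T",
                     sample_name = meta$sample[i], emit_reads = emit_reads)
  })
  names(libraries) <- meta$sample
  structure(list(libraries = libraries, meta = meta), class = "sim_cohort")
}

#' miRNA count matrix from a cohort's truth manifests
#'
#' @param cohort A `sim_cohort`.
#' @return An `expr_matrix` of realized per-miRNA read counts
#'   (miRNA x sample), unit `"counts"`.
#' @export
truth_counts_matrix <- function(cohort) {
  counts <- vapply(cohort$libraries, function(l) l$truth$mirna_counts,
                   numeric(length(cohort$libraries[[1]]$truth$mirna_counts)))
  expression_matrix(counts, cohort$meta$patient, cohort$meta$tissue,
                    unit = "counts")
}

#' Per-sample edited/wild-type totals from a cohort's truth manifests
#'
#' @param cohort A `sim_cohort`.
#' @return Data.frame `patient`, `tissue`, `edited`, `wildtype` summed over
#'   miRNAs (wildtype = miRNA reads without an edit).
#' @export
truth_editing_totals <- function(cohort) {
  ed <- vapply(cohort$libraries, function(l) sum(l$truth$edited_counts),
               numeric(1))
  wt <- vapply(cohort$libraries,
               function(l) sum(l$truth$mirna_counts - l$truth$edited_counts),
               numeric(1))
  data.frame(patient = cohort$meta$patient, tissue = cohort$meta$tissue,
             edited = unname(ed), wildtype = unname(wt),
             stringsAsFactors = FALSE)
}

#' Write a reference set to FASTA + BED
#'
#' @param ref A `reference_set`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             categories = file.path(dir, "categories.bed"),
             mature = file.path(dir, "mature.fa"),
             precursor = file.path(dir, "precursor.fa"))
  Biostrings::writeXStringSet(ref$genome, paths[["genome"]])
  write_bed_categories(ref$categories, paths[["categories"]])
  write_fasta(data.frame(id = names(ref$mature), sequence = ref$mature),
              paths[["mature"]])
  write_fasta(data.frame(id = names(ref$precursor), sequence = ref$precursor),
              paths[["precursor"]])
  invisible(paths)
}

#' Synthetic pathway collection
#'
#' Random gene sets over a universe, for enrichment testing; the first
#' pathway can later be spiked into a selected gene set.
#'
#' @param universe Character vector of gene ids.
#' @param n_pathways Number of pathways.
#' @param size_range Inclusive range of pathway sizes.
#' @param seed Integer RNG seed.
#' @return Named list of gene sets with a `description` attribute,
#'   writable by [write_gmt()].
#' @export
simulate_pathways <- function(universe, n_pathways = 200,
                              size_range = c(10, 50), seed = 0) {
  withr::with_seed(seed, {
    sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(universe, min(s, length(universe))))
  })
  names(sets) <- sprintf("PW%04d", seq_len(n_pathways))
  attr(sets, "description") <- setNames(
    sprintf("synthetic pathway %d", seq_len(n_pathways)), names(sets))
  sets
}

#' Synthetic miRNA-to-target map
#'
#' @param mirna_ids miRNA identifiers.
#' @param universe Gene universe to draw targets from.
#' @param targets_per_mirna Inclusive range of target counts per miRNA.
#' @param seed Integer RNG seed.
#' @return Named list miRNA -> unique target genes.
#' @export
simulate_target_map <- function(mirna_ids, universe,
                                targets_per_mirna = c(20, 200), seed = 0) {
  withr::with_seed(seed, {
    out <- lapply(mirna_ids, function(id) {
      k <- sample(targets_per_mirna[1]:targets_per_mirna[2], 1L)
      sample(universe, min(k, length(universe)))
    })
  })
  setNames(out, mirna_ids)
}
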