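ANNOT_PRIORITY <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                    "repeat", "exon_sense", "exon_antisense", "intron_sense",
                    "intron_antisense", "unannotated")

#' Build an exact-match annotation index
#'
#' Precomputes searchable subjects for the annotation cascade: the mature
#' and precursor miRNA catalogue, one concatenated oriented-sequence
#' subject per non-miRNA category, and both genome strands. Lookups are
#' exact (0-mismatch) full-length containment; genome mapping software is
#' deliberately replaced by this deterministic index since the cascade
#' logic, not the aligner, is the analysis.
#'
#' @param ref A `reference_set`.
#' @param priority Category priority order (highest first); `unannotated`
#'   must come last.
#' @return An object of class `annotation_index`.
#' @export
build_index <- function(ref, priority = ANNOT_PRIORITY) {
  if (utils::tail(priority, 1) != "unannotated")
    stop("'unannotated' must be the lowest-priority category", call. = FALSE)
  subjects <- list()
  for (cat in c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "repeat",
                "exon", "intron")) {
    seqs <- locus_sequences(ref, cat)
    subjects[[cat]] <- if (length(seqs)) paste(seqs, collapse = "N") else ""
  }
  genome_fwd <- paste(as.character(ref$genome), collapse = "N")
  structure(list(
    mature = ref$mature,
    mirna_subject = paste(c(ref$mature, ref$precursor), collapse = "N"),
    subjects = subjects,
    genome_fwd = genome_fwd,
    genome_rev = revcomp(genome_fwd),
    priority = priority), class = "annotation_index")
}

# TRUE for each tag that occurs verbatim in `subject`.
subject_hit <- function(tags, subject) {
  if (!nzchar(subject)) return(rep(FALSE, length(tags)))
  vapply(tags, grepl, logical(1), x = subject, fixed = TRUE,
         USE.NAMES = FALSE)
}

#' Classify tags through the annotation cascade
#'
#' Each tag is assigned to exactly one category, the first match in the
#' priority order miRNA > rRNA > tRNA > snRNA > snoRNA > scRNA > repeat >
#' exon (sense, then antisense) > intron (sense, then antisense) >
#' unannotated. A miRNA match is exact full-length containment in a mature
#' or precursor sequence; exon/intron sense means the tag matches the
#' annotated strand's sequence, antisense means its reverse complement
#' does; the remaining structural RNA classes accept either orientation.
#'
#' @param tags Tag data.frame (`sequence`, `count`) or character vector.
#' @param index An `annotation_index`.
#' @return Character vector of category labels, one per tag. Tags
#'   containing N never match and fall through to `unannotated`.
#' @export
classify_tags <- function(tags, index) {
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  n <- length(seqs)
  category <- rep("unannotated", n)
  open <- rep(TRUE, n)
  rc <- revcomp(seqs)
  for (cat in index$priority) {
    if (!any(open) || cat == "unannotated") break
    idx <- which(open)
    hit <- switch(cat,
      miRNA = subject_hit(seqs[idx], index$mirna_subject),
      exon_sense = subject_hit(seqs[idx], index$subjects[["exon"]]),
      exon_antisense = subject_hit(rc[idx], index$subjects[["exon"]]),
      intron_sense = subject_hit(seqs[idx], index$subjects[["intron"]]),
      intron_antisense = subject_hit(rc[idx], index$subjects[["intron"]]),
      subject_hit(seqs[idx], index$subjects[[cat]]) |
        subject_hit(rc[idx], index$subjects[[cat]]))
    category[idx[hit]] <- cat
    open[idx[hit]] <- FALSE
  }
  category
}

#' Per-sample library composition table
#'
#' Read-count weighted category composition of one or more classified tag
#' sets, in the shape of the published composition table: per (sample,
#' category) a read count and a percentage of the sample total, rounded
#' half-up to two decimals.
#'
#' @param samples Named list; each element a tag data.frame with columns
#'   `sequence`, `count`, `category`.
#' @return Data.frame `sample`, `category`, `count`, `pct` with every
#'   category of the cascade present for every sample (zero-filled);
#'   per-sample totals are attached as the `totals` attribute.
#' @export
composition_table <- function(samples) {
  if (is.data.frame(samples)) samples <- list(sample = samples)
  stopifnot(length(samples) > 0, !is.null(names(samples)))
  rows <- lapply(names(samples), function(s) {
    tags <- samples[[s]]
    if (!all(c("count", "category") %in% names(tags)))
      stop("each sample needs 'count' and 'category' columns", call. = FALSE)
    counts <- setNames(numeric(length(ANNOT_PRIORITY)), ANNOT_PRIORITY)
    agg <- tapply(tags$count, tags$category, sum)
    counts[names(agg)] <- agg
    total <- sum(counts)
    data.frame(sample = s, category = ANNOT_PRIORITY,
               count = unname(counts),
               pct = if (total > 0) round_half_up(unname(counts) / total * 100, 2)
                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "totals") <- vapply(samples, function(t) sum(t$count), numeric(1))
  out
}

#' Genome mapping rate of a tag set
#'
#' Read-count weighted fraction of reads whose tag occurs verbatim in the
#' genome on either strand.
#'
#' @param tags Tag data.frame (`sequence`, `count`).
#' @param index An `annotation_index`.
#' @return Fraction in \[0, 1\].
#' @export
mapping_rate <- function(tags, index) {
  if (nrow(tags) == 0L) return(NaN)
  hit <- subject_hit(tags$sequence, index$genome_fwd) |
    subject_hit(tags$sequence, index$genome_rev)
  sum(tags$count[hit]) / sum(tags$count)
}
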