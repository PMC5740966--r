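#' @importFrom stats p.adjust phyper pt sd setNames t.test rbinom rlnorm
#'   rmultinom runif hclust as.dist complete.cases aggregate
#' @importFrom utils head read.delim write.table
NULL

CATEGORY_LABELS <- c("miRNA_mature", "miRNA_precursor", "rRNA", "tRNA",
                     "snRNA", "snoRNA", "scRNA", "repeat", "exon", "intron")

#' Read a FASTA file
#'
#' Sequences are upper-cased; record order is preserved. The file is
#' structurally validated first so malformed input is reported with a line
#' number; parsing itself is delegated to [Biostrings::readDNAStringSet()].
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence`, and `quality`
#'   (all `NA` for FASTA).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (!startsWith(lines[nonempty[1]], ">"))
    stop("malformed FASTA: line ", nonempty[1],
         " precedes any '>' header", call. = FALSE)
  headers <- which(startsWith(lines, ">"))
  for (h in headers) {
    if (!nzchar(trimws(sub("^>", "", lines[h]))))
      stop("malformed FASTA: empty header at line ", h, call. = FALSE)
    nxt <- c(headers, length(lines) + 1L)
    nxt <- min(nxt[nxt > h])
    body <- lines[seq.int(h + 1L, length.out = max(0L, nxt - h - 1L))]
    if (sum(nchar(trimws(body))) == 0L)
      stop("malformed FASTA: record at line ", h,
           " has an empty sequence", call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(seqs),
             sequence = toupper(as.character(seqs)),
             quality = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records Data.frame with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  check_reads(records)
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Expects the 4-line-per-record layout. Structural problems (truncated
#' record, sequence/quality length mismatch) are reported with line numbers.
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `id`, `sequence` (upper case), and
#'   `quality` (Phred+33 string; decode with [phred_scores()]).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: truncated record at line ",
         4L * (length(lines) %/% 4L) + 1L, call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  if (!all(startsWith(lines[idx], "@")))
    stop("malformed FASTQ: header without '@' at line ",
         idx[which(!startsWith(lines[idx], "@"))[1]], call. = FALSE)
  if (!all(startsWith(lines[idx + 2L], "+")))
    stop("malformed FASTQ: separator without '+' at line ",
         idx[which(!startsWith(lines[idx + 2L], "+"))[1]] + 2L, call. = FALSE)
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ: sequence/quality length mismatch at line ",
         idx[bad[1]] + 3L, call. = FALSE)
  data.frame(id = sub("^@", "", lines[idx]),
             sequence = toupper(seqs),
             quality = quals,
             stringsAsFactors = FALSE)
}

#' Write records to FASTQ (Phred+33)
#'
#' @param records Data.frame with `id`, `sequence`, `quality` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  check_reads(records, need_quality = TRUE)
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(records$quality))
  invisible(path)
}

#' Load a packaged published summary table
#'
#' Returns the packaged transcription of one of the study's printed tables:
#' `table1` (per-library composition counts and percentages), `table4`
#' (per-patient edited / wild-type miRNA read counts), `table5`
#' (per-patient hsa-let-7e-5p edited / wild-type counts). Counts are exact
#' as printed and never recomputed.
#'
#' @param name One of `"table1"`, `"table4"`, `"table5"`.
#' @return A data.frame keyed by `(patient, tissue)`; tissue is `N`
#'   (non-tumor) or `T` (tumor).
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("table1", "table4", "table5"))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; expected one of table1, table4, table5", call. = FALSE)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "srnapipe",
                      mustWork = TRUE)
  out <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "fixture") <- name
  out
}

#' Read category annotations from BED6
#'
#' The BED name field carries the annotation category label; coordinates are
#' 0-based half-open (standard BED) and the strand is retained.
#'
#' @param path Path to a BED6 file.
#' @return A [GenomicRanges::GRanges] with a `category` metadata column.
#' @export
read_bed_categories <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  labels <- as.character(gr$name)
  bad <- setdiff(unique(labels), CATEGORY_LABELS)
  if (length(bad))
    stop("unknown category label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(CATEGORY_LABELS, collapse = ", "),
         call. = FALSE)
  gr$category <- labels
  gr
}

#' Write category annotations to BED6
#'
#' @param gr A GRanges with a `category` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_categories <- function(gr, path) {
  out <- gr
  out$name <- out$category
  out$score <- 0L
  out$category <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read pathway gene sets from GMT
#'
#' GMT lines are `set-id <TAB> description <TAB> member...`. Duplicate set
#' ids are an error; an empty member list is kept (with a warning) so that
#' set sizes remain auditable.
#'
#' @param path Path to a GMT file.
#' @return A named list of unique gene-symbol character vectors; pathway
#'   descriptions are attached as the `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop("malformed GMT: fewer than 2 fields at line ", short[1],
         call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate pathway id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
  names(sets) <- ids
  if (any(lengths(sets) == 0L))
    warning("pathway(s) with empty member list: ",
            paste(ids[lengths(sets) == 0L], collapse = ", "), call. = FALSE)
  attr(sets, "description") <- setNames(
    vapply(fields, `[[`, character(1), 2L), ids)
  sets
}

#' Write pathway gene sets to GMT
#'
#' @param sets Named list of gene vectors; optional `description` attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-to-target-gene map
#'
#' A two-column TSV (header `mirna`, `gene`; one pair per row), as produced
#' by exporting an interaction database query.
#'
#' @param path Path to the TSV.
#' @return Named list mapping each miRNA id to its unique target genes.
#' @export
read_target_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tab)))
    stop("target map needs columns 'mirna' and 'gene'", call. = FALSE)
  lapply(split(tab$gene, tab$mirna), unique)
}

#' Write a miRNA-to-target-gene map
#' @param map Named list of gene vectors per miRNA.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(map, path) {
  tab <- data.frame(
    mirna = rep(names(map), lengths(map)),
    gene = unlist(map, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
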