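#' Clean raw small RNA reads
#'
#' 3' adapter removal followed by quality, ambiguity and length filtering.
#' The adapter is located by matching its first 8 nt against the read with
#' at most one mismatch; the earliest hit wins and the read is truncated
#' before it. Reads with no adapter hit are kept only if they are already
#' short enough to be a complete insert (`<= max_len`). After trimming,
#' reads are discarded (first matching reason counts in the tally) when
#' their mean Phred score falls below `min_mean_q`, when they contain an N,
#' or when the trimmed length lies outside `[min_len, max_len]`.
#'
#' @param reads Data.frame with `id`, `sequence`, `quality` (Phred+33;
#'   `NA` qualities skip the quality filter).
#' @param adapter 3' adapter sequence, at least 8 nt.
#' @param min_len,max_len Retained insert length bounds (nt).
#' @param min_mean_q Minimum mean Phred score.
#' @return List with `reads` (cleaned data.frame, trimmed sequences and
#'   qualities) and `tally` (named integer vector: `input`, `retained`,
#'   and per-reason discard counts `low_quality`, `contains_n`,
#'   `too_short`, `too_long`, `no_adapter`).
#' @export
clean_reads <- function(reads, adapter, min_len = 18L, max_len = 30L,
                        min_mean_q = 20) {
  check_reads(reads, need_quality = TRUE)
  adapter <- toupper(adapter)
  if (nchar(adapter) < 8L)
    stop("adapter must be at least 8 nt, got ", nchar(adapter), call. = FALSE)
  n <- nrow(reads)
  tally <- c(input = n, retained = 0L, low_quality = 0L, contains_n = 0L,
             too_short = 0L, too_long = 0L, no_adapter = 0L)
  if (n == 0L) return(list(reads = reads, tally = tally))

  seed8 <- substr(adapter, 1L, 8L)
  hits <- Biostrings::vmatchPattern(seed8,
                                    Biostrings::DNAStringSet(reads$sequence),
                                    max.mismatch = 1, fixed = TRUE)
  first_hit <- vapply(IRanges::start(hits), function(s) {
    if (length(s) == 0L) NA_integer_ else min(s)
  }, integer(1))

  seq <- reads$sequence
  qual <- reads$quality
  trimmed <- !is.na(first_hit)
  end <- ifelse(trimmed, first_hit - 1L, nchar(seq))
  seq <- substr(seq, 1L, end)
  qual <- ifelse(is.na(qual), qual, substr(qual, 1L, end))

  len <- nchar(seq)
  meanq <- ifelse(is.na(qual) | len == 0L, Inf, mean_phred(qual))
  reason <- rep(NA_character_, n)
  reason[!trimmed & len > max_len] <- "no_adapter"
  sel <- is.na(reason) & meanq < min_mean_q
  reason[sel] <- "low_quality"
  sel <- is.na(reason) & grepl("N", seq, fixed = TRUE)
  reason[sel] <- "contains_n"
  sel <- is.na(reason) & len < min_len
  reason[sel] <- "too_short"
  sel <- is.na(reason) & len > max_len
  reason[sel] <- "too_long"

  keep <- is.na(reason)
  tab <- table(factor(reason, levels = c("low_quality", "contains_n",
                                         "too_short", "too_long",
                                         "no_adapter")))
  tally[names(tab)] <- as.integer(tab)
  tally[["retained"]] <- sum(keep)
  out <- data.frame(id = reads$id[keep], sequence = seq[keep],
                    quality = qual[keep], stringsAsFactors = FALSE)
  list(reads = out, tally = tally)
}

#' Collapse clean reads to unique tags
#'
#' @param reads Cleaned reads data.frame (or any data.frame with a
#'   `sequence` column).
#' @return Data.frame `sequence`, `count`, sorted by count (descending)
#'   then sequence; counts sum to the number of input reads.
#' @export
collapse_tags <- function(reads) {
  if (!is.data.frame(reads) || !"sequence" %in% names(reads))
    stop("reads must have a 'sequence' column", call. = FALSE)
  if (nrow(reads) == 0L)
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(reads$sequence)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-count weighted tag length distribution
#'
#' @param tags Tag data.frame (`sequence`, `count`).
#' @param range Lengths to report (zeros included).
#' @return Named integer vector: length -> total read count.
#' @export
length_distribution <- function(tags, range = 18:30) {
  len <- nchar(tags$sequence)
  hist <- setNames(integer(length(range)), range)
  agg <- tapply(tags$count, len, sum)
  shared <- intersect(names(agg), names(hist))
  hist[shared] <- as.integer(agg[shared])
  extra <- setdiff(names(agg), names(hist))
  if (length(extra)) {
    add <- setNames(as.integer(agg[extra]), extra)
    hist <- c(hist, add)[order(as.integer(names(c(hist, add))))]
  }
  hist
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the `tag_<i>_x<count>` convention so counts survive a
#' round trip through FASTA.
#'
#' @param tags Tag data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  write_fasta(data.frame(
    id = sprintf("tag_%d_x%d", seq_len(nrow(tags)), tags$count),
    sequence = tags$sequence, stringsAsFactors = FALSE), path)
}

#' Read collapsed tags from FASTA written by [write_tags()]
#' @param path Path to the tag FASTA.
#' @return Tag data.frame (`sequence`, `count`).
#' @export
read_tags <- function(path) {
  rec <- read_fasta(path)
  counts <- suppressWarnings(as.integer(sub(".*_x(\\d+)$", "\\1", rec$id)))
  if (anyNA(counts))
    stop("tag headers must end in _x<count>", call. = FALSE)
  data.frame(sequence = rec$sequence, count = counts, stringsAsFactors = FALSE)
}
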