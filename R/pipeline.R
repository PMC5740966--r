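#' Process one raw library through cleaning, collapsing, and annotation
#'
#' Convenience wrapper chaining [clean_reads()], [collapse_tags()],
#' [classify_tags()], and [length_distribution()] for a single library.
#'
#' @param reads Raw reads data.frame (`id`, `sequence`, `quality`).
#' @param adapter 3' adapter sequence.
#' @param index An `annotation_index` from [build_index()].
#' @param ... Passed to [clean_reads()].
#' @return List with `tags` (data.frame `sequence`, `count`, `category`),
#'   `tally` (cleaning tally), and `lengths` (tag length histogram).
#' @export
process_library <- function(reads, adapter, index, ...) {
  cleaned <- clean_reads(reads, adapter, ...)
  tags <- collapse_tags(cleaned$reads)
  tags$category <- if (nrow(tags)) classify_tags(tags, index) else character(0)
  list(tags = tags, tally = cleaned$tally,
       lengths = length_distribution(tags))
}

#' Wild-type miRNA read counts of a classified tag set
#'
#' Read counts of tags exactly equal to a mature miRNA sequence, the
#' denominator pool for editing percentages.
#'
#' @param tags Classified tag data.frame.
#' @param mature Named character vector of mature sequences.
#' @return Named numeric vector over all miRNAs (zero-filled).
#' @export
wildtype_counts <- function(tags, mature) {
  out <- setNames(numeric(length(mature)), names(mature))
  idx <- match(tags$sequence, mature)
  hit <- !is.na(idx)
  if (any(hit)) {
    agg <- tapply(tags$count[hit], names(mature)[idx[hit]], sum)
    out[names(agg)] <- agg
  }
  out
}
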