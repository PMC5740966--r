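SUBSTITUTION_TYPES <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, b, function(x, y) paste0(x, ">", y)))[as.vector(outer(b, b, "!="))]
}

#' Detect single-mismatch miRNA variants among unannotated tags
#'
#' A tag yields an edit event iff its length equals a mature miRNA's
#' length and exactly one position differs (all other positions exact);
#' tags with zero mismatches were absorbed by the annotation cascade
#' upstream and tags with two or more mismatches against every mature are
#' ignored. A tag at distance one from several matures is assigned to the
#' mature with the highest wild-type read count in the same sample, ties
#' broken lexicographically by miRNA id. Positions are 1-based from the 5'
#' end of the mature sequence; the seed window is positions 2-8.
#'
#' @param tags Unannotated tag data.frame (`sequence`, `count`).
#' @param mature Named character vector of mature miRNA sequences.
#' @param wildtype_counts Optional named vector of same-sample wild-type
#'   read counts per miRNA, used only to resolve multi-mature ties
#'   (missing miRNAs count as 0).
#' @return Data.frame of events: `mirna`, `position`, `ref`, `obs`,
#'   `in_seed`, `sequence`, `count`.
#' @export
detect_edits <- function(tags, mature, wildtype_counts = NULL) {
  if (length(mature) == 0L) stop("mature miRNA set is empty", call. = FALSE)
  empty <- data.frame(mirna = character(0), position = integer(0),
                      ref = character(0), obs = character(0),
                      in_seed = logical(0), sequence = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (nrow(tags) == 0L) return(empty)
  wt <- setNames(rep(0, length(mature)), names(mature))
  if (!is.null(wildtype_counts)) {
    shared <- intersect(names(wildtype_counts), names(wt))
    wt[shared] <- wildtype_counts[shared]
  }
  mat_raw <- lapply(mature, charToRaw)
  mat_len <- nchar(mature)
  by_len <- split(names(mature), mat_len)

  rows <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    s <- tags$sequence[i]
    cand <- by_len[[as.character(nchar(s))]]
    if (is.null(cand)) next
    sr <- charToRaw(s)
    mm <- vapply(mat_raw[cand], function(r) sum(r != sr), numeric(1))
    one <- cand[mm == 1]
    if (length(one) == 0L) next
    pick <- one[order(-wt[one], one)][1]
    pos <- which(mat_raw[[pick]] != sr)
    rows[[i]] <- data.frame(
      mirna = pick, position = pos,
      ref = substr(mature[[pick]], pos, pos),
      obs = substr(s, pos, pos),
      in_seed = pos >= 2L && pos <= 8L,
      sequence = s, count = tags$count[i], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$position, out$obs, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample editing summary (edited vs wild-type read counts)
#'
#' Totals the edited reads (optionally restricted to A-to-G events, the
#' sequencing signature of A-to-I editing) and the wild-type miRNA reads
#' per sample, with the percentage edited/(edited + wildtype) x 100
#' rounded half-up to 2 decimals, plus per-tissue total rows.
#'
#' @param events_by_sample Named list (sample -> event data.frame from
#'   [detect_edits()]).
#' @param wildtype_by_sample Named list or vector: per sample either a
#'   single wild-type read total or a named per-miRNA vector (summed).
#' @param meta Data.frame `sample`, `patient`, `tissue` covering the same
#'   sample names.
#' @param a_to_g_only Count only A>G events as edited?
#' @return Data.frame `patient`, `tissue`, `edited`, `wildtype`, `pct`
#'   with one `Total` row per tissue appended.
#' @export
editing_summary <- function(events_by_sample, wildtype_by_sample, meta,
                            a_to_g_only = FALSE) {
  stopifnot(all(meta$sample %in% names(events_by_sample)),
            all(meta$sample %in% names(wildtype_by_sample)))
  edited <- vapply(meta$sample, function(s) {
    ev <- events_by_sample[[s]]
    if (a_to_g_only) ev <- ev[ev$ref == "A" & ev$obs == "G", , drop = FALSE]
    sum(ev$count)
  }, numeric(1))
  wildtype <- vapply(meta$sample, function(s) sum(wildtype_by_sample[[s]]),
                     numeric(1))
  out <- data.frame(patient = meta$patient, tissue = meta$tissue,
                    edited = unname(edited), wildtype = unname(wildtype),
                    stringsAsFactors = FALSE)
  totals <- do.call(rbind, lapply(unique(out$tissue), function(ts) {
    data.frame(patient = "Total", tissue = ts,
               edited = sum(out$edited[out$tissue == ts]),
               wildtype = sum(out$wildtype[out$tissue == ts]),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(out, totals)
  out$pct <- editing_percentage(out$edited, out$wildtype)
  rownames(out) <- NULL
  out
}

#' Percentage of the miRNA pool carrying an edit
#'
#' `edited / (edited + wildtype) * 100`, half-up to 2 decimals; an edited
#' count with a zero wild-type pool reports 100, and an empty pool NA.
#'
#' @param edited,wildtype Non-negative read counts.
#' @return Numeric percentage vector.
#' @export
editing_percentage <- function(edited, wildtype) {
  total <- edited + wildtype
  ifelse(total == 0, NA_real_, round_half_up(edited / total * 100, 2))
}

#' Per-miRNA editing profile across samples
#'
#' @param events_by_sample Named list of event data.frames.
#' @param wildtype_by_sample Named list of per-miRNA wild-type count
#'   vectors (one per sample).
#' @param mirna_id The miRNA to profile.
#' @param meta Data.frame `sample`, `patient`, `tissue`.
#' @return List with `summary` (data.frame `patient`, `tissue`, `edited`,
#'   `wildtype`, `pct`) and `substitutions` (counts over the 12
#'   substitution types, summed over samples).
#' @export
per_mirna_editing <- function(events_by_sample, wildtype_by_sample, mirna_id,
                              meta) {
  known <- unique(unlist(lapply(wildtype_by_sample, names)))
  known <- union(known,
                 unique(unlist(lapply(events_by_sample, function(e) e$mirna))))
  if (!mirna_id %in% known)
    stop("unknown miRNA id: ", mirna_id, call. = FALSE)
  subs <- setNames(numeric(length(SUBSTITUTION_TYPES)), SUBSTITUTION_TYPES)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    s <- meta$sample[i]
    ev <- events_by_sample[[s]]
    ev <- ev[ev$mirna == mirna_id, , drop = FALSE]
    if (nrow(ev)) {
      t <- tapply(ev$count, paste0(ev$ref, ">", ev$obs), sum)
      subs[names(t)] <<- subs[names(t)] + t
    }
    wtv <- wildtype_by_sample[[s]]
    wt <- if (mirna_id %in% names(wtv)) wtv[[mirna_id]] else 0
    data.frame(patient = meta$patient[i], tissue = meta$tissue[i],
               edited = sum(ev$count), wildtype = wt,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary$pct <- editing_percentage(summary$edited, summary$wildtype)
  rownames(summary) <- NULL
  list(summary = summary, substitutions = subs)
}

#' Compare editing percentages between tumor and normal tissue
#'
#' Paired one-tailed t-test (tumor > normal) on the per-patient editing
#' percentage column, the same statistic used for the published
#' tumor-versus-normal editing comparison.
#'
#' @param summary Data.frame with `patient`, `tissue`, `pct` (Total rows
#'   are ignored); [editing_summary()] output or the packaged table.
#' @param alternative Direction of the alternative (default tumor > normal).
#' @return A `paired_t_test` object.
#' @export
compare_editing <- function(summary, alternative = "greater") {
  s <- summary[summary$patient != "Total", , drop = FALSE]
  patients <- unique(s$patient)
  tum <- vapply(patients, function(p)
    s$pct[s$patient == p & s$tissue == "T"][1], numeric(1))
  nor <- vapply(patients, function(p)
    s$pct[s$patient == p & s$tissue == "N"][1], numeric(1))
  if (anyNA(tum) || anyNA(nor))
    stop("incomplete tumor/normal pairs in the editing summary",
         call. = FALSE)
  if (length(patients) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  paired_t_test(tum, nor, alternative = alternative)
}
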