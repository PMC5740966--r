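#' Construct an expression matrix with sample metadata
#'
#' A thin wrapper around a numeric miRNA x sample matrix that carries the
#' paired design (patient, tissue N/T) and the unit (`counts` or `TPM`).
#'
#' @param values Numeric matrix, miRNAs in rows; row names required.
#' @param patients,tissues Per-column patient id and tissue (`"N"`/`"T"`).
#' @param unit `"counts"` or `"TPM"`.
#' @return An object of class `expr_matrix` (a matrix with `meta` and
#'   `unit` attributes; columns named `<patient><tissue>`).
#' @export
expression_matrix <- function(values, patients, tissues, unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("row names (miRNA ids) are required", call. = FALSE)
  if (length(patients) != ncol(values) || length(tissues) != ncol(values))
    stop("patients/tissues must match the number of columns", call. = FALSE)
  if (!all(tissues %in% c("N", "T")))
    stop("tissues must be 'N' or 'T'", call. = FALSE)
  if (unit == "counts" && any(values < 0))
    stop("counts must be non-negative", call. = FALSE)
  colnames(values) <- paste0(patients, tissues)
  structure(values,
            meta = data.frame(sample = colnames(values), patient = patients,
                              tissue = tissues, stringsAsFactors = FALSE),
            unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d miRNAs x %d samples\n",
              attr(x, "unit"), nrow(x), ncol(x)))
  invisible(x)
}

em_meta <- function(x) attr(x, "meta")
em_unit <- function(x) attr(x, "unit")

#' @export
`[.expr_matrix` <- function(x, i, j, drop = TRUE) {
  out <- unclass(x)[i, j, drop = drop]
  if (!is.matrix(out)) return(out)
  meta <- em_meta(x)[match(colnames(out), em_meta(x)$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(out, meta = meta, unit = em_unit(x),
            class = c("expr_matrix", "matrix", "array"))
}

#' Normalize counts to transcripts per million
#'
#' Column-wise `count * 1e6 / column total`; after normalization every
#' column sums to one million. The denominator is the matrix's own column
#' total, i.e. total miRNA-assigned reads per sample when the matrix is
#' miRNA-only (pass a matrix with extra rows to use a broader total).
#'
#' @param counts An `expr_matrix` with unit `"counts"`.
#' @return An `expr_matrix` with unit `"TPM"`.
#' @export
tpm_normalize <- function(counts) {
  if (em_unit(counts) != "counts")
    stop("input must be in counts", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  tpm <- sweep(unclass(counts), 2, totals, "/") * 1e6
  m <- em_meta(counts)
  expression_matrix(tpm, m$patient, m$tissue, unit = "TPM")
}

#' Detection and abundance filters
#'
#' Two published filters: detection (at least one count in more than
#' `min_detect_fraction` of samples) and abundance (average reads per
#' sample of at least `min_avg_reads`); the differential-expression set is
#' the abundance-filtered one.
#'
#' @param counts An `expr_matrix` with unit `"counts"`.
#' @param min_detect_fraction Fraction of samples that must detect the
#'   miRNA (strictly more than).
#' @param min_avg_reads Minimum average reads per sample (at least).
#' @return List with `detected` and `de_set` (character vectors of miRNA
#'   ids) and `report` (named counts: total, n_detected, n_de_set).
#' @export
detection_filters <- function(counts, min_detect_fraction = 0.5,
                              min_avg_reads = 100) {
  if (em_unit(counts) != "counts")
    stop("input must be in counts", call. = FALSE)
  detected <- rownames(counts)[rowSums(counts >= 1) > min_detect_fraction * ncol(counts)]
  de_set <- rownames(counts)[rowMeans(counts) >= min_avg_reads]
  list(detected = detected, de_set = de_set,
       report = c(total = nrow(counts), n_detected = length(detected),
                  n_de_set = length(de_set)))
}

FOLD_CLASSES <- c("up", "unchanged", "down", "missing")

#' Per-pair fold changes with expression classes
#'
#' For every miRNA and patient, the tumor/normal TPM ratio with a
#' symmetric pseudo-count, classified as `up` (ratio > 2), `unchanged`
#' (1/2 < ratio <= 2), `down` (ratio <= 1/2), or `missing` when either
#' member of the pair has a raw tag count below 5 (the cluster heat map's
#' grey rule).
#'
#' @param tpm An `expr_matrix` with unit `"TPM"`.
#' @param counts The matching `expr_matrix` of raw counts.
#' @param pseudo Pseudo-count added to both TPM values (default 0.01).
#' @param min_count Raw-count threshold below which a pair member counts
#'   as not expressed.
#' @return Data.frame `mirna`, `patient`, `ratio`, `log2_ratio`, `class`.
#' @export
pair_fold_changes <- function(tpm, counts, pseudo = 0.01, min_count = 5) {
  if (em_unit(tpm) != "TPM" || em_unit(counts) != "counts")
    stop("need a TPM matrix and a counts matrix", call. = FALSE)
  if (!identical(dim(tpm), dim(counts)) ||
      !identical(rownames(tpm), rownames(counts)))
    stop("tpm and counts matrices must be congruent", call. = FALSE)
  m <- em_meta(tpm)
  patients <- unique(m$patient)
  for (p in patients) {
    if (!all(c("N", "T") %in% m$tissue[m$patient == p]))
      stop("incomplete pair for patient ", p, call. = FALSE)
  }
  rows <- lapply(patients, function(p) {
    nc <- m$sample[m$patient == p & m$tissue == "N"]
    tc <- m$sample[m$patient == p & m$tissue == "T"]
    ratio <- (tpm[, tc] + pseudo) / (tpm[, nc] + pseudo)
    class <- ifelse(counts[, tc] < min_count | counts[, nc] < min_count,
                    "missing",
                    ifelse(ratio > 2, "up",
                           ifelse(ratio <= 0.5, "down", "unchanged")))
    data.frame(mirna = rownames(tpm), patient = p, ratio = unname(ratio),
               log2_ratio = unname(log2(ratio)), class = unname(class),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-miRNA paired differential-expression test
#'
#' Paired t-test on `log2(TPM + 1)`, tumor versus normal across patients,
#' two-tailed; direction is the sign of the mean paired difference.
#'
#' @param tpm An `expr_matrix` with unit `"TPM"`.
#' @param mirnas miRNAs to test (default: all rows); typically the
#'   abundance-filtered set from [detection_filters()].
#' @return Data.frame `mirna`, `mean_log2fc`, `t`, `p`, `direction`,
#'   sorted by p ascending.
#' @export
de_test <- function(tpm, mirnas = rownames(tpm)) {
  if (em_unit(tpm) != "TPM") stop("input must be TPM", call. = FALSE)
  m <- em_meta(tpm)
  patients <- unique(m$patient)
  if (length(patients) < 3)
    stop("need at least 3 complete pairs, got ", length(patients),
         call. = FALSE)
  ncol_ids <- vapply(patients, function(p)
    m$sample[m$patient == p & m$tissue == "N"], character(1))
  tcol_ids <- vapply(patients, function(p)
    m$sample[m$patient == p & m$tissue == "T"], character(1))
  lt <- log2(unclass(tpm)[mirnas, tcol_ids, drop = FALSE] + 1)
  ln <- log2(unclass(tpm)[mirnas, ncol_ids, drop = FALSE] + 1)
  res <- lapply(seq_along(mirnas), function(i) {
    fit <- paired_t_test(lt[i, ], ln[i, ], alternative = "two_sided")
    data.frame(mirna = mirnas[i], mean_log2fc = fit$mean_diff, t = fit$t,
               p = fit$p,
               direction = if (fit$mean_diff >= 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clustered log2-ratio matrix of per-pair fold changes
#'
#' Builds the miRNA x patient matrix of `log2(ratio)` with `missing`
#' cells as NA, then orders rows and columns by average-linkage
#' hierarchical clustering on Euclidean distance computed over the cells
#' both profiles share. Rows with no non-missing cell are dropped with a
#' warning; profiles sharing no cells are placed at the maximum observed
#' distance. Input rows are pre-sorted by miRNA id so ties resolve
#' deterministically.
#'
#' @param pfc Output of [pair_fold_changes()].
#' @return List with `matrix` (reordered), `row_order`, `col_order`, and
#'   the two `hclust` trees (`row_hclust`, `col_hclust`; NULL when fewer
#'   than 3 leaves).
#' @export
cluster_matrix <- function(pfc) {
  mirnas <- sort(unique(pfc$mirna))
  patients <- sort(unique(pfc$patient))
  mat <- matrix(NA_real_, length(mirnas), length(patients),
                dimnames = list(mirnas, patients))
  ok <- pfc$class != "missing"
  mat[cbind(pfc$mirna[ok], pfc$patient[ok])] <- pfc$log2_ratio[ok]
  all_na <- rowSums(!is.na(mat)) == 0
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " miRNA(s) with no non-missing pair",
            call. = FALSE)
    mat <- mat[!all_na, , drop = FALSE]
  }
  shared_dist <- function(x) {
    n <- nrow(x)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      sh <- !is.na(x[i, ]) & !is.na(x[j, ])
      d[i, j] <- d[j, i] <- if (any(sh))
        sqrt(sum((x[i, sh] - x[j, sh])^2)) else NA_real_
    }
    if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE) + 1
    d
  }
  order_of <- function(x) {
    if (nrow(x) < 3L)
      return(list(order = seq_len(nrow(x)), tree = NULL))
    hc <- hclust(as.dist(shared_dist(x)), method = "average")
    list(order = hc$order, tree = hc)
  }
  ro <- order_of(mat)
  co <- order_of(t(mat))
  list(matrix = mat[ro$order, co$order, drop = FALSE],
       row_order = rownames(mat)[ro$order],
       col_order = colnames(mat)[co$order],
       row_hclust = ro$tree, col_hclust = co$tree)
}

#' Most abundant miRNAs in a sample group
#'
#' @param counts An `expr_matrix` with unit `"counts"`.
#' @param tissue `"N"` or `"T"`: the group whose libraries are pooled.
#' @param k Number of miRNAs to report.
#' @return Data.frame `mirna`, `pct` (percentage of the group's total
#'   miRNA reads), descending; percentages of the listed rows sum to at
#'   most 100.
#' @export
top_abundance <- function(counts, tissue, k = 10) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  m <- em_meta(counts)
  cols <- m$sample[m$tissue == tissue]
  pooled <- rowSums(unclass(counts)[, cols, drop = FALSE])
  pct <- pooled / sum(pooled) * 100
  ord <- order(-pct, names(pct))
  out <- data.frame(mirna = names(pct)[ord], pct = unname(pct[ord]),
                    stringsAsFactors = FALSE)
  head(out, k)
}

#' Relative quantification by the delta-Ct method
#'
#' `2^-(Ct_target - Ct_reference)`: expression of the assayed miRNA (or
#' mRNA) relative to the endogenous reference in the same sample.
#'
#' @param ct_target,ct_reference Finite Ct values (vectors recycle).
#' @return Relative expression.
#' @export
ddct_relative_quantification <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite", call. = FALSE)
  2^(-(ct_target - ct_reference))
}
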