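#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' by the report tables. Base `round()` rounds half to even, which disagrees
#' with printed percentages at the .xx5 boundary.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode Phred+33 quality strings
#'
#' @param quality Character vector of ASCII-encoded quality strings.
#' @return A list of integer vectors (one per string) of per-base Phred
#'   scores; a single string yields a list of length one.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) {
    if (is.na(q)) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

#' Mean Phred score per read
#' @param quality Character vector of Phred+33 strings.
#' @return Numeric vector of per-read mean scores (NaN for empty strings).
#' @keywords internal
mean_phred <- function(quality) {
  vapply(quality, function(q) {
    if (is.na(q) || !nzchar(q)) return(NaN)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

# Random DNA of given lengths, one string per element of `len`.
random_dna <- function(len) {
  total <- sum(len)
  if (total == 0) return(character(length(len)))
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  starts <- cumsum(c(1L, len[-length(len)]))
  vapply(seq_along(len), function(i) {
    if (len[i] == 0L) return("")
    paste0(bases[starts[i]:(starts[i] + len[i] - 1L)], collapse = "")
  }, character(1))
}

# Stop unless x is a reads data frame with id/sequence columns.
check_reads <- function(x, need_quality = FALSE) {
  if (!is.data.frame(x) || !all(c("id", "sequence") %in% names(x)))
    stop("reads must be a data.frame with columns 'id' and 'sequence'",
         call. = FALSE)
  if (need_quality && !"quality" %in% names(x))
    stop("reads must carry a 'quality' column", call. = FALSE)
  invisible(x)
}
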