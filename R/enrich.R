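#' Union of predicted target genes of a miRNA set
#'
#' @param mirnas Character vector of miRNA ids.
#' @param target_map Named list miRNA -> target genes ([read_target_map()]).
#' @return Character vector of unique target genes; miRNAs absent from the
#'   map contribute nothing and are reported via a message.
#' @export
aggregate_targets <- function(mirnas, target_map) {
  missing <- setdiff(mirnas, names(target_map))
  if (length(missing))
    message("no target-map entry for: ", paste(missing, collapse = ", "))
  genes <- unique(unlist(target_map[intersect(mirnas, names(target_map))],
                         use.names = FALSE))
  if (length(genes) == 0L)
    warning("empty target gene set", call. = FALSE)
  genes
}

#' Hypergeometric pathway enrichment
#'
#' One upper-tail hypergeometric test per pathway: the probability of
#' drawing at least the observed number of pathway members when selecting
#' the target genes from the universe. Pathways are intersected with the
#' universe first; pathways with no universe member are not tested.
#' Bonferroni correction runs over all tested pathways.
#'
#' @param genes Selected gene set (e.g. [aggregate_targets()] output).
#' @param pathways Named list of pathway gene sets ([read_gmt()]).
#' @param universe Gene universe; defaults to all genes in the pathway
#'   collection. Typical use passes all genes of the target map.
#' @param alpha_report Keep rows with raw p below this (NULL keeps all).
#' @return Data.frame `pathway`, `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   sorted by raw p then pathway id.
#' @export
pathway_enrichment <- function(genes, pathways, universe = NULL,
                               alpha_report = 0.001) {
  if (is.null(universe))
    universe <- unique(unlist(pathways, use.names = FALSE))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  genes <- intersect(unique(genes), universe)
  desc <- attr(pathways, "description")
  members <- lapply(pathways, intersect, y = universe)
  tested <- names(members)[lengths(members) > 0L]
  if (length(tested) == 0L)
    return(data.frame(pathway = character(0), term = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE))
  K <- lengths(members[tested])
  k <- vapply(members[tested], function(mm) length(intersect(genes, mm)),
              integer(1))
  n <- length(genes)
  N <- length(universe)
  p <- vapply(seq_along(tested), function(i)
    hypergeometric_tail(k[i], K[i], n, N), numeric(1))
  out <- data.frame(
    pathway = tested,
    term = if (is.null(desc)) NA_character_ else unname(desc[tested]),
    k = unname(k), K = unname(K), n = n, N = N, p = unname(p),
    p_adj = multiplicity_correct(unname(p)),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  if (!is.null(alpha_report))
    out <- out[out$p < alpha_report, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direction-separated enrichment of up- and down-regulated miRNA targets
#'
#' Runs [aggregate_targets()] and [pathway_enrichment()] independently for
#' the up- and down-regulated miRNA sets, as in the published pathway
#' table's Up/Down blocks.
#'
#' @param up,down Character vectors of miRNA ids.
#' @param target_map Named list miRNA -> target genes.
#' @param pathways Named list of pathway gene sets.
#' @param universe Gene universe; defaults to all genes in the target map.
#' @param alpha_report Row filter on raw p (NULL keeps all).
#' @return Data.frame as [pathway_enrichment()] plus a `direction` column.
#' @export
enrich_directions <- function(up, down, target_map, pathways,
                              universe = NULL, alpha_report = 0.001) {
  if (is.null(universe))
    universe <- unique(unlist(target_map, use.names = FALSE))
  run <- function(mirnas, dir) {
    res <- pathway_enrichment(aggregate_targets(mirnas, target_map),
                              pathways, universe, alpha_report)
    if (nrow(res)) res$direction <- dir else res$direction <- character(0)
    res
  }
  out <- rbind(run(up, "up"), run(down, "down"))
  rownames(out) <- NULL
  out
}
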