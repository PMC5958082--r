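#' Fisher exact enrichment of a target set in a cluster
#'
#' One-sided (greater) Fisher's exact test of the 2x2 table
#' `[[k, m-k], [K-k, N-m-K+k]]`, where `k` is the overlap between the
#' cluster and the target set, `m` the cluster size, `K` the target-set
#' size and `N` the universe size — all after restricting cluster and
#' set to the universe (set members outside the universe, e.g. genes
#' not on the array, are dropped with a message). The one-sided p is the
#' exact hypergeometric upper tail, summed directly.
#'
#' @param cluster_genes Character vector of cluster member genes.
#' @param gene_set One entry of a [gene_set_collection()], or a
#'   character vector of target genes.
#' @param universe Character vector of all background genes (typically
#'   every gene tested on the array after collapsing).
#' @return A one-row `data.frame`: `regulator`, `kind`, `family`, `k`,
#'   `m`, `K`, `N_universe`, `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(cluster_genes, gene_set, universe) {
  if (is.character(gene_set)) {
    gene_set <- list(name = "set", kind = NA_character_,
                     family = NA_character_, members = gene_set)
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  cluster <- intersect(unique(as.character(cluster_genes)), universe)
  if (length(cluster) == 0) {
    stop("empty cluster (after restriction to universe)", call. = FALSE)
  }
  members <- unique(gene_set$members)
  dropped <- setdiff(members, universe)
  if (length(dropped)) {
    message("dropping ", length(dropped), " target(s) of ", gene_set$name,
            " absent from the universe")
  }
  targets <- intersect(members, universe)
  k <- length(intersect(cluster, targets))
  m <- length(cluster)
  K <- length(targets)
  N <- length(universe)
  p <- hyper_upper_tail(k, K, m, N)
  odds <- (k * (N - m - K + k)) / ((m - k) * (K - k))
  data.frame(regulator = gene_set$name, kind = gene_set$kind,
             family = gene_set$family,
             k = k, m = m, K = K, N_universe = N,
             odds_ratio = odds, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enrichment of every regulator target set against every cluster
#'
#' Runs [fisher_enrichment()] for each (cluster, target set) pair.
#' Following the low-stringency screening this pipeline implements, no
#' multiple-testing correction is applied; a regulator is enriched when
#' its one-sided p is strictly below `p_threshold` (default 0.01).
#'
#' @param clusters Named list of cluster member gene vectors (from
#'   [cluster_members()]).
#' @param collections A [gene_set_collection()] or list of them
#'   (e.g. miRNA and TF sets).
#' @param universe Background gene universe.
#' @param p_threshold Uncorrected p cutoff, exclusive (default 0.01).
#' @param keep_all Return all tests with a `significant` flag instead of
#'   only the enriched ones.
#' @return A `data.frame` of [fisher_enrichment()] rows plus
#'   `cluster_id` and `significant`, ordered by (cluster, p, regulator).
#' @export
enrich_all <- function(clusters, collections, universe,
                       p_threshold = 0.01, keep_all = FALSE) {
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  sets <- do.call(c, lapply(collections, unclass))
  rows <- list()
  for (cl in names(clusters)) {
    if (length(clusters[[cl]]) == 0) next
    for (s in sets) {
      res <- fisher_enrichment(clusters[[cl]], s, universe)
      res$cluster_id <- cl
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cluster_id = character(0), regulator = character(0),
                      kind = character(0), family = character(0),
                      k = integer(0), m = integer(0), K = integer(0),
                      N_universe = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < p_threshold
  out <- out[order(out$cluster_id, out$p_value, out$regulator), ,
             drop = FALSE]
  rownames(out) <- NULL
  cols <- c("cluster_id", "regulator", "kind", "family", "k", "m", "K",
            "N_universe", "odds_ratio", "p_value", "significant")
  out <- out[, cols]
  if (!keep_all) out <- out[out$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}
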