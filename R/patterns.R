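#' Union of per-contrast DEG lists
#'
#' Genes differentially expressed in at least one patient phenotype,
#' in deterministic (lexicographic) order.
#'
#' @param deg_lists List of character vectors (one per contrast).
#' @return Character vector.
#' @export
union_degs <- function(deg_lists) {
  sort(unique(unlist(lapply(deg_lists, as.character), use.names = FALSE)))
}

#' Direction pattern of one log2 fold-change triple
#'
#' Letter `i` is `U` if `log2fc_i > 0`, else `D`; an exact zero is `U`
#' by convention. The triple is ordered (ADU, ADT, ID).
#' @noRd
pattern_from_lfc <- function(lfc) {
  paste(ifelse(lfc < 0, "D", "U"), collapse = "")
}

#' Sub-pattern with attenuation refinement
#'
#' For same-direction patterns (UUU/DDD), the third letter is
#' lower-cased when the absolute fold change in ID is strictly smaller
#' than in ADU (expression moving back toward the healthy level).
#' @noRd
subpattern_from_lfc <- function(pattern, lfc) {
  if (pattern %in% c("UUU", "DDD") && abs(lfc[3]) < abs(lfc[1])) {
    paste0(substr(pattern, 1, 2), tolower(substr(pattern, 3, 3)))
  } else {
    pattern
  }
}

#' Assign direction patterns to genes from their fold-change triples
#'
#' Every gene gets a 3-letter pattern over (ADU, ADT, ID) from the signs
#' of its log2 fold changes versus HC — significance in a phenotype is
#' not required, only membership in the DEG union — plus the attenuation
#' sub-pattern and the dynamic group (1 = same direction throughout,
#' 2 = sign flip in ID, 3 = sign flip in ADT / other).
#'
#' @param lfc_matrix Numeric matrix: genes x 3 columns named
#'   `ADU`, `ADT`, `ID` of log2 fold changes versus HC.
#' @return A `data.frame`: `gene_id`, `lfc_ADU`, `lfc_ADT`, `lfc_ID`,
#'   `pattern`, `subpattern`, `group`.
#' @examples
#' assign_patterns(matrix(c(1.2, 0.8, 0.3), 1,
#'                        dimnames = list("G1", c("ADU", "ADT", "ID"))))
#' @export
assign_patterns <- function(lfc_matrix) {
  if (is.null(dim(lfc_matrix)) || ncol(lfc_matrix) != 3) {
    stop("lfc_matrix must have 3 columns (ADU, ADT, ID)", call. = FALSE)
  }
  if (!is.null(colnames(lfc_matrix))) {
    if (!setequal(colnames(lfc_matrix), CONTRAST_PHENOTYPES)) {
      stop("lfc_matrix columns must be ADU, ADT, ID", call. = FALSE)
    }
    lfc_matrix <- lfc_matrix[, CONTRAST_PHENOTYPES, drop = FALSE]
  }
  if (any(!is.finite(lfc_matrix))) {
    stop("non-finite log2 fold change(s)", call. = FALSE)
  }
  n_zero <- sum(lfc_matrix == 0)
  if (n_zero > 0) {
    message(n_zero, " log2fc value(s) exactly 0; letter 'U' by convention")
  }
  patterns <- apply(lfc_matrix, 1, pattern_from_lfc)
  subpatterns <- vapply(seq_len(nrow(lfc_matrix)), function(i)
    subpattern_from_lfc(patterns[i], lfc_matrix[i, ]), character(1))
  data.frame(
    gene_id = rownames(lfc_matrix) %||% as.character(seq_len(nrow(lfc_matrix))),
    lfc_ADU = lfc_matrix[, 1], lfc_ADT = lfc_matrix[, 2],
    lfc_ID = lfc_matrix[, 3],
    pattern = unname(patterns), subpattern = unname(subpatterns),
    group = unname(PATTERN_GROUPS[patterns]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cluster census of pattern assignments
#'
#' Counts and percentages (of the union total) for each of the 8
#' patterns, with the attenuated sub-cluster (UUu/DDd) counts reported
#' alongside their parent clusters. The 8 pattern counts sum to the
#' number of assigned genes.
#'
#' @param assignments Result of [assign_patterns()].
#' @param digits Decimal places for the reported percentages (default 2).
#' @return A `data.frame`: `pattern`, `count`, `percent`,
#'   `subcluster_count` (attenuated members, NA except UUU/DDD),
#'   `group`.
#' @export
cluster_census <- function(assignments, digits = 2) {
  total <- nrow(assignments)
  counts <- setNames(integer(length(ALL_PATTERNS)), ALL_PATTERNS)
  tab <- table(assignments$pattern)
  counts[names(tab)] <- as.integer(tab)
  sub_counts <- rep(NA_integer_, length(ALL_PATTERNS))
  names(sub_counts) <- ALL_PATTERNS
  sub_counts["UUU"] <- sum(assignments$subpattern == "UUu")
  sub_counts["DDD"] <- sum(assignments$subpattern == "DDd")
  data.frame(
    pattern = ALL_PATTERNS,
    count = unname(counts),
    percent = if (total > 0) round(100 * unname(counts) / total, digits)
              else NA_real_,
    subcluster_count = unname(sub_counts),
    group = unname(PATTERN_GROUPS[ALL_PATTERNS]),
    stringsAsFactors = FALSE)
}

#' Genes of each cluster, keyed by pattern or sub-pattern
#'
#' Splits assignments into member lists. With `use_subpattern = TRUE`
#' the attenuated sub-clusters (UUu, DDd) replace the genes they refine
#' inside UUU/DDD, matching how enrichment is run per (sub-)cluster.
#'
#' @param assignments Result of [assign_patterns()].
#' @param use_subpattern Key by `subpattern` instead of `pattern`.
#' @return Named list of character vectors.
#' @export
cluster_members <- function(assignments, use_subpattern = FALSE) {
  key <- if (use_subpattern) assignments$subpattern else assignments$pattern
  split(assignments$gene_id, key)
}
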