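#' miRNA-target direction consistency against a cluster pattern
#'
#' A miRNA regulating a cluster of target genes is expected to move in
#' the opposite direction to the cluster in each phenotype. For each of
#' (ADU, ADT, ID) the flag is true iff the sign of the miRNA's log2 fold
#' change is opposite to the cluster letter (`U` needs a negative miRNA
#' change, `D` a positive one); a zero miRNA fold change never counts as
#' opposite. Categories: `all_opposite` (all three), `treated_opposite`
#' (opposite in ADT and ID but not all three — consistent with a
#' therapy-induced effect), else `inconsistent`.
#'
#' @param mirna_id Label for the result row.
#' @param mirna_lfc Numeric triple of miRNA log2 fold changes over
#'   (ADU, ADT, ID).
#' @param cluster_pattern 3-letter cluster pattern; sub-cluster spellings
#'   (UUu, DDd) are accepted and read case-insensitively.
#' @param cluster_id Label for the cluster (defaults to the pattern).
#' @return A one-row `data.frame`: `mirna_id`, `cluster_id`,
#'   `cluster_pattern`, the three fold changes, `opposite_ADU`,
#'   `opposite_ADT`, `opposite_ID`, `category`.
#' @export
direction_consistency <- function(mirna_id, mirna_lfc, cluster_pattern,
                                  cluster_id = cluster_pattern) {
  if (length(mirna_lfc) != 3 || any(!is.finite(mirna_lfc))) {
    stop("mirna_lfc must be 3 finite values (ADU, ADT, ID)", call. = FALSE)
  }
  letters3 <- strsplit(toupper(cluster_pattern), "")[[1]]
  if (length(letters3) != 3 || !all(letters3 %in% c("U", "D"))) {
    stop("cluster_pattern must be 3 letters over {U, D}", call. = FALSE)
  }
  if (any(mirna_lfc == 0)) {
    message("zero miRNA fold change treated as not opposite")
  }
  flags <- ifelse(letters3 == "U", mirna_lfc < 0, mirna_lfc > 0)
  category <- if (all(flags)) "all_opposite"
              else if (flags[2] && flags[3]) "treated_opposite"
              else "inconsistent"
  data.frame(mirna_id = mirna_id, cluster_id = cluster_id,
             cluster_pattern = cluster_pattern,
             lfc_ADU = mirna_lfc[1], lfc_ADT = mirna_lfc[2],
             lfc_ID = mirna_lfc[3],
             opposite_ADU = flags[1], opposite_ADT = flags[2],
             opposite_ID = flags[3],
             category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Delta-delta-Ct fold changes from a qPCR Ct table
#'
#' For each feature, per-sample `dCt = Ct_target - Ct_reference`
#' (normalization to the reference assay run in parallel), group-mean
#' `dCt` per phenotype, `ddCt = mean dCt(case) - mean dCt(control)`, and
#' fold change `2^-ddCt`. Adding any constant to all Ct values of a
#' sample cancels in the reference subtraction.
#'
#' @param qpcr A `data.frame` with columns `sample_id`, `phenotype`,
#'   `feature_id`, `ct_target`, `ct_reference` (see [simulate_qpcr()]).
#' @param case_phenotype Patient phenotype (e.g. `"ADT"`).
#' @param control_phenotype Control group (default `"HC"`).
#' @return A `data.frame`: `feature_id`, `dct_case`, `dct_control`,
#'   `ddct`, `fold_change`, `log2_fold_change`.
#' @export
ddct_fold_change <- function(qpcr, case_phenotype,
                             control_phenotype = "HC") {
  need <- c("sample_id", "phenotype", "feature_id", "ct_target",
            "ct_reference")
  missing_cols <- setdiff(need, names(qpcr))
  if (length(missing_cols)) {
    stop("qPCR table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(qpcr$ct_target)) || any(!is.finite(qpcr$ct_reference)) ||
      any(qpcr$ct_target <= 0) || any(qpcr$ct_reference <= 0)) {
    stop("Ct values must be finite and positive (missing reference?)",
         call. = FALSE)
  }
  for (ph in c(case_phenotype, control_phenotype)) {
    if (!any(qpcr$phenotype == ph)) {
      stop("phenotype absent from qPCR table: ", ph, call. = FALSE)
    }
  }
  sub <- qpcr[qpcr$phenotype %in% c(case_phenotype, control_phenotype), ]
  sub$dct <- sub$ct_target - sub$ct_reference
  agg <- tapply(sub$dct, list(sub$feature_id, sub$phenotype), mean)
  features <- sort(rownames(agg))
  dct_case <- agg[features, case_phenotype]
  dct_ctrl <- agg[features, control_phenotype]
  if (any(is.na(dct_case)) || any(is.na(dct_ctrl))) {
    bad <- features[is.na(dct_case) | is.na(dct_ctrl)]
    stop("feature(s) missing in one group: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ddct <- dct_case - dct_ctrl
  data.frame(feature_id = features,
             dct_case = unname(dct_case), dct_control = unname(dct_ctrl),
             ddct = unname(ddct),
             fold_change = 2^(-unname(ddct)),
             log2_fold_change = -unname(ddct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-platform concordance of expression changes
#'
#' A feature is concordant when its array log2 fold change and its qPCR
#' fold change agree in direction (sign of the array log2fc equals the
#' sign of log2 of the qPCR fold change).
#'
#' @param array_log2fc Named numeric vector of array log2 fold changes.
#' @param qpcr_fold_change Named numeric vector of qPCR (linear) fold
#'   changes.
#' @return A list: `n_concordant`, `n_total`, `concordant` (named
#'   logical over the shared features).
#' @export
platform_concordance <- function(array_log2fc, qpcr_fold_change) {
  shared <- intersect(names(array_log2fc), names(qpcr_fold_change))
  if (length(shared) == 0) {
    stop("no shared features between platforms", call. = FALSE)
  }
  conc <- sign(array_log2fc[shared]) == sign(log2(qpcr_fold_change[shared]))
  list(n_concordant = sum(conc), n_total = length(shared),
       concordant = conc)
}
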