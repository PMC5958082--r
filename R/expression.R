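#' Expression matrix container
#'
#' A validated log2-scale feature-by-sample expression matrix. Rows are
#' features (genes or miRNAs), columns are samples. Values are assumed to
#' be on the log2 scale (e.g. RMA summaries).
#'
#' @param values Numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); all values finite.
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @return An object of class `expression_matrix` (a numeric matrix with
#'   a `feature_kind` attribute).
#' @export
expression_matrix <- function(values, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (features) and colnames (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "),
         " (collapse features first)", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  structure(values, feature_kind = feature_kind,
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d %s features x %d samples (log2)\n",
              nrow(x), attr(x, "feature_kind"), ncol(x)))
  invisible(x)
}

feature_kind <- function(x) attr(x, "feature_kind")

#' Sample design table
#'
#' Maps each sample id to one of the four phenotypes HC, ADU, ADT, ID.
#'
#' @param sample_id Character vector of unique sample ids.
#' @param phenotype Character vector of phenotype labels, same length.
#' @return A `data.frame` with columns `sample_id` and `phenotype`
#'   (factor with levels HC, ADU, ADT, ID), class `sample_design`.
#' @export
sample_design <- function(sample_id, phenotype) {
  sample_id <- as.character(sample_id)
  phenotype <- as.character(phenotype)
  if (length(sample_id) != length(phenotype)) {
    stop("sample_id and phenotype lengths differ", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids in design: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(phenotype), PHENOTYPES)
  if (length(bad)) {
    stop("unknown phenotype(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(PHENOTYPES, collapse = ", "),
         call. = FALSE)
  }
  structure(
    data.frame(sample_id = sample_id,
               phenotype = factor(phenotype, levels = PHENOTYPES),
               stringsAsFactors = FALSE),
    class = c("sample_design", "data.frame")
  )
}

#' Samples of a given phenotype
#' @noRd
design_samples <- function(design, phenotype) {
  design$sample_id[design$phenotype == phenotype]
}

#' Check a design against an expression matrix
#'
#' Every matrix sample must have exactly one phenotype, and every
#' phenotype used in a contrast must have at least `min_n` samples.
#' @noRd
check_design <- function(matrix, design, min_n = 2L) {
  missing <- setdiff(colnames(matrix), design$sample_id)
  if (length(missing)) {
    stop("samples missing from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Collapse features to genes by averaging
#'
#' Collapses multiple probe sets / isoforms mapping to the same gene by
#' taking the arithmetic mean of their log2 expression values within each
#' sample. Output genes are in lexicographic order.
#'
#' @param matrix An [expression_matrix()].
#' @param feature_to_gene Named character vector mapping every feature id
#'   in `matrix` to one gene id.
#' @return An [expression_matrix()] with one row per gene.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(4, 6, 5, 7), 2, 2,
#'          dimnames = list(c("ps1", "ps2"), c("s1", "s2"))))
#' collapse_features(m, c(ps1 = "G", ps2 = "G"))  # G = (5, 6)
#' @export
collapse_features <- function(matrix, feature_to_gene) {
  stopifnot(inherits(matrix, "expression_matrix"))
  unmapped <- setdiff(rownames(matrix), names(feature_to_gene))
  if (length(unmapped)) {
    stop("features without a gene mapping: ",
         paste(head(unmapped, 10), collapse = ", "),
         if (length(unmapped) > 10) sprintf(" (and %d more)",
                                            length(unmapped) - 10),
         call. = FALSE)
  }
  genes <- feature_to_gene[rownames(matrix)]
  # rowsum() sums per gene; divide by the feature count to get the mean
  sums <- rowsum(unclass(matrix), group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out, feature_kind = feature_kind(matrix))
}
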