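#' Row-wise two-group t-tests of a patient phenotype against HC
#'
#' Tests every feature for differential expression between one patient
#' phenotype and the healthy-control group with a two-sided two-sample
#' t-test. Welch's unequal-variance form is the default; `equal_var =
#' TRUE` switches to the pooled-variance Student's t. Features in which
#' both groups have zero variance get `t = 0`, `p = 1` (with a warning):
#' no evidence either way.
#'
#' @param matrix An [expression_matrix()] (log2 scale).
#' @param design A [sample_design()] covering the matrix samples.
#' @param case_phenotype One of `"ADU"`, `"ADT"`, `"ID"`.
#' @param equal_var Pooled-variance Student's t instead of Welch.
#' @return A `data.frame` with one row per feature: `feature_id`,
#'   `contrast`, `mean_case`, `mean_control`, `log2fc`
#'   (`mean_case - mean_control`), `t_statistic`, `p_value`.
#' @export
two_group_ttest <- function(matrix, design, case_phenotype,
                            equal_var = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!case_phenotype %in% CONTRAST_PHENOTYPES) {
    stop("case_phenotype must be one of ",
         paste(CONTRAST_PHENOTYPES, collapse = ", "),
         " (HC is the control)", call. = FALSE)
  }
  check_design(matrix, design)
  case_ids <- intersect(colnames(matrix),
                        design_samples(design, case_phenotype))
  ctrl_ids <- intersect(colnames(matrix), design_samples(design, "HC"))
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    stop("need >= 2 samples per group for contrast ", case_phenotype,
         "-HC (have ", length(case_ids), " case, ", length(ctrl_ids),
         " control)", call. = FALSE)
  }
  x <- unclass(matrix)[, case_ids, drop = FALSE]
  y <- unclass(matrix)[, ctrl_ids, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)

  if (equal_var) {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    # Welch-Satterthwaite degrees of freedom
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- !is.finite(tstat)
  if (any(degenerate)) {
    warning(sum(degenerate),
            " feature(s) with zero variance in both groups; p set to 1")
    tstat[degenerate] <- 0
    p[degenerate] <- 1
  }
  data.frame(feature_id = rownames(matrix),
             contrast = case_phenotype,
             mean_case = m1, mean_control = m2,
             log2fc = m1 - m2,
             t_statistic = tstat, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-based q-values: q = N * p / R
#'
#' Computes, for each p-value, the multiple-testing-adjusted q-value
#' `q_i = N * p_i / R_i`, where `N` is the number of features tested and
#' `R_i` is the ascending rank of `p_i` (ties share the maximum rank of
#' their group, so tied p-values get one q). By default the raw values
#' are then step-up monotonized (each q replaced by the minimum raw q at
#' its rank or any higher rank), which makes them identical to
#' Benjamini-Hochberg adjusted p-values; `monotonize = FALSE` keeps the
#' literal formula. Either way q is clipped to at most 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param monotonize Apply the step-up monotonization (default `TRUE`).
#' @return A `data.frame` with columns `p_value`, `rank_R`,
#'   `n_tested_N`, `q_raw` (unclipped `N*p/R`) and `q_value`.
#' @examples
#' compute_qvalues(c(0.01, 0.02, 0.03, 0.04, 0.05))$q_value  # all 0.05
#' @export
compute_qvalues <- function(p_values, monotonize = TRUE) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and within [0, 1]", call. = FALSE)
  }
  n <- length(p)
  r <- rank(p, ties.method = "max")
  q_raw <- n * p / r
  if (monotonize && n > 0) {
    o <- order(p, decreasing = TRUE)
    q <- numeric(n)
    q[o] <- cummin(q_raw[o])
  } else {
    q <- q_raw
  }
  data.frame(p_value = p, rank_R = as.integer(r), n_tested_N = n,
             q_raw = q_raw, q_value = pmin(q, 1))
}

#' Full differential-expression results for one contrast
#'
#' Runs [two_group_ttest()], attaches q-values over all tested features
#' (N = number of rows of the matrix, corrected independently per
#' contrast), direction calls and the significance flag.
#'
#' @inheritParams two_group_ttest
#' @param q_threshold Significance cutoff on q (default 0.05, inclusive).
#' @param monotonize Passed to [compute_qvalues()].
#' @return A `data.frame` (class `de_result`) with the t-test columns
#'   plus `rank_R`, `n_tested_N`, `q_value`, `direction` (`"U"`/`"D"`)
#'   and `significant`.
#' @export
de_contrast <- function(matrix, design, case_phenotype,
                        q_threshold = 0.05, equal_var = FALSE,
                        monotonize = TRUE) {
  tt <- two_group_ttest(matrix, design, case_phenotype,
                        equal_var = equal_var)
  qq <- compute_qvalues(tt$p_value, monotonize = monotonize)
  tt$rank_R <- qq$rank_R
  tt$n_tested_N <- qq$n_tested_N
  tt$q_value <- qq$q_value
  tt$direction <- direction_of(tt$log2fc)
  tt$significant <- tt$q_value <= q_threshold
  class(tt) <- c("de_result", "data.frame")
  attr(tt, "q_threshold") <- q_threshold
  tt
}

#' Direction letter from a log2 fold change
#'
#' `U` for positive, `D` for negative. An exact zero is called `U` by
#' convention (measure-zero on real data) with a message.
#' @noRd
direction_of <- function(log2fc) {
  if (any(log2fc == 0)) {
    message(sum(log2fc == 0),
            " log2fc value(s) exactly 0; direction set to 'U' by convention")
  }
  ifelse(log2fc < 0, "D", "U")
}

#' Call differentially expressed features from DE results
#'
#' Features with `q_value <= threshold` (inclusive), partitioned by
#' direction, in stable order (q, then feature id).
#'
#' @param de A result of [de_contrast()].
#' @param threshold q cutoff (default 0.05).
#' @return A list with `all`, `up`, `down` (character vectors of feature
#'   ids) and `table` (the significant rows).
#' @export
call_degs <- function(de, threshold = 0.05) {
  sig <- de[de$q_value <= threshold, , drop = FALSE]
  sig <- sig[order(sig$q_value, sig$feature_id), , drop = FALSE]
  list(all = sig$feature_id,
       up = sig$feature_id[sig$log2fc > 0],
       down = sig$feature_id[sig$log2fc < 0],
       table = sig)
}

#' Write a DE result table as TSV
#' @param de A [de_contrast()] result.
#' @param path Output path.
#' @export
write_de <- function(de, path) {
  cols <- c("feature_id", "mean_case", "mean_control", "log2fc",
            "t_statistic", "p_value", "rank_R", "q_value", "direction",
            "significant")
  write.table(de[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
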