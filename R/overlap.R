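#' Hypergeometric overlap test between two gene lists
#'
#' Tests whether two sets drawn from a common universe share more
#' members than expected by chance. The p-value is the exact upper tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, |A|, |B|)`, computed by direct
#' summation of the hypergeometric mass.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @param universe Either the universe size (a single number, e.g. the
#'   number of features tested for differential expression) or the full
#'   character vector of universe ids, in which case membership of both
#'   sets is checked.
#' @param name_a,name_b Labels used in the result.
#' @return A one-row `data.frame`: `set_a`, `set_b`, `size_a`, `size_b`,
#'   `overlap_count`, `universe_N`, `percent_of_smaller`, `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe,
                         name_a = "A", name_b = "B") {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  if (is.numeric(universe) && length(universe) == 1) {
    n_univ <- as.integer(universe)
  } else {
    u <- unique(as.character(universe))
    out <- setdiff(c(a, b), u)
    if (length(out)) {
      stop("set member(s) outside universe: ",
           paste(head(out, 5), collapse = ", "), call. = FALSE)
    }
    n_univ <- length(u)
  }
  if (n_univ < length(union(a, b))) {
    stop("universe smaller than |A union B|", call. = FALSE)
  }
  k <- length(intersect(a, b))
  p <- hyper_upper_tail(k, length(a), length(b), n_univ)
  smaller <- min(length(a), length(b))
  data.frame(set_a = name_a, set_b = name_b,
             size_a = length(a), size_b = length(b),
             overlap_count = k, universe_N = n_univ,
             percent_of_smaller = if (smaller > 0) 100 * k / smaller
                                  else NA_real_,
             p_value = p, stringsAsFactors = FALSE)
}

# Exact P(X >= k) for X ~ Hypergeom(N, K, n): sum of dhyper over the
# achievable upper range. k = 0 gives exactly 1.
hyper_upper_tail <- function(k, size_a, size_b, n_univ) {
  if (k <= 0) return(1)
  hi <- min(size_a, size_b)
  sum(dhyper(k:hi, size_a, n_univ - size_a, size_b))
}

#' Disjoint-region counts of a 2- or 3-set Venn partition
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector of the disjoint regions. For 3 sets the
#'   names are e.g. `"A_only"`, `"A_B"`, `"A_B_C"` built from the input
#'   names; counts sum to the size of the union.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3 ||
      is.null(names(sets))) {
    stop("`sets` must be a named list of 2 or 3 sets", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, ncol = length(sets),
                       dimnames = list(universe, names(sets)))
  region_of <- apply(membership, 1, function(m)
    paste(c(names(sets)[m],
            if (sum(m) == 1) "only"), collapse = "_"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    combn(names(sets), k, function(x)
      paste(c(x, if (k == 1) "only"), collapse = "_"))))
  counts <- setNames(integer(length(combos)), combos)
  tab <- table(region_of)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Count and percentage of set A unique to A relative to set B
#'
#' @param set_a,set_b Character vectors.
#' @return A list: `unique_count` = `|A \ B|` and `percent` =
#'   `100 * unique_count / |A|` (`NA` when A is empty).
#' @examples
#' # 1976 DEGs of which 295 shared: 1681 unique, 85.1%
#' @export
unique_fraction <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  u <- length(setdiff(a, b))
  list(unique_count = u,
       percent = if (length(a) > 0) 100 * u / length(a) else NA_real_)
}

#' All pairwise overlap tests among named DEG lists
#'
#' @param deg_lists Named list of character vectors (e.g. per-phenotype
#'   DEG lists).
#' @param universe Universe size or id vector (see [overlap_test()]).
#' @return A `data.frame` with one row per unordered pair, including
#'   unique counts/percentages in both directions.
#' @export
pairwise_overlaps <- function(deg_lists, universe) {
  nm <- names(deg_lists)
  pairs <- combn(nm, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    res <- overlap_test(deg_lists[[pr[1]]], deg_lists[[pr[2]]], universe,
                        name_a = pr[1], name_b = pr[2])
    ua <- unique_fraction(deg_lists[[pr[1]]], deg_lists[[pr[2]]])
    ub <- unique_fraction(deg_lists[[pr[2]]], deg_lists[[pr[1]]])
    res$unique_a <- ua$unique_count
    res$unique_a_percent <- ua$percent
    res$unique_b <- ub$unique_count
    res$unique_b_percent <- ub$percent
    res
  })
  do.call(rbind, rows)
}
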