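#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds feature ids and
#' whose header row holds sample ids; the body must be fully numeric.
#' Malformed input is rejected, never coerced.
#'
#' @param path Path to the TSV file.
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @param linear_input If `TRUE` the file holds linear-scale intensities
#'   and log2 is applied; non-positive values are then an error.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, feature_kind = c("mRNA", "miRNA"),
                            linear_input = FALSE) {
  feature_kind <- match.arg(feature_kind)
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file has no data rows", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header of ", path, call. = FALSE)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1]
    stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                 bad + 1L, path, nfield[bad], length(header)), call. = FALSE)
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, nrow = length(sample_ids))  # guard 1-sample edge case
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric or missing value at line %d (feature '%s'), column '%s'",
      bad[2] + 1L, ids[bad[2]], sample_ids[bad[1]]), call. = FALSE)
  }
  m <- t(vals)
  dimnames(m) <- list(ids, sample_ids)
  if (linear_input) {
    if (any(m <= 0)) {
      stop("linear-input mode requires strictly positive intensities",
           call. = FALSE)
    }
    m <- log2(m)
  }
  expression_matrix(m, feature_kind = feature_kind)
}

#' Write an expression matrix as TSV
#'
#' First column `feature_id`, then one column per sample. Round-trips
#' losslessly with [read_expression()] (values written at full precision).
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(feature_id = rownames(matrix),
                   unclass(matrix)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table (2-column TSV: sample_id, phenotype)
#' @param path Path to the TSV file (with header).
#' @return A [sample_design()].
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("design file needs 2 columns", call. = FALSE)
  sample_design(df[[1]], df[[2]])
}

#' Write a sample design table
#' @export
#' @param design A [sample_design()].
#' @param path Output path.
write_design <- function(design, path) {
  write.table(data.frame(sample_id = design$sample_id,
                         phenotype = as.character(design$phenotype)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-set collection
#'
#' A list of named regulator target-gene sets, each with a regulator kind
#' (miRNA or TF) and an optional family id (miRNAs of one family share a
#' seed sequence and a target repertoire).
#'
#' @param names Character vector of unique set names.
#' @param members List of character vectors (one per set, non-empty).
#' @param kind `"miRNA"` or `"TF"` (recycled).
#' @param family Optional character vector of family ids (NA = no family).
#' @return Object of class `gene_set_collection`: a list with one entry
#'   per set, each a list `(name, kind, family, members)`.
#' @export
gene_set_collection <- function(names, members, kind, family = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop("duplicate set name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(members) != length(names)) {
    stop("names and members lengths differ", call. = FALSE)
  }
  if (any(lengths(members) == 0)) {
    stop("empty gene set(s): ",
         paste(names[lengths(members) == 0], collapse = ", "), call. = FALSE)
  }
  kind <- rep_len(as.character(kind), length(names))
  if (!all(kind %in% c("miRNA", "TF"))) {
    stop("kind must be 'miRNA' or 'TF'", call. = FALSE)
  }
  family <- if (is.null(family)) rep(NA_character_, length(names))
            else rep_len(as.character(family), length(names))
  sets <- Map(function(n, k, f, m) {
    list(name = n, kind = k, family = f, members = unique(as.character(m)))
  }, names, kind, family, members)
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  kinds <- vapply(x, `[[`, character(1), "kind")
  cat(sprintf("<gene_set_collection> %d sets (%d miRNA, %d TF)\n",
              length(x), sum(kinds == "miRNA"), sum(kinds == "TF")))
  invisible(x)
}

set_names <- function(collection) {
  vapply(collection, `[[`, character(1), "name")
}

#' Read gene sets in GMT format
#'
#' Broad-dialect GMT: one set per line, `name TAB description TAB
#' member...`. A description of the form `family=<id>` is parsed as the
#' set's family id; any other description is kept but yields no family.
#'
#' @param path Path to the GMT file.
#' @param regulator_kind `"miRNA"` or `"TF"` for all sets in the file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, regulator_kind = c("miRNA", "TF")) {
  regulator_kind <- match.arg(regulator_kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields (empty set?)",
                 short[1]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  fam <- ifelse(grepl("^family=", desc), sub("^family=", "", desc),
                NA_character_)
  members <- lapply(fields, function(f) f[-(1:2)])
  gene_set_collection(nm, members, kind = regulator_kind, family = fam)
}

#' Write gene sets in GMT format
#'
#' The family id, when present, is written into the description field as
#' `family=<id>`; otherwise the description is empty.
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s) {
    desc <- if (is.na(s$family)) "" else paste0("family=", s$family)
    paste(c(s$name, desc, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' 2-column tab-delimited file of undirected gene-id pairs. Self-loops
#' are an error; duplicate pairs (in either order) are collapsed.
#'
#' @param path Path to the TSV file (no header by default).
#' @param header Whether the file has a header row.
#' @return A `data.frame` with columns `a`, `b` (canonical order,
#'   `a < b`), class `ppi_edges`.
#' @export
read_ppi <- function(path, header = FALSE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("PPI file needs 2 columns", call. = FALSE)
  ppi_edges(df[[1]], df[[2]])
}

#' Construct a PPI edge list from two id vectors
#' @param a,b Character vectors of interacting gene ids.
#' @return A de-duplicated undirected edge table, class `ppi_edges`.
#' @export
ppi_edges <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  loops <- a == b
  if (any(loops)) {
    stop("self-loop edge(s): ", paste(unique(a[loops]), collapse = ", "),
         call. = FALSE)
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste0(lo, "\r", hi))
  structure(data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE),
            class = c("ppi_edges", "data.frame"))
}
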