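#' Collapse same-family miRNAs in enrichment results
#'
#' miRNAs of one functional family share a target repertoire, so only
#' one representative per family enters a network: the member with the
#' smallest enrichment p, ties broken lexicographically by name. Rows
#' without a family id (NA) count as their own family; non-miRNA rows
#' pass through untouched. No family is ever removed entirely.
#'
#' @param enriched Enrichment `data.frame` (see [enrich_all()]) with
#'   columns `regulator`, `kind`, `family`, `p_value`.
#' @return The filtered `data.frame`.
#' @export
collapse_families <- function(enriched) {
  if (nrow(enriched) == 0) return(enriched)
  is_mirna <- enriched$kind == "miRNA"
  mir <- enriched[is_mirna, , drop = FALSE]
  if (nrow(mir) > 0) {
    mir <- mir[order(mir$p_value, mir$regulator), , drop = FALSE]
    fam <- ifelse(is.na(mir$family), paste0("__self__", mir$regulator),
                  mir$family)
    mir <- mir[!duplicated(fam), , drop = FALSE]
  }
  out <- rbind(mir, enriched[!is_mirna, , drop = FALSE])
  out <- out[order(out$p_value, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a per-cluster miRNA/TF co-regulatory network
#'
#' Joins the cluster's enriched regulators (miRNAs family-collapsed via
#' [collapse_families()]) to their in-cluster target genes, and adds
#' protein-protein interaction edges between cluster genes. Gene nodes
#' are cluster genes with at least one regulator edge or one retained
#' PPI edge; regulators whose target sets do not intersect the cluster
#' are dropped with a warning. With `expand_ppi = TRUE`, PPI edges with
#' one endpoint in the cluster are also retained and their outside
#' endpoint added as a gene node (first-neighbor expansion); by default
#' the network stays cluster-scoped.
#'
#' @param cluster_genes Character vector of the cluster's member genes.
#' @param enriched Enrichment rows for this cluster (from
#'   [enrich_all()]); only `significant` rows should be passed.
#' @param collections A [gene_set_collection()] or list of them holding
#'   the target sets of the enriched regulators.
#' @param ppi Optional [ppi_edges()] table.
#' @param cluster_id Label stored on the network.
#' @param expand_ppi Retain PPI edges with one endpoint outside the
#'   cluster (default `FALSE`).
#' @return An object of class `regulatory_network`: a list with
#'   `cluster_id`, `nodes` (`data.frame`: `id`, `node_type`), `edges`
#'   (`data.frame`: `source`, `target`, `edge_type`) and `provenance`
#'   (named enrichment p per regulator node).
#' @export
build_network <- function(cluster_genes, enriched, collections,
                          ppi = NULL, cluster_id = "cluster",
                          expand_ppi = FALSE) {
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  sets <- do.call(c, lapply(collections, unclass))
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  cluster_genes <- unique(as.character(cluster_genes))

  enriched <- collapse_families(enriched)
  edges <- list()
  provenance <- numeric(0)
  for (i in seq_len(nrow(enriched))) {
    reg <- enriched$regulator[i]
    if (!reg %in% names(sets)) {
      stop("no target set found for enriched regulator ", reg,
           call. = FALSE)
    }
    targets <- intersect(sets[[reg]]$members, cluster_genes)
    if (length(targets) == 0) {
      warning("regulator ", reg,
              " has no in-cluster targets; dropped from network")
      next
    }
    type <- if (enriched$kind[i] == "miRNA") "mirna_target" else "tf_target"
    edges[[length(edges) + 1L]] <- data.frame(
      source = reg, target = targets, edge_type = type,
      node_type_source = enriched$kind[i], stringsAsFactors = FALSE)
    provenance[reg] <- enriched$p_value[i]
  }
  reg_edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               edge_type = character(0), node_type_source = character(0),
               stringsAsFactors = FALSE)

  ppi_keep <- data.frame(a = character(0), b = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(ppi) && nrow(ppi) > 0) {
    in_a <- ppi$a %in% cluster_genes
    in_b <- ppi$b %in% cluster_genes
    keep <- if (expand_ppi) in_a | in_b else in_a & in_b
    ppi_keep <- ppi[keep, c("a", "b"), drop = FALSE]
  }

  gene_ids <- sort(unique(c(reg_edges$target, ppi_keep$a, ppi_keep$b)))
  reg_nodes <- unique(reg_edges[, c("source", "node_type_source")])
  nodes <- rbind(
    data.frame(id = gene_ids, node_type = rep("gene", length(gene_ids)),
               stringsAsFactors = FALSE),
    data.frame(id = reg_nodes$source, node_type = reg_nodes$node_type_source,
               stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$node_type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  all_edges <- rbind(
    reg_edges[, c("source", "target", "edge_type")],
    if (nrow(ppi_keep) > 0) {
      data.frame(source = ppi_keep$a, target = ppi_keep$b,
                 edge_type = "ppi", stringsAsFactors = FALSE)
    })
  all_edges <- all_edges[!duplicated(all_edges), , drop = FALSE]
  rownames(all_edges) <- NULL

  net <- structure(list(cluster_id = cluster_id, nodes = nodes,
                        edges = all_edges, provenance = provenance),
                   class = "regulatory_network")
  validate_network(net)
  net
}

#' Validate a regulatory network's structural constraints
#'
#' Regulator-to-target edges run from miRNA/TF nodes to gene nodes, PPI
#' edges connect genes only, every regulator node has at least one
#' target edge, there are no duplicate edges or self-loops, and at most
#' one miRNA node per family (checked upstream via family collapsing).
#' @param net A `regulatory_network`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (anyDuplicated(nodes$id)) stop("duplicate node id", call. = FALSE)
  type_of <- setNames(nodes$node_type, nodes$id)
  if (nrow(edges) > 0) {
    if (any(edges$source == edges$target)) {
      stop("self-loop edge in network", call. = FALSE)
    }
    if (anyDuplicated(edges)) stop("duplicate edge in network",
                                   call. = FALSE)
    unknown <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(unknown)) {
      stop("edge endpoint(s) not in node table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg <- edges$edge_type %in% c("mirna_target", "tf_target")
    if (any(type_of[edges$target[reg]] != "gene")) {
      stop("regulator edge targeting a non-gene node", call. = FALSE)
    }
    if (any(edges$edge_type == "mirna_target" &
            type_of[edges$source] != "miRNA") ||
        any(edges$edge_type == "tf_target" &
            type_of[edges$source] != "TF")) {
      stop("regulator edge from a node of the wrong type", call. = FALSE)
    }
    is_ppi <- edges$edge_type == "ppi"
    if (any(type_of[edges$source[is_ppi]] != "gene") ||
        any(type_of[edges$target[is_ppi]] != "gene")) {
      stop("ppi edge touching a non-gene node", call. = FALSE)
    }
  }
  regulators <- nodes$id[nodes$node_type %in% c("miRNA", "TF")]
  no_edge <- setdiff(regulators,
                     edges$source[edges$edge_type != "ppi"])
  if (length(no_edge)) {
    stop("regulator node(s) without target edges: ",
         paste(no_edge, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<regulatory_network> cluster %s: %d genes, %d miRNAs, %d TFs; %d edges\n",
    x$cluster_id, s$n_gene, s$n_mirna, s$n_tf, s$n_edges))
  invisible(x)
}

#' Node and edge counts of a regulatory network
#'
#' @param net A `regulatory_network`.
#' @return A list: `n_gene`, `n_mirna`, `n_tf`, `n_edges`,
#'   `n_mirna_target`, `n_tf_target`, `n_ppi`, `n_components`
#'   (weakly connected components; 0 for an empty network).
#' @export
network_summary <- function(net) {
  tt <- table(factor(net$nodes$node_type,
                     levels = c("gene", "miRNA", "TF")))
  et <- table(factor(net$edges$edge_type,
                     levels = c("mirna_target", "tf_target", "ppi")))
  n_comp <- if (nrow(net$nodes) == 0) 0L else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("source", "target")], directed = FALSE,
      vertices = net$nodes$id)
    igraph::count_components(g)
  }
  list(n_gene = as.integer(tt[["gene"]]),
       n_mirna = as.integer(tt[["miRNA"]]),
       n_tf = as.integer(tt[["TF"]]),
       n_edges = nrow(net$edges),
       n_mirna_target = as.integer(et[["mirna_target"]]),
       n_tf_target = as.integer(et[["tf_target"]]),
       n_ppi = as.integer(et[["ppi"]]),
       n_components = n_comp)
}

#' Export a regulatory network as SIF or GraphML
#'
#' SIF rows are `source TAB edge_type TAB target` (tab-delimited, so
#' node ids may contain spaces); GraphML carries `node_type` and
#' `edge_type` attributes. Both load in Cytoscape and round-trip through
#' [read_network()] with identical node and edge multisets.
#'
#' @param net A `regulatory_network`.
#' @param path Output file path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return The path, invisibly.
#' @export
export_network <- function(net, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$edge_type,
                     net$edges$target)
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = TRUE, vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network exported by [export_network()]
#'
#' GraphML restores node and edge types from attributes; SIF restores
#' edge types from the relation column and infers node types from edge
#' semantics (regulator edges start at miRNA/TF nodes, all other
#' endpoints are genes).
#'
#' @param path File path.
#' @param format `"SIF"` or `"GraphML"`.
#' @param cluster_id Label for the restored network.
#' @return A `regulatory_network`.
#' @export
read_network <- function(path, format = c("SIF", "GraphML"),
                         cluster_id = "imported") {
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 3)) {
      stop("malformed SIF line (expected 3 tab-separated fields)",
           call. = FALSE)
    }
    edges <- data.frame(
      source = vapply(fields, `[[`, character(1), 1),
      edge_type = vapply(fields, `[[`, character(1), 2),
      target = vapply(fields, `[[`, character(1), 3),
      stringsAsFactors = FALSE)[, c(1, 3, 2)]
    names(edges) <- c("source", "target", "edge_type")
    node_type <- setNames(
      rep("gene", length(unique(c(edges$source, edges$target)))),
      unique(c(edges$source, edges$target)))
    node_type[unique(edges$source[edges$edge_type == "mirna_target"])] <-
      "miRNA"
    node_type[unique(edges$source[edges$edge_type == "tf_target"])] <- "TF"
    nodes <- data.frame(id = names(node_type),
                        node_type = unname(node_type),
                        stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                        node_type = igraph::vertex_attr(g, "node_type"),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(source = el[, 1], target = el[, 2],
                        edge_type = igraph::edge_attr(g, "edge_type"),
                        stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$node_type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(cluster_id = cluster_id, nodes = nodes, edges = edges,
                 provenance = numeric(0)),
            class = "regulatory_network")
}
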