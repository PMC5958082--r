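enr_row <- function(regulator, kind, p, family = NA_character_,
                    cluster = "UUu") {
  data.frame(cluster_id = cluster, regulator = regulator, kind = kind,
             family = family, k = 5L, m = 20L, K = 10L,
             N_universe = 100L, odds_ratio = 3, p_value = p,
             significant = TRUE, stringsAsFactors = FALSE)
}

test_that("family collapsing keeps the strongest member per family", {
  enr <- rbind(enr_row("miR-300", "miRNA", 0.004, "miR-300/381"),
               enr_row("miR-381", "miRNA", 0.007, "miR-300/381"),
               enr_row("miR-9", "miRNA", 0.009))
  out <- collapse_families(enr)
  expect_setequal(out$regulator, c("miR-300", "miR-9"))

  # all distinct families: identity (up to ordering)
  enr2 <- rbind(enr_row("a", "miRNA", 0.002), enr_row("b", "miRNA", 0.003))
  expect_setequal(collapse_families(enr2)$regulator, c("a", "b"))

  # equal p: lexicographically first member kept
  enr3 <- rbind(enr_row("miR-z", "miRNA", 0.005, "fam"),
                enr_row("miR-a", "miRNA", 0.005, "fam"))
  expect_equal(collapse_families(enr3)$regulator, "miR-a")

  # TFs are never collapsed, and no family disappears
  enr4 <- rbind(enr_row("TF1", "TF", 0.001, "fam"),
                enr_row("TF2", "TF", 0.002, "fam"),
                enr_row("miR-1", "miRNA", 0.004, "famX"))
  out4 <- collapse_families(enr4)
  expect_setequal(out4$regulator, c("TF1", "TF2", "miR-1"))
})

demo_network <- function(ppi = NULL, expand_ppi = FALSE) {
  cluster <- sprintf("g%d", 1:6)
  col <- list(
    gene_set_collection("miR-x", list(c("g1", "g2", "g9")), "miRNA"),
    gene_set_collection("TF-y", list(c("g2", "g3")), "TF"))
  enr <- rbind(enr_row("miR-x", "miRNA", 0.001),
               enr_row("TF-y", "TF", 0.005))
  build_network(cluster, enr, col, ppi = ppi, cluster_id = "UUu",
                expand_ppi = expand_ppi)
}

test_that("networks join regulators to in-cluster targets plus PPI", {
  ppi <- ppi_edges(c("g2", "g5", "g6"), c("g3", "g6", "g7"))
  net <- demo_network(ppi)
  s <- network_summary(net)
  # g9 outside the cluster: miR-x targets g1, g2 only
  expect_equal(s$n_mirna_target, 2)
  expect_equal(s$n_tf_target, 2)
  # g6-g7 straddles the cluster boundary: dropped without expansion
  expect_equal(s$n_ppi, 2)
  expect_setequal(net$nodes$id[net$nodes$node_type == "gene"],
                  c("g1", "g2", "g3", "g5", "g6"))
  expect_true(validate_network(net))

  # first-neighbor expansion retains the boundary edge and its endpoint
  net2 <- demo_network(ppi, expand_ppi = TRUE)
  expect_equal(network_summary(net2)$n_ppi, 3)
  expect_true("g7" %in% net2$nodes$id)

  # removing the PPI input changes only ppi edges and PPI-only genes
  net0 <- demo_network(NULL)
  expect_equal(network_summary(net0)$n_ppi, 0)
  expect_setequal(net0$nodes$id[net0$nodes$node_type == "gene"],
                  c("g1", "g2", "g3"))
  reg_edges <- function(n) n$edges[n$edges$edge_type != "ppi", ]
  expect_equal(reg_edges(net0), reg_edges(net), ignore_attr = TRUE)
})

test_that("regulators without in-cluster targets are dropped with warning", {
  col <- gene_set_collection("miR-out", list(c("zz1", "zz2")), "miRNA")
  expect_warning(
    net <- build_network(c("g1", "g2"), enr_row("miR-out", "miRNA", 0.001),
                         col),
    "no in-cluster targets")
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
  expect_equal(network_summary(net)$n_components, 0)
})

test_that("TF-only enrichment yields networks without miRNA nodes", {
  col <- gene_set_collection(c("TF-a", "TF-b"),
                             list(c("g1", "g2"), c("g2", "g3")), "TF")
  enr <- rbind(enr_row("TF-a", "TF", 0.001), enr_row("TF-b", "TF", 0.002))
  net <- build_network(sprintf("g%d", 1:4), enr, col)
  expect_setequal(unique(net$nodes$node_type), c("gene", "TF"))
  expect_equal(network_summary(net)$n_mirna, 0)
})

test_that("a star network has the expected summary counts", {
  col <- gene_set_collection("TF-hub", list(sprintf("g%d", 1:5)), "TF")
  net <- build_network(sprintf("g%d", 1:5),
                       enr_row("TF-hub", "TF", 0.001), col)
  s <- network_summary(net)
  expect_equal(s$n_tf, 1)
  expect_equal(s$n_gene, 5)
  expect_equal(s$n_tf_target, 5)
  expect_equal(s$n_edges, 5)
  expect_equal(s$n_components, 1)
})

test_that("network type constraints are enforced on validation", {
  net <- demo_network()
  bad <- net
  bad$edges$edge_type[1] <- "tf_target"  # miRNA source on a TF edge
  expect_error(validate_network(bad), "wrong type")
  bad2 <- net
  bad2$edges <- rbind(bad2$edges, bad2$edges[1, ])
  expect_error(validate_network(bad2), "duplicate edge")
  bad3 <- net
  bad3$edges$target[1] <- bad3$edges$source[1]
  expect_error(validate_network(bad3), "self-loop")
  bad4 <- net
  bad4$edges <- rbind(bad4$edges,
                      data.frame(source = "miR-x", target = "TF-y",
                                 edge_type = "ppi"))
  expect_error(validate_network(bad4), "non-gene")
})

test_that("planted-bias-1 regulator degree equals its in-cluster set size", {
  cfg <- quick_config(seed = 17, regulator_cluster_bias = 1,
                      pattern_proportions = concentrated_proportions())
  sim <- simulate_expression(cfg)
  ts <- simulate_target_sets(sim, cfg)
  truth <- ts$truth
  reg <- names(truth$regulators)[1]
  info <- truth$regulators[[reg]]
  cluster <- names(truth$gene_pattern)[
    !is.na(truth$gene_pattern) & truth$gene_pattern == info$cluster]
  net <- build_network(cluster,
                       enr_row(reg, info$kind, 0.001, cluster = info$cluster),
                       if (info$kind == "miRNA") ts$mirna_sets else ts$tf_sets,
                       cluster_id = info$cluster)
  s <- network_summary(net)
  expect_equal(s$n_edges, length(intersect(info$members, cluster)))
  expect_equal(s$n_edges, length(info$members))  # bias 1: all in-cluster
})

test_that("SIF and GraphML exports round-trip node and edge multisets", {
  ppi <- ppi_edges(c("g2", "g5"), c("g3", "g6"))
  net <- demo_network(ppi)
  key <- function(e) sort(paste(e$source, e$edge_type, e$target))
  for (fmt in c("SIF", "GraphML")) {
    path <- withr::local_tempfile(fileext = tolower(paste0(".", fmt)))
    export_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_setequal(back$nodes$id, net$nodes$id)
    expect_equal(key(back$edges), key(net$edges))
    expect_equal(back$nodes[order(back$nodes$id), "node_type"],
                 net$nodes[order(net$nodes$id), "node_type"])
  }
})

test_that("round-trip survives awkward node ids", {
  set.seed(23)
  for (i in 1:5) {
    genes <- c("gene A", "g<&>2", "g'3", "naïve", "g_5")
    mirs <- c("miR 1*", "miR-2")
    picked <- sample(genes, 3)
    col <- gene_set_collection(mirs, list(picked, sample(genes, 2)),
                               "miRNA")
    enr <- rbind(enr_row(mirs[1], "miRNA", 0.001),
                 enr_row(mirs[2], "miRNA", 0.002))
    net <- build_network(genes, enr, col)
    key <- function(e) sort(paste(e$source, e$edge_type, e$target))
    for (fmt in c("SIF", "GraphML")) {
      path <- withr::local_tempfile()
      export_network(net, path, fmt)
      back <- read_network(path, fmt)
      expect_setequal(back$nodes$id, net$nodes$id)
      expect_equal(key(back$edges), key(net$edges))
    }
  }
})
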