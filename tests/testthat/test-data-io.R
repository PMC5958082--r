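test_that("expression TSV round-trips and rejects malformed input", {
  m <- tiny_matrix(c(1.5, 2.25, 3, 4, 5, 6.125),
                   features = c("f1", "f2", "f3"),
                   samples = c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path, "mRNA")
  expect_equal(unclass(back), unclass(m))

  # NA cell named by position
  writeLines(c("id\ts1\ts2", "f1\t1\tNA", "f2\t2\t3"), path)
  expect_error(read_expression(path, "mRNA"), "f1.*s2")

  # ragged row named by line
  writeLines(c("id\ts1\ts2", "f1\t1", "f2\t2\t3"), path)
  expect_error(read_expression(path, "mRNA"), "line 2")

  # duplicate sample ids
  writeLines(c("id\ts1\ts1", "f1\t1\t2"), path)
  expect_error(read_expression(path, "mRNA"), "duplicate sample")

  # duplicate feature ids must be collapsed upstream
  writeLines(c("id\ts1\ts2", "f1\t1\t2", "f1\t3\t4"), path)
  expect_error(read_expression(path, "mRNA"), "duplicate feature")
})

test_that("linear-input mode log2-transforms and rejects nonpositives", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "f1\t2\t8"), path)
  m <- read_expression(path, "mRNA", linear_input = TRUE)
  expect_equal(as.numeric(m), c(1, 3))
  writeLines(c("id\ts1\ts2", "f1\t0\t8"), path)
  expect_error(read_expression(path, "mRNA", linear_input = TRUE),
               "positive")
})

test_that("collapse_features averages probe sets on the log2 scale", {
  m <- tiny_matrix(c(4, 6, 10, 5, 7, 11),
                   features = c("ps1", "ps2", "ps3"),
                   samples = c("s1", "s2"))
  map <- c(ps1 = "G", ps2 = "G", ps3 = "H")
  out <- collapse_features(m, map)
  expect_equal(unname(unclass(out)["G", ]), c(5, 6))  # mean of 4,6 / 5,7
  expect_equal(unname(unclass(out)["H", ]), c(10, 11))
  expect_equal(rownames(out), c("G", "H"))  # lexicographic

  # one-to-one map is identity up to row order
  id_map <- setNames(rownames(m), rownames(m))
  out2 <- collapse_features(m, id_map)
  expect_equal(unclass(out2), unclass(m)[order(rownames(m)), ],
               ignore_attr = TRUE)

  # unmapped feature is an error listing the offender
  expect_error(collapse_features(m, c(ps1 = "G")), "ps2")
})

test_that("collapse_features matches a brute-force group mean", {
  set.seed(42)
  m <- tiny_matrix(rnorm(250), features = sprintf("f%02d", 1:50),
                   samples = sprintf("s%d", 1:5))
  map <- setNames(sample(sprintf("g%02d", 1:10), 50, replace = TRUE),
                  rownames(m))
  out <- collapse_features(m, map)
  # independent oracle: per-gene, per-sample mean via tapply
  for (g in unique(map)) {
    rows <- names(map)[map == g]
    expect_equal(unname(unclass(out)[g, ]),
                 unname(colMeans(unclass(m)[rows, , drop = FALSE])))
  }
})

test_that("GMT parsing handles families, rejects duplicates/empties", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("miR-300\tfamily=miR-300/381\tA\tB",
               "miR-1\t\tC\tD\tE"), path)
  col <- read_gmt(path, "miRNA")
  expect_length(col, 2)
  expect_equal(col[[1]]$members, c("A", "B"))
  expect_equal(col[[1]]$family, "miR-300/381")
  expect_true(is.na(col[[2]]$family))
  expect_equal(col[[2]]$kind, "miRNA")

  writeLines(c("s1\t\tA", "s1\t\tB"), path)
  expect_error(read_gmt(path, "TF"), "duplicate set name")

  writeLines("s1\tdesc", path)
  expect_error(read_gmt(path, "TF"), "fewer than 3")

  # write -> read round trip preserves sets and families
  col2 <- gene_set_collection(c("a", "b"), list(c("X", "Y"), "Z"),
                              kind = "TF", family = c("famA", NA))
  write_gmt(col2, path)
  back <- read_gmt(path, "TF")
  expect_equal(lapply(back, `[[`, "members"),
               lapply(col2, `[[`, "members"), ignore_attr = TRUE)
  expect_equal(back[[1]]$family, "famA")
})

test_that("PPI edges are deduplicated order-insensitively, loops rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tD"), path)
  ppi <- read_ppi(path)
  expect_equal(nrow(ppi), 2)
  expect_equal(ppi$a, c("A", "C"))
  writeLines("A\tA", path)
  expect_error(read_ppi(path), "self-loop")
})

test_that("sample design round-trips and validates phenotypes", {
  d <- balanced_design(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design(d, path)
  back <- read_design(path)
  expect_equal(back$sample_id, d$sample_id)
  expect_equal(as.character(back$phenotype), as.character(d$phenotype))
  expect_error(sample_design("s1", "XX"), "unknown phenotype")
  expect_error(sample_design(c("s1", "s1"), c("HC", "HC")), "duplicate")
})
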