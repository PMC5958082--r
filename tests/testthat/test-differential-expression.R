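make_two_group <- function(values_case, values_ctrl, n_features = 1) {
  n_case <- length(values_case) / n_features
  n_ctrl <- length(values_ctrl) / n_features
  m <- cbind(matrix(values_case, nrow = n_features),
             matrix(values_ctrl, nrow = n_features))
  dimnames(m) <- list(sprintf("f%d", seq_len(n_features)),
                      c(sprintf("ADT_%d", seq_len(n_case)),
                        sprintf("HC_%d", seq_len(n_ctrl))))
  list(matrix = expression_matrix(m, "mRNA"),
       design = sample_design(colnames(m),
                              rep(c("ADT", "HC"), c(n_case, n_ctrl))))
}

test_that("t-test gives t = 0, p = 1 for identical group means", {
  tg <- make_two_group(c(1, 2, 3), c(3, 2, 1))
  res <- two_group_ttest(tg$matrix, tg$design, "ADT")
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$log2fc, 0)
})

test_that("p tends to 0 as group separation sharpens", {
  jitter_p <- vapply(c(0.5, 0.05, 0.005), function(eps) {
    tg <- make_two_group(2 + eps * c(-1, 1, -1, 1),
                         0 + eps * c(1, -1, 1, -1))
    two_group_ttest(tg$matrix, tg$design, "ADT")$p_value
  }, numeric(1))
  expect_true(all(diff(jitter_p) < 0))
  expect_lt(jitter_p[3], 1e-8)
})

test_that("row-wise Welch and pooled t match stats::t.test exactly", {
  set.seed(7)
  n_feat <- 200
  m <- matrix(rnorm(n_feat * 20), n_feat,
              dimnames = list(sprintf("f%03d", 1:n_feat),
                              c(sprintf("ADU_%d", 1:8),
                                sprintf("HC_%d", 1:12))))
  mat <- expression_matrix(m, "mRNA")
  des <- sample_design(colnames(m), rep(c("ADU", "HC"), c(8, 12)))
  for (ev in c(FALSE, TRUE)) {
    res <- two_group_ttest(mat, des, "ADU", equal_var = ev)
    oracle <- t(vapply(seq_len(n_feat), function(i) {
      tt <- stats::t.test(m[i, 1:8], m[i, 9:20], var.equal = ev)
      c(tt$statistic, tt$p.value)
    }, numeric(2)))
    expect_equal(res$t_statistic, oracle[, 1], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(res$p_value, oracle[, 2], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("zero-variance-in-both-groups features get p = 1 with warning", {
  m <- rbind(f1 = c(2, 2, 2, 2, 2, 2), f2 = c(1, 2, 3, 0, 1, 2))
  colnames(m) <- c(paste0("ADT_", 1:3), paste0("HC_", 1:3))
  des <- sample_design(colnames(m), rep(c("ADT", "HC"), each = 3))
  expect_warning(
    res <- two_group_ttest(expression_matrix(m, "mRNA"), des, "ADT"),
    "zero variance")
  expect_equal(res$p_value[1], 1)
  expect_equal(res$t_statistic[1], 0)
  expect_lt(res$p_value[2], 1)  # the healthy feature still tested
})

test_that("q-value formula reproduces hand-computed worked example", {
  # N * p / R evaluated by hand: 5 * (0.01,...,0.05) / (1,...,5) = 0.05
  q <- compute_qvalues(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(q$q_value, rep(0.05, 5))
  expect_equal(q$rank_R, 1:5)
  # all p = 1 stays at the upper bound
  expect_equal(compute_qvalues(rep(1, 4))$q_value, rep(1, 4))
  # out-of-range p rejected
  expect_error(compute_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("tied p-values share the maximum rank and one q", {
  q <- compute_qvalues(c(0.02, 0.02, 0.5), monotonize = FALSE)
  expect_equal(q$rank_R, c(2L, 2L, 3L))
  expect_equal(q$q_raw[1], q$q_raw[2])
  expect_equal(q$q_raw[1], 3 * 0.02 / 2)
})

test_that("monotonized q equals Benjamini-Hochberg; literal mode is N*p/R", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:300, 1)
    p <- switch(1 + rep %% 3,
                runif(n),
                rbeta(n, 0.3, 4),            # enrichment-like skew
                round(runif(n), 2))           # heavy ties
    got <- compute_qvalues(p, monotonize = TRUE)$q_value
    expect_equal(got, p.adjust(p, method = "BH"), tolerance = 1e-12)
    lit <- compute_qvalues(p, monotonize = FALSE)
    r <- rank(p, ties.method = "max")
    expect_equal(lit$q_raw, n * p / r, tolerance = 1e-15)
    expect_equal(lit$q_value, pmin(1, n * p / r), tolerance = 1e-15)
    # q >= p and monotone in p always hold after monotonization
    expect_true(all(got >= p - 1e-15))
    expect_true(all(diff(got[order(p)]) >= -1e-15))
  }
})

test_that("swapping case and control negates fold changes, keeps p", {
  set.seed(21)
  m <- matrix(rnorm(50 * 10), 50,
              dimnames = list(sprintf("f%02d", 1:50),
                              c(sprintf("ADT_%d", 1:5),
                                sprintf("HC_%d", 1:5))))
  des_fwd <- sample_design(colnames(m), rep(c("ADT", "HC"), each = 5))
  des_rev <- sample_design(colnames(m), rep(c("HC", "ADT"), each = 5))
  fwd <- two_group_ttest(expression_matrix(m, "mRNA"), des_fwd, "ADT")
  rev <- two_group_ttest(expression_matrix(m, "mRNA"), des_rev, "ADT")
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p_value, fwd$p_value)
  d_fwd <- suppressMessages(de_contrast(expression_matrix(m, "mRNA"),
                                        des_fwd, "ADT"))
  d_rev <- suppressMessages(de_contrast(expression_matrix(m, "mRNA"),
                                        des_rev, "ADT"))
  flip <- c(U = "D", D = "U")
  expect_equal(unname(flip[d_fwd$direction]), d_rev$direction)
})

test_that("DEG calling is inclusive at the threshold and stably ordered", {
  de <- data.frame(feature_id = c("b", "a", "c", "d"),
                   log2fc = c(1, -1, 2, 0.5),
                   q_value = c(0.05, 0.05, 0.01, 0.2))
  got <- call_degs(de, threshold = 0.05)
  expect_equal(got$all, c("c", "a", "b"))  # q then feature id
  expect_equal(got$up, c("c", "b"))
  expect_equal(got$down, "a")
  expect_equal(call_degs(de[0, ], 0.05)$all, character(0))
  # threshold 1 calls everything
  expect_length(call_degs(de, threshold = 1)$all, 4)
})

test_that("planted DEGs are recovered with high recall and bounded FDR", {
  # 100 planted DEGs at |delta| = 2, noise 0.5, n = 20/group, 10 seeds
  recalls <- c(); fdrs <- c()
  for (seed in 1:10) {
    cfg <- sim_config(
      n_genes = 500, n_mirnas = 2,
      n_samples_per_phenotype = c(HC = 20, ADU = 2, ADT = 20, ID = 2),
      noise_sd = 0.5, effect_sizes = flat_effects(2),
      pattern_proportions = c(UUU = 0.1, UUD = 0, UDU = 0, UDD = 0,
                              DUU = 0, DUD = 0, DDU = 0, DDD = 0.1,
                              null = 0.8),
      seed = seed)
    sim <- simulate_expression(cfg)
    de <- de_contrast(sim$mrna, sim$design, "ADT")
    called <- call_degs(de)$all
    planted <- names(sim$truth$gene_pattern)[
      !is.na(sim$truth$gene_pattern)]
    recalls <- c(recalls, mean(planted %in% called))
    fdrs <- c(fdrs, if (length(called) > 0)
      mean(!called %in% planted) else 0)
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(fdrs), 0.10)
})
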