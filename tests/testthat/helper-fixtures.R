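# Shared fixture builders; everything is generated in code.

# tiny expression matrix with explicit values
tiny_matrix <- function(values, features = NULL, samples = NULL,
                        kind = "mRNA") {
  m <- matrix(values, nrow = length(features %||% rownames(values)))
  dimnames(m) <- list(features, samples)
  rewiremir::expression_matrix(m, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced 4-phenotype design with n samples per phenotype
balanced_design <- function(n) {
  ph <- rep(c("HC", "ADU", "ADT", "ID"), each = n)
  rewiremir::sample_design(paste0(ph, "_", rep(seq_len(n), 4)), ph)
}

# small simulation config used across tests
quick_config <- function(seed = 1, n_genes = 300, n_mirnas = 40,
                         noise_sd = 0.5, targets_per_regulator = 20,
                         ...) {
  rewiremir::sim_config(
    n_genes = n_genes, n_mirnas = n_mirnas,
    n_samples_per_phenotype = c(HC = 8, ADU = 8, ADT = 8, ID = 8),
    noise_sd = noise_sd, n_regulators_per_kind = 3,
    targets_per_regulator = targets_per_regulator, n_decoys_per_kind = 5,
    seed = seed, ...)
}

# effect sizes of constant magnitude for every pattern letter
flat_effects <- function(magnitude) {
  out <- lapply(c("UUU", "UUD", "UDU", "UDD", "DUU", "DUD", "DDU", "DDD"),
                function(p) {
                  ifelse(strsplit(p, "")[[1]] == "U", magnitude, -magnitude)
                })
  names(out) <- c("UUU", "UUD", "UDU", "UDD", "DUU", "DUD", "DDU", "DDD")
  out
}

# proportions concentrated on a few well-populated patterns
concentrated_proportions <- function(de_fraction = 0.4) {
  de <- c(UUU = 0.45, UUD = 0.05, UDU = 0, UDD = 0, DUU = 0, DUD = 0,
          DDU = 0.05, DDD = 0.45) * de_fraction
  c(de, null = 1 - de_fraction)
}

# observed log2 fold-change triples (group mean differences vs HC)
observed_lfc <- function(sim) {
  m <- unclass(sim$mrna)
  hc <- sim$design$sample_id[sim$design$phenotype == "HC"]
  out <- vapply(c("ADU", "ADT", "ID"), function(ph) {
    ids <- sim$design$sample_id[sim$design$phenotype == ph]
    rowMeans(m[, ids, drop = FALSE]) - rowMeans(m[, hc, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(out) <- rownames(m)
  out
}

# qPCR Ct table with planted ADT-vs-HC log2 fold changes
qpcr_fixture <- function(deltas, n = 4, noise = 0) {
  rows <- list()
  for (ph in c("HC", "ADT")) {
    for (i in seq_len(n)) {
      ref <- 18
      for (f in names(deltas)) {
        d <- if (ph == "ADT") deltas[[f]] else 0
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = paste0(ph, i), phenotype = ph, feature_id = f,
          ct_target = 24 - d + noise * rnorm(1), ct_reference = ref)
      }
    }
  }
  do.call(rbind, rows)
}

# brute-force upper-tail overlap probability by enumerating every
# possible draw of a |B|-subset from the universe (independent of the
# package's hypergeometric summation)
enumerate_overlap_p <- function(set_a, size_b, universe, k_obs) {
  draws <- combn(universe, size_b, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set_a)) >= k_obs,
              logical(1)))
}
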