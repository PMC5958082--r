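#' Simulation configuration
#'
#' Bundles every parameter of the synthetic multi-phenotype expression
#' generator and validates it. Defaults emulate the study design this
#' pipeline targets: four phenotypes (HC control plus ADU, ADT, ID
#' patient groups, sample sizes matching a typical cross-sectional
#' treatment-response cohort), additive Gaussian noise on the log2 scale
#' as appropriate for RMA-summarized arrays, and planted direction
#' patterns whose within-DEG proportions follow the cluster census this
#' kind of study reports (same-direction clusters dominating, sign-flip
#' clusters rare). Same-direction patterns are planted with an attenuated
#' inactive-disease effect so that UUu/DDd sub-clusters exist in truth.
#'
#' @param n_genes Number of genes in the mRNA matrix.
#' @param n_mirnas Number of miRNAs in the miRNA matrix.
#' @param n_samples_per_phenotype Named integer vector over
#'   `c(HC, ADU, ADT, ID)`.
#' @param baseline_mean Baseline log2 intensity.
#' @param noise_sd Gaussian noise SD, log2 units (> 0).
#' @param effect_sizes Named list mapping each 3-letter pattern to its
#'   `(delta_ADU, delta_ADT, delta_ID)` log2 effect triple; signs must
#'   match the pattern letters (U positive, D negative).
#' @param pattern_proportions Named numeric vector over the 8 patterns
#'   plus `"null"`, summing to 1.
#' @param n_regulators_per_kind Planted regulators of each kind
#'   (miRNA and TF).
#' @param targets_per_regulator Target-set size for planted regulators.
#' @param regulator_cluster_bias Fraction of a planted regulator's
#'   targets drawn from its planted cluster (0..1).
#' @param n_decoys_per_kind Decoy regulators (uniform member draw) of
#'   each kind emitted alongside the planted ones.
#' @param seed Integer seed; all randomness is local to this seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4000,
                       n_mirnas = 400,
                       n_samples_per_phenotype = c(HC = 43, ADU = 35,
                                                   ADT = 26, ID = 14),
                       baseline_mean = 8,
                       noise_sd = 0.8,
                       effect_sizes = NULL,
                       pattern_proportions = NULL,
                       n_regulators_per_kind = 5,
                       targets_per_regulator = 50,
                       regulator_cluster_bias = 0.8,
                       n_decoys_per_kind = 20,
                       seed = 1L) {
  if (is.null(effect_sizes)) effect_sizes <- default_effect_sizes()
  if (is.null(pattern_proportions)) {
    pattern_proportions <- default_pattern_proportions()
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_mirnas = as.integer(n_mirnas),
    n_samples_per_phenotype = n_samples_per_phenotype,
    baseline_mean = baseline_mean,
    noise_sd = noise_sd,
    effect_sizes = effect_sizes,
    pattern_proportions = pattern_proportions,
    n_regulators_per_kind = as.integer(n_regulators_per_kind),
    targets_per_regulator = as.integer(targets_per_regulator),
    regulator_cluster_bias = regulator_cluster_bias,
    n_decoys_per_kind = as.integer(n_decoys_per_kind),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default effect-size triples, log2 units
#'
#' Magnitude 1.5 for ADU/ADT letters; same-direction patterns get an
#' attenuated inactive-disease effect (|delta_ID| = 0.75 < |delta_ADU|)
#' so planted UUU/DDD genes carry a recoverable UUu/DDd sub-pattern.
#' @noRd
default_effect_sizes <- function(magnitude = 1.5, id_attenuated = 0.75) {
  out <- lapply(ALL_PATTERNS, function(p) {
    letters3 <- strsplit(p, "")[[1]]
    delta <- ifelse(letters3 == "U", magnitude, -magnitude)
    if (p %in% c("UUU", "DDD")) {
      delta[3] <- sign(delta[3]) * id_attenuated
    }
    delta
  })
  names(out) <- ALL_PATTERNS
  out
}

#' Default pattern proportions
#'
#' 40% of genes are differentially expressed; within the DE fraction the
#' pattern mix follows the census reported for treated-JIA neutrophil
#' DEGs (UUU 45.2%, DDD 44.96%, UUD 5.2%, DDU 2.87%, UDD 0.77%,
#' DUU 0.5%, UDU 0.45%, DUD 0.15%; renormalized to sum to 1).
#' @noRd
default_pattern_proportions <- function(de_fraction = 0.4) {
  census <- c(UUU = 45.2, UUD = 5.2, UDU = 0.45, UDD = 0.77,
              DUU = 0.5, DUD = 0.15, DDU = 2.87, DDD = 44.96)
  census <- census / sum(census)
  c(census * de_fraction, null = 1 - de_fraction)[c(ALL_PATTERNS, "null")]
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid simulation config: ", ...,
                                 call. = FALSE)
  counts <- c(cfg$n_genes, cfg$n_mirnas, cfg$n_regulators_per_kind,
              cfg$targets_per_regulator)
  if (any(counts <= 0)) stop_cfg("all counts must be > 0")
  if (!setequal(names(cfg$n_samples_per_phenotype), PHENOTYPES) ||
      any(cfg$n_samples_per_phenotype <= 0)) {
    stop_cfg("n_samples_per_phenotype must be positive over ",
             paste(PHENOTYPES, collapse = ", "))
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0) {
    stop_cfg("noise_sd must be >= 0")
  }
  pp <- cfg$pattern_proportions
  if (!setequal(names(pp), c(ALL_PATTERNS, "null"))) {
    stop_cfg("pattern_proportions must cover the 8 patterns plus 'null'")
  }
  if (any(pp < 0) || abs(sum(pp) - 1) > 1e-9) {
    stop_cfg("pattern_proportions must be non-negative and sum to 1")
  }
  if (!setequal(names(cfg$effect_sizes), ALL_PATTERNS)) {
    stop_cfg("effect_sizes must cover all 8 patterns")
  }
  for (p in ALL_PATTERNS) {
    delta <- cfg$effect_sizes[[p]]
    if (length(delta) != 3) stop_cfg("effect triple for ", p,
                                     " must have length 3")
    want <- ifelse(strsplit(p, "")[[1]] == "U", 1, -1)
    if (any(sign(delta) != want)) {
      stop_cfg("effect-size signs for pattern ", p,
               " do not match its letters")
    }
  }
  if (cfg$regulator_cluster_bias < 0 || cfg$regulator_cluster_bias > 1) {
    stop_cfg("regulator_cluster_bias must be in [0, 1]")
  }
  if (cfg$n_decoys_per_kind < 0) stop_cfg("n_decoys_per_kind must be >= 0")
  invisible(TRUE)
}

#' Simulate multi-phenotype mRNA and miRNA expression with planted truth
#'
#' Each gene is assigned a direction pattern (or the null class) by the
#' configured proportions. Its value for a sample of phenotype `p` is
#' `baseline + delta_p + N(0, noise_sd)`, where `delta_p` is the
#' pattern's effect for that phenotype (0 for HC and for null genes).
#' The first `n_regulators_per_kind` miRNAs are planted as
#' anti-correlated regulators: each is tied to a planted cluster drawn
#' from the non-empty DE patterns and carries the letter-wise opposite
#' effect triple. Remaining miRNAs are null.
#'
#' @param config A [sim_config()].
#' @return A list with elements `mrna` and `mirna`
#'   ([expression_matrix()]s), `design` ([sample_design()]) and `truth`
#'   (list with `gene_pattern`, `gene_subpattern`, `gene_effects`,
#'   `regulators`, `mirna_direction`, `seed`).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  with_local_seed(config$seed, simulate_expression_impl(config))
}

simulate_expression_impl <- function(config) {
  ns <- config$n_samples_per_phenotype[PHENOTYPES]
  phenos <- rep(PHENOTYPES, times = ns)
  sample_ids <- paste0(phenos, "_", unlist(lapply(ns, seq_len)))
  design <- sample_design(sample_ids, phenos)

  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  classes <- sample(names(config$pattern_proportions), config$n_genes,
                    replace = TRUE, prob = config$pattern_proportions)
  names(classes) <- gene_ids

  # per-gene effect triple over (ADU, ADT, ID); zero for null genes
  eff <- matrix(0, nrow = config$n_genes, ncol = 3,
                dimnames = list(gene_ids, CONTRAST_PHENOTYPES))
  for (p in ALL_PATTERNS) {
    idx <- classes == p
    if (any(idx)) eff[idx, ] <- matrix(config$effect_sizes[[p]],
                                       nrow = sum(idx), ncol = 3,
                                       byrow = TRUE)
  }

  # phenotype effect per sample column, then additive Gaussian noise
  delta_by_pheno <- cbind(HC = 0, eff)[, phenos, drop = FALSE]
  mrna_vals <- config$baseline_mean + delta_by_pheno +
    matrix(rnorm(config$n_genes * length(phenos), sd = config$noise_sd),
           nrow = config$n_genes)
  dimnames(mrna_vals) <- list(gene_ids, sample_ids)
  mrna <- expression_matrix(mrna_vals, "mRNA")

  # planted anti-correlated miRNA regulators: opposite effect triple to
  # the pattern of their planted cluster
  mirna_ids <- sprintf("miR-%04d", seq_len(config$n_mirnas))
  planted_patterns <- names(which(
    config$pattern_proportions[ALL_PATTERNS] > 0))
  if (length(planted_patterns) == 0) {
    planted_mirnas <- character(0)
  } else {
    n_reg <- min(config$n_regulators_per_kind, config$n_mirnas)
    planted_mirnas <- mirna_ids[seq_len(n_reg)]
  }
  mirna_cluster <- setNames(
    sample(planted_patterns, length(planted_mirnas), replace = TRUE),
    planted_mirnas)
  mirna_eff <- matrix(0, nrow = config$n_mirnas, ncol = 3,
                      dimnames = list(mirna_ids, CONTRAST_PHENOTYPES))
  for (m in planted_mirnas) {
    mirna_eff[m, ] <- -config$effect_sizes[[mirna_cluster[[m]]]]
  }
  mirna_delta <- cbind(HC = 0, mirna_eff)[, phenos, drop = FALSE]
  mirna_vals <- config$baseline_mean + mirna_delta +
    matrix(rnorm(config$n_mirnas * length(phenos), sd = config$noise_sd),
           nrow = config$n_mirnas)
  dimnames(mirna_vals) <- list(mirna_ids, sample_ids)
  mirna <- expression_matrix(mirna_vals, "miRNA")

  subpat <- vapply(gene_ids, function(g) {
    if (classes[[g]] == "null") NA_character_
    else subpattern_from_lfc(classes[[g]], eff[g, ])
  }, character(1))

  truth <- list(
    gene_pattern = ifelse(classes == "null", NA_character_, classes),
    gene_subpattern = subpat,
    gene_effects = eff,
    mirna_direction = mirna_eff,
    mirna_cluster = mirna_cluster,
    regulators = list(),   # filled by simulate_target_sets()
    seed = config$seed
  )
  list(mrna = mrna, mirna = mirna, design = design, truth = truth)
}

#' Simulate regulator target-set collections with planted enrichment
#'
#' For each planted regulator a target set of `targets_per_regulator`
#' genes is drawn: a fraction `regulator_cluster_bias` from the
#' regulator's planted cluster (genes whose true pattern matches) and
#' the remainder uniformly from the other genes. Planted miRNA
#' regulators reuse the anti-correlated miRNAs planted by
#' [simulate_expression()]; planted TFs are synthesized with clusters
#' drawn the same way. Decoy regulators draw all members uniformly.
#'
#' @param sim Result of [simulate_expression()] (its `truth` is updated).
#' @param config The same [sim_config()].
#' @return A list: `mirna_sets` and `tf_sets`
#'   ([gene_set_collection()]s) and the updated `truth`.
#' @export
simulate_target_sets <- function(sim, config) {
  validate_sim_config(config)
  with_local_seed(config$seed + 1L, simulate_target_sets_impl(sim, config))
}

simulate_target_sets_impl <- function(sim, config) {
  truth <- sim$truth
  gene_ids <- names(truth$gene_pattern)
  size <- config$targets_per_regulator
  if (size > length(gene_ids)) {
    stop("targets_per_regulator exceeds the gene universe", call. = FALSE)
  }
  bias <- config$regulator_cluster_bias

  draw_set <- function(cluster) {
    in_cluster <- gene_ids[!is.na(truth$gene_pattern) &
                             truth$gene_pattern == cluster]
    n_in <- min(round(bias * size), length(in_cluster))
    picked_in <- sample(in_cluster, n_in)
    pool <- setdiff(gene_ids, picked_in)
    c(picked_in, sample(pool, size - n_in))
  }

  planted_mirnas <- names(truth$mirna_cluster)
  planted_patterns <- names(which(
    config$pattern_proportions[ALL_PATTERNS] > 0))
  tf_names <- sprintf("TF_%03d", seq_len(config$n_regulators_per_kind))
  tf_cluster <- setNames(
    sample(planted_patterns, length(tf_names), replace = TRUE), tf_names)

  regulators <- list()
  mirna_members <- lapply(planted_mirnas, function(m)
    draw_set(truth$mirna_cluster[[m]]))
  for (i in seq_along(planted_mirnas)) {
    m <- planted_mirnas[i]
    regulators[[m]] <- list(kind = "miRNA", members = mirna_members[[i]],
                            cluster = truth$mirna_cluster[[m]])
  }
  tf_members <- lapply(tf_names, function(tf) draw_set(tf_cluster[[tf]]))
  for (i in seq_along(tf_names)) {
    regulators[[tf_names[i]]] <- list(kind = "TF", members = tf_members[[i]],
                                      cluster = tf_cluster[[tf_names[i]]])
  }

  decoy_members <- function(n) {
    lapply(seq_len(n), function(i) sample(gene_ids, size))
  }
  mirna_decoy_names <- sprintf("decoy-miR-%04d",
                               seq_len(config$n_decoys_per_kind))
  tf_decoy_names <- sprintf("decoy-TF_%03d",
                            seq_len(config$n_decoys_per_kind))
  mirna_decoys <- decoy_members(config$n_decoys_per_kind)
  tf_decoys <- decoy_members(config$n_decoys_per_kind)

  mirna_sets <- gene_set_collection(
    c(planted_mirnas, mirna_decoy_names),
    c(mirna_members, mirna_decoys),
    kind = "miRNA")
  tf_sets <- gene_set_collection(
    c(tf_names, tf_decoy_names),
    c(tf_members, tf_decoys),
    kind = "TF")

  truth$regulators <- regulators
  list(mirna_sets = mirna_sets, tf_sets = tf_sets, truth = truth)
}

#' Simulate a qPCR Ct table consistent with planted fold changes
#'
#' Generates per-sample threshold-cycle values for a panel of features
#' and a reference feature so that the 2^-ddCt fold change between a
#' patient phenotype and HC recovers the planted linear fold change
#' (up to noise): a planted log2 effect `delta` lowers the target Ct by
#' `delta` in that phenotype. The reference feature must have no planted
#' effect; passing a feature with a non-null planted pattern as
#' reference is an error.
#'
#' @param sim Result of [simulate_expression()].
#' @param config The same [sim_config()].
#' @param feature_ids Panel features (default: first 11 planted DE genes).
#' @param reference_id Reference feature id (default `"REF"`, a
#'   synthetic zero-effect feature).
#' @param phenotypes Phenotypes to include (default ADT and HC, the
#'   usual validation cohort design).
#' @param n_per_phenotype Samples per phenotype (default 8).
#' @param ct_noise_sd Gaussian noise SD on Ct values (default 0.2).
#' @return A `data.frame` with columns `sample_id`, `phenotype`,
#'   `feature_id`, `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(sim, config, feature_ids = NULL,
                          reference_id = "REF",
                          phenotypes = c("HC", "ADT"),
                          n_per_phenotype = 8, ct_noise_sd = 0.2) {
  truth <- sim$truth
  if (is.null(feature_ids)) {
    de <- names(truth$gene_pattern)[!is.na(truth$gene_pattern)]
    feature_ids <- head(de, 11)
  }
  if (reference_id %in% names(truth$gene_pattern) &&
      !is.na(truth$gene_pattern[[reference_id]])) {
    stop("reference feature '", reference_id,
         "' has a planted effect; a qPCR normalizer must be stable",
         call. = FALSE)
  }
  unknown <- setdiff(feature_ids, names(truth$gene_pattern))
  if (length(unknown)) {
    stop("unknown panel feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  with_local_seed(config$seed + 2L, {
    rows <- list()
    for (ph in phenotypes) {
      for (i in seq_len(n_per_phenotype)) {
        sid <- sprintf("q%s_%02d", ph, i)
        ct_ref <- 18 + rnorm(1, sd = ct_noise_sd)
        for (f in feature_ids) {
          delta <- if (ph == "HC" || is.na(truth$gene_pattern[[f]])) 0
                   else truth$gene_effects[f, ph]
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, phenotype = ph, feature_id = f,
            ct_target = 24 - delta + rnorm(1, sd = ct_noise_sd),
            ct_reference = ct_ref, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Write the planted truth of a simulation as JSON
#' @param truth The `truth` element of a simulation result.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    gene_pattern = as.list(truth$gene_pattern),
    gene_subpattern = as.list(truth$gene_subpattern),
    gene_effects = apply(truth$gene_effects, 1, as.list),
    mirna_direction = apply(truth$mirna_direction, 1, as.list),
    mirna_cluster = as.list(truth$mirna_cluster),
    regulators = truth$regulators,
    seed = truth$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
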