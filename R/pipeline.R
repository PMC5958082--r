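#' Pipeline configuration
#'
#' One object driving the full analysis arc: simulate (or load)
#' expression data, collapse probe sets, run the three phenotype-vs-HC
#' contrasts, overlap statistics, direction-pattern clustering,
#' regulator enrichment, miRNA direction-consistency checks and
#' co-regulatory network assembly.
#'
#' Exactly one of `simulation` and `inputs` must be given. `inputs` is a
#' named list of file paths: `mrna`, `design` (required), `mirna`,
#' `mirna_gmt`, `tf_gmt`, `ppi`, `feature_map` (optional; 2-column TSV
#' feature -> gene).
#'
#' @param simulation A [sim_config()], or `NULL`.
#' @param inputs Named list of input paths, or `NULL`.
#' @param q_threshold DEG cutoff on q (inclusive, default 0.05).
#' @param p_threshold Enrichment cutoff on uncorrected Fisher p
#'   (exclusive, default 0.01).
#' @param universe_override Optional universe size for overlap tests
#'   (default: number of genes tested).
#' @param equal_var,monotonize,linear_input,expand_ppi Flags forwarded
#'   to the respective stages.
#' @param out_dir Output directory (created); `NULL` for no files.
#' @param seed Integer seed used for simulation mode.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            q_threshold = 0.05, p_threshold = 0.01,
                            universe_override = NULL,
                            equal_var = FALSE, monotonize = TRUE,
                            linear_input = FALSE, expand_ppi = FALSE,
                            out_dir = NULL, seed = 1L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of `simulation` and `inputs` must be given",
         call. = FALSE)
  }
  if (q_threshold <= 0 || q_threshold > 1 ||
      p_threshold <= 0 || p_threshold > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(inputs)) {
    req <- setdiff(c("mrna", "design"), names(inputs))
    if (length(req)) {
      stop("inputs must include: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(simulation = simulation, inputs = inputs,
                 q_threshold = q_threshold, p_threshold = p_threshold,
                 universe_override = universe_override,
                 equal_var = equal_var, monotonize = monotonize,
                 linear_input = linear_input, expand_ppi = expand_ppi,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and (when `out_dir` is set) writes the
#' stage outputs as plain-text tables plus a JSON run manifest with the
#' seed, thresholds and md5 checksums of every written file, so a rerun
#' with an identical config is verifiably byte-identical. Any stage
#' error aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return A list bundle: `mrna`, `mirna`, `design`, `truth` (simulation
#'   mode), `de` (per-contrast results, mRNA), `mirna_de`, `degs`,
#'   `mirna_degs`, `overlaps`, `venn`, `assignments`, `census`,
#'   `clusters`, `enrichment` (all tests, with `significant` flag),
#'   `consistency`, `networks`, `network_summaries`, `qpcr`,
#'   `concordance`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- list()

  if (!is.null(config$simulation)) {
    sim <- stage("simulate", {
      s <- simulate_expression(config$simulation)
      ts <- simulate_target_sets(s, config$simulation)
      s$truth <- ts$truth
      s$mirna_sets <- ts$mirna_sets
      s$tf_sets <- ts$tf_sets
      s$qpcr <- simulate_qpcr(s, config$simulation)
      s
    })
    mrna <- sim$mrna; mirna <- sim$mirna; design <- sim$design
    mirna_sets <- sim$mirna_sets; tf_sets <- sim$tf_sets
    ppi <- NULL
    out$truth <- sim$truth
    out$qpcr <- sim$qpcr
  } else {
    inp <- config$inputs
    mrna <- stage("read_expression",
                  read_expression(inp$mrna, "mRNA",
                                  linear_input = config$linear_input))
    design <- stage("read_design", read_design(inp$design))
    mirna <- if (!is.null(inp$mirna)) {
      stage("read_expression",
            read_expression(inp$mirna, "miRNA",
                            linear_input = config$linear_input))
    }
    if (!is.null(inp$feature_map)) {
      fm <- read.delim(inp$feature_map, stringsAsFactors = FALSE)
      mrna <- stage("collapse_features",
                    collapse_features(mrna, setNames(fm[[2]], fm[[1]])))
    }
    mirna_sets <- if (!is.null(inp$mirna_gmt)) {
      stage("read_gmt", read_gmt(inp$mirna_gmt, "miRNA"))
    }
    tf_sets <- if (!is.null(inp$tf_gmt)) {
      stage("read_gmt", read_gmt(inp$tf_gmt, "TF"))
    }
    ppi <- if (!is.null(inp$ppi)) stage("read_ppi", read_ppi(inp$ppi))
  }
  out$mrna <- mrna; out$mirna <- mirna; out$design <- design

  out$de <- stage("differential_expression", {
    res <- lapply(CONTRAST_PHENOTYPES, function(ph)
      de_contrast(mrna, design, ph, q_threshold = config$q_threshold,
                  equal_var = config$equal_var,
                  monotonize = config$monotonize))
    names(res) <- CONTRAST_PHENOTYPES
    res
  })
  out$degs <- lapply(out$de, call_degs, threshold = config$q_threshold)

  if (!is.null(mirna)) {
    out$mirna_de <- stage("differential_expression_mirna", {
      res <- lapply(CONTRAST_PHENOTYPES, function(ph)
        de_contrast(mirna, design, ph, q_threshold = config$q_threshold,
                    equal_var = config$equal_var,
                    monotonize = config$monotonize))
      names(res) <- CONTRAST_PHENOTYPES
      res
    })
    out$mirna_degs <- lapply(out$mirna_de, call_degs,
                             threshold = config$q_threshold)
  }

  out$overlaps <- stage("overlap_analysis", {
    universe <- config$universe_override %||% nrow(mrna)
    deg_sets <- lapply(out$degs, `[[`, "all")
    pairwise_overlaps(deg_sets, universe)
  })
  out$venn <- stage("overlap_analysis",
                    venn_partition(lapply(out$degs, `[[`, "all")))

  out$assignments <- stage("dynamic_clustering", {
    union_genes <- union_degs(lapply(out$degs, `[[`, "all"))
    lfc <- vapply(out$de, function(d)
      setNames(d$log2fc, d$feature_id)[union_genes],
      numeric(length(union_genes)))
    lfc <- matrix(lfc, ncol = 3,
                  dimnames = list(union_genes, CONTRAST_PHENOTYPES))
    assign_patterns(lfc)
  })
  out$census <- cluster_census(out$assignments)
  out$clusters <- cluster_members(out$assignments, use_subpattern = TRUE)

  collections <- Filter(Negate(is.null), list(mirna_sets, tf_sets))
  if (length(collections)) {
    out$enrichment <- stage("regulator_enrichment",
      enrich_all(out$clusters, collections, universe = rownames(mrna),
                 p_threshold = config$p_threshold, keep_all = TRUE))

    sig <- out$enrichment[out$enrichment$significant, , drop = FALSE]

    if (!is.null(mirna)) {
      out$consistency <- stage("consistency_validation", {
        mir_sig <- sig[sig$kind == "miRNA" &
                         sig$regulator %in% rownames(mirna), , drop = FALSE]
        if (nrow(mir_sig) == 0) NULL else {
          lfc_of <- function(m) vapply(out$mirna_de, function(d)
            d$log2fc[match(m, d$feature_id)], numeric(1))
          do.call(rbind, lapply(seq_len(nrow(mir_sig)), function(i)
            direction_consistency(mir_sig$regulator[i],
                                  lfc_of(mir_sig$regulator[i]),
                                  mir_sig$cluster_id[i])))
        }
      })
    }

    out$networks <- stage("coregulatory_network", {
      nets <- list()
      for (cl in unique(sig$cluster_id)) {
        nets[[cl]] <- suppressWarnings(build_network(
          out$clusters[[cl]], sig[sig$cluster_id == cl, , drop = FALSE],
          collections, ppi = ppi, cluster_id = cl,
          expand_ppi = config$expand_ppi))
      }
      nets
    })
    out$network_summaries <- lapply(out$networks, network_summary)
  }

  if (!is.null(out$qpcr)) {
    out$concordance <- stage("consistency_validation", {
      fc <- ddct_fold_change(out$qpcr, "ADT")
      array_lfc <- setNames(out$de$ADT$log2fc, out$de$ADT$feature_id)
      platform_concordance(array_lfc[fc$feature_id],
                           setNames(fc$fold_change, fc$feature_id))
    })
  }

  if (!is.null(config$out_dir)) {
    out$manifest <- stage("write_outputs", write_bundle(out, config))
  }
  invisible(out)
}

#' Write the pipeline bundle to disk and build the run manifest
#' @noRd
write_bundle <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  written <- character(0)
  add <- function(path) written <<- c(written, path)

  for (ph in names(out$de)) {
    add(write_de(out$de[[ph]], p(sprintf("de_mrna_%s.tsv", ph))))
  }
  for (ph in names(out$mirna_de %||% list())) {
    add(write_de(out$mirna_de[[ph]], p(sprintf("de_mirna_%s.tsv", ph))))
  }
  write.table(out$overlaps, p("overlaps.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  add(p("overlaps.tsv"))
  jsonlite::write_json(as.list(out$venn), p("venn.json"),
                       auto_unbox = TRUE)
  add(p("venn.json"))
  write.table(out$assignments, p("patterns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add(p("patterns.tsv"))
  jsonlite::write_json(out$census, p("census.json"), digits = NA,
                       na = "null")
  add(p("census.json"))
  if (!is.null(out$enrichment)) {
    write.table(out$enrichment, p("enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add(p("enrichment.tsv"))
  }
  if (!is.null(out$consistency)) {
    write.table(out$consistency, p("consistency.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add(p("consistency.tsv"))
  }
  for (cl in names(out$networks %||% list())) {
    add(export_network(out$networks[[cl]],
                       p(sprintf("network_%s.sif", cl)), "SIF"))
  }
  if (!is.null(out$network_summaries)) {
    jsonlite::write_json(out$network_summaries, p("network_summary.json"),
                         auto_unbox = TRUE)
    add(p("network_summary.json"))
  }
  if (!is.null(out$truth)) {
    add(write_truth(out$truth, p("truth.json")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rewiremir")),
    seed = config$seed,
    q_threshold = config$q_threshold,
    p_threshold = config$p_threshold,
    flags = list(equal_var = config$equal_var,
                 monotonize = config$monotonize,
                 linear_input = config$linear_input,
                 expand_ppi = config$expand_ppi),
    files = as.list(tools::md5sum(sort(written)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}
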