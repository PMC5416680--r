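#' Default pipeline configuration
#'
#' Flat named list of every tunable the pipeline reads. Thresholds default to
#' the standard two-tier DEG stringency (fold >= 2 at P < 0.05 and P < 0.01),
#' enrichment alpha 0.01, and a 200-replicate topology null.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(fc_min = 2, p_max = 0.05, p_max_strict = 0.01,
              p_column = "raw", alpha_enrich = 0.01,
              topology_replicates = 200, rng_seed = 1,
              qpcr_reference = "GAPDH", qpcr_fc_min = 2, qpcr_p_max = 0.05,
              enrichment_universe = "interactome")
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stopf("unknown config key: %s", bad[1])
  cfg[names(override)] <- override
  stopifnot(cfg$fc_min > 0, cfg$p_max > 0, cfg$p_max_strict > 0,
            cfg$alpha_enrich > 0, cfg$topology_replicates >= 1)
  structure(cfg, class = c("run_config", "list"))
}

#' Read a flat key=value configuration file
#' @param path text file of `key = value` lines; `#` comments allowed.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    v
  })
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  do.call(run_config, vals)
}

#' Run the full analysis chain on one input bundle
#'
#' Executes, in order: differential expression, DEG selection at both
#' stringency tiers, locus-group accounting, sample clustering and PCA,
#' PIN construction with the random-null topology comparison, gene-set
#' over-representation, and qPCR quantification. All stage outputs are
#' written to `out_dir` as TSV/JSON plus a run manifest with the counts at
#' every filter.
#'
#' @param counts a [count_matrix()].
#' @param annotation annotation data.frame (see [annotation_table()]).
#' @param interactome reference `igraph`.
#' @param gene_sets named list of member vectors (see [read_gmt()]).
#' @param qpcr optional [qpcr_plate()].
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return the manifest list, invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(counts, annotation, interactome, gene_sets,
                         qpcr = NULL, config = run_config(),
                         out_dir = tempfile("degnet_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  fit <- stage("differential_expression", nb_exact_de(counts))
  write.table(fit$table, file.path(out_dir, "de_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  degs <- stage("deg_selection",
                select_degs(fit, config$fc_min, config$p_max, config$p_column))
  degs_strict <- select_degs(fit, config$fc_min, config$p_max_strict,
                             config$p_column)
  write.table(degs_strict, file.path(out_dir, "degs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  acct <- partition_locus_groups(degs_strict, annotation)

  lt <- stage("clustering", {
    tr <- transform_counts(counts, fit$size_factors)
    d <- euclidean_distances(tr)
    tree <- hierarchical_cluster(d)
    pca <- pca_two_components(tr)
    write.table(d, file.path(out_dir, "distances.tsv"), sep = "\t",
                quote = FALSE)
    ape_ok <- requireNamespace("ape", quietly = TRUE)
    if (ape_ok)
      ape::write.tree(ape::as.phylo(tree), file.path(out_dir, "tree.nwk"))
    write.table(data.frame(sample_id = rownames(pca$scores), pca$scores),
                file.path(out_dir, "pca.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(tree = tree, pca = pca)
  })

  net <- stage("network_topology", {
    pc <- degs_strict$gene_id[
      annotation$locus_group[match(degs_strict$gene_id,
                                   annotation$gene_id)] == "protein_coding"]
    symbols <- annotation$symbol[match(pc, annotation$gene_id)]
    mf <- mapped_seed_fraction(symbols, interactome)
    pin <- build_pin(symbols, interactome)
    cmp <- compare_topology(pin, interactome,
                            R = config$topology_replicates,
                            rng_seed = config$rng_seed)
    write.table(igraph::as_edgelist(pin$graph),
                file.path(out_dir, "pin_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(cmp$null, file.path(out_dir, "null_replicates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(mapped = mf, pin = pin, comparison = cmp)
  })

  enr <- stage("enrichment", {
    # query = PIN membership; universe = interactome nodes (default) or the
    # whole annotated symbol space
    universe <- if (identical(config$enrichment_universe, "interactome"))
      igraph::V(interactome)$name else unique(annotation$symbol)
    res <- fisher_enrichment(igraph::V(net$pin$graph)$name, gene_sets,
                             universe = universe,
                             alpha = config$alpha_enrich)
    write.table(res, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res
  })

  qp <- if (!is.null(qpcr)) stage("qpcr", {
    rel <- qpcr_relative_expression(qpcr, config$qpcr_reference,
                                    config$qpcr_fc_min, config$qpcr_p_max)
    write.table(rel, file.path(out_dir, "qpcr_relative_expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rel
  })

  manifest <- list(
    rng_seed = config$rng_seed,
    thresholds = config[c("fc_min", "p_max", "p_max_strict", "p_column",
                          "alpha_enrich", "topology_replicates")],
    n_genes_tested = nrow(fit$table),
    n_degs_tier1 = nrow(degs), n_degs_tier2 = nrow(degs_strict),
    n_up = acct$n_up, n_down = acct$n_down,
    locus_groups = as.list(acct$locus_groups),
    seeds_mapped = net$mapped$n_mapped, seeds_total = net$mapped$n_total,
    mapped_percent = net$mapped$percent,
    pin_nodes = net$comparison$observed$n_nodes,
    pin_edges = net$comparison$observed$n_edges,
    pin_density = net$comparison$observed$density,
    pin_aspl = net$comparison$observed$aspl,
    ks_paths_D = net$comparison$ks_paths$D,
    ks_degree_D = net$comparison$ks_degree$D,
    empirical_p_density = net$comparison$empirical_p_density,
    empirical_p_aspl = net$comparison$empirical_p_aspl,
    n_enriched_terms = if (nrow(enr)) sum(enr$significant) else 0L,
    qpcr_calls = if (!is.null(qp))
      as.list(stats::setNames(qp$call, qp$gene)) else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
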