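#' Simulation design for a case-control count matrix
#'
#' Defaults mirror the cohort shape the pipeline targets: a small iPSC-derived
#' neuronal study with 4 case vs 4 control samples, ~25,000 transcribed genes,
#' a small minority of differentially expressed genes at |log2FC| >= 1, and
#' negative-binomial overdispersion with unequal library sizes.
#'
#' @param n_genes number of genes.
#' @param n_case,n_control samples per group.
#' @param meanlog,sdlog log-normal parameters for baseline mean expression.
#' @param dispersion per-gene NB dispersion alpha (var = mu + alpha*mu^2);
#'   scalar or length `n_genes`.
#' @param de_fraction fraction of genes with a planted group effect.
#' @param log2fc_effect magnitude of planted log2 fold changes.
#' @param libsize_sdlog log-sd of the per-sample library size factors.
#' @param seed integer RNG seed.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(n_genes = 25000, n_case = 4, n_control = 4,
                       meanlog = 3.5, sdlog = 1.5, dispersion = 0.1,
                       de_fraction = 0.015, log2fc_effect = 2,
                       libsize_sdlog = 0.25, seed = 1) {
  stopifnot(n_genes >= 1, n_case >= 1, n_control >= 1,
            de_fraction >= 0, de_fraction <= 1, all(dispersion > 0),
            log2fc_effect >= 0)
  structure(as.list(environment()), class = "sim_design")
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Counts are drawn NB with mean `s_j * q_i * 2^(+-log2fc/2)` (the effect is
#' split symmetrically about the baseline so the baseline is the geometric
#' mean of the two group means) and dispersion `alpha_i`. Planted DE genes are
#' split evenly between up- and down-regulation.
#'
#' @param design a [sim_design()].
#' @return list with `counts` (a [count_matrix()]) and `truth` (data.frame
#'   gene_id, is_de, true_log2fc, locus_group) plus the drawn
#'   `size_factors`.
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  d <- design
  if (d$n_genes < 1) stopf("degenerate design: no genes")
  with_seed(d$seed, {
    n <- d$n_case + d$n_control
    q <- stats::rlnorm(d$n_genes, d$meanlog, d$sdlog)
    s <- stats::rlnorm(n, 0, d$libsize_sdlog)
    s <- s / exp(mean(log(s)))             # geometric mean 1
    n_de <- round(d$de_fraction * d$n_genes)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, d$n_genes - n_de))
    sign <- rep(0, d$n_genes)
    if (n_de > 0) sign[seq_len(n_de)] <- rep(c(1, -1), length.out = n_de)
    lfc <- sign * d$log2fc_effect
    alpha <- rep(d$dispersion, length.out = d$n_genes)
    group <- c(rep("case", d$n_case), rep("control", d$n_control))
    mu <- outer(q, ifelse(group == "case", 1, -1)) # placeholder sign matrix
    for (j in seq_len(n)) {
      shift <- if (group[j] == "case") lfc / 2 else -lfc / 2
      mu[, j] <- s[j] * q * 2^shift
    }
    counts <- matrix(stats::rnbinom(d$n_genes * n, mu = mu, size = 1 / alpha),
                     nrow = d$n_genes)
    gene_ids <- sprintf("G%05d", seq_len(d$n_genes))
    sample_ids <- c(sprintf("case_%d", seq_len(d$n_case)),
                    sprintf("ctrl_%d", seq_len(d$n_control)))
    dimnames(counts) <- list(gene_ids, sample_ids)
    locus <- sample(LOCUS_GROUPS, d$n_genes, replace = TRUE,
                    prob = c(0.69, 0.14, 0.155, 0.015))
    truth <- data.frame(gene_id = gene_ids, is_de = is_de,
                        true_log2fc = lfc, locus_group = locus,
                        stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, stats::setNames(group, sample_ids)),
         truth = truth, size_factors = stats::setNames(s, sample_ids))
  })
}

#' Simulate a heavy-tailed reference interactome
#'
#' Background graph by preferential attachment (`attach_m` edges per new
#' node), giving the heavy-tailed degree distribution typical of curated
#' protein-interaction databases. Optionally a dense module is planted:
#' every pair of the given member nodes gains an edge with probability
#' `module_p` (the simple-graph property is maintained).
#'
#' @param n_nodes number of proteins.
#' @param attach_m edges attached per new node (`n_nodes > attach_m >= 1`).
#' @param module_members character vector of member node names (must exist),
#'   or integer indices; `NULL` for no planted module.
#' @param module_p probability of an extra edge between each member pair.
#' @param seed RNG seed.
#' @return list with `graph` (igraph, vertex names `P0001`...) and `truth`
#'   (data.frame node, in_planted_module).
#' @export
simulate_interactome <- function(n_nodes, attach_m = 2, module_members = NULL,
                                 module_p = 0, seed = 1) {
  stopifnot(n_nodes > attach_m, attach_m >= 1)
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
    g <- igraph::simplify(g)
    names_v <- sprintf("P%04d", seq_len(n_nodes))
    igraph::V(g)$name <- names_v
    in_mod <- rep(FALSE, n_nodes)
    if (!is.null(module_members) && length(module_members)) {
      if (is.numeric(module_members)) {
        if (any(module_members < 1 | module_members > n_nodes))
          stopf("planted module member outside node set: index %d",
                module_members[module_members < 1 |
                                 module_members > n_nodes][1])
        module_members <- names_v[module_members]
      }
      if (!all(module_members %in% names_v))
        stopf("planted module member outside node set: %s",
              setdiff(module_members, names_v)[1])
      in_mod[match(module_members, names_v)] <- TRUE
    }
    if (sum(in_mod) > 1) {
      pairs <- utils::combn(names_v[in_mod], 2)
      take <- stats::runif(ncol(pairs)) < module_p
      if (any(take)) {
        g <- igraph::add_edges(g, as.vector(pairs[, take, drop = FALSE]))
        g <- igraph::simplify(g)
      }
    }
    list(graph = g,
         truth = data.frame(node = names_v, in_planted_module = in_mod,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a qPCR plate with known fold changes
#'
#' Ct values follow the exponential-amplification model: one cycle per
#' doubling, so `Ct = baseline - log2(relative expression) + noise`. Case
#' samples of a gene with planted fold change f are shifted by `-log2(f)`
#' cycles relative to controls; the reference gene has fold change 1 by
#' construction. Technical triplicates are emitted.
#'
#' @param n_case,n_control biological samples per group.
#' @param fold_changes named numeric vector of planted case/control fold
#'   changes per target gene (all > 0).
#' @param ref_gene reference gene name.
#' @param ct_noise_sd Gaussian noise sd in cycles (0 for a noise-free plate).
#' @param n_replicates technical replicates per reaction.
#' @param baseline_ct target-gene baseline Ct; the reference sits lower.
#' @param seed RNG seed.
#' @return list with `plate` (a [qpcr_plate()]) and `truth` (data.frame gene,
#'   true_fold).
#' @export
simulate_qpcr <- function(n_case = 4, n_control = 4, fold_changes,
                          ref_gene = "GAPDH", ct_noise_sd = 0.2,
                          n_replicates = 3, baseline_ct = 25, seed = 1) {
  if (is.null(names(fold_changes)) || !all(nzchar(names(fold_changes))))
    stopf("fold_changes must be named by gene")
  if (any(fold_changes <= 0)) stopf("fold changes must be positive")
  if (ref_gene %in% names(fold_changes))
    stopf("the reference gene has fold change 1 by definition; do not list it")
  with_seed(seed, {
    samples <- data.frame(
      sample_id = c(sprintf("case_%d", seq_len(n_case)),
                    sprintf("ctrl_%d", seq_len(n_control))),
      group = c(rep("case", n_case), rep("control", n_control)),
      stringsAsFactors = FALSE)
    genes <- c(names(fold_changes), ref_gene)
    rows <- expand.grid(i = seq_len(nrow(samples)), gene = genes,
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    fold <- c(fold_changes, stats::setNames(1, ref_gene))
    base <- stats::setNames(rep(baseline_ct, length(genes)), genes)
    base[ref_gene] <- baseline_ct - 7   # references are highly expressed
    rel <- ifelse(samples$group[rows$i] == "case", fold[rows$gene], 1)
    ct <- base[rows$gene] - log2(rel) +
      if (ct_noise_sd > 0) stats::rnorm(nrow(rows), 0, ct_noise_sd) else 0
    plate <- data.frame(sample_id = samples$sample_id[rows$i],
                        group = samples$group[rows$i],
                        gene = rows$gene, replicate = rows$replicate,
                        ct = as.numeric(ct),
                        is_reference = rows$gene == ref_gene,
                        stringsAsFactors = FALSE)
    list(plate = qpcr_plate(plate),
         truth = data.frame(gene = names(fold), true_fold = unname(fold),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a full cohort-scale synthetic fixture bundle
#'
#' One call produces every input the pipeline consumes, at the scale of the
#' target study design (>= 20,000 genes, 4 case vs 4 control): a count matrix
#' with planted DE genes, an annotation table covering the four locus groups,
#' a heavy-tailed interactome with a dense module planted among the planted
#' protein-coding DE genes, a GMT collection with one planted-enriched term,
#' and a qPCR plate. If `dir` is given, all pieces plus a JSON truth manifest
#' are written there.
#'
#' @param seed RNG seed.
#' @param dir optional output directory.
#' @param n_genes number of simulated genes.
#' @param interactome_nodes background interactome size.
#' @return list with `counts`, `truth`, `annotation`, `interactome`,
#'   `interactome_truth`, `gene_sets`, `qpcr`, `manifest`.
#' @export
make_cohort_fixture <- function(seed = 1, dir = NULL, n_genes = 20000,
                                interactome_nodes = 4000) {
  design <- sim_design(n_genes = n_genes, seed = seed)
  sim <- simulate_counts(design)
  truth <- sim$truth

  # annotation: symbol per gene; planted protein-coding DE genes map into the
  # interactome name space so they can seed the network
  ann <- data.frame(gene_id = truth$gene_id,
                    symbol = paste0("SYM", seq_len(n_genes)),
                    locus_group = truth$locus_group,
                    stringsAsFactors = FALSE)
  de_pc <- which(truth$is_de & truth$locus_group == "protein_coding")
  n_map <- ceiling(0.68 * length(de_pc))       # the mapped-seed fraction
  mapped <- de_pc[seq_len(n_map)]
  # map onto degree-typical nodes drawn at random, not the early (hub) nodes
  # of the preferential-attachment graph
  module_nodes <- with_seed(seed + 4,
    sample(sprintf("P%04d", seq_len(interactome_nodes)), n_map))
  ann$symbol[mapped] <- module_nodes
  ann$symbol <- toupper(ann$symbol)

  inter <- simulate_interactome(interactome_nodes, attach_m = 2,
                                module_members = ann$symbol[mapped],
                                module_p = 0.25, seed = seed + 1)

  # GMT: one term enriched in the mapped seeds plus background terms
  with_seed(seed + 2, {
    all_syms <- igraph::V(inter$graph)$name
    planted_term <- unique(c(ann$symbol[mapped],
                             sample(all_syms, 10)))
    sets <- list(PLANTED_01 = planted_term)
    for (k in 1:19)
      sets[[sprintf("RANDOM_%02d", k)]] <- sample(all_syms, 40)
    attr(sets, "term_names") <- stats::setNames(
      c("planted seed-enriched term", sprintf("random term %d", 1:19)),
      names(sets))
  })

  qp <- simulate_qpcr(fold_changes = c(TARGET_UP = 4, TARGET_DN = 0.25,
                                       TARGET_NS = 1),
                      ct_noise_sd = 0.2, seed = seed + 3)

  manifest <- list(seed = seed, n_genes = n_genes,
                   n_case = design$n_case, n_control = design$n_control,
                   de_fraction = design$de_fraction,
                   log2fc_effect = design$log2fc_effect,
                   n_planted_de = sum(truth$is_de),
                   n_planted_module = sum(inter$truth$in_planted_module),
                   qpcr_true_folds = as.list(
                     stats::setNames(qp$truth$true_fold, qp$truth$gene)))

  out <- list(counts = sim$counts, truth = truth, annotation = ann,
              interactome = inter$graph, interactome_truth = inter$truth,
              gene_sets = sets, qpcr = qp$plate, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(sim$counts, file.path(dir, "counts.tsv"),
                       file.path(dir, "samples.tsv"))
    write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_interactome(inter$graph, file.path(dir, "interactome.tsv"))
    write_gmt(sets, file.path(dir, "sets.gmt"))
    write_qpcr_plate(qp$plate, file.path(dir, "qpcr.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
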