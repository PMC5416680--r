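#' Build the seed-expanded protein-interaction subnetwork
#'
#' The PIN is the subgraph of the reference interactome induced by the seed
#' proteins (e.g. protein-coding DEGs) together with their direct neighbors
#' (first-degree interactors): node set = mapped seeds plus all their
#' neighbors, edge set = every interactome edge with both endpoints in that
#' node set. Seeds absent from the interactome are dropped and counted.
#'
#' @param seeds character vector of gene symbols (uppercased on entry).
#' @param interactome undirected simple `igraph` (see [read_interactome()]).
#' @return list of class `pin`: `graph` (induced igraph), `seeds` (mapped
#'   seed symbols), `n_seeds_given`, `n_seeds_mapped`.
#' @export
build_pin <- function(seeds, interactome) {
  seeds <- unique(toupper(seeds))
  present <- seeds[seeds %in% igraph::V(interactome)$name]
  log_filter("seeds absent from interactome (dropped)",
             length(seeds) - length(present))
  if (!length(present))
    stopf("none of the %d seeds map to the interactome", length(seeds))
  nb <- unique(unlist(igraph::adjacent_vertices(
    interactome, present), use.names = FALSE))
  nodes <- union(present, igraph::V(interactome)$name[nb])
  g <- igraph::induced_subgraph(interactome, nodes)
  structure(list(graph = g, seeds = present,
                 n_seeds_given = length(seeds),
                 n_seeds_mapped = length(present)),
            class = "pin")
}

#' @export
print.pin <- function(x, ...) {
  cat(sprintf("PIN: %d proteins, %d interactions (%d/%d seeds mapped)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$n_seeds_mapped, x$n_seeds_given))
  invisible(x)
}

#' Fraction of seed genes present in the interactome
#'
#' @param symbols character vector of candidate seed symbols.
#' @param interactome reference `igraph`.
#' @return list `n_mapped`, `n_total`, `percent` (rounded to integer,
#'   round-half-even as in base R).
#' @export
mapped_seed_fraction <- function(symbols, interactome) {
  symbols <- unique(toupper(symbols))
  if (!length(symbols)) stopf("no seed symbols given")
  n_mapped <- sum(symbols %in% igraph::V(interactome)$name)
  list(n_mapped = n_mapped, n_total = length(symbols),
       percent = round(100 * n_mapped / length(symbols)))
}

#' Structural summary of a network
#'
#' Density over all node pairs; average shortest path length (ASPL) and the
#' multiset of finite pairwise path lengths on the largest connected
#' component; the degree multiset over all nodes.
#'
#' @param x a `pin` or an `igraph`.
#' @return list `n_nodes`, `n_edges`, `density`, `aspl`, `n_components`,
#'   `path_lengths` (named integer table of length -> count),
#'   `degrees` (integer vector).
#' @export
topology_summary <- function(x) {
  g <- if (inherits(x, "pin")) x$graph else x
  n <- igraph::vcount(g)
  if (n < 2) stopf("topology summary needs >= 2 nodes")
  comp <- igraph::components(g)
  lcc <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  dmat <- igraph::distances(lcc)
  pl <- dmat[upper.tri(dmat)]
  pl <- pl[is.finite(pl) & pl > 0]
  list(n_nodes = n, n_edges = igraph::ecount(g),
       density = 2 * igraph::ecount(g) / (n * (n - 1)),
       aspl = if (length(pl)) mean(pl) else NA_real_,
       n_components = comp$no,
       path_lengths = table(as.integer(pl)),
       degrees = as.integer(igraph::degree(g)))
}

#' Random-seed null ensemble of PINs
#'
#' Each replicate draws `n_seeds` nodes uniformly without replacement from
#' the interactome and expands them with [build_pin()]; this is the null
#' model against which the observed seed set's topology is judged.
#'
#' @param interactome reference `igraph`.
#' @param n_seeds seeds per replicate.
#' @param R number of replicates.
#' @param rng_seed integer seed; the ensemble is deterministic given it.
#' @return list of `pin` objects, length `R`.
#' @export
sample_random_pins <- function(interactome, n_seeds, R, rng_seed = 1) {
  nodes <- igraph::V(interactome)$name
  if (n_seeds > length(nodes))
    stopf("n_seeds (%d) exceeds interactome size (%d)", n_seeds, length(nodes))
  stopifnot(R >= 1)
  with_seed(rng_seed, {
    lapply(seq_len(R), function(r)
      build_pin(sample(nodes, n_seeds), interactome))
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic two-sample Kolmogorov distribution.
#'
#' @param x,y numeric samples (either may carry ties; both non-empty).
#' @return list `D`, `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stopf("KS test needs non-empty samples")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

# KS on tabulated (value -> count) samples; avoids materializing the huge
# pooled path-length multisets. Same asymptotic p as ks_two_sample.
ks_from_counts <- function(tab_x, tab_y) {
  vx <- as.numeric(names(tab_x)); vy <- as.numeric(names(tab_y))
  grid <- sort(unique(c(vx, vy)))
  fx <- numeric(length(grid)); fx[match(vx, grid)] <- as.numeric(tab_x)
  fy <- numeric(length(grid)); fy[match(vy, grid)] <- as.numeric(tab_y)
  nx <- sum(fx); ny <- sum(fy)
  D <- max(abs(cumsum(fx) / nx - cumsum(fy) / ny))
  n_eff <- nx * ny / (nx + ny)
  list(D = D, p = kolmogorov_p(sqrt(n_eff) * D))
}

# Asymptotic Kolmogorov tail: P(sqrt(n) D >= lambda).
kolmogorov_p <- function(lambda) {
  if (lambda < 0.2) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Compare an observed PIN against the random-seed null
#'
#' Draws `R` random-seed PINs with the same number of seeds as were mapped
#' for the observed network, then compares topology along two routes: (a)
#' two-sample KS tests of the observed vs pooled-null shortest-path-length
#' and degree multisets; (b) one-sided add-one empirical p-values for the
#' scalar density (null >= observed) and ASPL (null <= observed), i.e. the
#' alternative that the observed seeds are more densely interconnected and
#' closer together than random seed sets.
#'
#' @param pin observed `pin` from [build_pin()].
#' @param interactome reference `igraph`.
#' @param R null replicates (>= 100 recommended).
#' @param rng_seed integer seed.
#' @return object of class `topology_comparison`: observed summary, null
#'   scalar table, KS results, empirical p-values, `R`, `rng_seed`.
#' @export
compare_topology <- function(pin, interactome, R = 200, rng_seed = 1) {
  stopifnot(inherits(pin, "pin"))
  obs <- topology_summary(pin)
  nulls <- sample_random_pins(interactome, pin$n_seeds_mapped, R, rng_seed)
  null_sum <- lapply(nulls, topology_summary)
  null_tab <- data.frame(
    replicate = seq_len(R),
    n_nodes = vapply(null_sum, `[[`, numeric(1), "n_nodes"),
    n_edges = vapply(null_sum, `[[`, numeric(1), "n_edges"),
    density = vapply(null_sum, `[[`, numeric(1), "density"),
    aspl = vapply(null_sum, `[[`, numeric(1), "aspl"))
  pool_tab <- function(field) {
    all <- unlist(lapply(null_sum, function(s) {
      t <- s[[field]]
      if (is.table(t)) stats::setNames(as.numeric(t), names(t))
      else table(t)
    }))
    tapply(all, names(all), sum)
  }
  pooled_paths <- pool_tab("path_lengths")
  pooled_degrees <- pool_tab("degrees")
  ks_paths <- ks_from_counts(obs$path_lengths, pooled_paths)
  ks_degree <- ks_from_counts(table(obs$degrees), pooled_degrees)
  # add-one empirical p-values: never exactly zero at finite R
  p_density <- (1 + sum(null_tab$density >= obs$density)) / (R + 1)
  p_aspl <- (1 + sum(null_tab$aspl <= obs$aspl, na.rm = TRUE)) / (R + 1)
  structure(list(observed = obs, null = null_tab,
                 ks_paths = ks_paths, ks_degree = ks_degree,
                 empirical_p_density = p_density, empirical_p_aspl = p_aspl,
                 R = R, rng_seed = rng_seed),
            class = "topology_comparison")
}

#' @export
print.topology_comparison <- function(x, ...) {
  o <- x$observed
  cat(sprintf("Observed PIN: %d nodes, %d edges, density %.4g, ASPL %.3f\n",
              o$n_nodes, o$n_edges, o$density, o$aspl))
  cat(sprintf("Null ensemble (R = %d random seed sets):\n", x$R))
  cat(sprintf("  density: mean %.4g, empirical p (null >= obs) = %.4g\n",
              mean(x$null$density), x$empirical_p_density))
  cat(sprintf("  ASPL:    mean %.3f, empirical p (null <= obs) = %.4g\n",
              mean(x$null$aspl, na.rm = TRUE), x$empirical_p_aspl))
  cat(sprintf("  KS path lengths: D = %.3f, p = %.3g\n",
              x$ks_paths$D, x$ks_paths$p))
  cat(sprintf("  KS degrees:      D = %.3f, p = %.3g\n",
              x$ks_degree$D, x$ks_degree$p))
  invisible(x)
}
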