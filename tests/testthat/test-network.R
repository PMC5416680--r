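make_graph <- function(edges) {
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

test_that("PIN construction keeps seeds plus first-degree interactors only", {
  g <- make_graph(rbind(c("A", "B"), c("B", "C")))
  pin <- build_pin("A", g)
  expect_setequal(igraph::V(pin$graph)$name, c("A", "B"))
  expect_equal(igraph::ecount(pin$graph), 1)

  # seeds covering every node reproduce the interactome
  pin_all <- build_pin(c("A", "B", "C"), g)
  expect_equal(igraph::ecount(pin_all$graph), igraph::ecount(g))
  expect_setequal(igraph::V(pin_all$graph)$name, igraph::V(g)$name)

  expect_error(suppressMessages(build_pin("ZZZ", g)), "none of the 1 seeds")
})

test_that("PIN node and edge sets equal a set-construction oracle", {
  set.seed(17)
  inter <- simulate_interactome(200, attach_m = 2, seed = 17)$graph
  el <- igraph::as_edgelist(inter)
  edges <- data.frame(a = el[, 1], b = el[, 2], stringsAsFactors = FALSE)
  seeds <- sample(igraph::V(inter)$name, 10)
  pin <- build_pin(seeds, inter)
  oracle <- oracle_pin(edges, seeds)
  expect_setequal(igraph::V(pin$graph)$name, oracle$nodes)
  want <- apply(cbind(oracle$edges$a, oracle$edges$b), 1,
                function(e) paste(sort(e), collapse = "|"))
  got <- apply(igraph::as_edgelist(pin$graph), 1,
               function(e) paste(sort(e), collapse = "|"))
  expect_setequal(got, want)

  # PIN invariants on random fixtures: every non-seed touches a seed,
  # edges are the induced set
  for (s in 1:5) {
    sds <- sample(igraph::V(inter)$name, 8)
    p <- build_pin(sds, inter)
    non_seed <- setdiff(igraph::V(p$graph)$name, p$seeds)
    touches <- vapply(non_seed, function(v) {
      nb <- igraph::V(inter)$name[
        as.integer(igraph::neighbors(inter, v))]
      any(nb %in% p$seeds)
    }, logical(1))
    expect_true(all(touches))
    expect_true(igraph::is_simple(p$graph))
  }
})

test_that("mapped seed fraction reports the printed rounding convention", {
  g <- make_graph(cbind(sprintf("S%03d", 1:168), sprintf("N%03d", 1:168)))
  symbols <- c(sprintf("S%03d", 1:168), sprintf("X%03d", 1:80))
  mf <- mapped_seed_fraction(symbols, g)
  expect_equal(mf$n_mapped, 168)
  expect_equal(mf$n_total, 248)
  expect_equal(mf$percent, 68)

  expect_equal(mapped_seed_fraction(sprintf("X%d", 1:10), g)$percent, 0)
  # 7 of 8 with round-half-even base-R rounding
  g2 <- make_graph(cbind(sprintf("A%d", 1:7), sprintf("B%d", 1:7)))
  expect_equal(mapped_seed_fraction(c(sprintf("A%d", 1:7), "NOPE"),
                                    g2)$percent, 88)
})

test_that("topology summaries match closed forms and Floyd-Warshall", {
  k4 <- make_graph(t(combn(c("a", "b", "c", "d"), 2)))
  ts <- topology_summary(k4)
  expect_equal(ts$density, 1)
  expect_equal(ts$aspl, 1)

  p4 <- make_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  tp <- topology_summary(p4)
  expect_equal(tp$density, 0.5)
  expect_equal(tp$aspl, 10 / 6)
  expect_equal(unname(as.vector(tp$path_lengths)), c(3, 2, 1))

  # 50-node random connected fixture against all-pairs Floyd-Warshall
  set.seed(23)
  g <- simulate_interactome(50, attach_m = 2, seed = 23)$graph
  summ <- topology_summary(g)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- oracle_floyd_warshall(adj)
  expect_equal(summ$aspl, mean(d[upper.tri(d)][is.finite(d[upper.tri(d)])]))
  expect_equal(summ$density,
               sum(adj) / (nrow(adj) * (nrow(adj) - 1)))
  expect_equal(sort(summ$degrees), sort(as.integer(unname(rowSums(adj)))))
  expect_error(topology_summary(make_graph(matrix("a", 0, 2))), ">= 2")
})

test_that("random PIN ensembles are deterministic and unbiased", {
  inter <- simulate_interactome(300, attach_m = 2, seed = 29)$graph
  e1 <- suppressMessages(sample_random_pins(inter, 10, R = 5, rng_seed = 3))
  e2 <- suppressMessages(sample_random_pins(inter, 10, R = 5, rng_seed = 3))
  expect_identical(lapply(e1, function(p) sort(p$seeds)),
                   lapply(e2, function(p) sort(p$seeds)))

  all_nodes <- suppressMessages(
    sample_random_pins(inter, igraph::vcount(inter), R = 1, rng_seed = 1))
  expect_equal(igraph::ecount(all_nodes[[1]]$graph), igraph::ecount(inter))

  expect_error(sample_random_pins(inter, 400, R = 1), "exceeds")

  # ensemble mean density within Monte-Carlo tolerance of a larger
  # reference ensemble
  small <- suppressMessages(sample_random_pins(inter, 15, R = 30,
                                               rng_seed = 7))
  big <- suppressMessages(sample_random_pins(inter, 15, R = 300,
                                             rng_seed = 8))
  dens <- function(e) vapply(e, function(p)
    topology_summary(p)$density, numeric(1))
  # difference of means bounded by ~3 standard errors of the small ensemble
  expect_lt(abs(mean(dens(small)) - mean(dens(big))),
            3 * sd(dens(small)) / sqrt(30))
})

test_that("KS statistic equals the pooled-grid supremum", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)

  set.seed(31)
  x <- rnorm(30); y <- rnorm(40, 0.5)
  ks <- ks_two_sample(x, y)
  expect_equal(ks$D, oracle_ks_d(x, y), tolerance = 1e-12)
  expect_gte(ks$D, 0); expect_lte(ks$D, 1)

  # tabulated variant agrees with the plain variant on tied integer data
  xi <- sample(1:6, 50, replace = TRUE)
  yi <- sample(2:8, 70, replace = TRUE)
  kc <- degnet:::ks_from_counts(table(xi), table(yi))
  expect_equal(kc$D, oracle_ks_d(xi, yi), tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("topology comparison flags the planted module and stays calibrated", {
  # planted-module alternative at the fixture's stated design: 1000-node
  # background (m = 2), 30-member module with extra edge probability 0.3
  set.seed(1)
  members <- sample(1000, 30)
  inter <- simulate_interactome(1000, 2, module_members = members,
                                module_p = 0.3, seed = 51)
  seeds <- inter$truth$node[inter$truth$in_planted_module]
  pin <- suppressMessages(build_pin(seeds, inter$graph))
  cmp <- suppressMessages(compare_topology(pin, inter$graph, R = 200,
                                           rng_seed = 52))
  expect_lte(cmp$empirical_p_density, 0.05)
  expect_lte(cmp$empirical_p_aspl, 0.05)
  expect_gte(cmp$ks_paths$D, 0); expect_lte(cmp$ks_paths$D, 1)

  # no planting: empirical p is add-one bounded and rarely small
  inter0 <- simulate_interactome(1000, 2, seed = 53)
  rejections <- 0
  for (k in 1:10) {
    set.seed(60 + k)
    p0 <- suppressMessages(
      build_pin(sample(inter0$truth$node, 30), inter0$graph))
    c0 <- suppressMessages(compare_topology(p0, inter0$graph, R = 60,
                                            rng_seed = 70 + k))
    rejections <- rejections +
      (c0$empirical_p_density <= 0.05 && c0$empirical_p_aspl <= 0.05)
    expect_gt(c0$empirical_p_density, 0)
    expect_lte(c0$empirical_p_density, 1)
  }
  expect_lte(rejections, 2)

  # R = 1 degenerate add-one arithmetic
  c1 <- suppressMessages(compare_topology(pin, inter$graph, R = 1,
                                          rng_seed = 99))
  expect_true(c1$empirical_p_density %in% c(0.5, 1))
  expect_true(c1$empirical_p_aspl %in% c(0.5, 1))
})
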