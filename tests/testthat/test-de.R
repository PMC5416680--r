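test_that("median-of-ratios size factors match hand evaluation", {
  # identical samples
  m <- matrix(c(3L, 3L, 8L, 8L), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  # [[2,4],[10,20]]: ratios give s proportional to (1,2); geometric-mean
  # rescale lands on (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(2L, 4L, 10L, 20L), 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))

  # scale equivariance: multiplying one column by c multiplies its factor
  # by c before the rescale (so the ratio of factors scales by c)
  set.seed(1)
  m3 <- matrix(rpois(200, 50), 50, 4,
               dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:4)))
  s_before <- estimate_size_factors(m3)
  m4 <- m3; m4[, 2] <- m4[, 2] * 3L
  s_after <- estimate_size_factors(m4)
  expect_equal(s_after[2] / s_after[1], 3 * s_before[2] / s_before[1],
               tolerance = 1e-12)

  zeros <- matrix(c(0L, 1L, 1L, 0L), 2,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(estimate_size_factors(zeros), "filter")
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(11)
  m <- matrix(rnbinom(2000, mu = 80, size = 5), 500, 4,
              dimnames = list(sprintf("g%d", 1:500), sprintf("s%d", 1:4)))
  m[, 3] <- m[, 3] * 2L
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same method up to the geometric-mean rescale convention
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]), tolerance = 1e-9)
})

test_that("dispersion estimation recovers the truth and floors degenerate genes", {
  # strong recovery regime: 20 vs 20 samples at alpha = 0.2
  d <- sim_design(n_genes = 1000, n_case = 20, n_control = 20,
                  meanlog = 4, sdlog = 0.5, dispersion = 0.2,
                  de_fraction = 0, seed = 13)
  sim <- simulate_counts(d)
  s <- estimate_size_factors(sim$counts)
  alpha <- estimate_dispersions(sim$counts, s)
  expect_gt(median(alpha), 0.1)
  expect_lt(median(alpha), 0.4)

  # Poisson data: most raw estimates fall at/near the floor-trend level
  dp <- sim_design(n_genes = 500, n_case = 10, n_control = 10,
                   meanlog = 4, sdlog = 0.3, dispersion = 1e-6,
                   de_fraction = 0, libsize_sdlog = 0, seed = 14)
  simp <- simulate_counts(dp)
  sp <- estimate_size_factors(simp$counts)
  ap <- estimate_dispersions(simp$counts, sp)
  expect_lt(median(ap), 0.02)

  # constant gene sits at the floor
  m <- matrix(5L, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  m[2:4, ] <- matrix(rpois(12, 50), 3)
  cm <- count_matrix(m, setNames(rep(c("case", "control"), each = 2),
                                 colnames(m)))
  a <- estimate_dispersions(cm, estimate_size_factors(cm))
  expect_lt(a[["g1"]], 0.05)

  # single-replicate group refuses
  cm2 <- count_matrix(m[, 1:3],
                      setNames(c("case", "control", "control"),
                               colnames(m)[1:3]))
  expect_error(estimate_dispersions(cm2, rep(1, 3)), "replicates")
})

test_that("NB exact test matches exhaustive partition enumeration", {
  # symmetric model, equal counts: the mode partition pulls in everything
  expect_equal(nb_exact_test(5, 5, c(1, 1), c(1, 1), 0.1), 1)
  expect_equal(nb_exact_test(0, 0, c(1, 1), c(1, 1), 0.1), 1)

  # S = 10, symmetric: direct summation over all 11 partitions
  p <- nb_exact_test(8, 2, c(1, 1), c(1, 1), 0.1)
  expect_equal(p, oracle_exact_p(8, 2, c(1, 1), c(1, 1), 0.1),
               tolerance = 1e-12)

  # a grid of small cases, asymmetric size factors and dispersions
  for (ka in c(0, 3, 7, 12)) for (kb in c(0, 2, 8)) {
    for (alpha in c(0.05, 0.5)) {
      s_a <- c(0.8, 1.1); s_b <- c(1.3, 0.9, 1.0)
      expect_equal(nb_exact_test(ka, kb, s_a, s_b, alpha),
                   oracle_exact_p(ka, kb, s_a, s_b, alpha),
                   tolerance = 1e-10)
    }
  }

  # two-sided symmetry under group-label swap (equal group size factors)
  p_ab <- nb_exact_test(9, 1, c(1, 1), c(1, 1), 0.2)
  p_ba <- nb_exact_test(1, 9, c(1, 1), c(1, 1), 0.2)
  expect_equal(p_ab, p_ba, tolerance = 1e-12)
})

test_that("BH step-up matches hand example, oracle and reference", {
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 0)), "0, 1")

  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p) && all(adj <= 1))
    # significance order preserved: adjusted values are monotone along
    # the raw-p ordering
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("DEG selection filters jointly, monotonically, and never silently", {
  sim <- simulate_counts(sim_design(n_genes = 500, de_fraction = 0.1,
                                    seed = 21))
  fit <- nb_exact_de(sim$counts)

  all_g <- suppressMessages(select_degs(fit, fc_min = 1, p_max = 1))
  expect_equal(nrow(all_g), 500)

  loose <- suppressMessages(select_degs(fit, 2, 0.05, "raw"))
  strict <- suppressMessages(select_degs(fit, 2, 0.01, "raw"))
  expect_lte(nrow(strict), nrow(loose))
  expect_true(all(strict$gene_id %in% loose$gene_id))
  expect_true(all(abs(loose$log2fc) >= 1 & loose$p_raw <= 0.05))
  expect_true(all(loose$direction == ifelse(loose$log2fc > 0, "up", "down")))

  empty <- suppressMessages(select_degs(fit, 1e6, 1e-12, "adj"))
  expect_equal(nrow(empty), 0)
})

test_that("locus-group accounting reproduces the printed partition arithmetic", {
  # the four printed locus groups and the direction split both total 361
  ann <- data.frame(
    gene_id = sprintf("g%03d", 1:361),
    symbol = sprintf("S%03d", 1:361),
    locus_group = rep(c("protein_coding", "ncRNA", "pseudogene", "other"),
                      times = c(248, 50, 57, 6)))
  degs <- data.frame(gene_id = ann$gene_id,
                     direction = rep(c("up", "down"), times = c(156, 205)))
  acct <- partition_locus_groups(degs, ann)
  expect_equal(unname(acct$locus_groups),
               c(248L, 50L, 57L, 6L))
  expect_equal(sum(acct$locus_groups), 361L)
  expect_equal(acct$n_up + acct$n_down, 361L)
  expect_equal(acct$total, 361L)

  # all-protein-coding fixture leaves the other three groups at zero
  ann2 <- ann; ann2$locus_group <- "protein_coding"
  acct2 <- partition_locus_groups(degs, ann2)
  expect_equal(unname(acct2$locus_groups), c(361L, 0L, 0L, 0L))

  # genes missing from annotation count as 'other'
  acct3 <- suppressMessages(
    partition_locus_groups(data.frame(gene_id = "nope", direction = "up"),
                           ann))
  expect_equal(unname(acct3$locus_groups["other"]), 1L)
})

test_that("null simulation holds type-I error near nominal, planted sim is recovered", {
  # under the null the exact test should be approximately nominal and
  # never anticonservative
  sim0 <- simulate_counts(sim_design(n_genes = 2000, de_fraction = 0,
                                     seed = 31))
  fit0 <- nb_exact_de(sim0$counts)
  rate <- mean(fit0$table$p_raw < 0.05)
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.075)

  # planted DE at the design of the recovery study: 2000 genes, 4v4,
  # alpha = 0.1, 10% DE at |log2FC| = 2
  sim1 <- simulate_counts(sim_design(n_genes = 2000, de_fraction = 0.1,
                                     dispersion = 0.1, log2fc_effect = 2,
                                     seed = 32))
  fit1 <- nb_exact_de(sim1$counts)
  degs <- suppressMessages(select_degs(fit1, 2, 0.05, "raw"))
  truth_de <- sim1$truth$gene_id[sim1$truth$is_de]
  recall <- mean(truth_de %in% degs$gene_id)
  fdr <- mean(!degs$gene_id %in% truth_de)
  expect_gte(recall, 0.8)
  expect_lte(fdr, 0.15)
})
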