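#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of the ratio of
#' its count to the per-gene geometric mean across samples, computed over the
#' genes with non-zero counts in every sample; factors are rescaled so their
#' geometric mean is 1. This is the classic read-count normalization for
#' library-depth differences.
#'
#' @param counts a [count_matrix()] or plain matrix.
#' @return named positive numeric vector of per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- unclass(counts)
  logm <- log(m)
  log_geo <- rowMeans(logm)                 # -Inf for any gene with a zero
  use <- is.finite(log_geo)
  if (!any(use))
    stopf(paste("no gene has positive counts in every sample;",
                "filter low-coverage genes or samples first"))
  s <- apply(logm[use, , drop = FALSE], 2, function(col)
    exp(stats::median(col - log_geo[use])))
  s <- s / exp(mean(log(s)))
  s
}

#' Per-gene NB dispersion with a mean-trend floor
#'
#' Method-of-moments on size-factor-normalized counts, with the group
#' structure removed by pooling within-group variances: for each gene the raw
#' dispersion is `(w - q*xi) / q^2` where `q` is the mean normalized count,
#' `w` the pooled within-group sample variance and `xi = q * mean(1/s_j)` the
#' shot-noise term. A mean-dispersion trend `a0 + a1/q` is then fitted across
#' genes, and each gene receives the maximum of its own estimate and the
#' trend value — a deliberately conservative rule for very small cohorts.
#'
#' @param counts a [count_matrix()].
#' @param size_factors per-sample factors from [estimate_size_factors()].
#' @param groups optional group labels (defaults to the matrix's own).
#' @param alpha_floor minimum dispersion returned.
#' @return named per-gene dispersion vector (alpha in `var = mu + alpha*mu^2`).
#' @export
estimate_dispersions <- function(counts, size_factors,
                                 groups = sample_groups(counts),
                                 alpha_floor = 1e-8) {
  m <- unclass(counts)
  groups <- validate_groups(groups, colnames(m))
  tab <- table(groups)
  if (any(tab < 2))
    stopf("dispersion estimation needs >=2 replicates per group (got %s=%d)",
          names(tab)[tab < 2][1], min(tab))
  y <- sweep(m, 2, size_factors, "/")
  q <- rowMeans(y)
  # pooled within-group variance
  ss <- 0
  for (g in unique(groups)) {
    cols <- groups == g
    mu_g <- rowMeans(y[, cols, drop = FALSE])
    ss <- ss + rowSums((y[, cols, drop = FALSE] - mu_g)^2)
  }
  w <- ss / (ncol(m) - length(unique(groups)))
  xi <- q * mean(1 / size_factors)
  raw <- (w - xi) / q^2
  raw[!is.finite(raw)] <- NA_real_
  # parametric mean-dispersion trend alpha(q) = a0 + a1/q on informative genes
  ok <- !is.na(raw) & raw > 0 & q > 0
  trend <- rep(alpha_floor, nrow(m))
  if (sum(ok) >= 10) {
    fit <- tryCatch(stats::lm(raw[ok] ~ I(1 / q[ok])), error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- pmax(stats::coef(fit), 0)
      trend <- cf[1] + cf[2] / pmax(q, .Machine$double.eps)
    }
  } else if (any(ok)) {
    trend <- rep(stats::median(raw[ok]), nrow(m))
  }
  alpha <- pmax(raw, trend, alpha_floor, na.rm = TRUE)
  stats::setNames(alpha, rownames(m))
}

#' Conditional NB exact test for one gene
#'
#' Tests equality of expression between two groups given the summed counts
#' `k_a` and `k_b`, conditioning on the total `S = k_a + k_b`: the p-value is
#' the probability, among all partitions `(a, S - a)` of the total, of those
#' at most as probable as the observed one,
#' `p = sum_{f(a) <= f(k_a)} f(a) / sum_a f(a)` with
#' `f(a) = dnbinom(a; mu_a, size_a) * dnbinom(S - a; mu_b, size_b)`.
#' Group sum moments come from the pooled mean `q` (per normalized counts),
#' the group size-factor totals and the gene's dispersion:
#' `mu_g = q * sum(s_j)`, `var_g = mu_g + alpha * q^2 * sum(s_j^2)`.
#'
#' @param k_a,k_b non-negative integer count sums for the two groups.
#' @param s_a,s_b size factors of the samples in each group.
#' @param alpha NB dispersion of the gene.
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(k_a, k_b, s_a, s_b, alpha) {
  stopifnot(k_a >= 0, k_b >= 0, k_a == round(k_a), k_b == round(k_b))
  S <- k_a + k_b
  if (S == 0) return(1)
  q <- S / sum(s_a, s_b)
  mu_a <- q * sum(s_a); mu_b <- q * sum(s_b)
  size_a <- sum(s_a)^2 / (alpha * sum(s_a^2))
  size_b <- sum(s_b)^2 / (alpha * sum(s_b^2))
  a <- 0:S
  f <- stats::dnbinom(a, mu = mu_a, size = size_a) *
       stats::dnbinom(S - a, mu = mu_b, size = size_b)
  tot <- sum(f)
  if (tot == 0) return(1)
  f_obs <- f[k_a + 1]
  min(1, sum(f[f <= f_obs * (1 + 1e-7)]) / tot)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in (0, 1].
#' @return adjusted p-values (same order as input), monotone in rank and
#'   capped at 1.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[order(o)]
}

#' Negative-binomial exact-test differential expression
#'
#' The full DE stage: size factors, dispersions, per-gene conditional exact
#' tests and BH adjustment. Fold changes are computed on normalized group
#' means with a pseudocount of 1 added to both means, so they are defined
#' (and positive) even for genes silent in one group.
#'
#' @param counts a [count_matrix()].
#' @param alpha_floor dispersion floor passed to [estimate_dispersions()].
#' @return object of class `nbde`: list with `table` (data.frame gene_id,
#'   base_mean, mean_control, mean_case, fold_change, log2fc, p_raw, p_adj),
#'   `size_factors`, `dispersions`, `groups`.
#' @examples
#' sim <- simulate_counts(sim_design(n_genes = 200, seed = 7))
#' fit <- nb_exact_de(sim$counts)
#' head(fit$table)
#' @export
nb_exact_de <- function(counts, alpha_floor = 1e-8) {
  stopifnot(inherits(counts, "count_matrix"))
  groups <- sample_groups(counts)
  s <- estimate_size_factors(counts)
  alpha <- estimate_dispersions(counts, s, groups, alpha_floor = alpha_floor)
  m <- unclass(counts)
  case <- groups == "case"; ctrl <- groups == "control"
  y <- sweep(m, 2, s, "/")
  mean_case <- rowMeans(y[, case, drop = FALSE])
  mean_ctrl <- rowMeans(y[, ctrl, drop = FALSE])
  k_case <- as.integer(round(rowSums(m[, case, drop = FALSE])))
  k_ctrl <- as.integer(round(rowSums(m[, ctrl, drop = FALSE])))
  s_case <- s[case]; s_ctrl <- s[ctrl]
  p_raw <- vapply(seq_len(nrow(m)), function(i)
    nb_exact_test(k_case[i], k_ctrl[i], s_case, s_ctrl, alpha[i]),
    numeric(1))
  fc <- (mean_case + 1) / (mean_ctrl + 1)
  tab <- data.frame(gene_id = rownames(m),
                    base_mean = rowMeans(y),
                    mean_control = mean_ctrl, mean_case = mean_case,
                    fold_change = fc, log2fc = log2(fc),
                    p_raw = p_raw, p_adj = adjust_bh(p_raw),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, size_factors = s, dispersions = alpha,
                 groups = groups),
            class = "nbde")
}

#' @export
print.nbde <- function(x, ...) {
  cat(sprintf("NB exact-test differential expression: %d genes, %d vs %d samples\n",
              nrow(x$table), sum(x$groups == "case"),
              sum(x$groups == "control")))
  cat(sprintf("  genes at p_raw < 0.05: %d; at p_adj < 0.05: %d\n",
              sum(x$table$p_raw < 0.05), sum(x$table$p_adj < 0.05)))
  invisible(x)
}

#' @export
summary.nbde <- function(object, fc_min = 2, p_max = 0.05,
                         p_column = c("raw", "adj"), ...) {
  p_column <- match.arg(p_column)
  degs <- select_degs(object, fc_min = fc_min, p_max = p_max,
                      p_column = p_column)
  cat(sprintf("DEGs at fold >= %g, p_%s < %g: %d (%d up, %d down)\n",
              fc_min, p_column, p_max, nrow(degs),
              sum(degs$direction == "up"), sum(degs$direction == "down")))
  invisible(degs)
}

#' Select differentially expressed genes
#'
#' Applies the joint fold-change and significance filter to a DE result and
#' assigns each passing gene a direction from the sign of its log2 fold
#' change.
#'
#' @param fit an `nbde` object (or its `table` data.frame).
#' @param fc_min minimum fold change (either direction), e.g. 2.
#' @param p_max significance threshold.
#' @param p_column which p-value the threshold applies to: `"raw"` (the
#'   default, matching P-value-quoted selection) or `"adj"` (BH-adjusted).
#' @return data.frame of the selected genes with a `direction` column
#'   (`up`/`down`); the thresholds are attached as attributes.
#' @export
select_degs <- function(fit, fc_min = 2, p_max = 0.05,
                        p_column = c("raw", "adj")) {
  p_column <- match.arg(p_column)
  stopifnot(fc_min > 0, p_max > 0)
  tab <- if (inherits(fit, "nbde")) fit$table else fit
  p <- if (p_column == "raw") tab$p_raw else tab$p_adj
  keep <- abs(tab$log2fc) >= log2(fc_min) & p <= p_max
  out <- tab[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  log_filter(sprintf("DEGs selected (fc>=%g, p_%s<=%g)", fc_min, p_column, p_max),
             nrow(out))
  attr(out, "thresholds") <- list(fc_min = fc_min, p_max = p_max,
                                  p_column = p_column)
  rownames(out) <- NULL
  out
}

#' Locus-group accounting of a DEG set
#'
#' Tallies the selected genes over the four locus groups (protein-coding,
#' non-coding RNA, pseudogene, other) and over direction. Genes absent from
#' the annotation are counted as `other` and logged.
#'
#' @param degs DEG data.frame from [select_degs()] (needs `gene_id`,
#'   `direction`).
#' @param annotation annotation data.frame (see [annotation_table()]).
#' @return list with `locus_groups` (named counts over the four groups),
#'   `n_up`, `n_down`, `total`.
#' @export
partition_locus_groups <- function(degs, annotation) {
  lg <- annotation$locus_group[match(degs$gene_id, annotation$gene_id)]
  n_missing <- sum(is.na(lg))
  log_filter("DEGs missing from annotation (counted as 'other')", n_missing)
  lg[is.na(lg)] <- "other"
  counts <- vapply(LOCUS_GROUPS, function(g) sum(lg == g), integer(1))
  list(locus_groups = counts,
       n_up = sum(degs$direction == "up"),
       n_down = sum(degs$direction == "down"),
       total = nrow(degs))
}
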