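#' Per-sample delta-Ct against a reference gene
#'
#' Technical replicates are averaged (arithmetic mean of Ct) per sample and
#' gene before subtraction; then `dCt = Ct_target - Ct_reference` within each
#' sample.
#'
#' @param plate a [qpcr_plate()].
#' @param reference reference gene name (must be measured in every sample).
#' @return data.frame sample_id, group, gene, delta_ct (target genes only).
#' @export
delta_ct <- function(plate, reference) {
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = plate,
                          FUN = mean)
  ref <- agg[agg$gene == reference, ]
  if (!nrow(ref)) stopf("reference gene '%s' not on the plate", reference)
  missing <- setdiff(unique(agg$sample_id), ref$sample_id)
  if (length(missing))
    stopf("sample '%s' lacks the reference gene '%s'", missing[1], reference)
  tgt <- agg[agg$gene != reference, ]
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  tgt$delta_ct <- tgt$ct - ref_ct[tgt$sample_id]
  tgt[, c("sample_id", "group", "gene", "delta_ct")]
}

#' Relative expression by the 2^(-ddCt) method
#'
#' `ddCt = mean dCt(case) - mean dCt(control)` per gene; the fold change
#' `2^(-ddCt)` assumes one doubling per PCR cycle. Groups are compared per
#' gene by a two-sided Student's t-test on the per-sample dCt values
#' (equal-variance by default, Welch via `var_equal = FALSE`).
#'
#' @param dcts per-sample delta-Ct table from [delta_ct()].
#' @param var_equal use the pooled-variance Student's t-test (default).
#' @return data.frame per gene: ddct, fold_change, t_statistic, p_value.
#' @export
ddct_fold_change <- function(dcts, var_equal = TRUE) {
  genes <- unique(dcts$gene)
  rows <- lapply(genes, function(g) {
    d <- dcts[dcts$gene == g, ]
    ca <- d$delta_ct[d$group == "case"]
    co <- d$delta_ct[d$group == "control"]
    if (!length(ca) || !length(co)) stopf("gene '%s': both groups needed", g)
    ddct <- mean(ca) - mean(co)
    tt <- group_ttest(ca, co, var_equal = var_equal)
    data.frame(gene = g, ddct = ddct, fold_change = 2^(-ddct),
               t_statistic = tt$t, p_value = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample t-test on group values
#'
#' Two-sided Student's t-test (equal variance) by default; degenerate inputs
#' with zero variance in both groups and equal means return p = 1.
#'
#' @param x,y numeric values for the two groups (>= 2 each).
#' @param var_equal pooled-variance test if TRUE (the default), Welch
#'   otherwise.
#' @return list `t`, `p`.
#' @export
group_ttest <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Volcano-style differential calls on relative expression
#'
#' A gene is called `up` when its fold change is at least `fc_min` and
#' `p < p_max`, `down` when the fold change is at most `1/fc_min` at the
#' same significance, otherwise `ns`. The PCR-array convention
#' (2-fold at P < 0.05) is the default.
#'
#' @param rel table from [ddct_fold_change()].
#' @param fc_min fold-change threshold (> 1).
#' @param p_max significance threshold.
#' @return `rel` with a `call` column plus volcano coordinates
#'   (`log2_fold`, `neg_log10_p`).
#' @export
volcano_calls <- function(rel, fc_min = 2, p_max = 0.05) {
  stopifnot(fc_min > 1, p_max > 0)
  rel$call <- ifelse(rel$fold_change >= fc_min & rel$p_value < p_max, "up",
              ifelse(rel$fold_change <= 1 / fc_min & rel$p_value < p_max,
                     "down", "ns"))
  rel$log2_fold <- log2(rel$fold_change)
  rel$neg_log10_p <- -log10(rel$p_value)
  rel
}

#' End-to-end qPCR quantification
#'
#' Convenience wrapper: [delta_ct()], [ddct_fold_change()], [volcano_calls()].
#'
#' @param plate a [qpcr_plate()].
#' @param reference reference gene name.
#' @param fc_min,p_max call thresholds (see [volcano_calls()]).
#' @param var_equal Student's (TRUE) or Welch (FALSE) t-test.
#' @return relative-expression data.frame with calls.
#' @export
qpcr_relative_expression <- function(plate, reference, fc_min = 2,
                                     p_max = 0.05, var_equal = TRUE) {
  volcano_calls(ddct_fold_change(delta_ct(plate, reference),
                                 var_equal = var_equal),
                fc_min = fc_min, p_max = p_max)
}
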