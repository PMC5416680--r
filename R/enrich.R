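#' Gene-set over-representation by Fisher's exact test
#'
#' One-sided hypergeometric tail per term: the probability of drawing at
#' least the observed overlap when `n_query` genes are sampled from a
#' universe containing `n_term_in_universe` term members. Query genes outside
#' the universe are dropped with a warning; terms with no universe overlap
#' are skipped and logged.
#'
#' @param query character vector of gene symbols (deduplicated, uppercased).
#' @param sets named list of member-symbol vectors (see [read_gmt()]).
#' @param universe character vector of background symbols.
#' @param alpha Bonferroni-corrected significance level for the flag.
#' @return data.frame, one row per tested term, sorted by `p_fisher`:
#'   term_id, term_name, n_query_in_term, n_query, n_term_in_universe,
#'   n_universe, p_fisher, p_bonferroni, significant.
#' @export
fisher_enrichment <- function(query, sets, universe, alpha = 0.01) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stopf("empty universe")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query genes outside the universe dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  term_names <- attr(sets, "term_names") %||%
    stats::setNames(names(sets), names(sets))
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(toupper(sets[[id]])), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(query, members))
    # one-sided over-representation tail P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = unname(term_names[id]),
               n_query_in_term = k, n_query = n,
               n_term_in_universe = K, n_universe = N,
               p_fisher = min(1, max(p, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  log_filter("terms with no universe overlap skipped", skipped)
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out <- bonferroni(out, alpha = alpha)
  out[order(out$p_fisher), , drop = FALSE]
}

#' Bonferroni correction over tested terms
#'
#' @param results data.frame with a `p_fisher` column (one row per tested
#'   term).
#' @param alpha significance level applied to the corrected p.
#' @return `results` with `p_bonferroni = min(1, m * p_fisher)` and a
#'   `significant` flag (`p_bonferroni < alpha`).
#' @export
bonferroni <- function(results, alpha = 0.01) {
  m <- nrow(results)
  stopifnot(m >= 1)
  results$p_bonferroni <- pmin(1, m * results$p_fisher)
  results$significant <- results$p_bonferroni < alpha
  results
}
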