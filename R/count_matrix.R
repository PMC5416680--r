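#' Construct a count matrix with group labels
#'
#' The entry point of the pipeline: a non-negative integer gene-by-sample
#' matrix of read counts (HTSeq-style) together with a case/control label per
#' sample.
#'
#' @param counts integer matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). All values must be non-negative
#'   integers.
#' @param groups named character vector mapping every sample ID to `"case"` or
#'   `"control"`.
#' @return An object of class `count_matrix`: the validated matrix with the
#'   group map attached as attribute `groups`.
#' @examples
#' m <- matrix(c(0L, 5L, 3L, 7L), 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cm <- count_matrix(m, c(s1 = "case", s2 = "control"))
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene ID: %s",
          rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample ID: %s",
          colnames(counts)[duplicated(colnames(counts))][1])
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, ]
    stopf("count at gene '%s', sample '%s' is not a non-negative integer",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  storage.mode(counts) <- "integer"
  groups <- validate_groups(groups, colnames(counts))
  structure(counts, groups = groups, class = c("count_matrix", class(counts)))
}

validate_groups <- function(groups, sample_ids) {
  if (is.null(names(groups))) stopf("groups must be named by sample ID")
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing)) stopf("no group label for sample '%s'", missing[1])
  groups <- groups[sample_ids]
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad)) stopf("group label must be 'case' or 'control', got '%s'", bad[1])
  if (length(unique(groups)) < 2 && length(sample_ids) > 1)
    stopf("need at least one sample in each of 'case' and 'control'")
  groups
}

#' @export
print.count_matrix <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("count_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x), ncol(x), sum(g == "case"), sum(g == "control")))
  invisible(x)
}

#' Group labels of a count matrix
#' @param x a `count_matrix`
#' @return named character vector of `"case"`/`"control"` labels.
#' @export
sample_groups <- function(x) attr(x, "groups")

#' Read a count matrix and sample sheet from TSV
#'
#' The counts file is tab-separated with a header row of sample IDs and the
#' gene IDs in the first column; the sample sheet is a two-column TSV
#' (sample ID, group). Lines starting with `#` are skipped in both.
#'
#' @param path counts TSV path.
#' @param sample_sheet path to the two-column sample sheet.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, sample_sheet) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stopf("counts TSV needs a gene column plus >=1 sample")
  gene_ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene ID in %s: %s", path, gene_ids[duplicated(gene_ids)][1])
  rownames(m) <- gene_ids
  ss <- read.delim(sample_sheet, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  # tolerate an optional header line
  if (identical(tolower(ss[1, 1]), "sample_id")) ss <- ss[-1, , drop = FALSE]
  groups <- stats::setNames(as.character(ss[[2]]), as.character(ss[[1]]))
  count_matrix(m, groups)
}

#' Write a count matrix (and its sample sheet) to TSV
#'
#' @param x a `count_matrix`.
#' @param path counts TSV path to write.
#' @param sample_sheet optional path for the two-column sample sheet.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, sample_sheet = NULL) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet)) {
    g <- attr(x, "groups")
    write.table(data.frame(names(g), unname(g)), sample_sheet, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `symbol`, `locus_group`; `locus_group` must be
#' one of `protein_coding`, `ncRNA`, `pseudogene`, `other`.
#'
#' @param path annotation TSV path.
#' @return data.frame with the three columns, symbols uppercased.
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  annotation_table(tab)
}

#' Validate an annotation table
#'
#' @param tab data.frame with columns `gene_id`, `symbol`, `locus_group`.
#' @return the validated data.frame (symbols uppercased).
#' @export
annotation_table <- function(tab) {
  need <- c("gene_id", "symbol", "locus_group")
  if (!all(need %in% names(tab)))
    stopf("annotation table needs columns %s; found: %s",
          paste(need, collapse = ", "), paste(names(tab), collapse = ", "))
  tab <- tab[, need]
  if (anyDuplicated(tab$gene_id))
    stopf("duplicate gene_id in annotation: %s",
          tab$gene_id[duplicated(tab$gene_id)][1])
  bad <- setdiff(unique(tab$locus_group), LOCUS_GROUPS)
  if (length(bad))
    stopf("unknown locus_group '%s' (allowed: %s)", bad[1],
          paste(LOCUS_GROUPS, collapse = ", "))
  tab$symbol <- toupper(tab$symbol)
  rownames(tab) <- NULL
  tab
}

#' Intersect two annotation universes
#'
#' Restricts the analysis universe to genes registered in both annotation
#' databanks (e.g. an ENSEMBL table and an HGNC table), the robustness step
#' applied before network and pathway annotation. Locus groups are taken from
#' the first table; conflicts are logged as warnings.
#'
#' @param a,b annotation data.frames (see [annotation_table()]).
#' @return annotation data.frame of the genes present in both, locus group
#'   from `a`.
#' @export
intersect_annotation_universes <- function(a, b) {
  a <- annotation_table(a); b <- annotation_table(b)
  keep <- a$gene_id %in% b$gene_id
  out <- a[keep, , drop = FALSE]
  conflicts <- merge(out, b, by = "gene_id", suffixes = c("", ".b"))
  n_conf <- sum(conflicts$locus_group != conflicts$locus_group.b)
  if (n_conf > 0) {
    warning(sprintf("%d genes with conflicting locus_group; first table wins",
                    n_conf), call. = FALSE)
    log_filter("locus_group conflicts (first table kept)", n_conf)
  }
  rownames(out) <- NULL
  out
}
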