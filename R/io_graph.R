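#' Read a protein-interaction reference graph
#'
#' Accepts either a plain two-column tab-separated edge list of gene symbols,
#' or a BioGRID tab export (columns `Official Symbol Interactor A` /
#' `Official Symbol Interactor B`). Symbols are uppercased; self-loops and
#' duplicate (unordered) edges are removed and their counts logged.
#'
#' @param path input file.
#' @param dialect `"edge_list"` or `"biogrid_tab"`.
#' @return an undirected simple `igraph` graph whose vertex names are
#'   uppercase gene symbols.
#' @export
read_interactome <- function(path, dialect = c("edge_list", "biogrid_tab")) {
  dialect <- match.arg(dialect)
  if (dialect == "edge_list") {
    tab <- tryCatch(
      read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                 stringsAsFactors = FALSE),
      error = function(e) data.frame())
    if (nrow(tab) == 0) {
      warning(sprintf("empty interactome file: %s", path), call. = FALSE)
      return(igraph::make_empty_graph(0, directed = FALSE))
    }
    if (ncol(tab) < 2) stopf("edge list needs two tab-separated columns")
    a <- as.character(tab[[1]]); b <- as.character(tab[[2]])
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                      check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
    if (!all(need %in% names(tab)))
      stopf("BioGRID export lacks required columns; found: %s",
            paste(names(tab), collapse = ", "))
    a <- as.character(tab[[need[1]]]); b <- as.character(tab[[need[2]]])
  }
  interactome_from_edges(a, b)
}

# Shared construction: uppercase, drop self-loops, dedupe unordered pairs.
interactome_from_edges <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  self <- a == b
  log_filter("self-loop edges removed", sum(self))
  a <- a[!self]; b <- b[!self]
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key)
  log_filter("duplicate edges removed", sum(dup))
  g <- igraph::graph_from_edgelist(cbind(a[!dup], b[!dup]), directed = FALSE)
  g
}

#' Write an interactome as a two-column edge list TSV
#' @param graph an undirected `igraph` graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `term_id`, description, then
#' member symbols. Duplicate members within a set are collapsed; members are
#' uppercased.
#'
#' @param path GMT file path.
#' @return a named list of uppercase member-symbol vectors, with the
#'   descriptions in attribute `term_names`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopf("GMT line %d has %d fields (need >=3: term, description, members)",
            i, length(f))
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) stopf("GMT line %d: set '%s' is empty", i, f[1])
    sets[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  structure(sets, term_names = descs)
}

#' Write a gene-set collection to GMT
#' @param sets named list of member vectors (as from [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "term_names") %||% stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descs[[id]] %||% id, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR plate of Ct values
#'
#' TSV with columns `sample_id`, `group`, `gene`, `replicate`, `ct`,
#' `is_reference`. Every sample must carry at least one reference-gene
#' measurement and all Ct values must be finite and positive.
#'
#' @param path plate TSV path.
#' @return validated data.frame of class `qpcr_plate`.
#' @export
read_qpcr_plate <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  qpcr_plate(tab)
}

#' Validate a qPCR plate table
#' @param tab data.frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct`, `is_reference`.
#' @return the validated data.frame, classed `qpcr_plate`.
#' @export
qpcr_plate <- function(tab) {
  need <- c("sample_id", "group", "gene", "replicate", "ct", "is_reference")
  if (!all(need %in% names(tab)))
    stopf("qPCR plate needs columns %s", paste(need, collapse = ", "))
  tab$is_reference <- as.logical(tab$is_reference)
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0))
    stopf("Ct values must be finite and > 0")
  by_sample <- tapply(tab$is_reference, tab$sample_id, any)
  if (!all(by_sample))
    stopf("sample '%s' has no reference-gene measurement",
          names(by_sample)[!by_sample][1])
  class(tab) <- c("qpcr_plate", "data.frame")
  tab
}

#' Write a qPCR plate to TSV
#' @param plate a `qpcr_plate` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qpcr_plate <- function(plate, path) {
  write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
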