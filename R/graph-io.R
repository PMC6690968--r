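#' Read an undirected protein-protein interaction network from an edge list
#'
#' Reads a two-column delimited file of node identifiers and returns a simple
#' undirected \pkg{igraph} graph. Self-loops and duplicate edges (in either
#' orientation) are removed, with a message reporting how many were dropped.
#' Columns beyond the first two are ignored; lines starting with `#` are
#' skipped. Node identifiers are opaque, case-sensitive strings.
#'
#' Isolated (degree-0) nodes cannot be expressed in an edge list; pass a
#' character vector of node names via `nodes` to include them. They receive
#' clustering coefficient 0 and link-clustering score 0 in downstream
#' topology tables.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter, default tab.
#' @param nodes Optional character vector of additional node names to include
#'   (degree-0 nodes not present in the edge list).
#' @return An undirected simple `igraph` graph with a `name` vertex attribute.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("a\tb", "b\ta", "c\tc", "a\tb", "b\tc"), tf)
#' g <- read_edge_list(tf)
#' igraph::ecount(g) # 2: the duplicate and the self-loop were dropped
read_edge_list <- function(path, delimiter = "\t", nodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(parts, function(p) sum(nzchar(p)) < 2L, logical(1)))
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", bad[1], ": fewer than 2 columns")
  }
  el <- t(vapply(parts, function(p) p[nzchar(p)][1:2], character(2)))
  graph_from_edges(el[, 1], el[, 2], extra_nodes = nodes)
}

#' Build a simple undirected graph from two node vectors
#'
#' Internal constructor shared by readers and the synthetic generator:
#' deduplicates undirected edges and strips self-loops.
#'
#' @param from,to Character vectors of edge endpoints.
#' @param extra_nodes Optional additional (possibly isolated) node names.
#' @return An undirected simple `igraph` graph.
#' @keywords internal
graph_from_edges <- function(from, to, extra_nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  loops <- from == to
  a <- pmin(from[!loops], to[!loops])
  b <- pmax(from[!loops], to[!loops])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dropped_loops <- sum(loops)
  n_dropped_dups <- sum(dup)
  if (n_dropped_loops + n_dropped_dups > 0L) {
    message(
      "dropped ", n_dropped_loops, " self-loop(s) and ",
      n_dropped_dups, " duplicate edge(s)"
    )
  }
  verts <- unique(c(from, to, as.character(extra_nodes)))
  igraph::graph_from_data_frame(
    data.frame(from = a[!dup], to = b[!dup]),
    directed = FALSE,
    vertices = sort(verts)
  )
}

#' Write a network as a two-column tab-separated edge list
#'
#' Round-trips with [read_edge_list()]: reading the written file reproduces
#' an identical node and edge set.
#'
#' @param net An undirected `igraph` graph with named vertices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(el,
    file = path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read essentiality labels
#'
#' Reads a two-column delimited file mapping gene to an essentiality token
#' and returns a tibble with a logical `essential` column. Duplicate rows
#' with consistent labels collapse to one (with a warning); conflicting
#' labels for the same gene are an error.
#'
#' @param path Path to the label file.
#' @param delimiter Field delimiter, default tab.
#' @param essential_tokens,nonessential_tokens Accepted label synonyms.
#' @return A tibble with columns `node` (character) and `essential` (logical).
#' @export
read_labels <- function(path, delimiter = "\t",
                        essential_tokens = c("E", "essential", "1"),
                        nonessential_tokens = c("NE", "non-essential", "nonessential", "0")) {
  df <- utils::read.table(path,
    sep = delimiter, header = FALSE, comment.char = "#",
    stringsAsFactors = FALSE, colClasses = "character"
  )
  if (ncol(df) < 2L) stop("label file must have at least 2 columns")
  tok <- df[[2]]
  known <- tok %in% c(essential_tokens, nonessential_tokens)
  if (!all(known)) {
    stop(
      "unknown essentiality label(s): ",
      paste(unique(tok[!known]), collapse = ", ")
    )
  }
  out <- tibble::tibble(node = df[[1]], essential = tok %in% essential_tokens)
  dup <- duplicated(out$node)
  if (any(dup)) {
    consistent <- !anyDuplicated(unique(out)[["node"]])
    if (!consistent) {
      conf <- unique(out$node[dup])[1]
      stop("conflicting labels for gene: ", conf)
    }
    warning(sum(dup), " duplicate label row(s) collapsed")
    out <- out[!dup, ]
  }
  out
}

#' Restrict essentiality labels to the nodes of a network
#'
#' Drops labels for genes absent from the graph and reports how many were
#' removed. Errors if the restriction leaves zero essential or zero
#' non-essential genes, since every label-dependent statistic needs both.
#'
#' @param labels A tibble as returned by [read_labels()].
#' @param net An `igraph` graph with named vertices.
#' @return The restricted label tibble.
#' @export
restrict_to_network <- function(labels, net) {
  stopifnot(all(c("node", "essential") %in% names(labels)))
  keep <- labels$node %in% igraph::V(net)$name
  n_removed <- sum(!keep)
  if (n_removed > 0L) message(n_removed, " label(s) not in network removed")
  out <- labels[keep, ]
  if (sum(out$essential) == 0L || sum(!out$essential) == 0L) {
    stop("restriction left zero essential or zero non-essential genes")
  }
  out
}

#' Read a flat term-to-gene annotation table
#'
#' One `term<TAB>gene` pair per line. Terms annotating fewer than `min_genes`
#' genes are dropped at load time (hypergeometric enrichment on tiny terms is
#' uninformative).
#'
#' @param path Path to the annotation file.
#' @param delimiter Field delimiter, default tab.
#' @param min_genes Minimum annotated genes per retained term (default 3).
#' @return A tibble with columns `term` and `gene`, one row per pair.
#' @export
read_annotations <- function(path, delimiter = "\t", min_genes = 3L) {
  df <- utils::read.table(path,
    sep = delimiter, header = FALSE, comment.char = "#",
    stringsAsFactors = FALSE, colClasses = "character"
  )
  if (ncol(df) < 2L) stop("annotation file must have at least 2 columns")
  ann <- tibble::tibble(term = df[[1]], gene = df[[2]])
  ann <- dplyr::distinct(ann)
  filter_annotation(ann, min_genes = min_genes)
}

#' Drop small terms from an annotation table
#'
#' @param ann A tibble with `term` and `gene` columns.
#' @param min_genes Minimum annotated genes per retained term.
#' @return The filtered annotation tibble.
#' @export
filter_annotation <- function(ann, min_genes = 3L) {
  sizes <- table(ann$term)
  keep <- names(sizes)[sizes >= min_genes]
  dropped <- length(sizes) - length(keep)
  if (dropped > 0L) {
    message(dropped, " term(s) with fewer than ", min_genes, " genes dropped")
  }
  ann[ann$term %in% keep, ]
}

#' Read a gene-by-condition fitness-effect matrix
#'
#' Expects a header row of condition identifiers and a first column of gene
#' identifiers. Values are dimensionless fitness effects (more negative =
#' stronger fitness loss upon knockout). Missing cells are permitted and are
#' excluded from broadness counts downstream.
#'
#' @param path Path to a CSV or TSV file.
#' @param delimiter Field delimiter; `","` (default) or `"\t"`.
#' @return A numeric matrix with gene rownames and condition colnames.
#' @export
read_fitness_matrix <- function(path, delimiter = ",") {
  df <- utils::read.table(path,
    sep = delimiter, header = TRUE, row.names = 1,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("fitness matrix needs gene rownames and condition colnames")
  }
  m
}
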