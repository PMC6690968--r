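#' Node clustering coefficient C
#'
#' For node i with degree k_i and T_i triangles through it,
#' C_i = 2 T_i / (k_i (k_i - 1)); nodes with fewer than two neighbours get
#' C = 0 so that downstream aggregation never propagates undefined values.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @return A named numeric vector of C values, one per node.
#' @export
node_clustering <- function(net) {
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  stats::setNames(cc, igraph::V(net)$name)
}

# common-neighbour count z_ij for every edge, via one sparse matrix product
edge_common_neighbors <- function(net) {
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  el <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(el) == 0L) return(numeric(0))
  a2 <- a %*% a
  as.numeric(a2[cbind(el[, 1], el[, 2])])
}

#' Edge-level clustering measures CXC, LCC and ECC
#'
#' Three link-clustering measures on every edge (i, j), with z_ij the number
#' of common neighbours of i and j:
#' \describe{
#'   \item{CXC}{product of the endpoint node clustering coefficients,
#'     C_i * C_j.}
#'   \item{LCC}{Jaccard overlap of the endpoint neighbourhoods excluding the
#'     endpoints themselves, z_ij / (k_i - 1 + k_j - 1 - z_ij).}
#'   \item{ECC}{triangle support of the edge relative to its maximum,
#'     (z_ij + offset) / min(k_i - 1, k_j - 1); `offset = 1` gives the
#'     Radicchi variant.}
#' }
#' Any measure with a zero denominator is defined as 0 rather than NaN.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param kind One of `"CXC"`, `"LCC"`, `"ECC"`.
#' @param offset Numerator offset for ECC, 0 (default) or 1.
#' @return A tibble with columns `from`, `to` and `value`, one row per edge.
#' @export
edge_measure <- function(net, kind = c("CXC", "LCC", "ECC"), offset = 0) {
  kind <- match.arg(kind)
  el <- igraph::as_edgelist(net)
  deg <- igraph::degree(net)
  if (nrow(el) == 0L) {
    return(tibble::tibble(from = character(), to = character(), value = numeric()))
  }
  ki <- deg[el[, 1]]
  kj <- deg[el[, 2]]
  value <- switch(kind,
    CXC = {
      cc <- node_clustering(net)
      unname(cc[el[, 1]] * cc[el[, 2]])
    },
    LCC = {
      z <- edge_common_neighbors(net)
      den <- ki - 1 + kj - 1 - z
      unname(ifelse(den > 0, z / den, 0))
    },
    ECC = {
      z <- edge_common_neighbors(net)
      den <- pmin(ki - 1, kj - 1)
      unname(ifelse(den > 0, (z + offset) / den, 0))
    }
  )
  tibble::tibble(from = el[, 1], to = el[, 2], value = value)
}

#' Aggregate an edge measure onto nodes
#'
#' Node-level aggregation of a link-clustering measure over each node's
#' incident edges: the mean gives the mu-aggregates (muCXC etc.) and the sum
#' the Sigma-aggregates. Degree-0 nodes get 0. The algebraic identity
#' Sigma = degree * mu holds exactly.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param edgevals A tibble as returned by [edge_measure()]; must cover
#'   every edge of `net`.
#' @param mode `"mean"` or `"sum"`.
#' @return A named numeric vector, one value per node.
#' @export
aggregate_edge_measure <- function(net, edgevals, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (nrow(edgevals) != igraph::ecount(net) || anyNA(edgevals$value)) {
    stop("edge values must be defined on all edges of the network")
  }
  nodes <- igraph::V(net)$name
  tot <- stats::setNames(numeric(length(nodes)), nodes)
  inc <- c(edgevals$from, edgevals$to)
  val <- c(edgevals$value, edgevals$value)
  sums <- tapply(val, inc, sum)
  tot[names(sums)] <- sums
  if (mode == "sum") return(tot)
  deg <- igraph::degree(net)[nodes]
  ifelse(deg > 0, tot / deg, 0)
}

#' Centrality measures DC, BC, CC, EC
#'
#' Degree (DC), normalized shortest-path betweenness (BC, divided by
#' (n-1)(n-2)/2 with fractional tie-splitting), closeness (CC) computed
#' within each connected component and scaled by (component size - 1)/(n - 1)
#' (the Wasserman-Faust correction, keeping values comparable across
#' components), and eigenvector centrality (EC, principal eigenvector scaled
#' to unit Euclidean norm; components other than the dominant one score
#' approximately 0).
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param kind One of `"DC"`, `"BC"`, `"CC"`, `"EC"`.
#' @return A named numeric vector, one value per node.
#' @export
centrality <- function(net, kind = c("DC", "BC", "CC", "EC")) {
  kind <- match.arg(kind)
  if (igraph::vcount(net) == 0L) stop("empty graph")
  nodes <- igraph::V(net)$name
  out <- switch(kind,
    DC = igraph::degree(net),
    BC = igraph::betweenness(net, normalized = TRUE),
    CC = closeness_wf(net),
    EC = {
      ec <- igraph::eigen_centrality(net)$vector
      nrm <- sqrt(sum(ec^2))
      if (nrm > 0) ec / nrm else ec
    }
  )
  stats::setNames(as.numeric(out[nodes]), nodes)
}

# closeness per connected component with Wasserman-Faust scaling
closeness_wf <- function(net) {
  n <- igraph::vcount(net)
  comp <- igraph::components(net)$membership
  nodes <- igraph::V(net)$name
  out <- stats::setNames(numeric(n), nodes)
  if (n <= 1L) return(out)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    nc <- length(idx)
    if (nc < 2L) next
    d <- igraph::distances(net, v = idx, to = idx)
    tot <- rowSums(d)
    out[nodes[idx]] <- (nc - 1) / tot * (nc - 1) / (n - 1)
  }
  out
}

#' Full per-node topology table
#'
#' Computes all eleven topology measures on one graph: the four centralities
#' (DC, BC, CC, EC), the node clustering coefficient C, and the mean and sum
#' node aggregations of the three link-clustering measures (muCXC, muLCC,
#' muECC, sumCXC, sumLCC, sumECC). Two aliases carry the analysis: `k` = DC
#' (degree) and `w` = muCXC, the link-clustering score used to characterize
#' non-central essential genes.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param ecc_offset Numerator offset for ECC (0 or 1), see [edge_measure()].
#' @return A tibble of class `topology_table`, one row per node, with columns
#'   `node`, `DC`, `BC`, `CC`, `EC`, `C`, `muCXC`, `muLCC`, `muECC`,
#'   `sumCXC`, `sumLCC`, `sumECC`, `k`, `w`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, a - c, b - c, a - d)
#' compute_table(g)
compute_table <- function(net, ecc_offset = 0) {
  if (igraph::vcount(net) == 0L) stop("empty graph")
  nodes <- igraph::V(net)$name
  cxc <- edge_measure(net, "CXC")
  lcc <- edge_measure(net, "LCC")
  ecc <- edge_measure(net, "ECC", offset = ecc_offset)
  tab <- tibble::tibble(
    node = nodes,
    DC = as.numeric(centrality(net, "DC")),
    BC = as.numeric(centrality(net, "BC")),
    CC = as.numeric(centrality(net, "CC")),
    EC = as.numeric(centrality(net, "EC")),
    C = as.numeric(node_clustering(net)[nodes]),
    muCXC = as.numeric(aggregate_edge_measure(net, cxc, "mean")[nodes]),
    muLCC = as.numeric(aggregate_edge_measure(net, lcc, "mean")[nodes]),
    muECC = as.numeric(aggregate_edge_measure(net, ecc, "mean")[nodes]),
    sumCXC = as.numeric(aggregate_edge_measure(net, cxc, "sum")[nodes]),
    sumLCC = as.numeric(aggregate_edge_measure(net, lcc, "sum")[nodes]),
    sumECC = as.numeric(aggregate_edge_measure(net, ecc, "sum")[nodes])
  )
  tab$k <- tab$DC
  tab$w <- tab$muCXC
  class(tab) <- c("topology_table", class(tab))
  tab
}
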