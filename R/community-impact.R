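#' Hierarchical community structure by random-walk agglomeration
#'
#' Runs the Walktrap algorithm, which measures node similarity by comparing
#' where short random walks from each node tend to land, and agglomerates
#' the most similar clusters first. The returned merge sequence encodes the
#' full dendrogram: replaying a prefix of the merges yields the community
#' partition at that hierarchical level. For a graph with N nodes and c
#' connected components the sequence holds M = N - c merges.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param walk_length Random-walk length (default 4).
#' @return An object of class `merge_sequence`: a list with `merges` (M x 2
#'   matrix; entries 1..N are singleton nodes, N + i is the cluster created
#'   by merge row i), `nodes` (node names), `n_merges`.
#' @export
build_hierarchy <- function(net, walk_length = 4) {
  if (igraph::vcount(net) == 0L) stop("empty graph")
  wt <- igraph::cluster_walktrap(net, steps = walk_length)
  merges <- wt$merges
  if (is.null(merges)) merges <- matrix(numeric(0), 0, 2)
  structure(
    list(
      merges = merges,
      nodes = igraph::V(net)$name,
      n_merges = nrow(merges)
    ),
    class = "merge_sequence"
  )
}

#' Communities at a hierarchy fraction
#'
#' Replays the first `ceiling(f_H * M)` merges of a merge sequence (so
#' f_H = 1 replays the whole dendrogram and any positive f_H replays at
#' least one merge) and returns the resulting clusters, discarding those
#' with fewer than `min_size` members.
#'
#' @param ms A `merge_sequence` from [build_hierarchy()].
#' @param f_H Hierarchy fraction in (0, 1]; small values give low (local)
#'   hierarchical levels.
#' @param min_size Minimum community size to retain (default 3).
#' @return A list of character vectors of node names, one per community.
#' @export
communities_at_level <- function(ms, f_H, min_size = 3L) {
  stopifnot(f_H > 0, f_H <= 1)
  n <- length(ms$nodes)
  m_replay <- ceiling(f_H * ms$n_merges)
  # union-find replay; cluster ids: 1..N singletons, N + i from merge row i
  parent <- seq_len(n + m_replay)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(m_replay)) {
    a <- find(ms$merges[i, 1])
    b <- find(ms$merges[i, 2])
    parent[a] <- n + i
    parent[b] <- n + i
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  comms <- split(ms$nodes, roots)
  comms <- unname(comms[lengths(comms) >= min_size])
  comms[order(vapply(comms, `[`, character(1), 1))]
}

#' Link-density impact of removing one node from its community
#'
#' For a community s of n_s nodes holding l_s internal links, removing node
#' i leaves l_s_after internal links; the change in link density is
#' dD = (l_s_after - l_s) / (n_s (n_s - 1) / 2), i.e. minus the fraction of
#' the community's possible links lost. The removed node stays in the
#' denominator's n_s, and l_s is measured before removal, so dD is in
#' [-1, 0] and equals 0 exactly when the node has no within-community links.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param community Character vector of community members (length >= 3).
#' @param node A member of `community` to remove.
#' @return A one-row tibble: `node`, `n_s`, `l_s`, `l_s_after`, `delta_d`.
#' @export
delta_density <- function(net, community, node) {
  if (!node %in% community) stop("node is not a member of the community")
  if (length(community) < 3L) stop("community must have at least 3 members")
  sub <- igraph::induced_subgraph(net, community)
  l_s <- igraph::ecount(sub)
  removed <- igraph::degree(sub, v = node)
  n_s <- length(community)
  tibble::tibble(
    node = node,
    n_s = as.integer(n_s),
    l_s = as.integer(l_s),
    l_s_after = as.integer(l_s - removed),
    delta_d = -as.numeric(removed) / (n_s * (n_s - 1) / 2)
  )
}

#' Mean link-density impact per essential-gene class across hierarchy levels
#'
#' At each hierarchy fraction, every classified node sitting in a community
#' of at least 3 members gets its [delta_density()] value in its own
#' community; group means and standard errors are returned per class.
#' Classes with no eligible members at a level yield missing means (logged).
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param ms A `merge_sequence` from [build_hierarchy()].
#' @param classes An `eg_classification` from [classify_egs()].
#' @param f_H_grid Hierarchy fractions to evaluate (default 0.1 to 1 by 0.1).
#' @return A tibble with `f_H`, `class`, `mean_delta_d`, `se`, `n`.
#' @export
group_delta_density <- function(net, ms, classes,
                                f_H_grid = seq(0.1, 1, by = 0.1)) {
  cls <- classes$nodes[, c("node", "class")]
  purrr::map_dfr(f_H_grid, function(fh) {
    comms <- communities_at_level(ms, fh)
    per_node <- purrr::map_dfr(comms, function(comm) {
      members <- intersect(comm, cls$node)
      if (length(members) == 0L) return(NULL)
      sub <- igraph::induced_subgraph(net, comm)
      deg_in <- igraph::degree(sub, v = members)
      n_s <- length(comm)
      tibble::tibble(
        node = members,
        delta_d = -as.numeric(deg_in) / (n_s * (n_s - 1) / 2)
      )
    })
    if (nrow(per_node) == 0L) {
      per_node <- tibble::tibble(node = character(), delta_d = numeric())
    }
    out <- dplyr::left_join(per_node, cls, by = "node") |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(
        mean_delta_d = mean(.data$delta_d),
        se = stats::sd(.data$delta_d) / sqrt(dplyr::n()),
        n = dplyr::n(),
        .groups = "drop"
      ) |>
      tidyr::complete(
        class = unique(cls$class),
        fill = list(mean_delta_d = NA_real_, se = NA_real_, n = 0L)
      )
    missing_classes <- out$class[out$n == 0L]
    if (length(missing_classes) > 0L) {
      message(
        "f_H = ", fh, ": no community members for class(es) ",
        paste(missing_classes, collapse = ", ")
      )
    }
    dplyr::mutate(out, f_H = fh, .before = 1)
  })
}
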