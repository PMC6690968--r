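# Brute-force oracles, independent of igraph's algorithms, plus shared fixtures.

# adjacency list from an edge-list matrix of node names
oracle_adj <- function(el, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]
    b <- el[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# node clustering coefficient by enumerating neighbour pairs
oracle_clustering <- function(net) {
  el <- igraph::as_edgelist(net)
  nodes <- igraph::V(net)$name
  adj <- oracle_adj(el, nodes)
  has_edge <- function(a, b) b %in% adj[[a]]
  vapply(nodes, function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (has_edge(nb[i], nb[j])) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# common-neighbour count per edge by set intersection
oracle_common_neighbors <- function(net) {
  el <- igraph::as_edgelist(net)
  adj <- oracle_adj(el, igraph::V(net)$name)
  vapply(seq_len(nrow(el)), function(i) {
    length(intersect(adj[[el[i, 1]]], adj[[el[i, 2]]]))
  }, numeric(1))
}

# all n-cliques by subset checking
oracle_cliques <- function(net, n) {
  nodes <- igraph::V(net)$name
  if (length(nodes) < n) return(list())
  el <- igraph::as_edgelist(net)
  adj <- oracle_adj(el, nodes)
  combos <- utils::combn(nodes, n, simplify = FALSE)
  Filter(function(cs) {
    all(utils::combn(cs, 2, function(p) p[2] %in% adj[[p[1]]]))
  }, combos)
}

# MCC-optimal cutoff by scanning every distinct value (and -Inf) directly
oracle_mcc_cutoff <- function(v, y) {
  cand <- c(-Inf, sort(unique(v)), Inf)
  mccs <- vapply(cand, function(ct) {
    pred <- v >= ct
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- sum(!pred & y); tn <- sum(!pred & !y)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }, numeric(1))
  max(mccs)
}

# delta-density by recounting edges in the induced subgraph
oracle_delta_density <- function(net, community, node) {
  el <- igraph::as_edgelist(net)
  inside <- el[, 1] %in% community & el[, 2] %in% community
  l_s <- sum(inside)
  touching <- inside & (el[, 1] == node | el[, 2] == node)
  n_s <- length(community)
  -sum(touching) / (n_s * (n_s - 1) / 2)
}

# upper-tail hypergeometric by exact combinatorial sum
oracle_hyper_upper <- function(q, m, n, k) {
  xs <- q:min(m, k)
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

# shared toy fixtures
kite_graph <- function() {
  igraph::make_graph(~ "1" - "2", "1" - "3", "2" - "3", "1" - "4")
}

two_clique_bridge <- function() {
  igraph::make_graph(
    ~ a - b, a - c, a - d, b - c, b - d, c - d,
    e - f, e - g, e - h, f - g, f - h, g - h,
    d - e
  )
}

random_small_graph <- function(n, p = 0.3) {
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", seq_len(n)))
}

# labels tibble shorthand
make_labels <- function(nodes, essential_nodes) {
  tibble::tibble(node = nodes, essential = nodes %in% essential_nodes)
}
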