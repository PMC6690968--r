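#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test of each annotation term against a hit set:
#' the probability of drawing at least the observed overlap when sampling
#' `|hits|` genes from the universe. Term members outside the universe are
#' excluded before testing; `hits` must be a subset of `universe`.
#'
#' @param ann Annotation tibble with `term` and `gene` columns.
#' @param hits Character vector of hit genes (e.g. one class of EGs).
#' @param universe Character vector of background genes.
#' @return A tibble with `term`, `term_size` (term genes in the universe),
#'   `overlap` and `p`.
#' @export
term_enrichment <- function(ann, hits, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  ann <- ann[ann$gene %in% universe, ]
  ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      term_size = dplyr::n_distinct(.data$gene),
      overlap = sum(unique(.data$gene) %in% hits),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p = stats::phyper(
        .data$overlap - 1, .data$term_size,
        length(universe) - .data$term_size, length(hits),
        lower.tail = FALSE
      )
    )
}

#' Tag terms as k-functions or w-functions
#'
#' A term is a k-function when it is enriched (p < `p_cutoff`) with
#' k-dependent essential genes in at least `min_networks` of the supplied
#' enrichment maps, and a w-function analogously; the two tags are tested
#' independently, so a term can be both. With a single network pass
#' `min_networks = 1` (logged).
#'
#' @param k_enrichments,w_enrichments Lists of [term_enrichment()] tibbles,
#'   one per network, for k-dependent and w-dependent hit sets.
#' @param min_networks Minimum number of networks a term must be enriched in.
#' @param p_cutoff Enrichment p-value cutoff (default 0.05).
#' @return A tibble with `term`, `is_k`, `is_w` and `tag` in
#'   \{"k-function", "w-function", "both", "neither"\}.
#' @export
tag_terms <- function(k_enrichments, w_enrichments, min_networks = 3,
                      p_cutoff = 0.05) {
  if (min_networks == 1L) message("single-network mode: min_networks = 1")
  count_hits <- function(maps) {
    hits <- purrr::map(maps, ~ .x$term[.x$p < p_cutoff])
    table(unlist(hits))
  }
  k_tab <- count_hits(k_enrichments)
  w_tab <- count_hits(w_enrichments)
  terms <- sort(unique(c(
    unlist(purrr::map(k_enrichments, "term")),
    unlist(purrr::map(w_enrichments, "term"))
  )))
  is_k <- terms %in% names(k_tab)[k_tab >= min_networks]
  is_w <- terms %in% names(w_tab)[w_tab >= min_networks]
  tibble::tibble(
    term = terms, is_k = is_k, is_w = is_w,
    tag = dplyr::case_when(
      is_k & is_w ~ "both",
      is_k ~ "k-function",
      is_w ~ "w-function",
      TRUE ~ "neither"
    )
  )
}

#' Term-overlap network
#'
#' Links two annotation terms when their gene overlap within the universe is
#' larger than expected (upper-tail hypergeometric p < `link_p_cutoff`).
#' Terms reduced below 3 universe genes are dropped.
#'
#' @param ann Annotation tibble with `term` and `gene` columns.
#' @param universe Character vector of background genes.
#' @param link_p_cutoff Overlap p-value cutoff for an edge (default 1e-5).
#' @return A list with `graph` (an `igraph` of terms; isolated terms are
#'   retained as vertices) and `overlaps` (tibble of tested pairs with `p`).
#' @export
build_term_network <- function(ann, universe, link_p_cutoff = 1e-5) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  ann <- ann[ann$gene %in% universe, ]
  sets <- split(ann$gene, ann$term)
  sets <- purrr::map(sets, unique)
  sets <- sets[lengths(sets) >= 3L]
  terms <- names(sets)
  nt <- length(terms)
  if (nt < 2L) {
    return(list(
      graph = igraph::set_vertex_attr(
        igraph::make_empty_graph(n = nt, directed = FALSE),
        "name",
        value = terms
      ),
      overlaps = tibble::tibble(
        term1 = character(), term2 = character(),
        overlap = integer(), p = numeric()
      )
    ))
  }
  pairs <- utils::combn(nt, 2)
  overlap <- vapply(
    seq_len(ncol(pairs)),
    function(j) length(intersect(sets[[pairs[1, j]]], sets[[pairs[2, j]]])),
    integer(1)
  )
  n1 <- lengths(sets)[pairs[1, ]]
  n2 <- lengths(sets)[pairs[2, ]]
  p <- stats::phyper(overlap - 1, n1, length(universe) - n1, n2,
    lower.tail = FALSE
  )
  overlaps <- tibble::tibble(
    term1 = terms[pairs[1, ]], term2 = terms[pairs[2, ]],
    overlap = overlap, p = as.numeric(p)
  )
  edges <- overlaps[overlaps$p < link_p_cutoff, c("term1", "term2")]
  g <- igraph::graph_from_data_frame(edges,
    directed = FALSE,
    vertices = data.frame(name = terms)
  )
  list(graph = g, overlaps = overlaps)
}

# observed k-k / k-w / w-w edge counts given per-term (is_k, is_w) tags
count_link_categories <- function(el_idx, is_k, is_w) {
  ki <- is_k[el_idx[, 1]]; kj <- is_k[el_idx[, 2]]
  wi <- is_w[el_idx[, 1]]; wj <- is_w[el_idx[, 2]]
  c(
    kk = sum(ki & kj),
    kw = sum((ki & wj) | (wi & kj)),
    ww = sum(wi & wj)
  )
}

#' Shuffle z-test for link categories in a term network
#'
#' Counts term-network links between two k-functions (k-k), between a
#' k-function and a w-function (k-w), and between two w-functions (w-w),
#' then shuffles the (is_k, is_w) tag pairs across tagged terms — preserving
#' the joint tag distribution — and reports a z-score per category against
#' the shuffled null. "Both"-tagged terms contribute through each of their
#' tags; untagged ("neither") terms are excluded.
#'
#' @param term_network Result of [build_term_network()], or an `igraph` of
#'   terms.
#' @param tags Tibble from [tag_terms()] with `term`, `is_k`, `is_w`.
#' @param n_shuffle Number of tag shuffles (default 10000).
#' @param seed Integer seed.
#' @return A tibble with one row per category: `category`, `observed`,
#'   `null_mean`, `null_sd`, `z` (NA with an explanatory `note` when the
#'   null spread is zero, e.g. all tags identical).
#' @export
link_category_ztest <- function(term_network, tags, n_shuffle = 10000, seed = 1) {
  g <- if (igraph::is_igraph(term_network)) term_network else term_network$graph
  tags <- tags[tags$is_k | tags$is_w, ]
  if (!any(tags$is_k) || !any(tags$is_w)) {
    stop("need at least one k-function and one w-function")
  }
  keep <- intersect(igraph::V(g)$name, tags$term)
  g <- igraph::induced_subgraph(g, keep)
  terms <- igraph::V(g)$name
  tags <- tags[match(terms, tags$term), ]
  el <- igraph::as_edgelist(g, names = FALSE)
  obs <- count_link_categories(el, tags$is_k, tags$is_w)
  set.seed(seed)
  nulls <- matrix(0, n_shuffle, 3)
  for (s in seq_len(n_shuffle)) {
    perm <- sample.int(length(terms))
    nulls[s, ] <- count_link_categories(el, tags$is_k[perm], tags$is_w[perm])
  }
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, stats::sd)
  tibble::tibble(
    category = c("k-k", "k-w", "w-w"),
    observed = as.numeric(obs),
    null_mean = mu,
    null_sd = sdv,
    z = ifelse(sdv > 0, (obs - mu) / sdv, NA_real_),
    note = ifelse(sdv > 0, NA_character_,
      "null sd is zero (tag assignment leaves this category invariant)"
    )
  )
}

#' Bias of n-cliques toward k-dependent or w-dependent essential genes
#'
#' Enumerates all fully connected subgraphs of `n` nodes. A clique is
#' k-biased when it holds strictly more k-dependent than w-dependent
#' members, w-biased in the reverse case, and tied otherwise (ties,
#' including 0-0, fall in neither fraction). The z-score treats the
#' w-biased count as binomial with success probability equal to the
#' k-biased fraction.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param classes An `eg_classification` from [classify_egs()].
#' @param n Clique size, 3 or 4.
#' @return A one-row tibble: `n`, `n_cliques`, `frac_k_biased`,
#'   `frac_w_biased`, `frac_tied`, `z`.
#' @export
clique_bias <- function(net, classes, n = 3) {
  stopifnot(n %in% c(3, 4))
  cls <- stats::setNames(as.character(classes$nodes$class), classes$nodes$node)
  cliques <- igraph::cliques(net, min = n, max = n)
  if (length(cliques) == 0L) stop("no ", n, "-cliques in the network")
  names_of <- igraph::V(net)$name
  counts <- vapply(cliques, function(cl) {
    members <- cls[names_of[as.integer(cl)]]
    c(
      sum(members == "k-dependent", na.rm = TRUE),
      sum(members == "w-dependent", na.rm = TRUE)
    )
  }, numeric(2))
  k_biased <- counts[1, ] > counts[2, ]
  w_biased <- counts[2, ] > counts[1, ]
  total <- length(cliques)
  p_hat <- mean(k_biased)
  nw <- sum(w_biased)
  z <- if (p_hat %in% c(0, 1)) {
    NA_real_
  } else {
    (nw - total * p_hat) / sqrt(total * p_hat * (1 - p_hat))
  }
  tibble::tibble(
    n = n, n_cliques = total,
    frac_k_biased = mean(k_biased),
    frac_w_biased = mean(w_biased),
    frac_tied = 1 - mean(k_biased) - mean(w_biased),
    z = z
  )
}

#' Decay of enriched-term counts under random essential-gene removal
#'
#' For each class of essential genes, repeatedly removes a random subset of
#' a given size from the class's hit set, recounts terms enriched at
#' p < `p_cutoff`, and averages over replicates. Removing the class whose
#' genes dominate term annotations erodes enrichment faster.
#'
#' @param ann Annotation tibble with `term` and `gene` columns.
#' @param egs_by_class Named list of character vectors, hit genes per class.
#' @param universe Character vector of background genes.
#' @param n_remove_grid Integer vector of removal sizes (each must not
#'   exceed the class size).
#' @param n_rep Replicates per removal size (default 20).
#' @param seed Integer seed.
#' @param p_cutoff Enrichment cutoff (default 0.05).
#' @return A tibble with `class`, `n_removed`, `mean_enriched_terms`.
#' @export
enriched_term_removal_curve <- function(ann, egs_by_class, universe,
                                        n_remove_grid, n_rep = 20, seed = 1,
                                        p_cutoff = 0.05) {
  set.seed(seed)
  purrr::imap_dfr(egs_by_class, function(genes, cl) {
    genes <- unique(genes)
    if (any(n_remove_grid > length(genes))) {
      stop("removal size exceeds class size for class ", cl)
    }
    purrr::map_dfr(n_remove_grid, function(r) {
      counts <- vapply(seq_len(n_rep), function(rep) {
        keep <- if (r > 0) sample(genes, length(genes) - r) else genes
        if (length(keep) == 0L) return(0L)
        enr <- term_enrichment(ann, keep, universe)
        sum(enr$p < p_cutoff)
      }, integer(1))
      tibble::tibble(
        class = cl, n_removed = r,
        mean_enriched_terms = mean(counts)
      )
    })
  })
}
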