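#' Degree-sequence-preserved randomization
#'
#' Rewires a graph by attempted double-edge swaps (the standard configuration
#' null model), rejecting any swap that would create a self-loop or multi-edge,
#' so the output is simple and every node keeps its exact degree.
#'
#' @param net An undirected simple `igraph` graph.
#' @param seed Integer seed; `NULL` uses the current RNG state (callers that
#'   loop over replicates seed once outside).
#' @param n_swap_multiplier Attempted swaps as a multiple of the edge count
#'   (default 10).
#' @return A rewired `igraph` graph with the same vertices and degree sequence.
#' @export
degree_preserved_randomize <- function(net, seed = NULL, n_swap_multiplier = 10) {
  if (!is.null(seed)) set.seed(seed)
  m <- igraph::ecount(net)
  if (m < 2L) return(net)
  igraph::rewire(net, igraph::keeping_degseq(niter = n_swap_multiplier * m))
}

#' Excess clustering relative to a degree-preserved null
#'
#' Per-node excess clustering dC_i = C_i(observed) - mean over `n_random`
#' degree-preserved randomizations of C_i, and the network-level value as the
#' unweighted mean of dC_i over nodes. The spread of the null replicate means
#' is returned so callers can form significance bands.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param n_random Number of null randomizations (default 100).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `per_node` (named vector of dC_i), `network` (mean
#'   dC), `null_sd` (sd over null replicates of the network mean C), and
#'   `n_random`.
#' @export
excess_clustering <- function(net, n_random = 100, seed = NULL) {
  stopifnot(n_random >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- node_clustering(net)
  null_sum <- numeric(length(obs))
  null_means <- numeric(n_random)
  for (r in seq_len(n_random)) {
    cr <- node_clustering(degree_preserved_randomize(net))
    null_sum <- null_sum + cr
    null_means[r] <- mean(cr)
  }
  per_node <- obs - null_sum / n_random
  list(
    per_node = per_node,
    network = mean(per_node),
    null_sd = stats::sd(null_means),
    n_random = n_random
  )
}

#' Pruning curve of excess clustering under progressive node removal
#'
#' Removes nodes progressively, in the given ranked order, in steps of
#' `step` of the total population, and recomputes network excess clustering
#' dC on the surviving graph at each removal fraction f in
#' \{0, step, ..., 0.95\}. Nulls are regenerated for each pruned graph so the
#' null stays degree-matched after removals.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param order Character vector of all node names, ranked in removal order
#'   (descending by the chosen measure; see [rank_nodes()]).
#' @param step Removal fraction step; must divide 0.95 evenly (default 0.05).
#' @param n_random Null randomizations per step.
#' @param seed Integer seed.
#' @return A tibble of class `pruning_curve` with columns `f`, `delta_c`,
#'   `sigma` (null spread at that step) and `n_nodes`.
#' @export
pruning_curve <- function(net, order, step = 0.05, n_random = 100, seed = 1) {
  n <- igraph::vcount(net)
  if (!setequal(order, igraph::V(net)$name) || length(order) != n) {
    stop("`order` must rank every node of the network exactly once")
  }
  if (abs(0.95 / step - round(0.95 / step)) > 1e-9) {
    stop("`step` must divide 0.95 evenly")
  }
  fs <- seq(0, 0.95, by = step)
  set.seed(seed)
  rows <- purrr::map_dfr(fs, function(f) {
    n_remove <- floor(f * n)
    g <- if (n_remove > 0) {
      igraph::delete_vertices(net, order[seq_len(n_remove)])
    } else {
      net
    }
    ex <- excess_clustering(g, n_random = n_random)
    tibble::tibble(
      f = f, delta_c = ex$network, sigma = ex$null_sd,
      n_nodes = igraph::vcount(g)
    )
  })
  class(rows) <- c("pruning_curve", class(rows))
  rows
}

#' Rank nodes for pruning by a topology measure
#'
#' Descending order of the measure, ties broken by node identifier so runs
#' are reproducible; `measure = "random"` gives a seeded random order.
#'
#' @param table A `topology_table` from [compute_table()].
#' @param measure Column of `table` to rank by, or `"random"`.
#' @param seed Seed used only for `measure = "random"`.
#' @return Character vector of node names in removal order.
#' @export
rank_nodes <- function(table, measure, seed = 1) {
  if (identical(measure, "random")) {
    set.seed(seed)
    return(sample(table$node))
  }
  if (!measure %in% names(table)) stop("unknown measure: ", measure)
  table$node[order(-table[[measure]], table$node)]
}

#' Reference band of random-pruning curves
#'
#' Averages pruning curves over several seeded random removal orders; the
#' returned `sigma` is the between-order standard deviation of dC at each
#' removal fraction, from which a +/- 3 sigma band can be drawn.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param n_orders Number of random orderings (default 20).
#' @param step,n_random,seed As in [pruning_curve()].
#' @return A tibble of class `pruning_curve` with columns `f`, `delta_c`
#'   (mean over orders), `sigma` and `n_nodes`.
#' @export
random_pruning_band <- function(net, n_orders = 20, step = 0.05,
                                n_random = 100, seed = 1) {
  nodes <- igraph::V(net)$name
  curves <- purrr::map(seq_len(n_orders), function(i) {
    set.seed(seed + i)
    ord <- sample(nodes)
    pruning_curve(net, ord, step = step, n_random = n_random, seed = seed + i)
  })
  all <- dplyr::bind_rows(curves, .id = "order")
  band <- all |>
    dplyr::group_by(.data$f) |>
    dplyr::summarise(
      sigma = stats::sd(.data$delta_c),
      delta_c = mean(.data$delta_c),
      n_nodes = .data$n_nodes[1],
      .groups = "drop"
    ) |>
    dplyr::select("f", "delta_c", "sigma", "n_nodes")
  class(band) <- c("pruning_curve", class(band))
  band
}

#' Area between a pruning curve and the random-pruning reference
#'
#' Linearly interpolates both curves onto the union of their f-grids and
#' returns the trapezoidal integral of (random - curve) over f in [0, 0.95].
#' Positive areas mean excess clustering decayed faster than under random
#' removal; a curve lying above the random reference gives a negative area.
#'
#' @param curve,random_curve Tibbles with `f` and `delta_c` columns spanning
#'   f in [0, 0.95].
#' @return The signed area, a single number.
#' @export
area_vs_random <- function(curve, random_curve) {
  if (nrow(curve) == 0L || nrow(random_curve) == 0L) stop("empty curve")
  for (cv in list(curve, random_curve)) {
    if (min(cv$f) > 0 || max(cv$f) < 0.95) {
      stop("curves must span f in [0, 0.95]")
    }
  }
  grid <- sort(unique(c(curve$f, random_curve$f)))
  grid <- grid[grid >= 0 & grid <= 0.95]
  yc <- stats::approx(curve$f, curve$delta_c, xout = grid)$y
  yr <- stats::approx(random_curve$f, random_curve$delta_c, xout = grid)$y
  diff_y <- yr - yc
  sum((diff_y[-1] + diff_y[-length(diff_y)]) / 2 * diff(grid))
}
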