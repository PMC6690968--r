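#' Binned correlation between a topology measure and the fraction of
#' essential genes
#'
#' Labeled nodes are sorted in increasing order of the measure (ties broken
#' by node identifier for determinism) and filled greedily into rank-ordered
#' bins of at least `ceiling(bin_frac * N)` nodes; leftover nodes that cannot
#' fill a final bin are absorbed into the last one. Pearson's R is then
#' computed between the per-bin mean measure value and the per-bin fraction
#' of essential genes f_E, with a two-sided t-approximation p-value on the
#' number of bins.
#'
#' @param values Named numeric vector of a topology measure (names = nodes).
#' @param labels Label tibble with columns `node` and `essential`.
#' @param bin_frac Minimum bin size as a fraction of the labeled population
#'   (default 0.02, i.e. bins of at least 2\%).
#' @return An object of class `binned_correlation`: a list with `bins` (a
#'   tibble with `bin`, `mean_value`, `f_E`, `n`), `R`, `p_value`, `n_bins`
#'   and `n_nodes`.
#' @export
binned_correlation <- function(values, labels, bin_frac = 0.02) {
  stopifnot(all(c("node", "essential") %in% names(labels)))
  labels <- labels[labels$node %in% names(values), ]
  v <- values[labels$node]
  if (length(v) < 2L) stop("need at least 2 labeled nodes")
  if (length(unique(v)) == 1L) stop("all measure values identical: zero variance")
  ord <- order(v, labels$node)
  v <- as.numeric(v[ord])
  ess <- labels$essential[ord]
  n <- length(v)
  target <- ceiling(bin_frac * n)
  n_full <- n %/% target
  if (n_full < 2L) stop("fewer than 2 bins possible at this bin fraction")
  # greedy fill: full bins of `target`; leftovers absorbed by the last bin
  bin <- pmin((seq_len(n) - 1L) %/% target + 1L, n_full)
  bins <- tibble::tibble(bin = bin, value = v, essential = ess) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_value = mean(.data$value),
      f_E = mean(.data$essential),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (nrow(bins) >= 3) {
    ct <- stats::cor.test(bins$mean_value, bins$f_E, method = "pearson")
    r <- unname(ct$estimate)
    pv <- ct$p.value
  } else {
    # two bins determine R but leave no degrees of freedom for a p-value
    r <- stats::cor(bins$mean_value, bins$f_E)
    pv <- NA_real_
  }
  structure(
    list(
      bins = bins,
      R = r,
      p_value = pv,
      n_bins = nrow(bins),
      n_nodes = n
    ),
    class = "binned_correlation"
  )
}

#' @export
print.binned_correlation <- function(x, ...) {
  stars <- if (is.na(x$p_value)) {
    ""
  } else if (x$p_value < 0.001) "**" else if (x$p_value < 0.05) "*" else ""
  cat(
    "Binned measure-essentiality correlation\n",
    "  bins: ", x$n_bins, " (", x$n_nodes, " labeled nodes)\n",
    "  Pearson R = ", format(x$R, digits = 4),
    ", p = ", format(x$p_value, digits = 3), " ", stars, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.binned_correlation <- function(x, ...) x$bins

#' @export
glance.binned_correlation <- function(x, ...) {
  tibble::tibble(
    R = x$R, p_value = x$p_value,
    n_bins = x$n_bins, n_nodes = x$n_nodes
  )
}

#' Principal component analysis of topology measures over essential genes
#'
#' Restricts a topology table to essential genes, standardizes each measure
#' to zero mean and unit variance, and runs a PCA. Constant measures are
#' dropped with a warning. The returned loadings expose whether the mean
#' link-clustering aggregates point orthogonally to the centrality measures.
#'
#' @param table A `topology_table` from [compute_table()].
#' @param labels Label tibble with `node` and `essential` columns.
#' @param measures Character vector of measure columns to include.
#' @return A list with `loadings` (variables x components matrix),
#'   `explained` (variance fractions), `n_genes`, and the `prcomp` fit.
#' @export
pca_over_egs <- function(table, labels,
                         measures = c(
                           "C", "muCXC", "muLCC", "muECC",
                           "sumCXC", "sumLCC", "sumECC",
                           "DC", "BC", "CC", "EC"
                         )) {
  eg <- labels$node[labels$essential]
  if (length(eg) < 3L) stop("need at least 3 essential genes for PCA")
  x <- as.matrix(table[table$node %in% eg, measures, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(
      "dropping constant measure(s): ",
      paste(colnames(x)[sds == 0], collapse = ", ")
    )
    x <- x[, sds > 0, drop = FALSE]
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  list(
    loadings = fit$rotation,
    explained = stats::setNames(expl, colnames(fit$rotation)),
    n_genes = nrow(x),
    fit = fit
  )
}

#' Angle between two families of PCA loading vectors
#'
#' Mean loading vector of each measure family (in the first `n_components`
#' components), and the angle between them in degrees. Near 90 degrees means
#' the families capture orthogonal structure.
#'
#' @param pca Result of [pca_over_egs()].
#' @param family_a,family_b Character vectors of measure names.
#' @param n_components Number of leading components to use (default 2).
#' @return Angle in degrees, a single number.
#' @export
loading_family_angle <- function(pca, family_a, family_b, n_components = 2) {
  l <- pca$loadings[, seq_len(n_components), drop = FALSE]
  a <- colMeans(l[rownames(l) %in% family_a, , drop = FALSE])
  b <- colMeans(l[rownames(l) %in% family_b, , drop = FALSE])
  cosang <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Robustness of k and w essentiality signals to link subsampling
#'
#' Repeatedly removes a fraction of edges uniformly at random, recomputes
#' degree k and the link-clustering score w = muCXC on the subsampled graph,
#' and re-evaluates the binned essentiality correlations. Mirrors the check
#' that both signals survive network incompleteness.
#'
#' @param net An undirected simple `igraph` graph with named vertices.
#' @param labels Label tibble with `node` and `essential` columns.
#' @param remove_frac Fraction of edges removed per replicate (in [0, 1)).
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @param bin_frac Bin fraction passed to [binned_correlation()].
#' @return A tibble with one row per replicate: `rep`, `R_k`, `R_w`,
#'   `cor_k_w` (Pearson correlation between k and w over nodes).
#' @export
link_subsample_robustness <- function(net, labels, remove_frac = 0.5,
                                      n_rep = 100, seed = 1, bin_frac = 0.02) {
  if (remove_frac >= 1) stop("remove_frac must be < 1")
  stopifnot(n_rep >= 1)
  m <- igraph::ecount(net)
  n_remove <- floor(remove_frac * m)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_rep), function(r) {
    g <- if (n_remove > 0) {
      igraph::delete_edges(net, sample.int(m, n_remove))
    } else {
      net
    }
    k <- centrality(g, "DC")
    w <- aggregate_edge_measure(g, edge_measure(g, "CXC"), "mean")
    lab <- labels[labels$node %in% names(k), ]
    tibble::tibble(
      rep = r,
      R_k = binned_correlation(k, lab, bin_frac)$R,
      R_w = binned_correlation(w, lab, bin_frac)$R,
      cor_k_w = stats::cor(as.numeric(k), as.numeric(w[names(k)]))
    )
  })
}
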