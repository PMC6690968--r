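#' Specification for the synthetic benchmark generator
#'
#' Bundles every parameter of the planted benchmark: a degree-heterogeneous
#' core grown by preferential attachment (triangle-poor, so hubs have high
#' degree k but low link clustering w) decorated with small near-clique
#' modules (triangle-rich, so members have high w but modest k) — the
#' minimal mechanism that makes k and w uncorrelated. Essentiality is
#' planted on both hubs (probability increasing with core degree) and
#' module members (a fixed fraction per module); annotations align one term
#' per module plus broad core-spanning terms; the fitness matrix scores
#' hub-EGs below the fitness cutoff in most conditions and module-EGs in
#' few, encoding broad versus contextual essentiality.
#'
#' @param seed Integer seed; the whole generation is deterministic given it.
#' @param n_core Core (preferential-attachment) nodes.
#' @param attach_probs Probabilities that a newly attached core node brings
#'   1, 2 or 3 edges (heavy-tailed degree sequence with many degree-1
#'   partners, as in curated interactomes).
#' @param core_closure Triadic-closure intensity of the core: wedge-closing
#'   edge additions attempted, as a fraction of the core edge count
#'   (Holme-Kim-style). Closure gives the core the local clustering of real
#'   interactomes; because a node's clustering coefficient falls
#'   quadratically with its degree, hub link-clustering scores stay low.
#' @param closure_bias Exponent of the degree bias when choosing wedge
#'   centres for closure; values above 1 concentrate neighbourhood
#'   interlinking around hubs, reproducing the dense complexes that
#'   surround highly connected proteins.
#' @param n_modules Number of planted modules.
#' @param module_size Nodes per module (must be >= 3).
#' @param module_p Internal edge probability within a module.
#' @param attach_edges Attachment edges per module to the core (1 or 2,
#'   drawn uniformly from this vector).
#' @param hub_intercept,hub_slope Logistic model for core essentiality:
#'   P(essential) = plogis(hub_intercept + hub_slope * degree).
#' @param module_eg_frac Fraction of each module's members that are
#'   essential.
#' @param noise_rate Probability that a remaining (non-planted) node is
#'   labeled essential anyway (label noise; its planted truth stays non-EG).
#' @param n_conditions Columns (cell lines) of the fitness matrix.
#' @param hub_in_frac,module_in_frac Probability per condition that a hub-EG
#'   (resp. module-EG) is essential in that condition.
#' @param effect_mean,effect_sd Normal fitness effect in essential-in cells
#'   (others are N(0, effect_sd^2)).
#' @param contamination Contaminating genes added to each module term, as a
#'   fraction of the module size.
#' @param n_broad_terms,broad_term_size Broad annotation terms covering
#'   random slices of the core.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1,
                           n_core = 520, attach_probs = c(0.5, 0.3, 0.2),
                           core_closure = 1.5, closure_bias = 3,
                           n_modules = 10, module_size = 6, module_p = 0.9,
                           attach_edges = c(1, 2),
                           hub_intercept = -6, hub_slope = 0.5,
                           module_eg_frac = 0.7,
                           noise_rate = 0.02,
                           n_conditions = 100,
                           hub_in_frac = 0.8, module_in_frac = 0.1,
                           effect_mean = -0.6, effect_sd = 0.1,
                           contamination = 0.1,
                           n_broad_terms = 10, broad_term_size = 30) {
  if (module_size < 3) stop("module_size must be at least 3")
  stopifnot(
    n_core > 0, n_modules > 0, module_p > 0, module_p <= 1,
    n_conditions > 0, effect_sd > 0
  )
  structure(
    list(
      seed = seed, n_core = n_core, attach_probs = attach_probs,
      core_closure = core_closure, closure_bias = closure_bias,
      n_modules = n_modules, module_size = module_size, module_p = module_p,
      attach_edges = attach_edges,
      hub_intercept = hub_intercept, hub_slope = hub_slope,
      module_eg_frac = module_eg_frac, noise_rate = noise_rate,
      n_conditions = n_conditions,
      hub_in_frac = hub_in_frac, module_in_frac = module_in_frac,
      effect_mean = effect_mean, effect_sd = effect_sd,
      contamination = contamination,
      n_broad_terms = n_broad_terms, broad_term_size = broad_term_size
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic benchmark data set
#'
#' Deterministically (given `spec$seed`) generates a planted network,
#' essentiality labels, a planted-truth table, a term annotation set and a
#' gene-by-condition fitness matrix, per the rules of [synthetic_spec()].
#'
#' @param spec A `synthetic_spec`.
#' @return A list with elements `network` (igraph), `labels` (tibble
#'   `node`/`essential`), `truth` (tibble `node`/`truth` in \{hub-EG,
#'   module-EG, non-EG\}), `annotation` (tibble `term`/`gene`), `fitness`
#'   (matrix), `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)

  # --- degree-heterogeneous core: preferential attachment with a
  # heavy-tailed stub sequence, then hub-biased triadic closure ---
  stubs <- sample(seq_along(spec$attach_probs), spec$n_core,
    replace = TRUE, prob = spec$attach_probs
  )
  stubs[1] <- 0
  core <- igraph::sample_pa(spec$n_core,
    out.seq = stubs, directed = FALSE,
    algorithm = "psumtree"
  )
  core_names <- sprintf("core%03d", seq_len(spec$n_core))
  core_el <- igraph::as_edgelist(core, names = FALSE)
  # wedge closure centred (with degree bias) on hubs: interlinks hub
  # neighbourhoods into dense complexes while each hub's own clustering
  # coefficient stays small (C falls as ~2T/k^2)
  n_close <- floor(spec$core_closure * nrow(core_el))
  closed <- matrix(integer(0), 0, 2)
  if (n_close > 0) {
    adj <- igraph::as_adj_list(core)
    deg <- igraph::degree(core)
    eligible <- which(deg >= 2)
    centers <- sample(eligible, n_close,
      replace = TRUE, prob = deg[eligible]^spec$closure_bias
    )
    closed <- t(vapply(centers, function(u) {
      sort(sample(as.integer(adj[[u]]), 2))
    }, integer(2)))
  }
  edges_from <- core_names[c(core_el[, 1], closed[, 1])]
  edges_to <- core_names[c(core_el[, 2], closed[, 2])]

  # --- near-clique modules (triangle-rich), attached by 1-2 bridge edges ---
  module_members <- list()
  for (mi in seq_len(spec$n_modules)) {
    members <- sprintf("m%02d_%d", mi, seq_len(spec$module_size))
    module_members[[mi]] <- members
    pairs <- utils::combn(members, 2)
    keep <- stats::runif(ncol(pairs)) < spec$module_p
    # keep each module connected: force a spanning path if sampling was thin
    path_pairs <- cbind(members[-length(members)], members[-1])
    edges_from <- c(edges_from, pairs[1, keep], path_pairs[, 1])
    edges_to <- c(edges_to, pairs[2, keep], path_pairs[, 2])
    n_attach <- sample(spec$attach_edges, 1)
    anchors <- sample(core_names, n_attach)
    edges_from <- c(edges_from, sample(members, n_attach, replace = TRUE))
    edges_to <- c(edges_to, anchors)
  }
  net <- suppressMessages(graph_from_edges(edges_from, edges_to))

  # --- planted truth and labels ---
  core_deg <- igraph::degree(net, v = core_names)
  p_core <- stats::plogis(spec$hub_intercept + spec$hub_slope * core_deg)
  core_ess <- stats::runif(spec$n_core) < p_core
  mod_nodes <- unlist(module_members)
  mod_ess_list <- lapply(module_members, function(members) {
    n_eg <- round(spec$module_eg_frac * length(members))
    members[sample.int(length(members), n_eg)]
  })
  mod_ess <- mod_nodes %in% unlist(mod_ess_list)
  truth <- tibble::tibble(
    node = c(core_names, mod_nodes),
    truth = c(
      ifelse(core_ess, "hub-EG", "non-EG"),
      ifelse(mod_ess, "module-EG", "non-EG")
    )
  )
  essential <- truth$truth != "non-EG"
  noise <- !essential & stats::runif(nrow(truth)) < spec$noise_rate
  labels <- tibble::tibble(node = truth$node, essential = essential | noise)

  # --- annotations: one term per module + broad core terms ---
  ann <- purrr::imap_dfr(module_members, function(members, mi) {
    n_cont <- floor(spec$contamination * length(members))
    extra <- if (n_cont > 0) sample(setdiff(truth$node, members), n_cont) else character()
    tibble::tibble(term = sprintf("MOD%02d", mi), gene = c(members, extra))
  })
  broad <- purrr::map_dfr(seq_len(spec$n_broad_terms), function(bi) {
    tibble::tibble(
      term = sprintf("BROAD%02d", bi),
      gene = sample(core_names, min(spec$broad_term_size, spec$n_core))
    )
  })
  annotation <- dplyr::bind_rows(ann, broad)

  # --- fitness matrix ---
  genes <- truth$node
  in_frac <- c(
    "hub-EG" = spec$hub_in_frac,
    "module-EG" = spec$module_in_frac,
    "non-EG" = 0
  )[truth$truth]
  ess_in <- matrix(
    stats::runif(length(genes) * spec$n_conditions) < in_frac,
    nrow = length(genes)
  )
  fitness <- matrix(
    stats::rnorm(
      length(genes) * spec$n_conditions,
      mean = ifelse(ess_in, spec$effect_mean, 0),
      sd = spec$effect_sd
    ),
    nrow = length(genes),
    dimnames = list(genes, sprintf("cond%03d", seq_len(spec$n_conditions)))
  )

  list(
    network = net, labels = labels, truth = truth,
    annotation = annotation, fitness = fitness, spec = spec
  )
}

#' Provenance record of a synthetic specification
#'
#' Flat one-row tibble of every generator parameter (including the seed),
#' suitable for writing alongside generated outputs. Round-trips:
#' `describe_spec(do.call(synthetic_spec, as.list(describe_spec(spec))))`
#' reproduces the record (vector-valued fields are packed as
#' comma-separated strings in the record).
#'
#' @param spec A `synthetic_spec`.
#' @return A one-row tibble with one column per parameter.
#' @export
describe_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vals <- purrr::map(unclass(spec), function(v) {
    if (length(v) > 1) paste(v, collapse = ",") else v
  })
  tibble::as_tibble(vals)
}

#' Rebuild a synthetic specification from its provenance record
#'
#' @param record A one-row tibble from [describe_spec()].
#' @return A `synthetic_spec`.
#' @export
spec_from_record <- function(record) {
  args <- purrr::map(as.list(record), function(v) {
    if (is.character(v) && grepl(",", v)) as.numeric(strsplit(v, ",")[[1]]) else v
  })
  do.call(synthetic_spec, args)
}
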