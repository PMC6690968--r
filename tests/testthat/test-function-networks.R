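test_that("hypergeometric enrichment matches closed forms and the sum oracle", {
  universe <- sprintf("g%02d", 1:20)
  ann <- tibble::tibble(term = "T1", gene = universe[1:5])
  hits <- universe[1:5]
  enr <- term_enrichment(ann, hits, universe)
  expect_equal(enr$p, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap: upper tail at 0 is 1
  enr0 <- term_enrichment(ann, universe[6:10], universe)
  expect_equal(enr0$p, 1)

  # genes outside the universe are excluded before testing
  ann2 <- tibble::tibble(term = "T1", gene = c(universe[1:5], "alien"))
  enr2 <- term_enrichment(ann2, hits, universe)
  expect_equal(enr2$term_size, 5)

  expect_error(term_enrichment(ann, hits, character()), "universe")
  expect_error(term_enrichment(ann, "alien", universe), "subset")

  # exact combinatorial sum oracle over small parameter combos
  for (m in c(3, 5, 8)) {
    for (k in c(2, 6, 10)) {
      for (q in 0:min(m, k)) {
        got <- stats::phyper(q - 1, m, 30 - m, k, lower.tail = FALSE)
        expect_equal(got, oracle_hyper_upper(q, m, 30 - m, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("terms are tagged by recurrent enrichment across networks", {
  mk <- function(p_t1, p_t2) tibble::tibble(term = c("T1", "T2"), p = c(p_t1, p_t2))
  k_maps <- list(mk(0.01, 0.5), mk(0.02, 0.5), mk(0.03, 0.5), mk(0.9, 0.5))
  w_maps <- list(mk(0.9, 0.01), mk(0.9, 0.02), mk(0.9, 0.5), mk(0.9, 0.5))
  tags <- tag_terms(k_maps, w_maps, min_networks = 3)
  expect_equal(tags$tag[tags$term == "T1"], "k-function") # 3/4 k, 0/4 w
  expect_equal(tags$tag[tags$term == "T2"], "neither") # 2/4 w only

  # enrichment on both sides in enough networks -> both
  both_k <- list(mk(0.01, 0.01), mk(0.01, 0.01), mk(0.01, 0.01), mk(0.9, 0.9))
  tags2 <- tag_terms(both_k, both_k, min_networks = 3)
  expect_true(all(tags2$tag == "both"))

  expect_message(tag_terms(k_maps[1], w_maps[1], min_networks = 1), "single-network")
})

test_that("term networks link terms with improbably large overlaps", {
  universe <- sprintf("g%03d", 1:100)
  ann <- tibble::tibble(
    term = rep(c("A", "B", "C"), each = 5),
    gene = c(universe[1:5], universe[1:5], universe[50:54])
  )
  tn <- build_term_network(ann, universe, link_p_cutoff = 1e-5)
  el <- igraph::as_edgelist(tn$graph)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("A", "B")) # identical terms linked
  expect_equal(
    tn$overlaps$p[tn$overlaps$term1 == "A" & tn$overlaps$term2 == "B"],
    1 / choose(100, 5),
    tolerance = 1e-12
  )
  # disjoint terms unlinked, p = 1
  expect_equal(
    tn$overlaps$p[tn$overlaps$term2 == "C" & tn$overlaps$term1 == "A"], 1
  )
})

test_that("planted module terms form within-module overlap structure", {
  d <- generate_synthetic(synthetic_spec(seed = 5))
  universe <- unique(d$annotation$gene)
  tn <- build_term_network(d$annotation, universe)
  el <- igraph::as_edgelist(tn$graph)
  if (nrow(el) > 0) {
    mod_pairs <- el[grepl("^MOD", el[, 1]) & grepl("^MOD", el[, 2]), , drop = FALSE]
    # distinct planted modules are disjoint (plus light contamination), so
    # they must not be linked to each other
    expect_equal(nrow(mod_pairs), 0)
  }
  succeed()
})

test_that("link-category z-test flags assortative tag placement", {
  # two overlap cliques: k-terms among themselves, w-terms among themselves
  terms <- c(paste0("K", 1:5), paste0("W", 1:5))
  el <- rbind(
    t(utils::combn(paste0("K", 1:5), 2)),
    t(utils::combn(paste0("W", 1:5), 2))
  )
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  tags <- tibble::tibble(
    term = terms,
    is_k = startsWith(terms, "K"),
    is_w = startsWith(terms, "W")
  )
  z <- link_category_ztest(g, tags, n_shuffle = 2000, seed = 3)
  expect_gt(z$z[z$category == "k-k"], 2)
  expect_gt(z$z[z$category == "w-w"], 2)
  expect_lt(z$z[z$category == "k-w"], -2) # fully assortative: k-w depleted
  # observed counts don't depend on the shuffle seed
  z2 <- link_category_ztest(g, tags, n_shuffle = 100, seed = 99)
  expect_equal(z2$observed, z$observed)

  # degenerate: all tags identical leaves the null with zero spread
  tags_k <- tibble::tibble(term = terms, is_k = TRUE, is_w = FALSE)
  expect_error(link_category_ztest(g, tags_k, n_shuffle = 10, seed = 1), "w-function")
  tags_k$is_w[1] <- TRUE
  zz <- link_category_ztest(g, tags_k, n_shuffle = 50, seed = 1)
  expect_true(is.na(zz$z[zz$category == "k-k"]))
  expect_match(zz$note[zz$category == "k-k"], "zero")
})

test_that("z-test is calibrated under random tag placement", {
  set.seed(41)
  terms <- sprintf("T%02d", 1:40)
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- terms
  n_ok <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    is_k <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    tags <- tibble::tibble(term = terms, is_k = is_k, is_w = !is_k)
    z <- link_category_ztest(g, tags, n_shuffle = 200, seed = r)
    if (all(abs(z$z) < 2, na.rm = TRUE)) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 80)
})

test_that("clique enumeration matches brute force and bias fractions add up", {
  # K4 holds four 3-cliques and one 4-clique
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(length(igraph::cliques(k4, min = 3, max = 3)), 4)
  expect_equal(length(igraph::cliques(k4, min = 4, max = 4)), 1)

  set.seed(19)
  for (i in 1:50) {
    g <- random_small_graph(sample(6:15, 1), stats::runif(1, 0.3, 0.7))
    for (n in 3:4) {
      got <- igraph::cliques(g, min = n, max = n)
      want <- oracle_cliques(g, n)
      got_sets <- sort(vapply(
        got, function(cl) paste(sort(igraph::V(g)$name[as.integer(cl)]), collapse = "+"),
        character(1)
      ))
      want_sets <- sort(vapply(want, paste, character(1), collapse = "+"))
      expect_equal(got_sets, want_sets)
    }
  }
})

test_that("clique bias separates a hub-clustered class", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  classes <- structure(
    list(nodes = tibble::tibble(
      node = c("a", "b", "c"),
      class = factor(c("k-dependent", "k-dependent", "non-EG"),
        levels = c("k-dependent", "w-dependent", "unclassified-EG", "non-EG")
      )
    )),
    class = "eg_classification"
  )
  cb <- clique_bias(k3, classes, n = 3)
  expect_equal(cb$n_cliques, 1)
  expect_equal(cb$frac_k_biased, 1)
  expect_equal(cb$frac_w_biased, 0)

  expect_error(
    clique_bias(igraph::make_star(5, mode = "undirected"), classes, n = 3),
    "cliques"
  )

  # planted network: triangle-rich hub cores put k-dependent genes in cliques
  d <- generate_synthetic(synthetic_spec(seed = 1))
  tab <- compute_table(d$network)
  cl <- suppressWarnings(classify_egs(tab, d$labels))
  cb3 <- clique_bias(d$network, cl, n = 3)
  expect_equal(cb3$frac_k_biased + cb3$frac_w_biased + cb3$frac_tied, 1)
  expect_gt(cb3$n_cliques, 0)
})

test_that("random essential-gene removal erodes enriched-term counts", {
  d <- generate_synthetic(synthetic_spec(seed = 2))
  universe <- unique(d$annotation$gene)
  mod_egs <- intersect(
    d$truth$node[d$truth$truth == "module-EG"], universe
  )
  hub_egs <- intersect(
    d$truth$node[d$truth$truth == "hub-EG"], universe
  )
  base <- term_enrichment(d$annotation, mod_egs, universe)
  n_base <- sum(base$p < 0.05)
  curve <- enriched_term_removal_curve(
    d$annotation,
    list(module = mod_egs),
    universe,
    n_remove_grid = c(0, length(mod_egs)),
    n_rep = 3, seed = 6
  )
  expect_equal(curve$mean_enriched_terms[curve$n_removed == 0], n_base)
  expect_equal(curve$mean_enriched_terms[curve$n_removed == length(mod_egs)], 0)
  expect_error(enriched_term_removal_curve(
    d$annotation, list(hub = hub_egs), universe,
    n_remove_grid = length(hub_egs) + 1
  ), "exceeds")
})
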