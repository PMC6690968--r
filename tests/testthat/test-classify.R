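test_that("constant predictor gives leave-one-out probabilities at prevalence", {
  nodes <- sprintf("g%02d", 1:20)
  values <- stats::setNames(rep(2.5, 20), nodes)
  labels <- make_labels(nodes, nodes[1:7])
  p <- loo_essentiality_prob(values, labels)
  # held-out prevalence is 7/19 or 6/19 depending on the left-out label
  expect_equal(unname(p[nodes[1]]), 6 / 19, tolerance = 1e-6)
  expect_equal(unname(p[nodes[10]]), 7 / 19, tolerance = 1e-6)
})

test_that("penalized fit handles separable data monotonically and flags it", {
  nodes <- sprintf("g%03d", 1:100)
  values <- stats::setNames(as.numeric(1:100), nodes)
  labels <- make_labels(nodes, nodes[values > 50])
  expect_warning(p <- loo_essentiality_prob(values, labels), "separation")
  ord <- order(values)
  expect_true(all(diff(p[ord]) >= -1e-8))
  expect_lt(p[["g001"]], 0.1)
  expect_gt(p[["g100"]], 0.9)
})

test_that("sign-flipping the predictor leaves probabilities unchanged", {
  set.seed(13)
  nodes <- sprintf("g%03d", 1:80)
  values <- stats::setNames(stats::rnorm(80), nodes)
  labels <- make_labels(nodes, sample(nodes, 30))
  p1 <- loo_essentiality_prob(values, labels)
  p2 <- loo_essentiality_prob(-values, labels)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("penalized fit agrees with glm when data are not separable", {
  set.seed(29)
  n <- 200
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(0.3 + 0.8 * x))
  fit <- linkess:::logistic_fit1(x, y)
  p_ours <- linkess:::logistic_predict1(fit, x)
  p_glm <- stats::predict(
    stats::glm(y ~ x, family = stats::binomial()),
    type = "response"
  )
  expect_lt(max(abs(p_ours - unname(p_glm))), 1e-4)
})

test_that("MCC cutoff scan finds perfect separations and matches brute force", {
  nodes <- letters[1:5]
  values <- stats::setNames(1:5, nodes)
  labels <- make_labels(nodes, c("c", "d", "e"))
  res <- mcc_optimal_cutoff(values, labels)
  expect_gt(res$cutoff, 2)
  expect_lte(res$cutoff, 3)
  expect_equal(res$mcc, 1)

  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    nd <- sprintf("g%02d", 1:n)
    v <- stats::setNames(sample(1:10, n, replace = TRUE), nd)
    ess <- sample(nd, sample(1:(n - 1), 1))
    lab <- make_labels(nd, ess)
    got <- mcc_optimal_cutoff(v, lab)
    want <- oracle_mcc_cutoff(as.numeric(v), nd %in% ess)
    expect_equal(got$mcc, want, tolerance = 1e-12)
  }
})

test_that("MCC under label shuffles stays near zero", {
  set.seed(23)
  nodes <- sprintf("g%03d", 1:500)
  values <- stats::setNames(stats::rnorm(500), nodes)
  labels <- make_labels(nodes, sample(nodes, 200))
  res <- mcc_optimal_cutoff(values, labels)
  expect_lt(abs(res$mcc), 0.2)
})

test_that("classification partitions labeled nodes with coherent classes", {
  d <- generate_synthetic(synthetic_spec(seed = 1))
  tab <- compute_table(d$network)
  cl <- suppressWarnings(classify_egs(tab, d$labels))
  nodes <- cl$nodes
  # partition: every labeled node in exactly one class
  expect_equal(nrow(nodes), nrow(d$labels))
  expect_false(any(is.na(nodes$class)))
  # only essential nodes get EG classes
  expect_true(all(nodes$class[!nodes$essential] == "non-EG"))
  eg_classes <- c("k-dependent", "w-dependent", "unclassified-EG")
  expect_true(all(nodes$class[nodes$essential] %in% eg_classes))
  # fractions over EGs sum to one
  gl <- glance(cl)
  expect_equal(
    gl$frac_k_dependent + gl$frac_w_dependent + gl$frac_unclassified, 1
  )
  # under-both-cutoffs EGs are exactly the unclassified ones with low k and w,
  # and classified EGs follow the probability comparison
  eg <- nodes[nodes$essential, ]
  under <- eg$k < cl$k_c & eg$w < cl$w_c
  expect_true(all(eg$class[under] == "unclassified-EG"))
  kdep <- eg$class == "k-dependent"
  expect_true(all(eg$P_E_k[kdep] > eg$P_E_w[kdep]))
  wdep <- eg$class == "w-dependent"
  expect_true(all(eg$P_E_w[wdep] > eg$P_E_k[wdep]))
})

test_that("exchangeable EGs all land in the same class", {
  # all EGs share one k and one w value: classes must agree
  nodes <- sprintf("g%02d", 1:40)
  tab <- tibble::tibble(
    node = nodes,
    k = c(rep(5, 20), rep(1, 20)),
    w = c(rep(0.2, 20), rep(0.8, 20))
  )
  labels <- make_labels(nodes, nodes[1:20])
  cl <- suppressWarnings(classify_egs(tab, labels))
  eg_classes <- cl$nodes$class[cl$nodes$essential]
  expect_equal(length(unique(as.character(eg_classes))), 1)
})

test_that("planted hub and module essential genes are recovered", {
  d <- generate_synthetic(synthetic_spec(seed = 1))
  tab <- compute_table(d$network)
  cl <- suppressWarnings(classify_egs(tab, d$labels))
  j <- dplyr::inner_join(cl$nodes, d$truth, by = "node")
  hub_rec <- mean(j$class[j$truth == "hub-EG"] == "k-dependent")
  mod_rec <- mean(j$class[j$truth == "module-EG"] == "w-dependent")
  expect_gt(hub_rec, 0.7)
  expect_gt(mod_rec, 0.7)
  # the Fig-3B-style topology contrast between the classes
  kdep <- j[j$class == "k-dependent", ]
  wdep <- j[j$class == "w-dependent", ]
  expect_gt(stats::median(wdep$w), stats::median(kdep$w))
  expect_lt(stats::median(wdep$k), stats::median(kdep$k))
  mwu_w <- stats::wilcox.test(wdep$w, kdep$w, alternative = "greater", exact = FALSE)
  mwu_k <- stats::wilcox.test(wdep$k, kdep$k, alternative = "less", exact = FALSE)
  expect_lt(mwu_w$p.value, 0.05)
  expect_lt(mwu_k$p.value, 0.05)
})
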