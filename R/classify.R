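#' Penalized one-predictor logistic fit
#'
#' Newton (IRLS) solver for logit P(essential) = b0 + b1 * x with a small
#' fixed L2 penalty on the slope of the standardized predictor. The penalty
#' (lambda = 1e-4) only matters under perfect separation, where it keeps the
#' likelihood bounded; on non-separable data the fit is numerically
#' indistinguishable from an unpenalized `glm` (max probability difference
#' below 1e-4 on test fixtures).
#'
#' @param x Numeric predictor.
#' @param y 0/1 response (1 = essential).
#' @param lambda Ridge penalty on the standardized slope.
#' @param start Optional c(intercept, slope) warm start (standardized scale).
#' @return A list with `coef` (intercept, slope on the standardized scale),
#'   `center`, `scale` of the predictor, and `separable` flag.
#' @keywords internal
logistic_fit1 <- function(x, y, lambda = 1e-4, start = NULL) {
  mu <- mean(x)
  sc <- stats::sd(x)
  if (sc == 0) sc <- 1
  z <- (x - mu) / sc
  prev <- min(max(mean(y), 0.01), 0.99)
  beta <- if (is.null(start)) c(stats::qlogis(prev), 0) else start
  X <- cbind(1, z)
  pen <- diag(c(0, lambda))
  for (it in 1:50) {
    eta <- X %*% beta
    p <- stats::plogis(eta)
    wt <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(X, y - p) - pen %*% beta
    hess <- crossprod(X * as.numeric(wt), X) + pen
    delta <- solve(hess, grad)
    beta <- beta + delta
    if (max(abs(delta)) < 1e-10) break
  }
  list(
    coef = as.numeric(beta), center = mu, scale = sc,
    separable = abs(beta[2]) > 15
  )
}

logistic_predict1 <- function(fit, x) {
  z <- (x - fit$center) / fit$scale
  as.numeric(stats::plogis(fit$coef[1] + fit$coef[2] * z))
}

#' Leave-one-out logistic probability of essentiality
#'
#' For each labeled node, fits a one-predictor logistic regression of
#' essentiality (essential = 1, non-essential = 0) on all other labeled
#' nodes and evaluates the held-out node, giving an out-of-sample
#' probability of being essential, P_E. Perfectly separable fits fall back
#' on the small fixed ridge penalty of [logistic_fit1()] with a warning.
#'
#' @param values Named numeric vector of the predictor (names = nodes).
#' @param labels Label tibble with `node` and `essential` columns.
#' @return A named numeric vector of P_E, one per labeled node.
#' @export
loo_essentiality_prob <- function(values, labels) {
  labels <- labels[labels$node %in% names(values), ]
  x <- as.numeric(values[labels$node])
  y <- as.numeric(labels$essential)
  if (sum(y) < 2L || sum(1 - y) < 2L) {
    stop("need at least 2 nodes in each essentiality class")
  }
  full <- logistic_fit1(x, y)
  if (full$separable) {
    warning("near-perfect separation; probabilities come from the penalized fit")
  }
  n <- length(x)
  p_out <- numeric(n)
  for (i in seq_len(n)) {
    fit <- logistic_fit1(x[-i], y[-i], start = full$coef)
    p_out[i] <- logistic_predict1(fit, x[i])
  }
  stats::setNames(p_out, labels$node)
}

# Matthews correlation coefficient from confusion counts; 0 when undefined
mcc_from_counts <- function(tp, fp, fn, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  num <- tp * tn - fp * fn
  ifelse(den == 0, 0, num / den)
}

#' MCC-optimal essentiality cutoff for a topology measure
#'
#' Scans every candidate threshold (midpoints between consecutive distinct
#' sorted values, plus -Inf and +Inf), predicting "essential" for nodes with
#' measure value >= threshold, and returns the cutoff maximizing Matthews'
#' correlation coefficient. Ties go to the smallest cutoff; an empty
#' predicted class scores MCC = 0 so the scan is total.
#'
#' @param values Named numeric vector of the measure (names = nodes).
#' @param labels Label tibble with `node` and `essential` columns.
#' @return A list with `cutoff` and `mcc`.
#' @export
mcc_optimal_cutoff <- function(values, labels) {
  labels <- labels[labels$node %in% names(values), ]
  v <- as.numeric(values[labels$node])
  y <- labels$essential
  if (!any(y) || all(y)) stop("both essentiality classes must be present")
  sv <- sort(unique(v))
  cand <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  # cumulative counts over descending thresholds would also work; the
  # candidate set is small (<= distinct values + 1), so score directly
  mccs <- vapply(cand, function(ct) {
    pred <- v >= ct
    mcc_from_counts(
      tp = sum(pred & y), fp = sum(pred & !y),
      fn = sum(!pred & y), tn = sum(!pred & !y)
    )
  }, numeric(1))
  best <- which.max(mccs) # which.max takes the first (smallest) on ties
  list(cutoff = cand[best], mcc = mccs[best])
}

#' Classify essential genes as k-dependent or w-dependent
#'
#' The central classification: each labeled node gets leave-one-out logistic
#' probabilities of essentiality from degree (P_E(k), k = DC) and from the
#' link-clustering score (P_E(w), w = muCXC), and MCC-optimal cutoffs k_c and
#' w_c are fitted on each measure. Essential genes below both cutoffs are
#' explained by neither measure and stay `unclassified-EG`; the rest are
#' `k-dependent` if P_E(k) > P_E(w), `w-dependent` if P_E(k) < P_E(w), and
#' `unclassified-EG` on an exact tie. Non-essential genes are `non-EG`.
#'
#' @param table A `topology_table` from [compute_table()] covering all
#'   labeled nodes.
#' @param labels Label tibble with `node` and `essential` columns.
#' @return An object of class `eg_classification`: a list with `nodes` (a
#'   tibble with `node`, `k`, `w`, `P_E_k`, `P_E_w`, `essential`, `class`),
#'   `k_c`, `w_c`, `mcc_k`, `mcc_w`.
#' @export
classify_egs <- function(table, labels) {
  labels <- labels[labels$node %in% table$node, ]
  if (!all(labels$node %in% table$node)) {
    stop("topology table must cover all labeled nodes")
  }
  k <- stats::setNames(table$k, table$node)[labels$node]
  w <- stats::setNames(table$w, table$node)[labels$node]
  p_k <- loo_essentiality_prob(k, labels)
  p_w <- loo_essentiality_prob(w, labels)
  cut_k <- mcc_optimal_cutoff(k, labels)
  cut_w <- mcc_optimal_cutoff(w, labels)
  ess <- labels$essential
  under_both <- k < cut_k$cutoff & w < cut_w$cutoff
  cls <- dplyr::case_when(
    !ess ~ "non-EG",
    under_both ~ "unclassified-EG",
    p_k > p_w ~ "k-dependent",
    p_k < p_w ~ "w-dependent",
    TRUE ~ "unclassified-EG"
  )
  nodes <- tibble::tibble(
    node = labels$node,
    k = as.numeric(k), w = as.numeric(w),
    P_E_k = as.numeric(p_k), P_E_w = as.numeric(p_w),
    essential = ess,
    class = factor(cls, levels = c("k-dependent", "w-dependent", "unclassified-EG", "non-EG"))
  )
  structure(
    list(
      nodes = nodes,
      k_c = cut_k$cutoff, w_c = cut_w$cutoff,
      mcc_k = cut_k$mcc, mcc_w = cut_w$mcc
    ),
    class = "eg_classification"
  )
}

#' @export
print.eg_classification <- function(x, ...) {
  tab <- table(x$nodes$class)
  n_eg <- sum(x$nodes$essential)
  cat("Essential-gene classification (", nrow(x$nodes), " labeled nodes, ",
    n_eg, " EGs)\n",
    sep = ""
  )
  cat(sprintf(
    "  k-dependent: %d (%.1f%% of EGs)   w-dependent: %d (%.1f%%)   unclassified: %d (%.1f%%)\n",
    tab[["k-dependent"]], 100 * tab[["k-dependent"]] / n_eg,
    tab[["w-dependent"]], 100 * tab[["w-dependent"]] / n_eg,
    tab[["unclassified-EG"]], 100 * tab[["unclassified-EG"]] / n_eg
  ))
  cat(sprintf(
    "  cutoffs: k_c = %.4g (MCC %.3f), w_c = %.4g (MCC %.3f)\n",
    x$k_c, x$mcc_k, x$w_c, x$mcc_w
  ))
  invisible(x)
}

#' @export
tidy.eg_classification <- function(x, ...) x$nodes

#' @export
glance.eg_classification <- function(x, ...) {
  n_eg <- sum(x$nodes$essential)
  tab <- table(x$nodes$class)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_eg = n_eg,
    frac_k_dependent = tab[["k-dependent"]] / n_eg,
    frac_w_dependent = tab[["w-dependent"]] / n_eg,
    frac_unclassified = tab[["unclassified-EG"]] / n_eg,
    k_c = x$k_c, w_c = x$w_c,
    mcc_k = x$mcc_k, mcc_w = x$mcc_w
  )
}
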