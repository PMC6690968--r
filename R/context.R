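#' Broadness of contextual essentiality
#'
#' Per gene, the number of conditions (cell lines) in which the fitness
#' effect is at or below `threshold` (default -0.3, the conventional
#' fitness-loss cutoff for CRISPR screens). Missing cells are excluded from
#' the count; genes with all cells missing get a missing broadness (logged).
#'
#' @param fm Numeric gene-by-condition matrix (see [read_fitness_matrix()]).
#' @param threshold Fitness-effect cutoff (default -0.3).
#' @return A tibble with `gene`, `broadness` (integer, NA when the gene has
#'   no observed cells) and `n_conditions` (non-missing cells).
#' @export
broadness <- function(fm, threshold = -0.3) {
  stopifnot(is.matrix(fm), !is.null(rownames(fm)))
  n_obs <- rowSums(!is.na(fm))
  b <- rowSums(fm <= threshold, na.rm = TRUE)
  b[n_obs == 0L] <- NA_integer_
  if (any(n_obs == 0L)) {
    message(sum(n_obs == 0L), " gene(s) with no observed fitness values")
  }
  tibble::tibble(
    gene = rownames(fm),
    broadness = as.integer(b),
    n_conditions = as.integer(n_obs)
  )
}

#' Binned comparison of broadness between essential-gene classes
#'
#' Sorts k-dependent and w-dependent essential genes by broadness, cuts them
#' into `n_bins` bins of as-equal-as-possible population (genes tied on
#' broadness stay together, falling in the lower bin), and tests the
#' bin-by-class contingency table with Pearson's chi-squared. A low p with
#' w-dependent mass concentrated in low-broadness bins is the signature of
#' contextual essentiality.
#'
#' @param profile A tibble from [broadness()] (columns `gene`, `broadness`).
#' @param classes An `eg_classification` from [classify_egs()].
#' @param n_bins Number of bins (default 5).
#' @return A list with `table` (bin x class contingency matrix),
#'   `per_gene` (tibble of gene, class, broadness, bin), `chisq`
#'   (the `htest`), `statistic` and `p_value`.
#' @export
binned_group_comparison <- function(profile, classes, n_bins = 5) {
  cls <- classes$nodes[classes$nodes$class %in% c("k-dependent", "w-dependent"), ]
  df <- dplyr::inner_join(
    tibble::tibble(gene = cls$node, class = droplevels(cls$class)),
    profile[, c("gene", "broadness")],
    by = "gene"
  )
  df <- df[!is.na(df$broadness), ]
  if (dplyr::n_distinct(df$class) < 2L) {
    stop("need genes from both k-dependent and w-dependent classes")
  }
  df <- df[order(df$broadness, df$gene), ]
  n <- nrow(df)
  # quantile-style edges; tie groups stay together in the lower bin
  raw_bin <- pmin(floor((seq_len(n) - 1L) / (n / n_bins)) + 1L, n_bins)
  bin <- stats::ave(raw_bin, df$broadness, FUN = min)
  if (length(unique(bin)) < n_bins) {
    warning("ties collapsed some bins: ", length(unique(bin)),
      " distinct bins instead of ", n_bins)
  }
  df$bin <- as.integer(factor(bin)) # renumber 1..n_distinct
  tab <- table(bin = df$bin, class = df$class)
  cs <- suppressWarnings(stats::chisq.test(tab))
  list(
    table = tab,
    per_gene = tibble::as_tibble(df),
    chisq = cs,
    statistic = unname(cs$statistic),
    p_value = cs$p.value
  )
}
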