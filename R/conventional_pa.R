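#' Differentially abundant metabolites by per-metabolite t-tests
#'
#' Two-sided independent t-tests per metabolite between the two sample
#' groups, Benjamini-Hochberg corrected; metabolites significant at
#' `q <= q_threshold` form the differential set (the usual ORA input).
#'
#' @param matrix a `MetaboliteMatrix` (or numeric matrix, samples in rows).
#' @param labels optional two-level factor; defaults to the matrix's group
#'   labels.
#' @param q_threshold BH q-value cut-off, default 0.05.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return A list with `significant` (character vector of metabolite ids) and
#'   `table` (per-metabolite statistic, p and q).
#' @export
differential_metabolites <- function(matrix, labels = NULL, q_threshold = 0.05,
                                     var_equal = TRUE) {
  mm <- as_metabolite_matrix(matrix)
  labels <- labels %||% mm$groups
  if (is.null(labels)) stopf("no group labels supplied or attached to matrix")
  tt <- col_ttests(mm$values, labels, var_equal = var_equal)
  q <- p.adjust(tt$p_value, method = "BH")
  tab <- data.frame(metabolite_id = colnames(mm$values),
                    statistic = tt$statistic, p_value = tt$p_value, q_value = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(significant = tab$metabolite_id[!is.na(q) & q <= q_threshold],
       table = tab)
}

#' Over-representation analysis (Fisher's exact test)
#'
#' One-sided Fisher's exact test on the 2x2 membership table (in/out pathway
#' x in/out differential set) per pathway. Only pathways containing at least
#' one differentially abundant metabolite receive a p-value; BH correction
#' runs over the tested pathways only.
#'
#' @param da_set character vector of differentially abundant metabolite ids
#'   (must be a subset of `background`).
#' @param collection a coverage-filtered `PathwayCollection`.
#' @param background the metabolite universe; conventionally all measured
#'   metabolites annotated to at least one pathway.
#' @return A `data.frame` with `pathway_id`, `odds_ratio`, `p_value`,
#'   `q_value`; the number of tested pathways is attached as attribute
#'   `"n_tested"`.
#' @export
ora <- function(da_set, collection, background) {
  background <- unique(normalize_metabolite_ids(background))
  if (!length(background)) stopf("empty background set")
  da_set <- unique(normalize_metabolite_ids(da_set))
  if (length(setdiff(da_set, background)))
    stopf("`da_set` must be a subset of `background`")
  res <- lapply(names(collection$sets), function(id) {
    mem <- intersect(collection$sets[[id]], background)
    a <- length(intersect(mem, da_set))
    if (a < 1L) return(NULL)
    b <- length(da_set) - a                  # DA, outside pathway
    c_ <- length(mem) - a                    # not DA, in pathway
    d <- length(background) - a - b - c_     # not DA, outside pathway
    ft <- fisher.test(matrix(c(a, b, c_, d), 2L, 2L), alternative = "greater")
    data.frame(pathway_id = id, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(pathway_id = character(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
    attr(res, "n_tested") <- 0L
    return(res)
  }
  res$q_value <- p.adjust(res$p_value, method = "BH")
  attr(res, "n_tested") <- nrow(res)
  res
}

# ES walk for one ranking vector (conventional GSEA): metabolites ranked by
# `stat` descending, in-set weights |stat|^weight, signed max deviation.
gsea_es <- function(stat, idx_list, weight) {
  ordv <- order(stat, decreasing = TRUE)
  w <- abs(stat)^weight
  as.numeric(cpp_es_walk(matrix(ordv, nrow = 1L), matrix(w, nrow = 1L),
                         idx_list, 2L))
}

#' Conventional GSEA with sample-label permutation
#'
#' Metabolites are ranked by a signed two-sample t-statistic; the enrichment
#' score is the signed maximum deviation of the weighted KS running sum
#' (weights `|stat|^weight`). Significance comes from sample-label
#' permutations: `p = (1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)`, a
#' two-sided test on the ES magnitude with the +1 estimator (lower bound
#' `1/(n_perm+1)`).
#'
#' @inheritParams differential_metabolites
#' @param collection a coverage-filtered `PathwayCollection`.
#' @param n_perm number of label permutations, default 1000 (values below
#'   100 trigger a warning).
#' @param weight ranking-statistic weight exponent, default 1 (`weight = 0`
#'   reduces the ES to the classic KS statistic).
#' @param seed permutation seed.
#' @return A `data.frame` with `pathway_id`, `es`, `p_value`, `q_value`;
#'   attribute `"n_tested"` gives the number of pathways tested.
#' @export
gsea <- function(matrix, labels = NULL, collection, n_perm = 1000, weight = 1,
                 seed = NULL, var_equal = TRUE) {
  mm <- as_metabolite_matrix(matrix)
  labels <- labels %||% mm$groups
  if (is.null(labels)) stopf("no group labels supplied or attached to matrix")
  if (n_perm < 100) warnf("n_perm = %d is small; p-values will be coarse", n_perm)
  X <- mm$values
  idx <- lapply(collection$sets, function(s) {
    i <- match(s, colnames(X)); i[!is.na(i)]
  })
  if (any(lengths(idx) == 0L))
    stopf("pathway(s) with no measured members; run filter_by_coverage() first")
  idx <- unname(idx)
  obs_stat <- col_ttests(X, labels, var_equal = var_equal)$statistic
  es_obs <- gsea_es(obs_stat, idx, weight)
  labels <- as.factor(labels)
  count_ge <- numeric(length(idx))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      st <- col_ttests(X, perm, var_equal = var_equal)$statistic
      es_b <- gsea_es(st, idx, weight)
      count_ge <- count_ge + (abs(es_b) >= abs(es_obs))
    }
  })
  p <- (1 + count_ge) / (n_perm + 1)
  res <- data.frame(pathway_id = names(collection$sets), es = es_obs,
                    p_value = p, q_value = p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "n_tested") <- nrow(res)
  res
}
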