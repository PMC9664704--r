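#' Hierarchical clustering of samples on pathway scores
#'
#' Agglomerative Ward clustering (Euclidean distance, `ward.D2`) on
#' per-pathway standardised score columns, with the tree cut to
#' `n_clusters` branches.
#'
#' @param scores a `PathwayScoreMatrix` (or numeric matrix, samples in rows).
#' @param n_clusters number of clusters to cut the tree into, default 2.
#' @param standardize standardise score columns (mean 0, sd 1) before
#'   clustering, default TRUE; constant columns are left centred only.
#' @return Integer vector of per-sample cluster labels, named by sample id.
#' @export
cluster_scores <- function(scores, n_clusters = 2, standardize = TRUE) {
  S <- pathway_scores(scores)
  if (n_clusters > nrow(S))
    stopf("n_clusters (%d) exceeds the number of samples (%d)", n_clusters,
          nrow(S))
  if (standardize) S <- standardize_columns(S)
  hc <- hclust(dist(S, method = "euclidean"), method = "ward.D2")
  cutree(hc, k = n_clusters)
}

standardize_columns <- function(S) {
  mu <- colMeans(S)
  sds <- apply(S, 2L, sd)
  sds[sds == 0] <- 1
  sweep(sweep(S, 2L, mu), 2L, sds, "/")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions; 1 for identical
#' partitions, about 0 for independent ones, and negative when agreement is
#' below the chance expectation.
#'
#' @param a,b label vectors of equal length.
#' @return The ARI (may be negative).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stopf("label vectors differ in length (%d vs %d)", length(a), length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Cumulative-threshold clustering performance curve
#'
#' Ranks features (metabolites or pathway scores) by BH q-value from
#' per-feature two-sample t-tests, keeps those significant at
#' `q <= q_threshold`, and for every cumulative prefix (top 1, top 2, ...)
#' clusters the samples on that feature subset and records the adjusted Rand
#' index against the true binary labels.
#'
#' @param features a `MetaboliteMatrix`, `PathwayScoreMatrix` or numeric
#'   matrix (samples in rows).
#' @param labels binary factor of true sample classes.
#' @param q_threshold BH significance cut-off, default 0.05.
#' @param var_equal pooled-variance t-tests (default) or Welch.
#' @return A `data.frame` with one row per prefix: `n_entities`,
#'   `entity_id` (the entity added), `q_value`, `ari`. Empty (with a
#'   warning) when nothing is significant.
#' @export
cumulative_ari_curve <- function(features, labels, q_threshold = 0.05,
                                 var_equal = TRUE) {
  S <- if (inherits(features, "MetaboliteMatrix")) abundances(features)
       else pathway_scores(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stopf("binary labels required")
  tt <- col_ttests(S, labels, var_equal = var_equal)
  q <- p.adjust(tt$p_value, method = "BH")
  keep <- which(!is.na(q) & q <= q_threshold)
  if (!length(keep)) {
    warnf("no entity significant at q <= %g; empty curve", q_threshold)
    return(data.frame(n_entities = integer(0), entity_id = character(0),
                      q_value = numeric(0), ari = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ord <- keep[order(q[keep], tt$p_value[keep], colnames(S)[keep])]
  ari <- vapply(seq_along(ord), function(j) {
    cl <- cluster_scores(S[, ord[seq_len(j)], drop = FALSE], n_clusters = 2)
    adjusted_rand_index(cl, labels)
  }, numeric(1))
  data.frame(n_entities = seq_along(ord), entity_id = colnames(S)[ord],
             q_value = q[ord], ari = ari, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pathway-score Spearman correlation network
#'
#' Selects the `top_n` pathways by ascending two-group t-test p-value (ties
#' broken by pathway id), assigns node cluster ids from a Ward clustering of
#' the selected (standardised) score columns cut at 2, computes all pairwise
#' Spearman correlations, and keeps edges with `rho >= rho_min` (signed
#' threshold; anti-correlated pairs are dropped unless `absolute = TRUE`).
#' Node attributes carry the mean standardised score per sample group, which
#' may be a finer grouping than the binary ranking labels (e.g. disease
#' subtypes).
#'
#' @param scores a `PathwayScoreMatrix` (or numeric matrix).
#' @param labels binary factor used for the t-test ranking.
#' @param top_n number of pathways to keep, default 50.
#' @param rho_min Spearman threshold for edges, default 0.4.
#' @param subtype_labels optional factor (any number of levels) used for the
#'   per-group node means; defaults to `labels`.
#' @param absolute threshold on `|rho|` instead of signed rho, default FALSE.
#' @param var_equal pooled-variance t-tests (default) or Welch.
#' @return A `PathwayNetwork`: list with `graph` (igraph), `nodes`
#'   (data.frame of id, name, cluster, per-group means) and `edges`
#'   (data.frame of from, to, rho).
#' @export
build_correlation_network <- function(scores, labels, top_n = 50, rho_min = 0.4,
                                      subtype_labels = NULL, absolute = FALSE,
                                      var_equal = TRUE) {
  S <- pathway_scores(scores)
  if (top_n > ncol(S))
    stopf("top_n (%d) exceeds the number of pathways (%d)", top_n, ncol(S))
  subtype_labels <- as.factor(subtype_labels %||% labels)
  tt <- col_ttests(S, labels, var_equal = var_equal)
  ord <- order(tt$p_value, colnames(S))
  sel <- ord[seq_len(top_n)]
  Ssel <- S[, sel, drop = FALSE]
  Z <- standardize_columns(Ssel)
  cluster <- if (top_n >= 2L) {
    hc <- hclust(dist(t(Z), method = "euclidean"), method = "ward.D2")
    cutree(hc, k = min(2L, top_n))
  } else setNames(1L, colnames(Z))
  const <- apply(Ssel, 2L, sd) == 0
  if (any(const))
    warnf("constant score column(s) kept edgeless: %s",
          paste(head(colnames(Ssel)[const], 5), collapse = ", "))
  rho <- suppressWarnings(cor(Ssel, method = "spearman"))
  grp_means <- t(vapply(levels(subtype_labels), function(g) {
    colMeans(Z[subtype_labels == g, , drop = FALSE])
  }, numeric(ncol(Z))))
  nodes <- data.frame(id = colnames(Ssel),
                      name = colnames(Ssel),
                      cluster = as.integer(cluster),
                      p_value = tt$p_value[sel],
                      t(grp_means),
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
  colnames(nodes)[-(1:4)] <- paste0("mean_", levels(subtype_labels))
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  w <- rho[pairs]
  ok <- !is.na(w) & (if (absolute) abs(w) else w) >= rho_min
  edges <- data.frame(from = colnames(Ssel)[pairs[ok, 1L]],
                      to = colnames(Ssel)[pairs[ok, 2L]],
                      rho = w[ok], row.names = NULL, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges,
                 params = list(top_n = top_n, rho_min = rho_min,
                               absolute = absolute)),
            class = "PathwayNetwork")
}

#' @export
print.PathwayNetwork <- function(x, ...) {
  cat(sprintf("PathwayNetwork: %d nodes, %d edges (rho >= %g%s)\n",
              nrow(x$nodes), nrow(x$edges), x$params$rho_min,
              if (x$params$absolute) ", absolute" else ""))
  invisible(x)
}

#' Write a pathway network to GraphML or a TSV edge list
#'
#' @param network a `PathwayNetwork`.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"` (TSV with from, to, rho).
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    write.table(network$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
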