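#' @title Single-sample pathway scoring
#'
#' @description Six scorers share one contract: a post-processed (log2,
#' per-metabolite standardised) samples x metabolites matrix plus a
#' coverage-filtered pathway collection yield a samples x pathways score
#' matrix. Scores of the dimensionality-reduction and clustering scorers
#' (SVD, ssClustPA, kPCA) carry an arbitrary sign that is fixed by
#' `sign_policy = "mean-correlation"`: the score column is flipped, if
#' needed, so it correlates non-negatively with the per-sample mean of the
#' pathway submatrix. This makes output deterministic without claiming
#' directional meaning.
#'
#' @param matrix a `MetaboliteMatrix` (or numeric matrix, samples in rows).
#' @param collection a coverage-filtered `PathwayCollection`.
#' @name sspa_methods
NULL

# Validate inputs shared by all scorers; returns list(X, sets, idx) where
# idx holds 1-based member column indices per pathway.
prepare_scoring <- function(matrix, collection, min_members = 1L) {
  mm <- as_metabolite_matrix(matrix)
  X <- mm$values
  if (anyNA(X)) stopf("matrix contains missing values; impute first")
  sets <- collection$sets
  idx <- lapply(sets, function(s) {
    i <- match(s, colnames(X))
    i[!is.na(i)]
  })
  short <- lengths(idx) < min_members
  if (any(short))
    stopf(paste0("pathway(s) with fewer than %d measured members: %s; run ",
                 "filter_by_coverage() first"), min_members,
          paste(head(names(sets)[short], 5), collapse = ", "))
  list(mm = mm, X = X, sets = sets, idx = idx)
}

new_score_matrix <- function(scores, matrix, collection, method, params) {
  dimnames(scores) <- list(rownames(abundances(matrix)), pathway_ids(collection))
  structure(list(scores = scores, method = method, params = params),
            class = "PathwayScoreMatrix")
}

#' @rdname sspa_methods
#' @param x a `PathwayScoreMatrix`.
#' @export
pathway_scores <- function(x) {
  if (inherits(x, "PathwayScoreMatrix")) x$scores else as.matrix(x)
}

#' @export
print.PathwayScoreMatrix <- function(x, ...) {
  cat(sprintf("PathwayScoreMatrix (%s): %d samples x %d pathways\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' z-score pathway scoring
#'
#' For a standardised matrix, the score of sample i for pathway k is the sum
#' of the member z-values divided by `sqrt(M_k)` (Lee-style normalised
#' z-score). A warning is raised when the matrix provenance does not record
#' standardisation.
#'
#' @inheritParams sspa_methods
#' @return A `PathwayScoreMatrix`.
#' @export
score_zscore <- function(matrix, collection) {
  prep <- prepare_scoring(matrix, collection)
  if (length(prep$mm$provenance) && !has_provenance(prep$mm, "standardize"))
    warnf("matrix provenance does not record standardisation; z-score assumes it")
  m <- ncol(prep$X)
  A <- vapply(prep$idx, function(i) {
    rowSums(prep$X[, i, drop = FALSE]) / sqrt(length(i))
  }, numeric(nrow(prep$X)))
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  new_score_matrix(A, matrix, collection, "zscore", list())
}

#' SVD (PLAGE) pathway scoring
#'
#' Scores are the entries of the unit-norm sample-side singular vector of the
#' pathway submatrix `Z_k` associated with its largest singular value.
#'
#' @inheritParams sspa_methods
#' @param sign_policy `"mean-correlation"` (default) or `"none"`.
#' @return A `PathwayScoreMatrix`.
#' @export
score_svd <- function(matrix, collection, sign_policy = c("mean-correlation", "none")) {
  sign_policy <- match.arg(sign_policy)
  prep <- prepare_scoring(matrix, collection)
  A <- vapply(prep$idx, function(i) {
    Z <- prep$X[, i, drop = FALSE]
    if (all(Z == 0)) stopf("degenerate pathway submatrix (all zeros)")
    # leading left singular vector via the small (Mk x Mk) Gram matrix
    e <- eigen(crossprod(Z), symmetric = TRUE)
    sigma <- sqrt(max(e$values[1L], 0))
    if (sigma <= 0) stopf("degenerate pathway submatrix (rank 0)")
    u <- as.numeric(Z %*% e$vectors[, 1L]) / sigma
    fix_sign(u, Z, sign_policy)
  }, numeric(nrow(prep$X)))
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  new_score_matrix(A, matrix, collection, "svd", list(sign_policy = sign_policy))
}

#' ssGSEA pathway scoring
#'
#' Per sample, metabolites are ranked by abundance (descending, average-rank
#' ties, stable order) and a weighted Kolmogorov-Smirnov-like random walk is
#' run: in-set steps climb by `rank^weight_alpha` (normalised), out-set steps
#' fall uniformly. The score is the integrated running sum (the ssGSEA
#' convention, distinguishing it from GSVA's extremum statistic).
#'
#' @inheritParams sspa_methods
#' @param weight_alpha rank-weight exponent, default 0.25.
#' @param normalize divide all scores by the global (max - min) range.
#' @return A `PathwayScoreMatrix`.
#' @export
score_ssgsea <- function(matrix, collection, weight_alpha = 0.25, normalize = FALSE) {
  prep <- prepare_scoring(matrix, collection)
  X <- prep$X
  n <- nrow(X); m <- ncol(X)
  if (any(lengths(prep$idx) >= m))
    stopf("a pathway covers all metabolites; out-set is empty")
  ord <- t(apply(X, 1L, function(x) order(x, decreasing = TRUE)))
  rk <- t(apply(X, 1L, rank, ties.method = "average")) # m = highest abundance
  w <- rk^weight_alpha
  A <- cpp_es_walk(ord, w, unname(prep$idx), 0L)
  if (normalize) {
    rng <- max(A) - min(A)
    if (rng > 0) A <- A / rng
  }
  new_score_matrix(A, matrix, collection, "ssgsea",
                   list(weight_alpha = weight_alpha, normalize = normalize))
}

#' GSVA pathway scoring
#'
#' Three steps: (1) per metabolite, a Gaussian kernel CDF estimate across
#' samples (bandwidth = sample sd / 4); (2) per sample, the kernel statistics
#' are ranked across metabolites and converted to the symmetric rank
#' statistic `|m/2 - rank|`; (3) a KS-like random walk in decreasing kernel
#' statistic order with in-set weights `|r|^tau`. The enrichment score is the
#' sum of the largest positive and smallest negative deviation (`"max-diff"`)
#' or the signed maximum deviation (`"signed-max"`).
#'
#' @inheritParams sspa_methods
#' @param kcdf kernel CDF; only `"gaussian"` is implemented.
#' @param tau rank-weight exponent, default 1.
#' @param es_mode enrichment statistic, `"max-diff"` (default) or
#'   `"signed-max"`.
#' @return A `PathwayScoreMatrix`.
#' @export
score_gsva <- function(matrix, collection, kcdf = c("gaussian"), tau = 1,
                       es_mode = c("max-diff", "signed-max")) {
  kcdf <- match.arg(kcdf)
  es_mode <- match.arg(es_mode)
  prep <- prepare_scoring(matrix, collection)
  X <- prep$X
  n <- nrow(X); m <- ncol(X)
  if (n < 3L) stopf("GSVA needs at least 3 samples for the kernel CDF")
  if (any(lengths(prep$idx) >= m))
    stopf("a pathway covers all metabolites; out-set is empty")
  Z <- cpp_gauss_kcdf(X) # errors on zero-variance columns
  ord <- t(apply(Z, 1L, function(z) order(z, decreasing = TRUE)))
  rdesc <- t(apply(-Z, 1L, rank, ties.method = "average")) # 1 = largest stat
  w <- abs(m / 2 - rdesc)^tau
  A <- cpp_es_walk(ord, w, unname(prep$idx),
                   if (es_mode == "max-diff") 1L else 2L)
  new_score_matrix(A, matrix, collection, "gsva",
                   list(kcdf = kcdf, tau = tau, es_mode = es_mode))
}

#' ssClustPA pathway scoring (k-means projection)
#'
#' For each pathway submatrix `Z_k`, 2-means clustering (Euclidean, best of
#' `restarts` seeded initialisations) locates two cluster centroids; samples
#' are projected onto the unit vector `u = (c1 - c2) / ||c1 - c2||` joining
#' them, `A_k = Z_k u`.
#'
#' @inheritParams score_svd
#' @param seed integer seed controlling the k-means initialisations.
#' @param restarts number of k-means restarts, default 10.
#' @return A `PathwayScoreMatrix`.
#' @export
score_ssclustpa <- function(matrix, collection, seed = NULL, restarts = 10,
                            sign_policy = c("mean-correlation", "none")) {
  sign_policy <- match.arg(sign_policy)
  prep <- prepare_scoring(matrix, collection)
  X <- prep$X
  if (nrow(X) < 2L) stopf("ssClustPA needs at least 2 samples")
  A <- with_seed(seed, {
    vapply(prep$idx, function(i) {
      Z <- X[, i, drop = FALSE]
      uz <- unique(Z)
      if (nrow(uz) < 2L)
        stopf("all samples identical for a pathway: zero centroid distance")
      km <- if (nrow(uz) == 2L) {
        # two distinct points: the optimal 2-means centroids are the points
        kmeans(Z, centers = uz, iter.max = 100L)
      } else {
        kmeans(Z, centers = 2L, nstart = restarts, iter.max = 100L)
      }
      u <- km$centers[1L, ] - km$centers[2L, ]
      nu <- sqrt(sum(u^2))
      if (nu == 0) stopf("zero centroid distance")
      fix_sign(as.numeric(Z %*% (u / nu)), Z, sign_policy)
    }, numeric(nrow(X)))
  })
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  new_score_matrix(A, matrix, collection, "ssclustpa",
                   list(seed = seed, restarts = restarts, sign_policy = sign_policy))
}

# Leading eigenpair of a symmetric PSD matrix: C++ power iteration with a
# deterministic start vector, eigen() fallback if not converged.
leading_eigenpair <- function(K, tol = 1e-9, max_iter = 500L) {
  ep <- cpp_power_eig(K, tol, as.integer(max_iter))
  if (!ep$converged) {
    e <- eigen(K, symmetric = TRUE)
    ep <- list(value = e$values[1L], vector = e$vectors[, 1L])
  }
  ep
}

#' kPCA pathway scoring (RBF kernel PCA)
#'
#' For each pathway submatrix, a radial basis function kernel
#' `K_ij = exp(-gamma ||x_i - x_j||^2)` is computed on the samples, double
#' centred, and the scores of the first principal component (leading
#' eigenvector scaled by the square root of its eigenvalue) are used as
#' pathway scores. The kernel width defaults to `gamma = 1/n` with `n` the
#' number of samples (note some libraries default to 1/#features instead).
#'
#' @inheritParams score_svd
#' @param gamma RBF kernel width; default `1 / nrow(matrix)`.
#' @return A `PathwayScoreMatrix`.
#' @export
score_kpca <- function(matrix, collection, gamma = NULL,
                       sign_policy = c("mean-correlation", "none")) {
  sign_policy <- match.arg(sign_policy)
  prep <- prepare_scoring(matrix, collection)
  X <- prep$X
  n <- nrow(X)
  gamma <- gamma %||% (1 / n)
  if (gamma <= 0) stopf("`gamma` must be > 0")
  A <- vapply(prep$idx, function(i) {
    Z <- X[, i, drop = FALSE]
    sq <- rowSums(Z^2)
    D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(Z), 0)
    K <- exp(-gamma * D2)
    # double centring
    rm_ <- rowMeans(K); gm <- mean(K)
    Kc <- K - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
    ep <- leading_eigenpair(Kc)
    if (ep$value <= 1e-12)
      stopf("degenerate kernel matrix: leading eigenvalue <= 0")
    fix_sign(ep$vector * sqrt(ep$value), Z, sign_policy)
  }, numeric(n))
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  new_score_matrix(A, matrix, collection, "kpca",
                   list(gamma = gamma, sign_policy = sign_policy))
}

#' Dispatch a single-sample pathway scorer by name
#'
#' @inheritParams sspa_methods
#' @param method one of `"zscore"`, `"svd"`, `"ssgsea"`, `"gsva"`,
#'   `"ssclustpa"`, `"kpca"`.
#' @param seed seed passed to stochastic scorers (ssClustPA).
#' @param ... further arguments passed to the scorer.
#' @return A `PathwayScoreMatrix`.
#' @export
sspa_score <- function(matrix, collection,
                       method = c("zscore", "svd", "ssgsea", "gsva",
                                  "ssclustpa", "kpca"),
                       seed = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         zscore    = score_zscore(matrix, collection, ...),
         svd       = score_svd(matrix, collection, ...),
         ssgsea    = score_ssgsea(matrix, collection, ...),
         gsva      = score_gsva(matrix, collection, ...),
         ssclustpa = score_ssclustpa(matrix, collection, seed = seed, ...),
         kpca      = score_kpca(matrix, collection, ...))
}

#' @rdname sspa_score
#' @export
sspa_method_names <- function() c("zscore", "svd", "ssgsea", "gsva",
                                  "ssclustpa", "kpca")
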