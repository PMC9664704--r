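#' Iterative-SVD imputation of missing values
#'
#' Fills missing entries by iterating: initialise missing cells with column
#' means, reconstruct the matrix from its rank-`rank` truncated SVD, and
#' overwrite the missing cells with the reconstruction, until the relative
#' Frobenius-norm change of the imputed entries drops below `tol` or
#' `max_iter` is reached. Observed entries are never altered.
#'
#' @param matrix a `MetaboliteMatrix` (or numeric matrix) possibly containing
#'   `NA` entries.
#' @param rank SVD rank; default `min(10, min(n, m) - 1)`.
#' @param max_iter maximum number of SVD iterations.
#' @param tol relative Frobenius convergence tolerance on imputed entries.
#' @return The completed `MetaboliteMatrix`; non-convergence is recorded as a
#'   provenance flag, not an error.
#' @export
impute_iterative_svd <- function(matrix, rank = NULL, max_iter = 100, tol = 1e-4) {
  mm <- as_metabolite_matrix(matrix)
  X <- mm$values
  n <- nrow(X); m <- ncol(X)
  rank <- rank %||% min(10L, min(n, m) - 1L)
  if (rank >= min(n, m)) stopf("`rank` must be < min(n, m) = %d", min(n, m))
  if (rank < 1L) stopf("`rank` must be >= 1")
  miss <- is.na(X)
  if (!any(miss)) return(mm)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stopf("column(s) with no observed values: %s",
          paste(head(colnames(X)[all_missing], 5), collapse = ", "))
  cm <- colMeans(X, na.rm = TRUE)
  Xf <- X
  Xf[miss] <- cm[col(X)[miss]]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sv <- svd(Xf, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    old <- Xf[miss]
    Xf[miss] <- recon[miss]
    denom <- sqrt(sum(old^2))
    delta <- sqrt(sum((Xf[miss] - old)^2)) / max(denom, .Machine$double.eps)
    if (delta < tol) { converged <- TRUE; break }
  }
  mm$values <- Xf
  tag <- sprintf("impute_iterative_svd(rank=%d)", rank)
  if (!converged) tag <- paste0(tag, "[not converged]")
  add_provenance(mm, tag)
}

#' Probabilistic quotient normalisation
#'
#' The reference spectrum is the per-metabolite median across samples. Each
#' sample is divided by the median, over metabolites, of its quotients
#' against the reference. Must be applied to strictly positive raw-scale
#' intensities (before any log transform).
#'
#' @param matrix a `MetaboliteMatrix` (or numeric matrix) of positive values.
#' @param reference reference policy; only `"median-spectrum"` is available.
#' @return The normalised `MetaboliteMatrix`.
#' @export
pqn_normalize <- function(matrix, reference = c("median-spectrum")) {
  reference <- match.arg(reference)
  mm <- as_metabolite_matrix(matrix)
  X <- mm$values
  if (anyNA(X)) stopf("missing values present; impute before PQN")
  if (any(X <= 0))
    stopf("PQN requires strictly positive values; apply before log transform")
  ref <- apply(X, 2L, median)
  quotients <- apply(sweep(X, 2L, ref, "/"), 1L, median)
  mm$values <- X / quotients
  add_provenance(mm, "pqn_normalize")
}

#' Log2 transform and per-metabolite standardisation
#'
#' Applies a log2 transform (skipped when provenance already marks the matrix
#' as log2 scale) followed by centring and scaling of every metabolite to
#' mean 0 and sample standard deviation 1 (n - 1 denominator).
#'
#' @param matrix a `MetaboliteMatrix` (or numeric matrix).
#' @param log_transform force (`TRUE`) or skip (`FALSE`) the log2 step;
#'   `NULL` (default) skips it when provenance contains a `"log2"` tag.
#' @return The standardised `MetaboliteMatrix`.
#' @export
log2_standardize <- function(matrix, log_transform = NULL) {
  mm <- as_metabolite_matrix(matrix)
  X <- mm$values
  if (anyNA(X)) stopf("missing values present; impute first")
  do_log <- log_transform %||% !has_provenance(mm, "log2")
  if (do_log) {
    if (any(X <= 0)) stopf("log2 requires strictly positive values")
    X <- log2(X)
    mm <- add_provenance(mm, "log2")
  }
  sds <- apply(X, 2L, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stopf("zero-variance metabolite(s): %s",
          paste(head(colnames(X)[zero], 10), collapse = ", "))
  mm$values <- scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
  attr(mm$values, "scaled:center") <- NULL
  attr(mm$values, "scaled:scale") <- NULL
  add_provenance(mm, "standardize")
}

#' Full post-processing chain
#'
#' Convenience wrapper enforcing the order impute -> PQN -> log2 ->
#' standardise; each step is also callable on its own. Imputation is run on
#' the log2 scale (where the low-rank model holds for intensity data) and
#' back-transformed, which also keeps every imputed intensity positive for
#' the PQN step.
#'
#' @inheritParams impute_iterative_svd
#' @export
preprocess_pipeline <- function(matrix, rank = NULL, max_iter = 100, tol = 1e-4) {
  mm <- as_metabolite_matrix(matrix)
  if (anyNA(mm$values)) {
    if (any(mm$values <= 0, na.rm = TRUE))
      stopf("raw intensities must be strictly positive")
    lg <- mm
    lg$values <- log2(mm$values)
    lg <- impute_iterative_svd(lg, rank = rank, max_iter = max_iter, tol = tol)
    mm$values <- 2^lg$values
    mm$provenance <- lg$provenance
  }
  mm <- pqn_normalize(mm)
  log2_standardize(mm)
}
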