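#' Specification for a synthetic base matrix
#'
#' Describes the statistical structure of a synthetic stand-in for a
#' post-processed untargeted MS metabolomics dataset: standardised log-scale
#' Gaussian marginals with block-diagonal correlation. Defaults mirror the
#' shape of a typical plasma metabolomics study (260 samples x 335
#' metabolites, correlation blocks of 5-20 metabolites at rho = 0.3).
#'
#' @param n_samples number of samples.
#' @param n_metabolites number of metabolites.
#' @param block_size_range integer range `(lo, hi)` of correlation block
#'   sizes.
#' @param rho within-block correlation, in `[0, 1)`.
#' @param marginal `"standardized"` (log2-standardised Gaussian, ready for
#'   scoring) or `"lognormal-raw"` (positive raw intensities with optional
#'   missingness, for exercising the preprocessing chain).
#' @param missing_rate MCAR missingness rate in `[0, 1)` (raw marginal only).
#' @param seed RNG seed.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_samples = 260, n_metabolites = 335,
                           block_size_range = c(5, 20), rho = 0.3,
                           marginal = c("standardized", "lognormal-raw"),
                           missing_rate = 0, seed = NULL) {
  marginal <- match.arg(marginal)
  if (rho < 0 || rho >= 1)
    stopf("`rho` must be in [0, 1) for a positive semi-definite block")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("`missing_rate` must be in [0, 1)")
  if (block_size_range[1] < 1 || block_size_range[2] < block_size_range[1])
    stopf("invalid block size range")
  structure(list(n_samples = as.integer(n_samples),
                 n_metabolites = as.integer(n_metabolites),
                 block_size_range = as.integer(block_size_range),
                 rho = rho, marginal = marginal,
                 missing_rate = missing_rate, seed = seed),
            class = "SyntheticSpec")
}

#' Generate a synthetic base matrix
#'
#' Draws a multivariate normal matrix with block-equicorrelated columns
#' (within a block of size b, `X_j = sqrt(rho) * z + sqrt(1 - rho) * e_j`
#' with a shared per-sample factor z — exactly the equicorrelation model),
#' then standardises every column to mean 0 and sd 1. Two placeholder groups
#' (first half A, second half B) are assigned; the benchmark permutes them
#' anyway. With the `"lognormal-raw"` marginal, raw positive intensities
#' `2^(10 + 2 * X)` with MCAR missingness are returned instead, for
#' exercising the preprocessing chain.
#'
#' @param spec a [synthetic_spec()].
#' @return A `MetaboliteMatrix`.
#' @export
generate_base_matrix <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$n_samples; m <- spec$n_metabolites
  with_seed(spec$seed, {
    sizes <- integer(0)
    while (sum(sizes) < m) {
      sizes <- c(sizes, sample(spec$block_size_range[1]:spec$block_size_range[2], 1L))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - m)
    X <- matrix(0, n, m)
    pos <- 0L
    for (b in sizes) {
      if (b == 0L) next
      z <- rnorm(n)
      E <- matrix(rnorm(n * b), n, b)
      X[, pos + seq_len(b)] <- sqrt(spec$rho) * z + sqrt(1 - spec$rho) * E
      pos <- pos + b
    }
    dimnames(X) <- list(sprintf("sample_%03d", seq_len(n)),
                        sprintf("met_%04d", seq_len(m)))
    groups <- factor(rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2))))
    if (spec$marginal == "lognormal-raw") {
      raw <- 2^(10 + 2 * X)
      if (spec$missing_rate > 0) {
        drop <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
        # keep at least one observed value per column
        for (j in which(colSums(!drop) == 0L)) drop[1L, j] <- FALSE
        raw[drop] <- NA_real_
      }
      return(metabolite_matrix(raw, groups = groups, provenance = "synthetic"))
    }
    sds <- apply(X, 2L, sd)
    X <- scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
    attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
    metabolite_matrix(X, groups = groups,
                      provenance = c("synthetic", "log2", "standardize"))
  })
}

#' Generate a synthetic pathway collection with controlled overlap
#'
#' Two overlap models: `"disjoint"` draws pairwise non-overlapping member
#' sets (all pairwise overlap coefficients are exactly 0), emulating a
#' non-redundant pathway set; `"shared-pool"` draws a fraction `reuse_rate`
#' of every pathway's members from a common pool, producing a controlled
#' spread of pairwise overlap coefficients (a redundant collection).
#'
#' @param n_pathways number of pathways.
#' @param size_range integer range `(lo, hi)` of member-set sizes.
#' @param overlap_model `"disjoint"` or `"shared-pool"`.
#' @param metabolite_universe character vector of available identifiers
#'   (e.g. `metabolite_ids()` of a base matrix).
#' @param pool_size size of the shared pool (shared-pool model); default
#'   `max(size hi, 30% of the universe)`.
#' @param reuse_rate fraction in `[0, 1]` of each pathway's members drawn
#'   from the pool; 0 reduces to near-disjoint sampling.
#' @param seed RNG seed.
#' @return A `PathwayCollection` (source `"synthetic"`).
#' @export
generate_pathway_collection <- function(n_pathways, size_range = c(2, 6),
                                        overlap_model = c("disjoint", "shared-pool"),
                                        metabolite_universe,
                                        pool_size = NULL, reuse_rate = 0.5,
                                        seed = NULL) {
  overlap_model <- match.arg(overlap_model)
  universe <- unique(as.character(metabolite_universe))
  with_seed(seed, {
    sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
    if (overlap_model == "disjoint") {
      if (sum(sizes) > length(universe))
        stopf("disjoint model infeasible: total size %d > universe %d",
              sum(sizes), length(universe))
      picks <- sample(universe, sum(sizes))
      ends <- cumsum(sizes)
      sets <- lapply(seq_len(n_pathways), function(i) {
        picks[(ends[i] - sizes[i] + 1L):ends[i]]
      })
    } else {
      pool_size <- pool_size %||% max(size_range[2],
                                      round(0.3 * length(universe)))
      if (pool_size > length(universe)) stopf("pool larger than universe")
      pool <- sample(universe, pool_size)
      rest <- setdiff(universe, pool)
      if (size_range[2] > length(rest) + pool_size)
        stopf("pathway sizes infeasible for this universe")
      sets <- lapply(seq_len(n_pathways), function(i) {
        L <- sizes[i]
        n_pool <- min(round(reuse_rate * L), pool_size)
        n_rest <- L - n_pool
        if (n_rest > length(rest)) { n_rest <- length(rest); n_pool <- L - n_rest }
        c(if (n_pool > 0) sample(pool, n_pool) else character(0),
          if (n_rest > 0) sample(rest, n_rest) else character(0))
      })
    }
    names(sets) <- sprintf("SYNP%04d", seq_len(n_pathways))
    pathway_collection(sets, source = "synthetic")
  })
}

#' Fixed 6 x 6 toy instance
#'
#' A deterministic miniature dataset used in examples and hand-checked
#' tests: 6 samples x 6 standardised metabolites (each column is the pattern
#' (-5,-3,-1,1,3,5)/sqrt(14), shuffled per column by fixed permutations),
#' three 2-member pathways that all pass `min_coverage = 2`, and balanced
#' A/B labels.
#'
#' @return A list with `matrix` (`MetaboliteMatrix`), `collection`
#'   (`PathwayCollection` of 3 pathways) and `labels` (factor).
#' @export
make_toy_fixture <- function() {
  base <- c(-5, -3, -1, 1, 3, 5) / sqrt(14) # mean 0, sd (n-1) exactly 1
  perms <- list(c(1, 2, 3, 4, 5, 6), c(6, 5, 4, 3, 2, 1), c(2, 4, 6, 1, 3, 5),
                c(3, 1, 5, 2, 6, 4), c(5, 6, 1, 4, 2, 3), c(4, 3, 6, 5, 1, 2))
  X <- vapply(perms, function(p) base[p], numeric(6))
  dimnames(X) <- list(paste0("s", 1:6), paste0("m", 1:6))
  labels <- factor(c("A", "A", "A", "B", "B", "B"))
  mm <- metabolite_matrix(X, groups = labels,
                          provenance = c("synthetic", "log2", "standardize"))
  coll <- pathway_collection(list(P1 = c("m1", "m2"), P2 = c("m3", "m4"),
                                  P3 = c("m5", "m6")),
                             source = "synthetic")
  list(matrix = mm, collection = coll, labels = labels)
}
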