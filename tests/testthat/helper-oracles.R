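# Independent oracles and small data builders used across the suite.

# iid standard-normal MetaboliteMatrix with exact per-column standardisation
std_matrix <- function(n, m, seed, groups = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("m%03d", 1:m)))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  metabolite_matrix(X, groups = groups,
                    provenance = c("synthetic", "log2", "standardize"))
}

# disjoint pathway collection over the first columns of a matrix
disjoint_collection <- function(ids, sizes) {
  stopifnot(sum(sizes) <= length(ids))
  ends <- cumsum(sizes)
  sets <- lapply(seq_along(sizes), function(i) {
    ids[(ends[i] - sizes[i] + 1):ends[i]]
  })
  names(sets) <- sprintf("P%02d", seq_along(sizes))
  pathway_collection(sets, source = "synthetic")
}

# ROC AUC by exhaustive pairwise comparison (ties count 1/2)
brute_auc <- function(score, positive) {
  s1 <- score[positive]; s0 <- score[!positive]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# one-sided hypergeometric tail P(X >= a) by direct binomial-coefficient sums
hyper_tail <- function(a, n_da, n_mem, N) {
  xs <- a:min(n_da, n_mem)
  sum(choose(n_mem, xs) * choose(N - n_mem, n_da - xs)) / choose(N, n_da)
}

# classic two-sample KS statistic between in-set and out-set rank positions
ks_rank_stat <- function(stat, members_idx) {
  m <- length(stat)
  ordv <- order(stat, decreasing = TRUE)
  inset <- ordv %in% members_idx
  Mk <- sum(inset)
  dev <- cumsum(ifelse(inset, 1 / Mk, -1 / (m - Mk)))
  max(abs(dev))
}
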