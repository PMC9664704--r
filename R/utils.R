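`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' When `seed` is NULL the expression runs against the global RNG stream;
#' otherwise the stream is set to `seed` for the duration of the call and
#' restored afterwards.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Derive n reproducible child seeds from a master seed
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

#' Vectorised per-column two-sample t-tests
#'
#' Equal-variance (Student) by default, Welch optionally. Columns with zero
#' pooled variance follow the convention: equal means give p = 1, unequal
#' means give p = 0.
#' @param X numeric matrix, samples in rows
#' @param g factor with exactly two levels
#' @noRd
col_ttests <- function(X, g, var_equal = TRUE) {
  g <- droplevels(as.factor(g))
  if (nlevels(g) != 2L) stopf("exactly two groups required, got %d", nlevels(g))
  i1 <- which(g == levels(g)[1L])
  i2 <- which(g == levels(g)[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stopf("each group needs at least 2 samples (got %d/%d)", n1, n2)
  X1 <- X[i1, , drop = FALSE]; X2 <- X[i2, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums(sweep(X1, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(X2, 2L, m2)^2) / (n2 - 1)
  dm <- m2 - m1
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, ncol(X))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- dm / se
  degen <- !is.finite(stat)
  if (any(degen)) {
    # zero variance in both groups: p = 1 when the means agree, 0 otherwise
    stat[degen] <- ifelse(abs(dm[degen]) < .Machine$double.eps^0.5, 0,
                          sign(dm[degen]) * Inf)
    df[degen & !is.finite(df)] <- n1 + n2 - 2
  }
  p <- 2 * pt(abs(stat), df = df, lower.tail = FALSE)
  list(statistic = stat, p_value = p, df = df, mean_diff = dm,
       degenerate = degen, groups = levels(g))
}

# Fix the sign of a score vector so it correlates non-negatively with the
# per-sample mean of the pathway submatrix (policy "mean-correlation").
fix_sign <- function(scores, Z, sign_policy = "mean-correlation") {
  if (identical(sign_policy, "none")) return(scores)
  ref <- rowMeans(Z)
  r <- if (sd(scores) == 0 || sd(ref) == 0) NA_real_ else cor(scores, ref)
  s <- if (is.na(r) || r == 0) {
    nz <- which(abs(scores) > 0)
    if (length(nz)) sign(scores[nz[1L]]) else 1
  } else sign(r)
  if (s < 0) -scores else scores
}
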