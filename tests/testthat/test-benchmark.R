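base20 <- std_matrix(20, 24, seed = 30,
                     groups = factor(rep(c("A", "B"), each = 10)))
coll20 <- disjoint_collection(metabolite_ids(base20), c(3, 4, 5, 2, 3))

test_that("permute-and-spike respects the additive model exactly", {
  sim0 <- simulate_dataset(base20, coll20, k = 2, alpha = 0, seed = 1)
  expect_identical(abundances(sim0$matrix), abundances(base20)) # alpha=0: Y == X
  sim <- simulate_dataset(base20, coll20, k = 2, alpha = 1, seed = 2)
  g <- sim$design$labels
  arows <- g == levels(g)[1]
  # group-A rows bit-identical for any alpha
  expect_identical(abundances(sim$matrix)[arows, ], abundances(base20)[arows, ])
  # spiked columns shifted by exactly alpha in group B, others untouched
  sp <- sim$design$spiked
  expect_identical(abundances(sim$matrix)[!arows, sp],
                   abundances(base20)[!arows, sp] + 1)
  other <- setdiff(metabolite_ids(base20), sp)
  expect_identical(abundances(sim$matrix)[!arows, other],
                   abundances(base20)[!arows, other])
  # alpha = 1 on the log2 scale is a raw-scale fold change of 2
  dm <- colMeans(abundances(sim$matrix)[!arows, sp, drop = FALSE]) -
        colMeans(abundances(base20)[!arows, sp, drop = FALSE])
  expect_equal(unname(2^dm), rep(2, length(sp)), tolerance = 1e-12)
  # signal fraction controls the spiked subset size
  sim50 <- simulate_dataset(base20, coll20, k = 2, alpha = 1,
                            signal_fraction = 50, seed = 3)
  expect_equal(length(sim50$design$spiked),
               round(0.5 * length(sim50$design$members)))
  expect_true(all(sim50$design$spiked %in% sim50$design$members))
  expect_error(simulate_dataset(base20, coll20, k = 99, alpha = 1), "exceeds")
})

test_that("coverage reduction deletes the right number of columns globally", {
  red <- reduce_coverage(base20, coll20, "P02", 50, seed = 4)
  kept <- intersect(coll20$sets$P02, metabolite_ids(red))
  expect_length(kept, 2L) # round(0.5 * 4)
  expect_equal(ncol(abundances(red)), 24 - 2)
  # 100% is the identity
  expect_identical(abundances(reduce_coverage(base20, coll20, "P02", 100)),
                   abundances(base20))
  expect_error(reduce_coverage(base20, coll20, "P04", 50), ">= 2")
})

test_that("pathway t-tests follow the two-sample conventions", {
  g <- factor(rep(c("A", "B"), each = 10))
  S <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(paste0("s", 1:20), paste0("P", 1:3)))
  # duplicate groups: identical distributions give p = 1
  S[11:20, 1] <- S[1:10, 1]
  p <- suppressWarnings(pathway_ttests(S, g))
  expect_equal(unname(p["P1"]), 1)
  # strong separation: p < 1e-10
  S[, 2] <- rep(c(-5, 5), each = 10) + rnorm(20, sd = 1)
  p <- suppressWarnings(pathway_ttests(S, g))
  expect_lt(p[["P2"]], 1e-10)
  # constant column: p = 1 by convention, with a warning
  S[, 3] <- 7
  expect_warning(p3 <- pathway_ttests(S, g), "constant")
  expect_equal(unname(p3["P3"]), 1)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(unname(bh_adjust(0.02)), 0.02)
  expect_equal(unname(bh_adjust(c(0.01, 0.02, 0.03))), c(0.03, 0.03, 0.03))
  set.seed(31)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15)) # q order follows p order
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
  expect_equal(q, p.adjust(p, method = "BH")) # agrees with the reference
  # NA entries (untested pathways) stay NA and do not affect the rest
  q2 <- bh_adjust(c(0.01, NA, 0.02, 0.03))
  expect_true(is.na(q2[2]))
  expect_equal(unname(q2[-2]), c(0.03, 0.03, 0.03))
})

test_that("outcome classification implements the OC truth model", {
  coll <- pathway_collection(list(E1 = c("a", "b"), Hi = c("a", "b", "x"),
                                  Mid = c("a", "y"), Lo = c("y", "z", "w"),
                                  Nul = c("q", "r")), source = "synthetic")
  design <- structure(list(labels = NULL, enriched = "E1",
                           members = c("a", "b"), spiked = c("a", "b"),
                           alpha = 1, signal_fraction = 100, seed = 1),
                      class = "SpikeDesign")
  # q chosen directly to exercise each branch at theta = 0.5
  p <- c(E1 = 0.001, Hi = 0.001, Mid = 0.01, Lo = 0.001, Nul = 0.5)
  q <- c(E1 = 0.01, Hi = 0.2, Mid = 0.2, Lo = 0.01, Nul = 0.9)
  cls <- classify_outcomes(p, design, coll, theta = 0.5, q = q)
  expect_equal(cls$outcome[cls$pathway_id == "E1"], "TP")  # in E, q <= 0.05
  expect_equal(cls$outcome[cls$pathway_id == "Hi"], "FN")  # oc = 1 >= theta, q > 0.05
  expect_equal(cls$outcome[cls$pathway_id == "Mid"], "FN") # oc = 0.5 >= theta
  expect_equal(cls$outcome[cls$pathway_id == "Lo"], "FP")  # oc = 0 < theta, q <= 0.05
  expect_equal(cls$outcome[cls$pathway_id == "Nul"], "TN")
  expect_equal(cls$oc[cls$pathway_id == "Hi"], 1)
  expect_equal(cls$oc[cls$pathway_id == "Mid"], 0.5)
  expect_equal(cls$oc[cls$pathway_id == "Lo"], 0)
})

test_that("every pathway gets exactly one outcome and theta acts monotonically", {
  set.seed(32)
  for (r in 1:10) {
    coll <- generate_pathway_collection(30, c(2, 8), "shared-pool",
                                        sprintf("m%03d", 1:100),
                                        pool_size = 30, reuse_rate = 0.5,
                                        seed = 320 + r)
    design <- simulate_dataset(
      std_matrix(10, 100, seed = 330 + r,
                 groups = factor(rep(c("A", "B"), 5))),
      coll, k = 3, alpha = 0, seed = 340 + r)$design
    p <- setNames(runif(30), pathway_ids(coll))
    pos_prev <- NULL
    for (theta in c(0.75, 0.5, 0.25)) {
      cls <- classify_outcomes(p, design, coll, theta = theta)
      # partition: every pathway gets exactly one of the four outcomes
      expect_equal(nrow(cls), 30L)
      expect_true(all(cls$outcome %in% c("TP", "FP", "TN", "FN")))
      cnt <- table(factor(cls$outcome, c("TP", "FP", "TN", "FN")))
      expect_equal(sum(cnt), 30L)
      pos <- sum(cls$positive)
      if (!is.null(pos_prev)) expect_gte(pos, pos_prev) # lowering theta grows positives
      pos_prev <- pos
    }
  }
})

test_that("performance metrics agree with direct definitions and a pair-count AUC", {
  # perfect detection
  coll <- disjoint_collection(letters, c(2, 2, 2, 2))
  design <- structure(list(enriched = c("P01", "P02"),
                           members = c(letters[1:4]), spiked = letters[1:4],
                           alpha = 1, signal_fraction = 100),
                      class = "SpikeDesign")
  p <- c(P01 = 1e-8, P02 = 1e-7, P03 = 0.8, P04 = 0.9)
  cls <- classify_outcomes(p, design, coll, theta = 0.5)
  met <- compute_metrics(cls)
  expect_equal(c(met$recall, met$precision, met$auc), c(1, 1, 1))
  # AUC equals the brute-force pairwise count on random inputs
  set.seed(33)
  for (r in 1:20) {
    n <- 20
    pr <- setNames(round(runif(n), 2), sprintf("P%02d", 1:n)) # ties included
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pos[1] <- TRUE; pos[2] <- FALSE
    rec <- data.frame(pathway_id = names(pr), p_value = unname(pr),
                      q_value = unname(pr), oc = 0, positive = pos,
                      outcome = ifelse(pos, "FN", "TN"), theta = 0.5)
    met <- compute_metrics(rec)
    expect_equal(met$auc, brute_auc(-log10(pr), pos), tolerance = 1e-12)
  }
  # zero discoveries: precision 0 with flag
  p1 <- c(P01 = 0.9, P02 = 0.8, P03 = 0.7, P04 = 0.95)
  met0 <- compute_metrics(classify_outcomes(p1, design, coll, theta = 0.5))
  expect_equal(met0$precision, 0)
  expect_true(met0$no_discoveries)
})

test_that("normalised ranks follow the midrank convention", {
  design <- structure(list(enriched = c("A", "B", "C")), class = "SpikeDesign")
  p <- setNames(seq(0.001, 0.255, length.out = 255), sprintf("P%03d", 1:255))
  names(p)[1:3] <- c("A", "B", "C")
  nr <- normalized_ranks(p, design)
  expect_equal(as.numeric(nr), 2 / 255, tolerance = 1e-12)
  # all-equal p-values: midrank puts the mean at ~0.5
  pe <- setNames(rep(0.5, 10), c("A", "B", "C", sprintf("x%d", 1:7)))
  expect_equal(as.numeric(normalized_ranks(pe, design)), 5.5 / 10)
  # untested enriched pathway gets the worst rank and is flagged
  pu <- setNames(c(0.01, NA, 0.02, 0.5, 0.6), c("A", "B", "C", "d", "e"))
  nru <- normalized_ranks(pu, design)
  expect_equal(attr(nru, "untested"), "B")
  expect_equal(as.numeric(nru), mean(c(1, 4, 2)) / 4)
  # random p-values: mean ~0.5 over repetitions
  set.seed(34)
  vals <- replicate(300, {
    pr <- setNames(runif(12), c("A", "B", "C", sprintf("x%d", 1:9)))
    as.numeric(normalized_ranks(pr, design))
  })
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("the benchmark loop is reproducible and null-calibrated", {
  mm <- std_matrix(30, 24, seed = 35, groups = factor(rep(c("A", "B"), 15)))
  r1 <- run_benchmark(mm, coll20, methods = c("zscore", "svd"),
                      grid_values = c(0, 1), iterations = 3, theta = 0.5,
                      seed = 77)
  r2 <- run_benchmark(mm, coll20, methods = c("zscore", "svd"),
                      grid_values = c(0, 1), iterations = 3, theta = 0.5,
                      seed = 77)
  expect_identical(r1$records, r2$records) # bit-identical under one master seed
  # alpha = 0: recall near zero (only chance BH discoveries)
  null_rec <- r1$records[r1$records$condition == 0, ]
  expect_lte(mean(null_rec$recall), 0.1)
  expect_false(any(r1$records$failed))
})

test_that("ORA and GSEA comparators run inside the benchmark loop", {
  mm <- std_matrix(30, 24, seed = 36, groups = factor(rep(c("A", "B"), 15)))
  r <- run_benchmark(mm, coll20, methods = c("ora", "gsea"),
                     grid_values = 1, iterations = 2, theta = 0.5,
                     n_perm = 100, seed = 5)
  expect_false(any(r$records$failed))
  expect_true(all(r$records$tp + r$records$fp +
                  r$records$tn + r$records$fn == length(coll20)))
})

test_that("pairwise Mann-Whitney tables carry the Bonferroni pair factor", {
  rec <- expand.grid(method = c("m1", "m2", "m3"), iteration = 1:30)
  rec$condition <- 1
  rec$failed <- FALSE
  set.seed(37)
  rec$recall <- runif(nrow(rec))
  rec$recall[rec$method == "m3"] <- rec$recall[rec$method == "m3"] + 0.5
  tab <- pairwise_method_tests(rec, metric = "recall", condition = 1)
  expect_equal(nrow(tab), choose(3, 2))
  expect_equal(tab$p_bonferroni, pmin(1, tab$p_value * 3))
  shifted <- tab[tab$method_b == "m3" | tab$method_a == "m3", ]
  expect_true(all(shifted$p_bonferroni < 0.05)) # +0.5 shift detected at n=30
  # identical values give p = 1
  rec$recall <- 0.5
  tab1 <- pairwise_method_tests(rec, metric = "recall", condition = 1)
  expect_true(all(tab1$p_value == 1))
})
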