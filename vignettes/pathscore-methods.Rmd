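---
title: "Single-sample pathway analysis for metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample pathway analysis for metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional pathway analysis compares two groups of samples and returns one
p-value per pathway. Single-sample pathway analysis (ssPA) instead transforms
the samples × metabolites abundance matrix $X_{n \times m}$ into a samples ×
pathways score matrix $A_{n \times P}$: one enrichment score per sample per
pathway. Scores support multi-group comparisons, per-patient pathway
signatures, clustering, and pathway-level machine learning — analyses that a
single two-group p-value cannot provide. Metabolomics differs from
transcriptomics, where these methods originate, chiefly through far lower
pathway coverage (typically a handful of measured metabolites per pathway)
and noisier feature identities, so method behaviour has to be established
for metabolomics data specifically. `pathscore` provides six scorers, the
conventional ORA/GSEA comparators, a semi-synthetic benchmarking engine for
evaluating any of them, and the downstream clustering/network machinery.

A pathway here is nothing more than a named set of metabolite identifiers
(e.g. ChEBI). All scoring operates on the *measured* member set — the
intersection of the annotated set with the matrix columns — obtained with
`filter_by_coverage()` (default: at least 2 measured members). Full
annotated sizes are retained for reporting via `coverage_report()`.

## Input processing

The expected input is a post-processed untargeted MS matrix. The pipeline
(`preprocess_pipeline()`, each step callable alone) is:

1. **Iterative-SVD imputation** (`impute_iterative_svd()`): missing cells are
   initialised with column means, then repeatedly overwritten with a rank-$r$
   SVD reconstruction until the relative Frobenius change of the imputed
   block falls below `tol` (default `1e-4`, `max_iter = 100`). Observed cells
   are never altered. The rank is not prescribed by the upstream literature;
   the default `min(10, min(n, m) - 1)` is deliberately modest and exposed as
   a parameter. Inside `preprocess_pipeline()` the imputation runs on the
   log2 scale and is back-transformed: intensity data are closer to low-rank
   in log space, and this also guarantees the imputed intensities stay
   positive for the next step.
2. **Probabilistic quotient normalisation** (`pqn_normalize()`): the
   reference spectrum is the per-metabolite median across samples; each
   sample is divided by the median of its quotients against that reference.
   Requires strictly positive raw intensities, hence its position before the
   log transform.
3. **log2 transform and per-metabolite standardisation**
   (`log2_standardize()`): every metabolite ends with mean 0 and sample
   standard deviation 1. The $n-1$ denominator is used throughout the
   package, so z-score pathway scores are exactly reproducible from the
   stated formula.

## The six scorers

All scorers share one contract: `(matrix, coverage-filtered collection) →
PathwayScoreMatrix`, with scores finite, columns matching the filtered
pathways, and output invariant to metabolite column order.

**z-score** — for standardised data,
$a_{ik} = \sum_{j \in p_k} z_{ij} / \sqrt{M_k}$. Self-contained (uses only
member columns), linear, and the fastest of the six.

**SVD (PLAGE)** — scores are the entries of the unit-norm left singular
vector of the pathway submatrix $Z_k$ for its largest singular value,
i.e. the dominant one-dimensional pattern across samples.

**ssGSEA** — per sample, metabolites are ranked by abundance (descending,
average-rank ties, stable order for exact ties) and a weighted
Kolmogorov–Smirnov-like random walk is run down the list: in-set steps climb
by $r^{\alpha}$ (normalised; $\alpha$ = `weight_alpha` = 0.25), out-set
steps fall by $1/(m - M_k)$. The score is the *integrated* running sum —
the convention of the ssGSEA lineage — rather than the extremum, which
distinguishes it from GSVA. An optional global max–min normalisation is off
by default since the upstream literature does not state it was applied.

**GSVA** — three stages: (i) per metabolite, a Gaussian-kernel CDF estimate
across samples with bandwidth $\mathrm{sd}/4$; (ii) per sample, those
statistics are ranked across metabolites and folded into the symmetric rank
statistic $|m/2 - r|$; (iii) a KS-like walk in decreasing statistic order
with in-set weights $|r|^{\tau}$ ($\tau$ = 1). The default enrichment
statistic is max-diff (largest positive plus smallest negative deviation);
`"signed-max"` is available.

**ssClustPA** — for each $Z_k$, 2-means clustering (Euclidean) finds
centroids $c_1, c_2$; samples are projected onto the unit inter-centroid
vector $u = (c_1 - c_2)/\lVert c_1 - c_2 \rVert$, $A_k = Z_k u$. The
projection captures the variation aligned with the dominant two-group
structure in the pathway subspace and discards variation orthogonal to it.
The clustering uses `stats::kmeans` (Hartigan–Wong) with `restarts`
seeded initialisations (default 10) rather than a bespoke k-means++
routine; with a fixed `seed` the output is bit-reproducible. Data whose
samples are all identical in the pathway subspace have no centroid axis and
raise an error.

**kPCA** — an RBF kernel $K_{ij} = \exp(-\gamma \lVert x_i - x_j \rVert^2)$
on the samples of $Z_k$ is double-centred and the first kernel principal
component (leading eigenvector scaled by $\sqrt{\lambda_1}$) is the score
vector. The kernel width default is $\gamma = 1/n$ with $n$ the number of
*samples*, following the method's stated formula; note that common library
defaults use 1/#features instead, so $\gamma$ is an explicit argument. As
$\gamma \to 0$ the scores converge (up to sign and scale) to linear PCA,
which the test suite exercises.

### Sign policy

SVD, ssClustPA and kPCA scores are defined only up to a global sign per
pathway. `sign_policy = "mean-correlation"` flips each column, if needed, so
that it correlates non-negatively with the per-sample mean of its pathway
submatrix. This makes output deterministic; it does **not** make the sign
biologically directional — direction can be recovered, when needed, from a
GSEA-based scorer whose statistic is signed by construction.

## Conventional comparators

`differential_metabolites()` (per-metabolite two-sided t-tests, BH,
`q <= 0.05`) feeds `ora()`, a one-sided Fisher's exact test on the 2×2
membership table. Following the usual ORA convention, only pathways with at
least one differential metabolite are tested, the background is the set of
measured, pathway-annotated metabolites (configurable), and BH runs over the
tested pathways. `gsea()` ranks metabolites by a signed t-statistic, takes
the signed maximum deviation of the weighted KS walk, and computes
significance from sample-label permutations. The permutation p-value is
two-sided on the ES magnitude with the +1 estimator,
$p = (1 + \#\{|ES_b| \ge |ES|\})/(B + 1)$: this keeps the null p-values
uniform, respects the $1/(B+1)$ lower bound, and handles the sign through
the statistic itself. (A sign-conditional tail normalised within its sign
class was considered and rejected: it cannot satisfy both properties at
once.)

## The permute-and-spike benchmark

Real datasets cannot say which pathways are "truly" enriched, so the
engine manufactures ground truth while keeping the data realistic:

1. shuffle the two-group labels, erasing any genuine signal while
   preserving the joint distribution of the features;
2. draw $k = 3$ pathways $E$ at random and add a constant $\alpha$
   (log2 scale, so $\alpha = 1$ is a fold change of 2) to the measured
   members $M_k$ of $E$, in the permuted group B only — optionally to a
   random `signal_fraction`% of $M_k$;
3. score the spiked matrix with each method, run per-pathway two-sample
   t-tests (pooled variance by default, Welch optional), BH-adjust;
4. classify every pathway with the overlap-coefficient truth model and
   compute recall, precision and rank-based ROC AUC
   (score $=-\log_{10} p$, midrank ties).

The truth model uses the Szymkiewicz–Simpson overlap coefficient
$OC(A, B) = |A \cap B| / \min(|A|, |B|)$: a pathway is a positive when it
belongs to $E$ *or* when $OC(M_k, p) \ge \theta$, because a pathway sharing
enough of the spiked metabolites is genuinely perturbed too. Thresholds
$\theta \in \{0.25, 0.5\}$ are the conventional choices. OC is preferred
over Jaccard because containment of a small pathway in a big one should
count as full overlap. Both OC and the truth model operate on measured
member sets, consistent with scoring.

Design choices worth stating explicitly:

* `simulate_dataset()` returns the spiked matrix exactly as defined —
  group-A rows and unspiked columns bit-identical to the input — so the
  fold-change semantics are exact. `run_benchmark(restandardize = TRUE)`
  optionally re-standardises each spiked matrix before scoring; the default
  is off because the generator's base matrices are already standardised, so
  $\alpha$ keeps its log2-fold-change interpretation. Re-standardisation
  slightly shrinks the effective spike (spiked columns gain variance) and is
  reported per mode if used.
* All methods within an iteration share one `SpikeDesign` (paired
  comparison); per-iteration and per-method RNG streams derive from one
  master seed, so a rerun is bit-identical.
* Precision with zero discoveries is recorded as 0 with a flag; iterations
  whose AUC is undefined (one-class) are excluded from aggregation and
  counted. A scorer failure marks the iteration failed with its reason and
  the run continues.
* In the coverage grid, the coverage-reduced exemplar pathway is always
  included in $E$ (plus $k - 1$ random others); otherwise most iterations
  would not exercise the reduced pathway at all.
* `pairwise_method_tests()` compares per-iteration metric values between
  methods with two-sided Mann–Whitney U tests, Bonferroni-corrected over
  the number of pairs.

## Synthetic data: what it does and does not emulate

`generate_base_matrix()` draws standardised Gaussian columns with
block-diagonal equicorrelation (shared per-sample factor construction, so
the block correlation is exact in expectation). The defaults — 260 samples
× 335 metabolites, block sizes 5–20, within-block $\rho_b = 0.3$ — mirror
the shape and modest correlation of a typical post-processed plasma
metabolomics matrix, and are the conditions under which the package's
acceptance checks run. `generate_pathway_collection()` produces either
pairwise-disjoint collections (the non-redundant scenario; a fixed point of
`build_nonredundant_set()`) or shared-pool collections whose pairwise
overlap coefficients spread above and below the usual $\theta$ thresholds
(the redundant scenario).

What the generator deliberately does **not** reproduce: heavy-tailed and
skewed marginals, missing-value structure tied to intensity,
batch/drift effects, and the long-range correlation of real biochemistry.
Passing benchmarks on this stand-in therefore demonstrates the engine's and
scorers' statistical behaviour under controlled conditions, not performance
on any particular real dataset. A raw-scale log-normal marginal with MCAR
missingness is available for exercising the preprocessing chain.

One behaviour the synthetic conditions make visible: competitive scorers
(ssGSEA, and GSVA to a lesser degree) compute a null pathway's score from
the ranks of *all* metabolites, so a strong spike slightly displaces the
out-set ranks and induces a small systematic group difference in null
pathway scores. At large sample sizes the t-test can detect it, costing
these methods some precision relative to the self-contained scorers — the
same ordering of methods the benchmarking literature reports.

## Numerical choices

* t-tests: pooled-variance ("independent two-sample") by default, Welch by
  flag; zero-variance columns with equal means give $p = 1$ by convention
  (with a warning), unequal means $p \to 0$.
* kPCA eigenpairs come from a deterministic power iteration (C++) with
  convergence declared at $1 - |v_t^\top v_{t+1}| < 10^{-9}$, falling back
  to a full `eigen()` if unconverged; the centred RBF kernel is PSD so the
  leading eigenvalue is the spectral radius. A non-positive leading
  eigenvalue (all samples identical) is an error.
* The KS random walks and Gaussian kernel CDFs are implemented in C++
  (`Rcpp`); the kernel CDF exploits $\Phi(d) + \Phi(-d) = 1$ to halve the
  normal-CDF evaluations.
* 2-means with exactly two distinct sample rows uses those rows as the
  (optimal) centroids directly, avoiding degenerate random initialisation.
* Ties: ranking ties use midranks everywhere (walk order additionally
  stable in column order); network t-test ranking ties break by pathway id;
  k-means assignment ties resolve to the lower cluster index inside
  `stats::kmeans`.
* BH is `stats::p.adjust(method = "BH")` applied to the tested (non-`NA`)
  p-values only; untested pathways (possible under ORA) stay `NA`, count as
  not significant, and receive the worst rank in `normalized_ranks()`.

## Downstream analyses

`cluster_scores()` standardises score columns and applies Ward (`ward.D2`)
agglomerative clustering on Euclidean distances, cut at `n_clusters`
(default 2). `adjusted_rand_index()` is the standard chance-corrected Rand
agreement (negative values possible). `cumulative_ari_curve()` ranks
entities by BH q-value, keeps those with `q <= 0.05`, and traces clustering
ARI as entities are added one at a time — the score-level curve typically
dominates the metabolite-level curve when pathway structure carries signal.
`build_correlation_network()` takes the `top_n` pathways by two-group
t-test p-value, clusters their score columns (Ward, 2 branches) for node
grouping, and keeps edges with Spearman $\rho \ge$ `rho_min` (default 0.4).
The threshold is *signed*, read literally from the usual presentation of
such networks; an absolute-value mode exists but is off by default. Node
attributes carry mean standardised scores per sample group and support more
groups than the binary ranking labels (e.g. disease subtypes). Networks
serialise to GraphML (via igraph) or TSV edge lists.

## Problem sizes used by the checks

The packaged acceptance checks run the full engine at 260 × 335 with 100
iterations per condition (18-pathway disjoint and 200-pathway redundant
collections) and 200 iterations for the null-calibration check; unit tests
use matrices from 6 × 6 up to 500 × 60. These sizes were chosen so the
whole suite completes comfortably on a single CPU while keeping the
binomial error of the stochastic checks small relative to their margins.

## Known limitations

* Two-group designs only in the spike engine; multi-group or continuous
  outcomes would need a different effect model.
* No topology-aware scoring; pathways are plain sets.
* No identifier translation: matrix columns and pathway members must share
  a namespace (ChEBI recommended), with only whitespace/case normalisation
  applied.
* ssClustPA assumes two clusters; on structureless data different seeds can
  settle in different 2-means optima, which the seeded restarts make
  reproducible but not seed-invariant.
* The GSVA kernel bandwidth ($\mathrm{sd}/4$) and the ssGSEA weight
  ($\alpha = 0.25$) follow the methods' customary defaults; both are
  exposed rather than tuned.
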