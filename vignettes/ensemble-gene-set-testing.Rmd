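---
title: "Ensemble gene set testing: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble gene set testing: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleGSA)
```

# The problem

Gene set enrichment methods ask whether a predefined set of genes shows
coordinated expression change between experimental conditions. Dozens of
algorithms exist and they disagree: competitive tests (is the set more
associated with the condition than the rest of the genome?) and
self-contained tests (is the set associated at all?) answer different null
hypotheses, and within each family the statistics, null distributions and
sensitivities differ. `ensembleGSA` runs a panel of ten base tests over the
same log-expression matrix and design/contrast specification and aggregates
their p-values and rankings into consensus scores, on the premise —
well-established for this class of tools — that combining methods damps the
idiosyncrasies of any single one and produces fewer false positives when
results are sorted by rank-based consensus scores.

# The model stack

## Gene-level engine

Gene-wise weighted linear models are fitted by least squares (per-gene
weighted normal equations when observation precision weights are present, a
shared QR factorisation otherwise). Contrast estimates `c'beta` and their
unscaled standard errors come from the coefficient covariance. Residual
variances are moderated by the standard empirical-Bayes scaled-F hierarchy:
the moments estimator (digamma/trigamma matching, via `limma::squeezeVar`)
yields prior degrees of freedom `d0` — possibly infinite when the gene-wise
variances are homogeneous — and a prior variance `s0^2`; moderated t
statistics use the posterior variance on `d0 + d` degrees of freedom.
Two-sided p-values are BH-adjusted per contrast. `d0 = 0` can be forced to
recover ordinary t statistics exactly.

For raw counts, the optional preprocessing path applies TMM normalisation
(`edgeR::calcNormFactors`, 30%/5% trims), the conventional
`log2((count + 0.5) / (lib + 1) * 1e6)` log-CPM transform, and
mean-variance precision weights (`limma::voom`, lowess span 0.5, constant
extrapolation, weights clamped to `[1e-6, 1e6]`). Microarray-style inputs
are supported through a detection filter (keep features with detection
p < 0.05 in at least 5 samples by default) and a collapse rule keeping the
highest-mean feature per gene.

## Base methods

All ten base tests are implemented in this package against a common
interface (per set: two-sided p, direction in {-1, 0, +1}, validity flag):

* **ora** — upper-tail hypergeometric test of the overlap between the set
  and the differentially expressed genes (gene FDR < 0.05). When no gene
  passes the cutoff the top 100 genes by p-value stand in as the DE list;
  without this fallback the test degenerates to `p = 1` for every set in
  low-powered experiments, which would poison both its calibration and the
  ensemble aggregation.
* **camera** — competitive pooled two-sample t on gene z-scores
  (probability-transformed moderated t) with the set variance inflated by
  `VIF = 1 + (m - 1) * rho`, `rho` being the mean inter-gene correlation of
  the set's residual rows. The *estimated* path floors the VIF at 1: with
  few residual degrees of freedom the correlation estimate is noisy, and
  spuriously negative averages would deflate the variance and inflate type
  I error (we measured 13% rejection at the 5% level at n = 3+3 without the
  floor, 3.3% with it). A fixed `rho` can be supplied instead (cf. the
  fixed inter-gene correlation used by limma's implementation), in which
  case the floor is the spec-level 1e-3 and `rho = 0` reduces the statistic
  to a plain pooled t.
* **fry** (rotation test) — self-contained. Each gene's standardised
  contrast effect (effect coordinate over effect-plus-residual norm) is
  mapped through its exact scaled-t null into a standard normal z; the set
  statistic is the mean z. Monte-Carlo mode rotates the contrast direction
  uniformly in the effect + residual space — one rotation shared by all
  genes, preserving inter-gene correlation — and applies the identical
  transform to the rotated effects (`p = (1 + #{|S_rot| >= |S_obs|}) /
  (n_rot + 1)`, default 9999 rotations). Analytic mode approximates this
  null by `2(1 - Phi(|zbar| sqrt(m / VIF)))`; the VIF here is exactly the
  device that captures the conditional variance of the rotation null, so
  the two modes agree on independent-gene data (mean |dp| ~ 0.01 at 20 000
  rotations with 18 residual dof). At very small sample sizes (3 + 3) the
  conditional rotation null is too coarse for any normal approximation;
  Monte-Carlo mode is the reference.
* **gage** — competitive Welch t of the set genes' z-scores against all
  other genes, Satterthwaite degrees of freedom.
* **padog** — permutation test of the weighted mean absolute two-group t,
  gene weights `1 + sqrt((f_max - f) / (f_max - f_min))` damping genes that
  occur in many sets of the collection.
* **plage / zscore / ssgsea** — per-sample set scores (first right-singular
  vector of the standardised set submatrix, sign-aligned to member genes;
  sum of standardised values over sqrt(m); weighted running-sum enrichment
  score with rank weights `rank^0.25`, stable ties, global max-min
  normalisation) followed by a shared ordinary-least-squares contrast test
  at the set level.
* **globaltest** — permutation test of the quadratic score
  `||X_set' y_c||^2 / (m y_c'y_c)` against label permutations.
* **safe** — permutation test of the Wilcoxon rank-sum of the set's |t|,
  with the gene statistics recomputed under every label permutation.

Permutation engines enumerate all label splits exhaustively whenever there
are no more than `B` of them (so n = 3+3 always uses the full 20 splits and
permutation p-values are exact, with granularity 0.1 because swapping the
two group labels reproduces the same statistic); otherwise `B` random
splits with the +1 small-sample correction. All stochastic components
derive their own sub-stream from the master seed keyed by method,
collection and contrast, so results are bit-identical for any worker count.

## Consensus scores

Per contrast, the valid per-method p-values of each set are combined
(default **Wilkinson** first order statistic, `1 - (1 - p_min)^k`; also
Fisher, Stouffer's sumz, Edgington's sump via the exact Irwin–Hall CDF,
logit, mean-p, vote counting, and the median order statistic via the Beta
CDF; inputs clipped to `[1e-300, 1 - 1e-15]`; a single p-value is returned
unchanged). Per-method rankings (ascending p, minimum tie rank, invalid
entries ranked last) are aggregated into `min.rank`, `avg.rank`,
`med.rank` (lower median, keeping integer values for even method counts)
and `vote.rank` (modal 5-wide rank bin, ties to the smallest bin).
Set-level fold-change summaries (`avg.logfc`, majority `direction`,
`avg.logfc.dir` over genes matching that direction) and a significance
score — `|avg.logfc| * -log10(p.adj)` min-max scaled to 0–100 within
collection and contrast, all 50 when constant — complete the table. The
cross-contrast comparison combines each method's per-contrast p-values with
the same combiner and then scores exactly like a single contrast, averaging
the fold-change summaries; `avg.logfc.dir` is likewise averaged over
contrasts.

`med.rank` and `vote.rank` are the recommended sort keys: they use the
full panel of rankings and are far less dominated by a single extreme
method than the combined p-value.

# Calibration: what holds and what cannot

On pure-noise data (2000 genes, 200 random sets of 20, n = 3+3, several
seeds) the continuous-statistic methods reject at the 5% level at rates
between 0.03 and 0.06 and pass a KS test against uniformity; the
permutation methods are calibrated at their smallest attainable exhaustive
level (0.1); camera (floored VIF) and ORA (discrete hypergeometric) deviate
only conservatively. The *combined* p-value, however, is not uniform under
the null and cannot be: all base methods test the same data, so their
p-values are strongly positively dependent, which makes sum-type combiners
(Fisher, Stouffer) anticonservative (measured rejection 0.10–0.14) and the
minimum-based Wilkinson combiner conservative (measured 0.017). Correcting
this would require modelling the inter-method dependence, which is out of
scope here; it is also why the rank-based consensus scores, whose planted-
signal behaviour is tested directly, are the recommended sort keys. The
acceptance suite states the nominal band for the combined p-value and
reports the failure rather than widening it.

# The synthetic generator

`make_dataset()` emulates a multi-group log-expression experiment: gene
baselines uniform on [2, 12] log2 units, Gaussian noise with default
`noise_sd = 0.5` (a typical residual sd for normalised bulk expression
data; planted log2 fold-changes of 1.0 are then clearly detectable, the
regime the planted-recovery properties of this package are stated in),
optional exchangeable within-set correlation via a shared latent factor
(the structure competitive VIF corrections exist for), planted effects on a
stated fraction of member genes in the samples loading positively on a
stated contrast, and an optional negative binomial counts mode (dispersion
0.1) for the TMM/voom path. It does *not* emulate library-size artefacts,
batch effects, outlier samples, or realistic gene–gene correlation beyond
the set-level factor — so passing tests demonstrate correctness of the
statistics under their assumed sampling models, not robustness to real-data
pathologies.

Problem sizes used by the test suite and the acceptance script (2000 genes,
200 sets, 3–10 seeds, 9999–20000 rotations, exhaustive permutations at
n = 3+3) were chosen to make Monte-Carlo tolerances small relative to the
asserted bands while keeping the whole suite comfortably reproducible on a
single CPU.

# Numerical choices and degenerate inputs

* p-values are clipped to `[1e-300, 1 - 1e-15]` before log/logit
  transforms; z-scores saturate at |z| = 37.
* Zero pooled variance in two-group statistics yields t = 0 (null), and a
  degenerate competitive comparison (all z equal) yields p = 1.
* Zero-variance genes are dropped from PLAGE sets with a warning; a set
  empty after dropping is flagged untestable, as are sets whose contrast
  cannot be reduced to two groups for permutation methods.
* Sets failing every method are dropped from the score table with a
  warning and excluded from BH.
* Gene-set indices are 1-based internally (idiomatic R; reports only ever
  show gene identifiers, so the convention is invisible externally).
* GMT member lists are tokenised on tabs only; duplicate members are
  dropped keeping first occurrence; the description field may be empty.
* The mean-variance trend behind the precision weights is assessed on the
  sqrt-sd scale: weights are the fourth power of the fitted trend, so even
  a few percent of trend-estimation noise fans out to tens of percent in
  the weights themselves.

# Known limitations

* GSVA's kernel-density scoring is not implemented (requesting `gsva`
  fails with a clear error), and roast's full statistic family is reduced
  to the mean-statistic rotation test described above.
* The ensemble combined p-value is a ranking device, not a calibrated
  error rate (see above); `p.adj` inherits this.
* ID mapping is exact string matching; no species-aware conversion is
  attempted, and no gene set content is bundled.
* The HTML report is deliberately static (no interactive widgets); colour
  semantics are emitted as categorical keys so renderers can restyle.

# A minimal session

```{r example, eval = FALSE}
d <- make_dataset(n_genes = 2000, groups = c(A = 5, B = 5), n_sets = 200,
                  set_size = 20,
                  planted = list(list(set = "SET_001", contrast = "AvsB",
                                      logfc = 1, fraction = 0.5)),
                  seed = 1)
ci <- build_index(d$sets, rownames(d$em$E), min_size = 5,
                  name = "Synthetic sets", label = "syn")
res <- gsa_analysis(d$em, d$design, d$contrasts, list(ci), seed = 1)
top_sets(res$collections$syn$tables$AvsB, sort_by = "med.rank", n = 10)
generate_report(res, "report-dir", number = 20)
```
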