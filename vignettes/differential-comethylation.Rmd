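---
title: "Differential co-methylation network analysis with comethnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-methylation network analysis with comethnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(comethnet)
```

`comethnet` decides, for each trait-associated co-methylation module, whether
its network topology changed between two time points (typically before and
after a treatment), using two statistically independent routes: permutation
module preservation and a generalized Hamming distance (GHD) test. This
vignette is the package's account of the model, its assumptions, the
synthetic world used for validation, and every numerically consequential
design choice.

## 1. The model, stage by stage

### Kinship LMM residualization

Family cohorts induce correlation between relatives at every probe. Per
probe, with beta values $y$ (or, for the screen, log-triglycerides):

$$ y = X\beta + g + e,\qquad g \sim N(0, \sigma_g^2 K),\qquad
   e \sim N(0, \sigma_e^2 I), $$

where $K$ is the expected-relatedness matrix (twice the kinship
coefficient; `build_kinship()` implements the tabular pedigree recursion)
and $X$ contains intercept, age (years), sex, field-center dummies, smoking
status, and optionally the first `n_pcs` principal components of the beta
matrix. REML estimation eigendecomposes $K$ once per cohort and optimizes
the single parameter $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ by Brent's
method (tolerance $10^{-8}$, boundary $h^2 = 0$ admitted; at $K = I$ the
profile is flat in $h^2$ and the tie-break selects $h^2 = 0$, so the model
collapses exactly to OLS).

**Residual type.** Networks are built from *conditional* residuals
$y - X\hat\beta - \hat g$ (BLUP subtracted). Marginal residuals
$y - X\hat\beta$ still carry family covariance, which would inflate
correlation edges between probes with shared heritable variation;
`lmm_residuals(type = "marginal")` is available for comparison. Residuals
are centered per probe before network construction.

**Wald screen.** The triglyceride screen keeps probes with nominal Wald
p < 0.05 (t reference with $n-p$ degrees of freedom) for the probe
coefficient, deliberately without multiplicity correction: an FDR-level
screen would discard probes whose relevance only appears through network
structure. The regression direction (logTG as outcome, probe as predictor)
follows standard lipid-EWAS practice; `outcome = "probe"` flips it. The
screen adjusts for the same covariates as residualization, including the
PCs.

### Quality control

* probes with residual variance below
  $10^{-10} \cdot \max|\text{residuals}|$ are dropped;
* samples with strictly more than half missing residuals are dropped;
* sample outliers: average-linkage clustering on Euclidean distance,
  flagging everything outside the largest cluster at `cut_height`. The
  `"auto"` height is **mean + 4 SD of merge heights**, not an upper
  quantile: a fixed quantile flags the top merges on *any* data, including
  perfectly homogeneous cohorts (we measured 20/160 clean samples flagged
  at the 99th percentile), whereas mean + 4 SD flags nothing unless a merge
  is genuinely extreme. A numeric cut height reproduces fixed published
  choices.

### Network construction

Unsigned adjacency $a_{ij} = |r_{ij}|^\beta$ on pairwise-complete Pearson
correlations (pairs with < 3 shared samples are zeroed with a warning).
$\beta$ is the smallest candidate power whose scale-free fit $R^2$ exceeds
0.9, where the fit regresses $\log_{10}$ bin frequency on $\log_{10}$ mean
connectivity over 10 equal-width bins and the index is sign-flipped so a
decaying degree distribution scores positively; if nothing passes, the
argmax is used with a warning. Topological overlap

$$ \mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
   {\min(k_i,k_j) + 1 - a_{ij}} $$

and modules come from average-linkage clustering of $d = 1-\mathrm{TOM}$.
The dissimilarity is $1-\mathrm{TOM}$, not $1-$adjacency: TOM is computed
precisely to de-noise the adjacency before clustering, so clustering the
raw adjacency would discard it (a flag restores that variant).

**Tree cut.** The reference dynamic hybrid tree-cut algorithm is
parameterized in ways the upstream description leaves open, so the package
implements a transparent height-scan variant: candidate static cuts are
taken between successive merge heights and the *lowest* cut producing the
maximal number of branches of size `min_module_size` (default 30) wins;
later merges attach loose probes and background, which remain unassigned
(label 0, grey). The low tie-break matters: preferring higher cuts absorbs
background probes into modules (planted-partition ARI drops from ~0.85 to
~0.5–0.7 in our experiments). Labels are renumbered by descending module
size with color aliases (pink, blue, brown, yellow, green, red, ...).
Whole-matrix computation is used with a probe-count guard rather than
block-wise chunking; desk-scale inputs (≤ 20,000 probes) fit in memory.

### Module preservation

For each module, four statistics: two density statistics evaluated in the
test network (mean within-module correlation; mean within-module adjacency)
and two connectivity statistics comparing reference and test restricted to
the same probe set (correlation of intramodular connectivity vectors
$k^{IM}_i=\sum_{j \in M} a_{ij}$; correlation of the vectorized
within-module correlation entries). The permutation null assigns each
module a random probe set of its own size — in *both* networks for the
comparative statistics, which is what makes them well defined probe-by-
probe and matches the label-permutation null of the preservation
literature. Then $Z = (\text{obs}-\mu_0)/\sigma_0$ per statistic,
$Z_{density}$ and $Z_{connectivity}$ are medians within their pair,
$Z_{summary}$ their average; $> 10$ strong preservation, 2–10 weak, $< 2$
none. `medianRank` is the median over statistics of the module's rank
(rank 1 = highest observed value, average ties) and is permutation-free —
the same result for any seed, which the tests assert. A null standard
deviation at or below $10^{-12}$ (e.g. test network identical to the
reference) yields $Z = \pm\infty$ with a warning rather than a spurious
finite value driven by floating-point jitter.

### GHD test

Both correlation matrices restricted to a module are binarized at
$|r| \ge \tau$ (default $\tau = 0.2$, boundary inclusive; a flag makes it
exclusive), converted to one-step topological-overlap weights (same formula
as TOM with zero diagonal; an isolated pair gets weight 0), and compared by

$$ \mathrm{GHD} = \frac{1}{n(n-1)}\sum_{i\ne j}
   \left(\bar w^A_{ij} - \bar w^B_{ij}\right)^2, $$

with each weight matrix centered by its off-diagonal mean so the statistic
is location-invariant. The null permutes node labels of the pre-treatment
network — equivalently permutes rows/columns of its weight matrix, since
relabeling commutes with the weight computation, so weights are computed
once. Monte-Carlo moments (default 1000 permutations) standardize the
observed value, $z = (\mathrm{GHD}-\mu_\pi)/\sigma_\pi$, with two-sided
normal p-value $2(1-\Phi(|z|))$. Two-sidedness is not arbitrary: it is the
only choice that reproduces every printed p-value of the source test table
from its printed Z scores (e.g. $z = 2.609 \to p = 0.009$; one-sided would
give 0.0045). Under the null the two module networks are *independent*;
rejecting at the Bonferroni level $\alpha/m$ therefore concludes the module
did **not** change. Preserved modules sit far in the left tail (observed
GHD below the null mean). Degenerate nulls — e.g. a saturated or empty
binarized module, where every permutation gives the same distance — raise a
classed condition and yield NA results instead of a fake p-value.

### Enrichment

Changed modules are mapped probe→gene (deduplicated, unannotated probes
counted and dropped) and tested per pathway with
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeometric}(N, K, n)$, BH-FDR across
pathways; both raw p and FDR are reported. The background is the gene set
mapped from the *screened* probes, not the whole array, matching the
screened-universe design. Plain hypergeometric is used (no probe-number
bias correction): the per-gene probe count is available in the annotation
output so a biased-urn variant can be added later.

## 2. The synthetic world

`simulate_study()` generates the stated world the tests run in:

* **Families.** 50 nuclear families of 4 (2 founders, 2 full sibs), i.e.
  200 pre-treatment samples; the post-treatment visit keeps a random 55%
  (mirroring a 530-of-995 dropout pattern).
* **Probes.** 600 probes, six planted modules of sizes 60, 50, 45, 40, 35,
  30 — a majority of probes outside modules, echoing an application where
  14,049 of 14,850 screened probes belonged to no module. A module-dominated
  matrix would also inflate the preservation permutation null (random probe
  sets would mostly consist of module probes).
* **Latent model.** Probe $i$ in module $m$:
  $z_i = \sqrt{h^2} g_i + \sqrt{1-h^2}\,(\lambda_i f_m +
  \sqrt{1-\lambda_i^2}\,\varepsilon_i)$ with kinship-correlated $g_i$,
  per-sample factor $f_m$, heritability $h^2 = 0.3$, and heterogeneous
  loadings $\lambda_i = \sqrt{\rho}\, u_i$, $u_i \sim U(0.5, 1)$,
  $\rho = 0.7$. Heterogeneity is essential, not cosmetic: with near-uniform
  loadings every within-module $|r|$ exceeds the GHD threshold 0.2, the
  binarized module is a complete graph, and the GHD permutation null is
  degenerate. Thresholding at 0.2 is described upstream as yielding a
  *nearly scale-free* network, which presupposes hub structure; $U(0.5,1)$
  loadings provide it, with hub pairs correlating at the $\rho$ scale.
  Betas are $\mathrm{logit}^{-1}$ transforms of the latent values around
  probe-specific baselines, so they live strictly in $(0,1)$.
* **Rewiring.** Modules ranked 3, 5 and 6 by size are "rewired" at the
  second time point: each of their probes moves onto its own independent
  factor, preserving marginal moments but destroying all within-module
  co-methylation. We deliberately do *not* merely redraw loadings on the
  same shared factor: that keeps the module internally correlated, leaves
  density statistics high, and contradicts the behavior a rewired module
  must show ($Z_{summary} < 2$, pre/post correlation patterns uncorrelated).
* **Phenotype.** logTG loads on every module factor (0.6 on the phenotype
  module, 0.4 on the rest) plus covariates and kinship-correlated noise
  (SD 0.5). The shared coupling is what lets a nominal p < 0.05 screen
  retain ~98% of module probes at $n = 200$, the way a real screened
  universe carries its modules; it is a test-harness choice, not a claim
  about any particular cohort's genetic architecture.
* **Covariates.** age $\sim U(20, 70)$, sex Bernoulli(0.5), three field
  centers (0.40/0.35/0.25), smoking Bernoulli(0.25), with latent-scale
  effects (age 0.01/year around 45, sex 0.25, center 0.2, smoking 0.3).
* **Batch (optional, off by default).** `n_batches` rank-`n_batches`
  technical components with total per-probe latent variance `batch_var`;
  the latent scale is standardized before squashing so batch does not
  saturate the betas.

### PCs and the synthetic world

The 10-PC adjustment exists to remove *technical* structure. The default
synthetic world plants none, and on a 600-probe matrix the six module
factors are the dominant variance directions — regressing out 10 PCs
removes the modules themselves (measured: planted-partition ARI collapses
from ~0.9 to ~0.03). All synthetic-world analyses therefore use
`n_pcs = 0`, while `n_pcs = 10` remains the default for real data, whose
top PCs are technical. With planted batch (`n_batches = 10`), the estimated
top PCs span the true batch score subspace and PC adjustment removes the
batch-induced spurious background correlation; but at desk scale the
squashed batch and module eigenvalues are not cleanly separable, so PC
adjustment also absorbs part of the module signal. This trade-off is
inherent to PC-based batch removal when biology is low-rank, and is exactly
why the batch-free world is analyzed without PCs.

### What a green test does and does not establish

The generator produces Gaussian-latent, logit-squashed betas with exact
one-factor modules, exchangeable families of constant size, covariates
independent of modules, and missingness only through sample dropout. It
does not emulate probe-type chemistry, genomic autocorrelation, cell-type
composition, or batch effects beyond low-rank components. Green tests
establish that the statistics separate planted preserved from planted
rewired structure under realistic noise, kinship and dropout — not that
they would do so under every failure mode of array data.

## 3. Numerical choices

* REML: Brent on $h^2 \in [0, 1-10^{-6}]$, tolerance $10^{-8}$; the
  returned optimum is asserted (in tests) to be at least as good as a
  21-point grid of the exact likelihood.
* Kinship eigendecomposition is reused across probes within a cohort;
  probes with missing values fall back to a per-probe decomposition of the
  complete-case submatrix.
* PSD tolerance for $K$: smallest eigenvalue $\ge -10^{-8}$, negatives
  clipped to 0.
* Correlations on pairwise-complete observations; pairs with fewer than 3
  shared samples or zero variance are zeroed and counted.
* `detect_modules` tie-break: lowest qualifying cut (see above); a
  homogeneous dissimilarity yields 0 or 1 module and must not crash.
* medianRank ties: average ranks.
* Per-stage seeds are derived deterministically from the single global seed
  and logged, so `run_pipeline()` output is byte-identical across reruns.
* Permutation defaults: 200 (preservation) and 1000 (GHD) — enough for
  |Z| thresholds at 2/10 and Bonferroni decisions at 0.00833; the GHD
  normal approximation is validated against 2000-permutation empirical
  p-values (agreement within 0.02 for $|z| < 3$).

## 4. Known limitations

* The tree cut is a simplified height-scan, not the full dynamic hybrid
  algorithm; very nested module structures may be split or merged
  differently.
* GHD moments are Monte-Carlo; closed-form null moments exist in the
  literature and would remove permutation cost (extension point).
* Only one-step topological overlap weights are implemented for GHD;
  higher-order overlap is future work upstream as well.
* Enrichment ignores per-gene probe counts (no Wallenius correction).
* The LMM supports a single random effect (kinship); no GxE or repeated
  measures.
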