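---
title: "Supervised principal-component risk scores for resected colorectal liver metastases"
author: "survMRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised principal-component risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survMRS)
```

# The problem

After complete resection of colorectal cancer metastases confined to
the liver, long-term outcomes vary enormously: some patients are cured,
others recur in the liver remnant and die within two to three years.
The established clinical risk score (CRS) — one point each for a
node-positive primary, a disease-free interval under 12 months,
preoperative CEA above 200 ng/ml, more than one hepatic tumour, and a
largest tumour above 5 cm, with a sum of 3 or more called high risk —
stratifies these outcomes only moderately well.  This package
implements, end to end, the construction and validation of a
**molecular risk score (MRS)** from tumour gene expression that is
intended to complement the CRS for two censored endpoints:
disease-specific survival (DSS) and liver-recurrence-free survival
(LRFS).

# The model

## Supervised principal components

The MRS follows the supervised principal-components recipe for
censored outcomes.  On the training cohort:

1. every gene is standardized (mean 0, SD 1 on training samples) and
   screened with a univariate Cox proportional-hazards model; the Wald
   statistic $z_g = \hat\beta_g/\widehat{se}_g$ is the *standardized
   Cox coefficient* of gene $g$;
2. genes with $p < \alpha$ survive, where the operating cutoff
   $\alpha$ is chosen by cross-validation (below), with $p < 0.001$
   the canonical operating point;
3. the first principal component of the selected genes' standardized
   training submatrix defines per-gene loadings $w_g$, and
   $\mathrm{MRS}_i = s\sum_g w_g\,(x_{gi}-c_g)/\sigma_g$ with centers
   $c_g$, scales $\sigma_g$, and a global sign $s\in\{+1,-1\}$ fixed
   so the score has a positive Cox coefficient on the training data
   (principal components are sign-indeterminate; this rule resolves
   the ambiguity identically on every run).

A second weight mode (`weight_mode = "coef"`) uses $w_g = z_g$
directly.  Both readings are supported because the originating
literature describes the score both as a first principal component and
as a combination weighted by standardized Cox coefficients; the two
estimate the same supervised direction and the package asserts their
training-score correlation in its test suite rather than claiming
either is uniquely correct.

The training **median** MRS is frozen as the dichotomization
threshold: it is robust to extreme scores and puts exactly half of an
even-sized training cohort in each group.  Scores strictly above the
threshold are high risk; a score exactly at the threshold goes to the
low-risk group (a deterministic convention — the realized median is a
sample score whenever $n$ is odd).

## Freeze discipline

Everything needed to score a new sample — gene list, centers, scales,
weights, orientation, threshold — lives in the `SignatureModel`
object, so scoring test samples cannot touch test outcomes even by
accident.  The same discipline is available at the normalization
layer: `normalizeCohort(cohort, split = ...)` quantile-normalizes the
training samples jointly and rank-maps test samples onto the frozen
training reference (`QuantileReference`).  Joint whole-cohort
normalization is also provided, since the original study most likely
normalized all arrays before splitting; the frozen mode is the default
offered for new deployments because it cannot leak test-set
distributional information.

## Cross-validated threshold selection

`cvSelectThreshold()` evaluates a grid of candidate cutoffs
(default $p \in \{10^{-2}, 10^{-2.5}, 10^{-3}, 10^{-3.5}, 10^{-4}\}$,
bracketing the canonical $10^{-3}$) by K-fold cross-validation
(default $K = 5$, folds seeded and stratified by event status).
Genes are **re-screened within each fold's training part** — reusing a
whole-training screen would leak the held-out fold's outcomes into
gene selection — the fold-trained direction scores the held-out
samples, and the Cox score statistic (squared score-test $z$ at
$\beta = 0$) of that held-out score is averaged over folds.  The
cutoff with the largest mean statistic wins; ties break toward the
stricter cutoff.  A fold whose training part has fewer than two events
is redrawn, with an error after a retry limit.

## Validation

Test samples are scored with the frozen model and summarized by:
Kaplan–Meier product-limit curves per risk group with the log-rank
test; Harrell's concordance index of the continuous MRS and of the
CRS (permissible pairs are those where the shorter observed time is an
event; pairs with tied times and both events are excluded; with a tied
time and exactly one event the event counts as earlier; score ties
count 1/2 — conventions pinned in `concordanceIndex()` and verified
against exhaustive pair enumeration); a multivariate Cox model with
the dichotomized CRS (≥ 3) and MRS (above threshold) giving hazard
ratios with normal-approximation 95% intervals; and the combined
stratification — both scores high → high, both low → low, otherwise
intermediate — with 3-year survival per group.

## Competing risks

For LRFS, cancer death without liver recurrence precludes observing
recurrence.  Cause-specific screening treats such deaths as censoring;
`screenGenes(..., analysis = "finegray")` instead fits the Fine–Gray
subdistribution hazard for recurrence via the
inverse-probability-of-censoring-weighted data expansion
(`survival::finegray()`) with robust standard errors, and
`comparePvalueSets()` correlates the two per-gene p-value sets.  When
no competing events exist the two analyses coincide exactly, a
reduction the test suite checks to $10^{-6}$ and cross-checks against
`cmprsk::crr`.

# The synthetic-cohort generator

`simulateCohort(simulationConfig(...))` emulates a resected
colorectal-liver-metastasis series with known ground truth.

**Expression.** Genes × samples Gaussian log-intensity-like values
(baselines uniform on 6–10, per-gene SD `noise_sd`, default 1).  The
`n_prognostic` planted genes (default 20) are noisy readouts of one
latent per-sample factor $u \sim N(0,1)$:
$x_g = \sqrt{\rho}\,u + \sqrt{1-\rho}\,\varepsilon_g$ with
`latent_cor` $\rho = 0.5$ by default.  This latent-module structure is
deliberate and is the generative model supervised principal components
is designed for: a single underlying risk process read out by a
co-expressed gene module.  Planting *independent* prognostic genes
instead would make each gene's marginal association collapse — with 20
independent genes at per-SD log hazard ratio 0.7 the total linear
predictor has SD $0.7\sqrt{20}\approx 3.1$, and the unmodelled
remainder acts as a massive frailty that attenuates every single-gene
coefficient far below its conditional value — while the latent-module
structure concentrates the marginal signal exactly as co-expression
does in real tumours.  A `mode = "raw"` variant returns unlogged
intensities with per-sample scale factors to exercise the
normalization path.

**Outcomes.** Event times are exponential with rate
$h_0\exp(\eta)$, $\eta = \beta\sum_{g\in\text{planted}} \tilde x_{gi}
+ \gamma\cdot(\text{adverse-factor count})$, where $\tilde x$ is
standardized expression, $\beta$ = `effect_size` (per-SD log hazard
ratio, default 0.5), $\gamma$ = `clinical_effect` (default 0.3, which
gives the CRS genuine prognostic value), and $h_0$ =
`baseline_hazard` (default 0.02 per month, putting median event times
on the tens-of-months scale of the disease).  Censoring is an
independent exponential whose rate is solved numerically so the
expected censored fraction equals `censoring_rate` (default 0.4,
matching roughly 60% cancer-specific events over follow-up).  For
LRFS, a Bernoulli(`competing_hazard_fraction`, default 0.15 — the
observed share of cancer deaths without liver recurrence) subset of
events is relabelled as competing, keeping event times fixed; this
directly controls the quantity the competing-risks diagnostic is
sensitive to.

**Clinical factors.** Five independent Bernoulli draws at prevalences
0.59, 0.53, 0.08, 0.60, 0.23 (the reported frequencies of the five
adverse factors in a 96-patient series).

**What the generator does not emulate.**  Probe-level artifacts,
batch effects, chemotherapy-induced expression changes, correlated
clinical factors (real adverse factors co-occur, so the real-world
fraction of CRS ≥ 3 — about 39% — exceeds the ~28% that independent
draws at the same prevalences produce), administrative end-of-study
censoring (the exponential censoring law has long tails), non-random
timing of competing deaths (relabelling is uniform over events, so
synthetic competing deaths can occur earlier than real extrahepatic
deaths typically do), and non-exponential hazard shapes.  Passing
tests therefore establish that the estimators and the pipeline are
correct and well calibrated under a proportional-hazards truth — not
that any particular discrimination level will be achieved on a real
cohort.

# Numerical choices

* **Cox fitting.** Newton–Raphson on the Efron-corrected partial
  likelihood (Efron being the modern default for tied event times),
  vectorised across genes as dense matrix products so a full
  microarray's worth of genes screens in well under the minute range;
  convergence at score $|U| \le 10^{-10}$ (reported tolerance
  $10^{-8}$), steps damped to $\pm 2$, and fits with a monotone
  likelihood (e.g. a covariate separating the earliest deaths) are
  flagged `converged = FALSE` rather than silently reported.
  `survival::coxph` is the independent cross-check in the tests, never
  the screening implementation.
* **Degenerate genes.** Zero-variance covariates return the convention
  $\beta = 0$, $se = \infty$, $p = 1$, flagged, never selected.
* **Wald tests** are used throughout screening for speed and
  comparability of $z_g$ across genes.
* **Quantile normalization.** The reference is the across-sample mean
  of per-sample sorted values; runs of tied values receive the mean of
  the reference entries their ranks span; idempotence holds to
  $10^{-9}$.  The implementation is in-package because the frozen
  reference must be re-applicable to single new samples, which the
  standard joint implementations do not expose; `limma` is the
  cross-check on the joint path.
* **Ranking ties** (equal $|z|$) break lexicographically by gene id;
  cross-validation ties break toward the stricter cutoff; threshold
  ties score low — every tie rule is deterministic, so identical
  inputs reproduce identical artifacts bit for bit.
* **The 2:1 split** rounds toward the training set
  ($n_\text{test} = \lfloor n/3\rfloor$) and is uniformly random given
  its seed; stratification by event status is available but off by
  default, since the emulated design used a plain random assignment.

# Test and validation problem sizes

The test suite exercises the pipeline at sizes chosen to make its
statistical assertions sharp but quick: screening calibration pools
ten 2,000-gene null cohorts of $n = 150$; planted-gene recovery uses
ten cohorts with 20 planted genes at per-SD log hazard ratio 0.7;
end-to-end discrimination runs twenty 1,000-gene cohorts of $n = 225$
split 2:1, requiring held-out concordance above 0.65 and a significant
log-rank split in at least 18 of 20; the competing-risks diagnostic
averages ten cohorts at the emulated training-set size ($n = 60$,
half censored, 15% competing) and expects a Cox/Fine–Gray p-value
correlation of at least 0.95 — a deliberately demanding bound, since
the correlation dips whenever a random draw lands many early competing
events; small-sample oracles (grid-search partial likelihood,
exhaustive concordance enumeration, hand-computed product-limit and
log-rank instances) pin the estimators exactly.

# Limitations

The package validates methodology on synthetic cohorts; it makes no
claim about which genes matter in real disease, and gene lists
selected from any single small cohort are expected to be unstable.
Overall (any-site) recurrence-free survival is deliberately out of
scope: the pipeline permits the attempt, but no adequate signature is
promised — in the motivating setting none could be found.  Hazard
ratios from small test sets can be monotone-likelihood-inflated (the
multivariate Cox fit then warns); the concordance index and log-rank
test are the more trustworthy small-sample summaries.
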