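# survMRS

Supervised principal-component survival modelling for gene-expression
cohorts, built around the prognostic question faced after curative
liver resection of metastatic colorectal cancer: can a tumour's
expression profile predict disease-specific survival (DSS) and
liver-recurrence-free survival (LRFS) beyond the established clinical
risk score?

## The method

The pipeline constructs a **molecular risk score (MRS)** on a training
cohort and validates it frozen on held-out samples:

1. **Screening.** Each gene *g* is standardized and tested for
   univariate survival association with a Cox proportional-hazards
   model; genes with Wald *p* < α survive.  The operating cutoff α is
   chosen by K-fold cross-validation over a grid bracketing
   *p* < 0.001, maximizing the held-out Cox score statistic of the
   fold-trained score.
2. **Signature.** The selected genes' training submatrix is centered
   and scaled, and the MRS is the first principal component of that
   submatrix (per-gene loadings *w_g*):
   `MRS_i = s · Σ_g w_g (x_gi − c_g)/σ_g`, oriented (sign *s*) so that
   higher MRS means higher hazard on the training data.  A second
   weight mode uses the standardized Cox coefficients *z_g* as
   weights.  The training **median** MRS is frozen as the high/low
   threshold.
3. **Validation.** Test samples are scored with the frozen model —
   nothing re-estimated — and assessed by Kaplan–Meier curves,
   log-rank tests, Harrell's concordance index, and a multivariate Cox
   model alongside the five-factor **clinical risk score (CRS)**
   (node-positive primary, disease-free interval < 12 months,
   CEA > 200 ng/ml, > 1 tumour, size > 5 cm; a sum ≥ 3 is high risk).
   CRS and MRS classes combine into a three-group stratification
   (both high / both low / mixed).
4. **Competing risks.** For LRFS, cancer death without liver
   recurrence competes with recurrence.  Screening can be repeated
   with Fine–Gray subdistribution regression and the per-gene
   p-values compared with the cause-specific Cox ones.

Because a real cohort is private by nature, the package ships a
first-class synthetic-cohort generator (`simulateCohort()`): planted
prognostic genes share a latent risk factor, hazards follow an
exponential proportional-hazards model with independent exponential
censoring tuned to a target rate, and a configurable fraction of LRFS
events is relabelled as competing.  Ground truth is recorded in the
cohort metadata, so recovery, calibration and discrimination are all
testable.

## Worked example

```r
library(survMRS)

## simulate a 96-patient cohort with 20 planted prognostic genes
cohort <- simulateCohort(simulationConfig(n_samples = 96, n_genes = 1000,
                                          effect_size = 0.5, seed = 42))
cohort
#> MRSExperiment: 1000 genes x 96 samples
#>   DSS events: 58/96; LRFS events: 50/96 (competing: 9)
#>   planted prognostic genes: 20

## 2:1 train/test split, then fit and freeze the signature
split <- splitCohort(colnames(cohort), seed = 42)
train <- cohort[, split$train_ids]
outcomes <- dssOutcomes(train)

cv <- cvSelectThreshold(exprsMatrix(train), outcomes, seed = 42)
model <- fitSignature(exprsMatrix(train), outcomes,
                      cutpoint = cv$cutpoint, weight_mode = "pc1",
                      endpoint = "dss", cv = cv$cv)
model
#> SignatureModel (dss, weight mode 'pc1')
#>   32 genes selected at p < 0.01
#>   orientation -1, MRS threshold -0.2723

## frozen-model validation on the held-out third
test <- cohort[, split$test_ids]
report <- buildReport(computeMRS(model, test),
                      computeCRS(clinicalFactors(test)),
                      dssOutcomes(test), endpoint = "dss")
report
#> ValidationReport (dss, test cohort)
#>   concordance: MRS 0.957, CRS 0.583
#>   log-rank high vs low MRS: chi2 = 30.11, p = 4.08e-08
#>   3-year survival by combined CRS+MRS group:
#>     intermediate 31%
#>     low          89%
#>     high         0%
```

Reading the output: cross-validation kept the lenient *p* < 0.01
cutoff, which admitted all 20 planted genes plus 12 passengers; on the
32 held-out patients the continuous MRS has concordance 0.96 (0.5 is
chance), the frozen median split separates survival with log-rank
*p* ≈ 4·10⁻⁸, and the combined CRS+MRS groups order 3-year survival
89% / 31% / 0% (low / intermediate / high).  The planted signal here
is strong; weaker `effect_size` values give correspondingly weaker
discrimination.

`runPipeline(config, outdir)` chains the whole thing — simulate (or
read TSV/CSV inputs), optional log2 + quantile normalization with a
frozen training reference, split, screen, train, score, validate — and
writes every artifact (signature JSON, screening TSV, score CSVs,
report JSON, manifest with a config hash) to `outdir`.

## The methods vignette

`vignettes/methods.Rmd` describes the generating model, every tunable
parameter with its default and rationale, the numerical conventions
(tie handling, convergence tolerances, orientation and threshold
rules), and what the synthetic cohorts do and do not establish about
real data.
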