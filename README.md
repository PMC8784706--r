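# etioscope

Soft clustering and etiological-process modelling for newly diagnosed type 2
diabetes (T2D).

T2D is heterogeneous: insulin deficiency, obesity, insulin resistance and
globally severe dysglycaemia coexist in one cohort, and most patients sit
between these poles rather than in any single box.  `etioscope` implements a
soft-clustering view of that heterogeneity for cohort studies with rich
baseline phenotyping: each subject is represented as a convex combination of
a small number of *archetypes* — extreme multivariate phenotype profiles —
so that the k per-subject archetype scores are non-negative and sum to 1.
Around that core it provides the full analysis pipeline such a study needs:
variable transformation and pruning, stability-based model selection, group
assignment, β-cell function modelling from meal tests, HbA1c progression
modelling, and association screens — plus a synthetic cohort generator with
recorded ground truth, so every estimator in the package is testable by
parameter recovery.

## The model at the core

Archetypal analysis decomposes a subjects-by-phenotypes matrix
`X ≈ A Z` with

* `A` (n × k): per-subject scores, rows on the probability simplex
  (`A ≥ 0`, `A 1 = 1`),
* `Z = B X` (k × m): archetypes constrained to the convex hull of the
  observations (`B` rows on the simplex),

fitted by alternating constrained least squares minimizing
`RSS = ‖X − A Z‖²_F`.  The inner step — simplex-constrained least squares —
is solved by Lawson–Hanson non-negative least squares on a system augmented
with a heavily weighted sum-to-one row (compiled, in `src/`).  A robust
variant downweights observations by Tukey bisquare weights of their residual
norms.  The number of archetypes is chosen from an RSS scree together with a
subsampling stability protocol: refit on random 90% subsamples, match
archetypes to the full-data fit by cosine similarity, label subjects by
thresholded membership, and score agreement with the adjusted Rand index
(ARI) across membership thresholds.

Beyond clustering:

* **β-cell model** (`fit_beta_cell_model`): insulin secretion rate
  `ISR(t) = P(t)·f(G(t)) + r·max(dG/dt, 0)` with a piecewise-linear dose
  response `f`, a positive potentiation factor `P` constrained to average 1
  over the test, and rate sensitivity `r`; fitted to mixed-meal tolerance
  test (MMTT) C-peptide curves by regularized least squares through a
  two-exponential C-peptide kinetics kernel, with smoothing/regularization
  weights chosen to match the assay errors (~1% glucose, ~4% C-peptide).
* **Progression model** (`fit_progression`): conditional linear mixed-effects
  model of HbA1c trajectories — per-subject random slopes plus
  sign-constrained fixed effects for BMI (≥ 0), metformin dose, other
  glucose-lowering drugs and insulin (≤ 0), with a 30-day medication
  effectiveness lag.
* **Association harness**: marginal score–phenotype OLS, Kruskal–Wallis and
  Mann–Whitney tests for extreme groups, logistic odds of medication use,
  an omics screen with Benjamini–Hochberg FDR control, and weighted
  (partitioned) genetic risk scores.

## Worked example

```r
library(etioscope)

## a 726-subject synthetic cohort with four latent archetypes
co <- generate_cohort(cohort_config(n_subjects = 726, seed = 42))

model <- best_of_restarts(co$phenotypes$values, k = 4, n_restarts = 20, seed = 1)
model
#> Archetypal analysis model (robust)
#>   k = 4 archetypes over 32 variables, 726 observations
#>   RSS = 3930.05 after 9 iterations (converged)

table(assign_extreme_groups(model$scores))
#>   A   B   C   D MIX
#>  96  98 102 100 330

match_archetypes(co$truth$archetype_profiles, model$archetypes)$similarity
#> 0.997 0.998 0.998 0.998
```

Every subject's four scores sum to 1; 330 of 726 subjects have no score
above 0.6 and form the mixed-etiology group, which
`assign_mixed_groups()` further splits into the 12 ordered
primary/secondary pairs.  The cosine similarities show the fitted archetypes
recover the generator's latent profiles almost exactly.

```r
rec <- generate_mmtt(beta_cell_truth(), seed = 7)
fit_beta_cell_model(rec)
#> Beta-cell secretion model fit
#>   glucose sensitivity: 83.8 pmol min^-1 m^-2 L mmol^-1
#>   secretion at 8 mmol/L: 245.7 pmol min^-1 m^-2
#>   rate sensitivity: 677 pmol m^-2 L mmol^-1
#>   potentiation ratio (2h/0h): 1.00
#>   basal / total secretion: 140.8 pmol min^-1 m^-2 / 51.6 nmol m^-2
#>   C-peptide residual SD: 2.81% (lambda = 1e+06, target not bracketed)
```

Here the true glucose sensitivity was 84: the dose-response slope is
recovered, while the flat potentiation ratio illustrates that per-subject
potentiation is only weakly identified from a single 2-h curve (see the
methods vignette for the identifiability discussion).

## Package layout

* `R/synthetic.R` — cohort/MMTT/HbA1c/omics/genotype generators with truth
* `R/preprocess.R` — rank-inverse-normal transform, residualization, pruning
* `R/archetypes.R`, `src/nnls.cpp` — archetypal analysis core
* `R/stability.R` — scree, ARI, subsampling stability, pruning search
* `R/grouping.R` — extreme/mixed groups, transition flows
* `R/glycemic.R` — β-cell secretion model
* `R/progression.R` — constrained HbA1c mixed model
* `R/association.R` — association screens, FDR, genetic risk scores
* `vignettes/etioscope-methods.Rmd` — models, assumptions, design choices
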