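# nutrimorph

Does nutritional status leave a measurable trace in the shape of the
face? `nutrimorph` is an R package and analysis workflow for linking
dietary condition — nutrient intakes estimated from a food-frequency
questionnaire (FFQ), eating-behavior scales, and body composition — to
three-dimensional facial shape in a geometric-morphometrics framework.
It is written for biostatisticians and morphometricians who want a
fully tested, end-to-end reimplementation of this analysis chain that
runs on synthetic cohorts with known planted structure, since cohort
data of this kind are typically restricted.

## What it computes

**Nutrition.** Daily intake of 53 nutrient items is estimated per food
group as

    intake = portion size (g) × amount-category weight × weekly frequency / 7 × nutrient density (per g)

with amount weights No = 0, "A little" = 0.5, Normal = 1, Plenty = 1.5,
cooking-method items as extra table rows, and household salt-taste
multipliers ×1.15 (equal to restaurant food) / ×1.3 (saltier). Seven
oil and fatty-acid ratios, percent-energy shares, body-composition
indices (BMI, fat %, FFMI, FMI with FFMI + FMI = BMI), and 7
eating-behavior scale sums from a 55-item questionnaire complete the
dietary picture.

**Morphometrics.** Landmark configurations are superimposed by
generalized Procrustes analysis (GPA: position, size and orientation
removed; centroid size CS kept as the size measure), then decomposed
into shape principal components (sPCs) retained by the Kaiser criterion
capped at 90% cumulative variance. A 16-variable inter-landmark
distance panel (normalized to exocanthion width) summarizes classical
facial proportions.

**Sexual shape dimorphism.** Each face is scored by projection onto a
male-minus-female reference axis,

    SShD(F⃗ᵢ) = (F⃗ᵢ − midpoint) · F⃗₍m−f₎ / |F⃗₍m−f₎|² ,

so the male reference mean scores +0.5 and the female mean −0.5, and
decomposed into an allometric (size-predicted, via multivariate
regression of shape on CS) and a non-allometric part that sum exactly
to the total.

**Inference.** Forward stepwise selection of sPCs for each dietary and
body variable (entry p < 0.05), MANCOVA via Wilks' Λ with Rao's F
approximation and partial η² = 1 − Λ^(1/s), canonical correlation
analysis with sequential Wilks tests, k-means clustering of nutrition
PCs + behavior sums with elbow selection of k, one-way ANOVA with
Tukey–Kramer post-hoc tests, and Benjamini–Hochberg FDR control.

**Synthetic cohorts.** `cohort_spec()` / `generate_cohort()` produce
cohorts with three planted dietary patterns (balanced low-calorie,
high-calorie, imbalanced low-calorie), diet-coupled body composition,
and faces carrying planted allometry and pattern-specific shifts along
the dimorphism axis — so every stage of the chain can be tested against
known truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated 115-woman cohort:

```sh
Rscript analysis/01_simulate.R      # cohort + male/female reference
Rscript analysis/02_nutrition.R     # nutrient profiles, behavior, body
Rscript analysis/03_morphometrics.R # GPA, shape PCA, distance panel
Rscript analysis/04_inference.R     # stepwise, MANCOVA, CCA, clustering
Rscript analysis/05_dimorphism.R    # SShD decomposition, per-code tests
```

Output of a full run (seed 20130514):

```
retained 7 shape PCs explaining 91.2 % of variance
retained 7 nutrition PCs
MANCOVA: Wilks lambda = 0.348, F(66, 529.8) = 1.75, p = 0.0005, partial eta^2 = 0.161
CV1: r = 0.48, Wilks lambda = 0.49, F(49, 517.2) = 1.59, p = 0.008
elbow chose k = 3 ; code sizes: 35 33 47
adjusted Rand index vs planted patterns: 1
sshd_total           F(2, 112) =  5.10, p = 0.0076, eta^2 = 0.084
sshd_allometric      F(2, 112) =  2.98, p = 0.0547, eta^2 = 0.051
sshd_nonallometric   F(2, 112) = 61.16, p = 0.0000, eta^2 = 0.522
```

Reading: the shape and nutrition spaces each reduce to seven
components; the dietary variables are multivariately related to facial
shape (MANCOVA, CCA); clustering recovers the three planted dietary
patterns exactly (adjusted Rand index 1.0); and the dietary codes
differ in the *non-allometric* (size-independent) part of sexual shape
dimorphism while total and allometric SShD barely do — the imbalanced
low-calorie pattern is shifted toward the masculine end of the axis.
All result tables are written under `results/`.

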