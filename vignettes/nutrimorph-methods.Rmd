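---
title: "Methods: linking nutritional status to 3D facial shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking nutritional status to 3D facial shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrimorph)
```

## The scientific question and the analysis chain

Facial morphology reflects genetics, hormones and environment; among
environmental factors, nutritional status is a candidate with plausible
biological routes (adiposity, sex-steroid metabolism in adipose
tissue). `nutrimorph` implements the analysis chain used to probe this
question in cohorts of young women: quantify each subject's dietary
condition (FFQ-estimated nutrient intakes, eating-behavior scales,
body composition), quantify facial shape in a Procrustes morphospace,
and connect the two by direct multivariate inference (stepwise
selection, MANCOVA, canonical correlation) and by indirect comparison
(cluster subjects into dietary patterns, then compare faces across
patterns, including sexual shape dimorphism scores).

Because cohort data of this kind are not publicly deposited, the
package pairs the analysis with a synthetic-cohort generator whose
planted structure makes every stage falsifiable.

## Nutrient estimation

Daily intake of nutrient $k$ is

$$\text{intake}_k=\sum_{g}\ \text{portion}_g\ w(\text{amount}_g)\ \frac{\text{freq}_g}{7}\ d_{gk},$$

with category weights $w$ = 0 / 0.5 / 1 / 1.5 for No / A little /
Normal / Plenty, cooking-method items entering as table rows at weight
1, and salt and sodium multiplied afterwards by the household-taste
factor (1.0 lighter, 1.15 equal, 1.3 saltier than restaurant food).
Fifty-three items are reported. Forty-three come straight from
per-gram densities; ten are derived: the percent-energy shares use
Atwater factors (4/9/4 kcal per g of protein/lipid/carbohydrate)
against the table's own energy column, since no conversion is specified
by the source methodology; carotene and tocopherol equivalents use the
standard composition-table conventions
($\beta$-carotene eq = $\beta$ + ($\alpha$ + cryptoxanthin)/2,
retinol eq = retinol + $\beta$-eq/12, tocopherol eq with weights
1/0.4/0.1/0.01). Seven oil and fatty-acid ratios are computed over
class totals (animal/vegetable/fish oil over total oil; SFA/MUFA/PUFA
over total fatty acids; n-6/n-3). The methodology this follows
announces six ratios but enumerates seven; all seven are implemented.

The bundled composition table
(`inst/extdata/food_composition_synthetic.csv`,
`synthetic_food_composition()`) is **synthetic**: 29 food groups and 10
cooking types with plausible magnitudes. Licensed national composition
tables are not redistributable; users can substitute any table in the
same schema.

The 55-item eating-behavior questionnaire is scored as per-category
sums over 7 scales. The published item-to-scale map lives in
supplementary material that is not reproduced, so the default map
splits items as evenly as possible (8,8,8,8,8,8,7) and is fully
configurable. Missing items are an error — no imputation.

## Geometric morphometrics

`gpa()` performs full generalized Procrustes analysis: every
configuration is centred and scaled to unit centroid size
($CS=\sqrt{\sum_i\|x_i-\bar x\|^2}$, the size measure kept aside),
rotated to the current mean by the orthogonal (Kabsch) solution, and
the mean is re-estimated until its RMS change falls below $10^{-10}$
(cap 100 iterations; the count is reported). Two numerical choices
matter:

* **Reflections are disallowed** (rotation determinant forced
  positive). Anatomical configurations must never be mirrored; a
  configuration that would prefer a reflected fit triggers a warning
  rather than a silent flip.
* **Unit-size scaling** (full Procrustes) is used because size is
  analysed separately through CS.

Shape PCA (`fit_shape_space()`) retains
$k=\min(\text{Kaiser count},\ \text{smallest }k\text{ reaching }90\%)$.
The literal Kaiser rule (eigenvalue > 1) is only meaningful for
correlation matrices, and Procrustes coordinates have arbitrary scale;
the package therefore uses the covariance matrix with
"eigenvalue > mean eigenvalue" as the Kaiser analogue for shape, and
the correlation matrix with the literal rule for nutrient intakes
(heterogeneous units). Both modes are exposed; which one the original
study used is unstated.

The inter-landmark panel implements **16 unique variables**: twelve
linear distances normalized to exocanthion width and four shape
ratios. The published list of 17 contains a typographic duplicate
(one ratio appears twice); the unique-16 reading is documented, not
asserted as the original authors' intent. Distances from a midline
landmark to a bilateral pair use the mean of the left and right
distances.

Pose normalization maps a face into the anatomical frame — nasion at
the origin, lateral axis from the exo/endocanthion left–right
direction, vertical axis from the least-squares plane through
exocanthions, porions and subnasale — and is invariant to rigid
motions of the input. It feeds the distance panel; GPA does not
require it.

## Sexual shape dimorphism

With a male–female axis $\vec F_{(m-f)}$ (male mean minus female mean),

$$\mathrm{SShD}(\vec F_i)=\frac{(\vec F_i-\text{midpoint})\cdot\vec F_{(m-f)}}{\|\vec F_{(m-f)}\|^2}.$$

The published formula leaves the origin of the projection unstated; the
package centres at the male/female midpoint so the two reference means
score symmetrically at $\pm0.5$ (configurable). The conventional
reading of scores beyond $\pm1$ as hyper-masculine/feminine is reported
but not used for any decision.

The allometric/non-allometric decomposition regresses shape vectors on
CS (multivariate linear regression). A subject's **allometric** score is
the projection of $\hat b\,(CS_i-\overline{CS})$ — the size-predicted
deviation from the mean-size prediction — onto the axis, and the
non-allometric score is the remainder, so the two sum to the total
exactly and a zero fitted slope yields zero allometric scores. External
references are carried into a cohort's Procrustes frame by rigid
alignment onto the consensus (`align_to_mean()`) before the axis is
built; projections would otherwise mix orientation with shape.

## Inference chain

* **Stepwise selection** is forward-only with entry at partial-F
  p < 0.05, since an inclusion criterion is the only stated rule; no
  removal step (a bidirectional variant was considered and rejected as
  unstated). Collinear candidates are dropped with a message.
* **MANCOVA** follows the design in which the selected dietary/body
  variables form the multivariate response and the selected sPCs the
  predictors, matching the single overall F reported in this kind of
  analysis. Wilks $\Lambda=\det E/\det(E+H)$ with Rao's F
  approximation; partial $\eta^2=1-\Lambda^{1/s}$, which for a
  single-root effect reduces to $1-\Lambda$. Per-predictor tests are
  drop-one (type III) Wilks tests, exact for single-df hypotheses.
* **Canonical correlation** uses the SVD of the whitened
  cross-covariance $S_{xx}^{-1/2}S_{xy}S_{yy}^{-1/2}$; roots are tested
  sequentially ($\Lambda_k=\prod_{i\ge k}(1-r_i^2)$, Rao F). Whether
  the original analysis tested roots jointly or sequentially is not
  fully stated; sequential is implemented. The first face-side weight
  vector is reconstructable into a shape vector for visualization.
* **Clustering** standardizes nutrition PC scores plus the seven
  behavior scale sums (sums, not raw items), runs Lloyd k-means with 25
  seeded restarts per candidate k, and picks the elbow as the interior
  candidate maximizing the second difference of the within-cluster
  sum-of-squares curve — the named method comes without a criterion, and
  the maximal-curvature reading is the least parametric one. A k whose
  WSS is numerically zero is preferred outright; empty-cluster fits are
  re-seeded with a message.
* **ANOVA / Tukey–Kramer / BH** use the standard `stats`
  implementations (`aov`, `TukeyHSD`, `p.adjust`), with
  $\eta^2 = SS_b/SS_t$ and Tukey–Kramer q statistics valid under
  unequal group sizes. Hand-computed step-up and studentized-range
  oracles verify them in the test suite.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` plants exactly the structure the analysis assumes:

* **Three dietary patterns** (balanced low-calorie, high-calorie,
  imbalanced low-calorie) in proportions 42/41/32 per 115. Pattern
  nutrient means are the intakes implied by three pattern-level
  food-group frequency profiles through the synthetic table; the
  generator *inverts* the intake formula (non-negative least squares
  back to expected frequencies, Poisson frequencies, amount categories
  with expected weight 1) so the estimator is exercised end to end.
* **Diet-coupled body composition**: higher fat mass in both unhealthy
  patterns, with high FFMI in the high-calorie pattern (obesity
  tendency) and high FMI / low FFMI in the imbalanced pattern
  (sarcopenic-obesity tendency).
* **Faces**: unit shape = template + pattern shift along a fixed
  masculinity field + allometric slope × (CS − mean CS) along the same
  field + smooth individual variation + isotropic landmark noise, all
  emitted at the drawn centroid size in template pose.

Two generator choices deserve emphasis. First, all planted fields are
built in the **Procrustes tangent space** of the template (orthogonal
to translation, scaling and rotation directions); otherwise
superimposition partially absorbs them and mixes individual variation
into the dimorphism projection. Second, landmark noise alone would
give a flat eigen-spectrum in which the Kaiser/90% rule retains
half the matrix rank; real facial variation is smooth and low-rank, so
subjects carry independent coefficients (SD `individual_sd`/√j) on 8
fixed smooth deformation fields, with the isotropic term (default
0.3 mm) kept as measurement error. Under the defaults this produces
roughly 7–8 retained sPCs, the order observed in real facial samples.

Default conditions: n = 115 subjects; 60 landmarks (the full
several-thousand-vertex mesh density is supported but not needed for
correctness); CS SD 15 mm; allometric slope 8×10⁻⁴ unit-shape per mm;
dimorphism shifts (0, −8×10⁻⁴, +1.2×10⁻³) unit-shape units — about
1–2 within-cluster SDs on the SShD scale, detectable but not trivial;
reference male–female separation 0.04 unit-shape units. One global
integer seed drives all streams through independent sub-streams, so
generating fewer streams never perturbs the others.

The generator does **not** emulate: the covariance texture of real
faces (the deformation fields are arbitrary smooth modes), skin or
texture information, measurement artifacts such as hair occlusion,
FFQ reporting biases (under-reporting, social desirability), or any
hormonal mechanism — group differences are planted geometrically, not
biologically. Passing tests therefore demonstrate that the *pipeline*
recovers known structure of the stated form, not that the biological
claims hold in any real population.

## Numerical and degenerate-input policy

GPA convergence $10^{-10}$ RMS / 100 iterations; pose normalization
rejects missing or collinear anchors; `centroid_size()` requires two
points; correlation-mode PCA rejects constant columns; `mancova()`
rejects singular residual matrices and clamps $\Lambda$ into
$(0,1]$ against rounding; canonical analysis rejects rank-deficient
sides (reduce to PC scores first); zero-frequency FFQs are valid and
yield zero intakes with all ratio denominators guarded; behavior
scoring rejects (rather than imputes) missing items;
`decompose_sshd()` requires varying CS. Report writing refuses to
overwrite a directory containing a completed manifest.

## Problem sizes in the verification suite

The test and acceptance computations use cohorts of 30–300 subjects at
60 landmarks, 400 Monte-Carlo replicates for the dimorphism power
study and 1000 replicates for the null calibrations (stepwise entry
with 3 candidates at n = 200; BH over 10 uniform p-values;
Tukey–Kramer with 3 × 20 null observations) — sizes chosen so the
planted-recovery checks have tight sampling error while the whole
suite runs in minutes.

## Known limitations

The MANCOVA response/predictor split is one of several defensible
readings of the source design; the panel's unique-16 interpretation and
the even behavior-scale split are documented guesses where the source
is ambiguous; the ±1 hyper-masculinity thresholds inherit an unstated
scaling convention from earlier work and are surfaced only as
annotations; and the synthetic composition table is plausible, not
authoritative — absolute intake levels should not be interpreted
nutritionally.
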