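---
title: "Quantifying floral symmetry with landmark morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying floral symmetry with landmark morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalmorph)
```

## The problem

Corolla symmetry in the Core Goodeniaceae (the Australian fan-flowers and
their relatives) spans three informally named forms: *fan* flowers with all
five petals swept to the ventral side of the dorsal slit, *bilabiate*
flowers with the two dorsal petals well separated from the lateral + ventral
group, and *pseudo-radial* flowers with roughly equal angles between all
five petals. These labels are subjective, and the transitions between them
look continuous. petalmorph implements a landmark-based geometric
morphometrics pipeline that turns a set of head-on flower photographs into
an objective, low-dimensional description of corolla symmetry: each flower
is reduced to five landmarks (one per petal apex), superimposed, decomposed
into bilaterally symmetric and asymmetric parts, and embedded in a
morphospace whose two leading axes describe dorsal-petal spread and
lateral-petal spread.

## The model, stage by stage

**Superimposition.** `gpa()` performs generalized Procrustes analysis:
every configuration is centered, scaled to unit centroid size (the square
root of the summed squared landmark distances from their centroid), and
iteratively rotated to the running consensus until the root-mean-squared
consensus movement falls below `tol` (default `1e-8`, `max_iter = 100`).
Only proper rotations are used; reflection is a modelled biological effect
here, not a nuisance, and is handled by the symmetry module. The 2-D
rotation subproblem has the closed form
$\theta = \operatorname{atan2}\!\big(\sum_i (x_i y'_i - y_i x'_i),\,
\sum_i (x_i x'_i + y_i y'_i)\big)$, which `align_pair()` exposes directly.
Aligned shapes are optionally (default on) projected orthogonally onto the
tangent space at the consensus, so that Euclidean multivariate statistics
apply; at the variance scale of flower photographs the projection changes
results negligibly, but the switch keeps the behaviour testable.

**Object symmetry.** A flower is a single structure with an internal
midline, so asymmetry is quantified by the reflection-relabelling
construction: `reflect_relabel()` negates the x-coordinates and swaps the
members of each mirror pair (dorsal left/right, lateral left/right; the
ventral landmark is self-paired). `decompose_symmetry()` runs one joint GPA
over the doubled set of originals and reflected copies, exactly symmetrizes
the consensus, and defines each specimen's *symmetric component* as the mean
of its two aligned copies and its *asymmetric component* as the remainder.
Two exact identities follow by construction and are asserted in the tests
at `1e-9`: symmetric + asymmetric reconstructs the aligned original, and
the symmetric component is a fixed point of `reflect_relabel()`.

Component sizes are reported in the specimen's original units: the
symmetric centroid size is the centroid size of the symmetric component
scaled back by the specimen's original centroid size, and the asymmetric
centroid size is the root summed squared asymmetric displacement scaled the
same way. The scaling convention matters only for the absolute numbers; the
asymmetric/symmetric ratio reported by `asymmetry_summary()` is scale-free.

**Procrustes ANOVA.** `procrustes_anova()` partitions the summed squared
Procrustes deviations of the doubled aligned set into a species effect
(variation among species mean symmetric shapes), a side effect (the
reflection main effect, i.e. directional asymmetry) and a residual
(within-species symmetric variation plus fluctuating asymmetry). Degrees of
freedom are the effect's level count minus one times the dimension of the
relevant shape subspace; those subspace dimensions are obtained numerically
as the rank of the corresponding component covariance rather than from a
closed-form count (for five landmarks in 2-D both the symmetric and the
asymmetric subspace have dimension 3). F ratios are Goodall-type, each
effect against the residual mean square; a seeded permutation test over
species labels is available as a self-contained nonparametric check.
Because each specimen is digitized once, the side effect is estimated from
the original-versus-reflected contrast and an individual-by-side
(fluctuating asymmetry) term cannot be separated from the residual — that
would require replicate landmarking.

**Shape PCA and reconstruction.** `shape_pca()` performs PCA on the
covariance matrix (not the correlation matrix) of the flattened symmetric
components about the consensus. All $2k$ components are kept internally —
zero eigenvalues included — while reports and clustering use the first
`n_retained` (default 2). `reconstruct()` maps a score vector back to a
landmark configuration (consensus plus score-weighted eigenvectors), and
`project()` is its inverse on the retained span; `morph_path()`
interpolates configurations between two morphospace positions, e.g. between
the mean fan and the mean non-fan flower.

Eigenvector signs are arbitrary, so `orient_axes()` fixes the convention:
+PC1 increases the dorsal separation angle of the reconstructed shape
(ventralizing the dorsal petals, towards the fan form) and +PC2 decreases
the lateral separation (ventralizing the lateral petals, towards the
bilabiate form). Angles are measured by `inter_petal_angles()` at the
configuration centroid between adjacent petal direction vectors; the five
adjacent angles sum to 360 degrees, the dorsal separation is measured
through the dorsal midline (the side with the dorsal slit) and the lateral
separation through the ventral petal. Note that an angle at the landmark
centroid is smaller than the angle between the same petals at the flower's
tube center when the landmarks are displaced to one side (a fan archetype
with petal directions 170 degrees apart at the tube center has a
centroid-measured dorsal separation of about 126 degrees — still comfortably
above the 120-degree fan criterion). The centroid convention is used because
the tube center is not itself a landmark and cannot be recovered from the
five apices alone.

**Morphotype clustering.** `cluster_morphotypes()` is a seeded wrapper over
`stats::kmeans` (default seed 42, 100 restarts, best run by within-cluster
sum of squares), applied to individual flowers, with species summaries
derived afterwards. With `k = 3`, `name_clusters()` names the clusters from
their center geometry — largest center PC1 is *fan*; of the remaining two,
larger center PC2 is *bilabiate*, the other *pseudo-radial* — and then
renumbers the codes 1 = fan, 2 = pseudo_radial, 3 = bilabiate. The numeric
codes exist only so that species mean cluster codes are comparable across
runs and with the published species table (whose text and figure captions
disagree with its own table about which code is bilabiate and which
pseudo-radial; the package follows the table's arithmetic and treats names,
not codes, as canonical). Majority ties at species level break toward the
lower code with a warning.

**Group statistics.** The clade comparisons use classical tests behind one
uniform result type: Wilcoxon rank sum (exact for small tie-free samples,
normal approximation with tie and continuity corrections otherwise),
Bartlett, Levene (mean-centered by default, as in the original test;
median-centering gives the Brown–Forsythe variant by flag), one-way ANOVA
with plain and group-count-adjusted $R^2$, and ordinary least squares for
the species-level allometry checks (mean corolla length against mean
centroid size and PC scores). Species flagged as outgroups participate in
superimposition, PCA and clustering but are excluded from clade
comparisons.

## The synthetic-flower generator

`simulate_flowers()` exists so every pipeline stage can be validated
against known ground truth. Its generative model is deliberately the model
the pipeline assumes: a species is an archetype (fan, bilabiate,
pseudo-radial, encoded as mirror-symmetric petal angles) perturbed along
two latent symmetric axes — dorsal spread and lateral spread, in degrees —
with Gaussian between-species and within-species variation; each image adds
per-landmark Gaussian coordinate noise (the only source of asymmetry) and a
random similarity transform (the photographic nuisance).

Defaults emulate the published study's sampling structure: 45 species split
17 fan / 18 bilabiate / 10 pseudo-radial (the subjective label counts),
image counts drawn around 7.4 ± 3.3 per species (clipped to 1–14),
between-species SD of 8 degrees and within-species SD of 3 degrees on both
latent axes, and free rotation, translation up to two petal radii and scale
0.5–2. The asymmetric noise SD defaults to 0.06 petal radii, chosen so the
decomposed synthetic data reproduce the asymmetric-to-symmetric
centroid-size ratio of roughly 4 percent that the real corollas show; fan
species are assigned to one clade and the others to the second, mirroring
the real clades' composition. The default archetype angles (dorsals at
±36/±30/±85 degrees and laterals at ±108/±150/±130 degrees from the dorsal
midline for pseudo-radial/bilabiate/fan) are package configuration chosen to
satisfy the verbal geometry of the three forms, not measurements of real
species.

What the generator does *not* emulate: petal outlines and landmark
placement error correlated along outlines, perspective and parallax from
imperfect head-on photography, recurved three-dimensional corollas (which
the real bilabiate species often have), unequal sampling across clades, and
any allometric coupling between size and shape. Passing the synthetic
recovery tests therefore shows the pipeline's estimators are correct under
the stated model, not that five landmarks suffice for any particular real
clade.

## Numerical choices

- GPA convergence is RMS consensus movement per coordinate below `1e-8`,
  at most 100 iterations; non-convergence warns and is flagged, never
  silently accepted.
- The doubled-set consensus is symmetrized exactly (averaged with its own
  reflection) before the final alignment pass, and the aligned reflected
  copies are constructed as exact reflections of the aligned originals —
  reflection and row permutation are exact floating-point operations, which
  is what makes the decomposition identities hold to machine precision.
- Orientation is standardized by rotating the solution so the midline
  vector (ventral landmark to mid-dorsal point) points along +y; for a
  symmetric consensus this is a flip decision only, so it cannot break the
  symmetry.
- Zero eigenvalues are retained in the shape PCA; rank decisions elsewhere
  use a relative `1e-8` eigenvalue threshold.
- Degenerate inputs error early and specifically: configurations with zero
  centroid size, landmarks coincident with the centroid in angle
  computations, a constant regressor, zero-variance groups in Bartlett's
  test, exact ties in the deciding cluster-center coordinates.

## Design decisions where the design was open

- **Axis identifiability in the recovery tests.** With equal latent SDs on
  both axes the in-span shape covariance is nearly isotropic and the PCA
  rotation within that span is statistically unidentifiable — no method
  could match PCs to axes. The axis-recovery simulation therefore makes the
  dorsal axis dominant (between-species SD 8 vs 4 degrees, within 3 vs 1.5),
  as in the real data where the dorsal axis carries most of the variance,
  and uses the bilabiate base archetype, whose two latent shape directions
  are the closest to orthogonal of the three (tangent-space cosine about
  −0.12, versus −0.30 for pseudo-radial and −0.61 for fan).
- **Sampling sizes in tests.** Unit tests run on datasets of roughly 10–60
  images; the acceptance checks use the full study-scale default (about 45
  species, 300+ images), a 240-image axis-recovery scenario, a 180-image
  clustering scenario, and 500-replicate null simulations with three groups
  of 200 for the type-I-error calibration (the group size at which Levene's
  F holds its nominal level; it is mildly liberal in very small samples).
- **Cluster-code numbering** follows the published table's arithmetic
  (1 = fan, 2 = pseudo_radial, 3 = bilabiate), as discussed above.
- **Input orientation** is taken as-is on read (no y-flip): superimposition
  and the symmetry decomposition are orientation-agnostic, and the final
  orientation is standardized explicitly.

## Limitations

- Five petal-apex landmarks capture petal placement, not petal shape,
  fusion depth, or three-dimensional posture; strongly recurved corollas
  are flattened into the image plane.
- Directional asymmetry and fluctuating asymmetry cannot be separated
  without replicate digitization of the same flowers.
- The fan / bilabiate / pseudo-radial naming rule assumes the three
  clusters occupy their usual morphospace regions; on data where that
  geometry does not hold, `name_clusters()` should not be trusted blindly
  (it errors only on exact ties).
- Reproducing the published study's numerical results end-to-end requires
  its deposited raw landmark coordinates (S1 Table of
  doi:10.1371/journal.pone.0154736), which are not redistributable with the
  package; the corresponding acceptance test documents the expected values
  and runs whenever that file is placed at
  `inst/extdata/s1_raw_landmarks.tsv`. The published species-level summary
  table ships with the package (`goodeniaceae_table1()`) and its counts,
  discordance pattern and clade means are verified exactly.

## A worked example

```{r example, fig.width = 6, fig.height = 5}
sim <- simulate_flowers(simulation_config(seed = 1))
fit <- fit_floral_symmetry(sim$dataset)
fit

head(fit$summaries)
fit$comparison
fit$anova

plot(fit)
```
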