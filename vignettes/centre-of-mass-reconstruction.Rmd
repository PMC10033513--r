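---
title: "Volumetric centre-of-mass reconstruction and its comparative statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric centre-of-mass reconstruction and its comparative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullcom)
```

## The problem

Whole-body centre of mass (CoM) is a first-order determinant of
locomotor mechanics in bipeds and fliers: where the mass sits relative
to the hip decides limb posture, joint moments and flight stability.
For living animals, CoM can be measured from image-based volumetric
models — closed "skin volume" meshes of each body segment, assigned
plausible tissue densities. For fossils only the skeleton survives, so
a living animal's shape has to be inferred around it. The minimum
convex hull (MCH) method does this reproducibly: wrap each body
segment's skeletal elements in their convex hull, then inflate that
hull to a predicted skin volume using hull-to-skin relationships
measured in extant relatives. hullcom implements this pipeline end to
end — mesh mass properties, hull construction, segment-specific
expansion models, the reconstruction grid, and the phylogenetic
comparative statistics applied to the resulting trait tables — plus a
synthetic-body generator that provides analytic ground truth for every
stage.

## Coordinate and measurement conventions

All geometry is in metres, converted at I/O (`read_mesh(units =)`).
The body frame is fixed throughout: **+x cranial, +z dorsal, +y
left**. The hip reference is the midpoint of the left and right
acetabular joint centres. From a whole-body CoM at `(x, y, z)`:

* `cc_com = x - hip_x` — cranio-caudal offset, positive cranial;
* `dv_com = hip_z - z` — dorso-ventral offset, positive ventral.

Both are normalised by `body_mass^(1/3)`, the dimensionally consistent
exponent for a length (a printed "0.33" is read as the exact 1/3; the
exponent is configurable via `norm_exponent`). Segment lengths are
joint-centre to joint-centre distances; sternum depth and length come
from three labelled landmarks (cranial, caudal, keel).

## Mesh mass properties

`mass_properties()` integrates volume and centroid by signed
tetrahedron decomposition against the origin (divergence theorem).
This is exact for closed polyhedra, origin-independent, and transforms
covariantly under rigid motion. `validate_mesh()` enforces the
preconditions: watertightness (every edge shared by exactly two
faces), consistent winding, and connectivity. A *globally* inverted
mesh is repaired by flipping all faces (a sign symmetry); *mixed*
winding is a hard error, because silently "fixing" it can flip the
sign of individual tetrahedra and corrupt the volume. The independent
check on all of this is `monte_carlo_volume()`: rejection sampling
with parity ray-casting containment, sharing no code with the
divergence-theorem path.

`convex_hull()` is an incremental (Quickhull-class) construction with
an interior-point orientation guard; its contract is enforced not by
the algorithm but by brute-force facet containment
(`hull_contains()`), which the test-suite applies to seeded random
point sets. All geometric tolerances are expressed relative to the
bounding-box diagonal, so models digitised in millimetres behave
identically to models in metres.

## Density scenarios

Three segment-density schemes are applied as sensitivity iterations:

| scenario | neck | torso | all other segments |
|---|---|---|---|
| standard | 800 | 850 | 1000 |
| homogeneous | 1000 | 1000 | 1000 |
| group-varying (non-avian sauropsid) | 850 | 900 | 1000 |
| group-varying (HLD bird) | 825 | 875 | 1000 |
| group-varying (FLD bird) | 800 | 850 | 1000 |

(kg m^-3). The lightened neck and torso account for respiratory
structures (lungs, air sacs); the group-varying scheme probes
postulated density reduction from skeletal pneumaticity along the bird
line. Note the group-varying values for FLD birds coincide with the
standard scheme.

## Hull expansion

Per body segment, three predictive model classes relate hull volume to
skin volume on training taxa with both geometries:

* `mean_ratio` — the arithmetic mean over taxa of per-taxon skin:hull
  volume ratios (the raw expansion factor);
* `ols_loglog` — `log10(skin) = a + b log10(hull)` by OLS (the
  conventional allometric form for volume–volume relations);
* `pgls_loglog` — the same regression under a Brownian-motion
  phylogenetic covariance.

Left and right limb volumes are pooled per taxon before fitting. No
back-transform bias correction is applied by default (the uncorrected
regression predicts the median response); a log-normal smearing
correction is available via `predict_skin_volume(correct_bias = TRUE)`.

Reconstruction (`reconstruct_taxon()`) crosses a set of volume models
with the density scenarios; the standard grid of four volume models
(all-taxa, birds-only and non-avian-only equations, plus the all-taxa
mean ratio) and three density scenarios yields **12 iterations per
fossil**. Each segment hull is inflated *isotropically about its own
CoM*, so a segment's CoM is invariant to its expansion: any other
centre would inject an arbitrary directional shift that the data
cannot constrain. Paired segments preserved on one side only are
mirrored across the sagittal plane before aggregation (logged in the
result). Whole-body mass is the sum of expanded segment masses and the
CoM their mass-weighted mean.

`validate_on_extant()` quantifies the method's error on taxa where
truth is known: apply-to-self and leave-one-out prediction error, and
an equal-volume mode that inflates hulls to the *true* skin volumes,
isolating pure hull-shape error from volume-prediction error.

## Comparative statistics

All methods share one piece of machinery: the Brownian-motion
covariance `C` from shared branch lengths, factored as `C = L L'`
(Cholesky) with data premultiplied by `L^-1` — numerically stabler for
ultrametric `C` than eigen-inversion.

* **pGLS** (`pgls()`): ML fitting (so AICc is comparable across
  fixed-effect structures), `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`
  with k counting coefficients plus sigma^2 (plus lambda when
  estimated). Coefficient intervals use the t distribution on n - p
  residual df with the unbiased variance, which makes the star-tree
  case collapse exactly onto OLS inference. Pagel's lambda is
  estimated by a coarse grid on [0, 1] refined by golden-section
  search.
* **Allometry** (`allometry_classify()`): a slope CI wholly below the
  isometric expectation (1/3 for log10 length or CoM offset against
  log10 mass) is negative allometry, wholly above positive, containing
  it isometric; the bounds are reported so narrow inclusions stay
  visible. The pipeline fits these on log10 of the *raw* hip-referenced
  offsets, dropping taxa whose offset lies on the wrong side of the hip
  (a log-log model cannot accommodate them).
* **pANOVA / phylANCOVA** (`phylo_anova()`): F statistics in the
  transformed space with significance by residual randomisation of the
  reduced model, `p = (1 + #[F* >= F]) / (1 + n_perm)`; n_perm
  defaults to 999 and a seed is mandatory. When the reduced model
  already fits exactly (zero residual variance) F is defined as 0.
* **Ancestral states** (`ancestral_states_bm()`): the joint-ML/GLS
  solution solved as a weighted graph-Laplacian system (each node is
  the 1/branch-length-weighted mean of its neighbours,
  simultaneously), handling polytomies and star trees natively.
  Estimate variances use the GLS rate with the n - 1 denominator,
  matching the established implementations; CI95 = estimate +/- 1.96
  sqrt(variance).
* **Phylogenetic PCA** (`phylo_pca()`): eigendecomposition of the
  evolutionary covariance (phylogenetic-mean-centred, `C^-1`-weighted,
  n - 1 divisor); node scores are projected ancestral estimates.
* **Spearman** (`spearman_cor()`): average ranks for ties; p by the t
  approximation, with exact enumeration available for n <= 8 (beyond
  that, full n! enumeration is impractical and the approximation is
  adequate).
* No multiple-testing correction is applied anywhere; raw p-values are
  reported.
* Topology uncertainty: `across_trees()` maps any analysis over a list
  of trees and reports per-tree values with across-tree median and
  2.5/97.5 percentiles. Ancestral-state variance and across-tree
  spread are thus reported separately, never merged.

## The synthetic-data generator

`body_plan()` + `build_body()` produce bilaterally organised digital
taxa: head/neck/torso/tail plus three-segment forelimbs and
four-segment hindlimbs, discretised from ellipsoids, capsules and
frusta. The central trick: each segment's "skeleton" is its skin
surface shrunk by a factor `s` about the segment CoM, so the convex
hull of the skeletal points is an exact scaled copy of the skin and
the hull:skin volume ratio is exactly `s^3` at *any* mesh resolution.
That makes the quantity the expansion method estimates analytically
known and controllable, without modelling osteology. Default shrink
factors span expansion factors of about 1.5 (distal limb) to 2.9
(neck). Log-normal noise on the ratio (`ratio_noise_sd`) emulates
real between-taxon soft-tissue scatter.

Archetypes are qualitative caricatures — HLD-like (long tail, long
hindlimbs), FLD-like (large forelimbs, deep sternum), non-avian
sauropsid (long tail, sprawling proportions) — deliberately not
calibrated to any real species; they exist so that group-difference
and recovery tests are exercisable. Proportions evolve as Brownian
log10 multipliers on a simulated pure-birth tree, so related taxa
have related shapes. Mesh resolutions are named coarse/medium/fine;
inscribed discretisations under-estimate smooth volumes by a few
percent at coarse and under 1% at fine, and the generator reports the
per-segment discretisation error bound in its ground-truth table.

What passing tests therefore show: the geometric and statistical
machinery is correct on bodies whose ground truth is known exactly.
What they do not show: that real skeletal hulls relate to real skin
volumes as simply as shrunken copies do — on real data the expansion
factors carry biological scatter, asymmetry and allometry that the
generator only caricatures (through its noise and BM-proportion
knobs), and CT segmentation/posing error has no synthetic counterpart.

## Numerical choices and degenerate inputs

* Tolerances are relative to bounding-box scale (1e-10 for hull
  visibility, 1e-9 for containment checks, 1e-9 relative for volume
  targets in `scale_to_volume()`).
* Hull construction inserts far points first and treats points within
  tolerance of a face plane as interior; coplanar or collinear input
  sets fail naming the rank deficiency.
* `phylo_anova` requires >= 2 groups with >= 2 taxa each and
  n_perm >= 99; taxa missing from the tree are dropped with a warning
  (the tree/data intersection is used everywhere).
* Fossil recovery error in the acceptance checks is reported as a
  percentage of normalised gleno-acetabular length (the shoulder-hip
  distance), because the cranio-caudal CoM offset changes sign across
  body plans and a ratio to it is ill-conditioned near zero.
* Problem sizes in the shipped tests: fixture sets of 9-12 extant and
  1-50 fossil taxa at coarse resolution, 10^5-point Monte-Carlo
  volume checks, 500 null permutation replicates and 200 interval
  coverage replicates — sizes at which every distributional check has
  comfortable Monte-Carlo headroom.

## Known limitations

Inertia tensors, non-isotropic ("sculpted") expansions, feather
surfaces and re-posing are out of scope: posture is taken exactly as
given in the input meshes. Binary PLY is not read (OBJ, ascii PLY and
ascii STL are). The comparative toolkit covers the Brownian-motion
family (plus Pagel's lambda); OU and multi-rate models are not
implemented.
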