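---
title: "Linking cortical folding to the microstructure of short-range white matter"
author: "foldconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking cortical folding to the microstructure of short-range white matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Cortical folding (gyrification) and the white matter beneath the cortex
develop together, and several neurodevelopmental conditions show
alterations in both. The analysis implemented here asks whether *local*
folding - quantified vertex-by-vertex as the local gyrification index
(lGI) - is statistically coupled to the diffusion properties of the fiber
tracts that terminate under a region of altered folding, and whether that
coupling is specific to short, cortico-cortical (U-shaped) tracts rather
than long-range bundles.

The pipeline chains five stages:

1. **Surface morphometry.** The lGI at a vertex is the area of a geodesic
   disc on the smooth *outer hull* of the brain divided into the area of
   the corresponding patch of the pial surface; values of 1 mean no
   buried cortex, larger values mean deeper folding. Vertex area,
   cortical thickness, sulcal depth and mean curvature are carried along
   as covariate features.
2. **Vertex-wise inference.** A per-vertex GLM
   (`lGI ~ group + center + age + FSIQ`) with surface-based smoothing,
   followed by random-field-theory (RFT) cluster correction for
   non-isotropic smoothness. The significant cluster becomes a surface
   ROI; its mirror image on the contralateral hemisphere is the control
   ROI.
3. **Tractography and dissection.** Deterministic streamline tracking on
   the diffusion-tensor field (seeds on the voxel grid at FA >= 0.2,
   1 mm Euler steps along the principal eigenvector of the cubic-
   interpolated tensor, 35 degree angle stop, 20 mm minimum length), then
   *endpoint dissection*: only streamlines that start or end in the ROI
   are kept - tracts merely passing through are excluded.
4. **Length classification.** Hartigan's dip test for multimodality of
   the pooled tract-length distribution; a univariate Gaussian mixture
   fitted by EM with the component count picked by split-half
   cross-validation. Boundaries between adjacent components sit at the
   posterior-0.5 density crossings; the pipeline's short/long cutoff is
   the boundary immediately above the lower of the two *dominant*
   (heaviest) components - robust when cross-validation splits one
   physical length class into two near-identical components, in which
   case the literal first boundary would sever the short class. Tracts
   above 150 mm are excluded.
5. **Coupling statistics.** Per-metric group GLMs (F with df = 1) over
   the eight tract-class x metric combinations with Bonferroni control
   (0.05/8 = 0.00625); moderation GLMs in both directions
   (`AD ~ group + lGI + group:lGI + center` and the converse);
   seemingly-unrelated-regression (SURE) chi-squared tests comparing
   effects across equations; and partial correlations of lGI with
   short-tract axial diffusivity (AD) given thickness, depth and
   curvature.

Because no real cohort ships with the package, a synthetic-cohort module
generates folded surfaces, tensor phantoms with planted bundles, and
subject tables with *known* ground truth, so every stage can be tested
end to end.

# The synthetic world

## Folded surfaces

A subject surface is an icosphere (subdivision 4, 2562 vertices, base
radius 40 mm) with concentric sinusoidal sulci cut *inward* inside a
circular patch (half-width 0.9 rad) around a fixed patch centre:

$$ r(\alpha) = R - a\, w(\alpha)\, \tfrac{1}{2}\big(1 + \cos(2\pi f \alpha + \varphi)\big),
   \qquad w(\alpha) = \cos^2\!\Big(\frac{\pi \alpha}{2\,\alpha_{max}}\Big), $$

with $\alpha$ the angle from the patch centre, fold density $f = 4$
cycles/radian, amplitude $a$ in mm and a per-subject random phase
$\varphi$ (SD 0.15 rad) modelling inter-individual variation in folding
pattern. Fold crests reach the base sphere regardless of the window, so
the *outer envelope of the folded surface is the base sphere*: the
morphological closing that defines the outer hull has a known analytic
answer, which the test-suite oracles exploit. The white surface is the
pial offset 2.5 mm inward along vertex normals.

Per-subject amplitudes are obtained by inverting a measured
amplitude-to-patch-mean-lGI calibration curve, so the cohort table's lGI
values - not fold amplitudes - are the primitive quantities.

One known artifact: because sulci are cut inward, subjects with deeper
folds lose a little $r^2$ surface area in the annulus around the patch,
which shows up as a thin *negative* lGI rim in the group contrast. The
pipeline selects the positive-signed significant cluster as the ROI, and
the rim is a useful reminder that cluster signs must be checked.

## Tensor phantoms

Each subject gets a 48^3 voxel grid (2 mm) of symmetric tensors:
near-isotropic background (0.7e-3 mm^2/s, FA = 0, below any tracking
threshold) plus four planted bundles whose principal eigenvector follows
the bundle tangent:

* a **short U-fiber** under the patch centre (endpoints anchored to the
  subject's own white surface +-16 degrees from the centre, apex 6 mm
  deep, 2.5 mm cross-section, arc about 24 mm) with the subject's
  short-tract eigenvalues (AD = lambda1, RD = lambda2 = lambda3);
* a **long straight bundle** from the patch into the depth (about 65 mm);
* mirrored copies of both on the contralateral side carrying the
  subject's *null* control diffusivities.

Anchoring endpoints to the subject's folded white surface keeps ROI
capture independent of folding amplitude - otherwise streamline counts
would artificially correlate with group, which the real study explicitly
ruled out.

## Cohort tables

`cohortSpec()` defaults encode the emulated study: 51 cases vs 48
controls, two acquisition centres, adult male age (18-43) and FSIQ
(77-137) ranges drawn matched between groups. Short-tract AD is

$$ AD_i = \beta_0 + s\,(lGI_i - \overline{lGI}) + \delta_{direct}\,G_i
          + \gamma\,C_i + \varepsilon_i, $$

with coupling slope $s$ set so the raw lGI-AD correlation is ~0.30
(matching the reported partial correlations of ~0.28), and the *total*
group difference (direct + lGI-mediated) calibrated to the reported
short-streamline row: means print as 1.10 vs 1.08 (x10^-3 mm^2/s) with
SD 0.04, and the standardized difference matches the reported
F(1) = 8.09 (the F pins the effect more precisely than the two-decimal
means). Long-tract AD and both radial diffusivities carry no planted
effects, as in the reported long-tract pattern. The lGI group difference
itself is nowhere reported numerically, so its size is the package's own
choice: 1.0 within-group SD, picked by power analysis so that a *single*
synthetic cohort reliably yields a detectable cluster - the reported
peak t of 3.6 would make cluster detection a coin flip at this mesh
resolution, which is useless as a positive control.

What the generator does **not** emulate: realistic cortical geometry,
raw diffusion-weighted signal and its noise, scanner/site distortions
beyond a mean offset, crossing fibers, and partial-volume anatomy.
Passing tests therefore certify the *statistical machinery and its
calibration*, not performance on real scans.

# Numerical choices worth knowing

* **Outer hull.** Grayscale morphological closing (dilation then erosion
  with a geodesic-disc structuring element, default diameter 15 mm)
  applied to the radial distance field of the star-shaped pial surface.
  This keeps exact hull-pial vertex correspondence and never cuts inside
  the pial surface. A general non-star-shaped brain would need a
  voxelization-based closing instead; synthetic surfaces are star-shaped
  by construction.
* **Geodesic discs** use Dijkstra distances on the edge graph - accurate
  to a few percent at the package's mesh resolutions; the lGI radius
  (default 10 mm for the 40 mm synthetic brain; the brain-scale
  convention of 25 mm scales proportionally) must exceed the mean edge
  length, which is enforced.
* **Smoothing** is iterated conservative edge diffusion: symmetric edge
  conductances conserve the surface integral exactly, constants are
  fixed points, positivity is preserved; the iteration count comes from
  FWHM^2 = 8 ln 2 sigma^2 with the per-iteration variance measured from
  the mesh. Default FWHM 5 mm, the value used in the emulated analysis.
* **RFT cluster p-values** use the 2-D t-field Euler-characteristic
  densities with resel counts (L0, L1, L2) = (2, 0, A_resel) for a
  closed surface. Non-isotropy is handled SurfStat-style: normalized
  residual differences give each edge a resel-space length, Heron's
  formula gives triangle resel areas, and cluster extent is measured in
  resels. Cluster-forming threshold defaults to vertex-wise p = 0.001
  (two-tailed) - unstated in the emulated study, so it is configurable,
  and the permutation oracle (max cluster resel extent, label shuffling
  within centre strata) guards the implementation. At error degrees of
  freedom below ~40 the parametric cluster p-values become liberal
  (a known t-field small-df issue); the package's calibration tests run
  at cohort-scale df (~97), where the family-wise error is within +-0.02
  of nominal.
* **Dip statistic.** Exact mode-scan formulation: a unimodal CDF is
  convex, then concave, and may jump only at its mode; for a fixed mode
  each flank's minimax error is half the largest deviation of the step
  CDF from the greatest convex minorant of its pre-jump counts (left) or
  the least concave majorant of its post-jump counts (right); both flank
  errors are monotone in the mode index, so bisection finds the optimum
  in O(n log n). Jump limits count, giving the conventional 1/(2n) floor
  (identical samples attain it exactly). The p-value is Monte-Carlo
  against the uniform null, the statistic's standard calibration. The
  dip is *not* invariant under non-affine monotone transforms (a
  monotone map that concentrates mass manufactures bimodality); the test
  suite asserts affine invariance, which does hold.
* **EM mixtures** use k-means initialization per restart, an explicit
  monotone log-likelihood guard, and collapse detection with retry.
  "Considerable improvement" in the split-half component selection is a
  relative held-out gain threshold, default 1% - the emulated analysis
  acknowledges using an informal criterion, so this is made explicit and
  configurable.
* **Short/long boundary semantics.** The printed convention
  ("<30 mm" vs "31-150 mm") leaves 30-31 ambiguous; the package uses
  short = [min, cutoff), long = [cutoff, 150], an exhaustive partition.
* **SURE** is two-equation FGLS with the cross-equation residual
  covariance from equation-wise OLS; the "fixed vs variable across
  equations" comparison is a Wald chi-squared (df = 1) on the
  coefficient difference under the joint covariance. lGI and AD are
  z-standardized first - cross-equation effect comparison presupposes a
  common scale that the emulated analysis never states, so its printed
  chi-squared values are not exact reproduction targets.
* **Moderation models** follow the printed equations exactly (group,
  predictor, interaction, centre; no age/FSIQ), with the predictor
  standardized before forming the interaction; a covariate-augmented
  variant is a one-line change on `fitGroupGLM`.

# Problem sizes

The default end-to-end run (99 subjects, 2562-vertex surfaces, 48^3
phantoms) takes about six minutes on one CPU; the calibration studies in
the test suite use a 642-vertex sphere with 10 mm smoothing, 1000 null
simulations for the family-wise error of RFT, 2000 replicates for dip
and SURE test sizes, and 100 replicates for mixture-selection
consistency. All randomness flows from explicit integer seeds; the
pipeline report is bit-reproducible for a fixed configuration and seed.

# Known limitations

* The synthetic folding model produces concentric ring sulci, not
  realistic gyral trees; the negative-rim artifact described above is a
  direct consequence.
* The marginal short-tract AD group effect (standardized difference
  ~0.57 per the emulated Table) has roughly 50% power at the corrected
  threshold in any single 99-subject cohort - exactly as marginal as the
  original report; the positive-control test therefore asserts the
  effect at the initial 0.05 level and leaves the corrected-threshold
  status to the reported numbers.
* Deterministic single-tensor tracking cannot represent crossing fibers;
  bundle-edge voxelization raggedness causes occasional early
  terminations, which appear as a small intermediate length class (and,
  pleasingly, a three-component mixture like the emulated data).
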