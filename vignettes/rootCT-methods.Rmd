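---
title: "Quantifying developing root systems from CT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developing root systems from CT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootCT)
```

## The problem

X-ray computed tomography lets us watch a root system develop inside its
pot, week after week, without washing a single grain of sand off a root.
The price is that everything downstream is image analysis: the scanner
delivers a stack of cross-sectional slices of CT numbers in Hounsfield
units (HU), and the root system has to be isolated from the surrounding
medium, reduced to measurable geometry, and summarized into statistics
that respect the repeated-measures design of a weekly scanning study.

`rootCT` implements that pipeline for the setting of a young corn
seedling grown in sieved dry sand and scanned weekly: two embryonic root
compartments (*lower* roots attached below the seed, *upper* roots
attached above it along the below-ground stem), each with primary axes
and secondary laterals, compared between an optimally watered control
group and a salt-shocked group. Because raw scans of this kind are rarely
deposited, the package ships a synthetic phantom generator that renders
stochastic root architectures into CT volumes with voxel-level ground
truth; every stage of the pipeline is validated against phantoms rather
than against irreproducible scans.

## The CT number scale

A CT number is a linear rescaling of the X-ray linear attenuation
coefficient,

$$\mathrm{CTN(HU)} = 1000\,\frac{\mu_{object}-\mu_{water}}
{\mu_{water}-\mu_{air}},$$

so that pure water maps to 0 HU and a standardized air sample to
−1000 HU. `hounsfield()` implements exactly this form; it reproduces both
calibration points and is strictly increasing in $\mu_{object}$.
Volumes are stored as `VoxelGrid` objects: a dense 3-D array of finite HU
values plus an anisotropic voxel spacing, by default
$0.35 \times 0.35 \times 0.4$ mm with the z axis along the scanner couch
(slice 1 is the stem end; 300 slices at 0.4 mm span 12 cm of pot depth).
On disk the native scalar type is a signed 16-bit integer (MetaImage
`.mhd`/`.raw` or one 16-bit TIFF per slice), matching clinical CT
convention; both round-trips are bit-exact.

## Root isolation

Dry sand attenuates far more than fresh root tissue, so root material
occupies the low end of the HU histogram. Isolation proceeds in four
stages:

1. **Segmentation** (`segmentRootMaterial`): threshold at 850 HU and
   keep 26-connected components of at least `min_component` voxels
   (default 50) to reject speckle.
2. **Thinning** (`skeletonizeMask`): reduce the mask to a 1-voxel
   curve skeleton with a topology-preserving algorithm. A voxel is
   deletable when it is *simple* in the (26, 6) sense — its removal
   changes neither the foreground 26-components in its neighborhood nor
   the background 6-components touching it — and is not a curve endpoint.
   Deletions proceed over the eight parity subfields of the grid with a
   sequential re-check at deletion time, so connectivity is exact by
   construction. Thinning of thick branches leaves short terminal spurs;
   these are pruned (branches shorter than 5 voxels measured from a
   branch voxel), and thinning and pruning alternate to a fixed point.
   This combination gives clean centerlines for tubes of both odd and
   even voxel width, a regime where classical 6-subiteration schemes
   either freeze spurs or delete entire thin columns.
3. **Labeling** (`classifyCompartments`): skeleton voxels inside a
   configurable stem-seed region (a cylinder of radius 2 mm around the
   stem axis down to the seed, plus a seed capsule of radius 3 mm) are
   set aside as stem-seed. Each remaining component is traced from its
   attachment points — voxels 26-adjacent to the stem-seed region.
   Compartment is decided by which side of the seed the geodesically
   nearest attachment sits on (the pot is scanned stem first, so
   "above the seed" is smaller z); this per-voxel rule splits the rare
   component that fuses upper and lower material at the junction instead
   of mislabeling it wholesale. Within a component, the *primary* path
   from each attachment is the maximal-hop geodesic, with ties broken by
   longer physical path and then lowest voxel index; attachments are
   processed longest-first and each aims at the farthest voxel not yet
   claimed, so merged axes are each traced from their own attachment.
   Everything off a primary path is *secondary*; components with no
   attachment are excluded as orphans, with a warning.
4. **Layer growing** (`expandSkeleton`): the labeled skeleton is dilated
   one 26-neighbor layer at a time. Primary voxels admit neighbors with
   HU ≤ 850 up to four layers; secondary voxels admit HU ≤ 950 up to two
   layers — secondary roots are finer, so a softer threshold and a
   tighter cap keep their estimated volumes from bleeding into sand.
   The stem-seed region is masked out of all candidates, and within a
   layer the lowest-index claim wins, making the operation deterministic.
   Growth is monotone in both the threshold and the layer cap.

## Structural complexity: cube counting

The fractal dimension of the skeleton is estimated by 3-D cube counting:
for a ladder of cube sidelengths $s$, $N(s)$ counts the cubes of the
origin-anchored partition (cube index $\lfloor c/s \rfloor$) containing
at least one skeleton voxel, and the dimension is the slope of the
ordinary least-squares fit

$$\log N(s) = k + \mathrm{FD}\,\log(1/s)$$

with natural logarithms. The ladder is dyadic: $s = 2^0 \dots 2^8$ (nine
sidelengths) once the grid footprint reaches 512 voxels, and
$2^0 \dots 2^{\lfloor \log_2 d \rfloor}$ for smaller grids. Both the
smallest cubes (dominated by digitization) and the largest (dominated by
the finite footprint) bias the slope, so only a middle subset enters the
fit: the default discards the three smallest and three largest
sidelengths of a nine-rung ladder, scaling to $\lfloor n/3 \rfloor$ per
end for shorter ladders; a best-subset mode instead scans every
contiguous run of 3–5 rungs that avoids the extremes and keeps the run
with the highest $R^2$. The cube partition is anchored at the grid
origin with no offset averaging — grid placement is a convention, and a
fixed anchor keeps the estimate deterministic. On the bundled fixtures
the estimator recovers the classical values: a 256-voxel straight line
gives FD 1 and a filled 256×256 sheet gives FD 2, exactly, because the
middle dyadic rungs of these constructions follow exact power laws.

By pipeline default the FD is computed on the lower-root skeleton only:
upper roots are absent in some plants and weeks, and the two compartments
form distinct systems that should not be pooled into one scaling fit.
Weekly complexity change is summarized by FD ratios
(`fdRatios`): each later week's FD divided by week 1's.

## Morphometry

Volumes are voxel counts times the voxel volume
($0.35 \times 0.35 \times 0.4 = 0.049$ mm³), per compartment, with
stem-seed voxels excluded by construction. Relative growth rate between
consecutive weeks is $(V_{t+1}-V_t)/V_t$, undefined (an error, distinct
from a missing compartment) when $V_t = 0$.

Skeleton length deserves a note. The naive estimator — summing Euclidean
steps between 26-adjacent skeleton voxels — systematically overestimates
the length of digitized curves: a straight tube digitized at this
resolution measures 8–17% long, because the digital path staircases
around the true line. `skeletonLength()` therefore decomposes the
skeleton into maximal unbranched runs and sums chords between voxels
four steps apart along each run (plus the remainder). Axis-aligned and
single-diagonal paths are unchanged — the worked examples
(11 collinear voxels at 0.4 mm → 4.0 mm; one in-plane diagonal step →
0.495 mm) hold exactly — while staircase error drops to a few percent.
`chord = 1` recovers the plain edge sum for comparison with tools that
use it. Length increments between weeks are exact differences; a
negative increment is allowed but warned about, since roots do not
shrink.

## Repeated-measures ANOVA

Each trait (FD, FDR, volumes, rates, lengths, increments) is analyzed as
a split plot: plants nested in groups, weeks as the repeated factor.
Between-subject (Group) effects are tested against subjects-within-group;
within-subject effects (Week, Week × Group) against the Week × subject
error. Because weekly measures on the same plant are autocorrelated and
possibly heteroscedastic, the classical within-subject F tests assume a
sphericity that real data violate; both degrees of freedom are therefore
multiplied by Box's epsilon, estimated in the Greenhouse–Geisser form
from the pooled within-group sample covariance:

$$\hat\varepsilon = \frac{(\sum_i \lambda_i)^2}{(k-1)\sum_i \lambda_i^2},
\qquad \hat\varepsilon \in \left[\tfrac{1}{k-1},\, 1\right],$$

over the eigenvalues of the doubly-centered covariance. The sample-based
Greenhouse–Geisser estimate was chosen over the Huynh–Feldt variant
because the design explicitly works from the sample covariance matrix at
very small n; with two repeated measures the estimate is identically 1
and no adjustment occurs. The adjusted P value is reported alongside the
unadjusted one and is clamped to never fall below it: the adjustment
exists to guard against liberal inference, and for F < 1 the raw
recomputation can paradoxically shrink the P value.

Per-week group differences use the two-group one-way ANOVA F test (the
square of the pooled-variance t statistic), and between-group variance
homogeneity the two-sided variance-ratio F test — the simplest defensible
choice at three plants per group. Three significance levels (0.01, 0.05,
0.10) are flagged with no multiplicity correction; with n = 3 per group
the study is a screening design, not a confirmatory one. Degenerate
inputs (zero within-cell variance, measured relative to the response
scale) yield an explicit "undefined" result rather than an infinite F.
Compartments missing in some weeks (upper roots under salt in week 1)
are handled by listwise restriction of the time levels, and the output
tables preserve N/A cells for the restricted rows.

## The phantom generator

`growArchitecture()` is a discrete weekly growth model, deliberately the
simplest thing that produces the study system's structure:

* axis tips elongate in 1.5 mm steps along a heading blended with a
  downward gravitropic bias plus Gaussian angular jitter (sd 0.22);
* lower primary axes start at the seed in a downward cone at evenly
  spaced azimuths, anchored just outside the seed so neighboring axes do
  not fuse at their exits; upper primary axes start on the stem above
  the seed, near-horizontal and only weakly gravitropic, and are
  deflected upward if they descend past the seed level — the two
  embryonic systems stay spatially distinct, as they do in the crop;
* secondary laterals arise as a Poisson process along primary segments
  older than `branch_delay`, at `branch_rate` expected laterals per mm
  per week;
* tips deflect at the grid margin and are repelled from the stem axis.

Default parameters: 3 lower and 2 upper axes, primary elongation
15 mm/week, lateral elongation 5 mm/week, branch rate 0.08 laterals per
mm per week, branch delay 1 week, gravitropism 0.6, radii 0.7 mm
(primary) and 0.4 mm (secondary). These are plausible magnitudes for a
corn seedling's first three weeks scaled to the desk-scale grid (see
below), chosen once when the generator was written. The salt preset
encodes the treatment contrast qualitatively: upper-axis onset delayed
to week 2, elongation reduced to 9 and 3.5 mm/week, branch rate to 0.03.
Snapshots are nested (roots only grow) and the same seed always yields
the same tree.

`voxelizePhantom()` renders a snapshot into HU: voxels within the local
radius of any root segment draw from Normal(`hu_root` = 200,
`noise_sd` = 60), all others from Normal(`hu_sand` = 1200, `noise_sd`);
the defaults keep root far below the 850 HU primary threshold and dry
sand far above the 950 HU secondary threshold, with noise small enough
that misclassified voxels are vanishingly rare. The architecture and
noise RNG streams are separate, so one plant can be re-imaged with fresh
noise. Ground truth (compartment and order per voxel, stem-seed
separately) is returned alongside the volume and exported as SWC.

**What the phantoms do not emulate:** beam hardening, scatter, partial
volume beyond an optional one-shell blend, soil heterogeneity, moisture
gradients, root decay, or contact between roots and pot walls. Passing
the phantom suite therefore shows that the geometry and statistics
pipeline is correct, not that segmentation at 850/950 HU would be
adequate for any particular scanner or soil; on real data those
thresholds are empirical choices tied to the medium and its moisture at
scan time.

## Problem sizes and determinism

The package's default grid is desk-scale, 128 × 128 × 150 voxels at the
clinical spacing (the full 512 × 512 × 300 is supported): it keeps a
full two-group, three-plant, three-week experiment — eighteen phantom
volumes through every pipeline stage — to roughly ten seconds on one
core, which makes the end-to-end suite routinely runnable. At this
footprint the dyadic ladder has eight rungs and the fixed-middle rule
keeps four. Simulated FD values at desk scale sit mostly between 0.8 and
1.2 — sparser than a three-week-old corn system scanned at full
resolution, as expected for architectures scaled into a 4.5 cm box.

Everything is deterministic under a fixed configuration: per-plant seeds
are derived from the experiment seed, voxel operations are sequential
with fixed tie-breaks (lowest linear index), and reruns produce
bit-identical result tables.

## Known limitations

* Order (primary/secondary) labeling is heuristic where axes merge into
  one skeleton component; compartment labels are the validated quantity
  (≥ 95% against phantom truth in the test suite), order agreement is
  typically lower.
* The skeleton length of very short branches (under the 5-voxel spur
  threshold) is unmeasurable by design; laterals below ~2 mm are
  invisible to the pipeline.
* The ANOVAR layer requires balanced designs after listwise restriction;
  plants missing a trait at a retained week drop the whole week for that
  trait's analysis.
* `best-subset` sidelength selection maximizes $R^2$, which at three
  retained rungs is a weak criterion; the fixed-middle default is the
  recommended mode.
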