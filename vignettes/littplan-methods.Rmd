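---
title: "Automated LiTT trajectory planning: models and methods"
author: "littplan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated LiTT trajectory planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littplan)
```

## The planning problem

Stereotactic laser interstitial thermal therapy (LiTT) for mesial temporal
lobe epilepsy ablates the amygdalohippocampal complex (AHC) through a
single laser fiber implanted along a straight trajectory. The quality of
the plan determines both safety (clearance from sulci and vessels,
avoidance of the ventricular system, a shallow drilling angle at the
skull) and efficacy (how much of the amygdala and hippocampus the thermal
cylinder covers, and how little of the neighboring parahippocampal gyrus
and entorhinal cortex it damages). `littplan` implements a fully automated
computer-assisted planning (CAP) pipeline over a parcellated label volume:
target generation from the amygdala, candidate entry points on prioritized
entry gyri, feasibility filtering, weighted ranking, cylindrical
ablation-zone modeling with per-structure volumetrics, and cohort
statistics for comparing automated plans against manual ones.

All geometry lives in RAS+ world millimetres (x right, y anterior, z
superior); voxel indices are 0-based in the affine algebra and a voxel is
represented by its center. NIfTI affines are honored on load.

## Target and entry model

The planning target is the amygdala centroid displaced 3 mm medially,
3 mm anteriorly and 3 mm inferiorly ("medial" means toward the midline,
so the sign of the x displacement follows the side of surgery). The
anterior shift places the target at the anterior amygdala surface; the
medial and inferior shifts improve coverage of the mesial hippocampal
head while keeping heat away from the temporal stem and globus pallidus.
The target is fixed: the planner searches only over entry points.

Entries are drawn from the lateral aspects of three gyri in strict
priority order — inferior occipital, middle occipital, posterior middle
temporal — matching the posteroinferior corridor approach, which
cannulates the long axis of the AHC between the occipital horn of the
lateral ventricle and the collateral sulcus. Candidate entries are the
surface voxels of the entry patch, deduplicated on a 2 mm world grid and
ordered lexicographically by (z, y, x) so that enumeration is
reproducible. The planner evaluates every candidate of a role against the
fixed target and only falls through to the next role when no candidate is
feasible; the first role with a feasible candidate always wins.

## Safety metrics

For a trajectory with entry $e$ and target $t$:

* **Intracerebral length** is measured from the first crossing of the
  inner skull surface to the target. The crossing is found by bisection
  on the trilinearly interpolated signed distance field of the
  intracranial mask, to 0.01 mm.
* **Drilling angle** is the angle between the trajectory direction and
  the outward normal of the outer skull surface at the entry-side
  crossing, folded into [0°, 90°]; 0° is orthogonal drilling. Normals are
  the normalized gradient of the signed outer-surface distance field,
  estimated with a finite-difference half-step of one voxel so that the
  quantization of the voxelized distance field averages out.
* **Pointwise risk** of a sample point at distance $d$ from the nearest
  critical structure is 1 for $d \le 3$ mm, 0 for $d \ge 10$ mm, and
  falls linearly in between. Only the endpoints of the ramp are part of
  the risk model's definition; the linear interior is the minimal
  assumption and both endpoints are configurable (`risk_params()`).
  Sulci serve as critical structures — a vasculature proxy, since
  vessels concentrate within sulci.
* **Overall risk** is the path integral of pointwise risk along the
  intracerebral segment (midpoint rule, 1 mm steps) divided by a
  normalizing length of 10 mm. The normalization makes sustained travel
  near critical structures produce values above 1; any positive scale
  factor leaves the planner's ranking unchanged, so the constant is
  explicit configuration rather than a calibrated quantity.
* **Minimum critical / brainstem distance** are the minima of the
  respective interpolated distance fields over the intracerebral
  segment, refined around the minimal sample by golden-section search to
  0.01 mm. A midpoint variant of the brainstem distance (distance at the
  segment center) is available as an option.
* **AHC center proportion** operationalizes "contact with the center of
  the structure": the arc length of the trajectory inside the AHC core
  (voxels at least 1.5 mm interior to the AHC boundary), divided by the
  extent of the AHC along its first principal axis, clipped to [0, 1].
  Both the core margin and the denominator are documented choices — no
  printed formula exists for this quantity — and the margin is a
  parameter.
* **Ventricle transgression** is checked at 0.25 mm sampling against the
  ventricular mask; the ventricular system is an exclusion zone, not a
  graded risk.

## Feasibility and ranking

A candidate is rejected with the first failing reason among: ventricular
transgression; minimum critical distance below the 3 mm planning safety
margin (derived from probe diameter plus three standard deviations of
implantation inaccuracy); drilling angle above 45°. Feasible candidates
are ranked by

$$s = w_r \, R - w_a \, A + w_l \, \frac{L}{150\text{ mm}} +
      w_\theta \, \frac{\theta}{90^\circ}$$

with default weights $(1, 1, 0.25, 0.25)$ for risk $R$, AHC proportion
$A$, length $L$ and angle $\theta$; lower is better. The normalizers put
length and angle on roughly [0, 1] so all four terms are commensurate.
The multi-objective combination is not published; the weights are
explicit configuration, and correctness is asserted as brute-force
optimality over the identical candidate set plus constraint satisfaction
rather than as particular weight values. Ties break by lower risk, then
shorter length, then enumeration order, which makes planning fully
deterministic.

## Ablation-zone model

The expected ablation zone is a flat-capped cylinder around the
trajectory: 15 mm diameter by default (a conservative ceiling within the
device's 5–20 mm ablation range), distal cap at the target and proximal
cap where the trajectory crosses the coronal plane of the tectal plate.
Only hippocampus anterior to the tectal plate enters AHC volumetrics, so
the tectal plane is also the natural posterior limit of the modeled
cavity; a fixed-length extent is available when a trajectory does not
cross the plane. Voxelization uses the voxel-center rule for
reproducibility, with an optional subvoxel supersampling estimate used by
the tests to bound the center-rule error.

Per-ROI volumetrics report ablated volume and percentage of the
anatomical volume for amygdala, (truncated) hippocampus, entorhinal
cortex and parahippocampal gyrus, with an AHC row that is exactly the sum
of the amygdala and hippocampus rows. The *residual depth of the mesial
hippocampal head* takes the head region (hippocampus anterior to the
coronal plane through the posterior amygdala border — the head has no
published boundary definition, so this plane is the package's documented
operationalization), and for every coronal slice walks laterally from the
medial-most head voxel to the first ablated head voxel; the reported
depth is the maximum slice residual. An achieved (manually segmented)
cavity mask can be substituted for the cylinder to produce the same
report plus the fraction of the cavity occupied by the mesial temporal
ROIs, and signed per-ROI estimation errors (expected minus achieved, as a
percentage of the anatomical volume) quantify the cylinder model's bias.

Heat-sink effects of the ventricles and basal cisterns are deliberately
not modeled: the expected cavity is a uniform cylinder, and the
estimation-error report is the place where the consequences of that
simplification surface.

## The synthetic phantom

Real evaluations of this pipeline require parcellated patient MRI, which
cannot ship with a package. The phantom module instead builds a fully
parametric head — spherical skull shell, ellipsoid amygdala, tube
hippocampus curving posteriorly along the planning corridor, a
ventricular horn tube running superolateral to it, thin planar sheets for
the collateral and occipitotemporal sulci anchored at the basal surface,
a brainstem cylinder, parahippocampal and entorhinal tubes, and three
disjoint angular surface patches for the entry gyri — so that every
downstream module is testable against analytic ground truth (exact
ellipsoid volumes, capsule closed forms, known centroids and the tectal
plane). Painting order resolves overlaps (the amygdala ellipsoid absorbs
the hippocampal tube head, keeping role masks disjoint), and the default
side is left. The default grid is 192³ voxels at 1 mm isotropic spacing;
the test-suite runs the same world geometry at 2 mm on a 96³ grid, which
keeps a full phantom–bundle–plan cycle under a few seconds while leaving
all corridor clearances several voxels wide. Optional seeded jitter
perturbs the tube centerlines to produce phantom families.

Two anatomical variants close the posteroinferior corridor by
construction, exercising the planner's entry fallback: a *deep collateral
sulcus* (the sulcal sheet deepens by 21 mm and thickens to 3 mm over its
posterior segment, staying clear of the hippocampal tail) and an
*enlarged occipital horn* (the ventricular tube balloons inferiorly into
the corridor). No quantitative anatomy exists for how deep a sulcus or
how large a horn defeats the inferior occipital entry in patients; the
variant parameters are chosen so that infeasibility of every inferior
occipital candidate is guaranteed by construction and verified
exhaustively in the tests, while the middle occipital corridor stays
open. A variant of magnitude zero reproduces the base phantom exactly.

What the phantom does **not** emulate: MRI intensities, cortical folding,
partial-volume effects, parcellation errors (real automated hippocampus
labels tend to overestimate in sclerosis), or vascular anatomy beyond the
sulcal proxy. Passing tests therefore demonstrate the correctness of the
geometry, metrics, search and reporting machinery — not clinical
performance on patient data.

## Numerical choices

* Distance fields are exact anisotropy-aware Euclidean distance
  transforms (separable lower-envelope algorithm in C++), validated
  against an all-pairs brute-force oracle; fields are sampled by
  trilinear interpolation, which keeps them continuous and 1-Lipschitz.
* Surface crossings: coarse 1 mm bracketing then bisection to 0.01 mm.
  Line minima: golden-section refinement around the minimal sample to
  0.01 mm.
* Integrals use the midpoint rule with the step chosen so that halving
  it changes every metric by well under 2 % on phantom trajectories.
* Cylinder voxelization uses voxel centers; tests place cap planes off
  the voxel lattice when comparing against closed forms so the center
  rule is unbiased.
* Statistics: the Mann-Whitney U uses tie-aware exact enumeration of all
  group assignments when the pooled sample has at most 12 observations
  and the tie- and continuity-corrected normal approximation otherwise;
  Kruskal-Wallis and the Pearson correlation (with Fisher-z 95 % CI)
  delegate to the standard R implementations. Comparisons are two-sided
  and unpaired, and no multiple-testing correction is applied by
  default, mirroring how such cohort tables are conventionally reported;
  a fully degenerate Kruskal-Wallis input returns H = 0, p = 1.

## Known limitations

Straight trajectories only; no thermal simulation (the cylinder is a
geometric surrogate); no vessel-specific risk without vascular imaging;
the tectal plane is supplied as a coordinate, not detected from anatomy;
and the phantom's stylized geometry means absolute metric values (e.g.
overall risk on a phantom) are not comparable to values computed on
patient parcellations, although orderings and all invariants are.
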