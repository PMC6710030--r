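---
title: "Measuring geometric congruence of spinal surface exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring geometric congruence of spinal surface exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinefit)
```

## The model

Surface-based spinal navigation registers an intra-operative surface scan of
the exposed posterior elements to pre-operative imaging by iterative
closest-point alignment. ICP minimises a point-to-surface distance that has
a *family* of near-minimisers whenever the scanned surface is close to a
symmetric primitive: a cylindrical surface tolerates translation along and
rotation about its axis, a spherical one any rotation about its centre, a
planar one in-plane sliding. `spinefit` quantifies that congruence
shape-by-shape.

For a cloud $P = \{p_1,\dots,p_N\}$ (mm) and a primitive $S$, the orthogonal
distances are

* plane $(n, d)$: $\;|n \cdot p + d|$,
* sphere $(c, r)$: $\;\big|\,\lVert p - c \rVert - r\,\big|$,
* cylinder $(a, v, r)$: $\;\big|\,\lVert (p-a) - ((p-a)\cdot v)v \rVert - r\,\big|$,

and the congruence score is the inliers-to-points ratio
$\mathrm{ITPR} = N^{-1}\,\#\{\,i : \mathrm{dist}(p_i, S) \le \varepsilon\,\}$
at the maximum inlier error $\varepsilon$. The primitive itself is estimated
by RANSAC: minimal samples (3 points for a plane; the circumsphere of 4
points; for a cylinder, 2 oriented points — axis along $n_1 \times n_2$,
axis position from the least-squares intersection of the two surface-normal
lines projected perpendicular to the axis, radius the mean axial distance of
the two points), each hypothesis scored by inlier count at $\varepsilon$.
Normals, where not supplied, come from local PCA over $k$ nearest
neighbours, oriented to the $+z$ hemisphere (an arbitrary fixed convention;
the cylinder estimator is sign-invariant).

### RANSAC discipline

The loop runs exactly `iterations` draws; a degenerate sample (collinear
triple, coplanar quadruple, near-parallel normals) consumes its iteration
rather than being redrawn, so the draw count is exact. The winner is the
hypothesis with the most inliers; ties break by lower inlier RMSE, then by
earlier iteration, so a fit is a deterministic function of (cloud order,
seed). With `refine = TRUE` (the default) the winner is polished once by
least squares on its inlier set — closed-form principal directions for the
plane, profiled quasi-Newton for sphere and cylinder (the radius is profiled
out, so the optimiser works in 3 and 6 parameters respectively) — and the
inlier mask is recomputed once against the polished model. There is no
iterated re-consensus: a single refine + re-mask keeps the procedure simple,
deterministic, and faithful to a 100-iteration budget. If polishing fails to
reduce the inlier residual the unrefined winner is kept and flagged.

Whether the RMSE should be taken over inliers or the whole cloud is
genuinely ambiguous; the inlier RMSE is primary (it is the quantity bounded
by $\varepsilon$) and `rmse_all` is reported alongside.

### Tolerance selection

$\varepsilon$ trades breadth for discrimination. Following the study design,
`select_epsilon()` evaluates $\varepsilon \in \{0.1, 0.5, 1.0, 2.0\}$ mm by
the coefficient of variation of the RANSAC RMSE over repeated re-seeded fits
(`cov_rmse()`, sample SD / mean, 20 repeats by default; identical or
all-zero RMSEs give 0 by convention) and takes the argmin, ties to the
smaller tolerance. All ITPR analyses here use $\varepsilon = 0.5$ mm, the
value selected on the original scan data. On synthetic cohorts the *argmin
structure* of the selection is what can be validated; the numeric CoV values
of the original data were never published, and the synthetic argmin need not
land on 0.5 mm.

## Exposure groups and study summaries

`reconstruct_group()` builds the three compared exposures from a labelled
cloud: Group A keeps every non-outlier point (bilateral exposure including
the spinous process); Groups B and C keep one side (sign of $x$ relative to
the midline), B additionally keeping that side's spinous-process *base* and
C excluding the spinous process entirely. For unlabelled clouds a midline
and band half-width substitute for labels; lacking per-point protrusion
values, the unlabelled Group B keeps the whole band of its side — a
documented approximation, not used for synthetic data.

`run_study()` emits one record per (specimen, level, group, side, shape) —
five reconstructions and three shapes per level, left and right unilateral
records pooled rather than averaged — and summarises mean ± sample SD ITPR
by group and by region (C1, C2, subaxial cervical C3–C7, thoracic, lumbar,
sacral), per-level B−A and C−B contrasts, and the two headline contrasts as
percent reductions $100(\bar x_{pre} - \bar x_{post})/\bar x_{pre}$,
reported to one decimal: *laterality* (unilateral B+C vs bilateral A) and
*spinous-process inclusion* (C vs B). Per-shape fits derive their seeds from
the record's base seed with fixed offsets (+1 plane, +2 sphere, +3
cylinder), making every record independently reproducible.

Group comparisons use classical one-way ANOVA, Tukey HSD (Tukey–Kramer
standard errors for unbalanced groups; adjusted p from the studentized-range
distribution, validated against the exact $q = t\sqrt 2$ equivalence at
$k = 2$) and Levene's test with mean centring. The original study
additionally fitted hierarchical mixed-effects models to absorb
specimen-level variation; that adjustment is out of scope here, and the
fixed-effects ANOVA treats records as independent — an approximation the
CLI documents.

## The synthetic cohort generator

No anatomically realistic vertebra model is attempted. The generator is a
minimal parametric composite in which each study finding has one
controllable cause:

| feature | parameter (default) | drives |
|---|---|---|
| laminar arch, cylinder radius `arch_radius` (14 mm), swept `arch_halfangle` (±55°) | cylindrical congruence of hemilaminae |
| box-like spinous-process ridge, `sp_height` (12 mm) × `sp_length` (10 mm), footprint half-width `sp_base_halfwidth` (4 mm) | symmetry disruption when the midline is included |
| hemispherical facet bumps at the patch margins, `facet_radius` / `facet_height` per region | regional congruence differences |
| `noise_sd` (0.15 mm), `outlier_fraction` (0.02) | sensor noise and stray returns |

Coordinates are mm, right-handed, $+y$ cranio-caudal, $+z$ dorsal, midline
at $x = 0$; each level cloud has 4000 points over a 25 mm cranio-caudal
patch. Points are allocated to the arch and the ridge walls in proportion to
surface area (a surface scanner samples area, so the tall ridge receives
correspondingly many points). Ridge points protruding at most 40% of
`sp_height` are labelled `sp_base` — an operationalisation of "the base of
the spinous process"; the threshold is a parameter. Region presets make
cervical levels wider-arched with lower relief and thoracolumbar levels
narrower with a taller ridge and coarser facets; a cohort applies
multiplicative log-normal jitter (SD 0.05) to the geometric parameters per
specimen × level. `relief_scale > 1` emulates the coarser relief of older
cadaveric specimens relative to in-vivo surfaces; the preset values are
illustrative configuration, not anatomical claims.

What passing tests on this generator do show: the fitting and scoring
machinery is correct (exactness on pure primitives, agreement with
exhaustive enumeration, known mixture fractions recovered), and the
*qualitative* study structure — mean ITPR ordered Group A < B < C for every
shape, cervical exceeding lumbar congruence in unilateral cylinder fits,
group effects overwhelming noise in the ANOVA — emerges from geometry alone.
What they cannot show: the absolute ITPR levels of real cadaveric or
clinical scans, which depend on anatomy the generator does not model
(osteophytes, soft-tissue remnants, scanner-specific noise). The published
percent reductions are therefore recomputed from the published group means,
not re-derived from synthetic data.

## Numerical choices and degenerate inputs

* Model representations are canonicalised (lexicographically larger of
  $\{n, -n\}$, cylinder anchor nearest the origin) so equality is testable.
* Degeneracy thresholds: collinear triples by cross-product norm
  $< 10^{-9}$ × sample scale; coplanar quadruples by determinant scale;
  cylinder samples by $\lVert n_1 \times n_2 \rVert \le 10^{-6}$. An exactly
  planar cloud therefore has *no* valid sphere hypothesis and the fit errors
  rather than inventing one.
* An all-degenerate loop raises "no valid hypothesis"; clouds smaller than
  the minimal sample raise "insufficient points".
* Single-observation summary cells report SD 0 with a `degenerate` flag.
* Problem sizes in the shipped tests are the package's own choices: the
  full synthetic study runs 4 specimens × 25 levels × 5 reconstructions × 3
  shapes = 1500 fits at 100 iterations, and the exhaustive-enumeration
  comparison uses ≥ 50 clouds of 40–60 points, where complete enumeration
  (up to ~490k sphere hypotheses per cloud) is tractable.

## Known limitations

* The cylinder RANSAC inherits normal-estimation error; on sparse,
  outlier-heavy clouds, PCA normals degrade the hypothesis pool. The
  enumeration-equivalence tests supply analytic normals to separate search
  completeness from normal quality.
* The generator's arch is exactly cylindrical, so unilateral synthetic
  exposures are *more* cylinder-congruent than real laminae; directionality,
  not magnitude, is the claim.
* No mesh reconstruction, ICP, CT handling, or shapes beyond
  plane/sphere/cylinder; no mixed-effects modelling.
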