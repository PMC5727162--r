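---
title: "Modular polymorphic design and mechanics of DNA origami hinges"
author: "modOrigami"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular polymorphic design and mechanics of DNA origami hinges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modOrigami)
```

## The problem

Scaffolded DNA origami folds a long single-stranded scaffold (M13mp18,
7,249 nt) into shape with ~200 short staple oligonucleotides. Because the
staple sequences are dictated by where they sit on the scaffold, even a
small design revision classically forces re-synthesis of a large part of
the staple pool. A module-based design sidesteps this: the bundle is
partitioned by *seam* regions (cross-sections of aligned scaffold
crossovers) into modules whose staples can be swapped independently.
Turning a structure module into a rotational *hinge* is then pure staple
removal, and a scaffold *adjuster* strand spanning the structure sets the
included angle of the bent shape, with the unused scaffold parked in a
reservoir. `modOrigami` implements this design engine, the
torsional-spring/worm-like-chain mechanics that predicts included angles
and hinge stiffness, and an AFM-image analysis stage that measures angles
and structural yield on synthetic height maps.

## The reference layout and its constraints

The reference is a 12-helix honeycomb bundle divided into nine modules
(L1, L2, L3, M1, M2, M3, R1, R2, R3) by eight 28-nt seams, with 180
staples: 108 body, 60 seam, 12 strut. The strut staples hybridize the
504-nt adjuster into dsDNA (12 x 42 nt = 504 nt, the only decomposition
consistent with both counts). L1 and R3 are 63 nt, and the central hinge
module M2 is 42 nt (a ds0hb hinge there leaves twelve 42-nt scaffold
single strands at the cross-section).

These printed numbers over-determine the scaffold budget: twelve
full-length helices at 63 + 63 + 7x(35..42) + 8x28 nt plus a 504-nt
adjuster would need more than the 7,249 scaffold bases available. The
package therefore treats the *counts* (180 = 108 + 60 + 12; 11 structural
staples per interior module; seam length 28; L1 = R3 = 63; M2 = 42) as
hard layout constraints and absorbs the overrun in the six remaining
interior modules, which default to 28 nt. That gives a 560-nt bundle span
and a total scaffold usage of 12 x 560 + 504 = 7,224 <= 7,249 nt. All
module spans are configurable through `defaultLayoutConfig()`; the budget
is re-checked on every construction.

Routing choices that the counts do not pin down were made once and kept
fixed:

* 60 seam-class staples = 6 per interior seam plus 6 per terminal cap.
  Cap staples pin the scaffold turns at the bundle ends and, like all
  seam staples, are never touched by any edit (seam immutability is a
  tested invariant).
* 108 body staples = 16 in L1, 11 per interior module (a brick pattern of
  two-helix staples), 15 in R3, six of which are *junction* staples at
  the adjuster/reservoir anchor.
* The scaffold runs as a terminal-loop serpentine (even helices forward,
  odd backward) and continues into the adjuster strand. Interior scaffold
  crossovers inside the seams are not drawn explicitly; every quantity
  the package reports is independent of that choice, and the seam staple
  set carries the seam semantics.

## Why variants are cheap: the replacement accounting

A `ds0hb` hinge removes the module's 11 staples and adds nothing;
`ds2hb`/`ds3hb`/`ds4hb`/`ds6hb` add 2/3/4/6 single-helix hinge staples
that keep that many helices duplexed at the cross-section. Shortening the
adjuster by k 21-nt units removes the struts beyond the new length (one
21-nt remainder becomes a shortened strut when k is odd) and re-breaks
the six junction staples, whose footprints shift with the reservoir
anchor. An adjuster edit therefore costs 6-7 new sequences, a hinge 0-6,
which reproduces the catalog accounting end to end:

```{r accounting}
ref <- buildReference()
scaf <- defaultScaffold()
refs <- assignSequences(ref, scaf)
v <- setAdjuster(applyHinge(ref, "M2", "ds0hb"), 357)
diffStaples(assignSequences(v, scaf), refs)
```

Single-hinge variants replace 7 staples (3.9% of the pool), double- and
triple-hinge variants 7-11, and the closed-form/double-adjuster cases
10-23, never exceeding 12.8% (`buildVariantCatalog()` builds all 24).

## Mechanics: torsional spring + worm-like chain

The total strain energy at included angle theta is

E(theta) = k/2 (theta - theta0)^2 + E_wlc(x(theta)),

with theta0 = 180 deg (the reference folds straight), x(theta) the
law-of-cosines chord between the adjuster exit points at distances r1, r2
from the pivot, and E_wlc the closed-form integral of the Marko-Siggia
interpolation force. Defaults: kT = 4.114 pN nm (298 K), ssDNA rise
0.63 nm/nt, ssDNA persistence length 1.0 nm (high-Mg regime), dsDNA rise
0.34 nm/bp. The equilibrium angle is the energy minimum, found by a
0.05-degree grid pre-search plus Brent minimization (ties broken toward
theta0); the hinge stiffness is estimated per observation from the torque
balance k (theta0 - theta) = F(x) r1 r2 sin(theta) / x and aggregated as
mean/min/max.

Two modeling decisions deserve emphasis:

* **Slack chains are force-free.** A chain whose contour length reaches
  the rest-angle extension can span the opening without nearing full
  extension; its residual entropic tension is neglected and the
  equilibrium stays at theta0. This is the reservoir regime - stored
  scaffold must not bend the structure - and it makes `estimateStiffness`
  skip (with a warning) observations that carry no usable torque signal.
* **Geometry default r1 = r2 = 42.84 nm** (126 nt x 0.34). The part of
  the adjuster anchored along the arms is fixed; shortening acts on the
  bridging segment, which equals 252 nt = 12 x 21-nt units at full
  length. The full fold range (180 deg to 0 deg) thus maps onto twelve
  21-nt units - 15 degrees per unit *on average*. The chord-angle map is
  a sine law, so the individual steps of the 11-design series run from
  ~10 to ~20 degrees; the equal-interval description is nominal target
  labeling, not geometry.

The ds-adjuster angle is computed purely geometrically
(`predictAngleDs()`), which makes it exactly independent of the hinge
stiffness - the same observation that motivates using ss-adjusters for
stiffness estimation and ds-adjusters for precise angle programming.

`pcaStiffness()` provides the equipartition estimator k = kT/var(theta)
(or kT/lambda_i per principal mode) for angle trajectories; it measures
only the simulated hinge part and is not expected to agree numerically
with the torque-balance estimate from full structures.

## Synthetic AFM scenes and what they do (not) show

`synthesizeScene()` renders each particle as two 6-nm-wide, 2-nm-tall
rods meeting at the hinge vertex, dilates by a 2-nm tip radius, and adds
Gaussian height noise (0.15 nm); particles sit on a seeded, jittered grid
so they never touch by accident. The defaults (512 x 512 px at 2 nm/px,
95.2-nm arms = the two halves of the bundle hinged at M2) emulate typical
non-contact AFM fields of deposited monomers.

Angle measurement is landmark-based: the two arm tips are the farthest
point pair of the mask, the vertex candidate the point farthest from the
tip-tip chord, and the true vertex the landmark whose connecting segments
stay inside the mask; arm directions are per-arm first principal
components. Straight rods (no off-chord excursion beyond the rod width)
are flagged `straight` at 180 deg, and short straight rods - a fully
folded particle whose arms overlap - are flagged `folded` at 0 deg.
Classification into monomer/aggregate/fragment uses area bands
[0.4, 1.6] x the expected two-arm footprint; the lower edge deliberately
admits folded monomers (half footprint) while rejecting half-length
fragments (quarter footprint).

The generator reproduces geometry, tip dilation and additive noise, but
not scan-line artifacts, tip asymmetry, surface-interaction deformation
or non-specific inter-strand interactions. Passing the recovery tests
therefore shows the measurement chain is unbiased on ideal particles
(mean absolute error < 5 degrees across the 0-150 degree design grid at
250 monomers per condition, structural yield recovered to +/- 0.03); it
does not certify performance on real micrographs. Experimental folding
and structural yields are properties of the wet-lab system and are out of
scope.

## Problem sizes and numerical choices

The shipped tests exercise the full 24-variant catalog and the 11-design
angle series at sequence level, stiffness recovery on 5-length series
(noise-free and with 5-degree particle noise, n = 250 per design as in
typical AFM cohorts), equipartition recovery at 10^4 samples, and AFM
recovery at 250 monomers per angle across the 0-150 degree grid - the
cohort sizes the method is designed around. Grid resolutions: 0.05 deg
for minimization pre-search, 0.25 deg default landscape, force/energy
consistency checked to 1e-6 relative. The WLC energy near full extension
diverges; landscape points with x >= Lc are flagged infeasible rather
than evaluated. TIFF height maps are stored 32-bit float normalized to a
10-nm full scale (the package reads them back in nm); the text-grid
format is exact.

## Known limitations

* The staple routing realizes the printed counts, not the (unpublished)
  laboratory routing; staple *sequences* are therefore not those of the
  laboratory pool, and the bundled scaffold is a labeled synthetic
  stand-in for M13mp18. All counting results are routing- and
  sequence-independent.
* The six interior modules default to 28 nt instead of the nominal
  35-42 nt band; this is the budget resolution described above.
* The hinge ssDNA portions are not added as extra entropic springs; their
  non-ideal interactions are exactly what makes wide-angle distributions
  broaden in experiments, and no attempt is made to model that here.
* The mechanics treats all non-hinge modules as rigid and the hinge as a
  single harmonic degree of freedom.
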