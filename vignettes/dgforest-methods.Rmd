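---
title: "Context-driven synthesis of the dentate granule cell forest: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-driven synthesis of the dentate granule cell forest: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `dgforest`: its
assumptions, its parameters and how they were calibrated, the places
where the implementation deliberately deviates from a literal reading of
its sources, and its known limitations.

## 1. The anatomical context

The package's central premise is that much of the morphological
variability of dentate granule cells is imposed by their anatomical
context, not by cell-intrinsic programs. Accordingly, generation starts
from an explicit model of the tissue:

* a **base surface** for the outer granule-cell-layer (GCL) boundary,
  parameterized by a septotemporal angle $u$ and a transverse angle $v$:
  a cross-section ellipse with semi-axes
  $A(u) = A_0 (1 + \varepsilon_a \cos u)$ and
  $B(u) = B_0(1 + \varepsilon_b \cos u)$ is swept along a circle of
  radius $R$ while rising as $z_0(u) = D_z \sin u$. Negative
  $\varepsilon_a$ makes the septal end smaller and sharper, matching the
  V-shaped septal and U-shaped temporal cross-sections of the real
  dentate gyrus;
* **layer shells** obtained by offsetting the base surface along the
  local ellipse normal: inward by the GCL thickness $w_{gcl}$, outward by
  thirds of the local molecular-layer thickness
  $w_{ml}(u) = w_{ml,0}(1 + \varepsilon_w \cos u)$, giving the inner,
  middle and outer molecular layers (IML, MML, OML);
* the transverse angle range (about $1.65\pi$) produces the C shape,
  with the suprapyramidal blade on one side of the crest and the
  infrapyramidal blade on the other.

### Calibration of the geometry

The nine surface parameters were calibrated (see
`scripts/calibrate_geometry.R`) against three printed constraints only:
GCL volume 3.78 mm³, molecular layer volume 9.02 mm³, and mean ML width
247 ± 33 µm measured as nearest-neighbour distances from the outer GCL
shell to the OML shell. `estimate_volume()` (rejection Monte Carlo) and
`ml_width()` reproduce all three within their sampling error. The layer
classifier `classify_points()` is a total function from any 3-D point to
{GCL, IML, MML, OML, OUTSIDE}, implemented by inverting the sweep
parameterization (`dg_coords()`).

## 2. Soma packing

Granule cell somata are modeled as 12.54 µm spheres separated by at
least 3.5 µm. `pack_somata()` arranges them on a hexagonal close-packed
lattice with center spacing 16.04 µm (the densest arrangement of equal
spheres) and keeps the spheres that lie entirely inside the GCL. The
packed count, ≈1.19 million, is an *emergent* check of the geometry: the
count parameter of the real dentate gyrus was never used in calibration,
yet the model reproduces it to 0.5 %.

Each soma is labeled with its blade (suprapyramidal on the low-$v$ side
of the crest) and its depth class (superficial = outer half of the GCL),
yielding the four anatomical subgroups that parameterize growth.

## 3. Target points and dendritic territories

Each cell's dendritic territory is an elliptical cone with its apex at
the soma, oriented toward the nearest point of the outer OML surface.
The transverse semi-axis exceeds the longitudinal one
(`rl_ratio = 0.56`), matching the wider transverse spread of real
granule cell fields. A per-cell quota of target points — the future
dendritic nodes — is drawn per layer (Poisson around subgroup means,
scaled by a common lognormal size factor) and sampled inside the cone.

Two shape knobs exist beyond the radii:

* `apex_offset` (40 µm) pushes the *virtual* apex below the soma so the
  cone has a non-zero cross-section at the soma and the dendritic fan
  can open immediately;
* `z_exp` controls the axial density ($z = h\,U^{1/z_{exp}}$;
  3 = uniform in volume, smaller = proximal bias). The superficial
  subgroups use 2.2, which compensates for their shorter soma-to-pia
  paths.

## 4. Tree growth by optimal wiring

Targets are connected one at a time; the next target attached is the one
minimizing
$$\mathrm{cost}(t) = \min_{n \in \text{tree}} \lVert t - n \rVert + bf \cdot pl(n),$$
where $pl(n)$ is the path length from the root to node $n$ and $bf$ is
the balancing factor. $bf = 0$ yields exactly Prim's minimum spanning
tree (verified against an independent implementation and by exhaustive
enumeration of all spanning trees on small sets); larger $bf$ trades
total cable for shorter conduction paths. The balancing factors are
fixed anatomical inputs per subgroup: 1.35 (suprapyramidal superficial),
0.90 (suprapyramidal deep), 1.22 (infrapyramidal).

### The maximum connection distance (a documented deviation)

Applied literally, the rule above cannot produce branched trees for
$bf > 1$: by the triangle inequality, attaching target $t$ to an
interior node $n$ beats attaching it to a stem $s$ only if
$\lVert t - s\rVert - \lVert t - n\rVert > bf\,(pl(n) - pl(s))$, and the
left side is bounded by $pl(n)$, so branching is confined to nodes with
$pl(n) < bf\,pl(s)/(bf-1)$ — a few tens of µm for the pinned balancing
factors. Trees collapse into near-stars with maximum branch order 1,
regardless of every other parameter.

Reference implementations of this wiring rule grow with a **maximum
connection distance**: targets farther than a threshold from every tree
node are ineligible until the tree grows toward them. This
frontier-limiting is what makes $bf > 1$ meaningful. `grow_tree()`
therefore accepts `max_reach` (default `Inf`, the literal rule, used by
all oracle tests; 50 µm in the calibrated table). With $bf = 0$ the
result is the minimum spanning tree for *any* `max_reach`.

### Post-processing

The sampled stem count (truncated Poisson on 1–4, rates solved exactly
for subgroup means 2.4/1.5/2.0/1.4) is enforced by attaching the
nearest targets to the soma first and then closing the root. The raw
polyline tree is resampled at 5 µm, displaced by per-branch Gaussian
fields smoothed at 10 µm and 50 µm length constants (amplitudes 2.5 and
12 µm), and given a quadratic diameter taper from ~2.2 µm proximally to
~0.75 µm at the tips with a steep near-soma ramp.

## 5. Calibration of the growth parameters

Besides the pinned balancing factors and stem rates, the growth model
has per-subgroup cone radii, node quotas, laminar fractions and jitter
amplitudes. These were calibrated (`scripts/calibrate_growth.R`)
against the printed population statistics: branches per cell 28 ± 5,
maximum branch order 5.7 ± 0.8, total length 3357 ± 691 µm, IML
branch-point share 61 ± 14 %, and the supra/infra contrasts. The
empirically mapped response surface:

* branch count scales with the node quota (≈0.65 branches per node);
* maximum order behaves like *branch points per wiring corridor*:
  narrower cones create fewer parallel corridors and deeper chains, so
  order can be raised at a fixed branch count by shrinking the cone —
  the key decoupling in the calibration;
* laminar branch-point shares follow the laminar quota fractions nearly
  one-to-one; GCL targets fold into the IML count while also deepening
  proximal chains;
* jitter amplitude adds length without changing topology.

The frozen table (`default_subgroup_params()`) lands the 200-cell
population at branches ≈31, order ≈5.2, length ≈2940 µm, IML share
≈53 %, with significant supra > infra contrasts in branches and length.

## 6. Known limitations

Three reference statistics are knowingly not reproduced; none of them
was patched over.

* **Partition asymmetry.** With terminal (1,1) cherries excluded from
  the per-branch-point mean (the convention under which a caterpillar
  tree of any size scores exactly 1 — the convention this package
  implements), greedy optimal wiring over uniform target clouds scores
  ≈0.9 at every balancing factor (minimum ≈0.78 near $bf = 0.3$; even
  the exact MST scores 0.89): the wiring attaches side twigs to trunks,
  producing (1, k) partitions, whereas a score of 0.45 requires balanced
  proximal cascades. Including cherries as zeros instead yields ≈0.40,
  inside the experimental range — strong evidence that the reference
  value of 0.45 was computed under the inclusion convention. The package
  keeps the exclusion convention and reports the honest ≈0.9.
* **Laminar length shares.** Wiring produces roughly uniform edge
  lengths, so the length profile tracks the target-point profile and
  cannot simultaneously match the reference branch-point profile
  (61/27/12 %) and length profile (29/32/39 %), whose ratio implies
  short proximal and long distal branches. The calibration prioritizes
  the branch-point profile; terminal branch lengths and the laminar
  cable-density gradient inherit the discrepancy.
* **Field spreads.** The narrow cones required for realistic branch
  orders (see §5) shrink the transverse spread to ≈180 µm versus the
  reference 309 ± 77 µm. With wide cones the spread is reproduced but
  branch order falls to ≈4.7. The trade-off is intrinsic to
  corridor-style greedy wiring.

All three are consequences of one structural property: frontier-limited
greedy wiring on uniform target clouds makes herringbone topologies, not
the balanced proximal fans of real granule cells. A target-point process
with proximal clustering, or a post-hoc rebalancing step, would be the
natural extension.

## 7. Reproducibility

All artifacts are pure functions of (configuration, master seed). Each
cell derives a private RNG substream from `(master seed, cell id)`, so
populations can be regenerated cell-by-cell, in any order, with
byte-identical SWC output. `run_pipeline()` bundles packing, growth,
export and reporting; `run_config()` round-trips through YAML.
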