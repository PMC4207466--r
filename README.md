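# dgforest

Context-driven synthesis of the complete dendritic forest of rat dentate
gyrus granule cells.

Granule cells are the input neurons of the hippocampal dentate gyrus.
Their dendrites span the molecular layer, where they receive entorhinal
and commissural input, and their shape is strongly constrained by the
anatomical context: somata sit in a thin, densely packed granule cell
layer (GCL), and each dendritic tree fans out through a conical territory
that ends at the outer pial surface. `dgforest` builds on that
observation: instead of growing each neuron in isolation from statistical
rules, it constructs an explicit parametric model of the layered dentate
volume, packs ~1.19 million somata into the GCL, and grows every cell
inside its own anatomically oriented territory with a single wiring
principle. Realistic population-level structure — laminar branch-point
profiles, blade and depth differences, dendritic overlap — then emerges
from the shared context rather than from per-feature fitting.

## The model in five stages

1. **Layered volume.** The dentate gyrus is modeled as a C-shaped band
   swept along a torus segment: a transverse ellipse (sharper at the
   septal pole, blunter temporally) extruded along a rising septotemporal
   arc. Offsetting the base surface inward yields the GCL shell and
   outward the inner, middle and outer molecular layers (IML/MML/OML,
   each one third of the local ML thickness). Nine parameters are
   calibrated so the model reproduces the measured GCL volume
   (3.78 mm³), molecular-layer volume (9.02 mm³) and mean ML width
   (247 ± 33 µm). See `build_dg_volume()`, `classify_points()`,
   `estimate_volume()`, `ml_width()`.
2. **Soma packing.** Spheres of 12.54 µm diameter with a 3.5 µm gap are
   placed on a hexagonal close-packed lattice and kept when entirely
   inside the GCL, giving ≈1.19 million somata — the full granule cell
   population — without tuning a count parameter. Each soma is labeled
   by blade (suprapyramidal/infrapyramidal) and GCL depth
   (superficial/deep). See `pack_somata()`, `assign_subgroups()`.
3. **Target points.** Each cell receives a quota of target points,
   distributed over the layers and drawn inside an elliptical cone from
   the soma to the nearest point of the outer OML surface (wider
   transversely than longitudinally, like real granule-cell fields).
   See `orient_cone()`, `draw_quota()`.
4. **Tree growth.** Targets are connected by greedy optimal wiring: each
   step attaches the target minimizing
   `distance to tree + bf × path length to soma`. The balancing factor
   `bf` trades total cable against conduction paths and is fixed per
   subgroup (1.35 suprapyramidal superficial, 0.90 suprapyramidal deep,
   1.22 infrapyramidal). `bf = 0` is exactly Prim's minimum spanning
   tree. Growth is frontier-limited by a 50 µm maximum connection
   distance (see the vignette for why). Stems are forced by a truncated
   Poisson draw; the raw tree is resampled at 5 µm, roughened by
   two-scale smoothed jitter and given a quadratic diameter taper. See
   `grow_tree()`, `generate_cell()`, `generate_population()`.
5. **Validation and analysis.** Single-cell morphometrics (branch
   counts and orders, Sholl profiles, contraction, partition asymmetry,
   laminar distributions, field spreads), population summaries with
   subgroup contrasts, voxel occupancy/cable-density grids, and a
   simulated axon-complexity probe. See `branch_stats()`,
   `population_summary()`, `build_grid()`, `axon_complexity()`.

Everything is deterministic given a master seed: each cell derives its
own substream from `(master seed, cell id)`, so any cell of the 1.19 M
forest can be regenerated in isolation, byte-identically.

## Worked example

```r
library(dgforest)

# anatomical context
vol <- build_dg_volume()
estimate_volume(vol, "GCL", n_samples = 1e6)$volume_mm3   # ~3.79
somata <- assign_subgroups(pack_somata(vol, seed = 1), vol)
nrow(somata)                                              # ~1.19 million

# grow a 200-cell sample of the forest
set.seed(1)
ids <- sort(sample(nrow(somata), 200))
trees <- generate_population(vol, somata, cell_ids = ids, master_seed = 1)

# single-cell and population morphometrics
branch_stats(trees[[1]])
summ <- population_summary(trees, vol)
round(summ$overall, 2)           # means and sds across the sample
subset(summ$tests, measure %in% c("n_branches", "total_length"))

# occupancy analysis
grid <- build_grid(trees, vol, edge = 25)
layer_profile(grid)
occupancy_correlations(grid)

# export / import
write_swc(trees[[1]], "cell1.swc")
tr <- read_swc("cell1.swc")
```

Or from the shell:

```sh
dgforest build-volume
dgforest pack-somata --out out/
dgforest grow --seed 1 --n-cells 50 --out out/
dgforest analyze out/ --out out/
dgforest occupancy out/ --out out/
```

## Package layout

| module | contents |
|---|---|
| `R/geometry.R` | parametric layered volume, classification, volumes, widths, meshes |
| `R/soma_packing.R` | HCP packing, subgroup labels |
| `R/target_points.R` | cones, quotas, target selection |
| `R/tree_growth.R` | optimal wiring, resampling, jitter, taper, cell/population generation |
| `R/morphometrics.R` | Sholl, contraction, asymmetry, branch statistics, laminar profiles |
| `R/population_analysis.R` | occupancy grids, axon complexity, surface maps |
| `R/fixtures.R` | analytic toy volumes and fixture trees with closed-form statistics |
| `R/io.R` | SWC import/export, YAML configs, pipeline driver |
| `exec/dgforest` | command-line interface |

Tests (`tests/testthat/`) validate the wiring engine against independent
oracles (igraph's minimum spanning tree, exhaustive spanning-tree
enumeration), the packer against the analytic HCP density, the
morphometrics against closed-form fixture trees, and the full pipeline
against the acceptance criteria above.
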