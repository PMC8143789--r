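---
title: "Methods: the cellpotts simulation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cellpotts simulation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model the package implements, the choices made
where the modelling literature leaves the design open, and what the test
suite does and does not establish. It states no empirical result that the
tests or `scripts/acceptance.R` do not themselves compute.

## The model

The cellular Potts model represents each cell as the set of lattice pixels
sharing an integer identity; identity 0 is the background medium. Each
identity maps to a *kind* (cell type, kind 0 = background), and all energy
parameters are per kind. Dynamics proceed by copy attempts: a target pixel
is drawn uniformly, a source pixel uniformly among its kernel neighbors,
and the source identity is copied onto the target with the Metropolis
probability `min(1, exp(-ΔH/T))` (so `ΔH ≤ 0` always succeeds). The
Hamiltonian contains adhesion (each unordered neighbor pair of pixels with
different identities contributes `J` of the two kinds), quadratic volume
elasticity `λ_V (v - V*)²`, and quadratic perimeter elasticity
`λ_P (p - P*)²`. The quadratic forms are the standard
differential-adhesion formulation; the source description of the engine's
energies ("penalties for stretching or compressing") fixes only their
intent, so the field-standard quadratic is adopted.

**Assumptions and conventions** (each of these is a point the CPM
literature does not fix uniquely; the package picks one convention,
documents it, and keeps it configurable where sensible):

- *Coordinates* are 0-based `(x, y)` with `x` indexing width; `y` grows
  downward in rendered images. Grids are toroidal on both axes by default
  (bounded axes are supported; kernel offsets falling off a bounded axis
  are simply dropped, and drop out of perimeter counts too).
- *Kernel*: Moore (8-neighbor) for copy attempts, interface energies,
  perimeter and connectivity alike. Configurable per Hamiltonian.
- *One MCS* = `width × height` attempt resolutions. Null attempts (equal
  identities, off-grid source, immutable pixel) consume an attempt slot.
- *Perimeter* of a cell is the number of ordered (member pixel, non-member
  in-grid neighbor) pairs. This double-counts shared boundary relative to
  some definitions but updates locally and exactly, which keeps the
  incremental `ΔH` exact.
- *Extinct cells*: a cell driven to volume 0 keeps contributing its
  quadratic penalties (`λ_V V*²`, `λ_P P*²`) to `H`. Both the incremental
  `ΔH` and the brute-force oracle use this convention; since the
  contribution of an extinct cell is constant, it never biases dynamics —
  it only keeps the two energy routes identical, which the oracle test
  asserts exactly.
- *`ΔH = 0`* is accepted with probability 1 (continuity of the `≤ 0`
  rule).

## The Act protrusion term

Migration uses the actin-inspired activity mechanism: when a cell conquers
a pixel, that pixel's activity is set to the cell kind's `max_act` and then
decays by 1 per MCS (floor 0, decay once per MCS, not per attempt). For a
proposed copy,

    ΔH_act = -(λ_act / max_act) · (GM_source - GM_target)

where `GM` of a pixel is the geometric mean of activity over the pixel and
its kernel neighbors *belonging to the same cell*; background pixels have
`GM = 0`, and a single zero activity in the set zeroes the mean.
Protrusion from active regions is thereby favoured and retraction into
them penalised. When source and target pixels belong to kinds with
different Act parameters, the source kind's `λ_act/max_act` is used if its
Act term is enabled, otherwise the target kind's; the benchmark
configurations never mix two Act-enabled kinds, so this tie rule is not
load-bearing there.

## Processes

- **Seeding**: requested cells are placed as single-pixel seeds at uniform
  random unoccupied sites within a disc (torus metric). An optional
  burn-in relaxes the state under the Hamiltonian so the volume constraint
  grows seeds toward target. Single-pixel seeds can be annihilated by a
  neighbor before they grow — runs log the realised cell count rather than
  hiding this.
- **Obstacles** are implemented as fresh cells of an *immutable* kind:
  dynamics never select their pixels as targets nor copy their identity
  outward, so the pixel sets are invariant (asserted bit-exactly in the
  acceptance suite), while adhesion with obstacles stays expressible
  through `J`.
- **Growth/division**: each MCS, eligible cells' *target* volumes grow by
  `growth_rate`; a cell whose *actual* volume reaches `division_volume`
  splits by a line through its centroid. In `minor-axis` mode the line is
  perpendicular to the principal axis (eigenvector of the larger
  eigenvalue of the second central moments of torus-unwrapped pixel
  coordinates), so daughters separate along the long axis; `random` mode
  draws a uniform orientation. The eigenvector sign is canonicalised
  (positive x, then positive y) so which daughter keeps the parent id is
  deterministic. Pixels exactly on the line go one at a time, in
  lexicographic order, to the currently smaller daughter, ties to the
  parent side. Degenerate geometries (all pixels projecting together) fall
  back to a median split, then to an index split, so division always
  yields two non-empty daughters for any cell of volume ≥ 2. Cells of
  volume < 2 are skipped with a warning. Cell ids are never reused.

## Observables

Centroids are arithmetic means on bounded axes and circular means on torus
axes (map each coordinate to an angle, average the resultant, map back),
so cells straddling the wrap get the geometrically correct centroid; for
compact cells the two estimators agree to 1e-9, which is tested. The
heterotypic interface counts unordered neighbor pairs whose cells belong
to two different non-background kinds; it is the sorting observable.
Connectivity uses breadth-first search under the dynamics kernel.

## Benchmark parameters

The published protocols fix grids, cell counts, seeding geometry, obstacle
placement and schedules, but reference simulator example files for the
energy values. The package therefore ships its own documented defaults
(in `benchmark_config()` and `inst/extdata/configs/*.json`); changing them
is a config edit, not a code change.

- **Cell sorting** (200×200, 50+50 cells in a radius-67 circle, 2000 MCS):
  `T = 10`, `J` = 16 (cell–medium), 6 (same kind), 20 (cross kind),
  `λ_V = 2`. `V* = 125` was chosen so that 100 cells approximately fill
  the radius-67 seeding disc (~14,100 px → ~141 px/cell, 125 leaves
  slack): the protocol's reference example starts from a confluent
  aggregate, and with a much smaller target volume the initial state is a
  *loose* aggregate whose compaction dominates the heterotypic-interface
  signal for hundreds of MCS. This was fixed once, on that geometric
  argument, and documented here; the sorting criterion is direction-only
  (median over 5 seeds decreases), which the acceptance suite evaluates at
  the full published scale. Burn-in: 50 MCS.
- **Protrusion** (200×200, one cell mid-grid, obstacles radius 10 at ±50
  px, 15,000 MCS): `T = 20`, cell–medium and cell–obstacle `J = 20`,
  `λ_V = 50, V* = 500`, `λ_P = 2, P* = 340`, `λ_act = 200, max_act = 80` —
  the parameter regime of the published Act model for a persistently
  migrating cell.
- **Division** (500×500, 20 founders in a radius-35 circle, 40,000 MCS):
  `T = 10`, `J` = 12 (medium) / 6 (cell–cell), `λ_V = 5`, base
  `V* = 100`, growth 0.2 px/MCS, division at 180 px, minor-axis split.
  The protocol names no division rule; the grow-target-then-threshold
  mechanism is standard CPM proliferation practice and all three
  parameters are config-exposed.
- **Game of Life** (50×50, 500 steps): "random initial conditions" is read
  as i.i.d. Bernoulli(0.5); torus boundaries, matching the lattice
  default.
- **Scalability sweep**: grid side `1.5·√P_tot` and seeding radius
  `0.8·√(P_tot/π)`. The protocol's printed forms omit the square roots
  and are dimensionally inconsistent as lengths; the square-root reading
  makes grid *area* proportional to total cell area (the doubling
  property is tested). Both coefficients are arguments. `P_tot` uses the
  sorting target volume (125 px/cell) by default; the per-cell volume
  behind the published sweep is unstated.

## What the synthetic data does and does not establish

All inputs are generated programmatically (random CA fields, circle-seeded
cells); there are no external datasets. The generators emulate the
*initial conditions* of the published benchmarks — counts, radii, grid
sizes — with single-pixel seeds grown by burn-in standing in for the
unspecified initial cell shapes. They do not emulate measured tissue
geometries, realistic cell-size dispersion, or any biochemical state.
Consequently a green sorting test establishes that differential adhesion
demixes the aggregate under the documented parameters — not that those
parameters reproduce any quantitative figure from the source, which prints
none (its performance numbers are hardware wall times and are excluded
from acceptance by design; throughput is recorded in run manifests as a
diagnostic only).

## Numerical and I/O choices

- Energies are doubles; with integer parameters all arithmetic is exact,
  and the oracle-equivalence test asserts *exact* equality of the
  incremental `ΔH` against the brute-force `total_H` difference over 10⁴
  random attempts. Fractional comparisons (Act geometric means, compact
  centroids) use 1e-9.
- One seedable RNG stream per run (R's global RNG): a trajectory is a pure
  function of (config, seed), asserted by identity of the full lattice
  after repeated runs. Bit-level agreement *across* implementations is
  not promised; distributional tests cover the sampling contracts.
- Configs are JSON (the deployment environment provides no R YAML parser);
  validation collects **all** schema violations, rejects unknown keys, and
  names the offending entries of an asymmetric `J`. The normalised form is
  a fixed point of save/load.
- Frames are PNG (one image pixel per site × integer zoom, fixed palette,
  fill-by-kind / fill-by-cell / borders-only modes) and are byte-identical
  across renders of the same state; statistics are tidy CSV
  (`stats_cells.csv`: one row per mcs × cell; `stats_global.csv`: counts,
  background, heterotypic interface), both including the MCS-0 row.

## Known limitations

2D only; square lattices only; no chemotaxis, connectivity constraint,
reaction–diffusion coupling, or death processes; no parallel update
schemes. The scaled-down runs used in some tests (noted in their comments)
trade equilibration depth for runtime; the acceptance criteria that depend
on long-time behaviour (sorting direction) run at full published scale.
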