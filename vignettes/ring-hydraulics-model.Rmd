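---
title: "Modelling tree-ring water transport from tracheid anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tree-ring water transport from tracheid anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringhydro)
```

## The problem

Measuring xylem hydraulic properties directly is invasive and hard to do
retrospectively, while cross-sectional cell anatomy — lumen diameter and
wall thickness along dated tree rings — is now cheap to measure at scale.
`ringhydro` bridges the two for conifers: it treats the annual ring as a
representative radial file of tracheids and computes its hydraulic
conductance from those two measurements alone, using isometric scaling to
infer the bordered-pit geometry that would otherwise require electron
microscopy.

## Model structure and assumptions

The ring is a set of *parallel, isolated* tracheids: each tracheid
exchanges water chiefly with its tangential neighbours, so conductances
add (`K_ring = Σ K_i`). Within a tracheid, the lumen and the wall (pit)
pathways are in *series* (`R = R_lum + R_wall`). The key assumptions are:

- water travels an overlap fraction `β = 0.5` of the tracheid length
  before crossing a pit;
- all pits of a tracheid are equal-sized, evenly split over the two
  radial walls, so `R_wall = 2 R_pit / N_pit` with the unrounded count
  `N_pit = α L l`;
- pits scale isometrically with lumen diameter (`D_m = 0.70 L` capped at
  `maxD_m`; `D_t = 0.50 D_m`; `D_a = 0.25 D_m`; `D_po = 0.03030 D_m`),
  and margo pores are uniform within a membrane;
- tracheid length `l` and tangential diameter `TD` are constant within a
  run;
- tangential-wall pits (relevant for radial water movement in latewood)
  are outside the axial-flow model.

The single-pit resistance is the series sum of three orifice/tube terms
(margo pores, two canals of length `t_a = WT`, two apertures). Narrow
thick-walled latewood cells are canal-dominated; in wide earlywood cells
the aperture term grows in relative weight and the margo never dominates.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `mu` | water viscosity at 20 °C | 1.002e-9 | MPa·s |
| `l` | tracheid length | 2.2 | mm |
| `TD` | tangential (outer) diameter | 30 | µm |
| `alpha` | pit density on radial walls | 6.5e8 | m⁻² |
| `beta` | overlap factor | 0.5 | — |
| `t_f` | margo strand thickness | 0.140 | µm |
| `maxDm` | pit membrane cap | 22 or 25 | µm |
| `c_Dm, c_Dt, c_Da, c_Dpo` | isometry slopes | 0.70, 0.50, 0.25, 0.03030 | — |
| `epsilon`, `margo_interaction` | margo pore fraction and interaction correction `f(ε)` | 0, `f ≡ 1` | — |

Two profiles package the calibrations used throughout:
`hydraulic_profile("pinaceae")` (maxDm = 22 µm, with the linear wall law
`WT = −8/70·L + 10` attached) for single-tracheid and single-pit
resistance curves, and `hydraulic_profile("larix")` (maxDm = 25 µm) for
the bundled Siberian larch rings, whose dominant trees carry larger pits.
The isometry slopes are parameters, not literals, because published
Pinaceae calibrations come with ± ranges; the defaults are the central
values.

Two parameters deserve comment. The pit density is sometimes quoted an
order of magnitude higher (6.5×10⁹ m⁻²); 6.5×10⁸ m⁻² is the value that
reproduces observed per-cell pit counts (≈52 pits for a 36 µm cell at
l = 2.2 mm) and is the default here. And no published closed form exists
for the interaction correction `f(ε)` between streams through
neighbouring margo pores, nor for the equivalent pore diameter `D_pe`
separate from `D_po`; the package defaults (`f ≡ 1`, `D_pe = D_po`) are
explicit, pluggable decisions (`margo_interaction`, `dpe_map` in
`model_params()`), and reproduce published reference resistances within
a few percent. Any substitute `f` should satisfy `f(0) = 1` and be
monotone in ε.

## Numerical choices

- **Units.** Everything internal is MPa–s–mm. The m³-basis numbers differ
  by exactly 10⁹, which is the classic trap in this literature;
  conversions are only ever explicit (`resistance_to_m3()`,
  `conductance_to_m3()`), and ring outputs carry both bases.
- **Rounding.** `N_pit` and `N_po` are real-valued wherever they enter a
  formula; integer pit counts exist only in written reports.
- **Mork tie-break.** `L = 2·WT` classifies as latewood (earlywood
  requires strict `L > 2·WT`).
- **Crossover search.** `crossover_diameter()` scans L on a ≤0.1 µm grid
  and linearly interpolates the sign change of `R_wall − R_lum`; a
  1000-fold grid refinement moves the answer by <0.001 µm, so the default
  grid is not a precision bottleneck.
- **Degenerate inputs.** Non-positive L or WT, walls with `WT ≥ TD/2`
  (no tangential lumen), duplicate or gapped tracheidogram positions, and
  empty rings are hard errors naming the ring and cell position; an empty
  input file is a warning plus an empty result.

## The synthetic generator

`generate_tracheidogram()` emulates the within-ring anatomy the model
assumes: an earlywood plateau at `L_max`, a monotone (cosine or linear)
decline to `L_min`, wall thickness from a law applied to the *noiseless*
lumen profile, and multiplicative lognormal noise (unit mean, coefficient
of variation `noise_cv`) on L only. Deriving WT from the noiseless
profile keeps the Mork classification stable at low noise — that is a
modelling convenience, not a claim about wood. Defaults (`n_cells = 30`,
`L_max = 40` µm, `L_min = 4` µm, `plateau_fraction = 0.35`,
`noise_cv = 0.05`) mirror the shape and range of the measured Larix
tracheidograms bundled with the package. Determinism: each ring draws
exactly `n_cells` normal deviates from a freshly seeded Mersenne–Twister
stream and restores the caller's RNG state; sweeps derive ring *j*'s
child seed as `seed + j`, so rings regenerate independently.

What the generator does *not* emulate: measurement noise on WT,
multi-file averaging artifacts, intra-annual density fluctuations (double
plateaus), or any cambial-dynamics process. Tests passing on synthetic
rings therefore validate the hydraulic arithmetic and its invariants, not
the anatomical realism of any particular ring.

## Desk-scale problem sizes

The test-suite and sensitivity experiments use rings of 10–60 cells and
ensembles of ~200 synthetic rings, matching the size of measured
tracheidograms (the bundled rings have 21 and 15 cells); each ring is a
vectorised evaluation, so the full suite runs in seconds.

## Worked checkpoints

```{r}
# single-cell benchmark under the curve profile
cv <- run_curves(hydraulic_profile("pinaceae"), L = c(10, 20))
data.frame(L = cv$L, R_m3 = resistance_to_m3(cv$R),
           wall_share = cv$wall_share)

# where wall and lumen resistance balance
crossover_diameter(hydraulic_profile("pinaceae"))

# the two bundled larch rings
p <- hydraulic_profile("larix")
rings <- lapply(larix_rings(),
                function(trg) integrate_ring(tracheid_hydraulics(trg, p)))
ring_table(rings)
```

## Known limitations

- The ring is one representative radial file; averaging multiple files
  into it is upstream of this package, and no radial/tangential network
  topology beyond the parallel idealisation is modelled.
- Uniform margo pore size and the isometric slopes are simplifications;
  real pore-size distributions are broad and membrane-level variability
  is documented.
- No embolism/air-seeding mechanics, no torus aspiration, no whole-tree
  or sapwood-area upscaling.
- The `f(ε)` and `D_pe` defaults absorb a residual few-percent gap
  between modelled and published single-pit resistances.
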