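---
title: "Strand-slippage intermediates of the parallel telomeric G-quadruplex: models, collective variables and reweighting"
author: "g4slip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-slippage intermediates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4slip)
```

## The physical picture

The propeller-type parallel G-quadruplex of the human telomeric repeat
d[AGGG(TTAGGG)3] stacks three G-tetrads: cyclic quartets in which each
guanine donates two Hoogsteen hydrogen bonds to its neighbour
(N1–H···O6 and N2–H···N7) while channel K+ ions coordinate the inward
O6 carbonyls between planes. With all guanines *anti* and all strands
parallel, nothing sterically prevents one strand's G-triplet from
sliding one helical rise along the axis. Such a vertical slip converts
the three-tetrad core into two tetrads plus a three-membered G-triad
(single slip) or two tetrads plus stranded guanines (two triplets
slipping together). These slipped cores are cation-stabilised,
partially folded states on the folding/unfolding pathway of the
parallel topology.

`g4slip` treats this system at two connected levels:

1. **Molecular level** — idealised coordinates for the native and every
   slipped topology; collective variables (CVs) that count the
   Hoogsteen network and the stacking density; classification of frames
   into topologies; geometric stability analyses.
2. **CV-space level** — a well-tempered metadynamics (WT-MetaD) sampler
   running overdamped Langevin dynamics on analytic model potentials,
   used to validate the bias deposition, the reweighting estimators and
   the basin free-energy machinery end to end against exactly known
   answers.

The second level is deliberately a surrogate: sampling the atomistic
landscape needs an explicit-solvent MD engine and is outside this
package's scope (a protocol for that route closes this vignette).

## The topology algebra

The G-core is a 4-column-by-3-plane grid; `defaultStrandLayout()` holds
the guanine residue numbers `[2,3,4], [8,9,10], [14,15,16], [20,21,22]`
(1-based, matching the usual G2…G22 labels of the 22-mer). A slip code
such as `4d` moves one column's guanines one plane towards 3'
("down"); `3u` is the 5'-ward mirror. `applySlip()` partitions the 12
core guanines into tetrads (4-member planes), triads (3-member planes,
tagged 5' or 3') and unpaired guanines; the partition property (every
guanine lands in exactly one class) holds for every code and is
enforced by the class validity.

`enumerateTopologies()` lists all 8 single slips and, at
`max_simultaneous_moves = 2`, the same-direction double slips
(opposite-direction doubles leave only one full tetrad and are dropped
by the ≥ 2-tetrads filter; a flag opens the full double-slip space for
exploration). Single down-slips leave a 5' triad, the one up-slip a 3'
triad, and the doubles no triad at all — e.g.

```{r}
applySlip(code = "24d")
```

## Idealised geometries

`buildIdealG4()` places a guanine template (ideal nucleotide geometry:
base heavy atoms plus C1'/O4' so the glycosidic torsion is defined,
base plane aligned to z = 0) on each grid position. The in-plane pose
of the template is solved at run time by a deterministic Nelder–Mead
refinement from a frozen starting pose, targeting

* Hoogsteen heavy-atom distances N1→O6 and N2→N7 of 2.9 Å between
  C4-symmetric neighbours (`hbond`),
* an O6 channel radius of 2.5 Å (`o6_radius`), which puts an axial K+
  midway between planes within ~3.0 Å of all eight coordinating O6,
* no steric contacts below H-bond range between neighbouring or
  diagonal guanines.

Planes are stacked at `rise = 3.4` Å with `twist = 30°`; a slipped-out
guanine simply continues the helix one rise beyond its end, which
preserves intra-strand stacking — the physical statement that vertical
slippage disrupts Hoogsteen pairing but not the stacked columns.
`core_radius` (5.5 Å) is retained as a weak preference only: the
Hoogsteen and channel constraints determine the pose (achieved base
centroid radius ≈ 4.8 Å), and forcing a larger radius would break the
H-bond geometry.

Cations sit on the axis between consecutive tetrad planes (two for the
native stem, one for two-tetrad cores). For single-slip structures the
triad can be built in three variants:

* **open** (default) — the native-like triad with canonical edges and
  an extra K+ between triad and tetrad (the bipyramidal site with
  3 + 4 O6 contacts);
* **closed** — a C3-symmetric rearranged triad whose neighbours touch
  only through the non-canonical N2→O6 contact, with no triad cation;
* **none** — triad left native-like but without the coordinating ion.

Optional extras give the stability analyses their fixtures: two
bridging waters straddling the triad vacancy midpoint (each within
H-bond reach of both flanking guanines, mimicking the slipped-out
guanine), and a four-atom 5' adenine placeholder whose glycosidic χ is
set exactly, so the *anti*→*syn* flip detector has a controlled input.

**What the generator does not emulate.** Loops and flanking residues
are omitted (or reduced to the A1 placeholder); geometries are ideal,
not force-field minima; thermal motion is represented by i.i.d.
Gaussian coordinate noise rather than correlated vibrations; waters
exist only as the two placed bridges. Tests passing on these fixtures
therefore validate the *algorithms* — pair-list generation, CV
behaviour, classification logic, contact geometry — not the
conformational realism of any particular force field.

## Collective variables

All contact CVs use the rational switching function
s(r) = (1 − x^n)/(1 − x^m) with x = (r − d0)/r0, n = 6, m = 12, the
removable singularity at x = 1 evaluated by its limit n/m, and r < d0
clamped to s = 1.

* **Hb_core** (one per topology): the sum of s over that topology's
  Hoogsteen donor–acceptor pairs, generated programmatically by
  `hoogsteenPairs()` — four cyclic edges per tetrad, two bonds per edge
  (N1→O6, N2→N7; a flag switches to the one-bond-per-edge convention).
  The fully formed native network counts 24, a two-tetrad network 16.
* **pipi_core**: the sum of s over the centroid distances of
  *within-column consecutive* guanine ring pairs. The restriction
  matters: an all-pairs aromatic packing density would double-count
  cross-column diagonals and break the 4 columns × 2 interfaces ≈ 8
  calibration of the native core.

Switching parameters (Å):

| CV family        | d0  | r0  | rationale |
|------------------|-----|-----|-----------|
| H-bond pairs     | 3.2 | 0.5 | formed pairs (2.8–3.1 Å) and their σ = 0.3 Å noise excursions score ≈ 1; a pair stretched by one rise (≈ 4.5 Å) scores ≈ 0; the 0.5 Å decay is what separates the two Hoogsteen networks that transiently coexist mid-slip |
| ring centroids   | 4.0 | 1.5 | stacked interfaces (3.4–4.4 Å depending on twist) score ≈ 1; an interface opened by one extra rise scores < 0.01 |

The flat-top (d0 > 0) form is essential: a zero-offset rational switch
cannot score a 2.9 Å contact near 1 while decaying by 4.5 Å, so no
parameterisation of it reproduces integer contact counts on ideal
geometry. Both CVs are pure functions of interatomic distances, hence
exactly invariant under global rotation and translation, and
coordination is monotone non-increasing when any listed pair
stretches — both properties are asserted in the tests.

## Classification of frames

For each frame the normalised fractions f_X = Hb_core_X / max_X are
computed for the native and every enumerated slipped topology (max_X =
the pair count, i.e. the ideal value). The flow is:

1. f_native ≥ `t_high` (0.80) → **A-like** (native stem).
2. else, the best slipped topology with f_X ≥ `t_slip` (0.70) that
   beats the slipped runner-up by ≥ `t_margin` (0.05) → **X**.
3. else f_native ≥ `t_low` (0.40) → **TS** (barely stacked,
   transition-state-like).
4. else **unassigned**. Ties fall through towards unassigned.

The gates are asymmetric on purpose. A structure part-way through a
slip keeps roughly two thirds of the native network (the tetrad edges
not involving the moving column are shared), so a symmetric gate at
0.75 reads late-transition frames as native. With the native gate at
0.80 and the slipped gate at 0.70, ideal fixtures classify exactly
(native f = 1 vs ≤ 0.67 for slipped codes; the matching slipped code
f = 1 vs ≤ 0.67 for the runner-up), and on noisy interpolated
transitions (σ = 0.3 Å) the first and last quartiles classify to their
endpoints at ≥ 95% across seeds. All four thresholds are exposed in
`classifyFrame()` and `g4RunConfig()`.

A G-triad is called **open** when at least two canonical Hoogsteen
edges are present *and* a cation sits within 4.0 Å of the triad O6
centroid; **closed** when the guanines are hydrogen-bonded through
rearranged edges, or through canonical edges with no coordinating ion
(coordination loss alone must not flip an intact triad to "none");
**none** when fewer than two G:G edges survive. Cutoffs: 3.5 Å
heavy-atom H-bond, 4.0 Å cation, both configurable. Reported contact
counts elsewhere (K+–O6, water bridges) are hard distance counts at
3.5 Å — smooth switching is reserved for CVs.

## The well-tempered engine

`runLangevinWTMetaD()` integrates position Langevin dynamics,
ds = −∇(U + V + W) dt/ζ + sqrt(2 kT dt/ζ) ξ, in 1 or 2 CV dimensions
(compiled kernel; R's RNG, so a seed fixes the trajectory bitwise).
Overdamped dynamics is the right level for validating bias and
reweighting — no masses or thermostats, one friction parameter ζ
(default 1 kJ/mol·ps per unit²). Every `pace` (1 ps) a Gaussian hill of
height W0·exp(−V/((γ−1)kT)) is deposited; defaults W0 = 2.48 kJ/mol,
γ = 20, kT = 2.494 kJ/mol (300 K), widths 0.2/0.5 in the molecular CV
units and 0.1–0.4 on the model potentials.

The bias lives on a regular grid: deposition adds the Gaussian exactly
at every node within 6σ (truncation error < 1e-7 kJ/mol at these
heights — the grid cache is asserted against direct hill summation to
1e-6), and per-step values/gradients are linearly interpolated. The
walker reflects at the grid edges; a NaN/Inf coordinate aborts with the
step number. Wall restraints are one-sided lower walls
κ(t − s)^e (κ = 500, e = 2 by default) — the same form used, at
thresholds Hb_core = 5 and pipi_core = 8, to confine a molecular run
to folded, stacked structures; on the model potentials walls are off
unless requested.

Model potentials (`makeModelPotential()`):

* `harmonic` (k = 10): equipartition and the well-tempered
  effective-temperature check (biased variance → γ·kT/k).
* `double_well_1d`: U = B(s² − 1)² + (a/2)s, barrier B = 15 kJ/mol and
  well asymmetry a = 3 kJ/mol — a two-state landscape whose exact
  free-energy gap comes from quadrature (`wellFreeEnergyGap()`).
* `three_basin_2d`: three inverted Gaussians at (−2,0), (0,2), (2,0)
  with basin levels (0, 8, 13) kJ/mol below-background depths
  (25, 17, 12) and widths scaled as sqrt(depth) so all basins share the
  same bottom curvature — with equal widths the deeper basin would be
  entropically penalised and the level parameters would not translate
  into free-energy gaps. A bowl term confines the flat background.
  This surface mimics a deep native basin, an intermediate
  transition-state basin and a high slipped-ensemble basin;
  `basinQuadrature()` provides the exact reference.

## Reweighting

The unbiasing offset is the standard bias-functional estimator,
evaluated at every hill time on a grid over the biased CVs:

c(t) = (1/β) ln [ Σ exp(βγV/(γ−1)) / Σ exp(βV/(γ−1)) ].

Frame weights are w_i ∝ exp[(V(s_i, t_i) − c(t_i))/kT], with c(t)
interpolated piecewise-constant (left-continuous) between hill times
and the instantaneous bias V(s_i, t_i) recorded by the engine in the
COLVAR table. Weights are invariant to any constant added to both V
and c (checked to 1e-10). `fesFromWeights()` bins any unbiased CVs and
sets F = −kT ln ΣW, referenced to zero at the visited minimum, masking
unvisited bins as NA; with uniform weights it reduces exactly to the
histogram estimator.

`basinFreeEnergy()` sums weights per basin (rectangles in CV space via
`assignBasins()`, or any labelling such as `classifyTrajectory()`
output — for slipped sub-states labels are the right choice because
the sub-ensembles overlap in most low-dimensional CV spaces) and
references to the deepest basin. Uncertainties are standard deviations
over 5 contiguous equal-frame blocks (configurable); block averaging
is the defensible default for a single correlated trajectory.

**Convergence.** `convergenceCheck()` compares −γ/(γ−1)·V snapshots at
checkpoints, mean-aligned on the commonly visited region. For the
asymptotic relation V + (1 − 1/γ)F = const the package checks the bias
averaged over the trailing quarter of the deposition record
(`biasGridAverage`) rather than the instantaneous end-time bias: the
instantaneous profile carries a travelling ripple of the order of the
late hill height wherever the walker last visited, which is a property
of the estimator, not a failure of convergence.

**Problem sizes.** The validation runs use 3e7 steps (dt = 0.002 ps,
so 60 ns of CV-time and 60 000 hills) for the double well, 8e6 steps
for the 2D surface and 1.6e7 for the harmonic checks — sizes chosen so
the stochastic errors (≈ 0.03 kJ/mol on the well gap, ≤ 0.5 kJ/mol
pointwise on well-sampled bins, ≤ 0.3 kJ/mol on 2D basin gaps) sit
well inside the tolerances asserted in the tests, across seeds.
"Well-sampled" means bins whose accumulated weight is ≥ 100 times the
largest single frame weight — a measure of unbiased effective mass;
biased visit counts would promote bins 60 kJ/mol up the walls where no
reweighted estimate can be accurate.

## Degenerate inputs and tie-breaks

Empty selections, empty CV spec lists, single frames for RMSF, missing
atoms for χ, conflicting moves on one column, non-adjacent transition
codes, out-of-order hill times and overlapping basin rectangles all
raise typed errors naming the offending entity. Classification ties
(margin below `t_margin`) fall to TS/unassigned rather than to an
arbitrary topology. The switching function's x = 1 singularity is
evaluated by its n/m limit; distances below d0 saturate at 1.

## Known limitations

* Ideal geometries are calibration fixtures, not conformational
  ensembles; loop dynamics enter only as injected noise.
* Transition trajectories interpolate linearly in Cartesian space — a
  convenient, reproducible path, not a minimum-energy one; mid-path
  frames transiently satisfy both Hoogsteen networks and are
  intentionally read as A-like/TS rather than forced to a label.
* H-bond criteria are distance-only (no angles); contact reporting is
  unswitched by design.
* The engine biases CV-space dynamics; it computes no atomistic
  forces, no CV gradients with respect to coordinates, no kinetics.
* Model potentials are 1D/2D; the classification-based basin
  bookkeeping is exercised at desk scale, not on atomistic ensembles.

## Protocol for full-scale runs

To apply the stack to the real system (the crystallographic parallel
telomeric G4, PDB 1KF1, in explicit solvent with K+):

1. Read the prepared structure (`readStructure()`), keep the channel
   K+; `neutralizingCounterions()` gives the ions to add for a neutral
   box (19 for the 22-mer with two channel ions retained).
2. Export the biased CV definitions: `hoogsteenPairs()` on the native
   composition (Hb_core) and the within-column ring pairs (pipi_core),
   with the switching parameters above, to your MD engine's
   metadynamics plugin; bias both CVs with W0 = 2.48 kJ/mol, pace
   1 ps, γ = 20, widths 0.2 and 0.5, and lower walls at Hb_core = 5
   and pipi_core = 8 to exclude unfolding.
3. Run WT-MetaD externally; the engine's COLVAR/HILLS text output in
   the `#! FIELDS` dialect reads back with `readColvar()`/`readHills()`.
4. Reweight with `computeCt()` + `frameWeights()`; build the FES on
   the unbiased pair (G-core RMSD via `rmsdSpec()` against the
   crystallographic core, and the per-topology Hb_core set) with
   `fesFromWeights()`.
5. Classify frames with `topologyCVSpecs()` + `classifyTrajectory()`,
   and feed the labels to `basinFreeEnergy()` for per-topology free
   energies with block uncertainties; `classifyTriadForm()`,
   `rmsdSeries()`, `rmsf()`, `glycosidicChi()`, `contactSeries()` and
   `waterBridgeCount()` cover the stability analyses of the slipped
   states.

Agreement with published per-topology free energies should be judged
within their reported uncertainties; at that scale the dominant error
is sampling, not the estimators validated here.
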