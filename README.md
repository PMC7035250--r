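# g4slip

Strand-slippage folding intermediates of the parallel human telomeric
G-quadruplex, modelled and classified with well-tempered metadynamics
machinery.

## The problem

The 22-nt human telomeric repeat d[AGGG(TTAGGG)3] folds, in K+, into a
propeller-type parallel G-quadruplex: three stacked G-tetrads (cyclic
quartets of guanines joined by Hoogsteen hydrogen bonds, N1–H···O6 and
N2–H···N7 around the cycle) with channel K+ ions between the planes.
Because every guanine is *anti*, a whole G-triplet (one strand's run of
three guanines, e.g. G20:G21:G22) can slip vertically by one plane.
The slipped states — two full tetrads plus a G-triad, or, when two
triplets slip together, two tetrads with stranded guanines — are the
natural folding/unfolding intermediates of this topology.

`g4slip` provides, for structural bioinformaticians and molecular
modellers studying this pathway:

* **Topology algebra** — enumerate every slipped arrangement of the
  4-column × 3-plane G-core, with the alphanumeric codes used in the
  field (`2d`, `3d`, `3u`, `4d`, `24d`, `34d`; digit = slipping
  G-triplet 5'→3', letter = direction, *d*own toward 3' / *u*p toward
  5'), and generate each topology's Hoogsteen donor–acceptor pair list.
* **Collective variables** — smooth, rotation-invariant counts of the
  Hoogsteen network (`Hb_core`, one per topology) and of the guanine
  stacking density (`pipi_core`), built on a rational switching
  function s(r) = (1 − x^n)/(1 − x^m), x = (r − d0)/r0.
* **A well-tempered metadynamics engine** — overdamped Langevin
  dynamics on analytic model potentials with Gaussian hill deposition
  (height W0·exp(−V/((γ−1)kT))), lower-wall restraints, and
  PLUMED-style COLVAR/HILLS text output.
* **Reweighting** — the time-dependent bias offset c(t), unbiasing
  frame weights w ∝ exp[(V(s,t) − c(t))/kT], free-energy surfaces
  F = −kT ln P on unbiased CVs, and per-basin free energies with
  block-averaged uncertainties.
* **Structure analyses** — Kabsch superposition, G-core RMSD and
  per-residue RMSF, glycosidic χ (syn/anti), K+–O6 contact counts and
  triad water bridges, plus open/closed G-triad calling.
* **A synthetic-data generator** — idealised native and slipped G4
  coordinates (with channel cations, triad variants, bridging waters
  and a χ-settable 5' adenine placeholder), noisy transition
  trajectories, and the model potentials (asymmetric double well;
  a three-basin surface mimicking the native / transition-state /
  slipped-ensemble landscape).

## Worked example

```r
library(g4slip)

pdb    <- system.file("extdata", "ideal_native_g4.pdb", package = "g4slip")
native <- readStructure(pdb)
native
#> G4Structure: 158 atoms, 14 residues
#>   resnames: DG:156 K:2

neutralizingCounterions("AGGGTTAGGGTTAGGGTTAGGG", retained_cations = 2)
#> [1] 19           # K+ ions needed to neutralise the strand's phosphates

specs <- topologyCVSpecs(native)          # Hb_core for native + all slips
coordinationCV(native, specs$native)
#> [1] 24           # 2 H-bonds x 4 edges x 3 tetrads, all formed

s4 <- buildIdealG4("4d", triad_form = "open")
cf <- classifyFrame(s4, specs)
cf$label                                  # flow-diagram assignment
#> [1] "4d"
round(sort(cf$scores, decreasing = TRUE)[1:3], 3)
#>     4d native     1u
#>  1.000  0.666  0.666

applySlip(code = "4d")
#> TetradComposition:
#>   tetrad {G3,G9,G15,G20}
#>   tetrad {G4,G10,G16,G21}
#>   triad {G2,G8,G14} at 5'
#>   unpaired {G22}
classifyTriadForm(s4, c(2, 8, 14))
#> [1] "open"       # canonical edges + a coordinating channel K+
```

The scores are normalised Hoogsteen fractions f_X = Hb_core_X / max_X:
the 4d network is fully formed (1.0) while only the tetrad edges shared
with the native stem survive of the native network (0.666), so the
frame is assigned `4d`.

A desk-scale biased run and its reweighting:

```r
pot <- makeModelPotential("double_well_1d", barrier = 15, asymmetry = 3)
p   <- wtMetaDParams(w0 = 2.48, pace = 1, gamma = 20, sigma = 0.1)
run <- runLangevinWTMetaD(pot, p, n_steps = 2e6, dt = 0.002, s0 = -1,
                          grid = list(c(-2.2, 2.2, 441)), seed = 1)
ct  <- computeCt(run$bias, list(seq(-1.9, 1.9, length.out = 191)), p)
keep <- seq(5e4, nrow(run$colvar))
w   <- frameWeights(run$colvar[keep, ], ct, p@kT)
s   <- run$colvar$cv1[keep]
-p@kT * (log(sum(w[s > 0])) - log(sum(w[s < 0])))
#> [1] 2.76         # reweighted well-to-well dF, kJ/mol
wellFreeEnergyGap(pot, p@kT, lim = 2.2)
#> [1] 2.88         # quadrature truth
```

The higher-level `runGenerate()` / `runSimulate()` / `runReweight()` /
`runClassify()` / `runAnalyze()` commands wrap these steps, write the
TSV/JSON/COLVAR/HILLS artifacts, and stamp every output directory with
a seeded, hashed manifest.

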