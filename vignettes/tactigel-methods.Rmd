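---
title: "Methods and modelling choices in tactigel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in tactigel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactigel)
```

This vignette documents the physical model behind `tactigel`, every
tunable parameter with its units and default, what the synthetic
trajectory generator does and does not emulate, the numerical choices
that affect results, and known limitations.

## 1. Physical model

### System

The package analyses a pair of poly(N-isopropylacrylamide) (PNIPAM)
chains, labelled A and B, each 30 residues long, in an orthorhombic
periodic box (default 9 × 9 × 9 nm). All lengths are in nanometres,
times in picoseconds, energies in kJ/mol.

### Tacticity

Each chain carries a dyad sequence of 29 symbols over {m, r} (meso /
racemo). `pnipamDyadSequences()` returns the two reference sequences:
an atactic chain with 13/29 meso dyads and an isotactic-rich chain with
17/29. Meso percentages are reported with half-away-from-zero rounding
(`mesoFraction`), giving 45% and 59%. `generateBernoullianSequence()`
draws dyads independently with probability `pMeso`, the standard
Bernoullian (zero-order Markov) model of free-radical polymerisation.
`excessMesoCount()` multiplies the per-chain meso difference by the
number of chains; for the two reference sequences and two chains it is
2 × (17 − 13) = 8.

### Residue model

Each residue is reduced to its 7 heavy-atom centres of interest:

| name | role | element | vdW radius (nm) |
|------|------|---------|-----------------|
| C1, C2 | backbone | C | 0.170 |
| N | polar (amide) | N | 0.155 |
| O | polar (carbonyl) | O | 0.152 |
| CI | hydrophobic (isopropyl CH) | C | 0.170 |
| CE, CF | hydrophobic (isopropyl methyls) | C | 0.170 |

Radii are Bondi values (`bondiRadii()`); masses are standard atomic
weights (`atomicMasses()`); the monomer molecular weight is 113.16
g/mol. Hydrogens are implicit everywhere except in the dyad notation.

## 2. Contact model

A contact is an inter-chain atom pair at minimum-image distance less
than or equal to a class-specific cutoff (`defaultContactSpec()`):

| pair class | cutoff (nm) | polarity |
|------------|-------------|----------|
| N(A)–O(B), N(B)–O(A) | 0.38 | polar (H-bond proxy) |
| CE/CF – CE/CF | 0.50 | hydrophobic |
| CE/CF – CI (both directions) | 0.62 | hydrophobic |
| CI – CI | 0.73 | hydrophobic |

Backbone carbons never form contacts. The cutoffs are positions of the
first minimum of the corresponding inter-chain radial distribution
functions; `radialDistribution()` and `firstMinimum()` (moving-average
smoothing, default window 5 bins, bin width 0.002 nm) let users rederive
such cutoffs from their own data. The comparison uses `<=`, so a pair at
exactly the cutoff is a contact.

## 3. Junction statistics

A *junction* is a maximal run of adjacent residues of one chain each of
which touches the other chain (`junctionsPerFrame`). Adjacency is
strict by default: a single non-contacting residue splits a junction. A
`gap` parameter (default 0) optionally merges runs separated by at most
`gap` unflagged residues. Per chain and frame the package reports NJ
(number of junctions), LJ_mean (mean junction length in residues) and
NR (total contacting residues); NR = NJ × LJ_mean by construction, and
`junctionsPerFrame` computes LJ_mean as NR/NJ so the identity is exact.

`summarizeJunctions()` averages over the analysis window, using **only
frames in which the chain has at least one contact**; a window with no
such frame yields NA statistics with an `empty` flag rather than zeros,
so "never in contact" is distinguishable from "in weak contact". Spread
is the population (not sample) standard deviation, matching the
convention of reporting fluctuation over an ensemble of frames rather
than estimating a superpopulation.

**LJ weighting (an open choice made explicit):** the trajectory-level
LJ_mean can weight each *frame* equally (default, `ljWeighting =
"frames"`: the mean of per-frame LJ_mean values) or each *junction*
equally (`"junctions"`: pooled sum(NR)/sum(NJ)). The two differ when
frames have different junction counts. The frame weighting is the
default because the other two summary statistics (mean NR, mean NJ) are
frame-weighted and comparisons across chains then share one ensemble.

## 4. Structural metrics

- `radiusOfGyration()` is mass-weighted over all heavy atoms of both
  chains by default (a selection argument restricts it to one chain);
  coordinates are unwrapped across periodic boundaries first so a chain
  straddling a box face is measured intact.
- `endToEndDistance()` runs from C1 of residue 1 to C2 of residue 30 of
  one chain, on unwrapped coordinates.
- `minDistanceMatrix()` reports, for each of the 60 × 60 residue pairs,
  the minimum-image distance between their closest heavy atoms,
  averaged over the frames of the window.

### SASA

`shrakeRupleySasa()` implements Shrake–Rupley numerical SASA: each
atom's van der Waals sphere is expanded by the probe radius (default
0.14 nm, a water molecule), sampled with `nPoints` quasi-uniform test
points from a golden-spiral (Fibonacci) construction, and a point is
accessible if outside every neighbouring expanded sphere. The default
`nPoints = 960` keeps the isolated-sphere error below 1% and the
960-versus-3840-point discrepancy on a full two-chain frame below 0.5%;
the pipeline default of 240 points trades roughly 1% accuracy for a
4-fold speedup on time series.

## 5. Thermodynamic estimates

These are literature-coefficient arithmetic, not free-energy
calculations:

- `sasaFreeEnergy(deltaSasa, gamma)`: ΔG ≈ γ·ΔSASA with γ = 10
  kJ mol⁻¹ nm⁻² by default; 5 nm² gives 50 kJ/mol.
- `dyadFreeEnergy(excessMeso, dGrToM)`: excess meso dyads × 1.2 kJ/mol
  per dyad; 8 × 1.2 = 9.6, reported as 10 to one significant figure
  (both the exact `value` and the rounded `reported` are returned).
- `swellingRatio(rgCollapsed)`: the collapsed-state volume per two
  chains from a mass balance (2 × 30 × 113.16 g/mol at 10% w/w in a
  1 g/cm³ solution: 112.8 nm³) divided by the volume of the collapsed
  globule. **Sphere-volume closure (an open choice made explicit):** by
  default the globule is a uniform-density sphere whose radius follows
  from Rg via R = √(5/3)·Rg (`radiusConvention = "uniform-sphere"`);
  `"direct"` uses R = Rg and scales the ratio by (5/3)^(3/2) ≈ 2.15.
  The uniform-sphere convention is the default because a collapsed
  globule is closer to uniform density than to a point-mass shell.

## 6. The synthetic trajectory generator

Atomistic simulations of this system run for hundreds of nanoseconds;
`generateTrajectory()` is a deterministic, seeded stand-in that emulates
only the *geometry of configurations* the analysis layer consumes —
self-avoiding chains with 0.25 nm backbone bonds, ≥ 0.15 nm non-bonded
separations, side groups on tacticity-determined sides of the backbone
— not dynamics, forces, solvent, or temperature. Frames are independent
jittered copies of one base configuration; there is no kinetics, so
time-correlation quantities are meaningless on synthetic data.

Four modes set the inter-chain arrangement: `separated` (no inter-chain
pair within any cutoff + 0.15 nm), `touching` (at least one contact),
`aggregated` (at least 25% of each chain's residues in contact), and
`planted` (an exact user-specified residue-contact pattern).

The planted mode is the workhorse for exactness tests: the two chains
are laid out as parallel rods near opposite box faces (2 nm apart
through the periodic boundary), and for each requested residue pair one
atom from each residue is relocated to a private site on a 1.5 nm grid
midway between the chains, at a separation of (cutoff − 0.05 nm) for
its atom class. Each residue has a finite atom pool (one N, one O, one
CI, two methyls), so over-constrained patterns (e.g. six pairs on one
residue) raise an "infeasible planted pattern" error rather than
silently dropping contacts.

**Jitter design:** each frame adds Gaussian noise (SD 0.02 nm,
truncated at ±1.25σ). The two atoms of a planted pair receive the
*same* displacement, so their separation is exactly preserved; without
this, independent jitter on a 0.05 nm margin (≈1.8σ of the relative
displacement) would break planted contacts in a nontrivial fraction of
frames. Unplanted pairs keep ≥ cutoff + 0.05 nm by layout, which
truncated jitter cannot bridge. After jittering, every frame is
re-verified against its mode's contract and re-jittered (up to 100
attempts) if violated, so the generator's guarantees hold per frame,
not just in expectation.

`twoJunctionFixture()` packages the canonical two-junction worked example —
contacts (5,12), (12,20), (13,20) on the isotactic topology — whose
junction decomposition is NR_A = 3, NJ_A = 2, LJ_mean,A = 1.5 and
NR_B = 2, NJ_B = 2, LJ_mean,B = 1.

## 7. Analysis window and problem sizes

`runPipeline()` analyses by default the **last 43%** of the trajectory
time span, the analog of discarding the approach-to-association
transient and averaging over the associated regime (as one would keep
the last 90 ns of a 210 ns run). Frames default to 5 ps spacing. The
30-residue, 2-chain, 9 nm box sizes are the package's own defaults
chosen so every test and example runs in seconds on a laptop; all are
arguments, not constants.

## 8. Verification strategy

Every geometric kernel is tested against an independent brute-force
oracle: minimum-image distances against explicit 27-image enumeration;
contact detection against a flat all-pairs scan with its own name-rule
table, including pairs placed exactly at a cutoff; junction
decomposition against run-length encoding over 10⁴ random flag
vectors; SASA against the analytic sphere, disjoint additivity, full
burial, and point-count convergence; GRO/PDB output against `bio3d` as
an external reader. The planted generator is tested by round trip:
detection on every jittered frame recovers exactly the planted residue
set. `scripts/acceptance.R` recomputes the headline numbers against the
installed package.

## 9. Limitations

- No dynamics: synthetic frames are uncorrelated; lifetimes,
  autocorrelations and kinetics cannot be studied on generated data.
- No solvent or energetics: the free-energy functions are coefficient
  arithmetic; no force field, sampling or perturbation is involved.
- Orthorhombic boxes only; triclinic GRO files are rejected with an
  error rather than mis-read.
- The 7-atom residue model ignores hydrogens and backbone carbonyl
  geometry; SASA values are for the reduced model, not the all-atom
  chain, and should be compared only within the package.
- Exactly two chains of equal length; melts and many-chain aggregates
  are out of scope.
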