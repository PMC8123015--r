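---
title: "Methods: simulating dose enhancement around a platinum nanoparticle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating dose enhancement around a platinum nanoparticle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodef)
```

## The question the package answers

High-Z nanoparticles are studied as radiosensitizers: when a photon beam
irradiates a cell loaded with platinum nanoparticles (Z = 78), the metal
interacts more strongly than tissue — in particular by photoelectric
absorption followed by Auger relaxation — and the resulting short-range
secondary electrons deposit extra energy in the immediate surroundings of
each particle. The quantity of interest is the **dose-enhancement factor
(DEF)**: the energy deposited per concentric shell around the nanoparticle
with platinum in place, divided by the same quantity with an equal water
volume in its place.

`nanodef` computes this for the configuration of a typical in vitro
irradiation: a parallel 662 keV gamma beam (a ^137^Cs source), 2.2 mm of
culture medium (water) above a 10 µm cell layer (water), and an isolated
spherical platinum particle of 3.2 nm core diameter. Energy deposits are
scored in 10 nm concentric shells — the scale of sensitive biomolecular
volumes — out to 2 µm from the particle surface.

The simulation is organised in three stages coupled by phase-space files:

1. **Photon transport** (`run_stage1`): source photons cross the culture
   medium; every particle (photon or secondary electron) entering the cell
   layer is recorded with its position, energy and direction.
2. **Nanoparticle stage** (`run_stage2`): the recorded field is driven onto
   the 3.2 nm sphere — platinum arm and water control arm — with forced
   interaction; the electrons escaping the sphere are recorded.
3. **Shell scoring** (`run_stage3`, `compute_def`): the escaping electrons
   (and the accompanying electron field) are transported in water and their
   deposits accumulated per shell, from which the DEF profile and its
   batch uncertainties follow.

## Physics model

### Photons

Compton scattering is sampled from the Klein–Nishina distribution on free
electrons (two-branch composition/rejection). Doppler broadening and
binding corrections are omitted; at 662 keV they are sub-percent effects.
Photoelectric absorption uses compact vendored cross-section tables with
explicit subshell edges for platinum (K at 78.394 keV, L1/L2/L3, effective
M and N edges) and log-log interpolation between grid nodes; the subshell
receiving the vacancy is sampled from tabulated region-wise shares derived
from edge-jump ratios. Rayleigh scattering changes direction only (a
Thomson-shaped angular law) and deposits no energy. Bremsstrahlung is
neglected: the radiative yield of sub-MeV electrons in water is below 1%.

### Atomic relaxation

A vacancy relaxes radiatively with probability equal to its fluorescence
yield (one characteristic photon, one daughter vacancy) or by Auger
emission (one Auger electron, two daughter vacancies one shell group
further out). The cascade is followed K → L → M → N for platinum; N
vacancies terminate with a ~300 eV Auger electron and a local deposit.
Energy is conserved exactly at every step: emitted energy never exceeds
the binding energy and the remainder is deposited on the spot. A single
K-shell photoabsorption therefore yields a photoelectron plus typically
6–8 cascade electrons between ~0.3 and 7 keV — the soft, short-range
component that dominates the near-particle enhancement. Coster–Kronig
transitions and shake-off are not modelled, so the true low-energy
multiplicity is still somewhat underestimated.

### Electrons

Electron transport is condensed-history in the continuous-slowing-down
approximation: each step consumes a fixed fraction (`step_frac`, default
0.05) of the current CSDA range, the energy after the step is read off the
range table (which makes per-track energy conservation exact by
construction), and the deposit is placed at the step midpoint. Direction
is perturbed per step: a Highland-parameterised Gaussian small angle above
10 keV (variance proportional to step length, so results are invariant
under step subdivision), and an isotropic redirection below 10 keV fired
with probability `step / (step_frac * range)` — low-energy electrons in
water scatter quasi-isotropically, and the path-scaled probability keeps
the angular diffusion per unit path independent of any scoring-driven step
capping. Tracking stops at 100 eV (the floor of the vendored tables) with
local deposition; knock-on (delta-ray) branching is not modelled, its
energy staying in the continuous loss — a redistribution below the 10 nm
scoring ambition.

Two numerical details matter near the scoring region. First, a step is
never allowed to leap across it: within (or approaching) the scored 2 µm
sphere the step is capped at 10 nm — with the cap ramping off as
`max(10 nm, distance beyond the region)` so that distant tracks advance at
full speed but can never jump over the shells. Second, when a track
terminates (next energy at or below 1.5x the cutoff) the remaining energy
is deposited at the end of its residual range along the current direction;
this makes the straight-ahead endpoint exactly equal to the CSDA range and
keeps the last ~50 eV from being parked a step short.

### Vendored data

All tables ship as plain-text CSV under `inst/extdata/physics/` and are
generated once by `data-raw/make_physics_tables.R`: Klein–Nishina closed
forms for the incoherent component; piecewise power-law photoelectric fits
calibrated to standard reference anchor values (the water total at 662 keV
reproduces 0.0857 cm²/g to better than 1%); the relativistic Bethe formula
(with the Møller closure) for collision stopping powers above 10 keV
(water) / 30 keV (platinum), joined to standard low-energy anchor values
below; CSDA ranges by integration of the reciprocal stopping power from
the 100 eV floor. Accuracy targets are a few percent for water and ~10%
for the platinum photoelectric component, adequate for shell-dose ratios.
The platinum stopping power below ~2 keV is an approximate solid-state
extension and is the least certain table in the package; it controls how
much of the sub-keV cascade is self-absorbed in the particle.

## The forced-interaction scheme and normalisation

A 3.2 nm target intercepts a traversing 662 keV photon with probability
~5×10⁻⁷, so analog simulation is hopeless. Every photon record is instead
aimed at the sphere (impact parameter uniform over the geometric
cross-section) and **forced** to interact along its chord with statistical
weight `w = 1 − exp(−μ_total · chord)`, the interaction point drawn from
the truncated exponential and the process chosen by relative attenuation.
The estimator is unbiased by construction; weights are never split, so
total outcome weight equals total injected weight exactly.

All tallies are normalised **per primary history for a beam fluence of one
primary per nm²**: the nanoparticle term carries the geometric factor
π r² (the rate at which a unit fluence feeds the cross-section disc) and
the background term the corresponding per-area weight. The DEF is the
ratio of the two arms' totals and is independent of the reference area.

### Electronic equilibrium and the background field

In `equilibrium` mode the secondary-electron field recorded in stage 1
accompanies the photons, establishing charged-particle equilibrium in the
scored shells. Because that field is laterally uniform on the micrometre
scale, its lateral coordinate is integrated analytically: a deposit at
depth *z* contributes to the shell `[r1, r2)` the disc area
`π((r2² − z²)₊ − (r1² − z²)₊)` per unit normalisation area. This
conditional-expectation (Rao–Blackwell) reduction removes the lateral
sampling noise entirely and makes the estimate *exactly* independent of
the equilibrium sampling radius, provided it exceeds its admissible
minimum (the CSDA range of the most energetic recorded electron, which
`run_stage2` enforces). The measured background deposit density,
~1.4×10⁻³ eV/nm³ per unit fluence, is about two thirds of the ideal
equilibrium kerma of a 662 keV beam — the expected shortfall for a 2.2 mm
buildup with no photon regeneration below the recording plane.

Both arms are scored against the **same background realisation** (same
records, same seed). This correlated-sampling choice is what makes a
relative enhancement of order 10⁻⁴ statistically resolvable at desk-scale
statistics: in the DEF ratio the shared background cancels, leaving only
the arm-specific nanoparticle terms to fluctuate. Consequently the DEF
uncertainty is estimated from the spread of *per-batch DEF ratios* (20
history batches by default) rather than from the quadrature of the two
arms' batch standard errors — quadrature would ignore the correlation and
overstate the uncertainty by orders of magnitude. The water-vs-water null
pipeline calibrates this estimator: the profile is 1 within two standard
errors in well over 95% of shells.

### The nanoparticle-sized beam and the equilibrium bias

`np_sized` mode implements the biased construction long warned against in
nanodosimetry: the beam is shrunk to the particle's own cross-section and
the accompanying electron field is discarded, so the denominator of the
DEF contains only the (rare) interactions in the water control sphere
rather than the full equilibrium dose. `equilibrium_bias()` reports the
ratio of the two constructions' peak DEFs. In this package's
fluence-normalised terms the bias is enormous — about three orders of
magnitude — because the water-sphere interaction rate is ~25× below
platinum's while the equilibrium background exceeds both by far.

### What the numbers mean — and what "DEF" means elsewhere

Under the fluence-normalised equilibrium construction a *single, isolated*
3.2 nm platinum sphere perturbs the local dose only weakly: the peak
enhancement is ~2×10⁻⁴ in the first shell, falling to ~10⁻⁶ by 50 nm.
That scale is fixed by first principles: the extra energy released per
unit fluence is bounded by `V_np · μ_Pt · E`, while the equilibrium dose
in a shell is `μ_en,water · E · V_shell`, and a 17 nm³ platinum inclusion
simply cannot triple the dose in a 3×10⁵ nm³ shell 45 nm away. Much larger
DEF values quoted in the radio-enhancement literature (factors of 2–10)
arise from different bookkeeping — beams collimated to the particle,
normalisation per interacting photon, or high particle concentrations —
not from the fluence-normalised single-particle quantity computed here.
The package therefore reports both constructions and the bias between
them; the *shape* of the equilibrium profile (a sub-100 nm principal peak
from the M/N-cascade electrons, a secondary structure near the ~6 keV
L-Auger range at several hundred nm, and decay below any practical
significance threshold beyond ~1.9 µm) is the physically robust content.

## Scoring conventions

Shells are indexed from the particle **surface**, half-open
`[i·t, (i+1)·t)` with t = 10 nm by default, and the profile reports shell
mid-radii. Deposits inside the sphere volume go to a dedicated internal
bin; deposits beyond the extent are discarded but counted. Re-aggregating
a 5 nm tally in pairs reproduces the 10 nm tally exactly. Tracks are
dropped only when provably unable to re-enter the scored region
(`distance − remaining range > extent`), which is conservative and exact.

## The synthetic fixtures

`make_pencil_beam()`, `make_toy_material()` and `make_golden_phsp()` make
every stage testable without running the stages upstream of it. Toy
materials have constant attenuation and stopping power, so transmission
(exponential law) and range (linear in energy) have closed forms; the
golden phase space is a 600-record, seed-reproducible caricature of the
stage-1 output (a dominant 662 keV line, a single-scatter continuum
bounded below by the 184 keV backscatter energy, a soft electron
continuum) committed as CSV. These fixtures emulate the *structure* of
real fields, not their physics: passing tests on them validates
bookkeeping, geometry, conservation and determinism, while agreement of
stage 1 with the Beer–Lambert oracle and of the scoring with analytic
disc-integral oracles validates the transport itself. None of this
certifies the vendored platinum tables beyond their stated ~10% accuracy.

## Default problem sizes

The shipped defaults are chosen so a full two-mode pipeline runs in
minutes on one core while keeping the correlated DEF profile resolved:
10⁵ primary histories in stage 1 for the analysis scripts and the
acceptance computation (2.5×10⁴ in the test suite), one phase-space reuse
in stage 2, 10 background reuses in stage 3, and 20 history batches. All
seeds are explicit; rerunning any stage with the same seed reproduces its
output byte for byte.

## Known limitations

* Condensed-history CSDA transport replaces event-by-event track
  structure; sub-10 nm dose microstructure is smoothed, and the first one
  or two shells inherit that smoothing.
* No delta-ray branching and a single-branch relaxation cascade: the
  escaping-electron spectrum is harder than a full cascade/track-structure
  treatment would give; in this model roughly 45% of the escaping weight
  lies below 3 keV, and a fuller cascade would push that above one half.
* The irradiator is a single clean 662 keV parallel beam; scattered
  photons from a real self-shielded irradiator cavity (and the 32 keV Ba
  X-ray line) would soften the field and increase the photoelectric share.
* Water radiolysis chemistry and any biological response are out of scope;
  the pipeline stops at physical energy deposition.
* The platinum sub-keV stopping power is an approximate extension; it
  mainly affects how much cascade energy is self-absorbed in the particle.
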