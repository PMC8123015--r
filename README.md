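# nanodef

Monte Carlo simulation of the dose-enhancement effect of a platinum
nanoparticle irradiated by a ^137^Cs gamma source in a cell-culture
geometry.

`nanodef` is for computational radiobiologists and medical physicists who
want a self-contained, desk-scale reimplementation of the three-stage
nanodosimetry pipeline used to predict radio-enhancement by high-Z
nanoparticles: photon transport through the culture medium, forced
interaction on a nanometric metal sphere, and energy-deposit scoring in
concentric nanometre shells. Everything — photon cross sections, electron
stopping powers, atomic relaxation data — ships with the package as
plain-text tables; there are no external data dependencies.

## The quantity computed

For an isolated spherical platinum particle (diameter d = 3.2 nm, Z = 78)
in water under a parallel 662 keV photon beam, the **dose-enhancement
factor** in the spherical shell `[r, r + Δr)` measured from the particle
surface is

```
DEF(r) = E_Pt(r) / E_water(r)
```

where `E_Pt` and `E_water` are the energy deposits per primary history
(per unit beam fluence) scored with the sphere made of platinum and of
water, respectively. Photons are forced to interact along their traversal
chords with statistical weight `w = 1 − exp(−μ_total ρ ℓ)` (unbiased
variance reduction); electrons are transported with condensed-history
CSDA stepping down to 100 eV; platinum vacancies relax through a K→L→M→N
Auger cascade. In the *electronic-equilibrium* construction the
secondary-electron field entering the cell layer accompanies the photons
and provides the background dose; in the *nanoparticle-sized-beam*
construction that field is ignored — the biased bookkeeping that
dramatically overstates enhancement.

## Worked example

A reduced-statistics run of the full pipeline (2×10⁴ primaries, one CPU,
under a minute):

```r
library(nanodef)
cfg <- pipeline_config(histories = 2e4, resamples = 1, bg_resamples = 10,
                       n_batches = 20, modes = c("equilibrium", "np_sized"),
                       seed = 42)
res <- run_pipeline(cfg, quiet = TRUE)
d <- res$def$equilibrium
head(as.data.frame(d), 5)
#>   shell r_mid_nm      def      rel_unc    e_pt_eV e_water_eV
#> 1     0        5 1.000175 1.790105e-05   9.497481   9.495816
#> 2     1       15 1.000032 3.253059e-06  52.220927  52.219260
#> 3     2       25 1.000005 4.942798e-07 138.088683 138.088034
#> 4     3       35 1.000001 9.281119e-08 286.393577 286.393385
#> 5     4       45 1.000000 4.190180e-08 482.437868 482.437725

def_report(d)
#> DEF maximum: 1.00018 +- 1.8e-05 at 5 nm from the nanoparticle surface
#> DEF near 100 nm: 1 +- 1.9e-08
#> plateau 0.2-1.5 um: enhancement 2.6e-09% to 2.4e-06%
#> no appreciable enhancement (>5%) at any distance

equilibrium_bias(res$def$np_sized, d)
#> [1] 1488
```

Reading the numbers: `e_water_eV` is the equilibrium background dose per
shell (it grows with shell volume); the platinum arm adds a small excess
concentrated in the first shells — the Auger-cascade electrons from
photoelectric events in the metal. Under fluence normalisation a single
3.2 nm particle enhances the local dose by only ~2×10⁻⁴ at its surface
(resolvable here at ~10 standard errors thanks to correlated sampling of
the shared background), decaying to nothing within tens of nanometres.
The last line is the cautionary result: shrinking the beam to the
particle's own cross-section and dropping the electron field inflates the
apparent peak enhancement by three orders of magnitude. The methods
vignette (`vignettes/nanodef-methods.Rmd`) discusses why fluence-normalised
single-particle DEF values are intrinsically small and how the much larger
factors quoted in the radio-enhancement literature arise from different
normalisations.

The `analysis/` directory holds the same study as three narrative scripts
(`01_photon_transport.R`, `02_np_stage.R`, `03_def_profiles.R`) that write
phase-space files, escape spectra and DEF profiles under `results/`.

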