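# Stage 1: Beer-Lambert behaviour, spectra, bookkeeping, determinism.

test_that("toy-material transmission follows the closed form within 3 sigma", {
  toy <- make_toy_material(mu_total = 2, S = 10, density = 1)
  g <- slab_geometry(medium_nm = 5e6, cell_nm = 1e4, medium = toy) # 0.5 cm
  n <- 4000
  ps <- run_stage1(source_spec(), g, n, seed = 13)
  p_exp <- analytic_transmission(g, 662e3)
  # uninteracted photons: unscattered 662 keV records moving straight +z
  r <- ps$records
  unint <- sum(r$kind == "photon" & r$energy_eV == 662e3 & r$uz == 1)
  expect_lt(abs(unint - n * p_exp), 3 * sqrt(n * p_exp * (1 - p_exp)) + 1)
})

test_that("137Cs through 2.2 mm water matches the analytic attenuation", {
  ps <- small_stage1()
  n <- ps$header$n_primaries
  p_exp <- analytic_transmission(slab_geometry(), 662e3)
  r <- ps$records
  unint <- sum(r$kind == "photon" & r$energy_eV == 662e3 & r$uz == 1)
  expect_lt(abs(unint - n * p_exp), 3 * sqrt(n * p_exp * (1 - p_exp)))
})

test_that("the photon spectrum entering the cell layer is 662 keV dominated", {
  ps <- small_stage1()
  br <- seq(0, 7e5, length.out = 36)
  sp <- summarize_spectrum(ps, "photon", br)
  expect_equal(which.max(sp$count_per_primary),
               findInterval(662e3, br))
})

test_that("per-run energy bookkeeping closes to 1e-6", {
  el <- attr(small_stage1(), "energy_ledger")
  closure <- el$source_eV -
    (el$recorded_eV + el$deposited_eV + el$escaped_eV)
  expect_equal(closure / el$source_eV, 0, tolerance = 1e-6)
})

test_that("recorded energies respect the kinematic ceilings", {
  r <- small_stage1()$records
  expect_lte(max(r$energy_eV[r$kind == "photon"]), 662e3)
  # Compton edge for 662 keV (verified against the backscatter relation)
  edge <- 662e3 - 662e3 / (1 + 2 * 662e3 / 510998.95)
  expect_equal(edge, 477650.5, tolerance = 1e-6)
  if (any(r$kind == "electron"))
    expect_lte(max(r$energy_eV[r$kind == "electron"]), edge)
})

test_that("a fixed seed reproduces the phase-space file byte for byte", {
  g <- slab_geometry()
  ps1 <- run_stage1(source_spec(), g, 1500, seed = 99)
  ps2 <- run_stage1(source_spec(), g, 1500, seed = 99)
  f1 <- tempfile(); f2 <- tempfile()
  write_phase_space(ps1, f1); write_phase_space(ps2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("analytic transmission has the exponential properties", {
  g <- slab_geometry(medium_nm = 1, cell_nm = 1)
  expect_equal(analytic_transmission(g, 662e3), 1, tolerance = 1e-6)
  expect_error(run_stage1(source_spec(), slab_geometry(), 0), ">= 1")
  expect_error(source_spec(data.frame(energy_eV = 1e3, intensity = 0.5)),
               "sum to 1")
  expect_error(slab_geometry(medium_nm = -1), "positive")
})
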