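# Synthetic fixtures: pencil beams, toy materials, the golden phase space.

test_that("pencil beams are monoenergetic unit-weight +z photons", {
  ps <- make_pencil_beam(662e3, 1)
  expect_equal(nrow(ps$records), 1)
  r <- ps$records
  expect_equal(sqrt(r$ux^2 + r$uy^2 + r$uz^2), 1)
  expect_equal(r$uz, 1)
  sp <- summarize_spectrum(make_pencil_beam(5e4, 20), "photon",
                           c(1e3, 4e4, 6e4, 1e5))
  expect_equal(sp$count_per_primary, c(0, 1, 0))
  expect_error(make_pencil_beam(1e3, 0), ">= 1")
})

test_that("toy materials obey the closed-form exponential and linear range", {
  toy <- make_toy_material(mu_total = 1, S = 10, density = 1)
  g <- slab_geometry(medium_nm = 1e7, cell_nm = 1e4, medium = toy)  # 1 cm
  expect_equal(analytic_transmission(g, 5e4), exp(-1), tolerance = 1e-9)
  # doubling the thickness squares the transmission
  g2 <- slab_geometry(medium_nm = 2e7, cell_nm = 1e4, medium = toy)
  expect_equal(analytic_transmission(g2, 5e4),
               analytic_transmission(g, 5e4)^2, tolerance = 1e-12)
  # constant stopping power: range linear in energy above the floor
  E <- c(1e4, 2e4, 4e4)
  r <- csda_range(toy, E)
  expect_equal(r, (E - 100) / (10 * 1e6) * 1e7, tolerance = 1e-3)
})

test_that("the golden phase space regenerates byte-for-byte from its seed", {
  ps <- make_golden_phsp(seed = 404L)
  ref <- read_phase_space_csv(system.file("extdata", "golden_phsp.csv",
                                          package = "nanodef"))
  expect_equal(ps$records, ref$records, tolerance = 1e-15)
  expect_equal(ps$header$n_primaries, ref$header$n_primaries)
  # round trip through the binary container as well
  f <- tempfile()
  write_phase_space(ps, f)
  expect_identical(read_phase_space(f)$records, ps$records)
  unlink(f)
})

test_that("the golden phase space drives stages 2-3 end to end", {
  ps <- make_golden_phsp(seed = 404L)
  t0 <- Sys.time()
  s2p <- run_stage2(ps, np_spec("Pt"), beam_mode("equilibrium"),
                    resamples = 1, seed = 3)
  s2w <- run_stage2(ps, np_spec("water"), beam_mode("equilibrium"),
                    resamples = 1, seed = 3)
  bn <- shell_binning(20, 400)
  tp <- run_stage3(s2p, bn, n_batches = 4, seed = 5, bg_resamples = 2)
  tw <- run_stage3(s2w, bn, n_batches = 4, seed = 5, bg_resamples = 2)
  d <- compute_def(tp, tw)
  expect_true(all(is.finite(d$def)))
  expect_gt(max(d$def), 1)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})
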