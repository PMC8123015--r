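# Stage 2: chord geometry, forced-interaction weighting, conservation.

test_that("chord length has the closed-form limits and mean 2d/3", {
  expect_equal(chord_length(3.2, 0), 3.2)
  expect_equal(chord_length(3.2, 1.6), 0)
  expect_equal(chord_length(3.2, 5), 0)
  expect_error(chord_length(3.2, -1), ">= 0")
  # mean chord under uniform-disc impact sampling (mean-chord theorem)
  set.seed(21)
  b <- 1.6 * sqrt(runif(2e5))
  expect_equal(mean(chord_length(3.2, b)), 2 * 3.2 / 3, tolerance = 0.005)
})

test_that("forced-interaction weights match the closed-form chord average", {
  ps <- make_pencil_beam(662e3, 4000)
  s2 <- run_stage2(ps, np_spec("Pt"), beam_mode("np_sized"),
                   resamples = 1, seed = 5)
  mu <- mass_attenuation(mat_platinum(), 662e3) * 21.45 * 1e-7  # 1/nm
  # oracle: E[1 - exp(-mu * 2 sqrt(r^2 - b^2))] over the uniform disc
  r <- 1.6
  oracle <- stats::integrate(function(b)
    (1 - exp(-mu * 2 * sqrt(r^2 - b^2))) * 2 * b / r^2, 0, r,
    rel.tol = 1e-10)$value
  got <- s2$stats$sum_forced_weight / s2$stats$n_events
  expect_equal(got, oracle, tolerance = 0.03)
  # no event weight can exceed the central-chord weight
  w_max <- 1 - exp(-mu * 3.2)
  expect_lte(max(s2$escape$records$weight), w_max * (1 + 1e-12))
})

test_that("weight and energy bookkeeping close exactly", {
  s2 <- small_stage2_pt()
  st <- s2$stats
  expect_equal(st$sum_outcome_weight, st$sum_forced_weight,
               tolerance = 1e-9)
  closure <- st$energy_in_w_eV -
    (st$escape_energy_w_eV + st$absorbed_energy_w_eV +
       st$fluorescence_escape_w_eV + st$scattered_photon_escape_w_eV)
  expect_equal(closure / st$energy_in_w_eV, 0, tolerance = 1e-9)
  # all escaping electrons of one forced event share that event's weight
  r <- s2$escape$records
  spread <- tapply(r$weight, r$history, function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("per-event escaping energy never exceeds the incident energy", {
  s2 <- small_stage2_pt()
  r <- s2$escape$records
  e_out <- tapply(r$energy_eV, r$history, sum)
  ps <- small_stage1()
  phr <- ps$records[ps$records$kind == "photon", ]
  e_in <- phr$energy_eV[as.integer(names(e_out))]
  expect_true(all(e_out <= e_in * (1 + 1e-9)))
})

test_that("escaping electrons start on the sphere surface, moving outward", {
  r <- small_stage2_pt()$escape$records
  d <- sqrt(r$x_nm^2 + r$y_nm^2 + r$z_nm^2)
  expect_equal(d, rep(1.6, length(d)), tolerance = 1e-6)
  outward <- r$x_nm * r$ux + r$y_nm * r$uy + r$z_nm * r$uz
  expect_true(all(outward > -1e-9))
})

test_that("the water control arm behaves as a control", {
  s2w <- small_stage2_water()
  s2p <- small_stage2_pt()
  # water interacts far less than platinum per traversal
  expect_lt(s2w$stats$sum_forced_weight, s2p$stats$sum_forced_weight / 10)
  # its spectrum is dominated by Compton electrons (no platinum cascade)
  expect_gt(nrow(s2w$escape$records), 0)
})

test_that("equilibrium radius below the admissible minimum is rejected", {
  ps <- small_stage1()
  expect_error(run_stage2(ps, np_spec("Pt"),
                          beam_mode("equilibrium", eq_radius_nm = 10),
                          resamples = 1, seed = 1),
               "below the admissible minimum")
  expect_error(run_stage2(phase_space(data.frame(), 1), np_spec("Pt")),
               "empty phase space")
})

test_that("np_sized mode carries no background field", {
  ps <- small_stage1()
  s2 <- run_stage2(ps, np_spec("Pt"), beam_mode("np_sized"),
                   resamples = 1, seed = 2)
  expect_null(s2$bg)
  s2e <- small_stage2_pt()
  expect_false(is.null(s2e$bg))
  expect_true(all(s2e$bg$records$kind == "electron"))
})
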