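# Shell scoring, DEF profiles, peaks and the equilibrium-bias ratio.

np0 <- function() np_spec("water", diameter_nm = 3.2)

test_that("deposits land in the right shells with half-open boundaries", {
  np <- np0()
  bn <- shell_binning(10, 100)
  dep <- data.frame(x_nm = c(1.6 + 15, 1.6 + 20, 0.5, 1.6 + 200),
                    y_nm = 0, z_nm = 0, energy_eV = c(100, 50, 25, 10))
  t <- score_shells(dep, np, bn)
  expect_equal(t$energy[2], 100)       # 15 nm -> shell [10, 20)
  expect_equal(t$energy[3], 50)        # exactly 20 nm -> shell [20, 30)
  expect_equal(t$internal, 25)         # inside the sphere volume
  expect_equal(t$beyond_energy, 10)    # beyond the extent, logged
  expect_equal(t$beyond_count, 1)
  # conservation: shells + internal + beyond = total
  expect_equal(sum(t$energy) + t$internal + t$beyond_energy,
               sum(dep$energy_eV), tolerance = 1e-12)
})

test_that("uniform deposits in an annulus score proportionally to volume", {
  set.seed(33)
  n <- 2e5
  r <- (50^3 + (150^3 - 50^3) * runif(n))^(1 / 3)   # uniform in volume
  u <- matrix(rnorm(3 * n), n, 3); u <- u / sqrt(rowSums(u^2))
  dep <- data.frame(x_nm = r * u[, 1], y_nm = r * u[, 2], z_nm = r * u[, 3],
                    energy_eV = 1)
  np <- np0(); bn <- shell_binning(10, 200)
  t <- score_shells(dep, np, bn)
  # shells fully inside the annulus: energy ratio = volume ratio
  vol <- function(i) (1.6 + 10 * i)^3 - (1.6 + 10 * (i - 1))^3
  sel <- 7:13                          # [60,70) ... [120,130) from surface
  expect_equal(t$energy[sel] / t$energy[8],
               vapply(sel, vol, 1) / vol(8), tolerance = 0.05)
})

test_that("halving shell thickness and re-aggregating pairs is exact", {
  set.seed(9)
  n <- 5000
  dep <- data.frame(x_nm = rnorm(n, 0, 300), y_nm = rnorm(n, 0, 300),
                    z_nm = rnorm(n, 0, 300), energy_eV = runif(n))
  np <- np0()
  t10 <- score_shells(dep, np, shell_binning(10, 400))
  t5 <- score_shells(dep, np, shell_binning(5, 400))
  agg <- t5$energy[seq(1, 79, 2)] + t5$energy[seq(2, 80, 2)]
  expect_identical(agg, t10$energy)
})

test_that("DEF identities: equal arms give 1, scaling is linear", {
  set.seed(4)
  bm <- matrix(abs(rnorm(200 * 4, 10)), 200, 4)
  t1 <- nanodef:::new_shell_tally(bm, 0, 0, 0, shell_binning(10, 2000), np0())
  d <- compute_def(t1, t1)
  expect_true(all(d$def == 1))
  t2 <- nanodef:::new_shell_tally(2 * bm, 0, 0, 0, shell_binning(10, 2000),
                                  np0())
  expect_true(all(compute_def(t2, t1)$def == 2))
  expect_error(compute_def(t1, nanodef:::new_shell_tally(
    bm, 0, 0, 0, shell_binning(20, 2000), np0())), "mismatched")
})

test_that("find_peaks flags only significant local maxima", {
  flat <- data.frame(shell = 0:49, r_mid_nm = seq(5, 495, 10),
                     def = rep(1, 50), rel_unc = rep(0.01, 50))
  class(flat) <- c("ndf_def_profile", "data.frame")
  expect_equal(nrow(find_peaks(flat)), 0)
  bump <- flat
  bump$def[11] <- 1.5
  pk <- find_peaks(bump)
  expect_equal(pk$r_mid_nm, 105)
  expect_equal(pk$def, 1.5)
  # a bump smaller than twice its uncertainty is not a peak
  bump$def[11] <- 1.015
  expect_equal(nrow(find_peaks(bump)), 0)
  expect_error(find_peaks(flat[1:2, ]), "at least 3")
})

test_that("equilibrium_bias is the ratio of peak DEFs", {
  p <- data.frame(shell = 0:9, r_mid_nm = seq(5, 95, 10),
                  def = c(1, 1, 3, 1, 1, 1, 1, 1, 1, 1), rel_unc = 0.01)
  class(p) <- c("ndf_def_profile", "data.frame")
  expect_equal(equilibrium_bias(p, p), 1)
  p10 <- p; p10$def <- 10 * p$def
  expect_equal(equilibrium_bias(p10, p), 10)
  pna <- p; pna$def <- NA_real_
  expect_error(equilibrium_bias(pna, p), "undefined peak")
})

test_that("background scoring matches the analytic uniform-beam oracle", {
  # straight-ahead monoenergetic electrons from z = 0 in a constant-stopping
  # toy medium: dE/dz = S * rho up to the range R; the expected shell energy
  # per track is the analytic integral of the lateral disc weights
  toy <- make_toy_material(mu_total = 1, S = 20, density = 1)  # R(E) = E/20 nm... (eV per nm: S*rho*1e-7*1e6*... )
  cfg <- transport_config(step_frac = 0.05, angular = "none")
  np <- np0(); bn <- shell_binning(10, 100)
  n <- 50
  res <- nanodef:::.score_transport_annulus(
    rep(5e4, n), rep(0, n), matrix(rep(c(0, 0, 1), each = n), n, 3),
    rep(1, n), rep(1:2, length.out = n), 2, toy, cfg, np, bn)
  got <- rowSums(res$acc) / n
  dEdz <- 20 * 1 * 0.1                # MeV cm2/g * g/cm3 -> eV/nm
  R <- csda_range(toy, 5e4)
  r_edges <- 1.6 + 10 * (0:10)
  oracle <- vapply(1:10, function(s) {
    f <- function(z) pi * (pmax(0, r_edges[s + 1]^2 - z^2) -
                             pmax(0, r_edges[s]^2 - z^2))
    stats::integrate(f, 0, min(R, r_edges[11]), rel.tol = 1e-9)$value * dEdz
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("stage-3 scoring is deterministic and conserves arm ordering", {
  s2 <- small_stage2_pt()
  bn <- shell_binning(20, 400)
  t1 <- run_stage3(s2, bn, n_batches = 4, seed = 77, bg_resamples = 2)
  t2 <- run_stage3(s2, bn, n_batches = 4, seed = 77, bg_resamples = 2)
  expect_identical(t1$energy, t2$energy)
  expect_identical(t1$batch, t2$batch)
  s2w <- small_stage2_water()
  tw <- run_stage3(s2w, bn, n_batches = 4, seed = 77, bg_resamples = 2)
  d <- compute_def(t1, tw)
  expect_true(all(is.finite(d$def)))
  expect_true(all(d$def >= 1 - 1e-6))  # platinum arm adds dose everywhere
})
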