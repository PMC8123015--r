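# Condensed-history electron transport: conservation, ranges, angular model.

test_that("a cutoff-energy electron deposits everything at its start", {
  rec <- data.frame(kind = "electron", energy_eV = 100, x_nm = 1, y_nm = 2,
                    z_nm = 3, ux = 0, uy = 0, uz = 1, weight = 1, history = 1)
  dep <- transport_electron(rec, mat_water())
  expect_equal(nrow(dep), 1)
  expect_equal(dep$energy_eV, 100)
  expect_equal(unlist(dep[1, c("x_nm", "y_nm", "z_nm")], use.names = FALSE),
               c(1, 2, 3))
  expect_error(transport_electron(transform(rec, kind = "photon"),
                                  mat_water()), "electron")
})

test_that("every track conserves energy and stays inside its CSDA sphere", {
  set.seed(8)
  E0 <- c(500, 3e3, 3e3, 5e4, 4e5)
  n <- length(E0)
  res <- transport_electrons(E0, matrix(0, n, 3),
                             matrix(rep(c(0, 0, 1), each = n), n, 3),
                             mat_water())
  d <- res$deposits
  sums <- rowsum(d$energy_eV, d$id)
  expect_equal(as.numeric(sums), E0, tolerance = 1e-9)
  rng <- csda_range(mat_water(), E0)
  dist <- sqrt(d$x_nm^2 + d$y_nm^2 + d$z_nm^2)
  expect_true(all(dist <= rng[d$id] * (1 + 1e-9)))
})

test_that("3 keV electrons in water stay within 300 nm of their origin", {
  set.seed(12)
  n <- 300
  res <- transport_electrons(rep(3e3, n), matrix(0, n, 3),
                             matrix(rep(c(0, 0, 1), each = n), n, 3),
                             mat_water())
  dist <- with(res$deposits, sqrt(x_nm^2 + y_nm^2 + z_nm^2))
  expect_lte(max(dist), csda_range(mat_water(), 3e3))
  expect_lte(max(dist), 300)
})

test_that("straight-ahead transport reaches exactly the CSDA range", {
  set.seed(1)
  cfg <- transport_config(angular = "none")
  out <- range_straggled_endpoint(2e4, mat_water(), n = 20, cfg = cfg)
  expect_equal(out$mean_depth_nm, csda_range(mat_water(), 2e4),
               tolerance = 1e-6)
  expect_equal(out$detour, 1, tolerance = 1e-6)
})

test_that("angular deflections produce a detour factor below one", {
  set.seed(3)
  out <- range_straggled_endpoint(2e4, mat_water(), n = 150)
  expect_lt(out$detour, 1)
  expect_gt(out$detour, 0.2)
})

test_that("the standard error of the endpoint mean scales like 1/sqrt(n)", {
  sem <- function(n, seed) {
    set.seed(seed)
    out <- range_straggled_endpoint(1e4, mat_water(), n = n)
    out$sd_depth_nm / sqrt(n)
  }
  s1 <- sem(100, 4); s4 <- sem(400, 5)
  expect_equal(s1 / s4, 2, tolerance = 0.5)
})

test_that("constant-stopping toy material gives uniform deposit spacing", {
  toy <- make_toy_material(mu_total = 1, S = 10, density = 1)
  cfg <- transport_config(step_frac = 0.1, angular = "none")
  res <- transport_electrons(1e4, matrix(0, 1, 3), matrix(c(0, 0, 1), 1, 3),
                             toy, cfg)
  z <- res$deposits$z_nm
  # each step is 10% of the remaining linear range: spacing ratio constant
  sp <- diff(z[-length(z)])
  expect_equal(sp[-1] / sp[-length(sp)], rep(0.9, length(sp) - 1),
               tolerance = 1e-6)
  # range linear in energy for constant S
  expect_equal(csda_range(toy, 5e4) / csda_range(toy, 2.5e4 + 50), 2,
               tolerance = 0.01)
})

test_that("plane crossings preserve energy bookkeeping", {
  set.seed(9)
  n <- 40
  res <- transport_electrons(rep(2e4, n), matrix(0, n, 3),
                             matrix(rep(c(0, 0, 1), each = n), n, 3),
                             mat_water(), plane_z = 2000)
  cr <- res$crossings
  expect_gt(nrow(cr), 0)
  dep_sum <- rowsum(res$deposits$energy_eV, res$deposits$id)
  tot <- numeric(n)
  tot[as.integer(rownames(dep_sum))] <- dep_sum
  tot[cr$id] <- tot[cr$id] + cr$energy_eV
  expect_equal(tot, rep(2e4, n), tolerance = 1e-9)
  expect_true(all(abs(cr$z_nm - 2000) < 1e-6))
})
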