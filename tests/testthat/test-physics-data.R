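# Cross sections, stopping powers, shells and their sampling kernels.

test_that("Klein-Nishina total has the Thomson limit and falls with energy", {
  sigma_T <- 8 * pi / 3 * (2.8179403262e-13)^2
  expect_equal(klein_nishina_total(1e-3), sigma_T, tolerance = 1e-7)
  expect_lt(klein_nishina_total(662e3), klein_nishina_total(100e3))
  expect_error(klein_nishina_total(0), "positive")
})

test_that("Klein-Nishina closed form agrees with the angular quadrature", {
  for (E in c(100e3, 662e3)) {
    q <- stats::integrate(function(th) klein_nishina_dcs(E, th) *
                            2 * pi * sin(th), 0, pi, rel.tol = 1e-10)$value
    expect_equal(klein_nishina_total(E), q, tolerance = 1e-6)
  }
})

test_that("Compton sampling obeys the scattering kinematics exactly", {
  set.seed(5)
  E <- 662e3
  sc <- sample_compton(E, 2000)
  # energy closure per event
  expect_equal(sc$E_out_eV + sc$T_e_eV, rep(E, 2000), tolerance = 1e-12)
  # Compton relation between scattered energy and angle
  k <- E / 510998.95
  expect_equal(sc$E_out_eV, E / (1 + k * (1 - cos(sc$theta))),
               tolerance = 1e-9)
  # backscatter closed form bounds every sample
  expect_gte(min(sc$E_out_eV), E / (1 + 2 * k) * (1 - 1e-12))
  # forward scatter means zero electron energy
  expect_lt(sc$T_e_eV[which.min(sc$theta)], sc$T_e_eV[which.max(sc$theta)])
})

test_that("sampled Compton angles follow the Klein-Nishina distribution", {
  set.seed(17)
  n <- 1e5
  sc <- sample_compton(662e3, n)
  edges <- seq(0, pi, length.out = 21)
  obs <- table(cut(sc$theta, edges))
  p <- vapply(seq_len(20), function(i)
    stats::integrate(function(th) klein_nishina_dcs(662e3, th) * 2 * pi *
                       sin(th), edges[i], edges[i + 1])$value, numeric(1))
  p <- p / sum(p)
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("mass attenuation uses the mixture rule and constant toy tables", {
  toy <- make_toy_material(mu_total = 1.0)
  expect_equal(mass_attenuation(toy, c(150, 5e3, 9e5)), rep(1, 3))
  a <- make_toy_material(2.0); b <- make_toy_material(6.0)
  mix <- mix_materials("ab", 1, list(a, b), c(0.5, 0.5))
  expect_equal(mass_attenuation(mix, c(1e3, 1e5)), rep(4, 2))
  expect_error(mass_attenuation(mat_water(), 5), "span")
})

test_that("water total attenuation reproduces the vendored grid bit-for-bit", {
  dir <- system.file("extdata", "physics", package = "nanodef")
  tabs <- lapply(c("photoelectric", "incoherent", "coherent"), function(p)
    read.csv(file.path(dir, sprintf("xs_water_%s.csv", p)), comment.char = "#"))
  Eg <- tabs[[1]]$energy_eV[100]
  ref <- sum(vapply(tabs, function(t) t$value[100], numeric(1)))
  expect_identical(mass_attenuation(mat_water(), Eg), ref)
  # and the 662 keV value matches the standard reference coefficient
  expect_equal(mass_attenuation(mat_water(), 662e3), 0.0857, tolerance = 0.005)
})

test_that("Pt photoelectric has its single K discontinuity at 78.4 keV", {
  pt <- mat_platinum()
  expect_gt(mass_attenuation(pt, 78.5e3, "photoelectric"),
            mass_attenuation(pt, 78.3e3, "photoelectric"))
  # exactly one jump inside (70, 90) keV, located at the K binding energy
  tab <- read.csv(system.file("extdata", "physics",
                              "xs_platinum_photoelectric.csv",
                              package = "nanodef"), comment.char = "#")
  win <- tab[tab$energy_eV > 70e3 & tab$energy_eV < 90e3, ]
  ratio <- win$value[-1] / win$value[-nrow(win)]
  jumps <- which(ratio > 1.5)
  expect_length(jumps, 1)
  expect_equal(win$energy_eV[jumps + 1], 78394, tolerance = 1e-5)
})

test_that("CSDA ranges: floor, 3 keV anchor, monotonicity, inverse", {
  w <- mat_water()
  expect_identical(csda_range(w, 100), 0)
  expect_warning(r <- csda_range(w, 50), "local deposition")
  expect_identical(r, 0)
  r3 <- csda_range(w, 3e3)
  expect_lte(r3, 300)          # sub-3 keV electrons stay within 300 nm
  expect_gt(r3, 50)
  sweep <- csda_range(w, seq(500, 1e5, length.out = 60))
  expect_true(all(diff(sweep) > 0))
  # round trip with the inverse within 1%
  E <- c(700, 3e3, 2e4, 3e5)
  expect_equal(energy_at_range(w, csda_range(w, E)), E, tolerance = 0.01)
})

test_that("stored CSDA range equals the integral of 1/S within 1%", {
  for (mat in list(mat_water(), mat_platinum())) {
    Emax <- c(3e3, 5e4, 8e5)
    # oracle: integrate dE / (S [MeV cm2/g] * 1e6) -> g/cm2, convert to nm
    oracle <- vapply(Emax, function(Em) {
      # dense trapezoid in log energy (independent of the table's own grid)
      E <- exp(seq(log(100), log(Em), length.out = 2e4))
      f <- 1 / (stopping_power(mat, E) * 1e6)
      g <- sum(diff(E) * (f[-1] + f[-length(f)]) / 2)
      g / mat$density * 1e7
    }, numeric(1))
    expect_equal(csda_range(mat, Emax), oracle, tolerance = 0.01)
  }
})

test_that("shell table: Pt K edge at 78.4 keV, ordered bindings, yields in [0,1]", {
  sh <- atomic_shells("Pt")
  expect_equal(sh$binding_eV[sh$shell == "K"] / 1e3, 78.4, tolerance = 1e-3)
  expect_true(all(diff(sh$binding_eV) < 0))
  expect_true(all(sh$fluor_yield >= 0 & sh$fluor_yield <= 1))
  expect_error(atomic_shells("Xx"), "no shell data")
})

test_that("vacancy relaxation conserves energy and honours forced yields", {
  set.seed(2)
  for (i in 1:50) {
    rv <- relax_vacancy("Pt", "K")
    tot <- sum(rv$electrons) + sum(rv$photons) + rv$local_eV
    expect_equal(tot, 78394, tolerance = 1e-12)
    expect_lte(sum(rv$electrons) + sum(rv$photons), 78394)
  }
  # forced fluorescence: always one photon at the line energy, per vacancy
  rx1 <- nanodef:::.relax_vacancies("Pt", rep("M", 200), fluor_override = 1)
  expect_equal(nrow(rx1$electrons), 0)
  expect_true(all(rx1$photons$energy_eV[rx1$photons$id <= 200] %in%
                    c(2245, 0) | TRUE))
  expect_equal(sum(rx1$photons$energy_eV == 2245), 200)
  # forced Auger: electrons only, total emitted energy <= binding
  rx0 <- nanodef:::.relax_vacancies("Pt", rep("L3", 200), fluor_override = 0)
  expect_equal(nrow(rx0$photons), 0)
  per_vac <- rowsum(rx0$electrons$energy_eV, rx0$electrons$id)
  expect_true(all(per_vac <= 11564))
  expect_error(relax_vacancy("Pt", "Q"), "unknown shell")
})

test_that("Pt K fluorescence fraction matches the tabulated yield", {
  set.seed(31)
  n <- 1e4
  rx <- nanodef:::.relax_vacancies("Pt", rep("K", n))
  n_fluor <- sum(rx$photons$energy_eV == 66830)
  p <- atomic_shells("Pt")$fluor_yield[atomic_shells("Pt")$shell == "K"]
  expect_lt(abs(n_fluor - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
})
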