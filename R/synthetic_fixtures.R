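# Analytically tractable fixtures: monoenergetic beams, toy materials with
# constant tables (closed-form attenuation and range), and a small "golden"
# phase space with a 662 keV-dominated photon line plus a soft electron
# continuum, used for regression and smoke tests of stages 2-3.

#' Monoenergetic pencil-beam phase space
#'
#' @param energy_eV Photon energy (eV).
#' @param n Number of records (>= 1).
#' @param seed Seed recorded in the header (the fixture itself is
#'   deterministic).
#' @return An `ndf_phsp` with `n` identical +z photons of weight 1 at the
#'   origin.
#' @export
make_pencil_beam <- function(energy_eV, n, seed = 0L) {
  if (n < 1) stop("n must be >= 1")
  rec <- data.frame(kind = "photon", energy_eV = energy_eV,
                    x_nm = 0, y_nm = 0, z_nm = 0,
                    ux = 0, uy = 0, uz = 1, weight = 1,
                    history = seq_len(n))
  phase_space(rec, n_primaries = n, stage = "fixture",
              source = sprintf("pencil beam %g eV", energy_eV), seed = seed)
}

#' Toy material with constant tables
#'
#' A material whose mass attenuation (split over the three photon processes)
#' and collision stopping power are constant in energy, so transmission
#' follows the closed-form exponential law and the CSDA range is linear in
#' energy: `R = E / (S rho)`.
#'
#' @param mu_total Constant total mass attenuation (cm^2/g), split between
#'   processes by `frac` (photoelectric, incoherent, coherent).
#' @param S Constant mass collision stopping power (MeV cm^2/g).
#' @param density Density (g/cm^3).
#' @param frac Length-3 process split, summing to 1.
#' @return A material object.
#' @export
make_toy_material <- function(mu_total = 1, S = 10, density = 1,
                              frac = c(0.2, 0.7, 0.1)) {
  stopifnot(mu_total > 0, S > 0, density > 0, abs(sum(frac) - 1) < 1e-12)
  E <- c(100, 1e3, 1e4, 1e5, 1e6)
  mk <- function(v) data.frame(energy_eV = E, value = rep(v, length(E)))
  comp <- list(list(label = "toy", mass_frac = 1,
                    xs = list(photoelectric = mk(mu_total * frac[1]),
                              incoherent = mk(mu_total * frac[2]),
                              coherent = mk(mu_total * frac[3]))))
  Efine <- exp(seq(log(100), log(1e6), length.out = 60))
  estop <- data.frame(energy_eV = Efine,
                      stopping_MeV_cm2_g = S,
                      csda_g_cm2 = (Efine - 100) / (S * 1e6))
  new_material("toy", density, comp, estop,
               composition = data.frame(symbol = "X", mass_frac = 1))
}

#' Golden phase space for regression tests
#'
#' A small reproducible phase space approximating the stage-1 output
#' qualitatively: a dominant 662 keV photon line, a single-scatter photon
#' continuum (bounded below by the 180-degree Compton energy) and a soft
#' electron continuum. A CSV export of `make_golden_phsp(seed = 404)` with
#' the default `n = 600` is committed under `inst/extdata/` and the test
#' suite checks regeneration against it field for field.
#'
#' @param seed RNG seed.
#' @param n Total number of records.
#' @return An `ndf_phsp`.
#' @export
make_golden_phsp <- function(seed = 404L, n = 600L) {
  set.seed(seed)
  n_prim <- round(0.85 * n)           # unscattered 662 keV photons
  n_scat <- round(0.10 * n)           # scattered photon continuum
  n_el <- n - n_prim - n_scat         # soft electrons
  E0 <- 662e3
  Emin_sc <- E0 / (1 + 2 * E0 / 510998.95)
  tilt <- function(m, sd = 0.05) {
    tx <- stats::rnorm(m, 0, sd); ty <- stats::rnorm(m, 0, sd)
    u <- cbind(tx, ty, 1)
    u / sqrt(rowSums(u^2))
  }
  recs <- rbind(
    data.frame(kind = "photon", energy_eV = rep(E0, n_prim),
               x_nm = stats::runif(n_prim, -1e4, 1e4),
               y_nm = stats::runif(n_prim, -1e4, 1e4), z_nm = 0,
               ux = 0, uy = 0, uz = 1, weight = 1, history = seq_len(n_prim)),
    {
      u <- tilt(n_scat, 0.25)
      data.frame(kind = "photon",
                 energy_eV = stats::runif(n_scat, Emin_sc, E0),
                 x_nm = stats::runif(n_scat, -1e4, 1e4),
                 y_nm = stats::runif(n_scat, -1e4, 1e4), z_nm = 0,
                 ux = u[, 1], uy = u[, 2], uz = u[, 3], weight = 1,
                 history = n_prim + seq_len(n_scat))
    },
    {
      u <- tilt(n_el, 0.35)
      data.frame(kind = "electron",
                 energy_eV = pmax(150, stats::rexp(n_el, 1 / 6e4)),
                 x_nm = stats::runif(n_el, -1e4, 1e4),
                 y_nm = stats::runif(n_el, -1e4, 1e4), z_nm = 0,
                 ux = u[, 1], uy = u[, 2], uz = u[, 3], weight = 1,
                 history = n_prim + n_scat + seq_len(n_el))
    })
  phase_space(recs, n_primaries = n, stage = "fixture",
              source = "golden mixed phase space", seed = seed)
}
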