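# Stage 1: transport of source photons through the culture-medium slab and
# recording of every particle (photon or secondary electron) that enters the
# cell layer. The irradiator is reduced to a parallel monoenergetic 662 keV
# beam at normal incidence on an infinite water slab; the recording plane is
# the medium/cell interface. Secondary electrons set in motion upstream are
# transported (condensed history) and recorded if they cross the plane --
# they are what later establishes charged-particle equilibrium downstream.

#' Photon source specification
#'
#' @param lines Data frame with `energy_eV` and `intensity` (intensities sum
#'   to 1). Default: the single 662 keV line of 137Cs.
#' @param beam Beam model; both supported models are parallel beams along +z
#'   ("parallel_broad" is the physical reading, "parallel_pencil" the
#'   numerically identical pencil used for transport since the slab is
#'   laterally infinite).
#' @return A `ndf_source` list.
#' @export
source_spec <- function(lines = data.frame(energy_eV = 662e3, intensity = 1),
                        beam = c("parallel_broad", "parallel_pencil")) {
  beam <- match.arg(beam)
  if (abs(sum(lines$intensity) - 1) > 1e-9) stop("intensities must sum to 1")
  if (any(lines$energy_eV <= 0)) stop("line energies must be positive")
  structure(list(lines = lines, beam = beam), class = "ndf_source")
}

#' Slab geometry of the cell-culture setup
#'
#' Ordered stack of slabs along +z with the recording plane at the interface
#' between the last upstream slab and the cell layer.
#'
#' @param medium_nm Thickness of the upstream culture medium (water);
#'   default 2.2 mm.
#' @param cell_nm Thickness of the cell layer (water); default 10 um.
#' @param medium Material of the upstream slab (default [mat_water()]).
#' @return A `ndf_geometry` list; the recording plane sits at
#'   `z = medium_nm`.
#' @export
slab_geometry <- function(medium_nm = 2.2e6, cell_nm = 1e4,
                          medium = mat_water()) {
  if (medium_nm <= 0 || cell_nm <= 0) stop("thicknesses must be positive")
  structure(list(medium_nm = medium_nm, cell_nm = cell_nm, medium = medium,
                 plane_z = medium_nm), class = "ndf_geometry")
}

#' Analytic uncollided transmission through the upstream slab
#'
#' `exp(-sum_i mu_i t_i)` over the upstream slabs; the test oracle for the
#' Beer-Lambert behaviour of [run_stage1()].
#'
#' @param geometry A [slab_geometry()].
#' @param energy_eV Photon energy (eV).
#' @return Probability that a photon crosses the slab without interacting.
#' @export
analytic_transmission <- function(geometry, energy_eV) {
  exp(-.mu_lin_nm(geometry$medium, energy_eV) * geometry$medium_nm)
}

# sample coherent (Rayleigh) scattering angles: Thomson-like (1+cos^2)
.sample_rayleigh_cos <- function(n) {
  out <- numeric(n); todo <- n
  while (todo > 0) {
    c0 <- stats::runif(todo, -1, 1)
    acc <- stats::runif(todo) < (1 + c0^2) / 2
    k <- sum(acc)
    if (k) out[(n - todo) + seq_len(k)] <- c0[acc]
    todo <- todo - k
  }
  out
}

# sample the dipole (sin^2 theta) photoelectron polar angle
.sample_dipole_cos <- function(n) {
  out <- numeric(n); todo <- n
  while (todo > 0) {
    c0 <- stats::runif(todo, -1, 1)
    acc <- stats::runif(todo) < (1 - c0^2)
    k <- sum(acc)
    if (k) out[(n - todo) + seq_len(k)] <- c0[acc]
    todo <- todo - k
  }
  out
}

#' Run stage 1: photon transport to the cell layer
#'
#' Tracks `n` primary photons (exponential free paths, per-process selection
#' by relative attenuation, Klein-Nishina Compton sampling, photoelectric
#' absorption with relaxation, Rayleigh deflection) through the upstream
#' medium, transporting secondary electrons, and records every particle that
#' crosses the recording plane.
#'
#' @param src A [source_spec()].
#' @param geometry A [slab_geometry()].
#' @param n Number of primary histories (>= 1).
#' @param seed RNG seed (fixed seed gives a byte-identical phase-space file).
#' @param cfg Electron [transport_config()].
#' @return An `ndf_phsp` with an `energy_ledger` attribute: per-run totals of
#'   source energy, recorded energy, upstream deposits and escaped energy.
#' @export
run_stage1 <- function(src, geometry, n, seed = 1L,
                       cfg = transport_config()) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  med <- geometry$medium
  zp <- geometry$plane_z
  # photon state
  ph <- list(E = src$lines$energy_eV[sample.int(nrow(src$lines), n,
                                                replace = TRUE,
                                                prob = src$lines$intensity)],
             P = matrix(0, n, 3),
             U = matrix(rep(c(0, 0, 1), each = n), n, 3),
             hist = seq_len(n))
  source_energy <- sum(ph$E)
  rec <- list()     # recorded plane crossings
  electrons <- list()  # secondary electrons awaiting transport
  e_dep_upstream <- 0
  e_escaped <- 0
  e_recorded_photon <- 0
  add_electrons <- function(E, P, U, hist) {
    keep <- E >= cfg$cutoff_eV
    if (any(!keep)) e_dep_upstream <<- e_dep_upstream + sum(E[!keep])
    if (any(keep))
      electrons[[length(electrons) + 1]] <<-
        list(E = E[keep], P = P[keep, , drop = FALSE],
             U = U[keep, , drop = FALSE], hist = hist[keep])
  }
  while (length(ph$E)) {
    mu <- .mu_lin_nm(med, ph$E)
    s <- stats::rexp(length(ph$E), rate = mu)
    newP <- ph$P + ph$U * s
    # crossing the recording plane before interacting
    cross <- newP[, 3] >= zp & ph$U[, 3] > 0
    # leaving through the upstream face (backscatter escape)
    out_back <- newP[, 3] < 0 & !cross
    if (any(cross)) {
      fr <- (zp - ph$P[cross, 3]) / (newP[cross, 3] - ph$P[cross, 3])
      hit <- ph$P[cross, , drop = FALSE] +
        ph$U[cross, , drop = FALSE] * (s[cross] * fr)
      rec[[length(rec) + 1]] <- data.frame(
        kind = "photon", energy_eV = ph$E[cross],
        x_nm = hit[, 1], y_nm = hit[, 2], z_nm = hit[, 3],
        ux = ph$U[cross, 1], uy = ph$U[cross, 2], uz = ph$U[cross, 3],
        weight = 1, history = ph$hist[cross])
      e_recorded_photon <- e_recorded_photon + sum(ph$E[cross])
    }
    if (any(out_back)) e_escaped <- e_escaped + sum(ph$E[out_back])
    inter <- !(cross | out_back)
    if (!any(inter)) break
    E <- ph$E[inter]; P <- newP[inter, , drop = FALSE]
    U <- ph$U[inter, , drop = FALSE]; hist <- ph$hist[inter]
    # per-process selection by relative attenuation
    m_pe  <- .mu_lin_nm(med, E, "photoelectric")
    m_in  <- .mu_lin_nm(med, E, "incoherent")
    m_co  <- .mu_lin_nm(med, E, "coherent")
    u <- stats::runif(length(E)) * (m_pe + m_in + m_co)
    is_pe <- u < m_pe
    is_in <- !is_pe & u < m_pe + m_in
    is_co <- !(is_pe | is_in)
    nextE <- numeric(0); nextP <- NULL; nextU <- NULL; nextH <- integer(0)
    if (any(is_in)) {                       # Compton
      sc <- sample_compton(E[is_in])
      phi_az <- stats::runif(sum(is_in), 0, 2 * pi)
      Ui <- U[is_in, , drop = FALSE]
      U_ph <- .rotate_dirs(Ui, sc$theta, phi_az)
      U_el <- .rotate_dirs(Ui, sc$phi_e, phi_az + pi)
      add_electrons(sc$T_e_eV, P[is_in, , drop = FALSE], U_el, hist[is_in])
      nextE <- c(nextE, sc$E_out_eV)
      nextP <- rbind(nextP, P[is_in, , drop = FALSE])
      nextU <- rbind(nextU, U_ph)
      nextH <- c(nextH, hist[is_in])
    }
    if (any(is_pe)) {                       # photoelectric + relaxation
      Epe <- E[is_pe]
      shl <- .pe_select_shell(med, Epe)
      B <- rep(20, length(shl))
      if (!is.na(med$relax_element)) {
        shtab <- atomic_shells(med$relax_element)
        B <- ifelse(shl == "valence", 20,
                    shtab$binding_eV[match(shl, shtab$shell)])
      }
      B <- pmin(B, Epe * 0.99)            # guard: vacancy needs E > B
      T_pe <- Epe - B
      cz <- .sample_dipole_cos(sum(is_pe))
      az <- stats::runif(sum(is_pe), 0, 2 * pi)
      U_pe <- .rotate_dirs(U[is_pe, , drop = FALSE], acos(cz), az)
      add_electrons(T_pe, P[is_pe, , drop = FALSE], U_pe, hist[is_pe])
      # relaxation cascade of the vacancies (photon must outrun the binding
      # energy for a real inner-shell vacancy; else treat as local absorption)
      vac <- shl != "valence" & B < Epe * 0.99
      if (any(vac)) {
        rx <- .relax_vacancies(med$relax_element, shl[vac])
        idx <- which(is_pe)[vac]
        e_dep_upstream <- e_dep_upstream + sum(rx$local_eV)
        if (nrow(rx$electrons)) {
          ne <- nrow(rx$electrons)
          czr <- stats::runif(ne, -1, 1); azr <- stats::runif(ne, 0, 2 * pi)
          szr <- sqrt(1 - czr^2)
          add_electrons(rx$electrons$energy_eV,
                        P[idx[rx$electrons$id], , drop = FALSE],
                        cbind(szr * cos(azr), szr * sin(azr), czr),
                        hist[idx[rx$electrons$id]])
        }
        if (nrow(rx$photons)) {
          np <- nrow(rx$photons)
          czf <- stats::runif(np, -1, 1); azf <- stats::runif(np, 0, 2 * pi)
          szf <- sqrt(1 - czf^2)
          nextE <- c(nextE, rx$photons$energy_eV)
          nextP <- rbind(nextP, P[idx[rx$photons$id], , drop = FALSE])
          nextU <- rbind(nextU, cbind(szf * cos(azf), szf * sin(azf), czf))
          nextH <- c(nextH, hist[idx[rx$photons$id]])
        }
      }
      if (any(!vac)) e_dep_upstream <- e_dep_upstream + sum(B[!vac])
    }
    if (any(is_co)) {                       # Rayleigh: deflection only
      cz <- .sample_rayleigh_cos(sum(is_co))
      az <- stats::runif(sum(is_co), 0, 2 * pi)
      U_co <- .rotate_dirs(U[is_co, , drop = FALSE], acos(cz), az)
      nextE <- c(nextE, E[is_co])
      nextP <- rbind(nextP, P[is_co, , drop = FALSE])
      nextU <- rbind(nextU, U_co)
      nextH <- c(nextH, hist[is_co])
    }
    # photons with energies below the table floor are absorbed locally
    if (length(nextE)) {
      okE <- nextE >= 110
      if (any(!okE)) e_dep_upstream <- e_dep_upstream + sum(nextE[!okE])
      ph <- list(E = nextE[okE], P = nextP[okE, , drop = FALSE],
                 U = nextU[okE, , drop = FALSE], hist = nextH[okE])
    } else ph <- list(E = numeric(0))
  }
  # transport the collected secondary electrons with plane recording
  if (length(electrons)) {
    Ee <- unlist(lapply(electrons, `[[`, "E"))
    Pe <- do.call(rbind, lapply(electrons, `[[`, "P"))
    Ue <- do.call(rbind, lapply(electrons, `[[`, "U"))
    He <- unlist(lapply(electrons, `[[`, "hist"))
    tr <- transport_electrons(Ee, Pe, Ue, med, cfg, plane_z = zp,
                              track_id = seq_along(Ee))
    e_dep_upstream <- e_dep_upstream + sum(tr$deposits$energy_eV)
    if (nrow(tr$crossings)) {
      cx <- tr$crossings
      rec[[length(rec) + 1]] <- data.frame(
        kind = "electron", energy_eV = cx$energy_eV,
        x_nm = cx$x_nm, y_nm = cx$y_nm, z_nm = cx$z_nm,
        ux = cx$ux, uy = cx$uy, uz = cx$uz,
        weight = 1, history = He[cx$id])
    }
  }
  records <- if (length(rec)) do.call(rbind, rec) else data.frame()
  ps <- phase_space(records, n_primaries = n, stage = "stage1",
                    source = sprintf("parallel beam, %d lines",
                                     nrow(src$lines)),
                    seed = seed,
                    geometry = sprintf("slab %gnm + cell %gnm",
                                       geometry$medium_nm, geometry$cell_nm))
  attr(ps, "energy_ledger") <- list(
    source_eV = source_energy,
    recorded_eV = if (nrow(ps$records)) sum(ps$records$energy_eV) else 0,
    deposited_eV = e_dep_upstream,
    escaped_eV = e_escaped)
  ps
}
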