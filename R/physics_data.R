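# Embedded photon cross sections, electron stopping powers and atomic
# relaxation data for liquid water and platinum, plus the sampling kernels
# built on them. All tables are plain-text CSV fixtures generated once by
# data-raw/make_physics_tables.R and shipped under inst/extdata/physics/.

# physical constants (CODATA)
.re_cm   <- 2.8179403262e-13   # classical electron radius [cm]
.mec2_eV <- 510998.95          # electron rest energy [eV]
.navo    <- 6.02214076e23

.ndf <- new.env(parent = emptyenv())

.ndf_datafile <- function(name) {
  path <- system.file("extdata", "physics", name, package = "nanodef")
  if (!nzchar(path)) stop("vendored physics table not found: ", name)
  path
}

.ndf_read_table <- function(name) {
  key <- paste0("tab_", name)
  if (is.null(.ndf[[key]])) {
    .ndf[[key]] <- utils::read.csv(.ndf_datafile(name), comment.char = "#")
  }
  .ndf[[key]]
}

# log-log interpolation used for every cross-section/stopping-power lookup;
# exact at grid nodes, range error outside the span
.loglog_interp <- function(E_tab, v_tab, E, what = "table") {
  if (any(E < E_tab[1] - 1e-9) || any(E > E_tab[length(E_tab)] * (1 + 1e-12)))
    stop(sprintf("energy outside %s span [%g, %g] eV", what,
                 E_tab[1], E_tab[length(E_tab)]))
  if (any(v_tab <= 0)) {
    # tables with zeros (e.g. toy materials with a disabled process)
    return(stats::approx(log(E_tab), v_tab, xout = log(E), rule = 2)$y)
  }
  exp(stats::approx(log(E_tab), log(v_tab), xout = log(E), rule = 2)$y)
}

## ---------------------------------------------------------------- elements

#' Elements known to the package
#'
#' @param symbol Element symbol ("H", "O" or "Pt").
#' @return A list with `symbol`, atomic number `Z` and atomic mass `A` (g/mol).
#' @export
element <- function(symbol) {
  tab <- list(H  = list(symbol = "H",  Z = 1L,  A = 1.008),
              O  = list(symbol = "O",  Z = 8L,  A = 15.999),
              Pt = list(symbol = "Pt", Z = 78L, A = 195.084))
  el <- tab[[symbol]]
  if (is.null(el)) stop("unknown element: ", symbol)
  stopifnot(el$Z >= 1L, el$A > 0)
  el
}

## ---------------------------------------------------------------- materials

new_material <- function(name, density, components, estop, composition,
                         effective_Z = NA_real_, relax_element = NA_character_) {
  fr <- vapply(components, function(cc) cc$mass_frac, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) stop("mass fractions must sum to 1")
  if (density <= 0) stop("density must be positive")
  structure(list(name = name, density = density, components = components,
                 estop = estop, composition = composition,
                 effective_Z = effective_Z, relax_element = relax_element,
                 interp = .estop_interp(estop, density)),
            class = "ndf_material")
}

# precomputed stopping-power / range / inverse-range interpolators (log-log,
# with the bottom table interval linear in energy since the range is 0 at
# the 100 eV floor); attached to every material for the transport loops
.estop_interp <- function(es, density) {
  lE <- log(es$energy_eV)
  f_S <- stats::approxfun(lE, log(es$stopping_MeV_cm2_g), rule = 2)
  r_nm <- es$csda_g_cm2 / density * 1e7
  E1 <- es$energy_eV[1]; E2 <- es$energy_eV[2]; r2 <- r_nm[2]
  f_R <- stats::approxfun(lE[-1], log(r_nm[-1]), rule = 2)
  f_inv <- stats::approxfun(log(r_nm[-1]), lE[-1], rule = 2)
  list(
    stop = function(E) exp(f_S(log(E))),
    range = function(E) {
      out <- numeric(length(E))
      hi <- E >= E2
      if (any(hi)) out[hi] <- exp(f_R(log(E[hi])))
      if (any(!hi)) out[!hi] <- pmax(0, E[!hi] - E1) / (E2 - E1) * r2
      out
    },
    einv = function(r) {
      out <- numeric(length(r))
      hi <- r > r2
      if (any(hi)) out[hi] <- exp(f_inv(log(r[hi])))
      if (any(!hi)) out[!hi] <- E1 + (E2 - E1) * pmax(0, r[!hi]) / r2
      out
    })
}

#' @export
print.ndf_material <- function(x, ...) {
  cat(sprintf("<material %s: rho = %g g/cm^3, Zeff = %s>\n",
              x$name, x$density,
              ifelse(is.na(x$effective_Z), "?", format(x$effective_Z))))
  invisible(x)
}

.xs_component <- function(prefix, mass_frac = 1, label = prefix) {
  list(label = label, mass_frac = mass_frac,
       xs = list(
         photoelectric = .ndf_read_table(paste0("xs_", prefix, "_photoelectric.csv")),
         incoherent    = .ndf_read_table(paste0("xs_", prefix, "_incoherent.csv")),
         coherent      = .ndf_read_table(paste0("xs_", prefix, "_coherent.csv"))))
}

#' Predefined liquid water material
#'
#' Liquid water at 1.0 g/cm^3 with the vendored photon cross-section and
#' electron stopping-power tables attached (Zeff = 7.42).
#' @return A material object.
#' @export
mat_water <- function() {
  if (is.null(.ndf$mat_water)) {
    es <- .ndf_read_table("estop_water.csv")
    .ndf$mat_water <- new_material(
      "water", 1.0, list(.xs_component("water")), es,
      composition = data.frame(symbol = c("H", "O"),
                               mass_frac = c(0.11190, 0.88810)),
      effective_Z = 7.42, relax_element = "O")
  }
  .ndf$mat_water
}

#' Predefined platinum material
#'
#' Solid platinum at 21.45 g/cm^3 (Z = 78) with vendored tables attached.
#' @return A material object.
#' @export
mat_platinum <- function() {
  if (is.null(.ndf$mat_platinum)) {
    es <- .ndf_read_table("estop_platinum.csv")
    .ndf$mat_platinum <- new_material(
      "platinum", 21.45, list(.xs_component("platinum")), es,
      composition = data.frame(symbol = "Pt", mass_frac = 1),
      effective_Z = 78, relax_element = "Pt")
  }
  .ndf$mat_platinum
}

#' Build a material from weighted components
#'
#' Combines existing materials' attached tables by the mass-fraction mixture
#' rule. Used for tests of the mixture rule and for toy media; the two
#' physical media of the pipeline are [mat_water()] and [mat_platinum()].
#'
#' @param name Material name.
#' @param density Mass density (g/cm^3).
#' @param parts Named list of materials to mix.
#' @param mass_frac Numeric vector of mass fractions (must sum to 1).
#' @return A material object.
#' @export
mix_materials <- function(name, density, parts, mass_frac) {
  stopifnot(length(parts) == length(mass_frac))
  comps <- list()
  for (i in seq_along(parts)) {
    for (cc in parts[[i]]$components) {
      cc$mass_frac <- cc$mass_frac * mass_frac[i]
      comps[[length(comps) + 1]] <- cc
    }
  }
  estop <- parts[[which.max(mass_frac)]]$estop
  new_material(name, density, comps, estop,
               composition = data.frame(symbol = vapply(comps, `[[`, "",
                                                        "label"),
                                        mass_frac = vapply(comps, `[[`, 0,
                                                           "mass_frac")))
}

## ------------------------------------------------------------ Klein-Nishina

#' Total Klein-Nishina cross section per electron
#'
#' Closed-form total cross section for Compton scattering of a photon on a
#' free electron. Tends to the Thomson cross section 8 pi re^2 / 3 as E -> 0.
#'
#' @param energy_eV Photon energy in eV (vectorised, must be > 0).
#' @return Cross section per electron in cm^2.
#' @export
klein_nishina_total <- function(energy_eV) {
  if (any(energy_eV <= 0)) stop("photon energy must be positive")
  k <- energy_eV / .mec2_eV
  out <- numeric(length(k))
  small <- k < 1e-3       # closed form cancels catastrophically; use series
  if (any(small)) {
    ks <- k[small]
    out[small] <- (8 * pi / 3) * .re_cm^2 *
      (1 - 2 * ks + 26 / 5 * ks^2 - 133 / 10 * ks^3)
  }
  if (any(!small)) {
    kb <- k[!small]
    t1 <- (1 + kb) / kb^2 * (2 * (1 + kb) / (1 + 2 * kb) - log(1 + 2 * kb) / kb)
    t2 <- log(1 + 2 * kb) / (2 * kb)
    t3 <- (1 + 3 * kb) / (1 + 2 * kb)^2
    out[!small] <- 2 * pi * .re_cm^2 * (t1 + t2 - t3)
  }
  out
}

#' Klein-Nishina differential cross section in scattering angle
#'
#' d sigma / d Omega for a free electron, evaluated at polar scattering
#' angle `theta`; multiply by `2 pi sin(theta)` for the density in theta.
#'
#' @param energy_eV Photon energy (eV).
#' @param theta Scattering angle (rad).
#' @return Differential cross section (cm^2/sr).
#' @export
klein_nishina_dcs <- function(energy_eV, theta) {
  if (any(energy_eV <= 0)) stop("photon energy must be positive")
  k <- energy_eV / .mec2_eV
  eps <- 1 / (1 + k * (1 - cos(theta)))
  0.5 * .re_cm^2 * eps^2 * (eps + 1 / eps - sin(theta)^2)
}

#' Sample Compton scattering events
#'
#' Draws scattering angles from the Klein-Nishina distribution (standard
#' two-branch composition/rejection sampling of the energy ratio) and applies
#' the Compton relation for the scattered photon and recoil electron.
#' Electron binding is neglected, so `E = E' + T_e` holds exactly per event.
#'
#' @param energy_eV Photon energy (eV), scalar or vector of length `n`.
#' @param n Number of events to sample.
#' @return Data frame with columns `E_out_eV` (scattered photon),
#'   `theta` (photon polar angle), `T_e_eV` (electron kinetic energy) and
#'   `phi_e` (electron polar angle, opposite azimuth to the photon).
#' @export
sample_compton <- function(energy_eV, n = length(energy_eV)) {
  if (any(energy_eV <= 0)) stop("photon energy must be positive")
  E <- rep_len(energy_eV, n)
  k <- E / .mec2_eV
  eps_min <- 1 / (1 + 2 * k)
  a1 <- -log(eps_min)               # weight of the 1/eps branch
  a2 <- (1 - eps_min^2) / 2         # weight of the eps branch
  eps <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    k_t <- k[todo]; emin <- eps_min[todo]
    br1 <- stats::runif(m) < a1[todo] / (a1[todo] + a2[todo])
    e <- numeric(m)
    e[br1]  <- emin[br1] * exp(-log(emin[br1]) * stats::runif(sum(br1)))
    e[!br1] <- sqrt(emin[!br1]^2 +
                      (1 - emin[!br1]^2) * stats::runif(sum(!br1)))
    ct <- 1 - (1 / e - 1) / k_t
    sin2 <- pmax(0, 1 - ct^2)
    g <- 1 - e * sin2 / (1 + e^2)
    acc <- stats::runif(m) < g
    eps[todo[acc]] <- e[acc]
    todo <- todo[!acc]
  }
  cos_t <- 1 - (1 / eps - 1) / k
  cos_t <- pmin(1, pmax(-1, cos_t))
  theta <- acos(cos_t)
  E_out <- E * eps
  T_e <- E - E_out
  # electron angle from kinematics: cot(phi) = (1 + k) tan(theta/2)
  phi_e <- atan(1 / ((1 + k) * tan(theta / 2)))
  phi_e[theta == 0] <- pi / 2
  data.frame(E_out_eV = E_out, theta = theta, T_e_eV = T_e, phi_e = phi_e)
}

## ------------------------------------------------------- mass attenuation

#' Mass attenuation coefficient of a material
#'
#' Mixture rule over the material's components with log-log interpolation
#' between grid points of the vendored tables.
#'
#' @param material A material object.
#' @param energy_eV Photon energies (eV), inside the table span.
#' @param process One of "total", "photoelectric", "incoherent", "coherent".
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
mass_attenuation <- function(material, energy_eV,
                             process = c("total", "photoelectric",
                                         "incoherent", "coherent")) {
  process <- match.arg(process)
  procs <- if (process == "total")
    c("photoelectric", "incoherent", "coherent") else process
  out <- numeric(length(energy_eV))
  for (cc in material$components) {
    for (p in procs) {
      tab <- cc$xs[[p]]
      out <- out + cc$mass_frac *
        .loglog_interp(tab$energy_eV, tab$value, energy_eV,
                       what = paste0(material$name, " ", p))
    }
  }
  out
}

# linear attenuation in 1/nm, used by the transport kernels
.mu_lin_nm <- function(material, energy_eV, process = "total") {
  mass_attenuation(material, energy_eV, process) * material$density * 1e-7
}

## --------------------------------------------------- stopping power / range

#' Collision stopping power
#'
#' @param material A material object.
#' @param energy_eV Electron kinetic energies (eV) within the table span.
#' @return Mass collision stopping power in MeV cm^2/g.
#' @export
stopping_power <- function(material, energy_eV) {
  es <- material$estop
  .loglog_interp(es$energy_eV, es$stopping_MeV_cm2_g, energy_eV,
                 what = paste0(material$name, " stopping power"))
}

#' CSDA range of an electron
#'
#' Continuous-slowing-down range integrated from the table's 100 eV floor,
#' divided by the material density and expressed in nm. Below the floor the
#' electron is considered locally absorbed and the range is 0 (with a
#' warning).
#'
#' @param material A material object.
#' @param energy_eV Electron kinetic energies (eV).
#' @return Range(s) in nm at the material's density.
#' @export
csda_range <- function(material, energy_eV) {
  floor_eV <- material$estop$energy_eV[1]
  if (any(energy_eV < floor_eV * (1 - 1e-12)))
    warning("energy below table floor: range set to 0 (local deposition)")
  material$interp$range(energy_eV)
}

#' Electron energy at a given CSDA range (inverse of [csda_range()])
#'
#' @param material A material object.
#' @param range_nm Ranges in nm (at the material's density).
#' @return Energies in eV; 0 for ranges at or below the table floor.
#' @export
energy_at_range <- function(material, range_nm) {
  material$interp$einv(range_nm)
}

## --------------------------------------------------------- atomic shells

#' Atomic shell data table
#'
#' @param element_symbol "Pt" or "O".
#' @return Data frame of shells (binding energy, fluorescence yield, line and
#'   Auger energies, cascade daughters), ordered by decreasing binding energy.
#' @export
atomic_shells <- function(element_symbol) {
  sh <- .ndf_read_table("shells.csv")
  out <- sh[sh$element == element_symbol, , drop = FALSE]
  if (!nrow(out)) stop("no shell data for element: ", element_symbol)
  out[order(-out$binding_eV), ]
}

# photoelectric subshell shares for platinum (piecewise-constant regions)
.pe_shares_pt <- function() .ndf_read_table("pe_shares_platinum.csv")

# sample the subshell receiving the photoelectric vacancy; returns labels
.pe_select_shell <- function(material, energy_eV) {
  n <- length(energy_eV)
  if (is.na(material$relax_element))          # toy media: no shell structure
    return(rep("valence", n))
  if (identical(material$relax_element, "Pt")) {
    sh <- .pe_shares_pt()
    lab <- c("K", "L1", "L2", "L3", "M", "N")
    out <- character(n)
    for (i in seq_len(nrow(sh))) {
      m <- energy_eV >= sh$E_min_eV[i] & energy_eV < sh$E_max_eV[i]
      if (!any(m)) next
      p <- as.numeric(sh[i, lab])
      out[m] <- lab[1 + findInterval(stats::runif(sum(m)) * sum(p),
                                     cumsum(p))]
    }
    out[out == ""] <- "N"
    out
  } else {
    ifelse(energy_eV > 543, "K", "valence")
  }
}

#' Relax an inner-shell vacancy
#'
#' Simulates the radiative/non-radiative relaxation of one vacancy and the
#' cascade of daughter vacancies it spawns: with probability equal to the
#' shell fluorescence yield a characteristic photon is emitted (leaving one
#' daughter vacancy), otherwise an Auger electron is emitted (leaving two
#' daughter vacancies one shell group further out). The cascade is followed
#' through K, L, M and N for platinum; energy not carried by emitted
#' particles is deposited locally. Per vacancy, emitted energy never exceeds
#' the binding energy.
#'
#' @param element_symbol "Pt" or "O".
#' @param shell Shell label of the initial vacancy ("K", "L1", ... ).
#' @return List with `electrons` (vector of Auger energies, eV), `photons`
#'   (fluorescence photon energies, eV) and `local_eV` (locally deposited
#'   remainder).
#' @export
relax_vacancy <- function(element_symbol, shell) {
  sh <- atomic_shells(element_symbol)
  if (!shell %in% sh$shell) stop("unknown shell ", shell, " for ", element_symbol)
  electrons <- numeric(0); photons <- numeric(0); local <- 0
  queue <- shell
  while (length(queue)) {
    s <- queue[1]; queue <- queue[-1]
    row <- sh[sh$shell == s, ]
    dB <- if (row$daughter == "none") 0 else sh$binding_eV[sh$shell == row$daughter]
    if (stats::runif(1) < row$fluor_yield) {
      photons <- c(photons, row$fluor_line_eV)
      local <- local + row$binding_eV - row$fluor_line_eV - dB
      if (row$daughter != "none") queue <- c(queue, row$daughter)
    } else {
      electrons <- c(electrons, row$auger_eV)
      nd <- row$n_daughters_auger
      local <- local + row$binding_eV - row$auger_eV - nd * dB
      if (nd > 0) queue <- c(queue, rep(row$daughter, nd))
    }
  }
  list(electrons = electrons, photons = photons, local_eV = local)
}

# vectorised cascade used by the transport kernels: one call relaxes many
# vacancies; returns a data.frame(id, kind, energy_eV) plus local deposits
.relax_vacancies <- function(element_symbol, shells_vec,
                             fluor_override = NULL) {
  sh <- atomic_shells(element_symbol)
  ids <- seq_along(shells_vec)
  cur_shell <- shells_vec
  cur_id <- ids
  e_id <- integer(0); e_en <- numeric(0)
  p_id <- integer(0); p_en <- numeric(0)
  local <- numeric(length(shells_vec))
  while (length(cur_id)) {
    nxt_shell <- character(0); nxt_id <- integer(0)
    for (s in unique(cur_shell)) {
      if (s %in% c("none", "valence")) next
      m <- cur_shell == s
      row <- sh[sh$shell == s, ]
      if (!nrow(row)) next
      idm <- cur_id[m]; nm <- length(idm)
      dB <- if (row$daughter == "none") 0 else sh$binding_eV[sh$shell == row$daughter]
      fy <- if (is.null(fluor_override)) row$fluor_yield else fluor_override
      isf <- stats::runif(nm) < fy
      # ids can repeat within a group (several vacancies of one event), so
      # local-deposit accumulation must aggregate before indexing
      add_local <- function(ids, amount) {
        if (!length(ids) || amount == 0) return()
        agg <- rowsum(rep(amount, length(ids)), ids)
        local[as.integer(rownames(agg))] <<-
          local[as.integer(rownames(agg))] + agg
      }
      if (any(isf)) {
        p_id <- c(p_id, idm[isf]); p_en <- c(p_en, rep(row$fluor_line_eV, sum(isf)))
        add_local(idm[isf], row$binding_eV - row$fluor_line_eV - dB)
        if (row$daughter != "none") {
          nxt_id <- c(nxt_id, idm[isf]); nxt_shell <- c(nxt_shell, rep(row$daughter, sum(isf)))
        }
      }
      if (any(!isf)) {
        e_id <- c(e_id, idm[!isf]); e_en <- c(e_en, rep(row$auger_eV, sum(!isf)))
        nd <- row$n_daughters_auger
        add_local(idm[!isf], row$binding_eV - row$auger_eV - nd * dB)
        if (nd > 0) {
          nxt_id <- c(nxt_id, rep(idm[!isf], nd))
          nxt_shell <- c(nxt_shell, rep(row$daughter, nd * sum(!isf)))
        }
      }
    }
    cur_id <- nxt_id; cur_shell <- nxt_shell
  }
  list(electrons = data.frame(id = e_id, energy_eV = e_en),
       photons = data.frame(id = p_id, energy_eV = p_en),
       local_eV = local)
}
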