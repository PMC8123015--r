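# Condensed-history electron transport with continuous (CSDA) energy loss.
# Steps are a fixed fraction of the current CSDA range; the energy after a
# step is read off the range table (E_next = E(R(E) * (1 - f))), so the sum
# of per-step deposits plus the final sub-cutoff deposit equals the starting
# kinetic energy by construction. Direction is perturbed per step with a
# Highland-style Gaussian small-angle model above 10 keV and isotropic step
# directions below (low-energy electrons in water scatter quasi-isotropically).
# Knock-on (delta-ray) branching is not modelled: its energy stays in the
# continuous loss, a redistribution below the 10 nm scoring ambition.

#' Transport configuration
#'
#' @param step_frac Step length as a fraction of the current CSDA range
#'   (0 < f <= 0.2; default 0.05).
#' @param cutoff_eV Kinetic energy below which the electron is absorbed
#'   locally (>= 100 eV, the vendored-table floor; default 100).
#' @param angular Angular model: `"auto"` (Highland Gaussian above 10 keV,
#'   isotropic below), `"isotropic"`, or `"none"` (straight-ahead; for
#'   tests).
#' @return A `ndf_transport_config` list.
#' @export
transport_config <- function(step_frac = 0.05, cutoff_eV = 100,
                             angular = c("auto", "isotropic", "none")) {
  angular <- match.arg(angular)
  if (!(step_frac > 0 && step_frac <= 0.2)) stop("step_frac must be in (0, 0.2]")
  if (cutoff_eV < 100) stop("cutoff_eV must be >= the 100 eV table floor")
  structure(list(step_frac = step_frac, cutoff_eV = cutoff_eV,
                 angular = angular), class = "ndf_transport_config")
}

# radiation lengths for the Highland parameterisation [g/cm^2]
.x0_gcm2 <- function(material) {
  switch(material$name, water = 36.08, platinum = 6.54, 36.08)
}

# rotate unit vectors u by polar angle theta (about a random azimuth phi)
.rotate_dirs <- function(u, theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi);   sp <- sin(phi)
  uz <- u[, 3]
  safe <- abs(uz) < 0.999999
  out <- u
  # general case: build an orthonormal frame around u
  if (any(safe)) {
    us <- u[safe, , drop = FALSE]
    den <- sqrt(1 - us[, 3]^2)
    e1 <- cbind(-us[, 2], us[, 1], 0) / den          # u x z / |..|
    e2 <- cbind(us[, 3] * us[, 1], us[, 3] * us[, 2],
                -(den^2)) / den                       # u x e1
    out[safe, ] <- us * ct[safe] +
      st[safe] * (e1 * cp[safe] + e2 * sp[safe])
  }
  if (any(!safe)) {
    sgn <- sign(uz[!safe])
    out[!safe, ] <- cbind(st[!safe] * cos(phi[!safe]),
                          st[!safe] * sin(phi[!safe]),
                          sgn * ct[!safe])
  }
  out / sqrt(rowSums(out^2))
}

.highland_theta0 <- function(E_eV, step_nm, material) {
  pc2 <- E_eV * (E_eV + 2 * .mec2_eV)
  etot <- E_eV + .mec2_eV
  beta_pc <- pc2 / etot                         # beta * p * c in eV
  x_over_x0 <- pmax(step_nm * 1e-7 * material$density / .x0_gcm2(material),
                    1e-12)
  th <- 13.6e6 / beta_pc * sqrt(x_over_x0) *
    (1 + 0.038 * log(x_over_x0))
  pmin(pmax(th, 0), 1.0)
}

# per-step angular perturbation shared by all transport loops. `step` is the
# actual step just taken and `Rstart` the CSDA range at its start; for the
# sub-10 keV isotropic model the redirection fires with probability
# step / (step_frac * Rstart) so the angular diffusion per unit path is
# independent of any scoring-driven step subdivision. The Highland branch
# uses the actual step length (Gaussian variance composes additively).
.perturb_dirs <- function(U, E, step, Rstart, material, cfg) {
  n <- length(E)
  if (cfg$angular == "none" || n == 0) return(U)
  iso_regime <- if (cfg$angular == "isotropic") rep(TRUE, n) else E < 1e4
  p_redir <- pmin(1, step / (cfg$step_frac * Rstart))
  iso <- iso_regime & stats::runif(n) < p_redir
  if (any(iso)) {
    cz <- stats::runif(sum(iso), -1, 1)
    az <- stats::runif(sum(iso), 0, 2 * pi)
    sz <- sqrt(1 - cz^2)
    U[iso, ] <- cbind(sz * cos(az), sz * sin(az), cz)
  }
  gau <- !iso_regime
  if (any(gau)) {
    th0 <- .highland_theta0(E[gau], step[gau], material)
    th <- pmin(abs(stats::rnorm(sum(gau))) * th0, pi)
    ph <- stats::runif(sum(gau), 0, 2 * pi)
    U[gau, ] <- .rotate_dirs(U[gau, , drop = FALSE], th, ph)
  }
  U
}

#' Batch condensed-history electron transport
#'
#' Transports many electrons through an infinite homogeneous medium and
#' returns every energy deposit. Optionally records crossings of the plane
#' `z = plane_z` (tracks stop there; used by stage 1), and supports an
#' early-kill criterion for shell scoring: a track is dropped once
#' `distance_from(center) - remaining_range > kill_beyond_nm`, i.e. once it
#' can no longer deposit inside the scoring extent.
#'
#' @param energy_eV,pos,dir Starting kinetic energies (vector), positions
#'   (n x 3 matrix, nm) and unit directions (n x 3 matrix).
#' @param material Medium (a material object).
#' @param cfg A [transport_config()].
#' @param plane_z If finite, a recording plane; tracks crossing it in +z are
#'   stopped and returned in `$crossings`.
#' @param center,kill_beyond_nm Optional early-kill sphere-center (length-3)
#'   and scoring extent for the kill criterion.
#' @param track_id Integer id per track propagated to deposits/crossings.
#' @return List with `deposits` (data.frame id, x_nm, y_nm, z_nm, energy_eV)
#'   and `crossings` (data.frame id, energy_eV, x_nm, y_nm, z_nm, ux, uy, uz).
#' @export
transport_electrons <- function(energy_eV, pos, dir, material,
                                cfg = transport_config(), plane_z = Inf,
                                center = NULL, kill_beyond_nm = Inf,
                                track_id = seq_along(energy_eV)) {
  n <- length(energy_eV)
  stopifnot(nrow(pos) == n, nrow(dir) == n)
  es <- material$estop
  floor_eV <- es$energy_eV[1]
  if (any(energy_eV < cfg$cutoff_eV))
    stop("starting energies must be >= the transport cutoff")
  E <- energy_eV
  P <- pos; U <- dir
  id <- as.integer(track_id)
  dep <- vector("list", 0)
  cro <- vector("list", 0)
  Rcur <- material$interp$range(E)
  while (length(E)) {
    Rstart <- Rcur
    step <- cfg$step_frac * Rcur
    E_next <- material$interp$einv(Rcur * (1 - cfg$step_frac))
    dE <- E - E_next
    below <- E_next <= cfg$cutoff_eV * 1.5
    # terminal: carry the residual range forward and deposit everything
    if (any(below)) {
      Pend <- P[below, , drop = FALSE] +
        U[below, , drop = FALSE] * Rcur[below]
      dep[[length(dep) + 1]] <- data.frame(
        id = id[below], x_nm = Pend[, 1], y_nm = Pend[, 2],
        z_nm = Pend[, 3], energy_eV = E[below])
    }
    keep <- !below
    if (!any(keep)) break
    E <- E[keep]; E_next <- E_next[keep]; dE <- dE[keep]
    P <- P[keep, , drop = FALSE]; U <- U[keep, , drop = FALSE]
    id <- id[keep]; step <- step[keep]; Rcur <- Rcur[keep]
    Rstart <- Rstart[keep]
    newP <- P + U * step
    # recording-plane crossing (stage 1): stop at the plane, deposit the
    # path-fraction of the step energy before it
    if (is.finite(plane_z)) {
      crossing <- (P[, 3] < plane_z) & (newP[, 3] >= plane_z)
      if (any(crossing)) {
        fr <- (plane_z - P[crossing, 3]) /
          (newP[crossing, 3] - P[crossing, 3])
        hit <- P[crossing, , drop = FALSE] +
          U[crossing, , drop = FALSE] * (fr * step[crossing])
        dE_c <- dE[crossing] * fr
        mid <- P[crossing, , drop = FALSE] +
          U[crossing, , drop = FALSE] * (fr * step[crossing] / 2)
        dep[[length(dep) + 1]] <- data.frame(
          id = id[crossing], x_nm = mid[, 1], y_nm = mid[, 2],
          z_nm = mid[, 3], energy_eV = dE_c)
        cro[[length(cro) + 1]] <- data.frame(
          id = id[crossing], energy_eV = E[crossing] - dE_c,
          x_nm = hit[, 1], y_nm = hit[, 2], z_nm = hit[, 3],
          ux = U[crossing, 1], uy = U[crossing, 2], uz = U[crossing, 3])
        keep <- !crossing
        E <- E[keep]; E_next <- E_next[keep]; dE <- dE[keep]
        P <- P[keep, , drop = FALSE]; U <- U[keep, , drop = FALSE]
        newP <- newP[keep, , drop = FALSE]
        id <- id[keep]; step <- step[keep]; Rstart <- Rstart[keep]
        if (!length(E)) break
      }
    }
    mid <- (P + newP) / 2
    dep[[length(dep) + 1]] <- data.frame(
      id = id, x_nm = mid[, 1], y_nm = mid[, 2], z_nm = mid[, 3],
      energy_eV = dE)
    P <- newP
    E <- E_next
    Rcur <- material$interp$range(E)
    # early kill: can this track still reach the scoring region?
    if (!is.null(center)) {
      d <- sqrt((P[, 1] - center[1])^2 + (P[, 2] - center[2])^2 +
                  (P[, 3] - center[3])^2)
      live <- (d - Rcur) <= kill_beyond_nm
      if (!all(live)) {
        E <- E[live]; P <- P[live, , drop = FALSE]
        U <- U[live, , drop = FALSE]; id <- id[live]
        Rcur <- Rcur[live]; step <- step[live]; Rstart <- Rstart[live]
        if (!length(E)) break
      }
    }
    U <- .perturb_dirs(U, E, step, Rstart, material, cfg)
  }
  deposits <- if (length(dep)) do.call(rbind, dep) else
    data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               z_nm = numeric(0), energy_eV = numeric(0))
  crossings <- if (length(cro)) do.call(rbind, cro) else
    data.frame(id = integer(0), energy_eV = numeric(0), x_nm = numeric(0),
               y_nm = numeric(0), z_nm = numeric(0), ux = numeric(0),
               uy = numeric(0), uz = numeric(0))
  list(deposits = deposits, crossings = crossings)
}

#' Transport a single electron phase-space record
#'
#' Thin wrapper over [transport_electrons()] for one record.
#'
#' @param record One-row data frame in phase-space record format (must be an
#'   electron).
#' @param medium Material to transport in.
#' @param cfg A [transport_config()].
#' @return Data frame of energy deposits (`x_nm`, `y_nm`, `z_nm`,
#'   `energy_eV`).
#' @export
transport_electron <- function(record, medium, cfg = transport_config()) {
  if (!identical(record$kind, "electron"))
    stop("transport_electron() expects an electron record")
  out <- transport_electrons(record$energy_eV,
                             cbind(record$x_nm, record$y_nm, record$z_nm),
                             cbind(record$ux, record$uy, record$uz),
                             medium, cfg)
  out$deposits[c("x_nm", "y_nm", "z_nm", "energy_eV")]
}

#' End-point depth statistics of monoenergetic electrons
#'
#' Diagnostic: transports `n` electrons from the origin along +z and
#' summarises the depth of the final (largest-z-track-end) deposit. With
#' angular deflection disabled the mean depth equals the CSDA range; with
#' deflections on it is strictly smaller (detour factor < 1).
#'
#' @param energy_eV Starting kinetic energy (eV).
#' @param medium Material object.
#' @param n Number of tracks.
#' @param cfg A [transport_config()].
#' @return List with `mean_depth_nm`, `sd_depth_nm`, `detour` (mean depth /
#'   CSDA range) and `n`.
#' @export
range_straggled_endpoint <- function(energy_eV, medium, n = 1000,
                                     cfg = transport_config()) {
  res <- transport_electrons(rep(energy_eV, n), matrix(0, n, 3),
                             matrix(rep(c(0, 0, 1), each = n), n, 3),
                             medium, cfg)
  d <- res$deposits
  endz <- vapply(split(seq_len(nrow(d)), d$id), function(ix) {
    d$z_nm[ix[length(ix)]]
  }, numeric(1))
  r0 <- csda_range(medium, energy_eV)
  list(mean_depth_nm = mean(endz), sd_depth_nm = stats::sd(endz),
       detour = mean(endz) / r0, n = n)
}
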