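# Stage 2: drive the stage-1 phase space onto a nanometric sphere of
# platinum (or water, the control arm) and record the electrons escaping it.
#
# An analog simulation of a 3.2 nm target is hopeless (the interaction
# probability per traversal is ~1e-7), so every photon aimed at the sphere
# is FORCED to interact along its chord with statistical weight
# w = 1 - exp(-mu_total * chord), which keeps the estimator unbiased. Impact
# parameters are sampled uniformly over the sphere's geometric cross-section
# in both beam modes; the modes differ in what else the downstream scoring
# receives: in `equilibrium` mode the incident electron field recorded in
# stage 1 accompanies the photons (charged-particle equilibrium), in
# `np_sized` mode only the photons aimed at the nanoparticle are injected --
# the biased construction the nanodosimetry literature warns against.

#' Nanoparticle specification
#'
#' @param material "Pt" or "water" (the control arm).
#' @param diameter_nm Sphere diameter (default 3.2 nm, the measured mean
#'   core diameter).
#' @param center Sphere centre (nm); scoring geometry is relative to it.
#' @return An `ndf_np` list with the resolved material attached.
#' @export
np_spec <- function(material = c("Pt", "water"), diameter_nm = 3.2,
                    center = c(0, 0, 0)) {
  material <- match.arg(material)
  if (diameter_nm <= 0) stop("diameter must be positive")
  structure(list(material_name = material,
                 material = if (material == "Pt") mat_platinum() else mat_water(),
                 diameter_nm = diameter_nm, radius_nm = diameter_nm / 2,
                 center = center),
            class = "ndf_np")
}

#' Beam-mode for stage 2
#'
#' @param mode "equilibrium" (incident electrons included; the physical
#'   construction) or "np_sized" (photons only, aimed at the nanoparticle;
#'   the biased construction).
#' @param eq_radius_nm Equilibrium sampling radius. Must be at least the
#'   CSDA range of the most energetic electron in the phase space; the
#'   default (`NULL`) takes that range rounded up to 1 um granularity. The
#'   lateral disc is integrated analytically in the scoring stage, so
#'   estimates are exactly independent of any admissible value.
#' @return An `ndf_beam_mode` list.
#' @export
beam_mode <- function(mode = c("equilibrium", "np_sized"),
                      eq_radius_nm = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, eq_radius_nm = eq_radius_nm),
            class = "ndf_beam_mode")
}

#' Chord length of a sphere at a given impact parameter
#'
#' @param diameter_nm Sphere diameter (nm).
#' @param b_nm Impact parameter(s) (nm, >= 0).
#' @return `2 sqrt(r^2 - b^2)` for `b < r`, else 0.
#' @export
chord_length <- function(diameter_nm, b_nm) {
  if (any(b_nm < 0)) stop("impact parameter must be >= 0")
  r <- diameter_nm / 2
  ifelse(b_nm < r, 2 * sqrt(pmax(0, r^2 - b_nm^2)), 0)
}

# orthonormal frame perpendicular to unit vectors u (n x 3)
.perp_frame <- function(u) {
  uz <- u[, 3]
  safe <- abs(uz) < 0.999999
  e1 <- matrix(0, nrow(u), 3)
  den <- sqrt(pmax(1 - uz^2, 1e-30))
  e1[safe, ] <- cbind(-u[safe, 2], u[safe, 1], 0) / den[safe]
  e1[!safe, ] <- matrix(rep(c(1, 0, 0), each = sum(!safe)), ncol = 3)
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

# condensed-history transport inside the nanoparticle sphere; electrons
# escaping through the surface are returned with their exit state
.transport_in_sphere <- function(E, pos, dir, material, r_np, cfg) {
  absorbed <- 0
  esc <- list()
  id <- seq_along(E)
  P <- pos; U <- dir
  alive <- length(E) > 0
  while (alive) {
    Rcur <- material$interp$range(E)
    step <- cfg$step_frac * Rcur
    E_next <- material$interp$einv(Rcur * (1 - cfg$step_frac))
    dE <- E - E_next
    # distance to the spherical boundary along the current direction
    pu <- rowSums(P * U)
    disc <- pmax(0, pu^2 + r_np^2 - rowSums(P^2))
    t_exit <- -pu + sqrt(disc)
    exits <- t_exit <= step & E > cfg$cutoff_eV
    if (any(exits)) {
      frac <- t_exit[exits] / step[exits]
      dE_in <- dE[exits] * frac
      E_out <- E[exits] - dE_in
      absorbed <- absorbed + sum(dE_in)
      ok <- E_out >= cfg$cutoff_eV
      if (any(ok)) {
        Pexit <- P[exits, , drop = FALSE] +
          U[exits, , drop = FALSE] * t_exit[exits]
        esc[[length(esc) + 1]] <- data.frame(
          id = id[exits][ok], energy_eV = E_out[ok],
          x_nm = Pexit[ok, 1], y_nm = Pexit[ok, 2], z_nm = Pexit[ok, 3],
          ux = U[exits, 1][ok], uy = U[exits, 2][ok], uz = U[exits, 3][ok])
      }
      absorbed <- absorbed + sum(E_out[!ok])
    }
    stay <- !exits
    # sub-cutoff or finished: absorb locally
    done <- stay & (E_next <= cfg$cutoff_eV * 1.5)
    absorbed <- absorbed + sum(E[done])
    keep <- stay & !done
    if (!any(keep)) break
    absorbed <- absorbed + sum(dE[keep])
    E <- E_next[keep]
    P <- (P + U * step)[keep, , drop = FALSE]
    U <- U[keep, , drop = FALSE]
    id <- id[keep]
    U <- .perturb_dirs(U, E, step[keep], Rcur[keep], material, cfg)
    alive <- length(E) > 0
  }
  escapes <- if (length(esc)) do.call(rbind, esc) else
    data.frame(id = integer(0), energy_eV = numeric(0), x_nm = numeric(0),
               y_nm = numeric(0), z_nm = numeric(0), ux = numeric(0),
               uy = numeric(0), uz = numeric(0))
  list(escapes = escapes, absorbed_eV = absorbed)
}

#' Run stage 2: forced interaction on the nanoparticle
#'
#' Resamples the stage-1 phase space onto the sphere. Each photon record is
#' aimed with an impact parameter drawn uniformly over the geometric
#' cross-section disc, forced to interact along its chord with weight
#' `w = 1 - exp(-mu total * chord)` (interaction point from the truncated
#' exponential; process by relative attenuation). Photoelectrons, Compton
#' electrons and relaxation-cascade electrons are transported inside the
#' nanoparticle material; electrons crossing the surface outward are
#' recorded with the event weight. Scattered and fluorescence photons leave
#' the nanometric sphere uninteracted and their energy is tallied as
#' escaping photon energy. In equilibrium mode the incident electron records
#' are passed through to the output as the accompanying field (their
#' sub-100 eV perturbation by the 3.2 nm sphere is neglected).
#'
#' @param ps Stage-1 phase space (`ndf_phsp`), non-empty.
#' @param np A [np_spec()].
#' @param mode A [beam_mode()].
#' @param resamples Number of reuses of each phase-space record (>= 1).
#' @param seed RNG seed.
#' @param cfg Electron [transport_config()].
#' @param spectrum_breaks_eV Bin edges for the escape spectrum.
#' @return List with `escape` (phase space of escaping electrons; positions
#'   relative to the nanoparticle centre; `history` is the forced-event
#'   index), `bg` (phase space of the accompanying electron field or `NULL`
#'   in np_sized mode), `spectrum` (an `ndf_escape_spectrum`) and `stats`
#'   (weight and energy bookkeeping).
#' @export
run_stage2 <- function(ps, np, mode = beam_mode(), resamples = 1, seed = 1L,
                       cfg = transport_config(),
                       spectrum_breaks_eV = exp(seq(log(100), log(7e5),
                                                    length.out = 61))) {
  stopifnot(inherits(ps, "ndf_phsp"), inherits(np, "ndf_np"),
            inherits(mode, "ndf_beam_mode"))
  if (!nrow(ps$records)) stop("empty phase space")
  if (resamples < 1) stop("resamples must be >= 1")
  set.seed(seed)
  recs <- ps$records
  phr <- recs[recs$kind == "photon", , drop = FALSE]
  elr <- recs[recs$kind == "electron", , drop = FALSE]
  # equilibrium-radius invariant (the admissible minimum): max electron
  # range in the phase space, rounded up to 1 um granularity
  if (mode$mode == "equilibrium") {
    r_min <- if (nrow(elr))
      ceiling(csda_range(mat_water(), max(elr$energy_eV)) / 1000) * 1000
    else 1000
    if (is.null(mode$eq_radius_nm)) mode$eq_radius_nm <- r_min
    if (mode$eq_radius_nm < r_min)
      stop(sprintf(paste0("equilibrium radius %g nm below the admissible ",
                          "minimum %g nm"), mode$eq_radius_nm, r_min))
  }
  mat <- np$material
  r_np <- np$radius_nm
  esc_all <- list()
  absorbed <- 0; fluor_escape <- 0; scat_escape <- 0
  sum_w_forced <- 0; sum_w_outcome <- 0
  e_in_w <- 0; e_secondary_w <- 0; e_local_w <- 0
  ev0 <- 0
  for (rs in seq_len(resamples)) {
    n <- nrow(phr)
    E <- phr$energy_eV
    U <- as.matrix(phr[c("ux", "uy", "uz")])
    w_rec <- phr$weight
    ev_id <- ev0 + seq_len(n)
    ev0 <- ev0 + n
    # impact point on the cross-section disc, perpendicular to each photon
    b <- r_np * sqrt(stats::runif(n))
    psi <- stats::runif(n, 0, 2 * pi)
    fr <- .perp_frame(U)
    bvec <- fr$e1 * (b * cos(psi)) + fr$e2 * (b * sin(psi))
    chord <- chord_length(np$diameter_nm, b)
    mu <- .mu_lin_nm(mat, E)
    w_int <- 1 - exp(-mu * chord)
    w <- w_rec * w_int
    sum_w_forced <- sum_w_forced + sum(w)
    e_in_w <- e_in_w + sum(w * E)
    # interaction point: truncated exponential along the chord
    uu <- stats::runif(n)
    s <- -log(1 - uu * w_int) / mu
    X <- bvec + U * (s - chord / 2)
    # process selection by relative attenuation
    m_pe <- .mu_lin_nm(mat, E, "photoelectric")
    m_in <- .mu_lin_nm(mat, E, "incoherent")
    m_co <- .mu_lin_nm(mat, E, "coherent")
    pick <- stats::runif(n) * (m_pe + m_in + m_co)
    is_pe <- pick < m_pe
    is_in <- !is_pe & pick < m_pe + m_in
    is_co <- !(is_pe | is_in)
    # secondary electron stack for the in-sphere transport
    se_E <- numeric(0); se_P <- NULL; se_U <- NULL
    se_w <- numeric(0); se_ev <- integer(0)
    if (any(is_in)) {
      sc <- sample_compton(E[is_in])
      az <- stats::runif(sum(is_in), 0, 2 * pi)
      U_el <- .rotate_dirs(U[is_in, , drop = FALSE], sc$phi_e, az + pi)
      keepT <- sc$T_e_eV >= cfg$cutoff_eV
      se_E <- c(se_E, sc$T_e_eV[keepT])
      se_P <- rbind(se_P, X[is_in, , drop = FALSE][keepT, , drop = FALSE])
      se_U <- rbind(se_U, U_el[keepT, , drop = FALSE])
      se_w <- c(se_w, w[is_in][keepT])
      se_ev <- c(se_ev, ev_id[is_in][keepT])
      absorbed <- absorbed + sum(w[is_in][!keepT] * sc$T_e_eV[!keepT])
      scat_escape <- scat_escape + sum(w[is_in] * sc$E_out_eV)
    }
    if (any(is_pe)) {
      Epe <- E[is_pe]
      shl <- .pe_select_shell(mat, Epe)
      shtab <- atomic_shells(mat$relax_element)
      B <- ifelse(shl == "valence", 20,
                  shtab$binding_eV[match(shl, shtab$shell)])
      B <- pmin(B, Epe * 0.99)
      vac <- shl != "valence" & B < Epe * 0.99
      T_pe <- Epe - B
      cz <- .sample_dipole_cos(sum(is_pe))
      azp <- stats::runif(sum(is_pe), 0, 2 * pi)
      U_pe <- .rotate_dirs(U[is_pe, , drop = FALSE], acos(cz), azp)
      keepT <- T_pe >= cfg$cutoff_eV
      se_E <- c(se_E, T_pe[keepT])
      se_P <- rbind(se_P, X[is_pe, , drop = FALSE][keepT, , drop = FALSE])
      se_U <- rbind(se_U, U_pe[keepT, , drop = FALSE])
      se_w <- c(se_w, w[is_pe][keepT])
      se_ev <- c(se_ev, ev_id[is_pe][keepT])
      absorbed <- absorbed + sum(w[is_pe][!keepT] * T_pe[!keepT])
      if (any(vac)) {
        rx <- .relax_vacancies(mat$relax_element, shl[vac])
        idx <- which(is_pe)[vac]
        absorbed <- absorbed + sum(w[idx] * rx$local_eV)
        if (nrow(rx$electrons)) {
          ne <- nrow(rx$electrons)
          czr <- stats::runif(ne, -1, 1); azr <- stats::runif(ne, 0, 2 * pi)
          szr <- sqrt(1 - czr^2)
          keepA <- rx$electrons$energy_eV >= cfg$cutoff_eV
          se_E <- c(se_E, rx$electrons$energy_eV[keepA])
          se_P <- rbind(se_P, X[idx[rx$electrons$id[keepA]], , drop = FALSE])
          se_U <- rbind(se_U, cbind(szr * cos(azr), szr * sin(azr),
                                    czr)[keepA, , drop = FALSE])
          se_w <- c(se_w, w[idx[rx$electrons$id[keepA]]])
          se_ev <- c(se_ev, ev_id[idx[rx$electrons$id[keepA]]])
          absorbed <- absorbed +
            sum(w[idx[rx$electrons$id[!keepA]]] *
                  rx$electrons$energy_eV[!keepA])
        }
        if (nrow(rx$photons))
          fluor_escape <- fluor_escape +
            sum(w[idx[rx$photons$id]] * rx$photons$energy_eV)
      }
      absorbed <- absorbed + sum(w[is_pe][!vac] * B[!vac])
    }
    if (any(is_co)) scat_escape <- scat_escape + sum(w[is_co] * E[is_co])
    # transport the secondary stack inside the sphere
    if (length(se_E)) {
      tr <- .transport_in_sphere(se_E, se_P, se_U, mat, r_np, cfg)
      # absorbed bookkeeping above is unweighted inside the helper: scale by
      # tracking weights through per-track absorption
      # (the helper reports unweighted sums; recompute with weights)
      esc <- tr$escapes
      if (nrow(esc)) {
        esc$weight <- se_w[esc$id]
        esc$history <- se_ev[esc$id]
        esc_all[[length(esc_all) + 1]] <- esc
      }
      # per-track energy bookkeeping: escaping energy (weighted)
      e_escaped_tracks <- if (nrow(esc)) sum(esc$weight * esc$energy_eV) else 0
      e_injected_tracks <- sum(se_w * se_E)
      absorbed <- absorbed + (e_injected_tracks - e_escaped_tracks)
      e_secondary_w <- e_secondary_w + e_injected_tracks
    }
    sum_w_outcome <- sum_w_outcome + sum(w)
  }
  escapes <- if (length(esc_all)) do.call(rbind, esc_all) else NULL
  esc_rec <- if (!is.null(escapes))
    data.frame(kind = "electron", energy_eV = escapes$energy_eV,
               x_nm = escapes$x_nm, y_nm = escapes$y_nm,
               z_nm = escapes$z_nm, ux = escapes$ux, uy = escapes$uy,
               uz = escapes$uz, weight = escapes$weight,
               history = escapes$history)
  else data.frame()
  escape_ps <- phase_space(esc_rec, n_primaries = ps$header$n_primaries,
                           stage = "stage2-escape",
                           source = sprintf("NP %s d=%gnm, %s mode",
                                            np$material_name, np$diameter_nm,
                                            mode$mode),
                           seed = seed)
  attr(escape_ps, "resamples") <- resamples
  bg <- NULL
  if (mode$mode == "equilibrium" && nrow(elr)) {
    bgr <- elr
    bgr$z_nm <- 0
    bgr$history <- seq_len(nrow(bgr))
    bg <- phase_space(bgr, n_primaries = ps$header$n_primaries,
                      stage = "stage2-bg",
                      source = "incident electron field", seed = seed)
    attr(bg, "resamples") <- 1L
  }
  # escape spectrum per primary history
  spec <- summarize_spectrum(escape_ps, "electron", spectrum_breaks_eV)
  n_events <- ev0
  stats_out <- list(
    n_photon_records = nrow(phr), n_electron_records = nrow(elr),
    resamples = resamples, n_events = n_events,
    sum_forced_weight = sum_w_forced,
    sum_outcome_weight = sum_w_outcome,
    escape_weight = if (!is.null(escapes)) sum(escapes$weight) else 0,
    escape_energy_w_eV = if (!is.null(escapes))
      sum(escapes$weight * escapes$energy_eV) else 0,
    absorbed_energy_w_eV = absorbed,
    fluorescence_escape_w_eV = fluor_escape,
    scattered_photon_escape_w_eV = scat_escape,
    energy_in_w_eV = e_in_w,
    escape_count_per_primary = if (!is.null(escapes))
      sum(escapes$weight) * pi * r_np^2 /
        (ps$header$n_primaries * resamples) else 0,
    mean_absorbed_eV = if (sum_w_forced > 0) absorbed / sum_w_forced else 0,
    eq_radius_nm = mode$eq_radius_nm)
  structure(list(escape = escape_ps, bg = bg, spectrum = spec,
                 stats = stats_out, np = np, mode = mode),
            class = "ndf_stage2")
}

#' @export
print.ndf_stage2 <- function(x, ...) {
  cat(sprintf(paste0("<stage 2 (%s, %s mode): %d escape records, ",
                     "forced weight %.4g, mean absorbed %.3g eV>\n"),
              x$np$material_name, x$mode$mode, nrow(x$escape$records),
              x$stats$sum_forced_weight, x$stats$mean_absorbed_eV))
  invisible(x)
}
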