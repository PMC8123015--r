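# Stage 3: transport the stage-2 output in liquid water and score energy
# deposits in concentric shells around the nanoparticle; form DEF profiles
# with history-batch uncertainties.
#
# Two scoring geometries are used. Electrons escaping the nanoparticle are
# scored directly: each deposit is binned by its sampled distance from the
# sphere surface. The accompanying (equilibrium) electron field represents a
# laterally uniform beam, so its lateral coordinate is integrated
# analytically: a deposit at depth z contributes to shell [r1, r2) the disc
# area pi * ((r2^2 - z^2)+ - (r1^2 - z^2)+) per unit normalisation area
# (a conditional-expectation / Rao-Blackwell reduction of the lateral
# sampling, which also makes results exactly independent of the equilibrium
# sampling radius). All tallies are per primary history for a beam fluence
# of one primary per nm^2.

#' Concentric shell binning
#'
#' Shells indexed from the nanoparticle surface; shell `i` covers
#' `[i t, (i+1) t)` (half-open) in distance from the surface.
#'
#' @param thickness_nm Shell thickness (default 10 nm).
#' @param extent_nm Outer extent (default 2000 nm).
#' @return An `ndf_binning` list with `n_shells`.
#' @export
shell_binning <- function(thickness_nm = 10, extent_nm = 2000) {
  if (thickness_nm <= 0) stop("thickness must be positive")
  if (extent_nm < thickness_nm) stop("extent must be >= thickness")
  n <- floor(extent_nm / thickness_nm + 1e-9)
  structure(list(thickness_nm = thickness_nm, extent_nm = n * thickness_nm,
                 n_shells = n), class = "ndf_binning")
}

# shell index (1-based) for distances d from the surface; 0 = internal,
# NA = beyond extent
.shell_index <- function(d_nm, binning) {
  idx <- floor(d_nm / binning$thickness_nm) + 1
  idx[d_nm < 0] <- 0
  idx[idx > binning$n_shells] <- NA
  idx
}

#' Score energy deposits into concentric shells
#'
#' @param deposits Data frame with `x_nm`, `y_nm`, `z_nm`, `energy_eV` and
#'   optionally `weight` (default 1).
#' @param np A [np_spec()]; distances are measured from its surface.
#' @param binning A [shell_binning()].
#' @return An `ndf_shell_tally` with per-shell energy (eV), an `internal`
#'   bin for deposits inside the nanoparticle volume, and the energy/count
#'   discarded beyond the extent.
#' @export
score_shells <- function(deposits, np, binning) {
  w <- if ("weight" %in% names(deposits)) deposits$weight else
    rep(1, nrow(deposits))
  d <- sqrt((deposits$x_nm - np$center[1])^2 +
              (deposits$y_nm - np$center[2])^2 +
              (deposits$z_nm - np$center[3])^2) - np$radius_nm
  idx <- .shell_index(d, binning)
  ew <- deposits$energy_eV * w
  energy <- numeric(binning$n_shells)
  sh <- !is.na(idx) & idx >= 1
  if (any(sh)) {
    agg <- rowsum(ew[sh], idx[sh])
    energy[as.integer(rownames(agg))] <- agg
  }
  internal <- sum(ew[!is.na(idx) & idx == 0])
  beyond <- is.na(idx)
  new_shell_tally(matrix(energy, ncol = 1), internal, sum(ew[beyond]),
                  sum(beyond), binning, np)
}

# batch_matrix columns are independent per-batch estimates of the per-primary
# shell energies; the point estimate is their mean
new_shell_tally <- function(batch_matrix, internal, beyond_energy,
                            beyond_count, binning, np, components = NULL) {
  structure(list(energy = rowMeans(batch_matrix),
                 batch = batch_matrix,
                 internal = internal,
                 beyond_energy = beyond_energy,
                 beyond_count = beyond_count,
                 binning = binning, np = np,
                 n_batches = ncol(batch_matrix),
                 components = components),
            class = "ndf_shell_tally")
}

#' @export
print.ndf_shell_tally <- function(x, ...) {
  cat(sprintf("<shell tally: %d shells x %d batches, total %.4g eV (+%.3g internal)>\n",
              x$binning$n_shells, x$n_batches, sum(x$energy), x$internal))
  invisible(x)
}

# --- scoring transport of sampled (nanoparticle-escape) electrons ---------
# condensed-history stepping identical to transport_electrons(), but deposits
# are binned immediately (shells x batches) instead of being materialised
.score_transport_sphere <- function(E, P, U, w, batch, n_batches, material,
                                    cfg, np, binning) {
  acc <- matrix(0, binning$n_shells, n_batches)
  internal <- 0; beyond_e <- 0; beyond_n <- 0
  kill_r <- np$radius_nm + binning$extent_nm
  add_dep <- function(x, y, z, e, wt, bt) {
    d <- sqrt((x - np$center[1])^2 + (y - np$center[2])^2 +
                (z - np$center[3])^2) - np$radius_nm
    idx <- .shell_index(d, binning)
    ew <- e * wt
    sh <- !is.na(idx) & idx >= 1
    if (any(sh)) {
      key <- (bt[sh] - 1) * binning$n_shells + idx[sh]
      agg <- rowsum(ew[sh], key)
      acc[as.integer(rownames(agg))] <<- acc[as.integer(rownames(agg))] + agg
    }
    internal <<- internal + sum(ew[!is.na(idx) & idx == 0])
    bey <- is.na(idx)
    beyond_e <<- beyond_e + sum(ew[bey]); beyond_n <<- beyond_n + sum(bey)
  }
  while (length(E)) {
    Rcur <- material$interp$range(E)
    # near the scoring region, cap the step so segment deposits resolve the
    # 10 nm shells; the cap ramps off with distance so that inbound tracks
    # cannot leap over the region (step <= distance still to go)
    d0 <- sqrt((P[, 1] - np$center[1])^2 + (P[, 2] - np$center[2])^2 +
                 (P[, 3] - np$center[3])^2)
    cap <- pmax(.score_step_cap_nm, d0 - kill_r)
    step <- pmin(cfg$step_frac * Rcur, cap)
    E_next <- material$interp$einv(Rcur - step)
    dE <- E - E_next
    below <- E_next <= cfg$cutoff_eV * 1.5
    if (any(below)) {
      Pend <- P[below, , drop = FALSE] +
        U[below, , drop = FALSE] * Rcur[below]
      add_dep(Pend[, 1], Pend[, 2], Pend[, 3], E[below], w[below],
              batch[below])
    }
    keep <- !below
    if (!any(keep)) break
    E <- E[keep]; E_next <- E_next[keep]; dE <- dE[keep]
    P <- P[keep, , drop = FALSE]; U <- U[keep, , drop = FALSE]
    w <- w[keep]; batch <- batch[keep]; step <- step[keep]
    Rstart <- Rcur[keep]
    newP <- P + U * step
    mid <- (P + newP) / 2
    add_dep(mid[, 1], mid[, 2], mid[, 3], dE, w, batch)
    P <- newP; E <- E_next
    Rcur <- material$interp$range(E)
    d <- sqrt((P[, 1] - np$center[1])^2 + (P[, 2] - np$center[2])^2 +
                (P[, 3] - np$center[3])^2)
    live <- (d - Rcur) <= kill_r
    if (!all(live)) {
      E <- E[live]; P <- P[live, , drop = FALSE]; U <- U[live, , drop = FALSE]
      w <- w[live]; batch <- batch[live]; Rcur <- Rcur[live]
      step <- step[live]; Rstart <- Rstart[live]
      if (!length(E)) break
    }
    U <- .perturb_dirs(U, E, step, Rstart, material, cfg)
  }
  list(acc = acc, internal = internal, beyond_e = beyond_e,
       beyond_n = beyond_n)
}

.score_step_cap_nm <- 10

# --- scoring transport of the laterally uniform background field ----------
# deposits contribute to shells through the analytic lateral-disc weights;
# only the depth coordinate of each deposit matters
.score_transport_annulus <- function(E, z0, U, w, batch, n_batches, material,
                                     cfg, np, binning) {
  nb <- binning$n_shells
  r_edges <- np$radius_nm + binning$thickness_nm * (0:nb)
  acc_cum <- matrix(0, nb + 1, n_batches)  # suffix ("full-area") accumulator
  acc_part <- matrix(0, nb, n_batches)     # partial band term
  internal <- 0
  add_dep <- function(z, e, wt, bt) {
    az <- abs(z)
    # band containing |z|: 0 = inside the sphere radius, 1..nb shells
    bnd <- findInterval(az, r_edges)        # 0 if az < r_np
    ew <- e * wt
    inside <- bnd == 0
    if (any(inside)) {
      internal <<- internal +
        sum(ew[inside] * pi * (np$radius_nm^2 - az[inside]^2))
      key <- (bt[inside] - 1) * (nb + 1) + 1
      agg <- rowsum(ew[inside], key)
      acc_cum[as.integer(rownames(agg))] <<-
        acc_cum[as.integer(rownames(agg))] + agg
    }
    mid <- bnd >= 1 & bnd <= nb
    if (any(mid)) {
      key <- (bt[mid] - 1) * nb + bnd[mid]
      agg <- rowsum(ew[mid] * pi * (r_edges[bnd[mid] + 1]^2 - az[mid]^2), key)
      acc_part[as.integer(rownames(agg))] <<-
        acc_part[as.integer(rownames(agg))] + agg
      key2 <- (bt[mid] - 1) * (nb + 1) + bnd[mid] + 1
      agg2 <- rowsum(ew[mid], key2)
      acc_cum[as.integer(rownames(agg2))] <<-
        acc_cum[as.integer(rownames(agg2))] + agg2
    }
  }
  P <- cbind(0, 0, z0)
  z_max <- r_edges[nb + 1]
  while (length(E)) {
    Rcur <- material$interp$range(E)
    cap <- pmax(.score_step_cap_nm, abs(P[, 3]) - z_max)
    step <- pmin(cfg$step_frac * Rcur, cap)
    E_next <- material$interp$einv(Rcur - step)
    dE <- E - E_next
    below <- E_next <= cfg$cutoff_eV * 1.5
    if (any(below))
      add_dep(P[below, 3] + U[below, 3] * Rcur[below], E[below], w[below],
              batch[below])
    keep <- !below
    if (!any(keep)) break
    E <- E[keep]; E_next <- E_next[keep]; dE <- dE[keep]
    P <- P[keep, , drop = FALSE]; U <- U[keep, , drop = FALSE]
    w <- w[keep]; batch <- batch[keep]; step <- step[keep]
    Rstart <- Rcur[keep]
    newP <- P + U * step
    mid <- (P + newP) / 2
    add_dep(mid[, 3], dE, w, batch)
    P <- newP; E <- E_next
    Rcur <- material$interp$range(E)
    live <- (abs(P[, 3]) - Rcur) <= z_max
    if (!all(live)) {
      E <- E[live]; P <- P[live, , drop = FALSE]; U <- U[live, , drop = FALSE]
      w <- w[live]; batch <- batch[live]; Rcur <- Rcur[live]
      step <- step[live]; Rstart <- Rstart[live]
      if (!length(E)) break
    }
    U <- .perturb_dirs(U, E, step, Rstart, material, cfg)
  }
  # assemble per-shell totals: full-area suffix term + partial band term
  areas <- pi * diff(r_edges^2)
  acc <- matrix(0, nb, n_batches)
  for (b in seq_len(n_batches)) {
    cum <- cumsum(acc_cum[, b])[seq_len(nb)]  # energy with |z| < r1 of shell s
    acc[, b] <- areas * cum + acc_part[, b]
  }
  list(acc = acc, internal = internal, beyond_e = 0, beyond_n = 0)
}

#' Run stage 3: shell dose scoring
#'
#' Transports the stage-2 escape electrons (and, in equilibrium mode, the
#' accompanying incident-electron field) in liquid water and accumulates the
#' per-shell energy deposit per primary history for a beam fluence of one
#' primary per nm^2. When the same `bg` object and seed are passed to both
#' arms the background realisation is identical, so the arm difference --
#' and hence the DEF -- is estimated with correlated sampling.
#'
#' @param st2 A `ndf_stage2` result from [run_stage2()].
#' @param binning A [shell_binning()].
#' @param n_batches Number of history batches for the uncertainty estimate
#'   (default 20).
#' @param seed RNG seed for the scoring transport.
#' @param cfg Electron [transport_config()].
#' @param bg_resamples Reuses of each background record (improves the
#'   smoothness of the shared background; default 10).
#' @return An `ndf_shell_tally`.
#' @export
run_stage3 <- function(st2, binning = shell_binning(), n_batches = 20,
                       seed = 1L, cfg = transport_config(),
                       bg_resamples = 10) {
  stopifnot(inherits(st2, "ndf_stage2"))
  if (n_batches < 2) stop("need at least 2 batches for uncertainties")
  set.seed(seed)
  np <- st2$np
  water <- mat_water()
  n_prim <- st2$escape$header$n_primaries
  resamples <- attr(st2$escape, "resamples")
  if (is.null(resamples)) resamples <- 1L
  # background first (identical RNG stream for both arms given same inputs)
  bg_part <- NULL
  if (!is.null(st2$bg) && nrow(st2$bg$records)) {
    r <- st2$bg$records
    rr <- r[rep(seq_len(nrow(r)), bg_resamples), , drop = FALSE]
    batch <- (rep(seq_len(nrow(rr))) - 1) %% n_batches + 1
    bg_part <- .score_transport_annulus(
      rr$energy_eV, rr$z_nm, as.matrix(rr[c("ux", "uy", "uz")]),
      rr$weight, batch, n_batches, water, cfg, np, binning)
    bg_norm <- n_prim * bg_resamples / n_batches   # per batch
  }
  # nanoparticle-escape electrons, chunked
  esc_acc <- matrix(0, binning$n_shells, n_batches)
  esc_int <- 0; esc_bey_e <- 0; esc_bey_n <- 0
  r <- st2$escape$records
  if (nrow(r)) {
    batch_all <- (r$history - 1) %% n_batches + 1
    chunks <- split(seq_len(nrow(r)),
                    ceiling(seq_len(nrow(r)) / 25000))
    for (ix in chunks) {
      res <- .score_transport_sphere(
        r$energy_eV[ix],
        as.matrix(r[ix, c("x_nm", "y_nm", "z_nm")]) +
          matrix(np$center, length(ix), 3, byrow = TRUE),
        as.matrix(r[ix, c("ux", "uy", "uz")]),
        r$weight[ix], batch_all[ix], n_batches, water, cfg, np, binning)
      esc_acc <- esc_acc + res$acc
      esc_int <- esc_int + res$internal
      esc_bey_e <- esc_bey_e + res$beyond_e
      esc_bey_n <- esc_bey_n + res$beyond_n
    }
  }
  # per-fluence normalisation (area A = 1 nm^2):
  #   escape term: x pi r_np^2 / (n_prim * resamples)
  #   background:  x 1 / (n_prim * bg_resamples)   [areas already in nm^2]
  geom <- pi * np$radius_nm^2
  esc_norm <- n_prim * resamples / n_batches       # per batch
  batchM <- esc_acc * geom / esc_norm
  internal <- esc_int * geom / (n_prim * resamples)
  beyond_e <- esc_bey_e * geom / (n_prim * resamples)
  comp <- list(np_term = rowSums(esc_acc) * geom / (n_prim * resamples))
  if (!is.null(bg_part)) {
    batchM <- batchM + bg_part$acc / bg_norm
    internal <- internal + bg_part$internal / (n_prim * bg_resamples)
    comp$bg_term <- rowSums(bg_part$acc) / (n_prim * bg_resamples)
  }
  new_shell_tally(batchM, internal, beyond_e, esc_bey_n, binning, np,
                  components = comp)
}

#' Compute the dose-enhancement factor profile
#'
#' DEF per shell is the normalised energy of the platinum arm over the water
#' control arm. The relative uncertainty is the batch standard error of the
#' per-batch DEF ratios, which respects the correlation deliberately built
#' into the two arms (they share the background-field realisation); when a
#' batch ratio is undefined the estimate falls back to the quadrature of the
#' two arms' batch standard errors. Shells with an empty denominator are
#' flagged undefined (NA).
#'
#' @param tally_pt,tally_water Shell tallies of the two arms (matching
#'   binning and batch structure).
#' @return An `ndf_def_profile` data frame with `shell`, `r_mid_nm` (shell
#'   mid-radius, measured from the nanoparticle surface), `def`, `rel_unc`,
#'   `e_pt_eV`, `e_water_eV`.
#' @export
compute_def <- function(tally_pt, tally_water) {
  b1 <- tally_pt$binning; b2 <- tally_water$binning
  if (b1$thickness_nm != b2$thickness_nm || b1$extent_nm != b2$extent_nm ||
      tally_pt$n_batches != tally_water$n_batches)
    stop("mismatched binning or batch structure between arms")
  nb <- tally_pt$n_batches
  se_rel <- function(t) {
    if (nb < 2) return(rep(NA_real_, b1$n_shells))
    m <- t$energy
    s <- apply(t$batch, 1, stats::sd) / sqrt(nb)
    ifelse(m > 0, s / m, NA_real_)
  }
  def <- ifelse(tally_water$energy > 0,
                tally_pt$energy / tally_water$energy, NA_real_)
  rel <- rep(NA_real_, b1$n_shells)
  if (nb >= 2) {
    ratio <- tally_pt$batch / tally_water$batch
    ok_row <- apply(is.finite(ratio) & tally_water$batch > 0, 1, all)
    if (any(ok_row)) {
      rb <- ratio[ok_row, , drop = FALSE]
      rel[ok_row] <- (apply(rb, 1, stats::sd) / sqrt(nb)) / rowMeans(rb)
    }
    fb <- !ok_row
    rel[fb] <- sqrt(se_rel(tally_pt)[fb]^2 + se_rel(tally_water)[fb]^2)
  }
  out <- data.frame(shell = seq_len(b1$n_shells) - 1L,
                    r_mid_nm = (seq_len(b1$n_shells) - 0.5) * b1$thickness_nm,
                    def = def, rel_unc = rel,
                    e_pt_eV = tally_pt$energy,
                    e_water_eV = tally_water$energy)
  structure(out, class = c("ndf_def_profile", "data.frame"),
            n_batches = nb,
            np_pt = tally_pt$np$material_name,
            np_water = tally_water$np$material_name)
}

#' Find significant local maxima of a DEF profile
#'
#' Local maxima where `DEF - 1` exceeds twice its (absolute) uncertainty,
#' sorted by DEF descending.
#'
#' @param profile An `ndf_def_profile` with at least 3 shells.
#' @return Data frame with `r_mid_nm` and `def` of each peak.
#' @export
find_peaks <- function(profile) {
  if (nrow(profile) < 3) stop("profile needs at least 3 shells")
  def <- profile$def
  unc_abs <- profile$rel_unc * def
  n <- length(def)
  is_max <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (is.na(def[i])) next
    lo <- if (i > 1) def[i - 1] else -Inf
    hi <- if (i < n) def[i + 1] else -Inf
    is_max[i] <- def[i] >= max(lo, hi, na.rm = TRUE) &&
      isTRUE(def[i] - 1 > 2 * unc_abs[i])
  }
  out <- data.frame(r_mid_nm = profile$r_mid_nm[is_max], def = def[is_max])
  out[order(-out$def), , drop = FALSE]
}

#' Peak-DEF ratio between the biased and equilibrium constructions
#'
#' @param profile_np_sized,profile_equilibrium DEF profiles computed with
#'   the nanoparticle-sized beam and with the equilibrium construction.
#' @return Ratio of the two profiles' maximum DEF values.
#' @export
equilibrium_bias <- function(profile_np_sized, profile_equilibrium) {
  p1 <- suppressWarnings(max(profile_np_sized$def, na.rm = TRUE))
  p2 <- suppressWarnings(max(profile_equilibrium$def, na.rm = TRUE))
  if (!is.finite(p1) || !is.finite(p2) || p2 <= 0)
    stop("undefined peak in one of the profiles")
  p1 / p2
}
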