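#' Block-averaged standard error of a time series
#'
#' Splits the series into `n_blocks` contiguous blocks and returns the
#' standard error of the block means, the package-wide uncertainty
#' convention for correlated MD channels.
#'
#' @param series numeric vector (length >= `n_blocks`)
#' @param n_blocks number of blocks (default 5)
#' @return standard error (same units as the series)
#' @export
block_error <- function(series, n_blocks = 5) {
  n <- length(series)
  if (n < n_blocks)
    stop("series too short (", n, " points) for ", n_blocks, " blocks")
  idx <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- tapply(series, idx, mean)
  sd(bm) / sqrt(n_blocks)
}

# analysis window: by default the final fraction of the trajectory
window_index <- function(traj, window = 0.25) {
  n <- length(traj$time)
  if (n < 1) stop("empty trajectory")
  if (length(window) == 2) {
    sel <- which(traj$time >= window[1] & traj$time <= window[2])
  } else {
    sel <- seq.int(max(1L, n - ceiling(window * n) + 1L), n)
  }
  if (!length(sel)) stop("empty analysis window")
  sel
}

obs_result <- function(value, err, traj, sel, n_blocks) {
  structure(list(value = value, uncertainty = err,
                 window = range(traj$time[sel]),
                 n_samples = length(sel), n_blocks = n_blocks),
            class = "cg_observable")
}

#' @export
print.cg_observable <- function(x, ...) {
  cat(signif(x$value, 6), "+/-", signif(x$uncertainty, 3),
      " (", x$n_samples, "samples,", x$n_blocks, "blocks )\n")
  invisible(x)
}

#' Mass density from a trajectory
#'
#' \eqn{\rho = \langle M / V \rangle} over the analysis window, in
#' kg/m^3, with block-averaged uncertainty. For NPT trajectories the
#' volume fluctuates; the per-frame density is averaged.
#'
#' @param traj a `cg_trajectory`
#' @param ff force field (bead masses)
#' @param window final fraction of the run to analyze (default 0.25, the
#'   last-quarter convention), or a length-2 time range in fs
#' @param n_blocks blocks for the uncertainty estimate
#' @return a `cg_observable` (kg/m^3)
#' @export
mass_density <- function(traj, ff, window = 0.25, n_blocks = 5) {
  sel <- window_index(traj, window)
  m_tot <- sum(ff$bead_types$mass[match(traj$types, ff$bead_types$name)])
  rho <- m_tot / traj$volume[sel] * cg_units$kgm3_per_amu_A3
  err <- if (length(sel) >= n_blocks) block_error(rho, n_blocks) else 0
  obs_result(mean(rho), err, traj, sel, n_blocks)
}

# shared Kirkwood-Irving estimator
ki_tension <- function(traj, sel, n_blocks, use_mean_lz) {
  P <- traj$pressure[sel, , drop = FALSE]
  Lz <- traj$box[sel, "Lz"]
  dP <- P[, "zz"] - (P[, "xx"] + P[, "yy"]) / 2
  Lz_use <- if (use_mean_lz) mean(Lz) else Lz
  g <- Lz_use / 2 * dP * cg_units$mNm_per_bar_A
  err <- if (length(g) >= n_blocks) block_error(g, n_blocks) else 0
  list(g = g, err = err)
}

#' Kirkwood-Irving surface tension of a slab
#'
#' \eqn{\gamma = \frac{L_z}{2}\langle P_{zz} - \frac{P_{xx}+P_{yy}}{2}\rangle}
#' in mN/m; the factor 1/2 accounts for the two liquid-vapor interfaces
#' of a slab. Intended for fixed-`L_z` (NVT) slab trajectories with the
#' interface normal along z.
#'
#' @inheritParams mass_density
#' @return a `cg_observable` (mN/m); a `warning` attribute is attached
#'   when the trajectory does not look slab-like (no stored frames to
#'   check, or a homogeneous density profile)
#' @export
surface_tension <- function(traj, window = 0.25, n_blocks = 5) {
  sel <- window_index(traj, window)
  k <- ki_tension(traj, sel, n_blocks, use_mean_lz = FALSE)
  out <- obs_result(mean(k$g), k$err, traj, sel, n_blocks)
  # sanity: a slab has empty space along z
  if (length(traj$frames)) {
    z <- traj$frames[[length(traj$frames)]]$pos[, 3]
    Lz <- traj$box[nrow(traj$box), "Lz"]
    h <- hist(z, breaks = seq(0, Lz, length.out = 13), plot = FALSE)
    if (all(h$counts > 0))
      attr(out, "warning") <- "no vacuum region detected: not a slab?"
  }
  out
}

#' Interfacial tension of a biphasic system
#'
#' The same Kirkwood-Irving estimator, with the mean of the fluctuating
#' `L_z` (NPzAT ensemble) in place of the fixed box length, and the 1/2
#' for the two liquid-liquid interfaces of the periodic stack.
#'
#' @inheritParams mass_density
#' @return a `cg_observable` (mN/m)
#' @export
interfacial_tension <- function(traj, window = 0.25, n_blocks = 5) {
  sel <- window_index(traj, window)
  k <- ki_tension(traj, sel, n_blocks, use_mean_lz = TRUE)
  obs_result(mean(k$g), k$err, traj, sel, n_blocks)
}

#' Osmotic pressure from virtual-wall forces
#'
#' The frame-averaged total force the ions exert on each semipermeable
#' wall, divided by the wall area \eqn{L_y L_z} and converted to bar;
#' the two walls are averaged. Requires the trajectory's per-frame wall
#' force channels.
#'
#' @inheritParams mass_density
#' @return a `cg_observable` (bar)
#' @export
osmotic_pressure <- function(traj, window = 0.25, n_blocks = 5) {
  if (is.null(traj$wall_forces) || ncol(traj$wall_forces) == 0)
    stop("trajectory carries no wall-force channels")
  sel <- window_index(traj, window)
  area <- traj$box[sel, "Ly"] * traj$box[sel, "Lz"]
  pw <- traj$wall_forces[sel, , drop = FALSE] / area *
    cg_units$bar_per_kcal_A3
  pi_series <- rowMeans(pw)
  err <- if (length(sel) >= n_blocks) block_error(pi_series, n_blocks) else 0
  obs_result(mean(pi_series), err, traj, sel, n_blocks)
}

#' Area per lipid
#'
#' \eqn{APL = \langle L_x\rangle \langle L_y\rangle / N_{lpl}} for one
#' leaflet, in A^2.
#'
#' @inheritParams mass_density
#' @param n_lipids_per_leaflet lipids per leaflet (> 0)
#' @return a `cg_observable` (A^2)
#' @export
area_per_lipid <- function(traj, n_lipids_per_leaflet, window = 0.25,
                           n_blocks = 5) {
  if (n_lipids_per_leaflet <= 0) stop("n_lipids_per_leaflet must be > 0")
  sel <- window_index(traj, window)
  apl_series <- traj$box[sel, "Lx"] * traj$box[sel, "Ly"] /
    n_lipids_per_leaflet
  err <- if (length(sel) >= n_blocks) block_error(apl_series, n_blocks) else 0
  obs_result(mean(traj$box[sel, "Lx"]) * mean(traj$box[sel, "Ly"]) /
               n_lipids_per_leaflet, err, traj, sel, n_blocks)
}

#' Transverse headgroup-headgroup distance
#'
#' \eqn{D_{HH}}: the absolute z distance between the centers of mass of
#' the upper-leaflet and lower-leaflet head beads, averaged over frames.
#' Leaflet assignment is fixed at the start of the analysis window (by
#' sign of z relative to the head-bead COM); flip-flop is not tracked.
#'
#' @param traj a `cg_trajectory` with stored frames
#' @param ff force field (bead masses for the COM)
#' @param head_selection bead indices of the head beads (e.g. the NC and
#'   PH beads of every lipid)
#' @inheritParams mass_density
#' @return a `cg_observable` (A)
#' @export
headgroup_distance <- function(traj, ff, head_selection, window = 0.25,
                               n_blocks = 5) {
  if (!length(head_selection)) stop("empty head selection")
  if (!length(traj$frames)) stop("trajectory has no stored frames")
  sel <- window_index(traj, window)
  sel <- sel[sel <= length(traj$frames)]
  m <- ff$bead_types$mass[match(traj$types[head_selection],
                                ff$bead_types$name)]
  z0 <- traj$frames[[sel[1]]]$pos[head_selection, 3]
  upper <- z0 > sum(z0 * m) / sum(m)
  if (!any(upper) || all(upper))
    stop("leaflet assignment failed: all head beads on one side")
  d <- vapply(sel, function(s) {
    z <- traj$frames[[s]]$pos[head_selection, 3]
    abs(sum(z[upper] * m[upper]) / sum(m[upper]) -
        sum(z[!upper] * m[!upper]) / sum(m[!upper]))
  }, numeric(1))
  err <- if (length(d) >= n_blocks) block_error(d, n_blocks) else 0
  obs_result(mean(d), err, traj, sel, n_blocks)
}

#' Acyl-chain bond order parameters
#'
#' For each bond position along the chains,
#' \eqn{S = \frac{1}{2}(3\langle(\hat b\cdot\hat n)^2\rangle - 1)} with
#' \eqn{\hat b} the unit bond vector between adjacent CG beads and
#' \eqn{\hat n} the bilayer normal; averaged over lipids and frames.
#' \eqn{S \in [-0.5, 1]}: 1 for bonds parallel to the normal, -0.5
#' perpendicular, 0 isotropic.
#'
#' @param traj a `cg_trajectory` with stored frames, or `NULL` when
#'   `bond_vectors` is given directly
#' @param chains list of per-lipid bead index vectors (consecutive beads
#'   along the chain)
#' @param normal normal axis (default `"z"`)
#' @inheritParams mass_density
#' @param bond_vectors optional n x 3 matrix of raw bond vectors; when
#'   supplied the estimator is applied to it directly (one S value)
#' @return named vector of S per bond position, or a single S for raw
#'   vectors; zero-length bonds are dropped with a warning
#' @export
order_parameters <- function(traj = NULL, chains = NULL, normal = "z",
                             window = 0.25, bond_vectors = NULL) {
  nax <- match(normal, c("x", "y", "z"))
  S_of <- function(bv) {
    len <- sqrt(rowSums(bv^2))
    bad <- len < 1e-12
    if (any(bad)) {
      warning(sum(bad), " zero-length bond vector(s) excluded")
      bv <- bv[!bad, , drop = FALSE]; len <- len[!bad]
    }
    cth2 <- (bv[, nax] / len)^2
    0.5 * (3 * mean(cth2) - 1)
  }
  if (!is.null(bond_vectors)) return(S_of(as.matrix(bond_vectors)))
  if (!length(traj$frames)) stop("trajectory has no stored frames")
  sel <- window_index(traj, window)
  sel <- sel[sel <= length(traj$frames)]
  nbond <- length(chains[[1]]) - 1
  out <- numeric(nbond)
  for (b in seq_len(nbond)) {
    bv <- do.call(rbind, lapply(sel, function(s) {
      p <- traj$frames[[s]]$pos
      t(vapply(chains, function(ch) p[ch[b + 1], ] - p[ch[b], ],
               numeric(3)))
    }))
    out[b] <- S_of(bv)
  }
  names(out) <- paste0("bond", seq_len(nbond))
  out
}

#' Density profile along an axis
#'
#' Per-frame histogram of selected beads along a box axis, normalized by
#' bin volume and frame count (number density in beads/A^3, or mass
#' density in kg/m^3 when `ff` is supplied).
#'
#' @param traj a `cg_trajectory` with stored frames
#' @param axis `"x"`, `"y"` or `"z"`
#' @param selection bead indices to include (default all)
#' @param bin_width bin width, A (> 0)
#' @param ff optional force field: weight beads by mass and report
#'   kg/m^3
#' @inheritParams mass_density
#' @return data frame with `coord` (bin centers, A) and `density`
#' @export
density_profile <- function(traj, axis = "z", selection = NULL,
                            bin_width = 2, ff = NULL, window = 0.25) {
  stopifnot(bin_width > 0)
  if (!length(traj$frames)) stop("trajectory has no stored frames")
  nax <- match(axis, c("x", "y", "z"))
  sel <- window_index(traj, window)
  sel <- sel[sel <= length(traj$frames)]
  L <- traj$box[sel[1], nax]
  nbin <- max(1, round(L / bin_width))
  edges <- seq(0, L, length.out = nbin + 1)
  counts <- numeric(nbin)
  if (is.null(selection)) selection <- seq_along(traj$types)
  w <- if (is.null(ff)) rep(1, length(selection))
       else ff$bead_types$mass[match(traj$types[selection],
                                     ff$bead_types$name)]
  vol_bin <- 0
  for (s in sel) {
    fr <- traj$frames[[s]]
    x <- fr$pos[selection, nax] %% fr$box[nax]
    bin <- pmin(nbin, pmax(1L, ceiling(x / fr$box[nax] * nbin)))
    counts <- counts + as.numeric(tapply(w, factor(bin, levels = seq_len(nbin)),
                                         sum, default = 0))
    vol_bin <- vol_bin + prod(fr$box) / nbin
  }
  dens <- counts / vol_bin
  if (!is.null(ff)) dens <- dens * cg_units$kgm3_per_amu_A3
  data.frame(coord = (edges[-1] + edges[-(nbin + 1)]) / 2,
             density = as.numeric(dens))
}
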