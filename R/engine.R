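#' Define a semipermeable virtual wall
#'
#' A one-sided repulsive plane acting only on selected bead types (the
#' ions), emulating a semipermeable membrane. With the default
#' `indent_quadratic` law a bead that has penetrated by \eqn{\Delta x}
#' feels a restoring force of magnitude \eqn{k \Delta x^2} (force constant
#' in kcal/mol/A^3, the indenter convention); the alternative
#' `half_harmonic_linear` law uses \eqn{k \Delta x} (k in kcal/mol/A^2).
#' Water is never listed in `affected`, so it crosses freely.
#'
#' @param axis `"x"`, `"y"` or `"z"`
#' @param position coordinate of the wall plane, A
#' @param side `"+"`: beads with coordinate above the plane are pushed
#'   back; `"-"`: beads below are pushed back
#' @param k force constant (default 20 kcal/mol/A^3)
#' @param affected character vector of bead types the wall acts on
#' @param force_law `"indent_quadratic"` or `"half_harmonic_linear"`
#' @return object of class `cg_wall`
#' @export
wall_spec <- function(axis = c("x", "y", "z"), position, side = c("+", "-"),
                      k = 20, affected,
                      force_law = c("indent_quadratic",
                                    "half_harmonic_linear")) {
  axis <- match.arg(axis); side <- match.arg(side)
  force_law <- match.arg(force_law)
  stopifnot(k >= 0, length(affected) >= 1)
  structure(list(axis = axis, position = position, side = side, k = k,
                 affected = affected, force_law = force_law),
            class = "cg_wall")
}

# internal: pack wall list for C++
walls_pack <- function(walls, type_names) {
  if (!length(walls)) return(list())
  nw <- length(walls)
  params <- matrix(0, nw, 5)
  aff <- matrix(0L, length(type_names), nw)
  for (w in seq_len(nw)) {
    wl <- walls[[w]]
    params[w, ] <- c(match(wl$axis, c("x", "y", "z")) - 1,
                     wl$position,
                     if (wl$side == "+") 1 else -1,
                     wl$k,
                     if (wl$force_law == "indent_quadratic") 1 else 2)
    aff[type_names %in% wl$affected, w] <- 1L
  }
  list(params = params, affected = aff)
}

#' Instantaneous force exerted on a virtual wall
#'
#' Sums \eqn{k \Delta x^2} (or \eqn{k \Delta x} for the linear law) over
#' every affected bead that has crossed the wall plane. Non-penetrating
#' beads contribute zero.
#'
#' @param sys a `cg_system`
#' @param wall a [wall_spec()]
#' @return total force in kcal/mol/A
#' @export
wall_force <- function(sys, wall) {
  ax <- match(wall$axis, c("x", "y", "z"))
  sel <- sys$types %in% wall$affected
  d <- (sys$pos[sel, ax] - wall$position) *
    (if (wall$side == "+") 1 else -1)
  d <- d[d > 0]
  if (!length(d)) return(0)
  if (wall$force_law == "indent_quadratic") sum(wall$k * d^2)
  else sum(wall$k * d)
}

#' Specify an ensemble for the integrator
#'
#' Velocity-Verlet propagation; temperature control by a Nose-Hoover
#' chain (length 3), pressure control by an MTK-style Nose-Hoover
#' barostat. `NPzAT` holds the lateral box fixed and couples only the
#' normal (z) axis to the barostat; `NPT` with `npt_mode = "xy_z"`
#' couples x and y together and z separately (the bilayer
#' semi-isotropic convention).
#'
#' @param kind `"NVE"`, `"NVT"`, `"NPT"` or `"NPzAT"`
#' @param temperature K (thermostatted kinds)
#' @param pressure bar
#' @param dt time step, fs (default 10, the CG production value; validation
#'   runs use 1-5 fs)
#' @param tau_t thermostat time constant, fs (default `100 * dt`)
#' @param tau_p barostat time constant, fs (default `1000 * dt`)
#' @param npt_mode `"iso"` or `"xy_z"` (ignored unless `kind = "NPT"`)
#' @return object of class `cg_ensemble`
#' @export
ensemble_spec <- function(kind = c("NVT", "NVE", "NPT", "NPzAT"),
                          temperature = 298, pressure = 1, dt = 10,
                          tau_t = 100 * dt, tau_p = 1000 * dt,
                          npt_mode = c("iso", "xy_z")) {
  kind <- match.arg(kind)
  npt_mode <- match.arg(npt_mode)
  stopifnot(dt > 0)
  if (kind != "NVE") stopifnot(temperature > 0)
  ckind <- if (kind == "NPzAT") "NPT" else kind
  cmode <- if (kind == "NPzAT") "z" else npt_mode
  structure(list(kind = kind, temperature = temperature, pressure = pressure,
                 dt = dt, tau_t = tau_t, tau_p = tau_p,
                 cpp = list(kind = ckind, temperature = temperature,
                            pressure = pressure, dt = dt, tau_t = tau_t,
                            tau_p = tau_p, npt_mode = cmode)),
            class = "cg_ensemble")
}

#' Evaluate forces, energy and virial for one configuration
#'
#' Nonbonded LJ with the table's per-pair form and 15 A-style cutoff,
#' electrostatics per the table's method (Ewald real + reciprocal space,
#' or shifted cutoff), harmonic bonds/angles, and virtual walls. Without
#' walls the forces sum to zero (Newton's third law). Wall contributions
#' are reported separately per wall and excluded from the internal virial.
#'
#' @param sys a `cg_system`
#' @param ff a `cg_forcefield`
#' @param walls list of [wall_spec()] objects
#' @param use_nlist evaluate through a Verlet neighbor list (identical
#'   result to the direct double loop)
#' @param skin neighbor-list skin, A
#' @return list with `forces` (N x 3, kcal/mol/A), `energy` (component
#'   breakdown, kcal/mol), `virial` (named 6-vector xx yy zz xy xz yz,
#'   kcal/mol) and `wall_forces` (per wall, kcal/mol/A)
#' @export
compute_forces <- function(sys, ff, walls = list(), use_nlist = FALSE,
                           skin = 2) {
  ti <- system_type_index(sys)
  rep <- validate_table(ff, ti$names)
  # missing pairs are allowed through when the LB fallback is on
  # (ff_pack warns per completed pair); everything else is fatal
  if (isTRUE(ff$options$mixing_fallback))
    rep <- rep[rep$finding != "missing_pair", , drop = FALSE]
  if (nrow(rep))
    stop("force-field table incomplete for composition: ",
         paste(rep$finding, rep$detail, collapse = "; "))
  packed <- ff_pack(ff, ti$names)
  topo <- resolve_topology(sys, ff)
  wl <- walls_pack(walls, ti$names)
  out <- cpp_compute_forces(sys$pos, sys$box, ti$idx0, packed, topo, wl,
                            use_nlist, skin)
  names(out$virial) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  out
}

#' Instantaneous pressure tensor of a configuration
#'
#' \eqn{P_{ab} = (\sum_i m_i v_{ia} v_{ib} + W_{ab}) / V} converted to
#' bar, with \eqn{W} the pair virial. The kinetic part uses the
#' instantaneous velocities; the trace/3 equals the scalar pressure.
#'
#' @param sys a `cg_system` with velocities
#' @param ff a `cg_forcefield`
#' @param virial named 6-vector from [compute_forces()] (kcal/mol); if
#'   missing it is computed
#' @return named 6-vector (`xx yy zz xy xz yz`) in bar
#' @export
pressure_tensor <- function(sys, ff, virial = NULL) {
  V <- prod(sys$box)
  if (V <= 0) stop("zero or negative box volume")
  if (is.null(virial)) virial <- compute_forces(sys, ff)$virial
  m <- ff$bead_types$mass[match(sys$types, ff$bead_types$name)]
  v <- sys$vel
  if (is.null(v)) v <- matrix(0, n_beads(sys), 3)
  kin <- c(sum(m * v[, 1]^2), sum(m * v[, 2]^2), sum(m * v[, 3]^2),
           sum(m * v[, 1] * v[, 2]), sum(m * v[, 1] * v[, 3]),
           sum(m * v[, 2] * v[, 3])) * cg_units$kcal_per_mvv
  p <- (kin + virial) / V * cg_units$bar_per_kcal_A3
  names(p) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  p
}

#' Kinetic temperature of a configuration
#'
#' @inheritParams pressure_tensor
#' @param remove_com degrees of freedom reduced by 3 for the fixed
#'   center of mass
#' @return temperature in K
#' @export
kinetic_temperature <- function(sys, ff, remove_com = TRUE) {
  m <- ff$bead_types$mass[match(sys$types, ff$bead_types$name)]
  ke2 <- sum(m * sys$vel^2) * cg_units$kcal_per_mvv
  Nf <- 3 * n_beads(sys) - if (remove_com) 3 else 0
  ke2 / (Nf * cg_units$kB)
}

#' Propagate a system through time
#'
#' Runs `n_steps` of velocity-Verlet dynamics in the requested ensemble
#' and samples scalar channels (energies, temperature, pressure tensor,
#' box, per-wall forces) every `sample_every` steps; optionally stores
#' full frames. Trajectories are bitwise reproducible for identical
#' inputs: all stochasticity lives in the initial velocities
#' ([init_velocities()] seed).
#'
#' @param sys a `cg_system`; velocities drawn at the ensemble temperature
#'   with `seed` if unset
#' @param ff a `cg_forcefield`
#' @param ensemble an [ensemble_spec()]
#' @param walls list of [wall_spec()]
#' @param n_steps number of integration steps (>= 1)
#' @param sample_every sampling stride in steps
#' @param seed seed used only if `sys$vel` is `NULL`
#' @param store_frames keep full frames (positions/velocities) at sample
#'   times
#' @param use_nlist use the Verlet neighbor list
#' @param skin neighbor-list skin, A
#' @return object of class `cg_trajectory`: scalar channels aligned with
#'   sample times, optional `frames`, and `final` system
#' @export
run_md <- function(sys, ff, ensemble, walls = list(), n_steps,
                   sample_every = 10, seed = 1, store_frames = FALSE,
                   use_nlist = TRUE, skin = 2) {
  stopifnot(inherits(ensemble, "cg_ensemble"), n_steps >= 0)
  if (is.null(sys$vel))
    sys <- init_velocities(sys, ff,
                           max(ensemble$temperature, 1), seed)
  ti <- system_type_index(sys)
  packed <- ff_pack(ff, ti$names)
  topo <- resolve_topology(sys, ff)
  wl <- walls_pack(walls, ti$names)
  mass_by_type <- ff$bead_types$mass[match(ti$names, ff$bead_types$name)]
  out <- cpp_run(sys$pos, sys$vel, sys$box, ti$idx0, mass_by_type, packed,
                 topo, wl, ensemble$cpp, as.integer(n_steps),
                 as.integer(sample_every), store_frames, use_nlist, skin)
  colnames(out$pressure) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  colnames(out$box) <- c("Lx", "Ly", "Lz")
  final <- sys
  final$pos <- out$final$pos
  final$vel <- out$final$vel
  final$box <- out$final$box
  final$time <- sys$time + n_steps * ensemble$dt
  structure(list(
    time = sys$time + out$time,
    pe = out$pe, ke = out$ke, temperature = out$temperature,
    volume = out$volume, pressure = out$pressure, box = out$box,
    wall_forces = out$wall_forces, frames = out$frames,
    sample_interval = sample_every * ensemble$dt,
    walls = walls, ensemble = ensemble, types = sys$types,
    final = final), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory>", length(x$time), "samples over",
      signif(diff(range(x$time)) / 1000, 4), "ps;",
      length(x$frames), "stored frames\n")
  cat("  ensemble:", x$ensemble$kind, "at", x$ensemble$temperature, "K\n")
  invisible(x)
}

#' Advance a system by a single integration step
#'
#' @inheritParams run_md
#' @return the updated `cg_system`
#' @export
step_md <- function(sys, ff, ensemble, walls = list(), seed = 1) {
  run_md(sys, ff, ensemble, walls, n_steps = 1, sample_every = 1,
         seed = seed, store_frames = FALSE)$final
}

#' Relax a configuration by capped steepest descent
#'
#' Removes packing overlaps before dynamics. Displacements per iteration
#' are capped (default 0.3 A) and the cap halves whenever the energy
#' rises.
#'
#' @inheritParams run_md
#' @param n_steps maximum descent iterations
#' @param max_disp displacement cap per iteration, A
#' @return the relaxed `cg_system`
#' @export
minimize_system <- function(sys, ff, walls = list(), n_steps = 200,
                            max_disp = 0.3) {
  ti <- system_type_index(sys)
  packed <- ff_pack(ff, ti$names)
  topo <- resolve_topology(sys, ff)
  wl <- walls_pack(walls, ti$names)
  out <- cpp_minimize(sys$pos, sys$box, ti$idx0, packed, topo, wl,
                      as.integer(n_steps), max_disp)
  sys$pos <- out$pos
  sys
}
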