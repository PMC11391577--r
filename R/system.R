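#' Construct a CG system (a frame plus topology)
#'
#' Positions live in an orthorhombic box with origin 0 and half-open
#' `[0, L)` wrapping. Bead species are carried as type names resolved
#' against a force-field table at evaluation time. Bonds and angles
#' reference bead indices; their parameters are looked up from the table
#' by bead-type pattern.
#'
#' @param positions N x 3 matrix, A
#' @param box length-3 vector `(Lx, Ly, Lz)`, A (> 0)
#' @param types character vector of bead type names, length N
#' @param velocities N x 3 matrix in A/fs, or `NULL` (assign later with
#'   [init_velocities()])
#' @param bonds integer matrix with columns `i, j` (1-based), or `NULL`
#' @param angles integer matrix with columns `i, j, k`, or `NULL`
#' @param geometry tag: `"bulk"`, `"slab"`, `"biphasic"`, `"osmotic"`,
#'   `"bilayer"` or `"other"`
#' @param meta free-form metadata list (composition, leaflet assignment, ...)
#' @return object of class `cg_system`
#' @export
cg_system <- function(positions, box, types, velocities = NULL,
                      bonds = NULL, angles = NULL, geometry = "other",
                      meta = list()) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0),
            length(types) == nrow(positions))
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(all(dim(velocities) == dim(positions)))
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    stopifnot(all(bonds >= 1), all(bonds <= nrow(positions)))
  }
  if (!is.null(angles)) {
    angles <- matrix(as.integer(angles), ncol = 3)
    stopifnot(all(angles >= 1), all(angles <= nrow(positions)))
  }
  structure(list(pos = positions, vel = velocities, box = as.numeric(box),
                 types = as.character(types), bonds = bonds, angles = angles,
                 time = 0, geometry = geometry, meta = meta),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system>", nrow(x$pos), "beads in box",
      paste(signif(x$box, 5), collapse = " x "), "A;",
      "geometry:", x$geometry, "\n")
  tb <- table(x$types)
  cat("  composition:", paste(names(tb), as.integer(tb), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of beads in a system
#' @param sys a `cg_system`
#' @return integer count
#' @export
n_beads <- function(sys) nrow(sys$pos)

#' Net charge of a system under a force-field table
#' @param sys a `cg_system`
#' @param ff a `cg_forcefield`
#' @return total charge in e
#' @export
net_charge <- function(sys, ff) {
  q <- ff$bead_types$charge[match(sys$types, ff$bead_types$name)]
  sum(q)
}

#' Total mass of a system
#' @inheritParams net_charge
#' @return mass in amu
#' @export
total_mass <- function(sys, ff) {
  m <- ff$bead_types$mass[match(sys$types, ff$bead_types$name)]
  sum(m)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns velocities at the requested temperature and removes the
#' center-of-mass drift, then rescales to hit the kinetic temperature
#' exactly (with `Nf = 3N - 3`).
#'
#' @param sys a `cg_system`
#' @param ff a `cg_forcefield` (for masses)
#' @param temperature K
#' @param seed integer RNG seed
#' @return the system with `vel` set
#' @export
init_velocities <- function(sys, ff, temperature, seed = 1) {
  set.seed(seed)
  N <- n_beads(sys)
  m <- ff$bead_types$mass[match(sys$types, ff$bead_types$name)]
  kT <- cg_units$kB * temperature / cg_units$kcal_per_mvv
  v <- matrix(rnorm(3 * N), N, 3) * sqrt(kT / m)
  # remove COM momentum
  p <- colSums(v * m)
  v <- sweep(v, 2, p / sum(m))
  ke2 <- sum(m * v^2)
  Nf <- 3 * N - 3
  v <- v * sqrt(Nf * kT / ke2)
  sys$vel <- v
  sys
}

# --- internal: pack topology for C++ (0-based indices, radians) ------------
resolve_topology <- function(sys, ff) {
  if (is.null(sys$bonds) && is.null(sys$angles)) return(list())
  bonds <- if (is.null(sys$bonds)) matrix(integer(), 0, 2) else sys$bonds
  angles <- if (is.null(sys$angles)) matrix(integer(), 0, 3) else sys$angles
  nb <- nrow(bonds); na <- nrow(angles)
  bond_k <- bond_r0 <- numeric(nb)
  if (nb) {
    bkey <- pair_key(ff$bonds$type_i, ff$bonds$type_j)
    for (e in seq_len(nb)) {
      ti <- sys$types[bonds[e, 1]]; tj <- sys$types[bonds[e, 2]]
      hit <- which(bkey == pair_key(ti, tj))
      if (!length(hit)) stop("no bond parameters for ", ti, "-", tj)
      bond_k[e] <- ff$bonds$k[hit[1]]; bond_r0[e] <- ff$bonds$r0[hit[1]]
    }
  }
  ang_k <- ang_th <- numeric(na); ang_corr <- integer(na)
  if (na) {
    akey <- paste(ff$angles$type_i, ff$angles$type_j, ff$angles$type_k)
    akey_rev <- paste(ff$angles$type_k, ff$angles$type_j, ff$angles$type_i)
    for (e in seq_len(na)) {
      key <- paste(sys$types[angles[e, 1]], sys$types[angles[e, 2]],
                   sys$types[angles[e, 3]])
      hit <- which(akey == key | akey_rev == key)
      if (!length(hit)) stop("no angle parameters for ", key)
      ang_k[e] <- ff$angles$k[hit[1]]
      ang_th[e] <- ff$angles$theta0[hit[1]] * pi / 180
      ang_corr[e] <- as.integer(isTRUE(ff$angles$corr[hit[1]]))
    }
  }
  list(bonds = bonds - 1L, bond_k = bond_k, bond_r0 = bond_r0,
       angles = angles - 1L, angle_k = ang_k, angle_theta0 = ang_th,
       angle_corr = ang_corr)
}

# type bookkeeping shared by engine entry points
system_type_index <- function(sys) {
  tn <- sort(unique(sys$types))
  list(names = tn, idx0 = match(sys$types, tn) - 1L)
}
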