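#' Seeded rejection packing of beads into a periodic box
#'
#' Places the requested numbers of beads uniformly at random subject to a
#' minimum periodic pair distance, with bounded retries (PACKMOL-style
#' initial configurations without the external binary). Deterministic for
#' a fixed seed.
#'
#' @param counts named integer vector: beads per type, e.g.
#'   `c(W = 300, SOD = 10, CLA = 10)`
#' @param box length-3 box vector, A
#' @param min_dist minimum allowed periodic pair distance, A
#' @param seed RNG seed
#' @param max_tries candidate draws per bead before the packing is
#'   declared infeasible
#' @param region optional 3 x 2 matrix of `(lo, hi)` bounds restricting
#'   placement to a sub-box (used for compartment construction)
#' @return a `cg_system` (bulk geometry, no velocities)
#' @export
pack_random <- function(counts, box, min_dist = 3.5, seed = 1,
                        max_tries = 2000, region = NULL) {
  stopifnot(all(counts >= 0), min_dist >= 0)
  N <- sum(counts)
  lo <- c(0, 0, 0); hi <- box
  if (!is.null(region)) { lo <- region[, 1]; hi <- region[, 2] }
  # feasibility heuristic: random packings reach ~half of close packing
  vol_sphere <- 4 / 3 * pi * (min_dist / 2)^3
  if (N * vol_sphere > 0.55 * prod(hi - lo))
    stop("requested density infeasible for min_dist = ", min_dist,
         " A; use a larger box")
  set.seed(seed)
  pos <- matrix(0, N, 3)
  n_placed <- 0L
  for (b in seq_len(N)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- lo + runif(3) * (hi - lo)
      if (cpp_candidate_ok(pos, n_placed, cand, box, min_dist)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("packing failed after ", max_tries, " tries at bead ", b,
           " of ", N, "; suggest a larger box or smaller min_dist")
    pos[b, ] <- cand
    n_placed <- n_placed + 1L
  }
  types <- rep(names(counts), counts)
  # interleave so ions are scattered through the list (cosmetic only)
  ord <- sample.int(N)
  cg_system(pos[ord, , drop = FALSE], box, types[ord], geometry = "bulk")
}

#' Ion and water bead counts for a target molarity
#'
#' The ion pair count is `round(molarity * N_A * V)`; the water bead
#' count fills the rest of the box with 3-water beads at the reference
#' water concentration, debiting the water molecules already grouped
#' into solvated ion beads.
#'
#' @param molarity salt concentration, mol/L (>= 0)
#' @param volume_A3 box volume in A^3
#' @param waters_per_ion water molecules per solvated ion bead (0 for
#'   bare ions)
#' @param water_molarity reference molar concentration of pure water
#'   (default 55.34 mol/L, liquid water near room temperature)
#' @return list with `n_water`, `n_cation`, `n_anion` (bead counts)
#' @export
counts_for_molarity <- function(molarity, volume_A3, waters_per_ion = 0,
                                water_molarity = 55.34) {
  stopifnot(molarity >= 0, volume_A3 > 0)
  v_L <- volume_A3 * 1e-27
  n_ion <- round(molarity * cg_units$avogadro * v_L)
  n_water_molec <- round(water_molarity * cg_units$avogadro * v_L)
  n_water_molec <- n_water_molec - 2 * n_ion * waters_per_ion
  n_water <- floor(n_water_molec / 3)
  if (n_water < 0)
    stop("molarity ", molarity, " M leaves no room for water beads")
  list(n_water = as.integer(n_water), n_cation = as.integer(n_ion),
       n_anion = as.integer(n_ion))
}

# cap the packing distance so the sphere packing fraction stays below
# ~0.25, where seeded rejection packing converges quickly; relevant for
# bare-ion systems at high molarity, where ions add to the bead count
adapt_min_dist <- function(min_dist, n, volume) {
  md_max <- (0.477 * volume / max(n, 1))^(1 / 3)
  min(min_dist, md_max)
}

#' Build a bulk electrolyte box
#'
#' Packs water and ion beads for the requested molarity. The default box
#' edge is chosen so the total bead count lands in the 1000-1200 range
#' used for bulk property runs; it shrinks automatically for lower
#' `total_beads`.
#'
#' @param molarity mol/L
#' @param ff force field (supplies `waters_included` metadata)
#' @param total_beads approximate bead budget (the box is sized so that
#'   water + ions come out near this number)
#' @param min_dist packing distance, A
#' @param seed RNG seed
#' @return a `cg_system` with `meta$molarity` set
#' @export
make_bulk <- function(molarity, ff, total_beads = 1100, min_dist = 3.4,
                      seed = 1) {
  wpi <- ff$bead_types$waters_included[ff$bead_types$name == "SOD"]
  # beads per A^3 of water-like liquid: 55.34 M / 3 waters per bead
  rho_bead <- 55.34 / 3 * cg_units$avogadro * 1e-27
  # ions add beads (bare) or replace waters (solvated); size on water alone
  L <- (total_beads / rho_bead)^(1 / 3)
  cnt <- counts_for_molarity(molarity, L^3, wpi)
  md <- adapt_min_dist(min_dist, cnt$n_water + 2 * cnt$n_cation, L^3)
  sys <- pack_random(c(W = cnt$n_water, SOD = cnt$n_cation,
                       CLA = cnt$n_anion), rep(L, 3), md, seed)
  sys$meta$molarity <- molarity
  sys
}

#' Elongate a bulk frame into a slab geometry
#'
#' Triples the box in z and centers the liquid, leaving vacuum above and
#' below, the standard starting point for Kirkwood-Irving surface-tension
#' runs. Coordinates are only translated, never rescaled.
#'
#' @param sys a bulk `cg_system`
#' @return a `cg_system` with `geometry = "slab"`
#' @export
make_slab <- function(sys) {
  Lz <- sys$box[3]
  sys$pos[, 3] <- sys$pos[, 3] + Lz
  sys$box[3] <- 3 * Lz
  sys$geometry <- "slab"
  sys
}

#' Build a three-compartment osmotic cell
#'
#' A concentrated electrolyte compartment is flanked along x by ion-free
#' water pads, and two one-sided virtual walls at the compartment
#' boundaries act on the ions only: the semipermeable-membrane setup for
#' osmotic-pressure runs. Water crosses freely.
#'
#' @param molarity salt concentration of the central compartment, mol/L
#'   (> 0)
#' @param ff force field
#' @param total_beads bead budget of the central compartment
#' @param pad_x width of each pure-water pad along x, A (default twice
#'   the cutoff)
#' @param wall_k wall force constant (kcal/mol/A^3 for the default
#'   quadratic law)
#' @param min_dist packing distance, A
#' @param seed RNG seed
#' @param ideal_solute build ions only (no water), for ideal-gas
#'   validation against the van 't Hoff law
#' @return list with `system` (a `cg_system`, geometry `"osmotic"`) and
#'   `walls` (list of two [wall_spec()])
#' @export
make_osmotic <- function(molarity, ff, total_beads = 600, pad_x = 30,
                         wall_k = 20, min_dist = 3.4, seed = 1,
                         ideal_solute = FALSE) {
  stopifnot(molarity > 0)
  wpi <- ff$bead_types$waters_included[ff$bead_types$name == "SOD"]
  rho_bead <- 55.34 / 3 * cg_units$avogadro * 1e-27
  L <- (total_beads / rho_bead)^(1 / 3)
  cnt <- counts_for_molarity(molarity, L^3, wpi)
  box <- c(L + 2 * pad_x, L, L)
  counts_centre <- c(SOD = cnt$n_cation, CLA = cnt$n_anion)
  if (!ideal_solute) counts_centre <- c(W = cnt$n_water, counts_centre)
  md <- adapt_min_dist(min_dist, sum(counts_centre), L^3)
  centre <- pack_random(counts_centre, box, md, seed,
                        region = cbind(c(pad_x, 0, 0), c(pad_x + L, L, L)))
  sys <- centre
  if (!ideal_solute) {
    n_pad <- counts_for_molarity(0, pad_x * L * L, 0)$n_water
    left <- pack_random(c(W = n_pad), box, min_dist, seed + 1,
                        region = cbind(c(0, 0, 0), c(pad_x, L, L)))
    right <- pack_random(c(W = n_pad), box, min_dist, seed + 2,
                         region = cbind(c(pad_x + L, 0, 0),
                                        c(box[1], L, L)))
    sys <- cg_system(rbind(centre$pos, left$pos, right$pos), box,
                     c(centre$types, left$types, right$types))
  }
  sys$geometry <- "osmotic"
  sys$meta$molarity <- molarity
  sys$meta$compartment <- c(pad_x, pad_x + L)
  walls <- list(
    wall_spec("x", pad_x, "-", k = wall_k, affected = c("SOD", "CLA")),
    wall_spec("x", pad_x + L, "+", k = wall_k, affected = c("SOD", "CLA")))
  list(system = sys, walls = walls)
}

#' Build a biphasic oil/water system
#'
#' Stacks an oil phase (3-bead `CT`-`CM`-`CT` decane-like chains, or
#' longer `triolein_like` chains) under an aqueous electrolyte phase
#' along z, for interfacial-tension runs in the NPzAT ensemble.
#' Desk-scale defaults are roughly a tenth of the production counts;
#' pass `full_scale = TRUE` for the production-sized system.
#'
#' @param oil `"decane_like"` or `"triolein_like"`
#' @param n_oil number of oil molecules (default 100 desk-scale)
#' @param n_aqueous approximate aqueous bead count (default 500)
#' @param molarity salt concentration of the aqueous phase, mol/L
#' @param ff force field
#' @param min_dist packing distance, A
#' @param seed RNG seed
#' @param full_scale use production counts (1000 decane or 400 triolein
#'   chains, 5000 aqueous beads)
#' @return a `cg_system` with `geometry = "biphasic"`
#' @export
make_biphasic <- function(oil = c("decane_like", "triolein_like"),
                          n_oil = 100, n_aqueous = 500, molarity = 0,
                          ff = default_forcefield(), min_dist = 3.4,
                          seed = 1, full_scale = FALSE) {
  oil <- match.arg(oil)
  if (full_scale) {
    n_oil <- if (oil == "decane_like") 1000 else 400
    n_aqueous <- 5000
  }
  stopifnot(n_oil >= 1, n_aqueous >= 1)
  chain_types <- if (oil == "decane_like") c("CT", "CM", "CT")
                 else c("CT", "CM", "CM", "CM", "CM", "CT")
  nb_chain <- length(chain_types)
  # lateral box from the aqueous phase at water-like density
  rho_bead <- 55.34 / 3 * cg_units$avogadro * 1e-27
  Lxy <- (n_aqueous / rho_bead)^(1 / 3)
  h_aq <- Lxy
  # oil bead density a bit lower than water's
  h_oil <- n_oil * nb_chain / (0.75 * rho_bead) / Lxy^2
  box <- c(Lxy, Lxy, h_oil + h_aq)
  set.seed(seed)
  # place oil chains as straight rods in the lower slab
  pos <- NULL; types <- NULL; bonds <- NULL; angles <- NULL
  spacing <- 3.4
  for (m in seq_len(n_oil)) {
    repeat {
      origin <- c(runif(2) * Lxy,
                  runif(1) * max(h_oil - nb_chain * spacing, 1))
      dir <- c(0, 0, 1)
      chain <- t(sapply(seq_len(nb_chain) - 1,
                        function(k) origin + k * spacing * dir))
      if (is.null(pos)) break
      ok <- TRUE
      for (b in seq_len(nb_chain))
        if (!cpp_candidate_ok(pos, nrow(pos), chain[b, ], box,
                              min_dist * 0.8)) { ok <- FALSE; break }
      if (ok) break
    }
    i0 <- if (is.null(pos)) 0L else nrow(pos)
    pos <- rbind(pos, chain)
    types <- c(types, chain_types)
    bonds <- rbind(bonds, cbind(i0 + seq_len(nb_chain - 1),
                                i0 + seq_len(nb_chain - 1) + 1))
    if (nb_chain >= 3)
      angles <- rbind(angles, cbind(i0 + seq_len(nb_chain - 2),
                                    i0 + seq_len(nb_chain - 2) + 1,
                                    i0 + seq_len(nb_chain - 2) + 2))
  }
  wpi <- ff$bead_types$waters_included[ff$bead_types$name == "SOD"]
  cnt <- counts_for_molarity(molarity, Lxy^2 * h_aq, wpi)
  md <- adapt_min_dist(min_dist, cnt$n_water + 2 * cnt$n_cation,
                       Lxy^2 * h_aq)
  aq <- pack_random(c(W = cnt$n_water, SOD = cnt$n_cation,
                      CLA = cnt$n_anion), box, md, seed + 7,
                    region = cbind(c(0, 0, h_oil), c(Lxy, Lxy, box[3])))
  sys <- cg_system(rbind(pos, aq$pos), box, c(types, aq$types),
                   bonds = bonds, angles = angles, geometry = "biphasic",
                   meta = list(molarity = molarity, oil = oil,
                               h_oil = h_oil))
  sys
}

#' Build a toy amphiphile bilayer
#'
#' Two leaflets of 4-bead amphiphiles (`NC`(+1) - `PH`(-1) - `TL` - `TL`)
#' on a lateral grid, tails inward, solvated with water and ions above
#' and below. Head beads are tagged for APL / headgroup-distance / order
#' parameter selection via `meta`.
#'
#' @param n_lipids_per_leaflet lipids per leaflet (>= 4; production-style
#'   systems use 128)
#' @param molarity salt concentration of the aqueous phase, mol/L
#' @param ff force field
#' @param apl_init initial area per lipid for the lateral grid, A^2
#' @param water_pad aqueous slab height on each side, A
#' @param min_dist packing distance for the solvent, A
#' @param seed RNG seed
#' @return a `cg_system` with `geometry = "bilayer"`; `meta$chains` lists
#'   the bead indices of each lipid (head to tail), `meta$leaflet` is
#'   +1/-1 per lipid
#' @export
make_toy_bilayer <- function(n_lipids_per_leaflet, molarity = 0,
                             ff = default_forcefield(), apl_init = 55,
                             water_pad = 25, min_dist = 3.4, seed = 1) {
  stopifnot(n_lipids_per_leaflet >= 4)
  nl <- n_lipids_per_leaflet
  grid <- ceiling(sqrt(nl))
  a <- sqrt(apl_init)
  Lxy <- grid * a
  chain_types <- c("NC", "PH", "TL", "TL")
  nb <- length(chain_types)
  spacing <- 3.4
  half_h <- nb * spacing            # leaflet thickness
  Lz <- 2 * half_h + 2 * water_pad
  z_mid <- Lz / 2
  pos <- NULL; types <- NULL; bonds <- NULL; angles <- NULL
  chains <- list(); leaflet <- integer()
  set.seed(seed)
  idx <- 0L
  for (side in c(+1, -1)) {
    placed <- 0L
    for (gx in seq_len(grid)) for (gy in seq_len(grid)) {
      if (placed >= nl) next
      placed <- placed + 1L
      xy <- c((gx - 0.5) * a, (gy - 0.5) * a) +
        (runif(2) - 0.5) * 0.3 * a
      # head outermost, tails toward the midplane
      z <- z_mid + side * (half_h - (seq_len(nb) - 1) * spacing)
      chain <- cbind(xy[1], xy[2], z)
      i0 <- idx
      pos <- rbind(pos, chain)
      types <- c(types, chain_types)
      bonds <- rbind(bonds, cbind(i0 + seq_len(nb - 1),
                                  i0 + seq_len(nb - 1) + 1))
      angles <- rbind(angles, cbind(i0 + seq_len(nb - 2),
                                    i0 + seq_len(nb - 2) + 1,
                                    i0 + seq_len(nb - 2) + 2))
      chains[[length(chains) + 1]] <- i0 + seq_len(nb)
      leaflet <- c(leaflet, side)
      idx <- idx + nb
    }
  }
  box <- c(Lxy, Lxy, Lz)
  # solvate both aqueous slabs
  wpi <- ff$bead_types$waters_included[ff$bead_types$name == "SOD"]
  v_aq <- Lxy^2 * water_pad
  cnt <- counts_for_molarity(molarity, 2 * v_aq, wpi)
  half <- function(n) c(floor(n / 2), ceiling(n / 2))
  w2 <- half(cnt$n_water); s2 <- half(cnt$n_cation); c2 <- half(cnt$n_anion)
  top <- pack_random(c(W = w2[1], SOD = s2[1], CLA = c2[1]), box, min_dist,
                     seed + 11,
                     region = cbind(c(0, 0, Lz - water_pad), c(Lxy, Lxy, Lz)))
  bot <- pack_random(c(W = w2[2], SOD = s2[2], CLA = c2[2]), box, min_dist,
                     seed + 12,
                     region = cbind(c(0, 0, 0), c(Lxy, Lxy, water_pad)))
  sys <- cg_system(rbind(pos, top$pos, bot$pos), box,
                   c(types, top$types, bot$types),
                   bonds = bonds, angles = angles, geometry = "bilayer",
                   meta = list(molarity = molarity, chains = chains,
                               leaflet = leaflet,
                               n_lipids_per_leaflet = nl,
                               head_types = c("NC", "PH")))
  sys
}
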