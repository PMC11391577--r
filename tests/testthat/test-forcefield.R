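test_that("LJ forms cross zero at sigma and reach -epsilon at their minima", {
  for (form in c("LJ9_6", "LJ12_4")) {
    for (eps in c(0.3, 1, 2.5)) for (sig in c(3, 4.5, 6)) {
      expect_equal(pair_energy_force(sig, eps, sig, form)$energy, 0)
      rmin <- if (form == "LJ9_6") (3 / 2)^(1 / 3) * sig else 3^(1 / 8) * sig
      at_min <- pair_energy_force(rmin, eps, sig, form)
      expect_equal(at_min$energy, -eps, tolerance = 1e-12)
      expect_equal(at_min$force, 0, tolerance = 1e-10)
    }
  }
})

test_that("LJ and Coulomb radial forces match finite differences of the energy", {
  h <- 1e-6
  r <- seq(2.5, 12, length.out = 50)
  for (form in c("LJ9_6", "LJ12_4")) {
    u <- function(x) pair_energy_force(x, 0.8, 3.7, form)$energy
    num <- -(u(r + h) - u(r - h)) / (2 * h)
    ana <- pair_energy_force(r, 0.8, 3.7, form)$force
    expect_equal(ana, num, tolerance = 1e-6)
  }
  es <- list(relative_permittivity = 80, method = "ewald",
             real_space_cutoff = 15)
  uc <- function(x) coulomb_energy_force(x, 1, -1, es)$energy
  num <- -(uc(r + h) - uc(r - h)) / (2 * h)
  expect_equal(coulomb_energy_force(r, 1, -1, es)$force, num,
               tolerance = 1e-6)
})

test_that("LJ is exactly zero beyond the cutoff and positive r is enforced", {
  out <- pair_energy_force(c(9.99, 10.01), 1, 4, "LJ9_6", cutoff = 10)
  expect_true(out$energy[1] != 0 && out$energy[2] == 0)
  expect_true(out$force[2] == 0)
  expect_error(pair_energy_force(0, 1, 4), "positive")
  expect_error(coulomb_energy_force(-1, 1, 1), "positive")
})

test_that("bare Coulomb term matches hand evaluation with C = 332.0637", {
  # +1/-1 at 15 A through eps_r = 80
  u <- coulomb_energy_force(15, 1, -1,
                            list(relative_permittivity = 80,
                                 method = "ewald",
                                 real_space_cutoff = 15))$energy
  expect_equal(u, -332.0637 / (80 * 15), tolerance = 1e-12)
  expect_equal(u, -0.2767, tolerance = 1e-3)
  # neutral bead: exactly zero
  z <- coulomb_energy_force(5, 0, -1, list(relative_permittivity = 80,
                                           method = "ewald",
                                           real_space_cutoff = 15))
  expect_identical(z$energy, 0)
  expect_identical(z$force, 0)
})

test_that("Ewald total energy matches a brute-force image sum on an 8-ion lattice", {
  ff <- default_forcefield("bare", es_method = "ewald", cutoff = 5)
  ff$electrostatics$accuracy_s <- 4.0
  L <- 12
  pos <- rbind(c(3, 3, 3), c(9, 9, 3), c(9, 3, 9), c(3, 9, 9),
               c(9, 3, 3), c(3, 9, 3), c(3, 3, 9), c(9, 9, 9))
  types <- c(rep("SOD", 4), rep("CLA", 4))
  sys <- cg_system(pos, rep(L, 3), types)
  e_ewald <- compute_forces(sys, ff)$energy$coul
  # direct sum over 11^3 > 10^3 periodic images (charge-neutral,
  # zero-dipole cell: absolutely convergent at this depth)
  C <- cg_units$coulomb / 80
  q <- ifelse(types == "SOD", 1, -1)
  E <- 0
  for (nx in -5:5) for (ny in -5:5) for (nz in -5:5) {
    shift <- c(nx, ny, nz) * L
    for (i in 1:8) for (j in 1:8) {
      if (all(shift == 0) && j <= i) next
      r <- sqrt(sum((pos[i, ] - pos[j, ] + shift)^2))
      w <- if (all(shift == 0)) 1 else 0.5
      E <- E + w * C * q[i] * q[j] / r
    }
  }
  expect_equal(e_ewald, E, tolerance = 1e-3)
})

test_that("pair lookup is symmetric and duplicates are rejected", {
  ff <- toy_ff()
  expect_equal(ff_pair(ff, "A", "B"), ff_pair(ff, "B", "A"))
  expect_error(cg_forcefield(
    bead_types = rbind(bead_type("A", 40), bead_type("B", 60)),
    pairs = data.frame(type_i = c("A", "B"), type_j = c("B", "A"),
                       epsilon = c(1, 1), sigma = c(3, 3),
                       form = "LJ9_6")), "duplicate")
})

test_that("apply_scaling rescales only the selected pairs", {
  ff <- default_forcefield("bare")
  # identity scaling returns an identical table
  expect_identical(apply_scaling(ff, 1, 1, c("SOD", "CLA"),
                                 c("CT", "CM", "TL"))$pairs, ff$pairs)
  sc <- apply_scaling(ff, 2, 1.1, "SOD", "CT")
  p_new <- ff_pair(sc, "SOD", "CT"); p_old <- ff_pair(ff, "SOD", "CT")
  expect_equal(p_new$epsilon, 2 * p_old$epsilon)
  expect_equal(p_new$sigma, 1.1 * p_old$sigma)
  untouched <- !(pair_key(ff$pairs$type_i, ff$pairs$type_j) %in%
                   pair_key("SOD", "CT"))
  expect_identical(sc$pairs[untouched, ], ff$pairs[untouched, ])
  # inverse composition recovers the original to round-off
  back <- apply_scaling(sc, 1 / 2, 1 / 1.1, "SOD", "CT")
  expect_equal(back$pairs$epsilon, ff$pairs$epsilon, tolerance = 1e-14)
  expect_equal(back$pairs$sigma, ff$pairs$sigma, tolerance = 1e-14)
  # empty selector is an error, not a silent no-op
  expect_error(apply_scaling(ff, 2, 1, "SOD", "NOPE"), "matched no pairs")
})

test_that("validate_table reports missing pairs and invariant violations", {
  ff <- toy_ff()
  expect_identical(nrow(validate_table(ff, c("A", "B"))), 0L)
  ff2 <- ff
  ff2$pairs <- ff2$pairs[-2, ] # drop A-B
  rep <- validate_table(ff2, c("A", "B"))
  expect_identical(rep$finding, "missing_pair")
  expect_identical(rep$detail, "A-B")
  ff3 <- ff
  ff3$pairs$epsilon[1] <- -1
  rep3 <- validate_table(ff3, c("A", "B"))
  expect_true(any(rep3$finding == "invalid_pair_parameter"))
})

test_that("force-field serialization round-trips every field exactly", {
  ff <- default_forcefield("solvated")
  ff <- ff_set_pair(ff, "W", "SOD", epsilon = 1 / 3, sigma = pi)
  path <- withr::local_tempfile(fileext = ".ff")
  write_forcefield(ff, path)
  back <- read_forcefield(path)
  expect_equal(back$bead_types, ff$bead_types)
  expect_equal(back$pairs, ff$pairs)
  expect_equal(back$bonds, ff$bonds)
  expect_equal(back$angles, ff$angles)
  expect_identical(back$electrostatics, ff$electrostatics)
  expect_identical(back$options, ff$options)
})

test_that("bonded terms vanish at equilibrium and match finite differences", {
  ff <- default_forcefield()
  # bond at r0: zero energy and force
  r0 <- ff$bonds$r0[ff$bonds$type_i == "CT"][1]
  sys <- cg_system(rbind(c(5, 5, 5), c(5 + r0, 5, 5)), rep(20, 3),
                   c("CT", "CM"), bonds = rbind(c(1, 2)))
  ffn <- ff; ffn$pairs$epsilon[] <- 1e-12 # suppress nonbonded
  fr <- compute_forces(sys, ffn)
  expect_equal(fr$energy$bond, 0, tolerance = 1e-12)
  # angle at theta0: zero angle energy (CT-CM-CT theta0 = 173 deg)
  th0 <- ff$angles$theta0[1] * pi / 180
  b <- 3.6
  # vertex at bead 2; arm to bead 3 at exactly theta0 from the arm to bead 1
  p3 <- c(5 + b, 5, 5) + b * c(-cos(th0), sin(th0), 0)
  sys2 <- cg_system(rbind(c(5, 5, 5), c(5 + b, 5, 5), p3), rep(24, 3),
                    c("CT", "CM", "CT"), bonds = rbind(c(1, 2), c(2, 3)),
                    angles = rbind(c(1, 2, 3)))
  ffa <- ff; ffa$angles$corr <- FALSE; ffa$pairs$epsilon[] <- 1e-12
  fra <- compute_forces(sys2, ffa)
  expect_equal(fra$energy$angle, 0, tolerance = 1e-10)
  # FD check on a bent 3-bead molecule with all terms on
  sys3 <- cg_system(rbind(c(10, 10, 10), c(13.2, 10.5, 10),
                          c(16, 12, 10.5)), rep(30, 3),
                    c("CT", "CM", "CT"), bonds = rbind(c(1, 2), c(2, 3)),
                    angles = rbind(c(1, 2, 3)))
  fr3 <- compute_forces(sys3, ff)
  h <- 1e-5
  num <- matrix(0, 3, 3)
  for (i in 1:3) for (d in 1:3) {
    sp <- sys3; sp$pos[i, d] <- sp$pos[i, d] + h
    sm <- sys3; sm$pos[i, d] <- sm$pos[i, d] - h
    num[i, d] <- -(compute_forces(sp, ff)$energy$potential -
                     compute_forces(sm, ff)$energy$potential) / (2 * h)
  }
  expect_equal(max(abs(num - fr3$forces)) / max(abs(fr3$forces)), 0,
               tolerance = 1e-6)
})

test_that("bond prefactor convention doubles the bonded energy", {
  ff <- default_forcefield()
  ff$pairs$epsilon[] <- 1e-12
  sys <- cg_system(rbind(c(5, 5, 5), c(9.0, 5, 5)), rep(20, 3),
                   c("CT", "CM"), bonds = rbind(c(1, 2)))
  e_full <- compute_forces(sys, ff)$energy$bond
  ff$options$bond_prefactor <- 0.5
  e_half <- compute_forces(sys, ff)$energy$bond
  expect_equal(e_full, 2 * e_half)
  r0 <- ff$bonds$r0[ff$bonds$type_i == "CT"][1]
  k <- ff$bonds$k[ff$bonds$type_i == "CT"][1]
  expect_equal(e_full, k * (4 - r0)^2, tolerance = 1e-10)
})

test_that("missing pair entries fail fast unless the LB fallback is enabled", {
  ff <- toy_ff()
  ff$pairs <- ff$pairs[ff$pairs$type_i != "A" | ff$pairs$type_j != "B", ]
  sys <- random_sys(10, seed = 3)
  expect_error(compute_forces(sys, ff), "missing")
  ff$options$mixing_fallback <- TRUE
  expect_warning(fr <- compute_forces(sys, ff), "Lorentz-Berthelot")
  expect_true(is.finite(fr$energy$potential))
})
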