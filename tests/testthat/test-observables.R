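# synthetic trajectory builder: hand-set channels, no dynamics
fake_traj <- function(n = 40, box = c(50, 50, 100), P = NULL,
                      wall = NULL, types = rep("W", 10), frames = NULL) {
  if (is.null(P)) P <- matrix(0, n, 6)
  colnames(P) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  B <- matrix(rep(box, each = n), n, 3)
  colnames(B) <- c("Lx", "Ly", "Lz")
  structure(list(time = seq_len(n) * 100, pe = numeric(n),
                 ke = numeric(n), temperature = rep(300, n),
                 volume = rep(prod(box), n), pressure = P, box = B,
                 wall_forces = wall, frames = frames,
                 types = types), class = "cg_trajectory")
}

test_that("block error: constant series, permutation invariance, sampling theory", {
  expect_identical(block_error(rep(3.2, 50)), 0)
  set.seed(1)
  x <- rnorm(1e5)
  # SE of 5 block means of iid N(0,1): sd(mean of 2e4)/sqrt(5)
  expect_equal(block_error(x, 5), 1 / sqrt(2e4) / sqrt(5), tolerance = 0.5)
  idx <- unlist(lapply(0:4, function(b) 2e4 * b + sample(2e4)))
  expect_equal(block_error(x[idx], 5), block_error(x, 5))
  expect_error(block_error(1:3, 5), "too short")
})

test_that("mass density converts amu/A^3 correctly and scales with mass", {
  ff <- cg_forcefield(bead_type("X", 100),
                      data.frame(type_i = "X", type_j = "X", epsilon = 1,
                                 sigma = 3, form = "LJ9_6"))
  tr <- fake_traj(n = 20, box = rep(50, 3), types = rep("X", 1000))
  rho <- mass_density(tr, ff, window = 1)
  expect_equal(rho$value, 1328.4, tolerance = 1e-4)
  expect_identical(rho$uncertainty, 0) # static trajectory
  ff2 <- ff; ff2$bead_types$mass <- 200
  expect_equal(mass_density(tr, ff2, window = 1)$value, 2 * rho$value)
  expect_error(mass_density(fake_traj(n = 0), ff), "empty")
})

test_that("Kirkwood-Irving estimator reproduces hand-computed values", {
  # isotropic tensor: exactly zero
  P <- matrix(rep(c(200, 200, 200, 0, 0, 0), each = 30), 30, 6)
  expect_identical(surface_tension(fake_traj(30, P = P))$value, 0)
  # constant anisotropy 100 bar, Lz = 100 A => 50 mN/m
  P2 <- matrix(rep(c(100, 100, 200, 0, 0, 0), each = 30), 30, 6)
  g <- surface_tension(fake_traj(30, P = P2), window = 1)
  expect_equal(g$value, 50)
  expect_identical(g$uncertainty, 0)
  # transverse relabeling x <-> y leaves gamma unchanged
  P3 <- matrix(rep(c(80, 120, 200, 0, 0, 0), each = 30), 30, 6)
  P3s <- P3[, c(2, 1, 3, 4, 5, 6)]
  expect_equal(surface_tension(fake_traj(30, P = P3))$value,
               surface_tension(fake_traj(30, P = P3s))$value)
})

test_that("interfacial tension uses the mean fluctuating Lz", {
  P <- matrix(rep(c(100, 100, 200, 0, 0, 0), each = 40), 40, 6)
  tr <- fake_traj(40, P = P)
  tr$box[, "Lz"] <- 100 + sin(seq_len(40)) * 10
  it <- interfacial_tension(tr, window = 1)
  expect_equal(it$value, mean(tr$box[, "Lz"]) / 2 * 100 * 1e-2)
  # zero anisotropy with fluctuating Lz: zero
  tr0 <- fake_traj(40)
  tr0$box[, "Lz"] <- 100 + sin(seq_len(40)) * 10
  expect_identical(interfacial_tension(tr0, window = 1)$value, 0)
  # duplicating frames leaves the value unchanged and shrinks the error
  Pj <- matrix(rep(c(100, 100, 200, 0, 0, 0), each = 40), 40, 6) +
    cbind(0, 0, rnorm(40, 0, 5), 0, 0, 0)
  t1 <- fake_traj(40, P = Pj)
  t2 <- fake_traj(80, P = rbind(Pj, Pj))
  expect_equal(interfacial_tension(t2, window = 1)$value,
               interfacial_tension(t1, window = 1)$value)
})

test_that("osmotic pressure converts wall force per area to bar", {
  # constant 20 kcal/mol/A on a 50 x 50 A^2 wall => ~555.8 bar
  wall <- matrix(20, 40, 2)
  tr <- fake_traj(40, box = c(120, 50, 50), wall = wall)
  pi_ <- osmotic_pressure(tr, window = 1)
  expect_equal(pi_$value, 20 / 2500 * cg_units$bar_per_kcal_A3)
  expect_equal(pi_$value, 555.8, tolerance = 1e-3)
  # no crossings: exactly zero
  expect_identical(osmotic_pressure(fake_traj(40, wall = matrix(0, 40, 2)),
                                    window = 1)$value, 0)
  expect_error(osmotic_pressure(fake_traj(40)), "wall")
})

test_that("area per lipid is box area over leaflet count", {
  tr <- fake_traj(20, box = c(64, 64, 80))
  apl <- area_per_lipid(tr, 128, window = 1)
  expect_equal(apl$value, 32)
  expect_identical(apl$uncertainty, 0)
  expect_equal(area_per_lipid(tr, 256, window = 1)$value, 16)
  expect_error(area_per_lipid(tr, 0), "> 0")
})

test_that("headgroup distance matches hand COM arithmetic and is translation invariant", {
  ff <- default_forcefield()
  # 4 lipids: two up (NC,PH near z = 60), two down (near z = 20)
  pos <- rbind(c(5, 5, 61), c(5, 5, 59),    # up lipid 1 heads
               c(15, 5, 62), c(15, 5, 58),  # up lipid 2
               c(5, 15, 21), c(5, 15, 19),  # down lipid 1
               c(15, 15, 22), c(15, 15, 18))
  types <- rep(c("NC", "PH"), 4)
  mk <- function(shift) {
    fr <- list(pos = sweep(pos, 2, c(0, 0, -shift)), box = c(30, 30, 80),
               vel = matrix(0, 8, 3), time = 0)
    tr <- fake_traj(1, box = c(30, 30, 80), types = types,
                    frames = list(fr))
    headgroup_distance(tr, ff, 1:8, window = 1)$value
  }
  m_nc <- ff$bead_types$mass[ff$bead_types$name == "NC"]
  m_ph <- ff$bead_types$mass[ff$bead_types$name == "PH"]
  up_com <- (m_nc * (61 + 62) + m_ph * (59 + 58)) / (2 * (m_nc + m_ph))
  dn_com <- (m_nc * (21 + 22) + m_ph * (19 + 18)) / (2 * (m_nc + m_ph))
  expect_equal(mk(0), up_com - dn_com)
  expect_equal(mk(5), mk(0)) # rigid translation
  # simple symmetric case: 40 A by construction
  pos2 <- rbind(matrix(c(5, 5, 60), 4, 3, byrow = TRUE) +
                  cbind(runif(4), runif(4), 0),
                matrix(c(5, 5, 20), 4, 3, byrow = TRUE) +
                  cbind(runif(4), runif(4), 0))
  fr2 <- list(pos = pos2, box = c(30, 30, 80), vel = matrix(0, 8, 3),
              time = 0)
  tr2 <- fake_traj(1, box = c(30, 30, 80), types = rep(c("NC", "PH"), 4),
                   frames = list(fr2))
  expect_equal(headgroup_distance(tr2, ff, 1:8, window = 1)$value, 40)
  expect_error(headgroup_distance(tr2, ff, integer(0)), "empty")
})

test_that("order parameter hits its exact limits and the isotropic average", {
  n <- 1e5
  par_bonds <- cbind(0, 0, rep(c(1, -1), n / 2))
  expect_equal(order_parameters(bond_vectors = par_bonds), 1)
  perp <- cbind(rnorm(n), rnorm(n), 0)
  expect_equal(order_parameters(bond_vectors = perp), -0.5)
  set.seed(42)
  iso <- matrix(rnorm(3 * n), n, 3)
  expect_equal(order_parameters(bond_vectors = iso), 0, tolerance = 0.01)
  # bounds hold for arbitrary vectors
  for (s in 1:5) {
    set.seed(s)
    S <- order_parameters(bond_vectors = matrix(rnorm(300), 100, 3))
    expect_gte(S, -0.5); expect_lte(S, 1)
  }
  expect_warning(order_parameters(bond_vectors = rbind(c(0, 0, 0),
                                                       c(0, 0, 1))),
                 "zero-length")
})

test_that("density profile is flat for a uniform gas and conserves counts", {
  set.seed(3)
  N <- 4000
  fr <- list(pos = matrix(runif(3 * N) * 40, N, 3), box = rep(40, 3),
             vel = matrix(0, N, 3), time = 0)
  tr <- fake_traj(1, box = rep(40, 3), types = rep("W", N),
                  frames = list(fr))
  prof <- density_profile(tr, "z", bin_width = 4, window = 1)
  # integral over bins recovers the bead count
  expect_equal(sum(prof$density) * prod(fr$box) / nrow(prof), N)
  # flat within Poisson noise (~ sqrt(400)/400 = 5% per bin, test at 4 sd)
  expect_lt(max(abs(prof$density - mean(prof$density))) /
              mean(prof$density), 0.2)
  # empty selection: all-zero profile
  prof0 <- density_profile(tr, "z", selection = integer(0), bin_width = 4,
                           window = 1)
  expect_true(all(prof0$density == 0))
})

test_that("estimators are invariant under rigid translation of stored frames", {
  wb <- local_water_box()
  tr <- run_md(init_velocities(wb$sys, wb$ff, 293, 1), wb$ff,
               ensemble_spec("NVT", 293, dt = 5), n_steps = 100,
               sample_every = 20, store_frames = TRUE)
  rho1 <- mass_density(tr, wb$ff, window = 1)$value
  tr2 <- tr
  tr2$frames <- lapply(tr$frames, function(f) {
    f$pos <- f$pos + 2.5; f
  })
  expect_equal(mass_density(tr2, wb$ff, window = 1)$value, rho1)
})
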