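test_that("engine forces equal the direct-sum oracle, with and without neighbor list", {
  ff <- toy_ff(lj_shift = TRUE)
  for (seed in 1:5) {
    sys <- random_sys(25, L = 18, seed = seed)
    orc <- oracle_forces(sys, ff)
    direct <- compute_forces(sys, ff, use_nlist = FALSE)
    nlist <- compute_forces(sys, ff, use_nlist = TRUE)
    expect_equal(direct$forces, orc$forces, tolerance = 1e-12)
    expect_identical(direct$forces, nlist$forces)
    expect_equal(direct$energy$lj, orc$e_lj, tolerance = 1e-12)
  }
})

test_that("forces sum to zero without walls and overlap raises an error", {
  ff <- toy_ff()
  sys <- random_sys(40, L = 22, seed = 11)
  fr <- compute_forces(sys, ff)
  expect_lt(max(abs(colSums(fr$forces))), 1e-8 * sum(abs(fr$forces)))
  # two beads beyond the cutoff: exactly nothing
  far <- cg_system(rbind(c(1, 1, 1), c(12, 1, 1)), rep(30, 3), c("A", "A"))
  fr2 <- compute_forces(far, ff)
  expect_identical(fr2$energy$potential, 0)
  expect_true(all(fr2$forces == 0))
  # overlapping pair is named
  ov <- cg_system(rbind(c(1, 1, 1), c(1.05, 1, 1)), rep(30, 3), c("A", "A"))
  expect_error(compute_forces(ov, ff), "overlap")
})

test_that("virtual wall force follows the indenter law", {
  w <- wall_spec("x", 50, "+", k = 20, affected = "SOD")
  ff <- default_forcefield("bare")
  # no crossing: zero
  sys <- cg_system(rbind(c(45, 5, 5), c(30, 6, 6)), rep(60, 3),
                   c("SOD", "CLA"))
  expect_identical(wall_force(sys, w), 0)
  # one ion 1 A past the wall: k * dx^2 = 20
  sys2 <- cg_system(rbind(c(51, 5, 5)), rep(60, 3), "SOD")
  expect_equal(wall_force(sys2, w), 20)
  # unaffected species feel nothing
  sys3 <- cg_system(rbind(c(55, 5, 5)), rep(60, 3), "CLA")
  expect_identical(wall_force(sys3, w), 0)
  # quadratic homogeneity: doubling every penetration quadruples the total
  set.seed(2)
  pen <- runif(6, 0.2, 1.5)
  s1 <- cg_system(cbind(50 + pen, seq(5, 30, 5), 5), rep(60, 3),
                  rep("SOD", 6))
  s2 <- cg_system(cbind(50 + 2 * pen, seq(5, 30, 5), 5), rep(60, 3),
                  rep("SOD", 6))
  expect_equal(wall_force(s2, w), 4 * wall_force(s1, w), tolerance = 1e-12)
  # linear law option
  wl <- wall_spec("x", 50, "+", k = 20, affected = "SOD",
                  force_law = "half_harmonic_linear")
  expect_equal(wall_force(sys2, wl), 20)
  expect_equal(wall_force(s2, wl), 2 * wall_force(s1, wl), tolerance = 1e-12)
  # engine-side wall channel agrees with the R evaluation
  fr <- compute_forces(sys2, default_forcefield("bare"), walls = list(w))
  expect_equal(fr$wall_forces, 20)
})

test_that("NVE: an isolated stationary bead stays put; momentum is conserved", {
  ff <- toy_ff()
  sys <- cg_system(matrix(c(5, 5, 5), 1, 3), rep(20, 3), "A",
                   velocities = matrix(0, 1, 3))
  tr <- run_md(sys, ff, ensemble_spec("NVE", dt = 1), n_steps = 50,
               sample_every = 10)
  expect_equal(tr$final$pos, sys$pos)
  wb <- local_water_box()
  sys2 <- init_velocities(wb$sys, wb$ff, 293, seed = 5)
  tr2 <- run_md(sys2, wb$ff, ensemble_spec("NVE", dt = 2), n_steps = 500,
                sample_every = 50, store_frames = TRUE)
  m <- wb$ff$bead_types$mass[match(sys2$types, wb$ff$bead_types$name)]
  p0 <- colSums(sys2$vel * m)
  pT <- colSums(tr2$final$vel * m)
  expect_lt(max(abs(pT - p0)), 1e-8)
})

test_that("run returns aligned channels, is seed-reproducible, and n_steps = 0 samples the input", {
  wb <- local_water_box()
  ens <- ensemble_spec("NVT", 293, dt = 5)
  tr0 <- run_md(wb$sys, wb$ff, ens, n_steps = 0, sample_every = 1,
                seed = 3, store_frames = TRUE)
  expect_length(tr0$time, 1)
  expect_equal(tr0$frames[[1]]$pos, wb$sys$pos %% wb$sys$box[1])
  tr1 <- run_md(wb$sys, wb$ff, ens, n_steps = 200, sample_every = 20,
                seed = 3)
  tr2 <- run_md(wb$sys, wb$ff, ens, n_steps = 200, sample_every = 20,
                seed = 3)
  expect_identical(tr1$final$pos, tr2$final$pos)
  expect_identical(tr1$pe, tr2$pe)
  expect_length(tr1$pe, length(tr1$time))
  expect_identical(nrow(tr1$pressure), length(tr1$time))
  # different seeds diverge but conserve composition
  tr3 <- run_md(wb$sys, wb$ff, ens, n_steps = 200, sample_every = 20,
                seed = 4)
  expect_false(identical(tr3$final$pos, tr1$final$pos))
  expect_identical(tr3$final$types, tr1$final$types)
})

test_that("strict time ordering and frame alignment hold on a sampled run", {
  wb <- local_water_box()
  tr <- run_md(init_velocities(wb$sys, wb$ff, 293, 1), wb$ff,
               ensemble_spec("NVT", 293, dt = 5), n_steps = 300,
               sample_every = 30, store_frames = TRUE)
  expect_true(all(diff(tr$time) > 0))
  expect_length(tr$frames, length(tr$time))
  expect_equal(vapply(tr$frames, `[[`, 0, "time") + tr$time[1], tr$time)
})

test_that("pressure tensor: kinetic term, two-body virial, and ideal-gas law", {
  ff <- toy_ff()
  # single stationary bead: zero kinetic contribution
  sys <- cg_system(matrix(c(5, 5, 5), 1, 3), rep(20, 3), "A",
                   velocities = matrix(0, 1, 3))
  expect_equal(unname(pressure_tensor(sys, ff)), rep(0, 6))
  # LJ dimer: trace of virial equals r * f_r by hand
  r <- 3.9
  dim <- cg_system(rbind(c(5, 5, 5), c(5 + r, 5, 5)), rep(20, 3),
                   c("A", "A"), velocities = matrix(0, 2, 3))
  fr <- compute_forces(dim, ff)
  f_hand <- pair_energy_force(r, 0.5, 3.2, "LJ9_6")$force
  expect_equal(sum(fr$virial[1:3]), r * f_hand, tolerance = 1e-10)
  P <- pressure_tensor(dim, ff, fr$virial)
  expect_equal(mean(P[1:3]),
               r * f_hand / (3 * 20^3) * cg_units$bar_per_kcal_A3,
               tolerance = 1e-10)
  # ideal gas at 298 K: <P> = rho k T (no interactions => kinetic only)
  ffi <- toy_ff()
  ffi$pairs$epsilon[] <- 1e-14
  set.seed(9)
  gas <- cg_system(matrix(runif(3 * 500) * 40, 500, 3), rep(40, 3),
                   rep("A", 500))
  gas <- init_velocities(gas, ffi, 298, seed = 10)
  P <- pressure_tensor(gas, ffi)
  rho_kT <- 500 / 40^3 * cg_units$kB * 298 * cg_units$bar_per_kcal_A3
  # velocities are rescaled to T with Nf = 3N - 3; per-axis spread ~ sqrt(2/N)
  expect_equal(mean(P[1:3]), rho_kT, tolerance = 0.05)
})

test_that("NPzAT scales only z; semi-isotropic mode keeps x and y coupled", {
  wb <- local_water_box()
  sys <- init_velocities(wb$sys, wb$ff, 293, 2)
  trz <- run_md(sys, wb$ff, ensemble_spec("NPzAT", 293, 1, dt = 5),
                n_steps = 300, sample_every = 30)
  expect_true(all(trz$box[, "Lx"] == trz$box[1, "Lx"]))
  expect_true(all(trz$box[, "Ly"] == trz$box[1, "Ly"]))
  expect_gt(sd(trz$box[, "Lz"]), 0)
  trs <- run_md(sys, wb$ff, ensemble_spec("NPT", 293, 1, dt = 5,
                                          npt_mode = "xy_z"),
                n_steps = 300, sample_every = 30)
  expect_equal(trs$box[, "Lx"] / trs$box[1, "Lx"],
               trs$box[, "Ly"] / trs$box[1, "Ly"], tolerance = 1e-12)
})

test_that("integration blow-up is reported, not silently propagated", {
  ff <- toy_ff()
  sys <- cg_system(rbind(c(5, 5, 5), c(5.35, 5, 5)), rep(20, 3),
                   c("A", "A"),
                   velocities = matrix(c(5, -5, 0, 0, 0, 0), 2, 3))
  expect_error(run_md(sys, ff, ensemble_spec("NVE", dt = 10),
                      n_steps = 500, sample_every = 10),
               "blow-up|overlap")
})
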