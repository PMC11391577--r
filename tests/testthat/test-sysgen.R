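test_that("rejection packing honors the minimum distance and is seed-stable", {
  s1 <- pack_random(c(A = 1), rep(10, 3), min_dist = 3, seed = 1)
  expect_true(all(s1$pos >= 0 & s1$pos <= 10))
  s2 <- pack_random(c(A = 150, B = 50), rep(30, 3), min_dist = 3, seed = 4)
  # brute-force periodic scan
  dmin <- Inf
  for (i in 1:199) for (j in (i + 1):200) {
    d <- s2$pos[i, ] - s2$pos[j, ]
    d <- d - s2$box * round(d / s2$box)
    dmin <- min(dmin, sqrt(sum(d^2)))
  }
  expect_gte(dmin, 3)
  s3 <- pack_random(c(A = 150, B = 50), rep(30, 3), min_dist = 3, seed = 4)
  expect_identical(s2$pos, s3$pos)
  expect_identical(s2$types, s3$types)
  # infeasible request fails with guidance
  expect_error(pack_random(c(A = 500), rep(10, 3), min_dist = 4),
               "infeasible|larger box")
})

test_that("ion counts follow molarity and box volume", {
  # 1 M in a (60 A)^3 box: round(1 * N_A * 2.16e-22 L) = 130 pairs
  cnt <- counts_for_molarity(1, 60^3, 0)
  expect_identical(cnt$n_cation, 130L)
  expect_identical(cnt$n_anion, 130L)
  expect_identical(counts_for_molarity(0, 60^3, 0)$n_cation, 0L)
  # extensivity: doubling the volume doubles counts within rounding
  c2 <- counts_for_molarity(1, 2 * 60^3, 0)
  expect_lte(abs(c2$n_cation - 2 * cnt$n_cation), 1)
  # solvated beads debit their grouped waters
  cs <- counts_for_molarity(1, 60^3, 3)
  expect_equal(cnt$n_water - cs$n_water, round(2 * 130 * 3 / 3))
  expect_error(counts_for_molarity(60, 40^3, 3), "no room")
})

test_that("slab construction triples z and centers the liquid", {
  ff <- default_forcefield()
  sys <- make_bulk(0.5, ff, total_beads = 150, seed = 2)
  slab <- make_slab(sys)
  expect_equal(slab$box, c(sys$box[1], sys$box[2], 3 * sys$box[3]))
  expect_identical(nrow(slab$pos), nrow(sys$pos))
  expect_true(all(slab$pos[, 3] >= sys$box[3] &
                    slab$pos[, 3] <= 2 * sys$box[3]))
  expect_identical(slab$geometry, "slab")
})

test_that("osmotic cell confines ions centrally with ion-only walls", {
  ff <- default_forcefield("solvated")
  cell <- make_osmotic(2, ff, total_beads = 200, pad_x = 20, seed = 3)
  sys <- cell$system
  comp <- sys$meta$compartment
  ion <- sys$types %in% c("SOD", "CLA")
  expect_gt(sum(ion), 0)
  expect_true(all(sys$pos[ion, 1] >= comp[1] & sys$pos[ion, 1] <= comp[2]))
  expect_length(cell$walls, 2)
  expect_setequal(vapply(cell$walls, `[[`, "", "side"), c("+", "-"))
  # water is not affected: zero wall force from a water bead past a wall
  wtest <- cg_system(matrix(c(comp[2] + 5, 5, 5), 1, 3), sys$box, "W")
  expect_identical(wall_force(wtest, cell$walls[[2]]), 0)
  # bookkeeping: centre + 2 pads
  n_pad <- sum(sys$types == "W" & (sys$pos[, 1] < comp[1] |
                                     sys$pos[, 1] > comp[2]))
  n_centre <- n_beads(sys) - n_pad
  expect_identical(n_beads(sys), n_centre + n_pad)
  expect_identical(net_charge(sys, ff), 0)
})

test_that("biphasic systems stack unbranched oil chains below the electrolyte", {
  ff <- default_forcefield()
  sys <- make_biphasic("decane_like", n_oil = 30, n_aqueous = 150,
                       molarity = 1, ff = ff, seed = 5)
  oil <- sys$types %in% c("CT", "CM")
  aq <- !oil
  # initial phase separation: z ranges overlap < 10%
  zo <- range(sys$pos[oil, 3]); za <- range(sys$pos[aq, 3])
  overlap <- max(0, min(zo[2], za[2]) - max(zo[1], za[1]))
  expect_lt(overlap / diff(range(sys$pos[, 3])), 0.1)
  # ions only in the aqueous phase
  ion <- sys$types %in% c("SOD", "CLA")
  expect_true(all(sys$pos[ion, 3] >= sys$meta$h_oil))
  # each chain is a path: bond degree <= 2, no branches
  deg <- tabulate(c(sys$bonds), nbins = n_beads(sys))
  expect_lte(max(deg), 2)
  expect_identical(sum(oil), 30L * 3L)
})

test_that("toy bilayer has separated leaflets, tagged heads and zero net charge", {
  ff <- default_forcefield("solvated")
  bl <- make_toy_bilayer(16, molarity = 0.5, ff = ff, seed = 6)
  expect_identical(length(bl$meta$chains), 32L) # 2 leaflets
  expect_identical(net_charge(bl, ff), 0)
  heads <- vapply(bl$meta$chains, `[[`, 1L, 1)
  tails <- unlist(lapply(bl$meta$chains, function(ch) ch[3:4]))
  up <- bl$meta$leaflet > 0
  hz_up <- mean(bl$pos[heads[up], 3]); hz_dn <- mean(bl$pos[heads[!up], 3])
  expect_gt(abs(hz_up - hz_dn), diff(range(bl$pos[tails, 3])) * 0.3)
  expect_identical(nrow(validate_table(ff, unique(bl$types))), 0L)
})

test_that("parametric target curves are monotone with exact noise-free anchors", {
  d <- reference_targets("density", molarity = seq(0, 5, 0.5))
  expect_equal(d$value[1], 998)
  expect_true(all(diff(d$value) > 0))
  g <- reference_targets("surface_tension", molarity = seq(0, 5, 0.5))
  expect_equal(g$value[1], 72.8)
  expect_true(all(diff(g$value) > 0))
  # van 't Hoff anchor: 0.1 M salt = 0.2 osmolar => ~4.96 bar at 298 K
  p <- reference_targets("osmotic_pressure", molarity = 0.1,
                         ideal_phi = TRUE)
  expect_equal(p$value, 4.96, tolerance = 2e-3)
  expect_true(all(diff(reference_targets("osmotic_pressure",
                                         molarity = seq(0.5, 5, 0.5))$value)
                  > 0))
  # target CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_target_curve(d, path)
  back <- read_target_curve(path)
  expect_equal(back$value, d$value)
  expect_identical(attr(back, "property"), "density")
})

test_that("generated bulk systems are electroneutral and table-complete", {
  for (ion_model in c("solvated", "bare")) {
    ff <- default_forcefield(ion_model)
    sys <- make_bulk(3, ff, total_beads = 120, seed = 8)
    expect_identical(net_charge(sys, ff), 0)
    expect_identical(nrow(validate_table(ff, unique(sys$types))), 0L)
  }
})
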