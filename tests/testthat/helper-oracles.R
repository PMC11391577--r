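# Shared fixtures and independent oracles used across tests.
# Oracles are deliberately written in plain R, independent of the
# compiled engine path they check.

# minimal two-type force field with known parameters
toy_ff <- function(es_method = "none", cutoff = 10, lj_shift = FALSE) {
  cg_forcefield(
    bead_types = rbind(
      bead_type("A", 40, 0, "other"),
      bead_type("B", 60, 0, "other")),
    pairs = data.frame(
      type_i = c("A", "A", "B"), type_j = c("A", "B", "B"),
      epsilon = c(0.5, 0.4, 0.6), sigma = c(3.2, 3.4, 3.6),
      form = c("LJ9_6", "LJ12_4", "LJ9_6")),
    electrostatics = list(method = es_method, real_space_cutoff = cutoff),
    cutoff = cutoff, lj_shift = lj_shift)
}

# direct O(N^2) minimum-image force/energy sum in R (no neighbor list),
# LJ + real-space Coulomb, matching the engine's cutoff conventions
oracle_forces <- function(sys, ff) {
  N <- nrow(sys$pos)
  f <- matrix(0, N, 3); e_lj <- 0; e_coul <- 0
  rc <- ff$options$cutoff
  bt <- ff$bead_types
  q <- bt$charge[match(sys$types, bt$name)]
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    d <- sys$pos[i, ] - sys$pos[j, ]
    d <- d - sys$box * round(d / sys$box)
    r <- sqrt(sum(d^2))
    if (r > rc) next
    p <- ff_pair(ff, sys$types[i], sys$types[j])
    lj <- pair_energy_force(r, p$epsilon, p$sigma, p$form, cutoff = rc)
    u <- lj$energy; fr <- lj$force
    if (isTRUE(ff$options$lj_shift))
      u <- u - pair_energy_force(rc, p$epsilon, p$sigma, p$form)$energy
    e_lj <- e_lj + u
    if (q[i] * q[j] != 0 &&
        identical(ff$electrostatics$method, "cutoff_shifted")) {
      cl <- coulomb_energy_force(r, q[i], q[j], ff$electrostatics)
      e_coul <- e_coul + cl$energy
      fr <- fr + cl$force
    }
    fv <- fr * d / r
    f[i, ] <- f[i, ] + fv
    f[j, ] <- f[j, ] - fv
  }
  list(forces = f, e_lj = e_lj, e_coul = e_coul)
}

# random well-separated configuration of the toy types
random_sys <- function(N, L = 20, seed = 1, types = c("A", "B")) {
  set.seed(seed)
  pos <- matrix(runif(3 * N) * L, N, 3)
  cg_system(pos, rep(L, 3), sample(types, N, replace = TRUE))
}

# equilibrated small water box (shared across engine tests; built once)
local_water_box <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ff <- default_forcefield("solvated", es_method = "none")
    sys <- pack_random(c(W = 100), rep(21, 3), min_dist = 3.4, seed = 7)
    sys <- minimize_system(sys, ff, n_steps = 120)
    cache <<- list(sys = sys, ff = ff)
    cache
  }
})
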