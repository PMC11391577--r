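# analytic surrogate: closed-form pseudo-response in place of MD, so the
# optimizer logic is testable in seconds. Density responds linearly to
# sigma and epsilon; surface tension mostly to epsilon.
surrogate_simulator <- function(ff) {
  function(property, molarity, ff_cand, budget, seed) {
    p <- ff_pair(ff_cand, "W", "SOD")
    val <- if (property == "density")
      998 + 40 * molarity + 120 * (p$sigma - 4.25) - 30 * (p$epsilon - 0.95)
    else
      72.8 + 1.7 * molarity + 60 * (p$epsilon - 0.95)
    structure(list(value = val, uncertainty = 0.1,
                   window = c(0, 1), n_samples = 1, n_blocks = 1),
              class = "cg_observable")
  }
}

test_that("condition-1 objective equals the hand-computed weighted sum on the surrogate", {
  ff <- default_forcefield("solvated")
  sim <- surrogate_simulator(ff)
  tgt <- list(
    density = reference_targets("density", c(1, 3)),
    surface_tension = reference_targets("surface_tension", c(1, 3)))
  # truth parameters reproduce the parametric curves exactly: objective 0
  expect_equal(condition1_objective(ff, tgt, simulator = sim), 0)
  # perturbed sigma: hand-compute the weighted sum of squared rel devs
  ffp <- ff_set_pair(ff, "W", "SOD", sigma = 4.35)
  drho <- 120 * 0.1
  hand <- sum((drho / tgt$density$value)^2)
  expect_equal(condition1_objective(ffp, tgt, w_gamma = 1, simulator = sim),
               hand, tolerance = 1e-10)
  # zero density weight makes the objective insensitive to density shifts
  expect_equal(condition1_objective(ffp, tgt, w_density = 0,
                                    simulator = sim), 0)
  # simulator failure yields the finite penalty, not an exception
  boom <- function(...) stop("blow-up")
  expect_identical(condition1_objective(ff, tgt, simulator = boom), 1e6)
})

test_that("Bayesian optimizer finds a 2-D quadratic minimum within 0.05 in 40 evaluations", {
  sp <- param_space(c("A-B", "A-B"), c("epsilon", "sigma"),
                    lower = c(0, 3), upper = c(1, 6))
  obj <- function(th) (th[1] - 0.5)^2 + (th[2] - 4)^2
  fit <- bayesian_optimize(obj, sp, fit_config(10, 30, seed = 11))
  expect_lt(abs(fit$best_par[1] - 0.5), 0.05)
  expect_lt(abs(fit$best_par[2] - 4), 0.05)
  expect_identical(nrow(fit$trace), 40L)
  expect_identical(fit$best_value, min(fit$trace$objective))
})

test_that("optimizer trace is deterministic per seed with monotone best-so-far", {
  sp <- param_space("A-B", "epsilon", 0, 2)
  obj <- function(th) (th[1] - 1.3)^2 + sin(5 * th[1]) * 0.05
  f1 <- bayesian_optimize(obj, sp, fit_config(5, 15, seed = 2))
  f2 <- bayesian_optimize(obj, sp, fit_config(5, 15, seed = 2))
  expect_identical(f1$trace, f2$trace)
  bsf <- cummin(f1$trace$objective)
  expect_true(all(diff(bsf) <= 1e-15))
  # convex 1-D: optimum found
  expect_lt(abs(f1$best_par[1] - 1.26), 0.1)
  # all-failing objective raises with the trace attached
  expect_error(bayesian_optimize(function(th) stop("no"), sp,
                                 fit_config(3, 2, seed = 1)), "failed")
})

test_that("optimizer recovers surrogate ion-water parameters from ground-truth targets", {
  ff <- default_forcefield("solvated")
  sim <- surrogate_simulator(ff)
  tgt <- list(density = reference_targets("density", c(1, 3)),
              surface_tension = reference_targets("surface_tension",
                                                  c(1, 3)))
  sp <- param_space(c("W-SOD", "W-SOD"), c("epsilon", "sigma"),
                    lower = c(0.5, 3.8), upper = c(1.5, 4.8))
  obj <- function(th) condition1_objective(apply_params(ff, sp, th), tgt,
                                           simulator = sim)
  fit <- bayesian_optimize(obj, sp, fit_config(10, 25, seed = 7))
  expect_lt(abs(fit$best_par[1] - 0.95) / 0.95, 0.1)
  expect_lt(abs(fit$best_par[2] - 4.25) / 4.25, 0.02)
})

test_that("condition-2 tuning touches only the SOD-CLA entry and honors tolerance", {
  ff <- default_forcefield("bare")
  # analytic monotone pseudo-osmometer: Pi falls as eps grows, rises with sigma
  osmo <- function(molarity, ffc, budget, seed) {
    p <- ff_pair(ffc, "SOD", "CLA")
    structure(list(value = 2 * molarity * 24.4 *
                     (1.3 - 0.5 * p$epsilon + 0.2 * (p$sigma - 3.3)),
                   uncertainty = 1, window = c(0, 1), n_samples = 1,
                   n_blocks = 1), class = "cg_observable")
  }
  pi0 <- osmo(5, ff, NULL, 1)$value
  # fixed point: target equal to the untuned model's own pressure
  same <- condition2_tune(ff, 5, pi0, simulator = osmo, tol = 0.05)
  expect_equal(ff_pair(same$ff, "SOD", "CLA")$epsilon,
               ff_pair(ff, "SOD", "CLA")$epsilon, tolerance = 1e-6)
  # a reachable lower target
  tuned <- condition2_tune(ff, 5, pi0 * 0.7, simulator = osmo, tol = 0.05)
  expect_lt(abs(tuned$achieved - pi0 * 0.7) / (pi0 * 0.7), 0.05)
  # locality: every other entry bit-identical
  changed <- pair_key(ff$pairs$type_i, ff$pairs$type_j) ==
    pair_key("SOD", "CLA")
  expect_identical(tuned$ff$pairs[!changed, ], ff$pairs[!changed, ])
  expect_identical(tuned$ff$bead_types, ff$bead_types)
  expect_identical(tuned$ff$bonds, ff$bonds)
  # the tuning direction for the bare model: weaker/larger cross term
  # (epsilon down or sigma up) raises the osmotic pressure
  p_t <- ff_pair(tuned$ff, "SOD", "CLA"); p_0 <- ff_pair(ff, "SOD", "CLA")
  expect_true(p_t$epsilon > p_0$epsilon || p_t$sigma < p_0$sigma)
  # unreachable target errors with the closest pressure
  expect_error(condition2_tune(ff, 5, pi0 * 50, simulator = osmo,
                               bounds = list(epsilon = c(0.35, 0.45),
                                             sigma = c(3.2, 3.4))),
               "unreachable")
})

test_that("evaluate_model reports exact and perturbed deviations deterministically", {
  ff <- default_forcefield("solvated")
  sim <- surrogate_simulator(ff)
  tgt <- list(density = reference_targets("density", c(1, 2, 3)))
  rep0 <- evaluate_model(ff, tgt, simulator = sim)
  expect_true(all(rep0$table$rel_dev == 0))
  expect_identical(unname(rep0$max_rel_dev["density"]), 0)
  # single point off by +10%
  tgt2 <- tgt
  tgt2$density$value[2] <- tgt2$density$value[2] / 1.1
  rep2 <- evaluate_model(ff, tgt2, simulator = sim)
  expect_equal(unname(rep2$max_rel_dev["density"]), 0.1, tolerance = 1e-6)
  expect_identical(evaluate_model(ff, tgt2, simulator = sim)$table,
                   rep2$table)
})

test_that("ground-truth targets give their generating table objective zero", {
  ff <- default_forcefield("solvated", es_method = "none")
  bud <- fit_budget(total_beads = 90, n_equil = 60, n_prod = 200,
                    sample_every = 5)
  tgt <- list(density = simulate_targets("density", c(1), ff, bud,
                                         seed = 13))
  expect_identical(attr(tgt$density, "provenance"), "ground_truth_sim")
  expect_identical(condition1_objective(ff, tgt, bud, w_gamma = 0,
                                        seed = 13), 0)
  # reproducible target generation
  tgt2 <- simulate_targets("density", c(1), ff, bud, seed = 13)
  expect_identical(tgt$density$value, tgt2$value)
})
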