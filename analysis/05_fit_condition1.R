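#!/usr/bin/env Rscript
# Condition-1 fit: Bayesian optimization of the ion-water LJ parameters
# against density and surface-tension target curves. Run here as a
# closed-loop recovery: the targets are generated by the engine itself
# with known parameters (ground_truth_sim mode), so the fit has a known
# answer to be judged against. Writes the evaluation trace, the best
# table and a session manifest under results/fit_condition1/.

library(cgionfit)

cfg <- run_config()
outdir <- file.path("results", "fit_condition1")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ff_truth <- default_forcefield("solvated", es_method = "cutoff_shifted")
bud <- fit_budget(total_beads = 280, n_equil = 200, n_prod = 800, dt = 10)
conc <- c(2, 4)
tseed <- cfg$seed + 20

message("generating ground-truth targets at ", paste(conc, collapse = ", "),
        " M ...")
targets <- list(
  density = simulate_targets("density", conc, ff_truth, bud, seed = tseed),
  surface_tension = simulate_targets("surface_tension", conc, ff_truth,
                                     bud, seed = tseed))
write_target_curve(targets$density, file.path(outdir, "target_density.csv"))
write_target_curve(targets$surface_tension,
                   file.path(outdir, "target_gamma.csv"))

space <- param_space(c("W-SOD", "W-SOD"), c("epsilon", "sigma"),
                     lower = c(0.6, 3.8), upper = c(1.4, 4.7))
obj <- function(th) condition1_objective(
  apply_params(ff_truth, space, th), targets, bud,
  w_density = cfg$fitopt$w_density, w_gamma = 0.1, seed = tseed)

message("running Bayesian optimization (", cfg$fitopt$n_initial, " + ",
        cfg$fitopt$n_iterations, " evaluations) ...")
fit <- bayesian_optimize(obj, space,
                         fit_config(cfg$fitopt$n_initial,
                                    cfg$fitopt$n_iterations,
                                    seed = cfg$seed + 4))
truth <- ff_pair(ff_truth, "W", "SOD")
rel <- abs(fit$best_par - c(truth$epsilon, truth$sigma)) /
  c(truth$epsilon, truth$sigma)
message(sprintf("best objective %.3g at eps = %.4f (truth %.4f, %.1f%% off), sigma = %.4f (truth %.4f, %.1f%% off)",
                fit$best_value, fit$best_par[1], truth$epsilon, 100 * rel[1],
                fit$best_par[2], truth$sigma, 100 * rel[2]))

write.csv(fit$trace, file.path(outdir, "trace.csv"), row.names = FALSE)
ff_best <- apply_params(ff_truth, space, unname(fit$best_par))
write_forcefield(ff_best, file.path(outdir, "bo_optimized.ff"))
write_manifest(cfg, file.path(outdir, c("trace.csv", "bo_optimized.ff",
                                        "target_density.csv",
                                        "target_gamma.csv")),
               c(global = cfg$seed, targets = tseed, bo = cfg$seed + 4),
               file.path(outdir, "manifest.json"))
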