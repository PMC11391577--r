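#!/usr/bin/env Rscript
# Reassessment report: collect the stage outputs and express them as the
# per-concentration relative-deviation tables the fitting pipeline is
# judged by. Requires 03 and 05/06 to have run. Writes
# results/deviation_report.csv.

library(cgionfit)

cfg <- run_config()
stopifnot(file.exists(file.path("results", "bulk_properties.csv")))
bulk <- read.csv(file.path("results", "bulk_properties.csv"))

rows <- rbind(
  data.frame(property = "density", molarity = bulk$molarity,
             target = bulk$density_target, simulated = bulk$density),
  data.frame(property = "surface_tension", molarity = bulk$molarity,
             target = bulk$gamma_target, simulated = bulk$gamma))
rows$rel_dev <- (rows$simulated - rows$target) / rows$target
write.csv(rows, file.path("results", "deviation_report.csv"),
          row.names = FALSE)

for (p in unique(rows$property))
  message(sprintf("%-16s max |rel dev| = %.1f%%", p,
                  100 * max(abs(rows$rel_dev[rows$property == p]))))

fit_dir <- file.path("results", "fit_condition1")
if (file.exists(file.path(fit_dir, "trace.csv"))) {
  tr <- read.csv(file.path(fit_dir, "trace.csv"), check.names = FALSE)
  message(sprintf("condition-1 fit: best objective %.3g after %d evaluations",
                  min(tr$objective, na.rm = TRUE), nrow(tr)))
}
fit2 <- file.path("results", "fit_condition2", "tune_trace.csv")
if (file.exists(fit2)) {
  t2 <- read.csv(fit2)
  message(sprintf("condition-2 tuning: %d evaluations, final Pi %.1f bar",
                  nrow(t2), t2$pi[which.min(t2$objective)]))
}
write_manifest(cfg, file.path("results", "deviation_report.csv"),
               c(global = cfg$seed),
               file.path("results", "report_manifest.json"))
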