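#!/usr/bin/env Rscript
# Build every system geometry the pipeline uses (bulk electrolyte boxes,
# z-tripled slab, three-compartment osmotic cell, decane-like biphasic
# stack, toy bilayer) at desk scale and write them as LAMMPS-style data
# files with a run manifest. Later stages rebuild systems on the fly;
# this stage exists to inspect geometries and to document the formats.

library(cgionfit)

cfg <- run_config(sysgen = list(total_beads = 600))
dir.create(file.path("results", "systems"), recursive = TRUE,
           showWarnings = FALSE)
ff <- default_forcefield(cfg$sysgen$ion_model)
out <- character()

for (m in c(0, 1, 3, 5)) {
  sys <- make_bulk(m, ff, cfg$sysgen$total_beads, seed = cfg$seed + m)
  f <- file.path("results", "systems", sprintf("bulk_%gM.data", m))
  write_lammps_data(sys, ff, f)
  out <- c(out, f)
  message(sprintf("bulk %g M: %d beads in a %.1f A box", m, n_beads(sys),
                  sys$box[1]))
}

slab <- make_slab(make_bulk(1, ff, cfg$sysgen$total_beads,
                            seed = cfg$seed))
f <- file.path("results", "systems", "slab_1M.data")
write_lammps_data(slab, ff, f); out <- c(out, f)
message(sprintf("slab: Lz tripled to %.1f A", slab$box[3]))

cell <- make_osmotic(3, ff, total_beads = 400, seed = cfg$seed)
f <- file.path("results", "systems", "osmotic_3M.data")
write_lammps_data(cell$system, ff, f); out <- c(out, f)
message(sprintf("osmotic cell: %d beads, walls at x = %.1f and %.1f A",
                n_beads(cell$system), cell$walls[[1]]$position,
                cell$walls[[2]]$position))

bi <- make_biphasic("decane_like", n_oil = 100, n_aqueous = 500,
                    molarity = 1, ff = ff, seed = cfg$seed)
f <- file.path("results", "systems", "biphasic_decane_1M.data")
write_lammps_data(bi, ff, f); out <- c(out, f)
message(sprintf("biphasic: %d oil beads under %d aqueous beads",
                sum(bi$types %in% c("CT", "CM")),
                sum(!bi$types %in% c("CT", "CM"))))

bl <- make_toy_bilayer(32, molarity = 0.5, ff = ff, seed = cfg$seed)
f <- file.path("results", "systems", "bilayer_32.data")
write_lammps_data(bl, ff, f); out <- c(out, f)
message(sprintf("bilayer: %d lipids/leaflet, %d beads total", 32,
                n_beads(bl)))

write_forcefield(ff, file.path("results", "systems", "default.ff"))
out <- c(out, file.path("results", "systems", "default.ff"))
write_manifest(cfg, out, c(global = cfg$seed),
               file.path("results", "systems", "manifest.json"))
message("wrote ", length(out), " artifacts + manifest")
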