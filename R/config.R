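#' Run configuration with fail-fast validation
#'
#' A nested list keyed by pipeline stage (`sysgen`, `engine`,
#' `observables`, `fitopt`) plus `seed`, `outdir` and `full_scale`.
#' Unknown sections or keys are rejected so typos cannot silently fall
#' back to defaults. The canonical hash of the configuration is recorded
#' in every output manifest.
#'
#' @param ... named overrides, e.g. `sysgen = list(total_beads = 400)`
#' @return list of class `run_config`
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1, outdir = "results", full_scale = FALSE,
    sysgen = list(total_beads = 1100, min_dist = 3.4, ion_model = "solvated",
                  waters_per_ion = 3, molarity_grid = seq(0.5, 5, 0.5)),
    engine = list(dt = 10, temperature_bulk = 293, temperature_osmotic = 298,
                  cutoff = 15, n_equil = 600, n_prod = 1800,
                  sample_every = 10, es_method = "ewald"),
    observables = list(window = 0.25, n_blocks = 5),
    fitopt = list(n_initial = 10, n_iterations = 30, w_density = 1,
                  w_gamma = 1, pi_tolerance = 0.05))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(over)) {
    if (is.list(defaults[[sec]])) {
      badk <- setdiff(names(over[[sec]]), names(defaults[[sec]]))
      if (length(badk))
        stop("unknown key(s) in [", sec, "]: ", paste(badk, collapse = ", "))
      defaults[[sec]] <- modifyList(defaults[[sec]], over[[sec]])
    } else defaults[[sec]] <- over[[sec]]
  }
  structure(defaults, class = "run_config")
}

#' Canonical hash of a run configuration
#'
#' Serializes the configuration to canonical sorted-key text and hashes
#' it (MD5); the hash changes iff a semantic field changes.
#'
#' @param cfg a [run_config()]
#' @return hex string
#' @export
config_hash <- function(cfg) {
  canon <- function(x, prefix = "") {
    if (is.list(x)) {
      nms <- sort(names(x))
      unlist(lapply(nms, function(n)
        canon(x[[n]], paste0(prefix, n, "."))))
    } else paste0(prefix, "=", paste(format(x, digits = 17), collapse = ","))
  }
  txt <- paste(canon(unclass(cfg)), collapse = "\n")
  f <- tempfile(); on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Write a run manifest
#'
#' Records the configuration hash, the seeds consumed, the package
#' version and an MD5 checksum for every output file, as JSON. Any
#' result can be regenerated from its manifest (same platform, same
#' package version) because all stochasticity is seed-derived.
#'
#' @param cfg a [run_config()]
#' @param files character vector of output file paths
#' @param seeds named numeric vector of seeds consumed by the run
#' @param path manifest output path (JSON)
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(cfg, files, seeds, path) {
  files <- files[file.exists(files)]
  man <- list(
    config_hash = config_hash(cfg),
    seeds = as.list(seeds),
    package_version = as.character(utils::packageVersion("cgionfit")),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
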