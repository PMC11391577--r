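#' Synthetic default force-field table
#'
#' A complete, self-consistent parameter set for the species this
#' pipeline simulates: 3-water beads (`W`), sodium and chloride beads in
#' solvated (ion + grouped waters) or bare variants, a 3-bead
#' decane-like alkane (`CT`-`CM`-`CT`) and a 4-bead toy amphiphile
#' (choline-like `NC`(+1) - phosphate-like `PH`(-1) - two tail beads
#' `TL`). Water-water and water-ion pairs use the LJ 12-4 form; all other
#' pairs use LJ 9-6. The values are the package's own synthetic
#' defaults: they are chosen to give a water-like liquid (density near
#' 1000 kg/m^3, cohesive slab) and physically plausible ion behavior at
#' desk scale, and are the starting point that the fitting pipeline
#' re-optimizes. They are not a published parameter library.
#'
#' @param ion_model `"solvated"` (ion bead includes `waters_per_ion`
#'   water molecules) or `"bare"`
#' @param waters_per_ion water molecules grouped into each solvated ion
#'   bead (default 3, configurable; bare ions carry 0)
#' @param cutoff nonbonded cutoff, A
#' @param es_method electrostatics method (`"ewald"`,
#'   `"cutoff_shifted"`, `"none"`)
#' @return a `cg_forcefield`
#' @export
default_forcefield <- function(ion_model = c("solvated", "bare"),
                               waters_per_ion = 3, cutoff = 15,
                               es_method = "ewald") {
  ion_model <- match.arg(ion_model)
  m_w <- 18.01528
  solv <- ion_model == "solvated"
  nwi <- if (solv) waters_per_ion else 0
  bt <- rbind(
    bead_type("W",   3 * m_w, 0, "water", 3),
    bead_type("SOD", 22.9898 + nwi * m_w, +1, "cation", nwi),
    bead_type("CLA", 35.4530 + nwi * m_w, -1, "anion", nwi),
    bead_type("CT", 43.089, 0, "alkane"),
    bead_type("CM", 42.081, 0, "alkane"),
    bead_type("NC", 87.164, +1, "headgroup"),
    bead_type("PH", 94.971, -1, "headgroup"),
    bead_type("TL", 56.108, 0, "alkane"))

  P <- function(a, b, e, s, f = "LJ9_6")
    data.frame(type_i = a, type_j = b, epsilon = e, sigma = s, form = f)
  if (solv) {
    ion_pairs <- rbind(
      P("W", "SOD", 0.95, 4.25, "LJ12_4"),
      P("W", "CLA", 0.95, 4.35, "LJ12_4"),
      P("SOD", "SOD", 0.35, 4.30),
      P("CLA", "CLA", 0.35, 4.50),
      P("SOD", "CLA", 0.50, 4.40))
    ion_alk_sig <- c(SOD = 4.45, CLA = 4.55)
  } else {
    ion_pairs <- rbind(
      P("W", "SOD", 0.80, 3.40, "LJ12_4"),
      P("W", "CLA", 0.80, 3.95, "LJ12_4"),
      P("SOD", "SOD", 0.30, 2.60),
      P("CLA", "CLA", 0.30, 4.00),
      P("SOD", "CLA", 0.40, 3.30))
    ion_alk_sig <- c(SOD = 3.60, CLA = 4.30)
  }
  pairs <- rbind(
    P("W", "W", 0.90, 4.38, "LJ12_4"),
    ion_pairs,
    # alkane and oil-water cross terms (hydrophobic: sub-geometric epsilon)
    P("CT", "CT", 0.42, 4.60), P("CM", "CM", 0.40, 4.60),
    P("CT", "CM", 0.41, 4.60),
    P("W", "CT", 0.35, 4.40), P("W", "CM", 0.33, 4.40),
    P("SOD", "CT", 0.36, ion_alk_sig["SOD"]),
    P("SOD", "CM", 0.35, ion_alk_sig["SOD"]),
    P("CLA", "CT", 0.36, ion_alk_sig["CLA"]),
    P("CLA", "CM", 0.35, ion_alk_sig["CLA"]),
    # toy amphiphile
    P("NC", "NC", 0.70, 5.00), P("PH", "PH", 0.90, 4.60),
    P("NC", "PH", 0.80, 4.80),
    P("W", "NC", 0.85, 4.60), P("W", "PH", 0.95, 4.50),
    P("SOD", "NC", 0.40, 4.60), P("SOD", "PH", 0.70, 4.30),
    P("CLA", "NC", 0.70, 4.60), P("CLA", "PH", 0.40, 4.50),
    P("TL", "TL", 0.42, 4.60), P("TL", "CT", 0.42, 4.60),
    P("TL", "CM", 0.41, 4.60),
    P("W", "TL", 0.36, 4.50),
    P("SOD", "TL", 0.35, ion_alk_sig["SOD"]),
    P("CLA", "TL", 0.35, ion_alk_sig["CLA"]),
    P("NC", "TL", 0.40, 4.80), P("PH", "TL", 0.40, 4.60))
  rownames(pairs) <- NULL

  B <- function(a, b, k, r0)
    data.frame(type_i = a, type_j = b, k = k, r0 = r0)
  bonds <- rbind(
    B("CT", "CM", 6.0, 3.6),
    B("NC", "PH", 12.0, 3.4),
    B("PH", "TL", 8.0, 3.6),
    B("TL", "TL", 6.0, 3.3))
  A <- function(a, b, c, k, th, corr)
    data.frame(type_i = a, type_j = b, type_k = c, k = k, theta0 = th,
               corr = corr)
  angles <- rbind(
    A("CT", "CM", "CT", 1.5, 173, TRUE),
    A("NC", "PH", "TL", 1.5, 112, TRUE),
    A("PH", "TL", "TL", 1.5, 168, TRUE))

  cg_forcefield(bt, pairs, bonds, angles,
                electrostatics = list(relative_permittivity = 80,
                                      method = es_method,
                                      real_space_cutoff = cutoff,
                                      accuracy_s = 3.0),
                cutoff = cutoff)
}
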