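#' Define a coarse-grained bead type
#'
#' A bead is a pseudo-particle standing for several atoms or molecules: a
#' 3-water bead, an ion with (solvated model) or without (bare model) its
#' accompanying water molecules, an alkane fragment, or a lipid headgroup
#' fragment. `waters_included` records how many water molecules the bead
#' subsumes so concentration and density bookkeeping can attribute them.
#'
#' @param name short identifier, e.g. `"W"`, `"SOD"`, `"CLA"`
#' @param mass bead mass in amu (> 0)
#' @param charge charge in elementary units; monovalent species only, so
#'   `abs(charge)` must be 0 or 1
#' @param category one of `"water"`, `"cation"`, `"anion"`, `"alkane"`,
#'   `"headgroup"`, `"other"`
#' @param waters_included number of water molecules grouped into the bead
#' @return one-row data frame usable as a `bead_types` entry
#' @export
bead_type <- function(name, mass, charge = 0,
                      category = c("other", "water", "cation", "anion",
                                   "alkane", "headgroup"),
                      waters_included = 0) {
  category <- match.arg(category)
  stopifnot(mass > 0, abs(charge) %in% c(0, 1), waters_included >= 0)
  data.frame(name = name, mass = mass, charge = charge, category = category,
             waters_included = waters_included, stringsAsFactors = FALSE)
}

#' Construct a force-field table
#'
#' The interaction model is fully explicit: every unordered pair of bead
#' types that co-occurs in a simulated system must have its own
#' Lennard-Jones entry (`LJ9_6` or `LJ12_4`). No combination rule is
#' applied at evaluation time; an optional Lorentz-Berthelot fallback can
#' be enabled but warns on every use, because cross terms are objects of
#' optimization here, not derived quantities.
#'
#' Bonded terms use the convention \eqn{U = k (x - x_0)^2} (no factor 1/2),
#' switchable via `bond_prefactor`.
#'
#' @param bead_types data frame of [bead_type()] rows
#' @param pairs data frame with columns `type_i, type_j, epsilon, sigma,
#'   form` (`epsilon` kcal/mol, `sigma` A, `form` in `"LJ9_6"`, `"LJ12_4"`)
#' @param bonds data frame `type_i, type_j, k, r0` (k kcal/mol/A^2, r0 A)
#' @param angles data frame `type_i, type_j, type_k, k, theta0, corr`
#'   (k kcal/mol/rad^2, theta0 degrees, corr logical: add the repulsive
#'   1-3 LJ term guarding against angle collapse)
#' @param electrostatics list with `relative_permittivity` (>= 1),
#'   `method` (`"ewald"`, `"cutoff_shifted"` or `"none"`),
#'   `real_space_cutoff` (A) and `accuracy_s` (dimensionless Ewald
#'   accuracy factor; `alpha = accuracy_s / cutoff`)
#' @param cutoff nonbonded LJ cutoff in A (default 15)
#' @param lj_shift shift LJ energies to vanish at the cutoff (engine
#'   default; the bare pair functions are unshifted)
#' @param bond_prefactor 1 for the \eqn{k (x-x_0)^2} convention, 0.5 for
#'   the half-factor convention
#' @param mixing_fallback allow Lorentz-Berthelot completion of missing
#'   pairs (with a warning per completed pair)
#' @return object of class `cg_forcefield`
#' @export
cg_forcefield <- function(bead_types, pairs,
                          bonds = empty_bonds(), angles = empty_angles(),
                          electrostatics = list(), cutoff = 15,
                          lj_shift = TRUE, bond_prefactor = 1,
                          mixing_fallback = FALSE) {
  es <- modifyList(list(relative_permittivity = 80, method = "ewald",
                        real_space_cutoff = cutoff, accuracy_s = 3.0),
                   electrostatics)
  stopifnot(es$relative_permittivity >= 1, es$real_space_cutoff > 0,
            es$method %in% c("ewald", "cutoff_shifted", "none"),
            cutoff > 0, bond_prefactor > 0)
  stopifnot(all(pairs$epsilon > 0), all(pairs$sigma > 0),
            all(pairs$form %in% c("LJ9_6", "LJ12_4")))
  if (nrow(bonds)) stopifnot(all(bonds$r0 > 0), all(bonds$k >= 0))
  if (nrow(angles)) stopifnot(all(angles$theta0 > 0), all(angles$theta0 <= 180))
  ff <- structure(list(
    bead_types = as.data.frame(bead_types),
    pairs = as.data.frame(pairs),
    bonds = as.data.frame(bonds),
    angles = as.data.frame(angles),
    electrostatics = es,
    options = list(cutoff = cutoff, lj_shift = lj_shift,
                   bond_prefactor = bond_prefactor,
                   mixing_fallback = mixing_fallback)
  ), class = "cg_forcefield")
  dup <- duplicated(t(apply(ff$pairs[, c("type_i", "type_j")], 1, sort)))
  if (any(dup))
    stop("duplicate pair entries (pairs are unordered): ",
         paste(ff$pairs$type_i[dup], ff$pairs$type_j[dup], collapse = ", "))
  ff
}

empty_bonds <- function()
  data.frame(type_i = character(), type_j = character(),
             k = numeric(), r0 = numeric(), stringsAsFactors = FALSE)

empty_angles <- function()
  data.frame(type_i = character(), type_j = character(), type_k = character(),
             k = numeric(), theta0 = numeric(), corr = logical(),
             stringsAsFactors = FALSE)

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("<cg_forcefield>", nrow(x$bead_types), "bead types,",
      nrow(x$pairs), "pair entries,", nrow(x$bonds), "bond types,",
      nrow(x$angles), "angle types\n")
  cat("  cutoff", x$options$cutoff, "A; electrostatics:",
      x$electrostatics$method, "(eps_r =",
      x$electrostatics$relative_permittivity, ")\n")
  invisible(x)
}

# canonical unordered pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

#' Look up the pair potential for two bead types
#'
#' Lookup is symmetric: `ff_pair(ff, a, b)` and `ff_pair(ff, b, a)` return
#' the same entry.
#'
#' @param ff a `cg_forcefield`
#' @param a,b bead type names
#' @return one-row data frame (`type_i, type_j, epsilon, sigma, form`) or
#'   `NULL` if absent
#' @export
ff_pair <- function(ff, a, b) {
  k <- pair_key(ff$pairs$type_i, ff$pairs$type_j)
  hit <- which(k == pair_key(a, b))
  if (!length(hit)) return(NULL)
  ff$pairs[hit[1], , drop = FALSE]
}

#' Replace (or insert) one pair entry
#'
#' @inheritParams ff_pair
#' @param epsilon,sigma,form new values; `NULL` keeps the current one
#' @return modified `cg_forcefield`
#' @export
ff_set_pair <- function(ff, a, b, epsilon = NULL, sigma = NULL, form = NULL) {
  k <- pair_key(ff$pairs$type_i, ff$pairs$type_j)
  hit <- which(k == pair_key(a, b))
  if (!length(hit)) {
    stopifnot(!is.null(epsilon), !is.null(sigma), !is.null(form))
    ff$pairs <- rbind(ff$pairs,
                      data.frame(type_i = a, type_j = b, epsilon = epsilon,
                                 sigma = sigma, form = form))
  } else {
    if (!is.null(epsilon)) ff$pairs$epsilon[hit[1]] <- epsilon
    if (!is.null(sigma)) ff$pairs$sigma[hit[1]] <- sigma
    if (!is.null(form)) ff$pairs$form[hit[1]] <- form
  }
  ff
}

#' Lennard-Jones pair energy and radial force
#'
#' Evaluates the SPICA-style LJ forms. `LJ9_6`:
#' \eqn{U = \frac{27}{4}\epsilon[(\sigma/r)^9 - (\sigma/r)^6]}; `LJ12_4`:
#' \eqn{U = \frac{3\sqrt3}{2}\epsilon[(\sigma/r)^{12} - (\sigma/r)^4]}.
#' Both cross zero at \eqn{r = \sigma} and have well depth exactly
#' \eqn{-\epsilon} (at \eqn{(3/2)^{1/3}\sigma} and \eqn{3^{1/8}\sigma}
#' respectively). The radial force is \eqn{-dU/dr} (positive = repulsive).
#' Beyond `cutoff` both are exactly zero; energies are unshifted here
#' (the engine applies the cutoff shift separately).
#'
#' @param r distance(s) in A, must be > 0
#' @param epsilon well depth, kcal/mol
#' @param sigma zero-crossing distance, A
#' @param form `"LJ9_6"` or `"LJ12_4"`
#' @param cutoff truncation distance in A (default `Inf`)
#' @return list with vectors `energy` (kcal/mol) and `force` (kcal/mol/A)
#' @export
pair_energy_force <- function(r, epsilon, sigma, form = c("LJ9_6", "LJ12_4"),
                              cutoff = Inf) {
  form <- match.arg(form)
  if (any(r <= 0)) stop("r must be positive (overlapping beads)")
  sr <- sigma / r
  if (form == "LJ9_6") {
    u <- 6.75 * epsilon * (sr^9 - sr^6)
    f <- 6.75 * epsilon * (9 * sr^9 - 6 * sr^6) / r
  } else {
    c124 <- 3 * sqrt(3) / 2
    u <- c124 * epsilon * (sr^12 - sr^4)
    f <- c124 * epsilon * (12 * sr^12 - 4 * sr^4) / r
  }
  out <- r > cutoff
  u[out] <- 0; f[out] <- 0
  list(energy = u, force = f)
}

#' Real-space Coulomb pair energy and force
#'
#' The screened-charge convention of the parent force field: charges
#' interact through a uniform relative permittivity (default 80), so the
#' bare pairwise term is \eqn{U = C q_i q_j / (\epsilon_r r)} with
#' \eqn{C = 332.0637} kcal A/(mol e^2). With `method = "cutoff_shifted"`
#' the energy is shifted to vanish at the cutoff; with `"ewald"` this
#' function reports the bare term (the engine adds the reciprocal-space
#' part during simulation).
#'
#' @param r distance(s), A (> 0)
#' @param q_i,q_j charges, e
#' @param es electrostatics spec (list as in [cg_forcefield()])
#' @return list with `energy` (kcal/mol) and `force` (kcal/mol/A)
#' @export
coulomb_energy_force <- function(r, q_i, q_j,
                                 es = list(relative_permittivity = 80,
                                           method = "ewald",
                                           real_space_cutoff = 15)) {
  if (any(r <= 0)) stop("r must be positive")
  pref <- cg_units$coulomb * q_i * q_j / es$relative_permittivity
  u <- pref / r
  f <- pref / r^2
  if (identical(es$method, "cutoff_shifted")) {
    rc <- es$real_space_cutoff
    u <- ifelse(r > rc, 0, u - pref / rc)
    f <- ifelse(r > rc, 0, f)
  }
  list(energy = u, force = f)
}

#' Scaling rule for selected cross interactions
#'
#' For ion-alkane style cross terms the LJ parameters are not re-optimized
#' but scaled: \eqn{\epsilon' = \kappa_\epsilon \epsilon},
#' \eqn{\sigma' = \kappa_\sigma \sigma} for every selected pair. All other
#' entries are returned bit-identical.
#'
#' @param ff a `cg_forcefield`
#' @param kappa_epsilon,kappa_sigma positive scale factors
#' @param types_a,types_b character vectors; every pair with one type in
#'   `types_a` and the other in `types_b` is selected
#' @return new `cg_forcefield`
#' @export
apply_scaling <- function(ff, kappa_epsilon = 1, kappa_sigma = 1,
                          types_a, types_b) {
  stopifnot(kappa_epsilon > 0, kappa_sigma > 0)
  sel <- (ff$pairs$type_i %in% types_a & ff$pairs$type_j %in% types_b) |
         (ff$pairs$type_i %in% types_b & ff$pairs$type_j %in% types_a)
  if (!any(sel))
    stop("scaling selector matched no pairs (types_a = ",
         paste(types_a, collapse = ","), "; types_b = ",
         paste(types_b, collapse = ","), ")")
  ff$pairs$epsilon[sel] <- kappa_epsilon * ff$pairs$epsilon[sel]
  ff$pairs$sigma[sel] <- kappa_sigma * ff$pairs$sigma[sel]
  ff
}

#' Validate a force-field table against a system composition
#'
#' Reports missing pair entries, non-positive parameters and invalid
#' charges/masses. An empty report means the table is complete for the
#' composition.
#'
#' @param ff a `cg_forcefield`
#' @param composition character vector of bead type names present in the
#'   system (duplicates ignored)
#' @return data frame with columns `finding` and `detail`; zero rows if valid
#' @export
validate_table <- function(ff, composition) {
  comp <- unique(composition)
  rep <- data.frame(finding = character(), detail = character(),
                    stringsAsFactors = FALSE)
  add <- function(f, d) rbind(rep, data.frame(finding = f, detail = d))
  unknown <- setdiff(comp, ff$bead_types$name)
  for (u in unknown) rep <- add("unknown_type", u)
  comp <- intersect(comp, ff$bead_types$name)
  if (length(comp) >= 1) {
    combos <- expand.grid(a = comp, b = comp, stringsAsFactors = FALSE)
    combos <- combos[combos$a <= combos$b, ]
    keys <- pair_key(ff$pairs$type_i, ff$pairs$type_j)
    for (i in seq_len(nrow(combos))) {
      k <- pair_key(combos$a[i], combos$b[i])
      if (!k %in% keys) rep <- add("missing_pair", k)
    }
  }
  bad <- ff$pairs$epsilon <= 0 | ff$pairs$sigma <= 0
  for (i in which(bad))
    rep <- add("invalid_pair_parameter",
               paste0(ff$pairs$type_i[i], "-", ff$pairs$type_j[i]))
  badm <- ff$bead_types$mass <= 0
  for (i in which(badm)) rep <- add("invalid_mass", ff$bead_types$name[i])
  badq <- !abs(ff$bead_types$charge) %in% c(0, 1)
  for (i in which(badq)) rep <- add("invalid_charge", ff$bead_types$name[i])
  if (nrow(ff$bonds) && any(ff$bonds$r0 <= 0))
    rep <- add("invalid_bond_r0", "r0 <= 0")
  if (nrow(ff$angles) && any(ff$angles$theta0 <= 0 | ff$angles$theta0 > 180))
    rep <- add("invalid_angle_theta0", "theta0 outside (0, 180]")
  rep
}

# --- internal: pack a force field for the C++ kernels ----------------------
# type_names fixes the integer type indexing used by the system
ff_pack <- function(ff, type_names) {
  nt <- length(type_names)
  idx <- match(type_names, ff$bead_types$name)
  if (anyNA(idx))
    stop("bead types not in table: ",
         paste(type_names[is.na(idx)], collapse = ", "))
  eps <- sig <- matrix(0, nt, nt)
  form <- matrix(0L, nt, nt)
  keys <- pair_key(ff$pairs$type_i, ff$pairs$type_j)
  for (i in seq_len(nt)) for (j in i:nt) {
    k <- pair_key(type_names[i], type_names[j])
    hit <- which(keys == k)
    if (length(hit)) {
      p <- ff$pairs[hit[1], ]
    } else if (isTRUE(ff$options$mixing_fallback)) {
      pi_ <- ff_pair(ff, type_names[i], type_names[i])
      pj_ <- ff_pair(ff, type_names[j], type_names[j])
      if (is.null(pi_) || is.null(pj_))
        stop("missing pair ", k, " and no self terms for fallback")
      warning("Lorentz-Berthelot fallback used for pair ", k)
      p <- data.frame(epsilon = sqrt(pi_$epsilon * pj_$epsilon),
                      sigma = (pi_$sigma + pj_$sigma) / 2,
                      form = "LJ9_6")
    } else stop("missing pair entry: ", k,
                " (explicit pairs required; see mixing_fallback)")
    eps[i, j] <- eps[j, i] <- p$epsilon
    sig[i, j] <- sig[j, i] <- p$sigma
    form[i, j] <- form[j, i] <- if (p$form == "LJ9_6") 1L else 2L
  }
  es_code <- switch(ff$electrostatics$method,
                    none = 0L, cutoff_shifted = 1L, ewald = 2L)
  list(eps = eps, sig = sig, form = form,
       cutoff = ff$options$cutoff,
       lj_shift = isTRUE(ff$options$lj_shift),
       es_method = es_code,
       eps_r = ff$electrostatics$relative_permittivity,
       ewald_s = ff$electrostatics$accuracy_s,
       charge = ff$bead_types$charge[idx],
       mass = ff$bead_types$mass[idx],
       bond_prefactor = ff$options$bond_prefactor)
}
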