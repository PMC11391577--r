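#' Physical constants and unit conversions
#'
#' The engine works in Angstrom / femtosecond / amu / kcal/mol internally;
#' observables are reported in the field's conventional units (kg/m^3 for
#' density, mN/m for tension, bar for pressure). All conversion factors are
#' centralized here.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/mol/K.}
#'   \item{coulomb}{Coulomb prefactor, kcal*A/(mol*e^2).}
#'   \item{avogadro}{Avogadro's number, 1/mol.}
#'   \item{R_gas}{Gas constant, J/mol/K.}
#'   \item{kcal_per_mvv}{1 amu*A^2/fs^2 expressed in kcal/mol.}
#'   \item{bar_per_kcal_A3}{1 kcal/mol/A^3 expressed in bar.}
#'   \item{kgm3_per_amu_A3}{1 amu/A^3 expressed in kg/m^3.}
#'   \item{mNm_per_bar_A}{1 bar*A expressed in mN/m.}
#' }
#' @export
cg_units <- list(
  kB              = 0.0019872041,
  coulomb         = 332.0637,
  avogadro        = 6.02214076e23,
  R_gas           = 8.31446261815324,
  kcal_per_mvv    = 2390.057361,
  bar_per_kcal_A3 = 69476.95457,
  kgm3_per_amu_A3 = 1660.53906660,
  mNm_per_bar_A   = 1e-2
)

#' Van 't Hoff osmotic pressure of an ideal solute
#'
#' \eqn{\Pi = c_{tot} R T}, the dilute ideal limit against which the
#' virtual-wall osmotic estimator is validated.
#'
#' @param molar_total total solute concentration in mol/L (for a fully
#'   dissociated 1:1 salt this is twice the salt molarity)
#' @param temperature temperature in K
#' @return osmotic pressure in bar
#' @export
vant_hoff_pressure <- function(molar_total, temperature = 298) {
  # mol/L -> mol/m^3 is *1000; Pa -> bar is /1e5
  molar_total * 1000 * cg_units$R_gas * temperature / 1e5
}
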