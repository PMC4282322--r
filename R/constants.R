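## Physical constants used throughout. Energies in kcal/mol, lengths in
## Angstrom, charges in elementary charges, masses in amu, temperature in K.

#' Physical constants
#'
#' Named list of the constants the package computes with:
#' \describe{
#'   \item{coulomb}{Coulomb constant, 332.0716 kcal A / (mol e^2)}
#'   \item{R}{gas constant, 1.9872e-3 kcal/mol/K}
#'   \item{avogadro}{Avogadro's number, 1/mol}
#'   \item{hc_over_k}{h*c/k_B in cm K (converts wavenumbers to kT units)}
#'   \item{freq_factor}{cm^-1 per sqrt(kcal/mol/A^2/amu) for normal modes}
#' }
#' @export
flexpbsa_constants <- list(
  coulomb     = 332.0716,
  R           = 1.9872e-3,
  avogadro    = 6.02214076e23,
  # h*c/k_B = 1.438777 cm K
  hc_over_k   = 1.438777,
  # omega = sqrt(lambda [kcal/mol/A^2/amu]) * 2.04553e13 rad/s;
  # nu~ = omega/(2 pi c) => 108.591 cm^-1 per sqrt unit
  freq_factor = 108.5914,
  # Planck over (amu * A^2) pieces folded into entropy formulas below
  h_J         = 6.62607015e-34,
  kB_J        = 1.380649e-23,
  amu_kg      = 1.66053907e-27
)

kCOUL <- flexpbsa_constants$coulomb
kR    <- flexpbsa_constants$R
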