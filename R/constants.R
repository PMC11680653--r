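# Physical constants (CODATA 2018 exact values where defined).
# Energies are kcal/mol package-wide; lengths m; viscosity Pa s.
.kB <- 1.380649e-23          # Boltzmann constant, J/K
.h  <- 6.62607015e-34        # Planck constant, J s
.NA <- 6.02214076e23         # Avogadro number, 1/mol
.c_cm <- 2.99792458e10       # speed of light, cm/s
.Rkcal <- 1.98720e-3         # gas constant, kcal/(mol K)
.hartree2kcal <- 627.5095    # hartree -> kcal/mol
# 1 cm^-1 expressed in kcal/mol: h * c * NA / 4184
.wavenumber2kcal <- .h * .c_cm * .NA / 4184

#' Physical constants used by the kinetics layer
#'
#' Returns the constants the rate-constant machinery relies on, mainly so
#' they can be inspected and used in downstream scripts without retyping.
#'
#' @return Named list with elements `kB` (J/K), `h` (J s), `NA` (1/mol),
#'   `c_cm` (cm/s), `R_kcal` (kcal mol^-1 K^-1), `hartree_to_kcal` and
#'   `wavenumber_to_kcal` (kcal/mol per cm^-1).
#' @examples
#' physicalConstants()$R_kcal
#' @export
physicalConstants <- function() {
  list(kB = .kB, h = .h, `NA` = .NA, c_cm = .c_cm, R_kcal = .Rkcal,
       hartree_to_kcal = .hartree2kcal, wavenumber_to_kcal = .wavenumber2kcal)
}
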