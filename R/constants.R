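#' Physical constants and unit conversions
#'
#' All internal energies are wavenumbers (cm\eqn{^{-1}}), times are
#' femtoseconds, distances Angstrom, transition dipoles Debye, charges
#' elementary charges and electric fields atomic units (e/a0^2).  The
#' conversions are assembled from CODATA values at load time rather than
#' transcribed, so every formula in the package shares one set of factors.
#'
#' `exc_const` is a list with elements:
#' \describe{
#'   \item{cm1_per_ev}{wavenumbers per eV (8065.544...)}
#'   \item{kB_cm1}{Boltzmann constant, cm\eqn{^{-1}}/K (0.6950348...)}
#'   \item{c_cmfs}{speed of light in cm/fs; the phase accumulated by a state of
#'     energy E (cm\eqn{^{-1}}) over t fs is \eqn{2\pi c E t}}
#'   \item{twopic}{\eqn{2\pi c} in rad/(cm\eqn{^{-1}} fs), 1.8836516e-4}
#'   \item{dipole_coupling_cm1}{point dipole-dipole prefactor f in
#'     cm\eqn{^{-1}} \eqn{\AA^3}/D\eqn{^2} (about 5034), derived from e,
#'     \eqn{\varepsilon_0}, h and c}
#'   \item{bohr_A}{Bohr radius in Angstrom}
#'   \item{au_field_V_per_A}{one atomic unit of electric field in V/\eqn{\AA}
#'     (51.422...); note 0.01 au = 0.514 V/\eqn{\AA}}
#' }
#'
#' @examples
#' exc_const$cm1_per_ev
#' # dimer of parallel 1 D dipoles, perpendicular to a 10 A separation:
#' exc_const$dipole_coupling_cm1 / 1000
#' @export
exc_const <- local({
  h    <- 6.62607015e-34     # J s (exact)
  c_ms <- 2.99792458e8       # m/s (exact)
  e    <- 1.602176634e-19    # C (exact)
  kB   <- 1.380649e-23       # J/K (exact)
  eps0 <- 8.8541878128e-12   # F/m
  a0   <- 5.29177210903e-11  # m
  debye <- 1e-21 / c_ms      # C m (1 D = 1e-18 statC cm)

  hc_Jcm <- h * c_ms * 100   # J per cm^-1
  f_dip  <- debye^2 / (4 * pi * eps0 * 1e-30) / hc_Jcm  # cm^-1 A^3 / D^2

  list(
    cm1_per_ev = e / hc_Jcm,
    kB_cm1     = kB / hc_Jcm,
    c_cmfs     = c_ms * 100 * 1e-15,
    twopic     = 2 * pi * c_ms * 100 * 1e-15,
    dipole_coupling_cm1 = f_dip,
    bohr_A     = a0 * 1e10,
    au_field_V_per_A = e / (4 * pi * eps0 * a0^2) / 1e10
  )
})
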