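#' Physical constants used throughout the package
#'
#' Single authoritative definition of the unit bridge between diffusion
#' coefficients and spectral line widths.  Energies are expressed in micro-eV
#' (ueV), times in nanoseconds and lengths in Angstroem, so that a Fickian
#' line has half-width at half-maximum (HWHM) `gamma = hbar * D * q^2` in ueV
#' when `D` is in A^2/ns and `q` in 1/A.
#'
#' @return Named list with elements
#'   \describe{
#'     \item{hbar}{reduced Planck constant, 0.6582119 ueV ns}
#'     \item{planck_h}{Planck constant, 4.135668 ueV ns}
#'   }
#' @examples
#' qens_constants()$hbar
#' @export
qens_constants <- function() {
  list(hbar = 0.6582119, planck_h = 4.135668)
}

# internal shorthand
.hbar <- function() 0.6582119
.planck_h <- function() 4.135668
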