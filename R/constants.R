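#' Physical constants used throughout the solver
#'
#' Vacuum permittivity is kept at 8.8e-12 F/m, the value the electromagnetic
#' model is parameterized with; the speed of light and free-space impedance are
#' derived from (mu0, eps0) so that k0, beta and the TEM power normalization
#' stay mutually consistent.
#' @keywords internal
#' @name constants
NULL

EPS0 <- 8.8e-12            # vacuum permittivity, F/m
MU0 <- 4e-7 * pi           # vacuum permeability, H/m
C0 <- 1 / sqrt(MU0 * EPS0) # speed of light, m/s
ETA0 <- sqrt(MU0 / EPS0)   # free-space wave impedance, Ohm

REGION_TAGS <- c("liver", "tumor", "dielectric", "catheter", "slot")
SURFACE_TAGS <- c("pec", "port", "exterior")

#' Free-space propagation constant
#'
#' @param frequency frequency in Hz
#' @return k0 in 1/m
#' @export
free_space_k0 <- function(frequency) 2 * pi * frequency / C0
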