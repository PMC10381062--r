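#' Electromagnetic material set
#'
#' Per-region relative permittivity, permeability and electric conductivity
#' at the operating frequency, with the derived angular frequency, free-space
#' propagation constant and complex relative permittivity.
#'
#' Defaults are the dielectric properties of the single-slot antenna and of
#' liver/tumor tissue at 2.45 GHz: dielectric 2.03/1/0, catheter 2.1/1/0,
#' slot 1/1/0, liver 43.03/1/1.69, tumor 48.03/1/2 (eps_r / mu_r / sigma).
#'
#' The solver uses the engineering time convention exp(+j omega t), under
#' which the lossy complex permittivity is
#' eps_R = eps_r - j sigma/(omega eps0) and all absorption mechanisms
#' (volume conduction, port, exterior absorber) are positive-imaginary in
#' the assembled operator.
#'
#' @param frequency operating frequency (Hz)
#' @param eps_r,mu_r,sigma optional named numeric vectors overriding the
#'   per-region defaults (names among liver, tumor, dielectric, catheter, slot)
#' @param eps0 vacuum permittivity (F/m)
#' @return object of class `abl_em_materials`
#' @export
em_materials <- function(frequency = 2.45e9,
                         eps_r = NULL, mu_r = NULL, sigma = NULL,
                         eps0 = EPS0) {
  tab <- data.frame(
    region = REGION_TAGS,
    eps_r = c(43.03, 48.03, 2.03, 2.1, 1),
    mu_r = c(1, 1, 1, 1, 1),
    sigma = c(1.69, 2, 0, 0, 0),
    row.names = REGION_TAGS)
  for (nm in names(eps_r)) tab[nm, "eps_r"] <- eps_r[[nm]]
  for (nm in names(mu_r)) tab[nm, "mu_r"] <- mu_r[[nm]]
  for (nm in names(sigma)) tab[nm, "sigma"] <- sigma[[nm]]
  if (any(tab$eps_r < 1)) stop("eps_r must be >= 1 in every region")
  if (any(tab$sigma < 0)) stop("sigma must be >= 0")
  omega <- 2 * pi * frequency
  structure(list(
    frequency = frequency, omega = omega, eps0 = eps0,
    k0 = free_space_k0(frequency), table = tab,
    eps_R = stats::setNames(
      complex(real = tab$eps_r, imaginary = -tab$sigma / (omega * eps0)),
      REGION_TAGS)
  ), class = "abl_em_materials")
}

# per-element material vectors aligned with mesh$region
region_lookup <- function(materials, mesh, what) {
  idx <- as.integer(mesh$region)
  switch(what,
         eps_r = materials$table$eps_r[idx],
         mu_r = materials$table$mu_r[idx],
         sigma = materials$table$sigma[idx],
         eps_R = materials$eps_R[idx],
         stop("unknown material field"))
}

#' TEM incident field of a coaxial port
#'
#' Radial transverse-electromagnetic profile E(r) = C/r between the inner and
#' outer conductor, with the amplitude C set so that the Poynting flux through
#' the annulus equals the requested input power under the wave impedance of
#' the coax dielectric: C = sqrt(eta P / (pi ln(r_out/r_in))),
#' eta = eta0/sqrt(eps_r). The propagation constant is beta = k0 sqrt(eps_r).
#'
#' Below `r_in` the profile is capped at its `r_in` value (the inner
#' conductor is not resolved on coarse meshes).
#'
#' @param power input power (W)
#' @param r_in,r_out inner/outer conductor radii (m)
#' @param eps_r_diel relative permittivity of the coax dielectric
#' @param frequency frequency (Hz)
#' @param axis x,y position of the coax axis (m)
#' @return list with `beta` (1/m), `C` (V), `field(points)` returning a
#'   complex n x 3 matrix, and the inputs
#' @export
tem_incident_field <- function(power, r_in, r_out, eps_r_diel = 2.03,
                               frequency = 2.45e9, axis = c(0, 0)) {
  if (power < 0) stop("input power must be non-negative")
  if (!(r_in > 0 && r_out > r_in)) stop("need 0 < r_in < r_out")
  eta <- ETA0 / sqrt(eps_r_diel)
  k0 <- free_space_k0(frequency)
  C <- sqrt(eta * power / (pi * log(r_out / r_in)))
  beta <- k0 * sqrt(eps_r_diel)
  field <- function(points) {
    points <- rbind(points)
    dx <- points[, 1] - axis[1]
    dy <- points[, 2] - axis[2]
    r <- sqrt(dx^2 + dy^2)
    rr <- pmax(r, r_in)
    amp <- C / rr
    safe <- pmax(r, 1e-300)
    out <- cbind(amp * dx / safe, amp * dy / safe, 0)
    out + 0i
  }
  list(beta = beta, C = C, field = field, power = power,
       r_in = r_in, r_out = r_out, eps_r_diel = eps_r_diel,
       frequency = frequency, axis = axis)
}
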