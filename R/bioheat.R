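#' Thermal material set for the Pennes bioheat model
#'
#' Per-region density, baseline specific heat and thermal conductivity
#' (tissue 3540/0.497/1030, tumor 3960/0.57/1040 in J/kg.C, W/m.C, kg/m3),
#' blood properties (C_b = 3600 J/kg.C, rho_b = 1058 kg/m3, T_b = 37 C,
#' baseline perfusion 0.0036 1/s), metabolic heat Q_m = 33800 W/m3, and the
#' latent-heat coefficient of the effective specific heat.
#'
#' The antenna regions (dielectric/catheter/slot) are not tissue: they get
#' PTFE-like properties, no perfusion and no metabolic heat.
#'
#' `alpha` (J/kg) couples the water-content slope dW/dT into the effective
#' specific heat C = C_t - alpha dW/dT. It is not fixed by the treatment
#' design tables; the default is the latent heat of water vaporization,
#' 2.26e6 J/kg, applied to the water mass fraction W. With
#' `alpha_grouping = "water_density"` the latent term is scaled by
#' rho_water/rho_tissue instead.
#'
#' @param rho,C_t,k0_th,dk named per-region overrides (see defaults)
#' @param T0_ref reference temperature for k(T) (C)
#' @param rho_b,C_b,T_b,omega0 blood density, specific heat, temperature,
#'   baseline perfusion rate
#' @param Q_m metabolic heat (W/m3), applied in liver and tumor only
#' @param alpha latent-heat coefficient (J/kg)
#' @param alpha_grouping `"mass_fraction"` (default) or `"water_density"`
#' @param dWdT_clamp upper bound on |dW/dT| entering C (1/C)
#' @return object of class `abl_thermal_materials`
#' @export
thermal_materials <- function(rho = NULL, C_t = NULL, k0_th = NULL, dk = NULL,
                              T0_ref = 37,
                              rho_b = 1058, C_b = 3600, T_b = 37,
                              omega0 = 0.0036, Q_m = 33800,
                              alpha = 2.26e6,
                              alpha_grouping = c("mass_fraction",
                                                 "water_density"),
                              dWdT_clamp = 0.1) {
  tab <- data.frame(
    region = REGION_TAGS,
    rho = c(1030, 1040, 2200, 2200, 1.2),
    C_t = c(3540, 3960, 1050, 1050, 1005),
    k0_th = c(0.497, 0.57, 0.25, 0.25, 0.026),
    dk = c(0, 0, 0, 0, 0),
    tissue = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    row.names = REGION_TAGS)
  for (nm in names(rho)) tab[nm, "rho"] <- rho[[nm]]
  for (nm in names(C_t)) tab[nm, "C_t"] <- C_t[[nm]]
  for (nm in names(k0_th)) tab[nm, "k0_th"] <- k0_th[[nm]]
  for (nm in names(dk)) tab[nm, "dk"] <- dk[[nm]]
  if (any(tab$rho <= 0) || any(tab$C_t <= 0) || any(tab$k0_th <= 0))
    stop("rho, C_t and k0_th must be positive in every region")
  structure(list(table = tab, T0_ref = T0_ref, rho_b = rho_b, C_b = C_b,
                 T_b = T_b, omega0 = omega0, Q_m = Q_m, alpha = alpha,
                 alpha_grouping = match.arg(alpha_grouping),
                 dWdT_clamp = dWdT_clamp),
            class = "abl_thermal_materials")
}

# Hermite join of the two exponential water-content branches on (103, 104].
# Coefficients computed once at load time from continuity of value and slope.
water_cubic_coefs <- function() {
  w1 <- function(T) 0.778 * (1 - exp((T - 106) / 3.42))
  d1 <- function(T) -0.778 / 3.42 * exp((T - 106) / 3.42)
  w3 <- function(T) 0.778 * exp(-(T - 80) / 34.37)
  d3 <- function(T) -0.778 / 34.37 * exp(-(T - 80) / 34.37)
  a0 <- w1(103); a1 <- d1(103)
  dv <- w3(104) - a0 - a1
  ds <- d3(104) - a1
  a3 <- ds - 2 * dv
  a2 <- dv - a3
  c(a0 = a0, a1 = a1, a2 = a2, a3 = a3)
}
WATER_CUBIC <- water_cubic_coefs()

#' Tissue water content as a function of temperature
#'
#' Piecewise model of the tissue water mass fraction: a plateau near 0.778
#' with an exponential decay approaching 103 C, a steep cubic vaporization
#' transition on (103, 104] C (a Hermite join continuous in value and slope
#' with both neighbours; its leading coefficient is 0.0289 T^3 in absolute
#' temperature), and a slow exponential tail above 104 C.
#'
#' @param T temperature (C), vectorized
#' @return water mass fraction
#' @export
water_content <- function(T) {
  w <- 0.778 * (1 - exp((T - 106) / 3.42))
  hi <- T > 104
  w[hi] <- 0.778 * exp(-(T[hi] - 80) / 34.37)
  mid <- T > 103 & T <= 104
  if (any(mid)) {
    s <- T[mid] - 103
    w[mid] <- WATER_CUBIC[1] + s * (WATER_CUBIC[2] +
                s * (WATER_CUBIC[3] + s * WATER_CUBIC[4]))
  }
  w
}

#' Analytic temperature derivative of the water content
#' @param T temperature (C), vectorized
#' @return dW/dT (1/C)
#' @export
water_content_slope <- function(T) {
  d <- -0.778 / 3.42 * exp((T - 106) / 3.42)
  hi <- T > 104
  d[hi] <- -0.778 / 34.37 * exp(-(T[hi] - 80) / 34.37)
  mid <- T > 103 & T <= 104
  if (any(mid)) {
    s <- T[mid] - 103
    d[mid] <- WATER_CUBIC[2] + s * (2 * WATER_CUBIC[3] +
                s * 3 * WATER_CUBIC[4])
  }
  d
}

#' Effective specific heat including water vaporization
#'
#' C(T) = C_t - alpha dW/dT with dW/dT clamped to the configured bound; the
#' latent term raises C wherever water is being driven off (dW/dT <= 0), so
#' heating stalls through the vaporization band.
#'
#' @param T temperature (C), vectorized
#' @param materials an `abl_thermal_materials`
#' @param region region name(s) for C_t and density (default liver)
#' @return effective specific heat (J/kg.C)
#' @export
effective_specific_heat <- function(T, materials, region = "liver") {
  tab <- materials$table
  Ct <- tab[region, "C_t"]
  d <- water_content_slope(T)
  d <- sign(d) * pmin(abs(d), materials$dWdT_clamp)
  scale <- if (materials$alpha_grouping == "water_density")
    1000 / tab[region, "rho"] else 1
  lat <- ifelse(tab[region, "tissue"], materials$alpha * scale, 0)
  Ct - lat * d
}

#' Temperature-dependent thermal conductivity k(T) = k0 + dk (T - T0)
#' @param T temperature (C), vectorized
#' @param materials an `abl_thermal_materials`
#' @param region region name(s)
#' @return conductivity (W/m.C)
#' @export
thermal_conductivity <- function(T, materials, region = "liver") {
  tab <- materials$table
  tab[region, "k0_th"] + tab[region, "dk"] * (T - materials$T0_ref)
}

#' Blood perfusion rate with irreversible 60 C shutdown
#'
#' Perfusion is the baseline rate while an element's mean temperature has
#' never reached 60 C, and zero permanently afterwards (microvascular
#' collapse). Non-tissue regions never perfuse.
#'
#' @param T_element element mean temperatures (C)
#' @param latched logical vector: element already shut down
#' @param materials an `abl_thermal_materials`
#' @param tissue logical vector: element is tissue
#' @return list with `omega` (1/s per element) and updated `latched`
#' @export
perfusion_rate <- function(T_element, latched, materials, tissue = TRUE) {
  latched <- latched | (T_element >= 60)
  omega <- ifelse(!latched & tissue, materials$omega0, 0)
  list(omega = omega, latched = latched)
}

#' Build the nodal P1 bioheat solver on a mesh
#'
#' Precomputes the element stiffness geometry (so the temperature-dependent
#' conductivity only rescales static triplets each step), the lumped-mass
#' scatter and the per-element tissue masks for the given mesh and region
#' tagging.
#'
#' @param mesh an `abl_mesh`
#' @param materials an `abl_thermal_materials`
#' @return object of class `abl_bioheat_solver`
#' @export
bioheat_solver <- function(mesh, materials) {
  geom <- tet_geometry(mesh)
  m <- nrow(mesh$tets); nv <- nrow(mesh$vertices)
  # static per-element P1 stiffness: V * (G_a . G_b)
  K0 <- matrix(0, m, 16)
  ii <- matrix(0L, m, 16); jj <- matrix(0L, m, 16)
  for (a in 1:4) for (b in 1:4) {
    col <- (b - 1) * 4 + a
    K0[, col] <- geom$volume * rowSums(geom$grads[[a]] * geom$grads[[b]])
    ii[, col] <- mesh$tets[, a]
    jj[, col] <- mesh$tets[, b]
  }
  reg <- as.character(mesh$region)
  tab <- materials$table
  structure(list(
    mesh = mesh, materials = materials, geom = geom,
    K0 = as.numeric(K0), Ki = as.vector(ii), Kj = as.vector(jj),
    n_nodes = nv, n_elem = m,
    region = reg,
    tissue = tab[reg, "tissue"],
    rho = tab[reg, "rho"],
    V4 = geom$volume / 4,
    cache = new.env(parent = emptyenv())
  ), class = "abl_bioheat_solver")
}

#' Initial thermal state
#'
#' @param solver an `abl_bioheat_solver`
#' @param T0 initial temperature (C), scalar or nodal vector
#' @return object of class `abl_thermal_state` with nodal `T`, per-element
#'   perfusion `latched`, time `t`
#' @export
thermal_state <- function(solver, T0 = 37) {
  Tn <- rep_len(T0, solver$n_nodes)
  structure(list(T = Tn, latched = rep(FALSE, solver$n_elem), t = 0),
            class = "abl_thermal_state")
}

element_mean_T <- function(solver, Tn) {
  t4 <- solver$mesh$tets
  (Tn[t4[, 1]] + Tn[t4[, 2]] + Tn[t4[, 3]] + Tn[t4[, 4]]) / 4
}

#' Advance the bioheat equation by one backward-Euler step
#'
#' Nodal P1 finite elements with lumped mass, insulated (natural) exterior
#' boundary, and single-lag evaluation of C(T), k(T) and the perfusion latch
#' at the previous step's temperature. Each step solves
#' (M/dt + K + P) T_new = M/dt T_old + F with a sparse Cholesky
#' factorization.
#'
#' @param solver an `abl_bioheat_solver`
#' @param state an `abl_thermal_state`
#' @param Qe per-element electromagnetic heat source (W/m3)
#' @param dt time step (s), positive
#' @return updated `abl_thermal_state`
#' @export
advance_temperature <- function(solver, state, Qe, dt) {
  if (dt <= 0) stop("time step must be positive")
  if (length(Qe) == 1) Qe <- rep(Qe, solver$n_elem)
  if (length(Qe) != solver$n_elem)
    stop("Qe has ", length(Qe), " entries but the mesh has ",
         solver$n_elem, " elements (mesh mismatch)")
  mat <- solver$materials
  Te <- element_mean_T(solver, state$T)
  pf <- perfusion_rate(Te, state$latched, mat, solver$tissue)
  ke <- thermal_conductivity(Te, mat, solver$region)
  Ce <- effective_specific_heat(Te, mat, solver$region)
  rhoC4 <- solver$rho * Ce * solver$V4
  perf4 <- mat$rho_b * mat$C_b * pf$omega * solver$V4
  qm <- ifelse(solver$tissue, mat$Q_m, 0)
  src4 <- (Qe + qm) * solver$V4

  nv <- solver$n_nodes
  t4v <- as.vector(solver$mesh$tets)
  scatter <- function(vals) {
    out <- numeric(nv)
    agg <- rowsum(rep(vals, 4), t4v, reorder = TRUE)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
  }
  Mlump <- scatter(rhoC4)
  Plump <- scatter(perf4)
  Flump <- scatter(src4)
  if (any(Mlump <= 0))
    stop("isolated vertex: every node must belong to a tetrahedron")
  kx <- solver$K0 * ke  # recycles per element across the 16 entries
  A <- Matrix::sparseMatrix(i = solver$Ki, j = solver$Kj, x = kx,
                            dims = c(nv, nv), symmetric = FALSE)
  A <- Matrix::forceSymmetric(A + Matrix::Diagonal(nv, Mlump / dt + Plump))
  rhs <- Mlump / dt * state$T + Flump + Plump * mat$T_b
  Tn <- solve_spd(solver, A, rhs)
  if (any(!is.finite(Tn))) stop("bioheat solve produced non-finite temperatures")
  structure(list(T = Tn, latched = pf$latched, t = state$t + dt),
            class = "abl_thermal_state")
}

# sparse SPD solve with the symbolic factorization cached in the solver's
# environment (the sparsity pattern is fixed by the mesh)
solve_spd <- function(solver, A, rhs) {
  env <- solver$cache
  if (is.null(env$chol)) {
    env$chol <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  } else {
    env$chol <- Matrix::update(env$chol, A)
  }
  as.numeric(Matrix::solve(env$chol, rhs))
}
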