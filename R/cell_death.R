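#' Three-state thermal cell-death model
#'
#' Kinetic model with alive (A), vulnerable (V) and dead (D) fractions,
#' A + V + D = 1: alive cells convert to vulnerable at the
#' temperature-dependent forward rate and back at a constant self-healing
#' rate, and vulnerable cells die irreversibly at the forward rate:
#' dA/dt = -kf A + kb (1 - A - D), dD/dt = kf (1 - A - D),
#' kf = kf0 exp(T / T_k) (1 - A).
#'
#' The rate constants are not fixed by the treatment tables; defaults follow
#' the established three-state hyperthermia parameterization
#' (kf0 = 3.33e-3 1/s, kb = 7.77e-3 1/s, T_k = 40.5 C, A0 = 0.99, D0 = 0)
#' and are configuration-exposed.
#'
#' @param kf0 forward scaling factor (1/s)
#' @param kb backward (self-healing) rate (1/s)
#' @param T_k exponential temperature scale (C)
#' @param A0,D0 initial alive/dead fractions
#' @param T_cap temperature (C) at which the forward rate saturates. The
#'   exponential is calibrated in the hyperthermia range; near the antenna
#'   the constant-property heat source can push nodal temperatures to
#'   several hundred degrees where the extrapolated rate would be
#'   astronomically large (and the integrator step astronomically small)
#'   without changing the outcome -- the node is dead within a second
#'   either way.
#' @return object of class `abl_cell_params`
#' @export
cell_death_params <- function(kf0 = 3.33e-3, kb = 7.77e-3, T_k = 40.5,
                              A0 = 0.99, D0 = 0, T_cap = 150) {
  stopifnot(kf0 >= 0, kb >= 0, T_k > 0, A0 >= 0, D0 >= 0, A0 + D0 <= 1,
            T_cap > 0)
  structure(list(kf0 = kf0, kb = kb, T_k = T_k, A0 = A0, D0 = D0,
                 T_cap = T_cap),
            class = "abl_cell_params")
}

#' Forward rate of the cell-death model
#'
#' kf = kf0 exp(T/T_k) (1 - A): grows exponentially with temperature and
#' saturates as the alive pool empties.
#'
#' @param T temperature (C), vectorized
#' @param A alive fraction, vectorized
#' @param params an `abl_cell_params`
#' @return forward rate (1/s)
#' @export
forward_rate <- function(T, A, params) {
  Tc <- if (is.null(params$T_cap)) T else pmin(T, params$T_cap)
  params$kf0 * exp(Tc / params$T_k) * (1 - A)
}

#' Initial nodal cell state
#' @param n number of nodes
#' @param params an `abl_cell_params`
#' @return object of class `abl_cell_state` with nodal `A`, `D`
#' @export
cell_state <- function(n, params = cell_death_params()) {
  structure(list(A = rep(params$A0, n), D = rep(params$D0, n),
                 params = params),
            class = "abl_cell_state")
}

#' Advance the cell-death ODE over one interval
#'
#' Explicit sub-stepped finite-difference integration (Heun's two-stage
#' scheme): the sub-step is chosen so that dt_sub (kf + kb) <= 0.1 at the
#' hottest node. V = 1 - A - D is maintained exactly by construction; D is
#' non-decreasing because both stage rates kf V are non-negative. Fractions
#' drifting outside [0, 1] by more than 1e-9 raise a stability error instead
#' of being silently repaired.
#'
#' @param state an `abl_cell_state`
#' @param T_nodal nodal temperatures (C), or a two-column matrix giving the
#'   start/end temperatures of the interval (linear in time between them)
#' @param dt interval length (s)
#' @return updated `abl_cell_state`
#' @export
step_cell_state <- function(state, T_nodal, dt) {
  p <- state$params
  A <- state$A; D <- state$D
  Tm <- if (is.matrix(T_nodal)) T_nodal else cbind(T_nodal, T_nodal)
  if (nrow(Tm) != length(A)) stop("temperature/cell state length mismatch")
  kf_max <- p$kf0 * exp(min(max(Tm), p$T_cap %||% Inf) / p$T_k)
  n_sub <- max(1L, ceiling(dt * (kf_max + p$kb) / 0.05))
  h <- dt / n_sub
  for (s in seq_len(n_sub)) {
    frac <- (s - 0.5) / n_sub
    T_now <- Tm[, 1] * (1 - frac) + Tm[, 2] * frac
    kf <- forward_rate(T_now, A, p)
    Vv <- 1 - A - D
    dA1 <- -kf * A + p$kb * Vv
    dD1 <- kf * Vv
    A1 <- A + h * dA1
    D1 <- D + h * dD1
    kf2 <- forward_rate(T_now, A1, p)
    V1 <- 1 - A1 - D1
    A <- A + h / 2 * (dA1 - kf2 * A1 + p$kb * V1)
    D <- D + h / 2 * (dD1 + kf2 * V1)
  }
  tol <- 1e-9
  if (any(A < -tol | A > 1 + tol | D < -tol | D > 1 + tol | A + D > 1 + tol))
    stop("stability error: cell fractions left [0,1]; use a smaller sub-step")
  A <- pmin(pmax(A, 0), 1)
  D <- pmin(pmax(D, 0), 1)
  structure(list(A = A, D = D, params = p), class = "abl_cell_state")
}

#' Ablation-zone volume accounting
#'
#' An element counts as ablated when its mean nodal dead-plus-vulnerable
#' fraction (D + V = 1 - A) reaches the classification threshold. Reported
#' in cm^3 over tissue elements only:
#' ablation volume (all ablated tissue), healthy damage (ablated liver) and
#' remaining tumor (tumor volume minus ablated tumor).
#'
#' @param mesh an `abl_mesh`
#' @param cstate an `abl_cell_state` (nodal)
#' @param threshold classification level on D + V (default 0.8)
#' @return list with `ablation_cm3`, `healthy_damage_cm3`,
#'   `remaining_tumor_cm3`, `tumor_cm3`, `pct_tumor_killed`
#' @export
ablation_accounting <- function(mesh, cstate, threshold = 0.8) {
  t4 <- mesh$tets
  dv <- 1 - cstate$A
  dv_e <- (dv[t4[, 1]] + dv[t4[, 2]] + dv[t4[, 3]] + dv[t4[, 4]]) / 4
  ablated <- dv_e >= threshold
  tissue <- mesh$region %in% c("liver", "tumor")
  vol <- mesh$volumes * 1e6  # cm^3
  ablation <- sum(vol[ablated & tissue])
  healthy <- sum(vol[ablated & mesh$region == "liver"])
  tumor_total <- sum(vol[mesh$region == "tumor"])
  tumor_killed <- sum(vol[ablated & mesh$region == "tumor"])
  list(ablation_cm3 = ablation,
       healthy_damage_cm3 = healthy,
       remaining_tumor_cm3 = tumor_total - tumor_killed,
       tumor_cm3 = tumor_total,
       pct_tumor_killed = if (tumor_total > 0)
         100 * tumor_killed / tumor_total else NA_real_)
}
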