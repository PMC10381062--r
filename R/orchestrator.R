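#' Multi-ablation heating protocol
#'
#' An ordered list of antenna tip positions with contiguous heating
#' intervals starting at t = 0: the antenna sits at position i over
#' (t_{i-1}, t_i]. Positions must respect a minimum spacing (default 14 mm,
#' the separation that avoids non-ablated gaps without clefting).
#'
#' @param positions n x 3 matrix of tip positions (m)
#' @param durations length-n vector of heating times per position (s)
#' @param power input power (W)
#' @param frequency operating frequency (Hz)
#' @param min_spacing minimum pairwise distance between positions (m)
#' @param label protocol label used in reports
#' @return object of class `abl_protocol`
#' @export
ablation_protocol <- function(positions, durations, power = 50,
                              frequency = 2.45e9, min_spacing = 14e-3,
                              label = "protocol") {
  positions <- rbind(positions)
  durations <- as.numeric(durations)
  if (nrow(positions) != length(durations))
    stop("one duration per position required")
  if (any(durations <= 0)) stop("durations must be positive")
  if (nrow(positions) > 1) {
    dmin <- min(stats::dist(positions))
    if (dmin < min_spacing - 1e-9)
      stop("positions closer than the minimum spacing (",
           signif(dmin * 1e3, 3), " mm < ",
           signif(min_spacing * 1e3, 3), " mm)")
  }
  structure(list(positions = positions, durations = durations,
                 t_bounds = cumsum(durations), power = power,
                 frequency = frequency, label = label),
            class = "abl_protocol")
}

#' Antenna position scheduled at a given time
#'
#' Intervals are half-open on the left: t in (t_{i-1}, t_i] maps to position
#' i, and t = 0 to position 1.
#'
#' @param t time (s)
#' @param protocol an `abl_protocol`
#' @return length-3 position (m)
#' @export
location_at <- function(t, protocol) {
  if (t < 0 || t > protocol$t_bounds[length(protocol$t_bounds)] + 1e-9)
    stop("time outside the protocol schedule")
  i <- 1 + sum(t > protocol$t_bounds + 1e-9)
  i <- min(i, nrow(protocol$positions))
  protocol$positions[i, ]
}

#' Built-in treatment protocols
#'
#' `four_3min`/`four_4min`: the antenna visits the four square-pattern
#' positions (-7,7,10), (7,7,10), (-7,-7,10), (7,-7,10) mm for 3 or 4
#' minutes each. `three_5min`: an equilateral triangle of side 14 mm at the
#' same depth, 5 minutes each. `single_20min`: one central ablation at
#' (0,0,10) mm for 20 minutes.
#'
#' @param name protocol name
#' @param power input power (W)
#' @param frequency frequency (Hz)
#' @return an `abl_protocol`
#' @export
protocol_preset <- function(name = c("four_3min", "four_4min", "three_5min",
                                     "single_20min"),
                            power = 50, frequency = 2.45e9) {
  name <- match.arg(name)
  sq <- rbind(c(-7, 7, 10), c(7, 7, 10), c(-7, -7, 10), c(7, -7, 10)) * 1e-3
  r3 <- 14e-3 / sqrt(3)
  tri <- rbind(c(0, r3, 0.010),
               c(-7e-3, -r3 / 2, 0.010),
               c(7e-3, -r3 / 2, 0.010))
  switch(name,
    four_3min = ablation_protocol(sq, rep(180, 4), power, frequency,
                                  label = "four positions, 3 min each"),
    four_4min = ablation_protocol(sq, rep(240, 4), power, frequency,
                                  label = "four positions, 4 min each"),
    three_5min = ablation_protocol(tri, rep(300, 3), power, frequency,
                                   label = "three positions, 5 min each"),
    single_20min = ablation_protocol(matrix(c(0, 0, 0.010), 1), 1200,
                                     power, frequency,
                                     label = "single position, 20 min"))
}

#' Run the full multiphysics ablation simulation
#'
#' For each scheduled antenna position: re-tag the shared graded phantom for
#' that position, assemble and solve the electromagnetic problem once (the
#' source is temperature-independent within an interval), then advance the
#' bioheat equation with backward-Euler steps, integrating the cell-death
#' model and recording probe temperatures continuously across position
#' switches.
#'
#' @param protocol an `abl_protocol` (or preset name)
#' @param spec an `abl_geometry_spec` (its `scale` controls resolution)
#' @param dt bioheat time step (s)
#' @param em an `abl_em_materials` (defaults to the protocol's frequency)
#' @param thermal an `abl_thermal_materials`
#' @param cell an `abl_cell_params`
#' @param threshold ablation classification level on D + V
#' @param probe_offsets radial probe distances from the antenna slot (m)
#' @param T0 initial/baseline temperature (C)
#' @param mesh optional prebuilt phantom mesh (must resolve all positions)
#' @param normalize_power rescale the (linear) electromagnetic solution so
#'   the power absorbed in tissue equals the protocol's input power. On a
#'   coarse mesh the discrete antenna is imperfectly matched and part of the
#'   nominal input reflects at the port; clinical generators regulate
#'   delivered power, and this keeps heating comparable across mesh
#'   resolutions. Set FALSE to use the raw port-driven solution.
#' @param verbose print per-interval summaries
#' @return object of class `abl_run_result`
#' @export
run_protocol <- function(protocol, spec = geometry_spec(), dt = 1,
                         em = NULL, thermal = thermal_materials(),
                         cell = cell_death_params(), threshold = 0.8,
                         probe_offsets = c(3e-3, 5e-3), T0 = 37,
                         mesh = NULL, normalize_power = TRUE,
                         verbose = TRUE) {
  if (is.character(protocol)) protocol <- protocol_preset(protocol)
  if (is.null(em)) em <- em_materials(protocol$frequency)
  npos <- nrow(protocol$positions)
  if (is.null(mesh))
    mesh <- build_phantom(spec, protocol$positions[1, ],
                          clusters = protocol$positions)
  scale <- if (!is.null(mesh$phantom)) mesh$phantom$scale else spec$scale
  eff <- effective_antenna(spec, scale)

  # probes: radially offset from the slot mid-height of every position
  # (the slot sits just below the tip on the feed side)
  z_slot <- protocol$positions[, 3] - spec$slot_offset - eff$slot_height / 2
  probes <- do.call(rbind, lapply(seq_len(npos), function(i) {
    do.call(rbind, lapply(probe_offsets, function(off)
      c(protocol$positions[i, 1] + eff$r_cath + off,
        protocol$positions[i, 2], z_slot[i])))
  }))
  probe_meta <- data.frame(
    position = rep(seq_len(npos), each = length(probe_offsets)),
    offset_mm = rep(probe_offsets, npos) * 1e3)
  ploc <- locate_points(mesh, probes)
  t4 <- mesh$tets

  nt_total <- ceiling(protocol$t_bounds[npos] / dt)
  times <- numeric(0)
  probe_T <- matrix(NA_real_, 0, nrow(probes))
  tstate <- NULL
  cstate <- cell_state(nrow(mesh$vertices), cell)
  latched <- NULL
  summaries <- list()
  t_now <- 0

  for (i in seq_len(npos)) {
    pos <- protocol$positions[i, ]
    mesh_i <- retag_antenna(mesh, spec, pos)
    edges_i <- build_edge_structure(mesh_i)
    if (protocol$power > 0) {
      port <- tem_incident_field(protocol$power, spec$r_inner, eff$r_diel,
                                 em$table["dielectric", "eps_r"],
                                 protocol$frequency, axis = pos[1:2])
      sys <- assemble_system(mesh_i, edges_i, em, port = port)
      sol <- solve_em(sys)
      qs <- compute_qe_sar(sol, em,
                           stats::setNames(thermal$table$rho, REGION_TAGS))
      Qe <- qs$Qe
      if (normalize_power) {
        tis <- mesh_i$region %in% c("liver", "tumor")
        p_abs <- sum((Qe * mesh_i$volumes)[tis])
        if (p_abs > 0) Qe <- Qe * (protocol$power / p_abs)
      }
      resid <- sol$residual
      rm(sys, sol); gc(FALSE)
    } else {
      Qe <- numeric(nrow(mesh_i$tets)); resid <- 0
    }
    solver <- bioheat_solver(mesh_i, thermal)
    if (is.null(tstate)) tstate <- thermal_state(solver, T0)
    if (!is.null(latched)) tstate$latched <- latched
    tstate$t <- t_now

    t_end <- protocol$t_bounds[i]
    while (t_now < t_end - 1e-9) {
      step <- min(dt, t_end - t_now)
      T_old <- tstate$T
      tstate <- advance_temperature(solver, tstate, Qe, step)
      cstate <- step_cell_state(cstate, cbind(T_old, tstate$T), step)
      t_now <- t_now + step
      times <- c(times, t_now)
      pv <- matrix(tstate$T[t4[ploc$elem, ]], ncol = 4)
      probe_T <- rbind(probe_T, as.numeric(rowSums(pv * ploc$lambda)))
    }
    latched <- tstate$latched
    acc <- ablation_accounting(mesh_i, cstate, threshold)
    summaries[[i]] <- data.frame(
      interval = i, t_end = t_end,
      residual = resid, max_T = max(tstate$T),
      absorbed_W = sum(Qe * mesh_i$volumes),
      ablation_cm3 = acc$ablation_cm3)
    if (verbose)
      message(sprintf(
        "interval %d (%s mm): resid %.2e, absorbed %.1f W, maxT %.1f C, ablated %.2f cm3",
        i, paste(signif(pos * 1e3, 3), collapse = ", "),
        resid, sum(Qe * mesh_i$volumes), max(tstate$T), acc$ablation_cm3))
  }

  windows <- data.frame(
    probe = seq_len(nrow(probes)),
    t_start = c(0, protocol$t_bounds)[probe_meta$position],
    t_end = protocol$t_bounds[probe_meta$position])
  contraction <- cbind(probe_meta,
                       contraction_report(times, probe_T, windows, T0))
  acc <- ablation_accounting(retag_antenna(mesh, spec,
                                           protocol$positions[npos, ]),
                             cstate, threshold)
  structure(list(
    protocol = protocol, spec = spec, dt = dt, threshold = threshold,
    mesh = mesh, times = times, probe_T = probe_T, probes = probes,
    probe_meta = probe_meta, accounting = acc, contraction = contraction,
    interval_summaries = do.call(rbind, summaries),
    final_T = tstate$T, final_cell = cstate
  ), class = "abl_run_result")
}

#' Damage report of one or more protocol runs
#'
#' One row per run: ablation volume, healthy damage, remaining tumor (cm^3)
#' and the percentage of tumor killed.
#'
#' @param ... `abl_run_result` objects (or a single list of them)
#' @return data.frame
#' @export
damage_report <- function(...) {
  runs <- list(...)
  if (length(runs) == 1 && !inherits(runs[[1]], "abl_run_result"))
    runs <- runs[[1]]
  if (!length(runs))
    return(data.frame(protocol = character(0), ablation_cm3 = numeric(0),
                      healthy_damage_cm3 = numeric(0),
                      remaining_tumor_cm3 = numeric(0),
                      pct_tumor_killed = numeric(0)))
  do.call(rbind, lapply(runs, function(r) {
    a <- r$accounting
    data.frame(protocol = r$protocol$label,
               ablation_cm3 = a$ablation_cm3,
               healthy_damage_cm3 = a$healthy_damage_cm3,
               remaining_tumor_cm3 = a$remaining_tumor_cm3,
               pct_tumor_killed = a$pct_tumor_killed)
  }))
}

#' Write the outputs of a run to a directory
#'
#' Emits the final temperature/cell fields as VTU, the probe temperature
#' histories and contraction table as CSV, and the damage accounting as
#' JSON.
#'
#' @param result an `abl_run_result`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_run_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vtu = file.path(dir, "final_fields.vtu"),
    probes = file.path(dir, "probe_temperatures.csv"),
    contraction = file.path(dir, "contraction.csv"),
    damage = file.path(dir, "damage_report.json"))
  write_vtu(result$mesh, paths["vtu"],
            point_data = list(temperature = result$final_T,
                              alive = result$final_cell$A,
                              dead = result$final_cell$D))
  pt <- data.frame(time_s = result$times, result$probe_T)
  names(pt)[-1] <- sprintf("probe_%d_pos%d_%gmm",
                           seq_len(nrow(result$probes)),
                           result$probe_meta$position,
                           result$probe_meta$offset_mm)
  utils::write.csv(pt, paths["probes"], row.names = FALSE)
  utils::write.csv(result$contraction, paths["contraction"],
                   row.names = FALSE)
  jsonlite::write_json(c(list(protocol = result$protocol$label),
                         result$accounting),
                       paths["damage"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
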