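#' Read a declarative run configuration
#'
#' A single YAML document drives a full simulation: protocol (a preset name
#' or explicit positions/durations), power, frequency, time step, mesh
#' scale, geometry and material overrides, cell-death constants, probe
#' offsets and output directory. Geometric lengths in the file are in
#' millimetres (the treatment-planning unit) and are converted to metres on
#' load; frequency may be given as `frequency_GHz` or `frequency_Hz`.
#'
#' @param path YAML file path, or a pre-parsed list
#' @return list with `protocol`, `spec`, `em`, `thermal`, `cell`, `dt`,
#'   `threshold`, `probe_offsets`, `output_dir`
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  power <- cfg$power_W %||% 50
  freq <- if (!is.null(cfg$frequency_Hz)) cfg$frequency_Hz
          else (cfg$frequency_GHz %||% 2.45) * 1e9
  pr <- cfg$protocol %||% list(preset = "four_3min")
  protocol <- if (!is.null(pr$preset)) {
    protocol_preset(pr$preset, power = power, frequency = freq)
  } else {
    pos <- do.call(rbind, pr$positions_mm) * 1e-3
    ablation_protocol(pos, pr$durations_s, power = power, frequency = freq,
                      min_spacing = (pr$min_spacing_mm %||% 14) * 1e-3,
                      label = pr$label %||% "custom protocol")
  }
  g <- cfg$geometry %||% list()
  scale <- cfg$scale %||% 1
  spec <- geometry_spec(
    liver_radius = (g$liver_radius_mm %||% 40) * 1e-3,
    liver_height = (g$liver_height_mm %||% 80) * 1e-3,
    tumor_radius = (g$tumor_radius_mm %||% 20) * 1e-3,
    r_inner = (g$r_inner_mm %||% 0.135) * 1e-3,
    r_diel = (g$r_diel_mm %||% 0.47) * 1e-3,
    r_cath = (g$r_cath_mm %||% 0.895) * 1e-3,
    slot_offset = (g$slot_offset_mm %||% 2.5) * 1e-3,
    slot_height = (g$slot_height_mm %||% 1) * 1e-3,
    scale = scale)
  me <- cfg$materials$em %||% list()
  em <- em_materials(frequency = freq,
                     eps_r = unlist(me$eps_r), mu_r = unlist(me$mu_r),
                     sigma = unlist(me$sigma))
  mt <- cfg$materials$thermal %||% list()
  thermal <- thermal_materials(
    rho = unlist(mt$rho), C_t = unlist(mt$C_t),
    k0_th = unlist(mt$k0_th), dk = unlist(mt$dk),
    alpha = mt$alpha %||% 2.26e6,
    alpha_grouping = mt$alpha_grouping %||% "mass_fraction",
    Q_m = mt$Q_m %||% 33800,
    omega0 = mt$omega0 %||% 0.0036)
  cc <- cfg$cell %||% list()
  cell <- cell_death_params(kf0 = cc$kf0 %||% 3.33e-3,
                            kb = cc$kb %||% 7.77e-3,
                            T_k = cc$T_k %||% 40.5,
                            A0 = cc$A0 %||% 0.99,
                            D0 = cc$D0 %||% 0)
  list(protocol = protocol, spec = spec, em = em, thermal = thermal,
       cell = cell,
       dt = cfg$dt_s %||% 1,
       threshold = cfg$threshold %||% 0.8,
       probe_offsets = (unlist(cfg$probe_offsets_mm) %||% c(3, 5)) * 1e-3,
       output_dir = cfg$output_dir %||% "ablatesim_out")
}

#' Run a simulation from a configuration
#'
#' @param config path to a YAML run configuration or a pre-parsed list
#' @param scale optional mesh-scale override
#' @param out optional output-directory override (NULL disables writing)
#' @param verbose print progress
#' @return an `abl_run_result`
#' @export
run_from_config <- function(config, scale = NULL, out, verbose = TRUE) {
  cfg <- read_run_config(config)
  if (!is.null(scale)) cfg$spec$scale <- scale
  res <- run_protocol(cfg$protocol, spec = cfg$spec, dt = cfg$dt,
                      em = cfg$em, thermal = cfg$thermal, cell = cfg$cell,
                      threshold = cfg$threshold,
                      probe_offsets = cfg$probe_offsets, verbose = verbose)
  if (missing(out)) out <- cfg$output_dir
  if (!is.null(out)) write_run_outputs(res, out)
  res
}
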