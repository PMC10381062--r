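#' Weighted temperature-time integral (thermal dose for contraction)
#'
#' TTI = int w(T) (T - T0)+ dt with the weight selected by the instantaneous
#' temperature band: 0 up to 12 C, 0.1573 on (12, 44.1], 0.3011 on
#' (44.1, 102.1] and 0.5416 above 102.1 C. The band weight follows the
#' current sample (so the dose rate jumps when the temperature crosses a
#' band edge) and the excess over the initial temperature is floored at
#' zero, so cooling below baseline never produces negative dose.
#' Accumulation is trapezoidal over the supplied samples.
#'
#' @param times strictly increasing sample times (s)
#' @param temps temperatures at the samples (C)
#' @param T0 initial temperature (C), default 37
#' @return TTI (weighted C.s)
#' @export
weighted_tti <- function(times, temps, T0 = 37) {
  if (length(times) != length(temps)) stop("times and temps differ in length")
  if (length(times) < 2) return(0)
  if (any(diff(times) <= 0)) stop("time vector must be strictly increasing")
  w <- tti_weight(temps)
  integrand <- w * pmax(temps - T0, 0)
  sum(diff(times) * (integrand[-1] + integrand[-length(integrand)]) / 2)
}

tti_weight <- function(T) {
  ifelse(T <= 12, 0,
         ifelse(T <= 44.1, 0.1573,
                ifelse(T <= 102.1, 0.3011, 0.5416)))
}

#' Localized tissue contraction from the weighted dose
#'
#' Power-law regression of mean localized contraction against the weighted
#' temperature-time integral: LC = 0.003 TTI^0.4684. Zero at zero dose,
#' strictly increasing and concave.
#'
#' @param tti weighted temperature-time integral (C.s)
#' @return contraction fraction (0.05 means 5 percent)
#' @export
localized_contraction <- function(tti) {
  if (any(tti < 0)) stop("TTI must be non-negative")
  0.003 * tti^0.4684
}

#' Contraction report for probe temperature histories
#'
#' @param probe_times sample times (s)
#' @param probe_T matrix of temperatures, one column per probe
#' @param windows data.frame with columns `probe` (column index), `t_start`,
#'   `t_end`: the time window to integrate for each probe
#' @param T0 initial temperature (C)
#' @return data.frame with probe, window, TTI and contraction (percent)
#' @export
contraction_report <- function(probe_times, probe_T, windows, T0 = 37) {
  out <- windows
  out$tti <- NA_real_; out$contraction_pct <- NA_real_
  for (i in seq_len(nrow(windows))) {
    sel <- probe_times >= windows$t_start[i] - 1e-9 &
           probe_times <= windows$t_end[i] + 1e-9
    tti <- weighted_tti(probe_times[sel], probe_T[sel, windows$probe[i]], T0)
    out$tti[i] <- tti
    out$contraction_pct[i] <- 100 * localized_contraction(tti)
  }
  out
}
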