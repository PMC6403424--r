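#' Energy-input protocols
#'
#' A protocol is an ordered sequence of timed energy-input events: heat
#' pulses (instantaneous activation of the inactive pool) and UV pulses
#' (finite windows during which both relaxation rates are multiplied by
#' \code{uv_factor}, rapidly collapsing the chains).
#'
#' @param events A list of events, each created by [heat_event()] or
#'   [uv_event()].
#' @return An object of class \code{"protocol"}.
#' @seealso [single_fuel()], [repeated_fuel()], [uv_quench()].
#' @export
protocol <- function(events = list()) {
  if (length(events)) {
    times <- vapply(events, function(e) e$time, numeric(1))
    if (any(times < 0)) stop("event times must be non-negative", call. = FALSE)
    o <- order(times)
    events <- events[o]
    times <- times[o]
    if (any(diff(times) <= 0)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(events = events), class = "protocol")
}

#' @rdname protocol
#' @param time Event time in days.
#' @param efficiency Optional heat-pulse activation efficiency override.
#' @export
heat_event <- function(time, efficiency = NULL) {
  list(kind = "heat_pulse", time = time, efficiency = efficiency)
}

#' @rdname protocol
#' @param duration UV window length in days (default 5 minutes).
#' @param factor Optional override of \code{uv_factor}.
#' @export
uv_event <- function(time, duration = 5 / (60 * 24), factor = NULL) {
  if (duration <= 0) stop("UV window duration must be > 0", call. = FALSE)
  list(kind = "uv_pulse", time = time, duration = duration, factor = factor)
}

#' @export
print.protocol <- function(x, ...) {
  cat("protocol with", length(x$events), "event(s)\n")
  for (e in x$events) {
    if (e$kind == "heat_pulse") {
      cat(sprintf("  t = %8.4g d  heat pulse%s\n", e$time,
                  if (is.null(e$efficiency)) "" else
                    sprintf(" (efficiency %.3g)", e$efficiency)))
    } else {
      cat(sprintf("  t = %8.4g d  UV window, %.3g d%s\n", e$time, e$duration,
                  if (is.null(e$factor)) "" else
                    sprintf(" (factor %.3g)", e$factor)))
    }
  }
  invisible(x)
}

#' Single heat fuelling
#'
#' One heat pulse (50 degrees C for 20 minutes, modelled as
#' instantaneous) at time \code{t0}; the reference experiment that starts
#' one full polymerization-depolymerization cycle.
#'
#' @param t0 Pulse time in days.
#' @export
single_fuel <- function(t0 = 0) protocol(list(heat_event(t0)))

#' Repeated heat fuelling
#'
#' Heat pulses at \code{0, period, ..., (n_cycles - 1) * period} days.
#' With the default 4-day period the system is refuelled before
#' depolymerization sets in and the active state is sustained.
#'
#' @param period Days between pulses (> 0).
#' @param n_cycles Number of pulses (>= 1).
#' @export
#' @examples
#' repeated_fuel(4, 3)  # pulses at 0, 4, 8 days
repeated_fuel <- function(period = 4, n_cycles = 2) {
  if (period <= 0) stop("period must be > 0", call. = FALSE)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  protocol(lapply(seq_len(n_cycles) - 1, function(k) heat_event(k * period)))
}

#' UV quench event
#'
#' A UV irradiation window starting at \code{t_uv} during which both
#' relaxation rates are multiplied by \code{uv_factor}, so the chains
#' depolymerize within minutes instead of days. Default duration is
#' 5 minutes expressed in days.
#'
#' @param t_uv Window start (days, >= 0).
#' @param duration Window length (days).
#' @param factor Optional multiplier override.
#' @return A \code{"protocol"} containing the single UV event (combine
#'   with other protocols via [merge_protocols()]).
#' @export
uv_quench <- function(t_uv, duration = 5 / (60 * 24), factor = NULL) {
  if (t_uv < 0) stop("t_uv must be >= 0", call. = FALSE)
  protocol(list(uv_event(t_uv, duration, factor)))
}

#' Merge protocols into one ordered event sequence
#' @param ... \code{"protocol"} objects.
#' @export
merge_protocols <- function(...) {
  protocol(do.call(c, lapply(list(...), function(p) p$events)))
}

#' Concentration sweep
#'
#' Scales the initial unit count of a configuration at fixed volume, so
#' concentration scales with count; paired seeds allow a matched
#' comparison of growth rates across concentrations. Polymerization is
#' concentration dependent while the relaxation (CD decay) rate is not.
#'
#' @param config A run configuration list (see [read_run_config()]) or a
#'   \code{"system_state"}.
#' @param factors Positive multipliers for the initial unit count.
#' @return A list of scaled configurations/states, one per factor.
#' @export
concentration_sweep <- function(config, factors) {
  if (any(factors <= 0)) stop("factors must be > 0", call. = FALSE)
  lapply(factors, function(f) {
    if (inherits(config, "system_state")) {
      st <- config
      st$n_inactive <- round(st$n_inactive * f)
      st$n_active_closed <- round(st$n_active_closed * f)
      st$n_active_open <- round(st$n_active_open * f)
      st  # volume unchanged: counts scale, concentration scales with them
    } else {
      cfg <- config
      cfg$initial$n_units <- round(cfg$initial$n_units * f)
      cfg$initial$conc_uM <- cfg$initial$conc_uM * f
      cfg
    }
  })
}

# Flatten a protocol into the piecewise-constant segments the engines
# integrate over: instantaneous heat pulses and [start, end) UV windows.
#' @keywords internal
protocol_segments <- function(prot, t_end, params) {
  if (!inherits(prot, "protocol")) stop("not a protocol", call. = FALSE)
  heat <- Filter(function(e) e$kind == "heat_pulse", prot$events)
  uv <- Filter(function(e) e$kind == "uv_pulse", prot$events)
  breaks <- c(0, t_end,
              vapply(heat, function(e) e$time, numeric(1)),
              unlist(lapply(uv, function(e) c(e$time, e$time + e$duration))))
  breaks <- sort(unique(pmin(pmax(breaks, 0), t_end)))
  segs <- list()
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    mult <- 1
    for (e in uv) {
      if (t0 >= e$time && t1 <= e$time + e$duration) {
        mult <- mult * (if (is.null(e$factor)) params$uv_factor else e$factor)
      }
    }
    pulses <- Filter(function(e) e$time == t0, heat)
    segs[[length(segs) + 1L]] <- list(t0 = t0, t1 = t1, uv = mult,
                                      heat = pulses)
  }
  # a heat pulse exactly at t_end still fires
  final_heat <- Filter(function(e) e$time == t_end && t_end > 0, heat)
  list(segments = segs, final_heat = final_heat)
}
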