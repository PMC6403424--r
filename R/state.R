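AVOGADRO <- 6.02214076e23

#' System state of the stochastic model
#'
#' Counts of free toroid species plus the multiset of active helical chain
#' lengths at one time point. Free toroids are either inactive (eclipsed,
#' equilibrium packing), active closed (slipped packing, kinetically
#' trapped) or active open (spirally open with two reactive ends). Chains
#' are represented by their integer lengths in toroid units (>= 2); every
#' in-chain subunit is active by construction.
#'
#' @param n_inactive,n_active_closed,n_active_open Non-negative integer
#'   counts of free toroids.
#' @param chains Integer vector of chain lengths (each >= 2), possibly empty.
#' @param time Time of the snapshot (days).
#' @param volume Effective reaction volume in litres, used to convert
#'   between counts and concentrations.
#' @return An object of class \code{"system_state"}.
#' @seealso [initial_state()] for the desk-scale constructor.
#' @export
system_state <- function(n_inactive = 0, n_active_closed = 0,
                         n_active_open = 0, chains = integer(),
                         time = 0, volume = count_volume(1e4, 30)) {
  chains <- as.integer(round(chains))
  st <- structure(list(
    time = as.numeric(time),
    n_inactive = as.numeric(round(n_inactive)),
    n_active_closed = as.numeric(round(n_active_closed)),
    n_active_open = as.numeric(round(n_active_open)),
    chains = chains,
    volume = as.numeric(volume)
  ), class = "system_state")
  validate_state(st)
  st
}

#' @keywords internal
validate_state <- function(st) {
  cnt <- c(st$n_inactive, st$n_active_closed, st$n_active_open)
  if (any(is.na(cnt)) || any(cnt < 0)) {
    stop("species counts must be non-negative", call. = FALSE)
  }
  if (length(st$chains) && any(st$chains < 2L)) {
    stop("every chain length must be >= 2 toroid units", call. = FALSE)
  }
  if (!is.numeric(st$volume) || st$volume <= 0) {
    stop("volume must be a positive number of litres", call. = FALSE)
  }
  invisible(st)
}

#' Volume that maps a unit count onto a concentration
#'
#' Returns the reaction volume (litres) in which \code{n_units} toroids
#' give a total concentration \code{conc_uM}.
#'
#' @param n_units Total number of toroid units.
#' @param conc_uM Total concentration in uM.
#' @export
count_volume <- function(n_units, conc_uM = 30) {
  if (n_units <= 0 || conc_uM <= 0) stop("n_units and conc_uM must be > 0")
  n_units / (AVOGADRO * conc_uM * 1e-6)
}

#' uM of concentration carried by one toroid unit in a given state volume
#' @param state A \code{"system_state"}.
#' @export
uM_per_unit <- function(state) {
  1e6 / (AVOGADRO * state$volume)
}

#' Desk-scale initial state
#'
#' All-inactive starting state in which \code{n_units} toroid units stand
#' for a solution at \code{conc_uM} (default 30 uM represented by 1e4
#' units); polymerization is started by applying a heat-pulse protocol.
#'
#' @inheritParams count_volume
#' @return A \code{"system_state"} with all units in the inactive pool.
#' @export
#' @examples
#' st <- initial_state(1e4, 30)
#' total_units(st)
initial_state <- function(n_units = 1e4, conc_uM = 30) {
  system_state(n_inactive = n_units, time = 0,
               volume = count_volume(n_units, conc_uM))
}

#' Total number of toroid units in a state
#'
#' Conserved by every reaction channel: free toroids plus the summed
#' lengths of all chains.
#'
#' @param state A \code{"system_state"}.
#' @export
total_units <- function(state) {
  state$n_inactive + state$n_active_closed + state$n_active_open +
    sum(as.numeric(state$chains))
}

#' Fraction of all subunits in the activated (slipped) packing
#'
#' Free active toroids (closed or open) and every in-chain subunit count
#' as active; this is the quantity the circular dichroism proxy reports.
#'
#' @param state A \code{"system_state"}.
#' @export
active_fraction <- function(state) {
  tot <- total_units(state)
  if (tot == 0) return(0)
  (state$n_active_closed + state$n_active_open +
     sum(as.numeric(state$chains))) / tot
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state at t = %.4g d: inactive %g, active closed %g, open %g, %d chain(s) holding %g units (total %g)\n",
              x$time, x$n_inactive, x$n_active_closed, x$n_active_open,
              length(x$chains), sum(as.numeric(x$chains)), total_units(x)))
  invisible(x)
}
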