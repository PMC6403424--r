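#' Build the reaction network of the polymerization cycle
#'
#' Formalizes the dissipative polymerization-depolymerization cycle as
#' seven reaction channels grouped into three dynamic processes:
#' activation/relaxation (\code{open}, \code{close}, \code{relax_free}),
#' cooperative growth (\code{nucleate}, \code{elongate}, \code{join}) and
#' collapse (\code{relax_scission}, per-subunit relaxation inside chains
#' that severs the chain at the relaxed toroid).
#'
#' Bimolecular channels use counts-based combinatorics with the
#' volume-scaled stochastic rate: with \code{f} the uM carried by one
#' unit in the state's volume, nucleation has propensity
#' \code{2 k_nuc f * n_open (n_open - 1) / 2}, elongation
#' \code{k_el f * n_chains * n_open} (chain ends treated as equivalent
#' and saturating), joining \code{k_join f * C (C - 1) / 2} over distinct
#' chain pairs, and scission \code{k_relax_chain * total in-chain units}
#' (times the UV multiplier while a UV window is on).
#'
#' @param params A [rate_params()] object.
#' @return A named list of channels, each with fields \code{name},
#'   \code{propensity(state, uv = 1)} (events/day) and
#'   \code{apply(state)} (draws any needed random choices from the
#'   current R random number generator).
#' @export
#' @examples
#' net <- build_reaction_network(default_params())
#' names(net)
build_reaction_network <- function(params) {
  if (!inherits(params, "rate_params")) params <- do.call(rate_params, params)
  validate_rate_params(params)
  p <- params

  ch <- function(name, propensity, apply) {
    structure(list(name = name, propensity = propensity, apply = apply),
              class = "reaction_channel")
  }

  list(
    open = ch("open",
      function(state, uv = 1) p$k_open * state$n_active_closed,
      function(state) {
        state$n_active_closed <- state$n_active_closed - 1
        state$n_active_open <- state$n_active_open + 1
        state
      }),
    close = ch("close",
      function(state, uv = 1) p$k_close * state$n_active_open,
      function(state) {
        state$n_active_open <- state$n_active_open - 1
        state$n_active_closed <- state$n_active_closed + 1
        state
      }),
    relax_free = ch("relax_free",
      function(state, uv = 1) uv * p$k_relax_free * state$n_active_closed,
      function(state) {
        state$n_active_closed <- state$n_active_closed - 1
        state$n_inactive <- state$n_inactive + 1
        state
      }),
    nucleate = ch("nucleate",
      function(state, uv = 1) {
        n <- state$n_active_open
        2 * p$k_nuc * uM_per_unit(state) * n * (n - 1) / 2
      },
      function(state) {
        state$n_active_open <- state$n_active_open - 2
        state$chains <- c(state$chains, 2L)
        state
      }),
    elongate = ch("elongate",
      function(state, uv = 1) {
        p$k_el * uM_per_unit(state) * length(state$chains) * state$n_active_open
      },
      function(state) {
        i <- sample.int(length(state$chains), 1L)
        state$chains[i] <- state$chains[i] + 1L
        state$n_active_open <- state$n_active_open - 1
        state
      }),
    join = ch("join",
      function(state, uv = 1) {
        C <- length(state$chains)
        p$k_join * uM_per_unit(state) * C * (C - 1) / 2
      },
      function(state) {
        ij <- sample.int(length(state$chains), 2L)
        merged <- state$chains[ij[1L]] + state$chains[ij[2L]]
        state$chains <- c(state$chains[-ij], merged)
        state
      }),
    relax_scission = ch("relax_scission",
      function(state, uv = 1) {
        uv * p$k_relax_chain * sum(as.numeric(state$chains))
      },
      function(state) {
        len <- as.numeric(state$chains)
        i <- sample.int(length(len), 1L, prob = len)
        n <- state$chains[i]
        site <- sample.int(n, 1L)  # relaxed subunit, uniform over the chain
        state$chains <- state$chains[-i]
        state$n_inactive <- state$n_inactive + 1
        for (frag in c(site - 1L, n - site)) {
          if (frag >= 2L) {
            state$chains <- c(state$chains, frag)
          } else if (frag == 1L) {
            state$n_active_open <- state$n_active_open + 1
          }
        }
        state
      })
  )
}

#' Fire one reaction channel on a state
#'
#' Applies the channel's stoichiometry, drawing any random choices
#' (which chain elongates, which pair joins, which subunit relaxes) from
#' the current R random number generator. Total toroid units are
#' conserved by every channel.
#'
#' @param state A \code{"system_state"}.
#' @param channel One element of [build_reaction_network()].
#' @param uv UV rate multiplier in force (only affects the propensity
#'   check, not the stoichiometry).
#' @return The updated \code{"system_state"}.
#' @export
apply_channel <- function(state, channel, uv = 1) {
  stopifnot(inherits(channel, "reaction_channel"))
  if (channel$propensity(state, uv) <= 0) {
    stop("channel '", channel$name,
         "' applied to a state lacking its reactants", call. = FALSE)
  }
  st <- channel$apply(state)
  st
}

#' Instantaneous heat pulse
#'
#' Converts a deterministic fraction \code{activation_efficiency} of the
#' inactive pool into active closed toroids:
#' \code{floor(n_inactive * efficiency)} units move, the remainder stays
#' inactive. The 20-minute, 50 degree treatment is far shorter than the
#' day-scale dynamics, so the pulse is modelled as instantaneous.
#' In-chain subunits and toroid/chain structures are unaffected (chains
#' are active by construction; heat treatment leaves the toroidal
#' architecture intact).
#'
#' @param state A \code{"system_state"}.
#' @param params A [rate_params()] object (or an efficiency override in
#'   \code{efficiency}).
#' @param efficiency Optional override of \code{params$activation_efficiency}.
#' @return The post-pulse \code{"system_state"}.
#' @export
#' @examples
#' st <- initial_state(1000, 30)
#' apply_heat_pulse(st, default_params())
apply_heat_pulse <- function(state, params, efficiency = NULL) {
  eff <- if (is.null(efficiency)) params$activation_efficiency else efficiency
  if (is.na(eff) || eff < 0 || eff > 1) {
    stop("activation efficiency must lie in [0, 1]", call. = FALSE)
  }
  moved <- floor(state$n_inactive * eff)
  state$n_inactive <- state$n_inactive - moved
  state$n_active_closed <- state$n_active_closed + moved
  state
}
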