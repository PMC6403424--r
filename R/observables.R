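#' Mean assembly length of a state
#'
#' @param state A \code{"system_state"}.
#' @param mode \code{"all_assemblies"} (default; free toroids count as
#'   length 1, matching cryo-TEM counting of every object in the image)
#'   or \code{"chains_only"} (average over chains, defined as 1 when no
#'   chain exists).
#' @return Mean length in toroid units.
#' @export
#' @examples
#' st <- system_state(n_active_open = 2, chains = c(2, 4))
#' mean_chain_length(st, "chains_only")    # 3
#' mean_chain_length(st, "all_assemblies") # (2*1 + 6)/4 = 2
mean_chain_length <- function(state, mode = c("all_assemblies", "chains_only")) {
  mode <- match.arg(mode)
  M <- sum(as.numeric(state$chains))
  C <- length(state$chains)
  if (mode == "chains_only") {
    if (C == 0) return(1)
    return(M / C)
  }
  free <- state$n_inactive + state$n_active_closed + state$n_active_open
  if (free + C == 0) return(1)
  (free + M) / (free + C)
}

#' Circular dichroism proxy
#'
#' The CD intensity at the diagnostic wavelength tracks the fraction of
#' subunits in the chirally slipped (active) packing; the proxy is affine
#' and monotone in that fraction, hence intensive: it does not depend on
#' system size at fixed composition, which is why the relaxation decay it
#' reports is concentration independent.
#'
#' @param active_fraction Fraction of subunits in the active state.
#' @param baseline Signal at zero active fraction.
#' @param amplitude Signal span (>= 0).
#' @export
cd_proxy <- function(active_fraction, baseline = 0, amplitude = 1) {
  if (any(amplitude < 0)) stop("amplitude must be >= 0", call. = FALSE)
  baseline + amplitude * active_fraction
}

#' Physical length of an assembly
#'
#' Chains of n toroid units measure n turns of the helix, n x pitch nm
#' along the axis; a single free toroid reports its external diameter.
#'
#' @param n_units Assembly size(s) in toroid units (>= 1).
#' @param geometry A [toroid_geometry()].
#' @export
#' @examples
#' length_to_nm(1)  # 12 nm, the toroid itself
#' length_to_nm(2)  # two turns
length_to_nm <- function(n_units, geometry = toroid_geometry()) {
  if (any(n_units < 1)) stop("n_units must be >= 1", call. = FALSE)
  ifelse(n_units == 1, geometry$external_diameter, n_units * geometry$pitch)
}

#' Inverse of [length_to_nm()]
#' @param nm Measured lengths (nm).
#' @inheritParams length_to_nm
#' @export
nm_to_length <- function(nm, geometry = toroid_geometry()) {
  ifelse(nm <= geometry$external_diameter, 1, nm / geometry$pitch)
}

# Hydrodynamic diameter of a single assembly. Monomers are spheres of the
# toroid's external diameter d. Chains are rigid rods of axial length
# L = n * pitch and diameter d with the short-rod end correction
# D_h = L / (ln(L/d) + 0.32). That expression has a minimum at
# L* = d e^{0.68} where it equals L*; below L* (stubby helices) the rod
# picture breaks down and we use D_h = max(d, L), which splices
# continuously and keeps D_h non-decreasing in chain length.
#' @keywords internal
assembly_dh <- function(n_units, geometry) {
  d <- geometry$external_diameter
  L <- n_units * geometry$pitch
  Lstar <- d * exp(0.68)
  dh <- ifelse(L > Lstar, L / (log(L / d) + 0.32), pmax(d, L))
  ifelse(n_units == 1, d, dh)
}

#' Dynamic light scattering proxy
#'
#' Intensity-weighted mean hydrodynamic diameter of the assembly
#' population: spheres (external diameter) for free toroids, rigid rods
#' with the standard short-rod end correction
#' \code{D_h = L / (ln(L/d) + 0.32)} for chains, weights proportional to
#' the squared assembly mass (units^2) as the simplest DLS-like
#' intensity weighting. Both rules are documented approximations; only
#' the 12 nm to a few-hundred-nm trend is meaningful.
#'
#' @param state A \code{"system_state"}.
#' @param geometry A [toroid_geometry()].
#' @param include_monomers Count free toroids in the average (default TRUE).
#' @return Intensity-weighted mean diameter in nm (NA for an empty state).
#' @export
#' @examples
#' dls_proxy(system_state(n_inactive = 100))  # all monomers: 12 nm
dls_proxy <- function(state, geometry = toroid_geometry(),
                      include_monomers = TRUE) {
  sizes <- as.numeric(state$chains)
  counts <- rep(1, length(sizes))
  if (include_monomers) {
    free <- state$n_inactive + state$n_active_closed + state$n_active_open
    if (free > 0) {
      sizes <- c(1, sizes)
      counts <- c(free, counts)
    }
  }
  if (!length(sizes)) return(NA_real_)
  dh <- assembly_dh(sizes, geometry)
  w <- counts * sizes^2
  sum(w * dh) / sum(w)
}

#' Simulated cryo-TEM length sample
#'
#' Draws \code{n} assemblies with probability proportional to their
#' number (each object in the field of view equally likely; monomers
#' included by default), maps them to physical length and applies
#' multiplicative log-normal measurement noise.
#'
#' @param state A \code{"system_state"}.
#' @param n Sample size (default 100 objects per time point).
#' @param noise_sd_log Standard deviation of the log-normal measurement
#'   noise (0 for exact lengths).
#' @param geometry A [toroid_geometry()].
#' @param include_monomers Whether free toroids are observable objects.
#' @return Numeric vector of \code{n} measured lengths (nm).
#' @export
sample_cryotem <- function(state, n = 100, noise_sd_log = 0.1,
                           geometry = toroid_geometry(),
                           include_monomers = TRUE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  sizes <- as.numeric(state$chains)
  counts <- rep(1, length(sizes))
  if (include_monomers) {
    free <- state$n_inactive + state$n_active_closed + state$n_active_open
    if (free > 0) {
      sizes <- c(1, sizes)
      counts <- c(free, counts)
    }
  }
  if (!length(sizes)) {
    # chains-only sampling of a chain-free field of view: report the
    # toroids themselves (what a micrograph would show)
    free <- state$n_inactive + state$n_active_closed + state$n_active_open
    if (free <= 0) stop("state holds no observable assemblies", call. = FALSE)
    sizes <- 1
    counts <- free
  }
  pick <- sample.int(length(sizes), n, replace = TRUE, prob = counts)
  true_nm <- length_to_nm(sizes[pick], geometry)
  if (noise_sd_log > 0) {
    true_nm <- true_nm * exp(stats::rnorm(n, 0, noise_sd_log))
  }
  true_nm
}

#' Observable time series of a simulation
#'
#' One row per snapshot: species counts, chain statistics, mean lengths
#' (units and nm), active fraction and the CD / DLS proxies.
#'
#' @param sim A \code{"toroid_sim"}.
#' @param geometry A [toroid_geometry()].
#' @param cd_baseline,cd_amplitude Passed to [cd_proxy()].
#' @return A data.frame.
#' @export
sim_observables <- function(sim, geometry = toroid_geometry(),
                            cd_baseline = 0, cd_amplitude = 1) {
  rows <- lapply(sim$states, function(st) {
    ml <- mean_chain_length(st, "all_assemblies")
    data.frame(
      time = st$time,
      n_inactive = st$n_inactive,
      n_active_closed = st$n_active_closed,
      n_active_open = st$n_active_open,
      n_chains = length(st$chains),
      chain_units = sum(as.numeric(st$chains)),
      mean_length_units = ml,
      mean_length_chains = mean_chain_length(st, "chains_only"),
      mean_length_nm = {
        free <- st$n_inactive + st$n_active_closed + st$n_active_open
        C <- length(st$chains)
        if (free + C == 0) geometry$external_diameter
        else (free * geometry$external_diameter +
                sum(length_to_nm(pmax(as.numeric(st$chains), 2), geometry))) /
          (free + C)
      },
      active_fraction = active_fraction(st),
      cd_signal = cd_proxy(active_fraction(st), cd_baseline, cd_amplitude),
      dls_nm = dls_proxy(st, geometry)
    )
  })
  do.call(rbind, rows)
}
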