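#' Kinetic rate parameters of the toroid polymerization network
#'
#' Container for all rate constants and event multipliers of the
#' activation / polymerization / collapse reaction network. Units are
#' explicit: first-order rates in 1/day, bimolecular rates in
#' 1/(uM day), times in days.
#'
#' @param k_open Closed -> open spiral transition rate of an active
#'   toroid (1/day).
#' @param k_close Open -> closed rate (1/day). The ratio
#'   \code{k_open / k_close} is the open/closed equilibrium constant of a
#'   single active toroid (default 5.5e-3).
#' @param k_nuc Bimolecular nucleation rate, open + open -> chain of 2
#'   (1/(uM day)). Nucleation is slow relative to elongation
#'   (cooperative mechanism).
#' @param k_el Bimolecular elongation rate, chain end + open toroid
#'   (1/(uM day)).
#' @param k_join Bimolecular end-to-end chain joining rate (1/(uM day));
#'   set to 0 to disable joining.
#' @param k_relax_free First-order relaxation (active -> inactive) of
#'   free closed toroids (1/day). The default \code{log(20)/20} makes the
#'   active fraction decay to 5\% of its post-pulse value in 20 days.
#' @param k_relax_chain Per-subunit first-order relaxation rate of
#'   in-chain toroids (1/day); each relaxation event severs the chain at
#'   the relaxed subunit.
#' @param uv_factor Dimensionless multiplier (>= 1) applied to both
#'   relaxation rates while a UV pulse is on.
#' @param activation_efficiency Fraction in [0, 1] of the inactive pool
#'   converted to active closed toroids by one heat pulse.
#'
#' @return An object of class \code{"rate_params"} (a named list).
#' @seealso [default_params()] for the shipped calibrated set,
#'   [build_reaction_network()] for the channels the rates drive.
#' @export
#' @examples
#' p <- rate_params(k_open = 0.55, k_close = 100)
#' p$k_open / p$k_close
rate_params <- function(k_open = 0.55,
                        k_close = 100,
                        k_nuc = 0.7,
                        k_el = 6000,
                        k_join = 220,
                        k_relax_free = log(20) / 20,
                        k_relax_chain = 0.07,
                        uv_factor = 2e4,
                        activation_efficiency = 1) {
  p <- list(
    k_open = k_open, k_close = k_close, k_nuc = k_nuc, k_el = k_el,
    k_join = k_join, k_relax_free = k_relax_free,
    k_relax_chain = k_relax_chain, uv_factor = uv_factor,
    activation_efficiency = activation_efficiency
  )
  validate_rate_params(p)
  structure(p, class = "rate_params")
}

#' @keywords internal
validate_rate_params <- function(p) {
  rates <- c("k_open", "k_close", "k_nuc", "k_el", "k_join",
             "k_relax_free", "k_relax_chain")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("invalid rate parameter '", nm, "': must be a single number >= 0",
           call. = FALSE)
    }
  }
  if (!is.numeric(p$uv_factor) || length(p$uv_factor) != 1L ||
      is.na(p$uv_factor) || p$uv_factor < 1) {
    stop("invalid rate parameter 'uv_factor': must be >= 1", call. = FALSE)
  }
  ae <- p$activation_efficiency
  if (!is.numeric(ae) || length(ae) != 1L || is.na(ae) || ae < 0 || ae > 1) {
    stop("invalid rate parameter 'activation_efficiency': must lie in [0, 1]",
         call. = FALSE)
  }
  invisible(p)
}

#' Shipped calibrated default parameter set
#'
#' The default rates reproduce the reference experimental conditions of the
#' system the package models: 30 uM toroids activated by a single heat
#' pulse polymerize with a short lag, the mean assembly length peaks near
#' day 4, the intensity-weighted hydrodynamic diameter grows from 12 nm to
#' roughly 250 nm by day 4, the chains then collapse over about 7 days,
#' and with polymerization disabled the active fraction relaxes to 5% of
#' its post-pulse value in 20 days (first-order circular dichroism decay).
#' The open/closed ratio is pinned at 5.5e-3. Absolute bimolecular rates
#' are calibration products of this package (see the methods vignette);
#' they are not measured constants.
#'
#' @return A \code{"rate_params"} object.
#' @export
#' @examples
#' default_params()
default_params <- function() {
  rate_params(
    k_open = 0.8,
    k_close = 0.8 / 5.5e-3,
    k_nuc = 0.7,
    k_el = 6000,
    k_join = 220,
    k_relax_free = log(20) / 20,
    k_relax_chain = 0.07,
    uv_factor = 2e4,
    activation_efficiency = 1
  )
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Toroid polymerization rate parameters\n")
  cat(sprintf("  k_open        %10.4g /day      k_close   %10.4g /day  (K = %.3g)\n",
              x$k_open, x$k_close,
              if (x$k_close > 0) x$k_open / x$k_close else NA_real_))
  cat(sprintf("  k_nuc         %10.4g /uM/day   k_el      %10.4g /uM/day (k_el/k_nuc = %.3g)\n",
              x$k_nuc, x$k_el,
              if (x$k_nuc > 0) x$k_el / x$k_nuc else Inf))
  cat(sprintf("  k_join        %10.4g /uM/day\n", x$k_join))
  cat(sprintf("  k_relax_free  %10.4g /day      k_relax_chain %6.4g /day/subunit\n",
              x$k_relax_free, x$k_relax_chain))
  cat(sprintf("  uv_factor     %10.4g           activation_efficiency %.3g\n",
              x$uv_factor, x$activation_efficiency))
  invisible(x)
}

#' Modify a subset of rate parameters
#'
#' @param params A \code{"rate_params"} object.
#' @param ... Named replacements for individual fields.
#' @return A validated \code{"rate_params"} object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "rate_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) {
    stop("unknown rate parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params[names(repl)] <- repl
  validate_rate_params(params)
  structure(params, class = "rate_params")
}
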