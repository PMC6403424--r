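#' Mean-field initial state
#'
#' Deterministic (length-resolved master equation) image of the
#' stochastic model: concentrations in uM of the free species plus a
#' truncated chain-length distribution \code{c_n}, n = 2..n_max (uM of
#' chains).
#'
#' @param conc_uM Total toroid-unit concentration (uM), all inactive.
#' @param n_max Truncation length (>= 2). The default 3000 keeps the
#'   truncation leakage of the calibrated default dynamics well below
#'   the tolerated bound over a 15-day horizon.
#' @return An object of class \code{"meanfield_state"}.
#' @export
meanfield_init <- function(conc_uM = 30, n_max = 3000) {
  if (n_max < 2) stop("n_max must be >= 2", call. = FALSE)
  structure(list(inactive = conc_uM, active_closed = 0, active_open = 0,
                 c = numeric(n_max - 1), n_max = as.integer(n_max)),
            class = "meanfield_state")
}

#' Convert a stochastic state to its mean-field image
#' @param state A \code{"system_state"}.
#' @param n_max Truncation length.
#' @export
as_meanfield <- function(state, n_max = 3000) {
  f <- uM_per_unit(state)
  mf <- meanfield_init(0, n_max)
  mf$inactive <- state$n_inactive * f
  mf$active_closed <- state$n_active_closed * f
  mf$active_open <- state$n_active_open * f
  if (length(state$chains)) {
    tab <- table(factor(pmin(state$chains, n_max), levels = 2:n_max))
    mf$c <- as.numeric(tab) * f
  }
  mf
}

# RHS of the length-resolved mean-field system. y = (I, A, O, c_2..c_nmax,
# leak_units); leak_units absorbs the unit mass of chains pushed past the
# truncation by elongation or joining so that total units stay conserved.
# The heavy lifting (elongation ladder, scission tail sums, FFT-based
# joining convolution) is compiled; see src/meanfield.cpp.
#' @keywords internal
meanfield_rhs <- function(t, y, parms) {
  list(meanfield_rhs_cpp(t, y, parms$p, parms$uv,
                         isTRUE(parms$reflect), isTRUE(parms$qss)))
}

#' Deterministic simulation of the mean-field master equation
#'
#' Integrates the length-resolved ODE twin of the stochastic network
#' with event handling at protocol times. Truncation leakage (unit mass
#' pushed past \code{n_max} by elongation/joining) is tracked in an
#' absorbing bin and the run fails loudly when it exceeds
#' \code{leak_bound} of the total units: raise \code{n_max}.
#'
#' @param initial A \code{"meanfield_state"} (see [meanfield_init()]).
#' @param params A [rate_params()] object.
#' @param protocol A [protocol()].
#' @param t_end Horizon (days).
#' @param record_times Output times (default: daily).
#' @param rel_tol,abs_tol Solver tolerances (> 0).
#' @param leak_bound Maximum tolerated truncation leakage as a fraction
#'   of total units (default 1e-3).
#' @param method deSolve integration method. The default \code{"adams"}
#'   (variable-order, Jacobian-free) suits this system: the RHS is cheap
#'   but the length-resolved state is large, so the dense-Jacobian setup
#'   of the stiff solvers costs far more than the moderate step-size
#'   limit set by the fast open/close interconversion.
#' @param boundary Truncation handling at \code{n_max}: \code{"leak"}
#'   (default; flux past the boundary drains into an absorbing bin,
#'   subject to \code{leak_bound}) or \code{"reflect"} (boundary chains
#'   stop elongating and over-long pair joins are rejected, conserving
#'   units exactly; used by the fitting objective, where the mass
#'   partition rather than the far tail drives the observables).
#' @param qss_open Treat the open-spiral pool as quasi-stationary
#'   (\code{O* = k_open A / (k_close + k_el C)}), folding its sub-percent
#'   mass into the closed pool. Removes the fastest time scales so the
#'   integrator takes ~10x fewer steps; used by the fitting objective.
#'   The full two-state dynamics remain the default.
#' @return An object of class \code{"meanfield_sim"}: \code{times},
#'   \code{summary} (data.frame of observables), \code{c} (matrix of
#'   chain-length concentrations, one row per time), \code{leak_units}.
#' @export
#' @examples
#' mf <- ode_simulate(meanfield_init(30, 400), default_params(),
#'                    single_fuel(), t_end = 2, record_times = 0:2,
#'                    rel_tol = 1e-6, abs_tol = 1e-9, boundary = "reflect")
#' mf$summary$mean_length_units
ode_simulate <- function(initial, params, protocol = single_fuel(), t_end,
                         record_times = NULL, rel_tol = 1e-8,
                         abs_tol = 1e-10, leak_bound = 1e-3,
                         method = "adams",
                         boundary = c("leak", "reflect"),
                         qss_open = FALSE) {
  boundary <- match.arg(boundary)
  if (!inherits(initial, "meanfield_state")) stop("initial must be a meanfield_state")
  if (!inherits(params, "rate_params")) params <- do.call(rate_params, params)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (is.null(record_times)) record_times <- seq(0, t_end, by = 1)
  record_times <- sort(unique(as.numeric(record_times)))
  if (any(record_times < 0) || any(record_times > t_end)) {
    stop("record_times must lie within [0, t_end]", call. = FALSE)
  }

  m <- initial$n_max - 1L
  ns <- seq.int(2L, initial$n_max)
  y <- c(initial$inactive, initial$active_closed, initial$active_open,
         initial$c, 0)
  total0 <- y[1] + y[2] + y[3] + sum(ns * initial$c)
  segs <- protocol_segments(protocol, t_end, params)

  out_times <- numeric(0)
  out_rows <- NULL
  for (si in seq_along(segs$segments)) {
    seg <- segs$segments[[si]]
    for (e in seg$heat) {
      eff <- if (is.null(e$efficiency)) params$activation_efficiency else e$efficiency
      moved <- y[1] * eff
      y[1] <- y[1] - moved
      y[2] <- y[2] + moved
    }
    last_seg <- si == length(segs$segments)
    keep <- record_times >= seg$t0 &
      (if (last_seg) record_times <= seg$t1 else record_times < seg$t1)
    tt <- sort(unique(c(seg$t0, record_times[keep], seg$t1)))
    if (length(tt) < 2) tt <- c(seg$t0, seg$t1)
    parms <- list(p = params, uv = seg$uv, m = m, ns = ns,
                  reflect = boundary == "reflect", qss = qss_open)
    sol <- suppressWarnings(
      deSolve::ode(y = y, times = tt, func = meanfield_rhs,
                   parms = parms, method = method, rtol = rel_tol,
                   atol = abs_tol, maxsteps = 20000)
    )
    # a negative istate or a truncated output (early return on excessive
    # work) are both integration failures; never hand back partial rows
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(tt)) {
      dy <- meanfield_rhs(tt[length(tt)], y, parms)[[1]]
      wi <- which.max(abs(dy))
      stop(sprintf("solver failure in segment [%g, %g] (reached t = %g); worst derivative index %d (%.3g)",
                   seg$t0, seg$t1, sol[nrow(sol), 1], wi, dy[wi]),
           call. = FALSE)
    }
    sel <- sol[, 1] %in% record_times[keep]
    out_times <- c(out_times, sol[sel, 1])
    out_rows <- rbind(out_rows, sol[sel, -1, drop = FALSE])
    y <- as.numeric(sol[nrow(sol), -1])
  }
  for (e in segs$final_heat) {
    eff <- if (is.null(e$efficiency)) params$activation_efficiency else e$efficiency
    y[2] <- y[2] + y[1] * eff
    y[1] <- y[1] * (1 - eff)
  }

  leak <- out_rows[, ncol(out_rows)]
  if (boundary == "leak" && max(leak) > leak_bound * total0) {
    stop(sprintf("truncation leakage %.3g uM exceeds %.3g of total units: raise n_max",
                 max(leak), leak_bound), call. = FALSE)
  }

  cmat <- out_rows[, 4:(3 + m), drop = FALSE]
  cmat[cmat < 0] <- 0
  I <- out_rows[, 1]; A <- out_rows[, 2]; O <- out_rows[, 3]
  Ctot <- as.numeric(cmat %*% rep(1, m))
  M <- as.numeric(cmat %*% ns)
  free <- I + A + O
  total <- free + M
  summary <- data.frame(
    time = out_times,
    inactive = I, active_closed = A, active_open = O,
    chain_conc = Ctot, chain_units = M,
    mean_length_units = ifelse(free + Ctot > 0, (free + M) / (free + Ctot), 1),
    mean_length_chains = ifelse(Ctot > 0, M / Ctot, 1),
    active_fraction = ifelse(total > 0, (A + O + M) / total, 0),
    total_units = total,
    leak_units = leak
  )
  structure(list(times = out_times, summary = summary, c = cmat,
                 lengths = ns, total0 = total0, params = params),
            class = "meanfield_sim")
}

#' @export
print.meanfield_sim <- function(x, ...) {
  drift <- max(abs(x$summary$total_units + x$summary$leak_units - x$total0)) /
    x$total0
  cat(sprintf("meanfield_sim: %d time points over [%g, %g] d, n_max %d, rel. mass drift %.2g\n",
              length(x$times), min(x$times), max(x$times),
              max(x$lengths), drift))
  invisible(x)
}

#' Cross-validation of the stochastic engine against the mean-field twin
#'
#' Runs an SSA ensemble and the ODE from the same configuration and
#' reports per-time z-scores of the ensemble mean against the
#' deterministic solution for the mean assembly length and the active
#' fraction. Passes when |z| <= 3 at >= 95 percent of compared times.
#'
#' @param initial A \code{"system_state"}.
#' @param params A [rate_params()] object.
#' @param protocol A [protocol()].
#' @param t_end Horizon (days).
#' @param record_times Comparison times.
#' @param n_reps SSA replicates.
#' @param seed_base Base seed for the ensemble.
#' @param n_max ODE truncation.
#' @param params_ode Optional different parameter set for the ODE side
#'   (negative-control use).
#' @return List with \code{table} (time, observable, z), \code{pass}.
#' @export
crosscheck_with_ssa <- function(initial, params, protocol = single_fuel(),
                                t_end = 6, record_times = 0:6, n_reps = 20,
                                seed_base = 1, n_max = 2000,
                                params_ode = params) {
  ens <- run_ensemble(n_reps, seed_base, initial, params, protocol,
                      t_end, record_times)
  conc <- total_units(initial) * uM_per_unit(initial)
  mf0 <- as_meanfield(initial, n_max)
  ode <- ode_simulate(mf0, params_ode, protocol, t_end, record_times)

  zrow <- function(obs) {
    mu <- ens$summary[[obs]]
    sdv <- ens$sd[[obs]]
    se <- sdv / sqrt(n_reps)
    ref <- ode$summary[[obs]]
    z <- ifelse(se > 0, (mu - ref) / se,
                ifelse(abs(mu - ref) < 1e-12, 0, Inf))
    data.frame(time = ens$summary$time, observable = obs, ssa = mu,
               ode = ref, z = z)
  }
  tab <- rbind(zrow("mean_length_units"), zrow("active_fraction"))
  pass <- mean(abs(tab$z) <= 3) >= 0.95
  list(table = tab, pass = pass, n_reps = n_reps, conc_uM = conc)
}
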