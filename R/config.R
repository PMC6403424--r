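CONFIG_SCHEMA_VERSION <- "1.0"

# allowed keys per config section; unknown keys are rejected
config_schema <- list(
  top = c("schema_version", "rates", "initial", "protocol", "geometry",
          "observables", "simulation"),
  rates = c("k_open_per_day", "k_close_per_day", "k_nuc_per_uM_per_day",
            "k_el_per_uM_per_day", "k_join_per_uM_per_day",
            "k_relax_free_per_day", "k_relax_chain_per_day",
            "uv_factor", "activation_efficiency"),
  initial = c("n_units", "conc_uM"),
  geometry = c("external_diameter_nm", "tube_diameter_nm", "pitch_nm",
               "chirality"),
  observables = c("cd_baseline", "cd_amplitude",
                  "cryotem_include_monomers", "cryotem_noise_sd_log"),
  simulation = c("t_end_days", "record_every_days", "seed"),
  event = c("kind", "time_days", "efficiency", "duration_days", "factor")
)

#' Default run configuration
#'
#' The shipped reference configuration: 30 uM represented by 1e4 toroid
#' units, the calibrated default rates, a single heat pulse at t = 0 and
#' a 15-day horizon recorded daily. All rate keys carry explicit units.
#'
#' @return A validated configuration list.
#' @export
default_run_config <- function() {
  p <- default_params()
  cfg <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    rates = list(
      k_open_per_day = p$k_open,
      k_close_per_day = p$k_close,
      k_nuc_per_uM_per_day = p$k_nuc,
      k_el_per_uM_per_day = p$k_el,
      k_join_per_uM_per_day = p$k_join,
      k_relax_free_per_day = p$k_relax_free,
      k_relax_chain_per_day = p$k_relax_chain,
      uv_factor = p$uv_factor,
      activation_efficiency = p$activation_efficiency
    ),
    initial = list(n_units = 1e4, conc_uM = 30),
    protocol = list(list(kind = "heat_pulse", time_days = 0)),
    geometry = list(external_diameter_nm = 12, tube_diameter_nm = 3,
                    pitch_nm = 3, chirality = 1),
    observables = list(cd_baseline = 0, cd_amplitude = 1,
                       cryotem_include_monomers = TRUE,
                       cryotem_noise_sd_log = 0.1),
    simulation = list(t_end_days = 15, record_every_days = 1, seed = 1)
  )
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks the schema version, rejects unknown keys at every level, and
#' type-checks the numeric fields before any computation.
#'
#' @param cfg A configuration list (e.g. from [read_run_config()]).
#' @return The validated configuration, invisibly usable.
#' @export
validate_run_config <- function(cfg) {
  reject_unknown <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown config key(s) at ", where, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(cfg$schema_version)) {
    stop("config lacks schema_version", call. = FALSE)
  }
  if (!identical(as.character(cfg$schema_version), CONFIG_SCHEMA_VERSION)) {
    stop(sprintf("config schema_version '%s' not supported (expected '%s')",
                 cfg$schema_version, CONFIG_SCHEMA_VERSION), call. = FALSE)
  }
  reject_unknown(cfg, config_schema$top, "top level")
  for (sec in c("rates", "initial", "geometry", "observables", "simulation")) {
    if (!is.null(cfg[[sec]])) reject_unknown(cfg[[sec]], config_schema[[sec]], sec)
  }
  if (!is.null(cfg$protocol)) {
    for (i in seq_along(cfg$protocol)) {
      ev <- cfg$protocol[[i]]
      reject_unknown(ev, config_schema$event, sprintf("protocol[%d]", i))
      if (!ev$kind %in% c("heat_pulse", "uv_pulse")) {
        stop(sprintf("protocol[%d]: unknown event kind '%s'", i, ev$kind),
             call. = FALSE)
      }
      if (is.null(ev$time_days) || ev$time_days < 0) {
        stop(sprintf("protocol[%d]: time_days must be >= 0", i), call. = FALSE)
      }
    }
  }
  # constructing the typed objects applies the full invariant checks
  config_params(cfg)
  config_geometry(cfg)
  cfg
}

#' Read a run configuration file (YAML or JSON)
#' @param path Configuration file path; format chosen by extension
#'   (.json reads as JSON, anything else as YAML — JSON-equivalent).
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' Write a run configuration file
#' @param cfg A validated configuration list.
#' @param path Output path (.yaml/.yml or .json).
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

# rates omitted from the config fall back to the calibrated defaults
#' @keywords internal
config_params <- function(cfg) {
  r <- cfg$rates
  d <- default_params()
  pick <- function(key, default) if (is.null(r[[key]])) default else r[[key]]
  rate_params(k_open = pick("k_open_per_day", d$k_open),
              k_close = pick("k_close_per_day", d$k_close),
              k_nuc = pick("k_nuc_per_uM_per_day", d$k_nuc),
              k_el = pick("k_el_per_uM_per_day", d$k_el),
              k_join = pick("k_join_per_uM_per_day", d$k_join),
              k_relax_free = pick("k_relax_free_per_day", d$k_relax_free),
              k_relax_chain = pick("k_relax_chain_per_day", d$k_relax_chain),
              uv_factor = pick("uv_factor", d$uv_factor),
              activation_efficiency = pick("activation_efficiency",
                                           d$activation_efficiency))
}

#' @keywords internal
config_geometry <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g)) return(toroid_geometry())
  d <- toroid_geometry()
  pick <- function(key, default) if (is.null(g[[key]])) default else g[[key]]
  toroid_geometry(external_diameter = pick("external_diameter_nm",
                                           d$external_diameter),
                  tube_diameter = pick("tube_diameter_nm", d$tube_diameter),
                  pitch = pick("pitch_nm", d$pitch),
                  chirality = pick("chirality", d$chirality))
}

#' @keywords internal
config_protocol <- function(cfg) {
  if (is.null(cfg$protocol) || !length(cfg$protocol)) return(protocol())
  protocol(lapply(cfg$protocol, function(e) {
    if (e$kind == "heat_pulse") {
      heat_event(e$time_days, e$efficiency)
    } else {
      uv_event(e$time_days,
               if (is.null(e$duration_days)) 5 / (60 * 24) else e$duration_days,
               e$factor)
    }
  }))
}

#' Run a full simulation from a configuration
#'
#' The programmatic equivalent of the command-line \code{simulate}
#' subcommand: builds parameters, initial state and protocol from the
#' config and runs the stochastic engine.
#'
#' @param cfg A validated configuration list.
#' @param seed Optional seed override (otherwise \code{simulation$seed}).
#' @return A \code{"toroid_sim"}.
#' @export
run_config <- function(cfg, seed = NULL) {
  cfg <- validate_run_config(cfg)
  params <- config_params(cfg)
  prot <- config_protocol(cfg)
  sim_cfg <- cfg$simulation
  if (is.null(seed)) seed <- sim_cfg$seed
  if (is.null(seed)) stop("no seed: pass one or set simulation$seed",
                          call. = FALSE)
  t_end <- if (is.null(sim_cfg$t_end_days)) 15 else sim_cfg$t_end_days
  every <- if (is.null(sim_cfg$record_every_days)) 1 else
    sim_cfg$record_every_days
  rts <- seq(0, t_end, by = every)
  ssa_simulate(initial_state(cfg$initial$n_units, cfg$initial$conc_uM),
               params, prot, t_end, rts, seed)
}

#' Reproducibility manifest of a run
#'
#' @param cfg The configuration used.
#' @param seed The seed used.
#' @param path Output JSON path.
#' @export
write_manifest <- function(cfg, seed, path) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "toroidyn",
    version = as.character(utils::packageVersion("toroidyn")),
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    config = cfg,
    rng = RNGkind()[1],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
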