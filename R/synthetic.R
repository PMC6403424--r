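DATASET_SCHEMA_VERSION <- "1.0"

#' Generate a synthetic experimental dataset
#'
#' Runs one stochastic trajectory and converts it into the three data
#' streams the analysis consumes, with realistic measurement noise:
#' per-time cryo-TEM length samples (n objects per time point,
#' multiplicative log-normal noise), a CD trace (affine proxy of the
#' active fraction with additive Gaussian noise) and a DLS trace
#' (intensity-weighted diameter with relative Gaussian noise). The
#' noiseless ground truth is stored alongside; regeneration from the
#' stored metadata is bit-identical.
#'
#' @param params Generating [rate_params()].
#' @param protocol Energy input [protocol()].
#' @param sample_times Observation times (days).
#' @param n_per_time Cryo-TEM objects measured per time point (default 100).
#' @param noise List with \code{cryotem_sd_log} (sd of log-normal length
#'   noise), \code{cd_sd} (additive CD sd, fraction of amplitude),
#'   \code{dls_rel_sd} (relative DLS sd). Zeros give exact observations.
#' @param seed Integer seed controlling the trajectory and all noise.
#' @param n_units Desk-scale unit count.
#' @param conc_uM Total concentration the units represent.
#' @param geometry A [toroid_geometry()].
#' @param include_monomers Whether cryo-TEM sampling sees free toroids.
#' @return An object of class \code{"toroid_dataset"} with fields
#'   \code{metadata}, \code{cryotem} (long data.frame: time_days,
#'   replicate, length_nm), \code{cd_trace}, \code{dls_trace},
#'   \code{truth}.
#' @export
#' @examples
#' ds <- generate_dataset(default_params(), single_fuel(), c(0, 2, 4),
#'                        n_per_time = 20, seed = 7, n_units = 1000)
#' head(ds$cryotem)
generate_dataset <- function(params, protocol = single_fuel(),
                             sample_times = c(0, 1, 2, 3, 4, 5, 8, 12),
                             n_per_time = 100,
                             noise = list(cryotem_sd_log = 0.1,
                                          cd_sd = 0.02,
                                          dls_rel_sd = 0.05),
                             seed = 1, n_units = 1e4, conc_uM = 30,
                             geometry = toroid_geometry(),
                             include_monomers = TRUE) {
  sample_times <- sort(unique(as.numeric(sample_times)))
  sim <- ssa_simulate(initial_state(n_units, conc_uM), params, protocol,
                      t_end = max(sample_times), record_times = sample_times,
                      seed = seed)
  truth <- sim_observables(sim, geometry)
  # one RNG stream for all measurement noise, seeded independently of the
  # trajectory seed so truth and noise are separable but reproducible
  set.seed(as.integer(seed) + 1000003L)
  cstream <- lapply(seq_along(sample_times), function(i) {
    ln <- sample_cryotem(sim$states[[i]], n_per_time,
                         noise_sd_log = noise$cryotem_sd_log,
                         geometry = geometry,
                         include_monomers = include_monomers)
    data.frame(time_days = sample_times[i], replicate = seq_len(n_per_time),
               length_nm = ln)
  })
  cryotem <- do.call(rbind, cstream)
  cd <- truth$cd_signal
  if (noise$cd_sd > 0) cd <- cd + stats::rnorm(length(cd), 0, noise$cd_sd)
  dls <- truth$dls_nm
  if (noise$dls_rel_sd > 0) {
    dls <- dls * (1 + stats::rnorm(length(dls), 0, noise$dls_rel_sd))
  }
  structure(list(
    metadata = list(schema_version = DATASET_SCHEMA_VERSION,
                    params = unclass(params),
                    protocol = protocol_to_list(protocol),
                    sample_times = sample_times,
                    n_per_time = n_per_time, noise = noise,
                    seed = as.integer(seed), n_units = n_units,
                    conc_uM = conc_uM,
                    geometry = unclass(geometry),
                    include_monomers = include_monomers),
    cryotem = cryotem,
    cd_trace = data.frame(time_days = sample_times, cd_signal = cd),
    dls_trace = data.frame(time_days = sample_times, diameter_nm = dls),
    truth = truth
  ), class = "toroid_dataset")
}

#' @export
print.toroid_dataset <- function(x, ...) {
  cat(sprintf("toroid_dataset: %d time points, %d cryo-TEM objects/time, seed %d\n",
              length(x$metadata$sample_times), x$metadata$n_per_time,
              x$metadata$seed))
  invisible(x)
}

#' Fitting table of a synthetic dataset
#'
#' Collapses the cryo-TEM length samples to per-time mean and standard
#' error and joins the CD trace, yielding the table [calibrate()]
#' consumes.
#'
#' @param dataset A \code{"toroid_dataset"}.
#' @return data.frame with time_days, mean_length_nm, mean_length_se,
#'   cd_signal.
#' @export
dataset_for_fit <- function(dataset) {
  ag <- stats::aggregate(length_nm ~ time_days, dataset$cryotem,
                         function(v) c(mean(v), stats::sd(v) / sqrt(length(v))))
  out <- data.frame(time_days = ag$time_days,
                    mean_length_nm = ag$length_nm[, 1],
                    mean_length_se = pmax(ag$length_nm[, 2], 1e-6))
  merge(out, dataset$cd_trace, by = "time_days")
}

#' @keywords internal
protocol_to_list <- function(prot) {
  lapply(prot$events, function(e) e[!vapply(e, is.null, logical(1))])
}

#' @keywords internal
protocol_from_list <- function(lst) {
  if (is.data.frame(lst)) {
    # a JSON reader may have collapsed the event list to a data.frame
    lst <- lapply(seq_len(nrow(lst)), function(i) {
      row <- as.list(lst[i, , drop = FALSE])
      row[!vapply(row, function(v) length(v) != 1 || is.na(v), logical(1))]
    })
  }
  protocol(lapply(lst, function(e) {
    if (e$kind == "heat_pulse") {
      heat_event(e$time, e$efficiency)
    } else {
      uv_event(e$time, e$duration, e$factor)
    }
  }))
}

#' Write a synthetic dataset to a directory
#'
#' Lossless plain-text layout: \code{manifest.json} (metadata, schema
#' version and md5 checksums) plus \code{cryotem.csv}, \code{cd.csv},
#' \code{dls.csv}, \code{truth.csv}.
#'
#' @param dataset A \code{"toroid_dataset"}.
#' @param path Output directory (created if missing).
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(cryotem = dataset$cryotem, cd = dataset$cd_trace,
               dls = dataset$dls_trace, truth = dataset$truth)
  sums <- list()
  for (nm in names(tabs)) {
    fp <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], fp, row.names = FALSE)
    sums[[paste0(nm, ".csv")]] <- unname(tools::md5sum(fp))
  }
  manifest <- c(dataset$metadata, list(checksums = sums))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a synthetic dataset back from a directory
#'
#' Verifies the schema version and the md5 checksum of every table
#' before returning; a mismatch is an explicit error.
#'
#' @param path Directory written by [write_dataset()].
#' @return A \code{"toroid_dataset"}.
#' @export
read_dataset <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  if (!identical(mf$schema_version, DATASET_SCHEMA_VERSION)) {
    stop(sprintf("dataset schema version mismatch: file has '%s', package reads '%s'",
                 mf$schema_version, DATASET_SCHEMA_VERSION), call. = FALSE)
  }
  for (nm in names(mf$checksums)) {
    fp <- file.path(path, nm)
    if (!file.exists(fp)) stop("missing dataset table: ", nm, call. = FALSE)
    if (!identical(unname(tools::md5sum(fp)), mf$checksums[[nm]])) {
      stop("checksum mismatch for dataset table ", nm, call. = FALSE)
    }
  }
  meta <- mf[setdiff(names(mf), "checksums")]
  structure(list(
    metadata = meta,
    cryotem = utils::read.csv(file.path(path, "cryotem.csv")),
    cd_trace = utils::read.csv(file.path(path, "cd.csv")),
    dls_trace = utils::read.csv(file.path(path, "dls.csv")),
    truth = utils::read.csv(file.path(path, "truth.csv"))
  ), class = "toroid_dataset")
}

#' Regenerate a dataset from its stored metadata
#'
#' Re-runs [generate_dataset()] with the metadata's parameters, protocol
#' and seed; the result is bit-identical to the original.
#'
#' @param dataset A \code{"toroid_dataset"} (possibly read from disk).
#' @export
regenerate_dataset <- function(dataset) {
  md <- dataset$metadata
  params <- do.call(rate_params, md$params)
  geom <- do.call(toroid_geometry, md$geometry)
  prot <- protocol_from_list(md$protocol)
  generate_dataset(params, prot, md$sample_times, md$n_per_time,
                   as.list(md$noise), md$seed, md$n_units, md$conc_uM,
                   geom, md$include_monomers)
}
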