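#' Read and validate a run configuration file
#'
#' YAML dialect describing one simulation: model (variant, topology, alpha,
#' d, drive weights, scale), simulation settings (dt, settle_s), an optional
#' protocol (name + overrides) or explicit epoch list, and mandatory seeds.
#' Explicit seeds are required: runs must be reproducible from the file
#' alone.
#'
#' @param path Path to a YAML configuration file.
#' @return Validated configuration list of class `cpg_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    rlang::abort(paste0("config file not found: ", path),
                 class = "spinalcpg_config_error")
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- function(key, where = cfg) {
    if (is.null(where[[key]]))
      rlang::abort(paste0("config missing required key: ", key),
                   class = "spinalcpg_config_error")
    where[[key]]
  }
  seeds <- need("seeds")
  for (k in c("build", "run")) need(k, seeds)
  if (is.null(cfg$protocol) && is.null(cfg$model))
    rlang::abort("config missing required key: model (or protocol)",
                 class = "spinalcpg_config_error")
  cfg$sim <- cfg$sim %||% list()
  cfg$sim$dt <- cfg$sim$dt %||% 0.1
  cfg$sim$settle_s <- cfg$sim$settle_s %||% 10
  cfg$sim$record_s <- cfg$sim$record_s %||% 60
  structure(cfg, class = "cpg_config")
}

#' Serialise a run configuration to YAML
#'
#' @param cfg A configuration list (as returned by [read_run_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Execute a run configuration end to end
#'
#' Builds the model, runs the simulation, analyses the rhythm, and writes a
#' self-describing output bundle: `raster.csv` (neuron, population, side,
#' spike time), `histograms.csv`, `metrics.csv`, `coordination.csv`, and
#' `run_log.yaml` (parameter echo, seeds, package version).
#'
#' @param cfg A `cpg_config` (or path to one).
#' @param out_dir Output directory (created if absent).
#' @return The `cpg_recordings`, invisibly.
#' @export
run_from_config <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- sim_config(dt = cfg$sim$dt, settle_s = cfg$sim$settle_s,
                    record_s = cfg$sim$record_s)
  if (!is.null(cfg$protocol)) {
    ov <- cfg$protocol
    nm <- ov$name %||% rlang::abort("protocol entry needs a name",
                                    class = "spinalcpg_config_error")
    ov$name <- NULL
    if (!is.null(ov$drive_weights)) ov$drive_weights <- unlist(ov$drive_weights)
    p <- do.call(make_protocol, c(list(nm), ov))
    seeds <- c(cfg$seeds$build, cfg$seeds$run)
    net <- default_model(variant = p$variant, topology = p$topology,
                         alpha = p$alpha, d = p$d,
                         drive_weights = p$drive_weights %||% default_drive_weights(),
                         scale = cfg$model$scale %||% 1, seed = seeds[1])
    rec <- run_simulation(net, epochs = protocol_epochs(p), config = sim,
                          seed = seeds[2])
    rec$meta$protocol <- p$name
  } else {
    m <- cfg$model
    net <- default_model(variant = m$variant %||% "drug",
                         topology = m$topology %||% "intact",
                         alpha = m$alpha %||% 0,
                         d = m$d %||% if ((m$variant %||% "drug") == "brainstem") 1 else 0,
                         drive_weights = if (is.null(m$drive_weights))
                           default_drive_weights() else unlist(m$drive_weights),
                         scale = m$scale %||% 1, seed = cfg$seeds$build)
    rec <- run_simulation(net, config = sim, seed = cfg$seeds$run)
  }
  write_raster_csv(rec, file.path(out_dir, "raster.csv"))
  pops <- unique(rec$pop_sizes$population)
  hist_tbl <- purrr::map(pops, function(p) {
    purrr::map(unique(rec$pop_sizes$side[rec$pop_sizes$population == p]),
               function(s) population_histogram(rec, p, s)) |>
      dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  readr::write_csv(hist_tbl, file.path(out_dir, "histograms.csv"))
  metrics <- rhythm_metrics(rec)
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
  coord <- coordination_summary(rec, window = "control")
  readr::write_csv(coord, file.path(out_dir, "coordination.csv"))
  log <- list(package_version = as.character(utils::packageVersion("spinalcpg")),
              seeds = list(build = rec$meta$build_seed, run = rec$meta$run_seed),
              variant = rec$meta$variant, topology = rec$meta$topology,
              alpha = rec$meta$alpha, d = rec$meta$d,
              scale = rec$meta$scale, dt = rec$meta$dt,
              settle_s = rec$meta$settle_s,
              protocol = rec$meta$protocol %||% "none")
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(rec)
}

#' Write / read a spike raster as CSV
#'
#' @param recordings A `cpg_recordings`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a spike tibble (reader).
#' @export
write_raster_csv <- function(recordings, path) {
  readr::write_csv(recordings$spikes, path)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    neuron = readr::col_integer(),
                    population = readr::col_character(),
                    side = readr::col_character(),
                    time_ms = readr::col_double(),
                    epoch = readr::col_character()))
}

#' Build a recordings object from an external spike raster
#'
#' Wraps a spike table in the container the analysis layer consumes, e.g.
#' for rasters written by [write_raster_csv()] or produced outside the
#' package in the same dialect.
#'
#' @param spikes Spike tibble (`neuron`, `population`, `side`, `time_ms`,
#'   optional `epoch`).
#' @param pop_sizes Tibble (`population`, `side`, `N`); when `NULL`, `N` is
#'   inferred as the number of distinct firing neurons per population
#'   (an undercount if some neurons stayed silent).
#' @param window_ms Recording window length; defaults to the last spike
#'   time rounded up to the next 100 ms.
#' @return A `cpg_recordings`.
#' @export
recordings_from_raster <- function(spikes, pop_sizes = NULL,
                                   window_ms = NULL) {
  if (is.null(spikes$epoch)) spikes$epoch <- "control"
  if (is.null(pop_sizes)) {
    pop_sizes <- dplyr::summarise(
      dplyr::group_by(spikes, .data$population, .data$side),
      N = dplyr::n_distinct(.data$neuron), .groups = "drop")
  }
  if (is.null(window_ms)) window_ms <- 100 * ceiling(max(spikes$time_ms) / 100)
  structure(list(
    spikes = spikes,
    epochs = tibble::tibble(epoch = unique(spikes$epoch)[1], start_ms = 0,
                            end_ms = window_ms, gAr = 0, gCh = 0,
                            target = "both"),
    traces = NULL, pop_sizes = pop_sizes,
    meta = list(dt = NA_real_, settle_s = NA_real_, threshold = NA_real_,
                run_seed = NA, build_seed = NA, variant = "external",
                topology = "external", alpha = NA_real_, d = NA_real_,
                scale = NA_real_)), class = "cpg_recordings")
}

#' Export a sampled connectome as a tabular edge list
#'
#' @param network A `cpg_network`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
export_connectome <- function(network, path) {
  readr::write_csv(network$edges, path)
  invisible(path)
}
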