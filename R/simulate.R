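#' Simulation configuration
#'
#' @param dt Integration step, ms.
#' @param settle_s Settling period discarded from outputs, s (>= 0; the
#'   default model uses 10 s, enough for initial-condition transients of the
#'   slow persistent-sodium inactivation to wash out of the rhythm metrics).
#' @param record_s Recording duration when no epoch schedule is given, s.
#' @param threshold Spike detection threshold, mV.
#' @param trace_ids Neuron ids whose membrane potential is recorded
#'   (decimated to `trace_ms`).
#' @param trace_ms Voltage trace sampling interval, ms.
#' @return A list of class `cpg_sim_config`.
#' @export
sim_config <- function(dt = 0.1, settle_s = 10, record_s = 60,
                       threshold = -10, trace_ids = integer(),
                       trace_ms = 1) {
  stopifnot(dt > 0, settle_s >= 0, record_s > 0, trace_ms >= dt)
  structure(list(dt = dt, settle_s = settle_s, record_s = record_s,
                 threshold = threshold, trace_ids = as.integer(trace_ids),
                 trace_ms = trace_ms),
            class = "cpg_sim_config")
}

#' Photostimulation epoch constructor
#'
#' Exactly one of the two photoconductances may be nonzero within an epoch:
#' archaerhodopsin (`gAr`, hyperpolarising, reversal -80 mV) or
#' channelrhodopsin (`gCh`, depolarising, reversal -10 mV).
#'
#' @param label Epoch label.
#' @param duration_s Epoch duration, s.
#' @param gAr,gCh Photoconductance applied during the epoch, mS/cm^2.
#' @param target `"V1"`, `"V1-1"`, or `"both"` ("all V1 neurons").
#' @return One-row tibble usable in an epoch schedule.
#' @export
photostim_epoch <- function(label = "stim", duration_s, gAr = 0, gCh = 0,
                            target = "both") {
  if (gAr < 0 || gCh < 0)
    rlang::abort("photoconductances must be non-negative",
                 class = "spinalcpg_config_error")
  if (gAr > 0 && gCh > 0)
    rlang::abort("at most one of gAr/gCh may be nonzero in an epoch",
                 class = "spinalcpg_config_error")
  if (!target %in% c("V1", "V1-1", "both"))
    rlang::abort("target must be 'V1', 'V1-1' or 'both'",
                 class = "spinalcpg_config_error")
  tibble::tibble(epoch = label, duration_s = duration_s,
                 gAr = gAr, gCh = gCh, target = target)
}

target_code <- function(target) {
  c("V1" = 1, "V1-1" = 2, "both" = 3)[[target]]
}

#' Run a network simulation
#'
#' Advances the network with the exponential-Euler integrator through a
#' settling period (discarded) and a schedule of recording epochs. Within a
#' photostimulation epoch the selected V1-class neurons receive the epoch's
#' archaerhodopsin or channelrhodopsin conductance; outside every epoch both
#' are 0 (control condition). Given identical network and run seeds the
#' recordings are bit-identical across runs.
#'
#' @param network A `cpg_network`.
#' @param epochs Epoch schedule: tibble with `epoch`, `duration_s`, `gAr`,
#'   `gCh`, `target` rows (e.g. built from [photostim_epoch()] rows);
#'   `NULL` means a single control epoch of `config$record_s`.
#' @param config A [sim_config()].
#' @param seed Run seed (initial membrane potentials; required).
#' @param v0 Optional vector of initial membrane potentials (mV), one per
#'   neuron, overriding the seeded `U(EL - 5, EL + 5)` draw.
#' @return A `cpg_recordings` object: `spikes` tibble (`neuron`,
#'   `population`, `side`, `time_ms` relative to recording start, `epoch`),
#'   `epochs` tibble with absolute recording-window boundaries, `traces`
#'   (optional decimated voltages), `pop_sizes`, and `meta` (seeds,
#'   parameters, voltage range).
#' @export
run_simulation <- function(network, epochs = NULL, config = sim_config(),
                           seed, v0 = NULL) {
  stopifnot(inherits(network, "cpg_network"))
  if (missing(seed) || is.null(seed))
    rlang::abort("an explicit run seed is required", class = "spinalcpg_config_error")
  if (is.null(epochs)) {
    epochs <- tibble::tibble(epoch = "control", duration_s = config$record_s,
                             gAr = 0, gCh = 0, target = "both")
  }
  if (any(epochs$gAr > 0 & epochs$gCh > 0))
    rlang::abort("at most one of gAr/gCh may be nonzero in an epoch",
                 class = "spinalcpg_config_error")
  nrn <- network$neurons
  n <- nrow(nrn)
  settle_ms <- config$settle_s * 1000
  epochs$end_ms <- cumsum(epochs$duration_s) * 1000
  epochs$start_ms <- epochs$end_ms - epochs$duration_s * 1000
  total_ms <- settle_ms + max(epochs$end_ms)

  if (n == 0) {
    return(new_recordings(empty_spikes(), epochs, NULL, network, config, seed))
  }

  if (is.null(v0)) {
    v0 <- withr::with_seed(seed, stats::runif(n, nrn$EL - 5, nrn$EL + 5))
  } else stopifnot(length(v0) == n)

  # CSR edge layout by source neuron (0-based targets)
  ed <- network$edges
  ord <- order(ed$src)
  counts <- tabulate(ed$src, nbins = n)
  edge_ptr <- c(0L, cumsum(counts))
  edge_tgt <- as.integer(ed$tgt[ord] - 1L)
  edge_w <- ed$weight[ord]

  stim <- epochs[epochs$gAr > 0 | epochs$gCh > 0, , drop = FALSE]
  ep_mat <- if (nrow(stim)) {
    cbind(settle_ms + stim$start_ms, settle_ms + stim$end_ms,
          stim$gAr, stim$gCh, vapply(stim$target, target_code, numeric(1)))
  } else matrix(numeric(0), 0, 5)

  trace_every <- max(1L, as.integer(round(config$trace_ms / config$dt)))
  res <- cpp_run_network(
    nrn = list(C = nrn$C, gNa = nrn$gNa, gNaP = nrn$gNaP, gK = nrn$gK,
               gL = nrn$gL, EL = nrn$EL,
               has_nap = as.integer(nrn$has_inap), photo = as.integer(nrn$photo),
               ENa = 55, EK = -80, EAr = -80, ECh = -10),
    syn = list(gE = network$syn$gE, gI = network$syn$gI,
               EsynE = network$syn$EsynE, EsynI = network$syn$EsynI,
               tauE = network$syn$tauE, tauI = network$syn$tauI),
    edge_ptr = edge_ptr, edge_tgt = edge_tgt, edge_w = edge_w,
    g_drive = network_drive(network),
    epochs = ep_mat, v0 = v0, dt = config$dt, t_total_ms = total_ms,
    record_from_ms = settle_ms, spike_thresh = config$threshold,
    trace_idx = config$trace_ids, trace_every = trace_every)

  t_rec <- res$spike_time - settle_ms
  spikes <- tibble::tibble(
    neuron = res$spike_neuron,
    population = nrn$population[res$spike_neuron],
    side = nrn$side[res$spike_neuron],
    time_ms = t_rec,
    epoch = epochs$epoch[findInterval(t_rec, c(epochs$start_ms[1], epochs$end_ms),
                                      left.open = TRUE, rightmost.closed = TRUE)])
  traces <- NULL
  if (length(config$trace_ids)) {
    traces <- tibble::as_tibble(res$traces, .name_repair = "minimal")
    names(traces) <- paste0("n", config$trace_ids)
    traces$time_ms <- res$trace_time - settle_ms
  }
  rec <- new_recordings(spikes, epochs, traces, network, config, seed)
  rec$meta$v_range <- res$v_range
  rec
}

empty_spikes <- function() {
  tibble::tibble(neuron = integer(), population = character(),
                 side = character(), time_ms = numeric(), epoch = character())
}

new_recordings <- function(spikes, epochs, traces, network, config, seed) {
  pop_sizes <- dplyr::count(network$neurons, .data$population, .data$side,
                            name = "N")
  structure(list(
    spikes = spikes,
    epochs = epochs[, c("epoch", "start_ms", "end_ms", "gAr", "gCh", "target")],
    traces = traces,
    pop_sizes = pop_sizes,
    meta = list(dt = config$dt, settle_s = config$settle_s,
                threshold = config$threshold,
                run_seed = seed, build_seed = network$meta$seed,
                variant = network$meta$variant,
                topology = network$meta$topology,
                alpha = network$meta$alpha, d = network$meta$d,
                scale = network$meta$scale)
  ), class = "cpg_recordings")
}

#' @export
print.cpg_recordings <- function(x, ...) {
  cat(sprintf("<cpg_recordings> %s/%s model: %d spikes from %d populations over %.1f s\n",
              x$meta$variant, x$meta$topology, nrow(x$spikes),
              nrow(x$pop_sizes), max(x$epochs$end_ms) / 1000))
  cat(sprintf("  epochs: %s\n", paste(x$epochs$epoch, collapse = ", ")))
  cat(sprintf("  seeds: build %s, run %s\n",
              format(x$meta$build_seed), format(x$meta$run_seed)))
  invisible(x)
}

#' Simulate one isolated neuron
#'
#' Convenience wrapper building a one-neuron network (no synapses) and
#' running it; useful for regime scans and integrator validation.
#'
#' @param params Neuron parameter list from [neuron_parameters()].
#' @param duration_s Recorded duration, s.
#' @param settle_s Settling period, s.
#' @param dt Step, ms.
#' @param gSynE Constant excitatory conductance clamped onto the neuron
#'   (delivered through the drive pathway), mS/cm^2.
#' @param gAr,gCh Photoconductances applied for the whole recording, mS/cm^2
#'   (the neuron is treated as photocurrent-capable if either is nonzero).
#' @param V0 Initial membrane potential (default `EL`).
#' @param trace Record the voltage trace (sampled every `dt`)?
#' @return List with `spike_times` (ms, relative to recording start), and
#'   if `trace`, `trace` tibble (`time_ms`, `V`).
#' @export
run_single_neuron <- function(params, duration_s = 10, settle_s = 0, dt = 0.1,
                              gSynE = 0, gAr = 0, gCh = 0, V0 = params$EL,
                              trace = FALSE) {
  neurons <- tibble::tibble(
    id = 1L, population = "single", side = "left", index = 1L,
    C = params$C, gNa = params$gNa, gNaP = params$gNaP, gK = params$gK,
    gL = params$gL, EL_mean0 = params$EL, EL_eps = 0, EL = params$EL,
    has_inap = isTRUE(params$has_inap),
    photo = if (gAr > 0 || gCh > 0) 1L else 0L)
  net <- structure(list(
    neurons = neurons,
    edges = tibble::tibble(src = integer(), tgt = integer(), weight = numeric(),
                           source_pop = character(), target_pop = character(),
                           source_side = character(), target_side = character(),
                           laterality = character()),
    syn = synaptic_parameters(),
    meta = list(variant = "drug", topology = "intact", alpha = 0, d = 0,
                drive_weights = NULL, seed = 0L, scale = 1)), class = "cpg_network")
  epochs <- if (gAr > 0 || gCh > 0) {
    photostim_epoch("stim", duration_s, gAr = gAr, gCh = gCh, target = "V1")
  } else NULL
  cfg <- sim_config(dt = dt, settle_s = settle_s, record_s = duration_s,
                    trace_ids = if (trace) 1L else integer(),
                    trace_ms = dt)
  # clamp conductance rides the drive vector
  if (gSynE > 0) {
    net$meta$variant <- "brainstem"
    net$meta$drive_weights <- c(single = gSynE / net$syn$gEd)
    net$meta$d <- 1
  }
  rec <- run_simulation(net, epochs = epochs, config = cfg, seed = 1, v0 = V0)
  out <- list(spike_times = rec$spikes$time_ms)
  if (trace) out$trace <- tibble::tibble(time_ms = rec$traces$time_ms,
                                         V = rec$traces$n1)
  out
}

#' Classify the firing regime of a single-neuron spike train
#'
#' Splits the train at inter-spike intervals longer than `gap_ms`. The
#' neuron is `"silent"` with fewer than 3 spikes; `"tonic"` when a single
#' spike group spans the whole observation window (firing starts near the
#' window start and continues to its end); `"bursting"` otherwise —
#' several groups separated by long quiescent gaps, or one burst framed by
#' silence (periods near the silence boundary can exceed the window).
#'
#' @param spike_times Spike times, ms (relative to window start).
#' @param window_ms Observation window length, ms.
#' @param gap_ms Minimal inter-burst gap, ms.
#' @return List: `regime`, `n_bursts`, `burst_freq_hz` (burst onsets per
#'   second from mean inter-onset interval; `NA` with fewer than 2
#'   bursts).
#' @export
neuron_regime <- function(spike_times, window_ms, gap_ms = 300) {
  if (length(spike_times) < 3)
    return(list(regime = "silent", n_bursts = 0L, burst_freq_hz = NA_real_))
  isi <- diff(spike_times)
  grp <- cumsum(c(0, isi > gap_ms))
  sizes <- tabulate(grp + 1)
  n_grp <- length(sizes)
  edge <- 2 * gap_ms
  continuous <- n_grp == 1 && spike_times[1] < edge &&
    (window_ms - spike_times[length(spike_times)]) < edge
  # slow regular firing (isolated single spikes) is tonic, not bursting
  if (continuous || (n_grp >= 2 && mean(sizes) < 2))
    return(list(regime = "tonic", n_bursts = 1L, burst_freq_hz = NA_real_))
  onsets <- spike_times[!duplicated(grp)]
  freq <- if (n_grp > 1) (n_grp - 1) / (diff(range(onsets)) / 1000) else NA_real_
  list(regime = "bursting", n_bursts = n_grp, burst_freq_hz = freq)
}
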