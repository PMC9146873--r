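#' Named experiment protocols
#'
#' Returns one of the nine canonical experiment recipes: drug-induced or
#' brainstem-evoked locomotion, intact cord or hemicord, with optional
#' photostimulation of the V1-class populations. Defaults (drug-excitation
#' level `alpha`, drive level `d`, photoconductance magnitudes) follow the
#' condition each protocol models; any field can be overridden.
#'
#' Valid names: `intact_drug_control`, `intact_drug_v1_hyper`,
#' `intact_drug_v1_depol`, `hemicord_drug_control`,
#' `hemicord_drug_v1_hyper`, `hemicord_drug_v1_depol`,
#' `brainstem_control`, `brainstem_v1_depol`, `brainstem_v1_hyper`.
#'
#' @param name Protocol name (see above).
#' @param ... Named overrides of protocol fields (`alpha`, `d`, `gAr`,
#'   `gCh`, `target`, `control_s`, `stim_s`, `recovery_s`,
#'   `drive_weights`).
#' @return A `cpg_protocol` list: `name`, `variant`, `topology`, `alpha`,
#'   `d`, `drive_weights`, `gAr`, `gCh`, `target`, `control_s`, `stim_s`,
#'   `recovery_s`.
#' @export
make_protocol <- function(name, ...) {
  defaults <- list(
    intact_drug_control    = list(variant = "drug", topology = "intact",
                                  alpha = 0.17, gAr = 0, gCh = 0),
    intact_drug_v1_hyper   = list(variant = "drug", topology = "intact",
                                  alpha = 0.16, gAr = 7, gCh = 0),
    intact_drug_v1_depol   = list(variant = "drug", topology = "intact",
                                  alpha = 0.15, gAr = 0, gCh = 0.7),
    hemicord_drug_control  = list(variant = "drug", topology = "hemicord",
                                  alpha = 0.2, gAr = 0, gCh = 0),
    hemicord_drug_v1_hyper = list(variant = "drug", topology = "hemicord",
                                  alpha = 0.18, gAr = 7, gCh = 0),
    hemicord_drug_v1_depol = list(variant = "drug", topology = "hemicord",
                                  alpha = 0.2, gAr = 0, gCh = 0.7),
    brainstem_control      = list(variant = "brainstem", topology = "intact",
                                  alpha = 0, gAr = 0, gCh = 0),
    brainstem_v1_depol     = list(variant = "brainstem", topology = "intact",
                                  alpha = 0, gAr = 0, gCh = 0.7),
    brainstem_v1_hyper     = list(variant = "brainstem", topology = "intact",
                                  alpha = 0, gAr = 7, gCh = 0)
  )
  if (!name %in% names(defaults))
    rlang::abort(paste0("unknown protocol '", name, "'; valid names: ",
                        paste(names(defaults), collapse = ", ")),
                 class = "spinalcpg_config_error")
  p <- defaults[[name]]
  p$name <- name
  p$d <- if (p$variant == "brainstem") 1 else 0
  p$drive_weights <- if (p$variant == "brainstem") default_drive_weights() else NULL
  p$target <- "both"
  p$control_s <- 60; p$stim_s <- 60; p$recovery_s <- 60
  ov <- list(...)
  bad <- setdiff(names(ov), c("alpha", "d", "gAr", "gCh", "target",
                              "control_s", "stim_s", "recovery_s",
                              "drive_weights"))
  if (length(bad))
    rlang::abort(paste0("unknown protocol field(s): ", paste(bad, collapse = ", ")),
                 class = "spinalcpg_config_error")
  p[names(ov)] <- ov
  if (p$gAr > 0 && p$gCh > 0)
    rlang::abort("a protocol applies at most one of gAr/gCh",
                 class = "spinalcpg_config_error")
  structure(p, class = "cpg_protocol")
}

#' Epoch schedule of a protocol
#'
#' Control epoch, then (when the protocol stimulates) a photostimulation
#' epoch and a recovery epoch.
#'
#' @param protocol A `cpg_protocol`.
#' @param recovery Include the recovery epoch (default TRUE)?
#' @return Epoch tibble for [run_simulation()].
#' @export
protocol_epochs <- function(protocol, recovery = TRUE) {
  stopifnot(inherits(protocol, "cpg_protocol"))
  has_stim <- protocol$gAr > 0 || protocol$gCh > 0
  ep <- tibble::tibble(epoch = "control", duration_s = protocol$control_s,
                       gAr = 0, gCh = 0, target = protocol$target)
  if (has_stim) {
    ep <- dplyr::bind_rows(
      ep,
      photostim_epoch("stim", protocol$stim_s, gAr = protocol$gAr,
                      gCh = protocol$gCh, target = protocol$target))
    if (recovery)
      ep <- dplyr::bind_rows(ep, tibble::tibble(
        epoch = "recovery", duration_s = protocol$recovery_s,
        gAr = 0, gCh = 0, target = protocol$target))
  }
  ep
}

#' Build the network a protocol calls for and run it
#'
#' @param protocol A `cpg_protocol` from [make_protocol()].
#' @param scale Model size scaling factor.
#' @param seed Build/run master seed (two independent streams are derived:
#'   structural sampling and initial conditions).
#' @param config A [sim_config()]; its `record_s` is ignored in favour of
#'   the protocol's epoch durations.
#' @param recovery Include the recovery epoch?
#' @return A `cpg_recordings`.
#' @export
run_protocol <- function(protocol, scale = 1, seed = 1,
                         config = sim_config(), recovery = TRUE) {
  stopifnot(inherits(protocol, "cpg_protocol"))
  seeds <- derive_seeds(seed, 2L)
  net <- default_model(variant = protocol$variant, topology = protocol$topology,
                       alpha = protocol$alpha, d = protocol$d,
                       drive_weights = protocol$drive_weights %||%
                         default_drive_weights(),
                       scale = scale, seed = seeds[1])
  rec <- run_simulation(net, epochs = protocol_epochs(protocol, recovery),
                        config = config, seed = seeds[2])
  rec$meta$protocol <- protocol$name
  rec
}

#' Frequency-versus-excitation sweep
#'
#' Runs the drug-variant model across a grid of drug-excitation levels
#' (`alpha`) for the requested topologies and replicate seeds, measuring the
#' flexor-half-center burst frequency in each run. Non-oscillatory runs
#' (< 3 bursts in the window) are flagged, not dropped.
#'
#' @param alphas Strictly increasing grid of excitation levels.
#' @param topologies Character subset of `c("intact", "hemicord")`.
#' @param replicates Number of replicate seeds per grid point.
#' @param seed Master seed from which replicate seeds derive.
#' @param scale Model size scaling factor.
#' @param config A [sim_config()] (its `record_s` is the measurement
#'   window).
#' @return A `cpg_sweep` tibble: `alpha`, `topology`, `replicate`,
#'   `frequency_hz`, `n_bursts`, `oscillatory`.
#' @export
alpha_sweep <- function(alphas = seq(0.12, 0.24, by = 0.02),
                        topologies = c("intact", "hemicord"),
                        replicates = 3, seed = 1, scale = 1,
                        config = sim_config()) {
  if (any(diff(alphas) <= 0))
    rlang::abort("alpha grid must be strictly increasing",
                 class = "spinalcpg_config_error")
  stopifnot(replicates >= 1)
  topologies <- match.arg(topologies, c("intact", "hemicord"),
                          several.ok = TRUE)
  rep_seeds <- derive_seeds(seed, replicates)
  grid <- tidyr::expand_grid(alpha = alphas, topology = topologies,
                             replicate = seq_len(replicates))
  out <- purrr::pmap(grid, function(alpha, topology, replicate) {
    seeds <- derive_seeds(rep_seeds[replicate], 2L)
    net <- default_model(variant = "drug", topology = topology,
                         alpha = alpha, scale = scale, seed = seeds[1])
    rec <- run_simulation(net, config = config, seed = seeds[2])
    m <- rhythm_metrics(rec, populations = "F",
                        sides = if (topology == "hemicord") "left" else "left")
    tibble::tibble(alpha = alpha, topology = topology, replicate = replicate,
                   frequency_hz = m$frequency_hz[1], n_bursts = m$n_bursts[1],
                   oscillatory = m$oscillatory[1])
  }) |> dplyr::bind_rows()
  structure(out, class = c("cpg_sweep", class(out)),
            seed = seed, scale = scale,
            record_s = config$record_s)
}

#' Direction-of-effect matrix over all named protocols
#'
#' Runs every named protocol, compares flexor burst frequency between the
#' control and photostimulation epochs, and labels the direction of the
#' effect. Protocols without stimulation report the control frequency only.
#'
#' @param scale Model size scaling factor.
#' @param seed Master seed.
#' @param config A [sim_config()].
#' @param control_s,stim_s Epoch durations, s (override protocol defaults).
#' @param change_min Minimal relative frequency change counted as an effect.
#' @return A `cpg_matrix` tibble: `protocol`, `control_hz`, `stim_hz`,
#'   `control_oscillatory`, `stim_oscillatory`, `direction` (`"increase"`,
#'   `"decrease"`, `"suppressed"`, `"no_change"` or `NA` for pure
#'   controls).
#' @export
experiment_matrix <- function(scale = 1, seed = 1, config = sim_config(),
                              control_s = 60, stim_s = 60,
                              change_min = 0.05) {
  names <- c("intact_drug_control", "intact_drug_v1_hyper",
             "intact_drug_v1_depol", "hemicord_drug_control",
             "hemicord_drug_v1_hyper", "hemicord_drug_v1_depol",
             "brainstem_control", "brainstem_v1_depol", "brainstem_v1_hyper")
  out <- purrr::map(names, function(nm) {
    p <- make_protocol(nm, control_s = control_s, stim_s = stim_s)
    rec <- run_protocol(p, scale = scale, seed = seed, config = config,
                        recovery = FALSE)
    m <- rhythm_metrics(rec, populations = "F", sides = "left")
    ctrl <- m[m$epoch == "control", ]
    row <- tibble::tibble(protocol = nm,
                          control_hz = ctrl$frequency_hz,
                          stim_hz = NA_real_,
                          control_oscillatory = ctrl$oscillatory,
                          stim_oscillatory = NA,
                          direction = NA_character_)
    if ("stim" %in% m$epoch) {
      st <- m[m$epoch == "stim", ]
      row$stim_hz <- st$frequency_hz
      row$stim_oscillatory <- st$oscillatory
      row$direction <- effect_direction(ctrl$frequency_hz, st$frequency_hz,
                                        ctrl$oscillatory, st$oscillatory,
                                        change_min)
    }
    row
  }) |> dplyr::bind_rows()
  structure(out, class = c("cpg_matrix", class(out)), seed = seed,
            scale = scale)
}

effect_direction <- function(f_ctrl, f_stim, osc_ctrl, osc_stim,
                             change_min = 0.05) {
  if (isTRUE(osc_ctrl) && !isTRUE(osc_stim)) return("suppressed")
  if (f_ctrl <= 0) return(NA_character_)
  rel <- (f_stim - f_ctrl) / f_ctrl
  if (rel > change_min) "increase"
  else if (rel < -change_min) "decrease"
  else "no_change"
}
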