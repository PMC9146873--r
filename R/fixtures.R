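#' Deterministic test fixtures
#'
#' Minimal systems with known behaviour, used throughout the test suite and
#' handy for interactive exploration:
#'
#' * `single_f_burster` — one flexor-half-center neuron (INaP present);
#'   traverses silence, rhythmic bursting and tonic firing as its leak
#'   reversal is depolarised.
#' * `single_simple_spiker` — one interneuron-type neuron without INaP;
#'   silent or tonically firing, never intrinsically bursting.
#' * `two_cell_halfcenter` — two INaP bursters coupled by mutual
#'   inhibition; anti-phase burst alternation.
#' * `small_bilateral` — the full bilateral model at quarter scale with
#'   connection probabilities rescaled (x4, capped at 1) to preserve
#'   expected per-neuron in-degree.
#' * `square_wave_trains` — a pair of ideal 1 Hz anti-phase burst trains
#'   for analysis-layer tests.
#'
#' @param name Fixture name (see above).
#' @param seed Integer seed; every fixture is deterministic given it.
#' @param ... Overrides: `EL` for the single neurons, `inhibition` weight
#'   for the half-center, `alpha`/`variant`/`topology` for
#'   `small_bilateral`, `freq_hz`/`duration_s` for `square_wave_trains`.
#' @return A `cpg_network` for the network fixtures, a parameter list for
#'   the single neurons, or a list of two burst-train tibbles.
#' @export
make_fixture <- function(name, seed = 1, ...) {
  ov <- list(...)
  switch(name,
    single_f_burster = {
      neuron_parameters("F", EL = ov$EL %||% -64)
    },
    single_simple_spiker = {
      neuron_parameters("Ini", EL = ov$EL %||% -60)
    },
    two_cell_halfcenter = halfcenter_fixture(
      EL = ov$EL %||% -64, inhibition = ov$inhibition %||% -6),
    small_bilateral = default_model(
      variant = ov$variant %||% "drug",
      topology = ov$topology %||% "intact",
      alpha = ov$alpha %||% 0.17,
      scale = 0.25, seed = seed),
    square_wave_trains = square_wave_trains(
      freq_hz = ov$freq_hz %||% 1, duration_s = ov$duration_s %||% 30,
      phase = ov$phase %||% 0.5),
    rlang::abort(paste0("unknown fixture: ", name),
                 class = "spinalcpg_config_error")
  )
}

# two mutually inhibiting INaP bursters (a half-center oscillator)
halfcenter_fixture <- function(EL = -64, inhibition = -6) {
  p <- neuron_parameters("F", EL = EL)
  neurons <- tibble::tibble(
    id = 1:2, population = c("F", "F"), side = c("left", "right"),
    index = c(1L, 1L), C = p$C, gNa = p$gNa, gNaP = p$gNaP, gK = p$gK,
    gL = p$gL, EL_mean0 = EL, EL_eps = 0, EL = EL,
    has_inap = TRUE, photo = 0L)
  edges <- tibble::tibble(
    src = c(1L, 2L), tgt = c(2L, 1L), weight = inhibition,
    source_pop = "F", target_pop = "F",
    source_side = c("left", "right"), target_side = c("right", "left"),
    laterality = "contra")
  structure(list(neurons = neurons, edges = edges,
                 syn = synaptic_parameters(),
                 meta = list(variant = "drug", topology = "intact",
                             alpha = 0, d = 0, drive_weights = NULL,
                             seed = 0L, scale = 1)),
            class = "cpg_network")
}

# ideal periodic burst trains with a fixed phase offset
square_wave_trains <- function(freq_hz = 1, duration_s = 30, phase = 0.5) {
  period_ms <- 1000 / freq_hz
  onsets_a <- seq(0, duration_s * 1000 - period_ms, by = period_ms)
  a <- tibble::tibble(onset = onsets_a, offset = onsets_a + period_ms / 2,
                      peak_rate = 1)
  b <- a
  b$onset <- b$onset + phase * period_ms
  b$offset <- b$offset + phase * period_ms
  keep <- b$offset <= duration_s * 1000
  list(a = a, b = b[keep, ])
}
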