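#' Steady-state activation/inactivation of a voltage-gated channel
#'
#' Sigmoidal steady-state curves for the fast sodium (Na), persistent sodium
#' (NaP) and delayed-rectifier potassium (K) channels of the locomotor
#' network neurons. Potassium inactivation is constant at 1 (the channel does
#' not inactivate).
#'
#' @param channel One of `"Na"`, `"NaP"`, `"K"`.
#' @param gate One of `"m"` (activation) or `"h"` (inactivation).
#' @param V Membrane potential in mV (vectorised).
#' @return Gate steady-state value(s) in `[0, 1]`.
#' @examples
#' gate_steady_state("Na", "m", -34)   # half-activation
#' gate_steady_state("K", "h", -120)   # always 1
#' @export
gate_steady_state <- function(channel, gate, V) {
  stopifnot(is.numeric(V), all(is.finite(V)))
  key <- paste(channel, gate, sep = ".")
  switch(key,
    "Na.m"  = 1 / (1 + exp(-(V + 34) / 7.8)),
    "Na.h"  = 1 / (1 + exp((V + 55) / 7)),
    "NaP.m" = 1 / (1 + exp(-(V + 47.1) / 3.1)),
    "NaP.h" = 1 / (1 + exp((V + 60) / 6.5)),
    "K.m"   = 1 / (1 + exp(-(V + 28) / 4)),
    "K.h"   = rep(1, length(V)),
    rlang::abort(paste0("unknown channel/gate: ", key), class = "spinalcpg_config_error")
  )
}

#' Voltage-dependent time constant of a channel gate
#'
#' Sodium (Na and NaP) activation is treated as instantaneous, so its time
#' constant is identically 0. Potassium does not inactivate (`tau` is
#' irrelevant and returned as 0 alongside the constant gate).
#'
#' @inheritParams gate_steady_state
#' @return Time constant(s) in ms, `>= 0`.
#' @examples
#' gate_time_constant("NaP", "h", -60)  # 18000 ms at the inactivation center
#' gate_time_constant("K", "m", -40)    # 3.5 ms
#' @export
gate_time_constant <- function(channel, gate, V) {
  stopifnot(is.numeric(V), all(is.finite(V)))
  key <- paste(channel, gate, sep = ".")
  switch(key,
    "Na.m"  = rep(0, length(V)),
    "Na.h"  = 20 / (exp((V + 50) / 15) + exp(-(V + 50) / 16)),
    "NaP.m" = rep(0, length(V)),
    "NaP.h" = 18000 / cosh((V + 60) / 13),
    "K.m"   = 3.5 / cosh((V + 40) / 40),
    "K.h"   = rep(0, length(V)),
    rlang::abort(paste0("unknown channel/gate: ", key), class = "spinalcpg_config_error")
  )
}

#' Default single-neuron parameter set
#'
#' Returns the parameter list for one neuron. Defaults correspond to a
#' generic simple spiking interneuron; use the `population` argument to get
#' the tabulated set of a named population type, or override any field.
#'
#' @param population Optional population type name (e.g. `"F"`, `"V1"`).
#' @param ... Named overrides of individual fields.
#' @return A list with fields `C` (uF/cm^2), `gNa`, `gNaP`, `gK`, `gL`
#'   (mS/cm^2), `EL`, `ENa`, `EK`, `EAr`, `ECh` (mV), `has_inap`, `photo`
#'   (0 = no photocurrents, 1 = V1 group, 2 = V1-1 group).
#' @export
neuron_parameters <- function(population = NULL, ...) {
  p <- list(C = 1, gNa = 10, gNaP = 0, gK = 5, gL = 0.1, EL = -64,
            ENa = 55, EK = -80, EAr = -80, ECh = -10,
            has_inap = FALSE, photo = 0L)
  if (!is.null(population)) {
    tab <- population_table()
    row <- tab[tab$population == population, ]
    if (nrow(row) != 1)
      rlang::abort(paste0("unknown population: ", population),
                   class = "spinalcpg_config_error")
    p$gNa <- row$gNa; p$gNaP <- row$gNaP_mean; p$gK <- row$gK
    p$gL <- row$gL; p$EL <- row$EL_mean
    p$has_inap <- row$has_inap; p$photo <- row$photo
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad))
    rlang::abort(paste0("unknown neuron parameter(s): ", paste(bad, collapse = ", ")),
                 class = "spinalcpg_config_error")
  p[names(ov)] <- ov
  if (any(unlist(p[c("gNa", "gNaP", "gK", "gL")]) < 0))
    rlang::abort("conductances must be non-negative", class = "spinalcpg_config_error")
  p
}

#' Instantaneous ionic currents of one neuron
#'
#' Evaluates each ionic current term at a given membrane potential and gate
#' configuration. Sodium activation gates (Na, NaP) are instantaneous
#' functions of `V`; the dynamic gates are taken from `gates`.
#'
#' @param V Membrane potential, mV.
#' @param params Neuron parameter list from [neuron_parameters()].
#' @param gates Named list with dynamic gate values `hNa`, `hNaP`, `mK`;
#'   defaults to their steady states at `V`.
#' @param gAr,gCh Photostimulation conductances, mS/cm^2 (0 in control).
#' @return Named numeric vector: `INa`, `INaP`, `IK`, `IL`, `IAr`, `ICh`
#'   in uA/cm^2 (positive = outward for V above the reversal).
#' @export
ionic_currents <- function(V, params, gates = NULL, gAr = 0, gCh = 0) {
  stopifnot(is.finite(V))
  if (gAr < 0 || gCh < 0)
    rlang::abort("photoconductances must be non-negative",
                 class = "spinalcpg_config_error")
  if (is.null(gates)) {
    gates <- list(hNa = gate_steady_state("Na", "h", V),
                  hNaP = gate_steady_state("NaP", "h", V),
                  mK = gate_steady_state("K", "m", V))
  }
  mNa <- gate_steady_state("Na", "m", V)
  mNaP <- gate_steady_state("NaP", "m", V)
  inap <- if (isTRUE(params$has_inap))
    params$gNaP * mNaP * gates$hNaP * (V - params$ENa) else 0
  c(INa  = params$gNa * mNa^3 * gates$hNa * (V - params$ENa),
    INaP = inap,
    IK   = params$gK * gates$mK^4 * (V - params$EK),
    IL   = params$gL * (V - params$EL),
    IAr  = gAr * (V - params$EAr),
    ICh  = gCh * (V - params$ECh))
}

#' One exponential-Euler integration step for a single neuron
#'
#' Advances membrane potential and dynamic gates by one step of size `dt`.
#' Total conductance and the effective reversal potential are frozen within
#' the step; gates relax exactly toward their steady states with their
#' voltage-dependent time constants (evaluated at the pre-step `V`).
#'
#' This is the scalar reference for the vectorised network engine; the two
#' produce the same trajectory for a single neuron.
#'
#' @param state List with `V` (mV) and gate values `hNa`, `hNaP`, `mK`.
#' @param params Neuron parameter list from [neuron_parameters()].
#' @param gSynE,gSynI Synaptic (plus drive) conductances, mS/cm^2.
#' @param gAr,gCh Photostimulation conductances, mS/cm^2.
#' @param dt Step size in ms (default 0.1).
#' @param syn Synaptic parameter list from [synaptic_parameters()] (only the
#'   reversal potentials are used here).
#' @return Updated state list.
#' @export
exp_euler_step <- function(state, params, gSynE = 0, gSynI = 0,
                           gAr = 0, gCh = 0, dt = 0.1,
                           syn = synaptic_parameters()) {
  stopifnot(dt > 0)
  V <- state$V
  relax <- function(x, inf, tau) {
    if (tau <= 0) return(inf)
    inf + (x - inf) * exp(-dt / tau)
  }
  hNa <- relax(state$hNa, gate_steady_state("Na", "h", V),
               gate_time_constant("Na", "h", V))
  mK <- relax(state$mK, gate_steady_state("K", "m", V),
              gate_time_constant("K", "m", V))
  hNaP <- state$hNaP
  g_nap <- 0
  if (isTRUE(params$has_inap)) {
    hNaP <- relax(state$hNaP, gate_steady_state("NaP", "h", V),
                  gate_time_constant("NaP", "h", V))
    g_nap <- params$gNaP * gate_steady_state("NaP", "m", V) * hNaP
  }
  g_na <- params$gNa * gate_steady_state("Na", "m", V)^3 * hNa
  g_k <- params$gK * mK^4
  G <- g_na + g_nap + g_k + params$gL + gAr + gCh + gSynE + gSynI
  Esum <- (g_na + g_nap) * params$ENa + g_k * params$EK + params$gL * params$EL +
    gAr * params$EAr + gCh * params$ECh + gSynE * syn$EsynE + gSynI * syn$EsynI
  veq <- Esum / G
  vnew <- veq + (V - veq) * exp(-G * dt / params$C)
  if (!is.finite(vnew))
    rlang::abort("numerical instability: non-finite V after step",
                 class = "spinalcpg_numerical_error")
  list(V = vnew, hNa = hNa, hNaP = hNaP, mK = mK)
}

#' Initialise neuron state at a given membrane potential
#'
#' Gates are set to their steady-state values at `V`.
#'
#' @param V Initial membrane potential, mV.
#' @return State list for [exp_euler_step()].
#' @export
init_state <- function(V) {
  list(V = V,
       hNa = gate_steady_state("Na", "h", V),
       hNaP = gate_steady_state("NaP", "h", V),
       mK = gate_steady_state("K", "m", V))
}

#' Detect spikes in a voltage trace
#'
#' One event per upward crossing of the threshold; the neuron must fall
#' below threshold before a new event can be registered.
#'
#' @param v Numeric vector of membrane potentials sampled at `dt`.
#' @param dt Sampling interval, ms.
#' @param threshold Spike threshold, mV (default -10).
#' @param t0 Time of the first sample, ms.
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(v, dt = 0.1, threshold = -10, t0 = 0) {
  above <- v >= threshold
  crossing <- which(above & !c(FALSE, above[-length(above)]))
  t0 + (crossing - 1) * dt
}
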