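#' Synaptic parameter set
#'
#' Exponentially decaying conductance synapses. A spike with signed weight
#' `w > 0` increments the target's excitatory conductance by `gE * w`; a
#' spike with `w < 0` increments the inhibitory conductance by `gI * |w|`.
#' Both conductances decay with their time constants between spikes.
#'
#' @param gE,gI Unit conductance increments, mS/cm^2.
#' @param gEd Unit drive conductance, mS/cm^2.
#' @param EsynE,EsynI Synaptic reversal potentials, mV.
#' @param tauE,tauI Decay time constants, ms.
#' @return Named list of synaptic parameters.
#' @export
synaptic_parameters <- function(gE = 0.05, gI = 0.05, gEd = 0.05,
                                EsynE = -10, EsynI = -70,
                                tauE = 5, tauI = 5) {
  stopifnot(gE > 0, gI > 0, gEd > 0, tauE > 0, tauI > 0)
  list(gE = gE, gI = gI, gEd = gEd, EsynE = EsynE, EsynI = EsynI,
       tauE = tauE, tauI = tauI)
}

#' Register an arriving spike on a synaptic state
#'
#' @param state List with `gSynE` and `gSynI` (mS/cm^2).
#' @param weight Signed synaptic weight of the arriving spike.
#' @param syn Synaptic parameters from [synaptic_parameters()].
#' @return Updated state.
#' @export
register_spike <- function(state, weight, syn = synaptic_parameters()) {
  stopifnot(is.finite(weight))
  if (weight > 0) state$gSynE <- state$gSynE + syn$gE * weight
  if (weight < 0) state$gSynI <- state$gSynI + syn$gI * (-weight)
  state
}

#' Decay synaptic conductances over an interval
#'
#' Multiplies each conductance by `exp(-dt/tau)`; equivalent to evaluating
#' the explicit sum over past spikes after `dt` with no new arrivals. The
#' tonic drive component is untouched.
#'
#' @inheritParams register_spike
#' @param dt Elapsed time, ms (`>= 0`).
#' @return Updated state.
#' @export
decay_conductances <- function(state, dt, syn = synaptic_parameters()) {
  stopifnot(dt >= 0)
  state$gSynE <- state$gSynE * exp(-dt / syn$tauE)
  state$gSynI <- state$gSynI * exp(-dt / syn$tauI)
  state
}

#' Synaptic currents at a membrane potential
#'
#' @param V Membrane potential, mV.
#' @inheritParams register_spike
#' @param g_drive Tonic drive conductance added to the excitatory term,
#'   mS/cm^2.
#' @return Named vector `ISynE`, `ISynI` in uA/cm^2.
#' @export
synaptic_currents <- function(V, state, syn = synaptic_parameters(),
                              g_drive = 0) {
  c(ISynE = (state$gSynE + g_drive) * (V - syn$EsynE),
    ISynI = state$gSynI * (V - syn$EsynI))
}

#' Tonic drive conductance from a brainstem drive
#'
#' Rectified product of the population drive weight and the drive level:
#' `gEd * max(wd * d, 0)`.
#'
#' @param wd Population drive weight (dimensionless, signed).
#' @param d Drive level (dimensionless).
#' @param gEd Unit drive conductance, mS/cm^2.
#' @return Conductance in mS/cm^2, `>= 0`.
#' @examples
#' drive_conductance(2, 1)   # 0.1 (the Ini drive weight at full drive)
#' @export
drive_conductance <- function(wd, d, gEd = 0.05) {
  gEd * pmax(wd * d, 0)
}
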