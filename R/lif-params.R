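#' Leaky integrate-and-fire neuron parameters (alpha-shaped PSCs)
#'
#' Defaults follow the common alpha-current LIF parameterization: membrane
#' capacitance 250 pF, membrane time constant 10 ms, resting and reset
#' potential -70 mV, threshold -55 mV, synaptic alpha time constant 2 ms and
#' a 1 ms absolute refractory period. With these values the minimal DC
#' current that makes an isolated neuron fire (rheobase) is just above
#' `C_m * (V_th - E_L) / tau_m = 375` pA; see [rheobase()].
#'
#' @param C_m Membrane capacitance, pF.
#' @param tau_m Membrane time constant, ms.
#' @param E_L Resting (leak) potential, mV.
#' @param V_th Spike threshold, mV (must exceed `E_L` and `V_reset`).
#' @param V_reset Post-spike reset potential, mV.
#' @param t_ref Absolute refractory period, ms.
#' @param tau_syn Alpha-function synaptic time constant, ms.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(C_m = 250, tau_m = 10, E_L = -70, V_th = -55,
                       V_reset = -70, t_ref = 1, tau_syn = 2) {
  stopifnot(C_m > 0, tau_m > 0, tau_syn > 0, t_ref >= 0,
            V_th > E_L, V_th > V_reset)
  structure(
    list(C_m = C_m, tau_m = tau_m, E_L = E_L, V_th = V_th,
         V_reset = V_reset, t_ref = t_ref, tau_syn = tau_syn),
    class = "lif_params"
  )
}

#' Spike-timing-dependent plasticity parameters
#'
#' Nearest-neighbour pair-based STDP with soft weight bounds: a post spike at
#' lag `dt = t_post - t_pre > 0` potentiates by
#' `A_plus * exp(-dt / tau_plus) * (w_max - w)` and a pre spike after a post
#' spike depresses by `A_minus * exp(dt / tau_minus) * (w - w_min)`
#' (`dt < 0`). Weights can therefore never leave `[w_min, w_max]`.
#'
#' Synaptic weights throughout the package are PSC peak amplitudes in pA.
#' `w_max = 1800` pA is comfortably above the ~1154 pA single-spike firing
#' threshold of the default neuron (see [lif_params()]), so a saturated
#' synapse reliably triggers its target with one spike.
#'
#' @param tau_plus,tau_minus Trace time constants, ms.
#' @param A_plus,A_minus Dimensionless amplitudes. The defaults (0.05 with a
#'   5% depression bias) are sized for training rounds of tens of
#'   presentations per class, so that a pair co-firing in most presentations
#'   of one class separates clearly from its weight under other classes.
#' @param w_min,w_max Weight bounds, pA.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(tau_plus = 20, tau_minus = 20,
                        A_plus = 0.05, A_minus = 0.0525,
                        w_min = 0, w_max = 1800) {
  stopifnot(tau_plus > 0, tau_minus > 0, A_plus >= 0, A_minus >= 0,
            w_max > w_min, w_min >= 0)
  structure(
    list(tau_plus = tau_plus, tau_minus = tau_minus,
         A_plus = A_plus, A_minus = A_minus,
         w_min = w_min, w_max = w_max),
    class = "stdp_params"
  )
}

#' STDP weight update for a single pre/post spike lag
#'
#' @param delta_t Spike lag `t_post - t_pre` in ms (vectorized).
#' @param w Current weight(s), pA.
#' @param params An [stdp_params()] object.
#' @return The weight change (same length as the inputs); zero at
#'   `delta_t = 0`.
#' @export
stdp_delta_w <- function(delta_t, w, params = stdp_params()) {
  dw <- numeric(length(delta_t))
  pos <- delta_t > 0
  neg <- delta_t < 0
  dw[pos] <- params$A_plus * exp(-delta_t[pos] / params$tau_plus) *
    (params$w_max - w[pos])
  dw[neg] <- -params$A_minus * exp(delta_t[neg] / params$tau_minus) *
    (w[neg] - params$w_min)
  dw
}

#' Default static input weight
#'
#' PSC peak amplitude (pA) used for the one-to-one input-to-memory-layer
#' synapses: equal to the STDP ceiling `w_max`, i.e. suprathreshold for a
#' single spike, so the first memory layer mirrors the encoded input timing.
#'
#' @return A scalar weight in pA.
#' @export
default_input_weight <- function() stdp_params()$w_max
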