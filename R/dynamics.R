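#' Dendritic activation nonlinearity
#'
#' Sigmoidal activation `f(v) = 1 / (1 + exp(-(v - E_d) / D_d))` of the
#' dendritic compartment. Its output gates both the regenerative dendritic
#' current (plateau/calcium events) and the dendro-somatic coupling.
#'
#' @param v membrane potential (scaled units), vectorized.
#' @param E_d half-point of the activation.
#' @param D_d slope; must be strictly positive.
#' @return activation in (0, 1).
#' @export
dendritic_nonlinearity <- function(v, E_d, D_d) {
  if (!is.numeric(D_d) || length(D_d) != 1 || D_d <= 0) {
    stop("invalid parameter: dendritic slope D_d must be > 0")
  }
  1 / (1 + exp(-(v - E_d) / D_d))
}

#' Single Euler step of the somatic compartment
#'
#' Leaky integrate-and-fire soma with spike-triggered adaptation and
#' dendro-somatic coupling `g_s * f(v_d)`. On crossing the threshold the
#' membrane is reset to rest, an absolute refractory period starts (during
#' which the membrane is clamped at rest), and the adaptation variable jumps
#' by `b_s` (scaled). All arguments are vectorized over neurons.
#'
#' @param state list with numeric vectors `v` (membrane potential), `w`
#'   (adaptation, scaled current units/ms) and `refrac` (remaining refractory
#'   time, ms).
#' @param v_d dendritic membrane potential (for the coupling term).
#' @param I_total total input current in scaled units (units/ms): external +
#'   background + inhibitory.
#' @param params parameter list from [default_params()].
#' @param dt step size (ms).
#' @return list with updated `state` and logical vector `spike`.
#' @export
step_soma <- function(state, v_d, I_total, params, dt = params$dt) {
  k <- scaled_constants(params)
  fd <- dendritic_nonlinearity(v_d, params$dend$E_d, params$dend$D_d)
  v_pre <- state$v * (1 - dt / params$soma$tau) +
    dt * (k$gs * fd + state$w + I_total)
  if (any(!is.finite(v_pre))) stop("non-finite somatic state")
  active <- state$refrac <= 0
  spike <- active & (v_pre >= params$theta)
  v_new <- ifelse(active & !spike, v_pre, params$E_L)
  refrac <- ifelse(spike, params$refrac, pmax(state$refrac - dt, 0))
  w_new <- state$w * (1 - dt / params$soma$tau_w) + k$bs * spike
  list(state = list(v = v_new, w = w_new, refrac = refrac), spike = spike)
}

#' Single Euler step of the dendritic compartment
#'
#' Leaky dendrite with regenerative sigmoidal current `g_d * f(v_d)`,
#' voltage-activated adaptation, and a back-propagating action-potential
#' (BAP) current: a boxcar of amplitude `c_d` that starts 1 ms after each
#' somatic spike and lasts 2 ms. There is no sub-threshold coupling from the
#' soma to the dendrite; the soma influences the dendrite only through the
#' BAP. With `dt = 1` ms the boxcar occupies exactly the two steps following
#' the spike step, which the caller provides as the lagged spike indicators.
#'
#' @param state list with vectors `v` and `w` (voltage-activated adaptation).
#' @param spike_lag1,spike_lag2 somatic spike indicators of the previous and
#'   the second-to-last step (0/1), vectorized over neurons.
#' @param I_total total input current (scaled units): external + background +
#'   inhibitory.
#' @inheritParams step_soma
#' @return list with updated `state` (no spiking in the dendrite).
#' @export
step_dendrite <- function(state, spike_lag1, spike_lag2, I_total, params,
                          dt = params$dt) {
  k <- scaled_constants(params)
  fd <- dendritic_nonlinearity(state$v, params$dend$E_d, params$dend$D_d)
  bap <- k$cd * (spike_lag1 + spike_lag2)
  v_new <- state$v * (1 - dt / params$dend$tau) +
    dt * (k$gd * fd + bap + state$w + I_total)
  w_new <- state$w * (1 - dt / params$dend$tau_w) +
    (dt * k$kad / params$dend$tau_w) * state$v
  if (any(!is.finite(v_new))) stop("non-finite dendritic state")
  list(state = list(v = v_new, w = w_new))
}

#' Single Euler step of an interneuron
#'
#' Leaky integrate-and-fire unit with the same threshold, reset and
#' refractory contract as the soma, but without adaptation.
#'
#' @param state list with vectors `v` and `refrac`.
#' @inheritParams step_soma
#' @return list with updated `state` and logical vector `spike`.
#' @export
step_interneuron <- function(state, I_total, params, dt = params$dt) {
  v_pre <- state$v * (1 - dt / params$inter$tau) + dt * I_total
  if (any(!is.finite(v_pre))) stop("non-finite interneuron state")
  active <- state$refrac <= 0
  spike <- active & (v_pre >= params$theta)
  v_new <- ifelse(active & !spike, v_pre, params$E_L)
  refrac <- ifelse(spike, params$refrac, pmax(state$refrac - dt, 0))
  list(state = list(v = v_new, refrac = refrac), spike = spike)
}

#' Euler-Maruyama step of the Ornstein-Uhlenbeck background current
#'
#' `dI = -(I - mu)/tau dt + sigma dW`. The stationary distribution is
#' normal with mean `mu` and variance `sigma^2 * tau / 2`.
#'
#' @param x current value(s), pA.
#' @param mu mean, pA.
#' @param sigma white-noise amplitude, pA / sqrt(ms).
#' @param tau relaxation time constant, ms; must be > 0.
#' @param dt step (ms).
#' @param noise standard-normal draws supplied by the caller (same length as
#'   `x`); the caller owns the RNG.
#' @return updated value(s).
#' @export
step_ou <- function(x, mu, sigma, tau, dt, noise) {
  if (tau <= 0) stop("invalid parameter: OU time constant must be > 0")
  x + dt * (mu - x) / tau + sigma * sqrt(dt) * noise
}

#' Single step of Tsodyks-Markram short-term plasticity
#'
#' Utilization `u` relaxes towards the initial release probability `U` with
#' time constant `tau_u` and jumps by `(1 - u) * F` at a presynaptic spike
#' (facilitation). Resources `R` relax towards 1 with `tau_R` and are
#' depleted by `u * R` at a spike, with facilitation applied before
#' depletion. The release scale is `mu = u * R` evaluated at the spike, with
#' the facilitated `u` and the pre-depletion `R` (the classical
#' Tsodyks-Markram convention): a synapse with `U = 0` transmits purely
#' through facilitation and can never reach full release on the first spike
#' of a train.
#'
#' @param state list with `u` and `R` (vectors or matrices).
#' @param spike presynaptic spike indicator (0/1), broadcastable to `u`.
#' @param pars list with `U`, `F`, `tau_u`, `tau_R`.
#' @param dt step (ms).
#' @return list with updated `state` and `mu`, the release scale.
#' @export
step_stp <- function(state, spike, pars, dt = 1) {
  if (any(pars$U < 0 | pars$U > 1)) stop("invalid parameter: U must lie in [0, 1]")
  if (pars$F < 0 || pars$F > 1) stop("invalid parameter: F must lie in [0, 1]")
  u1 <- state$u * (1 - dt / pars$tau_u) + (dt / pars$tau_u) * pars$U
  R1 <- state$R * (1 - dt / pars$tau_R) + dt / pars$tau_R
  u2 <- u1 + (1 - u1) * pars$F * spike
  mu <- u2 * R1
  R2 <- R1 * (1 - u2 * spike)
  list(state = list(u = u2, R = R2), mu = mu)
}

#' Single step of an exponentially decaying synaptic trace
#'
#' The trace decays with time constant `tau` and is incremented at each
#' presynaptic spike (`increment` defaults to 1).
#'
#' @param s trace value(s), non-negative.
#' @param spike spike indicator (0/1), broadcastable to `s`.
#' @param tau decay time constant (ms), > 0.
#' @param dt step (ms).
#' @param increment trace increment per spike.
#' @return updated trace.
#' @export
step_synaptic_trace <- function(s, spike, tau, dt = 1, increment = 1) {
  if (tau <= 0) stop("invalid parameter: trace time constant must be > 0")
  s * (1 - dt / tau) + increment * spike
}

#' Surrogate derivative of the spike threshold
#'
#' `1 / (1 + beta * |v - theta|)^2`: the smooth stand-in used for the
#' derivative of the hard spike nonlinearity during backpropagation. The
#' forward simulation keeps hard threshold crossings.
#'
#' @param v membrane potential (scaled), vectorized.
#' @param theta threshold.
#' @param beta slope; larger values concentrate the derivative at threshold.
#' @return derivative values in (0, 1].
#' @export
surrogate_spike_derivative <- function(v, theta = 1, beta = 10) {
  if (beta <= 0) stop("invalid parameter: surrogate slope beta must be > 0")
  1 / (1 + beta * abs(v - theta))^2
}

# Smooth "relaxed" spike used only for gradient verification: a ramp whose
# exact derivative is the surrogate above.
relaxed_spike <- function(v, theta = 1, beta = 10) {
  0.5 + (v - theta) / (1 + beta * abs(v - theta))
}
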