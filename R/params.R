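#' Default biophysical parameters
#'
#' Returns the default parameter set of the spiking circuit model. Membrane
#' voltages are expressed in scaled units in which the resting potential is
#' `E_L = 0` and the spike threshold is `theta = 1`; one voltage unit
#' corresponds to `mv_per_unit` millivolts (default 20 mV, i.e. a rest of
#' -70 mV and a threshold of -50 mV). Currents at the user interface are in
#' pA and are converted internally to scaled units of voltage per ms by
#' dividing by `mv_per_unit * C` of the target compartment.
#'
#' The pyramidal-cell values follow the two-compartment description of layer-5
#' cells with dendrite-dependent bursting (somatic leaky integrate-and-fire
#' with spike-triggered adaptation, dendritic compartment with a sigmoidal
#' regenerative nonlinearity, a back-propagating action-potential boxcar, and
#' voltage-activated dendritic adaptation). Interneurons are plain
#' integrate-and-fire units. All values can be overridden via `overrides`.
#'
#' @param overrides named list of replacements; nested names as in the
#'   returned list, e.g. `list(stp = list(tau_R = 30))`.
#' @return nested list of parameters.
#' @export
default_params <- function(overrides = list()) {
  p <- list(
    dt = 1,                       # simulation step (ms)
    theta = 1,                    # spike threshold (scaled)
    E_L = 0,                      # resting/reset potential (scaled)
    refrac = 3,                   # absolute refractory period (ms)
    soma = list(
      tau = 16,                   # membrane time constant (ms)
      C = 370,                    # capacitance (pF)
      g = 1300,                   # dendro-somatic coupling (pA at f = 1)
      b = -100,                   # spike-triggered adaptation jump (pA)
      tau_w = 100                 # adaptation time constant (ms)
    ),
    dend = list(
      tau = 7,
      C = 170,
      g = 1200,                   # regenerative (calcium) conductance drive (pA at f = 1)
      c_bap = 3200,               # back-propagating AP amplitude (pA)
      E_d = 2.0,                  # half-point of the dendritic nonlinearity (scaled; -30 mV)
      D_d = 0.3,                  # slope of the dendritic nonlinearity (scaled; 6 mV)
      a = -13,                    # voltage-activated adaptation (nS)
      tau_w = 30
    ),
    inter = list(
      tau = 10,
      C = 100
    ),
    syn = list(tau = 15),         # synaptic trace decay (ms)
    stp = list(
      F = 0.25,                   # facilitation fraction
      tau_u = 100,                # facilitation time constant (ms)
      tau_R = 20                  # depression recovery time constant (ms)
    ),
    bg = list(                    # Ornstein-Uhlenbeck background per target
      mu_s = 560, sigma_s = 100 * sqrt(2 / 10),
      mu_d = 100, sigma_d = 100 * sqrt(2 / 10),
      mu_i = 200, sigma_i = 200 * sqrt(2 / 10),
      tau = 10
    ),
    scale = list(mv_per_unit = 20),
    surrogate_beta = 10           # slope of the surrogate spike derivative
  )
  p <- modify_list_strict(p, overrides, "params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(p$dt > 0, p$refrac >= 0)
  if (p$dend$D_d <= 0) stop("invalid parameter: dendritic slope D_d must be > 0")
  for (tau in c(p$soma$tau, p$dend$tau, p$inter$tau, p$syn$tau,
                p$stp$tau_u, p$stp$tau_R, p$soma$tau_w, p$dend$tau_w)) {
    if (tau <= 0) stop("invalid parameter: time constants must be > 0")
  }
  if (p$bg$tau <= 0) stop("invalid parameter: background tau must be > 0")
  if (p$stp$F < 0 || p$stp$F > 1) stop("invalid parameter: F must lie in [0, 1]")
  invisible(p)
}

# Conversion from pA to scaled current (voltage units per ms) for one
# compartment: divide by (mv_per_unit * C).
current_scale <- function(p, compartment = c("soma", "dend", "inter")) {
  compartment <- match.arg(compartment)
  C <- switch(compartment, soma = p$soma$C, dend = p$dend$C, inter = p$inter$C)
  1 / (p$scale$mv_per_unit * C)
}

# Precomputed scaled constants used by the simulator core.
scaled_constants <- function(p) {
  ss <- current_scale(p, "soma")
  sd_ <- current_scale(p, "dend")
  si <- current_scale(p, "inter")
  list(
    ss = ss, sd = sd_, si = si,
    gs = p$soma$g * ss,             # units/ms at f = 1
    gd = p$dend$g * sd_,
    cd = p$dend$c_bap * sd_,
    bs = p$soma$b * ss,             # adaptation jump (units/ms)
    kad = p$dend$a / p$dend$C,      # dendritic adaptation drive coefficient (1/ms)
    mu_s = p$bg$mu_s * ss,          # scaled background means
    mu_d = p$bg$mu_d * sd_,
    mu_i = p$bg$mu_i * si
  )
}

# Strict recursive list update: every name in `new` must already exist in
# `base`; unknown keys raise an error naming the offending field.
modify_list_strict <- function(base, new, path = "config") {
  if (length(new) == 0) return(base)
  if (is.null(names(new)) || any(names(new) == "")) {
    stop(sprintf("all entries under '%s' must be named", path))
  }
  for (nm in names(new)) {
    if (!nm %in% names(base)) {
      stop(sprintf("unknown field '%s' in '%s'", nm, path))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(new[[nm]])) {
        stop(sprintf("field '%s' in '%s' must be a named list", nm, path))
      }
      base[[nm]] <- modify_list_strict(base[[nm]], new[[nm]],
                                       paste(path, nm, sep = "$"))
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

# Deterministic expansion of one master seed into named sub-streams, kept
# below 2^31 so the result is always a valid integer seed.
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 48271 + h * 1009) %% 2147483629)
}
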