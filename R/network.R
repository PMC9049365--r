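#' Network configuration
#'
#' Describes population sizes, wiring mode and structural constraints of a
#' circuit of `N_E` two-compartment pyramidal cells (PCs) and `N_I`
#' interneurons (INs).
#'
#' @param N_E,N_I population sizes (>= 1).
#' @param output_mode `"shared"`: every IN projects to all PC somata with one
#'   weight and to all PC dendrites with another (2 x N_I output parameters);
#'   `"heterogeneous"`: per-target weights (two N_I x N_E matrices).
#' @param preassign if `TRUE`, the first half of the INs may only inhibit
#'   somata and the second half only dendrites (the other compartment's
#'   output weights are structurally fixed at zero). The halves are labelled
#'   PV-like and SST-like respectively.
#' @param knockout character vector of IN->IN connection classes to fix at
#'   zero (requires `preassign = TRUE`): any of `"pv_pv"`, `"pv_sst"`,
#'   `"sst_pv"`, `"sst_sst"`, written pre_post.
#' @param init initial-distribution settings: positive uniform weights of
#'   order 1/N (`w_ei_scale / N_E`, `w_ii_scale / N_I`, `w_out_scale / N_I`
#'   upper bounds) and the half-width `u_halfwidth` of the uniform initial
#'   release probability around the paired-pulse-neutral value.
#' @return object of class `ci_config`.
#' @export
network_config <- function(N_E = 400, N_I = 50,
                           output_mode = c("shared", "heterogeneous"),
                           preassign = FALSE, knockout = NULL,
                           init = list()) {
  output_mode <- match.arg(output_mode)
  stopifnot(N_E >= 1, N_I >= 1)
  init_def <- list(w_ei_scale = 5, w_ii_scale = 1, w_out_scale = 0.5,
                   u_halfwidth = 0.2)
  init <- modify_list_strict(init_def, init, "init")
  knockout <- unique(knockout)
  bad <- setdiff(knockout, c("pv_pv", "pv_sst", "sst_pv", "sst_sst"))
  if (length(bad)) stop("unknown knockout class: ", paste(bad, collapse = ", "))
  if (length(knockout) && !preassign) {
    stop("connection knockouts require preassigned interneuron classes")
  }
  structure(list(N_E = N_E, N_I = N_I, output_mode = output_mode,
                 preassign = preassign, knockout = knockout, init = init),
            class = "ci_config")
}

# Initial release probability is drawn uniformly around the value at which
# facilitation and depression cancel (paired-pulse ratio 1 at a 10 ms
# inter-spike interval), so the population starts paired-pulse neutral.
u_neutral <- function(stp, isi = 10) {
  f <- function(U) measure_ppr(U, stp$F, stp$tau_u, stp$tau_R, isi = isi)$ppr - 1
  if (f(0) < 0) return(0)   # even U = 0 is depressing for these parameters
  if (f(1) > 0) return(1)   # even U = 1 still facilitates
  stats::uniroot(f, c(0, 1), tol = 1e-10)$root
}

#' Build a network with randomly initialized weights
#'
#' Draws all synaptic weights from positive uniform distributions of order
#' 1/N (in scaled current units, so that trained weights come out of order
#' `1/N`), draws the per-synapse initial release probabilities `U` uniformly
#' on an interval symmetric about the paired-pulse-neutral value (so the
#' initial mean paired-pulse ratio is approximately 1), and applies the
#' structural masks (pre-assignment, knockouts, no autapses).
#'
#' @param config a [network_config()].
#' @param params biophysical parameters, see [default_params()].
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @return object of class `ci_network`.
#' @export
build_network <- function(config, params = default_params(), seed = 1) {
  stopifnot(inherits(config, "ci_config"))
  set.seed(derive_seed(seed, "init"))
  N_E <- config$N_E; N_I <- config$N_I
  ini <- config$init

  W_ei <- matrix(stats::runif(N_E * N_I, 0, ini$w_ei_scale / N_E), N_E, N_I)
  us <- u_neutral(params$stp)
  hw <- ini$u_halfwidth
  lo <- max(0, us - hw); hi <- min(1, us + hw)
  U <- matrix(stats::runif(N_E * N_I, lo, hi), N_E, N_I)
  W_ii <- matrix(stats::runif(N_I * N_I, 0, ini$w_ii_scale / N_I), N_I, N_I)

  mask_ei <- matrix(1, N_E, N_I)
  mask_ii <- matrix(1, N_I, N_I); diag(mask_ii) <- 0

  preassigned <- NULL
  if (config$preassign) {
    n_pv <- ceiling(N_I / 2)
    preassigned <- factor(rep(c("PV", "SST"), c(n_pv, N_I - n_pv)),
                          levels = c("PV", "SST"))
  }
  pop_idx <- function(lab) which(preassigned == lab)
  for (ko in config$knockout) {
    pre <- toupper(sub("_.*", "", ko)); post <- toupper(sub(".*_", "", ko))
    mask_ii[pop_idx(post), pop_idx(pre)] <- 0   # row = post, col = pre
  }
  diag(mask_ii) <- 0

  if (config$output_mode == "shared") {
    w_soma <- stats::runif(N_I, 0, ini$w_out_scale / N_I)
    w_dend <- stats::runif(N_I, 0, ini$w_out_scale / N_I)
    mask_soma <- rep(1, N_I); mask_dend <- rep(1, N_I)
    if (config$preassign) {
      mask_soma[preassigned == "SST"] <- 0
      mask_dend[preassigned == "PV"] <- 0
    }
  } else {
    w_soma <- matrix(stats::runif(N_I * N_E, 0, ini$w_out_scale / N_I), N_I, N_E)
    w_dend <- matrix(stats::runif(N_I * N_E, 0, ini$w_out_scale / N_I), N_I, N_E)
    mask_soma <- matrix(1, N_I, N_E); mask_dend <- matrix(1, N_I, N_E)
    if (config$preassign) {
      mask_soma[preassigned == "SST", ] <- 0
      mask_dend[preassigned == "PV", ] <- 0
    }
  }
  w_soma <- w_soma * mask_soma
  w_dend <- w_dend * mask_dend
  W_ii <- W_ii * mask_ii

  structure(list(config = config, params = params,
                 W_ei = W_ei, U = U, W_ii = W_ii,
                 w_soma = w_soma, w_dend = w_dend,
                 masks = list(ei = mask_ei, ii = mask_ii,
                              soma = mask_soma, dend = mask_dend),
                 preassigned = preassigned, seed = seed),
            class = "ci_network")
}

#' @export
print.ci_network <- function(x, ...) {
  cat(sprintf("<ci_network> N_E = %d PCs, N_I = %d INs, output mode '%s'%s\n",
              x$config$N_E, x$config$N_I, x$config$output_mode,
              if (x$config$preassign) ", pre-assigned" else ""))
  if (length(x$config$knockout)) {
    cat("  knockouts:", paste(x$config$knockout, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stimulus protocol
#'
#' Step-current stimulation of PC somata and dendrites: a periodic train of
#' `pulse_ms` pulses at `rate_hz`, with amplitudes drawn from `amplitudes`
#' (pA) and, unless `jitter = FALSE`, a circularly uniform random phase per
#' trial and compartment. Independent phases and amplitudes make the two
#' compartments' traces uncorrelated in expectation; with probability
#' `correlation` the dendritic train instead copies the somatic phase and
#' amplitudes, so `correlation = 1` yields identical traces (Pearson r = 1)
#' and intermediate values interpolate. [stimulus_correlation()] reports the
#' realized correlation.
#'
#' @param pulse_ms pulse duration (ms).
#' @param rate_hz pulse rate (Hz).
#' @param amplitudes amplitude set (pA).
#' @param trial_ms trial duration (ms).
#' @param correlation soma-dendrite input correlation control in \[0, 1\].
#' @param fixed_amplitude if non-`NULL`, all pulses use this amplitude (pA),
#'   e.g. 300 pA for the standard evaluation stimulus.
#' @param jitter randomize pulse onsets within their windows.
#' @return object of class `ci_protocol`.
#' @export
stimulus_protocol <- function(pulse_ms = 100, rate_hz = 2.5,
                              amplitudes = c(100, 200, 300, 400),
                              trial_ms = 600, correlation = 0,
                              fixed_amplitude = NULL, jitter = TRUE) {
  stopifnot(pulse_ms > 0, rate_hz > 0, trial_ms >= pulse_ms,
            correlation >= 0, correlation <= 1)
  period <- 1000 / rate_hz
  structure(list(pulse_ms = pulse_ms, rate_hz = rate_hz, period = period,
                 amplitudes = amplitudes, trial_ms = trial_ms,
                 correlation = correlation, fixed_amplitude = fixed_amplitude,
                 jitter = jitter),
            class = "ci_protocol")
}

#' Generate paired step-current stimulus traces
#'
#' @param protocol a [stimulus_protocol()].
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param dt time step (ms).
#' @return list with `soma` and `dend` (`T x n_trials` matrices, pA), pulse
#'   bookkeeping (`onsets_s`, `onsets_d`, `amps_s`, `amps_d`; windows x
#'   trials), and the protocol.
#' @export
make_stimulus <- function(protocol, n_trials = 8, seed = 1, dt = 1) {
  stopifnot(inherits(protocol, "ci_protocol"))
  set.seed(derive_seed(seed, "stimulus"))
  T_ <- round(protocol$trial_ms / dt)
  n_win <- ceiling(protocol$trial_ms / protocol$period)
  if (protocol$period < protocol$pulse_ms) stop("pulses overlap at this rate")
  win_start <- (seq_len(n_win) - 1) * protocol$period

  draw_amp <- function(n) {
    if (!is.null(protocol$fixed_amplitude)) rep(protocol$fixed_amplitude, n)
    else sample(protocol$amplitudes, n, replace = TRUE)
  }
  # Each compartment receives the periodic pulse pattern with a circularly
  # uniform random phase per trial. Independent phases make the two traces
  # uncorrelated in expectation; with probability `correlation` the
  # dendritic train copies the somatic phase and amplitudes instead.
  phase_s <- if (protocol$jitter) stats::runif(n_trials, 0, protocol$trial_ms)
             else rep(0, n_trials)
  amps_s <- matrix(draw_amp(n_win * n_trials), n_win, n_trials)
  share <- stats::runif(n_trials) < protocol$correlation
  phase_d <- ifelse(share,
                    phase_s,
                    if (protocol$jitter) stats::runif(n_trials, 0, protocol$trial_ms)
                    else rep(0, n_trials))
  amps_d <- matrix(draw_amp(n_win * n_trials), n_win, n_trials)
  amps_d[, share] <- amps_s[, share]

  onsets <- function(phase) {            # (n_win, n_trials)
    outer(win_start, phase, function(w, p) (w + p) %% protocol$trial_ms)
  }
  onsets_s <- onsets(phase_s); onsets_d <- onsets(phase_d)
  trace <- function(ons, amps) {
    out <- matrix(0, T_, n_trials)
    tt <- (seq_len(T_) - 1) * dt
    for (b in seq_len(n_trials)) {
      for (w in seq_len(n_win)) {
        on <- ons[w, b]
        # circular placement: a pulse crossing the trial end wraps around
        hit <- ((tt - on) %% protocol$trial_ms) < protocol$pulse_ms
        out[hit, b] <- amps[w, b]
      }
    }
    out
  }
  list(soma = trace(onsets_s, amps_s), dend = trace(onsets_d, amps_d),
       onsets_s = onsets_s, onsets_d = onsets_d,
       amps_s = amps_s, amps_d = amps_d, protocol = protocol, dt = dt)
}

#' Realized correlation between the two stimulus traces
#'
#' Pearson correlation between the concatenated somatic and dendritic
#' current traces of a stimulus, the quantity controlled by the
#' `correlation` parameter of [stimulus_protocol()].
#'
#' @param stim result of [make_stimulus()].
#' @return Pearson r.
#' @export
stimulus_correlation <- function(stim) {
  stats::cor(as.vector(stim$soma), as.vector(stim$dend))
}

# Ornstein-Uhlenbeck background arrays (pA), dim (n, B, T); started from the
# stationary distribution.
make_ou_noise <- function(n, B, T_, mu, sigma, tau, dt = 1) {
  out <- array(0, c(n, B, T_))
  x <- matrix(stats::rnorm(n * B, mu, sigma * sqrt(tau / 2)), n, B)
  for (t in seq_len(T_)) {
    x <- step_ou(x, mu, sigma, tau, dt, matrix(stats::rnorm(n * B), n, B))
    out[, , t] <- x
  }
  out
}

# Assemble scaled simulator inputs (stimulus + background noise) for a batch.
make_inputs <- function(net, stim, seed) {
  p <- net$params; k <- scaled_constants(p)
  B <- ncol(stim$soma); T_ <- nrow(stim$soma)
  set.seed(derive_seed(seed, "noise"))
  bg_s <- make_ou_noise(net$config$N_E, B, T_, p$bg$mu_s, p$bg$sigma_s, p$bg$tau, p$dt)
  bg_d <- make_ou_noise(net$config$N_E, B, T_, p$bg$mu_d, p$bg$sigma_d, p$bg$tau, p$dt)
  bg_i <- make_ou_noise(net$config$N_I, B, T_, p$bg$mu_i, p$bg$sigma_i, p$bg$tau, p$dt)
  list(stim_s = stim$soma * k$ss, stim_d = stim$dend * k$sd,
       bg_s = bg_s * k$ss, bg_d = bg_d * k$sd, bg_i = bg_i * k$si,
       B = B, T_ = T_)
}

#' Simulate a network
#'
#' Runs the forward simulation (forward Euler, `dt = 1` ms) of the full
#' spiking circuit for a batch of trials and records spike rasters and the
#' compartment-resolved excitatory and inhibitory currents of every PC.
#' Background Ornstein-Uhlenbeck noise is drawn internally from `seed`.
#'
#' Recorded currents are in scaled units (threshold-to-rest voltage units per
#' ms); excitation is the external input (stimulus + background), inhibition
#' is the synaptic current `-sum_j |W_j| s_j(t)` and is always <= 0.
#'
#' @param net a [build_network()] result.
#' @param stim a [make_stimulus()] result.
#' @param seed integer seed for the background noise.
#' @return object of class `ci_record`: spike arrays `spikes_E`, `spikes_I`
#'   (`N x trials x T`), current arrays `E_s`, `E_d` (`N_E x trials x T`),
#'   `I_s`, `I_d` (`trials x T` in shared mode, `N_E x trials x T` in
#'   heterogeneous mode), interneuron rates `rate_I` (spk/s), and stimulus
#'   traces.
#' @export
simulate_network <- function(net, stim, seed = 1) {
  inputs <- make_inputs(net, stim, seed)
  rec <- ci_forward_fast(net, inputs)
  rec$stim <- stim
  rec
}

# Forward pass of the batch simulator. Semantics per element match the
# step_* functions (dt = params$dt); vectorized over neurons, synapses and
# trials. With keep_history = TRUE all intermediate quantities needed by the
# adjoint (backward) pass are stored. In relaxed mode every hard threshold
# is replaced by the smooth ramp `relaxed_spike()` and refractoriness is
# disabled; this mode exists to verify the backward pass against finite
# differences.
ci_forward <- function(net, inputs, keep_history = FALSE, relaxed = FALSE) {
  p <- net$params; k <- scaled_constants(p)
  cfg <- net$config
  N_E <- cfg$N_E; N_I <- cfg$N_I
  B <- inputs$B; T_ <- inputs$T_
  dt <- p$dt
  shared <- cfg$output_mode == "shared"
  beta <- p$surrogate_beta

  a_s <- 1 - dt / p$soma$tau;  a_w <- 1 - dt / p$soma$tau_w
  a_d <- 1 - dt / p$dend$tau;  a_dw <- 1 - dt / p$dend$tau_w
  a_i <- 1 - dt / p$inter$tau; a_syn <- 1 - dt / p$syn$tau
  a_u <- 1 - dt / p$stp$tau_u; a_r <- 1 - dt / p$stp$tau_R
  kd <- dt * k$kad / p$dend$tau_w
  Fs <- p$stp$F

  W_ei_abs <- abs(net$W_ei) * net$masks$ei
  W_ii_abs <- abs(net$W_ii) * net$masks$ii
  ws_abs <- abs(net$w_soma) * net$masks$soma
  wd_abs <- abs(net$w_dend) * net$masks$dend

  rep_j <- rep(seq_len(N_I), B)          # synapse block layout (N_E, N_I*B)
  rep_b <- rep(seq_len(B), each = N_I)
  W_rep <- W_ei_abs[, rep_j, drop = FALSE]
  U_rep <- net$U[, rep_j, drop = FALSE]

  vs <- matrix(0, N_E, B); ws <- matrix(0, N_E, B); refs <- matrix(0, N_E, B)
  vd <- matrix(0, N_E, B); wd <- matrix(0, N_E, B)
  vi <- matrix(0, N_I, B); refi <- matrix(0, N_I, B)
  sE <- matrix(0, N_E, B); sI <- matrix(0, N_I, B)
  u <- U_rep; R <- matrix(1, N_E, N_I * B)
  SE1 <- matrix(0, N_E, B); SE2 <- matrix(0, N_E, B)

  spikes_E <- array(0, c(N_E, B, T_)); spikes_I <- array(0, c(N_I, B, T_))
  E_s <- array(0, c(N_E, B, T_)); E_d <- array(0, c(N_E, B, T_))
  if (shared) { I_s <- matrix(0, B, T_); I_d <- matrix(0, B, T_) }
  else { I_s <- array(0, c(N_E, B, T_)); I_d <- array(0, c(N_E, B, T_)) }

  if (keep_history) {
    H <- list(
      vs_pre = vector("list", T_), vi_pre = vector("list", T_),
      actS = vector("list", T_), actI = vector("list", T_),
      SE = vector("list", T_), SI = vector("list", T_),
      vd = vector("list", T_ + 1),
      sE = vector("list", T_ + 1), sI = vector("list", T_ + 1),
      u = vector("list", T_ + 1), R = vector("list", T_ + 1)
    )
    H$vd[[1]] <- vd; H$sE[[1]] <- sE; H$sI[[1]] <- sI
    H$u[[1]] <- u; H$R[[1]] <- R
  }

  for (t in seq_len(T_)) {
    fd <- 1 / (1 + exp(-(vd - p$dend$E_d) / p$dend$D_d))
    if (shared) {
      inh_s_b <- as.vector(ws_abs %*% sI)      # length B
      inh_d_b <- as.vector(wd_abs %*% sI)
      inh_s <- matrix(inh_s_b, N_E, B, byrow = TRUE)
      inh_d <- matrix(inh_d_b, N_E, B, byrow = TRUE)
    } else {
      inh_s <- crossprod(ws_abs, sI)           # (N_E, B)
      inh_d <- crossprod(wd_abs, sI)
    }
    Es <- matrix(inputs$stim_s[t, ], N_E, B, byrow = TRUE) + inputs$bg_s[, , t]
    Ed <- matrix(inputs$stim_d[t, ], N_E, B, byrow = TRUE) + inputs$bg_d[, , t]

    vs_pre <- vs * a_s + dt * (k$gs * fd + ws + Es - inh_s)
    if (relaxed) {
      actS <- matrix(1, N_E, B)
      SE <- relaxed_spike(vs_pre, p$theta, beta)
    } else {
      actS <- (refs <= 0) * 1
      SE <- actS * (vs_pre >= p$theta)
    }
    vs <- actS * (1 - SE) * vs_pre
    if (!relaxed) { refs <- pmax(refs - dt, 0); refs[SE > 0] <- p$refrac }
    ws <- ws * a_w + k$bs * SE

    bap <- k$cd * (SE1 + SE2)
    vd_new <- vd * a_d + dt * (k$gd * fd + bap + wd + Ed - inh_d)
    wd <- wd * a_dw + kd * vd
    vd <- vd_new

    mu <- u * R
    SE_big <- SE[, rep_b, drop = FALSE]
    driveE <- matrix(colSums(W_rep * mu * sE[, rep_b, drop = FALSE]), N_I, B)
    driveI <- W_ii_abs %*% sI
    vi_pre <- vi * a_i + dt * (driveE - driveI + inputs$bg_i[, , t])
    if (relaxed) {
      actI <- matrix(1, N_I, B)
      SI <- relaxed_spike(vi_pre, p$theta, beta)
    } else {
      actI <- (refi <= 0) * 1
      SI <- actI * (vi_pre >= p$theta)
    }
    vi <- actI * (1 - SI) * vi_pre
    if (!relaxed) { refi <- pmax(refi - dt, 0); refi[SI > 0] <- p$refrac }

    sE <- sE * a_syn + SE
    sI <- sI * a_syn + SI

    u1 <- u * a_u + (dt / p$stp$tau_u) * U_rep
    u <- u1 + (1 - u1) * Fs * SE_big
    R1 <- R * a_r + (dt / p$stp$tau_R)
    R <- R1 * (1 - u * SE_big)

    SE2 <- SE1; SE1 <- SE

    spikes_E[, , t] <- SE; spikes_I[, , t] <- SI
    E_s[, , t] <- Es; E_d[, , t] <- Ed
    if (shared) { I_s[, t] <- -inh_s_b; I_d[, t] <- -inh_d_b }
    else { I_s[, , t] <- -inh_s; I_d[, , t] <- -inh_d }

    if (keep_history) {
      H$vs_pre[[t]] <- vs_pre; H$vi_pre[[t]] <- vi_pre
      H$actS[[t]] <- actS; H$actI[[t]] <- actI
      H$SE[[t]] <- SE; H$SI[[t]] <- SI
      H$vd[[t + 1]] <- vd
      H$sE[[t + 1]] <- sE; H$sI[[t + 1]] <- sI
      H$u[[t + 1]] <- u; H$R[[t + 1]] <- R
    }
    if (t %% 100 == 0 && any(!is.finite(vs), !is.finite(vd), !is.finite(vi))) {
      stop("non-finite network state at step ", t)
    }
  }

  rate_I <- rowMeans(spikes_I) * 1000 / dt
  record <- structure(
    list(spikes_E = spikes_E, spikes_I = spikes_I,
         E_s = E_s, E_d = E_d, I_s = I_s, I_d = I_d,
         rate_I = rate_I, dt = dt, n_trials = B, T_ = T_,
         shared = shared),
    class = "ci_record")
  list(record = record, hist = if (keep_history) H else NULL)
}

#' @export
print.ci_record <- function(x, ...) {
  cat(sprintf("<ci_record> %d trials x %d ms; mean PC rate %.1f spk/s, mean IN rate %.1f spk/s\n",
              x$n_trials, x$T_ * x$dt,
              mean(x$spikes_E) * 1000 / x$dt, mean(x$rate_I)))
  invisible(x)
}
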