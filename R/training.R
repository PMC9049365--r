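#' Compartment-specific excitation-inhibition matching loss
#'
#' Squared mismatch between baseline-corrected excitation and inhibition,
#' summed over time and PCs and averaged over trials, for each compartment:
#' `sum_t sum_i (E^x_i(t) - alpha * mu_x + I^x_i(t))^2`, where `E` is the
#' external excitatory input (stimulus plus background), `I <= 0` the
#' recorded inhibitory current and `mu_x` the mean background input of
#' compartment `x`. With `alpha_base = 1` inhibition is asked to cancel only
#' the excitation above the mean background, so interneurons can stay silent
#' when a compartment receives its minimum excitation; lowering `alpha_base`
#' raises the inhibitory target baseline, which forces a nonzero minimum
#' interneuron rate.
#'
#' @param record a `ci_record` from [simulate_network()].
#' @param alpha_base baseline-subtraction fraction in \[0.8, 1\].
#' @return list with `total`, `soma` and `dend` loss terms.
#' @export
ei_loss <- function(record, alpha_base = 1) {
  if (is.null(record$params)) stop("record lacks background metadata (params)")
  k <- scaled_constants(record$params)
  B <- record$n_trials
  rs <- residuals_ei(record, alpha_base)
  soma <- sum(rs$r_s^2) / B
  dend <- sum(rs$r_d^2) / B
  list(total = soma + dend, soma = soma, dend = dend)
}

# Per-PC balance residuals E + I - alpha * mu, arrays (N_E, B, T).
residuals_ei <- function(record, alpha_base) {
  k <- scaled_constants(record$params)
  N_E <- dim(record$E_s)[1]; B <- record$n_trials; T_ <- record$T_
  if (record$shared) {
    I_s <- aperm(array(record$I_s, c(B, T_, N_E)), c(3, 1, 2))
    I_d <- aperm(array(record$I_d, c(B, T_, N_E)), c(3, 1, 2))
  } else {
    I_s <- record$I_s; I_d <- record$I_d
  }
  list(r_s = record$E_s + I_s - alpha_base * k$mu_s,
       r_d = record$E_d + I_d - alpha_base * k$mu_d)
}

# Broadcast a (N_I, B) matrix across rows of the (N_E, N_I*B) synapse layout.
rep_row <- function(m, N_E) matrix(as.vector(m), N_E, length(m), byrow = TRUE)

# Sum the (N_E, N_I*B) synapse layout over the N_I columns of each trial
# block, giving (N_E, B).
fold_blocks <- function(M, N_I, B) {
  out <- matrix(0, nrow(M), B)
  for (b in seq_len(B)) {
    out[, b] <- rowSums(M[, ((b - 1) * N_I + 1):(b * N_I), drop = FALSE])
  }
  out
}

# Sum the synapse layout over trials, giving (N_E, N_I).
fold_trials <- function(M, N_I, B) {
  out <- matrix(0, nrow(M), N_I)
  for (b in seq_len(B)) {
    out <- out + M[, ((b - 1) * N_I + 1):(b * N_I), drop = FALSE]
  }
  out
}

# Adjoint (backpropagation-through-time) pass matching ci_forward.
#
# The spike nonlinearity uses the surrogate derivative
# 1/(1 + beta|v - theta|)^2 wherever a spike indicator feeds a downstream
# variable (traces, STP jumps, adaptation, back-propagating APs). The spike
# reset and refractory clamp are treated as non-differentiable gates
# (detached), except in relaxed mode where the forward pass itself is smooth
# and the reset product term is included, so that gradients agree with
# finite differences of the relaxed forward loss.
#
# Returns raw-parameter gradients (sign chain through |W| applied, masks
# applied) of the trial-averaged loss.
ci_backward <- function(net, inputs, fw, alpha_base = 1, relaxed = FALSE) {
  p <- net$params; k <- scaled_constants(p)
  cfg <- net$config
  N_E <- cfg$N_E; N_I <- cfg$N_I
  B <- inputs$B; T_ <- inputs$T_
  dt <- p$dt
  shared <- cfg$output_mode == "shared"
  beta <- p$surrogate_beta
  H <- fw$hist; rec <- fw$record
  if (is.null(H)) stop("forward pass was run without keep_history")

  a_s <- 1 - dt / p$soma$tau;  a_w <- 1 - dt / p$soma$tau_w
  a_d <- 1 - dt / p$dend$tau;  a_dw <- 1 - dt / p$dend$tau_w
  a_i <- 1 - dt / p$inter$tau; a_syn <- 1 - dt / p$syn$tau
  a_u <- 1 - dt / p$stp$tau_u; a_r <- 1 - dt / p$stp$tau_R
  ku <- dt / p$stp$tau_u; kr <- dt / p$stp$tau_R
  kd <- dt * k$kad / p$dend$tau_w
  Fs <- p$stp$F

  W_ei_abs <- abs(net$W_ei) * net$masks$ei
  W_ii_abs <- abs(net$W_ii) * net$masks$ii
  ws_abs <- abs(net$w_soma) * net$masks$soma
  wd_abs <- abs(net$w_dend) * net$masks$dend
  rep_j <- rep(seq_len(N_I), B)
  rep_b <- rep(seq_len(B), each = N_I)
  W_rep <- W_ei_abs[, rep_j, drop = FALSE]
  U_rep <- net$U[, rep_j, drop = FALSE]

  FB <- kronecker(diag(B), matrix(1, N_I, 1))     # block fold: (N_I*B, B)
  FT <- do.call(rbind, rep(list(diag(N_I)), B))   # trial fold: (N_I*B, N_I)
  mu_s_base <- alpha_base * k$mu_s
  mu_d_base <- alpha_base * k$mu_d

  zE <- matrix(0, N_E, B); zI <- matrix(0, N_I, B)
  lam_vs <- zE; lam_ws <- zE; lam_vd <- zE; lam_wd <- zE
  lam_vi <- zI; lam_sE <- zE; lam_sI <- zI
  lam_u <- matrix(0, N_E, N_I * B); lam_R <- matrix(0, N_E, N_I * B)
  pendA <- zE; pendB <- zE

  gU_acc <- matrix(0, N_E, N_I * B)
  gA_acc <- matrix(0, N_E, N_I * B)
  gB <- matrix(0, N_I, N_I)
  if (shared) { g_ws <- numeric(N_I); g_wd <- numeric(N_I) }
  else { g_ws <- matrix(0, N_I, N_E); g_wd <- matrix(0, N_I, N_E) }

  sl3 <- function(a, t, d1, d2) { m <- a[, , t, drop = FALSE]; dim(m) <- c(d1, d2); m }

  for (t in rev(seq_len(T_))) {
    SE <- H$SE[[t]]; SI <- H$SI[[t]]
    vs_pre <- H$vs_pre[[t]]; vi_pre <- H$vi_pre[[t]]
    actS <- H$actS[[t]]; actI <- H$actI[[t]]
    vd_prev <- H$vd[[t]]; sE_prev <- H$sE[[t]]; sI_prev <- H$sI[[t]]
    u_prev <- H$u[[t]]; R_prev <- H$R[[t]]
    u_post <- H$u[[t + 1]]
    Es <- matrix(inputs$stim_s[t, ], N_E, B, byrow = TRUE) +
      sl3(inputs$bg_s, t, N_E, B)
    Ed <- matrix(inputs$stim_d[t, ], N_E, B, byrow = TRUE) +
      sl3(inputs$bg_d, t, N_E, B)
    if (shared) {
      r_s <- Es + matrix(rec$I_s[, t], N_E, B, byrow = TRUE) - mu_s_base
      r_d <- Ed + matrix(rec$I_d[, t], N_E, B, byrow = TRUE) - mu_d_base
    } else {
      r_s <- Es + sl3(rec$I_s, t, N_E, B) - mu_s_base
      r_d <- Ed + sl3(rec$I_d, t, N_E, B) - mu_d_base
    }

    SEb <- SE[, rep_b, drop = FALSE]
    u1 <- u_prev * a_u + ku * U_rep
    R1 <- R_prev * a_r + kr

    ## --- short-term plasticity ---
    lam_R1 <- lam_R * (1 - u_post * SEb)
    lam_u_tot <- lam_u - lam_R * R1 * SEb
    lam_u1 <- lam_u_tot * (1 - Fs * SEb)
    gU_acc <- gU_acc + lam_u1 * ku
    gSE <- (lam_u_tot * (1 - u1) * Fs - lam_R * u_post * R1) %*% FB
    lam_u_new <- lam_u1 * a_u
    lam_R_new <- lam_R1 * a_r

    ## --- synaptic traces ---
    gSI <- lam_sI
    lam_sI_new <- lam_sI * a_syn
    gSE <- gSE + lam_sE
    lam_sE_new <- lam_sE * a_syn

    ## --- interneurons ---
    sur_i <- surrogate_spike_derivative(vi_pre, p$theta, beta)
    lam_vi_pre <- lam_vi * actI * (1 - SI) + gSI * actI * sur_i
    if (relaxed) lam_vi_pre <- lam_vi_pre - lam_vi * vi_pre * sur_i
    lam_vi <- lam_vi_pre * a_i
    lam_dE <- dt * lam_vi_pre
    lam_dI <- -dt * lam_vi_pre

    mu <- u_prev * R_prev
    sE_big <- sE_prev[, rep_b, drop = FALSE]
    ldE_big <- rep_row(lam_dE, N_E)
    P <- W_rep * ldE_big
    gA_acc <- gA_acc + mu * sE_big * ldE_big
    lam_mu <- P * sE_big
    lam_u_new <- lam_u_new + lam_mu * R_prev
    lam_R_new <- lam_R_new + lam_mu * u_prev
    lam_sE_new <- lam_sE_new + (P * mu) %*% FB
    gB <- gB + tcrossprod(lam_dI, sI_prev)
    lam_sI_new <- lam_sI_new + crossprod(W_ii_abs, lam_dI)

    ## --- dendrite ---
    lam_wd_new <- lam_wd * a_dw + lam_vd * dt
    lam_vd_prev <- lam_vd * a_d + lam_wd * kd
    fd <- 1 / (1 + exp(-(vd_prev - p$dend$E_d) / p$dend$D_d))
    lam_fd <- lam_vd * dt * k$gd
    bap_contrib <- k$cd * dt * lam_vd
    if (shared) {
      lam_inh_d <- -dt * colSums(lam_vd) - (2 / B) * colSums(r_d)
    } else {
      lam_inh_d <- -dt * lam_vd - (2 / B) * r_d
    }

    ## --- soma (after all spike-path adjoints are collected) ---
    gSE <- gSE + lam_ws * k$bs + pendA
    sur_s <- surrogate_spike_derivative(vs_pre, p$theta, beta)
    lam_vs_pre <- lam_vs * actS * (1 - SE) + gSE * actS * sur_s
    if (relaxed) lam_vs_pre <- lam_vs_pre - lam_vs * vs_pre * sur_s
    lam_ws <- lam_ws * a_w + lam_vs_pre * dt
    lam_vs <- lam_vs_pre * a_s
    lam_fd <- lam_fd + lam_vs_pre * dt * k$gs
    lam_vd_prev <- lam_vd_prev + lam_fd * fd * (1 - fd) / p$dend$D_d
    if (shared) {
      lam_inh_s <- -dt * colSums(lam_vs_pre) - (2 / B) * colSums(r_s)
    } else {
      lam_inh_s <- -dt * lam_vs_pre - (2 / B) * r_s
    }

    ## --- output-weight paths (use sI at t-1) ---
    if (shared) {
      g_ws <- g_ws + as.vector(sI_prev %*% lam_inh_s)
      g_wd <- g_wd + as.vector(sI_prev %*% lam_inh_d)
      lam_sI_new <- lam_sI_new + outer(ws_abs, lam_inh_s) + outer(wd_abs, lam_inh_d)
    } else {
      g_ws <- g_ws + tcrossprod(sI_prev, lam_inh_s)
      g_wd <- g_wd + tcrossprod(sI_prev, lam_inh_d)
      lam_sI_new <- lam_sI_new + ws_abs %*% lam_inh_s + wd_abs %*% lam_inh_d
    }

    ## rotate carried adjoints
    lam_vd <- lam_vd_prev
    lam_wd <- lam_wd_new
    lam_sE <- lam_sE_new
    lam_sI <- lam_sI_new
    lam_u <- lam_u_new
    lam_R <- lam_R_new
    newA <- pendB + bap_contrib
    pendB <- bap_contrib
    pendA <- newA
  }

  # the utilization state is initialized at u(0) = U, so the adjoint left at
  # t = 0 flows into the U gradient as well
  gU_acc <- gU_acc + lam_u
  sgn <- function(w) sign(w)
  list(
    W_ei = (gA_acc %*% FT) * sgn(net$W_ei) * net$masks$ei,
    U = (gU_acc %*% FT) * net$masks$ei,
    W_ii = gB * sgn(net$W_ii) * net$masks$ii,
    w_soma = g_ws * sgn(net$w_soma) * net$masks$soma,
    w_dend = g_wd * sgn(net$w_dend) * net$masks$dend
  )
}

#' Training configuration
#'
#' @param n_updates maximum number of Adam updates (parameter updates); each
#'   update uses one fresh batch.
#' @param batch_size trials per batch.
#' @param protocol stimulus protocol for the training batches, see
#'   [stimulus_protocol()].
#' @param lr named list of Adam learning rates per parameter group
#'   (`w_ei`, `u`, `w_ii`, `w_out`).
#' @param alpha_base baseline-subtraction fraction, see [ei_loss()].
#' @param clip gradients are clipped elementwise to `[-clip, clip]` before
#'   the update.
#' @param freeze_stp if `TRUE`, the initial release probabilities `U` are not
#'   optimized (their learning rate is set to 0): the no-short-term-plasticity
#'   control.
#' @param patience stop early when the smoothed loss has not improved for
#'   this many updates (`Inf` disables early stopping).
#' @param lr_decay,lr_decay_at learning rates are multiplied by `lr_decay`
#'   after the fraction `lr_decay_at` of `n_updates`, for a refinement phase
#'   with smaller steps.
#' @return list of class `ci_train_config`.
#' @export
train_config <- function(n_updates = 400, batch_size = 8,
                         protocol = stimulus_protocol(),
                         lr = list(w_ei = 1e-3, u = 4e-3, w_ii = 1e-3,
                                   w_out = 1e-3),
                         alpha_base = 1, clip = 1, freeze_stp = FALSE,
                         patience = 100, lr_decay = 0.3, lr_decay_at = 0.6) {
  lr_def <- list(w_ei = 1e-3, u = 4e-3, w_ii = 1e-3, w_out = 1e-3)
  lr <- modify_list_strict(lr_def, lr, "lr")
  if (alpha_base < 0.8 || alpha_base > 1) {
    stop("alpha_base must lie in [0.8, 1]")
  }
  structure(list(n_updates = n_updates, batch_size = batch_size,
                 protocol = protocol, lr = lr, alpha_base = alpha_base,
                 clip = clip, freeze_stp = freeze_stp, patience = patience,
                 lr_decay = lr_decay, lr_decay_at = lr_decay_at),
            class = "ci_train_config")
}

#' Optimize a network for compartment-specific feedback inhibition
#'
#' Gradient descent through the spiking simulation: every update simulates a
#' fresh batch of trials, computes the excitation-inhibition matching loss
#' [ei_loss()], backpropagates through time with surrogate spike
#' derivatives, clips gradients elementwise to `[-1, 1]`, takes an Adam step
#' for each parameter group (PC->IN weights and release probabilities,
#' IN->IN weights, IN->PC output weights), and clips the release
#' probabilities to `[0, 1]`. Structurally masked connections (pre-assigned
#' zero compartments, knockouts, autapses) never move.
#'
#' @param net a [build_network()] result.
#' @param config a [train_config()].
#' @param seed integer master seed; stimulus and noise streams are derived
#'   from it deterministically.
#' @return list of class `ci_training` with the trained `net`, a per-update
#'   `history` data frame (loss terms and the E/I correlation of each
#'   compartment on the training batch), and the `config`.
#' @export
train_network <- function(net, config = train_config(), seed = 1) {
  stopifnot(inherits(config, "ci_train_config"))
  lr <- config$lr
  if (config$freeze_stp) lr$u <- 0
  groups <- c("W_ei", "U", "W_ii", "w_soma", "w_dend")
  lrs <- c(W_ei = lr$w_ei, U = lr$u, W_ii = lr$w_ii,
           w_soma = lr$w_out, w_dend = lr$w_out)
  m <- lapply(net[groups], function(x) x * 0)
  v <- lapply(net[groups], function(x) x * 0)
  names(m) <- names(v) <- groups
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  hist_rows <- vector("list", config$n_updates)
  best <- Inf; best_at <- 0
  best_snapshot <- net[groups]
  n_done <- 0
  for (it in seq_len(config$n_updates)) {
    stim <- make_stimulus(config$protocol, config$batch_size,
                          seed = derive_seed(seed, paste0("stim", it)))
    inputs <- make_inputs(net, stim, seed = derive_seed(seed, paste0("bg", it)))
    step <- ci_grad_fast(net, inputs, config$alpha_base)
    loss <- step$loss
    if (!is.finite(loss$total)) stop("loss diverged (non-finite) at update ", it)
    # optimize the per-step, per-PC mean of the balance error: the gradient
    # rescaling keeps typical gradients well inside the clip bounds so that
    # clipping only catches outliers (its intended role)
    gscale <- 1 / (dim(inputs$bg_s)[3] * net$config$N_E)
    grads <- lapply(step$grads, function(g) g * gscale)

    decay <- if (it > config$lr_decay_at * config$n_updates) config$lr_decay else 1
    for (g in groups) {
      if (lrs[[g]] == 0) next
      gr <- pmin(pmax(grads[[g]], -config$clip), config$clip)
      m[[g]] <- b1 * m[[g]] + (1 - b1) * gr
      v[[g]] <- b2 * v[[g]] + (1 - b2) * gr^2
      mh <- m[[g]] / (1 - b1^it)
      vh <- v[[g]] / (1 - b2^it)
      net[[g]] <- net[[g]] - decay * lrs[[g]] * mh / (sqrt(vh) + eps)
    }
    net$U <- pmin(pmax(net$U, 0), 1)
    net$W_ii <- net$W_ii * net$masks$ii
    net$w_soma <- net$w_soma * net$masks$soma
    net$w_dend <- net$w_dend * net$masks$dend

    r <- ei_correlation_parts(inputs, step$I_s, step$I_d,
                              net$config$output_mode == "shared")
    hist_rows[[it]] <- data.frame(update = it, loss = loss$total,
                                  loss_soma = loss$soma, loss_dend = loss$dend,
                                  r_soma = r[["soma"]], r_dend = r[["dend"]])
    n_done <- it
    sm <- mean(vapply(hist_rows[max(1, it - 9):it],
                      function(h) h$loss, numeric(1)))
    if (sm < best * 0.995) {
      best <- sm; best_at <- it
      best_snapshot <- net[groups]
    }
    if (is.finite(config$patience) && it - best_at >= config$patience) break
  }
  # keep the parameters with the best smoothed loss seen during training
  net[groups] <- best_snapshot
  history <- do.call(rbind, hist_rows[seq_len(n_done)])
  structure(list(net = net, history = history, config = config, seed = seed),
            class = "ci_training")
}

#' @export
print.ci_training <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<ci_training> %d updates; loss %.4g -> %.4g; final E/I r (soma, dend) = (%.2f, %.2f)\n",
              n, x$history$loss[1], x$history$loss[n],
              x$history$r_soma[n], x$history$r_dend[n]))
  invisible(x)
}
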