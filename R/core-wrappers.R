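# Wrappers around the compiled simulation core. The pure-R implementation
# (ci_forward / ci_backward) defines the reference semantics; parity tests
# hold the two implementations together, and finite-difference tests anchor
# the gradients.

ci_consts <- function(net) {
  p <- net$params; k <- scaled_constants(p); dt <- p$dt
  list(dt = dt, theta = p$theta, refrac = p$refrac, beta = p$surrogate_beta,
       a_s = 1 - dt / p$soma$tau, a_w = 1 - dt / p$soma$tau_w,
       a_d = 1 - dt / p$dend$tau, a_dw = 1 - dt / p$dend$tau_w,
       a_i = 1 - dt / p$inter$tau, a_syn = 1 - dt / p$syn$tau,
       a_u = 1 - dt / p$stp$tau_u, a_r = 1 - dt / p$stp$tau_R,
       ku = dt / p$stp$tau_u, kr = dt / p$stp$tau_R,
       kd = dt * k$kad / p$dend$tau_w,
       gs = k$gs, gd = k$gd, cd = k$cd, bs = k$bs, Fs = p$stp$F,
       Ed = p$dend$E_d, Dd = p$dend$D_d)
}

ci_net_list <- function(net) {
  list(N_E = net$config$N_E, N_I = net$config$N_I,
       shared = net$config$output_mode == "shared",
       W_ei_abs = abs(net$W_ei) * net$masks$ei,
       W_ii_abs = abs(net$W_ii) * net$masks$ii,
       U = net$U,
       ws_abs = abs(net$w_soma) * net$masks$soma,
       wd_abs = abs(net$w_dend) * net$masks$dend)
}

# Reconstruct the per-PC excitatory input arrays (N_E, B, T) from the
# scaled inputs (stimulus broadcast over PCs plus per-PC background).
excitation_arrays <- function(inputs, N_E) {
  T_ <- inputs$T_; B <- inputs$B
  stim_arr <- function(stim) aperm(array(stim, c(T_, B, N_E)), c(3, 2, 1))
  list(E_s = inputs$bg_s + stim_arr(inputs$stim_s),
       E_d = inputs$bg_d + stim_arr(inputs$stim_d))
}

# Forward simulation through the compiled core; returns a ci_record.
ci_forward_fast <- function(net, inputs, relaxed = FALSE) {
  raw <- cpp_forward(ci_net_list(net), ci_consts(net),
                     inputs[c("stim_s", "stim_d", "bg_s", "bg_d", "bg_i")],
                     relaxed)
  ex <- excitation_arrays(inputs, net$config$N_E)
  shared <- net$config$output_mode == "shared"
  structure(
    list(spikes_E = raw$spikes_E, spikes_I = raw$spikes_I,
         E_s = ex$E_s, E_d = ex$E_d,
         I_s = raw$I_s, I_d = raw$I_d,
         rate_I = rowMeans(raw$spikes_I) * 1000 / net$params$dt,
         dt = net$params$dt, n_trials = inputs$B, T_ = inputs$T_,
         shared = shared, params = net$params),
    class = "ci_record")
}

# Fused forward + gradient step through the compiled core. Returns loss
# terms, raw-parameter gradients, and the population-level pieces needed
# for the per-update E/I correlation.
ci_grad_fast <- function(net, inputs, alpha_base = 1, relaxed = FALSE) {
  k <- scaled_constants(net$params)
  raw <- cpp_train_step(ci_net_list(net), ci_consts(net),
                        inputs[c("stim_s", "stim_d", "bg_s", "bg_d", "bg_i")],
                        alpha_base * k$mu_s, alpha_base * k$mu_d, relaxed)
  g <- raw$grads
  grads <- list(
    W_ei = g$W_ei_abs * sign(net$W_ei) * net$masks$ei,
    U = g$U * net$masks$ei,
    W_ii = g$W_ii_abs * sign(net$W_ii) * net$masks$ii,
    w_soma = drop_to_shape(g$ws_abs, net$w_soma) * sign(net$w_soma) * net$masks$soma,
    w_dend = drop_to_shape(g$wd_abs, net$w_dend) * sign(net$w_dend) * net$masks$dend)
  shared <- net$config$output_mode == "shared"
  list(loss = list(total = raw$loss_soma + raw$loss_dend,
                   soma = raw$loss_soma, dend = raw$loss_dend),
       grads = grads,
       I_s = raw$I_s, I_d = raw$I_d,
       spikes_I = raw$spikes_I)
}

drop_to_shape <- function(x, template) {
  if (is.matrix(template)) x else as.vector(x)
}

# E/I correlation computed from scaled inputs and recorded inhibition,
# without materializing the full excitation arrays.
ei_correlation_parts <- function(inputs, I_s, I_d, shared) {
  pop_e_s <- t(inputs$stim_s) + apply(inputs$bg_s, c(2, 3), mean)   # (B, T)
  pop_e_d <- t(inputs$stim_d) + apply(inputs$bg_d, c(2, 3), mean)
  pop_i_s <- if (shared) I_s else apply(I_s, c(2, 3), mean)
  pop_i_d <- if (shared) I_d else apply(I_d, c(2, 3), mean)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  c(soma = safe_cor(as.vector(pop_e_s), -as.vector(pop_i_s)),
    dend = safe_cor(as.vector(pop_e_d), -as.vector(pop_i_d)))
}
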