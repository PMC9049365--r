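test_that("network construction is deterministic and applies structural masks", {
  net1 <- tiny_network(seed = 3)
  net2 <- tiny_network(seed = 3)
  expect_identical(net1$W_ei, net2$W_ei)
  expect_identical(net1$U, net2$U)
  expect_identical(net1$w_soma, net2$w_soma)
  net3 <- tiny_network(seed = 4)
  expect_false(identical(net1$W_ei, net3$W_ei))

  # pre-assignment: half of the INs lose their dendritic weights, half somatic
  net <- tiny_network(N_I = 6, preassign = TRUE)
  expect_equal(sum(net$w_dend[net$preassigned == "PV"]), 0)
  expect_equal(sum(net$w_soma[net$preassigned == "SST"]), 0)
  expect_true(all(net$w_soma[net$preassigned == "PV"] > 0))

  # knockout: the PV -> SST block of W_II is structurally zero
  net <- tiny_network(N_I = 6, preassign = TRUE, knockout = "pv_sst")
  pv <- net$preassigned == "PV"; sst <- !pv
  expect_true(all(net$W_ii[sst, pv] == 0))
  expect_true(any(net$W_ii[pv, sst] != 0))
  expect_true(all(diag(net$W_ii) == 0))    # no autapses

  expect_error(network_config(knockout = "pv_sst"), "preassigned")
  expect_error(network_config(knockout = "foo", preassign = TRUE), "knockout")
})

test_that("initial release probabilities give a mean paired-pulse ratio near 1", {
  net <- build_network(network_config(N_E = 200, N_I = 30), default_params(),
                       seed = 5)
  expect_equal(mean(network_ppr(net)), 1, tolerance = 0.05)
})

test_that("stimulus protocol produces one pulse per 400 ms window with controlled correlation", {
  proto <- stimulus_protocol()   # 100 ms pulses at 2.5 Hz, 600 ms trials
  stim <- make_stimulus(proto, 40, seed = 6)
  # two pulses per 600 ms trial; each trace carries exactly 200 ms of pulse
  expect_equal(nrow(stim$onsets_s), 2)
  expect_true(all(colSums(stim$soma > 0) == 200))
  # the two pulses of a trial keep the periodic 400 ms spacing (circularly)
  gaps <- (stim$onsets_s[2, ] - stim$onsets_s[1, ]) %% 600
  expect_true(all(gaps == 400))
  expect_true(all(stim$soma %in% c(0, proto$amplitudes)))

  # correlation control: shared sampling gives r = 1, independent ~ 0
  s1 <- make_stimulus(stimulus_protocol(correlation = 1), 20, seed = 7)
  expect_equal(stimulus_correlation(s1), 1)
  s0 <- make_stimulus(stimulus_protocol(correlation = 0), 200, seed = 8)
  expect_lt(abs(stimulus_correlation(s0)), 0.1)
  s05 <- make_stimulus(stimulus_protocol(correlation = 0.5), 200, seed = 9)
  expect_gt(stimulus_correlation(s05), stimulus_correlation(s0))
  expect_lt(stimulus_correlation(s05), 1)

  # deterministic onsets without jitter: pulses start exactly every 400 ms
  sreg <- make_stimulus(stimulus_protocol(jitter = FALSE), 2, seed = 10)
  expect_equal(sreg$onsets_s[, 1], c(0, 400))
})

test_that("silent network with zero weights and no noise stays silent", {
  p <- default_params(list(bg = list(mu_s = 0, sigma_s = 0, mu_d = 0,
                                     sigma_d = 0, mu_i = 0, sigma_i = 0)))
  net <- build_network(network_config(N_E = 5, N_I = 3), p, seed = 1)
  net$W_ei[] <- 0; net$W_ii[] <- 0; net$w_soma[] <- 0; net$w_dend[] <- 0
  proto <- stimulus_protocol()
  stim <- make_stimulus(proto, 2, seed = 2)
  stim$soma[] <- 0; stim$dend[] <- 0
  rec <- simulate_network(net, stim, seed = 3)
  expect_equal(sum(rec$spikes_E), 0)
  expect_equal(sum(rec$spikes_I), 0)
  expect_true(all(rec$I_s == 0) && all(rec$I_d == 0))
})

test_that("recorded inhibitory currents are non-positive and replayable from the raster", {
  net <- tiny_network(N_E = 10, N_I = 5, seed = 2)
  stim <- make_stimulus(stimulus_protocol(), 3, seed = 3)
  rec <- simulate_network(net, stim, seed = 4)
  expect_true(all(rec$I_s <= 0) && all(rec$I_d <= 0))

  # offline replay: rebuild the IN traces from the spike raster and recompute
  # the inhibitory current; must match the recording exactly
  p <- net$params
  ws <- abs(net$w_soma) * net$masks$soma
  for (b in 1:3) {
    sI <- numeric(net$config$N_I)
    for (t in seq_len(rec$T_)) {
      expect_equal(rec$I_s[b, t], -sum(ws * sI), tolerance = 1e-12)
      sI <- sI * (1 - 1 / p$syn$tau) + rec$spikes_I[, b, t]
    }
  }
})

test_that("a strongly driven PC makes its interneuron fire after the trace rises", {
  p <- default_params(list(bg = list(mu_s = 0, sigma_s = 0, mu_d = 0,
                                     sigma_d = 0, mu_i = 0, sigma_i = 0)))
  net <- build_network(network_config(N_E = 1, N_I = 1), p, seed = 1)
  net$W_ei[] <- 2; net$W_ii[] <- 0; net$w_soma[] <- 0; net$w_dend[] <- 0
  T_ <- 200
  stim <- list(soma = matrix(1000, T_, 1), dend = matrix(0, T_, 1), dt = 1)
  rec <- simulate_network(net, stim, seed = 2)
  tE <- which(rec$spikes_E[1, 1, ] > 0)
  tI <- which(rec$spikes_I[1, 1, ] > 0)
  expect_gt(length(tE), 3)
  expect_gt(length(tI), 0)
  expect_gt(min(tI), min(tE))   # IN fires only after PC spikes feed the trace
})

test_that("ablating IN -> PC weights makes PC activity independent of the interneurons", {
  net <- tiny_network(N_E = 8, N_I = 4, seed = 6)
  net$w_soma[] <- 0; net$w_dend[] <- 0
  stim <- make_stimulus(stimulus_protocol(), 2, seed = 7)
  rec1 <- simulate_network(net, stim, seed = 8)
  net2 <- net
  net2$W_ii <- net2$W_ii * 3   # changing the IN circuit must not matter
  rec2 <- simulate_network(net2, stim, seed = 8)
  expect_identical(rec1$spikes_E, rec2$spikes_E)
})

test_that("doubling N_E with duplicated inputs and 1/N-scaled weights preserves the mean field", {
  p <- default_params(list(bg = list(sigma_s = 0, sigma_d = 0, sigma_i = 0)))
  cfg1 <- network_config(N_E = 6, N_I = 3)
  net1 <- build_network(cfg1, p, seed = 9)
  stim <- make_stimulus(stimulus_protocol(), 2, seed = 10)
  rec1 <- simulate_network(net1, stim, seed = 11)

  cfg2 <- network_config(N_E = 12, N_I = 3)
  net2 <- build_network(cfg2, p, seed = 9)
  net2$W_ei <- rbind(net1$W_ei, net1$W_ei) / 2   # duplicate PCs, halve weights
  net2$U <- rbind(net1$U, net1$U)
  net2$W_ii <- net1$W_ii
  net2$w_soma <- net1$w_soma; net2$w_dend <- net1$w_dend
  rec2 <- simulate_network(net2, stim, seed = 11)
  # identical per-PC drive (no noise): population-mean currents coincide
  expect_equal(rec2$I_s, rec1$I_s, tolerance = 1e-10)
  expect_equal(rec2$spikes_E[1:6, , ], rec1$spikes_E, tolerance = 1e-12)
})

test_that("simulation composed of the exported step functions matches the core", {
  # single PC + single IN, no noise: the vectorized core must agree with the
  # stateless step_* functions composed in R
  p <- default_params(list(bg = list(mu_s = 300, sigma_s = 0, mu_d = 150,
                                     sigma_d = 0, mu_i = 0, sigma_i = 0)))
  net <- build_network(network_config(N_E = 1, N_I = 1), p, seed = 12)
  T_ <- 300
  stim <- list(soma = matrix(rep(c(0, 400), each = T_ / 2), T_, 1),
               dend = matrix(rep(c(300, 0), each = T_ / 2), T_, 1), dt = 1)
  rec <- simulate_network(net, stim, seed = 13)

  k <- compinhib:::scaled_constants(p)
  soma <- list(v = 0, w = 0, refrac = 0)
  dend <- list(v = 0, w = 0)
  inter <- list(v = 0, refrac = 0)
  sE <- 0; sI <- 0
  stp_state <- list(u = net$U[1, 1], R = 1)
  lag1 <- 0; lag2 <- 0
  w_ei <- abs(net$W_ei[1, 1]); w_s <- abs(net$w_soma[1]); w_d <- abs(net$w_dend[1])
  spikes <- numeric(T_)
  for (t in seq_len(T_)) {
    mu <- stp_state$u * stp_state$R
    I_soma <- stim$soma[t, 1] * k$ss + p$bg$mu_s * k$ss - w_s * sI
    I_dend <- stim$dend[t, 1] * k$sd + p$bg$mu_d * k$sd - w_d * sI
    I_in <- w_ei * mu * sE
    out_s <- step_soma(soma, dend$v, I_soma, p)
    dend <- step_dendrite(dend, lag1, lag2, I_dend, p)$state
    out_i <- step_interneuron(inter, I_in, p)
    soma <- out_s$state; inter <- out_i$state
    sE <- step_synaptic_trace(sE, out_s$spike, p$syn$tau)
    sI <- step_synaptic_trace(sI, out_i$spike, p$syn$tau)
    stp_state <- step_stp(stp_state, as.numeric(out_s$spike),
                          c(list(U = net$U[1, 1]), p$stp))$state
    lag2 <- lag1; lag1 <- as.numeric(out_s$spike)
    spikes[t] <- as.numeric(out_s$spike)
  }
  expect_equal(as.vector(rec$spikes_E[1, 1, ]), spikes)
})
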