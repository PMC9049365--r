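test_that("paired-pulse ratio matches a brute-force fine-step integration", {
  set.seed(11)
  for (rep in 1:25) {
    U <- runif(1); F <- runif(1, 0, 0.9)
    tau_u <- runif(1, 20, 300); tau_R <- runif(1, 5, 150)
    rel <- stp_brute_force(c(5, 15), U, F, tau_u, tau_R)
    m <- measure_ppr(U, F, tau_u, tau_R, isi = 10)
    if (rel[1] > 1e-9) {
      expect_equal(m$ppr, rel[2] / rel[1], tolerance = 1e-3)
    }
    expect_equal(m$mu1, rel[1], tolerance = 1e-3)
    expect_equal(m$mu2, rel[2], tolerance = 1e-3)
  }
})

test_that("PPR limiting cases: pure depression, full depletion, neutral synapse", {
  # F = 0: second release scaled by the non-recovered resources, PPR = 1 - U e^{-isi/tau_R}
  m <- measure_ppr(0.4, 0, 100, 50, isi = 10)
  expect_equal(m$ppr, 1 - 0.4 * exp(-10 / 50), tolerance = 1e-10)
  expect_lt(m$ppr, 1)
  # U = 1, F = 0, slow recovery: near-complete depletion
  expect_lt(measure_ppr(1, 0, 100, 1e4, isi = 10)$ppr, 0.01)
  # the neutral U solved by the initializer really gives PPR = 1
  stp <- default_params()$stp
  us <- compinhib:::u_neutral(stp)
  expect_equal(measure_ppr(us, stp$F, stp$tau_u, stp$tau_R)$ppr, 1,
               tolerance = 1e-6)
  # a synapse that cannot release at all on the first pulse is flagged
  expect_true(measure_ppr(0, 0, 100, 50)$facilitation_dominated)
  expect_false(measure_ppr(0.2, 0.3, 100, 50)$facilitation_dominated)
})

test_that("event detection groups spikes greedily and partitions the train", {
  expect_equal(detect_events(0)$event_times, 0)
  expect_false(any(detect_events(0)$is_burst))

  # three spikes with 10 ms gaps: one burst timestamped at the first spike
  de <- detect_events(c(0, 10, 20))
  expect_equal(de$event_times, 0)
  expect_true(de$is_burst)
  expect_equal(de$n_spikes, 3L)

  # gap above the window: two singlet events
  de <- detect_events(c(0, 20))
  expect_equal(de$event_times, c(0, 20))
  expect_equal(sum(de$is_burst), 0)

  expect_error(detect_events(c(5, 1)), "sorted")

  # partition property: every spike belongs to exactly one event
  set.seed(2)
  for (rep in 1:20) {
    st <- sort(runif(30, 0, 500))
    de <- detect_events(st)
    expect_equal(sum(de$n_spikes), length(st))
    expect_equal(de$event_times, st[c(1, which(diff(st) > 16) + 1)])
  }
})

test_that("burst probability is the burst/event rate ratio in percent", {
  expect_equal(burst_probability(0, 5), 0)
  expect_equal(burst_probability(5, 5), 100)
  expect_equal(burst_probability(1, 4), 25)
  expect_equal(burst_probability(0, 0), 0)
  expect_error(burst_probability(2, 1), "event_rate >= burst_rate")
  # aggregation consistency: merged counts give the same ratio
  b <- c(1, 3); e <- c(4, 6)
  expect_equal(burst_probability(sum(b), sum(e)),
               100 * sum(b) / sum(e))
})

test_that("population rate traces conserve mass and flatten Poisson input", {
  pr <- population_rates(numeric(0), t_max = 100)
  expect_true(all(pr$rate == 0))
  # kernel normalization: smoothed counts sum to the number of events
  pr <- population_rates(c(40, 50, 50.5, 60), t_max = 100)
  expect_equal(sum(pr$rate) / 1000, 4, tolerance = 1e-6)
  # constant-rate Poisson raster: flat trace within sampling error
  set.seed(4)
  times <- sort(runif(20000, 0, 1000))
  pr <- population_rates(times, t_max = 1000, n_neurons = 20)
  mid <- pr$rate[100:900]
  expect_equal(mean(mid), 1000, tolerance = 0.05)  # 20 Hz * ... 1 spk/ms pooled
  expect_lt(sd(mid) / mean(mid), 0.2)
})

test_that("specialization index has the stated endpoints and cosine form", {
  expect_equal(specialization(c(1, 0), c(0, 1)), 1)       # disjoint support
  expect_equal(specialization(c(2, 1), c(4, 2)), 0)       # proportional
  expect_equal(specialization(c(1, 0), c(1, 1) / sqrt(2)), 1 - 1 / sqrt(2))
  expect_true(is.na(specialization(c(0, 0), c(1, 1))))
  expect_error(specialization(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("E/I correlation is 1 for mirrored currents and ~0 for stimulus-blind inhibition", {
  # synthetic record: inhibition exactly mirrors excitation above baseline
  T_ <- 300; B <- 2; N_E <- 5
  ex <- array(rep(rep(c(0.1, 0.5), each = T_ / 2), each = N_E * B), c(N_E, B, T_))
  rec <- structure(list(
    E_s = ex, E_d = ex,
    I_s = -apply(ex, c(2, 3), mean), I_d = -apply(ex, c(2, 3), mean),
    shared = TRUE, n_trials = B, T_ = T_), class = "ci_record")
  r <- ei_correlation(rec)
  expect_equal(unname(r["soma"]), 1)
  # inhibition independent of the stimulus: correlation near zero
  set.seed(5)
  rec$I_s <- matrix(-abs(rnorm(B * T_)), B, T_)
  r <- ei_correlation(rec)
  expect_lt(abs(r[["soma"]]), 0.15)
  # zero-variance trace: undefined, reported as missing
  rec$I_d <- matrix(0, B, T_)
  expect_true(is.na(ei_correlation(rec)[["dend"]]))
})

test_that("mixture clustering recovers well-separated classes and names them by PPR", {
  set.seed(6)
  n <- 120
  pv <- data.frame(w_soma = rnorm(n, 0.06, 0.004), w_dend = rnorm(n, 0.005, 0.003),
                   ppr = rnorm(n, 0.7, 0.05))
  sst <- data.frame(w_soma = rnorm(n, 0.005, 0.003), w_dend = rnorm(n, 0.06, 0.004),
                    ppr = rnorm(n, 1.5, 0.05))
  feats <- rbind(pv, sst)
  feats$w_soma <- pmax(feats$w_soma, 0); feats$w_dend <- pmax(feats$w_dend, 0)
  feats$rate <- 5
  truth <- rep(c("PV", "SST"), each = n)
  cl <- cluster_interneurons(feats, 2)
  expect_gte(mean(as.character(cl$labels) == truth), 0.99)
  # naming: the higher-PPR component is the SST-like one
  expect_gt(cl$means["SST", "ppr"], cl$means["PV", "ppr"])

  # filters: inactive and weakly projecting INs are dropped before fitting
  feats2 <- feats
  feats2$rate[1:10] <- 0.2
  feats2$w_soma[11:15] <- 0.001; feats2$w_dend[11:15] <- 0.001
  cl2 <- cluster_interneurons(feats2, 2)
  expect_equal(sum(cl2$keep), nrow(feats) - 15)

  expect_error(cluster_interneurons(feats[1:2, ], 4), "fewer data points")
})

test_that("a single blob fit with two components does not split spuriously", {
  set.seed(8)
  n <- 150
  blob <- data.frame(w_soma = rnorm(n, 0.03, 0.005), w_dend = rnorm(n, 0.03, 0.005),
                     ppr = rnorm(n, 1, 0.08), rate = 5)
  cl <- cluster_interneurons(blob, 2)
  # component means closer than twice the within-component spread
  d <- sqrt(sum((cl$means["PV", c("w_soma", "w_dend")] -
                 cl$means["SST", c("w_soma", "w_dend")])^2))
  expect_lt(d, 2 * 0.005 * 2)
})

test_that("cluster connectivity averages the labelled blocks of W_II exactly", {
  labels <- factor(c("PV", "PV", "SST", "SST"), levels = c("PV", "SST"))
  W <- matrix(0, 4, 4)           # rows = postsynaptic
  W[1:2, 1:2] <- 1               # PV -> PV
  W[3:4, 1:2] <- 2               # PV -> SST
  W[1:2, 3:4] <- 3               # SST -> PV
  W[3:4, 3:4] <- 4               # SST -> SST
  cc <- cluster_connectivity(labels, W)
  expect_equal(unname(cc), c(1, 2, 3, 4))
  # all-equal matrix: four equal means
  cc2 <- cluster_connectivity(labels, matrix(0.5, 4, 4))
  expect_true(all(cc2 == 0.5))
})
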