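p0 <- default_params()

test_that("dendritic nonlinearity has logistic midpoint, saturation and slope", {
  expect_equal(dendritic_nonlinearity(2.0, 2.0, 0.3), 0.5)
  expect_equal(dendritic_nonlinearity(-1e6, 2.0, 0.3), 0)
  expect_equal(dendritic_nonlinearity(1e6, 2.0, 0.3), 1)
  # one slope-length above the half-point: closed form 1 / (1 + e^-1)
  expect_equal(dendritic_nonlinearity(2.0 + 0.3, 2.0, 0.3), 1 / (1 + exp(-1)))
  v <- seq(-2, 5, by = 0.05)
  expect_true(all(diff(dendritic_nonlinearity(v, 2.0, 0.3)) > 0))
  expect_error(dendritic_nonlinearity(0, 2.0, 0), "D_d")
  expect_error(dendritic_nonlinearity(0, 2.0, -1), "D_d")
})

test_that("soma at rest with zero input is a fixed point and suprathreshold drive spikes", {
  st <- list(v = 0, w = 0, refrac = 0)
  out <- step_soma(st, v_d = -1e3, I_total = 0, p0)
  expect_equal(out$state$v, 0)
  expect_false(out$spike)

  # hand-integrated Euler recursion under constant drive (no dendritic input)
  I <- 0.2
  v <- 0
  for (k in 1:3) v <- v * (1 - 1 / p0$soma$tau) + I
  st <- list(v = 0, w = 0, refrac = 0)
  for (k in 1:3) st <- step_soma(st, v_d = -1e3, I_total = I, p0)$state
  expect_equal(st$v, v, tolerance = 1e-12)

  # crossing the threshold emits a spike, resets to rest, and adaptation jumps
  st <- list(v = 0.99, w = 0, refrac = 0)
  out <- step_soma(st, v_d = -1e3, I_total = 0.2, p0)
  expect_true(out$spike)
  expect_equal(out$state$v, p0$E_L)
  expect_equal(out$state$refrac, p0$refrac)
  expect_lt(out$state$w, 0)   # b_s < 0: hyperpolarizing adaptation
})

test_that("refractoriness separates spikes by more than tau_r", {
  st <- list(v = 0, w = 0, refrac = 0)
  spikes <- c()
  for (t in 1:200) {
    out <- step_soma(st, v_d = -1e3, I_total = 0.5, p0)  # strong drive
    st <- out$state
    # freeze adaptation so the drive stays suprathreshold
    st$w <- 0
    if (out$spike) spikes <- c(spikes, t)
  }
  expect_gt(length(spikes), 5)
  expect_true(all(diff(spikes) > p0$refrac))
})

test_that("BAP boxcar hits the dendrite exactly 1 and 2 ms after a somatic spike", {
  k <- compinhib:::scaled_constants(p0)
  st <- list(v = 0, w = 0)
  # spike at step 1: lag-1 indicator is active at step 2, lag-2 at step 3
  lags1 <- c(0, 1, 0, 0, 0)
  lags2 <- c(0, 0, 1, 0, 0)
  vs <- numeric(5)
  for (t in 1:5) {
    st <- step_dendrite(st, lags1[t], lags2[t], I_total = 0, p0)$state
    vs[t] <- st$v
  }
  # without regenerative feedback at rest the first bump appears at step 2
  expect_equal(vs[1], p0$dt * k$gd * dendritic_nonlinearity(0, p0$dend$E_d, p0$dend$D_d),
               tolerance = 1e-10)
  expect_gt(vs[2], vs[1] + 0.5 * p0$dt * k$cd)
  expect_gt(vs[3], vs[2])       # second boxcar step still injecting
  expect_lt(vs[5], vs[3])       # decays after the boxcar ends
})

test_that("dendritic plateau dynamics match a fine-step independent integrator", {
  skip_if_not_installed("deSolve")
  # subthreshold-to-plateau trajectory of the smooth 2-D dendrite ODE
  k <- compinhib:::scaled_constants(p0)
  I <- 0.12
  rhs <- function(t, y, parms) {
    fd <- 1 / (1 + exp(-(y[1] - p0$dend$E_d) / p0$dend$D_d))
    dv <- -y[1] / p0$dend$tau + k$gd * fd + y[2] + I
    dw <- (-y[2] + k$kad * y[1]) / p0$dend$tau_w
    list(c(dv, dw))
  }
  fine <- deSolve::ode(c(v = 0.5, w = 0), seq(0, 40, by = 1), rhs, NULL,
                       method = "ode45")
  st <- list(v = 0.5, w = 0)
  coarse <- numeric(40)
  for (t in 1:40) {
    st <- step_dendrite(st, 0, 0, I_total = I, p0)$state
    coarse[t] <- st$v
  }
  # Euler at dt = 1 tracks the true trajectory to within a few percent of range
  expect_lt(max(abs(coarse - fine[-1, "v"])), 0.07 * diff(range(fine[, "v"])))
})

test_that("interneuron matches LIF closed forms (steady state and ISI)", {
  # subthreshold: v converges to I * tau
  I <- 0.05
  st <- list(v = 0, refrac = 0)
  for (t in 1:10000) st <- step_interneuron(st, I, p0, dt = 0.01)$state
  expect_equal(st$v, I * p0$inter$tau, tolerance = 1e-3)
  expect_false(step_interneuron(st, I, p0, dt = 0.01)$spike)

  # suprathreshold: inter-spike interval matches tau * log(vinf / (vinf - 1)) + refrac
  I <- 0.2
  vinf <- I * p0$inter$tau
  isi_true <- p0$inter$tau * log(vinf / (vinf - p0$theta)) + p0$refrac
  st <- list(v = 0, refrac = 0)
  spikes <- c()
  dt <- 0.01
  for (t in 1:20000) {
    out <- step_interneuron(st, I, p0, dt = dt)
    st <- out$state
    if (out$spike) spikes <- c(spikes, t * dt)
  }
  expect_equal(mean(diff(spikes)), isi_true, tolerance = 0.01)
})

test_that("OU background has the stationary mean and variance of its parameterization", {
  set.seed(42)
  tau <- 10; mu <- 100; sigma <- 40
  n <- 2e5
  x <- numeric(n); x[1] <- mu
  noise <- rnorm(n)
  for (t in 2:n) x[t] <- step_ou(x[t - 1], mu, sigma, tau, dt = 1, noise[t])
  expect_equal(mean(x), mu, tolerance = 0.02)
  # exact discrete-time stationary variance of the Euler-Maruyama chain,
  # which converges to sigma^2 * tau / 2 as dt -> 0
  a <- 1 - 1 / tau
  expect_equal(var(x), sigma^2 / (1 - a^2), tolerance = 0.05)
  expect_equal(sigma^2 / (1 - a^2), sigma^2 * tau / 2, tolerance = 0.06)
  # sigma = 0: deterministic monotone relaxation to mu
  y <- 0
  ys <- numeric(50)
  for (t in 1:50) { y <- step_ou(y, mu, 0, tau, 1, 0); ys[t] <- y }
  expect_true(all(diff(ys) > 0))
  expect_equal(step_ou(mu, mu, 0, tau, 1, 0), mu)
  expect_error(step_ou(0, 0, 1, -1, 1, 0), "OU time constant")
})

test_that("STP fixed point, depression, and U = 0 facilitation behave as derived", {
  pars <- list(U = 0.5, F = 0, tau_u = 100, tau_R = 20)
  st <- list(u = 0.5, R = 1)
  # no spikes: u stays at U, R at 1, release scale U
  out <- step_stp(st, 0, pars)
  expect_equal(out$state$u, 0.5, tolerance = 1e-12)
  expect_equal(out$state$R, 1)
  expect_equal(out$mu, 0.5)

  # two spikes 10 ms apart, F = 0: second release strictly weaker (depression)
  rel <- stp_brute_force(c(1, 11), U = 0.5, F = 0, tau_u = 100, tau_R = 20)
  expect_lt(rel[2], rel[1])

  # U = 0: the synapse transmits purely through facilitation; every release
  # stays well below full (residual facilitation, never complete release)
  rel0 <- stp_brute_force(c(1, 11, 21), U = 0, F = 0.3, tau_u = 100, tau_R = 20)
  expect_equal(rel0[1], 0.3)   # only the spike's own facilitation
  expect_true(all(rel0 > 0) && all(rel0 < 1))

  expect_error(step_stp(list(u = 0, R = 1), 1, list(U = 1.5, F = 0, tau_u = 1, tau_R = 1)),
               "U must lie")
})

test_that("STP state stays in [0,1] for random trains and forgets after long silence", {
  set.seed(7)
  for (rep in 1:20) {
    pars <- list(U = runif(1), F = runif(1), tau_u = runif(1, 10, 300),
                 tau_R = runif(1, 5, 200))
    st <- list(u = pars$U, R = 1)
    train <- runif(300) < 0.2
    for (s in train) {
      out <- step_stp(st, as.numeric(s), pars)
      st <- out$state
      expect_true(all(st$u >= 0 & st$u <= 1))
      expect_true(all(st$R >= 0 & st$R <= 1))
      expect_true(out$mu >= 0 && out$mu <= 1)
    }
    # silence of 10 * max(tau): next release scale returns to the rest value
    for (k in seq_len(10 * max(pars$tau_u, pars$tau_R))) {
      st <- step_stp(st, 0, pars)$state
    }
    rest <- step_stp(list(u = pars$U, R = 1), 1, pars)$mu
    expect_equal(step_stp(st, 1, pars)$mu, rest, tolerance = 1e-3)
  }
})

test_that("a U = 0 synapse never reaches full release on the first spike", {
  for (F in c(0.1, 0.5, 0.9)) {
    out <- step_stp(list(u = 0, R = 1), 1, list(U = 0, F = F, tau_u = 100, tau_R = 20))
    expect_equal(out$mu, F)    # only the spike's own facilitation contributes
    expect_lt(out$mu, 1)
  }
})

test_that("synaptic trace decays exponentially and accumulates spikes linearly", {
  tau <- 10
  s <- 1
  for (t in 1:2000) s <- step_synaptic_trace(s, 0, tau, dt = 0.01)
  expect_equal(s, exp(-2), tolerance = 5e-3)   # 20 ms of decay at tau = 10
  expect_equal(step_synaptic_trace(0, 1, tau), 1)
  # steady-state mean of a filtered spike train: rate * tau (filtered Poisson)
  set.seed(3)
  rate <- 0.05  # per ms
  s <- 0; acc <- 0; n <- 5e4
  for (t in 1:n) {
    s <- step_synaptic_trace(s, rbinom(1, 1, rate), tau)
    acc <- acc + s
  }
  expect_equal(acc / n, rate * tau, tolerance = 0.1)
  expect_error(step_synaptic_trace(0, 0, -1), "trace time constant")
})

test_that("halving dt changes subthreshold trajectories by O(dt) (Euler order)", {
  p <- default_params()
  I <- 0.03
  run <- function(dt) {
    st <- list(v = 0, refrac = 0)
    for (t in seq_len(20 / dt)) st <- step_interneuron(st, I, p, dt = dt)$state
    st$v
  }
  v_ref <- I * p$inter$tau * (1 - exp(-20 / p$inter$tau))
  e1 <- abs(run(0.2) - v_ref)
  e2 <- abs(run(0.1) - v_ref)
  expect_lt(e2, 0.6 * e1)   # first-order convergence: error halves with dt
})

test_that("surrogate spike derivative peaks at threshold and is even in v - theta", {
  expect_equal(surrogate_spike_derivative(1, 1, 10), 1)
  expect_equal(surrogate_spike_derivative(100, 1, 10), 0, tolerance = 1e-5)
  d <- runif(5)
  expect_equal(surrogate_spike_derivative(1 + d, 1, 10),
               surrogate_spike_derivative(1 - d, 1, 10))
})
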