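test_that("double-exponential waveforms start at zero, peak at gmax and stay non-negative", {
  syn <- nml_double_exp_synapse("s", gmax = 2, erev = 0, rise = 0.5,
                                decays = data.frame(tau = 4, fraction = 1))
  expect_equal(conductance_at(syn, 0), 0)
  expect_equal(conductance_at(syn, -1), 0)
  t <- seq(0, 40, by = 0.001)
  g <- conductance_at(syn, t)
  expect_true(all(g >= 0))
  expect_equal(max(g), 2, tolerance = 1e-6)

  inst <- nml_double_exp_synapse("s", gmax = 3, erev = 0, rise = 0,
                                 decays = data.frame(tau = 5, fraction = 1))
  expect_equal(conductance_at(inst, 0), 3)
})

test_that("the single-decay peak time matches the closed form", {
  tr <- 0.7; td <- 6
  syn <- nml_double_exp_synapse("s", gmax = 1, erev = 0, rise = tr,
                                decays = data.frame(tau = td, fraction = 1))
  t_star <- tr * td / (td - tr) * log(td / tr)
  # dense-grid maximization oracle
  t <- seq(0, 30, by = 1e-4)
  g <- conductance_at(syn, t)
  expect_equal(t[which.max(g)], t_star, tolerance = 1e-3)
  expect_equal(conductance_at(syn, t_star), 1, tolerance = 1e-9)
})

test_that("rise equal to decay degenerates to the alpha function", {
  syn <- nml_double_exp_synapse("s", gmax = 1, erev = 0, rise = 3,
                                decays = data.frame(tau = 3, fraction = 1))
  t <- seq(0, 30, by = 0.001)
  g <- conductance_at(syn, t)
  expect_equal(max(g), 1, tolerance = 1e-6)
  expect_equal(t[which.max(g)], 3, tolerance = 1e-2)  # alpha peaks at tau
})

test_that("multi-component decays honour their fractional amplitudes", {
  syn <- nml_double_exp_synapse("s", gmax = 1, erev = 0, rise = 0,
                                decays = data.frame(tau = c(2, 20),
                                                    fraction = c(0.7, 0.3)))
  expect_equal(conductance_at(syn, 0), 1)
  expect_equal(conductance_at(syn, 10),
               0.7 * exp(-5) + 0.3 * exp(-0.5), tolerance = 1e-12)
  expect_error(nml_double_exp_synapse("s", 1, 0, 0,
                                      decays = data.frame(tau = c(2, 20),
                                                          fraction = c(0.7, 0.7))),
               "sum to 1")
})

test_that("magnesium block is 1 without magnesium and monotone in voltage", {
  b0 <- nml_mg_block(mg_concentration = 0)
  v <- seq(-90, 60, by = 5)
  expect_equal(mg_block_factor(b0, v), rep(1, length(v)))
  b <- nml_mg_block(mg_concentration = 1, eta = 0.33, gamma = 0.06)
  f <- mg_block_factor(b, v)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f <= 1))
  # direct substitution at v = 0
  expect_equal(mg_block_factor(b, 0), 1 / (1 + 0.33), tolerance = 1e-12)
  expect_lt(mg_block_factor(b, -200), 1e-3)
})

test_that("STP with both time constants zero reproduces the base synapse on every spike", {
  base <- nml_double_exp_synapse("b", 1, 0, 0.5,
                                 data.frame(tau = 5, fraction = 1))
  syn <- nml_stp_synapse(base, U = 0.5, tau_rec = 0, tau_fac = 0)
  s <- stp_state(syn)
  scales <- numeric(10)
  for (i in 1:10) {
    r <- stp_on_spike(syn, s, i * 10)
    scales[i] <- r$scale
    s <- r$state
  }
  expect_equal(scales, rep(1, 10))
})

test_that("the depressing configuration yields strictly non-increasing releases", {
  base <- nml_double_exp_synapse("b", 1, 0, 0.5,
                                 data.frame(tau = 5, fraction = 1))
  syn <- nml_stp_synapse(base, U = 0.5, tau_rec = 120, tau_fac = 0)
  s <- stp_state(syn)
  rel <- numeric(12)
  for (i in 1:12) {
    r <- stp_on_spike(syn, s, i * 25)  # train faster than recovery
    rel[i] <- r$release
    s <- r$state
    expect_true(r$release >= 0 && r$release <= 1)
  }
  expect_true(all(diff(rel) < 0))
})

test_that("the facilitating configuration yields non-decreasing releases", {
  base <- nml_double_exp_synapse("b", 1, 0, 0.5,
                                 data.frame(tau = 5, fraction = 1))
  syn <- nml_stp_synapse(base, U = 0.2, tau_rec = 0, tau_fac = 300)
  s <- stp_state(syn)
  rel <- numeric(12)
  for (i in 1:12) {
    r <- stp_on_spike(syn, s, i * 25)
    rel[i] <- r$release
    s <- r$state
  }
  expect_true(all(diff(rel) >= 0))
})

test_that("periodic depression settles at the fixed point of the resource map", {
  U <- 0.4; tau_rec <- 120; period <- 30
  base <- nml_double_exp_synapse("b", 1, 0, 0.5,
                                 data.frame(tau = 5, fraction = 1))
  syn <- nml_stp_synapse(base, U = U, tau_rec = tau_rec, tau_fac = 0)
  # oracle: iterate the between/at-spike update map to convergence
  em <- exp(-period / tau_rec)
  x <- 1
  for (i in 1:500) x <- 1 - (1 - x * (1 - U)) * em
  # closed-form fixed point of x_{n+1} = 1 - (1 - x_n (1 - U)) e^-T/tau
  x_star <- (1 - em) / (1 - (1 - U) * em)
  expect_equal(x, x_star, tolerance = 1e-12)

  s <- stp_state(syn)
  rel <- NA
  for (i in 1:500) {
    r <- stp_on_spike(syn, s, i * period)
    rel <- r$release
    s <- r$state
  }
  expect_equal(rel, U * x_star, tolerance = 1e-9)
})

test_that("STP state errors on non-increasing spike times", {
  base <- nml_double_exp_synapse("b", 1, 0, 0.5,
                                 data.frame(tau = 5, fraction = 1))
  syn <- nml_stp_synapse(base, 0.5, 120, 0)
  s <- stp_on_spike(syn, stp_state(syn), 10)$state
  expect_error(stp_on_spike(syn, s, 10), "strictly increasing")
})

test_that("STDP potentiates pre-before-post and leaves lone spikes alone", {
  syn <- nml_stdp_synapse(w_max = 1, A_plus = 0.01, A_minus = 0.012,
                          tau_plus = 20, tau_minus = 20, w0 = 0.5)
  s <- stdp_state(syn)
  s <- stdp_on_pre(syn, s, 10)
  expect_equal(s$w, 0.5)  # single pre, no post
  s2 <- stdp_on_post(syn, s, 10 + 1e-9)
  expect_equal(s2$w, 0.5 + 0.01, tolerance = 1e-6)  # maximal potentiation
  # post then pre depresses
  s3 <- stdp_state(syn)
  s3 <- stdp_on_post(syn, s3, 10)
  s3 <- stdp_on_pre(syn, s3, 15)
  expect_equal(s3$w, 0.5 - 0.012 * exp(-5 / 20) * 1, tolerance = 1e-9)
})

test_that("trace-based STDP equals the brute-force pairwise replay on random trains", {
  # naive O(n^2) oracle: every opposite-stream pair contributes an
  # exponential term; clipping applied event by event in time order
  brute <- function(syn, events) {
    w <- syn$w0
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      earlier <- events[seq_len(i - 1L), , drop = FALSE]
      if (e$kind == "post") {
        pre <- earlier$t[earlier$kind == "pre"]
        w <- w + syn$A_plus * syn$w_max * sum(exp(-(e$t - pre) /
                                                    syn$tau_plus))
      } else {
        post <- earlier$t[earlier$kind == "post"]
        w <- w - syn$A_minus * syn$w_max * sum(exp(-(e$t - post) /
                                                     syn$tau_minus))
      }
      w <- min(max(w, 0), syn$w_max)
    }
    w
  }
  syn <- nml_stdp_synapse(w_max = 2, A_plus = 0.03, A_minus = 0.035,
                          tau_plus = 17, tau_minus = 34, w0 = 1)
  for (seed in 1:5) {
    set.seed(seed)
    events <- data.frame(
      t = sort(stats::runif(60, 0, 500)),
      kind = sample(c("pre", "post"), 60, replace = TRUE))
    s <- stdp_state(syn)
    for (i in seq_len(nrow(events))) {
      s <- if (events$kind[i] == "pre") stdp_on_pre(syn, s, events$t[i])
      else stdp_on_post(syn, s, events$t[i])
      expect_true(s$w >= 0 && s$w <= syn$w_max)
    }
    expect_equal(s$w, brute(syn, events), tolerance = 1e-9)
  }
})

test_that("gap junction currents are ohmic and antisymmetric", {
  gj <- nml_gap_junction("gj", conductance = 3e-4)  # 300 pS in uS
  expect_equal(gap_current(gj, -60, -60), 0)
  # 300 pS x 10 mV = 3 pA = 3e-3 nA, by unit arithmetic
  expect_equal(gap_current(gj, -70, -60), 3e-3)
  set.seed(3)
  va <- stats::runif(50, -80, 40); vb <- stats::runif(50, -80, 40)
  expect_equal(gap_current(gj, va, vb) + gap_current(gj, vb, va),
               rep(0, 50))
})
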