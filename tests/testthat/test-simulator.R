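test_that("a single-cable cell with 4 divisions builds 4 compartments with the right links", {
  fx <- generate_fixture("ball-and-stick", divisions = 4L)
  cfg <- solver_config(symmetry = "symmetric")
  g <- build_graph(fx$document, config = cfg)
  dend <- g$comps[g$comps$cable == "dend_cable", ]
  expect_equal(nrow(dend), 4)
  # symmetric link = sum of the two half-resistances
  i <- dend$comp[2]
  p <- g$parent[i]
  expect_equal(g$link_res[i],
               (g$comps$r_axial[i] + g$comps$r_axial[p]) / 2)
  ga <- build_graph(fx$document,
                    config = solver_config(symmetry = "asymmetric"))
  expect_equal(ga$link_res[i], ga$comps$r_axial[i])
})

test_that("total graph membrane area equals the morphology surface area", {
  fx <- generate_fixture("ball-and-stick", divisions = 16L)
  g <- build_graph(fx$document)
  morph <- fx$document$cells[[1]]$morphology
  # direct frusta-area sum plus the spherical soma
  dend_area <- oracle_frustum_area(100, 1, 1)
  soma_area <- pi * 20^2
  expect_equal(sum(g$comps$area), dend_area + soma_area, tolerance = 1e-9)
  expect_equal(sum(g$comps$area[g$comps$cable == "dend_cable"]),
               cableml:::cable_area(morph, "dend_cable"),
               tolerance = 1e-9)
})

test_that("non-uniform densities are evaluated at compartment centre path distances", {
  fx <- generate_fixture("ball-and-stick", divisions = 5L)
  doc <- fx$document
  doc$cells[[1]]$placements[[2]] <- list(
    channel = "kdr",
    vp = nml_variable_parameter("gmax", "1 + 0.5 * d",
                                groups = "dendrite_group"),
    groups = "dendrite_group")
  g <- build_graph(doc)
  kdr <- NULL
  for (m in g$mechanisms)
    if (m$channel$id == "kdr" && length(m$comps) == 5) kdr <- m
  centres <- g$comps$centre_d[match(kdr$comps, g$comps$comp)]
  expect_equal(centres, c(10, 30, 50, 70, 90))
  expect_equal(kdr$gmax_abs,
               (1 + 0.5 * centres) * 1e-5 *
                 g$comps$area[match(kdr$comps, g$comps$comp)],
               tolerance = 1e-12)
})

test_that("a passive compartment charges like the analytic RC circuit", {
  # membrane values from the voltage-clamp protocols: leak 3.0e-9 mS/um2
  # (0.3 mS/cm2), capacitance 1e-8 uF/um2 (1 uF/cm2) -> tau = c/g = 10/3 ms
  fx <- generate_fixture("passive-pair-gap-junction")
  run_at <- function(dt) {
    g <- build_graph(fx$document, cells = "cellA",
                     config = solver_config(dt = dt))
    stim <- nml_stimulus("current-pulse", comp = 1, amplitude = 0.19,
                         delay = 0, duration = Inf)
    rec <- run_simulation(g, list(stim), duration = 25)
    area <- g$comps$area[1]
    gl <- 0.3e-5 * area; cm <- 1e-5 * area
    analytic <- -65 + 0.19 / gl * (1 - exp(-rec$time / (cm / gl)))
    list(err = max(abs(rec$v[, 1] - analytic)), tau = cm / gl)
  }
  r1 <- run_at(0.02)
  expect_equal(r1$tau, 10 / 3, tolerance = 1e-6)
  expect_lt(r1$err, 0.05)  # mV
  # first-order method: error shrinks linearly as dt halves
  r2 <- run_at(0.01); r3 <- run_at(0.005)
  expect_gt(r1$err / r2$err, 1.6)
  expect_lt(r1$err / r2$err, 2.4)
  expect_gt(r2$err / r3$err, 1.6)
  expect_lt(r2$err / r3$err, 2.4)
})

test_that("the second-order option converges faster than first order", {
  fx <- generate_fixture("passive-pair-gap-junction")
  err_at <- function(dt, method) {
    g <- build_graph(fx$document, cells = "cellA",
                     config = solver_config(dt = dt, method = method))
    stim <- nml_stimulus("current-pulse", comp = 1, amplitude = 0.19,
                         delay = 0, duration = Inf)
    rec <- run_simulation(g, list(stim), duration = 25)
    area <- g$comps$area[1]
    gl <- 0.3e-5 * area; cm <- 1e-5 * area
    analytic <- -65 + 0.19 / gl * (1 - exp(-rec$time / (cm / gl)))
    max(abs(rec$v[, 1] - analytic))
  }
  e1 <- err_at(0.02, "semi-implicit-second-order")
  e2 <- err_at(0.01, "semi-implicit-second-order")
  expect_gt(e1 / e2, 3.2)  # ~ 4x for a second-order scheme
  expect_lt(e1, err_at(0.02, "implicit-first-order"))
})

test_that("with no stimulus at the resting potential the voltage stays constant", {
  fx <- generate_fixture("passive-pair-gap-junction")
  doc <- fx$document
  g <- build_graph(doc, cells = "cellA")
  rec <- run_simulation(g, list(), duration = 10)
  expect_equal(unique(as.numeric(rec$v)), -65)
})

test_that("identical inputs and seed give bit-identical recordings", {
  fx <- generate_fixture("hh-point-cell")
  g <- build_graph(fx$document, config = solver_config(dt = 0.01, seed = 9))
  stim <- list(nml_stimulus("continuous-random-current", comp = 1,
                            range = c(0.05, 0.15), id = "noise"),
               nml_stimulus("current-pulse", comp = 1, amplitude = 0.05,
                            delay = 5, duration = 20))
  r1 <- run_simulation(g, stim, duration = 40)
  r2 <- run_simulation(g, stim, duration = 40)
  expect_identical(r1$v, r2$v)
  # a different seed changes the noise stream
  g2 <- build_graph(fx$document, config = solver_config(dt = 0.01,
                                                        seed = 10))
  r3 <- run_simulation(g2, stim, duration = 40)
  expect_false(identical(r1$v, r3$v))
})

test_that("spike counts converge as the time step is refined", {
  fx <- generate_fixture("hh-point-cell")
  spikes_at <- function(dt) {
    g <- build_graph(fx$document, config = solver_config(dt = dt))
    stim <- nml_stimulus("current-pulse", comp = 1, amplitude = 0.1,
                         delay = 10, duration = Inf)
    rec <- run_simulation(g, list(stim), duration = 100)
    detect_spikes(rec$v[, 1], time = rec$time)
  }
  dts <- c(0.02, 0.01, 0.005, 0.002)
  trains <- lapply(dts, spikes_at)
  counts <- lengths(trains)
  expect_equal(length(unique(counts)), 1)  # same count at dt and dt/2 etc.
  # discrepancy between consecutive refinements shrinks monotonically
  disc <- vapply(seq_len(3), function(i)
    compare_runs(trains[[i]], trains[[i + 1]],
                 100)$max_discrepancy_percent, 0)
  expect_true(all(diff(disc) < 0))
})

test_that("the voltage clamp holds quietly at the leak reversal and scales AMPA EPSCs ohmically", {
  fx <- generate_fixture("ampa-nmda-clamp-cell")
  g <- build_graph(fx$document, config = solver_config(dt = 0.01))
  # clamped at E_leak with no input: current settles to zero
  rec0 <- run_voltage_clamp(g, comp = 1, holding = -65, duration = 20)
  expect_lt(abs(rec0$i_clamp[length(rec0$i_clamp)]), 1e-9)

  ampa <- fx$document$synapses[["ampa"]]
  peak_at <- function(h) {
    rec <- run_voltage_clamp(g, comp = 1, holding = h, synapse = ampa,
                             event_times = 10, duration = 60)
    base <- rec$i_clamp[max(which(rec$time <= 10))]
    max(abs(rec$i_clamp[rec$time > 10 & rec$time < 59] - base))
  }
  # linear-ohmic proportionality: driving forces -80-0 vs -20-0
  expect_equal(peak_at(-80) / peak_at(-20), 80 / 20, tolerance = 1e-3)
})

test_that("the NMDA block inverts the driving-force relation between -80 and -20 mV", {
  fx <- generate_fixture("ampa-nmda-clamp-cell")
  g <- build_graph(fx$document, config = solver_config(dt = 0.01))
  nmda <- fx$document$synapses[["nmda"]]
  peak_at <- function(h) {
    rec <- run_voltage_clamp(g, comp = 1, holding = h, synapse = nmda,
                             event_times = 10, duration = 100)
    base <- rec$i_clamp[max(which(rec$time <= 10))]
    max(abs(rec$i_clamp[rec$time > 10 & rec$time < 99] - base))
  }
  p80 <- peak_at(-80); p20 <- peak_at(-20)
  expect_gt(p20, p80)
  # oracle: block factor x driving force at both potentials
  b <- nmda$mg_block
  ratio_oracle <- (mg_block_factor(b, -20) * 20) /
    (mg_block_factor(b, -80) * 80)
  expect_equal(p20 / p80, ratio_oracle, tolerance = 0.05)
})

test_that("two passive cells coupled by a gap junction settle at the linear-system solution", {
  fx <- generate_fixture("passive-pair-gap-junction")
  g <- build_graph(fx$document, cells = c("cellA", "cellB"),
                   config = solver_config(dt = 0.01))
  gc <- fx$document$synapses[["gj300"]]$conductance
  g <- add_gap_junction(g, 1, 2, gc)
  stim <- nml_stimulus("current-pulse", comp = 1, amplitude = 0.19,
                       delay = 0, duration = Inf)
  rec <- run_simulation(g, list(stim), duration = 80)
  v_end <- rec$v[nrow(rec$v), ]
  area <- g$comps$area[1]
  gl <- 0.3e-5 * area
  # steady-state conductance balance, solved directly
  A <- matrix(c(gl + gc, -gc, -gc, gl + gc), 2, byrow = TRUE)
  v_star <- solve(A, c(gl * -65 + 0.19, gl * -65))
  expect_equal(v_end, v_star, tolerance = 1e-6)
  # coupled cell is depolarized but less than the injected cell
  expect_gt(v_end[1], v_end[2])
  expect_gt(v_end[2], -65)
  # coupling currents cancel exactly at every recorded step
  gj <- nml_gap_junction("g", gc)
  ia <- gap_current(gj, rec$v[, 1], rec$v[, 2])
  ib <- gap_current(gj, rec$v[, 2], rec$v[, 1])
  expect_equal(ia + ib, rep(0, length(ia)))
})

test_that("spike detection interpolates crossings and matches a naive scan", {
  expect_length(detect_spikes(rep(-65, 100), dt = 0.1), 0)
  # triangle crossing 0 mV once between samples 10 and 11
  tri <- c(seq(-20, 20, length.out = 21), seq(18, -20, length.out = 20))
  sp <- detect_spikes(tri, dt = 1)
  expect_length(sp, 1)
  expect_equal(as.numeric(sp), 10)  # crosses exactly at sample 10
  shifted <- tri + 1  # crossing now between samples, interpolated
  sp2 <- detect_spikes(shifted, dt = 1, threshold = 0)
  expect_equal(as.numeric(sp2), 9.5, tolerance = 1e-9)

  set.seed(21)
  noisy <- as.numeric(stats::filter(stats::rnorm(2000), rep(0.2, 12),
                                    sides = 1))
  noisy[is.na(noisy)] <- 0
  got <- detect_spikes(noisy, dt = 0.05, threshold = 0.4)
  # brute-force oracle scan
  want <- c()
  for (i in seq_len(length(noisy) - 1))
    if (noisy[i] < 0.4 && noisy[i + 1] >= 0.4) {
      t0 <- (i - 1) * 0.05
      want <- c(want, t0 + (0.4 - noisy[i]) / (noisy[i + 1] - noisy[i]) *
                  0.05)
    }
  expect_equal(as.numeric(got), want)
})

test_that("compare_runs implements the percent-of-run-time criterion", {
  expect_equal(compare_runs(c(10, 50), c(10, 50),
                            200)$max_discrepancy_percent, 0)
  # spikes at 200 ms differing by 1 ms over a 200 ms run = exactly 0.5 %
  r <- compare_runs(c(200), c(199), 200)
  expect_true(r$same_count)
  expect_equal(r$max_discrepancy_percent, 0.5)
  # count mismatch is reported, not raised
  r2 <- compare_runs(c(1, 2, 3), c(1, 2), 100)
  expect_false(r2$same_count)
  set.seed(4)
  a <- sort(stats::runif(20, 0, 500))
  b <- a + stats::rnorm(20, 0, 0.3)
  r3 <- compare_runs(a, b, 500)
  expect_equal(r3$max_discrepancy_percent,
               100 * max(abs(a - b)) / 500)  # direct max oracle
})

test_that("numeric blow-up raises a divergence error naming dt", {
  fx <- generate_fixture("hh-point-cell")
  g <- build_graph(fx$document, config = solver_config(dt = 0.01))
  stim <- nml_stimulus("current-pulse", comp = 1, amplitude = 1e7,
                       delay = 0, duration = Inf)
  expect_error(run_simulation(g, list(stim), duration = 5), "divergence")
})

test_that("integrate-and-fire cells spike, reset and respect refractoriness", {
  fx <- generate_fixture("stp-pair")
  g <- build_graph(fx$document, cells = "pre_cell",
                   config = solver_config(dt = 0.01))
  rec <- run_simulation(g, list(), duration = 100)
  sp <- g$iafs  # spikes live in the recordings
  train <- rec$spikes[[1]]
  expect_gt(length(train), 2)
  expect_true(all(diff(train) >= 2))  # refractory period 2 ms
  expect_true(all(rec$v[, 1] <= -49.9))
})
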