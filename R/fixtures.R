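#' Built-in model fixtures
#'
#' Self-validating NeuroML documents exercising every part of the package,
#' generated in code so no downloads are needed. Each fixture also returns
#' a companion protocol description (stimuli, clamp levels, run time)
#' mirroring the classic cross-simulator test configurations: a point cell
#' with squid Hodgkin-Huxley kinetics, a ball-and-stick cell, a pair of
#' passive cells coupled by a 300 pS gap junction driven by a 0.19 nA
#' step, a voltage-clamped cell receiving AMPA- or NMDA-type input at -80
#' and -20 mV holding potentials, an integrate-and-fire pair connected by
#' a short-term-plasticity synapse (depressing: tau_rec 120 ms, tau_fac 0;
#' facilitating: tau_rec 0, tau_fac 300 ms; control: both 0), and a
#' reduced Layer 2/3 network skeleton of 56 cells in five populations
#' (20 regular-spiking and 6 fast-rhythmic-bursting pyramidal cells, 10
#' low-threshold-spiking, 10 axo-axonic and 10 basket interneurons)
#' placed at random in a cylindrical region, with electrical coupling
#' within each population (2.1 nS) and the original random current
#' drives. The network fixture uses placeholder point-cell dynamics: the
#' full multi-conductance kinetics live in external model files and are
#' out of scope here.
#'
#' @param name fixture name: `"hh-point-cell"`, `"ball-and-stick"`,
#'   `"passive-pair-gap-junction"`, `"ampa-nmda-clamp-cell"`,
#'   `"stp-pair"`, `"reduced-L23-network"`.
#' @param seed integer seed recorded in template networks.
#' @param divisions dendrite `internal_divisions` for `"ball-and-stick"`.
#' @param stp_mode `"control"`, `"depression"` or `"facilitation"` for
#'   `"stp-pair"`.
#' @return list with elements `document` (an [nml_document()]) and
#'   `protocol` (named list describing the companion stimulation).
#' @export
generate_fixture <- function(name = c("hh-point-cell", "ball-and-stick",
                                      "passive-pair-gap-junction",
                                      "ampa-nmda-clamp-cell", "stp-pair",
                                      "reduced-L23-network"),
                             seed = 1L, divisions = 32L,
                             stp_mode = c("control", "depression",
                                          "facilitation")) {
  name <- match.arg(name)
  switch(name,
         "hh-point-cell" = fixture_hh_point(),
         "ball-and-stick" = fixture_ball_stick(divisions),
         "passive-pair-gap-junction" = fixture_gap_pair(),
         "ampa-nmda-clamp-cell" = fixture_clamp_cell(),
         "stp-pair" = fixture_stp_pair(match.arg(stp_mode)),
         "reduced-L23-network" = fixture_l23(seed))
}

# classic squid-axon Hodgkin-Huxley kinetics (rates in 1/ms, voltages mV,
# resting potential convention -65 mV); fixture values, not figure values
hh_channels <- function() {
  exp_law <- function(A, k, d) nml_rate_law("exponential", A = A, k = k, d = d)
  sig_law <- function(A, k, d) nml_rate_law("sigmoid", A = A, k = k, d = d)
  lin_law <- function(A, k, d) nml_rate_law("exp_linear", A = A, k = k, d = d)
  na <- nml_channel("na", gmax_density = 120, erev = 50, ion = "na",
    gates = list(
      nml_gate("m", 3,
               forward = lin_law(1, 0.1, -40),
               backward = exp_law(4, -1 / 18, -65)),
      nml_gate("h", 1,
               forward = exp_law(0.07, -1 / 20, -65),
               backward = sig_law(1, -0.1, -35))))
  k <- nml_channel("kdr", gmax_density = 36, erev = -77, ion = "k",
    gates = list(
      nml_gate("n", 4,
               forward = lin_law(0.1, 0.1, -55),
               backward = exp_law(0.125, -1 / 80, -65))))
  leak <- nml_channel("leak", gmax_density = 0.3, erev = -54.3,
                      passive = TRUE)
  list(na = na, kdr = k, leak = leak)
}

sphere_cell <- function(id, diameter, groups = "soma_group",
                        internal_divisions = 1L) {
  p <- nml_point(0, 0, 0, diameter)
  nml_cell(id,
           segments = list(nml_segment("soma", distal = p, proximal = p,
                                       cable = "soma_cable")),
           cables = list(nml_cable("soma_cable", "soma",
                                   groups = groups,
                                   internal_divisions = internal_divisions)))
}

fixture_metadata <- function(comment) {
  nml_metadata(
    authors = list(list(name = "cableml fixture generator",
                        institution = NA_character_)),
    comments = comment,
    status = list(value = "stable", notes = "generated test fixture"))
}

fixture_hh_point <- function() {
  morph <- sphere_cell("hhcell", diameter = 20)
  cell <- nml_biophysical_cell(
    morph, specific_capacitance = 1, axial_resistivity = 0.1,
    placements = list(
      list(channel = "na", density = 120, groups = "all"),
      list(channel = "kdr", density = 36, groups = "all"),
      list(channel = "leak", density = 0.3, groups = "all")),
    init_potential = -65)
  doc <- nml_document(level = 2, metadata = fixture_metadata(
    "single-compartment cell with squid Hodgkin-Huxley kinetics"),
    cells = list(cell), channels = unname(hh_channels()))
  list(document = doc,
       protocol = list(kind = "current-pulse", amplitude = 0.1,
                       delay = 10, duration = Inf, run_time = 100))
}

fixture_ball_stick <- function(divisions = 32L) {
  soma_d <- 20
  p_soma <- nml_point(0, 0, 0, soma_d)
  segs <- list(nml_segment("soma", distal = p_soma, proximal = p_soma,
                           cable = "soma_cable"))
  # 5 collinear 20 um segments, uniform 2 um diameter
  prev <- "soma"
  for (i in 1:5) {
    segs[[length(segs) + 1L]] <- nml_segment(
      paste0("dend", i), distal = nml_point(20 * i, 0, 0, 2),
      proximal = if (i == 1) nml_point(0, 0, 0, 2) else NULL,
      parent = prev, cable = "dend_cable")
    prev <- paste0("dend", i)
  }
  morph <- nml_cell("ballstick", segs, cables = list(
    nml_cable("soma_cable", "soma", groups = "soma_group"),
    nml_cable("dend_cable", "dendrite", groups = "dendrite_group",
              internal_divisions = divisions)))
  cell <- nml_biophysical_cell(
    morph, specific_capacitance = 1, axial_resistivity = 0.1,
    placements = list(
      list(channel = "na", density = 120, groups = "soma_group"),
      list(channel = "kdr", density = 36, groups = "soma_group"),
      list(channel = "leak", density = 0.3, groups = "all")),
    init_potential = -65)
  doc <- nml_document(level = 2, metadata = fixture_metadata(
    "ball-and-stick cell: HH soma, passive dendrite"),
    cells = list(cell), channels = unname(hh_channels()))
  list(document = doc,
       protocol = list(kind = "current-pulse", amplitude = 0.3,
                       delay = 5, duration = Inf, run_time = 200,
                       target_segment = "soma"))
}

fixture_gap_pair <- function() {
  # passive compartments with the voltage-clamp-protocol membrane values:
  # leak 3.0e-9 mS/um2 (= 0.3 mS/cm2), capacitance 1e-8 uF/um2 (= 1 uF/cm2)
  mk <- function(id) {
    morph <- sphere_cell(id, diameter = 56.419)  # area ~ 1e4 um2
    nml_biophysical_cell(
      morph, specific_capacitance = 1, axial_resistivity = 0.1,
      placements = list(list(channel = "leak", density = 0.3,
                             groups = "all")),
      init_potential = -65)
  }
  leak <- nml_channel("leak", gmax_density = 0.3, erev = -65,
                      passive = TRUE)
  gj <- nml_gap_junction("gj300", conductance = 3e-4)  # 300 pS in uS
  doc <- nml_document(level = 2, metadata = fixture_metadata(
    "pair of passive cells coupled by a 300 pS gap junction"),
    cells = list(mk("cellA"), mk("cellB")), channels = list(leak),
    synapses = list(gj))
  list(document = doc,
       protocol = list(kind = "current-pulse", amplitude = 0.19,
                       delay = 20, duration = 100, run_time = 150,
                       gap_conductance = 3e-4))
}

fixture_clamp_cell <- function() {
  morph <- sphere_cell("clampcell", diameter = 56.419)
  leak <- nml_channel("leak", gmax_density = 0.3, erev = -65,
                      passive = TRUE)
  cell <- nml_biophysical_cell(
    morph, specific_capacitance = 1, axial_resistivity = 0.1,
    placements = list(list(channel = "leak", density = 0.3,
                           groups = "all")),
    init_potential = -65,
    connectivity = list(list(synapse = "ampa", groups = "soma_group"),
                        list(synapse = "nmda", groups = "soma_group")))
  ampa <- nml_double_exp_synapse("ampa", gmax = 1e-3, erev = 0,
                                 rise = 0.2,
                                 decays = data.frame(tau = 2, fraction = 1))
  nmda <- nml_double_exp_synapse("nmda", gmax = 1e-3, erev = 0,
                                 rise = 3,
                                 decays = data.frame(tau = 40, fraction = 1),
                                 mg_block = nml_mg_block())
  doc <- nml_document(level = 3, metadata = fixture_metadata(
    "voltage-clamped passive cell with AMPA- and NMDA-type synapses"),
    cells = list(cell), channels = list(leak),
    synapses = list(ampa, nmda))
  list(document = doc,
       protocol = list(kind = "voltage-clamp",
                       holding = c(-80, -20), event_time = 10,
                       run_time = 120))
}

fixture_stp_pair <- function(mode = "control") {
  taus <- switch(mode,
                 control = c(tau_rec = 0, tau_fac = 0),
                 depression = c(tau_rec = 120, tau_fac = 0),
                 facilitation = c(tau_rec = 0, tau_fac = 300))
  mk <- function(id, e_leak) {
    morph <- sphere_cell(id, diameter = 20)
    nml_biophysical_cell(
      morph, specific_capacitance = 1, axial_resistivity = 0.1,
      placements = list(),
      init_potential = -65,
      iaf = nml_iaf(threshold = -50, reset = -65, refractory = 2,
                    g_leak = 0.01, e_leak = e_leak))
  }
  base <- nml_double_exp_synapse("stp_base", gmax = 1e-3, erev = 0,
                                 rise = 0.5,
                                 decays = data.frame(tau = 5, fraction = 1))
  stp <- nml_stp_synapse(base, U = 0.5, tau_rec = taus[["tau_rec"]],
                         tau_fac = taus[["tau_fac"]])
  doc <- nml_document(level = 3, metadata = fixture_metadata(
    paste0("integrate-and-fire pair with STP synapse (", mode, ")")),
    # presynaptic leak reversal just above threshold -> spontaneous firing
    cells = list(mk("pre_cell", e_leak = -49), mk("post_cell",
                                                  e_leak = -65)),
    synapses = list(stp))
  list(document = doc,
       protocol = list(kind = "stp", mode = mode, spike_period = 25,
                       n_spikes = 8, run_time = 250))
}

fixture_l23 <- function(seed = 1L) {
  # placeholder point cell standing in for the detailed cortical cells
  point <- nml_biophysical_cell(
    sphere_cell("point_cell", diameter = 20),
    specific_capacitance = 1, axial_resistivity = 0.1,
    placements = list(list(channel = "leak", density = 0.3,
                           groups = "all")),
    init_potential = -65,
    iaf = nml_iaf(threshold = -50, reset = -65, refractory = 2,
                  g_leak = 0.01, e_leak = -65))
  leak <- nml_channel("leak", gmax_density = 0.3, erev = -65,
                      passive = TRUE)
  gj <- nml_gap_junction("gap_within", conductance = 2.1e-3)  # 2.1 nS
  exc <- nml_double_exp_synapse("exc_syn", gmax = 4e-4, erev = 0,
                                rise = 0.5,
                                decays = data.frame(tau = 3, fraction = 1))
  region <- list(shape = "cylinder", x0 = 0, y0 = 0, z0 = 0,
                 radius = 300, height = 100)
  sizes <- c(RS = 20L, FRB = 6L, LTS = 10L, AxAx = 10L, Basket = 10L)
  pops <- lapply(names(sizes), function(nm)
    nml_template_population(nm, "point_cell", sizes[[nm]], region))
  inputs <- list(
    nml_network_input("frb_drive", "continuous-random-current", "FRB",
                      params = list(amplitude_range = c(0.15, 0.25))),
    nml_network_input("lts_drive", "continuous-random-current", "LTS",
                      params = list(amplitude_range = c(0, 0.2))),
    nml_network_input("axax_drive", "continuous-random-current", "AxAx",
                      params = list(amplitude_range = c(0, 0.02))),
    nml_network_input("basket_drive", "continuous-random-current",
                      "Basket", params = list(amplitude_range = c(0, 0.02))),
    nml_network_input("rs_pulses", "random-synaptic-events", "RS",
                      params = list(rate = 1, synapse = "exc_syn")))
  net <- nml_network(pops, projections = list(), inputs = inputs,
                     seed = as.integer(seed))
  doc <- nml_document(level = 3, metadata = fixture_metadata(
    "reduced Layer 2/3 network skeleton: 56 point cells in 5 populations"),
    cells = list(point), channels = list(leak),
    synapses = list(gj, exc), network = net)
  list(document = doc,
       protocol = list(kind = "network", seed = seed,
                       gap_conductance = 2.1e-3))
}
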