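#' Double-exponential synaptic conductance waveforms
#'
#' Conductance time course with an exponential rise and one to three decay
#' components: `g(t) = gmax * N * (sum_i f_i exp(-t/tau_d_i) - exp(-t/tau_r))`
#' where the normalization `N` is chosen so the peak equals `gmax` (the
#' amplitude-interpretable convention needed when comparing simulated EPSC
#' peaks). `rise = 0` gives an instantaneous-rise waveform peaking at `t = 0`;
#' a rise equal to a lone decay constant degenerates to the alpha function
#' `(t/tau) exp(1 - t/tau)`. Events superpose linearly.
#'
#' @param id synapse id.
#' @param gmax peak conductance (uS).
#' @param erev reversal potential (mV).
#' @param rise rise time constant (ms); 0 means instantaneous.
#' @param decays data frame with columns `tau` (ms, > 0) and `fraction`
#'   (summing to 1); 1 to 3 rows.
#' @param mg_block optional [nml_mg_block()] for NMDA-receptor synapses.
#' @export
nml_double_exp_synapse <- function(id, gmax, erev, rise,
                                   decays = data.frame(tau = 1, fraction = 1),
                                   mg_block = NULL) {
  stopifnot(is.data.frame(decays), nrow(decays) >= 1, nrow(decays) <= 3,
            all(decays$tau > 0), rise >= 0, gmax >= 0)
  if (abs(sum(decays$fraction) - 1) > 1e-9)
    stop("decay fractions must sum to 1")
  syn <- structure(list(id = as.character(id), gmax = gmax, erev = erev,
                        rise = rise, decays = decays, mg_block = mg_block,
                        norm = 1, t_peak = 0),
                   class = "nml_double_exp_synapse")
  # peak-normalize once at construction
  if (rise > 0) {
    w <- function(t) syn_waveform(syn, t)
    t_hi <- 10 * max(decays$tau, rise)
    opt <- stats::optimize(w, c(0, t_hi), maximum = TRUE, tol = 1e-12)
    syn$t_peak <- opt$maximum
    syn$norm <- 1 / opt$objective
  }
  syn
}

# unnormalized waveform (fractional-decay mixture minus rise), alpha-function
# limit when rise coincides with a decay constant
syn_waveform <- function(syn, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  decay_sum <- rep(0, length(tp))
  for (i in seq_len(nrow(syn$decays))) {
    tau_d <- syn$decays$tau[i]; f <- syn$decays$fraction[i]
    if (syn$rise > 0 && abs(tau_d - syn$rise) < 1e-12 * tau_d) {
      # degenerate limit: f * (t/tau) * exp(-t/tau), rise term dropped for
      # this component (it cancels in the limit)
      decay_sum <- decay_sum + f * (tp / tau_d) * exp(-tp / tau_d)
    } else {
      decay_sum <- decay_sum + f * exp(-tp / tau_d)
    }
  }
  rise_term <- if (syn$rise > 0) {
    degen <- any(abs(syn$decays$tau - syn$rise) < 1e-12 * syn$rise)
    if (degen) 0 else exp(-tp / syn$rise)
  } else 0
  out[pos] <- pmax(decay_sum - rise_term, 0)
  out
}

#' @param syn an `nml_double_exp_synapse`.
#' @param t_since_event time since the presynaptic event (ms); vectorized,
#'   negative times give 0.
#' @return conductance in uS.
#' @rdname nml_double_exp_synapse
#' @export
conductance_at <- function(syn, t_since_event) {
  stopifnot(inherits(syn, "nml_double_exp_synapse"))
  syn$gmax * syn$norm * syn_waveform(syn, t_since_event)
}

#' NMDA-receptor magnesium block
#'
#' Voltage-dependent multiplicative factor
#' `1 / (1 + eta * [Mg] * exp(-gamma * v))`, in `(0, 1]` for all finite `v`,
#' monotone increasing in `v`. The default parameters are package
#' conventions (documented, not literature-fitted values).
#'
#' @param mg_concentration external magnesium concentration (mM).
#' @param eta block sensitivity (1/mM).
#' @param gamma voltage sensitivity (1/mV).
#' @export
nml_mg_block <- function(mg_concentration = 1, eta = 0.33, gamma = 0.06) {
  stopifnot(mg_concentration >= 0, eta >= 0, gamma >= 0)
  structure(list(mg_concentration = mg_concentration, eta = eta,
                 gamma = gamma), class = "nml_mg_block")
}

#' @param block an [nml_mg_block()].
#' @param v membrane potential (mV); vectorized.
#' @rdname nml_mg_block
#' @export
mg_block_factor <- function(block, v) {
  stopifnot(inherits(block, "nml_mg_block"))
  1 / (1 + block$eta * block$mg_concentration * exp(-block$gamma * v))
}

#' Short-term plasticity (Tsodyks-Markram)
#'
#' Resource/utilisation dynamics per connection. Between spikes the resource
#' fraction `x` recovers toward 1 with time constant `tau_rec` (instantly
#' when `tau_rec = 0`) and the utilisation `u` decays toward `U` with
#' `tau_fac` (pinned at `U` when `tau_fac = 0`). At a spike, facilitation
#' first increments `u <- u + U * (1 - u)` (only when `tau_fac > 0`), the
#' released fraction is `u * x`, and then `x <- x - u * x`. The event
#' conductance is scaled by `release / U` so that with both time constants
#' zero every event reproduces the base synapse unchanged.
#'
#' @param base an [nml_double_exp_synapse()].
#' @param U baseline utilisation in `[0, 1]`.
#' @param tau_rec recovery time constant (ms, >= 0).
#' @param tau_fac facilitation time constant (ms, >= 0).
#' @export
nml_stp_synapse <- function(base, U, tau_rec, tau_fac) {
  stopifnot(inherits(base, "nml_double_exp_synapse"),
            U >= 0, U <= 1, tau_rec >= 0, tau_fac >= 0)
  structure(list(base = base, U = U, tau_rec = tau_rec, tau_fac = tau_fac),
            class = "nml_stp_synapse")
}

#' @return `stp_state()`: fresh per-connection state (full resources,
#'   baseline utilisation, no previous spike).
#' @rdname nml_stp_synapse
#' @export
stp_state <- function(syn) {
  list(x = 1, u = syn$U, last_spike = -Inf)
}

#' @param syn an `nml_stp_synapse`.
#' @param state connection state from `stp_state()` or a previous call.
#' @param t_spike spike time (ms), strictly after the previous one.
#' @return `stp_on_spike()`: list with `release` (fraction in `[0, 1]`),
#'   `scale` (`release / U`, the factor applied to the base event
#'   conductance) and the updated `state`.
#' @rdname nml_stp_synapse
#' @export
stp_on_spike <- function(syn, state, t_spike) {
  stopifnot(inherits(syn, "nml_stp_synapse"))
  if (t_spike <= state$last_spike)
    stop("spike times must be strictly increasing")
  dt <- t_spike - state$last_spike
  x <- if (syn$tau_rec == 0) 1 else
    1 - (1 - state$x) * exp(-dt / syn$tau_rec)
  u <- if (syn$tau_fac == 0) syn$U else
    syn$U + (state$u - syn$U) * exp(-dt / syn$tau_fac)
  if (syn$tau_fac > 0) u <- u + syn$U * (1 - u)
  release <- u * x
  x <- x - release
  list(release = release,
       scale = if (syn$U > 0) release / syn$U else 0,
       state = list(x = x, u = u, last_spike = t_spike))
}

#' Spike-timing-dependent plasticity (additive, trace-based)
#'
#' Additive STDP in the style of Song & Abbott: a presynaptic spike at lag
#' `dt` before a postsynaptic one potentiates the weight by
#' `A_plus * exp(-dt/tau_plus) * w_max`, summed over all prior pre spikes
#' via an exponential trace; post-before-pre pairs depress by
#' `A_minus * exp(-dt/tau_minus) * w_max`. The weight is clipped to
#' `[0, w_max]` after every update.
#'
#' @param id synapse id.
#' @param w_max maximum weight.
#' @param A_plus,A_minus dimensionless amplitudes.
#' @param tau_plus,tau_minus trace time constants (ms).
#' @param w0 initial weight in `[0, w_max]`.
#' @export
nml_stdp_synapse <- function(id = "stdp", w_max = 1, A_plus = 0.005,
                             A_minus = 0.00525, tau_plus = 20,
                             tau_minus = 20, w0 = w_max / 2) {
  stopifnot(w_max > 0, tau_plus > 0, tau_minus > 0, w0 >= 0, w0 <= w_max)
  structure(list(id = as.character(id), w_max = w_max, A_plus = A_plus,
                 A_minus = A_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus, w0 = w0),
            class = "nml_stdp_synapse")
}

#' @return `stdp_state()`: weight at `w0` with empty pre/post traces.
#' @rdname nml_stdp_synapse
#' @export
stdp_state <- function(syn) {
  list(w = syn$w0, pre_trace = 0, post_trace = 0, t_last = -Inf)
}

stdp_decay <- function(syn, state, t) {
  if (is.finite(state$t_last)) {
    dt <- t - state$t_last
    if (dt < 0) stop("event times must be non-decreasing")
    state$pre_trace <- state$pre_trace * exp(-dt / syn$tau_plus)
    state$post_trace <- state$post_trace * exp(-dt / syn$tau_minus)
  } else {
    state$pre_trace <- 0; state$post_trace <- 0
  }
  state$t_last <- t
  state
}

#' @param syn an `nml_stdp_synapse`.
#' @param state from `stdp_state()` or a previous update.
#' @param t event time (ms); times must be non-decreasing across the merged
#'   pre/post stream.
#' @rdname nml_stdp_synapse
#' @export
stdp_on_pre <- function(syn, state, t) {
  state <- stdp_decay(syn, state, t)
  # depression from earlier post spikes
  state$w <- min(max(state$w - syn$A_minus * state$post_trace * syn$w_max, 0),
                 syn$w_max)
  state$pre_trace <- state$pre_trace + 1
  state
}

#' @rdname nml_stdp_synapse
#' @export
stdp_on_post <- function(syn, state, t) {
  state <- stdp_decay(syn, state, t)
  # potentiation from earlier pre spikes
  state$w <- min(max(state$w + syn$A_plus * state$pre_trace * syn$w_max, 0),
                 syn$w_max)
  state$post_trace <- state$post_trace + 1
  state
}

#' Electrical synapses (gap junctions)
#'
#' An ohmic coupling conductance between two compartments. The current into
#' side `a` is `g * (v_b - v_a)`; the current into side `b` is its exact
#' negative, so the pair conserves charge at every step.
#'
#' @param id synapse id.
#' @param conductance coupling conductance (uS; 300 pS = 3e-4 uS).
#' @export
nml_gap_junction <- function(id, conductance) {
  stopifnot(conductance >= 0)
  structure(list(id = as.character(id), conductance = conductance),
            class = "nml_gap_junction")
}

#' @param gj an `nml_gap_junction`.
#' @param v_a,v_b membrane potentials (mV) of the two coupled sides.
#' @return current into side `a` (nA).
#' @rdname nml_gap_junction
#' @export
gap_current <- function(gj, v_a, v_b) {
  stopifnot(inherits(gj, "nml_gap_junction"))
  gj$conductance * (v_b - v_a)
}
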