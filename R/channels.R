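#' Transition-rate laws
#'
#' Voltage-dependent transition rates for channel gates follow the canonical
#' ChannelML v1.x triad, with `A` a rate (ms^-1 in Physiological units), `k`
#' an inverse voltage (mV^-1; its sign carries the direction) and `d` a
#' midpoint voltage (mV):
#'
#' * `exponential`: `A * exp(k * (v - d))`
#' * `sigmoid`: `A / (1 + exp(k * (v - d)))`
#' * `exp_linear`: `A * ((v - d)/k') / (1 - exp(-(v - d)/k'))` with
#'   `k' = 1/k`; the removable singularity at `v = d` is filled with its
#'   limit `A` inside a guard band of 1e-7 mV.
#' * `generic`: a safe arithmetic expression in `v`, `ca` and `celsius`
#'   ([parse_expr()]), used for ligand-gated (e.g. BK/SK-type) rates.
#'
#' @param form one of `"exponential"`, `"sigmoid"`, `"exp_linear"`,
#'   `"generic"`.
#' @param A rate constant (1/ms).
#' @param k inverse voltage scale (1/mV).
#' @param d midpoint voltage (mV).
#' @param expression expression source or `nml_expr`, for `form = "generic"`.
#' @export
nml_rate_law <- function(form = c("exponential", "sigmoid", "exp_linear",
                                  "generic"),
                         A = NULL, k = NULL, d = NULL, expression = NULL) {
  form <- match.arg(form)
  if (form == "generic") {
    if (is.null(expression)) stop("generic rate law needs an expression")
    expression <- if (inherits(expression, "nml_expr")) expression else
      parse_expr(expression, vars = c("v", "ca", "celsius"))
  } else {
    stopifnot(is.numeric(A), is.numeric(k), is.numeric(d))
    if (form == "exp_linear" && k == 0) stop("exp_linear needs k != 0")
  }
  structure(list(form = form, A = A, k = k, d = d, expression = expression),
            class = "nml_rate_law")
}

#' Q10 temperature scaling
#'
#' Transition rates are multiplied by `q10_factor^((temp - experimental_temp)/10)`.
#' At the experimental temperature the scaling is the identity.
#'
#' @param q10_factor positive dimensionless factor per 10 degrees C.
#' @param experimental_temp temperature (degrees C) the rates were measured at.
#' @export
nml_q10 <- function(q10_factor, experimental_temp) {
  stopifnot(q10_factor > 0)
  structure(list(q10_factor = q10_factor,
                 experimental_temp = experimental_temp), class = "nml_q10")
}

q10_scale <- function(q10, temp) {
  if (is.null(q10) || is.null(temp)) return(1)
  q10$q10_factor^((temp - q10$experimental_temp) / 10)
}

#' Evaluate a transition rate
#'
#' @param law an [nml_rate_law()].
#' @param v membrane potential (mV); vectorized.
#' @param ca intracellular calcium concentration (mM), for ligand-dependent
#'   generic laws.
#' @param temp simulation temperature (degrees C); with `q10` supplied the
#'   result is scaled by the Q10 rule.
#' @param q10 optional [nml_q10()].
#' @return rate in 1/ms (same shape as `v`).
#' @export
evaluate_rate <- function(law, v, ca = NULL, temp = NULL, q10 = NULL) {
  stopifnot(inherits(law, "nml_rate_law"))
  r <- switch(law$form,
    exponential = law$A * exp(law$k * (v - law$d)),
    sigmoid = law$A / (1 + exp(law$k * (v - law$d))),
    exp_linear = {
      x <- law$k * (v - law$d)
      out <- ifelse(abs(v - law$d) < 1e-7, law$A,
                    law$A * x / (1 - exp(-x)))
      out
    },
    generic = eval_expr(law$expression,
                        list(v = v,
                             ca = if (is.null(ca)) 0 else ca,
                             celsius = if (is.null(temp)) 0 else temp))
  )
  r <- r * q10_scale(q10, temp)
  if (any(!is.finite(r)))
    stop("rate law '", law$form, "' is non-finite at v = ",
         paste(utils::head(v[!is.finite(r)], 3), collapse = ", "))
  if (any(r < 0))
    stop("rate law '", law$form, "' is negative at v = ",
         paste(utils::head(v[r < 0], 3), collapse = ", "))
  r
}

#' Hodgkin-Huxley gates
#'
#' A gate is a two-state (open/closed) particle with voltage-dependent
#' forward (`alpha`) and backward (`beta`) transition rates, raised to the
#' power `instances` in the channel's conductance product.
#'
#' @param name gate name (e.g. `"n"`).
#' @param instances positive integer power.
#' @param forward,backward [nml_rate_law()]s for alpha and beta.
#' @param ligand logical; `TRUE` when the rates depend on calcium.
#' @export
nml_gate <- function(name, instances, forward, backward, ligand = FALSE) {
  instances <- as.integer(instances)
  if (is.na(instances) || instances < 1L)
    stop("gate instances must be a positive integer")
  stopifnot(inherits(forward, "nml_rate_law"),
            inherits(backward, "nml_rate_law"))
  structure(list(name = name, instances = instances, forward = forward,
                 backward = backward, ligand = isTRUE(ligand)),
            class = "nml_gate")
}

#' @param gate an [nml_gate()].
#' @inheritParams evaluate_rate
#' @return `tau_inf()`: list with vectors `tau` (ms) and `inf`.
#' @rdname nml_gate
#' @export
tau_inf <- function(gate, v, ca = NULL, temp = NULL, q10 = NULL) {
  a <- evaluate_rate(gate$forward, v, ca, temp, q10)
  b <- evaluate_rate(gate$backward, v, ca, temp, q10)
  s <- a + b
  if (any(s <= 0))
    stop("alpha + beta = 0 at v = ", paste(v[s <= 0], collapse = ", "))
  list(tau = 1 / s, inf = a / s)
}

#' @param m gating state in `[0, 1]`.
#' @return `gate_derivative()`: dm/dt in 1/ms.
#' @rdname nml_gate
#' @export
gate_derivative <- function(gate, m, v, ca = NULL, temp = NULL, q10 = NULL) {
  stopifnot(all(m >= 0 & m <= 1))
  a <- evaluate_rate(gate$forward, v, ca, temp, q10)
  b <- evaluate_rate(gate$backward, v, ca, temp, q10)
  a * (1 - m) - b * m
}

#' Markov kinetic schemes
#'
#' Multi-state channel models with a rate matrix; conductance is
#' proportional to the summed occupancy of the open states. The
#' Hodgkin-Huxley gate is the two-state special case.
#'
#' @param states data frame with columns `name` and logical `open`.
#' @param transitions list of `list(from =, to =, rate = nml_rate_law)`.
#' @export
nml_kinetic_scheme <- function(states, transitions) {
  stopifnot(is.data.frame(states), all(c("name", "open") %in% names(states)))
  for (tr in transitions) {
    if (!all(c(tr$from, tr$to) %in% states$name))
      stop("transition references unknown state")
    stopifnot(inherits(tr$rate, "nml_rate_law"))
  }
  structure(list(states = states, transitions = transitions),
            class = "nml_kinetic_scheme")
}

# generator matrix Q (column-stochastic convention: dp/dt = Q %*% p)
scheme_generator <- function(scheme, v, ca = NULL, temp = NULL, q10 = NULL) {
  n <- nrow(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states$name,
                                       scheme$states$name))
  for (tr in scheme$transitions) {
    r <- evaluate_rate(tr$rate, v, ca, temp, q10)
    Q[tr$to, tr$from] <- Q[tr$to, tr$from] + r
    Q[tr$from, tr$from] <- Q[tr$from, tr$from] - r
  }
  Q
}

#' @param scheme an [nml_kinetic_scheme()].
#' @param occupancies probability vector over states.
#' @param dt time step (ms). The step is an implicit (backward Euler)
#'   propagation of the master equation; it preserves the probability-vector
#'   property to machine precision.
#' @inheritParams evaluate_rate
#' @rdname nml_kinetic_scheme
#' @export
scheme_step <- function(scheme, occupancies, v, dt, ca = NULL, temp = NULL,
                        q10 = NULL) {
  stopifnot(length(occupancies) == nrow(scheme$states))
  if (abs(sum(occupancies) - 1) > 1e-9 || any(occupancies < -1e-12))
    stop("occupancies must form a probability vector")
  Q <- scheme_generator(scheme, v, ca, temp, q10)
  p <- solve(diag(nrow(Q)) - dt * Q, occupancies)
  unname(pmin(pmax(p, 0), 1))
}

scheme_open_fraction <- function(scheme, occupancies) {
  sum(occupancies[scheme$states$open])
}

#' Distributed conductances
#'
#' A `channel_type`: maximum conductance density, reversal potential and
#' either a set of HH gates or a Markov kinetic scheme (exclusively one of
#' the two), plus optional Q10 temperature scaling.
#'
#' @param id channel id.
#' @param gmax_density maximum conductance density (mS/cm2, Physiological).
#' @param erev reversal potential (mV).
#' @param gates list of [nml_gate()]s.
#' @param scheme an [nml_kinetic_scheme()]; mutually exclusive with `gates`.
#' @param q10 optional [nml_q10()].
#' @param passive `TRUE` for an ungated leak conductance (no gates, no
#'   scheme).
#' @param ion carried ion: `"non_specific"`, `"na"`, `"k"` or `"ca"`
#'   (calcium currents drive [nml_ca_pool()]s).
#' @export
nml_channel <- function(id, gmax_density, erev, gates = NULL, scheme = NULL,
                        q10 = NULL, passive = FALSE, ion = "non_specific") {
  if (passive) {
    if (!is.null(gates) || !is.null(scheme))
      stop("a passive channel has neither gates nor a scheme")
  } else if (is.null(gates) == is.null(scheme)) {
    stop("channel must have gates xor a kinetic scheme")
  }
  if (!is.null(gates)) {
    stopifnot(all(vapply(gates, inherits, TRUE, "nml_gate")))
    names(gates) <- vapply(gates, `[[`, "", "name")
  }
  structure(list(id = as.character(id), gmax_density = gmax_density,
                 erev = erev, gates = gates, scheme = scheme, q10 = q10,
                 passive = isTRUE(passive), ion = as.character(ion)),
            class = "nml_channel")
}

#' @param channel an [nml_channel()].
#' @param states one value per gate (in gate order), or the occupancy vector
#'   for a kinetic scheme.
#' @param v membrane potential (mV).
#' @param area membrane area (um2).
#' @return current in nA (Physiological internal units): the conductance
#'   product times the driving force `v - erev`.
#' @rdname nml_channel
#' @export
channel_current <- function(channel, states, v, area) {
  gmax_abs <- channel$gmax_density * 1e-5 * area  # mS/cm2 * um2 -> uS
  if (channel$passive) {
    open <- 1
    return(gmax_abs * open * (v - channel$erev))
  }
  if (!is.null(channel$gates)) {
    if (length(states) != length(channel$gates))
      stop("expected ", length(channel$gates), " gate states, got ",
           length(states))
    open <- prod(mapply(function(g, m) m^g$instances, channel$gates, states))
  } else {
    open <- scheme_open_fraction(channel$scheme, states)
  }
  gmax_abs * open * (v - channel$erev)  # uS * mV = nA
}

#' Decaying calcium pools
#'
#' First-order intracellular concentration model: the pool decays toward its
#' resting concentration with time constant `tau` and is driven by calcium
#' influx, `dc/dt = -(c - resting)/tau + phi * i_ca`. `phi` converts the
#' compartment's total calcium current (nA) to a concentration rate
#' (mM/ms); it is a per-compartment scaling, a documented convention since
#' shell geometry is not part of the description.
#'
#' @param id pool id.
#' @param resting resting concentration (mM).
#' @param tau decay time constant (ms).
#' @param phi influx scaling (mM / (nA ms)).
#' @export
nml_ca_pool <- function(id, resting, tau, phi) {
  stopifnot(resting >= 0, tau > 0)
  structure(list(id = as.character(id), resting = resting, tau = tau,
                 phi = phi), class = "nml_ca_pool")
}

#' @param pool an [nml_ca_pool()].
#' @param c concentration (mM).
#' @param i_ca calcium current (nA; inward influx positive).
#' @rdname nml_ca_pool
#' @export
ca_pool_derivative <- function(pool, c, i_ca) {
  stopifnot(c >= 0)
  -(c - pool$resting) / pool$tau + pool$phi * i_ca
}

#' Integrate-and-fire mechanism
#'
#' Basic leaky integrate-and-fire point-neuron mechanism: when the membrane
#' potential crosses `threshold` it is reset to `reset` and held for the
#' refractory period.
#'
#' @param threshold,reset voltages (mV), `reset < threshold`.
#' @param refractory refractory period (ms).
#' @param g_leak leak conductance (uS).
#' @param e_leak leak reversal potential (mV).
#' @export
nml_iaf <- function(threshold, reset, refractory, g_leak, e_leak) {
  if (!(reset < threshold)) stop("reset must be below threshold")
  stopifnot(refractory >= 0, g_leak >= 0)
  structure(list(threshold = threshold, reset = reset,
                 refractory = refractory, g_leak = g_leak, e_leak = e_leak),
            class = "nml_iaf")
}
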