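# Reference branched-cable simulator.
#
# Internal unit system: mV, ms, uS, nF, nA, um, mM. These are mutually
# consistent (uS * mV = nA; nF * mV / ms = nA; MOhm = 1 / uS), so no
# conversion factors appear inside the integration loop.
#
# Integration: first-order implicit (backward Euler) solve of the branched
# cable equation over the whole compartment tree each step, with channel
# conductances frozen at the current gate states; gate states advance by
# the staggered exponential update m <- inf + (m - inf) exp(-dt/tau), which
# keeps them in [0, 1] unconditionally. An explicit exponential-Euler
# scheme would need a far smaller time step for the same accuracy; the
# implicit solve is what makes dt ~ 0.005 ms usable.

#' Solver configuration
#'
#' @param dt time step (ms).
#' @param symmetry `"symmetric"` (axial resistance split in half at each
#'   end of a compartment, voltage at the centre) or `"asymmetric"` (all
#'   axial resistance on one side, voltage at the distal node).
#' @param temperature simulation temperature (degrees C) for Q10 scaling.
#' @param method `"implicit-first-order"` (default) or
#'   `"semi-implicit-second-order"` (Crank-Nicolson-style average, for
#'   convergence studies).
#' @param seed integer seed for stochastic stimuli. Random streams are
#'   counter-based and keyed by (seed, target id), so adding a recording or
#'   another stimulus never perturbs an existing noise stream.
#' @export
solver_config <- function(dt = 0.005,
                          symmetry = c("symmetric", "asymmetric"),
                          temperature = 6.3,
                          method = c("implicit-first-order",
                                     "semi-implicit-second-order"),
                          seed = 1L) {
  stopifnot(dt > 0)
  structure(list(dt = dt, symmetry = match.arg(symmetry),
                 temperature = temperature, method = match.arg(method),
                 seed = as.integer(seed)),
            class = "nml_solver_config")
}

# closed-form rate law as a lean closure, Q10 folded in; validation of
# finiteness/negativity happened at validate/build time
compile_rate <- function(law, q10f, temp) {
  A <- law$A * q10f; k <- law$k; d <- law$d
  switch(law$form,
    exponential = function(v, ca) A * exp(k * (v - d)),
    sigmoid = function(v, ca) A / (1 + exp(k * (v - d))),
    exp_linear = function(v, ca) {
      x <- k * (v - d)
      out <- A * x / (1 - exp(-x))
      sing <- abs(v - d) < 1e-7
      if (any(sing)) out[sing] <- A
      out
    },
    generic = {
      expr <- law$expression
      function(v, ca) q10f * eval_expr(expr, list(v = v, ca = ca,
                                                  celsius = temp))
    })
}

# Park-Miller stream keyed by (seed, id string); pure counter-based draws
nml_stream <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483646
  state <- (as.numeric(seed) * 48271 + h) %% 2147483646 + 1
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (16807 * state) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

#' Discretize cells into a compartment graph
#'
#' Builds the simulator's state: every cable of every (biophysical) cell is
#' mapped through [recompartmentalize()] into its `internal_divisions`
#' equivalent cylinders; spherical somata become single spherical
#' compartments (area `pi d^2`, axial contribution of an equal-diameter
#' cylinder). Axial links follow the configured symmetry convention.
#' Mechanism densities -- including non-uniform `variable_parameter`
#' placements -- are evaluated at each compartment's centre path distance.
#'
#' @param doc an [nml_document()] supplying channel/pool definitions.
#' @param cells character vector of cell ids to instantiate (each id once;
#'   repeat ids for multiple instances), default all biophysical cells.
#' @param config a [solver_config()].
#' @return an object of class `nml_graph`.
#' @export
build_graph <- function(doc, cells = NULL, config = solver_config()) {
  stopifnot(inherits(doc, "nml_document"))
  if (is.null(cells))
    cells <- names(doc$cells)[vapply(doc$cells, inherits, TRUE,
                                     "nml_biophysical_cell")]
  stopifnot(length(cells) > 0)

  comp_rows <- list()
  mech_list <- list()   # per channel placement: comps, gmax_abs, channel
  pool_list <- list()
  iaf_list <- list()
  parent <- integer(0)
  link_res <- numeric(0)  # MOhm, resistance of link comp->parent
  n <- 0L

  for (inst in seq_along(cells)) {
    cell <- doc$cells[[cells[inst]]]
    if (is.null(cell)) stop("unknown cell id: ", cells[inst])
    if (!inherits(cell, "nml_biophysical_cell"))
      stop("cell '", cells[inst], "' carries no biophysics")
    morph <- cell$morphology
    root_id <- cell_root_id(morph)

    # order cables root-first so parents exist before children
    cable_first_seg <- vapply(morph$cables, function(cb) {
      fr <- cable_frusta(morph, cb$id); fr$segment[1]
    }, "")
    depth <- vapply(cable_first_seg, function(sid)
      path_distance(morph, sid, 0), 0)
    cable_order <- names(morph$cables)[order(depth)]

    first_comp <- n + 1L
    comp_of_segment_end <- character(0)  # segment id -> comp index (chr names)
    comp_idx_of_segment_end <- integer(0)
    cable_spans <- list()

    for (cb_id in cable_order) {
      cb <- morph$cables[[cb_id]]
      fr <- cable_frusta(morph, cb_id)
      spherical <- all(fr$len <= 1e-12)
      d_start <- path_distance(morph, fr$segment[1], 0)
      ra_val <- resolve_group_value(cell$axial_resistivity,
                                    cable_groups(cb))
      cm_val <- resolve_group_value(cell$specific_capacitance,
                                    cable_groups(cb))
      if (is.na(ra_val) || is.na(cm_val))
        stop("no passive properties resolve for cable '", cb_id, "'")

      if (spherical) {
        diam <- 2 * fr$r0[1]
        area <- pi * diam^2
        axial <- diam / (pi * (diam / 2)^2)
        cyl <- data.frame(length = diam, radius = diam / 2, area = area,
                          axial = axial, axial_residual = 0)
      } else {
        cyl <- recompartmentalize(morph, cb_id)
      }
      spans <- integer(nrow(cyl))
      cum_len <- c(0, cumsum(cyl$length))
      for (k in seq_len(nrow(cyl))) {
        n <- n + 1L
        spans[k] <- n
        centre_arc <- if (spherical) 0 else
          (cum_len[k] + cum_len[k + 1]) / 2
        comp_rows[[n]] <- data.frame(
          comp = n, instance = inst, cell = cells[inst], cable = cb_id,
          span = k, length = cyl$length[k], radius = cyl$radius[k],
          area = cyl$area[k],
          cm = cm_val * 1e-5 * cyl$area[k],        # uF/cm2 * um2 -> nF
          r_axial = 10 * ra_val * cyl$axial[k],    # kohm cm / um -> MOhm
          centre_d = d_start + centre_arc,
          arc0 = cum_len[k], arc1 = cum_len[k + 1],
          spherical = spherical,
          stringsAsFactors = FALSE)
        if (k > 1L) {
          parent[n] <- spans[k - 1L]
        } else {
          # attach to the compartment holding the parent segment's end
          pseg <- morph$segments[[fr$segment[1]]]$parent
          if (is.na(pseg)) {
            parent[n] <- NA_integer_
          } else {
            pc <- comp_idx_of_segment_end[match(pseg, comp_of_segment_end)]
            if (is.na(pc))
              stop("cable '", cb_id, "' attaches to an undiscretized segment")
            parent[n] <- pc
          }
        }
        link_res[n] <- NA_real_  # filled below once all comps exist
      }
      cable_spans[[cb_id]] <- spans
      # record which compartment contains each segment's distal end
      arc_end <- 0
      for (si in seq_len(nrow(fr))) {
        arc_end <- arc_end + fr$len[si]
        k <- if (spherical) 1L else
          max(1L, min(nrow(cyl), findInterval(arc_end - 1e-9, cum_len,
                                              all.inside = TRUE)))
        comp_of_segment_end <- c(comp_of_segment_end, fr$segment[si])
        comp_idx_of_segment_end <- c(comp_idx_of_segment_end, spans[k])
      }
    }

    comp_df_cell <- do.call(rbind, comp_rows[first_comp:n])

    # resolved mechanism placements
    for (pl in cell$placements) {
      gg <- if (!is.null(pl$vp)) pl$vp$groups else pl$groups
      sel <- unname(which(vapply(comp_df_cell$cable, function(cid)
        any(gg %in% cable_groups(morph$cables[[cid]])), TRUE,
        USE.NAMES = FALSE)))
      if (length(sel) == 0L) next
      comps <- comp_df_cell$comp[sel]
      chn <- doc$channels[[pl$channel]]
      if (is.null(chn)) stop("unresolved channel id: ", pl$channel)
      dens <- if (!is.null(pl$vp)) {
        vapply(sel, function(i) {
          loc <- graph_arc_locate(morph, comp_df_cell, i)
          evaluate_density(pl$vp, morph, loc$segment, loc$fraction)
        }, 0)
      } else rep(pl$density, length(sel))
      mech_list[[length(mech_list) + 1L]] <- list(
        channel = chn, comps = comps,
        gmax_abs = dens * 1e-5 * comp_df_cell$area[sel])
    }
    for (ip in cell$ion_pools) {
      pool <- doc$ion_pools[[ip$pool]]
      if (is.null(pool)) stop("unresolved pool id: ", ip$pool)
      sel <- which(vapply(comp_df_cell$cable, function(cid)
        any(ip$groups %in% cable_groups(morph$cables[[cid]])), TRUE))
      if (length(sel) > 0L)
        pool_list[[length(pool_list) + 1L]] <-
          list(pool = pool, comps = comp_df_cell$comp[sel])
    }
    if (!is.null(cell$iaf)) {
      iaf_list[[length(iaf_list) + 1L]] <-
        list(iaf = cell$iaf, comp = first_comp)
      # the IaF leak is an absolute conductance on the (point) cell body
      mech_list[[length(mech_list) + 1L]] <- list(
        channel = nml_channel(paste0("iaf_leak_", inst),
                              gmax_density = 0, erev = cell$iaf$e_leak,
                              passive = TRUE),
        comps = first_comp, gmax_abs = cell$iaf$g_leak)
    }
  }

  comps <- do.call(rbind, comp_rows)
  rownames(comps) <- NULL

  # link resistances under the chosen convention
  for (i in seq_len(n)) {
    p <- parent[i]
    if (is.na(p)) next
    link_res[i] <- if (config$symmetry == "symmetric")
      (comps$r_axial[i] + comps$r_axial[p]) / 2
    else comps$r_axial[i]
  }

  structure(list(comps = comps, parent = parent, link_res = link_res,
                 mechanisms = mech_list, pools = pool_list,
                 iafs = iaf_list, gap_junctions = list(),
                 config = config, doc_cells = cells,
                 init_potential = vapply(cells, function(id)
                   doc$cells[[id]]$init_potential, 0),
                 morphs = stats::setNames(lapply(unique(cells), function(id)
                   cell_morphology(doc$cells[[id]])), unique(cells))),
            class = "nml_graph")
}

# locate a compartment centre as (segment, fraction) on the morphology
graph_arc_locate <- function(morph, comp_df, i) {
  fr <- cable_frusta(morph, comp_df$cable[i])
  target <- (comp_df$arc0[i] + comp_df$arc1[i]) / 2
  acc <- 0
  for (j in seq_len(nrow(fr))) {
    if (target <= acc + fr$len[j] || j == nrow(fr)) {
      frac <- if (fr$len[j] > 0) (target - acc) / fr$len[j] else 0
      return(list(segment = fr$segment[j],
                  fraction = min(max(frac, 0), 1)))
    }
    acc <- acc + fr$len[j]
  }
}

#' @export
print.nml_graph <- function(x, ...) {
  cat(sprintf("<nml_graph> %d compartments (%s convention), %d mechanism placements\n",
              nrow(x$comps), x$config$symmetry, length(x$mechanisms)))
  invisible(x)
}

#' Couple two compartments electrically
#'
#' Adds an ohmic gap-junction link; the coupling currents on the two sides
#' are exact negatives of each other at every step.
#'
#' @param graph an `nml_graph`.
#' @param comp_a,comp_b compartment indices.
#' @param conductance coupling conductance (uS).
#' @export
add_gap_junction <- function(graph, comp_a, comp_b, conductance) {
  stopifnot(inherits(graph, "nml_graph"), conductance >= 0)
  graph$gap_junctions[[length(graph$gap_junctions) + 1L]] <-
    list(a = comp_a, b = comp_b, g = conductance)
  graph
}

#' Locate the compartment containing a point on a cell
#'
#' @param graph an `nml_graph`.
#' @param instance which cell instance (position in the graph's cell list).
#' @param segment segment id; default the cell's root.
#' @param fraction fraction along the segment.
#' @return compartment index.
#' @export
comp_at <- function(graph, instance = 1L, segment = NULL, fraction = 0.5) {
  cm <- graph$comps
  rows <- which(cm$instance == instance)
  if (length(rows) == 0L) stop("no such cell instance: ", instance)
  if (is.null(segment)) return(rows[1L])
  rows_cable <- NULL; arc <- NA_real_
  for (cb in unique(cm$cable[rows])) {
    sub <- rows[cm$cable[rows] == cb]
    # does this cable of this instance contain the segment?
    # find arc position of (segment, fraction) within the cable
    doc_cell <- cm$cell[sub[1L]]
    arc_try <- tryCatch(
      segment_arc_in_cable(graph, doc_cell, cb, segment, fraction),
      error = function(e) NULL)
    if (!is.null(arc_try)) { rows_cable <- sub; arc <- arc_try; break }
  }
  if (is.null(rows_cable))
    stop("segment '", segment, "' not found on instance ", instance)
  k <- findInterval(arc, c(cm$arc0[rows_cable][1],
                           cm$arc1[rows_cable]), all.inside = TRUE)
  rows_cable[k]
}

segment_arc_in_cable <- function(graph, cell_id, cable_id, segment,
                                 fraction) {
  morph <- graph$morphs[[cell_id]]
  if (is.null(morph)) stop("no morphology for cell '", cell_id, "'")
  fr <- cable_frusta(morph, cable_id)
  i <- match(segment, fr$segment)
  if (is.na(i)) stop("segment not in cable")
  sum(fr$len[seq_len(i - 1L)]) + fraction * fr$len[i]
}

#' Stimuli
#'
#' @param kind `"current-pulse"` (amplitude, delay, duration),
#'   `"continuous-random-current"` (uniform per-step amplitude in
#'   `range`), or `"synaptic-events"` (a synapse object plus explicit
#'   event `times`, optionally jittered Poisson via `rate`).
#' @param comp target compartment index.
#' @param amplitude current amplitude (nA).
#' @param delay,duration pulse timing (ms).
#' @param range two-element amplitude range (nA) for random current.
#' @param synapse synapse object for synaptic events.
#' @param times event times (ms).
#' @param id stable identifier keying the stimulus' random stream.
#' @export
nml_stimulus <- function(kind = c("current-pulse",
                                  "continuous-random-current",
                                  "synaptic-events"),
                         comp, amplitude = 0, delay = 0, duration = Inf,
                         range = NULL, synapse = NULL, times = NULL,
                         id = "stim") {
  kind <- match.arg(kind)
  structure(list(kind = kind, comp = comp, amplitude = amplitude,
                 delay = delay, duration = duration, range = range,
                 synapse = synapse, times = times, id = id),
            class = "nml_stimulus")
}

#' Run a simulation
#'
#' Backward-Euler integration of the compartment tree with staggered
#' exponential gate updates, calcium-pool dynamics and synaptic event
#' conductances. Deterministic: identical graph, stimuli, duration and
#' config (including seed) give bit-identical recordings.
#'
#' @param graph an `nml_graph` from [build_graph()].
#' @param stimuli list of [nml_stimulus()].
#' @param duration run time (ms).
#' @param record integer vector of compartments whose voltage to record
#'   (default: all).
#' @param record_gates record gate-state trajectories as well.
#' @param v_clamp optional `list(comp =, level =)` voltage clamp; the
#'   recording then includes the clamp current trace `i_clamp` (nA).
#' @return an `nml_recordings` object: `time` (ms), `v` (matrix steps x
#'   recorded comps), optional `gates`, `ca`, `i_clamp`, and `spikes` for
#'   integrate-and-fire cells.
#' @export
run_simulation <- function(graph, stimuli = list(), duration,
                           record = NULL, record_gates = FALSE,
                           v_clamp = NULL) {
  stopifnot(inherits(graph, "nml_graph"), duration > 0)
  cfg <- graph$config
  dt <- cfg$dt
  nstep <- floor(duration / dt)
  cm <- graph$comps
  n <- nrow(cm)
  if (is.null(record)) record <- seq_len(n)

  # static axial matrix (off-diagonal conductances and their diagonal sums)
  A_off <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p <- graph$parent[i]
    if (is.na(p)) next
    g <- 1 / graph$link_res[i]
    A_off[i, p] <- A_off[i, p] - g
    A_off[p, i] <- A_off[p, i] - g
    A_off[i, i] <- A_off[i, i] + g
    A_off[p, p] <- A_off[p, p] + g
  }
  for (gj in graph$gap_junctions) {
    g <- gj$g
    A_off[gj$a, gj$b] <- A_off[gj$a, gj$b] - g
    A_off[gj$b, gj$a] <- A_off[gj$b, gj$a] - g
    A_off[gj$a, gj$a] <- A_off[gj$a, gj$a] + g
    A_off[gj$b, gj$b] <- A_off[gj$b, gj$b] + g
  }

  # initial state: each instance starts at its cell's init_potential
  V <- numeric(n)
  for (inst in unique(cm$instance))
    V[cm$instance == inst] <- graph$init_potential[inst]

  temp <- cfg$temperature
  mechs <- graph$mechanisms
  # precompiled rate closures (checks done once; loop stays lean)
  mcomp <- lapply(mechs, function(m) {
    chn <- m$channel
    if (chn$passive || is.null(chn$gates)) return(NULL)
    q10f <- q10_scale(chn$q10, temp)
    lapply(chn$gates, function(g) list(
      fa = compile_rate(g$forward, q10f, temp),
      fb = compile_rate(g$backward, q10f, temp),
      instances = g$instances, ligand = g$ligand))
  })
  mstate <- lapply(mechs, function(m) {
    chn <- m$channel
    if (chn$passive) return(NULL)
    if (!is.null(chn$gates)) {
      sapply(chn$gates, function(g) {
        ti <- tau_inf(g, V[m$comps], ca = 1e-4, temp = temp, q10 = chn$q10)
        ti$inf
      }, simplify = "array")
    } else {
      # start in the first state
      occ <- matrix(0, length(m$comps), nrow(chn$scheme$states))
      occ[, 1] <- 1
      occ
    }
  })
  pool_state <- lapply(graph$pools, function(pp) rep(pp$pool$resting,
                                                     length(pp$comps)))
  ca_comp <- rep(NA_real_, n)  # concentration per comp (first pool wins)
  for (pp_i in seq_along(graph$pools))
    ca_comp[graph$pools[[pp_i]]$comps] <- pool_state[[pp_i]]

  # precompute stimulus currents and synaptic conductance timelines
  tgrid <- seq_len(nstep) * dt
  I_stim <- matrix(0, nstep, n)
  syn_g <- list()  # per synaptic stimulus: list(comp, g (vec), erev, block)
  for (st in stimuli) {
    if (st$kind == "current-pulse") {
      on <- tgrid > st$delay & tgrid <= st$delay + st$duration
      I_stim[on, st$comp] <- I_stim[on, st$comp] + st$amplitude
    } else if (st$kind == "continuous-random-current") {
      draw <- nml_stream(cfg$seed, st$id)
      u <- draw(nstep)
      I_stim[, st$comp] <- I_stim[, st$comp] +
        st$range[1] + u * (st$range[2] - st$range[1])
    } else if (st$kind == "synaptic-events") {
      syn <- st$synapse
      base <- if (inherits(syn, "nml_stp_synapse")) syn$base else syn
      times <- st$times
      scales <- rep(1, length(times))
      if (inherits(syn, "nml_stp_synapse")) {
        s <- stp_state(syn)
        for (ti in seq_along(times)) {
          r <- stp_on_spike(syn, s, times[ti])
          scales[ti] <- r$scale
          s <- r$state
        }
      }
      gvec <- numeric(nstep)
      for (ti in seq_along(times))
        gvec <- gvec + scales[ti] * conductance_at(base, tgrid - times[ti])
      syn_g[[length(syn_g) + 1L]] <- list(comp = st$comp, g = gvec,
                                          erev = base$erev,
                                          block = base$mg_block)
    }
  }

  rec_v <- matrix(NA_real_, nstep + 1L, length(record))
  rec_v[1L, ] <- V[record]
  rec_gates <- if (record_gates) vector("list", nstep + 1L)
  if (record_gates) rec_gates[[1L]] <- mstate
  rec_ca <- if (length(graph$pools) > 0)
    matrix(NA_real_, nstep + 1L, length(graph$pools))
  if (!is.null(rec_ca))
    rec_ca[1L, ] <- vapply(pool_state, function(s) s[1L], 0)
  i_clamp <- if (!is.null(v_clamp)) numeric(nstep + 1L)
  if (!is.null(v_clamp)) V[v_clamp$comp] <- v_clamp$level

  iaf_refract_until <- rep(-Inf, length(graph$iafs))
  iaf_spikes <- lapply(graph$iafs, function(x) numeric(0))

  cap_dt <- cm$cm / dt
  crank <- cfg$method == "semi-implicit-second-order"

  for (step in seq_len(nstep)) {
    t_now <- tgrid[step]

    # 1. advance gate states (exponential update at current V, ca)
    g_sum <- numeric(n)
    gE_sum <- numeric(n)
    i_ca_comp <- numeric(n)
    for (k in seq_along(mechs)) {
      m <- mechs[[k]]
      chn <- m$channel
      vk <- V[m$comps]
      if (chn$passive) {
        open <- 1
      } else if (!is.null(chn$gates)) {
        st_mat <- mstate[[k]]
        if (is.null(dim(st_mat)))
          st_mat <- matrix(st_mat, ncol = length(chn$gates))
        gates_c <- mcomp[[k]]
        open <- 1
        for (gi in seq_along(gates_c)) {
          gc <- gates_c[[gi]]
          cav <- if (gc$ligand) ca_comp[m$comps] else 0
          a <- gc$fa(vk, cav); b <- gc$fb(vk, cav)
          s <- a + b
          inf <- a / s
          st_mat[, gi] <- inf + (st_mat[, gi] - inf) * exp(-dt * s)
          open <- open * st_mat[, gi]^gc$instances
        }
        mstate[[k]] <- st_mat
      } else {
        occ <- mstate[[k]]
        for (r in seq_along(m$comps)) {
          Q <- scheme_generator(chn$scheme, vk[r],
                                ca = if (is.na(ca_comp[m$comps[r]])) NULL
                                else ca_comp[m$comps[r]],
                                temp = temp, q10 = chn$q10)
          occ[r, ] <- solve(diag(nrow(Q)) - dt * Q, occ[r, ])
        }
        occ <- pmin(pmax(occ, 0), 1)
        mstate[[k]] <- occ
        open <- occ %*% as.numeric(chn$scheme$states$open)
        open <- as.numeric(open)
      }
      gk <- m$gmax_abs * open
      g_sum[m$comps] <- g_sum[m$comps] + gk
      gE_sum[m$comps] <- gE_sum[m$comps] + gk * chn$erev
      if (identical(chn$ion, "ca"))
        i_ca_comp[m$comps] <- i_ca_comp[m$comps] + gk * (vk - chn$erev)
    }

    # synaptic conductances at this step (Mg block at previous V)
    for (sg in syn_g) {
      gk <- sg$g[step]
      if (gk == 0) next
      if (!is.null(sg$block))
        gk <- gk * mg_block_factor(sg$block, V[sg$comp])
      g_sum[sg$comp] <- g_sum[sg$comp] + gk
      gE_sum[sg$comp] <- gE_sum[sg$comp] + gk * sg$erev
    }

    # 2. implicit voltage solve
    if (crank) {
      # trapezoidal average of old- and new-time membrane/axial currents
      A <- A_off / 2
      diag(A) <- diag(A) + cap_dt + g_sum / 2
      b <- cap_dt * V - as.numeric(A_off %*% V) / 2 - g_sum * V / 2 +
        gE_sum + I_stim[step, ]
    } else {
      A <- A_off
      diag(A) <- diag(A) + cap_dt + g_sum
      b <- cap_dt * V + gE_sum + I_stim[step, ]
    }
    if (!is.null(v_clamp)) {
      A[v_clamp$comp, ] <- 0
      A[v_clamp$comp, v_clamp$comp] <- 1
      b[v_clamp$comp] <- v_clamp$level
    }
    Vn <- solve(A, b)
    if (any(!is.finite(Vn)) || any(abs(Vn) > 1000))
      stop("numeric divergence (|V| > 1000 mV) at t = ", t_now,
           " ms; reduce dt = ", dt)
    if (!is.null(v_clamp)) {
      # clamp current: membrane + synaptic + axial current at the node
      i_mem <- g_sum[v_clamp$comp] * v_clamp$level - gE_sum[v_clamp$comp]
      i_ax <- sum(A_off[v_clamp$comp, ] * Vn) -
        A_off[v_clamp$comp, v_clamp$comp] * Vn[v_clamp$comp] +
        A_off[v_clamp$comp, v_clamp$comp] * v_clamp$level
      i_clamp[step + 1L] <- i_mem + i_ax - I_stim[step, v_clamp$comp]
    }
    V <- as.numeric(Vn)

    # 3. integrate-and-fire threshold/reset
    for (fi in seq_along(graph$iafs)) {
      f <- graph$iafs[[fi]]
      if (t_now < iaf_refract_until[fi]) {
        V[f$comp] <- f$iaf$reset
      } else if (V[f$comp] >= f$iaf$threshold) {
        iaf_spikes[[fi]] <- c(iaf_spikes[[fi]], t_now)
        V[f$comp] <- f$iaf$reset
        iaf_refract_until[fi] <- t_now + f$iaf$refractory
      }
    }

    # 4. calcium pools (exponential update toward instantaneous target)
    for (pp_i in seq_along(graph$pools)) {
      pp <- graph$pools[[pp_i]]
      influx <- -i_ca_comp[pp$comps]  # inward Ca current raises [Ca]
      target <- pp$pool$resting + pp$pool$phi * pp$pool$tau * influx
      pool_state[[pp_i]] <- target + (pool_state[[pp_i]] - target) *
        exp(-dt / pp$pool$tau)
      pool_state[[pp_i]] <- pmax(pool_state[[pp_i]], 0)
      ca_comp[pp$comps] <- pool_state[[pp_i]]
    }

    rec_v[step + 1L, ] <- V[record]
    if (record_gates) rec_gates[[step + 1L]] <- mstate
    if (!is.null(rec_ca))
      rec_ca[step + 1L, ] <- vapply(pool_state, function(s) s[1L], 0)
  }

  structure(list(time = c(0, tgrid), v = rec_v, record = record,
                 gates = rec_gates, ca = rec_ca, i_clamp = i_clamp,
                 spikes = iaf_spikes, dt = dt, config = cfg),
            class = "nml_recordings")
}

#' @export
print.nml_recordings <- function(x, ...) {
  cat(sprintf("<nml_recordings> %d samples (dt = %g ms) x %d compartments\n",
              length(x$time), x$dt, ncol(x$v)))
  invisible(x)
}

#' Voltage-clamp protocol
#'
#' Pins one compartment at a holding potential, delivers synaptic events
#' there, and records the clamp current (the total membrane, synaptic and
#' axial current the amplifier must supply).
#'
#' @param graph an `nml_graph`.
#' @param comp clamped compartment.
#' @param holding holding potential (mV).
#' @param synapse synapse object delivering events.
#' @param event_times event times (ms).
#' @param duration run time (ms).
#' @return `nml_recordings` with the `i_clamp` trace (nA).
#' @export
run_voltage_clamp <- function(graph, comp, holding, synapse = NULL,
                              event_times = numeric(0), duration) {
  stim <- if (!is.null(synapse) && length(event_times) > 0)
    list(nml_stimulus("synaptic-events", comp = comp, synapse = synapse,
                      times = event_times, id = "clamp_events"))
  else list()
  run_simulation(graph, stim, duration, record = comp,
                 v_clamp = list(comp = comp, level = holding))
}

#' Detect spikes by threshold crossing
#'
#' Upward crossings of `threshold`, with the crossing time linearly
#' interpolated between samples.
#'
#' @param trace numeric voltage trace (mV), uniformly sampled.
#' @param dt sample interval (ms), or supply `time`.
#' @param time sample times (ms) overriding `dt`.
#' @param threshold detection threshold (mV); default 0.
#' @return numeric vector of spike times (ms), class `nml_spike_train`.
#' @export
detect_spikes <- function(trace, dt = NULL, time = NULL, threshold = 0) {
  if (inherits(trace, "nml_recordings")) {
    time <- trace$time
    trace <- trace$v[, 1]
  }
  if (is.null(time)) {
    stopifnot(!is.null(dt))
    time <- (seq_along(trace) - 1L) * dt
  }
  below <- trace < threshold
  idx <- which(below[-length(trace)] & !below[-1])
  t_cross <- vapply(idx, function(i) {
    v0 <- trace[i]; v1 <- trace[i + 1]
    time[i] + (threshold - v0) / (v1 - v0) * (time[i + 1] - time[i])
  }, 0)
  structure(t_cross, class = "nml_spike_train")
}

#' Compare two runs by spike timing
#'
#' The cross-run convergence measure: after checking the two trains have
#' the same spike count, spikes are matched in order and the maximum
#' absolute timing difference is expressed as a percentage of the run
#' time. Two runs of one model are considered convergent when counts match
#' and the discrepancy is at most 0.5 % of the run time (e.g. spikes at
#' 200 ms differing by no more than 1 ms). When counts differ the
#' mismatch is reported, not raised; the discrepancy is then computed over
#' the first `min(n_a, n_b)` spikes.
#'
#' @param train_a,train_b spike-time vectors (ms).
#' @param run_time total run time (ms).
#' @return list with `same_count`, `n_a`, `n_b`,
#'   `max_discrepancy_percent`.
#' @export
compare_runs <- function(train_a, train_b, run_time) {
  a <- as.numeric(train_a); b <- as.numeric(train_b)
  k <- min(length(a), length(b))
  disc <- if (k == 0) 0 else max(abs(a[seq_len(k)] - b[seq_len(k)]))
  list(same_count = length(a) == length(b),
       n_a = length(a), n_b = length(b),
       max_discrepancy_percent = 100 * disc / run_time)
}
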