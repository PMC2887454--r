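# XML parsing. Built on xml2; the default namespace is stripped after read
# so element access is by local name. Parsing is deliberately lenient about
# *invariant* violations (negative gate instances, decay fractions that do
# not sum to one, ...): those become validation-report entries rather than
# parse crashes, so a validator run can enumerate every problem in a file.
# Reference errors, however, abort parse_document() -- its contract is a
# fully resolved document.

#' Parse a NeuroML document
#'
#' @param source XML text (anything starting with `<`) or a file path.
#' @param expected_level optional level 1-3; a document declaring a higher
#'   level is rejected.
#' @return an [nml_document()] with all magnitudes converted to the internal
#'   Physiological set; unknown elements are preserved opaquely (and listed
#'   in `$warnings`), not silently dropped.
#' @export
parse_document <- function(source, expected_level = NULL) {
  x <- tryCatch(xml2::read_xml(source),
                error = function(e) stop("XML parse error: ",
                                         conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(x)
  if (xml2::xml_name(x) != "neuroml")
    stop("root element is <", xml2::xml_name(x), ">, expected <neuroml>")

  units_attr <- xml2::xml_attr(x, "units")
  S <- parse_units_label(units_attr)
  if (is.na(S)) stop("unknown unit system: ", units_attr)
  level <- suppressWarnings(as.integer(xml2::xml_attr(x, "level")))
  if (is.na(level)) level <- 1L
  if (!is.null(expected_level) && level > expected_level)
    stop("document declares Level ", level, ", expected Level <= ",
         expected_level)

  warnings <- character(0)
  unknown <- list()
  conflicts <- character(0)
  note_unknown <- function(node, at, path) {
    unknown[[length(unknown) + 1L]] <<- list(at = at,
                                             xml = as.character(node))
    warnings <<- c(warnings,
                   paste0("unknown element <", xml2::xml_name(node),
                          "> at ", path, " (preserved verbatim)"))
  }
  check_units_override <- function(node, path) {
    u <- xml2::xml_attr(node, "units")
    if (!is.na(u)) {
      s2 <- parse_units_label(u)
      if (is.na(s2) || s2 != S)
        conflicts <<- c(conflicts,
                        paste0(path, ": declares '", u,
                               "' inside a ", S, " document"))
    }
  }

  metadata <- NULL
  cells <- list(); channels <- list(); pools <- list(); synapses <- list()
  network <- NULL

  for (node in xml2::xml_children(x)) {
    nm <- xml2::xml_name(node)
    if (nm == "metadata") {
      metadata <- parse_metadata(node)
    } else if (nm == "cells") {
      for (cn in xml2::xml_children(node)) {
        if (xml2::xml_name(cn) == "cell") {
          cells[[length(cells) + 1L]] <- parse_cell(cn, S)
        } else note_unknown(cn, "cells", "neuroml/cells")
      }
    } else if (nm == "channels") {
      for (cn in xml2::xml_children(node)) {
        cnm <- xml2::xml_name(cn)
        if (cnm == "channel_type") {
          check_units_override(cn, paste0("channel_type[",
                                          xml2::xml_attr(cn, "id"), "]"))
          channels[[length(channels) + 1L]] <- parse_channel(cn, S)
        } else if (cnm == "ion_concentration") {
          pools[[length(pools) + 1L]] <- parse_pool(cn, S)
        } else note_unknown(cn, "channels", "neuroml/channels")
      }
    } else if (nm == "synapses") {
      for (cn in xml2::xml_children(node)) {
        if (xml2::xml_name(cn) == "synapse_type") {
          check_units_override(cn, paste0("synapse_type[",
                                          xml2::xml_attr(cn, "id"), "]"))
          synapses[[length(synapses) + 1L]] <- parse_synapse(cn, S)
        } else note_unknown(cn, "synapses", "neuroml/synapses")
      }
    } else if (nm == "network") {
      network <- parse_network(node, S)
    } else {
      note_unknown(node, "root", "neuroml")
    }
  }

  doc <- nml_document(level = level, unit_system = S, metadata = metadata,
                      cells = cells, channels = channels, ion_pools = pools,
                      synapses = synapses, network = network)
  doc$unknown <- unknown
  doc$warnings <- warnings
  doc$unit_conflicts <- conflicts
  rep <- validate_document(doc)
  refs <- rep$message[rep$severity == "error" & rep$class == "reference"]
  if (length(refs) > 0)
    stop("unresolved references:\n  ", paste(refs, collapse = "\n  "),
         call. = FALSE)
  if (length(conflicts) > 0)
    stop("mixed unit systems:\n  ", paste(conflicts, collapse = "\n  "),
         call. = FALSE)
  doc
}

parse_units_label <- function(u) {
  if (is.na(u)) return("Physiological")
  switch(tolower(trimws(sub("Units$", "", u, ignore.case = TRUE))),
         "si" = "SI",
         "physiological" = "Physiological",
         NA_character_)
}

num_attr <- function(node, name, default = NA_real_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) return(default)
  suppressWarnings(as.numeric(v))
}

chr_attr <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

split_groups <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return("all")
  strsplit(trimws(s), "\\s+")[[1]]
}

parse_metadata <- function(node) {
  authors <- list(); translators <- list(); pubs <- character()
  refs <- list(); comments <- NULL; status <- NULL
  person <- function(p) list(name = chr_attr(p, "name"),
                             institution = chr_attr(p, "institution"))
  for (cn in xml2::xml_children(node)) {
    nm <- xml2::xml_name(cn)
    if (nm == "authors") {
      authors <- lapply(xml2::xml_children(cn), person)
    } else if (nm == "translators") {
      translators <- lapply(xml2::xml_children(cn), person)
    } else if (nm == "publication") {
      pubs <- c(pubs, xml2::xml_text(cn))
    } else if (nm == "database_ref") {
      refs[[length(refs) + 1L]] <- list(database = chr_attr(cn, "database"),
                                        accession = chr_attr(cn, "accession"))
    } else if (nm == "comments") {
      comments <- xml2::xml_text(cn)
    } else if (nm == "status") {
      status <- list(value = chr_attr(cn, "value"),
                     notes = xml2::xml_text(cn))
    }
  }
  nml_metadata(authors, translators, pubs, refs, comments, status)
}

parse_point <- function(node, S) {
  list(x = conv_in(num_attr(node, "x"), "length", S),
       y = conv_in(num_attr(node, "y"), "length", S),
       z = conv_in(num_attr(node, "z"), "length", S),
       diameter = conv_in(num_attr(node, "diameter"), "length", S))
}

parse_cell <- function(node, S) {
  id <- chr_attr(node, "id")
  segments <- list(); cables <- list(); metadata <- NULL
  bio <- NULL; connectivity <- list()
  for (cn in xml2::xml_children(node)) {
    nm <- xml2::xml_name(cn)
    if (nm == "metadata") metadata <- parse_metadata(cn)
    if (nm == "segments") {
      for (sn in xml2::xml_children(cn)) {
        prox <- xml2::xml_find_first(sn, "./proximal")
        dist <- xml2::xml_find_first(sn, "./distal")
        par <- chr_attr(sn, "parent")
        segments[[length(segments) + 1L]] <- structure(list(
          id = chr_attr(sn, "id"), name = nullable_chr(sn, "name"),
          distal = if (!inherits(dist, "xml_missing")) parse_point(dist, S),
          proximal = if (!inherits(prox, "xml_missing"))
            parse_point(prox, S),
          parent = par, cable = chr_attr(sn, "cable")),
          class = "nml_segment")
      }
    }
    if (nm == "cables") {
      for (bn in xml2::xml_children(cn)) {
        grps <- vapply(xml2::xml_find_all(bn, "./group"), xml2::xml_text, "")
        cables[[length(cables) + 1L]] <- structure(list(
          id = chr_attr(bn, "id"), name = chr_attr(bn, "name"),
          groups = as.character(grps),
          internal_divisions =
            as.integer(num_attr(bn, "internal_divisions", 1))),
          class = "nml_cable")
      }
    }
    if (nm == "biophysics") bio <- cn
    if (nm == "connectivity") {
      for (pn in xml2::xml_find_all(cn, "./potential_syn_loc"))
        connectivity[[length(connectivity) + 1L]] <-
          list(synapse = chr_attr(pn, "synapse"),
               groups = split_groups(chr_attr(pn, "group")))
    }
  }
  morph <- nml_cell(id, segments, cables, metadata)
  if (is.null(bio) && length(connectivity) == 0) return(morph)

  cm <- list(list(value = 1, groups = "all"))
  ra <- list(list(value = 0.1, groups = "all"))
  placements <- list(); ion_pools <- list(); iaf <- NULL
  init_v <- -65
  if (!is.null(bio)) {
    cm <- list(); ra <- list()
    for (bn in xml2::xml_children(bio)) {
      nm <- xml2::xml_name(bn)
      if (nm == "specific_capacitance")
        cm[[length(cm) + 1L]] <- list(
          value = conv_in(num_attr(bn, "value"), "specific-capacitance", S),
          groups = split_groups(chr_attr(bn, "group")))
      if (nm == "axial_resistivity")
        ra[[length(ra) + 1L]] <- list(
          value = conv_in(num_attr(bn, "value"), "resistivity", S),
          groups = split_groups(chr_attr(bn, "group")))
      if (nm == "init_potential")
        init_v <- conv_in(num_attr(bn, "value"), "voltage", S)
      if (nm == "mechanism") {
        vp_node <- xml2::xml_find_first(bn, "./variable_parameter")
        if (!inherits(vp_node, "xml_missing")) {
          vp <- nml_variable_parameter(
            parameter = chr_attr(vp_node, "parameter", "gmax"),
            expression = chr_attr(vp_node, "expression"),
            metric = chr_attr(vp_node, "metric"),
            groups = split_groups(chr_attr(vp_node, "group")))
          placements[[length(placements) + 1L]] <-
            list(channel = chr_attr(bn, "channel"), vp = vp,
                 groups = vp$groups)
        } else {
          placements[[length(placements) + 1L]] <- list(
            channel = chr_attr(bn, "channel"),
            density = conv_in(num_attr(bn, "density"),
                              "specific-conductance", S),
            groups = split_groups(chr_attr(bn, "group")))
        }
      }
      if (nm == "ion_pool")
        ion_pools[[length(ion_pools) + 1L]] <-
          list(pool = chr_attr(bn, "pool"),
               groups = split_groups(chr_attr(bn, "group")))
      if (nm == "integrate_and_fire")
        iaf <- structure(list(
          threshold = conv_in(num_attr(bn, "threshold"), "voltage", S),
          reset = conv_in(num_attr(bn, "reset"), "voltage", S),
          refractory = conv_in(num_attr(bn, "refractory"), "time", S),
          g_leak = conv_in(num_attr(bn, "g_leak"), "conductance", S),
          e_leak = conv_in(num_attr(bn, "e_leak"), "voltage", S)),
          class = "nml_iaf")
    }
    if (length(cm) == 0) cm <- list(list(value = 1, groups = "all"))
    if (length(ra) == 0) ra <- list(list(value = 0.1, groups = "all"))
  }
  structure(list(morphology = morph, specific_capacitance = cm,
                 axial_resistivity = ra, placements = placements,
                 init_potential = init_v, ion_pools = ion_pools,
                 connectivity = connectivity, iaf = iaf),
            class = "nml_biophysical_cell")
}

nullable_chr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

parse_rate <- function(node, S) {
  form <- chr_attr(node, "form")
  if (identical(form, "generic")) {
    structure(list(form = "generic", A = NULL, k = NULL, d = NULL,
                   expression = parse_expr(chr_attr(node, "expression"),
                                           vars = c("v", "ca", "celsius"))),
              class = "nml_rate_law")
  } else {
    structure(list(form = form,
                   A = conv_in_inv(num_attr(node, "A"), "time", S),
                   k = conv_in_inv(num_attr(node, "k"), "voltage", S),
                   d = conv_in(num_attr(node, "d"), "voltage", S),
                   expression = NULL),
              class = "nml_rate_law")
  }
}

parse_channel <- function(node, S) {
  gates <- list(); scheme <- NULL; q10 <- NULL
  for (cn in xml2::xml_children(node)) {
    nm <- xml2::xml_name(cn)
    if (nm == "q10")
      q10 <- structure(list(q10_factor = num_attr(cn, "factor"),
                            experimental_temp =
                              num_attr(cn, "experimental_temp")),
                       class = "nml_q10")
    if (nm == "gate") {
      fwd <- parse_rate(xml2::xml_find_first(cn, "./forward"), S)
      bwd <- parse_rate(xml2::xml_find_first(cn, "./backward"), S)
      gates[[length(gates) + 1L]] <- structure(list(
        name = chr_attr(cn, "name"),
        instances = as.integer(num_attr(cn, "instances", 1)),
        forward = fwd, backward = bwd,
        ligand = identical(chr_attr(cn, "ligand"), "true")),
        class = "nml_gate")
    }
    if (nm == "kinetic_scheme") {
      sts <- xml2::xml_find_all(cn, "./state")
      states <- data.frame(
        name = vapply(sts, chr_attr, "", name = "name"),
        open = vapply(sts, function(s)
          identical(chr_attr(s, "open"), "true"), TRUE),
        stringsAsFactors = FALSE)
      trans <- lapply(xml2::xml_find_all(cn, "./transition"), function(tn)
        list(from = chr_attr(tn, "from"), to = chr_attr(tn, "to"),
             rate = parse_rate(xml2::xml_find_first(tn, "./rate"), S)))
      scheme <- structure(list(states = states, transitions = trans),
                          class = "nml_kinetic_scheme")
    }
  }
  if (length(gates) > 0) names(gates) <- vapply(gates, `[[`, "", "name")
  structure(list(id = chr_attr(node, "id"),
                 gmax_density = conv_in(num_attr(node, "cond_density"),
                                        "specific-conductance", S),
                 erev = conv_in(num_attr(node, "reversal_potential"),
                                "voltage", S),
                 gates = if (length(gates) > 0) gates,
                 scheme = scheme, q10 = q10,
                 passive = identical(chr_attr(node, "passive"), "true"),
                 ion = chr_attr(node, "ion", "non_specific")),
            class = "nml_channel")
}

parse_pool <- function(node, S) {
  structure(list(id = chr_attr(node, "id"),
                 resting = conv_in(num_attr(node, "resting"),
                                   "concentration", S),
                 tau = conv_in(num_attr(node, "tau"), "time", S),
                 phi = conv_in_phi(num_attr(node, "phi"), S)),
            class = "nml_ca_pool")
}

parse_synapse <- function(node, S) {
  id <- chr_attr(node, "id")
  body <- xml2::xml_children(node)[[1]]
  parse_synapse_body(body, id, S)
}

parse_synapse_body <- function(node, id, S) {
  nm <- xml2::xml_name(node)
  if (nm == "doub_exp_syn") {
    dn <- xml2::xml_find_all(node, "./decay")
    decays <- data.frame(
      tau = vapply(dn, function(d) conv_in(num_attr(d, "tau"), "time", S), 0),
      fraction = vapply(dn, num_attr, 0, name = "fraction"))
    mg <- xml2::xml_find_first(node, "./mg_block")
    block <- if (!inherits(mg, "xml_missing"))
      structure(list(
        mg_concentration = conv_in(num_attr(mg, "mg_concentration"),
                                   "concentration", S),
        eta = conv_in_inv(num_attr(mg, "eta"), "concentration", S),
        gamma = conv_in_inv(num_attr(mg, "gamma"), "voltage", S)),
        class = "nml_mg_block")
    raw <- structure(list(id = id,
                          gmax = conv_in(num_attr(node, "gmax"),
                                         "conductance", S),
                          erev = conv_in(num_attr(node, "erev"),
                                         "voltage", S),
                          rise = conv_in(num_attr(node, "rise"), "time", S),
                          decays = decays, mg_block = block,
                          norm = 1, t_peak = 0),
                     class = "nml_double_exp_synapse")
    # recompute normalization when the waveform is well-formed; otherwise
    # leave it for the validator to report
    ok <- nrow(decays) >= 1 && all(is.finite(decays$tau)) &&
      all(decays$tau > 0) && is.finite(raw$rise) && raw$rise >= 0 &&
      abs(sum(decays$fraction) - 1) <= 1e-9
    if (ok && raw$rise > 0) {
      rebuilt <- nml_double_exp_synapse(id, raw$gmax, raw$erev, raw$rise,
                                        decays, block)
      raw$norm <- rebuilt$norm; raw$t_peak <- rebuilt$t_peak
    }
    raw
  } else if (nm == "stp_syn") {
    base <- parse_synapse_body(xml2::xml_children(node)[[1]], id, S)
    structure(list(base = base, U = num_attr(node, "U"),
                   tau_rec = conv_in(num_attr(node, "tau_rec"), "time", S),
                   tau_fac = conv_in(num_attr(node, "tau_fac"), "time", S)),
              class = "nml_stp_synapse")
  } else if (nm == "stdp_syn") {
    structure(list(id = id, w_max = num_attr(node, "w_max"),
                   A_plus = num_attr(node, "A_plus"),
                   A_minus = num_attr(node, "A_minus"),
                   tau_plus = conv_in(num_attr(node, "tau_plus"), "time", S),
                   tau_minus = conv_in(num_attr(node, "tau_minus"),
                                       "time", S),
                   w0 = num_attr(node, "w0")),
              class = "nml_stdp_synapse")
  } else if (nm == "gap_junction") {
    structure(list(id = id,
                   conductance = conv_in(num_attr(node, "conductance"),
                                         "conductance", S)),
              class = "nml_gap_junction")
  } else stop("unknown synapse body element <", nm, ">")
}

parse_network <- function(node, S) {
  pops <- list(); prjs <- list(); inps <- list()
  kind <- chr_attr(node, "kind", "instance")
  seed <- num_attr(node, "seed", NA_real_)
  for (cn in xml2::xml_children(node)) {
    nm <- xml2::xml_name(cn)
    if (nm == "population") {
      tmpl <- xml2::xml_find_first(cn, "./template")
      if (!inherits(tmpl, "xml_missing")) {
        shape <- chr_attr(tmpl, "shape")
        region <- if (shape == "box") {
          list(shape = "box",
               x0 = conv_in(num_attr(tmpl, "x0"), "length", S),
               y0 = conv_in(num_attr(tmpl, "y0"), "length", S),
               z0 = conv_in(num_attr(tmpl, "z0"), "length", S),
               dx = conv_in(num_attr(tmpl, "dx"), "length", S),
               dy = conv_in(num_attr(tmpl, "dy"), "length", S),
               dz = conv_in(num_attr(tmpl, "dz"), "length", S))
        } else {
          list(shape = "cylinder",
               x0 = conv_in(num_attr(tmpl, "x0"), "length", S),
               y0 = conv_in(num_attr(tmpl, "y0"), "length", S),
               z0 = conv_in(num_attr(tmpl, "z0"), "length", S),
               radius = conv_in(num_attr(tmpl, "radius"), "length", S),
               height = conv_in(num_attr(tmpl, "height"), "length", S))
        }
        pops[[length(pops) + 1L]] <- nml_template_population(
          chr_attr(cn, "name"), chr_attr(cn, "cell_type"),
          as.integer(num_attr(tmpl, "count")), region,
          min_separation = conv_in(num_attr(tmpl, "min_separation", 0),
                                   "length", S))
      } else {
        ins <- xml2::xml_find_all(cn, "./instances/instance")
        df <- data.frame(
          index = as.integer(xml2::xml_attr(ins, "id")),
          x = conv_in(as.numeric(xml2::xml_attr(ins, "x")), "length", S),
          y = conv_in(as.numeric(xml2::xml_attr(ins, "y")), "length", S),
          z = conv_in(as.numeric(xml2::xml_attr(ins, "z")), "length", S),
          node_id = suppressWarnings(
            as.integer(xml2::xml_attr(ins, "node_id"))))
        pops[[length(pops) + 1L]] <- nml_population(
          chr_attr(cn, "name"), chr_attr(cn, "cell_type"), df)
      }
    }
    if (nm == "projection") {
      co <- xml2::xml_find_all(cn, "./connections/connection")
      df <- data.frame(
        pre_cell = as.integer(xml2::xml_attr(co, "pre_cell")),
        pre_segment = xml2::xml_attr(co, "pre_segment"),
        pre_fraction = as.numeric(xml2::xml_attr(co, "pre_fraction")),
        post_cell = as.integer(xml2::xml_attr(co, "post_cell")),
        post_segment = xml2::xml_attr(co, "post_segment"),
        post_fraction = as.numeric(xml2::xml_attr(co, "post_fraction")),
        weight = as.numeric(xml2::xml_attr(co, "weight")),
        delay = conv_in(as.numeric(xml2::xml_attr(co, "delay")), "time", S),
        stringsAsFactors = FALSE)
      prjs[[length(prjs) + 1L]] <- nml_projection(
        chr_attr(cn, "name"), chr_attr(cn, "source"),
        chr_attr(cn, "target"), chr_attr(cn, "synapse"), df,
        electrical = identical(chr_attr(cn, "electrical"), "true"))
    }
    if (nm == "input") {
      params <- list()
      if (!is.na(num_attr(cn, "amplitude")))
        params$amplitude <- conv_in(num_attr(cn, "amplitude"), "current", S)
      if (!is.na(num_attr(cn, "amplitude_min")))
        params$amplitude_range <- conv_in(
          c(num_attr(cn, "amplitude_min"), num_attr(cn, "amplitude_max")),
          "current", S)
      if (!is.na(num_attr(cn, "delay")))
        params$delay <- conv_in(num_attr(cn, "delay"), "time", S)
      if (!is.na(num_attr(cn, "duration")))
        params$duration <- conv_in(num_attr(cn, "duration"), "time", S)
      if (!is.na(num_attr(cn, "rate"))) params$rate <- num_attr(cn, "rate")
      if (!is.na(chr_attr(cn, "synapse")))
        params$synapse <- chr_attr(cn, "synapse")
      if (!is.na(chr_attr(cn, "segment")))
        params$segment <- chr_attr(cn, "segment")
      inps[[length(inps) + 1L]] <- nml_network_input(
        chr_attr(cn, "name"), chr_attr(cn, "kind"),
        chr_attr(cn, "population"), params)
    }
  }
  net <- nml_network(pops, prjs, inps,
                     seed = if (is.na(seed)) NULL else as.integer(seed))
  if (kind == "template" && !net$template)
    class(net) <- c("nml_network_template", class(net))
  net
}
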