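# XML serialization. The writer builds the document as text (vectorized for
# the large instance lists of NetworkML) and targets the NeuroML v1.8.1
# dialect: default namespace and schema version are stamped on the root.

NML_NAMESPACE <- "http://morphml.org/neuroml/schema"
NML_SCHEMA_VERSION <- "1.8.1"

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g", width = 1)
  out[is.na(x)] <- NA_character_
  trimws(out)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# attribute string from a named list, dropping NULL/NA entries
attrs <- function(...) {
  a <- list(...)
  a <- a[!vapply(a, function(v) is.null(v) || (length(v) == 1 && is.na(v)),
                 TRUE)]
  if (length(a) == 0L) return("")
  vals <- vapply(a, function(v)
    if (is.numeric(v)) fmt_num(v) else xml_escape(as.character(v)), "")
  paste0(" ", paste0(names(a), "=\"", vals, "\"", collapse = " "))
}

tag <- function(.name, ..., children = NULL, text = NULL) {
  at <- attrs(...)
  if (is.null(children) && is.null(text))
    return(paste0("<", .name, at, "/>"))
  inner <- if (!is.null(text)) xml_escape(text) else
    paste0(children, collapse = "\n")
  paste0("<", .name, at, ">", if (is.null(text)) "\n" else "", inner,
         if (is.null(text)) "\n" else "", "</", .name, ">")
}

#' Serialize a document to NeuroML XML
#'
#' The document must validate cleanly (errors refuse serialization with the
#' validation report attached). All magnitudes are converted to
#' `target_system` on the way out; generic rate-law and variable-parameter
#' expressions are written verbatim and are therefore only meaningful in
#' the unit system they were authored in (a documented limitation).
#' Serializing then re-parsing yields a structurally equal document.
#'
#' @param doc an [nml_document()].
#' @param target_system `"SI"` or `"Physiological"`.
#' @param file optional path to write to.
#' @return the XML text, invisibly when `file` is given.
#' @export
serialize_document <- function(doc, target_system = doc$unit_system,
                               file = NULL) {
  stopifnot(inherits(doc, "nml_document"))
  target_system <- match.arg(target_system, c("SI", "Physiological"))
  rep <- validate_document(doc)
  if (any(rep$severity == "error")) {
    stop("document does not validate:\n",
         paste(utils::capture.output(print(rep)), collapse = "\n"))
  }
  S <- target_system
  parts <- character(0)
  if (!metadata_is_empty(doc$metadata))
    parts <- c(parts, ser_metadata(doc$metadata))
  if (length(doc$cells) > 0)
    parts <- c(parts, tag("cells", children = c(
      vapply(doc$cells, ser_cell, "", S = S),
      unknown_at(doc, "cells"))))
  if (length(doc$channels) + length(doc$ion_pools) > 0)
    parts <- c(parts, tag("channels", children = c(
      vapply(doc$channels, ser_channel, "", S = S),
      vapply(doc$ion_pools, ser_pool, "", S = S),
      unknown_at(doc, "channels"))))
  if (length(doc$synapses) > 0)
    parts <- c(parts, tag("synapses", children = c(
      vapply(doc$synapses, ser_synapse, "", S = S),
      unknown_at(doc, "synapses"))))
  if (!is.null(doc$network))
    parts <- c(parts, ser_network(doc$network, S))
  parts <- c(parts, unknown_at(doc, "root"))

  units_label <- if (S == "SI") "SI Units" else "Physiological Units"
  out <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    tag("neuroml", xmlns = NML_NAMESPACE,
        schema_version = NML_SCHEMA_VERSION,
        level = doc$level, units = units_label,
        children = parts), "\n")
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}

unknown_at <- function(doc, where) {
  kept <- Filter(function(u) identical(u$at, where), doc$unknown)
  vapply(kept, `[[`, "", "xml")
}

ser_metadata <- function(md) {
  ch <- character(0)
  person <- function(p) tag("person", name = p$name,
                            institution = p$institution)
  if (length(md$authors))
    ch <- c(ch, tag("authors", children = vapply(md$authors, person, "")))
  if (length(md$translators))
    ch <- c(ch, tag("translators",
                    children = vapply(md$translators, person, "")))
  for (p in md$publications)
    ch <- c(ch, tag("publication", text = p))
  for (r in md$database_refs)
    ch <- c(ch, tag("database_ref", database = r$database,
                    accession = r$accession))
  if (!is.null(md$comments)) ch <- c(ch, tag("comments", text = md$comments))
  if (!is.null(md$status))
    ch <- c(ch, tag("status", value = md$status$value,
                    text = md$status$notes))
  tag("metadata", children = ch)
}

ser_point <- function(name, p, S) {
  tag(name, x = conv_out(p$x, "length", S), y = conv_out(p$y, "length", S),
      z = conv_out(p$z, "length", S),
      diameter = conv_out(p$diameter, "length", S))
}

ser_cell <- function(cell, S) {
  bio <- inherits(cell, "nml_biophysical_cell")
  morph <- cell_morphology(cell)
  segs <- vapply(morph$segments, function(s) {
    ch <- character(0)
    if (!is.null(s$proximal)) ch <- c(ch, ser_point("proximal", s$proximal, S))
    ch <- c(ch, ser_point("distal", s$distal, S))
    tag("segment", id = s$id, name = s$name,
        parent = if (is.na(s$parent)) NULL else s$parent,
        cable = s$cable, children = ch)
  }, "")
  cabs <- vapply(morph$cables, function(cb) {
    tag("cable", id = cb$id, name = cb$name,
        internal_divisions = cb$internal_divisions,
        children = if (length(cb$groups))
          vapply(cb$groups, function(g) tag("group", text = g), "")
        else NULL)
  }, "")
  ch <- c(
    if (!metadata_is_empty(morph$metadata)) ser_metadata(morph$metadata),
    tag("segments", children = segs),
    tag("cables", children = cabs))
  if (bio) ch <- c(ch, ser_biophysics(cell, S))
  if (bio && length(cell$connectivity) > 0)
    ch <- c(ch, tag("connectivity", children = vapply(
      cell$connectivity, function(cn)
        tag("potential_syn_loc", synapse = cn$synapse,
            group = paste(cn$groups, collapse = " ")), "")))
  tag("cell", id = morph$id, children = ch)
}

ser_biophysics <- function(cell, S) {
  ch <- c(
    vapply(cell$specific_capacitance, function(r)
      tag("specific_capacitance",
          value = conv_out(r$value, "specific-capacitance", S),
          group = paste(r$groups, collapse = " ")), ""),
    vapply(cell$axial_resistivity, function(r)
      tag("axial_resistivity",
          value = conv_out(r$value, "resistivity", S),
          group = paste(r$groups, collapse = " ")), ""),
    tag("init_potential",
        value = conv_out(cell$init_potential, "voltage", S)))
  ch <- c(ch, vapply(cell$placements, function(pl) {
    if (!is.null(pl$vp)) {
      vp <- pl$vp
      tag("mechanism", channel = pl$channel,
          children = tag("variable_parameter", parameter = vp$parameter,
                         metric = vp$metric,
                         expression = vp$expression$source,
                         group = paste(vp$groups, collapse = " ")))
    } else {
      tag("mechanism", channel = pl$channel,
          density = conv_out(pl$density, "specific-conductance", S),
          group = paste(pl$groups, collapse = " "))
    }
  }, ""))
  ch <- c(ch, vapply(cell$ion_pools, function(ip)
    tag("ion_pool", pool = ip$pool,
        group = paste(ip$groups, collapse = " ")), ""))
  if (!is.null(cell$iaf)) {
    f <- cell$iaf
    ch <- c(ch, tag("integrate_and_fire",
                    threshold = conv_out(f$threshold, "voltage", S),
                    reset = conv_out(f$reset, "voltage", S),
                    refractory = conv_out(f$refractory, "time", S),
                    g_leak = conv_out(f$g_leak, "conductance", S),
                    e_leak = conv_out(f$e_leak, "voltage", S)))
  }
  tag("biophysics", children = ch)
}

ser_rate <- function(name, law, S) {
  if (law$form == "generic")
    return(tag(name, form = "generic", expression = law$expression$source))
  tag(name, form = law$form,
      A = conv_out_inv(law$A, "time", S),
      k = conv_out_inv(law$k, "voltage", S),
      d = conv_out(law$d, "voltage", S))
}

ser_channel <- function(chn, S) {
  ch <- character(0)
  if (!is.null(chn$q10))
    ch <- c(ch, tag("q10", factor = chn$q10$q10_factor,
                    experimental_temp = chn$q10$experimental_temp))
  if (chn$passive) {
    # no gating children
  } else if (!is.null(chn$gates)) {
    ch <- c(ch, vapply(chn$gates, function(g)
      tag("gate", name = g$name, instances = g$instances,
          ligand = tolower(as.character(g$ligand)),
          children = c(ser_rate("forward", g$forward, S),
                       ser_rate("backward", g$backward, S))), ""))
  } else {
    sc <- chn$scheme
    states <- vapply(seq_len(nrow(sc$states)), function(i)
      tag("state", name = sc$states$name[i],
          open = tolower(as.character(sc$states$open[i]))), "")
    trans <- vapply(sc$transitions, function(tr)
      tag("transition", from = tr$from, to = tr$to,
          children = ser_rate("rate", tr$rate, S)), "")
    ch <- c(ch, tag("kinetic_scheme", children = c(states, trans)))
  }
  tag("channel_type", id = chn$id,
      cond_density = conv_out(chn$gmax_density, "specific-conductance", S),
      reversal_potential = conv_out(chn$erev, "voltage", S),
      passive = tolower(as.character(chn$passive)), ion = chn$ion,
      children = if (length(ch)) ch else NULL)
}

ser_pool <- function(pool, S) {
  tag("ion_concentration", id = pool$id,
      resting = conv_out(pool$resting, "concentration", S),
      tau = conv_out(pool$tau, "time", S),
      phi = conv_out_phi(pool$phi, S))
}

ser_synapse <- function(syn, S) {
  body <- ser_synapse_body(syn, S)
  tag("synapse_type", id = synapse_id(syn), children = body)
}

ser_synapse_body <- function(syn, S) {
  if (inherits(syn, "nml_double_exp_synapse")) {
    ch <- vapply(seq_len(nrow(syn$decays)), function(i)
      tag("decay", tau = conv_out(syn$decays$tau[i], "time", S),
          fraction = syn$decays$fraction[i]), "")
    if (!is.null(syn$mg_block)) {
      b <- syn$mg_block
      ch <- c(ch, tag("mg_block",
                      mg_concentration = conv_out(b$mg_concentration,
                                                  "concentration", S),
                      eta = conv_out_inv(b$eta, "concentration", S),
                      gamma = conv_out_inv(b$gamma, "voltage", S)))
    }
    tag("doub_exp_syn", gmax = conv_out(syn$gmax, "conductance", S),
        erev = conv_out(syn$erev, "voltage", S),
        rise = conv_out(syn$rise, "time", S), children = ch)
  } else if (inherits(syn, "nml_stp_synapse")) {
    tag("stp_syn", U = syn$U,
        tau_rec = conv_out(syn$tau_rec, "time", S),
        tau_fac = conv_out(syn$tau_fac, "time", S),
        children = ser_synapse_body(syn$base, S))
  } else if (inherits(syn, "nml_stdp_synapse")) {
    tag("stdp_syn", w_max = syn$w_max, A_plus = syn$A_plus,
        A_minus = syn$A_minus,
        tau_plus = conv_out(syn$tau_plus, "time", S),
        tau_minus = conv_out(syn$tau_minus, "time", S), w0 = syn$w0)
  } else if (inherits(syn, "nml_gap_junction")) {
    tag("gap_junction",
        conductance = conv_out(syn$conductance, "conductance", S))
  } else stop("unknown synapse class")
}

ser_network <- function(net, S) {
  pops <- vapply(net$populations, function(p) {
    if (inherits(p, "nml_template_population")) {
      r <- p$region
      tag("population", name = p$name, cell_type = p$cell_type,
          children = tag("template", count = p$count, shape = r$shape,
                         x0 = conv_out(r$x0, "length", S),
                         y0 = conv_out(r$y0, "length", S),
                         z0 = conv_out(r$z0, "length", S),
                         dx = if (r$shape == "box") conv_out(r$dx, "length", S) else NULL,
                         dy = if (r$shape == "box") conv_out(r$dy, "length", S) else NULL,
                         dz = if (r$shape == "box") conv_out(r$dz, "length", S) else NULL,
                         radius = if (r$shape == "cylinder") conv_out(r$radius, "length", S) else NULL,
                         height = if (r$shape == "cylinder") conv_out(r$height, "length", S) else NULL,
                         min_separation = conv_out(p$min_separation,
                                                   "length", S)))
    } else {
      ins <- p$instances
      # vectorized: instance lists dominate large network files
      node_attr <- ifelse(is.na(ins$node_id), "",
                          sprintf(" node_id=\"%d\"", ins$node_id))
      rows <- sprintf("<instance id=\"%s\" x=\"%s\" y=\"%s\" z=\"%s\"%s/>",
                      ins$index, fmt_num(conv_out(ins$x, "length", S)),
                      fmt_num(conv_out(ins$y, "length", S)),
                      fmt_num(conv_out(ins$z, "length", S)), node_attr)
      tag("population", name = p$name, cell_type = p$cell_type,
          children = tag("instances", size = nrow(ins), children = rows))
    }
  }, "")
  prjs <- vapply(net$projections, function(pr) {
    cn <- pr$connections
    rows <- sprintf(paste0(
      "<connection id=\"%d\" pre_cell=\"%s\"%s pre_fraction=\"%s\"",
      " post_cell=\"%s\"%s post_fraction=\"%s\" weight=\"%s\"",
      " delay=\"%s\"/>"),
      seq_len(nrow(cn)) - 1L, cn$pre_cell,
      ifelse(is.na(cn$pre_segment), "",
             sprintf(" pre_segment=\"%s\"", cn$pre_segment)),
      fmt_num(cn$pre_fraction), cn$post_cell,
      ifelse(is.na(cn$post_segment), "",
             sprintf(" post_segment=\"%s\"", cn$post_segment)),
      fmt_num(cn$post_fraction), fmt_num(cn$weight),
      fmt_num(conv_out(cn$delay, "time", S)))
    tag("projection", name = pr$name, source = pr$source,
        target = pr$target, synapse = pr$synapse,
        electrical = tolower(as.character(pr$electrical)),
        children = tag("connections", size = nrow(cn), children = rows))
  }, "")
  inps <- vapply(net$inputs, function(ip) {
    pr <- ip$params
    tag("input", name = ip$name, kind = ip$kind,
        population = ip$population,
        amplitude = if (!is.null(pr[["amplitude"]]))
          conv_out(pr[["amplitude"]], "current", S) else NULL,
        amplitude_min = if (!is.null(pr[["amplitude_range"]]))
          conv_out(pr[["amplitude_range"]][1], "current", S) else NULL,
        amplitude_max = if (!is.null(pr[["amplitude_range"]]))
          conv_out(pr[["amplitude_range"]][2], "current", S) else NULL,
        delay = if (!is.null(pr[["delay"]]))
          conv_out(pr[["delay"]], "time", S) else NULL,
        duration = if (!is.null(pr[["duration"]]))
          conv_out(pr[["duration"]], "time", S) else NULL,
        rate = pr[["rate"]], synapse = pr[["synapse"]],
        segment = pr[["segment"]])
  }, "")
  tag("network", kind = if (net$template) "template" else "instance",
      seed = net$seed, children = c(pops, prjs, inps))
}
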