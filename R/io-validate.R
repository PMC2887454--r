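#' Validate a document
#'
#' Checks every type invariant and reference constraint of the document
#' model and returns a deterministic report ordered by document position.
#' Problems are report rows, never exceptions. Severity policy: structural
#' and reference violations are errors; stylistic issues (missing
#' provenance metadata, morphological discontinuities, zero-length
#' segments) are warnings.
#'
#' Checked, among others: every referenced id (channel in a density
#' placement, cell type in a population, synapse in a projection) resolves
#' within the document; elements respect the document's declared Level;
#' gates have positive instance counts and rate laws stay finite and
#' non-negative on the physiological voltage range (-100 to +60 mV); decay
#' fractions sum to 1; gap junction conductances are non-negative;
#' integrate-and-fire resets lie below threshold; morphologies are acyclic
#' and connected; projection targets respect the target cell's declared
#' connectivity groups.
#'
#' @param doc an [nml_document()].
#' @return an `nml_validation_report`: data frame with columns `severity`
#'   (`"error"`/`"warning"`), `class`, `path`, `message`.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "nml_document"))
  rows <- list()
  add <- function(severity, class, path, message)
    rows[[length(rows) + 1L]] <<- data.frame(
      severity = severity, class = class, path = path, message = message,
      stringsAsFactors = FALSE)

  if (!doc$level %in% 1:3)
    add("error", "schema", "neuroml", paste("illegal level:", doc$level))

  for (cf in doc$unit_conflicts)
    add("error", "units", "neuroml", paste("mixed unit systems:", cf))

  if (metadata_is_empty(doc$metadata))
    add("warning", "style", "neuroml/metadata",
        "no provenance metadata (authors, publications, status)")

  # level gating
  has_bio <- any(vapply(doc$cells, inherits, TRUE, "nml_biophysical_cell"))
  if (doc$level < 2 &&
      (has_bio || length(doc$channels) > 0 || length(doc$synapses) > 0 ||
       length(doc$ion_pools) > 0))
    add("error", "level", "neuroml",
        "Level 1 document contains Level 2 elements (biophysics/ChannelML)")
  if (doc$level < 3 && !is.null(doc$network))
    add("error", "level", "neuroml",
        "network element requires a Level 3 document")

  channel_ids <- names(doc$channels)
  pool_ids <- names(doc$ion_pools)
  synapse_ids <- names(doc$synapses)
  cell_ids <- names(doc$cells)

  for (ci in seq_along(doc$cells)) {
    cell <- doc$cells[[ci]]
    morph <- cell_morphology(cell)
    path <- paste0("neuroml/cells/cell[", morph$id, "]")

    for (seg in morph$segments) {
      if (!is.na(seg$parent) && !seg$parent %in% names(morph$segments))
        add("error", "reference", paste0(path, "/segment[", seg$id, "]"),
            paste0("parent segment id '", seg$parent, "' does not resolve"))
      if (!seg$cable %in% names(morph$cables))
        add("error", "reference", paste0(path, "/segment[", seg$id, "]"),
            paste0("cable id '", seg$cable, "' does not resolve"))
      for (pt in list(seg$proximal, seg$distal))
        if (!is.null(pt) && (!is.finite(pt$diameter) || pt$diameter < 0))
          add("error", "invariant", paste0(path, "/segment[", seg$id, "]"),
              "point diameter must be >= 0")
    }
    for (cb in morph$cables) {
      if (is.na(cb$internal_divisions) || cb$internal_divisions < 1)
        add("error", "invariant", paste0(path, "/cable[", cb$id, "]"),
            "internal_divisions must be a positive integer")
      n_in_cable <- sum(vapply(morph$segments, function(s)
        identical(s$cable, cb$id), TRUE))
      if (n_in_cable > 0) {
        ok <- tryCatch({ cable_frusta(morph, cb$id); TRUE },
                       error = function(e) FALSE)
        if (!ok)
          add("error", "invariant", paste0(path, "/cable[", cb$id, "]"),
              "cable segments do not form a single unbranched path")
      }
    }
    findings <- tryCatch(check_integrity(morph), error = function(e) NULL)
    if (!is.null(findings)) for (i in seq_len(nrow(findings))) {
      f <- findings[i, ]
      sev <- if (f$kind %in% c("cycle", "isolated-element")) "error"
      else "warning"
      add(sev, "integrity", paste0(path, "/segment[", f$segment, "]"),
          paste0(f$kind, ": ", f$detail))
    }

    if (inherits(cell, "nml_biophysical_cell")) {
      groups <- cell_all_groups(morph)
      for (pl in cell$placements) {
        if (!pl$channel %in% channel_ids)
          add("error", "reference", paste0(path, "/biophysics"),
              paste0("mechanism references undefined channel id '",
                     pl$channel, "'"))
        gg <- if (!is.null(pl$vp)) pl$vp$groups else pl$groups
        for (g in setdiff(gg, groups))
          add("error", "reference", paste0(path, "/biophysics"),
              paste0("group label '", g, "' not present on the morphology"))
        if (is.null(pl$vp) &&
            (!is.finite(pl$density) || pl$density < 0))
          add("error", "invariant", paste0(path, "/biophysics"),
              paste0("density for channel '", pl$channel,
                     "' must be finite and >= 0"))
      }
      for (ip in cell$ion_pools) {
        if (!ip$pool %in% pool_ids)
          add("error", "reference", paste0(path, "/biophysics"),
              paste0("ion_pool references undefined pool id '", ip$pool,
                     "'"))
      }
      for (cn in cell$connectivity) {
        if (length(synapse_ids) > 0 && !cn$synapse %in% synapse_ids)
          add("error", "reference", paste0(path, "/connectivity"),
              paste0("potential_syn_loc references undefined synapse id '",
                     cn$synapse, "'"))
        for (g in setdiff(cn$groups, groups))
          add("error", "reference", paste0(path, "/connectivity"),
              paste0("group label '", g, "' not present on the morphology"))
      }
      if (!is.null(cell$iaf) && !(cell$iaf$reset < cell$iaf$threshold))
        add("error", "invariant", paste0(path, "/biophysics"),
            "integrate_and_fire reset must be below threshold")
    }
  }

  vgrid <- seq(-100, 60, by = 2)
  check_rate <- function(law, path, what) {
    r <- tryCatch(evaluate_rate(law, vgrid, ca = 1e-3, temp = 20),
                  error = function(e) NULL)
    if (is.null(r))
      add("error", "invariant", path,
          paste0(what,
                 " rate law is non-finite or negative on [-100, 60] mV"))
  }
  for (chn in doc$channels) {
    path <- paste0("neuroml/channels/channel_type[", chn$id, "]")
    if (chn$passive) {
      if (!is.null(chn$gates) || !is.null(chn$scheme))
        add("error", "invariant", path,
            "a passive channel has neither gates nor a scheme")
    } else if (is.null(chn$gates) == is.null(chn$scheme)) {
      add("error", "invariant", path,
          "channel must have gates xor a kinetic scheme")
    }
    if (!is.finite(chn$gmax_density) || chn$gmax_density < 0)
      add("error", "invariant", path, "cond_density must be >= 0")
    for (g in chn$gates) {
      if (is.na(g$instances) || g$instances < 1)
        add("error", "invariant", paste0(path, "/gate[", g$name, "]"),
            "gate instance count must be a positive integer")
      check_rate(g$forward, paste0(path, "/gate[", g$name, "]"), "forward")
      check_rate(g$backward, paste0(path, "/gate[", g$name, "]"), "backward")
    }
    if (!is.null(chn$scheme)) {
      sc <- chn$scheme
      for (tr in sc$transitions) {
        if (!all(c(tr$from, tr$to) %in% sc$states$name))
          add("error", "reference", paste0(path, "/kinetic_scheme"),
              paste0("transition references unknown state '",
                     setdiff(c(tr$from, tr$to), sc$states$name)[1], "'"))
        check_rate(tr$rate, paste0(path, "/kinetic_scheme"), "transition")
      }
      if (!any(sc$states$open))
        add("warning", "invariant", paste0(path, "/kinetic_scheme"),
            "scheme has no open state; channel never conducts")
    }
    if (!is.null(chn$q10) &&
        (!is.finite(chn$q10$q10_factor) || chn$q10$q10_factor <= 0))
      add("error", "invariant", path, "q10 factor must be > 0")
  }

  for (pool in doc$ion_pools) {
    path <- paste0("neuroml/channels/ion_concentration[", pool$id, "]")
    if (!is.finite(pool$tau) || pool$tau <= 0)
      add("error", "invariant", path, "decay time constant must be > 0")
    if (!is.finite(pool$resting) || pool$resting < 0)
      add("error", "invariant", path, "resting concentration must be >= 0")
  }

  for (syn in doc$synapses) {
    path <- paste0("neuroml/synapses/synapse_type[", synapse_id(syn), "]")
    validate_synapse(syn, path, add)
  }

  if (!is.null(doc$network)) {
    net <- doc$network
    pop_names <- vapply(net$populations, `[[`, "", "name")
    pop_sizes <- vapply(net$populations, function(p)
      if (inherits(p, "nml_template_population")) p$count else
        nrow(p$instances), 0L)
    names(pop_sizes) <- pop_names
    for (p in net$populations) {
      path <- paste0("neuroml/network/population[", p$name, "]")
      if (!p$cell_type %in% cell_ids)
        add("error", "reference", path,
            paste0("population references undefined cell id '",
                   p$cell_type, "'"))
      if (!inherits(p, "nml_template_population")) {
        if (anyDuplicated(p$instances$index))
          add("error", "invariant", path, "instance indices must be unique")
      }
    }
    for (pr in net$projections) {
      path <- paste0("neuroml/network/projection[", pr$name, "]")
      if (!pr$synapse %in% synapse_ids)
        add("error", "reference", path,
            paste0("projection references undefined synapse id '",
                   pr$synapse, "'"))
      for (side in c("source", "target"))
        if (!pr[[side]] %in% pop_names)
          add("error", "reference", path,
              paste0(side, " population '", pr[[side]], "' does not exist"))
      if (pr$target %in% pop_names && nrow(pr$connections) > 0) {
        nmax <- pop_sizes[[pr$target]]
        if (any(pr$connections$post_cell < 0 |
                pr$connections$post_cell >= nmax))
          add("error", "reference", path,
              "connection post_cell index outside the target population")
        # connectivity-group restriction on the post side
        tpop <- net$populations[[match(pr$target, pop_names)]]
        tcell <- doc$cells[[tpop$cell_type]]
        if (!is.null(tcell) && inherits(tcell, "nml_biophysical_cell") &&
            length(tcell$connectivity) > 0 && pr$synapse %in%
            vapply(tcell$connectivity, `[[`, "", "synapse")) {
          allowed <- unlist(lapply(tcell$connectivity, function(cn)
            if (cn$synapse == pr$synapse) cn$groups))
          segs <- stats::na.omit(unique(pr$connections$post_segment))
          for (sg in segs) {
            grps <- tryCatch(segment_groups(cell_morphology(tcell), sg),
                             error = function(e) character(0))
            if (!any(allowed %in% grps))
              add("error", "reference", path,
                  paste0("post segment '", sg,
                         "' lies outside connectivity groups [",
                         paste(allowed, collapse = ", "), "] for synapse '",
                         pr$synapse, "'"))
          }
        }
      }
    }
    for (ip in net$inputs) {
      path <- paste0("neuroml/network/input[", ip$name, "]")
      if (!ip$population %in% pop_names)
        add("error", "reference", path,
            paste0("input targets undefined population '", ip$population,
                   "'"))
    }
  }

  for (w in doc$warnings)
    add("warning", "unknown-element", "neuroml", w)

  rep <- if (length(rows) == 0L)
    data.frame(severity = character(), class = character(),
               path = character(), message = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  class(rep) <- c("nml_validation_report", "data.frame")
  rep
}

validate_synapse <- function(syn, path, add) {
  if (inherits(syn, "nml_double_exp_synapse")) {
    if (abs(sum(syn$decays$fraction) - 1) > 1e-9)
      add("error", "invariant", path, "decay fractions must sum to 1")
    if (any(!is.finite(syn$decays$tau) | syn$decays$tau <= 0))
      add("error", "invariant", path, "decay time constants must be > 0")
    if (!is.finite(syn$rise) || syn$rise < 0)
      add("error", "invariant", path, "rise time must be >= 0")
    if (!is.finite(syn$gmax) || syn$gmax < 0)
      add("error", "invariant", path, "gmax must be >= 0")
    if (!is.null(syn$mg_block)) {
      b <- syn$mg_block
      if (any(!is.finite(c(b$mg_concentration, b$eta, b$gamma))) ||
          b$mg_concentration < 0 || b$eta < 0 || b$gamma < 0)
        add("error", "invariant", paste0(path, "/mg_block"),
            "mg_block parameters must be finite and >= 0")
    }
  } else if (inherits(syn, "nml_stp_synapse")) {
    if (!is.finite(syn$U) || syn$U < 0 || syn$U > 1)
      add("error", "invariant", path, "STP utilisation U must lie in [0,1]")
    if (syn$tau_rec < 0 || syn$tau_fac < 0)
      add("error", "invariant", path, "STP time constants must be >= 0")
    validate_synapse(syn$base, path, add)
  } else if (inherits(syn, "nml_stdp_synapse")) {
    if (!is.finite(syn$w_max) || syn$w_max <= 0)
      add("error", "invariant", path, "w_max must be > 0")
    if (syn$w0 < 0 || syn$w0 > syn$w_max)
      add("error", "invariant", path, "initial weight outside [0, w_max]")
    if (syn$tau_plus <= 0 || syn$tau_minus <= 0)
      add("error", "invariant", path, "STDP trace time constants must be > 0")
  } else if (inherits(syn, "nml_gap_junction")) {
    if (!is.finite(syn$conductance) || syn$conductance < 0)
      add("error", "invariant", path, "gap junction conductance must be >= 0")
  }
}

#' Validate XML against the bundled structural schema
#'
#' Checks element structure against the packaged XSD for the NeuroML v1.x
#' subset this package reads and writes (`inst/schema/neuroml-subset.xsd`).
#' Attributes are deliberately left open in the schema -- their magnitudes
#' depend on the document's unit system and are range-checked by
#' [validate_document()] instead.
#'
#' @param xml XML text or path.
#' @return logical; attribute `"errors"` carries libxml2 messages on
#'   failure.
#' @export
validate_xml_schema <- function(xml) {
  xsd_path <- system.file("schema", "neuroml-subset.xsd",
                          package = "cableml")
  stopifnot(nzchar(xsd_path))
  xml2::xml_validate(xml2::read_xml(xml), xml2::read_xml(xsd_path))
}

#' @export
print.nml_validation_report <- function(x, ...) {
  ne <- sum(x$severity == "error"); nw <- sum(x$severity == "warning")
  cat(sprintf("<validation report> %d error(s), %d warning(s)\n", ne, nw))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$path[i], x$message[i]))
  invisible(x)
}
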