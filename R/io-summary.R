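#' Render a human-readable document summary
#'
#' Produces a standalone HTML page listing document metadata, cells and all
#' mechanism parameters, plus one curve table per channel gate: forward
#' (alpha) and backward (beta) transition rates, the time constant
#' `tau = 1/(alpha+beta)` and the steady state `inf = alpha/(alpha+beta)`
#' sampled on a configurable voltage grid.
#'
#' @param doc an [nml_document()].
#' @param v voltage grid (mV) for the curve tables.
#' @param file optional path for the HTML; curve tables can be written
#'   alongside as tab-separated files via [write_curves()].
#' @return list with elements `html` (character scalar) and `curves` (named
#'   list of data frames `v`, `alpha`, `beta`, `tau`, `inf`, one per
#'   `channel.gate`).
#' @export
render_summary <- function(doc, v = seq(-100, 60, by = 1), file = NULL) {
  stopifnot(inherits(doc, "nml_document"))
  if (length(doc$channels) == 0 && length(doc$cells) == 0) {
    warning("document contains no channels or cells; summary is empty")
    return(list(html = "<html><body><p>empty document</p></body></html>",
                curves = list()))
  }
  esc <- xml_escape
  h <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'/>",
         "<title>NeuroML summary</title></head><body>",
         sprintf("<h1>NeuroML Level %d document (%s units)</h1>",
                 doc$level, esc(doc$unit_system)))
  if (!metadata_is_empty(doc$metadata)) {
    md <- doc$metadata
    h <- c(h, "<h2>Metadata</h2><ul>")
    for (a in md$authors)
      h <- c(h, sprintf("<li>author: %s (%s)</li>", esc(a$name),
                        esc(if (is.na(a$institution)) "" else a$institution)))
    for (a in md$translators)
      h <- c(h, sprintf("<li>translator: %s</li>", esc(a$name)))
    for (p in md$publications)
      h <- c(h, sprintf("<li>publication: %s</li>", esc(p)))
    for (r in md$database_refs)
      h <- c(h, sprintf("<li>database: %s accession %s</li>",
                        esc(r$database), esc(r$accession)))
    if (!is.null(md$comments))
      h <- c(h, sprintf("<li>comments: %s</li>", esc(md$comments)))
    if (!is.null(md$status))
      h <- c(h, sprintf("<li>status: %s</li>", esc(md$status$value)))
    h <- c(h, "</ul>")
  }
  for (cell in doc$cells) {
    morph <- cell_morphology(cell)
    h <- c(h, sprintf("<h2>Cell %s</h2>", esc(morph$id)),
           sprintf("<p>%d segments in %d cables</p>",
                   length(morph$segments), length(morph$cables)))
    if (inherits(cell, "nml_biophysical_cell")) {
      h <- c(h, "<ul>")
      for (pl in cell$placements) {
        h <- c(h, if (!is.null(pl$vp)) {
          sprintf("<li>%s: %s over %s (%s)</li>", esc(pl$channel),
                  esc(pl$vp$expression$source),
                  esc(paste(pl$vp$groups, collapse = " ")),
                  esc(pl$vp$metric))
        } else {
          sprintf("<li>%s: %.6g mS/cm2 over %s</li>", esc(pl$channel),
                  pl$density, esc(paste(pl$groups, collapse = " ")))
        })
      }
      h <- c(h, "</ul>")
    }
  }
  curves <- list()
  for (chn in doc$channels) {
    h <- c(h, sprintf("<h2>Channel %s</h2>", esc(chn$id)),
           sprintf("<p>max conductance density %.6g mS/cm2, reversal %.6g mV</p>",
                   chn$gmax_density, chn$erev))
    if (!is.null(chn$q10))
      h <- c(h, sprintf("<p>Q10 %.4g at %.4g degC</p>",
                        chn$q10$q10_factor, chn$q10$experimental_temp))
    for (g in chn$gates) {
      ti <- tau_inf(g, v, q10 = chn$q10)
      tab <- data.frame(v = v,
                        alpha = evaluate_rate(g$forward, v, q10 = chn$q10),
                        beta = evaluate_rate(g$backward, v, q10 = chn$q10),
                        tau = ti$tau, inf = ti$inf)
      curves[[paste0(chn$id, ".", g$name)]] <- tab
      h <- c(h, sprintf(
        "<h3>Gate %s (%d instances)</h3><p>alpha: %s; beta: %s</p>",
        esc(g$name), g$instances, esc(describe_rate(g$forward)),
        esc(describe_rate(g$backward))))
    }
    if (!is.null(chn$scheme))
      h <- c(h, sprintf("<p>kinetic scheme: %d states (%d open), %d transitions</p>",
                        nrow(chn$scheme$states),
                        sum(chn$scheme$states$open),
                        length(chn$scheme$transitions)))
  }
  for (syn in doc$synapses)
    h <- c(h, sprintf("<h2>Synapse %s</h2><p>%s</p>", esc(synapse_id(syn)),
                      esc(describe_synapse(syn))))
  for (pool in doc$ion_pools)
    h <- c(h, sprintf(
      "<h2>Ca pool %s</h2><p>resting %.6g mM, tau %.6g ms, phi %.6g</p>",
      esc(pool$id), pool$resting, pool$tau, pool$phi))
  h <- c(h, "</body></html>")
  html <- paste(h, collapse = "\n")
  if (!is.null(file)) writeLines(html, file)
  list(html = html, curves = curves)
}

describe_rate <- function(law) {
  if (law$form == "generic") return(paste("generic:", law$expression$source))
  sprintf("%s(A = %.6g /ms, k = %.6g /mV, d = %.6g mV)",
          law$form, law$A, law$k, law$d)
}

describe_synapse <- function(syn) {
  if (inherits(syn, "nml_double_exp_synapse")) {
    sprintf("conductance waveform: gmax %.6g uS, erev %.6g mV, rise %.6g ms, decays [%s]%s",
            syn$gmax, syn$erev, syn$rise,
            paste(sprintf("%.6g ms (%.3g)", syn$decays$tau,
                          syn$decays$fraction), collapse = ", "),
            if (!is.null(syn$mg_block)) "; NMDA Mg block" else "")
  } else if (inherits(syn, "nml_stp_synapse")) {
    sprintf("short-term plasticity: U %.4g, tau_rec %.6g ms, tau_fac %.6g ms; base %s",
            syn$U, syn$tau_rec, syn$tau_fac, describe_synapse(syn$base))
  } else if (inherits(syn, "nml_stdp_synapse")) {
    sprintf("STDP: w_max %.4g, A+ %.4g, A- %.4g, tau+ %.6g ms, tau- %.6g ms",
            syn$w_max, syn$A_plus, syn$A_minus, syn$tau_plus, syn$tau_minus)
  } else if (inherits(syn, "nml_gap_junction")) {
    sprintf("gap junction: %.6g uS", syn$conductance)
  } else "unknown"
}

#' @param curves the `curves` element of a [render_summary()] result.
#' @param dir directory to write one tab-separated file per gate into.
#' @rdname render_summary
#' @export
write_curves <- function(curves, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(curves)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(curves[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
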