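#' NeuroML documents
#'
#' The in-memory document model for NeuroML v1.x files. A document declares
#' a Level (1: morphology + metadata; 2: adds biophysics and ChannelML
#' mechanisms; 3: adds NetworkML) and exactly one unit system. A Level-N
#' document may contain any element legal at Level N or below. All
#' magnitudes are held internally in the Physiological unit set
#' ([nml_unit_table()]); `unit_system` records how the document was (or will
#' be) written on disk.
#'
#' @param level document level, 1, 2 or 3.
#' @param unit_system `"SI"` or `"Physiological"`.
#' @param metadata optional [nml_metadata()].
#' @param cells list of [nml_cell()] / [nml_biophysical_cell()].
#' @param channels list of [nml_channel()].
#' @param ion_pools list of [nml_ca_pool()].
#' @param synapses list of synapse objects ([nml_double_exp_synapse()],
#'   [nml_stp_synapse()], [nml_stdp_synapse()], [nml_gap_junction()]).
#' @param network optional [nml_network()].
#' @return an object of class `"nml_document"`.
#' @export
nml_document <- function(level = 1L, unit_system = "Physiological",
                         metadata = NULL, cells = list(), channels = list(),
                         ion_pools = list(), synapses = list(),
                         network = NULL) {
  level <- as.integer(level)
  unit_system <- match.arg(unit_system, c("SI", "Physiological"))
  doc <- structure(list(level = level, unit_system = unit_system,
                        metadata = metadata, cells = cells,
                        channels = channels, ion_pools = ion_pools,
                        synapses = synapses, network = network,
                        unknown = list(), warnings = character(),
                        unit_conflicts = character()),
                   class = "nml_document")
  names(doc$cells) <- vapply(doc$cells, doc_cell_id, "")
  names(doc$channels) <- vapply(doc$channels, `[[`, "", "id")
  names(doc$ion_pools) <- vapply(doc$ion_pools, `[[`, "", "id")
  names(doc$synapses) <- vapply(doc$synapses, synapse_id, "")
  doc
}

doc_cell_id <- function(cell) {
  if (inherits(cell, "nml_biophysical_cell")) cell$morphology$id else cell$id
}

cell_morphology <- function(cell) {
  if (inherits(cell, "nml_biophysical_cell")) cell$morphology else cell
}

synapse_id <- function(syn) {
  if (inherits(syn, "nml_stp_synapse")) syn$base$id else syn$id
}

#' @export
print.nml_document <- function(x, ...) {
  cat(sprintf(paste0("<nml_document> Level %d, %s units: %d cells, ",
                     "%d channels, %d pools, %d synapses%s\n"),
              x$level, x$unit_system, length(x$cells), length(x$channels),
              length(x$ion_pools), length(x$synapses),
              if (is.null(x$network)) "" else ", 1 network"))
  if (length(x$warnings))
    cat(" warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Structural document equality
#'
#' Compares two documents field by field (numerics to a relative tolerance),
#' ignoring parse warnings. Used to state the parse/serialize round-trip
#' property.
#'
#' @param a,b documents.
#' @param tol relative numeric tolerance.
#' @export
nml_doc_equal <- function(a, b, tol = 1e-9) {
  strip <- function(d) {
    d$warnings <- NULL
    d$unit_conflicts <- NULL
    d$unit_system <- NULL  # a converted copy is still the same model
    d
  }
  isTRUE(all.equal(strip(a), strip(b), tolerance = tol,
                   check.attributes = TRUE))
}

# ---- unit conversion helpers shared by parse/serialize -------------------

# multiply a Physiological magnitude into the target system
conv_out <- function(x, dim, system) {
  if (system == "SI") x * unit_factor(dim) else x
}
# inverse-dimension attributes (1/time, 1/voltage)
conv_out_inv <- function(x, dim, system) {
  if (system == "SI") x / unit_factor(dim) else x
}
conv_in <- function(x, dim, system) {
  if (system == "SI") x / unit_factor(dim) else x
}
conv_in_inv <- function(x, dim, system) {
  if (system == "SI") x * unit_factor(dim) else x
}
# calcium-influx scaling phi: concentration / (current * time)
phi_factor <- function() {
  1 / (unit_factor("current") * unit_factor("time")) *
    unit_factor("concentration")
}
conv_out_phi <- function(x, system) if (system == "SI") x * phi_factor() else x
conv_in_phi <- function(x, system) if (system == "SI") x / phi_factor() else x
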