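#' Biophysical cells
#'
#' A Level 2 cell: a morphology plus passive membrane properties and the
#' placement of distributed mechanisms on labelled groups of cables.
#' Densities are either uniform (mS/cm2) or an [nml_variable_parameter()]
#' expression in a spatial metric. A Level 3 cell may additionally restrict
#' where synapse types are allowed to land (`connectivity`).
#'
#' All magnitudes are stored in the Physiological unit set (see
#' [nml_unit_table()]): specific capacitance uF/cm2, axial resistivity
#' kohm cm, densities mS/cm2.
#'
#' @param morphology an [nml_cell()].
#' @param specific_capacitance uF/cm2; a single number (applies to group
#'   `"all"`) or a list of `list(value =, groups =)` records.
#' @param axial_resistivity kohm cm; same shapes as `specific_capacitance`.
#' @param placements list of `list(channel =, density = <number> | vp =
#'   <nml_variable_parameter>, groups =)` records.
#' @param init_potential initial membrane potential (mV).
#' @param ion_pools list of `list(pool =, groups =)` records.
#' @param connectivity list of `list(synapse =, groups =)` records naming
#'   which groups a synapse type may target.
#' @param iaf optional [nml_iaf()] making this a point integrate-and-fire
#'   cell.
#' @export
nml_biophysical_cell <- function(morphology, specific_capacitance = 1,
                                 axial_resistivity = 0.1,
                                 placements = list(),
                                 init_potential = -65,
                                 ion_pools = list(),
                                 connectivity = list(),
                                 iaf = NULL) {
  stopifnot(inherits(morphology, "nml_cell"))
  structure(list(
    morphology = morphology,
    specific_capacitance = as_group_records(specific_capacitance),
    axial_resistivity = as_group_records(axial_resistivity),
    placements = placements,
    init_potential = init_potential,
    ion_pools = ion_pools,
    connectivity = connectivity,
    iaf = iaf
  ), class = "nml_biophysical_cell")
}

as_group_records <- function(x) {
  if (is.numeric(x)) return(list(list(value = x, groups = "all")))
  x
}

#' @export
print.nml_biophysical_cell <- function(x, ...) {
  cat(sprintf("<nml_biophysical_cell> %s: %d segments, %d mechanism placements\n",
              x$morphology$id, length(x$morphology$segments),
              length(x$placements)))
  invisible(x)
}

# groups declared anywhere on a cell's cables
cell_all_groups <- function(cell) {
  unique(c("all", unlist(lapply(cell$cables, `[[`, "groups"))))
}

# last matching group record wins; 'all' matches every cable
resolve_group_value <- function(records, groups) {
  val <- NA_real_
  for (rec in records) if (any(rec$groups %in% groups)) val <- rec$value
  val
}

#' Metadata
#'
#' Provenance information carried by documents and cells: original authors,
#' translators to the interchange format, publications, database references
#' (e.g. a ModelDB accession), free-text comments and a stability status.
#' Every field is optional and preserved verbatim on round-trip.
#'
#' @param authors,translators lists of `list(name =, institution =)`.
#' @param publications character vector of citation strings.
#' @param database_refs list of `list(database =, accession =)`.
#' @param comments free text.
#' @param status `list(value =, notes =)`; `value` is a stability tag such
#'   as `"stable"` or `"known_issues"`.
#' @export
nml_metadata <- function(authors = list(), translators = list(),
                         publications = character(), database_refs = list(),
                         comments = NULL, status = NULL) {
  structure(list(authors = authors, translators = translators,
                 publications = publications, database_refs = database_refs,
                 comments = comments, status = status),
            class = "nml_metadata")
}

metadata_is_empty <- function(md) {
  is.null(md) || (length(md$authors) == 0 && length(md$translators) == 0 &&
    length(md$publications) == 0 && length(md$database_refs) == 0 &&
    is.null(md$comments) && is.null(md$status))
}
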