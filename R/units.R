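#' Unit systems and physical quantities
#'
#' NeuroML documents declare exactly one unit system: `"SI"` or
#' `"Physiological"`. The Physiological set used throughout this package is
#' the mV / ms family conventional in compartmental modelling:
#'
#' | dimension            | Physiological | SI      |
#' |----------------------|---------------|---------|
#' | voltage              | mV            | V       |
#' | time                 | ms            | s       |
#' | length               | um            | m       |
#' | specific-capacitance | uF/cm2        | F/m2    |
#' | specific-conductance | mS/cm2        | S/m2    |
#' | conductance          | uS            | S       |
#' | current              | nA            | A       |
#' | concentration        | mM            | mol/m3  |
#' | temperature          | degC          | degC    |
#' | resistivity          | kohm cm       | ohm m   |
#' | dimensionless        | 1             | 1       |
#'
#' Segment geometry is always in micrometres; membrane densities use the
#' cm2-based units above. Conversion factors live in a single authoritative
#' table so that SI <-> Physiological conversion is an exact bijection
#' (pure multiplication by a power of ten; temperature is degrees Celsius
#' in both systems).
#'
#' @param magnitude numeric value.
#' @param dimension one of the dimension names in the table above.
#' @param system `"SI"` or `"Physiological"`.
#' @return `nml_quantity()` returns an object of class `"nml_quantity"`;
#'   `convert_quantity()` the same quantity expressed in `target`.
#' @examples
#' q <- nml_quantity(1, "voltage", "Physiological")   # 1 mV
#' convert_quantity(q, "SI")$magnitude                # 0.001 V
#' @export
nml_quantity <- function(magnitude, dimension, system = "Physiological") {
  dimension <- match.arg(dimension, nml_dimensions())
  system <- match.arg(system, c("SI", "Physiological"))
  stopifnot(is.numeric(magnitude), all(is.finite(magnitude)))
  structure(list(magnitude = magnitude, dimension = dimension,
                 system = system), class = "nml_quantity")
}

# one authoritative conversion table: factor takes Physiological -> SI
.nml_unit_table <- data.frame(
  dimension = c("voltage", "time", "length", "specific-capacitance",
                "specific-conductance", "conductance", "current",
                "concentration", "temperature", "resistivity",
                "dimensionless"),
  phys_unit = c("mV", "ms", "um", "uF_per_cm2", "mS_per_cm2", "uS", "nA",
                "mM", "degC", "kohm_cm", ""),
  si_unit = c("V", "s", "m", "F_per_m2", "S_per_m2", "S", "A",
              "mol_per_m3", "degC", "ohm_m", ""),
  factor = c(1e-3, 1e-3, 1e-6, 1e-2, 10, 1e-6, 1e-9, 1, 1, 10, 1),
  stringsAsFactors = FALSE
)

#' @rdname nml_quantity
#' @export
nml_dimensions <- function() .nml_unit_table$dimension

#' @rdname nml_quantity
#' @export
nml_unit_table <- function() .nml_unit_table

unit_factor <- function(dimension) {
  i <- match(dimension, .nml_unit_table$dimension)
  if (any(is.na(i))) stop("unknown dimension: ",
                          paste(dimension[is.na(i)], collapse = ", "))
  .nml_unit_table$factor[i]
}

#' @param q an `nml_quantity`.
#' @param target target unit system.
#' @rdname nml_quantity
#' @export
convert_quantity <- function(q, target) {
  stopifnot(inherits(q, "nml_quantity"))
  target <- match.arg(target, c("SI", "Physiological"))
  if (identical(q$system, target)) return(q)
  f <- unit_factor(q$dimension)
  m <- if (target == "SI") q$magnitude * f else q$magnitude / f
  nml_quantity(m, q$dimension, target)
}

#' @export
print.nml_quantity <- function(x, ...) {
  i <- match(x$dimension, .nml_unit_table$dimension)
  unit <- if (x$system == "SI") .nml_unit_table$si_unit[i] else
    .nml_unit_table$phys_unit[i]
  cat(format(x$magnitude), unit, sprintf("[%s, %s]\n", x$dimension, x$system))
  invisible(x)
}

# scalar magnitude in the given system regardless of the stored one
quantity_in <- function(q, system) convert_quantity(q, system)$magnitude
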