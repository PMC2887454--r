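#' NetworkML populations, projections and inputs
#'
#' A network is either *instance based* -- explicit 3D positions for every
#' cell and an explicit connection list, which stays compact because each
#' cell type is described once no matter how many cells instantiate it --
#' or *template based*: a generative rule (count + region + placement rule)
#' plus a seed, expanded deterministically by [instantiate()].
#'
#' @param name population name.
#' @param cell_type id of the cell description this population instantiates.
#' @param instances data frame with columns `index`, `x`, `y`, `z` and
#'   optionally `node_id` (parsed and preserved for parallel-execution
#'   partitioning; never interpreted by the simulator here).
#' @export
nml_population <- function(name, cell_type, instances) {
  stopifnot(is.data.frame(instances),
            all(c("index", "x", "y", "z") %in% names(instances)))
  if (anyDuplicated(instances$index)) stop("instance indices must be unique")
  if (is.null(instances$node_id))
    instances$node_id <- rep(NA_integer_, nrow(instances))
  structure(list(name = name, cell_type = as.character(cell_type),
                 instances = instances), class = "nml_population")
}

#' @param count number of cells to place.
#' @param region `list(shape = "box", x0, y0, z0, dx, dy, dz)` or
#'   `list(shape = "cylinder", x0, y0, z0, radius, height)` (axis along y).
#' @param min_separation minimal distance between somata (um); 0 disables
#'   the check. Placement uses rejection sampling with a retry cap of 1e4
#'   per cell.
#' @rdname nml_population
#' @export
nml_template_population <- function(name, cell_type, count, region,
                                    min_separation = 0) {
  count <- as.integer(count)
  stopifnot(count >= 0, region$shape %in% c("box", "cylinder"))
  structure(list(name = name, cell_type = as.character(cell_type),
                 count = count, region = region,
                 min_separation = min_separation),
            class = "nml_template_population")
}

#' @param source,target population names.
#' @param synapse synapse-type id.
#' @param connections data frame with columns `pre_cell`, `pre_segment`,
#'   `pre_fraction`, `post_cell`, `post_segment`, `post_fraction`, `weight`,
#'   `delay`.
#' @param electrical logical; `TRUE` for gap-junction projections, whose
#'   symmetric pairs are stored once.
#' @rdname nml_population
#' @export
nml_projection <- function(name, source, target, synapse,
                           connections = empty_connections(),
                           electrical = FALSE) {
  stopifnot(is.data.frame(connections))
  for (col in names(empty_connections()))
    if (is.null(connections[[col]]))
      connections[[col]] <- if (col %in% c("pre_fraction", "post_fraction"))
        0.5 else if (col == "weight") 1 else if (col == "delay") 0 else
          stop("connections lack column ", col)
  structure(list(name = name, source = source, target = target,
                 synapse = as.character(synapse),
                 connections = connections, electrical = isTRUE(electrical)),
            class = "nml_projection")
}

empty_connections <- function() {
  data.frame(pre_cell = integer(), pre_segment = character(),
             pre_fraction = numeric(), post_cell = integer(),
             post_segment = character(), post_fraction = numeric(),
             weight = numeric(), delay = numeric(), stringsAsFactors = FALSE)
}

#' @param kind input kind: `"current-pulse"`, `"continuous-random-current"`
#'   or `"random-synaptic-events"`.
#' @param population target population name.
#' @param params named list of input parameters: `amplitude` or
#'   `amplitude_range` (nA), `delay`, `duration` (ms), `rate` (Hz),
#'   `synapse`, `segment`.
#' @rdname nml_population
#' @export
nml_network_input <- function(name, kind = c("current-pulse",
                                             "continuous-random-current",
                                             "random-synaptic-events"),
                              population, params = list()) {
  kind <- match.arg(kind)
  amp <- c(params[["amplitude"]], params[["amplitude_range"]])
  if (!is.null(amp) && any(amp < 0) && kind != "current-pulse")
    stop("rates/amplitudes must be non-negative")
  if (!is.null(params[["rate"]]) && params[["rate"]] < 0)
    stop("rates/amplitudes must be non-negative")
  structure(list(name = name, kind = kind, population = population,
                 params = params), class = "nml_network_input")
}

#' @param populations list of [nml_population()] (instance networks) or
#'   [nml_template_population()] (templates).
#' @param projections list of [nml_projection()].
#' @param inputs list of [nml_network_input()].
#' @param seed template seed (template networks only).
#' @rdname nml_population
#' @export
nml_network <- function(populations = list(), projections = list(),
                        inputs = list(), seed = NULL) {
  template <- any(vapply(populations, inherits, TRUE,
                         "nml_template_population"))
  if (length(populations) > 0)
    names(populations) <- vapply(populations, `[[`, "", "name")
  if (length(projections) > 0)
    names(projections) <- vapply(projections, `[[`, "", "name")
  structure(list(populations = populations, projections = projections,
                 inputs = inputs, seed = seed, template = template),
            class = if (template) c("nml_network_template", "nml_network")
            else "nml_network")
}

#' @export
print.nml_network <- function(x, ...) {
  n <- sum(vapply(x$populations, function(p)
    if (inherits(p, "nml_template_population")) p$count else
      nrow(p$instances), 0L))
  cat(sprintf("<%s> %d populations (%d cells), %d projections, %d inputs\n",
              if (x$template) "nml_network_template" else "nml_network",
              length(x$populations), n, length(x$projections),
              length(x$inputs)))
  invisible(x)
}

# evaluate expr under a locally seeded RNG, restoring caller state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

region_sample <- function(region, n) {
  if (region$shape == "box") {
    data.frame(x = region$x0 + stats::runif(n) * region$dx,
               y = region$y0 + stats::runif(n) * region$dy,
               z = region$z0 + stats::runif(n) * region$dz)
  } else {
    # uniform in a cylinder with axis along y
    r <- region$radius * sqrt(stats::runif(n))
    th <- 2 * pi * stats::runif(n)
    data.frame(x = region$x0 + r * cos(th),
               y = region$y0 + stats::runif(n) * region$height,
               z = region$z0 + r * sin(th))
  }
}

region_contains <- function(region, p) {
  if (region$shape == "box") {
    p$x >= region$x0 & p$x <= region$x0 + region$dx &
      p$y >= region$y0 & p$y <= region$y0 + region$dy &
      p$z >= region$z0 & p$z <= region$z0 + region$dz
  } else {
    sqrt((p$x - region$x0)^2 + (p$z - region$z0)^2) <= region$radius &
      p$y >= region$y0 & p$y <= region$y0 + region$height
  }
}

#' Instantiate a template network
#'
#' Expands every template population into explicit 3D positions, placing
#' cells uniformly at random in the declared region (box or cylinder).
#' Deterministic: the same `(template, seed)` always yields the identical
#' instance. With a positive `min_separation` each cell is rejection-sampled
#' until it clears all previously placed cells, up to 1e4 retries.
#'
#' @param template an `nml_network_template` (from [nml_network()]).
#' @param seed integer seed.
#' @return an instance-based `nml_network`.
#' @export
instantiate <- function(template, seed = 1L) {
  stopifnot(inherits(template, "nml_network"))
  with_seed(seed, {
    pops <- lapply(template$populations, function(p) {
      if (!inherits(p, "nml_template_population")) return(p)
      if (p$count == 0L)
        return(nml_population(p$name, p$cell_type, data.frame(
          index = integer(), x = numeric(), y = numeric(), z = numeric())))
      if (p$min_separation <= 0) {
        pos <- region_sample(p$region, p$count)
      } else {
        pos <- region_sample(p$region, 1L)
        while (nrow(pos) < p$count) {
          placed <- FALSE
          for (try in seq_len(1e4)) {
            cand <- region_sample(p$region, 1L)
            d2 <- (pos$x - cand$x)^2 + (pos$y - cand$y)^2 +
              (pos$z - cand$z)^2
            if (all(d2 >= p$min_separation^2)) {
              pos <- rbind(pos, cand); placed <- TRUE; break
            }
          }
          if (!placed)
            stop("placement failed for population '", p$name,
                 "': region too crowded at min_separation ",
                 p$min_separation)
        }
      }
      nml_population(p$name, p$cell_type,
                     cbind(index = seq_len(p$count) - 1L, pos))
    })
    nml_network(pops, template$projections, template$inputs)
  })
}

#' Build a projection between populations
#'
#' Connection rules: `all-to-all` (every source to every target cell),
#' `per-cell` (exactly `count` targets per source cell, drawn without
#' replacement), `probability` (each ordered pair connected independently
#' with probability `p`). Self-connections within a single population are
#' excluded unless `allow_self = TRUE`. When the target cell declares
#' connectivity groups for the synapse, `post_segment`/`post_groups` must
#' respect them (checked by [validate_document()]).
#'
#' @param source,target [nml_population()]s.
#' @param rule `"all-to-all"`, `"per-cell"` or `"probability"`.
#' @param synapse synapse-type id.
#' @param count per-source connection count (`rule = "per-cell"`).
#' @param p connection probability (`rule = "probability"`).
#' @param post_segment segment id stamped on every connection's target.
#' @param weight,delay defaults stamped on every connection (1 and 0 ms).
#' @param allow_self allow autapses within one population.
#' @param seed integer seed; the result is a pure function of
#'   (populations, rule, seed).
#' @param name projection name.
#' @return an [nml_projection()].
#' @export
connect <- function(source, target, rule = c("all-to-all", "per-cell",
                                             "probability"),
                    synapse, count = NULL, p = NULL,
                    post_segment = NA_character_, weight = 1, delay = 0,
                    allow_self = FALSE, seed = 1L,
                    name = paste0(source$name, "_to_", target$name)) {
  rule <- match.arg(rule)
  src <- source$instances$index
  tgt <- target$instances$index
  same_pop <- identical(source$name, target$name)
  pairs <- with_seed(seed, switch(rule,
    "all-to-all" = {
      g <- expand.grid(pre = src, post = tgt)
      if (same_pop && !allow_self) g <- g[g$pre != g$post, ]
      g
    },
    "per-cell" = {
      stopifnot(!is.null(count))
      out <- lapply(src, function(s) {
        avail <- if (same_pop && !allow_self) setdiff(tgt, s) else tgt
        if (count > length(avail))
          stop("per-cell count ", count, " exceeds ", length(avail),
               " available targets")
        data.frame(pre = s, post = sample(avail, count))
      })
      do.call(rbind, out)
    },
    "probability" = {
      stopifnot(!is.null(p), p >= 0, p <= 1)
      g <- expand.grid(pre = src, post = tgt)
      if (same_pop && !allow_self) g <- g[g$pre != g$post, ]
      g[stats::runif(nrow(g)) < p, ]
    }))
  conns <- data.frame(
    pre_cell = pairs$pre, pre_segment = NA_character_, pre_fraction = 0.5,
    post_cell = pairs$post, post_segment = post_segment,
    post_fraction = 0.5, weight = weight, delay = delay,
    stringsAsFactors = FALSE)
  rownames(conns) <- NULL
  nml_projection(name, source$name, target$name, synapse, conns)
}

#' Electrical coupling within a population
#'
#' Builds a projection of gap junctions over unordered cell pairs of one
#' population; each symmetric pair is stored once. Rules as in [connect()]
#' interpreted over pairs: `"all-to-all"` couples every pair,
#' `"probability"` each pair independently, `"per-cell"` draws `count`
#' partners per cell (deduplicated as unordered pairs).
#'
#' @inheritParams connect
#' @param pop the population.
#' @param conductance coupling conductance stamped on each connection as its
#'   weight multiplier is 1; scaling factors are applied by the caller
#'   before passing the value (uS).
#' @export
attach_gap_junctions <- function(pop, rule = c("all-to-all", "probability",
                                               "per-cell"),
                                 synapse, conductance = NULL, p = NULL,
                                 count = NULL, seed = 1L,
                                 name = paste0(pop$name, "_gap")) {
  rule <- match.arg(rule)
  idx <- pop$instances$index
  pairs <- with_seed(seed, {
    if (length(idx) < 2L) {
      data.frame(pre = integer(), post = integer())
    } else {
      allp <- t(utils::combn(sort(idx), 2L))
      allp <- data.frame(pre = allp[, 1], post = allp[, 2])
      switch(rule,
        "all-to-all" = allp,
        "probability" = {
          stopifnot(!is.null(p))
          allp[stats::runif(nrow(allp)) < p, ]
        },
        "per-cell" = {
          stopifnot(!is.null(count))
          picked <- lapply(idx, function(s) {
            partners <- sample(setdiff(idx, s), min(count,
                                                    length(idx) - 1L))
            data.frame(pre = pmin(s, partners), post = pmax(s, partners))
          })
          unique(do.call(rbind, picked))
        })
    }
  })
  conns <- if (nrow(pairs) == 0L) empty_connections() else data.frame(
    pre_cell = pairs$pre, pre_segment = NA_character_, pre_fraction = 0.5,
    post_cell = pairs$post, post_segment = NA_character_,
    post_fraction = 0.5,
    weight = if (is.null(conductance)) 1 else conductance,
    delay = 0, stringsAsFactors = FALSE)
  rownames(conns) <- NULL
  nml_projection(name, pop$name, pop$name, synapse, conns,
                 electrical = TRUE)
}
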