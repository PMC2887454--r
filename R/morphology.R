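#' Morphology building blocks
#'
#' A cell is a forest of conical-frustum `segment`s, each defined by explicit
#' 3D proximal and distal points with diameters (micrometres). Segments are
#' grouped into `cable`s, the unbranched neurites that carry discretisation
#' counts (`internal_divisions`, the "nseg" of the cable) and group labels
#' such as `soma_group` or `apical_dendrite`. A segment whose proximal point
#' is omitted inherits its parent's distal point.
#'
#' Conventions fixed by this package: `fraction_along` is 0 at the proximal
#' and 1 at the distal point of a segment; a spherical soma is a single
#' segment whose proximal and distal points coincide, and it contributes
#' zero path length.
#'
#' @param x,y,z,diameter coordinates and diameter in micrometres.
#' @export
nml_point <- function(x, y, z, diameter) {
  stopifnot(is.finite(x), is.finite(y), is.finite(z), is.finite(diameter))
  if (diameter < 0) stop("point diameter must be >= 0")
  list(x = x, y = y, z = z, diameter = diameter)
}

#' @param id segment identifier (scalar, unique within the cell).
#' @param distal,proximal `nml_point()`s; `proximal = NULL` inherits the
#'   parent's distal point.
#' @param parent parent segment id, or `NULL` for a root segment.
#' @param cable id of the cable this segment belongs to.
#' @param name optional segment name.
#' @rdname nml_point
#' @export
nml_segment <- function(id, distal, proximal = NULL, parent = NULL,
                        cable, name = NULL) {
  structure(list(id = as.character(id), name = name, distal = distal,
                 proximal = proximal,
                 parent = if (is.null(parent)) NA_character_ else as.character(parent),
                 cable = as.character(cable)),
            class = "nml_segment")
}

#' @param groups character vector of group labels (the implicit group
#'   `"all"` always matches).
#' @param internal_divisions positive integer discretisation count.
#' @rdname nml_point
#' @export
nml_cable <- function(id, name = as.character(id), groups = character(),
                      internal_divisions = 1L) {
  internal_divisions <- as.integer(internal_divisions)
  if (is.na(internal_divisions) || internal_divisions < 1L)
    stop("internal_divisions must be a positive integer")
  structure(list(id = as.character(id), name = name,
                 groups = as.character(groups),
                 internal_divisions = internal_divisions),
            class = "nml_cable")
}

#' @param segments list of `nml_segment()`s (parents must precede children).
#' @param cables list of `nml_cable()`s.
#' @param metadata optional [nml_metadata()].
#' @rdname nml_point
#' @export
nml_cell <- function(id, segments, cables, metadata = NULL) {
  ids <- vapply(segments, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate segment ids")
  cids <- vapply(cables, `[[`, "", "id")
  if (anyDuplicated(cids)) stop("duplicate cable ids")
  names(segments) <- ids
  names(cables) <- cids
  structure(list(id = as.character(id), segments = segments, cables = cables,
                 metadata = metadata), class = "nml_cell")
}

#' @export
print.nml_cell <- function(x, ...) {
  cat(sprintf("<nml_cell> %s: %d segments in %d cables\n",
              x$id, length(x$segments), length(x$cables)))
  invisible(x)
}

# proximal point of a segment, following the inheritance rule
segment_proximal <- function(cell, seg) {
  if (!is.null(seg$proximal)) return(seg$proximal)
  if (is.na(seg$parent))
    stop("root segment '", seg$id, "' has no proximal point")
  cell$segments[[seg$parent]]$distal
}

point_dist <- function(a, b) sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)

segment_length <- function(cell, seg) point_dist(segment_proximal(cell, seg), seg$distal)

segment_children <- function(cell) {
  par <- vapply(cell$segments, `[[`, "", "parent")
  split(names(par), factor(par, levels = names(cell$segments)))
}

cell_root_id <- function(cell) {
  par <- vapply(cell$segments, `[[`, "", "parent")
  roots <- names(cell$segments)[is.na(par)]
  if (length(roots) == 0L) stop("cell '", cell$id, "' has no root segment")
  roots[[1L]]
}

cable_groups <- function(cable) unique(c("all", cable$groups))

segment_groups <- function(cell, segment_id) {
  cable_groups(cell$cables[[cell$segments[[segment_id]]$cable]])
}

#' Morphology integrity check
#'
#' Scans a cell for the four structural defect classes that creep into
#' manually reconstructed morphologies: `discontinuity` (a child's explicit
#' proximal point displaced from its parent's distal point),
#' `isolated-element` (a segment, or whole subtree, not connected to the
#' root), `zero-length` (a degenerate segment that is not a spherical root
#' soma) and `cycle` (a parent chain that loops).
#'
#' @param cell an [nml_cell()].
#' @param tol displacement (micrometres) above which an explicit proximal
#'   point counts as discontinuous.
#' @return data frame with columns `kind`, `segment`, `detail`; zero rows
#'   for a connected, continuous cell.
#' @export
check_integrity <- function(cell, tol = 1e-9) {
  stopifnot(inherits(cell, "nml_cell"))
  findings <- list()
  add <- function(kind, segment, detail)
    findings[[length(findings) + 1L]] <<- data.frame(
      kind = kind, segment = segment, detail = detail,
      stringsAsFactors = FALSE)

  ids <- names(cell$segments)
  par <- vapply(cell$segments, `[[`, "", "parent")

  # cycles: follow parent chains with a visited set
  in_cycle <- rep(FALSE, length(ids)); names(in_cycle) <- ids
  for (id in ids) {
    seen <- character(0); cur <- id
    while (!is.na(cur) && cur %in% ids) {
      if (cur %in% seen) { in_cycle[id] <- TRUE; break }
      seen <- c(seen, cur)
      cur <- par[[cur]]
    }
  }
  for (id in ids[in_cycle])
    add("cycle", id, "parent chain returns to this segment")

  # connectivity: flood from the root over the acyclic part
  acyclic <- ids[!in_cycle]
  roots <- acyclic[is.na(par[acyclic])]
  reach <- character(0)
  if (length(roots) > 0L && length(acyclic) > 0L) {
    frontier <- roots[[1L]]
    reach <- frontier
    while (length(frontier) > 0L) {
      nxt <- acyclic[par[acyclic] %in% frontier & !(acyclic %in% reach)]
      reach <- c(reach, nxt)
      frontier <- nxt
    }
  }
  for (id in setdiff(acyclic, reach)) {
    if (!is.na(par[[id]]) && !(par[[id]] %in% ids)) {
      add("isolated-element", id,
          sprintf("parent '%s' does not exist", par[[id]]))
    } else {
      add("isolated-element", id, "not connected to the root segment")
    }
  }

  # discontinuities and zero-length segments
  root1 <- if (length(roots) > 0L) roots[[1L]] else NA_character_
  for (id in ids) {
    seg <- cell$segments[[id]]
    if (!is.null(seg$proximal) && !is.na(seg$parent) &&
        seg$parent %in% ids && !in_cycle[[id]]) {
      gap <- point_dist(seg$proximal, cell$segments[[seg$parent]]$distal)
      if (gap > tol)
        add("discontinuity", id,
            sprintf("proximal point displaced %.6g um from parent distal", gap))
    }
    len <- tryCatch(segment_length(cell, seg), error = function(e) NA_real_)
    if (!is.na(len) && len <= tol) {
      spherical_root <- identical(id, root1) &&
        !is.null(seg$proximal) &&
        isTRUE(all.equal(seg$proximal$diameter, seg$distal$diameter))
      if (!spherical_root)
        add("zero-length", id, "zero-length segment outside a spherical soma")
    }
  }

  if (length(findings) == 0L)
    return(data.frame(kind = character(), segment = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Path distance from the soma
#'
#' Arc-length distance from the root segment's proximal point to the point a
#' fraction of the way along a segment. Spherical somata have zero length and
#' therefore contribute nothing.
#'
#' @inheritParams check_integrity
#' @param segment_id segment to measure to.
#' @param fraction_along position within the segment, 0 (proximal) to 1
#'   (distal).
#' @return distance in micrometres.
#' @export
path_distance <- function(cell, segment_id, fraction_along = 1) {
  stopifnot(inherits(cell, "nml_cell"))
  segment_id <- as.character(segment_id)
  if (!segment_id %in% names(cell$segments))
    stop("unknown segment id: ", segment_id)
  if (fraction_along < 0 || fraction_along > 1)
    stop("fraction_along must lie in [0, 1]")
  d <- fraction_along * segment_length(cell, cell$segments[[segment_id]])
  cur <- cell$segments[[segment_id]]$parent
  steps <- 0L
  while (!is.na(cur)) {
    seg <- cell$segments[[cur]]
    d <- d + segment_length(cell, seg)
    cur <- seg$parent
    steps <- steps + 1L
    if (steps > length(cell$segments)) stop("cycle in parent chain")
  }
  d
}

# 3D point a fraction of the way along a segment
segment_point_at <- function(cell, seg, fraction) {
  p <- segment_proximal(cell, seg); q <- seg$distal
  list(x = p$x + fraction * (q$x - p$x),
       y = p$y + fraction * (q$y - p$y),
       z = p$z + fraction * (q$z - p$z),
       diameter = p$diameter + fraction * (q$diameter - p$diameter))
}

#' Non-uniform parameter placements
#'
#' A `variable_parameter` expresses a biophysical parameter (typically a
#' channel density, mS/cm2) as an arithmetic expression in a spatial metric:
#' `d`, the path distance from the soma, or `r`, the straight-line 3D
#' distance from the root's proximal point (both micrometres).
#'
#' @param parameter name of the parameter being varied.
#' @param expression expression in `d` or `r`, parsed with [parse_expr()].
#' @param metric `"path-distance-from-soma"` or `"3D-radial-distance"`.
#' @param groups group labels the placement applies to.
#' @export
nml_variable_parameter <- function(parameter, expression,
                                   metric = c("path-distance-from-soma",
                                              "3D-radial-distance"),
                                   groups = "all") {
  metric <- match.arg(metric)
  expr <- if (inherits(expression, "nml_expr")) expression else
    parse_expr(expression, vars = c("d", "r"))
  structure(list(parameter = parameter, metric = metric, expression = expr,
                 groups = as.character(groups)),
            class = "nml_variable_parameter")
}

#' @param vp an [nml_variable_parameter()].
#' @inheritParams path_distance
#' @rdname nml_variable_parameter
#' @export
evaluate_density <- function(vp, cell, segment_id, fraction_along = 0.5) {
  stopifnot(inherits(vp, "nml_variable_parameter"))
  segment_id <- as.character(segment_id)
  grps <- segment_groups(cell, segment_id)
  if (!any(vp$groups %in% grps))
    stop("segment '", segment_id, "' is outside groups: ",
         paste(vp$groups, collapse = ", "))
  metric <- if (vp$metric == "path-distance-from-soma") {
    path_distance(cell, segment_id, fraction_along)
  } else {
    root <- cell$segments[[cell_root_id(cell)]]
    p0 <- segment_proximal(cell, root)
    pt <- segment_point_at(cell, cell$segments[[segment_id]], fraction_along)
    point_dist(p0, pt)
  }
  val <- eval_expr(vp$expression, list(d = metric, r = metric))
  if (!is.finite(val) || val < 0)
    stop("variable parameter evaluates to ", val, " at metric ", metric)
  val
}

# ---- recompartmentalization ---------------------------------------------

# frusta profile of a cable: data.frame(len, r0, r1), zero-length frusta kept
cable_frusta <- function(cell, cable_id) {
  segs <- Filter(function(s) identical(s$cable, cable_id), cell$segments)
  if (length(segs) == 0L) stop("cable '", cable_id, "' has no segments")
  # order along the unbranched path: root-most first
  par <- vapply(segs, `[[`, "", "parent")
  ids <- names(segs)
  first <- ids[!(par %in% ids)]
  if (length(first) != 1L)
    stop("cable '", cable_id, "' is not a single unbranched path")
  order_ids <- first
  repeat {
    nxt <- ids[par %in% order_ids[length(order_ids)] & !(ids %in% order_ids)]
    if (length(nxt) == 0L) break
    if (length(nxt) > 1L)
      stop("cable '", cable_id, "' branches internally")
    order_ids <- c(order_ids, nxt)
  }
  if (length(order_ids) != length(ids))
    stop("cable '", cable_id, "' is not a single unbranched path")
  data.frame(
    segment = order_ids,
    len = vapply(order_ids, function(i) segment_length(cell, segs[[i]]), 0),
    r0 = vapply(order_ids, function(i)
      segment_proximal(cell, segs[[i]])$diameter / 2, 0),
    r1 = vapply(order_ids, function(i) segs[[i]]$distal$diameter / 2, 0),
    stringsAsFactors = FALSE)
}

frustum_area <- function(len, r0, r1) pi * (r0 + r1) * sqrt(len^2 + (r1 - r0)^2)
frustum_axial <- function(len, r0, r1) len / (pi * r0 * r1)  # / resistivity
# electrotonic weight density ~ 1/sqrt(r); closed form over a linear taper
frustum_eweight <- function(len, r0, r1) {
  b <- (r1 - r0) / len
  if (abs(b) < 1e-12) len / sqrt(r0) else 2 * (sqrt(r1) - sqrt(r0)) / b
}
# arc position x in [0, len] where cumulative electrotonic weight reaches w
frustum_eweight_invert <- function(len, r0, r1, w) {
  b <- (r1 - r0) / len
  if (abs(b) < 1e-12) return(w * sqrt(r0))
  ((sqrt(r0) + w * b / 2)^2 - r0) / b
}

#' Map a cable onto equivalent cylinders
#'
#' Discretizes an unbranched cable of tapered frusta into
#' `internal_divisions` equivalent-cylinder compartments. The cable is cut
#' into spans of equal electrotonic weight (integral of 1 / sqrt(radius)
#' along the arc). Each compartment reports its span's exact arc `length`,
#' a `radius` chosen so the cylinder's lateral area equals the span's
#' frusta area, and the span's exact integrated `axial` resistance factor
#' (micrometre^-1; multiply by axial resistivity for ohms). Totals of all
#' three quantities therefore equal the cable's. A single cylinder cannot in
#' general realize area and axial resistance through one radius, so the
#' relative gap between the stored axial factor and the cylinder-geometry
#' one is reported per compartment as `axial_residual`.
#'
#' @inheritParams check_integrity
#' @param cable_id id of the cable to discretize.
#' @param n number of compartments; defaults to the cable's
#'   `internal_divisions`.
#' @return data frame with columns `length`, `radius`, `area`, `axial`,
#'   `axial_residual` (one row per compartment, proximal first).
#' @export
recompartmentalize <- function(cell, cable_id, n = NULL) {
  cable_id <- as.character(cable_id)
  cable <- cell$cables[[cable_id]]
  if (is.null(cable)) stop("unknown cable id: ", cable_id)
  if (is.null(n)) n <- cable$internal_divisions
  n <- as.integer(n)
  stopifnot(n >= 1L)
  fr <- cable_frusta(cell, cable_id)
  fr <- fr[fr$len > 0, , drop = FALSE]
  if (nrow(fr) == 0L) stop("cable '", cable_id, "' has zero length")

  total_w <- sum(mapply(frustum_eweight, fr$len, fr$r0, fr$r1))
  targets <- total_w * seq_len(n - 1L) / n

  # split the frusta chain at the electrotonic-weight targets
  pieces <- list()  # per span: list of (len, r0, r1)
  span <- list()
  cuts <- c(targets, Inf)
  ci <- 1L
  acc <- 0  # electrotonic weight consumed so far
  for (j in seq_len(nrow(fr))) {
    a <- 0  # arc consumed within frustum j
    repeat {
      rem_len <- fr$len[j] - a
      rem_w <- frustum_eweight(rem_len, radius_at(fr, j, a), fr$r1[j])
      if (is.finite(cuts[ci]) && cuts[ci] - acc < rem_w - 1e-12 * total_w) {
        # cut inside this frustum
        x <- frustum_eweight_invert(rem_len, radius_at(fr, j, a),
                                    fr$r1[j], cuts[ci] - acc)
        x <- min(max(x, 0), rem_len)
        span[[length(span) + 1L]] <- c(x, radius_at(fr, j, a),
                                       radius_at(fr, j, a + x))
        pieces[[length(pieces) + 1L]] <- span
        span <- list()
        acc <- cuts[ci]
        a <- a + x
        ci <- ci + 1L
      } else {
        span[[length(span) + 1L]] <- c(rem_len, radius_at(fr, j, a), fr$r1[j])
        acc <- acc + rem_w
        break
      }
    }
  }
  pieces[[length(pieces) + 1L]] <- span
  stopifnot(length(pieces) == n)

  out <- lapply(pieces, function(sp) {
    sp <- Filter(function(p) p[1] > 0, sp)
    l <- sum(vapply(sp, `[[`, 0, 1L))
    s <- sum(vapply(sp, function(p) frustum_area(p[1], p[2], p[3]), 0))
    g <- sum(vapply(sp, function(p) frustum_axial(p[1], p[2], p[3]), 0))
    r <- s / (2 * pi * l)
    g_geom <- l / (pi * r^2)
    data.frame(length = l, radius = r, area = s, axial = g,
               axial_residual = abs(g_geom - g) / g)
  })
  do.call(rbind, out)
}

radius_at <- function(fr, j, a) fr$r0[j] + (fr$r1[j] - fr$r0[j]) * a / fr$len[j]

# total lateral surface area of a cable (frusta sum; spheres handled upstream)
cable_area <- function(cell, cable_id) {
  fr <- cable_frusta(cell, cable_id)
  fr <- fr[fr$len > 0, , drop = FALSE]
  if (nrow(fr) == 0L) return(0)
  sum(mapply(frustum_area, fr$len, fr$r0, fr$r1))
}

cable_length <- function(cell, cable_id) {
  fr <- cable_frusta(cell, cable_id)
  sum(fr$len)
}

cable_axial_factor <- function(cell, cable_id) {
  fr <- cable_frusta(cell, cable_id)
  fr <- fr[fr$len > 0, , drop = FALSE]
  sum(mapply(frustum_axial, fr$len, fr$r0, fr$r1))
}
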