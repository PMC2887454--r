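test_that("integrity check passes a clean cell and flags the four defect classes", {
  soma <- nml_point(0, 0, 0, 10)
  clean <- nml_cell("c", list(
    nml_segment("root", proximal = soma, distal = nml_point(10, 0, 0, 10),
                cable = "cb"),
    nml_segment("child", distal = nml_point(20, 0, 0, 8), parent = "root",
                cable = "cb")),
    list(nml_cable("cb")))
  expect_equal(nrow(check_integrity(clean)), 0)

  # child proximal displaced 1 um from parent distal
  disc <- nml_cell("c", list(
    nml_segment("root", proximal = soma, distal = nml_point(10, 0, 0, 10),
                cable = "cb"),
    nml_segment("child", proximal = nml_point(10, 1, 0, 8),
                distal = nml_point(20, 1, 0, 8), parent = "root",
                cable = "cb")),
    list(nml_cable("cb")))
  f <- check_integrity(disc)
  expect_equal(sum(f$kind == "discontinuity"), 1)
  expect_equal(f$segment[f$kind == "discontinuity"], "child")

  # a parentless, childless segment in a 3-segment cell
  iso <- nml_cell("c", list(
    nml_segment("root", proximal = soma, distal = nml_point(10, 0, 0, 10),
                cable = "cb"),
    nml_segment("child", distal = nml_point(20, 0, 0, 8), parent = "root",
                cable = "cb"),
    nml_segment("stray", proximal = nml_point(50, 50, 0, 2),
                distal = nml_point(60, 50, 0, 2), cable = "cb2")),
    list(nml_cable("cb"), nml_cable("cb2")))
  f <- check_integrity(iso)
  expect_equal(sum(f$kind == "isolated-element"), 1)
  expect_equal(f$segment[f$kind == "isolated-element"], "stray")

  # zero-length segment that is not a spherical soma
  zl <- nml_cell("c", list(
    nml_segment("root", proximal = soma, distal = nml_point(10, 0, 0, 10),
                cable = "cb"),
    nml_segment("flat", proximal = nml_point(10, 0, 0, 8),
                distal = nml_point(10, 0, 0, 4), parent = "root",
                cable = "cb")),
    list(nml_cable("cb")))
  expect_equal(sum(check_integrity(zl)$kind == "zero-length"), 1)

  # cycle in the parent chain
  cyc <- nml_cell("c", list(
    nml_segment("a", proximal = nml_point(0, 0, 0, 2),
                distal = nml_point(5, 0, 0, 2), parent = "b", cable = "cb"),
    nml_segment("b", proximal = nml_point(5, 0, 0, 2),
                distal = nml_point(10, 0, 0, 2), parent = "a",
                cable = "cb")),
    list(nml_cable("cb")))
  expect_gte(sum(check_integrity(cyc)$kind == "cycle"), 1)
})

test_that("a spherical soma is not a zero-length finding", {
  p <- nml_point(0, 0, 0, 20)
  cell <- nml_cell("c", list(nml_segment("soma", proximal = p, distal = p,
                                         cable = "cb")),
                   list(nml_cable("cb")))
  expect_equal(nrow(check_integrity(cell)), 0)
})

test_that("path distance sums arc lengths from the root's proximal point", {
  fx <- generate_fixture("ball-and-stick")
  morph <- fx$document$cells[[1]]$morphology
  # spherical soma contributes 0: by-hand sum of the printed segment
  # lengths is 5 x 20 um
  expect_equal(path_distance(morph, "soma", 0), 0)
  expect_equal(path_distance(morph, "dend5", 1), 100)
  # fraction 0.5 of the terminal 20 um segment
  expect_equal(path_distance(morph, "dend5", 0.5), 90)
  expect_error(path_distance(morph, "nope"), "unknown segment")
})

test_that("path distance is additive along the path and monotone in fraction", {
  cell <- random_tapered_cell(10, seed = 5)
  ids <- paste0("s", 1:10)
  d_end <- vapply(ids, function(i) path_distance(cell, i, 1), 0)
  expect_true(all(diff(d_end) > 0))
  for (i in c(2, 7)) {
    f <- seq(0, 1, by = 0.25)
    d <- vapply(f, function(x) path_distance(cell, ids[i], x), 0)
    expect_true(all(diff(d) > 0))
    expect_equal(d[1], path_distance(cell, ids[i - 1], 1))
  }
})

test_that("density expressions evaluate at the point's metric value", {
  fx <- generate_fixture("ball-and-stick")
  morph <- fx$document$cells[[1]]$morphology
  const <- nml_variable_parameter("gmax", "5", groups = "dendrite_group")
  expect_equal(evaluate_density(const, morph, "dend3", 0.2), 5)
  lin <- nml_variable_parameter("gmax", "2 + 0.1 * d",
                                groups = "dendrite_group")
  # closed form at the root end of the first dendrite segment: d = 0
  expect_equal(evaluate_density(lin, morph, "dend1", 0), 2)
  # midpoint of the distal segment: d = 90 um
  expect_equal(evaluate_density(lin, morph, "dend5", 0.5), 2 + 0.1 * 90)
  expect_error(evaluate_density(lin, morph, "soma", 0.5), "outside groups")
})

test_that("a 20-segment cable with 4 internal divisions maps to 4 conserving compartments", {
  cell <- straight_cable_cell(n = 20, divisions = 4L)
  out <- recompartmentalize(cell, "c")
  expect_equal(nrow(out), 4)
  fr_len <- 20 * 5
  expect_equal(sum(out$length), fr_len, tolerance = 1e-9)
  expect_equal(sum(out$area), cableml:::cable_area(cell, "c"),
               tolerance = 1e-9)
  expect_equal(sum(out$axial), cableml:::cable_axial_factor(cell, "c"),
               tolerance = 1e-9)
})

test_that("a uniform cylinder with one division is returned unchanged", {
  cell <- nml_cell("c", list(nml_segment("s",
                                         proximal = nml_point(0, 0, 0, 6),
                                         distal = nml_point(30, 0, 0, 6),
                                         cable = "cb")),
                   list(nml_cable("cb", internal_divisions = 1L)))
  out <- recompartmentalize(cell, "cb")
  expect_equal(nrow(out), 1)
  expect_equal(out$length, 30)
  expect_equal(out$radius, 3, tolerance = 1e-12)
  expect_equal(out$axial, 30 / (pi * 9), tolerance = 1e-12)
  expect_lt(out$axial_residual, 1e-12)
})

test_that("a two-frustum tapered cable with two divisions satisfies the conservation system", {
  segs <- list(
    nml_segment("a", proximal = nml_point(0, 0, 0, 8),
                distal = nml_point(12, 0, 0, 4), cable = "cb"),
    nml_segment("b", distal = nml_point(30, 0, 0, 1), parent = "a",
                cable = "cb"))
  cell <- nml_cell("c", segs, list(nml_cable("cb",
                                             internal_divisions = 2L)))
  out <- recompartmentalize(cell, "cb")
  expect_equal(nrow(out), 2)

  # independent conservation targets from the frusta closed forms
  L <- 12 + 18
  S <- oracle_frustum_area(12, 4, 2) + oracle_frustum_area(18, 2, 0.5)
  G <- oracle_frustum_axial(12, 4, 2) + oracle_frustum_axial(18, 2, 0.5)
  expect_equal(sum(out$length), L, tolerance = 1e-9)
  expect_equal(sum(out$area), S, tolerance = 1e-9)
  expect_equal(sum(out$axial), G, tolerance = 1e-9)

  # per-compartment radii solve area = 2 pi r l; cross-check by numerically
  # re-solving the per-span system from the returned spans
  for (i in 1:2) {
    r_solved <- stats::uniroot(function(r) 2 * pi * r * out$length[i] -
                                 out$area[i], c(1e-6, 100))$root
    expect_equal(out$radius[i], r_solved, tolerance = 1e-6)
  }
})

test_that("recompartmentalization conserves the three quantities for random tapered cables", {
  for (seed in 1:8) {
    cell <- random_tapered_cell(nseg = 3 + seed %% 6, seed = seed)
    n_div <- 1 + seed %% 5
    out <- recompartmentalize(cell, "c", n = n_div)
    expect_equal(nrow(out), n_div)
    expect_equal(sum(out$length), cableml:::cable_length(cell, "c"),
                 tolerance = 1e-9)
    expect_equal(sum(out$area), cableml:::cable_area(cell, "c"),
                 tolerance = 1e-9)
    expect_equal(sum(out$axial),
                 cableml:::cable_axial_factor(cell, "c"),
                 tolerance = 1e-9)
    expect_true(all(out$length > 0) && all(out$radius > 0))
  }
})

test_that("integrity findings are invariant under serialize-then-parse", {
  fx <- generate_fixture("ball-and-stick")
  doc2 <- parse_document(serialize_document(fx$document))
  m1 <- cableml:::cell_morphology(fx$document$cells[[1]])
  m2 <- cableml:::cell_morphology(doc2$cells[[1]])
  expect_identical(check_integrity(m1), check_integrity(m2))
})
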