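# shared in-code builders for small morphologies and channels

# a straight cable of `n` segments with linearly interpolated diameters
straight_cable_cell <- function(n = 20, seg_len = 5, d0 = 4, d1 = 4,
                                divisions = 4L) {
  segs <- list(nml_segment("s1",
                           proximal = nml_point(0, 0, 0, d0),
                           distal = nml_point(seg_len, 0, 0,
                                              d0 + (d1 - d0) / n),
                           cable = "c"))
  for (i in 2:n) {
    segs[[i]] <- nml_segment(paste0("s", i),
                             distal = nml_point(seg_len * i, 0, 0,
                                                d0 + (d1 - d0) * i / n),
                             parent = paste0("s", i - 1), cable = "c")
  }
  nml_cell("straight", segs,
           list(nml_cable("c", internal_divisions = divisions)))
}

# random tapered cable for property tests
random_tapered_cell <- function(nseg, seed) {
  set.seed(seed)
  lens <- stats::runif(nseg, 1, 15)
  diams <- stats::runif(nseg + 1, 0.5, 8)
  segs <- list(nml_segment("s1",
                           proximal = nml_point(0, 0, 0, diams[1]),
                           distal = nml_point(lens[1], 0, 0, diams[2]),
                           cable = "c"))
  x <- cumsum(lens)
  for (i in seq_len(nseg)[-1])
    segs[[i]] <- nml_segment(paste0("s", i),
                             distal = nml_point(x[i], 0, 0, diams[i + 1]),
                             parent = paste0("s", i - 1), cable = "c")
  nml_cell("tapered", segs,
           list(nml_cable("c", internal_divisions = 1L)))
}

squid_k_gate <- function() {
  nml_gate("n", 4,
           forward = nml_rate_law("exp_linear", A = 0.1, k = 0.1, d = -55),
           backward = nml_rate_law("exponential", A = 0.125, k = -1 / 80,
                                   d = -65))
}

# reference frusta formulas, independent of the implementation's internals
oracle_frustum_area <- function(len, r0, r1)
  pi * (r0 + r1) * sqrt(len^2 + (r1 - r0)^2)
oracle_frustum_axial <- function(len, r0, r1) len / (pi * r0 * r1)

fixture_names <- function() {
  c("hh-point-cell", "ball-and-stick", "passive-pair-gap-junction",
    "ampa-nmda-clamp-cell", "stp-pair", "reduced-L23-network")
}
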