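# Shared fixtures, built in code. Properties follow the homogeneous disk /
# slab phantoms used throughout: standard disk mua = 0.01, musp = 1,
# n = 1.33; fluorescence disk muax = 0.0089, muspx = 1.3141, muam = 0.0062,
# muspm = 1.2739, gamma = 0.00018, tau = 1 ns, n = 1.33; slab mua = 0.01,
# musp = 1, n = 1.37.

disk_props <- function() standard_props(mua = 0.01, musp = 1, ri = 1.33)

disk_fluor_props <- function() fluor_props(
  muax = 0.0089, muspx = 1.3141, muam = 0.0062, muspm = 1.2739,
  gamma = 0.00018, tau = 1e-9, ri = 1.33)

slab_props <- function() standard_props(mua = 0.01, musp = 1, ri = 1.37)

# small optode-equipped disk: radius r, roughly n nodes, 1 source + 15
# circumferential detectors
small_disk <- function(radius = 15, nodes = 300, props = disk_props()) {
  make_disk_mesh(radius, nodes, props, optodes = TRUE)
}

# tiny single-tetrahedron mesh (unit right tet)
unit_tet_mesh <- function(props = standard_props()) {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  fem_mesh(nodes, matrix(1:4, 1), props)
}

# dense reference solve of a real sparse system
dense_solve <- function(A, Q) {
  solve(as.matrix(A), as.matrix(Q))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected)), tol)
}
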