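test_that("slab mesh conserves volume exactly and has positive elements", {
  mesh <- make_slab_mesh(10, 10, 10, 5, standard_props())
  vol <- element_volumes(mesh)
  expect_true(all(vol > 0))
  # 8 cells x 6 tets
  expect_equal(nrow(mesh$elements), 48L)
  expect_equal(sum(vol), 1000, tolerance = 1e-12)

  big <- make_slab_mesh(120, 120, 60, 10, standard_props())
  expect_equal(sum(element_volumes(big)), 864000, tolerance = 1e-12)
})

test_that("disk mesh area converges monotonically to the circle area", {
  areas <- vapply(c(50, 200, 800, 3200), function(n)
    sum(element_volumes(make_disk_mesh(43, n, standard_props()))),
    numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_lt(abs(areas[4] - pi * 43^2) / (pi * 43^2), 0.01)
  tiny <- make_disk_mesh(1, 10, standard_props())
  expect_lt(abs(sum(element_volumes(tiny)) - pi) / pi, 0.10)
})

test_that("generated meshes hit the node-count target and flag the rim", {
  mesh <- make_disk_mesh(43, 2000, disk_props())
  expect_lt(abs(nrow(mesh$nodes) - 2000) / 2000, 0.20)
  r <- sqrt(rowSums(mesh$nodes^2))
  expect_setequal(which(mesh$boundary_flag), which(r > 43 - 1e-6))
  # boundary flag matches faces shared by exactly one element
  slab <- make_slab_mesh(20, 20, 10, 5, standard_props())
  on_surface <- apply(slab$nodes, 1, function(p)
    any(abs(p - c(0, 0, 0)) < 1e-9) || abs(p[1] - 20) < 1e-9 ||
      abs(p[2] - 20) < 1e-9 || abs(p[3] - 10) < 1e-9)
  expect_equal(slab$boundary_flag, on_surface)
})

test_that("mesh constructor rejects bad input", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(fem_mesh(nodes, matrix(c(1, 2, 3, 5), 1), standard_props()),
               "out of range")
  expect_error(fem_mesh(nodes, matrix(c(1, 2, 3, 3), 1), standard_props()),
               "degenerate")
  expect_error(fem_mesh(nodes, matrix(1:4, 1), standard_props(mua = -1)),
               "mua")
})

test_that("NIRFAST ASCII round trip is the identity for all three kinds", {
  dir <- withr::local_tempdir()
  meshes <- list(
    stnd = make_disk_mesh(15, 200, disk_props(), optodes = TRUE),
    fluor = make_disk_mesh(15, 200, disk_fluor_props(), optodes = TRUE),
    dcs = make_disk_mesh(15, 200, dcs_props(alphaDb = 1e-6, wavelength = 750))
  )
  for (kind in names(meshes)) {
    base <- file.path(dir, kind)
    save_nirfast_ascii(meshes[[kind]], base)
    back <- load_nirfast_ascii(base)
    expect_equal(back$kind, kind)
    expect_equal(back$nodes, meshes[[kind]]$nodes, tolerance = 1e-12)
    expect_identical(back$elements, meshes[[kind]]$elements)
    for (f in setdiff(names(meshes[[kind]]$props), "wavelength"))
      expect_equal(back$props[[f]], meshes[[kind]]$props[[f]],
                   tolerance = 1e-12, label = f)
    if (kind != "dcs") {
      expect_equal(back$optodes$sources, meshes[[kind]]$optodes$sources,
                   tolerance = 1e-12)
      expect_equal(back$optodes$detectors, meshes[[kind]]$optodes$detectors,
                   tolerance = 1e-12)
      expect_identical(back$optodes$link, meshes[[kind]]$optodes$link)
      expect_identical(back$optodes$moved, meshes[[kind]]$optodes$moved)
    }
  }
  # fluorescence .param carries seven property columns
  lines <- readLines(file.path(dir, "fluor.param"))
  expect_identical(trimws(lines[1]), "fluor")
  expect_length(strsplit(trimws(lines[2]), "\\s+")[[1]], 7L)
  # a mesh without optodes emits no optode files
  expect_false(file.exists(file.path(dir, "dcs.source")))
  expect_false(file.exists(file.path(dir, "dcs.link")))
})

test_that("loader reports malformed files", {
  dir <- withr::local_tempdir()
  mesh <- make_disk_mesh(5, 50, standard_props())
  base <- file.path(dir, "m")
  save_nirfast_ascii(mesh, base)
  expect_error(load_nirfast_ascii(file.path(dir, "missing")), "mandatory")
  # element index beyond the node count
  el <- readLines(paste0(base, ".elem"))
  el[1] <- paste(nrow(mesh$nodes) + 5, "2 3")
  writeLines(el, paste0(base, ".elem"))
  expect_error(load_nirfast_ascii(base), "out of range")
})

test_that("locate_point finds elements, nodes, and reports outside", {
  mesh <- make_disk_mesh(10, 100, standard_props())
  e <- 7L
  centroid <- colMeans(mesh$nodes[mesh$elements[e, ], ])
  loc <- locate_point(mesh, centroid)
  expect_equal(sort(photonfem:::bary_weights(mesh, loc$element, centroid)),
               sort(loc$weights))
  expect_equal(loc$weights, rep(1 / 3, 3), tolerance = 1e-9)
  nd <- mesh$nodes[12, ]
  loc2 <- locate_point(mesh, nd)
  expect_equal(max(loc2$weights), 1, tolerance = 1e-9)
  expect_true(is.na(locate_point(mesh, c(1e6, 1e6))$element))
})

test_that("source placement moves one scattering length inside", {
  for (musp in c(1, 2)) {
    mesh <- make_slab_mesh(40, 40, 20, 4, standard_props(musp = musp))
    mesh <- place_optodes(mesh, matrix(c(20, 20, 25), 1),
                          matrix(c(18, 20, 26), 1))
    # raw optodes above the top face z = 20: projected there, source moved in
    expect_equal(mesh$optodes$sources[1, ], c(20, 20, 20 - 1 / musp),
                 tolerance = 1e-9)
    expect_equal(mesh$optodes$detectors[1, ], c(18, 20, 20), tolerance = 1e-9)
    expect_true(mesh$optodes$moved[1])
  }
  # fluorescence meshes use the excitation scattering length
  fl <- make_slab_mesh(40, 40, 20, 4, disk_fluor_props())
  fl <- place_optodes(fl, matrix(c(20, 20, 25), 1), matrix(c(18, 20, 26), 1))
  expect_equal(fl$optodes$sources[1, 3], 20 - 1 / 1.3141, tolerance = 1e-9)
  # move_sources = FALSE projects only
  ns <- place_optodes(make_slab_mesh(40, 40, 20, 4, standard_props()),
                      matrix(c(20, 20, 25), 1), matrix(c(18, 20, 26), 1),
                      move_sources = FALSE)
  expect_equal(ns$optodes$sources[1, 3], 20)
  expect_false(ns$optodes$moved[1])
})

test_that("thin geometry truncates the source displacement with a warning", {
  mesh <- make_slab_mesh(20, 20, 0.5, 0.25, standard_props(musp = 1))
  expect_warning(
    mesh <- place_optodes(mesh, matrix(c(10, 10, 1), 1),
                          matrix(c(8, 10, 1), 1)),
    "truncated")
  expect_false(is.na(locate_point(mesh, mesh$optodes$sources[1, ])$element))
})
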