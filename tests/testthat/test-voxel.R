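# Grid mapping, absorbed energy, adjoint Jacobians, Tikhonov reconstruction.

test_that("grid mapping is a partition of unity and reproduces affine fields", {
  mesh <- make_disk_mesh(15, 400, disk_props())
  g <- seq(-14, 14, by = 2)
  grid <- build_grid_mapping(mesh, g, g)
  rs <- Matrix::rowSums(grid$mapping)
  expect_equal(rs[grid$inside], rep(1, sum(grid$inside)), tolerance = 1e-9)
  expect_true(all(rs[!grid$inside] == 0))
  const <- grid_projected <- photonfem:::grid_project(grid, rep(3.5, nrow(mesh$nodes)))
  expect_equal(const[grid$inside, 1], rep(3.5, sum(grid$inside)),
               tolerance = 1e-9)
  aff <- 2 * mesh$nodes[, 1] - 0.7 * mesh$nodes[, 2] + 1
  av <- photonfem:::grid_project(grid, aff)
  truth <- 2 * grid$centers[, 1] - 0.7 * grid$centers[, 2] + 1
  expect_equal(av[grid$inside, 1], truth[grid$inside], tolerance = 1e-9)
})

test_that("interpolated fluence at a fixed point is grid-resolution independent", {
  mesh <- small_disk(15, 400)
  fd <- femdata_standard(mesh, 0)
  vals <- vapply(c(1, 2, 3), function(h) {
    g <- seq(-6, 6, by = h)   # all three grids contain the point (0, 0)
    grid <- build_grid_mapping(mesh, g, g)
    pv <- photonfem:::grid_project(grid, fd$phi)
    at0 <- which(grid$centers[, 1] == 0 & grid$centers[, 2] == 0)
    pv[at0, 1]
  }, numeric(1))
  expect_equal(vals[2], vals[1], tolerance = 1e-12)
  expect_equal(vals[3], vals[1], tolerance = 1e-12)
})

test_that("absorbed energy: exact in mesh space, quantization error shrinks with finer grids", {
  mesh <- make_disk_mesh(15, 500, disk_props())
  n <- nrow(mesh$nodes)
  ae <- absorbed_energy(mesh, rep(1, n))
  expect_equal(ae$mesh_value, 0.01 * sum(element_volumes(mesh)),
               tolerance = 1e-12)
  # trend holds while voxels remain much larger than the elements
  mesh2 <- small_disk(20, 2500)
  fd <- femdata_standard(mesh2, 0)
  errs <- vapply(c(8, 2), function(h) {
    g <- seq(-20 + h / 2, 20 - h / 2, by = h)
    grid <- build_grid_mapping(mesh2, g, g)
    absorbed_energy(mesh2, fd$phi[, 1], grid)$error_pct
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("standard CW Jacobian: signs, banana shape, and uniform-perturbation oracle", {
  mesh <- small_disk(15, 400)
  g <- seq(-14.5, 14.5, by = 1)
  grid <- build_grid_mapping(mesh, g, g)
  J <- jacobian_standard(mesh, grid, 0, log_data = TRUE)
  expect_equal(ncol(J$matrix), 2L * sum(grid$inside))
  nv <- sum(grid$inside)
  Jmua <- J$matrix[, seq_len(nv)]
  # more absorption everywhere -> less light at every channel
  expect_true(all(Jmua <= 1e-12))
  # banana: the peak-sensitivity voxel of a channel sits between source and
  # detector and near the surface
  ch <- 8  # detector opposite-ish the source
  centers <- grid$centers[grid$inside, ]
  peak <- centers[which.max(abs(Jmua[ch, ])), ]
  src <- mesh$optodes$sources[1, ]
  det <- mesh$optodes$detectors[link_det <- J$link[ch, 2], ]
  expect_lt(sqrt(sum((peak - (src + det) / 2)^2)),
            sqrt(sum((src - det)^2)))
  # uniform-perturbation oracle: d log I = rowSum(J_mua) * dmua
  dmua <- 2e-4
  base <- femdata_standard(mesh, 0)$boundary
  pert <- mesh; pert$props$mua <- pert$props$mua + dmua
  up <- femdata_standard(pert, 0)$boundary
  predicted <- rowSums(Jmua) * dmua
  actual <- log(up) - log(base)
  expect_lt(max(abs(predicted - actual) / abs(actual)), 0.05)
})

test_that("local-perturbation finite-difference oracle for the mua and musp blocks", {
  mesh <- small_disk(15, 800)
  g <- seq(-14.5, 14.5, by = 1)
  grid <- build_grid_mapping(mesh, g, g)
  J <- jacobian_standard(mesh, grid, 0, log_data = FALSE)
  nv <- sum(grid$inside)
  # smooth Gaussian bump centered between the source and a detector; the
  # Jacobian applied to the bump sampled at voxel centers must match the
  # nonlinear forward difference
  ctr <- c(7, 3)
  bump_at <- function(xy) exp(-rowSums(sweep(xy, 2, ctr)^2) / (2 * 2^2))
  base <- femdata_standard(mesh, 0)$boundary
  for (blk in 1:2) {
    fldname <- c("mua", "musp")[blk]
    delta <- c(1e-3, 0.01)[blk]
    pert <- mesh
    pert$props[[fldname]] <- pert$props[[fldname]] + delta * bump_at(mesh$nodes)
    up <- femdata_standard(pert, 0)$boundary
    dvox <- delta * bump_at(grid$centers[grid$inside, , drop = FALSE])
    predicted <- as.numeric(J$matrix[, (blk - 1) * nv + seq_len(nv)] %*% dvox)
    actual <- up - base
    expect_lt(max(abs(predicted - actual)) / max(abs(actual)), 0.05,
              label = paste("block", fldname))
  }
})

test_that("fluorescence CW Jacobian is the real gamma block and predicts scaling", {
  mesh <- small_disk(15, 400, disk_fluor_props())
  g <- seq(-14.5, 14.5, by = 1)
  grid <- build_grid_mapping(mesh, g, g)
  J <- jacobian_fluorescence(mesh, grid, 0)
  expect_identical(J$blocks, "gamma")
  expect_true(is.double(J$matrix))
  expect_equal(nrow(J$matrix), 15L)
  # emission is linear in gamma, so (dI/dgamma) . gamma = I exactly in the
  # continuum; the voxelized row-sum identity holds to coverage error
  born <- femdata_fluorescence(mesh, 0)$born_ratio
  predicted <- as.numeric(J$matrix %*% rep(mesh$props$gamma[1],
                                           sum(grid$inside)))
  expect_lt(max(abs(predicted - born) / born), 0.05)
})

test_that("FD Jacobians interleave real and imaginary rows", {
  mesh <- small_disk(10, 200)
  g <- seq(-9.5, 9.5, by = 2)
  grid <- build_grid_mapping(mesh, g, g)
  omega <- 2 * pi * 1e8
  J <- jacobian_standard(mesh, grid, omega)
  expect_equal(nrow(J$matrix), 30L)
  # finite difference on a uniform mua bump, complex data
  dmua <- 2e-4
  base <- femdata_standard(mesh, omega)$boundary
  pert <- mesh; pert$props$mua <- pert$props$mua + dmua
  up <- femdata_standard(pert, omega)$boundary
  nv <- sum(grid$inside)
  predR <- rowSums(J$matrix[seq(1, 30, 2), seq_len(nv)]) * dmua
  predI <- rowSums(J$matrix[seq(2, 30, 2), seq_len(nv)]) * dmua
  expect_lt(max(Mod(complex(real = predR, imaginary = predI) - (up - base))) /
            max(Mod(up - base)), 0.05)
})

test_that("DCS Jacobians vanish at tau 0 and pass a finite-difference oracle", {
  taus <- c(0, 1e-6, 2e-6)
  mesh <- small_disk(15, 400, dcs_props(mua = 0.01, musp = 1, ri = 1.33,
                                        alphaDb = 1e-6, wavelength = 750))
  g <- seq(-14.5, 14.5, by = 1)
  grid <- build_grid_mapping(mesh, g, g)
  Js <- jacobian_dcs(mesh, grid, taus, log_data = TRUE)
  expect_equal(max(abs(Js[[1]]$matrix)), 0)
  base <- femdata_dcs(mesh, taus)
  dadb <- 5e-8
  pert <- mesh; pert$props$alphaDb <- pert$props$alphaDb + dadb
  up <- femdata_dcs(pert, taus)
  for (k in 2:3) {
    predicted <- rowSums(Js[[k]]$matrix) * dadb
    actual <- log(up$G1[k, ]) - log(base$G1[k, ])
    expect_lt(max(abs(predicted - actual) / abs(actual)), 0.05)
  }
  # chain rule: at small delays, where the correlation field is still close
  # to the CW field, J(tau) scales linearly with tau
  Jraw <- jacobian_dcs(mesh, grid, taus, log_data = FALSE)
  r32 <- Jraw[[3]]$matrix[1, ] / Jraw[[2]]$matrix[1, ]
  keep <- abs(Jraw[[2]]$matrix[1, ]) > max(abs(Jraw[[2]]$matrix[1, ])) * 1e-3
  expect_gt(stats::median(r32[keep]), 2 * 0.95)
  expect_lt(stats::median(r32[keep]), 2 * 1.05)
})

test_that("coarsening the grid scales per-voxel sensitivities by voxel volume", {
  mesh <- small_disk(15, 400)
  g1 <- seq(-14, 14, by = 1); g2 <- seq(-14, 14, by = 2)
  grid1 <- build_grid_mapping(mesh, g1, g1)
  grid2 <- build_grid_mapping(mesh, g2, g2)
  J1 <- jacobian_standard(mesh, grid1, 0)
  J2 <- jacobian_standard(mesh, grid2, 0)
  # compare at a shared deep voxel location (0, -6)
  v1 <- which(grid1$centers[grid1$inside, 1] == 0 &
              grid1$centers[grid1$inside, 2] == -6)
  v2 <- which(grid2$centers[grid2$inside, 1] == 0 &
              grid2$centers[grid2$inside, 2] == -6)
  ratio <- J2$matrix[1, v2] / J1$matrix[1, v1]
  expect_equal(ratio, grid2$voxel_volume / grid1$voxel_volume,
               tolerance = 1e-6)
})

test_that("region-of-interest grids restrict the Jacobian to masked voxels", {
  mesh <- small_disk(15, 300)
  g <- seq(0, 10, by = 2)  # covers only one quadrant
  grid <- build_grid_mapping(mesh, g, g)
  J <- jacobian_standard(mesh, grid, 0)
  expect_equal(ncol(J$matrix), 2L * sum(grid$inside))
  expect_lt(sum(grid$inside), length(grid$inside) + 1)
})

test_that("Tikhonov reconstruction: degenerate inputs and regularization limits", {
  set.seed(1)
  J <- matrix(rnorm(15 * 60), 15)
  expect_equal(tikhonov_reconstruct(J, rep(0, 15), 10)$update, rep(0, 60))
  y <- rnorm(15)
  norms <- vapply(c(0.1, 1, 10, 100, 1e4), function(l)
    sqrt(sum(tikhonov_reconstruct(J, y, l)$update^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_error(tikhonov_reconstruct(J, y, 0), "lambda")
  expect_error(tikhonov_reconstruct(J, y[1:3], 10), "rows")
})

test_that("a 5 percent absorption anomaly is localized within 10 mm at three grid resolutions", {
  set.seed(202)
  # tomographic ring: 8 sources interleaved with 8 detectors, all 64 channels
  mesh <- make_disk_mesh(43, 1200, disk_props())
  ang_s <- 2 * pi * (0:7) / 8
  ang_d <- ang_s + pi / 8
  mesh <- place_optodes(mesh, cbind(43 * cos(ang_s), 43 * sin(ang_s)),
                        cbind(43 * cos(ang_d), 43 * sin(ang_d)))
  truth <- c(18, 8)
  r2 <- rowSums(sweep(mesh$nodes, 2, truth)^2)
  pert <- mesh
  pert$props$mua <- pert$props$mua * (1 + 0.05 * (r2 < 8^2))
  base <- femdata_standard(mesh, 0)$boundary
  bump <- femdata_standard(pert, 0)$boundary
  y0 <- log(bump) - log(base)
  y <- y0 * (1 + 0.05 * rnorm(length(y0)))   # 5 percent white noise
  for (h in c(3, 4, 5)) {
    g <- seq(-42, 42, by = h)
    grid <- build_grid_mapping(mesh, g, g)
    J <- jacobian_standard(mesh, grid, 0, log_data = TRUE)
    nv <- sum(grid$inside)
    rec <- tikhonov_reconstruct(J$matrix[, seq_len(nv)], y, 10)
    up <- rec$update
    centers <- grid$centers[grid$inside, ]
    # centroid of the strongest positive-update voxels
    sel <- up > max(up) * 0.5
    centroid <- colSums(centers[sel, , drop = FALSE] * up[sel]) / sum(up[sel])
    expect_lt(sqrt(sum((centroid - truth)^2)), 10)
  }
})
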