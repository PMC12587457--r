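# Adjoint voxel-space Jacobians. Direct fields (per source) and adjoint
# fields (per detector, injected like sources but without the scattering-
# length displacement) are solved in mesh space, mapped to voxels once, and
# each channel's sensitivity row is an elementwise product times the voxel
# volume — the whole point of working in voxel space.

# adjoint measurement sources: unit load at the projected detector points
adjoint_source_vectors <- function(mesh) {
  t(measurement_matrix(mesh))
}

# per-element gradient fields sampled at voxel centers (piecewise-constant
# P1 gradients of the located element), as a P x S matrix per dimension
voxel_gradients <- function(mesh, grid, field) {
  eg <- element_gradients(mesh)
  el <- mesh$elements
  rows <- which(grid$inside)
  elems <- grid$element[rows]
  field <- as.matrix(field)
  P <- length(grid$inside)
  out <- vector("list", mesh$dim)
  for (k in seq_len(mesh$dim)) {
    g <- eg$grads[[k]]              # E x (dim+1) basis gradients
    gv <- matrix(NA_real_, P, ncol(field))
    acc <- 0
    for (i in seq_len(ncol(el))) {
      acc <- acc + g[elems, i] * field[el[elems, i], , drop = FALSE]
    }
    gv[rows, ] <- acc
    out[[k]] <- gv
  }
  out
}

jacobian_obj <- function(J, blocks, grid, log_data, omega, extra = list()) {
  structure(c(list(matrix = J, blocks = blocks, inside = grid$inside,
                   dims = grid$dims, voxel_volume = grid$voxel_volume,
                   log_data = log_data, omega = omega), extra),
            class = "fem_jacobian")
}

#' @exportS3Method base::print
print.fem_jacobian <- function(x, ...) {
  cat(sprintf("fem_jacobian: %d rows x %d cols; blocks: %s%s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$blocks, collapse = ", "),
              if (x$log_data) " (log data)" else ""))
  invisible(x)
}

#' Voxel-space Jacobian for the standard problem
#'
#' Rows are channels (for frequency-domain data, interleaved real/imaginary
#' row pairs); columns are inside voxels in two parameter blocks. The mua
#' block is \code{-Phi .* Psi * voxel_volume} (direct times adjoint field);
#' the musp block applies the chain rule through the diffusion coefficient,
#' \code{dkappa/dmusp = -3 kappa^2}, to the gradient term
#' \code{grad(Phi) . grad(Psi)} (per-element P1 gradients sampled at voxel
#' centers). With \code{log_data} each channel row is divided by its
#' boundary value.
#'
#' @param mesh standard \code{fem_mesh} with placed optodes
#' @param grid a \code{voxel_grid} from \code{\link{build_grid_mapping}}
#' @param omega modulation angular frequency, rad/s
#' @param log_data divide each row by the channel's boundary value
#' @param opts solver options
#' @return a \code{fem_jacobian} with blocks \code{mua}, \code{musp}
#' @export
jacobian_standard <- function(mesh, grid, omega = 0, log_data = FALSE,
                              opts = solver_defaults()) {
  sys <- assemble_standard(mesh)
  Q <- build_source_vectors(mesh)
  Qadj <- adjoint_source_vectors(mesh)
  link <- mesh$optodes$link
  if (omega == 0) {
    phi <- solve_real(sys$A, Q, "cw", opts)$x
    M <- build_fsai(sys$A, "pcg_diag4")
    psi <- pcg_solve(sys$A, M, as.matrix(Qadj), tol = opts$tol,
                     maxit = opts$maxit)$x
  } else {
    M <- build_fsai(sys$A, "bicgstab3")
    Ac <- list(re = sys$A, im = omega * sys$B)
    phi <- bicgstab_solve(Ac, M, as.matrix(Q), tol = opts$tol,
                          maxit = opts$maxit)$x
    psi <- bicgstab_solve(Ac, M, as.matrix(Qadj), tol = opts$tol,
                          maxit = opts$maxit)$x
  }
  meas <- measurement_matrix(mesh)
  bval <- channel_values(meas, phi, link)
  phiv <- grid_project(grid, phi)
  psiv <- grid_project(grid, psi)
  gphi <- voxel_gradients(mesh, grid, phi)
  gpsi <- voxel_gradients(mesh, grid, psi)
  kapv <- grid_project(grid, kappa_field(mesh))[, 1]
  rows <- which(grid$inside)
  vol <- grid$voxel_volume
  nch <- nrow(link)
  nv <- length(rows)
  Jc <- matrix(if (omega == 0) 0 else 0i, nch, 2L * nv)
  for (ch in seq_len(nch)) {
    s <- link[ch, 1]; dct <- link[ch, 2]
    mua_blk <- -phiv[rows, s] * psiv[rows, dct] * vol
    gdot <- 0
    for (k in seq_along(gphi))
      gdot <- gdot + gphi[[k]][rows, s] * gpsi[[k]][rows, dct]
    musp_blk <- 3 * kapv[rows]^2 * gdot * vol
    row <- c(mua_blk, musp_blk)
    if (log_data) {
      if (abs(bval[ch]) == 0)
        stop("channel ", ch, " has zero boundary value; cannot form log data")
      row <- row / bval[ch]
    }
    Jc[ch, ] <- row
  }
  J <- if (omega == 0) Re(Jc) else interleave_ri(Jc)
  jacobian_obj(J, c("mua", "musp"), grid, log_data, omega,
               extra = list(boundary = bval, link = link))
}

# complex channel rows -> interleaved (Re, Im, Re, Im, ...) real rows
interleave_ri <- function(Jc) {
  out <- matrix(0, 2L * nrow(Jc), ncol(Jc))
  out[seq(1, 2 * nrow(Jc), by = 2), ] <- Re(Jc)
  out[seq(2, 2 * nrow(Jc), by = 2), ] <- Im(Jc)
  out
}

#' Voxel-space Jacobian for the fluorescence problem
#'
#' Sensitivity of the re-emission data (by default the Born ratio: emission
#' over excitation boundary data) to the fluorescence yield gamma and, in the
#' frequency domain, to the lifetime tau. The gamma block is
#' \code{Phi_x/(1+1i*omega*tau) .* Psi_m * voxel_volume}; the tau block
#' differentiates the lifetime kernel (zero at omega = 0, so CW returns only
#' the real gamma block).
#'
#' @inheritParams jacobian_standard
#' @param mesh fluorescence \code{fem_mesh}
#' @param born_ratio divide rows by the excitation boundary data (default)
#' @return a \code{fem_jacobian} with block \code{gamma} (CW) or blocks
#'   \code{gamma}, \code{tau} (FD)
#' @export
jacobian_fluorescence <- function(mesh, grid, omega = 0, born_ratio = TRUE,
                                  opts = solver_defaults()) {
  sys <- assemble_fluorescence(mesh)
  Q <- build_source_vectors(mesh)
  Qadj <- adjoint_source_vectors(mesh)
  link <- mesh$optodes$link
  p <- mesh$props
  meas <- measurement_matrix(mesh)
  if (omega == 0) {
    phix <- solve_real(sys$x$A, Q, "cw", opts)$x
    Mm <- build_fsai(sys$m$A, "pcg_diag4")
    psim <- pcg_solve(sys$m$A, Mm, as.matrix(Qadj), tol = opts$tol,
                      maxit = opts$maxit)$x
  } else {
    Mx <- build_fsai(sys$x$A, "bicgstab3")
    phix <- bicgstab_solve(list(re = sys$x$A, im = omega * sys$x$B), Mx,
                           as.matrix(Q), tol = opts$tol, maxit = opts$maxit)$x
    Mm <- build_fsai(sys$m$A, "bicgstab3")
    psim <- bicgstab_solve(list(re = sys$m$A, im = omega * sys$m$B), Mm,
                           as.matrix(Qadj), tol = opts$tol,
                           maxit = opts$maxit)$x
  }
  bx <- channel_values(meas, phix, link)
  lifetime_kernel <- 1 / (1 + 1i * omega * p$tau)
  phixv <- grid_project(grid, phix)
  psimv <- grid_project(grid, psim)
  kernv <- grid_project(grid, lifetime_kernel)[, 1]
  gamv <- grid_project(grid, p$gamma)[, 1]
  rows <- which(grid$inside)
  vol <- grid$voxel_volume
  nch <- nrow(link); nv <- length(rows)
  fd <- omega != 0
  Jg <- matrix(if (fd) 0i else 0, nch, nv)
  Jt <- if (fd) matrix(0i, nch, nv) else NULL
  for (ch in seq_len(nch)) {
    s <- link[ch, 1]; dct <- link[ch, 2]
    prod_sd <- phixv[rows, s] * psimv[rows, dct] * vol
    Jg[ch, ] <- prod_sd * kernv[rows]
    if (fd)
      Jt[ch, ] <- prod_sd * gamv[rows] * (-1i * omega * kernv[rows]^2)
    if (born_ratio) {
      Jg[ch, ] <- Jg[ch, ] / bx[ch]
      if (fd) Jt[ch, ] <- Jt[ch, ] / bx[ch]
    }
  }
  if (!fd) {
    jacobian_obj(Re(Jg), "gamma", grid, FALSE, omega,
                 extra = list(excitation_boundary = bx, link = link,
                              born_ratio = born_ratio))
  } else {
    jacobian_obj(interleave_ri(cbind(Jg, Jt)), c("gamma", "tau"), grid,
                 FALSE, omega,
                 extra = list(excitation_boundary = bx, link = link,
                              born_ratio = born_ratio))
  }
}

#' Voxel-space DCS Jacobians over a delay sweep
#'
#' For each correlation delay tau, the sensitivity of G1(tau) (by default of
#' log G1(tau)) to the voxel flow index alphaDb: the adjoint mua-type product
#' scaled by the local factor \code{2*musp*k0^2*tau} from the
#' correlation-diffusion absorption substitution. The tau = 0 entry is the
#' zero matrix.
#'
#' @inheritParams jacobian_standard
#' @param mesh dcs \code{fem_mesh}
#' @param tau_vector ascending delays, seconds, starting at 0
#' @param log_data return d log(G1) / d alphaDb (the default)
#' @return list of \code{fem_jacobian}, one per delay
#' @export
jacobian_dcs <- function(mesh, grid, tau_vector, log_data = TRUE,
                         opts = solver_defaults()) {
  if (is.unsorted(tau_vector) || tau_vector[1] != 0)
    stop("tau_vector must be ascending and start at 0")
  sys <- assemble_dcs(mesh, 0)
  Q <- as.matrix(build_source_vectors(mesh))
  Qadj <- as.matrix(adjoint_source_vectors(mesh))
  meas <- measurement_matrix(mesh)
  link <- mesh$optodes$link
  k0 <- k0_wavenumber(mesh)
  muspv <- grid_project(grid, mesh$props$musp)[, 1]
  rows <- which(grid$inside)
  vol <- grid$voxel_volume
  out <- vector("list", length(tau_vector))
  prev_phi <- NULL; prev_psi <- NULL
  for (k in seq_along(tau_vector)) {
    tau <- tau_vector[k]
    A <- if (tau == 0) sys$A0 else sys$A0 + tau * sys$Mdyn
    M <- build_fsai(A, "pcg_diag4")
    phi <- pcg_solve(A, M, Q, tol = opts$tol, maxit = opts$maxit,
                     x0 = prev_phi)$x
    psi <- pcg_solve(A, M, Qadj, tol = opts$tol, maxit = opts$maxit,
                     x0 = prev_psi)$x
    prev_phi <- phi; prev_psi <- psi
    bval <- channel_values(meas, phi, link)
    phiv <- grid_project(grid, phi)
    psiv <- grid_project(grid, psi)
    J <- matrix(0, nrow(link), length(rows))
    if (tau > 0) {
      scale <- 2 * muspv[rows] * k0^2 * tau
      for (ch in seq_len(nrow(link))) {
        row <- -phiv[rows, link[ch, 1]] * psiv[rows, link[ch, 2]] *
          scale * vol
        if (log_data) row <- row / bval[ch]
        J[ch, ] <- row
      }
    }
    out[[k]] <- jacobian_obj(J, "alphaDb", grid, log_data, 0,
                             extra = list(tau = tau, boundary = bval,
                                          link = link))
  }
  out
}

#' Tikhonov-regularized linear reconstruction
#'
#' Underdetermined-form Tikhonov update:
#' \code{x = J' (J J' + lambda * max(diag(J J')) I)^-1 y}. Scaling the
#' regularizer by the largest diagonal of \code{J J'} makes \code{lambda}
#' scale-free. Returns the update image on the full grid with outside voxels
#' set to \code{NA}.
#'
#' @param J a \code{fem_jacobian} (or plain matrix with attribute-free rows)
#' @param y data vector, length \code{nrow(J)}
#' @param lam regularization parameter (> 0), e.g. 10
#' @return list with \code{image} (full-grid voxel vector, NA outside),
#'   \code{update} (inside-voxel coefficients, all parameter blocks)
#' @export
tikhonov_reconstruct <- function(J, y, lam) {
  if (lam <= 0) stop("lambda must be > 0")
  Jm <- if (inherits(J, "fem_jacobian")) J$matrix else as.matrix(J)
  if (nrow(Jm) != length(y)) stop("rows(J) must equal length(y)")
  JJt <- Jm %*% t(Jm)
  reg <- lam * max(diag(JJt))
  x <- as.numeric(t(Jm) %*% solve(JJt + reg * diag(nrow(JJt)), y))
  out <- list(update = x)
  if (inherits(J, "fem_jacobian")) {
    nv <- sum(J$inside)
    nblk <- length(J$blocks)
    img <- vector("list", nblk)
    for (b in seq_len(nblk)) {
      full <- rep(NA_real_, length(J$inside))
      full[J$inside] <- x[((b - 1) * nv + 1):(b * nv)]
      img[[b]] <- full
    }
    names(img) <- J$blocks
    out$image <- if (nblk == 1L) img[[1]] else img
    out$dims <- J$dims
  }
  out
}
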