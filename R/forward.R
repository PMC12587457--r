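# Forward data engines. All of them assemble Eq.-(3)-style operators, pick a
# Krylov solver via choose_solver(), solve per source, and read out boundary
# channel data by barycentric interpolation at the projected detector points.

solver_defaults <- function(tol = 1e-12, maxit = 1000, force = "auto") {
  list(tol = tol, maxit = maxit, force = force)
}

# solve A X = Q with the auto-selected solver for a real problem kind
solve_real <- function(A, Q, kind, opts = solver_defaults(), x0 = NULL,
                       M = NULL) {
  sel <- choose_solver(kind, opts$force)
  if (is.null(M)) M <- build_fsai(A, sel$pattern)
  res <- if (sel$solver == "pcg")
    pcg_solve(A, M, Q, tol = opts$tol, maxit = opts$maxit, x0 = x0)
  else
    bicgstab_solve(A, M, Q, tol = opts$tol, maxit = opts$maxit, x0 = x0)
  check_convergence(res, opts)
  res$M <- M
  res
}

check_convergence <- function(res, opts) {
  bad <- which(res$residuals > opts$tol * 10 & res$iterations >= opts$maxit)
  if (length(bad))
    stop("solver failed to converge for column(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (worst relative residual ",
         format(max(res$residuals), digits = 3), ")")
  invisible(TRUE)
}

channel_values <- function(meas, phi, link) {
  bnd <- as.matrix(meas %*% Re(phi))
  if (is.complex(phi)) bnd <- bnd + 1i * as.matrix(meas %*% Im(phi))
  bnd[cbind(link[, 2], link[, 1])]
}

#' CW / frequency-domain forward data on a standard mesh
#'
#' Solves \code{(A + 1i*omega*B) Phi = Q} for every source and reads out the
#' boundary channel data of the link table. At \code{omega = 0} the problem
#' is real and solved with FSAI-preconditioned CG; otherwise with BiCGStab.
#'
#' @param mesh a standard (or dcs) \code{fem_mesh} with placed optodes
#' @param omega modulation angular frequency, rad/s (0 for CW)
#' @param grid optional \code{voxel_grid}: also return the fluence mapped to
#'   voxels
#' @param opts solver options from \code{\link{solver_defaults}}
#' @return \code{field_data}: nodal fluence \code{phi} (N x S), per-channel
#'   \code{boundary} values, \code{omega}, optionally \code{phi_voxel}
#' @export
femdata_standard <- function(mesh, omega = 0, grid = NULL,
                             opts = solver_defaults()) {
  sys <- assemble_standard(mesh)
  Q <- build_source_vectors(mesh)
  meas <- measurement_matrix(mesh)
  if (omega == 0) {
    res <- solve_real(sys$A, Q, "cw", opts)
    phi <- res$x
  } else {
    M <- build_fsai(sys$A, choose_solver("fd", opts$force)$pattern)
    res <- if (choose_solver("fd", opts$force)$solver == "pcg")
      stop("PCG cannot solve the complex FD system; use force = 'auto' or 'bicgstab'")
    else bicgstab_solve(list(re = sys$A, im = omega * sys$B), M, Q,
                        tol = opts$tol, maxit = opts$maxit)
    check_convergence(res, opts)
    phi <- res$x
  }
  out <- list(phi = phi, omega = omega,
              boundary = channel_values(meas, phi, mesh$optodes$link),
              link = mesh$optodes$link)
  if (!is.null(grid)) out$phi_voxel <- grid_project(grid, phi)
  structure(out, class = "field_data")
}

#' CW / frequency-domain forward data on a fluorescence mesh
#'
#' Solves the excitation field, forms the nodal emission source
#' \code{q_m = U (gamma * Phi_x / (1 + 1i*omega*tau))}, solves the re-emission
#' field, and reports per-channel excitation and emission boundary data plus
#' their ratio (the Born ratio, the default reported quantity).
#'
#' @inheritParams femdata_standard
#' @param mesh a fluorescence \code{fem_mesh}
#' @return list of \code{field_data} \code{x} and \code{m}, plus
#'   \code{born_ratio} per channel
#' @export
femdata_fluorescence <- function(mesh, omega = 0, grid = NULL,
                                 opts = solver_defaults()) {
  sys <- assemble_fluorescence(mesh)
  Q <- build_source_vectors(mesh)
  meas <- measurement_matrix(mesh)
  p <- mesh$props
  link <- mesh$optodes$link
  if (omega == 0) {
    phix <- solve_real(sys$x$A, Q, "cw", opts)$x
    qm <- as.matrix(sys$U %*% (p$gamma * phix))
    phim <- solve_real(sys$m$A, qm, "cw", opts)$x
  } else {
    Mx <- build_fsai(sys$x$A, "bicgstab3")
    rx <- bicgstab_solve(list(re = sys$x$A, im = omega * sys$x$B), Mx, Q,
                         tol = opts$tol, maxit = opts$maxit)
    check_convergence(rx, opts)
    phix <- rx$x
    src <- phix * (p$gamma / (1 + 1i * omega * p$tau))
    qm <- as.matrix(sys$U %*% Re(src)) + 1i * as.matrix(sys$U %*% Im(src))
    Mm <- build_fsai(sys$m$A, "bicgstab3")
    rm_ <- bicgstab_solve(list(re = sys$m$A, im = omega * sys$m$B), Mm, qm,
                          tol = opts$tol, maxit = opts$maxit)
    check_convergence(rm_, opts)
    phim <- rm_$x
  }
  bx <- channel_values(meas, phix, link)
  bm <- channel_values(meas, phim, link)
  out <- list(
    x = structure(list(phi = phix, omega = omega, boundary = bx, link = link),
                  class = "field_data"),
    m = structure(list(phi = phim, omega = omega, boundary = bm, link = link),
                  class = "field_data"),
    born_ratio = bm / bx)
  if (!is.null(grid)) {
    out$x$phi_voxel <- grid_project(grid, phix)
    out$m$phi_voxel <- grid_project(grid, phim)
  }
  out
}

#' Time-resolved boundary data (TPSF) on a standard mesh by time stepping
#'
#' Theta-scheme stepping (Crank-Nicolson by default) of
#' \code{B dPhi/dt + A Phi = 0} after an impulse launch \code{B Phi0 = Q}
#' (mass-consistent delta, which preserves the time integral of the TPSF
#' equal to the CW boundary value up to discretization error). One FSAI
#' preconditioner of the constant step operator is reused across all steps,
#' and each step's solve is warm-started from the previous field.
#'
#' @param mesh standard \code{fem_mesh} with placed optodes
#' @param t_end simulated span, seconds
#' @param dt time step, seconds
#' @param grid optional \code{voxel_grid} for internal voxel-space curves
#' @param theta implicitness parameter in (0, 1]; 0.5 = Crank-Nicolson,
#'   1 = backward Euler (more damping, robust for stiff early times)
#' @param opts solver options
#' @return \code{tpsf_data}: \code{time} (seconds), \code{curves}
#'   (time x channels), optionally \code{voxel} (time-major list)
#' @export
femdata_tpsf_standard <- function(mesh, t_end, dt, grid = NULL, theta = 0.5,
                                  opts = solver_defaults()) {
  if (dt <= 0 || t_end <= 0) stop("t_end and dt must be positive")
  sys <- assemble_standard(mesh)
  Q <- build_source_vectors(mesh)
  meas <- measurement_matrix(mesh)
  step <- tpsf_stepper(sys$A, sys$B, dt, theta, opts)
  nt <- as.integer(round(t_end / dt))
  phi <- step$init(as.matrix(Q))
  link <- mesh$optodes$link
  curves <- matrix(0, nt + 1L, nrow(link))
  curves[1, ] <- channel_values(meas, phi, link)
  voxel <- if (!is.null(grid)) vector("list", nt + 1L) else NULL
  if (!is.null(grid)) voxel[[1]] <- grid_project(grid, phi)
  for (k in seq_len(nt)) {
    phi <- step$advance(phi)
    curves[k + 1L, ] <- channel_values(meas, phi, link)
    if (!is.null(grid)) voxel[[k + 1L]] <- grid_project(grid, phi)
  }
  structure(list(time = dt * (0:nt), curves = curves, voxel = voxel,
                 link = link), class = "tpsf_data")
}

# shared theta-scheme stepping machinery: L1 = B/dt + theta*A,
# L2 = B/dt - (1-theta)*A; solves are PCG with one FSAI, warm-started
tpsf_stepper <- function(A, B, dt, theta, opts) {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  L1 <- B / dt + theta * A
  L2 <- B / dt - (1 - theta) * A
  sel <- choose_solver("tpsf", opts$force)
  M1 <- build_fsai(L1, sel$pattern)
  MB <- build_fsai(B, sel$pattern)
  list(
    init = function(Q) {
      res <- pcg_solve(B, MB, Q, tol = opts$tol, maxit = opts$maxit)
      check_convergence(res, opts)
      res$x
    },
    advance = function(phi, extra_rhs = NULL) {
      rhs <- as.matrix(L2 %*% phi)
      if (!is.null(extra_rhs)) rhs <- rhs + extra_rhs
      res <- pcg_solve(L1, M1, rhs, tol = opts$tol, maxit = opts$maxit,
                       x0 = phi)
      check_convergence(res, opts)
      res$x
    })
}

#' Time-resolved excitation and re-emission TPSFs on a fluorescence mesh
#'
#' The excitation field is stepped as in the standard problem; the emission
#' source at each step is the running exponential convolution of the
#' excitation field with the fluorophore decay kernel,
#' \code{w_{k+1} = w_k exp(-dt/tau) + (gamma*Phi_x_{k+1}) (1 - exp(-dt/tau))}
#' (elementwise, per-node lifetimes; tau = 0 degenerates to instantaneous
#' re-emission \code{w = gamma*Phi_x}), applied through the overlap matrix
#' \code{U}; the emission field is then stepped with that source.
#'
#' @inheritParams femdata_tpsf_standard
#' @param mesh fluorescence \code{fem_mesh}
#' @return list of \code{tpsf_data} for \code{x} and \code{m}
#' @export
femdata_tpsf_fluorescence <- function(mesh, t_end, dt, grid = NULL,
                                      theta = 0.5, opts = solver_defaults()) {
  if (dt <= 0 || t_end <= 0) stop("t_end and dt must be positive")
  sys <- assemble_fluorescence(mesh)
  Q <- build_source_vectors(mesh)
  meas <- measurement_matrix(mesh)
  p <- mesh$props
  decay <- exp(-dt / p$tau)          # tau = 0 -> 0: instantaneous emission
  gain <- 1 - decay
  stepx <- tpsf_stepper(sys$x$A, sys$x$B, dt, theta, opts)
  stepm <- tpsf_stepper(sys$m$A, sys$m$B, dt, theta, opts)
  nt <- as.integer(round(t_end / dt))
  link <- mesh$optodes$link
  phix <- stepx$init(as.matrix(Q))
  phim <- matrix(0, nrow(phix), ncol(phix))
  w <- phix * 0
  cx <- matrix(0, nt + 1L, nrow(link)); cm <- matrix(0, nt + 1L, nrow(link))
  cx[1, ] <- channel_values(meas, phix, link)
  src_prev <- as.matrix(sys$U %*% w)
  for (k in seq_len(nt)) {
    phix <- stepx$advance(phix)
    w <- w * decay + (p$gamma * phix) * gain
    src <- as.matrix(sys$U %*% w)
    phim <- stepm$advance(phim, extra_rhs = (src + src_prev) / 2)
    src_prev <- src
    cx[k + 1L, ] <- channel_values(meas, phix, link)
    cm[k + 1L, ] <- channel_values(meas, phim, link)
  }
  tvec <- dt * (0:nt)
  list(x = structure(list(time = tvec, curves = cx, link = link),
                     class = "tpsf_data"),
       m = structure(list(time = tvec, curves = cm, link = link),
                     class = "tpsf_data"))
}

#' Direct time-resolved moments on a standard mesh (Mellin recursion)
#'
#' The Mellin transforms of the nodal TPSF satisfy \code{m_0 = A^-1 Q} (the
#' CW solve) and \code{m_n = n A^-1 (B m_{n-1})}, so each moment order costs
#' a single linear solve instead of a full time-stepping run. Boundary
#' moments are detector interpolations of the Mellin fields; normalized
#' moments are \code{<t^n> = m_n / m_0} per channel.
#'
#' @param mesh standard \code{fem_mesh} with placed optodes
#' @param max_order highest moment order K (>= 0)
#' @param grid optional \code{voxel_grid} for voxel-space Mellin fields
#' @param opts solver options
#' @return \code{moments_data}: \code{mellin} (list of N x S fields),
#'   \code{boundary_mellin} ((K+1) x channels), \code{normalized},
#'   \code{mean_time}, \code{variance}
#' @export
moments_standard <- function(mesh, max_order = 2, grid = NULL,
                             opts = solver_defaults()) {
  if (max_order < 0) stop("max_order must be >= 0")
  sys <- assemble_standard(mesh)
  Q <- build_source_vectors(mesh)
  meas <- measurement_matrix(mesh)
  sel <- choose_solver("moments", opts$force)
  M <- build_fsai(sys$A, sel$pattern)
  mellin <- vector("list", max_order + 1L)
  res <- pcg_solve(sys$A, M, as.matrix(Q), tol = opts$tol, maxit = opts$maxit)
  check_convergence(res, opts)
  mellin[[1]] <- res$x
  for (n in seq_len(max_order)) {
    rhs <- n * as.matrix(sys$B %*% mellin[[n]])
    res <- pcg_solve(sys$A, M, rhs, tol = opts$tol, maxit = opts$maxit)
    check_convergence(res, opts)
    mellin[[n + 1L]] <- res$x
  }
  finalize_moments(mesh, meas, mellin, grid)
}

finalize_moments <- function(mesh, meas, mellin, grid) {
  link <- mesh$optodes$link
  K <- length(mellin) - 1L
  bnd <- t(vapply(mellin, function(mm) channel_values(meas, mm, link),
                  numeric(nrow(link))))
  if (nrow(link) == 1L) bnd <- matrix(bnd, ncol = 1L)
  normalized <- sweep(bnd, 2, bnd[1, ], "/")
  out <- list(mellin = mellin, boundary_mellin = bnd, normalized = normalized,
              link = link)
  out$mean_time <- if (K >= 1) normalized[2, ] else NULL
  out$variance <- if (K >= 2) normalized[3, ] - normalized[2, ]^2 else NULL
  if (!is.null(grid)) out$mellin_voxel <- lapply(mellin, function(mm)
    grid_project(grid, mm))
  structure(out, class = "moments_data")
}

#' Direct moments on a fluorescence mesh (coupled Mellin recursions)
#'
#' Implements the coupled three-line recursion: at order 0,
#' \code{m0x = Ax^-1 qx}, \code{s0 = gamma*m0x}, \code{m0m = Am^-1 U s0}
#' (the CW coupled solve); for n >= 1,
#' \code{mnx = n Ax^-1 Bx m(n-1)x},
#' \code{sn = gamma*mnx + n (tau*s(n-1))},
#' \code{mnm = Am^-1 (n Bm m(n-1)m + U sn)},
#' with elementwise products; normalized moments are \code{mn / m0} per
#' channel for both fields.
#'
#' @inheritParams moments_standard
#' @param mesh fluorescence \code{fem_mesh}
#' @return list of \code{moments_data} for \code{x} and \code{m}
#' @export
moments_fluorescence <- function(mesh, max_order = 2, grid = NULL,
                                 opts = solver_defaults()) {
  if (max_order < 0) stop("max_order must be >= 0")
  sys <- assemble_fluorescence(mesh)
  Q <- build_source_vectors(mesh)
  meas <- measurement_matrix(mesh)
  p <- mesh$props
  Mx <- build_fsai(sys$x$A, "pcg_diag4")
  Mm <- build_fsai(sys$m$A, "pcg_diag4")
  slv <- function(A, M, rhs) {
    res <- pcg_solve(A, M, as.matrix(rhs), tol = opts$tol, maxit = opts$maxit)
    check_convergence(res, solver_defaults(opts$tol, opts$maxit))
    res$x
  }
  mx <- vector("list", max_order + 1L)
  mm <- vector("list", max_order + 1L)
  mx[[1]] <- slv(sys$x$A, Mx, Q)
  s <- p$gamma * mx[[1]]
  mm[[1]] <- slv(sys$m$A, Mm, sys$U %*% s)
  if (any(abs(channel_values(meas, mm[[1]], mesh$optodes$link)) == 0))
    stop("degenerate normalization: zero emission intensity on a channel")
  for (n in seq_len(max_order)) {
    mx[[n + 1L]] <- slv(sys$x$A, Mx, n * (sys$x$B %*% mx[[n]]))
    s <- p$gamma * mx[[n + 1L]] + n * (p$tau * s)
    mm[[n + 1L]] <- slv(sys$m$A, Mm, n * (sys$m$B %*% mm[[n]]) + sys$U %*% s)
  }
  list(x = finalize_moments(mesh, meas, mx, grid),
       m = finalize_moments(mesh, meas, mm, grid))
}

#' DCS forward data: G1 and g1 curves
#'
#' Sweeps the correlation delay: for each tau solves
#' \code{A(tau) G1 = Q} with the cached dynamic-absorption decomposition
#' \code{A(tau) = A(0) + tau*Mdyn}, and normalizes each channel by its own
#' tau = 0 (CW) value to obtain g1. Solutions are warm-started along the
#' sweep.
#'
#' @param mesh dcs \code{fem_mesh} with placed optodes
#' @param tau_vector ascending delays, seconds, starting at 0
#' @param grid optional \code{voxel_grid} for voxel-space G1 fields
#' @param opts solver options
#' @return \code{g1_data}: \code{tau}, \code{G1} (delays x channels),
#'   \code{g1}, optionally voxel fields at each delay
#' @export
femdata_dcs <- function(mesh, tau_vector, grid = NULL,
                        opts = solver_defaults()) {
  if (is.unsorted(tau_vector) || tau_vector[1] != 0)
    stop("tau_vector must be ascending and start at 0")
  sys <- assemble_dcs(mesh, 0)
  Q <- as.matrix(build_source_vectors(mesh))
  meas <- measurement_matrix(mesh)
  link <- mesh$optodes$link
  nt <- length(tau_vector)
  G1 <- matrix(0, nt, nrow(link))
  voxel <- if (!is.null(grid)) vector("list", nt) else NULL
  prev <- NULL
  for (k in seq_len(nt)) {
    A <- if (tau_vector[k] == 0) sys$A0 else sys$A0 + tau_vector[k] * sys$Mdyn
    M <- build_fsai(A, choose_solver("dcs", opts$force)$pattern)
    res <- pcg_solve(A, M, Q, tol = opts$tol, maxit = opts$maxit, x0 = prev)
    check_convergence(res, opts)
    prev <- res$x
    G1[k, ] <- channel_values(meas, res$x, link)
    if (!is.null(grid)) voxel[[k]] <- grid_project(grid, res$x)
  }
  g1 <- sweep(G1, 2, G1[1, ], "/")
  structure(list(tau = tau_vector, G1 = G1, g1 = g1, voxel = voxel,
                 link = link), class = "g1_data")
}

# trapezoidal rule, used for TPSF integrals
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
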