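#' @importFrom Matrix sparseMatrix drop0 forceSymmetric crossprod t diag solve
NULL

# ---- low-level weighted element matrices -----------------------------------

# P1 gradient vectors per element: list of dim matrices E x (dim+1), plus
# volumes; grads[[k]][e, i] = d(basis_i)/d(x_k) on element e
element_gradients <- function(mesh) {
  el <- mesh$elements; nd <- mesh$nodes
  d <- mesh$dim
  vol <- element_signed_volumes(mesh)
  if (d == 2L) {
    a <- nd[el[, 1], , drop = FALSE]; b <- nd[el[, 2], , drop = FALSE]
    c3 <- nd[el[, 3], , drop = FALSE]
    det2 <- 2 * vol
    gx <- cbind(b[, 2] - c3[, 2], c3[, 2] - a[, 2], a[, 2] - b[, 2]) / det2
    gy <- cbind(c3[, 1] - b[, 1], a[, 1] - c3[, 1], b[, 1] - a[, 1]) / det2
    list(grads = list(gx, gy), vol = vol)
  } else {
    a <- nd[el[, 1], , drop = FALSE]; b <- nd[el[, 2], , drop = FALSE]
    c3 <- nd[el[, 3], , drop = FALSE]; e4 <- nd[el[, 4], , drop = FALSE]
    det6 <- 6 * vol
    crossv <- function(u, v)
      cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
            u[, 3] * v[, 1] - u[, 1] * v[, 3],
            u[, 1] * v[, 2] - u[, 2] * v[, 1])
    # grad of basis i = (opposite-face normal scaled) / 6V, inward orientation
    g1 <- crossv(e4 - b, c3 - b) / det6
    g2 <- crossv(c3 - a, e4 - a) / det6
    g3 <- crossv(e4 - a, b - a) / det6
    g4 <- crossv(b - a, c3 - a) / det6
    list(grads = list(cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
                      cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
                      cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])),
         vol = vol)
  }
}

# sparse symmetric matrix from per-element (dim+1)x(dim+1) blocks given as a
# function block(i, j) -> numeric(E)
assemble_blocks <- function(mesh, block) {
  el <- mesh$elements
  k <- mesh$dim + 1L
  n <- nrow(mesh$nodes)
  ii <- list(); jj <- list(); xx <- list(); t <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    t <- t + 1L
    ii[[t]] <- el[, i]; jj[[t]] <- el[, j]; xx[[t]] <- block(i, j)
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(n, n))
}

# stiffness matrix weighted by the element mean of a nodal coefficient field
stiffness_matrix <- function(mesh, coef) {
  eg <- element_gradients(mesh)
  ce <- rowMeans(matrix(coef[mesh$elements], nrow(mesh$elements)))
  w <- ce * eg$vol
  assemble_blocks(mesh, function(i, j) {
    s <- 0
    for (g in eg$grads) s <- s + g[, i] * g[, j]
    w * s
  })
}

# mass matrix weighted by the element mean of a nodal field
# (P1 exact: int lam_i lam_j = V/20*(1+delta) in 3D, A/12*(1+delta) in 2D)
mass_matrix <- function(mesh, coef = NULL) {
  vol <- element_signed_volumes(mesh)
  ce <- if (is.null(coef)) rep(1, nrow(mesh$elements)) else
    rowMeans(matrix(coef[mesh$elements], nrow(mesh$elements)))
  base <- if (mesh$dim == 2L) vol / 12 else vol / 20
  w <- ce * base
  assemble_blocks(mesh, function(i, j) w * (1 + (i == j)))
}

# surface mass matrix over the boundary faces (triangle: Area/12*(1+delta);
# 2D edge: Length/6*(1+delta))
boundary_mass_matrix <- function(mesh) {
  bf <- boundary_faces(mesh)
  faces <- bf$faces
  n <- nrow(mesh$nodes)
  k <- ncol(faces)
  base <- if (mesh$dim == 2L) bf$measure / 6 else bf$measure / 12
  ii <- list(); jj <- list(); xx <- list(); t <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    t <- t + 1L
    ii[[t]] <- faces[, i]; jj[[t]] <- faces[, j]
    xx[[t]] <- base * (1 + (i == j))
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(n, n))
}

# ---- user-facing assembly ---------------------------------------------------

fem_system <- function(A, B, U, beta, extra = list()) {
  structure(c(list(A = A, B = B, U = U, beta = beta), extra),
            class = "fem_system")
}

#' Assemble the FEM system matrices for a standard (or DCS-base) mesh
#'
#' Builds the sparse symmetric operators of the discretized diffusion model:
#' \code{A = K(kappa) + M(mua) + (1/(2*beta)) * M_boundary} (stiffness +
#' absorption + Robin boundary term), the 1/c-weighted mass matrix \code{B}
#' (so the frequency-domain operator is \code{A + 1i*omega*B}), and the
#' basis-overlap matrix \code{U} (unweighted mass matrix). Per-element
#' weighted integrals use the element mean of the nodal property values
#' (lowest-order P1 choice). The Robin scalar beta is computed from the modal
#' boundary refractive index, by default with the Groenhuis empirical method.
#'
#' @param mesh a \code{fem_mesh} of kind \code{stnd} or \code{dcs}
#' @param beta_method method passed to \code{\link{boundary_beta}}
#' @param n_outside refractive index of the surrounding medium (default 1, air)
#' @return a \code{fem_system} with fields \code{A}, \code{B}, \code{U},
#'   \code{beta}
#' @export
assemble_standard <- function(mesh, beta_method = "groenhuis", n_outside = 1) {
  if (!mesh$kind %in% c("stnd", "dcs"))
    stop("assemble_standard needs a standard or dcs mesh")
  p <- mesh$props
  kap <- kappa_field(mesh)
  beta <- boundary_beta(modal_boundary_ri(mesh), n_outside, beta_method)
  A <- stiffness_matrix(mesh, kap) + mass_matrix(mesh, p$mua) +
    boundary_mass_matrix(mesh) / (2 * beta)
  B <- mass_matrix(mesh, 1 / c_field(mesh))
  U <- mass_matrix(mesh)
  fem_system(drop0(forceSymmetric(A)), drop0(forceSymmetric(B)),
             drop0(forceSymmetric(U)), beta)
}

modal_boundary_ri <- function(mesh) {
  ri <- mesh$props$ri[mesh$boundary_flag]
  ux <- unique(ri)
  ux[which.max(tabulate(match(ri, ux)))]
}

#' Assemble the coupled fluorescence systems
#'
#' Two independent standard assemblies at the excitation (x) and re-emission
#' (m) optical properties; the basis-overlap matrix \code{U}, through which
#' the excitation field drives the emission source, is shared.
#'
#' @inheritParams assemble_standard
#' @param mesh a \code{fem_mesh} of kind \code{fluor}
#' @return list with \code{fem_system}s \code{x} and \code{m} and the shared
#'   overlap matrix \code{U}
#' @export
assemble_fluorescence <- function(mesh, beta_method = "groenhuis", n_outside = 1) {
  if (mesh$kind != "fluor") stop("assemble_fluorescence needs a fluorescence mesh")
  p <- mesh$props
  beta <- boundary_beta(modal_boundary_ri(mesh), n_outside, beta_method)
  Mb <- boundary_mass_matrix(mesh) / (2 * beta)
  B <- drop0(forceSymmetric(mass_matrix(mesh, 1 / c_field(mesh))))
  U <- drop0(forceSymmetric(mass_matrix(mesh)))
  Ax <- stiffness_matrix(mesh, kappa_field(mesh, "x")) +
    mass_matrix(mesh, p$muax) + Mb
  Am <- stiffness_matrix(mesh, kappa_field(mesh, "m")) +
    mass_matrix(mesh, p$muam) + Mb
  list(x = fem_system(drop0(forceSymmetric(Ax)), B, U, beta),
       m = fem_system(drop0(forceSymmetric(Am)), B, U, beta),
       U = U, beta = beta)
}

#' Assemble the correlation-diffusion system at a delay time
#'
#' For the DCS model the operator at delay \code{tau_delay} is
#' \code{A(tau) = A(0) + tau * M(2*alphaDb*musp*k0^2)}: the standard assembly
#' plus a dynamic-absorption mass term. \code{A(0)} and the dynamic mass
#' matrix are both returned so a tau sweep costs one sparse add per delay.
#'
#' @inheritParams assemble_standard
#' @param mesh a \code{fem_mesh} of kind \code{dcs}
#' @param tau_delay correlation delay time, seconds (>= 0)
#' @return a \code{fem_system} with extra fields \code{A0} (operator at
#'   tau = 0) and \code{Mdyn} (dynamic mass term); \code{A = A0 + tau*Mdyn}
#' @export
assemble_dcs <- function(mesh, tau_delay = 0, beta_method = "groenhuis",
                         n_outside = 1) {
  if (mesh$kind != "dcs") stop("assemble_dcs needs a dcs mesh")
  if (tau_delay < 0) stop("tau_delay must be >= 0")
  s0 <- assemble_standard(mesh, beta_method, n_outside)
  k0 <- k0_wavenumber(mesh)
  Mdyn <- drop0(forceSymmetric(mass_matrix(
    mesh, 2 * mesh$props$alphaDb * mesh$props$musp * k0^2)))
  A <- if (tau_delay > 0) s0$A + tau_delay * Mdyn else s0$A
  fem_system(A, s0$B, s0$U, s0$beta,
             extra = list(A0 = s0$A, Mdyn = Mdyn, tau_delay = tau_delay))
}

#' Build FEM point-source load vectors
#'
#' Each (placed) source deposits unit total strength on the vertices of its
#' containing element, split by barycentric weights, so every column of
#' \code{Q} sums to one.
#'
#' @param mesh a \code{fem_mesh} with placed optodes
#' @param smat optional \code{fem_system} (unused by the P1 load; accepted for
#'   call-site symmetry)
#' @return sparse N x S matrix \code{Q}
#' @export
build_source_vectors <- function(mesh, smat = NULL) {
  src <- mesh$optodes$sources
  if (nrow(src) == 0) stop("mesh has no sources; call place_optodes() first")
  loc <- locate_points(mesh, src, tol = 1e-7)
  if (anyNA(loc$element))
    stop("source ", which(is.na(loc$element))[1], " lies outside the mesh")
  k <- mesh$dim + 1L
  n <- nrow(mesh$nodes)
  ii <- as.vector(t(mesh$elements[loc$element, , drop = FALSE]))
  jj <- rep(seq_len(nrow(src)), each = k)
  xx <- as.vector(t(loc$weights))
  Q <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, nrow(src)))
  Q
}

# sparse D x N detector interpolation (measurement) matrix
measurement_matrix <- function(mesh) {
  det <- mesh$optodes$detectors
  if (nrow(det) == 0) stop("mesh has no detectors; call place_optodes() first")
  loc <- locate_points(mesh, det, tol = 1e-6)
  if (anyNA(loc$element))
    stop("detector ", which(is.na(loc$element))[1], " lies outside the mesh")
  k <- mesh$dim + 1L
  sparseMatrix(i = rep(seq_len(nrow(det)), each = k),
               j = as.vector(t(mesh$elements[loc$element, , drop = FALSE])),
               x = as.vector(t(loc$weights)),
               dims = c(nrow(det), nrow(mesh$nodes)))
}
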