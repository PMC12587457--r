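#' Structured tetrahedral slab mesh
#'
#' Builds a box [0,lx] x [0,ly] x [0,lz] on a uniform grid with the requested
#' spacing (dimensions are divided into the nearest whole number of cells).
#' Each hexahedral cell is split into six tetrahedra along its main diagonal
#' (Kuhn split), which is conforming across neighboring cells, so the summed
#' element volume equals lx*ly*lz exactly.
#'
#' @param lx,ly,lz slab dimensions, mm
#' @param spacing target grid spacing, mm: a scalar, or a length-3 vector of
#'   per-axis spacings (anisotropic lattices concentrate resolution along the
#'   axis with the steepest field gradients, typically depth)
#' @param props homogeneous \code{standard_props}/\code{fluor_props}/
#'   \code{dcs_props} applied to all nodes
#' @param grid optional list of three ascending grid-plane vectors
#'   \code{list(xs, ys, zs)} overriding \code{spacing}; non-uniform (graded)
#'   plane spacings concentrate resolution near sources and detectors, the
#'   same adaptivity an unstructured mesher provides. Each vector must start
#'   at 0 and end at the corresponding dimension.
#' @return a \code{fem_mesh}
#' @export
make_slab_mesh <- function(lx, ly, lz, spacing, props = standard_props(),
                           grid = NULL) {
  if (any(c(lx, ly, lz) <= 0)) stop("slab dimensions must be positive")
  if (is.null(grid)) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    if (any(spacing >= c(lx, ly, lz)))
      stop("spacing must be smaller than the corresponding dimension")
    ncx <- max(1L, round(lx / spacing[1]))
    ncy <- max(1L, round(ly / spacing[2]))
    ncz <- max(1L, round(lz / spacing[3]))
    xs <- seq(0, lx, length.out = ncx + 1L)
    ys <- seq(0, ly, length.out = ncy + 1L)
    zs <- seq(0, lz, length.out = ncz + 1L)
  } else {
    xs <- grid[[1]]; ys <- grid[[2]]; zs <- grid[[3]]
    for (g in list(xs, ys, zs))
      if (is.unsorted(g, strictly = TRUE) || length(g) < 2)
        stop("grid plane vectors must be strictly ascending")
    if (abs(xs[1]) > 1e-12 || abs(ys[1]) > 1e-12 || abs(zs[1]) > 1e-12 ||
        abs(xs[length(xs)] - lx) > 1e-9 || abs(ys[length(ys)] - ly) > 1e-9 ||
        abs(zs[length(zs)] - lz) > 1e-9)
      stop("grid plane vectors must span [0, dimension]")
    ncx <- length(xs) - 1L; ncy <- length(ys) - 1L; ncz <- length(zs) - 1L
  }
  nx <- ncx + 1L; ny <- ncy + 1L; nz <- ncz + 1L
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  # cell corner ids, vectorized over all cells
  ci <- rep(seq_len(ncx), times = ncy * ncz)
  cj <- rep(rep(seq_len(ncy), each = ncx), times = ncz)
  ck <- rep(seq_len(ncz), each = ncx * ncy)
  v <- list()
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    v[[paste0(dx, dy, dz)]] <- nid(ci + dx, cj + dy, ck + dz)
  # Kuhn split: six tets sharing the main diagonal 000 -> 111
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  step_key <- function(s) paste0(s[1], s[2], s[3])
  tets <- vector("list", 6)
  for (t in seq_along(perms)) {
    p <- perms[[t]]
    s0 <- c(0L, 0L, 0L)
    s1 <- s0; s1[p[1]] <- 1L
    s2 <- s1; s2[p[2]] <- 1L
    tets[[t]] <- cbind(v[["000"]], v[[step_key(s1)]], v[[step_key(s2)]], v[["111"]])
  }
  elements <- do.call(rbind, tets)
  fem_mesh(nodes, elements, props)
}

#' Triangulated 2D disk mesh
#'
#' Places nodes on concentric rings (spacing ~ radius/K with K chosen from the
#' node-count target) and triangulates adjacent rings with a deterministic
#' angular-merge ("zipper") pass, so no external meshing binary is needed.
#' Optionally places one source and 15 equally spaced detectors on the
#' circumference (the standard single-source circular tomography layout),
#' linking all 15 channels.
#'
#' @param radius disk radius, mm
#' @param target_nodes requested node count (achieved within about 20 percent)
#' @param props homogeneous property set
#' @param optodes if TRUE, place 1 source + 15 circumferential detectors
#' @return a \code{fem_mesh}
#' @export
make_disk_mesh <- function(radius = 43, target_nodes = 2000,
                           props = standard_props(), optodes = FALSE) {
  if (radius <= 0) stop("radius must be positive")
  if (target_nodes < 10) stop("target_nodes must be at least 10")
  K <- max(2L, as.integer(round(sqrt(target_nodes / pi))))
  ring_n <- pmax(6L, as.integer(round(2 * pi * seq_len(K))))
  ids <- vector("list", K + 1L)
  ids[[1]] <- 1L
  coords <- list(matrix(0, 1, 2))
  nxt <- 2L
  for (k in seq_len(K)) {
    nk <- ring_n[k]
    ang <- 2 * pi * (seq_len(nk) - 1) / nk + (k %% 2) * pi / nk
    r <- radius * k / K
    coords[[k + 1L]] <- cbind(r * cos(ang), r * sin(ang))
    ids[[k + 1L]] <- seq.int(nxt, nxt + nk - 1L)
    nxt <- nxt + nk
  }
  nodes <- do.call(rbind, coords)
  angles <- lapply(seq_len(K), function(k)
    atan2(nodes[ids[[k + 1L]], 2], nodes[ids[[k + 1L]], 1]) %% (2 * pi))
  tris <- list()
  # center fan
  r1 <- ids[[2]]; n1 <- length(r1)
  tris[[1]] <- cbind(1L, r1, r1[c(2:n1, 1L)])
  # zipper between consecutive rings
  for (k in 2:K) {
    tris[[k]] <- zipper_rings(ids[[k]], angles[[k - 1L]],
                              ids[[k + 1L]], angles[[k]])
  }
  elements <- do.call(rbind, tris)
  mesh <- fem_mesh(nodes, elements, props)
  if (optodes) {
    ang <- 2 * pi * (0:15) / 16
    pts <- cbind(radius * cos(ang), radius * sin(ang))
    link <- cbind(source = 1L, detector = 1:15, active = 1L)
    mesh <- place_optodes(mesh, pts[1, , drop = FALSE],
                          pts[-1, , drop = FALSE], link)
  }
  mesh
}

# triangulate the annulus between an inner ring and an outer ring, both given
# as node ids with angles sorted ascending in [0, 2pi); produces nI+nO
# triangles; orientation is normalized downstream by the mesh constructor
zipper_rings <- function(inner_ids, inner_ang, outer_ids, outer_ang) {
  oi <- order(inner_ang); inner_ids <- inner_ids[oi]; inner_ang <- inner_ang[oi]
  oo <- order(outer_ang); outer_ids <- outer_ids[oo]; outer_ang <- outer_ang[oo]
  nI <- length(inner_ids); nO <- length(outer_ids)
  ai <- c(inner_ang, inner_ang[1] + 2 * pi)
  bo <- c(outer_ang, outer_ang[1] + 2 * pi)
  tri <- matrix(0L, nI + nO, 3)
  i <- 1L; j <- 1L; t <- 0L
  wrapI <- function(k) inner_ids[(k - 1L) %% nI + 1L]
  wrapO <- function(k) outer_ids[(k - 1L) %% nO + 1L]
  while (i <= nI || j <= nO) {
    adv_outer <- (j <= nO) && (i > nI || bo[j + 1L] <= ai[i + 1L])
    t <- t + 1L
    if (adv_outer) {
      tri[t, ] <- c(wrapO(j), wrapO(j + 1L), wrapI(i))
      j <- j + 1L
    } else {
      tri[t, ] <- c(wrapI(i), wrapI(i + 1L), wrapO(j))
      i <- i + 1L
    }
  }
  tri[seq_len(t), , drop = FALSE]
}

#' Graded grid planes for a slab axis
#'
#' Builds a strictly ascending vector of grid planes spanning [0, len] with a
#' uniform fine band [fine_from, fine_to] at spacing h_fine, stretched
#' geometrically (by `ratio` per step, capped at h_coarse) toward both ends.
#' Used to concentrate slab resolution near optodes, mirroring the adaptive
#' grading an unstructured mesher provides.
#'
#' @param len axis length, mm
#' @param fine_from,fine_to extent of the finely resolved band, mm
#' @param h_fine spacing inside the band, mm
#' @param h_coarse maximum spacing far from the band, mm
#' @param ratio geometric stretch factor per step (> 1)
#' @return numeric vector of plane positions from 0 to len
#' @export
graded_planes <- function(len, fine_from, fine_to, h_fine, h_coarse,
                          ratio = 1.3) {
  stopifnot(len > 0, h_fine > 0, h_coarse >= h_fine, ratio > 1,
            fine_from >= 0, fine_to <= len, fine_from <= fine_to)
  stretch <- function(from, to, h0) {
    # steps from `from` toward `to` growing geometrically, then rescaled so
    # the last plane lands exactly on `to`
    gap <- abs(to - from)
    if (gap < 1e-12) return(numeric(0))
    steps <- c()
    h <- h0
    while (sum(steps) < gap) {
      h <- min(h * ratio, h_coarse)
      steps <- c(steps, h)
    }
    steps <- steps * (gap / sum(steps))
    from + sign(to - from) * cumsum(steps)
  }
  band <- seq(fine_from, fine_to, by = h_fine)
  if (abs(band[length(band)] - fine_to) > 1e-9) band <- c(band, fine_to)
  lower <- rev(stretch(fine_from, 0, h_fine))
  upper <- stretch(fine_to, len, h_fine)
  unique(c(lower, band, upper))
}
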