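#' Place sources and detectors on a mesh
#'
#' Raw optode positions are first projected onto the nearest point of the mesh
#' surface (exact point-to-triangle / point-to-segment projection over all
#' boundary faces, ties broken by lowest face index). Sources are then moved
#' inside along the inward surface normal by one scattering length (1/musp,
#' or 1/muspx on fluorescence meshes) evaluated at the projection point, to
#' satisfy the isotropic-source assumption of the diffusion model; detectors
#' stay on the surface. If a displaced source would exit the mesh (thin
#' geometry), it falls back to the deepest interior point along the normal,
#' with a warning.
#'
#' @param mesh a \code{fem_mesh} with a closed boundary
#' @param raw_sources S x dim matrix of source positions, mm
#' @param raw_detectors D x dim matrix of detector positions, mm
#' @param link optional channel table: columns (source, detector[, active]);
#'   default links every source to every detector
#' @param move_sources move sources one scattering length inside (default TRUE)
#' @return the mesh with its \code{optodes} field populated (positions after
#'   projection/displacement, per-source \code{moved} flags, link table)
#' @export
place_optodes <- function(mesh, raw_sources, raw_detectors, link = NULL,
                          move_sources = TRUE) {
  d <- mesh$dim
  raw_sources <- matrix(as.numeric(raw_sources), ncol = d)
  raw_detectors <- matrix(as.numeric(raw_detectors), ncol = d)
  if (any(!is.finite(raw_sources)) || any(!is.finite(raw_detectors)))
    stop("optode positions must be finite")
  bf <- boundary_faces(mesh)
  ns <- nrow(raw_sources); ndet <- nrow(raw_detectors)
  src <- matrix(NA_real_, ns, d); moved <- logical(ns)
  for (s in seq_len(ns)) {
    pr <- project_to_surface(mesh, bf, raw_sources[s, ])
    if (move_sources) {
      depth <- 1 / scatter_at(mesh, pr$point)
      cand <- pr$point + depth * pr$inward
      if (is.na(locate_point(mesh, cand, tol = 1e-7)$element)) {
        # thin geometry: probe along the normal for the deepest interior point
        ss <- seq(depth, depth / 50, length.out = 50)
        ok <- NA_real_
        for (sc in ss) {
          if (!is.na(locate_point(mesh, pr$point + sc * pr$inward,
                                  tol = 1e-7)$element)) { ok <- sc; break }
        }
        if (is.na(ok)) stop("could not place source ", s, " inside the mesh")
        warning("source ", s, " displacement truncated to ",
                format(ok, digits = 4), " mm (thin geometry)")
        cand <- pr$point + ok * pr$inward
      }
      src[s, ] <- cand; moved[s] <- TRUE
    } else {
      src[s, ] <- pr$point; moved[s] <- FALSE
    }
  }
  det <- matrix(NA_real_, ndet, d)
  for (k in seq_len(ndet)) {
    det[k, ] <- project_to_surface(mesh, bf, raw_detectors[k, ])$point
  }
  if (is.null(link)) {
    link <- cbind(source = rep(seq_len(ns), each = ndet),
                  detector = rep(seq_len(ndet), times = ns),
                  active = 1L)
  } else {
    link <- as.matrix(link)
    if (ncol(link) == 2L) link <- cbind(link, 1L)
    colnames(link) <- c("source", "detector", "active")
    if (any(link[, 1] < 1) || any(link[, 1] > ns) ||
        any(link[, 2] < 1) || any(link[, 2] > ndet))
      stop("link table indices out of range")
  }
  storage.mode(link) <- "integer"
  mesh$optodes <- list(sources = src, moved = moved, detectors = det,
                       link = link)
  mesh
}

# 1/musp (standard, dcs) or 1/muspx (fluorescence) interpolated at a point
scatter_at <- function(mesh, p) {
  loc <- locate_point(mesh, p, tol = 1e-6)
  musp <- if (mesh$kind == "fluor") mesh$props$muspx else mesh$props$musp
  if (is.na(loc$element)) {
    # surface point just outside by round-off: nearest node value
    i <- which.min(rowSums(sweep(mesh$nodes, 2, p)^2))
    return(musp[i])
  }
  sum(loc$weights * musp[mesh$elements[loc$element, ]])
}

# nearest-point projection of p onto the boundary, with the inward normal at
# the projection (area-weighted average of the adjacent face normals, negated).
# Faces are prefiltered by centroid distance (centroid bound: the exact
# nearest face's centroid lies within min centroid distance + max diameter).
project_to_surface <- function(mesh, bf, p) {
  d <- mesh$dim
  nf <- nrow(bf$faces)
  cent <- matrix(0, nf, d)
  for (i in seq_len(ncol(bf$faces)))
    cent <- cent + mesh$nodes[bf$faces[, i], , drop = FALSE]
  cent <- cent / ncol(bf$faces)
  cd <- sqrt(rowSums(sweep(cent, 2, p)^2))
  diam <- if (d == 2L) bf$measure else {
    e1 <- mesh$nodes[bf$faces[, 1], , drop = FALSE]
    e2 <- mesh$nodes[bf$faces[, 2], , drop = FALSE]
    e3 <- mesh$nodes[bf$faces[, 3], , drop = FALSE]
    sqrt(pmax(rowSums((e1 - e2)^2), rowSums((e2 - e3)^2),
              rowSums((e1 - e3)^2)))
  }
  keep <- which(cd <= min(cd) + max(diam) + 1e-9)
  proj <- matrix(NA_real_, nf, d)
  if (d == 2L) {
    a <- mesh$nodes[bf$faces[keep, 1], , drop = FALSE]
    b <- mesh$nodes[bf$faces[keep, 2], , drop = FALSE]
    ab <- b - a
    tpar <- rowSums(sweep(-a, 2, p, FUN = "+") * ab) / rowSums(ab^2)
    tpar <- pmin(1, pmax(0, tpar))
    proj[keep, ] <- a + ab * tpar
  } else {
    for (f in keep) {
      proj[f, ] <- closest_point_triangle(
        p, mesh$nodes[bf$faces[f, 1], ], mesh$nodes[bf$faces[f, 2], ],
        mesh$nodes[bf$faces[f, 3], ])
    }
  }
  d2 <- rowSums(sweep(proj, 2, p)^2)
  best <- which.min(d2)  # lowest index wins ties (which.min is first-match)
  q <- proj[best, ]
  near <- which(d2 <= d2[best] + 1e-18 + 1e-12 * d2[best])
  w <- bf$measure[near]
  nrm <- colSums(bf$normal[near, , drop = FALSE] * w) / sum(w)
  nrm <- nrm / sqrt(sum(nrm^2))
  list(point = q, inward = -nrm, face = best)
}

# exact closest point on triangle (a,b,c) to point p (Ericson's algorithm)
closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * (d1 / (d1 - d3)))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * (d2 / (d2 - d6)))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c - b) * ((d4 - d3) / ((d4 - d3) + (d5 - d6))))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}
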