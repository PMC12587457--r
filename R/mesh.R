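#' @useDynLib photonfem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as new
#' @importFrom stats integrate rnorm runif
#' @importFrom utils head tail
NULL

C_VACUUM <- 2.99792458e11  # speed of light in vacuum, mm/s

#' Homogeneous property set for a standard (single-wavelength) medium
#'
#' @param mua absorption coefficient, mm^-1 (scalar or per-node)
#' @param musp reduced scattering coefficient, mm^-1
#' @param ri refractive index (>= 1)
#' @return object of class \code{standard_props}
#' @export
standard_props <- function(mua = 0.01, musp = 1, ri = 1.33) {
  structure(list(mua = mua, musp = musp, ri = ri), class = "standard_props")
}

#' Property set for a fluorescence medium
#'
#' Two wavelength blocks (excitation x, re-emission m) plus the lumped
#' fluorophore yield gamma = eta * muaf (mm^-1) and lifetime tau (seconds).
#'
#' @param muax,muspx excitation-wavelength absorption / reduced scattering, mm^-1
#' @param muam,muspm re-emission-wavelength absorption / reduced scattering, mm^-1
#' @param gamma lumped fluorescence yield eta*muaf, mm^-1
#' @param tau fluorophore lifetime, seconds
#' @param ri refractive index
#' @return object of class \code{fluor_props}
#' @export
fluor_props <- function(muax = 0.0089, muspx = 1.3141,
                        muam = 0.0062, muspm = 1.2739,
                        gamma = 0.00018, tau = 1e-9, ri = 1.33) {
  structure(list(muax = muax, muspx = muspx, muam = muam, muspm = muspm,
                 gamma = gamma, tau = tau, ri = ri), class = "fluor_props")
}

#' Property set for a DCS (correlation diffusion) medium
#'
#' @param mua,musp,ri as for \code{\link{standard_props}}
#' @param alphaDb lumped flow index alpha*Db, mm^2/s
#' @param wavelength laser wavelength, nm (sets the wavenumber k0 = 2*pi/lambda)
#' @return object of class \code{dcs_props}
#' @export
dcs_props <- function(mua = 0.01, musp = 1, ri = 1.37,
                      alphaDb = 1e-6, wavelength = 750) {
  structure(list(mua = mua, musp = musp, ri = ri, alphaDb = alphaDb,
                 wavelength = wavelength), class = "dcs_props")
}

prop_kind <- function(props) {
  if (inherits(props, "standard_props")) "stnd"
  else if (inherits(props, "fluor_props")) "fluor"
  else if (inherits(props, "dcs_props")) "dcs"
  else stop("unrecognized property object")
}

expand_props <- function(props, n) {
  kind <- prop_kind(props)
  fields <- setdiff(names(props), "wavelength")
  out <- props
  for (f in fields) {
    v <- props[[f]]
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n) stop("property '", f, "' must be scalar or per-node")
    out[[f]] <- as.numeric(v)
  }
  validate_props(out, kind)
  out
}

validate_props <- function(props, kind) {
  chk_pos <- function(x, nm) if (any(!is.finite(x)) || any(x <= 0))
    stop("property '", nm, "' must be finite and > 0")
  chk_nneg <- function(x, nm) if (any(!is.finite(x)) || any(x < 0))
    stop("property '", nm, "' must be finite and >= 0")
  if (kind == "stnd" || kind == "dcs") {
    chk_pos(props$mua, "mua"); chk_pos(props$musp, "musp")
    if (any(props$ri < 1)) stop("refractive index must be >= 1")
  }
  if (kind == "fluor") {
    chk_pos(props$muax, "muax"); chk_pos(props$muspx, "muspx")
    chk_pos(props$muam, "muam"); chk_pos(props$muspm, "muspm")
    chk_nneg(props$gamma, "gamma"); chk_nneg(props$tau, "tau")
    if (any(props$ri < 1)) stop("refractive index must be >= 1")
  }
  if (kind == "dcs") {
    chk_nneg(props$alphaDb, "alphaDb")
    if (props$wavelength <= 0) stop("wavelength must be > 0")
  }
  invisible(TRUE)
}

empty_optodes <- function(dim) {
  list(sources = matrix(numeric(0), 0, dim),
       moved = logical(0),
       detectors = matrix(numeric(0), 0, dim),
       link = matrix(integer(0), 0, 3,
                     dimnames = list(NULL, c("source", "detector", "active"))))
}

#' Construct a finite-element mesh
#'
#' Builds the central mesh object: node coordinates (mm), simplicial elements
#' (triangles in 2D, tetrahedra in 3D, one-based indices), per-element region
#' labels, per-node optical properties and optode layout. Element orientation
#' is normalized so all signed volumes are positive, and boundary nodes (nodes
#' on faces shared by exactly one element) are flagged.
#'
#' @param nodes N x dim numeric matrix of coordinates, mm
#' @param elements E x (dim+1) integer matrix of one-based node indices
#' @param props a \code{standard_props}, \code{fluor_props} or \code{dcs_props}
#'   object; scalars are expanded to per-node fields
#' @param region optional per-element integer labels (default 1)
#' @return object of class \code{fem_mesh}
#' @export
fem_mesh <- function(nodes, elements, props, region = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  dim <- ncol(nodes)
  if (!dim %in% 2:3) stop("mesh must be 2D or 3D")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  if (ncol(elements) != dim + 1L) stop("elements must have dim+1 columns")
  n <- nrow(nodes)
  if (any(elements < 1L) || any(elements > n))
    stop("element index out of range [1, ", n, "]")
  if (is.null(region)) region <- rep(1L, nrow(elements))
  mesh <- structure(list(
    dim = dim, nodes = nodes, elements = elements,
    region = as.integer(region),
    boundary_flag = logical(n),
    kind = prop_kind(props),
    props = expand_props(props, n),
    optodes = empty_optodes(dim)
  ), class = "fem_mesh")
  mesh <- orient_elements(mesh)
  vol <- element_volumes(mesh)
  if (any(vol <= 0))
    stop("degenerate element (non-positive volume) at index ",
         which(vol <= 0)[1])
  mesh$boundary_flag <- compute_boundary_flag(mesh)
  mesh
}

# signed volume/area of each element under the stored vertex order
element_signed_volumes <- function(mesh) {
  el <- mesh$elements; nd <- mesh$nodes
  if (mesh$dim == 2L) {
    a <- nd[el[, 1], , drop = FALSE]; b <- nd[el[, 2], , drop = FALSE]
    c3 <- nd[el[, 3], , drop = FALSE]
    0.5 * ((b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1]))
  } else {
    a <- nd[el[, 1], , drop = FALSE]; b <- nd[el[, 2], , drop = FALSE]
    c3 <- nd[el[, 3], , drop = FALSE]; d <- nd[el[, 4], , drop = FALSE]
    u <- b - a; v <- c3 - a; w <- d - a
    (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  }
}

#' Element volumes (3D) or areas (2D)
#' @param mesh a \code{fem_mesh}
#' @return numeric vector, strictly positive for a valid mesh
#' @export
element_volumes <- function(mesh) element_signed_volumes(mesh)

orient_elements <- function(mesh) {
  sv <- element_signed_volumes(mesh)
  flip <- which(sv < 0)
  if (length(flip)) {
    k <- ncol(mesh$elements)
    tmp <- mesh$elements[flip, k - 1L]
    mesh$elements[flip, k - 1L] <- mesh$elements[flip, k]
    mesh$elements[flip, k] <- tmp
  }
  mesh
}

# all faces of all elements: list(faces = F x dim matrix,
# key = order-independent numeric id, elem = parent element, opp = opposite vertex
element_faces <- function(mesh) {
  el <- mesh$elements
  ne <- nrow(el); d <- mesh$dim
  k <- d + 1L
  faces <- vector("list", k); opp <- vector("list", k)
  for (i in seq_len(k)) {
    faces[[i]] <- el[, -i, drop = FALSE]
    opp[[i]] <- el[, i]
  }
  f <- do.call(rbind, faces)
  n1 <- as.numeric(nrow(mesh$nodes)) + 1
  if (d == 2L) {
    a <- pmin(f[, 1], f[, 2]); b <- pmax(f[, 1], f[, 2])
    key <- a + b * n1
  } else {
    a <- pmin(f[, 1], f[, 2], f[, 3])
    c3 <- pmax(f[, 1], f[, 2], f[, 3])
    b <- as.numeric(f[, 1]) + f[, 2] + f[, 3] - a - c3
    key <- a + b * n1 + c3 * n1 * n1
  }
  list(faces = f, key = key,
       elem = rep(seq_len(ne), times = k),
       opp = unlist(opp))
}

# faces occurring in exactly one element -> boundary faces with outward normals
boundary_faces <- function(mesh) {
  ef <- element_faces(mesh)
  uk <- unique(ef$key)
  m <- match(ef$key, uk)
  cnt <- tabulate(m, length(uk))
  bnd <- which(cnt[m] == 1L)
  faces <- ef$faces[bnd, , drop = FALSE]
  elem <- ef$elem[bnd]
  opp <- ef$opp[bnd]
  nd <- mesh$nodes
  if (mesh$dim == 2L) {
    a <- nd[faces[, 1], , drop = FALSE]; b <- nd[faces[, 2], , drop = FALSE]
    tanv <- b - a
    len <- sqrt(rowSums(tanv^2))
    nrm <- cbind(tanv[, 2], -tanv[, 1]) / len
    # orient outward: away from the opposite vertex
    toopp <- nd[opp, , drop = FALSE] - a
    s <- sign(rowSums(nrm * toopp))
    nrm <- nrm * ifelse(s > 0, -1, 1)
    measure <- len
  } else {
    a <- nd[faces[, 1], , drop = FALSE]; b <- nd[faces[, 2], , drop = FALSE]
    c3 <- nd[faces[, 3], , drop = FALSE]
    u <- b - a; v <- c3 - a
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    area2 <- sqrt(rowSums(cr^2))
    nrm <- cr / area2
    toopp <- nd[opp, , drop = FALSE] - a
    s <- sign(rowSums(nrm * toopp))
    nrm <- nrm * ifelse(s > 0, -1, 1)
    measure <- area2 / 2
  }
  list(faces = faces, elem = elem, normal = nrm, measure = measure)
}

compute_boundary_flag <- function(mesh) {
  bf <- boundary_faces(mesh)
  flag <- logical(nrow(mesh$nodes))
  flag[unique(as.vector(bf$faces))] <- TRUE
  flag
}

#' @exportS3Method base::print
print.fem_mesh <- function(x, ...) {
  cat(sprintf("fem_mesh (%dD, kind '%s'): %d nodes, %d elements\n",
              x$dim, x$kind, nrow(x$nodes), nrow(x$elements)))
  cat(sprintf("  boundary nodes: %d | sources: %d | detectors: %d | channels: %d\n",
              sum(x$boundary_flag), nrow(x$optodes$sources),
              nrow(x$optodes$detectors), nrow(x$optodes$link)))
  invisible(x)
}

# diffusion coefficient kappa = 1/(3(mua+musp)) per node; block "x"/"m" for
# fluorescence meshes, "" for standard/dcs
kappa_field <- function(mesh, block = "") {
  p <- mesh$props
  if (mesh$kind == "fluor") {
    if (block == "x") 1 / (3 * (p$muax + p$muspx))
    else if (block == "m") 1 / (3 * (p$muam + p$muspm))
    else stop("block must be 'x' or 'm' for fluorescence meshes")
  } else 1 / (3 * (p$mua + p$musp))
}

# speed of light in the medium, mm/s
c_field <- function(mesh) C_VACUUM / mesh$props$ri

k0_wavenumber <- function(mesh) {
  stopifnot(mesh$kind == "dcs")
  lambda_mm <- mesh$props$wavelength * 1e-6  # nm -> mm
  2 * pi / lambda_mm
}

#' Locate a point in the mesh
#'
#' Finds the element containing point \code{p} and the barycentric weights of
#' \code{p} with respect to that element's vertices. Points outside the mesh
#' are reported with \code{element = NA} (a value, not an error).
#'
#' @param mesh a \code{fem_mesh}
#' @param p numeric vector of length \code{mesh$dim}
#' @param tol barycentric slack: weights >= -tol are accepted (points on
#'   faces/edges land in one of the adjacent elements deterministically)
#' @return list with \code{element} (integer or NA) and \code{weights}
#'   (length dim+1, summing to 1)
#' @export
locate_point <- function(mesh, p, tol = 1e-8) {
  res <- locate_points(mesh, matrix(p, nrow = 1), tol = tol)
  list(element = res$element[1], weights = res$weights[1, ])
}

# vectorized point location with a uniform-bin element index
locate_points <- function(mesh, pts, tol = 1e-8) {
  pts <- as.matrix(pts)
  d <- mesh$dim
  stopifnot(ncol(pts) == d)
  np <- nrow(pts)
  idx <- mesh_bin_index(mesh)
  elem <- rep(NA_integer_, np)
  wts <- matrix(NA_real_, np, d + 1L)
  for (q in seq_len(np)) {
    cand <- bin_candidates(idx, pts[q, ])
    if (!length(cand)) next
    best_e <- NA_integer_; best_w <- NULL; best_min <- -Inf
    for (e in cand) {
      w <- bary_weights(mesh, e, pts[q, ])
      mn <- min(w)
      if (mn >= -tol) { best_e <- e; best_w <- w; break }
      if (mn > best_min) { best_min <- mn; }
    }
    if (!is.na(best_e)) { elem[q] <- best_e; wts[q, ] <- best_w }
  }
  list(element = elem, weights = wts)
}

bary_weights <- function(mesh, e, p) {
  v <- mesh$elements[e, ]
  nd <- mesh$nodes[v, , drop = FALSE]
  d <- mesh$dim
  A <- t(nd[seq_len(d), , drop = FALSE]) - nd[d + 1L, ]
  w <- tryCatch(solve(A, p - nd[d + 1L, ]), error = function(e) rep(NA_real_, d))
  c(w, 1 - sum(w))
}

# uniform-bin spatial index over element bounding boxes; cached on the mesh
# via an environment keyed by topology size (cheap identity heuristic)
mesh_bin_index <- function(mesh) {
  cache <- attr(mesh, "bin_index")
  if (!is.null(cache)) return(cache)
  d <- mesh$dim
  el <- mesh$elements; nd <- mesh$nodes
  ne <- nrow(el)
  nb <- pmax(1L, pmin(128L, as.integer(ceiling(ne^(1 / d)))))
  lo <- apply(nd, 2, min); hi <- apply(nd, 2, max)
  span <- pmax(hi - lo, 1e-12)
  # element bbox -> bin ranges
  binfo <- vector("list", d)
  for (k in seq_len(d)) {
    xs <- matrix(nd[el, k], nrow = ne)
    emin <- do.call(pmin, as.data.frame(xs))
    emax <- do.call(pmax, as.data.frame(xs))
    b0 <- pmax(1L, pmin(nb, as.integer(floor((emin - lo[k]) / span[k] * nb)) + 1L))
    b1 <- pmax(1L, pmin(nb, as.integer(floor((emax - lo[k]) / span[k] * nb)) + 1L))
    binfo[[k]] <- cbind(b0, b1)
  }
  # enumerate (element, linear bin) pairs
  reps <- rep(1L, ne)
  for (k in seq_len(d)) reps <- reps * (binfo[[k]][, 2] - binfo[[k]][, 1] + 1L)
  eid <- rep.int(seq_len(ne), reps)
  # build linear bin ids by explicit expansion (one pass per dimension);
  # within an element's bin-range combos, dimension 1 varies fastest
  expand_dim <- function(b0, b1, reps_before, reps_after) {
    unlist(mapply(function(a, b, rb, ra) rep(rep(a:b, each = rb), times = ra),
                  b0, b1, reps_before, reps_after, SIMPLIFY = FALSE),
           use.names = FALSE)
  }
  width <- lapply(seq_len(d), function(k) binfo[[k]][, 2] - binfo[[k]][, 1] + 1L)
  binid <- rep(0, length(eid))
  for (k in seq_len(d)) {
    rb <- rep(1L, ne); ra <- rep(1L, ne)
    if (k > 1) for (j in seq_len(k - 1)) rb <- rb * width[[j]]
    if (k < d) for (j in (k + 1):d) ra <- ra * width[[j]]
    ids_k <- expand_dim(binfo[[k]][, 1], binfo[[k]][, 2], rb, ra)
    binid <- binid + (ids_k - 1) * nb^(k - 1)
  }
  buckets <- split(eid, binid)
  idx <- list(nb = nb, lo = lo, span = span, d = d, buckets = buckets)
  idx
}

bin_candidates <- function(idx, p) {
  b <- pmax(1L, pmin(idx$nb,
        as.integer(floor((p - idx$lo) / idx$span * idx$nb)) + 1L))
  key <- as.character(sum((b - 1L) * idx$nb^(seq_len(idx$d) - 1L)))
  cand <- idx$buckets[[key]]
  if (is.null(cand)) integer(0) else cand
}

# attach (memoize) the bin index; used by routines doing many lookups
with_bin_index <- function(mesh) {
  if (is.null(attr(mesh, "bin_index")))
    attr(mesh, "bin_index") <- mesh_bin_index(mesh)
  mesh
}
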