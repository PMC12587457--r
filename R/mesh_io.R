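#' Read a mesh in the classic ASCII NIRFAST multi-file format
#'
#' Reads \code{basename.node}, \code{basename.elem} and \code{basename.param}
#' (mandatory), plus \code{basename.source}, \code{basename.meas} and
#' \code{basename.link} when present. The dialect (documented in the README)
#' is: one node per line as \code{boundary_flag x y [z]}; one element per line
#' of one-based indices; \code{.param} starting with a kind keyword
#' (\code{stnd}, \code{fluor} or \code{dcs}) followed by per-node property
#' columns; optode files with a \code{fixed} header line. Legacy files that
#' deviate slightly are read best-effort with warnings.
#'
#' @param basename path prefix of the mesh file set
#' @return a \code{fem_mesh}
#' @export
load_nirfast_ascii <- function(basename) {
  fn <- function(ext) paste0(basename, ".", ext)
  for (ext in c("node", "elem", "param"))
    if (!file.exists(fn(ext)))
      stop("mandatory mesh file missing: ", fn(ext))
  nodetab <- read_num_table(fn("node"))
  if (ncol(nodetab) < 3L || ncol(nodetab) > 4L)
    stop("malformed node file (expect 3 or 4 columns): ", fn("node"))
  dim <- ncol(nodetab) - 1L
  bflag <- nodetab[, 1] != 0
  nodes <- nodetab[, -1, drop = FALSE]
  elemtab <- read_num_table(fn("elem"))
  if (ncol(elemtab) != dim + 1L)
    stop("malformed element file (expect ", dim + 1L, " columns): ", fn("elem"))
  elements <- matrix(as.integer(round(elemtab)), ncol = dim + 1L)
  if (any(elements < 1L) || any(elements > nrow(nodes)))
    stop("element index out of range in ", fn("elem"))

  plines <- readLines(fn("param"))
  plines <- plines[nzchar(trimws(plines))]
  hdr <- strsplit(trimws(plines[1]), "\\s+")[[1]]
  kind <- hdr[1]
  ptab <- parse_num_lines(plines[-1], fn("param"))
  n <- nrow(nodes)
  if (nrow(ptab) != n)
    stop("param file has ", nrow(ptab), " rows for ", n, " nodes: ", fn("param"))
  props <- switch(kind,
    stnd = {
      if (ncol(ptab) < 3) stop("stnd param file needs columns mua kappa ri")
      kappa <- ptab[, 2]
      standard_props(mua = ptab[, 1], musp = 1 / (3 * kappa) - ptab[, 1],
                     ri = ptab[, 3])
    },
    fluor = {
      if (ncol(ptab) < 7) stop("fluor param file needs 7 columns: muax kappax ri muam kappam gamma tau")
      fluor_props(muax = ptab[, 1], muspx = 1 / (3 * ptab[, 2]) - ptab[, 1],
                  ri = ptab[, 3],
                  muam = ptab[, 4], muspm = 1 / (3 * ptab[, 5]) - ptab[, 4],
                  gamma = ptab[, 6], tau = ptab[, 7])
    },
    dcs = {
      if (ncol(ptab) < 4) stop("dcs param file needs columns mua kappa ri alphaDb")
      wl <- if (length(hdr) >= 2) as.numeric(hdr[2]) else 750
      dcs_props(mua = ptab[, 1], musp = 1 / (3 * ptab[, 2]) - ptab[, 1],
                ri = ptab[, 3], alphaDb = ptab[, 4], wavelength = wl)
    },
    stop("unknown mesh kind keyword '", kind, "' in ", fn("param"))
  )
  mesh <- fem_mesh(nodes, elements, props)
  if (!identical(mesh$boundary_flag, bflag))
    warning("boundary flags in ", fn("node"),
            " disagree with the mesh topology; using recomputed flags")

  has_src <- file.exists(fn("source"))
  has_det <- file.exists(fn("meas"))
  if (has_src || has_det) {
    src <- if (has_src) read_optode_file(fn("source"), dim) else
      list(pos = matrix(numeric(0), 0, dim), moved = logical(0))
    det <- if (has_det) read_optode_file(fn("meas"), dim) else
      list(pos = matrix(numeric(0), 0, dim), moved = logical(0))
    link <- if (file.exists(fn("link"))) {
      lt <- read_num_table(fn("link"), skip_nonnumeric = TRUE)
      lt <- matrix(as.integer(round(lt)), ncol = ncol(lt))
      if (ncol(lt) == 2L) lt <- cbind(lt, 1L)
      lt[, 1:3, drop = FALSE]
    } else matrix(integer(0), 0, 3)
    colnames(link) <- c("source", "detector", "active")
    mesh$optodes <- list(sources = src$pos,
                         moved = if (length(src$moved)) src$moved else
                           rep(TRUE, nrow(src$pos)),
                         detectors = det$pos, link = link)
  }
  mesh
}

#' Write a mesh in the classic ASCII NIRFAST multi-file format
#'
#' Inverse of \code{\link{load_nirfast_ascii}}; coordinates and properties are
#' written with 15 significant digits so that a load/save round trip is the
#' identity to write precision. Optode files are only emitted when optodes
#' are present.
#'
#' @param mesh a \code{fem_mesh}
#' @param basename path prefix for the emitted files
#' @return invisibly, the vector of files written
#' @export
save_nirfast_ascii <- function(mesh, basename) {
  fn <- function(ext) paste0(basename, ".", ext)
  g <- function(x) sprintf("%.15g", x)
  written <- character(0)
  emit <- function(lines, ext) {
    ok <- tryCatch({ writeLines(lines, fn(ext)); TRUE },
                   error = function(e) stop("cannot write ", fn(ext), ": ",
                                            conditionMessage(e)))
    written <<- c(written, fn(ext))
  }
  nd <- mesh$nodes
  emit(paste(as.integer(mesh$boundary_flag),
             apply(matrix(g(nd), nrow(nd)), 1, paste, collapse = " ")),
       "node")
  emit(apply(mesh$elements, 1, paste, collapse = " "), "elem")
  p <- mesh$props
  ptab <- switch(mesh$kind,
    stnd = cbind(p$mua, 1 / (3 * (p$mua + p$musp)), p$ri),
    fluor = cbind(p$muax, 1 / (3 * (p$muax + p$muspx)), p$ri,
                  p$muam, 1 / (3 * (p$muam + p$muspm)), p$gamma, p$tau),
    dcs = cbind(p$mua, 1 / (3 * (p$mua + p$musp)), p$ri, p$alphaDb))
  hdr <- if (mesh$kind == "dcs") paste("dcs", g(p$wavelength)) else mesh$kind
  emit(c(hdr, apply(matrix(g(ptab), nrow(ptab)), 1, paste, collapse = " ")),
       "param")
  opt <- mesh$optodes
  if (nrow(opt$sources) > 0) {
    emit(c("fixed",
           paste(apply(matrix(g(opt$sources), nrow(opt$sources)), 1,
                       paste, collapse = " "),
                 as.integer(opt$moved))),
         "source")
  }
  if (nrow(opt$detectors) > 0) {
    emit(c("fixed",
           apply(matrix(g(opt$detectors), nrow(opt$detectors)), 1,
                 paste, collapse = " ")),
         "meas")
  }
  if (nrow(opt$link) > 0) {
    emit(apply(opt$link, 1, paste, collapse = " "), "link")
  }
  invisible(written)
}

read_num_table <- function(path, skip_nonnumeric = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (skip_nonnumeric) {
    keep <- grepl("^\\s*-?[0-9.]", lines)
    lines <- lines[keep]
  }
  parse_num_lines(lines, path)
}

parse_num_lines <- function(lines, path) {
  toks <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(toks)
  if (!length(toks)) stop("empty file: ", path)
  if (length(unique(ncols)) != 1L)
    stop("inconsistent column count in ", path, " at line ",
         which(ncols != ncols[1])[1])
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- which(vapply(toks, function(t)
      anyNA(suppressWarnings(as.numeric(t))), logical(1)))[1]
    stop("non-numeric entry in ", path, " at line ", bad)
  }
  matrix(vals, ncol = ncols[1], byrow = TRUE)
}

read_optode_file <- function(path, dim) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^[a-zA-Z]", trimws(lines[1])))
    lines <- lines[-1]
  else
    warning("optode file ", path, " has no header line; reading best-effort")
  if (!length(lines))
    return(list(pos = matrix(numeric(0), 0, dim), moved = logical(0)))
  tab <- parse_num_lines(lines, path)
  if (ncol(tab) == dim + 1L) {
    list(pos = tab[, seq_len(dim), drop = FALSE],
         moved = tab[, dim + 1L] != 0)
  } else if (ncol(tab) == dim) {
    list(pos = tab, moved = logical(0))
  } else {
    warning("optode file ", path, " has ", ncol(tab),
            " columns; using the first ", dim)
    list(pos = tab[, seq_len(dim), drop = FALSE], moved = logical(0))
  }
}
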