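# FSAI preconditioner + Krylov solvers (CPU path of the auto-selection rule:
# BiCGStab only for frequency-domain problems, PCG for everything real).

#' Build a factorized sparse approximate inverse (FSAI) preconditioner
#'
#' Computes a sparse lower-triangular factor \code{G} with positive diagonal
#' such that \code{M^-1 = G'G} approximates \code{A^-1}; applying the
#' preconditioner is two sparse matrix-vector products. The sparsity pattern
#' of row i is chosen from the lower-triangular row of \code{A}:
#' \describe{
#'   \item{\code{bicgstab3}}{the three largest-magnitude entries among
#'     columns 1..i (diagonal forced in);}
#'   \item{\code{pcg_diag4}}{the diagonal plus the four largest-magnitude
#'     entries among columns 1..i-1;}
#'   \item{\code{full_lower}}{the complete lower triangle, columns 1..i (for an SPD
#'     matrix this reproduces the exact inverse Cholesky factor).}
#' }
#' Ties are broken toward the smaller column index. A numerically singular
#' local system drops that row to diagonal-only, with a warning.
#'
#' @param A sparse symmetric matrix with positive diagonal
#' @param pattern one of \code{"pcg_diag4"}, \code{"bicgstab3"},
#'   \code{"full_lower"}
#' @return object of class \code{fsai} with fields \code{G} (sparse lower
#'   triangular) and \code{pattern_kind}
#' @export
build_fsai <- function(A, pattern = c("pcg_diag4", "bicgstab3", "full_lower")) {
  pattern <- match.arg(pattern)
  A <- as(as(as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(diag(A) <= 0)) stop("FSAI needs a positive diagonal")
  pat <- match(pattern, c("bicgstab3", "pcg_diag4", "full_lower")) - 1L
  res <- fsai_build(A@p, A@i, A@x, nrow(A), pat)
  if (res$fallbacks > 0)
    warning("FSAI: ", res$fallbacks,
            " row(s) fell back to diagonal-only (singular local system)")
  G <- sparseMatrix(i = res$i + 1L, j = res$j + 1L, x = res$x,
                    dims = dim(A))
  structure(list(G = G, pattern_kind = pattern), class = "fsai")
}

# M^-1 v = G' (G v); v may be real or complex, vector or matrix
fsai_apply <- function(M, v) {
  if (is.complex(v)) {
    re <- as.matrix(crossprod(M$G, M$G %*% Re(v)))
    im <- as.matrix(crossprod(M$G, M$G %*% Im(v)))
    re + 1i * im
  } else {
    as.matrix(crossprod(M$G, M$G %*% v))
  }
}

#' @exportS3Method base::print
print.fsai <- function(x, ...) {
  cat(sprintf("FSAI preconditioner: %d x %d, pattern '%s', %d nonzeros\n",
              nrow(x$G), ncol(x$G), x$pattern_kind, length(x$G@x)))
  invisible(x)
}

#' Preconditioned conjugate-gradient solver
#'
#' Solves \code{A x = q} for each column of \code{Q} independently, with an
#' optional FSAI preconditioner; terminates a column when the true relative
#' residual \code{||A x - q|| / ||q||} drops below \code{tol}.
#'
#' @param A sparse symmetric positive definite matrix
#' @param M an \code{fsai} preconditioner, or NULL for plain CG
#' @param Q right-hand side vector or matrix (one system per column)
#' @param tol relative residual tolerance (default 1e-12)
#' @param maxit maximum iterations per column (default 1000)
#' @param x0 optional initial guess (same shape as Q)
#' @return list with \code{x} (solution matrix), \code{iterations} and
#'   \code{residuals} (final relative residual) per column
#' @export
pcg_solve <- function(A, M = NULL, Q, tol = 1e-12, maxit = 1000, x0 = NULL) {
  Q <- as.matrix(Q)
  ns <- ncol(Q)
  X <- matrix(0, nrow(Q), ns)
  iters <- integer(ns); resid <- numeric(ns)
  for (s in seq_len(ns)) {
    q <- Q[, s]
    qn <- sqrt(sum(q^2))
    if (qn == 0) { iters[s] <- 0L; resid[s] <- 0; next }
    x <- if (is.null(x0)) numeric(length(q)) else as.matrix(x0)[, s]
    r <- q - as.numeric(A %*% x)
    z <- if (is.null(M)) r else as.numeric(fsai_apply(M, r))
    p <- z
    rz <- sum(r * z)
    it <- 0L
    rel <- sqrt(sum(r^2)) / qn
    while (rel > tol && it < maxit) {
      Ap <- as.numeric(A %*% p)
      curv <- sum(p * Ap)
      if (curv <= 0) stop("PCG breakdown (non-positive curvature) in column ", s)
      alpha <- rz / curv
      x <- x + alpha * p
      r <- r - alpha * Ap
      rel <- sqrt(sum(r^2)) / qn
      if (rel <= tol) { it <- it + 1L; break }
      z <- if (is.null(M)) r else as.numeric(fsai_apply(M, r))
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
      it <- it + 1L
    }
    X[, s] <- x; iters[s] <- it; resid[s] <- rel
  }
  list(x = X, iterations = iters, residuals = resid)
}

#' Preconditioned BiCGStab solver for complex symmetric systems
#'
#' Solves \code{Ac x = q} per column of \code{Q}, where \code{Ac = A + 1i*w*B}
#' is the frequency-domain operator. The preconditioner is built from the
#' real SPD part only and applied with real triangular factors to the complex
#' vectors. A rho-breakdown triggers one restart from the current iterate
#' before erroring.
#'
#' @param Ac sparse complex (or real) matrix
#' @param M an \code{fsai} preconditioner built from the real part, or NULL
#' @param Q right-hand sides (vector or matrix)
#' @param tol relative residual tolerance
#' @param maxit maximum iterations
#' @param x0 optional initial guess
#' @return list with \code{x}, \code{iterations}, \code{residuals}
#' @export
bicgstab_solve <- function(Ac, M = NULL, Q, tol = 1e-12, maxit = 1000,
                           x0 = NULL) {
  Q <- as.matrix(Q)
  ns <- ncol(Q)
  cplx <- is.complex(Q) || (is.list(Ac) && !is.null(Ac$im))
  amul <- make_amul(Ac)
  if (cplx) Q <- Q + 0i
  X <- matrix(if (cplx) 0i else 0, nrow(Q), ns)
  iters <- integer(ns); resid <- numeric(ns)
  for (s in seq_len(ns)) {
    q <- Q[, s]
    qn <- sqrt(sum(Mod(q)^2))
    if (qn == 0) { next }
    x <- if (is.null(x0)) q * 0 else as.matrix(x0)[, s]
    r <- q - amul(x)
    restarted <- FALSE
    it <- 0L
    repeat {
      rhat <- r
      rho <- 1; alpha <- 1; omega <- 1
      v <- r * 0; p <- r * 0
      broke <- FALSE
      while (it < maxit) {
        rel <- sqrt(sum(Mod(r)^2)) / qn
        if (rel <= tol) break
        rho1 <- sum(Conj(rhat) * r)
        if (Mod(rho1) < 1e-300) { broke <- TRUE; break }
        beta <- (rho1 / rho) * (alpha / omega)
        p <- r + beta * (p - omega * v)
        phat <- if (is.null(M)) p else fsai_apply(M, p)[, 1]
        v <- amul(phat)
        alpha <- rho1 / sum(Conj(rhat) * v)
        ss <- r - alpha * v
        if (sqrt(sum(Mod(ss)^2)) / qn <= tol) {
          x <- x + alpha * phat
          r <- ss
          it <- it + 1L
          break
        }
        shat <- if (is.null(M)) ss else fsai_apply(M, ss)[, 1]
        tt <- amul(shat)
        omega <- sum(Conj(tt) * ss) / sum(Conj(tt) * tt)
        x <- x + alpha * phat + omega * shat
        r <- ss - omega * tt
        rho <- rho1
        it <- it + 1L
      }
      rel <- sqrt(sum(Mod(r)^2)) / qn
      if (rel <= tol || it >= maxit) break
      if (broke) {
        if (restarted) stop("BiCGStab rho-breakdown in column ", s)
        restarted <- TRUE
        r <- q - amul(x)
        next
      }
      break
    }
    X[, s] <- x
    iters[s] <- it
    resid[s] <- sqrt(sum(Mod(q - amul(x))^2)) / qn
  }
  list(x = X, iterations = iters, residuals = resid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# matrix-vector product closure; complex operators A + i*w*B are carried as a
# list(re = A, im = w*B) of real sparse Matrix objects (the Matrix package has
# no complex sparse class)
make_amul <- function(Ac) {
  if (is.list(Ac) && !is.null(Ac$re)) {
    function(v) as.numeric(Ac$re %*% Re(v)) - as.numeric(Ac$im %*% Im(v)) +
      1i * (as.numeric(Ac$re %*% Im(v)) + as.numeric(Ac$im %*% Re(v)))
  } else {
    function(v) {
      if (is.complex(v))
        as.numeric(Ac %*% Re(v)) + 1i * as.numeric(Ac %*% Im(v))
      else as.numeric(Ac %*% v)
    }
  }
}

#' Automatic solver and preconditioner-pattern selection
#'
#' Frequency-domain problems get BiCGStab with the \code{bicgstab3} pattern;
#' every real-valued problem (CW, time stepping, moments, DCS) gets PCG with
#' the \code{pcg_diag4} pattern.
#'
#' @param problem_kind one of \code{"cw"}, \code{"fd"}, \code{"tpsf"},
#'   \code{"moments"}, \code{"dcs"}
#' @param force override: \code{"auto"} (default), \code{"pcg"} or
#'   \code{"bicgstab"}
#' @return list with \code{solver} and \code{pattern}
#' @export
choose_solver <- function(problem_kind, force = "auto") {
  if (!problem_kind %in% c("cw", "fd", "tpsf", "moments", "dcs"))
    stop("unknown problem kind '", problem_kind, "'")
  solver <- if (force != "auto") force
  else if (problem_kind == "fd") "bicgstab" else "pcg"
  pattern <- if (solver == "bicgstab") "bicgstab3" else "pcg_diag4"
  list(solver = solver, pattern = pattern)
}
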