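# Closed-form semi-infinite-medium solutions: the package's validation
# oracles, and the source of the Robin boundary scalar beta.

#' Boundary reflection parameter beta
#'
#' The Robin boundary scalar beta encodes the internal reflection caused by
#' the refractive-index mismatch at the tissue-air interface. Three methods:
#' \describe{
#'   \item{\code{fresnel_exact}}{angular integrals of the exact (unpolarized)
#'     Fresnel coefficient, with total internal reflection beyond the
#'     critical angle; adaptive quadrature to 1e-8;}
#'   \item{\code{fresnel_approx}}{two-step approximation of the Fresnel
#'     curve, closed form;}
#'   \item{\code{groenhuis}}{Groenhuis's empirical cubic in the relative
#'     index (fast, no integration; the default used by the FEM assembly).}
#' }
#'
#' @param n_in refractive index inside the medium (>= 1)
#' @param n_out refractive index outside (default 1, air)
#' @param method one of \code{"groenhuis"}, \code{"fresnel_exact"},
#'   \code{"fresnel_approx"}
#' @return scalar beta > 0
#' @export
boundary_beta <- function(n_in, n_out = 1,
                          method = c("groenhuis", "fresnel_exact",
                                     "fresnel_approx")) {
  method <- match.arg(method)
  if (n_in < 1 || n_out < 1) stop("refractive indices must be >= 1")
  nrel <- n_in / n_out
  if (method == "groenhuis") {
    reff <- -1.440 * nrel^-2 + 0.710 * nrel^-1 + 0.668 + 0.0636 * nrel
    return((1 + reff) / (1 - reff))
  }
  if (method == "fresnel_approx") {
    # two-step Fresnel approximation: R0 below the critical angle, total
    # reflection above it
    r0 <- (n_in - n_out)^2 / (n_in + n_out)^2
    cos_tc <- if (n_in > n_out) cos(asin(n_out / n_in)) else 0
    return((2 / (1 - r0) - 1 + abs(cos_tc)^3) / (1 - abs(cos_tc)^2))
  }
  # exact Fresnel: theta is the internal incidence angle
  rf <- function(theta) {
    s <- n_in * sin(theta) / n_out
    out <- rep(1, length(theta))  # total internal reflection
    ok <- s <= 1
    tp <- asin(pmin(1, s[ok]))  # refracted angle
    th <- theta[ok]
    r_s <- ((n_in * cos(th) - n_out * cos(tp)) /
            (n_in * cos(th) + n_out * cos(tp)))^2
    r_p <- ((n_in * cos(tp) - n_out * cos(th)) /
            (n_in * cos(tp) + n_out * cos(th)))^2
    out[ok] <- 0.5 * r_p + 0.5 * r_s
    out
  }
  rphi <- integrate(function(th) 2 * sin(th) * cos(th) * rf(th),
                    0, pi / 2, abs.tol = 1e-8, rel.tol = 1e-10,
                    subdivisions = 500L)$value
  rj <- integrate(function(th) 3 * sin(th) * cos(th)^2 * rf(th),
                  0, pi / 2, abs.tol = 1e-8, rel.tol = 1e-10,
                  subdivisions = 500L)$value
  reff <- (rphi + rj) / (2 - rphi + rj)
  (1 + reff) / (1 - reff)
}

#' Semi-infinite problem setup
#'
#' Bundles the homogeneous optical properties and geometry used by the
#' analytical solutions, with the derived quantities: diffusion coefficient
#' kappa, transport depth z0 = 1/(mua+musp) (the isotropic-source depth),
#' speed of light c in the medium, and boundary offset zb (0 for the zero
#' boundary condition; 2*beta*kappa for the extrapolated and partial-current
#' conditions).
#'
#' @param mua,musp absorption / reduced scattering, mm^-1
#' @param ri_in,ri_out refractive indices inside / outside
#' @param bc_kind boundary condition: \code{"ebc"} (default), \code{"zbc"} or
#'   \code{"pcb"}
#' @param beta_method method for \code{\link{boundary_beta}}
#' @return object of class \code{semi_infinite_setup}
#' @export
semi_infinite_setup <- function(mua = 0.01, musp = 1, ri_in = 1.33,
                                ri_out = 1,
                                bc_kind = c("ebc", "zbc", "pcb"),
                                beta_method = "groenhuis") {
  bc_kind <- match.arg(bc_kind)
  kappa <- 1 / (3 * (mua + musp))
  beta <- boundary_beta(ri_in, ri_out, beta_method)
  structure(list(
    mua = mua, musp = musp, ri_in = ri_in, ri_out = ri_out,
    kappa = kappa, c = C_VACUUM / ri_in,
    z0 = 1 / (mua + musp),
    beta = beta,
    zb = if (bc_kind == "zbc") 0 else 2 * beta * kappa,
    bc_kind = bc_kind, beta_method = beta_method
  ), class = "semi_infinite_setup")
}

#' Frequency-domain / CW fluence in a semi-infinite medium
#'
#' Image-source Green's-function solution with the diffusion wavenumber
#' \code{k = sqrt((mua*c - 1i*omega)/(c*kappa))} (reducing to sqrt(mua/kappa)
#' at omega = 0). ZBC/EBC use an image source at depth -(z0 + 2*zb); PCB adds
#' the exponential boundary-integral term, evaluated by adaptive quadrature
#' truncated at 40*zb.
#'
#' @param setup a \code{\link{semi_infinite_setup}}
#' @param rho radial source-detector distance(s), mm
#' @param z depth into the medium, mm (0 = surface)
#' @param omega modulation angular frequency, rad/s (0 for CW)
#' @return complex fluence (real at omega = 0), vectorized over \code{rho}
#' @export
semi_infinite_fd <- function(setup, rho, z = 0, omega = 0) {
  st <- setup
  if (any(rho < 0) || any(z < 0)) stop("rho and z must be >= 0")
  k <- sqrt(complex(real = st$mua / st$kappa,
                    imaginary = -omega / (st$c * st$kappa)))
  r1 <- sqrt((z - st$z0)^2 + rho^2)
  if (all(r1 == 0)) stop("field point coincides with the source")
  if (st$bc_kind != "pcb") {
    rb <- sqrt((z + st$z0 + 2 * st$zb)^2 + rho^2)
    val <- (exp(-k * r1) / r1 - exp(-k * rb) / rb) / (4 * pi * st$kappa)
  } else {
    r2 <- sqrt((z + st$z0)^2 + rho^2)
    val <- (exp(-k * r1) / r1 + exp(-k * r2) / r2) / (4 * pi * st$kappa)
    zb <- st$zb
    for (q in seq_along(rho)) {
      f_re <- function(l) {
        rr <- sqrt((z + zb + l)^2 + rho[q]^2)
        exp(-l / zb) * Re(exp(-k * rr)) / rr
      }
      f_im <- function(l) {
        rr <- sqrt((z + zb + l)^2 + rho[q]^2)
        exp(-l / zb) * Im(exp(-k * rr)) / rr
      }
      intg <- integrate(f_re, 0, 40 * zb, rel.tol = 1e-8,
                        subdivisions = 500L)$value
      if (omega != 0)
        intg <- complex(real = intg,
                        imaginary = integrate(f_im, 0, 40 * zb,
                                              rel.tol = 1e-8,
                                              subdivisions = 500L)$value)
      val[q] <- val[q] - (2 / zb) * intg / (4 * pi * st$kappa)
    }
  }
  if (omega == 0) Re(val) else val
}

#' Time-resolved fluence and reflectance in a semi-infinite medium
#'
#' Image-source time-domain Green's functions. Returns both the fluence
#' phi(rho, z, t) and the boundary reflectance R(rho, t) (z = 0 hybrid flux
#' expression; for PCB the reflectance uses the erfc-form kernel).
#'
#' @param setup a \code{\link{semi_infinite_setup}}
#' @param rho radial distance, mm (scalar)
#' @param t_vector strictly positive times, seconds
#' @param z depth for the fluence output, mm
#' @return list with \code{time}, \code{fluence}, \code{reflectance}
#' @export
semi_infinite_tr <- function(setup, rho, t_vector, z = 0) {
  st <- setup
  if (any(t_vector <= 0)) stop("all times must be > 0 (t = 0 is singular)")
  t <- t_vector
  cc <- st$c; kap <- st$kappa
  decay <- exp(-st$mua * cc * t)
  if (st$bc_kind != "pcb") {
    r1sq <- (z - st$z0)^2 + rho^2
    rbsq <- (z + st$z0 + 2 * st$zb)^2 + rho^2
    flu <- cc * decay / (4 * pi * kap * cc * t)^(3 / 2) *
      (exp(-r1sq / (4 * kap * cc * t)) - exp(-rbsq / (4 * kap * cc * t)))
    refl <- 0.5 * decay / ((4 * pi * kap * cc)^(3 / 2) * t^(5 / 2)) *
      (st$z0 * exp(-(st$z0^2 + rho^2) / (4 * kap * cc * t)) +
       (st$z0 + 2 * st$zb) *
         exp(-((st$z0 + 2 * st$zb)^2 + rho^2) / (4 * kap * cc * t)))
  } else {
    r1sq <- (z - st$z0)^2 + rho^2
    r2sq <- (z + st$z0)^2 + rho^2
    zb <- st$zb
    intg <- vapply(t, function(tk) {
      integrate(function(l)
        exp(-l / zb) * exp(-((z + st$z0 + l)^2 + rho^2) / (4 * kap * cc * tk)),
        0, 40 * zb, rel.tol = 1e-8, subdivisions = 500L)$value
    }, numeric(1))
    flu <- cc * decay / (4 * pi * kap * cc * t)^(3 / 2) *
      (exp(-r1sq / (4 * kap * cc * t)) + exp(-r2sq / (4 * kap * cc * t)) -
       (2 / zb) * intg)
    a <- st$z0 * st$beta / (cc * t)
    b <- 4 * st$beta / 3
    erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
    tpcb <- (1 / a) * (1 - sqrt(pi / (a * b)) * exp((1 + a)^2 / (a * b)) *
                         erfc((1 + a) / sqrt(a * b)))
    refl <- st$z0 * decay / ((4 * pi * kap * cc)^(3 / 2) * t^(5 / 2)) *
      exp(-(st$z0^2 + rho^2) / (4 * kap * cc * t)) * tpcb
  }
  list(time = t, fluence = flu, reflectance = refl)
}

#' Analytical DCS g1 curve in a semi-infinite medium
#'
#' The correlation-diffusion solution is the CW solution with the absorption
#' substitution \code{mua -> mua + 2*alphaDb*musp*k0^2*tau}; g1 is the curve
#' normalized by its tau = 0 value.
#'
#' @param setup a \code{\link{semi_infinite_setup}}
#' @param alphaDb lumped flow index, mm^2/s
#' @param wavelength laser wavelength, nm
#' @param tau_vector correlation delays, seconds, including 0
#' @param rho source-detector distance, mm
#' @param z depth, mm
#' @return list with \code{tau}, \code{G1}, \code{g1}
#' @export
semi_infinite_dcs <- function(setup, alphaDb, wavelength, tau_vector,
                              rho, z = 0) {
  if (!any(tau_vector == 0)) stop("tau_vector must include 0")
  k0 <- 2 * pi / (wavelength * 1e-6)  # nm -> mm
  g1v <- vapply(tau_vector, function(tau) {
    st2 <- setup
    st2$mua <- setup$mua + 2 * alphaDb * setup$musp * k0^2 * tau
    # kappa, z0, zb are properties of the static medium: unchanged
    semi_infinite_fd(st2, rho, z, 0)
  }, numeric(1))
  g0 <- g1v[which(tau_vector == 0)[1]]
  list(tau = tau_vector, G1 = g1v, g1 = g1v / g0)
}
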