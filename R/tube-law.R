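#' Arterial tube law: pressure from area
#'
#' Constitutive closure of the 1D model for a thin, incompressible,
#' homogeneous, isotropic, linearly elastic wall deforming axisymmetrically:
#' \deqn{P(A) = P_d + \frac{\beta}{A_d}\left(\sqrt{A} - \sqrt{A_d}\right),}
#' where \eqn{A_d} is the luminal area at the diastolic pressure \eqn{P_d}
#' and \eqn{\beta} lumps the elastic properties of the wall (units Pa m).
#' The law is strictly increasing and continuously differentiable in
#' \eqn{A > 0}.
#'
#' @param A luminal area, m^2 (vectorised; must be > 0).
#' @param Ad diastolic area, m^2.
#' @param beta elastic parameter, Pa m.
#' @param Pd diastolic pressure, Pa.
#' @return transmural pressure in Pa.
#' @seealso [tube_law_area()] for the inverse, [wave_speed()].
#' @export
tube_law_pressure <- function(A, Ad, beta, Pd) {
  stopifnot(all(A > 0), all(Ad > 0), all(beta > 0))
  Pd + (beta / Ad) * (sqrt(A) - sqrt(Ad))
}

#' Arterial tube law: area from pressure (closed-form inverse)
#'
#' @param P pressure, Pa.
#' @inheritParams tube_law_pressure
#' @return luminal area in m^2. Errors if `P` is below the collapse
#'   pressure at which the law would give non-positive area.
#' @export
tube_law_area <- function(P, Ad, beta, Pd) {
  s <- sqrt(Ad) + (P - Pd) * Ad / beta
  if (any(s <= 0)) stop("pressure below the collapse limit of the tube law")
  s^2
}

#' Pulse wave velocity of the tube law
#'
#' From \eqn{c^2 = (A/\rho)\,\partial P/\partial A} the tube law gives the
#' closed form
#' \deqn{c(A) = \sqrt{\frac{\beta}{2 \rho A_d}}\, A^{1/4}.}
#' At \eqn{A = A_d} this reduces to the diastolic wave speed used to
#' calibrate \eqn{\beta} from measured pulse wave velocity.
#'
#' @inheritParams tube_law_pressure
#' @param rho blood density, kg/m^3.
#' @return wave speed in m/s.
#' @export
wave_speed <- function(A, Ad, beta, rho) {
  stopifnot(all(A > 0), all(Ad > 0), all(beta > 0), rho > 0)
  sqrt(beta / (2 * rho * Ad)) * A^0.25
}

#' Elastic parameter from diastolic wave speed
#'
#' Inverts the diastolic limit of [wave_speed()]:
#' \deqn{\beta = 2 \rho c_d^2 \sqrt{A_d},}
#' relating the elastic parameter required by the 1D model to the pulse
#' wave velocity at diastolic pressure estimated from data.
#'
#' @param c_d diastolic wave speed, m/s.
#' @param Ad diastolic area, m^2.
#' @param rho blood density, kg/m^3.
#' @return elastic parameter beta in Pa m.
#' @export
beta_from_speed <- function(c_d, Ad, rho) {
  stopifnot(all(c_d > 0), all(Ad > 0), rho > 0)
  2 * rho * c_d^2 * sqrt(Ad)
}

#' Elastic modulus from diastolic wave speed
#'
#' For a thin membrane the elastic parameter relates to the wall's Young
#' modulus and thickness as \eqn{\beta = \tfrac{4}{3}\sqrt{\pi} E h}, so
#' with \eqn{h = } `wall_thickness_ratio` \eqn{\times\, r_d},
#' \deqn{E = \frac{3 \beta}{4 \sqrt{\pi} h}
#'         = \frac{3 \rho c_d^2}{2\, h/r_d}.}
#' When the wall thickness is a fixed fraction of the radius (default 10%),
#' `E` depends only on `c_d` and `rho`.
#'
#' @inheritParams beta_from_speed
#' @param r_d diastolic luminal radius, m.
#' @param wall_thickness_ratio wall thickness as a fraction of `r_d`
#'   (default 0.1).
#' @return Young modulus E in Pa.
#' @export
elastic_modulus_from_speed <- function(c_d, r_d, rho,
                                       wall_thickness_ratio = 0.1) {
  stopifnot(all(c_d > 0), all(r_d > 0), rho > 0, wall_thickness_ratio > 0)
  Ad <- pi * r_d^2
  beta <- beta_from_speed(c_d, Ad, rho)
  h <- wall_thickness_ratio * r_d
  3 * beta / (4 * sqrt(pi) * h)
}

#' Diastolic wave speed implied by an elastic modulus
#'
#' Closure of the beta/E conversions: inverts
#' [elastic_modulus_from_speed()].
#'
#' @param E Young modulus, Pa.
#' @inheritParams elastic_modulus_from_speed
#' @return diastolic wave speed in m/s.
#' @export
speed_from_elastic_modulus <- function(E, r_d, rho,
                                       wall_thickness_ratio = 0.1) {
  h <- wall_thickness_ratio * r_d
  beta <- 4 * sqrt(pi) * E * h / 3
  Ad <- pi * r_d^2
  wave_speed(Ad, Ad, beta, rho)
}

#' Local area compliance of the tube law
#'
#' \eqn{dA/dP = 2 A_d \sqrt{A} / \beta}; at diastolic conditions
#' \eqn{dA/dP = 2 A_d^{3/2}/\beta}. Integrated axially this yields a
#' segment's conduit compliance.
#'
#' @inheritParams tube_law_pressure
#' @return dA/dP in m^2/Pa.
#' @keywords internal
area_compliance <- function(A, Ad, beta) 2 * Ad * sqrt(A) / beta

#' Blood properties of the 1D model
#'
#' @param rho density, kg/m^3 (default 1060).
#' @param mu dynamic viscosity, Pa s (default 4e-3; `mu = 0` selects the
#'   inviscid model).
#' @param zeta polynomial order of the axisymmetric axial velocity profile
#'   (default 9; sets the wall friction coefficient `2*(zeta+2)*pi*mu`).
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1060, mu = 4e-3, zeta = 9) {
  stopifnot(rho > 0, mu >= 0, zeta >= 2)
  structure(list(rho = rho, mu = mu, zeta = zeta),
            class = "fluid_properties")
}
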