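# Closed-form constitutive evaluators for the fiber-bundle materials.
#
# Fibers and ECM are transversely isotropic, nearly incompressible
# hyperelastic materials: a Mooney-Rivlin ground substance F1, an
# along-fiber response F2(lambda~) with an exponential toe region and a
# linear region above the transition stretch lambda_m, and a dilatational
# term K/2 [ln J]^2. Active fiber tension follows a time-varying elastance
# model with calcium sensitivity ECa50 depending on sarcomere length.

#' Constitutive parameters for a transversely isotropic material
#'
#' `c6` is derived from stress continuity at the transition stretch:
#' `c5 * lambda_m + c6 = c3 * (exp(c4 * (lambda_m - 1)) - 1)`.
#'
#' @param c1,c2 Mooney-Rivlin ground-substance constants (kPa).
#' @param c3,c4,c5 Along-fiber response constants (`c3`, `c5` in kPa,
#'   `c4` dimensionless).
#' @param K Bulk modulus (kPa).
#' @param lambda_m Transition stretch between the exponential and linear
#'   fiber regimes (> 1).
#' @param density Material density (unused by the strain surrogate; kept for
#'   sensitivity bookkeeping).
#' @return A list of class `constitutive_params` including the derived `c6`.
#' @examples
#' fiber_params() # fiber defaults
#' ecm_params()   # ECM differs only in c1
#' @export
constitutive_params <- function(c1 = 15, c2 = 0, c3 = 2, c4 = 60, c5 = 600,
                                K = 1000, lambda_m = 1.06, density = 1) {
  stopifnot(c1 >= 0, c3 >= 0, c4 >= 0, c5 >= 0, K > 0, lambda_m > 1,
            density > 0)
  c6 <- c3 * (exp(c4 * (lambda_m - 1)) - 1) - c5 * lambda_m
  structure(
    list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6, K = K,
         lambda_m = lambda_m, density = density),
    class = "constitutive_params"
  )
}

#' @rdname constitutive_params
#' @export
fiber_params <- function() constitutive_params(c1 = 15)

#' @rdname constitutive_params
#' @export
ecm_params <- function() constitutive_params(c1 = 0.5)

#' Along-fiber stress response
#'
#' Evaluates `lambda~ * dF2/dlambda~`, the fiber Cauchy stress contribution:
#' 0 below unit stretch, `c3 * (exp(c4 * (l - 1)) - 1)` in the exponential
#' toe region, and `c5 * l + c6` above `lambda_m`. Continuous at both branch
#' points by construction of `c6`.
#'
#' @param lambda_t Deviatoric fiber stretch (> 0), vectorised.
#' @param p A `constitutive_params`.
#' @return Stress response, kPa.
#' @export
fiber_stress <- function(lambda_t, p = fiber_params()) {
  stopifnot(all(lambda_t > 0))
  out <- numeric(length(lambda_t))
  mid <- lambda_t > 1 & lambda_t <= p$lambda_m
  hi <- lambda_t > p$lambda_m
  out[mid] <- p$c3 * (exp(p$c4 * (lambda_t[mid] - 1)) - 1)
  out[hi] <- p$c5 * lambda_t[hi] + p$c6
  out
}

#' Along-fiber strain-energy response
#'
#' The fiber family energy `F2(lambda~)`: 0 below unit stretch,
#' `c3 * (exp(-c4) * (Ei(c4 l) - Ei(c4)) - ln l)` in the toe region (Ei is
#' the exponential integral), and `c5 * (l - 1) + c6 * ln l` above
#' `lambda_m`. Its logarithmic derivative `l * dF2/dl` reproduces
#' [fiber_stress()] on the toe region.
#'
#' @inheritParams fiber_stress
#' @return Energy density, kPa.
#' @export
fiber_energy <- function(lambda_t, p = fiber_params()) {
  stopifnot(all(lambda_t > 0))
  if (p$c4 <= 0) stop_("exponential integral argument c4 * lambda_t must be nonzero")
  out <- numeric(length(lambda_t))
  mid <- lambda_t > 1 & lambda_t <= p$lambda_m
  hi <- lambda_t > p$lambda_m
  if (any(mid)) {
    lm <- lambda_t[mid]
    out[mid] <- p$c3 * (exp(-p$c4) *
                          (pracma::expint_Ei(p$c4 * lm) - pracma::expint_Ei(p$c4)) -
                          log(lm))
  }
  out[hi] <- p$c5 * (lambda_t[hi] - 1) + p$c6 * log(lambda_t[hi])
  out
}

#' Active contraction parameters (time-varying elastance model)
#'
#' @param Tmax Maximum isometric tension, kPa.
#' @param Ca0_max Peak intracellular calcium concentration, uM.
#' @param B Calcium-length sensitivity constant, 1/um.
#' @param l0 Sarcomere length with no active tension, um.
#' @param refl Reference (optimal) sarcomere length, um.
#' @param ascl Activation scale.
#' @param Ct Activation level C(t) in [0, 1].
#' @return A list of class `active_params`.
#' @export
active_params <- function(Tmax = 135.7, Ca0_max = 4.35, B = 4.75, l0 = 1.58,
                          refl = 2.04, ascl = 1, Ct = 1) {
  stopifnot(Tmax > 0, Ca0_max > 0, B > 0, l0 > 0, Ct >= 0, Ct <= 1)
  structure(list(Tmax = Tmax, Ca0_max = Ca0_max, B = B, l0 = l0, refl = refl,
                 ascl = ascl, Ct = Ct),
            class = "active_params")
}

#' Active fiber tension
#'
#' `Ta = Tmax * Ca0^2 / (Ca0^2 + ECa50^2) * C(t)` with `Ca0 = Ca0_max`.
#' The default (`form = "standard"`) calcium sensitivity is
#' `ECa50 = Ca0_max / sqrt(exp(B * (l - l0)) - 1)`, which vanishes-tension
#' at the slack length `l0` and saturates toward `Tmax * C(t)` at long
#' sarcomere lengths. `form = "literal"` exposes the alternative reading
#' `ECa50 = Tmax * Ca0_max * exp(B * (l - l0)) - 1`. Below slack length the
#' tension is 0 by convention.
#'
#' @param l Sarcomere length, um (vectorised).
#' @param a An `active_params`.
#' @param form `"standard"` or `"literal"` (see Details).
#' @return Active tension, kPa, in `[0, Tmax * Ct]`.
#' @export
active_tension <- function(l, a = active_params(), form = c("standard", "literal")) {
  form <- match.arg(form)
  out <- numeric(length(l))
  above <- l > a$l0
  if (any(above)) {
    la <- l[above]
    eca50 <- if (form == "standard") {
      a$Ca0_max / sqrt(exp(a$B * (la - a$l0)) - 1)
    } else {
      a$Tmax * a$Ca0_max * exp(a$B * (la - a$l0)) - 1
    }
    ca2 <- a$Ca0_max^2
    out[above] <- a$Tmax * ca2 / (ca2 + eca50^2) * a$Ct
  }
  out
}
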