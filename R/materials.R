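# Passive and active myocardial material laws.
#
# The ventricular wall is transversely isotropic (Guccione strain-energy
# law); atria, vessels and surrounding tissue are Neo-Hookean. Near
# incompressibility is enforced by a volumetric penalty on det(F).

#' Conversion between mmHg and Pa
#'
#' @param x pressure values.
#' @return Converted pressure. One mmHg is 133.322 Pa.
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' Passive material parameter presets
#'
#' Named parameter sets for the tissue regions of the heart model. The
#' ventricular row parameterizes the Guccione law (shear modulus `C` in Pa,
#' dimensionless exponents `b_f`, `b_t`, `b_ft`); all other rows are
#' Neo-Hookean with stiffness `C` in Pa. `K` is the incompressibility
#' penalty modulus in Pa and `rho0` the tissue density in kg/m^3.
#'
#' @param tissue one of `"ventricle"`, `"atrium"`, `"pericardium"`, `"fat"`,
#'   `"vein"`, `"artery"`, `"valve_plane"`.
#' @return A list of material parameters with class `"guccione_params"`
#'   (ventricle) or `"neo_hooke_params"` (all other rows).
#' @export
material_presets <- function(tissue = c("ventricle", "atrium", "pericardium",
                                        "fat", "vein", "artery",
                                        "valve_plane")) {
  tissue <- match.arg(tissue)
  rho0 <- 1082
  p <- switch(tissue,
    ventricle   = list(C = 278, b_f = 12.0, b_t = 4.8, b_ft = 8.4,
                       K = 200e3, rho0 = rho0),
    atrium      = list(C = 7450,   K = 200e3,  rho0 = rho0),
    pericardium = list(C = 10000,  K = 1000e3, rho0 = rho0),
    fat         = list(C = 3725,   K = 1000e3, rho0 = rho0),
    vein        = list(C = 14900,  K = 200e3,  rho0 = rho0),
    artery      = list(C = 14900,  K = 200e3,  rho0 = rho0),
    valve_plane = list(C = 200000, K = 200e3,  rho0 = rho0))
  class(p) <- if (tissue == "ventricle") "guccione_params" else
    "neo_hooke_params"
  p$tissue <- tissue
  p
}

#' Green strain state from a deformation gradient
#'
#' Computes the Green-Lagrange strain tensor E = (F'F - I)/2 and the
#' Jacobian J = det(F). Components are interpreted in the local
#' fiber/sheet/normal frame (indices 1, 2, 3).
#'
#' @param F 3x3 deformation-gradient matrix with positive determinant.
#' @return A list with class `"strain_state"`: `E` (3x3 symmetric matrix)
#'   and `J` (scalar, det F).
#' @export
green_strain <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)), all(is.finite(F)))
  J <- det(F)
  if (J <= 0) {
    stop("kinematics error: non-positive determinant det(F) = ", J)
  }
  E <- 0.5 * (crossprod(F) - diag(3))
  structure(list(E = E, J = J), class = "strain_state")
}

as_strain_state <- function(strain) {
  if (inherits(strain, "strain_state")) return(strain)
  stopifnot(is.list(strain), !is.null(strain$E), !is.null(strain$J))
  structure(list(E = as.matrix(strain$E), J = strain$J),
            class = "strain_state")
}

#' Guccione transversely isotropic strain-energy density
#'
#' W = C/2 (exp(Q) - 1) + K/2 (J - 1)^2 with
#' Q = b_f E11^2 + b_t (E22^2 + E33^2 + E23^2 + E32^2)
#'   + b_ft (E12^2 + E21^2 + E13^2 + E31^2),
#' where index 1 is the fiber direction. The exponent is clipped at 700
#' to avoid overflow; a clipped evaluation is flagged.
#'
#' @param strain a `strain_state` (see [green_strain()]).
#' @param p Guccione parameters, e.g. `material_presets("ventricle")`.
#' @return Energy density in Pa, with attribute `"clipped"` (logical).
#' @export
guccione_energy <- function(strain, p = material_presets("ventricle")) {
  s <- as_strain_state(strain)
  E <- s$E
  Q <- p$b_f * E[1, 1]^2 +
    p$b_t * (E[2, 2]^2 + E[3, 3]^2 + E[2, 3]^2 + E[3, 2]^2) +
    p$b_ft * (E[1, 2]^2 + E[2, 1]^2 + E[1, 3]^2 + E[3, 1]^2)
  clipped <- Q > 700
  W <- p$C / 2 * (exp(min(Q, 700)) - 1) + p$K / 2 * (s$J - 1)^2
  attr(W, "clipped") <- clipped
  W
}

#' Neo-Hookean strain-energy density (isochoric split)
#'
#' W = C/2 (Ibar1 - 3) + K/2 (J - 1)^2, with Ibar1 = J^(-2/3) tr(F'F)
#' the isochoric first invariant. tr(F'F) is recovered from the Green
#' strain as 2 tr(E) + 3.
#'
#' @inheritParams guccione_energy
#' @param p Neo-Hooke parameters, e.g. `material_presets("atrium")`.
#' @return Energy density in Pa.
#' @export
neo_hooke_energy <- function(strain, p = material_presets("atrium")) {
  s <- as_strain_state(strain)
  I1 <- 2 * sum(diag(s$E)) + 3
  I1bar <- s$J^(-2 / 3) * I1
  p$C / 2 * (I1bar - 3) + p$K / 2 * (s$J - 1)^2
}

# Q and dQ/dlambda under the plane-strain incompressible membrane
# kinematics: E11 = (l^2-1)/2 (circumferential fiber), E22 = 0,
# E33 = (l^-2-1)/2 (transmural), J = 1.
membrane_Q <- function(lambda, p, fiber_blend = 1) {
  b_circ <- fiber_blend * p$b_f + (1 - fiber_blend) * p$b_t
  E11 <- (lambda^2 - 1) / 2
  E33 <- (lambda^-2 - 1) / 2
  list(
    Q = b_circ * E11^2 + p$b_t * E33^2,
    dQ = 2 * b_circ * E11 * lambda - 2 * p$b_t * E33 * lambda^-3
  )
}

#' Passive membrane tension of the ventricular wall
#'
#' Reduces the Guccione law to the one-dimensional kinematics of the wall
#' solver: circumferential fiber stretch `lambda`, plane strain along the
#' chamber axis and incompressible transmural thinning
#' (E11 = (lambda^2-1)/2, E22 = 0, E33 = (lambda^-2-1)/2, J = 1).
#' Tension per unit length is T = h0 * lambda * dW/dlambda, evaluated
#' analytically; T(1) = 0 at the reference state.
#'
#' @param lambda circumferential stretch ratio (> 0); vectorized.
#' @param p Guccione parameters.
#' @param h0 reference wall thickness in m.
#' @param fiber_blend weight in `[0, 1]` mixing the fiber exponent `b_f`
#'   (weight 1, default: purely circumferential fibers) with the
#'   cross-fiber exponent `b_t`, emulating a transmural +/-60 degree
#'   fiber-angle average.
#' @return Tension per unit length in N/m.
#' @export
membrane_tension <- function(lambda, p = material_presets("ventricle"),
                             h0 = 0.01, fiber_blend = 1) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("kinematics error: stretch lambda must be positive and finite")
  }
  q <- membrane_Q(lambda, p, fiber_blend)
  dW <- p$C / 2 * exp(pmin(q$Q, 700)) * q$dQ
  h0 * lambda * dW
}

#' Activation (active tension) parameters
#'
#' Parameters of the periodic double-Hill activation driver: peak active
#' tension `T_peak` (Pa), phase centers `alpha1 < alpha2` (fractions of the
#' cycle), Hill exponents `n1`, `n2`, heart period `T_cycle` (s, default
#' 1.247) and activation onset delay `t_onset` (s).
#'
#' @param T_peak peak active tension in Pa.
#' @param alpha1,alpha2 dimensionless phase centers, 0 < alpha1 < alpha2 < 1.
#' @param n1,n2 Hill exponents (>= 1).
#' @param T_cycle heart period in s.
#' @param t_onset activation delay within the cycle in s.
#' @return A list with class `"activation_params"`.
#' @export
activation_params <- function(T_peak = 80e3, alpha1 = 0.303, alpha2 = 0.508,
                              n1 = 1.32, n2 = 21.9, T_cycle = 1.247,
                              t_onset = 0.15) {
  stopifnot(T_cycle > 0, n1 >= 1, n2 >= 1,
            alpha1 > 0, alpha1 < alpha2, alpha2 < 1)
  structure(list(T_peak = T_peak, alpha1 = alpha1, alpha2 = alpha2,
                 n1 = n1, n2 = n2, T_cycle = T_cycle, t_onset = t_onset),
            class = "activation_params")
}

#' Periodic double-Hill active tension
#'
#' a(tau) = h0 * T_peak * g1(tau) * g2(tau) with
#' tau = ((t - t_onset) mod T_cycle) / T_cycle,
#' g1 = (tau/alpha1)^n1 / (1 + (tau/alpha1)^n1) and
#' g2 = 1 / (1 + (tau/alpha2)^n2). The driver is periodic with period
#' `T_cycle` and vanishes at tau = 0.
#'
#' @param t time in s (vectorized), t >= 0.
#' @param p an [activation_params()] list.
#' @param h0 wall thickness in m converting the active stress `T_peak`
#'   (Pa) into a tension per unit length; the default `h0 = 1` returns
#'   the active stress itself.
#' @return Active tension per unit length in N/m (stress in Pa for
#'   `h0 = 1`).
#' @export
active_tension <- function(t, p = activation_params(), h0 = 1) {
  tau <- ((t - p$t_onset) %% p$T_cycle) / p$T_cycle
  g1 <- (tau / p$alpha1)^p$n1
  g1 <- g1 / (1 + g1)
  g2 <- 1 / (1 + (tau / p$alpha2)^p$n2)
  h0 * p$T_peak * g1 * g2
}
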