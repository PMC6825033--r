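## Reference (R-level) implementation of the point constitutive model.  The
## assembler uses an equivalent compiled kernel; tests cross-check the two.

#' Kinematic state at a material point
#'
#' Computes the spatial kinematic quantities used by the constitutive model
#' from a deformation gradient `F` and the reference fibre frame: the Jacobian
#' `J = det F`, the left Cauchy--Green tensor `b = F F'`, the first invariant
#' `I1 = tr b`, the squared fibre stretches `I4 = M . C M`, `I6 = Mp . C Mp`
#' and the spatial fibre vectors `m = F M`, `mp = F Mp`.
#'
#' @param F 3x3 deformation gradient with `det F > 0`.
#' @param frame A [fiber_frame()]; `Mp` may be absent.
#' @return An object of class `"kinematic_state"`: list with `F`, `J`, `b`,
#'   `I1`, `I4`, `I6` (`NA` if the family is absent), `m`, `mp`.
#' @examples
#' fr <- fiber_frame(c(1, 0, 0))
#' compute_kinematics(diag(3), fr)$I1  # 3
#' @export
compute_kinematics <- function(F, frame) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!(J > 0))
    stop("invalid deformation: det F = ", format(J), " (must be > 0)")
  b <- tcrossprod(F)             # F F'
  C <- crossprod(F)              # F' F
  m <- drop(F %*% frame$M)
  I4 <- drop(crossprod(frame$M, C %*% frame$M))
  if (!is.null(frame$Mp)) {
    mp <- drop(F %*% frame$Mp)
    I6 <- drop(crossprod(frame$Mp, C %*% frame$Mp))
  } else {
    mp <- NULL; I6 <- NA_real_
  }
  structure(list(F = F, J = J, b = b, I1 = sum(diag(b)),
                 I4 = I4, I6 = I6, m = m, mp = mp),
            class = "kinematic_state")
}

#' Effective isotropic energy density (ground matrix + volumetric)
#'
#' Compressible neo-Hookean ground-matrix energy plus a convex volumetric
#' penalty, both stress-free at the reference state:
#' `Psi0_iso = mu/2 (I1 - 3 - 2 ln J) + kappa/4 (J^2 - 1 - 2 ln J)`.
#'
#' @param state A [compute_kinematics()] result.
#' @param p [material_params()].
#' @return Energy density, kPa (non-negative).
#' @export
psi0_iso <- function(state, p) {
  if (!(state$J > 0))
    stop("invalid deformation: det F = ", format(state$J), " (must be > 0)")
  0.5 * p$mu * (state$I1 - 3 - 2 * log(state$J)) +
    0.25 * p$kappa * (state$J^2 - 1 - 2 * log(state$J))
}

#' Effective anisotropic (fibre) energy density
#'
#' Exponential HGO fibre energy summed over the families present,
#' `Psi0_ani = k1/(2 k2) sum_i [exp(k2 <Ii - 1>^2) - 1]`, with the Macaulay
#' bracket implementing the tension-only switch: fibres under compressive
#' stretch (`Ii <= 1`) store no energy.
#'
#' @inheritParams psi0_iso
#' @param tension_only If `FALSE`, compressed fibres also store energy (the
#'   bracket is dropped).
#' @return Energy density, kPa (non-negative; zero at `I4 = I6 = 1`).
#' @export
psi0_ani <- function(state, p, tension_only = TRUE) {
  Is <- c(state$I4, if (!is.na(state$I6)) state$I6)
  if (p$k1 == 0 || length(Is) == 0L) return(0)
  E <- Is - 1
  if (tension_only) E <- macaulay(E)
  q <- p$k2 * E^2
  if (any(q > 700))
    stop("fibre energy overflow: invariant value ", format(Is[which.max(q)]))
  sum(0.5 * p$k1 / p$k2 * (exp(q) - 1))
}

#' Degradation function g(d) = (1 - d)^a
#'
#' Monotone energy-degradation multiplier with `g(0) = 1`, `g(1) = 0` and
#' saturation `g'(1) = 0` for exponents `a > 1`.
#'
#' @param d Damage phase field, in `[0, 1]`.
#' @param a Exponent (> 1); 2 gives the quadratic degradation used by default.
#' @return `g(d)`, same shape as `d`.
#' @export
degradation <- function(d, a = 2) {
  if (any(d < 0 | d > 1)) stop("`d` must lie in [0, 1]")
  (1 - d)^a
}

#' Degraded energy density
#'
#' `Psi = g_iso(d) Psi0_iso + g_ani(d) Psi0_ani`: the stored energy of the
#' damaged material, recovering the intact model at `d = 0` and vanishing at
#' `d = 1`.
#'
#' @inheritParams psi0_ani
#' @param d Damage value in `[0, 1]`.
#' @param pf [phase_field_params()] supplying the degradation exponents.
#' @return Energy density, kPa.
#' @export
degraded_energy <- function(state, d, p, pf, tension_only = TRUE) {
  degradation(d, pf$a_iso) * psi0_iso(state, p) +
    degradation(d, pf$a_ani) * psi0_ani(state, p, tension_only)
}

fiber_dpsi <- function(I, p, tension_only) {
  E <- I - 1
  if (tension_only && E <= 0) return(0)
  p$k1 * E * exp(p$k2 * E^2)
}

#' Kirchhoff stress of the degrading material
#'
#' Closed-form Kirchhoff stress `tau = 2 dPsi/dg` (spatial metric derivative),
#' i.e.
#' `tau = g_iso(d) [ mu (b - I) + kappa/2 (J^2 - 1) I ]
#'       + g_ani(d) sum_i 2 k1 <Ii-1> exp(k2 <Ii-1>^2) m_i %o% m_i`.
#'
#' @inheritParams degraded_energy
#' @return Symmetric 3x3 Kirchhoff stress, kPa; zero at the reference state
#'   and at `d = 1`.
#' @export
kirchhoff_stress <- function(state, d, p, pf, tension_only = TRUE) {
  stopifnot(d >= 0, d <= 1)
  g_iso <- degradation(d, pf$a_iso)
  g_ani <- degradation(d, pf$a_ani)
  tau <- g_iso * (p$mu * (state$b - diag(3)) +
                    0.5 * p$kappa * (state$J^2 - 1) * diag(3))
  tau <- tau + g_ani * 2 * fiber_dpsi(state$I4, p, tension_only) *
    tcrossprod(state$m)
  if (!is.na(state$I6))
    tau <- tau + g_ani * 2 * fiber_dpsi(state$I6, p, tension_only) *
      tcrossprod(state$mp)
  tau
}

#' Energetic force conjugate to the phase field
#'
#' `f = -dPsi/dd = a_iso (1-d)^(a_iso-1) Psi0_iso
#'               + a_ani (1-d)^(a_ani-1) Psi0_ani`, non-negative, vanishing at
#' full rupture (`d = 1`) by the saturation property of `g`.
#'
#' @inheritParams degraded_energy
#' @return Scalar energetic force, kPa.
#' @export
energetic_force <- function(state, d, p, pf, tension_only = TRUE) {
  stopifnot(d >= 0, d <= 1)
  pf$a_iso * (1 - d)^(pf$a_iso - 1) * psi0_iso(state, p) +
    pf$a_ani * (1 - d)^(pf$a_ani - 1) * psi0_ani(state, p, tension_only)
}

#' Spatial elasticity tensor of the degrading material
#'
#' Consistent linearisation of the Kirchhoff stress for the Newton solver,
#' returned as the rank-4 spatial (Lie-derivative) modulus `c` with both minor
#' and major symmetries:
#' `c = g_iso [ kappa J^2 I x I + (2 mu - kappa (J^2-1)) IIsym ]
#'     + g_ani sum_i 4 psi''(Ii) m_i x m_i x m_i x m_i`.
#' The directional derivative of `tau` under a superposed velocity gradient
#' `lv` is `dtau = c : sym(lv) + lv tau + tau lv'`.
#'
#' @inheritParams degraded_energy
#' @return A `3 x 3 x 3 x 3` array, kPa.
#' @export
material_tangent <- function(state, d, p, pf, tension_only = TRUE) {
  g_iso <- degradation(d, pf$a_iso)
  g_ani <- degradation(d, pf$a_ani)
  A <- g_iso * p$kappa * state$J^2
  B <- g_iso * (2 * p$mu - p$kappa * (state$J^2 - 1))
  cc <- array(0, c(3, 3, 3, 3))
  I3 <- diag(3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    cc[i, j, k, l] <- A * I3[i, j] * I3[k, l] +
      0.5 * B * (I3[i, k] * I3[j, l] + I3[i, l] * I3[j, k])
  add_fiber <- function(cc, I, m) {
    E <- I - 1
    if (tension_only && E <= 0) return(cc)
    ddpsi <- p$k1 * exp(p$k2 * E^2) * (1 + 2 * p$k2 * E^2)
    cc + g_ani * 4 * ddpsi * (m %o% m %o% m %o% m)
  }
  cc <- add_fiber(cc, state$I4, state$m)
  if (!is.na(state$I6)) cc <- add_fiber(cc, state$I6, state$mp)
  cc
}
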