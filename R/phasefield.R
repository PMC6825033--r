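## Regularised crack geometry, anisotropic structure tensor, crack driving
## sources and the irreversible history field.

#' Anisotropic structure tensor of the regularised crack surface
#'
#' `L = l^2 (I + omega_M M %o% M + omega_Mp Mp %o% Mp)`, positive definite for
#' anisotropy parameters in (-1, Inf), together with its isotropic/anisotropic
#' split `L_iso = l^2 I`, `L_ani = L - L_iso`.  As `omega -> Inf` the
#' crack-gradient energy forces `grad d` to align with the fibre direction, so
#' the crack runs parallel to the fibres.
#'
#' @param pf [phase_field_params()].
#' @param frame [fiber_frame()].
#' @return List with `L`, `L_iso`, `L_ani` (3x3, mm^2).
#' @export
structure_tensor <- function(pf, frame) {
  if (pf$omega_M <= -1 || pf$omega_Mp <= -1)
    stop("ellipticity requires anisotropy parameters in the open range (-1, Inf)")
  L_iso <- pf$l^2 * diag(3)
  L_ani <- pf$l^2 * pf$omega_M * frame$A_M
  if (!is.null(frame$A_Mp))
    L_ani <- L_ani + pf$l^2 * pf$omega_Mp * frame$A_Mp
  list(L = L_iso + L_ani, L_iso = L_iso, L_ani = L_ani)
}

#' Anisotropic crack surface density
#'
#' `gamma = (1/2l) (d^2 + grad_d . L grad_d)`, the volume density whose
#' integral regularises the sharp crack area.  With `L = l^2 I` it reduces to
#' the isotropic density `(1/2l)(d^2 + l^2 |grad d|^2)`; for a single fibre
#' family it expands to the three-term penalty form
#' `d^2/2l + l/2 |grad d|^2 + l/2 omega_M (grad_d . M)^2`.
#'
#' @param d Phase-field value in `[0, 1]`.
#' @param grad_d Length-3 gradient, 1/mm.
#' @param L Structure tensor (3x3, mm^2), e.g. `structure_tensor(...)$L`.
#' @param l Length scale, mm.
#' @return Crack surface density, 1/mm.
#' @export
crack_density <- function(d, grad_d, L, l) {
  stopifnot(d >= 0, d <= 1)
  grad_d <- as.numeric(grad_d)
  (d^2 + drop(crossprod(grad_d, L %*% grad_d))) / (2 * l)
}

#' Crack driving source terms
#'
#' Effective (undegraded) energies normalised by the respective critical
#' fracture energies per length: `Hbar_iso = Psi0_iso / (gc_iso/l)`,
#' `Hbar_ani = Psi0_ani / (gc_ani/l)` and their sum `Hbar`.  The failure
#' surface is `Hbar = 1`.
#'
#' @param psi_iso,psi_ani Effective energy densities, kPa (>= 0).
#' @param pf [phase_field_params()].
#' @return List with `H_iso`, `H_ani`, `H` (dimensionless).
#' @export
crack_sources <- function(psi_iso, psi_ani, pf) {
  if (!(pf$gc_iso_over_l > 0) || !(pf$gc_ani_over_l > 0))
    stop("gc/l must be positive")
  H_iso <- psi_iso / pf$gc_iso_over_l
  H_ani <- psi_ani / pf$gc_ani_over_l
  list(H_iso = H_iso, H_ani = H_ani, H = H_iso + H_ani)
}

#' Irreversible history-field update
#'
#' `H = max(H_prev, <Hbar - 1>)`: the Macaulay bracket keeps the solid intact
#' until the failure surface `Hbar = 1` is crossed, and the running maximum
#' makes the crack driving source non-decreasing over the load history.
#'
#' @param H_prev Previous history values (>= 0).
#' @param Hbar Current crack driving source `Hbar_iso + Hbar_ani`.
#' @return Updated history field, elementwise.
#' @export
update_history <- function(H_prev, Hbar) {
  stopifnot(all(H_prev >= 0))
  pmax(H_prev, macaulay(Hbar - 1))
}

#' Homogeneous rate-independent phase-field solution
#'
#' With a spatially uniform history field the divergence term vanishes and the
#' rate-independent evolution equation `(1 - d) H = d` has the closed-form
#' root `d = H / (1 + H)`, used as an analytic oracle for the discrete solver.
#'
#' @param H History field values (>= 0).
#' @return `d` in `[0, 1)`, elementwise.
#' @export
homogeneous_d <- function(H) {
  stopifnot(all(H >= 0))
  H / (1 + H)
}
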