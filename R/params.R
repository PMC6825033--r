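#' Hyperelastic material parameters for one tissue layer
#'
#' Parameters of the Holzapfel--Gasser--Ogden (HGO) model: a neo-Hookean ground
#' matrix of shear modulus `mu`, two collagen fibre families with exponential
#' stiffening (`k1`, `k2`) whose mean directions lie in the
#' circumferential--axial tangent plane at `+/- alpha` to the circumferential
#' direction, and a volumetric penalty with bulk modulus `kappa`.
#'
#' When `kappa` is not supplied it defaults to `3 * mu`, preserving the
#' bulk-to-shear ratio used in the single-edge-notch sensitivity study
#' (mu = 1 kPa, kappa = 3 kPa) at any stiffness scale.
#'
#' @param mu Shear modulus of the ground matrix, kPa (> 0).
#' @param k1 Fibre stiffness, kPa (>= 0).
#' @param k2 Dimensionless fibre stiffening exponent (> 0).
#' @param alpha Fibre angle versus the circumferential direction, degrees,
#'   in `[0, 90)`.
#' @param kappa Bulk modulus, kPa (> 0); default `3 * mu`.
#' @return An object of class `"material_params"` (a named list).
#' @examples
#' material_params(mu = 83.509, k1 = 101.651, k2 = 4.173, alpha = 44.705)
#' @export
material_params <- function(mu, k1, k2, alpha, kappa = 3 * mu) {
  stopifnot(is.numeric(mu), length(mu) == 1L)
  if (!(mu > 0)) stop("`mu` must be > 0 (got ", mu, ")")
  if (!(k1 >= 0)) stop("`k1` must be >= 0 (got ", k1, ")")
  if (!(k2 > 0)) stop("`k2` must be > 0 (got ", k2, ")")
  if (!(alpha >= 0 && alpha < 90))
    stop("`alpha` must lie in [0, 90) degrees (got ", alpha, ")")
  if (!(kappa > 0)) stop("`kappa` must be > 0 (got ", kappa, ")")
  structure(list(mu = mu, k1 = k1, k2 = k2, alpha = alpha, kappa = kappa),
            class = "material_params")
}

#' @method print material_params
#' @export
print.material_params <- function(x, ...) {
  cat(sprintf(
    "HGO material: mu = %g kPa, k1 = %g kPa, k2 = %g, alpha = %g deg, kappa = %g kPa\n",
    x$mu, x$k1, x$k2, x$alpha, x$kappa))
  invisible(x)
}

#' Crack phase-field parameters
#'
#' Fracture constants of the anisotropic crack phase-field model: the
#' regularisation length scale `l` over which a sharp crack is smeared, the
#' critical fracture energies per length `gc_iso_over_l` (ground matrix) and
#' `gc_ani_over_l` (fibrous content), the anisotropy (penalty) parameters
#' `omega_M`, `omega_Mp` biasing the crack-gradient energy towards the fibre
#' directions, an optional artificial viscosity `eta` for rate-dependent
#' continuation, and the degradation exponents `a_iso`, `a_ani` of
#' `g(d) = (1 - d)^a`.
#'
#' `gc/l` is the quantity the failure criterion actually uses
#' (`Hbar = Psi0 / (gc/l)`), so it is configured directly; `l` additionally
#' sets the structure tensor scale and must respect the mesh rule `l > 2h`.
#'
#' @param l Length scale, mm (> 0).
#' @param gc_iso_over_l Isotropic critical fracture energy over `l`, kPa (> 0).
#' @param gc_ani_over_l Anisotropic critical fracture energy over `l`, kPa (> 0).
#' @param omega_M,omega_Mp Anisotropy parameters, dimensionless, each in the
#'   open range (-1, Inf) required for ellipticity of the regularised crack
#'   surface.
#' @param eta Artificial viscosity, kPa s (>= 0); 0 gives the rate-independent
#'   evolution.
#' @param a_iso,a_ani Degradation exponents (> 1); quadratic by default.
#' @return An object of class `"phase_field_params"`.
#' @examples
#' phase_field_params(l = 0.1, gc_iso_over_l = 1e-2, gc_ani_over_l = 1e-2,
#'                    omega_M = 10)
#' @export
phase_field_params <- function(l, gc_iso_over_l, gc_ani_over_l,
                               omega_M = 0, omega_Mp = 0, eta = 0,
                               a_iso = 2, a_ani = 2) {
  if (!(l > 0)) stop("`l` must be > 0")
  if (!(gc_iso_over_l > 0) || !(gc_ani_over_l > 0))
    stop("critical fracture energies `gc/l` must be > 0")
  if (omega_M <= -1 || omega_Mp <= -1)
    stop("anisotropy parameters must lie in the open range (-1, Inf); got omega_M = ",
         omega_M, ", omega_Mp = ", omega_Mp)
  if (eta < 0) stop("`eta` must be >= 0")
  if (a_iso <= 1 || a_ani <= 1)
    stop("degradation exponents must be > 1")
  structure(list(l = l, gc_iso_over_l = gc_iso_over_l,
                 gc_ani_over_l = gc_ani_over_l,
                 omega_M = omega_M, omega_Mp = omega_Mp, eta = eta,
                 a_iso = a_iso, a_ani = a_ani),
            class = "phase_field_params")
}

#' @method print phase_field_params
#' @export
print.phase_field_params <- function(x, ...) {
  cat(sprintf(
    "phase field: l = %g mm, gc_iso/l = %g kPa, gc_ani/l = %g kPa, omega = (%g, %g), eta = %g\n",
    x$l, x$gc_iso_over_l, x$gc_ani_over_l, x$omega_M, x$omega_Mp, x$eta))
  invisible(x)
}

#' Reference fibre directions of one or two collagen families
#'
#' Stores the unit mean-fibre vectors `M` (and optionally `Mp`) together with
#' their rank-one structure tensors `A_M = M %o% M`, `A_Mp`.
#'
#' @param M Numeric length-3 vector, first mean fibre direction (normalised).
#' @param Mp Optional second family direction; `NULL` for a single family.
#' @return An object of class `"fiber_frame"`.
#' @seealso [fiber_frame_from_angle()]
#' @export
fiber_frame <- function(M, Mp = NULL) {
  M <- as.numeric(M)
  stopifnot(length(M) == 3L)
  nm <- sqrt(sum(M^2))
  if (nm == 0) stop("`M` must be a non-zero vector")
  M <- M / nm
  if (!is.null(Mp)) {
    Mp <- as.numeric(Mp)
    stopifnot(length(Mp) == 3L)
    np <- sqrt(sum(Mp^2))
    if (np == 0) stop("`Mp` must be a non-zero vector")
    Mp <- Mp / np
  }
  structure(list(M = M, Mp = Mp,
                 A_M = tcrossprod(M),
                 A_Mp = if (is.null(Mp)) NULL else tcrossprod(Mp)),
            class = "fiber_frame")
}

#' Fibre frame from an angle to the circumferential direction
#'
#' Builds the two symmetric fibre families at `+/- alpha` to the local
#' circumferential axis `e1` within the `e1`--`e2` tangent plane (`e2` axial).
#'
#' @param alpha Fibre angle, degrees.
#' @param e1,e2 Orthonormal circumferential and axial directions.
#' @param two_families If `FALSE`, only the `+alpha` family is kept (the
#'   single-family configuration of the notched-plate study).
#' @return A [fiber_frame()].
#' @export
fiber_frame_from_angle <- function(alpha, e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                                   two_families = TRUE) {
  a <- alpha * pi / 180
  M <- cos(a) * e1 + sin(a) * e2
  Mp <- if (two_families) cos(a) * e1 - sin(a) * e2 else NULL
  fiber_frame(M, Mp)
}

#' Layer parameter table for the aortic tube analysis
#'
#' The per-layer elastic and phase-field constants used in the multi-layer
#' extension--inflation--torsion analysis: a degenerated medial sub-layer
#' carrying the medial fit, healthy medial sub-layers with constitutive
#' parameters increased by 20%, and a stiffer adventitia.  `gc/l` values are
#' in kPa, `omega` dimensionless.
#'
#' @return A tibble with columns `layer`, `mu`, `k1`, `k2`, `alpha`,
#'   `gc_iso_over_l`, `gc_ani_over_l`, `omega_M`.
#' @examples
#' aorta_layer_table()
#' @export
aorta_layer_table <- function() {
  tibble::tibble(
    layer = c("healthy_media", "degenerated_media", "adventitia"),
    mu = c(100.21, 83.51, 200.0),
    k1 = c(121.98, 101.65, 400.0),
    k2 = c(5.01, 4.17, 4.0),
    alpha = c(44.71, 44.71, 44.71),
    gc_iso_over_l = c(100.0, 6.0, 100.0),
    gc_ani_over_l = c(300.0, 18.0, 300.0),
    omega_M = c(1e3, 1e3, 1e3))
}

#' Medial parameter set identified from the combined shear/extension tests
#'
#' The full-precision elastic constants of the (degenerated) aortic media used
#' as ground truth by the synthetic data generator and as the seed for the
#' healthy-layer scaling.
#'
#' @return A [material_params()] object.
#' @export
medial_fit_params <- function() {
  material_params(mu = 83.509, k1 = 101.651, k2 = 4.173, alpha = 44.705)
}

#' Healthy-media constants from the degenerated-media fit
#'
#' Healthy medial sub-layers are assigned the degenerated-media constitutive
#' parameters `mu`, `k1`, `k2` increased by 20% (fibre angle unchanged),
#' rounded to the tabulated 2-decimal precision.
#'
#' @param p [material_params()] of the degenerated media (full precision).
#' @param digits Rounding applied to the scaled values; `NULL` for none.
#' @return A named numeric vector with `mu`, `k1`, `k2`, `alpha`.
#' @examples
#' healthy_from_degenerated(medial_fit_params())
#' @export
healthy_from_degenerated <- function(p, digits = 2) {
  out <- c(mu = 1.2 * p$mu, k1 = 1.2 * p$k1, k2 = 1.2 * p$k2, alpha = p$alpha)
  ## half-up decimal rounding (table convention; round() is half-to-even and
  ## 44.705 binary-represents just below the midpoint)
  if (!is.null(digits)) out <- round(out + 1e-9, digits)
  out
}
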