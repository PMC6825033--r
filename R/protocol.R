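## Load protocols: Dirichlet constraint sets and follower pressure histories
## on pseudo-time [0, T].

#' Build a load protocol
#'
#' A protocol bundles time-dependent Dirichlet constraints, an optional
#' follower pressure on a facet set, and the node set whose reactions are
#' logged.  Constraint values are piecewise functions of pseudo-time and
#' (optionally) of the reference coordinates of the constrained nodes.
#'
#' @param t_end End of the pseudo-time interval.
#' @param dirichlet List of constraints, each a list with `nodes` (indices),
#'   `dof` (1 = x, 2 = y, 3 = z; may be a vector) and `value`, a
#'   `function(t, X)` returning one value per node (recycled if scalar).
#' @param pressure `NULL`, or a list with `facets` (F x 3 oriented triangles)
#'   and `p`, a `function(t)` returning the pressure in kPa.
#' @param reaction `NULL`, or a list with `nodes` and `dof` defining the
#'   reaction-force log (mN).
#' @return An object of class `"load_protocol"`.
#' @export
load_protocol <- function(t_end, dirichlet = list(), pressure = NULL,
                          reaction = NULL) {
  stopifnot(t_end > 0)
  structure(list(t_end = t_end, dirichlet = dirichlet, pressure = pressure,
                 reaction = reaction),
            class = "load_protocol")
}

#' Piecewise-linear saw-tooth history
#'
#' Returns a `function(t)` interpolating linearly through the given
#' `(time, value)` break points and holding the end values outside the range.
#'
#' @param times,values Break points.
#' @return A function of `t`.
#' @export
sawtooth <- function(times, values) {
  force(times); force(values)
  function(t) approx(times, values, xout = t, rule = 2)$y
}

#' Extension--inflation--torsion protocol for the tube analysis
#'
#' Two saw-tooth cycles: a physiological cycle with peak pressure 120 mmHg at
#' instant A (t = 0.4) returning to 80 mmHg, and a supra-physiological cycle
#' peaking at 600 mmHg at instant B (t = 1.2), ending at t = 1.6 (instant C).
#' The axial displacement ramps to `uz` (default 8 mm on a 40 mm segment,
#' i.e. axial stretch 1.2) during the physiological rise and is then held;
#' the twist angle follows saw-teeth with peaks `phi_phys` and `phi_supra`.
#' Pressure is applied to the `inner` facet set as a follower load; the
#' intra-cycle ramps are synchronous and piecewise linear.
#'
#' @param mesh A tube mesh from [make_tube_segment()].
#' @param p_peaks_mmHg Pressures at times `c(0, 0.4, 0.8, 1.2, 1.6)`, mmHg.
#' @param uz Axial displacement plateau, mm.
#' @param phi_phys,phi_supra Twist peaks, degrees.
#' @return A [load_protocol()].
#' @export
tube_protocol <- function(mesh, p_peaks_mmHg = c(0, 120, 80, 600, 80),
                          uz = 8, phi_phys = 10, phi_supra = 30) {
  H <- attr(mesh, "spec")$H
  tk <- c(0, 0.4, 0.8, 1.2, 1.6)
  p_fun <- sawtooth(tk, mmHg_to_kPa(p_peaks_mmHg))
  uz_fun <- sawtooth(tk, c(0, uz, uz, uz, uz))
  phi_fun <- sawtooth(tk, c(0, phi_phys, 0, phi_supra, 0))
  top <- mesh$sets$top
  bottom <- mesh$sets$bottom
  twist_val <- function(dof) {
    function(t, X) {
      phi <- phi_fun(t) * pi / 180
      if (dof == 1L) X[, 1] * (cos(phi) - 1) - X[, 2] * sin(phi)
      else           X[, 1] * sin(phi) + X[, 2] * (cos(phi) - 1)
    }
  }
  load_protocol(
    t_end = 1.6,
    dirichlet = list(
      list(nodes = bottom, dof = 1:3, value = function(t, X) 0),
      list(nodes = top, dof = 3L, value = function(t, X) uz_fun(t)),
      list(nodes = top, dof = 1L, value = twist_val(1L)),
      list(nodes = top, dof = 2L, value = twist_val(2L))),
    pressure = list(facets = mesh$facets$inner, p = p_fun),
    reaction = list(nodes = top, dof = 3L))
}

#' Monotone tension protocol for the notched plate
#'
#' Bottom edge held at `u_y = 0` (with one corner pinned in x), top edge
#' driven by a monotonically increasing vertical displacement reaching
#' `u_max` at `t_end`.
#'
#' @param mesh A [make_notched_plate()] mesh.
#' @param u_max Peak applied displacement, mm.
#' @param t_end Pseudo-time at peak (default 1).
#' @return A [load_protocol()].
#' @export
plate_tension_protocol <- function(mesh, u_max, t_end = 1) {
  load_protocol(
    t_end = t_end,
    dirichlet = list(
      list(nodes = mesh$sets$bottom, dof = 2L, value = function(t, X) 0),
      list(nodes = mesh$sets$bottom_left, dof = 1L, value = function(t, X) 0),
      list(nodes = mesh$sets$top, dof = 2L,
           value = function(t, X) u_max * t / t_end)),
    reaction = list(nodes = mesh$sets$top, dof = 2L))
}

## Expand a protocol's Dirichlet list at time t into (dof indices, values).
dirichlet_at <- function(protocol, mesh, t) {
  dim <- mesh$dim
  idx <- integer(0); val <- numeric(0)
  for (con in protocol$dirichlet) {
    X <- mesh$nodes[con$nodes, , drop = FALSE]
    for (dof in con$dof) {
      v <- con$value(t, X)
      if (length(v) == 1L) v <- rep(v, length(con$nodes))
      idx <- c(idx, (con$nodes - 1L) * dim + dof)
      val <- c(val, v)
    }
  }
  keep <- !duplicated(idx)
  list(idx = idx[keep], val = val[keep])
}
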