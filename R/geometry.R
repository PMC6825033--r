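## Programmatic benchmark geometries: single-edge-notched plate (plane
## strain) and multi-layer aortic tube segment with an initial tear.

#' Single-edge-notched plate mesh
#'
#' Structured plane-strain quadrilateral mesh of a square plate with an edge
#' notch modelled as a geometric slit (duplicated nodes) running from the
#' mid-left edge to the plate centre.  Node sets: `bottom` (u_y = 0), `top`
#' (driven edge), `bottom_left` (x-fixing corner), `notch_tip`.
#'
#' @param side Plate side length, mm.
#' @param notch_len Notch length from the left edge, mm (< `side`).
#' @param h Target element size, mm (snapped so that `side/h` is an even
#'   integer).
#' @param paper_scale If `TRUE`, use the published discretisation density
#'   (about 197 x 197 elements) instead of `h`.
#' @return A [pf_mesh()] with the notch as an internal free surface.
#' @export
make_notched_plate <- function(side = 1, notch_len = side / 2, h = side / 50,
                               paper_scale = FALSE) {
  if (!(notch_len < side)) stop("notch length must be smaller than the side")
  n <- if (paper_scale) 197L else max(2L, round(side / h))
  if (n %% 2L == 1L) n <- n + 1L   # notch line must be a node row
  nx <- ny <- n
  hx <- side / nx
  xs <- seq(0, side, length.out = nx + 1L)
  ys <- seq(0, side, length.out = ny + 1L)
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i      # i = 1..nx+1, j = 1..ny+1
  nodes <- cbind(rep(xs, ny + 1L), rep(ys, each = nx + 1L))

  ## duplicate the notch-line nodes (y = side/2, x < notch_len): lower copy is
  ## the original row, upper copy is appended; tip node stays shared.
  jmid <- ny %/% 2L + 1L
  itip <- which.min(abs(xs - notch_len))              # tip column index
  dup_i <- seq_len(itip - 1L)                          # strictly left of tip
  dup_orig <- nid(dup_i, jmid)
  dup_new <- nrow(nodes) + seq_along(dup_i)
  nodes <- rbind(nodes, nodes[dup_orig, , drop = FALSE])
  upper_of <- seq_len(nrow(nodes))                     # identity map
  upper_of[dup_orig] <- dup_new

  elems <- matrix(0L, nx * ny, 4L)
  e <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      e <- e + 1L
      n1 <- nid(i, j); n2 <- nid(i + 1L, j)
      n3 <- nid(i + 1L, j + 1L); n4 <- nid(i, j + 1L)
      if (j >= jmid) {                                 # row at/above the slit
        if (j == jmid) { n1 <- upper_of[n1]; n2 <- upper_of[n2] }
      }
      elems[e, ] <- c(n1, n2, n3, n4)
    }
  }
  sets <- list(bottom = as.integer(nid(seq_len(nx + 1L), 1L)),
               top = as.integer(nid(seq_len(nx + 1L), ny + 1L)),
               bottom_left = nid(1L, 1L),
               notch_tip = nid(itip, jmid))
  m <- pf_mesh(nodes, elems, etype = "quad4", sets = sets)
  attr(m, "spec") <- list(side = side, notch_len = notch_len, h = hx)
  m
}

#' Multi-layer aortic tube segment with an initial tear
#'
#' Idealised cylindrical segment of an ascending aorta: six concentric layers
#' (four medial sub-layers of thickness `t_med`, two adventitial sub-layers of
#' thickness `t_adv`), meshed with four-node tetrahedra via a parity-flipped
#' five-tet split of a structured hex grid (which guarantees conforming
#' faces).  An initial tear of circumferential extent `beta` (arc length
#' `pi * Ri * beta / 180`), axial width `w` centred at mid-height, reaching
#' radially through the innermost `tear_layers` medial sub-layers, is carved
#' out as a meshed void whose faces are traction free.
#'
#' Region tags 1..4 are media 1..4 (tag `degenerated_layer` is the degenerated
#' sub-layer), 5..6 the adventitia.  Node sets: `bottom` (z = 0, fully fixed),
#' `top` (z = H, extension/twist driven).  Facet set `inner` holds the
#' pressurised inner surface triangles, oriented so the follower load acts
#' outward.
#'
#' @param Ri,Ro Inner and outer radii, mm.
#' @param H Segment length, mm.
#' @param t_med,t_adv Medial / adventitial sub-layer thicknesses, mm.
#' @param n_med,n_adv Number of medial / adventitial sub-layers.
#' @param beta Tear angle, degrees, in (0, 180).
#' @param w Tear axial width, mm.
#' @param tear_layers Number of innermost medial sub-layers the tear crosses
#'   (at most 3, per the assumed tear shape).
#' @param degenerated_layer Region tag of the degenerated medial sub-layer.
#' @param n_theta Circumferential divisions (even; `beta` and `360 - beta`
#'   should be multiples of the `360/n_theta` cell angle for a crisp tear).
#' @param radial_subdiv Radial cells per physical layer (>= 1); refinement for
#'   convergence studies, region tags still follow the physical layers.
#' @param z_levels Axial node positions; the default refines around the tear
#'   so its 2 mm width is resolved. Must contain `H/2 - w/2` and `H/2 + w/2`.
#' @return A [pf_mesh()] with attribute `frame_type = "cylindrical"`.
#' @export
make_tube_segment <- function(Ri = 15, Ro = 17.5, H = 40,
                              t_med = 0.375, t_adv = 0.5,
                              n_med = 4L, n_adv = 2L,
                              beta = 30, w = 2, tear_layers = 3L,
                              degenerated_layer = 3L,
                              n_theta = 36L,
                              z_levels = NULL,
                              radial_subdiv = 1L) {
  if (!(beta > 0 && beta < 180)) stop("tear angle `beta` must lie in (0, 180) degrees")
  if (tear_layers > 3L) stop("the tear spans at most 3 medial sub-layers")
  thick <- c(rep(t_med, n_med), rep(t_adv, n_adv))
  if (abs(sum(thick) - (Ro - Ri)) > 1e-9)
    stop("layer thicknesses must add up to the wall thickness Ro - Ri = ", Ro - Ri)
  if (n_theta %% 2L != 0L) stop("`n_theta` must be even (parity tet split)")
  radial_subdiv <- as.integer(radial_subdiv)
  stopifnot(radial_subdiv >= 1L)
  thick_sub <- rep(thick / radial_subdiv, each = radial_subdiv)
  layer_of_cell <- rep(seq_along(thick), each = radial_subdiv)
  radii <- Ri + cumsum(c(0, thick_sub))
  nr <- length(radii)                     # radial node surfaces
  if (is.null(z_levels)) {
    zmid <- H / 2
    z_levels <- sort(unique(c(0, H * c(0.125, 0.25, 0.35, 0.45),
                              zmid - w / 2, zmid + w / 2,
                              H - H * c(0.125, 0.25, 0.35, 0.45), H)))
  }
  zt <- sort(unique(z_levels))
  if (!all(abs(range(zt) - c(0, H)) < 1e-9))
    stop("`z_levels` must span [0, H]")
  nzl <- length(zt)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  nid <- function(it, iz, ir)             # 1-based indices
    (ir - 1L) * n_theta * nzl + (iz - 1L) * n_theta + it
  nodes <- matrix(0, n_theta * nzl * nr, 3)
  for (ir in seq_len(nr)) for (iz in seq_len(nzl)) {
    idx <- nid(seq_len(n_theta), iz, ir)
    nodes[idx, ] <- cbind(radii[ir] * cos(th), radii[ir] * sin(th), zt[iz])
  }

  ## tear extent (centred at theta = 0, z = H/2)
  dth <- 2 * pi / n_theta
  half_b <- beta / 2 * pi / 180
  zmid <- H / 2
  in_tear <- function(tc, zc, cell_r) {
    layer <- layer_of_cell[cell_r]
    layer <= tear_layers &&
      (abs(atan2(sin(tc), cos(tc))) < half_b - 1e-9) &&
      (zc > zmid - w / 2 + 1e-9 && zc < zmid + w / 2 - 1e-9)
  }

  ## five-tet split with parity flip for conformity
  tets_a <- rbind(c(1, 2, 4, 5), c(2, 3, 4, 7), c(2, 5, 6, 7),
                  c(4, 5, 7, 8), c(2, 4, 5, 7))
  tets_b <- rbind(c(1, 2, 3, 6), c(1, 3, 4, 8), c(1, 5, 6, 8),
                  c(3, 6, 7, 8), c(1, 3, 6, 8))

  elems <- vector("list", (nr - 1L) * (nzl - 1L) * n_theta)
  region <- integer(0)
  e <- 0L
  keep_regions <- integer(length(elems))
  for (ir in seq_len(nr - 1L)) {
    for (iz in seq_len(nzl - 1L)) {
      for (it in seq_len(n_theta)) {
        it2 <- if (it == n_theta) 1L else it + 1L
        tc <- th[it] + dth / 2
        zc <- (zt[iz] + zt[iz + 1L]) / 2
        if (in_tear(tc, zc, ir)) next
        corners <- c(nid(it,  iz,     ir),  nid(it2, iz,     ir),
                     nid(it2, iz + 1L, ir), nid(it,  iz + 1L, ir),
                     nid(it,  iz,     ir + 1L), nid(it2, iz,     ir + 1L),
                     nid(it2, iz + 1L, ir + 1L), nid(it, iz + 1L, ir + 1L))
        pat <- if ((it + iz + ir) %% 2L == 0L) tets_a else tets_b
        e <- e + 1L
        elems[[e]] <- matrix(corners[pat], 5L, 4L)
        keep_regions[e] <- layer_of_cell[ir]
      }
    }
  }
  elems <- do.call(rbind, elems[seq_len(e)])
  region <- rep(keep_regions[seq_len(e)], each = 5L)

  ## drop unused nodes (tear void interior), remap
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes2 <- nodes[used, , drop = FALSE]
  elems2 <- matrix(remap[elems], ncol = 4L)

  ## fix tet orientation (positive volume)
  v <- pf_mesh_tet_vol(nodes2, elems2)
  flip <- v < 0
  if (any(flip)) elems2[flip, c(3, 4)] <- elems2[flip, c(4, 3)]

  ## node sets
  zc <- nodes2[, 3]
  sets <- list(bottom = which(abs(zc) < 1e-9),
               top = which(abs(zc - H) < 1e-9))

  ## inner pressurised surface: faces of innermost-layer cells at r = Ri,
  ## excluding cells removed by the tear; oriented outward (away from axis)
  tris <- list(); k <- 0L
  for (iz in seq_len(nzl - 1L)) {
    for (it in seq_len(n_theta)) {
      it2 <- if (it == n_theta) 1L else it + 1L
      tc <- th[it] + dth / 2
      zc2 <- (zt[iz] + zt[iz + 1L]) / 2
      if (in_tear(tc, zc2, 1L)) next
      q <- c(nid(it, iz, 1L), nid(it2, iz, 1L),
             nid(it2, iz + 1L, 1L), nid(it, iz + 1L, 1L))
      ## split consistently with the hex parity split (face 1-2-3-4)
      if ((it + iz + 1L) %% 2L == 0L) {
        t1 <- q[c(1, 2, 4)]; t2 <- q[c(2, 3, 4)]
      } else {
        t1 <- q[c(1, 2, 3)]; t2 <- q[c(1, 3, 4)]
      }
      k <- k + 1L; tris[[k]] <- rbind(t1, t2)
    }
  }
  tris <- matrix(remap[do.call(rbind, tris)], ncol = 3L)
  ## orient so (x2-x1) x (x3-x1) points outward (radially away from axis)
  e21 <- nodes2[tris[, 2], ] - nodes2[tris[, 1], ]
  e31 <- nodes2[tris[, 3], ] - nodes2[tris[, 1], ]
  nrm <- cbind(e21[, 2] * e31[, 3] - e21[, 3] * e31[, 2],
               e21[, 3] * e31[, 1] - e21[, 1] * e31[, 3],
               e21[, 1] * e31[, 2] - e21[, 2] * e31[, 1])
  cent3 <- (nodes2[tris[, 1], ] + nodes2[tris[, 2], ] + nodes2[tris[, 3], ]) / 3
  outward <- rowSums(nrm[, 1:2, drop = FALSE] * cent3[, 1:2, drop = FALSE])
  swap <- outward < 0
  tris[swap, c(2, 3)] <- tris[swap, c(3, 2)]

  m <- pf_mesh(nodes2, elems2, etype = "tet4", region = region,
               sets = sets, facets = list(inner = tris))
  attr(m, "frame_type") <- "cylindrical"
  attr(m, "spec") <- list(Ri = Ri, Ro = Ro, H = H, t_med = t_med, t_adv = t_adv,
                          n_med = n_med, n_adv = n_adv, beta = beta, w = w,
                          tear_layers = tear_layers,
                          degenerated_layer = degenerated_layer,
                          tear_arc_length = pi * Ri * beta / 180,
                          radii = radii, z_levels = zt, n_theta = n_theta)
  m
}

## signed tet volumes without constructing a pf_mesh (used during build)
pf_mesh_tet_vol <- function(nodes, elems) {
  a <- nodes[elems[, 2], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 3], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  c_ <- nodes[elems[, 4], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Default layer material table for the tube analysis
#'
#' Builds the region-tag keyed table consumed by [assign_layers()] from the
#' per-layer constants of [aorta_layer_table()]: healthy media on the medial
#' sub-layers except the degenerated one, adventitia on the outer two layers.
#' The bulk modulus defaults to `3 * mu` per layer; `l` is the tube length
#' scale (0.1875 mm).
#'
#' @param mesh A tube mesh from [make_tube_segment()].
#' @param l Phase-field length scale, mm.
#' @param eta Artificial viscosity, kPa s.
#' @return A named list keyed by region tag.
#' @export
tube_layer_materials <- function(mesh, l = 0.1875, eta = 0) {
  spec <- attr(mesh, "spec")
  tab <- aorta_layer_table()
  row_of <- function(role) tab[tab$layer == role, ]
  entry <- function(role) {
    r <- row_of(role)
    list(material = material_params(mu = r$mu, k1 = r$k1, k2 = r$k2,
                                    alpha = r$alpha),
         phase_field = phase_field_params(l = l,
                                          gc_iso_over_l = r$gc_iso_over_l,
                                          gc_ani_over_l = r$gc_ani_over_l,
                                          omega_M = r$omega_M,
                                          omega_Mp = r$omega_M,
                                          eta = eta))
  }
  tags <- sort(unique(mesh$region))
  out <- list()
  for (tg in tags) {
    role <- if (tg == spec$degenerated_layer) "degenerated_media"
            else if (tg <= spec$n_med) "healthy_media" else "adventitia"
    out[[as.character(tg)]] <- entry(role)
  }
  out
}
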