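# Shared fixtures: random deformations/rotations, small meshes with assigned
# materials, tube boundary conditions.

random_F <- function(scale = 0.2) {
  repeat {
    F <- diag(3) + scale * matrix(rnorm(9), 3)
    if (det(F) > 0.3) return(F)
  }
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

default_mat <- function() material_params(mu = 2, k1 = 3, k2 = 1.5, alpha = 40)
default_pf <- function(...) {
  args <- utils::modifyList(
    list(l = 0.1, gc_iso_over_l = 6, gc_ani_over_l = 18,
         omega_M = 5, omega_Mp = 2),
    list(...))
  do.call(phase_field_params, args)
}
default_frame <- function() fiber_frame_from_angle(40)

# thin horizontal strip of nx quadrilaterals on [0, len] x [0, len/nx]
strip_mesh <- function(nx, len = 1) {
  xs <- seq(0, len, length.out = nx + 1)
  nodes <- as.matrix(expand.grid(xs, c(0, len / nx)))
  nid <- function(i, j) (j - 1) * (nx + 1) + i
  elems <- t(vapply(seq_len(nx), function(i)
    as.integer(c(nid(i, 1), nid(i + 1, 1), nid(i + 1, 2), nid(i, 2))),
    integer(4)))
  pf_mesh(nodes, elems, etype = "quad4")
}

assign_uniform <- function(mesh, mat = default_mat(), pf = default_pf(),
                           frame = default_frame()) {
  tags <- sort(unique(mesh$region))
  assign_layers(mesh, stats::setNames(
    lapply(tags, function(tg) list(material = mat, phase_field = pf,
                                   frame = frame)),
    as.character(tags)))
}

# square nx x nx plate (no notch), bottom fixed in y, pulled at the top
square_plate <- function(nx, side = 1) {
  xs <- seq(0, side, length.out = nx + 1)
  nodes <- as.matrix(expand.grid(xs, xs))
  nid <- function(i, j) (j - 1) * (nx + 1) + i
  elems <- do.call(rbind, lapply(seq_len(nx), function(j)
    t(vapply(seq_len(nx), function(i)
      as.integer(c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1),
                   nid(i, j + 1))), integer(4)))))
  pf_mesh(nodes, elems, etype = "quad4",
          sets = list(bottom = which(nodes[, 2] == 0),
                      top = which(nodes[, 2] == side),
                      bottom_left = which(nodes[, 1] == 0 & nodes[, 2] == 0)))
}

# uniaxial plane-strain tension protocol for a square plate
plate_pull <- function(mesh, u_max, t_end = 1) {
  load_protocol(
    t_end = t_end,
    dirichlet = list(
      list(nodes = mesh$sets$bottom, dof = 2L, value = function(t, X) 0),
      list(nodes = mesh$sets$bottom_left, dof = 1L, value = function(t, X) 0),
      list(nodes = mesh$sets$top, dof = 2L,
           value = function(t, X) u_max * t / t_end)),
    reaction = list(nodes = mesh$sets$top, dof = 2L))
}

# short tear-free tube with generalized plane-strain BCs for inflation tests
inflation_tube <- function(n_theta = 32, radial_subdiv = 1, H = 5,
                           mu = 10, kappa = 30) {
  mesh <- make_tube_segment(H = H, beta = 1e-3, w = 1e-3, n_theta = n_theta,
                            z_levels = seq(0, H, length.out = 3),
                            radial_subdiv = radial_subdiv)
  mat <- material_params(mu = mu, k1 = 1e-8, k2 = 1, alpha = 44.71,
                         kappa = kappa)
  pf <- phase_field_params(l = 0.1875, gc_iso_over_l = 1e6,
                           gc_ani_over_l = 1e6)
  mesh <- assign_uniform(mesh, mat, pf, frame = NULL)
  nd <- mesh$nodes
  pin <- function(ang, dof) {
    cand <- which(abs(atan2(nd[, 2], nd[, 1]) - ang) < 1e-6)
    (cand - 1L) * 3L + dof
  }
  idx <- unique(c((which(abs(nd[, 3]) < 1e-9) - 1L) * 3L + 3L,
                  (which(abs(nd[, 3] - H) < 1e-9) - 1L) * 3L + 3L,
                  pin(0, 2L), pin(pi, 2L), pin(pi / 2, 1L), pin(-pi / 2, 1L)))
  list(mesh = mesh, bc = list(idx = idx, val = rep(0, length(idx))),
       mu = mu, kappa = kappa)
}
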