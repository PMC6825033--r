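## Staggered (one-pass operator-splitting) finite element solver for the
## coupled deformation / crack phase-field problem.

#' Solver settings
#'
#' @param dt Initial pseudo-time increment.
#' @param dt_min Smallest increment allowed by step cutting; on Newton failure
#'   the increment is halved until `dt_min`, then the run stops at the last
#'   converged state.
#' @param newton_rtol,newton_atol Relative/absolute force-residual tolerances.
#' @param max_iter Newton iteration cap per step.
#' @param resid_stiff Residual stiffness factor added to the degradation
#'   functions inside the solver so fully broken elements keep an invertible
#'   tangent (the exported constitutive functions use the exact `g`).
#' @param tension_only Tension-only fibre switch (see [psi0_ani()]).
#' @param degrade_volumetric If `FALSE`, the volumetric stiffness is excluded
#'   from degradation inside the solver (the failure criterion still uses the
#'   full effective energy): a stabilisation that prevents fully broken
#'   elements from inverting under compressive transmural stress.
#' @param dt_grow Factor by which the increment recovers after a converged
#'   step, capped at the initial `dt`.
#' @return An object of class `"solver_settings"`.
#' @export
solver_settings <- function(dt = 1e-2, dt_min = 1e-4, newton_rtol = 1e-8,
                            newton_atol = 1e-10, max_iter = 25L,
                            resid_stiff = 1e-6, tension_only = TRUE,
                            degrade_volumetric = TRUE, dt_grow = 1.5) {
  stopifnot(dt >= dt_min, dt_min > 0)
  structure(list(dt = dt, dt_min = dt_min, newton_rtol = newton_rtol,
                 newton_atol = newton_atol, max_iter = as.integer(max_iter),
                 resid_stiff = resid_stiff, tension_only = tension_only,
                 degrade_volumetric = degrade_volumetric, dt_grow = dt_grow),
            class = "solver_settings")
}

etype_code <- function(mesh) if (mesh$etype == "quad4") 0L else 1L

n_qp <- function(mesh) nrow(mesh$elems) * if (mesh$etype == "quad4") 4L else 1L

#' Assemble the mechanical residual and tangent
#'
#' Galerkin residual of the balance of linear momentum at frozen phase field
#' `d` (one-pass splitting), with the consistent tangent, the effective
#' energies per quadrature point and per-element mean Cauchy stresses.
#' Optionally adds a follower pressure (with its load-stiffness term) on an
#' oriented facet set.
#'
#' @param mesh A [pf_mesh()] with materials assigned.
#' @param u Displacement matrix (N x dim).
#' @param d Nodal phase field (length N).
#' @param settings [solver_settings()].
#' @param pressure Optional list `list(facets, p)` with `p` in kPa.
#' @return List with `R` (out-of-balance force, internal minus external), `K`
#'   (sparse tangent), `psi_iso`, `psi_ani` (per quadrature point), `cauchy`
#'   (E x 6), `f_ext`.
#' @export
assemble_mechanics <- function(mesh, u, d, settings = solver_settings(),
                               pressure = NULL) {
  fm <- flatten_materials(mesh)
  out <- .cpp_assemble_mechanics(mesh$nodes, mesh$elems - 1L, u, d,
                                 fm$mat_id0, fm$mats, mesh$fibM, mesh$fibMp,
                                 settings$tension_only, settings$resid_stiff,
                                 isTRUE(settings$degrade_volumetric),
                                 etype_code(mesh))
  if (!out$ok)
    stop("mesh error: non-positive Jacobian or invalid state in element ",
         out$bad_elem, call. = FALSE)
  ndof <- nrow(mesh$nodes) * mesh$dim
  K <- Matrix::sparseMatrix(i = out$Ki, j = out$Kj, x = as.numeric(out$Kx),
                            dims = c(ndof, ndof))
  R <- as.numeric(out$R)
  f_ext <- numeric(ndof)
  if (!is.null(pressure) && length(pressure$facets) && pressure$p != 0) {
    pl <- .cpp_pressure_load(mesh$nodes + u, pressure$facets - 1L, pressure$p)
    f_ext <- as.numeric(pl$f)
    R <- R - f_ext
    K <- K - Matrix::sparseMatrix(i = pl$Ki, j = pl$Kj, x = as.numeric(pl$Kx),
                                  dims = c(ndof, ndof))
  }
  list(R = R, K = K, psi_iso = as.numeric(out$psi_iso),
       psi_ani = as.numeric(out$psi_ani), cauchy = out$cauchy, f_ext = f_ext)
}

#' Newton solve of the mechanical sub-problem
#'
#' Full Newton iteration on the displacement field at frozen phase field,
#' with Dirichlet values imposed by elimination.  Convergence is declared
#' when the free-dof residual norm falls below
#' `max(newton_atol * (1 + |f_ext|), newton_rtol * r0)`.  Divergence is
#' reported (not raised) so the caller can cut the time step.
#'
#' @param mesh,d,settings See [assemble_mechanics()].
#' @param u Start guess (N x dim), typically the previous converged state.
#' @param bc List `list(idx, val)` of constrained global dofs (1-based,
#'   `(node-1)*dim + dof`) and their values.
#' @param pressure Optional follower pressure, as in [assemble_mechanics()].
#' @return List with `u`, `converged`, `iterations`, `res_norms`, and the
#'   last assembly (`asm`).
#' @export
newton_solve_mechanics <- function(mesh, u, d, bc, settings = solver_settings(),
                                   pressure = NULL) {
  dim <- mesh$dim
  ndof <- nrow(mesh$nodes) * dim
  free <- setdiff(seq_len(ndof), bc$idx)
  ut <- t(u)                       # dof-major view
  ut[bc$idx] <- bc$val
  u <- t(ut)
  res_norms <- numeric(0)
  asm <- NULL
  tol <- NA_real_
  for (it in seq_len(settings$max_iter)) {
    asm <- tryCatch(assemble_mechanics(mesh, u, d, settings, pressure),
                    error = function(e) e)
    if (inherits(asm, "error"))
      return(list(u = u, converged = FALSE, iterations = it - 1L,
                  res_norms = res_norms, asm = NULL, reason = conditionMessage(asm)))
    r <- asm$R[free]
    rn <- sqrt(sum(r^2))
    res_norms <- c(res_norms, rn)
    if (it == 1L)
      tol <- max(settings$newton_atol * (1 + sqrt(sum(asm$f_ext^2))),
                 settings$newton_rtol * max(rn, sqrt(sum(asm$R^2)), 1e-300))
    if (!is.finite(rn) || rn > 1e8 * (1 + res_norms[1]))
      return(list(u = u, converged = FALSE, iterations = it,
                  res_norms = res_norms, asm = asm, reason = "divergence"))
    if (rn <= tol)
      return(list(u = u, converged = TRUE, iterations = it - 1L,
                  res_norms = res_norms, asm = asm))
    du <- solve_tangent(asm$K[free, free, drop = FALSE], r)
    if (is.null(du) || !all(is.finite(du)))
      return(list(u = u, converged = FALSE, iterations = it,
                  res_norms = res_norms, asm = asm, reason = "singular tangent"))
    ut <- t(u)
    ut[free] <- ut[free] - du
    u <- t(ut)
  }
  list(u = u, converged = FALSE, iterations = settings$max_iter,
       res_norms = res_norms, asm = asm, reason = "max iterations")
}

#' One linear solve of the phase-field evolution equation
#'
#' Backward-Euler weak form of the crack evolution equation
#' `eta d_t d = (1 - d) H - [d - 1/2 Div(L grad d)]` with the natural
#' boundary condition `L grad d . N = 0`: a single symmetric positive
#' definite solve for the nodal phase field, followed by the irreversibility
#' projection `d := min(max(d, d_n), 1)`.
#'
#' @param mesh A [pf_mesh()] with materials assigned.
#' @param H History field per quadrature point.
#' @param d_n Previous nodal phase field.
#' @param dt Time increment (only used when `eta > 0`).
#' @param project If `FALSE`, the raw linear-solve result is returned
#'   (no irreversibility clamp).
#' @return Nodal phase field (length N).
#' @export
solve_phasefield <- function(mesh, H, d_n, dt = 1, project = TRUE) {
  fm <- flatten_materials(mesh)
  eta_over_dt <- if (fm$eta > 0) fm$eta / dt else 0
  sys <- .cpp_assemble_phasefield(mesh$nodes, mesh$elems - 1L, H, d_n,
                                  fm$mat_id0, fm$pf_mats, mesh$fibM, mesh$fibMp,
                                  eta_over_dt, 0.5, etype_code(mesh))
  A <- Matrix::sparseMatrix(i = sys$Ai, j = sys$Aj, x = as.numeric(sys$Ax),
                            dims = rep(nrow(mesh$nodes), 2))
  d <- as.numeric(Matrix::solve(A, as.numeric(sys$b)))
  if (project) d <- pmin(pmax(d, d_n), 1)
  d
}

#' Regularised profile of a prescribed sharp crack
#'
#' Solves the geometric Euler--Lagrange equation of the regularised crack
#' surface, `d - Div(L grad d) = 0` with `d = 1` on the prescribed crack set
#' and natural boundary conditions elsewhere.  In 1-D with an isotropic
#' structure tensor the solution is the exponential optimal profile
#' `exp(-x / l)`.
#'
#' @param mesh A [pf_mesh()] with materials assigned.
#' @param crack_nodes Node indices where `d = 1` is prescribed.
#' @return Nodal phase field.
#' @export
solve_crack_profile <- function(mesh, crack_nodes) {
  N <- nrow(mesh$nodes)
  fm <- flatten_materials(mesh)
  sys <- .cpp_assemble_phasefield(mesh$nodes, mesh$elems - 1L,
                                  numeric(n_qp(mesh)), numeric(N),
                                  fm$mat_id0, fm$pf_mats, mesh$fibM, mesh$fibMp,
                                  0, 1.0, etype_code(mesh))
  A <- Matrix::sparseMatrix(i = sys$Ai, j = sys$Aj, x = as.numeric(sys$Ax),
                            dims = c(N, N))
  free <- setdiff(seq_len(N), crack_nodes)
  d <- numeric(N)
  d[crack_nodes] <- 1
  rhs <- -as.numeric(A[free, crack_nodes, drop = FALSE] %*% d[crack_nodes])
  d[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], rhs))
  d
}

#' Reaction force on a constrained node set
#'
#' Sum of internal-force contributions at the given nodes along one dof
#' direction, evaluated from a converged assembly.
#'
#' @param asm Result of [assemble_mechanics()] at the converged state.
#' @param nodes Node indices of the constrained set.
#' @param dof Direction (1 = x, 2 = y, 3 = z).
#' @param dim Spatial dimension of the mesh.
#' @return Reaction force, mN.
#' @export
reaction_force <- function(asm, nodes, dof, dim) {
  sum(asm$R[(nodes - 1L) * dim + dof] + asm$f_ext[(nodes - 1L) * dim + dof])
}

#' Run the one-pass staggered simulation
#'
#' Advances the coupled problem over pseudo-time with the one-pass
#' operator-splitting algorithm: per increment, (1) Newton solve of the
#' mechanics at frozen phase field, (2) update of the irreversible history
#' field from the effective energies at the quadrature points, (3) one linear
#' phase-field solve.  Newton failure triggers halving of the increment down
#' to `dt_min`; afterwards the run returns the last converged state with a
#' diagnostic.  The run is deterministic: no randomness enters the solver.
#'
#' A warning is issued when the length scale fails the resolution rule
#' `l > 2 h`.
#'
#' @param mesh A [pf_mesh()] with materials assigned.
#' @param protocol A [load_protocol()].
#' @param settings [solver_settings()].
#' @param snapshot_times Times at which `u`, `d` and Cauchy stresses are
#'   stored (the stepper lands on them exactly).
#' @param stop_when Optional `function(state)` evaluated after every converged
#'   step on `list(t, u, d, H, mesh)`; returning `TRUE` ends the run early
#'   (e.g. once a crack has traversed the specimen).
#' @param out_dir If non-`NULL`, a per-step CSV log and VTK time series are
#'   written there.
#' @param verbose Print per-step progress.
#' @return List with fields `u`, `d`, `H`, `log` (tibble with time, dt,
#'   Newton iterations, residual norm, max d, reaction force), `snapshots`,
#'   `completed`, `reason`.
#' @export
pf_simulate <- function(mesh, protocol, settings = solver_settings(),
                        snapshot_times = NULL, out_dir = NULL,
                        stop_when = NULL, verbose = FALSE) {
  fm <- flatten_materials(mesh)
  lmin <- min(fm$pf_mats[, "l"])
  h <- mesh_h(mesh)
  if (lmin <= 2 * h)
    warning(sprintf(paste0("length scale l = %.4g does not satisfy l > 2h ",
                           "(h = %.4g); the diffusive crack surface is ",
                           "under-resolved"), lmin, h))
  N <- nrow(mesh$nodes); dim <- mesh$dim
  u <- matrix(0, N, dim)
  d <- numeric(N)
  H <- numeric(n_qp(mesh))
  t_now <- 0
  dt <- settings$dt
  marks <- sort(unique(c(snapshot_times, protocol$t_end)))
  snapshots <- list()
  log <- list()
  step <- 0L
  completed <- TRUE
  reason <- "end of protocol"
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  while (t_now < protocol$t_end - 1e-12) {
    t_try <- min(t_now + dt, marks[marks > t_now + 1e-12][1])
    bc <- dirichlet_at(protocol, mesh, t_try)
    pr <- if (!is.null(protocol$pressure))
      list(facets = protocol$pressure$facets, p = protocol$pressure$p(t_try))
    sol <- newton_solve_mechanics(mesh, u, d, bc, settings, pr)
    if (!sol$converged) {
      if (dt / 2 >= settings$dt_min) {
        dt <- dt / 2
        if (verbose) message(sprintf("t = %.4g: step cut, dt -> %.3g", t_try, dt))
        next
      }
      completed <- FALSE
      reason <- sprintf("step-cut exhaustion at t = %.6g (%s)", t_try,
                        sol$reason %||% "no convergence")
      break
    }
    u <- sol$u
    ## history update from effective energies (ALGO_M done, now ALGO_C)
    Hbar <- sol$asm$psi_iso / fm$gc_iso[qp_elem(mesh)] +
            sol$asm$psi_ani / fm$gc_ani[qp_elem(mesh)]
    H <- pmax(H, pmax(Hbar - 1, 0))
    d <- solve_phasefield(mesh, H, d, dt = t_try - t_now)
    t_now <- t_try
    step <- step + 1L
    rf <- if (!is.null(protocol$reaction))
      reaction_force(sol$asm, protocol$reaction$nodes, protocol$reaction$dof, dim)
    else NA_real_
    log[[step]] <- c(time = t_now, dt = dt, iters = sol$iterations,
                     res = utils::tail(sol$res_norms, 1), max_d = max(d),
                     reaction = rf)
    if (verbose)
      message(sprintf("t = %.4g  iters = %d  max d = %.3f  reaction = %.4g",
                      t_now, sol$iterations, max(d), rf))
    if (any(abs(marks - t_now) < 1e-12) &&
        (is.null(snapshot_times) || any(abs(snapshot_times - t_now) < 1e-9) ||
         abs(t_now - protocol$t_end) < 1e-12)) {
      snapshots[[sprintf("t=%g", t_now)]] <-
        list(t = t_now, u = u, d = d, cauchy = sol$asm$cauchy)
      if (!is.null(out_dir))
        write_vtu(mesh, file.path(out_dir, sprintf("state_%04d.vtu", step)),
                  point_data = list(d = d, u = u),
                  cell_data = list(layer = mesh$region))
    }
    if (!is.null(stop_when) &&
        isTRUE(stop_when(list(t = t_now, u = u, d = d, H = H, mesh = mesh)))) {
      reason <- sprintf("stop criterion met at t = %.6g", t_now)
      break
    }
    dt <- min(dt * settings$dt_grow, settings$dt)
  }
  log <- if (length(log)) tibble::as_tibble(do.call(rbind, log)) else
    tibble::tibble(time = numeric(0), dt = numeric(0), iters = numeric(0),
                   res = numeric(0), max_d = numeric(0), reaction = numeric(0))
  if (!is.null(out_dir))
    utils::write.csv(log, file.path(out_dir, "steps.csv"), row.names = FALSE)
  list(u = u, d = d, H = H, log = log, snapshots = snapshots,
       completed = completed, reason = reason, mesh = mesh)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Linear solve of the Newton system.  The mechanics tangent is symmetric up
## to the follower-load stiffness (relative asymmetry ~1e-4), so a sparse
## Cholesky of the symmetrised matrix is attempted first (CHOLMOD, about 20x
## faster here than sparse LU); an indefinite tangent falls back to LU.
solve_tangent <- function(K, b) {
  du <- tryCatch({
    Ks <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
    ch <- Matrix::Cholesky(Ks, LDL = FALSE, perm = TRUE)
    as.numeric(Matrix::solve(ch, b))
  }, error = function(e) NULL)
  if (is.null(du))
    du <- tryCatch(as.numeric(Matrix::solve(K, b)), error = function(e) NULL)
  if (!is.null(du) && !all(is.finite(du))) du <- NULL
  du
}

## quadrature point -> element index
qp_elem <- function(mesh) {
  nq <- if (mesh$etype == "quad4") 4L else 1L
  rep(seq_len(nrow(mesh$elems)), each = nq)
}

#' Crack angle from a thresholded phase field
#'
#' Principal direction (total least squares via PCA) of the element centroids
#' whose mean phase field exceeds `threshold`, measured in degrees from the
#' horizontal axis and folded into [0, 90].  Centroids inside the filter
#' region (e.g. the initial notch) are excluded.  If no element exceeds the
#' threshold, `NA` is returned (no crack: distinct from an angle of 0).
#'
#' @param mesh A [pf_mesh()].
#' @param d Nodal phase field.
#' @param threshold Damage threshold defining the crack zone (default 0.8).
#' @param region Optional `function(xy)` on the centroid matrix returning a
#'   logical filter (e.g. beyond the notch tip).
#' @return Angle in degrees, or `NA_real_` when the thresholded set is empty.
#' @export
crack_angle <- function(mesh, d, threshold = 0.8, region = NULL) {
  cent <- element_centroids(mesh)
  dg <- rowMeans(matrix(d[mesh$elems], ncol = 4L))
  keep <- dg >= threshold
  if (!is.null(region)) keep <- keep & region(cent)
  if (sum(keep) < 2L) return(NA_real_)
  xy <- cent[keep, 1:2, drop = FALSE]
  v <- prcomp(xy, center = TRUE, scale. = FALSE)$rotation[, 1]
  atan2(abs(v[2]), abs(v[1])) * 180 / pi
}
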