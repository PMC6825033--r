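## Canned studies: parameter fit, single-edge-notch anisotropy sweep, and the
## multi-layer tube dissection demonstration.

#' Run the parameter-identification study
#'
#' Synthesises (or reads) stress-strain curves for the four test modes, runs
#' the nonlinear least-squares identification, and optionally writes the fit
#' result as JSON, the residuals as CSV and the four-panel overlay figure.
#'
#' @param data Optional dataset tibble; if `NULL`, curves are synthesised
#'   from `truth` with `noise_sd`.
#' @param truth Generating parameters for synthesis (default the medial fit).
#' @param noise_sd Gaussian noise, kPa.
#' @param n_per_mode Points per mode for synthesis.
#' @param init Optimiser start; default is a uniformly perturbed truth
#'   (`0.5 x`), exercising genuine recovery.
#' @param seed Seed (noise and multistart).
#' @param out_dir Optional output directory.
#' @return The [fit_parameters()] result.
#' @export
run_fit <- function(data = NULL, truth = medial_fit_params(), noise_sd = 0,
                    n_per_mode = 25, init = NULL, seed = 1L, out_dir = NULL) {
  if (is.null(data))
    data <- generate_synthetic_dataset(truth, n_per_mode = n_per_mode,
                                       noise_sd = noise_sd, seed = seed)
  if (is.null(init))
    init <- material_params(mu = 0.5 * truth$mu, k1 = 0.5 * truth$k1,
                            k2 = 0.5 * truth$k2, alpha = 0.5 * truth$alpha)
  fit <- fit_parameters(data, init = init, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(estimates = as.list(fit$estimates), chi2 = fit$chi2,
           r2 = as.list(fit$r2), epsilon = fit$epsilon, q = fit$q,
           n_obs = fit$n_obs, converged = fit$converged),
      file.path(out_dir, "fit.json"), digits = NA, auto_unbox = TRUE)
    resid_tab <- fit$data
    resid_tab$residual <- resid_tab$stress_kPa - resid_tab$fitted
    utils::write.csv(resid_tab, file.path(out_dir, "residuals.csv"),
                     row.names = FALSE)
    write_dataset_csv(fit$data, out_dir)
    ggplot2::ggsave(file.path(out_dir, "fit_overlay.pdf"), autoplot(fit),
                    width = 7, height = 5)
  }
  fit
}

#' Build and assign the single-edge-notch study configuration
#'
#' Plane-strain notched plate with a single fibre family at `alpha` degrees
#' to the horizontal axis and the sensitivity-study constants
#' (`mu = k1 = k2 = 1`, `kappa = 3` kPa, `gc_iso/l = gc_ani/l = 1e-2` kPa,
#' `l = 0.1` mm).
#'
#' @param omega_M Anisotropy parameter.
#' @param n Mesh divisions per side.
#' @param alpha Fibre angle, degrees.
#' @param l Length scale, mm.
#' @param eta Artificial viscosity (continuation aid for large `omega_M`).
#' @return A [pf_mesh()] ready for [pf_simulate()].
#' @export
senp_mesh <- function(omega_M, n = 50, alpha = 45, l = 0.1, eta = 0) {
  mesh <- make_notched_plate(side = 1, notch_len = 0.5, h = 1 / n)
  mat <- material_params(mu = 1, k1 = 1, k2 = 1, alpha = alpha, kappa = 3)
  pf <- phase_field_params(l = l, gc_iso_over_l = 1e-2, gc_ani_over_l = 1e-2,
                           omega_M = omega_M, omega_Mp = 0, eta = eta)
  frame <- fiber_frame_from_angle(alpha, two_families = FALSE)
  assign_layers(mesh, list(`1` = list(material = mat, phase_field = pf,
                                      frame = frame)))
}

#' Anisotropy-parameter sweep on the single-edge-notched plate
#'
#' For each `omega_M`, pulls the notched plate in monotone tension with the
#' one-pass staggered solver and extracts the crack angle (thresholded
#' phase field beyond the notch tip) and the peak reaction force.  Larger
#' `omega_M` steers the crack towards the fibre direction and raises the
#' force needed for fracture; non-convergence at large `omega_M` is reported
#' per entry and the sweep continues.
#'
#' @param omega Vector of anisotropy parameters (each > -1).
#' @param n Mesh divisions per side (elements ~ n^2).
#' @param u_max Peak applied displacement, mm.
#' @param n_steps Number of displacement increments.
#' @param threshold Damage threshold for the crack zone.
#' @param out_dir Optional output directory (per-omega VTK + summary CSV).
#' @param verbose Per-step progress.
#' @return Tibble with `omega_M`, `theta_deg`, `peak_force_mN`, `max_d`,
#'   `completed`.
#' @export
run_senp_sweep <- function(omega = c(0, 1, 10, 500), n = 50, u_max = 0.2,
                           n_steps = 160, threshold = 0.8, out_dir = NULL,
                           verbose = FALSE) {
  if (any(omega <= -1)) stop("anisotropy parameters must be > -1")
  rows <- lapply(omega, function(om) {
    mesh <- senp_mesh(om, n = n)
    protocol <- plate_tension_protocol(mesh, u_max = u_max)
    settings <- solver_settings(dt = 1 / n_steps, dt_min = 1 / n_steps / 64)
    ## end the pull once the crack band has traversed to an outer boundary;
    ## afterwards the broken plate only accumulates spurious bulk damage
    cent <- element_centroids(mesh)
    traversed <- function(state) {
      de <- rowMeans(matrix(state$d[mesh$elems], ncol = 4L))
      any(de >= threshold & (cent[, 1] > 0.95 | cent[, 2] > 0.95 |
                               cent[, 2] < 0.05))
    }
    res <- pf_simulate(mesh, protocol, settings, stop_when = traversed,
                       out_dir = if (!is.null(out_dir))
                         file.path(out_dir, sprintf("omega_%g", om)))
    tip_x <- mesh$nodes[mesh$sets$notch_tip, 1]
    th <- crack_angle(mesh, res$d, threshold = threshold,
                      region = function(xy) xy[, 1] > tip_x + 0.04)
    tibble::tibble(omega_M = om, theta_deg = th,
                   peak_force_mN = if (nrow(res$log)) max(res$log$reaction) else NA_real_,
                   max_d = max(res$d), completed = res$completed)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "senp_summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' Multi-layer tube dissection demonstration
#'
#' Builds the six-layer tube segment with an initial tear of angle `beta`,
#' assigns the per-layer constants, applies the two-cycle
#' extension--inflation--torsion protocol and reports, at the requested
#' instants, the volume fraction of the degenerated medial sub-layer whose
#' phase field exceeds `threshold` (the damage zone), along with stress
#' slices in cylindrical components.
#'
#' @param beta Tear angle, degrees (30 or 60 in the reference setup).
#' @param n_theta,z_levels Mesh resolution controls (see
#'   [make_tube_segment()]).
#' @param dt Initial pseudo-time increment.
#' @param instants Snapshot times (A, B, C by default).
#' @param threshold Damage-zone threshold.
#' @param l Phase-field length scale, mm.
#' @param eta Artificial viscosity.
#' @param resid_stiff Residual stiffness of fully broken elements; the tube
#'   demonstration keeps a slightly larger value than the generic default so
#'   that crushed, fully damaged elements inside the helical damage zone do
#'   not invert under the supra-physiological pressure.
#' @param out_dir Optional output directory (VTK series + CSV log).
#' @param verbose Per-step progress.
#' @return List with `metrics` (tibble: instant, time, damage volume fraction
#'   of the degenerated layer, max d), `result` (the [pf_simulate()] output)
#'   and `mesh`.
#' @export
run_tube_demo <- function(beta = 30, n_theta = 24L, z_levels = NULL, dt = 0.05,
                          instants = c(A = 0.4, B = 1.2, C = 1.6),
                          threshold = 0.8, l = 0.1875, eta = 0,
                          resid_stiff = 1e-3, out_dir = NULL, verbose = FALSE) {
  mesh <- make_tube_segment(beta = beta, n_theta = n_theta, z_levels = z_levels)
  mesh <- assign_layers(mesh, tube_layer_materials(mesh, l = l, eta = eta))
  protocol <- tube_protocol(mesh)
  ## volumetric stiffness kept undegraded: broken medial elements must not
  ## invert under the compressive transmural stress of the 600 mmHg cycle
  settings <- solver_settings(dt = dt, dt_min = 1e-4, resid_stiff = resid_stiff,
                              degrade_volumetric = FALSE)
  res <- suppressWarnings(
    pf_simulate(mesh, protocol, settings, snapshot_times = unname(instants),
                out_dir = out_dir, verbose = verbose))
  deg <- mesh$region == attr(mesh, "spec")$degenerated_layer
  vol <- element_volumes(mesh)
  metrics <- lapply(seq_along(instants), function(i) {
    snap <- res$snapshots[[sprintf("t=%g", unname(instants[i]))]]
    if (is.null(snap))
      return(tibble::tibble(instant = names(instants)[i],
                            time = unname(instants[i]),
                            damage_volume_fraction = NA_real_,
                            max_d = NA_real_))
    delem <- rowMeans(matrix(snap$d[mesh$elems], ncol = 4L))
    tibble::tibble(instant = names(instants)[i], time = snap$t,
                   damage_volume_fraction =
                     sum(vol[deg & delem >= threshold]) / sum(vol[deg]),
                   max_d = max(snap$d))
  })
  metrics <- do.call(rbind, metrics)
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "damage_metrics.csv"),
                     row.names = FALSE)
    last <- res$snapshots[[length(res$snapshots)]]
    if (!is.null(last))
      utils::write.csv(cbind(cylindrical_stress(mesh, last$cauchy),
                             layer = mesh$region),
                       file.path(out_dir, "stress_slices.csv"),
                       row.names = FALSE)
  }
  list(metrics = metrics, result = res, mesh = mesh)
}

#' Read a study configuration file
#'
#' YAML configuration with top-level keys `study` (`fit`, `senp` or `tube`),
#' `seed`, `out_dir` and study-specific overrides mirroring the arguments of
#' [run_fit()], [run_senp_sweep()] and [run_tube_demo()] (material keys
#' mirror the layer-table column names `mu`, `k1`, `k2`, `alpha`,
#' `gc_iso_over_l`, `gc_ani_over_l`, `omega_M`).
#'
#' @param path YAML file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$study) || !cfg$study %in% c("fit", "senp", "tube"))
    stop("config must set `study` to one of: fit, senp, tube")
  cfg
}

#' Execute a study from a configuration list
#'
#' Dispatches to the study runner named in the configuration, writes a
#' resolved copy of the configuration (with the seed) into the output
#' directory for reproducibility, and returns the study result.
#'
#' @param cfg List from [read_run_config()] (or constructed directly).
#' @return The study result object.
#' @export
run_study <- function(cfg) {
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  }
  seed <- cfg$seed %||% 1L
  args <- cfg[setdiff(names(cfg), c("study", "seed", "out_dir"))]
  switch(cfg$study,
    fit = do.call(run_fit, c(args, list(seed = seed, out_dir = out_dir))),
    senp = do.call(run_senp_sweep, c(args, list(out_dir = out_dir))),
    tube = do.call(run_tube_demo, c(args, list(out_dir = out_dir))))
}
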