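## Homogeneous closed-form responses for the four test modes, the chi^2
## objective, nonlinear least-squares identification and the synthetic
## stress-strain data generator.

FIT_MODES <- c("rtheta", "rz", "thetatheta", "zz")

## run `code` under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

fiber_dpsi_vec <- function(I4, p, tension_only = TRUE) {
  E <- I4 - 1
  ## exponent guard: keeps the lateral-stretch root-finder and the optimizer
  ## finite when a search iterate wanders far outside the physical range
  q <- pmin(p$k2 * E^2, 600)
  out <- p$k1 * E * exp(q)
  if (tension_only) out[E <= 0] <- 0
  out
}

## Lateral stretch of incompressible uniaxial extension: for loading along the
## in-plane axis `ax` (1 = circumferential, 2 = axial) solve the traction-free
## condition in the other in-plane direction; the radial direction follows
## from incompressibility and carries no fibre stress (fibres lie in-plane).
uniax_lateral <- function(lambda, p, ax) {
  a <- p$alpha * pi / 180
  c2 <- cos(a)^2; s2 <- sin(a)^2
  w_load <- if (ax == 1L) c2 else s2      # fibre weight on the loading axis
  w_lat <- 1 - w_load
  vapply(lambda, function(lm) {
    g <- function(l2) {
      l3 <- 1 / (lm * l2)
      I4 <- lm^2 * w_load + l2^2 * w_lat
      p$mu * (l2^2 - l3^2) + 4 * fiber_dpsi_vec(I4, p) * l2^2 * w_lat
    }
    uniroot(g, c(1e-3, 1e3), tol = 1e-13)$root
  }, numeric(1))
}

#' Closed-form homogeneous Cauchy stress for one test mode
#'
#' Analytical incompressible response of the HGO model under the four test
#' modes used for parameter identification: uniaxial extension along the
#' circumferential (`"thetatheta"`) or axial (`"zz"`) direction with
#' traction-free lateral faces (Lagrange pressure eliminated, lateral stretch
#' solved numerically), and in-plane simple shear on the radial plane along
#' the circumferential (`"rtheta"`) or axial (`"rz"`) direction.  The two
#' fibre families lie at `+/- alpha` to the circumferential direction in the
#' circumferential--axial plane, so they are not stretched by the in-plane
#' shear modes and the shear response is the neo-Hookean `mu * gamma`.
#'
#' @param mode One of `"rtheta"`, `"rz"`, `"thetatheta"`, `"zz"`.
#' @param x Deformation measure: amount of shear `gamma` (shear modes) or
#'   stretch `lambda` (uniaxial modes).
#' @param p [material_params()].
#' @return Cauchy stress, kPa (same length as `x`).
#' @export
model_stress <- function(mode, x, p) {
  if (!mode %in% FIT_MODES)
    stop("unknown mode '", mode, "'; modes are: ", paste(FIT_MODES, collapse = ", "))
  if (mode %in% c("rtheta", "rz")) {
    if (any(x < 0)) stop("amount of shear must be >= 0")
    return(p$mu * x)
  }
  if (any(x <= 0)) stop("stretch must be > 0")
  a <- p$alpha * pi / 180
  ax <- if (mode == "thetatheta") 1L else 2L
  w_load <- if (ax == 1L) cos(a)^2 else sin(a)^2
  l2 <- uniax_lateral(x, p, ax)
  l3 <- 1 / (x * l2)
  I4 <- x^2 * w_load + l2^2 * (1 - w_load)
  p$mu * (x^2 - l3^2) + 4 * fiber_dpsi_vec(I4, p) * x^2 * w_load
}

#' Sum-of-squares objective over all test modes
#'
#' `chi2 = sum_modes sum_n (sigma_model - sigma_obs)^2` in kPa^2; zero iff the
#' model reproduces every observation.  Modes absent from the data contribute
#' nothing.
#'
#' @param data Tibble with columns `mode`, `deformation`, `stress_kPa` (as
#'   produced by [generate_synthetic_dataset()] or [read_dataset_csv()]).
#' @param p [material_params()] (the `kappa` entry is irrelevant here: the
#'   homogeneous responses are fully incompressible).
#' @return chi-squared, kPa^2.
#' @export
chi2_objective <- function(data, p) {
  stopifnot(nrow(data) > 0)
  bad <- setdiff(unique(data$mode), FIT_MODES)
  if (length(bad))
    stop("unknown mode(s) ", paste(bad, collapse = ", "),
         "; modes are: ", paste(FIT_MODES, collapse = ", "))
  sum(vapply(split(data, data$mode), function(dm) {
    sum((model_stress(dm$mode[1], dm$deformation, p) - dm$stress_kPa)^2)
  }, numeric(1)))
}

fit_residuals <- function(data, p) {
  r <- unlist(lapply(split(data, data$mode), function(dm)
    model_stress(dm$mode[1], dm$deformation, p) - dm$stress_kPa),
    use.names = FALSE)
  ## bound residuals so optimizer excursions into the fibre-exponential
  ## overflow region stay finite
  r[!is.finite(r)] <- 1e100
  r
}

## Root-mean-square goodness of fit: sqrt(chi2 / (N - q)) normalised by the
## sum over modes of the mean observed stress.
rmse_epsilon <- function(data, chi2, q = 4L) {
  n_tot <- nrow(data)
  denom <- sum(vapply(split(data$stress_kPa, data$mode), mean, numeric(1)))
  sqrt(chi2 / (n_tot - q)) / denom
}

#' Identify the elastic constants from stress-strain curves
#'
#' Trust-region Levenberg--Marquardt least squares over
#' `p = (mu, k1, k2, alpha)` minimising [chi2_objective()], with bounds and a
#' deterministic multistart to guard against local minima (best chi-squared
#' wins; ties broken by the smallest `k2`).  Returns the per-mode correlation
#' coefficients `R^2` and the normalised root-mean-square error `epsilon`
#' computed from `sqrt(chi2 / (N - q))` over the summed per-mode mean
#' stresses.
#'
#' @param data Tibble with columns `mode`, `deformation`, `stress_kPa`;
#'   ideally spanning all four modes (a subset triggers a warning).
#' @param init Optional [material_params()] start; when supplied it is used
#'   as the first start of the multistart.
#' @param lower,upper Bounds on `(mu, k1, k2, alpha)`.
#' @param multistart Number of deterministic starts (>= 1).
#' @param seed Seed for the multistart draw (fits are deterministic given
#'   `init`, bounds and `seed`).
#' @return An object of class `"hgo_fit"`: fitted [material_params()], the
#'   estimates, `chi2` (kPa^2), per-mode `r2`, `epsilon`, `q = 4`,
#'   `converged`, and the data with fitted values attached.
#' @export
fit_parameters <- function(data, init = NULL,
                           lower = c(mu = 1e-3, k1 = 0, k2 = 1e-4, alpha = 0.01),
                           upper = c(mu = 1e3, k1 = 1e3, k2 = 1e2, alpha = 89.99),
                           multistart = 5L, seed = 1L) {
  missing_modes <- setdiff(FIT_MODES, unique(data$mode))
  if (length(missing_modes))
    warning("fitting without mode(s): ", paste(missing_modes, collapse = ", "))
  as_p <- function(th) material_params(mu = th[1], k1 = th[2], k2 = th[3],
                                       alpha = th[4])
  resid_fn <- function(th) fit_residuals(data, as_p(th))

  starts <- list()
  if (!is.null(init)) starts[[1]] <- c(init$mu, init$k1, init$k2, init$alpha)
  starts <- c(starts, with_seed(seed, {
    extra <- list()
    while (length(extra) + length(starts) < multistart) {
      extra[[length(extra) + 1L]] <-
        lower + runif(4) * (pmin(upper, c(200, 200, 20, 89)) - lower)
    }
    extra
  }))

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(th0, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2 * (1 - 1e-8) ||
        (abs(chi2 - best$chi2) <= best$chi2 * 1e-8 + 1e-300 &&
         fit$par[3] < best$par[3]))
      best <- list(par = fit$par, chi2 = chi2,
                   converged = fit$info %in% 1:4, info = fit$info)
  }
  if (is.null(best)) stop("all optimizer starts failed")
  if (!best$converged)
    warning("optimizer did not report convergence (info = ", best$info,
            "); best iterate returned")

  p_hat <- as_p(best$par)
  data$fitted <- unsplit(lapply(split(data, data$mode), function(dm)
    model_stress(dm$mode[1], dm$deformation, p_hat)), data$mode)
  r2 <- vapply(split(data, data$mode), function(dm) {
    ss_res <- sum((dm$stress_kPa - dm$fitted)^2)
    ss_tot <- sum((dm$stress_kPa - mean(dm$stress_kPa))^2)
    1 - ss_res / ss_tot
  }, numeric(1))
  structure(list(params = p_hat,
                 estimates = setNames(best$par, c("mu", "k1", "k2", "alpha")),
                 chi2 = best$chi2, r2 = r2,
                 epsilon = rmse_epsilon(data, best$chi2),
                 q = 4L, n_obs = nrow(data), converged = best$converged,
                 data = tibble::as_tibble(data)),
            class = "hgo_fit")
}

#' @method print hgo_fit
#' @export
print.hgo_fit <- function(x, ...) {
  cat("HGO least-squares fit\n")
  cat(sprintf("  mu = %.3f kPa, k1 = %.3f kPa, k2 = %.3f, alpha = %.3f deg\n",
              x$estimates[1], x$estimates[2], x$estimates[3], x$estimates[4]))
  cat(sprintf("  chi2 = %.6g kPa^2, epsilon = %.4g, n = %d\n",
              x$chi2, x$epsilon, x$n_obs))
  cat("  R2:", paste(sprintf("%s = %.4f", names(x$r2), x$r2), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted HGO model
#'
#' @param x An `"hgo_fit"`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`, `unit`).
#' @importFrom generics tidy
#' @export
tidy.hgo_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 unit = c("kPa", "kPa", "1", "deg"))
}

#' One-row fit summary
#'
#' @param x An `"hgo_fit"`.
#' @param ... Unused.
#' @return Tibble with `chi2`, `epsilon`, per-mode `r2_*`, `n_obs`,
#'   `converged`.
#' @importFrom generics glance
#' @export
glance.hgo_fit <- function(x, ...) {
  out <- tibble::tibble(chi2 = x$chi2, epsilon = x$epsilon, n_obs = x$n_obs,
                        converged = x$converged)
  for (m in names(x$r2)) out[[paste0("r2_", m)]] <- unname(x$r2[m])
  out
}

#' Plot data and fitted curves per test mode
#'
#' Four-panel overlay of the observed stresses (points) and the fitted model
#' response (lines) against the deformation measure of each mode.
#'
#' @param object An `"hgo_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.hgo_fit <- function(object, ...) {
  dat <- object$data
  grids <- do.call(rbind, lapply(split(dat, dat$mode), function(dm) {
    xs <- seq(min(dm$deformation), max(dm$deformation), length.out = 80)
    tibble::tibble(mode = dm$mode[1], deformation = xs,
                   stress_kPa = model_stress(dm$mode[1], xs, object$params))
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$deformation, y = .data$stress_kPa)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_line(data = grids, colour = "steelblue") +
    ggplot2::facet_wrap(~mode, scales = "free") +
    ggplot2::labs(x = "amount of shear / stretch", y = "Cauchy stress (kPa)")
}

#' Generate synthetic stress-strain curves from the constitutive model
#'
#' Emulates the four experimental test modes by evaluating the closed-form
#' homogeneous response on regular deformation grids and adding Gaussian
#' noise: shear modes over amounts of shear up to `gamma_max`, uniaxial modes
#' over stretches up to `lambda_max`.
#'
#' @param p Generating [material_params()].
#' @param n_per_mode Points per mode.
#' @param gamma_max Largest amount of shear (default 0.5).
#' @param lambda_max Largest stretch (default 1.2).
#' @param noise_sd Gaussian noise standard deviation, kPa (0 = noiseless).
#' @param seed Seed for the noise (same seed, same dataset).
#' @return Tibble with columns `mode`, `deformation`, `stress_kPa`.
#' @export
generate_synthetic_dataset <- function(p, n_per_mode = 25,
                                       gamma_max = 0.5, lambda_max = 1.2,
                                       noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  out <- with_seed(seed, lapply(FIT_MODES, function(m) {
    x <- if (m %in% c("rtheta", "rz"))
      seq(gamma_max / n_per_mode, gamma_max, length.out = n_per_mode)
    else
      seq(1 + (lambda_max - 1) / n_per_mode, lambda_max, length.out = n_per_mode)
    tibble::tibble(mode = m, deformation = x,
                   stress_kPa = model_stress(m, x, p) +
                     rnorm(n_per_mode, sd = noise_sd))
  }))
  do.call(rbind, out)
}

#' Write / read one-mode-per-file CSV datasets
#'
#' Each mode is stored as `mode_<name>.csv` with header
#' `deformation,stress_kPa`.
#'
#' @param data Tibble with `mode`, `deformation`, `stress_kPa`.
#' @param dir Directory for the per-mode CSV files.
#' @return `write_dataset_csv` returns `dir` invisibly; `read_dataset_csv`
#'   returns the combined tibble.
#' @export
write_dataset_csv <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in unique(data$mode)) {
    dm <- data[data$mode == m, c("deformation", "stress_kPa")]
    utils::write.csv(dm, file.path(dir, paste0("mode_", m, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(dir) {
  files <- list.files(dir, pattern = "^mode_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no mode_*.csv files in ", dir)
  do.call(rbind, lapply(files, function(f) {
    m <- sub("^mode_(.*)\\.csv$", "\\1", basename(f))
    dd <- utils::read.csv(f)
    tibble::tibble(mode = m, deformation = dd$deformation,
                   stress_kPa = dd$stress_kPa)
  }))
}
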