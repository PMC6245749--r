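# Dimensionless post-processing: the Stokes number
# Stk = rho_p dp^2 Um Cc / (18 mu Do) with the mouth hydraulic diameter as
# the characteristic length and a device-specific characteristic velocity,
# pooled deposition-efficiency curves vs Stk, Gaussian peak extraction for
# the conducting airways and inversion for the optimal aerosol diameter.

#' Cunningham slip correction factor
#'
#' `Cc = 1 + Kn (1.257 + 0.4 exp(-1.1 / Kn))` with Knudsen number
#' `Kn = 2 lambda / dp`; tends to 1 in the continuum limit of large
#' particles.
#'
#' @param dp Particle diameter(s) (m); must be positive.
#' @param lambda_mfp Mean free path of air (m).
#' @return Dimensionless correction factor(s), >= 1.
#' @examples
#' slip_correction(1e-6)   # ~1.166
#' slip_correction(10e-6)  # ~1.017
#' @export
slip_correction <- function(dp, lambda_mfp = 6.6e-8) {
  if (any(!is.finite(dp)) || any(dp <= 0))
    stop("`dp` must be positive", call. = FALSE)
  kn <- 2 * lambda_mfp / dp
  1 + kn * (1.257 + 0.4 * exp(-1.1 / kn))
}

#' Stokes-number context for one age x device scenario
#'
#' Bundles the characteristic velocity `Um`, the characteristic length `Do`
#' (mouth hydraulic diameter) and the fluid/particle constants entering the
#' Stokes number.
#'
#' @param Um Characteristic velocity (m/s); see
#'   [characteristic_velocity()] for the device conventions.
#' @param Do Characteristic length (m): the mouth hydraulic diameter.
#' @param rho_p Particle density (kg/m^3).
#' @param mu Dynamic viscosity of air (Pa s).
#' @param lambda_mfp Mean free path of air (m).
#' @param age,device Optional labels.
#' @return An object of class `stokes_context`.
#' @export
stokes_context <- function(Um, Do, rho_p = 1000, mu = 1.81e-5,
                           lambda_mfp = 6.6e-8, age = NA, device = NA) {
  vals <- c(Um = Um, Do = Do, rho_p = rho_p, mu = mu,
            lambda_mfp = lambda_mfp)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Um, Do, rho_p, mu and lambda_mfp must be positive", call. = FALSE)
  structure(list(Um = Um, Do = Do, rho_p = rho_p, mu = mu,
                 lambda_mfp = lambda_mfp, age = age, device = device),
            class = "stokes_context")
}

#' Stokes context for a tabulated age x device scenario
#'
#' Builds the scaled tree and maneuver for the age point and derives
#' `Um` and `Do` from them.
#'
#' @param age Age in years (5, 10 or 25).
#' @param device `"DPI"` or `"NEBULIZER"`.
#' @param config A [tree_config()].
#' @param params Optional [maneuver_params()] override.
#' @param ... Passed to [stokes_context()] (e.g. `mu`).
#' @return A `stokes_context`.
#' @examples
#' ctx <- stokes_context_for(5, "DPI")
#' stokes_number(5.5e-6, ctx)  # ~0.061
#' @export
stokes_context_for <- function(age, device, config = tree_config(),
                               params = NULL, ...) {
  if (is.null(params)) params <- maneuver_params(age, device)
  tree <- airway_tree(age, config)
  stokes_context(Um = characteristic_velocity(params, tree$mouth_inlet_area),
                 Do = tree$mouth_hydraulic_diameter,
                 age = age, device = params$device, ...)
}

#' Stokes number of a particle in a flow context
#'
#' `Stk = rho_p dp^2 Um Cc / (18 mu Do)`; quantifies the relative importance
#' of particle inertia and governs impaction-dominated deposition.
#'
#' @param dp Particle diameter(s) (m); zero maps to zero.
#' @param ctx A [stokes_context()].
#' @return Dimensionless Stokes number(s).
#' @export
stokes_number <- function(dp, ctx) {
  stopifnot(inherits(ctx, "stokes_context"))
  out <- numeric(length(dp))
  pos <- dp > 0
  cc <- slip_correction(dp[pos], ctx$lambda_mfp)
  out[pos] <- ctx$rho_p * dp[pos]^2 * ctx$Um * cc / (18 * ctx$mu * ctx$Do)
  out
}

#' Mouth-inlet Reynolds number
#'
#' `Re = 4 Q / (pi D nu)` for a circular inlet of diameter `D` carrying
#' volumetric flow `Q`.
#'
#' @param Q Volumetric flow rate (m^3/s).
#' @param D Inlet diameter (m).
#' @param nu Kinematic viscosity of air (m^2/s).
#' @return Dimensionless Reynolds number(s).
#' @examples
#' reynolds_number(40 / 60000, 0.011)  # ~5100 at age-5 DPI peak flow
#' @export
reynolds_number <- function(Q, D, nu = 1.5e-5) {
  if (any(D <= 0) || any(nu <= 0))
    stop("`D` and `nu` must be positive", call. = FALSE)
  4 * Q / (pi * D * nu)
}

#' Pooled deposition-efficiency curve on the Stokes axis
#'
#' Maps each (age, dp) deposition result to a point (Stk via the Eq-1
#' context of its age, regional efficiency) and pools all ages into one
#' curve; the collapse hypothesis is that points from all ages fall on a
#' single curve.
#'
#' @param results List of `deposition_result` objects sharing one device.
#' @param region `"conducting"`, `"mouth_throat"` or `"total"` (total =
#'   mouth-throat + trachea + conducting).
#' @param contexts Either a single [stokes_context()] or a list of contexts
#'   named by age (e.g. `list("5" = ctx5, ...)`).
#' @return An object of class `efficiency_curve`: a data frame with columns
#'   `stk`, `efficiency`, `dp`, `age`, sorted by `stk`, with `region` and
#'   `device` attributes.
#' @export
efficiency_curve <- function(results,
                             region = c("conducting", "mouth_throat",
                                        "total"),
                             contexts) {
  region <- match.arg(region)
  if (length(results) == 0L) stop("`results` is empty", call. = FALSE)
  if (inherits(results, "deposition_result")) results <- list(results)
  devices <- unique(vapply(results, function(r) r$device, ""))
  if (length(devices) != 1L)
    stop("all results must share one device", call. = FALSE)
  if (inherits(contexts, "stokes_context"))
    contexts <- stats::setNames(list(contexts),
                                as.character(results[[1]]$age))
  rows <- lapply(results, function(r) {
    ctx <- contexts[[as.character(r$age)]]
    if (is.null(ctx))
      stop("no Stokes context supplied for age ", r$age, call. = FALSE)
    eff <- switch(region,
                  conducting = r$efficiencies[["conducting"]],
                  mouth_throat = r$efficiencies[["mouth_throat"]],
                  total = r$efficiencies[["mouth_throat"]] +
                    r$efficiencies[["trachea"]] +
                    r$efficiencies[["conducting"]])
    data.frame(stk = stokes_number(r$dp, ctx), efficiency = eff,
               dp = r$dp, age = r$age)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stk), ]
  rownames(out) <- NULL
  structure(out, region = region, device = devices,
            class = c("efficiency_curve", "data.frame"))
}

#' Fit a Gaussian peak to a deposition-efficiency curve
#'
#' Nonlinear least squares of
#' `eta(Stk) = A exp(-(Stk - mu*)^2 / (2 sigma*^2))`, initialized at the
#' empirical maximum with sigma* set to half the Stk interquartile range.
#' Requires at least 5 points and an interior maximum; a monotone curve
#' (e.g. the mouth-throat sigmoid) is rejected.
#'
#' @param curve An [efficiency_curve()].
#' @param max_iter Maximum optimizer iterations.
#' @return An object of class `gaussian_fit` with elements `amplitude`,
#'   `peak_stk`, `sigma_stk`, `rmse` and the underlying `fit`.
#' @export
fit_gaussian <- function(curve, max_iter = 500) {
  stk <- curve$stk; eff <- curve$efficiency
  if (length(stk) < 5L)
    stop("need at least 5 points to fit a peak", call. = FALSE)
  imax <- which.max(eff)
  if (imax == 1L || imax == length(eff))
    stop("no interior peak: the efficiency maximum sits at the edge of ",
         "the Stk range", call. = FALSE)
  start <- list(A = max(eff), m = stk[imax],
                s = max(diff(stats::quantile(stk, c(0.25, 0.75))) / 2,
                        1e-4))
  fit <- tryCatch(
    minpack.lm::nlsLM(eff ~ A * exp(-(stk - m)^2 / (2 * s^2)),
                      start = start,
                      lower = c(A = 1e-6, m = 1e-8, s = 1e-8),
                      upper = c(A = 1, m = Inf, s = Inf),
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter)),
    error = function(e) stop("Gaussian fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["A"]), peak_stk = unname(cf["m"]),
                 sigma_stk = unname(cf["s"]),
                 rmse = sqrt(mean(stats::resid(fit)^2)),
                 n_points = length(stk),
                 region = attr(curve, "region"),
                 device = attr(curve, "device"),
                 fit = fit),
            class = "gaussian_fit")
}

#' @export
coef.gaussian_fit <- function(object, ...) {
  c(amplitude = object$amplitude, peak_stk = object$peak_stk,
    sigma_stk = object$sigma_stk)
}

#' @export
predict.gaussian_fit <- function(object, stk, ...) {
  object$amplitude *
    exp(-(stk - object$peak_stk)^2 / (2 * object$sigma_stk^2))
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("Gaussian peak fit (", x$region, ", ", x$device, ", ", x$n_points,
      " points)\n", sep = "")
  cat("  amplitude ", signif(x$amplitude, 4), " at Stk* ",
      signif(x$peak_stk, 4), " (sigma* ", signif(x$sigma_stk, 4),
      "), RMSE ", signif(x$rmse, 3), "\n", sep = "")
  invisible(x)
}

#' Invert the Stokes number for the particle diameter
#'
#' Solves `Stk = rho_p dp^2 Um Cc(dp) / (18 mu Do)` for `dp` by fixed-point
#' iteration on the slip correction (start at `Cc = 1`, relative tolerance
#' 1e-4, at most `max_iter` iterations).
#'
#' @param peak_stk Target Stokes number (> 0; 0 maps to 0).
#' @param ctx A [stokes_context()].
#' @param tol Relative convergence tolerance on `dp`.
#' @param max_iter Maximum fixed-point iterations.
#' @return Particle diameter in meters.
#' @examples
#' ctx <- stokes_context_for(5, "DPI")
#' optimal_diameter(0.061, ctx) * 1e6  # ~5.5 um
#' @export
optimal_diameter <- function(peak_stk, ctx, tol = 1e-4, max_iter = 50) {
  stopifnot(inherits(ctx, "stokes_context"))
  if (peak_stk < 0) stop("`peak_stk` must be non-negative", call. = FALSE)
  if (peak_stk == 0) return(0)
  cc <- 1
  dp <- sqrt(18 * ctx$mu * ctx$Do * peak_stk / (ctx$rho_p * ctx$Um * cc))
  for (i in seq_len(max_iter)) {
    cc <- slip_correction(dp, ctx$lambda_mfp)
    dp_new <- sqrt(18 * ctx$mu * ctx$Do * peak_stk /
                     (ctx$rho_p * ctx$Um * cc))
    if (abs(dp_new - dp) / dp < tol) return(dp_new)
    dp <- dp_new
  }
  stop("slip-correction fixed point did not converge", call. = FALSE)
}

#' Optimal aerosol size for one age point
#'
#' Maps a fitted conducting-airway peak through the Stokes inversion:
#' `dp_opt` from the peak Stokes number and a diameter spread obtained by
#' inverting `peak_stk +/- sigma_stk` (half their difference; if the lower
#' edge is non-positive, the upper half-width is used).
#'
#' @param fit A [fit_gaussian()] result.
#' @param ctx The [stokes_context()] of the age point.
#' @return An object of class `optimal_size` with `dp_opt` and `dp_spread`
#'   in meters, plus age/device labels.
#' @export
optimal_size <- function(fit, ctx) {
  stopifnot(inherits(fit, "gaussian_fit"))
  dp_opt <- optimal_diameter(fit$peak_stk, ctx)
  hi <- optimal_diameter(fit$peak_stk + fit$sigma_stk, ctx)
  lo_stk <- fit$peak_stk - fit$sigma_stk
  spread <- if (lo_stk > 0) (hi - optimal_diameter(lo_stk, ctx)) / 2
            else hi - dp_opt
  structure(list(age = ctx$age, device = ctx$device, dp_opt = dp_opt,
                 dp_spread = spread),
            class = "optimal_size")
}

#' @export
print.optimal_size <- function(x, ...) {
  cat("Optimal aerosol size: age ", x$age, " y, ", x$device, ": ",
      signif(x$dp_opt * 1e6, 3), " um (spread ",
      signif(x$dp_spread * 1e6, 3), " um)\n", sep = "")
  invisible(x)
}

#' Master-curve collapse diagnostic
#'
#' Interpolates each per-age efficiency curve onto a common Stokes grid and
#' returns the largest across-age spread (max - min efficiency) anywhere on
#' the grid; 0 means perfect collapse onto a single master curve.
#'
#' @param per_age_curves List of [efficiency_curve()]s sharing device and
#'   region (one per age).
#' @param n_grid Number of grid points.
#' @return Maximum across-age efficiency deviation (efficiency units).
#' @export
collapse_diagnostic <- function(per_age_curves, n_grid = 50) {
  if (length(per_age_curves) < 2L)
    stop("need at least two curves", call. = FALSE)
  regs <- unique(vapply(per_age_curves, attr, "", which = "region"))
  devs <- unique(vapply(per_age_curves, attr, "", which = "device"))
  if (length(regs) != 1L || length(devs) != 1L)
    stop("curves must share one region and one device", call. = FALSE)
  lo <- max(vapply(per_age_curves, function(cv) min(cv$stk), 0))
  hi <- min(vapply(per_age_curves, function(cv) max(cv$stk), 0))
  if (lo >= hi)
    stop("curves have non-overlapping Stk ranges", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  mat <- vapply(per_age_curves, function(cv) {
    stats::approx(cv$stk, cv$efficiency, xout = grid, ties = "ordered")$y
  }, numeric(n_grid))
  max(apply(mat, 1L, max) - apply(mat, 1L, min))
}

#' Per-age efficiency curves at matched Stokes numbers
#'
#' The clean way to probe the master-curve hypothesis: for every age point
#' the particle diameters are chosen by inverting the Stokes number, so all
#' ages are simulated at identical Stk abscissas and
#' [collapse_diagnostic()] compares efficiencies directly instead of
#' through interpolation of differently-gridded curves (which on a steep
#' sigmoid is dominated by interpolation error, not physics).
#'
#' @param ages Age points (years).
#' @param device `"DPI"` or `"NEBULIZER"`.
#' @param stk_grid Stokes numbers at which every age is sampled.
#' @param region Region for the returned curves.
#' @param n_per_size Particles per (age, Stk) point.
#' @param seed Master seed (shared across ages; per-size sub-seeds derive
#'   from it).
#' @param ... Passed to [run_config()] (e.g. `geometry`, `mechanisms`).
#' @return List of [efficiency_curve()]s, one per age, all with the same
#'   Stk abscissas.
#' @export
matched_stk_curves <- function(ages, device,
                               stk_grid = c(0.01, 0.02, 0.04, 0.06, 0.08,
                                            0.1, 0.13),
                               region = "mouth_throat",
                               n_per_size = 28500, seed = 1L, ...) {
  lapply(ages, function(a) {
    ctx <- stokes_context_for(a, device)
    dps <- vapply(stk_grid, optimal_diameter, numeric(1), ctx = ctx)
    sc <- run_scenario(run_config(a, device, sizes_um = dps * 1e6,
                                  n_per_size = n_per_size, seed = seed,
                                  ...))
    efficiency_curve(sc$results, region,
                     stats::setNames(list(ctx), as.character(a)))
  })
}

#' @export
plot.efficiency_curve <- function(x, fit = NULL, ...) {
  ages <- sort(unique(x$age))
  cols <- seq_along(ages)
  graphics::plot(x$stk, x$efficiency, log = "x",
                 col = cols[match(x$age, ages)], pch = 19,
                 xlab = "Stokes number", ylab = "deposition efficiency",
                 main = paste0(attr(x, "region"), ", ", attr(x, "device")),
                 ylim = c(0, 1), ...)
  if (!is.null(fit)) {
    gr <- exp(seq(log(min(x$stk)), log(max(x$stk)), length.out = 200))
    graphics::lines(gr, predict(fit, gr))
  }
  graphics::legend("topleft", legend = paste(ages, "y"), col = cols,
                   pch = 19, bty = "n")
  invisible(x)
}
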