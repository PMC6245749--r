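# Scenario orchestration: one (age x device) run sweeps the device's aerosol
# size range, with a counter-based per-size seed derivation so results for a
# given size are invariant to which other sizes are requested.

#' Configuration of one (age x device) scenario
#'
#' @param age Age in years (5, 10 or 25 for the tabulated defaults).
#' @param device `"DPI"` or `"NEBULIZER"`.
#' @param sizes_um Aerosol diameters to sweep (micrometers); defaults to
#'   1-12 um (DPI) or 1-20 um (nebulizer) in 1-um steps.
#' @param n_per_size Particles per size (default 28,500).
#' @param seed Master integer seed; per-size sub-seeds are derived from it.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @param geometry A [tree_config()].
#' @param maneuver Optional [maneuver_params()] override.
#' @param mechanisms A [mechanism_params()].
#' @param lobar_fractions Named lobar flow fractions.
#' @param rho_p Particle density (kg/m^3).
#' @param dt Waveform time step (s).
#' @return An object of class `run_config`.
#' @export
run_config <- function(age, device, sizes_um = NULL, n_per_size = 28500,
                       seed = 1L, output_dir = NULL,
                       geometry = tree_config(), maneuver = NULL,
                       mechanisms = mechanism_params(),
                       lobar_fractions = c(LU = 0.15, LL = 0.31, RU = 0.14,
                                           RM = 0.07, RL = 0.33),
                       rho_p = 1000, dt = 1e-3) {
  device <- .match_device(device)
  if (is.null(sizes_um))
    sizes_um <- if (device == "DPI") 1:12 else 1:20
  if (length(sizes_um) == 0L || any(sizes_um <= 0))
    stop("`sizes_um` must be a non-empty vector of positive diameters",
         call. = FALSE)
  if (n_per_size <= 0) stop("`n_per_size` must be positive", call. = FALSE)
  if (is.null(maneuver)) maneuver <- maneuver_params(age, device)
  structure(list(age = age, device = device, sizes_um = sizes_um,
                 n_per_size = as.integer(n_per_size),
                 seed = as.integer(seed), output_dir = output_dir,
                 geometry = geometry, maneuver = maneuver,
                 mechanisms = mechanisms,
                 lobar_fractions = lobar_fractions, rho_p = rho_p,
                 dt = dt),
            class = "run_config")
}

# counter-based sub-seed: independent of which other sizes are in the sweep
.sub_seed <- function(master, size_um) {
  counter <- as.numeric(round(size_um * 1000))
  as.integer((as.numeric(master) * 1009 + 97 * counter) %% 2147483647)
}

# md5 of the canonical JSON serialization of the configuration
.config_hash <- function(config) {
  plain <- config
  plain$output_dir <- NULL
  json <- jsonlite::toJSON(lapply(plain, unclass), auto_unbox = TRUE,
                           digits = NA)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Run one (age x device) deposition scenario
#'
#' Builds the scaled tree, the inhalation waveform and the lobar flow field,
#' then simulates one particle ensemble per aerosol size.  Per-size
#' sub-seeds are derived from the master seed by a counter keyed on the size
#' itself, so adding or removing sizes leaves the others bit-identical.
#' With an `output_dir`, writes `deposition.csv`, `segments.csv` (per-segment
#' deposit counts) and `run.json` (configuration echo, hash and seeds);
#' identical configuration and seed reproduce identical files.
#'
#' @param config A [run_config()].
#' @return An object of class `scenario_result`: per-size
#'   `deposition_result`s, the `config`, `tree`, `profile`, `context`
#'   ([stokes_context()]) and the configuration hash.
#' @examples
#' \donttest{
#' sc <- run_scenario(run_config(5, "DPI", sizes_um = c(4, 6),
#'                               n_per_size = 2000))
#' sc$results[[2]]
#' }
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tree <- airway_tree(config$age, config$geometry)
  profile <- build_profile(config$maneuver, config$dt)
  flow <- distribute_flow(tree, profile, config$lobar_fractions)
  ctx <- stokes_context(
    Um = characteristic_velocity(config$maneuver, tree$mouth_inlet_area),
    Do = tree$mouth_hydraulic_diameter, rho_p = config$rho_p,
    mu = config$mechanisms$mu_air,
    lambda_mfp = config$mechanisms$lambda_mfp,
    age = config$age, device = config$device)

  results <- lapply(config$sizes_um, function(um) {
    s <- .sub_seed(config$seed, um)
    set.seed(s)
    rel <- sample_release_times(config$maneuver, config$n_per_size)
    ens <- particle_ensemble(um * 1e-6, rel, config$rho_p)
    res <- simulate_deposition(tree, flow, ens, config$mechanisms,
                               seed = NULL)
    res$seed <- s
    res
  })
  out <- structure(list(results = results, config = config, tree = tree,
                        profile = profile, flow = flow, context = ctx,
                        config_hash = .config_hash(config)),
                   class = "scenario_result")
  if (!is.null(config$output_dir)) write_scenario(out, config$output_dir)
  out
}

#' Total particles injected in a scenario
#' @param scenario A `scenario_result`.
#' @return Integer count summed over all sizes.
#' @export
total_injected <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_result"))
  sum(vapply(scenario$results, function(r) r$injected, 0L))
}

#' Write scenario outputs to a directory
#'
#' @param scenario A `scenario_result`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "scenario_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- scenario$context
  dep <- do.call(rbind, lapply(scenario$results, function(r) {
    data.frame(age_yr = r$age, device = r$device, dp_um = r$dp * 1e6,
               stk = stokes_number(r$dp, ctx),
               region = names(r$counts),
               count = as.integer(r$counts),
               efficiency = as.numeric(r$efficiencies),
               seed = r$seed)
  }))
  utils::write.csv(dep, file.path(dir, "deposition.csv"),
                   row.names = FALSE, quote = FALSE)
  seg <- do.call(rbind, lapply(scenario$results, function(r) {
    nz <- which(r$per_segment > 0)
    if (!length(nz)) return(NULL)
    data.frame(segment_id = as.integer(names(r$per_segment)[nz]),
               dp_um = r$dp * 1e6, count = as.integer(r$per_segment[nz]))
  }))
  if (is.null(seg))
    seg <- data.frame(segment_id = integer(0), dp_um = numeric(0),
                      count = integer(0))
  utils::write.csv(seg, file.path(dir, "segments.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    age = scenario$config$age, device = scenario$config$device,
    sizes_um = scenario$config$sizes_um,
    n_per_size = scenario$config$n_per_size,
    seed = scenario$config$seed,
    sub_seeds = vapply(scenario$results, function(r) r$seed, 0L),
    config_hash = scenario$config_hash,
    total_injected = total_injected(scenario),
    package_version = as.character(utils::packageVersion("aerotree")))
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario: age ", x$config$age, " y, ", x$config$device, ", ",
      length(x$results), " sizes x ", x$config$n_per_size,
      " particles (seed ", x$config$seed, ")\n", sep = "")
  cat("  total injected: ", total_injected(x), " | config hash ",
      substr(x$config_hash, 1, 8), "\n", sep = "")
  invisible(x)
}

#' Cross-age Stokes-number analysis of deposition scenarios
#'
#' Pools scenarios from several age points (one device) into regional
#' efficiency curves on the Stokes axis, fits the conducting-airway Gaussian
#' peak, inverts the peak for the optimal aerosol diameter of every age
#' point and reports the master-curve collapse diagnostic.  The result is
#' invariant to the order in which scenarios are supplied.  For the
#' monotone mouth-throat region no Gaussian is fitted.
#'
#' @param scenarios List of `scenario_result`s sharing one device, at least
#'   two age points.
#' @param region Target region, default `"conducting"`.
#' @param json_path Optional path for a JSON summary.
#' @return An object of class `deposition_analysis`: pooled `curve`,
#'   per-age `curves`, `fit` (or NULL for a monotone region), per-age
#'   `optima`, `collapse` deviation and a per-age summary table.
#' @export
run_analysis <- function(scenarios, region = "conducting",
                         json_path = NULL) {
  if (length(scenarios) < 2L)
    stop("need scenarios from at least two age points", call. = FALSE)
  devs <- unique(vapply(scenarios, function(s) s$config$device, ""))
  if (length(devs) != 1L)
    stop("all scenarios must share one device", call. = FALSE)
  ages <- vapply(scenarios, function(s) s$config$age, 0)
  if (anyDuplicated(ages))
    stop("duplicate age points supplied", call. = FALSE)
  scenarios <- scenarios[order(ages)]
  ages <- sort(ages)

  contexts <- stats::setNames(lapply(scenarios, function(s) s$context),
                              as.character(ages))
  all_results <- unlist(lapply(scenarios, function(s) s$results),
                        recursive = FALSE)
  pooled <- efficiency_curve(all_results, region, contexts)
  per_age <- lapply(scenarios, function(s)
    efficiency_curve(s$results, region, contexts))
  collapse <- collapse_diagnostic(per_age)

  fit <- NULL; optima <- NULL
  if (region != "mouth_throat") {
    fit <- fit_gaussian(pooled)
    optima <- lapply(contexts, function(ctx) optimal_size(fit, ctx))
  }
  summary_tab <- do.call(rbind, lapply(seq_along(ages), function(i) {
    ctx <- contexts[[i]]
    prm <- scenarios[[i]]$config$maneuver
    data.frame(age_yr = ages[i], device = devs, Um_m_s = ctx$Um,
               Do_m = ctx$Do,
               Re_at_pifr = reynolds_number(prm$pifr / 60000, ctx$Do),
               dp_opt_um = if (is.null(optima)) NA_real_
                           else optima[[i]]$dp_opt * 1e6,
               dp_spread_um = if (is.null(optima)) NA_real_
                              else optima[[i]]$dp_spread * 1e6)
  }))
  out <- structure(list(device = devs, region = region, curve = pooled,
                        curves = per_age, fit = fit, optima = optima,
                        collapse = collapse, summary = summary_tab),
                   class = "deposition_analysis")
  if (!is.null(json_path)) {
    js <- list(device = devs, region = region,
               collapse_max_deviation = collapse,
               gaussian = if (!is.null(fit))
                 list(amplitude = fit$amplitude, peak_stk = fit$peak_stk,
                      sigma_stk = fit$sigma_stk, rmse = fit$rmse),
               per_age = summary_tab)
    jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  out
}

#' @export
print.deposition_analysis <- function(x, ...) {
  cat("Stokes-number deposition analysis (", x$region, ", ", x$device,
      ")\n", sep = "")
  if (!is.null(x$fit))
    cat("  peak: ", signif(100 * x$fit$amplitude, 3), "% at Stk* ",
        signif(x$fit$peak_stk, 3), " (sigma* ", signif(x$fit$sigma_stk, 3),
        ", RMSE ", signif(x$fit$rmse, 3), ")\n", sep = "")
  cat("  collapse max deviation: ", signif(x$collapse, 3), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read a scenario configuration from YAML
#'
#' Single YAML file with optional blocks `geometry`, `maneuver`,
#' `mechanisms` and `run` (age, device, sizes_um, n_per_size, seed,
#' output_dir); block entries override the defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run <- y$run
  if (is.null(run$age) || is.null(run$device))
    stop("YAML block `run:` must supply `age` and `device`", call. = FALSE)
  geometry <- do.call(tree_config, as.list(y$geometry))
  mechanisms <- do.call(mechanism_params, as.list(y$mechanisms))
  maneuver <- if (is.null(y$maneuver)) NULL else
    do.call(maneuver_params,
            c(list(age = run$age, device = run$device), as.list(y$maneuver)))
  args <- list(age = run$age, device = run$device, geometry = geometry,
               mechanisms = mechanisms, maneuver = maneuver)
  for (k in c("sizes_um", "n_per_size", "seed", "output_dir", "rho_p", "dt"))
    if (!is.null(run[[k]])) args[[k]] <- run[[k]]
  do.call(run_config, args)
}
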