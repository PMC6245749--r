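# Age- and device-specific inhalation waveforms.  Nebulizer (tidal) breathing
# is a half-sine; the dry-powder-inhaler maneuver is a quarter-sine rise to
# peak inspiratory flow rate (PIFR) at 0.45 s, a plateau at PIFR until 0.6 s,
# and a volume-constrained cos^gamma decay to zero flow at end-inspiration.

# tidal volume (l), PIFR (l/min), inspiration time (s) per age x device
.maneuver_table <- data.frame(
  age = rep(c(5, 10, 25), 2),
  device = rep(c("DPI", "NEBULIZER"), each = 3),
  tidal_volume = c(0.89, 1.33, 2.95, 0.108, 0.168, 0.5),
  pifr = c(40, 60, 90, 8.14, 10, 22),
  t_insp = c(2, 2, 3, 1.25, 1.58, 2.14),
  stringsAsFactors = FALSE)

.match_device <- function(device) {
  d <- toupper(device)
  if (d %in% c("NEB", "NEBULIZER")) return("NEBULIZER")
  if (d == "DPI") return("DPI")
  stop("`device` must be \"DPI\" or \"NEBULIZER\"", call. = FALSE)
}

#' Inhalation maneuver parameters
#'
#' Tidal volume, peak inspiratory flow rate and inspiration duration for one
#' age x device maneuver.  For the tabulated age points (5, 10, 25 years)
#' unspecified values default to the reference table; any value can be
#' overridden.
#'
#' @param age Age in years.
#' @param device `"DPI"` or `"NEBULIZER"` (`"neb"` accepted).
#' @param tidal_volume Inhaled volume per breath (liters).
#' @param pifr Peak inspiratory flow rate (liters/minute).
#' @param t_insp Inspiration duration (s).
#' @param t_peak DPI only: time at which PIFR is reached (s).
#' @param t_plateau_end DPI only: end of the PIFR plateau (s); particle
#'   release spans `[t_peak, t_plateau_end]`.
#' @return An object of class `maneuver_params`.
#' @examples
#' maneuver_params(5, "DPI")
#' @export
maneuver_params <- function(age, device, tidal_volume = NULL, pifr = NULL,
                            t_insp = NULL, t_peak = 0.45,
                            t_plateau_end = 0.6) {
  device <- .match_device(device)
  row <- .maneuver_table[.maneuver_table$age == age &
                           .maneuver_table$device == device, ]
  if (is.null(tidal_volume)) tidal_volume <- if (nrow(row)) row$tidal_volume
  if (is.null(pifr)) pifr <- if (nrow(row)) row$pifr
  if (is.null(t_insp)) t_insp <- if (nrow(row)) row$t_insp
  if (is.null(tidal_volume) || is.null(pifr) || is.null(t_insp))
    stop("age ", age, " is not tabulated; supply tidal_volume, pifr and ",
         "t_insp explicitly", call. = FALSE)
  vals <- c(tidal_volume = tidal_volume, pifr = pifr, t_insp = t_insp)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("maneuver parameters must be non-negative", call. = FALSE)
  if (device == "DPI" && !(t_peak < t_plateau_end && t_plateau_end < t_insp))
    stop("DPI maneuver requires t_peak < t_plateau_end < t_insp",
         call. = FALSE)
  structure(list(age = age, device = device, tidal_volume = tidal_volume,
                 pifr = pifr, t_insp = t_insp, t_peak = t_peak,
                 t_plateau_end = t_plateau_end),
            class = "maneuver_params")
}

.profile_grid <- function(t_insp, dt) {
  times <- seq(0, t_insp, by = dt)
  if (times[length(times)] < t_insp) times <- c(times, t_insp)
  times
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Nebulizer (tidal breathing) inhalation profile
#'
#' Half-sine inspiratory waveform `Q(t) = PIFR sin(pi t / t_insp)` on
#' `[0, t_insp]`, whose closed-form volume is `(2/pi) PIFR t_insp`.  If that
#' volume disagrees with the stated tidal volume by more than 2% a warning is
#' raised and the tidal volume is replaced by the integral.
#'
#' @param params A [maneuver_params()] with `device = "NEBULIZER"`.
#' @param dt Time step of the sampled waveform (s); at most 1e-3.
#' @return An object of class `inhalation_profile`: uniform time grid
#'   `times` (s), `flow` (m^3/s), the `params`, and `dt`.
#' @examples
#' pr <- nebulizer_profile(maneuver_params(5, "neb"))
#' inhaled_volume(pr)  # ~0.108 l
#' @export
nebulizer_profile <- function(params, dt = 1e-3) {
  stopifnot(inherits(params, "maneuver_params"))
  if (params$device != "NEBULIZER")
    stop("`params` must describe a nebulizer maneuver", call. = FALSE)
  if (dt > 1e-3 || dt <= 0)
    stop("`dt` must be positive and at most 1e-3 s", call. = FALSE)
  qpk <- params$pifr / 60000                     # l/min -> m^3/s
  closed_l <- (2 / pi) * qpk * params$t_insp * 1000
  if (abs(closed_l - params$tidal_volume) / params$tidal_volume > 0.02) {
    warning("half-sine volume (", signif(closed_l, 4),
            " l) inconsistent with stated tidal volume (",
            params$tidal_volume, " l); using the integral", call. = FALSE)
    params$tidal_volume <- closed_l
  }
  times <- .profile_grid(params$t_insp, dt)
  flow <- pmax(qpk * sin(pi * times / params$t_insp), 0)
  structure(list(times = times, flow = flow, params = params, dt = dt),
            class = "inhalation_profile")
}

# decay-phase volume (l) of PIFR * cos^gamma(0.5 pi s), s in [0, 1]
.dpi_decay_volume <- function(gamma, qpk, t_decay, dt) {
  s <- seq(0, 1, length.out = max(ceiling(t_decay / dt) + 1L, 201L))
  .trapz(s * t_decay, qpk * cos(pi * s / 2)^gamma) * 1000
}

#' Dry-powder-inhaler inhalation profile
#'
#' Piecewise waveform: quarter-sine rise from zero to PIFR on `[0, t_peak]`,
#' plateau at PIFR on `[t_peak, t_plateau_end]`, then
#' `Q(t) = PIFR cos^gamma(pi/2 (t - t_plateau_end)/(t_insp - t_plateau_end))`
#' with the exponent `gamma` solved by bisection (volume tolerance 1e-6 l)
#' so the total integral matches the tidal volume.  Flow is exactly zero at
#' end-inspiration.
#'
#' @inheritParams nebulizer_profile
#' @param params A [maneuver_params()] with `device = "DPI"`.
#' @return An `inhalation_profile`; the solved exponent is stored in
#'   `$gamma`.
#' @examples
#' pr <- dpi_profile(maneuver_params(5, "DPI"))
#' inhaled_volume(pr)  # ~0.89 l
#' @export
dpi_profile <- function(params, dt = 1e-3) {
  stopifnot(inherits(params, "maneuver_params"))
  if (params$device != "DPI")
    stop("`params` must describe a DPI maneuver", call. = FALSE)
  if (dt > 1e-3 || dt <= 0)
    stop("`dt` must be positive and at most 1e-3 s", call. = FALSE)
  qpk <- params$pifr / 60000
  t_pk <- params$t_peak; t_pl <- params$t_plateau_end
  t_decay <- params$t_insp - t_pl
  rise_l <- (2 / pi) * qpk * t_pk * 1000
  plateau_l <- qpk * (t_pl - t_pk) * 1000
  target_l <- params$tidal_volume - rise_l - plateau_l
  vol <- function(g) .dpi_decay_volume(g, qpk, t_decay, dt)
  lo <- 0.05; hi <- 20
  if (target_l > vol(lo) || target_l < vol(hi))
    stop("infeasible maneuver: tidal volume ", params$tidal_volume,
         " l incompatible with PIFR/t_insp for exponent in [0.05, 20]",
         call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- vol(mid)
    if (abs(v - target_l) <= 1e-6) break
    if (v > target_l) lo <- mid else hi <- mid
  }
  gamma <- mid
  times <- .profile_grid(params$t_insp, dt)
  flow <- numeric(length(times))
  rise <- times <= t_pk
  flow[rise] <- qpk * sin(pi * times[rise] / (2 * t_pk))
  plat <- times > t_pk & times <= t_pl
  flow[plat] <- qpk
  dec <- times > t_pl
  flow[dec] <- qpk * pmax(cos(pi / 2 * (times[dec] - t_pl) / t_decay), 0)^gamma
  flow[length(flow)] <- 0
  out <- structure(list(times = times, flow = flow, params = params,
                        dt = dt, gamma = gamma),
                   class = "inhalation_profile")
  out
}

#' Build the inhalation profile for a maneuver
#'
#' Dispatches to [dpi_profile()] or [nebulizer_profile()] by device.
#' @inheritParams nebulizer_profile
#' @export
build_profile <- function(params, dt = 1e-3) {
  if (params$device == "DPI") dpi_profile(params, dt)
  else nebulizer_profile(params, dt)
}

#' Inhaled volume of a sampled profile
#'
#' Trapezoidal integral of the flow waveform over inspiration.
#' @param profile An `inhalation_profile`.
#' @return Volume in liters.
#' @export
inhaled_volume <- function(profile) {
  stopifnot(inherits(profile, "inhalation_profile"))
  .trapz(profile$times, profile$flow) * 1000
}

#' Characteristic inlet velocity of a maneuver
#'
#' The device-specific velocity entering the Stokes number: for DPI the mean
#' inlet velocity during the PIFR window (the plateau is constant, so this is
#' `PIFR / mouth_area`); for the nebulizer the mean inhalation velocity over
#' the whole inspiration, `tidal_volume / (t_insp * mouth_area)`.
#'
#' @param params A [maneuver_params()].
#' @param mouth_area Mouth inlet area (m^2).
#' @return Velocity in m/s.
#' @examples
#' tr <- airway_tree(5)
#' characteristic_velocity(maneuver_params(5, "DPI"), tr$mouth_inlet_area)
#' @export
characteristic_velocity <- function(params, mouth_area) {
  stopifnot(inherits(params, "maneuver_params"))
  if (!is.numeric(mouth_area) || mouth_area <= 0)
    stop("`mouth_area` must be positive", call. = FALSE)
  if (params$device == "DPI") {
    (params$pifr / 60000) / mouth_area
  } else {
    (params$tidal_volume / 1000) / (params$t_insp * mouth_area)
  }
}

#' Write a waveform to CSV
#' @param profile An `inhalation_profile`.
#' @param path File path; columns `t_s`, `Q_m3_per_s`.
#' @export
write_waveform_csv <- function(profile, path) {
  stopifnot(inherits(profile, "inhalation_profile"))
  utils::write.csv(data.frame(t_s = profile$times,
                              Q_m3_per_s = profile$flow),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.maneuver_params <- function(x, ...) {
  cat("Inhalation maneuver: age ", x$age, " y, ", x$device, "\n",
      "  VT ", x$tidal_volume, " l | PIFR ", x$pifr, " l/min | t_insp ",
      x$t_insp, " s\n", sep = "")
  if (x$device == "DPI")
    cat("  PIFR reached at ", x$t_peak, " s, plateau until ",
        x$t_plateau_end, " s\n", sep = "")
  invisible(x)
}

#' @export
print.inhalation_profile <- function(x, ...) {
  cat("Inhalation profile (", x$params$device, ", age ", x$params$age,
      " y): ", length(x$times), " samples, dt ", x$dt, " s\n",
      "  peak flow ", signif(max(x$flow) * 60000, 4),
      " l/min, inhaled volume ", signif(inhaled_volume(x), 4), " l\n",
      sep = "")
  invisible(x)
}

#' @export
plot.inhalation_profile <- function(x, ...) {
  graphics::plot(x$times, x$flow * 60000, type = "l", xlab = "time (s)",
                 ylab = "flow (l/min)",
                 main = paste0(x$params$device, ", age ", x$params$age,
                               " y"), ...)
  invisible(x)
}
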