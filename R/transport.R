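# Quasi-steady surrogate for unsteady airway flow + Lagrangian tracking.
# The instantaneous inlet flow is distributed through the tree by lobar
# weighting; particles transit segment-by-segment as plugs with velocity
# U_seg(t) = fraction * Q(t) / (pi d^2 / 4), and deposit by Bernoulli trials:
# a Stokes-number sigmoid at the lumped mouth-throat, and bounded exponential
# impaction / tube-sedimentation closures in the trachea and bronchi.

#' Physical and calibration constants of the deposition surrogate
#'
#' @param mu_air Dynamic viscosity of air (Pa s).
#' @param lambda_mfp Mean free path of air (m), for the Cunningham slip
#'   correction.
#' @param g Gravitational acceleration (m/s^2); gravity acts along -Y.
#' @param mt_stk50 Stokes number of 50% mouth-throat deposition (sigmoid
#'   midpoint).
#' @param mt_slope Hill slope of the mouth-throat sigmoid.
#' @param k_impact Dimensionless gain of the bifurcation impaction closure.
#' @return An object of class `mechanism_params`.
#' @export
mechanism_params <- function(mu_air = 1.81e-5, lambda_mfp = 6.6e-8,
                             g = 9.81, mt_stk50 = 0.075, mt_slope = 9,
                             k_impact = 6) {
  vals <- c(mu_air = mu_air, lambda_mfp = lambda_mfp, g = g,
            mt_stk50 = mt_stk50, mt_slope = mt_slope, k_impact = k_impact)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all mechanism parameters must be positive", call. = FALSE)
  structure(as.list(vals), class = "mechanism_params")
}

#' Aerosol particle specification
#'
#' Spherical particle of diameter `dp` and density `rho_p`, released at the
#' mouth inlet at `release_time`.  Brownian motion is neglected, which is
#' adequate for micron-sized and larger particles.
#'
#' @param dp Particle diameter (m).
#' @param rho_p Particle density (kg/m^3).
#' @param release_time Release time (s) from the start of inspiration.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(dp, rho_p = 1000, release_time = 0) {
  if (!is.numeric(dp) || dp <= 0) stop("`dp` must be positive", call. = FALSE)
  if (rho_p <= 0) stop("`rho_p` must be positive", call. = FALSE)
  structure(list(dp = dp, rho_p = rho_p, release_time = release_time),
            class = "particle_spec")
}

#' Particle ensemble for one aerosol size
#'
#' @param dp Particle diameter (m), shared by the ensemble.
#' @param release_times Vector of release times (s).
#' @param rho_p Particle density (kg/m^3).
#' @return An object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(dp, release_times, rho_p = 1000) {
  if (!is.numeric(dp) || dp <= 0) stop("`dp` must be positive", call. = FALSE)
  if (length(release_times) < 1L)
    stop("ensemble must contain at least one particle", call. = FALSE)
  structure(list(dp = dp, rho_p = rho_p, release_times = release_times),
            class = "particle_ensemble")
}

#' Sample particle release times
#'
#' DPI: the device empties as a short bolus during the PIFR window, so times
#' are uniform on `[t_peak, t_plateau_end]`.  Nebulizer: aerosol is injected
#' continuously during the whole inspiration; the default is a constant
#' number rate (uniform on `[0, t_insp]`), with a flow-proportional variant
#' available.
#'
#' @param params A [maneuver_params()].
#' @param n Number of particles.
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @param weight `"constant"` (default) or `"flow"`; nebulizer only.
#' @param profile Required when `weight = "flow"`: the inhalation profile to
#'   weight by.
#' @return Numeric vector of `n` release times (s).
#' @export
sample_release_times <- function(params, n, seed = NULL,
                                 weight = c("constant", "flow"),
                                 profile = NULL) {
  stopifnot(inherits(params, "maneuver_params"))
  weight <- match.arg(weight)
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (params$device == "DPI") {
    stats::runif(n, params$t_peak, params$t_plateau_end)
  } else if (weight == "constant") {
    stats::runif(n, 0, params$t_insp)
  } else {
    if (is.null(profile))
      stop("flow-weighted release needs `profile`", call. = FALSE)
    cum <- cumsum(c(0, diff(profile$times) *
                      (profile$flow[-1] + profile$flow[-length(profile$flow)]) / 2))
    stats::approx(cum / cum[length(cum)], profile$times,
                  xout = stats::runif(n), ties = "ordered")$y
  }
}

#' Distribute the inlet flow through the tree by lobar weighting
#'
#' Each terminal outlet belonging to lobe `l` receives an equal share
#' `fraction(l) / n_outlets(l)` of the instantaneous inlet flow; interior
#' segment fractions follow by summation up the tree, so the trachea carries
#' fraction 1 and flow is conserved at every junction.
#'
#' @param tree An `airway_tree`.
#' @param profile Optional `inhalation_profile` carried along for transport.
#' @param lobar_fractions Named fractions for lobes LU, LL, RU, RM, RL;
#'   must sum to 1 within 1e-9.
#' @return An object of class `flow_field`: per-segment flow `fraction`
#'   (named by segment id), the `lobar_fractions` and the `profile`.
#' @examples
#' ff <- distribute_flow(airway_tree(25))
#' ff$fraction[["2"]]  # trachea carries everything
#' @export
distribute_flow <- function(tree, profile = NULL,
                            lobar_fractions = c(LU = 0.15, LL = 0.31,
                                                RU = 0.14, RM = 0.07,
                                                RL = 0.33)) {
  stopifnot(inherits(tree, "airway_tree"))
  needed <- c("LU", "LL", "RU", "RM", "RL")
  if (!setequal(names(lobar_fractions), needed))
    stop("`lobar_fractions` must be named LU, LL, RU, RM, RL", call. = FALSE)
  lobar_fractions <- lobar_fractions[needed]
  if (abs(sum(lobar_fractions) - 1) > 1e-9)
    stop("lobar flow fractions must sum to 1", call. = FALSE)
  segs <- tree$segments
  term <- segs$level == max(segs$level)
  n_lobe <- table(segs$lobe[term])
  if (!all(needed %in% names(n_lobe)))
    stop("every lobe must be present among the outlets", call. = FALSE)
  frac <- numeric(nrow(segs))
  frac[term] <- lobar_fractions[segs$lobe[term]] /
    as.numeric(n_lobe[segs$lobe[term]])
  for (lv in (max(segs$level) - 1L):(-1L)) {
    at <- which(segs$level == lv)
    for (i in at) {
      frac[i] <- sum(frac[segs$parent_id == segs$id[i]], na.rm = TRUE)
    }
  }
  names(frac) <- segs$id
  structure(list(fraction = frac, lobar_fractions = lobar_fractions,
                 profile = profile),
            class = "flow_field")
}

# segment-scale Stokes number: rho dp^2 Cc U / (18 mu d)
.seg_stokes <- function(dp, rho_p, cc, u, d, mu) {
  rho_p * dp^2 * cc * u / (18 * mu * d)
}

# terminal settling velocity under Stokes drag
.settling_velocity <- function(dp, rho_p, cc, g, mu) {
  rho_p * dp^2 * g * cc / (18 * mu)
}

.p_impact <- function(theta, stk_seg, k) -expm1(-k * theta * stk_seg)

.p_sediment <- function(vts, len, gang, d, u) {
  -expm1(-4 * vts * len * cos(gang) / (pi * d * u))
}

#' Mouth-throat deposition efficiency
#'
#' Sigmoidal (Hill) filter in the Stokes number lumping the oropharyngeal and
#' laryngeal impaction of the mouth-throat compartment:
#' `eta = Stk^s / (Stk^s + Stk50^s)`.  Monotone increasing, 0 at Stk = 0 and
#' saturating at 1.
#'
#' @param stk Stokes number(s), computed at the mouth with the local inlet
#'   velocity.
#' @param params A [mechanism_params()].
#' @return Deposition probability in `[0, 1)`.
#' @examples
#' mouth_throat_efficiency(0.075)  # sigmoid midpoint: 0.5
#' @export
mouth_throat_efficiency <- function(stk, params = mechanism_params()) {
  if (any(stk < 0)) stop("`stk` must be non-negative", call. = FALSE)
  s <- params$mt_slope
  x <- stk^s
  out <- x / (x + params$mt_stk50^s)
  out[stk == 0] <- 0
  out
}

#' Inertial impaction probability in a branching segment
#'
#' Bounded closure `P_I = 1 - exp(-k theta Stk_seg)` with the segment-scale
#' Stokes number `Stk_seg = rho_p dp^2 Cc U / (18 mu d)`; zero for a straight
#' entry (the trachea, `theta = 0`) and vanishing quadratically as `dp -> 0`.
#'
#' @param segment One row of an airway segment table (needs `diameter_m` and
#'   `branching_angle_rad`).
#' @param local_velocity Quasi-steady plug velocity in the segment (m/s).
#' @param particle A [particle_spec()].
#' @param params A [mechanism_params()].
#' @return Probability in `[0, 1)`.
#' @export
impaction_probability <- function(segment, local_velocity, particle,
                                  params = mechanism_params()) {
  cc <- slip_correction(particle$dp, params$lambda_mfp)
  stk <- .seg_stokes(particle$dp, particle$rho_p, cc, local_velocity,
                     segment$diameter_m, params$mu_air)
  .p_impact(segment$branching_angle_rad, stk, params$k_impact)
}

#' Gravitational sedimentation probability in a segment
#'
#' Tube-sedimentation closure
#' `P_S = 1 - exp(-4 v_ts L cos(phi) / (pi d U))` with terminal settling
#' velocity `v_ts = rho_p dp^2 g Cc / (18 mu)` and `phi` the segment's
#' inclination from the horizontal; a vertical segment (the trachea)
#' collects nothing by sedimentation.
#'
#' @inheritParams impaction_probability
#' @return Probability in `[0, 1)`.
#' @export
sedimentation_probability <- function(segment, local_velocity, particle,
                                      params = mechanism_params()) {
  if (any(local_velocity <= 0))
    stop("`local_velocity` must be positive (no quasi-steady transit)",
         call. = FALSE)
  cc <- slip_correction(particle$dp, params$lambda_mfp)
  vts <- .settling_velocity(particle$dp, particle$rho_p, cc, params$g,
                            params$mu_air)
  .p_sediment(vts, segment$length_m, segment$gravity_angle_rad,
              segment$diameter_m, local_velocity)
}

.fate_codes <- c(mouth_throat = 1L, trachea = 2L, conducting = 3L,
                 escaped = 4L)

#' Monte-Carlo particle transport through the airway tree
#'
#' Routes every particle mouth -> outlet along a path sampled with
#' probability proportional to the outlet flow fraction.  At the lumped
#' mouth-throat a Bernoulli trial uses the Stokes sigmoid evaluated at the
#' release-time inlet velocity; in the trachea and each conducting segment
#' the combined trial probability is `1 - (1 - P_I)(1 - P_S)` at the
#' quasi-steady velocity of the particle's arrival time, with arrival
#' advanced by the residence time `L / U` per segment.  Particles reaching an
#' outlet, and particles still in flight when the flow has decayed to zero,
#' are tallied as escaped (by lobe).
#'
#' @param tree An `airway_tree`.
#' @param flow A `flow_field` from [distribute_flow()]; must carry a profile.
#' @param particles A [particle_ensemble()].
#' @param params A [mechanism_params()].
#' @param seed Optional integer seed.
#' @return An object of class `deposition_result` with counts and regional
#'   efficiencies (fractions of injected) for mouth-throat, trachea,
#'   conducting airways and escape (per lobe), plus per-segment deposit
#'   counts.
#' @export
simulate_deposition <- function(tree, flow, particles,
                                params = mechanism_params(), seed = NULL) {
  stopifnot(inherits(tree, "airway_tree"), inherits(flow, "flow_field"),
            inherits(particles, "particle_ensemble"))
  profile <- flow$profile
  if (is.null(profile))
    stop("`flow` must carry an inhalation profile", call. = FALSE)
  if (all(profile$flow <= 0))
    stop("profile has zero flow everywhere", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  segs <- tree$segments
  n <- length(particles$release_times)
  dp <- particles$dp; rho_p <- particles$rho_p
  cc <- slip_correction(dp, params$lambda_mfp)
  vts <- .settling_velocity(dp, rho_p, cc, params$g, params$mu_air)
  qfun <- stats::approxfun(profile$times, profile$flow, yleft = 0,
                           yright = 0, ties = "ordered")

  # id-indexed geometry lookups (ids are contiguous 1..nrow)
  dvec <- segs$diameter_m[order(segs$id)]
  lvec <- segs$length_m[order(segs$id)]
  bvec <- segs$branching_angle_rad[order(segs$id)]
  gvec <- segs$gravity_angle_rad[order(segs$id)]
  fvec <- flow$fraction[as.character(seq_len(nrow(segs)))]
  area <- pi * dvec^2 / 4

  pm <- .path_matrix(tree)
  term <- terminal_ids(tree)
  ofr <- fvec[term]
  lobe_of_outlet <- segs$lobe[match(term, segs$id)]

  rt <- particles$release_times
  u0 <- qfun(rt) / tree$mouth_inlet_area
  stk0 <- .seg_stokes(dp, rho_p, cc, u0, tree$mouth_hydraulic_diameter,
                      params$mu_air)
  fate <- integer(n)                 # 0 = in transit
  seg_dep <- rep(NA_integer_, n)
  dep_mt <- stats::runif(n) < mouth_throat_efficiency(stk0, params)
  fate[dep_mt] <- .fate_codes["mouth_throat"]
  seg_dep[dep_mt] <- 1L

  outlet <- sample.int(length(term), n, replace = TRUE, prob = ofr)
  stall0 <- !dep_mt & u0 <= 0        # released with no flow: in-flight escape
  fate[stall0] <- .fate_codes["escaped"]
  t_arr <- rt + ifelse(u0 > 0, segs$length_m[1] / u0, Inf)

  for (col in 2:ncol(pm)) {          # trachea, then bronchial levels 1..6
    idx <- which(fate == 0L)
    if (!length(idx)) break
    sid <- pm[cbind(outlet[idx], col)]
    u <- fvec[sid] * qfun(t_arr[idx]) / area[sid]
    stalled <- u <= 0
    stk <- .seg_stokes(dp, rho_p, cc, u, dvec[sid], params$mu_air)
    p_i <- .p_impact(bvec[sid], stk, params$k_impact)
    p_s <- .p_sediment(vts, lvec[sid], gvec[sid], dvec[sid], u)
    p <- 1 - (1 - p_i) * (1 - p_s)
    p[stalled] <- 0
    dep <- stats::runif(length(idx)) < p
    code <- if (col == 2L) .fate_codes["trachea"] else
      .fate_codes["conducting"]
    fate[idx[dep]] <- code
    seg_dep[idx[dep]] <- sid[dep]
    fate[idx[stalled]] <- .fate_codes["escaped"]
    keep <- !dep & !stalled
    t_arr[idx[keep]] <- t_arr[idx[keep]] + lvec[sid[keep]] / u[keep]
  }
  fate[fate == 0L] <- .fate_codes["escaped"]

  esc <- fate == .fate_codes["escaped"]
  esc_by_lobe <- table(factor(lobe_of_outlet[outlet[esc]],
                              levels = c("LU", "LL", "RU", "RM", "RL")))
  counts <- c(mouth_throat = sum(fate == 1L), trachea = sum(fate == 2L),
              conducting = sum(fate == 3L), escaped = sum(esc))
  stopifnot(sum(counts) == n)
  per_segment <- tabulate(seg_dep[!is.na(seg_dep)], nbins = nrow(segs))
  names(per_segment) <- seq_len(nrow(segs))

  structure(list(age = tree$age_label,
                 device = profile$params$device,
                 dp = dp, rho_p = rho_p,
                 injected = n,
                 counts = counts,
                 escaped_by_lobe = c(esc_by_lobe),
                 efficiencies = counts / n,
                 per_segment = per_segment,
                 seed = seed),
            class = "deposition_result")
}

#' Closed-form expected regional deposition for one release time
#'
#' Independent oracle for the Monte-Carlo transport: for a single particle
#' released at a fixed time it enumerates all 64 mouth-to-outlet paths,
#' multiplies the per-segment survival/deposition terms along each
#' deterministic transit (same arrival-time advancement as the simulator)
#' and weights by the outlet flow fraction, yielding exact expected
#' probabilities for every region.
#'
#' @param tree An `airway_tree`.
#' @param flow A `flow_field` carrying a profile.
#' @param particle A [particle_spec()] (its `release_time` is used).
#' @param params A [mechanism_params()].
#' @return Named probabilities `mouth_throat`, `trachea`, `conducting`,
#'   `escaped`, summing to 1.
#' @export
expected_deposition <- function(tree, flow, particle,
                                params = mechanism_params()) {
  stopifnot(inherits(tree, "airway_tree"), inherits(flow, "flow_field"),
            inherits(particle, "particle_spec"))
  profile <- flow$profile
  if (is.null(profile))
    stop("`flow` must carry an inhalation profile", call. = FALSE)
  segs <- tree$segments
  dp <- particle$dp; rho_p <- particle$rho_p
  cc <- slip_correction(dp, params$lambda_mfp)
  vts <- .settling_velocity(dp, rho_p, cc, params$g, params$mu_air)
  qfun <- stats::approxfun(profile$times, profile$flow, yleft = 0,
                           yright = 0, ties = "ordered")
  dvec <- segs$diameter_m[order(segs$id)]
  lvec <- segs$length_m[order(segs$id)]
  bvec <- segs$branching_angle_rad[order(segs$id)]
  gvec <- segs$gravity_angle_rad[order(segs$id)]
  fvec <- flow$fraction[as.character(seq_len(nrow(segs)))]
  area <- pi * dvec^2 / 4
  pm <- .path_matrix(tree)
  term <- terminal_ids(tree)
  ofr <- fvec[term]

  u0 <- qfun(particle$release_time) / tree$mouth_inlet_area
  stk0 <- .seg_stokes(dp, rho_p, cc, u0, tree$mouth_hydraulic_diameter,
                      params$mu_air)
  p_mt <- mouth_throat_efficiency(max(stk0, 0), params)
  if (u0 <= 0)
    return(c(mouth_throat = unname(p_mt), trachea = 0, conducting = 0,
             escaped = unname(1 - p_mt)))
  t0 <- particle$release_time + lvec[1] / u0

  p_tr <- 0; p_cd <- 0; p_esc <- 0
  for (k in seq_along(term)) {
    w <- ofr[k]; surv <- 1; t <- t0
    for (col in 2:ncol(pm)) {
      sid <- pm[k, col]
      u <- fvec[sid] * qfun(t) / area[sid]
      if (u <= 0) { p_esc <- p_esc + w * surv; surv <- 0; break }
      stk <- .seg_stokes(dp, rho_p, cc, u, dvec[sid], params$mu_air)
      p <- 1 - (1 - .p_impact(bvec[sid], stk, params$k_impact)) *
        (1 - .p_sediment(vts, lvec[sid], gvec[sid], dvec[sid], u))
      if (col == 2L) p_tr <- p_tr + w * surv * p
      else p_cd <- p_cd + w * surv * p
      surv <- surv * (1 - p)
      t <- t + lvec[sid] / u
    }
    p_esc <- p_esc + w * surv
  }
  surv0 <- 1 - p_mt
  out <- c(mouth_throat = unname(p_mt), trachea = unname(surv0 * p_tr),
           conducting = unname(surv0 * p_cd),
           escaped = unname(surv0 * p_esc))
  out
}

#' @export
print.deposition_result <- function(x, ...) {
  cat("Deposition result: age ", x$age, " y, ", x$device, ", dp ",
      signif(x$dp * 1e6, 4), " um, n = ", x$injected, "\n", sep = "")
  eff <- round(100 * x$efficiencies, 2)
  cat("  mouth-throat ", eff[["mouth_throat"]], "% | trachea ",
      eff[["trachea"]], "% | conducting ", eff[["conducting"]],
      "% | escaped ", eff[["escaped"]], "%\n", sep = "")
  invisible(x)
}
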