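# Idealized upper-airway geometry: a lumped mouth-throat compartment feeding a
# trachea and six levels of dichotomous, mildly asymmetric bronchial branching
# (64 lobe-labelled outlets).  The adult tree is anchored to reference
# morphometry (mouth hydraulic diameter 19 mm, trachea 16 mm, main bronchi
# 10.8 mm) and scaled homothetically to younger age points.

#' Geometry configuration for the idealized airway tree
#'
#' Collects every knob of the procedural airway generator.  Levels distal to
#' the main bronchi are not morphometrically tabulated anywhere, so they are
#' generated Weibel-style from per-level child/parent diameter ratios with a
#' mild, deterministic asymmetry.
#'
#' @param mouth_dh Hydraulic diameter of the mouth inlet (m). The mouth-throat
#'   is a single lumped compartment characterized by this diameter.
#' @param mouth_length Path length of the mouth-throat compartment (m).
#' @param trachea_d Tracheal diameter (m).
#' @param trachea_L_over_d Tracheal length-to-diameter ratio.
#' @param bronchus_d Main (level-1) bronchus diameter (m); left and right main
#'   bronchi share it.
#' @param major_ratio,minor_ratio Child/parent diameter ratios for the major
#'   and minor daughter at levels 2-6; must lie in (0, 1].
#' @param L_over_d Length-to-diameter ratio of every conducting segment.
#' @param branching_angle Angle of every daughter branch from its parent axis
#'   (rad); the trachea and mouth-throat have zero branching angle.
#' @param gravity_angle_odd,gravity_angle_even Inclination of conducting
#'   segments from the horizontal plane (rad), alternating with level parity
#'   (odd levels 1,3,5 vs even levels 2,4,6).  Gravity acts along -Y; the
#'   trachea is vertical.
#' @param lobe_counts Named integer vector giving the number of terminal
#'   outlets per lobe.  The left main-bronchus subtree hosts LU and LL
#'   (summing to 32), the right subtree RU, RM and RL (summing to 32).
#'
#' @return An object of class `tree_config` (a validated list).
#' @examples
#' cfg <- tree_config()
#' cfg$bronchus_d
#' @export
tree_config <- function(mouth_dh = 0.019,
                        mouth_length = 0.17,
                        trachea_d = 0.016,
                        trachea_L_over_d = 6.25,
                        bronchus_d = 0.0108,
                        major_ratio = 0.86,
                        minor_ratio = 0.72,
                        L_over_d = 3,
                        branching_angle = 35 * pi / 180,
                        gravity_angle_odd = 20 * pi / 180,
                        gravity_angle_even = 50 * pi / 180,
                        lobe_counts = c(RU = 10, RM = 6, RL = 16,
                                        LU = 12, LL = 20)) {
  for (r in c(major_ratio = major_ratio, minor_ratio = minor_ratio)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0 || r > 1)
      stop("child/parent diameter ratios must lie in (0, 1]", call. = FALSE)
  }
  pos <- c(mouth_dh = mouth_dh, mouth_length = mouth_length,
           trachea_d = trachea_d, trachea_L_over_d = trachea_L_over_d,
           bronchus_d = bronchus_d, L_over_d = L_over_d)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all geometric dimensions and ratios must be positive", call. = FALSE)
  if (bronchus_d > trachea_d)
    stop("main bronchus diameter cannot exceed the tracheal diameter",
         call. = FALSE)
  if (branching_angle < 0 || branching_angle > pi / 2)
    stop("`branching_angle` must lie in [0, pi/2]", call. = FALSE)
  lobe_counts <- unlist(lobe_counts)
  needed <- c("RU", "RM", "RL", "LU", "LL")
  if (!setequal(names(lobe_counts), needed))
    stop("`lobe_counts` must be named RU, RM, RL, LU, LL", call. = FALSE)
  lobe_counts <- lobe_counts[needed]
  if (any(lobe_counts <= 0) || any(lobe_counts != round(lobe_counts)))
    stop("lobe outlet counts must be positive integers", call. = FALSE)
  if (sum(lobe_counts[c("LU", "LL")]) != 32L ||
      sum(lobe_counts[c("RU", "RM", "RL")]) != 32L)
    stop("lobe outlet counts must sum to 32 per lung (64 outlets)",
         call. = FALSE)
  structure(list(mouth_dh = mouth_dh, mouth_length = mouth_length,
                 trachea_d = trachea_d, trachea_L_over_d = trachea_L_over_d,
                 bronchus_d = bronchus_d, major_ratio = major_ratio,
                 minor_ratio = minor_ratio, L_over_d = L_over_d,
                 branching_angle = branching_angle,
                 gravity_angle_odd = gravity_angle_odd,
                 gravity_angle_even = gravity_angle_even,
                 lobe_counts = lobe_counts),
            class = "tree_config")
}

#' Build the adult reference airway tree
#'
#' Deterministically generates the 25-year-old tree: one mouth-throat
#' compartment (level -1), one vertical trachea (level 0) and six levels of
#' dichotomous branching ending in 64 lobe-labelled outlets.  Which daughter
#' is the major one alternates deterministically with the parent's index
#' within its level, so repeated builds are identical.
#'
#' @param config A [tree_config()] object.
#' @return An object of class `airway_tree`: a list with the segment table
#'   (`segments`), `age_label`, `scale_factor`, `mouth_hydraulic_diameter`
#'   (m), `mouth_inlet_area` (m^2, circular-inlet convention) and the
#'   generating `config`.
#' @examples
#' tr <- build_adult_tree()
#' subset(tr$segments, level <= 1)
#' @export
build_adult_tree <- function(config = tree_config()) {
  if (!inherits(config, "tree_config")) config <- do.call(tree_config, config)
  n_levels <- 6L
  n_seg <- 2L + (2L^(n_levels + 1L) - 2L)          # 128
  id <- seq_len(n_seg)
  region <- character(n_seg)
  level <- integer(n_seg)
  parent_id <- rep(NA_integer_, n_seg)
  lobe <- rep("NONE", n_seg)
  diameter <- numeric(n_seg)
  len <- numeric(n_seg)
  bang <- numeric(n_seg)
  gang <- numeric(n_seg)

  region[1] <- "MOUTH_THROAT"; level[1] <- -1L
  diameter[1] <- config$mouth_dh; len[1] <- config$mouth_length
  bang[1] <- 0; gang[1] <- 0

  region[2] <- "TRACHEA"; level[2] <- 0L; parent_id[2] <- 1L
  diameter[2] <- config$trachea_d
  len[2] <- config$trachea_L_over_d * config$trachea_d
  bang[2] <- 0; gang[2] <- pi / 2

  for (lv in seq_len(n_levels)) {
    start <- 2L^lv + 1L                            # first id of this level
    g_lv <- if (lv %% 2L == 1L) config$gravity_angle_odd
            else config$gravity_angle_even
    for (j in 0:(2L^lv - 1L)) {
      i <- start + j
      region[i] <- "CONDUCTING"; level[i] <- lv
      if (lv == 1L) {
        parent_id[i] <- 2L
        diameter[i] <- config$bronchus_d
      } else {
        pj <- j %/% 2L                             # parent index within level
        parent_id[i] <- 2L^(lv - 1L) + 1L + pj
        first_is_major <- (pj %% 2L == 0L)
        is_first <- (j %% 2L == 0L)
        ratio <- if (is_first == first_is_major) config$major_ratio
                 else config$minor_ratio
        diameter[i] <- diameter[parent_id[i]] * ratio
      }
      len[i] <- config$L_over_d * diameter[i]
      bang[i] <- config$branching_angle
      gang[i] <- g_lv
    }
  }

  # terminal (level-6) outlets: left subtree first (indices 0-31 descend from
  # the first main bronchus), then right; lobes fill LU,LL | RU,RM,RL in order
  lc <- config$lobe_counts
  lobe_terminal <- c(rep("LU", lc[["LU"]]), rep("LL", lc[["LL"]]),
                     rep("RU", lc[["RU"]]), rep("RM", lc[["RM"]]),
                     rep("RL", lc[["RL"]]))
  lobe[level == n_levels] <- lobe_terminal

  segments <- data.frame(id = id, region = region, level = level,
                         parent_id = parent_id, lobe = lobe,
                         length_m = len, diameter_m = diameter,
                         branching_angle_rad = bang,
                         gravity_angle_rad = gang,
                         stringsAsFactors = FALSE)
  structure(list(segments = segments,
                 age_label = 25,
                 scale_factor = 1,
                 mouth_hydraulic_diameter = config$mouth_dh,
                 mouth_inlet_area = pi * config$mouth_dh^2 / 4,
                 config = config),
            class = "airway_tree")
}

#' Homothetic scale factor for a tabulated age point
#'
#' Maps an age point to the uniform geometric scaling factor applied to the
#' adult airway tree: 0.578 at 5 years, 0.743 at 10 years, 1.0 at 25 years.
#' No interpolation between age points is attempted.
#'
#' @param age Age in years; one of 5, 10, 25.
#' @return The dimensionless scale factor.
#' @examples
#' age_scale_factor(5)
#' @export
age_scale_factor <- function(age) {
  tab <- c("5" = 0.578, "10" = 0.743, "25" = 1.0)
  key <- as.character(age)
  if (length(age) != 1L || is.na(age) || !key %in% names(tab))
    stop("age point not tabulated: ", age,
         " (supported age points: 5, 10, 25 years)", call. = FALSE)
  unname(tab[key])
}

#' Scale an airway tree homothetically
#'
#' Multiplies every segment length and diameter by `factor` (and the mouth
#' inlet area by `factor^2`); angles, topology and lobe labels are untouched.
#'
#' @param tree An `airway_tree`.
#' @param factor Positive scale factor.
#' @return The scaled `airway_tree`.
#' @export
scale_tree <- function(tree, factor) {
  stopifnot(inherits(tree, "airway_tree"))
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor <= 0)
    stop("`factor` must be a single positive number", call. = FALSE)
  tree$segments$length_m <- tree$segments$length_m * factor
  tree$segments$diameter_m <- tree$segments$diameter_m * factor
  tree$mouth_hydraulic_diameter <- tree$mouth_hydraulic_diameter * factor
  tree$mouth_inlet_area <- tree$mouth_inlet_area * factor^2
  tree$scale_factor <- tree$scale_factor * factor
  tree
}

#' Build the airway tree for an age point
#'
#' Convenience wrapper: builds the adult reference tree and scales it by the
#' homothetic factor of the requested age point.
#'
#' @param age Age in years (5, 10 or 25).
#' @param config A [tree_config()].
#' @return An `airway_tree` with `age_label` set to `age`.
#' @examples
#' tr5 <- airway_tree(5)
#' tr5$mouth_hydraulic_diameter  # ~11 mm
#' @export
airway_tree <- function(age = 25, config = tree_config()) {
  f <- age_scale_factor(age)
  tree <- scale_tree(build_adult_tree(config), f)
  tree$age_label <- age
  tree
}

#' Terminal outlet ids of a tree
#' @param tree An `airway_tree`.
#' @return Integer vector of the 64 terminal segment ids, in id order.
#' @export
terminal_ids <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  tree$segments$id[tree$segments$level == max(tree$segments$level)]
}

#' Path from the mouth to a terminal outlet
#'
#' @param tree An `airway_tree`.
#' @param outlet_id Id of a terminal segment.
#' @return The segment table rows along the path, ordered mouth-throat,
#'   trachea, then one segment per bronchial level down to the outlet
#'   (8 rows).
#' @export
path_to_outlet <- function(tree, outlet_id) {
  stopifnot(inherits(tree, "airway_tree"))
  segs <- tree$segments
  if (!outlet_id %in% terminal_ids(tree))
    stop("segment ", outlet_id, " is not a terminal outlet", call. = FALSE)
  path <- integer(0)
  cur <- outlet_id
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- segs$parent_id[segs$id == cur]
  }
  segs[match(path, segs$id), , drop = FALSE]
}

# 64 x 8 matrix of segment ids: row k = path (mouth-throat, trachea,
# levels 1..6) to the k-th terminal outlet in id order.
.path_matrix <- function(tree) {
  segs <- tree$segments
  term <- terminal_ids(tree)
  n_levels <- max(segs$level)
  pm <- matrix(NA_integer_, nrow = length(term), ncol = n_levels + 2L)
  pm[, n_levels + 2L] <- term
  for (col in (n_levels + 1L):1L) {
    pm[, col] <- segs$parent_id[match(pm[, col + 1L], segs$id)]
  }
  pm
}

#' Write / read an airway segment table
#'
#' Plain-CSV serialization of the per-segment geometry, deterministic row
#' order by id.  `read_airway_csv()` restores a full `airway_tree` object;
#' `age_label` and `scale_factor` are not stored in the table and come back
#' as `NA` unless supplied.
#'
#' @param tree An `airway_tree`.
#' @param path File path.
#' @param age_label,scale_factor Optional metadata to attach on read.
#' @return `write_airway_csv()` returns `path` invisibly; `read_airway_csv()`
#'   returns an `airway_tree`.
#' @export
write_airway_csv <- function(tree, path) {
  stopifnot(inherits(tree, "airway_tree"))
  segs <- tree$segments[order(tree$segments$id), ]
  utils::write.csv(segs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_airway_csv
#' @export
read_airway_csv <- function(path, age_label = NA_real_,
                            scale_factor = NA_real_) {
  segs <- utils::read.csv(path, stringsAsFactors = FALSE)
  segs <- segs[order(segs$id), ]
  mouth <- segs[segs$region == "MOUTH_THROAT", ]
  if (nrow(mouth) != 1L)
    stop("segment table must contain exactly one MOUTH_THROAT row",
         call. = FALSE)
  structure(list(segments = segs,
                 age_label = age_label,
                 scale_factor = scale_factor,
                 mouth_hydraulic_diameter = mouth$diameter_m,
                 mouth_inlet_area = pi * mouth$diameter_m^2 / 4,
                 config = NULL),
            class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  segs <- x$segments
  term <- segs$level == max(segs$level)
  cat("Idealized airway tree (age ", x$age_label, " y, scale factor ",
      signif(x$scale_factor, 4), ")\n", sep = "")
  cat("  segments: ", nrow(segs), " (", sum(term), " terminal outlets)\n",
      sep = "")
  cat("  mouth Dh: ", signif(1e3 * x$mouth_hydraulic_diameter, 4),
      " mm | trachea d: ",
      signif(1e3 * segs$diameter_m[segs$region == "TRACHEA"], 4),
      " mm | main bronchi d: ",
      signif(1e3 * segs$diameter_m[segs$level == 1][1], 4), " mm\n", sep = "")
  cat("  outlets per lobe: ",
      paste(names(table(segs$lobe[term])), table(segs$lobe[term]),
            sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.airway_tree <- function(object, ...) {
  segs <- object$segments
  by_level <- split(segs$diameter_m, segs$level)
  out <- data.frame(level = as.integer(names(by_level)),
                    n = lengths(by_level),
                    d_min_mm = 1e3 * vapply(by_level, min, 0),
                    d_max_mm = 1e3 * vapply(by_level, max, 0))
  rownames(out) <- NULL
  out
}
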