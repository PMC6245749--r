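test_that("mouth-throat sigmoid has the calibrated midpoint and tail", {
  expect_equal(mouth_throat_efficiency(0), 0)
  expect_equal(mouth_throat_efficiency(0.075), 0.5)
  # hand-evaluated Hill form: 0.1^9 / (0.1^9 + 0.075^9)
  expect_equal(mouth_throat_efficiency(0.1), 0.930160, tolerance = 1e-5)
  expect_equal(mouth_throat_efficiency(100), 1, tolerance = 1e-9)
  # monotone over a dense grid
  grid <- seq(0, 0.5, length.out = 200)
  expect_true(all(diff(mouth_throat_efficiency(grid)) >= 0))
  expect_error(mouth_throat_efficiency(-0.1), "non-negative")
})

test_that("impaction closure matches hand evaluation and its limits", {
  prt <- particle_spec(5e-6)
  # straight entry (trachea) collects nothing by impaction
  expect_equal(impaction_probability(fake_segment(0.016,
                                                  branching_angle_rad = 0),
                                     10, prt), 0)
  # vanishes with particle size
  expect_lt(impaction_probability(fake_segment(0.0062), 1,
                                  particle_spec(1e-8)), 1e-5)
  # 1 - exp(-6 * 0.611 * 0.18) evaluated by hand, via a segment solved to
  # give Stk_seg = 0.18 exactly: U = 0.18 * 18 mu d / (rho dp^2 Cc)
  dp <- 5e-6; cc <- slip_correction(dp)
  u <- 0.18 * 18 * 1.81e-5 * 0.0062 / (1000 * dp^2 * cc)
  expect_equal(impaction_probability(fake_segment(0.0062), u,
                                     particle_spec(dp)),
               0.48307, tolerance = 1e-4)
})

test_that("sedimentation closure matches hand evaluation and its limits", {
  # dp = 10 um, L = 20 mm, d = 6.2 mm, U = 1 m/s, horizontal tube:
  # v_ts = 3.06 mm/s and P_S = 1 - exp(-4 v_ts L / (pi d U)) = 0.0125
  seg <- fake_segment(0.0062, length_m = 0.02, gravity_angle_rad = 0)
  expect_equal(sedimentation_probability(seg, 1, particle_spec(10e-6)),
               0.0125, tolerance = 2e-3)
  vert <- fake_segment(0.0062, gravity_angle_rad = pi / 2)
  expect_lt(sedimentation_probability(vert, 1, particle_spec(10e-6)), 1e-12)
  expect_lt(sedimentation_probability(seg, 1, particle_spec(1e-8)), 1e-6)
  expect_error(sedimentation_probability(seg, 0, particle_spec(10e-6)),
               "positive")
})

test_that("release times follow the device injection protocols", {
  rel <- sample_release_times(dpi5, 5000, seed = 3)
  expect_gte(min(rel), 0.45)
  expect_lte(max(rel), 0.6)
  expect_length(sample_release_times(dpi5, 1, seed = 3), 1L)

  n <- 1e5
  rel <- sample_release_times(neb5, n, seed = 3)
  expect_gte(min(rel), 0)
  expect_lte(max(rel), neb5$t_insp)
  se <- neb5$t_insp / sqrt(12) / sqrt(n)
  expect_lt(abs(mean(rel) - neb5$t_insp / 2), 3 * se)

  # flow-weighted variant concentrates mass where the flow is strong
  relw <- sample_release_times(neb5, n, seed = 3, weight = "flow",
                               profile = profile_neb5)
  expect_lt(sd(relw), sd(rel))
  expect_error(sample_release_times(dpi5, 0), "positive")
})

test_that("lobar flow weighting conserves flow through the tree", {
  ff <- flow_dpi5
  segs <- tree5$segments
  expect_equal(unname(ff$fraction[["2"]]), 1, tolerance = 1e-12)
  expect_equal(sum(ff$fraction[as.character(terminal_ids(tree5))]), 1,
               tolerance = 1e-12)
  # every RM outlet carries 0.07 / 6
  rm_ids <- segs$id[segs$lobe == "RM"]
  expect_equal(unname(ff$fraction[as.character(rm_ids)]),
               rep(0.07 / 6, 6))
  # junction conservation everywhere
  for (lv in 0:5) {
    at <- segs$id[segs$level == lv]
    for (i in at) {
      kids <- segs$id[!is.na(segs$parent_id) & segs$parent_id == i]
      expect_equal(unname(ff$fraction[[as.character(i)]]),
                   sum(ff$fraction[as.character(kids)]),
                   tolerance = 1e-12)
    }
  }
  # lobar sums reproduce the physiological fractions exactly
  term <- segs[segs$level == 6, ]
  sums <- tapply(ff$fraction[as.character(term$id)], term$lobe, sum)
  expect_equal(as.numeric(sums[c("LU", "LL", "RU", "RM", "RL")]),
               c(0.15, 0.31, 0.14, 0.07, 0.33), tolerance = 1e-12)
  expect_error(distribute_flow(tree5, lobar_fractions = c(
    LU = 0.2, LL = 0.31, RU = 0.14, RM = 0.07, RL = 0.33)), "sum to 1")
})

test_that("the oracle is a total-probability decomposition", {
  for (dp in c(1e-6, 5e-6, 10e-6)) {
    or <- expected_deposition(tree5, flow_dpi5,
                              particle_spec(dp, release_time = 0.5))
    expect_equal(sum(or), 1, tolerance = 1e-12)
    expect_true(all(or >= 0))
  }
  # vanishing inertia and settling: everything escapes
  tiny <- expected_deposition(tree5, flow_dpi5,
                              particle_spec(1e-9, release_time = 0.5))
  expect_gt(tiny[["escaped"]], 0.999)
  # saturation: very coarse particles are filtered at the mouth-throat
  coarse <- expected_deposition(tree5, flow_dpi5,
                                particle_spec(100e-6, release_time = 0.5))
  expect_gt(coarse[["mouth_throat"]], 0.999)
  # release after flow cessation: nothing deposits
  late <- expected_deposition(tree5, flow_dpi5,
                              particle_spec(5e-6, release_time = 10))
  expect_equal(late[["escaped"]], 1)
})

test_that("oracle regional probabilities are monotone in particle size", {
  dps <- seq(1, 12, by = 0.5) * 1e-6
  ors <- t(vapply(dps, function(d)
    expected_deposition(tree5, flow_dpi5,
                        particle_spec(d, release_time = 0.5)),
    numeric(4)))
  expect_true(all(diff(ors[, "mouth_throat"]) >= -1e-12))
  total <- 1 - ors[, "escaped"]
  expect_true(all(diff(total) >= -1e-12))
})

test_that("Monte-Carlo efficiencies converge to the oracle", {
  or <- expected_deposition(tree5, flow_dpi5,
                            particle_spec(5e-6, release_time = 0.5))
  for (n in c(1e3, 1e4)) {
    mc <- simulate_deposition(tree5, flow_dpi5,
                              particle_ensemble(5e-6, rep(0.5, n)),
                              seed = 42)
    se <- sqrt(or * (1 - or) / n)
    expect_true(all(abs(mc$efficiencies - or) <= 4 * pmax(se, 1e-12)),
                label = paste("n =", n))
  }
})

test_that("simulated counts are conserved and reproducible", {
  ens <- particle_ensemble(6e-6, sample_release_times(dpi5, 4000, seed = 1))
  a <- simulate_deposition(tree5, flow_dpi5, ens, seed = 9)
  b <- simulate_deposition(tree5, flow_dpi5, ens, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$per_segment, b$per_segment)
  expect_equal(sum(a$counts), a$injected)
  expect_equal(sum(a$escaped_by_lobe), a$counts[["escaped"]])
  expect_equal(sum(a$per_segment),
               a$injected - a$counts[["escaped"]])
  expect_equal(sum(a$efficiencies), 1, tolerance = 1e-12)
  # the trachea is vertical with straight entry: it collects nothing
  expect_equal(a$counts[["trachea"]], 0L)
  expect_error(simulate_deposition(tree5, distribute_flow(tree5), ens),
               "profile")
})

test_that("small particles deposit weakly, per the oracle's expectation", {
  # both deposition mechanisms vanish quadratically in dp; at 1 um the
  # mouth-throat filter is negligible and the conducting deposit is the
  # residue of many small impaction trials (oracle-frozen values)
  or <- expected_deposition(tree5, flow_dpi5,
                            particle_spec(1e-6, release_time = 0.5))
  expect_lt(or[["mouth_throat"]], 0.001)
  expect_equal(or[["conducting"]], 0.1457, tolerance = 1e-3)
  or25 <- expected_deposition(airway_tree(25),
                              distribute_flow(airway_tree(25),
                                              dpi_profile(maneuver_params(25, "DPI"))),
                              particle_spec(1e-6, release_time = 0.5))
  expect_lt(or25[["conducting"]], or[["conducting"]])
})
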