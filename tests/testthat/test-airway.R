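test_that("adult reference tree matches the anchor morphometry", {
  segs <- adult_tree$segments
  expect_equal(adult_tree$mouth_hydraulic_diameter, 0.019)
  expect_equal(segs$diameter_m[segs$region == "TRACHEA"], 0.016)
  expect_equal(unique(segs$diameter_m[segs$level == 1]), 0.0108)
  expect_equal(adult_tree$mouth_inlet_area, pi * 0.019^2 / 4)

  term <- segs[segs$level == 6, ]
  expect_equal(nrow(term), 64L)
  expect_setequal(unique(term$lobe), c("RU", "RM", "RL", "LU", "LL"))
  expect_equal(as.vector(table(term$lobe)[c("RU", "RM", "RL", "LU", "LL")]),
               c(10, 6, 16, 12, 20))
  expect_true(all(segs$lobe[segs$level < 6] == "NONE"))

  # topology: exactly one mouth-throat and one trachea, 0 or 2 children
  expect_equal(sum(segs$region == "MOUTH_THROAT"), 1L)
  expect_equal(sum(segs$region == "TRACHEA"), 1L)
  kids <- table(factor(segs$parent_id, levels = segs$id))
  expect_equal(kids[["1"]], 1L)  # mouth-throat feeds the trachea
  expect_true(all(kids[names(kids) != "1"] %in% c(0L, 2L)))

  # physiologic taper: no child wider than its parent
  has_parent <- !is.na(segs$parent_id)
  expect_true(all(segs$diameter_m[has_parent] <=
                    segs$diameter_m[match(segs$parent_id[has_parent],
                                          segs$id)]))
  # determinism
  expect_identical(build_adult_tree(), adult_tree)
})

test_that("symmetric diameter ratios give identical diameters per level", {
  tr <- build_adult_tree(tree_config(major_ratio = 0.8, minor_ratio = 0.8))
  per_level <- split(tr$segments$diameter_m, tr$segments$level)
  expect_true(all(vapply(per_level,
                         function(d) diff(range(d)) < 1e-15, TRUE)))
})

test_that("invalid geometry configuration is rejected", {
  expect_error(tree_config(major_ratio = 0), "ratios")
  expect_error(tree_config(minor_ratio = 1.2), "ratios")
  expect_error(tree_config(trachea_d = -1), "positive")
  expect_error(tree_config(lobe_counts = c(RU = 16, RM = 6, RL = 10,
                                           LU = 16, LL = 20)),
               "sum to 32")
})

test_that("age scale factors follow the tabulated homothetic factors", {
  expect_equal(age_scale_factor(25), 1.0)
  expect_equal(age_scale_factor(5), 0.578)
  expect_equal(age_scale_factor(10), 0.743)
  expect_error(age_scale_factor(7), "not tabulated")
  # scaled mouth diameters land on the reference table (0.3 mm rounding)
  expect_equal(0.578 * 19, 11, tolerance = 0.3 / 11)
  expect_equal(0.743 * 19, 14, tolerance = 0.3 / 14)
  expect_equal(0.578 * 10.8, 6.2, tolerance = 0.3 / 6.2)
  expect_equal(0.743 * 10.8, 8, tolerance = 0.3 / 8)
})

test_that("homothetic scaling is exactly self-similar", {
  f <- 0.578
  tr <- scale_tree(adult_tree, f)
  expect_equal(tr$segments$diameter_m, adult_tree$segments$diameter_m * f)
  expect_equal(tr$segments$length_m, adult_tree$segments$length_m * f)
  expect_equal(tr$mouth_inlet_area, adult_tree$mouth_inlet_area * f^2)
  expect_equal(tr$scale_factor, f)
  # angles, topology and lobe labels untouched
  expect_identical(tr$segments$gravity_angle_rad,
                   adult_tree$segments$gravity_angle_rad)
  expect_identical(tr$segments$lobe, adult_tree$segments$lobe)
  # identity and composition
  expect_identical(scale_tree(adult_tree, 1), adult_tree)
  expect_error(scale_tree(adult_tree, 0), "positive")
  # total path length scales linearly for every outlet
  p_adult <- path_to_outlet(adult_tree, terminal_ids(adult_tree)[1])
  p_child <- path_to_outlet(tr, terminal_ids(tr)[1])
  expect_equal(sum(p_child$length_m), f * sum(p_adult$length_m))
})

test_that("mouth-to-outlet paths have the expected structure", {
  term <- terminal_ids(adult_tree)
  for (ot in term[c(1, 33, 64)]) {
    p <- path_to_outlet(adult_tree, ot)
    expect_equal(nrow(p), 8L)
    expect_equal(p$region[1:2], c("MOUTH_THROAT", "TRACHEA"))
    expect_equal(p$level, -1:6)
  }
  # an RM outlet descends through the right main bronchus subtree
  segs <- adult_tree$segments
  rm_outlet <- segs$id[segs$lobe == "RM"][1]
  p <- path_to_outlet(adult_tree, rm_outlet)
  right_main <- segs$id[segs$level == 1][2]
  expect_true(right_main %in% p$id)
  expect_error(path_to_outlet(adult_tree, 2), "terminal")
})

test_that("segment tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_airway_csv(tree5, path)
  back <- read_airway_csv(path, age_label = 5, scale_factor = 0.578)
  expect_equal(back$segments$diameter_m, tree5$segments$diameter_m)
  expect_equal(back$segments$lobe, tree5$segments$lobe)
  expect_equal(back$mouth_hydraulic_diameter,
               tree5$mouth_hydraulic_diameter)
})
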