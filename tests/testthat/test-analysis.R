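test_that("slip correction matches the standard form at anchor sizes", {
  expect_equal(slip_correction(1e-6), 1.166, tolerance = 1e-3)
  expect_equal(slip_correction(10e-6), 1.017, tolerance = 1e-3)
  expect_equal(slip_correction(1), 1, tolerance = 1e-6)
  expect_true(all(slip_correction(c(1, 5, 20) * 1e-6) >= 1))
  expect_error(slip_correction(0), "positive")
})

test_that("Stokes numbers reproduce the derived scenario anchors", {
  ctx5d <- stokes_context_for(5, "DPI")
  expect_equal(ctx5d$Um, 7.02, tolerance = 0.01)
  expect_equal(ctx5d$Do, 0.010982)
  expect_equal(stokes_number(5.5e-6, ctx5d), 0.061, tolerance = 0.01)
  ctx5n <- stokes_context_for(5, "NEBULIZER")
  expect_equal(ctx5n$Um, 0.91, tolerance = 0.01)
  expect_equal(stokes_number(12e-6, ctx5n), 0.037, tolerance = 0.01)
  expect_equal(stokes_number(0, ctx5d), 0)
  expect_error(stokes_context(Um = -1, Do = 0.019), "positive")
})

test_that("mouth-inlet Reynolds numbers at DPI peak flow are recovered", {
  d_mouth <- 0.019 * c(0.578, 0.743, 1)
  re <- reynolds_number(c(40, 60, 90) / 60000, d_mouth)
  expect_equal(re, c(5000, 5800, 6500), tolerance = 0.1)
  expect_equal(reynolds_number(0, 0.019), 0)
})

test_that("Eq-1 inversion round-trips over the therapeutic size range", {
  for (device in c("DPI", "NEBULIZER")) {
    for (age in all_ages) {
      ctx <- stokes_context_for(age, device)
      for (dp in c(1, 5, 12, 20) * 1e-6) {
        stk <- stokes_number(dp, ctx)
        expect_equal(optimal_diameter(stk, ctx), dp, tolerance = 1e-4)
      }
    }
  }
  ctx <- stokes_context_for(5, "DPI")
  expect_equal(optimal_diameter(1e-12, ctx), 0, tolerance = 1e-8)
  expect_equal(optimal_diameter(0, ctx), 0)
})

test_that("efficiency curves pool results on the Stokes axis", {
  res <- structure(list(age = 5, device = "DPI", dp = 5e-6, injected = 100,
                        efficiencies = c(mouth_throat = 0.1, trachea = 0,
                                         conducting = 0.6, escaped = 0.3)),
                   class = "deposition_result")
  ctx <- stokes_context_for(5, "DPI")
  cv <- efficiency_curve(list(res), "conducting", ctx)
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$efficiency, 0.6)
  expect_equal(cv$stk, stokes_number(5e-6, ctx))
  cv_tot <- efficiency_curve(list(res), "total", ctx)
  expect_equal(cv_tot$efficiency, 0.7)
  expect_error(efficiency_curve(list(), "conducting", ctx), "empty")
  res2 <- res; res2$device <- "NEBULIZER"
  expect_error(efficiency_curve(list(res, res2), "conducting", ctx),
               "one device")
  # matched-Stk design: per-age diameters equalize the abscissa
  ctxs <- all_contexts("DPI")
  dps <- vapply(ctxs, function(cx) optimal_diameter(0.06, cx), 0)
  stks <- mapply(function(d, cx) stokes_number(d, cx), dps, ctxs)
  expect_true(all(abs(stks - 0.06) < 0.06 * 2e-4))
})

test_that("Gaussian fitting recovers exact and noisy synthetic peaks", {
  mk_curve <- function(eff, stk) {
    structure(data.frame(stk = stk, efficiency = eff, dp = stk, age = 5),
              region = "conducting", device = "DPI",
              class = c("efficiency_curve", "data.frame"))
  }
  stk <- seq(0.01, 0.15, length.out = 20)
  true <- c(A = 0.8, m = 0.06, s = 0.02)
  eff <- true["A"] * exp(-(stk - true["m"])^2 / (2 * true["s"]^2))
  fit <- fit_gaussian(mk_curve(eff, stk))
  expect_equal(fit$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(fit$peak_stk, 0.06, tolerance = 1e-6)
  expect_equal(fit$sigma_stk, 0.02, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)

  set.seed(99)
  n_bad_A <- 0; n_bad_m <- 0; reps <- 100
  for (r in seq_len(reps)) {
    noisy <- pmax(eff + runif(20, -0.02, 0.02), 0)
    f <- fit_gaussian(mk_curve(noisy, stk))
    if (abs(f$amplitude - 0.8) > 0.05) n_bad_A <- n_bad_A + 1
    if (abs(f$peak_stk - 0.06) > 0.005) n_bad_m <- n_bad_m + 1
  }
  expect_equal(n_bad_A, 0)
  expect_equal(n_bad_m, 0)
})

test_that("Gaussian fitting rejects degenerate inputs", {
  mono <- structure(data.frame(stk = seq(0.01, 0.2, length.out = 10),
                               efficiency = seq(0.05, 0.95,
                                                length.out = 10),
                               dp = 1:10, age = 5),
                    region = "mouth_throat", device = "DPI",
                    class = c("efficiency_curve", "data.frame"))
  expect_error(fit_gaussian(mono), "no interior peak")
  short <- mono[1:4, ]
  expect_error(fit_gaussian(short), "at least 5")
})

test_that("collapse diagnostic is zero for identical curves and guards", {
  stk <- seq(0.01, 0.1, length.out = 10)
  mk <- function(eff, stk) structure(
    data.frame(stk = stk, efficiency = eff, dp = stk, age = 5),
    region = "conducting", device = "DPI",
    class = c("efficiency_curve", "data.frame"))
  a <- mk(mouth_throat_efficiency(stk), stk)
  expect_equal(collapse_diagnostic(list(a, a, a)), 0)
  b <- mk(mouth_throat_efficiency(stk) + 0.03, stk)
  expect_equal(collapse_diagnostic(list(a, b)), 0.03, tolerance = 1e-9)
  far <- mk(rep(0.5, 10), stk + 10)
  expect_error(collapse_diagnostic(list(a, far)), "non-overlapping")
  expect_error(collapse_diagnostic(list(a)), "at least two")
})
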