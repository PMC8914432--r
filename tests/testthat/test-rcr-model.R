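test_that("survival evaluation matches closed-form arithmetic and S(0) = 1", {
  expect_identical(rcr_survival(toy_params(), 0), 1)
  for (p in random_params(10, seed = 42)) {
    expect_identical(rcr_survival(p, 0), 1)
  }
  # pure exponential branch
  expect_equal(rcr_survival(rcr_params(0.5, 0, 1), 2), exp(-1), tolerance = 1e-12)
  # full model at d = 2: e^-1 + 2 e^-2
  expect_equal(rcr_survival(rcr_params(0.5, 1, 1), 2), exp(-1) + 2 * exp(-2),
               tolerance = 1e-12)
  # fitted-value aliases at the conventional doses
  expect_equal(rcr_survival(rcr_params(0.5, 0, 1), 2), exp(-1), tolerance = 1e-12)
  expect_equal(rcr_survival(toy_params(), 3.5),
               exp(-1.4) + 2.8 * exp(-4.2), tolerance = 1e-12)
  expect_error(rcr_survival(toy_params(), -1), "non-negative")
  expect_error(rcr_params(-0.1, 0, 1), "`a`")
  expect_error(rcr_params(0.1, -1, 1), "`b`")
  expect_error(rcr_params(0.1, 0, 0), "`c`")
})

test_that("SF3.5 < SF2 across a sweep of valid parameters", {
  for (p in random_params(50, seed = 7)) {
    expect_lt(rcr_survival(p, 3.5), rcr_survival(p, 2))
  }
})

test_that("surviving fraction from counts is the PE-normalised ratio", {
  expect_equal(compute_sf(50, 100, 0.5), 1.0)
  expect_equal(compute_sf(25, 1000, 0.1), 0.25)
  expect_equal(compute_sf(0, 1000, 0.3), 0)
  # noisy counts may exceed 1 and are not clipped
  expect_gt(compute_sf(80, 100, 0.5), 1)
  expect_error(compute_sf(10, 100, 0), "plating_efficiency")
  expect_error(compute_sf(10, 100, -0.2), "plating_efficiency")
})

test_that("fit recovers exact parameters from noise-free model data", {
  d <- c(0, 1, 2, 4, 6, 8)
  truth <- toy_params()
  fit <- fit_rcr(data.frame(dose = d, sf = rcr_survival(truth, d)))
  expect_true(fit$converged)
  est <- tidy(fit)$estimate
  expect_equal(est, c(0.4, 0.8, 1.2), tolerance = 1e-4)
  expect_lt(glance(fit)$rss_log, 1e-8)
})

test_that("fit collapses to a pure exponential when the data are log-linear", {
  d <- c(0, 1, 2, 4, 6, 8)
  fit <- fit_rcr(data.frame(dose = d, sf = exp(-0.5 * d)))
  expect_equal(fit$params$a, 0.5, tolerance = 1e-4)
  expect_equal(fit$params$b, 0, tolerance = 1e-4)
})

test_that("fit validates its inputs", {
  expect_error(fit_rcr(data.frame(dose = c(0, 1, 2), sf = c(1, 0.8, 0.5))),
               "4 distinct dose levels")
  expect_warning(
    fit_rcr(data.frame(dose = c(0, 1, 2, 4, 6, 8),
                       sf = c(1, 0.7, 0.5, 0.2, 0.05, 0))),
    "SF = 0")
  expect_error(fit_rcr(data.frame(dose = c(0, 1, 2, 4), sf = c(1, 0.5, -0.1, 0.2))),
               "non-negative")
})

test_that("fit recovers truth within 5% from Poisson-simulated assays", {
  truth <- toy_params()
  design <- clonogenic_design(cells_seeded = 1e5, replicates = 3, seed = 2)
  records <- clonogenic_sf(simulate_clonogenic(truth, design))
  fit <- fit_rcr(records, dose = dose_Gy, sf = sf)
  est <- tidy(fit)$estimate
  expect_equal(est[1], truth$a, tolerance = 0.05)
  expect_equal(est[2], truth$b, tolerance = 0.05)
  expect_equal(est[3], truth$c, tolerance = 0.05)
})

test_that("dose at target survival inverts the curve", {
  # closed form: pure exponential, D10 = ln(10)/a
  expect_equal(dose_at_survival(rcr_params(log(10) / 5, 0, 1), 0.1), 5,
               tolerance = 1e-9)
  # brute-force dense-grid oracle for the full model
  p <- toy_params()
  d10 <- dose_at_survival(p, 0.1)
  expect_equal(d10, grid_scan_dose(p, 0.1), tolerance = 2e-4)
  # round trip within 1e-9 across random parameters and targets
  for (p in random_params(10, seed = 11)) {
    for (s in c(0.5, 0.1, 0.01)) {
      expect_equal(rcr_survival(p, dose_at_survival(p, s)), s,
                   tolerance = 1e-9)
    }
  }
  expect_error(dose_at_survival(p, 1.2), "in \\(0, 1\\)")
  expect_error(dose_at_survival(p, 0), "in \\(0, 1\\)")
})

test_that("closed-form mean inactivation dose matches quadrature", {
  expect_equal(mean_inactivation_dose_param(rcr_params(0.5, 0, 1)), 2)
  expect_equal(mean_inactivation_dose_param(rcr_params(0.5, 1, 1)), 3)
  for (p in random_params(10, seed = 13)) {
    quad <- stats::integrate(function(d) rcr_survival(p, d), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(mean_inactivation_dose_param(p), quad, tolerance = 1e-6)
  }
  expect_error(mean_inactivation_dose_param(rcr_params(0, 1, 1)), "diverges")
})

test_that("trapezoidal mean inactivation dose converges to the closed form", {
  expect_equal(mean_inactivation_dose_auc(rcr_params(0.5, 0, 1),
                                          d_max = 200, step = 0.01),
               2, tolerance = 1e-3)
  p <- rcr_params(0.5, 1, 1)
  expect_equal(mean_inactivation_dose_auc(p), 3, tolerance = 1e-3)
  # monotone convergence as the step shrinks (trapezoid underestimates the
  # convex tail, so error decreases monotonically toward the closed form)
  steps <- c(1, 0.3, 0.1, 0.03, 0.01)
  errs <- vapply(steps, function(st) {
    abs(mean_inactivation_dose_auc(p, d_max = 60, step = st) -
          mean_inactivation_dose_param(p))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # coarse grids are systematically less accurate: the leading composite
  # trapezoid error is (h^2/12)(a - b), so its sign flips with a vs b but
  # its magnitude always shrinks with the step
  for (p in random_params(10, seed = 17)) {
    ref <- mean_inactivation_dose_param(p)
    expect_gt(abs(mean_inactivation_dose_auc(p, d_max = 60, step = 1) - ref),
              abs(mean_inactivation_dose_auc(p, d_max = 60, step = 0.01) - ref))
  }
  expect_error(mean_inactivation_dose_auc(p, d_max = 1, step = 2), "step")
})

test_that("limiting slope D0 approaches 1/min(a, c) on distal windows", {
  # log-linear curve: D0 exact at any window
  expect_equal(limiting_slope_d0(rcr_params(0.5, 0, 1), c(1, 5)), 2,
               tolerance = 1e-9)
  # slow mode c < a dominates distally; ln S ~ ln(bd) - cd there, so the
  # 1/d correction to the slope only drops below 1% for d >~ 200/c
  expect_equal(limiting_slope_d0(rcr_params(2, 1, 0.5), c(400, 600)), 2,
               tolerance = 0.01)
  # other branch: a < c, the pure exponential mode has no 1/d correction
  expect_equal(limiting_slope_d0(rcr_params(0.5, 1, 2), c(20, 30)), 2,
               tolerance = 0.01)
  for (p in random_params(10, seed = 19)) {
    if (abs(p$a - p$c) < 0.2) next # mixed-mode windows converge too slowly
    w <- c(200, 300) / min(p$a, p$c)
    expect_equal(limiting_slope_d0(p, w), 1 / min(p$a, p$c),
                 tolerance = 0.011)
  }
  expect_error(limiting_slope_d0(toy_params(), c(5, 2)), "window")
})

test_that("survival metrics assemble coherently from a fit", {
  d <- c(0, 1, 2, 4, 6, 8)
  truth <- toy_params()
  fit <- fit_rcr(data.frame(dose = d, sf = rcr_survival(truth, d)))
  m <- survival_metrics(fit)
  expect_equal(m$sf2, rcr_survival(truth, 2), tolerance = 1e-4)
  expect_lt(m$sf35, m$sf2)
  expect_equal(m$dbar_auc, m$dbar_param, tolerance = 1e-3)
  expect_lt(m$dbar_auc, m$dbar_param) # finite trapezoid underestimates
  expect_true(all(unlist(m) > 0))
  expect_error(survival_metrics(toy_params()), "d_max")
})

test_that("grouped curve fitting returns one row of metrics per curve", {
  truth <- list(gamma = rcr_params(0.4, 0.3, 1.0),
                carbon = rcr_params(0.9, 0.5, 1.8))
  records <- dplyr::bind_rows(
    clonogenic_sf(simulate_clonogenic(
      truth$gamma, clonogenic_design(cells_seeded = 1e5, seed = 21),
      cell_line = "L1", quality = "gamma")),
    clonogenic_sf(simulate_clonogenic(
      truth$carbon,
      clonogenic_design(doses = c(0, 0.5, 1, 2, 4, 6), cells_seeded = 1e5,
                        seed = 22),
      cell_line = "L1", quality = "carbon")))
  fits <- fit_survival_curves(records)
  expect_equal(nrow(fits), 2)
  expect_true(all(c("a", "b", "c", "sf2", "sf35", "d10", "dbar_param",
                    "dbar_auc", "d0") %in% names(fits)))
  carbon <- fits[fits$quality == "carbon", ]
  gamma <- fits[fits$quality == "gamma", ]
  expect_lt(carbon$d10, gamma$d10) # ions kill more per Gy
})

test_that("plating efficiency comes from dose-0 controls and is required", {
  records <- simulate_clonogenic(toy_params(),
                                 clonogenic_design(plating_efficiency = 0.4,
                                                   cells_seeded = 1e5,
                                                   seed = 23))
  withsf <- clonogenic_sf(records)
  expect_equal(unique(withsf$plating_efficiency), 0.4, tolerance = 0.01)
  sf0 <- withsf$sf[withsf$dose_Gy == 0]
  expect_equal(mean(sf0), 1, tolerance = 1e-6) # controls recover SF ~= 1
  no0 <- records[records$dose_Gy > 0, ]
  expect_error(clonogenic_sf(no0), "dose-0")
})
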