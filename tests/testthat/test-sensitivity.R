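test_that("sweep at the baseline value reproduces the baseline ICER", {
  p <- default_parameters()
  base <- p$tests$colotect$compliance
  sp <- sweep_spec("colotect.compliance", base, base + 1e-9, steps = 2)
  sw <- one_way_sweep(sp, "colotect", "none", p, fx_inc(), fx_life())
  rs <- fx_run("colotect"); rr <- fx_run("none")
  baseline_icer <- (rs$costs[["total"]] - rr$costs[["total"]]) /
    (rr$life_years_lost - rs$life_years_lost)
  expect_identical(sw$icer[1], baseline_icer)          # bit-for-bit
  expect_equal(sw$icer[2], sw$icer[1], tolerance = 1e-6)  # continuity
})

test_that("a parameter without model influence sweeps to a constant ICER", {
  # per-polypectomy bleeding rate is inert under the per-colonoscopy basis
  sp <- sweep_spec("procedure.bleeding_rate_per_polypectomy", 0.001, 0.05,
                   steps = 3)
  sw <- one_way_sweep(sp, "colotect", "none", default_parameters(),
                      fx_inc(), fx_life())
  expect_equal(diff(sw$icer), c(0, 0))
})

test_that("sweep_spec validates its inputs", {
  expect_error(sweep_spec("fit.banana", 0, 1), "unknown parameter")
  expect_error(sweep_spec("fit.compliance", 0.8, 0.2), "low must be")
  expect_error(sweep_spec("fit.compliance", 0.2, 0.8, steps = 1), "steps")
  expect_error(one_way_sweep(sweep_spec("fit.sensitivity", 0.5, 1.5),
                             "fit", "none", default_parameters(),
                             fx_inc(), fx_life()),
               "out of range|invalid")
})

test_that("tornado orders bars, is permutation-invariant, non-negative", {
  p <- default_parameters()
  specs <- list(sweep_spec("colotect.specificity", 0.736, 1),
                sweep_spec("colotect.compliance", 0.776, 1),
                sweep_spec("colotect.cost", 45, 75))
  tor <- tornado(specs, "colotect", "none", p, fx_inc(), fx_life())
  expect_equal(nrow(tor), 3)
  expect_true(all(tor$bar_width >= 0))
  expect_true(all(diff(tor$bar_width) <= 0))
  tor2 <- tornado(rev(specs), "colotect", "none", p, fx_inc(), fx_life())
  expect_identical(tor, tor2)

  single <- tornado(specs[1], "colotect", "none", p, fx_inc(), fx_life())
  expect_equal(nrow(single), 1)
  # lower specificity (more false-positive colonoscopies) raises the ICER
  expect_gt(single$icer_at_low, single$icer_at_high)
  expect_error(tornado(list(), "colotect"), "at least one")
})

test_that("compliance-cost grid is monotone in kit cost and consistent", {
  p <- default_parameters()
  g <- compliance_cost_grid(costs = c(55, 60, 65),
                            compliance_points = c(0.8, 0.9698),
                            params = p, incidence = fx_inc(),
                            life = fx_life())
  # ICER increases with kit cost at every compliance level
  expect_true(all(apply(g, 1, diff) > 0))
  # the baseline cell equals the headline ICER
  rs <- fx_run("colotect"); rr <- fx_run("none")
  expect_equal(g["0.9698", "60"],
               (rs$costs[["total"]] - rr$costs[["total"]]) /
                 (rr$life_years_lost - rs$life_years_lost))
  expect_error(compliance_cost_grid(numeric(0)), "non-empty")
  expect_error(compliance_cost_grid(60, 1.2), "\\[0,1\\]")
})

test_that("wtp_crossing brackets and bisects the threshold kit cost", {
  p <- default_parameters()
  # the ICER rises roughly linearly in kit cost; bracket generously
  v <- wtp_crossing("colotect.cost", 60, 2000, "colotect", "none", p,
                    fx_inc(), fx_life(), tol = 0.5)
  expect_false(is.na(v))
  pv <- set_param(p, "colotect.cost", v)
  rs <- run_cohort("colotect", pv, fx_inc(), fx_life())
  rr <- fx_run("none")
  ic <- (rs$costs[["total"]] - rr$costs[["total"]]) /
    (rr$life_years_lost - rs$life_years_lost)
  expect_equal(ic, wtp_threshold_usd(), tolerance = 1e-3)
  # no crossing inside a bracket that stays below the threshold
  expect_true(is.na(wtp_crossing("colotect.cost", 55, 65, "colotect",
                                 "none", p, fx_inc(), fx_life())))
})

test_that("default tornado specs stay inside validity ranges", {
  specs <- default_tornado_specs()
  expect_length(specs, 6)
  for (sp in specs) {
    expect_s3_class(sp, "sweep_spec")
    expect_lt(sp$low, sp$high)
  }
})
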