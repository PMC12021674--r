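# Unit and property tests for the deterministic cohort engine.

test_that("screening_round computes expected positives and referrals", {
  p <- default_parameters()
  s <- new_cohort_state(p)
  s$masses[] <- 0
  s$masses["well"] <- 1000
  test <- list(sensitivity = 0.88, specificity = 0.92, compliance = 1)
  # 1,000 attending of whom 10 have CRC: 10*0.88 + 990*0.08 = 88
  out <- screening_round(s, test, p, prevalence = 0.01)
  expect_equal(out$positives, 88)
  expect_equal(out$referred_mass, 88)   # full post-positive compliance
  expect_equal(out$tests_used, 1000)

  test$compliance <- 0
  out <- screening_round(s, test, p)
  expect_equal(out$referred_mass, 0)
  expect_equal(out$tests_used, 0)

  test$compliance <- 1; test$specificity <- 1
  out <- screening_round(s, test, p, prevalence = 0)
  expect_equal(out$referred_mass, 0)
})

test_that("colonoscopy_round reproduces complication expectations", {
  p <- default_parameters()
  s <- new_cohort_state(p)
  s$masses["well"] <- 200000
  out <- colonoscopy_round(s, p$procedure, p, mass = 100792)
  expect_equal(out$tallies$perforations, 100792 * 0.0008)  # 80.63 -> 81
  expect_equal(round(out$tallies$perforations), 81)
  expect_equal(round(13796 * p$procedure$perforation_rate), 11)
  expect_equal(out$tallies$ther_count, 100792 * 0.1405)
  # mass routed: therapeutic to surveillance, rest to pause, deaths aside
  expect_equal(unname(out$state$masses["surv0"] + out$state$masses["pause0"] +
                 out$state$masses["dead_compl"]), 100792)

  z <- colonoscopy_round(new_cohort_state(p), p$procedure, p, mass = 0)
  expect_equal(z$tallies$n, 0)
  expect_equal(z$state$masses, new_cohort_state(p)$masses)
})

test_that("apply_incidence scales, prevents and stage-assigns", {
  p <- default_parameters()
  s <- new_cohort_state(p)
  out <- apply_incidence(s, 1e-3, protected_fraction = 1, prevention = 1,
                         params = p)
  expect_equal(sum(out$new_cases_by_stage), 0)

  out <- apply_incidence(s, 1e-3, 1, 0.54, p)
  expect_equal(sum(out$new_cases_by_stage), 46)  # 100,000 * 1e-3 * 0.46

  out <- apply_incidence(s, 1e-3, 0, 0, p)
  expect_equal(unname(out$new_cases_by_stage),
               100 * c(0.112, 0.245, 0.315, 0.328))
  expect_equal(unname(out$state$masses["well"]), 100000 - 100)
})

test_that("stage shift moves late-stage mass forward proportionally", {
  d <- c(0.112, 0.245, 0.315, 0.328)
  s <- shift_stage_distribution(d, 0.5)
  expect_equal(sum(s), 1)
  expect_equal(s[3], 0.315 / 2)
  expect_equal(s[4], 0.328 / 2)
  expect_gt(s[1], d[1]); expect_gt(s[2], d[2])
  expect_equal(s[1] / s[2], d[1] / d[2])  # proportional reallocation
  expect_equal(shift_stage_distribution(d, 0), d)
})

test_that("apply_stage_mortality applies the published annual rates", {
  p <- default_parameters()
  s <- new_cohort_state(p)
  s$masses[] <- 0
  s$masses["s4"] <- 1000
  out <- apply_stage_mortality(s, p)
  expect_equal(out$crc_deaths, 430)
  s$masses[] <- 0
  s$masses["s1y2"] <- 1000
  expect_equal(apply_stage_mortality(s, p)$crc_deaths, 10)
  s$masses[] <- 0
  expect_equal(apply_stage_mortality(s, p)$crc_deaths, 0)
})

test_that("life_years_lost discounts death-age contributions", {
  life0 <- gen_life_table(0, 0, 0)   # e(a) = 110 - a
  d <- c("50" = 1)
  expect_equal(life_years_lost(d, life0, 0), 60)
  d <- c("60" = 1)                    # one death 10 years in, e = 50
  expect_equal(life_years_lost(d, life0, 0.03), 50 / 1.03^10)
  expect_equal(life_years_lost(numeric(0), life0, 0.03), 0)
})

test_that("zero incidence gives zero cases and life-years lost", {
  p <- default_parameters()
  inc0 <- gen_incidence(1e-300, 0, jitter_sd = 0)
  inc0$rate[] <- 0
  for (s in c("none", "colotect")) {
    r <- run_cohort(s, p, inc0, fx_life())
    expect_equal(r$cases_total, 0, label = s)
    expect_equal(r$life_years_lost, 0, label = s)
  }
})

test_that("neutral screening reproduces the no-screening tallies exactly", {
  p <- default_parameters()
  p$tests$fit$sensitivity <- 0
  p$tests$fit$prevention <- 0
  p$tests$fit$specificity <- 1
  rs <- run_cohort("fit", p, fx_inc(), fx_life())
  r0 <- run_cohort("none", p, fx_inc(), fx_life())
  expect_equal(rs$cases_by_stage, r0$cases_by_stage)
  expect_equal(rs$deaths_by_age, r0$deaths_by_age)
  expect_equal(rs$life_years_lost, r0$life_years_lost)
  expect_equal(rs$colonoscopies$total, 0)
  # costs differ only by the test kits
  expect_equal(rs$costs[["total"]] - rs$costs[["kit"]], r0$costs[["total"]])
})

test_that("constant incidence matches the closed-form cumulative cases", {
  p <- default_parameters()
  inc <- gen_incidence(1e-3, 0, jitter_sd = 0)
  life0 <- gen_life_table(0, 0, 0)
  r <- run_cohort("none", p, inc, life0)
  expect_equal(r$cases_total, 100000 * (1 - (1 - 1e-3)^26),
               tolerance = 1 / r$cases_total)  # within 1 person
})

test_that("mass is conserved at every cycle for every strategy", {
  p <- default_parameters()
  for (s in strategy_names()) {
    r <- fx_run(s)
    expect_lt(max(abs(r$mass_audit - p$model$cohort_size)), 1e-6)
  }
})

test_that("zero discount rate removes all discounting", {
  p <- default_parameters()
  p$model$discount_rate <- 0
  r <- run_cohort("colotect", p, fx_inc(), fx_life())
  expect_equal(r$life_years_lost,
               life_years_lost(r$deaths_by_age, fx_life(), 0))
  expect_equal(r$costs[["kit"]], r$tests_used * p$tests$colotect$cost)
  expect_equal(r$costs[["colonoscopy"]],
               r$colonoscopies$total *
                 (p$procedure$cost + p$procedure$consultation))
})

test_that("prevention and compliance move tallies monotonically", {
  p <- default_parameters()
  cases <- vapply(c(0, 0.25, 0.5, 1), function(pr) {
    run_cohort("colotect", set_param(p, "colotect.prevention", pr),
               fx_inc(), fx_life())$cases_total
  }, numeric(1))
  expect_true(all(diff(cases) <= 0))

  tests <- vapply(c(0.2, 0.5, 0.8, 1), function(cc) {
    run_cohort("colotect", set_param(p, "colotect.compliance", cc),
               fx_inc(), fx_life())$tests_used
  }, numeric(1))
  expect_true(all(diff(tests) >= 0))
})

test_that("therapeutic colonoscopies equal the polypectomy-rate share", {
  for (s in c("fit", "colotect", "colonoscopy")) {
    r <- fx_run(s)
    expect_lt(abs(r$colonoscopies$therapeutic -
                    0.1405 * r$colonoscopies$total), 0.5)
    expect_equal(r$colonoscopies$total,
                 r$colonoscopies$diagnostic + r$colonoscopies$therapeutic)
  }
})

test_that("attendance models behave as documented", {
  p <- default_parameters()
  p$model$attendance_model <- "once_ever"
  r_once <- run_cohort("colotect", p, fx_inc(), fx_life())
  r_ind <- fx_run("colotect")
  # once-ever screens a fixed subcohort: fewer distinct people protected,
  # tallies still a valid mass balance
  expect_equal(unname(r_once$mass_audit[length(r_once$mass_audit)]),
               p$model$cohort_size, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(r_once$cases_total, r_ind$cases_total)))

  p$model$attendance_model <- "geometric_attrition"
  r_geo <- run_cohort("colotect", p, fx_inc(), fx_life())
  expect_lt(r_geo$tests_used, r_ind$tests_used)

  expect_error(run_cohort("nope", default_parameters(), fx_inc(), fx_life()))
})
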