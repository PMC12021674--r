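# Cost-effectiveness arithmetic against the published table identities and
# against an independent frontier-construction oracle.

test_that("discount_factor follows (1+r)^-t", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(25, 0.03), 1 / 1.03^25)
  expect_equal(round(discount_factor(1, 0.03), 6), 0.970874)
  expect_equal(round(discount_factor(25, 0.03), 6), 0.477606)
  expect_error(discount_factor(-1, 0.03), ">= 0")
})

test_that("additional cost is exact subtraction", {
  expect_identical(additional_cost(297587292, 224665128), 72922164)
  expect_identical(additional_cost(237692344, 224665128), 13027216)
  expect_identical(additional_cost(5, 5), 0)
})

test_that("icer divides and is antisymmetric in the cost difference", {
  expect_equal(icer(72922164, 2236), 32613, tolerance = 1e-4)
  expect_equal(icer(59894948, 1968), 30434, tolerance = 1e-4)
  expect_equal(icer(0, 5), 0)
  expect_error(icer(10, 0), "undefined")
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, -1e6, 1e6); b <- runif(1, -1e6, 1e6)
    e <- runif(1, 0.1, 1000)
    expect_equal(icer(a - b, e) + icer(b - a, e), 0)
  }
})

test_that("cost per life-year saved and proportion prevented reproduce", {
  expect_equal(cost_per_life_year_saved(297587292, 2236), 133089.0,
               tolerance = 1e-5)
  expect_equal(cost_per_life_year_saved(0, 1), 0)
  expect_error(cost_per_life_year_saved(1, 0), "> 0")
  expect_equal(proportion_prevented(3233, 2010), 37.8)
  expect_equal(proportion_prevented(3233, 1546), 52.2)
  expect_equal(proportion_prevented(500, 500), 0)
  expect_error(proportion_prevented(0, 5), "> 0")
})

test_that("WTP threshold converts GDP per capita", {
  expect_identical(wtp_threshold_usd(395429, 7.8), 50696L)
  expect_identical(wtp_threshold_usd(7.8, 7.8), 1L)
  expect_error(wtp_threshold_usd(-1, 7.8), "> 0")
  # the stool-DNA strategy's headline ICER clears the threshold
  expect_lt(32610, wtp_threshold_usd())
})

test_that("frontier on the published totals extended-dominates FIT", {
  tab <- data.frame(label = c("none", "fit", "colotect", "colonoscopy"),
                    cost = c(224665128, 237692344, 297587292, 434230750),
                    effect = c(0, 268, 2236, 2940))
  fr <- efficiency_frontier(tab)
  expect_equal(fr$label[fr$on_frontier], c("none", "colotect", "colonoscopy"))
  expect_true(fr$extended_dominated[fr$label == "fit"])
  expect_false(any(fr$dominated))
  ic <- fr$incremental_icer[fr$on_frontier]
  expect_true(all(diff(ic[!is.na(ic)]) > 0))
  # the removed incremental step: 48,609 vs the cheaper 30,434 next step
  expect_equal(fr$incremental_icer[fr$label == "colotect"],
               72922164 / 2236, tolerance = 1e-9)
})

test_that("frontier handles ties, pairs and bad input", {
  two <- data.frame(label = c("a", "b"), cost = c(10, 20), effect = c(0, 1))
  fr <- efficiency_frontier(two)
  expect_equal(sum(fr$on_frontier), 2)
  expect_equal(fr$incremental_icer[2], 10)

  tie <- data.frame(label = c("a", "b"), cost = c(10, 10), effect = c(1, 1))
  fr <- efficiency_frontier(tie)
  expect_false(fr$dominated[fr$label == "a"])
  expect_true(fr$dominated[fr$label == "b"])

  expect_error(efficiency_frontier(two[1, ]), "at least two")
  expect_error(efficiency_frontier(
    data.frame(label = c("a", "a"), cost = 1:2, effect = 1:2)), "duplicate")
})

test_that("frontier matches the greedy lowest-ICER oracle on random sets", {
  set.seed(2024)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    x <- data.frame(label = letters[1:n],
                    cost = runif(n, 1e5, 5e5),
                    effect = runif(n, 0, 3000))
    fr <- efficiency_frontier(x)
    expect_identical(fr$label[fr$on_frontier], oracle_frontier_labels(x),
                     label = paste("instance", i))
    ic <- fr$incremental_icer[fr$on_frontier]
    ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
  }
})

test_that("compare_strategies and icer_matrix wire results together", {
  res <- lapply(c("none", "colotect"), fx_run)
  cmp <- compare_strategies(res, "none")
  expect_equal(cmp$life_years_saved[cmp$strategy == "none"], 0)
  expect_true(is.na(cmp$icer_vs_reference[cmp$strategy == "none"]))
  ly <- res[[1]]$life_years_lost - res[[2]]$life_years_lost
  expect_equal(cmp$icer_vs_reference[cmp$strategy == "colotect"],
               (res[[2]]$costs[["total"]] - res[[1]]$costs[["total"]]) / ly)
  im <- icer_matrix(res)
  expect_true(all(is.na(diag(im))))
  expect_equal(im["none", "colotect"],
               cmp$icer_vs_reference[cmp$strategy == "colotect"])
  expect_error(compare_strategies(res, "fit"), "not among")
})
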