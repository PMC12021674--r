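test_that("incidence generator matches its closed form", {
  flat <- gen_incidence(1e-3, 0, seed = 1, jitter_sd = 0)
  expect_equal(flat$rate, rep(1e-3, 26))
  expect_equal(flat$age, 50:75)

  inc <- gen_incidence(1e-3, 0.05, seed = 1, jitter_sd = 0)
  expect_equal(inc$rate[inc$age == 60], 1e-3 * exp(0.5))
  expect_equal(inc$rate[inc$age == 75], 1e-3 * exp(0.05 * 25))
  # default curve is non-decreasing in age and within the valid range
  def <- gen_incidence()
  expect_true(all(diff(def$rate) >= 0))
  expect_true(all(def$rate >= 0 & def$rate <= 0.05))
  expect_error(gen_incidence(0), "base_rate_at_50")
})

test_that("jitter is seed-deterministic and leaves the caller's RNG alone", {
  a <- gen_incidence(1e-3, 0.05, seed = 42, jitter_sd = 0.1)
  b <- gen_incidence(1e-3, 0.05, seed = 42, jitter_sd = 0.1)
  expect_identical(a, b)
  c_ <- gen_incidence(1e-3, 0.05, seed = 43, jitter_sd = 0.1)
  expect_false(identical(a$rate, c_$rate))
  set.seed(99); before <- runif(1)
  set.seed(99); gen_incidence(seed = 1, jitter_sd = 0.2); after <- runif(1)
  expect_identical(before, after)
})

test_that("life table obeys the Gompertz-Makeham closed forms", {
  z <- gen_life_table(0, 0, 0)
  expect_equal(z$qx, rep(0, nrow(z)))
  expect_equal(remaining_life_expectancy(z, 75), 110 - 75)
  expect_equal(remaining_life_expectancy(z, 50), 60)

  # constant hazard: truncated geometric sum
  g <- gen_life_table(0.01, 0, 0)
  ages_left <- 110 - 50
  expect_equal(remaining_life_expectancy(g, 50),
               sum(0.99^(1:ages_left)))
  # q = 0.5 with a distant closing age: e converges to sum 0.5^k = 1
  h <- gen_life_table(0.5, 0, 0, closing_age = 200L)
  expect_equal(remaining_life_expectancy(h, 50), 1, tolerance = 1e-9)

  d <- gen_life_table()
  expect_true(all(diff(d$qx) >= 0))
  expect_true(all(diff(d$ex) < 0))
  expect_error(gen_life_table(-1, 0, 0), ">= 0")
  expect_error(remaining_life_expectancy(d, 40), "outside")
})

test_that("life expectancy equals the brute-force survival-product oracle", {
  d <- gen_life_table()
  for (age in c(50, 60, 75, 90)) {
    i <- match(age, d$age)
    expect_equal(remaining_life_expectancy(d, age),
                 oracle_life_expectancy(d$qx, i), label = paste("age", age))
  }
})

test_that("tables round-trip as delimited text, quinquennial rates expand", {
  inc <- gen_incidence(seed = 5, jitter_sd = 0.05)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_incidence_table(inc, f)
  back <- read_incidence_table(f)
  expect_equal(back$rate, inc$rate, tolerance = 1e-12)

  quin <- data.frame(age = seq(50, 75, by = 5),
                     rate = c(6, 8, 11, 15, 20, 26) * 1e-4)
  q <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(quin, q, sep = "\t", row.names = FALSE, quote = FALSE)
  ann <- read_incidence_table(q)
  expect_equal(ann$age, 50:75)
  expect_equal(ann$rate[ann$age %in% 55:59], rep(8e-4, 5))
  expect_equal(ann$rate[ann$age == 75], 26e-4)

  lt <- gen_life_table()
  g <- withr::local_tempfile(fileext = ".tsv")
  write_life_table(lt, g)
  back <- read_life_table(g)
  expect_equal(back$qx, lt$qx, tolerance = 1e-12)
  expect_equal(back$ex, lt$ex, tolerance = 1e-9)
})
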