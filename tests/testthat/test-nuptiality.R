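test_that("rate-to-probability conversion matches direct evaluation", {
  expect_equal(rate_to_probability(0), 0)
  expect_equal(rate_to_probability(2), 1)
  expect_equal(rate_to_probability(0.25), 2 * 0.25 / 2.25)
  expect_error(rate_to_probability(2.1), "exceed 2")
  expect_error(rate_to_probability(-0.1), "non-negative")
})

test_that("no decrements leaves the cohort intact", {
  mar <- marriage_rate_schedule(rep(0, 35))
  tab <- build_table(mar, zero_mortality())
  expect_true(all(tab$l_x == 100000))
  expect_true(all(tab$f_x[tab$x < 50] == 0))
  expect_true(all(tab$d_x[tab$x < 50] == 0))
})

test_that("single-age absorption and the hand recursion", {
  n <- rep(0, 35); n[25 - 15 + 1] <- 1
  tab <- build_table(schedule_from_probs(n), zero_mortality())
  expect_equal(tab$f_x[tab$x == 25], 100000)
  expect_equal(tab$l_x[tab$x == 25], 100000)
  expect_equal(tab$l_x[tab$x == 26], 0)

  n2 <- rep(0, 35); n2[1] <- 0.5; n2[2] <- 1
  tab2 <- build_table(schedule_from_probs(n2), zero_mortality())
  expect_equal(tab2$f_x[tab2$x == 15], 50000)
  expect_equal(tab2$l_x[tab2$x == 16], 50000)
  expect_equal(tab2$f_x[tab2$x == 16], 50000)
  expect_equal(tab2$l_x[tab2$x == 17], 0)
})

test_that("person-years use the midpoint convention; censor zeroes the open group", {
  n <- rep(0, 35); n[1] <- 1          # all marry at 15
  tab <- build_table(schedule_from_probs(n), zero_mortality())
  expect_equal(tab$L_x[tab$x == 15], 50000)
  expect_equal(attr(tab, "fma0"), 15.5)
  expect_equal(attr(tab, "fma0") - 15, tab$e_x[tab$x == 15])

  mar <- gen_marriage_schedule(27, 4, 0.9)
  mort <- calibrate_to_e0(75, "male")
  cen <- build_table(mar, mort, open_age_policy = "censor")
  expect_equal(cen$L_x[cen$x == 50], 0)
  full <- build_table(mar, mort)
  expect_equal(full$L_x[full$x == 50],
               full$l_x[full$x == 50] * life_expectancy(mort, 50))
})

test_that("combined decrements above 1 raise an error naming the age", {
  n <- rep(0, 35); n[10] <- 0.995
  heavy <- hazard_schedule(level = 0, slope = 0.1, makeham = 0.05)
  expect_error(build_table(schedule_from_probs(n), heavy), "24")
})

test_that("T_x is non-increasing, e_x >= 0 and fma0 = e_15 + 15 always", {
  for (seed in 1:8) {
    sc <- random_schedules(seed)
    tab <- build_table(sc$marriage, sc$mortality)
    expect_true(all(diff(tab$T_x) <= 1e-9))
    expect_true(all(tab$e_x >= 0, na.rm = TRUE))
    expect_equal(attr(tab, "fma0"), tab$e_x[tab$x == 15] + 15)
    expect_true(all(tab$l_x >= 0) && all(diff(tab$l_x) <= 1e-9))
  }
})

test_that("exact conservation l_{x+1} = l_x - f_x - d_x at every age", {
  for (seed in 1:10) {
    sc <- random_schedules(seed)
    tab <- build_table(sc$marriage, sc$mortality)
    i <- seq_len(nrow(tab) - 1L)
    expect_equal(max(abs(tab$l_x[i] - tab$f_x[i] - tab$d_x[i] -
                           tab$l_x[i + 1L])), 0)
  }
})

test_that("undefined expectancy when the cohort is exhausted", {
  n <- rep(0, 35); n[11] <- 1         # all marry at 25
  tab <- build_table(schedule_from_probs(n), zero_mortality())
  expect_true(all(is.na(tab$e_x[tab$x > 25])))
  expect_false(is.na(tab$e_x[tab$x == 25]))
})

test_that("mean-age identity under zero mortality and full absorption", {
  mar <- gen_marriage_schedule(mean_age = 26, spread = 3.5,
                               ultimate_proportion = 1)
  tab <- build_table(mar, zero_mortality())
  f <- tab$f_x[tab$x >= 15 & tab$x <= 49]
  mids <- 15:49 + 0.5
  expect_equal(attr(tab, "fma0"), sum(f * mids) / sum(f), tolerance = 1e-12)
  expect_equal(tab$l_x[tab$x == 50], 0, tolerance = 1e-6)
})

test_that("raising any single marriage probability does not delay fma0", {
  sc <- random_schedules(3)
  base <- build_table(sc$marriage, sc$mortality)
  n0 <- rate_to_probability(sc$marriage$mu)
  q <- rate_to_probability(pmin(sc$mortality$m[16:50], 2))
  for (i in c(1, 8, 20, 35)) {
    n1 <- n0
    n1[i] <- min(n1[i] + 0.1, 1 - q[i] - 1e-9)   # keep n + q <= 1
    if (n1[i] <= n0[i]) next
    bumped <- build_table(schedule_from_probs(n1), sc$mortality)
    expect_lte(attr(bumped, "fma0"), attr(base, "fma0") + 1e-12)
  }
})

test_that("gross table dominates the net table and coincides at zero mortality", {
  sc <- random_schedules(5)
  net <- build_table(sc$marriage, sc$mortality)
  gro <- gross_table(sc$marriage)
  expect_true(all(gro$l_x >= net$l_x - 1e-9))
  net0 <- build_table(sc$marriage, zero_mortality())
  expect_equal(gro$l_x, net0$l_x)
  expect_equal(attr(gro, "fma0"), attr(net0, "fma0"))
})

test_that("never-married proportion: universal marriage and zero marriage limits", {
  mort <- calibrate_to_e0(78, "female")
  none <- build_table(marriage_rate_schedule(rep(0, 35)), mort)
  for (a in c(15, 30, 49, 50))
    expect_equal(never_married_proportion(none, mort, a), 1)
  sat <- rep(0, 35); sat[1:20] <- 0.8
  tab <- build_table(schedule_from_probs(sat), mort)
  expect_lt(never_married_proportion(tab, mort, 49), 1e-10)
  expect_equal(never_married_proportion(tab, mort, 49),
               tab$l_x[tab$x == 49] / (100000 *
                 prod(1 - rate_to_probability(pmin(mort$m[1:49], 2)))))
})

test_that("table CSV write/read round trip preserves values and fma0", {
  sc <- random_schedules(7)
  tab <- build_table(sc$marriage, sc$mortality)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_nuptiality_table(tab, f)
  back <- read_nuptiality_table(f)
  for (cl in c("n_x", "q_x", "l_x", "d_x", "f_x", "L_x", "T_x", "e_x"))
    expect_equal(back[[cl]], tab[[cl]], tolerance = 1e-14)
  expect_equal(attr(back, "fma0"), attr(tab, "fma0"), tolerance = 1e-14)
})
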