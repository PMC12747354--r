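test_that("marriage-schedule generator hits its calibration contract", {
  for (ma in c(22, 25, 28.5)) {
    sched <- gen_marriage_schedule(mean_age = ma, spread = 4,
                                   ultimate_proportion = 1)
    gro <- gross_table(sched)
    expect_lt(abs(attr(gro, "fma0") - ma), 0.1)
  }
  sched <- gen_marriage_schedule(26, 5, ultimate_proportion = 0.9)
  gro <- gross_table(sched)
  married <- sum(gro$f_x) / 100000
  expect_lt(abs(married - 0.9), 0.005)
})

test_that("a small spread concentrates marriages near the mean age", {
  sched <- gen_marriage_schedule(mean_age = 25, spread = 0.3,
                                 ultimate_proportion = 1)
  gro <- gross_table(sched)
  f <- gro$f_x[gro$x >= 15 & gro$x <= 49]
  near <- gro$x[gro$x >= 15 & gro$x <= 49] %in% 24:26
  expect_gte(sum(f[near]) / sum(f), 0.99)
})

test_that("infeasible mean/spread combinations are rejected", {
  expect_error(gen_marriage_schedule(16, 8, 1), "not attainable")
  expect_error(gen_marriage_schedule(25, -1, 1), "positive")
  expect_error(gen_marriage_schedule(25, 4, 0), "\\(0, 1\\]")
})

test_that("generators are pure functions of their seed", {
  a <- gen_marriage_schedule(26, 4, 0.95, seed = 3)
  b <- gen_marriage_schedule(26, 4, 0.95, seed = 99)
  expect_identical(a$mu, b$mu)        # deterministic construction
  st <- default_strata(2)
  c1 <- gen_census_counts(st, exposure = 1e3, seed = 11)
  c2 <- gen_census_counts(st, exposure = 1e3, seed = 11)
  expect_identical(c1, c2)
  p1 <- gen_panel(5, 4, seed = 8)
  p2 <- gen_panel(5, 4, seed = 8)
  expect_identical(p1, p2)
})

test_that("census counts recover the generator rates at large exposure", {
  st <- default_strata(1, sexes = "female")
  counts <- gen_census_counts(st, exposure = 1e6, seed = 2)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(counts, f, row.names = FALSE, quote = FALSE)
  rates <- census_rates(read_census_counts(f))
  expect_length(rates, 1)
  truth <- gen_marriage_schedule(st$mean_age, st$spread,
                                 st$ultimate_proportion)
  sel <- truth$mu >= 0.05
  rel <- abs(rates[[1]]$mu[sel] - truth$mu[sel]) / truth$mu[sel]
  expect_lt(max(rel), 0.01)
})

test_that("stratum mean ages pass through to ordered fma0", {
  st <- data.frame(province = c("A", "B"), sex = "female",
                   residence = "total", mean_age = c(24, 29), spread = 4,
                   ultimate_proportion = 0.98)
  counts <- gen_census_counts(st, exposure = 1e5, seed = 5)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(counts, f, row.names = FALSE, quote = FALSE)
  rates <- census_rates(read_census_counts(f))
  mort <- calibrate_to_e0(80, "female")
  fm <- vapply(rates, function(r) attr(build_table(r, mort), "fma0"),
               numeric(1))
  expect_lt(fm[["A.female.total"]], fm[["B.female.total"]])
})

test_that("microsim degenerate cases are exact", {
  n <- rep(0, 35); n[25 - 15 + 1] <- 1
  ms <- microsim_cohort(schedule_from_probs(n), zero_mortality(), 1000,
                        seed = 1)
  expect_equal(ms$e15, 10.5)
  expect_equal(ms$e15_se, 0)
  expect_equal(ms$cohort$f_prop[ms$cohort$age == 25], 1)
  expect_equal(ms$cohort$l_prop[ms$cohort$age == 50], 0)

  none <- marriage_rate_schedule(rep(0, 35))
  cs <- microsim_cohort(none, zero_mortality(), 500, seed = 2,
                        open_age_policy = "censor")
  expect_equal(cs$e15, 35)
})

test_that("microsim agrees with the analytic table on a bell schedule", {
  mar <- gen_marriage_schedule(26, 4.5, 0.95)
  mort <- calibrate_to_e0(76, "male")
  tab <- build_table(mar, mort)
  ms <- microsim_cohort(mar, mort, 30000, seed = 42)
  expect_lt(abs(ms$e15 - (attr(tab, "fma0") - 15)), 3 * ms$e15_se)
  l_true <- tab$l_x[tab$x %in% 15:50] / 100000
  z <- abs(ms$cohort$l_prop - l_true) / pmax(ms$cohort$l_se, 1e-6)
  expect_lt(max(z), 4)        # 36 simultaneous binomial comparisons
})

test_that("panel generator: dimensions, balance and noiseless identification", {
  pan <- gen_panel(31, 25, seed = 1)
  expect_equal(nrow(pan), 775)
  expect_equal(length(unique(pan$province)) * length(unique(pan$year)), 775)
  p0 <- gen_panel(10, 8, noise_sd = 0, seed = 4)
  fit <- fit_fe(p0, "twoway_fe")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  tr <- attr(p0, "truth")
  expect_equal(unname(est["edu_log"]), tr$beta_edu, tolerance = 1e-10)
  expect_equal(unname(est["ethnic_ratio"]), tr$beta_eth, tolerance = 1e-10)
  expect_equal(unname(est["income_log"]),
               unname(tr$beta_controls["income_log"]), tolerance = 1e-10)
})

test_that("regressors are correlated with province effects (pooled OLS is biased)", {
  pan <- gen_panel(31, 25, noise_sd = 0, seed = 9)
  d <- data.frame(y = log(pan$first_marriage_age),
                  e = log(pan$edu_years), r = pan$ethnic_ratio,
                  i = log(pan$income_pc), u = pan$urban_rate,
                  dp = pan$dependency_ratio)
  pooled <- coef(lm(y ~ e + r + i + u + dp, d))[["e"]]
  expect_gt(abs(pooled - attr(pan, "truth")$beta_edu), 0.01)
})
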