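test_that("peak age: spike, tie rule, and missing for all-zero profiles", {
  prof <- setNames(rep(0, 35), 15:49)
  expect_true(is.na(peak_age(prof)$age))
  prof["26"] <- 0.3
  expect_equal(peak_age(prof)$age, 26L)
  expect_equal(peak_age(prof)$probability, 0.3)
  flat <- setNames(rep(0.1, 35), 15:49)
  expect_equal(peak_age(flat)$age, 15L)      # ties break young
})

test_that("peak ages order with the generator mean age", {
  mort <- calibrate_to_e0(78, "male")
  t24 <- build_table(gen_marriage_schedule(24, 3, 0.95, province = "A"), mort)
  t29 <- build_table(gen_marriage_schedule(29, 3, 0.95, province = "B"), mort)
  sm <- table_summary(list(t24, t29))
  expect_lt(sm$peak_age[sm$province == "A"], sm$peak_age[sm$province == "B"])
})

test_that("separable level groups are recovered and labelled low/medium/high", {
  base <- rate_to_probability(gen_marriage_schedule(26, 4, 0.9)$mu)
  P <- rbind(base, base + 0.002, base + 0.05, base + 0.052,
             base + 0.10, base + 0.102)
  rownames(P) <- paste0("P", 1:6); colnames(P) <- 15:49
  cl <- cluster_provinces(P, k = 3, seed = 4)
  expect_identical(unname(cl[c("P1", "P2")]), rep("low", 2))
  expect_identical(unname(cl[c("P3", "P4")]), rep("medium", 2))
  expect_identical(unname(cl[c("P5", "P6")]), rep("high", 2))
  # invariant to row permutation
  cl2 <- cluster_provinces(P[sample(6), ], k = 3, seed = 4)
  expect_identical(cl2[names(cl)], cl)
  # a duplicated province joins its twin's cluster
  P7 <- rbind(P, P7 = P["P5", ])
  cl3 <- cluster_provinces(P7, k = 3, seed = 4)
  expect_identical(unname(cl3["P7"]), unname(cl3["P5"]))
})

test_that("degenerate cluster counts follow the documented label rule", {
  P <- matrix(runif(70), nrow = 2, dimnames = list(c("A", "B"), 15:49))
  expect_identical(unname(cluster_provinces(P, k = 1)), rep("low", 2))
  expect_error(cluster_provinces(P, k = 3), "exceeds")
})

test_that("Moran's I: checkerboard, brute-force identity and null expectation", {
  lat <- lattice_rook(4, 4)
  res <- morans_i(lat$checker, lat$W, permutations = 999, seed = 1)
  expect_equal(res$I, -1, tolerance = 1e-12)
  expect_equal(res$expectation, -1 / 15)
  # vectorized vs double-loop brute force on random instances
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(16)
    expect_equal(morans_i(v, lat$W, permutations = 9, seed = 1)$I,
                 morans_i_bruteforce(v, lat$W), tolerance = 1e-12)
  }
  # contiguous blocks of equal-ish values: positive autocorrelation
  blocks <- rep(c(0, 1), each = 8) + rnorm(16, 0, 1e-3)
  expect_gt(morans_i(blocks, lat$W, permutations = 9, seed = 1)$I, 0)
})

test_that("Moran's I input guards", {
  lat <- lattice_rook(4, 4)
  expect_error(morans_i(rep(1, 16), lat$W), "constant")
  expect_error(morans_i(rnorm(3), lat$W[1:3, 1:3]), "at least 4")
  Wbad <- lat$W; Wbad[1, 2] <- 5
  expect_error(morans_i(rnorm(16), Wbad), "symmetric")
})

test_that("weights edge lists are symmetrized on load", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(data.frame(province_a = c("A", "B"), province_b = c("B", "C"),
                       weight = c(1, 2)), f, row.names = FALSE)
  W <- read_weights_edges(f, c("A", "B", "C", "D"))
  expect_equal(W["A", "B"], 1); expect_equal(W["B", "A"], 1)
  expect_equal(W["C", "B"], 2)
  expect_true(all(diag(W) == 0))
  expect_error(read_weights_edges(f, c("A", "B")), "unknown province")
})

test_that("gap table reproduces the published male-female gaps", {
  s2020 <- data.frame(province = "total", sex = c("male", "female"),
                      residence = "total", fma0 = c(33.63, 29.56),
                      e15 = c(18.63, 14.56))
  expect_equal(gap_table(s2020, "sex")$gap_fma0, 4.07)
  s2000 <- data.frame(province = "total", sex = c("male", "female"),
                      residence = "total", fma0 = c(26.85, 23.75),
                      e15 = c(11.85, 8.75))
  expect_equal(gap_table(s2000, "sex")$gap_fma0, 3.1)
})

test_that("gap table: zero for identical strata, antisymmetric, flags missing", {
  mort <- calibrate_to_e0(78, "male")
  mar <- gen_marriage_schedule(26, 4, 0.95)
  tu <- build_table(marriage_rate_schedule(mar$mu, province = "A",
                                           sex = "male",
                                           residence = "urban"), mort)
  tr <- build_table(marriage_rate_schedule(mar$mu, province = "A",
                                           sex = "male",
                                           residence = "rural"), mort)
  sm <- table_summary(list(tu, tr))
  g <- gap_table(sm, "residence")
  expect_equal(g$gap_fma0, 0)
  swapped <- gap_table(sm, "residence", first = "rural", second = "urban")
  expect_equal(swapped$gap_fma0, -g$gap_fma0)
  # missing counterpart flagged, not dropped
  lone <- sm[sm$residence == "urban", ]
  g2 <- gap_table(lone, "residence")
  expect_true(g2$missing_counterpart)
  expect_true(is.na(g2$gap_fma0))
})
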