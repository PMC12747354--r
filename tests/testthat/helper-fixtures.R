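# shared fixture builders; everything is generated in code

zero_mortality <- function(omega = 100L) {
  hazard_schedule(level = 0, slope = 0.1, makeham = 0, infant = 0,
                  omega = omega)
}

# marriage schedule with probabilities given directly (n_x -> mu inversion)
schedule_from_probs <- function(n, ages = 15:49, ...) {
  stopifnot(length(n) == length(ages), all(n >= 0), all(n <= 1))
  marriage_rate_schedule(2 * n / (2 - n), ages = ages, ...)
}

# a random valid (marriage, mortality) pair, deterministic in `seed`
random_schedules <- function(seed) {
  set.seed(seed)
  mar <- gen_marriage_schedule(mean_age = runif(1, 22, 30),
                               spread = runif(1, 2.5, 6),
                               ultimate_proportion = runif(1, 0.8, 1))
  mort <- calibrate_to_e0(runif(1, 60, 90), sample(c("male", "female",
                                                     "total"), 1))
  list(marriage = mar, mortality = mort)
}

# rook-adjacency weights for an r x c lattice, plus a checkerboard vector
lattice_rook <- function(r = 4, c = 4) {
  coord <- expand.grid(row = seq_len(r), col = seq_len(c))
  n <- nrow(coord)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(coord$row[i] - coord$row[j]) +
        abs(coord$col[i] - coord$col[j]) == 1) W[i, j] <- 1
  list(W = W, checker = ifelse((coord$row + coord$col) %% 2 == 0, 1, -1))
}

# brute-force double-loop Moran's I (independent of the vectorized path)
morans_i_bruteforce <- function(values, W, row_standardize = TRUE) {
  n <- length(values)
  if (row_standardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

write_toy_census <- function(path, provinces = c("A", "B"), sex = "male",
                             residence = "total") {
  g <- expand.grid(province = provinces, sex = sex, residence = residence,
                   age = 15:49, stringsAsFactors = FALSE)
  g$never_married_pop <- 1000L
  g$first_marriages <- 50L
  g <- g[order(g$province, g$age), ]
  write.csv(g, path, row.names = FALSE, quote = FALSE)
  g
}
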