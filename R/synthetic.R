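# Generators for census-like inputs with known ground truth, plus a
# discrete-time cohort microsimulation used as an independent oracle for
# the analytic table construction.

# run `code` with a private RNG stream; the caller's .Random.seed survives
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a bell-shaped first-marriage rate schedule
#'
#' Constructs a unimodal age schedule of first-marriage rates over ages
#' 15--49 from three interpretable parameters: the mean age at first
#' marriage of the implied (mortality-free) cohort, the spread of marriage
#' ages, and the ultimate proportion ever marrying.  The marriage-age
#' density is a discretized Gaussian truncated to the marriageable span;
#' its centre is solved internally so that the truncated, discretized mean
#' equals \code{mean_age} (mid-interval event timing), and the density is
#' scaled to total \code{ultimate_proportion}.  Rates are recovered by
#' inverting the \eqn{2\mu/(2+\mu)} probability conversion on the implied
#' per-age marriage probabilities, so a gross nuptiality table built from
#' the result reproduces the requested marriage-age distribution exactly.
#'
#' The construction is deterministic; \code{seed} is accepted for interface
#' uniformity with the other generators and ignored.
#'
#' @param mean_age target mean age at first marriage (years), typically
#'   22--30; must be attainable after truncation to 15--49.
#' @param spread standard deviation of the marriage-age bell, years.
#' @param ultimate_proportion fraction ever marrying absent mortality,
#'   in (0, 1].
#' @param shape curve family; only \code{"bell"} is implemented.
#' @param seed ignored (deterministic generator).
#' @param ages marriageable ages, default \code{15:49}.
#' @inheritParams marriage_rate_schedule
#' @return A \code{marriage_rate_schedule}.
#' @examples
#' sched <- gen_marriage_schedule(mean_age = 25, spread = 4,
#'                                ultimate_proportion = 1)
#' attr(gross_table(sched), "fma0")   # 25 (mean-age identity)
#' @export
gen_marriage_schedule <- function(mean_age, spread, ultimate_proportion = 1,
                                  shape = "bell", seed = NULL, ages = 15:49,
                                  province = NA_character_,
                                  sex = NA_character_,
                                  residence = NA_character_) {
  shape <- match.arg(shape, "bell")
  if (spread <= 0) stop("'spread' must be positive", call. = FALSE)
  if (ultimate_proportion <= 0 || ultimate_proportion > 1)
    stop("'ultimate_proportion' must be in (0, 1]", call. = FALSE)
  mid <- ages + 0.5
  trunc_mean <- function(centre) {
    w <- exp(-(mid - centre)^2 / (2 * spread^2))
    sum(w * mid) / sum(w)
  }
  lo <- min(ages) - 10 * spread
  hi <- max(ages) + 10 * spread
  if (trunc_mean(lo) > mean_age - 1e-9 || trunc_mean(hi) < mean_age + 1e-9)
    stop(sprintf(paste0("mean_age %.1f with spread %.1f is not attainable ",
                        "on ages %d-%d (truncated mean range %.2f-%.2f)"),
                 mean_age, spread, min(ages), max(ages),
                 trunc_mean(lo), trunc_mean(hi)), call. = FALSE)
  centre <- stats::uniroot(function(c) trunc_mean(c) - mean_age,
                           c(lo, hi), tol = 1e-10)$root
  if (centre < min(ages) || centre > max(ages) + 1)
    stop(sprintf(paste0("mean_age %.1f with spread %.1f is not attainable ",
                        "by a bell peaking inside ages %d-%d (the required ",
                        "centre %.1f falls outside the span)"),
                 mean_age, spread, min(ages), max(ages), centre),
         call. = FALSE)
  w <- exp(-(mid - centre)^2 / (2 * spread^2))
  f <- ultimate_proportion * w / sum(w)     # marriage-age density per age
  # recover per-age probabilities from the density: n_x = f_x / survivors
  S <- 1 - c(0, cumsum(f))[seq_along(f)]
  n <- ifelse(S > 1e-12, pmin(1, f / S), 0)
  mu <- 2 * n / (2 - n)                     # inverse of 2*mu/(2+mu); n=1 -> 2
  marriage_rate_schedule(mu, ages, province = province, sex = sex,
                         residence = residence)
}

#' Default stratum design for the census generator
#'
#' Produces a province x sex x residence design with mean marriage ages
#' that vary across provinces and sexes the way census tabulations do:
#' males marry about two years later than females, urban strata about a
#' year later than rural, and provinces spread around the national mean.
#'
#' @param n_provinces number of provinces.
#' @param sexes,residences stratum vocabularies.
#' @param base_mean_age national female mean age at first marriage.
#' @param province_range half-range of the deterministic across-province
#'   spread in mean age, years.
#' @return A data.frame with one row per stratum and columns
#'   \code{province, sex, residence, mean_age, spread,
#'   ultimate_proportion}.
#' @export
default_strata <- function(n_provinces, sexes = c("male", "female"),
                           residences = "total", base_mean_age = 26,
                           province_range = 2) {
  prov <- sprintf("P%02d", seq_len(n_provinces))
  offs <- if (n_provinces == 1L) 0 else
    seq(-province_range, province_range, length.out = n_provinces)
  g <- expand.grid(province = prov, sex = sexes, residence = residences,
                   stringsAsFactors = FALSE)
  g$mean_age <- base_mean_age + offs[match(g$province, prov)] +
    ifelse(g$sex == "male", 2, 0) + ifelse(g$residence == "urban", 1, 0)
  g$spread <- 4.5
  g$ultimate_proportion <- 0.98
  g
}

#' Generate census-like first-marriage count tables
#'
#' For each stratum row, draws integer first-marriage counts around the
#' stratum's bell-schedule rates with a constant never-married exposure per
#' age, emulating a census mid-year tabulation.  Counts per (age, exposure)
#' cell are Binomial(2 exposure, mu/2), so the empirical rate
#' first_marriages / never_married_pop is unbiased for mu and bounded by 2.
#' Rows with zero exposure are excluded from the output.
#'
#' @param strata a stratum design as returned by [default_strata()]
#'   (columns \code{province, sex, residence, mean_age, spread,
#'   ultimate_proportion}).
#' @param exposure mid-year never-married population per single-year age
#'   cell (default 1e5).
#' @param seed integer seed; the generator is a pure function of
#'   (strata, exposure, seed).
#' @param ages marriageable ages.
#' @return A data.frame in the census-counts schema: \code{province, sex,
#'   residence, age, never_married_pop, first_marriages}.
#' @export
gen_census_counts <- function(strata, exposure = 1e5, seed = 1, ages = 15:49) {
  need <- c("province", "sex", "residence", "mean_age", "spread",
            "ultimate_proportion")
  if (!all(need %in% names(strata)))
    stop("'strata' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (exposure < 0) stop("'exposure' must be non-negative", call. = FALSE)
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(strata)), function(i) {
      st <- strata[i, ]
      sched <- gen_marriage_schedule(st$mean_age, st$spread,
                                     st$ultimate_proportion, ages = ages)
      events <- stats::rbinom(length(ages), size = 2L * round(exposure),
                              prob = sched$mu / 2)
      data.frame(province = st$province, sex = st$sex,
                 residence = st$residence, age = ages,
                 never_married_pop = round(exposure),
                 first_marriages = events)
    })
    out <- do.call(rbind, rows)
    out[out$never_married_pop > 0, , drop = FALSE]
  })
}

#' Discrete-time cohort microsimulation of the double-decrement process
#'
#' Simulates \code{n} individuals from birth through the same decrement
#' model the analytic table encodes: each year a never-married, alive
#' individual draws one uniform and marries if \eqn{u < n_x} (ages 15--49),
#' dies if \eqn{n_x \le u < n_x + q_x}, with events at mid-interval.
#' Probabilities for ages 0--49 use the table's \eqn{2m/(2+m)} conversion;
#' past age 50 (policy \code{"mortality_expectancy"}) survival uses the
#' \eqn{1-e^{-m}} conversion that defines the open-group expectancy, so the
#' simulated process shares the analytic table's model exactly and serves
#' as an independent oracle for it.
#'
#' @inheritParams build_table
#' @param n number of simulated individuals.
#' @param seed integer seed.
#' @return A list with \code{cohort}: data.frame over exact ages 15--50 of
#'   empirical never-married survivorship \code{l_prop} (fraction of the
#'   initial cohort) with standard error, and first-marriage fractions
#'   \code{f_prop} (NA at 50); \code{e15} and \code{e15_se}: mean and
#'   standard error of single person-years lived from exact age 15 among
#'   those never-married and alive at 15; \code{n}, \code{n15}.
#' @export
microsim_cohort <- function(marriage, mortality, n, seed = 1,
                            open_age_policy = c("mortality_expectancy",
                                                "censor")) {
  stopifnot(inherits(marriage, "marriage_rate_schedule"),
            inherits(mortality, "mortality_schedule"), n >= 1)
  open_age_policy <- match.arg(open_age_policy)
  a_min <- min(marriage$age); a_max <- max(marriage$age)
  omega <- mortality$params$omega
  n_x <- rate_to_probability(marriage$mu)
  q_tab <- rate_to_probability(pmin(mortality$m, 2))  # ages 0..omega
  if (any(n_x + q_tab[marriage$age + 1L] > 1))
    stop("combined decrement n_x + q_x exceeds 1", call. = FALSE)

  with_local_seed(seed, {
    state <- integer(n)                     # 0 single, 1 married, 2 dead
    years <- numeric(n)                     # single years from a_min
    rec_age <- a_min:(a_max + 1L)
    l_cnt <- integer(length(rec_age)); f_cnt <- integer(length(rec_age))
    for (x in 0:(a_min - 1L)) {             # childhood: mortality only
      idx <- which(state == 0L)
      died <- idx[stats::runif(length(idx)) < q_tab[x + 1L]]
      state[died] <- 2L
    }
    at15 <- which(state == 0L)
    for (x in a_min:a_max) {
      i <- x - a_min + 1L
      idx <- which(state == 0L)
      l_cnt[i] <- length(idx)
      u <- stats::runif(length(idx))
      nm <- n_x[i]; qm <- q_tab[x + 1L]
      marry <- u < nm
      die <- !marry & u < nm + qm
      years[idx] <- years[idx] + ifelse(marry | die, 0.5, 1)
      state[idx[marry]] <- 1L
      state[idx[die]] <- 2L
      f_cnt[i] <- sum(marry)
    }
    l_cnt[length(rec_age)] <- sum(state == 0L)
    if (open_age_policy == "mortality_expectancy") {
      q_open <- pmin(1, 1 - exp(-mortality$m))
      for (x in (a_max + 1L):(omega - 1L)) {
        idx <- which(state == 0L)
        if (!length(idx)) break
        die <- idx[stats::runif(length(idx)) < q_open[x + 1L]]
        years[idx] <- years[idx] + 1
        years[die] <- years[die] - 0.5      # died mid-interval
        state[die] <- 2L
      }                                     # omega survivors: die at exact omega
    }
    l_prop <- l_cnt / n
    f_prop <- c(f_cnt[-length(rec_age)] / n, NA_real_)
    n15 <- length(at15)
    e15 <- mean(years[at15])
    e15_se <- stats::sd(years[at15]) / sqrt(n15)
    list(cohort = data.frame(age = rec_age, l_prop = l_prop,
                             l_se = sqrt(pmax(l_prop * (1 - l_prop), 0) / n),
                             f_prop = f_prop,
                             f_se = sqrt(pmax(f_prop * (1 - f_prop), 0) / n)),
         e15 = e15, e15_se = e15_se, n = n, n15 = n15)
  })
}

#' Generate a balanced province x year panel with known coefficients
#'
#' Data-generating process for the panel regression: the log of the average
#' first-marriage age is linear in log schooling, the ethnic-minority
#' proportion and three controls (log per-capita income, urbanization rate,
#' dependency ratio), plus province effects, year effects and i.i.d. noise.
#' Regressors carry a province-level component correlated with the province
#' effects, so pooled OLS is biased and the within transformation is
#' genuinely needed.  The true coefficients are attached as
#' \code{attr(panel, "truth")} for recovery tests.
#'
#' @param n_provinces,n_years panel dimensions (each at least 2).
#' @param beta_edu elasticity of first-marriage age w.r.t. schooling.
#' @param beta_eth coefficient on the ethnic-minority proportion.
#' @param beta_controls named coefficients for \code{income_log},
#'   \code{urban_rate}, \code{dependency_ratio}.
#' @param noise_sd standard deviation of the idiosyncratic error.
#' @param seed integer seed (pure function of arguments and seed).
#' @param sex label stored in the \code{sex} column.
#' @param start_year first calendar year.
#' @param interaction optional planted region-specific slope shift:
#'   \code{list(focal = "edu"|"ethnic", region = <label>, delta = <shift>)}
#'   adds \code{delta * focal * 1[province in region]} to the outcome.
#' @param region_map optional named vector province -> region; default
#'   splits provinces into East/Central/West thirds.
#' @return A \code{data.frame} (class \code{province_panel}) with columns
#'   \code{province, year, sex, first_marriage_age, edu_years,
#'   ethnic_ratio, income_pc, urban_rate, dependency_ratio, region}.
#' @examples
#' pan <- gen_panel(31, 25, seed = 3)
#' nrow(pan)   # 775
#' @export
gen_panel <- function(n_provinces = 31, n_years = 25, beta_edu = 0.10,
                      beta_eth = -0.03,
                      beta_controls = c(income_log = 0.01, urban_rate = 0.02,
                                        dependency_ratio = 0.001),
                      noise_sd = 0.01, seed = 1, sex = "total",
                      start_year = 1996, interaction = NULL,
                      region_map = NULL) {
  if (n_provinces < 2 || n_years < 2)
    stop("panel needs at least 2 provinces and 2 years", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  prov <- sprintf("P%02d", seq_len(n_provinces))
  years <- start_year + 0:(n_years - 1L)
  if (is.null(region_map)) {
    thirds <- cut(seq_len(n_provinces), 3, labels = c("East", "Central",
                                                      "West"))
    region_map <- stats::setNames(as.character(thirds), prov)
  }
  with_local_seed(seed, {
    g <- expand.grid(province = prov, year = years, stringsAsFactors = FALSE)
    g <- g[order(g$province, g$year), ]
    t_idx <- g$year - start_year
    gamma <- stats::rnorm(n_provinces, 0, 0.05)
    alpha <- 0.004 * (years - start_year) + stats::rnorm(n_years, 0, 0.01)
    pi_ <- match(g$province, prov); ti <- match(g$year, years)

    edu_base <- log(8) + 0.8 * gamma + stats::rnorm(n_provinces, 0, 0.08)
    g$edu_years <- exp(edu_base[pi_] + 0.012 * t_idx +
                         stats::rnorm(nrow(g), 0, 0.03))
    eth_base <- stats::plogis(stats::rnorm(n_provinces, -2, 1.2))
    g$ethnic_ratio <- pmin(0.999, pmax(1e-4, eth_base[pi_] +
                                         stats::rnorm(nrow(g), 0, 0.01)))
    inc_base <- 8.5 + 1.5 * gamma + stats::rnorm(n_provinces, 0, 0.3)
    g$income_pc <- exp(inc_base[pi_] + 0.06 * t_idx +
                         stats::rnorm(nrow(g), 0, 0.05))
    urb_base <- stats::qlogis(0.35) + stats::rnorm(n_provinces, 0, 0.5)
    g$urban_rate <- stats::plogis(urb_base[pi_] + 0.03 * t_idx +
                                    stats::rnorm(nrow(g), 0, 0.05))
    g$dependency_ratio <- 40 + 5 * stats::rnorm(n_provinces)[pi_] -
      0.2 * t_idx + stats::rnorm(nrow(g), 0, 1)
    g$region <- region_map[g$province]

    log_y <- 2.6 + beta_edu * log(g$edu_years) + beta_eth * g$ethnic_ratio +
      beta_controls[["income_log"]] * log(g$income_pc) +
      beta_controls[["urban_rate"]] * g$urban_rate +
      beta_controls[["dependency_ratio"]] * g$dependency_ratio +
      gamma[pi_] + alpha[ti] + stats::rnorm(nrow(g), 0, noise_sd)
    if (!is.null(interaction)) {
      focal_col <- switch(match.arg(interaction$focal, c("edu", "ethnic")),
                          edu = log(g$edu_years), ethnic = g$ethnic_ratio)
      log_y <- log_y + interaction$delta * focal_col *
        (g$region == interaction$region)
    }
    g$first_marriage_age <- exp(log_y)
    g$sex <- sex
    rownames(g) <- NULL
    g <- g[, c("province", "year", "sex", "first_marriage_age", "edu_years",
               "ethnic_ratio", "income_pc", "urban_rate", "dependency_ratio",
               "region")]
    structure(g, class = c("province_panel", "data.frame"),
              truth = list(beta_edu = beta_edu, beta_eth = beta_eth,
                           beta_controls = beta_controls,
                           noise_sd = noise_sd, interaction = interaction,
                           region_map = region_map))
  })
}
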