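# Readers and writers for the CSV schemas: census counts, life-expectancy
# reference, province x year panel.  UTF-8, header row, period decimal
# separator; province names are opaque labels.

.census_cols <- c("province", "sex", "residence", "age", "never_married_pop",
                  "first_marriages")
.panel_cols <- c("province", "year", "sex", "first_marriage_age", "edu_years",
                 "ethnic_ratio", "income_pc", "urban_rate",
                 "dependency_ratio")

#' Read and validate a census-counts table
#'
#' Expects columns \code{province, sex, residence, age, never_married_pop,
#' first_marriages}: one row per province x sex x residence x single year
#' of age, with the mid-year never-married population (exposure) and the
#' count of first marriages during the year.  Validation errors report the
#' offending file line numbers (header is line 1).  Checks: schema; closed
#' vocabularies for sex and residence; non-negative counts; no duplicate
#' keys; a contiguous age run covering at least 15-49 per stratum; events
#' with zero exposure rejected; occurrence/exposure rate below 2.
#'
#' @param path CSV file path.
#' @param min_age,max_age marriageable span each stratum must cover.
#' @return data.frame of class \code{census_counts}.
#' @export
read_census_counts <- function(path, min_age = 15, max_age = 49) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.census_cols, names(df))
  if (length(miss))
    stop("census file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L                  # file line = row + header
  bad_sex <- !df$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("invalid sex at line(s) ", paste(line[bad_sex], collapse = ", "),
         call. = FALSE)
  bad_res <- !df$residence %in% c("urban", "rural", "total")
  if (any(bad_res))
    stop("invalid residence at line(s) ",
         paste(line[bad_res], collapse = ", "), call. = FALSE)
  neg <- df$never_married_pop < 0 | df$first_marriages < 0 |
    !is.finite(df$never_married_pop) | !is.finite(df$first_marriages)
  if (any(neg))
    stop("negative or non-numeric counts at line(s) ",
         paste(line[neg], collapse = ", "), call. = FALSE)
  key <- paste(df$province, df$sex, df$residence, df$age, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (province, sex, residence, age) key at line(s) ",
         paste(line[dup], collapse = ", "), call. = FALSE)
  zero_exp <- df$never_married_pop == 0 & df$first_marriages > 0
  if (any(zero_exp))
    stop("first marriages with zero never-married exposure at line(s) ",
         paste(line[zero_exp], collapse = ", "), call. = FALSE)
  rate <- ifelse(df$never_married_pop > 0,
                 df$first_marriages / df$never_married_pop, 0)
  hot <- rate > 2
  if (any(hot))
    stop("first-marriage rate exceeds 2 at line(s) ",
         paste(line[hot], collapse = ", "), call. = FALSE)
  sk <- split(df, paste(df$province, df$sex, df$residence, sep = "\r"))
  for (s in sk) {
    ages <- sort(s$age)
    if (min(ages) > min_age || max(ages) < max_age ||
        !identical(as.integer(ages), min(ages) + 0:(length(ages) - 1L)))
      stop(sprintf("stratum %s/%s/%s does not cover a contiguous age run %d-%d",
                   s$province[1], s$sex[1], s$residence[1], min_age, max_age),
           call. = FALSE)
  }
  structure(df, class = c("census_counts", "data.frame"))
}

#' Occurrence/exposure first-marriage rates per stratum
#'
#' Splits a validated census-counts table into strata and computes
#' \eqn{\mu_x} = first_marriages / never_married_pop on the marriageable
#' ages of each stratum.
#'
#' @param counts a \code{census_counts} data.frame.
#' @param min_age,max_age marriageable span.
#' @return Named list of \code{marriage_rate_schedule} objects,
#'   names \code{province.sex.residence}.
#' @export
census_rates <- function(counts, min_age = 15, max_age = 49) {
  sk <- split(counts, list(counts$province, counts$sex, counts$residence),
              drop = TRUE)
  lapply(sk, function(s) {
    s <- s[s$age >= min_age & s$age <= max_age, ]
    s <- s[order(s$age), ]
    marriage_rate_schedule(s$first_marriages / s$never_married_pop,
                           ages = s$age, province = s$province[1],
                           sex = s$sex[1], residence = s$residence[1])
  })
}

#' Read the life-expectancy reference
#'
#' CSV with columns \code{province, sex, e0}: life expectancy at birth per
#' province and sex, used to calibrate the parametric mortality schedules.
#'
#' @param path CSV file path.
#' @return data.frame with those columns.
#' @export
read_life_expectancy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("province", "sex", "e0"), names(df))
  if (length(miss))
    stop("life-expectancy file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$e0)))
    stop("non-numeric e0 values", call. = FALSE)
  df
}

#' Read and validate a balanced province x year panel
#'
#' Expects the panel schema \code{province, year, sex, first_marriage_age,
#' edu_years, ethnic_ratio, income_pc, urban_rate, dependency_ratio}.
#' Verifies balance: every province present in every year (within each sex
#' when several sexes are stacked); missing cells are named in the error.
#'
#' @param path CSV file path.
#' @return data.frame of class \code{province_panel}; \code{N} = provinces
#'   x years (per sex).
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.panel_cols, names(df))
  if (length(miss))
    stop("panel file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (sx in unique(df$sex)) {
    sub <- df[df$sex == sx, ]
    want <- expand.grid(province = unique(sub$province),
                        year = unique(sub$year), stringsAsFactors = FALSE)
    have <- paste(sub$province, sub$year)
    lost <- want[!paste(want$province, want$year) %in% have, ]
    if (nrow(lost))
      stop("unbalanced panel (sex ", sx, "); missing cell(s): ",
           paste(sprintf("(%s, %s)", lost$province, lost$year),
                 collapse = ", "), call. = FALSE)
    if (anyDuplicated(have))
      stop("duplicate (province, year) rows for sex ", sx, call. = FALSE)
  }
  structure(df, class = c("province_panel", "data.frame"))
}

#' Write a data.frame as the package's CSV dialect
#'
#' UTF-8, header row, period decimal separator, no quoting, numeric
#' columns at 15 significant digits so write/read round trips are exact at
#' double precision.
#'
#' @param df data.frame.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (cl in names(out))
    if (is.double(out[[cl]]))
      out[[cl]] <- formatC(out[[cl]], format = "g", digits = 15)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle run configuration
#'
#' Collects the knobs shared by the table builder and CLI: marriageable
#' age span, radix, open-age-group policy, person-years convention
#' (midpoint only), cluster count, seed and the province -> region map.
#'
#' @param min_marriage_age,max_marriage_age marriageable span.
#' @param radix initial cohort size.
#' @param open_age_policy \code{"mortality_expectancy"} or \code{"censor"}.
#' @param cluster_k number of profile clusters.
#' @param seed integer seed.
#' @param region_map named vector province -> region.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(min_marriage_age = 15, max_marriage_age = 49,
                       radix = 100000,
                       open_age_policy = c("mortality_expectancy", "censor"),
                       cluster_k = 3, seed = 1, region_map = NULL) {
  if (min_marriage_age >= max_marriage_age)
    stop("min_marriage_age must be below max_marriage_age", call. = FALSE)
  if (radix <= 0) stop("radix must be positive", call. = FALSE)
  structure(list(min_marriage_age = min_marriage_age,
                 max_marriage_age = max_marriage_age, radix = radix,
                 open_age_policy = match.arg(open_age_policy),
                 L_convention = "midpoint", cluster_k = cluster_k,
                 seed = seed, region_map = region_map),
            class = "run_config")
}
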