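#' Age-specific first-marriage rate schedule
#'
#' Holds occurrence/exposure first-marriage rates \eqn{\mu_x} (first
#' marriages during the year divided by the mid-year never-married
#' population) on a contiguous run of integer ages, by convention 15--49;
#' the rate is zero outside this range.  \eqn{\mu_x \le 2} is required so
#' that the probability conversion \eqn{2\mu/(2+\mu)} stays in \eqn{[0,1]}
#' (equality gives a probability of exactly 1).
#'
#' @param mu numeric vector of non-negative rates, one per age.
#' @param ages integer ages, contiguous; default \code{15:49}.
#' @param province,sex,residence optional stratum labels carried along.
#' @return An object of class \code{marriage_rate_schedule}.
#' @export
marriage_rate_schedule <- function(mu, ages = 15:49, province = NA_character_,
                                   sex = NA_character_,
                                   residence = NA_character_) {
  ages <- as.integer(ages)
  if (length(mu) != length(ages))
    stop("'mu' and 'ages' lengths differ", call. = FALSE)
  if (!identical(ages, ages[1L] + 0:(length(ages) - 1L)))
    stop("'ages' must be contiguous", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("first-marriage rates must be finite and non-negative", call. = FALSE)
  if (any(mu > 2)) {
    bad <- ages[mu > 2]
    stop("first-marriage rate exceeds 2 at age(s) ",
         paste(bad, collapse = ", "),
         " (probability conversion would exceed 1)", call. = FALSE)
  }
  structure(list(age = ages, mu = as.numeric(mu), province = province,
                 sex = sex, residence = residence),
            class = "marriage_rate_schedule")
}

#' @export
print.marriage_rate_schedule <- function(x, ...) {
  cat("<marriage_rate_schedule>  ages ", min(x$age), "..", max(x$age), sep = "")
  if (!is.na(x$province))
    cat("  [", x$province, "/", x$sex, "/", x$residence, "]", sep = "")
  cat("\n  peak rate ", formatC(max(x$mu), digits = 3, format = "g"),
      " at age ", x$age[which.max(x$mu)], "\n", sep = "")
  invisible(x)
}

#' Convert an occurrence/exposure rate to a single-year probability
#'
#' The linear-exposure conversion used throughout the table construction:
#' \deqn{p = \frac{2r}{2 + r}}
#' Applied to the first-marriage rate \eqn{\mu_x} it gives the
#' first-marriage probability \eqn{n_x}; applied to the death rate
#' \eqn{m_x} it gives the death probability \eqn{q_x}.  The domain is
#' \eqn{0 \le r \le 2}: \eqn{r = 2} maps to probability 1 and larger rates
#' have no valid probability.
#'
#' @param rate numeric vector of rates in \code{[0, 2]}.
#' @return Probabilities in \code{[0, 1]}.
#' @examples
#' rate_to_probability(0.25)   # 0.2222...
#' @export
rate_to_probability <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("'rate' must be finite and non-negative", call. = FALSE)
  if (any(rate > 2))
    stop("'rate' must not exceed 2 (probability would exceed 1)", call. = FALSE)
  2 * rate / (2 + rate)
}

#' Build a net (multi-decrement) nuptiality table
#'
#' Follows a synthetic birth cohort of \code{radix} never-married people
#' through two decrements: death (all ages) and first marriage (ages
#' 15--49).  Rates are converted to probabilities with
#' [rate_to_probability()]; below age 15 only mortality depletes the
#' cohort, and from 15 to 49 the recursion is
#' \deqn{l_{x+1} = l_x - f_x - d_x, \quad f_x = l_x n_x, \quad d_x = l_x q_x.}
#' Joint marry-then-die events within a year are deliberately omitted,
#' which is standard for nuptiality tables at the low mortality of
#' marriageable ages.  Person-years use the midpoint convention
#' \eqn{L_x = (l_x + l_{x+1})/2}; the open age group 50+ receives
#' \eqn{L_{50+} = l_{50}\, e_{50}} under the default
#' \code{"mortality_expectancy"} policy (never-married survivors remain
#' single for their remaining lifetime; no first marriages occur past 50)
#' or 0 under \code{"censor"}.  Then \eqn{T_x = \sum_{i \ge x} L_i},
#' \eqn{e_x = T_x / l_x} (the expected years remaining in the single state),
#' and the expected duration of singlehood since birth is
#' \eqn{fma_0 = e_{15} + 15}.
#'
#' @param marriage a \code{marriage_rate_schedule}.
#' @param mortality a \code{mortality_schedule}; its central death rates
#'   \code{m} feed the \eqn{2m/(2+m)} conversion, and its full schedule
#'   defines the open-group expectancy.
#' @param radix initial cohort size at age 0 (default 100000).
#' @param open_age_policy \code{"mortality_expectancy"} or \code{"censor"}.
#' @return A \code{data.frame} of class \code{net_nuptiality_table} with
#'   columns \code{x, n_x, q_x, l_x, d_x, f_x, L_x, T_x, e_x}; the final
#'   row is the open age group (labelled \code{max_age + 1}, i.e. 50,
#'   meaning "50+").  Attributes: \code{fma0}, \code{radix},
#'   \code{open_age_policy} and the stratum labels of \code{marriage}.
#' @examples
#' mort <- calibrate_to_e0(78, "male")
#' mar <- gen_marriage_schedule(mean_age = 27, spread = 4,
#'                              ultimate_proportion = 0.97)
#' tab <- build_table(mar, mort)
#' attr(tab, "fma0")
#' @export
build_table <- function(marriage, mortality, radix = 100000,
                        open_age_policy = c("mortality_expectancy", "censor")) {
  stopifnot(inherits(marriage, "marriage_rate_schedule"),
            inherits(mortality, "mortality_schedule"))
  open_age_policy <- match.arg(open_age_policy)
  if (radix <= 0) stop("'radix' must be positive", call. = FALSE)
  a_min <- min(marriage$age)
  a_max <- max(marriage$age)
  open_age <- a_max + 1L
  if (mortality$params$omega < open_age)
    stop("mortality schedule does not cover the marriageable ages", call. = FALSE)

  x <- 0:open_age
  n_x <- numeric(length(x))
  n_x[match(marriage$age, x)] <- rate_to_probability(marriage$mu)
  q_x <- rate_to_probability(pmin(mortality$m[seq_along(x)], 2))
  q_x[length(x)] <- NA_real_                # open group: no single-year q

  bad <- which(n_x + q_x > 1 & x < open_age)
  if (length(bad))
    stop("combined decrement n_x + q_x exceeds 1 at age(s) ",
         paste(x[bad], collapse = ", "), call. = FALSE)

  l_x <- d_x <- f_x <- numeric(length(x))
  l_x[1L] <- radix
  for (i in seq_len(open_age)) {            # ages 0 .. open_age-1
    age_i <- x[i]
    f_x[i] <- if (age_i >= a_min) l_x[i] * n_x[i] else 0
    d_x[i] <- l_x[i] * q_x[i]
    l_x[i + 1L] <- l_x[i] - f_x[i] - d_x[i]
  }
  # open group: everyone eventually dies never-married, no more marriages
  f_x[length(x)] <- 0
  d_x[length(x)] <- l_x[length(x)]

  L_x <- c((l_x[-length(x)] + l_x[-1L]) / 2,
           if (open_age_policy == "mortality_expectancy")
             l_x[length(x)] * life_expectancy(mortality, open_age)
           else 0)
  T_x <- rev(cumsum(rev(L_x)))
  e_x <- ifelse(l_x > 0, T_x / l_x, NA_real_)
  fma0 <- if (l_x[a_min + 1L] > 0) e_x[a_min + 1L] + a_min else NA_real_

  out <- data.frame(x = x, n_x = n_x, q_x = q_x, l_x = l_x, d_x = d_x,
                    f_x = f_x, L_x = L_x, T_x = T_x, e_x = e_x)
  structure(out,
            class = c("net_nuptiality_table", "data.frame"),
            fma0 = fma0, radix = radix, open_age_policy = open_age_policy,
            marriage_ages = c(a_min, a_max),
            province = marriage$province, sex = marriage$sex,
            residence = marriage$residence)
}

#' Build a gross nuptiality table
#'
#' Identical construction to [build_table()] with all death probabilities
#' forced to zero: first marriage is the only decrement.  Comparing gross
#' and net tables isolates the contribution of never-married mortality.
#'
#' @inheritParams build_table
#' @param omega terminal age for the zero-mortality schedule backing the
#'   open age group.
#' @return A \code{net_nuptiality_table} with \code{q_x = 0} everywhere.
#' @export
gross_table <- function(marriage, radix = 100000,
                        open_age_policy = c("mortality_expectancy", "censor"),
                        omega = 100L) {
  no_mort <- hazard_schedule(level = 0, slope = 0.1, omega = omega)
  build_table(marriage, no_mort, radix = radix,
              open_age_policy = match.arg(open_age_policy))
}

#' @export
print.net_nuptiality_table <- function(x, ...) {
  cat("<net_nuptiality_table>  radix ", attr(x, "radix"),
      ", open-age policy '", attr(x, "open_age_policy"), "'\n", sep = "")
  if (!is.na(attr(x, "province")))
    cat("  stratum: ", attr(x, "province"), "/", attr(x, "sex"), "/",
        attr(x, "residence"), "\n", sep = "")
  cat("  expected duration of singlehood since birth (fma0): ",
      formatC(attr(x, "fma0"), format = "f", digits = 2), " years\n", sep = "")
  NextMethod()
}

#' Proportion never married among survivors
#'
#' \eqn{l_x / s_x}, where \eqn{s_x} is the mortality-only survivorship from
#' the same radix (same \eqn{2m/(2+m)} probability conversion as the table).
#' Under the assumption that death is unrelated to marriage, this is the
#' proportion never married among people alive at exact age \code{age}.
#'
#' @param table a \code{net_nuptiality_table}.
#' @param mortality the \code{mortality_schedule} the table was built with.
#' @param age integer age within the table's marriageable span (15--50).
#' @return A proportion in \code{[0, 1]}, or \code{NA} if no survivors.
#' @export
never_married_proportion <- function(table, mortality, age) {
  stopifnot(inherits(table, "net_nuptiality_table"),
            inherits(mortality, "mortality_schedule"))
  span <- attr(table, "marriage_ages")
  if (age < span[1L] || age > span[2L] + 1L)
    stop("'age' must be within the marriageable span of the table", call. = FALSE)
  q <- rate_to_probability(pmin(mortality$m[seq_len(age)], 2))  # ages 0..age-1
  s <- attr(table, "radix") * prod(1 - q)
  if (s == 0) return(NA_real_)
  table$l_x[table$x == age] / s
}

#' Summarise one or more nuptiality tables
#'
#' Collapses a list of tables into one tidy row per stratum with the
#' headline quantities: fma0 (expected duration of singlehood since birth),
#' e15 (expected years in the single state at 15), the never-married
#' survivors at the top of the marriageable span, and the peak
#' first-marriage probability and its age.
#'
#' @param tables a \code{net_nuptiality_table} or a list of them.
#' @return A \code{data.frame} with columns \code{province, sex, residence,
#'   fma0, e15, l_top, peak_age, peak_probability}.
#' @export
table_summary <- function(tables) {
  if (inherits(tables, "net_nuptiality_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    span <- attr(tb, "marriage_ages")
    mar <- tb$x >= span[1L] & tb$x <= span[2L]
    pk <- if (all(tb$n_x[mar] == 0)) c(NA_real_, NA_real_) else {
      i <- which.max(tb$n_x[mar])     # which.max breaks ties toward younger
      c(tb$x[mar][i], tb$n_x[mar][i])
    }
    data.frame(province = attr(tb, "province"), sex = attr(tb, "sex"),
               residence = attr(tb, "residence"),
               fma0 = attr(tb, "fma0"),
               e15 = attr(tb, "fma0") - span[1L],
               l_top = tb$l_x[tb$x == span[2L] + 1L],
               peak_age = pk[1L], peak_probability = pk[2L])
  })
  do.call(rbind, rows)
}

#' Write / read a nuptiality table as CSV
#'
#' Columns \code{x, n_x, q_x, l_x, d_x, f_x, L_x, T_x, e_x} with a footer
#' row whose \code{x} field is \code{"fma0"} and whose \code{e_x} field
#' carries the expected duration of singlehood since birth.  Numbers are
#' written with 15 significant digits so a write/read round trip preserves
#' values to full stored precision.
#'
#' @param table a \code{net_nuptiality_table}.
#' @param path file path.
#' @return \code{write_nuptiality_table} returns \code{path}, invisibly;
#'   \code{read_nuptiality_table} returns the table (numeric columns and
#'   the \code{fma0} attribute restored; stratum attributes are not stored
#'   in the file).
#' @export
write_nuptiality_table <- function(table, path) {
  stopifnot(inherits(table, "net_nuptiality_table"))
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 15))
  df <- data.frame(x = as.character(table$x),
                   n_x = fmt(table$n_x), q_x = fmt(table$q_x),
                   l_x = fmt(table$l_x), d_x = fmt(table$d_x),
                   f_x = fmt(table$f_x), L_x = fmt(table$L_x),
                   T_x = fmt(table$T_x), e_x = fmt(table$e_x))
  df[nrow(df) + 1L, ] <- c("fma0", rep("", 7L), fmt(attr(table, "fma0")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nuptiality_table
#' @export
read_nuptiality_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  foot <- df$x == "fma0"
  fma0 <- as.numeric(df$e_x[foot])
  df <- df[!foot, ]
  out <- data.frame(x = as.integer(df$x))
  for (cl in c("n_x", "q_x", "l_x", "d_x", "f_x", "L_x", "T_x", "e_x"))
    out[[cl]] <- as.numeric(df[[cl]])
  structure(out, class = c("net_nuptiality_table", "data.frame"),
            fma0 = fma0, radix = out$l_x[1L],
            open_age_policy = NA_character_,
            marriage_ages = c(15L, max(out$x) - 1L),
            province = NA_character_, sex = NA_character_,
            residence = NA_character_)
}
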