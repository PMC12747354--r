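#' Parametric mortality schedule
#'
#' Evaluates a Gompertz-Makeham hazard with an additive infant-mortality
#' component on integer ages \code{0..omega}:
#' \deqn{m_x = makeham + level \cdot e^{slope \cdot x} + infant \cdot e^{-decay \cdot x}}
#' and converts it to single-year death probabilities assuming a constant
#' hazard within each year, \eqn{q_x = 1 - e^{-m_x}}.  The table is closed
#' out at \code{omega}: anyone surviving to exact age \code{omega} dies there,
#' so survivorship reaches zero and the implied life expectancy is finite
#' even with a null hazard.
#'
#' This family is a self-contained parametric stand-in for an external model
#' life table: at marriageable ages mortality is low and the nuptiality
#' results depend on it only weakly, so any smooth schedule with the right
#' life expectancy at birth serves as the never-married mortality proxy.
#'
#' @param level Gompertz level (baseline senescent hazard), positive.
#' @param slope Gompertz slope per year of age, positive.
#' @param makeham age-independent background hazard, non-negative.
#' @param infant infant-mortality hazard at age 0, non-negative; decays
#'   as \code{exp(-decay * x)}.
#' @param decay decay rate of the infant component per year of age.
#' @param omega terminal age of the closed-out table.
#' @return An object of class \code{mortality_schedule}: a list with integer
#'   ages \code{age} (\code{0..omega}), central death rates \code{m},
#'   death probabilities \code{q} (capped at 1), the implied life
#'   expectancy at birth \code{e0}, and the parameters.
#' @seealso [calibrate_to_e0()], [life_expectancy()]
#' @examples
#' sched <- hazard_schedule(level = 5e-5, slope = 0.1)
#' sched$e0
#' @export
hazard_schedule <- function(level, slope, makeham = 0, infant = 0,
                            decay = 1, omega = 100L) {
  if (!is.numeric(level) || length(level) != 1L || level < 0)
    stop("'level' must be a non-negative scalar", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("'slope' must be a positive scalar", call. = FALSE)
  if (makeham < 0 || infant < 0 || decay < 0)
    stop("'makeham', 'infant' and 'decay' must be non-negative", call. = FALSE)
  age <- 0:omega
  m <- makeham + level * exp(slope * age) + infant * exp(-decay * age)
  q <- pmin(1, 1 - exp(-m))
  out <- structure(
    list(age = age, m = m, q = q, e0 = NA_real_,
         params = list(level = level, slope = slope, makeham = makeham,
                       infant = infant, decay = decay, omega = omega)),
    class = "mortality_schedule")
  out$e0 <- life_expectancy(out, 0L)
  out
}

#' @export
print.mortality_schedule <- function(x, ...) {
  p <- x$params
  cat("<mortality_schedule>  ages 0..", p$omega,
      "  e0 = ", formatC(x$e0, format = "f", digits = 2), "\n", sep = "")
  cat(sprintf("  level=%.3g slope=%.3g makeham=%.3g infant=%.3g\n",
              p$level, p$slope, p$makeham, p$infant))
  invisible(x)
}

# default shape constants per sex; only the level is solved for in calibration
.mortality_shape_defaults <- function(sex) {
  switch(match.arg(sex, c("male", "female", "total")),
         male   = list(slope = 0.095, makeham = 2.0e-4, infant = 0.010),
         female = list(slope = 0.100, makeham = 1.5e-4, infant = 0.008),
         total  = list(slope = 0.097, makeham = 1.8e-4, infant = 0.009))
}

#' Calibrate the mortality schedule to a target life expectancy
#'
#' Solves for the Gompertz level parameter by bisection (on the log scale)
#' so that the implied life expectancy at birth matches \code{target_e0}
#' within 0.01 years.  Slope, background and infant components are fixed at
#' sex-specific default shape constants; \code{sex} therefore selects the
#' shape of the schedule while \code{target_e0} sets its level.
#'
#' @param target_e0 target life expectancy at birth, in years (40--95).
#' @param sex one of \code{"male"}, \code{"female"}, \code{"total"}.
#' @param tol convergence tolerance on e0, years.
#' @return A calibrated \code{mortality_schedule} whose \code{e0} matches
#'   the target within \code{tol}.
#' @examples
#' s <- calibrate_to_e0(78, "female")
#' abs(s$e0 - 78) < 0.01
#' @export
calibrate_to_e0 <- function(target_e0, sex = "total", tol = 0.01) {
  if (!is.numeric(target_e0) || length(target_e0) != 1L)
    stop("'target_e0' must be a scalar", call. = FALSE)
  if (target_e0 < 40 || target_e0 > 95)
    stop("'target_e0' must lie in [40, 95] years", call. = FALSE)
  shape <- .mortality_shape_defaults(sex)
  e0_at <- function(log_level) {
    hazard_schedule(exp(log_level), shape$slope, shape$makeham,
                    shape$infant)$e0
  }
  lo <- log(1e-12); hi <- log(1)     # e0 decreasing in level
  e_hi <- e0_at(lo); e_lo <- e0_at(hi)
  if (target_e0 > e_hi || target_e0 < e_lo)
    stop(sprintf("target e0 %.2f outside achievable range [%.2f, %.2f] for sex '%s'",
                 target_e0, e_lo, e_hi, sex), call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    e_mid <- e0_at(mid)
    if (abs(e_mid - target_e0) < tol / 4) break
    if (e_mid > target_e0) lo <- mid else hi <- mid
  }
  hazard_schedule(exp(mid), shape$slope, shape$makeham, shape$infant)
}

#' Remaining life expectancy at a given age
#'
#' Standard single-decrement life-table expectancy with midpoint
#' person-years: survivorship \eqn{l} is computed from \eqn{q_x},
#' \eqn{L_x = (l_x + l_{x+1})/2}, and survivors to the terminal age
#' \code{omega} die at exact age \code{omega} (contributing no further
#' person-years).
#'
#' @param schedule a \code{mortality_schedule}.
#' @param age integer age in \code{[0, omega]}.
#' @return Expected remaining years at exact \code{age}.
#' @export
life_expectancy <- function(schedule, age = 0L) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  omega <- schedule$params$omega
  if (age < 0 || age > omega) stop("'age' must be in [0, omega]", call. = FALSE)
  if (age == omega) return(0)
  q <- schedule$q[(age + 1L):omega]         # q at ages age .. omega-1
  l <- cumprod(c(1, 1 - q))                 # l at ages age .. omega
  if (l[1L] == 0) return(NA_real_)
  L <- (l[-length(l)] + l[-1L]) / 2
  sum(L) / l[1L]
}

#' Serialize / read a mortality schedule
#'
#' CSV columns: \code{age, m_x, q_x}.  Values are written at full double
#' precision (15 significant digits) so a write/read round trip is exact.
#'
#' @param schedule a \code{mortality_schedule}.
#' @param path file path.
#' @return \code{write_mortality_schedule} returns \code{path} invisibly.
#' @export
write_mortality_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  df <- data.frame(age = schedule$age,
                   m_x = formatC(schedule$m, format = "g", digits = 15),
                   q_x = formatC(schedule$q, format = "g", digits = 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
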