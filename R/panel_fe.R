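# Within (fixed-effects) estimation of the determinants of log
# first-marriage age, with province-clustered CR1 standard errors, plus an
# LSDV brute-force oracle used in tests.

.panel_terms <- c(edu_log = "log(edu_years)", ethnic_ratio = "ethnic_ratio",
                  income_log = "log(income_pc)", urban_rate = "urban_rate",
                  dependency_ratio = "dependency_ratio")

# outcome and substantive regressor columns on the estimation scale
.panel_design <- function(panel) {
  need <- c("province", "year", "first_marriage_age", "edu_years",
            "ethnic_ratio", "income_pc", "urban_rate", "dependency_ratio")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(panel$first_marriage_age <= 0) || any(panel$edu_years <= 0) ||
      any(panel$income_pc <= 0))
    stop("logged variables must be strictly positive", call. = FALSE)
  X <- cbind(edu_log = log(panel$edu_years),
             ethnic_ratio = panel$ethnic_ratio,
             income_log = log(panel$income_pc),
             urban_rate = panel$urban_rate,
             dependency_ratio = panel$dependency_ratio)
  list(y = log(panel$first_marriage_age), X = X,
       province = as.character(panel$province),
       year = as.integer(panel$year))
}

# year indicator columns (first year as reference)
.year_dummies <- function(year) {
  ys <- sort(unique(year))[-1L]
  D <- vapply(ys, function(t) as.numeric(year == t), numeric(length(year)))
  colnames(D) <- paste0("year_", ys)
  D
}

.demean_by <- function(M, g) {
  M - apply(M, 2, function(col) stats::ave(col, g))
}

# CR1 cluster-robust vcov: G/(G-1) * (N-1)/(N-k) * bread %*% meat %*% bread
.cr1_vcov <- function(X, u, cluster, k) {
  G <- length(unique(cluster)); N <- nrow(X)
  Xu <- X * u
  scores <- rowsum(Xu, cluster)                       # G x p cluster score sums
  meat <- crossprod(scores)
  bread <- chol2inv(chol(crossprod(X)))
  corr <- G / (G - 1) * (N - 1) / (N - k)
  corr * bread %*% meat %*% bread
}

.stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

# shared estimation core on an already-assembled design
.fit_within <- function(y, X, province, cluster, n_absorbed) {
  yt <- y - stats::ave(y, province)
  Xt <- .demean_by(X, province)
  qrX <- qr(Xt)
  if (qrX$rank < ncol(Xt)) {
    dropped <- colnames(Xt)[qrX$pivot[(qrX$rank + 1L):ncol(Xt)]]
    stop("rank deficiency after demeaning; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, yt)
  u <- yt - Xt %*% beta
  N <- length(y); G <- length(unique(cluster))
  k <- ncol(Xt) + n_absorbed
  V <- .cr1_vcov(Xt, as.numeric(u), cluster, k)
  se <- sqrt(diag(V))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = G - 1)
  r2 <- 1 - sum(u^2) / sum(yt^2)
  list(beta = beta, se = se, p = p, r2 = r2, n = N, G = G, k = k, vcov = V,
       residuals = as.numeric(u))
}

#' Fit a fixed-effects panel regression of log first-marriage age
#'
#' Regresses the log of the average first-marriage age on log years of
#' schooling, the ethnic-minority proportion and three controls (log
#' per-capita income, urbanization rate, dependency ratio), absorbing
#' province effects by the within transformation; under
#' \code{spec = "twoway_fe"} year indicator variables are added as well.
#' Coefficients are numerically identical to the least-squares dummy
#' variable (LSDV) estimator.  Standard errors are clustered at the
#' province with the CR1 small-sample correction
#' \eqn{G/(G-1) \cdot (N-1)/(N-k)}, where \eqn{k} counts slopes plus
#' absorbed fixed effects; p-values use a t reference with \eqn{G-1}
#' degrees of freedom.  Significance stars follow the 0.01 / 0.05 / 0.1
#' convention.
#'
#' @param panel a balanced province x year data.frame in the panel schema
#'   (see [gen_panel()] / [read_panel()]).  Slice by sex beforehand for
#'   sex-specific fits.
#' @param spec \code{"area_fe"} (province effects only) or
#'   \code{"twoway_fe"} (province and year effects).
#' @param cluster clustering variable; only \code{"province"} is supported.
#' @return An object of class \code{fe_result}: list with
#'   \code{coefficients} (data.frame \code{term, estimate, cluster_se,
#'   p_value, stars, nuisance}), \code{r_squared} (within-R-squared),
#'   \code{n_obs}, \code{n_clusters}, \code{spec}, \code{vcov}.
#' @examples
#' pan <- gen_panel(10, 8, seed = 2)
#' fit_fe(pan, "twoway_fe")
#' @export
fit_fe <- function(panel, spec = c("area_fe", "twoway_fe"),
                   cluster = "province") {
  spec <- match.arg(spec)
  cluster <- match.arg(cluster, "province")
  d <- .panel_design(panel)
  if (length(unique(d$province)) < 2 || length(unique(d$year)) < 2)
    stop("need at least 2 provinces and 2 years", call. = FALSE)
  X <- d$X
  if (spec == "twoway_fe") X <- cbind(X, .year_dummies(d$year))
  f <- .fit_within(d$y, X, d$province, d$province,
                   n_absorbed = length(unique(d$province)))
  co <- data.frame(term = colnames(X), estimate = as.numeric(f$beta),
                   cluster_se = f$se, p_value = as.numeric(f$p),
                   stars = .stars(as.numeric(f$p)),
                   nuisance = grepl("^year_", colnames(X)),
                   row.names = NULL)
  structure(list(coefficients = co, r_squared = f$r2, n_obs = f$n,
                 n_clusters = f$G, spec = spec, vcov = f$vcov),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat("<fe_result>  spec: ", x$spec, ",  N = ", x$n_obs,
      ",  clusters = ", x$n_clusters, "\n", sep = "")
  co <- x$coefficients[!x$coefficients$nuisance, ]
  out <- data.frame(term = co$term,
                    estimate = formatC(co$estimate, format = "f", digits = 4),
                    cluster_se = formatC(co$cluster_se, format = "f",
                                         digits = 4),
                    p = formatC(co$p_value, format = "g", digits = 3),
                    ` ` = co$stars, check.names = FALSE)
  print(out, row.names = FALSE)
  if (any(x$coefficients$nuisance)) cat("Year fixed effects: yes\n")
  cat("Province fixed effects: yes\n")
  cat("within R-squared: ", formatC(x$r_squared, format = "f", digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Region-interaction fixed-effects specification
#'
#' Adds an interaction of the focal regressor (log schooling or the
#' ethnic-minority proportion) with a region indicator to the two-way
#' fixed-effects specification with all controls.  The region indicator
#' itself is province-constant and hence absorbed by the province effects;
#' the interaction is identified through the focal regressor's variation
#' over time.
#'
#' @inheritParams fit_fe
#' @param focal \code{"edu"} or \code{"ethnic"}.
#' @param region region label, e.g. \code{"East"}.
#' @param region_map named vector province -> region; defaults to the
#'   panel's \code{region} column.
#' @return An \code{fe_result}; the interaction term is named
#'   \code{<focal>:<region>}.
#' @export
fit_interaction <- function(panel, focal = c("edu", "ethnic"), region,
                            region_map = NULL, cluster = "province") {
  focal <- match.arg(focal)
  d <- .panel_design(panel)
  if (is.null(region_map)) {
    if (!"region" %in% names(panel))
      stop("provide 'region_map' or a 'region' column", call. = FALSE)
    region_map <- stats::setNames(as.character(panel$region), d$province)
  }
  miss <- setdiff(unique(d$province), names(region_map))
  if (length(miss))
    stop("region map misses province(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  in_region <- region_map[d$province] == region
  if (!any(in_region))
    stop("region '", region, "' contains no provinces", call. = FALSE)
  focal_col <- if (focal == "edu") d$X[, "edu_log"] else d$X[, "ethnic_ratio"]
  inter <- focal_col * in_region
  X <- cbind(d$X, .year_dummies(d$year))
  X <- cbind(X, matrix(inter, ncol = 1,
                       dimnames = list(NULL, paste0(focal, ":", region))))
  f <- .fit_within(d$y, X, d$province, d$province,
                   n_absorbed = length(unique(d$province)))
  co <- data.frame(term = colnames(X), estimate = as.numeric(f$beta),
                   cluster_se = f$se, p_value = as.numeric(f$p),
                   stars = .stars(as.numeric(f$p)),
                   nuisance = grepl("^year_", colnames(X)),
                   row.names = NULL)
  structure(list(coefficients = co, r_squared = f$r2, n_obs = f$n,
                 n_clusters = f$G, spec = "twoway_fe",
                 interaction = paste0(focal, ":", region), vcov = f$vcov),
            class = "fe_result")
}

#' Brute-force LSDV oracle
#'
#' Plain least squares on explicit province (and, for the two-way
#' specification, year) indicator columns via \code{stats::lm}.  Intended
#' for tests: the within estimator must reproduce these slope coefficients
#' to numerical precision.  The LSDV intercept and dummy coefficients are
#' absorbed fixed effects and are not returned.
#'
#' @inheritParams fit_fe
#' @param interaction optional list \code{list(focal =, region =,
#'   region_map = )} matching [fit_interaction()].
#' @return Named vector of slope coefficients (substantive terms, plus the
#'   interaction term if requested).
#' @export
lsdv_oracle <- function(panel, spec = c("area_fe", "twoway_fe"),
                        interaction = NULL) {
  spec <- match.arg(spec)
  d <- .panel_design(panel)
  df <- data.frame(y = d$y, d$X, province = d$province,
                   year = factor(d$year), check.names = FALSE)
  rhs <- colnames(d$X)
  if (!is.null(interaction)) {
    rmap <- interaction$region_map
    if (is.null(rmap))
      rmap <- stats::setNames(as.character(panel$region), d$province)
    focal_col <- if (interaction$focal == "edu") d$X[, "edu_log"] else
      d$X[, "ethnic_ratio"]
    nm <- paste0(interaction$focal, ":", interaction$region)
    df[[nm]] <- focal_col * (rmap[d$province] == interaction$region)
    rhs <- c(rhs, nm)
    spec <- "twoway_fe"
  }
  fml <- stats::as.formula(paste(
    "y ~", paste(sprintf("`%s`", rhs), collapse = " + "),
    "+ factor(province)", if (spec == "twoway_fe") "+ year" else ""))
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  keep <- vapply(rhs, function(t) {
    if (t %in% names(cf)) cf[[t]] else cf[[paste0("`", t, "`")]]
  }, numeric(1))
  names(keep) <- rhs
  keep
}

#' Write a regression table to CSV
#'
#' Columns \code{term, estimate, cluster_se, p_value, stars}; nuisance
#' (year-dummy) rows are excluded and summary rows for N and the within
#' R-squared are appended.
#'
#' @param result an \code{fe_result}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_fe_csv <- function(result, path) {
  stopifnot(inherits(result, "fe_result"))
  co <- result$coefficients[!result$coefficients$nuisance,
                            c("term", "estimate", "cluster_se", "p_value",
                              "stars")]
  co$estimate <- formatC(co$estimate, format = "g", digits = 15)
  co$cluster_se <- formatC(co$cluster_se, format = "g", digits = 15)
  co$p_value <- formatC(co$p_value, format = "g", digits = 15)
  co <- rbind(co, data.frame(term = c("N", "within_r_squared"),
                             estimate = c(result$n_obs, result$r_squared),
                             cluster_se = "", p_value = "", stars = ""))
  utils::write.csv(co, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
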