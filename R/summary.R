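# Cross-stratum analytics: first-marriage probability profiles, low/medium/
# high clustering, urban-rural and gender gap tables, global Moran's I.

#' Province x age first-marriage probability profile matrix
#'
#' Assembles one row per province of first-marriage probabilities n_x over
#' the marriageable ages, for one sex, from a list of built tables.
#'
#' @param tables list of \code{net_nuptiality_table} objects for a single
#'   sex/residence, with province attributes set.
#' @return Numeric matrix, rows named by province, columns by age.
#' @export
profile_matrix <- function(tables) {
  if (inherits(tables, "net_nuptiality_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    span <- attr(tb, "marriage_ages")
    sel <- tb$x >= span[1L] & tb$x <= span[2L]
    stats::setNames(tb$n_x[sel], tb$x[sel])
  })
  M <- do.call(rbind, rows)
  rownames(M) <- vapply(tables, function(tb) attr(tb, "province"),
                        character(1))
  if (anyNA(M)) stop("profile matrix has missing cells", call. = FALSE)
  M
}

#' Age of peak first-marriage probability
#'
#' Argmax age of a province's probability profile; ties are broken toward
#' the younger age.  An all-zero profile has no peak and is reported as
#' missing.
#'
#' @param profile named numeric vector of probabilities (names = ages), or
#'   one row of a [profile_matrix()].
#' @return list with \code{age} and \code{probability} (both \code{NA} for
#'   an all-zero profile).
#' @export
peak_age <- function(profile) {
  if (is.null(names(profile))) stop("'profile' must be named by age",
                                    call. = FALSE)
  if (all(profile == 0))
    return(list(age = NA_integer_, probability = NA_real_))
  i <- which.max(profile)          # first maximum = youngest age on ties
  list(age = as.integer(names(profile)[i]), probability = unname(profile[i]))
}

#' Cluster provinces into low / medium / high first-marriage levels
#'
#' k-means on the rows of the probability profile matrix (25 restarts,
#' seeded), with clusters relabelled by ascending mean probability averaged
#' over ages: for \code{k = 3} the labels are low / medium / high, for
#' \code{k = 2} low / high, for \code{k = 1} low, and \code{level_1..k}
#' otherwise.  Rows are sorted by province name before clustering so the
#' result does not depend on input order.
#'
#' @param profiles a [profile_matrix()].
#' @param k number of clusters (default 3).
#' @param seed integer seed for the k-means restarts.
#' @return Named character vector province -> level label.
#' @export
cluster_provinces <- function(profiles, k = 3, seed = 1) {
  if (k > nrow(profiles))
    stop("k exceeds the number of provinces", call. = FALSE)
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  labels <- switch(as.character(k), "1" = "low", "2" = c("low", "high"),
                   "3" = c("low", "medium", "high"),
                   paste0("level_", seq_len(k)))
  if (k == 1L) {
    out <- rep("low", nrow(profiles))
  } else {
    km <- with_local_seed(seed,
                          stats::kmeans(profiles, centers = k, nstart = 25,
                                        iter.max = 100))
    ord <- order(rowMeans(km$centers))           # ascending mean level
    out <- labels[match(km$cluster, ord)]
  }
  stats::setNames(out, rownames(profiles))
}

#' Read a spatial weights edge list
#'
#' CSV with columns \code{province_a, province_b, weight}; edges are
#' symmetrized on load (each listed edge contributes to both directions).
#'
#' @param path file path.
#' @param provinces province labels fixing the matrix order.
#' @return Square symmetric matrix with zero diagonal.
#' @export
read_weights_edges <- function(path, provinces) {
  ed <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("province_a", "province_b", "weight")
  if (!all(need %in% names(ed)))
    stop("weights file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(c(ed$province_a, ed$province_b)), provinces)
  if (length(unknown))
    stop("unknown province(s) in weights file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(provinces)
  W <- matrix(0, n, n, dimnames = list(provinces, provinces))
  for (i in seq_len(nrow(ed))) {
    a <- ed$province_a[i]; b <- ed$province_b[i]
    W[a, b] <- W[a, b] + ed$weight[i]
    W[b, a] <- W[b, a] + ed$weight[i]
  }
  diag(W) <- 0
  W
}

#' Global Moran's I with a permutation test
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \cdot
#'       \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z} the mean-centred values.  The pseudo p-value comes from a
#' seeded permutation null (values randomly reassigned to units), two-sided:
#' twice the smaller of the upper and lower tail proportions, with the
#' observed statistic counted in each tail.  Under the permutation null the
#' expectation of I is \eqn{-1/(n-1)}.
#'
#' @param values province-indexed numeric vector (at least 4 units, not all
#'   equal).
#' @param weights square non-negative matrix over the same units, zero
#'   diagonal, symmetric (before any row-standardization).
#' @param permutations number of permutations (at least 999 recommended).
#' @param seed integer seed.
#' @param row_standardize scale each row of the weights to sum to 1
#'   (rows with no neighbours stay zero and are flagged with a warning).
#' @return list with \code{I}, \code{expectation} (\eqn{-1/(n-1)}),
#'   \code{p_value}, \code{permutations}, \code{perm_mean}.
#' @export
morans_i <- function(values, weights, permutations = 999, seed = 1,
                     row_standardize = TRUE) {
  n <- length(values)
  if (n < 4) stop("need at least 4 units", call. = FALSE)
  if (!is.matrix(weights) || nrow(weights) != n || ncol(weights) != n)
    stop("'weights' must be an n x n matrix", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (any(diag(weights) != 0)) stop("weights diagonal must be zero",
                                    call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("weights must be symmetric before row-standardization",
         call. = FALSE)
  if (stats::var(values) == 0)
    stop("values are constant; Moran's I is undefined", call. = FALSE)
  W <- weights
  if (row_standardize) {
    rs <- rowSums(W)
    if (any(rs == 0)) warning("isolated unit(s) with no neighbours")
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  S0 <- sum(W)
  I_of <- function(v) {
    z <- v - mean(v)
    (n / S0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  }
  I_obs <- I_of(values)
  perm <- with_local_seed(seed, {
    vapply(seq_len(permutations), function(i) I_of(sample(values)),
           numeric(1))
  })
  p_hi <- (1 + sum(perm >= I_obs)) / (permutations + 1)
  p_lo <- (1 + sum(perm <= I_obs)) / (permutations + 1)
  list(I = I_obs, expectation = -1 / (n - 1),
       p_value = min(1, 2 * min(p_hi, p_lo)),
       permutations = permutations, perm_mean = mean(perm))
}

#' Gap table between paired strata
#'
#' Per-province differences in the expected duration of singlehood since
#' birth (fma0) and in e15, between two levels of a contrast variable:
#' \code{"sex"} (default male minus female) or \code{"residence"} (default
#' urban minus rural).  The sign convention is first-listed minus
#' second-listed.  A province missing its counterpart stratum is kept in
#' the output with \code{NA} gaps and \code{missing_counterpart = TRUE},
#' never silently dropped.
#'
#' @param summaries a stratum summary data.frame as returned by
#'   [table_summary()] (columns province, sex, residence, fma0, e15), or a
#'   list of \code{net_nuptiality_table}s which will be summarised first.
#' @param contrast \code{"sex"} or \code{"residence"}.
#' @param first,second the two contrast levels, first minus second.
#' @return data.frame with columns \code{province}, the held-fixed stratum
#'   variable, \code{gap_fma0}, \code{gap_e15},
#'   \code{missing_counterpart}.
#' @examples
#' s <- data.frame(province = "total", sex = c("male", "female"),
#'                 residence = "total", fma0 = c(33.63, 29.56),
#'                 e15 = c(18.63, 14.56))
#' gap_table(s, "sex")$gap_fma0   # 4.07
#' @export
gap_table <- function(summaries, contrast = c("sex", "residence"),
                      first = NULL, second = NULL) {
  contrast <- match.arg(contrast)
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- table_summary(summaries)
  if (is.null(first))
    first <- if (contrast == "sex") "male" else "urban"
  if (is.null(second))
    second <- if (contrast == "sex") "female" else "rural"
  other <- if (contrast == "sex") "residence" else "sex"
  keys <- unique(summaries[, c("province", other)])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- summaries[summaries$province == keys$province[i] &
                       summaries[[other]] == keys[[other]][i], ]
    a <- sub[sub[[contrast]] == first, ]
    b <- sub[sub[[contrast]] == second, ]
    miss <- nrow(a) != 1L || nrow(b) != 1L
    out <- data.frame(province = keys$province[i],
                      gap_fma0 = if (miss) NA_real_ else a$fma0 - b$fma0,
                      gap_e15 = if (miss) NA_real_ else a$e15 - b$e15,
                      missing_counterpart = miss)
    out[[other]] <- keys[[other]][i]
    out[, c("province", other, "gap_fma0", "gap_e15",
            "missing_counterpart")]
  })
  res <- do.call(rbind, rows)
  attr(res, "contrast") <- sprintf("%s: %s - %s", contrast, first, second)
  res
}
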