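#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The two-sided p-value uses
#' exact permutation enumeration for n <= 10 and the t-approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` with n - 2 degrees of freedom otherwise.
#'
#' @param x,y Paired numeric vectors (pairs with missing values are dropped;
#'   at least 4 complete pairs required).
#' @return A `cohort_test` list: `rho`, `p`, `n`, `method`.
#' @export
#' @examples
#' spearman(1:4, c(2, 1, 4, 3))$rho  # 0.6
spearman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  abort_if(n < 4, "need at least 4 complete pairs")
  abort_if(length(unique(x)) == 1 || length(unique(y)) == 1,
           "undefined correlation")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    p <- spearman_exact_p_cpp(rx, ry)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p = min(p, 1), n = n, method = method,
                 test = "spearman"),
            class = "cohort_test")
}

#' Mann-Whitney U test
#'
#' U statistic with average ranks for ties. The two-sided p-value is exact
#' (full enumeration of group assignments) for combined n <= 20 and a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param a,b Numeric vectors for the two independent groups (>= 3 each).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (of `a` relative
#'   to `b`).
#' @return A `cohort_test` list: `U` (for group `a`), `p`, `n`, `method`.
#' @export
mann_whitney <- function(a, b, alternative = c("two_sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  abort_if(length(a) < 3 || length(b) < 3,
           "both groups need at least 3 observations")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (N <= 20) {
    combos <- utils::combn(N, n1)
    R1_all <- colSums(matrix(r[combos], nrow = n1))
    U_all <- R1_all - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_le <- mean(U_all <= U + eps)
    p_ge <- mean(U_all >= U - eps)
    p <- switch(alternative,
                two_sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    abort_if(sigma == 0, "all observations tied")
    z <- switch(alternative,
                two_sided = (abs(U - mu) - 0.5) / sigma,
                less = (U - mu + 0.5) / sigma,
                greater = (U - mu - 0.5) / sigma)
    p <- switch(alternative,
                two_sided = 2 * stats::pnorm(-max(z, 0)),
                less = stats::pnorm(z),
                greater = stats::pnorm(-z))
    method <- "normal approximation"
  }
  structure(list(U = U, p = min(p, 1), n = c(n1 = n1, n2 = n2),
                 method = method, test = "mann_whitney",
                 alternative = alternative),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  if (x$test == "spearman") {
    cat("Spearman: rho = ", format(x$rho, digits = 4), ", p = ",
        format(x$p, digits = 4), " (n = ", x$n, ", ", x$method, ")\n",
        sep = "")
  } else {
    cat("Mann-Whitney: U = ", x$U, ", p = ", format(x$p, digits = 4),
        " (n = ", x$n[1], "+", x$n[2], ", ", x$method, ")\n", sep = "")
  }
  invisible(x)
}

#' Split a cohort into extreme groups
#'
#' Selects the bottom and top `n_per_group` rows by the key variable
#' (e.g. the youngest and the oldest donors, n = 8 of 44; or n = 6 of the
#' 31-donor lateralization subset). Ties at the cut are broken by id order
#' and reported.
#'
#' @param table Cohort tibble with an `id` column.
#' @param key Column name to rank by (`"age"`, `"pct_lipofuscin"`, ...).
#' @param n_per_group Group size.
#' @param subset Optional logical vector or expression result selecting the
#'   rows eligible for splitting (e.g. donors with a lateralization value).
#' @return List with `low` and `high` tibbles and `tie_broken` (logical).
#' @export
split_extreme_groups <- function(table, key, n_per_group, subset = NULL) {
  abort_if(!key %in% names(table), paste("no column", key))
  tb <- table
  if (!is.null(subset)) tb <- tb[subset, ]
  tb <- tb[!is.na(tb[[key]]), ]
  abort_if(nrow(tb) < 2 * n_per_group, "insufficient rows")
  ord <- order(tb[[key]], tb$id)
  low <- tb[ord[seq_len(n_per_group)], ]
  high <- tb[rev(ord)[seq_len(n_per_group)], ]
  v <- sort(tb[[key]])
  tie_low <- v[n_per_group] == v[n_per_group + 1]
  tie_high <- v[nrow(tb) - n_per_group] == v[nrow(tb) - n_per_group + 1]
  list(low = low, high = high, tie_broken = tie_low || tie_high)
}

#' Median and interquartile range summary
#'
#' `median [Q1, Q3]` with type-7 (linear interpolation) quantiles.
#'
#' @param x Numeric vector (missing values dropped).
#' @param digits Significant digits for the formatted string.
#' @return Tibble with `median`, `q1`, `q3`, `n` and a formatted `label`.
#' @export
median_iqr <- function(x, digits = 3) {
  x <- x[!is.na(x)]
  abort_if(length(x) == 0, "no data")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3], n = length(x),
                 label = sprintf("%s [%s, %s]",
                                 format(q[2], digits = digits),
                                 format(q[1], digits = digits),
                                 format(q[3], digits = digits)))
}

#' Correlate cohort metrics against a key variable
#'
#' Runs [spearman()] of every metric column against the key and returns a
#' tidy table.
#'
#' @param table Cohort tibble.
#' @param key Column correlated against (default `"age"`).
#' @param metrics Character vector of metric columns (default: the canonical
#'   morphometry columns present in the table).
#' @return Tibble with one row per metric: `metric`, `rho`, `p`, `n`.
#' @export
cohort_correlations <- function(table, key = "age", metrics = NULL) {
  if (is.null(metrics))
    metrics <- intersect(c("pct_cx43_cm", "pct_cx43_t", "expr_cm", "expr_t",
                           "heterogeneity_um", "pct_lateral", "pct_fibrosis",
                           "pct_lipofuscin"), names(table))
  abort_if(length(metrics) == 0, "no metric columns found")
  rows <- lapply(metrics, function(mcol) {
    t <- tryCatch(spearman(table[[key]], table[[mcol]]),
                  error = function(e) NULL)
    tibble::tibble(metric = mcol,
                   rho = if (is.null(t)) NA_real_ else t$rho,
                   p = if (is.null(t)) NA_real_ else t$p,
                   n = if (is.null(t)) sum(complete.cases(
                     table[[key]], table[[mcol]])) else t$n)
  })
  dplyr::bind_rows(rows)
}

#' Compare two cohort groups metric by metric
#'
#' Runs [mann_whitney()] for every metric column between the two groups of a
#' [split_extreme_groups()] result and returns a tidy table with
#' median-\[IQR\] summaries.
#'
#' @param groups List with `low` and `high` tibbles.
#' @param metrics Metric columns (default as in [cohort_correlations()]).
#' @return Tibble with one row per metric: `metric`, `low_label`,
#'   `high_label`, `U`, `p`.
#' @export
compare_groups <- function(groups, metrics = NULL) {
  if (is.null(metrics))
    metrics <- intersect(c("pct_cx43_cm", "pct_cx43_t", "expr_cm", "expr_t",
                           "heterogeneity_um", "pct_lateral", "pct_fibrosis",
                           "pct_lipofuscin"), names(groups$low))
  rows <- lapply(metrics, function(mcol) {
    a <- groups$low[[mcol]]; b <- groups$high[[mcol]]
    t <- tryCatch(mann_whitney(a, b), error = function(e) NULL)
    tibble::tibble(metric = mcol,
                   low_label = median_iqr(a)$label,
                   high_label = median_iqr(b)$label,
                   U = if (is.null(t)) NA_real_ else t$U,
                   p = if (is.null(t)) NA_real_ else t$p)
  })
  dplyr::bind_rows(rows)
}
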