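#' Exact two-tailed Mann-Whitney U test
#'
#' Rank-sum test with the U statistic computed from midranks. For group
#' sizes with `max(n1, n2) <= 8` and no ties, the p-value is exact: the
#' null distribution of U is built by full enumeration of all
#' `choose(n1 + n2, n1)` group labelings, and the two-tailed p doubles the
#' smaller tail (capped at 1). With larger groups or ties, the normal
#' approximation with continuity and tie correction is used.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max Largest group size for which enumeration is attempted.
#' @return A `mwu_test` list: `U` (for the first group), `p_two_tailed`,
#'   `n1`, `n2`, `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney_exact(1:6, 7:12)$p_two_tailed  # 2/924, complete separation
mann_whitney_exact <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) {
    stop("mann_whitney_exact: both groups must be nonempty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                          # midranks for ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && max(n1, n2) <= exact_max) {
    tab <- u_null_distribution(n1, n2)
    p_le <- sum(tab$count[tab$u <= U]) / sum(tab$count)
    p_ge <- sum(tab$count[tab$u >= U]) / sum(tab$count)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(U = U, p_two_tailed = p, n1 = n1, n2 = n2, method = method),
            class = "mwu_test")
}

# exact null distribution of U for group sizes n1, n2 (no ties):
# enumerate all rank subsets of size n1 out of n1 + n2
u_null_distribution <- function(n1, n2) {
  combs <- utils::combn(n1 + n2, n1)
  us <- colSums(combs) - n1 * (n1 + 1) / 2
  tab <- table(us)
  list(u = as.numeric(names(tab)), count = as.numeric(tab))
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-tailed p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_tailed, x$method))
  invisible(x)
}

#' Least-squares linear fit through the origin
#'
#' Fits `y = slope * x` with `slope = sum(x y) / sum(x^2)`. `r_squared` is
#' computed against the centered total sum of squares (comparable to an
#' ordinary regression R^2; the uncentered convention is available with
#' `centered_r2 = FALSE`, with a warning since it flatters the fit). The
#' 95% confidence interval is `slope +/- t(0.975, n - 1) * se`.
#'
#' @param x,y Numeric vectors (e.g. power in mW, signal in nm).
#' @param centered_r2 Use the centered total sum of squares (default).
#' @details The standard error is heteroscedasticity-robust (HC3 sandwich):
#'   photothermal signals carry noise proportional to the signal itself, so
#'   residual variance grows with `x` and the classical homoscedastic
#'   standard error badly understates the slope uncertainty. The t quantile
#'   uses `(number of distinct x levels) - 1` degrees of freedom -- for a
#'   design with replicate eyes per power this is the between-level
#'   information actually carried by the slope.
#' @return A `fit_origin` list: `slope`, `r_squared`, `ci95`, `se`, `df`,
#'   `n_points`, `r_squared_flagged` (TRUE when R^2 is undefined and
#'   reported as 0, e.g. constant y).
#' @export
linear_fit_origin <- function(x, y, centered_r2 = TRUE) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("linear_fit_origin: need at least 2 points", call. = FALSE)
  if (all(x == 0)) stop("linear_fit_origin: all x are zero", call. = FALSE)
  sxx <- sum(x^2)
  slope <- sum(x * y) / sxx
  res <- y - slope * x
  n <- length(x)
  ssres <- sum(res^2)
  sstot <- if (centered_r2) sum((y - mean(y))^2) else sum(y^2)
  if (!centered_r2) {
    warning("linear_fit_origin: uncentered R^2 requested; values are not",
            " comparable to ordinary regression R^2")
  }
  flagged <- sstot == 0
  r2 <- if (flagged) 0 else 1 - ssres / sstot
  h <- pmin(x^2 / sxx, 0.999)                 # leverage, guarded
  se <- sqrt(sum(x^2 * res^2 / (1 - h)^2)) / sxx
  df <- max(1L, length(unique(x[x != 0])) - 1L)
  ci <- slope + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(slope = slope, r_squared = r2, ci95 = ci, se = se,
                 df = df, n_points = n, r_squared_flagged = flagged),
            class = "fit_origin")
}

#' @export
print.fit_origin <- function(x, ...) {
  cat(sprintf("through-origin fit: slope %.4g [95%% CI %.4g, %.4g], R^2 %.3f (n = %d)\n",
              x$slope, x$ci95[1], x$ci95[2], x$r_squared, x$n_points))
  invisible(x)
}

#' Pre-registered group comparisons on a result table
#'
#' Runs [mann_whitney_exact()] for each requested pair of groups. No
#' multiple-testing correction is applied; the number of comparisons is
#' annotated in the output.
#'
#' @param table Data frame with columns `group` and `value` (one row per
#'   eye).
#' @param pairs List of length-2 character vectors naming group pairs.
#' @return Data frame: one row per comparison with `group1`, `group2`,
#'   `n1`, `n2`, `U`, `p_two_tailed`, `method`, `significant_05`,
#'   `significant_01`, plus attribute `n_comparisons`.
#' @export
compare_groups <- function(table, pairs) {
  stopifnot(is.data.frame(table), all(c("group", "value") %in% names(table)))
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    if (!all(pr %in% table$group)) {
      stop("compare_groups: unknown group label in ",
           paste(pr, collapse = " vs "), call. = FALSE)
    }
    a <- table$value[table$group == pr[1]]
    b <- table$value[table$group == pr[2]]
    t <- mann_whitney_exact(a, b)
    data.frame(group1 = pr[1], group2 = pr[2], n1 = t$n1, n2 = t$n2,
               U = t$U, p_two_tailed = t$p_two_tailed, method = t$method,
               significant_05 = t$p_two_tailed < 0.05,
               significant_01 = t$p_two_tailed < 0.01)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_comparisons") <- nrow(out)
  out
}

#' Power-series analysis: through-origin fit and detection flags
#'
#' Summarizes a power-series result table (columns `power`, `value`,
#' optionally `eye_id`): per-power mean and standard deviation, a
#' through-origin fit of mean signal versus power, and -- when a 0 mW group
#' is present -- a per-power flag marking powers whose values do not differ
#' from the 0 mW group (Mann-Whitney, p >= 0.05): the detection limit.
#'
#' @param table Data frame with `power` (mW) and `value` (nm).
#' @return List: `fit` ([linear_fit_origin()] on the per-power means),
#'   `per_power` (data.frame `power`, `mean`, `sd`, `n`,
#'   `detected`), `n_eyes`.
#' @export
power_series_analysis <- function(table) {
  stopifnot(is.data.frame(table), all(c("power", "value") %in% names(table)))
  powers <- sort(unique(table$power))
  if (length(powers) < 2) {
    stop("power_series_analysis: need at least 2 power levels", call. = FALSE)
  }
  per <- do.call(rbind, lapply(powers, function(p) {
    v <- table$value[table$power == p]
    data.frame(power = p, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  # fit on all per-eye rows: for a balanced design the slope equals the
  # fit of the per-power means, while the replicate scatter informs the CI
  nz_rows <- table$power > 0
  fit <- linear_fit_origin(table$power[nz_rows], table$value[nz_rows])
  per$detected <- NA
  if (any(table$power == 0)) {
    zero <- table$value[table$power == 0]
    per$detected <- vapply(per$power, function(p) {
      if (p == 0) return(FALSE)
      v <- table$value[table$power == p]
      mann_whitney_exact(v, zero)$p_two_tailed < 0.05
    }, logical(1))
  }
  list(fit = fit, per_power = per,
       n_eyes = if ("eye_id" %in% names(table))
         length(unique(table$eye_id)) else NA_integer_)
}
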