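#' Mann-Whitney U test for two independent groups
#'
#' Rank-sum test with midrank handling of ties. The U statistic is computed
#' from the rank sum of the first group; the two-sided p value comes from
#' the exact null distribution when the samples are tie-free and
#' `n1 * n2 <= 400`, and otherwise from the normal approximation with tie
#' correction and continuity correction (via [stats::wilcox.test()]).
#'
#' @param a,b numeric vectors of observations, each non-empty.
#' @return list of class `"stat_result"`: `statistic` (U of group `a`),
#'   `p_value` (two-sided), `n1`, `n2`, `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && n1 * n2 <= 400
  p <- if (stats::var(c(a, b)) == 0) 1 else   # all observations equal
    unname(suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value))
  structure(list(statistic = u, p_value = p,
                 n1 = n1, n2 = n2,
                 method = if (exact) "exact" else "normal_approx"),
            class = "stat_result")
}

#' Spearman rank correlation with permutation p value
#'
#' rho is the Pearson correlation of midranks. The two-sided p value is a
#' permutation p: exact enumeration of all n! orderings for n <= 8, and a
#' seeded Monte-Carlo permutation test otherwise. The caller's RNG state is
#' left untouched.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_perm Monte-Carlo permutations when n > 8 (default 10000).
#' @param seed seed for the Monte-Carlo draw (default 1).
#' @return list of class `"stat_result"`: `statistic` (rho), `p_value`,
#'   `n1` = `n2` = n, `method`. A constant input gives `NA` rho with a
#'   warning.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))  # rho = 0.7
#' @export
spearman_cor <- function(x, y, n_perm = 10000, seed = 1) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input: Spearman rho undefined")
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          n1 = n, n2 = n, method = "undefined"),
                     class = "stat_result"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  eps <- 1e-12
  if (n <= 8) {
    P <- pracma::perms(seq_len(n))
    rho_perm <- apply(P, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rho_perm) >= abs(rho) - eps)
    method <- "exact"
  } else {
    rho_perm <- with_seed(seed, replicate(n_perm, stats::cor(rx, sample(ry))))
    # add-one correction keeps the Monte-Carlo p valid and never exactly 0
    p_value <- (1 + sum(abs(rho_perm) >= abs(rho) - eps)) / (n_perm + 1)
    method <- "monte_carlo"
  }
  structure(list(statistic = rho, p_value = p_value, n1 = n, n2 = n,
                 method = method),
            class = "stat_result")
}

#' Median and quartiles
#'
#' Summary used for all reported fluorescence and growth distributions:
#' median with lower and upper quartiles under the inclusive
#' linear-interpolation rule (R's default quantile type 7). The rule's name
#' is carried in the result so summaries are auditable.
#'
#' @param values numeric vector, n >= 1.
#' @return list with `q1`, `median`, `q3`, `n` and `rule`.
#' @examples
#' median_quartiles(1:5)  # 2, 3, 4
#' @export
median_quartiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(q1 = q[1], median = q[2], q3 = q[3], n = length(values),
       rule = "linear interpolation (R quantile type 7)")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("statistic = %.6g, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$statistic, x$p_value, x$n1, x$n2, x$method))
  invisible(x)
}
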