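## Pair-level normalization, the asymmetry variance decomposition,
## randomization inference for jointly normalized pair data, regression
## slope comparison, and Bartlett's variance-homogeneity test.

#' Pair normalization
#'
#' Each daughter value X in a pair is transformed to `(X - u)/u` with
#' `u = (old + new)/2` the pair mean. The two normalized values of a pair
#' sum to exactly zero, which is what makes the variance decomposition
#' identity exact.
#'
#' @param old_value,new_value matched raw values; every pair mean must be
#'   positive.
#' @return list with vectors `old` and `new` of normalized values.
#' @export
pair_normalize <- function(old_value, new_value) {
  u <- (old_value + new_value) / 2
  if (any(u <= 0)) stop("pair mean must be > 0")
  list(old = (old_value - u) / u, new = (new_value - u) / u)
}

#' Quartile normalization
#'
#' Divides each length-quartile density by the sum of the cell's four
#' quartile densities; the normalized quartet sums to exactly 1.
#'
#' @param densities numeric vector of 4 (NP, L2, L3, OP) or an n x 4 matrix.
#' @return same shape, rows summing to 1.
#' @export
quartile_normalize <- function(densities) {
  if (is.matrix(densities)) {
    if (ncol(densities) != 4L) stop("need 4 quartile columns")
    s <- rowSums(densities)
    if (any(s <= 0)) stop("quartile sum must be > 0")
    densities / s
  } else {
    if (length(densities) != 4L) stop("need 4 quartile densities")
    s <- sum(densities)
    if (s <= 0) stop("quartile sum must be > 0")
    densities / s
  }
}

## population (divide by n) or sample (n-1) variance
.variance <- function(x, convention) {
  m <- mean(x)
  ss <- sum((x - m)^2)
  if (convention == "population") ss / length(x) else ss / (length(x) - 1)
}

#' Variance decomposition of paired daughter values
#'
#' Separates the total variance of pooled pair-normalized daughter values
#' into a deterministic component due to the systematic old/new asymmetry
#' and a stochastic remainder. With normalized values `+-d_i/2` per pair:
#' `D = mean(new - old)`, `V_T` = variance of the pooled 2n values,
#' `h^2 = (D^2/4) / V_T`, `V_E = V_T - D^2/4 = V_T (1 - h^2)`. Under the
#' population-variance convention the identity
#' `V_T = (V_Old + V_New)/2 + D^2/4` is exact, because pair normalization
#' forces each pair to sum to zero.
#'
#' @param pairs pair table (`data.frame` with `old_value`, `new_value`, and
#'   optionally `mother_type`).
#' @param mother_class optionally restrict to one `mother_type`.
#' @param convention "population" (default; identity exact) or "sample".
#' @return object of class `decomposition_result`: list with `V_T`, `D`,
#'   `D2_4`, `h2`, `V_E`, `V_old`, `V_new`, `n`, `p_D_gt_0` (one-tailed
#'   paired t-test of D > 0), `convention`.
#' @export
variance_decomposition <- function(pairs, mother_class = NULL,
                                   convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (!is.null(mother_class)) {
    if (!"mother_type" %in% names(pairs))
      stop("pair table has no mother_type column")
    pairs <- pairs[pairs$mother_type == mother_class, , drop = FALSE]
  }
  if (nrow(pairs) < 2L) stop("need at least 2 pairs")
  z <- pair_normalize(pairs$old_value, pairs$new_value)
  D <- mean(z$new - z$old)
  pooled <- c(z$old, z$new)
  V_T <- .variance(pooled, convention)
  D2_4 <- D^2 / 4
  if (V_T == 0 && D != 0)
    stop("internal inconsistency: V_T = 0 with D != 0")  # impossible
  h2 <- if (V_T > 0) D2_4 / V_T else 0
  diffs <- z$new - z$old
  p <- if (stats::sd(diffs) > 0)
    stats::t.test(diffs, mu = 0, alternative = "greater")$p.value
  else NA_real_
  structure(list(V_T = V_T, D = D, D2_4 = D2_4, h2 = h2,
                 V_E = V_T - D2_4,
                 V_old = .variance(z$old, convention),
                 V_new = .variance(z$new, convention),
                 n = nrow(pairs), p_D_gt_0 = p, convention = convention),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("Variance decomposition (n = %d pairs, %s variance)\n",
              x$n, x$convention))
  cat(sprintf("  V_T   = %.5g\n  D     = %.4g  (p[D>0] = %.3g)\n", x$V_T,
              x$D, x$p_D_gt_0))
  cat(sprintf("  D^2/4 = %.5g\n  h^2   = %.3f\n  V_E   = %.5g\n",
              x$D2_4, x$h2, x$V_E))
  invisible(x)
}

#' Decomposition arithmetic from summary values
#'
#' Computes `h^2` and `V_E` from a reported total variance and either the
#' asymmetry `D` or the deterministic component `D^2/4` directly (published
#' tables sometimes round the two inconsistently).
#'
#' @param V_T total variance (> 0).
#' @param D mean normalized difference (optional if `D2_4` given).
#' @param D2_4 deterministic component (optional; computed from `D` if
#'   missing).
#' @return list with `V_T`, `D2_4`, `h2`, `V_E`.
#' @export
decomposition_from_summary <- function(V_T, D = NULL, D2_4 = NULL) {
  if (V_T <= 0) stop("V_T must be > 0")
  if (is.null(D2_4)) {
    if (is.null(D)) stop("supply D or D2_4")
    D2_4 <- D^2 / 4
  }
  h2 <- D2_4 / V_T
  list(V_T = V_T, D2_4 = D2_4, h2 = h2, V_E = V_T * (1 - h2))
}

#' Randomization test for the correlation of jointly normalized pair data
#'
#' The 2n pooled points (one old-daughter and one new-daughter point per
#' mother) are not independent: joint pair normalization forces the two
#' members of each pair to mirror each other. The observed correlation and
#' regression slope are therefore assessed against a null built by shuffling
#' which mother's y-pair is matched to each x-pair (keeping pair structure
#' intact) and additionally swapping the y-pair's old/new labels with
#' probability 1/2 per pair. `p = (1 + #[null >= observed]) / (n_perm + 1)`,
#' one-tailed for positive association.
#'
#' @param x_old,x_new pair-normalized x values (e.g. ribosome density).
#' @param y_old,y_new pair-normalized y values (e.g. elongation rate),
#'   matched by mother.
#' @param n_perm number of permutations (>= 1); default 1e5.
#' @param seed optional integer seed for the permutation stream.
#' @return list with `r`, `slope`, `p`, `n_pairs`, `n_perm`.
#' @export
randomization_correlation <- function(x_old, x_new, y_old, y_new,
                                      n_perm = 1e5, seed = NULL) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  n <- length(x_old)
  stopifnot(length(x_new) == n, length(y_old) == n, length(y_new) == n)
  if (!is.null(seed)) set.seed(seed)
  x <- c(x_old, x_new); y <- c(y_old, y_new)
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) stop("degenerate (constant) values")
  sxy_obs <- sum((x - mean(x)) * (y - mean(y)))
  r_obs <- sxy_obs / sqrt(sxx * syy)
  slope <- sxy_obs / sxx
  # jointly normalized pairs are antisymmetric (old = -new), so the pooled
  # cross-product reduces to 2 * sum(x_new * y_new) over matched pairs and
  # swapping a y-pair's labels flips the sign of its contribution
  xc <- x_new - mean(x) # pooled mean is 0 for exactly normalized input
  yc <- y_new - mean(y)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    sxy_null <- 2 * sum(xc * sgn * yc[perm])
    r_null <- sxy_null / sqrt(sxx * syy)
    if (r_null >= r_obs) exceed <- exceed + 1L
  }
  list(r = r_obs, slope = slope, p = (1 + exceed) / (n_perm + 1),
       n_pairs = n, n_perm = n_perm)
}

#' Compare two regression slopes from their SEMs
#'
#' `t = (slope1 - slope2) / sqrt(sem1^2 + sem2^2)` with
#' `df = n1 + n2 - 4` (two simple regressions, two parameters each);
#' two-tailed p from the t distribution.
#'
#' @param slope1,slope2 estimated slopes.
#' @param sem1,sem2 their standard errors (> 0).
#' @param n1,n2 the regression sample sizes.
#' @return list with `t`, `df`, `p`.
#' @export
compare_slopes <- function(slope1, sem1, n1, slope2, sem2, n2) {
  if (sem1 <= 0 || sem2 <= 0) stop("SEMs must be > 0")
  t <- (slope1 - slope2) / sqrt(sem1^2 + sem2^2)
  df <- n1 + n2 - 4
  if (df < 1) stop("not enough observations")
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Bartlett's test of homogeneity of variances
#'
#' Closed-form Bartlett statistic across k groups:
#' `X^2 = [(N - k) ln s_p^2 - sum (n_i - 1) ln s_i^2] / C` with
#' `C = 1 + (sum 1/(n_i - 1) - 1/(N - k)) / (3 (k - 1))`, compared to a
#' chi-square with k - 1 df. Sample variances (n - 1 denominator) are used,
#' as the test assumes.
#'
#' @param groups list of numeric vectors, each of length >= 2 with positive
#'   variance.
#' @return list with `statistic`, `df`, `p`.
#' @export
variance_homogeneity <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("every group needs n >= 2")
  v <- vapply(groups, stats::var, 0)
  if (any(v <= 0)) stop("a group has zero variance")
  N <- sum(n)
  sp2 <- sum((n - 1) * v) / (N - k)
  stat_num <- (N - k) * log(sp2) - sum((n - 1) * log(v))
  C <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  stat <- stat_num / C
  list(statistic = stat, df = k - 1L,
       p = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

#' Table-style decomposition report for a pair table
#'
#' Reproduces the variance-component report for a measured quantity:
#' block A/B rows are the per-mother-class decompositions for the value and
#' rate columns, block C compares the stochastic components (Bartlett's test
#' across mother classes on the pair-difference residuals, whose variance
#' estimates V_E).
#'
#' @param pairs pair table with `mother_type`, `old_value`, `new_value` and
#'   optionally `old_rate`, `new_rate`.
#' @param convention variance convention, see [variance_decomposition()].
#' @return list with `value` and (if rates present) `rate` blocks (each a
#'   `data.frame` with one row per mother class) and `V_E_comparison`
#'   (Bartlett p-values).
#' @export
analyze_pair_table <- function(pairs, convention = "population") {
  classes <- sort(unique(pairs$mother_type), decreasing = TRUE) # old, new
  one_block <- function(old_col, new_col) {
    rows <- lapply(classes, function(cl) {
      sub <- pairs[pairs$mother_type == cl, , drop = FALSE]
      d <- variance_decomposition(
        data.frame(old_value = sub[[old_col]], new_value = sub[[new_col]]),
        convention = convention)
      data.frame(mother_class = cl, n = d$n, V_T = d$V_T, D = d$D,
                 D2_4 = d$D2_4, h2 = d$h2, V_E = d$V_E,
                 p_D_gt_0 = d$p_D_gt_0, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  residuals_by_class <- function(old_col, new_col) {
    lapply(classes, function(cl) {
      sub <- pairs[pairs$mother_type == cl, , drop = FALSE]
      z <- pair_normalize(sub[[old_col]], sub[[new_col]])
      (z$new - z$old) / 2   # variance of this estimates V_E
    })
  }
  out <- list(value = one_block("old_value", "new_value"))
  comp <- list(value_across_mothers = if (length(classes) >= 2L)
    variance_homogeneity(residuals_by_class("old_value", "new_value"))$p
    else NA_real_)
  if (all(c("old_rate", "new_rate") %in% names(pairs)) &&
      all(pairs$old_rate + pairs$new_rate > 0)) {
    out$rate <- one_block("old_rate", "new_rate")
    comp$rate_across_mothers <- if (length(classes) >= 2L)
      variance_homogeneity(residuals_by_class("old_rate", "new_rate"))$p
      else NA_real_
    for (cl in classes) {
      comp[[paste0("rate_vs_value_", cl)]] <- variance_homogeneity(list(
        residuals_by_class("old_value", "new_value")[[match(cl, classes)]],
        residuals_by_class("old_rate", "new_rate")[[match(cl, classes)]]))$p
    }
  }
  out$V_E_comparison <- comp
  out
}
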