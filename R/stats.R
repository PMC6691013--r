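# Study-level statistics: Holm-Sidak familywise adjustment, two-sample
# t-test power and sample size via the noncentral t, and tidy reporting glue
# over the standard rank tests.

#' Holm-Sidak adjusted p-values
#'
#' Step-down Sidak procedure controlling the familywise error rate: sort the
#' raw p-values ascending, form \eqn{1-(1-p_{(j)})^{m-j+1}}, enforce
#' monotonicity by a running maximum, cap at 1, and map back to the input
#' order. (Some software labels this method "step-up"; the named procedure
#' is the step-down one and that is what is computed.)
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_sidak(c(0.01, 0.04))
#' @export
holm_sidak <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_data("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Power of the two-sided two-sample pooled t-test
#'
#' Exact power via the noncentral t distribution with \eqn{df = 2n - 2} and
#' noncentrality \eqn{(\delta/\sigma)\sqrt{n/2}} for equal group sizes.
#'
#' @param n_per_group Sample size per group (>= 2).
#' @param delta True difference in group means.
#' @param sd Common standard deviation (> 0).
#' @param alpha Two-sided type-1 error rate.
#' @return Power in [0, 1].
#' @export
ttest_power <- function(n_per_group, delta, sd, alpha = 0.05) {
  check_scalar(n_per_group, "n_per_group", lower = 2)
  check_scalar(sd, "sd", lower = 0, closed_lower = FALSE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  df <- 2 * n_per_group - 2
  ncp <- (delta / sd) * sqrt(n_per_group / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Smallest per-group sample size reaching a target power
#'
#' Increments n from 2 until [ttest_power()] reaches \code{target_power}.
#' With the study's planning figures (mean incidences 75\% vs 25\%, SD 20\%,
#' alpha 0.05, power 0.80) this returns 4 per group.
#'
#' @param delta True difference in group means (non-zero).
#' @param sd Common standard deviation.
#' @param alpha Two-sided type-1 error rate.
#' @param target_power Required power in (0, 1).
#' @param n_max Search bound.
#' @return Smallest integer n per group.
#' @examples
#' sample_size(delta = 50, sd = 20)  # 4
#' @export
sample_size <- function(delta, sd, alpha = 0.05, target_power = 0.80,
                        n_max = 1e5) {
  if (delta == 0) stop_data("`delta` must be non-zero")
  check_scalar(target_power, "target_power", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  n <- 2
  while (n <= n_max) {
    if (ttest_power(n, abs(delta), sd, alpha) >= target_power) return(n)
    n <- n + 1
  }
  stop_data("target power not reachable within the search bound")
}

#' Significance stars for a p-value
#'
#' The reporting convention: * p < 0.05, ** p < 0.01, *** p < 0.001,
#' **** p < 0.0001; "ns" otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  cut_levels <- c(0.0001, 0.001, 0.01, 0.05)
  vapply(p, function(x) {
    k <- sum(x < cut_levels)
    if (k == 0) "ns" else strrep("*", k)
  }, character(1))
}

#' Rank-test group comparison with familywise adjustment
#'
#' Unpaired two-group comparisons use the Mann-Whitney U test; unpaired
#' multi-group designs report the Kruskal-Wallis omnibus test plus pairwise
#' Mann-Whitney comparisons. Pairwise p-values are adjusted across the family
#' with [holm_sidak()] and annotated with [significance_stars()].
#'
#' @param values Numeric measurements.
#' @param condition Group label per measurement (>= 2 non-empty groups).
#' @return data.frame with \code{comparison}, \code{test}, \code{p_raw},
#'   \code{p_adjusted}, \code{stars}.
#' @export
compare_groups <- function(values, condition) {
  condition <- as.character(condition)
  groups <- unique(condition)
  if (length(groups) < 2)
    stop_data("need at least two groups to compare")
  if (any(table(condition) == 0)) stop_data("every group must be non-empty")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  p_pair <- vapply(pairs, function(gp) {
    stats::wilcox.test(values[condition == gp[1]],
                       values[condition == gp[2]], exact = FALSE)$p.value
  }, numeric(1))
  adj <- holm_sidak(p_pair)
  out <- data.frame(
    comparison = vapply(pairs, paste, character(1), collapse = " vs "),
    test = "Mann-Whitney U",
    p_raw = p_pair, p_adjusted = adj, stars = significance_stars(adj),
    stringsAsFactors = FALSE
  )
  if (length(groups) > 2) {
    kw <- stats::kruskal.test(values, factor(condition))
    out <- rbind(data.frame(comparison = "omnibus",
                            test = "Kruskal-Wallis",
                            p_raw = kw$p.value, p_adjusted = kw$p.value,
                            stars = significance_stars(kw$p.value),
                            stringsAsFactors = FALSE),
                 out)
  }
  rownames(out) <- NULL
  out
}
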