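# Behavioral and expression-level group statistics: bootstrap-resampled
# ANOVA and t tests, multiple-comparison and FDR corrections, two-sample
# KS tests, Cohen's d, and bootstrap CIs of means.

.split_groups <- function(values, group) {
  split(values, factor(group, levels = unique(group)))
}

#' One-way ANOVA F statistic
#'
#' Classical between/within mean-square ratio `F = MS_between / MS_within`
#' on the empirical grouping. Used as the statistic of interest inside
#' [bootstrap_p()]; its null distribution is never referred to an F table
#' there, so no normality assumption is imported.
#'
#' @param values numeric outcomes (e.g. freezing seconds) or a
#'   [behavior_table()].
#' @param group group labels (ignored when `values` is a behavior table).
#' @return the F statistic.
#' @export
oneway_F <- function(values, group = NULL) {
  if (inherits(values, "behavior_table")) {
    group <- values$group
    values <- values$freezing_s
  }
  g <- .split_groups(values, group)
  if (length(g) < 2) stop("need at least 2 groups")
  n <- length(values)
  k <- length(g)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  if (ssw == 0) stop("zero within-group variance; F undefined")
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Bootstrap null p-value of a statistic
#'
#' Builds a sample-based null distribution of an arbitrary group statistic
#' by 1) resampling the pooled subjects with replacement, 2) assigning the
#' resampled values positionally to the original group slots (which breaks
#' the group-outcome link, so the resampled statistics form a null
#' distribution), 3) repeating `n_resamples` times. The p-value is the
#' fraction of resampled statistics strictly greater than the empirical one
#' (`add_one` switches to the (b + 1)/(m + 1) convention).
#'
#' @param statistic_fn function of `(values, group)` returning a scalar.
#' @param values numeric outcomes or a [behavior_table()].
#' @param group group labels (ignored for a behavior table).
#' @param n_resamples bootstrap resamples (values below 100 warn).
#' @param rng_seed integer seed; the same seed gives the identical p.
#' @param add_one add-one small-sample correction.
#' @return list with `statistic` (empirical value), `p`, `n_resamples`.
#' @export
bootstrap_p <- function(statistic_fn, values, group = NULL,
                        n_resamples = 10000, rng_seed = 1L,
                        add_one = FALSE) {
  if (inherits(values, "behavior_table")) {
    group <- values$group
    values <- values$freezing_s
  }
  if (n_resamples < 100)
    warning("fewer than 100 resamples gives an unstable p-value")
  emp <- statistic_fn(values, group)
  set.seed(as.integer(rng_seed))
  n <- length(values)
  count <- 0L
  for (b in seq_len(n_resamples)) {
    stat_b <- statistic_fn(values[sample.int(n, replace = TRUE)], group)
    if (is.finite(stat_b) && stat_b > emp) count <- count + 1L
  }
  p <- if (add_one) (count + 1) / (n_resamples + 1) else count / n_resamples
  list(statistic = emp, p = p, n_resamples = n_resamples)
}

# Welch t statistic between two vectors
.welch_t <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Pairwise bootstrap t tests with multiplicity correction
#'
#' Welch (unequal-variance) t per comparison, with the two-sided bootstrap
#' null p of [bootstrap_p()] applied to `|t|`, and the p-value corrected by
#' the number of concomitant comparisons (Bonferroni: `min(1, p * k)`).
#'
#' @param bt a [behavior_table()] (or data.frame with `group` and
#'   `freezing_s`).
#' @param comparisons list of length-2 character vectors of group labels;
#'   default all unordered pairs.
#' @param n_resamples bootstrap resamples per comparison.
#' @param rng_seed integer seed.
#' @return data.frame: `group_a, group_b, t, p, p_corrected` (one row per
#'   comparison; `k` attached as an attribute).
#' @export
pairwise_t_bootstrap <- function(bt, comparisons = NULL,
                                 n_resamples = 10000, rng_seed = 1L) {
  groups <- unique(bt$group)
  if (is.null(comparisons)) {
    cmb <- utils::combn(groups, 2)
    comparisons <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  k <- length(comparisons)
  rows <- lapply(seq_along(comparisons), function(j) {
    pair <- comparisons[[j]]
    sel <- bt$group %in% pair
    vals <- bt$freezing_s[sel]
    grp <- bt$group[sel]
    stat_fn <- function(v, g) abs(.welch_t(v[g == pair[1]], v[g == pair[2]]))
    bp <- bootstrap_p(stat_fn, vals, grp, n_resamples = n_resamples,
                      rng_seed = as.integer(rng_seed) + j)
    t_emp <- .welch_t(bt$freezing_s[bt$group == pair[1]],
                      bt$freezing_s[bt$group == pair[2]])
    data.frame(group_a = pair[1], group_b = pair[2],
               t = t_emp, p = bp$p, p_corrected = min(1, bp$p * k))
  })
  out <- do.call(rbind, rows)
  attr(out, "k") <- k
  out
}

#' Region-wise expression comparison with FDR correction
#'
#' Compares each common region's expression between two groups by a Welch t
#' test with the bootstrap null p of [bootstrap_p()] (two-sided via `|t|`),
#' then applies Benjamini-Hochberg false-discovery-rate correction across
#' regions.
#'
#' @param exprA,exprB [expression_matrix()] objects.
#' @param n_resamples bootstrap resamples per region.
#' @param rng_seed integer seed.
#' @return data.frame: `region, t, p, p_fdr`.
#' @export
regionwise_expression_test <- function(exprA, exprB,
                                       n_resamples = 10000, rng_seed = 1L) {
  common <- intersect(exprA$regions, exprB$regions)
  if (length(common) == 0) stop("no common regions")
  rows <- lapply(seq_along(common), function(j) {
    reg <- common[j]
    a <- exprA$values[, reg]
    b <- exprB$values[, reg]
    vals <- c(a, b)
    grp <- rep(c("A", "B"), c(length(a), length(b)))
    stat_fn <- function(v, g) abs(.welch_t(v[g == "A"], v[g == "B"]))
    bp <- bootstrap_p(stat_fn, vals, grp, n_resamples = n_resamples,
                      rng_seed = as.integer(rng_seed) + j)
    data.frame(region = reg, t = .welch_t(a, b), p = bp$p)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum gap between the two empirical CDFs; the p-value uses
#' the asymptotic two-sample Kolmogorov distribution.
#'
#' @param a,b numeric samples.
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Cohen's d effect size
#'
#' `d = (mean_a - mean_b) / s_pooled` with the pooled standard deviation
#' weighted by `n - 1` per group. Reported as a magnitude by default;
#' `magnitude = FALSE` keeps the sign (antisymmetric in its arguments).
#'
#' @param a,b numeric samples.
#' @param magnitude report `|d|` (default TRUE).
#' @return effect size.
#' @export
cohens_d <- function(a, b, magnitude = TRUE) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled standard deviation; d undefined")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  if (magnitude) abs(d) else d
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the sample with replacement `n_resamples` times and returns
#' the percentile interval of the resampled means. (Unlike the null scheme
#' of [bootstrap_p()], this is an ordinary within-sample bootstrap: no group
#' structure is broken.)
#'
#' @param x numeric sample.
#' @param n_resamples bootstrap resamples.
#' @param level confidence level.
#' @param rng_seed integer seed.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrap_ci_mean <- function(x, n_resamples = 10000, level = 0.95,
                              rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  n <- length(x)
  means <- vapply(seq_len(n_resamples),
                  function(b) mean(x[sample.int(n, replace = TRUE)]),
                  numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE)
  c(lo = q[1], hi = q[2])
}
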