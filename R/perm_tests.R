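#' Welch's t statistic
#'
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/n_x + var(y)/n_y)`. When both
#' groups have zero variance the standard error is zero; the statistic is
#' then defined as 0 for equal means and signed infinity otherwise (the
#' permutation machinery treats an infinite observed statistic as maximal).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return the t statistic (unsigned degrees of freedom are not needed by
#'   the permutation tests; use [stats::t.test()] for a parametric p-value).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("design error: each group needs n >= 2")
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  diff <- mean(x) - mean(y)
  if (se2 == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / sqrt(se2)
}

#' Permutation ANOVA / t-test
#'
#' Randomizes the response over the group labels `permutations` times and
#' compares the observed statistic (one-way ANOVA F, or |Welch t| for two
#' groups) against the randomized null: `p = max(n_exceed, 1) / B`, where
#' `n_exceed` counts randomized statistics greater than or equal to the
#' observed one. The floor keeps the smallest reportable p at `1/B`
#' (1e-4 at the default 10,000 randomizations) instead of an impossible
#' zero. Permutations are sampled with replacement from the permutation
#' group (standard Monte Carlo).
#'
#' @param values numeric response.
#' @param groups group labels (factor or coercible).
#' @param statistic `"anova_F"` (any number of groups) or `"welch_t_abs"`
#'   (exactly two groups, two-sided via |t|).
#' @param permutations number of randomizations B (default 10,000).
#' @param seed optional integer seed.
#' @return object of class `perm_test`: `statistic_name`, `observed`,
#'   `permutations`, `exceed`, `p`, `seed`.
#' @export
perm_test <- function(values, groups,
                      statistic = c("anova_F", "welch_t_abs"),
                      permutations = 10000, seed = NULL) {
  statistic <- match.arg(statistic)
  groups <- as.factor(groups)
  if (length(values) != length(groups))
    stop("values and groups lengths differ")
  sizes <- table(groups)
  if (any(sizes < 2) || length(sizes) < 2)
    stop("design error: need >= 2 groups with >= 2 observations")
  if (statistic == "welch_t_abs" && length(sizes) != 2)
    stop("welch_t_abs requires exactly two groups")

  if (stats::var(values) == 0) {
    warning("constant response: statistic undefined, p = 1")
    return(structure(list(statistic_name = statistic, observed = NA_real_,
                          permutations = permutations,
                          exceed = permutations, p = 1, seed = seed),
                     class = "perm_test"))
  }

  stat_fun <- if (statistic == "anova_F") {
    function(v) anova_f(v, groups)
  } else {
    i1 <- groups == levels(groups)[1]
    function(v) abs(welch_t(v[i1], v[!i1]))
  }
  observed <- stat_fun(values)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(permutations)) {
    if (stat_fun(sample(values)) >= observed) exceed <- exceed + 1L
  }
  structure(list(statistic_name = statistic, observed = observed,
                 permutations = permutations, exceed = exceed,
                 p = max(exceed, 1) / permutations, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  lab <- if (x$statistic_name == "anova_F") "F" else "|t|"
  cat("Permutation test (", x$permutations, " randomizations)\n", sep = "")
  cat(sprintf("  observed %s = %.4f, exceedances = %d, p = %.4g\n",
              lab, x$observed, x$exceed, x$p))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Classical Tukey honest significant differences on a one-way fit: pairwise
#' mean differences tested against the studentized-range distribution with
#' the pooled within-group variance; unbalanced designs use the Tukey-Kramer
#' form (this is what [stats::TukeyHSD()] computes, used here).
#'
#' @param values numeric response.
#' @param groups group labels, >= 2 levels, no singleton groups.
#' @param conf_level confidence level for the intervals.
#' @return data.frame with columns `level_a`, `level_b`, `estimate`
#'   (difference of means, a - b), `lwr`, `upr`, `p_adjusted`, `method`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2))
    stop("design error: singleton group")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(level_a = vapply(pairs, `[`, "", 1),
             level_b = vapply(pairs, `[`, "", 2),
             estimate = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adjusted = tk[, "p adj"],
             method = "tukey",
             row.names = NULL)
}

#' Pairwise permutation t-tests with Bonferroni adjustment
#'
#' All pairwise two-sided permutation tests on |Welch t| (see [perm_test()]),
#' with Bonferroni-adjusted p-values.
#'
#' @inheritParams perm_test
#' @return data.frame with `level_a`, `level_b`, `estimate`, `p`,
#'   `p_adjusted`, `method`.
#' @export
pairwise_perm_test <- function(values, groups, permutations = 10000,
                               seed = NULL) {
  groups <- as.factor(groups)
  levs <- levels(groups)
  if (length(levs) < 2) stop("need >= 2 groups")
  if (!is.null(seed)) set.seed(seed)
  cmb <- utils::combn(levs, 2)
  res <- apply(cmb, 2, function(pr) {
    sel <- groups %in% pr
    pt <- perm_test(values[sel], droplevels(groups[sel]),
                    statistic = "welch_t_abs", permutations = permutations)
    c(estimate = mean(values[groups == pr[1]]) -
        mean(values[groups == pr[2]]), p = pt$p)
  })
  data.frame(level_a = cmb[1, ], level_b = cmb[2, ],
             estimate = res["estimate", ],
             p = res["p", ],
             p_adjusted = bonferroni(res["p", ]),
             method = "bonferroni_perm", row.names = NULL)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` over the m tests supplied.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bonferroni <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks, with average ranks for ties
#' ([stats::cor()] with `method = "spearman"`).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(x, y, method = "spearman")
}
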