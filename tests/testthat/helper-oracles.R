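# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# classical one-way ANOVA F via lm/anova
oracle_anova_f <- function(values, groups) {
  as.numeric(stats::anova(stats::lm(values ~ factor(groups)))[1, "F value"])
}

# exhaustive two-group permutation p for |t| (or any statistic), n small
oracle_exhaustive_p <- function(x, y, stat = function(a, b)
  abs(unname(stats::t.test(a, b)$statistic))) {
  v <- c(x, y)
  nx <- length(x)
  obs <- stat(x, y)
  picks <- utils::combn(length(v), nx)
  stats_all <- apply(picks, 2, function(idx) stat(v[idx], v[-idx]))
  mean(stats_all >= obs - 1e-12)
}

# Spearman rho by explicit average ranks + Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small standard curve used in qPCR tests: perfect doubling, intercept 40
doubling_curve <- function(lod_copies = 100, rrna_loci = 4L,
                           target_id = "target")
  standard_curve(target_id = target_id, slope = -1 / log10(2),
                 intercept = 40, lod_copies = lod_copies,
                 rrna_loci = rrna_loci)

# random annotated count fixture
random_counts <- function(n_taxa = 20, n_samples = 10, seed = 1,
                          lambda = 8) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  m
}
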