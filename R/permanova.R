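#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance (Anderson's one-way
#' formulation). Sums of squares are computed directly from squared
#' dissimilarities: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_groups sum_{i<j in group} d_ij^2 / n_group`, and the
#' pseudo-F is `(SS_between / (a-1)) / (SS_within / (n-a))`. On univariate
#' Euclidean distances this reduces exactly to the classical one-way ANOVA F.
#' The p-value counts the observed configuration among the permutations:
#' `p = (n_exceed + 1) / (B + 1)`, so the smallest attainable p is
#' `1 / (B + 1)`.
#'
#' @param d a `dist` or symmetric dissimilarity matrix over samples.
#' @param groups factor (or coercible) of group labels, one per sample;
#'   at least two groups with two samples each.
#' @param permutations number of random label permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return object of class `permanova`: `f` (pseudo-F), `ss` (between,
#'   within, total), `df`, `p`, `exceed`, `permutations`, `groups`.
#' @export
permanova <- function(d, groups, permutations = 999, seed = NULL) {
  d2 <- as.matrix(d)^2
  groups <- as.factor(groups)
  n <- nrow(d2)
  if (length(groups) != n)
    stop("groups length does not match the dissimilarity matrix")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("design error: need >= 2 groups with >= 2 samples each")
  a <- length(sizes)
  ss_total <- sum(d2) / (2 * n)
  pseudo_f <- function(g) {
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- pseudo_f(groups)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(permutations)) {
    if (pseudo_f(sample(groups)) >= f_obs) exceed <- exceed + 1L
  }
  ss_w <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  structure(list(f = f_obs,
                 ss = c(between = ss_total - ss_w, within = ss_w,
                        total = ss_total),
                 df = c(between = a - 1L, within = n - a),
                 exceed = exceed,
                 permutations = permutations,
                 p = (exceed + 1) / (permutations + 1),
                 groups = groups),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (one-way), ", x$permutations, " permutations\n", sep = "")
  cat(sprintf("  pseudo-F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  invisible(x)
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the dissimilarity matrix by principal coordinates analysis,
#' handling negative eigenvalues by the real/imaginary split (squared
#' distances in the imaginary axes are subtracted), and measures each
#' sample's distance to its group centroid in that space. Equality of group
#' dispersions is tested with the classical one-way F on these distances,
#' with a permutation p-value (distances permuted across samples, observed
#' configuration counted, as in [permanova()]).
#'
#' @inheritParams permanova
#' @return object of class `dispersion_test`: `distances` (per sample),
#'   `groups`, `f`, `df`, `p`, `exceed`, `permutations`.
#' @export
dispersion <- function(d, groups, permutations = 999, seed = NULL) {
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(dm)
  if (length(groups) != n)
    stop("groups length does not match the dissimilarity matrix")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("design error: need >= 2 groups with >= 2 samples each")

  # principal coordinates: double-centred -d^2/2, eigendecomposition
  A <- -0.5 * dm^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > tol
  neg <- e$values < -tol
  U <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  V <- if (any(neg)) e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg)) else
      matrix(0, n, 0)

  dist_to_centroid <- numeric(n)
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    cu <- colMeans(U[idx, , drop = FALSE])
    cv <- if (ncol(V)) colMeans(V[idx, , drop = FALSE]) else numeric(0)
    for (i in idx) {
      z2 <- sum((U[i, ] - cu)^2) -
        if (ncol(V)) sum((V[i, ] - cv)^2) else 0
      dist_to_centroid[i] <- sqrt(max(z2, 0))
    }
  }

  f_obs <- anova_f(dist_to_centroid, groups)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(permutations)) {
    if (anova_f(sample(dist_to_centroid), groups) >= f_obs)
      exceed <- exceed + 1L
  }
  structure(list(distances = stats::setNames(dist_to_centroid,
                                             rownames(dm)),
                 groups = groups,
                 f = f_obs,
                 df = c(between = nlevels(groups) - 1L,
                        within = n - nlevels(groups)),
                 exceed = exceed,
                 permutations = permutations,
                 p = (exceed + 1) / (permutations + 1)),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Multivariate dispersion test, ", x$permutations,
      " permutations\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  m <- tapply(x$distances, x$groups, mean)
  cat("  mean distance to centroid:\n")
  for (lev in names(m)) cat(sprintf("    %s: %.4f\n", lev, m[lev]))
  invisible(x)
}

# classical one-way ANOVA F, shared by the permutation engines
anova_f <- function(values, groups) {
  n <- length(values)
  a <- nlevels(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  sizes <- tabulate(groups)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  (ssb / (a - 1)) / (ssw / (n - a))
}
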