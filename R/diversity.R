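#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * ln p_i)` with zero entries contributing zero. Abundance
#' vectors are normalized internally, so the index is invariant to rescaling
#' by a positive constant. Natural log is used throughout so that
#' `exp(H)` is the effective number of species.
#'
#' @param x nonnegative abundance or proportion vector, or a taxa x samples
#'   matrix (one index per column).
#' @return Shannon index in nats (vector input) or a named vector of indices
#'   (matrix input).
#' @export
shannon_index <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, shannon_index))
  if (any(x < 0)) stop("input error: negative abundances")
  tot <- sum(x)
  if (tot <= 0) stop("input error: all-zero abundance vector")
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Effective number of species
#'
#' The exponent of the Shannon index: the number of equally abundant taxa
#' giving the same diversity. Bounded by 1 and the observed richness.
#'
#' @param H Shannon index (nats), as returned by [shannon_index()].
#' @return effective number of species, `exp(H)`.
#' @export
effective_species <- function(H) {
  if (any(H < 0)) stop("Shannon index must be nonnegative")
  exp(H)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`, bounded in [0, 1]. Computed
#' with [vegan::vegdist()].
#'
#' @param abund abundance matrix; by default taxa in rows and samples in
#'   columns (the package's count-matrix orientation).
#' @param samples_in `"columns"` (default) or `"rows"`.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(abund, samples_in = c("columns", "rows")) {
  samples_in <- match.arg(samples_in)
  m <- if (samples_in == "columns") t(abund) else as.matrix(abund)
  if (any(m < 0)) stop("input error: negative abundances")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("input error: all-zero sample(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Log10 transform with the zero-to-one rule
#'
#' Below-LOD abundances are carried as exact zeros; for log display and
#' log-scale statistics they are replaced by 1 before taking log10, so a
#' non-detection maps to 0 on the log scale. Idempotent on the zero set.
#'
#' @param x nonnegative numeric vector or matrix.
#' @return log10 of `x` with zeros mapped to 0.
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stop("input error: negative abundances")
  x[x == 0] <- 1
  log10(x)
}

#' Principal component analysis of (log) abundances
#'
#' Centered, by default unscaled PCA via the singular value decomposition.
#' Constant columns are dropped with a warning. Signs are fixed so that the
#' largest-magnitude entry of each loading vector is positive, making results
#' deterministic across platforms.
#'
#' @param x samples x variables numeric matrix (typically
#'   `t(log_transform(abund))`).
#' @param scale. scale variables to unit variance? Default `FALSE`.
#' @return object of class `qmp_pca`: `scores` (samples x PCs), `loadings`
#'   (variables x PCs), `sdev`, `explained` (fraction of variance per PC).
#' @export
pca_ordination <- function(x, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs at least 2 samples and 2 variables")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 non-constant variables")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  flip <- apply(fit$rotation, 2, function(l) l[which.max(abs(l))] < 0)
  fit$rotation[, flip] <- -fit$rotation[, flip]
  fit$x[, flip] <- -fit$x[, flip]
  structure(list(scores = fit$x,
                 loadings = fit$rotation,
                 sdev = fit$sdev,
                 explained = fit$sdev^2 / sum(fit$sdev^2)),
            class = "qmp_pca")
}

#' @export
print.qmp_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$loadings), "variables\n")
  ev <- round(100 * x$explained[seq_len(min(4, length(x$explained)))], 1)
  cat("  explained variance (%):", paste(ev, collapse = ", "), "...\n")
  invisible(x)
}
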