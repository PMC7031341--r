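#' Remove off-target reads from a count matrix
#'
#' Drops taxa annotated as excluded (mitochondria, chloroplast, eukaryotes)
#' before any abundance filtering. Counts of the remaining taxa are untouched.
#'
#' @param counts integer matrix, taxa in rows (rownames = taxon ids), samples
#'   in columns.
#' @param annotations data.frame with columns `taxon_id`, `category`
#'   (`core`/`noncore`/`minor`/`excluded`) and, for excluded taxa,
#'   `excluded_reason`.
#' @return the count matrix without excluded taxa.
#' @export
exclude_off_target <- function(counts, annotations) {
  counts <- validate_counts(counts)
  missing <- setdiff(rownames(counts), annotations$taxon_id)
  if (length(missing))
    stop("annotation error: unannotated taxa: ",
         paste(missing, collapse = ", "))
  cat_of <- annotations$category[match(rownames(counts),
                                       annotations$taxon_id)]
  out <- counts[cat_of != "excluded", , drop = FALSE]
  if (nrow(out) == 0L)
    warning("all taxa excluded as off-target; empty count matrix")
  out
}

#' Prevalence/abundance filter for amplicon taxa
#'
#' Retains taxa present (count > 0) in at least `min_samples` samples AND with
#' at least `min_total` reads summed over all samples. The defaults are the
#' usual two-samples/ten-reads rule for low-complexity gut communities.
#'
#' @param counts taxa x samples integer matrix.
#' @param min_samples minimum number of samples with a nonzero count.
#' @param min_total minimum row total.
#' @return the filtered count matrix.
#' @export
abundance_filter <- function(counts, min_samples = 2, min_total = 10) {
  counts <- validate_counts(counts)
  keep <- rowSums(counts > 0) >= min_samples & rowSums(counts) >= min_total
  counts[keep, , drop = FALSE]
}

#' Collapse sequence variants into phylotypes
#'
#' Sums counts of sequence variants assigned to the same phylotype, per
#' sample. Column (sample) totals are conserved.
#'
#' @inheritParams exclude_off_target
#' @param annotations data.frame with `taxon_id` and `phylotype` columns.
#' @return phylotype x samples count matrix.
#' @export
collapse_phylotypes <- function(counts, annotations) {
  counts <- validate_counts(counts)
  phylo <- annotations$phylotype[match(rownames(counts),
                                       annotations$taxon_id)]
  if (any(is.na(phylo) | phylo == ""))
    stop("annotation error: missing phylotype label for: ",
         paste(rownames(counts)[is.na(phylo) | phylo == ""], collapse = ", "))
  rowsum(counts, group = phylo)
}

#' Per-sample taxon proportions
#'
#' @param counts taxa x samples matrix (nonnegative).
#' @return matrix of the same shape whose columns each sum to 1.
#' @export
taxon_proportions <- function(counts) {
  depth <- colSums(counts)
  if (any(depth <= 0))
    stop("depth error: zero-depth sample(s): ",
         paste(colnames(counts)[depth <= 0], collapse = ", "))
  sweep(counts, 2, depth, "/")
}

#' Scale proportions to absolute genome equivalents (QMP)
#'
#' Quantitative microbiome profiling: each taxon's proportion is multiplied
#' by the sample's total 16S rRNA gene copy number (from the universal qPCR
#' assay) and divided by the taxon's 16S operon number, yielding absolute
#' genome equivalents per gut. A taxon with zero reads in a sample therefore
#' has zero genome equivalents there (below the detection limit of the
#' amplicon assay).
#'
#' @param props taxa x samples proportion matrix (columns sum to 1).
#' @param total_16s named vector of universal-assay normalized 16S copies per
#'   gut, one per sample.
#' @param rrna_loci named vector of 16S operons per genome, one per taxon.
#' @return object of class `qmp`: list with `abs_ge` (taxa x samples),
#'   `total_16s`, `rrna_loci`, `props`.
#' @export
to_absolute <- function(props, total_16s, rrna_loci) {
  stopifnot(is.matrix(props))
  missing <- setdiff(colnames(props), names(total_16s))
  if (length(missing))
    stop("missing total 16S load for sample(s): ",
         paste(missing, collapse = ", "))
  missing <- setdiff(rownames(props), names(rrna_loci))
  if (length(missing))
    stop("annotation error: missing rrna_loci for: ",
         paste(missing, collapse = ", "))
  tot <- total_16s[colnames(props)]
  if (any(tot <= 0)) stop("total_16s must be positive")
  loci <- rrna_loci[rownames(props)]
  if (any(loci < 1)) stop("rrna_loci must be >= 1")
  abs_ge <- sweep(sweep(props, 2, tot, "*"), 1, loci, "/")
  structure(list(abs_ge = abs_ge, total_16s = tot,
                 rrna_loci = loci, props = props),
            class = "qmp")
}

#' @export
print.qmp <- function(x, ...) {
  cat("QMP matrix:", nrow(x$abs_ge), "taxa x", ncol(x$abs_ge), "samples\n")
  cat("total 16S copies/gut, range:",
      format(range(x$total_16s), digits = 3), "\n")
  invisible(x)
}

#' Full amplicon-to-QMP chain
#'
#' Applies, in order: off-target exclusion, the prevalence/abundance filter,
#' phylotype collapsing, per-sample proportions (renormalized over retained
#' taxa), and scaling to absolute genome equivalents. The order is part of
#' the method: sequence variants are filtered before collapsing, and
#' proportions are computed over the retained community.
#'
#' @inheritParams exclude_off_target
#' @param total_16s named per-sample universal 16S load.
#' @param phylotype_loci named vector of 16S operon numbers at the phylotype
#'   level; default: mean of the member taxa's `rrna_loci` annotations,
#'   rounded to the annotation values when uniform.
#' @param min_samples,min_total filter thresholds.
#' @return a `qmp` object (see [to_absolute()]).
#' @export
qmp_pipeline <- function(counts, annotations, total_16s,
                         phylotype_loci = NULL,
                         min_samples = 2, min_total = 10) {
  x <- exclude_off_target(counts, annotations)
  x <- abundance_filter(x, min_samples, min_total)
  x <- collapse_phylotypes(x, annotations)
  props <- taxon_proportions(x)
  if (is.null(phylotype_loci)) {
    loci <- tapply(annotations$rrna_loci, annotations$phylotype,
                   function(z) mean(z))
    phylotype_loci <- stats::setNames(as.numeric(loci), names(loci))
  }
  to_absolute(props, total_16s, phylotype_loci)
}

# shared validation for count matrices
validate_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("count matrix needs unique taxon rownames")
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at taxon '", rownames(counts)[bad[1]],
         "', sample '", colnames(counts)[bad[2]], "'")
  }
  counts
}
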