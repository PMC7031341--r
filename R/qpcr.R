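#' Raw template copies from a Cq value
#'
#' Inverts the standard curve: `n_raw = E^(intercept - Cq)` copies per
#' microlitre of template. Cq values beyond the assay's LOD Cq, and undetected
#' reactions (`NA`), are unquantifiable and reported as zero with
#' `below_lod = TRUE`. Technical replicates should be averaged on the Cq scale
#' before calling (see [quantify_samples()]).
#'
#' @param curve a [standard_curve()].
#' @param cq numeric vector of quantification cycles; `NA` = undetected.
#' @param target_id optional target id of the measurements; must match the
#'   curve's if given.
#' @return data.frame with columns `n_raw` and `below_lod`.
#' @export
raw_copies <- function(curve, cq, target_id = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.null(target_id) && !all(target_id == curve$target_id))
    stop("input error: measurements for '", unique(target_id),
         "' passed to the '", curve$target_id, "' curve")
  if (any(cq <= 0, na.rm = TRUE))
    stop("input error: detected Cq values must be positive")
  below <- is.na(cq) | cq > curve$lod_cq
  n_raw <- ifelse(below, 0, curve$efficiency^(curve$intercept - cq))
  data.frame(n_raw = n_raw, below_lod = below)
}

#' Actin-normalized copies per gut
#'
#' Scales the raw per-microlitre copy number by the sample's host actin signal
#' to correct for gut-size and extraction-efficiency variation:
#' `n_abs = (n_raw / n_actin) * median_actin * extract_volume_ul`.
#'
#' @param n_raw raw target copies per ul.
#' @param n_actin actin copies per ul in the same sample (must be > 0; a
#'   sample with failed actin amplification cannot be normalized).
#' @param median_actin median actin copies over the batch of samples processed
#'   together.
#' @param extract_volume_ul total DNA extract volume (default 200 ul).
#' @return normalized copies per gut.
#' @export
normalize_per_gut <- function(n_raw, n_actin, median_actin,
                              extract_volume_ul = 200) {
  if (any(!is.finite(n_actin)) || any(n_actin <= 0))
    stop("sample failure: nonpositive actin copy number; ",
         "sample cannot be normalized")
  if (!is.finite(median_actin) || median_actin <= 0)
    stop("median_actin must be positive")
  (n_raw / n_actin) * median_actin * extract_volume_ul
}

#' Genome equivalents from normalized 16S copies
#'
#' Divides normalized 16S rRNA gene copies per gut by the number of 16S
#' operons per genome of the target, giving a proxy for cell number. For a
#' universal (all-bacteria) assay no single operon number applies, so the
#' pipeline reports `n_abs` rather than genome equivalents for that target.
#'
#' @param n_abs normalized copies per gut.
#' @param rrna_loci 16S operons per genome (>= 1).
#' @return genome equivalents per gut.
#' @export
genome_equivalents <- function(n_abs, rrna_loci) {
  if (any(rrna_loci < 1)) stop("rrna_loci must be >= 1")
  n_abs / rrna_loci
}

#' Total bacterial load as the summed phylotype abundances
#'
#' Sums genome equivalents over a configured phylotype set per sample.
#' Below-LOD targets carry zero and therefore contribute nothing; phylotypes
#' absent from the table count as zero.
#'
#' @param abundances data.frame as returned by [quantify_samples()] (columns
#'   `sample_id`, `target_id`, `n_ge`).
#' @param phylotypes character vector of target ids to sum (default: the
#'   seven monitored phylotypes, [phylotypes()]).
#' @return named numeric vector of total genome equivalents per sample.
#' @export
summed_load <- function(abundances, phylotypes = beeQMP::phylotypes()) {
  keep <- abundances$target_id %in% phylotypes
  sub <- abundances[keep, , drop = FALSE]
  samples <- unique(abundances$sample_id)
  out <- stats::setNames(numeric(length(samples)), samples)
  if (nrow(sub)) {
    s <- tapply(sub$n_ge, sub$sample_id, sum)
    out[names(s)] <- s
  }
  out
}

#' Run the full qPCR quantification chain on a Cq table
#'
#' For each sample x target: average technical replicates on the Cq scale
#' (undetected replicates are dropped; all-undetected means undetected),
#' invert the standard curve (`n_raw = E^(intercept - Cq)`), apply the LOD
#' rule, normalize by the sample's actin signal and the batch median actin,
#' and convert to genome equivalents using the target's 16S operon number.
#' For the universal assay (`universal_target`) `n_ge` is reported as `NA`
#' and `n_abs` is the quantity of record.
#'
#' @param cq_table data.frame with columns `sample_id`, `target_id`,
#'   `replicate`, `cq` (`NA` = undetected).
#' @param curves named list of [standard_curve()] objects covering every
#'   target in the table.
#' @param actin_target name of the host normalization assay (default
#'   `"actin"`). Samples whose actin signal is undetected or below the actin
#'   LOD are dropped with a warning (they cannot be normalized).
#' @param universal_target name of the universal all-bacteria 16S assay,
#'   if present.
#' @param median_actin override for the batch median actin copies/ul;
#'   default: median over the samples in `cq_table`.
#' @param extract_volume_ul DNA extract volume (default 200).
#' @return data.frame with one row per sample x bacterial target:
#'   `sample_id`, `target_id`, `n_raw`, `n_actin`, `n_abs`, `n_ge`,
#'   `below_lod`.
#' @export
quantify_samples <- function(cq_table, curves,
                             actin_target = "actin",
                             universal_target = "universal",
                             median_actin = NULL,
                             extract_volume_ul = 200) {
  stopifnot(is.data.frame(cq_table),
            all(c("sample_id", "target_id", "cq") %in% names(cq_table)))
  targets <- unique(cq_table$target_id)
  missing <- setdiff(targets, names(curves))
  if (length(missing))
    stop("no standard curve for target(s): ", paste(missing, collapse = ", "))
  if (!actin_target %in% targets)
    stop("quantify stage requires the '", actin_target, "' assay")

  # replicate-averaged Cq per sample x target (Cq scale; all-NA stays NA)
  mean_cq <- stats::aggregate(
    cq ~ sample_id + target_id, data = cq_table,
    FUN = function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE),
    na.action = stats::na.pass)

  actin <- mean_cq[mean_cq$target_id == actin_target, , drop = FALSE]
  actin_raw <- raw_copies(curves[[actin_target]], actin$cq)
  n_actin <- stats::setNames(actin_raw$n_raw, actin$sample_id)
  failed <- names(n_actin)[actin_raw$below_lod]
  if (length(failed)) {
    warning("sample failure: no usable actin amplification for ",
            paste(failed, collapse = ", "), "; sample(s) excluded")
    n_actin <- n_actin[!names(n_actin) %in% failed]
  }
  if (!length(n_actin)) stop("no sample with usable actin amplification")
  if (is.null(median_actin)) median_actin <- stats::median(n_actin)

  bact <- mean_cq[mean_cq$target_id != actin_target, , drop = FALSE]
  bact <- bact[bact$sample_id %in% names(n_actin), , drop = FALSE]
  out <- do.call(rbind, lapply(split(bact, bact$target_id), function(d) {
    curve <- curves[[d$target_id[1]]]
    rc <- raw_copies(curve, d$cq)
    na <- unname(n_actin[d$sample_id])
    n_abs <- normalize_per_gut(rc$n_raw, na, median_actin, extract_volume_ul)
    n_ge <- if (identical(d$target_id[1], universal_target)) NA_real_ else
      genome_equivalents(n_abs, curve$rrna_loci)
    data.frame(sample_id = d$sample_id, target_id = d$target_id,
               n_raw = rc$n_raw, n_actin = na, n_abs = n_abs, n_ge = n_ge,
               below_lod = rc$below_lod)
  }))
  rownames(out) <- NULL
  out[order(out$sample_id, out$target_id), , drop = FALSE]
}
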