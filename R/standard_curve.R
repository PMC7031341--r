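#' qPCR standard curves
#'
#' A standard curve relates the quantification cycle (Cq) to the log10
#' template copy number per microlitre: `cq = intercept + slope * log10(copies)`.
#' The amplification efficiency is `E = 10^(-1/slope)` (E = 2 for perfect
#' doubling), and the Cq corresponding to `lod_copies` is the assay's limit
#' of detection (LOD): samples with a Cq beyond it are treated as
#' unquantifiable and set to zero downstream.
#'
#' @param dilutions data.frame with columns `copies_per_ul` and `cq`, one row
#'   per dilution level x technical replicate.
#' @param lod_copies copies/ul at the limit of detection (typically 10 or 100).
#' @param included_range length-2 numeric `(min_copies, max_copies)`; only
#'   dilution points inside this (closed) range enter the fit. Default: all.
#' @param rrna_loci 16S rRNA operons per genome of the target (1 for non-16S
#'   targets such as the host actin gene).
#' @param target_id name of the assay target.
#' @return An object of class `standard_curve` with elements `target_id`,
#'   `slope`, `intercept`, `efficiency`, `lod_copies`, `lod_cq`, `rrna_loci`,
#'   `n_points`, `sigma` (residual sd of the fit).
#' @examples
#' dil <- data.frame(copies_per_ul = 10^(2:7),
#'                   cq = 40 - 10/3 * (2:7))
#' fit_standard_curve(dil, lod_copies = 100)
#' @export
fit_standard_curve <- function(dilutions, lod_copies,
                               included_range = NULL,
                               rrna_loci = 1L,
                               target_id = "target") {
  stopifnot(is.data.frame(dilutions),
            all(c("copies_per_ul", "cq") %in% names(dilutions)))
  copies <- dilutions$copies_per_ul
  cq <- dilutions$cq
  if (any(!is.finite(copies)) || any(copies <= 0))
    stop("dilution copy numbers must be positive and finite")
  if (!is.null(included_range)) {
    keep <- copies >= included_range[1] & copies <= included_range[2]
    copies <- copies[keep]
    cq <- cq[keep]
  }
  keep <- is.finite(cq)
  copies <- copies[keep]
  cq <- cq[keep]
  if (length(unique(copies)) < 3L)
    stop("degenerate standard curve for '", target_id,
         "': fewer than 3 distinct dilution levels in the included range")
  fit <- stats::lm(cq ~ log10(copies))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0)
    stop("calibration error for '", target_id,
         "': nonnegative slope (", format(slope), ")")
  standard_curve(target_id = target_id, slope = slope, intercept = intercept,
                 lod_copies = lod_copies, rrna_loci = rrna_loci,
                 n_points = length(cq),
                 sigma = sqrt(sum(stats::residuals(fit)^2) /
                                stats::df.residual(fit)))
}

#' Construct a standard curve from known parameters
#'
#' Builds a `standard_curve` directly from a slope and intercept (e.g. taken
#' from an assay sheet) instead of refitting a dilution series. Efficiency and
#' the LOD Cq are derived from the parameters.
#'
#' @inheritParams fit_standard_curve
#' @param slope Cq change per log10 copies (must be negative).
#' @param intercept Cq at 1 copy/ul.
#' @param n_points,sigma optional fit metadata.
#' @return object of class `standard_curve`.
#' @export
standard_curve <- function(target_id, slope, intercept, lod_copies,
                           rrna_loci = 1L, n_points = NA_integer_,
                           sigma = NA_real_) {
  if (!is.numeric(slope) || slope >= 0)
    stop("calibration error: slope must be negative")
  if (!is.numeric(lod_copies) || lod_copies <= 0)
    stop("lod_copies must be positive")
  rrna_loci <- as.integer(rrna_loci)
  if (is.na(rrna_loci) || rrna_loci < 1L)
    stop("rrna_loci must be a positive integer")
  eff <- efficiency_from_slope(slope)
  if (eff <= 1 || eff > 2.5)
    stop("calibration error for '", target_id, "': efficiency ",
         format(eff), " outside (1, 2.5]")
  structure(list(target_id = target_id,
                 slope = slope,
                 intercept = intercept,
                 efficiency = eff,
                 lod_copies = lod_copies,
                 lod_cq = intercept + slope * log10(lod_copies),
                 rrna_loci = rrna_loci,
                 n_points = n_points,
                 sigma = sigma),
            class = "standard_curve")
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope)`; a slope of -3.32 corresponds to perfect doubling
#' (E = 2).
#'
#' @param slope negative slope of Cq on log10 copies.
#' @return per-cycle amplification factor.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || any(!is.finite(slope)) || any(slope >= 0))
    stop("calibration error: slope must be negative")
  10^(-1 / slope)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve:", x$target_id, "\n")
  cat(sprintf("  Cq = %.4f %+.4f * log10(copies/ul)\n", x$intercept, x$slope))
  cat(sprintf("  efficiency E = %.4f\n", x$efficiency))
  cat(sprintf("  LOD: %g copies/ul (Cq %.3f)\n", x$lod_copies, x$lod_cq))
  cat(sprintf("  16S loci per genome: %d\n", x$rrna_loci))
  if (!is.na(x$n_points))
    cat(sprintf("  fit on %d points, residual sd %.3f Cq\n",
                x$n_points, x$sigma))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted Cq for given template copy numbers
#'
#' @param object a `standard_curve`.
#' @param copies_per_ul template copies per microlitre (positive).
#' @param ... unused.
#' @return expected Cq values.
#' @export
predict.standard_curve <- function(object, copies_per_ul, ...) {
  stopifnot(all(copies_per_ul > 0))
  object$intercept + object$slope * log10(copies_per_ul)
}
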