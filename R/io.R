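#' Read a Cq table
#'
#' TSV with columns `sample_id`, `target_id`, `replicate`, `cq`. Undetected
#' reactions may be an empty field or the literal token `NA`; both map to
#' below-LOD downstream.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_cq_table <- function(path) {
  d <- read_tsv_checked(path, c("sample_id", "target_id", "replicate",
                                "cq"))
  d$cq <- suppressWarnings(as.numeric(ifelse(d$cq == "", NA, d$cq)))
  bad <- which(!is.na(d$cq) & d$cq <= 0)
  if (length(bad))
    stop("load error in ", path, ": nonpositive Cq at line(s) ",
         paste(bad + 1L, collapse = ", "))
  d
}

#' Read a standard-curve dilution table
#'
#' TSV with columns `target_id`, `copies_per_ul`, `cq` (one row per
#' dilution x replicate).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_standards <- function(path) {
  d <- read_tsv_checked(path, c("target_id", "copies_per_ul", "cq"))
  d$copies_per_ul <- as.numeric(d$copies_per_ul)
  d$cq <- as.numeric(d$cq)
  bad <- which(is.na(d$copies_per_ul) | d$copies_per_ul <= 0)
  if (length(bad))
    stop("load error in ", path, ": invalid copies_per_ul at line(s) ",
         paste(bad + 1L, collapse = ", "))
  d
}

#' Read a taxa x samples count matrix
#'
#' TSV whose first column is `taxon_id` and remaining columns are samples
#' (integer cells).
#'
#' @param path file path.
#' @return integer matrix with taxon rownames.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(d)[1] != "taxon_id")
    stop("load error in ", path, ": first column must be 'taxon_id'")
  if (anyDuplicated(d$taxon_id))
    stop("load error in ", path, ": duplicated taxon_id '",
         d$taxon_id[duplicated(d$taxon_id)][1], "'")
  samples <- names(d)[-1]
  if (anyDuplicated(samples))
    stop("load error in ", path, ": duplicated sample id '",
         samples[duplicated(samples)][1], "'")
  m <- as.matrix(d[, -1, drop = FALSE])
  colnames(m) <- samples
  rownames(m) <- d$taxon_id
  if (any(is.na(m)))
    stop("load error in ", path, ": NA count")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("load error in ", path, ": negative count at taxon '",
         rownames(m)[bad[1]], "', sample '", colnames(m)[bad[2]], "'")
  }
  storage.mode(m) <- "integer"
  m
}

#' Read a taxon annotation table
#'
#' TSV with columns `taxon_id`, `phylotype`, `category`, `excluded_reason`,
#' `rrna_loci`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_taxonomy <- function(path) {
  d <- read_tsv_checked(path, c("taxon_id", "phylotype", "category",
                                "excluded_reason", "rrna_loci"))
  if (anyDuplicated(d$taxon_id))
    stop("load error in ", path, ": duplicated taxon_id '",
         d$taxon_id[duplicated(d$taxon_id)][1], "'")
  d$excluded_reason[is.na(d$excluded_reason)] <- ""
  mismatch <- (d$category == "excluded") != (d$excluded_reason != "")
  if (any(mismatch))
    stop("load error in ", path,
         ": category 'excluded' must pair with an excluded_reason (taxa: ",
         paste(d$taxon_id[mismatch], collapse = ", "), ")")
  d$rrna_loci <- as.integer(d$rrna_loci)
  d
}

#' Read sample metadata
#'
#' TSV with at least `sample_id`; typical columns are `bee_type`, `hive`,
#' `month`, `gut_weight_mg`, `treatment`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d))
    stop("load error in ", path, ": missing sample_id column")
  if (anyDuplicated(d$sample_id))
    stop("load error in ", path, ": duplicated sample_id '",
         d$sample_id[duplicated(d$sample_id)][1], "'")
  d
}

# shared column-checked TSV reader
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("load error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  d
}

#' Write a data.frame as TSV at full double precision
#'
#' Numeric columns are written with 17 significant digits so that a write
#' followed by a read round-trips every value exactly.
#'
#' @param d data.frame.
#' @param path output path.
#' @export
write_tsv_precise <- function(d, path) {
  for (j in seq_along(d))
    if (is.double(d[[j]]))
      d[[j]] <- ifelse(is.na(d[[j]]), NA, sprintf("%.17g", d[[j]]))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Write a count matrix as TSV
#'
#' @param counts taxa x samples matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(taxon_id = rownames(counts), counts,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the published analysis order on a set of input tables: fit
#' standard curves from the dilution series, quantify the Cq table into
#' genome equivalents, convert amplicon counts to absolute abundances with
#' the universal 16S load (QMP), compute per-sample diversity, and run the
#' group statistics (permutation ANOVA on total load, PERMANOVA and
#' dispersion on Bray-Curtis dissimilarities of the QMP matrix). Writes all
#' result tables plus a JSON run manifest (config echo, seed, package
#' version, input checksums) so any output can be regenerated from manifest
#' plus inputs.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   `standards`, `cq_table`, `counts` (optional), `taxonomy` (optional),
#'   `metadata` paths; `out` output directory; `curve_config` optional
#'   per-target list with `lod_copies`, `included_range`, `rrna_loci`;
#'   `group_var` metadata column for the statistics (default `bee_type`);
#'   `permutations` (default 999 multivariate / 10000 univariate as a
#'   length-1 or -2 vector); `seed` (required).
#' @return invisibly, a list with `curves`, `abundances`, `qmp`,
#'   `diversity`, `stats` and the manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: seed must be set")
  seed <- as.integer(config$seed)
  group_var <- config$group_var %||% "bee_type"
  perms <- config$permutations %||% c(999, 10000)
  if (length(perms) == 1) perms <- rep(perms, 2)
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- unlist(config[c("standards", "cq_table", "counts", "taxonomy",
                            "metadata")])
  curves <- stage("curves", {
    std <- read_standards(config$standards)
    cfg <- config$curve_config %||% default_curve_config()
    lapply(split(std, std$target_id), function(d) {
      tg <- d$target_id[1]
      cc <- cfg[[tg]]
      if (is.null(cc))
        stop("no curve configuration for target '", tg, "'")
      fit_standard_curve(d, lod_copies = cc$lod_copies,
                         included_range = cc$included_range,
                         rrna_loci = cc$rrna_loci, target_id = tg)
    })
  })
  abund <- stage("quantify", {
    cq <- read_cq_table(config$cq_table)
    quantify_samples(cq, curves)
  })
  meta <- stage("metadata", read_metadata(config$metadata))

  qmp <- NULL
  if (!is.null(config$counts)) {
    qmp <- stage("qmp", {
      counts <- read_counts(config$counts)
      tax <- read_taxonomy(config$taxonomy)
      uni <- abund[abund$target_id == "universal", , drop = FALSE]
      total <- stats::setNames(uni$n_abs, uni$sample_id)
      total <- total[names(total) %in% colnames(counts)]
      qmp_pipeline(counts[, names(total), drop = FALSE], tax, total)
    })
  }

  diversity <- stage("diversity", {
    load <- summed_load(abund)
    ge_mat <- stats::xtabs(n_ge ~ target_id + sample_id,
                           data = abund[abund$target_id %in% phylotypes(), ])
    H <- shannon_index(as.matrix(ge_mat)[, colSums(ge_mat) > 0,
                                         drop = FALSE])
    data.frame(sample_id = names(H), shannon = unname(H),
               effective_species = unname(effective_species(H)),
               total_load = unname(load[names(H)]))
  })

  stat_res <- stage("stats", {
    set.seed(seed)
    div <- diversity[match(meta$sample_id, diversity$sample_id), ]
    keep <- !is.na(div$total_load) & !is.na(meta[[group_var]])
    groups <- meta[[group_var]][keep]
    res <- list(load_test = perm_test(log_transform(div$total_load[keep]),
                                      groups, "anova_F",
                                      permutations = perms[2]))
    if (!is.null(qmp)) {
      qsamp <- colnames(qmp$abs_ge)
      qgroups <- meta[[group_var]][match(qsamp, meta$sample_id)]
      keepq <- !is.na(qgroups)
      d <- bray_curtis(qmp$abs_ge[, keepq, drop = FALSE])
      res$permanova <- permanova(d, qgroups[keepq],
                                 permutations = perms[1])
      res$dispersion <- dispersion(d, qgroups[keepq],
                                   permutations = perms[1])
    }
    res
  })

  # outputs + manifest
  write_tsv_precise(abund, file.path(out_dir, "abundances.tsv"))
  write_tsv_precise(diversity, file.path(out_dir, "diversity.tsv"))
  if (!is.null(qmp)) {
    long <- data.frame(
      sample_id = rep(colnames(qmp$abs_ge), each = nrow(qmp$abs_ge)),
      phylotype = rep(rownames(qmp$abs_ge), ncol(qmp$abs_ge)),
      proportion = as.vector(qmp$props),
      abs_ge = as.vector(qmp$abs_ge),
      total_16s = rep(unname(qmp$total_16s), each = nrow(qmp$abs_ge)))
    write_tsv_precise(long, file.path(out_dir, "qmp.tsv"))
  }
  stats_df <- data.frame(
    test = "perm_anova_total_load", grouping = group_var,
    statistic = "anova_F", observed = stat_res$load_test$observed,
    B = stat_res$load_test$permutations, p = stat_res$load_test$p,
    seed = seed)
  if (!is.null(stat_res$permanova))
    stats_df <- rbind(stats_df, data.frame(
      test = c("permanova_bray", "dispersion_bray"), grouping = group_var,
      statistic = c("pseudo_F", "anova_F"),
      observed = c(stat_res$permanova$f, stat_res$dispersion$f),
      B = perms[1],
      p = c(stat_res$permanova$p, stat_res$dispersion$p), seed = seed))
  write_tsv_precise(stats_df, file.path(out_dir, "stats.tsv"))

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("beeQMP")),
                   input_md5 = as.list(tools::md5sum(inputs)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(curves = curves, abundances = abund, qmp = qmp,
                 diversity = diversity, stats = stat_res,
                 manifest = manifest_path))
}

#' Default per-target curve configuration
#'
#' LOD, included dilution range and operon number per assay, mirroring the
#' shipped [default_curves()]: 100 copies/ul LOD with a 1e2-1e7 fitted range
#' for Frischella, Snodgrassella, Bartonella, Firm-4 and Firm-5; 10
#' copies/ul with the full 1e1-1e7 range for Gilliamella, Bifidobacterium,
#' actin and the universal assay.
#'
#' @return named list of per-target lists.
#' @export
default_curve_config <- function() {
  curves <- default_curves()
  lapply(curves, function(crv) list(
    lod_copies = crv$lod_copies,
    included_range = if (crv$lod_copies >= 100) c(1e2, 1e7) else c(1e1, 1e7),
    rrna_loci = crv$rrna_loci))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
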