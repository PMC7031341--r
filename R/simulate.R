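#' The seven monitored phylotypes
#'
#' Target ids of the seven gut phylotypes followed by the phylotype-specific
#' qPCR assays: *Gilliamella*, *Snodgrassella*, *Bifidobacterium*,
#' *Lactobacillus* Firm-4, *Lactobacillus* Firm-5, *Frischella* and
#' *Bartonella*.
#'
#' @return character vector of length 7.
#' @export
phylotypes <- function() {
  c("gilliamella", "snodgrassella", "bifidobacterium",
    "firm4", "firm5", "frischella", "bartonella")
}

#' Default per-bee-type community profiles
#'
#' Lognormal load profiles for foragers, nurses and winter bees. Each taxon
#' has, per bee type, a detectability (probability that a bee is colonized
#' above the LOD), and a log10 mean and sd of genome equivalents per gut
#' when colonized. The defaults encode the field anchors this generator is
#' built around: Firm-4 detectable in 98.4% of bees, Bartonella and
#' Frischella below the detection limit in 5.3% and 26.9% of bees, a
#' winter:forager expected total-load ratio of 10, a characteristic winter
#' shift toward high Bartonella/Commensalibacter with loss of minor taxa
#' (Apibacter, L. kunkeii), and foragers with roughly half the gut weight of
#' nurses and winter bees. Absolute scales (forager total load ~10^7.8 GE)
#' are free parameters chosen as plausible placeholders; only the ratios and
#' prevalences are anchored.
#'
#' @return list of class `bee_profiles` with elements `loads` (data.frame:
#'   `bee_type`, `taxon`, `log10_mean`, `log10_sd`, `detectability`),
#'   `gut_weight` (per-type mean/sd, mg) and `actin` (log10 mean/sd of actin
#'   copies per ul).
#' @export
default_profiles <- function() {
  core <- phylotypes()
  minor <- c("commensalibacter", "apibacter", "lkunkeii",
             "bombella", "klebsiella")
  sd_core <- c(0.4, 0.4, 0.5, 0.5, 0.4, 0.7, 0.8)
  det_core <- c(1, 1, 1, 0.984, 1, 0.731, 0.947)
  mu <- list(
    forager = c(7.0, 6.8, 6.6, 6.3, 7.2, 6.3, 5.8),
    nurse   = c(7.0, 6.9, 7.6, 7.3, 8.1, 6.3, 7.1),
    winter  = c(7.0, 7.1, 7.9, 7.7, 8.2, 5.3, 7.51))
  mu_minor <- list(
    forager = c(5.5, 5.0, 4.5, 4.5, 4.8),
    nurse   = c(5.5, 5.0, 4.5, 4.5, 4.8),
    winter  = c(6.8, 4.5, 4.5, 4.5, 4.8))
  det_minor <- list(
    forager = c(1, 1, 0.5, 0.4, 0.05),
    nurse   = c(1, 1, 0.5, 0.4, 0.80),
    winter  = c(1, 0.36, 0, 0.2, 0.05))
  loads <- do.call(rbind, lapply(names(mu), function(bt) {
    data.frame(bee_type = bt,
               taxon = c(core, minor),
               log10_mean = c(mu[[bt]], mu_minor[[bt]]),
               log10_sd = c(sd_core, rep(0.5, length(minor))),
               detectability = c(det_core, det_minor[[bt]]))
  }))
  structure(list(
    loads = loads,
    gut_weight = data.frame(bee_type = c("forager", "nurse", "winter"),
                            mean_mg = c(35, 70, 70),
                            sd_mg = c(8, 15, 15)),
    actin = list(log10_mean = 4.0, log10_sd = 0.2)),
    class = "bee_profiles")
}

#' Default qPCR assay definitions
#'
#' Standard-curve parameters, LODs and 16S operon numbers for the seven
#' phylotype assays, the host actin assay and the universal bacterial 16S
#' assay. Slopes/intercepts are realistic assay-sheet values; the operon
#' numbers are rrnDB-style per-phylotype values and are configuration, not
#' biological constants. LOD is 100 copies/ul for assays whose lowest
#' dilution is unreliable (Frischella, Snodgrassella, Bartonella, Firm-4,
#' Firm-5) and 10 copies/ul for the rest, with matching included dilution
#' ranges.
#'
#' @return named list of [standard_curve()] objects.
#' @export
default_curves <- function() {
  spec <- data.frame(
    target = c(phylotypes(), "actin", "universal"),
    slope = c(-3.40, -3.35, -3.45, -3.38, -3.42, -3.50, -3.30,
              -3.33, -3.36),
    intercept = c(37.5, 38.0, 37.0, 38.5, 38.2, 37.8, 38.8, 36.0, 38.0),
    lod = c(10, 100, 10, 100, 100, 100, 100, 10, 10),
    loci = c(4L, 4L, 3L, 4L, 4L, 4L, 2L, 1L, 1L))
  curves <- lapply(seq_len(nrow(spec)), function(i)
    standard_curve(target_id = spec$target[i], slope = spec$slope[i],
                   intercept = spec$intercept[i], lod_copies = spec$lod[i],
                   rrna_loci = spec$loci[i]))
  stats::setNames(curves, spec$target)
}

#' Default 16S operon numbers at the phylotype level
#'
#' @return named vector covering the seven monitored phylotypes and the
#'   minor community members of the default simulation.
#' @export
default_loci <- function() {
  c(gilliamella = 4, snodgrassella = 4, bifidobacterium = 3,
    firm4 = 4, firm5 = 4, frischella = 4, bartonella = 2,
    commensalibacter = 5, apibacter = 3, lkunkeii = 5,
    bombella = 2, klebsiella = 8)
}

#' Simulate individual bees from per-type community profiles
#'
#' For each bee and taxon, colonization is Bernoulli(detectability); a
#' colonized taxon's genome equivalents are `10^Normal(log10_mean,
#' log10_sd)`, a non-colonized taxon's are exactly zero. Gut weight is drawn
#' per type (normal, truncated at 5 mg) and actin copies per ul are
#' lognormal. The result carries the ground truth for recovery tests.
#'
#' @param n_per_type named integer vector, bees per type, e.g.
#'   `c(forager = 100, winter = 100)`.
#' @param profiles a `bee_profiles` object ([default_profiles()]).
#' @param hives number of hives; bees are assigned cyclically.
#' @param seed optional integer seed (generators are pure functions of
#'   config and seed).
#' @return object of class `simulated_bees`: `meta` (data.frame:
#'   `sample_id`, `bee_type`, `hive`, `month`, `gut_weight_mg`, `actin`)
#'   and `ge` (taxa x bees matrix of true genome equivalents).
#' @export
gen_hive <- function(n_per_type = c(forager = 100, nurse = 100,
                                    winter = 100),
                     profiles = default_profiles(), hives = 1,
                     seed = NULL) {
  if (any(n_per_type < 1)) stop("config error: n_per_type must be >= 1")
  bad <- profiles$loads$detectability < 0 | profiles$loads$detectability > 1
  if (any(bad)) stop("config error: detectability outside [0, 1]")
  if (any(profiles$loads$log10_sd < 0))
    stop("config error: negative log10_sd")
  if (!is.null(seed)) set.seed(seed)
  types <- rep(names(n_per_type), n_per_type)
  n <- length(types)
  ids <- sprintf("bee%03d", seq_len(n))
  taxa <- unique(profiles$loads$taxon)
  ge <- matrix(0, nrow = length(taxa), ncol = n,
               dimnames = list(taxa, ids))
  for (bt in unique(types)) {
    idx <- which(types == bt)
    prof <- profiles$loads[profiles$loads$bee_type == bt, , drop = FALSE]
    prof <- prof[match(taxa, prof$taxon), , drop = FALSE]
    for (t in seq_along(taxa)) {
      col <- stats::rbinom(length(idx), 1, prof$detectability[t]) == 1
      load <- 10^stats::rnorm(length(idx), prof$log10_mean[t],
                              prof$log10_sd[t])
      ge[t, idx] <- ifelse(col, load, 0)
    }
  }
  gw <- profiles$gut_weight[match(types, profiles$gut_weight$bee_type), ]
  meta <- data.frame(
    sample_id = ids, bee_type = types,
    hive = sprintf("H%02d", (seq_len(n) - 1L) %% hives + 1L),
    month = ifelse(types == "winter", "Jan", "Jul"),
    gut_weight_mg = pmax(5, stats::rnorm(n, gw$mean_mg, gw$sd_mg)),
    actin = 10^stats::rnorm(n, profiles$actin$log10_mean,
                            profiles$actin$log10_sd))
  structure(list(meta = meta, ge = ge), class = "simulated_bees")
}

#' @export
print.simulated_bees <- function(x, ...) {
  cat("Simulated bees:", nrow(x$meta), "guts,",
      nrow(x$ge), "taxa\n")
  print(table(x$meta$bee_type))
  invisible(x)
}

#' Simulate a Cq table from simulated bees
#'
#' The exact inverse of the quantification chain: for each bee and assayed
#' target, the template concentration is
#' `copies_per_ul = GE * loci * (actin_i / median(actin)) / 200`, and
#' `Cq = intercept + slope * log10(copies_per_ul) + Normal(0, sigma_cq)`.
#' The universal assay sees the summed `GE * loci` over all bacterial taxa.
#' True zeros are emitted as undetected (`NA`); concentrations below the
#' assay LOD are emitted at face value (the quantification chain applies the
#' LOD rule downstream). The batch median of the simulated actin draws is
#' used, so at `sigma_cq = 0` the chain returns the true genome equivalents
#' exactly.
#'
#' @param bees a `simulated_bees` object.
#' @param curves named list of [standard_curve()] objects
#'   ([default_curves()]); must cover every assayed target.
#' @param sigma_cq Cq noise sd (cycles), default 0.1.
#' @param replicates technical replicates per reaction.
#' @param extract_volume_ul DNA extract volume, matching the chain.
#' @param seed optional integer seed.
#' @return data.frame with columns `sample_id`, `target_id`, `replicate`,
#'   `cq` (`NA` = undetected).
#' @export
gen_cq <- function(bees, curves = default_curves(), sigma_cq = 0.1,
                   replicates = 1, extract_volume_ul = 200, seed = NULL) {
  stopifnot(inherits(bees, "simulated_bees"))
  if (!is.null(seed)) set.seed(seed)
  targets <- intersect(c(phylotypes(), "actin", "universal"), names(curves))
  missing <- setdiff(intersect(phylotypes(), rownames(bees$ge)),
                     targets)
  if (length(missing))
    stop("config error: no curve for target(s): ",
         paste(missing, collapse = ", "))
  actin <- bees$meta$actin
  med <- stats::median(actin)
  loci <- vapply(curves, `[[`, 1L, "rrna_loci")
  rows <- lapply(targets, function(tg) {
    copies <- switch(tg,
      actin = actin,
      universal = {
        tot <- colSums(bees$ge * default_loci()[rownames(bees$ge)])
        tot * (actin / med) / extract_volume_ul
      },
      bees$ge[tg, ] * loci[tg] * (actin / med) / extract_volume_ul)
    crv <- curves[[tg]]
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      cq <- ifelse(copies <= 0, NA_real_,
                   crv$intercept + crv$slope * log10(pmax(copies, 1e-300)) +
                     stats::rnorm(length(copies), 0, sigma_cq))
      data.frame(sample_id = bees$meta$sample_id, target_id = tg,
                 replicate = r, cq = cq)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate amplicon read counts and the universal 16S load
#'
#' Per sample, reads are multinomial with weights proportional to
#' `GE * rrna_loci` (higher-copy-number taxa are overrepresented in reads),
#' and the universal-assay load is the exact `sum(GE * loci)`. Optionally
#' pools guts by hive x bee type (arithmetic mean of per-gut genome
#' equivalents, emulating equal-mass pooled extractions), splits each core
#' phylotype into two sequence variants (binomial thinning) so that
#' phylotype collapsing is exercised, and adds off-target host mitochondrial
#' and pollen chloroplast reads that the QMP chain must exclude.
#'
#' @param bees a `simulated_bees` object.
#' @param depth reads per sample (default 27,000).
#' @param pooled pool guts by hive x bee type?
#' @param split_asvs split core phylotypes into two ASVs each?
#' @param offtarget_frac expected fraction of off-target (mitochondria +
#'   chloroplast) reads.
#' @param seed optional integer seed.
#' @return list with `counts` (taxa x samples integer matrix), `total_16s`
#'   (named vector), `taxonomy` (annotation data.frame for the QMP chain)
#'   and `truth_ge` (taxa x samples true genome equivalents, post pooling).
#' @export
gen_amplicon <- function(bees, depth = 27000, pooled = FALSE,
                         split_asvs = TRUE, offtarget_frac = 0.02,
                         seed = NULL) {
  stopifnot(inherits(bees, "simulated_bees"), depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  ge <- bees$ge
  if (pooled) {
    grp <- interaction(bees$meta$hive, bees$meta$bee_type, sep = "_",
                       drop = TRUE)
    ge <- t(apply(ge, 1, function(r) tapply(r, grp, mean)))
    colnames(ge) <- levels(grp)
  }
  loci <- default_loci()[rownames(ge)]
  w <- ge * loci
  total_16s <- colSums(w)
  if (any(total_16s <= 0))
    stop("degenerate sample: all-zero community in ",
         paste(colnames(ge)[total_16s <= 0], collapse = ", "))

  # off-target reads (host mitochondria; chloroplast from pollen)
  w_all <- if (offtarget_frac > 0) {
    scale <- offtarget_frac / (1 - offtarget_frac)
    rbind(w,
          host_mitochondria = 0.75 * scale * total_16s,
          pollen_chloroplast = 0.25 * scale * total_16s)
  } else w
  counts <- vapply(seq_len(ncol(w_all)), function(j)
    stats::rmultinom(1, depth, w_all[, j])[, 1],
    integer(nrow(w_all)))
  dimnames(counts) <- dimnames(w_all)

  tax <- data.frame(taxon_id = rownames(w),
                    phylotype = rownames(w),
                    category = ifelse(rownames(w) %in% phylotypes(),
                                      ifelse(rownames(w) %in%
                                               c("frischella", "bartonella"),
                                             "noncore", "core"),
                                      "minor"),
                    excluded_reason = "",
                    rrna_loci = unname(loci))
  if (split_asvs) {
    core <- intersect(phylotypes(), rownames(counts))
    extra <- matrix(0L, nrow = length(core), ncol = ncol(counts),
                    dimnames = list(paste0(core, "_asv2"), colnames(counts)))
    for (t in core) {
      second <- stats::rbinom(ncol(counts), counts[t, ], 0.4)
      extra[paste0(t, "_asv2"), ] <- second
      counts[t, ] <- counts[t, ] - second
    }
    rownames(counts)[match(core, rownames(counts))] <-
      paste0(core, "_asv1")
    counts <- rbind(counts, extra)
    tax2 <- tax[tax$taxon_id %in% core, ]
    tax <- tax[!tax$taxon_id %in% core, ]
    tax <- rbind(
      transform(tax2, taxon_id = paste0(taxon_id, "_asv1")),
      transform(tax2, taxon_id = paste0(taxon_id, "_asv2")),
      tax)
  }
  tax <- rbind(tax, data.frame(
    taxon_id = c("host_mitochondria", "pollen_chloroplast"),
    phylotype = c("host", "plant"),
    category = "excluded",
    excluded_reason = c("mitochondria", "chloroplast"),
    rrna_loci = 1))
  rownames(tax) <- NULL
  list(counts = counts, total_16s = total_16s, taxonomy = tax,
       truth_ge = ge)
}

#' Simulate the gnotobiotic colonization experiment
#'
#' Two arms of age-matched microbiota-depleted bees colonized with the
#' seven-phylotype community and fed sugar water only (SW) or sugar water
#' plus pollen (SW+P). Defaults encode the anchors the experiment is built
#' around: Bartonella colonizes only 75% and Frischella under half of the SW
#' bees (both colonize every SW+P bee), SW+P loads exceed SW loads, SW+P
#' guts weigh about twice as much as SW guts, and gut weight is positively
#' rank-correlated with total load (Gaussian-copula latent pair; the target
#' Spearman rho, default 0.7, is approximate — exact only at 0).
#'
#' @param n_per_arm named vector, e.g. `c(SW = 100, `SW+P` = 100)`.
#' @param rho target Spearman correlation between gut weight and total load.
#' @param seed optional integer seed.
#' @return a `simulated_bees` object whose `meta` has a `treatment` column.
#' @export
gen_colonization <- function(n_per_arm = c(SW = 100, `SW+P` = 100),
                             rho = 0.7, seed = NULL) {
  if (any(n_per_arm < 1)) stop("config error: n_per_arm must be >= 1")
  if (abs(rho) > 1) stop("config error: |rho| must be <= 1")
  if (!is.null(seed)) set.seed(seed)
  taxa <- phylotypes()
  mu_sw <- c(6.6, 6.4, 6.0, 5.9, 6.6, 5.3, 5.8)
  dmu_swp <- c(0.4, 0.3, 0.9, 0.9, 0.9, 1.0, 0.1)
  det_sw <- c(1, 1, 1, 1, 1, 0.45, 0.75)
  gw <- list(SW = c(35, 6), `SW+P` = c(70, 10))
  arms <- rep(names(n_per_arm), n_per_arm)
  n <- length(arms)
  ids <- sprintf("colbee%03d", seq_len(n))
  r <- 2 * sin(pi * rho / 6)            # copula: Spearman -> Pearson
  z_gut <- stats::rnorm(n)
  z_load <- r * z_gut + sqrt(1 - r^2) * stats::rnorm(n)
  ge <- matrix(0, length(taxa), n, dimnames = list(taxa, ids))
  weight <- numeric(n)
  for (arm in unique(arms)) {
    idx <- which(arms == arm)
    mu <- if (arm == "SW") mu_sw else mu_sw + dmu_swp
    det <- if (arm == "SW") det_sw else rep(1, length(taxa))
    for (t in seq_along(taxa)) {
      col <- stats::rbinom(length(idx), 1, det[t]) == 1
      load <- 10^(mu[t] + 0.4 * z_load[idx] +
                    stats::rnorm(length(idx), 0, 0.3))
      ge[t, idx] <- ifelse(col, load, 0)
    }
    weight[idx] <- pmax(5, gw[[arm]][1] + gw[[arm]][2] * z_gut[idx])
  }
  meta <- data.frame(sample_id = ids, bee_type = "experimental",
                     hive = "lab", month = "lab",
                     treatment = arms, gut_weight_mg = weight,
                     actin = 10^stats::rnorm(n, 4.0, 0.2))
  structure(list(meta = meta, ge = ge), class = "simulated_bees")
}

#' Write a complete synthetic fixture set
#'
#' Simulates a multi-hive survey and writes every input table the pipeline
#' consumes: `standards.tsv` (noisy dilution series per assay),
#' `cq_table.tsv`, `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, and
#' `truth.tsv` (ground-truth genome equivalents for recovery tests).
#'
#' @param dir output directory (created if needed).
#' @param n_per_type bees per type.
#' @param hives number of hives.
#' @param depth amplicon reads per sample.
#' @param sigma_cq Cq noise sd.
#' @param pooled pool amplicon samples by hive x bee type? Default `FALSE`
#'   so that the amplicon and qPCR tables share per-gut sample ids.
#' @param seed integer seed.
#' @return invisibly, the list of written file paths.
#' @export
simulate_dataset <- function(dir, n_per_type = c(forager = 20, nurse = 20,
                                                 winter = 20),
                             hives = 2, depth = 27000, sigma_cq = 0.1,
                             pooled = FALSE, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  curves <- default_curves()
  bees <- gen_hive(n_per_type, hives = hives)
  cq <- gen_cq(bees, curves, sigma_cq = sigma_cq)
  amp <- gen_amplicon(bees, depth = depth, pooled = pooled)

  standards <- do.call(rbind, lapply(curves, function(crv) {
    copies <- rep(10^(1:7), each = 2)
    data.frame(target_id = crv$target_id, copies_per_ul = copies,
               cq = predict(crv, copies) +
                 stats::rnorm(length(copies), 0, 0.15))
  }))
  truth <- data.frame(sample_id = rep(colnames(bees$ge),
                                      each = nrow(bees$ge)),
                      taxon = rep(rownames(bees$ge), ncol(bees$ge)),
                      ge = as.vector(bees$ge))
  paths <- list(
    standards = file.path(dir, "standards.tsv"),
    cq_table = file.path(dir, "cq_table.tsv"),
    counts = file.path(dir, "counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_tsv_precise(standards, paths$standards)
  write_tsv_precise(cq, paths$cq_table)
  write_counts(amp$counts, paths$counts)
  write_tsv_precise(amp$taxonomy, paths$taxonomy)
  write_tsv_precise(bees$meta, paths$metadata)
  write_tsv_precise(truth, paths$truth)
  invisible(paths)
}
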