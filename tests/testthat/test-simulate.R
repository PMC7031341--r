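test_that("generators are pure functions of config and seed", {
  b1 <- gen_hive(c(forager = 10, winter = 10), seed = 50)
  b2 <- gen_hive(c(forager = 10, winter = 10), seed = 50)
  expect_identical(b1, b2)
  expect_identical(gen_cq(b1, sigma_cq = 0.1, seed = 51),
                   gen_cq(b2, sigma_cq = 0.1, seed = 51))
  expect_identical(gen_amplicon(b1, depth = 1000, seed = 52),
                   gen_amplicon(b2, depth = 1000, seed = 52))
  expect_identical(gen_colonization(c(SW = 5, `SW+P` = 5), seed = 53),
                   gen_colonization(c(SW = 5, `SW+P` = 5), seed = 53))
})

test_that("detectability controls colonization exactly at the extremes", {
  prof <- default_profiles()
  prof$loads$detectability[prof$loads$taxon == "gilliamella"] <- 0
  bees <- gen_hive(c(forager = 50), profiles = prof, seed = 54)
  expect_true(all(bees$ge["gilliamella", ] == 0))
  expect_true(all(bees$ge["firm5", ] > 0))
  bad <- default_profiles()
  bad$loads$detectability[1] <- 1.5
  expect_error(gen_hive(c(forager = 2), profiles = bad), "config error")
})

test_that("default profiles encode the prevalence and load-ratio anchors", {
  bees <- gen_hive(c(forager = 500, winter = 500), seed = 55)
  ge <- bees$ge
  f4 <- mean(ge["firm4", ] > 0)
  expect_lt(abs(f4 - 0.984), 3 * sqrt(0.984 * 0.016 / 1000))
  fri_below <- mean(ge["frischella", ] == 0)
  expect_lt(abs(fri_below - 0.269), 3 * sqrt(0.269 * 0.731 / 1000))
  bt <- bees$meta$bee_type
  tot <- colSums(ge[phylotypes(), ])
  ratio <- mean(tot[bt == "winter"]) / mean(tot[bt == "forager"])
  expect_lt(abs(ratio - 10) / 10, 0.25)
  # winter bees lose the minor taxa
  expect_equal(sum(ge["lkunkeii", bt == "winter"]), 0)
  expect_gt(mean(ge["lkunkeii", bt == "forager"] > 0), 0.3)
})

test_that("the Cq chain inverts the quantification formulas exactly", {
  bees <- gen_hive(c(forager = 15), seed = 56)
  cq <- gen_cq(bees, sigma_cq = 0, seed = 57)
  ab <- quantify_samples(cq, default_curves())
  truth <- bees$ge[phylotypes(), ]
  for (tg in phylotypes()) {
    sub <- ab[ab$target_id == tg, ]
    est <- setNames(sub$n_ge, sub$sample_id)[colnames(truth)]
    true_v <- truth[tg, ]
    # above-LOD loads recovered to 1e-6 relative, zeros stay zero
    lod_ge <- default_curves()[[tg]]$lod_copies * 200 /
      default_curves()[[tg]]$rrna_loci
    ok <- true_v > 10 * lod_ge  # margin for the actin-ratio spread
    if (any(ok))
      expect_equal(est[ok], true_v[ok], tolerance = 1e-6)
    expect_true(all(est[true_v == 0] == 0))
  }
  # GE = 0 is emitted as undetected
  zero_rows <- cq$cq[cq$target_id == "frischella"][
    bees$ge["frischella", ] == 0]
  expect_true(all(is.na(zero_rows)))
})

test_that("Cq noise propagates to log10 GE by the delta method", {
  bees <- gen_hive(c(winter = 400), seed = 58)
  cq <- gen_cq(bees, sigma_cq = 0.2, seed = 59)
  ab <- quantify_samples(cq, default_curves())
  crv <- default_curves()[["firm5"]]
  sub <- ab[ab$target_id == "firm5" & !ab$below_lod, ]
  est <- setNames(sub$n_ge, sub$sample_id)
  true_v <- bees$ge["firm5", names(est)]
  err <- log10(est) - log10(true_v)
  # target and actin Cq noise both enter the normalized copy number
  actin <- default_curves()[["actin"]]
  expected_sd <- sqrt((0.2 * log10(crv$efficiency))^2 +
                      (0.2 * log10(actin$efficiency))^2)
  expect_lt(abs(mean(err)), 3 * expected_sd / sqrt(length(err)))
  expect_lt(abs(sd(err) - expected_sd) / expected_sd, 0.15)
})

test_that("amplicon weights are genome equivalents times operon number", {
  # equal GE, loci 4 (gilliamella) vs 2 (bartonella): 2:1 expected reads
  ge <- matrix(1e6, 2, 1, dimnames = list(c("gilliamella", "bartonella"),
                                          "s1"))
  bees <- structure(list(
    meta = data.frame(sample_id = "s1", bee_type = "forager", hive = "H01",
                      month = "Jul", gut_weight_mg = 35, actin = 1e4),
    ge = ge), class = "simulated_bees")
  amp <- gen_amplicon(bees, depth = 1e6, split_asvs = FALSE,
                      offtarget_frac = 0, seed = 60)
  ratio <- amp$counts["gilliamella", 1] / amp$counts["bartonella", 1]
  expect_lt(abs(ratio - 2), 0.05)
  expect_equal(unname(amp$total_16s), 1e6 * 4 + 1e6 * 2)
  # large depth: proportions converge to the weights
  p_hat <- amp$counts[, 1] / sum(amp$counts[, 1])
  expect_equal(unname(p_hat), c(4, 2) / 6, tolerance = 0.01)
  # all-zero community is rejected
  bees$ge[] <- 0
  expect_error(gen_amplicon(bees, depth = 100), "degenerate")
})

test_that("pooling averages guts and QMP recovers pooled truth", {
  bees <- gen_hive(c(forager = 20, winter = 20), hives = 2, seed = 61)
  amp <- gen_amplicon(bees, depth = 50000, pooled = TRUE, seed = 62)
  expect_equal(ncol(amp$counts), 4)  # 2 hives x 2 bee types
  grp <- interaction(bees$meta$hive, bees$meta$bee_type, sep = "_",
                     drop = TRUE)
  manual <- tapply(bees$ge["firm5", ], grp, mean)
  expect_equal(amp$truth_ge["firm5", names(manual)], manual,
               tolerance = 1e-12, ignore_attr = TRUE)
  q <- qmp_pipeline(amp$counts, amp$taxonomy, amp$total_16s)
  common <- intersect(rownames(q$abs_ge), rownames(amp$truth_ge))
  props <- sweep(amp$truth_ge * default_loci()[rownames(amp$truth_ge)],
                 2, amp$total_16s, "/")
  sel <- props[common, ] > 0.02
  rel <- abs(q$abs_ge[common, ][sel] - amp$truth_ge[common, ][sel]) /
    amp$truth_ge[common, ][sel]
  expect_lt(median(rel), 0.05)
})

test_that("colonization arms encode prevalence, weight and correlation", {
  bees <- gen_colonization(c(SW = 300, `SW+P` = 300), seed = 63)
  tr <- bees$meta$treatment
  sw <- tr == "SW"
  bar <- mean(bees$ge["bartonella", sw] > 0)
  expect_lt(abs(bar - 0.75), 3 * sqrt(0.75 * 0.25 / 300))
  fri <- mean(bees$ge["frischella", sw] > 0)
  expect_lt(abs(fri - 0.45), 3 * sqrt(0.45 * 0.55 / 300))
  expect_true(all(bees$ge["bartonella", !sw] > 0))
  gw <- bees$meta$gut_weight_mg
  expect_lt(abs(mean(gw[!sw]) / mean(gw[sw]) - 2), 0.2)
  # SW+P carries higher loads
  tot <- colSums(bees$ge)
  expect_gt(mean(tot[!sw]) / mean(tot[sw]), 2)
  # gut weight and load are rank-correlated; switch off at rho = 0
  expect_gt(spearman_rho(gw[sw], tot[sw]), 0.4)
  b0 <- gen_colonization(c(SW = 500), rho = 0, seed = 64)
  expect_lt(abs(spearman_rho(b0$meta$gut_weight_mg, colSums(b0$ge))),
            0.15)
})
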