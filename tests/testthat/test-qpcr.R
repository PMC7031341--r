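test_that("raw copies invert the curve and apply the LOD rule", {
  crv <- doubling_curve(lod_copies = 100)
  expect_equal(raw_copies(crv, 30)$n_raw, 1024)  # 2^10
  und <- raw_copies(crv, NA_real_)
  expect_equal(und$n_raw, 0)
  expect_true(und$below_lod)
  # Cq beyond the LOD Cq is unquantifiable even though detected
  past <- raw_copies(crv, 35)
  expect_true(past$below_lod)
  expect_equal(past$n_raw, 0)
  expect_error(raw_copies(crv, 30, target_id = "other"), "input error")
})

test_that("cq -> copies round-trips over the quantifiable range", {
  crv <- standard_curve("t", slope = -3.48, intercept = 37.2,
                        lod_copies = 100)
  true_copies <- 10^seq(log10(100), 9, length.out = 25)
  cq <- crv$intercept + crv$slope * log10(true_copies)
  got <- raw_copies(crv, cq)
  expect_false(any(got$below_lod))
  expect_equal(got$n_raw, true_copies, tolerance = 1e-6)
  # monotone: higher Cq, fewer copies
  cqs <- seq(10, crv$lod_cq - 1e-6, length.out = 50)
  expect_true(all(diff(raw_copies(crv, cqs)$n_raw) < 0))
})

test_that("actin normalization follows (n_raw/n_actin)*median*200", {
  expect_equal(normalize_per_gut(1024, 512, 512), 204800)
  expect_equal(normalize_per_gut(1024, 2000, 1000), 102400)
  expect_equal(normalize_per_gut(0, 2000, 1000), 0)
  expect_error(normalize_per_gut(10, 0, 1000), "sample failure")
  # neutrality: when every sample sits at the median, n_abs = n_raw * 200
  n_raw <- runif(10, 1, 1e5)
  expect_equal(normalize_per_gut(n_raw, 777, 777), n_raw * 200)
})

test_that("genome equivalents divide by the operon number", {
  expect_equal(genome_equivalents(204800, 4), 51200)
  expect_equal(genome_equivalents(123.4, 1), 123.4)
  expect_error(genome_equivalents(10, 0), "rrna_loci")
})

test_that("summed load adds the phylotype set with below-LOD as zero", {
  ab <- data.frame(sample_id = "s1", target_id = phylotypes(),
                   n_ge = c(10, 20, 0, 0, 0, 0, 5))
  expect_equal(unname(summed_load(ab)), 35)
  ab$n_ge <- 0
  expect_equal(unname(summed_load(ab)), 0)
  # off-list targets are ignored
  ab2 <- rbind(ab, data.frame(sample_id = "s1", target_id = "universal",
                              n_ge = 999))
  expect_equal(unname(summed_load(ab2)), 0)
})

test_that("quantify_samples averages replicates on the Cq scale", {
  crv <- doubling_curve(target_id = "firm5")
  actin_crv <- standard_curve("actin", slope = -1 / log10(2),
                              intercept = 36, lod_copies = 10, rrna_loci = 1)
  cq <- data.frame(
    sample_id = "s1",
    target_id = c("firm5", "firm5", "actin"),
    replicate = c(1, 2, 1),
    cq = c(30, 32, 36 - log10(500) / log10(2)))  # actin = 500 copies/ul
  out <- quantify_samples(cq, list(firm5 = crv, actin = actin_crv),
                          median_actin = 500)
  expect_equal(out$n_raw, 2^(40 - 31))  # mean Cq 31, not mean copies
  expect_equal(out$n_actin, 500, tolerance = 1e-9)
  expect_equal(out$n_abs, out$n_raw * 200, tolerance = 1e-9)
  expect_equal(out$n_ge, out$n_abs / 4, tolerance = 1e-9)
})

test_that("below-LOD records are zeroed and never contribute downstream", {
  crv <- doubling_curve(target_id = "firm5")
  actin_crv <- standard_curve("actin", slope = -1 / log10(2),
                              intercept = 36, lod_copies = 10, rrna_loci = 1)
  cq <- data.frame(sample_id = c("s1", "s1", "s2", "s2"),
                   target_id = c("firm5", "actin", "firm5", "actin"),
                   replicate = 1,
                   cq = c(30, 27, NA, 27))
  out <- quantify_samples(cq, list(firm5 = crv, actin = actin_crv))
  s2 <- out[out$sample_id == "s2", ]
  expect_true(s2$below_lod)
  expect_equal(s2$n_raw + s2$n_abs + s2$n_ge, 0)
  expect_equal(unname(summed_load(out, "firm5")["s2"]), 0)
})

test_that("samples with failed actin amplification are excluded", {
  crv <- doubling_curve(target_id = "firm5")
  actin_crv <- standard_curve("actin", slope = -1 / log10(2),
                              intercept = 36, lod_copies = 10, rrna_loci = 1)
  cq <- data.frame(sample_id = c("ok", "ok", "bad", "bad"),
                   target_id = c("firm5", "actin", "firm5", "actin"),
                   replicate = 1,
                   cq = c(30, 27, 30, NA))
  expect_warning(out <- quantify_samples(cq, list(firm5 = crv,
                                                  actin = actin_crv)),
                 "actin")
  expect_equal(out$sample_id, "ok")
})

test_that("the universal assay reports n_abs, not genome equivalents", {
  uni <- standard_curve("universal", slope = -1 / log10(2), intercept = 40,
                        lod_copies = 10, rrna_loci = 1)
  actin_crv <- standard_curve("actin", slope = -1 / log10(2),
                              intercept = 36, lod_copies = 10, rrna_loci = 1)
  cq <- data.frame(sample_id = "s1", target_id = c("universal", "actin"),
                   replicate = 1, cq = c(25, 27))
  out <- quantify_samples(cq, list(universal = uni, actin = actin_crv))
  expect_true(is.na(out$n_ge))
  expect_gt(out$n_abs, 0)
})
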