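make_tax <- function(ids, phylo = ids, category = "core", reason = "",
                     loci = 4) {
  data.frame(taxon_id = ids, phylotype = phylo, category = category,
             excluded_reason = reason, rrna_loci = loci)
}

test_that("off-target taxa are removed without touching other counts", {
  m <- random_counts(5, 4, seed = 2)
  tax <- make_tax(rownames(m))
  tax$category[3] <- "excluded"; tax$excluded_reason[3] <- "chloroplast"
  out <- exclude_off_target(m, tax)
  expect_equal(rownames(out), rownames(m)[-3])
  expect_identical(out, m[-3, ])
  # identity when nothing is excluded
  expect_identical(exclude_off_target(m, make_tax(rownames(m))), m)
  # degenerate: everything excluded
  tax_all <- make_tax(rownames(m), category = "excluded",
                      reason = "mitochondria")
  expect_warning(empty <- exclude_off_target(m, tax_all), "all taxa")
  expect_equal(nrow(empty), 0)
  expect_error(exclude_off_target(m, make_tax(rownames(m)[-1])),
               "unannotated")
})

test_that("abundance filter is the two-predicate conjunction", {
  m <- matrix(0L, 3, 5, dimnames = list(c("a", "b", "c"), paste0("s", 1:5)))
  m["a", 1] <- 9L            # one sample, 9 reads: out
  m["b", 1:2] <- 5L          # two samples, 10 reads: boundary, in
  m["c", 1:3] <- 100L
  out <- abundance_filter(m)
  expect_equal(rownames(out), c("b", "c"))

  # brute force over a random matrix
  r <- random_counts(20, 10, seed = 3, lambda = 1)
  kept <- rownames(abundance_filter(r, min_samples = 2, min_total = 10))
  expected <- rownames(r)[vapply(seq_len(nrow(r)), function(i)
    sum(r[i, ] > 0) >= 2 && sum(r[i, ]) >= 10, logical(1))]
  expect_equal(kept, expected)
})

test_that("phylotype collapsing sums variants and conserves totals", {
  m <- matrix(c(3L, 7L, 2L, 1L, 4L, 9L), 3, 2,
              dimnames = list(c("f5_a", "f5_b", "gil_a"), c("s1", "s2")))
  tax <- make_tax(rownames(m), phylo = c("firm5", "firm5", "gilliamella"))
  out <- collapse_phylotypes(m, tax)
  expect_equal(out["firm5", "s1"], 10)
  expect_equal(colSums(out), colSums(m))
  # one variant per phylotype: identity up to relabeling
  tax2 <- make_tax(rownames(m), phylo = paste0("p", 1:3))
  out2 <- collapse_phylotypes(m, tax2)
  expect_equal(unname(out2[order(rownames(out2)), ]),
               unname(m[order(paste0("p", 1:3)), ]))
  tax$phylotype[2] <- NA
  expect_error(collapse_phylotypes(m, tax), "missing phylotype")
})

test_that("proportions are per-sample and sum to one", {
  m <- matrix(c(50L, 30L, 20L), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(taxon_proportions(m)[, 1]), c(0.5, 0.3, 0.2))
  one <- matrix(7L, 1, 1, dimnames = list("a", "s1"))
  expect_equal(unname(taxon_proportions(one)[1, 1]), 1.0)
  r <- random_counts(8, 6, seed = 4)
  expect_equal(unname(colSums(taxon_proportions(r))), rep(1, 6),
               tolerance = 1e-12)
  bad <- r; bad[, 2] <- 0L
  expect_error(taxon_proportions(bad), "s2")
})

test_that("QMP scaling divides the 16S load by the operon number", {
  props <- matrix(c(0.5, 0.3, 0.2), 3, 1,
                  dimnames = list(c("a", "b", "c"), "s1"))
  q <- to_absolute(props, c(s1 = 1e6), c(a = 4, b = 3, c = 2))
  expect_equal(unname(q$abs_ge[, 1]), c(125000, 1e5, 1e5))
  # loci of one: abs_ge = props * total
  q1 <- to_absolute(props, c(s1 = 1e6), c(a = 1, b = 1, c = 1))
  expect_equal(unname(q1$abs_ge[, 1]), c(5e5, 3e5, 2e5))
  # invariant: sum(abs_ge * loci) returns the total load
  expect_equal(unname(colSums(q$abs_ge * q$rrna_loci)),
               unname(q$total_16s), tolerance = 1e-6)
  expect_error(to_absolute(props, c(s1 = 1e6), c(a = 4, b = 3)),
               "rrna_loci")
})

test_that("the pipeline applies its stages in the published order", {
  set.seed(9)
  m <- random_counts(12, 6, seed = 9, lambda = 30)
  tax <- make_tax(rownames(m),
                  phylo = rep(c("firm5", "gilliamella", "bartonella",
                                "host"), each = 3),
                  loci = rep(c(4, 4, 2, 1), each = 3))
  tax$category <- ifelse(tax$phylotype == "host", "excluded", "core")
  tax$excluded_reason <- ifelse(tax$category == "excluded",
                                "mitochondria", "")
  # make one taxon fail the abundance filter
  m[2, ] <- 0L; m[2, 1] <- 4L
  total <- setNames(runif(6, 1e6, 1e7), colnames(m))
  q <- qmp_pipeline(m, tax, total)

  manual <- exclude_off_target(m, tax)
  manual <- abundance_filter(manual)
  manual <- collapse_phylotypes(manual, tax)
  manual_props <- taxon_proportions(manual)
  expect_equal(q$props, manual_props)
  # copy-number identity: abs_ge * loci / total == proportions exactly
  back <- sweep(q$abs_ge * q$rrna_loci, 2, q$total_16s, "/")
  expect_equal(back, q$props, tolerance = 1e-12)
  # a swapped order (collapse before filter) changes the result
  swapped <- collapse_phylotypes(exclude_off_target(m, tax), tax)
  swapped <- abundance_filter(swapped)
  expect_false(isTRUE(all.equal(taxon_proportions(swapped), manual_props)))
})

test_that("zero reads mean zero absolute abundance (amplicon LOD)", {
  m <- matrix(c(0L, 50L, 12L, 38L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tax <- make_tax(rownames(m), loci = c(2, 4))
  q <- qmp_pipeline(m, tax, c(s1 = 1e6, s2 = 1e6), min_samples = 1,
                    min_total = 1)
  expect_equal(q$abs_ge["a", "s1"], 0)
  expect_gt(q$abs_ge["a", "s2"], 0)
})
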