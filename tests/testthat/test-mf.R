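test_that("deduplication collapses within-sample clones only", {
  m <- data.frame(
    sample_id = c("s1", "s1", "s1", "s1", "s2"),
    chrom = "chr1", pos = c(5, 5, 5, 9, 5),
    ref = "C", alt = "A", multiplicity = 1L,
    stringsAsFactors = FALSE
  )
  dd <- deduplicate(m)
  # 3 identical records + 1 distinct in s1, the same variant again in s2
  expect_equal(nrow(dd$unique[dd$unique$sample_id == "s1", ]), 2L)
  expect_equal(nrow(dd$unique), 3L) # no cross-sample collapsing
  expect_equal(dd$clonal_extra, 2L)

  one <- data.frame(sample_id = "s1", chrom = "chr1", pos = 5,
                    ref = "C", alt = "A", multiplicity = 5L)
  dd5 <- deduplicate(one)
  expect_equal(nrow(dd5$unique), 1L)
  expect_equal(dd5$clonal_extra, 4L)
})

test_that("MF arithmetic matches direct calculation and clone accounting", {
  m <- tiny_mutations()
  est <- compute_mf(m, tiny_depths(), tiny_metadata(), tiny_panel(),
                    by = "sample")
  s1 <- est[est$sample_id == "s1", ]
  # 2 unique with multiplicities (1, 3) over 2e7 bp
  expect_equal(s1$mf, 2 / 2e7)
  expect_equal(s1$mf_clonal, 4 / 2e7)
  expect_true(all(est$mf_clonal >= est$mf))
})

test_that("compute_mf agrees with a brute-force recount on small cohorts", {
  cfg <- small_config(depth_mean = 5e6, n_per_dose = 2L)
  coh <- generate_cohort(cfg, seed = 8)
  dd <- deduplicate(coh$mutations)$unique
  expect_lte(nrow(dd), 150L)
  for (by in list("dose", "sample", c("dose", "region_class"))) {
    est <- compute_mf(dd, coh$depths, coh$metadata, cfg$panel, by = by)
    # oracle: loop over rows, recount from raw records
    for (i in seq_len(nrow(est))) {
      keep_m <- rep(TRUE, nrow(dd))
      keep_d <- rep(TRUE, nrow(coh$depths))
      dose_of <- coh$metadata$dose[match(dd$sample_id, coh$metadata$sample_id)]
      dose_of_d <- coh$metadata$dose[match(coh$depths$sample_id,
                                           coh$metadata$sample_id)]
      rc_of <- cfg$panel$region_class[match(dd$target, cfg$panel$name)]
      rc_of_d <- cfg$panel$region_class[match(coh$depths$target,
                                              cfg$panel$name)]
      if ("dose" %in% names(est)) {
        keep_m <- keep_m & dose_of == est$dose[i]
        keep_d <- keep_d & dose_of_d == est$dose[i]
      }
      if ("sample_id" %in% names(est)) {
        keep_m <- keep_m & dd$sample_id == est$sample_id[i]
        keep_d <- keep_d & coh$depths$sample_id == est$sample_id[i]
      }
      if ("region_class" %in% names(est)) {
        keep_m <- keep_m & rc_of == est$region_class[i]
        keep_d <- keep_d & rc_of_d == est$region_class[i]
      }
      expect_identical(est$n_mutations[i], sum(keep_m))
      expect_equal(est$duplex_bp[i], sum(coh$depths$duplex_bp[keep_d]))
      expect_equal(est$mf[i], sum(keep_m) / sum(coh$depths$duplex_bp[keep_d]))
    }
  }
})

test_that("cohort MF is the depth-weighted mean of per-sample MFs", {
  cfg <- small_config(depth_mean = 2e7, n_per_dose = 3L)
  coh <- generate_cohort(cfg, seed = 14)
  dd <- deduplicate(coh$mutations)$unique
  whole <- compute_mf(dd, coh$depths, coh$metadata, by = "cohort")
  per_s <- compute_mf(dd, coh$depths, coh$metadata, by = "sample")
  expect_equal(whole$mf,
               sum(per_s$mf * per_s$duplex_bp) / sum(per_s$duplex_bp),
               tolerance = 1e-12)
})

test_that("fold change and percent reduction reproduce the printed contrasts", {
  expect_equal(round(fold_change(3.3e-7, 1.3e-7), 1), 2.5)
  expect_equal(round(fold_change(6.8e-7, 1.3e-7), 1), 5.2)
  expect_equal(round(fold_change(10.4e-7, 1.3e-7), 1), 8.0)
  expect_equal(fold_change(4e-7, 4e-7), 1)
  expect_error(fold_change(1e-7, 0), "positive")

  expect_equal(round(percent_reduction(1.35e-7, 1.04e-7)), 23)
  expect_equal(round(percent_reduction(8.8e-7, 5.1e-7)), 42)
  expect_equal(percent_reduction(5e-7, 5e-7), 0)
  expect_error(percent_reduction(0, 1e-7), "positive")
})

test_that("Holm-Sidak adjustment is monotone, dominated by 1 and step-down", {
  # worked example: m = 2, raw (0.01, 0.04) -> (1 - 0.99^2, 0.04)
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # non-decreasing in the sorted raw order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("dose contrasts behave at the null and detect the simulated effect", {
  # symmetric null: identical counts and depths in both groups
  depths <- data.frame(sample_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
                       target = rep(c("t1", "t2"), 4), duplex_bp = 1e7)
  muts <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2"), target = "t1", chrom = "chr1",
    pos = c(101, 102, 101, 102), ref = "C", alt = "A", var_class = "SNV",
    multiplicity = 1L, tri_context = "ACA", stringsAsFactors = FALSE
  )
  meta <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                     dose = c(0, 0, 50, 50), group = c("c", "c", "t", "t"))
  ct <- fit_binomial_dose_model(muts, depths, meta)
  expect_equal(ct$estimate, 0, tolerance = 1e-9)
  expect_equal(ct$p_raw, 1)

  # simulated dose effect: every exposed dose separates from control
  cfg <- small_config(depth_mean = 1e8, n_per_dose = 3L)
  coh <- generate_cohort(cfg, seed = 9)
  dd <- deduplicate(coh$mutations)$unique
  ct2 <- fit_binomial_dose_model(dd, coh$depths, coh$metadata)
  expect_equal(nrow(ct2), 3L)
  expect_true(all(ct2$p_adjusted < 0.001))
  expect_true(all(ct2$p_adjusted >= ct2$p_raw))
})

test_that("a zero-count dose group triggers the continuity correction", {
  depths <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                       target = "t1", duplex_bp = 1e6)
  muts <- data.frame(
    sample_id = c("b1", "b2"), target = "t1", chrom = "chr1",
    pos = c(101, 102), ref = "C", alt = "A", var_class = "SNV",
    multiplicity = 1L, tri_context = "ACA", stringsAsFactors = FALSE
  )
  meta <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                     dose = c(0, 0, 50, 50), group = c("c", "c", "t", "t"))
  expect_warning(ct <- fit_binomial_dose_model(muts, depths, meta),
                 "continuity")
  expect_true(is.finite(ct$wald_z))
})

test_that("GC grouping test is null-calibrated and detects a built-in effect", {
  cfg <- small_config(depth_mean = 1e8, n_per_dose = 3L)
  coh <- generate_cohort(cfg, seed = 19)
  dd <- deduplicate(coh$mutations)$unique

  # an explicit 42.9% threshold reproduces the intended grouping
  g <- gc_group_test(dd, coh$depths, coh$metadata, cfg$panel,
                     gc_threshold = 0.429)
  expect_equal(g$n_low + g$n_high, 20L)
  expect_true(g$p >= 0 && g$p <= 1)
  expect_error(
    gc_group_test(dd, coh$depths, coh$metadata, cfg$panel, gc_threshold = 0.9),
    "one GC group"
  )

  # flat cohort (no modifiers): GC term should be null ~uniformly
  cfg0 <- small_config(depth_mean = 1e8, n_per_dose = 3L)
  cfg0$genic_reduction[] <- 0
  cfg0$heterochromatin_multiplier <- 1
  ps <- vapply(1:5, function(s) {
    coh0 <- generate_cohort(cfg0, seed = 100 + s)
    dd0 <- deduplicate(coh0$mutations)$unique
    gc_group_test(dd0, coh0$depths, coh0$metadata, cfg0$panel)$p
  }, numeric(1))
  expect_gt(max(ps), 0.05) # not all significant under the null

  # 2x multiplier on high-GC targets: strong signal at this depth
  cfg2 <- small_config(depth_mean = 2e8, n_per_dose = 3L)
  cfg2$genic_reduction[] <- 0
  cfg2$heterochromatin_multiplier <- 1
  hits <- vapply(1:3, function(s) {
    coh2 <- generate_cohort(cfg2, seed = 200 + s)
    m <- coh2$mutations
    # thin low-GC targets to emulate a 2x high-GC effect
    hi_gc <- cfg2$panel$name[cfg2$panel$gc_fraction > mean(cfg2$panel$gc_fraction)]
    keep <- m$target %in% hi_gc |
      (seq_len(nrow(m)) %% 2L == 0L)
    dd2 <- deduplicate(m[keep, ])$unique
    gc_group_test(dd2, coh2$depths, coh2$metadata, cfg2$panel)$p < 0.05
  }, logical(1))
  expect_true(all(hits))
})
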