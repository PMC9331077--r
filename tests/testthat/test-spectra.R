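test_that("single-mutation spectra and marginal conservation hold", {
  m <- tiny_mutations()[1, ] # A[C>A]... context ACG, C>A
  s <- build_spectrum96(m, normalization = "proportion")
  expect_equal(unname(s["A[C>A]G"]), 1)
  expect_equal(sum(s), 1)

  cfg <- small_config(depth_mean = 5e7, n_per_dose = 2L)
  coh <- generate_cohort(cfg, seed = 23)
  dd <- deduplicate(coh$mutations)$unique
  s96 <- build_spectrum96(dd)
  s6 <- build_spectrum6(dd)
  # conservation: total SNVs equal the channel sum; marginals match
  expect_equal(sum(s96), sum(dd$var_class == "SNV"))
  cls <- substr(names(s96), 3L, 5L)
  for (k in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")) {
    expect_equal(unname(s6$counts[k]), sum(s96[cls == k]))
  }
  expect_equal(sum(s6$counts),
               nrow(dd))
  expect_equal(sum(s6$proportions), 1)
})

test_that("spectra are invariant to reverse-complementing the input calls", {
  cfg <- small_config(depth_mean = 2e7, n_per_dose = 1L)
  coh <- generate_cohort(cfg, seed = 29)
  dd <- deduplicate(coh$mutations)$unique
  snv <- dd[dd$var_class == "SNV", ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc3 <- function(s) vapply(strsplit(s, ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
  flipped <- snv
  flipped$ref <- unname(comp[snv$ref])
  flipped$alt <- unname(comp[snv$alt])
  flipped$tri_context <- rc3(snv$tri_context)
  # contexts stay stored pyrimidine-normalized
  flip_back <- substr(flipped$tri_context, 2L, 2L) %in% c("A", "G")
  flipped$tri_context[flip_back] <- rc3(flipped$tri_context[flip_back])
  expect_equal(build_spectrum96(flipped), build_spectrum96(snv))
})

test_that("per-bp and per-context normalizations rescale counts correctly", {
  cfg <- small_config(depth_mean = 5e7, n_per_dose = 1L)
  coh <- generate_cohort(cfg, seed = 31)
  dd <- deduplicate(coh$mutations)$unique
  bp <- sum(coh$depths$duplex_bp)
  counts <- build_spectrum96(dd)
  per_bp <- build_spectrum96(dd, "per_bp", duplex_bp = bp)
  expect_equal(as.numeric(per_bp), as.numeric(counts) / bp)

  ab <- colSums(panel_tri_abundance(cfg$panel))
  pcb <- build_spectrum96(dd, "per_context_bp", duplex_bp = bp,
                          tri_abundance = ab)
  # reconstruct one channel by hand
  ch <- "C[C>A]C"
  depth_per_site <- bp / sum(ab)
  expect_equal(unname(pcb[ch]),
               unname(counts[ch] / (ab["CCC"] * depth_per_site)))
  expect_error(build_spectrum96(dd, "per_context_bp", duplex_bp = bp),
               "tri_abundance")
})

test_that("spectrum homogeneity test calibrates at both extremes", {
  flat <- matrix(c(10, 10, 10, 10), 2, 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  r <- spectrum_contingency_test(flat, B = 999, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_overall, 1)

  apart <- matrix(c(50, 0, 0, 50), 2, 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("x", "y")))
  r2 <- spectrum_contingency_test(apart, B = 9999, seed = 1)
  expect_lte(r2$p_overall, 2 / 10000)
  expect_error(spectrum_contingency_test(rbind(a = c(0, 0), b = c(5, 5))),
               "zero total")
})

test_that("exposed vs control spectra differ, driven by C>A", {
  cfg <- small_config(depth_mean = 3e8, n_per_dose = 3L)
  coh <- generate_cohort(cfg, seed = 37)
  dd <- deduplicate(coh$mutations)$unique
  meta <- coh$metadata
  groups <- c(0, 50)
  tab <- t(vapply(groups, function(d) {
    sub <- dd[dd$sample_id %in% meta$sample_id[meta$dose == d], ]
    build_spectrum6(sub)$counts[1:6]
  }, numeric(6)))
  rownames(tab) <- c("control", "high")
  r <- spectrum_contingency_test(tab, control = "control", B = 999, seed = 5)
  expect_lt(r$p_overall, 0.01)
  ca <- r$per_class[r$per_class$class == "C>A", ]
  expect_lt(ca$p_adjusted, 0.01)
})

test_that("CpG site mutation fraction counts distinct sites once", {
  p <- tiny_panel()
  # t2 = CCGG repeated: site inventory from the sequence
  sites <- panel_cpg_sites(p)
  expect_equal(length(sites$t2), 25L) # one CG per CCGG repeat
  n_sites <- sum(lengths(sites))

  # two mutations at the same CpG (C on plus strand and G on minus strand)
  m <- data.frame(
    sample_id = c("s1", "s2"), target = "t2", chrom = "chr2",
    pos = c(202, 203), # local positions 2 (C of CG) and 3 (G of the same CG)
    ref = c("C", "G"), alt = c("A", "T"), var_class = "SNV",
    multiplicity = 1L, tri_context = c("CCG", "CCG"),
    stringsAsFactors = FALSE
  )
  r <- cpg_mutated_fraction(m, p)
  expect_equal(r$n_mutated, 1L)
  expect_equal(r$fraction, 1 / n_sites)

  none <- m[0, ]
  expect_equal(cpg_mutated_fraction(none, p)$fraction, 0)
})

test_that("CpG mutation fraction rises with dose in the default cohort", {
  cfg <- small_config(depth_mean = 1e8, n_per_dose = 2L)
  coh <- generate_cohort(cfg, seed = 41)
  dd <- deduplicate(coh$mutations)$unique
  meta <- coh$metadata
  fr <- vapply(c(0, 50), function(d) {
    sub <- dd[dd$sample_id %in% meta$sample_id[meta$dose == d], ]
    cpg_mutated_fraction(sub, cfg$panel)$fraction
  }, numeric(1))
  expect_gt(fr[2], fr[1])
})
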